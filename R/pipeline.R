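# End-to-end orchestration: simulate -> demultiplex -> assign -> cluster ->
# diversity -> compare -> phylogeny -> biomass, with a flat key-value
# configuration, a read-count ledger, and report tables mirroring the
# survey summaries (per-sample diversity table, group proportions,
# fold changes).

#' Default pipeline configuration
#'
#' All analysis parameters default to the conventional values for 18S tag
#' pyrosequencing surveys: BLAST E-value 1e-5, MEGAN min-score 5,
#' top-percent 1 and min-support 1, OTU identity 0.97, taxon validation at
#' 3 reads, representative length floor 400 nt, 1000 bootstrap replicates.
#' Simulation sizes are a desk-scale version of a two-date bloom survey:
#' a pre-bloom sample and a bloom sample whose read totals keep the
#' roughly 1:2.2 ratio of the original dates, with the bloom taxon at 90%
#' of the bloom-date community.
#'
#' @param seed master integer seed; every stage derives its own stream
#'   from it.
#' @param ... named overrides of any default.
#' @return a named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    sample_a = "mar", sample_b = "apr",
    tag_a = "ACGTACGTAC", tag_b = "TGCATGCATG",
    # simulation
    n_families = 3L, genera_per_family = 3L, species_per_genus = 3L,
    n_taxa = 10L, community_ratio = 0.7, bloom_fraction = 0.9,
    bloom_rank = 4L,
    n_reads_a = 180L, n_reads_b = 410L,
    error_rate = 0.01, p_full = 0.30, min_len = 150L, mean_extra = 130,
    # demultiplexing
    primer_mismatches = 1L,
    # LCA binning
    e_max = 1e-5, min_score = 5, top_percent = 1, min_support = 1L,
    # OTU / diversity
    identity_threshold = 0.97, min_reads = 3L,
    representative_min_len = 400L,
    # phylogeny
    bootstrap_replicates = 1000L,
    # output
    out_dir = "")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$e_max > 0, cfg$min_score > 0, cfg$top_percent > 0,
            cfg$min_support >= 1,
            cfg$identity_threshold > 0.5, cfg$identity_threshold <= 1,
            cfg$min_reads >= 1, cfg$representative_min_len >= 1,
            cfg$bootstrap_replicates >= 1,
            cfg$bloom_fraction > 0, cfg$bloom_fraction < 1,
            cfg$error_rate >= 0, cfg$error_rate <= 0.2,
            cfg$n_reads_a >= 1, cfg$n_reads_b >= 1)
  invisible(cfg)
}

#' Write and read a pipeline configuration
#'
#' Flat `key=value` serialization; the round trip write -> read -> write
#' is byte-identical.
#'
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return `read_config()` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) format(v, digits = 15, scientific = FALSE)
    else as.character(v)
  }, character(1))
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  template <- default_config()
  cfg <- template
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(template)) stop("unknown config key: ", k)
    proto <- template[[k]]
    cfg[[k]] <- if (is.integer(proto)) as.integer(vals[i])
    else if (is.numeric(proto)) as.numeric(vals[i])
    else vals[i]
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

# bloom-date community: same taxa as the pre-bloom community, with the
# taxon ranked `bloom_rank` promoted to `bloom_fraction` of the community
# and the rest sharing the remainder geometrically in their original order.
bloom_community <- function(community_a, bloom_fraction, bloom_rank,
                            ratio, sample_id) {
  ids <- community_a$taxa$ref_id
  bloom_rank <- min(bloom_rank, length(ids))
  bloom <- ids[bloom_rank]
  rest <- setdiff(ids, bloom)
  if (length(rest)) {
    w <- ratio^(seq_along(rest) - 1)
    ab <- c(bloom_fraction, (1 - bloom_fraction) * w / sum(w))
  } else {
    ab <- 1
  }
  structure(list(sample_id = sample_id,
                 taxa = data.frame(ref_id = c(bloom, rest), abundance = ab,
                                   stringsAsFactors = FALSE),
                 bloom_taxon = bloom),
            class = "community_profile")
}

#' Default microscopy scenario for the simulated survey
#'
#' Two dates spanning a *Phaeocystis*-type bloom. Abundances are set so
#' that, at the dimension means, the phytoplankton stock runs from about
#' 43 to about 1440 ug C L^-1 between the dates (a ~34-fold increase,
#' driven by colonies and diatoms) and the microzooplankton stock
#' (heterotrophic ciliates plus dinoflagellates) from about 6.3 to about
#' 26.4 ug C L^-1 (~4-fold), the magnitudes typical of an eastern English
#' Channel spring bloom; dimension jitter adds a few percent of noise.
#'
#' @param date_a,date_b date labels.
#' @return a list of taxon specs for [generate_microscopy_table()].
#' @export
default_microscopy_specs <- function(date_a = "mar", date_b = "apr") {
  ab <- function(a, b) setNames(c(a, b), c(date_a, date_b))
  list(
    list(taxon = "Phaeocystis colonies", group = "phaeocystis_colony",
         trophic = "auto", shape = "sphere",
         abundance = ab(1.5e2, 9.0e4), dims_mean = 60, dims_sd = 3),
    list(taxon = "Rhizosolenia-like diatom", group = "diatom",
         trophic = "auto", shape = "cylinder",
         abundance = ab(1.7e4, 1.1e5), dims_mean = c(150, 20),
         dims_sd = c(8, 1)),
    list(taxon = "Guinardia-like diatom", group = "diatom",
         trophic = "auto", shape = "cylinder",
         abundance = ab(7.0e3, 1.4e5), dims_mean = c(60, 18),
         dims_sd = c(3, 1)),
    list(taxon = "autotrophic nanoflagellates", group = "nanoflagellate",
         trophic = "auto", shape = "sphere",
         abundance = ab(5.0e5, 6.0e6), dims_mean = 5, dims_sd = 0.3),
    list(taxon = "Gyrodinium-like dinoflagellate",
         group = "dinoflagellate", trophic = "hetero",
         shape = "prolate_spheroid", abundance = ab(2.5e3, 1.0e4),
         dims_mean = c(50, 20), dims_sd = c(3, 1)),
    list(taxon = "Strombidium-like ciliate", group = "ciliate",
         trophic = "hetero", shape = "cone",
         abundance = ab(1.45e3, 6.4e3), dims_mean = c(40, 30),
         dims_sd = c(2, 1.5)),
    list(taxon = "heterotrophic nanoflagellates", group = "nanoflagellate",
         trophic = "hetero", shape = "sphere",
         abundance = ab(7.7e5, 5.7e6), dims_mean = 4, dims_sd = 0.2))
}

#' Run the full simulated-survey pipeline
#'
#' Executes simulate -> demultiplex -> align/assign (LCA) -> cluster ->
#' diversity -> between-date comparison -> phylogeny of the bloom family's
#' OTU representatives -> microscopy biomass, keeping a read-count ledger
#' at every stage (inputs = outputs + itemized drops). Fully reproducible
#' from the config seed; when `config$out_dir` is set, all artifacts
#' (FASTA, TSV tables, Newick tree, config) are written there.
#'
#' @param config a [default_config()] configuration.
#' @return a `run_report` list: `config`, `ledger`, `scheme`, `truth`,
#'   `group_proportions`, `diversity`, `rarefaction`, `otu_matrix`,
#'   `compare`, `tree`, `biomass`, `fold_changes`.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  seed <- config$seed
  ledger <- list()
  note <- function(stage, input, output, dropped = input - output) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      stage = stage, input = input, output = output, dropped = dropped,
      stringsAsFactors = FALSE)
  }

  ## -- simulate ----------------------------------------------------------
  db <- generate_reference_db(config$n_families, config$genera_per_family,
                              config$species_per_genus,
                              seed = derive_seed(seed, 1L))
  scheme <- tag_scheme(setNames(c(config$tag_a, config$tag_b),
                                c(config$sample_a, config$sample_b)))
  comm_a <- generate_community(db, config$n_taxa, seed = derive_seed(seed, 2L),
                               ratio = config$community_ratio,
                               sample_id = config$sample_a)
  comm_b <- bloom_community(comm_a, config$bloom_fraction,
                            config$bloom_rank, config$community_ratio,
                            config$sample_b)
  lm <- length_model(config$p_full, config$min_len, config$mean_extra)
  gen_a <- generate_reads(comm_a, db, scheme, config$n_reads_a,
                          config$error_rate, lm,
                          seed = derive_seed(seed, 3L))
  gen_b <- generate_reads(comm_b, db, scheme, config$n_reads_b,
                          config$error_rate, lm,
                          seed = derive_seed(seed, 4L))
  raw <- c(gen_a$reads, gen_b$reads)
  truth <- rbind(gen_a$truth, gen_b$truth)
  note("simulate", config$n_reads_a + config$n_reads_b, length(raw), 0L)

  ## -- demultiplex -------------------------------------------------------
  dmx <- demultiplex(raw, scheme, config$primer_mismatches)
  n_assigned <- sum(vapply(dmx$samples, function(s) length(s$reads),
                           integer(1)))
  note("demultiplex", length(raw), n_assigned)
  qc <- do.call(rbind, lapply(dmx$samples, function(s) {
    cbind(sample = s$sample_id, length_stats(s))
  }))

  ## -- LCA assignment ----------------------------------------------------
  group_proportions <- list()
  assignments <- list()
  for (sid in names(dmx$samples)) {
    reads <- dmx$samples[[sid]]$reads
    hits <- align_reads(reads, db)
    asg <- assign_reads(hits, db, names(reads),
                        e_max = config$e_max, min_score = config$min_score,
                        top_percent = config$top_percent)
    tree <- taxonomy_counts(build_taxonomy(db), asg)
    tree <- apply_min_support(tree, config$min_support)
    group_proportions[[sid]] <- summarize_groups(tree, unique(db$family))
    assignments[[sid]] <- asg
    note(paste0("assign_", sid), length(reads), nrow(asg))
  }

  ## -- OTU clustering and diversity -------------------------------------
  cleaned <- unlist(lapply(dmx$samples, function(s) s$reads))
  names(cleaned) <- unlist(lapply(dmx$samples, function(s) names(s$reads)))
  read_samples <- setNames(
    unlist(lapply(dmx$samples, function(s) {
      rep(s$sample_id, length(s$reads))
    }), use.names = FALSE),
    unlist(lapply(dmx$samples, function(s) names(s$reads)),
           use.names = FALSE))
  otus <- cluster_greedy(cleaned, config$identity_threshold)
  val <- validate_taxa(otus, config$min_reads)
  validated <- select_representatives(val$validated, cleaned,
                                      config$representative_min_len)
  note("cluster", length(cleaned),
       sum(vapply(otus, function(o) length(o$members), integer(1))), 0L)
  note("validate_taxa",
       length(otus), length(validated),
       length(val$rejected))
  m_all <- otu_counts(otus, read_samples)
  diversity <- diversity_summary(m_all)
  rarefaction <- lapply(colnames(m_all), function(s) {
    rarefaction_curve(m_all[, s])
  })
  names(rarefaction) <- colnames(m_all)

  ## -- between-date comparison ------------------------------------------
  m_val <- otu_counts(validated, read_samples)
  compare <- compare_samples(m_val,
                             sample_a = config$sample_a,
                             sample_b = config$sample_b)
  bloom_otu <- NA_character_
  for (o in validated) {
    tr <- truth$ref_id[match(o$members, truth$read_id)]
    if (mean(tr == comm_b$bloom_taxon) > 0.5) { bloom_otu <- o$otu_id; break }
  }

  ## -- phylogeny of the bloom family ------------------------------------
  bloom_family <- db$family[db$ref_id == comm_b$bloom_taxon]
  fam_refs <- setNames(db$sequence[db$family == bloom_family],
                       paste0("ref_", db$ref_id[db$family == bloom_family]))
  rep_ids <- vapply(validated, function(o) o$representative, character(1))
  rep_seqs <- cleaned[rep_ids[!is.na(rep_ids)]]
  tree <- NULL
  if (length(rep_seqs) >= 2) {
    aln <- align_representatives(c(rep_seqs, fam_refs))
    tree <- bootstrap_support(aln, config$bootstrap_replicates,
                              seed = derive_seed(seed, 5L))
  }

  ## -- biomass -----------------------------------------------------------
  micro <- generate_microscopy_table(
    default_microscopy_specs(config$sample_a, config$sample_b),
    seed = derive_seed(seed, 6L))
  biomass <- community_biomass(micro)
  fold_changes <- fold_change_summary(biomass$category_stocks)

  report <- list(config = config,
                 ledger = do.call(rbind, ledger),
                 scheme = scheme, truth = truth, qc = qc,
                 communities = list(a = comm_a, b = comm_b),
                 group_proportions = group_proportions,
                 assignments = assignments,
                 diversity = diversity, rarefaction = rarefaction,
                 otu_matrix = m_all, validated_otus = validated,
                 compare = compare, bloom_otu = bloom_otu,
                 tree = tree, microscopy = micro, biomass = biomass,
                 fold_changes = fold_changes)
  class(report) <- "run_report"
  if (nzchar(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write_config(report$config, file.path(out_dir, "config.txt"))
  tsv(report$ledger, "ledger.tsv")
  tsv(report$diversity, "diversity.tsv")
  tsv(report$qc, "length_qc.tsv")
  tsv(do.call(rbind, lapply(names(report$group_proportions), function(s) {
    cbind(sample = s, report$group_proportions[[s]])
  })), "group_proportions.tsv")
  tsv(cbind(otu_id = rownames(report$otu_matrix),
            as.data.frame(report$otu_matrix)), "otu_table.tsv")
  tsv(report$compare, "relative_change.tsv")
  tsv(do.call(rbind, lapply(names(report$rarefaction), function(s) {
    cbind(sample = s, report$rarefaction[[s]])
  })), "rarefaction.tsv")
  write_truth_table(report$truth, file.path(out_dir, "truth.tsv"))
  tsv(report$biomass$records, "biomass_records.tsv")
  tsv(report$biomass$category_stocks, "biomass_stocks.tsv")
  tsv(report$fold_changes, "fold_changes.tsv")
  if (!is.null(report$tree)) {
    write_newick(report$tree, file.path(out_dir, "bloom_family_nj.nwk"))
  }
  invisible(out_dir)
}

#' Between-date relative change per OTU
#'
#' Applies the normalized relative-change statistic
#' `R = (n_B / N_B) / (n_A / N_A)` to every OTU of a two-sample count
#' matrix, flagging taxa absent from one date as `"new"` or `"lost"`.
#'
#' @param count_matrix OTU-by-sample count matrix with exactly two
#'   columns.
#' @param sample_a,sample_b column names of the earlier and later date
#'   (default: first and second column).
#' @return a `data.frame` with `otu_id`, `n_a`, `n_b`, `R`, `status`,
#'   ordered by decreasing `R` among present taxa.
#' @export
compare_samples <- function(count_matrix,
                            sample_a = colnames(count_matrix)[1],
                            sample_b = colnames(count_matrix)[2]) {
  if (ncol(count_matrix) != 2L) {
    stop("between-date comparison needs exactly 2 samples, got ",
         ncol(count_matrix))
  }
  n_a <- count_matrix[, sample_a]
  n_b <- count_matrix[, sample_b]
  total_a <- sum(n_a)
  total_b <- sum(n_b)
  r <- relative_change(n_a, n_b, total_a, total_b)
  out <- data.frame(otu_id = rownames(count_matrix),
                    n_a = as.integer(n_a), n_b = as.integer(n_b),
                    R = as.numeric(r), status = attr(r, "status"),
                    stringsAsFactors = FALSE)
  out <- out[out$status != "absent", , drop = FALSE]
  out[order(-ifelse(is.finite(out$R), out$R, Inf)), , drop = FALSE]
}
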