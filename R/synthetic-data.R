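# Synthetic fixtures: ranked reference database, bloom-structured
# communities, tagged error-laden 454-style reads, and microscopy tables.
# Everything is seeded; the same seed gives bit-identical output.

#' Tag scheme for demultiplexing 454-style amplicon reads
#'
#' Each sample is identified by a 10-nt tag followed by the fixed 4-nt
#' instrument key `TCAG` and the forward PCR primer. Defaults use the
#' universal eukaryote 18S primer pair 18S-82F / Ek-516r that amplifies the
#' ~470-480 bp V2-V3 region.
#'
#' @param tags named character vector of 10-nt sample tags; names are sample
#'   ids. Tags must be pairwise distinct.
#' @param key 4-nt instrument key; the 454 standard is `"TCAG"`.
#' @param fwd_primer,rev_primer forward and reverse primer sequences (5'-3').
#' @return an object of class `tag_scheme`.
#' @examples
#' tag_scheme(c(mar = "ACGTACGTAC", apr = "TGCATGCATG"))
#' @export
tag_scheme <- function(tags,
                       key = "TCAG",
                       fwd_primer = "GAAACTGCGAATGGCTC",
                       rev_primer = "ACCAGACTTGCCCTCC") {
  if (is.null(names(tags)) || any(!nzchar(names(tags)))) {
    stop("'tags' must be a named character vector (names are sample ids)")
  }
  if (anyDuplicated(tags)) stop("sample tags must be pairwise distinct")
  if (any(nchar(tags) != 10L)) stop("every tag must be exactly 10 nt")
  if (nchar(key) != 4L) stop("the instrument key must be 4 nt")
  structure(list(tags = tags, key = key,
                 fwd_primer = fwd_primer, rev_primer = rev_primer),
            class = "tag_scheme")
}

#' Generate a ranked-taxonomy reference database
#'
#' Emulates a small SSU rRNA reference: an ancestral ~V2-V3 sequence is
#' mutated down a family -> genus -> species rank tree at per-rank rates
#' chosen so that expected pairwise divergence is about `genus_div` within a
#' genus, `family_div` within a family, and `between_div` between families.
#' This ordering is what makes 97% OTU clustering and LCA binning meaningful
#' on synthetic data.
#'
#' @param n_families,genera_per_family,species_per_genus positive counts.
#' @param seed integer seed; the same seed gives identical output.
#' @param seq_length reference sequence length in nt (default 500, the
#'   approximate amplified V2-V3 span).
#' @param genus_div,family_div,between_div target expected pairwise
#'   divergences (proportions) within genus / within family / between
#'   families; must be increasing.
#' @return a `data.frame` with columns `ref_id`, `family`, `genus`,
#'   `species`, `lineage` (a `rank:name;...` path) and `sequence`.
#' @examples
#' db <- generate_reference_db(2, 2, 2, seed = 7)
#' nrow(db)  # 8
#' @export
generate_reference_db <- function(n_families, genera_per_family,
                                  species_per_genus, seed,
                                  seq_length = 500L,
                                  genus_div = 0.02,
                                  family_div = 0.08,
                                  between_div = 0.15) {
  counts <- c(n_families, genera_per_family, species_per_genus)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("n_families, genera_per_family and species_per_genus must be ",
         "positive integers")
  }
  if (!(genus_div < family_div && family_div < between_div)) {
    stop("divergence parameters must satisfy genus < family < between-family")
  }
  # Per-branch substitution rates: two branches separate any pair at a rank,
  # and deeper divergence adds to the shallower one.
  sp_rate  <- genus_div / 2
  gen_rate <- (family_div - genus_div) / 2
  fam_rate <- (between_div - family_div) / 2
  with_seed(seed, {
    root <- random_dna(seq_length)
    out <- vector("list", prod(counts))
    k <- 0L
    for (f in seq_len(n_families)) {
      fam_name <- sprintf("Fam%02d", f)
      fam_seq <- mutate_seq(root, fam_rate)
      for (g in seq_len(genera_per_family)) {
        gen_name <- sprintf("%s_Gen%02d", fam_name, g)
        gen_seq <- mutate_seq(fam_seq, gen_rate)
        for (s in seq_len(species_per_genus)) {
          sp_name <- sprintf("%s_Sp%02d", gen_name, s)
          k <- k + 1L
          out[[k]] <- data.frame(
            ref_id = sprintf("F%02dG%02dS%02d", f, g, s),
            family = fam_name, genus = gen_name, species = sp_name,
            lineage = sprintf("family:%s;genus:%s;species:%s",
                              fam_name, gen_name, sp_name),
            sequence = mutate_seq(gen_seq, sp_rate),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Generate a bloom-structured community profile
#'
#' Relative abundances follow a geometric series (a standard rank-abundance
#' model for plankton assemblages); optionally one taxon is promoted to a
#' "bloom" taxon holding a fixed fraction of the community, emulating the
#' dominance of *Phaeocystis globosa* during its spring bloom.
#'
#' @param db reference database from [generate_reference_db()].
#' @param n_taxa number of community members (`<= nrow(db)`).
#' @param bloom_fraction optional proportion in (0, 1) assigned to the bloom
#'   taxon; remaining taxa share `1 - bloom_fraction` geometrically.
#' @param seed integer seed.
#' @param ratio geometric decay ratio between successive ranked taxa.
#' @param spread `"any"` samples taxa freely; `"family"` picks at most one
#'   taxon per family, giving well-separated community members.
#' @param sample_id label for the sample.
#' @return a list of class `community_profile` with elements `sample_id`,
#'   `taxa` (data.frame `ref_id`, `abundance`) and `bloom_taxon`.
#' @export
generate_community <- function(db, n_taxa, bloom_fraction = NULL, seed,
                               ratio = 0.5, spread = c("any", "family"),
                               sample_id = "S1") {
  spread <- match.arg(spread)
  if (n_taxa < 1) stop("n_taxa must be >= 1")
  if (n_taxa > nrow(db)) stop("n_taxa exceeds the reference database size")
  if (!is.null(bloom_fraction) &&
      (bloom_fraction <= 0 || bloom_fraction >= 1)) {
    stop("bloom_fraction must lie strictly between 0 and 1")
  }
  with_seed(seed, {
    if (spread == "family") {
      fams <- unique(db$family)
      if (n_taxa > length(fams)) {
        stop("spread = 'family' requires n_taxa <= number of families")
      }
      picked_fams <- sample(fams, n_taxa)
      ids <- vapply(picked_fams, function(f) {
        sample(db$ref_id[db$family == f], 1L)
      }, character(1), USE.NAMES = FALSE)
    } else {
      ids <- sample(db$ref_id, n_taxa)
    }
    if (is.null(bloom_fraction)) {
      ab <- ratio^(seq_len(n_taxa) - 1)
      ab <- ab / sum(ab)
      bloom <- NULL
    } else if (n_taxa == 1L) {
      ab <- 1
      bloom <- ids[1]
    } else {
      rest <- ratio^(seq_len(n_taxa - 1) - 1)
      ab <- c(bloom_fraction, (1 - bloom_fraction) * rest / sum(rest))
      bloom <- ids[1]
    }
    structure(list(sample_id = sample_id,
                   taxa = data.frame(ref_id = ids, abundance = ab,
                                     stringsAsFactors = FALSE),
                   bloom_taxon = bloom),
              class = "community_profile")
  })
}

#' Default read-length attrition model
#'
#' A two-component mixture emulating 454 length attrition: a fraction
#' `p_full` of reads keep the full insert, the rest are truncated to
#' `min_len` plus a geometric excess with mean `mean_extra`. The defaults
#' put roughly 75% of reads above 200 bp and 40% above 400 bp for a
#' ~480-500 nt insert, the attrition observed in coastal 18S tag
#' pyrosequencing runs.
#'
#' @param p_full probability a read keeps the full insert.
#' @param min_len minimum truncated insert length (nt).
#' @param mean_extra mean geometric excess beyond `min_len` (nt).
#' @return a list of the three parameters.
#' @export
length_model <- function(p_full = 0.30, min_len = 150L, mean_extra = 130) {
  stopifnot(p_full >= 0, p_full <= 1, min_len >= 1, mean_extra > 0)
  list(p_full = p_full, min_len = as.integer(min_len),
       mean_extra = mean_extra)
}

#' Generate tagged, error-laden amplicon reads
#'
#' Reads are sampled multinomially from a community profile. Each raw read
#' is `tag + key + forward primer + insert`, where the insert is the
#' reference V2-V3 sequence, possibly truncated per the length model and
#' point-mutated at `error_rate` per base. A truth table recording each
#' read's source reference accompanies the reads.
#'
#' @param community a `community_profile`.
#' @param db reference database covering every community `ref_id`.
#' @param scheme a [tag_scheme()] whose tags include `community$sample_id`.
#' @param n_reads number of reads to generate.
#' @param error_rate per-base substitution probability in `[0, 0.2]`.
#' @param lmodel a [length_model()]; use `length_model(p_full = 1)` for
#'   full-length reads.
#' @param seed integer seed.
#' @param revcomp_fraction fraction of reads emitted reverse-complemented
#'   (off by default; the tagged-end protocol reads forward).
#' @return a list with `reads` (named character vector of raw reads) and
#'   `truth` (data.frame `read_id`, `ref_id`, `insert_length`).
#' @export
generate_reads <- function(community, db, scheme, n_reads,
                           error_rate = 0.01, lmodel = length_model(),
                           seed, revcomp_fraction = 0) {
  if (!inherits(community, "community_profile")) {
    stop("'community' must come from generate_community()")
  }
  if (nrow(community$taxa) == 0L) stop("community is empty")
  if (error_rate < 0 || error_rate > 0.2) {
    stop("error_rate must lie in [0, 0.2]")
  }
  sid <- community$sample_id
  if (!sid %in% names(scheme$tags)) {
    stop("tag scheme has no tag for sample '", sid, "'")
  }
  refseq <- setNames(db$sequence, db$ref_id)
  missing <- setdiff(community$taxa$ref_id, names(refseq))
  if (length(missing)) {
    stop("community taxa absent from db: ", paste(missing, collapse = ", "))
  }
  prefix <- paste0(scheme$tags[[sid]], scheme$key, scheme$fwd_primer)
  with_seed(seed, {
    origin <- sample(community$taxa$ref_id, n_reads, replace = TRUE,
                     prob = community$taxa$abundance)
    full_len <- nchar(refseq[origin])
    keep_full <- runif(n_reads) < lmodel$p_full
    trunc_len <- lmodel$min_len +
      rgeom(n_reads, prob = 1 / (lmodel$mean_extra + 1))
    ins_len <- ifelse(keep_full, full_len, pmin(full_len, trunc_len))
    ids <- sprintf("%s_r%05d", sid, seq_len(n_reads))
    inserts <- vapply(seq_len(n_reads), function(i) {
      mutate_seq(substr(refseq[[origin[i]]], 1L, ins_len[i]), error_rate)
    }, character(1))
    reads <- paste0(prefix, inserts)
    if (revcomp_fraction > 0) {
      flip <- runif(n_reads) < revcomp_fraction
      reads[flip] <- revcomp(reads[flip])
    }
    list(reads = setNames(reads, ids),
         truth = data.frame(read_id = ids, ref_id = unname(origin),
                            insert_length = unname(ins_len),
                            stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic microscopy count table
#'
#' Emulates inverted-microscope and epifluorescence count sheets: one row
#' per taxon per date with cell abundance and lognormally jittered linear
#' dimensions (length, width/diameter) around stated means.
#'
#' @param groups list of taxon specs; each a list with `taxon`, `group`
#'   (one of `diatom`, `dinoflagellate`, `ciliate`, `nanoflagellate`,
#'   `phaeocystis_colony`), `trophic` (`auto`, `hetero`, `mixo`), `shape`
#'   (a registered geometric shape, see [biovolume()]), `abundance` (named
#'   numeric vector: date -> cells per litre), `dims_mean` (dimension means,
#'   um) and optional `dims_sd` (same length; default 0 = no jitter).
#' @param seed integer seed.
#' @return a `data.frame` with one row per taxon x date: `taxon`, `group`,
#'   `trophic`, `shape`, `date`, `abundance_cells_per_L`, `dim1_um`,
#'   `dim2_um` (NA for one-dimension shapes).
#' @export
generate_microscopy_table <- function(groups, seed) {
  valid_groups <- c("diatom", "dinoflagellate", "ciliate", "nanoflagellate",
                    "phaeocystis_colony")
  with_seed(seed, {
    rows <- lapply(groups, function(g) {
      if (!g$group %in% valid_groups) {
        stop("unknown plankton group: ", g$group)
      }
      nd <- shape_dim_count(g$shape)  # errors on unknown shape
      if (length(g$dims_mean) != nd) {
        stop("shape '", g$shape, "' needs ", nd, " dimension(s)")
      }
      sds <- if (is.null(g$dims_sd)) rep(0, nd) else g$dims_sd
      trophic <- if (is.null(g$trophic)) "auto" else g$trophic
      dates <- names(g$abundance)
      do.call(rbind, lapply(dates, function(d) {
        dims <- vapply(seq_len(nd), function(i) {
          m <- g$dims_mean[i]; s <- sds[i]
          if (s <= 0) return(m)
          sigma <- sqrt(log(1 + (s / m)^2))
          rlnorm(1, meanlog = log(m) - sigma^2 / 2, sdlog = sigma)
        }, numeric(1))
        data.frame(taxon = g$taxon, group = g$group, trophic = trophic,
                   shape = g$shape, date = d,
                   abundance_cells_per_L = unname(g$abundance[[d]]),
                   dim1_um = dims[1],
                   dim2_um = if (nd >= 2) dims[2] else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
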