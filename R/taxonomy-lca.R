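# MEGAN-style taxonomic binning: per-read hit filtering (E-value,
# min-score, top-percent), lowest-common-ancestor assignment over a ranked
# lineage table, min-support pruning, and group summaries. A built-in
# seed-and-extend aligner stands in for external BLASTN so the whole stage
# runs download-free.

#' Filter BLAST hits per read before LCA assignment
#'
#' Retains, within each query, hits with `evalue <= e_max` and
#' `bitscore >= min_score`, and among those only hits whose bit score lies
#' within `top_percent` percent of the best retained score
#' (`bitscore >= (1 - top_percent/100) * best`). Defaults are the standard
#' MEGAN settings for 18S tag reads: E-value 1e-5, min-score 5,
#' top-percent 1.
#'
#' @param hits hit `data.frame` (see [read_hit_table()]); may span several
#'   queries, filtering is per `qseqid`.
#' @param e_max maximum E-value.
#' @param min_score minimum bit score.
#' @param top_percent percentage band below the best bit score.
#' @return the retained hits, same columns; attribute `audit` holds per-query
#'   counts of hits seen and retained.
#' @export
filter_hits <- function(hits, e_max = 1e-5, min_score = 5, top_percent = 1) {
  if (e_max <= 0 || min_score <= 0 || top_percent <= 0) {
    stop("filter parameters must be positive")
  }
  if (nrow(hits) == 0L) {
    attr(hits, "audit") <- data.frame(qseqid = character(),
                                      seen = integer(), retained = integer())
    return(hits)
  }
  pass1 <- hits$evalue <= e_max & hits$bitscore >= min_score
  keep <- logical(nrow(hits))
  for (q in unique(hits$qseqid)) {
    idx <- which(hits$qseqid == q & pass1)
    if (length(idx)) {
      best <- max(hits$bitscore[idx])
      keep[idx] <- hits$bitscore[idx] >= (1 - top_percent / 100) * best
    }
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  seen <- table(hits$qseqid)
  ret <- table(factor(out$qseqid, levels = names(seen)))
  attr(out, "audit") <- data.frame(qseqid = names(seen),
                                   seen = as.integer(seen),
                                   retained = as.integer(ret),
                                   stringsAsFactors = FALSE)
  out
}

# Parse "rank:name;rank:name;..." into a named character vector
# (names = ranks, values = node names); empty string -> length 0.
parse_lineage <- function(lineage) {
  if (is.na(lineage) || !nzchar(lineage)) return(character(0))
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  setNames(vapply(kv, `[`, character(1), 2L),
           vapply(kv, `[`, character(1), 1L))
}

#' Lowest-common-ancestor assignment for one read
#'
#' The read is placed on the deepest taxonomy node lying on every retained
#' hit's lineage. With no retained hits the read is binned as `"No hits"`;
#' when retained hits exist but none of their references carries a
#' resolvable lineage, the read is `"Not assigned"`; disjoint lineages
#' collapse to the root.
#'
#' @param retained_hits retained hits for a single read (after
#'   [filter_hits()]).
#' @param lineages named list mapping `ref_id` to a parsed lineage (named
#'   character vector, ranks to node names), e.g. from [lineage_lookup()].
#' @return a list with `node` (node name, or `"No hits"` / `"Not assigned"`
#'   / `"root"`), `rank` and `path` (the lineage down to `node`).
#' @export
assign_lca <- function(retained_hits, lineages) {
  if (nrow(retained_hits) == 0L) {
    return(list(node = "No hits", rank = "reserved", path = character(0)))
  }
  refs <- unique(retained_hits$sseqid)
  missing <- setdiff(refs, names(lineages))
  if (length(missing)) {
    stop("ref_id absent from lineage table: ",
         paste(missing, collapse = ", "))
  }
  lins <- lineages[refs]
  has_lineage <- vapply(lins, length, integer(1)) > 0L
  if (!any(has_lineage)) {
    return(list(node = "Not assigned", rank = "reserved",
                path = character(0)))
  }
  lins <- lins[has_lineage]
  common <- lins[[1]]
  for (l in lins[-1]) {
    n <- min(length(common), length(l))
    agree <- which(common[seq_len(n)] == l[seq_len(n)])
    depth <- if (length(agree) && all(agree == seq_along(agree))) {
      max(agree)
    } else 0L
    common <- common[seq_len(depth)]
    if (depth == 0L) break
  }
  if (length(common) == 0L) {
    return(list(node = "root", rank = "root", path = character(0)))
  }
  list(node = unname(common[[length(common)]]),
       rank = names(common)[[length(common)]],
       path = common)
}

#' Build a lineage lookup from a lineage table
#'
#' @param lineage_df `data.frame(ref_id, lineage)` as written by
#'   [write_lineage_table()].
#' @return a named list: `ref_id` -> parsed lineage.
#' @export
lineage_lookup <- function(lineage_df) {
  setNames(lapply(lineage_df$lineage, parse_lineage), lineage_df$ref_id)
}

#' Assign every read by filtered-hit LCA
#'
#' Runs [filter_hits()] then [assign_lca()] per read. Reads in `read_ids`
#' without any hit row are binned as `"No hits"`, so the result is a
#' partition of the input reads.
#'
#' @param hits hit table covering any subset of `read_ids`.
#' @param lineage_df lineage table (`ref_id`, `lineage`).
#' @param read_ids character vector of all read ids in the sample.
#' @param e_max,min_score,top_percent see [filter_hits()].
#' @return `data.frame(read_id, node, rank)` with one row per read.
#' @export
assign_reads <- function(hits, lineage_df, read_ids,
                         e_max = 1e-5, min_score = 5, top_percent = 1) {
  retained <- filter_hits(hits, e_max, min_score, top_percent)
  lineages <- lineage_lookup(lineage_df)
  res <- lapply(read_ids, function(r) {
    h <- retained[retained$qseqid == r, , drop = FALSE]
    a <- assign_lca(h, lineages)
    data.frame(read_id = r, node = a$node, rank = a$rank,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build a taxonomy tree from a lineage table
#'
#' Nodes are the union of all lineage paths plus a root and the two
#' reserved bins `"Not assigned"` and `"No hits"` (children of the root).
#'
#' @param lineage_df lineage table (`ref_id`, `lineage`).
#' @return an object of class `taxonomy_tree`: a `data.frame` with `id`,
#'   `name`, `rank`, `parent` (id, `NA` for root) and a zeroed `count`
#'   column for direct read assignments.
#' @export
build_taxonomy <- function(lineage_df) {
  nodes <- data.frame(id = 1L, name = "root", rank = "root",
                      parent = NA_integer_, stringsAsFactors = FALSE)
  add_node <- function(name, rank, parent) {
    hit <- which(nodes$name == name)
    if (length(hit)) return(hit[1])
    nodes[nrow(nodes) + 1L, ] <<- list(nrow(nodes) + 1L, name, rank, parent)
    nrow(nodes)
  }
  for (lin in lineage_df$lineage) {
    path <- parse_lineage(lin)
    parent <- 1L
    for (i in seq_along(path)) {
      parent <- add_node(unname(path[[i]]), names(path)[[i]], parent)
    }
  }
  add_node("Not assigned", "reserved", 1L)
  add_node("No hits", "reserved", 1L)
  nodes$count <- 0L
  structure(nodes, class = c("taxonomy_tree", "data.frame"))
}

#' Tally per-node direct read counts on a taxonomy tree
#'
#' @param tree a [build_taxonomy()] tree.
#' @param assignments output of [assign_reads()].
#' @return the tree with its `count` column filled; the counts (including
#'   the reserved bins) sum to `nrow(assignments)`.
#' @export
taxonomy_counts <- function(tree, assignments) {
  idx <- match(assignments$node, tree$name)
  if (anyNA(idx)) {
    stop("assignment to unknown node: ",
         paste(unique(assignments$node[is.na(idx)]), collapse = ", "))
  }
  tab <- table(idx)
  tree$count <- 0L
  tree$count[as.integer(names(tab))] <- as.integer(tab)
  tree
}

# Subtree (cumulative) count of each node, by accumulating direct counts
# up the parent chain.
cumulative_counts <- function(tree) {
  cum <- tree$count
  ord <- order(node_depths(tree), decreasing = TRUE)
  for (i in ord) {
    p <- tree$parent[i]
    if (!is.na(p)) cum[p] <- cum[p] + cum[i]
  }
  cum
}

node_depths <- function(tree) {
  depth <- integer(nrow(tree))
  for (i in seq_len(nrow(tree))) {
    d <- 0L
    p <- tree$parent[i]
    while (!is.na(p)) {
      d <- d + 1L
      p <- tree$parent[p]
    }
    depth[i] <- d
  }
  depth
}

#' Min-support pruning of a counted taxonomy tree
#'
#' Nodes whose direct read count is positive but below `min_support` have
#' their reads re-assigned to the nearest ancestor whose cumulative
#' (subtree) count reaches `min_support`; the root absorbs anything left.
#' With `min_support = 1` (the usual setting for tag reads) the tree is
#' returned unchanged. Total read count is conserved.
#'
#' @param tree a counted `taxonomy_tree`.
#' @param min_support minimum reads per retained node (`>= 1`).
#' @return the pruned tree.
#' @export
apply_min_support <- function(tree, min_support = 1L) {
  if (min_support < 1) stop("min_support must be >= 1")
  if (min_support == 1L) return(tree)
  cum <- cumulative_counts(tree)  # subtree totals of the unpruned tree
  reserved <- tree$rank == "reserved"
  new_count <- tree$count
  for (i in seq_len(nrow(tree))) {
    if (reserved[i] || is.na(tree$parent[i])) next
    if (tree$count[i] > 0L && tree$count[i] < min_support) {
      moved <- tree$count[i]
      new_count[i] <- new_count[i] - moved
      p <- tree$parent[i]
      while (!is.na(tree$parent[p]) && cum[p] < min_support) {
        p <- tree$parent[p]
      }
      new_count[p] <- new_count[p] + moved
    }
  }
  tree$count <- new_count
  tree
}

#' Summarize read proportions for selected taxonomic groups
#'
#' Reports cumulative read counts and percentages of the sample total for a
#' set of grouping nodes (e.g. the major phyla of a pie chart), plus a
#' remainder row so that percentages sum to 100.
#'
#' @param tree a counted `taxonomy_tree`.
#' @param groups character vector of node names; must exist in the tree and
#'   must not contain an ancestor/descendant pair.
#' @return `data.frame(group, reads, percent)`; the last row is the
#'   remainder (`"other"`).
#' @export
summarize_groups <- function(tree, groups) {
  total <- sum(tree$count)
  if (total == 0L) stop("empty sample: no reads counted on the tree")
  idx <- match(groups, tree$name)
  if (anyNA(idx)) {
    stop("unknown grouping node: ",
         paste(groups[is.na(idx)], collapse = ", "))
  }
  # reject ancestor/descendant pairs (their reads would double-count)
  for (a in idx) {
    p <- tree$parent[a]
    while (!is.na(p)) {
      if (p %in% idx) {
        stop("grouping nodes overlap: '", tree$name[a],
             "' is a descendant of '", tree$name[p], "'")
      }
      p <- tree$parent[p]
    }
  }
  cum <- cumulative_counts(tree)
  reads <- cum[idx]
  out <- data.frame(group = groups, reads = reads,
                    percent = 100 * reads / total,
                    stringsAsFactors = FALSE)
  rest <- total - sum(reads)
  rbind(out, data.frame(group = "other", reads = rest,
                        percent = 100 * rest / total))
}

#' Align reads against a reference database (built-in aligner)
#'
#' A seed-and-extend local aligner producing BLAST-tabular-compatible hits,
#' so the binning stage runs without an external BLASTN. Candidate
#' references sharing at least one exact k-mer with the read are aligned
#' with Smith-Waterman (affine gaps) via Biostrings; a bit score and a
#' Karlin-Altschul-style E-value are computed from the raw score, the read
#' length and the database length. `method = "full"` skips the k-mer screen
#' and aligns every read against every reference (the slow exact mode).
#'
#' @param reads named character vector of cleaned reads.
#' @param db reference `data.frame` with `ref_id` and `sequence`.
#' @param match,mismatch,gap_open,gap_ext alignment scores (defaults are
#'   the classic +2/-3 nucleotide scheme with 5/2 affine gaps).
#' @param k seed k-mer length for the screen (default 11).
#' @param max_candidates at most this many seed-sharing references are
#'   aligned per read.
#' @param top_k hits reported per read, best bit score first.
#' @param method `"seed"` (default) or `"full"`.
#' @return a hit `data.frame` in outfmt-6 column layout.
#' @export
align_reads <- function(reads, db, match = 2, mismatch = -3,
                        gap_open = 5, gap_ext = 2, k = 11L,
                        max_candidates = 10L, top_k = 10L,
                        method = c("seed", "full")) {
  method <- match.arg(method)
  if (length(reads) == 0L) stop("no reads to align")
  if (nrow(db) == 0L) stop("empty reference database")
  # Ungapped Karlin-Altschul parameters for the +2/-3 scheme.
  lambda <- 0.625
  kconst <- 0.41
  db_len <- sum(nchar(db$sequence))
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)

  if (method == "seed") {
    ref_kmers <- lapply(db$sequence, function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      unique(substring(s, 1:(n - k + 1L), k:n))
    })
    index <- new.env(hash = TRUE, parent = emptyenv())
    for (j in seq_along(ref_kmers)) {
      for (km in ref_kmers[[j]]) {
        index[[km]] <- c(index[[km]], j)
      }
    }
    candidates <- lapply(reads, function(r) {
      n <- nchar(r)
      if (n < k) return(integer(0))
      kms <- unique(substring(r, 1:(n - k + 1L), k:n))
      hits <- unlist(lapply(kms, function(km) index[[km]]), use.names = FALSE)
      if (is.null(hits) || length(hits) == 0L) return(integer(0))
      tab <- sort(table(hits), decreasing = TRUE)
      utils::head(as.integer(names(tab)), max_candidates)
    })
  } else {
    candidates <- rep(list(seq_len(nrow(db))), length(reads))
  }

  # Group reads by candidate reference so each reference is aligned once
  # against a vector of reads.
  per_ref <- vector("list", nrow(db))
  for (i in seq_along(reads)) {
    for (j in candidates[[i]]) per_ref[[j]] <- c(per_ref[[j]], i)
  }
  rows <- list()
  for (j in seq_len(nrow(db))) {
    ridx <- per_ref[[j]]
    if (is.null(ridx)) next
    aln <- Biostrings::pairwiseAlignment(
      pattern = unname(reads[ridx]), subject = db$sequence[j],
      type = "local", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_ext)
    alen <- Biostrings::nchar(aln)
    nmat <- Biostrings::nmatch(aln)
    nmis <- Biostrings::nmismatch(aln)
    ind <- Biostrings::nindel(aln)
    gapopen <- Biostrings::insertion(ind)[, "Length"] +
      Biostrings::deletion(ind)[, "Length"]
    raw <- Biostrings::score(aln)
    bits <- (lambda * raw - log(kconst)) / log(2)
    ev <- nchar(reads[ridx]) * db_len * 2^(-bits)
    prange <- Biostrings::pattern(aln)
    srange <- Biostrings::subject(aln)
    rows[[length(rows) + 1L]] <- data.frame(
      qseqid = names(reads)[ridx], sseqid = db$ref_id[j],
      pident = round(100 * nmat / alen, 2), length = alen,
      mismatch = nmis, gapopen = as.integer(gapopen),
      qstart = Biostrings::start(prange), qend = Biostrings::end(prange),
      sstart = Biostrings::start(srange), send = Biostrings::end(srange),
      evalue = ev, bitscore = round(bits, 1),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(read_hit_table(tempfile_empty()))
  }
  out <- do.call(rbind, rows)
  # per read keep the top_k hits by bit score
  out <- do.call(rbind, lapply(split(out, out$qseqid), function(h) {
    utils::head(h[order(-h$bitscore), , drop = FALSE], top_k)
  }))
  rownames(out) <- NULL
  out[order(out$qseqid, -out$bitscore), , drop = FALSE]
}

# An empty file path, used to materialize an empty hit table with the
# canonical column types.
tempfile_empty <- function() {
  f <- tempfile(fileext = ".tsv")
  file.create(f)
  f
}
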