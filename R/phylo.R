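# Distance phylogenetics of OTU representatives: progressive multiple
# alignment, Kimura two-parameter distances with pairwise deletion,
# neighbor-joining, seeded column-bootstrap supports, and Newick I/O.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Kimura two-parameter distance between two aligned rows
#'
#' Columns where either row carries a gap or an ambiguity are excluded
#' (pairwise deletion). With `P` the transition and `Q` the transversion
#' proportion over the comparable columns,
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. When the logarithms are
#' undefined (substitution saturation) the distance is reported as
#' `max_distance` with attribute `saturated = TRUE`.
#'
#' @param a,b equal-length gapped sequence strings.
#' @param max_distance value reported for saturated pairs.
#' @return the distance, with attributes `P`, `Q` and (when relevant)
#'   `saturated`.
#' @examples
#' # P = 0.1, Q = 0.05 gives about 0.1702
#' @export
k2p_distance <- function(a, b, max_distance = 10) {
  if (nchar(a) != nchar(b)) stop("aligned rows must have equal length")
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  if (!any(ok)) stop("no comparable (gap-free) columns between the rows")
  ca <- ca[ok]; cb <- cb[ok]
  n <- length(ca)
  diff <- ca != cb
  transition <- diff & ((ca %in% PURINES & cb %in% PURINES) |
                        (ca %in% PYRIMIDINES & cb %in% PYRIMIDINES))
  p <- sum(transition) / n
  q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  if (w1 <= 0 || w2 <= 0) {
    return(structure(max_distance, P = p, Q = q, saturated = TRUE))
  }
  structure(-0.5 * log(w1) - 0.25 * log(w2), P = p, Q = q)
}

#' K2P distance matrix for an aligned block
#'
#' @param aln named character vector of equal-length gapped rows.
#' @param max_distance see [k2p_distance()].
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
k2p_matrix <- function(aln, max_distance = 10) {
  n <- length(aln)
  if (length(unique(nchar(aln))) != 1L) {
    stop("all aligned rows must have the same length")
  }
  m <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- as.numeric(k2p_distance(aln[[i]], aln[[j]], max_distance))
        m[i, j] <- d
        m[j, i] <- d
      }
    }
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration (exact on additive matrices).
#' Negative branch lengths, an occasional artifact of NJ on noisy
#' distances, are clamped to zero with the deficit moved to a sister
#' branch so path lengths are approximately preserved.
#'
#' @param dm symmetric numeric matrix with zero diagonal, non-negative
#'   entries and at least 3 taxa; row/column names are the leaf labels.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor-joining needs at least 3 taxa")
  if (any(dm < 0)) stop("distance matrix has negative entries")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  tree <- ape::nj(dm)
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sibs)) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] +
        tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Bootstrap supports for the NJ/K2P tree of an alignment
#'
#' Alignment columns are resampled with replacement per replicate
#' (replicate `r` draws from a seed derived from `(seed, r)`, so runs are
#' reproducible and parallelizable); each replicate is run through K2P
#' distances and NJ, and the support of each internal edge of the
#' full-data tree is the fraction of replicate trees containing the same
#' bipartition. Supports are attached as node labels in `[0, 1]`.
#'
#' @param aln named character vector of equal-length gapped rows.
#' @param n_replicates bootstrap replicates (1000 by convention).
#' @param seed integer seed.
#' @param max_distance see [k2p_distance()].
#' @return the full-data `phylo` tree; with 4 or more rows its
#'   `node.label` holds supports (root label empty), with fewer rows the
#'   tree is returned unannotated.
#' @export
bootstrap_support <- function(aln, n_replicates = 1000L, seed = 1L,
                              max_distance = 10) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  full <- nj_tree(k2p_matrix(aln, max_distance))
  if (length(aln) < 4) return(full)
  mat <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  rownames(mat) <- names(aln)
  ncol_full <- ncol(mat)
  reps <- lapply(seq_len(n_replicates), function(r) {
    idx <- with_seed(derive_seed(seed, r),
                     sample.int(ncol_full, ncol_full, replace = TRUE))
    sub <- mat[, idx, drop = FALSE]
    rows <- setNames(apply(sub, 1, paste, collapse = ""), rownames(mat))
    nj_tree(k2p_matrix(rows, max_distance))
  })
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- counts / n_replicates
  labels <- as.character(round(support, 4))
  labels[1] <- ""  # root of the unrooted representation
  full$node.label <- labels
  full
}

# Does a Newick label need single-quoting (structural characters)?
newick_needs_quote <- function(x) grepl("[][ ():;,']", x)

#' Write and read Newick trees
#'
#' Wrappers around ape's Newick support that additionally handle labels
#' containing spaces, parentheses or quotes by single-quoting them on
#' output and restoring them on input. Round trips preserve topology,
#' branch lengths (to at least 1e-9) and node-label supports.
#'
#' @param tree an `ape::phylo` object.
#' @param path file path.
#' @return `read_newick()` returns a `phylo`; `write_newick()` returns
#'   `path` invisibly.
#' @export
write_newick <- function(tree, path) {
  # ape::write.tree rewrites awkward labels, so labels needing quotes are
  # swapped for placeholders and spliced back, quoted, into the text
  quoted <- character(0)
  protect <- function(x) {
    needs <- newick_needs_quote(x)
    for (i in which(needs)) {
      quoted <<- c(quoted, x[i])
      x[i] <- sprintf("XQLBLX%03d", length(quoted))
    }
    x
  }
  tree$tip.label <- protect(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- protect(tree$node.label)
  txt <- ape::write.tree(tree, digits = 12)
  for (i in seq_along(quoted)) {
    txt <- sub(sprintf("XQLBLX%03d", i),
               paste0("'", gsub("'", "''", quoted[i]), "'"), txt,
               fixed = TRUE)
  }
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  # replace quoted labels with placeholders ape can parse
  labels <- character(0)
  out <- character(0)
  rest <- txt
  repeat {
    m <- regexpr("'(?:[^']|'')*'", rest)
    if (m < 0) { out <- paste0(out, rest); break }
    lab <- substr(rest, m + 1L, m + attr(m, "match.length") - 2L)
    labels <- c(labels, gsub("''", "'", lab))
    out <- paste0(out, substr(rest, 1L, m - 1L),
                  sprintf("XQLBLX%03d", length(labels)))
    rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
  }
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = out)),
                   error = function(e) NULL)
  if (is.null(tree)) {
    stop("malformed Newick in ", path)
  }
  restore <- function(x) {
    hit <- regmatches(x, regexpr("^XQLBLX[0-9]{3}$", x))
    idx <- grepl("^XQLBLX[0-9]{3}$", x)
    x[idx] <- labels[as.integer(sub("XQLBLX", "", x[idx]))]
    x
  }
  tree$tip.label <- restore(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- restore(tree$node.label)
  tree
}

# char codes for the compiled profile aligner: 0 gap, 1..4 = A C G T
encode_profile <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  code <- matrix(match(mat, c("A", "C", "G", "T"), nomatch = 0L),
                 nrow = nrow(mat))
  code[is.na(code)] <- 0L
  code
}

decode_profile <- function(code) {
  alpha <- c("-", "A", "C", "G", "T")
  apply(code, 1, function(r) paste(alpha[r + 1L], collapse = ""))
}

# merge two profiles (character matrices of rows) along a traceback path
merge_profiles <- function(pa, pb, path) {
  na <- nrow(pa); nb <- nrow(pb)
  out <- matrix(0L, nrow = na + nb, ncol = length(path))
  ia <- 0L; ib <- 0L
  for (k in seq_along(path)) {
    mv <- path[k]
    if (mv == 1L) {
      ia <- ia + 1L; ib <- ib + 1L
      out[seq_len(na), k] <- pa[, ia]
      out[na + seq_len(nb), k] <- pb[, ib]
    } else if (mv == 2L) {
      ia <- ia + 1L
      out[seq_len(na), k] <- pa[, ia]
    } else {
      ib <- ib + 1L
      out[na + seq_len(nb), k] <- pb[, ib]
    }
  }
  out
}

#' Progressive multiple alignment of representative sequences
#'
#' A deterministic progressive aligner: pairwise identities build an
#' average-linkage guide tree, and profiles are merged with an affine-gap
#' profile-profile dynamic program (compiled). Intended for the handful of
#' OTU representatives plus reference sequences that feed tree building,
#' not for large alignments.
#'
#' @param seqs named character vector of 2 or more DNA sequences.
#' @param match,mismatch,gap_open,gap_ext alignment scores.
#' @return a named character vector of equal-length gapped rows, in the
#'   input order.
#' @export
align_representatives <- function(seqs, match = 2, mismatch = -3,
                                  gap_open = 5, gap_ext = 2) {
  if (length(seqs) < 2) stop("need at least 2 sequences to align")
  n <- length(seqs)
  ids <- names(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- 1 - pairwise_identity(seqs[[i]], seqs[[j]])
    }
  }
  hc <- hclust(as.dist(d), method = "average")
  profiles <- lapply(seqs, function(s) encode_profile(s))
  rows_of <- as.list(seq_len(n))
  merged <- vector("list", nrow(hc$merge))
  merged_rows <- vector("list", nrow(hc$merge))
  fetch <- function(k) {
    if (k < 0) list(prof = profiles[[-k]], rows = rows_of[[-k]])
    else list(prof = merged[[k]], rows = merged_rows[[k]])
  }
  for (s in seq_len(nrow(hc$merge))) {
    a <- fetch(hc$merge[s, 1])
    b <- fetch(hc$merge[s, 2])
    path <- align_profiles_cpp(a$prof, b$prof, match, mismatch,
                               gap_open, gap_ext)
    merged[[s]] <- merge_profiles(a$prof, b$prof, path)
    merged_rows[[s]] <- c(a$rows, b$rows)
  }
  final <- merged[[nrow(hc$merge)]]
  ord <- order(merged_rows[[nrow(hc$merge)]])
  setNames(decode_profile(final)[ord], ids)
}
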