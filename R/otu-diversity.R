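# Greedy centroid OTU clustering at a fixed identity threshold, taxon
# validation, representative selection, rarefaction, the four diversity
# indices (Chao1, Shannon, Margalef, Simpson) and the normalized
# between-date relative-change statistic.

#' Pairwise sequence identity
#'
#' Semi-global identity underlying the 97% OTU threshold: the shorter
#' sequence is aligned end-to-end against the best-matching region of the
#' longer one (affine gaps), and identity is matches divided by alignment
#' columns, terminal gaps excluded. Symmetric in its arguments. Truncated
#' pyrosequencing reads are therefore compared over their overlap with a
#' full-length centroid rather than penalized for missing 3' sequence.
#'
#' @param a,b non-empty DNA strings.
#' @return identity in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGT", "ACGA")  # 0.75
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  st <- glocal_align_stats_cpp(a, b, 2, -3, 5, 2)
  st[1] / st[2]
}

#' Greedy centroid OTU clustering
#'
#' Uclust-style greedy clustering: reads are processed in a deterministic
#' order (decreasing length, ties broken by read id); the first read seeds
#' the first centroid, and each subsequent read joins the first existing
#' centroid (in founding order) whose [pairwise_identity()] to it reaches
#' the threshold, otherwise it founds a new centroid.
#'
#' Candidate centroids are pre-screened by shared-word content (as Uclust
#' does): a centroid is only aligned when at least `screen_frac` of the
#' read's k-mers occur in it. At the default settings a pair at 97%
#' identity shares ~70% of its 11-mers while sequences from different
#' families (~15% divergence) share ~17%, so the screen skips only pairs
#' far below the threshold; set `screen_frac = 0` for exhaustive
#' comparison.
#'
#' @param reads named character vector of cleaned reads.
#' @param identity_threshold clustering threshold in (0.5, 1]; 0.97 is the
#'   conventional species-proxy level for 18S tags.
#' @param screen_k word length of the candidate screen.
#' @param screen_frac minimum shared-word fraction before alignment.
#' @return a list of OTUs, each a list with `otu_id`, `centroid` (read id),
#'   `centroid_seq` and `members` (read ids).
#' @export
cluster_greedy <- function(reads, identity_threshold = 0.97,
                           screen_k = 11L, screen_frac = 0.25) {
  if (length(reads) == 0L) stop("no reads to cluster")
  if (identity_threshold <= 0.5 || identity_threshold > 1) {
    stop("identity_threshold must lie in (0.5, 1]")
  }
  kmers <- function(s) {
    n <- nchar(s)
    if (n < screen_k) return(s)
    unique(substring(s, 1:(n - screen_k + 1L), screen_k:n))
  }
  ord <- order(-nchar(reads), names(reads))
  reads <- reads[ord]
  read_kmers <- lapply(reads, kmers)
  centroid_seq <- character(0)
  centroid_id <- character(0)
  centroid_kmers <- list()
  members <- list()
  for (i in seq_along(reads)) {
    placed <- FALSE
    for (c in seq_along(centroid_seq)) {
      if (screen_frac > 0 &&
          mean(read_kmers[[i]] %in% centroid_kmers[[c]]) < screen_frac) {
        next
      }
      if (pairwise_identity(reads[[i]], centroid_seq[[c]]) >=
          identity_threshold) {
        members[[c]] <- c(members[[c]], names(reads)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroid_seq <- c(centroid_seq, reads[[i]])
      centroid_id <- c(centroid_id, names(reads)[i])
      centroid_kmers[[length(centroid_kmers) + 1L]] <- read_kmers[[i]]
      members[[length(members) + 1L]] <- names(reads)[i]
    }
  }
  lapply(seq_along(centroid_id), function(c) {
    list(otu_id = sprintf("OTU%04d", c), centroid = centroid_id[c],
         centroid_seq = centroid_seq[[c]], members = members[[c]])
  })
}

#' Validate OTUs by minimum read support
#'
#' A taxon is accepted when its cluster holds at least `min_reads` member
#' reads (the conventional floor of three screens out singleton sequencing
#' artifacts); smaller clusters are kept in a rejected list for audit, so
#' validated plus rejected partition the input.
#'
#' @param otus list of OTUs from [cluster_greedy()].
#' @param min_reads minimum cluster size (`>= 1`).
#' @return a list with `validated` and `rejected` OTU lists.
#' @export
validate_taxa <- function(otus, min_reads = 3L) {
  if (min_reads < 1) stop("min_reads must be >= 1")
  sizes <- vapply(otus, function(o) length(o$members), integer(1))
  list(validated = otus[sizes >= min_reads],
       rejected = otus[sizes < min_reads])
}

#' Select representative reads for OTUs
#'
#' The longest member read is the representative, provided it exceeds
#' `min_len` (400 nt by convention, so representatives span enough of the
#' V2-V3 region for tree building); ties break by read id. OTUs whose
#' longest member is at or below the floor get no representative.
#'
#' @param otus list of OTUs.
#' @param reads named character vector covering all member reads.
#' @param min_len representative length floor in nt.
#' @return the OTU list with a `representative` field added (read id or
#'   `NA`).
#' @export
select_representatives <- function(otus, reads, min_len = 400L) {
  lapply(otus, function(o) {
    mem <- o$members
    len <- nchar(reads[mem])
    ord <- order(-len, mem)
    best <- mem[ord[1]]
    o$representative <- if (nchar(reads[[best]]) > min_len) best else
      NA_character_
    o
  })
}

#' Per-sample OTU count matrix
#'
#' @param otus list of OTUs.
#' @param read_samples named character vector mapping read id to sample id.
#' @return integer matrix, OTUs in rows, samples in columns.
#' @export
otu_counts <- function(otus, read_samples) {
  samples <- sort(unique(unname(read_samples)))
  m <- matrix(0L, nrow = length(otus), ncol = length(samples),
              dimnames = list(vapply(otus, `[[`, character(1), "otu_id"),
                              samples))
  for (i in seq_along(otus)) {
    tab <- table(read_samples[otus[[i]]$members])
    m[i, names(tab)] <- as.integer(tab)
  }
  m
}

check_counts <- function(counts) {
  if (length(counts) == 0L || sum(counts) == 0) {
    stop("abundance vector is empty (N = 0)")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
}

#' Chao1 richness estimator
#'
#' `S_chao1 = S + n1^2 / (2 n2)`, with `n1` the number of singleton OTUs.
#' By default `n2` counts OTUs holding two reads *or more*; set
#' `classic = TRUE` for the textbook definition where `n2` counts exact
#' doubletons. When no OTU qualifies for `n2` the bias-corrected degenerate
#' form `S + n1 (n1 - 1) / 2` is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param counts per-OTU read counts for one sample.
#' @param classic use exact doubletons for `n2`.
#' @return the richness estimate (always `>= S`).
#' @examples
#' chao1(c(1, 1, 2, 3))  # 5
#' @export
chao1 <- function(counts, classic = FALSE) {
  check_counts(counts)
  s <- sum(counts > 0)
  n1 <- sum(counts == 1)
  n2 <- if (classic) sum(counts == 2) else sum(counts >= 2)
  if (n2 == 0) {
    structure(s + n1 * (n1 - 1) / 2, degenerate = TRUE)
  } else {
    s + n1^2 / (2 * n2)
  }
}

#' Diversity indices: Shannon, Margalef, Simpson
#'
#' `shannon_index()` computes `H' = -sum(p_i log p_i)` (natural log by
#' default); `margalef_index()` computes `d = (S - 1) / ln N` (0 when
#' `N = 1`); `simpson_index()` defaults to the Gini-Simpson complement
#' `1 - sum(p_i^2)`, with the dominance form `sum(p_i^2)` and the unbiased
#' finite-sample complement also available.
#'
#' @param counts per-OTU read counts for one sample.
#' @param base logarithm base for Shannon.
#' @param variant Simpson variant.
#' @return the index value (finite, `>= 0`).
#' @export
shannon_index <- function(counts, base = exp(1)) {
  check_counts(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' @rdname shannon_index
#' @export
margalef_index <- function(counts) {
  check_counts(counts)
  n <- sum(counts)
  s <- sum(counts > 0)
  if (n == 1) return(0)
  (s - 1) / log(n)
}

#' @rdname shannon_index
#' @export
simpson_index <- function(counts,
                          variant = c("gini", "dominance", "unbiased")) {
  variant <- match.arg(variant)
  check_counts(counts)
  n <- sum(counts)
  p <- counts[counts > 0] / n
  switch(variant,
         gini = 1 - sum(p^2),
         dominance = sum(p^2),
         unbiased = {
           if (n < 2) stop("unbiased Simpson needs N >= 2")
           1 - sum(counts * (counts - 1)) / (n * (n - 1))
         })
}

#' Per-sample diversity summary table
#'
#' One row per sample with the read count, observed OTU number, Chao1,
#' Margalef, Shannon and Simpson values - the standard richness /
#' heterogeneity companion table to a rarefaction figure.
#'
#' @param count_matrix OTU-by-sample count matrix (see [otu_counts()]).
#' @param ... passed to the index functions.
#' @return a `data.frame` with columns `sample`, `reads`, `otus`, `chao1`,
#'   `margalef`, `shannon`, `simpson`.
#' @export
diversity_summary <- function(count_matrix, ...) {
  out <- lapply(colnames(count_matrix), function(s) {
    x <- count_matrix[, s]
    data.frame(sample = s, reads = sum(x), otus = sum(x > 0),
               chao1 = as.numeric(chao1(x)),
               margalef = margalef_index(x),
               shannon = shannon_index(x),
               simpson = simpson_index(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rarefaction curve
#'
#' Expected number of OTUs in a random subsample of each depth. The
#' analytic mode uses the hypergeometric expectation
#' `E[S_n] = sum_i (1 - choose(N - n_i, n) / choose(N, n))`; the Monte
#' Carlo mode subsamples reads without replacement and agrees with the
#' analytic form within sampling error.
#'
#' @param counts per-OTU read counts for one sample.
#' @param depths subsampling depths (each `<= N`); defaults to 20 evenly
#'   spaced depths up to `N`.
#' @param mode `"analytic"` or `"montecarlo"`.
#' @param n_rep Monte Carlo replicates.
#' @param seed seed for the Monte Carlo mode.
#' @return a `data.frame` with `depth`, `expected_otus` and (Monte Carlo
#'   only) `se`, the standard error of the mean across replicates.
#' @export
rarefaction_curve <- function(counts, depths = NULL,
                              mode = c("analytic", "montecarlo"),
                              n_rep = 100L, seed = 1L) {
  mode <- match.arg(mode)
  check_counts(counts)
  counts <- counts[counts > 0]
  n_total <- sum(counts)
  if (is.null(depths)) {
    depths <- unique(round(seq(1, n_total, length.out = 20)))
  }
  if (any(depths < 1) || any(depths > n_total)) {
    stop("depths must lie in [1, N]")
  }
  if (mode == "analytic") {
    exp_s <- vapply(depths, function(n) {
      sum(1 - exp(lchoose(n_total - counts, n) - lchoose(n_total, n)))
    }, numeric(1))
    data.frame(depth = depths, expected_otus = exp_s)
  } else {
    pool <- rep.int(seq_along(counts), counts)
    with_seed(seed, {
      res <- vapply(depths, function(n) {
        draws <- vapply(seq_len(n_rep), function(r) {
          length(unique(sample(pool, n)))
        }, numeric(1))
        c(mean(draws), stats::sd(draws) / sqrt(n_rep))
      }, numeric(2))
      data.frame(depth = depths, expected_otus = res[1, ], se = res[2, ])
    })
  }
}

#' Normalized relative change between two sampling dates
#'
#' `R = (n_iB / N_B) / (n_iA / N_A)`: the fold change in a taxon's read
#' proportion between date A and date B, normalizing for unequal sample
#' totals. Taxa absent on date A are flagged `"new"` (`R = Inf`); taxa
#' absent on date B are flagged `"lost"` (`R = 0`).
#'
#' @param n_a,n_b reads for the taxon on dates A and B (vectorized).
#' @param total_a,total_b total reads per date (both `> 0`).
#' @return numeric vector of `R` values with a `status` attribute
#'   (`"ok"`, `"new"`, `"lost"` or `"absent"`).
#' @examples
#' relative_change(660, 5435, 18280, 41057)  # 3.666..., i.e. 3.7-fold
#' @export
relative_change <- function(n_a, n_b, total_a, total_b) {
  if (total_a <= 0 || total_b <= 0) stop("sample totals must be positive")
  if (any(n_a < 0) || any(n_b < 0)) stop("read counts must be non-negative")
  pa <- n_a / total_a
  pb <- n_b / total_b
  r <- ifelse(n_a == 0 & n_b == 0, NaN,
       ifelse(n_a == 0, Inf,
       ifelse(n_b == 0, 0, pb / pa)))
  status <- ifelse(n_a == 0 & n_b == 0, "absent",
            ifelse(n_a == 0, "new",
            ifelse(n_b == 0, "lost", "ok")))
  structure(r, status = status)
}
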