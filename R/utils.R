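#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded generators do not perturb the session stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-stream seed
#'
#' Maps a master seed and a stage offset to a distinct 31-bit seed so that
#' each pipeline stage consumes an independent, reproducible stream.
#'
#' @param seed master integer seed.
#' @param offset small non-negative integer identifying the stream.
#' @return an integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(offset) * 9973) %% 2147483647)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA string
#' @param n length in nucleotides.
#' @return a single character string over A/C/G/T.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Point-mutate a DNA string
#'
#' Substitutes each position independently with probability `rate`; the
#' replacement base is always different from the original.
#'
#' @param seq single DNA string.
#' @param rate per-base substitution probability in `[0, 1]`.
#' @return mutated string of the same length.
#' @keywords internal
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA strings.
#' @return reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Hamming mismatch count between equal-length strings.
n_mismatch <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}
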