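# Shared fixture builders and independent oracles. All fixtures are
# generated in code under fixed seeds; nothing is read from disk.

seeded <- planktondiv:::with_seed
rand_dna <- function(n, seed) seeded(seed, planktondiv:::random_dna(n))
mutated <- function(s, rate, seed) {
  seeded(seed, planktondiv:::mutate_seq(s, rate))
}

default_scheme <- function() {
  tag_scheme(c(mar = "ACGTACGTAC", apr = "TGCATGCATG"))
}

# a hit-table row in outfmt-6 layout
hit_row <- function(qseqid, sseqid, evalue, bitscore, pident = 99,
                    length = 400L) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, mismatch = 2L, gapopen = 0L,
             qstart = 1L, qend = length, sstart = 1L, send = length,
             evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

# Independent identity oracle: Biostrings semi-global alignment, shorter
# sequence aligned globally against the best region of the longer one.
biostrings_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  sm <- Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global-local",
    substitutionMatrix = sm, gapOpening = 5, gapExtension = 2)
  Biostrings::pid(aln, type = "PID1") / 100
}

# Brute-force single-linkage components at an identity threshold
# (union-find over all pairs), the clustering oracle for well-separated
# templates.
single_linkage_components <- function(reads, threshold) {
  n <- length(reads)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (pairwise_identity(reads[[i]], reads[[j]]) >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(names(reads), roots)
}

# a small database of well-separated taxa: one species per family
separated_db <- function(n_taxa, seed) {
  generate_reference_db(n_taxa, 1, 1, seed = seed)
}
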