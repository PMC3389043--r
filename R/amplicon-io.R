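# FASTA / BLAST-tabular / TSV input-output and read pre-processing:
# demultiplexing by tag+key+primer, primer stripping, and length QC.

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings that exchange reads as named character
#' vectors (names are record ids, values sequences), the representation
#' used throughout the pipeline.
#'
#' @param path file path.
#' @param reads named character vector of sequences.
#' @return `read_fasta()` returns a named character vector (empty for an
#'   empty file); `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e))
                  })
  setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(reads, path) {
  set <- Biostrings::DNAStringSet(unname(as.character(reads)))
  names(set) <- names(reads)
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta",
                              width = 70L)
  invisible(path)
}

#' A demultiplexed per-sample read set
#'
#' @param sample_id sample label.
#' @param reads named character vector of cleaned reads (tag, key and
#'   primer removed).
#' @param date_label free-text date annotation.
#' @return an object of class `sample_read_set`.
#' @export
sample_read_set <- function(sample_id, reads, date_label = "") {
  if (anyDuplicated(names(reads))) {
    stop("read ids must be unique within a sample")
  }
  structure(list(sample_id = sample_id, reads = reads,
                 date_label = date_label),
            class = "sample_read_set")
}

#' Demultiplex tagged amplicon reads
#'
#' A read is assigned to a sample iff its first 10 nt exactly match one of
#' the scheme's tags, positions 11-14 equal the instrument key, and the
#' forward primer follows the key within `primer_mismatches` substitutions.
#' Assigned reads are emitted with tag, key and primer removed; everything
#' else lands in the unassigned bin, so the output is a partition of the
#' input.
#'
#' @param reads named character vector of raw reads.
#' @param scheme a [tag_scheme()]; tags must be pairwise distinct.
#' @param primer_mismatches allowed substitutions in the forward primer
#'   match (default 1).
#' @param trim_rev_primer if `TRUE`, an exact reverse-complemented reverse
#'   primer found in a cleaned read is trimmed (together with anything 3'
#'   of it); reads without it are kept untrimmed, as truncated 454 reads
#'   are expected.
#' @return a list with `samples` (named list of [sample_read_set()]) and
#'   `unassigned` (named character vector of raw reads).
#' @export
demultiplex <- function(reads, scheme, primer_mismatches = 1L,
                        trim_rev_primer = TRUE) {
  if (anyDuplicated(scheme$tags)) stop("duplicate tags in scheme")
  if (primer_mismatches < 0) stop("primer_mismatches must be >= 0")
  n <- length(reads)
  tag_len <- 10L
  key_len <- nchar(scheme$key)
  p_len <- nchar(scheme$fwd_primer)
  prefix_len <- tag_len + key_len + p_len
  tag <- substr(reads, 1L, tag_len)
  key <- substr(reads, tag_len + 1L, tag_len + key_len)
  primer_obs <- substr(reads, tag_len + key_len + 1L, prefix_len)
  sample_idx <- match(tag, scheme$tags)
  primer_chars <- strsplit(scheme$fwd_primer, "", fixed = TRUE)[[1]]
  primer_ok <- vapply(primer_obs, function(p) {
    nchar(p) == p_len &&
      sum(strsplit(p, "", fixed = TRUE)[[1]] != primer_chars) <=
        primer_mismatches
  }, logical(1), USE.NAMES = FALSE)
  assigned <- !is.na(sample_idx) & key == scheme$key & primer_ok &
    nchar(reads) > prefix_len
  cleaned <- substring(reads, prefix_len + 1L)
  if (trim_rev_primer) {
    rc <- revcomp(scheme$rev_primer)
    pos <- regexpr(rc, cleaned, fixed = TRUE)
    hit <- which(pos > 0L)
    cleaned[hit] <- substr(cleaned[hit], 1L, pos[hit] - 1L)
  }
  samples <- lapply(seq_along(scheme$tags), function(i) {
    keep <- which(assigned & sample_idx == i)
    sample_read_set(names(scheme$tags)[i],
                    setNames(cleaned[keep], names(reads)[keep]))
  })
  names(samples) <- names(scheme$tags)
  list(samples = samples, unassigned = reads[!assigned])
}

#' Read-length QC statistics
#'
#' Fraction of reads whose length exceeds each threshold, the QC summary
#' reported for 454 runs (e.g. the share of reads above 200 bp / 400 bp).
#'
#' @param reads a [sample_read_set()] or named character vector.
#' @param thresholds positive lengths in nt (default `c(200, 400)`).
#' @return a `data.frame` with `threshold` and `fraction_above`; for an
#'   empty read set the fractions are `NA` (undefined, not zero).
#' @export
length_stats <- function(reads, thresholds = c(200L, 400L)) {
  if (inherits(reads, "sample_read_set")) reads <- reads$reads
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  thresholds <- sort(thresholds)
  if (length(reads) == 0L) {
    return(data.frame(threshold = thresholds, fraction_above = NA_real_))
  }
  len <- nchar(reads)
  data.frame(threshold = thresholds,
             fraction_above = vapply(thresholds,
                                     function(t) mean(len > t), numeric(1)))
}

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read and write BLAST tabular (outfmt 6) hit tables
#'
#' The 12-column tab-separated dialect: qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore.
#'
#' @param path file path.
#' @param hits a hit `data.frame` with the 12 outfmt-6 columns.
#' @return `read_hit_table()` returns a `data.frame` with typed columns
#'   (empty for an empty file); `write_hit_table()` returns `path`
#'   invisibly.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- setNames(
    data.frame(character(), character(), numeric(), integer(), integer(),
               integer(), integer(), integer(), integer(), integer(),
               numeric(), numeric(), stringsAsFactors = FALSE),
    HIT_COLS)
  if (file.size(path) == 0L) return(empty)
  nf <- utils::count.fields(path, sep = "\t", quote = "",
                            comment.char = "")
  bad <- which(nf != 12L)
  if (length(bad)) {
    stop("expected 12 tab-separated columns, found ", nf[bad[1]],
         " at row ", bad[1])
  }
  hits <- utils::read.delim(path, header = FALSE, col.names = HIT_COLS,
                            colClasses = c("character", "character",
                                           rep("numeric", 10)),
                            quote = "", comment.char = "")
  for (col in c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send")) {
    hits[[col]] <- as.integer(hits[[col]])
  }
  hits
}

#' @rdname read_hit_table
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(identical(names(hits), HIT_COLS))
  write.table(hits, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write lineage tables
#'
#' Two tab-separated columns: `ref_id` and `lineage`, the latter a
#' `rank:name;rank:name;...` path from the highest to the lowest rank. An
#' empty lineage string marks a reference without a resolvable taxonomy
#' (its reads become "Not assigned").
#'
#' @param db a reference `data.frame` with `ref_id` and `lineage` columns.
#' @param path file path.
#' @return `read_lineage_table()` returns a `data.frame(ref_id, lineage)`.
#' @export
write_lineage_table <- function(db, path) {
  write.table(db[, c("ref_id", "lineage")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_lineage_table
#' @export
read_lineage_table <- function(path) {
  out <- utils::read.delim(path, header = TRUE,
                           colClasses = c("character", "character"),
                           quote = "")
  stopifnot(identical(names(out), c("ref_id", "lineage")))
  out
}

#' Read and write read-origin truth tables
#'
#' @param truth a `data.frame` with at least `read_id` and `ref_id`.
#' @param path file path.
#' @return `read_truth_table()` returns the table.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  utils::read.delim(path, header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}
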