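#!/usr/bin/env Rscript

# Step 3 -- taxonomic binning by filtered-hit LCA.
#
# Aligns each sample's cleaned reads against the reference database with
# the built-in seed-and-extend aligner, filters hits with the standard
# MEGAN thresholds (E-value 1e-5, min-score 5, top-percent 1), assigns
# each read to the lowest common ancestor of its retained hits, applies
# min-support 1 (identity), and tabulates per-family read proportions --
# the numbers behind a group-proportion pie chart.

suppressPackageStartupMessages(library(planktondiv))

sim <- "results/simulated"
out <- "results/taxonomy"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ref <- read_fasta(file.path(sim, "reference.fasta"))
lineage <- read_lineage_table(file.path(sim, "lineage.tsv"))
db <- data.frame(ref_id = names(ref), sequence = unname(ref),
                 stringsAsFactors = FALSE)
db <- merge(db, lineage, by = "ref_id", sort = FALSE)

for (sid in c("mar", "apr")) {
  reads <- read_fasta(file.path("results/demux",
                                paste0(sid, "_clean.fasta")))
  hits <- align_reads(reads, db)
  write_hit_table(hits, file.path(out, paste0(sid, "_hits.tsv")))
  asg <- assign_reads(hits, db, names(reads),
                      e_max = 1e-5, min_score = 5, top_percent = 1)
  write.table(asg, file.path(out, paste0(sid, "_assignments.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tree <- apply_min_support(taxonomy_counts(build_taxonomy(db), asg),
                            min_support = 1)
  fams <- sort(unique(sub(";.*", "", sub("family:", "", db$lineage))))
  groups <- summarize_groups(tree, fams)
  write.table(groups, file.path(out, paste0(sid, "_groups.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("Sample", sid, "-", length(reads), "reads;",
      sum(tree$count), "counted on the tree (conserved:",
      sum(tree$count) == length(reads), ")\n")
  print(groups, row.names = FALSE)
}
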