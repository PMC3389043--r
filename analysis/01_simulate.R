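#!/usr/bin/env Rscript

# Step 1 -- simulate the survey's raw inputs.
#
# Generates the fixtures that stand in for the study's raw data: a ranked
# 18S reference database, a pre-bloom and a bloom community over the same
# ten taxa (bloom taxon at 90% of the bloom-date community), tagged
# error-laden amplicon reads for both dates at a ~1:2.2 read-depth ratio,
# and a two-date microscopy count table. Everything is seeded; rerunning
# reproduces the files byte for byte.

suppressPackageStartupMessages(library(planktondiv))

seed <- 1L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

db <- generate_reference_db(3, 3, 3, seed = derive_seed(seed, 1))
write_fasta(setNames(db$sequence, db$ref_id), file.path(out, "reference.fasta"))
write_lineage_table(db, file.path(out, "lineage.tsv"))

scheme <- tag_scheme(c(mar = "ACGTACGTAC", apr = "TGCATGCATG"))
comm_a <- generate_community(db, 10, seed = derive_seed(seed, 2),
                             ratio = 0.7, sample_id = "mar")
comm_b <- planktondiv:::bloom_community(comm_a, bloom_fraction = 0.9,
                                        bloom_rank = 4, ratio = 0.7,
                                        sample_id = "apr")
gen_a <- generate_reads(comm_a, db, scheme, 180, error_rate = 0.01,
                        seed = derive_seed(seed, 3))
gen_b <- generate_reads(comm_b, db, scheme, 410, error_rate = 0.01,
                        seed = derive_seed(seed, 4))

write_fasta(c(gen_a$reads, gen_b$reads), file.path(out, "raw_reads.fasta"))
write_truth_table(rbind(gen_a$truth, gen_b$truth),
                  file.path(out, "truth.tsv"))

micro <- generate_microscopy_table(default_microscopy_specs(),
                                   seed = derive_seed(seed, 6))
write.table(micro, file.path(out, "microscopy.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated", length(gen_a$reads), "pre-bloom and", length(gen_b$reads),
    "bloom reads from", nrow(comm_a$taxa), "taxa;",
    "bloom taxon", comm_b$bloom_taxon, "at 90% of the bloom community.\n")
cat("Wrote reference.fasta, lineage.tsv, raw_reads.fasta, truth.tsv,",
    "microscopy.tsv under", out, "\n")
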