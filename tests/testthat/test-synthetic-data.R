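test_that("reference database has the requested shape and rank-ordered divergence", {
  one <- generate_reference_db(1, 1, 1, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_length(planktondiv:::parse_lineage(one$lineage), 3L)

  db <- generate_reference_db(2, 2, 2, seed = 7)
  expect_equal(nrow(db), 8L)
  expect_true(all(strsplit(paste(db$sequence, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  expect_false(anyDuplicated(db$ref_id) > 0)

  # mean identity within genus > within family > between families
  pairs <- t(combn(nrow(db), 2))
  ident <- apply(pairs, 1, function(p) {
    pairwise_identity(db$sequence[p[1]], db$sequence[p[2]])
  })
  same_genus <- db$genus[pairs[, 1]] == db$genus[pairs[, 2]]
  same_family <- db$family[pairs[, 1]] == db$family[pairs[, 2]]
  expect_gt(mean(ident[same_genus]), mean(ident[!same_genus & same_family]))
  expect_gt(mean(ident[!same_genus & same_family]), mean(ident[!same_family]))

  expect_identical(db, generate_reference_db(2, 2, 2, seed = 7))
  expect_error(generate_reference_db(0, 1, 1, seed = 1), "positive")
})

test_that("community profiles follow a geometric series with optional bloom", {
  db <- generate_reference_db(3, 3, 3, seed = 5)
  single <- generate_community(db, 1, seed = 2)
  expect_equal(single$taxa$abundance, 1)

  bloom <- generate_community(db, 10, bloom_fraction = 0.9, seed = 3)
  expect_identical(bloom$taxa$ref_id[1], bloom$bloom_taxon)
  expect_equal(bloom$taxa$abundance[1], 0.9)
  expect_equal(sum(bloom$taxa$abundance), 1, tolerance = 1e-9)

  plain <- generate_community(db, 5, seed = 4)
  expect_equal(sum(plain$taxa$abundance), 1, tolerance = 1e-9)
  expect_true(all(diff(plain$taxa$abundance) < 0))

  expect_error(generate_community(db, nrow(db) + 1, seed = 1), "exceeds")
  expect_error(generate_community(db, 2, bloom_fraction = 1, seed = 1),
               "strictly between")
})

test_that("reads carry tag+key+primer, sample community abundances, and honor the length model", {
  db <- separated_db(4, seed = 11)
  scheme <- default_scheme()
  one <- generate_community(db, 1, seed = 1, sample_id = "mar")

  # error-free, full-length: inserts identical to the reference
  gen <- generate_reads(one, db, scheme, 10, error_rate = 0,
                        lmodel = length_model(p_full = 1), seed = 2)
  prefix <- paste0(scheme$tags[["mar"]], scheme$key, scheme$fwd_primer)
  expect_true(all(startsWith(gen$reads, prefix)))
  ref <- db$sequence[db$ref_id == one$taxa$ref_id[1]]
  expect_true(all(substring(gen$reads, nchar(prefix) + 1) == ref))

  # bloom-taxon read fraction within 3 binomial SD of its abundance
  comm <- generate_community(db, 4, bloom_fraction = 0.9, seed = 3,
                             sample_id = "mar")
  gen2 <- generate_reads(comm, db, scheme, 1500, error_rate = 0, seed = 4)
  frac <- mean(gen2$truth$ref_id == comm$bloom_taxon)
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 1500))

  # default attrition model: ~75% of reads above 200 bp
  expect_gt(mean(gen2$truth$insert_length > 200), 0.70)
  expect_lt(mean(gen2$truth$insert_length > 200), 0.80)

  expect_identical(gen2,
                   generate_reads(comm, db, scheme, 1500, error_rate = 0,
                                  seed = 4))
  expect_error(generate_reads(comm, db, scheme, 10, error_rate = 0.5,
                              seed = 1), "error_rate")
})

test_that("microscopy tables honor means, ratios, seeds and the shape registry", {
  spec <- list(list(taxon = "t1", group = "ciliate", trophic = "hetero",
                    shape = "cone",
                    abundance = c(mar = 100, apr = 3400),
                    dims_mean = c(40, 30), dims_sd = c(0, 0)))
  tab <- generate_microscopy_table(spec, seed = 1)
  expect_equal(tab$dim1_um, c(40, 40))
  expect_equal(tab$dim2_um, c(30, 30))
  expect_equal(tab$abundance_cells_per_L[tab$date == "apr"] /
                 tab$abundance_cells_per_L[tab$date == "mar"], 34)
  expect_identical(tab, generate_microscopy_table(spec, seed = 1))

  bad <- spec
  bad[[1]]$shape <- "dodecahedron"
  expect_error(generate_microscopy_table(bad, seed = 1), "unknown shape")
  bad2 <- spec
  bad2[[1]]$group <- "kelp"
  expect_error(generate_microscopy_table(bad2, seed = 1), "unknown plankton")
})
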