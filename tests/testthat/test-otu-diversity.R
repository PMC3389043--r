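test_that("pairwise identity matches the semi-global alignment oracle", {
  expect_equal(pairwise_identity("ACGTACGTAA", "ACGTACGTAA"), 1)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)

  # symmetric, and equal to the independent Biostrings alignment
  base <- rand_dna(300, seed = 51)
  for (i in 1:8) {
    other <- mutated(base, 0.05, seed = 60 + i)
    if (i %% 2 == 0) other <- substr(other, 1, 180)  # truncated-read case
    mine <- pairwise_identity(base, other)
    expect_equal(pairwise_identity(other, base), mine)
    expect_equal(mine, biostrings_identity(base, other), tolerance = 1e-12)
  }
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
})

test_that("greedy clustering reproduces single-linkage components on separated templates", {
  ident <- setNames(rep("ACGTACGTACGTACGTACGTACGT", 5), paste0("r", 1:5))
  one <- cluster_greedy(ident)
  expect_length(one, 1L)
  expect_length(one[[1]]$members, 5L)

  a <- rand_dna(100, seed = 71)
  b <- mutated(a, 0.10, seed = 72)  # ~90% identity
  expect_length(cluster_greedy(c(r1 = a, r2 = b), 0.97), 2L)

  # 60 noisy reads from 3 well-separated templates
  db <- separated_db(3, seed = 73)
  scheme <- default_scheme()
  comm <- generate_community(db, 3, seed = 74, sample_id = "mar")
  gen <- generate_reads(comm, db, scheme, 60, error_rate = 0.005,
                        lmodel = length_model(p_full = 1), seed = 75)
  reads <- demultiplex(gen$reads, scheme)$samples$mar$reads
  otus <- cluster_greedy(reads, 0.97)
  expect_length(otus, 3L)
  oracle <- single_linkage_components(reads, 0.97)
  expect_length(oracle, 3L)
  got <- lapply(otus, function(o) sort(o$members))
  want <- lapply(oracle, sort)
  expect_setequal(
    vapply(got, paste, character(1), collapse = ","),
    vapply(want, paste, character(1), collapse = ","))
  # memberships match the generator truth
  for (o in otus) {
    expect_length(unique(gen$truth$ref_id[match(o$members,
                                                gen$truth$read_id)]), 1L)
  }

  # label permutation does not change the cluster count
  relabeled <- setNames(unname(reads), rev(names(reads)))
  expect_length(cluster_greedy(relabeled, 0.97), 3L)
})

test_that("taxon validation partitions OTUs at the read-support floor", {
  reads <- setNames(
    c(rep(strrep("ACGT", 30), 5), rep(strrep("GGTA", 30), 3),
      rep(strrep("TTAC", 30), 2), strrep("CCAG", 30)),
    paste0("r", 1:11))
  otus <- cluster_greedy(reads)
  sizes <- vapply(otus, function(o) length(o$members), integer(1))
  expect_setequal(sizes, c(5L, 3L, 2L, 1L))
  val <- validate_taxa(otus, 3)
  expect_setequal(vapply(val$validated, function(o) length(o$members),
                         integer(1)), c(5L, 3L))
  expect_length(c(val$validated, val$rejected), length(otus))
  expect_identical(validate_taxa(otus, 1)$validated, otus)
})

test_that("representatives are the longest member above the length floor", {
  reads <- c(r1 = strrep("A", 450), r2 = strrep("A", 500),
             r3 = strrep("A", 300))
  otus <- list(list(otu_id = "OTU1", centroid = "r1",
                    centroid_seq = reads[["r1"]],
                    members = c("r1", "r2", "r3")),
               list(otu_id = "OTU2", centroid = "r3",
                    centroid_seq = reads[["r3"]], members = "r3"))
  out <- select_representatives(otus, reads, 400)
  expect_equal(out[[1]]$representative, "r2")
  expect_true(is.na(out[[2]]$representative))
})

test_that("Chao1 follows the survey's n2 definition with a degenerate fallback", {
  expect_equal(as.numeric(chao1(c(1, 1, 2, 3))), 5)    # n1=2, n2=2 (>=2 reads)
  expect_equal(as.numeric(chao1(c(2, 5, 9))), 3)       # no singletons: S
  all_single <- chao1(c(1, 1, 1))
  expect_equal(as.numeric(all_single), 6)              # 3 + 3*2/2
  expect_true(isTRUE(attr(all_single, "degenerate")))
  expect_equal(as.numeric(chao1(c(1, 1, 2, 3), classic = TRUE)), 6)
  expect_error(chao1(integer(0)), "empty")

  # estimator never undershoots observed richness
  for (seed in 1:25) {
    x <- seeded(seed, stats::rpois(30, 2))
    if (sum(x) == 0) next
    expect_gte(as.numeric(chao1(x)), sum(x > 0))
  }
})

test_that("Shannon, Margalef and Simpson match closed forms and vegan", {
  expect_equal(shannon_index(5), 0)
  expect_equal(simpson_index(5), 0)
  expect_equal(shannon_index(rep(3, 4)), log(4))
  expect_equal(simpson_index(rep(3, 4)), 0.75)
  expect_equal(margalef_index(rep(10, 10)), 9 / log(100))
  expect_equal(shannon_index(c(8, 2), base = 2),
               -(0.8 * log2(0.8) + 0.2 * log2(0.2)))
  expect_equal(simpson_index(c(3, 1), variant = "dominance"), 0.625)
  expect_equal(simpson_index(c(3, 1), variant = "unbiased"),
               1 - (3 * 2 + 0) / (4 * 3))

  for (seed in 1:10) {
    x <- seeded(seed, stats::rpois(20, 3)) + 1L
    expect_equal(shannon_index(x), as.numeric(vegan::diversity(x, "shannon")))
    expect_equal(simpson_index(x), as.numeric(vegan::diversity(x, "simpson")))
  }

  # Shannon is maximal at the uniform vector for fixed S
  unif <- rep(10L, 8)
  h_max <- shannon_index(unif)
  for (seed in 1:10) {
    bump <- seeded(seed, {
      i <- sample(8, 2)
      y <- unif
      y[i[1]] <- y[i[1]] + 3L
      y[i[2]] <- y[i[2]] - 3L
      y
    })
    expect_lt(shannon_index(bump), h_max)
  }
})

test_that("rarefaction matches the hypergeometric expectation, vegan and Monte Carlo", {
  x <- c(5L, 3L, 1L)
  expect_equal(rarefaction_curve(x, sum(x))$expected_otus, 3)
  expect_equal(rarefaction_curve(c(2L, 2L), 1)$expected_otus, 1)
  expect_error(rarefaction_curve(x, sum(x) + 1), "depths")

  depths <- c(1, 3, 5, 9)
  ana <- rarefaction_curve(x, depths)$expected_otus
  expect_true(all(diff(ana) >= 0))
  expect_equal(ana, as.numeric(vegan::rarefy(x, depths)), tolerance = 1e-10)

  mc <- rarefaction_curve(x, 4, mode = "montecarlo", n_rep = 1000, seed = 9)
  ana4 <- rarefaction_curve(x, 4)$expected_otus
  expect_lt(abs(mc$expected_otus - ana4), 3 * mc$se)
})

test_that("normalized relative change matches the survey's worked example and identities", {
  r <- relative_change(660, 5435, 18280, 41057)
  expect_equal(as.numeric(r), (5435 / 41057) / (660 / 18280))
  expect_equal(round(as.numeric(r), 1), 3.7)
  expect_equal(attr(r, "status"), "ok")

  expect_equal(as.numeric(relative_change(10, 20, 100, 200)), 1)

  fwd <- as.numeric(relative_change(7, 13, 100, 250))
  rev <- as.numeric(relative_change(13, 7, 250, 100))
  expect_equal(fwd * rev, 1)

  new <- relative_change(0, 5, 100, 100)
  expect_equal(attr(new, "status"), "new")
  lost <- relative_change(5, 0, 100, 100)
  expect_equal(as.numeric(lost), 0)
  expect_equal(attr(lost, "status"), "lost")
  expect_error(relative_change(-1, 5, 100, 100), "non-negative")
  expect_error(relative_change(1, 5, 0, 100), "positive")
})
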