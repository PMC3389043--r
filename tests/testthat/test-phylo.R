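test_that("K2P distance matches its closed form, symmetry and ape", {
  expect_equal(as.numeric(k2p_distance("ACGTACGT", "ACGTACGT")), 0)

  # 100 comparable columns, 10 transitions (A<->G), 5 transversions
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  d <- k2p_distance(a, b)
  expect_equal(as.numeric(d), -0.5 * log(0.75) - 0.25 * log(0.90),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(d), 4), 0.1702)
  expect_equal(attr(d, "P"), 0.10)
  expect_equal(attr(d, "Q"), 0.05)

  # gapped columns are excluded (pairwise deletion)
  a2 <- paste0("--", a)
  b2 <- paste0("CC", b)
  expect_equal(as.numeric(k2p_distance(a2, b2)), as.numeric(d))

  # symmetry on random pairs, and agreement with ape::dist.dna K80
  base <- rand_dna(200, seed = 81)
  for (i in 1:5) {
    other <- mutated(base, 0.08, seed = 90 + i)
    expect_equal(as.numeric(k2p_distance(base, other)),
                 as.numeric(k2p_distance(other, base)))
    bin <- ape::as.DNAbin(rbind(a = strsplit(tolower(base), "")[[1]],
                                b = strsplit(tolower(other), "")[[1]]))
    expect_equal(as.numeric(k2p_distance(base, other)),
                 as.numeric(ape::dist.dna(bin, model = "K80")),
                 tolerance = 1e-10)
  }

  sat <- k2p_distance(strrep("A", 10), strrep("G", 10), max_distance = 7)
  expect_equal(as.numeric(sat), 7)
  expect_true(isTRUE(attr(sat, "saturated")))
})

test_that("neighbor-joining is exact on additive matrices and label-invariant", {
  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 3, 5, 3, 0, 4, 5, 4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  expect_equal(unname(ape::cophenetic.phylo(t3)[c("a", "b", "c"),
                                                c("a", "b", "c")]),
               unname(d3), tolerance = 1e-9)

  # additive 4-taxon matrix from a known tree: path lengths reproduced
  d4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d4["a", "b"] <- d4["b", "a"] <- 3
  d4["a", "c"] <- d4["c", "a"] <- 5
  d4["a", "d"] <- d4["d", "a"] <- 3
  d4["b", "c"] <- d4["c", "b"] <- 6
  d4["b", "d"] <- d4["d", "b"] <- 4
  d4["c", "d"] <- d4["d", "c"] <- 4
  t4 <- nj_tree(d4)
  expect_equal(unname(ape::cophenetic.phylo(t4)[rownames(d4), rownames(d4)]),
               unname(d4), tolerance = 1e-9)
  # (a,b | c,d) is the unique additive quartet: ab+cd = 7 < ac+bd = ad+bc
  expect_true(ape::is.monophyletic(ape::root(t4, "b"), c("c", "d")))

  perm <- c("c", "a", "d", "b")
  t4p <- nj_tree(d4[perm, perm])
  expect_true(ape::all.equal.phylo(ape::unroot(t4), ape::unroot(t4p),
                                   use.edge.length = FALSE))

  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")
  bad <- d4; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
  neg <- d4; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(nj_tree(neg), "negative")
  expect_true(all(nj_tree(d4)$edge.length >= 0))
})

test_that("bootstrap supports are seeded, bounded and strong for a clean split", {
  base <- rand_dna(300, seed = 101)
  far <- mutated(base, 0.15, seed = 102)
  aln <- align_representatives(c(
    a1 = mutated(base, 0.02, seed = 103),
    a2 = mutated(base, 0.02, seed = 104),
    b1 = mutated(far, 0.02, seed = 105),
    b2 = mutated(far, 0.02, seed = 106)))

  tr <- bootstrap_support(aln, n_replicates = 200, seed = 7)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 1))
  expect_gte(max(sup), 0.95)  # the single internal edge is rock solid

  tr2 <- bootstrap_support(aln, n_replicates = 200, seed = 7)
  expect_identical(tr$node.label, tr2$node.label)

  one <- bootstrap_support(aln, n_replicates = 1, seed = 3)
  sup1 <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 1)))

  # fewer than 4 rows: no internal edges, tree returned unannotated
  tri <- bootstrap_support(aln[1:3], n_replicates = 10, seed = 1)
  expect_null(tri$node.label)
})

test_that("Newick round trips preserve topology, lengths, supports and quoting", {
  txt <- "((a:1,b:2)0.9:0.5,c:3,d:1);"
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(txt, f)
  tr <- read_newick(f)
  expect_setequal(tr$tip.label, c("a", "b", "c", "d"))
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f2)
  tr2 <- read_newick(f2)
  expect_true(ape::all.equal.phylo(tr, tr2))
  expect_identical(tr$node.label, tr2$node.label)

  tr$tip.label[1] <- "Phaeocystis (clone) A'1"
  write_newick(tr, f2)
  tr3 <- read_newick(f2)
  expect_setequal(tr3$tip.label, tr$tip.label)

  writeLines("((a:1,b:2", f)
  expect_error(read_newick(f), "malformed")
})

test_that("the progressive aligner places gaps where pairwise alignment does", {
  same <- c(s1 = "ACGTACGTAC", s2 = "ACGTACGTAC", s3 = "ACGTACGTAC")
  aln <- align_representatives(same)
  expect_identical(unname(aln), unname(same))  # ungapped block

  full <- rand_dna(120, seed = 111)
  deleted <- paste0(substr(full, 1, 50), substr(full, 61, 120))
  out <- align_representatives(c(a = full, b = deleted))
  expect_equal(unname(nchar(out)), c(120L, 120L))
  expect_equal(out[["a"]], full)
  gaps <- gregexpr("-", out[["b"]], fixed = TRUE)[[1]]
  expect_length(gaps, 10L)
  expect_true(all(diff(gaps) == 1))          # one contiguous gap run
  expect_true(all(gaps > 40 & gaps <= 70))   # at the deleted segment

  mixed <- c(x = rand_dna(80, seed = 112), y = rand_dna(95, seed = 113),
             z = rand_dna(90, seed = 114))
  block <- align_representatives(mixed)
  expect_gte(unique(nchar(block)), max(nchar(mixed)))
  expect_identical(align_representatives(mixed), block)  # deterministic
  expect_error(align_representatives(mixed[1]), "at least 2")
})
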