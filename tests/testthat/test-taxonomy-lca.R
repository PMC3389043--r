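test_that("hit filtering applies E-value, min-score and top-percent as specified", {
  hits <- rbind(hit_row("q1", "s1", 1e-30, 100),
                hit_row("q1", "s2", 1e-30, 99.5),
                hit_row("q1", "s3", 1e-30, 80))
  kept <- filter_hits(hits, top_percent = 1)
  expect_setequal(kept$sseqid, c("s1", "s2"))  # 99.5 >= 0.99 * 100; 80 < 99

  expect_equal(nrow(filter_hits(hit_row("q1", "s1", 1e-3, 100))), 0L)
  expect_equal(nrow(filter_hits(hit_row("q1", "s1", 1e-30, 4))), 0L)
  expect_error(filter_hits(hits, e_max = 0), "positive")

  # idempotence and per-query independence on a random table
  many <- do.call(rbind, lapply(1:30, function(i) {
    hit_row(paste0("q", i %% 5), paste0("s", i),
            10^-seeded(i, sample(3:40, 1)), seeded(i + 100, runif(1, 3, 200)))
  }))
  once <- filter_hits(many)
  twice <- filter_hits(once)
  attr(once, "audit") <- NULL
  attr(twice, "audit") <- NULL
  expect_equal(twice, once)
})

test_that("LCA lands on the deepest shared node and reserved bins behave", {
  lineage_df <- data.frame(
    ref_id = c("x1", "x2", "y1", "z1", "u1"),
    lineage = c("family:F1;genus:F1_G1;species:F1_G1_S1",
                "family:F1;genus:F1_G1;species:F1_G1_S2",
                "family:F1;genus:F1_G2;species:F1_G2_S1",
                "family:F2;genus:F2_G1;species:F2_G1_S1",
                ""),
    stringsAsFactors = FALSE)
  lin <- lineage_lookup(lineage_df)

  one <- assign_lca(hit_row("q", "x1", 1e-30, 100), lin)
  expect_equal(one$node, "F1_G1_S1")
  expect_equal(one$rank, "species")

  sisters <- assign_lca(rbind(hit_row("q", "x1", 1e-30, 100),
                              hit_row("q", "x2", 1e-30, 100)), lin)
  expect_equal(sisters$node, "F1_G1")   # sister species -> their genus

  genera <- assign_lca(rbind(hit_row("q", "x1", 1e-30, 100),
                             hit_row("q", "y1", 1e-30, 100)), lin)
  expect_equal(genera$node, "F1")       # two genera -> their family

  families <- assign_lca(rbind(hit_row("q", "x1", 1e-30, 100),
                               hit_row("q", "z1", 1e-30, 100)), lin)
  expect_equal(families$node, "root")   # disjoint families -> root

  expect_equal(assign_lca(hit_row("q", "u1", 1e-30, 100), lin)$node,
               "Not assigned")
  empty <- hit_row("q", "x1", 1e-30, 100)[0, ]
  expect_equal(assign_lca(empty, lin)$node, "No hits")
  expect_error(assign_lca(hit_row("q", "nope", 1e-30, 100), lin), "absent")
})

test_that("min-support pruning conserves reads and moves weak nodes upward", {
  lineage_df <- data.frame(
    ref_id = c("a", "b"),
    lineage = c("family:F1;genus:F1_G1;species:F1_G1_S1",
                "family:F1;genus:F1_G1;species:F1_G1_S2"),
    stringsAsFactors = FALSE)
  tree <- build_taxonomy(lineage_df)
  asg <- data.frame(read_id = c("r1", "r2", "r3"),
                    node = c("F1_G1_S1", "F1_G1_S1", "F1_G1_S2"),
                    rank = "species", stringsAsFactors = FALSE)
  counted <- taxonomy_counts(tree, asg)
  expect_identical(apply_min_support(counted, 1), counted)

  pruned <- apply_min_support(counted, 2)
  expect_equal(pruned$count[pruned$name == "F1_G1_S2"], 0L)
  expect_equal(pruned$count[pruned$name == "F1_G1"], 1L)  # moved to parent
  expect_equal(sum(pruned$count), sum(counted$count))

  # conservation across random assignments and support levels
  for (seed in 1:5) {
    nodes <- tree$name[tree$rank != "reserved"]
    rnd <- data.frame(read_id = paste0("r", 1:20),
                      node = seeded(seed, sample(nodes, 20, TRUE)),
                      rank = "any", stringsAsFactors = FALSE)
    counted <- taxonomy_counts(tree, rnd)
    for (ms in c(1L, 2L, 3L, 10L)) {
      expect_equal(sum(apply_min_support(counted, ms)$count), 20L)
    }
  }
})

test_that("group summaries cover the sample and reject overlapping nodes", {
  lineage_df <- data.frame(
    ref_id = c("a", "b", "c"),
    lineage = c("family:F1;genus:F1_G1;species:F1_G1_S1",
                "family:F1;genus:F1_G2;species:F1_G2_S1",
                "family:F2;genus:F2_G1;species:F2_G1_S1"),
    stringsAsFactors = FALSE)
  tree <- build_taxonomy(lineage_df)
  asg <- data.frame(read_id = paste0("r", 1:10),
                    node = c(rep("F1_G1_S1", 9), "F2_G1_S1"),
                    rank = "species", stringsAsFactors = FALSE)
  counted <- taxonomy_counts(tree, asg)

  root_only <- summarize_groups(counted, "root")
  expect_equal(root_only$percent[1], 100)

  fams <- summarize_groups(counted, c("F1", "F2"))
  expect_equal(sum(fams$percent), 100)
  expect_equal(fams$reads[fams$group == "F1"], 9)

  expect_error(summarize_groups(counted, c("F1", "F1_G1")), "overlap")
  expect_error(summarize_groups(build_taxonomy(lineage_df), "F1"), "empty")
})

test_that("the built-in aligner finds true sources and respects orientation", {
  db <- separated_db(5, seed = 31)
  # error-free read = exact prefix of its source reference
  read <- setNames(substr(db$sequence[2], 1, 300), "r1")
  hits <- align_reads(read, db)
  best <- hits[which.max(hits$bitscore), ]
  expect_equal(best$sseqid, db$ref_id[2])
  expect_equal(best$pident, 100)
  expect_lt(best$evalue, 1e-5)

  # reversed read, no reverse-complement search: nothing crosses the screen
  rev_read <- setNames(revcomp(read), "r1rc")
  rev_hits <- align_reads(rev_read, db)
  expect_true(nrow(rev_hits) == 0L || all(rev_hits$evalue > 1e-5))

  # on a seeded noisy set, >= 95% of reads keep their true source among
  # the retained hits
  scheme <- default_scheme()
  comm <- generate_community(db, 5, seed = 32, sample_id = "mar")
  gen <- generate_reads(comm, db, scheme, 60, error_rate = 0.01, seed = 33)
  reads <- demultiplex(gen$reads, scheme)$samples$mar$reads
  retained <- filter_hits(align_reads(reads, db))
  hit_ok <- vapply(seq_len(nrow(gen$truth)), function(i) {
    gen$truth$ref_id[i] %in%
      retained$sseqid[retained$qseqid == gen$truth$read_id[i]]
  }, logical(1))
  expect_gte(mean(hit_ok), 0.95)
})

test_that("assignment is a partition and generalizes monotonically with top-percent", {
  db <- generate_reference_db(2, 2, 2, seed = 41)
  scheme <- default_scheme()
  comm <- generate_community(db, 6, seed = 42, sample_id = "mar")
  gen <- generate_reads(comm, db, scheme, 50, error_rate = 0.01, seed = 43)
  reads <- demultiplex(gen$reads, scheme)$samples$mar$reads
  hits <- align_reads(reads, db)

  asg <- assign_reads(hits, db, names(reads))
  expect_setequal(asg$read_id, names(reads))  # partition: every read binned
  tree <- taxonomy_counts(build_taxonomy(db), asg)
  expect_equal(sum(tree$count), length(reads))

  # enlarging top-percent can only move an assignment to an ancestor
  wide <- assign_reads(hits, db, names(reads), top_percent = 25)
  lin <- lineage_lookup(db)
  ancestors_of <- function(node) {
    for (l in lin) {
      i <- match(node, l)
      if (!is.na(i)) return(c("root", unname(l[seq_len(i)])))
    }
    c("root", node)
  }
  for (r in names(reads)) {
    narrow_node <- asg$node[asg$read_id == r]
    wide_node <- wide$node[wide$read_id == r]
    if (narrow_node %in% c("No hits", "Not assigned")) next
    expect_true(wide_node %in% ancestors_of(narrow_node))
  }
})
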