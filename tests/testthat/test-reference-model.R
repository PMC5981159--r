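# Reference-model construction, validation and round-trip I/O.

test_that("label reconciliation flags unsequenced tips and drops orphan rows", {
  tree <- ape::read.tree(text = "((g1:1,g2:1):1,(g3:1,g4:1):1,g5:2);")
  traits <- matrix(1, 3, 2,
                   dimnames = list(c("g1", "g2", "g3"), c("K00001", "K00002")))
  copies <- c(g1 = 1, g2 = 2, g3 = 3)

  b <- format_tree_and_traits(tree, traits, copies)
  expect_s3_class(b, "ref_bundle")
  expect_equal(sum(b$sequenced), 3L)
  expect_equal(sum(!b$sequenced), 2L)
  expect_true(validate_bundle(b))

  # identical label sets: identity reorder
  tr2 <- ape::keep.tip(tree, c("g1", "g2", "g3"))
  b2 <- format_tree_and_traits(tr2, traits[c(3, 1, 2), ], copies)
  expect_true(all(b2$sequenced))
  expect_equal(rownames(b2$traits), tr2$tip.label)
  expect_equal(b2$traits[rownames(traits), ], traits)

  # orphan trait row dropped with exactly one warning
  traits_x <- rbind(traits, gX = c(1, 1))
  expect_warning(bx <- format_tree_and_traits(tree, traits_x,
                                              c(copies, gX = 1)),
                 "gX")
  expect_false("gX" %in% rownames(bx$traits))

  # fatal cases
  expect_error(format_tree_and_traits(tree,
      matrix(1, 1, 1, dimnames = list("zz", "K00001")), c(zz = 1)),
      "no trait-table row")
  dup <- traits[c(1, 1, 2), ]
  expect_error(format_tree_and_traits(tree, dup, copies), "duplicate")
})

test_that("format_tree_and_traits is idempotent", {
  b <- tiny_bundle()
  b2 <- format_tree_and_traits(b$tree, b$traits, b$copies,
                               seqs = b$seqs, brite = b$brite)
  expect_equal(b2$traits, b$traits)
  expect_equal(b2$copies, b$copies)
  expect_equal(b2$sequenced, b$sequenced)
  expect_equal(ape::write.tree(b2$tree), ape::write.tree(b$tree))
})

test_that("bundle write/read round-trip is the identity", {
  for (seed in 1:5) {
    fx <- random_bundle(seed)
    dir <- withr::local_tempdir()
    write_bundle(fx$bundle, dir)
    back <- read_bundle(dir)
    expect_equal(back$traits, fx$bundle$traits)
    expect_equal(back$copies, fx$bundle$copies)
    expect_equal(back$sequenced, fx$bundle$sequenced)
    expect_equal(as.character(back$seqs), as.character(fx$bundle$seqs))
    expect_equal(back$brite, fx$bundle$brite)
    # branch lengths to 10 significant digits
    expect_equal(back$tree$edge.length, fx$bundle$tree$edge.length,
                 tolerance = 1e-9)
    expect_equal(back$tree$tip.label, fx$bundle$tree$tip.label)
  }
})

test_that("table reader enforces the format and reports bad cells", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.tsv")

  writeLines(c("#OTU ID\tK00001\tK00002", "g1\t1\t2", "g2\t0\t3"), p)
  m <- read_tsv_matrix(p)     # BIOM-classic header accepted
  expect_equal(rownames(m), c("g1", "g2"))
  expect_equal(m["g2", "K00002"], 3)

  writeLines(c("ID\tK00001", "g1\t-1"), p)
  expect_error(read_tsv_matrix(p), "line 2, column 2")

  writeLines(c("ID\tK00001", "g1\tabc"), p)
  expect_error(read_tsv_matrix(p), "non-numeric cell 'abc'")

  writeLines(c("ID\tK00001", "g1\t1", "g1\t2"), p)
  expect_error(read_tsv_matrix(p), "duplicate")
})

test_that("trait-table builder counts KO annotations per genome", {
  ann <- data.frame(genome = c("g1", "g1", "g1"),
                    gene = c("a", "b", "c"),
                    ko = c("K00001", "K00001", "K00002"))
  brite <- data.frame(ko = "K00002", level1 = "M",
                      level2 = c("x", "y"), level3 = c("P1", "P2"))
  tabs <- build_trait_tables(ann, brite)
  expect_equal(unname(tabs$deduplicated["g1", ]), c(2, 1))
  expect_equal(unname(tabs$duplicated["g1", ]), c(2, 1, 1))
  expect_equal(colnames(tabs$duplicated), c("K00001", "K00002", "K00002"))

  # empty annotation set for a genome -> all-zero row
  expect_message(
    tabs2 <- build_trait_tables(ann, genomes = c("g1", "g2")),
    "g2")
  expect_equal(unname(tabs2$deduplicated["g2", ]), c(0, 0))

  # disjoint KO sets -> union of columns, zeros off-block
  ann3 <- data.frame(genome = c("g1", "g2"), gene = c("a", "b"),
                     ko = c("K00001", "K00009"))
  t3 <- build_trait_tables(ann3)$deduplicated
  expect_equal(dim(t3), c(2L, 2L))
  expect_equal(unname(t3["g1", ]), c(1, 0))
  expect_equal(unname(t3["g2", ]), c(0, 1))

  expect_error(build_trait_tables(
    data.frame(genome = "g1", gene = "a", ko = "bogus")), "invalid KO")
})

test_that("collapsing duplicated columns by first occurrence recovers the deduplicated table", {
  for (seed in 1:5) {
    set.seed(seed)
    kos <- sprintf("K%05d", sample(99999, 6))
    ann <- data.frame(genome = sample(paste0("g", 1:3), 40, replace = TRUE),
                      gene = paste0("gene", 1:40),
                      ko = sample(kos, 40, replace = TRUE))
    cfg <- sim_config(n_tips = 2, f = 1, seed = seed)
    brite <- simulate_brite(kos, cfg)
    tabs <- build_trait_tables(ann, brite)
    first <- !duplicated(colnames(tabs$duplicated))
    collapsed <- tabs$duplicated[, first, drop = FALSE]
    attr(collapsed, "membership") <- NULL
    expect_identical(collapsed,
                     tabs$deduplicated[, colnames(collapsed), drop = FALSE])
    # each repeated column is an exact copy
    for (k in unique(colnames(tabs$duplicated))) {
      cols <- which(colnames(tabs$duplicated) == k)
      for (j in cols)
        expect_identical(unname(tabs$duplicated[, j]),
                         unname(tabs$deduplicated[, k]))
    }
  }
})
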