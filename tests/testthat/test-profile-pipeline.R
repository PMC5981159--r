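# Classification, aggregation, normalization, metagenome prediction and
# pathway collapse.

test_that("classification assigns by global identity with inclusive threshold", {
  set.seed(101)   # aperiodic random 100-mers so no shifted self-matches
  ref <- c(g7 = paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""),
           g2 = paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""))

  # exact match -> 100%
  a <- classify_otus(c(q1 = ref[["g7"]]), ref, threshold = 97)
  expect_equal(a$reference_id, "g7")
  expect_equal(a$identity, 100)

  # 3 mismatches in 100 columns -> exactly 97.0, assigned (inclusive)
  flip <- function(x, i) {
    substr(x, i, i) <- setdiff(c("A", "C", "G", "T"),
                               substr(x, i, i))[1]
    x
  }
  q <- flip(flip(flip(ref[["g7"]], 10), 50), 90)
  a <- classify_otus(c(q1 = q), ref, threshold = 97)
  expect_equal(a$reference_id, "g7")
  expect_equal(a$identity, 97)

  # 10 mismatches -> 90% < 97 -> UNASSIGNED
  q <- ref[["g7"]]
  for (i in seq(5, 41, by = 4)) q <- flip(q, i)
  a <- classify_otus(c(q1 = q), ref, threshold = 97)
  expect_true(is.na(a$reference_id))
  expect_true(is.na(a$identity))

  # only-N query -> UNASSIGNED with warning
  expect_warning(
    an <- classify_otus(c(qn = strrep("N", 100)), ref),
    "UNASSIGNED")
  expect_true(is.na(an$reference_id))

  expect_error(classify_otus(c(q1 = "ACGT"), character(0)), "empty reference")
})

test_that("classification ties break to the smallest reference ID and runs are deterministic", {
  s <- paste(rep("ACGTTGCA", 20), collapse = "")
  ref <- c(g9 = s, g10 = s, g2 = s)    # identical references
  q <- c(q1 = s)
  for (rep in 1:3) {
    a <- classify_otus(q, ref)
    expect_equal(a$reference_id, "g10")  # radix (C collation): g10 < g2 < g9
    expect_equal(a$identity, 100)
  }
})

test_that("terminal gaps are excluded from identity", {
  core <- paste(rep("ACGT", 25), collapse = "")
  ref <- c(g1 = paste0("TTTTTTTT", core, "GGGGGGGG"))  # query is a fragment
  a <- classify_otus(c(q1 = core), ref, threshold = 97)
  expect_equal(a$identity, 100)
  expect_equal(a$reference_id, "g1")
})

test_that("aggregation sums abundances per reference and drops unassigned", {
  otus <- matrix(c(3, 5, 7,
                   1, 2, 4), ncol = 2,
                 dimnames = list(c("otu1", "otu2", "otu3"), c("s1", "s2")))
  a <- data.frame(otu_id = c("otu1", "otu2", "otu3"),
                  reference_id = c("g1", "g1", NA),
                  identity = c(100, 99, NA))
  expect_message(cl <- aggregate_by_reference(a, otus), "1 unassigned")
  expect_equal(unname(cl["g1", ]), c(8, 3))
  expect_equal(colSums(cl), colSums(otus) - otus["otu3", ])

  # single assigned OTU: row copied unchanged
  a1 <- a[1, ]
  cl1 <- aggregate_by_reference(a1, otus[1, , drop = FALSE])
  expect_equal(unname(cl1["g1", ]), unname(otus["otu1", ]))

  a$reference_id <- NA
  expect_error(aggregate_by_reference(a, otus), "no classifiable OTUs")
})

test_that("copy-number normalization divides by clamped predicted copies", {
  cl <- matrix(c(4, 6), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(normalize_by_copy_number(cl, c(g1 = 2, g2 = 1))[, 1]),
               c(2, 6))
  # divisor below 1 clamped
  expect_equal(unname(normalize_by_copy_number(cl, c(g1 = 0.4, g2 = 1))[, 1]),
               c(4, 6))
  expect_error(normalize_by_copy_number(cl, c(g1 = 2)), "no predicted")
})

test_that("metagenome prediction is the normalized-abundance x trait product", {
  traits <- matrix(c(1, 0,
                     2, 1), nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("K1", "K2")))
  norm <- matrix(c(2, 2), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  m <- predict_metagenome(norm, traits)
  expect_equal(unname(m[, 1]), c(6, 2))

  # zero column in, zero column out
  norm0 <- cbind(norm, s2 = c(0, 0))
  expect_equal(unname(predict_metagenome(norm0, traits)[, "s2"]), c(0, 0))

  # single organism, unit abundance: profile column = trait row
  n1 <- matrix(1, 1, 1, dimnames = list("g2", "s1"))
  expect_equal(unname(predict_metagenome(n1, traits)[, 1]),
               unname(traits["g2", ]))

  expect_error(predict_metagenome(
    matrix(1, 1, 1, dimnames = list("zz", "s1")), traits), "missing")
})

test_that("metagenome prediction is linear per sample column", {
  set.seed(3)
  traits <- matrix(runif(12), 3, 4,
                   dimnames = list(paste0("g", 1:3), paste0("K", 1:4)))
  x <- matrix(runif(3), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  y <- matrix(runif(3), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  expect_equal(predict_metagenome(2 * x + 5 * y, traits),
               2 * predict_metagenome(x, traits) +
                 5 * predict_metagenome(y, traits))
})

test_that("pathway collapse fans out or conserves counts by mode", {
  brite <- data.frame(ko = c("K1", "K1", "K2"),
                      level1 = "Metabolism", level2 = "L2",
                      level3 = c("P1", "P2", "P1"))
  prof <- matrix(c(5, 3), ncol = 1, dimnames = list(c("K1", "K2"), "s1"))

  dup <- collapse_to_pathways(prof, brite, "duplicated")
  expect_equal(unname(dup["P1", 1]), 8)
  expect_equal(unname(dup["P2", 1]), 5)
  expect_gte(sum(dup), sum(prof))

  ded <- collapse_to_pathways(prof, brite, "deduplicated")
  expect_equal(unname(ded["P1", 1]), 8)   # K1 first-listed membership is P1
  expect_false("P2" %in% rownames(ded))
  expect_equal(colSums(ded), colSums(prof))

  # unmapped KO pools into Unclassified
  prof2 <- rbind(prof, K9 = 2)
  ded2 <- collapse_to_pathways(prof2, brite, "deduplicated")
  expect_equal(unname(ded2["Unclassified", 1]), 2)
  expect_equal(colSums(ded2), colSums(prof2))

  # all single-membership: totals conserved in both modes
  b1 <- brite[-2, ]
  expect_equal(sum(collapse_to_pathways(prof, b1, "duplicated")), sum(prof))
  expect_equal(sum(collapse_to_pathways(prof, b1, "deduplicated")), sum(prof))

  # hierarchy annotation covers every output row
  h <- attr(dup, "hierarchy")
  expect_equal(h$level3, rownames(dup))
})

test_that("end-to-end pipeline on a synthetic fixture conserves abundance", {
  fx <- random_bundle(5, n_tips = 10L, f = 0.8)
  res <- run_profile_pipeline(fx$query$table, fx$query$seqs, fx$bundle,
                              threshold = 90)
  expect_true(all(colSums(res$classified) <= colSums(fx$query$table) + 1e-9))
  # mass accounting: sum_k M[k,s] = sum_g norm[g,s] * rowSums(traits)[g]
  pred <- predict_traits(fx$bundle)
  row_tot <- rowSums(pred$traits)[rownames(res$normalized)]
  expect_equal(colSums(res$profile),
               colSums(res$normalized * row_tot))
})
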