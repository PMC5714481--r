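test_that("two-member proportions follow the unique-count ratio", {
  expect_equal(round(proportionTwo(291, 86), 4), 0.7719)
  expect_equal(proportionTwo(5, 5), 0.5)
  expect_equal(proportionTwo(0, 0), 0.5)     # identical-paralog equal split
  expect_error(proportionTwo(-1, 3), "nonnegative")

  ## pseudocounted variant
  expect_equal(proportionTwo(7, 38, pseudocount = 0.01), 7.01 / 45.02)
  expect_equal(proportionTwo(0, 0, pseudocount = 0.01), 0.5)

  ## per-kilobase standardization corrects for unequal gene length
  expect_equal(proportionTwo(100, 100, lengths = c(1000, 2000)),
               (1000 * 100 / 1000) / (1000 * 100 / 1000 + 1000 * 100 / 2000))
})

test_that("progressive allocation reproduces the three-gene worked example", {
  res <- progressiveAllocate(
    c(A = 7, B = 6, C = 12),
    list(list(genes = c("B", "C"), count = 20),
         list(genes = c("A", "B", "C"), count = 23)))
  expect_equal(allocatedCounts(res),
               c(A = 10.57778, B = 19.14074, C = 38.28148), tolerance = 5e-7)
  expect_equal(round(sharedProportions(res)[["A+B+C"]], 5),
               c(A = 0.15556, B = 0.28148, C = 0.56296))
  ## the pairwise stage leaves B and C at 6 + 20/3 and 12 + 40/3
  expect_equal(stageCounts(res)$size2,
               c(A = 7, B = 12.66667, C = 25.33333), tolerance = 5e-7)
  ## exact rational identities behind the printed decimals
  expect_equal(allocatedCounts(res)[["A"]], 7 + 23 * 7 / 45)
  expect_equal(allocatedCounts(res)[["C"]], 12 + 40 / 3 + 23 * (76 / 3) / 45)
})

test_that("progressive allocation conserves reads and ignores input order", {
  uniq <- c(A = 7, B = 6, C = 12)
  sets <- list(list(genes = c("B", "C"), count = 20),
               list(genes = c("A", "B", "C"), count = 23))
  res <- progressiveAllocate(uniq, sets)
  expect_equal(sum(allocatedCounts(res)), sum(uniq) + 20 + 23)
  for (p in sharedProportions(res))
    expect_equal(sum(p), 1, tolerance = 1e-12)

  ## permuting genes and set order changes nothing
  res2 <- progressiveAllocate(uniq[c("C", "A", "B")], rev(sets))
  expect_equal(allocatedCounts(res2)[names(uniq)], allocatedCounts(res))

  ## equal-size sets are resolved from the same stage-entry state
  sets3 <- list(list(genes = c("A", "B"), count = 10),
                list(genes = c("B", "C"), count = 20))
  r3a <- progressiveAllocate(uniq, sets3)
  r3b <- progressiveAllocate(uniq, rev(sets3))
  expect_equal(allocatedCounts(r3a), allocatedCounts(r3b))
})

test_that("progressive allocation reduces to the two-member ratio at F = 2", {
  for (nu in list(c(g1 = 291, g2 = 86), c(g1 = 3, g2 = 0), c(g1 = 0, g2 = 0))) {
    res <- progressiveAllocate(
      nu, list(list(genes = names(nu), count = 12)),
      params = allocationParams(lengthNormalize = "never"))
    p1 <- proportionTwo(nu[[1]], nu[[2]])
    expect_equal(allocatedCounts(res)[[1]], nu[[1]] + 12 * p1)
    expect_equal(allocatedCounts(res)[[2]], nu[[2]] + 12 * (1 - p1))
  }
  ## identical paralogs with no unique evidence split equally
  res0 <- progressiveAllocate(
    c(A = 0, B = 0), list(list(genes = c("A", "B"), count = 10)),
    params = allocationParams(lengthNormalize = "never"))
  expect_equal(allocatedCounts(res0), c(A = 5, B = 5))
})

test_that("progressive allocation validates its inputs", {
  expect_error(progressiveAllocate(c(A = 1), list(list(genes = "A", count = 3))),
               "at least two")
  expect_error(progressiveAllocate(c(A = 1, B = 2),
                                   list(list(genes = c("A", "Z"), count = 3))),
               "unknown gene")
  expect_error(progressiveAllocate(c(A = -1, B = 2), list()), "nonnegative")
})

test_that("bit-score and e-value weighting behave as documented", {
  expect_equal(allocateBitscore(c(100, 100)), c(0.5, 0.5))
  expect_equal(allocateBitscore(c(100, 50)), c(2 / 3, 1 / 3))
  expect_error(allocateBitscore(c(100, 0)), "positive")
  set.seed(3)
  b <- runif(7, 10, 200)
  expect_equal(sum(allocateBitscore(b)), 1, tolerance = 1e-12)

  expect_equal(allocateEvalue(c(1e-5, 1e-5)), c(0.5, 0.5))
  expect_equal(allocateEvalue(c(1e-10, 1e-5)),
               c(1 / (1 + 1e-5), 1e-5 / (1 + 1e-5)))
  expect_equal(sum(allocateEvalue(c(0, 1e-50, 3e-10))), 1)
  expect_error(allocateEvalue(c(-1, 1)), "nonnegative")

  ## e-value weighting is strictly more biased toward the best hit than
  ## bit-score weighting for the same ranking
  bs <- c(98, 93)
  ev <- c(1e-20, 1e-18)
  expect_gt(allocateEvalue(ev)[1], allocateBitscore(bs)[1])
})

test_that("allocateAll partitions families, conserves reads, allocates shared sets", {
  mkTable <- function(readId, copy, genes, scores = NULL) {
    n <- length(readId)
    if (is.null(scores)) scores <- lapply(lengths(genes), function(m) rep(50, m))
    new("MatchTable", hits = S4Vectors::DataFrame(
      readId = readId, copyNumber = as.integer(copy),
      genes = IRanges::CharacterList(genes),
      scores = IRanges::NumericList(scores),
      evalues = IRanges::NumericList(lapply(lengths(genes), function(m)
        rep(NA_real_, m)))))
  }
  ## two independent families plus an unmapped read
  mt <- mkTable(c("S1_7", "S2_6", "S3_12", "S4_20", "S5_23", "S6_9", "S7_4", "S8_2"),
                c(7, 6, 12, 20, 23, 9, 4, 2),
                list("A", "B", "C", c("B", "C"), c("A", "B", "C"),
                     "X", c("X", "Y"), character(0)))
  lens <- c(A = 500, B = 500, C = 500, X = 400, Y = 400)
  res <- allocateAll(mt, lens)
  cnt <- allocatedCounts(res)
  expect_equal(cnt[c("A", "B", "C")],
               c(A = 10.57778, B = 19.14074, C = 38.28148), tolerance = 5e-7)
  expect_equal(cnt[["X"]], 13)    # 9 unique + all 4 shared (Y has none)
  expect_equal(cnt[["Y"]], 0)
  expect_equal(unmappedCount(res), 2)
  expect_equal(sum(cnt) + unmappedCount(res), 7 + 6 + 12 + 20 + 23 + 9 + 4 + 2)
  fam <- geneFamilies(res)
  expect_equal(fam[["A"]], fam[["B"]])
  expect_true(fam[["A"]] != fam[["X"]])

  ## only unique matches: allocation is the identity on raw counts
  mtU <- mkTable(c("S1_5", "S2_3"), c(5, 3), list("A", "B"))
  expect_equal(allocatedCounts(allocateAll(mtU, lens))[c("A", "B")],
               c(A = 5, B = 3))
})

test_that("per-read bit-score and e-value schemes divide each shared read", {
  h <- S4Vectors::DataFrame(
    readId = c("S1_10", "S2_6"),
    copyNumber = c(10L, 6L),
    genes = IRanges::CharacterList(list(c("g1", "g2"), "g1")),
    scores = IRanges::NumericList(list(c(98, 49), 50)),
    evalues = IRanges::NumericList(list(c(1e-20, 1e-10), 1e-12)))
  mt <- new("MatchTable", hits = h)
  resB <- allocateAll(mt, params = allocationParams(scheme = "bitscore"))
  expect_equal(allocatedCounts(resB)[["g1"]], 6 + 10 * 98 / 147)
  expect_equal(sum(allocatedCounts(resB)), 16)
  resE <- allocateAll(mt, params = allocationParams(scheme = "evalue"))
  expect_equal(allocatedCounts(resE)[["g1"]],
               6 + 10 * (1 / (1 + 1e-10)))
  expect_equal(sum(allocatedCounts(resE)), 16)
})

test_that("simulated three-gene family counts are recovered within 3 SE", {
  ## independent reads (no PCR duplication) so the binomial error oracle
  ## applies read-by-read
  genes <- makeFamily(3, 600, divergence = 0.1, seed = 11, segmented = TRUE)
  sim <- simulateReads(genes, c(A = 7000, B = 6000, C = 7000),
                       readLength = 50, errorRate = 0, dupSkew = 0,
                       seed = 11)
  idx <- buildKmerIndex(genes)
  mt <- matchReads(collapseReads(sim$reads)$unique, idx)
  res <- allocateAll(mt, genes)
  total <- length(sim$reads)
  expect_equal(sum(allocatedCounts(res)) + unmappedCount(res), total)
  for (g in names(genes)) {
    p <- sim$truth[[g]] / total
    se <- sqrt(total * p * (1 - p))
    expect_lt(abs(allocatedCounts(res)[[g]] - sim$truth[[g]]), 3 * se)
  }
})
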