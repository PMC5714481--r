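test_that("index construction covers both strands and rejects bad input", {
  set.seed(11)
  g <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  genes <- Biostrings::DNAStringSet(c(g1 = g))
  idx <- buildKmerIndex(genes, k = 12)
  ## L - k + 1 forward positions, plus as many on the reverse complement
  expect_equal(length(ls(idx$table)), length(unique(
    c(substring(g, 1:39, 12:50),
      substring(as.character(Biostrings::reverseComplement(genes[[1]])),
                1:39, 12:50)))))

  expect_error(buildKmerIndex(Biostrings::DNAStringSet(), k = 12), "empty")
  expect_error(buildKmerIndex(genes, k = 5), "\\[8, 32\\]")
  expect_warning(
    buildKmerIndex(Biostrings::DNAStringSet(c(g1 = g, tiny = "ACGTACGT")),
                   k = 15), "shorter than k")
})

test_that("a read finds its source gene with a full-length score", {
  set.seed(12)
  g <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  genes <- Biostrings::DNAStringSet(c(g1 = g))
  idx <- buildKmerIndex(genes)
  read <- substr(g, 101, 150)
  h <- matchRead(read, idx)
  expect_equal(nrow(h), 1L)
  expect_equal(h$gene, "g1")
  expect_equal(h$score, 50L)
  expect_equal(h$span, 50L)
  expect_equal(h$strand, "+")

  ## strand symmetry: the reverse complement hits the same gene set
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(read)))
  h2 <- matchRead(rc, idx)
  expect_equal(h2$gene, "g1")
  expect_equal(h2$score, 50L)
  expect_equal(h2$strand, "-")
})

test_that("identical paralogs tie and duplicated genes hit symmetrically", {
  genes <- makeFamily(2, 200, divergence = 0, seed = 4)
  idx <- buildKmerIndex(genes)
  read <- substr(as.character(genes[[1]]), 51, 100)
  best <- classifyHits(matchRead(read, idx))
  expect_setequal(best$gene, c("A", "B"))
  expect_equal(unique(best$score), 50L)

  ## every read drawn from identical paralogs is classified shared
  sim <- simulateReads(genes, c(A = 150, B = 150), readLength = 50, seed = 4)
  mt <- matchReads(collapseReads(sim$reads)$unique, idx)
  expect_true(all(lengths(hits(mt)$genes) == 2L))
})

test_that("reads overhanging a gene end count when enough bases align inside", {
  set.seed(13)
  bases <- c("A", "C", "G", "T")
  g <- paste(sample(bases, 100, replace = TRUE), collapse = "")
  genes <- Biostrings::DNAStringSet(c(tail36 = g))
  idx <- buildKmerIndex(genes)
  read <- paste0(substr(g, 65, 100),
                 paste(sample(bases, 14, replace = TRUE), collapse = ""))
  h <- matchRead(read, idx, minInGene = 25)
  expect_equal(h$gene, "tail36")
  expect_equal(h$span, 36L)
  expect_equal(h$score, 36L)
  ## raising the floor above the in-gene span drops the hit
  expect_equal(nrow(matchRead(read, idx, minInGene = 40)), 0L)
})

test_that("classification keeps exactly the top-score set", {
  df <- data.frame(gene = c("g1", "g2"), score = c(60, 40))
  expect_equal(classifyHits(df)$gene, "g1")
  df2 <- data.frame(gene = c("g1", "g2"), score = c(50, 50))
  expect_setequal(classifyHits(df2)$gene, c("g1", "g2"))
  expect_equal(nrow(classifyHits(df[0, ])), 0L)
  ## e-value breaks a bit-score tie when present
  df3 <- data.frame(gene = c("g1", "g2"), score = c(50, 50),
                    evalue = c(1e-30, 1e-20))
  expect_equal(classifyHits(df3)$gene, "g1")
})

test_that("divergent genes' own substrings map uniquely back (self-match)", {
  genes <- makeFamily(3, 400, divergence = 0.2, seed = 6)
  idx <- buildKmerIndex(genes)
  set.seed(6)
  for (g in names(genes)) {
    s <- as.character(genes[[g]])
    for (start in sample(1:(400 - 30), 5)) {
      best <- classifyHits(matchRead(substr(s, start, start + 29), idx,
                                     minInGene = 25))
      expect_equal(best$gene, g)
    }
  }
})

test_that("tabular hits parse copies, break ties on bit score and e-value", {
  f <- tempfile()
  row <- function(...) paste(..., sep = "\t")
  writeLines(c(
    row("S1_200", "g1", "100", "50", "0", "0", "1", "50", "1", "50", "1e-20", "98.0"),
    row("S2_5", "g1", "100", "50", "0", "0", "1", "50", "1", "50", "1e-20", "98.0"),
    row("S2_5", "g2", "100", "50", "0", "0", "1", "50", "1", "50", "1e-20", "98.0"),
    row("S3_4", "g1", "100", "50", "0", "0", "1", "50", "1", "50", "1e-20", "98.0"),
    row("S3_4", "g2", "100", "50", "0", "0", "1", "50", "1", "50", "1e-19", "97.1")
  ), f)
  mt <- loadTabularHits(f)
  h <- hits(mt)
  expect_equal(h$copyNumber, c(200L, 5L, 4L))
  expect_equal(h$genes[[1]], "g1")                  # unique match
  expect_setequal(h$genes[[2]], c("g1", "g2"))      # exact tie -> shared
  expect_equal(h$genes[[3]], "g1")                  # 98.0 beats 97.1

  ## unparseable copy suffix warns and counts one copy
  f2 <- tempfile()
  writeLines(row("readX", "g1", "100", "50", "0", "0", "1", "50", "1", "50",
                 "1e-20", "98.0"), f2)
  expect_warning(mt2 <- loadTabularHits(f2), "assuming 1 copy")
  expect_equal(hits(mt2)$copyNumber, 1L)

  ## malformed rows are reported with their line number
  f3 <- tempfile()
  writeLines(c(row("S1_2", "g1", "100", "50", "0", "0", "1", "50", "1", "50",
                   "1e-20", "98.0"),
               "S2_3\tg1\tonly_three_columns"), f3)
  expect_error(loadTabularHits(f3), "line 2")
})
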