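test_that("low-count filter drops genes below the total-count threshold", {
  m <- matrix(c(2, 2, 0, 2, 2, 1, 3, 2, 1), 3, 3,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b", "c")))
  # gene totals 4, 5, 6 with the default threshold of 5
  m[1, ] <- c(1, 2, 1); m[2, ] <- c(2, 2, 1); m[3, ] <- c(3, 2, 1)
  out <- lowCountFilter(m)
  expect_equal(rownames(out), c("g2", "g3"))
  expect_equal(lowCountFilter(m, min_total = 0), m)
  expect_error(lowCountFilter(matrix(0, 3, 2)), "no gene")
  expect_error(lowCountFilter(-m), "nonnegative")
})

test_that("GMT round-trips with category tags and exclusion flags", {
  sigs <- defaultSignatures(700)
  sigs[[3]]@excluded <- TRUE
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "s.gmt")
  writeGMT(sigs, gmt)
  tags <- file.path(dir, "tags.tsv")
  write.table(data.frame(
    signature = vapply(sigs, function(s) s@name, character(1)),
    category = vapply(sigs, function(s) s@category, character(1)),
    excluded = vapply(sigs, function(s) s@excluded, logical(1))),
    tags, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readGMT(gmt, tags)
  expect_length(back, length(sigs) - 1)  # excluded signature dropped
  expect_equal(back[[1]]@genes, sigs[[1]]@genes)
  expect_equal(back[[6]]@category, sigs[[7]]@category)
})

test_that("enrichment walk attains its analytic extremes", {
  # 60 genes, 3 samples; in sample s1 the signature genes dominate every
  # ranking statistic, the rest sit at the bottom
  n <- 60
  ids <- sprintf("g%03d", 1:n)
  sig_genes <- ids[1:10]
  expr <- matrix(rnorm(n * 3, sd = 0.1), n, 3,
                 dimnames = list(ids, c("s1", "s2", "s3")))
  expr[1:10, "s1"] <- 100 + 1:10
  expr[11:n, "s1"] <- -100 - (11:n)
  sig <- new("SignatureSet", name = "top", genes = sig_genes,
             category = "neutral", excluded = FALSE)
  sc <- scoreSignatures(expr, list(sig))
  # fully separated list: the walk climbs to its maximum of 1 and never
  # dips below its endpoint at 0
  expect_equal(unname(scoreMatrix(sc)["s1", "top"]), 1)
  # whole-universe signature scores 0 by definition
  all_sig <- new("SignatureSet", name = "all", genes = ids,
                 category = "neutral", excluded = FALSE)
  expect_equal(unname(scoreMatrix(scoreSignatures(expr, list(all_sig)))[, 1]),
               rep(0, 3))
})

test_that("a signature and its complement score to exact opposites", {
  set.seed(31)
  n <- 80
  ids <- sprintf("g%03d", 1:n)
  expr <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(ids, paste0("s", 1:6)))
  sig <- new("SignatureSet", name = "a", genes = ids[1:15],
             category = "neutral", excluded = FALSE)
  comp <- new("SignatureSet", name = "b", genes = ids[16:n],
              category = "neutral", excluded = FALSE)
  sc <- scoreMatrix(scoreSignatures(expr, list(sig, comp)))
  expect_equal(sc[, "a"], -sc[, "b"], tolerance = 1e-12)
})

test_that("scores are invariant to monotone transformations of expression", {
  set.seed(32)
  st <- setNames(seq(-1, 1, length.out = 10), sprintf("L%02d", 1:10))
  sigs <- defaultSignatures(700)
  ex <- simulateExpression(st, n_genes = 700, signatures = sigs, seed = 33)
  s1 <- scoreMatrix(scoreSignatures(ex$expression, sigs))
  s2 <- scoreMatrix(scoreSignatures(exp(ex$expression / 3), sigs))
  expect_identical(s1, s2)
})

test_that("small signatures are skipped with a warning", {
  set.seed(34)
  expr <- matrix(rnorm(300), 100, 3,
                 dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:3)))
  tiny <- new("SignatureSet", name = "tiny", genes = c("g001", "g002"),
              category = "neutral", excluded = FALSE)
  ok <- new("SignatureSet", name = "ok", genes = sprintf("g%03d", 1:20),
            category = "neutral", excluded = FALSE)
  expect_warning(sc <- scoreSignatures(expr, list(tiny, ok)), "skipped")
  expect_equal(colnames(scoreMatrix(sc)), "ok")
})

test_that("the NIR gradient recovers planted rank-one score structure", {
  set.seed(35)
  u <- rnorm(12)
  dir <- c(rep(1, 4), rep(-1, 4), rep(0.5, 2))
  m <- outer(u, dir)
  dimnames(m) <- list(sprintf("L%02d", 1:12), sprintf("sig%02d", 1:10))
  tags <- setNames(rep(c("neurodevelopmental", "mesenchymal-injury",
                         "neutral"), c(4, 4, 2)), colnames(m))
  sc <- new("SignatureScores", scores = m, tags = tags)
  nir <- nirGradient(sc)
  expect_equal(abs(cor(nirCoordinates(nir), u)), 1, tolerance = 1e-8)
  # orientation rule: mean neurodevelopmental loading >= 0 makes the
  # gradient co-directional with u (ND columns carry +u)
  expect_gt(cor(nirCoordinates(nir), u), 0)
  # negating every score column reverses the biology, and the oriented
  # gradient follows: high coordinate stays aligned with high ND scores
  sc2 <- new("SignatureScores", scores = -m, tags = tags)
  nir2 <- nirGradient(sc2)
  expect_equal(nirCoordinates(nir2), -nirCoordinates(nir),
               tolerance = 1e-8)
  nd_cols <- names(tags)[tags == "neurodevelopmental"]
  expect_gt(cor(nirCoordinates(nir), rowMeans(m[, nd_cols])), 0)
  expect_gt(cor(nirCoordinates(nir2), rowMeans(-m[, nd_cols])), 0)
  expect_gte(nir@varianceFraction, 0.99)
})

test_that("degenerate score matrices are rejected", {
  m <- matrix(1, 5, 3, dimnames = list(paste0("s", 1:5), paste0("k", 1:3)))
  tags <- setNames(rep("neutral", 3), colnames(m))
  expect_error(nirGradient(new("SignatureScores", scores = m, tags = tags)),
               "degenerate")
  expect_error(nirGradient(new("SignatureScores",
                               scores = m[1:2, ], tags = tags)),
               ">= 3 samples")
})
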