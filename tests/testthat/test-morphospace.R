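test_that("normalization scales per sample then standardizes rows", {
  ft <- make_feature_table(n_samples = 2, n_tp = 3, seed = 2)
  ft@data$asm <- rep(c(2, 4, 8), 2)  # a known column within each sample
  ftn <- normalizeFeatures(ft)
  # step-1 record: the per-sample max-abs factors are kept
  expect_equal(unname(ftn@normalization$per_sample_max$S01$a_f["asm"]), 8)
  fm <- featureMatrix(ftn)
  expect_lt(max(abs(rowMeans(fm))), 1e-12)
  expect_lt(max(abs(apply(fm, 1, sd) - 1)), 1e-12)
})

test_that("per-sample scaling removes gross between-sample scale", {
  ft <- make_feature_table(n_samples = 1, n_tp = 5, seed = 3)
  b <- ft@data; b$sample_id <- "S99"
  b[, featureNames(ft)] <- 3 * b[, featureNames(ft)]
  ft2 <- ft
  ft2@data <- rbind(ft@data, b)
  ftn <- normalizeFeatures(ft2)
  fa <- featureMatrix(ftn)[ftn@data$sample_id == "S01", ]
  fb <- featureMatrix(ftn)[ftn@data$sample_id == "S99", ]
  expect_equal(fa, fb, tolerance = 1e-12)
})

test_that("flat feature rows are flagged, not standardized into NaN", {
  ft <- make_feature_table(n_samples = 1, n_tp = 4, seed = 4)
  ft@data[2, featureNames(ft)] <- 0
  ftn <- expect_silent(normalizeFeatures(ft))
  expect_equal(ftn@normalization$flat_rows, 2L)
  expect_true(all(is.finite(featureMatrix(ftn))))
})

test_that("equal-frequency binning distributes groups evenly and monotonically", {
  ft <- make_feature_table(n_samples = 5, n_tp = 18, seed = 5)  # 90 groups
  lv <- assignConfluencyLevels(ft, n_levels = 9L)
  a <- lv@assignments
  expect_equal(as.vector(table(a$level)), rep(10L, 9))
  ord <- order(a$group_mean_area)
  expect_true(all(diff(a$level[ord]) >= 0))
  # ties broken deterministically, every level non-empty
  ft2 <- make_feature_table(n_samples = 3, n_tp = 6, seed = 6)
  ft2@data$confluency <- 0.5
  lv2 <- assignConfluencyLevels(ft2, n_levels = 6L)
  expect_equal(sort(unique(lv2@assignments$level)), 1:6)
  expect_error(assignConfluencyLevels(ft2, n_levels = 99L), "smaller")
})

test_that("per-level PCA matches eigendecomposition and is well-formed", {
  ft <- make_feature_table(n_samples = 4, n_tp = 9, n_rep = 3, seed = 7)
  ftn <- normalizeFeatures(ft)
  lv <- assignConfluencyLevels(ftn, n_levels = 3L)
  mp <- pcaPerLevel(ftn, lv)
  for (m in mp@models) {
    expect_equal(crossprod(m$loadings),
                 diag(ncol(m$loadings)), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(diff(m$varianceFraction) <= 1e-12))
    expect_lte(sum(m$varianceFraction), 1 + 1e-9)
  }
  # brute-force check on one level: loadings are covariance eigenvectors
  m1 <- mp@models[[1]]
  idx <- morpholink:::level_of_rows(ftn, lv) == m1$level
  x <- morpholink:::scale_safe(featureMatrix(ftn)[idx, ])
  ev <- eigen(cov(x))$vectors[, seq_len(ncol(m1$loadings))]
  align <- abs(colSums(ev * m1$loadings))
  expect_equal(unname(align), rep(1, ncol(m1$loadings)), tolerance = 1e-8)
})

test_that("rank-one structure concentrates variance on PC1", {
  set.seed(8)
  n <- 40
  u <- rnorm(n)
  fm <- outer(u, rnorm(29)) + matrix(rnorm(n * 29, sd = 1e-3), n, 29)
  ft <- make_feature_table(n_samples = 1, n_tp = 20, n_rep = 2, seed = 8)
  ft@data[, featureNames(ft)] <- fm
  lv <- assignConfluencyLevels(ft, n_levels = 2L)
  mp <- suppressWarnings(pcaPerLevel(ft, lv))
  expect_gte(mp@models[[1]]$varianceFraction[1], 0.99)
})

test_that("levels with too few images are skipped with a warning", {
  ft <- make_feature_table(n_samples = 1, n_tp = 5, seed = 9)
  lv <- assignConfluencyLevels(ft, n_levels = 5L)  # 1 image per level
  expect_warning(expect_error(pcaPerLevel(ft, lv), "enough"), "skipped")
})

test_that("sign alignment is idempotent and fixes the reference imc2 rule", {
  ft <- make_feature_table(n_samples = 4, n_tp = 9, n_rep = 2, seed = 10)
  ftn <- normalizeFeatures(ft)
  lv <- assignConfluencyLevels(ftn, n_levels = 3L)
  mp <- pcaPerLevel(ftn, lv)
  al1 <- alignSigns(mp)
  expect_gte(al1@models[[which(vapply(al1@models, function(m) m$level,
                                      integer(1)) == al1@reference)]]$
               loadings["imc2", 2], 0)
  al2 <- alignSigns(al1, reference = al1@reference)
  for (k in seq_along(al1@models)) {
    expect_equal(al2@models[[k]]$loadings, al1@models[[k]]$loadings)
    expect_equal(al2@models[[k]]$scores, al1@models[[k]]$scores)
  }
  # aligned levels agree in direction: loading dot products non-negative
  ref <- al1@models[[1]]
  for (m in al1@models)
    for (k in 1:2)
      expect_gte(sum(m$loadings[, k] *
                       al1@models[[which(vapply(al1@models,
                                                function(x) x$level,
                                                integer(1)) ==
                                           al1@reference)]]$loadings[, k]),
                 0)
})

test_that("mean PC profiles average scores per sample and level", {
  ft <- make_feature_table(n_samples = 3, n_tp = 8, n_rep = 2, seed = 11)
  ftn <- normalizeFeatures(ft)
  lv <- assignConfluencyLevels(ftn, n_levels = 4L)
  mp <- alignSigns(pcaPerLevel(ftn, lv))
  prof <- meanPCBySample(mp)
  m1 <- mp@models[[1]]
  s <- m1$meta$sample_id[1]
  expect_equal(profileMatrix(prof, 1L)[s, 1],
               mean(m1$scores[m1$meta$sample_id == s, 1]))
  # permuting the images within the level leaves the profile unchanged
  perm <- sample(nrow(m1$scores))
  mp2 <- mp
  mp2@models[[1]]$scores <- m1$scores[perm, , drop = FALSE]
  mp2@models[[1]]$meta <- m1$meta[perm, , drop = FALSE]
  expect_equal(profileMatrix(meanPCBySample(mp2), 2L),
               profileMatrix(prof, 2L))
  # samples missing from a level give NA entries, never zeros
  drop_s <- mp@models[[2]]$meta$sample_id != "S01"
  mp3 <- mp
  mp3@models[[2]]$scores <- mp@models[[2]]$scores[drop_s, , drop = FALSE]
  mp3@models[[2]]$meta <- mp@models[[2]]$meta[drop_s, , drop = FALSE]
  expect_true(is.na(profileMatrix(meanPCBySample(mp3), 1L)["S01", 2]))
})

test_that("extreme-quartile composition finds the shifted sample", {
  set.seed(12)
  mk_level <- function(l) {
    sid <- rep(sprintf("S%02d", 1:4), each = 100)
    sc <- rnorm(400)
    sc[sid == "S03"] <- sc[sid == "S03"] + 5
    list(level = l, loadings = diag(29)[, 1:2],
         scores = cbind(PC1 = sc, PC2 = sc),
         varianceFraction = c(0.5, 0.3), signFlips = c(FALSE, FALSE),
         meta = data.frame(sample_id = sid, timepoint_hours = 1))
  }
  mp <- new("MorphoPCA", models = list(mk_level(1L), mk_level(2L)),
            reference = 1L, aligned = TRUE,
            featureNames = morpholink:::all_feature_names())
  comp <- extremeComposition(mp)
  expect_equal(sum(comp$top_count), floor(0.25 * 800))
  expect_gte(comp$top_count[comp$sample_id == "S03"] / sum(comp$top_count),
             0.95)
  expect_true(all(comp$top_fraction >= 0 & comp$top_fraction <= 1))
  expect_true(all(comp$bottom_fraction >= 0 & comp$bottom_fraction <= 1))
})
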