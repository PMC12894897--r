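# Build a small matched (profile, scores) pair with planted structure.
make_profile <- function(u, n_levels = 4, seed = 41) {
  set.seed(seed)
  samples <- names(u)
  prof <- array(NA_real_, c(length(u), n_levels, 2),
                dimnames = list(samples, paste0("C", seq_len(n_levels)),
                                c("PC1", "PC2")))
  for (l in seq_len(n_levels)) {
    prof[, l, 1] <- rnorm(length(u))
    prof[, l, 2] <- u + rnorm(length(u), sd = 1e-8)
  }
  new("SamplePCProfile", profile = prof)
}

test_that("perfect linear relations give r = 1 at p < 0.01 on every level", {
  u <- setNames(rnorm(15, sd = 1), sprintf("L%02d", 1:15))
  prof <- make_profile(u)
  scores <- matrix(2 * u, 15, 3,
                   dimnames = list(names(u), paste0("sig", 1:3)))
  scores[, 2] <- -scores[, 2]
  scores[, 3] <- 1  # constant column: undefined correlation
  sc <- new("SignatureScores", scores = scores,
            tags = setNames(c("neurodevelopmental", "mesenchymal-injury",
                              "neutral"), colnames(scores)))
  out <- correlateProfiles(prof, sc)
  pc2 <- out[out$component == "PC2", ]
  s1 <- pc2[pc2$signature == "sig1", ]
  expect_true(all(s1$defined))
  expect_equal(s1$pearson_r, rep(1, 4), tolerance = 1e-6)
  expect_true(all(s1$p_value < 0.01))
  expect_equal(pc2$pearson_r[pc2$signature == "sig2"], rep(-1, 4),
               tolerance = 1e-6)
  s3 <- pc2[pc2$signature == "sig3", ]
  expect_true(all(!s3$defined))
  expect_true(all(is.na(s3$pearson_r)))
})

test_that("correlation behaves like the permutation null on shuffled labels", {
  set.seed(42)
  n <- 15
  u <- setNames(rnorm(n), sprintf("L%02d", 1:n))
  prof <- make_profile(u, n_levels = 1)
  r <- replicate(1000, {
    perm <- sample(n)
    cor(prof@profile[, 1, 2], u[perm])
  })
  expect_lte(mean(abs(r)), 2 / sqrt(n - 1) + 0.05)
})

test_that("correlation results are scale-invariant", {
  u <- setNames(rnorm(12), sprintf("L%02d", 1:12))
  prof <- make_profile(u, n_levels = 2)
  sc1 <- matrix(u + rnorm(12, sd = 0.3), 12, 1,
                dimnames = list(names(u), "sig"))
  mk <- function(m) new("SignatureScores", scores = m,
                        tags = setNames("neutral", "sig"))
  out1 <- correlateProfiles(prof, mk(sc1))
  out2 <- correlateProfiles(prof, mk(sc1 * 37))
  expect_equal(out1$pearson_r, out2$pearson_r)
  expect_equal(out1$p_value, out2$p_value)
})

test_that("feature aggregation averages within then across levels", {
  ft <- make_feature_table(n_samples = 3, n_tp = 8, n_rep = 2, seed = 43)
  ftn <- normalizeFeatures(ft)
  lv <- assignConfluencyLevels(ftn, n_levels = 4L)
  X <- aggregateImageFeatures(ftn, lv)
  expect_equal(dim(X), c(3, 29))
  expect_true(all(is.finite(X)))
  # duplicating every image leaves the aggregate unchanged
  ft2 <- ftn
  ft2@data <- rbind(ftn@data, ftn@data)
  X2 <- aggregateImageFeatures(ft2, lv)
  expect_equal(X2, X, tolerance = 1e-12)
})

test_that("two opposite level means aggregate to zero", {
  # one sample, one feature engineered to +1 / -1 level means
  ft <- make_feature_table(n_samples = 2, n_tp = 4, n_rep = 2, seed = 44)
  ftn <- normalizeFeatures(ft)
  lv <- assignConfluencyLevels(ftn, n_levels = 2L)
  lvs <- morpholink:::level_of_rows(ftn, lv)
  f1 <- featureNames(ftn)[1]
  x <- ftn@data[[f1]]
  s1 <- ftn@data$sample_id == "S01"
  x[s1 & lvs == 1] <- 1; x[!s1 & lvs == 1] <- -1
  x[s1 & lvs == 2] <- -1; x[!s1 & lvs == 2] <- 1
  ftn@data[[f1]] <- x
  X <- aggregateImageFeatures(ftn, lv)
  # within-level standardization maps S01's images to +1/-1 z values,
  # opposite in the two levels, so the across-level mean is 0
  expect_equal(unname(X["S01", f1]), 0, tolerance = 1e-12)
})

test_that("regularized fits recover a realizable linear target", {
  set.seed(45)
  n <- 40
  X <- matrix(rnorm(n * 29), n, 29,
              dimnames = list(sprintf("L%02d", 1:n),
                              morpholink:::all_feature_names()))
  y <- setNames(X[, 1] - 2 * X[, 5] + 0.5 * X[, 20], rownames(X))
  fits <- fitModels(X, y)
  expect_named(fits, c("ridge", "elastic_net", "lasso"))
  for (f in fits) expect_gte(f@rSquared, 0.99)
  # ridge never zeroes coefficients
  expect_equal(sum(fits$ridge@weights == 0), 0)
})

test_that("ridge at vanishing penalty approaches ordinary least squares", {
  set.seed(46)
  n <- 60; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rnorm(n)
  xs <- morpholink:::scale_safe(X)
  fit <- glmnet::glmnet(xs, y, alpha = 0,
                        lambda = c(1, 1e-4, 1e-10) * sd(y),
                        standardize = FALSE, thresh = 1e-14)
  b <- as.numeric(coef(fit, s = 1e-10 * sd(y)))
  ols <- coef(lm(y ~ xs))
  expect_lt(max(abs(b - ols)), 1e-6)
})

test_that("lasso sparsifies under sparse truth while ridge does not", {
  set.seed(47)
  n <- 40
  X <- matrix(rnorm(n * 29), n, 29,
              dimnames = list(sprintf("L%02d", 1:n),
                              morpholink:::all_feature_names()))
  active <- c(2, 9, 17)
  y <- setNames(drop(X[, active] %*% c(2, -2, 1.5)) + rnorm(n, sd = 0.5),
                rownames(X))
  fits <- fitModels(X, y)
  inactive <- setdiff(seq_len(29), active)
  expect_gte(mean(fits$lasso@weights[inactive] == 0), 0.5)
  expect_equal(sum(fits$ridge@weights == 0), 0)
})

test_that("permuted responses fit poorly under LOOCV-selected penalties", {
  set.seed(48)
  n <- 15
  X <- matrix(rnorm(n * 29), n, 29,
              dimnames = list(sprintf("L%02d", 1:n),
                              morpholink:::all_feature_names()))
  y <- setNames(rnorm(n), rownames(X))
  r2 <- vapply(1:10, function(i) {
    yp <- setNames(sample(y), names(y))
    fitModels(X, yp, alphas = 1)$lasso@rSquared
  }, numeric(1))
  expect_lte(median(r2), 0.3)
})

test_that("the reduced model is exact when the response is one feature", {
  set.seed(49)
  X2 <- matrix(rnorm(24), 12, 2, dimnames = list(sprintf("L%02d", 1:12),
                                                 c("gran_13", "imc1")))
  y <- setNames(X2[, 1], rownames(X2))
  fit <- fitReduced(X2, y)
  expect_equal(fit@rSquared, 1, tolerance = 1e-10)
  expect_equal(fit@kind, "ols_reduced")
  expect_false(fit@saturated)
  # n = 3 with 2 features: exact by construction, flagged saturated
  fit3 <- fitReduced(X2[1:3, ], y[1:3])
  expect_true(fit3@saturated)
  expect_equal(fit3@rSquared, 1, tolerance = 1e-8)
  expect_error(fitReduced(cbind(X2[, 1], X2[, 1]), y), "collinear")
})

test_that("reduced features are the extreme averaged PC2 loadings", {
  ft <- make_feature_table(n_samples = 4, n_tp = 9, n_rep = 2, seed = 50)
  ftn <- normalizeFeatures(ft)
  lv <- assignConfluencyLevels(ftn, n_levels = 3L)
  mp <- alignSigns(pcaPerLevel(ftn, lv))
  feats <- reducedFeatureNames(mp)
  L <- sapply(mp@models, function(m) m$loadings[, 2])
  avg <- rowMeans(L)
  expect_equal(feats[1], names(which.max(avg)))
  expect_equal(feats[2], names(which.min(avg)))
  expect_length(unique(feats), 2)
})

test_that("prediction reproduces fitted values and matches columns by name", {
  set.seed(51)
  n <- 15
  X <- matrix(rnorm(n * 29), n, 29,
              dimnames = list(sprintf("L%02d", 1:n),
                              morpholink:::all_feature_names()))
  y <- setNames(X[, 3] + rnorm(n, sd = 0.2), rownames(X))
  fit <- fitModels(X, y, alphas = 1)$lasso
  pred <- predictNIR(fit, X, y)
  expect_equal(unname(pred$predicted), unname(fit@fitted),
               tolerance = 1e-10)
  # reordering feature columns changes nothing (matched by name)
  perm <- sample(ncol(X))
  pred2 <- predictNIR(fit, X[, perm], y)
  expect_equal(pred2$predicted, pred$predicted)
  expect_error(predictNIR(fit, X[, -3]), "missing feature")
})
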