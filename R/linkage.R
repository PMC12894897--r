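#' Correlate mean-PC profiles with signature scores
#'
#' For every (confluency level, component, signature) cell, the Pearson
#' correlation between the per-sample mean PC score at that level and the
#' signature's per-sample enrichment scores, over the samples shared by
#' both sides, with the p value from the t distribution with n-2 degrees
#' of freedom. Constant vectors on either side give a flagged undefined
#' entry (never a silent 0). A Benjamini-Hochberg adjusted column is
#' emitted alongside the raw p values; the conventional significance
#' threshold on the raw p is 0.01.
#'
#' @param profile a [SamplePCProfile].
#' @param scores a [SignatureScores].
#' @param components component indices to correlate (default 1:2).
#' @return data.frame with `level`, `component`, `signature`, `category`,
#'   `pearson_r`, `p_value`, `p_bh`, `n_samples`, `defined`.
#' @export
correlateProfiles <- function(profile, scores, components = 1:2) {
  prof <- profile@profile
  sm <- scoreMatrix(scores)
  tags <- categoryTags(scores)
  shared <- intersect(dimnames(prof)[[1]], rownames(sm))
  rows <- list()
  for (li in seq_len(dim(prof)[2])) for (k in components) {
    v <- prof[shared, li, k]
    for (sig in colnames(sm)) {
      w <- sm[shared, sig]
      ok <- !is.na(v)
      n <- sum(ok)
      if (n < 3 || stats::sd(v[ok]) == 0 || stats::sd(w[ok]) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          level = dimnames(prof)[[2]][li], component = paste0("PC", k),
          signature = sig, category = unname(tags[sig]),
          pearson_r = NA_real_, p_value = NA_real_, n_samples = n,
          defined = FALSE)
        next
      }
      ct <- stats::cor.test(v[ok], w[ok])
      rows[[length(rows) + 1]] <- data.frame(
        level = dimnames(prof)[[2]][li], component = paste0("PC", k),
        signature = sig, category = unname(tags[sig]),
        pearson_r = unname(ct$estimate), p_value = ct$p.value,
        n_samples = n, defined = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  out$p_bh[out$defined] <- stats::p.adjust(out$p_value[out$defined],
                                           method = "BH")
  # heatmap-ready ordering: signatures by their mean correlation
  mr <- tapply(out$pearson_r, out$signature, mean, na.rm = TRUE)
  out$signature <- factor(out$signature, names(sort(mr, na.last = TRUE)))
  out[order(out$component, out$signature, out$level), ]
}

#' Aggregate within-level-standardized features per sample
#'
#' Produces the one-row-per-sample predictor matrix for the regression:
#' features are standardized within each confluency level, averaged over
#' a sample's images in that level, then averaged across the levels the
#' sample occupies. Duplicating images or reordering them leaves the
#' aggregate unchanged.
#'
#' @param table a normalized [FeatureTable].
#' @param levels a [ConfluencyLevels].
#' @return samples x 29 numeric matrix.
#' @export
aggregateImageFeatures <- function(table, levels) {
  fn <- table@featureNames
  lv <- level_of_rows(table, levels)
  samples <- sort(unique(table@data$sample_id))
  per_level <- list()
  for (l in sort(unique(lv))) {
    idx <- which(lv == l)
    # population-sd standardization: invariant to duplicating images
    xm <- as.matrix(table@data[idx, fn])
    mu <- colMeans(xm)
    sdv <- sqrt(colMeans(sweep(xm, 2, mu, "-")^2))
    x <- sweep(xm, 2, mu, "-")
    live <- sdv > 1e-12
    x[, live] <- sweep(x[, live, drop = FALSE], 2, sdv[live], "/")
    x[, !live] <- 0
    sid <- table@data$sample_id[idx]
    mu <- rowsum(x, sid) / as.vector(table(sid)[sort(unique(sid))])
    per_level[[as.character(l)]] <- mu
  }
  out <- matrix(NA_real_, length(samples), length(fn),
                dimnames = list(samples, fn))
  for (s in samples) {
    mats <- lapply(per_level, function(m)
      if (s %in% rownames(m)) m[s, ] else NULL)
    mats <- mats[!vapply(mats, is.null, logical(1))]
    if (!length(mats)) {
      warning("sample ", s, " has no images in any level; excluded")
      next
    }
    out[s, ] <- colMeans(do.call(rbind, mats))
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

# Shared LOOCV-over-a-lambda-grid engine for the regularized fits.
loocv_glmnet <- function(x, y, alpha, lambda_grid) {
  n <- nrow(x)
  err <- matrix(NA_real_, n, length(lambda_grid))
  for (i in seq_len(n)) {
    fit <- glmnet::glmnet(x[-i, , drop = FALSE], y[-i], alpha = alpha,
                          lambda = lambda_grid, standardize = FALSE)
    pred <- stats::predict(fit, x[i, , drop = FALSE], s = lambda_grid,
                           exact = FALSE)
    err[i, ] <- (pred - y[i])^2
  }
  colMeans(err)
}

#' Fit regularized regressions of the NIR gradient on image features
#'
#' For each elastic-net mixing value alpha in {0 (ridge), 0.5 (elastic
#' net), 1 (lasso)}, the penalty lambda is chosen by leave-one-out
#' cross-validated mean squared error over a 100-point logarithmic grid
#' spanning `[1e-4, 1e2] * sd(y)`, then the model is refitted on all
#' samples at the chosen lambda. Predictors are column-standardized
#' internally and the standardization statistics stored for prediction on
#' new cohorts. `r_squared` is the squared Pearson correlation of fitted
#' vs observed (the predicted-versus-actual convention); the alternative
#' `1 - SSE/SST` value is reported alongside.
#'
#' @param X samples x features numeric matrix (>= 8 samples).
#' @param y response: a [NIRGradient] or a named numeric vector; names
#'   are matched against `rownames(X)`.
#' @param alphas elastic-net mixing values to fit.
#' @return named list of [RegressionFit] (`ridge`, `elastic_net`,
#'   `lasso`).
#' @export
fitModels <- function(X, y, alphas = c(0, 0.5, 1)) {
  y <- as_response(y, rownames(X))
  if (nrow(X) < 8) stop("need >= 8 samples")
  if (stats::sd(y) == 0) stop("constant response")
  xs <- scale_safe(X)
  grid <- rev(10^seq(log10(1e-4), log10(1e2), length.out = 100)) *
    stats::sd(y)
  kinds <- c(`0` = "ridge", `0.5` = "elastic_net", `1` = "lasso")
  out <- list()
  for (a in alphas) {
    cv <- loocv_glmnet(xs, y, a, grid)
    lam <- grid[which.min(cv)]
    fit <- glmnet::glmnet(xs, y, alpha = a, lambda = grid,
                          standardize = FALSE)
    beta <- as.numeric(stats::coef(fit, s = lam))
    w <- stats::setNames(beta[-1], colnames(X))
    fitted <- as.numeric(beta[1] + xs %*% w)
    kind <- kinds[as.character(a)]
    if (is.na(kind)) kind <- sprintf("enet_alpha_%g", a)
    out[[kind]] <- regression_fit(kind, a, lam, w, beta[1], xs, y, fitted,
                                  cv_table = data.frame(lambda = grid,
                                                        loocv_mse = cv))
  }
  out
}

as_response <- function(y, sample_names) {
  if (is(y, "NIRGradient")) y <- nirCoordinates(y)
  if (!is.null(names(y)) && !is.null(sample_names)) {
    if (!all(sample_names %in% names(y)))
      stop("response lacks values for some samples")
    y <- y[sample_names]
  }
  y
}

regression_fit <- function(kind, alpha, lambda, w, intercept, xs, y,
                           fitted, cv_table = data.frame(),
                           saturated = FALSE) {
  r2 <- if (stats::sd(fitted) == 0) 0 else stats::cor(fitted, y)^2
  p <- if (stats::sd(fitted) == 0 || length(y) < 3 || saturated) NA_real_
       else stats::cor.test(fitted, y)$p.value
  sst <- sum((y - mean(y))^2)
  new("RegressionFit", kind = kind, alpha = alpha, lambda = lambda,
      weights = w, intercept = intercept,
      center = attr(xs, "center"), scale = attr(xs, "scale"),
      rSquared = r2, rSquaredSSE = 1 - sum((y - fitted)^2) / sst,
      pValue = p, fitted = stats::setNames(fitted, names(y)),
      cvTable = cv_table, saturated = saturated)
}

#' Names of the two reduced-model features
#'
#' The averaged (across levels) aligned PC2 loadings are computed and the
#' features with the highest positive and the most negative loading are
#' returned — the two-feature reduced predictor set.
#'
#' @param models an aligned [MorphoPCA].
#' @return character(2): c(top positive, top negative).
#' @export
reducedFeatureNames <- function(models) {
  L <- sapply(models@models, function(m) m$loadings[, 2])
  avg <- rowMeans(L)
  c(names(avg)[which.max(avg)], names(avg)[which.min(avg)])
}

#' Ordinary least squares on a two-feature reduced predictor set
#'
#' @param X2 samples x 2 matrix (the reduced features, e.g. selected by
#'   [reducedFeatureNames()]).
#' @param y response (see [fitModels()]).
#' @return a [RegressionFit] of kind `"ols_reduced"`; flagged saturated
#'   when residual degrees of freedom are exhausted.
#' @export
fitReduced <- function(X2, y) {
  y <- as_response(y, rownames(X2))
  if (ncol(X2) != 2) stop("reduced model expects exactly 2 features")
  if (qr(cbind(1, X2))$rank < 3)
    stop("collinear or duplicate reduced-feature columns")
  xs <- scale_safe(X2)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, xs), y)
  w <- stats::setNames(fit$coefficients[-1], colnames(X2))
  saturated <- length(y) <= 3
  regression_fit("ols_reduced", NA_real_, 0, w, fit$coefficients[1], xs,
                 y, as.numeric(cbind(1, xs) %*% fit$coefficients),
                 saturated = saturated)
}

#' Predict the NIR gradient for new samples
#'
#' Applies a fitted model to a new feature matrix. Columns are matched by
#' name (order-independent) and standardized with the training
#' statistics; a missing feature column is an error naming it. When
#' observed responses are supplied, the predicted-vs-observed squared
#' Pearson correlation and its test p value are reported.
#'
#' @param fit a [RegressionFit].
#' @param X_new samples x features matrix with named columns.
#' @param y optional observed response for evaluation.
#' @return list with `predicted` (named numeric) and, when `y` is given,
#'   `r_squared`, `pearson_r` and `p_value`.
#' @export
predictNIR <- function(fit, X_new, y = NULL) {
  need <- names(fit@weights)
  miss <- setdiff(need, colnames(X_new))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  x <- X_new[, need, drop = FALSE]
  xs <- sweep(sweep(x, 2, fit@center[need], "-"), 2, fit@scale[need], "/")
  pred <- as.numeric(fit@intercept + xs %*% fit@weights)
  names(pred) <- rownames(X_new)
  out <- list(predicted = pred)
  if (!is.null(y)) {
    y <- as_response(y, rownames(X_new))
    r <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, y)
    out$pearson_r <- r
    out$r_squared <- r^2
    out$p_value <- if (stats::sd(pred) == 0 || length(y) < 3) NA_real_
                   else stats::cor.test(pred, y)$p.value
  }
  out
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes simulate -> QC -> feature extraction -> normalization ->
#' confluency binning -> per-level PCA with sign alignment -> signature
#' scoring -> NIR gradient -> correlation -> regression, writing every
#' intermediate table as TSV under `out_dir`. Given identical `config`
#' the run is fully deterministic and the written tables byte-identical
#' across repeats.
#'
#' @param config list of settings; recognized keys (with defaults):
#'   `n_lines` (15), `seed` (1), `n_timepoints` (30), `frame_shape`
#'   (c(256, 256)), `effect_size` (2), `noise_sd` (0.5), `n_levels` (9),
#'   `glcm_levels` (8), `glcm_distance` (3), `write_frames` (FALSE).
#' @param out_dir output directory.
#' @return invisible list of the main in-memory results (`features`,
#'   `levels`, `models`, `profile`, `scores`, `nir`, `X`, `fits`,
#'   `reduced`, `correlations`).
#' @export
runPipeline <- function(config = list(), out_dir) {
  cfg <- utils::modifyList(list(n_lines = 15L, seed = 1L,
                                n_timepoints = 30L,
                                frame_shape = c(256L, 256L),
                                effect_size = 2, noise_sd = 0.5,
                                n_levels = 9L, glcm_levels = 8L,
                                glcm_distance = 3L, write_frames = FALSE),
                           config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulateCohort(n_lines = cfg$n_lines, seed = cfg$seed,
                       n_timepoints = cfg$n_timepoints,
                       frame_shape = cfg$frame_shape,
                       effect_size = cfg$effect_size,
                       noise_sd = cfg$noise_sd)
  if (isTRUE(cfg$write_frames)) writeCohort(ds, file.path(out_dir, "data"))
  qc <- qcFilter(ds@frames)
  write_tsv_stable(qc$report, file.path(out_dir, "qc_report.tsv"))
  ft <- extractFeatures(qc$kept, levels = cfg$glcm_levels,
                        distance = cfg$glcm_distance,
                        qc_report = qc$report)
  write_tsv_stable(ft@data, file.path(out_dir, "features_raw.tsv"))
  ftn <- normalizeFeatures(ft)
  write_tsv_stable(ftn@data, file.path(out_dir, "features_normalized.tsv"))
  lv <- assignConfluencyLevels(ftn, n_levels = cfg$n_levels)
  write_tsv_stable(lv@assignments, file.path(out_dir, "levels.tsv"))
  models <- alignSigns(pcaPerLevel(ftn, lv))
  for (m in models@models)
    write_tsv_stable(data.frame(feature = rownames(m$loadings),
                                m$loadings),
                     file.path(out_dir,
                               sprintf("loadings_C%d.tsv", m$level)))
  prof <- meanPCBySample(models)
  pm <- profileMatrix(prof, 2L)
  write_tsv_stable(data.frame(sample_id = rownames(pm), pm),
                   file.path(out_dir, "mean_pc2_profile.tsv"))
  comp <- extremeComposition(models)
  write_tsv_stable(comp, file.path(out_dir, "extreme_composition.tsv"))
  sc <- scoreSignatures(ds@expression, ds@signatures)
  write_tsv_stable(data.frame(sample_id = rownames(scoreMatrix(sc)),
                              scoreMatrix(sc)),
                   file.path(out_dir, "signature_scores.tsv"))
  nir <- nirGradient(sc)
  write_tsv_stable(data.frame(sample_id = names(nirCoordinates(nir)),
                              nir = unname(nirCoordinates(nir))),
                   file.path(out_dir, "nir_gradient.tsv"))
  corr <- correlateProfiles(prof, sc)
  corr$signature <- as.character(corr$signature)
  write_tsv_stable(corr, file.path(out_dir, "correlations.tsv"))
  X <- aggregateImageFeatures(ftn, lv)
  fits <- fitModels(X, nir)
  red_feats <- reducedFeatureNames(models)
  reduced <- fitReduced(X[, red_feats, drop = FALSE], nir)
  fit_summary <- data.frame(
    model = c(names(fits), "ols_reduced"),
    alpha = c(vapply(fits, function(f) f@alpha, numeric(1)), NA),
    lambda = c(vapply(fits, function(f) f@lambda, numeric(1)), 0),
    r_squared = c(vapply(fits, function(f) f@rSquared, numeric(1)),
                  reduced@rSquared),
    r_squared_sse = c(vapply(fits, function(f) f@rSquaredSSE, numeric(1)),
                      reduced@rSquaredSSE),
    p_value = c(vapply(fits, function(f) f@pValue, numeric(1)),
                reduced@pValue),
    n_nonzero = c(vapply(fits, function(f) sum(f@weights != 0),
                         numeric(1)),
                  sum(reduced@weights != 0)))
  write_tsv_stable(fit_summary, file.path(out_dir, "fit_summary.tsv"))
  invisible(list(dataset = ds, features = ftn, levels = lv,
                 models = models, profile = prof, scores = sc, nir = nir,
                 X = X, fits = fits, reduced = reduced,
                 correlations = corr, fit_summary = fit_summary))
}
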