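#' Normalize a feature table (per-sample max scaling, then row z-norm)
#'
#' Two-step normalization of the 29 feature columns:
#' \enumerate{
#'   \item within each sample, every feature column is divided by its
#'     maximum absolute value (the diagonal scaling that expresses each
#'     feature as a fraction of the sample's maximum; zero-max columns
#'     pass through unscaled and are logged);
#'   \item each image's 29-feature row is standardized to mean 0, sd 1
#'     across features (rows with zero variance are left unstandardized
#'     and flagged).
#' }
#' The applied scale factors and transform order are recorded in the
#' returned table's `normalization` slot for reproducibility.
#'
#' @param table a [FeatureTable].
#' @return a normalized [FeatureTable].
#' @export
normalizeFeatures <- function(table) {
  dat <- table@data
  fn <- table@featureNames
  scale_log <- list()
  for (s in unique(dat$sample_id)) {
    idx <- dat$sample_id == s
    mx <- apply(abs(dat[idx, fn, drop = FALSE]), 2, max)
    zero <- mx == 0
    if (any(zero))
      scale_log[[s]] <- list(zero_max_columns = fn[zero])
    mx[zero] <- 1
    dat[idx, fn] <- sweep(dat[idx, fn, drop = FALSE], 2, mx, "/")
    scale_log[[s]] <- c(scale_log[[s]], list(a_f = mx))
  }
  fm <- as.matrix(dat[, fn])
  mu <- rowMeans(fm)
  sdv <- apply(fm, 1, stats::sd)
  flat <- sdv == 0
  live <- !flat
  fm[live, ] <- (fm[live, , drop = FALSE] - mu[live]) / sdv[live]
  dat[, fn] <- fm
  norm <- table@normalization
  norm$per_sample_max <- scale_log
  norm$flat_rows <- which(flat)
  norm$applied_order <- c("per-sample max-abs scaling",
                          "per-image row z-normalization")
  new("FeatureTable", data = dat, featureNames = fn, normalization = norm)
}

#' Assign images to confluency levels
#'
#' Groups images by (sample, time-point), computes each group's mean
#' confluency, and assigns groups to `n_levels` levels by equal-frequency
#' (quantile) binning of the group means across all samples; all images
#' inherit their group's level. Ties on the group mean are broken by
#' (sample_id, time-point) lexical order so every level is non-empty.
#'
#' @param table a [FeatureTable] with `confluency` present.
#' @param n_levels number of levels (the pipeline default is 9).
#' @return a [ConfluencyLevels].
#' @export
assignConfluencyLevels <- function(table, n_levels = 9L) {
  dat <- table@data
  key <- paste(dat$sample_id, dat$timepoint_hours, sep = "\r")
  grp <- stats::aggregate(dat$confluency,
                          by = list(sample_id = dat$sample_id,
                                    timepoint_hours = dat$timepoint_hours),
                          FUN = mean)
  names(grp)[3] <- "group_mean_area"
  if (nrow(grp) < n_levels)
    stop(sprintf(
      "only %d (sample, time-point) groups for %d levels; use a smaller n_levels",
      nrow(grp), n_levels))
  ord <- order(grp$group_mean_area, grp$sample_id, grp$timepoint_hours)
  lev <- integer(nrow(grp))
  # equal-frequency binning of the rank order
  lev[ord] <- as.integer(ceiling(seq_along(ord) / length(ord) * n_levels))
  grp$level <- lev
  new("ConfluencyLevels", assignments = grp, nLevels = as.integer(n_levels))
}

# Map feature-table rows to their group's level (NA when unassigned).
level_of_rows <- function(table, levels) {
  dat <- table@data
  a <- levels@assignments
  key <- paste(dat$sample_id, dat$timepoint_hours, sep = "\r")
  akey <- paste(a$sample_id, a$timepoint_hours, sep = "\r")
  a$level[match(key, akey)]
}

#' Per-confluency-level principal component analysis
#'
#' Within each level, the 29 feature columns are standardized (mean 0,
#' sd 1 across the level's images, controlling for cell density) and
#' decomposed by PCA. Levels with fewer than 3 images are skipped with a
#' warning. Loadings are orthonormal and variance fractions non-increasing;
#' results are deterministic up to component sign, which is fixed later by
#' [alignSigns()].
#'
#' @param table a normalized [FeatureTable].
#' @param levels a [ConfluencyLevels].
#' @param n_components number of components to retain.
#' @return a [MorphoPCA] (unaligned).
#' @export
pcaPerLevel <- function(table, levels, n_components = 5L) {
  fn <- table@featureNames
  lv <- level_of_rows(table, levels)
  models <- list()
  for (l in sort(unique(lv))) {
    idx <- which(lv == l)
    if (length(idx) < 3) {
      warning(sprintf("level %d has %d images; skipped", l, length(idx)))
      next
    }
    x <- scale_safe(as.matrix(table@data[idx, fn]))
    k <- min(n_components, ncol(x), length(idx) - 1L)
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    tot <- sum(pc$sdev^2)
    models[[length(models) + 1]] <- list(
      level = as.integer(l),
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      scores = pc$x[, seq_len(k), drop = FALSE],
      varianceFraction = (pc$sdev^2 / tot)[seq_len(k)],
      signFlips = rep(FALSE, k),
      meta = table@data[idx, c("sample_id", "timepoint_hours")])
  }
  if (!length(models)) stop("no level with enough images")
  new("MorphoPCA", models = models, reference = NA_integer_,
      aligned = FALSE, featureNames = fn)
}

#' Align principal component signs across confluency levels
#'
#' PCA component signs are arbitrary; to compare components across levels
#' they are aligned to a common direction. The reference level (by
#' default the level whose images cover the most samples) first has its
#' PC2 oriented so that the `imc2` loading is non-negative — fixing "high
#' PC2" to the pole where the second informational measure of correlation
#' loads positively. Every other level's component k is then flipped when
#' the dot product of its loading vector with the reference's component-k
#' loading vector is negative. The operation is idempotent.
#'
#' @param models a [MorphoPCA].
#' @param reference optional explicit reference level id.
#' @return an aligned [MorphoPCA].
#' @export
alignSigns <- function(models, reference = NULL) {
  ms <- models@models
  if (is.null(reference)) {
    cover <- vapply(ms, function(m) length(unique(m$meta$sample_id)),
                    integer(1))
    reference <- ms[[which.max(cover)]]$level
  }
  ridx <- which(vapply(ms, function(m) m$level, integer(1)) == reference)
  if (!length(ridx)) stop("reference level not present")
  ref <- ms[[ridx]]
  # orient the reference's PC2 by the imc2 loading
  if (ncol(ref$loadings) >= 2) {
    w <- ref$loadings["imc2", 2]
    if (!is.na(w) && w < 0) {
      ref$loadings[, 2] <- -ref$loadings[, 2]
      ref$scores[, 2] <- -ref$scores[, 2]
      ref$signFlips[2] <- !ref$signFlips[2]
    }
  }
  ms[[ridx]] <- ref
  for (j in seq_along(ms)) {
    if (j == ridx) next
    m <- ms[[j]]
    for (k in seq_len(min(ncol(m$loadings), ncol(ref$loadings)))) {
      if (sum(m$loadings[, k] * ref$loadings[, k]) < 0) {
        m$loadings[, k] <- -m$loadings[, k]
        m$scores[, k] <- -m$scores[, k]
        m$signFlips[k] <- !m$signFlips[k]
      }
    }
    ms[[j]] <- m
  }
  new("MorphoPCA", models = ms, reference = as.integer(reference),
      aligned = TRUE, featureNames = models@featureNames)
}

#' Mean PC score per sample and confluency level
#'
#' For each (sample, level, component), the arithmetic mean of the
#' sample's image scores in that level; samples absent from a level get a
#' missing entry, never a zero.
#'
#' @param models an aligned [MorphoPCA].
#' @return a [SamplePCProfile].
#' @export
meanPCBySample <- function(models) {
  ms <- models@models
  samples <- sort(unique(unlist(lapply(ms, function(m) m$meta$sample_id))))
  lv <- vapply(ms, function(m) m$level, integer(1))
  K <- min(vapply(ms, function(m) ncol(m$scores), integer(1)))
  prof <- array(NA_real_, dim = c(length(samples), length(lv), K),
                dimnames = list(samples, paste0("C", lv),
                                paste0("PC", seq_len(K))))
  for (j in seq_along(ms)) {
    m <- ms[[j]]
    for (s in unique(m$meta$sample_id)) {
      rows <- m$meta$sample_id == s
      prof[s, j, ] <- colMeans(m$scores[rows, seq_len(K), drop = FALSE])
    }
  }
  new("SamplePCProfile", profile = prof)
}

#' Extreme-quartile sample composition along a component
#'
#' Component scores are z-normalized within each confluency level, all
#' images concatenated and ranked by the component; the top and bottom
#' `fraction` of images are taken and each sample's contribution to the
#' two extreme sets is reported as a count and as a fraction of the
#' sample's own image total.
#'
#' @param models an aligned [MorphoPCA].
#' @param fraction extreme-tail fraction (default 0.25).
#' @param component component index (default 2 = PC2).
#' @return data.frame with per-sample `n_images`, `top_count`,
#'   `bottom_count`, `top_fraction`, `bottom_fraction`.
#' @export
extremeComposition <- function(models, fraction = 0.25, component = 2L) {
  ms <- models@models
  z <- lapply(ms, function(m) {
    v <- m$scores[, component]
    s <- stats::sd(v)
    data.frame(sample_id = m$meta$sample_id,
               z = if (s > 0) (v - mean(v)) / s else v * 0)
  })
  all <- do.call(rbind, z)
  n_take <- floor(fraction * nrow(all))
  ord <- order(all$z, decreasing = TRUE)
  top <- all$sample_id[ord[seq_len(n_take)]]
  bottom <- all$sample_id[rev(ord)[seq_len(n_take)]]
  samples <- sort(unique(all$sample_id))
  data.frame(
    sample_id = samples,
    n_images = as.integer(table(factor(all$sample_id, samples))),
    top_count = as.integer(table(factor(top, samples))),
    bottom_count = as.integer(table(factor(bottom, samples))),
    top_fraction = as.numeric(table(factor(top, samples)) /
                                table(factor(all$sample_id, samples))),
    bottom_fraction = as.numeric(table(factor(bottom, samples)) /
                                   table(factor(all$sample_id, samples))))
}
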