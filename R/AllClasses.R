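#' @import methods
NULL

#' CultureSet: a set of paired phase-contrast frames and foreground masks
#'
#' Container for grayscale time-lapse frames of adherent cultures together
#' with their foreground (cell-region) masks and per-frame metadata. Frames
#' are stored as numeric matrices with intensities in `[0, 1]`; masks are
#' logical matrices of identical shape. One row of `meta` describes one
#' frame/mask pair.
#'
#' @slot images list of numeric matrices, one per frame, intensities in
#'   `[0, 1]`.
#' @slot masks list of logical matrices, same shapes as `images`.
#' @slot meta data.frame with columns `sample_id`, `timepoint_hours`,
#'   `pixel_size_um` (one row per frame, kept sorted by sample then time).
#' @slot truth list of generator ground truth (may be empty for loaded
#'   data); per line: planted state, cell orientations, per-frame footprint
#'   pixel counts.
#' @export
setClass("CultureSet",
  representation(images = "list", masks = "list", meta = "data.frame",
                 truth = "list"))

setValidity("CultureSet", function(object) {
  n <- nrow(object@meta)
  if (length(object@images) != n || length(object@masks) != n)
    return("images, masks and meta rows must have equal length")
  need <- c("sample_id", "timepoint_hours", "pixel_size_um")
  if (!all(need %in% names(object@meta)))
    return(paste("meta must contain:", paste(need, collapse = ", ")))
  for (i in seq_len(n)) {
    im <- object@images[[i]]; mk <- object@masks[[i]]
    if (!is.matrix(im) || !is.numeric(im))
      return(sprintf("image %d is not a numeric matrix", i))
    if (!all(is.finite(im)))
      return(sprintf("image %d contains non-finite pixels", i))
    if (!is.matrix(mk) || !is.logical(mk))
      return(sprintf("mask %d is not a logical matrix", i))
    if (!identical(dim(im), dim(mk)))
      return(sprintf("image/mask shape mismatch at frame %d (%s)",
                     i, object@meta$sample_id[i]))
  }
  if (any(object@meta$timepoint_hours < 0))
    return("timepoint_hours must be >= 0")
  TRUE
})

#' FeatureTable: per-image whole-image feature vectors
#'
#' One row per image: 13 gray-level co-occurrence (Haralick) features, a
#' 16-step granularity spectrum, plus the auxiliary columns `confluency`
#' (mask area fraction) and `plls` (power-spectrum log-log slope). The 29
#' texture/granularity columns are the analysis features; the auxiliaries
#' never enter the PCA.
#'
#' @slot data data.frame with `sample_id`, `timepoint_hours`, the 29
#'   feature columns, `confluency`, `plls`.
#' @slot featureNames character(29), the feature column names in canonical
#'   order.
#' @slot normalization list recording the normalization applied (empty
#'   before [normalizeFeatures()]): per-sample scale factors and the order
#'   of transforms.
#' @export
setClass("FeatureTable",
  representation(data = "data.frame", featureNames = "character",
                 normalization = "list"))

setValidity("FeatureTable", function(object) {
  if (length(object@featureNames) != 29)
    return("featureNames must have length 29")
  need <- c("sample_id", "timepoint_hours", object@featureNames,
            "confluency", "plls")
  miss <- setdiff(need, names(object@data))
  if (length(miss))
    return(paste("data lacks columns:", paste(miss, collapse = ", ")))
  fm <- as.matrix(object@data[, object@featureNames])
  if (!all(is.finite(fm))) return("feature values must all be finite")
  TRUE
})

#' ConfluencyLevels: grouping of images into confluency levels
#'
#' Assignment of every (sample, time-point) group to one of `nLevels`
#' confluency levels by equal-frequency binning of group mean confluency
#' across all samples. All images of a group inherit its level.
#'
#' @slot assignments data.frame with `sample_id`, `timepoint_hours`,
#'   `group_mean_area`, `level`.
#' @slot nLevels integer, number of levels (default pipeline uses 9).
#' @export
setClass("ConfluencyLevels",
  representation(assignments = "data.frame", nLevels = "integer"))

setValidity("ConfluencyLevels", function(object) {
  a <- object@assignments
  need <- c("sample_id", "timepoint_hours", "group_mean_area", "level")
  if (!all(need %in% names(a)))
    return(paste("assignments must contain:", paste(need, collapse = ", ")))
  if (any(a$level < 1L | a$level > object@nLevels))
    return("levels out of range")
  TRUE
})

#' MorphoPCA: per-confluency-level principal component models
#'
#' One PCA per confluency level, fitted on within-level standardized
#' feature rows, with optional cross-level sign alignment against a
#' reference level.
#'
#' @slot models list, one element per retained level: `level`, `loadings`
#'   (29 x K orthonormal), `scores` (images x K), `varianceFraction`,
#'   `signFlips` (logical K), `meta` (data.frame of the level's rows).
#' @slot reference integer, level id used as alignment reference (NA before
#'   alignment).
#' @slot aligned logical flag.
#' @slot featureNames character(29).
#' @export
setClass("MorphoPCA",
  representation(models = "list", reference = "integer",
                 aligned = "logical", featureNames = "character"))

#' SamplePCProfile: mean PC score per sample and confluency level
#'
#' @slot profile 3-d numeric array `[samples, levels, components]`; `NA`
#'   where a sample has no image in a level.
#' @export
setClass("SamplePCProfile", representation(profile = "array"))

#' SignatureSet: a named gene set with a biological category tag
#'
#' @slot name character(1).
#' @slot genes character vector of gene ids.
#' @slot category one of `"neurodevelopmental"`, `"mesenchymal-injury"`,
#'   `"neutral"`.
#' @slot excluded logical(1); marks signatures flagged as downregulated
#'   duplicates to be dropped at load.
#' @export
setClass("SignatureSet",
  representation(name = "character", genes = "character",
                 category = "character", excluded = "logical"))

setValidity("SignatureSet", function(object) {
  ok <- c("neurodevelopmental", "mesenchymal-injury", "neutral")
  if (!object@category %in% ok)
    return(paste("category must be one of:", paste(ok, collapse = ", ")))
  if (!length(object@genes)) return("empty gene set")
  TRUE
})

#' SignatureScores: samples x signatures enrichment score matrix
#'
#' @slot scores numeric matrix, rows = samples, columns = signatures.
#' @slot tags named character, category per signature column.
#' @export
setClass("SignatureScores",
  representation(scores = "matrix", tags = "character"))

setValidity("SignatureScores", function(object) {
  if (!all(is.finite(object@scores))) return("scores must be finite")
  if (!identical(sort(names(object@tags)), sort(colnames(object@scores))))
    return("tags must name every score column")
  TRUE
})

#' NIRGradient: per-sample coordinate on the NIR axis
#'
#' First principal component of the signature score matrix, oriented so
#' that higher values are more neurodevelopmental and lower values more
#' mesenchymal/injury-response.
#'
#' @slot coordinates named numeric, one value per sample.
#' @slot varianceFraction numeric(1), variance explained by the component.
#' @slot orientation character(1) description of the fixed orientation.
#' @export
setClass("NIRGradient",
  representation(coordinates = "numeric", varianceFraction = "numeric",
                 orientation = "character"))

#' RegressionFit: a fitted image-features-to-NIR regression model
#'
#' @slot kind `"ridge"`, `"lasso"`, `"elastic_net"` or `"ols_reduced"`.
#' @slot alpha elastic-net mixing parameter (0, 0.5 or 1; NA for OLS).
#' @slot lambda penalty chosen by leave-one-out cross-validation (0 for
#'   OLS).
#' @slot weights named numeric coefficient vector (on standardized
#'   predictors).
#' @slot intercept numeric(1).
#' @slot center,scale named numeric: training standardization statistics.
#' @slot rSquared squared Pearson correlation of fitted vs observed.
#' @slot rSquaredSSE the alternative 1 - SSE/SST definition.
#' @slot pValue correlation-test p value of fitted vs observed.
#' @slot fitted named numeric fitted values.
#' @slot cvTable data.frame of the lambda grid and LOOCV mean squared
#'   errors (empty for OLS).
#' @slot saturated logical: TRUE when residual degrees of freedom are
#'   exhausted (fit is exact by construction).
#' @export
setClass("RegressionFit",
  representation(kind = "character", alpha = "numeric", lambda = "numeric",
                 weights = "numeric", intercept = "numeric",
                 center = "numeric", scale = "numeric",
                 rSquared = "numeric", rSquaredSSE = "numeric",
                 pValue = "numeric", fitted = "numeric",
                 cvTable = "data.frame", saturated = "logical"))

#' SyntheticDataset: a simulated culture cohort with planted ground truth
#'
#' @slot frames [CultureSet] of all lines' images and masks.
#' @slot expression numeric matrix, genes x lines.
#' @slot signatures list of [SignatureSet].
#' @slot truthState named numeric: planted latent state per line, in
#'   `[-1, 1]` (+1 neurodevelopmental pole, -1 injury-response pole).
#' @slot truthActivity numeric matrix lines x signatures: planted mean
#'   expression shift of each signature in each line.
#' @export
setClass("SyntheticDataset",
  representation(frames = "CultureSet", expression = "matrix",
                 signatures = "list", truthState = "numeric",
                 truthActivity = "matrix"))

setValidity("SyntheticDataset", function(object) {
  lines_img <- unique(object@frames@meta$sample_id)
  lines_exp <- colnames(object@expression)
  if (!all(lines_img %in% names(object@truthState)))
    return("truthState must cover every imaged line")
  if (!all(lines_exp %in% names(object@truthState)))
    return("truthState must cover every expression column")
  TRUE
})
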