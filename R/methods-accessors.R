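#' @describeIn CultureSet-class number of frames
#' @param x,i,object see generic
#' @export
setMethod("nFrames", "CultureSet", function(x) nrow(x@meta))

#' @describeIn CultureSet-class extract one frame image
#' @export
setMethod("frameImage", "CultureSet", function(x, i) x@images[[i]])

#' @describeIn CultureSet-class extract one frame mask
#' @export
setMethod("frameMask", "CultureSet", function(x, i) x@masks[[i]])

#' @describeIn CultureSet-class per-frame metadata
#' @export
setMethod("frameMeta", "CultureSet", function(x) x@meta)

#' @describeIn CultureSet-class compact display
#' @export
setMethod("show", "CultureSet", function(object) {
  m <- object@meta
  cat("CultureSet with", nrow(m), "frame/mask pairs,",
      length(unique(m$sample_id)), "sample(s)\n")
  if (nrow(m)) {
    d <- dim(object@images[[1]])
    cat("  frame size:", d[1], "x", d[2],
        sprintf("(%.2f um/px)", m$pixel_size_um[1]), "\n")
    cat("  time span:", min(m$timepoint_hours), "-",
        max(m$timepoint_hours), "h\n")
  }
  if (length(object@truth)) cat("  carries generator ground truth\n")
})

#' @describeIn FeatureTable-class feature matrix (images x 29)
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) {
  m <- as.matrix(x@data[, x@featureNames])
  rownames(m) <- NULL
  m
})

#' @describeIn FeatureTable-class canonical feature names
#' @export
setMethod("featureNames", "FeatureTable", function(x) x@featureNames)

#' @describeIn FeatureTable-class per-image metadata and auxiliaries
#' @export
setMethod("frameMeta", "FeatureTable", function(x)
  x@data[, c("sample_id", "timepoint_hours", "confluency", "plls")])

#' @describeIn FeatureTable-class compact display
#' @export
setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable:", nrow(object@data), "images x",
      length(object@featureNames), "features",
      "(+ confluency, plls)\n")
  if (length(object@normalization))
    cat("  normalized:",
        paste(object@normalization$applied_order, collapse = " -> "), "\n")
})

#' @describeIn MorphoPCA-class canonical feature names
#' @export
setMethod("featureNames", "MorphoPCA", function(x) x@featureNames)

#' @describeIn MorphoPCA-class compact display
#' @export
setMethod("show", "MorphoPCA", function(object) {
  lv <- vapply(object@models, function(m) m$level, integer(1))
  cat("MorphoPCA over", length(lv), "confluency levels:",
      paste(lv, collapse = ", "), "\n")
  cat("  aligned:", object@aligned,
      if (object@aligned) paste0("(reference level ", object@reference, ")")
      else "", "\n")
})

#' @describeIn SamplePCProfile-class mean-PC matrix for one component
#' @param component integer, 1 = PC1, 2 = PC2
#' @export
setMethod("profileMatrix", "SamplePCProfile",
  function(x, component = 2L) x@profile[, , component, drop = TRUE])

#' @describeIn SamplePCProfile-class compact display
#' @export
setMethod("show", "SamplePCProfile", function(object) {
  d <- dim(object@profile)
  cat("SamplePCProfile:", d[1], "samples x", d[2], "levels x",
      d[3], "components;",
      sum(is.na(object@profile[, , 1])), "missing cells in PC1\n")
})

#' @describeIn SignatureScores-class enrichment score matrix
#' @export
setMethod("scoreMatrix", "SignatureScores", function(x) x@scores)

#' @describeIn SignatureScores-class category per signature
#' @export
setMethod("categoryTags", "SignatureScores", function(x) x@tags)

#' @describeIn SignatureScores-class compact display
#' @export
setMethod("show", "SignatureScores", function(object) {
  cat("SignatureScores:", nrow(object@scores), "samples x",
      ncol(object@scores), "signatures\n")
  print(table(object@tags))
})

#' @describeIn NIRGradient-class per-sample coordinates
#' @export
setMethod("nirCoordinates", "NIRGradient", function(x) x@coordinates)

#' @describeIn NIRGradient-class compact display
#' @export
setMethod("show", "NIRGradient", function(object) {
  cat("NIRGradient over", length(object@coordinates), "samples;",
      sprintf("variance fraction %.3f\n", object@varianceFraction))
  cat("  orientation:", object@orientation, "\n")
})

#' @describeIn RegressionFit-class compact display
#' @export
setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("RegressionFit [%s] alpha=%s lambda=%.4g\n", object@kind,
              format(object@alpha), object@lambda))
  cat(sprintf("  R^2 (cor^2) = %.3f, R^2 (1-SSE/SST) = %.3f, p = %.3g\n",
              object@rSquared, object@rSquaredSSE, object@pValue))
  nz <- sum(object@weights != 0)
  cat("  nonzero weights:", nz, "of", length(object@weights),
      if (object@saturated) " [saturated fit]" else "", "\n")
})

#' @describeIn SyntheticDataset-class planted latent state per line
#' @export
setMethod("truthState", "SyntheticDataset", function(x) x@truthState)

#' @describeIn SyntheticDataset-class compact display
#' @export
setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", length(object@truthState), "lines,",
      nFrames(object@frames), "frames,",
      nrow(object@expression), "genes,",
      length(object@signatures), "signatures\n")
})
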