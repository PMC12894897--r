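#' Number of frames in a CultureSet
#' @param x a [CultureSet]
#' @return integer count of frame/mask pairs
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Extract one frame image
#' @param x a [CultureSet]
#' @param i frame index
#' @return numeric matrix of intensities in `[0, 1]`
#' @export
setGeneric("frameImage", function(x, i) standardGeneric("frameImage"))

#' Extract one frame mask
#' @param x a [CultureSet]
#' @param i frame index
#' @return logical matrix
#' @export
setGeneric("frameMask", function(x, i) standardGeneric("frameMask"))

#' Per-frame metadata
#' @param x a [CultureSet] or [FeatureTable]
#' @return data.frame of per-frame metadata
#' @export
setGeneric("frameMeta", function(x) standardGeneric("frameMeta"))

#' The 29-column feature matrix of a FeatureTable
#' @param x a [FeatureTable]
#' @return numeric matrix, images x 29
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Canonical feature names
#' @param x a [FeatureTable] or [MorphoPCA]
#' @return character(29)
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Per-sample mean-PC matrix for one component
#' @param x a [SamplePCProfile]
#' @param component integer component index (1 = PC1, 2 = PC2)
#' @return samples x levels numeric matrix with NA for missing cells
#' @export
setGeneric("profileMatrix",
           function(x, component = 2L) standardGeneric("profileMatrix"))

#' Enrichment score matrix
#' @param x a [SignatureScores]
#' @return numeric matrix, samples x signatures
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' Signature category tags
#' @param x a [SignatureScores]
#' @return named character vector of categories
#' @export
setGeneric("categoryTags", function(x) standardGeneric("categoryTags"))

#' NIR coordinates per sample
#' @param x a [NIRGradient]
#' @return named numeric vector
#' @export
setGeneric("nirCoordinates", function(x) standardGeneric("nirCoordinates"))

#' Planted latent state of a synthetic cohort
#' @param x a [SyntheticDataset]
#' @return named numeric vector in `[-1, 1]`, one value per line
#' @export
setGeneric("truthState", function(x) standardGeneric("truthState"))
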