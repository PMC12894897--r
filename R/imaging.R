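#' Load paired frames and masks from a manifest
#'
#' Reads a TSV manifest (columns `path`, `sample_id`, `timepoint_hours`,
#' `kind` = image|mask, optional `pixel_size_um`) and returns paired
#' records in time order per sample. Intensities are rescaled to `[0, 1]`
#' by bit depth (the tiff reader already maps integer TIFF to `[0, 1]`);
#' masks are any nonzero pixel.
#'
#' @param manifest path to the manifest TSV; relative `path` entries are
#'   resolved against the manifest's directory.
#' @return a [CultureSet].
#' @export
loadFrames <- function(manifest) {
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("path", "sample_id", "timepoint_hours", "kind")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(man$pixel_size_um)) man$pixel_size_um <- 1.34
  if (is.null(man$well)) man$well <- 1L
  root <- dirname(manifest)
  imgs <- man[man$kind == "image", ]
  msks <- man[man$kind == "mask", ]
  key <- function(d) paste(d$sample_id, d$well, d$timepoint_hours,
                           sep = "\r")
  ik <- key(imgs); mk <- key(msks)
  if (anyDuplicated(ik))
    stop("duplicate image time-point in manifest row for ",
         imgs$path[duplicated(ik)][1])
  if (!setequal(ik, mk))
    stop("unpaired image/mask rows in manifest (e.g. ",
         c(setdiff(ik, mk), setdiff(mk, ik))[1], ")")
  msks <- msks[match(ik, mk), ]
  ord <- order(imgs$sample_id, imgs$timepoint_hours, imgs$well)
  imgs <- imgs[ord, ]; msks <- msks[ord, ]
  read_one <- function(p) {
    fp <- if (file.exists(p)) p else file.path(root, p)
    if (!file.exists(fp)) stop("missing file referenced by manifest: ", p)
    x <- tiff::readTIFF(fp)
    if (length(dim(x)) == 3) x <- x[, , 1]
    x
  }
  images <- vector("list", nrow(imgs))
  masks <- vector("list", nrow(imgs))
  for (i in seq_len(nrow(imgs))) {
    im <- read_one(imgs$path[i])
    mk1 <- read_one(msks$path[i]) > 0
    if (!identical(dim(im), dim(mk1)))
      stop(sprintf("mask shape differs from image for %s t=%s (%s)",
                   imgs$sample_id[i], imgs$timepoint_hours[i],
                   imgs$path[i]))
    images[[i]] <- im
    masks[[i]] <- mk1
  }
  meta <- data.frame(sample_id = imgs$sample_id,
                     timepoint_hours = imgs$timepoint_hours,
                     pixel_size_um = imgs$pixel_size_um,
                     well = imgs$well,
                     stringsAsFactors = FALSE)
  new("CultureSet", images = images, masks = masks, meta = meta,
      truth = list())
}

#' Confluency: foreground area fraction of a mask
#'
#' @param mask logical matrix (foreground = TRUE).
#' @return fraction of foreground pixels, in `[0, 1]`.
#' @export
confluency <- function(mask) {
  if (!length(mask)) stop("empty mask")
  mean(mask)
}

#' Power log-log slope (PLLS) of an image
#'
#' Least-squares slope of log10 radially averaged power spectral density
#' against log10 spatial frequency, the focus/quality statistic used to
#' flag aberrant frames: blurred or artifact-laden images show an
#' abnormally steep (or otherwise shifted) spectral roll-off. The power
#' spectrum is averaged over annular frequency bins one frequency sample
#' wide; the zero-frequency (DC) bin is excluded and the fit is restricted
#' to frequencies at or below the Nyquist radius, where annuli are fully
#' sampled.
#'
#' @param image numeric matrix of intensities.
#' @param window `"none"` (default) or `"hann"` apodization before the
#'   transform.
#' @return slope (dimensionless).
#' @export
plls <- function(image, window = c("none", "hann")) {
  window <- match.arg(window)
  if (stats::sd(image) == 0)
    stop("constant image: power log-log slope is undefined")
  nr <- nrow(image); nc <- ncol(image)
  x <- image - mean(image)
  if (window == "hann") {
    wr <- 0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)))
    wc <- 0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
    x <- x * outer(wr, wc)
  }
  P <- Mod(stats::fft(x))^2
  fr <- ifelse(seq_len(nr) - 1 > nr / 2, seq_len(nr) - 1 - nr,
               seq_len(nr) - 1) / nr
  fc <- ifelse(seq_len(nc) - 1 > nc / 2, seq_len(nc) - 1 - nc,
               seq_len(nc) - 1) / nc
  R <- sqrt(outer(fr^2, fc^2, "+"))
  n <- max(nr, nc)
  bin <- as.integer(round(R * n))
  keep <- bin > 0L & R <= 0.5
  b <- bin[keep]
  pw <- as.vector(rowsum(P[keep], b)) / tabulate(factor(b))
  f <- sort(unique(b)) / n
  ok <- pw > 0
  if (sum(ok) < 2)
    stop("constant image: power log-log slope is undefined")
  unname(stats::coef(stats::lsfit(log10(f[ok]), log10(pw[ok])))[2])
}

#' Quality-control filter on the power log-log slope
#'
#' Computes [plls()] for every frame and removes frames whose slope falls
#' outside an acceptance band. With `band = NULL` the band is automatic
#' and per sample: median(slope) +/- 3 * MAD(slope) (MAD with the usual
#' 1.4826 consistency constant); a zero MAD keeps all of that sample's
#' frames. An explicit `band = c(low, high)` is applied globally instead.
#' Removal is a single pass against the band computed from the input
#' set; on data whose slopes are stable apart from genuine outliers
#' (the intended use) re-filtering the kept set removes nothing further.
#'
#' @param set a [CultureSet].
#' @param band optional numeric(2) explicit slope acceptance band.
#' @return list with `kept` (a [CultureSet]) and `report` (data.frame:
#'   `sample_id`, `timepoint_hours`, `plls_slope`, `passed`, `reason`).
#' @export
qcFilter <- function(set, band = NULL) {
  m <- set@meta
  slopes <- vapply(seq_len(nFrames(set)),
                   function(i) plls(set@images[[i]]), numeric(1))
  passed <- rep(TRUE, length(slopes))
  reason <- rep("within band", length(slopes))
  if (!is.null(band)) {
    passed <- slopes >= band[1] & slopes <= band[2]
    reason[!passed] <- sprintf("slope outside explicit band [%g, %g]",
                               band[1], band[2])
  } else {
    for (s in unique(m$sample_id)) {
      idx <- which(m$sample_id == s)
      if (length(idx) < 5)
        warning("fewer than 5 frames for sample ", s,
                "; automatic band may be unstable")
      med <- stats::median(slopes[idx])
      md <- stats::mad(slopes[idx])
      if (md == 0) next  # degenerate spread: keep all
      bad <- idx[abs(slopes[idx] - med) > 3 * md]
      passed[bad] <- FALSE
      reason[bad] <- sprintf(
        "slope outside sample band median %.3f +/- 3*MAD %.3f", med, md)
    }
  }
  report <- data.frame(sample_id = m$sample_id,
                       timepoint_hours = m$timepoint_hours,
                       well = if (!is.null(m$well)) m$well else 1L,
                       plls_slope = slopes, passed = passed,
                       reason = reason, stringsAsFactors = FALSE)
  if (!any(passed)) warning("QC removed every frame")
  kept <- new("CultureSet", images = set@images[passed],
              masks = set@masks[passed],
              meta = m[passed, , drop = FALSE], truth = set@truth)
  list(kept = kept, report = report)
}

#' Fallback foreground masker (Otsu threshold + morphological closing)
#'
#' For real images that arrive without foreground masks. Phase-contrast
#' cells deviate from the plate background in both directions (dark body,
#' bright halo), so the absolute deviation from the median background
#' level is Otsu-thresholded and closed with a small disk. Synthetic data
#' always carries exact generator masks; this masker replaces interactive
#' pixel-classifier training, which is out of scope.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param closing_radius radius (px) of the closing structuring element.
#' @return logical foreground mask.
#' @export
thresholdMask <- function(image, closing_radius = 3L) {
  dev <- abs(image - stats::median(image))
  rng <- range(dev)
  if (diff(rng) == 0) return(matrix(FALSE, nrow(image), ncol(image)))
  th <- EBImage::otsu(EBImage::Image((dev - rng[1]) / diff(rng)))
  fg <- (dev - rng[1]) / diff(rng) > th
  brush <- EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
  out <- EBImage::closing(EBImage::Image(fg * 1), brush)
  matrix(as.numeric(out) > 0.5, nrow(image), ncol(image))
}
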