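#' Gray-level co-occurrence matrix of a masked image
#'
#' Intensities inside the mask are quantized to `levels` equal-width bins
#' between the masked minimum and maximum. Pixel pairs at offset
#' `(0, +distance)` — the single "east" direction — with both endpoints
#' inside the mask are tallied; the matrix is symmetrized (each pair
#' counted in both orders) and normalized to sum 1. Pairs with either
#' endpoint outside the mask are excluded entirely, so plate background
#' never contaminates the texture statistics. A constant masked region
#' maps to a single occupied bin (all mass at the (1,1) cell).
#'
#' @param image numeric intensity matrix.
#' @param mask logical matrix, same shape; `NULL` means full frame.
#' @param levels number of gray levels (quantization bins), >= 2.
#' @param distance horizontal pair offset in pixels, >= 1.
#' @return list of class `"GLCMatrix"`: `matrix` (levels x levels,
#'   normalized, symmetric), `levels`, `offset`, `n_pairs`.
#' @export
computeGLCM <- function(image, mask = NULL, levels = 8L, distance = 3L) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(identical(dim(image), dim(mask)), levels >= 2, distance >= 1)
  q <- quantize_masked(image, mask, levels)
  nc <- ncol(q)
  if (nc <= distance) stop("no valid pixel pair at this distance")
  left <- q[, seq_len(nc - distance), drop = FALSE]
  right <- q[, (distance + 1):nc, drop = FALSE]
  ok <- !is.na(left) & !is.na(right)
  if (!any(ok)) stop("no valid pixel pair inside the mask")
  idx <- (right[ok] - 1L) * levels + left[ok]
  counts <- tabulate(idx, nbins = levels * levels)
  M <- matrix(counts, levels, levels)  # M[left, right]
  M <- M + t(M)
  structure(list(matrix = M / sum(M), levels = as.integer(levels),
                 offset = c(0L, as.integer(distance)),
                 n_pairs = sum(ok)),
            class = "GLCMatrix")
}

# Equal-width quantization inside the mask; NA outside. A constant masked
# region collapses to bin 1.
quantize_masked <- function(image, mask, levels) {
  vals <- image[mask]
  if (!length(vals)) stop("empty mask")
  mn <- min(vals); mx <- max(vals)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (mx == mn) {
    q[mask] <- 1L
  } else {
    q[mask] <- pmin(levels, floor((image[mask] - mn) / (mx - mn) *
                                    levels) + 1L)
  }
  q
}

#' The 13 Haralick texture features of a normalized GLCM
#'
#' Computed from the normalized co-occurrence matrix, its (equal, by
#' symmetry) marginals and the sum/difference distributions. Conventions:
#' logarithms base 2 with 0*log(0) = 0; correlation is 0 when a marginal
#' standard deviation is 0; the sum-variance is taken about the
#' sum-average; `imc1 = (HXY - HXY1) / max(HX, HY)` (0 when the marginals
#' carry no entropy) and `imc2 = sqrt(1 - exp(-2 (HXY2 - HXY)))` with the
#' radicand clamped at 0.
#'
#' @param glcm a `"GLCMatrix"` from [computeGLCM()], or a plain normalized
#'   square matrix.
#' @return named numeric(13): `asm`, `contrast`, `correlation`,
#'   `variance`, `idm`, `sum_avg`, `sum_var`, `sum_ent`, `entropy`,
#'   `diff_var`, `diff_ent`, `imc1`, `imc2`.
#' @export
haralickFeatures <- function(glcm) {
  P <- if (inherits(glcm, "GLCMatrix")) glcm$matrix else as.matrix(glcm)
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must be normalized to sum 1")
  L <- nrow(P)
  i <- seq_len(L)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(i * px); mu_y <- sum(i * py)
  sd_x <- sqrt(sum((i - mu_x)^2 * px))
  sd_y <- sqrt(sum((i - mu_y)^2 * py))
  II <- matrix(i, L, L); JJ <- t(II)
  log2z <- function(x) ifelse(x > 0, log2(x), 0)

  asm <- sum(P^2)
  # sum (k = i + j, 2..2L) and difference (k = |i - j|, 0..L-1) marginals
  psum <- vapply(2:(2 * L), function(k) sum(P[II + JJ == k]), numeric(1))
  pdiff <- vapply(0:(L - 1), function(k) sum(P[abs(II - JJ) == k]),
                  numeric(1))
  kd <- 0:(L - 1); ks <- 2:(2 * L)
  contrast <- sum(kd^2 * pdiff)
  correlation <- if (sd_x == 0 || sd_y == 0) 0 else
    (sum(II * JJ * P) - mu_x * mu_y) / (sd_x * sd_y)
  variance <- sum((i - mu_x)^2 * px)
  idm <- sum(P / (1 + (II - JJ)^2))
  sum_avg <- sum(ks * psum)
  sum_var <- sum((ks - sum_avg)^2 * psum)
  sum_ent <- -sum(psum * log2z(psum))
  entropy <- -sum(P * log2z(P))
  mu_d <- sum(kd * pdiff)
  diff_var <- sum((kd - mu_d)^2 * pdiff)
  diff_ent <- -sum(pdiff * log2z(pdiff))
  hx <- -sum(px * log2z(px)); hy <- -sum(py * log2z(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * log2z(pxpy))
  hxy2 <- -sum(pxpy * log2z(pxpy))
  imc1 <- if (max(hx, hy) == 0) 0 else (entropy - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_avg = sum_avg, sum_var = sum_var,
    sum_ent = sum_ent, entropy = entropy, diff_var = diff_var,
    diff_ent = diff_ent, imc1 = imc1, imc2 = imc2)
}

#' Morphological granularity spectrum of a masked image
#'
#' Opening-based granulometry: the masked image is background-levelled
#' (subtraction of a large-radius opening, floored at 0), then subjected
#' to successive morphological openings with discrete disk structuring
#' elements of radius r = 1..`n_steps`. Step r of the spectrum is the
#' percentage of total starting intensity removed by the opening at
#' radius r: `100 * (S[r-1] - S[r]) / S[0]`, where `S[r]` is the total
#' masked intensity after the radius-r opening. Structures of size ~r
#' vanish when the element no longer fits inside them, so step r reflects
#' structure at that size. The spectrum is invariant to uniform intensity
#' scaling.
#'
#' @param image numeric intensity matrix.
#' @param mask logical matrix (`NULL` = full frame); pixels outside the
#'   mask are zeroed before the morphology.
#' @param n_steps number of opening radii (the 16-step default matches the
#'   usual granularity feature set).
#' @param leveling_radius radius of the background-levelling opening, px.
#' @return numeric(`n_steps`), percent units, each >= 0 and summing to
#'   <= 100.
#' @export
granularitySpectrum <- function(image, mask = NULL, n_steps = 16L,
                                leveling_radius = 40L) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  x <- image
  x[!mask] <- 0
  if (sum(x) <= 0) stop("zero total masked intensity")
  bg <- ebi_opening(x, leveling_radius)
  x <- pmax(x - bg, 0)
  x[!mask] <- 0
  s0 <- sum(x)
  if (s0 <= 0) stop("zero total masked intensity after levelling")
  s_prev <- s0
  out <- numeric(n_steps)
  for (r in seq_len(n_steps)) {
    op <- ebi_opening(x, r)
    op[!mask] <- 0
    s_r <- sum(op)
    out[r] <- 100 * (s_prev - s_r) / s0
    s_prev <- s_r
  }
  names(out) <- granularity_feature_names(n_steps)
  out
}

# Grayscale opening with an exact discrete disk (dx^2 + dy^2 <= r^2),
# delegated to EBImage's chord-based morphology. EBImage clamps grayscale
# to [0, 1], so the input is rescaled by its maximum first (opening is
# equivariant under positive scaling).
ebi_opening <- function(x, r) {
  d <- 2L * as.integer(r) + 1L
  off <- seq_len(d) - (r + 1)
  brush <- outer(off^2, off^2, "+") <= r^2
  mx <- max(x)
  if (mx <= 0) return(x)
  as.matrix(EBImage::opening(EBImage::Image(x / mx), brush * 1)) * mx
}

#' Extract the 29-feature table from a culture set
#'
#' One row per frame: the 13 Haralick features of the east-offset GLCM,
#' the 16-step granularity spectrum, plus the auxiliaries `confluency`
#' (mask area fraction) and `plls` (power-spectrum slope; reused from a
#' QC report when supplied). Degenerate frames (no valid pixel pair, zero
#' masked intensity) are recorded as skipped with a reason, never silently
#' dropped. Output row order is canonical (sample, then time-point), so
#' the result is invariant to input order.
#'
#' @param set a [CultureSet] (QC-passed).
#' @param levels GLCM quantization levels.
#' @param distance GLCM horizontal offset, px.
#' @param n_steps granularity spectrum length.
#' @param leveling_radius background-levelling opening radius, px.
#' @param qc_report optional data.frame from [qcFilter()] whose
#'   `plls_slope` values are reused instead of recomputing.
#' @return a [FeatureTable]; skipped frames (if any) are recorded in its
#'   `normalization$skipped` data.frame.
#' @export
extractFeatures <- function(set, levels = 8L, distance = 3L,
                            n_steps = 16L, leveling_radius = 40L,
                            qc_report = NULL) {
  m <- set@meta
  well <- if (!is.null(m$well)) m$well else rep(1L, nrow(m))
  ord <- order(m$sample_id, m$timepoint_hours, well)
  rows <- vector("list", length(ord))
  skipped <- list()
  qc_key <- if (!is.null(qc_report)) {
    qw <- if (!is.null(qc_report$well)) qc_report$well else
      rep(1L, nrow(qc_report))
    paste(qc_report$sample_id, qc_report$timepoint_hours, qw)
  } else character(0)
  for (k in seq_along(ord)) {
    i <- ord[k]
    img <- set@images[[i]]; msk <- set@masks[[i]]
    key <- paste(m$sample_id[i], m$timepoint_hours[i], well[i])
    slope <- if (key %in% qc_key)
      qc_report$plls_slope[match(key, qc_key)] else plls(img)
    feat <- tryCatch({
      h <- haralickFeatures(computeGLCM(img, msk, levels, distance))
      g <- granularitySpectrum(img, msk, n_steps, leveling_radius)
      c(h, g)
    }, error = function(e) e)
    if (inherits(feat, "error")) {
      skipped[[length(skipped) + 1]] <-
        data.frame(sample_id = m$sample_id[i],
                   timepoint_hours = m$timepoint_hours[i],
                   reason = conditionMessage(feat))
      next
    }
    rows[[k]] <- data.frame(sample_id = m$sample_id[i],
                            timepoint_hours = m$timepoint_hours[i],
                            well = well[i],
                            t(feat), confluency = confluency(msk),
                            plls = slope, stringsAsFactors = FALSE)
  }
  dat <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(dat) || !nrow(dat)) stop("no extractable frames")
  rownames(dat) <- NULL
  norm <- list()
  if (length(skipped)) norm$skipped <- do.call(rbind, skipped)
  new("FeatureTable", data = dat,
      featureNames = c(glcm_feature_names(),
                       granularity_feature_names(n_steps)),
      normalization = norm)
}
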