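#' Configuration for one synthetic culture line
#'
#' Builds the parameter set for [simulateLine()]. The latent state
#' `state_s` in `[-1, 1]` encodes the neurodevelopmental (+1) to
#' injury-response (-1) pole of a line and is mapped to multicellular
#' patterning parameters by a fixed, documented convention:
#' \itemize{
#'   \item `orientation_kappa = 4 * max(state_s, 0)` — neurodevelopmental
#'     lines grow anisotropically (cells aligned along a common axis),
#'     injury-response lines isotropically;
#'   \item `overlap_prob = 0.1 + 0.4 * max(-state_s, 0)` — injury-response
#'     lines tolerate more cell-cell overlap;
#'   \item `cluster_radius_px` interpolated 8 to 24 px as `state_s` goes
#'     +1 to -1 — injury-response lines form looser, larger clumps.
#' }
#' Any of the three can be overridden explicitly.
#'
#' @param line_id character sample identifier.
#' @param state_s latent state in `[-1, 1]`.
#' @param seed integer RNG seed; identical (config, seed) gives
#'   bit-identical output.
#' @param n_timepoints number of frames (every `interval_hours` h).
#' @param frame_shape integer(2) frame dimensions (rows, cols), >= 64.
#' @param initial_cells cells present at seeding.
#' @param growth_rate logistic growth rate per hour.
#' @param carrying_capacity cell count plateau.
#' @param orientation_kappa,overlap_prob,cluster_radius_px optional
#'   explicit overrides of the state mapping.
#' @param noise_sd additive Gaussian pixel noise sd (on the `[0, 1]`
#'   intensity scale).
#' @param interval_hours imaging interval in hours.
#' @param cell_axes numeric(2): ellipse semi-major/semi-minor axes in px.
#' @param cell_scale multiplicative factor on `cell_axes` (per-line gross
#'   cell-size nuisance; see [simulateCohort()]).
#' @param halo_scale bright halo outer radius as a multiple of the body.
#' @param pixel_size_um physical pixel size recorded in metadata.
#' @return a validated list of class `"SyntheticLineConfig"`.
#' @export
lineConfig <- function(line_id, state_s, seed,
                       n_timepoints = 30L,
                       frame_shape = c(256L, 256L),
                       initial_cells = 40L,
                       growth_rate = 0.04,
                       carrying_capacity = 900L,
                       orientation_kappa = NULL,
                       overlap_prob = NULL,
                       cluster_radius_px = NULL,
                       noise_sd = 0.03,
                       interval_hours = 8,
                       cell_axes = c(6, 2.5),
                       cell_scale = 1,
                       halo_scale = 1.3,
                       pixel_size_um = 1.34) {
  if (abs(state_s) > 1) stop("state_s must lie in [-1, 1]")
  if (any(frame_shape < 64)) stop("frame dimensions must be >= 64")
  if (initial_cells < 1 || carrying_capacity < initial_cells)
    stop("need 1 <= initial_cells <= carrying_capacity")
  if (n_timepoints < 1 || interval_hours <= 0 || growth_rate <= 0)
    stop("nonpositive time/growth configuration")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  cfg <- list(
    line_id = as.character(line_id),
    state_s = state_s,
    seed = as.integer(seed),
    n_timepoints = as.integer(n_timepoints),
    frame_shape = as.integer(frame_shape),
    initial_cells = as.integer(initial_cells),
    growth_rate = growth_rate,
    carrying_capacity = as.integer(carrying_capacity),
    orientation_kappa = if (is.null(orientation_kappa))
      4 * max(state_s, 0) else orientation_kappa,
    overlap_prob = if (is.null(overlap_prob))
      0.1 + 0.4 * max(-state_s, 0) else overlap_prob,
    cluster_radius_px = if (is.null(cluster_radius_px))
      8 + (24 - 8) * (1 - state_s) / 2 else cluster_radius_px,
    noise_sd = noise_sd,
    interval_hours = interval_hours,
    cell_axes = cell_axes * cell_scale,
    halo_scale = halo_scale,
    pixel_size_um = pixel_size_um)
  if (cfg$orientation_kappa < 0) stop("orientation_kappa must be >= 0")
  if (cfg$overlap_prob < 0 || cfg$overlap_prob > 1)
    stop("overlap_prob must lie in [0, 1]")
  if (cfg$cluster_radius_px <= 0) stop("cluster_radius_px must be > 0")
  class(cfg) <- "SyntheticLineConfig"
  cfg
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 is
# the uniform circular distribution.
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  (out + mu + pi) %% (2 * pi) - pi
}

#' Circular variance of axial orientations
#'
#' For axial data (orientations defined modulo pi, as for cell long axes)
#' the statistic is `1 - |mean(exp(2 i theta))|`: 0 for perfectly aligned
#' cells, 1 for orientations spread uniformly.
#'
#' @param theta orientations in radians.
#' @return numeric in `[0, 1]`.
#' @export
circularVariance <- function(theta) {
  1 - sqrt(mean(cos(2 * theta))^2 + mean(sin(2 * theta))^2)
}

# Render one ellipse (body + halo) into canvas/occupancy.
render_cell <- function(canvas, occupancy, cy, cx, a, b, theta, halo_scale,
                        body_int = 0.35, halo_int = 0.85) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  rmax <- ceiling(halo_scale * a) + 1L
  i0 <- max(1L, floor(cy - rmax)); i1 <- min(nr, ceiling(cy + rmax))
  j0 <- max(1L, floor(cx - rmax)); j1 <- min(nc, ceiling(cx + rmax))
  if (i0 > i1 || j0 > j1)
    return(list(canvas = canvas, occupancy = occupancy, body = integer(0)))
  ii <- i0:i1; jj <- j0:j1
  dy <- ii - cy; dx <- jj - cx
  # orientation theta = 0 points east (along columns/x)
  DX <- matrix(dx, nrow = length(dy), ncol = length(dx), byrow = TRUE)
  DY <- matrix(dy, nrow = length(dy), ncol = length(dx))
  u <- DX * cos(theta) + DY * sin(theta)
  v <- -DX * sin(theta) + DY * cos(theta)
  r2 <- (u / a)^2 + (v / b)^2
  body <- r2 <= 1
  halo <- r2 > 1 & r2 <= halo_scale^2
  sub <- canvas[ii, jj, drop = FALSE]
  occ <- occupancy[ii, jj, drop = FALSE]
  sub[halo] <- halo_int
  sub[body] <- body_int
  canvas[ii, jj] <- sub
  occ[body | halo] <- TRUE
  occupancy[ii, jj] <- occ
  list(canvas = canvas, occupancy = occupancy)
}

#' Simulate one culture line as a phase-contrast time-lapse
#'
#' Cells follow a seeded logistic growth trajectory; each new cell is
#' placed near a randomly chosen existing cell with Gaussian dispersion
#' `cluster_radius_px`, with its long axis drawn from a von Mises
#' distribution of concentration `orientation_kappa` (axial, mean
#' direction east). Candidate positions whose body substantially overlaps
#' already-occupied area are accepted with probability `overlap_prob`,
#' otherwise re-drawn (up to 15 attempts). Cells are rendered with a dark
#' body (0.35), bright halo ring (0.85) on a 0.55 background — the
#' contrast inversion typical of phase-contrast optics — and additive
#' Gaussian noise. Cells persist across time-points, so the foreground
#' footprint is non-decreasing until the logistic plateau.
#'
#' @param config a `"SyntheticLineConfig"` from [lineConfig()].
#' @return a [CultureSet] for the line, with generator ground truth
#'   (planted state, per-cell orientations, per-frame footprint pixel
#'   counts and cell counts) in its `truth` slot.
#' @export
simulateLine <- function(config) {
  stopifnot(inherits(config, "SyntheticLineConfig"))
  with_seed(config$seed, simulate_line_impl(config))
}

simulate_line_impl <- function(cfg) {
  nr <- cfg$frame_shape[1]; nc <- cfg$frame_shape[2]
  canvas <- matrix(0.55, nr, nc)
  occupancy <- matrix(FALSE, nr, nc)
  hours <- (seq_len(cfg$n_timepoints) - 1) * cfg$interval_hours
  n0 <- cfg$initial_cells; K <- cfg$carrying_capacity
  target <- round(K * n0 / (n0 + (K - n0) * exp(-cfg$growth_rate * hours)))
  centers <- matrix(NA_real_, 0, 2)
  orientations <- numeric(0)
  images <- vector("list", cfg$n_timepoints)
  masks <- vector("list", cfg$n_timepoints)
  footprint <- integer(cfg$n_timepoints)
  for (t in seq_len(cfg$n_timepoints)) {
    while (nrow(centers) < target[t]) {
      theta <- rvonmises(1, 0, cfg$orientation_kappa) / 2
      a <- cfg$cell_axes[1] * stats::runif(1, 0.85, 1.15)
      b <- cfg$cell_axes[2] * stats::runif(1, 0.85, 1.15)
      placed <- FALSE
      for (try in 1:15) {
        if (nrow(centers) == 0) {
          cy <- stats::runif(1, 1, nr); cx <- stats::runif(1, 1, nc)
        } else {
          anchor <- centers[sample.int(nrow(centers), 1), ]
          cy <- anchor[1] + stats::rnorm(1, 0, cfg$cluster_radius_px)
          cx <- anchor[2] + stats::rnorm(1, 0, cfg$cluster_radius_px)
          cy <- min(max(cy, 1), nr); cx <- min(max(cx, 1), nc)
        }
        # crude overlap probe: fraction of the body-sized disk already taken
        pr <- max(1L, round(cy)); pc <- max(1L, round(cx))
        w <- ceiling(b)
        i0 <- max(1L, pr - w); i1 <- min(nr, pr + w)
        j0 <- max(1L, pc - w); j1 <- min(nc, pc + w)
        frac <- mean(occupancy[i0:i1, j0:j1])
        if (frac < 0.25 || stats::runif(1) < cfg$overlap_prob) {
          placed <- TRUE
          break
        }
      }
      # when no candidate passed the probe, the last draw is accepted
      res <- render_cell(canvas, occupancy, cy, cx, a, b, theta,
                         cfg$halo_scale)
      canvas <- res$canvas; occupancy <- res$occupancy
      centers <- rbind(centers, c(cy, cx))
      orientations <- c(orientations, theta)
    }
    img <- canvas
    if (cfg$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
    images[[t]] <- pmin(pmax(img, 0), 1)
    masks[[t]] <- occupancy
    footprint[t] <- sum(occupancy)
  }
  meta <- data.frame(sample_id = cfg$line_id, timepoint_hours = hours,
                     pixel_size_um = cfg$pixel_size_um,
                     stringsAsFactors = FALSE)
  truth <- list()
  truth[[cfg$line_id]] <- list(state = cfg$state_s,
                               orientations = orientations,
                               n_cells = target,
                               footprint_px = footprint)
  new("CultureSet", images = images, masks = masks, meta = meta,
      truth = truth)
}

#' Combine several CultureSets
#'
#' @param ... [CultureSet] objects.
#' @return one [CultureSet], frames ordered by (sample_id, timepoint).
#' @export
combineCultureSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is(sets[[1]], "CultureSet"))
    sets <- sets[[1]]
  meta <- do.call(rbind, lapply(sets, function(s) s@meta))
  images <- do.call(c, lapply(sets, function(s) s@images))
  masks <- do.call(c, lapply(sets, function(s) s@masks))
  truth <- do.call(c, lapply(sets, function(s) s@truth))
  ord <- order(meta$sample_id, meta$timepoint_hours)
  new("CultureSet", images = images[ord], masks = masks[ord],
      meta = meta[ord, , drop = FALSE], truth = truth)
}

#' Default gene-signature collection for synthetic cohorts
#'
#' Twelve disjoint 50-gene signatures over a universe of `n_genes` genes:
#' five neurodevelopmental, five mesenchymal/injury-response and two
#' neutral, standing in for the catalogue of brain cell type and GBM
#' signatures used on real data.
#'
#' @param n_genes gene universe size (>= total signature genes).
#' @param genes_per_sig genes per signature.
#' @param n_per_category integer(3): counts of (neurodevelopmental,
#'   mesenchymal-injury, neutral) signatures.
#' @return list of [SignatureSet].
#' @export
defaultSignatures <- function(n_genes = 2000L, genes_per_sig = 50L,
                              n_per_category = c(5L, 5L, 2L)) {
  total <- sum(n_per_category) * genes_per_sig
  if (n_genes < total)
    stop("n_genes smaller than the union of signature genes")
  ids <- sprintf("g%04d", seq_len(n_genes))
  cats <- rep(c("neurodevelopmental", "mesenchymal-injury", "neutral"),
              n_per_category)
  prefix <- rep(c("ND", "MI", "NEU"), n_per_category)
  idx <- unlist(lapply(c("ND", "MI", "NEU"), function(p) seq_len(sum(prefix == p))))
  out <- vector("list", length(cats))
  for (k in seq_along(cats)) {
    genes <- ids[((k - 1) * genes_per_sig + 1):(k * genes_per_sig)]
    out[[k]] <- new("SignatureSet",
                    name = sprintf("%s_%02d", prefix[k], idx[k]),
                    genes = genes, category = cats[k], excluded = FALSE)
  }
  out
}

#' Simulate matched expression profiles with planted signature activity
#'
#' For genes belonging to a tagged signature, expression is
#' `baseline + direction * effect_size * state_s + noise`, with direction
#' +1 for neurodevelopmental, -1 for mesenchymal/injury-response and 0 for
#' neutral signatures; other genes are baseline + noise. Baselines are
#' N(5, 1) on a log-like scale. The planted per-(line, signature) mean
#' shift is returned as `truth_activity`.
#'
#' @param truth_state named numeric, latent state per line.
#' @param n_genes gene universe size.
#' @param signatures list of [SignatureSet]; all their genes must fit in
#'   the universe.
#' @param effect_size mean expression shift at `|state_s| = 1`.
#' @param noise_sd per-gene Gaussian noise sd.
#' @param seed integer RNG seed.
#' @return list with `expression` (genes x lines matrix) and
#'   `truth_activity` (lines x signatures matrix).
#' @export
simulateExpression <- function(truth_state, n_genes = 2000L,
                               signatures = defaultSignatures(n_genes),
                               effect_size = 2, noise_sd = 0.5,
                               seed = 1L) {
  ids <- sprintf("g%04d", seq_len(n_genes))
  sig_genes <- unlist(lapply(signatures, function(s) s@genes))
  if (!all(sig_genes %in% ids))
    stop("n_genes smaller than the union of signature genes")
  lines <- names(truth_state)
  if (is.null(lines)) stop("truth_state must be a named vector")
  dir_of <- c(neurodevelopmental = 1, `mesenchymal-injury` = -1, neutral = 0)
  with_seed(seed, {
    baseline <- stats::rnorm(n_genes, 5, 1)
    expr <- matrix(baseline, n_genes, length(lines),
                   dimnames = list(ids, lines))
    dir_gene <- numeric(n_genes); names(dir_gene) <- ids
    for (s in signatures)
      dir_gene[s@genes] <- dir_of[[s@category]]
    for (j in seq_along(lines))
      expr[, j] <- expr[, j] + dir_gene * effect_size * truth_state[j]
    expr <- expr + matrix(stats::rnorm(length(expr), 0, noise_sd),
                          nrow(expr), ncol(expr))
    act <- sapply(signatures, function(s)
      dir_of[[s@category]] * effect_size * truth_state)
    act <- matrix(act, nrow = length(lines),
                  dimnames = list(lines,
                                  vapply(signatures, function(s) s@name,
                                         character(1))))
    list(expression = expr, truth_activity = act)
  })
}

#' Simulate a full synthetic cohort (images, masks, expression, truth)
#'
#' Generates `n_lines` culture lines with latent states evenly spaced on
#' `[-1, 1]` (by default), renders their time-lapse frames and simulates a
#' matched expression matrix in which neurodevelopmental signatures rise
#' and mesenchymal/injury-response signatures fall with the state.
#'
#' The latent state drives four morphological channels: orientation
#' anisotropy, cell-cell overlap and cluster granularity (see
#' [lineConfig()]), plus the single-cell shape channel described under
#' `elongation_span` and `halo_span`. By default each line is imaged in
#' `n_wells = 5` replicate wells at `n_timepoints = 6` daily frames --
#' 30 frames per line -- spanning seeding to near-confluence.
#'
#' @param n_lines number of lines.
#' @param seed master seed; per-line and expression seeds are derived from
#'   it deterministically.
#' @param states latent states, length `n_lines`.
#' @param cell_area ellipse area (product of the semi-axes, px^2) held
#'   constant across lines so that the state does not leak into the
#'   confluency trajectory.
#' @param elongation_span cell aspect ratios at `state_s = -1` and `+1`;
#'   the per-line ratio interpolates geometrically between them. High
#'   state (neurodevelopmental-like) lines grow elongated, process-
#'   bearing cells, low state (injury-like) lines rounder ones.
#' @param halo_span phase-contrast halo thickness factor at
#'   `state_s = -1` and `+1` (linear interpolation); injury-like rounded
#'   cells carry the thicker bright halo.
#' @param cell_scale_range per-line gross cell-size factors are drawn
#'   uniformly from this interval (seeded); real patient-derived lines
#'   differ in cell size independently of their transcriptional state.
#'   Default `c(1, 1)` (off).
#' @param noise_sd_range per-line pixel-noise levels drawn uniformly from
#'   this interval (seeded). Default `c(0.03, 0.03)` (uniform across
#'   lines); widening it adds a noise-quality nuisance axis, at the cost
#'   of heavy interaction with the texture features.
#' @param seeding_jitter,growth_jitter per-well multiplicative jitter
#'   intervals on initial cell count and growth rate (seeded), modelling
#'   plating variability. Default `c(1, 1)` (off): replicate wells then
#'   differ only through their independent seeded fields, which keeps
#'   every line's wells on a common confluency schedule.
#' @param n_timepoints,interval_hours,frame_shape passed to
#'   [lineConfig()].
#' @param n_wells independent replicate wells simulated per line (each
#'   its own seeded field, imaged on the same schedule); the real
#'   acquisitions this emulates image several wells per line, and
#'   replicate fields are what separates line biology from single-field
#'   layout accidents.
#' @param effect_size,noise_sd expression effect and noise
#'   (see [simulateExpression()]).
#' @param n_genes expression universe size.
#' @param signatures signature collection (default [defaultSignatures()]).
#' @param ... further arguments forwarded to [lineConfig()].
#' @return a [SyntheticDataset].
#' @export
simulateCohort <- function(n_lines = 15L, seed = 1L,
                           states = seq(-1, 1, length.out = n_lines),
                           n_timepoints = 6L,
                           n_wells = 5L,
                           interval_hours = 24,
                           frame_shape = c(256L, 256L),
                           effect_size = 2, noise_sd = 0.5,
                           n_genes = 2000L,
                           signatures = defaultSignatures(n_genes),
                           cell_area = 15,
                           elongation_span = c(1.3, 3.2),
                           halo_span = c(1.6, 1.3),
                           cell_scale_range = c(1, 1),
                           noise_sd_range = c(0.03, 0.03),
                           seeding_jitter = c(1, 1),
                           growth_jitter = c(1, 1), ...) {
  stopifnot(length(states) == n_lines)
  line_ids <- sprintf("L%02d", seq_len(n_lines))
  cell_scale <- with_seed(seed * 1000L + 500L,
                          stats::runif(n_lines, cell_scale_range[1],
                                       cell_scale_range[2]))
  line_noise <- with_seed(seed * 1000L + 501L,
                          stats::runif(n_lines, noise_sd_range[1],
                                       noise_sd_range[2]))
  # state -> single-cell morphology: lines high on the state axis grow
  # elongated, thin-haloed (process-bearing, neurodevelopmental-like)
  # cells; lines low on it grow rounder cells with thick phase halos
  # (injury-like). The aspect ratio moves geometrically between the span
  # endpoints at constant ellipse area, so the cell footprint (and with
  # it the confluency trajectory) is the same for every line.
  u <- (states + 1) / 2
  aspect <- elongation_span[1] * (elongation_span[2] / elongation_span[1])^u
  line_axes <- cbind(sqrt(cell_area * aspect), sqrt(cell_area / aspect))
  line_halo <- halo_span[1] + (halo_span[2] - halo_span[1]) * u
  # per-well plating variability: seeding density and growth rate jitter
  # (wells of the same line start and grow slightly differently, which is
  # what spreads cell area within a confluency level in real cohorts)
  well_seeding <- with_seed(seed * 1000L + 503L,
                            matrix(stats::runif(n_lines * n_wells,
                                                seeding_jitter[1],
                                                seeding_jitter[2]),
                                   n_lines, n_wells))
  well_growth <- with_seed(seed * 1000L + 504L,
                           matrix(stats::runif(n_lines * n_wells,
                                               growth_jitter[1],
                                               growth_jitter[2]),
                                  n_lines, n_wells))
  dots <- list(...)
  base_initial <- if (is.null(dots$initial_cells)) 40L
                  else dots$initial_cells
  base_growth <- if (is.null(dots$growth_rate)) 0.04
                 else dots$growth_rate
  dots$initial_cells <- NULL; dots$growth_rate <- NULL
  sets <- vector("list", n_lines * n_wells)
  for (i in seq_len(n_lines)) {
    for (w in seq_len(n_wells)) {
      cfg <- do.call(lineConfig, c(list(
        line_ids[i], states[i],
        seed = seed * 1000L + (w - 1L) * 100L + i,
        n_timepoints = n_timepoints,
        interval_hours = interval_hours,
        frame_shape = frame_shape,
        cell_axes = line_axes[i, ],
        cell_scale = cell_scale[i],
        noise_sd = line_noise[i],
        halo_scale = line_halo[i],
        initial_cells = max(1L, round(base_initial * well_seeding[i, w])),
        growth_rate = base_growth * well_growth[i, w]), dots))
      s <- simulateLine(cfg)
      s@meta$well <- w
      nm <- paste0(cfg$line_id, "_w", w)
      names(s@truth) <- nm
      sets[[(i - 1L) * n_wells + w]] <- s
    }
  }
  frames <- combineCultureSets(sets)
  truth_state <- stats::setNames(states, line_ids)
  ex <- simulateExpression(truth_state, n_genes = n_genes,
                           signatures = signatures,
                           effect_size = effect_size, noise_sd = noise_sd,
                           seed = seed * 1000L + 999L)
  new("SyntheticDataset", frames = frames, expression = ex$expression,
      signatures = signatures, truthState = truth_state,
      truthActivity = ex$truth_activity)
}

#' Write a synthetic cohort to disk
#'
#' Images and masks are written as single-frame grayscale TIFF (16-bit for
#' images, 8-bit 0/1 for masks) with a sidecar TSV manifest (columns
#' `path`, `sample_id`, `timepoint_hours`, `pixel_size_um`, `kind`);
#' expression as a genes x lines TSV; signatures as GMT with a sidecar
#' category-tag TSV; the planted state as a TSV.
#'
#' @param dataset a [SyntheticDataset].
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(dataset, dir) {
  dir.create(file.path(dir, "frames"), recursive = TRUE,
             showWarnings = FALSE)
  fr <- dataset@frames
  m <- fr@meta
  rows <- vector("list", 2L * nrow(m))
  for (i in seq_len(nrow(m))) {
    base <- sprintf("%s%s_t%04d", m$sample_id[i],
                    if (!is.null(m$well)) sprintf("_w%d", m$well[i]) else "",
                    round(m$timepoint_hours[i]))
    ipath <- file.path("frames", paste0(base, "_img.tif"))
    mpath <- file.path("frames", paste0(base, "_mask.tif"))
    tiff::writeTIFF(fr@images[[i]], file.path(dir, ipath),
                    bits.per.sample = 16)
    tiff::writeTIFF(fr@masks[[i]] * 1, file.path(dir, mpath),
                    bits.per.sample = 8)
    w <- if (!is.null(m$well)) m$well[i] else 1L
    rows[[2 * i - 1]] <- data.frame(path = ipath,
                                    sample_id = m$sample_id[i],
                                    timepoint_hours = m$timepoint_hours[i],
                                    pixel_size_um = m$pixel_size_um[i],
                                    well = w, kind = "image")
    rows[[2 * i]] <- data.frame(path = mpath, sample_id = m$sample_id[i],
                                timepoint_hours = m$timepoint_hours[i],
                                pixel_size_um = m$pixel_size_um[i],
                                well = w, kind = "mask")
  }
  manifest <- do.call(rbind, rows)
  write_tsv_stable(manifest, file.path(dir, "manifest.tsv"))
  expr <- data.frame(gene = rownames(dataset@expression),
                     dataset@expression, check.names = FALSE)
  write_tsv_stable(expr, file.path(dir, "expression.tsv"))
  writeGMT(dataset@signatures, file.path(dir, "signatures.gmt"))
  tags <- data.frame(
    signature = vapply(dataset@signatures, function(s) s@name,
                       character(1)),
    category = vapply(dataset@signatures, function(s) s@category,
                      character(1)),
    excluded = vapply(dataset@signatures, function(s) s@excluded,
                      logical(1)))
  write_tsv_stable(tags, file.path(dir, "signature_tags.tsv"))
  write_tsv_stable(data.frame(sample_id = names(dataset@truthState),
                              state_s = unname(dataset@truthState)),
                   file.path(dir, "truth_state.tsv"))
  invisible(file.path(dir, "manifest.tsv"))
}
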