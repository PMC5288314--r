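#' Preprocessing configuration
#'
#' Parameters of the spectral preprocessing chain. Defaults follow standard
#' practice for phosphate-buffered tissue extracts at 600 MHz: the water
#' region 4.49-5.89 ppm and the TSP region below 0.14 ppm are excluded, and
#' the generalized-log transform uses y0 = 1e-7, lambda = 5e-4.
#'
#' @param tsp_search_window ppm interval searched for the TSP apex.
#' @param exclusion_regions List of ppm intervals `c(lo, hi)` removed before
#'   modelling.
#' @param alignment_segments List of ppm intervals aligned segmentally
#'   (defaults: citrate, taurine/choline and lactate regions, where pH-driven
#'   shifts are largest).
#' @param max_segment_shift Maximum per-segment shift, grid points.
#' @param knot_spacing Baseline anchor window width, ppm.
#' @param glog_y0,glog_lambda Generalized-log parameters.
#' @return An object of class `PreprocessConfig`.
#' @export
preprocess_config <- function(tsp_search_window = c(-0.25, 0.25),
                              exclusion_regions = list(c(4.49, 5.89),
                                                       c(-Inf, 0.14)),
                              alignment_segments = list(c(2.35, 2.75),
                                                        c(3.15, 3.50),
                                                        c(1.25, 1.45)),
                              max_segment_shift = 10,
                              knot_spacing = 0.25,
                              glog_y0 = 1e-7, glog_lambda = 5e-4) {
  if (glog_lambda <= 0) stop("glog_lambda must be > 0", call. = FALSE)
  check_disjoint <- function(regs, what) {
    if (length(regs) < 2) return(invisible())
    m <- do.call(rbind, regs)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-nrow(m), 2] > m[-1, 1])) {
      stop(what, " intervals overlap", call. = FALSE)
    }
  }
  check_disjoint(exclusion_regions, "exclusion")
  check_disjoint(alignment_segments, "alignment")
  structure(
    list(tsp_search_window = tsp_search_window,
         exclusion_regions = exclusion_regions,
         alignment_segments = alignment_segments,
         max_segment_shift = as.integer(max_segment_shift),
         knot_spacing = knot_spacing,
         glog_y0 = glog_y0, glog_lambda = glog_lambda),
    class = "PreprocessConfig"
  )
}

# shift one spectrum by k grid points, filling vacated positions by
# edge-value repetition (avoids spurious area steps before normalization)
shift_vector <- function(y, k) {
  n <- length(y)
  if (k == 0 || abs(k) >= n) return(y)
  if (k > 0) c(rep(y[1], k), y[seq_len(n - k)])
  else c(y[(-k + 1):n], rep(y[n], -k))
}

#' Align spectra on the reference (TSP) signal
#'
#' Shifts each spectrum by an integer number of grid points so that the
#' intensity maximum inside the TSP search window lands on the grid point
#' nearest 0.00 ppm.
#'
#' @param set A `SpectrumSet` on a uniform grid.
#' @param config A `PreprocessConfig`.
#' @return The aligned `SpectrumSet`; applied shifts are recorded in the log.
#' @export
reference_align <- function(set, config = preprocess_config()) {
  ppm <- set$ppm
  validate_ppm(ppm, uniform = TRUE)
  win <- which(ppm >= config$tsp_search_window[1] &
                 ppm <= config$tsp_search_window[2])
  if (length(win) == 0) stop("TSP search window outside grid", call. = FALSE)
  target <- ppm_index(ppm, 0)
  shifts <- integer(nrow(set$intensities))
  for (i in seq_len(nrow(set$intensities))) {
    seg <- set$intensities[i, win]
    if (max(seg) - min(seg) < .Machine$double.eps * max(1, abs(max(seg)))) {
      warning("no detectable TSP maximum for sample ",
              set$metadata$sample_id[i], "; zero shift applied")
      next
    }
    apex <- win[which.max(seg)]
    shifts[i] <- target - apex
    if (shifts[i] != 0) {
      set$intensities[i, ] <- shift_vector(set$intensities[i, ], shifts[i])
    }
  }
  log_step(set, "reference_align",
           list(window = config$tsp_search_window, shifts = shifts))
}

#' Spline baseline correction
#'
#' Estimates a per-spectrum baseline as a natural cubic spline through one
#' anchor per window of width `knot_spacing`: the anchor sits at the window
#' center and takes the window's median intensity. The median tracks the
#' baseline level wherever peaks occupy a minority of the window and, unlike
#' a window minimum, is unbiased on noisy peak-free stretches, so correcting
#' pure noise re-centers it on zero. Negative intensities in the result are
#' retained (the glog transform accepts them).
#'
#' @param set A `SpectrumSet`.
#' @param knot_spacing Anchor window width in ppm; must exceed the grid
#'   spacing and be narrower than the grid itself.
#' @return Baseline-corrected `SpectrumSet`.
#' @export
baseline_correct <- function(set, knot_spacing = 0.25) {
  ppm <- set$ppm
  if (knot_spacing <= min(diff(ppm))) {
    stop("knot_spacing must exceed the grid spacing", call. = FALSE)
  }
  if (knot_spacing >= diff(range(ppm))) {
    stop("knot_spacing wider than the grid", call. = FALSE)
  }
  edges <- seq(min(ppm), max(ppm), by = knot_spacing)
  if (edges[length(edges)] < max(ppm)) edges <- c(edges, max(ppm))
  bin <- cut(ppm, edges, include.lowest = TRUE)
  idx <- split(seq_along(ppm), bin)
  idx <- idx[vapply(idx, length, 0L) > 0]
  anchor_x <- vapply(idx, function(j) mean(ppm[j]), 0)
  for (i in seq_len(nrow(set$intensities))) {
    y <- set$intensities[i, ]
    anchor_val <- vapply(idx, function(j) stats::median(y[j]), 0)
    base <- stats::spline(anchor_x, anchor_val, xout = ppm,
                          method = "natural")$y
    set$intensities[i, ] <- y - base
  }
  log_step(set, "baseline_correct", list(knot_spacing = knot_spacing))
}

#' Exclude spectral regions
#'
#' Removes the grid columns falling inside any configured exclusion region
#' (by default the water and TSP regions). The surviving grid may be
#' non-uniform, which downstream steps accept.
#'
#' @param set A `SpectrumSet`.
#' @param config A `PreprocessConfig`.
#' @return The reduced `SpectrumSet`.
#' @export
exclude_regions <- function(set, config = preprocess_config()) {
  drop <- rep(FALSE, length(set$ppm))
  for (reg in config$exclusion_regions) {
    drop <- drop | (set$ppm >= reg[1] & set$ppm <= reg[2])
  }
  if (all(drop)) stop("exclusion regions remove every column", call. = FALSE)
  out <- set[, which(!drop)]
  out$log <- set$log
  log_step(out, "exclude_regions",
           list(regions = config$exclusion_regions,
                n_removed = sum(drop)))
}

#' Segmental (interval) alignment
#'
#' For each configured ppm segment, shifts each spectrum's segment by the
#' integer offset (within `max_segment_shift` points) that maximizes its
#' Pearson correlation with the corresponding segment of the mean spectrum.
#' Vacated positions are filled by edge-value repetition. This corrects
#' resonances displaced by small sample-to-sample differences such as pH.
#'
#' @param set A `SpectrumSet`.
#' @param config A `PreprocessConfig`.
#' @return The aligned `SpectrumSet`.
#' @export
segmental_align <- function(set, config = preprocess_config()) {
  if (config$max_segment_shift < 1) {
    stop("max_segment_shift must be >= 1", call. = FALSE)
  }
  target <- colMeans(set$intensities)
  all_shifts <- list()
  for (s in seq_along(config$alignment_segments)) {
    seg <- config$alignment_segments[[s]]
    cols <- which(set$ppm >= seg[1] & set$ppm <= seg[2])
    if (length(cols) == 0) next
    if (length(cols) < 3) stop("alignment segment shorter than 3 points",
                               call. = FALSE)
    tgt <- target[cols]
    if (stats::sd(tgt) == 0) next
    shifts <- integer(nrow(set$intensities))
    for (i in seq_len(nrow(set$intensities))) {
      y <- set$intensities[i, cols]
      if (stats::sd(y) == 0) next
      best_k <- 0L
      best_r <- stats::cor(y, tgt)
      for (k in seq(-config$max_segment_shift, config$max_segment_shift)) {
        if (k == 0) next
        shifted <- shift_vector(y, k)
        if (stats::sd(shifted) == 0) next   # fully displaced off the segment
        r <- stats::cor(shifted, tgt)
        if (!is.na(r) && r > best_r + 1e-12) { best_r <- r; best_k <- k }
      }
      if (best_k != 0) {
        set$intensities[i, cols] <- shift_vector(y, best_k)
      }
      shifts[i] <- best_k
    }
    all_shifts[[paste(seg, collapse = "..")]] <- shifts
  }
  log_step(set, "segmental_align",
           list(segments = config$alignment_segments,
                max_shift = config$max_segment_shift, shifts = all_shifts))
}

#' Total-area normalization
#'
#' Divides each spectrum by its summed intensity so every row sums to one,
#' making spectra comparable across differing extract amounts.
#'
#' @param set A `SpectrumSet`.
#' @return The normalized `SpectrumSet`.
#' @export
total_area_normalize <- function(set) {
  areas <- rowSums(set$intensities)
  bad <- which(areas <= 0)
  if (length(bad)) {
    stop("non-positive total area for sample(s): ",
         paste(set$metadata$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  set$intensities <- set$intensities / areas
  log_step(set, "total_area_normalize", list())
}

#' Generalized-log transform
#'
#' `g(y) = ln((y - y0 + sqrt((y - y0)^2 + lambda)) / 2)`, defined for all
#' real `y` (negative intensities after baseline correction are allowed).
#' Behaves like `ln(y)` for large `y` and stays finite near and below zero,
#' increasing the weight of weak resonances in multivariate models.
#'
#' @param y Numeric vector or matrix.
#' @param y0 Offset parameter (default 1e-7).
#' @param lambda Transition parameter (default 5e-4); must be positive.
#' @return Transformed values, same shape as `y`.
#' @export
glog <- function(y, y0 = 1e-7, lambda = 5e-4) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  z <- y - y0
  log((z + sqrt(z^2 + lambda)) / 2)
}

#' Analytic inverse of [glog()]
#'
#' @inheritParams glog
#' @param g Transformed values.
#' @return Original-scale values.
#' @export
glog_inverse <- function(g, y0 = 1e-7, lambda = 5e-4) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  u <- exp(g)
  (u - lambda / (4 * u)) + y0
}

#' Apply the glog transform to a SpectrumSet
#'
#' @param set A `SpectrumSet`.
#' @param config A `PreprocessConfig` carrying `glog_y0` and `glog_lambda`.
#' @return The transformed `SpectrumSet`.
#' @export
glog_transform <- function(set, config = preprocess_config()) {
  set$intensities <- glog(set$intensities, config$glog_y0, config$glog_lambda)
  log_step(set, "glog_transform",
           list(y0 = config$glog_y0, lambda = config$glog_lambda))
}

#' Mean-center a matrix, returning the training means
#'
#' @param X Numeric matrix with at least two rows.
#' @param means Optional column means to apply (for held-out data, supply
#'   the training means instead of recomputing them).
#' @return List with `centered` (matrix) and `means` (numeric vector).
#' @export
mean_center <- function(X, means = NULL) {
  X <- as.matrix(X)
  if (is.null(means)) {
    if (nrow(X) < 2) stop("mean centering needs >= 2 rows", call. = FALSE)
    means <- colMeans(X)
  }
  list(centered = sweep(X, 2, means), means = means)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: TSP alignment, spline baseline correction, region
#' exclusion, segmental alignment, total-area normalization and the glog
#' transform. Mean centering is left to the modelling stage so that held-out
#' data can be centered with training means.
#'
#' @param set A raw `SpectrumSet`.
#' @param config A `PreprocessConfig`.
#' @param glog Apply the glog transform (TRUE for multivariate modelling;
#'   univariate peak intensities use the normalized, pre-glog matrix).
#' @return The processed `SpectrumSet`.
#' @export
preprocess <- function(set, config = preprocess_config(), glog = TRUE) {
  set <- reference_align(set, config)
  set <- baseline_correct(set, config$knot_spacing)
  set <- exclude_regions(set, config)
  set <- segmental_align(set, config)
  set <- total_area_normalize(set)
  if (glog) set <- glog_transform(set, config)
  set
}
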