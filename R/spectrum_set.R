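#' Construct a uniform ppm grid
#'
#' The chemical-shift axis on which spectra are evaluated. Stored ascending;
#' NMR display convention (descending ppm) is applied only at export time.
#'
#' @param from,to Range of the axis in ppm. The default covers -0.5 to 10 ppm,
#'   matching a ~12 ppm spectral window at 600 MHz with margin below the TSP
#'   reference at 0 ppm.
#' @param n_points Number of grid points (default `2^14`).
#' @return Numeric vector of ppm values, strictly increasing, uniform spacing.
#' @export
ppm_grid <- function(from = -0.5, to = 10, n_points = 2^14) {
  stopifnot(is.numeric(from), is.numeric(to), to > from, n_points >= 2)
  seq(from, to, length.out = n_points)
}

#' Validate a ppm grid
#'
#' @param ppm Numeric vector of chemical shifts.
#' @param uniform Require constant spacing (to within 1e-9 ppm)? Grids become
#'   non-uniform after region exclusion, which downstream steps accept.
#' @return `ppm`, invisibly, after validation.
#' @keywords internal
validate_ppm <- function(ppm, uniform = TRUE) {
  if (length(ppm) < 2 || any(diff(ppm) <= 0)) {
    stop("ppm axis must be strictly increasing", call. = FALSE)
  }
  if (uniform) {
    d <- diff(ppm)
    if (max(d) - min(d) > 1e-9) {
      stop("ppm axis spacing must be uniform to within 1e-9 ppm", call. = FALSE)
    }
  }
  invisible(ppm)
}

#' Create a SpectrumSet
#'
#' The central container of the pipeline: a samples x ppm intensity matrix,
#' its chemical-shift axis, per-sample metadata, and an append-only log of
#' the processing steps applied so far.
#'
#' @param intensities Numeric matrix, one row per sample.
#' @param ppm Numeric vector of chemical shifts, one per column.
#' @param metadata Data frame with at least `sample_id`, `subject_id`,
#'   `class_id` and `chemo_flag`, one row per spectrum.
#' @param log List of processing-log entries (each a named list with `step`
#'   and `params`).
#' @return An object of class `SpectrumSet`.
#' @export
spectrum_set <- function(intensities, ppm, metadata, log = list()) {
  intensities <- as.matrix(intensities)
  if (!is.numeric(intensities)) stop("intensities must be numeric", call. = FALSE)
  if (ncol(intensities) != length(ppm)) {
    stop("grid length must equal the number of intensity columns", call. = FALSE)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  required <- c("sample_id", "subject_id", "class_id", "chemo_flag")
  missing <- setdiff(required, names(metadata))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(metadata) != nrow(intensities)) {
    stop("metadata row count must equal the number of spectra", call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicated sample_id in metadata", call. = FALSE)
  }
  validate_ppm(ppm, uniform = FALSE)
  rownames(intensities) <- metadata$sample_id
  structure(
    list(intensities = intensities, ppm = as.numeric(ppm),
         metadata = metadata, log = log),
    class = "SpectrumSet"
  )
}

#' @export
print.SpectrumSet <- function(x, ...) {
  cat(sprintf("SpectrumSet: %d spectra x %d points, %.2f to %.2f ppm\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$ppm), max(x$ppm)))
  cl <- table(x$metadata$class_id)
  cat("classes:", paste(sprintf("%s(n=%d)", names(cl), cl), collapse = " "), "\n")
  if (length(x$log)) {
    cat("processing:", paste(vapply(x$log, `[[`, "", "step"), collapse = " -> "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.SpectrumSet <- function(x) dim(x$intensities)

#' Subset a SpectrumSet by sample and/or column
#' @param x A `SpectrumSet`.
#' @param i Row (sample) index. @param j Column (ppm) index.
#' @param ... Ignored.
#' @return A `SpectrumSet`.
#' @export
`[.SpectrumSet` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  spectrum_set(x$intensities[i, j, drop = FALSE], x$ppm[j],
               x$metadata[i, , drop = FALSE], x$log)
}

# append one entry to the processing log (append-only by construction)
log_step <- function(set, step, params = list()) {
  set$log[[length(set$log) + 1L]] <- list(step = step, params = params)
  set
}

#' Nearest grid index for a ppm value
#' @keywords internal
ppm_index <- function(ppm, value) which.min(abs(ppm - value))
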