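#' Write a SpectrumSet to the interchange CSV
#'
#' One header row (metadata column names, then ppm values in fixed decimal
#' notation) and one row per sample: sample_id, subject_id, class_id,
#' chemo_flag, then intensities. ppm columns are written in descending
#' order (NMR display convention) with 10 decimal places so that a uniform
#' grid survives the round trip to within the 1e-9 ppm spacing invariant.
#'
#' @param set A `SpectrumSet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(set, path) {
  ord <- order(set$ppm, decreasing = TRUE)
  digits <- 10
  ppm_lab <- formatC(set$ppm[ord], format = "f", digits = digits)
  header <- c("sample_id", "subject_id", "class_id", "chemo_flag", ppm_lab)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  md <- set$metadata
  X <- set$intensities[, ord, drop = FALSE]
  for (i in seq_len(nrow(X))) {
    writeLines(paste(c(md$sample_id[i], md$subject_id[i],
                       as.character(md$class_id[i]),
                       as.character(md$chemo_flag[i]),
                       formatC(X[i, ], format = "g", digits = 15)),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Read a SpectrumSet from the interchange CSV
#'
#' @param path File written by [write_spectrum_csv()] (or matching its
#'   schema).
#' @return A `SpectrumSet` (ppm axis ascending internally).
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "subject_id", "class_id", "chemo_flag")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing metadata column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("empty data section", call. = FALSE)
  ppm_cols <- setdiff(names(df), required)
  ppm <- suppressWarnings(as.numeric(ppm_cols))
  if (anyNA(ppm)) stop("non-numeric ppm column header", call. = FALSE)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) {
    dominant <- sign(stats::median(d))
    bad <- which(sign(d) != dominant)[1] + 1L
    stop("ppm header not strictly monotone at column ", bad, call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id", call. = FALSE)
  }
  X <- as.matrix(df[, ppm_cols, drop = FALSE])
  if (ppm[1] > ppm[length(ppm)]) {     # stored descending: flip to ascending
    ppm <- rev(ppm)
    X <- X[, rev(seq_len(ncol(X))), drop = FALSE]
  }
  md <- df[, required, drop = FALSE]
  md$chemo_flag <- as.logical(md$chemo_flag)
  md$class_id <- as.character(md$class_id)
  spectrum_set(X, ppm, md)
}

#' Export the processing log as JSON lines
#'
#' One JSON object per applied step, carrying the step name and its
#' parameters: enough to replay the preprocessing exactly.
#'
#' @param set A `SpectrumSet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_processing_log <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (entry in set$log) {
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Serialize a PLS-DA model to JSON
#'
#' Writes weights, loadings, regression vector, centering means and the
#' class encoding, sufficient to reapply the model to new matrices.
#'
#' @param model A `PlsdaModel`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
model_to_json <- function(model, path) {
  payload <- list(
    type = "PlsdaModel",
    n_latent_variables = model$n_latent_variables,
    n_osc_components = model$n_osc_components,
    x_weights = model$x_weights, x_loadings = model$x_loadings,
    y_loadings = model$y_loadings,
    regression_vector = model$regression_vector,
    osc_weights = model$osc$weights, osc_loadings = model$osc$loadings,
    x_means = model$x_means, y_means = model$y_means,
    classes = model$class_encoding$classes,
    targets = model$class_encoding$targets
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a PLS-DA model from JSON
#'
#' @param path File written by [model_to_json()].
#' @return A `PlsdaModel`.
#' @export
model_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$type, "PlsdaModel")) stop("not a PlsdaModel file",
                                             call. = FALSE)
  as_mat <- function(x) if (is.null(x)) NULL else as.matrix(x)
  targets <- as_mat(p$targets)
  rownames(targets) <- p$classes
  structure(
    list(n_latent_variables = p$n_latent_variables,
         n_osc_components = p$n_osc_components,
         osc = list(weights = as_mat(p$osc_weights),
                    loadings = as_mat(p$osc_loadings)),
         x_weights = as_mat(p$x_weights), x_scores = NULL,
         x_loadings = as_mat(p$x_loadings), y_loadings = as_mat(p$y_loadings),
         regression_vector = as_mat(p$regression_vector),
         class_encoding = list(Y = NULL, classes = p$classes,
                               targets = targets),
         x_means = p$x_means, y_means = p$y_means),
    class = "PlsdaModel"
  )
}
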