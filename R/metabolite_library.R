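#' Define a metabolite signature
#'
#' A signature is the set of Lorentzian peaks a metabolite contributes to a
#' simulated spectrum, plus its baseline (log) concentration. Multiplet fine
#' structure is encoded as an explicit peak list, not J-coupling.
#'
#' @param name Metabolite name.
#' @param peaks Data frame (or list coercible to one) with columns
#'   `center_ppm`, `relative_intensity` (> 0, proportional to proton count)
#'   and `linewidth_hz` (> 0, Lorentzian FWHM in Hz).
#' @param base_log_concentration Baseline natural-log concentration.
#' @param reference_peak ppm of the well-resolved peak used for univariate
#'   tracking; defaults to the first peak.
#' @return An object of class `MetaboliteSignature`.
#' @export
metabolite_signature <- function(name, peaks, base_log_concentration = 0,
                                 reference_peak = NULL) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center_ppm", "relative_intensity", "linewidth_hz") %in%
                  names(peaks)))
  if (nrow(peaks) < 1) stop("signature needs at least one peak", call. = FALSE)
  if (any(peaks$relative_intensity <= 0)) {
    stop("relative_intensity must be positive", call. = FALSE)
  }
  if (any(peaks$linewidth_hz <= 0)) {
    stop("linewidth_hz must be positive", call. = FALSE)
  }
  if (is.null(reference_peak)) reference_peak <- peaks$center_ppm[1]
  structure(
    list(name = name, peaks = peaks,
         base_log_concentration = base_log_concentration,
         reference_peak = reference_peak),
    class = "MetaboliteSignature"
  )
}

#' Load a metabolite library from YAML
#'
#' @param path Path to a YAML file with a top-level `metabolites` list; see
#'   the packaged default at
#'   `system.file("extdata", "metabolite_library.yaml", package = "nmrfield")`.
#' @return Named list of `MetaboliteSignature` objects.
#' @export
read_metabolite_library <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$metabolites)) stop("no 'metabolites' entry in ", path,
                                     call. = FALSE)
  sigs <- lapply(cfg$metabolites, function(m) {
    peaks <- do.call(rbind, lapply(m$peaks, as.data.frame))
    metabolite_signature(m$name, peaks,
                         base_log_concentration = m$base_log_concentration,
                         reference_peak = m$reference_peak)
  })
  names(sigs) <- vapply(sigs, `[[`, "", "name")
  sigs
}

#' The default metabolite library
#'
#' The ~25 metabolites reported as discriminating between esophageal tissue
#' classes, with literature chemical shifts, plus the TSP reference singlet
#' at 0 ppm. Positions and intensities are editable simulation defaults.
#'
#' @return Named list of `MetaboliteSignature` objects.
#' @export
default_metabolite_library <- function() {
  read_metabolite_library(
    system.file("extdata", "metabolite_library.yaml", package = "nmrfield",
                mustWork = TRUE)
  )
}

#' Reference peak positions of a metabolite library
#'
#' @param signatures Named list of `MetaboliteSignature`.
#' @param exclude Metabolites to drop (the TSP reference is excluded from
#'   quantification by default: its spectral region is removed in
#'   preprocessing).
#' @return Named numeric vector of reference ppm values.
#' @export
library_reference_peaks <- function(signatures, exclude = "TSP") {
  sigs <- signatures[setdiff(names(signatures), exclude)]
  vapply(sigs, `[[`, 0, "reference_peak")
}
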