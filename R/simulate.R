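#' Describe a simulated tissue cohort
#'
#' @param class_sizes Named integer vector mapping class ids ("1".."9") to
#'   sample counts.
#' @param pairing Data frame with columns `subject_id`, `class_id`,
#'   `sample_id` assigning every sample to a subject; subjects appearing more
#'   than once contribute paired samples.
#' @param noise_sd Additive spectral (Gaussian) noise SD, intensity units.
#' @param shift_jitter_sd Per-metabolite chemical-shift jitter SD (ppm),
#'   emulating pH-driven displacement.
#' @param sample_shift_sd Per-sample global shift SD (ppm), emulating
#'   referencing error removed later by TSP alignment.
#' @param baseline_amplitude Amplitude of the smooth cosine baseline.
#' @param subject_sd SD of the per-subject random effect on natural-log
#'   concentration (shared by all samples of a subject).
#' @param concentration_sd SD of per-sample log-concentration noise.
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @return An object of class `CohortDesign`.
#' @export
cohort_design <- function(class_sizes, pairing = NULL, noise_sd = 0.02,
                          shift_jitter_sd = 0.003, sample_shift_sd = 0.01,
                          baseline_amplitude = 0.5, subject_sd = 0.2,
                          concentration_sd = 0.3, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  class_sizes <- stats::setNames(as.integer(class_sizes), names(class_sizes))
  if (any(class_sizes < 0)) stop("class size < 0", call. = FALSE)
  if (!all(names(class_sizes) %in% as.character(1:9))) {
    stop("class ids must be drawn from 1..9", call. = FALSE)
  }
  if (is.null(pairing)) pairing <- unpaired_pairing(class_sizes)
  pairing <- as.data.frame(pairing, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "class_id", "sample_id") %in% names(pairing)))
  got <- table(factor(as.character(pairing$class_id),
                      levels = names(class_sizes)))
  if (!all(got == class_sizes)) {
    stop("pairing table does not match class_sizes", call. = FALSE)
  }
  structure(
    list(class_sizes = class_sizes, pairing = pairing, noise_sd = noise_sd,
         shift_jitter_sd = shift_jitter_sd, sample_shift_sd = sample_shift_sd,
         baseline_amplitude = baseline_amplitude, subject_sd = subject_sd,
         concentration_sd = concentration_sd, seed = as.integer(seed)),
    class = "CohortDesign"
  )
}

# one subject per sample when no pairing structure is requested
unpaired_pairing <- function(class_sizes) {
  do.call(rbind, lapply(names(class_sizes), function(cl) {
    n <- class_sizes[[cl]]
    if (n == 0) return(NULL)
    data.frame(subject_id = sprintf("S%s_%02d", cl, seq_len(n)),
               class_id = cl,
               sample_id = sprintf("c%s_%02d", cl, seq_len(n)),
               stringsAsFactors = FALSE)
  }))
}

#' The default study design
#'
#' Nine tissue classes at the study's sample counts (68/7/30/7/4/28/29/9/29,
#' 211 spectra in total), with paired-subject structure: Barrett's patients
#' contribute normal + Barrett's tissue (classes 2 and 4); EAC patients
#' contribute normal, Barrett's and tumor tissue pre-chemotherapy (classes
#' 3/5/6) and, for a subset, matching post-chemotherapy samples (7/8/9) --
#' 15 paired normal and 14 paired tumor samples across chemotherapy.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [cohort_design()].
#' @return A `CohortDesign`.
#' @export
default_cohort_design <- function(seed, ...) {
  sizes <- c("1" = 68, "2" = 7, "3" = 30, "4" = 7, "5" = 4, "6" = 28,
             "7" = 29, "8" = 9, "9" = 29)
  rows <- list()
  put <- function(subject, cls, tag) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = subject, class_id = cls,
      sample_id = sprintf("%s_c%s", tag, cls), stringsAsFactors = FALSE)
  }
  for (i in 1:68) put(sprintf("CTRL%02d", i), "1", sprintf("CTRL%02d", i))
  for (i in 1:7) {               # Barrett's patients: paired classes 2 + 4
    put(sprintf("BO%02d", i), "2", sprintf("BO%02d", i))
    put(sprintf("BO%02d", i), "4", sprintf("BO%02d", i))
  }
  for (i in 1:30) put(sprintf("EAC%02d", i), "3", sprintf("EAC%02d", i))
  for (i in 1:4)  put(sprintf("EAC%02d", i), "5", sprintf("EAC%02d", i))
  for (i in 1:28) put(sprintf("EAC%02d", i), "6", sprintf("EAC%02d", i))
  # post-chemotherapy: 15 paired + 14 new subjects for normal tissue,
  # 14 paired + 15 new for tumor tissue, 4 paired + 5 new for Barrett's
  for (i in 1:15) put(sprintf("EAC%02d", i), "7", sprintf("EAC%02d", i))
  for (i in 1:14) put(sprintf("EACPO%02d", i), "7", sprintf("EACPO%02d", i))
  for (i in 1:4)  put(sprintf("EAC%02d", i), "8", sprintf("EAC%02d", i))
  for (i in 1:5)  put(sprintf("EACPO%02d", i), "8", sprintf("EACPO%02d", i))
  for (i in 1:14) put(sprintf("EAC%02d", i), "9", sprintf("EAC%02d", i))
  for (i in 1:15) put(sprintf("EACPO%02d", i), "9", sprintf("EACPO%02d", i))
  cohort_design(class_sizes = sizes, pairing = do.call(rbind, rows),
                seed = seed, ...)
}

#' Simulate one frequency-domain spectrum
#'
#' Builds a spectrum as a sum of metabolite Lorentzians plus a smooth cosine
#' baseline and i.i.d. Gaussian noise. Peak height of each Lorentzian is
#' `exp(log_concentration) * relative_intensity`; the full width at half
#' maximum is `linewidth_hz / spectrometer_mhz` ppm.
#'
#' @param signatures List of `MetaboliteSignature`.
#' @param log_concentrations Named numeric vector of natural-log
#'   concentrations (names matching signatures; missing names fall back to
#'   each signature's `base_log_concentration`).
#' @param grid Ppm grid (ascending numeric vector).
#' @param jitter_sd Per-metabolite chemical-shift jitter SD (ppm).
#' @param baseline_amplitude Amplitude of the 3-term cosine baseline.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed; the call is deterministic given it.
#' @param global_shift Extra ppm offset applied to every peak (referencing
#'   error; default 0).
#' @param spectrometer_mhz Proton frequency used to convert Hz linewidths to
#'   ppm (default 600).
#' @return Numeric intensity vector on `grid`.
#' @export
simulate_spectrum <- function(signatures, log_concentrations = NULL,
                              grid, jitter_sd = 0, baseline_amplitude = 0,
                              noise_sd = 0, seed, global_shift = 0,
                              spectrometer_mhz = 600) {
  if (length(signatures) == 0) stop("empty signature list", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  validate_ppm(grid, uniform = FALSE)
  set.seed(as.integer(seed))
  y <- numeric(length(grid))
  rng <- range(grid)
  for (sig in signatures) {
    if (!inherits(sig, "MetaboliteSignature")) {
      stop("signatures must be MetaboliteSignature objects", call. = FALSE)
    }
    lc <- if (!is.null(log_concentrations) &&
              sig$name %in% names(log_concentrations)) {
      log_concentrations[[sig$name]]
    } else sig$base_log_concentration
    jit <- if (jitter_sd > 0) stats::rnorm(1, 0, jitter_sd) else 0
    amp <- exp(lc)
    for (k in seq_len(nrow(sig$peaks))) {
      pk <- sig$peaks[k, ]
      if (pk$linewidth_hz <= 0) stop("non-positive linewidth", call. = FALSE)
      ctr <- pk$center_ppm + jit + global_shift
      ctr <- min(max(ctr, rng[1]), rng[2])   # truncate jitter to the grid
      hw <- (pk$linewidth_hz / spectrometer_mhz) / 2
      y <- y + amp * pk$relative_intensity * hw^2 / ((grid - ctr)^2 + hw^2)
    }
  }
  if (baseline_amplitude > 0) {
    phases <- stats::runif(3, 0, 2 * pi)
    x01 <- (grid - rng[1]) / diff(rng)
    for (k in 1:3) {
      y <- y + baseline_amplitude / k * cos(2 * pi * k * x01 + phases[k])
    }
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(grid), 0, noise_sd)
  y
}

#' Per-sample log-concentrations implied by a design
#'
#' The generative model on the natural-log concentration scale:
#' base + log(2) * class log2-offset + subject random effect + sample noise.
#' Exposed separately so tests can check effect recovery on concentrations
#' directly.
#'
#' @inheritParams simulate_cohort
#' @return List with `log_concentrations` (samples x metabolites matrix) and
#'   `metadata` (sample_id, subject_id, class_id, chemo_flag).
#' @export
cohort_concentrations <- function(design, effects, signatures) {
  stopifnot(inherits(design, "CohortDesign"), inherits(effects, "EffectTable"))
  if (is.null(names(signatures))) {
    names(signatures) <- vapply(signatures, `[[`, "", "name")
  }
  pairing <- design$pairing
  mets <- names(signatures)
  base <- vapply(signatures, `[[`, 0, "base_log_concentration")
  set.seed(design$seed)
  subjects <- unique(pairing$subject_id)
  subj_eff <- matrix(stats::rnorm(length(subjects) * length(mets), 0,
                                  design$subject_sd),
                     nrow = length(subjects),
                     dimnames = list(subjects, mets))
  n <- nrow(pairing)
  lc <- matrix(0, n, length(mets), dimnames = list(pairing$sample_id, mets))
  eff_mets <- intersect(mets, colnames(effects$offsets))
  for (i in seq_len(n)) {
    cls <- as.character(pairing$class_id[i])
    row <- base
    if (cls %in% rownames(effects$offsets)) {
      row[eff_mets] <- row[eff_mets] +
        log(2) * effects$offsets[cls, eff_mets]
    }
    row <- row + subj_eff[pairing$subject_id[i], ]
    if (design$concentration_sd > 0) {
      row <- row + stats::rnorm(length(mets), 0, design$concentration_sd)
    }
    lc[i, ] <- row
  }
  if ("TSP" %in% mets) {   # reference compound: fixed amount, no biology
    lc[, "TSP"] <- base[["TSP"]]
  }
  md <- data.frame(sample_id = pairing$sample_id,
                   subject_id = pairing$subject_id,
                   class_id = as.character(pairing$class_id),
                   chemo_flag = as.character(pairing$class_id) %in%
                     c("7", "8", "9"),
                   stringsAsFactors = FALSE)
  list(log_concentrations = lc, metadata = md)
}

#' Simulate a full cohort of spectra
#'
#' @param design A `CohortDesign`.
#' @param effects An `EffectTable`.
#' @param signatures Named list of `MetaboliteSignature` (default: the
#'   packaged metabolite library).
#' @param grid Ppm grid (default [ppm_grid()]).
#' @return A `SpectrumSet` with populated metadata.
#' @export
simulate_cohort <- function(design, effects = default_effect_table(),
                            signatures = default_metabolite_library(),
                            grid = ppm_grid()) {
  conc <- cohort_concentrations(design, effects, signatures)
  n <- nrow(conc$metadata)
  # continue the seeded stream: per-sample shifts and child seeds
  shifts <- if (design$sample_shift_sd > 0) {
    stats::rnorm(n, 0, design$sample_shift_sd)
  } else numeric(n)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n)
  X <- matrix(0, n, length(grid),
              dimnames = list(conc$metadata$sample_id, NULL))
  for (i in seq_len(n)) {
    lc_i <- stats::setNames(conc$log_concentrations[i, ],
                            colnames(conc$log_concentrations))
    X[i, ] <- simulate_spectrum(
      signatures, lc_i, grid,
      jitter_sd = design$shift_jitter_sd,
      baseline_amplitude = design$baseline_amplitude,
      noise_sd = design$noise_sd, seed = child_seeds[i],
      global_shift = shifts[i])
  }
  set <- spectrum_set(X, grid, conc$metadata)
  log_step(set, "simulate",
           list(seed = design$seed, n = n,
                noise_sd = design$noise_sd,
                shift_jitter_sd = design$shift_jitter_sd,
                sample_shift_sd = design$sample_shift_sd,
                baseline_amplitude = design$baseline_amplitude,
                subject_sd = design$subject_sd,
                concentration_sd = design$concentration_sd))
}
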