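# Shared fixtures: desk-scale grids and cohort builders used across tests.
# All fixtures are generated in code at test time; grids are coarser than
# the package default to keep the suite fast.

test_grid <- function(n_points = 1024) ppm_grid(n_points = n_points)

# a single-singlet signature at an isolated position (useful for exact
# amplitude arithmetic, free of neighbouring-peak tails)
singlet_signature <- function(name = "formate", center = 8.46,
                              base_log_concentration = 0, linewidth = 2) {
  metabolite_signature(
    name,
    data.frame(center_ppm = center, relative_intensity = 1,
               linewidth_hz = linewidth),
    base_log_concentration = base_log_concentration)
}

# two-class cohort (class ids "1" and "6") at chosen sizes
two_class_design <- function(n1 = 68, n6 = 28, seed, ...) {
  cohort_design(class_sizes = c("1" = n1, "6" = n6), seed = seed, ...)
}

# cohort with no class effects: labels independent of spectra
null_effect_table <- function() {
  off <- matrix(0, 9, length(names(nmrfield:::default_signature_names())),
                dimnames = list(as.character(1:9),
                                names(nmrfield:::default_signature_names())))
  effect_table(off)
}

# paired cohort: n_subjects each contributing one class-3 and one class-6
# sample (the paired tissue design)
paired_design <- function(n_subjects = 16, seed, ...) {
  pairing <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    data.frame(subject_id = sprintf("P%02d", i), class_id = c("3", "6"),
               sample_id = sprintf("P%02d_c%s", i, c("3", "6")),
               stringsAsFactors = FALSE)
  }))
  cohort_design(class_sizes = c("3" = n_subjects, "6" = n_subjects),
                pairing = pairing, seed = seed, ...)
}

# simulate + preprocess in both scales: glog for multivariate work,
# pre-glog (normalized) for peak tracking
prepped_cohort <- function(design, grid = test_grid(), effects = NULL) {
  if (is.null(effects)) effects <- default_effect_table()
  raw <- simulate_cohort(design, effects = effects, grid = grid)
  pre <- preprocess(raw, glog = FALSE)
  list(pre_glog = pre, glog = glog_transform(pre), raw = raw)
}
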