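test_that("reference peaks are picked at the apex within the search window", {
  grid <- test_grid(4096)
  sigs <- list(singlet_signature("formate", 8.46),
               singlet_signature("acetate", 1.92))
  y <- simulate_spectrum(sigs, grid = grid, seed = 1)
  set <- spectrum_set(rbind(y, y), grid, data.frame(
    sample_id = c("s1", "s2"), subject_id = c("s1", "s2"),
    class_id = "1", chemo_flag = FALSE))
  refs <- pick_reference_peaks(set, c(formate = 8.46, acetate = 1.92))
  expect_lt(max(abs(refs$reference_ppm - refs$target_ppm)), diff(grid)[1])
  expect_false(any(refs$unresolved))
  # a peak jittered off its nominal position is still found in the window
  y2 <- simulate_spectrum(list(singlet_signature("formate", 8.47)),
                          grid = grid, seed = 2)
  set2 <- set; set2$intensities[1, ] <- y2
  refs2 <- pick_reference_peaks(set2, c(formate = 8.46), window = 0.03)
  expect_lt(abs(refs2$reference_ppm - 8.47), diff(grid)[1])
  expect_error(pick_reference_peaks(set, c(x = 12.5)), "window")
})

test_that("overlapping targets are flagged unresolved", {
  grid <- test_grid(4096)
  y <- simulate_spectrum(list(singlet_signature("a", 3.21),
                              singlet_signature("b", 3.22)),
                         grid = grid, seed = 3)
  set <- spectrum_set(rbind(y, y), grid, data.frame(
    sample_id = c("s1", "s2"), subject_id = c("s1", "s2"),
    class_id = "1", chemo_flag = FALSE))
  refs <- pick_reference_peaks(set, c(a = 3.21, b = 3.22), window = 0.03)
  expect_true(all(refs$unresolved))
})

test_that("tracked intensities recover generated amplitudes", {
  grid <- test_grid(8192)
  # put the singlet exactly on a grid point so the sampled apex equals the
  # analytic peak height
  on_grid <- grid[which.min(abs(grid - 8.46))]
  sig <- list(singlet_signature("formate", on_grid))
  d <- cohort_design(c("1" = 4), seed = 5, noise_sd = 0,
                     shift_jitter_sd = 0, sample_shift_sd = 0,
                     baseline_amplitude = 0, subject_sd = 0,
                     concentration_sd = 0.2)
  set <- simulate_cohort(d, effects = null_effect_table(),
                         signatures = sig, grid = grid)
  conc <- cohort_concentrations(d, null_effect_table(), sig)
  pk <- track_peaks(set, c(formate = 8.46), window = 0.03)
  # peak height = exp(log concentration) x relative intensity (1) within 1%
  expect_equal(unname(pk$intensity[, "formate"]),
               unname(exp(conc$log_concentrations[, "formate"])),
               tolerance = 0.01)
  # a metabolite absent from the spectra is flagged low-prominence
  d2 <- cohort_design(c("1" = 3), seed = 6, noise_sd = 0.05,
                      baseline_amplitude = 0, subject_sd = 0,
                      sample_shift_sd = 0, shift_jitter_sd = 0)
  set2 <- simulate_cohort(d2, effects = null_effect_table(),
                          signatures = sig, grid = grid)
  pk2 <- track_peaks(set2, c(formate = 8.46, lactate = 1.33), window = 0.03)
  expect_true(all(pk2$low_prominence[, "lactate"]))
  expect_false(any(pk2$low_prominence[, "formate"]))
  # window 0 degenerates to the grid point nearest the reference
  pk0 <- track_peaks(set, c(formate = 8.46), window = 0)
  j <- which.min(abs(grid - 8.46))
  expect_equal(unname(pk0$intensity[, "formate"]),
               unname(set$intensities[, j]))
})

test_that("the normality gate maps to exactly the four documented tests", {
  expect_equal(select_test(FALSE, c(0.30, 0.40)), "welch")
  expect_equal(select_test(FALSE, c(0.30, 0.01)), "wilcoxon_rank_sum")
  expect_equal(select_test(FALSE, c(0.01, 0.30)), "wilcoxon_rank_sum")
  expect_equal(select_test(TRUE, 0.30), "paired_t")
  expect_equal(select_test(TRUE, 0.04), "wilcoxon_signed_rank")
  # boundary: p exactly at the cutoff retains the null
  expect_equal(select_test(TRUE, 0.05), "paired_t")
  expect_equal(select_test(FALSE, c(0.05, 0.05)), "welch")
  expect_error(select_test(TRUE, c(0.1, 0.2)), "one Shapiro")
  expect_error(select_test(FALSE, 0.1), "two Shapiro")
})

test_that("every (paired, normality) combination maps to one test", {
  set.seed(113)
  for (i in 1:50) {
    p2 <- stats::runif(2)
    t_unpaired <- select_test(FALSE, p2)
    expect_true(t_unpaired %in% c("welch", "wilcoxon_rank_sum"))
    expect_equal(t_unpaired == "welch", all(p2 >= 0.05))
    p1 <- stats::runif(1)
    t_paired <- select_test(TRUE, p1)
    expect_true(t_paired %in% c("paired_t", "wilcoxon_signed_rank"))
    expect_equal(t_paired == "paired_t", p1 >= 0.05)
  }
})

test_that("class comparison reports direction, tier, and consistent tests", {
  grid <- test_grid(2048)
  co <- prepped_cohort(two_class_design(12, 12, seed = 127))
  targets <- library_reference_peaks(default_metabolite_library())
  targets <- targets[targets > 0.2 & targets < 10]
  refs <- pick_reference_peaks(co$pre_glog, targets)
  pk <- track_peaks(co$pre_glog, refs)
  res <- compare_classes(pk, c("1", "6"))
  # designed positive formate effect comes out "up"
  expect_equal(res$direction[res$metabolite == "formate"], "up")
  expect_equal(res$direction[res$metabolite == "glutamine"], "down")
  # tier labels always consistent with the p value
  expect_true(all(
    (res$p_value < 5e-4) == (res$tier == "p<.0005") |
      (res$p_value >= 5e-4 & res$p_value < 5e-3) == (res$tier == "p<.005")))
  for (i in seq_len(nrow(res))) {
    expected_tier <- if (res$p_value[i] < 5e-4) "p<.0005"
      else if (res$p_value[i] < 5e-3) "p<.005"
      else if (res$p_value[i] < 0.05) "p<.05" else "ns"
    expect_equal(res$tier[i], expected_tier)
    # the test used agrees with the recorded Shapiro p values
    expect_equal(res$test_used[i],
                 select_test(FALSE, c(res$shapiro_p_a[i],
                                      res$shapiro_p_b[i])))
  }
  expect_error(compare_classes(pk, c("1", "9")), "present")
})

test_that("identical groups give no evidence against the null", {
  set.seed(131)
  vals <- stats::rnorm(8, mean = 5)
  intensity <- matrix(c(vals, vals), ncol = 1,
                      dimnames = list(NULL, "met"))
  pk <- structure(list(
    metabolites = "met", reference_ppm = c(met = 1), window = 0.03,
    intensity = intensity, picked_ppm = intensity * 0 + 1,
    low_prominence = intensity == Inf,
    metadata = data.frame(
      sample_id = sprintf("s%d", 1:16),
      subject_id = rep(sprintf("p%d", 1:8), 2),
      class_id = rep(c("1", "6"), each = 8), chemo_flag = FALSE)),
    class = "PeakTable")
  res <- compare_classes(pk, c("1", "6"))
  expect_gt(res$p_value, 0.05)
  expect_equal(res$tier, "ns")
  # paired branch matches subjects and is exercised by the same table
  resp <- compare_classes(pk, c("1", "6"), paired = TRUE)
  expect_equal(resp$tier, "ns")
  expect_true(resp$test_used %in% c("paired_t", "wilcoxon_signed_rank"))
})

test_that("paired comparisons require enough matched subjects", {
  intensity <- matrix(stats::rnorm(8), ncol = 1,
                      dimnames = list(NULL, "met"))
  pk <- structure(list(
    metabolites = "met", reference_ppm = c(met = 1), window = 0.03,
    intensity = intensity, picked_ppm = intensity * 0 + 1,
    low_prominence = intensity == Inf,
    metadata = data.frame(
      sample_id = sprintf("s%d", 1:8),
      subject_id = sprintf("q%d", 1:8),          # no shared subjects
      class_id = rep(c("1", "6"), each = 4), chemo_flag = FALSE)),
    class = "PeakTable")
  expect_error(compare_classes(pk, c("1", "6"), paired = TRUE), "paired")
  # unpaired with a group of 2 is rejected (Shapiro undefined)
  pk$metadata$class_id <- c(rep("1", 6), "6", "6")
  expect_error(compare_classes(pk, c("1", "6")), "group size")
})

test_that("fold changes are ratios of class means with reciprocity", {
  grid <- test_grid(4096)
  sig <- list(singlet_signature("formate", 8.46))
  eff <- default_effect_table()
  d <- cohort_design(c("1" = 3, "6" = 3), seed = 137, noise_sd = 0,
                     shift_jitter_sd = 0, sample_shift_sd = 0,
                     baseline_amplitude = 0, subject_sd = 0,
                     concentration_sd = 0)
  set <- simulate_cohort(d, effects = eff, signatures = sig, grid = grid)
  pk <- track_peaks(set, c(formate = 8.46), window = 0.03)
  fc <- fold_changes(pk, c("1", "6"))
  expect_equal(fc$fold_change, 2, tolerance = 0.01)   # designed log2FC = 1
  fc_rev <- fold_changes(pk, c("6", "1"))
  expect_equal(fc$fold_change * fc_rev$fold_change, 1, tolerance = 1e-9)
  # equal means give exactly 1
  pk$intensity[, "formate"] <- 1
  expect_equal(fold_changes(pk, c("1", "6"))$fold_change, 1)
  # non-positive means flagged, not computed
  pk$intensity[1:3, "formate"] <- -1
  expect_true(fold_changes(pk, c("1", "6"))$undefined_ratio)
})

test_that("the univariate chain is calibrated under the null", {
  grid <- test_grid(1024)
  hits <- 0; total <- 0
  for (r in 1:12) {
    co <- prepped_cohort(two_class_design(34, 14, seed = 3000 + r),
                         grid = grid, effects = null_effect_table())
    targets <- library_reference_peaks(default_metabolite_library())
    targets <- targets[targets > 0.2 & targets < 10]
    pk <- track_peaks(co$pre_glog,
                      pick_reference_peaks(co$pre_glog, targets))
    res <- compare_classes(pk, c("1", "6"))
    hits <- hits + sum(res$p_value < 0.05)
    total <- total + nrow(res)
  }
  # 99% binomial band around 5% for ~288 tests
  expect_gte(hits / total, 0.01)
  expect_lte(hits / total, 0.10)
})
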