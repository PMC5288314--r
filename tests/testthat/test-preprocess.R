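# small helper: wrap a plain matrix as a SpectrumSet
as_set <- function(X, ppm) {
  n <- nrow(X)
  spectrum_set(X, ppm, data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    subject_id = sprintf("s%02d", seq_len(n)),
    class_id = rep("1", n), chemo_flag = FALSE))
}

test_that("reference alignment moves the TSP apex to 0 ppm", {
  grid <- test_grid(2048)
  sig <- list(singlet_signature("TSP", 0, base_log_concentration = 2))
  y_off <- simulate_spectrum(sig, grid = grid, seed = 1, global_shift = 0.02)
  y_ok <- simulate_spectrum(sig, grid = grid, seed = 1)
  set <- as_set(rbind(y_off, y_ok), grid)
  out <- reference_align(set)
  tgt <- which.min(abs(grid))
  for (i in 1:2) {
    win <- which(grid >= -0.25 & grid <= 0.25)
    expect_equal(win[which.max(out$intensities[i, win])], tgt)
  }
  # the already-aligned spectrum is untouched
  expect_identical(out$intensities[2, ], set$intensities[2, ])
  shifts <- out$log[[length(out$log)]]$params$shifts
  expect_equal(shifts[2], 0L)
})

test_that("spectra offset by exactly k grid points align identically", {
  grid <- test_grid(2048)
  sig <- list(singlet_signature("TSP", 0, base_log_concentration = 2),
              singlet_signature("formate", 8.46))
  y <- simulate_spectrum(sig, grid = grid, seed = 2)
  k <- 5L
  y_shift <- c(rep(y[1], k), y[seq_len(length(y) - k)])  # shift right by k
  set <- reference_align(as_set(rbind(y, y_shift), grid))
  # interiors must agree exactly (edges refilled by repetition)
  interior <- (k + 1):(length(y) - k)
  expect_equal(set$intensities[1, interior], set$intensities[2, interior],
               tolerance = 1e-12)
})

test_that("flat reference window warns and applies zero shift", {
  grid <- test_grid(512)
  X <- matrix(1, 1, length(grid))
  expect_warning(out <- reference_align(as_set(X, grid)), "no detectable")
  expect_identical(out$intensities, as_set(X, grid)$intensities)
})

test_that("baseline correction leaves a flat-baseline spectrum unchanged", {
  grid <- test_grid(2048)
  # compactly supported peaks on an exactly zero baseline
  y <- numeric(length(grid))
  for (ctr in c(8.46, 1.92)) {
    j <- which.min(abs(grid - ctr))
    y[(j - 3):(j + 3)] <- c(0.1, 0.4, 0.8, 1, 0.8, 0.4, 0.1)
  }
  out <- baseline_correct(as_set(rbind(y, y), grid), knot_spacing = 0.25)
  expect_lt(max(abs(out$intensities[1, ] - y)), 1e-6 * max(y))
})

test_that("baseline correction removes a known slowly varying curve", {
  grid <- test_grid(2048)
  y <- simulate_spectrum(list(singlet_signature("formate", 8.46,
                                                base_log_concentration = 2)),
                         grid = grid, seed = 4)
  curve <- 0.5 * sin(2 * pi * (grid - min(grid)) / diff(range(grid))) + 0.3
  out <- baseline_correct(as_set(rbind(y + curve, y + curve), grid),
                          knot_spacing = 0.25)
  peak_free <- abs(grid - 8.46) > 0.3
  resid <- out$intensities[1, peak_free] - y[peak_free]
  expect_lt(sqrt(mean(resid^2)), 0.05 * sqrt(mean(curve^2)))
})

test_that("baseline correction recenters pure noise around zero", {
  grid <- test_grid(2048)
  set.seed(6)
  y <- stats::rnorm(length(grid), mean = 5, sd = 0.1)
  out <- baseline_correct(as_set(rbind(y, y), grid), knot_spacing = 0.5)
  expect_lt(abs(mean(out$intensities[1, ])),
            5 * 0.1 / sqrt(length(grid)) + 0.02)
  expect_error(baseline_correct(as_set(rbind(y, y), grid),
                                knot_spacing = 20), "wider")
})

test_that("region exclusion removes exactly the configured columns", {
  grid <- test_grid(2048)
  set <- as_set(matrix(stats::rnorm(2 * length(grid)), 2), grid)
  out <- exclude_regions(set)
  expect_false(any(out$ppm >= 4.49 & out$ppm <= 5.89))
  expect_false(any(out$ppm < 0.14))
  mask <- (grid >= 4.49 & grid <= 5.89) | grid <= 0.14
  expect_equal(ncol(out$intensities), length(grid) - sum(mask))
  # empty exclusion list is the identity
  cfg0 <- preprocess_config(exclusion_regions = list())
  out0 <- exclude_regions(set, cfg0)
  expect_identical(out0$intensities, set$intensities)
  cfg_all <- preprocess_config(exclusion_regions = list(c(-1, 11)))
  expect_error(exclude_regions(set, cfg_all), "every column")
})

test_that("segmental alignment recovers known integer displacements", {
  grid <- test_grid(2048)
  base <- simulate_spectrum(list(singlet_signature("succinate", 2.41),
                                 singlet_signature("citrate", 2.54)),
                            grid = grid, seed = 7)
  X <- rbind(base, base, base)
  seg_cols <- which(grid >= 2.35 & grid <= 2.75)
  # displace the third spectrum's segment by +3 points
  X[3, seg_cols] <- nmrfield:::shift_vector(X[3, seg_cols], 3L)
  cfg <- preprocess_config(alignment_segments = list(c(2.35, 2.75)),
                           max_segment_shift = 10)
  out <- segmental_align(as_set(X, grid), cfg)
  shifts <- out$log[[length(out$log)]]$params$shifts[[1]]
  expect_equal(shifts, c(0L, 0L, -3L))
  interior <- seg_cols[5:(length(seg_cols) - 5)]
  expect_equal(out$intensities[3, interior], base[interior],
               tolerance = 1e-12)
  # alignment never decreases the correlation with the mean target
  target <- colMeans(as_set(X, grid)$intensities)[seg_cols]
  for (i in 1:3) {
    expect_gte(stats::cor(out$intensities[i, seg_cols], target),
               stats::cor(X[i, seg_cols], target) - 1e-12)
  }
})

test_that("total-area normalization scales rows to unit sum", {
  ppm <- c(1, 2, 3)
  set <- as_set(rbind(c(1, 2, 3), c(0.2, 0.3, 0.5)), ppm)
  out <- total_area_normalize(set)
  expect_equal(out$intensities[1, ], c(1, 2, 3) / 6, tolerance = 1e-15,
               ignore_attr = TRUE)
  # idempotence on already-normalized rows
  expect_equal(out$intensities[2, ], c(0.2, 0.3, 0.5), tolerance = 1e-15,
               ignore_attr = TRUE)
  expect_true(all(abs(rowSums(out$intensities) - 1) < 1e-12))
  expect_error(total_area_normalize(as_set(rbind(c(0, 0, 0)), ppm)),
               "s01")
})

test_that("glog matches its defining formula and analytic properties", {
  # direct evaluation at y = y0
  expect_equal(glog(1e-7), log(sqrt(5e-4) / 2), tolerance = 1e-12)
  expect_equal(glog(1e-7), -4.49361, tolerance = 1e-5)
  # lambda -> 0 limit is the natural log
  expect_lt(abs(glog(1, y0 = 0, lambda = 1e-18) - log(1)), 1e-6)
  # strict monotonicity on random pairs
  set.seed(8)
  a <- stats::rnorm(500); b <- a + stats::runif(500, 1e-6, 2)
  expect_true(all(glog(b) > glog(a)))
  # analytic inverse round-trips
  y <- stats::runif(200, -0.5, 3)
  expect_equal(glog_inverse(glog(y)), y, tolerance = 1e-9)
  expect_error(glog(1, lambda = 0), "lambda")
})

test_that("mean centering returns reusable training means", {
  X <- cbind(c(1, 3), c(10, 30))
  cen <- mean_center(X)
  expect_equal(cen$centered[, 1], c(-1, 1))
  expect_equal(cen$means, c(2, 20))
  # centering twice equals centering once
  expect_equal(mean_center(cen$centered)$centered, cen$centered)
  # held-out rows use training means, not their own
  held <- matrix(c(5, 50), 1)
  expect_equal(mean_center(held, means = cen$means)$centered,
               matrix(c(3, 30), 1))
  expect_error(mean_center(matrix(1:3, 1)), ">= 2 rows")
})

test_that("the preprocessing chain is ordered, logged, and deterministic", {
  grid <- test_grid(1024)
  d <- two_class_design(4, 4, seed = 17)
  raw <- simulate_cohort(d, grid = grid)
  p1 <- preprocess(raw)
  p2 <- preprocess(raw)
  expect_identical(p1$intensities, p2$intensities)
  steps <- vapply(p1$log, `[[`, "", "step")
  expect_equal(steps, c("simulate", "reference_align", "baseline_correct",
                        "exclude_regions", "segmental_align",
                        "total_area_normalize", "glog_transform"))
  # normalize -> glog -> inverse-glog -> renormalize is the identity
  pre <- preprocess(raw, glog = FALSE)
  back <- glog_inverse(glog(pre$intensities))
  back <- back / rowSums(back)
  expect_equal(back, pre$intensities, tolerance = 1e-9)
})
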