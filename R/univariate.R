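#' Pick one reference peak per metabolite in the first spectrum
#'
#' For each metabolite target, records the ppm of the intensity maximum
#' within `window` of the target in the first spectrum of the set. A target
#' is flagged unresolved when the apex of another listed metabolite, at
#' least as intense, lies inside its window.
#'
#' @param set A `SpectrumSet` (normalized, pre-glog scale).
#' @param targets Named numeric vector of nominal ppm positions.
#' @param window Half-width of the search window, ppm (default 0.03).
#' @return Data frame: `metabolite`, `target_ppm`, `reference_ppm`,
#'   `intensity`, `unresolved`.
#' @export
pick_reference_peaks <- function(set, targets, window = 0.03) {
  ppm <- set$ppm
  first <- set$intensities[1, ]
  out <- data.frame(metabolite = names(targets),
                    target_ppm = as.numeric(targets),
                    reference_ppm = NA_real_, intensity = NA_real_,
                    unresolved = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    cols <- which(abs(ppm - out$target_ppm[i]) <= window)
    if (length(cols) == 0) {
      stop("no grid points within the window of ", out$metabolite[i],
           call. = FALSE)
    }
    j <- cols[which.max(first[cols])]
    out$reference_ppm[i] <- ppm[j]
    out$intensity[i] <- first[j]
  }
  for (i in seq_len(nrow(out))) {
    others <- out[-i, , drop = FALSE]
    clash <- abs(others$reference_ppm - out$target_ppm[i]) <= window &
      others$intensity >= out$intensity[i]
    if (any(clash)) out$unresolved[i] <- TRUE
  }
  out
}

#' Track reference peaks across all spectra
#'
#' Picks, for every spectrum and metabolite, the intensity maximum within
#' `window` of the reference ppm. Picks whose intensity is below five times
#' the spectrum's noise level (estimated from the median absolute
#' first difference) are flagged low-prominence, never dropped.
#'
#' @param set A `SpectrumSet` (normalized, pre-glog scale).
#' @param references Data frame from [pick_reference_peaks()] (or a named
#'   ppm vector).
#' @param window Half-width of the search window, ppm; 0 picks the single
#'   grid point nearest the reference.
#' @return An object of class `PeakTable`: `metabolites`, `reference_ppm`,
#'   `window`, `intensity` (samples x metabolites), `picked_ppm`,
#'   `low_prominence` (logical matrices), `metadata`.
#' @export
track_peaks <- function(set, references, window = 0.03) {
  if (is.data.frame(references)) {
    refs <- stats::setNames(references$reference_ppm, references$metabolite)
  } else {
    refs <- references
  }
  ppm <- set$ppm
  n <- nrow(set$intensities)
  m <- length(refs)
  intensity <- picked <- matrix(NA_real_, n, m,
                                dimnames = list(set$metadata$sample_id,
                                                names(refs)))
  flag <- matrix(FALSE, n, m, dimnames = dimnames(intensity))
  for (j in seq_len(m)) {
    cols <- which(abs(ppm - refs[j]) <= window)
    if (length(cols) == 0) cols <- ppm_index(ppm, refs[j])
    for (i in seq_len(n)) {
      y <- set$intensities[i, cols]
      k <- which.max(y)
      intensity[i, j] <- y[k]
      picked[i, j] <- ppm[cols[k]]
    }
  }
  noise <- apply(set$intensities, 1, function(y) {
    stats::median(abs(diff(y))) / sqrt(2)
  })
  flag[] <- intensity < 5 * noise
  structure(
    list(metabolites = names(refs), reference_ppm = refs, window = window,
         intensity = intensity, picked_ppm = picked, low_prominence = flag,
         metadata = set$metadata),
    class = "PeakTable"
  )
}

#' Select the significance test from the normality gate
#'
#' The four-way decision tree: unpaired data use Welch's t-test when both
#' groups pass the Shapiro-Wilk normality test (p >= 0.05 for each),
#' otherwise the Wilcoxon rank-sum test; paired data use the paired t-test
#' when the differences pass Shapiro-Wilk, otherwise the Wilcoxon
#' signed-rank test.
#'
#' @param paired Logical.
#' @param shapiro_p Shapiro-Wilk p-values: two (one per group) when
#'   unpaired, one (for the within-pair differences) when paired.
#' @param cutoff Normality cutoff (default 0.05).
#' @return One of `"welch"`, `"wilcoxon_rank_sum"`, `"paired_t"`,
#'   `"wilcoxon_signed_rank"`.
#' @export
select_test <- function(paired, shapiro_p, cutoff = 0.05) {
  if (paired) {
    if (length(shapiro_p) != 1) {
      stop("paired branch expects one Shapiro p (for the differences)",
           call. = FALSE)
    }
    if (shapiro_p >= cutoff) "paired_t" else "wilcoxon_signed_rank"
  } else {
    if (length(shapiro_p) != 2) {
      stop("unpaired branch expects two Shapiro p-values", call. = FALSE)
    }
    if (all(shapiro_p >= cutoff)) "welch" else "wilcoxon_rank_sum"
  }
}

# significance tier labels used in reporting
p_tier <- function(p) {
  ifelse(p < 5e-4, "p<.0005",
         ifelse(p < 5e-3, "p<.005",
                ifelse(p < 0.05, "p<.05", "ns")))
}

# Shapiro-Wilk p, tolerating degenerate (constant) samples, which are
# maximally non-normal: treated as rejecting normality
safe_shapiro_p <- function(x) {
  if (stats::sd(x) == 0) return(0)
  stats::shapiro.test(x)$p.value
}

#' Compare two tissue classes metabolite by metabolite
#'
#' For each tracked metabolite: Shapiro-Wilk normality gate, test selection
#' via [select_test()], p-value, direction (sign of the mean difference,
#' second class minus first) and significance tier. A Benjamini-Hochberg
#' adjusted column (`p_adjust_bh`) is emitted alongside the raw tiers as an
#' extension.
#'
#' @param table A `PeakTable`.
#' @param class_pair Length-2 vector of class ids; direction "up" means
#'   elevated in the second class.
#' @param paired Match samples by `subject_id` and use the paired branch?
#' @return Data frame of class `UnivariateResult` rows: metabolite,
#'   class_pair, paired, shapiro p-values, test_used, p_value, direction,
#'   group means and SDs, tier, p_adjust_bh.
#' @export
compare_classes <- function(table, class_pair, paired = FALSE) {
  stopifnot(inherits(table, "PeakTable"), length(class_pair) == 2)
  md <- table$metadata
  cls <- as.character(class_pair)
  rows_a <- which(md$class_id == cls[1])
  rows_b <- which(md$class_id == cls[2])
  if (length(rows_a) == 0 || length(rows_b) == 0) {
    stop("both classes must be present in the peak table", call. = FALSE)
  }
  if (paired) {
    common <- intersect(md$subject_id[rows_a], md$subject_id[rows_b])
    if (length(common) == 0) stop("no paired subjects between classes",
                                  call. = FALSE)
    rows_a <- rows_a[match(common, md$subject_id[rows_a])]
    rows_b <- rows_b[match(common, md$subject_id[rows_b])]
  }
  if (length(rows_a) < 3 || length(rows_b) < 3) {
    stop("group size < 3: Shapiro-Wilk test undefined", call. = FALSE)
  }
  res <- lapply(table$metabolites, function(met) {
    a <- table$intensity[rows_a, met]
    b <- table$intensity[rows_b, met]
    if (paired) {
      d <- b - a
      sp <- safe_shapiro_p(d)
      test <- select_test(TRUE, sp)
      p <- if (test == "paired_t") {
        stats::t.test(b, a, paired = TRUE)$p.value
      } else {
        stats::wilcox.test(b, a, paired = TRUE, exact = FALSE)$p.value
      }
      sp_a <- sp_b <- sp
    } else {
      sp_a <- safe_shapiro_p(a); sp_b <- safe_shapiro_p(b)
      test <- select_test(FALSE, c(sp_a, sp_b))
      p <- if (test == "welch") {
        stats::t.test(b, a, var.equal = FALSE)$p.value
      } else {
        stats::wilcox.test(b, a, exact = FALSE)$p.value
      }
    }
    if (is.na(p)) p <- 1   # identical groups: no evidence against the null
    data.frame(metabolite = met,
               class_a = cls[1], class_b = cls[2], paired = paired,
               shapiro_p_a = sp_a, shapiro_p_b = sp_b, test_used = test,
               p_value = p,
               direction = if (mean(b) >= mean(a)) "up" else "down",
               mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               tier = p_tier(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjust_bh <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("UnivariateResult", class(out))
  out
}

#' Fold changes between two classes
#'
#' Ratio of class mean peak intensities (second class over first), with the
#' group means and SDs attached. Ratios with a non-positive mean are
#' returned as NA with `undefined_ratio = TRUE`.
#'
#' @inheritParams compare_classes
#' @return Data frame: metabolite, mean/SD per class, `fold_change`,
#'   `undefined_ratio`.
#' @export
fold_changes <- function(table, class_pair) {
  stopifnot(inherits(table, "PeakTable"), length(class_pair) == 2)
  md <- table$metadata
  cls <- as.character(class_pair)
  rows_a <- which(md$class_id == cls[1])
  rows_b <- which(md$class_id == cls[2])
  out <- lapply(table$metabolites, function(met) {
    a <- table$intensity[rows_a, met]; b <- table$intensity[rows_b, met]
    bad <- mean(a) <= 0 || mean(b) <= 0
    data.frame(metabolite = met, class_a = cls[1], class_b = cls[2],
               mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               fold_change = if (bad) NA_real_ else mean(b) / mean(a),
               undefined_ratio = bad, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
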