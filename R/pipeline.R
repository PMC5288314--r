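#' Run one class-comparison model
#'
#' The dispatch rule of the study workflow: unpaired comparisons run
#' OSC-PLS-DA with scheme-by-size cross-validation and a 100-cycle
#' permutation test; comparisons marked paired run multilevel PLS-DA with
#' double cross-validation (20 repeats, max 3 latent variables) and a
#' 200-cycle within-subject permutation test.
#'
#' Before modelling, a PCA Q-residual screen (95% Jackson-Mudholkar limit)
#' excludes outlying spectra; exclusions are reported in the summary.
#'
#' @param set A preprocessed (glog-scale) `SpectrumSet`.
#' @param classes Length-2+ vector of class ids to compare.
#' @param paired Use the multilevel path (requires subjects present in all
#'   compared classes)?
#' @param n_osc OSC components for the unpaired path (default 1).
#' @param max_lv Maximum latent variables (default 3).
#' @param scheme CV scheme override (`"auto"`, `"venetian_blinds"`,
#'   `"leave_one_out"`); unpaired path only.
#' @param n_perm Permutation cycles (default 100 unpaired, 200 paired).
#' @param n_pca Components for the Q-residual screen (default 2).
#' @param screen Apply the Q-residual screen (default TRUE)?
#' @param seed Integer seed; mandatory.
#' @param out_dir If non-NULL, write `summary_<classes>.json`,
#'   `null_errors_<classes>.csv` and `scores_<classes>.csv` there.
#' @return List with `summary` (auroc/cver/p and metadata), `validation`
#'   (the `ValidationResult`), `permutation` and `excluded` sample ids.
#' @export
run_model_command <- function(set, classes, paired = FALSE, n_osc = 1,
                              max_lv = 3, scheme = "auto", n_perm = NULL,
                              n_pca = 2, screen = TRUE, seed,
                              out_dir = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  classes <- as.character(classes)
  keep <- set$metadata$class_id %in% classes
  if (!all(classes %in% set$metadata$class_id)) {
    stop("requested class(es) absent from data: ",
         paste(setdiff(classes, set$metadata$class_id), collapse = ", "),
         call. = FALSE)
  }
  sub <- set[which(keep), ]
  y <- sub$metadata$class_id
  excluded <- character(0)
  if (screen) {
    cen <- mean_center(sub$intensities)
    pca <- fit_pca(cen$centered, min(n_pca, nrow(cen$centered) - 1))
    scr <- q_residual_screen(pca, cen$centered)
    if (length(scr$excluded)) {
      excluded <- sub$metadata$sample_id[scr$excluded]
      sub <- sub[-scr$excluded, ]
      y <- sub$metadata$class_id
    }
  }
  X <- sub$intensities
  if (paired) {
    subj <- sub$metadata$subject_id
    in_all <- Reduce(intersect,
                     lapply(classes, function(cl) subj[y == cl]))
    if (length(in_all) == 0) {
      stop("paired model requested but no subject spans all classes",
           call. = FALSE)
    }
    rows <- which(subj %in% in_all)
    X <- X[rows, , drop = FALSE]; y <- y[rows]; subj <- subj[rows]
    if (is.null(n_perm)) n_perm <- 200
    val <- double_cross_validate(X, y, subj, n_repeats = 20,
                                 max_lv = max_lv, seed = seed)
    perm <- ml_permutation_test(X, y, subj, n_cycles = n_perm,
                                seed = seed + 1L, max_lv = max_lv,
                                observed = val)
  } else {
    if (is.null(n_perm)) n_perm <- 100
    val <- cross_validate(X, y, max_lv = max_lv, n_osc = n_osc,
                          scheme = scheme)
    perm <- permutation_test(X, y, n_cycles = n_perm, seed = seed + 1L,
                             max_lv = max_lv, n_osc = n_osc,
                             scheme = scheme, observed = val)
  }
  summary <- list(
    classes = classes, paired = paired, method = if (paired) "ML-PLS-DA"
              else "o-PLS-DA",
    n_samples = length(y), scheme = val$scheme, seed = seed,
    excluded_samples = as.list(excluded),
    chosen_n_lv = val$chosen_n_lv,
    cver = val$cver,
    auroc = as.list(val$auroc_per_class),
    empirical_p = perm$empirical_p,
    per_class_p = if (is.null(perm$per_class_p)) NULL
                  else as.list(perm$per_class_p),
    n_permutations = perm$n_cycles
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    tag <- paste(classes, collapse = "v")
    jsonlite::write_json(summary,
                         file.path(out_dir, paste0("summary_", tag, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    utils::write.csv(data.frame(null_error = perm$null_errors),
                     file.path(out_dir, paste0("null_errors_", tag, ".csv")),
                     row.names = FALSE)
    sc <- data.frame(sample_id = rownames(X), class_id = y,
                     val$cv_scores, check.names = FALSE)
    utils::write.csv(sc,
                     file.path(out_dir, paste0("scores_", tag, ".csv")),
                     row.names = FALSE)
  }
  list(summary = summary, validation = val, permutation = perm,
       excluded = excluded)
}

#' Univariate comparison over a preprocessed cohort
#'
#' Tracks the configured metabolite reference peaks on the normalized,
#' pre-glog matrix and runs the Shapiro-gated decision tree for one class
#' pair.
#'
#' @param set_pre_glog A preprocessed `SpectrumSet` *without* the glog step
#'   (`preprocess(..., glog = FALSE)`).
#' @param class_pair Length-2 vector of class ids.
#' @param targets Named ppm vector (default: the packaged library's
#'   reference peaks).
#' @param window Search half-window, ppm (default 0.03).
#' @param paired Paired comparison by subject?
#' @return List with `peaks` (`PeakTable`), `results`
#'   (`UnivariateResult`) and `fold_changes`.
#' @export
run_univariate_command <- function(set_pre_glog, class_pair,
                                   targets = NULL, window = 0.03,
                                   paired = FALSE) {
  if (is.null(targets)) {
    targets <- library_reference_peaks(default_metabolite_library())
    targets <- targets[targets >= min(set_pre_glog$ppm) &
                         targets <= max(set_pre_glog$ppm)]
  }
  refs <- pick_reference_peaks(set_pre_glog, targets, window)
  peaks <- track_peaks(set_pre_glog, refs, window)
  list(peaks = peaks,
       results = compare_classes(peaks, class_pair, paired = paired),
       fold_changes = fold_changes(peaks, class_pair))
}

#' Collate model summaries into one overview table
#'
#' The machine analogue of a study overview figure: one row per class
#' comparison with its AUROC, cross-validated error rate and permutation
#' p-value(s).
#'
#' @param results List of outputs of [run_model_command()].
#' @return Data frame with one row per comparison.
#' @export
report_comparisons <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    s <- r$summary
    data.frame(
      comparison = paste(s$classes, collapse = " vs "),
      method = s$method, n = s$n_samples, scheme = s$scheme,
      cver = s$cver,
      auroc = paste(sprintf("%.2f", unlist(s$auroc)), collapse = "/"),
      empirical_p = s$empirical_p,
      per_class_p = if (is.null(s$per_class_p)) NA_character_
                    else paste(sprintf("%.3f", unlist(s$per_class_p)),
                               collapse = "/"),
      n_excluded = length(s$excluded_samples),
      stringsAsFactors = FALSE)
  }))
}
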