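#' Choose the cross-validation scheme by model size
#'
#' Leave-one-out for models with 20 or fewer spectra, interleaved
#' Venetian-blinds folds otherwise.
#'
#' @param n_samples Number of spectra in the model.
#' @return `"leave_one_out"` or `"venetian_blinds"`.
#' @export
choose_scheme <- function(n_samples) {
  if (n_samples < 3) stop("need at least 3 samples", call. = FALSE)
  if (n_samples <= 20) "leave_one_out" else "venetian_blinds"
}

# Rotate a wide matrix (p > n) into its n-dimensional row space: X = U D V'
# becomes A = U D. Every modelling step downstream (centering, OSC, PLS,
# prediction for held-out rows of the same matrix) is linear on the row
# space, so cross-validation on A yields identical predictions at a
# fraction of the cost.
compress_rows <- function(X) {
  if (ncol(X) <= nrow(X)) return(X)
  sv <- svd(X, nv = 0)
  sv$u %*% diag(sv$d, length(sv$d))
}

# fold assignment: venetian blinds interleaves samples over class-sorted
# order (sample i -> fold i mod n_folds); LOO gives one fold per sample
make_folds <- function(y, scheme, n_folds = NULL) {
  n <- length(y)
  if (scheme == "leave_one_out") return(split(seq_len(n), seq_len(n)))
  if (is.null(n_folds)) n_folds <- min(10L, n %/% 3L)
  ord <- order(as.character(y))           # stable class-sorted order
  fold_id <- integer(n)
  fold_id[ord] <- ((seq_len(n) - 1L) %% n_folds) + 1L
  split(seq_len(n), fold_id)
}

#' Cross-validated error rate
#'
#' @param class_predictions,labels Equal-length vectors.
#' @return Fraction misclassified.
#' @export
cver <- function(class_predictions, labels) {
  if (length(class_predictions) == 0) stop("empty input", call. = FALSE)
  if (length(class_predictions) != length(labels)) {
    stop("length mismatch", call. = FALSE)
  }
  mean(as.character(class_predictions) != as.character(labels))
}

#' Area under the receiver-operator curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' sample scores higher than a randomly chosen negative one, ties counting
#' one half. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores Continuous predictions.
#' @param positive Logical (or two-level) vector marking the positive class.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, positive) {
  positive <- as.logical(positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)   # midranks handle ties
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cross-validate an OSC-PLS-DA model
#'
#' Runs the full modelling chain (training-fold centering, OSC, PLS-DA)
#' under the selected scheme, computes the error rate at each number of
#' latent variables, and keeps the fewest latent variables minimizing it.
#'
#' @param X Numeric matrix (glog scale, not centered: centering is fitted
#'   per training fold).
#' @param y Class labels.
#' @param max_lv Maximum latent variables to consider.
#' @param n_osc OSC components removed per training fold (default 1).
#' @param scheme `"auto"` (size rule), `"venetian_blinds"` or
#'   `"leave_one_out"`.
#' @param n_folds Venetian-blinds fold count; default `min(10, n %/% 3)`.
#' @param leaky If TRUE, centering and OSC are fitted once on the whole
#'   matrix before splitting (reproduces legacy whole-matrix filtering;
#'   default FALSE, leakage-free).
#' @return An object of class `ValidationResult`: `scheme`, `n_folds`,
#'   `per_lv_cver`, `chosen_n_lv`, `cv_scores`, `cv_class`, `cver`,
#'   `auroc_per_class`.
#' @export
cross_validate <- function(X, y, max_lv = 3, n_osc = 1, scheme = "auto",
                           n_folds = NULL, leaky = FALSE) {
  X <- compress_rows(as.matrix(X))
  y <- as.character(y)
  if (max_lv < 1) stop("max_lv must be >= 1", call. = FALSE)
  if (scheme == "auto") scheme <- choose_scheme(nrow(X))
  folds <- make_folds(y, scheme, n_folds)
  enc <- encode_classes(y)
  for (f in folds) {
    if (length(unique(y[-f])) < length(enc$classes)) {
      stop("a training fold lacks a class; use fewer folds", call. = FALSE)
    }
  }
  if (leaky) {
    # whole-matrix centering + OSC, then CV of the PLS step only
    cen <- mean_center(X)
    Yc <- sweep(enc$Y, 2, colMeans(enc$Y))
    X <- if (n_osc > 0) osc_filter(cen$centered, Yc, n_osc)$X_filtered
         else cen$centered
  }
  n <- nrow(X)
  scores_by_lv <- replicate(max_lv,
                            matrix(NA_real_, n, ncol(enc$Y)),
                            simplify = FALSE)
  for (f in folds) {
    fit <- if (leaky) {
      fit_plsda(X[-f, , drop = FALSE], y[-f],
                n_lv = min(max_lv, min(length(y) - length(f), ncol(X))),
                x_means = rep(0, ncol(X)),
                y_means = colMeans(encode_classes(y[-f])$Y))
    } else {
      fit_oplsda(X[-f, , drop = FALSE], y[-f],
                 n_lv = min(max_lv, min(length(y) - length(f) - 1, ncol(X))),
                 n_osc = n_osc)
    }
    for (a in seq_len(max_lv)) {
      pr <- predict(fit, X[f, , drop = FALSE], n_lv = a)
      scores_by_lv[[a]][f, ] <- pr$scores
    }
  }
  per_lv <- vapply(scores_by_lv, function(s) {
    cver(assign_classes(s, enc), y)
  }, 0)
  chosen <- which.min(per_lv)               # smallest LV count on ties
  cv_scores <- scores_by_lv[[chosen]]
  cv_class <- assign_classes(cv_scores, enc)
  structure(
    list(scheme = scheme, n_folds = length(folds),
         per_lv_cver = per_lv, chosen_n_lv = chosen,
         cv_scores = cv_scores, cv_class = cv_class,
         cver = per_lv[chosen],
         auroc_per_class = per_class_auroc(cv_scores, y, enc),
         classes = enc$classes),
    class = "ValidationResult"
  )
}

# one-vs-rest AUROC per class from continuous CV predictions
per_class_auroc <- function(scores, y, enc) {
  out <- stats::setNames(numeric(length(enc$classes)), enc$classes)
  for (k in seq_along(enc$classes)) {
    cls <- enc$classes[k]
    s <- class_direction_scores(scores, enc, k)
    out[cls] <- auroc(s, y == cls)
  }
  out
}

# continuous score "toward class k": signed score for +/-1 coding,
# the class's own column for one-hot coding
class_direction_scores <- function(scores, enc, k) {
  if (length(enc$classes) == 2) {
    if (k == 2) scores[, 1] else -scores[, 1]
  } else {
    scores[, k]
  }
}

#' Permutation test of a cross-validated model
#'
#' Re-runs the full cross-validation under `n_cycles` seeded label
#' permutations, forming a null distribution of error rates. The empirical
#' p-value uses the add-one estimator `(k + 1) / (n + 1)` so it is never
#' zero. Per-class p-values compare each class's observed cross-validated
#' predictions with the pooled permuted predictions by one-sided two-sample
#' t-tests (reported alongside, as two p-values per two-class model).
#'
#' @inheritParams cross_validate
#' @param n_cycles Number of permutation cycles (>= 19 for usable p
#'   resolution; the study default is 100).
#' @param seed Integer seed driving all permutations.
#' @param observed Optional precomputed `ValidationResult` for the
#'   unpermuted labels (avoids refitting).
#' @return List with `n_cycles`, `null_errors`, `observed_error`,
#'   `empirical_p`, `per_class_p`, and the observed `result`.
#' @export
permutation_test <- function(X, y, n_cycles = 100, seed, max_lv = 3,
                             n_osc = 1, scheme = "auto", n_folds = NULL,
                             observed = NULL) {
  if (n_cycles < 19) {
    stop("n_cycles < 19 gives too coarse a p resolution", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  y <- as.character(y)
  X <- compress_rows(as.matrix(X))
  if (is.null(observed)) {
    observed <- cross_validate(X, y, max_lv = max_lv, n_osc = n_osc,
                               scheme = scheme, n_folds = n_folds)
  }
  enc <- encode_classes(y)
  null_errors <- numeric(n_cycles)
  null_scores <- vector("list", n_cycles)
  null_labels <- vector("list", n_cycles)
  set.seed(as.integer(seed))
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_cycles)
  for (b in seq_len(n_cycles)) {
    set.seed(perm_seeds[b])
    y_perm <- sample(y)
    res <- cross_validate(X, y_perm, max_lv = max_lv, n_osc = n_osc,
                          scheme = scheme, n_folds = n_folds)
    null_errors[b] <- res$cver
    null_scores[[b]] <- res$cv_scores
    null_labels[[b]] <- y_perm
  }
  empirical_p <- (sum(null_errors <= observed$cver) + 1) / (n_cycles + 1)
  per_class_p <- stats::setNames(numeric(length(enc$classes)), enc$classes)
  for (k in seq_along(enc$classes)) {
    cls <- enc$classes[k]
    obs_k <- class_direction_scores(observed$cv_scores, enc, k)[y == cls]
    null_k <- unlist(lapply(seq_len(n_cycles), function(b) {
      class_direction_scores(null_scores[[b]], enc, k)[null_labels[[b]] == cls]
    }))
    per_class_p[cls] <- stats::t.test(obs_k, null_k,
                                      alternative = "greater")$p.value
  }
  list(n_cycles = n_cycles, null_errors = null_errors,
       observed_error = observed$cver, empirical_p = empirical_p,
       per_class_p = per_class_p, result = observed)
}

#' Double cross-validation for multilevel PLS-DA
#'
#' Nested subject-wise cross-validation for paired designs: the outer loop
#' holds out all samples of one subject; the inner loop, over the remaining
#' subjects, selects the latent-variable count minimizing the inner error.
#' The whole procedure is repeated with reshuffled inner folds and the
#' reported error is the mean outer misclassification rate over repeats.
#' Models are fitted on the within-subject matrix ([multilevel_split()]);
#' held-out subjects are centered on their own subject mean, so no training
#' statistic touches them.
#'
#' @param X Numeric matrix (glog scale).
#' @param y Class labels, balanced within subject.
#' @param subject_ids Subject id per row; each subject needs >= 2 samples.
#' @param n_repeats Outer repetitions with reshuffled inner folds
#'   (default 20).
#' @param max_lv Maximum latent variables (default 3).
#' @param seed Integer seed for the inner-fold shuffles.
#' @param n_inner_folds Inner subject-fold count (default
#'   `min(7, n_subjects - 1)`).
#' @return A `ValidationResult` with mean outer error (`cver`), per-sample
#'   averaged continuous predictions (`cv_scores`), consensus class
#'   predictions and per-class AUROC.
#' @export
double_cross_validate <- function(X, y, subject_ids, n_repeats = 20,
                                  max_lv = 3, seed, n_inner_folds = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  X <- compress_rows(as.matrix(X)); y <- as.character(y)
  subject_ids <- as.character(subject_ids)
  subjects <- unique(subject_ids)
  if (length(subjects) < 4) stop("need at least 4 subjects", call. = FALSE)
  split0 <- multilevel_split(X, subject_ids)   # validates the pairing
  for (s in subjects) {
    if (length(unique(y[subject_ids == s])) < 2) {
      stop("subject ", s, " has a single class; paired design required",
           call. = FALSE)
    }
  }
  enc <- encode_classes(y)
  n <- nrow(X)
  if (is.null(n_inner_folds)) n_inner_folds <- min(7L, length(subjects) - 1L)
  set.seed(as.integer(seed))
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  score_sum <- matrix(0, n, ncol(enc$Y))
  err_sum <- 0
  for (r in seq_len(n_repeats)) {
    set.seed(repeat_seeds[r])
    scores_r <- matrix(NA_real_, n, ncol(enc$Y))
    for (s in subjects) {
      test_rows <- which(subject_ids == s)
      train_rows <- which(subject_ids != s)
      tr_subj <- subject_ids[train_rows]
      W_train <- multilevel_split(X[train_rows, , drop = FALSE], tr_subj)
      Xw_train <- W_train$within_matrix
      y_train <- y[train_rows]
      # within-part of the held-out subject: deviation from its own mean
      Xt <- X[test_rows, , drop = FALSE]
      Xw_test <- sweep(Xt, 2, colMeans(Xt))
      # inner loop: subject-wise folds select the latent-variable count
      uniq_tr <- unique(tr_subj)
      fold_of <- sample(rep(seq_len(n_inner_folds),
                            length.out = length(uniq_tr)))
      names(fold_of) <- uniq_tr
      inner_scores <- replicate(max_lv,
                                matrix(NA_real_, length(train_rows),
                                       ncol(enc$Y)),
                                simplify = FALSE)
      for (fi in seq_len(n_inner_folds)) {
        hold_subj <- uniq_tr[fold_of[uniq_tr] == fi]
        if (length(hold_subj) == 0) next
        hold <- which(tr_subj %in% hold_subj)
        fit_in <- fit_plsda_centered(Xw_train[-hold, , drop = FALSE],
                                     y_train[-hold],
                                     max_lv)
        Xin <- Xw_train[hold, , drop = FALSE]
        for (a in seq_len(max_lv)) {
          inner_scores[[a]][hold, ] <-
            predict(fit_in, Xin, n_lv = a)$scores
        }
      }
      inner_err <- vapply(inner_scores, function(sc) {
        cver(assign_classes(sc, enc), y_train)
      }, 0)
      best_lv <- which.min(inner_err)
      fit_out <- fit_plsda_centered(Xw_train, y_train, best_lv)
      scores_r[test_rows, ] <- predict(fit_out, Xw_test)$scores
    }
    err_sum <- err_sum + cver(assign_classes(scores_r, enc), y)
    score_sum <- score_sum + scores_r
  }
  cv_scores <- score_sum / n_repeats
  cv_class <- assign_classes(cv_scores, enc)
  structure(
    list(scheme = "leave_one_subject_out", n_folds = length(subjects),
         n_repeats = n_repeats, max_lv = max_lv,
         per_lv_cver = NULL, chosen_n_lv = NA_integer_,
         cv_scores = cv_scores, cv_class = cv_class,
         cver = err_sum / n_repeats,
         auroc_per_class = per_class_auroc(cv_scores, y, enc),
         classes = enc$classes),
    class = "ValidationResult"
  )
}

# centering fitted on the given rows, no OSC: the multilevel path
fit_plsda_centered <- function(X, y, n_lv) {
  cen <- mean_center(X)
  enc <- encode_classes(y)
  y_means <- colMeans(enc$Y)
  fit_plsda(cen$centered, y, min(n_lv, min(dim(X)) - 1),
            x_means = cen$means, y_means = y_means)
}

#' Permutation test for a multilevel model
#'
#' Permutes class labels *within subject* (each subject's labels are
#' randomly flipped), re-runs the double cross-validation, and forms the
#' null error distribution. Matches the exchangeability structure of a
#' paired design.
#'
#' @inheritParams double_cross_validate
#' @param n_cycles Permutation cycles (study default 200 for multilevel
#'   models).
#' @param n_repeats_null Double-CV repeats used inside each permutation
#'   cycle (default 1: the null error is averaged over cycles anyway).
#' @param observed Optional precomputed observed `ValidationResult`.
#' @return As [permutation_test()], without per-class t-tests (the paired
#'   model reports the single empirical p).
#' @export
ml_permutation_test <- function(X, y, subject_ids, n_cycles = 200, seed,
                                n_repeats = 20, max_lv = 3,
                                n_repeats_null = 1, observed = NULL) {
  if (n_cycles < 19) {
    stop("n_cycles < 19 gives too coarse a p resolution", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  y <- as.character(y); subject_ids <- as.character(subject_ids)
  X <- compress_rows(as.matrix(X))
  set.seed(as.integer(seed))
  cycle_seeds <- sample.int(.Machine$integer.max - 1L, n_cycles + 1L)
  if (is.null(observed)) {
    observed <- double_cross_validate(X, y, subject_ids,
                                      n_repeats = n_repeats, max_lv = max_lv,
                                      seed = cycle_seeds[n_cycles + 1L])
  }
  null_errors <- numeric(n_cycles)
  for (b in seq_len(n_cycles)) {
    set.seed(cycle_seeds[b])
    y_perm <- y
    for (s in unique(subject_ids)) {
      rows <- which(subject_ids == s)
      y_perm[rows] <- sample(y_perm[rows])
    }
    res <- double_cross_validate(X, y_perm, subject_ids,
                                 n_repeats = n_repeats_null, max_lv = max_lv,
                                 seed = cycle_seeds[b])
    null_errors[b] <- res$cver
  }
  empirical_p <- (sum(null_errors <= observed$cver) + 1) / (n_cycles + 1)
  list(n_cycles = n_cycles, null_errors = null_errors,
       observed_error = observed$cver, empirical_p = empirical_p,
       per_class_p = NULL, result = observed)
}

#' @export
print.ValidationResult <- function(x, ...) {
  cat(sprintf("ValidationResult: %s, CVER = %.3f\n", x$scheme, x$cver))
  cat("AUROC:", paste(sprintf("%s = %.3f", names(x$auroc_per_class),
                              x$auroc_per_class), collapse = ", "), "\n")
  invisible(x)
}
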