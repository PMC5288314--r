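#' Class-target encoding for PLS-DA
#'
#' Two classes are coded as a single +/-1 column (lexicographically first
#' class -> -1); three or more classes as a one-hot matrix. Targets are the
#' values continuous predictions are compared against when assigning classes.
#'
#' @param y Vector of class labels (2+ distinct values).
#' @return List with `Y` (target matrix), `classes` (sorted labels) and
#'   `targets` (classes x columns matrix of target values).
#' @keywords internal
encode_classes <- function(y) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("y must contain >= 2 classes", call. = FALSE)
  if (length(classes) == 2) {
    Y <- matrix(ifelse(y == classes[2], 1, -1), ncol = 1)
    targets <- matrix(c(-1, 1), ncol = 1, dimnames = list(classes, NULL))
  } else {
    Y <- outer(y, classes, `==`) * 1
    targets <- diag(length(classes))
    dimnames(targets) <- list(classes, NULL)
  }
  list(Y = Y, classes = classes, targets = targets)
}

#' Orthogonal signal correction (Wold's NIPALS-OSC)
#'
#' Removes from a centered matrix up to `n_osc` components of large spectral
#' variation whose scores are orthogonal to the class targets. Weights and
#' loadings are stored so the same filter can be applied to held-out rows.
#'
#' @param X Centered numeric matrix.
#' @param y Class labels (or an encoded target matrix).
#' @param n_osc Number of components to remove (0 = identity).
#' @param max_iter,tol NIPALS convergence controls.
#' @return List with `X_filtered`, `weights`, `loadings`, `scores`
#'   (each a column per removed component).
#' @export
osc_filter <- function(X, y, n_osc = 1, max_iter = 50, tol = 1e-10) {
  X <- as.matrix(X)
  if (n_osc < 0) stop("n_osc must be >= 0", call. = FALSE)
  if (n_osc >= min(nrow(X), ncol(X))) {
    stop("n_osc must be smaller than rank(X)", call. = FALSE)
  }
  Y <- if (is.matrix(y)) y else encode_classes(y)$Y
  W <- P <- Tm <- NULL
  if (n_osc > 0) {
    # projector removing the part of a score explainable by the targets
    YtYinv <- solve(crossprod(Y))
    orth_y <- function(t) t - Y %*% (YtYinv %*% crossprod(Y, t))
    for (comp in seq_len(n_osc)) {
      # first principal score via the (small) n x n Gram matrix
      eg <- eigen(tcrossprod(X), symmetric = TRUE)
      t <- eg$vectors[, 1, drop = FALSE] * sqrt(max(eg$values[1], 0))
      w <- NULL
      for (it in seq_len(max_iter)) {
        t_star <- orth_y(t)
        w <- crossprod(X, t_star) / drop(crossprod(t_star))
        w <- w / sqrt(drop(crossprod(w)))
        t_new <- X %*% w
        if (sqrt(drop(crossprod(t_new - t))) <
            tol * sqrt(drop(crossprod(t_new)))) { t <- t_new; break }
        t <- t_new
      }
      t_star <- orth_y(t)                   # exactly orthogonal to targets
      p <- crossprod(X, t_star) / drop(crossprod(t_star))
      X <- X - t_star %*% t(p)
      W <- cbind(W, w); P <- cbind(P, p); Tm <- cbind(Tm, t_star)
    }
  }
  list(X_filtered = X, weights = W, loadings = P, scores = Tm)
}

# apply a fitted OSC filter to new (already centered) rows
osc_apply <- function(X_new, weights, loadings) {
  if (is.null(weights)) return(X_new)
  for (k in seq_len(ncol(weights))) {
    t_new <- X_new %*% weights[, k, drop = FALSE]
    X_new <- X_new - t_new %*% t(loadings[, k, drop = FALSE])
  }
  X_new
}

#' Fit a PLS-DA model by NIPALS
#'
#' NIPALS partial least squares regression of class targets on a (filtered,
#' centered) spectral matrix: PLS1 for two classes (+/-1 coding), PLS2 for
#' one-hot multi-class targets. X is deflated per latent variable and Y is
#' deflated in the PLS2 case, so the regression vector reproduces the
#' training predictions exactly.
#'
#' @param X Centered (and optionally OSC-filtered) matrix.
#' @param y Class labels.
#' @param n_lv Number of latent variables.
#' @param x_means,y_means Optional training means already removed from X and
#'   the target matrix (stored for prediction).
#' @param osc Optional fitted OSC filter (from [osc_filter()]) to apply to
#'   new data at prediction time.
#' @param max_iter,tol NIPALS convergence controls (PLS2 only).
#' @return An object of class `PlsdaModel`.
#' @export
fit_plsda <- function(X, y, n_lv, x_means = NULL, y_means = NULL,
                      osc = NULL, max_iter = 200, tol = 1e-10) {
  X <- as.matrix(X)
  enc <- encode_classes(y)
  if (n_lv < 1) stop("n_lv must be >= 1", call. = FALSE)
  if (n_lv > min(dim(X))) stop("n_lv exceeds rank bound", call. = FALSE)
  if (is.null(y_means)) y_means <- rep(0, ncol(enc$Y))
  Y <- sweep(enc$Y, 2, y_means)
  Xd <- X; Yd <- Y
  W <- P <- Tm <- Q <- NULL
  for (a in seq_len(n_lv)) {
    if (ncol(Yd) == 1) {
      w <- crossprod(Xd, Yd)
      nw <- sqrt(drop(crossprod(w)))
      if (nw < 1e-300) break
      w <- w / nw
      t <- Xd %*% w
    } else {
      u <- Yd[, which.max(colSums(Yd^2)), drop = FALSE]
      w <- t <- NULL
      for (it in seq_len(max_iter)) {
        w <- crossprod(Xd, u) / drop(crossprod(u))
        w <- w / sqrt(drop(crossprod(w)))
        t <- Xd %*% w
        q <- crossprod(Yd, t) / drop(crossprod(t))
        u_new <- Yd %*% q / drop(crossprod(q))
        if (sqrt(drop(crossprod(u_new - u))) <
            tol * sqrt(drop(crossprod(u_new)))) { u <- u_new; break }
        u <- u_new
      }
    }
    tt <- drop(crossprod(t))
    if (tt < 1e-300) break
    p <- crossprod(Xd, t) / tt
    q <- crossprod(Yd, t) / tt
    Xd <- Xd - t %*% t(p)
    Yd <- Yd - t %*% t(q)
    W <- cbind(W, w); P <- cbind(P, p); Tm <- cbind(Tm, t); Q <- cbind(Q, q)
  }
  structure(
    list(n_latent_variables = ncol(W),
         n_osc_components = if (is.null(osc$weights)) 0L
                            else ncol(osc$weights),
         osc = osc,
         x_weights = W, x_scores = Tm, x_loadings = P, y_loadings = Q,
         regression_vector = pls_regression_vector(W, P, Q, ncol(W)),
         class_encoding = enc, x_means = x_means, y_means = y_means),
    class = "PlsdaModel"
  )
}

# B_a = W_a (P_a' W_a)^{-1} Q_a' using the first a latent variables
pls_regression_vector <- function(W, P, Q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  Qa <- Q[, seq_len(a), drop = FALSE]
  Wa %*% solve(crossprod(Pa, Wa), t(Qa))
}

#' Fit centering + OSC + PLS-DA in one step
#'
#' The supervised modelling chain applied to glog-transformed spectra:
#' mean-center the x-block, remove `n_osc` orthogonal components, fit
#' PLS-DA. All three are fitted here so the returned model can be applied
#' to held-out rows without information leakage.
#'
#' @param X Unfiltered (glog) matrix.
#' @param y Class labels.
#' @param n_lv Latent variables.
#' @param n_osc Orthogonal components to remove (default 1).
#' @return A `PlsdaModel` carrying centering means and the OSC filter.
#' @export
fit_oplsda <- function(X, y, n_lv, n_osc = 1) {
  cen <- mean_center(X)
  enc <- encode_classes(y)
  y_means <- colMeans(enc$Y)
  osc <- if (n_osc > 0) osc_filter(cen$centered, sweep(enc$Y, 2, y_means),
                                   n_osc = n_osc)
         else list(X_filtered = cen$centered, weights = NULL, loadings = NULL)
  fit_plsda(osc$X_filtered, y, n_lv, x_means = cen$means, y_means = y_means,
            osc = osc[c("weights", "loadings")])
}

#' Predict classes for new spectra
#'
#' Centers new rows with the *training* means, applies the stored OSC
#' filter, projects through the regression vector and assigns each sample
#' to the nearest class target (sign for two classes, arg-max for one-hot).
#' Exact ties are broken toward the lexicographically first class.
#'
#' @param object A `PlsdaModel`.
#' @param X_new Matrix with the training column count.
#' @param n_lv Number of latent variables to use (default: all fitted).
#' @param ... Ignored.
#' @return List with `scores` (continuous predictions, targets scale) and
#'   `class` (character vector of assignments).
#' @export
predict.PlsdaModel <- function(object, X_new, n_lv = NULL, ...) {
  X_new <- as.matrix(X_new)
  p_train <- nrow(object$regression_vector)
  if (ncol(X_new) != p_train) {
    stop("X_new has ", ncol(X_new), " columns; model expects ", p_train,
         call. = FALSE)
  }
  if (!is.null(object$x_means)) X_new <- sweep(X_new, 2, object$x_means)
  if (!is.null(object$osc$weights)) {
    X_new <- osc_apply(X_new, object$osc$weights, object$osc$loadings)
  }
  a <- if (is.null(n_lv)) object$n_latent_variables
       else min(n_lv, object$n_latent_variables)
  B <- if (a == object$n_latent_variables) object$regression_vector
       else pls_regression_vector(object$x_weights, object$x_loadings,
                                  object$y_loadings, a)
  scores <- sweep(X_new %*% B, 2, object$y_means, `+`)
  list(scores = scores, class = assign_classes(scores, object$class_encoding))
}

# nearest-target class assignment; ties to the lexicographically first class
assign_classes <- function(scores, encoding) {
  targets <- encoding$targets
  cls <- character(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    d <- colSums((t(targets) - scores[i, ])^2)
    cls[i] <- encoding$classes[which.min(d)]   # which.min takes first on tie
  }
  cls
}

#' @export
print.PlsdaModel <- function(x, ...) {
  cat(sprintf("PlsdaModel: %d latent variable(s), %d OSC component(s), %d classes\n",
              x$n_latent_variables, x$n_osc_components,
              length(x$class_encoding$classes)))
  invisible(x)
}

#' Multilevel (between/within-subject) decomposition
#'
#' Splits a paired-design matrix into the subject-mean (between) part and
#' the deviation-from-subject-mean (within) part:
#' `X = grand_mean + between + within`. Multilevel PLS-DA is ordinary
#' PLS-DA fitted on the within part, isolating the paired within-subject
#' effect from between-subject variability.
#'
#' @param X Numeric matrix, one row per sample.
#' @param subject_ids Subject identifier per row; every subject needs at
#'   least two samples.
#' @return An object of class `MultilevelSplit` with `grand_mean`,
#'   `between_matrix`, `within_matrix`.
#' @export
multilevel_split <- function(X, subject_ids) {
  X <- as.matrix(X)
  subject_ids <- as.character(subject_ids)
  counts <- table(subject_ids)
  singletons <- names(counts)[counts < 2]
  if (length(singletons)) {
    stop("subject(s) with a single sample: ",
         paste(singletons, collapse = ", "), call. = FALSE)
  }
  grand <- colMeans(X)
  rs <- rowsum(X, subject_ids)
  rs <- rs / as.vector(counts[rownames(rs)])
  subj_means <- rs[subject_ids, , drop = FALSE]
  structure(
    list(grand_mean = grand,
         between_matrix = sweep(subj_means, 2, grand),
         within_matrix = X - subj_means,
         subject_ids = subject_ids),
    class = "MultilevelSplit"
  )
}
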