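#' Principal component analysis with Q-residual screening
#'
#' Fits PCA by singular value decomposition of a column-centered matrix.
#' The model retains all singular values so that the Jackson-Mudholkar
#' Q-residual confidence limit can be computed from the discarded
#' eigenvalue spectrum.
#'
#' @param X Numeric matrix, already column-centered.
#' @param n_components Number of components to retain.
#' @return An object of class `PcaModel` with `scores`, `loadings`,
#'   `explained_variance_fraction`, `singular_values`, `q_residuals` and
#'   `q_limit` (95% Jackson-Mudholkar approximation).
#' @export
fit_pca <- function(X, n_components) {
  X <- as.matrix(X)
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  if (n_components > min(nrow(X) - 1, ncol(X))) {
    stop("n_components exceeds min(rows - 1, cols)", call. = FALSE)
  }
  sv <- svd(X)
  k <- n_components
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  evf <- sv$d^2 / sum(sv$d^2)
  resid <- X - scores %*% t(loadings)
  q <- rowSums(resid^2)
  model <- structure(
    list(n_components = k, scores = scores, loadings = loadings,
         explained_variance_fraction = evf[seq_len(k)],
         singular_values = sv$d, n_samples = nrow(X),
         q_residuals = q, q_limit = NA_real_),
    class = "PcaModel"
  )
  model$q_limit <- jackson_mudholkar_limit(model)
  model
}

# 95% Q-residual limit from the residual eigenvalue spectrum
# (Jackson & Mudholkar approximation)
jackson_mudholkar_limit <- function(model, alpha = 0.05) {
  ev <- model$singular_values^2 / (model$n_samples - 1)
  resid_ev <- ev[-seq_len(model$n_components)]
  resid_ev <- resid_ev[resid_ev > .Machine$double.eps * max(ev)]
  if (length(resid_ev) == 0) return(Inf)
  th1 <- sum(resid_ev); th2 <- sum(resid_ev^2); th3 <- sum(resid_ev^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 <= 0) h0 <- 1e-3
  ca <- stats::qnorm(1 - alpha)
  # per-observation residual sum of squares scale: the variance of each
  # residual score equals the corresponding covariance eigenvalue
  th1 * (ca * sqrt(2 * th2 * h0^2) / th1 +
           1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

#' Screen samples by Q-residual
#'
#' Computes each sample's squared reconstruction residual against a fitted
#' PCA model and flags samples exceeding the 95% Jackson-Mudholkar limit
#' for exclusion. Exclusions are reported, never applied silently.
#'
#' @param model A `PcaModel`.
#' @param X The (centered) matrix the model was fitted on, or new data in
#'   the same column space.
#' @param q_limit Override for the exclusion limit (default: the model's).
#' @return List with `q` (per-sample residuals) and `excluded` (row indices
#'   with `q > q_limit`).
#' @export
q_residual_screen <- function(model, X, q_limit = model$q_limit) {
  X <- as.matrix(X)
  P <- model$loadings
  resid <- X - X %*% P %*% t(P)
  q <- rowSums(resid^2)
  list(q = q, excluded = which(q > q_limit), q_limit = q_limit)
}

#' @export
print.PcaModel <- function(x, ...) {
  cat(sprintf("PcaModel: %d components, %.1f%% variance explained\n",
              x$n_components, 100 * sum(x$explained_variance_fraction)))
  invisible(x)
}
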