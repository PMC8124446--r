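#' Ridge-penalized Cox regression
#'
#' Maximizes the penalized partial log-likelihood
#' \eqn{\ell(\beta) - \lambda \|\beta\|^2 / 2} (Breslow tie handling) by
#' Newton iterations with step halving. Deterministic; at `lambda = 0` it
#' reduces to the unpenalized Cox fit.
#'
#' @param X numeric matrix, patients x genes.
#' @param time,status survival times (> 0) and event indicators (0/1).
#' @param lambda ridge penalty (>= 0).
#' @param beta_init optional warm start.
#' @param maxit,tol Newton iteration cap and convergence tolerance on the
#'   penalized log-likelihood.
#' @return list with `beta` (named), `loglik` (unpenalized partial
#'   log-likelihood at the optimum), `penalized_loglik`, `iter`,
#'   `converged`, `lambda`.
#' @export
ridge_cox <- function(X, time, status, lambda, beta_init = NULL,
                      maxit = 50, tol = 1e-9) {
  X <- as.matrix(X)
  stopifnot(lambda >= 0, nrow(X) == length(time),
            length(time) == length(status), all(time > 0),
            all(status %in% c(0, 1)))
  if (sum(status) < 1) stop("no events: partial likelihood undefined")
  ord <- order(time)
  if (is.null(beta_init)) beta_init <- rep(0, ncol(X))
  fit <- cpp_cox_ridge_newton(X[ord, , drop = FALSE], time[ord], status[ord],
                              lambda, beta_init, maxit, tol)
  if (!fit$converged) {
    stop("ridge Cox did not converge in ", maxit, " iterations (lambda = ",
         lambda, ", final penalized loglik = ",
         signif(fit$penalized_loglik, 8), ")")
  }
  beta <- as.numeric(fit$beta)
  names(beta) <- colnames(X)
  list(beta = beta, loglik = fit$loglik,
       penalized_loglik = fit$penalized_loglik, iter = fit$iter,
       converged = fit$converged, lambda = lambda)
}

#' Cox partial log-likelihood
#'
#' Breslow partial log-likelihood of a coefficient vector on a dataset
#' (used by the cross-validated likelihood criterion).
#' @inheritParams ridge_cox
#' @param beta coefficient vector.
#' @return log-likelihood value.
#' @export
cox_loglik <- function(X, time, status, beta) {
  X <- as.matrix(X)
  ord <- order(time)
  cpp_cox_loglik(X[ord, , drop = FALSE], time[ord], status[ord],
                 as.numeric(beta))
}

#' Default shrinkage grid
#'
#' 25 log-spaced penalties spanning effectively unpenalized to fully shrunk.
#' @param n_points number of grid points.
#' @param range lower/upper bounds.
#' @return decreasing numeric vector.
#' @export
lambda_grid <- function(n_points = 25, range = c(1e-2, 1e4)) {
  sort(exp(seq(log(range[1]), log(range[2]), length.out = n_points)),
       decreasing = TRUE)
}

#' Event-stratified cross-validation folds
#'
#' Assigns fold ids separately within events and censored records so every
#' fold sees events. Deterministic given the record order and seed; callers
#' that need permutation invariance sort records by patient id first.
#'
#' @param status event indicators.
#' @param nfolds number of folds (reduced with a warning when there are
#'   fewer events than folds).
#' @param seed integer seed (local; does not disturb the caller's RNG).
#' @return list with `foldid` (integer vector) and `nfolds`.
#' @export
make_cv_folds <- function(status, nfolds = 10, seed = 1) {
  n_ev <- sum(status == 1)
  if (n_ev < nfolds) {
    nfolds <- max(2L, n_ev)
    warning("fewer events than folds: using ", nfolds, " folds",
            call. = FALSE)
  }
  foldid <- integer(length(status))
  with_local_seed(seed, {
    for (s in c(1, 0)) {
      idx <- which(status == s)
      if (length(idx)) {
        foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
      }
    }
  })
  list(foldid = foldid, nfolds = nfolds)
}

#' Select the ridge penalty by cross-validated partial likelihood
#'
#' 10-fold cross-validation optimizing the cross-validated partial
#' likelihood (the full-data log-likelihood at the fold-out estimate minus
#' the training log-likelihood, summed over folds). Ties on the criterion go
#' to the larger penalty.
#'
#' @inheritParams ridge_cox
#' @param grid decreasing penalty grid (see [lambda_grid()]).
#' @param nfolds folds (event-stratified).
#' @param foldid optional explicit fold assignment.
#' @param seed seed for fold assignment when `foldid` is `NULL`.
#' @return list with `lambda` (selected), `cvl` (criterion per grid value)
#'   and `grid`.
#' @export
select_lambda_cv <- function(X, time, status, grid = lambda_grid(),
                             nfolds = 10, foldid = NULL, seed = 1) {
  X <- as.matrix(X)
  grid <- sort(grid, decreasing = TRUE)
  if (is.null(foldid)) {
    foldid <- make_cv_folds(status, nfolds, seed)$foldid
  }
  ord <- order(time)
  cvl <- as.numeric(cpp_cox_cvl_grid(X[ord, , drop = FALSE], time[ord],
                                     status[ord],
                                     as.integer(foldid[ord]), grid))
  best <- which(cvl >= max(cvl) - 1e-12)[1] # grid is decreasing: first = largest
  list(lambda = grid[best], cvl = cvl, grid = grid)
}
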