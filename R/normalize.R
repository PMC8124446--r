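#' Background estimation for one channel
#'
#' Default method fits a low-order polynomial surface by least squares,
#' iteratively restricted to the pixels in the lower `quantile` of residuals,
#' so that cellular signal and tissue carpet do not bias the estimate; on a
#' channel that is exactly a polynomial field the fit is exact. The
#' `"tophat"` alternative uses a morphological opening with a disc.
#'
#' @param channel numeric matrix.
#' @param params a [pipeline_params()].
#' @param support optional logical matrix marking signal-free pixels (e.g.
#'   the jointly dark pixels of all channels); when given, the surface is
#'   fit once on the support with no iteration.
#' @return background estimate, same dimensions as `channel`.
#' @keywords internal
estimate_background <- function(channel, params = pipeline_params(),
                                support = NULL) {
  if (params$background_method == "tophat") {
    brush <- EBImage::makeBrush(2 * params$tophat_radius + 1, shape = "disc")
    return(EBImage::opening(channel, brush))
  }
  nr <- nrow(channel); nc <- ncol(channel)
  u <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  v <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  deg <- params$background_degree
  terms <- list()
  for (i in 0:deg) for (j in 0:(deg - i)) terms[[length(terms) + 1]] <- u^i * v^j
  X <- vapply(terms, as.vector, numeric(nr * nc))
  y <- as.vector(channel)
  # subsample for fitting; predict everywhere
  stride <- max(1L, floor(length(y) / 40000))
  idx <- seq(1L, length(y), by = stride)
  if (!is.null(support)) {
    use <- idx[support[idx]]
    if (length(use) < 2 * ncol(X)) use <- idx
    fit <- stats::lm.fit(X[use, , drop = FALSE], y[use])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    return(matrix(X %*% beta, nr, nc))
  }
  inliers <- idx
  beta <- rep(0, ncol(X))
  # Single-channel path: two shedding passes keep only pixels at or below
  # the fit, expelling blobs that pull the fit upward; two debiasing passes
  # then keep everything within 2 robust SDs of the negative residuals,
  # recentering the fit on the noise. A fallback keeps at least
  # `background_quantile` of the pixels so the fit never collapses. This
  # path assumes the channel has no broad smooth carpet (use `support` for
  # those).
  cuts <- c("shed", "shed", "debias", "debias")
  for (it in seq_along(cuts)) {
    fit <- stats::lm.fit(X[inliers, , drop = FALSE], y[inliers])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    res <- y[idx] - X[idx, , drop = FALSE] %*% beta
    neg <- res[res < 0]
    sig <- if (length(neg) >= 50) stats::mad(neg, center = 0) else 0
    cut <- if (cuts[it] == "shed") 0 else 2 * sig
    keep <- res <= cut
    if (sum(keep) < params$background_quantile * length(idx)) {
      keep <- res <= stats::quantile(res, params$background_quantile,
                                     names = FALSE)
    }
    inliers <- idx[keep]
  }
  fit <- stats::lm.fit(X[inliers, , drop = FALSE], y[inliers])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  matrix(X %*% beta, nr, nc)
}

#' Per-channel background correction and normalization
#'
#' Each channel has its background estimate subtracted, negatives clipped to
#' zero, and is divided by a robust per-channel scale: the `norm_quantile`
#' quantile of the corrected pixels above a noise floor (5 robust SDs of
#' the negative correction residuals). The scale pins the
#' dim, nonspecific signal population near 1 so the fixed foreground (0.2)
#' and phenotype (0.5 / 1.5) thresholds are meaningful, and the result is
#' invariant to multiplying a raw channel by any positive constant. Channels
#' with no signal above background are returned as all-zero with a warning.
#'
#' @param raw a [multiplex_image()] with non-negative channels.
#' @param params a [pipeline_params()].
#' @return a normalized [multiplex_image()].
#' @export
normalize_image <- function(raw, params = pipeline_params()) {
  stopifnot(inherits(raw, "multiplex_image"))
  out <- raw
  # background support: pixels dark in every channel, i.e. the tissue-free
  # margin; a broad carpet (autofluorescence) cannot be told apart from a
  # smooth background field by any single channel alone. Channels are put
  # on a common scale and combined by pixelwise maximum so a pixel bright
  # anywhere is excluded.
  mx <- Reduce(pmax, lapply(raw$channels, function(ch) {
    ch / max(stats::quantile(ch, 0.99, names = FALSE), 1e-12)
  }))
  support <- mx <= stats::quantile(mx, params$dark_quantile, names = FALSE)
  if (mean(support) < 0.05) support <- NULL
  for (nm in names(raw$channels)) {
    ch <- raw$channels[[nm]]
    resid <- ch - estimate_background(ch, params, support)
    corr <- pmax(resid, 0)
    # noise floor from the negative residuals (pure noise: signal only adds
    # positive mass), so noise pixels never enter the scale estimate
    neg <- resid[resid < 0]
    floor <- if (length(neg) >= 100) 5 * 1.4826 * stats::median(-neg) else 0
    # never let numerical dust from an exact background fit count as signal
    floor <- max(floor, 1e-6 * max(corr))
    pos <- corr[corr > floor]
    scale <- if (length(pos) >= 10) {
      stats::quantile(pos, params$norm_quantile, names = FALSE)
    } else 0
    if (scale <= 1e-8 * max(ch, 0)) {
      warning("channel '", nm, "' has no signal above background; ",
              "returning zeros", call. = FALSE)
      out$channels[[nm]] <- matrix(0, nrow(ch), ncol(ch))
    } else {
      out$channels[[nm]] <- corr / scale
    }
  }
  out
}
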