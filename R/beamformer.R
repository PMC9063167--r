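#' LCMV beamformer weights
#'
#' Linearly constrained minimum variance spatial filter: for parcel `i`
#' with leadfield column `l_i` and regularized sensor covariance `C`,
#' `w_i = (l_i' C^-1 l_i)^-1 l_i' C^-1`. Each weight row has unit gain on
#' its own leadfield column (`w_i . l_i = 1`) while minimizing output
#' variance from all other sources.
#'
#' @param leadfield Sensors x parcels matrix, full column rank.
#' @param covariance Sensors x sensors symmetric PSD data covariance.
#' @param regularization Fraction of the mean sensor variance added to the
#'   covariance diagonal (default 0.05).
#' @return Parcels x sensors weight matrix with attribute
#'   `"regularization"`.
#' @export
compute_lcmv_weights <- function(leadfield, covariance,
                                 regularization = 0.05) {
  stopifnot(nrow(covariance) == ncol(covariance),
            nrow(leadfield) == nrow(covariance),
            regularization >= 0)
  if (max(abs(covariance - t(covariance))) > 1e-8 * max(abs(covariance))) {
    stop("covariance must be symmetric", call. = FALSE)
  }
  C <- covariance
  if (regularization > 0) {
    C <- C + regularization * mean(diag(C)) * diag(nrow(C))
  }
  Ci <- tryCatch(solve(C), error = function(e) {
    stop("covariance is singular; supply a positive regularization fraction",
         call. = FALSE)
  })
  CiL <- Ci %*% leadfield                     # sensors x parcels
  gains <- colSums(leadfield * CiL)           # l_i' C^-1 l_i
  if (any(gains <= 0)) {
    stop("covariance is not positive definite after regularization",
         call. = FALSE)
  }
  W <- t(CiL) / gains                         # parcels x sensors
  attr(W, "regularization") <- regularization
  W
}

#' Reconstruct parcel ("virtual sensor") time series
#'
#' Applies beamformer weights to sensor epochs; one time series per parcel,
#' in leadfield column order.
#'
#' @param weights Parcels x sensors matrix from [compute_lcmv_weights()].
#' @param epochs Trials x sensors x samples array, or a sensors x samples
#'   matrix for a single epoch.
#' @return Trials x parcels x samples array (matrix in, matrix out).
#' @export
reconstruct_parcel_timeseries <- function(weights, epochs) {
  if (is.matrix(epochs)) {
    if (ncol(weights) != nrow(epochs)) stop("dimension mismatch", call. = FALSE)
    return(weights %*% epochs)
  }
  stopifnot(length(dim(epochs)) == 3)
  if (ncol(weights) != dim(epochs)[2]) stop("dimension mismatch", call. = FALSE)
  n_trials <- dim(epochs)[1]
  out <- array(0, dim = c(n_trials, nrow(weights), dim(epochs)[3]))
  for (tr in seq_len(n_trials)) out[tr, , ] <- weights %*% epochs[tr, , ]
  out
}

#' Closest-orthogonal leakage correction
#'
#' Finds the set of mutually uncorrelated (zero instantaneous correlation)
#' time series closest in summed squared distance to the input, by
#' alternating an orthogonal-Procrustes rotation with per-signal rescaling.
#' Beamformed parcel series share zero-lag variance through the limited
#' spatial resolution of the inverse problem; removing those zero-lag
#' correlations before amplitude envelope correlation prevents spurious
#' envelope coupling. It is applied per subject and band before AEC only
#' (wPLI is already insensitive to zero-lag mixing, so it never sees
#' corrected data).
#'
#' @param parcels Parcels x samples matrix (more samples than parcels).
#' @param tol Relative residual tolerance for convergence.
#' @param max_iter Maximum alternation iterations.
#' @return Parcels x samples matrix of mutually uncorrelated signals, with
#'   attributes `"iterations"` and `"residual"` (final Frobenius distance).
#' @export
orthogonalize_closest <- function(parcels, tol = 1e-8, max_iter = 100L) {
  stopifnot(is.matrix(parcels), nrow(parcels) >= 2,
            ncol(parcels) > nrow(parcels))
  X <- t(parcels)                             # samples x parcels
  X <- sweep(X, 2, colMeans(X))               # zero correlation = orthogonality
  p <- ncol(X)
  d <- sqrt(colSums(X^2))
  if (any(d < .Machine$double.eps)) {
    stop("zero-variance parcel time series cannot be orthogonalized",
         call. = FALSE)
  }
  resid_prev <- Inf
  O <- NULL
  for (it in seq_len(max_iter)) {
    sv <- La.svd(X %*% diag(d, p), nu = p, nv = p)
    O <- sv$u %*% sv$vt                       # orthonormal columns
    d <- colSums(X * O)                       # per-signal scale
    Y <- O %*% diag(d, p)
    resid <- sqrt(sum((X - Y)^2))
    normX <- sqrt(sum(X^2))
    if (resid <= tol * normX ||
        (is.finite(resid_prev) &&
         abs(resid_prev - resid) <= tol * max(resid, tol * normX))) {
      out <- t(Y)
      attr(out, "iterations") <- it
      attr(out, "residual") <- resid
      return(out)
    }
    resid_prev <- resid
  }
  stop(sprintf(
    "closest-orthogonalization did not converge in %d iterations (residual %g)",
    max_iter, resid_prev), call. = FALSE)
}
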