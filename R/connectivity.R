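#' Analytic signal via the Hilbert transform
#'
#' FFT-based analytic extension of a band-limited signal: the envelope is
#' its magnitude and the instantaneous phase its angle. The first and last
#' `trim_s` seconds are discarded to avoid Hilbert/filter edge effects.
#'
#' @param x Numeric vector or channels x samples matrix (band-limited).
#' @param fs Sampling rate (Hz).
#' @param trim_s Seconds trimmed from each end (default 0).
#' @return List with `z` (complex analytic signal, channels x samples),
#'   `envelope` and `phase` (same shape). All-zero channels get zero
#'   envelope, `NA` phase and set the `"degenerate"` attribute.
#' @export
analytic_signal <- function(x, fs, trim_s = 0) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Z <- t(apply(x, 1, function(row) {
    stats::fft(stats::fft(row) * h, inverse = TRUE) / n
  }))
  trim <- round(trim_s * fs)
  if (trim > 0) {
    if (2 * trim >= n) stop("trim longer than the epoch", call. = FALSE)
    Z <- Z[, (trim + 1):(n - trim), drop = FALSE]
  }
  env <- Mod(Z)
  ph <- Arg(Z)
  degen <- apply(abs(Z), 1, max) < .Machine$double.eps
  if (any(degen)) ph[degen, ] <- NA_real_
  out <- list(z = Z, envelope = env, phase = ph)
  attr(out, "degenerate") <- degen
  out
}

#' Weighted phase lag index between two analytic signals
#'
#' With the per-sample cross-spectral term `S(t) = zA(t) * Conj(zB(t))`,
#' `wPLI = |sum Im S| / sum |Im S|`. Samples are weighted by the magnitude
#' of their imaginary component, making the index insensitive to zero-lag
#' (leakage) coupling: zero-lag terms have no imaginary part.
#'
#' @param zA,zB Complex analytic-signal vectors of equal length.
#' @return Value in `[0, 1]`; if the imaginary cross-spectrum vanishes
#'   identically the value is 0 with attribute `"degenerate" = TRUE`.
#' @export
compute_wpli <- function(zA, zB) {
  if (length(zA) != length(zB)) stop("length mismatch", call. = FALSE)
  imS <- Im(zA * Conj(zB))
  den <- sum(abs(imS))
  if (den < .Machine$double.eps) {
    return(structure(0, degenerate = TRUE))
  }
  abs(sum(imS)) / den
}

#' Amplitude envelope correlation between two envelopes
#'
#' Pearson correlation over time of the two amplitude-envelope series,
#' capturing slow co-modulation of band-limited power. For leakage-safe
#' estimates the parcel signals must be orthogonalized upstream.
#'
#' @param envA,envB Non-negative envelope vectors of equal length.
#' @return Correlation in `[-1, 1]`; `NA` with attribute
#'   `"degenerate" = TRUE` when either envelope has zero variance.
#' @export
compute_aec <- function(envA, envB) {
  if (length(envA) != length(envB)) stop("length mismatch", call. = FALSE)
  if (stats::sd(envA) < .Machine$double.eps ||
      stats::sd(envB) < .Machine$double.eps) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  stats::cor(envA, envB)
}

# all-pairs wPLI from a parcels x samples complex matrix
wpli_matrix <- function(Z) {
  p <- nrow(Z)
  ReZ <- Re(Z); ImZ <- Im(Z)
  num <- ImZ %*% t(ReZ) - ReZ %*% t(ImZ)     # sum_t Im(z_i conj z_j)
  W <- matrix(0, p, p)
  for (i in seq_len(p)) {
    # Im(z_i conj z_j)(t) for all j at once
    imS <- outer(rep(1, p), ImZ[i, ]) * ReZ - outer(rep(1, p), ReZ[i, ]) * ImZ
    den <- rowSums(abs(imS))
    w <- ifelse(den < .Machine$double.eps, 0, abs(num[i, ]) / den)
    W[i, ] <- w
  }
  W <- (W + t(W)) / 2                         # numerically symmetric
  diag(W) <- 0
  W
}

# all-pairs AEC from a parcels x samples envelope matrix
aec_matrix <- function(env) {
  keep <- apply(env, 1, stats::sd) > .Machine$double.eps
  A <- matrix(NA_real_, nrow(env), nrow(env))
  if (any(keep)) {
    A[keep, keep] <- stats::cor(t(env[keep, , drop = FALSE]))
  }
  diag(A) <- 0
  A
}

#' Per-trial connectivity adjacency matrix
#'
#' Computes the chosen metric between all parcel pairs within each epoch of
#' one trial and averages over the trial's epochs. For AEC the epochs are
#' leakage-corrected with [orthogonalize_closest()] first (the default);
#' wPLI is always computed on uncorrected signals. `mode = "roi"` returns
#' the parcels x seeds rectangular matrix whose columns are the seed
#' parcels; entries agree exactly with the whole-brain matrix.
#'
#' @param epochs List of band-limited parcels x samples matrices (one
#'   trial's epochs).
#' @param fs Sampling rate (Hz).
#' @param metric `"AEC"` or `"wPLI"`.
#' @param mode `"whole_brain"` or `"roi"`.
#' @param seeds Integer indices of seed parcels (required for ROI mode).
#' @param trim_s Edge trim passed to [analytic_signal()] (default 1 s).
#' @param orthogonalize Apply closest-orthogonal correction before AEC.
#' @return Parcels x parcels symmetric (or parcels x seeds) matrix with
#'   zero diagonal/self-pairs.
#' @export
build_adjacency <- function(epochs, fs, metric = c("AEC", "wPLI"),
                            mode = c("whole_brain", "roi"), seeds = NULL,
                            trim_s = 1, orthogonalize = NULL) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  stopifnot(is.list(epochs), length(epochs) >= 1)
  p <- nrow(epochs[[1]])
  if (mode == "roi") {
    if (is.null(seeds) || length(seeds) == 0) {
      stop("ROI mode requires a non-empty seed set", call. = FALSE)
    }
    if (any(seeds < 1 | seeds > p)) {
      stop("unknown seed index: ",
           paste(seeds[seeds < 1 | seeds > p], collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(orthogonalize)) orthogonalize <- metric == "AEC"
  acc <- matrix(0, p, p)
  n_used <- 0
  for (ep in epochs) {
    x <- ep
    if (orthogonalize) x <- orthogonalize_closest(x)
    az <- analytic_signal(x, fs, trim_s = trim_s)
    M <- if (metric == "wPLI") wpli_matrix(az$z) else aec_matrix(az$envelope)
    M[is.na(M)] <- 0
    acc <- acc + M
    n_used <- n_used + 1
  }
  M <- acc / n_used
  if (mode == "roi") M[, seeds, drop = FALSE] else M
}

#' Average trial matrices and subtract the resting baseline
#'
#' Elementwise mean over the task-trial matrices minus the elementwise mean
#' over the resting-state matrices, yielding one baselined connectivity
#' matrix per subject, condition, band and metric.
#'
#' @param trial_mats List of per-trial connectivity matrices (same shape).
#' @param rest_mats List of resting-state matrices (same shape).
#' @return Baselined matrix.
#' @export
average_and_baseline <- function(trial_mats, rest_mats) {
  stopifnot(length(trial_mats) >= 1, length(rest_mats) >= 1)
  d <- dim(trial_mats[[1]])
  ok <- vapply(c(trial_mats, rest_mats),
               function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) stop("matrix shape mismatch between task and rest",
                     call. = FALSE)
  Reduce(`+`, trial_mats) / length(trial_mats) -
    Reduce(`+`, rest_mats) / length(rest_mats)
}
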