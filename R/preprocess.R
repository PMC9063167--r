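#' Split a continuous trial into fixed-length epochs
#'
#' Consecutive non-overlapping epochs of exactly `epoch_s` seconds; a
#' trailing remainder shorter than one epoch is discarded. The 30 s music
#' trials are epoched into three 10 s chunks so that head movement rejects
#' an epoch rather than the whole trial.
#'
#' @param x Channels x samples matrix (a vector is treated as one channel).
#' @param epoch_s Epoch length in seconds.
#' @param fs Sampling rate in Hz.
#' @return List of channels x `epoch_s * fs` matrices.
#' @export
epoch_trials <- function(x, epoch_s, fs) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  len <- round(epoch_s * fs)
  n <- ncol(x)
  if (n < len) stop("trial shorter than one epoch", call. = FALSE)
  k <- n %/% len
  lapply(seq_len(k), function(e) x[, ((e - 1) * len + 1):(e * len), drop = FALSE])
}

#' Reject trials exceeding a head-motion threshold
#'
#' Trials whose per-trial maximum head displacement is strictly greater
#' than `threshold_mm` are removed (a trial at exactly the threshold is
#' kept). The study rule is 10 mm.
#'
#' @param manifest Trial manifest with a `motion_mm` column.
#' @param threshold_mm Rejection threshold in millimetres.
#' @return List with `manifest` (kept trials) and `report` (a `data.frame`
#'   of kept/dropped counts per subject).
#' @export
reject_motion_trials <- function(manifest, threshold_mm = 10) {
  stopifnot(is.data.frame(manifest), "motion_mm" %in% names(manifest))
  if (any(is.na(manifest$motion_mm))) {
    bad <- manifest$trial[is.na(manifest$motion_mm)]
    stop("missing motion value for trial(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  drop <- manifest$motion_mm > threshold_mm
  kept <- manifest[!drop, , drop = FALSE]
  report <- stats::aggregate(
    cbind(kept = !drop, dropped_motion = drop),
    by = list(subject = manifest$subject), FUN = sum)
  list(manifest = kept, report = report)
}

#' Exclude subjects with too few trials in any condition
#'
#' Subjects must retain at least `min_trials` music trials in each of the
#' familiar and unfamiliar conditions (response-derived labels, liked and
#' disliked already collapsed) to be analyzed; the study minimum is 3.
#'
#' @param manifest Trial manifest (music trials; rest records are ignored).
#' @param min_trials Minimum trials per condition.
#' @return List with `included` (character vector of subject ids) and
#'   `report` (per-subject condition counts and the inclusion flag).
#' @export
qc_min_trials <- function(manifest, min_trials = 3L) {
  stopifnot(is.data.frame(manifest))
  music <- manifest[!manifest$is_rest, , drop = FALSE]
  subjects <- unique(music$subject)
  counts <- lapply(subjects, function(s) {
    m <- music[music$subject == s, ]
    data.frame(subject = s,
               n_familiar = sum(m$condition_response == "familiar"),
               n_unfamiliar = sum(m$condition_response == "unfamiliar"),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, counts)
  report$included <- report$n_familiar >= min_trials &
    report$n_unfamiliar >= min_trials
  list(included = report$subject[report$included], report = report)
}

# --- FastICA (symmetric decorrelation, logcosh contrast) ------------------

fastica_decompose <- function(X, n_components, max_iter = 200, tol = 1e-6) {
  # X: channels x samples, assumed centered
  n <- ncol(X)
  cv <- tcrossprod(X) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-10)
  m <- min(n_components, length(keep))
  if (m < 1) stop("decomposition failure: data covariance is degenerate ",
                  "(condition number ~ ",
                  format(max(eg$values) / max(min(eg$values), 1e-300)), ")",
                  call. = FALSE)
  K <- diag(1 / sqrt(eg$values[1:m]), m) %*% t(eg$vectors[, 1:m, drop = FALSE])
  Z <- K %*% X
  W <- qr.Q(qr(matrix(stats::rnorm(m * m), m)))
  sym_decorrelate <- function(W) {
    sv <- La.svd(W)
    crossprod(t(sv$u), sv$vt)
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gp <- rowMeans(1 - G^2)
    W_new <- tcrossprod(G, Z) / n - diag(gp, m) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(tcrossprod(W_new, W))) - 1))
    W <- W_new
    if (delta < tol) break
  }
  S <- W %*% Z                                # components x samples
  unmix <- W %*% K                            # components x channels
  mix <- eg$vectors[, 1:m, drop = FALSE] %*%
    diag(sqrt(eg$values[1:m]), m) %*% t(W)    # channels x components
  list(S = S, mixing = mix, unmixing = unmix)
}

#' Remove artifact components from sensor epochs
#'
#' Estimates an ICA decomposition per subject (epochs concatenated in
#' time), identifies components whose absolute correlation with any
#' artifact reference channel exceeds `r_threshold`, zeroes them (up to
#' `max_components`), and reconstructs the sensor data. This automates the
#' visual component inspection of conventional MEG preprocessing using the
#' simulator's artifact reference time courses.
#'
#' @param epochs Trials x sensors x samples array.
#' @param references Trials x k x samples array of artifact time courses,
#'   time-aligned with `epochs`, or `NULL` (no removal attempted).
#' @param max_components Maximum number of components estimated/removed
#'   (study cap: 60 inspected per participant).
#' @param r_threshold Absolute-correlation threshold for flagging a
#'   component as artifactual.
#' @param seed Seed for the ICA initialization (deterministic result).
#' @return List with `epochs` (cleaned array), `report` (components
#'   estimated/removed and their reference correlations).
#' @export
remove_artifact_components <- function(epochs, references,
                                       max_components = 60L,
                                       r_threshold = 0.4, seed = 1L) {
  stopifnot(length(dim(epochs)) == 3, dim(epochs)[2] >= 2)
  n_trials <- dim(epochs)[1]
  ns <- dim(epochs)[2]
  n <- dim(epochs)[3]
  X <- matrix(0, ns, n_trials * n)
  for (tr in seq_len(n_trials)) X[, ((tr - 1) * n + 1):(tr * n)] <- epochs[tr, , ]
  mu <- rowMeans(X)
  Xc <- X - mu
  set.seed(as.integer(seed))
  m <- min(max_components, ns, ncol(Xc) - 1L)
  ica <- fastica_decompose(Xc, m)
  removed <- integer(0)
  cors <- numeric(0)
  if (!is.null(references)) {
    k <- dim(references)[2]
    R <- matrix(0, k, n_trials * n)
    for (tr in seq_len(n_trials)) R[, ((tr - 1) * n + 1):(tr * n)] <- references[tr, , ]
    cmat <- abs(stats::cor(t(ica$S), t(R)))   # components x refs
    maxcor <- apply(cmat, 1, max)
    removed <- order(maxcor, decreasing = TRUE)
    removed <- removed[maxcor[removed] > r_threshold]
    removed <- utils::head(removed, max_components)
    cors <- maxcor[removed]
  }
  if (length(removed) > 0) {
    Xc <- Xc - ica$mixing[, removed, drop = FALSE] %*%
      ica$S[removed, , drop = FALSE]
  }
  Xclean <- Xc + mu
  out <- array(0, dim = dim(epochs))
  for (tr in seq_len(n_trials)) out[tr, , ] <- Xclean[, ((tr - 1) * n + 1):(tr * n)]
  list(epochs = out,
       report = list(n_components = nrow(ica$S),
                     n_removed = length(removed),
                     removed = removed, reference_correlation = cors))
}

# --- FIR filterbank -------------------------------------------------------

# FIR order: 3 cycles of the band's low edge, floored at one second of
# taps so high-frequency bands keep a narrow transition; forced even so
# band-stop designs are valid and group delay is integral.
fir_order <- function(fs, lo) {
  n <- max(round(3 * fs / lo), round(fs))
  if (n %% 2 == 1) n <- n + 1
  n
}

#' Zero-phase FIR filterbank with power-line notch
#'
#' Applies a 60 Hz FIR notch (band-stop) and then splits the signal into
#' the requested bands with two-pass (forward-backward, zero net phase)
#' Hamming-window FIR band-pass filters. Output length equals input length.
#'
#' @param x Channels x samples numeric matrix (vector = one channel).
#' @param bands Band table (`label`, `lo`, `hi`), e.g. [canonical_bands()].
#' @param fs Sampling rate (Hz); must exceed twice the highest band edge.
#' @param notch_hz Notch center frequency, or `NULL` to skip; half-width
#'   2 Hz.
#' @return Named list (by band label) of filtered channels x samples
#'   matrices.
#' @export
bandpass_filterbank <- function(x, bands = canonical_bands(), fs,
                                notch_hz = 60) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (any(bands$hi >= fs / 2)) {
    stop("band edge at or above Nyquist frequency", call. = FALSE)
  }
  nyq <- fs / 2
  filt_rows <- function(x, b) {
    t(apply(x, 1, function(row) signal::filtfilt(b, row)))
  }
  if (!is.null(notch_hz)) {
    n_notch <- fir_order(fs, 3)        # one second of taps
    bstop <- signal::fir1(n_notch, c(notch_hz - 2, notch_hz + 2) / nyq,
                          type = "stop")
    x <- filt_rows(x, bstop)
  }
  out <- vector("list", nrow(bands))
  names(out) <- bands$label
  for (b in seq_len(nrow(bands))) {
    ord <- fir_order(fs, bands$lo[b])
    bp <- signal::fir1(ord, c(bands$lo[b], bands$hi[b]) / nyq, type = "pass")
    out[[b]] <- filt_rows(x, bp)
  }
  out
}
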