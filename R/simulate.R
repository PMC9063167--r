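#' Canonical frequency bands
#'
#' Theta (4--7 Hz), alpha (8--14), beta (15--29), gamma1 (30--55) and
#' gamma2 (65--80), the five analysis bands of the pipeline.
#'
#' @return A `data.frame` with columns `label`, `lo`, `hi` (Hz).
#' @export
canonical_bands <- function() {
  data.frame(
    label = c("theta", "alpha", "beta", "gamma1", "gamma2"),
    lo = c(4, 8, 15, 30, 65),
    hi = c(7, 14, 29, 55, 80),
    stringsAsFactors = FALSE
  )
}

#' Planted-edge table constructor
#'
#' One row per planted coupling. `metric` selects the coupling mechanism:
#' `"wPLI"` plants a shared oscillation with a quarter-period lag (non-zero
#' imaginary cross-spectrum), `"AEC"` plants a shared slow amplitude
#' modulator. `group`/`condition` restrict the coupling to one cell of the
#' design; `"*"` matches every group or condition.
#'
#' @param band Band label (must appear in the config's band table).
#' @param metric `"wPLI"` or `"AEC"`.
#' @param group Group label or `"*"`.
#' @param condition Condition label or `"*"`.
#' @param i,j 1-based parcel indices of the edge.
#' @param effect Dimensionless effect size in `[0, 1]`.
#' @return `data.frame` of planted edges.
#' @export
planted_edges <- function(band, metric, group, condition, i, j, effect) {
  data.frame(band = band, metric = metric, group = group,
             condition = condition, i = as.integer(i), j = as.integer(j),
             effect = as.numeric(effect), stringsAsFactors = FALSE)
}

empty_planted_edges <- function() {
  planted_edges(character(0), character(0), character(0), character(0),
                integer(0), integer(0), numeric(0))
}

#' Simulation configuration
#'
#' Defines the synthetic cohort: two groups of `n_subjects_per_group`
#' subjects, `n_parcels` source parcels, band-limited oscillations in the
#' configured bands, planted phase- and envelope-coupled edges, zero-lag
#' linear leakage mixing, sensor projection with artifact components, and
#' log-normal per-trial head motion.
#'
#' @param n_subjects_per_group Subjects per group (study cohort: 24).
#' @param n_parcels Number of source parcels (study: 92).
#' @param bands Band table as from [canonical_bands()].
#' @param planted Planted-edge table ([planted_edges()]); empty by default.
#' @param leakage_mixing_strength Strength in `[0, 1]` of the zero-lag
#'   near-identity mixing applied to parcel signals (0 = no leakage).
#' @param artifact_components Number of artifact components mixed into the
#'   sensors by [project_to_sensors()].
#' @param sensor_count Number of sensors (study system: 151 channels).
#' @param noise_sd White sensor-noise standard deviation, in signal units.
#' @param osc_amplitude Amplitude of each band-limited oscillation.
#' @param background_amplitude Amplitude of the 1/f background.
#' @param envelope_depth Modulation depth of planted envelope couplings;
#'   must stay below 0.5 so envelopes remain positive (modulators are
#'   clipped at two standard deviations).
#' @param motion_median_mm Median of the log-normal per-trial head motion.
#' @param motion_sdlog Log-scale SD of the motion distribution.
#' @param trial_duration_s,sampling_rate_hz Trial geometry.
#' @param response_flip_rate Probability an in-scanner familiarity response
#'   disagrees with the stimulus label.
#' @param seed Integer master seed; all randomness derives from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects_per_group = 24L, n_parcels = 92L,
                              bands = canonical_bands(),
                              planted = empty_planted_edges(),
                              leakage_mixing_strength = 0,
                              artifact_components = 0L,
                              sensor_count = 151L,
                              noise_sd = 0.1,
                              osc_amplitude = 1,
                              background_amplitude = 0.25,
                              envelope_depth = 0.4,
                              motion_median_mm = 5,
                              motion_sdlog = 0.5,
                              trial_duration_s = 30,
                              sampling_rate_hz = 600,
                              response_flip_rate = 0,
                              seed = 1L) {
  cfg <- list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_parcels = as.integer(n_parcels),
    bands = bands, planted = planted,
    leakage_mixing_strength = leakage_mixing_strength,
    artifact_components = as.integer(artifact_components),
    sensor_count = as.integer(sensor_count),
    noise_sd = noise_sd,
    osc_amplitude = osc_amplitude,
    background_amplitude = background_amplitude,
    envelope_depth = envelope_depth,
    motion_median_mm = motion_median_mm,
    motion_sdlog = motion_sdlog,
    trial_duration_s = trial_duration_s,
    sampling_rate_hz = sampling_rate_hz,
    response_flip_rate = response_flip_rate,
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_subjects_per_group >= 1L, cfg$n_parcels >= 2L,
            all(c("label", "lo", "hi") %in% names(bands)),
            all(bands$lo < bands$hi),
            all(bands$hi < cfg$sampling_rate_hz / 2),
            cfg$leakage_mixing_strength >= 0,
            cfg$leakage_mixing_strength <= 1,
            cfg$sensor_count >= cfg$n_parcels,
            cfg$noise_sd >= 0)
  if (nrow(planted) > 0) {
    if (any(planted$i < 1 | planted$i > cfg$n_parcels |
            planted$j < 1 | planted$j > cfg$n_parcels | planted$i == planted$j)) {
      stop("planted edges must reference distinct valid parcel indices",
           call. = FALSE)
    }
    if (any(planted$effect < 0 | planted$effect > 1)) {
      stop("planted effect sizes must lie in [0, 1]", call. = FALSE)
    }
    if (!all(planted$band %in% bands$label)) {
      stop("planted edge bands must appear in the band table", call. = FALSE)
    }
  }
  # modulators are clipped at +/- 2 SD, so depth >= 0.5 can drive the
  # envelope to zero or below
  if (cfg$envelope_depth >= 0.5 || cfg$envelope_depth < 0) {
    stop("envelope_depth must lie in [0, 0.5) to keep envelopes positive",
         call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# Low-pass (< cutoff Hz) Gaussian modulator, unit variance, length n.
slow_modulator <- function(n, fs, cutoff = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freqs <- seq(0, fs, length.out = n + 1)[1:n]
  freqs <- pmin(freqs, fs - freqs)
  X[freqs > cutoff] <- 0
  m <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(m)
  if (s < .Machine$double.eps) return(rep(0, n))
  m / s
}

# Band-limited Gaussian noise via FFT masking: unit variance, band [lo, hi].
bandlimited_noise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freqs <- seq(0, fs, length.out = n + 1)[1:n]
  freqs <- pmin(freqs, fs - freqs)
  X[freqs < lo | freqs > hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s < .Machine$double.eps) return(rep(0, n))
  y / s
}

# constant-envelope narrowband carrier: a tone at the band's center
# frequency with slow random frequency modulation (deviation <= 1 Hz, kept
# well inside the band). Carriers for different parcels are independent and
# drift apart in phase, so planted envelope couplings carry no zero-lag
# correlation and survive leakage orthogonalization.
fm_carrier <- function(n, fs, lo, hi) {
  fc <- (lo + hi) / 2
  dev <- min(0.75, (hi - lo) / 3)
  u <- slow_modulator(n, fs, cutoff = 1)
  ph <- 2 * pi * cumsum(fc + dev * u) / fs + stats::runif(1, 0, 2 * pi)
  cos(ph)
}

# 1/f (pink-ish) background noise, unit variance.
one_over_f_noise <- function(n, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freqs <- seq(0, fs, length.out = n + 1)[1:n]
  freqs <- pmin(freqs, fs - freqs)
  scale <- 1 / sqrt(pmax(freqs, 1))
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  y / stats::sd(y)
}

# circular shift by k samples (k >= 0 delays the signal)
circshift <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

#' Zero-lag leakage mixing matrix
#'
#' Identity plus `strength` times a symmetric random perturbation,
#' row-normalized, emulating the zero-lag linear field spread that leakage
#' correction must remove and wPLI must ignore.
#'
#' @param n_parcels Matrix dimension.
#' @param strength Perturbation strength in `[0, 1]`.
#' @return `n_parcels` x `n_parcels` mixing matrix.
#' @export
make_leakage_matrix <- function(n_parcels, strength) {
  P <- matrix(stats::rnorm(n_parcels^2), n_parcels)
  P <- (P + t(P)) / 2
  P <- P / max(abs(P))
  M <- diag(n_parcels) + strength * P
  M / rowSums(abs(M))
}

#' Simulate one subject's parcel time series with known planted structure
#'
#' Each parcel carries one band-limited oscillation per configured band plus
#' 1/f background noise. Planted phase-coupled pairs share a common
#' narrowband signal with the second node receiving a quarter-period delayed
#' copy, mixed in with weight equal to the effect size. Planted
#' envelope-coupled pairs are constant-envelope carriers at the band's
#' center frequency whose amplitudes follow slow (< 1 Hz) Gaussian
#' modulators sharing a common component; the sharing coefficient equals the
#' target envelope correlation. Finally parcel signals are post-multiplied
#' by a near-identity zero-lag mixing matrix of the configured leakage
#' strength. Everything is deterministic given `(config, seed)`.
#'
#' @param config A [simulation_config()].
#' @param subject Subject id (character).
#' @param group Group label.
#' @param condition Condition label (planted edges are filtered on it).
#' @param n_trials Number of trials to simulate.
#' @param seed Integer seed for this subject/condition block.
#' @return A list of class `parcel_timeseries` with `data` (array
#'   `n_trials` x `n_parcels` x `n_samples`), `fs`, `subject`, `group`,
#'   `condition`, and `ground_truth` (planted edges active in this cell,
#'   per-trial `motion_mm`, and the leakage matrix used).
#' @export
simulate_subject_timeseries <- function(config, subject, group, condition,
                                        n_trials, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"), n_trials >= 1)
  set.seed(as.integer(seed))
  fs <- config$sampling_rate_hz
  n <- round(config$trial_duration_s * fs)
  p <- config$n_parcels
  active <- config$planted[
    (config$planted$group == "*" | config$planted$group == group) &
      (config$planted$condition == "*" | config$planted$condition == condition), ,
    drop = FALSE]
  mix <- if (config$leakage_mixing_strength > 0) {
    make_leakage_matrix(p, config$leakage_mixing_strength)
  } else {
    diag(p)
  }
  dat <- array(0, dim = c(n_trials, p, n))
  for (tr in seq_len(n_trials)) {
    sig <- matrix(0, p, n)
    for (b in seq_len(nrow(config$bands))) {
      lo <- config$bands$lo[b]; hi <- config$bands$hi[b]
      lab <- config$bands$label[b]
      fc <- (lo + hi) / 2
      band_sig <- matrix(0, p, n)
      for (k in seq_len(p)) {
        band_sig[k, ] <- config$osc_amplitude * bandlimited_noise(n, fs, lo, hi)
      }
      # phase couplings: chain shared narrowband signals so edges that
      # share a node keep their already-planted structure
      ph <- active[active$band == lab & active$metric == "wPLI", ,
                   drop = FALSE]
      lag <- max(1L, round(fs / (4 * fc)))
      assigned <- rep(FALSE, p)
      for (e in seq_len(nrow(ph))) {
        i <- ph$i[e]; j <- ph$j[e]; eff <- ph$effect[e]
        if (!assigned[i] && !assigned[j]) {
          common <- bandlimited_noise(n, fs, lo, hi)
          band_sig[i, ] <- config$osc_amplitude * common
          band_sig[j, ] <- config$osc_amplitude *
            (eff * circshift(common, lag) +
               sqrt(max(0, 1 - eff^2)) * bandlimited_noise(n, fs, lo, hi))
        } else if (assigned[i] && !assigned[j]) {
          band_sig[j, ] <- eff * circshift(band_sig[i, ], lag) +
            sqrt(max(0, 1 - eff^2)) * config$osc_amplitude *
              bandlimited_noise(n, fs, lo, hi)
        } else if (!assigned[i] && assigned[j]) {
          band_sig[i, ] <- eff * circshift(band_sig[j, ], -lag) +
            sqrt(max(0, 1 - eff^2)) * config$osc_amplitude *
              bandlimited_noise(n, fs, lo, hi)
        }                                    # both assigned: already coupled
        assigned[i] <- TRUE; assigned[j] <- TRUE
      }
      # envelope couplings: draw jointly correlated slow modulators for all
      # involved nodes (target correlations factored via Cholesky)
      ec <- active[active$band == lab & active$metric == "AEC", ,
                   drop = FALSE]
      if (nrow(ec) > 0) {
        nodes <- sort(unique(c(ec$i, ec$j)))
        k <- length(nodes)
        Sig <- diag(k)
        for (e in seq_len(nrow(ec))) {
          a <- match(ec$i[e], nodes); b <- match(ec$j[e], nodes)
          Sig[a, b] <- Sig[b, a] <- ec$effect[e]
        }
        ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < -1e-8) {
          stop("planted envelope correlations are not jointly realizable",
               call. = FALSE)
        }
        Lc <- chol(Sig + diag(1e-9, k))
        Zm <- matrix(0, k, n)
        for (r in seq_len(k)) Zm[r, ] <- slow_modulator(n, fs)
        Mmod <- t(Lc) %*% Zm
        for (r in seq_len(k)) {
          m_r <- pmax(pmin(Mmod[r, ], 2), -2)
          env_r <- 1 + config$envelope_depth * m_r
          if (any(env_r <= 0)) {
            stop("envelope coupling produced non-positive envelopes; ",
                 "reduce envelope_depth", call. = FALSE)
          }
          band_sig[nodes[r], ] <- config$osc_amplitude * env_r *
            fm_carrier(n, fs, lo, hi)
        }
      }
      sig <- sig + band_sig
    }
    for (k in seq_len(p)) {
      sig[k, ] <- sig[k, ] + config$background_amplitude * one_over_f_noise(n, fs)
    }
    dat[tr, , ] <- mix %*% sig
  }
  motion <- stats::rlnorm(n_trials, meanlog = log(config$motion_median_mm),
                          sdlog = config$motion_sdlog)
  structure(list(
    data = dat, fs = fs, subject = subject, group = group,
    condition = condition,
    ground_truth = list(planted = active, motion_mm = motion,
                        leakage_matrix = mix)
  ), class = "parcel_timeseries")
}

#' Random leadfield with orthonormal columns
#'
#' Synthetic linear forward model: one column per parcel (scalar sources),
#' orthonormalized so the model is full column rank by construction.
#'
#' @param sensor_count Number of sensors (rows).
#' @param n_parcels Number of parcels (columns).
#' @return `sensor_count` x `n_parcels` matrix.
#' @export
make_leadfield <- function(sensor_count, n_parcels) {
  stopifnot(sensor_count >= n_parcels)
  qr.Q(qr(matrix(stats::rnorm(sensor_count * n_parcels), sensor_count)))
}

# ECG-like artifact time course: periodic sharp pulses plus baseline drift.
artifact_timecourse <- function(n, fs, rate_hz = 1.2) {
  tt <- seq_len(n) / fs
  phase <- (tt * rate_hz) %% 1
  pulses <- exp(-((phase - 0.5)^2) / (2 * 0.02^2))
  x <- pulses + 0.2 * sin(2 * pi * 0.3 * tt + stats::runif(1, 0, 2 * pi))
  (x - mean(x)) / stats::sd(x)
}

#' Project parcel signals into sensor space
#'
#' `sensors = leadfield %*% sources + artifact loadings %*% artifact time
#' courses + white noise`. The artifact time courses are returned alongside
#' as reference channels for automated artifact-component identification.
#'
#' @param source A `parcel_timeseries` (see [simulate_subject_timeseries()]).
#' @param leadfield Sensors x parcels matrix, full column rank.
#' @param artifact_loadings Sensors x k matrix of artifact mixing vectors,
#'   or `NULL` for none.
#' @param noise_sd White sensor-noise SD.
#' @param artifact_amplitude Scale of each artifact time course.
#' @return List with `data` (trials x sensors x samples), `fs`,
#'   `references` (trials x k x samples array or `NULL`), `loadings`.
#' @export
project_to_sensors <- function(source, leadfield, artifact_loadings = NULL,
                               noise_sd = 0, artifact_amplitude = 1) {
  stopifnot(inherits(source, "parcel_timeseries"))
  p <- dim(source$data)[2]
  if (ncol(leadfield) != p) stop("leadfield has wrong number of columns")
  if (qr(leadfield)$rank < ncol(leadfield)) {
    stop("leadfield is rank deficient; regularize or reduce parcel count",
         call. = FALSE)
  }
  n_trials <- dim(source$data)[1]
  n <- dim(source$data)[3]
  ns <- nrow(leadfield)
  k <- if (is.null(artifact_loadings)) 0L else ncol(artifact_loadings)
  out <- array(0, dim = c(n_trials, ns, n))
  refs <- if (k > 0) array(0, dim = c(n_trials, k, n)) else NULL
  for (tr in seq_len(n_trials)) {
    s <- leadfield %*% source$data[tr, , ]
    if (k > 0) {
      a <- matrix(0, k, n)
      for (ci in seq_len(k)) {
        a[ci, ] <- artifact_amplitude * artifact_timecourse(n, source$fs)
      }
      s <- s + artifact_loadings %*% a
      refs[tr, , ] <- a
    }
    if (noise_sd > 0) s <- s + matrix(stats::rnorm(ns * n, sd = noise_sd), ns)
    out[tr, , ] <- s
  }
  list(data = out, fs = source$fs, references = refs,
       loadings = artifact_loadings, subject = source$subject,
       group = source$group, condition = source$condition)
}
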