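test_that("epoching cuts 30 s trials into three 10 s chunks and drops remainders", {
  x <- matrix(rnorm(2 * 18000), 2)
  ep <- epoch_trials(x, 10, 600)
  expect_length(ep, 3)
  expect_true(all(vapply(ep, ncol, integer(1)) == 6000))
  expect_equal(do.call(cbind, ep), x)        # sample-conserving up to remainder
  expect_length(epoch_trials(rnorm(2000), 10, 200), 1)
  ep2 <- epoch_trials(rnorm(5000), 10, 200)  # 25 s at 200 Hz
  expect_length(ep2, 2)
  expect_error(epoch_trials(rnorm(100), 10, 200), "shorter")
})

test_that("motion rejection is strict at the threshold", {
  man <- toy_manifest("S1", 3, 3, motion = c(12, 0, 10, 9, 11, 2))
  res <- reject_motion_trials(man, 10)
  expect_equal(res$manifest$trial, c(2, 3, 4, 6))  # 12 and 11 dropped, 10 kept
  expect_equal(res$report$dropped_motion, 2)
  man$motion_mm[2] <- NA
  expect_error(reject_motion_trials(man, 10), "trial\\(s\\): 2")
})

test_that("minimum-trials QC excludes subjects and matches a counting oracle", {
  man <- rbind(toy_manifest("S1", 2, 5), toy_manifest("S2", 3, 3),
               toy_manifest("S3", 6, 2))
  qc <- qc_min_trials(man, 3)
  expect_equal(qc$included, "S2")
  qc_all <- qc_min_trials(rbind(toy_manifest("S1", 3, 3),
                                toy_manifest("S2", 4, 8)), 3)
  expect_equal(sort(qc_all$included), c("S1", "S2"))
  # independent group-by tally oracle
  tab <- table(man$subject, man$condition_response)
  oracle <- rownames(tab)[tab[, "familiar"] >= 3 & tab[, "unfamiliar"] >= 3]
  expect_equal(sort(qc$included), sort(oracle))
  # order independence
  set.seed(1)
  qc_shuf <- qc_min_trials(man[sample.int(nrow(man)), ], 3)
  expect_equal(sort(qc_shuf$included), sort(qc$included))
})

test_that("the filterbank passes in-band tones and stops out-of-band ones", {
  fs <- 600
  t <- seq_len(6000) / fs
  fb <- bandpass_filterbank(cos(2 * pi * 10 * t), canonical_bands(), fs)
  mid <- 2000:4000
  expect_gt(max(abs(fb$alpha[1, mid])), 0.95)
  expect_lt(max(abs(fb$alpha[1, mid])), 1.05)
  expect_lt(max(abs(fb$beta[1, mid])), 0.05)
  expect_error(bandpass_filterbank(rnorm(100),
                                   data.frame(label = "x", lo = 100, hi = 301),
                                   fs), "Nyquist")
})

test_that("the 60 Hz notch attenuates power-line interference by >= 20 dB", {
  fs <- 600
  t <- seq_len(6000) / fs
  x <- cos(2 * pi * 60 * t)
  fb <- bandpass_filterbank(x, data.frame(label = "g", lo = 40, hi = 70), fs,
                            notch_hz = 60)
  # periodogram oracle at 60 Hz
  pw <- function(y) {
    X <- Mod(stats::fft(y))^2
    freqs <- (seq_along(y) - 1) * fs / length(y)
    sum(X[abs(freqs - 60) < 0.5])
  }
  expect_lt(10 * log10(pw(fb$g[1, ]) / pw(x)), -20)
})

test_that("band-pass output concentrates spectral mass inside the band", {
  fs <- 600
  set.seed(2)
  wn <- rnorm(6000)
  fb <- bandpass_filterbank(wn, canonical_bands(), fs, notch_hz = NULL)
  bands <- canonical_bands()
  for (b in seq_len(nrow(bands))) {
    y <- fb[[b]][1, ]
    X <- Mod(stats::fft(y))^2
    freqs <- (seq_along(y) - 1) * fs / length(y)
    freqs <- pmin(freqs, fs - freqs)
    frac <- sum(X[freqs >= bands$lo[b] - 1 & freqs <= bands$hi[b] + 1]) / sum(X)
    expect_gt(frac, 0.95)
  }
})

test_that("two-pass filtering introduces zero net phase shift", {
  fs <- 200
  set.seed(3)
  x <- megfc:::bandlimited_noise(2000, fs, 8, 14)
  y <- bandpass_filterbank(x, one_band(), fs, notch_hz = NULL)$alpha[1, ]
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(abs(cc$acf))], 0)
})

test_that("clean sensor data passes through artifact removal almost unchanged", {
  set.seed(4)
  epochs <- array(rnorm(2 * 6 * 400), dim = c(2, 6, 400))
  res <- remove_artifact_components(epochs, references = NULL)
  expect_equal(res$report$n_removed, 0)
  for (tr in 1:2) {
    for (ch in 1:6) {
      expect_gt(stats::cor(res$epochs[tr, ch, ], epochs[tr, ch, ]), 0.99)
    }
  }
})

test_that("a planted high-amplitude artifact loses >= 90% of its variance", {
  set.seed(6)
  cfg <- simulation_config(n_parcels = 4, bands = one_band(),
                           sensor_count = 12, trial_duration_s = 5,
                           sampling_rate_hz = 200, seed = 6)
  st <- simulate_subject_timeseries(cfg, "S", "TD", "familiar", 3, seed = 6)
  L <- make_leadfield(12, 4)
  load <- matrix(rnorm(12), 12)
  sens <- project_to_sensors(st, L, load, noise_sd = 0.05,
                             artifact_amplitude = 8)
  clean_ref <- project_to_sensors(st, L, NULL, noise_sd = 0)
  res <- remove_artifact_components(sens$data, sens$references,
                                    max_components = 10, r_threshold = 0.4)
  expect_gte(res$report$n_removed, 1)
  v_before <- sum((sens$data - clean_ref$data)^2)
  v_after <- sum((res$epochs - clean_ref$data)^2)
  expect_lt(v_after / v_before, 0.10)
})

test_that("realistic contamination drops a few components, not dozens", {
  set.seed(8)
  cfg <- simulation_config(n_parcels = 4, bands = one_band(),
                           sensor_count = 16, trial_duration_s = 5,
                           sampling_rate_hz = 200, seed = 8)
  st <- simulate_subject_timeseries(cfg, "S", "TD", "familiar", 3, seed = 8)
  L <- make_leadfield(16, 4)
  load <- matrix(rnorm(16 * 3), 16)
  sens <- project_to_sensors(st, L, load, noise_sd = 0.05,
                             artifact_amplitude = 6)
  res <- remove_artifact_components(sens$data, sens$references,
                                    max_components = 60, r_threshold = 0.4)
  expect_gte(res$report$n_removed, 2)
  expect_lte(res$report$n_removed, 6)
})
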