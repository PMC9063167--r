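test_that("simulation is bit-identical given the same config and seed", {
  cfg <- simulation_config(n_subjects_per_group = 1, n_parcels = 4,
                           bands = one_band(), trial_duration_s = 5,
                           sampling_rate_hz = 200, seed = 7)
  a <- simulate_subject_timeseries(cfg, "S1", "TD", "familiar", 2, seed = 7)
  b <- simulate_subject_timeseries(cfg, "S1", "TD", "familiar", 2, seed = 7)
  expect_identical(a$data, b$data)
  expect_identical(a$ground_truth$motion_mm, b$ground_truth$motion_mm)
  c <- simulate_subject_timeseries(cfg, "S1", "TD", "familiar", 2, seed = 8)
  expect_false(identical(a$data, c$data))
})

test_that("ground truth is consistent with the dataset and config validation bites", {
  pl <- planted_edges("alpha", "wPLI", "*", "*", 1, 3, 0.8)
  cfg <- simulation_config(n_parcels = 4, bands = one_band(), planted = pl,
                           trial_duration_s = 5, sampling_rate_hz = 200)
  st <- simulate_subject_timeseries(cfg, "S1", "TD", "familiar", 1)
  expect_true(all(st$ground_truth$planted$i <= dim(st$data)[2]))
  expect_true(all(st$ground_truth$planted$j <= dim(st$data)[2]))
  expect_error(simulation_config(n_parcels = 4, bands = one_band(),
                                 planted = planted_edges("alpha", "wPLI",
                                                         "*", "*", 1, 9, 1)),
               "valid parcel indices")
  expect_error(simulation_config(envelope_depth = 0.6), "positive")
  expect_error(simulation_config(n_parcels = 4, bands = one_band(),
                                 planted = planted_edges("beta", "wPLI",
                                                         "*", "*", 1, 2, 1)),
               "band table")
})

test_that("planted edges only act in their configured group and condition", {
  pl <- planted_edges("alpha", "wPLI", "ASD", "unfamiliar", 1, 2, 1)
  cfg <- simulation_config(n_parcels = 3, bands = one_band(), planted = pl,
                           trial_duration_s = 5, sampling_rate_hz = 200)
  st_hit <- simulate_subject_timeseries(cfg, "S", "ASD", "unfamiliar", 1)
  st_miss <- simulate_subject_timeseries(cfg, "S", "TD", "unfamiliar", 1)
  expect_equal(nrow(st_hit$ground_truth$planted), 1)
  expect_equal(nrow(st_miss$ground_truth$planted), 0)
})

test_that("a zero effect size leaves planted pairs at null connectivity", {
  fs <- 200
  pl <- planted_edges("alpha", "wPLI", "*", "*", 1, 2, 0)
  cfg <- simulation_config(n_parcels = 4, bands = one_band(), planted = pl,
                           trial_duration_s = 5, sampling_rate_hz = fs,
                           seed = 3)
  st <- simulate_subject_timeseries(cfg, "S", "TD", "familiar", 50, seed = 3)
  wpli_tr <- function(tr, i, j) {
    fb <- bandpass_filterbank(st$data[tr, , ], one_band(), fs,
                              notch_hz = NULL)$alpha
    az <- analytic_signal(fb, fs, trim_s = 0.5)
    compute_wpli(az$z[i, ], az$z[j, ])
  }
  planted_vals <- vapply(1:50, wpli_tr, numeric(1), i = 1, j = 2)
  null_vals <- vapply(1:50, wpli_tr, numeric(1), i = 3, j = 4)
  expect_gt(stats::t.test(planted_vals, null_vals)$p.value, 0.01)
})

test_that("a planted phase edge at full effect dominates non-planted wPLI", {
  fs <- 200
  pl <- planted_edges("alpha", "wPLI", "*", "*", 1, 2, 1)
  cfg <- simulation_config(n_parcels = 6, bands = one_band(), planted = pl,
                           trial_duration_s = 5, sampling_rate_hz = fs,
                           seed = 9)
  st <- simulate_subject_timeseries(cfg, "S", "TD", "familiar", 30, seed = 9)
  mats <- lapply(1:30, function(tr) {
    fb <- bandpass_filterbank(st$data[tr, , ], one_band(), fs,
                              notch_hz = NULL)$alpha
    build_adjacency(list(fb), fs, metric = "wPLI", trim_s = 0.5)
  })
  W <- Reduce(`+`, mats) / 30
  others <- W[upper.tri(W)]
  others <- others[-1]                       # drop the (1,2) planted entry
  expect_gt(W[1, 2], stats::quantile(others, 0.95))
})

test_that("sensor projection obeys the linear forward model", {
  cfg <- simulation_config(n_parcels = 3, bands = one_band(),
                           sensor_count = 6, trial_duration_s = 2,
                           sampling_rate_hz = 200, seed = 2)
  st <- simulate_subject_timeseries(cfg, "S", "TD", "familiar", 2)
  # identity-padded leadfield, no artifacts, no noise: sensors == sources
  L <- rbind(diag(3), matrix(0, 3, 3))
  sens <- project_to_sensors(st, L, NULL, noise_sd = 0)
  expect_equal(sens$data[, 1:3, ], st$data, tolerance = 1e-12)
  expect_true(all(sens$data[, 4:6, ] == 0))
  # artifact variance bookkeeping: added power = |loading|^2 * artifact power
  load <- matrix(c(1, 2, 0, 0, 0, 0), 6)
  set.seed(4)
  sens_a <- project_to_sensors(st, L, load, noise_sd = 0,
                               artifact_amplitude = 1)
  added <- sum((sens_a$data - sens$data)^2)
  ref_power <- sum(sens_a$references^2)
  expect_equal(added, sum(load^2) * ref_power, tolerance = 1e-8)
  # orthonormal leadfield + no noise: least squares recovers the sources
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:3]
  sens_q <- project_to_sensors(st, Q, NULL, noise_sd = 0)
  rec <- t(Q) %*% sens_q$data[1, , ]
  expect_equal(rec, st$data[1, , ], tolerance = 1e-10)
  # rank-deficient leadfield errors with advice
  Lr <- cbind(L[, 1], L[, 1], L[, 2])
  expect_error(project_to_sensors(st, Lr), "rank deficient")
})

test_that("simulated motion exercises the 10 mm rejection rule", {
  cfg <- simulation_config(n_parcels = 2, bands = one_band(),
                           trial_duration_s = 2, sampling_rate_hz = 200,
                           motion_median_mm = 5, motion_sdlog = 0.5,
                           seed = 21)
  st <- simulate_subject_timeseries(cfg, "S", "TD", "familiar", 200,
                                    seed = 21)
  mm <- st$ground_truth$motion_mm
  expect_true(all(mm > 0))
  expect_gt(sum(mm > 10), 0)                  # some trials must be rejectable
  expect_lt(sum(mm > 10), 100)                # but not the majority
})
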