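test_that("the analytic signal recovers envelope, modulator and frequency", {
  fs <- 600
  t <- seq_len(6000) / fs
  az <- analytic_signal(cos(2 * pi * 10 * t), fs, trim_s = 1)
  expect_lt(max(abs(az$envelope - 1)), 0.01)
  # AM demodulation oracle
  x <- (1 + 0.5 * cos(2 * pi * 0.5 * t)) * cos(2 * pi * 20 * t)
  az2 <- analytic_signal(x, fs, trim_s = 1)
  modu <- (1 + 0.5 * cos(2 * pi * 0.5 * t))[601:5400]
  expect_gt(stats::cor(az2$envelope[1, ], modu), 0.99)
  # unwrapped phase derivative ~ 2*pi*10 rad/s
  dph <- diff(az$phase[1, ])
  dph[dph < -pi] <- dph[dph < -pi] + 2 * pi
  expect_lt(abs(mean(dph) * fs / (2 * pi) - 10) / 10, 0.01)
  # all-zero input: zero envelope, undefined phase
  az0 <- analytic_signal(rep(0, 100), fs)
  expect_true(all(az0$envelope == 0))
  expect_true(all(is.na(az0$phase)))
  expect_true(attr(az0, "degenerate"))
})

test_that("wPLI is 1 for a constant quarter-period lag and degenerate at zero lag", {
  fs <- 600
  t <- seq_len(3000) / fs
  zA <- analytic_signal(cos(2 * pi * 10 * t), fs)$z[1, ]
  zB <- analytic_signal(cos(2 * pi * 10 * (t - 1 / 40)), fs)$z[1, ]
  expect_equal(as.numeric(compute_wpli(zA, zB)), 1.0, tolerance = 1e-9)
  w0 <- compute_wpli(zA, zA)
  expect_equal(as.numeric(w0), 0)
  expect_true(attr(w0, "degenerate"))
  expect_error(compute_wpli(zA, zB[1:10]), "length")
})

test_that("wPLI matches a naive two-loop evaluation of its formula", {
  fs <- 200
  set.seed(1)
  for (rep in 1:5) {
    x <- megfc:::bandlimited_noise(600, fs, 8, 14)
    y <- 0.5 * c(x[-(1:3)], x[1:3]) + megfc:::bandlimited_noise(600, fs, 8, 14)
    zA <- analytic_signal(x, fs)$z[1, ]
    zB <- analytic_signal(y, fs)$z[1, ]
    num <- 0; den <- 0
    for (k in seq_along(zA)) {                # brute-force formula oracle
      im <- Im(zA[k] * Conj(zB[k]))
      num <- num + im
      den <- den + abs(im)
    }
    expect_equal(as.numeric(compute_wpli(zA, zB)), abs(num) / den,
                 tolerance = 1e-12)
  }
})

test_that("wPLI ignores zero-lag mixtures (leakage resistance)", {
  fs <- 200
  set.seed(2)
  a <- megfc:::bandlimited_noise(2000, fs, 8, 14)
  ind <- megfc:::bandlimited_noise(2000, fs, 8, 14)
  b <- 0.7 * a + 0.3 * ind
  za <- analytic_signal(a, fs)$z[1, ]
  zb <- analytic_signal(b, fs)$z[1, ]
  w_obs <- as.numeric(compute_wpli(za, zb))
  # permutation oracle: circular time shifts destroy any genuine phase lock
  null <- vapply(1:200, function(k) {
    s <- sample(100:1900, 1)
    as.numeric(compute_wpli(za, c(zb[(s + 1):2000], zb[1:s])))
  }, numeric(1))
  expect_lt(w_obs, stats::quantile(null, 0.95))
})

test_that("wPLI bounds and symmetries hold on random signals", {
  fs <- 200
  set.seed(3)
  for (rep in 1:10) {
    za <- analytic_signal(megfc:::bandlimited_noise(500, fs, 8, 14), fs)$z[1, ]
    zb <- analytic_signal(megfc:::bandlimited_noise(500, fs, 8, 14), fs)$z[1, ]
    w <- as.numeric(compute_wpli(za, zb))
    expect_gte(w, 0); expect_lte(w, 1)
    expect_equal(w, as.numeric(compute_wpli(zb, za)), tolerance = 1e-12)
    rot <- exp(1i * stats::runif(1, 0, 2 * pi))  # global phase rotation
    expect_equal(w, as.numeric(compute_wpli(za * rot, zb * rot)),
                 tolerance = 1e-9)
  }
})

test_that("AEC is a plain envelope correlation with its symmetries", {
  env <- abs(rnorm(500)) + 0.1
  expect_equal(as.numeric(compute_aec(env, env)), 1.0)
  set.seed(4)
  e1 <- abs(rnorm(500)) + 0.1; e2 <- abs(rnorm(500)) + 0.1
  a <- as.numeric(compute_aec(e1, e2))
  expect_equal(a, as.numeric(compute_aec(e2, e1)))
  expect_equal(a, as.numeric(compute_aec(3.7 * e1, e2)), tolerance = 1e-12)
  flagged <- compute_aec(rep(1, 500), e2)
  expect_true(is.na(flagged) && attr(flagged, "degenerate"))
  # independent envelopes hover near zero
  set.seed(5)
  vals <- vapply(1:20, function(k) {
    fs <- 200
    x <- analytic_signal(rnorm(6000), fs)
    y <- analytic_signal(rnorm(6000), fs)
    abs(as.numeric(compute_aec(x$envelope[1, ], y$envelope[1, ])))
  }, numeric(1))
  expect_gte(sum(vals < 0.05), 17)
})

test_that("adjacency matrices are symmetric, zero-diagonal, and ROI-consistent", {
  fs <- 200
  set.seed(6)
  epochs <- list(matrix(rnorm(5 * 600), 5), matrix(rnorm(5 * 600), 5))
  for (m in c("AEC", "wPLI")) {
    M <- build_adjacency(epochs, fs, metric = m, trim_s = 0.5)
    expect_equal(dim(M), c(5, 5))
    expect_equal(M, t(M))
    expect_true(all(diag(M) == 0))
    R <- build_adjacency(epochs, fs, metric = m, mode = "roi",
                         seeds = c(2, 4), trim_s = 0.5)
    expect_equal(dim(R), c(5, 2))
    expect_equal(R, M[, c(2, 4)])            # shared entries agree exactly
  }
  expect_error(build_adjacency(epochs, fs, mode = "roi", seeds = 9),
               "seed")
  expect_error(build_adjacency(epochs, fs, mode = "roi", seeds = NULL),
               "seed")
})

test_that("baselining is elementwise, linear, and shape-checked", {
  A1 <- matrix(0.4, 3, 3); A2 <- matrix(0.6, 3, 3); R <- matrix(0.3, 3, 3)
  expect_equal(average_and_baseline(list(A1, A2), list(R)),
               matrix(0.2, 3, 3))
  expect_equal(average_and_baseline(list(R), list(R)), matrix(0, 3, 3))
  a <- 2.5
  expect_equal(average_and_baseline(list(a * A1, a * A2), list(a * R)),
               a * average_and_baseline(list(A1, A2), list(R)))
  expect_error(average_and_baseline(list(A1), list(matrix(0, 2, 2))),
               "shape")
})
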