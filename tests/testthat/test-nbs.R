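test_that("edgewise statistics match closed forms", {
  p <- 4
  des <- nbs_design("between_groups", 3.0, 10)
  # identical groups: all t = 0
  set.seed(1)
  g <- random_symmetric_matrices(5, p)
  tmap <- edgewise_stats(list(group1 = g, group2 = g), des)
  expect_true(all(tmap == 0))
  # textbook two-sample t: means 0.5 vs 0.0, common SD 0.5, n = 24/24
  mk_const <- function(n, mu, sdev) {
    vals <- stats::qnorm(stats::ppoints(n))       # mean 0, then standardized
    vals <- (vals - mean(vals)) / stats::sd(vals) * sdev + mu
    lapply(vals, function(v) {
      M <- matrix(0, p, p); M[1, 2] <- M[2, 1] <- v; M
    })
  }
  t12 <- edgewise_stats(list(group1 = mk_const(24, 0.5, 0.5),
                             group2 = mk_const(24, 0.0, 0.5)), des)[1, 2]
  expect_equal(t12, 0.5 / (0.5 * sqrt(2 / 24)), tolerance = 1e-10)
  expect_equal(t12, 3.4641, tolerance = 1e-4)
})

test_that("the interaction F is the squared difference-score t everywhere", {
  p <- 6
  set.seed(2)
  dat <- list(group1_familiar = random_symmetric_matrices(8, p),
              group1_unfamiliar = random_symmetric_matrices(8, p),
              group2_familiar = random_symmetric_matrices(9, p),
              group2_unfamiliar = random_symmetric_matrices(9, p))
  Fmap <- edgewise_stats(dat, nbs_design("interaction_2x2", 7, 10))
  D1 <- mapply(function(a, b) a - b, dat$group1_familiar,
               dat$group1_unfamiliar, SIMPLIFY = FALSE)
  D2 <- mapply(function(a, b) a - b, dat$group2_familiar,
               dat$group2_unfamiliar, SIMPLIFY = FALSE)
  tmap <- edgewise_stats(list(group1 = D1, group2 = D2),
                         nbs_design("between_groups", 3, 10))
  expect_lt(max(abs(Fmap - tmap^2)), 1e-10)
})

test_that("suprathreshold components match a union-find oracle", {
  # path graph
  M <- matrix(0, 5, 5)
  for (e in list(c(1, 2), c(2, 3), c(3, 4))) {
    M[e[1], e[2]] <- M[e[2], e[1]] <- 5
  }
  comps <- extract_components(M, 3)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$n_edges, 3)
  expect_equal(comps[[1]]$n_nodes, 4)
  expect_equal(comps[[1]]$nodes, 1:4)
  expect_length(extract_components(M, 10), 0)
  # random maps vs an independent union-find re-implementation
  uf_components <- function(M, thr) {
    pr <- which(upper.tri(M) & M > thr, arr.ind = TRUE)
    parent <- seq_len(nrow(M))
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    for (r in seq_len(nrow(pr))) {
      parent[find(pr[r, 1])] <- find(pr[r, 2])
    }
    if (nrow(pr) == 0) return(integer(0))
    roots <- vapply(seq_len(nrow(pr)), function(r) find(pr[r, 1]), integer(1))
    sort(as.integer(table(roots)), decreasing = TRUE)
  }
  set.seed(3)
  for (rep in 1:10) {
    R <- matrix(0, 30, 30)
    R[upper.tri(R)] <- rnorm(30 * 29 / 2)
    R <- R + t(R)
    comps <- extract_components(R, 1.5)
    sizes <- vapply(comps, `[[`, integer(1), "n_edges")
    expect_equal(as.integer(sizes), uf_components(R, 1.5))
  }
})

test_that("raising the primary threshold never grows a component", {
  set.seed(4)
  R <- matrix(0, 20, 20)
  R[upper.tri(R)] <- rnorm(190, sd = 2)
  R <- R + t(R)
  thrs <- c(1, 2, 3)
  maxe <- vapply(thrs, function(th) {
    comps <- extract_components(R, th)
    if (length(comps) == 0) 0L else comps[[1]]$n_edges
  }, integer(1))
  expect_true(all(diff(maxe) <= 0))
})

test_that("the permutation p-value follows the (1+k)/(1+K) estimator", {
  set.seed(5)
  g1 <- random_symmetric_matrices(12, 10, clique_edges(3), 2.5)
  g2 <- random_symmetric_matrices(12, 10)
  res <- nbs_permutation_test(list(group1 = g1, group2 = g2),
                              nbs_design("between_groups", 3, 200, seed = 9))
  expect_gt(length(res$components), 0)
  K <- length(res$null_max)
  expect_equal(K, 200)
  for (cc in res$components) {
    expect_equal(cc$p_fwer,
                 (1 + sum(res$null_max >= cc$n_edges)) / (1 + K))
    expect_gte(cc$p_fwer, 1 / (1 + K))
    expect_lte(cc$p_fwer, 1)
  }
})

test_that("permutation results are reproducible and order-invariant under enumeration", {
  set.seed(6)
  g1 <- random_symmetric_matrices(5, 8, clique_edges(3), 2)
  g2 <- random_symmetric_matrices(5, 8)
  des <- nbs_design("between_groups", 2, 500, seed = 42)
  r1 <- suppressWarnings(nbs_permutation_test(list(group1 = g1, group2 = g2),
                                              des))
  r2 <- suppressWarnings(nbs_permutation_test(list(group1 = g1, group2 = g2),
                                              des))
  expect_identical(r1$null_max, r2$null_max)
  # subject order within groups must not matter when labelings are enumerated
  r3 <- suppressWarnings(nbs_permutation_test(
    list(group1 = g1[c(3, 1, 5, 2, 4)], group2 = g2[c(2, 5, 1, 4, 3)]), des))
  expect_equal(sort(r3$null_max), sort(r1$null_max))
  expect_equal(vapply(r3$components, `[[`, numeric(1), "p_fwer"),
               vapply(r1$components, `[[`, numeric(1), "p_fwer"))
  expect_warning(nbs_permutation_test(list(group1 = g1, group2 = g2), des),
                 "enumeration")
})

test_that("null NBS keeps the family-wise error near nominal at reduced scale", {
  set.seed(7)
  hits <- 0
  for (rep in 1:20) {
    g1 <- random_symmetric_matrices(10, 30)
    g2 <- random_symmetric_matrices(10, 30)
    res <- nbs_permutation_test(list(group1 = g1, group2 = g2),
                                nbs_design("between_groups", 3, 500,
                                           seed = 100 + rep))
    pmin_ <- if (length(res$components) == 0) 1 else
      min(vapply(res$components, `[[`, numeric(1), "p_fwer"))
    hits <- hits + (pmin_ < 0.05)
  }
  expect_lte(hits, 3)
})

test_that("a shared condition effect cancels in the interaction contrast", {
  set.seed(8)
  p <- 12
  base1 <- random_symmetric_matrices(10, p)
  base2 <- random_symmetric_matrices(10, p)
  shift <- matrix(0.8, p, p); diag(shift) <- 0
  dat <- list(group1_familiar = lapply(base1, function(M) M + shift),
              group1_unfamiliar = base1,
              group2_familiar = lapply(base2, function(M) M + shift),
              group2_unfamiliar = base2)
  Fmap <- edgewise_stats(dat, nbs_design("interaction_2x2", 7, 10))
  expect_lt(max(Fmap), stats::qf(0.9999, 1, 18))
})

test_that("Bonferroni families reproduce the 0.0125 and 0.025 thresholds", {
  b <- bonferroni_band_correction(c(0.012, 0.02), "between")
  expect_equal(b$threshold, 0.0125)
  expect_equal(b$significant, c(TRUE, FALSE))
  w <- bonferroni_band_correction(c(0.012, 0.03), "within")
  expect_equal(w$threshold, 0.025)
  expect_equal(w$significant, c(TRUE, FALSE))
  expect_equal(bonferroni_band_correction(0.04, 1)$threshold, 0.05)
  expect_error(bonferroni_band_correction(0.04, 0), "positive")
})

test_that("ROI maps embed symmetrically into the full node graph", {
  map <- matrix(seq_len(10), 5, 2)
  M <- embed_roi_map(map, seeds = c(2, 4), p = 5)
  expect_equal(M, t(M))
  expect_equal(M[1, 2], map[1, 1])
  expect_equal(M[5, 4], map[5, 2])
  expect_equal(M[1, 3], 0)                   # non-seed pair absent
  expect_true(all(diag(M) == 0))
})
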