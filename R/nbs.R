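#' NBS design specification
#'
#' Contrast, primary component-forming threshold, permutation count and
#' seed for a Network-Based Statistics analysis. Study defaults: primary
#' t thresholds 2.75/3.0/3.5 for AEC and 3.0 for wPLI, F = 7 for the 2x2
#' interaction, 5000 permutations.
#'
#' @param contrast One of `"between_groups"`, `"within_group_paired"`,
#'   `"interaction_2x2"`.
#' @param primary_threshold Edgewise t (or F, for the interaction)
#'   component-forming threshold.
#' @param n_permutations Number of permutations.
#' @param alpha Component-level significance level.
#' @param seed Integer seed for the permutation stream.
#' @return List of class `nbs_design`.
#' @export
nbs_design <- function(contrast = c("between_groups", "within_group_paired",
                                    "interaction_2x2"),
                       primary_threshold = 3.0, n_permutations = 5000L,
                       alpha = 0.05, seed = 1L) {
  contrast <- match.arg(contrast)
  stopifnot(primary_threshold > 0, n_permutations >= 1,
            alpha > 0, alpha < 1)
  structure(list(contrast = contrast, primary_threshold = primary_threshold,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 seed = as.integer(seed)),
            class = "nbs_design")
}

# --- edge vector <-> matrix helpers --------------------------------------

# pair (i, j) for each position of M[upper.tri(M)] (column-major order)
edge_pairs <- function(p) {
  which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
}

mat_to_edges <- function(M) M[upper.tri(M)]

edges_to_mat <- function(v, p) {
  M <- matrix(0, p, p)
  M[upper.tri(M)] <- v
  M + t(M)
}

# stack a list of p x p symmetric matrices into subjects x edges
stack_matrices <- function(mats) {
  do.call(rbind, lapply(mats, mat_to_edges))
}

#' Embed a rectangular ROI connectivity map into the full node graph
#'
#' ROI (parcels x seeds) maps are symmetrized onto the complete node set so
#' that NBS components may span seed and non-seed nodes; entries for pairs
#' of non-seed nodes are absent (zero).
#'
#' @param map Parcels x seeds matrix.
#' @param seeds Integer seed indices (column order of `map`).
#' @param p Total number of parcels.
#' @return p x p symmetric matrix.
#' @export
embed_roi_map <- function(map, seeds, p) {
  stopifnot(ncol(map) == length(seeds), nrow(map) == p)
  M <- matrix(0, p, p)
  for (k in seq_along(seeds)) {
    s <- seeds[k]
    M[, s] <- map[, k]
    M[s, ] <- map[, k]
  }
  diag(M) <- 0
  M
}

# --- vectorized edgewise t statistics ------------------------------------

# two-sample pooled t for each column of X (group g1 rows) vs rest
pooled_t_cols <- function(X, g1) {
  n <- nrow(X)
  n1 <- sum(g1); n2 <- n - n1
  X1 <- X[g1, , drop = FALSE]; X2 <- X[!g1, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- colSums(sweep(X1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(X2, 2, m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se < .Machine$double.eps, 0, (m1 - m2) / se)
  t
}

paired_t_cols <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m)^2) / (n - 1))
  ifelse(s < .Machine$double.eps, 0, m / (s / sqrt(n)))
}

#' Edgewise statistics for an NBS contrast
#'
#' `between_groups`: two-sample pooled-variance t per edge.
#' `within_group_paired`: paired t on the familiar - unfamiliar difference.
#' `interaction_2x2`: per-subject condition difference, then a two-sample t
#' across groups on the differences, reported as F = t^2 per edge. Edges
#' with zero within-cell variance get statistic 0.
#'
#' @param data Named list of lists of same-shape symmetric matrices:
#'   `between_groups` needs `group1`, `group2`;
#'   `within_group_paired` needs `familiar`, `unfamiliar` (paired by
#'   position); `interaction_2x2` needs `group1_familiar`,
#'   `group1_unfamiliar`, `group2_familiar`, `group2_unfamiliar`.
#' @param design An [nbs_design()].
#' @return p x p symmetric statistic matrix (t, or F for the interaction).
#' @export
edgewise_stats <- function(data, design) {
  stopifnot(inherits(design, "nbs_design"))
  p <- nrow(data[[1]][[1]])
  v <- switch(design$contrast,
    between_groups = {
      X <- rbind(stack_matrices(data$group1), stack_matrices(data$group2))
      g1 <- rep(c(TRUE, FALSE), c(length(data$group1), length(data$group2)))
      pooled_t_cols(X, g1)
    },
    within_group_paired = {
      stopifnot(length(data$familiar) == length(data$unfamiliar))
      D <- stack_matrices(data$familiar) - stack_matrices(data$unfamiliar)
      paired_t_cols(D)
    },
    interaction_2x2 = {
      D1 <- stack_matrices(data$group1_familiar) -
        stack_matrices(data$group1_unfamiliar)
      D2 <- stack_matrices(data$group2_familiar) -
        stack_matrices(data$group2_unfamiliar)
      t <- pooled_t_cols(rbind(D1, D2),
                         rep(c(TRUE, FALSE), c(nrow(D1), nrow(D2))))
      t^2
    })
  edges_to_mat(v, p)
}

# max component edge count from an edge index list (union-find)
max_component_edges <- function(ei, ej) {
  if (length(ei) == 0) return(0L)
  nodes <- sort(unique(c(ei, ej)))
  parent <- seq_along(nodes)
  idx <- function(v) match(v, nodes)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  ri <- idx(ei); rj <- idx(ej)
  for (k in seq_along(ri)) {
    ra <- find(ri[k]); rb <- find(rj[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(ri, find, integer(1))
  max(tabulate(roots))
}

#' Connected suprathreshold components of a statistic map
#'
#' Builds the undirected graph of edges whose statistic strictly exceeds
#' the threshold and returns its connected components, largest (by edge
#' count) first.
#'
#' @param stat_map p x p symmetric statistic matrix.
#' @param threshold Component-forming threshold (same units as the map).
#' @return List of components, each with `edges` (m x 2 matrix), `nodes`,
#'   `n_edges`, `n_nodes`, `stat_sum` (sum of suprathreshold statistics).
#' @export
extract_components <- function(stat_map, threshold) {
  stopifnot(nrow(stat_map) == ncol(stat_map))
  p <- nrow(stat_map)
  pairs <- edge_pairs(p)
  v <- stat_map[upper.tri(stat_map)]
  sup <- which(v > threshold)
  if (length(sup) == 0) return(list())
  el <- pairs[sup, , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    cbind(as.character(el[, 1]), as.character(el[, 2])), directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[as.character(el[, 1])]
  comps <- lapply(sort(unique(comp_of_edge)), function(cc) {
    sel <- comp_of_edge == cc
    edges <- el[sel, , drop = FALSE]
    colnames(edges) <- c("i", "j")
    list(edges = edges,
         nodes = sort(unique(as.vector(edges))),
         n_edges = sum(sel),
         n_nodes = length(unique(as.vector(edges))),
         stat_sum = sum(v[sup][sel]))
  })
  comps[order(vapply(comps, `[[`, integer(1), "n_edges"), decreasing = TRUE)]
}

# all distinct group-1 index sets if enumerable within limit, else NULL
enumerate_labelings <- function(n, n1, limit) {
  total <- choose(n, n1)
  if (total > limit) return(NULL)
  utils::combn(n, n1, simplify = FALSE)
}

#' Network-Based Statistics permutation test
#'
#' Observed suprathreshold components are scored by edge count; the null
#' distribution is the maximal component edge count over permuted
#' relabelings (group labels for between-group and interaction contrasts,
#' within-subject condition sign flips for the paired contrast). The
#' family-wise corrected p-value of each observed component is
#' `(1 + #permutation maxima >= observed) / (1 + n_permutations)`.
#' When fewer distinct relabelings exist than requested, all of them are
#' enumerated exactly (with a warning).
#'
#' @inheritParams edgewise_stats
#' @return List of class `nbs_result`: `components` (each with `p_fwer`),
#'   `stat_map`, `null_max` (permutation distribution), `design`.
#' @export
nbs_permutation_test <- function(data, design) {
  stopifnot(inherits(design, "nbs_design"))
  p <- nrow(data[[1]][[1]])
  thr <- design$primary_threshold
  pairs <- edge_pairs(p)

  if (design$contrast %in% c("between_groups", "interaction_2x2")) {
    if (design$contrast == "between_groups") {
      X <- rbind(stack_matrices(data$group1), stack_matrices(data$group2))
      n1 <- length(data$group1)
    } else {
      D1 <- stack_matrices(data$group1_familiar) -
        stack_matrices(data$group1_unfamiliar)
      D2 <- stack_matrices(data$group2_familiar) -
        stack_matrices(data$group2_unfamiliar)
      X <- rbind(D1, D2)
      n1 <- nrow(D1)
    }
    n <- nrow(X); n2 <- n - n1
    obs_v <- pooled_t_cols(X, seq_len(n) <= n1)
    if (design$contrast == "interaction_2x2") obs_v <- obs_v^2
    exact <- enumerate_labelings(n, n1, design$n_permutations)
    set.seed(design$seed)
    if (!is.null(exact)) {
      warning("fewer distinct relabelings than requested permutations; ",
              "using exact enumeration (", length(exact), ")")
      G <- t(vapply(exact, function(ix) as.numeric(seq_len(n) %in% ix),
                    numeric(n)))
    } else {
      G <- t(vapply(seq_len(design$n_permutations),
                    function(k) as.numeric(seq_len(n) %in% sample.int(n, n1)),
                    numeric(n)))
    }
    # all-permutation pooled t via two matrix products
    S_tot <- colSums(X); Q_tot <- colSums(X^2)
    S1 <- G %*% X; Q1 <- G %*% X^2
    S2 <- sweep(-S1, 2, S_tot, `+`); Q2 <- sweep(-Q1, 2, Q_tot, `+`)
    m1 <- S1 / n1; m2 <- S2 / n2
    v1 <- (Q1 - S1^2 / n1) / (n1 - 1)
    v2 <- (Q2 - S2^2 / n2) / (n2 - 1)
    se <- sqrt(pmax(((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2), 0) *
                 (1 / n1 + 1 / n2))
    Tm <- ifelse(se < .Machine$double.eps, 0, (m1 - m2) / se)
    if (design$contrast == "interaction_2x2") Tm <- Tm^2
  } else {                                   # within_group_paired
    stopifnot(length(data$familiar) == length(data$unfamiliar))
    D <- stack_matrices(data$familiar) - stack_matrices(data$unfamiliar)
    n <- nrow(D)
    obs_v <- paired_t_cols(D)
    set.seed(design$seed)
    if (2^n <= design$n_permutations) {
      warning("fewer distinct sign flips than requested permutations; ",
              "using exact enumeration (", 2^n, ")")
      Fm <- t(vapply(seq_len(2^n) - 1L, function(k) {
        2 * as.numeric(bitwAnd(k, 2^(seq_len(n) - 1L)) > 0) - 1
      }, numeric(n)))
    } else {
      Fm <- matrix(sample(c(-1, 1), design$n_permutations * n, replace = TRUE),
                   ncol = n)
    }
    q <- colSums(D^2) / n
    M <- Fm %*% D / n
    varm <- sweep(-(M^2), 2, q, `+`) * n / (n - 1)
    se <- sqrt(pmax(varm, 0) / n)
    Tm <- ifelse(se < .Machine$double.eps, 0, M / se)
  }

  obs_map <- edges_to_mat(obs_v, p)
  comps <- extract_components(obs_map, thr)
  null_max <- vapply(seq_len(nrow(Tm)), function(k) {
    sup <- which(Tm[k, ] > thr)
    max_component_edges(pairs[sup, 1], pairs[sup, 2])
  }, numeric(1))
  K <- length(null_max)
  comps <- lapply(comps, function(cc) {
    cc$p_fwer <- (1 + sum(null_max >= cc$n_edges)) / (1 + K)
    cc
  })
  structure(list(components = comps, stat_map = obs_map,
                 null_max = null_max, design = design),
            class = "nbs_result")
}

#' Bonferroni correction across frequency bands within an analysis family
#'
#' Per-test significance threshold `alpha / family_size`, applied within
#' metric. With `alpha = 0.05`, the between-group family (size 4) gives the
#' 0.0125 threshold and the within-group family (size 2) gives 0.025.
#'
#' @param p Numeric vector of component p-values.
#' @param family `"between"` (size 4), `"within"` (size 2), or a positive
#'   integer family size.
#' @param alpha Family-wise alpha (default 0.05).
#' @return List with `threshold`, `significant` (logical vector), `family_size`.
#' @export
bonferroni_band_correction <- function(p, family = c("between", "within"),
                                       alpha = 0.05) {
  if (is.numeric(family)) {
    fam_size <- family
  } else {
    family <- match.arg(family)
    fam_size <- c(between = 4, within = 2)[[family]]
  }
  if (fam_size <= 0) stop("family size must be positive", call. = FALSE)
  thr <- alpha / fam_size
  list(threshold = thr, significant = p < thr, family_size = fam_size)
}
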