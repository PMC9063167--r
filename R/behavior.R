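#' Network strength of a subject's connectivity matrix over an edge set
#'
#' Sum of the matrix entries over the given undirected edges, each edge
#' counted once — the per-subject scalar summary correlated with
#' behavioral scores.
#'
#' @param matrix Square connectivity matrix.
#' @param edges m x 2 matrix (or data.frame) of node index pairs.
#' @return Numeric scalar (0 for an empty edge set).
#' @export
network_strength <- function(matrix, edges) {
  edges <- as.matrix(edges)
  if (nrow(edges) == 0) return(0)
  if (any(edges < 1 | edges > nrow(matrix))) {
    stop("edge index outside matrix bounds", call. = FALSE)
  }
  sum(matrix[edges])
}

#' Correlate per-subject network strengths with a behavioral score
#'
#' Pearson correlation with a two-sided p-value from the t transform,
#' uncorrected. Subjects with a missing score (or strength) are dropped
#' pairwise; at least 3 complete pairs are required.
#'
#' @param strengths Numeric vector of per-subject network strengths.
#' @param scores Numeric vector of behavioral scores, same order.
#' @return List with `r`, `p`, `n` (pairs used after missing-data removal).
#' @export
correlate_with_behavior <- function(strengths, scores) {
  stopifnot(length(strengths) == length(scores))
  ok <- is.finite(strengths) & is.finite(scores)
  x <- strengths[ok]; y <- scores[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs", call. = FALSE)
  if (stats::sd(x) < .Machine$double.eps ||
      stats::sd(y) < .Machine$double.eps) {
    stop("zero variance in strengths or scores", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' Recomputes a group comparison from printed mean, SD and n (e.g. for
#' cohort demographic tables); pooled variance, `df = n1 + n2 - 2`.
#'
#' @param mean1,sd1,n1 Group 1 summaries.
#' @param mean2,sd2,n2 Group 2 summaries.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
summary_group_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(is.finite(mean1), is.finite(mean2),
            sd1 > 0 || sd2 > 0, n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
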