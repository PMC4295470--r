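# Rank tests used for the window comparisons. Small samples are handled by
# exact enumeration over midranks (valid with ties); larger samples fall back
# to the tie-corrected normal approximation of stats::wilcox.test.

#' Two-sample rank-sum (Wilcoxon/Mann-Whitney) test
#'
#' Exact enumeration of the permutation distribution of the rank sum
#' (midranks for ties) when both samples have at most `exact_max`
#' observations; otherwise the tie-corrected normal approximation.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or `"less"`.
#' @param exact_max exact-enumeration size cutoff per sample.
#' @return list: `statistic` (rank sum of `x`), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                          exact_max = 10L) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each sample needs >= 2 values", call. = FALSE)
  r <- rank(c(x, y))                     # midranks
  w_obs <- sum(r[seq_len(nx)])
  if (nx <= exact_max && ny <= exact_max) {
    combs <- utils::combn(nx + ny, nx)
    sums <- colSums(matrix(r[combs], nrow = nx))
    eps <- 1e-9
    p_ge <- mean(sums >= w_obs - eps)
    p_le <- mean(sums <= w_obs + eps)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_ge, p_le)),
                greater = p_ge,
                less = p_le)
    return(list(statistic = w_obs, p_value = p, method = "exact rank-sum"))
  }
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = switch(alternative, two.sided = "two.sided",
                               greater = "greater", less = "less"),
    exact = FALSE, correct = TRUE))
  list(statistic = w_obs, p_value = wt$p.value,
       method = "normal-approximation rank-sum")
}

#' One-sample signed-rank test against a reference value
#'
#' Zero differences are dropped (standard practice). Exact sign-flip
#' enumeration over midranks of |differences| for at most `exact_max`
#' non-zero differences; otherwise the normal approximation.
#'
#' @param x numeric sample.
#' @param mu reference value (e.g. 1 for a neutrality test on omega).
#' @param alternative `"greater"` (median > mu), `"less"`, or `"two.sided"`.
#' @param exact_max exact-enumeration cutoff.
#' @return list: `statistic` (positive-rank sum), `p_value`, `n_used`, `method`.
#' @export
signed_rank_test <- function(x, mu = 1,
                             alternative = c("greater", "less", "two.sided"),
                             exact_max = 10L) {
  alternative <- match.arg(alternative)
  d <- x[is.finite(x)] - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                method = "degenerate (all values equal reference)"))
  }
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sums <- as.vector(signs %*% r)
    eps <- 1e-9
    p_ge <- mean(sums >= v_obs - eps)
    p_le <- mean(sums <= v_obs + eps)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    return(list(statistic = v_obs, p_value = p, n_used = n,
                method = "exact signed-rank"))
  }
  wt <- suppressWarnings(stats::wilcox.test(
    d, mu = 0, alternative = alternative, exact = FALSE, correct = TRUE))
  list(statistic = v_obs, p_value = wt$p.value, n_used = n,
       method = "normal-approximation signed-rank")
}
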