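#' Sliding-window Ka/Ks profile for one sequence group
#'
#' Windows of `window_nt` nucleotides advance by `step_nt` along the codon
#' alignment (alignment coordinates; gap columns count toward the window).
#' Within each window, Ka/Ks is estimated for every unordered pair of group
#' members; pairs with fewer than `min_codons` comparable codons in the
#' window, and pairs whose ratio is undefined or saturated there, are
#' excluded from the window mean and SEM (exclusions are counted).
#'
#' @param aln [codon_alignment()].
#' @param group character vector of member ids (>= 2, all in `aln`).
#' @param window_nt window size in nt (default 75 = 25 codons).
#' @param step_nt step in nt (default 15); both must be multiples of 3.
#' @param method `"NG86"` or `"YN-approx"`.
#' @param min_codons minimum comparable codons for a pair in a window.
#' @param group_label label carried into the output.
#' @return tibble: group, window_index (1-based), start_nt (0-based),
#'   start_1based_nt, n_pairs_used, n_excluded, mean_omega, sem_omega, and a
#'   list-column `omegas` with the defined per-pair ratios.
#' @export
window_profile <- function(aln, group, window_nt = 75L, step_nt = 15L,
                           method = c("NG86", "YN-approx"), min_codons = 10L,
                           group_label = "group") {
  method <- match.arg(method)
  if (window_nt %% 3L != 0L || step_nt %% 3L != 0L) {
    stop("window_nt and step_nt must be multiples of 3", call. = FALSE)
  }
  missing_ids <- setdiff(group, names(aln))
  if (length(missing_ids)) {
    stop("group members not in alignment: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  if (length(group) < 2L) stop("group must have >= 2 members", call. = FALSE)
  L <- nchar(aln[[1L]])
  if (window_nt > L) {
    stop("alignment (", L, " nt) shorter than one window", call. = FALSE)
  }
  starts <- seq(0L, L - window_nt, by = step_nt)
  wcod <- window_nt %/% 3L
  scod <- step_nt %/% 3L

  pairs <- utils::combn(group, 2L)
  counts <- lapply(seq_len(ncol(pairs)), function(k) {
    pair_codon_counts(aln[[pairs[1L, k]]], aln[[pairs[2L, k]]], method = method)
  })

  rows <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    cod_idx <- (starts[w] %/% 3L) + seq_len(wcod)
    omegas <- numeric(0)
    n_excl <- 0L
    for (k in seq_along(counts)) {
      cc <- counts[[k]]
      comp <- cc$comparable[cod_idx]
      if (sum(comp) < min_codons) { n_excl <- n_excl + 1L; next }
      idx <- cod_idx[comp]
      est <- kaks_from_counts(sum(cc$s_sites[idx]), sum(cc$n_sites[idx]),
                              sum(cc$sd[idx]), sum(cc$nd[idx]),
                              n_comparable = length(idx))
      if (est$omega_flag == "ok") {
        omegas <- c(omegas, est$omega)
      } else {
        n_excl <- n_excl + 1L
      }
    }
    n <- length(omegas)
    rows[[w]] <- tibble(
      group = group_label, window_index = w, start_nt = starts[w],
      start_1based_nt = starts[w] + 1L,
      n_pairs_used = n, n_excluded = n_excl,
      mean_omega = if (n) mean(omegas) else NA_real_,
      sem_omega = if (n > 1L) stats::sd(omegas) / sqrt(n) else NA_real_,
      omegas = list(omegas))
  }
  do.call(rbind, rows)
}

#' Per-window comparison of two group profiles
#'
#' Two-sided rank-sum test on the per-pair omega lists of corresponding
#' windows, with the significance rule "p < alpha and fold change > fold_min".
#' Windows where either side has fewer than two defined ratios are skipped
#' (flagged in the output, not dropped).
#'
#' @param p1,p2 window profiles from [window_profile()] with identical window
#'   geometry (`start_nt` must match).
#' @param alpha significance level (default 1e-4).
#' @param fold_min minimum fold increase of mean(p1)/mean(p2) (default 2).
#' @return tibble: window_index, start_nt, group1, group2, n1, n2, statistic,
#'   p_value, fold_change, flag_significant, skipped.
#' @export
compare_window_groups <- function(p1, p2, alpha = 1e-4, fold_min = 2) {
  if (!identical(p1$start_nt, p2$start_nt)) {
    stop("profiles do not share window geometry", call. = FALSE)
  }
  rows <- vector("list", nrow(p1))
  for (w in seq_len(nrow(p1))) {
    o1 <- p1$omegas[[w]]; o2 <- p2$omegas[[w]]
    if (length(o1) < 2L || length(o2) < 2L) {
      rows[[w]] <- tibble(window_index = p1$window_index[w],
                          start_nt = p1$start_nt[w],
                          group1 = p1$group[w], group2 = p2$group[w],
                          n1 = length(o1), n2 = length(o2),
                          statistic = NA_real_, p_value = NA_real_,
                          fold_change = NA_real_, flag_significant = FALSE,
                          skipped = TRUE)
      next
    }
    tst <- rank_sum_test(o1, o2, alternative = "two.sided")
    fold <- mean(o1) / mean(o2)
    rows[[w]] <- tibble(window_index = p1$window_index[w],
                        start_nt = p1$start_nt[w],
                        group1 = p1$group[w], group2 = p2$group[w],
                        n1 = length(o1), n2 = length(o2),
                        statistic = tst$statistic, p_value = tst$p_value,
                        fold_change = fold,
                        flag_significant = !is.na(tst$p_value) &&
                          tst$p_value < alpha && fold > fold_min,
                        skipped = FALSE)
  }
  out <- do.call(rbind, rows)
  n_skip <- sum(out$skipped)
  if (n_skip) message(n_skip, " window(s) skipped (fewer than 2 defined ratios)")
  out
}

#' Window-vs-window comparison within one group
#'
#' Rank-sum comparison of the omega lists of two windows of the same profile,
#' e.g. an evidently relaxed window against the window with the lowest mean.
#'
#' @param profile a [window_profile()] result.
#' @param window_a,window_b window indices (1-based).
#' @inheritParams compare_window_groups
#' @return one-row tibble like [compare_window_groups()].
#' @export
compare_windows_within <- function(profile, window_a, window_b,
                                   alpha = 1e-4, fold_min = 2) {
  o1 <- profile$omegas[[window_a]]; o2 <- profile$omegas[[window_b]]
  if (length(o1) < 2L || length(o2) < 2L) {
    stop("both windows need >= 2 defined ratios", call. = FALSE)
  }
  tst <- rank_sum_test(o1, o2, alternative = "two.sided")
  fold <- mean(o1) / mean(o2)
  tibble(window_index = window_a, vs_window = window_b,
         group = profile$group[window_a],
         n1 = length(o1), n2 = length(o2),
         statistic = tst$statistic, p_value = tst$p_value,
         fold_change = fold,
         flag_significant = tst$p_value < alpha && fold > fold_min)
}

#' Test whether a window's omega distribution exceeds one
#'
#' One-sided signed-rank test of the per-pair ratios against 1
#' (H1: median > 1); used to ask whether apparent relaxation crosses into
#' positive selection.
#'
#' @param omegas numeric vector of defined per-pair ratios (>= 2 values), or a
#'   one-row slice of a [window_profile()] tibble.
#' @param alpha significance level (default 0.05).
#' @return list: `p_value`, `exceeds_one`, `n_used`.
#' @export
test_window_vs_one <- function(omegas, alpha = 0.05) {
  if (is.data.frame(omegas)) omegas <- omegas$omegas[[1L]]
  if (length(omegas) < 2L) stop("need >= 2 defined ratios", call. = FALSE)
  tst <- signed_rank_test(omegas, mu = 1, alternative = "greater")
  list(p_value = tst$p_value, exceeds_one = tst$p_value < alpha,
       n_used = tst$n_used)
}
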