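test_that("window geometry follows floor((L - 75)/15) + 1", {
  fam <- simulate_family(sim_config(n_groups = 1, members_per_group = 3,
                                    n_codons = 165, seed = 2))
  wp <- window_profile(fam$alignment, fam$groups$g1)
  expect_equal(nrow(wp), floor((495 - 75) / 15) + 1)  # 29 windows
  expect_equal(wp$start_nt, seq(0, 420, by = 15))
  expect_equal(wp$start_1based_nt, wp$start_nt + 1L)

  cfg <- sim_config(n_groups = 1, members_per_group = 2, n_codons = 25,
                    region_map = tibble::tibble(start = 0L, end = 25L,
                                                omega = 0.5),
                    anchors = tibble::tibble(subdomain = character(0),
                                             motif = character(0),
                                             codon_start = integer(0)),
                    seed = 3)
  one <- simulate_family(cfg)
  wp1 <- window_profile(one$alignment, one$groups$g1)
  expect_equal(nrow(wp1), 1)
  expect_equal(wp1$start_nt, 0L)

  expect_error(window_profile(one$alignment, one$groups$g1, window_nt = 90),
               "shorter than one window")
  expect_error(window_profile(one$alignment, one$groups$g1[1]),
               ">= 2 members")
  expect_error(window_profile(one$alignment, one$groups$g1, window_nt = 70),
               "multiples of 3")
})

test_that("identical sequences produce all-excluded windows with NA means", {
  s <- strrep("ATGGCTAAAGTT", 10)  # 120 nt
  aln <- codon_alignment(c(a = s, b = s, c = s))
  wp <- window_profile(aln, c("a", "b", "c"))
  expect_true(all(is.na(wp$mean_omega)))
  expect_true(all(wp$n_pairs_used == 0))
  expect_true(all(wp$n_excluded == 3))  # all pairs undefined (Ka=Ks=0)
})

test_that("group comparison flags require both p < alpha and fold > fold_min", {
  mk_profile <- function(omegas_list, label) {
    tibble::tibble(group = label, window_index = seq_along(omegas_list),
                   start_nt = (seq_along(omegas_list) - 1L) * 15L,
                   start_1based_nt = (seq_along(omegas_list) - 1L) * 15L + 1L,
                   n_pairs_used = lengths(omegas_list), n_excluded = 0L,
                   mean_omega = vapply(omegas_list, mean, 0),
                   sem_omega = NA_real_, omegas = omegas_list)
  }
  o <- seq(0.2, 0.8, length.out = 20)
  p1 <- mk_profile(list(o, o * 10), "g1")
  p2 <- mk_profile(list(o, o), "g2")
  cmp <- suppressMessages(compare_window_groups(p1, p2))

  # identical lists: p ~ 1, fold 1, not significant
  expect_gt(cmp$p_value[1], 0.99)
  expect_equal(cmp$fold_change[1], 1)
  expect_false(cmp$flag_significant[1])

  # complete separation at n = 20 vs 20: exact tail 2/choose(40,20)
  expect_lt(cmp$p_value[2], 1e-4)
  expect_equal(cmp$fold_change[2], 10)
  expect_true(cmp$flag_significant[2])

  # a side with < 2 defined ratios is skipped with a message
  p3 <- mk_profile(list(o, numeric(0)), "g3")
  expect_message(cmp3 <- compare_window_groups(p1, p3), "skipped")
  expect_true(cmp3$skipped[2])
  expect_false(cmp3$flag_significant[2])

  expect_error(compare_window_groups(p1, mk_profile(list(o), "g4")),
               "window geometry")
})

test_that("rank-sum p-values match exact enumeration for small samples", {
  set.seed(5)
  for (k in 1:5) {
    x <- round(stats::runif(sample(4:7, 1)), 2)
    y <- round(stats::runif(sample(4:7, 1)), 2)
    got <- rank_sum_test(x, y)$p_value
    expect_equal(got, oracle_rank_sum_p(x, y), tolerance = 1e-12)
  }
  # tie-free case cross-checked against the standard exact implementation
  x <- c(0.1, 0.5, 0.9, 1.4); y <- c(0.2, 0.6, 1.0, 1.1)
  expect_equal(rank_sum_test(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("window-vs-1 test follows the exact signed-rank distribution", {
  low <- rep(0.1, 10)
  t_low <- test_window_vs_one(low)
  expect_false(t_low$exceeds_one)

  high <- rep(5.0, 10)
  t_high <- test_window_vs_one(high)
  expect_equal(t_high$p_value, 1 / 1024, tolerance = 1e-12)
  expect_true(t_high$exceeds_one)

  # degenerate case: every ratio exactly 1 -> p = 1
  ones <- rep(1, 8)
  t_one <- test_window_vs_one(ones)
  expect_equal(t_one$p_value, 1)
  expect_false(t_one$exceeds_one)

  expect_error(test_window_vs_one(0.5), ">= 2 defined ratios")

  # general agreement with independent enumeration
  set.seed(2)
  for (k in 1:5) {
    x <- round(stats::runif(8, 0.5, 1.5), 2)
    expect_equal(signed_rank_test(x, mu = 1, alternative = "greater")$p_value,
                 oracle_signed_rank_p(x, 1), tolerance = 1e-12)
  }
})

test_that("window-vs-window comparison within a group works", {
  o1 <- seq(1, 2, length.out = 12)
  o2 <- o1 / 8
  prof <- tibble::tibble(group = "g", window_index = 1:2,
                         start_nt = c(0L, 15L), start_1based_nt = c(1L, 16L),
                         n_pairs_used = 12L, n_excluded = 0L,
                         mean_omega = c(mean(o1), mean(o2)),
                         sem_omega = NA_real_, omegas = list(o1, o2))
  cmp <- compare_windows_within(prof, 1, 2)
  expect_true(cmp$flag_significant)
  expect_equal(cmp$fold_change, 8)
})

test_that("window sums equal whole-pair estimates on a window-sized alignment", {
  cfg <- sim_config(n_groups = 1, members_per_group = 4, n_codons = 25,
                    region_map = tibble::tibble(start = 0L, end = 25L,
                                                omega = 0.6),
                    anchors = tibble::tibble(subdomain = character(0),
                                             motif = character(0),
                                             codon_start = integer(0)),
                    seed = 41)
  fam <- simulate_family(cfg)
  wp <- window_profile(fam$alignment, fam$groups$g1)
  pairs <- utils::combn(fam$groups$g1, 2)
  direct <- vapply(seq_len(ncol(pairs)), function(k) {
    e <- kaks_pair(fam$alignment[[pairs[1, k]]], fam$alignment[[pairs[2, k]]])
    if (e$omega_flag == "ok") e$omega else NA_real_
  }, 0)
  expect_equal(sort(wp$omegas[[1]]), sort(direct[!is.na(direct)]),
               tolerance = 1e-12)
})
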