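test_that("the TTT/TTC single-difference codon pair is counted by hand", {
  # TTT (Phe) vs TTC (Phe): third-position change is synonymous.
  # NG86 sites for both codons: only the third position carries 1/3
  # synonymous site, so per-codon S = 1/3, N = 8/3.
  rest <- strrep("GAA", 9)
  e <- kaks_pair(paste0("TTT", rest), paste0("TTC", rest))
  expect_equal(e$Sd, 1)
  expect_equal(e$Nd, 0)
  ttt_s <- oracle_syn_sites("TTT")
  expect_equal(ttt_s, 1 / 3)
  expect_equal(3 - ttt_s, 8 / 3)
  expect_gt(e$Ks, 0)
  expect_equal(e$Ka, 0)
  expect_equal(e$omega, 0)
})

test_that("identical rows give zero rates and an undefined ratio", {
  s <- strrep("ATGGCTAAA", 5)
  e <- kaks_pair(s, s)
  expect_equal(e$Nd, 0)
  expect_equal(e$Sd, 0)
  expect_equal(e$Ka, 0)
  expect_equal(e$Ks, 0)
  expect_identical(e$omega_flag, "undefined_na")
  expect_true(is.na(e$omega))
})

test_that("site counts satisfy N + S = 3 per comparable codon and symmetry", {
  set.seed(13)
  cods <- rlkscan:::sense_codons(rlkscan:::genetic_code())
  for (k in 1:10) {
    a <- paste(sample(cods, 30, replace = TRUE), collapse = "")
    b <- paste(sample(cods, 30, replace = TRUE), collapse = "")
    e1 <- kaks_pair(a, b)
    e2 <- kaks_pair(b, a)
    expect_equal(e1$N + e1$S, 3 * e1$n_codons_compared, tolerance = 1e-9)
    expect_equal(e1[c("N", "S", "Nd", "Sd", "Ka", "Ks")],
                 e2[c("N", "S", "Nd", "Sd", "Ka", "Ks")], tolerance = 1e-12)
  }
})

test_that("gap and ambiguity codons are skipped, saturation is flagged", {
  a <- "ATG---GCTANA"
  b <- "ATGAAAGCAAAA"
  e <- kaks_pair(a, b)
  expect_equal(e$n_codons_compared, 2)  # ATG/ATG and GCT/GCA
  expect_equal(e$n_codons_skipped, 2)

  # maximally different codons at every position saturate the correction
  a2 <- strrep("ATG", 4)
  b2 <- strrep("CGC", 4)
  e2 <- kaks_pair(a2, b2)
  expect_identical(e2$omega_flag, "saturated")
  expect_error(kaks_pair("---", "ATG"), "no comparable codons")
})

test_that("NG86 omega recovers the simulated omega at kappa = 2, omega = 0.2", {
  # 100-codon pairs at moderate divergence; mean estimate within +-0.1
  est <- numeric(50)
  empty_anchors <- tibble::tibble(subdomain = character(0),
                                  motif = character(0),
                                  codon_start = integer(0))
  for (r in seq_len(50)) {
    cfg <- sim_config(n_groups = 1, members_per_group = 2, n_codons = 100,
                      kappa = 2, branch_length = 0.15,
                      group_branch_length = 0,
                      region_map = tibble::tibble(start = 0L, end = 100L,
                                                  omega = 0.2),
                      anchors = empty_anchors, rd_per_group = TRUE,
                      seed = 300 + r)
    fam <- simulate_family(cfg)
    e <- kaks_pair(fam$alignment[[1]], fam$alignment[[2]])
    est[r] <- if (e$omega_flag == "ok") e$omega else NA_real_
  }
  expect_lt(abs(mean(est, na.rm = TRUE) - 0.2), 0.1)
})

test_that("the kappa-weighted estimator runs and reports its kappa", {
  cfg <- sim_config(n_groups = 1, members_per_group = 2, n_codons = 150,
                    kappa = 4, branch_length = 0.3, group_branch_length = 0,
                    region_map = tibble::tibble(start = 0L, end = 150L,
                                                omega = 0.3),
                    anchors = tibble::tibble(subdomain = character(0),
                                             motif = character(0),
                                             codon_start = integer(0)),
                    seed = 77)
  fam <- simulate_family(cfg)
  e <- kaks_pair(fam$alignment[[1]], fam$alignment[[2]], method = "YN-approx")
  expect_identical(e$method, "YN-approx")
  expect_true(e$kappa >= 0.5 && e$kappa <= 20)
  expect_equal(e$N + e$S, 3 * e$n_codons_compared, tolerance = 1e-9)
})
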