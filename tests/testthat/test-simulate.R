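test_that("zero branch lengths yield members identical to the ancestor", {
  fam <- simulate_family(sim_config(n_groups = 2, members_per_group = 3,
                                    branch_length = 0,
                                    group_branch_length = 0, seed = 1))
  seqs <- unclass(fam$alignment)
  expect_equal(length(unique(seqs[fam$groups$g1])), 1)
  # groups differ only at the planted RD/non-RD codon when labels differ
  expect_true(is.null(fam$truth) || nrow(fam$truth) == 0)
})

test_that("omega = 0 forbids non-synonymous substitutions", {
  cfg <- sim_config(n_groups = 1, members_per_group = 4,
                    branch_length = 0.4, group_branch_length = 0,
                    region_map = default_region_map(165, omega_relaxed = 0,
                                                    omega_constrained = 0),
                    seed = 6)
  fam <- simulate_family(cfg)
  expect_gt(nrow(fam$truth), 0)
  expect_true(all(fam$truth$syn))
  prot <- unique(vapply(gsub("-", "", unclass(fam$alignment)), translate_nt, ""))
  expect_length(prot, 1)  # all members encode the same protein
})

test_that("the same seed reproduces the family byte-identically", {
  f1 <- simulate_family(sim_config(seed = 99))
  f2 <- simulate_family(sim_config(seed = 99))
  expect_identical(unclass(f1$alignment)[], unclass(f2$alignment)[])
  expect_identical(f1$truth, f2$truth)
  f3 <- simulate_family(sim_config(seed = 100))
  expect_false(identical(unclass(f1$alignment)[], unclass(f3$alignment)[]))
})

test_that("realized synonymous divergence grows with branch length", {
  ks_at <- function(bl) {
    cfg <- sim_config(n_groups = 1, members_per_group = 2, n_codons = 300,
                      branch_length = bl, group_branch_length = 0,
                      region_map = tibble::tibble(start = 0L, end = 300L,
                                                  omega = 0.1),
                      anchors = tibble::tibble(subdomain = character(0),
                                               motif = character(0),
                                               codon_start = integer(0)),
                      seed = 1234)
    fam <- simulate_family(cfg)
    kaks_pair(fam$alignment[[1]], fam$alignment[[2]])$Ks
  }
  ks <- vapply(c(0.05, 0.15, 0.3), ks_at, 0)
  expect_true(all(diff(ks) > 0))
})

test_that("anchor codons are frozen and RD labels are planted per group", {
  fam <- simulate_family(sim_config(n_groups = 2, members_per_group = 4,
                                    rd_per_group = c(TRUE, FALSE),
                                    branch_length = 0.3, seed = 15))
  anchor_cols <- unlist(lapply(seq_len(nrow(fam$anchors)), function(i) {
    fam$anchors$codon_start[i] + seq_len(nchar(fam$anchors$motif[i]))
  }))
  expect_false(any(fam$truth$codon_pos %in% anchor_cols))
  prot <- vapply(gsub("-", "", unclass(fam$alignment)), translate_nt, "")
  expect_true(all(grepl("HRD", prot[fam$groups$g1])))
  expect_true(all(grepl("HCD", prot[fam$groups$g2])))
})

test_that("pseudogene degradation validates input and shifts frames", {
  cds <- strrep("ATGGCTAAAGTTCCA", 6)  # 90 nt
  expect_error(degrade_to_pseudogene(cds, n_indels = 0), ">= 1")
  expect_error(degrade_to_pseudogene("ATGGCT", 1), "10 codons")
  psi <- degrade_to_pseudogene(cds, n_indels = 1, seed = 5)
  expect_true(nchar(psi) %% 3 != 0 || nchar(psi) == nchar(cds) + 2 ||
              nchar(psi) == nchar(cds) - 2)

  fam <- simulate_family(sim_config(n_groups = 1, members_per_group = 3,
                                    pseudogene_fraction = 0.25, seed = 44))
  expect_equal(length(fam$pseudogenes), 1)
  expect_match(names(fam$pseudogenes), "\\.psi$")
})

test_that("planted primer sites are recoverable by in-silico PCR", {
  fwd <- degenerate_primer("f", "GARGARTTYACN", "forward")
  rev <- degenerate_primer("r", "CCNGGRTCYTTR", "reverse")
  tmpl <- random_nt(800, seed = 3)
  out <- plant_primer_sites(tmpl, fwd, rev, positions = c(50L, 600L), seed = 4)
  amp <- insilico_pcr(c(t = out), fwd, rev, trim_primers = FALSE)
  expect_true(any(amp$start == 50 & amp$end == 612))

  expect_error(plant_primer_sites(tmpl, fwd, rev, positions = c(-1L, 600L)),
               "out of range")
  expect_error(plant_primer_sites(tmpl, fwd, rev, positions = c(795L, 600L)),
               "out of range")
  expect_error(
    plant_primer_sites(tmpl, fwd, rev, positions = c(50L, 600L),
                       anchor_nt_ranges = cbind(55L, 70L)),
    "overlaps a planted anchor")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(region_map = tibble::tibble(
    start = c(0L, 40L), end = c(30L, 165L), omega = c(1, 0.1))), "tile")
  expect_error(sim_config(n_codons = 100), "outside the sequence")
  expect_error(sim_config(region_map = tibble::tibble(
    start = 0L, end = 165L, omega = -1)), ">= 0")
})
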