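test_that("planted anchors are located at their exact offsets", {
  s <- scaffold_kinase(seed = 42)
  sd <- annotate_subdomains(s)
  got <- stats::setNames(sd$anchor_start, sd$subdomain)
  expect_equal(got[c("I", "II", "III", "VIB", "VII", "VIII")],
               c(I = 5L, II = 30L, III = 55L, VIB = 95L, VII = 125L,
                 VIII = 148L))
  expect_identical(subdomain_span_string(sd), "I → VIII")
  # spans are ordered, non-overlapping, and tile up to the fragment end
  m <- sd[sd$matched, ]
  expect_true(all(diff(m$span_start) > 0))
  expect_true(all(m$span_end[-nrow(m)] == m$span_start[-1]))
  expect_equal(m$span_end[nrow(m)], nchar(s))
})

test_that("invariant audit classifies typical vs atypical", {
  s <- scaffold_kinase(seed = 42)
  ann <- annotate_kinase(c(k1 = s))
  expect_identical(ann$kinase_class, "typical")
  expect_false(any(ann$invariant_audit$status == "mismatch"))

  # DFG -> DFA: anchor context still matches, invariant Gly does not
  s2 <- scaffold_kinase(seed = 42, mutate = list(pos = 127, to = "A"))
  ann2 <- annotate_kinase(c(k2 = s2))
  expect_identical(ann2$kinase_class, "atypical")
  mism <- ann2$invariant_audit[ann2$invariant_audit$status == "mismatch", ]
  expect_equal(nrow(mism), 1)
  expect_identical(mism$subdomain, "VII")
  expect_identical(mism$observed, "A")
})

test_that("fragments ending before a subdomain report it not spanned", {
  s <- substr(scaffold_kinase(seed = 42), 1, 120)  # ends before DFG
  ann <- annotate_kinase(c(k = s))
  aud <- ann$invariant_audit
  expect_true(all(aud$status[aud$subdomain %in% c("VII", "VIII")] ==
                  "not spanned"))
  expect_identical(ann$kinase_class, "typical")
  expect_null(ann$activation_segment)
})

test_that("RD and non-RD kinases are recognised from the catalytic loop", {
  rd <- annotate_kinase(c(a = scaffold_kinase(seed = 7, rd = TRUE)))
  expect_identical(rd$catalytic_class, "RD")
  expect_true(is.na(rd$rd_substituent))

  nonrd <- annotate_kinase(c(b = scaffold_kinase(seed = 7, rd = FALSE)))
  expect_identical(nonrd$catalytic_class, "nonRD")
  expect_identical(nonrd$rd_substituent, "C")

  # no recognisable catalytic-loop context -> undetermined, not an error
  noVIB <- scaffold_kinase(seed = 7, mutate = list(pos = 95, to = "P"))
  trunc <- annotate_kinase(c(c = noVIB))
  expect_identical(trunc$catalytic_class, "undetermined")
})

test_that("random 200-mers are rejected as non-kinase fragments", {
  set.seed(1)
  errs <- 0
  for (k in 1:100) {
    s <- random_aa(200)
    r <- tryCatch(annotate_subdomains(s), error = function(e) "err")
    if (identical(r, "err")) errs <- errs + 1
  }
  expect_gte(errs, 99)
})

test_that("activation-segment report matches key T-loop positions", {
  s <- scaffold_kinase(seed = 5)
  ch <- strsplit(s, "")[[1]]
  ch[125 + 14 + 1] <- "S"   # position aligned to the Pto Ser-198 analog
  ch[125 + 15 + 1] <- "T"   # T-loop phospho-threonine analog
  ch[125 + 20 + 1] <- "T"   # substrate-recognition Thr analog
  s <- paste(ch, collapse = "")
  ann <- annotate_kinase(c(k = s))
  rep <- activation_segment_report(list(ann), c(k = s))
  pto <- rep[rep$motif == "Pto_190_215", ]
  expect_true(pto$spanned)
  expect_equal(pto$n_matched, 3)
  bri <- rep[rep$motif == "BRI1_1039_1057", ]
  expect_equal(bri$n_key, 2)  # the insertion position belongs to the motif only

  # non-consensus positions are masked as X
  ch[125 + 20 + 1] <- "W"
  s3 <- paste(ch, collapse = "")
  rep3 <- activation_segment_report(list(annotate_kinase(c(k = s3))),
                                    c(k = s3))
  expect_match(rep3$match_string[rep3$motif == "Pto_190_215"], "X$")

  # fragments without an activation segment are flagged, not dropped
  st <- substr(s, 1, 130)
  rep4 <- activation_segment_report(list(annotate_kinase(c(k = st))),
                                    c(k = st))
  expect_true(all(!rep4$spanned))
  expect_true(all(rep4$detail == "not spanned"))
})

test_that("family summary tallies groups, spans, non-RD and identity ranges", {
  fam <- simulate_family(sim_config(n_groups = 3, members_per_group = 3,
                                    rd_per_group = c(TRUE, FALSE, TRUE),
                                    seed = 31))
  cds <- stats::setNames(gsub("-", "", unclass(fam$alignment)),
                         names(fam$alignment))
  prot <- vapply(cds, translate_nt, "")
  anns <- annotate_kinase_all(prot)
  memb <- stats::setNames(rep(names(fam$groups), lengths(fam$groups)),
                          unlist(fam$groups, use.names = FALSE))
  tab <- summarize_families(anns, memb, cds,
                            aa_aln = seq_set(prot, "aa", gapped = TRUE),
                            nt_aln = fam$alignment)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$n, c(3L, 3L, 3L))
  expect_equal(tab$n_nonRD, c(0L, 3L, 0L))
  expect_equal(tab$nt_len_min, rep(495L, 3))

  # a group of identical sequences has a degenerate 100-100 identity range
  ident <- seq_set(c(x1 = "MKLVV", x2 = "MKLVV"), "aa", gapped = TRUE)
  expect_identical(rlkscan:::ident_range(ident, c("x1", "x2")), "100–100")

  # unlabeled sequences fall under "unassigned"
  tab2 <- summarize_families(anns, memb[-1], cds)
  expect_true("unassigned" %in% tab2$group)
})
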