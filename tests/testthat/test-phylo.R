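test_that("Poisson correction follows -ln(1 - p)", {
  # two rows of length 10 differing at one position: p = 0.1
  aln <- protein_alignment(c(a = "MKLVVAGHTE", b = "MKLVVAGHTD"))
  d <- poisson_distance(aln)
  expect_equal(d["a", "b"], -log(0.9), tolerance = 1e-7)
  expect_equal(d["a", "b"], 0.1053605, tolerance = 1e-6)
  expect_equal(diag(d), c(a = 0, b = 0))

  ident <- protein_alignment(c(a = "MKLV", b = "MKLV"))
  expect_equal(poisson_distance(ident)["a", "b"], 0)

  # d(p) ~ p as p -> 0 and is monotone in p
  p <- c(0.01, 0.05, 0.2, 0.5)
  d <- -log(1 - p)
  expect_lt(abs(d[1] - 0.01) / 0.01, 0.01)
  expect_true(all(diff(d) > 0))
})

test_that("gap handling: pairwise vs complete deletion and degenerate pairs", {
  aln <- protein_alignment(c(a = "MK-V", b = "MKLV", c = "MKLA"))
  dp <- poisson_distance(aln, "pairwise")  # a vs c over 3 columns, 1 diff
  expect_equal(dp["a", "c"], -log(1 - 1 / 3), tolerance = 1e-9)
  dc <- poisson_distance(aln, "complete")  # gap column dropped for everyone
  expect_equal(dc["b", "c"], -log(1 - 1 / 3), tolerance = 1e-9)

  bad <- protein_alignment(c(a = "MK--", b = "--LV", c = "MKLV"))
  expect_error(poisson_distance(bad, "pairwise"), "no comparable columns")
  sat <- protein_alignment(c(a = "MKLV", b = "AREA"))
  expect_error(poisson_distance(sat), "p >= 1")
})

test_that("3-taxon NJ matches the closed-form branch lengths", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.4
  d["A", "C"] <- d["C", "A"] <- 0.6
  d["B", "C"] <- d["C", "B"] <- 0.8
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length,
                        ifelse(tr$edge[, 2] <= 3, tr$tip.label[tr$edge[, 2]], "int"))
  expect_equal(bl[["A"]], (0.4 + 0.6 - 0.8) / 2, tolerance = 1e-9)
  expect_equal(bl[["B"]], (0.4 + 0.8 - 0.6) / 2, tolerance = 1e-9)
  expect_equal(bl[["C"]], (0.6 + 0.8 - 0.4) / 2, tolerance = 1e-9)

  expect_error(nj_tree(d[1:2, 1:2]), ">= 3 taxa")
  d2 <- d; d2["A", "B"] <- 0.5
  expect_error(nj_tree(d2), "not symmetric")
  d3 <- d; d3["A", "B"] <- d3["B", "A"] <- -0.1
  expect_error(nj_tree(d3), "negative")
})

test_that("NJ recovers a known additive 6-taxon tree exactly", {
  set.seed(7)
  true <- ape::rtree(6, br = function(n) stats::runif(n, 0.1, 0.5))
  true <- ape::unroot(true)
  dm <- ape::cophenetic.phylo(true)
  dm <- dm[order(rownames(dm)), order(colnames(dm))]
  tr <- nj_tree(dm)
  expect_equal(ape::dist.topo(ape::unroot(tr), true), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  back <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(back, dm, tolerance = 1e-8)
})

test_that("bootstrap supports are reproducible and bounded", {
  fam <- simulate_family(sim_config(n_groups = 2, members_per_group = 4,
                                    seed = 5))
  prot <- protein_alignment(vapply(gsub("-", "", unclass(fam$alignment)),
                                   translate_nt, ""))
  t1 <- bootstrap_support(prot, replicates = 30, seed = 19)
  t2 <- bootstrap_support(prot, replicates = 30, seed = 19)
  expect_identical(t1$node.label, t2$node.label)
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 100))

  tr1 <- bootstrap_support(prot, replicates = 1, seed = 3)
  expect_true(all(tr1$node.label %in% c(0, 100)))
})

test_that("well-separated clades get near-maximal support, invariant to leaf order", {
  fam <- simulate_family(sim_config(n_groups = 2, members_per_group = 4,
                                    branch_length = 0.05,
                                    group_branch_length = 1.0, seed = 11))
  prot <- vapply(gsub("-", "", unclass(fam$alignment)), translate_nt, "")
  paln <- protein_alignment(prot)
  tr <- bootstrap_support(paln, replicates = 200, seed = 11)
  # the bipartition separating g1 from g2 must be present and near 100%
  g1 <- fam$groups$g1
  clade_support <- max(vapply(seq_len(tr$Nnode), function(k) {
    tips <- tr$tip.label[rlkscan:::phangorn_descendants(
      tr, length(tr$tip.label) + k)]
    if (setequal(tips, g1) || setequal(tips, setdiff(tr$tip.label, g1)))
      tr$node.label[k] else -1
  }, 0))
  expect_gte(clade_support, 99)

  perm <- protein_alignment(prot[sample(names(prot))])
  trp <- bootstrap_support(perm, replicates = 50, seed = 4)
  tro <- bootstrap_support(paln, replicates = 50, seed = 4)
  sup_of <- function(tr) {
    k <- which(vapply(seq_len(tr$Nnode), function(k) {
      tips <- tr$tip.label[rlkscan:::phangorn_descendants(
        tr, length(tr$tip.label) + k)]
      setequal(tips, g1) || setequal(tips, setdiff(tr$tip.label, g1))
    }, TRUE))
    tr$node.label[k]
  }
  expect_identical(sup_of(trp), sup_of(tro))
})

test_that("subfamily assignment uses the smallest supported clade", {
  fam <- simulate_family(sim_config(n_groups = 3, members_per_group = 4,
                                    seed = 23))
  prot <- protein_alignment(vapply(gsub("-", "", unclass(fam$alignment)),
                                   translate_nt, ""))
  tr <- bootstrap_support(prot, replicates = 100, seed = 23)
  panel <- stats::setNames(names(fam$groups),
                           vapply(fam$groups, `[`, "", 1))
  asg <- assign_groups(tr, panel, min_support = 70)
  truth <- stats::setNames(rep(names(fam$groups), lengths(fam$groups)),
                           unlist(fam$groups, use.names = FALSE))
  hit <- asg$subfamily == truth[asg$seq_id]
  expect_true(all(hit | asg$subfamily == "uncertain"))

  expect_error(assign_groups(tr, c(nope = "X")), "no reference leaves")

  # a query whose smallest supported enclosing clade mixes subfamilies
  # (both references labelled differently inside one clade) is uncertain
  mixed_panel <- stats::setNames(c("fam1", "fam2"),
                                 fam$groups$g1[1:2])
  asg2 <- assign_groups(tr, mixed_panel, min_support = 70)
  g1_rows <- asg2[asg2$seq_id %in% fam$groups$g1, ]
  expect_true(any(g1_rows$subfamily == "uncertain") || nrow(g1_rows) == 0)
})
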