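# Codon-evolution simulator. Generates families of homologous kinase-domain
# coding fragments organised in clades, evolved under a continuous-time
# codon process with region-specific omega (relaxed vs constrained),
# kappa-weighted transitions, zero rate into stop codons, and frozen
# planted anchor motifs (glycine loop, VAIK, helix-C Glu, HRD/HCD, DFG,
# APE). The per-branch process is Gillespie-style event sampling on the
# codon chain: simple, exact for this model, and fully auditable -- every
# realised substitution is recorded in a truth map.

# fixed codons used when planting amino-acid motifs
.AA2CODON <- c(G = "GGT", S = "TCT", F = "TTT", V = "GTT", A = "GCT",
               I = "ATT", K = "AAA", L = "CTT", E = "GAA", H = "CAT",
               R = "CGT", C = "TGT", D = "GAT", P = "CCA", N = "AAT",
               T = "ACT", Y = "TAT", M = "ATG", W = "TGG", Q = "CAA")

default_anchor_layout <- function() {
  tibble(subdomain = c("I", "II", "III", "VIB", "VII", "VIII"),
         motif = c("GSGGFG", "VAIK", "LEV", "HRDLKPEN", "DFG", "APE"),
         codon_start = c(5L, 30L, 55L, 95L, 125L, 148L))  # 0-based
}

default_region_map <- function(n_codons = 165L, omega_relaxed = 1,
                               omega_constrained = 0.1) {
  # relaxed stretches mirror the subdomain I-II, V-VIA and VII-VIII analogs
  tibble(start = c(0L, 35L, 70L, 95L, 125L, 151L),
         end = c(35L, 70L, 95L, 125L, 151L, n_codons),
         omega = c(omega_relaxed, omega_constrained, omega_relaxed,
                   omega_constrained, omega_relaxed, omega_constrained))
}

#' Simulation configuration
#'
#' Defaults mimic the scale of a kinase-domain candidate survey: 4 groups of
#' 8 members, 165 codons (495 nt), kappa = 2, within-group branch length
#' 0.15 substitutions/site (so a cherry diverges at roughly Ks 0.3), groups
#' separated by a long stem, relaxed (omega = 1) regions over the
#' subdomain I-II, V-VIA and VII-VIII analogs and constrained (omega = 0.1)
#' elsewhere. Branch lengths are expected substitutions per nucleotide site
#' under neutrality.
#'
#' @param n_groups number of clades.
#' @param members_per_group sequences per clade.
#' @param n_codons fragment length in codons.
#' @param kappa transition/transversion rate ratio.
#' @param branch_length within-group terminal branch length.
#' @param group_branch_length stem length from the root to each group
#'   ancestor.
#' @param tree_shape `"star"` (members radiate from the group ancestor) or
#'   `"balanced"` (recursive bifurcation with the same root-to-tip length).
#' @param region_map tibble start/end (0-based codon intervals, tiling the
#'   fragment) and omega.
#' @param anchors anchor layout tibble (subdomain, motif, codon_start);
#'   anchor codons are frozen.
#' @param rd_per_group logical vector (recycled) -- `TRUE` plants the RD
#'   motif (HRD...), `FALSE` the non-RD Cys variant (HCD...).
#' @param pseudogene_fraction fraction of members duplicated as
#'   frameshift-degraded pseudogene copies (ids suffixed `.psi`).
#' @param seed RNG seed.
#' @return `sim_config` list.
#' @export
sim_config <- function(n_groups = 4L, members_per_group = 8L, n_codons = 165L,
                       kappa = 2, branch_length = 0.15,
                       group_branch_length = 0.4,
                       tree_shape = c("star", "balanced"),
                       region_map = default_region_map(n_codons),
                       anchors = default_anchor_layout(),
                       rd_per_group = c(TRUE, TRUE, FALSE, TRUE),
                       pseudogene_fraction = 0,
                       seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_groups >= 1L, members_per_group >= 2L, n_codons >= 10L,
            kappa > 0, branch_length >= 0, group_branch_length >= 0,
            pseudogene_fraction >= 0, pseudogene_fraction < 1)
  if (any(region_map$omega < 0)) stop("omegas must be >= 0", call. = FALSE)
  rm <- region_map[order(region_map$start), ]
  if (rm$start[1L] != 0L || rm$end[nrow(rm)] != n_codons ||
      (nrow(rm) > 1L && any(rm$end[-nrow(rm)] != rm$start[-1L]))) {
    stop("region map must tile [0, n_codons) without overlap", call. = FALSE)
  }
  for (i in seq_len(nrow(anchors))) {
    if (anchors$codon_start[i] + nchar(anchors$motif[i]) > n_codons) {
      stop("anchor '", anchors$subdomain[i], "' outside the sequence",
           call. = FALSE)
    }
  }
  structure(list(n_groups = n_groups, members_per_group = members_per_group,
                 n_codons = n_codons, kappa = kappa,
                 branch_length = branch_length,
                 group_branch_length = group_branch_length,
                 tree_shape = tree_shape, region_map = rm, anchors = anchors,
                 rd_per_group = rep_len(rd_per_group, n_groups),
                 pseudogene_fraction = pseudogene_fraction, seed = seed),
            class = "sim_config")
}

# neighbor table: for each sense codon, its single-nt neighbors with
# transition flag, synonymous flag, and stop flag
codon_neighbors <- function() {
  if (!is.null(.codon_cache[["neighbors"]])) return(.codon_cache[["neighbors"]])
  code <- genetic_code()
  cods <- sense_codons(code)
  out <- lapply(cods, function(cd) {
    ch <- strsplit(cd, "", fixed = TRUE)[[1L]]
    rows <- list()
    for (pos in 1:3) {
      for (nt in setdiff(.NT, ch[pos])) {
        mut <- ch; mut[pos] <- nt
        mcd <- paste(mut, collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          to = mcd, ts = is_transition(ch[pos], nt),
          syn = code[[mcd]] != "*" && code[[mcd]] == code[[cd]],
          stop = code[[mcd]] == "*", stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  names(out) <- cods
  .codon_cache[["neighbors"]] <- out
  out
}

# evolve one codon sequence along one branch; returns list(seq, events)
evolve_branch <- function(codons, t, omega_per_codon, frozen, kappa,
                          lineage = "branch") {
  if (t <= 0) return(list(codons = codons, events = NULL))
  nb <- codon_neighbors()
  scale <- 1 / (kappa + 2)  # neutral rate = 1 substitution / nt site / unit t
  codon_rate <- function(i) {
    if (frozen[i]) return(0)
    tab <- nb[[codons[i]]]
    w <- ifelse(tab$ts, kappa, 1) * ifelse(tab$syn, 1, omega_per_codon[i])
    w[tab$stop] <- 0
    sum(w) * scale
  }
  rates <- vapply(seq_along(codons), codon_rate, 0)
  total <- sum(rates)
  elapsed <- 0
  events <- list()
  while (total > 0) {
    elapsed <- elapsed + stats::rexp(1L, total)
    if (elapsed > t) break
    i <- sample.int(length(codons), 1L, prob = rates)
    tab <- nb[[codons[i]]]
    w <- ifelse(tab$ts, kappa, 1) * ifelse(tab$syn, 1, omega_per_codon[i])
    w[tab$stop] <- 0
    j <- sample.int(nrow(tab), 1L, prob = w)
    events[[length(events) + 1L]] <- tibble(
      lineage = lineage, codon_pos = i, from = codons[i], to = tab$to[j],
      syn = tab$syn[j])
    codons[i] <- tab$to[j]
    rates[i] <- codon_rate(i)
    total <- sum(rates)
  }
  list(codons = codons,
       events = if (length(events)) do.call(rbind, events) else NULL)
}

draw_ancestor <- function(cfg) {
  code <- genetic_code()
  cods <- sense_codons(code)
  if (nrow(cfg$anchors) == 0L) {
    return(sample(cods, cfg$n_codons, replace = TRUE))
  }
  planted <- plant_anchor_codons(cfg, rd = TRUE)
  for (try in 1:50) {
    anc <- sample(cods, cfg$n_codons, replace = TRUE)
    anc[!is.na(planted)] <- planted[!is.na(planted)]
    aa <- translate_nt(paste(anc, collapse = ""))
    sd <- tryCatch(annotate_subdomains(aa), error = function(e) NULL)
    if (is.null(sd)) next
    want <- cfg$anchors$codon_start
    got <- sd$anchor_start[match(cfg$anchors$subdomain, sd$subdomain)]
    if (all(!is.na(got)) && all(got == want)) return(anc)
  }
  stop("could not draw an ancestor with clean anchor matches", call. = FALSE)
}

plant_anchor_codons <- function(cfg, rd = TRUE) {
  planted <- rep(NA_character_, cfg$n_codons)
  for (i in seq_len(nrow(cfg$anchors))) {
    motif <- cfg$anchors$motif[i]
    if (cfg$anchors$subdomain[i] == "VIB" && !rd) {
      substr(motif, 2L, 2L) <- "C"  # HRD... -> HCD... (non-RD Cys variant)
    }
    aas <- strsplit(motif, "", fixed = TRUE)[[1L]]
    planted[cfg$anchors$codon_start[i] + seq_along(aas)] <- .AA2CODON[aas]
  }
  planted
}

#' Simulate a codon-aligned family of kinase-domain fragments
#'
#' See [sim_config()] for the model. The returned alignment is the true
#' homology (gapless by default), so it satisfies the codon-alignment
#' invariants trivially. The truth map records every realised substitution.
#'
#' @param cfg a [sim_config()].
#' @param shared_nonsyn_positions optional 0-based codon columns at which one
#'   member of every group is given an extra non-synonymous edit after
#'   evolution (planted shared variable positions; must avoid anchors).
#' @return list: `alignment` ([codon_alignment()]), `groups` (named list of
#'   member ids), `truth` (substitution tibble), `rd_labels` (named logical,
#'   `TRUE` = RD), `anchors` (codon layout), `config`.
#' @export
simulate_family <- function(cfg, shared_nonsyn_positions = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  omega_per_codon <- rep(NA_real_, cfg$n_codons)
  for (i in seq_len(nrow(cfg$region_map))) {
    omega_per_codon[(cfg$region_map$start[i] + 1L):cfg$region_map$end[i]] <-
      cfg$region_map$omega[i]
  }
  frozen <- rep(FALSE, cfg$n_codons)
  for (i in seq_len(nrow(cfg$anchors))) {
    frozen[cfg$anchors$codon_start[i] + seq_len(nchar(cfg$anchors$motif[i]))] <- TRUE
  }
  if (!is.null(shared_nonsyn_positions) &&
      any(frozen[shared_nonsyn_positions + 1L])) {
    stop("shared_nonsyn_positions overlap planted anchors", call. = FALSE)
  }
  anc <- draw_ancestor(cfg)
  truth <- list()
  seqs <- character(0)
  groups <- list()
  code <- genetic_code()
  for (g in seq_len(cfg$n_groups)) {
    glab <- paste0("g", g)
    ganc <- anc
    # force the group's RD/non-RD variant before the stem so all members share it
    planted <- plant_anchor_codons(cfg, rd = cfg$rd_per_group[g])
    ganc[!is.na(planted)] <- planted[!is.na(planted)]
    stem <- evolve_branch(ganc, cfg$group_branch_length, omega_per_codon,
                          frozen, cfg$kappa, lineage = paste0(glab, ".stem"))
    truth[[length(truth) + 1L]] <- stem$events
    member_ids <- paste0(glab, ".m", seq_len(cfg$members_per_group))
    groups[[glab]] <- member_ids
    tips <- evolve_clade(stem$codons, member_ids, cfg, omega_per_codon, frozen)
    truth <- c(truth, tips$events)
    seqs <- c(seqs, tips$seqs)
  }
  # planted shared non-synonymous positions: one deterministic edit per group
  if (!is.null(shared_nonsyn_positions)) {
    for (p in shared_nonsyn_positions) {
      for (g in names(groups)) {
        id <- groups[[g]][1L]
        cods <- split_codons(seqs[[id]])
        cur_aa <- code[[cods[p + 1L]]]
        new_aa <- if (cur_aa == "A") "S" else "A"
        truth[[length(truth) + 1L]] <- tibble(
          lineage = id, codon_pos = p + 1L, from = cods[p + 1L],
          to = .AA2CODON[[new_aa]], syn = FALSE)
        cods[p + 1L] <- .AA2CODON[[new_aa]]
        seqs[id] <- paste(cods, collapse = "")
      }
    }
  }
  truth <- do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
  pseudo <- NULL
  if (cfg$pseudogene_fraction > 0) {
    n_psi <- max(1L, round(cfg$pseudogene_fraction * length(seqs) /
                             (1 - cfg$pseudogene_fraction)))
    donors <- sample(names(seqs), n_psi, replace = n_psi > length(seqs))
    pseudo <- stats::setNames(
      vapply(seq_along(donors), function(k) {
        degrade_to_pseudogene(seqs[[donors[k]]], n_indels = 1L,
                              seed = cfg$seed + 7919L + k)
      }, ""),
      paste0(make.unique(donors), ".psi"))
  }
  list(alignment = codon_alignment(seqs),
       groups = groups,
       truth = truth,
       pseudogenes = pseudo,
       rd_labels = stats::setNames(cfg$rd_per_group,
                                   paste0("g", seq_len(cfg$n_groups))),
       anchors = cfg$anchors,
       config = cfg)
}

# evolve a clade from its ancestor; star or balanced shape
evolve_clade <- function(anc, ids, cfg, omega_per_codon, frozen) {
  events <- list()
  seqs <- character(0)
  if (cfg$tree_shape == "star" || length(ids) <= 2L) {
    for (id in ids) {
      r <- evolve_branch(anc, cfg$branch_length, omega_per_codon, frozen,
                         cfg$kappa, lineage = id)
      events[[length(events) + 1L]] <- r$events
      seqs[id] <- paste(r$codons, collapse = "")
    }
  } else {
    depth <- ceiling(log2(length(ids)))
    el <- cfg$branch_length / depth
    recurse <- function(node_seq, node_ids, level) {
      if (length(node_ids) == 1L) {
        r <- evolve_branch(node_seq, el * (depth - level), omega_per_codon,
                           frozen, cfg$kappa, lineage = node_ids)
        events[[length(events) + 1L]] <<- r$events
        seqs[node_ids] <<- paste(r$codons, collapse = "")
        return(invisible())
      }
      half <- ceiling(length(node_ids) / 2L)
      for (part in list(node_ids[seq_len(half)], node_ids[-seq_len(half)])) {
        r <- evolve_branch(node_seq, el, omega_per_codon, frozen, cfg$kappa,
                           lineage = paste(part, collapse = "+"))
        events[[length(events) + 1L]] <<- r$events
        recurse(r$codons, part, level + 1L)
      }
    }
    recurse(anc, ids, 0L)
    seqs <- seqs[ids]
  }
  list(events = events, seqs = seqs)
}

#' Degrade a coding fragment into a frameshifted pseudogene
#'
#' Inserts or deletes 1-2 nt at random positions outside anchor ranges,
#' emulating the frameshift indels seen in pseudogene or truncated-gene
#' amplicons (which typically surface a downstream stop in [orf_screen()]).
#'
#' @param seq nt string (>= 10 codons).
#' @param n_indels number of indel events (>= 1).
#' @param seed RNG seed.
#' @param anchor_nt_ranges optional two-column matrix of 0-based half-open nt
#'   ranges to avoid.
#' @param max_rel_pos indels are placed within the first `max_rel_pos`
#'   fraction of the sequence (default 0.75): a frameshift very close to the
#'   3' end leaves too little downstream sequence for a stop to surface, so
#'   such copies would be indistinguishable from intact genes.
#' @return degraded nt string.
#' @export
degrade_to_pseudogene <- function(seq, n_indels = 1L, seed = 1L,
                                  anchor_nt_ranges = NULL,
                                  max_rel_pos = 0.75) {
  s <- toupper(seq[[1L]])
  if (nchar(s) < 30L) stop("sequence shorter than 10 codons", call. = FALSE)
  if (n_indels < 1L) stop("n_indels must be >= 1", call. = FALSE)
  set.seed(seed)
  ok_pos <- function(p, w) {
    if (is.null(anchor_nt_ranges)) return(TRUE)
    !any(p < anchor_nt_ranges[, 2L] & (p + w) > anchor_nt_ranges[, 1L])
  }
  for (k in seq_len(n_indels)) {
    repeat {
      width <- sample(1:2, 1L)
      insert <- stats::runif(1) < 0.5
      lim <- max(1L, floor(max_rel_pos * nchar(s)) - width)
      p <- sample.int(lim, 1L)  # 0-based edit position
      if (ok_pos(p, width)) break
    }
    if (insert) {
      ins <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                   collapse = "")
      s <- paste0(substr(s, 1L, p), ins, substr(s, p + 1L, nchar(s)))
    } else {
      s <- paste0(substr(s, 1L, p), substr(s, p + width + 1L, nchar(s)))
    }
  }
  s
}

#' Plant concrete degenerate-primer sites into a sequence
#'
#' Writes a concrete expansion of the forward primer at `positions[1]` and
#' the reverse complement of an expansion of the reverse primer at
#' `positions[2]` (both 0-based starts on the forward strand), so that
#' [insilico_pcr()] with the same primers recovers the amplicon.
#'
#' @param seq nt string.
#' @param fwd,rev [degenerate_primer()] objects.
#' @param positions integer vector of two 0-based site starts.
#' @param anchor_nt_ranges optional 0-based half-open nt ranges that the
#'   sites must not overlap.
#' @param seed seed for choosing among degenerate expansions.
#' @return modified nt string.
#' @export
plant_primer_sites <- function(seq, fwd, rev, positions,
                               anchor_nt_ranges = NULL, seed = 1L) {
  s <- toupper(seq[[1L]])
  set.seed(seed)
  expand_one <- function(iupac) {
    ch <- strsplit(iupac, "", fixed = TRUE)[[1L]]
    paste(vapply(ch, function(c) sample(.IUPAC[[c]], 1L), ""), collapse = "")
  }
  f_site <- expand_one(fwd$iupac)
  r_site <- revcomp(expand_one(rev$iupac))
  sites <- list(c(positions[1L], nchar(f_site), f_site),
                c(positions[2L], nchar(r_site), r_site))
  for (st in sites) {
    p <- as.integer(st[[1L]]); w <- as.integer(st[[2L]])
    if (p < 0L || p + w > nchar(s)) stop("primer site out of range", call. = FALSE)
    if (!is.null(anchor_nt_ranges) &&
        any(p < anchor_nt_ranges[, 2L] & (p + w) > anchor_nt_ranges[, 1L])) {
      stop("primer site overlaps a planted anchor", call. = FALSE)
    }
  }
  substr(s, positions[1L] + 1L, positions[1L] + nchar(f_site)) <- f_site
  substr(s, positions[2L] + 1L, positions[2L] + nchar(r_site)) <- r_site
  s
}
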