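# Activation-segment consensus comparison. The segment between the DFG and
# APE anchors carries the T-loop (regulatory autophosphorylation) and the
# P+1 loop (substrate binding). Query fragments are compared position-wise
# against consensus motifs anchored at the DFG motif. The default tables are
# reduced, implementer-transcribed consensus sets limited to the
# functionally characterised T-loop serine/threonine positions of the Pto
# and BRI1 activation segments; they are plain config tables and are meant
# to be replaced/extended by the user.

#' Default activation-segment consensus motifs
#'
#' Offsets are residue distances from the start of the DFG anchor. The BRI1
#' motif carries one extra serine relative to Pto; following the convention
#' adopted here, the second serine (BRI1 Ser-1044) is treated as an
#' insertion so that the two phospho-threonines align. Set
#' `bri1_insertion = "S1042"` for the alternative gap placement.
#'
#' @param bri1_insertion which BRI1 serine is the insertion
#'   (`"S1044"` default, or `"S1042"`).
#' @return tibble: motif, label, offset (NA for insertion positions),
#'   allowed (string of allowed residues), weight.
#' @export
default_consensus_motifs <- function(bri1_insertion = c("S1044", "S1042")) {
  bri1_insertion <- match.arg(bri1_insertion)
  pto <- tibble(motif = "Pto_190_215",
                label = c("S198", "T199", "T204"),
                offset = c(14L, 15L, 20L),
                allowed = c("ST", "ST", "T"),
                weight = c("key", "key", "key"))
  if (bri1_insertion == "S1044") {
    bri1 <- tibble(motif = "BRI1_1039_1057",
                   label = c("S1042", "S1044(ins)", "T1045"),
                   offset = c(14L, NA_integer_, 15L),
                   allowed = c("ST", "ST", "ST"),
                   weight = c("key", "key", "key"))
  } else {
    bri1 <- tibble(motif = "BRI1_1039_1057",
                   label = c("S1042(ins)", "S1044", "T1045"),
                   offset = c(NA_integer_, 14L, 15L),
                   allowed = c("ST", "ST", "ST"),
                   weight = c("key", "key", "key"))
  }
  rbind(pto, bri1)
}

#' Activation-segment consensus match table
#'
#' For every annotated sequence and every consensus motif, reports how many
#' key positions match, with a per-position string in which non-consensus
#' residues are masked as `X`. Sequences whose activation segment (DFG and
#' APE anchors) was not located are flagged `not spanned`. Insertion
#' positions (offset NA) belong to the motif, not the query, and are skipped
#' in matching.
#'
#' @param annotations list of [annotate_kinase()] results.
#' @param seqs named aa vector (same ids).
#' @param motifs consensus table, see [default_consensus_motifs()].
#' @return tibble: seq_id, motif, spanned, n_key, n_matched, match_string,
#'   detail (per-position "label=obs(+/-)" summary).
#' @export
activation_segment_report <- function(annotations, seqs,
                                      motifs = default_consensus_motifs()) {
  rows <- list()
  for (ann in annotations) {
    id <- ann$seq_id
    for (mname in unique(motifs$motif)) {
      mt <- motifs[motifs$motif == mname, , drop = FALSE]
      if (is.null(ann$activation_segment) || !is.null(ann$error)) {
        rows[[length(rows) + 1L]] <- tibble(
          seq_id = id, motif = mname, spanned = FALSE,
          n_key = sum(mt$weight == "key"), n_matched = NA_integer_,
          match_string = NA_character_, detail = "not spanned")
        next
      }
      s <- toupper(seqs[[id]])
      dfg_start <- ann$activation_segment[1L]  # 0-based
      obs <- character(nrow(mt)); ok <- logical(nrow(mt))
      for (j in seq_len(nrow(mt))) {
        if (is.na(mt$offset[j])) { obs[j] <- "-"; ok[j] <- NA; next }
        pos <- dfg_start + mt$offset[j]        # 0-based
        obs[j] <- substr(s, pos + 1L, pos + 1L)
        allowed <- strsplit(mt$allowed[j], "", fixed = TRUE)[[1L]]
        ok[j] <- nzchar(obs[j]) && obs[j] %in% allowed
      }
      shown <- ifelse(is.na(ok), "-", ifelse(ok, obs, "X"))
      rows[[length(rows) + 1L]] <- tibble(
        seq_id = id, motif = mname, spanned = TRUE,
        n_key = sum(mt$weight == "key" & !is.na(mt$offset)),
        n_matched = sum(ok[mt$weight == "key"], na.rm = TRUE),
        match_string = paste(shown, collapse = ""),
        detail = paste0(mt$label, "=", obs,
                        ifelse(is.na(ok), "(ins)", ifelse(ok, "(+)", "(-)")),
                        collapse = " "))
    }
  }
  do.call(rbind, rows)
}

#' Family summary table
#'
#' Per-group roll-up in the style of a candidate-gene survey table: member
#' count, subdomain-span tally, nt length range, non-RD and atypical counts,
#' and within-group pairwise identity ranges at the amino-acid and (when a
#' codon alignment is given) nucleotide level. Sequences without a group
#' label are tallied under `"unassigned"`.
#'
#' @param annotations list of [annotate_kinase()] results (or failed entries).
#' @param assignments named character vector id -> group label.
#' @param seqs named ungapped nt sequences (for length range).
#' @param aa_aln optional protein alignment for identity ranges.
#' @param nt_aln optional codon alignment for nt identity ranges.
#' @return tibble: group, n, span_tally, nt_len_min, nt_len_max, n_nonRD,
#'   n_atypical, aa_ident_range, nt_ident_range.
#' @export
summarize_families <- function(annotations, assignments, seqs,
                               aa_aln = NULL, nt_aln = NULL) {
  ids <- vapply(annotations, function(a) a$seq_id, "")
  grp <- assignments[ids]
  grp[is.na(grp)] <- "unassigned"
  rows <- list()
  for (g in unique(grp)) {
    members <- ids[grp == g]
    anns <- annotations[match(members, ids)]
    failed <- vapply(anns, function(a) !is.null(a$error), TRUE)
    spans <- vapply(anns[!failed], function(a) a$span_string, "")
    tal <- sort(table(spans), decreasing = TRUE)
    span_tally <- paste0(names(tal), " (", as.integer(tal), ")", collapse = "; ")
    lens <- nchar(seqs[intersect(members, names(seqs))])
    n_nonRD <- sum(vapply(anns[!failed],
                          function(a) a$catalytic_class == "nonRD", TRUE))
    n_atyp <- sum(vapply(anns[!failed],
                         function(a) a$kinase_class == "atypical", TRUE))
    rows[[length(rows) + 1L]] <- tibble(
      group = g, n = length(members),
      span_tally = if (length(spans)) span_tally else "",
      nt_len_min = if (length(lens)) min(lens) else NA_integer_,
      nt_len_max = if (length(lens)) max(lens) else NA_integer_,
      n_nonRD = n_nonRD, n_atypical = n_atyp,
      aa_ident_range = ident_range(aa_aln, members),
      nt_ident_range = ident_range(nt_aln, members))
  }
  do.call(rbind, rows)
}

# min-max % pairwise identity among members over shared non-gap columns
ident_range <- function(aln, members, digits = 1) {
  if (is.null(aln)) return(NA_character_)
  members <- intersect(members, names(aln))
  if (length(members) < 2L) return(NA_character_)
  chars <- do.call(rbind, strsplit(unclass(aln)[members], "", fixed = TRUE))
  vals <- c()
  for (i in seq_len(nrow(chars) - 1L)) {
    for (j in (i + 1L):nrow(chars)) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(ok)) next
      vals <- c(vals, 100 * mean(chars[i, ok] == chars[j, ok]))
    }
  }
  if (!length(vals)) return(NA_character_)
  paste0(round(min(vals), digits), "–", round(max(vals), digits))
}
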