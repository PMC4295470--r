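# Kinase subdomain annotation. Fragments from domain-targeted cloning start
# and end at different subdomains, so subdomains are located by ordered
# anchor-motif matching rather than fixed offsets. Anchor patterns are
# permissive contexts; the stricter invariant-residue expectations are
# audited separately so that a mutated invariant (e.g. DFG -> DFA) still
# anchors but is reported as atypical.

#' Default subdomain anchor profile
#'
#' One row per anchored subdomain: a regular-expression context and the
#' invariant residues expected at fixed offsets inside the match
#' (`offset:residue`, comma-separated; offsets 0-based).
#'
#' @return tibble: subdomain, pattern, invariants.
#' @export
default_anchor_profile <- function() {
  tibble(
    subdomain = c("I", "II", "III", "VIB", "VII", "VIII"),
    pattern = c("G.G..G",                 # glycine-rich loop
                "[VAIL][AGST][VAIL]K",    # VAIK lysine context
                "[LIVMF]E[LIVMF]",        # helix-C glutamate
                "H.[DN][LIVMFA][KRN]",    # catalytic loop (HRD context)
                "D[FLY][GASC]",           # DFG
                "[AGST]PE"),              # APE
    invariants = c("0:G,2:G,5:G", "3:K", "1:E", "2:D", "0:D,2:G", "2:E"))
}

#' Annotate kinase subdomains by ordered anchor matching
#'
#' Anchors are searched left to right in subdomain order; each anchor is the
#' first match after the previous one. Subdomain spans run from one anchor
#' start to the next; the last anchored subdomain runs to the fragment end.
#' A fragment matching fewer than `min_anchors` anchors is rejected as not a
#' kinase fragment (random sequences are rejected with high probability).
#'
#' @param seq single aa string (>= 100 residues).
#' @param anchor_profile anchor table, see [default_anchor_profile()].
#' @param min_anchors minimum anchors required (default 3).
#' @return tibble (`subdomain_map`): subdomain, anchor_start, anchor_end,
#'   span_start, span_end (0-based half-open), matched.
#' @export
annotate_subdomains <- function(seq, anchor_profile = default_anchor_profile(),
                                min_anchors = 3L) {
  s <- toupper(seq[[1L]])
  if (nchar(s) < 100L) stop("fragment shorter than 100 aa", call. = FALSE)
  n <- nrow(anchor_profile)
  anchor_start <- anchor_end <- rep(NA_integer_, n)
  pos <- 0L  # search offset (0-based)
  for (i in seq_len(n)) {
    m <- regexpr(anchor_profile$pattern[i], substr(s, pos + 1L, nchar(s)),
                 perl = TRUE)
    if (m[1L] == -1L) next
    anchor_start[i] <- pos + m[1L] - 1L
    anchor_end[i] <- anchor_start[i] + attr(m, "match.length")
    pos <- anchor_end[i]
  }
  matched <- !is.na(anchor_start)
  if (sum(matched) < min_anchors) {
    stop("not a kinase fragment (", sum(matched), "/", n,
         " anchor motifs matched)", call. = FALSE)
  }
  idx <- which(matched)
  span_start <- span_end <- rep(NA_integer_, n)
  for (k in seq_along(idx)) {
    i <- idx[k]
    span_start[i] <- anchor_start[i]
    span_end[i] <- if (k < length(idx)) anchor_start[idx[k + 1L]] else nchar(s)
  }
  out <- tibble(subdomain = anchor_profile$subdomain,
                anchor_start = anchor_start, anchor_end = anchor_end,
                span_start = span_start, span_end = span_end,
                matched = matched)
  attr(out, "seq_length") <- nchar(s)
  class(out) <- c("subdomain_map", class(out))
  out
}

#' Roman-numeral span string for a subdomain map ("I -> VIII" style)
#' @param sd subdomain map.
#' @return character scalar.
#' @export
subdomain_span_string <- function(sd) {
  m <- sd$subdomain[sd$matched]
  if (!length(m)) return("none")
  paste0(m[1L], " → ", m[length(m)])
}

#' Audit invariant kinase residues
#'
#' Checks every configured invariant residue at its anchored position. Any
#' mismatch classifies the fragment as atypical; invariants in unmatched
#' subdomains are reported "not spanned" (not mismatches).
#'
#' @param seq aa string.
#' @param sd subdomain map from [annotate_subdomains()].
#' @param anchor_profile the profile used for annotation.
#' @return list: `audit` (tibble: subdomain, position, expected, observed,
#'   status), `kinase_class` ("typical"/"atypical").
#' @export
audit_invariants <- function(seq, sd, anchor_profile = default_anchor_profile()) {
  s <- toupper(seq[[1L]])
  rows <- list()
  for (i in seq_len(nrow(anchor_profile))) {
    spec <- anchor_profile$invariants[i]
    if (!nzchar(spec)) next
    parts <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    for (p in parts) {
      off <- as.integer(p[[1L]]); expected <- p[[2L]]
      if (!sd$matched[i]) {
        rows[[length(rows) + 1L]] <- tibble(
          subdomain = sd$subdomain[i], position = NA_integer_,
          expected = expected, observed = NA_character_, status = "not spanned")
        next
      }
      pos <- sd$anchor_start[i] + off  # 0-based
      observed <- substr(s, pos + 1L, pos + 1L)
      rows[[length(rows) + 1L]] <- tibble(
        subdomain = sd$subdomain[i], position = pos,
        expected = expected, observed = observed,
        status = if (observed == expected) "conserved" else "mismatch")
    }
  }
  audit <- do.call(rbind, rows)
  list(audit = audit,
       kinase_class = if (any(audit$status == "mismatch")) "atypical" else "typical")
}

#' RD / non-RD classification
#'
#' Locates the catalytic aspartate of the subdomain VIB anchor and inspects
#' the residue immediately N-terminal: arginine gives an RD kinase, anything
#' else a non-RD kinase (the substituting residue is reported -- in
#' pathogen-recognition-receptor kinase groups this is frequently Cys).
#' Fragments not spanning subdomain VIB are `"undetermined"`.
#'
#' @param seq aa string.
#' @param sd subdomain map.
#' @param asp_offset offset of the catalytic Asp inside the VIB anchor match
#'   (default 2, the D of the HRD context).
#' @return list: `catalytic_class` ("RD"/"nonRD"/"undetermined"),
#'   `rd_substituent` (aa or NA), `asp_position` (0-based or NA).
#' @export
classify_rd <- function(seq, sd, asp_offset = 2L) {
  s <- toupper(seq[[1L]])
  i <- which(sd$subdomain == "VIB")
  if (!length(i) || !sd$matched[i]) {
    return(list(catalytic_class = "undetermined", rd_substituent = NA_character_,
                asp_position = NA_integer_))
  }
  asp_pos <- sd$anchor_start[i] + asp_offset  # 0-based
  before <- substr(s, asp_pos, asp_pos)       # residue immediately N-terminal
  if (identical(before, "R")) {
    list(catalytic_class = "RD", rd_substituent = NA_character_,
         asp_position = asp_pos)
  } else {
    list(catalytic_class = "nonRD", rd_substituent = before,
         asp_position = asp_pos)
  }
}

#' Full kinase annotation of one sequence
#'
#' @param seq single named aa string.
#' @param anchor_profile anchor table.
#' @param min_anchors see [annotate_subdomains()].
#' @return list of class `kinase_annotation`: seq_id, subdomains,
#'   invariant_audit, kinase_class, catalytic_class, rd_substituent,
#'   activation_segment (c(start, end), 0-based half-open, DFG start to APE
#'   end, or NULL), span_string.
#' @export
annotate_kinase <- function(seq, anchor_profile = default_anchor_profile(),
                            min_anchors = 3L) {
  id <- if (!is.null(names(seq))) names(seq)[1L] else "seq"
  sd <- annotate_subdomains(seq, anchor_profile, min_anchors = min_anchors)
  aud <- audit_invariants(seq, sd, anchor_profile)
  rd <- classify_rd(seq, sd)
  i7 <- which(sd$subdomain == "VII"); i8 <- which(sd$subdomain == "VIII")
  act <- NULL
  if (length(i7) && length(i8) && sd$matched[i7] && sd$matched[i8]) {
    act <- c(sd$anchor_start[i7], sd$anchor_end[i8])
  }
  structure(list(seq_id = id, subdomains = sd, invariant_audit = aud$audit,
                 kinase_class = aud$kinase_class,
                 catalytic_class = rd$catalytic_class,
                 rd_substituent = rd$rd_substituent,
                 activation_segment = act,
                 span_string = subdomain_span_string(sd)),
            class = "kinase_annotation")
}

#' Annotate a collection of sequences, tolerating failures
#'
#' @param seqs named aa character vector.
#' @param ... passed to [annotate_kinase()].
#' @return list of `kinase_annotation` (failures recorded as list entries
#'   with `error` set).
#' @export
annotate_kinase_all <- function(seqs, ...) {
  out <- lapply(seq_along(seqs), function(i) {
    tryCatch(annotate_kinase(seqs[i], ...),
             error = function(e) list(seq_id = names(seqs)[i],
                                      error = conditionMessage(e)))
  })
  stats::setNames(out, names(seqs))
}
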