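# IUPAC nucleotide expansions. Matching is asymmetric on purpose: primer
# codes are degenerate (match any of their expansions) while the only template
# ambiguity honoured is N, which pairs with anything -- this mirrors how a
# degenerate oligo anneals to an uncertain template base call.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

#' Reverse-complement a nucleotide string (IUPAC-aware)
#' @param seq nucleotide string.
#' @return reverse complement, preserving ambiguity codes.
#' @export
revcomp <- function(seq) {
  ch <- rev(strsplit(toupper(seq), "", fixed = TRUE)[[1L]])
  out <- .IUPAC_COMP[ch]
  if (anyNA(out)) stop("invalid nucleotide character in sequence", call. = FALSE)
  paste(out, collapse = "")
}

#' Define a degenerate primer
#'
#' @param name primer label.
#' @param iupac primer sequence 5'->3' over the full IUPAC nucleotide code;
#'   a reverse primer is written 5'->3' on the antisense strand (standard
#'   notation) and is matched against the reverse-complemented template.
#' @param direction `"forward"` or `"reverse"`.
#' @return a `degenerate_primer` list.
#' @export
degenerate_primer <- function(name, iupac, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  iupac <- toupper(iupac)
  ch <- strsplit(iupac, "", fixed = TRUE)[[1L]]
  if (length(ch) < 10L) stop("primer '", name, "' shorter than 10 nt", call. = FALSE)
  bad <- which(!(ch %in% names(.IUPAC)))
  if (length(bad)) {
    stop("invalid IUPAC code '", ch[bad[1L]], "' at position ", bad[1L],
         " in primer '", name, "'", call. = FALSE)
  }
  structure(list(name = name, iupac = iupac, direction = direction),
            class = "degenerate_primer")
}

#' Read primers from a TSV (columns: name, direction, iupac)
#' @param path tab-separated file; lines starting with `#` are comments.
#' @return list of [degenerate_primer()] objects.
#' @export
read_primers <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)),
         function(i) degenerate_primer(df$name[i], df$iupac[i], df$direction[i]))
}

# Mismatch-tolerant degenerate match offsets (0-based starts) of a primer
# pattern against a template string.
primer_match_starts <- function(template_chars, primer_chars, max_mismatches) {
  lp <- length(primer_chars)
  lt <- length(template_chars)
  if (lp > lt) return(integer(0))
  ok <- matrix(FALSE, nrow = lp, ncol = lt)
  for (j in seq_len(lp)) {
    exp_j <- .IUPAC[[primer_chars[j]]]
    ok[j, ] <- template_chars %in% exp_j | template_chars == "N"
  }
  starts <- integer(0)
  for (s in 0:(lt - lp)) {
    mm <- sum(!ok[cbind(seq_len(lp), s + seq_len(lp))])
    if (mm <= max_mismatches) starts <- c(starts, s)
  }
  starts
}

#' In-silico PCR with degenerate primers
#'
#' Finds all forward/reverse primer site pairs on a template and returns the
#' predicted amplicons. The forward primer is matched on the forward strand;
#' the reverse primer (written 5'->3' on the antisense strand) is matched via
#' its reverse complement. Matching is IUPAC-aware and mismatch-tolerant.
#'
#' @param template single named nt string (or unnamed character scalar).
#' @param fwd,rev [degenerate_primer()] objects.
#' @param max_mismatches tolerated mismatches per primer site.
#' @param min_len,max_len full product length bounds (primer-to-primer).
#' @param trim_primers if `TRUE` (default, matching the convention of trimming
#'   primer sequences before analysis) the returned `sequence` is the insert
#'   between the primer sites; coordinates of the full product are always
#'   reported.
#' @return tibble: template_id, start, end (0-based half-open, full product),
#'   fwd_end, rev_start (insert bounds), fwd_name, rev_name, length, sequence.
#'   Sorted by start, then end.
#' @export
insilico_pcr <- function(template, fwd, rev, max_mismatches = 0L,
                         min_len = 0L, max_len = Inf, trim_primers = TRUE) {
  stopifnot(inherits(fwd, "degenerate_primer"), inherits(rev, "degenerate_primer"))
  template_id <- if (!is.null(names(template))) names(template)[1L] else "template"
  tmpl <- toupper(template[[1L]])
  tch <- strsplit(tmpl, "", fixed = TRUE)[[1L]]
  fch <- strsplit(fwd$iupac, "", fixed = TRUE)[[1L]]
  # reverse primer binds the antisense strand; its footprint on the forward
  # strand is the reverse complement of the primer
  rch <- strsplit(revcomp(rev$iupac), "", fixed = TRUE)[[1L]]

  empty <- tibble(template_id = character(0), start = integer(0),
                  end = integer(0), fwd_end = integer(0), rev_start = integer(0),
                  fwd_name = character(0), rev_name = character(0),
                  length = integer(0), sequence = character(0))
  if (length(fch) > length(tch) || length(rch) > length(tch)) return(empty)

  f_starts <- primer_match_starts(tch, fch, max_mismatches)
  r_starts <- primer_match_starts(tch, rch, max_mismatches)
  if (!length(f_starts) || !length(r_starts)) return(empty)

  rows <- list()
  for (fs in f_starts) {
    for (rs in r_starts) {
      start <- fs
      end <- rs + length(rch)           # half-open
      len <- end - start
      if (rs < fs + length(fch)) next   # sites must not overlap/invert
      if (len < min_len || len > max_len) next
      ins_start <- fs + length(fch)
      ins_end <- rs
      seqout <- if (trim_primers) {
        substr(tmpl, ins_start + 1L, ins_end)
      } else {
        substr(tmpl, start + 1L, end)
      }
      rows[[length(rows) + 1L]] <- tibble(
        template_id = template_id, start = start, end = end,
        fwd_end = ins_start, rev_start = ins_end,
        fwd_name = fwd$name, rev_name = rev$name,
        length = len, sequence = seqout)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}
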