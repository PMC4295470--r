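#' Pairwise protein alignment with EMBOSS-style statistics
#'
#' Optimal affine-gap alignment under BLOSUM62 with gap open 10 and gap
#' extend 0.5 (a gap of length L costs 10 + 0.5 L, i.e. the open cost is
#' charged together with the first gap residue). Identity, similarity and gap
#' percentages use the full alignment length as denominator, matching the
#' "id.(%) sim.(%) Gaps n/len (%)" reporting style of EMBOSS tools. Similarity
#' counts columns whose substitution score is positive (identities included).
#'
#' @param a,b single ungapped aa strings (named or plain).
#' @param mode `"local"` (Smith-Waterman) or `"global"` (Needleman-Wunsch).
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' @return list with `aligned` (two gapped strings), `score`, and `stats`
#'   (tibble: identity_pct, similarity_pct, gap_count, gap_pct, aligned_length).
#' @export
align_pairwise <- function(a, b, mode = c("local", "global"),
                           gap_open = 10, gap_extend = 0.5) {
  mode <- match.arg(mode)
  sa <- toupper(a[[1L]]); sb <- toupper(b[[1L]])
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence", call. = FALSE)
  if (grepl("-", sa, fixed = TRUE) || grepl("-", sb, fixed = TRUE)) {
    stop("input sequences must be ungapped", call. = FALSE)
  }
  mat <- blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    type = if (mode == "local") "local" else "global",
    substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  stats <- alignment_stats(al_a, al_b, mat)
  list(aligned = c(al_a, al_b), score = Biostrings::score(pa), stats = stats)
}

blosum62 <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  get("BLOSUM62", envir = environment())
}

#' Column statistics for a pairwise alignment
#'
#' @param al_a,al_b equal-length gapped strings.
#' @param mat substitution matrix (defaults to BLOSUM62).
#' @return one-row tibble: identity_pct, similarity_pct, gap_count, gap_pct,
#'   aligned_length.
#' @export
alignment_stats <- function(al_a, al_b, mat = blosum62()) {
  ca <- strsplit(al_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(al_b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  L <- length(ca)
  gap <- ca == "-" | cb == "-"
  ident <- !gap & ca == cb
  pos <- logical(L)
  both <- which(!gap & ca %in% rownames(mat) & cb %in% colnames(mat))
  pos[both] <- mat[cbind(ca[both], cb[both])] > 0
  tibble(identity_pct = 100 * sum(ident) / L,
         similarity_pct = 100 * sum(pos | ident) / L,
         gap_count = sum(gap),
         gap_pct = 100 * sum(gap) / L,
         aligned_length = L)
}

#' Back-translate a protein alignment into a codon-delimited alignment
#'
#' Each amino-acid column expands to one codon column; protein gaps become
#' `---`. Every protein row must translate exactly (frame 0) from its coding
#' sequence.
#'
#' @param prot_aln gapped aa records (a [protein_alignment()] or compatible).
#' @param cds named ungapped nt sequences covering every aligned id.
#' @return a [codon_alignment()].
#' @export
backtranslate_alignment <- function(prot_aln, cds) {
  out <- character(length(prot_aln))
  names(out) <- names(prot_aln)
  for (i in seq_along(prot_aln)) {
    id <- names(prot_aln)[i]
    if (!(id %in% names(cds))) {
      stop("no coding sequence for aligned record '", id, "'", call. = FALSE)
    }
    aa_aln <- strsplit(prot_aln[[i]], "", fixed = TRUE)[[1L]]
    aa_ungapped <- aa_aln[aa_aln != "-"]
    nt <- toupper(cds[[id]])
    if (nchar(nt) < 3L * length(aa_ungapped)) {
      stop("coding sequence for '", id, "' shorter than the aligned protein",
           call. = FALSE)
    }
    trans <- strsplit(translate_nt(nt), "", fixed = TRUE)[[1L]][seq_along(aa_ungapped)]
    mism <- which(trans != aa_ungapped)
    if (length(mism)) {
      stop("record '", id, "': coding sequence translation differs from the ",
           "aligned protein at aa position ", mism[1L],
           " (", trans[mism[1L]], " vs ", aa_ungapped[mism[1L]], ")",
           call. = FALSE)
    }
    starts <- (seq_along(aa_ungapped) - 1L) * 3L + 1L
    codons <- substring(nt, starts, starts + 2L)
    row <- character(length(aa_aln))
    row[aa_aln == "-"] <- "---"
    row[aa_aln != "-"] <- codons
    out[i] <- paste(row, collapse = "")
  }
  codon_alignment(out)
}
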