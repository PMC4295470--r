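# Standard nuclear genetic code, taken from the Biostrings reference table.
# Kept as a plain named vector so the codon-counting machinery can iterate it.
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.codon_cache <- new.env(parent = emptyenv())

sense_codons <- function(code = genetic_code()) {
  names(code)[code != "*"]
}

#' Translate a nucleotide string
#'
#' Translates from `frame_offset` up to the last complete codon; 1-2 trailing
#' nucleotides are ignored. Codons containing `N` or any other ambiguity code
#' translate to `X`.
#'
#' @param seq nucleotide string (no gaps).
#' @param frame_offset 0, 1 or 2.
#' @param code genetic code as a named character vector (codon -> aa).
#' @return amino-acid string (may contain `*` for stops and `X`).
#' @export
translate_nt <- function(seq, frame_offset = 0L, code = genetic_code()) {
  stopifnot(frame_offset %in% 0:2)
  seq <- toupper(gsub("U", "T", seq))
  n <- nchar(seq)
  if (n < 3L + frame_offset) stop("sequence too short to translate", call. = FALSE)
  starts <- seq(1L + frame_offset, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Screen an open reading frame for interruptions
#'
#' A fragment is `intact` iff its translation in the given frame, up to the
#' last complete codon, contains no stop codon. Pseudogene-like fragments
#' carrying frameshift indels typically surface a downstream stop and are
#' reported `interrupted` with the stop codon indices (0-based).
#'
#' @param seq nucleotide string.
#' @param frame_offset reading-frame offset, 0-2.
#' @param code genetic code table.
#' @return list with `status` ("intact"/"interrupted"), `aa` (translation),
#'   and `reasons` (character vector naming internal stop codon indices).
#' @export
orf_screen <- function(seq, frame_offset = 0L, code = genetic_code()) {
  aa <- translate_nt(seq, frame_offset = frame_offset, code = code)
  stops <- which(strsplit(aa, "", fixed = TRUE)[[1L]] == "*")
  if (length(stops)) {
    list(status = "interrupted", aa = aa,
         reasons = paste0("stop codon at codon index ", stops - 1L))
  } else {
    list(status = "intact", aa = aa, reasons = character(0))
  }
}

#' Screen a collection of fragments and tabulate ORF status
#'
#' @param records named nt character vector.
#' @param frame_offset reading frame used for every fragment.
#' @return tibble: id, status, n_stops, aa.
#' @export
orf_screen_all <- function(records, frame_offset = 0L) {
  rows <- lapply(seq_along(records), function(i) {
    sc <- orf_screen(records[[i]], frame_offset = frame_offset)
    tibble(id = names(records)[i], status = sc$status,
           n_stops = length(sc$reasons), aa = sc$aa)
  })
  do.call(rbind, rows)
}
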