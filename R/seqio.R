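#' @importFrom tibble tibble as_tibble
#' @importFrom rlang hash
NULL

# Alphabets. Gaps ('-') are legal only when reading/holding alignments.
.NT_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")
.AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
               "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X", "B", "Z", "*")

#' Construct a validated sequence set
#'
#' A sequence set is a named character vector with an `alphabet` attribute
#' (`"nt"` or `"aa"`). All user-facing readers and the simulator return this
#' shape; most functions also accept a plain named character vector.
#'
#' @param residues named character vector of sequences (names are ids).
#' @param alphabet `"nt"` or `"aa"`.
#' @param gapped logical; allow `-` characters (alignment rows).
#' @return the validated named character vector with attributes set.
#' @export
seq_set <- function(residues, alphabet = c("nt", "aa"), gapped = FALSE) {
  alphabet <- match.arg(alphabet)
  ids <- names(residues)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every sequence must have a non-empty id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate sequence id: '", dup, "'", call. = FALSE)
  }
  if (any(!nzchar(residues))) {
    stop("empty sequence for id '", ids[!nzchar(residues)][1L], "'", call. = FALSE)
  }
  residues <- toupper(residues)
  legal <- if (alphabet == "nt") .NT_CHARS else .AA_CHARS
  if (gapped) legal <- c(legal, "-")
  for (i in seq_along(residues)) {
    ch <- strsplit(residues[[i]], "", fixed = TRUE)[[1L]]
    bad <- which(!(ch %in% legal))
    if (length(bad)) {
      stop("illegal character '", ch[bad[1L]], "' at position ", bad[1L],
           " in sequence '", ids[i], "' (alphabet: ", alphabet, ")",
           call. = FALSE)
    }
  }
  structure(residues, alphabet = alphabet, gapped = gapped, class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat("<seq_set> ", length(x), " ", attr(x, "alphabet"), " sequence(s)\n", sep = "")
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- x[[i]]
    cat("  ", names(x)[i], " [", nchar(s), "] ",
        substr(s, 1, 40), if (nchar(s) > 40) "..." else "", "\n", sep = "")
  }
  if (length(x) > n) cat("  ... and ", length(x) - n, " more\n", sep = "")
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, i) {
  structure(NextMethod(), alphabet = attr(x, "alphabet"),
            gapped = attr(x, "gapped"), class = "seq_set")
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @param alphabet `"nt"` or `"aa"`.
#' @param gapped allow `-` (set `TRUE` when reading alignments).
#' @return a [seq_set()]; record order follows the file. An empty file yields
#'   an empty set with a warning.
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa"), gapped = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(seq_set_empty(alphabet, gapped))
  }
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not FASTA: first non-blank line is not a header", call. = FALSE)
  idx <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  grp <- factor(idx[!hdr], levels = seq_len(sum(hdr)))
  seqs <- vapply(split(lines[!hdr], grp),
                 function(x) paste(gsub("\\s", "", x), collapse = ""), "")
  # a header with no sequence lines yields "" and errors inside seq_set
  res <- seq_set(stats::setNames(seqs, ids), alphabet = alphabet, gapped = gapped)
  attr(res, "descriptions") <- headers
  res
}

seq_set_empty <- function(alphabet, gapped = FALSE) {
  structure(stats::setNames(character(0), character(0)),
            alphabet = alphabet, gapped = gapped, class = "seq_set")
}

#' Write sequences to FASTA
#'
#' Round-trips with [read_fasta()]. An empty set writes an empty file.
#'
#' @param records named character vector / [seq_set()].
#' @param path output file.
#' @param wrap line width for sequence lines.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(wrap >= 1L)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a protein multiple alignment (FASTA or Clustal)
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param alphabet `"aa"` (default) or `"nt"`.
#' @return a gapped [seq_set()] whose rows all have equal length.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           alphabet = c("aa", "nt")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  if (format == "fasta") {
    res <- read_fasta(path, alphabet = alphabet, gapped = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !grepl("^CLUSTAL", lines[1L], ignore.case = TRUE)) {
      stop("not a Clustal file (missing CLUSTAL header)", call. = FALSE)
    }
    body <- lines[-1L]
    body <- body[nzchar(trimws(body))]
    body <- body[!grepl("^\\s", body)]            # drop conservation lines
    parts <- regmatches(body, regexec("^(\\S+)\\s+([A-Za-z*.-]+)\\s*\\d*$", body))
    keep <- lengths(parts) == 3L
    acc <- list()
    for (p in parts[keep]) {
      acc[[p[2L]]] <- paste0(acc[[p[2L]]] %||% "", gsub("\\.", "-", p[3L]))
    }
    if (!length(acc)) stop("no sequences found in Clustal file", call. = FALSE)
    res <- seq_set(stats::setNames(toupper(unlist(acc)), names(acc)),
                   alphabet = alphabet, gapped = TRUE)
  }
  if (length(res) && length(unique(nchar(res))) != 1L) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  res
}

#' Validate a protein alignment
#'
#' @param records gapped aa sequences, all the same length, at least two.
#' @return the records, classed as a protein alignment.
#' @export
protein_alignment <- function(records) {
  records <- seq_set(unclass(records), alphabet = "aa", gapped = TRUE)
  if (length(records) < 2L) stop("an alignment needs >= 2 records", call. = FALSE)
  if (length(unique(nchar(records))) != 1L) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  class(records) <- c("protein_alignment", "seq_set")
  records
}

#' Validate a codon-delimited nucleotide alignment
#'
#' Checks the codon-alignment invariants: column count divisible by three,
#' every gap run occupying whole codons, and a stop-free reading frame after
#' ungapping each row.
#'
#' @param records gapped nt sequences of equal length.
#' @param check_stops verify ungapped rows are stop-free (frame 0).
#' @return the records, classed as a codon alignment.
#' @export
codon_alignment <- function(records, check_stops = TRUE) {
  records <- seq_set(unclass(records), alphabet = "nt", gapped = TRUE)
  if (length(records) < 2L) stop("an alignment needs >= 2 records", call. = FALSE)
  L <- unique(nchar(records))
  if (length(L) != 1L) stop("alignment rows have unequal lengths", call. = FALSE)
  if (L %% 3L != 0L) stop("alignment length ", L, " not divisible by 3", call. = FALSE)
  for (i in seq_along(records)) {
    ch <- strsplit(records[[i]], "", fixed = TRUE)[[1L]]
    codons <- matrix(ch, nrow = 3L)
    gap_per_codon <- colSums(codons == "-")
    if (any(gap_per_codon %in% c(1L, 2L))) {
      stop("gap run not codon-delimited in record '", names(records)[i], "'",
           call. = FALSE)
    }
    if (check_stops) {
      aa <- translate_nt(gsub("-", "", records[[i]]))
      if (grepl("*", aa, fixed = TRUE)) {
        stop("record '", names(records)[i],
             "' contains an internal stop codon after ungapping", call. = FALSE)
      }
    }
  }
  class(records) <- c("codon_alignment", "seq_set")
  records
}

#' Split alignment rows into codon matrices
#'
#' @param aln codon alignment.
#' @return character matrix, rows = records, columns = codon columns.
#' @export
codon_matrix <- function(aln) {
  n_cod <- nchar(aln[[1L]]) %/% 3L
  starts <- (seq_len(n_cod) - 1L) * 3L + 1L
  m <- matrix("", nrow = length(aln), ncol = n_cod,
              dimnames = list(names(aln), NULL))
  for (i in seq_along(aln)) m[i, ] <- substring(aln[[i]], starts, starts + 2L)
  m
}
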