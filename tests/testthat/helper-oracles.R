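# Independent oracle implementations used to validate the package's
# machinery. These deliberately re-derive everything from first principles
# (plain enumeration), sharing no code with the implementation under test.

.ORACLE_CODE <- as.character(Biostrings::GENETIC_CODE)
names(.ORACLE_CODE) <- names(Biostrings::GENETIC_CODE)

oracle_neighbors <- function(codon) {
  nts <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) for (nt in setdiff(nts, ch[pos])) {
    mut <- ch; mut[pos] <- nt
    out <- c(out, paste(mut, collapse = ""))
  }
  out
}

# NG86 synonymous site count of one codon: per position, fraction of the 3
# single-nt changes that preserve the amino acid (stop = non-synonymous).
oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa <- .ORACLE_CODE[codon]
  s <- 0
  for (pos in 1:3) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[pos])
    syn <- 0
    for (nt in alt) {
      mut <- ch; mut[pos] <- nt
      m <- paste(mut, collapse = "")
      if (.ORACLE_CODE[m] != "*" && .ORACLE_CODE[m] == aa) syn <- syn + 1
    }
    s <- s + syn / 3
  }
  s
}

# all orderings of a set (tiny n)
oracle_perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], oracle_perms(v[-i]))
  }))
}

# pathway-averaged syn/nonsyn differences between two codons, uniform
# weights over stop-free minimal pathways; c(NA, NA) if all blocked
oracle_pair_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(0, 0))
  perms <- oracle_perms(pos)
  sds <- c(); nds <- c()
  for (r in seq_len(nrow(perms))) {
    cur <- a; sd <- 0; nd <- 0; ok <- TRUE
    for (p in perms[r, ]) {
      nxt <- cur; nxt[p] <- b[p]
      if (.ORACLE_CODE[paste(nxt, collapse = "")] == "*") { ok <- FALSE; break }
      if (.ORACLE_CODE[paste(cur, collapse = "")] ==
          .ORACLE_CODE[paste(nxt, collapse = "")]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { sds <- c(sds, sd); nds <- c(nds, nd) }
  }
  if (!length(sds)) return(c(NA_real_, NA_real_))
  c(mean(sds), mean(nds))
}

# brute-force in-silico PCR: scan every offset pair with IUPAC expansion
oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_site_matches <- function(template, pattern, max_mm) {
  tch <- strsplit(template, "")[[1]]
  pch <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  if (length(pch) > length(tch)) return(hits)
  for (s in 0:(length(tch) - length(pch))) {
    mm <- 0
    for (j in seq_along(pch)) {
      tb <- tch[s + j]
      if (!(tb %in% oracle_iupac[[pch[j]]] || tb == "N")) mm <- mm + 1
    }
    if (mm <= max_mm) hits <- c(hits, s)
  }
  hits
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

oracle_pcr <- function(template, fwd_iupac, rev_iupac, max_mm, min_len, max_len) {
  f <- oracle_site_matches(template, fwd_iupac, max_mm)
  r <- oracle_site_matches(template, oracle_revcomp(rev_iupac), max_mm)
  rl <- nchar(rev_iupac); fl <- nchar(fwd_iupac)
  out <- NULL
  for (fs in f) for (rs in r) {
    if (rs < fs + fl) next
    len <- rs + rl - fs
    if (len >= min_len && len <= max_len) out <- rbind(out, c(fs, rs + rl))
  }
  out
}

# exhaustive affine-gap global alignment score by memoised 3-state recursion
# (gap of length L costs open + ext * L); independent of Biostrings
oracle_global_score <- function(a, b, mat, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    if (i > 0 && j > 0) {
      s <- mat[A[i], B[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    }
    if (i > 0) {  # gap in b (consume A[i])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
    }
    if (j > 0) {  # gap in a
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exact rank-sum two-sided p by full subset enumeration (midranks)
oracle_rank_sum_p <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x)
  w <- sum(r[seq_len(nx)])
  combs <- combn(length(r), nx)
  sums <- apply(combs, 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(sums >= w - 1e-9), mean(sums <= w + 1e-9)))
}

# exact one-sided (greater) signed-rank p by sign-flip enumeration
oracle_signed_rank_p <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  n <- length(d)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  sums <- grid %*% r
  mean(sums >= v - 1e-9)
}

random_aa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_nt <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a kinase-like scaffold with canonical anchors at fixed aa offsets,
# built by hand (not via the simulator) for annotation tests
scaffold_kinase <- function(seed = 42, rd = TRUE, length_aa = 165,
                            mutate = NULL) {
  set.seed(seed)
  pool <- strsplit("ARNDQHIMFPSTWYV", "")[[1]]  # no G/K/E/L/C: avoids chance anchors
  s <- sample(pool, length_aa, replace = TRUE)
  put <- function(s, pos, motif) {  # pos 0-based
    s[pos + seq_len(nchar(motif))] <- strsplit(motif, "")[[1]]
    s
  }
  s <- put(s, 5, "GSGGFG")
  s <- put(s, 30, "VAIK")
  s <- put(s, 55, "LEV")
  s <- put(s, 95, if (rd) "HRDLKPEN" else "HCDLKPEN")
  s <- put(s, 125, "DFG")
  s <- put(s, 148, "APE")
  if (!is.null(mutate)) s[mutate$pos + 1] <- mutate$to
  paste(s, collapse = "")
}
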