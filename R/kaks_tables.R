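# Codon-counting machinery shared by the NG86 and kappa-weighted ("YN-approx")
# estimators. Everything is precomputed once per (code, kappa) into lookup
# tables: synonymous site fractions per codon, and pathway-averaged
# synonymous / non-synonymous difference counts per ordered codon pair.

.NT <- c("A", "C", "G", "T")

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Synonymous sites of one codon. Each of the 3 positions contributes the
# (kappa-)weighted fraction of its 3 possible changes that are synonymous;
# changes creating a stop codon count as non-synonymous. N + S = 3 exactly.
codon_syn_sites <- function(codon, code, kappa = 1) {
  ch <- strsplit(codon, "", fixed = TRUE)[[1L]]
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    w_syn <- 0; w_tot <- 0
    for (nt in setdiff(.NT, ch[pos])) {
      mut <- ch; mut[pos] <- nt
      mcodon <- paste(mut, collapse = "")
      w <- if (is_transition(ch[pos], nt)) kappa else 1
      w_tot <- w_tot + w
      if (code[[mcodon]] != "*" && code[[mcodon]] == aa) w_syn <- w_syn + w
    }
    s <- s + w_syn / w_tot
  }
  s
}

# Average synonymous/non-synonymous step counts over all minimal mutational
# pathways between two codons. Pathways passing through a stop codon are
# discarded; NG86 weights surviving pathways uniformly, the kappa-weighted
# variant weights each pathway by the product of its step rates. Returns
# c(sd, nd) or c(NA, NA) when every pathway is blocked.
codon_pair_diffs <- function(c1, c2, code, kappa = 1) {
  a <- strsplit(c1, "", fixed = TRUE)[[1L]]
  b <- strsplit(c2, "", fixed = TRUE)[[1L]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0L) return(c(0, 0))
  perms <- perms_of(pos)
  tot_w <- 0; sd_acc <- 0; nd_acc <- 0
  for (p in seq_len(nrow(perms))) {
    cur <- a
    sd_p <- 0; nd_p <- 0; w <- 1; blocked <- FALSE
    for (step in perms[p, ]) {
      nxt <- cur; nxt[step] <- b[step]
      ncodon <- paste(nxt, collapse = "")
      if (code[[ncodon]] == "*") { blocked <- TRUE; break }
      syn <- code[[paste(cur, collapse = "")]] == code[[ncodon]]
      if (syn) sd_p <- sd_p + 1 else nd_p <- nd_p + 1
      if (kappa != 1 && is_transition(cur[step], b[step])) w <- w * kappa
      cur <- nxt
    }
    if (blocked) next
    tot_w <- tot_w + w
    sd_acc <- sd_acc + w * sd_p
    nd_acc <- nd_acc + w * nd_p
  }
  if (tot_w == 0) return(c(NA_real_, NA_real_))
  c(sd_acc / tot_w, nd_acc / tot_w)
}

perms_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L))
  if (n == 2L) return(rbind(x, rev(x)))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- perms_of(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  unname(out)
}

#' Precomputed codon-counting tables
#'
#' Builds (and caches) the per-codon synonymous site counts and the
#' pathway-averaged difference-count matrices for all sense-codon pairs,
#' for a given transition/transversion weight.
#'
#' @param kappa transition/transversion rate ratio used to weight sites and
#'   pathways (`1` recovers plain NG86 counting).
#' @return list: `codons` (sense codons), `syn_sites` (numeric, per codon),
#'   `sd`, `nd` (61 x 61 matrices, `NA` where all pathways are blocked).
#' @export
codon_count_tables <- function(kappa = 1) {
  key <- paste0("k", format(kappa, digits = 10))
  if (!is.null(.codon_cache[[key]])) return(.codon_cache[[key]])
  code <- genetic_code()
  cods <- sense_codons(code)
  n <- length(cods)
  syn_sites <- vapply(cods, codon_syn_sites, 0, code = code, kappa = kappa)
  sd <- matrix(0, n, n, dimnames = list(cods, cods))
  nd <- sd
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- codon_pair_diffs(cods[i], cods[j], code, kappa = kappa)
      sd[i, j] <- sd[j, i] <- d[1L]
      nd[i, j] <- nd[j, i] <- d[2L]
    }
  }
  res <- list(codons = cods, syn_sites = syn_sites, sd = sd, nd = nd,
              kappa = kappa)
  .codon_cache[[key]] <- res
  res
}
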