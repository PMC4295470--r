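#' Pairwise Ka/Ks estimation on codon-aligned rows
#'
#' Nei-Gojobori (NG86) counting with pathway averaging and Jukes-Cantor
#' correction, or a kappa-weighted variant (`"YN-approx"`) in which sites and
#' pathways are weighted by a transition/transversion ratio estimated from
#' four-fold degenerate sites. Codon columns containing a gap, an ambiguity
#' code, or a stop in either row are skipped, as are codon pairs whose every
#' minimal mutational pathway passes through a stop.
#'
#' @param a,b codon-aligned nucleotide strings (rows of one codon alignment).
#' @param method `"NG86"` (default) or `"YN-approx"`.
#' @return list of class `kaks_estimate`: `N`, `S` (site counts),
#'   `Nd`, `Sd` (difference counts), `pn`, `ps`, `Ka`, `Ks`, `omega`,
#'   `omega_flag` (`"ok"`, `"undefined_inf"`, `"undefined_na"`, `"saturated"`),
#'   `n_codons_compared`, `n_codons_skipped`, `kappa`, `method`.
#' @export
kaks_pair <- function(a, b, method = c("NG86", "YN-approx")) {
  method <- match.arg(method)
  cc <- pair_codon_counts(a, b, method = method)
  est <- kaks_from_counts(sum(cc$s_sites[cc$comparable]),
                          sum(cc$n_sites[cc$comparable]),
                          sum(cc$sd[cc$comparable]),
                          sum(cc$nd[cc$comparable]),
                          n_comparable = sum(cc$comparable))
  est$n_codons_skipped <- sum(!cc$comparable)
  est$kappa <- cc$kappa
  est$method <- method
  class(est) <- "kaks_estimate"
  est
}

# Per-codon-column counts for one aligned pair. Returns vectors over codon
# columns: comparable flag, (averaged) synonymous / non-synonymous sites,
# pathway-averaged difference counts. Shared by kaks_pair() and the sliding
# window machinery (window sums are sums over these arrays).
pair_codon_counts <- function(a, b, method = c("NG86", "YN-approx")) {
  method <- match.arg(method)
  ca <- split_codons(a)
  cb <- split_codons(b)
  stopifnot(length(ca) == length(cb))
  kappa <- 1
  if (method == "YN-approx") kappa <- estimate_kappa_4fold(ca, cb)
  tab <- codon_count_tables(kappa = kappa)
  ia <- match(ca, tab$codons)
  ib <- match(cb, tab$codons)
  comparable <- !is.na(ia) & !is.na(ib)
  n <- length(ca)
  s_sites <- n_sites <- sd <- nd <- numeric(n)
  idx <- which(comparable)
  if (length(idx)) {
    s_sites[idx] <- (tab$syn_sites[ia[idx]] + tab$syn_sites[ib[idx]]) / 2
    n_sites[idx] <- 3 - s_sites[idx]
    sd[idx] <- tab$sd[cbind(ia[idx], ib[idx])]
    nd[idx] <- tab$nd[cbind(ia[idx], ib[idx])]
    blocked <- idx[is.na(sd[idx])]
    if (length(blocked)) {    # all pathways hit stops: skip the codon pair
      comparable[blocked] <- FALSE
      s_sites[blocked] <- n_sites[blocked] <- sd[blocked] <- nd[blocked] <- 0
    }
  }
  list(comparable = comparable, s_sites = s_sites, n_sites = n_sites,
       sd = sd, nd = nd, kappa = kappa)
}

split_codons <- function(x) {
  x <- toupper(x[[1L]])
  stopifnot(nchar(x) %% 3L == 0L)
  starts <- seq(1L, nchar(x), by = 3L)
  substring(x, starts, starts + 2L)
}

# Estimate kappa (ts/tv) from third positions of four-fold degenerate codons
# shared by the pair (first two codon positions identical between the rows).
# At neutral sites the expected ts:tv count ratio is kappa:2.
estimate_kappa_4fold <- function(ca, cb) {
  code <- genetic_code()
  fourfold <- function(codon) {
    if (is.na(code[codon]) || code[codon] == "*") return(FALSE)
    pre <- substr(codon, 1L, 2L)
    length(unique(code[paste0(pre, .NT)])) == 1L
  }
  ts <- 0L; tv <- 0L
  for (i in seq_along(ca)) {
    if (!(ca[i] %in% names(code)) || !(cb[i] %in% names(code))) next
    if (substr(ca[i], 1, 2) != substr(cb[i], 1, 2)) next
    if (!fourfold(ca[i]) || !fourfold(cb[i])) next
    x <- substr(ca[i], 3, 3); y <- substr(cb[i], 3, 3)
    if (x == y) next
    if (is_transition(x, y)) ts <- ts + 1L else tv <- tv + 1L
  }
  if (ts + tv == 0L) return(1)
  max(0.5, min(20, 2 * ts / max(tv, 0.5)))
}

#' Assemble a Ka/Ks estimate from aggregated counts
#'
#' Applies the Jukes-Cantor multiple-hit correction
#' `d = -(3/4) log(1 - (4/3) p)` to the synonymous and non-synonymous
#' difference proportions.
#'
#' @param S,N synonymous / non-synonymous site counts.
#' @param Sd,Nd synonymous / non-synonymous difference counts.
#' @param n_comparable number of comparable codons behind the counts.
#' @return list with the `kaks_estimate` fields (unclassed).
#' @export
kaks_from_counts <- function(S, N, Sd, Nd, n_comparable = NA_integer_) {
  if (is.na(n_comparable) || n_comparable == 0L) {
    stop("no comparable codons between the two rows", call. = FALSE)
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    if (p == 0) return(0)
    -(3 / 4) * log(1 - (4 / 3) * p)
  }
  Ks <- jc(ps); Ka <- jc(pn)
  flag <- "ok"
  omega <- NA_real_
  if (is.na(Ka) || is.na(Ks)) {
    flag <- "saturated"
  } else if (Ks == 0 && Ka == 0) {
    flag <- "undefined_na"
  } else if (Ks == 0) {
    flag <- "undefined_inf"
    omega <- Inf
  } else {
    omega <- Ka / Ks
  }
  list(N = N, S = S, Nd = Nd, Sd = Sd, pn = pn, ps = ps,
       Ka = Ka, Ks = Ks, omega = omega, omega_flag = flag,
       n_codons_compared = n_comparable)
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat("<kaks_estimate> ", x$method, "  codons=", x$n_codons_compared,
      " (skipped ", x$n_codons_skipped, ")\n", sep = "")
  cat(sprintf("  S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n", x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  Ks=%.4f Ka=%.4f omega=%s [%s]\n", x$Ks, x$Ka,
              format(x$omega, digits = 4), x$omega_flag))
  invisible(x)
}
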