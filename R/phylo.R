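#' Poisson-corrected amino-acid distance matrix
#'
#' For each pair, `p` = differing positions / compared positions over the
#' alignment columns retained by the deletion mode, and
#' `d = -ln(1 - p)` (substitutions per site, rate uniformity among sites).
#'
#' @param aln protein alignment (gapped [seq_set()] / [protein_alignment()]).
#' @param deletion `"pairwise"` (default; columns gap-free in the two rows
#'   being compared) or `"complete"` (columns gap-free in every row).
#' @return symmetric labeled distance matrix.
#' @export
poisson_distance <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  n <- length(aln)
  if (n < 2L) stop("need >= 2 sequences", call. = FALSE)
  chars <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  rownames(chars) <- names(aln)
  if (deletion == "complete") {
    keep <- colSums(chars == "-") == 0L
    if (!any(keep)) stop("no gap-free columns under complete deletion", call. = FALSE)
    chars <- chars[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable columns between '", names(aln)[i], "' and '",
             names(aln)[j], "' under pairwise deletion", call. = FALSE)
      }
      p <- mean(chars[i, ok] != chars[j, ok])
      if (p >= 1) {
        stop("Poisson distance undefined (p >= 1) for pair '",
             names(aln)[i], "' / '", names(aln)[j], "'", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via the standard implementation in \pkg{ape});
#' negative branch-length estimates are clamped to zero for reporting, with
#' the raw minimum recorded as an attribute.
#'
#' @param dm symmetric non-negative distance matrix with labels.
#' @return an \pkg{ape} `phylo` object (unrooted).
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (nrow(dm) < 3L) stop("need >= 3 taxa to build a tree", call. = FALSE)
  if (any(dm < 0)) stop("negative distances in input", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix not symmetric", call. = FALSE)
  if (any(!is.finite(dm))) stop("non-finite distances in input", call. = FALSE)
  tr <- ape::nj(stats::as.dist(dm))
  raw_min <- min(tr$edge.length)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "raw_min_edge") <- raw_min
  tr
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-distance NJ tree per replicate, and annotates each internal
#' bipartition of the point-estimate tree with the percentage of replicates
#' containing it (stored in `node.label`). Replicates in which a pairwise
#' distance is undefined (p >= 1 or no comparable columns) are dropped and
#' counted; more than 10% dropped is an error.
#'
#' @param aln protein alignment.
#' @param replicates bootstrap replicates (>= 1; the classical choice is 1000).
#' @param seed RNG seed (reproducible supports).
#' @param deletion gap-deletion mode, see [poisson_distance()].
#' @return `phylo` tree with `node.label` supports (%); attributes
#'   `n_dropped` and `replicates_used`.
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed = 1L,
                              deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(replicates >= 1L)
  point <- nj_tree(poisson_distance(aln, deletion = deletion))
  L <- nchar(aln[[1L]])
  set.seed(seed)
  trees <- vector("list", replicates)
  dropped <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    res <- resample_columns(aln, cols)
    tr <- tryCatch(nj_tree(poisson_distance(res, deletion = deletion)),
                   error = function(e) NULL)
    if (is.null(tr)) dropped <- dropped + 1L else trees[[r]] <- tr
  }
  if (dropped > 0.1 * replicates) {
    stop(dropped, "/", replicates,
         " bootstrap replicates had undefined distances", call. = FALSE)
  }
  if (dropped) warning(dropped, " bootstrap replicate(s) dropped", call. = FALSE)
  trees <- trees[!vapply(trees, is.null, TRUE)]
  counts <- ape::prop.clades(point, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- round(100 * counts / length(trees), 1)
  attr(point, "n_dropped") <- dropped
  attr(point, "replicates_used") <- length(trees)
  point
}

resample_columns <- function(aln, cols) {
  chars <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  out <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
  structure(stats::setNames(out, names(aln)), alphabet = attr(aln, "alphabet"),
            gapped = TRUE, class = "seq_set")
}

#' Subfamily assignment from a supported tree and a reference panel
#'
#' A query leaf is labeled with subfamily S iff the smallest supported clade
#' (bipartition side with support >= `min_support`) containing the query
#' contains at least one reference leaf and all its reference leaves belong
#' to S; queries in mixed or unsupported neighborhoods are `"uncertain"`.
#'
#' @param tree `phylo` with `node.label` percent supports (see
#'   [bootstrap_support()]).
#' @param reference_labels named character vector: reference leaf id ->
#'   subfamily.
#' @param min_support support threshold in percent (default 70).
#' @return tibble: seq_id, subfamily ("uncertain" when unresolved),
#'   clade_support, n_reference_in_clade.
#' @export
assign_groups <- function(tree, reference_labels, min_support = 70) {
  refs <- intersect(names(reference_labels), tree$tip.label)
  if (!length(refs)) stop("tree contains no reference leaves", call. = FALSE)
  queries <- setdiff(tree$tip.label, names(reference_labels))
  ntip <- length(tree$tip.label)
  supports <- suppressWarnings(as.numeric(tree$node.label))
  # leaf sets of each internal node (rooted view); in the unrooted tree each
  # internal edge's bipartition is {clade leaves, complement} -- consider both
  clades <- lapply(seq_len(tree$Nnode) + ntip, function(nd) {
    tree$tip.label[phangorn_descendants(tree, nd)]
  })
  rows <- lapply(queries, function(q) {
    cands <- list()
    for (k in seq_along(clades)) {
      if (is.na(supports[k]) || supports[k] < min_support) next
      side <- clades[[k]]
      comp <- setdiff(tree$tip.label, side)
      if (q %in% side) cands[[length(cands) + 1L]] <- list(set = side, sup = supports[k])
      if (q %in% comp) cands[[length(cands) + 1L]] <- list(set = comp, sup = supports[k])
    }
    cands <- cands[order(vapply(cands, function(z) length(z$set), 0L))]
    for (cand in cands) {
      crefs <- intersect(cand$set, refs)
      if (!length(crefs)) next
      fams <- unique(reference_labels[crefs])
      if (length(fams) == 1L) {
        return(tibble(seq_id = q, subfamily = unname(fams),
                      clade_support = cand$sup,
                      n_reference_in_clade = length(crefs)))
      } else {
        return(tibble(seq_id = q, subfamily = "uncertain",
                      clade_support = cand$sup,
                      n_reference_in_clade = length(crefs)))
      }
    }
    tibble(seq_id = q, subfamily = "uncertain", clade_support = NA_real_,
           n_reference_in_clade = 0L)
  })
  do.call(rbind, rows)
}

# Tip indices descending from an internal node (simple traversal; avoids a
# hard dependency on phangorn for one helper).
phangorn_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

#' Write a tree to Newick with supports as internal node labels
#' @param tree `phylo` object.
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
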