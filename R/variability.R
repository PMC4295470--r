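#' Map codon positions subject to non-synonymous variation per group
#'
#' A codon column is non-synonymously variable within a group iff at least
#' two distinct amino acids are encoded among the group's gap-free members at
#' that column. A column is analysed iff at least one group is gap-free there
#' in >= 2 members ("excluding gaps"); per-group participation requires the
#' group to have >= 2 gap-free members at the column. An optional stricter
#' codon-level mode additionally requires a non-synonymous nucleotide
#' difference between some pair of member codons (equivalent at gap-free
#' columns, but stated for completeness).
#'
#' @param aln [codon_alignment()].
#' @param groups named list: group label -> character vector of member ids
#'   (>= 2 members each).
#' @param level `"aa"` (default; >= 2 distinct encoded amino acids) or
#'   `"codon"` (pairwise non-synonymous nucleotide change).
#' @return tibble (`variability_table`): position (1-based aa/codon column),
#'   analysed, one logical column `var_<group>` per group, n_groups_variable,
#'   shared_class ("not_variable", "exclusive", "shared_2plus", "shared_all"),
#'   residue inventory string per group (`inv_<group>`, e.g. "G:3,S:1").
#' @export
nonsyn_position_map <- function(aln, groups, level = c("aa", "codon")) {
  level <- match.arg(level)
  code <- genetic_code()
  for (g in names(groups)) {
    if (length(groups[[g]]) < 2L) {
      stop("group '", g, "' has fewer than 2 members", call. = FALSE)
    }
    missing_ids <- setdiff(groups[[g]], names(aln))
    if (length(missing_ids)) {
      stop("group '", g, "' members not in alignment: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
  }
  cm <- codon_matrix(aln)
  n_pos <- ncol(cm)
  n_grp <- length(groups)
  gnames <- names(groups)

  var_mat <- matrix(FALSE, n_pos, n_grp, dimnames = list(NULL, gnames))
  part_mat <- matrix(FALSE, n_pos, n_grp)  # group participates at column
  inv_mat <- matrix(NA_character_, n_pos, n_grp)
  for (gi in seq_len(n_grp)) {
    sub <- cm[groups[[gnames[gi]]], , drop = FALSE]
    for (p in seq_len(n_pos)) {
      cods <- sub[, p]
      cods <- cods[!grepl("-", cods, fixed = TRUE)]
      if (length(cods) < 2L) next
      part_mat[p, gi] <- TRUE
      aas <- code[cods]
      aas[is.na(aas)] <- "X"
      if (level == "aa") {
        var_mat[p, gi] <- length(unique(aas)) >= 2L
      } else {
        var_mat[p, gi] <- any(outer(aas, aas, "!=") &
                              outer(cods, cods, "!="))
      }
      tab <- sort(table(aas), decreasing = TRUE)
      inv_mat[p, gi] <- paste0(names(tab), ":", as.integer(tab), collapse = ",")
    }
  }
  analysed <- rowSums(part_mat) >= 1L
  n_var <- rowSums(var_mat)
  shared <- ifelse(!analysed | n_var == 0L, ifelse(analysed, "not_variable", "not_analysed"),
            ifelse(n_var == 1L, "exclusive",
            ifelse(n_var == n_grp, "shared_all", "shared_2plus")))
  out <- tibble(position = seq_len(n_pos), analysed = analysed,
                n_groups_variable = as.integer(n_var), shared_class = shared)
  for (gi in seq_len(n_grp)) {
    out[[paste0("var_", gnames[gi])]] <- var_mat[, gi]
    out[[paste0("inv_", gnames[gi])]] <- inv_mat[, gi]
  }
  n_skipped <- sum(!analysed)
  if (n_skipped) {
    message(n_skipped, " column(s) skipped (gap-only or single-member in all groups)")
  }
  class(out) <- c("variability_table", class(out))
  out
}

#' Summary counts for a variability table
#'
#' Note `shared_all` positions also satisfy `shared_2plus` (nested classes):
#' `n_shared_2plus` counts positions variable in two or more groups,
#' `n_shared_all` those variable in every group. Percentages are reported
#' against both the variable-position and the shared-position denominators.
#'
#' @param vt a [nonsyn_position_map()] result.
#' @return list: n_positions_analysed, n_variable, n_shared_2plus,
#'   n_shared_all, pct_shared_2plus_of_variable, pct_shared_all_of_variable,
#'   pct_shared_all_of_shared, per_group_exclusive (named integer vector).
#' @export
shared_position_summary <- function(vt) {
  stopifnot(nrow(vt) > 0)
  var_cols <- grep("^var_", names(vt), value = TRUE)
  gnames <- sub("^var_", "", var_cols)
  n_analysed <- sum(vt$analysed)
  variable <- vt$n_groups_variable >= 1L
  n_variable <- sum(variable)
  n_2plus <- sum(vt$n_groups_variable >= 2L)
  n_all <- sum(vt$shared_class == "shared_all")
  excl <- vapply(var_cols, function(cl) {
    sum(vt[[cl]] & vt$n_groups_variable == 1L)
  }, 0L)
  names(excl) <- gnames
  list(n_positions_analysed = n_analysed,
       n_variable = n_variable,
       n_shared_2plus = n_2plus,
       n_shared_all = n_all,
       pct_shared_2plus_of_variable = if (n_variable) 100 * n_2plus / n_variable else NA_real_,
       pct_shared_all_of_variable = if (n_variable) 100 * n_all / n_variable else NA_real_,
       pct_shared_all_of_shared = if (n_2plus) 100 * n_all / n_2plus else NA_real_,
       per_group_exclusive = excl)
}
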