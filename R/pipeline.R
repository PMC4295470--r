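#' Run the full candidate-gene analysis workflow
#'
#' Config-driven orchestration: data (simulate or load) -> ORF screening ->
#' kinase annotation and RD classification -> NJ phylogeny with bootstrap and
#' subfamily assignment -> sliding-window Ka/Ks with group comparisons ->
#' non-synonymous position map. Each stage writes its artifacts under
#' `out_dir`; a JSON manifest records the package version, a config hash, the
#' seed, and per-stage counts. Reruns with the same config and seed are
#' byte-identical.
#'
#' @param cfg a named list (or path to a YAML file) with elements:
#'   * `out_dir` -- output directory (created if needed);
#'   * `seed` -- integer seed;
#'   * `simulate` -- list of [sim_config()] arguments (simulate mode), OR
#'     `inputs` -- list with `alignment` (codon-alignment FASTA), `groups`
#'     (TSV: id, group) and optionally `reference_panel` (TSV: id, subfamily);
#'   * `params` -- optional overrides: window_nt (75), step_nt (15),
#'     alpha (1e-4), fold_min (2), bootstrap_replicates (200),
#'     min_support (70), method ("NG86"), control_group (last group);
#'   * `stages` -- optional logical toggles: screen, annotate, phylogeny,
#'     selection, variability (all TRUE by default).
#' @return (invisibly) the manifest list; artifacts land in `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (is.null(cfg$out_dir)) stop("cfg$out_dir is required", call. = FALSE)
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop("cfg must contain either a 'simulate' block or an 'inputs' block",
         call. = FALSE)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  par <- cfg$params %||% list()
  window_nt <- par$window_nt %||% 75L
  step_nt <- par$step_nt %||% 15L
  alpha <- par$alpha %||% 1e-4
  fold_min <- par$fold_min %||% 2
  n_boot <- par$bootstrap_replicates %||% 200L
  min_support <- par$min_support %||% 70
  method <- par$method %||% "NG86"
  stages <- cfg$stages %||% list()
  on_stage <- function(s) isTRUE(stages[[s]] %||% TRUE)
  manifest <- list(package = "rlkscan",
                   version = as.character(utils::packageVersion("rlkscan")),
                   seed = seed, config_hash = rlang::hash(cfg), stages = list())

  # ---- stage: data -------------------------------------------------------
  stage <- "data"
  res <- with_stage(stage, {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      sim_args$seed <- sim_args$seed %||% seed
      fam <- do.call(sim_config, sim_args)
      fam <- simulate_family(fam)
      groups <- fam$groups
      # one reference leaf per group: the first member, labeled by its group
      panel <- stats::setNames(names(groups),
                               vapply(groups, `[`, "", 1L))
      list(fam = fam, aln = fam$alignment, groups = groups, panel = panel)
    } else {
      aln <- codon_alignment(read_fasta(cfg$inputs$alignment, "nt", gapped = TRUE))
      gdf <- utils::read.delim(cfg$inputs$groups, comment.char = "#",
                               stringsAsFactors = FALSE)
      groups <- split(gdf$id, gdf$group)
      panel <- NULL
      if (!is.null(cfg$inputs$reference_panel)) {
        pdf <- utils::read.delim(cfg$inputs$reference_panel, comment.char = "#",
                                 stringsAsFactors = FALSE)
        panel <- stats::setNames(pdf$subfamily, pdf$id)
      }
      list(fam = NULL, aln = aln, groups = groups, panel = panel)
    }
  })
  aln <- res$aln; groups <- res$groups
  write_fasta(aln, file.path(cfg$out_dir, "alignment.fasta"))
  gtab <- tibble(id = unlist(groups, use.names = FALSE),
                 group = rep(names(groups), lengths(groups)))
  write_tsv_commented(gtab, file.path(cfg$out_dir, "groups.tsv"),
                      "sequence id and clade/group label")
  manifest$stages$data <- list(n_sequences = length(aln),
                               n_groups = length(groups),
                               alignment_nt = nchar(aln[[1L]]))

  # ungapped CDS + translations used by later stages
  cds <- stats::setNames(gsub("-", "", unclass(aln)), names(aln))
  prot <- stats::setNames(vapply(cds, translate_nt, ""), names(aln))

  # ---- stage: screen -----------------------------------------------------
  if (on_stage("screen")) {
    pool <- cds
    if (!is.null(res$fam) && !is.null(res$fam$pseudogenes)) {
      pool <- c(pool, res$fam$pseudogenes)
    }
    screen <- with_stage("screen", orf_screen_all(pool))
    write_tsv_commented(screen[, c("id", "status", "n_stops")],
                        file.path(cfg$out_dir, "orf_screen.tsv"),
                        "ORF status per fragment (frame 0)")
    manifest$stages$screen <- list(
      n_screened = nrow(screen),
      n_intact = sum(screen$status == "intact"),
      n_interrupted = sum(screen$status == "interrupted"))
  }

  # ---- stage: annotate ---------------------------------------------------
  anns <- NULL
  if (on_stage("annotate")) {
    anns <- with_stage("annotate", annotate_kinase_all(prot))
    ok <- !vapply(anns, function(a) !is.null(a$error), TRUE)
    atab <- do.call(rbind, lapply(anns[ok], function(a) tibble(
      id = a$seq_id, span = a$span_string, kinase_class = a$kinase_class,
      catalytic_class = a$catalytic_class,
      rd_substituent = a$rd_substituent %||% NA_character_)))
    write_tsv_commented(atab, file.path(cfg$out_dir, "kinase_annotation.tsv"),
                        "subdomain span and RD/typical classification")
    act <- activation_segment_report(anns[ok], prot)
    write_tsv_commented(act[, setdiff(names(act), "detail")],
                        file.path(cfg$out_dir, "activation_segment.tsv"),
                        "activation-segment consensus matches")
    memb <- stats::setNames(rep(names(groups), lengths(groups)),
                            unlist(groups, use.names = FALSE))
    fam_tab <- summarize_families(anns[ok], memb, cds, aa_aln = seq_set(
      prot, "aa", gapped = TRUE), nt_aln = aln)
    write_tsv_commented(fam_tab, file.path(cfg$out_dir, "family_summary.tsv"),
                        "per-group survey summary")
    manifest$stages$annotate <- list(
      n_annotated = sum(ok), n_failed = sum(!ok),
      n_nonRD = sum(vapply(anns[ok], function(a)
        a$catalytic_class == "nonRD", TRUE)),
      n_atypical = sum(vapply(anns[ok], function(a)
        a$kinase_class == "atypical", TRUE)))
  }

  # ---- stage: phylogeny --------------------------------------------------
  assign_tab <- NULL
  if (on_stage("phylogeny")) {
    if (is.null(res$panel)) {
      stop("pipeline stage 'phylogeny': no reference panel available",
           call. = FALSE)
    }
    paln <- protein_alignment(prot)
    tr <- with_stage("phylogeny",
                     bootstrap_support(paln, replicates = n_boot, seed = seed))
    write_tree_newick(tr, file.path(cfg$out_dir, "nj_tree.nwk"))
    assign_tab <- assign_groups(tr, res$panel, min_support = min_support)
    write_tsv_commented(assign_tab, file.path(cfg$out_dir, "assignments.tsv"),
                        "subfamily assignment from supported clades")
    manifest$stages$phylogeny <- list(
      replicates_used = attr(tr, "replicates_used"),
      n_dropped = attr(tr, "n_dropped"),
      n_assigned = sum(assign_tab$subfamily != "uncertain"),
      n_uncertain = sum(assign_tab$subfamily == "uncertain"))
  }

  # ---- stage: selection --------------------------------------------------
  if (on_stage("selection")) {
    profiles <- with_stage("selection", lapply(names(groups), function(g) {
      window_profile(aln, groups[[g]], window_nt = window_nt,
                     step_nt = step_nt, method = method, group_label = g)
    }))
    names(profiles) <- names(groups)
    ptab <- do.call(rbind, lapply(profiles, function(p)
      p[, setdiff(names(p), "omegas")]))
    write_tsv_commented(ptab, file.path(cfg$out_dir, "window_profile.tsv"),
                        "per-window mean Ka/Ks and SEM per group")
    control <- par$control_group %||% names(groups)[length(groups)]
    comp <- do.call(rbind, lapply(setdiff(names(groups), control), function(g) {
      suppressMessages(compare_window_groups(profiles[[g]],
                                             profiles[[control]],
                                             alpha = alpha,
                                             fold_min = fold_min))
    }))
    write_tsv_commented(comp, file.path(cfg$out_dir, "window_comparison.tsv"),
                        paste0("per-window rank-sum comparison vs control ('",
                               control, "')"))
    vs1 <- do.call(rbind, lapply(names(groups), function(g) {
      p <- profiles[[g]]
      do.call(rbind, lapply(seq_len(nrow(p)), function(w) {
        if (length(p$omegas[[w]]) < 2L) {
          return(tibble(group = g, window_index = w, p_value = NA_real_,
                        exceeds_one = NA))
        }
        t1 <- test_window_vs_one(p$omegas[[w]])
        tibble(group = g, window_index = w, p_value = t1$p_value,
               exceeds_one = t1$exceeds_one)
      }))
    }))
    write_tsv_commented(vs1, file.path(cfg$out_dir, "window_vs_one.tsv"),
                        "one-sided signed-rank test of window omegas against 1")
    manifest$stages$selection <- list(
      n_windows = nrow(profiles[[1L]]),
      n_significant_vs_control = sum(comp$flag_significant, na.rm = TRUE),
      n_windows_exceeding_one = sum(vs1$exceeds_one, na.rm = TRUE))
  }

  # ---- stage: variability ------------------------------------------------
  if (on_stage("variability")) {
    vt <- with_stage("variability",
                     suppressMessages(nonsyn_position_map(aln, groups)))
    write_tsv_commented(vt, file.path(cfg$out_dir, "variability.tsv"),
                        "non-synonymous variability and sharing per codon position")
    sm <- shared_position_summary(vt)
    manifest$stages$variability <- sm[c("n_positions_analysed", "n_variable",
                                        "n_shared_2plus", "n_shared_all")]
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Write a TSV with a commented header line describing the columns
#' @param df data frame.
#' @param path output path.
#' @param what one-line description placed in a leading `#` comment.
#' @export
write_tsv_commented <- function(df, path, what = "") {
  df <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) vapply(col, function(x) paste(x, collapse = ","), "")
    else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", what, " | columns: ",
                    paste(names(df), collapse = ", ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
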