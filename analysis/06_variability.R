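#!/usr/bin/env Rscript
# Non-synonymous position map: which codon positions vary non-synonymously
# within each clade, and how much of that variability is shared between
# clades versus clade-exclusive.
suppressPackageStartupMessages(library(rlkscan))

aln <- codon_alignment(read_fasta("results/data/alignment.fasta", "nt",
                                  gapped = TRUE))
grp <- utils::read.delim("results/data/groups.tsv", comment.char = "#")
groups <- split(grp$id, grp$group)
dir.create("results/variability", showWarnings = FALSE, recursive = TRUE)

vt <- suppressMessages(nonsyn_position_map(aln, groups))
write_tsv_commented(vt, "results/variability/positions.tsv",
                    "per-position variability, sharing class, residue inventory")
sm <- shared_position_summary(vt)
jsonlite::write_json(sm, "results/variability/summary.json",
                     auto_unbox = TRUE, digits = NA)

cat("Of", sm$n_positions_analysed, "positions analysed,", sm$n_variable,
    "were subject to non-synonymous variation;",
    sm$n_shared_2plus,
    sprintf("(%.0f%%) shared by two or more clades,", sm$pct_shared_2plus_of_variable),
    sm$n_shared_all,
    sprintf("(%.0f%%) present in all clades.\n", sm$pct_shared_all_of_variable))
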