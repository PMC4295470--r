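#!/usr/bin/env Rscript
# Generate the synthetic study: four clades of kinase-domain coding
# fragments (one of them a non-RD clade), evolved with relaxed purifying
# selection (omega = 1) in the subdomain I-II / V-VIA / VII-VIII analogs and
# strong constraint (omega = 0.1) elsewhere, plus frameshift-degraded
# pseudogene copies. Writes the inputs every later step consumes.
suppressPackageStartupMessages(library(rlkscan))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(pseudogene_fraction = 0.18, seed = seed)
fam <- simulate_family(cfg)

write_fasta(fam$alignment, file.path(out, "alignment.fasta"))
write_fasta(c(stats::setNames(gsub("-", "", unclass(fam$alignment)),
                              names(fam$alignment)),
              fam$pseudogenes),
            file.path(out, "fragments.fasta"))
write_tsv_commented(
  tibble::tibble(id = unlist(fam$groups, use.names = FALSE),
                 group = rep(names(fam$groups), lengths(fam$groups)),
                 rd_planted = rep(fam$rd_labels, lengths(fam$groups))),
  file.path(out, "groups.tsv"), "planted clade membership and RD label")
write_tsv_commented(fam$truth, file.path(out, "truth_substitutions.tsv"),
                    "every realised substitution (lineage, position, syn flag)")
jsonlite::write_json(list(seed = seed, n_codons = cfg$n_codons,
                          n_groups = cfg$n_groups,
                          members_per_group = cfg$members_per_group,
                          kappa = cfg$kappa,
                          config_hash = rlang::hash(cfg)),
                     file.path(out, "run_manifest.json"), auto_unbox = TRUE)

cat("Simulated", length(fam$alignment), "fragments of",
    nchar(fam$alignment[[1]]), "nt in", length(fam$groups), "clades;",
    nrow(fam$truth), "substitutions recorded,",
    length(fam$pseudogenes), "pseudogene copies.\n")
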