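#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study data.
#
# Emulates the two data sources the analysis needs: a tyrosine-kinase
# peptide array experiment (144 substrate peptides, 3 technical replicates,
# ER+ samples with PR and HER2 labels, three planted driver kinases) and an
# ER+ expression/survival cohort (1000 genes, 300 patients, a 24-gene
# kinase signature differentially expressed by PR status, and a latent
# two-cluster structure with a hazard ratio of 2). Ground truth is saved so
# later stages can be judged against it.

suppressMessages(library(kinact))

seed <- 7L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- array_sim_config(n_peptides = 144L, n_samples = 20L,
                        n_replicates = 3L, pr_pos_frac = 0.5,
                        her2_neg_frac = 1, n_kinases = 20L,
                        substrates_per_kinase = 6L, overlap = 0,
                        driver_kinases = c(KIN01 = 1.0, KIN02 = 1.5,
                                           KIN03 = 2.0),
                        seed = seed)
sim <- simulate_array(cfg)
# name the first four prediction sets after real tyrosine-kinase genes so
# the integration stage can intersect upstream hits with expression hits
alias <- c(KIN01 = "LCK", KIN02 = "FGFR4", KIN03 = "FRK", KIN04 = "MST1R")
idx <- match(names(alias), names(sim$ks_sets))
names(sim$ks_sets)[idx] <- unname(alias)
drivers <- setNames(cfg$driver_kinases,
                    unname(alias[names(cfg$driver_kinases)]))
names(sim$ground_truth$affected_peptides) <- names(drivers)
write_signal_tsv(sim$experiment, file.path(out, "signals.tsv"))
write.table(sim$annotation, file.path(out, "annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_gmt(sim$ks_sets, file.path(out, "kinase_sets.gmt"))
message("array: ", length(sim$experiment$peptide_ids), " peptides x ",
        length(sim$experiment$sample_ids), " samples x 3 replicates; ",
        "planted drivers: ", paste(names(drivers), collapse = ", "))

co <- simulate_cohort(cohort_sim_config(n_samples = 300L, seed = seed + 1L))
write_matrix_tsv(co$expr, file.path(out, "expression.tsv"), id_col = "gene")
write.table(co$annotation, file.path(out, "cohort_annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(co$survival, file.path(out, "survival.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("cohort: ", nrow(co$expr), " genes x ", ncol(co$expr),
        " samples; ", sum(co$annotation$pr == "neg"), " PR-; ",
        "signature of ", length(co$ground_truth$signature_effects),
        " kinase genes; cluster hazard ratio ",
        co$ground_truth$cluster_hazard_ratio)

jsonlite::write_json(
  list(seed = seed,
       array_drivers = as.list(drivers),
       affected_peptides = sim$ground_truth$affected_peptides,
       cohort_signature = as.list(co$ground_truth$signature_effects),
       cohort_cluster = as.list(co$ground_truth$cluster)),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
message("ground truth written to ", file.path(out, "ground_truth.json"))
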