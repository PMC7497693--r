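#!/usr/bin/env Rscript
# Stage 4 — upstream kinase analysis.
#
# Ranks the candidate upstream kinases by the sum of two permutation
# Q-scores: significance (sample-label permutations) and specificity
# (substrate-set permutations), each Q = -10*log10(max(m/M, 1/M)) with
# M = 500. tau > 0 means lower substrate phosphorylation in PR+ samples.

suppressMessages(library(kinact))

mat <- read_matrix_tsv("results/matrix.tsv")
annot <- read_annotation_tsv("results/data/annotation.tsv")
sets <- read_kinase_sets("results/data/kinase_sets.gmt")

uka <- rank_kinases(mat, annot, sets, M = 500L, seed = 7L,
                    stratum = c(er = "pos", her2 = "neg"), grouping = "pr")
write.table(uka, "results/uka.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(list(M = 500, seed = 7,
                          stratum = list(er = "pos", her2 = "neg"),
                          grouping = "pr"),
                     "results/uka_meta.json", auto_unbox = TRUE)

truth <- jsonlite::read_json("results/data/ground_truth.json")
planted <- names(truth$array_drivers)
message("ranked ", nrow(uka), " kinases; top 5: ",
        paste(head(uka$kinase, 5), collapse = ", "))
message("planted drivers ", paste(planted, collapse = ", "),
        " at ranks ",
        paste(uka$rank[match(planted, uka$kinase)], collapse = ", "),
        "; all in top 5: ",
        all(planted %in% head(uka$kinase, 5)))
message("tau > 0 (higher activity in PR-) for ", sum(uka$tau > 0),
        " of ", nrow(uka), " kinases")
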