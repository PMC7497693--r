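#!/usr/bin/env Rscript
# Stage 3 — differential substrate phosphorylation by PR status.
#
# Welch tests per peptide (PR+ vs PR- within the ER+/HER2- stratum), BH
# correction, unsupervised peptide clustering into three activity levels,
# and per-cluster mean summaries with subgroup tests.

suppressMessages(library(kinact))

mat <- read_matrix_tsv("results/matrix.tsv")
annot <- read_annotation_tsv("results/data/annotation.tsv")

res <- group_test(mat, annot, stratum = c(er = "pos", her2 = "neg"),
                  grouping = "pr")
sig <- select_significant(res, alpha = 0.05, on = "p_raw")
write.table(res, "results/diffphos.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(nrow(sig), " substrates with raw p < 0.05 (",
        attr(sig, "n_genes"), " distinct genes); all lfc negative: ",
        all(sig$lfc < 0),
        " (negative lfc = higher phosphorylation in PR-)")

cl <- cluster_peptides(mat, k = 3)
write.table(data.frame(substrate_id = names(cl$assignment),
                       cluster = unname(cl$assignment)),
            "results/peptide_clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
groups <- setNames(paste0("PR", ifelse(annot$pr == "pos", "+", "-")),
                   annot$sample_id)[colnames(mat)]
summ <- cluster_mean_summary(mat, cl, groups)
write.table(summ$sample_means, "results/cluster_means.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(summ$tests, "results/cluster_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("peptide clusters of size ",
        paste(table(cl$assignment), collapse = "/"),
        "; per-cluster PR+ vs PR- p-values: ",
        paste(signif(summ$tests$p, 3), collapse = ", "))
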