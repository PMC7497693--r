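#!/usr/bin/env Rscript
# Stage 5 — expression-cohort integration.
#
# Bonferroni differential expression by PR status in the HER2- stratum,
# restriction to kinome genes, two-cluster sample stratification on that
# signature, Kaplan-Meier/log-rank survival comparison (overall and within
# PR strata), and intersection of the upstream kinase hits with the
# differentially expressed kinase genes.

suppressMessages(library(kinact))

expr <- read_matrix_tsv("results/data/expression.tsv")
annot <- read_annotation_tsv("results/data/cohort_annotation.tsv")
surv <- read_survival_tsv("results/data/survival.tsv")
kinome <- read_kinome_list(system.file("extdata", "kinome_ptk.txt",
                                       package = "kinact"))
uka <- read.delim("results/uka.tsv")

de <- de_genes(expr, annot, stratum = c(er = "pos", her2 = "neg"),
               correction = "bonferroni", alpha = 0.05)
kin <- filter_kinome(de, kinome)
write.table(de, "results/de_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(kin, "results/de_kinome.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(nrow(de), " genes differentially expressed (Bonferroni < 0.05) ",
        "of ", attr(de, "n_tested"), " tested; ", nrow(kin),
        " encode tyrosine kinases")

her2neg <- annot$sample_id[annot$her2 == "neg"]
sc <- cluster_samples(expr[, intersect(colnames(expr), her2neg)],
                      kin$gene, orient_genes = kin$gene[kin$lfc < 0])
write.table(data.frame(sample_id = names(sc$clusters),
                       cluster = unname(sc$clusters)),
            "results/sample_clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
pr <- setNames(annot$pr, annot$sample_id)[names(sc$clusters)]
tab <- table(pr, sc$clusters)
message("signature clustering: cluster sizes ",
        paste(table(sc$clusters), collapse = "/"),
        "; PR- fraction in cluster 2: ",
        round(tab["neg", "2"] / sum(tab[, "2"]), 2),
        " vs cluster 1: ", round(tab["neg", "1"] / sum(tab[, "1"]), 2))

surv_st <- surv[surv$sample_id %in% names(sc$clusters), ]
km_all <- km_logrank(surv_st, sc$clusters)
message(sprintf("survival, cluster 2 vs 1: chi-square %.2f, p = %.3g",
                km_all$chi_square, km_all$p))
strata_out <- list(overall = list(chi_square = km_all$chi_square,
                                  p = km_all$p))
for (st in c("neg", "pos")) {
  ids <- names(pr)[pr == st]
  s2 <- surv_st[surv_st$sample_id %in% ids, ]
  cl2 <- sc$clusters[ids]
  if (length(unique(cl2)) == 2L) {
    km <- km_logrank(s2, cl2)
    strata_out[[paste0("pr_", st)]] <- list(chi_square = km$chi_square,
                                            p = km$p)
    message(sprintf("  within PR%s: chi-square %.2f, p = %.3g",
                    ifelse(st == "pos", "+", "-"), km$chi_square, km$p))
  }
}
jsonlite::write_json(strata_out, "results/survival.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cand <- intersect_candidates(uka, kin)
write.table(cand, "results/candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(nrow(cand), " candidate kinase(s) shared by the upstream ranking ",
        "and the DE kinome list: ", paste(cand$kinase, collapse = ", "))
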