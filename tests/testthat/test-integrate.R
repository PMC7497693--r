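test_that("differential expression applies Bonferroni over the tested universe", {
  set.seed(121)
  G <- 100L
  expr <- matrix(rnorm(G * 20, 8, 0.5), G, 20,
                 dimnames = list(sprintf("G%03d", 1:G),
                                 sprintf("P%03d", 1:20)))
  annot <- make_annot(colnames(expr), pr = rep(c("neg", "pos"), each = 10))
  expr["G001", 1:10] <- expr["G001", 1:10] + 3   # planted gene
  expr["G002", ] <- 5                            # zero variance everywhere
  de <- de_genes(expr, annot, alpha = 0.05)
  expect_equal(attr(de, "n_tested"), G)          # flat gene stays in universe
  expect_true("G001" %in% de$gene)
  expect_false("G002" %in% de$gene)
  # Bonferroni arithmetic: adjusted p = min(1, raw p * G)
  full <- de_genes(expr, annot, alpha = 1.0000001)
  expect_equal(full$p_adj, pmin(1, full$p_raw * G), tolerance = 1e-12)

  ident <- cbind(expr[, 1:10], expr[, 1:10])
  colnames(ident) <- colnames(expr)
  expect_equal(nrow(de_genes(ident, annot)), 0L)
})

test_that("Bonferroni selection is a subset of BH selection at the same alpha", {
  set.seed(131)
  expr <- matrix(rnorm(200 * 16, 8), 200, 16,
                 dimnames = list(sprintf("G%03d", 1:200),
                                 sprintf("P%03d", 1:16)))
  expr[1:20, 1:8] <- expr[1:20, 1:8] + seq(0.5, 2, length.out = 20)
  annot <- make_annot(colnames(expr), pr = rep(c("neg", "pos"), each = 8))
  bon <- de_genes(expr, annot, correction = "bonferroni")
  bh <- de_genes(expr, annot, correction = "BH")
  expect_true(all(bon$gene %in% bh$gene))
})

test_that("kinome filtering is a case-normalized intersection", {
  tab <- data.frame(gene = c("LCK", "fgfr4", "GAPDH"), lfc = 1:3,
                    p_adj = 0.01)
  out <- filter_kinome(tab, c("LCK", "FGFR4", "FRK"))
  expect_equal(out$gene, c("LCK", "fgfr4"))
  empty <- filter_kinome(tab[0, ], c("LCK"))
  expect_equal(nrow(empty), 0L)
})

test_that("signature clustering recovers planted sample blocks with oriented labels", {
  set.seed(141)
  genes <- sprintf("G%02d", 1:10)
  lo <- matrix(rnorm(10 * 6, 0, 0.3), 10, 6)
  hi <- matrix(rnorm(10 * 5, 5, 0.3), 10, 5)
  expr <- cbind(lo, hi)
  dimnames(expr) <- list(genes, sprintf("P%03d", 1:11))
  sc <- cluster_samples(expr, genes)
  expect_equal(unname(sc$clusters[1:6]), rep(1L, 6))   # low block -> cluster 1
  expect_equal(unname(sc$clusters[7:11]), rep(2L, 5))  # high block -> cluster 2

  # label convention survives sample permutation
  perm <- sample(11)
  sc2 <- cluster_samples(expr[, perm], genes)
  expect_equal(sc2$clusters[colnames(expr)], sc$clusters)

  flat <- matrix(3, 10, 6, dimnames = list(genes, sprintf("P%03d", 1:6)))
  expect_error(cluster_samples(flat, genes), "indistinguishable")
  expect_error(cluster_samples(expr, c(genes, "MISSING")), "absent")
})

test_that("PR- samples are enriched in the high-expression cluster of a synthetic cohort", {
  co <- simulate_cohort(cohort_sim_config(n_samples = 200L, seed = 5L))
  de <- de_genes(co$expr, co$annotation)
  kin <- filter_kinome(de, read_kinome_list(extdata("kinome_ptk.txt")))
  stratum <- co$annotation$sample_id[co$annotation$her2 == "neg"]
  sc <- cluster_samples(co$expr[, stratum], kin$gene,
                        orient_genes = kin$gene[kin$lfc < 0])
  pr <- co$annotation$pr[match(names(sc$clusters),
                               co$annotation$sample_id)]
  tab <- table(pr, sc$clusters)
  odds <- (tab["neg", "2"] / tab["neg", "1"]) /
    (tab["pos", "2"] / tab["pos", "1"])
  expect_gt(odds, 1)
})

test_that("Kaplan-Meier curves start at 1 and are non-increasing", {
  set.seed(151)
  km <- km_curve(rexp(40, 0.1), rbinom(40, 1, 0.7))
  expect_equal(km$surv[km$time == 0], 1)
  expect_true(all(diff(km$surv) <= 1e-12))
})

test_that("log-rank statistic matches a hand-worked 6-subject example exactly", {
  surv <- data.frame(sample_id = paste0("P", 1:6),
                     time = c(1, 3, 5, 2, 4, 6),
                     event = c(1, 1, 0, 1, 0, 1))
  groups <- rep(c("A", "B"), each = 3)
  # 2x2 tables at event times 1, 2, 3, 6 (group A at risk / total at risk):
  #  t=1: 3/6, d=1 in A -> E1 += 0.5,  V += 1*(3/6)*(3/6)*(5/5) = 0.25
  #  t=2: 2/5, d=1 in B -> E1 += 0.4,  V += 1*(2/5)*(3/5)*(4/4) = 0.24
  #  t=3: 2/4, d=1 in A -> E1 += 0.5,  V += 1*(2/4)*(2/4)*(3/3) = 0.25
  #  t=6: 0/1, d=1 in B -> E1 += 0,    V += 0 (single subject at risk)
  # O1 = 2, E1 = 1.4, V = 0.74
  lr <- km_logrank(surv, groups)
  expect_equal(lr$chi_square, (2 - 1.4)^2 / 0.74, tolerance = 1e-12)
  expect_equal(unname(lr$observed["A"]), 2)
  expect_equal(unname(lr$expected["A"]), 1.4, tolerance = 1e-12)

  # symmetric under label swap
  lr2 <- km_logrank(surv, rev(groups)[c(4:6, 1:3)])
  expect_equal(lr2$chi_square, lr$chi_square, tolerance = 1e-12)

  # identical survival in both groups -> chi-square 0
  dup <- data.frame(sample_id = paste0("Q", 1:12),
                    time = rep(c(2, 4, 6, 8, 10, 12), 2),
                    event = rep(c(1, 0, 1, 1, 0, 1), 2))
  lr0 <- km_logrank(dup, rep(c("A", "B"), each = 6))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
})

test_that("log-rank agrees with survival::survdiff on random censored data", {
  skip_if_not_installed("survival")
  set.seed(161)
  for (i in 1:5) {
    n <- 60
    t_event <- rexp(n, rate = c(0.05, 0.1))
    t_cens <- rexp(n, 0.03)
    time <- round(pmin(t_event, t_cens), 1)  # rounding induces ties
    event <- as.integer(t_event <= t_cens)
    g <- rep(c("A", "B"), n / 2)
    surv <- data.frame(sample_id = paste0("P", 1:n), time = time,
                       event = event)
    lr <- km_logrank(surv, g)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    expect_equal(lr$chi_square, unname(sd$chisq), tolerance = 1e-10)
  }
})

test_that("candidate intersection mirrors the four-kinase overlap logic", {
  uka <- data.frame(kinase = c("LCK", "FRK", "FGFR4", "MST1R", "EGFR"),
                    tau = c(0.9, 0.5, 0.8, 0.4, 0.2),
                    rank = 1:5)
  de <- data.frame(gene = c("LCK", "FRK", "FGFR4", "MST1R", "CDK9"),
                   lfc = c(0.8, -0.6, 0.7, -0.5, 0.1),
                   p_adj = 0.01)
  cand <- intersect_candidates(uka, de)
  expect_equal(cand$kinase, c("LCK", "FRK", "FGFR4", "MST1R"))
  expect_equal(cand$direction, rep("higher_activity_in_neg", 4))
  disjoint <- intersect_candidates(uka, data.frame(gene = "AAK1", lfc = 1,
                                                   p_adj = 0.01))
  expect_equal(nrow(disjoint), 0L)
})
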