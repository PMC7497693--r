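test_that("array simulation is bitwise deterministic per seed", {
  cfg <- array_sim_config(n_peptides = 30L, n_samples = 10L, seed = 17L,
                          pr_pos_frac = 0.5, her2_neg_frac = 1,
                          n_kinases = 4L, substrates_per_kinase = 5L)
  a <- simulate_array(cfg)
  b <- simulate_array(cfg)
  expect_identical(a$experiment$signal, b$experiment$signal)
  expect_identical(a$experiment$saturated, b$experiment$saturated)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$ks_sets, b$ks_sets)
})

test_that("kinase-substrate maps honour disjointness and determinism", {
  m1 <- simulate_ks_map(60, 8, 7, overlap = 0, seed = 3)
  m2 <- simulate_ks_map(60, 8, 7, overlap = 0, seed = 3)
  expect_identical(m1, m2)
  for (i in 1:7) for (j in (i + 1):8)
    expect_length(intersect(m1[[i]], m1[[j]]), 0L)
  expect_true(all(unlist(m1) %in% attr(m1, "universe")))
  expect_error(simulate_ks_map(10, 3, 4, overlap = 0), "infeasible")

  near_all <- simulate_ks_map(20, 1, 19, seed = 1)
  expect_length(near_all[[1]], 19L)
})

test_that("saturation flags clip at the threshold and dropout produces missing spots", {
  cfg <- array_sim_config(n_peptides = 50L, n_samples = 10L,
                          baseline_mean = 10, baseline_sd = 2,
                          saturation_threshold = 2^11,
                          dropout_prob = 0.1, pr_pos_frac = 0.5,
                          her2_neg_frac = 1, n_kinases = 4L,
                          substrates_per_kinase = 5L, seed = 23L)
  sim <- simulate_array(cfg)
  sig <- sim$experiment$signal
  sat <- sim$experiment$saturated
  expect_gt(sum(sat), 0)
  expect_true(all(sig[sat] == 2^11))
  expect_true(all(sig[!sat & !is.na(sig)] < 2^11))
  expect_gt(sum(is.na(sig)), 0)
})

test_that("planted driver shifts are realized at the configured magnitude", {
  diffs <- vapply(1:10, function(s) {
    cfg <- recovery_config(seed = 100 + s)
    cfg$driver_kinases <- c(KIN01 = 2.0)
    sim <- simulate_array(cfg)
    mat <- suppressMessages(preprocess_experiment(sim$experiment))
    peps <- intersect(sim$ground_truth$affected_peptides$KIN01,
                      rownames(mat))
    neg <- sim$annotation$sample_id[sim$annotation$pr == "neg"]
    pos <- sim$annotation$sample_id[sim$annotation$pr == "pos"]
    mean(rowMeans(mat[peps, neg], na.rm = TRUE) -
           rowMeans(mat[peps, pos], na.rm = TRUE))
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 2.0), 0.2)
})

test_that("experiments round-trip through the signal TSV readers and writers", {
  sim <- simulate_array(array_sim_config(
    n_peptides = 12L, n_samples = 6L, pr_pos_frac = 0.5,
    her2_neg_frac = 1, n_kinases = 2L, substrates_per_kinase = 4L,
    driver_kinases = c(KIN01 = 1.0),
    dropout_prob = 0.1, saturation_threshold = 2^9, seed = 29L))
  path <- tempfile(fileext = ".tsv")
  write_signal_tsv(sim$experiment, path)
  back <- read_signal_tsv(path)
  expect_equal(back$signal, sim$experiment$signal)
  expect_equal(back$saturated, sim$experiment$saturated)
  expect_identical(back$peptide_ids, sim$experiment$peptide_ids)
})

test_that("cohort simulation is deterministic with hazards tied to the latent cluster", {
  cfg <- cohort_sim_config(n_samples = 100L, seed = 31L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$survival, b$survival)
  gt <- a$ground_truth
  expect_setequal(unique(gt$cluster), c(1L, 2L))
  expect_equal(unname(gt$hazard[gt$cluster == 2L][1]) /
                 unname(gt$hazard[gt$cluster == 1L][1]),
               cfg$cluster_hazard_ratio)
  # censoring near target rate over several seeds
  rates <- vapply(1:10, function(s)
    mean(simulate_cohort(cohort_sim_config(n_samples = 200L,
                                           seed = s))$survival$event == 0),
    numeric(1))
  expect_lt(abs(mean(rates) - 0.3), 0.08)
})

test_that("log-rank p-values are uniform under a unit hazard ratio", {
  ps <- vapply(1:100, function(s) {
    co <- simulate_cohort(cohort_sim_config(
      n_samples = 150L, cluster_hazard_ratio = 1, seed = 1000 + s))
    km_logrank(co$survival,
               setNames(co$ground_truth$cluster,
                        co$survival$sample_id))$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a null signature yields no Bonferroni discoveries and planted ones are recovered", {
  co0 <- simulate_cohort(cohort_sim_config(
    n_samples = 150L, signature_effects = c(LCK = 0, FRK = 0), seed = 37L))
  expect_lte(nrow(de_genes(co0$expr, co0$annotation)), 1L)

  # large planted effect: magnitude 1.5 on the default 24-gene signature
  big <- sign(cohort_sim_config()$signature_effects) * 1.5
  co <- simulate_cohort(cohort_sim_config(n_samples = 300L,
                                          signature_effects = big,
                                          seed = 41L))
  de <- de_genes(co$expr, co$annotation)
  kin <- filter_kinome(de, read_kinome_list(extdata("kinome_ptk.txt")))
  expect_setequal(kin$gene, names(co$ground_truth$signature_effects))
  expect_equal(nrow(kin), 24L)
})
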