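test_that("Q-score matches its closed form, bounds and monotonicity", {
  for (M in c(1L, 10L, 500L)) {
    m <- 0:M
    q <- q_from_counts(m, M)
    expect_identical(q, -10 * log10(pmax(m / M, 1 / M)))
    expect_true(all(q >= 0 & q <= 10 * log10(max(M, 1)) + 1e-12))
    expect_true(all(diff(q) <= 0))  # non-increasing in m
  }
  expect_equal(q_from_counts(0, 500), 26.98970, tolerance = 1e-6)
  expect_equal(q_from_counts(25, 500), 13.01030, tolerance = 1e-6)
  expect_equal(q_from_counts(500, 500), 0)
  expect_error(q_from_counts(5, 4), "m <= M")
  expect_error(q_from_counts(1, 0), "m <= M")
})

test_that("per-substrate effects match the standardized-mean-difference formula", {
  set.seed(71)
  mat <- matrix(rnorm(6 * 8, 7), 6, 8,
                dimnames = list(sprintf("P%03d_1_2", 1:6),
                                sprintf("S%02d", 1:8)))
  annot <- make_annot(colnames(mat), pr = rep(c("neg", "pos"), each = 4))
  d <- peptide_effect(mat, annot)
  for (p in names(d))
    expect_equal(d[[p]], smd_oracle(mat[p, 1:4], mat[p, 5:8]),
                 tolerance = 1e-12)

  # identical groups -> delta 0; zero-variance substrate excluded
  mat2 <- mat
  mat2[1, ] <- c(2, 2, 2, 2, 1, 1, 1, 1)   # zero variance within groups
  d2 <- suppressMessages(peptide_effect(mat2, annot))
  expect_false("P001_1_2" %in% names(d2))
  mat3 <- mat
  mat3[2, 5:8] <- mat3[2, 1:4]
  d3 <- peptide_effect(mat3, annot)
  expect_equal(unname(d3["P002_1_2"]), 0)
})

test_that("kinase statistic is the weighted mean effect over the set", {
  delta <- c(A_1_2 = 1, B_1_2 = 2, C_1_2 = 3, D_1_2 = 1.5)
  expect_equal(kinase_statistic(delta, "D_1_2"), 1.5)
  expect_equal(kinase_statistic(delta * 0, c("A_1_2", "B_1_2")), 0)
  expect_equal(kinase_statistic(delta, c("A_1_2", "B_1_2", "C_1_2")), 2)
  expect_equal(kinase_statistic(delta, c("A_1_2", "C_1_2"),
                                weights = c(3, 1)), (3 * 1 + 1 * 3) / 4)
  expect_warning(ks <- kinase_statistic(delta, "ZZZ_1_2"), "no overlap")
  expect_true(is.na(ks))
})

test_that("significance score equals exhaustive enumeration on 3+3 samples", {
  set.seed(81)
  mat <- matrix(rnorm(12 * 6, 7), 12, 6,
                dimnames = list(sprintf("P%03d_1_2", 1:12),
                                sprintf("S%02d", 1:6)))
  mat[1:4, 1:3] <- mat[1:4, 1:3] + 1.2   # modest planted shift
  annot <- make_annot(colnames(mat), pr = rep(c("neg", "pos"), each = 3))
  members <- rownames(mat)[1:4]
  got <- suppressMessages(
    significance_score(mat, annot, members, M = 500L, seed = 1L))
  want <- sig_count_oracle(mat, annot$pr == "neg", members)
  expect_true(got$exhaustive)
  expect_equal(got$M, 20L)
  expect_equal(got$tau, want$tau, tolerance = 1e-12)
  expect_equal(got$m, want$m)
  expect_equal(got$q, q_from_counts(want$m, 20L))
})

test_that("specificity score equals exhaustive enumeration on a 4-substrate universe", {
  delta <- c(A_1_2 = 0.4, B_1_2 = -1.1, C_1_2 = 2.0, D_1_2 = 0.1)
  got <- specificity_score(delta, c("B_1_2", "C_1_2"), M = 500L, seed = 1L)
  want <- spec_count_oracle(delta, c("B_1_2", "C_1_2"))
  expect_true(got$exhaustive)
  expect_equal(got$M, 6L)
  expect_equal(got$tau, want$tau, tolerance = 1e-12)
  expect_equal(got$m, want$m)
  expect_error(specificity_score(delta, names(delta)),
               "whole scoreable universe")
})

test_that("a strong planted shift saturates the significance score", {
  set.seed(91)
  mat <- matrix(rnorm(30 * 20, 7, 0.3), 30, 20,
                dimnames = list(sprintf("P%03d_1_2", 1:30),
                                sprintf("S%02d", 1:20)))
  annot <- make_annot(colnames(mat), pr = rep(c("neg", "pos"), each = 10))
  members <- rownames(mat)[1:6]
  mat[1:6, 1:10] <- mat[1:6, 1:10] + 4
  got <- suppressMessages(
    significance_score(mat, annot, members, M = 500L, seed = 2L))
  expect_identical(got$m, 0L)
  expect_equal(got$q, 10 * log10(500))
})

test_that("null data give uniform-ish exceedance fractions", {
  set.seed(101)
  fracs <- replicate(200, {
    mat <- matrix(rnorm(12 * 10, 7), 12, 10,
                  dimnames = list(sprintf("P%03d_1_2", 1:12),
                                  sprintf("S%02d", 1:10)))
    annot <- make_annot(colnames(mat), pr = rep(c("neg", "pos"), each = 5))
    s <- significance_score(mat, annot, rownames(mat)[1:4], M = 100L)
    s$m / s$M
  })
  expect_lt(abs(mean(fracs) - 0.5), 0.1)
})

test_that("kinase ranking is invariant to set order and breaks ties by name", {
  set.seed(111)
  sim <- simulate_array(array_sim_config(
    n_peptides = 40L, n_samples = 12L, pr_pos_frac = 0.5,
    her2_neg_frac = 1, n_kinases = 6L, substrates_per_kinase = 5L,
    driver_kinases = c(KIN01 = 1.5), dropout_prob = 0, seed = 7L))
  mat <- suppressMessages(preprocess_experiment(sim$experiment))
  sets <- sim$ks_sets
  r1 <- rank_kinases(mat, sim$annotation, sets, M = 100L, seed = 5L)
  r2 <- rank_kinases(mat, sim$annotation, rev(sets), M = 100L, seed = 5L)
  expect_equal(r1, r2, ignore_attr = TRUE)

  # identical sets -> identical tau and q_sig, name decides the order
  twin <- list(ZKIN = sets$KIN02, AKIN = sets$KIN02)
  rt <- rank_kinases(mat, sim$annotation, twin, M = 50L, seed = 5L)
  expect_equal(rt$tau[1], rt$tau[2])
  expect_equal(rt$q_sig[1], rt$q_sig[2])
  i_a <- which(rt$kinase == "AKIN"); i_z <- which(rt$kinase == "ZKIN")
  if (rt$combined[i_a] == rt$combined[i_z]) expect_lt(i_a, i_z)

  # single scoreable kinase -> rank 1; none -> error
  single <- rank_kinases(mat, sim$annotation, sets["KIN03"], M = 50L,
                         seed = 5L)
  expect_equal(single$rank, 1L)
  expect_error(
    suppressMessages(rank_kinases(mat, sim$annotation,
                                  list(K = "NOPE_1_2"), M = 50L)),
    "no kinase set")
})
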