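#' Array simulation configuration
#'
#' Defaults emulate the profiled study design: 144 tyrosine-kinase
#' substrate peptides, 29 ER+ tumor samples with a PR+/PR- and HER2+/HER2-
#' mix, and 3 technical replicates per sample, with Gaussian noise on the
#' log2 scale, hard saturation clipping on the raw scale and Bernoulli
#' detection dropout.
#'
#' @param n_peptides,n_samples,n_replicates array dimensions.
#' @param pr_pos_frac,her2_neg_frac fractions of PR+ and HER2- samples
#'   (ER is positive throughout); counts are rounded deterministically.
#' @param n_kinases,substrates_per_kinase,overlap kinase-substrate map
#'   dimensions; `overlap` is the fraction of each set redrawn from the
#'   whole universe (0 = pairwise-disjoint sets).
#' @param driver_kinases named numeric vector of standardized effect sizes
#'   for planted driver kinases (names must be among the simulated
#'   kinases); the effect raises the log2 signal of the driver's substrates
#'   in PR- samples of the HER2- stratum, in units of the between-sample
#'   noise sd.
#' @param baseline_mean,baseline_sd per-peptide baseline log2 level.
#' @param sample_sd between-sample biological noise sd (log2).
#' @param replicate_noise_sd technical replicate noise sd (log2).
#' @param saturation_threshold raw-scale clip-and-flag threshold.
#' @param dropout_prob per-spot probability of a missing measurement.
#' @param seed integer seed; the simulation is fully deterministic per
#'   seed.
#' @return list of class `array_sim_config`.
#' @export
array_sim_config <- function(n_peptides = 144L, n_samples = 29L,
                             n_replicates = 3L,
                             pr_pos_frac = 0.75, her2_neg_frac = 0.7,
                             n_kinases = 20L, substrates_per_kinase = 6L,
                             overlap = 0,
                             driver_kinases = c(KIN01 = 1.0, KIN02 = 1.5,
                                                KIN03 = 2.0),
                             baseline_mean = 7, baseline_sd = 1.5,
                             sample_sd = 1, replicate_noise_sd = 0.25,
                             saturation_threshold = 2^16,
                             dropout_prob = 0.05, seed = 1L) {
  cfg <- list(n_peptides = as.integer(n_peptides),
              n_samples = as.integer(n_samples),
              n_replicates = as.integer(n_replicates),
              pr_pos_frac = pr_pos_frac, her2_neg_frac = her2_neg_frac,
              n_kinases = as.integer(n_kinases),
              substrates_per_kinase = as.integer(substrates_per_kinase),
              overlap = overlap, driver_kinases = driver_kinases,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              sample_sd = sample_sd,
              replicate_noise_sd = replicate_noise_sd,
              saturation_threshold = saturation_threshold,
              dropout_prob = dropout_prob, seed = as.integer(seed))
  stopifnot(cfg$n_peptides >= 1L, cfg$n_samples >= 4L,
            cfg$n_replicates >= 1L,
            cfg$pr_pos_frac > 0, cfg$pr_pos_frac < 1,
            cfg$her2_neg_frac >= 0, cfg$her2_neg_frac <= 1,
            cfg$overlap >= 0, cfg$overlap <= 1,
            cfg$dropout_prob >= 0, cfg$dropout_prob <= 1,
            all(is.finite(cfg$driver_kinases)),
            cfg$substrates_per_kinase <= cfg$n_peptides)
  kin_names <- sprintf("KIN%02d", seq_len(cfg$n_kinases))
  if (length(cfg$driver_kinases) &&
      !all(names(cfg$driver_kinases) %in% kin_names))
    stop("driver kinases must be among the simulated kinases (KIN01..)")
  structure(cfg, class = "array_sim_config")
}

#' Simulate a kinase-to-substrate prediction map
#'
#' Random assignment of substrate peptides to kinases, standing in for an
#' in-silico kinase-substrate prediction matrix. With `overlap = 0` the
#' sets are pairwise disjoint (requires
#' `n_kinases * substrates_per_kinase <= n_peptides`); a positive overlap
#' fraction redraws that share of each set uniformly from the whole
#' universe, producing shared substrates.
#'
#' @param n_peptides universe size (peptide ids `PEP001_1_13`, ...) or a
#'   character vector of peptide ids to use as the universe.
#' @param n_kinases number of kinase sets.
#' @param substrates_per_kinase set size.
#' @param overlap fraction in `[0, 1]` of each set redrawn from the
#'   universe.
#' @param seed integer seed.
#' @return named list of substrate-id vectors with attribute `universe`.
#' @export
simulate_ks_map <- function(n_peptides, n_kinases, substrates_per_kinase,
                            overlap = 0, seed = 1L) {
  if (is.character(n_peptides)) {
    universe <- n_peptides
  } else {
    universe <- sprintf("PEP%03d_%d_%d", seq_len(n_peptides),
                        1L + seq_len(n_peptides) %% 50L,
                        13L + seq_len(n_peptides) %% 50L)
  }
  P <- length(universe)
  k <- as.integer(substrates_per_kinase)
  if (k > P) stop("substrates_per_kinase exceeds the number of peptides")
  if (n_kinases * k > P && overlap == 0)
    stop("disjoint sets infeasible: n_kinases * substrates_per_kinase > n_peptides")
  set.seed(seed)
  base <- sample(P)  # disjoint backbone
  sets <- lapply(seq_len(n_kinases), function(i) {
    if (overlap == 0 || n_kinases * k <= P) {
      idx <- base[((i - 1L) * k + 1L):(i * k)]
    } else {
      idx <- sample.int(P, k)
    }
    n_shared <- floor(overlap * k)
    if (n_shared > 0L) {
      pool <- setdiff(seq_len(P), idx)
      idx[seq_len(n_shared)] <- sample(pool, n_shared)
    }
    universe[sort(idx)]
  })
  names(sets) <- sprintf("KIN%02d", seq_len(n_kinases))
  attr(sets, "universe") <- universe
  sets
}

#' Simulate a peptide-array experiment with planted kinase drivers
#'
#' Generates log2 signal as `baseline(peptide) + sum_k effect_k * [peptide
#' in set(k)] * [sample is PR- in the HER2- stratum] + sample noise +
#' replicate noise`, converts to the raw scale, clips and flags entries at
#' the saturation threshold, and applies Bernoulli detection dropout.
#' Ground truth (drivers, affected peptides, kinase map, true shifts) is
#' returned for recovery testing.
#'
#' @param cfg an [array_sim_config()].
#' @param ks optional pre-built kinase-substrate map (as from
#'   [simulate_ks_map()]); built from `cfg` when omitted.
#' @return list with `experiment` (a [peptide_array_experiment()], raw
#'   scale), `annotation` (data.frame), `ks_sets`, `ground_truth`.
#' @export
simulate_array <- function(cfg = array_sim_config(), ks = NULL) {
  stopifnot(inherits(cfg, "array_sim_config"))
  set.seed(cfg$seed)
  P <- cfg$n_peptides; S <- cfg$n_samples; R <- cfg$n_replicates
  if (is.null(ks))
    ks <- simulate_ks_map(P, cfg$n_kinases, cfg$substrates_per_kinase,
                          cfg$overlap, seed = cfg$seed + 104729L)
  peptide_ids <- attr(ks, "universe")
  stopifnot(length(peptide_ids) == P)
  sample_ids <- sprintf("S%02d", seq_len(S))

  n_pr_pos <- round(cfg$pr_pos_frac * S)
  n_her2_neg <- round(cfg$her2_neg_frac * S)
  pr <- rep("neg", S); pr[sample(S, n_pr_pos)] <- "pos"
  her2 <- rep("pos", S); her2[sample(S, n_her2_neg)] <- "neg"
  annot <- data.frame(sample_id = sample_ids, er = "pos", pr = pr,
                      her2 = her2, stringsAsFactors = FALSE)

  baseline <- rnorm(P, cfg$baseline_mean, cfg$baseline_sd)
  shift <- matrix(0, P, S, dimnames = list(peptide_ids, sample_ids))
  target <- pr == "neg" & her2 == "neg"
  for (k in names(cfg$driver_kinases)) {
    rows <- match(ks[[k]], peptide_ids)
    shift[rows, target] <- shift[rows, target] +
      cfg$driver_kinases[[k]] * cfg$sample_sd
  }
  mu <- baseline + shift  # P x S expected log2 level
  log2sig <- array(NA_real_, dim = c(P, S, R),
                   dimnames = list(peptide_ids, sample_ids, NULL))
  biological <- matrix(rnorm(P * S, 0, cfg$sample_sd), P, S)
  for (r in seq_len(R))
    log2sig[, , r] <- mu + biological +
      matrix(rnorm(P * S, 0, cfg$replicate_noise_sd), P, S)
  raw <- 2^log2sig
  saturated <- raw >= cfg$saturation_threshold
  raw[saturated] <- cfg$saturation_threshold
  drop <- array(runif(P * S * R) < cfg$dropout_prob, dim = dim(raw))
  raw[drop] <- NA_real_
  saturated[drop] <- FALSE

  exp <- peptide_array_experiment(raw, saturated, peptide_ids, sample_ids)
  affected <- lapply(names(cfg$driver_kinases), function(k) ks[[k]])
  names(affected) <- names(cfg$driver_kinases)
  list(experiment = exp, annotation = annot, ks_sets = ks,
       ground_truth = list(driver_kinases = cfg$driver_kinases,
                           affected_peptides = affected,
                           true_shift = shift,
                           baseline_log2 = setNames(baseline, peptide_ids)))
}

#' Cohort simulation configuration
#'
#' Defaults emulate a desk-scale ER+ expression cohort: mostly HER2-
#' samples, ~30\% PR-, a 24-gene kinase signature differentially expressed
#' by PR status in the HER2- stratum, a latent two-cluster structure
#' concordant with PR status, and exponential survival with a
#' cluster-dependent hazard and independent exponential censoring.
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param pr_neg_frac,her2_neg_frac sample label fractions (ER+ always).
#' @param signature_effects named numeric vector: per-gene log-expression
#'   shift applied to PR- samples of the HER2- stratum (positive = up in
#'   PR-). The default plants 24 tyrosine-kinase genes, including LCK and
#'   FGFR4 up and FRK and MST1R down in PR-, at magnitude 0.8.
#' @param cluster_pr_concordance probability that a PR- sample falls in the
#'   high-risk latent cluster (and a PR+ sample in the low-risk one).
#' @param cluster_hazard_ratio multiplicative event hazard of the high-risk
#'   cluster.
#' @param baseline_hazard exponential event rate of the low-risk cluster
#'   (per month; default median survival ~ 58 months).
#' @param censoring_rate target fraction of censored records.
#' @param baseline_mean,baseline_sd,noise_sd expression model parameters
#'   (log-intensity scale).
#' @param seed integer seed.
#' @return list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_genes = 1000L, n_samples = 300L,
                              pr_neg_frac = 0.3, her2_neg_frac = 0.93,
                              signature_effects = NULL,
                              cluster_pr_concordance = 0.8,
                              cluster_hazard_ratio = 2,
                              baseline_hazard = 0.012,
                              censoring_rate = 0.3,
                              baseline_mean = 8, baseline_sd = 1,
                              noise_sd = 1, seed = 1L) {
  if (is.null(signature_effects)) {
    up <- c("LCK", "FGFR4", "EGFR", "ERBB2", "INSR", "JAK2", "KDR",
            "FLT1", "RET", "EPHA2", "EPHB1", "FES")
    down <- c("FRK", "MST1R", "PDGFRA", "FGFR3", "EPHA1", "EPHA7", "NTRK1",
              "SRC", "SYK", "TEK", "ABL1", "MET")
    signature_effects <- c(setNames(rep(0.8, length(up)), up),
                           setNames(rep(-0.8, length(down)), down))
  }
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              pr_neg_frac = pr_neg_frac, her2_neg_frac = her2_neg_frac,
              signature_effects = signature_effects,
              cluster_pr_concordance = cluster_pr_concordance,
              cluster_hazard_ratio = cluster_hazard_ratio,
              baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(cfg$n_genes >= length(cfg$signature_effects),
            cfg$n_samples >= 8L,
            cfg$pr_neg_frac > 0, cfg$pr_neg_frac < 1,
            cfg$cluster_hazard_ratio > 0,
            cfg$censoring_rate >= 0, cfg$censoring_rate < 1,
            cfg$cluster_pr_concordance >= 0,
            cfg$cluster_pr_concordance <= 1)
  structure(cfg, class = "cohort_sim_config")
}

#' Simulate an expression/survival cohort
#'
#' Expression is Gaussian around per-gene baselines; the signature genes
#' are shifted by PR status within the HER2- stratum. Each sample carries a
#' latent risk-cluster label concordant with its PR status; survival times
#' are exponential with the high-risk cluster's hazard multiplied by
#' `cluster_hazard_ratio`, under independent exponential censoring tuned to
#' the target censoring rate.
#'
#' @param cfg a [cohort_sim_config()].
#' @return list with `expr` (gene x sample matrix), `annotation`,
#'   `survival` (data.frame `sample_id`, `time`, `event`), `ground_truth`
#'   (signature effects, latent cluster labels, hazards).
#' @export
simulate_cohort <- function(cfg = cohort_sim_config()) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes; S <- cfg$n_samples
  sig <- cfg$signature_effects
  other <- sprintf("GENE%04d", seq_len(G - length(sig)))
  genes <- c(names(sig), other)
  sample_ids <- sprintf("P%04d", seq_len(S))

  n_pr_neg <- round(cfg$pr_neg_frac * S)
  n_her2_neg <- round(cfg$her2_neg_frac * S)
  pr <- rep("pos", S); pr[sample(S, n_pr_neg)] <- "neg"
  her2 <- rep("pos", S); her2[sample(S, n_her2_neg)] <- "neg"
  annot <- data.frame(sample_id = sample_ids, er = "pos", pr = pr,
                      her2 = her2, stringsAsFactors = FALSE)

  baseline <- rnorm(G, cfg$baseline_mean, cfg$baseline_sd)
  expr <- matrix(rnorm(G * S, 0, cfg$noise_sd), G, S,
                 dimnames = list(genes, sample_ids)) + baseline
  target <- pr == "neg" & her2 == "neg"
  expr[names(sig), target] <- expr[names(sig), target] + sig

  p_high <- ifelse(pr == "neg", cfg$cluster_pr_concordance,
                   1 - cfg$cluster_pr_concordance)
  cluster <- ifelse(runif(S) < p_high, 2L, 1L)
  hazard <- cfg$baseline_hazard *
    ifelse(cluster == 2L, cfg$cluster_hazard_ratio, 1)
  t_event <- rexp(S, rate = hazard)
  cens_rate <- mean(hazard) * cfg$censoring_rate /
    max(1 - cfg$censoring_rate, 1e-12)
  t_cens <- if (cfg$censoring_rate > 0) rexp(S, rate = cens_rate) else
    rep(Inf, S)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  survival <- data.frame(sample_id = sample_ids, time = time,
                         event = event, stringsAsFactors = FALSE)
  list(expr = expr, annotation = annot, survival = survival,
       ground_truth = list(signature_effects = sig,
                           cluster = setNames(cluster, sample_ids),
                           hazard = setNames(hazard, sample_ids),
                           cluster_hazard_ratio = cfg$cluster_hazard_ratio))
}
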