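# Programmatic fixtures and independent brute-force oracles used across the
# suite. Oracles deliberately use plain loops, not the package's vectorised
# code paths.

make_exp <- function(signal, saturated = NULL) {
  d <- dim(signal)
  dimnames(signal) <- list(sprintf("PEP%03d_1_13", seq_len(d[1])),
                           sprintf("S%02d", seq_len(d[2])), NULL)
  peptide_array_experiment(signal, saturated)
}

make_annot <- function(sample_ids, pr, er = "pos", her2 = "neg") {
  data.frame(sample_id = sample_ids, er = er, pr = pr, her2 = her2,
             stringsAsFactors = FALSE)
}

# Brute-force reimplementation of the preprocessing rules, applied in the
# stated order: saturation masking -> replicate collapse (CV rule) ->
# detection filter. Plain per-cell loops.
brute_preprocess <- function(exp, cfg) {
  sig <- exp$signal
  sig[exp$saturated] <- NA_real_
  if (cfg$input_scale == "log2") sig <- 2^sig
  keep1 <- logical(dim(sig)[1])
  for (i in seq_len(dim(sig)[1])) keep1[i] <- any(!is.na(sig[i, , ]))
  sig <- sig[keep1, , , drop = FALSE]
  P <- dim(sig)[1]; S <- dim(sig)[2]
  M <- matrix(NA_real_, P, S,
              dimnames = list(exp$peptide_ids[keep1], exp$sample_ids))
  for (i in seq_len(P)) for (j in seq_len(S)) {
    reps <- sig[i, j, ]
    reps <- reps[!is.na(reps)]
    if (!length(reps)) next
    if (length(reps) >= 2) {
      cv <- stats::sd(reps) / mean(reps)
      if (is.finite(cv) && cv > cfg$replicate_cv_max) {
        far <- which.max(abs(reps - stats::median(reps)))
        reps <- reps[-far]
      }
    }
    M[i, j] <- log2(mean(reps))
  }
  keep2 <- logical(P)
  for (i in seq_len(P)) {
    det <- 0
    for (j in seq_len(S))
      if (!is.na(M[i, j]) && M[i, j] > cfg$detection_floor) det <- det + 1
    keep2[i] <- det / S >= cfg$min_detect_frac
  }
  M[keep2, , drop = FALSE]
}

# Standardized mean difference by the defining formula, plain arithmetic.
smd_oracle <- function(x_neg, x_pos) {
  n1 <- length(x_neg); n2 <- length(x_pos)
  sp2 <- ((n1 - 1) * stats::var(x_neg) + (n2 - 1) * stats::var(x_pos)) /
    (n1 + n2 - 2)
  (mean(x_neg) - mean(x_pos)) / sqrt(sp2)
}

# Exhaustive sample-label permutation count for one kinase set: enumerates
# every split of the columns into a neg group of the observed size and
# counts strict exceedances of |tau|.
sig_count_oracle <- function(X, is_neg, members) {
  n <- ncol(X)
  n_neg <- sum(is_neg)
  tau_for <- function(neg_idx) {
    pos_idx <- setdiff(seq_len(n), neg_idx)
    mean(vapply(members, function(p)
      smd_oracle(X[p, neg_idx], X[p, pos_idx]), numeric(1)))
  }
  tau_obs <- tau_for(which(is_neg))
  splits <- utils::combn(n, n_neg)
  m <- 0
  for (j in seq_len(ncol(splits)))
    if (abs(tau_for(splits[, j])) > abs(tau_obs)) m <- m + 1
  list(tau = tau_obs, m = m, M = ncol(splits))
}

# Exhaustive substrate-subset count: every subset of the universe of the
# set's size.
spec_count_oracle <- function(delta, members) {
  tau_obs <- mean(delta[members])
  subsets <- utils::combn(names(delta), length(members))
  m <- 0
  for (j in seq_len(ncol(subsets)))
    if (abs(mean(delta[subsets[, j]])) > abs(tau_obs)) m <- m + 1
  list(tau = tau_obs, m = m, M = ncol(subsets))
}

recovery_config <- function(seed) {
  array_sim_config(n_peptides = 144L, n_samples = 20L, n_replicates = 3L,
                   pr_pos_frac = 0.5, her2_neg_frac = 1,
                   n_kinases = 20L, substrates_per_kinase = 6L,
                   overlap = 0,
                   driver_kinases = c(KIN01 = 1.0, KIN02 = 1.5,
                                      KIN03 = 2.0),
                   seed = seed)
}

extdata <- function(f) system.file("extdata", f, package = "kinact")
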