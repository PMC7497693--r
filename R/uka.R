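#' Per-substrate group effect
#'
#' Standardized mean difference per peptide: `delta = (mean of the
#' receptor-negative group - mean of the receptor-positive group) / pooled
#' sd`, on log2 values. The sign convention makes the downstream kinase
#' statistic tau positive when activity is lower in the positive (e.g. PR+)
#' group. Substrates with zero pooled variance or fewer than two values per
#' group are excluded with a log entry.
#'
#' @inheritParams group_test
#' @return named numeric vector of effects, one per scoreable substrate.
#' @export
peptide_effect <- function(mat, annot, stratum = c(er = "pos", her2 = "neg"),
                           grouping = "pr") {
  validate_annotation(annot, colnames(mat))
  samples <- intersect(colnames(mat), .stratum_samples(annot, stratum))
  g <- .group_labels(annot, samples, grouping)
  idx_neg <- which(g == "neg")
  idx_pos <- which(g == "pos")
  if (length(idx_neg) < 2L || length(idx_pos) < 2L)
    stop("each group needs at least 2 samples")
  X <- mat[, samples, drop = FALSE]
  d <- .row_smd(X, idx_neg, idx_pos)
  names(d) <- rownames(X)
  if (anyNA(d))
    message(sum(is.na(d)), " substrate(s) excluded (zero pooled variance ",
            "or too few values): ",
            paste(names(d)[is.na(d)], collapse = ", "))
  d[!is.na(d)]
}

#' Kinase difference statistic
#'
#' tau is the (prediction-)weighted mean of the per-substrate effects over a
#' kinase's predicted substrate set; tau > 0 indicates lower activity of
#' that kinase's substrates in the receptor-positive group.
#'
#' @param delta named effect vector from [peptide_effect()].
#' @param set character vector of substrate ids predicted for the kinase.
#' @param weights optional positive prediction weights, either named by
#'   substrate or aligned with `set`; uniform when absent.
#' @return tau, or `NA` (with a warning) when the set does not intersect the
#'   scored substrates.
#' @export
kinase_statistic <- function(delta, set, weights = NULL) {
  if (!is.null(weights) && is.null(names(weights)))
    names(weights) <- set
  members <- intersect(set, names(delta))
  if (!length(members)) {
    warning("substrate set has no overlap with scored substrates")
    return(NA_real_)
  }
  w <- if (is.null(weights)) rep(1, length(members)) else
    unname(weights[members])
  if (any(!is.finite(w) | w <= 0)) stop("prediction weights must be positive")
  weighted.mean(delta[members], w)
}

#' Permutation Q-score from exceedance counts
#'
#' `Q = -10 * log10(max(m / M, 1 / M))` where `m` is the number of the `M`
#' permutations whose statistic strictly exceeds the observed one in
#' absolute value. Q is 0 when every permutation exceeds and is capped at
#' `10 * log10(M)` when none does.
#'
#' @param m integer count(s) of exceedances, `0 <= m <= M`.
#' @param M number of permutations, `>= 1`.
#' @return numeric Q-score(s).
#' @examples
#' q_from_counts(0, 500)   # 26.9897
#' q_from_counts(25, 500)  # 13.0103
#' @export
q_from_counts <- function(m, M) {
  if (any(M < 1) || any(m < 0) || any(m > M))
    stop("require 0 <= m <= M and M >= 1")
  -10 * log10(pmax(m / M, 1 / M))
}

# Sample-label assignments: columns are index sets for the "neg" group.
# Exhaustive over all choose(n, n_neg) distinct assignments when that count
# is <= M, otherwise M simple Monte Carlo draws (uniqueness not enforced).
.label_splits <- function(n, n_neg, M) {
  total <- choose(n, n_neg)
  if (total <= M) {
    list(neg = combn(n, n_neg), M = as.integer(total), exhaustive = TRUE)
  } else {
    list(neg = replicate(M, sort(sample.int(n, n_neg))), M = as.integer(M),
         exhaustive = FALSE)
  }
}

# Substrate subsets of size k from a universe of size U: columns are index
# vectors. Exhaustive when choose(U, k) <= M.
.subset_splits <- function(U, k, M) {
  total <- choose(U, k)
  if (total <= M) {
    list(idx = combn(U, k), M = as.integer(total), exhaustive = TRUE)
  } else {
    list(idx = replicate(M, sample.int(U, k)), M = as.integer(M),
         exhaustive = FALSE)
  }
}

# Strict exceedance count |tau_p| > |tau| with a tiny relative guard so
# exact mathematical ties (e.g. the label complement, where tau_p = -tau)
# are never counted when the two code paths round differently.
.count_exceed <- function(tau_p, tau) {
  sum(abs(tau_p) > abs(tau) * (1 + 1e-12) + 1e-12, na.rm = TRUE)
}

# Effect matrix over label permutations: draws x peptides.
.perm_delta <- function(X, splits) {
  n <- ncol(X)
  out <- matrix(NA_real_, nrow = splits$M, ncol = nrow(X))
  for (j in seq_len(splits$M)) {
    neg <- splits$neg[, j]
    out[j, ] <- .row_smd(X, neg, setdiff(seq_len(n), neg))
  }
  out
}

#' Significance score of a kinase set
#'
#' Permutes the sample (group) labels within the stratum, recomputes the
#' kinase statistic tau for each permutation, and counts how often the
#' permuted |tau| strictly exceeds the observed |tau|. When the number of
#' distinct label assignments is at most `M` the permutations are
#' enumerated exhaustively instead of sampled.
#'
#' @inheritParams group_test
#' @param set substrate ids of the kinase's predicted set.
#' @param weights optional prediction weights (see [kinase_statistic()]).
#' @param M number of permutations (default 500).
#' @param seed optional integer seed for the permutation draws.
#' @return list with `tau`, `m` (exceedance count), `M` (permutations
#'   used), `q`, `exhaustive`.
#' @export
significance_score <- function(mat, annot, set, weights = NULL, M = 500L,
                               seed = NULL,
                               stratum = c(er = "pos", her2 = "neg"),
                               grouping = "pr") {
  stopifnot(M >= 1L)
  if (!is.null(seed)) set.seed(seed)
  samples <- intersect(colnames(mat), .stratum_samples(annot, stratum))
  g <- .group_labels(annot, samples, grouping)
  n_neg <- sum(g == "neg")
  if (n_neg == 0L || n_neg == length(g))
    stop("degenerate grouping: one group is empty")
  delta <- peptide_effect(mat, annot, stratum, grouping)
  tau <- kinase_statistic(delta, set, weights)
  if (is.na(tau)) stop("substrate set has no scoreable overlap")
  if (!is.null(weights) && is.null(names(weights))) names(weights) <- set
  members <- intersect(set, names(delta))
  w <- if (is.null(weights)) NULL else unname(weights[members])
  X <- mat[members, samples, drop = FALSE]
  splits <- .label_splits(length(samples), n_neg, M)
  D <- .perm_delta(X, splits)
  tau_p <- .weighted_row_means(D, seq_along(members), w)
  m <- .count_exceed(tau_p, tau)
  list(tau = tau, m = m, M = splits$M, q = q_from_counts(m, splits$M),
       exhaustive = splits$exhaustive)
}

#' Specificity score of a kinase set
#'
#' Permutes the peptide (substrate) labels: draws random substrate subsets
#' of the same size as the kinase's set from the scoreable universe, applies
#' the same weight multiset in drawn order, recomputes tau, and counts
#' strict exceedances of |tau|. Exhaustive over all subsets when their
#' number is at most `M`.
#'
#' @param delta named effect vector from [peptide_effect()]; its names are
#'   the scoreable universe.
#' @inheritParams significance_score
#' @return list with `tau`, `m`, `M`, `q`, `exhaustive`.
#' @export
specificity_score <- function(delta, set, weights = NULL, M = 500L,
                              seed = NULL) {
  stopifnot(M >= 1L)
  if (!is.null(seed)) set.seed(seed)
  universe <- names(delta)
  if (!is.null(weights) && is.null(names(weights))) names(weights) <- set
  members <- intersect(set, universe)
  if (!length(members)) stop("substrate set has no scoreable overlap")
  if (length(members) >= length(universe))
    stop("specificity undefined: set covers the whole scoreable universe")
  tau <- kinase_statistic(delta, members, weights)
  w <- if (is.null(weights)) NULL else unname(weights[members])
  sub <- .subset_splits(length(universe), length(members), M)
  if (is.null(w)) {
    tau_p <- colMeans(matrix(delta[as.vector(sub$idx)],
                             nrow = length(members)))
  } else {
    tau_p <- as.vector(w %*% matrix(delta[as.vector(sub$idx)],
                                    nrow = length(members))) / sum(w)
  }
  m <- .count_exceed(tau_p, tau)
  list(tau = tau, m = m, M = sub$M, q = q_from_counts(m, sub$M),
       exhaustive = sub$exhaustive)
}

# Deterministic per-kinase RNG stream so specificity draws do not depend on
# the order the sets are supplied.
.kinase_seed <- function(seed, name) {
  (as.integer(seed) + sum(utf8ToInt(name)) * 131L) %% 2147483587L
}

#' Upstream kinase ranking
#'
#' Scores every kinase set against the observed group difference: tau (the
#' weighted standardized-mean-difference statistic), a significance Q-score
#' from sample-label permutations and a specificity Q-score from
#' substrate-set permutations, then ranks kinases by the sum of the two
#' Q-scores (descending). Ties are broken by |tau| descending, then kinase
#' name. Kinases whose predicted set has no overlap with the scoreable
#' substrates are skipped and reported in the `skipped` attribute.
#'
#' Sample-label permutations are shared across kinases (they permute the
#' same column labels); specificity draws use a per-kinase stream derived
#' from `seed` and the kinase name, so the ranking does not depend on the
#' order the sets are supplied.
#'
#' @inheritParams group_test
#' @param sets named list: kinase name -> character vector of substrate ids
#'   (e.g. from [read_kinase_sets()]).
#' @param weights optional named list of per-kinase prediction weight
#'   vectors.
#' @param M permutations per score (default 500).
#' @param seed integer seed driving all permutation draws.
#' @return data.frame sorted by `combined` descending with columns
#'   `kinase`, `n_substrates`, `tau`, `m_sig`, `q_sig`, `m_spec`, `q_spec`,
#'   `combined`, `rank`; attributes `M_sig`, `M_spec` (per-kinase
#'   permutation counts) and `skipped`.
#' @export
rank_kinases <- function(mat, annot, sets, weights = NULL, M = 500L,
                         seed = 1L, stratum = c(er = "pos", her2 = "neg"),
                         grouping = "pr") {
  stopifnot(M >= 1L, is.list(sets), !is.null(names(sets)))
  delta <- peptide_effect(mat, annot, stratum, grouping)
  universe <- names(delta)
  members <- lapply(sets, intersect, y = universe)
  skipped <- names(sets)[lengths(members) == 0L]
  keep <- setdiff(names(sets), skipped)
  if (!length(keep)) stop("no kinase set overlaps the scoreable substrates")
  if (length(skipped))
    message(length(skipped), " kinase(s) skipped (no substrate overlap): ",
            paste(skipped, collapse = ", "))

  samples <- intersect(colnames(mat), .stratum_samples(annot, stratum))
  g <- .group_labels(annot, samples, grouping)
  n_neg <- sum(g == "neg")
  X <- mat[universe, samples, drop = FALSE]

  wts <- function(k) {
    if (is.null(weights) || is.null(weights[[k]])) return(NULL)
    w <- weights[[k]]
    if (is.null(names(w))) names(w) <- sets[[k]]
    unname(w[members[[k]]])
  }

  tau <- vapply(keep, function(k)
    kinase_statistic(delta, members[[k]], wts(k)), numeric(1))

  # significance: one shared set of label permutations
  set.seed(seed)
  splits <- .label_splits(length(samples), n_neg, M)
  D <- .perm_delta(X, splits)
  colnames(D) <- universe
  m_sig <- vapply(keep, function(k) {
    tau_p <- .weighted_row_means(D, members[[k]], wts(k))
    .count_exceed(tau_p, tau[[k]])
  }, numeric(1))
  q_sig <- q_from_counts(m_sig, splits$M)

  # specificity: per-kinase substrate-set permutations
  spec <- lapply(keep, function(k) {
    if (length(members[[k]]) >= length(universe))
      stop("specificity undefined for '", k,
           "': set covers the whole scoreable universe")
    specificity_score(delta, members[[k]], wts(k), M = M,
                      seed = .kinase_seed(seed, k))
  })
  m_spec <- vapply(spec, `[[`, numeric(1), "m")
  q_spec <- vapply(spec, `[[`, numeric(1), "q")
  M_spec <- vapply(spec, `[[`, integer(1), "M")

  res <- data.frame(
    kinase = keep,
    n_substrates = lengths(members)[keep],
    tau = unname(tau),
    m_sig = unname(m_sig), q_sig = unname(q_sig),
    m_spec = unname(m_spec), q_spec = unname(q_spec),
    combined = unname(q_sig + q_spec),
    stringsAsFactors = FALSE
  )
  ord <- order(-res$combined, -abs(res$tau), res$kinase)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "M_sig") <- splits$M
  attr(res, "M_spec") <- M_spec
  attr(res, "skipped") <- skipped
  res
}
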