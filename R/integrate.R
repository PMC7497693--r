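#' Differential gene expression by receptor status
#'
#' Per-gene Welch t-test between the two `grouping` groups within a
#' stratum, with family-wise (Bonferroni, default) or BH correction over
#' all tested genes. Genes with zero variance in both groups get adjusted
#' p = 1 but remain in the tested universe (they count towards the
#' correction factor).
#'
#' @param expr gene x sample log-intensity matrix with unique rownames.
#' @inheritParams group_test
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @param alpha adjusted-p threshold (strict `<`).
#' @return data.frame of the selected genes (`gene`, `p_raw`, `p_adj`,
#'   `mean_neg`, `mean_pos`, `lfc`), sorted by `p_raw`; attribute
#'   `n_tested` holds the size of the tested universe.
#' @export
de_genes <- function(expr, annot, stratum = c(er = "pos", her2 = "neg"),
                     grouping = "pr", correction = c("bonferroni", "BH"),
                     alpha = 0.05) {
  correction <- match.arg(correction)
  if (anyDuplicated(rownames(expr))) stop("duplicate gene symbols")
  validate_annotation(annot, colnames(expr))
  samples <- intersect(colnames(expr), .stratum_samples(annot, stratum))
  g <- .group_labels(annot, samples, grouping)
  idx_neg <- which(g == "neg")
  idx_pos <- which(g == "pos")
  if (length(idx_neg) < 2L || length(idx_pos) < 2L)
    stop("each group needs at least 2 samples")
  X <- expr[, samples, drop = FALSE]
  w <- .row_welch(X, idx_neg, idx_pos)
  p <- w$p
  flat <- !is.finite(w$t) & w$var1 == 0 & w$var2 == 0
  p[flat] <- 1
  p_adj <- p.adjust(p, method = correction)
  res <- data.frame(gene = rownames(X), p_raw = p, p_adj = p_adj,
                    mean_neg = w$mean1, mean_pos = w$mean2,
                    lfc = w$mean2 - w$mean1, stringsAsFactors = FALSE)
  res <- res[!is.na(res$p_adj) & res$p_adj < alpha, , drop = FALSE]
  res <- res[order(res$p_raw), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- nrow(X)
  res
}

#' Restrict a gene table to kinome genes
#'
#' Intersects differential-expression hits with a catalogue of kinase gene
#' symbols (case-normalized). The packaged default catalogue of human
#' protein tyrosine kinase symbols is at
#' `system.file("extdata", "kinome_ptk.txt", package = "kinact")`.
#'
#' @param gene_table data.frame with a `gene` column (e.g. [de_genes()]).
#' @param kinome_list character vector of kinase gene symbols.
#' @return the subset of `gene_table` whose genes are in the kinome list.
#' @export
filter_kinome <- function(gene_table, kinome_list) {
  stopifnot(length(kinome_list) > 0L)
  keep <- toupper(gene_table$gene) %in% toupper(kinome_list)
  out <- gene_table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-cluster sample stratification on a gene signature
#'
#' Hierarchical clustering of the sample columns (Euclidean distance,
#' complete linkage) on the expression of the signature genes, cut at
#' `k = 2`. Cluster labels are oriented deterministically: cluster 2 is the
#' cluster with the higher mean expression of `orient_genes` (by default
#' the whole signature) — so with a signature of genes up-regulated in the
#' receptor-negative group, cluster 2 is the receptor-negative-enriched,
#' high-risk cluster.
#'
#' @param expr gene x sample expression matrix.
#' @param signature_genes genes to cluster on; must be present in `expr`.
#' @param k number of clusters (the stratification is defined for 2).
#' @param orient_genes genes whose mean expression orients the labels;
#'   defaults to `signature_genes`.
#' @return list of class `signature_clustering` with `selected_genes`,
#'   `clusters` (named integer vector, values 1/2), `hclust`, `distance`,
#'   `linkage`.
#' @export
cluster_samples <- function(expr, signature_genes, k = 2L,
                            orient_genes = NULL) {
  missing_genes <- setdiff(signature_genes, rownames(expr))
  if (length(missing_genes))
    stop("signature genes absent from expression matrix: ",
         paste(missing_genes, collapse = ", "))
  if (k > ncol(expr)) stop("k exceeds the number of samples")
  S <- expr[signature_genes, , drop = FALSE]
  d <- dist(t(S), method = "euclidean")
  if (max(d) == 0)
    stop("samples are indistinguishable on the signature; no second cluster")
  hc <- hclust(d, method = "complete")
  raw <- cutree(hc, k = k)
  if (length(unique(raw)) < k) stop("empty cluster after cut")
  if (is.null(orient_genes)) orient_genes <- signature_genes
  sig_mean <- colMeans(expr[orient_genes, , drop = FALSE], na.rm = TRUE)
  cl_mean <- tapply(sig_mean, raw, mean)
  # relabel so labels follow increasing signature mean: cluster 2 = high
  relabel <- rank(cl_mean, ties.method = "first")
  clusters <- setNames(as.integer(relabel[as.character(raw)]), names(raw))
  structure(list(selected_genes = signature_genes, clusters = clusters,
                 hclust = hc, distance = "euclidean",
                 linkage = "complete"),
            class = "signature_clustering")
}

#' Kaplan-Meier curve
#'
#' Product-limit estimator for right-censored data, computed from the
#' defining formula: at each distinct observed time, `S(t)` is multiplied
#' by `1 - d/n` with `d` events among `n` at risk. A leading row at time 0
#' with survival 1 is included.
#'
#' @param time non-negative event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @return data.frame with `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), all(time >= 0),
            all(event %in% c(0, 1)))
  times <- sort(unique(time))
  n_risk <- vapply(times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(times, function(t) sum(time == t & event == 1),
                    numeric(1))
  n_censor <- vapply(times, function(t) sum(time == t & event == 0),
                     numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  rbind(
    data.frame(time = 0, n_risk = length(time), n_event = 0, n_censor = 0,
               surv = 1),
    data.frame(time = times, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, surv = surv)
  )
}

#' Two-sample log-rank test with Kaplan-Meier curves
#'
#' Standard log-rank statistic computed from the 2 x 2 tables at each
#' distinct event time: with `n1` of `n` subjects at risk in group 1 and
#' `d` events, group 1 contributes observed `d1`, expected `d * n1 / n` and
#' hypergeometric variance `d * (n1/n) * (1 - n1/n) * (n - d)/(n - 1)`.
#' The statistic `(O1 - E1)^2 / V` is referred to a chi-square with 1
#' degree of freedom.
#'
#' @param survival data.frame with columns `sample_id`, `time`, `event`.
#' @param groups two-level factor/vector aligned with `survival` rows, or
#'   named by `sample_id`.
#' @return list with `chi_square`, `p`, `observed`, `expected` (per
#'   group), and `curves` — a named list of [km_curve()] data.frames.
#' @export
km_logrank <- function(survival, groups) {
  stopifnot(all(c("sample_id", "time", "event") %in% colnames(survival)),
            all(survival$time >= 0), all(survival$event %in% c(0, 1)))
  if (!is.null(names(groups)))
    groups <- groups[as.character(survival$sample_id)]
  if (length(groups) != nrow(survival))
    stop("group labels do not align with survival records")
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required")
  if (any(table(groups) == 0L)) stop("a group has no subjects")
  if (sum(survival$event) == 0L) stop("no events observed")

  time <- survival$time
  event <- survival$event
  g1 <- groups == levels(groups)[1]
  ev_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  curves <- lapply(levels(groups), function(lv) {
    i <- groups == lv
    km_curve(time[i], event[i])
  })
  names(curves) <- levels(groups)
  obs <- c(O1, sum(event) - O1)
  exp_ <- c(E1, sum(event) - E1)
  names(obs) <- names(exp_) <- levels(groups)
  list(chi_square = chi, p = p, observed = obs, expected = exp_,
       curves = curves)
}

#' Intersect upstream kinase hits with differentially expressed kinase genes
#'
#' Candidate regulators are the kinases that both score in the upstream
#' kinase ranking and appear among the differentially expressed kinome
#' genes. Each candidate is annotated with its tau direction (which group
#' its substrate activity favours) and its expression log fold change, and
#' the list is sorted by upstream-kinase rank.
#'
#' @param uka_scores [rank_kinases()] output.
#' @param kinase_gene_table [filter_kinome()] output (needs `gene`, `lfc`,
#'   `p_adj`).
#' @return data.frame `kinase`, `rank`, `tau`, `direction`,
#'   `expression_lfc`, `expression_p_adj`, sorted by rank.
#' @export
intersect_candidates <- function(uka_scores, kinase_gene_table) {
  stopifnot(nrow(uka_scores) > 0L, nrow(kinase_gene_table) > 0L)
  i <- match(toupper(uka_scores$kinase), toupper(kinase_gene_table$gene))
  hit <- !is.na(i)
  out <- data.frame(
    kinase = uka_scores$kinase[hit],
    rank = uka_scores$rank[hit],
    tau = uka_scores$tau[hit],
    direction = ifelse(uka_scores$tau[hit] > 0,
                       "higher_activity_in_neg", "higher_activity_in_pos"),
    expression_lfc = kinase_gene_table$lfc[i[hit]],
    expression_p_adj = kinase_gene_table$p_adj[i[hit]],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
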