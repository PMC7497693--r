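#' Per-peptide two-group differential phosphorylation
#'
#' Welch two-sample t-test on log2 activity values for each peptide,
#' comparing the `grouping` status (default progesterone-receptor status)
#' within a receptor stratum (default ER+/HER2-). Reports raw p, BH-adjusted
#' q, per-group means and the log2 fold change `lfc = mean_pos - mean_neg`
#' (negative lfc means higher phosphorylation in the receptor-negative
#' group). Missing values are dropped pairwise per peptide; a peptide with
#' fewer than two non-missing values in either group, or no variance in
#' both groups, is skipped with a log entry.
#'
#' @param mat peptide x sample log2 matrix (from
#'   [preprocess_experiment()]).
#' @param annot sample annotation data.frame (`sample_id`, `er`, `pr`,
#'   `her2`).
#' @param stratum named character vector of status requirements applied
#'   before grouping, e.g. `c(er = "pos", her2 = "neg")`.
#' @param grouping annotation column defining the two groups (levels
#'   `"neg"`, `"pos"`).
#' @param gene_map optional named vector mapping protein names (the prefix
#'   of the substrate id) to gene symbols.
#' @return data.frame sorted by `p_raw` ascending with columns
#'   `substrate_id`, `gene_symbol`, `p_raw`, `q`, `mean_neg`, `mean_pos`,
#'   `lfc`.
#' @export
group_test <- function(mat, annot, stratum = c(er = "pos", her2 = "neg"),
                       grouping = "pr", gene_map = NULL) {
  validate_annotation(annot, colnames(mat))
  samples <- intersect(colnames(mat), .stratum_samples(annot, stratum))
  if (length(samples) < 4L)
    stop("fewer than 4 samples in the requested stratum")
  X <- mat[, samples, drop = FALSE]
  g <- .group_labels(annot, samples, grouping)
  idx_neg <- which(g == "neg")
  idx_pos <- which(g == "pos")
  if (length(idx_neg) < 2L || length(idx_pos) < 2L)
    stop("each ", grouping, " group needs at least 2 samples in the stratum")
  w <- .row_welch(X, idx_neg, idx_pos)
  skip <- w$n1 < 2L | w$n2 < 2L | !is.finite(w$t)
  if (any(skip))
    message(sum(skip), " peptide(s) skipped (insufficient values or zero variance): ",
            paste(rownames(X)[skip], collapse = ", "))
  ids <- rownames(X)[!skip]
  parsed <- parse_peptide_id(ids, gene_map)
  res <- data.frame(
    substrate_id = ids,
    gene_symbol = ifelse(is.na(parsed$gene_symbol),
                         parsed$protein_name, parsed$gene_symbol),
    p_raw = w$p[!skip],
    q = NA_real_,
    mean_neg = w$mean1[!skip],
    mean_pos = w$mean2[!skip],
    lfc = w$mean2[!skip] - w$mean1[!skip],
    stringsAsFactors = FALSE
  )
  res$q <- p.adjust(res$p_raw, method = "BH")
  res <- res[order(res$p_raw, res$substrate_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select significant substrates
#'
#' Filters a differential-phosphorylation table at the chosen statistic and
#' threshold, sorted by raw p; the number of distinct gene symbols among the
#' selected substrates is attached as attribute `n_genes` (several peptides
#' can probe the same kinase gene).
#'
#' @param results output of [group_test()] (or any table with `p_raw`, `q`,
#'   `gene_symbol`).
#' @param alpha significance threshold (strict `<`).
#' @param on statistic to threshold: raw p or BH q.
#' @return filtered data.frame, attribute `n_genes` = distinct gene symbols.
#' @export
select_significant <- function(results, alpha = 0.05,
                               on = c("p_raw", "q")) {
  on <- match.arg(on)
  stopifnot(nrow(results) > 0L)
  sel <- results[!is.na(results[[on]]) & results[[on]] < alpha, ,
                 drop = FALSE]
  sel <- sel[order(sel$p_raw), , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "n_genes") <- length(unique(sel$gene_symbol))
  sel
}

#' Unsupervised peptide clustering
#'
#' Agglomerative hierarchical clustering of peptide rows (Euclidean
#' distance, complete linkage), with the tree cut into `k` clusters. On
#' these arrays the clusters separate peptides by overall phosphorylation
#' level (high / moderate / low), hence the default `k = 3`.
#'
#' @param mat peptide x sample log2 matrix; rows must not be all-missing.
#' @param k number of clusters.
#' @return list of class `peptide_clusters` with `assignment` (named
#'   integer vector of cluster labels), `hclust`, `distance`, `linkage`.
#' @export
cluster_peptides <- function(mat, k = 3L) {
  stopifnot(is.matrix(mat))
  if (k > nrow(mat)) stop("k exceeds the number of peptides")
  if (any(rowSums(!is.na(mat)) == 0L))
    stop("all-missing peptide rows are not clusterable")
  hc <- hclust(dist(mat, method = "euclidean"), method = "complete")
  assignment <- cutree(hc, k = k)
  structure(list(assignment = assignment, hclust = hc,
                 distance = "euclidean", linkage = "complete"),
            class = "peptide_clusters")
}

#' Per-sample cluster-mean summaries with subgroup tests
#'
#' For each peptide cluster, computes each sample's mean log2
#' phosphorylation over the cluster's peptides, then tests every pair of
#' sample subgroups (Welch t-test on the per-sample means) within each
#' cluster — the tabular counterpart of per-cluster boxplots.
#'
#' @param mat peptide x sample log2 matrix.
#' @param clusters a [cluster_peptides()] result, or a named vector of
#'   cluster labels covering the rows of `mat`.
#' @param groups named factor/character vector assigning each sample column
#'   to a subgroup (e.g. `"HER2-/PR+"`).
#' @return list with `sample_means` (data.frame: sample_id, cluster, group,
#'   mean) and `tests` (data.frame: cluster, group1, group2, p).
#' @export
cluster_mean_summary <- function(mat, clusters, groups) {
  if (inherits(clusters, "peptide_clusters")) clusters <- clusters$assignment
  if (!all(rownames(mat) %in% names(clusters)))
    stop("cluster assignment does not cover all matrix rows")
  clusters <- clusters[rownames(mat)]
  if (is.null(names(groups))) names(groups) <- colnames(mat)
  groups <- factor(groups[colnames(mat)])
  labs <- sort(unique(clusters))
  means <- list()
  for (cl in labs) {
    rows <- names(clusters)[clusters == cl]
    if (!length(rows)) {
      warning("cluster ", cl, " is empty; excluded")
      next
    }
    m <- colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)
    means[[as.character(cl)]] <- data.frame(
      sample_id = colnames(mat), cluster = cl,
      group = as.character(groups), mean = unname(m),
      stringsAsFactors = FALSE)
  }
  sample_means <- do.call(rbind, means)
  rownames(sample_means) <- NULL
  lv <- levels(groups)
  tests <- list()
  for (cl in unique(sample_means$cluster)) {
    sm <- sample_means[sample_means$cluster == cl, ]
    if (length(lv) < 2L) next
    for (a in seq_len(length(lv) - 1L)) for (b in seq((a + 1L), length(lv))) {
      x <- sm$mean[sm$group == lv[a]]
      y <- sm$mean[sm$group == lv[b]]
      p <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) {
        # constant data: identical means carry no evidence of difference
        if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      })
      tests[[length(tests) + 1L]] <- data.frame(
        cluster = cl, group1 = lv[a], group2 = lv[b], p = p,
        stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(cluster = integer(), group1 = character(),
               group2 = character(), p = numeric())
  list(sample_means = sample_means, tests = tests)
}
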