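#' Run the full analysis pipeline from a configuration
#'
#' Chains preprocessing, differential phosphorylation, upstream kinase
#' analysis and (when cohort inputs are configured) the expression/survival
#' integration stage. All input paths are validated before any computation;
#' every source of randomness flows from the single top-level `seed`
#' (split deterministically per stage), so a rerun with the same
#' configuration and seed produces byte-identical outputs.
#'
#' The configuration is a YAML file or an equivalent nested list:
#' \preformatted{
#' seed: 7
#' out_dir: results/run1
#' preprocess:
#'   signals: signals.tsv        # long-format signal TSV
#'   annot: annotation.tsv
#'   min_detect_frac: 0.25
#'   input_scale: raw
#' diffphos:
#'   stratum: {er: pos, her2: neg}
#'   grouping: pr
#'   alpha: 0.05
#'   k_clusters: 3
#' uka:
#'   sets: kinases.gmt
#'   weights: ~                  # optional weights TSV
#'   permutations: 500
#' integrate:                    # optional stage
#'   expr: expression.tsv
#'   annot: cohort_annotation.tsv
#'   surv: survival.tsv
#'   kinome: kinome.txt
#' }
#'
#' @param config path to a YAML file, or a nested list with the same
#'   structure.
#' @return the run report (named list), invisibly; also written to
#'   `out_dir/report.json` alongside the stage output TSVs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir),
            !is.null(config$preprocess), !is.null(config$uka))
  seed <- as.integer(config$seed %||% 1L)

  # validate all referenced inputs before computing anything
  paths <- c(config$preprocess$signals, config$preprocess$annot,
             config$uka$sets, config$uka$weights,
             config$integrate$expr, config$integrate$annot,
             config$integrate$surv, config$integrate$kinome)
  missing_paths <- paths[!file.exists(paths)]
  if (length(missing_paths))
    stop("input file(s) not found: ", paste(missing_paths, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  pp <- config$preprocess
  cfg <- preprocess_config(
    min_detect_frac = pp$min_detect_frac %||% 0.25,
    detection_floor = pp$detection_floor %||% 0,
    saturation_threshold = pp$saturation_threshold %||% 2^16,
    replicate_cv_max = pp$replicate_cv_max %||% 0.5,
    input_scale = pp$input_scale %||% "raw")
  exp <- read_signal_tsv(pp$signals)
  annot <- read_annotation_tsv(pp$annot)
  n_raw <- length(exp$peptide_ids)
  message("preprocess: ", n_raw, " peptides, ",
          length(exp$sample_ids), " samples")
  exp2 <- remove_saturated(exp, cfg)
  mat <- detection_filter(collapse_replicates(exp2, cfg), cfg)
  write_matrix_tsv(mat, file.path(config$out_dir, "matrix.tsv"),
                   id_col = "peptide_id")
  message("preprocess: ", nrow(mat), " peptides retained")

  dp <- config$diffphos %||% list()
  stratum <- unlist(dp$stratum %||% list(er = "pos", her2 = "neg"))
  grouping <- dp$grouping %||% "pr"
  alpha <- dp$alpha %||% 0.05
  res <- group_test(mat, annot, stratum = stratum, grouping = grouping)
  sig <- select_significant(res, alpha = alpha, on = "p_raw")
  clusters <- cluster_peptides(mat, k = dp$k_clusters %||% 3L)
  write.table(res, file.path(config$out_dir, "diffphos.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(substrate_id = names(clusters$assignment),
               cluster = unname(clusters$assignment)),
    file.path(config$out_dir, "peptide_clusters.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  message("diffphos: ", nrow(sig), " substrates significant at ",
          alpha, " (", attr(sig, "n_genes"), " genes)")

  uk <- config$uka
  sets <- read_kinase_sets(uk$sets, uk$weights)
  uka <- rank_kinases(mat, annot, sets,
                      weights = attr(sets, "weights"),
                      M = uk$permutations %||% 500L,
                      seed = seed + 1L, stratum = stratum,
                      grouping = grouping)
  write.table(uka, file.path(config$out_dir, "uka.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message("uka: ", nrow(uka), " kinases ranked; top: ",
          paste(head(uka$kinase, 3L), collapse = ", "))

  report <- list(
    seed = seed,
    parameters = list(preprocess = unclass(cfg), stratum = as.list(stratum),
                      grouping = grouping, alpha = alpha,
                      permutations = uk$permutations %||% 500L),
    counts = list(peptides_raw = n_raw,
                  peptides_after_saturation = length(exp2$peptide_ids),
                  peptides_retained = nrow(mat),
                  substrates_significant = nrow(sig),
                  distinct_genes_significant = attr(sig, "n_genes"),
                  kinases_ranked = nrow(uka)),
    top_kinases = head(uka$kinase, 10L)
  )

  if (!is.null(config$integrate)) {
    it <- config$integrate
    expr <- read_matrix_tsv(it$expr)
    cannot <- read_annotation_tsv(it$annot)
    surv <- read_survival_tsv(it$surv)
    kinome <- read_kinome_list(it$kinome)
    de <- de_genes(expr, cannot, stratum = stratum, grouping = grouping,
                   correction = "bonferroni", alpha = it$alpha %||% 0.05)
    kin <- filter_kinome(de, kinome)
    write.table(de, file.path(config$out_dir, "de_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(kin, file.path(config$out_dir, "de_kinome.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$counts$de_genes <- nrow(de)
    report$counts$de_kinome_genes <- nrow(kin)
    if (nrow(kin) >= 2L) {
      # cluster and compare survival within the configured stratum only
      stratum_samples <- intersect(colnames(expr),
                                   .stratum_samples(cannot, stratum))
      orient <- kin$gene[kin$lfc < 0]  # up in the receptor-negative group
      if (!length(orient)) orient <- kin$gene
      sc <- cluster_samples(expr[, stratum_samples, drop = FALSE],
                            kin$gene, orient_genes = orient)
      surv_st <- surv[surv$sample_id %in% stratum_samples, , drop = FALSE]
      lab <- sc$clusters[as.character(surv_st$sample_id)]
      lr <- km_logrank(surv_st, lab)
      write.table(
        data.frame(sample_id = names(sc$clusters),
                   cluster = unname(sc$clusters)),
        file.path(config$out_dir, "sample_clusters.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(chi_square = lr$chi_square, p = lr$p,
             observed = as.list(lr$observed),
             expected = as.list(lr$expected),
             curves = lapply(lr$curves, function(cv)
               list(time = cv$time, surv = cv$surv))),
        file.path(config$out_dir, "survival.json"),
        auto_unbox = TRUE, digits = NA)
      report$survival <- list(chi_square = lr$chi_square, p = lr$p)
      message(sprintf("integrate: log-rank chi-square %.3f (p = %.3g)",
                      lr$chi_square, lr$p))
    }
    if (nrow(kin)) {
      cand <- intersect_candidates(uka, kin)
      write.table(cand, file.path(config$out_dir, "candidates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report$candidates <- cand$kinase
      report$counts$candidates <- nrow(cand)
      message("integrate: ", nrow(cand),
              " candidate kinase(s) in both analyses")
    }
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
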