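#' Read a long-format signal TSV into a peptide-array experiment
#'
#' Expected columns: `peptide_id`, `sample_id`, `replicate` (1-based
#' integer), `signal`, `saturated` (0/1). Missing spots may be encoded as
#' `NA` in `signal` or simply absent as rows.
#'
#' @param path TSV file path.
#' @return a [peptide_array_experiment()].
#' @export
read_signal_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide_id", "sample_id", "replicate", "signal", "saturated")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("signal TSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  peptides <- unique(df$peptide_id)
  samples <- unique(df$sample_id)
  R <- max(df$replicate)
  sig <- array(NA_real_, dim = c(length(peptides), length(samples), R),
               dimnames = list(peptides, samples, NULL))
  sat <- array(FALSE, dim = dim(sig), dimnames = dimnames(sig))
  idx <- cbind(match(df$peptide_id, peptides),
               match(df$sample_id, samples), df$replicate)
  sig[idx] <- df$signal
  sat[idx] <- df$saturated == 1 & !is.na(df$signal)
  peptide_array_experiment(sig, sat, peptides, samples)
}

#' Write a peptide-array experiment as a long-format signal TSV
#'
#' @param exp a [peptide_array_experiment()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_signal_tsv <- function(exp, path) {
  d <- dim(exp$signal)
  df <- data.frame(
    peptide_id = rep(exp$peptide_ids, times = d[2] * d[3]),
    sample_id = rep(rep(exp$sample_ids, each = d[1]), times = d[3]),
    replicate = rep(seq_len(d[3]), each = d[1] * d[2]),
    signal = as.vector(exp$signal),
    saturated = as.integer(as.vector(exp$saturated))
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a numeric matrix TSV
#'
#' Rows are features (peptides or genes) in the first column, columns are
#' samples; missing values are encoded `NA`.
#'
#' @param path TSV path.
#' @return `read_matrix_tsv`: numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param mat numeric matrix with dimnames.
#' @param id_col name for the feature-id column.
#' @return `write_matrix_tsv`: `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation TSV
#'
#' Columns: `sample_id`, `er`, `pr`, `her2` with `pos`/`neg` statuses.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_annotation_tsv <- function(path) {
  annot <- read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(annot)
  annot
}

#' Read kinase-substrate sets from a GMT file
#'
#' Standard GMT: one kinase per line, `name<TAB>description<TAB>id...`.
#' Parsed with [fgsea::gmtPathways()]. An optional weights TSV (`kinase`,
#' `substrate_id`, `weight`) supplies positive prediction weights.
#'
#' @param path GMT path.
#' @param weights_path optional weights TSV path.
#' @return named list of substrate-id vectors; when weights are given,
#'   attribute `weights` holds a named list of weight vectors.
#' @export
read_kinase_sets <- function(path, weights_path = NULL) {
  sets <- fgsea::gmtPathways(path)
  if (any(lengths(sets) == 0L)) stop("empty kinase set in GMT")
  if (!is.null(weights_path)) {
    wdf <- read.delim(weights_path, stringsAsFactors = FALSE)
    need <- c("kinase", "substrate_id", "weight")
    if (!all(need %in% colnames(wdf)))
      stop("weights TSV lacks column(s): ",
           paste(setdiff(need, colnames(wdf)), collapse = ", "))
    if (any(wdf$weight <= 0)) stop("prediction weights must be positive")
    weights <- lapply(split(wdf, wdf$kinase), function(d)
      setNames(d$weight, d$substrate_id))
    attr(sets, "weights") <- weights
  }
  sets
}

#' Write kinase-substrate sets as GMT
#'
#' @param sets named list of substrate-id vectors.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "kinase substrate set") {
  lines <- vapply(names(sets), function(k)
    paste(c(k, description, sets[[k]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a kinome gene list (one symbol per line)
#'
#' @param path text file path; blank lines and `#` comments ignored.
#' @return character vector of gene symbols.
#' @export
read_kinome_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("empty kinome list")
  unique(x)
}

#' Read a survival TSV
#'
#' Columns: `sample_id`, `time` (non-negative), `event` (0/1).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_survival_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("survival TSV lacks column(s): ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  stopifnot(all(df$time >= 0), all(df$event %in% c(0, 1)))
  df
}
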