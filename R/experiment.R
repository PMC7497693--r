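#' Peptide-array experiment container
#'
#' Bundles the raw end-level signal tensor (peptide x sample x technical
#' replicate), a saturation flag tensor of the same shape, and the peptide /
#' sample identifiers. Signal values are non-negative fluorescence readouts;
#' a flagged entry means the spot reached the scanner's saturation threshold
#' and its value is unreliable.
#'
#' @param signal numeric 3-d array, peptides x samples x replicates. May
#'   contain `NA` for dropped-out spots.
#' @param saturated logical array of the same dimensions; `NULL` means no
#'   entry is saturated.
#' @param peptide_ids,sample_ids character vectors naming the first two
#'   dimensions; taken from `dimnames(signal)` when omitted.
#' @return An object of class `peptide_array_experiment`: a list with
#'   elements `signal`, `saturated`, `peptide_ids`, `sample_ids`.
#' @export
peptide_array_experiment <- function(signal, saturated = NULL,
                                     peptide_ids = NULL, sample_ids = NULL) {
  if (!is.array(signal) || length(dim(signal)) != 3L)
    stop("`signal` must be a 3-d array (peptide x sample x replicate)")
  if (is.null(peptide_ids)) peptide_ids <- dimnames(signal)[[1]]
  if (is.null(sample_ids)) sample_ids <- dimnames(signal)[[2]]
  if (is.null(peptide_ids) || is.null(sample_ids))
    stop("peptide and sample identifiers are required")
  if (anyDuplicated(peptide_ids))
    stop("peptide identifiers must be unique")
  if (length(peptide_ids) != dim(signal)[1] ||
      length(sample_ids) != dim(signal)[2])
    stop("identifier lengths do not match signal dimensions")
  if (is.null(saturated)) {
    saturated <- array(FALSE, dim = dim(signal))
  }
  if (!identical(dim(saturated), dim(signal)))
    stop("`saturated` must have the same dimensions as `signal`")
  if (any(signal < 0, na.rm = TRUE))
    stop("signal values must be non-negative")
  dimnames(signal) <- list(peptide_ids, sample_ids, NULL)
  dimnames(saturated) <- dimnames(signal)
  structure(
    list(signal = signal, saturated = saturated,
         peptide_ids = peptide_ids, sample_ids = sample_ids),
    class = "peptide_array_experiment"
  )
}

#' @export
print.peptide_array_experiment <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf(
    "peptide_array_experiment: %d peptides x %d samples x %d replicates\n",
    d[1], d[2], d[3]))
  cat(sprintf("  saturated entries: %d; missing entries: %d\n",
              sum(x$saturated, na.rm = TRUE), sum(is.na(x$signal))))
  invisible(x)
}

#' Parse a substrate peptide identifier
#'
#' Array substrates are identified as `<protein>_<start>_<end>`, e.g.
#' `"CDK2_8_20"` is residues 8-20 of CDK2. The gene symbol can differ from
#' the protein name (e.g. peptide `B3AT_39_51` maps to gene `SLC4A1`), so it
#' is only filled in when a protein-to-gene mapping is supplied.
#'
#' @param id character vector of substrate identifiers.
#' @param gene_map optional named character vector mapping protein names to
#'   gene symbols.
#' @return data.frame with columns `substrate_id`, `protein_name`,
#'   `start_residue`, `end_residue`, `gene_symbol` (NA when unmapped).
#' @examples
#' parse_peptide_id(c("CDK2_8_20", "EPHB1_921_933"))
#' @export
parse_peptide_id <- function(id, gene_map = NULL) {
  pat <- "^(.+)_([0-9]+)_([0-9]+)$"
  ok <- grepl(pat, id)
  if (any(!ok))
    stop("malformed substrate id(s): ", paste(id[!ok], collapse = ", "))
  protein <- sub(pat, "\\1", id)
  start <- as.integer(sub(pat, "\\2", id))
  end <- as.integer(sub(pat, "\\3", id))
  bad <- start > end | start <= 0L
  if (any(bad))
    stop("invalid residue range in substrate id(s): ",
         paste(id[bad], collapse = ", "))
  gene <- rep(NA_character_, length(id))
  if (!is.null(gene_map)) {
    hit <- protein %in% names(gene_map)
    gene[hit] <- unname(gene_map[protein[hit]])
  }
  data.frame(substrate_id = id, protein_name = protein,
             start_residue = start, end_residue = end,
             gene_symbol = gene, stringsAsFactors = FALSE)
}

# Samples matching every status requirement in `stratum`,
# e.g. c(er = "pos", her2 = "neg"). Order of annot rows is preserved.
.stratum_samples <- function(annot, stratum) {
  keep <- rep(TRUE, nrow(annot))
  for (marker in names(stratum)) {
    col <- match(marker, colnames(annot))
    if (is.na(col)) stop("annotation lacks a '", marker, "' column")
    keep <- keep & !is.na(annot[[col]]) & annot[[col]] == stratum[[marker]]
  }
  annot$sample_id[keep]
}

# pos/neg factor of `grouping` status for the given samples.
.group_labels <- function(annot, samples, grouping = "pr") {
  i <- match(samples, annot$sample_id)
  if (anyNA(i)) stop("samples missing from annotation: ",
                     paste(samples[is.na(i)], collapse = ", "))
  g <- annot[[grouping]][i]
  if (anyNA(g)) stop("missing '", grouping, "' status for grouped samples")
  factor(g, levels = c("neg", "pos"))
}

#' Validate a sample annotation table
#'
#' @param annot data.frame with columns `sample_id`, `er`, `pr`, `her2`;
#'   statuses coded `"pos"`/`"neg"`.
#' @param sample_ids optional identifiers that must all be annotated.
#' @return the annotation, invisibly, after validation.
#' @export
validate_annotation <- function(annot, sample_ids = NULL) {
  need <- c("sample_id", "er", "pr", "her2")
  miss <- setdiff(need, colnames(annot))
  if (length(miss)) stop("annotation lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(annot$sample_id))
    stop("duplicate sample_id in annotation")
  for (col in c("er", "pr", "her2")) {
    bad <- !annot[[col]] %in% c("pos", "neg", NA)
    if (any(bad)) stop("invalid ", col, " status: ",
                       paste(unique(annot[[col]][bad]), collapse = ", "))
  }
  if (!is.null(sample_ids)) {
    absent <- setdiff(sample_ids, annot$sample_id)
    if (length(absent)) stop("samples missing from annotation: ",
                             paste(absent, collapse = ", "))
  }
  invisible(annot)
}
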