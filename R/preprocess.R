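#' Preprocessing configuration
#'
#' Collects the quality-filtering parameters applied to a raw peptide-array
#' experiment before any group comparison.
#'
#' @param min_detect_frac minimum fraction of samples in which a peptide must
#'   be detected to be retained (boundary inclusive). Default 0.25, i.e. a
#'   peptide detected in at least 25\% of the samples is kept.
#' @param detection_floor a collapsed log2 value must be strictly above this
#'   floor (and non-missing) to count as detected. Default 0.
#' @param saturation_threshold raw-scale signal at or above which a spot is
#'   considered saturated (used by the simulator and at load time).
#' @param replicate_cv_max maximum coefficient of variation (raw scale)
#'   tolerated among technical replicates of one (peptide, sample) cell;
#'   above it the replicate farthest from the median is excluded before
#'   averaging. Default 0.5.
#' @param input_scale `"raw"` if the signal tensor holds raw fluorescence
#'   (log2 applied at collapse), `"log2"` if already log2-transformed.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(min_detect_frac = 0.25,
                              detection_floor = 0,
                              saturation_threshold = 2^16,
                              replicate_cv_max = 0.5,
                              input_scale = c("raw", "log2")) {
  input_scale <- match.arg(input_scale)
  stopifnot(is.finite(min_detect_frac), min_detect_frac > 0,
            min_detect_frac <= 1,
            is.finite(detection_floor), detection_floor >= 0,
            is.finite(saturation_threshold), saturation_threshold >= 0,
            is.finite(replicate_cv_max), replicate_cv_max > 0)
  structure(list(min_detect_frac = min_detect_frac,
                 detection_floor = detection_floor,
                 saturation_threshold = saturation_threshold,
                 replicate_cv_max = replicate_cv_max,
                 input_scale = input_scale),
            class = "preprocess_config")
}

#' Mask saturated spots
#'
#' Saturated spots are unreliable and are removed from the analysis: every
#' flagged entry becomes missing, and peptides whose entries are all masked
#' or missing are dropped entirely.
#'
#' @param exp a [peptide_array_experiment()].
#' @param cfg a [preprocess_config()] (unused beyond validation; masking is
#'   driven by the experiment's saturation flags).
#' @return a `peptide_array_experiment` with saturated entries set to `NA`
#'   and fully-masked peptides removed.
#' @export
remove_saturated <- function(exp, cfg = preprocess_config()) {
  stopifnot(inherits(exp, "peptide_array_experiment"))
  sig <- exp$signal
  sig[exp$saturated] <- NA_real_
  keep <- apply(!is.na(sig), 1L, any)
  if (!all(keep))
    message(sum(!keep), " peptide(s) fully saturated/missing, removed: ",
            paste(exp$peptide_ids[!keep], collapse = ", "))
  sat <- exp$saturated
  sat[] <- FALSE
  peptide_array_experiment(sig[keep, , , drop = FALSE],
                           sat[keep, , , drop = FALSE],
                           exp$peptide_ids[keep], exp$sample_ids)
}

#' Collapse technical replicates to a per-sample log2 matrix
#'
#' Per (peptide, sample) cell: if the raw-scale coefficient of variation of
#' the unmasked replicates exceeds `replicate_cv_max`, the replicate
#' farthest from the replicate median is excluded; the mean of the remaining
#' replicates is then log2-transformed. Cells with no unmasked replicate
#' become `NA`.
#'
#' @inheritParams remove_saturated
#' @return numeric matrix, peptides x samples, log2 scale.
#' @examples
#' sig <- array(c(100, 100, 1000), dim = c(1, 1, 3),
#'              dimnames = list("PEP1_1_13", "S1", NULL))
#' exp <- peptide_array_experiment(sig)
#' collapse_replicates(exp, preprocess_config(replicate_cv_max = 0.5))
#' @export
collapse_replicates <- function(exp, cfg = preprocess_config()) {
  stopifnot(inherits(exp, "peptide_array_experiment"),
            inherits(cfg, "preprocess_config"))
  sig <- exp$signal
  if (cfg$input_scale == "log2") sig <- 2^sig
  n_rep <- rowSums(!is.na(sig), dims = 2L)
  m <- rowMeans(sig, na.rm = TRUE, dims = 2L)
  m[n_rep == 0L] <- NA_real_
  # replicate variance via E[x^2] - mean^2, unbiased
  m2 <- rowMeans(sig^2, na.rm = TRUE, dims = 2L)
  v <- (m2 - m^2) * n_rep / pmax(n_rep - 1L, 1L)
  v[v < 0] <- 0  # numerical guard
  cv <- sqrt(v) / m
  flagged <- which(n_rep >= 2L & is.finite(cv) & cv > cfg$replicate_cv_max,
                   arr.ind = TRUE)
  if (nrow(flagged)) {
    for (r in seq_len(nrow(flagged))) {
      i <- flagged[r, 1L]; j <- flagged[r, 2L]
      reps <- sig[i, j, ]
      avail <- which(!is.na(reps))
      drop <- avail[which.max(abs(reps[avail] - median(reps[avail])))]
      m[i, j] <- mean(reps[setdiff(avail, drop)])
    }
    message(nrow(flagged),
            " replicate set(s) exceeded CV threshold; one replicate excluded each")
  }
  none <- sum(n_rep == 0L)
  if (none > 0L)
    message(none, " (peptide, sample) cell(s) had no usable replicate -> NA")
  out <- log2(m)
  dimnames(out) <- list(exp$peptide_ids, exp$sample_ids)
  out
}

#' Detection filter
#'
#' Keeps exactly the peptides detected in at least `min_detect_frac` of the
#' samples (boundary inclusive), where "detected" means a non-missing value
#' strictly above `detection_floor`. Row order is preserved.
#'
#' @param mat peptide x sample matrix of collapsed log2 values.
#' @param cfg a [preprocess_config()].
#' @return the filtered matrix.
#' @export
detection_filter <- function(mat, cfg = preprocess_config()) {
  stopifnot(is.matrix(mat), inherits(cfg, "preprocess_config"))
  detected <- !is.na(mat) & mat > cfg$detection_floor
  frac <- rowMeans(detected)
  keep <- frac >= cfg$min_detect_frac
  if (!any(keep))
    warning("no peptide passed the detection filter")
  mat[keep, , drop = FALSE]
}

#' Full array preprocessing
#'
#' Applies the three quality rules in order: saturation masking, technical
#' replicate collapsing (with high-CV replicate exclusion and log2
#' transform), then the detection filter. Sample identifiers and their
#' order are never modified.
#'
#' @inheritParams remove_saturated
#' @return peptide x sample matrix of log2 activity values.
#' @export
preprocess_experiment <- function(exp, cfg = preprocess_config()) {
  exp <- remove_saturated(exp, cfg)
  mat <- collapse_replicates(exp, cfg)
  detection_filter(mat, cfg)
}
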