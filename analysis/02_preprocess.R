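#!/usr/bin/env Rscript
# Stage 2 — array preprocessing.
#
# Applies the three quality rules in order: saturated spots are masked (and
# fully saturated peptides dropped), technical replicates are collapsed to a
# per-sample mean with high-CV replicate exclusion and log2 transform, and
# peptides detected in fewer than 25% of samples are removed.

suppressMessages(library(kinact))

exp <- read_signal_tsv("results/data/signals.tsv")
cfg <- preprocess_config(min_detect_frac = 0.25, replicate_cv_max = 0.5,
                         input_scale = "raw")
message("input: ", length(exp$peptide_ids), " peptides, ",
        sum(exp$saturated), " saturated spots, ",
        sum(is.na(exp$signal)), " missing spots")
exp2 <- remove_saturated(exp, cfg)
mat <- detection_filter(collapse_replicates(exp2, cfg), cfg)
write_matrix_tsv(mat, "results/matrix.tsv", id_col = "peptide_id")
message("retained ", nrow(mat), " of ", length(exp$peptide_ids),
        " peptides after saturation, replicate and detection filters; ",
        "log2 activity matrix written to results/matrix.tsv")
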