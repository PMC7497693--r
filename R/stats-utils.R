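# Row-wise two-sample Welch statistics with per-row NA handling.
# Group 1 / group 2 are column index vectors. Returns per-row counts, means,
# variances, Welch t, Satterthwaite df and two-sided p. Rows where a group
# has < 2 non-missing values, or the pooled variance is zero, yield NaN/NA
# statistics; callers decide how to treat them.
.row_welch <- function(X, idx1, idx2) {
  X1 <- X[, idx1, drop = FALSE]
  X2 <- X[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(X1))
  n2 <- rowSums(!is.na(X2))
  m1 <- rowMeans(X1, na.rm = TRUE)
  m2 <- rowMeans(X2, na.rm = TRUE)
  v1 <- rowSums((X1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1L, 1L)
  v2 <- rowSums((X2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1L, 1L)
  v1[n1 < 2L] <- NA_real_
  v2[n2 < 2L] <- NA_real_
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(-abs(t), df)
  list(n1 = n1, n2 = n2, mean1 = m1, mean2 = m2,
       var1 = v1, var2 = v2, t = t, df = df, p = p)
}

# Row-wise standardized mean difference (mean1 - mean2) / pooled sd.
# Rows with zero pooled variance or < 2 values per group give NA.
.row_smd <- function(X, idx1, idx2) {
  w <- .row_welch(X, idx1, idx2)
  sp2 <- ((w$n1 - 1L) * w$var1 + (w$n2 - 1L) * w$var2) /
    (w$n1 + w$n2 - 2L)
  d <- (w$mean1 - w$mean2) / sqrt(sp2)
  d[!is.finite(d)] <- NA_real_
  d
}

# Column-wise weighted means of D[, members] with NA-aware renormalisation.
# D: draws x peptides matrix; w: weights aligned with `members`.
.weighted_row_means <- function(D, members, w = NULL) {
  S <- D[, members, drop = FALSE]
  if (is.null(w)) w <- rep(1, length(members))
  ok <- !is.na(S)
  S[!ok] <- 0
  num <- as.vector(S %*% w)
  den <- as.vector(ok %*% w)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
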