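# Independent straight-line re-evaluation of the MELD formula, kept separate
# from the package's scoring path on purpose: clamps and rounding are applied
# inline, scalar by scalar.
meld_oracle <- function(bili_umol, crea_umol, inr, dialysis_qualifying = FALSE) {
  b <- bili_umol / 17.1
  k <- crea_umol / 88.4
  if (dialysis_qualifying) k <- 4.0
  if (b < 1) b <- 1
  if (k < 1) k <- 1
  if (k > 4) k <- 4
  i <- if (inr < 1) 1 else inr
  s <- 10 * (0.957 * log(k) + 0.378 * log(b) + 1.12 * log(i) + 0.643)
  s <- floor(s + 0.5 + 1e-9)
  if (s < 6) s <- 6
  if (s > 40) s <- 40
  as.integer(s)
}

# Pearson chi-squared statistic from the textbook formula, no correction.
pearson_oracle <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}
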