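# Independent oracles, kept deliberately naive (plain double loops) so they
# share no code path with the implementation they check.

brute_force_s <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      s <- s + sign(x[i] - x[j])
    }
  }
  s
}

closed_form_z <- function(x) {
  n <- length(x)
  s <- brute_force_s(x)
  tie_counts <- as.numeric(table(x))
  tie_counts <- tie_counts[tie_counts > 1]
  v <- (n * (n - 1) * (2 * n + 5) -
        sum(tie_counts * (tie_counts - 1) * (2 * tie_counts + 5))) / 18
  if (s == 0 || v == 0) return(0)
  (s - sign(s)) / sqrt(v)
}

brute_force_uf <- function(x) {
  n <- length(x)
  uf <- numeric(n)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (x[i] > x[j]) s <- s + 1
      if (x[i] == x[j]) s <- s + 0.5
    }
    e <- i * (i - 1) / 4
    v <- i * (i - 1) * (2 * i + 5) / 72
    uf[i] <- if (v > 0) (s - e) / sqrt(v) else 0
  }
  uf
}

# confusion-matrix helper for mask recovery checks
mask_scores <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1, na.rm = TRUE)
  fp <- sum(pred == 1 & truth == 0, na.rm = TRUE)
  fn <- sum(pred == 0 & truth == 1, na.rm = TRUE)
  tn <- sum(pred == 0 & truth == 0, na.rm = TRUE)
  list(precision = tp / (tp + fp), recall = tp / (tp + fn),
       accuracy = (tp + tn) / (tp + fp + fn + tn))
}
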