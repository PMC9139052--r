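# Independent oracles and fixture builders shared across test files.

# Direct O(N^2) circular convolution: (x * p)[n] = sum_k x[k] p[(n - k) mod N].
circ_conv <- function(x, p) {
  N <- length(x)
  vapply(0:(N - 1), function(n) {
    sum(x * p[((n - (0:(N - 1))) %% N) + 1])
  }, numeric(1))
}

# Direct O(N^4) 2-D circular convolution of matrix m with kernel kern.
circ_conv_2d <- function(m, kern) {
  H1 <- nrow(m); H2 <- ncol(m)
  out <- matrix(0, H1, H2)
  for (i in 0:(H1 - 1)) for (j in 0:(H2 - 1)) {
    acc <- 0
    for (a in 0:(H1 - 1)) for (b in 0:(H2 - 1)) {
      acc <- acc + m[a + 1, b + 1] * kern[((i - a) %% H1) + 1, ((j - b) %% H2) + 1]
    }
    out[i + 1, j + 1] <- acc
  }
  out
}

# Brute-force AUC: all positive/negative pairs, ties count 1/2.
pairwise_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Hand-evaluated metric formulas, independent of the package implementation.
oracle_metrics <- function(tp, fp, tn, fn) {
  den_or_na <- function(num, den) if (den == 0) NA_real_ else num / den
  list(acc = 100 * (tp + tn) / (tp + fp + tn + fn),
       sen = 100 * den_or_na(tp, tp + fn),
       spec = 100 * den_or_na(tn, tn + fp),
       pr = 100 * den_or_na(tp, tp + fp),
       mcc = den_or_na(tp * tn - fp * fn,
                       sqrt((tp + fn) * (tp + fp) * (tn + fp) * (tn + fn))))
}

# Minimal PSI-BLAST-style ASCII PSSM fixture with controllable rows.
write_pssm_fixture <- function(path, residues, scores) {
  letters20 <- aa_alphabet()
  header <- paste0("          ",
                   paste(sprintf("%4s", c(letters20, letters20)), collapse = ""))
  body <- vapply(seq_along(residues), function(m) {
    sc <- sprintf("%4d", scores[m, ])
    paste0(sprintf("%5d %s ", m, residues[[m]]), paste(c(sc, sc), collapse = ""))
  }, character(1))
  writeLines(c("", "Last position-specific scoring matrix computed",
               header, body, ""), path)
  path
}

# Small labeled feature tibble with a single perfectly separating feature.
separable_features <- function(n = 40, p = 4, seed = 7) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(d) <- sprintf("d%04d", seq_len(p))
  label <- rep(c(0L, 1L), length.out = n)
  d$d0001 <- ifelse(label == 1L, d$d0001 + 10, d$d0001 - 10)
  tibble::as_tibble(cbind(d, label = label))
}
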