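# Independent brute-force oracles used to pin expected values.

# Exhaustive two-sided Fisher p: enumerate every 2x2 table with the observed
# margins, compute each table's point probability from the multinomial
# factorial formula, and sum those not exceeding the observed table's
# probability. Tie comparison uses a 1e-9 relative slack; for margins <= 12
# distinct point probabilities differ by >= ~4e-7 relative, so the slack can
# only absorb floating-point error in mathematically exact ties.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  lprob <- function(x) {
    xs <- c(x, r1 - x, c1 - x, r2 - (c1 - x))
    if (any(xs < 0)) return(-Inf)
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
      lfactorial(n) - sum(lfactorial(xs))
  }
  support <- max(0, c1 - r2):min(c1, r1)
  lp <- vapply(support, lprob, numeric(1))
  obs <- lp[support == a]
  sum(exp(lp[lp <= obs + log1p(1e-9)]))
}

# Naive covariance-formula Pearson correlation (explicit loops, no cor()).
corr_oracle <- function(x, y) {
  x <- unname(x); y <- unname(y)
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Full pairwise correlation of matrix rows via the naive oracle.
corr_matrix_oracle <- function(m) {
  n <- nrow(m)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) out[i, j] <- corr_oracle(m[i, ], m[j, ])
  }
  dimnames(out) <- list(rownames(m), rownames(m))
  out
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small toy lipidome (3 species x 4 samples, 2 conditions) built in code
toy_lipidome <- function() {
  vals <- matrix(c(2, 3, 5, 4, 6, 10, 1, 1, 2, 2, 2, 4), nrow = 3,
                 dimnames = list(c("TG(52:0)", "FA 16:1", "PE(38:5p)"),
                                 c("S1", "S2", "S3", "S4")))
  design <- data.frame(
    condition_id = c("C75_3h", "C75_3h", "DMSO_3h", "DMSO_3h"),
    treatment = c("C75", "C75", "DMSO", "DMSO"),
    dose = c("30 uM", "30 uM", "0", "0"),
    timepoint_h = 3,
    sample_id = c("S1", "S2", "S3", "S4"),
    control_condition_id = "DMSO_3h")
  lipidome_matrix(vals, design)
}
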