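# Independent oracles used by the test suite.
#
# The worksheet tables below are a second, independent transcription in a
# different layout (flat row-major vectors, keyed the way the printed
# worksheet reads) from the CSV data shipped with the package, so a typo
# in either transcription surfaces as a cell mismatch.

# Table A, read neck-block by neck-block; within a block, trunk rows 1..5,
# legs columns 1..4.
oracle_table_a_flat <- c(
  # neck 1
  1, 2, 3, 4,
  2, 3, 4, 5,
  2, 4, 5, 6,
  3, 5, 6, 7,
  4, 6, 7, 8,
  # neck 2
  1, 2, 3, 4,
  3, 4, 5, 6,
  4, 5, 6, 7,
  5, 6, 7, 8,
  6, 7, 8, 9,
  # neck 3
  3, 3, 5, 6,
  4, 5, 6, 7,
  5, 6, 7, 8,
  6, 7, 8, 9,
  7, 8, 9, 9
)
oracle_table_a <- function(neck, trunk, legs) {
  oracle_table_a_flat[(neck - 1) * 20 + (trunk - 1) * 4 + legs]
}

# Table B, upper-arm rows 1..6; columns lower-arm 1 (wrist 1..3) then
# lower-arm 2 (wrist 1..3).
oracle_table_b_flat <- c(
  1, 2, 2,  1, 2, 3,
  1, 2, 3,  2, 3, 4,
  3, 4, 5,  4, 5, 5,
  4, 5, 5,  5, 6, 7,
  6, 7, 8,  7, 8, 8,
  7, 8, 8,  8, 9, 9
)
oracle_table_b <- function(upper_arm, lower_arm, wrist) {
  oracle_table_b_flat[(upper_arm - 1) * 6 + (lower_arm - 1) * 3 + wrist]
}

# Table C, score A rows 1..12, score B columns 1..12.
oracle_table_c_flat <- c(
  1, 1, 1, 2, 3, 3, 4, 5, 6, 7, 7, 7,
  1, 2, 2, 3, 4, 4, 5, 6, 6, 7, 7, 8,
  2, 3, 3, 3, 4, 5, 6, 7, 7, 8, 8, 8,
  3, 4, 4, 4, 5, 6, 7, 8, 8, 9, 9, 9,
  4, 4, 4, 5, 6, 7, 8, 8, 9, 9, 9, 9,
  6, 6, 6, 7, 8, 8, 9, 9, 10, 10, 10, 10,
  7, 7, 7, 8, 9, 9, 9, 10, 10, 11, 11, 11,
  8, 8, 8, 9, 10, 10, 10, 10, 10, 11, 11, 11,
  9, 9, 9, 10, 10, 10, 11, 11, 11, 12, 12, 12,
  10, 10, 10, 11, 11, 11, 11, 12, 12, 12, 12, 12,
  11, 11, 11, 11, 12, 12, 12, 12, 12, 12, 12, 12,
  12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12
)
oracle_table_c <- function(sa, sb) {
  sa <- pmin(sa, 12); sb <- pmin(sb, 12)
  oracle_table_c_flat[(sa - 1) * 12 + sb]
}

oracle_grand <- function(neck, trunk, legs, ua, la, wr,
                         load, coupling, activity) {
  sa <- oracle_table_a(neck, trunk, legs) + load
  sb <- oracle_table_b(ua, la, wr) + coupling
  pmin(pmax(oracle_table_c(sa, sb) + activity, 1), 15)
}

# --- statistics oracles ------------------------------------------------------

oracle_rmse <- function(r, t) sqrt(sum((t - r)^2) / length(r))

# classic sum-of-squared-rank-differences formula; valid without ties
oracle_spearman <- function(r, t) {
  n <- length(r)
  d <- rank(r) - rank(t)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# ICC via the stats::aov two-way ANOVA table
oracle_icc <- function(m, model) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (model == "two_way_random_absolute") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

# weighted kappa via explicit pairwise weight sums, no contingency table
oracle_weighted_kappa <- function(a, b, categories) {
  k <- length(categories)
  ia <- match(a, categories); ib <- match(b, categories)
  n <- length(a)
  w <- function(i, j) 1 - abs(i - j) / (k - 1)
  po <- mean(w(ia, ib))
  pe <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pe <- pe + mean(ia == i) * mean(ib == j) * w(i, j)
    }
  }
  (po - pe) / (1 - pe)
}

oracle_unweighted_kappa <- function(a, b, categories) {
  ia <- match(a, categories); ib <- match(b, categories)
  po <- mean(ia == ib)
  pe <- 0
  for (i in seq_along(categories)) {
    pe <- pe + mean(ia == i) * mean(ib == i)
  }
  (po - pe) / (1 - pe)
}

oracle_paired_t <- function(r, t) {
  d <- t - r
  mean(d) / (stats::sd(d) / sqrt(length(d)))
}
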