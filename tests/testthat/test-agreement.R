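test_that("rmse matches hand computation and is shift invariant", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  set.seed(11)
  r <- rnorm(20); t <- rnorm(20)
  expect_equal(rmse(r + 5, t + 5), rmse(r, t))
  # rmse^2 = bias^2 + variance of differences (population form)
  d <- t - r
  expect_equal(rmse(r, t)^2,
               mean(d)^2 + mean((d - mean(d))^2), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "shape")
})

test_that("spearman rho matches the rank-formula oracle on 100 instances", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    r <- sample(100000, n)          # tie-free
    t <- r + stats::runif(n, -2e4, 2e4)  # continuous: almost surely tie-free
    got <- spearman_rho(r, t)
    expect_equal(got$rho, oracle_spearman(r, t), tolerance = 1e-12)
    expect_true(got$p_value >= 0 && got$p_value <= 1)
  }
  expect_equal(spearman_rho(1:5, 2 * (1:5))$rho, 1)
  expect_equal(spearman_rho(1:5, 5:1)$rho, -1)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("icc matches the ANOVA-table oracle and its limiting cases", {
  # worked 4x3 matrix against the aov decomposition
  m <- matrix(c(9, 6, 8, 7,
                2, 1, 4, 1,
                5, 3, 6, 2,
                8, 2, 8, 6), nrow = 4, byrow = TRUE)
  for (model in c("two_way_random_absolute", "two_way_mixed_consistency")) {
    expect_equal(icc(m, model)$icc, oracle_icc(m, model), tolerance = 1e-9)
  }
  set.seed(202)
  for (i in 1:100) {
    n <- sample(4:10, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, sd = 2) + rep(rnorm(n, sd = 3), k), n, k)
    model <- sample(c("two_way_random_absolute",
                      "two_way_mixed_consistency"), 1)
    expect_equal(icc(m, model)$icc, oracle_icc(m, model), tolerance = 1e-9)
  }
  # identical raters with between-subject variance: perfect reliability
  m1 <- matrix(rep(c(1, 5, 9, 3), 3), ncol = 3)
  expect_equal(icc(m1)$icc, 1)
  # independent noise: ICC near zero at large n
  set.seed(7)
  m0 <- matrix(rnorm(3000), ncol = 3)
  expect_lt(abs(icc(m0)$icc), 0.1)
  expect_error(icc(matrix(1, 4, 3)), "degenerate")
})

test_that("proportion agreement counts exact matches", {
  expect_equal(proportion_agreement(1:4, 1:4), 1)
  expect_equal(proportion_agreement(1:4, c(2, 3, 4, 5)), 0)
  expect_equal(proportion_agreement(1:4, c(1, 2, 3, 5)), 0.75)
  expect_error(proportion_agreement(1:3, 1:4), "shape")
})

test_that("weighted kappa matches the explicit weight-sum oracle", {
  expect_equal(weighted_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1))$kappa, 1)
  set.seed(303)
  for (i in 1:100) {
    n <- sample(8:25, 1)
    k <- sample(3:5, 1)
    a <- sample(k, n, replace = TRUE)
    b <- pmin(pmax(a + sample(-1:1, n, replace = TRUE), 1), k)
    got <- weighted_kappa(a, b, categories = seq_len(k))
    expect_equal(got$kappa, oracle_weighted_kappa(a, b, seq_len(k)),
                 tolerance = 1e-12)
  }
  expect_error(weighted_kappa(rep(1, 5), rep(1, 5)), "kappa")
})

test_that("agreement exactly at chance gives kappa zero", {
  # 2x2 table with independent margins: counts n_ij = n * p_i * q_j
  a <- rep(c(1, 1, 2, 2), times = c(6, 6, 2, 2))   # margins 12/4 and 8/8
  b <- rep(c(1, 2, 1, 2), times = c(6, 6, 2, 2))
  expect_equal(weighted_kappa(a, b, 1:2)$kappa, 0, tolerance = 1e-12)
})

test_that("weighted kappa with two categories equals unweighted kappa", {
  set.seed(404)
  for (i in 1:50) {
    n <- sample(10:30, 1)
    a <- sample(1:2, n, replace = TRUE)
    b <- sample(1:2, n, replace = TRUE)
    if (length(unique(c(a, b))) < 2) next
    wk <- tryCatch(weighted_kappa(a, b, 1:2)$kappa, error = function(e) NULL)
    uk <- tryCatch(oracle_unweighted_kappa(a, b, 1:2),
                   error = function(e) NULL)
    if (is.null(wk) || is.null(uk) || !is.finite(uk)) next
    expect_equal(wk, uk, tolerance = 1e-12)
  }
})

test_that("paired t-test matches the textbook formula and flags significance", {
  r <- c(12.1, 11.8, 13.0, 12.5, 11.2, 12.9, 13.3, 12.0)
  t <- r + c(0.4, -0.2, 0.5, 0.1, 0.6, -0.1, 0.3, 0.2)
  got <- paired_t_test(r, t)
  expect_equal(got$t, oracle_paired_t(r, t), tolerance = 1e-12)
  set.seed(505)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    r <- rnorm(n); t <- r + rnorm(n, 0.3, 0.4)
    expect_equal(paired_t_test(r, t)$t, oracle_paired_t(r, t),
                 tolerance = 1e-9)
  }
  same <- paired_t_test(1:5 + 0.5 * rnorm(5), 1:5 + 0.5 * rnorm(5))
  expect_type(same$significant, "logical")
  # constant offset with tiny variance: overwhelmingly significant
  r <- rnorm(10)
  shifted <- paired_t_test(r, r + 10 + rnorm(10, sd = 1e-3))
  expect_true(shifted$significant)
  expect_error(paired_t_test(1:4, 1:4 + 2), "degenerate")
})

test_that("Landis-Koch labels follow the published bands", {
  expect_identical(strength_of_agreement(0.710), "substantial")
  expect_identical(strength_of_agreement(1.0), "almost perfect")
  expect_identical(strength_of_agreement(0.0), "slight")
  expect_identical(strength_of_agreement(-0.2), "poor")
  expect_identical(strength_of_agreement(0.35), "fair")
  expect_identical(strength_of_agreement(0.5), "moderate")
  expect_error(strength_of_agreement(1.2), "kappa")
})

test_that("statistics are invariant under reordering of subjects", {
  set.seed(606)
  r <- rnorm(15); t <- r + rnorm(15)
  a <- sample(1:4, 15, replace = TRUE); b <- sample(1:4, 15, replace = TRUE)
  perm <- sample(15)
  expect_equal(rmse(r, t), rmse(r[perm], t[perm]))
  expect_equal(spearman_rho(r, t)$rho, spearman_rho(r[perm], t[perm])$rho)
  expect_equal(proportion_agreement(a, b),
               proportion_agreement(a[perm], b[perm]))
  expect_equal(weighted_kappa(a, b, 1:4)$kappa,
               weighted_kappa(a[perm], b[perm], 1:4)$kappa)
  expect_equal(paired_t_test(r, t)$t, paired_t_test(r[perm], t[perm])$t)
})

test_that("agreement_report summarises per column and pooled", {
  set.seed(707)
  ref <- data.frame(angle = rnorm(24, 30, 10),
                    score = sample(1:5, 24, replace = TRUE))
  tst <- data.frame(angle = ref$angle + rnorm(24, 0, 2),
                    score = pmin(pmax(ref$score +
                                        sample(-1:1, 24, replace = TRUE),
                                      1), 5))
  rep <- agreement_report(ref, tst)
  expect_s3_class(rep, "agreement_report")
  expect_equal(rep$series, c("angle", "score", "(pooled)"))
  expect_true(all(rep$rmse >= 0))
  score_row <- rep[rep$series == "score", ]
  expect_false(is.na(score_row$p0))
  expect_false(is.na(score_row$kappa))
  expect_true(is.na(rep[rep$series == "angle", ]$p0))
  expect_error(agreement_report(ref, tst[1:10, ]), "shape")
})
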