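nat <- 0.45
plat <- 0.12

test_that("peptide rate fit recovers a noise-free rate constant", {
  days <- rep(c(15, 30, 45, 60), each = 3)
  m0 <- expected_M0(days, 0.02, nat, plat)
  fit <- fit_peptide_k(days, m0, nat, plat)
  expect_equal(fit$k, 0.02, tolerance = 1e-8)
  expect_true(fit$measurable)
  expect_true(fit$converged)
})

test_that("a series flat at natural abundance yields k = 0, not measurable", {
  days <- rep(c(15, 45, 60), each = 2)
  fit <- fit_peptide_k(days, rep(nat, length(days)), nat, plat)
  expect_equal(fit$k, 0)
  expect_false(fit$measurable)
  expect_error(fit_peptide_k(rep(15, 4), rep(0.4, 4), nat, plat), "degenerate")
})

test_that("rate recovery is within 10% under 1% multiplicative noise", {
  k_true <- 0.021
  k_hat <- vapply(1:100, function(s) {
    set.seed(s)
    days <- rep(c(15, 45, 60), each = 4)
    m0 <- expected_M0(days, k_true, nat, plat) * rlnorm(length(days), 0, 0.01)
    fit_peptide_k(days, m0, nat, plat)$k
  }, numeric(1))
  expect_true(all(abs(k_hat - k_true) / k_true < 0.10))
})

test_that("rate fit is invariant to observation order", {
  set.seed(9)
  days <- rep(c(15, 30, 60), each = 3)
  m0 <- expected_M0(days, 0.015, nat, plat) * rlnorm(9, 0, 0.01)
  f1 <- fit_peptide_k(days, m0, nat, plat)
  perm <- sample(9)
  f2 <- fit_peptide_k(days[perm], m0[perm], nat, plat)
  expect_equal(f1$k, f2$k, tolerance = 1e-10)
})

test_that("Grubbs filter matches the t-distribution critical-value formula", {
  res <- grubbs_filter(c(0.010, 0.011, 0.012), alpha = 0.05)
  expect_equal(res$retained, c(0.010, 0.011, 0.012))
  expect_equal(res$n_removed, 0L)

  res2 <- grubbs_filter(c(0.010, 0.011, 0.50), alpha = 0.05)
  expect_equal(res2$removed, 0.50)
  expect_equal(sort(res2$retained), c(0.010, 0.011))

  expect_warning(res3 <- grubbs_filter(c(0.010, 0.011)), "fewer than 3")
  expect_equal(sort(res3$retained), c(0.010, 0.011))

  # property: single-pass decisions agree with the textbook formula
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(sample(4:9, 1), 0.02, 0.002)
    if (s %% 2 == 0) x[1] <- x[1] + 0.05  # plant an outlier half the time
    got <- grubbs_filter(x, alpha = 0.05)
    expect_equal(got$n_removed >= 1, oracle_grubbs_rejects(x, 0.05))
  }
})

test_that("Grubbs filter output is invariant to input order", {
  set.seed(3)
  x <- c(rnorm(6, 0.02, 0.001), 0.08)
  a <- grubbs_filter(x)
  b <- grubbs_filter(rev(x))
  expect_equal(a$retained, b$retained)
  expect_equal(sort(a$removed), sort(b$removed))
})

test_that("protein aggregation pools peptide rates and variances", {
  one <- list(list(k = 0.02, residual_sd = 0.004, df = 5, measurable = TRUE))
  ag1 <- aggregate_protein(one)
  expect_equal(ag1$k, 0.02)
  expect_equal(ag1$pooled_sd, 0.004)
  expect_equal(ag1$half_life_d, log(2) / 0.02)

  two <- list(list(k = 0.02, residual_sd = 0.003, df = 8, measurable = TRUE),
              list(k = 0.04, residual_sd = 0.003, df = 8, measurable = TRUE))
  ag2 <- aggregate_protein(two)
  expect_equal(ag2$k, 0.03)
  expect_equal(ag2$pooled_sd, 0.003)
  expect_equal(ag2$n_peptides, 2L)

  none <- list(list(k = 0, residual_sd = 0.001, df = 5, measurable = FALSE))
  expect_false(aggregate_protein(none)$measurable)
  expect_true(is.na(aggregate_protein(none)$half_life_d))
  expect_error(aggregate_protein(list()), "no peptide")
})

test_that("protein mean k is consistent with peptide spread across seeds", {
  k_true <- 0.0211
  days <- rep(c(15, 45, 60), each = 4)
  covered <- vapply(1:50, function(s) {
    set.seed(s)
    ks <- vapply(1:4, function(i) {
      m0 <- expected_M0(days, k_true, nat, plat) * rlnorm(length(days), 0, 0.01)
      fit_peptide_k(days, m0, nat, plat)$k
    }, numeric(1))
    ci <- mean(ks) + c(-1, 1) * qt(0.975, 3) * sd(ks) / 2
    k_true >= ci[1] && k_true <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("noise-free protein-level mean equals the generating k exactly", {
  days <- rep(c(15, 30, 45, 60), each = 2)
  fits <- lapply(1:5, function(i) {
    m0 <- expected_M0(days, 0.0211, nat, plat)
    fit_peptide_k(days, m0, nat, plat)
  })
  expect_equal(aggregate_protein(fits)$k, 0.0211, tolerance = 1e-8)
})

test_that("half-life and year conversions follow the printed conventions", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.021133), 32.8, tolerance = 1e-3)
  expect_true(is.na(half_life(0)))
  # round trip k -> half-life -> k at machine precision
  ks <- c(0.0005, 0.0211, 0.3, 1.5)
  expect_equal(log(2) / half_life(ks), ks, tolerance = 1e-15)

  expect_equal(round(days_to_years(277259) / 10) * 10, 760)
  expect_equal(days_to_years(365), 1)
  expect_equal(days_to_years(0), 0)
  expect_error(days_to_years(-1), "negative")
})
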