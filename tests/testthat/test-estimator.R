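test_that("boundary cases of the closed-form estimator", {
  # no rare variants at all -> full depletion
  tab <- toy_site_table(rep(0.05, 30))
  expect_warning(fit <- estimate_lambda(tab), "boundary")
  expect_equal(fit$lambda_s, 1)
  expect_equal(fit$stderr, 0)

  # observed exactly matches expected -> no depletion, LRT p = 1
  tab2 <- toy_site_table(rep(0.05, 300), y = rep(c(1L, 0L), c(15L, 285L)))
  fit2 <- estimate_lambda(tab2)
  expect_equal(fit2$lambda_s, 0)
  expect_equal(fit2$p_value, 1, tolerance = 1e-6)
})

test_that("log-likelihood boundary values at lambda_s = 1", {
  with_rare <- toy_site_table(rep(0.05, 3), y = c(1L, 0L, 0L))
  expect_equal(loglikelihood(with_rare, 1), -Inf)
  no_rare <- toy_site_table(rep(0.05, 3))
  expect_equal(loglikelihood(no_rare, 1), 0)
  expect_error(loglikelihood(no_rare, -30), "outside")
})

test_that("closed form agrees with brute-force likelihood maximization", {
  # 50-site instances with a common allele-level rate below 0.01; for
  # homogeneous rates the bias-corrected closed form solves the exact score
  # equation, so grid search over the exact likelihood must land on it
  for (seed in 1:10) {
    set.seed(seed)
    p <- rep(0.009, 150)
    y <- rbinom(150, 1L, runif(1, 0.3, 1) * p)
    tab <- toy_site_table(p, y)
    fit <- suppressWarnings(estimate_lambda(tab))
    coarse <- seq(-4, 0.999, by = 1e-3)
    ll <- vapply(coarse, function(l) loglikelihood(tab, l), 0)
    lam0 <- coarse[which.max(ll)]
    fine <- seq(lam0 - 2e-3, min(lam0 + 2e-3, 0.9999), by = 1e-4)
    llf <- vapply(fine, function(l) loglikelihood(tab, l), 0)
    lam_grid <- fine[which.max(llf)]
    expect_lt(abs(fit$lambda_s - lam_grid), 2e-3)
    expect_lt(abs(fit$lambda_s - fit$lambda_mle), 1e-3)
  }
})

test_that("closed form tracks the exact maximizer for heterogeneous rates", {
  # with many sites the fluctuation term that separates the bias-corrected
  # closed form from the exact maximizer averages out
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(6000, 0.001, 0.01)
    y <- rbinom(6000, 1L, 0.7 * p)
    fit <- estimate_lambda(toy_site_table(p, y))
    expect_lt(abs(fit$lambda_s - fit$lambda_mle), 1e-3)
  }
})

test_that("reported standard error matches the variance formula", {
  set.seed(20)
  p <- runif(3000, 0.01, 0.1)
  y <- rbinom(3000, 1L, 0.6 * p)
  fit <- estimate_lambda(toy_site_table(p, y))
  MP <- fit$M * fit$P_bar
  v <- (1 - fit$lambda_s) / MP - (1 - fit$lambda_s)^2 * fit$T / MP^2
  expect_equal(fit$stderr, sqrt(v))
  expect_equal(fit$R_prime, sum(y))
  expect_equal(fit$P_bar, sum(p) / 1000)
  expect_equal(fit$Q_bar, fit$P_bar / 3)
})

test_that("negative depletion is returned without clamping", {
  # twice as many rare variants as expected
  set.seed(21)
  p <- rep(0.04, 3000)
  y <- rbinom(3000, 1L, 0.08)
  fit <- estimate_lambda(toy_site_table(p, y))
  expect_lt(fit$lambda_s, -0.5)
  expect_lt(fit$p_value, 0.001)
})

test_that("excluded sites contribute to neither R' nor M", {
  set.seed(22)
  p <- rep(0.05, 300)
  y <- rbinom(300, 1L, 0.05)
  tab <- toy_site_table(p, y)
  extra <- as.data.frame(toy_site_table(rep(0.3, 30), rep(1L, 30)))
  extra$pos0 <- extra$pos0 + 1000L
  extra$excluded <- TRUE
  extra$reason <- "common"
  both <- as_site_table(rbind(as.data.frame(tab), extra))
  f1 <- estimate_lambda(tab)
  f2 <- estimate_lambda(both)
  expect_equal(f2$lambda_s, f1$lambda_s)
  expect_equal(f2$M, f1$M)
  expect_equal(f2$R_prime, f1$R_prime)
})

test_that("full and simple estimators coincide without multi-allelic sites", {
  set.seed(23)
  m <- 500L
  p <- runif(3L * m, 0.01, 0.05)
  # at most one rare variant per site
  y <- rep(0L, 3L * m)
  hit_sites <- sample.int(m, 60L)
  y[(hit_sites - 1L) * 3L + sample.int(3L, 60L, replace = TRUE)] <- 1L
  tab <- toy_site_table(p, y)
  fit <- estimate_lambda(tab)
  per_site_p <- tapply(p, rep(seq_len(m), each = 3L), sum)
  simple <- estimate_lambda_simple(60L, m, mean(per_site_p))
  expect_equal(fit$lambda_s, simple, tolerance = 1e-12)

  # with a multi-allelic site they differ
  y2 <- y
  y2[(hit_sites[1] - 1L) * 3L + 1:3] <- 1L
  fit2 <- estimate_lambda(toy_site_table(p, y2))
  expect_lt(fit2$lambda_s, fit$lambda_s)
})

test_that("simple estimator validates its inputs", {
  expect_equal(estimate_lambda_simple(0L, 100L, 0.1), 1)
  expect_equal(estimate_lambda_simple(10L, 100L, 0.1), 0)
  expect_error(estimate_lambda_simple(101L, 100L, 0.1), "exceeds")
  expect_error(estimate_lambda_simple(1L, 0L, 0.1), "positive")
  expect_error(estimate_lambda_simple(1L, 10L, 0), "positive")
})

test_that("LRT p-values fall as the deficit grows", {
  p <- rep(0.05, 3000) # M * Pbar = 150
  pv <- vapply(c(150L, 120L, 90L, 60L, 30L), function(r) {
    y <- rep(0L, 3000)
    if (r > 0) y[seq_len(r)] <- 1L
    estimate_lambda(toy_site_table(p, y))$p_value
  }, 0)
  expect_true(all(diff(pv) < 0))
  expect_true(all(pv >= 0 & pv <= 1))
})

test_that("estimates are unbiased and noise-insensitive (light check)", {
  set.seed(24)
  n <- 3000L
  base_p <- rep(0.05, n)
  for (lam in c(0, 0.5)) {
    est <- vapply(1:150, function(r) {
      y <- rbinom(n, 1L, (1 - lam) * base_p)
      estimate_lambda(toy_site_table(base_p, y))$lambda_s
    }, 0)
    expect_lt(abs(mean(est) - lam), 2 * sd(est) / sqrt(150))
  }
  # mean-preserving noise in P barely moves the sampling spread
  sd_clean <- sd(vapply(1:150, function(r) {
    y <- rbinom(n, 1L, 0.5 * base_p)
    estimate_lambda(toy_site_table(base_p, y))$lambda_s
  }, 0))
  sd_noisy <- sd(vapply(1:150, function(r) {
    pr <- base_p * runif(n, 0.5, 1.5)
    pr <- pr * mean(base_p) / mean(pr)
    y <- rbinom(n, 1L, 0.5 * pr)
    estimate_lambda(toy_site_table(pr, y))$lambda_s
  }, 0))
  expect_lt(abs(sd_noisy / sd_clean - 1), 0.25)
})

test_that("lambda_fit behaves like a standard fitted model object", {
  set.seed(25)
  p <- rep(0.05, 3000)
  y <- rbinom(3000, 1L, 0.03)
  fit <- estimate_lambda(toy_site_table(p, y))
  expect_named(coef(fit), "lambda_s")
  expect_equal(unname(sqrt(vcov(fit)[1, 1])), fit$stderr)
  ci <- confint(fit)
  expect_lt(ci[1], fit$lambda_s)
  expect_gt(ci[2], fit$lambda_s)
  expect_equal(as.numeric(logLik(fit)), fit$loglik_alt)
  s <- summary(fit)
  expect_equal(unname(s["p_value"]), fit$p_value)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(3000L, 3L))
  sims2 <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(sims, sims2)
  expect_output(print(fit), "lambda_s")
  # subsampling cap is honoured and seeded
  f1 <- estimate_lambda(toy_site_table(p, y), max_sites = 200, seed = 3)
  f2 <- estimate_lambda(toy_site_table(p, y), max_sites = 200, seed = 3)
  expect_equal(f1$M, 200)
  expect_identical(f1$lambda_s, f2$lambda_s)
})
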