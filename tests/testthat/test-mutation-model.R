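test_that("context rates reproduce count ratios and normalize", {
  # context X seen 1000 times; allele C carries 10 rare variants
  set.seed(1)
  tab <- sim_context_table(1000L, c(TATATAT = 0))
  tab$Y <- 0L
  tab$Y[tab$alt == "C"][1:10] <- 1L
  raw0 <- fit_context_rates(tab, pseudocount = 0)
  expect_equal(context_rate(raw0, "TATATAT", "C"), 0.01)
  expect_equal(context_rate(raw0, "TATATAT", "G"), 0)

  # normalization: 3 alt rates + no-mutation rate sum to 1 (any pseudocount)
  raw <- fit_context_rates(tab)
  pc <- raw$pseudocount
  n <- 1000
  alts <- sum(context_rate(raw, rep("TATATAT", 3), c("A", "C", "G")))
  no_mut <- (n - 10 + pc) / (n + 4 * pc)
  expect_equal(alts + no_mut, 1, tolerance = 1e-12)
})

test_that("a context with no variants is degenerate at no-mutation", {
  tab <- sim_context_table(50L, c(AATAAAT = 0))
  raw0 <- fit_context_rates(tab, pseudocount = 0)
  expect_equal(context_rate(raw0, rep("AATAAAT", 3), c("A", "C", "G")),
               c(0, 0, 0))
})

test_that("unseen contexts fall back from 7-mer to 3-mer to base marginal", {
  set.seed(2)
  tab <- sim_context_table(500L, c(AATATAA = 0.05, CGTTTGC = 0.05))
  raw <- fit_context_rates(tab)
  # same central 3-mer "TAT", different flanks: falls back to the 3-mer rate
  r_fallback <- context_rate(raw, "GGTATGG", "C")
  expect_equal(r_fallback,
               unname((raw$k3$y["TAT C"] + 0.5) / (raw$k3$n_sites["TAT"] + 2)))
  # unseen 3-mer: central-base marginal
  r_marg <- context_rate(raw, "GGGTGGG", "C")
  expect_equal(r_marg,
               unname((raw$k1$y["T C"] + 0.5) / (raw$k1$n_sites["T"] + 2)))
  expect_error(context_rate(raw, "GGTATGG", "C", fallback = FALSE),
               "unseen")
})

test_that("covariate model recovers a unit slope on self-generated data", {
  set.seed(3)
  rates <- c(AAAAAAA = 0.02, CCCACCC = 0.04, GGGAGGG = 0.07,
             TTTATTT = 0.12, AATAAAA = 0.03, CCTCCCC = 0.055,
             GGTGGGG = 0.09, TTTTTTA = 0.015)
  tab <- sim_context_table(8500L, rates) # ~204k (site, allele) rows
  raw <- fit_context_rates(tab)
  cov <- fit_covariate_model(tab, raw, sample_fraction = 1, seed = 11)
  expect_lt(abs(cov$coefficients["logit_raw"] - 1), 0.1)
  expect_lt(abs(cov$coefficients["log_coverage"]), 0.1)
  expect_lt(abs(cov$coefficients["gc_frac"]), 0.1)
  expect_lt(abs(cov$coefficients["cpg_island"]), 0.1)
})

test_that("constant covariates give intercept-only mean recovery", {
  set.seed(4)
  tab <- sim_context_table(5000L, c(TATATAT = 0.1))
  raw <- fit_context_rates(tab)
  cov <- fit_covariate_model(tab, raw, sample_fraction = 1, seed = 11)
  pred <- predict_rates(tab, raw, cov)
  expect_lt(abs(mean(pred$P) - 0.1), 0.01)
})

test_that("covariate fits are deterministic given the seed", {
  set.seed(5)
  tab <- sim_context_table(2000L, c(TATATAT = 0.05, AACAAAA = 0.08))
  raw <- fit_context_rates(tab)
  c1 <- fit_covariate_model(tab, raw, sample_fraction = 0.5, seed = 9)
  c2 <- fit_covariate_model(tab, raw, sample_fraction = 0.5, seed = 9)
  expect_identical(c1$coefficients, c2$coefficients)
  expect_identical(c1$intercept, c2$intercept)
  expect_error(fit_covariate_model(tab, raw, sample_fraction = 0.5),
               "seed")
})

test_that("regional intercepts are recovered from shifted data", {
  set.seed(6)
  m <- 25000L
  base_logit <- stats::qlogis(0.05)
  tab <- toy_site_table(rep(0.05, 3L * m))
  tab$pos0 <- rep(seq.int(0L, by = 10L, length.out = m), each = 3L)
  tab$Y <- rbinom(3L * m, 1L, stats::plogis(base_logit + 0.5))
  sc <- fit_regional_scalers(tab, rep(base_logit, 3L * m),
                             window = 150000, step = 50000)
  expect_true(all(abs(sc$windows$intercept - 0.5) < 0.1))

  tab$Y <- rbinom(3L * m, 1L, stats::plogis(base_logit))
  sc0 <- fit_regional_scalers(tab, rep(base_logit, 3L * m),
                              window = 150000, step = 50000)
  expect_true(all(abs(sc0$windows$intercept) < 0.05))
})

test_that("window arithmetic clips the final window to the chromosome", {
  expect_equal(window_starts(250000L, 150000L, 50000L),
               c(0L, 50000L, 100000L))
  expect_equal(window_starts(100000L, 150000L, 50000L), 0L)
  # tail not reachable by a full window gets a clipped extra window
  expect_equal(window_starts(260000L, 150000L, 50000L),
               c(0L, 50000L, 100000L, 150000L))
  expect_error(fit_regional_scalers(toy_site_table(rep(0.05, 3)),
                                    rep(0, 3), window = 0),
               "positive")
})

test_that("prediction composes the stages on the logit scale", {
  set.seed(7)
  tab <- sim_context_table(200L, c(TATATAT = 0.05, AACAAAA = 0.08))
  raw <- fit_context_rates(tab)
  # identity composition: no covariate model, no scaler -> raw rates
  p_raw <- predict_rates(tab, raw)
  expect_equal(p_raw$P, context_rate(raw, tab$context7, tab$alt))

  # a +0.5 regional intercept shifts every site by exactly 0.5 logits
  sc <- structure(list(windows = data.frame(chrom = "sim", win_start = 0L,
                                            win_end = 10^9,
                                            intercept = 0.5, n_sites = 200L),
                       chrom_intercepts = c(sim = 0.5),
                       window = 150000, step = 50000, min_sites = 100),
                  class = "regional_scaler")
  p_shift <- predict_rates(tab, raw, scaler = sc)
  expect_equal(stats::qlogis(p_shift$P) - stats::qlogis(p_raw$P),
               rep(0.5, nrow(tab)), tolerance = 1e-9)
  expect_equal(stats::plogis(stats::qlogis(p_raw$P[1]) + 0.5), p_shift$P[1])
})

test_that("calibration holds on data simulated from the fitted model", {
  set.seed(8)
  rates <- c(AAAAAAA = 0.02, CCCACCC = 0.05, GGGAGGG = 0.09,
             TTTATTT = 0.13)
  tab <- sim_context_table(6000L, rates)
  model <- fit_mutation_model(tab, sample_fraction = 1, seed = 13,
                              regional = FALSE)
  tab <- predict(model, tab)
  sim <- bernoulli_simulate(tab, lambda_s = 0, seed = 21)
  rep10 <- calibration_report(sim$table, bins = 10)
  se <- sqrt(rep10$mean_P * (1 - rep10$mean_P) / rep10$n)
  expect_true(all(abs(rep10$obs_frac - rep10$mean_P) < 3 * se))

  # depletion scales observed fractions by (1 - lambda_s) in every bin
  sim5 <- bernoulli_simulate(tab, lambda_s = 0.5, seed = 22)
  rep5 <- calibration_report(sim5$table, bins = 5)
  expect_true(all(abs(rep5$obs_frac - 0.5 * rep5$mean_P) <
                    3 * sqrt(0.5 * rep5$mean_P / rep5$n)))

  one <- calibration_report(sim$table, bins = 1)
  expect_equal(one$obs_frac, mean(sim$table$Y[!sim$table$excluded]))
  expect_equal(sum(rep10$n), sum(!tab$excluded))
  expect_error(calibration_report(toy_site_table(rep(NA_real_, 3))),
               "P has not been filled|in \\(0,1\\)")
})

test_that("strand asymmetry is preserved (no reverse-complement collapsing)", {
  set.seed(9)
  tab <- sim_context_table(400L, c(AAAAAAA = 0.02, TTTTTTT = 0.10))
  raw <- fit_context_rates(tab)
  # A->G in AAAAAAA vs its reverse complement T->C in TTTTTTT
  expect_false(isTRUE(all.equal(context_rate(raw, "AAAAAAA", "G"),
                                context_rate(raw, "TTTTTTT", "C"))))
})

test_that("the estimator is null-calibrated on model-simulated data", {
  set.seed(10)
  rates <- c(AAAAAAA = 0.03, CCCACCC = 0.06, GGGAGGG = 0.10)
  tab <- sim_context_table(8000L, rates)
  model <- fit_mutation_model(tab, sample_fraction = 1, seed = 17,
                              regional = FALSE)
  tab <- predict(model, tab)
  sim <- bernoulli_simulate(tab, lambda_s = 0, seed = 23)
  fit <- estimate_lambda(sim$table)
  expect_lt(abs(fit$lambda_s), 2 * fit$stderr)
})

test_that("model bundles round-trip through the plain-text serialization", {
  set.seed(11)
  tab <- sim_context_table(1500L, c(TATATAT = 0.05, AACAAAA = 0.08))
  model <- fit_mutation_model(tab, sample_fraction = 1, seed = 19,
                              window = 2000, step = 1000, min_sites = 10)
  dir <- tempfile("bundle")
  save_mutation_model(model, dir)
  expect_true(all(file.exists(file.path(dir, c("context_rates.tsv",
                                               "covariates.json",
                                               "regional.tsv",
                                               "manifest.json")))))
  back <- load_mutation_model(dir)
  p1 <- predict(model, tab)$P
  p2 <- predict(back, tab)$P
  expect_equal(p1, p2, tolerance = 1e-12)
})
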