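# MCMC tests run shortened convergence runs (a few hundred to a couple of
# thousand iterations) to stay inside the test-time budget; the full
# 10,000-iteration protocol is exercised once in test-acceptance.R.

test_that("retained draw count is n_chains * n_post / thin", {
  coh <- generate_mixed_cohort("MQD", n_subjects = 8, seed = 3)
  cfg <- mcmc_config(n_iterations = 200, n_post = 100, thin = 10, seed = 5)
  fit <- suppressWarnings(fit_mixed(coh, "MQD", cfg))
  expect_equal(nrow(fit$samples), 3 * 100 / 10)
  expect_equal(length(fit$chain_draws), 3)
  expect_equal(nrow(fit$chain_draws[[1]]), 10)
  expect_error(mcmc_config(n_post = 100, thin = 7), "thin")
  expect_error(mcmc_config(n_chains = 1))
})

test_that("psrf is 1 on identical chains and large on separated chains", {
  v <- sin(seq_len(200))
  expect_equal(psrf(list(v, v, v)), 1)
  # equal variance, means 10 SDs apart: far above the 1.2 threshold
  set.seed(1)
  a <- rnorm(500); b <- rnorm(500) + 10
  expect_gt(psrf(list(a, b)), 1.2)
  # same distribution, long chains: R near 1
  set.seed(2)
  chains <- replicate(3, rnorm(5000), simplify = FALSE)
  expect_lt(abs(psrf(chains) - 1), 0.05)
  # degenerate: constant but different chains
  expect_identical(psrf(list(rep(1, 50), rep(2, 50))), Inf)
  expect_error(psrf(list(a)), "chains")
  expect_error(psrf(list(1:5, 1:5)), "length")
})

test_that("psrf matches a hand-computed between/within evaluation", {
  set.seed(3)
  chains <- list(rnorm(100, 0, 1), rnorm(100, 0.5, 1.5))
  half <- lapply(chains, function(v) v[51:100])
  n <- 50; m <- 2
  W <- mean(vapply(half, var, numeric(1)))
  B <- n * var(vapply(half, mean, numeric(1)))
  expect_equal(psrf(chains), sqrt(((n - 1) / n * W + B / n) / W))
})

test_that("sampled delays respect their truncation boxes", {
  coh <- generate_mixed_cohort("MQDV", nu2 = 0.1^2, n_subjects = 10, seed = 4)
  cfg <- mcmc_config(n_iterations = 400, n_post = 200, thin = 10, seed = 6)
  fit <- suppressWarnings(fit_mixed(coh, "MQDV", cfg))
  dat <- fit$data
  cc <- fit$samples[, "c"]
  expect_true(all(cc >= dat$xmin & cc <= dat$xmax))
  for (i in seq_len(dat$m)) {
    ci <- cc + fit$samples[, paste0("gamma.", dat$ids[i])]
    expect_true(all(ci >= dat$xmin_i[i] - 1e-12 & ci <= dat$xmax_i[i] + 1e-12))
  }
})

test_that("dic is deterministic given draws and matches a plain-loop oracle", {
  coh <- generate_mixed_cohort("MQD", n_subjects = 10, seed = 8)
  cfg <- mcmc_config(n_iterations = 400, n_post = 200, thin = 10, seed = 9)
  fit <- suppressWarnings(fit_mixed(coh, "MQD", cfg))
  d1 <- dic(fit); d2 <- dic(fit)
  expect_identical(d1$dic, d2$dic)

  # independent loop over draws: plain dnorm sums, no shared code path
  dat <- fit$data
  dev_loop <- apply(fit$samples, 1, function(s) {
    z <- pmax(dat$x - s[["c"]], 0)
    mu <- s[["a"]] + s[["b1"]] * z + s[["b2"]] * z^2 +
      s[paste0("u.", dat$ids)][dat$id]
    -2 * (sum(dnorm(dat$y, mu, sqrt(s[["sigma2"]]), log = TRUE)) +
            sum(dnorm(s[paste0("u.", dat$ids)], 0, sqrt(s[["tau2"]]),
                      log = TRUE)))
  })
  sbar <- colMeans(fit$samples)
  z <- pmax(dat$x - sbar[["c"]], 0)
  mu <- sbar[["a"]] + sbar[["b1"]] * z + sbar[["b2"]] * z^2 +
    sbar[paste0("u.", dat$ids)][dat$id]
  dev_hat <- -2 * (sum(dnorm(dat$y, mu, sqrt(sbar[["sigma2"]]), log = TRUE)) +
                     sum(dnorm(sbar[paste0("u.", dat$ids)], 0,
                               sqrt(sbar[["tau2"]]), log = TRUE)))
  expect_equal(d1$dic, 2 * mean(dev_loop) - dev_hat, tolerance = 1e-8)
  # conditional DIC drops the random-effect densities
  expect_false(isTRUE(all.equal(dic(fit, conditional = TRUE)$dic, d1$dic)))
})

test_that("with the likelihood switched off the delay reproduces its uniform prior", {
  coh <- generate_mixed_cohort("MQD", n_subjects = 2, points_range = c(10, 10),
                               seed = 10)
  cfg <- mcmc_config(n_iterations = 2000, n_post = 2000, thin = 2, seed = 11,
                     likelihood_weight = 0)
  fit <- suppressWarnings(fit_mixed(coh, "MQD", cfg))
  cc <- fit$samples[, "c"]
  lo <- fit$data$xmin; hi <- fit$data$xmax
  expect_true(all(cc >= lo & cc <= hi))
  expect_equal(mean(cc), (lo + hi) / 2, tolerance = 0.05 * (hi - lo))
  expect_equal(sd(cc), (hi - lo) / sqrt(12), tolerance = 0.1 * (hi - lo))
})

test_that("the MQD sampler recovers a known common delay", {
  coh <- generate_mixed_cohort("MQD", fixed = list(a = 0.5, b1 = 7, b2 = 5,
                                                   c = 0.35),
                               sigma2 = 0.25, tau2 = 0.3,
                               n_subjects = 40, seed = 12)
  cfg <- mcmc_config(n_iterations = 1500, n_post = 1000, thin = 10, seed = 13)
  fit <- fit_mixed(coh, "MQD", cfg)
  ci <- quantile(fit$samples[, "c"], c(0.025, 0.975))
  expect_lt(ci[1], 0.35)
  expect_gt(ci[2], 0.35)
  expect_equal(nrow(fit$samples), 300)
})

test_that("a zero random-intercept variance shrinks tau2 toward zero", {
  coh <- generate_mixed_cohort("MQD", tau2 = 0, sigma2 = 0.25,
                               n_subjects = 30, seed = 14)
  cfg <- mcmc_config(n_iterations = 1000, n_post = 500, thin = 10, seed = 15)
  fit <- suppressWarnings(fit_mixed(coh, "MQD", cfg))
  expect_lt(mean(fit$samples[, "tau2"]), 0.05)
})

test_that("summarize_posterior has the expected shape and a quantile oracle", {
  coh <- generate_mixed_cohort("MQDV", nu2 = 0.08^2, n_subjects = 8, seed = 16)
  cfg <- mcmc_config(n_iterations = 300, n_post = 200, thin = 10, seed = 17)
  fit <- suppressWarnings(fit_mixed(coh, "MQDV", cfg))
  ps <- summarize_posterior(fit)
  expect_setequal(ps$parameter,
                  c("a", "b1", "b2", "c", "sigma2", "tau2", "nu2"))
  expect_true(all(ps$q2.5 <= ps$mean & ps$mean <= ps$q97.5))
  row <- ps[ps$parameter == "c", ]
  expect_equal(row$mean, mean(fit$samples[, "c"]))
  expect_equal(row$q2.5,
               unname(quantile(fit$samples[, "c"], 0.025)))
  # random effects appear on request
  ps_all <- summarize_posterior(fit, include_random = TRUE)
  expect_true(any(grepl("^u\\.", ps_all$parameter)))
  expect_true(any(grepl("^gamma\\.", ps_all$parameter)))

  # degenerate single repeated draw: mean = draw, zero-width interval
  fit2 <- fit
  fit2$samples <- fit$samples[rep(1, 40), , drop = FALSE]
  ps2 <- summarize_posterior(fit2)
  expect_equal(ps2$q2.5, ps2$q97.5)
  expect_equal(ps2$mean, ps2$q2.5)
})

test_that("MPD exponent sampling stays within its prior box", {
  coh <- generate_mixed_cohort("MPD", fixed = list(a = 0.4, b2 = 6, d = 1.5,
                                                   c = 0.3),
                               n_subjects = 10, seed = 18)
  cfg <- mcmc_config(n_iterations = 400, n_post = 200, thin = 10, seed = 19)
  fit <- suppressWarnings(fit_mixed(coh, "MPD", cfg))
  expect_true(all(fit$samples[, "d"] > 0 & fit$samples[, "d"] <= 10))
  expect_true("d" %in% names(fit$psrf))
})
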