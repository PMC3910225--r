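test_that("compute_criteria implements the printed formulas", {
  # AICc penalty by direct substitution: 2*4*5/(6-4-1) = 40
  cr <- compute_criteria(sse = 1.2, n = 6, k = 4)
  expect_equal(cr$aicc - cr$aic, 40)
  expect_equal(cr$bic, 4 * log(6) - 2 * cr$loglik)
  expect_equal(cr$aic, 2 * 4 - 2 * cr$loglik)

  # rmse arithmetic oracle on random inputs
  set.seed(7)
  for (i in 1:100) {
    sse <- runif(1, 0, 50); n <- sample(4:15, 1)
    expect_equal(compute_criteria(sse, n, 3)$rmse, sqrt(sse / n))
  }

  # degenerate and undefined-AICc flags
  cr0 <- compute_criteria(0, 8, 3)
  expect_equal(cr0$rmse, 0)
  expect_true(cr0$degenerate)
  cr_na <- compute_criteria(1, 4, 3)  # n <= k + 1
  expect_false(cr_na$aicc_defined)
  expect_true(is.na(cr_na$aicc))
  # AICc >= AIC whenever defined
  cr1 <- compute_criteria(2, 10, 4)
  expect_gte(cr1$aicc, cr1$aic)
})

test_that("fit_individual recovers the printed worked-example curves", {
  fq <- fit_individual(curve_traj("qd", "QD", printed_qd), "QD")
  expect_equal(fq$params$c, 0.46, tolerance = 0.01)
  expect_lt(fq$criteria$rmse, 1e-3)

  fp <- fit_individual(curve_traj("p", "P", printed_p), "P")
  expect_equal(fp$params$d, 4.7, tolerance = 0.1)

  fpd <- fit_individual(curve_traj("pd", "PD", printed_pd), "PD")
  expect_equal(fpd$params$d, 0.9, tolerance = 0.05)
  expect_equal(fpd$params$c, 0.40, tolerance = 0.01)
})

test_that("a linear trajectory drives the delay to its lower bound", {
  xs <- (1:10) / 10
  tr <- subject_trajectory("lin", xs, 1 + 2 * xs)
  f <- fit_individual(tr, "D")
  # SSE cannot be exactly 0: the box forces c = min(x) + margin, leaving a
  # residual of b1 * margin = 2e-3 at the first point only
  expect_lt(f$criteria$rmse, 1e-3)
  expect_equal(f$params$b1, 2, tolerance = 1e-3)
  lb <- min(xs) + fit_config()$delay_lower_margin
  expect_equal(f$params$c, lb, tolerance = 1e-4)
})

test_that("fit_individual rejects underdetermined trajectories", {
  tr <- subject_trajectory("tiny", c(0.5, 1), c(1, 2))
  expect_error(fit_individual(tr, "QD"), "insufficient observations")
  expect_error(grid_oracle_fit(tr, "QD"), "insufficient observations")
})

test_that("grid oracle handles a flat trajectory in the P family", {
  tr <- subject_trajectory("flat", (1:8) / 8, rep(4, 8))
  g <- grid_oracle_fit(tr, "P")
  expect_equal(g$params$a + g$params$b2 * mean(((1:8) / 8)^g$params$d), 4,
               tolerance = 1e-6)
  expect_lt(g$criteria$rmse, 1e-8)
})

test_that("optimizer matches the grid oracle on random subjects", {
  # scaled-down version of the acceptance sweep (20 subjects here)
  coh <- generate_cohort(cohort_config(n_subjects = 20, seed = 31))
  ok <- 0L
  for (sid in cohort_ids(coh)) {
    fam <- coh$truth[[sid]]$family
    tr <- coh$trajectories[[sid]]
    opt <- fit_individual(tr, fam)
    ora <- grid_oracle_fit(tr, fam, grid_resolution = 200)
    tol <- max(1e-6, 0.01 * ora$criteria$rmse^2 * n_obs(tr))
    if (opt$criteria$rmse^2 <= ora$criteria$rmse^2 + tol) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("oracle agrees with the optimizer on the printed QD fixture", {
  g <- grid_oracle_fit(curve_traj("qd", "QD", printed_qd), "QD", 200)
  grid_step <- (1 - (1 / 12 + 1e-3)) / 199
  expect_equal(g$params$c, 0.46, tolerance = grid_step + 1e-8)
})

test_that("nested families dominate in SSE", {
  coh <- generate_cohort(cohort_config(n_subjects = 15, seed = 17))
  for (sid in cohort_ids(coh)) {
    tr <- coh$trajectories[[sid]]
    sse <- function(f) fit_individual(tr, f)$criteria$rmse^2 * n_obs(tr)
    s_d <- sse("D")
    tol <- 1e-6 + 0.01 * s_d
    expect_lte(sse("QD"), s_d + tol)
    expect_lte(sse("PD"), s_d + tol)
  }
})

test_that("rescaling ratings rescales coefficients and fixes c, d", {
  xs <- (1:12) / 12
  y <- predict_rating("PD", list(a = 0.3, b2 = 5, c = 0.4, d = 1.3), xs)
  f1 <- fit_individual(subject_trajectory("s", xs, y, check_range = FALSE), "PD")
  s <- 0.5
  f2 <- fit_individual(subject_trajectory("s", xs, s * y, check_range = FALSE), "PD")
  expect_equal(f2$params$a, s * f1$params$a, tolerance = 1e-3)
  expect_equal(f2$params$b2, s * f1$params$b2, tolerance = 0.05)
  expect_equal(f2$params$c, f1$params$c, tolerance = 0.01)
  expect_equal(f2$params$d, f1$params$d, tolerance = 0.02)
})

test_that("compare_families exploits nesting and flags the best fits", {
  tr <- curve_traj("d", "D", list(a = 0.4, b1 = 6, c = 0.35))
  cmp <- compare_families(tr)
  n <- n_obs(tr)
  expect_lt(cmp$fits$D$criteria$rmse, 1e-5)
  expect_lt(cmp$fits$PD$criteria$rmse, 1e-4)
  expect_lt(cmp$fits$QD$criteria$rmse, 1e-4)
  expect_gt(cmp$fits$P$criteria$rmse, 1e-3)  # P cannot represent the kink
  expect_true(cmp$best$rmse %in% c("D", "PD", "QD"))

  qd <- compare_families(curve_traj("qd", "QD", printed_qd))
  expect_lte(qd$fits$QD$criteria$rmse, qd$fits$D$criteria$rmse)
  pd <- compare_families(curve_traj("pd", "PD", printed_pd))
  expect_lt(pd$fits$PD$criteria$rmse, 1e-4)
})

test_that("summarize_fits reports medians/IQRs and matches a quantile oracle", {
  coh <- generate_cohort(cohort_config(n_subjects = 12, seed = 19))
  cf <- fit_cohort(coh, families = c("D", "QD"))
  s <- summarize_fits(cf, coh)
  # quantile oracle on the pooled delay estimates for D
  cs <- cf$table$c[cf$table$family == "D"]
  row <- s[s$family == "D" & s$quantity == "c", ]
  expect_equal(row$median, unname(stats::quantile(cs, 0.5)))
  expect_equal(row$q1, unname(stats::quantile(cs, 0.25)))
  expect_equal(row$q3, unname(stats::quantile(cs, 0.75)))
  # max-rating summary present
  expect_true("max_rating" %in% s$quantity)

  # single fit: median equals the fit, zero IQR width
  one <- fit_cohort(rpe_cohort(coh$trajectories[1]), families = "D")
  s1 <- summarize_fits(one)
  r1 <- s1[s1$quantity == "c", ]
  expect_equal(r1$q1, r1$q3)
  expect_equal(r1$median, one$table$c[1])

  # stratified summaries run (groups from covariates)
  sg <- summarize_fits(cf, coh, group_by = "sex")
  expect_true(all(sg$group %in% c("male", "female", NA)))
  expect_error(summarize_fits(structure(list(table = NULL),
                                        class = "cohort_fits")),
               "no fits")
})

test_that("rmse_difference_analysis excludes low-information subjects and is zero on identical pairs", {
  xs <- (1:8) / 8
  t1 <- subject_trajectory("two", xs, rep(c(1, 2), each = 4))       # 2 levels
  t2 <- subject_trajectory("three", xs, rep(c(1, 2, 3), c(3, 3, 2))) # 3 levels
  t3 <- subject_trajectory("six", xs, c(0, 1, 2, 3, 4, 5, 5, 5))     # 6 levels
  coh <- rpe_cohort(list(t1, t2, t3))
  cf <- fit_cohort(coh)
  rd <- suppressWarnings(
    rmse_difference_analysis(cf, coh, pairs = c("QD-QD", "P-D")))
  expect_setequal(unique(rd$points$subject_id), c("three", "six"))
  expect_equal(rd$excluded, "two")
  expect_true(all(rd$points$diff[rd$points$pair == "QD-QD"] == 0))
})

test_that("curved cohorts favour QD over P on average", {
  arch <- list(archetype("q", "QD",
    list(a = dist_norm(0.3, 0.1, 0, 0.6), b1 = dist_norm(2, 0.5, 1, 3),
         b2 = dist_norm(7, 1, 5, 9), c = dist_norm(0.4, 0.05, 0.3, 0.5)), 1))
  coh <- generate_cohort(cohort_config(n_subjects = 25, noise_sd = 0.2,
                                       archetypes = arch, seed = 23))
  cf <- fit_cohort(coh, families = c("P", "QD"))
  rd <- rmse_difference_analysis(cf, coh, pairs = "P-QD")
  expect_gt(mean(rd$points$diff), 0)
  expect_false(is.null(rd$smoothers[["P-QD"]]))
})
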