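test_that("a constant trajectory is represented exactly", {
  coh <- rpe_cohort(list(subject_trajectory("c1", (1:10) / 10, rep(3, 10))))
  cf <- represent_trajectories(coh)
  grid <- seq(0.01, 1, length.out = 200)
  B <- exertraj:::basis_eval(trajectory_basis(), grid)
  expect_lt(max(abs(B %*% cf[1, ] - 3)), 1e-4)
  # on the observed range the fit is essentially exact
  Bobs <- exertraj:::basis_eval(trajectory_basis(), (1:10) / 10)
  expect_lt(max(abs(Bobs %*% cf[1, ] - 3)), 1e-6)
})

test_that("a trajectory on a single basis function returns a near-unit coefficient vector", {
  basis <- trajectory_basis()
  xs <- seq(0.02, 1, length.out = 60)
  B <- exertraj:::basis_eval(basis, xs)
  j <- 5L
  coh <- rpe_cohort(list(subject_trajectory("b5", xs, B[, j])))
  cf <- represent_trajectories(coh, basis, ridge = 1e-6)
  e <- numeric(basis$dim); e[j] <- 1
  expect_lt(max(abs(cf[1, ] - e)), 1e-3)
})

test_that("dense noiseless delay curves are reconstructed accurately", {
  xs <- seq(0.02, 1, length.out = 80)
  qd <- predict_rating("QD", list(a = 0.3, b1 = 3, b2 = 6, c = 0.4), xs)
  coh <- rpe_cohort(list(subject_trajectory("q", xs, qd)))
  cf <- represent_trajectories(coh)
  B <- exertraj:::basis_eval(trajectory_basis(), xs)
  err <- drop(B %*% cf[1, ]) - qd
  # the cubic basis cannot reproduce the slope kink exactly; mean error is
  # well under 0.05 rating units (max sits at the changepoint)
  expect_lt(sqrt(mean(err^2)), 0.05)
  expect_lt(max(abs(err)), 0.1)
  expect_error(represent_trajectories(
    rpe_cohort(list(subject_trajectory("s", c(0.5, 1), c(1, 2)))),
    trajectory_basis(), ridge = -1))
})

test_that("two well-separated archetypes are recovered at auto K", {
  coh <- two_archetype_cohort(n_subjects = 60, noise_sd = 0.2, seed = 21)
  co <- represent_trajectories(coh)
  cm <- cluster_trajectories(co, K = "auto", seed = 3)
  expect_equal(cm$K, 2L)
  expect_gte(cluster_accuracy(cm$assignment, truth_labels(coh)), 0.95)
  # auto-K stable across seeds
  for (s in 1:5) {
    expect_equal(cluster_trajectories(co, K = "auto", seed = s)$K, 2L)
  }
})

test_that("four moderately separated archetypes beat random labelling", {
  arch <- list(
    archetype("lin", "D", list(a = dist_point(0.3), b1 = dist_point(8),
                               c = dist_point(0.2)), 0.25),
    archetype("slow", "D", list(a = dist_point(0.3), b1 = dist_point(3),
                                c = dist_point(0.3)), 0.25),
    archetype("quad", "QD", list(a = dist_point(0.3), b1 = dist_point(1),
                                 b2 = dist_point(8), c = dist_point(0.3)), 0.25),
    archetype("plate", "QD", list(a = dist_point(0.4), b1 = dist_point(26),
                                  b2 = dist_point(-20), c = dist_point(0.45)), 0.25))
  wins <- 0L
  for (rep in 1:10) {
    coh <- generate_cohort(cohort_config(n_subjects = 40, noise_sd = 0.25,
                                         archetypes = arch, seed = 100 + rep))
    co <- represent_trajectories(coh)
    cm <- cluster_trajectories(co, K = 4, seed = 1)
    truth <- truth_labels(coh)
    ari <- adjusted_rand(cm$assignment, truth)
    set.seed(rep)
    ari_rand <- adjusted_rand(sample(cm$assignment), truth)
    if (ari > ari_rand) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("identical subjects collapse to one cluster in auto mode", {
  tr <- subject_trajectory("s1", (1:8) / 8, c(0, 0, 1, 1, 2, 3, 5, 7))
  trs <- lapply(1:10, function(i) {
    t <- tr; t$subject_id <- paste0("s", i); t
  })
  co <- represent_trajectories(rpe_cohort(trs))
  cm <- cluster_trajectories(co, K = "auto", seed = 2)
  expect_equal(cm$K, 1L)
  expect_equal(unname(cm$sizes), 10L)
})

test_that("duplicating a subject never splits its cluster", {
  coh <- two_archetype_cohort(n_subjects = 40, seed = 33)
  co <- represent_trajectories(coh)
  dup <- rbind(co, dup1 = co["S001", ])
  cm <- cluster_trajectories(dup, K = 2, seed = 4)
  expect_equal(unname(cm$assignment["dup1"]), unname(cm$assignment["S001"]))
})

test_that("assignments are invariant to subject order", {
  coh <- two_archetype_cohort(n_subjects = 30, seed = 34)
  co <- represent_trajectories(coh)
  cm1 <- cluster_trajectories(co, K = 2, seed = 5)
  perm <- rev(seq_len(nrow(co)))
  cm2 <- cluster_trajectories(co[perm, ], K = 2, seed = 5)
  expect_equal(cm2$assignment[rownames(co)], cm1$assignment[rownames(co)])
})

test_that("cluster sizes, labels and guards behave", {
  coh <- two_archetype_cohort(n_subjects = 30, seed = 35)
  co <- represent_trajectories(coh)
  cm <- cluster_trajectories(co, K = 3, seed = 6)
  expect_equal(sum(cm$sizes), 30L)
  expect_true(all(diff(cm$sizes) <= 0))          # ordered by size
  expect_setequal(unique(cm$assignment), seq_len(cm$K))  # compacted labels
  expect_error(cluster_trajectories(co, K = 31), "exceeds")
})

test_that("describe_clusters matches an independent tabulation", {
  coh <- generate_cohort(cohort_config(n_subjects = 24, seed = 36))
  co <- represent_trajectories(coh)
  cm <- cluster_trajectories(co, K = 2, seed = 7)
  dc <- describe_clusters(cm, coh)
  expect_equal(sum(dc$n), 24L)
  # independent counting oracle for cluster 1
  ids1 <- names(cm$assignment)[cm$assignment == 1]
  male1 <- sum(vapply(ids1, function(s)
    identical(coh$trajectories[[s]]$covariates$sex, "male"), logical(1)))
  expect_equal(dc$male[dc$cluster == 1], male1)
  expect_equal(dc$pct_male[dc$cluster == 1], 100 * male1 / length(ids1))
  # single cluster reproduces cohort composition
  cm1 <- cluster_trajectories(co, K = 1, seed = 7)
  dc1 <- describe_clusters(cm1, coh)
  all_male <- sum(vapply(coh$trajectories, function(t)
    identical(t$covariates$sex, "male"), logical(1)))
  expect_equal(dc1$male, all_male)
  expect_equal(dc1$n, 24L)
})

test_that("cluster mean curves evaluate on the basis", {
  coh <- two_archetype_cohort(n_subjects = 20, seed = 37)
  basis <- trajectory_basis()
  co <- represent_trajectories(coh, basis)
  cm <- cluster_trajectories(co, K = 2, seed = 8, basis = basis)
  mc <- cluster_mean_curves(cm, grid = seq(0.1, 1, length.out = 10))
  expect_equal(nrow(mc), 20L)
  expect_setequal(unique(mc$cluster), 1:2)
  expect_true(all(is.finite(mc$mean_rating)))
})
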