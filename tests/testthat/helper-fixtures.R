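# Worked-example curves printed in the source analysis, reused as fixtures.
xs12 <- (1:12) / 12

printed_qd <- list(a = 0.5, b1 = 30.31, b2 = -22.35, c = 0.46)  # plateau QD
printed_pd <- list(a = 0.4, b2 = 16.7, c = 0.40, d = 0.9)       # plateau PD
printed_p  <- list(a = -0.1, b2 = 4.2, d = 4.7)                 # long-delay P

# noiseless trajectory on a model curve (curves may exceed the 0-10 scale
# slightly; fixtures skip the range check)
curve_traj <- function(id, family, params, xs = xs12) {
  subject_trajectory(id, xs, predict_rating(family, params, xs),
                     check_range = FALSE)
}

# well-separated two-archetype cohort: steep linear vs long-delay rise
two_archetype_cohort <- function(n_subjects = 60, noise_sd = 0.2, seed = 21) {
  arch <- list(
    archetype("steep", "D",
              list(a = dist_point(0.3), b1 = dist_point(8),
                   c = dist_point(0.2)), 0.5),
    archetype("delayed", "PD",
              list(a = dist_point(0.3), b2 = dist_point(9),
                   c = dist_point(0.55), d = dist_point(1.2)), 0.5))
  generate_cohort(cohort_config(n_subjects = n_subjects, noise_sd = noise_sd,
                                archetypes = arch, seed = seed))
}

truth_labels <- function(cohort) {
  vapply(cohort$truth, function(t) t$archetype, character(1))
}

# fraction of subjects correctly recovered under the best label mapping
cluster_accuracy <- function(labels, truth) {
  tab <- table(truth, labels)
  sum(apply(tab, 2, max)) / length(labels)
}

# adjusted Rand index (independent of label permutation)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(0)
  (sij - expected) / (maxi - expected)
}
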