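#' Parameter distribution specifications for archetypes
#'
#' Small helpers describing how a single model parameter is drawn when a
#' synthetic subject is generated: a point mass, a uniform range, or a
#' (optionally truncated) normal.
#'
#' @param value,lo,hi,mean,sd Distribution parameters.
#' @return A `param_dist` list.
#' @name param_dist
NULL

#' @rdname param_dist
#' @export
dist_point <- function(value) {
  structure(list(type = "point", value = value), class = "param_dist")
}

#' @rdname param_dist
#' @export
dist_unif <- function(lo, hi) {
  stopifnot(lo <= hi)
  structure(list(type = "unif", lo = lo, hi = hi), class = "param_dist")
}

#' @rdname param_dist
#' @export
dist_norm <- function(mean, sd, lo = -Inf, hi = Inf) {
  stopifnot(sd >= 0, lo < hi)
  structure(list(type = "norm", mean = mean, sd = sd, lo = lo, hi = hi),
            class = "param_dist")
}

draw_param <- function(spec) {
  switch(spec$type,
    point = spec$value,
    unif = stats::runif(1, spec$lo, spec$hi),
    norm = {
      # truncated normal by inverse CDF (exact, one uniform draw)
      plo <- stats::pnorm(spec$lo, spec$mean, spec$sd)
      phi <- stats::pnorm(spec$hi, spec$mean, spec$sd)
      stats::qnorm(stats::runif(1, plo, phi), spec$mean, spec$sd)
    },
    stop("unknown distribution type", call. = FALSE))
}

#' Define a trajectory archetype
#'
#' An archetype is a model family plus per-parameter sampling distributions
#' and a mixing weight; a synthetic cohort is a mixture of archetypes.
#'
#' @param name Label stored as ground truth.
#' @param family Family name (`"P"`, `"D"`, `"PD"`, `"QD"`).
#' @param params Named list of `param_dist` objects (or bare numerics,
#'   treated as point masses) covering the family's parameters.
#' @param weight Non-negative mixing weight (normalized across archetypes).
#' @return An `archetype` list.
#' @export
archetype <- function(name, family, params, weight = 1) {
  family <- as_family(family)
  params <- lapply(params, function(p) {
    if (inherits(p, "param_dist")) p else dist_point(as.numeric(p))
  })
  need <- family$parameter_names
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    stop("archetype '", name, "' missing parameter distributions: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  stopifnot(weight >= 0)
  structure(list(name = name, family = family, params = params,
                 weight = weight), class = "archetype")
}

#' Study-like default archetype suite
#'
#' Five shapes spanning the patterns functional clustering finds in pediatric
#' exertion data: steep and shallow linear rises after a delay, a quadratic
#' rise, a delayed power rise, and a delayed sharp rise that plateaus
#' (negative quadratic curvature).  Delays centre near 40% of Wmax — the
#' typical individual delay in this population — with heterogeneity across
#' subjects.
#'
#' @return List of five `archetype` objects with equal weights.
#' @export
default_archetypes <- function() {
  list(
    archetype("steep_linear", "D",
      list(a = dist_norm(0.3, 0.2, 0, 1),
           b1 = dist_norm(9, 1.5, 5, 14),
           c = dist_norm(0.25, 0.08, 0.18, 0.45)),
      weight = 0.2),
    archetype("shallow_linear", "D",
      list(a = dist_norm(0.3, 0.2, 0, 1),
           b1 = dist_norm(4, 1, 2, 7),
           c = dist_norm(0.35, 0.1, 0.18, 0.6)),
      weight = 0.2),
    archetype("quadratic_rise", "QD",
      list(a = dist_norm(0.3, 0.2, 0, 1),
           b1 = dist_norm(3, 1, 0.5, 6),
           b2 = dist_norm(6, 2, 2, 11),
           c = dist_norm(0.4, 0.1, 0.18, 0.65)),
      weight = 0.2),
    archetype("delayed_power", "PD",
      list(a = dist_norm(0.3, 0.2, 0, 1),
           b2 = dist_norm(9, 2, 4, 14),
           c = dist_norm(0.45, 0.1, 0.18, 0.68),
           d = dist_norm(1.2, 0.3, 0.5, 2.5)),
      weight = 0.2),
    archetype("plateau", "QD",
      list(a = dist_norm(0.4, 0.2, 0, 1),
           b1 = dist_norm(26, 5, 15, 36),
           b2 = dist_norm(-20, 5, -32, -10),
           c = dist_norm(0.45, 0.08, 0.2, 0.65)),
      weight = 0.2)
  )
}

#' Synthetic cohort configuration
#'
#' The generator emulates the structure of pediatric incremental-exercise
#' rating data: per subject an archetype is drawn by weight, model parameters
#' are drawn from the archetype's distributions, the number of 1-minute work
#' increments n_i is uniform over `points_range`, the work grid is equally
#' spaced x_j = j/n_i ending exactly at the individual Wmax (x = 1), and
#' ratings are the family prediction plus N(0, noise_sd^2) noise, optionally
#' clipped to the 0-10 Borg scale and/or snapped to the legal Borg values
#' {0, 0.5, 1, 2, ..., 10}.
#'
#' @param n_subjects Cohort size (default 100).
#' @param points_range Integer range of ratings per subject, default c(6, 12).
#' @param noise_sd Rating-scale residual SD, default 0.3 (typical individual
#'   RMSE for this kind of data sits around 0.25-0.35).
#' @param archetypes List of [archetype()]s; default [default_archetypes()].
#' @param round_to_borg Snap ratings to the legal Borg value set (default
#'   FALSE: the analysis treats ratings as continuous).
#' @param truncate Clip ratings to \[0, 10\] (default TRUE).
#' @param covariate_model List with `p_male`, `age_range`, `p_diagnosis`
#'   (named healthy/asthma/cystic_fibrosis).
#' @param seed RNG seed for archetype/parameter/covariate draws.
#' @param noise_seed RNG seed for the rating noise stream; defaults to
#'   `seed + 1`.  Keeping the streams separate means changing the noise seed
#'   leaves the true parameters unchanged.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 100L, points_range = c(6L, 12L),
                          noise_sd = 0.3, archetypes = default_archetypes(),
                          round_to_borg = FALSE, truncate = TRUE,
                          covariate_model = list(
                            p_male = 0.58, age_range = c(8, 18),
                            p_diagnosis = c(healthy = 0.40, asthma = 0.33,
                                            cystic_fibrosis = 0.27)),
                          seed = 1L, noise_seed = NULL) {
  stopifnot(n_subjects >= 1L, length(points_range) == 2L,
            points_range[1] >= 2L, points_range[1] <= points_range[2],
            noise_sd >= 0, length(archetypes) >= 1L)
  w <- vapply(archetypes, `[[`, numeric(1), "weight")
  if (sum(w) <= 0) stop("archetype weights must sum to > 0", call. = FALSE)
  pd <- covariate_model$p_diagnosis
  stopifnot(abs(sum(pd) - 1) < 1e-6, covariate_model$p_male >= 0,
            covariate_model$p_male <= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 points_range = as.integer(points_range),
                 noise_sd = noise_sd, archetypes = archetypes,
                 round_to_borg = round_to_borg, truncate = truncate,
                 covariate_model = covariate_model,
                 seed = as.integer(seed),
                 noise_seed = as.integer(if (is.null(noise_seed)) seed + 1L else noise_seed)),
            class = "cohort_config")
}

#' Legal Borg category-ratio values
#'
#' The printed anchors of the 0-10 scale: 0, 0.5 ("very, very slight"), then
#' the integers 1 through 10.
#' @return Numeric vector of legal values.
#' @export
borg_levels <- function() c(0, 0.5, 1:10)

snap_to_borg <- function(y) {
  lv <- borg_levels()
  lv[max.col(-abs(outer(y, lv, "-")), ties.method = "first")]
}

# validate a drawn parameter set against family constraints given the x grid
check_drawn_params <- function(family, params, x) {
  if ("c" %in% family$parameter_names) {
    if (params$c <= min(x)) {
      stop(sprintf(
        "archetype produced delay c=%.3f <= min(x)=%.3f; tighten its distribution",
        params$c, min(x)), call. = FALSE)
    }
  }
  if ("d" %in% family$parameter_names && params$d < 0) {
    stop("archetype produced negative exponent", call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a synthetic cohort with stored ground truth
#'
#' @param config A [cohort_config()].
#' @return An `rpe_cohort` whose `truth` element stores, per subject, the
#'   archetype label, family name and true parameters (including the noise
#'   SD), and whose `config` element echoes `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 5, seed = 42))
#' coh$truth[[1]]$family
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  arch <- config$archetypes
  w <- vapply(arch, `[[`, numeric(1), "weight")
  w <- w / sum(w)
  m <- config$n_subjects

  # stream 1: archetypes, parameters, grid sizes, covariates
  set.seed(config$seed)
  arch_idx <- sample.int(length(arch), m, replace = TRUE, prob = w)
  pts <- seq(config$points_range[1], config$points_range[2])
  n_i <- pts[sample.int(length(pts), m, replace = TRUE)]
  subjects <- vector("list", m)
  truth <- vector("list", m)
  cm <- config$covariate_model
  for (i in seq_len(m)) {
    a <- arch[[arch_idx[i]]]
    x <- seq_len(n_i[i]) / n_i[i]
    params <- lapply(a$params, draw_param)
    check_drawn_params(a$family, params, x)
    cov <- list(
      age = round(stats::runif(1, cm$age_range[1], cm$age_range[2])),
      sex = if (stats::runif(1) < cm$p_male) "male" else "female",
      diagnosis = sample(names(cm$p_diagnosis), 1, prob = cm$p_diagnosis))
    subjects[[i]] <- list(x = x, family = a$family, params = params,
                          cov = cov, archetype = a$name)
  }

  # stream 2: rating noise (independent of the parameter stream)
  set.seed(config$noise_seed)
  trajectories <- vector("list", m)
  for (i in seq_len(m)) {
    s <- subjects[[i]]
    mu <- predict_rating(s$family, s$params, s$x)
    y <- mu + stats::rnorm(length(s$x), 0, config$noise_sd)
    if (config$truncate) y <- pmin(pmax(y, 0), 10)
    if (config$round_to_borg) y <- snap_to_borg(y)
    sid <- sprintf("S%03d", i)
    # untruncated cohorts may legitimately exceed the printed scale
    trajectories[[i]] <- subject_trajectory(sid, s$x, y, covariates = s$cov,
                                            check_range = config$truncate)
    truth[[i]] <- list(subject_id = sid, archetype = s$archetype,
                       family = s$family$name, params = s$params,
                       noise_sd = config$noise_sd)
  }
  names(truth) <- vapply(truth, `[[`, character(1), "subject_id")
  rpe_cohort(trajectories, truth = truth, config = config)
}

#' Generate a cohort from a mixed-effects delay model
#'
#' Companion generator for the Bayesian mixed-effects variants: every subject
#' shares the fixed effects, receives a random intercept u_i ~ N(0, tau2)
#' and, for the varying-delay variants, a random delay deviation
#' gamma_i ~ N(0, nu2) truncated so that c_i = c + gamma_i stays inside the
#' subject's observed work-fraction range.
#'
#' @param variant `"MPD"`, `"MQD"`, `"MPDV"` or `"MQDV"`.
#' @param fixed Named list of fixed effects: `a`, `c`, plus `b1`, `b2` for
#'   quadratic variants or `b2`, `d` for power variants.
#' @param sigma2 Residual variance, default 0.25.
#' @param tau2 Random-intercept variance, default 0.3.
#' @param nu2 Random-delay variance (varying variants only), default 0.01.
#' @param n_subjects Cohort size.
#' @param points_range Ratings per subject, default c(6, 12).
#' @param seed RNG seed.
#' @param truncate Clip ratings to \[0, 10\] (default FALSE: recovery
#'   fixtures should not be censored).
#' @return An `rpe_cohort`; `truth` stores the generating parameters and the
#'   per-subject u_i and gamma_i.
#' @export
generate_mixed_cohort <- function(variant = c("MQD", "MPD", "MQDV", "MPDV"),
                                  fixed = list(a = 0.5, b1 = 7, b2 = 5,
                                               d = 1.3, c = 0.35),
                                  sigma2 = 0.25, tau2 = 0.3, nu2 = 0.01,
                                  n_subjects = 30L, points_range = c(6L, 12L),
                                  seed = 1L, truncate = FALSE) {
  variant <- match.arg(variant)
  info <- variant_info(variant)
  stopifnot(sigma2 >= 0, tau2 >= 0, nu2 >= 0, n_subjects >= 2L)
  set.seed(seed)
  pts <- seq(points_range[1], points_range[2])
  n_i <- pts[sample.int(length(pts), n_subjects, replace = TRUE)]
  trajectories <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)
  fam <- if (info$quad) "QD" else "PD"
  for (i in seq_len(n_subjects)) {
    x <- seq_len(n_i[i]) / n_i[i]
    u_i <- stats::rnorm(1, 0, sqrt(tau2))
    g_i <- 0
    if (info$varying && nu2 > 0) {
      # truncated so the subject delay stays inside the observed-x box
      lo <- min(x) - fixed$c; hi <- max(x) - fixed$c
      pl <- stats::pnorm(lo, 0, sqrt(nu2)); ph <- stats::pnorm(hi, 0, sqrt(nu2))
      g_i <- stats::qnorm(stats::runif(1, pl, ph), 0, sqrt(nu2))
    }
    pars <- list(a = fixed$a, b1 = fixed$b1, b2 = fixed$b2, d = fixed$d,
                 c = fixed$c + g_i)
    mu <- predict_rating(fam, pars, x) + u_i
    y <- mu + stats::rnorm(length(x), 0, sqrt(sigma2))
    if (truncate) y <- pmin(pmax(y, 0), 10)
    sid <- sprintf("S%03d", i)
    trajectories[[i]] <- subject_trajectory(sid, x, y, check_range = FALSE)
    truth[[i]] <- list(subject_id = sid, variant = variant, fixed = fixed,
                       sigma2 = sigma2, tau2 = tau2, nu2 = nu2,
                       u = u_i, gamma = g_i)
  }
  names(truth) <- vapply(truth, `[[`, character(1), "subject_id")
  rpe_cohort(trajectories, truth = truth,
             config = list(generator = "mixed", variant = variant,
                           fixed = fixed, sigma2 = sigma2, tau2 = tau2,
                           nu2 = nu2, seed = seed))
}

#' Retain subjects with enough ratings
#'
#' Reliable parameter estimation needs a minimum number of points per
#' trajectory (the canonical filter keeps subjects with at least 6).
#'
#' @param cohort An `rpe_cohort`.
#' @param min_points Minimum observations per subject (>= 2), default 6.
#' @return List with `cohort` (filtered; `NULL` with a warning if everyone is
#'   excluded) and `report`, a data frame of excluded ids, their counts and
#'   the reason.
#' @export
filter_min_points <- function(cohort, min_points = 6L) {
  stopifnot(inherits(cohort, "rpe_cohort"), min_points >= 2L)
  np <- vapply(cohort$trajectories, n_obs, integer(1))
  keep <- np >= min_points
  report <- data.frame(
    subject_id = names(np)[!keep], n_points = unname(np[!keep]),
    reason = rep(sprintf("fewer than %d data points", min_points), sum(!keep)),
    stringsAsFactors = FALSE)
  if (!any(keep)) {
    warning("all subjects excluded by the minimum-points filter")
    return(list(cohort = NULL, report = report))
  }
  filtered <- rpe_cohort(cohort$trajectories[keep],
                         truth = if (!is.null(cohort$truth)) cohort$truth[keep] else NULL,
                         config = cohort$config)
  list(cohort = filtered, report = report)
}

#' Parameter-recovery experiment
#'
#' Validation harness: repeatedly generates cohorts, fits the requested
#' families per subject, and tabulates estimator bias and root-mean-square
#' error against the stored truth (per family and parameter, subjects whose
#' true family matches the fitted one).
#'
#' @param config A [cohort_config()]; its seed is re-derived per replicate.
#' @param families Families to fit (each subject is fitted with its own true
#'   family when that family is listed).
#' @param n_replicates Number of generated cohorts.
#' @param seed Seed controlling the replicate seeds.
#' @param fit_cfg A [fit_config()].
#' @return Data frame: family, parameter, n, bias, rmse, n_failed.
#' @export
recovery_experiment <- function(config, families = c("P", "D", "PD", "QD"),
                                n_replicates = 3L, seed = 1L,
                                fit_cfg = fit_config()) {
  stopifnot(inherits(config, "cohort_config"), n_replicates >= 1L)
  errs <- list()  # per family/param accumulated (estimate - truth)
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer((seed * 1000L + r) %% .Machine$integer.max)
    cfg$noise_seed <- cfg$seed + 1L
    coh <- generate_cohort(cfg)
    for (sid in cohort_ids(coh)) {
      tr <- coh$trajectories[[sid]]
      tru <- coh$truth[[sid]]
      if (!tru$family %in% families) next
      fit <- tryCatch(fit_individual(tr, tru$family, fit_cfg),
                      error = function(e) NULL)
      if (is.null(fit)) { n_failed <- n_failed + 1L; next }
      for (p in fit$family$parameter_names) {
        key <- paste(tru$family, p, sep = ".")
        errs[[key]] <- c(errs[[key]], fit$params[[p]] - tru$params[[p]])
      }
    }
  }
  if (!length(errs)) stop("no subjects matched the requested families", call. = FALSE)
  rows <- lapply(names(errs), function(key) {
    e <- errs[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    data.frame(family = parts[1], parameter = parts[2], n = length(e),
               bias = mean(e), rmse = sqrt(mean(e^2)),
               median_abs_error = stats::median(abs(e)),
               n_failed = n_failed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
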