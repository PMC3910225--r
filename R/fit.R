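#' Configuration for per-subject model fitting
#'
#' The nonlinear least-squares problem for every family is linear in the
#' coefficients (a, b1, b2) once the delay c and/or exponent d are fixed, so
#' fitting profiles the linear coefficients out and optimizes only over the
#' nonlinear parameters under box constraints: the delay must exceed the
#' smallest observed work fraction (enforced as min(x) + `delay_lower_margin`
#' since optimizers need closed boxes) and cannot exceed the largest, and the
#' exponent lies in \[0, `exponent_max`\].  The SSE surface is multimodal in
#' c, hence the multistart grid.
#'
#' @param delay_lower_margin Small positive offset turning the strict bound
#'   c > min(x) into a closed box; default 1e-3 work-fraction units.
#' @param exponent_max Upper bound for the exponent d; default 10.
#' @param n_c_starts,n_d_starts Multistart counts over the c and d boxes
#'   (nested-model warm starts are added on top); defaults 8 and 5.
#' @param max_iterations Optimizer iteration cap per start; default 200.
#' @param tolerance SSE tolerance used for convergence and for breaking ties
#'   between starts (smaller c wins, then smaller d); default 1e-8.
#' @return A `fit_config` list.
#' @export
fit_config <- function(delay_lower_margin = 1e-3, exponent_max = 10,
                       n_c_starts = 8L, n_d_starts = 5L,
                       max_iterations = 200L, tolerance = 1e-8) {
  stopifnot(delay_lower_margin > 0, exponent_max > 1,
            n_c_starts >= 1L, n_d_starts >= 1L,
            max_iterations >= 1L, tolerance > 0)
  structure(list(delay_lower_margin = delay_lower_margin,
                 exponent_max = exponent_max,
                 n_c_starts = as.integer(n_c_starts),
                 n_d_starts = as.integer(n_d_starts),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "fit_config")
}

# design matrix of the linear-coefficient subproblem at fixed (c, d)
design_matrix <- function(family, x, c = NA_real_, d = NA_real_) {
  switch(family$name,
    P  = cbind(1, x^d),
    D  = cbind(1, pmax(x - c, 0)),
    PD = cbind(1, delayed_pow(x, c, d)),
    QD = { z <- pmax(x - c, 0); cbind(1, z, z^2) }
  )
}

# rank-tolerant linear least squares; NA coefficients (dropped columns) -> 0
lin_ls <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  r <- y - drop(X %*% beta)
  list(beta = beta, sse = sum(r^2))
}

# profile SSE at fixed nonlinear parameters; theta named subset of (c, d)
profile_sse <- function(family, x, y, theta) {
  X <- design_matrix(family, x,
                     c = if ("c" %in% names(theta)) theta[["c"]] else NA_real_,
                     d = if ("d" %in% names(theta)) theta[["d"]] else NA_real_)
  lin_ls(X, y)
}

# assemble a full ParamSet from nonlinear params + profiled linear coefs
assemble_params <- function(family, theta, beta) {
  coef_names <- setdiff(family$parameter_names, c("c", "d"))
  params <- as.list(stats::setNames(as.numeric(beta), coef_names))
  for (nm in intersect(family$parameter_names, names(theta))) {
    params[[nm]] <- as.numeric(theta[[nm]])
  }
  params
}

delay_bounds <- function(traj, config) {
  c(min(traj$x) + config$delay_lower_margin, max(traj$x))
}

# multistart set over the nonlinear box, plus nested-model warm starts
start_points <- function(family, traj, config) {
  cb <- delay_bounds(traj, config)
  c_starts <- seq(cb[1], cb[2], length.out = config$n_c_starts + 1L)[-(config$n_c_starts + 1L)]
  d_starts <- unique(c(seq(0.25, config$exponent_max, length.out = config$n_d_starts), 1, 2))
  switch(family$name,
    P  = lapply(d_starts, function(d) c(d = d)),
    D  = lapply(c_starts, function(cc) c(c = cc)),
    QD = lapply(c_starts, function(cc) c(c = cc)),
    PD = {
      grid <- expand.grid(c = c_starts, d = d_starts)
      # d = 1 starts make the nested delay-model solution reachable
      lapply(seq_len(nrow(grid)), function(i) c(c = grid$c[i], d = grid$d[i]))
    }
  )
}

nonlinear_bounds <- function(family, traj, config) {
  cb <- delay_bounds(traj, config)
  switch(family$name,
    P  = list(lower = c(d = 0), upper = c(d = config$exponent_max)),
    D  = ,
    QD = list(lower = c(c = cb[1]), upper = c(c = cb[2])),
    PD = list(lower = c(c = cb[1], d = 0),
              upper = c(c = cb[2], d = config$exponent_max))
  )
}

#' Fit one model family to one subject by profiled multistart least squares
#'
#' Box-constrained quasi-Newton (`optim` L-BFGS-B) over the nonlinear
#' parameters with the linear coefficients solved exactly at every step;
#' the best SSE over all starts wins, with ties (within `tolerance`) broken
#' by smaller delay, then smaller exponent.
#'
#' @param traj A `subject_trajectory` with at least `family$k` observations.
#' @param family A `model_family` or name.
#' @param config A [fit_config()].
#' @return An `individual_fit`: `subject_id`, `family`, `params` (including
#'   the profile-MLE `sigma2`), `criteria` (see [compute_criteria()]),
#'   `converged`, `n_starts_used`.
#' @examples
#' xs <- (1:12) / 12
#' tr <- subject_trajectory("ex", xs,
#'   predict_rating("D", list(a = 0.4, b1 = 7, c = 0.4), xs))
#' fit_individual(tr, "D")$params$c
#' @export
fit_individual <- function(traj, family, config = fit_config()) {
  stopifnot(inherits(traj, "subject_trajectory"))
  family <- as_family(family)
  n <- n_obs(traj)
  if (n < family$k) {
    stop(sprintf("insufficient observations: n=%d < k=%d for family %s",
                 n, family$k, family$name), call. = FALSE)
  }
  x <- traj$x; y <- traj$y
  starts <- start_points(family, traj, config)
  bounds <- nonlinear_bounds(family, traj, config)
  obj <- function(theta) profile_sse(family, x, y, stats::setNames(theta, names(bounds$lower)))$sse

  results <- lapply(starts, function(th0) {
    th0 <- th0[names(bounds$lower)]
    opt <- tryCatch(
      stats::optim(th0, obj, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = config$max_iterations,
                                  factr = config$tolerance / .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(opt)) {
      list(theta = th0, sse = obj(th0), converged = FALSE)
    } else {
      list(theta = stats::setNames(opt$par, names(bounds$lower)),
           sse = opt$value, converged = opt$convergence == 0L)
    }
  })

  sses <- vapply(results, `[[`, numeric(1), "sse")
  tol <- max(config$tolerance, 1e-8 * (1 + min(sses)))
  cand <- which(sses <= min(sses) + tol)
  # tie-break: smaller c, then smaller d
  key_c <- vapply(cand, function(i) {
    th <- results[[i]]$theta
    if ("c" %in% names(th)) th[["c"]] else 0
  }, numeric(1))
  key_d <- vapply(cand, function(i) {
    th <- results[[i]]$theta
    if ("d" %in% names(th)) th[["d"]] else 0
  }, numeric(1))
  best <- cand[order(key_c, key_d)][1L]

  theta <- results[[best]]$theta
  ls <- profile_sse(family, x, y, theta)
  params <- assemble_params(family, theta, ls$beta)
  crit <- compute_criteria(ls$sse, n, family$k)
  params$sigma2 <- crit$sigma2_hat
  structure(list(subject_id = traj$subject_id,
                 family = family,
                 params = params,
                 criteria = crit,
                 converged = any(vapply(results, `[[`, logical(1), "converged")),
                 n_starts_used = length(starts)),
            class = "individual_fit")
}

#' @export
print.individual_fit <- function(x, ...) {
  pv <- x$params[x$family$parameter_names]
  cat(sprintf("<individual_fit> subject %s, family %s: %s | RMSE %.3g%s\n",
              x$subject_id, x$family$name,
              paste(sprintf("%s=%.3g", names(pv), unlist(pv)), collapse = ", "),
              x$criteria$rmse,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Exhaustive grid-search oracle fit
#'
#' Independent verification route for [fit_individual()]: an exhaustive grid
#' over the nonlinear parameter(s) with exact linear least squares for the
#' remaining coefficients at every grid point.  Slower but free of optimizer
#' pathologies; used throughout the test suite as the brute-force oracle.
#'
#' @inheritParams fit_individual
#' @param grid_resolution Number of grid points per nonlinear dimension.
#' @return An `individual_fit` (with `converged = TRUE`, `n_starts_used` =
#'   number of grid points evaluated).
#' @export
grid_oracle_fit <- function(traj, family, grid_resolution = 200L,
                            config = fit_config()) {
  stopifnot(inherits(traj, "subject_trajectory"))
  family <- as_family(family)
  n <- n_obs(traj)
  if (n < family$k) {
    stop(sprintf("insufficient observations: n=%d < k=%d for family %s",
                 n, family$k, family$name), call. = FALSE)
  }
  x <- traj$x; y <- traj$y
  cb <- delay_bounds(traj, config)
  c_grid <- seq(cb[1], cb[2], length.out = grid_resolution)
  d_grid <- seq(0, config$exponent_max, length.out = grid_resolution)
  # closed-form SSE of y ~ 1 + v for a matrix of candidate regressors v
  # (valid at the LS solution: SSE = Syy - a*Sy - b*Svy); rank-deficient
  # columns (v constant) fall back to the intercept-only SSE
  sse_2col <- function(V) {
    n <- length(y); Sy <- sum(y); Syy <- sum(y^2)
    Sv <- colSums(V); Svv <- colSums(V^2); Svy <- colSums(V * y)
    det <- n * Svv - Sv^2
    b <- ifelse(abs(det) > 1e-12, (n * Svy - Sv * Sy) / det, 0)
    a <- (Sy - b * Sv) / n
    pmax(Syy - a * Sy - b * Svy, 0)
  }
  theta <- switch(family$name,
    P = {
      V <- outer(x, d_grid, `^`)
      c(d = d_grid[which.min(sse_2col(V))])
    },
    PD = {
      best <- c(Inf, NA, NA)
      for (cc in c_grid) {
        z <- pmax(x - cc, 0)
        V <- outer(z, d_grid, `^`)
        V[z == 0, ] <- 0  # flat-before-delay convention at the 0^0 corner
        ss <- sse_2col(V)
        i <- which.min(ss)
        if (ss[i] < best[1] - 1e-12) best <- c(ss[i], cc, d_grid[i])
      }
      c(c = best[2], d = best[3])
    },
    { # D and QD: one-dimensional grid over the delay
      sses <- vapply(c_grid, function(cc)
        profile_sse(family, x, y, c(c = cc))$sse, numeric(1))
      c(c = c_grid[which.min(sses)])
    })
  ls <- profile_sse(family, x, y, theta)
  params <- assemble_params(family, theta, ls$beta)
  crit <- compute_criteria(ls$sse, n, family$k)
  params$sigma2 <- crit$sigma2_hat
  n_eval <- switch(family$name, P = length(d_grid),
                   PD = length(c_grid) * length(d_grid), length(c_grid))
  structure(list(subject_id = traj$subject_id, family = family,
                 params = params, criteria = crit,
                 converged = TRUE, n_starts_used = n_eval),
            class = "individual_fit")
}

#' Model-selection criteria from a residual sum of squares
#'
#' RMSE = sqrt(SSE/n); the log-likelihood is the Gaussian profile
#' log-likelihood at sigma2_hat = SSE/n; AIC = 2k - 2 logL;
#' AICc = AIC + 2k(k+1)/(n - k - 1) (the small-sample correction, undefined
#' when n <= k + 1); BIC = k log(n) - 2 logL.  sigma is profiled out and not
#' counted in k (k = 3, 3, 4, 4 for the four families).
#'
#' @param sse Residual sum of squares (>= 0).
#' @param n Number of observations (> 0).
#' @param k Number of estimated coefficients (> 0).
#' @return A `fit_criteria` list: `rmse`, `loglik`, `aic`, `aicc`, `bic`,
#'   `k`, `n`, `sigma2_hat`, plus flags `degenerate` (SSE = 0; criteria are
#'   -Inf sentinels) and `aicc_defined`.
#' @examples
#' compute_criteria(sse = 2.4, n = 8, k = 3)$aicc
#' @export
compute_criteria <- function(sse, n, k) {
  stopifnot(n > 0, k > 0, sse >= 0)
  ll <- gaussian_profile_loglik(sse, n)
  aic <- 2 * k - 2 * ll$loglik
  aicc_defined <- n > k + 1
  aicc <- if (aicc_defined) aic + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  bic <- k * log(n) - 2 * ll$loglik
  structure(list(rmse = sqrt(sse / n), loglik = ll$loglik,
                 aic = aic, aicc = aicc, bic = bic,
                 k = as.integer(k), n = as.integer(n),
                 sigma2_hat = ll$sigma2_hat,
                 degenerate = ll$perfect_fit,
                 aicc_defined = aicc_defined),
            class = "fit_criteria")
}

#' Fit all four families to one subject
#'
#' @inheritParams fit_individual
#' @param families Character vector of family names to fit.
#' @return A `family_comparison`: named list `fits`, plus `best`, a list
#'   naming the minimum-RMSE, minimum-AICc and minimum-BIC family.
#' @export
compare_families <- function(traj, config = fit_config(),
                             families = c("P", "D", "PD", "QD")) {
  fits <- stats::setNames(
    lapply(families, function(f) fit_individual(traj, f, config)), families)
  pick <- function(field) {
    v <- vapply(fits, function(f) {
      val <- f$criteria[[field]]
      if (is.null(val) || is.na(val)) Inf else val
    }, numeric(1))
    names(which.min(v))
  }
  structure(list(fits = fits,
                 best = list(rmse = pick("rmse"), aicc = pick("aicc"),
                             bic = pick("bic"))),
            class = "family_comparison")
}

#' Fit families across a whole cohort
#'
#' @param cohort An `rpe_cohort`.
#' @param families Families to fit to every subject.
#' @param config A [fit_config()].
#' @param min_obs Subjects with fewer observations than a family needs are
#'   skipped for that family (recorded in the table with NA parameters).
#' @return A `cohort_fits` object: `fits` (subject -> family -> fit) and
#'   `table`, a tidy data frame with one row per subject x family.
#' @export
fit_cohort <- function(cohort, families = c("P", "D", "PD", "QD"),
                       config = fit_config()) {
  stopifnot(inherits(cohort, "rpe_cohort"))
  fits <- lapply(cohort$trajectories, function(traj) {
    out <- list()
    for (f in families) {
      out[[f]] <- tryCatch(fit_individual(traj, f, config),
                           error = function(e) NULL)
    }
    out
  })
  structure(list(fits = fits, table = fits_table(fits)),
            class = "cohort_fits")
}

#' @export
print.cohort_fits <- function(x, ...) {
  cat(sprintf("<cohort_fits> %d subjects x {%s}\n", length(x$fits),
              paste(unique(x$table$family), collapse = ", ")))
  invisible(x)
}

# tidy one-row-per-subject-x-family table
fits_table <- function(fits) {
  rows <- list()
  for (sid in names(fits)) {
    for (fam in names(fits[[sid]])) {
      f <- fits[[sid]][[fam]]
      if (is.null(f)) next
      p <- f$params
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, family = fam,
        a = p$a %||% NA_real_, b1 = p$b1 %||% NA_real_,
        b2 = p$b2 %||% NA_real_, c = p$c %||% NA_real_,
        d = p$d %||% NA_real_, sigma2 = p$sigma2 %||% NA_real_,
        rmse = f$criteria$rmse, loglik = f$criteria$loglik,
        aic = f$criteria$aic, aicc = f$criteria$aicc, bic = f$criteria$bic,
        k = f$criteria$k, n = f$criteria$n,
        converged = f$converged, degenerate = f$criteria$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

covariate_group <- function(cohort, group_by) {
  vapply(cohort$trajectories, function(t) {
    cv <- t$covariates
    if (is.null(cv)) return(NA_character_)
    switch(group_by,
      sex = as.character(cv$sex %||% NA_character_),
      diagnosis = as.character(cv$diagnosis %||% NA_character_),
      age_group = if (is.null(cv$age)) NA_character_ else
        if (cv$age < 13) "age<13" else "age>=13",
      stop("group_by must be one of sex, diagnosis, age_group", call. = FALSE))
  }, character(1))
}

#' Median/IQR summaries of fitted parameters and criteria
#'
#' Pools per-subject fits by family and reports median, first and third
#' quartile of every parameter and criterion, plus the per-subject maximal
#' rating when the cohort is supplied — the shape of the classic
#' parameter-summary table for this analysis.
#'
#' @param cohort_fits A `cohort_fits` from [fit_cohort()].
#' @param cohort Optional `rpe_cohort` for maximal-rating summaries and
#'   covariate grouping.
#' @param group_by Optional `"sex"`, `"diagnosis"` or `"age_group"` (<13 vs
#'   >=13); requires `cohort` with covariates.
#' @return Data frame: family, group (if any), quantity, n, median, q1, q3.
#' @export
summarize_fits <- function(cohort_fits, cohort = NULL, group_by = NULL) {
  stopifnot(inherits(cohort_fits, "cohort_fits"))
  tab <- cohort_fits$table
  if (is.null(tab) || nrow(tab) == 0L) stop("no fits to summarize", call. = FALSE)
  if (!is.null(group_by)) {
    if (is.null(cohort)) stop("group_by requires the cohort", call. = FALSE)
    grp <- covariate_group(cohort, group_by)
    tab$group <- grp[tab$subject_id]
  } else {
    tab$group <- "all"
  }
  quantities <- c("a", "b1", "b2", "c", "d", "rmse", "aicc", "bic")
  out <- list()
  for (fam in unique(tab$family)) {
    for (g in unique(tab$group)) {
      sub <- tab[tab$family == fam & tab$group %in% g, , drop = FALSE]
      for (q in quantities) {
        v <- sub[[q]]
        v <- v[is.finite(v)]
        if (!length(v)) next
        qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          family = fam, group = g, quantity = q, n = length(v),
          median = qs[2], q1 = qs[1], q3 = qs[3], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(cohort)) {
    maxr <- vapply(cohort$trajectories, function(t) max(t$y), numeric(1))
    grp <- if (!is.null(group_by)) covariate_group(cohort, group_by) else
      rep("all", length(maxr))
    for (g in unique(grp)) {
      v <- maxr[grp %in% g]
      qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      res <- rbind(res, data.frame(
        family = "(cohort)", group = g, quantity = "max_rating",
        n = length(v), median = qs[2], q1 = qs[1], q3 = qs[3],
        stringsAsFactors = FALSE))
    }
  }
  rownames(res) <- NULL
  res
}

#' Per-subject RMSE differences between families against the estimated delay
#'
#' For each requested family pair A-B, computes RMSE_A - RMSE_B per subject
#' and pairs it with that subject's estimated delay (from `delay_family`,
#' default QD), overlaid with a loess smoother — the classic diagnostic for
#' whether the size of the delay drives the advantage of one family over
#' another.  Subjects whose ratings take fewer than 3 distinct values are
#' excluded (they cannot discriminate the families).
#'
#' @param cohort_fits A `cohort_fits` containing all families involved.
#' @param cohort The `rpe_cohort` the fits came from (for the
#'   distinct-rating-level filter).
#' @param pairs Character vector like `"P-D"`; defaults to the four classic
#'   panels.
#' @param delay_family Family whose delay estimate is used for the x-axis.
#' @param loess_span,loess_degree Smoother settings (span 0.75, degree 1).
#' @return An `rmse_diff` object: `points` (data frame subject_id, pair,
#'   delay, diff), `smoothers` (per pair, data frame delay/fitted or NULL if
#'   too few points), `excluded` (ids dropped by the filter).
#' @export
rmse_difference_analysis <- function(cohort_fits, cohort,
                                     pairs = c("P-D", "P-QD", "QD-D", "PD-QD"),
                                     delay_family = "QD",
                                     loess_span = 0.75, loess_degree = 1) {
  stopifnot(inherits(cohort_fits, "cohort_fits"), inherits(cohort, "rpe_cohort"))
  n_levels <- vapply(cohort$trajectories, function(t) length(unique(t$y)), integer(1))
  keep <- names(n_levels)[n_levels >= 3L]
  excluded <- setdiff(cohort_ids(cohort), keep)
  tab <- cohort_fits$table
  points <- list(); smoothers <- list()
  for (pr in pairs) {
    fams <- strsplit(pr, "-", fixed = TRUE)[[1]]
    if (length(fams) != 2L) stop("pair must look like 'P-D'", call. = FALSE)
    rows <- lapply(keep, function(sid) {
      fA <- tab[tab$subject_id == sid & tab$family == fams[1], , drop = FALSE]
      fB <- tab[tab$subject_id == sid & tab$family == fams[2], , drop = FALSE]
      fC <- tab[tab$subject_id == sid & tab$family == delay_family, , drop = FALSE]
      if (!nrow(fA) || !nrow(fB) || !nrow(fC)) return(NULL)
      data.frame(subject_id = sid, pair = pr, delay = fC$c[1],
                 diff = fA$rmse[1] - fB$rmse[1], stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    points[[pr]] <- df
    if (!is.null(df) && nrow(df) >= 7L) {
      lo <- stats::loess(diff ~ delay, data = df, span = loess_span,
                         degree = loess_degree)
      grid <- seq(min(df$delay), max(df$delay), length.out = 100)
      smoothers[[pr]] <- data.frame(delay = grid,
                                    fitted = stats::predict(lo, newdata = data.frame(delay = grid)))
    } else {
      warning(sprintf("pair %s: too few points for loess, smoother skipped", pr))
      smoothers[pr] <- list(NULL)
    }
  }
  structure(list(points = do.call(rbind, points), smoothers = smoothers,
                 excluded = excluded, delay_family = delay_family),
            class = "rmse_diff")
}

#' @export
print.rmse_diff <- function(x, ...) {
  cat(sprintf("<rmse_diff> pairs {%s}, %d subjects, %d excluded (x-axis: %s delay)\n",
              paste(unique(x$points$pair), collapse = ", "),
              length(unique(x$points$subject_id)), length(x$excluded),
              x$delay_family))
  invisible(x)
}

#' @export
plot.rmse_diff <- function(x, ...) {
  prs <- unique(x$points$pair)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(prs)))
  on.exit(graphics::par(op))
  for (pr in prs) {
    df <- x$points[x$points$pair == pr, ]
    graphics::plot(df$delay, df$diff, xlab = "estimated delay (fraction Wmax)",
                   ylab = "RMSE difference", main = pr, ...)
    graphics::abline(h = 0, lty = 3)
    sm <- x$smoothers[[pr]]
    if (!is.null(sm)) graphics::lines(sm$delay, sm$fitted, col = 2, lwd = 2)
  }
  invisible(x)
}
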