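#' MCMC configuration for the mixed-effects delay models
#'
#' The estimation protocol: several independent chains are run for a fixed
#' convergence run of `n_iterations`, convergence is checked with the
#' Gelman-Rubin potential scale reduction factor (PSRF < `psrf_threshold`
#' for every parameter), then `n_post` further iterations are sampled every
#' `thin` iterations, giving `n_chains * n_post / thin` retained posterior
#' draws (300 under the defaults).  Metropolis proposal SDs are tuned toward
#' a 20-50% acceptance rate during the first half of the convergence run and
#' frozen afterwards.
#'
#' @param n_chains Number of chains (>= 2), default 3.
#' @param n_iterations Convergence-run length, default 10000.
#' @param n_post Post-convergence iterations, default 1000.
#' @param thin Thinning interval (must divide `n_post`), default 10.
#' @param seed Base RNG seed; chain ch uses `seed * 100 + ch`.
#' @param proposal_sd Named list of initial random-walk SDs for `c`, `d` and
#'   the per-subject delay deviations `gamma`.
#' @param prior List of hyperparameters: `beta_var` (variance of the
#'   dispersed Gaussian prior on a, b1, b2), `ig_shape`, `ig_rate`
#'   (inverse-gamma prior on sigma2, tau2, nu2), `d_max` (upper end of the
#'   uniform prior on the exponent).
#' @param psrf_threshold Convergence bound, default 1.2.
#' @param likelihood_weight Multiplier on every likelihood contribution
#'   (default 1); 0 turns the sampler into a prior sampler, used to verify
#'   that the delay's posterior then reproduces its uniform prior.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 3L, n_iterations = 10000L, n_post = 1000L,
                        thin = 10L, seed = 1L,
                        proposal_sd = list(c = 0.05, d = 0.15, gamma = 0.08),
                        prior = list(beta_var = 1000, ig_shape = 0.01,
                                     ig_rate = 0.01, d_max = 10),
                        psrf_threshold = 1.2, likelihood_weight = 1) {
  stopifnot(n_chains >= 2L, n_iterations >= 10L, n_post >= 1L, thin >= 1L,
            n_post %% thin == 0L,
            all(unlist(proposal_sd) > 0),
            likelihood_weight >= 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_post = as.integer(n_post), thin = as.integer(thin),
                 seed = as.integer(seed), proposal_sd = proposal_sd,
                 prior = prior, psrf_threshold = psrf_threshold,
                 likelihood_weight = likelihood_weight),
            class = "mcmc_config")
}

mixed_variants <- c("MPD", "MQD", "MPDV", "MQDV")

variant_info <- function(variant) {
  variant <- match.arg(variant, mixed_variants)
  list(variant = variant,
       quad = variant %in% c("MQD", "MQDV"),
       varying = variant %in% c("MPDV", "MQDV"))
}

# flatten a cohort for the sampler
prep_mixed_data <- function(cohort) {
  stopifnot(inherits(cohort, "rpe_cohort"))
  trs <- cohort$trajectories
  if (length(trs) < 2L) stop("need at least 2 subjects", call. = FALSE)
  y <- unlist(lapply(trs, `[[`, "y"), use.names = FALSE)
  x <- unlist(lapply(trs, `[[`, "x"), use.names = FALSE)
  n_i <- vapply(trs, n_obs, integer(1))
  id <- rep(seq_along(trs), n_i)
  list(y = y, x = x, id = id, n_i = n_i, m = length(trs), N = length(y),
       ids = names(trs),
       xmin_i = vapply(trs, function(t) min(t$x), numeric(1)),
       xmax_i = vapply(trs, function(t) max(t$x), numeric(1)),
       xmin = min(x), xmax = max(x))
}

# mean structure design matrix; cvec is scalar (fixed delay) or length-m
mixed_design <- function(dat, info, cvec, d = NA_real_) {
  cs <- if (length(cvec) == 1L) cvec else cvec[dat$id]
  z <- pmax(dat$x - cs, 0)
  if (info$quad) {
    cbind(1, z, z * z)
  } else {
    v <- numeric(length(z)); pos <- z > 0
    v[pos] <- z[pos]^d
    cbind(1, v)
  }
}

# log N(r | X beta, s2 I) with beta integrated out under N(0, v0 I);
# matrix determinant lemma keeps everything p x p (p <= 3)
beta_marginal_loglik <- function(X, r, s2, v0) {
  p <- ncol(X); N <- length(r)
  A <- crossprod(X) + diag(s2 / v0, p)
  cA <- chol(A)
  quad <- sum(backsolve(cA, crossprod(X, r), transpose = TRUE)^2)
  logdet <- 2 * sum(log(diag(cA))) - p * log(s2 / v0)
  -N / 2 * log(2 * pi * s2) - logdet / 2 - (sum(r * r) - quad) / (2 * s2)
}

rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1, shape = shape, rate = rate)

# single chain of the Gibbs-within-Metropolis sampler
run_mixed_chain <- function(dat, info, config, chain_seed) {
  set.seed(chain_seed)
  w <- config$likelihood_weight
  v0 <- config$prior$beta_var
  a0 <- config$prior$ig_shape; b0 <- config$prior$ig_rate
  d_max <- config$prior$d_max
  m <- dat$m; N <- dat$N; id <- dat$id; y <- dat$y
  p <- if (info$quad) 3L else 2L
  beta_names <- if (info$quad) c("a", "b1", "b2") else c("a", "b2")

  # initial state
  cc <- stats::median(dat$x)
  d <- 1
  u <- numeric(m); gam <- numeric(m)
  sigma2 <- max(stats::var(y) / 4, 0.05); tau2 <- 0.5; nu2 <- 0.01
  beta <- numeric(p)
  sd_c <- config$proposal_sd$c
  sd_d <- config$proposal_sd$d
  sd_g <- config$proposal_sd$gamma

  par_names <- c(beta_names, "c",
                 if (!info$quad) "d",
                 "sigma2", "tau2",
                 if (info$varying) "nu2",
                 paste0("u.", dat$ids),
                 if (info$varying) paste0("gamma.", dat$ids))
  n_keep <- config$n_post %/% config$thin
  trace <- matrix(NA_real_, config$n_iterations, length(par_names),
                  dimnames = list(NULL, par_names))
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  acc <- c(c = 0, d = 0, gamma = 0); prop <- c(c = 0, d = 0, gamma = 0)
  adapt_until <- config$n_iterations %/% 2L
  kept <- 0L

  cvec_of <- function(cc) if (info$varying) cc + gam else cc
  total_iter <- config$n_iterations + config$n_post

  for (it in seq_len(total_iter)) {
    X <- mixed_design(dat, info, cvec_of(cc), d)

    ## beta | rest (conjugate Gaussian)
    r <- y - u[id]
    A <- w * crossprod(X) / sigma2 + diag(1 / v0, p)
    cA <- chol(A)
    mu <- backsolve(cA, backsolve(cA, w * crossprod(X, r) / sigma2,
                                  transpose = TRUE))
    beta <- drop(mu + backsolve(cA, stats::rnorm(p)))
    fitted <- drop(X %*% beta)

    ## u_i | rest (conjugate Gaussian)
    res <- y - fitted
    prec <- w * dat$n_i / sigma2 + 1 / tau2
    mean_u <- (w * drop(rowsum(res, id)) / sigma2) / prec
    u <- stats::rnorm(m, mean_u, sqrt(1 / prec))

    ## sigma2 | rest (conjugate inverse gamma)
    sse <- sum((res - u[id])^2)
    sigma2 <- rinvgamma1(a0 + w * N / 2, b0 + w * sse / 2)

    ## tau2 | rest
    tau2 <- rinvgamma1(a0 + m / 2, b0 + sum(u * u) / 2)

    ## delay c: random-walk Metropolis, beta collapsed
    r <- y - u[id]
    if (info$varying) {
      # recentring Gibbs move: shift c by delta ~ N(mean(gamma), nu2/m)
      # truncated to the observed-x box; every c_i = c + gamma_i unchanged
      lo <- dat$xmin - cc; hi <- dat$xmax - cc
      mu_d <- mean(gam); sd_dlt <- sqrt(nu2 / m)
      pl <- stats::pnorm(lo, mu_d, sd_dlt); ph <- stats::pnorm(hi, mu_d, sd_dlt)
      if (ph > pl) {
        delta <- stats::qnorm(stats::runif(1, pl, ph), mu_d, sd_dlt)
        cc <- cc + delta; gam <- gam - delta
      }
      ## gamma_i: per-subject random-walk Metropolis (truncated normal prior
      ## handled by rejecting proposals outside the subject's observed-x box)
      Xb_cur <- fitted_for <- NULL
      cur_c <- cc + gam
      z <- pmax(dat$x - cur_c[id], 0)
      mu_all <- if (info$quad) beta[1] + beta[2] * z + beta[3] * z * z else {
        v <- numeric(N); posz <- z > 0; v[posz] <- z[posz]^d
        beta[1] + beta[2] * v
      }
      gam_new <- gam + stats::rnorm(m, 0, sd_g)
      prop["gamma"] <- prop["gamma"] + m
      for (i in seq_len(m)) {
        ci_new <- cc + gam_new[i]
        if (ci_new < dat$xmin_i[i] || ci_new > dat$xmax_i[i]) next
        rows <- which(id == i)
        zi <- pmax(dat$x[rows] - ci_new, 0)
        mui_new <- if (info$quad) beta[1] + beta[2] * zi + beta[3] * zi * zi else {
          vi <- numeric(length(zi)); posi <- zi > 0; vi[posi] <- zi[posi]^d
          beta[1] + beta[2] * vi
        }
        ll_new <- -w * sum((r[rows] - mui_new)^2) / (2 * sigma2) -
          gam_new[i]^2 / (2 * nu2)
        ll_old <- -w * sum((r[rows] - mu_all[rows])^2) / (2 * sigma2) -
          gam[i]^2 / (2 * nu2)
        if (log(stats::runif(1)) < ll_new - ll_old) {
          gam[i] <- gam_new[i]
          acc["gamma"] <- acc["gamma"] + 1
        }
      }
      ## nu2 | rest
      nu2 <- rinvgamma1(a0 + m / 2, b0 + sum(gam * gam) / 2)
    } else {
      cc_new <- cc + stats::rnorm(1, 0, sd_c)
      prop["c"] <- prop["c"] + 1
      if (cc_new >= dat$xmin && cc_new <= dat$xmax) {
        lr <- if (w == 0) 0 else  # prior-only mode: uniform within the box
          w * (beta_marginal_loglik(mixed_design(dat, info, cc_new, d), r, sigma2, v0) -
               beta_marginal_loglik(mixed_design(dat, info, cc, d), r, sigma2, v0))
        if (log(stats::runif(1)) < lr) {
          cc <- cc_new; acc["c"] <- acc["c"] + 1
        }
      }
    }

    ## exponent d (power-family variants): collapsed random-walk Metropolis
    if (!info$quad) {
      d_new <- d + stats::rnorm(1, 0, sd_d)
      prop["d"] <- prop["d"] + 1
      if (d_new > 0 && d_new <= d_max) {
        lr <- if (w == 0) 0 else
          w * (beta_marginal_loglik(mixed_design(dat, info, cvec_of(cc), d_new), r, sigma2, v0) -
               beta_marginal_loglik(mixed_design(dat, info, cvec_of(cc), d), r, sigma2, v0))
        if (log(stats::runif(1)) < lr) {
          d <- d_new; acc["d"] <- acc["d"] + 1
        }
      }
    }

    ## proposal adaptation during the first half of the convergence run
    if (it <= adapt_until && it %% 100L == 0L) {
      tune <- function(sd, a, np) {
        if (np == 0) return(sd)
        rate <- a / np
        if (rate < 0.2) sd * 0.7 else if (rate > 0.5) sd * 1.4 else sd
      }
      sd_c <- tune(sd_c, acc["c"], prop["c"])
      sd_d <- tune(sd_d, acc["d"], prop["d"])
      sd_g <- tune(sd_g, acc["gamma"], prop["gamma"])
      acc[] <- 0; prop[] <- 0
    }

    state <- c(beta, cc, if (!info$quad) d, sigma2, tau2,
               if (info$varying) nu2, u, if (info$varying) gam)
    if (it <= config$n_iterations) {
      trace[it, ] <- state
    } else if ((it - config$n_iterations) %% config$thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- state
    }
  }

  list(trace = trace, draws = draws,
       acceptance = ifelse(prop > 0, acc / prop, NA_real_),
       proposal_sd = c(c = sd_c, d = sd_d, gamma = sd_g))
}

#' Fit a Bayesian mixed-effects delay model
#'
#' Four variants of the nonlinear mixed-effects model for pooled exertion
#' trajectories, all with a subject random intercept u_i ~ N(0, tau2) and
#' residual eps ~ N(0, sigma2):
#' \describe{
#'   \item{MQD}{y_ij = a + b1 max(x-c,0) + b2 max(x-c,0)^2 + u_i + eps, common delay}
#'   \item{MPD}{y_ij = a + b2 max(x-c,0)^d + u_i + eps, common delay}
#'   \item{MQDV/MPDV}{same mean structures with subject delays c_i = c + gamma_i,
#'     gamma_i ~ N(0, nu2), c_i constrained to the subject's observed-x range}
#' }
#' Estimation is Gibbs-within-Metropolis: conjugate Gaussian updates for the
#' coefficients and random intercepts, conjugate inverse-gamma updates for
#' the variances, and random-walk Metropolis for c, d and each gamma_i (the
#' delay moves integrate the coefficients out analytically for better
#' mixing).  Priors are dispersed: N(0, 1000) coefficients,
#' IG(0.01, 0.01) variances, uniform c over the observed-x range, uniform d
#' on (0, 10].
#'
#' @param cohort An `rpe_cohort` with >= 2 subjects.
#' @param variant `"MPD"`, `"MQD"`, `"MPDV"` or `"MQDV"`.
#' @param config An [mcmc_config()].
#' @return A `mixed_fit`: `samples` (retained draws, pooled across chains),
#'   `chain_draws`, `traces` (convergence-run traces per chain), `psrf`
#'   (per parameter), `max_psrf`, `converged`, `dic`, `pD`,
#'   `acceptance`, `posterior_summary`, `variant`, `config`, `data`.
#' @export
fit_mixed <- function(cohort, variant = c("MQD", "MPD", "MQDV", "MPDV"),
                      config = mcmc_config()) {
  variant <- match.arg(variant)
  info <- variant_info(variant)
  stopifnot(inherits(config, "mcmc_config"))
  dat <- prep_mixed_data(cohort)
  chains <- lapply(seq_len(config$n_chains), function(ch) {
    run_mixed_chain(dat, info, config, chain_seed = config$seed * 100L + ch)
  })
  traces <- lapply(chains, `[[`, "trace")
  psrf_vals <- psrf(traces)
  max_psrf <- max(psrf_vals, na.rm = TRUE)
  converged <- is.finite(max_psrf) && max_psrf < config$psrf_threshold
  if (!converged) {
    warning(sprintf("PSRF %.3f above threshold %.2f: chains not converged",
                    max_psrf, config$psrf_threshold))
  }
  samples <- do.call(rbind, lapply(chains, `[[`, "draws"))
  res <- structure(list(variant = variant, samples = samples,
                        chain_draws = lapply(chains, `[[`, "draws"),
                        traces = traces, psrf = psrf_vals,
                        max_psrf = max_psrf, converged = converged,
                        acceptance = lapply(chains, `[[`, "acceptance"),
                        config = config, data = dat, info = info),
                   class = "mixed_fit")
  if (nrow(samples) < 30L) warning("fewer than 30 retained draws: DIC unstable")
  d <- dic(res)
  res$dic <- d$dic; res$pD <- d$pD
  res$posterior_summary <- summarize_posterior(res)
  res
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit> %s: %d retained draws (%d chains), max PSRF %.3f%s, DIC %.1f (pD %.1f)\n",
              x$variant, nrow(x$samples), x$config$n_chains, x$max_psrf,
              if (x$converged) "" else " [NOT CONVERGED]", x$dic, x$pD))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF computed on the second half of each chain: with m chains of
#' (halved) length n, W the mean within-chain variance and B the
#' between-chain variance of the chain means scaled by n,
#' R = sqrt(((n-1)/n W + B/n) / W).  If every chain has zero within-chain
#' variance, R is 1 when the chains are identical and Inf otherwise.
#'
#' @param chains List (one element per chain) of equal-length numeric vectors
#'   or of matrices with identical column names (one column per parameter).
#' @return Named numeric vector of R values (scalar for vector input).
#' @export
psrf <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 2L)
  if (is.matrix(chains[[1]])) {
    cols <- colnames(chains[[1]])
    out <- vapply(seq_len(ncol(chains[[1]])), function(j) {
      psrf(lapply(chains, function(ch) ch[, j]))
    }, numeric(1))
    names(out) <- cols
    return(out)
  }
  len <- unique(vapply(chains, length, integer(1)))
  if (length(len) != 1L || len < 10L) {
    stop("chains must have equal length >= 10", call. = FALSE)
  }
  half <- lapply(chains, function(v) v[(length(v) %/% 2L + 1L):length(v)])
  n <- length(half[[1]]); m <- length(half)
  if (all(vapply(half, function(v) isTRUE(all.equal(v, half[[1]])),
                 logical(1)))) {
    return(1)  # degenerate: identical chains carry no between-chain signal
  }
  if (!all(vapply(half, function(v) all(is.finite(v)), logical(1)))) {
    return(NA_real_)  # heavy-tailed prior draws can overflow; no diagnosis
  }
  means <- vapply(half, mean, numeric(1))
  vars <- vapply(half, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= .Machine$double.eps) {
    identical_chains <- all(vapply(half, function(v)
      isTRUE(all.equal(v, half[[1]])), logical(1)))
    return(if (identical_chains) 1 else Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

# complete-data deviance at one parameter state
complete_deviance <- function(state, dat, info, conditional = FALSE) {
  beta <- if (info$quad) state[c("a", "b1", "b2")] else state[c("a", "b2")]
  cc <- state[["c"]]
  d <- if (!info$quad) state[["d"]] else NA_real_
  u <- state[paste0("u.", dat$ids)]
  gam <- if (info$varying) state[paste0("gamma.", dat$ids)] else NULL
  sigma2 <- state[["sigma2"]]; tau2 <- state[["tau2"]]
  cvec <- if (info$varying) cc + gam else cc
  X <- mixed_design(dat, info, cvec, d)
  mu <- drop(X %*% beta) + u[dat$id]
  ll <- sum(stats::dnorm(dat$y, mu, sqrt(sigma2), log = TRUE))
  if (!conditional) {
    ll <- ll + sum(stats::dnorm(u, 0, sqrt(tau2), log = TRUE))
    if (info$varying) {
      ll <- ll + sum(stats::dnorm(gam, 0, sqrt(state[["nu2"]]), log = TRUE))
    }
  }
  -2 * ll
}

#' Deviance information criterion from the complete likelihood
#'
#' DIC = 2 * mean(D(theta)) - D(theta_bar), where D is the complete-data
#' deviance (data likelihood plus the random-effect densities for u_i and,
#' for varying-delay variants, gamma_i) and theta_bar plugs in the posterior
#' means of all parameters and random effects.  `conditional = TRUE` drops
#' the random-effect density terms (conditional-likelihood DIC).  Smaller
#' values indicate better predictive ability.
#'
#' @param result A `mixed_fit`.
#' @param conditional Use the conditional likelihood instead (default FALSE).
#' @return List with `dic`, `pD` (effective number of parameters),
#'   `mean_deviance`, `deviance_at_mean`.
#' @export
dic <- function(result, conditional = FALSE) {
  stopifnot(inherits(result, "mixed_fit"))
  draws <- result$samples
  if (nrow(draws) < 30L) warning("fewer than 30 draws: DIC unstable")
  devs <- apply(draws, 1L, complete_deviance, dat = result$data,
                info = result$info, conditional = conditional)
  dbar <- mean(devs)
  dhat <- complete_deviance(colMeans(draws), result$data, result$info,
                            conditional = conditional)
  list(dic = 2 * dbar - dhat, pD = dbar - dhat,
       mean_deviance = dbar, deviance_at_mean = dhat)
}

#' Write retained draws as tidy CSV
#'
#' One row per (chain, iteration, parameter): the long format downstream
#' tools expect for posterior draws.
#'
#' @param result A `mixed_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(result, path) {
  stopifnot(inherits(result, "mixed_fit"))
  rows <- lapply(seq_along(result$chain_draws), function(ch) {
    d <- result$chain_draws[[ch]]
    data.frame(chain = ch,
               iteration = rep(seq_len(nrow(d)), times = ncol(d)),
               parameter = rep(colnames(d), each = nrow(d)),
               value = as.vector(d), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Posterior mean and central 95% interval per parameter
#'
#' @param result A `mixed_fit`.
#' @param include_random Include per-subject random effects (default FALSE:
#'   only the fixed effects and variance components, the shape of the
#'   classic posterior-summary table).
#' @return Data frame: parameter, mean, q2.5, q97.5.
#' @export
summarize_posterior <- function(result, include_random = FALSE) {
  stopifnot(inherits(result, "mixed_fit"))
  draws <- result$samples
  if (nrow(draws) == 0L) stop("no retained draws", call. = FALSE)
  keep <- colnames(draws)
  if (!include_random) keep <- keep[!grepl("^(u|gamma)\\.", keep)]
  out <- lapply(keep, function(p) {
    v <- draws[, p]
    qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = p, mean = mean(v), q2.5 = qs[1], q97.5 = qs[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
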