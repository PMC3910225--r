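#' B-spline basis for trajectory representation
#'
#' Trajectories live on work fractions in \[0, 1\] (x is normalized to each
#' subject's own Wmax), so one common basis makes per-subject coefficient
#' vectors comparable across subjects.
#'
#' @param order Spline order (4 = cubic), default 4.
#' @param n_interior_knots Equally spaced interior knots on (0, 1), default 5.
#' @return A `trajectory_basis` with the full (replicated-boundary) knot
#'   vector and dimension `order + n_interior_knots`.
#' @export
trajectory_basis <- function(order = 4L, n_interior_knots = 5L) {
  stopifnot(order >= 2L, n_interior_knots >= 0L)
  interior <- if (n_interior_knots > 0)
    seq(0, 1, length.out = n_interior_knots + 2L)[-c(1L, n_interior_knots + 2L)]
  else numeric(0)
  knots <- c(rep(0, order), interior, rep(1, order))
  structure(list(order = as.integer(order), interior = interior,
                 knots = knots,
                 dim = as.integer(order + n_interior_knots)),
            class = "trajectory_basis")
}

basis_eval <- function(basis, x) {
  # splineDesign requires x within the knot span; x in (0,1] by construction
  splines::splineDesign(basis$knots, x, ord = basis$order,
                        outer.ok = FALSE)
}

#' Project trajectories onto a common B-spline basis
#'
#' Penalized least-squares projection of each subject's (x, y) pairs onto
#' the basis.  The penalty is `ridge` times the squared second difference of
#' the coefficient vector (plus a vanishing pure-ridge term for rank
#' safety): it leaves constants and straight lines untouched, keeps short
#' trajectories (fewer points than basis dimension) well-posed, and makes
#' coefficients comparable across subjects with different grid sizes.
#'
#' @param cohort An `rpe_cohort`.
#' @param basis A [trajectory_basis()].
#' @param ridge Smoothness penalty weight, default 1e-4.
#' @return Matrix (subjects x basis dimension), rownames = subject ids.
#' @export
represent_trajectories <- function(cohort, basis = trajectory_basis(),
                                   ridge = 1e-4) {
  stopifnot(inherits(cohort, "rpe_cohort"), inherits(basis, "trajectory_basis"),
            ridge >= 0)
  D2 <- diff(diag(basis$dim), differences = 2L)
  P <- ridge * crossprod(D2) + diag(1e-10, basis$dim)
  out <- t(vapply(cohort$trajectories, function(tr) {
    if (n_obs(tr) < 2L) stop("subject ", tr$subject_id, " has fewer than 2 points",
                             call. = FALSE)
    B <- basis_eval(basis, tr$x)
    drop(solve(crossprod(B) + P, crossprod(B, tr$y)))
  }, numeric(basis$dim)))
  rownames(out) <- cohort_ids(cohort)
  out
}

## ---- Gaussian-mixture EM (diagonal or full covariance) ----
## small self-contained implementation: the environment offers no mixture
## package, and the clustering needs deterministic seeding + BIC selection

gmm_loglik_matrix <- function(X, means, vars, weights, full) {
  n <- nrow(X); K <- length(weights)
  ll <- matrix(0, n, K)
  for (k in seq_len(K)) {
    if (full) {
      S <- vars[[k]]
      cS <- chol(S)
      dev <- forwardsolve(t(cS), t(X) - means[k, ])
      ll[, k] <- -0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(cS))) +
                           colSums(dev^2))
    } else {
      v <- vars[[k]]
      ll[, k] <- -0.5 * colSums((t(X) - means[k, ])^2 / v) -
        0.5 * sum(log(2 * pi * v))
    }
    ll[, k] <- ll[, k] + log(weights[k])
  }
  ll
}

fit_gmm <- function(X, K, full = FALSE, seed = 1L, max_iter = 200L,
                    tol = 1e-8, var_floor = 1e-3) {
  n <- nrow(X); p <- ncol(X)
  set.seed(seed)
  if (K == 1L) {
    centers <- matrix(colMeans(X), 1L)
    assign0 <- rep(1L, n)
  } else {
    km <- tryCatch(stats::kmeans(X, centers = K, nstart = 10L, iter.max = 50L),
                   error = function(e) NULL)
    if (is.null(km)) { # fewer distinct points than centers
      return(NULL)
    }
    centers <- km$centers
    assign0 <- km$cluster
  }
  weights <- tabulate(assign0, K) / n
  means <- centers
  vars <- lapply(seq_len(K), function(k) {
    Xi <- X[assign0 == k, , drop = FALSE]
    if (full) {
      S <- if (nrow(Xi) > p) stats::cov(Xi) else diag(stats::var(as.vector(X)), p)
      S + diag(var_floor, p)
    } else {
      v <- if (nrow(Xi) > 1) apply(Xi, 2, stats::var) else rep(stats::var(as.vector(X)), p)
      pmax(v, var_floor)
    }
  })
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    lmat <- tryCatch(gmm_loglik_matrix(X, means, vars, weights, full),
                     error = function(e) NULL)
    if (is.null(lmat)) return(NULL)
    mx <- apply(lmat, 1, max)
    pr <- exp(lmat - mx)
    rowsum_pr <- rowSums(pr)
    resp <- pr / rowsum_pr
    ll <- sum(mx + log(rowsum_pr))
    nk <- colSums(resp)
    if (any(nk < 1e-8)) break # empty component; keep previous estimates
    weights <- nk / n
    means <- t(resp) %*% X / nk
    for (k in seq_len(K)) {
      dev <- sweep(X, 2, means[k, ])
      if (full) {
        S <- crossprod(dev * sqrt(resp[, k])) / nk[k]
        vars[[k]] <- S + diag(var_floor, p)
      } else {
        vars[[k]] <- pmax(colSums(dev^2 * resp[, k]) / nk[k], var_floor)
      }
    }
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) { ll_old <- ll; break }
    ll_old <- ll
  }
  npar <- (K - 1) + K * p + if (full) K * p * (p + 1) / 2 else K * p
  list(K = K, weights = weights, means = means, vars = vars,
       loglik = ll_old, resp = resp, bic = -2 * ll_old + npar * log(n),
       full = full)
}

#' Cluster trajectory coefficients with a Gaussian mixture
#'
#' Functional clustering: subjects are represented by their B-spline
#' coefficient vectors ([represent_trajectories()]) and grouped by a
#' Gaussian-mixture model fitted by EM.  `K = "auto"` selects the number of
#' clusters in 1..12 by BIC.  Labels are relabelled in order of decreasing
#' cluster size, empty clusters are compacted away, and the whole procedure
#' is deterministic given `seed`.
#'
#' @param coefficients Subjects x dimension coefficient matrix (rownames =
#'   subject ids), e.g. from [represent_trajectories()].
#' @param K Integer number of clusters, or `"auto"`.
#' @param covariance `"diagonal"` (default) or `"full"`; a singular full
#'   covariance falls back to diagonal with a warning.
#' @param seed Seed for the deterministic k-means initialization.
#' @param basis Optional `trajectory_basis` stored in the model (for mean
#'   curves).
#' @return A `cluster_model`: `K`, `cluster_means` (K x dim), `weights`,
#'   `assignment_probabilities`, `assignment` (named integer labels),
#'   `sizes`, `bic`, `bic_by_k`, `basis`.
#' @export
cluster_trajectories <- function(coefficients, K = "auto",
                                 covariance = c("diagonal", "full"),
                                 seed = 1L, basis = NULL) {
  covariance <- match.arg(covariance)
  X <- as.matrix(coefficients)
  n <- nrow(X)
  if (n < 1L) stop("no subjects", call. = FALSE)
  full <- covariance == "full"
  n_distinct <- nrow(unique(X))
  fit_one <- function(k) {
    f <- if (full) {
      ff <- tryCatch(fit_gmm(X, k, full = TRUE, seed = seed),
                     error = function(e) NULL)
      if (is.null(ff)) {
        warning("singular full covariance: falling back to diagonal")
        fit_gmm(X, k, full = FALSE, seed = seed)
      } else ff
    } else {
      fit_gmm(X, k, full = FALSE, seed = seed)
    }
    f
  }
  if (identical(K, "auto")) {
    kmax <- min(12L, n_distinct)
    fits <- list(); bics <- c(); admissible <- c()
    for (k in seq_len(kmax)) {
      f <- fit_one(k)
      if (is.null(f)) next
      fits[[as.character(k)]] <- f
      bics[as.character(k)] <- f$bic
      # a hard-assigned singleton is an outlier, not a pattern group; such
      # solutions are recorded but not selected in auto mode
      hard_sizes <- tabulate(max.col(f$resp, ties.method = "first"), f$K)
      admissible[as.character(k)] <- all(hard_sizes[hard_sizes > 0] >= 2L) || f$K == 1L
    }
    if (!length(fits)) stop("no mixture could be fitted", call. = FALSE)
    pool <- if (any(admissible)) bics[admissible] else bics
    best <- fits[[names(which.min(pool))]]
    bic_by_k <- bics
  } else {
    K <- as.integer(K)
    if (K > n) stop("K exceeds the number of subjects", call. = FALSE)
    if (K > n_distinct) stop("K exceeds the number of distinct subjects", call. = FALSE)
    best <- fit_one(K)
    if (is.null(best)) stop("mixture fit failed", call. = FALSE)
    bic_by_k <- stats::setNames(best$bic, as.character(K))
  }
  hard <- max.col(best$resp, ties.method = "first")
  # drop empty clusters, then order labels by decreasing size
  sizes0 <- tabulate(hard, best$K)
  keep <- which(sizes0 > 0L)
  remap <- stats::setNames(rank(-sizes0[keep], ties.method = "first"),
                           keep)
  labels <- as.integer(remap[as.character(hard)])
  ord <- order(remap)
  means <- best$means[keep[ord], , drop = FALSE]
  resp <- best$resp[, keep[ord], drop = FALSE]
  weights <- best$weights[keep[ord]]
  names(labels) <- rownames(X)
  structure(list(K = length(keep), cluster_means = means, weights = weights,
                 assignment_probabilities = resp, assignment = labels,
                 sizes = tabulate(labels, length(keep)), bic = best$bic,
                 bic_by_k = bic_by_k, covariance = covariance,
                 basis = basis),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K=%d (%s covariance), sizes: %s, BIC %.1f\n",
              x$K, x$covariance, paste(x$sizes, collapse = "/"), x$bic))
  invisible(x)
}

#' Cluster mean curves on a grid
#'
#' @param model A `cluster_model` carrying a basis.
#' @param grid Work fractions to evaluate on, default 100 points in (0, 1\].
#' @return Data frame: cluster, x, mean_rating.
#' @export
cluster_mean_curves <- function(model, grid = seq(0.01, 1, length.out = 100)) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(model$basis)) stop("model carries no basis", call. = FALSE)
  B <- basis_eval(model$basis, grid)
  out <- lapply(seq_len(model$K), function(k) {
    data.frame(cluster = k, x = grid,
               mean_rating = drop(B %*% model$cluster_means[k, ]))
  })
  do.call(rbind, out)
}

#' Cluster composition by covariates
#'
#' Per-cluster counts and percentages of male sex, age < 13, and each
#' diagnosis — the classic cluster-membership description table.
#' Percentages are computed over subjects with a non-missing covariate (a
#' footnote attribute records when that happened).
#'
#' @param model A `cluster_model` (or named integer vector of labels).
#' @param cohort The `rpe_cohort` carrying covariates for the same subjects.
#' @return Data frame with one row per cluster: n, male, pct_male, age_lt_13,
#'   pct_age_lt_13, and count/pct per diagnosis.
#' @export
describe_clusters <- function(model, cohort) {
  labels <- if (inherits(model, "cluster_model")) model$assignment else model
  stopifnot(inherits(cohort, "rpe_cohort"))
  ids <- names(labels)
  if (!all(ids %in% cohort_ids(cohort))) {
    stop("assignment and cohort cover different subjects", call. = FALSE)
  }
  get_cov <- function(sid, field) {
    v <- cohort$trajectories[[sid]]$covariates[[field]]
    if (is.null(v)) NA else v
  }
  sex <- vapply(ids, function(s) as.character(get_cov(s, "sex")), character(1))
  age <- vapply(ids, function(s) as.numeric(get_cov(s, "age")), numeric(1))
  dia <- vapply(ids, function(s) as.character(get_cov(s, "diagnosis")), character(1))
  missing_any <- anyNA(sex) || anyNA(age) || anyNA(dia)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  rows <- lapply(sort(unique(labels)), function(k) {
    in_k <- labels == k
    sx <- sex[in_k]; ag <- age[in_k]; dg <- dia[in_k]
    data.frame(
      cluster = k, n = sum(in_k),
      male = sum(sx == "male", na.rm = TRUE),
      pct_male = pct(sum(sx == "male", na.rm = TRUE), sum(!is.na(sx))),
      age_lt_13 = sum(ag < 13, na.rm = TRUE),
      pct_age_lt_13 = pct(sum(ag < 13, na.rm = TRUE), sum(!is.na(ag))),
      asthma = sum(dg == "asthma", na.rm = TRUE),
      pct_asthma = pct(sum(dg == "asthma", na.rm = TRUE), sum(!is.na(dg))),
      cystic_fibrosis = sum(dg == "cystic_fibrosis", na.rm = TRUE),
      pct_cystic_fibrosis = pct(sum(dg == "cystic_fibrosis", na.rm = TRUE), sum(!is.na(dg))),
      healthy = sum(dg == "healthy", na.rm = TRUE),
      pct_healthy = pct(sum(dg == "healthy", na.rm = TRUE), sum(!is.na(dg))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (missing_any) {
    attr(out, "footnote") <- "percentages computed over non-missing covariates"
  }
  out
}
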