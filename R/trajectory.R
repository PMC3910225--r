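#' Construct a single subject's exertion trajectory
#'
#' A trajectory holds one subject's Borg ratings of perceived leg exertion
#' `y` observed at increasing fractions of the subject's individual maximal
#' work capacity `x` (so `x` lives in (0, 1] and typically ends at 1, the
#' final, maximal work increment).
#'
#' @param subject_id Identifier (coerced to character).
#' @param x Numeric vector of work fractions in (0, 1], strictly increasing.
#' @param y Numeric vector of Borg ratings in \[0, 10\], same length as `x`.
#' @param covariates Optional named list with any of `age` (years), `sex`
#'   (`"male"`/`"female"`), `diagnosis` (`"healthy"`, `"asthma"`,
#'   `"cystic_fibrosis"`).
#' @param check_range Enforce y in \[0, 10\] (default TRUE).  Noiseless
#'   fixtures sampled from a fitted model curve can exceed 10 slightly;
#'   disable the check for those.
#' @return An object of class `subject_trajectory`.
#' @examples
#' tr <- subject_trajectory("s1", x = (1:8) / 8, y = c(0, 0, 1, 1, 2, 3, 5, 7))
#' print(tr)
#' @export
subject_trajectory <- function(subject_id, x, y, covariates = NULL,
                               check_range = TRUE) {
  stopifnot(length(subject_id) == 1L)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("a trajectory needs at least 2 observations", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("x must be strictly increasing", call. = FALSE)
  }
  if (any(x <= 0) || any(x > 1 + 1e-8)) {
    stop("x must lie in (0, 1]: work fractions of individual Wmax", call. = FALSE)
  }
  if (check_range && (any(y < 0 - 1e-8) || any(y > 10 + 1e-8))) {
    stop("ratings y must lie in [0, 10]", call. = FALSE)
  }
  if (!is.null(covariates)) {
    stopifnot(is.list(covariates))
    ok <- c("age", "sex", "diagnosis")
    bad <- setdiff(names(covariates), ok)
    if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "), call. = FALSE)
    if (!is.null(covariates$diagnosis) &&
        !covariates$diagnosis %in% c("healthy", "asthma", "cystic_fibrosis")) {
      stop("diagnosis must be one of healthy, asthma, cystic_fibrosis", call. = FALSE)
    }
  }
  structure(
    list(subject_id = as.character(subject_id), x = x, y = y,
         covariates = covariates),
    class = "subject_trajectory"
  )
}

#' @export
print.subject_trajectory <- function(x, ...) {
  cat(sprintf("<subject_trajectory> %s: %d ratings, x in [%.2f, %.2f], max rating %.1f\n",
              x$subject_id, length(x$x), min(x$x), max(x$x), max(x$y)))
  invisible(x)
}

#' Number of observations in a trajectory
#' @param traj A `subject_trajectory`.
#' @return Integer count of (x, y) pairs.
#' @export
n_obs <- function(traj) length(traj$x)

#' Bundle trajectories into a cohort
#'
#' @param trajectories List of `subject_trajectory` objects with unique ids.
#' @param truth Optional per-subject ground-truth list (used by the synthetic
#'   generator); stored as-is.
#' @param config Optional echo of the generating configuration.
#' @return An object of class `rpe_cohort`: a list with elements
#'   `trajectories` (named by subject id), `truth`, `config`.
#' @export
rpe_cohort <- function(trajectories, truth = NULL, config = NULL) {
  stopifnot(is.list(trajectories), length(trajectories) >= 1L)
  ok <- vapply(trajectories, inherits, logical(1), "subject_trajectory")
  if (!all(ok)) stop("all elements must be subject_trajectory objects", call. = FALSE)
  ids <- vapply(trajectories, function(t) t$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids in cohort", call. = FALSE)
  names(trajectories) <- ids
  if (!is.null(truth)) {
    if (!all(ids %in% names(truth))) {
      stop("truth must cover every subject", call. = FALSE)
    }
    truth <- truth[ids]
  }
  structure(list(trajectories = trajectories, truth = truth, config = config),
            class = "rpe_cohort")
}

#' @export
print.rpe_cohort <- function(x, ...) {
  n <- length(x$trajectories)
  np <- vapply(x$trajectories, n_obs, integer(1))
  cat(sprintf("<rpe_cohort> %d subjects, %d-%d ratings each%s\n",
              n, min(np), max(np),
              if (!is.null(x$truth)) " (ground truth attached)" else ""))
  invisible(x)
}

#' @export
length.rpe_cohort <- function(x) length(x$trajectories)

#' Subject ids of a cohort
#' @param cohort An `rpe_cohort`.
#' @return Character vector of ids.
#' @export
cohort_ids <- function(cohort) names(cohort$trajectories)
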