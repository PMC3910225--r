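#' The four trajectory model families
#'
#' Ratings of perceived exertion y as a function of work fraction x are
#' described by one of four families, each with a Gaussian error term
#' eps ~ N(0, sigma^2):
#' \describe{
#'   \item{P (power)}{y = a + b2 * x^d}
#'   \item{D (delay)}{y = a + b1 * max(x - c, 0)}
#'   \item{PD (power-delay)}{y = a + b2 * max(x - c, 0)^d}
#'   \item{QD (quadratic-delay)}{y = a + b1 * max(x - c, 0) + b2 * max(x - c, 0)^2}
#' }
#' The delay c is the fraction of maximal work capacity below which predicted
#' ratings stay flat at the intercept a; the exponent d >= 0 is a Stevens-type
#' psychophysical growth exponent.  The number of estimated coefficients is
#' k = 3, 3, 4, 4 for P, D, PD, QD (sigma^2 is profiled out, not counted).
#'
#' @param name One of `"P"`, `"D"`, `"PD"`, `"QD"`.
#' @return A `model_family` object with fields `name`, `k`,
#'   `parameter_names`, and `nonlinear` (the subset of parameters the
#'   least-squares problem is nonlinear in).
#' @examples
#' model_family("QD")$k  # 4
#' @export
model_family <- function(name) {
  name <- match.arg(name, c("P", "D", "PD", "QD"))
  spec <- switch(name,
    P  = list(k = 3L, parameter_names = c("a", "b2", "d"),       nonlinear = "d"),
    D  = list(k = 3L, parameter_names = c("a", "b1", "c"),       nonlinear = "c"),
    PD = list(k = 4L, parameter_names = c("a", "b2", "c", "d"),  nonlinear = c("c", "d")),
    QD = list(k = 4L, parameter_names = c("a", "b1", "b2", "c"), nonlinear = "c")
  )
  structure(c(list(name = name), spec), class = "model_family")
}

#' @export
print.model_family <- function(x, ...) {
  cat(sprintf("<model_family> %s: k=%d, parameters {%s}\n",
              x$name, x$k, paste(x$parameter_names, collapse = ", ")))
  invisible(x)
}

as_family <- function(family) {
  if (inherits(family, "model_family")) family else model_family(family)
}

# delayed power term with the "flat before the delay" convention:
# max(x - c, 0)^d is defined as exactly 0 whenever x <= c, for every d >= 0,
# so the 0^0 corner never produces a jump at the changepoint.
delayed_pow <- function(x, c, d) {
  z <- x - c
  out <- numeric(length(x))
  pos <- z > 0
  out[pos] <- z[pos]^d
  out
}

check_params <- function(family, params) {
  need <- family$parameter_names
  miss <- need[!vapply(need, function(p) {
    !is.null(params[[p]]) && is.finite(params[[p]])
  }, logical(1))]
  if (length(miss)) {
    stop(sprintf("missing required parameter(s) for family %s: %s",
                 family$name, paste(miss, collapse = ", ")), call. = FALSE)
  }
  if ("d" %in% need && params$d < 0) {
    stop("exponent d must be >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Predicted rating under a model family
#'
#' @param family A `model_family` or its name.
#' @param params Named list with the family's parameters (see
#'   [model_family()]); extra entries are ignored.
#' @param x Work fraction(s) in \[0, 1\].
#' @return Numeric vector of predicted ratings, same length as `x`.
#' @examples
#' predict_rating("QD", list(a = 0.5, b1 = 30.31, b2 = -22.35, c = 0.46), 0.46)
#' @export
predict_rating <- function(family, params, x) {
  family <- as_family(family)
  check_params(family, params)
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1 + 1e-8)) {
    stop("x must lie in [0, 1]", call. = FALSE)
  }
  with(params, switch(family$name,
    P  = a + b2 * x^d,
    D  = a + b1 * pmax(x - c, 0),
    PD = a + b2 * delayed_pow(x, c, d),
    QD = a + b1 * pmax(x - c, 0) + b2 * pmax(x - c, 0)^2
  ))
}

#' Residual sum of squares and profile Gaussian log-likelihood
#'
#' Evaluates SSE = sum (y_j - yhat_j)^2 and the Gaussian log-likelihood at the
#' profile maximum-likelihood variance sigma2_hat = SSE / n, i.e. the
#' maximized likelihood that the information criteria are built on.
#'
#' @param traj A `subject_trajectory`.
#' @param family A `model_family` or name.
#' @param params Named parameter list for the family.
#' @return List with `sse`, `loglik`, `sigma2_hat`, `n`, and `perfect_fit`
#'   (TRUE when SSE is numerically zero; `loglik` is then `Inf`, a sentinel
#'   for the degenerate perfect fit, not an error).
#' @export
sse_and_loglik <- function(traj, family, params) {
  stopifnot(inherits(traj, "subject_trajectory"))
  n <- n_obs(traj)
  if (n == 0L) stop("empty trajectory", call. = FALSE)
  yhat <- predict_rating(family, params, traj$x)
  sse <- sum((traj$y - yhat)^2)
  gaussian_profile_loglik(sse, n)
}

# profile log-likelihood pieces shared with compute_criteria()
gaussian_profile_loglik <- function(sse, n) {
  if (sse <= .Machine$double.eps * n) {
    return(list(sse = sse, loglik = Inf, sigma2_hat = 0, n = n,
                perfect_fit = TRUE))
  }
  s2 <- sse / n
  ll <- -n / 2 * (log(2 * pi * s2) + 1)
  list(sse = sse, loglik = ll, sigma2_hat = s2, n = n, perfect_fit = FALSE)
}
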