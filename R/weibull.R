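#' Bernard's median rank
#'
#' The plotting position \code{(i - 0.3) / (n + 0.4)} estimating the CDF at
#' the i-th order statistic of a sample of size n.
#'
#' @param i rank(s), integer(s) in \code{[1, n]}.
#' @param n sample size.
#' @return value(s) in (0, 1), strictly increasing in \code{i}.
#' @export
bernard_median_rank <- function(i, n) {
  if (any(i < 1L) || any(i > n)) stop("rank i must satisfy 1 <= i <= n")
  (i - 0.3) / (n + 0.4)
}

#' Gini statistic on power-transformed spacings
#'
#' For sorted positive values \eqn{x_{(1)} \le \dots \le x_{(N)}} (with
#' \eqn{x_{(0)} \equiv 0}) and a candidate Weibull shape \eqn{\beta}, the
#' normalised spacings \eqn{W_i = (N-i+1)(x_{(i)}^\beta - x_{(i-1)}^\beta)}
#' are i.i.d. exponential exactly when the data are Weibull with shape
#' \eqn{\beta}, whatever the scale. The statistic
#' \deqn{G_N = \frac{\sum_{i=1}^{N-1} i\,W_{i+1}}{(N-1)\sum_{i=1}^N W_i}}
#' lies in [0, 1], is scale-free, and has mean about 1/2 under the null.
#'
#' @param values strictly positive numeric vector, length >= 3 (sorted
#'   internally).
#' @param beta candidate shape, > 0.
#' @return the Gini statistic, a number in [0, 1].
#' @examples
#' gini_statistic(c(1, 2, 3), beta = 1)  # 1/3
#' gini_statistic(c(1, 2, 3), beta = 2)  # 4/7
#' @export
gini_statistic <- function(values, beta) {
  n <- length(values)
  if (n < 3L) stop("at least three values are required")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be strictly positive; shift the data first")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("beta must be a single positive number")
  x <- sort(values) / max(values)  # the statistic is scale-free; rescaling
  xb <- x^beta                     # guards x^beta against overflow
  w <- (n:1) * (xb - c(0, xb[-n]))
  sum(seq_len(n - 1L) * w[-1L]) / ((n - 1L) * sum(w))
}

# coefficients c_j = (n-j)/(n-1), j = 1..n-1, and the per-term constants of
# the exact CDF; cached per n since only n in 3..20 ever reaches here
.gini_cdf_consts <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cj <- (n - seq_len(n - 1L)) / (n - 1L)
    # denominators c_j * prod_{k != j} (c_k - c_j), computed pairwise
    denom <- vapply(seq_len(n - 1L), function(j) {
      cj[j] * prod(cj[-j] - cj[j])
    }, numeric(1))
    out <- list(cj = cj, denom = denom, lead = 1 / prod(cj))
    cache[[key]] <<- out
    out
  }
})

#' Exact CDF of the Gini statistic under the Weibull-shape null
#'
#' For sample sizes 3 to 20 the null distribution of \code{\link{gini_statistic}}
#' is known in closed form: with \eqn{c_j = (N-j)/(N-1)},
#' \deqn{P(G_N \le x) = \frac{x^{N-1}}{\prod_j c_j}
#'   - \sum_{j > m} \frac{(x - c_j)^{N-1}}{c_j \prod_{k \ne j}(c_k - c_j)},}
#' where \eqn{m} is the largest index with \eqn{x \le c_m}. The function
#' returns 0 for \code{x <= 0} and 1 for \code{x >= 1}.
#'
#' @param x evaluation point(s).
#' @param n sample size, integer in \code{[3, 20]}; larger samples use the
#'   normal approximation in \code{\link{gini_p_value}}.
#' @return probability(ies), monotone non-decreasing in \code{x}.
#' @examples
#' gini_exact_cdf(0.5, 3)   # 0.5  (for n = 3 the CDF is 2 x^2 below 1/2)
#' gini_exact_cdf(0.25, 3)  # 0.125
#' @export
gini_exact_cdf <- function(x, n) {
  if (length(n) != 1L || n != round(n) || n < 3L || n > 20L)
    stop("n must be an integer in [3, 20]; use the normal branch beyond 20")
  cst <- .gini_cdf_consts(as.integer(n))
  vapply(x, function(xi) {
    if (is.na(xi)) return(NA_real_)
    if (xi <= 0) return(0)
    if (xi >= 1) return(1)
    p <- xi^(n - 1) * cst$lead
    over <- which(cst$cj < xi)  # j > m, i.e. terms with x > c_j
    if (length(over))
      p <- p - sum((xi - cst$cj[over])^(n - 1) / cst$denom[over])
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Two-sided p-value for the Gini statistic
#'
#' Exact for sample sizes 3 to 20 (\code{p = 2 min(F(g), 1 - F(g))} with
#' \code{F} the exact CDF); for larger samples
#' \eqn{Z = \sqrt{12(N-1)}\,(g - 1/2)} is treated as standard normal and
#' \code{p = 2 (1 - \Phi(|z|))}.
#'
#' @param g observed Gini statistic.
#' @param n sample size, >= 3.
#' @return an object of class \code{gini_result}: list with \code{g_n},
#'   \code{p_value}, \code{method} ("exact" or "normal") and \code{z}
#'   (normal branch only, else \code{NA}).
#' @export
gini_p_value <- function(g, n) {
  if (length(n) != 1L || n != round(n) || n < 3L) stop("n must be >= 3")
  if (n <= 20L) {
    f <- gini_exact_cdf(g, n)
    res <- list(g_n = g, p_value = min(1, 2 * min(f, 1 - f)),
                method = "exact", z = NA_real_)
  } else {
    z <- sqrt(12 * (n - 1)) * (g - 0.5)
    res <- list(g_n = g, p_value = 2 * stats::pnorm(-abs(z)),
                method = "normal", z = z)
  }
  structure(res, class = "gini_result")
}

#' Default shape-parameter search grid
#'
#' A coarse pass over \code{seq(from, to, by)} followed by one local
#' refinement at step \code{refine_by} around the coarse maximiser. The
#' default 0.05..10 generously brackets the exponential (beta = 1) to
#' near-normal (beta about 3-4) shapes relevant in practice.
#'
#' @param from,to,by coarse grid limits and step.
#' @param refine_by refinement step.
#' @export
beta_grid <- function(from = 0.05, to = 10, by = 0.05, refine_by = 0.005) {
  stopifnot(from > 0, to > from, by > 0, refine_by > 0)
  structure(list(from = from, to = to, by = by, refine_by = refine_by),
            class = "beta_grid")
}

# select the best beta from a candidate set: maximal p-value, ties broken by
# smaller SSE (lambda from the closed form), then smaller beta
.select_beta <- function(x_pos, betas, n) {
  p <- vapply(betas, function(b)
    gini_p_value(gini_statistic(x_pos, b), n)$p_value, numeric(1))
  best <- which(p >= max(p) - 1e-12)
  if (length(best) > 1L) {
    sse <- vapply(betas[best], function(b)
      weibull_sse(x_pos, b, estimate_lambda(x_pos, b)), numeric(1))
    best <- best[sse <= min(sse) + 1e-12]
    best <- best[which.min(betas[best])]
  }
  best <- best[1L]
  list(beta = betas[best], p_value = p[best])
}

#' Estimate the Weibull shape by the maximal-p-value rule
#'
#' Runs the Gini goodness-of-fit test across a grid of null shapes and
#' returns the shape whose test yields the largest p-value -- the
#' "counterintuitive" use of a hypothesis test as an estimator. Ties are
#' broken by smaller median-rank SSE, then by the smaller shape.
#'
#' @param values strictly positive numeric vector, length >= 3.
#' @param grid a \code{\link{beta_grid}} search specification.
#' @return list with \code{beta} and \code{p_value}.
#' @export
estimate_beta <- function(values, grid = beta_grid()) {
  n <- length(values)
  if (n < 3L) stop("minority class size must be at least three")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be strictly positive; shift the data first")
  stopifnot(inherits(grid, "beta_grid"))
  coarse <- .select_beta(values, seq(grid$from, grid$to, by = grid$by), n)
  lo <- max(grid$refine_by, coarse$beta - grid$by)
  hi <- coarse$beta + grid$by
  .select_beta(values, seq(lo, hi, by = grid$refine_by), n)
}

#' Closed-form scale estimate given the shape
#'
#' Median-rank least squares: on the log-log scale the Weibull CDF is linear,
#' \eqn{\ln(-\ln(1 - F)) = \beta \ln x - \beta \ln \lambda}, and for a fixed
#' shape the residual sum of squares is quadratic in \eqn{\ln\lambda}; its
#' minimiser is
#' \deqn{\lambda = \exp\{-\tfrac{1}{\beta}\,\tfrac{1}{N}\sum_i
#'   [\ln(-\ln(1 - \hat F_i)) - \beta \ln x_{(i)}]\}}
#' with Bernard plotting positions \eqn{\hat F_i}.
#'
#' @param values strictly positive numeric vector.
#' @param beta shape, > 0.
#' @return the scale estimate, a positive number.
#' @export
estimate_lambda <- function(values, beta) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be strictly positive; shift the data first")
  n <- length(values)
  fr <- bernard_median_rank(seq_len(n), n)
  exp(-(1 / beta) * mean(log(-log(1 - fr)) - beta * log(sort(values))))
}

#' Median-rank sum of squared residuals
#'
#' The least-squares objective on the log-log Weibull scale:
#' \eqn{\sum_i [\ln(-\ln(1 - \hat F_i)) - \beta \ln x_{(i)} + \beta \ln \lambda]^2}.
#'
#' @inheritParams estimate_lambda
#' @param lambda scale, > 0.
#' @export
weibull_sse <- function(values, beta, lambda) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be strictly positive; shift the data first")
  if (lambda <= 0) stop("lambda must be positive")
  n <- length(values)
  fr <- bernard_median_rank(seq_len(n), n)
  sum((log(-log(1 - fr)) - beta * log(sort(values)) + beta * log(lambda))^2)
}

#' Fit a two-parameter Weibull by the Gini maximal-p-value procedure
#'
#' Shifts the data onto positive support if necessary, estimates the shape
#' with \code{\link{estimate_beta}} and the scale with
#' \code{\link{estimate_lambda}}, and records the p-value at the chosen
#' shape and the median-rank SSE. The support shift is 0 for strictly
#' positive input; otherwise \code{min - 0.01 * range} (or \code{min - 1}
#' for constant input), recorded in the fit and added back on generation.
#'
#' @param values numeric vector, length >= 3, finite.
#' @param grid a \code{\link{beta_grid}} search specification.
#' @return an object of class \code{weibull_fit}: list with \code{beta},
#'   \code{lambda}, \code{shift}, \code{p_value}, \code{sse}, \code{n}.
#' @export
fit_weibull <- function(values, grid = beta_grid()) {
  n <- length(values)
  if (n < 3L) stop("minority class size must be at least three")
  if (any(!is.finite(values))) stop("non-finite input")
  rng <- max(values) - min(values)
  shift <- if (min(values) > 0) 0
  else if (rng > 0) min(values) - 0.01 * rng
  else min(values) - 1
  x <- values - shift
  est <- estimate_beta(x, grid)
  lambda <- estimate_lambda(x, est$beta)
  structure(
    list(beta = est$beta, lambda = lambda, shift = shift,
         p_value = est$p_value, sse = weibull_sse(x, est$beta, lambda),
         n = n),
    class = "weibull_fit"
  )
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Two-parameter Weibull fit (Gini maximal-p-value)\n")
  cat(sprintf("  shape beta = %g, scale lambda = %g, shift = %g\n",
              x$beta, x$lambda, x$shift))
  cat(sprintf("  p-value = %.4g, SSE = %.4g, n = %d\n", x$p_value, x$sse, x$n))
  invisible(x)
}

#' Generate synthetic values from a Weibull fit by median-rank inversion
#'
#' Inverts the fitted CDF at the Bernard plotting positions of the requested
#' sample size: \eqn{\hat x_i = \lambda\{-\ln[1 - (i-0.3)/(n'+0.4)]\}^{1/\beta}}
#' plus the support shift. \code{mode = "median_rank"} returns the values in
#' increasing order (the literal quantile set); \code{mode = "permuted"}
#' returns the same multiset in a random order drawn from the current RNG
#' stream, which is what the resampler uses so that different features of a
#' synthetic row are not comonotone.
#'
#' @param fit a \code{weibull_fit}.
#' @param n_prime number of values to generate, >= 0.
#' @param mode \code{"median_rank"} (sorted) or \code{"permuted"}.
#' @return numeric vector of length \code{n_prime}.
#' @export
generate_samples <- function(fit, n_prime, mode = c("median_rank", "permuted")) {
  stopifnot(inherits(fit, "weibull_fit"))
  mode <- match.arg(mode)
  if (length(n_prime) != 1L || n_prime != round(n_prime) || n_prime < 0)
    stop("n_prime must be a nonnegative integer")
  if (n_prime == 0L) return(numeric(0))
  fr <- bernard_median_rank(seq_len(n_prime), n_prime)
  x <- fit$lambda * (-log(1 - fr))^(1 / fit$beta) + fit$shift
  if (mode == "permuted") x <- x[sample.int(n_prime)]
  x
}
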