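#' Mega-Trend-Diffusion domain estimate for one feature
#'
#' Estimates a plausible domain \code{[a, b]} around the observed values by
#' variance-scaled, skewness-weighted diffusion. The midpoint of the observed
#' range, \code{u_set = (min + max) / 2}, splits the sample into \code{n_l}
#' values strictly below and \code{n_u} strictly above (ties at \code{u_set}
#' count in neither), and the bounds diffuse outward from \code{u_set} by
#' \deqn{a = u_{set} - S_L \sqrt{-2 (s_x^2 / N_L) \ln 10^{-20}}, \qquad
#'       b = u_{set} + S_U \sqrt{-2 (s_x^2 / N_U) \ln 10^{-20}},}
#' with skewness weights \eqn{S_L = N_L/(N_L+N_U)}, \eqn{S_U = N_U/(N_L+N_U)}
#' and sample variance \eqn{s_x^2}. When \code{n_l = 0} the lower bound falls
#' back to \code{min / 5}; when \code{n_u = 0} the upper bound is
#' \code{5 * max}. The bounds are applied literally: \code{a} is not clipped
#' at zero for nonnegative data, and if \code{a > min} (possible for a
#' lopsided sample with tiny variance) a warning is emitted because observed
#' points below \code{a} would receive membership zero.
#'
#' @param values numeric vector, length >= 1, all finite.
#' @return an object of class \code{mtd_model}: a list with components
#'   \code{u_set}, \code{data_min}, \code{data_max}, \code{n_l}, \code{n_u},
#'   \code{s_l}, \code{s_u}, \code{variance}, \code{a}, \code{b},
#'   \code{diffusion_log} (the constant \eqn{\ln 10^{-20}}) and
#'   \code{degenerate} (TRUE when \code{a = b = u_set}).
#' @examples
#' fit_mtd(c(2, 4, 6, 8))  # symmetric sample: b - u_set equals u_set - a
#' fit_mtd(c(4, 4, 4))     # constant data: a = min/5 = 0.8, b = 5*max = 20
#' @export
fit_mtd <- function(values) {
  if (length(values) == 0L) stop("empty feature")
  if (!is.numeric(values) || any(!is.finite(values))) stop("non-finite input")
  dmin <- min(values); dmax <- max(values)
  u_set <- (dmin + dmax) / 2
  n_l <- sum(values < u_set)
  n_u <- sum(values > u_set)
  variance <- if (length(values) >= 2L) stats::var(values) else 0
  diffusion_log <- log(1e-20)
  if (n_l + n_u > 0L) {
    s_l <- n_l / (n_l + n_u)
    s_u <- n_u / (n_l + n_u)
  } else {
    s_l <- s_u <- 0
  }
  a <- if (n_l == 0L) dmin / 5 else
    u_set - s_l * sqrt(-2 * variance / n_l * diffusion_log)
  b <- if (n_u == 0L) dmax * 5 else
    u_set + s_u * sqrt(-2 * variance / n_u * diffusion_log)
  if (a > dmin + 1e-12 * max(1, abs(dmin)))
    warning("MTD lower bound exceeds the observed minimum; ",
            "data below 'a' get membership 0")
  if (b < dmax - 1e-12 * max(1, abs(dmax)))
    warning("MTD upper bound is below the observed maximum; ",
            "data above 'b' get membership 0")
  structure(
    list(u_set = u_set, data_min = dmin, data_max = dmax,
         n_l = n_l, n_u = n_u, s_l = s_l, s_u = s_u,
         variance = variance, a = a, b = b,
         diffusion_log = diffusion_log,
         degenerate = (a == b)),
    class = "mtd_model"
  )
}

#' @export
print.mtd_model <- function(x, ...) {
  cat("Mega-Trend-Diffusion domain model\n")
  cat(sprintf("  u_set = %g, observed range [%g, %g]\n",
              x$u_set, x$data_min, x$data_max))
  cat(sprintf("  n_l = %d, n_u = %d, variance = %g\n", x$n_l, x$n_u, x$variance))
  cat(sprintf("  estimated domain [a, b] = [%g, %g]\n", x$a, x$b))
  invisible(x)
}

#' Triangular membership of a point under an MTD model
#'
#' Membership rises linearly from 0 at \code{a} to 1 at \code{u_set} and
#' falls linearly back to 0 at \code{b}; it is 0 outside \code{[a, b]}.
#' For a degenerate model (\code{a = b = u_set}) membership is 1 exactly at
#' \code{u_set} and 0 elsewhere.
#'
#' @param model an \code{mtd_model} from \code{\link{fit_mtd}}.
#' @param x numeric vector of evaluation points.
#' @return numeric vector of memberships in \code{[0, 1]}.
#' @export
mtd_membership <- function(model, x) {
  stopifnot(inherits(model, "mtd_model"))
  a <- model$a; b <- model$b; u <- model$u_set
  if (model$degenerate) return(as.numeric(x == u))
  out <- numeric(length(x))
  left <- x >= a & x <= u
  right <- x > u & x <= b
  if (u > a) out[left] <- (x[left] - a) / (u - a) else out[left] <- 1
  if (b > u) out[right] <- (b - x[right]) / (b - u)
  out
}

#' Alpha-cut interval of an MTD membership function
#'
#' The crisp set of points with membership at least \code{alpha}:
#' \code{[(u_set - a) * alpha + a,  b - (b - u_set) * alpha]}. The intervals
#' are nested: larger \code{alpha} gives a narrower interval, from the full
#' domain \code{[a, b]} at \code{alpha = 0} down to the single point
#' \code{u_set} at \code{alpha = 1}.
#'
#' @inheritParams mtd_membership
#' @param alpha membership threshold in \code{[0, 1]}.
#' @return an object of class \code{alpha_cut}: list with \code{lo},
#'   \code{hi}, \code{alpha}.
#' @export
alpha_cut_region <- function(model, alpha) {
  stopifnot(inherits(model, "mtd_model"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  structure(
    list(lo = (model$u_set - model$a) * alpha + model$a,
         hi = model$b - (model$b - model$u_set) * alpha,
         alpha = alpha),
    class = "alpha_cut"
  )
}

#' Retain-mask for values inside the alpha-cut region
#'
#' @inheritParams alpha_cut_region
#' @param values numeric vector to filter.
#' @return logical vector, \code{TRUE} where
#'   \code{lo <= values[i] <= hi} (closed interval).
#' @export
filter_by_alpha_cut <- function(values, model, alpha) {
  cut <- alpha_cut_region(model, alpha)
  values >= cut$lo & values <= cut$hi
}
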