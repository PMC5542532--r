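#' Box-and-whisker statistics for one feature
#'
#' Computes the quartiles, interquartile range and Tukey inner fences of a
#' numeric vector. Values outside \code{[lif, uif]} are suspected outliers.
#'
#' The default quartile convention is Tukey hinges (the median of the lower
#' and upper half of the sorted data, each half including the overall median
#' when the sample size is odd), the convention of the original box plot.
#' \code{convention = "interpolation"} selects linear interpolation of order
#' statistics (\code{\link[stats]{quantile}} type 7) instead.
#'
#' @param values numeric vector, length >= 1, all finite.
#' @param convention quartile convention, \code{"hinges"} (default) or
#'   \code{"interpolation"}.
#' @return an object of class \code{box_stats}: a list with components
#'   \code{q1}, \code{q2}, \code{q3}, \code{iqr}, \code{lif}, \code{uif}.
#' @examples
#' compute_box_stats(1:9)          # q1 = 3, q3 = 7, fences at -3 and 13
#' compute_box_stats(c(1:9, 100))  # the fence moves, 100 lies above uif
#' @export
compute_box_stats <- function(values, convention = c("hinges", "interpolation")) {
  convention <- match.arg(convention)
  if (length(values) == 0L) stop("empty feature")
  if (!is.numeric(values) || any(!is.finite(values))) stop("non-finite input")
  if (convention == "hinges") {
    fn <- stats::fivenum(values)
    q1 <- fn[2L]; q2 <- fn[3L]; q3 <- fn[4L]
  } else {
    qs <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    q1 <- qs[1L]; q2 <- qs[2L]; q3 <- qs[3L]
  }
  iqr <- q3 - q1
  structure(
    list(q1 = q1, q2 = q2, q3 = q3, iqr = iqr,
         lif = q1 - 1.5 * iqr, uif = q3 + 1.5 * iqr),
    class = "box_stats"
  )
}

#' @export
print.box_stats <- function(x, ...) {
  cat("Box-whisker statistics\n")
  cat(sprintf("  Q1 = %g, Q2 = %g, Q3 = %g (IQR = %g)\n", x$q1, x$q2, x$q3, x$iqr))
  cat(sprintf("  inner fences: [%g, %g]\n", x$lif, x$uif))
  invisible(x)
}

#' Flag suspected outliers by the inner-fence rule
#'
#' @inheritParams compute_box_stats
#' @return logical vector, \code{TRUE} where the value falls outside the
#'   inner fences of \code{\link{compute_box_stats}(values)}.
#' @examples
#' flag_outliers(c(1:9, 100))  # only 100 is flagged
#' @export
flag_outliers <- function(values, convention = c("hinges", "interpolation")) {
  bs <- compute_box_stats(values, convention)
  values < bs$lif | values > bs$uif
}
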