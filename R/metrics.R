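#' Confusion counts for a binary prediction
#'
#' Tabulates true/false positives and negatives, with the minority class as
#' the positive label.
#'
#' @param y_true,y_pred equal-length vectors of class labels.
#' @param positive the positive (minority) label; both vectors may only
#'   contain this label and one other.
#' @return an object of class \code{confusion_counts}: list with \code{tp},
#'   \code{fn}, \code{fp}, \code{tn}.
#' @export
confusion <- function(y_true, y_pred, positive) {
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  labs <- unique(c(y_true, y_pred))
  if (length(labs) > 2L)
    stop("labels are not binary: found ", paste(labs, collapse = ", "))
  if (!positive %in% labs && length(labs) == 2L)
    stop("positive label '", positive, "' not present among labels")
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_counts")
}

.check_counts <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn + c$fp + c$tn == 0L) stop("all confusion counts are zero")
}

#' @rdname imbalance_metrics
#' @export
accuracy <- function(c) {
  .check_counts(c)
  (c$tp + c$tn) / (c$tp + c$tn + c$fp + c$fn)
}

#' Imbalanced-classification metrics
#'
#' \code{accuracy} is \eqn{(TP+TN)/N}; \code{g_mean} is the geometric mean
#' of sensitivity \eqn{TPR = TP/(TP+FN)} and specificity
#' \eqn{TNR = TN/(TN+FP)}; \code{f_measure} is the harmonic mean of
#' precision \eqn{P = TP/(TP+FP)} and recall \eqn{R = TPR}. A 0/0 ratio
#' (no predicted positives, no actual negatives) is taken as 0, keeping the
#' metrics total; a test set with no actual positives is rejected since
#' sensitivity is then undefined.
#'
#' @param c a \code{confusion_counts} object.
#' @return a number in [0, 1].
#' @name imbalance_metrics
#' @examples
#' cc <- structure(list(tp = 3, fn = 1, fp = 2, tn = 4),
#'                 class = "confusion_counts")
#' accuracy(cc)   # 0.7
#' g_mean(cc)     # sqrt(0.75 * 2/3) = 0.7071
#' f_measure(cc)  # 0.6667
NULL

.ratio0 <- function(num, den) if (den == 0) 0 else num / den

#' @rdname imbalance_metrics
#' @export
g_mean <- function(c) {
  .check_counts(c)
  if (c$tp + c$fn == 0L) stop("no actual positive examples")
  sqrt(.ratio0(c$tp, c$tp + c$fn) * .ratio0(c$tn, c$tn + c$fp))
}

#' @rdname imbalance_metrics
#' @export
f_measure <- function(c) {
  .check_counts(c)
  if (c$tp + c$fn == 0L) stop("no actual positive examples")
  p <- .ratio0(c$tp, c$tp + c$fp)
  r <- .ratio0(c$tp, c$tp + c$fn)
  if (p + r == 0) 0 else 2 * r * p / (r + p)
}
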