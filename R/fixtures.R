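#' Specification for a synthetic imbalanced dataset
#'
#' Describes a two-class numeric dataset: Gaussian majority features,
#' Weibull minority features (so that the oversampler's distributional
#' assumption holds by construction and parameter recovery is testable),
#' and an optional fraction of majority rows with one feature displaced far
#' beyond the fences to emulate gross outliers.
#'
#' Defaults emulate a mid-sized clinical table: 400 majority and 100
#' minority rows, four features, majority means spread around 10 with unit
#' to double spread, minority Weibull shapes in the exponential-to-Rayleigh
#' range shifted to overlap the lower majority tail, and a 2\% gross-outlier
#' rate.
#'
#' @param n_major,n_minor class sizes (minority >= 3).
#' @param p number of features (>= 1).
#' @param majority_model list of per-feature lists with \code{location} and
#'   \code{scale} (Gaussian); recycled defaults if \code{NULL}.
#' @param minority_model list of per-feature lists with \code{beta},
#'   \code{lambda}, \code{shift} (two-parameter Weibull plus offset);
#'   defaults if \code{NULL}.
#' @param outlier_rate fraction of majority rows, in \code{[0, 1)}, given
#'   one far-displaced feature value.
#' @param seed integer seed.
#' @export
fixture_spec <- function(n_major = 400L, n_minor = 100L, p = 4L,
                         majority_model = NULL, minority_model = NULL,
                         outlier_rate = 0.02, seed = 1L) {
  if (n_minor < 3L) stop("minority class size must be at least three")
  if (p < 1L) stop("at least one feature is required")
  if (outlier_rate < 0 || outlier_rate >= 1)
    stop("outlier_rate must be in [0, 1)")
  if (is.null(majority_model))
    majority_model <- lapply(seq_len(p), function(j)
      list(location = 10 + j, scale = 1 + 0.25 * j))
  if (is.null(minority_model))
    minority_model <- lapply(seq_len(p), function(j)
      list(beta = 1.5 + 0.5 * (j %% 3), lambda = 2, shift = 6 + j))
  stopifnot(length(majority_model) == p, length(minority_model) == p)
  structure(
    list(n_major = as.integer(n_major), n_minor = as.integer(n_minor),
         p = as.integer(p), majority_model = majority_model,
         minority_model = minority_model, outlier_rate = outlier_rate,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate a synthetic imbalanced dataset
#'
#' Deterministic given \code{spec$seed}. Majority rows chosen for outlier
#' injection get one randomly chosen feature displaced by 12 IQRs of that
#' feature, well beyond both the inner fences and any plausible alpha-cut.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return a \code{labeled_dataset} with labels \code{"neg"}/\code{"pos"}
#'   and \code{positive_label = "pos"}.
#' @export
make_synthetic_imbalanced <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  maj <- vapply(spec$majority_model, function(mm)
    stats::rnorm(spec$n_major, mm$location, mm$scale),
    numeric(spec$n_major))
  n_out <- round(spec$outlier_rate * spec$n_major)
  if (n_out > 0L) {
    rows <- sample.int(spec$n_major, n_out)
    cols <- sample.int(spec$p, n_out, replace = TRUE)
    for (k in seq_len(n_out)) {
      j <- cols[k]
      maj[rows[k], j] <- maj[rows[k], j] + 12 * stats::IQR(maj[, j])
    }
  }
  mino <- vapply(spec$minority_model, function(mm)
    stats::rweibull(spec$n_minor, shape = mm$beta, scale = mm$lambda) + mm$shift,
    numeric(spec$n_minor))
  feats <- rbind(maj, mino)
  colnames(feats) <- paste0("V", seq_len(spec$p))
  labeled_dataset(feats,
                  rep(c("neg", "pos"), c(spec$n_major, spec$n_minor)),
                  positive_label = "pos")
}

#' Specification for one imbalanced train/test scenario
#'
#' A training set of \code{n_train} rows holds \code{m} minority rows, where
#' \code{m} is \code{r\%} of \code{n_train} rounded half-up and floored at 3
#' (the minimum sample size the Weibull fit accepts), and
#' \code{M = n_train - m} majority rows; all remaining rows form the test
#' set. At \code{r = 5} this yields (M, m) = (57, 3), (76, 4), (95, 5),
#' (142, 8) for \code{n_train} = 60, 80, 100, 150.
#'
#' @param r minority percentage of the training set.
#' @param n_train training-set size.
#' @param repetitions number of independent train/test redraws.
#' @param seed integer seed.
#' @export
scenario_spec <- function(r, n_train, repetitions = 50L, seed = 1L) {
  if (r <= 0 || r >= 100) stop("r must be a percentage in (0, 100)")
  m <- max(floor(r / 100 * n_train + 0.5), 3L)
  if (m >= n_train) stop("minority count reaches the training size")
  structure(
    list(r = r, n_train = as.integer(n_train),
         m_minor = as.integer(m), m_major = as.integer(n_train - m),
         repetitions = as.integer(repetitions), seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' Draw one train/test split for a scenario
#'
#' Samples the scenario's majority and minority training counts without
#' replacement; everything else becomes the test set. Deterministic given
#' \code{(spec$seed, rep)}.
#'
#' @param dataset a \code{labeled_dataset} with enough rows of each class.
#' @param spec a \code{\link{scenario_spec}}.
#' @param rep repetition index, >= 1.
#' @return list with \code{train} and \code{test}, both
#'   \code{labeled_dataset}s.
#' @export
make_scenario <- function(dataset, spec, rep = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(spec, "scenario_spec"))
  pos <- which(dataset$labels == dataset$positive_label)
  neg <- which(dataset$labels != dataset$positive_label)
  if (length(pos) < spec$m_minor + 1L)
    stop("not enough minority rows for this scenario")
  if (length(neg) < spec$m_major + 1L)
    stop("not enough majority rows for this scenario")
  set.seed((spec$seed + 7919L * as.integer(rep)) %% 2147483647L)
  tr_pos <- sample(pos, spec$m_minor)
  tr_neg <- sample(neg, spec$m_major)
  tr <- c(tr_neg, tr_pos)
  list(train = .ds_rows(dataset, tr),
       test = .ds_rows(dataset, setdiff(seq_along(dataset$labels), tr)))
}

#' Reference classifier hook: polynomial-kernel SVM
#'
#' The reference configuration for the experiment harness: a support vector
#' machine with polynomial kernel of degree 2 and cost 1 (via
#' \pkg{e1071}). Any function with the same signature
#' \code{function(train, test)} returning predicted labels for the test
#' rows can be plugged into \code{\link{run_experiment}} instead.
#'
#' @return a classifier hook function.
#' @export
svm_poly_classifier <- function() {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("the reference SVM hook needs the 'e1071' package")
  function(train, test) {
    fit <- e1071::svm(x = train$features, y = factor(train$labels),
                      kernel = "polynomial", degree = 2, cost = 1)
    as.character(stats::predict(fit, test$features))
  }
}

#' Run repeated raw-vs-resampled experiments
#'
#' For each scenario and repetition, draws a train/test split, trains the
#' classifier hook on (a) the raw imbalanced training set and (b) the
#' training set balanced by \code{\link{ppdp_resample}}, and scores
#' accuracy, G-mean and F-measure on the held-out test rows. Deterministic
#' given the scenario seeds and \code{config$seed}.
#'
#' @param dataset a \code{labeled_dataset} to draw scenarios from.
#' @param scenarios list of \code{\link{scenario_spec}}s.
#' @param config a \code{\link{ppdp_config}}.
#' @param classifier a hook \code{function(train, test)} returning predicted
#'   labels for the test rows (both arguments are \code{labeled_dataset}s;
#'   an honest classifier ignores \code{test$labels}).
#' @param methods which training sets to score: subset of
#'   \code{c("raw", "ppdp")}.
#' @return data frame with one row per scenario x method, columns \code{r},
#'   \code{n_train}, \code{m_major}, \code{m_minor}, \code{method},
#'   \code{acc}, \code{g_mean}, \code{f1}, \code{repetitions}.
#' @export
run_experiment <- function(dataset, scenarios, config = ppdp_config(),
                           classifier, methods = c("raw", "ppdp")) {
  stopifnot(is.function(classifier))
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (sc in scenarios) {
    stopifnot(inherits(sc, "scenario_spec"))
    acc <- gm <- f1 <- matrix(NA_real_, sc$repetitions, length(methods),
                              dimnames = list(NULL, methods))
    for (rep in seq_len(sc$repetitions)) {
      split <- make_scenario(dataset, sc, rep)
      for (meth in methods) {
        train <- if (meth == "raw") split$train else {
          cfg <- config
          cfg$seed <- (config$seed + 104729L * rep) %% 2147483647L
          suppressWarnings(ppdp_resample(split$train, cfg)$balanced)
        }
        pred <- tryCatch(classifier(train, split$test), error = function(e)
          stop("classifier failed at r=", sc$r, ", n_train=", sc$n_train,
               ", rep=", rep, ": ", conditionMessage(e)))
        cc <- confusion(split$test$labels, pred, dataset$positive_label)
        acc[rep, meth] <- accuracy(cc)
        gm[rep, meth] <- g_mean(cc)
        f1[rep, meth] <- f_measure(cc)
      }
    }
    for (meth in methods)
      rows[[length(rows) + 1L]] <- data.frame(
        r = sc$r, n_train = sc$n_train,
        m_major = sc$m_major, m_minor = sc$m_minor,
        method = meth, acc = mean(acc[, meth]), g_mean = mean(gm[, meth]),
        f1 = mean(f1[, meth]), repetitions = sc$repetitions)
  }
  do.call(rbind, rows)
}
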