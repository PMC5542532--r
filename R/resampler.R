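#' Labelled numeric dataset for binary resampling
#'
#' The container the pipeline consumes and returns: an N x P matrix of
#' finite numeric features and a length-N binary label vector. The positive
#' label identifies the class of interest (usually the minority).
#'
#' @param features numeric matrix or data frame, N x P, all finite.
#' @param labels length-N vector with exactly two distinct values.
#' @param positive_label the positive-class label; defaults to the less
#'   frequent one.
#' @return an object of class \code{labeled_dataset}.
#' @export
labeled_dataset <- function(features, labels, positive_label = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) stop("features must be numeric")
  if (any(!is.finite(features))) {
    bad <- which(!is.finite(features), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite feature value at row %d, column %s",
                 bad[1L], colnames(features)[bad[2L]] %||% bad[2L]))
  }
  if (nrow(features) != length(labels))
    stop("row count of features must equal label count")
  classes <- unique(labels)
  if (length(classes) != 2L)
    stop("exactly two classes are required, found ", length(classes))
  if (is.null(positive_label)) {
    tab <- table(labels)
    positive_label <- names(tab)[which.min(tab)]
  }
  if (!positive_label %in% as.character(classes))
    stop("positive_label '", positive_label, "' not present in labels")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("V", seq_len(ncol(features)))
  structure(
    list(features = features, labels = as.character(labels),
         feature_names = colnames(features),
         positive_label = as.character(positive_label)),
    class = "labeled_dataset"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("Labelled dataset: %d rows, %d features\n",
              nrow(x$features), ncol(x$features)))
  cat(sprintf("  classes: %s (positive = '%s')\n",
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$positive_label))
  invisible(x)
}

# subset rows, keeping class and metadata
.ds_rows <- function(ds, idx) {
  out <- ds
  out$features <- ds$features[idx, , drop = FALSE]
  out$labels <- ds$labels[idx]
  out
}

#' Resampling configuration
#'
#' @param alpha membership threshold of the alpha-cut undersampling stage,
#'   in \code{[0, 1]}. 0.5 is the recommended operating point: lower values
#'   retain unrepresentative majority tails, higher values shrink the
#'   training set towards the domain midpoint.
#' @param seed integer seed governing all stochastic choices of a run.
#' @param generation_mode how synthetic minority rows are assembled:
#'   \code{"permuted"} (default) permutes the median-rank quantiles
#'   independently per feature so features are not comonotone;
#'   \code{"median_rank"} keeps the literal increasing quantile order.
#' @param quartile_convention passed to \code{\link{compute_box_stats}}.
#' @param grid a \code{\link{beta_grid}} for the Weibull shape search.
#' @export
ppdp_config <- function(alpha = 0.5, seed = 42L,
                        generation_mode = c("permuted", "median_rank"),
                        quartile_convention = c("hinges", "interpolation"),
                        grid = beta_grid()) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  structure(
    list(alpha = alpha, seed = as.integer(seed),
         generation_mode = match.arg(generation_mode),
         quartile_convention = match.arg(quartile_convention),
         grid = grid),
    class = "ppdp_config"
  )
}

#' Split a dataset into minority and majority classes
#'
#' The minority is the class with fewer rows; on a tie the declared positive
#' label is taken as the minority, with a warning.
#'
#' @param dataset a \code{labeled_dataset}.
#' @return list with components \code{minority} and \code{majority}, both
#'   \code{labeled_dataset}s; the partition is exhaustive and disjoint.
#' @export
split_by_class <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  pos <- dataset$labels == dataset$positive_label
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  if (n_pos == n_neg)
    warning("classes are the same size; taking the positive label as minority")
  minority_is_pos <- n_pos <= n_neg
  idx_min <- if (minority_is_pos) which(pos) else which(!pos)
  idx_maj <- if (minority_is_pos) which(!pos) else which(pos)
  list(minority = .ds_rows(dataset, idx_min),
       majority = .ds_rows(dataset, idx_maj))
}

#' Undersample the majority class
#'
#' Two stages, each applied per feature with a per-row union rule (a row is
#' removed as soon as any of its features violates the rule, which is what
#' makes the removal counts scalar):
#' \enumerate{
#'   \item box-whisker: rows with any feature outside that feature's inner
#'     fences are deleted (count \code{s_box});
#'   \item alpha-cut: Mega-Trend-Diffusion domains are fitted per feature on
#'     the stage-1 survivors, and rows with any feature outside that
#'     feature's alpha-cut interval are deleted (count \code{s_mtd}).
#'     Zero-variance features are skipped in this stage.
#' }
#'
#' @param majority a \code{labeled_dataset} holding only majority rows.
#' @param config a \code{\link{ppdp_config}}.
#' @return list with \code{reduced} (a \code{labeled_dataset}),
#'   \code{s_box}, \code{s_mtd}, \code{box_stats} and \code{mtd_models}
#'   (per-feature lists), and \code{removed_row_ids} (list of row indices
#'   into \code{majority}, components \code{box} and \code{mtd}).
#' @export
undersample_majority <- function(majority, config = ppdp_config()) {
  stopifnot(inherits(majority, "labeled_dataset"))
  x <- majority$features
  if (nrow(x) == 0L) stop("majority class is empty")

  box_stats <- lapply(seq_len(ncol(x)), function(j)
    compute_box_stats(x[, j], config$quartile_convention))
  box_bad <- Reduce(`|`, lapply(seq_len(ncol(x)), function(j) {
    bs <- box_stats[[j]]
    x[, j] < bs$lif | x[, j] > bs$uif
  }), init = rep(FALSE, nrow(x)))
  removed_box <- which(box_bad)
  keep1 <- which(!box_bad)
  if (length(keep1) == 0L)
    stop("box-whisker stage removed the entire majority class")

  x1 <- x[keep1, , drop = FALSE]
  mtd_models <- lapply(seq_len(ncol(x1)), function(j) fit_mtd(x1[, j]))
  mtd_bad <- Reduce(`|`, lapply(seq_len(ncol(x1)), function(j) {
    m <- mtd_models[[j]]
    if (m$variance == 0 || m$degenerate) rep(FALSE, nrow(x1))
    else !filter_by_alpha_cut(x1[, j], m, config$alpha)
  }), init = rep(FALSE, nrow(x1)))
  removed_mtd <- keep1[mtd_bad]
  keep2 <- keep1[!mtd_bad]
  if (length(keep2) == 0L)
    stop("alpha-cut removed entire majority class; lower alpha")

  names(box_stats) <- names(mtd_models) <- majority$feature_names
  list(reduced = .ds_rows(majority, keep2),
       s_box = length(removed_box), s_mtd = length(removed_mtd),
       box_stats = box_stats, mtd_models = mtd_models,
       removed_row_ids = list(box = removed_box, mtd = removed_mtd))
}

#' Oversample the minority class with Weibull synthetic rows
#'
#' Each feature is fitted independently with \code{\link{fit_weibull}} on
#' all minority rows (no outlier removal on the minority side), and
#' \code{n_synthetic} synthetic rows are appended, feature columns generated
#' by \code{\link{generate_samples}} and labelled positive.
#'
#' @param minority a \code{labeled_dataset} holding only minority rows
#'   (at least 3).
#' @param n_synthetic number of synthetic rows to append, >= 0.
#' @param config a \code{\link{ppdp_config}}.
#' @return list with \code{extended} (a \code{labeled_dataset}) and
#'   \code{fits} (per-feature \code{weibull_fit}s).
#' @export
oversample_minority <- function(minority, n_synthetic, config = ppdp_config()) {
  stopifnot(inherits(minority, "labeled_dataset"))
  if (nrow(minority$features) < 3L)
    stop("minority class size must be at least three")
  if (n_synthetic < 0) stop("n_synthetic must be nonnegative")
  fits <- lapply(seq_len(ncol(minority$features)), function(j)
    fit_weibull(minority$features[, j], config$grid))
  names(fits) <- minority$feature_names
  if (n_synthetic == 0L) return(list(extended = minority, fits = fits))
  synth <- vapply(fits, function(f)
    generate_samples(f, n_synthetic, config$generation_mode),
    numeric(n_synthetic))
  synth <- matrix(synth, nrow = n_synthetic,
                  dimnames = list(NULL, minority$feature_names))
  out <- minority
  out$features <- rbind(minority$features, synth)
  out$labels <- c(minority$labels, rep(minority$positive_label, n_synthetic))
  list(extended = out, fits = fits)
}

#' Balance an imbalanced binary dataset
#'
#' The full pipeline: split by class, undersample the majority
#' (box-whisker then alpha-cut), fit per-feature Weibull models to the
#' minority, and append synthetic minority rows until the classes balance.
#' With M majority and m minority rows in, the output holds
#' M' = M - s_box - s_mtd majority rows and m' = M' minority rows
#' (m original plus M' - m synthetic), provided M' > m; otherwise no rows
#' are synthesised and a warning is emitted. The run is deterministic given
#' \code{config$seed}.
#'
#' @param dataset a \code{labeled_dataset}.
#' @param config a \code{\link{ppdp_config}}.
#' @return list with \code{balanced} (a \code{labeled_dataset}) and
#'   \code{report} (a \code{ppdp_report}).
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60 * 2, 10), ncol = 2),
#'            matrix(rweibull(3 * 2, 2, 2) + 8, ncol = 2))
#' ds <- labeled_dataset(x, rep(c("neg", "pos"), c(60, 3)), "pos")
#' res <- ppdp_resample(ds, ppdp_config(alpha = 0.5, seed = 7))
#' res$report
#' @export
ppdp_resample <- function(dataset, config = ppdp_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "ppdp_config"))
  set.seed(config$seed)
  parts <- split_by_class(dataset)
  m_major <- nrow(parts$majority$features)
  m_minor <- nrow(parts$minority$features)
  us <- undersample_majority(parts$majority, config)
  m_major_prime <- nrow(us$reduced$features)
  n_synthetic <- max(m_major_prime - m_minor, 0L)
  if (m_major_prime <= m_minor)
    warning("classes already balanced after undersampling; no synthesis")
  os <- oversample_minority(parts$minority, n_synthetic, config)
  balanced <- us$reduced
  balanced$features <- rbind(us$reduced$features, os$extended$features)
  balanced$labels <- c(us$reduced$labels, os$extended$labels)
  per_feature <- lapply(dataset$feature_names, function(nm)
    list(box_stats = us$box_stats[[nm]],
         mtd_model = us$mtd_models[[nm]],
         weibull_fit = os$fits[[nm]]))
  names(per_feature) <- dataset$feature_names
  report <- structure(
    list(m_major = m_major, s_box = us$s_box, s_mtd = us$s_mtd,
         m_major_prime = m_major_prime,
         m_minor = m_minor, n_synthetic = n_synthetic,
         m_minor_prime = m_minor + n_synthetic,
         alpha = config$alpha, seed = config$seed,
         generation_mode = config$generation_mode,
         per_feature = per_feature,
         removed_row_ids = us$removed_row_ids),
    class = "ppdp_report"
  )
  list(balanced = balanced, report = report)
}

#' @export
print.ppdp_report <- function(x, ...) {
  cat("PPDP resampling report\n")
  cat(sprintf("  majority: M = %d, removed %d (box) + %d (alpha-cut) -> M' = %d\n",
              x$m_major, x$s_box, x$s_mtd, x$m_major_prime))
  cat(sprintf("  minority: m = %d, + %d synthetic -> m' = %d\n",
              x$m_minor, x$n_synthetic, x$m_minor_prime))
  cat(sprintf("  alpha = %g, seed = %d, generation mode = %s\n",
              x$alpha, x$seed, x$generation_mode))
  invisible(x)
}

#' Read a labelled dataset from CSV
#'
#' The file must have a header row, a label column, and numeric feature
#' columns with no missing values.
#'
#' @param path file path.
#' @param label_column name of the label column.
#' @param positive_label optional positive-class value (default: the less
#'   frequent class).
#' @return a \code{labeled_dataset}.
#' @export
read_labeled_csv <- function(path, label_column, positive_label = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found in ", path)
  labels <- as.character(df[[label_column]])
  feats <- df[setdiff(names(df), label_column)]
  for (nm in names(feats)) {
    if (!is.numeric(feats[[nm]]))
      stop("feature column '", nm, "' is not numeric")
    if (anyNA(feats[[nm]]))
      stop(sprintf("missing value in column '%s', row %d",
                   nm, which(is.na(feats[[nm]]))[1L]))
  }
  labeled_dataset(as.matrix(feats), labels, positive_label)
}

#' Write a labelled dataset to CSV
#'
#' Numeric values are written with 17 significant digits so that a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param dataset a \code{labeled_dataset}.
#' @param path file path.
#' @param label_column name for the label column (default \code{"class"}).
#' @export
write_labeled_csv <- function(dataset, path, label_column = "class") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  df <- as.data.frame(
    apply(dataset$features, 2, function(v) sprintf("%.17g", v)),
    check.names = FALSE
  )
  df[[label_column]] <- dataset$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

# strip S3 classes recursively so jsonlite serialises plain lists
.unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), .unclass_deep) else x
}

#' Serialise a resampling report to JSON
#'
#' @param report a \code{ppdp_report}.
#' @param path output file path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "ppdp_report"))
  jsonlite::write_json(.unclass_deep(report), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
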