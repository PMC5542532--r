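# Monte Carlo sampler of the Gini statistic under the Weibull-shape null.
# Under H0 the normalised spacings W_i are i.i.d. unit exponentials, so G_N
# can be simulated directly from exponentials without touching the package's
# spacing computation -- an independent oracle for the exact CDF.
simulate_gini_null <- function(n, replicates) {
  w <- matrix(stats::rexp(replicates * n), replicates)
  as.vector((w[, -1, drop = FALSE] %*% seq_len(n - 1)) /
              ((n - 1) * rowSums(w)))
}

# brute-force counts for a confusion table
counts <- function(tp, fn, fp, tn) {
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_counts")
}

# single-class row subset (bypasses the two-class constructor check)
.ds_rows_for_test <- function(ds, idx) {
  out <- ds
  out$features <- ds$features[idx, , drop = FALSE]
  out$labels <- ds$labels[idx]
  out
}

# a small two-feature imbalanced dataset at the heavy-imbalance scenario
# scale; few features so the union alpha-cut leaves a usable majority core
small_fixture <- function(seed = 1, n_major = 57, n_minor = 3, p = 2) {
  make_synthetic_imbalanced(fixture_spec(
    n_major = n_major, n_minor = n_minor, p = p,
    outlier_rate = 0, seed = seed))
}
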