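Package: ppdp
Title: Representative Undersampling and Weibull Oversampling for Imbalanced Binary Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pre-processing for imbalanced two-class numeric data sets. The
    majority class is reduced to its representative core by Tukey box-whisker
    outlier removal followed by Mega-Trend-Diffusion alpha-cut filtering; the
    minority class is enlarged by fitting a two-parameter Weibull distribution
    per feature -- the shape chosen by maximising the p-value of an exact
    Gini-spacings goodness-of-fit test, the scale by median-rank least
    squares -- and generating synthetic samples by median-rank inversion.
    Includes confusion-matrix metrics for imbalanced evaluation (accuracy,
    G-mean, F-measure), a synthetic-data generator, and a scenario harness
    for repeated train/test experiments with a pluggable classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
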