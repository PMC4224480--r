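#' Welch two-sample t test (vectorized over features)
#'
#' Unequal-variance t statistic
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p value from
#' Student's t distribution. `x` and `y` may be vectors (one feature) or
#' matrices with features in rows and samples in columns.
#'
#' @param x,y numeric vectors, or matrices with equal row counts.
#' @return data.frame with columns `t`, `df`, `p` (one row per feature).
#' @examples
#' welchTest(c(10.1, 9.8, 10.3, 10.0), c(8.9, 9.2, 9.0, 9.3))
#' @export
welchTest <- function(x, y) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  nx <- ncol(x); ny <- ncol(y)
  if (nx < 2 || ny < 2) stop("each group needs at least 2 values")
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  if (any(vx + vy == 0)) stop("both group variances are zero")
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  data.frame(t = tstat, df = df, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up construction (`stats::p.adjust(method = "BH")`) with
#' input validation; q values are returned in the input order and satisfy
#' `q >= p`, `q <= 1`, and monotonicity in p.
#'
#' @param p numeric vector of p values in [0, 1].
#' @return vector of q values (BH-adjusted p values).
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Univariate screen of a feature matrix
#'
#' For every non-internal-standard feature: a Welch t test of case versus
#' control integrated areas, the case/control fold change of arithmetic
#' means, the BH q value (computed over all features entering the screen),
#' and quality-control proxies for extracted-ion-chromatogram review -- the
#' maximum per-sample area must exceed `min_peak_height` and the feature
#' must be present (nonzero) in at least `min_presence_fraction` of samples.
#' A feature passes the screen iff `p < alpha` and both QC rules hold.
#'
#' @param ms a normalized, merged [MetaboSet-class] whose `colData` carries
#'   `diagnosis` with both classes.
#' @param alpha uncorrected significance threshold (default 0.05).
#' @param min_peak_height area units (default 3000).
#' @param min_presence_fraction fraction of samples with nonzero area.
#' @return data.frame (one row per screened feature): feature_id, platform,
#'   t_statistic, df, p_value, q_value, fold_change, max_peak_height_proxy,
#'   presence_fraction, qc_pass, passed_screen. The attribute `"counts"`
#'   records n_tested, n_significant, n_qc_removed and n_passed
#'   (n_significant - n_qc_removed == n_passed).
#' @export
screenFeatures <- function(ms, alpha = 0.05, min_peak_height = 3000,
                           min_presence_fraction = 0.5) {
  stopifnot(is(ms, "MetaboSet"))
  d <- diagnosis(ms)
  if (is.null(d) || length(unique(d[!is.na(d)])) < 2)
    stop("diagnosis must contain both classes")
  keep <- !isInternalStandard(ms)
  a <- areas(ms)[keep, , drop = FALSE]
  fd <- featureData(ms)[keep, , drop = FALSE]
  case <- a[, d == "case", drop = FALSE]
  ctrl <- a[, d == "control", drop = FALSE]
  wt <- welchTest(case, ctrl)
  fold <- rowMeans(case) / rowMeans(ctrl)
  maxh <- apply(a, 1, max)
  pres <- rowMeans(a > 0)
  q <- bhAdjust(wt$p)
  qc <- maxh > min_peak_height & pres >= min_presence_fraction
  sig <- wt$p < alpha
  out <- data.frame(feature_id = fd$feature_id, platform = fd$platform,
                    t_statistic = wt$t, df = wt$df, p_value = wt$p,
                    q_value = q, fold_change = fold,
                    max_peak_height_proxy = maxh, presence_fraction = pres,
                    qc_pass = qc, passed_screen = sig & qc,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(n_tested = nrow(out), n_significant = sum(sig),
                           n_qc_removed = sum(sig & !qc),
                           n_passed = sum(sig & qc))
  out
}

#' Subset a MetaboSet to the features passing a screen
#'
#' @param ms the screened [MetaboSet-class].
#' @param screen result of [screenFeatures()].
#' @return [MetaboSet-class] restricted to `passed_screen` features.
#' @export
modelingSet <- function(ms, screen) {
  keep <- screen$feature_id[screen$passed_screen]
  ms[rownames(ms) %in% keep, ]
}

#' Write a univariate screening table
#'
#' Tab-delimited, mirroring the usual reporting columns (feature id, fold
#' change, p, FDR) plus QC flags.
#'
#' @param screen result of [screenFeatures()].
#' @param path output file.
#' @export
writeScreenTable <- function(screen, path) {
  write.table(screen, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
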