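# Two-way mixed-effects, absolute-agreement, single-rater intraclass
# correlation with F-based 95% confidence intervals, negative truncation,
# and four-category stratification of reliability.

#' Intraclass correlation (two-way, absolute agreement, single rater)
#'
#' Computes the two-way ANOVA decomposition of an n-subjects x k-raters
#' matrix (raters are settings profiles or platform versions) and the
#' single-measure absolute-agreement ICC
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' where MSR, MSC and MSE are the subject, rater and residual mean squares.
#' The mixed- and random-effects two-way models share this point estimate.
#' The confidence interval is the standard F-based interval for this ICC
#' form. The estimate and both CI bounds are truncated at zero and the
#' upper bound capped at one.
#'
#' Degenerate inputs are resolved by convention and flagged: if the matrix
#' has no rater or residual variation (columns identical), agreement is
#' exact and the ICC is 1 with CI (1, 1); if the matrix is entirely
#' constant, the ICC is likewise defined as 1 with CI (1, 1).
#'
#' @param values Numeric n x k matrix, n >= 2 subjects in rows, k >= 2
#'   raters in columns. Rows with missing cells are dropped listwise.
#' @param feature_name Optional label carried through to reports.
#' @param conf Confidence level (default 0.95).
#' @return An `icc_result`: estimate, ci_low, ci_high, ms_rows, ms_cols,
#'   ms_error, n, k, n_dropped, flag (`""`, `"exact_agreement"` or
#'   `"zero_variance"`), and the categories from [classify_reliability()].
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(40), 10, 4) + rnorm(10)  # subject effects
#' icc_absolute_agreement(m)
#' @export
icc_absolute_agreement <- function(values, feature_name = NULL, conf = 0.95) {
  values <- as.matrix(values)
  keep <- stats::complete.cases(values)
  n_dropped <- sum(!keep)
  values <- values[keep, , drop = FALSE]
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2)
    stop("need at least 2 subjects and 2 raters after listwise deletion",
         call. = FALSE)
  grand <- mean(values)
  rm <- rowMeans(values); cm <- colMeans(values)
  ssr <- k * sum((rm - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((values - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  scale <- max(msr, msc, mse, 0)
  flag <- ""
  if (sst <= .Machine$double.eps * max(1, abs(grand))^2 * n * k) {
    est <- 1; lo <- 1; hi <- 1; flag <- "zero_variance"
  } else if (msc <= 1e-10 * scale && mse <= 1e-10 * scale) {
    est <- 1; lo <- 1; hi <- 1; flag <- "exact_agreement"
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    alpha <- 1 - conf
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    # the F interval can break down numerically for strongly negative raw
    # estimates; fall back to the uninformative bound on that side
    if (!is.finite(lo)) { lo <- 0; flag <- "ci_degenerate" }
    if (!is.finite(hi)) { hi <- 1; flag <- "ci_degenerate" }
  }
  # truncation at zero, cap at one, enforce ordering around the estimate
  est <- min(max(est, 0), 1)
  lo <- min(max(lo, 0), est)
  hi <- max(min(hi, 1), est)
  res <- structure(list(feature_name = feature_name, estimate = est,
                        ci_low = lo, ci_high = hi,
                        ms_rows = msr, ms_cols = msc, ms_error = mse,
                        n = n, k = k, n_dropped = n_dropped, flag = flag),
                   class = "icc_result")
  cls <- classify_reliability(res)
  res$category <- cls$category
  res$category_estimate <- cls$category_estimate
  res$category_upper <- cls$category_upper
  res$straddle <- cls$straddle
  res
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result>%s ICC = %.4f, %s CI (%.4f, %.4f) -> %s%s%s\n",
              if (is.null(x$feature_name)) "" else paste0(" ", x$feature_name),
              x$estimate, "95%", x$ci_low, x$ci_high, x$category,
              if (x$straddle) " [CI straddles categories]" else "",
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

reliability_category <- function(x) {
  # boundaries assigned to the lower category
  if (x <= 0.5) "poor" else if (x <= 0.75) "moderate"
  else if (x <= 0.9) "good" else "excellent"
}

#' Stratify an ICC result into reliability categories
#'
#' Thresholds 0.5 / 0.75 / 0.9 separate poor, moderate, good and excellent
#' reliability. The primary `category` applies the thresholds to the CI
#' lower bound (the conservative reading); categories for the point
#' estimate and the CI upper bound are also reported, with a `straddle`
#' flag when the two CI bounds fall in different categories. Boundary
#' values are assigned to the lower category.
#'
#' @param res An [icc_absolute_agreement()] result, or a list with
#'   `estimate`, `ci_low`, `ci_high`.
#' @return List: `category`, `category_estimate`, `category_upper`,
#'   `straddle`.
#' @export
classify_reliability <- function(res) {
  lo <- reliability_category(res$ci_low)
  up <- reliability_category(res$ci_high)
  list(category = lo,
       category_estimate = reliability_category(res$estimate),
       category_upper = up,
       straddle = !identical(lo, up))
}

#' Per-feature reliability study across settings profiles
#'
#' For every canonical feature, assembles the subjects x raters matrix from
#' a long feature table (one row per subject-profile pair) and computes the
#' absolute-agreement ICC with CI and categories. Raters can be subset
#' (e.g. dropping a non-standard profile from the comparison). Features
#' that are constant over all subjects and raters carry no reliability
#' information; they are flagged `constant` and excluded from category
#' summaries.
#'
#' @param table A feature table from [extract_features()] (columns
#'   `subject`, `profile`, features).
#' @param raters Character vector of profile labels to compare (>= 2);
#'   default all profiles present.
#' @param features Feature columns to analyse; default the canonical 17.
#' @param conf Confidence level.
#' @return A `reliability_study` data frame: one row per feature with
#'   estimate, CI, mean squares, categories, straddle and flags.
#' @export
reliability_study <- function(table, raters = NULL,
                              features = canonical_feature_names(),
                              conf = 0.95) {
  stopifnot(is.data.frame(table), all(c("subject", "profile") %in% names(table)))
  if (is.null(raters)) raters <- unique(table$profile)
  if (length(raters) < 2) stop("need at least 2 raters", call. = FALSE)
  missing_r <- setdiff(raters, unique(table$profile))
  if (length(missing_r))
    stop("raters not present in table: ", paste(missing_r, collapse = ", "),
         call. = FALSE)
  missing_f <- setdiff(features, names(table))
  if (length(missing_f))
    stop("features not present in table: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  subjects <- unique(table$subject)
  rows <- lapply(features, function(f) {
    m <- sapply(raters, function(r) {
      v <- table[table$profile == r, ]
      v[[f]][match(subjects, v$subject)]
    })
    m <- matrix(m, nrow = length(subjects),
                dimnames = list(NULL, raters))
    if (max(m, na.rm = TRUE) - min(m, na.rm = TRUE) == 0) {
      return(data.frame(feature = f, estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, ms_rows = NA_real_,
                        ms_cols = NA_real_, ms_error = NA_real_,
                        n = sum(stats::complete.cases(m)), k = length(raters),
                        category = NA_character_,
                        category_estimate = NA_character_,
                        straddle = NA, flag = "constant",
                        stringsAsFactors = FALSE))
    }
    r <- icc_absolute_agreement(m, feature_name = f, conf = conf)
    data.frame(feature = f, estimate = r$estimate, ci_low = r$ci_low,
               ci_high = r$ci_high, ms_rows = r$ms_rows, ms_cols = r$ms_cols,
               ms_error = r$ms_error, n = r$n, k = r$k,
               category = r$category, category_estimate = r$category_estimate,
               straddle = r$straddle, flag = r$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reliability_study", "data.frame")
  attr(out, "raters") <- raters
  out
}

#' Category counts of a reliability study
#'
#' The "x / 17 features excellent" style summary: counts of analysable
#' features per reliability category (constant-feature rows are excluded
#' and reported separately).
#'
#' @param study A [reliability_study()] result.
#' @return Data frame with columns `category`, `count`, plus attributes
#'   `n_features` and `n_constant`.
#' @export
reliability_summary <- function(study) {
  stopifnot(inherits(study, "reliability_study"))
  ok <- is.na(study$flag) | study$flag != "constant"
  lev <- c("poor", "moderate", "good", "excellent")
  counts <- table(factor(study$category[ok], levels = lev))
  out <- data.frame(category = lev, count = as.integer(counts))
  attr(out, "n_features") <- sum(ok)
  attr(out, "n_constant") <- sum(!ok)
  out
}

#' Boxplot-style view of a reliability study
#'
#' Plots each feature's ICC estimate with its CI segment, coloured by
#' category, mirroring the per-feature interval plots used in multi-rater
#' reliability reports.
#'
#' @param x A [reliability_study()] result.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.reliability_study <- function(x, ...) {
  ok <- !is.na(x$estimate)
  d <- x[ok, ]
  cols <- c(poor = "firebrick", moderate = "darkorange",
            good = "goldenrod", excellent = "forestgreen")
  graphics::plot(seq_len(nrow(d)), d$estimate, ylim = c(0, 1), pch = 19,
                 col = cols[d$category], xaxt = "n", xlab = "",
                 ylab = "ICC (absolute agreement)", ...)
  graphics::segments(seq_len(nrow(d)), d$ci_low, seq_len(nrow(d)), d$ci_high,
                     col = cols[d$category])
  graphics::abline(h = c(0.5, 0.75, 0.9), lty = 3, col = "grey50")
  graphics::axis(1, at = seq_len(nrow(d)), labels = d$feature, las = 2,
                 cex.axis = 0.6)
  invisible(x)
}
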