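# Univariable survival screen: per-feature standardisation, Cox
# proportional-hazards fit (Efron ties), p-value binning, and the
# profile-by-profile heat-map table.

#' Survival cohort container
#'
#' @param time Follow-up time in years (> 0).
#' @param event Binary death indicator (0/1 or logical).
#' @param ids Optional subject identifiers aligned with a feature table.
#' @return A `survival_cohort` data frame with columns `id`, `time`,
#'   `event`.
#' @export
survival_cohort <- function(time, event, ids = NULL) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("follow-up times must be positive", call. = FALSE)
  if (!all(event %in% c(0L, 1L)))
    stop("event must be binary 0/1", call. = FALSE)
  if (sum(event) < 2)
    stop("need at least 2 events for survival modelling", call. = FALSE)
  if (is.null(ids)) ids <- seq_along(time)
  if (length(ids) != length(time) || length(event) != length(time))
    stop("id/time/event lengths differ", call. = FALSE)
  structure(data.frame(id = ids, time = time, event = event),
            class = c("survival_cohort", "data.frame"))
}

#' Standardise a feature column to mean 0, SD 1
#'
#' Subtracts the mean and divides by the sample (n-1) standard deviation,
#' so hazard ratios are comparable across features as "per one SD".
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Standardised vector (mean 0, SD 1).
#' @export
standardise <- function(x) {
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("constant feature, excluded from screen", call. = FALSE)
  (x - mean(x)) / s
}

p_value_bin <- function(p) {
  if (!is.finite(p)) return(NA_character_)
  if (p < 0.05) "lt_0.05" else if (p < 0.1) "0.05_to_0.1" else "gt_0.1"
}

#' Univariable Cox proportional-hazards fit for one standardised feature
#'
#' Maximises the Efron-tie partial likelihood (via the survival package)
#' for a single covariate and reports the per-SD log-hazard, hazard ratio,
#' standard error, Wald p value and the heat-map p bin
#' (`lt_0.05`, `0.05_to_0.1`, `gt_0.1`). Monotone-likelihood
#' non-convergence (a covariate that perfectly separates event order) is
#' flagged as an infinite-hazard result rather than an error.
#'
#' @param cohort A [survival_cohort()].
#' @param z Numeric covariate, typically a [standardise()]d feature.
#' @return A `cox_result`: `beta`, `hr`, `se`, `p`, `bin`, `infinite`,
#'   `n`, `events`.
#' @export
cox_univariable <- function(cohort, z) {
  stopifnot(inherits(cohort, "survival_cohort"))
  z <- as.numeric(z)
  if (length(z) != nrow(cohort))
    stop("covariate length differs from cohort size", call. = FALSE)
  if (length(unique(z)) < 2)
    stop("constant feature, excluded from screen", call. = FALSE)
  infinite <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(cohort$time, cohort$event) ~ z,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged", conditionMessage(w)))
        infinite <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  p <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(beta = beta, hr = exp(beta), se = se, p = p,
                 bin = p_value_bin(p), infinite = infinite,
                 n = nrow(cohort), events = sum(cohort$event)),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> beta/SD = %.4f (HR %.3f, se %.4f), p = %.4g [%s]%s\n",
              x$beta, x$hr, x$se, x$p, x$bin,
              if (x$infinite) " [monotone likelihood]" else ""))
  invisible(x)
}

#' Univariable screen of all features across settings profiles
#'
#' For every (canonical feature, profile) cell: standardise the feature
#' within that profile, fit the univariable Cox model against overall
#' survival, and report the coefficient, hazard ratio, Wald p value and p
#' bin. Per-feature failures (constant features, degenerate fits) are
#' recorded in the cell's `note` rather than aborting the screen, mirroring
#' a heat-map in which some cells are simply unavailable.
#'
#' @param table A feature table from [extract_features()].
#' @param cohort A [survival_cohort()] whose `id`s match `table$subject`.
#' @param profiles Profile labels to screen; default all in the table.
#' @param features Feature columns; default the canonical 17.
#' @param p_adjust Optional multiple-testing correction applied across
#'   features within each profile (e.g. `"BH"`); the default `"none"`
#'   reports raw p values, which is also what the screen's bins use.
#' @return Data frame with columns `feature`, `profile`, `beta`, `hr`,
#'   `se`, `p`, `p_adj`, `bin`, `note`.
#' @export
survival_screen <- function(table, cohort, profiles = NULL,
                            features = canonical_feature_names(),
                            p_adjust = "none") {
  stopifnot(is.data.frame(table), inherits(cohort, "survival_cohort"))
  if (is.null(profiles)) profiles <- unique(table$profile)
  rows <- list()
  for (pr in profiles) {
    sub <- table[table$profile == pr, ]
    m <- match(cohort$id, sub$subject)
    if (anyNA(m))
      stop(sprintf("profile '%s': cohort subjects missing from table", pr),
           call. = FALSE)
    sub <- sub[m, ]
    for (f in features) {
      cell <- tryCatch({
        res <- cox_univariable(cohort, standardise(sub[[f]]))
        data.frame(feature = f, profile = pr, beta = res$beta, hr = res$hr,
                   se = res$se, p = res$p, bin = res$bin,
                   note = if (res$infinite) "monotone_likelihood" else "",
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(feature = f, profile = pr, beta = NA_real_, hr = NA_real_,
                   se = NA_real_, p = NA_real_, bin = NA_character_,
                   note = conditionMessage(e), stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::ave(out$p, out$profile, FUN = function(p)
    stats::p.adjust(p, method = p_adjust))
  out <- out[, c("feature", "profile", "beta", "hr", "se", "p", "p_adj",
                 "bin", "note")]
  class(out) <- c("survival_screen", "data.frame")
  out
}
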