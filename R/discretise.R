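# Grey-level discretisation of masked intensities.
#
# All three dialects share the half-open bin convention
# [lo + (k-1)*delta, lo + k*delta) with the top edge closed, so that the
# masked maximum maps to the last bin and the voxel count is conserved.

resolve_bound <- function(b, x) {
  if (is.null(b)) return(NULL)
  if (identical(b, "roi_min")) return(min(x))
  if (identical(b, "roi_max")) return(max(x))
  b
}

#' Discretise the ROI intensities of a volume under a profile
#'
#' Maps each masked voxel's intensity to an integer grey level according to
#' the discretisation block of the profile for the requested matrix family
#' (`histogram`, `glcm` or `ngtdm` — platform defaults may differ between
#' families).
#'
#' Modes:
#' * fixed bin number over the ROI range: `g = floor(Ng*(x-lo)/(hi-lo)) + 1`
#'   with `lo`/`hi` the masked minimum/maximum and `x = hi` clamped to `Ng`;
#' * fixed bin number over fixed bounds: same formula with the profile's
#'   numeric bounds; out-of-range intensities are clamped into the end bins
#'   (never dropped, so the level histogram conserves the voxel count);
#' * fixed bin width: `g = floor((x-lo)/w) + 1`, anchored at the (numeric or
#'   symbolic) lower bound; intensities below the anchor clamp to level 1 and
#'   a numeric upper bound, when present, caps the levels.
#'
#' A flat ROI (or collapsed resolved range) is handled by convention: every
#' voxel gets level 1 and the result is flagged `degenerate` so downstream
#' texture features can take their homogeneous-ROI conventions.
#'
#' @param vm A [volume_with_mask()].
#' @param profile A [settings_profile()] (or a name/path accepted by
#'   [read_profile()]).
#' @param family Which discretisation block to use.
#' @return A `discretised_roi`: list with `levels` (integer array on the
#'   original grid, `NA` outside the mask), `mask`, `ng_eff` (highest
#'   occupied level), `resolved_bounds`, `mode` and `degenerate` flag.
#' @examples
#' vm <- volume_with_mask(array(c(10, 20, 30, 40, 0, 0, 0, 0), c(2, 2, 2)),
#'                        array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2)))
#' p <- settings_profile("fbn4", disc_settings("fixed_bin_number_roi_range", 4))
#' d <- discretise(vm, p)
#' d$levels[vm$mask]  # 1 2 3 4
#' @export
discretise <- function(vm, profile, family = c("histogram", "glcm", "ngtdm")) {
  stopifnot(inherits(vm, "volume_with_mask"))
  profile <- read_profile(profile)
  family <- match.arg(family)
  ds <- switch(family, histogram = profile$disc, glcm = profile$glcm_disc,
               ngtdm = profile$ngtdm_disc)
  x <- vm$intensity[vm$mask]
  degenerate <- FALSE
  if (ds$mode == "fixed_bin_width") {
    lo <- resolve_bound(ds$lower, x)
    hi <- if (is.numeric(ds$upper)) ds$upper else NULL
    xx <- pmax(x, lo)
    if (!is.null(hi)) xx <- pmin(xx, hi)
    g <- as.integer(floor((xx - lo) / ds$bin_width)) + 1L
    bounds <- c(lo, if (is.null(hi)) NA_real_ else hi)
  } else {
    if (ds$mode == "fixed_bin_number_roi_range") {
      lo <- min(x); hi <- max(x)
    } else {
      lo <- resolve_bound(ds$lower, x); hi <- resolve_bound(ds$upper, x)
    }
    ng <- ds$n_bins
    if (hi <= lo) {
      degenerate <- TRUE
      g <- rep(1L, length(x))
    } else {
      xx <- pmin(pmax(x, lo), hi)
      g <- as.integer(floor(ng * (xx - lo) / (hi - lo))) + 1L
      g[g > ng] <- ng
    }
    bounds <- c(lo, hi)
  }
  if (length(unique(g)) == 1L) degenerate <- TRUE
  levels <- array(NA_integer_, dim(vm$mask))
  levels[vm$mask] <- g
  structure(list(levels = levels, mask = vm$mask,
                 ng_eff = max(g), resolved_bounds = bounds,
                 mode = ds$mode, degenerate = degenerate),
            class = "discretised_roi")
}

#' @export
print.discretised_roi <- function(x, ...) {
  cat(sprintf("<discretised_roi> %s, %d voxels, levels 1..%d%s\n",
              x$mode, sum(x$mask), x$ng_eff,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
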