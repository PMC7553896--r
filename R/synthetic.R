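# Synthetic stand-ins for the clinical inputs: CT-like tumour phantoms
# (ellipsoidal masks with spatially correlated intensity texture), survival
# cohorts with a planted feature-hazard link, and multi-rater ratings
# matrices with known variance components. All generators are pure
# functions of their spec and seed.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# separable Gaussian smoothing of a 3D array (reflected edges)
gaussian_smooth3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in 1:3) {
    x <- aperm(x, c(axis, setdiff(1:3, axis)))
    d <- dim(x)
    m <- matrix(x, d[1], d[2] * d[3])
    pad_top <- m[pmin(r:1, d[1]), , drop = FALSE]
    pad_bot <- m[pmax(d[1] - (1:r) + 1, 1), , drop = FALSE]
    mp <- rbind(pad_top, m, pad_bot)
    sm <- stats::filter(mp, k, sides = 2)
    m <- sm[(r + 1):(r + d[1]), , drop = FALSE]
    x <- array(m, d)
    x <- aperm(x, order(c(axis, setdiff(1:3, axis))))
  }
  x
}

#' Specification of a synthetic tumour phantom
#'
#' Describes a CT-like phantom: an ellipsoidal (optionally lobulated)
#' region of interest inside a grid with anisotropic voxel spacing, filled
#' with a base intensity plus a spatially correlated Gaussian texture field
#' (Gaussian-filtered white noise rescaled to a target SD) plus independent
#' voxel noise. Defaults emulate a contrast-enhanced soft-tissue tumour on
#' a radiotherapy planning CT: ~1 mm in-plane resolution with 3 mm slices,
#' semi-axes of 18 x 14 x 12 mm (~13 mL), base 45 HU with 25 HU of
#' correlated heterogeneity and 10 HU of uncorrelated noise.
#'
#' @param grid Integer length-3 grid shape (voxels).
#' @param spacing Voxel spacing in mm.
#' @param semi_axes Ellipsoid semi-axes in mm.
#' @param lobulation Relative amplitude of the angular boundary
#'   perturbation (0 = smooth ellipsoid).
#' @param base Base intensity (HU).
#' @param gradient_amplitude Amplitude (HU) of a deterministic radial
#'   enhancement profile `A * (1 - rho^2)` inside the ROI (`rho` is the
#'   normalised ellipsoid radius), emulating centre-to-rim contrast
#'   enhancement; 0 disables it. Unlike the stochastic texture, this
#'   component sets the ROI intensity range almost deterministically.
#' @param texture_corr Correlation length of the texture field, in voxels.
#' @param texture_sd SD of the correlated texture component (HU).
#' @param noise_sd SD of the independent voxel noise (HU).
#' @param seed Integer seed; the phantom is deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = c(56, 56, 28), spacing = c(1, 1, 3),
                         semi_axes = c(18, 14, 12), lobulation = 0,
                         base = 45, gradient_amplitude = 0,
                         texture_corr = 3, texture_sd = 25,
                         noise_sd = 10, seed = 1L) {
  grid <- as.integer(grid); spacing <- as.numeric(spacing)
  semi_axes <- as.numeric(semi_axes)
  stopifnot(length(grid) == 3, length(spacing) == 3, length(semi_axes) == 3)
  if (any(semi_axes <= 0)) stop("degenerate ellipsoid axes", call. = FALSE)
  if (texture_sd < 0 || noise_sd < 0 || texture_corr < 0)
    stop("SDs and correlation length must be >= 0", call. = FALSE)
  # the (possibly lobulated) mask must keep a one-voxel margin to the border
  max_r <- semi_axes * (1 + abs(lobulation))
  if (any(max_r / spacing > (grid - 3) / 2))
    stop("mask does not fit inside the grid with a one-voxel margin",
         call. = FALSE)
  structure(list(grid = grid, spacing = spacing, semi_axes = semi_axes,
                 lobulation = lobulation, base = base,
                 gradient_amplitude = gradient_amplitude,
                 texture_corr = texture_corr, texture_sd = texture_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a tumour phantom
#'
#' @param spec A [phantom_spec()].
#' @return A [volume_with_mask()]; bitwise identical for identical specs.
#' @examples
#' vm <- generate_phantom(phantom_spec(seed = 7))
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  centre <- (g + 1) / 2
  cx <- (seq_len(g[1]) - centre[1]) * spec$spacing[1]
  cy <- (seq_len(g[2]) - centre[2]) * spec$spacing[2]
  cz <- (seq_len(g[3]) - centre[3]) * spec$spacing[3]
  X <- array(rep(cx, times = g[2] * g[3]), g)
  Y <- array(rep(rep(cy, each = g[1]), times = g[3]), g)
  Z <- array(rep(cz, each = g[1] * g[2]), g)
  rho <- sqrt((X / spec$semi_axes[1])^2 + (Y / spec$semi_axes[2])^2 +
                (Z / spec$semi_axes[3])^2)
  thr <- 1
  if (spec$lobulation != 0) {
    az <- atan2(Y, X)
    r3 <- sqrt(X^2 + Y^2 + Z^2)
    incl <- ifelse(r3 > 0, acos(pmin(pmax(Z / pmax(r3, 1e-12), -1), 1)), 0)
    thr <- 1 + spec$lobulation * cos(3 * az) * sin(2 * incl)
  }
  mask <- rho <= thr
  gradient <- if (spec$gradient_amplitude != 0)
    spec$gradient_amplitude * pmax(1 - rho^2, 0) else 0
  with_seed(spec$seed, {
    field <- array(stats::rnorm(prod(g)), g)
    if (spec$texture_sd > 0 && spec$texture_corr > 0) {
      field <- gaussian_smooth3d(field, spec$texture_corr)
      field <- field / stats::sd(field) * spec$texture_sd
    } else {
      field <- field * 0
    }
    noise <- if (spec$noise_sd > 0)
      array(stats::rnorm(prod(g), sd = spec$noise_sd), g) else 0
    volume_with_mask(spec$base + gradient + field + noise, mask,
                     spec$spacing)
  })
}

#' Generate a cohort of varied tumour phantoms
#'
#' Draws per-subject phantom specs around the defaults — semi-axes,
#' lobulation, base intensity, texture SD, correlation length and noise SD
#' each varied across stated ranges — and generates the volumes. The
#' per-subject latent parameters are returned alongside so studies can
#' plant outcome links on a known trait.
#'
#' @param n Number of subjects.
#' @param seed Integer seed (per-subject phantom seeds derive from it).
#' @param grid,spacing Passed to every [phantom_spec()].
#' @param semi_axis_range Multiplicative range applied to the default
#'   semi-axes.
#' @param lobulation_range,base_range,texture_sd_range,texture_corr_range,noise_sd_range
#'   Ranges for the per-subject draws.
#' @return List with `volumes` (list of [volume_with_mask()]) and `traits`
#'   (data frame of the per-subject parameters, `subject` = 1..n).
#' @export
phantom_cohort <- function(n, seed = 1L, grid = c(64, 64, 28),
                           spacing = c(1, 1, 3),
                           semi_axis_range = c(0.7, 1.3),
                           lobulation_range = c(0, 0.25),
                           base_range = c(30, 70),
                           texture_sd_range = c(15, 45),
                           texture_corr_range = c(2, 5),
                           noise_sd_range = c(5, 15)) {
  stopifnot(n >= 1)
  traits <- with_seed(seed, data.frame(
    subject = seq_len(n),
    ax = stats::runif(n, semi_axis_range[1], semi_axis_range[2]) * 18,
    ay = stats::runif(n, semi_axis_range[1], semi_axis_range[2]) * 14,
    az = stats::runif(n, semi_axis_range[1], semi_axis_range[2]) * 12,
    lobulation = stats::runif(n, lobulation_range[1], lobulation_range[2]),
    base = stats::runif(n, base_range[1], base_range[2]),
    texture_sd = stats::runif(n, texture_sd_range[1], texture_sd_range[2]),
    texture_corr = stats::runif(n, texture_corr_range[1], texture_corr_range[2]),
    noise_sd = stats::runif(n, noise_sd_range[1], noise_sd_range[2]),
    phantom_seed = sample.int(2^30, n)))
  volumes <- lapply(seq_len(n), function(i) {
    t <- traits[i, ]
    generate_phantom(phantom_spec(grid = grid, spacing = spacing,
                                  semi_axes = c(t$ax, t$ay, t$az),
                                  lobulation = t$lobulation, base = t$base,
                                  texture_corr = t$texture_corr,
                                  texture_sd = t$texture_sd,
                                  noise_sd = t$noise_sd,
                                  seed = t$phantom_seed))
  })
  list(volumes = volumes, traits = traits)
}

#' Write a phantom cohort as NIfTI pairs with a manifest
#'
#' @param cohort A [phantom_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_phantom_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cohort$volumes)
  manifest <- data.frame(
    subject = cohort$traits$subject,
    image = sprintf("subject%03d_image.nii.gz", seq_len(n)),
    mask = sprintf("subject%03d_mask.nii.gz", seq_len(n)))
  for (i in seq_len(n))
    write_volume_nifti(cohort$volumes[[i]],
                       file.path(dir, manifest$image[i]),
                       file.path(dir, manifest$mask[i]))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(cbind(manifest, cohort$traits[-1]), path,
                   row.names = FALSE)
  invisible(path)
}

#' Specification of a synthetic survival cohort
#'
#' Event times follow an exponential hazard `h0 * exp(beta * z)` for a
#' standardised driving covariate `z`, with administrative censoring at the
#' follow-up horizon. The baseline hazard `h0` is calibrated so that the
#' expected event count matches the target fraction at the horizon. The
#' defaults emulate a head-and-neck cohort: 108 subjects with 28 expected
#' deaths within 2.2 years.
#'
#' @param n Number of subjects.
#' @param horizon Follow-up horizon in years.
#' @param event_fraction Target expected fraction of subjects with an
#'   event by the horizon (strictly between 0 and 1).
#' @param beta Planted log-hazard per SD of the driving covariate.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 108, horizon = 2.2, event_fraction = 28 / 108,
                        beta = 0, seed = 1L) {
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  if (event_fraction <= 0 || event_fraction >= 1)
    stop(sprintf(
      "target event fraction %.3f unattainable: must be strictly in (0, 1)",
      event_fraction), call. = FALSE)
  structure(list(n = as.integer(n), horizon = horizon,
                 event_fraction = event_fraction, beta = beta,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

calibrate_baseline_hazard <- function(spec, z) {
  expected <- function(log_h0)
    mean(1 - exp(-exp(log_h0) * exp(spec$beta * z) * spec$horizon)) -
      spec$event_fraction
  exp(stats::uniroot(expected, lower = -25, upper = 25, tol = 1e-12)$root)
}

#' Generate a survival cohort with a planted feature-hazard link
#'
#' @param spec A [cohort_spec()].
#' @param z Driving covariate per subject (standardised internally unless
#'   constant; `beta = 0` in the spec makes it irrelevant). Length must be
#'   `spec$n`; may be omitted when `beta = 0`.
#' @param ids Optional subject ids.
#' @return A [survival_cohort()] with attributes `baseline_hazard` and
#'   `expected_events`.
#' @export
generate_cohort <- function(spec, z = NULL, ids = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(z)) {
    if (spec$beta != 0)
      stop("a driving covariate is required when beta != 0", call. = FALSE)
    z <- rep(0, spec$n)
  }
  if (length(z) != spec$n) stop("length(z) != n", call. = FALSE)
  if (stats::sd(z) > 0) z <- standardise(z)
  h0 <- calibrate_baseline_hazard(spec, z)
  with_seed(spec$seed, {
    t_event <- stats::rexp(spec$n, rate = h0 * exp(spec$beta * z))
    event <- as.integer(t_event <= spec$horizon)
    time <- pmin(t_event, spec$horizon)
    out <- survival_cohort(time, event, ids = ids)
    attr(out, "baseline_hazard") <- h0
    attr(out, "expected_events") <- spec$n * spec$event_fraction
    out
  })
}

#' Generate a subjects x raters matrix with known variance components
#'
#' `value(s, r) = subject_effect(s) + rater_effect(r) + noise(s, r)`, all
#' independent Gaussians with the given SDs. The theoretical
#' absolute-agreement ICC is
#' `sd_subject^2 / (sd_subject^2 + sd_rater^2 + sd_noise^2)`.
#'
#' @param n,k Numbers of subjects and raters.
#' @param sd_subject,sd_rater,sd_noise Component SDs (>= 0).
#' @param seed Integer seed.
#' @return Numeric n x k matrix.
#' @export
generate_ratings <- function(n, k, sd_subject = 1, sd_rater = 0,
                             sd_noise = 0.5, seed = 1L) {
  stopifnot(n >= 2, k >= 2, sd_subject >= 0, sd_rater >= 0, sd_noise >= 0)
  with_seed(seed, {
    subj <- stats::rnorm(n, sd = sd_subject)
    rate <- stats::rnorm(k, sd = sd_rater)
    noise <- matrix(stats::rnorm(n * k, sd = sd_noise), n, k)
    outer(subj, rate, "+") + noise
  })
}
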