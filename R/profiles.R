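#' @keywords internal
"_PACKAGE"

# ---- discretisation settings -------------------------------------------

DISC_MODES <- c("fixed_bin_number_roi_range", "fixed_bin_width",
                "fixed_bin_number_fixed_range")

#' Discretisation settings block
#'
#' One dialect of grey-level discretisation:
#' * `fixed_bin_number_roi_range` — Ng bins between the masked minimum and
#'   maximum (the classic FBN scheme; invariant under affine rescaling).
#' * `fixed_bin_number_fixed_range` — Ng bins over fixed numeric bounds;
#'   out-of-range intensities are clamped into the end bins.
#' * `fixed_bin_width` — bins of width `bin_width` anchored at `lower`
#'   (FBS); `lower`/`upper` may be numeric or the symbolic bounds
#'   `"roi_min"`/`"roi_max"`, resolved against the masked voxels at
#'   extraction time.
#'
#' @param mode One of the three modes above.
#' @param n_bins Positive integer number of grey levels (FBN modes).
#' @param bin_width Positive bin width in intensity units (FBS mode).
#' @param lower,upper Range bounds: numeric, `"roi_min"`/`"roi_max"`, or
#'   `NULL` (FBS upper bound optional).
#' @return A `disc_settings` list.
#' @export
disc_settings <- function(mode, n_bins = NULL, bin_width = NULL,
                          lower = NULL, upper = NULL) {
  mode <- match.arg(mode, DISC_MODES)
  if (mode %in% c("fixed_bin_number_roi_range", "fixed_bin_number_fixed_range")) {
    if (is.null(n_bins) || n_bins < 2 || n_bins != round(n_bins))
      stop("fixed-bin-number modes require integer n_bins >= 2", call. = FALSE)
    n_bins <- as.integer(n_bins)
  }
  if (mode == "fixed_bin_width") {
    if (is.null(bin_width) || !is.finite(bin_width) || bin_width <= 0)
      stop("fixed_bin_width requires bin_width > 0", call. = FALSE)
    if (is.null(lower))
      stop("fixed_bin_width requires a lower bound (numeric or \"roi_min\")",
           call. = FALSE)
  }
  if (mode == "fixed_bin_number_fixed_range") {
    if (is.null(lower) || is.null(upper))
      stop("fixed_bin_number_fixed_range requires both bounds", call. = FALSE)
  }
  chk_bound <- function(b, nm) {
    if (is.null(b)) return(b)
    if (is.character(b)) {
      if (!b %in% c("roi_min", "roi_max"))
        stop(sprintf("symbolic %s bound must be \"roi_min\" or \"roi_max\"", nm),
             call. = FALSE)
      return(b)
    }
    if (!is.numeric(b) || !is.finite(b)) stop("bounds must be finite", call. = FALSE)
    as.numeric(b)
  }
  lower <- chk_bound(lower, "lower"); upper <- chk_bound(upper, "upper")
  if (is.numeric(lower) && is.numeric(upper) && lower >= upper)
    stop("lower bound must be < upper bound", call. = FALSE)
  structure(list(mode = mode, n_bins = n_bins, bin_width = bin_width,
                 lower = lower, upper = upper),
            class = "disc_settings")
}

# ---- direction sets -----------------------------------------------------

#' Unique 3D co-occurrence directions at Chebyshev distance 1
#'
#' The 26 neighbours of a voxel pair into 13 symmetric direction classes;
#' symmetric co-occurrence accumulation needs only one representative per
#' class.
#'
#' @return Integer 13 x 3 matrix of displacement vectors.
#' @export
glcm_directions_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  # keep the representative whose first non-zero component is positive
  keep <- apply(g, 1, function(v) v[which(v != 0)[1]] > 0)
  d <- g[keep, , drop = FALSE]
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

#' The four canonical in-plane 2D directions
#'
#' Used slice-wise (z displacement 0) and merged, for profiles that define
#' only four co-occurrence directions.
#'
#' @return Integer 4 x 3 matrix.
#' @export
glcm_directions_2d_inplane <- function() {
  matrix(as.integer(c(1, 0, 0,
                      0, 1, 0,
                      1, 1, 0,
                      1, -1, 0)), ncol = 3, byrow = TRUE)
}

# ---- settings profile ---------------------------------------------------

#' Construct a settings profile
#'
#' A settings profile is the complete set of user-defined calculation
#' settings — discretisation per matrix family, co-occurrence directions and
#' offsets, neighbourhood distance — that identifies one "platform" rater.
#' Discretisation may differ between the histogram, GLCM and NGTDM families
#' (as the platform defaults do); `glcm_disc`/`ngtdm_disc` default to the
#' histogram block.
#'
#' @param name Profile label (used as the rater id downstream).
#' @param disc Histogram-family [disc_settings()].
#' @param glcm_disc,ngtdm_disc Optional family-specific [disc_settings()].
#' @param glcm_directions Integer matrix of displacement vectors (rows).
#' @param glcm_offsets Positive integer displacement multiples.
#' @param glcm_symmetric Must be `TRUE`: pairs are counted in both orders.
#' @param ngtdm_distance Positive integer Chebyshev neighbourhood radius.
#' @param eps_guard Small positive guard used in divide-by-zero conventions
#'   of the texture features; stored per profile so degeneracy handling is
#'   itself a setting.
#' @return A `settings_profile` object.
#' @seealso [builtin_profile()] for the shipped platform profiles.
#' @export
settings_profile <- function(name, disc,
                             glcm_disc = disc, ngtdm_disc = disc,
                             glcm_directions = glcm_directions_3d(),
                             glcm_offsets = 1L,
                             glcm_symmetric = TRUE,
                             ngtdm_distance = 1L,
                             eps_guard = 1e-12) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (d in list(disc, glcm_disc, ngtdm_disc))
    if (!inherits(d, "disc_settings"))
      stop("discretisation blocks must be built with disc_settings()", call. = FALSE)
  glcm_directions <- as.matrix(glcm_directions)
  storage.mode(glcm_directions) <- "integer"
  if (ncol(glcm_directions) != 3L || nrow(glcm_directions) < 1L)
    stop("glcm_directions must be an n x 3 integer matrix", call. = FALSE)
  if (any(rowSums(abs(glcm_directions)) == 0))
    stop("zero displacement vector is not a direction", call. = FALSE)
  glcm_offsets <- as.integer(sort(unique(glcm_offsets)))
  if (any(glcm_offsets < 1L)) stop("offsets must be positive integers", call. = FALSE)
  if (!isTRUE(glcm_symmetric))
    stop("only symmetric co-occurrence accumulation is supported", call. = FALSE)
  ngtdm_distance <- as.integer(ngtdm_distance)
  if (ngtdm_distance < 1L) stop("ngtdm_distance must be >= 1", call. = FALSE)
  if (!is.finite(eps_guard) || eps_guard <= 0)
    stop("eps_guard must be a small positive real", call. = FALSE)
  structure(list(name = name, disc = disc, glcm_disc = glcm_disc,
                 ngtdm_disc = ngtdm_disc,
                 glcm_directions = glcm_directions,
                 glcm_offsets = glcm_offsets,
                 glcm_symmetric = TRUE,
                 ngtdm_distance = ngtdm_distance,
                 eps_guard = eps_guard),
            class = "settings_profile")
}

#' @export
print.settings_profile <- function(x, ...) {
  fmt_disc <- function(d) {
    b <- function(v) if (is.null(v)) "-" else as.character(v)
    switch(d$mode,
      fixed_bin_number_roi_range = sprintf("FBN %d over ROI range", d$n_bins),
      fixed_bin_number_fixed_range = sprintf("FBN %d over [%s, %s]", d$n_bins,
                                             b(d$lower), b(d$upper)),
      fixed_bin_width = sprintf("FBS width %g from %s%s", d$bin_width,
                                b(d$lower),
                                if (is.null(d$upper)) "" else sprintf(" (cap %s)", b(d$upper))))
  }
  cat(sprintf("<settings_profile> %s\n", x$name))
  cat("  histogram: ", fmt_disc(x$disc), "\n", sep = "")
  cat("  glcm:      ", fmt_disc(x$glcm_disc),
      sprintf(", %d directions, offsets {%s}, symmetric",
              nrow(x$glcm_directions), paste(x$glcm_offsets, collapse = ",")),
      "\n", sep = "")
  cat("  ngtdm:     ", fmt_disc(x$ngtdm_disc),
      sprintf(", distance %d", x$ngtdm_distance), "\n", sep = "")
  invisible(x)
}

#' Names of the shipped settings profiles
#' @return Character vector of the five built-in profile names.
#' @export
builtin_profile_names <- function() {
  c("lifex_default", "ibex_default", "pyradiomics_default",
    "cerr_default", "harmonised")
}

#' Built-in settings profiles
#'
#' The default calculation settings of the four widely used feature
#' platforms (LIFEx, IBEX, PyRadiomics, CERR) plus the harmonised settings
#' used for the cross-platform reliability design: 64 grey levels between
#' the ROI minimum and maximum, 13 symmetric co-occurrence directions at
#' offset 1, and NGTDM neighbourhood distance 1.
#'
#' The platform defaults differ in discretisation dialect (fixed bin number
#' over a fixed Hounsfield range for LIFEx and IBEX, fixed bin width for
#' PyRadiomics and CERR), in the bounds, in the number of co-occurrence
#' directions (CERR: 4 in-plane), in offsets (IBEX: 1, 4 and 7) and in the
#' NGTDM distance (IBEX: 2).
#'
#' @param name One of [builtin_profile_names()].
#' @return A [settings_profile()].
#' @examples
#' builtin_profile("harmonised")
#' @export
builtin_profile <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% builtin_profile_names())
    stop(sprintf("unknown profile %s; shipped profiles are: %s",
                 deparse(substitute(name)),
                 paste(builtin_profile_names(), collapse = ", ")),
         call. = FALSE)
  switch(name,
    lifex_default = {
      d <- disc_settings("fixed_bin_number_fixed_range", n_bins = 400,
                         lower = -1000, upper = 3000)
      settings_profile("lifex_default", d, ngtdm_distance = 1L)
    },
    ibex_default = {
      hist <- disc_settings("fixed_bin_number_fixed_range", n_bins = 256,
                            lower = 0, upper = 4096)
      glcm <- disc_settings("fixed_bin_number_fixed_range", n_bins = 100,
                            lower = 0, upper = 2100)
      settings_profile("ibex_default", hist, glcm_disc = glcm,
                       ngtdm_disc = hist,
                       glcm_offsets = c(1L, 4L, 7L), ngtdm_distance = 2L)
    },
    pyradiomics_default = {
      d <- disc_settings("fixed_bin_width", bin_width = 25,
                         lower = "roi_min", upper = "roi_max")
      settings_profile("pyradiomics_default", d, ngtdm_distance = 1L)
    },
    cerr_default = {
      d <- disc_settings("fixed_bin_width", bin_width = 25,
                         lower = 0, upper = 500)
      settings_profile("cerr_default", d,
                       glcm_directions = glcm_directions_2d_inplane(),
                       ngtdm_distance = 1L)
    },
    harmonised = {
      d <- disc_settings("fixed_bin_number_roi_range", n_bins = 64)
      settings_profile("harmonised", d, ngtdm_distance = 1L)
    })
}

#' Clone a profile with modified settings
#'
#' Used to emulate a "version change" of a platform: the clone differs from
#' the base profile only in the named settings (for example a different bin
#' count) and carries a new rater label.
#'
#' @param profile A [settings_profile()].
#' @param name Label of the perturbed profile.
#' @param n_bins,bin_width Optional discretisation perturbations applied to
#'   all three family blocks.
#' @param ngtdm_distance Optional neighbourhood distance perturbation.
#' @return A new `settings_profile`.
#' @export
perturb_profile <- function(profile, name, n_bins = NULL, bin_width = NULL,
                            ngtdm_distance = NULL) {
  stopifnot(inherits(profile, "settings_profile"))
  tweak <- function(d) {
    if (!is.null(n_bins) && grepl("fixed_bin_number", d$mode)) d$n_bins <- as.integer(n_bins)
    if (!is.null(bin_width) && d$mode == "fixed_bin_width") d$bin_width <- bin_width
    d
  }
  settings_profile(name,
                   tweak(profile$disc),
                   glcm_disc = tweak(profile$glcm_disc),
                   ngtdm_disc = tweak(profile$ngtdm_disc),
                   glcm_directions = profile$glcm_directions,
                   glcm_offsets = profile$glcm_offsets,
                   ngtdm_distance = if (is.null(ngtdm_distance))
                     profile$ngtdm_distance else as.integer(ngtdm_distance),
                   eps_guard = profile$eps_guard)
}

# ---- YAML serialisation -------------------------------------------------

profile_to_list <- function(p) {
  dl <- function(d) {
    out <- list(mode = d$mode)
    for (f in c("n_bins", "bin_width", "lower", "upper"))
      if (!is.null(d[[f]])) out[[f]] <- d[[f]]
    out
  }
  list(name = p$name,
       disc = dl(p$disc),
       glcm_disc = dl(p$glcm_disc),
       ngtdm_disc = dl(p$ngtdm_disc),
       glcm_directions = apply(p$glcm_directions, 1, paste, collapse = " "),
       glcm_offsets = p$glcm_offsets,
       glcm_symmetric = TRUE,
       ngtdm_distance = p$ngtdm_distance,
       eps_guard = p$eps_guard)
}

profile_from_list <- function(x) {
  dd <- function(d) disc_settings(d$mode, n_bins = d$n_bins,
                                  bin_width = d$bin_width,
                                  lower = d$lower, upper = d$upper)
  dirs <- do.call(rbind, lapply(x$glcm_directions,
                                function(s) as.integer(strsplit(s, " ")[[1]])))
  settings_profile(x$name, dd(x$disc), glcm_disc = dd(x$glcm_disc),
                   ngtdm_disc = dd(x$ngtdm_disc),
                   glcm_directions = dirs,
                   glcm_offsets = x$glcm_offsets,
                   glcm_symmetric = isTRUE(x$glcm_symmetric),
                   ngtdm_distance = x$ngtdm_distance,
                   eps_guard = x$eps_guard)
}

#' Write a settings profile to a YAML file
#' @param profile A [settings_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "settings_profile"))
  yaml::write_yaml(profile_to_list(profile), path)
  invisible(path)
}

#' Resolve a profile reference
#'
#' Accepts a `settings_profile` object, a built-in profile name, or a path
#' to a YAML profile file (the `--profile <name|path>` contract).
#'
#' @param x Profile object, built-in name, or YAML path.
#' @return A [settings_profile()].
#' @export
read_profile <- function(x) {
  if (inherits(x, "settings_profile")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (x %in% builtin_profile_names()) return(builtin_profile(x))
  if (file.exists(x)) return(profile_from_list(yaml::read_yaml(x)))
  stop(sprintf("unknown profile '%s': not a shipped name (%s) nor a file",
               x, paste(builtin_profile_names(), collapse = ", ")),
       call. = FALSE)
}

# ---- canonical feature names and platform aliases -----------------------

#' The 17 canonical feature names
#'
#' Three shape features, four raw-intensity first-order features, one
#' discretised-histogram feature, six co-occurrence (GLCM) features and
#' three neighbourhood grey tone difference (NGTDM) features — the set of
#' features shared by all four platforms, named in standardised
#' nomenclature.
#'
#' @return Character vector of length 17, in canonical order.
#' @export
canonical_feature_names <- function() {
  c("volume", "sphericity", "area",
    "minimum", "maximum", "mean", "standard_deviation",
    "skewness",
    "glcm_correlation", "glcm_contrast", "glcm_angular_second_moment",
    "glcm_joint_entropy", "glcm_difference_average", "glcm_inverse_difference",
    "ngtdm_busyness", "ngtdm_coarseness", "ngtdm_contrast")
}

# features whose value depends on the discretisation settings (histogram +
# texture families); the complement (shape + raw first order) is invariant
# across profiles because no preprocessing is applied
#' Which canonical features depend on the calculation settings?
#'
#' Shape and raw-intensity first-order features are computed from the mask
#' and raw intensities only, so they are identical under every settings
#' profile; skewness and the nine texture features inherit the profile's
#' discretisation (and direction/distance) choices.
#'
#' @return Named logical vector over [canonical_feature_names()].
#' @export
settings_dependent_features <- function() {
  f <- canonical_feature_names()
  dep <- !(f %in% c("volume", "sphericity", "area",
                    "minimum", "maximum", "mean", "standard_deviation"))
  names(dep) <- f
  dep
}

feature_alias_table <- function() {
  row <- function(canonical, ibsi, lifex, ibex, pyradiomics, cerr)
    data.frame(canonical = canonical,
               platform = c("ibsi", "lifex", "ibex", "pyradiomics", "cerr"),
               alias = c(ibsi, lifex, ibex, pyradiomics, cerr),
               stringsAsFactors = FALSE)
  do.call(rbind, list(
    row("volume", "Volume (mesh) and volume (voxel counting)", "Volume",
        "Volume", "Mesh volume and voxel volume", "Volume"),
    row("sphericity", "Sphericity", "Sphericity", "Sphericity", "Sphericity",
        "Sphericity"),
    row("area", "Surface area (mesh)", "Surface area", "Surface area",
        "Surface area", "Surface area"),
    row("skewness", "Discretised intensity skewness", "Histogram skewness",
        "Intensity histogram skewness", "First-order skewness", "Skewness"),
    row("glcm_correlation", "GLCM correlation", "GLCM correlation",
        "GLCM correlation", "GLCM correlation", "GLCM correlation"),
    row("glcm_contrast", "GLCM contrast", "GLCM contrast = variance",
        "GLCM contrast", "GLCM contrast", "GLCM contrast"),
    row("glcm_angular_second_moment", "GLCM angular second moment",
        "GLCM energy = angular second moment", "GLCM energy",
        "GLCM joint energy", "GLCM joint energy"),
    row("glcm_joint_entropy", "GLCM joint entropy",
        "GLCM entropy Log2 = joint entropy", "GLCM entropy",
        "GLCM joint entropy", "GLCM joint entropy"),
    row("glcm_difference_average", "GLCM difference average",
        "GLCM dissimilarly", "GLCM dissimilarly", "GLCM difference average",
        "Dissimilarity (difference average)"),
    row("glcm_inverse_difference", "GLCM inverse difference",
        "GLCM homogeneity = inverse difference", "GLCM homogeneity",
        "GLCM ID", "GLCM inverse difference"),
    row("ngtdm_busyness", "NGTDM busyness", "NGLDM busyness",
        "Neighbour intensity difference busyness", "NGTDM busyness",
        "NGTDM busyness"),
    row("ngtdm_coarseness", "NGTDM coarseness", "NGLDM coarseness",
        "Neighbour intensity difference coarseness", "NGTDM coarseness",
        "NGTDM coarseness"),
    row("ngtdm_contrast", "NGTDM contrast", "NGLDM contrast",
        "Neighbour intensity difference contrast", "NGTDM contrast",
        "NGTDM contrast"),
    row("minimum", "Minimum intensity", "Conventional HU minimum",
        "Global Minimum", "First-order minimum", "Minimum"),
    row("maximum", "Maximum intensity", "Conventional HU maximum",
        "Global maximum", "First-order maximum", "Maximum"),
    row("mean", "Mean intensity", "Conventional HU mean", "Global mean",
        "First-order mean", "Mean"),
    row("standard_deviation", "Not defined (variance is defined)",
        "Conventional HU standard deviation",
        "Global standard deviation", "First-order standard deviation",
        "Standard deviation")))
}

#' Map a platform-specific feature name to its canonical name
#'
#' Naming conventions differ across platforms (for example "GLCM
#' dissimilarly" and "Dissimilarity (difference average)" both denote the
#' difference average). The registry maps every platform alias to the
#' canonical name used throughout the pipeline. Matching is
#' case-insensitive; canonical names map to themselves for any platform.
#'
#' @param platform One of `"ibsi"`, `"lifex"`, `"ibex"`, `"pyradiomics"`,
#'   `"cerr"`.
#' @param alias Platform feature name (or an already-canonical name).
#' @return The canonical feature name.
#' @examples
#' canonical_feature_name("ibex", "GLCM dissimilarly")
#' canonical_feature_name("pyradiomics", "GLCM joint energy")
#' @export
canonical_feature_name <- function(platform, alias) {
  reg <- feature_alias_table()
  platform <- match.arg(tolower(platform), unique(reg$platform))
  stopifnot(is.character(alias), length(alias) == 1L)
  if (tolower(alias) %in% canonical_feature_names()) return(tolower(alias))
  sub <- reg[reg$platform == platform, ]
  hit <- which(tolower(sub$alias) == tolower(alias))
  if (length(hit) == 1L) return(sub$canonical[hit])
  near <- unique(sub$alias[agrepl(alias, sub$alias, ignore.case = TRUE,
                                  max.distance = 0.3)])
  stop(sprintf("unknown %s feature name '%s'%s", platform, alias,
               if (length(near)) paste0("; near matches: ",
                                        paste(near, collapse = ", ")) else ""),
       call. = FALSE)
}
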