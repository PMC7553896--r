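# Grey-level co-occurrence matrix: 3D merged-symmetric accumulation and the
# six Haralick-style features shared by the platforms.

# extract the aligned (source, target) level arrays for displacement d;
# returns NULL when the displacement exceeds the grid
shifted_level_pairs <- function(lev, d) {
  dims <- dim(lev)
  rng <- vector("list", 3)
  for (a in 1:3) {
    lo <- max(1L, 1L - d[a]); hi <- min(dims[a], dims[a] - d[a])
    if (lo > hi) return(NULL)
    rng[[a]] <- lo:hi
  }
  list(a = lev[rng[[1]], rng[[2]], rng[[3]], drop = FALSE],
       b = lev[rng[[1]] + d[1], rng[[2]] + d[2], rng[[3]] + d[3], drop = FALSE])
}

#' Build the merged symmetric co-occurrence matrix
#'
#' Counts pairs of grey levels at every displacement `direction * offset`
#' of the profile, over voxel pairs that are both inside the mask. Each
#' pair is counted in both orders (symmetric) and all displacements are
#' merged into a single matrix, so downstream features see one matrix per
#' subject regardless of how many directions or offsets the profile lists.
#'
#' @param disc A [discretise()] result (use the `glcm` family).
#' @param profile A [settings_profile()].
#' @return A `glcm` object: `counts` (Ng x Ng), `p` (probabilities), `ng`,
#'   `n_pairs` and a `degenerate` flag (no valid pair).
#' @export
build_glcm <- function(disc, profile) {
  stopifnot(inherits(disc, "discretised_roi"))
  profile <- read_profile(profile)
  ng <- disc$ng_eff
  counts <- matrix(0, ng, ng)
  for (off in profile$glcm_offsets) {
    for (r in seq_len(nrow(profile$glcm_directions))) {
      d <- profile$glcm_directions[r, ] * off
      pr <- shifted_level_pairs(disc$levels, d)
      if (is.null(pr)) next
      ok <- !is.na(pr$a) & !is.na(pr$b)
      if (!any(ok)) next
      idx <- (pr$a[ok] - 1L) * ng + pr$b[ok]
      counts <- counts + matrix(tabulate(idx, nbins = ng * ng), ng, ng,
                                byrow = TRUE)
    }
  }
  counts <- counts + t(counts)
  tot <- sum(counts)
  structure(list(counts = counts,
                 p = if (tot > 0) counts / tot else counts,
                 ng = ng, n_pairs = tot, degenerate = tot == 0),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> %dx%d, %g symmetric pair counts%s\n", x$ng, x$ng,
              x$n_pairs, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' The six co-occurrence features
#'
#' From the joint probability matrix `P(i,j)`:
#' correlation `sum (i-mu_i)(j-mu_j) P / (sigma_i sigma_j)`,
#' contrast `sum (i-j)^2 P`,
#' angular second moment `sum P^2`,
#' joint entropy `-sum P log2 P` (with `0 log 0 = 0`),
#' difference average `sum_k k p_(|i-j|=k)`, and
#' inverse difference `sum P / (1 + |i-j|)`.
#'
#' A homogeneous ROI concentrates all mass in one cell; the conventions are
#' then contrast 0, ASM 1, entropy 0, difference average 0, inverse
#' difference 1 and correlation 1 (a flat region is perfectly
#' self-correlated; the convention avoids 0/0 and is flagged via
#' `eps_guard`). A degenerate matrix (no valid pair) takes the same
#' conventions.
#'
#' @param glcm A [build_glcm()] result.
#' @param eps_guard Divide-by-zero guard for the marginal SDs.
#' @return Named numeric vector of the six features.
#' @export
glcm_features <- function(glcm, eps_guard = 1e-12) {
  stopifnot(inherits(glcm, "glcm"))
  homogeneous <- c(glcm_correlation = 1, glcm_contrast = 0,
                   glcm_angular_second_moment = 1, glcm_joint_entropy = 0,
                   glcm_difference_average = 0, glcm_inverse_difference = 1)
  if (glcm$degenerate) return(homogeneous)
  P <- glcm$p
  ng <- glcm$ng
  i <- seq_len(ng)
  pi_m <- rowSums(P)            # == colSums(P) by symmetry
  mu <- sum(i * pi_m)
  sigma <- sqrt(sum((i - mu)^2 * pi_m))
  ii <- matrix(i, ng, ng)       # row index
  jj <- t(ii)
  correlation <- if (sigma < eps_guard) 1 else
    sum((ii - mu) * (jj - mu) * P) / sigma^2
  contrast <- sum((ii - jj)^2 * P)
  asm <- sum(P^2)
  nz <- P > 0
  joint_entropy <- -sum(P[nz] * log2(P[nz]))
  k <- abs(ii - jj)
  difference_average <- sum(k * P)
  inverse_difference <- sum(P / (1 + k))
  c(glcm_correlation = correlation, glcm_contrast = contrast,
    glcm_angular_second_moment = asm, glcm_joint_entropy = joint_entropy,
    glcm_difference_average = difference_average,
    glcm_inverse_difference = inverse_difference)
}
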