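# Neighbourhood grey tone difference matrix and its three features.

#' Build the neighbourhood grey tone difference table
#'
#' The neighbourhood of a voxel is the full Chebyshev-distance-`d` cube
#' minus the centre, intersected with the mask. A voxel is valid if it has
#' at least one masked neighbour; for each valid voxel the absolute
#' difference between its level `i` and the mean level of its masked
#' neighbours is accumulated into `s_i`. Voxels with no masked neighbour
#' are excluded from the valid count `N_v`.
#'
#' @param disc A [discretise()] result (use the `ngtdm` family).
#' @param profile A [settings_profile()]; `ngtdm_distance` sets `d`.
#' @return An `ngtdm` object: data frame `table` with columns `level`,
#'   `n` (voxel count), `p` (= n/N_v), `s`; plus `n_valid`, `n_levels`
#'   (occupied levels) and a `degenerate` flag (no valid voxel).
#' @export
build_ngtdm <- function(disc, profile) {
  stopifnot(inherits(disc, "discretised_roi"))
  profile <- read_profile(profile)
  d <- profile$ngtdm_distance
  lev <- disc$levels
  dims <- dim(lev)
  offs <- as.matrix(expand.grid(dx = -d:d, dy = -d:d, dz = -d:d))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nbr_sum <- array(0, dims)
  nbr_cnt <- array(0, dims)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    rng <- vector("list", 3); ok_rng <- TRUE
    for (a in 1:3) {
      lo <- max(1L, 1L - o[a]); hi <- min(dims[a], dims[a] - o[a])
      if (lo > hi) { ok_rng <- FALSE; break }
      rng[[a]] <- lo:hi
    }
    if (!ok_rng) next
    nb <- lev[rng[[1]] + o[1], rng[[2]] + o[2], rng[[3]] + o[3], drop = FALSE]
    present <- !is.na(nb)
    nb[!present] <- 0L
    nbr_sum[rng[[1]], rng[[2]], rng[[3]]] <-
      nbr_sum[rng[[1]], rng[[2]], rng[[3]]] + as.vector(nb)
    nbr_cnt[rng[[1]], rng[[2]], rng[[3]]] <-
      nbr_cnt[rng[[1]], rng[[2]], rng[[3]]] + as.vector(present)
  }
  valid <- disc$mask & nbr_cnt > 0
  n_valid <- sum(valid)
  if (n_valid == 0) {
    return(structure(list(table = data.frame(level = integer(), n = integer(),
                                             p = numeric(), s = numeric()),
                          n_valid = 0L, n_levels = 0L, degenerate = TRUE),
                     class = "ngtdm"))
  }
  g <- lev[valid]
  abar <- nbr_sum[valid] / nbr_cnt[valid]
  dev <- abs(g - abar)
  n_i <- tabulate(g, nbins = disc$ng_eff)
  agg <- rowsum(dev, g)
  s_i <- numeric(disc$ng_eff)
  s_i[as.integer(rownames(agg))] <- agg[, 1]
  occ <- n_i > 0
  tab <- data.frame(level = seq_len(disc$ng_eff)[occ], n = n_i[occ],
                    p = n_i[occ] / n_valid, s = s_i[occ])
  structure(list(table = tab, n_valid = n_valid, n_levels = sum(occ),
                 degenerate = FALSE),
            class = "ngtdm")
}

#' @export
print.ngtdm <- function(x, ...) {
  cat(sprintf("<ngtdm> %d occupied levels over %d valid voxels%s\n",
              x$n_levels, x$n_valid, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' The three neighbourhood grey tone difference features
#'
#' With occupied levels `i`, occupancy probabilities `p_i` and difference
#' sums `s_i` over `N_v` valid voxels and `N_gp` occupied levels:
#' * coarseness `1 / sum(p_i s_i)`, returned as the cap `1e6` when the
#'   denominator falls below `eps_guard` (uniform ROI);
#' * busyness `sum(p_i s_i) / sum_{i,j} |i p_i - j p_j|` over occupied
#'   pairs, 0 when the denominator falls below `eps_guard`;
#' * contrast `[sum_{i,j} p_i p_j (i-j)^2 / (N_gp (N_gp - 1))] *
#'   [sum(s_i) / N_v]`, 0 when only one level is occupied.
#'
#' @param ngtdm A [build_ngtdm()] result.
#' @param eps_guard Degeneracy guard (taken from the profile in the
#'   pipeline).
#' @return Named numeric vector: busyness, coarseness, contrast.
#' @export
ngtdm_features <- function(ngtdm, eps_guard = 1e-12) {
  stopifnot(inherits(ngtdm, "ngtdm"))
  if (ngtdm$degenerate)
    return(c(ngtdm_busyness = 0, ngtdm_coarseness = 1e6, ngtdm_contrast = 0))
  tb <- ngtdm$table
  i <- tb$level; p <- tb$p; s <- tb$s
  ps <- sum(p * s)
  coarseness <- if (ps < eps_guard) 1e6 else 1 / ps
  ip <- i * p
  busy_den <- sum(abs(outer(ip, ip, "-")))
  busyness <- if (busy_den < eps_guard) 0 else ps / busy_den
  ngp <- ngtdm$n_levels
  contrast <- if (ngp < 2) 0 else
    sum(outer(p, p) * outer(i, i, "-")^2) / (ngp * (ngp - 1)) *
      (sum(s) / ngtdm$n_valid)
  c(ngtdm_busyness = busyness, ngtdm_coarseness = coarseness,
    ngtdm_contrast = contrast)
}
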