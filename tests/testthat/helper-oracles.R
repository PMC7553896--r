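# Independent oracles and small fixture builders used across the suite.
# Each oracle is a direct, unoptimised transcription of the defining
# formula, kept independent of the implementation paths it checks.

# --- fixtures -----------------------------------------------------------

digital_ball <- function(r, margin = 2) {
  n <- 2 * r + 1 + 2 * margin
  c0 <- (n + 1) / 2
  idx <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  array((idx$x - c0)^2 + (idx$y - c0)^2 + (idx$z - c0)^2 <= r^2, c(n, n, n))
}

toy_volume <- function(values, dims, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dims)
  volume_with_mask(array(values, dims), mask, c(1, 1, 1))
}

# unit cube mesh fixture: 8 vertices, 12 triangles, outward-oriented
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- matrix(c(1, 3, 2, 2, 3, 4,     # z = 0
                5, 6, 7, 6, 8, 7,     # z = 1
                1, 2, 5, 2, 6, 5,     # y = 0
                3, 7, 4, 4, 7, 8,     # y = 1
                1, 5, 3, 3, 5, 7,     # x = 0
                2, 4, 6, 4, 8, 6),    # x = 1
              ncol = 3, byrow = TRUE)
  triangle_mesh(v, f)
}

# --- texture oracles ----------------------------------------------------

# exhaustive pair enumeration over every voxel pair at the profile's
# displacements, both orders counted
brute_glcm_counts <- function(disc, profile) {
  ng <- disc$ng_eff
  counts <- matrix(0, ng, ng)
  dims <- dim(disc$levels)
  disps <- do.call(rbind, lapply(profile$glcm_offsets, function(o)
    profile$glcm_directions * o))
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- disc$levels[x, y, z]
    if (is.na(a)) next
    for (r in seq_len(nrow(disps))) {
      q <- c(x, y, z) + disps[r, ]
      if (any(q < 1) || any(q > dims)) next
      b <- disc$levels[q[1], q[2], q[3]]
      if (is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts
}

# per-voxel neighbourhood means computed by explicit looping
brute_ngtdm_table <- function(disc, d) {
  dims <- dim(disc$levels)
  lev <- disc$levels
  recs <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    g <- lev[x, y, z]
    if (is.na(g)) next
    nb <- c()
    for (dx in -d:d) for (dy in -d:d) for (dz in -d:d) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (any(q < 1) || any(q > dims)) next
      v <- lev[q[1], q[2], q[3]]
      if (!is.na(v)) nb <- c(nb, v)
    }
    if (length(nb) == 0) next
    recs[[length(recs) + 1]] <- c(level = g, dev = abs(g - mean(nb)))
  }
  m <- do.call(rbind, recs)
  n_valid <- nrow(m)
  levels <- sort(unique(m[, "level"]))
  data.frame(level = levels,
             n = sapply(levels, function(l) sum(m[, "level"] == l)),
             p = sapply(levels, function(l) sum(m[, "level"] == l)) / n_valid,
             s = sapply(levels, function(l) sum(m[m[, "level"] == l, "dev"])))
}

# --- reliability oracle -------------------------------------------------

# two-way ANOVA mean squares via stats::aov, independent of the closed-form
# decomposition used by the implementation
aov_mean_squares <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  list(msr = tab["subj", "Mean Sq"], msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}

icc_from_ms <- function(ms, n, k) {
  (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
}

# --- survival oracle ----------------------------------------------------

# Efron-tie log partial likelihood, written from the definition
efron_loglik <- function(beta, time, event, z) {
  eta <- beta * z
  ll <- 0
  for (tt in sort(unique(time[event == 1]))) {
    dead <- which(time == tt & event == 1)
    risk <- which(time >= tt)
    d <- length(dead)
    sum_risk <- sum(exp(eta[risk]))
    sum_dead <- sum(exp(eta[dead]))
    ll <- ll + sum(eta[dead])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum_risk - (l / d) * sum_dead)
  }
  ll
}

efron_beta_hat <- function(time, event, z) {
  stats::optimize(function(b) -efron_loglik(b, time, event, z),
                  c(-8, 8), tol = 1e-9)$minimum
}
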