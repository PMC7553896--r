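fbn_profile <- function(ng, ...) settings_profile(
  paste0("fbn", ng), disc_settings("fixed_bin_number_roi_range", ng), ...)

test_that("co-occurrence counts equal exhaustive pair enumeration", {
  # 2x2x1 grid with levels [[1,2],[1,2]]
  vm <- toy_volume(c(0, 0, 10, 10), c(2, 2, 1))
  p <- fbn_profile(2)
  d <- discretise(vm, p, family = "glcm")
  g <- build_glcm(d, p)
  expect_equal(g$counts, brute_glcm_counts(d, p))
  expect_equal(sum(g$p), 1)

  # random toys under varied direction sets and offsets
  set.seed(11)
  profiles <- list(
    fbn_profile(4),
    fbn_profile(3, glcm_directions = glcm_directions_2d_inplane()),
    fbn_profile(5, glcm_offsets = c(1L, 2L)),
    fbn_profile(4, glcm_offsets = c(1L, 4L, 7L)))
  for (p in profiles) {
    vals <- sample(0:40, 64, replace = TRUE)
    mask <- array(runif(64) > 0.25, c(4, 4, 4))
    mask[2, 2, 2] <- TRUE
    vm <- volume_with_mask(array(vals, c(4, 4, 4)), mask)
    d <- discretise(vm, p, family = "glcm")
    expect_equal(build_glcm(d, p)$counts, brute_glcm_counts(d, p))
  }
})

test_that("glcm is symmetric and direction merge order is irrelevant", {
  set.seed(12)
  vm <- toy_volume(sample(0:30, 64, replace = TRUE), c(4, 4, 4))
  p1 <- fbn_profile(6)
  p2 <- fbn_profile(6, glcm_directions = p1$glcm_directions[13:1, ])
  d <- discretise(vm, p1, family = "glcm")
  g1 <- build_glcm(d, p1)
  expect_equal(g1$counts, t(g1$counts))
  expect_equal(g1$counts, build_glcm(d, p2)$counts)
})

test_that("homogeneous ROI takes the single-cell feature conventions", {
  vm <- toy_volume(rep(5, 64), c(4, 4, 4))
  p <- builtin_profile("harmonised")
  g <- build_glcm(discretise(vm, p, family = "glcm"), p)
  expect_equal(sum(g$p != 0), 1L)
  expect_equal(g$p[1, 1], 1)
  f <- glcm_features(g)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_angular_second_moment"]), 1)
  expect_equal(unname(f["glcm_joint_entropy"]), 0)
  expect_equal(unname(f["glcm_difference_average"]), 0)
  expect_equal(unname(f["glcm_inverse_difference"]), 1)
  expect_equal(unname(f["glcm_correlation"]), 1)  # flat-ROI convention
})

test_that("checkerboard features match a hand-computed co-occurrence matrix", {
  # strict two-level checkerboard on a 4x4 plane, single in-plane direction
  vals <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  p <- settings_profile("one_dir",
                        disc_settings("fixed_bin_number_roi_range", 2),
                        glcm_directions = matrix(c(1L, 0L, 0L), 1))
  vm <- toy_volume(as.numeric(vals), c(4, 4, 1))
  d <- discretise(vm, p, family = "glcm")
  g <- build_glcm(d, p)
  # every pair along x alternates levels: all mass off-diagonal
  expect_equal(g$counts, matrix(c(0, 12, 12, 0), 2))
  f <- glcm_features(g)
  expect_equal(unname(f["glcm_contrast"]), 1)
  expect_equal(unname(f["glcm_joint_entropy"]), 1)       # two cells at 1/2
  expect_equal(unname(f["glcm_angular_second_moment"]), 0.5)
  expect_equal(unname(f["glcm_difference_average"]), 1)
  expect_equal(unname(f["glcm_inverse_difference"]), 0.5)
  expect_equal(unname(f["glcm_correlation"]), -1)
})

test_that("joint entropy is self-consistent and bounded", {
  set.seed(13)
  for (rep in 1:5) {
    vm <- toy_volume(rnorm(125, 50, 20), c(5, 5, 5))
    p <- fbn_profile(8)
    g <- build_glcm(discretise(vm, p, family = "glcm"), p)
    f <- glcm_features(g)
    nz <- g$p[g$p > 0]
    expect_equal(unname(f["glcm_joint_entropy"]), -sum(nz * log2(nz)),
                 tolerance = 1e-12)
    expect_lte(f["glcm_joint_entropy"], 2 * log2(g$ng))
    expect_gt(f["glcm_angular_second_moment"], 0)
    expect_lte(f["glcm_angular_second_moment"], 1)
    expect_gt(f["glcm_inverse_difference"], 0)
    expect_lte(f["glcm_inverse_difference"], 1)
    expect_gte(f["glcm_contrast"], 0)
  }
})

test_that("ngtdm tables equal exhaustive neighbourhood enumeration", {
  # 3x3x1 plane: centre level 2, ring level 1
  vals <- matrix(1, 3, 3); vals[2, 2] <- 2
  p <- fbn_profile(2)
  vm <- toy_volume(as.numeric(vals) * 10, c(3, 3, 1))
  d <- discretise(vm, p, family = "ngtdm")
  tab <- build_ngtdm(d, p)$table
  oracle <- brute_ngtdm_table(d, 1)
  expect_equal(tab$level, oracle$level)
  expect_equal(tab$n, oracle$n)
  expect_equal(tab$s, oracle$s, tolerance = 1e-12)
  expect_equal(tab$s[tab$level == 2], 1)  # |2 - mean(eight 1s)|

  # random toys with masked-out voxels, d = 1 and 2
  set.seed(14)
  for (dist in c(1L, 2L)) {
    pd <- fbn_profile(4, ngtdm_distance = dist)
    mask <- array(runif(64) > 0.3, c(4, 4, 4))
    mask[1, 1, 1] <- TRUE
    vm <- volume_with_mask(array(sample(0:30, 64, TRUE), c(4, 4, 4)), mask)
    d <- discretise(vm, pd, family = "ngtdm")
    got <- build_ngtdm(d, pd)
    oracle <- brute_ngtdm_table(d, dist)
    expect_equal(got$table$level, oracle$level)
    expect_equal(got$table$n, oracle$n)
    expect_equal(got$table$p, oracle$p, tolerance = 1e-12)
    expect_equal(got$table$s, oracle$s, tolerance = 1e-10)
    expect_equal(got$n_valid, sum(oracle$n))
    expect_equal(sum(got$table$p), 1)
  }
})

test_that("masked-out neighbours are excluded from the neighbourhood mean", {
  # two masked voxels separated by a masked-out one: each voxel's only
  # neighbour inside distance 1 is the unmasked gap, so neither is valid
  mask <- array(FALSE, c(3, 1, 1)); mask[c(1, 3), 1, 1] <- TRUE
  vm <- volume_with_mask(array(c(0, 99, 10), c(3, 1, 1)), mask)
  p <- fbn_profile(2)
  got <- build_ngtdm(discretise(vm, p, family = "ngtdm"), p)
  expect_true(got$degenerate)
  expect_equal(got$n_valid, 0L)
  expect_equal(ngtdm_features(got),
               c(ngtdm_busyness = 0, ngtdm_coarseness = 1e6,
                 ngtdm_contrast = 0))
})

test_that("ngtdm features match direct formula evaluation", {
  vals <- matrix(1, 3, 3); vals[2, 2] <- 2
  p <- fbn_profile(2)
  vm <- toy_volume(as.numeric(vals) * 10, c(3, 3, 1))
  got <- build_ngtdm(discretise(vm, p, family = "ngtdm"), p)
  f <- ngtdm_features(got)
  tb <- got$table
  ps <- sum(tb$p * tb$s)
  expect_equal(unname(f["ngtdm_coarseness"]), 1 / ps, tolerance = 1e-12)
  busy_den <- sum(abs(outer(tb$level * tb$p, tb$level * tb$p, "-")))
  expect_equal(unname(f["ngtdm_busyness"]), ps / busy_den, tolerance = 1e-12)
  ngp <- nrow(tb)
  con <- sum(outer(tb$p, tb$p) * outer(tb$level, tb$level, "-")^2) /
    (ngp * (ngp - 1)) * sum(tb$s) / got$n_valid
  expect_equal(unname(f["ngtdm_contrast"]), con, tolerance = 1e-12)

  # uniform ROI: all s_i zero, conventions apply
  vm_u <- toy_volume(rep(4, 27), c(3, 3, 3))
  got_u <- build_ngtdm(discretise(vm_u, p, family = "ngtdm"), p)
  expect_true(all(got_u$table$s == 0))
  expect_equal(ngtdm_features(got_u),
               c(ngtdm_busyness = 0, ngtdm_coarseness = 1e6,
                 ngtdm_contrast = 0))

  # homogeneity: doubling every s halves coarseness
  got2 <- got
  got2$table$s <- got2$table$s * 2
  expect_equal(unname(ngtdm_features(got2)["ngtdm_coarseness"]),
               unname(f["ngtdm_coarseness"]) / 2, tolerance = 1e-12)
})
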