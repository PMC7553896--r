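test_that("built-in profiles reproduce the platform calculation settings", {
  h <- builtin_profile("harmonised")
  expect_equal(h$disc$mode, "fixed_bin_number_roi_range")
  expect_equal(h$disc$n_bins, 64L)
  expect_equal(h$glcm_offsets, 1L)
  expect_equal(nrow(h$glcm_directions), 13L)
  expect_equal(h$ngtdm_distance, 1L)

  lf <- builtin_profile("lifex_default")
  expect_equal(lf$disc$mode, "fixed_bin_number_fixed_range")
  expect_equal(lf$disc$n_bins, 400L)
  expect_equal(lf$disc$lower, -1000)
  expect_equal(lf$disc$upper, 3000)
  expect_equal(lf$ngtdm_distance, 1L)

  ib <- builtin_profile("ibex_default")
  expect_equal(ib$glcm_offsets, c(1L, 4L, 7L))
  expect_equal(ib$ngtdm_distance, 2L)
  # per-family discretisation: GLCM block differs from the histogram block
  expect_equal(ib$disc$n_bins, 256L)
  expect_equal(ib$glcm_disc$n_bins, 100L)
  expect_equal(ib$glcm_disc$upper, 2100)

  py <- builtin_profile("pyradiomics_default")
  expect_equal(py$disc$mode, "fixed_bin_width")
  expect_equal(py$disc$bin_width, 25)
  expect_equal(py$disc$lower, "roi_min")

  ce <- builtin_profile("cerr_default")
  expect_equal(ce$disc$bin_width, 25)
  expect_equal(ce$disc$lower, 0)
  expect_equal(ce$disc$upper, 500)
  expect_equal(nrow(ce$glcm_directions), 4L)
  expect_true(all(ce$glcm_directions[, 3] == 0))  # in-plane only

  expect_error(builtin_profile("no_such_platform"), "unknown profile")
})

test_that("the five shipped profiles differ pairwise and all are symmetric", {
  profs <- lapply(builtin_profile_names(), builtin_profile)
  for (i in seq_along(profs)) {
    expect_true(profs[[i]]$glcm_symmetric)
    for (j in seq_along(profs))
      if (i < j) expect_false(identical(profs[[i]][-1], profs[[j]][-1]))
  }
})

test_that("profiles round-trip through YAML serialisation unchanged", {
  for (nm in builtin_profile_names()) {
    p <- builtin_profile(nm)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_profile(p, path)
    expect_equal(read_profile(path), p)
  }
  expect_error(read_profile("not_a_profile_or_file"), "unknown profile")
})

test_that("the 13 unique 3D directions pair up the 26 Chebyshev-1 neighbours", {
  d <- glcm_directions_3d()
  expect_equal(nrow(d), 13L)
  all26 <- rbind(d, -d)
  expect_equal(nrow(unique(all26)), 26L)
  expect_true(all(abs(all26) <= 1))
})

test_that("platform aliases resolve to canonical names", {
  expect_length(canonical_feature_names(), 17L)
  expect_equal(canonical_feature_name("ibex", "GLCM dissimilarly"),
               "glcm_difference_average")
  expect_equal(canonical_feature_name("lifex",
                                      "GLCM homogeneity = inverse difference"),
               "glcm_inverse_difference")
  expect_equal(canonical_feature_name("pyradiomics", "GLCM joint energy"),
               "glcm_angular_second_moment")
  expect_equal(canonical_feature_name("cerr", "Dissimilarity (difference average)"),
               "glcm_difference_average")
  # idempotent on canonical names, for any platform
  for (f in canonical_feature_names())
    expect_equal(canonical_feature_name("lifex", f), f)
  # unknown aliases fail with near matches
  expect_error(canonical_feature_name("ibex", "GLCM dissimilarity"),
               "near matches")
})

test_that("alias resolution is total over every platform column", {
  reg <- radharm:::feature_alias_table()
  for (pl in unique(reg$platform)) {
    sub <- reg[reg$platform == pl, ]
    expect_equal(nrow(sub), 17L)
    expect_false(anyDuplicated(sub$alias) > 0)
    for (r in seq_len(nrow(sub)))
      expect_equal(canonical_feature_name(pl, sub$alias[r]), sub$canonical[r])
  }
})

test_that("profile validation rejects inconsistent settings", {
  expect_error(disc_settings("fixed_bin_number_roi_range", n_bins = 1),
               "n_bins")
  expect_error(disc_settings("fixed_bin_width", bin_width = -1), "bin_width")
  expect_error(disc_settings("fixed_bin_number_fixed_range", n_bins = 8,
                             lower = 10, upper = 10), "lower bound")
  expect_error(settings_profile("x", disc_settings("fixed_bin_number_roi_range", 8),
                                glcm_symmetric = FALSE), "symmetric")
  expect_error(settings_profile("x", disc_settings("fixed_bin_number_roi_range", 8),
                                ngtdm_distance = 0), "ngtdm_distance")
})

test_that("perturb_profile clones only the named settings", {
  h <- builtin_profile("harmonised")
  p <- perturb_profile(h, "harmonised_v2", n_bins = 32)
  expect_equal(p$name, "harmonised_v2")
  expect_equal(p$disc$n_bins, 32L)
  expect_equal(p$glcm_disc$n_bins, 32L)
  expect_equal(p$glcm_directions, h$glcm_directions)
  expect_equal(p$ngtdm_distance, h$ngtdm_distance)
  # a pure rename leaves every setting untouched
  clone <- perturb_profile(h, "harmonised_b")
  expect_equal(clone[-1], h[-1])
})
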