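test_that("phantom generation is deterministic and spec-driven", {
  spec <- phantom_spec(seed = 51)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$mask, b$mask)
  # a different seed moves the texture but not the mask
  c2 <- generate_phantom(phantom_spec(seed = 52))
  expect_identical(a$mask, c2$mask)
  expect_false(identical(a$intensity, c2$intensity))
  # generators leave the caller's RNG stream untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_phantom(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("phantom intensity moments track the spec", {
  spec <- phantom_spec(grid = c(40, 40, 40), spacing = c(1, 1, 1),
                       semi_axes = c(14, 14, 14), base = 45,
                       texture_corr = 2, texture_sd = 30, noise_sd = 10,
                       seed = 53)
  vals <- sapply(1:8, function(s) {
    sp <- spec; sp$seed <- 53 + s
    v <- masked_values(generate_phantom(sp))
    c(mean(v), stats::sd(v))
  })
  expect_lt(abs(mean(vals[1, ]) - 45), 10)
  target_sd <- sqrt(30^2 + 10^2)
  expect_lt(abs(mean(vals[2, ]) - target_sd) / target_sd, 0.25)
})

test_that("a flat spherical phantom hits the degenerate conventions", {
  spec <- phantom_spec(grid = c(40, 40, 40), spacing = c(1, 1, 1),
                       semi_axes = c(12, 12, 12), texture_sd = 0,
                       noise_sd = 0, seed = 54)
  vm <- generate_phantom(spec)
  expect_true(all(masked_values(vm) == spec$base))
  expect_gt(shape_features(vm)$sphericity, 0.95)
  tab <- extract_features(vm, list("harmonised"))
  expect_equal(tab$glcm_joint_entropy, 0)
  expect_equal(tab$ngtdm_coarseness, 1e6)
  expect_equal(tab$skewness, 0)
})

test_that("smoother texture raises ngtdm coarseness", {
  coarse_at <- function(corr, s) {
    spec <- phantom_spec(grid = c(36, 36, 18), spacing = c(1, 1, 1),
                         semi_axes = c(12, 10, 6), texture_corr = corr,
                         texture_sd = 30, noise_sd = 0, seed = s)
    vm <- generate_phantom(spec)
    p <- builtin_profile("harmonised")
    ngtdm_features(build_ngtdm(discretise(vm, p, family = "ngtdm"), p))[
      "ngtdm_coarseness"]
  }
  seeds <- 1:20
  smooth <- mean(sapply(seeds, function(s) coarse_at(4, 60 + s)))
  rough <- mean(sapply(seeds, function(s) coarse_at(1, 60 + s)))
  expect_gt(smooth, rough)
})

test_that("phantom specs reject impossible geometry", {
  expect_error(phantom_spec(semi_axes = c(0, 10, 10)), "degenerate")
  expect_error(phantom_spec(grid = c(20, 20, 10), semi_axes = c(30, 10, 5)),
               "margin")
  expect_error(phantom_spec(texture_sd = -1), ">= 0")
})

test_that("survival cohorts calibrate to the target event fraction", {
  events <- sapply(1:40, function(s)
    sum(generate_cohort(cohort_spec(seed = 400 + s))$event))
  # defaults: n = 108, horizon 2.2 years, 28 expected events
  expect_lt(abs(mean(events) - 28), 2.5)
  co <- generate_cohort(cohort_spec(seed = 1))
  expect_equal(attr(co, "expected_events"), 28, tolerance = 1e-9)
  expect_true(all(co$time <= 2.2))
  expect_error(cohort_spec(event_fraction = 1.2), "unattainable")
  # deterministic per seed
  expect_identical(generate_cohort(cohort_spec(seed = 5)),
                   generate_cohort(cohort_spec(seed = 5)))
})

test_that("planted cohort effects are recoverable", {
  set.seed(55)
  z <- rnorm(1000)
  co <- generate_cohort(cohort_spec(n = 1000, beta = 0.7,
                                    event_fraction = 0.4, seed = 56), z = z)
  fit <- cox_univariable(co, standardise(z))
  expect_lt(abs(fit$beta - 0.7), 3 * fit$se)
})

test_that("ratings matrices reproduce their variance components", {
  m <- generate_ratings(6, 3, seed = 57)
  expect_identical(m, generate_ratings(6, 3, seed = 57))
  # zero noise and bias: columns identical, agreement exact
  m0 <- generate_ratings(10, 4, sd_subject = 1, sd_rater = 0, sd_noise = 0,
                         seed = 58)
  expect_equal(icc_absolute_agreement(m0)$estimate, 1)
})

test_that("phantom cohorts vary subjects and keep traits aligned", {
  coh <- phantom_cohort(4, seed = 59)
  expect_length(coh$volumes, 4L)
  expect_equal(nrow(coh$traits), 4L)
  vols <- sapply(coh$volumes, function(v) sum(v$mask))
  expect_gt(stats::sd(vols), 0)
  # traits drive the phantoms: regenerating from a trait row matches
  t1 <- coh$traits[1, ]
  vm <- generate_phantom(phantom_spec(grid = c(64, 64, 28),
                                      spacing = c(1, 1, 3),
                                      semi_axes = c(t1$ax, t1$ay, t1$az),
                                      lobulation = t1$lobulation,
                                      base = t1$base,
                                      texture_corr = t1$texture_corr,
                                      texture_sd = t1$texture_sd,
                                      noise_sd = t1$noise_sd,
                                      seed = t1$phantom_seed))
  expect_identical(vm$intensity, coh$volumes[[1]]$intensity)
})

test_that("phantom cohorts round-trip through NIfTI files", {
  dir <- withr::local_tempdir()
  coh <- phantom_cohort(2, seed = 61, grid = c(32, 32, 16),
                        semi_axis_range = c(0.5, 0.7))
  write_phantom_cohort(coh, dir)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(manifest), 2L)
  vm <- read_volume_with_mask(file.path(dir, manifest$image[1]),
                              file.path(dir, manifest$mask[1]))
  expect_equal(vm$spacing, coh$volumes[[1]]$spacing, tolerance = 1e-6)
  expect_identical(vm$mask, coh$volumes[[1]]$mask)
  expect_equal(vm$intensity, coh$volumes[[1]]$intensity, tolerance = 1e-6)
})
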