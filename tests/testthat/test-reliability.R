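test_that("icc matches the aov-based two-way decomposition", {
  set.seed(21)
  for (rep in 1:10) {
    m <- matrix(rnorm(15), 5, 3) + rnorm(5) + rep(rnorm(3), each = 5)
    r <- icc_absolute_agreement(m)
    ms <- aov_mean_squares(m)
    expect_equal(r$ms_rows, ms$msr, tolerance = 1e-10)
    expect_equal(r$ms_cols, ms$msc, tolerance = 1e-10)
    expect_equal(r$ms_error, ms$mse, tolerance = 1e-10)
    raw <- icc_from_ms(ms, 5, 3)
    expect_equal(r$estimate, min(max(raw, 0), 1), tolerance = 1e-10)
  }
})

test_that("icc recovers known variance components", {
  # sd_subject = sd_noise = 1 gives a theoretical ICC of 0.5
  m <- generate_ratings(1000, 4, sd_subject = 1, sd_rater = 0, sd_noise = 1,
                        seed = 2)
  r <- icc_absolute_agreement(m)
  expect_lt(abs(r$estimate - 0.5), 0.05)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
})

test_that("identical columns give exact agreement with ICC 1", {
  set.seed(22)
  col <- rnorm(12)
  r <- icc_absolute_agreement(cbind(col, col, col))
  expect_equal(r$estimate, 1)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
  expect_equal(r$flag, "exact_agreement")
  expect_equal(r$category, "excellent")
  # an entirely constant matrix is also exact, with its own flag
  rz <- icc_absolute_agreement(matrix(3, 4, 3))
  expect_equal(rz$estimate, 1)
  expect_equal(rz$flag, "zero_variance")
})

test_that("negative estimates and bounds truncate to exactly zero", {
  set.seed(23)
  col <- rnorm(20)
  # anti-correlated raters: raw estimate is negative
  m <- cbind(col, -col) + matrix(rnorm(40, sd = 0.1), 20)
  ms <- aov_mean_squares(m)
  expect_lt(icc_from_ms(ms, 20, 2), 0)
  r <- icc_absolute_agreement(m)
  expect_identical(r$estimate, 0)
  expect_identical(r$ci_low, 0)
  expect_gte(r$ci_high, 0)
  expect_lte(r$ci_high, 1)
})

test_that("confidence bounds stay ordered and inside [0, 1]", {
  set.seed(24)
  for (rep in 1:25) {
    n <- sample(4:30, 1); k <- sample(2:6, 1)
    m <- matrix(rnorm(n * k), n, k) + rnorm(n) * runif(1, 0, 3) +
      rep(rnorm(k), each = n) * runif(1, 0, 1)
    r <- icc_absolute_agreement(m)
    expect_true(0 <= r$ci_low && r$ci_low <= r$estimate &&
                  r$estimate <= r$ci_high && r$ci_high <= 1)
  }
})

test_that("classification applies the 0.5/0.75/0.9 thresholds to the CI", {
  cat_of <- function(lo, hi, est = (lo + hi) / 2)
    classify_reliability(list(estimate = est, ci_low = lo, ci_high = hi))
  expect_equal(cat_of(0.992, 1)$category, "excellent")
  c1 <- cat_of(0.30, 0.60)
  expect_equal(c1$category, "poor")          # lower-bound rule
  expect_true(c1$straddle)
  c2 <- cat_of(0.75, 0.75, 0.75)
  expect_equal(c2$category, "moderate")      # boundary to the lower category
  expect_false(c2$straddle)
  expect_equal(cat_of(0.5, 0.5, 0.5)$category, "poor")
  expect_equal(cat_of(0.9, 0.95)$category, "good")
  expect_equal(cat_of(0.91, 0.95)$category, "excellent")
})

test_that("the 95% interval covers the theoretical ICC at the nominal rate", {
  hits <- 0
  reps <- 500
  for (s in seq_len(reps)) {
    m <- generate_ratings(40, 4, sd_subject = 1, sd_rater = 0.3,
                          sd_noise = 0.8, seed = 1000 + s)
    theta <- 1 / (1 + 0.3^2 + 0.8^2)
    r <- icc_absolute_agreement(m)
    if (r$ci_low <= theta && theta <= r$ci_high) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.90)
  expect_lte(hits / reps, 0.99)
})

test_that("noisier raters depress the agreement estimate in expectation", {
  mean_icc <- function(noise_sd) {
    mean(sapply(1:30, function(s) {
      base <- generate_ratings(30, 3, sd_subject = 1, sd_rater = 0,
                               sd_noise = 0.2, seed = 300 + s)
      extra <- with_seed_noise(noise_sd, 30, 400 + s)
      base[, 3] <- base[, 3] + extra
      icc_absolute_agreement(base)$estimate
    }))
  }
  with_seed_noise <- function(sd, n, seed) {
    set.seed(seed); rnorm(n, sd = sd)
  }
  m0 <- mean_icc(0)
  m1 <- mean_icc(1)
  m2 <- mean_icc(2.5)
  expect_gt(m0, m1)
  expect_gt(m1, m2)
})

test_that("rater bias lowers absolute agreement", {
  icc_at_bias <- function(b) {
    mean(sapply(1:20, function(s)
      icc_absolute_agreement(generate_ratings(40, 4, sd_subject = 1,
                                              sd_rater = b, sd_noise = 0.3,
                                              seed = 500 + s))$estimate))
  }
  expect_gt(icc_at_bias(0), icc_at_bias(0.8))
  expect_gt(icc_at_bias(0.8), icc_at_bias(2))
})

test_that("reliability_study assembles matrices, flags constants, summarises", {
  set.seed(26)
  subj <- rep(1:10, 2)
  tab <- data.frame(subject = subj, profile = rep(c("a", "b"), each = 10),
                    f1 = c(x <- rnorm(10), x),             # identical raters
                    f2 = c(y <- rnorm(10), y + rnorm(10)), # noisy second rater
                    f3 = 5)                                # constant
  st <- reliability_study(tab, features = c("f1", "f2", "f3"))
  expect_equal(st$estimate[st$feature == "f1"], 1)
  expect_equal(st$category[st$feature == "f1"], "excellent")
  expect_lt(st$estimate[st$feature == "f2"], 1)
  expect_equal(st$flag[st$feature == "f3"], "constant")
  sm <- reliability_summary(st)
  expect_equal(sum(sm$count), 2L)
  expect_equal(attr(sm, "n_constant"), 1L)
  # listwise deletion drops incomplete subjects
  tab2 <- tab
  tab2$f2[3] <- NA
  st2 <- reliability_study(tab2, features = "f2")
  expect_equal(st2$n, 9L)
  # rater subsetting must name profiles present in the table
  expect_error(reliability_study(tab, raters = c("a", "zz")), "not present")
})
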