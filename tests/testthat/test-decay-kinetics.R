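test_that("normalization divides by loading and anchors t0 at 1", {
  out <- normalize_timecourse(data.frame(time = c(0, 1),
                                         intensity = c(10, 5)))
  expect_equal(out$intensity, c(1, 0.5))

  out <- normalize_timecourse(data.frame(time = c(0, 1),
                                         intensity = c(10, 5),
                                         loading = c(2, 1)))
  expect_equal(out$intensity, c(1, 1))

  for (seed in 1:10) {
    set.seed(seed)
    tc <- data.frame(time = c(0, 1, 2, 4),
                     intensity = stats::runif(4, 0.1, 10),
                     loading = stats::runif(4, 0.5, 2))
    expect_equal(normalize_timecourse(tc)$intensity[1], 1)
  }

  expect_error(normalize_timecourse(
    data.frame(time = c(0, 1), intensity = c(0, 5))),
    class = "ligasetrap_validation_error")
  expect_error(normalize_timecourse(
    data.frame(time = c(1, 2), intensity = c(1, 0.5))),
    class = "ligasetrap_validation_error")
})

test_that("noiseless exponentials are recovered exactly over a rate grid", {
  fit <- fit_halflife(data.frame(time = 0:2, intensity = c(1, 0.5, 0.25)))
  expect_equal(fit$k, log(2), tolerance = 1e-12)
  expect_equal(fit$half_life, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  for (k in c(0.05, 0.2, 1, 2.5, 5)) {
    tc <- simulate_decay(k, times = c(0, 0.4, 0.9, 1.5, 2),
                         noise_sigma = 0, seed = 1)
    fit <- fit_halflife(tc, floor = 1e-8)
    expect_equal(fit$k, k, tolerance = 1e-10, info = paste("k =", k))
  }
})

test_that("non-decaying timecourses are flagged stable", {
  fit <- fit_halflife(data.frame(time = c(0, 1, 2), intensity = 1))
  expect_true(fit$stable)
  expect_identical(fit$half_life, Inf)
  expect_true(fit_halflife(simulate_decay(0, noise_sigma = 0))$stable)
})

test_that("floor exclusion and insufficient points are handled", {
  tc <- data.frame(time = c(0, 1, 2), intensity = c(1, 0.5, 0.005))
  expect_warning(fit <- fit_halflife(tc), "floor")
  expect_equal(fit$n_points, 2)
  expect_error(
    suppressWarnings(fit_halflife(
      data.frame(time = c(0, 1, 2), intensity = c(1, 0.004, 0.001)))),
    class = "ligasetrap_fit_error")
})

test_that("points outside the window never change the fit", {
  inside <- data.frame(time = c(0, 0.5, 1, 2), intensity = NA)
  set.seed(4)
  inside$intensity <- exp(-0.6 * inside$time) * exp(rnorm(4, 0, 0.1))
  with_outside <- rbind(inside,
                        data.frame(time = c(4, 8), intensity = c(0.9, 0.8)))
  f1 <- fit_halflife(inside, window = c(0, 2))
  f2 <- fit_halflife(with_outside, window = c(0, 2))
  expect_equal(f1$k, f2$k)
  expect_equal(f1$r_squared, f2$r_squared)
  expect_equal(f1$n_points, f2$n_points)
})

test_that("rate recovery under multiplicative noise stays within tolerance", {
  k_true <- 0.347
  errs <- vapply(1:100, function(seed) {
    tc <- simulate_decay(k_true, times = c(0, 0.5, 1, 2),
                         noise_sigma = 0.05, seed = seed)
    abs(fit_halflife(tc)$k - k_true) / k_true
  }, numeric(1))
  expect_lte(median(errs), 0.15)
  halves <- vapply(1:100, function(seed) {
    tc <- simulate_decay(k_true, times = c(0, 0.5, 1, 2),
                         noise_sigma = 0.05, seed = seed)
    fit_halflife(tc)$half_life
  }, numeric(1))
  expect_lt(abs(median(halves) - 2) / 2, 0.15)
})

test_that("median rate error scales with the noise level", {
  for (sigma in c(0.05, 0.1)) {
    for (k_true in c(0.3, 1)) {
      errs <- vapply(1:200, function(seed) {
        tc <- simulate_decay(k_true, times = c(0, 0.5, 1, 2),
                             noise_sigma = sigma, seed = seed + 1000)
        abs(fit_halflife(tc)$k - k_true) / k_true
      }, numeric(1))
      expect_true(median(errs) <= sigma * 3,
                  info = paste("sigma", sigma, "k", k_true))
    }
  }
})

test_that("stabilization ratios map onto the yes/partial/no/stable labels", {
  mk <- function(k) fit_halflife(simulate_decay(k, noise_sigma = 0),
                                 floor = 1e-9)
  treated4 <- mk(log(2) / 4)
  ref1 <- mk(log(2))
  res <- stabilization_ratio(treated4, ref1)
  expect_equal(res$ratio, 4, tolerance = 1e-8)
  expect_equal(res$class, "yes")

  same <- stabilization_ratio(ref1, ref1)
  expect_equal(same$ratio, 1, tolerance = 1e-12)
  expect_equal(same$class, "no")

  partial <- stabilization_ratio(mk(log(2) / 1.5), ref1)
  expect_equal(partial$class, "partial")

  stable_fit <- mk(0)
  expect_equal(stabilization_ratio(stable_fit, ref1)$class, "stable")
  expect_identical(stabilization_ratio(stable_fit, ref1)$ratio, Inf)
  expect_equal(stabilization_ratio(stable_fit, stable_fit)$class, "stable")
})

test_that("translation recovery ratios are plain reference-normalized fractions", {
  out <- translation_recovery_ratio(
    data.frame(condition = c("untreated", "CPT"),
               densitometry = c(100, 20)))
  expect_equal(out$ratio, c(1, 0.2))

  equal <- translation_recovery_ratio(
    data.frame(condition = c("untreated", "a", "b"),
               densitometry = c(50, 30, 30)))
  expect_equal(equal$ratio[2], equal$ratio[3])

  # a mutant lane at twice the wildtype lane gives exactly a 2x ratio
  wt <- translation_recovery_ratio(
    data.frame(condition = c("untreated", "recovery_2h"),
               densitometry = c(100, 15)))
  mut <- translation_recovery_ratio(
    data.frame(condition = c("untreated", "recovery_2h"),
               densitometry = c(100, 30)))
  expect_equal(mut$ratio[2] / wt$ratio[2], 2)

  expect_error(translation_recovery_ratio(
    data.frame(condition = "CPT", densitometry = 10)),
    class = "ligasetrap_validation_error")
})
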