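# The 12 performance variables: printed micro-fixtures, degenerate inputs,
# and the limb-swap/symmetry identities.

test_that("movement and only-time use the strict counts > 2 rule", {
  x <- cs(c(0L, 3L, 5L, 1L, 2L, 7L))
  expect_equal(movement_time(x), 3 / 3600)   # 3, 5, 7 move; 2 does not
  expect_equal(movement_time(cs(rep(0L, 100))), 0)
  expect_equal(movement_time(cs(rep(10L, 24 * 3600))), 24)
  # monotone non-increasing in the threshold
  thr <- c(0, 1, 2, 4, 6, 10)
  mt <- vapply(thr, function(th) movement_time(x, th), numeric(1))
  expect_true(all(diff(mt) <= 0))

  target <- cs(c(5L, 5L, 5L, 0L, 0L))
  other <- cs(c(0L, 0L, 5L, 5L, 0L))
  expect_equal(only_time(target, other), 2 / 3600)
  expect_equal(only_time(target, target), 0)
  expect_equal(only_time(target, cs(rep(0L, 5))), movement_time(target))
  expect_error(only_time(target, cs(rep(0L, 4))), "misaligned")
})

test_that("moving-epoch magnitude summaries match hand values", {
  x <- cs(c(0L, 3L, 5L, 1L, 7L))
  expect_equal(median_magnitude(x), 5)
  expect_equal(median_magnitude(cs(c(4L, 4L, 4L))), 4)
  expect_true(is.na(median_magnitude(cs(c(0L, 1L, 2L)))))

  expect_equal(magnitude_sd(cs(c(3L, 5L, 7L, 0L))), 2)
  expect_equal(magnitude_sd(cs(c(4L, 6L))), sqrt(2))
  expect_equal(magnitude_sd(cs(rep(9L, 10))), 0)
  expect_true(is.na(magnitude_sd(cs(c(0L, 5L)))))

  expect_equal(bilateral_magnitude(60, 30), 90)
  expect_equal(bilateral_magnitude(0, 0), 0)
})

test_that("use and magnitude ratios follow their printed definitions", {
  expect_equal(use_ratio(4, 8), 0.5)
  expect_equal(use_ratio(8, 8), 1)
  expect_equal(use_ratio(0, 8), 0)
  expect_true(is.na(use_ratio(4, 0)))

  expect_equal(magnitude_ratio(30, 60, "raw"), 0.5)
  expect_equal(magnitude_ratio(45, 45), 0)
  expect_equal(magnitude_ratio(30, 60), log(0.5))
  expect_true(is.na(magnitude_ratio(0, 60)))
})

test_that("jerk asymmetry equals the normalized jerk difference", {
  fs <- 30
  ramp <- function(slope) vm_series(slope * (0:299) / fs, fs = fs)
  expect_equal(jerk_asymmetry(ramp(1), ramp(1)), 0)
  expect_equal(jerk_asymmetry(ramp(3), ramp(1)), 0.5)  # (3-1)/(3+1)
  # static preferred limb: all jerk on the non-preferred side
  expect_equal(jerk_asymmetry(ramp(2), vm_series(rep(0.3, 300), fs = fs)), 1)
  expect_true(is.na(jerk_asymmetry(vm_series(rep(0, 300)), vm_series(rep(0, 300)))))
})

test_that("sparc is amplitude-invariant and penalizes high-frequency content", {
  fs <- 30
  t <- (0:(8 * fs - 1)) / fs
  smooth <- vm_series(exp(-((t - 4) / 0.8)^2) * sin(2 * pi * 1 * t), fs = fs)
  expect_equal(sparc(smooth), sparc(vm_series(10 * smooth$vm, fs = fs)),
               tolerance = 1e-9)
  composite <- vm_series(smooth$vm + 0.3 * exp(-((t - 4) / 0.8)^2) *
                           sin(2 * pi * 8 * t), fs = fs)
  expect_lt(sparc(composite), sparc(smooth))
  expect_lt(sparc(smooth), 0)
  expect_true(is.na(sparc(vm_series(rep(0, 100)))))
  expect_true(is.na(sparc(vm_series(0.5))))
})

test_that("performance vector honors symmetry fixed points and limb swaps", {
  profile <- subject_profile("control", latent_performance = 1, asymmetry = 0,
                             activity_level = 1, seed = 31L)
  cp <- simulate_limb_counts(profile, "preferred", wear_hours = 24, seed = 101L)
  cn <- simulate_limb_counts(profile, "non_preferred", wear_hours = 24, seed = 202L)
  rp <- filter_raw(simulate_limb_signal(profile, "preferred", 15 / 60, seed = 11L))
  rn <- filter_raw(simulate_limb_signal(profile, "non_preferred", 15 / 60, seed = 12L))

  pv <- compute_performance_vector(cp, cn, rp, rn)
  expect_equal(pv$use_ratio, 1, tolerance = 0.1)
  expect_equal(pv$magnitude_ratio, 0, tolerance = 0.1)
  # the index is a Monte-Carlo symmetric difference over ~60 bouts per limb
  expect_equal(pv$jerk_asymmetry_index, 0, tolerance = 0.25)

  swapped <- compute_performance_vector(cn, cp, rn, rp)
  expect_equal(swapped$use_ratio, 1 / pv$use_ratio, tolerance = 1e-6)
  expect_equal(swapped$magnitude_ratio, -pv$magnitude_ratio, tolerance = 1e-6)
  expect_equal(swapped$jerk_asymmetry_index, -pv$jerk_asymmetry_index,
               tolerance = 1e-6)
  expect_equal(swapped$sparc_preferred, pv$sparc_non_preferred)
  expect_equal(swapped$sparc_non_preferred, pv$sparc_preferred)
  expect_lte(pv$preferred_only_time, pv$preferred_time)
  expect_lte(pv$non_preferred_only_time, pv$non_preferred_time)
})

test_that("fully asymmetric profiles silence the non-preferred limb", {
  profile <- subject_profile("stroke", latent_performance = 0.3, asymmetry = 1,
                             activity_level = 1, seed = 77L)
  cn <- simulate_limb_counts(profile, "non_preferred", wear_hours = 24)
  expect_equal(movement_time(cn), 0)
  cp <- simulate_limb_counts(profile, "preferred", wear_hours = 24)
  pv <- compute_performance_vector(cp, cn)
  expect_equal(pv$non_preferred_time, 0)
  expect_equal(pv$use_ratio, 0)
  expect_true(is.na(pv$non_preferred_magnitude))
})

test_that("performance vector refuses subjects failing the valid-day rule", {
  short <- cs(rep(10L, 3600 * 20))
  expect_error(compute_performance_vector(short, short), "valid-day")
})

test_that("variable sets are nested with the documented membership", {
  vs <- variable_sets()
  expect_length(vs$v12, 12)
  expect_setequal(vs$v5, c("non_preferred_magnitude", "non_preferred_time",
                           "non_preferred_variance", "preferred_time", "use_ratio"))
  expect_true(all(vs$v5 %in% vs$v7))
  expect_true(all(vs$v7 %in% vs$v9))
  expect_true(all(vs$v9 %in% vs$v12))
})
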