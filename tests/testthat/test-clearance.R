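test_that("three points are interpolated exactly by the offset power law", {
  p <- distance_profile(c(0, 40, 100), c(2356, 401, 83), height = 100,
                        sequence_label = "B2")
  f <- fit_decay(p)
  expect_equal(f$d0, 53.8, tolerance = 0.01)
  expect_equal(f$n, 3.19, tolerance = 0.01)
  expect_equal(f$rms_log_residual, 0, tolerance = 1e-9)
  # fitted curve passes through all three points (log space, 1e-9 relative)
  expect_equal(log(predict(f, p$distance)), log(p$index), tolerance = 1e-9)
})

test_that("known decay parameters are recovered from exact points", {
  truth <- decay_ground_truth(A = 5e8, d0 = 62, n = 3.4)
  prof <- gen_distance_profile(truth, c(0, 30, 70, 120, 180))
  f <- fit_decay(prof)
  expect_equal(f$A, truth$A, tolerance = 1e-6)
  expect_equal(f$d0, truth$d0, tolerance = 1e-6)
  expect_equal(f$n, truth$n, tolerance = 1e-6)
})

test_that("four-point survey profile fits with small but nonzero residual", {
  p <- distance_profile(c(0, 50, 100, 150), c(2642, 338, 100, 44.4),
                        sequence_label = "C2")
  f <- fit_decay(p)
  expect_gt(f$rms_log_residual, 0)
  expect_lt(f$rms_log_residual, 0.05)
})

test_that("profiled offset search agrees with an independent Levenberg-Marquardt fit", {
  dat <- data.frame(d = c(0, 50, 100, 150), I = c(2642, 338, 100, 44.4))
  f <- fit_decay(distance_profile(dat$d, dat$I))
  lmfit <- minpack.lm::nlsLM(
    log(I) ~ log(A) - n * log(d + d0), data = dat,
    start = list(A = dat$I[1] * 50^3, d0 = 50, n = 3),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15))
  co <- coef(lmfit)
  expect_equal(f$A, unname(co["A"]), tolerance = 1e-4)
  expect_equal(f$d0, unname(co["d0"]), tolerance = 1e-5)
  expect_equal(f$n, unname(co["n"]), tolerance = 1e-5)
})

test_that("degenerate profiles are rejected", {
  expect_error(fit_decay(distance_profile(c(0, 50, 100), c(5, 5, 5) + 0:2 * 0)),
               "degenerate|equal")
  expect_error(fit_decay(distance_profile(c(0, 50, 100), c(10, 20, 40))),
               "not decreasing")
  expect_error(distance_profile(c(0, 50, 50), c(3, 2, 1)),
               "strictly increasing")
  expect_error(distance_profile(c(0, 50, 100), c(3, -2, 1)), "positive")
})

test_that("clearance crossing solves the fitted model at the threshold", {
  truth <- decay_ground_truth(A = 100 * 150^3, d0 = 50, n = 3)  # crossing 100
  prof <- gen_distance_profile(truth, c(0, 40, 100, 160))
  cl <- clearance_distance(fit_decay(prof))
  expect_equal(cl$distance, 100, tolerance = 1e-6)
  expect_false(cl$compliant_everywhere)
  expect_false(cl$extrapolated)
  # threshold exactly at the d = 0 value puts the crossing at the origin
  cl0 <- clearance_distance(fit_decay(prof), threshold = 100 * (150 / 50)^3)
  expect_equal(cl0$distance, 0, tolerance = 1e-6)
  # threshold above the whole profile: compliant everywhere
  clc <- clearance_distance(fit_decay(prof), threshold = 1e5)
  expect_true(clc$compliant_everywhere)
  expect_equal(clc$distance, 0)
})

test_that("scaling a profile up strictly increases the clearance", {
  truth <- decay_ground_truth(A = 100 * 150^3, d0 = 50, n = 3)
  prof <- gen_distance_profile(truth, c(0, 40, 100, 160))
  d1 <- clearance_distance(fit_decay(prof))$distance
  prof2 <- distance_profile(prof$distance, prof$index * 1.5)
  d2 <- clearance_distance(fit_decay(prof2))$distance
  expect_gt(d2, d1)
})

test_that("clearance uncertainty is a small half-range for the survey profiles", {
  fx <- gen_measurement_fixture("B")
  cl <- clearance_distance(fit_decay(fixture_profile(fx, "B2", 100)))
  expect_gt(cl$uncertainty, 0)
  expect_lte(cl$uncertainty, 3)
  cl4 <- clearance_distance(fit_decay(
    fixture_profile(gen_measurement_fixture("C"), "C2", 100)))
  expect_gt(cl4$uncertainty, 0)
  expect_lte(cl4$uncertainty, 4)
})

test_that("zone classification follows the EN 50499 definitions", {
  expect_equal(as.character(classify_zone(76.0, 2.0, 1.5)), "Zone0")
  expect_equal(as.character(classify_zone(2356, 76.0, 72.5)), "Zone1a")
  expect_equal(as.character(classify_zone(150, 101, 99)), "Zone1b")
  expect_equal(as.character(classify_zone(150, 120, 101)), "Zone2")
  # ties are compliant
  expect_equal(as.character(classify_zone(100, 100, 100)), "Zone0")
  expect_error(classify_zone(-1, 0, 0), "non-negative")
  expect_warning(classify_zone(10, 50, 2), "ordering")
})

test_that("classification flips from Zone 1a to Zone 0 exactly at the fitted clearance", {
  f <- fit_decay(distance_profile(c(0, 40, 100), c(2356, 401, 83)))
  dstar <- clearance_distance(f)$distance
  eps <- 1e-6
  inside <- predict(f, dstar - eps)
  outside <- predict(f, dstar + eps)
  expect_equal(as.character(classify_zone(inside, 1, 1)), "Zone1a")
  expect_equal(as.character(classify_zone(outside, 1, 1)), "Zone0")
})

test_that("zone boundary map recovers known crossings in order", {
  d <- c(0, 40, 100, 160)
  mk <- function(cross, curve) {
    truth <- decay_ground_truth(A = 100 * (cross + 50)^3, d0 = 50, n = 3)
    gen_distance_profile(truth, d, curve_id = curve)
  }
  zb <- zone_boundary_map(list(mk(120, "RL_B"), mk(60, "LOW_AL_B"),
                               mk(30, "HIGH_AL_B")))
  expect_equal(zb$distance, c(120, 60, 30), tolerance = 1e-4)
  expect_equal(zb$boundary_label,
               c("Zone 0 / Zone 1a", "Zone 1a / Zone 1b", "Zone 1b / Zone 2"))
  # all-compliant profiles produce no boundaries, only Zone 0
  low <- decay_ground_truth(A = 50 * 50^3, d0 = 50, n = 3)
  zb0 <- zone_boundary_map(list(
    gen_distance_profile(low, d, curve_id = "RL_B"),
    gen_distance_profile(low, d, curve_id = "LOW_AL_B")))
  expect_true(all(zb0$compliant_everywhere))
  # mismatched geometries are rejected
  expect_error(zone_boundary_map(list(mk(120, "RL_B"),
    gen_distance_profile(low, c(0, 50, 100, 150), curve_id = "LOW_AL_B"))),
    "share distances")
})

test_that("noisy profiles still recover the clearance to a few percent", {
  truth <- decay_ground_truth(index_at_zero = 2356, d0 = 53.7, n = 3.18,
                              noise_sd = 0.05)
  target <- true_clearance(truth)
  err <- vapply(1:40, function(s) {
    prof <- gen_distance_profile(truth, c(0, 40, 100, 150), seed = s)
    f <- fit_decay(prof)
    abs((f$A / 100)^(1 / f$n) - f$d0 - target)
  }, numeric(1))
  expect_lt(stats::median(err) / target, 0.05)
})
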