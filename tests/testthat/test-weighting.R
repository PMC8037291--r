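test_that("complex weight magnitude is the inverse peak-equivalent limit", {
  sp <- weighting_spec("RL_B")
  expect_equal(Mod(complex_weight(sp, 2000)), 1 / (sqrt(2) * 6.25))
  expect_equal(Arg(complex_weight(sp, 2000)), 0)
  # sqrt(2) flag off
  sp2 <- weighting_spec("RL_B", rms_to_peak = FALSE)
  expect_equal(Mod(complex_weight(sp2, 2000)), 1 / 6.25)
  # constant across a constant segment
  sp3 <- weighting_spec("LOW_AL_B")
  w <- Mod(complex_weight(sp3, c(30, 100, 299)))
  expect_equal(w, rep(w[1], 3))
  # zero outside the assessment band
  expect_equal(complex_weight(sp3, 0.5), 0 + 0i)
})

test_that("cascade phase saturates to zero above the last corner", {
  sp <- weighting_spec("LOW_AL_B", phase_model = "first_order_cascade")
  ph <- Arg(complex_weight(sp, c(1e5, 1e6)))
  expect_lt(abs(ph[1]), 0.03)
  expect_lt(abs(ph[2]), 0.003)
  expect_error(complex_weight(sp, 0), "f > 0")
  # exact magnitude in the default cascade mode
  expect_equal(Mod(complex_weight(sp, 123)),
               1 / (sqrt(2) * limit_value("LOW_AL_B", 123)))
})

test_that("cascade-shaped magnitude matches the exact one away from corners", {
  sp <- weighting_spec("LOW_AL_B", phase_model = "first_order_cascade",
                       magnitude = "cascade")
  spx <- weighting_spec("LOW_AL_B")
  # mid-plateau, about a decade from the 3 kHz and 10 MHz corners
  for (f in c(1e5, 1e6)) {
    expect_equal(Mod(complex_weight(sp, f)), Mod(complex_weight(spx, f)),
                 tolerance = 0.05)
  }
  # at a corner the first-order response is 3 dB off the asymptote
  ratio <- Mod(complex_weight(sp, 3000)) / Mod(complex_weight(spx, 3000))
  expect_gt(abs(log(ratio)), 0.1)
})

test_that("single tones reproduce the closed-form index in both backends", {
  sp <- weighting_spec("LOW_AL_B")
  for (f in c(50, 400, 1000)) {
    A <- 3 * limit_value("LOW_AL_B", f)
    want <- 100 * A / (sqrt(2) * limit_value("LOW_AL_B", f))
    expect_equal(wp_index_spectral(spectral_lines(f, A), sp)$index_percent,
                 want, tolerance = 1e-3)
    expect_equal(wp_index_time(tone_record(f, A), sp)$index_percent,
                 want, tolerance = 5e-3)
  }
})

test_that("index is homogeneous of degree one in the waveform", {
  sp <- weighting_spec("RL_B")
  ts1 <- ref_train(amplitude = 20)
  ts2 <- ref_train(amplitude = 20 * 3.7)
  i1 <- wp_index_time(ts1, sp)$index_percent
  i2 <- wp_index_time(ts2, sp)$index_percent
  expect_equal(i2 / i1, 3.7, tolerance = 1e-3)
})

test_that("duplicating a tone on two of three axes scales the index by sqrt(2)", {
  sp <- weighting_spec("RL_B")
  single <- wp_index_time(tone_record(1000, 10), sp)
  dual <- wp_index_time(tone_record(1000, 10, axis_gains = c(1, 1, 0)), sp)
  expect_equal(dual$index_percent / single$index_percent, sqrt(2),
               tolerance = 1e-6)
  expect_named(dual$per_axis_index, c("Bx", "By", "Bz"))
  expect_equal(unname(dual$per_axis_index[1]), single$index_percent,
               tolerance = 1e-9)
  # combined maximum dominates every per-axis maximum
  expect_true(all(dual$per_axis_index <= dual$index_percent + 1e-9))
})

test_that("two-line superposition matches the brute-force oracle and the analytic maximum", {
  # lines at f and 3f on the low-AL constant plateau: max of
  # cos(x) + cos(3x)/3 is 4/3 at x = 0
  sp <- weighting_spec("LOW_AL_B")
  A <- 500
  lines <- spectral_lines(c(50, 150), c(A, A / 3))
  got <- wp_index_spectral(lines, sp)$index_percent
  oracle <- brute_force_wp(lines, sp)
  analytic <- 100 * A * (4 / 3) / (sqrt(2) * 1000)
  expect_equal(got, oracle, tolerance = 1e-3)
  expect_equal(got, analytic, tolerance = 1e-3)
})

test_that("time and spectral backends agree on a band-limited periodic train", {
  spec <- sequence_spec("trapezoid_train", fundamental = 500,
                        rise_time = 1e-4, plateau = 5e-4, amplitude = 50,
                        repetitions = 20, sample_rate = 128000)
  ts <- gen_waveform(spec)
  lines <- trapezoid_fourier_lines(spec, k_max = 127)  # below Nyquist
  for (curve in c("LOW_AL_B", "RL_B")) {
    sp <- weighting_spec(curve)
    it <- wp_index_time(ts, sp)$index_percent
    is <- wp_index_spectral(lines, sp)$index_percent
    expect_equal(it, is, tolerance = 0.01, label = curve)
  }
})

test_that("index ordering follows the limit ordering RL >= LowAL >= HighAL", {
  ts <- ref_train(amplitude = 30)
  i_rl <- wp_index_time(ts, weighting_spec("RL_B"))$index_percent
  i_lo <- wp_index_time(ts, weighting_spec("LOW_AL_B"))$index_percent
  i_hi <- wp_index_time(ts, weighting_spec("HIGH_AL_B"))$index_percent
  expect_gte(i_rl, i_lo)
  expect_gte(i_lo, i_hi)
})

test_that("low-cut high-pass attenuates low-frequency tones by the first-order gain", {
  sp <- weighting_spec("RL_B", low_cut = 30)
  sp0 <- weighting_spec("RL_B")
  f <- 10
  r <- f / 30
  gain <- r / sqrt(1 + r^2)
  i0 <- wp_index_time(tone_record(f, 100, samples_per_period = 256), sp0)
  i1 <- wp_index_time(tone_record(f, 100, samples_per_period = 256), sp)
  expect_equal(i1$index_percent / i0$index_percent, gain, tolerance = 1e-3)
  # well above the corner the high-pass is transparent
  i2 <- wp_index_time(tone_record(1000, 100), sp)
  i3 <- wp_index_time(tone_record(1000, 100), sp0)
  expect_equal(i2$index_percent, i3$index_percent, tolerance = 1e-3)
})

test_that("low and high AL indices nearly coincide for >300 Hz content, ratio 6 at 50 Hz", {
  pair <- index_pair_lowal_highal(ref_train())
  expect_gt(pair$energy_above_300hz, 0.95)
  expect_equal(pair$low_al$index_percent, pair$high_al$index_percent,
               tolerance = 0.1)
  tone <- tone_record(50, 1000)
  pair50 <- index_pair_lowal_highal(tone)
  expect_equal(pair50$low_al$index_percent / pair50$high_al$index_percent,
               6, tolerance = 1e-6)
  tone1k <- tone_record(1000, 100)
  pair1k <- index_pair_lowal_highal(tone1k)
  expect_equal(pair1k$low_al$index_percent, pair1k$high_al$index_percent,
               tolerance = 1e-9)
})

test_that("degenerate inputs are rejected or flagged", {
  sp <- weighting_spec("RL_B")
  expect_error(spectral_lines(numeric(0), numeric(0)), "empty")
  expect_error(spectral_lines(-5, 1), "> 0")
  bad <- gmf_timeseries(c(1, NaN, 3, 4), 100)
  expect_error(wp_index_time(bad, sp), "NaN|finite")
  # line outside the curve domain
  expect_error(wp_index_spectral(spectral_lines(2e7, 1),
                                 weighting_spec("LOW_AL_B")), "domain")
  # undersampled content (within 5% of Nyquist) is flagged in the result
  n <- 256
  x <- cos(2 * pi * 125 * (0:(n - 1)) / 256)  # 125 Hz at fs 256
  r <- wp_index_time(gmf_timeseries(x, 256), sp)
  expect_true(length(r$warnings) > 0)
})
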