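# Shared fixtures and independent oracles for the test suite.

# integer-period sampled tone record
tone_record <- function(f, amplitude, periods = 20, samples_per_period = 64,
                        axis_gains = 1) {
  gen_waveform(sequence_spec("tone", fundamental = f, amplitude = amplitude,
                             repetitions = periods,
                             sample_rate = samples_per_period * f),
               axis_gains = axis_gains)
}

# Brute-force weighted-peak oracle for a spectral line set: dense time scan
# of sum_i A_i |W_i| cos(2 pi f_i t + phi_i + arg W_i), independent of the
# grid-refinement logic in wp_index_spectral().
brute_force_wp <- function(lines, spec, n_grid = 1e6, n_periods = 10) {
  W <- complex_weight(spec, lines$f)
  phase <- if (is.null(lines$phase)) 0 else lines$phase
  t <- seq(0, n_periods / min(lines$f), length.out = n_grid)
  wav <- numeric(length(t))
  for (i in seq_len(nrow(lines))) {
    wav <- wav + lines$amplitude[i] * Mod(W[i]) *
      cos(2 * pi * lines$f[i] * t + phase[i] + Arg(W[i]))
  }
  100 * max(abs(wav))
}

# Analytic Fourier-series lines of the unipolar trapezoid train: the lobe is
# the convolution of two rectangles (widths rise+plateau and rise), so
# |c_k| = (A/T) (r+p) sinc(k(r+p)/T) sinc(kr/T), with sinc(x)=sin(pi x)/(pi x).
trapezoid_fourier_lines <- function(spec, k_max) {
  T <- 1 / spec$fundamental
  r <- spec$rise_time; p <- spec$plateau; A <- spec$amplitude
  k <- seq_len(k_max)
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  ck <- (A / T) * (r + p) * sinc(k * (r + p) / T) * sinc(k * r / T) *
    exp(-1i * pi * k * (2 * r + p) / T)
  keep <- Mod(ck) > 0
  spectral_lines(f = k[keep] * spec$fundamental,
                 amplitude = 2 * Mod(ck)[keep],
                 phase = Arg(ck)[keep])
}

# reference gradient-like train used across tests (fundamental 500 Hz,
# 0.1 ms rise, 0.5 ms plateau)
ref_train <- function(amplitude = 50, repetitions = 20, sample_rate = 64000) {
  gen_waveform(sequence_spec("trapezoid_train", fundamental = 500,
                             rise_time = 1e-4, plateau = 5e-4,
                             amplitude = amplitude,
                             repetitions = repetitions,
                             sample_rate = sample_rate))
}
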