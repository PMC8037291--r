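# Synthetic MRI-gradient-like signals and distance profiles with known
# ground truth. The generators stand in for the tomographs: gradient
# sequences produce trains of trapezoidal lobes whose spectral content sits
# above a few hundred hertz, and the stray-field index decays with distance
# from the gantry mouth approximately as an offset power law.

#' Specify a synthetic gradient sequence
#'
#' @param kind `"tone"` (sampled cosine), `"trapezoid_train"` (one trapezoidal
#'   lobe per period: linear rise, flat plateau, linear fall, rest at zero) or
#'   `"bipolar_epi_train"` (EPI-readout-like: one lobe per half-period with
#'   alternating polarity).
#' @param fundamental Repetition frequency in Hz.
#' @param rise_time Lobe rise (= fall) time in seconds; ignored for tones.
#' @param plateau Lobe plateau duration in seconds; ignored for tones.
#' @param amplitude Peak flux density at the reference position, microtesla.
#' @param repetitions Integer number of periods to generate.
#' @param sample_rate Sampling rate in Hz (at least 20 x fundamental).
#' @return A `sequence_spec` object.
#' @export
#' @examples
#' sequence_spec("trapezoid_train", fundamental = 500,
#'               rise_time = 1e-4, plateau = 5e-4, amplitude = 80)
sequence_spec <- function(kind = c("tone", "trapezoid_train",
                                   "bipolar_epi_train"),
                          fundamental, rise_time = 0, plateau = 0,
                          amplitude = 1, repetitions = 10,
                          sample_rate = 200 * fundamental) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(fundamental), fundamental > 0,
            is.numeric(amplitude), amplitude > 0,
            repetitions >= 1, repetitions == round(repetitions))
  if (rise_time < 0) stop("rise_time must be >= 0")
  if (plateau < 0) stop("plateau must be >= 0")
  period <- 1 / fundamental
  if (sample_rate < 20 * fundamental) {
    stop("sample_rate must be at least 20 x fundamental (got ",
         sample_rate, " Hz for fundamental ", fundamental, " Hz)")
  }
  if (kind == "trapezoid_train" && 2 * rise_time + plateau > period * (1 + 1e-12)) {
    stop("2*rise_time + plateau must not exceed the period (1/fundamental)")
  }
  if (kind == "bipolar_epi_train" &&
      2 * rise_time + plateau > period / 2 * (1 + 1e-12)) {
    stop("2*rise_time + plateau must not exceed the half-period for a bipolar train")
  }
  if (kind != "tone" && rise_time == 0 && plateau == 0) {
    stop("trapezoid lobes need rise_time > 0 or plateau > 0")
  }
  structure(list(kind = kind, fundamental = fundamental,
                 rise_time = rise_time, plateau = plateau,
                 amplitude = amplitude, repetitions = as.integer(repetitions),
                 sample_rate = sample_rate),
            class = "sequence_spec")
}

# trapezoid lobe value at phase time u in [0, period), 0 outside the lobe
.trapezoid_lobe <- function(u, rise, plateau, amplitude) {
  out <- numeric(length(u))
  if (rise > 0) {
    s <- u >= 0 & u < rise
    out[s] <- amplitude * u[s] / rise
  }
  s <- u >= rise & u < rise + plateau
  out[s] <- amplitude
  if (rise > 0) {
    s <- u >= rise + plateau & u < 2 * rise + plateau
    out[s] <- amplitude * (2 * rise + plateau - u[s]) / rise
  }
  out
}

#' Generate a sampled waveform from a sequence specification
#'
#' The record always contains an integer number of periods (the sample rate
#' is adjusted to the nearest integer number of samples per period, recorded
#' in the result), so FFT-based assessment sees no spectral leakage.
#'
#' @param spec A `sequence_spec`.
#' @param axis_gains Numeric vector of per-axis projection gains; length 1 or
#'   3. The same waveform is projected on each axis with the given gain
#'   (e.g. `c(0.8, 0.6, 0)` for an oblique field direction).
#' @return A `gmf_timeseries`.
#' @export
gen_waveform <- function(spec, axis_gains = 1) {
  stopifnot(inherits(spec, "sequence_spec"))
  if (!length(axis_gains) %in% c(1L, 3L)) {
    stop("axis_gains must have length 1 or 3")
  }
  period <- 1 / spec$fundamental
  m <- round(spec$sample_rate * period)
  fs <- m / period
  u <- (seq_len(m) - 1) / fs
  one <- switch(spec$kind,
    tone = spec$amplitude * cos(2 * pi * spec$fundamental * u),
    trapezoid_train = .trapezoid_lobe(u, spec$rise_time, spec$plateau,
                                      spec$amplitude),
    bipolar_epi_train = {
      half <- period / 2
      .trapezoid_lobe(u %% half, spec$rise_time, spec$plateau,
                      spec$amplitude) * ifelse(u < half, 1, -1)
    })
  wave <- rep(one, spec$repetitions)
  B <- outer(wave, axis_gains)
  axes <- if (length(axis_gains) == 1) "B" else c("Bx", "By", "Bz")
  gmf_timeseries(B, fs, axes = axes)
}

#' Ground truth for a synthetic index-versus-distance profile
#'
#' The weighted-peak index decays with distance `d` (cm) from the gantry
#' mouth as `index(d) = A * (d + d0)^(-n)`, where `d0` is the offset of the
#' effective source centre behind the mouth and `n` the decay exponent.
#'
#' @param A Coefficient (index scale, percent x cm^n); or use `index_at_zero`.
#' @param d0 Source-centre offset in cm (> 0).
#' @param n Decay exponent (> 0); near-field gradient-coil stray fields fall
#'   off with exponents around 3.
#' @param noise_sd Relative (multiplicative) noise standard deviation,
#'   emulating probe-positioning reproducibility error.
#' @param index_at_zero Alternative to `A`: the index (%) at distance 0.
#' @return A `decay_ground_truth` object.
#' @export
#' @examples
#' decay_ground_truth(index_at_zero = 2356, d0 = 53.7, n = 3.18)
decay_ground_truth <- function(A = NULL, d0, n, noise_sd = 0,
                               index_at_zero = NULL) {
  if (is.null(A) + is.null(index_at_zero) != 1) {
    stop("give exactly one of A or index_at_zero")
  }
  if (is.null(A)) A <- index_at_zero * d0^n
  stopifnot(A > 0, d0 > 0, n > 0, noise_sd >= 0)
  structure(list(A = A, d0 = d0, n = n, noise_sd = noise_sd),
            class = "decay_ground_truth")
}

#' True clearance distance of a ground-truth decay model
#'
#' @param truth A `decay_ground_truth`.
#' @param threshold Index threshold in percent (default 100).
#' @return Distance in cm where the noise-free model crosses the threshold
#'   (0 if the model is below the threshold everywhere).
#' @export
true_clearance <- function(truth, threshold = 100) {
  stopifnot(inherits(truth, "decay_ground_truth"), threshold > 0)
  max(0, (truth$A / threshold)^(1 / truth$n) - truth$d0)
}

#' Generate a synthetic index-versus-distance profile
#'
#' Evaluates the ground-truth decay model at the given distances and applies
#' multiplicative Gaussian noise `(1 + eps)`, `eps ~ N(0, noise_sd)`,
#' reproducibly from `seed`. With `noise_sd = 0` the model values are exact.
#'
#' @param truth A `decay_ground_truth`.
#' @param distances Strictly increasing non-negative distances in cm (>= 3).
#' @param seed Integer seed for the noise (ignored when `noise_sd = 0`).
#' @param height,sequence_label,curve_id Metadata carried on the profile.
#' @return A `distance_profile`.
#' @export
gen_distance_profile <- function(truth, distances, seed = NULL, height = 100,
                                 sequence_label = "SYN", curve_id = "RL_B") {
  stopifnot(inherits(truth, "decay_ground_truth"))
  if (length(distances) < 3) {
    stop("need at least 3 distances (the decay fit has three parameters)")
  }
  if (any(distances < 0) || any(diff(distances) <= 0)) {
    stop("distances must be non-negative and strictly increasing")
  }
  idx <- truth$A * (distances + truth$d0)^(-truth$n)
  if (truth$noise_sd > 0) {
    eps <- .with_seed(seed, stats::rnorm(length(distances),
                                         sd = truth$noise_sd))
    idx <- idx * pmax(1 + eps, 0.05)
  }
  distance_profile(distances, idx, height = height,
                   sequence_label = sequence_label, curve_id = curve_id)
}

# run code under a temporary RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Packaged survey measurements for a tomograph
#'
#' Returns the packaged weighted-peak index tables measured around three
#' clinical MRI tomographs: `"A"` (Philips Panorama 1 T, open magnet),
#' `"B"` (Philips Ingenia 1.5 T) and `"C"` (Siemens Magnetom Aera 1.5 T).
#' Indices are percentages versus the stated limit curve, at positions along
#' the departure line from the gantry mouth (label `LINE`, distance in cm) or
#' at the `OP` / `REAR` spot positions.
#'
#' @param tomograph_id `"A"`, `"B"` or `"C"`.
#' @return Data frame with columns `table`, `sequence`, `position_label`,
#'   `distance_cm`, `height_cm`, `curve_id`, `index_percent`, `instrument`.
#' @export
#' @examples
#' b <- gen_measurement_fixture("B")
#' subset(b, sequence == "B2" & curve_id == "RL_B" & height_cm == 100)
gen_measurement_fixture <- function(tomograph_id) {
  tables <- switch(as.character(tomograph_id),
                   A = c(4, 5), B = c(6, 7), C = 8,
                   stop("unknown tomograph id '", tomograph_id,
                        "'; expected A, B or C"))
  out <- do.call(rbind, lapply(tables, function(tb) {
    path <- system.file("extdata", sprintf("table%d.tsv", tb),
                        package = "gmfassess", mustWork = TRUE)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    cbind(table = tb, df)
  }))
  rownames(out) <- NULL
  out
}

#' All packaged survey tables
#' @return Data frame as in [gen_measurement_fixture()], all tomographs.
#' @export
fixture_tables <- function() {
  out <- do.call(rbind, lapply(c("A", "B", "C"), gen_measurement_fixture))
  rownames(out) <- NULL
  out
}

#' Extract a fittable distance profile from a fixture table
#'
#' Filters one (sequence, height, curve) group of departure-line points from
#' a fixture table and returns it as a `distance_profile` ready for
#' [fit_decay()].
#'
#' @param fixture Data frame from [gen_measurement_fixture()].
#' @param sequence Sequence code (e.g. `"B2"`).
#' @param height Height above the floor in cm.
#' @param curve_id Limit-curve identifier (default `"RL_B"`).
#' @param instrument Optional instrument filter.
#' @return A `distance_profile`.
#' @export
fixture_profile <- function(fixture, sequence, height, curve_id = "RL_B",
                            instrument = NULL) {
  sel <- fixture$sequence == sequence & fixture$height_cm == height &
    fixture$curve_id == curve_id & fixture$position_label == "LINE"
  if (!is.null(instrument)) sel <- sel & fixture$instrument == instrument
  df <- fixture[sel & !is.na(fixture$distance_cm), ]
  df <- df[order(df$distance_cm), ]
  distance_profile(df$distance_cm, df$index_percent, height = height,
                   sequence_label = sequence, curve_id = curve_id)
}
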