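# Sampled flux-density waveform container and its file dialects.

#' Construct a sampled flux-density record
#'
#' @param samples Numeric vector (single axis) or matrix with 1 or 3 columns
#'   (axes), instantaneous flux density in microtesla.
#' @param sample_rate Sampling rate in Hz.
#' @param axes Optional axis labels; defaults to `"B"` or `c("Bx","By","Bz")`.
#' @return A `gmf_timeseries` object: list with elements `B` (n x k matrix),
#'   `sample_rate` (Hz), `duration` (s) and `axes`.
#' @export
#' @examples
#' ts <- gmf_timeseries(cos(2 * pi * 50 * (0:999) / 1e4), 1e4)
gmf_timeseries <- function(samples, sample_rate, axes = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("samples must be a numeric vector or matrix")
  }
  if (!ncol(samples) %in% c(1L, 3L)) {
    stop("samples must have 1 or 3 axis columns, got ", ncol(samples))
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar (Hz)")
  }
  if (is.null(axes)) {
    axes <- if (ncol(samples) == 1) "B" else c("Bx", "By", "Bz")
  }
  colnames(samples) <- axes
  structure(list(B = samples, sample_rate = sample_rate,
                 duration = nrow(samples) / sample_rate, axes = axes),
            class = "gmf_timeseries")
}

#' @export
print.gmf_timeseries <- function(x, ...) {
  cat(sprintf("<gmf_timeseries> %d samples x %d axis(es), fs = %g Hz, %.4g s\n",
              nrow(x$B), ncol(x$B), x$sample_rate, x$duration))
  cat(sprintf("  peak |B| = %.4g uT\n", max(abs(x$B))))
  invisible(x)
}

#' Time stamps of a record
#' @param ts A `gmf_timeseries`.
#' @return Numeric vector of sample times in seconds (starting at 0).
#' @export
time_points <- function(ts) {
  stopifnot(inherits(ts, "gmf_timeseries"))
  (seq_len(nrow(ts$B)) - 1) / ts$sample_rate
}

#' Read a waveform file
#'
#' Two dialects are supported. The headered dialect carries comment lines
#' `# sample_rate_hz=...` and `# units=uT` followed by a column header
#' `t Bx [By Bz]` (tab or comma separated). The headerless two-column dialect
#' is plain `t B` pairs, with the sample rate supplied via `sample_rate`.
#'
#' @param path File path.
#' @param sample_rate Sample rate in Hz, required for the headerless dialect;
#'   when given together with a header it must agree within 0.1%.
#' @return A `gmf_timeseries`.
#' @export
read_waveform <- function(path, sample_rate = NULL) {
  if (!file.exists(path)) stop("waveform file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("waveform file has no data rows: ", path)
  fs_hdr <- NULL
  m <- regmatches(hdr, regexec("sample_rate_hz\\s*=\\s*([0-9.eE+-]+)", hdr))
  m <- Filter(function(x) length(x) == 2, m)
  if (length(m)) fs_hdr <- as.numeric(m[[1]][2])
  sep <- if (grepl("\t", body[1])) "\t" else if (grepl(",", body[1])) "," else ""
  has_header <- grepl("^[A-Za-z]", trimws(body[1]))
  df <- tryCatch(
    utils::read.table(text = paste(body, collapse = "\n"), header = has_header,
                      sep = sep, strip.white = TRUE),
    error = function(e) stop("malformed waveform file ", path, ": ",
                             conditionMessage(e)))
  if (!has_header) {
    if (ncol(df) != 2) {
      stop("headerless waveform dialect requires exactly 2 columns (t, B); ",
           "got ", ncol(df), " in ", path)
    }
    names(df) <- c("t", "B")
  }
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    stop("non-numeric values in waveform file ", path,
         " (column ", paste(names(df)[bad], collapse = ", "),
         "); first data line ", length(hdr) + has_header + 1)
  }
  tt <- df[[1]]
  fs <- fs_hdr
  if (!is.null(sample_rate)) {
    if (!is.null(fs) && abs(fs - sample_rate) > 1e-3 * fs) {
      stop("sample_rate argument disagrees with file header in ", path)
    }
    fs <- sample_rate
  }
  if (is.null(fs)) {
    dt <- diff(tt)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6 * stats::median(dt)) {
      stop("cannot infer sample rate: time column of ", path,
           " is not uniformly increasing and no sample_rate_hz header given")
    }
    fs <- 1 / stats::median(dt)
  }
  gmf_timeseries(as.matrix(df[, -1, drop = FALSE]), fs,
                 axes = names(df)[-1])
}

#' Write a waveform file in the headered dialect
#'
#' @param ts A `gmf_timeseries`.
#' @param path Output path.
#' @param extra_header Named character vector of extra `# key=value` lines.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(ts, path, extra_header = NULL) {
  stopifnot(inherits(ts, "gmf_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz=%.10g", ts$sample_rate), con)
  writeLines("# units=uT", con)
  if (!is.null(extra_header)) {
    writeLines(sprintf("# %s=%s", names(extra_header), extra_header), con)
  }
  df <- data.frame(t = time_points(ts), ts$B, check.names = FALSE)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fraction of AC spectral energy above a frequency
#'
#' Computes, from the discrete spectrum of a record, the fraction of signal
#' energy (DC excluded) carried by components at or above `f_min`. DC is
#' excluded because a static offset is outside the action-level curve domain
#' and carries no time-varying exposure.
#'
#' @param ts A `gmf_timeseries`.
#' @param f_min Frequency threshold in Hz.
#' @param exclude_dc Drop the DC bin from the energy total (default `TRUE`).
#' @return Scalar in `[0, 1]`, summed over all axes.
#' @export
spectral_energy_fraction <- function(ts, f_min, exclude_dc = TRUE) {
  stopifnot(inherits(ts, "gmf_timeseries"))
  n <- nrow(ts$B)
  f <- (seq_len(n) - 1) * ts$sample_rate / n
  f <- pmin(f, ts$sample_rate - f)  # alias to [0, fs/2]
  tot <- 0; above <- 0
  for (k in seq_len(ncol(ts$B))) {
    p <- Mod(stats::fft(ts$B[, k]))^2
    if (exclude_dc) p[1] <- 0
    tot <- tot + sum(p)
    above <- above + sum(p[f >= f_min])
  }
  if (tot == 0) return(NA_real_)
  above / tot
}
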