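# Offset power-law decay fitting, clearance distances and EN 50499 zoning.
#
# The index-versus-distance profile measured along the departure line is
# fitted with I(d) = A * (d + d0)^(-n) by unweighted least squares in log
# space; the clearance is the distance where the fitted index crosses the
# compliance threshold (100%).

.zone_levels <- c("Zone0", "Zone1a", "Zone1b", "Zone2")

#' Construct an index-versus-distance profile
#'
#' @param distance Non-negative, strictly increasing distances in cm from the
#'   gantry mouth along the departure line.
#' @param index Positive weighted-peak indices in percent versus `curve_id`.
#' @param height Measurement height above the floor, cm.
#' @param sequence_label Gradient-sequence label.
#' @param curve_id Limit curve the indices refer to.
#' @return A `distance_profile` object.
#' @export
distance_profile <- function(distance, index, height = NA_real_,
                             sequence_label = NA_character_,
                             curve_id = "RL_B") {
  stopifnot(is.numeric(distance), is.numeric(index),
            length(distance) == length(index))
  if (any(distance < 0)) stop("distances must be non-negative")
  if (any(diff(distance) <= 0)) stop("distances must be strictly increasing")
  if (any(index <= 0)) stop("indices must be positive")
  structure(list(distance = as.numeric(distance), index = as.numeric(index),
                 height = height, sequence_label = sequence_label,
                 curve_id = curve_id),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile> %s vs %s, height %s cm, %d points\n",
              x$sequence_label, x$curve_id, format(x$height),
              length(x$distance)))
  print(data.frame(distance_cm = x$distance, index_percent = x$index))
  invisible(x)
}

# Residual sum of squares of log(index) ~ log(A) - n log(d + d0), profiled
# over the linear parameters for a fixed d0.
.profiled_fit <- function(d, logI, d0) {
  x <- log(d + d0)
  fit <- stats::lm.fit(cbind(1, x), logI)
  list(logA = unname(fit$coefficients[1]), n = -unname(fit$coefficients[2]),
       rss = sum(fit$residuals^2))
}

#' Fit an offset power-law decay to a distance profile
#'
#' Fits `index(d) = A * (d + d0)^(-n)` by unweighted least squares of
#' `log(index)` against `log(d + d0)`, with the inner linear problem solved
#' exactly and the offset `d0` found by a deterministic one-dimensional
#' search. Three points are interpolated exactly (zero residual); with more
#' points the residual is the usual least-squares one.
#'
#' @param profile A `distance_profile` with at least 3 points.
#' @param d0_range Search interval for the offset, cm.
#' @return A `decay_fit` object: `A`, `d0`, `n`, `rms_log_residual`,
#'   `n_points`, plus the profile it was fitted to.
#' @export
#' @examples
#' p <- distance_profile(c(0, 40, 100), c(2356, 401, 83))
#' fit_decay(p)   # d0 ~ 54 cm, n ~ 3.2
fit_decay <- function(profile, d0_range = c(1e-3, 1e4)) {
  stopifnot(inherits(profile, "distance_profile"))
  d <- profile$distance; I <- profile$index
  if (length(d) < 3) stop("decay fit needs at least 3 points")
  if (diff(range(I)) == 0) stop("degenerate profile: all indices equal")
  if (any(diff(I) >= 0)) {
    # a non-decreasing pair makes the monotone power-law model inapplicable
    if (stats::cor(d, I) >= 0) {
      stop("profile is not decreasing with distance; offset power-law ",
           "decay model does not apply")
    }
  }
  logI <- log(I)
  rss_of <- function(ld0) .profiled_fit(d, logI, exp(ld0))$rss
  interval <- log(d0_range)
  if (length(d) == 3) {
    # exact interpolation: the three points are collinear in
    # (log(d + d0), log I) at the root of the slope-difference function
    g <- function(ld0) {
      d0 <- exp(ld0)
      s1 <- (logI[2] - logI[1]) / (log(d[2] + d0) - log(d[1] + d0))
      s2 <- (logI[3] - logI[2]) / (log(d[3] + d0) - log(d[2] + d0))
      s1 - s2
    }
    glo <- g(interval[1]); ghi <- g(interval[2])
    if (is.finite(glo) && is.finite(ghi) && glo * ghi < 0) {
      root <- stats::uniroot(g, interval, tol = 1e-13)
      ld0 <- root$root
    } else {
      ld0 <- stats::optimize(rss_of, interval, tol = 1e-12)$minimum
    }
  } else {
    ld0 <- stats::optimize(rss_of, interval, tol = 1e-12)$minimum
  }
  d0 <- exp(ld0)
  pf <- .profiled_fit(d, logI, d0)
  if (!is.finite(pf$rss) || pf$n <= 0) {
    stop(sprintf(
      "decay fit did not converge to an admissible model (d0 search over [%g, %g] cm): fitted n = %.3g",
      d0_range[1], d0_range[2], pf$n))
  }
  structure(list(A = exp(pf$logA), d0 = d0, n = pf$n,
                 rms_log_residual = sqrt(pf$rss / length(d)),
                 n_points = length(d), profile = profile),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> index(d) = %.4g * (d + %.3f)^(-%.4f)  [%d points, rms log residual %.2e]\n",
    x$A, x$d0, x$n, x$n_points, x$rms_log_residual))
  invisible(x)
}

#' Predict indices from a decay fit
#' @param object A `decay_fit`.
#' @param distance Distances in cm.
#' @param ... Unused.
#' @return Predicted indices in percent.
#' @export
predict.decay_fit <- function(object, distance, ...) {
  object$A * (distance + object$d0)^(-object$n)
}

.crossing <- function(A, d0, n, threshold) {
  max(0, (A / threshold)^(1 / n) - d0)
}

#' Clearance distance where the fitted index crosses a threshold
#'
#' Solves `A * (d + d0)^(-n) = threshold` for `d`. If the fitted index is
#' below the threshold already at `d = 0` the clearance is 0 and the result
#' is flagged compliant everywhere. The uncertainty (half-width) is the
#' half-range of crossings over leave-one-out refits when the profile has at
#' least 4 points, and over refits with each index perturbed by +/-5%
#' (one at a time) for 3-point profiles.
#'
#' @param fit A `decay_fit`.
#' @param threshold Compliance threshold in percent (default 100; indices at
#'   or below it are compliant).
#' @return A `clearance_result`: `distance` (cm), `uncertainty` (cm),
#'   `threshold`, `compliant_everywhere`, `extrapolated` (crossing outside
#'   the sampled distance range) and `boundary_label`.
#' @export
clearance_distance <- function(fit, threshold = 100) {
  stopifnot(inherits(fit, "decay_fit"))
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  prof <- fit$profile
  at0 <- predict(fit, 0)
  compliant <- at0 <= threshold
  dist <- if (compliant) 0 else .crossing(fit$A, fit$d0, fit$n, threshold)
  refit_cross <- function(d, I) {
    f <- tryCatch(fit_decay(distance_profile(d, I, height = prof$height,
                                             sequence_label = prof$sequence_label,
                                             curve_id = prof$curve_id)),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else .crossing(f$A, f$d0, f$n, threshold)
  }
  unc <- 0
  if (!compliant) {
    cr <- if (fit$n_points >= 4) {
      vapply(seq_along(prof$distance), function(i)
        refit_cross(prof$distance[-i], prof$index[-i]), numeric(1))
    } else {
      unlist(lapply(seq_along(prof$index), function(i) {
        vapply(c(0.95, 1.05), function(k) {
          I <- prof$index; I[i] <- I[i] * k
          refit_cross(prof$distance, I)
        }, numeric(1))
      }))
    }
    cr <- cr[is.finite(cr)]
    if (length(cr)) unc <- (max(cr) - min(cr)) / 2
  }
  label <- switch(prof$curve_id %||% "RL_B",
                  RL_B = "Zone 0 / Zone 1a",
                  LOW_AL_B = "Zone 1a / Zone 1b",
                  HIGH_AL_B = "Zone 1b / Zone 2",
                  NA_character_)
  structure(list(distance = dist, uncertainty = unc, threshold = threshold,
                 compliant_everywhere = compliant,
                 extrapolated = !compliant &&
                   (dist < min(prof$distance) || dist > max(prof$distance)),
                 boundary_label = label,
                 curve_id = prof$curve_id,
                 sequence_label = prof$sequence_label,
                 height = prof$height),
            class = "clearance_result")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' @export
print.clearance_result <- function(x, ...) {
  if (x$compliant_everywhere) {
    cat(sprintf("<clearance_result> compliant everywhere (index <= %g%% at the gantry mouth)\n",
                x$threshold))
  } else {
    cat(sprintf("<clearance_result> %.0f +/- %.0f cm at index = %g%% (%s)%s\n",
                x$distance, ceiling(x$uncertainty), x$threshold,
                x$boundary_label,
                if (x$extrapolated) " [extrapolated]" else ""))
  }
  invisible(x)
}

#' EN 50499 Annex E zone classification of an assessment point
#'
#' Classifies a point from its weighted-peak indices versus the three limit
#' curves: Zone 0 if the reference-level index is at most 100%, else Zone 1a
#' if the low action-level index is at most 100%, else Zone 1b if the high
#' action-level index is at most 100%, else Zone 2. Ties (index exactly 100)
#' are compliant.
#'
#' @param index_rl,index_lowal,index_highal Indices in percent (vectorized).
#' @return Factor with levels `Zone0`, `Zone1a`, `Zone1b`, `Zone2`.
#' @export
#' @examples
#' classify_zone(76, 2, 1.5)      # Zone0
#' classify_zone(2356, 76, 72.5)  # Zone1a
classify_zone <- function(index_rl, index_lowal, index_highal) {
  n <- max(length(index_rl), length(index_lowal), length(index_highal))
  index_rl <- rep_len(index_rl, n)
  index_lowal <- rep_len(index_lowal, n)
  index_highal <- rep_len(index_highal, n)
  if (any(c(index_rl, index_lowal, index_highal) < 0, na.rm = TRUE)) {
    stop("indices must be non-negative")
  }
  if (any(index_rl < index_lowal - 1e-9) || any(index_lowal < index_highal - 1e-9)) {
    warning("index ordering RL >= Low AL >= High AL violated; ",
            "classification proceeds on the values as given (measurement noise?)")
  }
  z <- ifelse(index_rl <= 100, "Zone0",
              ifelse(index_lowal <= 100, "Zone1a",
                     ifelse(index_highal <= 100, "Zone1b", "Zone2")))
  factor(z, levels = .zone_levels)
}

#' Zone boundary map from per-curve distance profiles
#'
#' Given distance profiles of the same transect measured against the
#' reference-level, low action-level and high action-level curves, fits each
#' profile that exceeds 100% anywhere and returns the ordered boundary
#' distances of the zone transitions (reference-level crossing = Zone 0 /
#' Zone 1a boundary, and so on). Boundaries are checked for the physical
#' ordering (the reference-level crossing lies farthest out).
#'
#' @param profiles List of `distance_profile` objects for curves `RL_B`,
#'   `LOW_AL_B`, `HIGH_AL_B` (any subset, named or identified by `curve_id`),
#'   sharing the same distances, height and sequence.
#' @param threshold Compliance threshold in percent (default 100).
#' @return Data frame with one row per zone transition: `curve_id`,
#'   `boundary_label`, `distance`, `uncertainty`, `compliant_everywhere`.
#' @export
zone_boundary_map <- function(profiles, threshold = 100) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  ids <- vapply(profiles, function(p) p$curve_id, character(1))
  names(profiles) <- ids
  ref <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!isTRUE(all.equal(p$distance, ref$distance)) ||
        !identical(p$height, ref$height)) {
      stop("profiles must share distances and geometry")
    }
  }
  order_ids <- intersect(c("RL_B", "LOW_AL_B", "HIGH_AL_B"), ids)
  rows <- lapply(order_ids, function(id) {
    p <- profiles[[id]]
    if (max(p$index) <= threshold) {
      cl <- list(distance = 0, uncertainty = 0, compliant_everywhere = TRUE,
                 boundary_label = switch(id, RL_B = "Zone 0 / Zone 1a",
                                         LOW_AL_B = "Zone 1a / Zone 1b",
                                         HIGH_AL_B = "Zone 1b / Zone 2"))
    } else {
      cl <- clearance_distance(fit_decay(p), threshold = threshold)
    }
    data.frame(curve_id = id, boundary_label = cl$boundary_label,
               distance = cl$distance, uncertainty = cl$uncertainty,
               compliant_everywhere = cl$compliant_everywhere,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dd <- out$distance
  if (any(diff(dd) > 1e-6 + pmax(out$uncertainty[-1], out$uncertainty[-nrow(out)]))) {
    warning("zone boundaries out of physical order ",
            "(inner boundary beyond an outer one)")
  }
  out
}

#' Read distance profiles from a TSV file
#'
#' Expects columns `distance_cm`, `index_percent` and optionally `height_cm`,
#' `sequence`, `curve_id` (defaulted when absent). Lines starting with `#`
#' are ignored.
#'
#' @param path File path.
#' @return List of `distance_profile`, one per (sequence, height, curve)
#'   group, ordered by group.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed profile file ", path, ": ",
                             conditionMessage(e)))
  need <- c("distance_cm", "index_percent")
  if (!all(need %in% names(df))) {
    stop("profile file ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  if (is.null(df$height_cm)) df$height_cm <- NA_real_
  if (is.null(df$sequence)) df$sequence <- "SEQ"
  if (is.null(df$curve_id)) df$curve_id <- "RL_B"
  groups <- split(df, interaction(df$sequence, df$height_cm, df$curve_id,
                                  drop = TRUE))
  lapply(groups, function(g) {
    g <- g[order(g$distance_cm), ]
    distance_profile(g$distance_cm, g$index_percent,
                     height = g$height_cm[1], sequence_label = g$sequence[1],
                     curve_id = g$curve_id[1])
  })
}

#' Write distance profiles to a TSV file
#' @param profiles A `distance_profile` or list of them.
#' @param path Output path.
#' @param header Optional character vector of `# ` comment lines.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, header = NULL) {
  if (inherits(profiles, "distance_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(sequence = p$sequence_label, height_cm = p$height,
               curve_id = p$curve_id, distance_cm = p$distance,
               index_percent = p$index, stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
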