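## Gait event detection and stride extraction.
##
## Raw pelvis/tibia acceleration drives the segmentation; joint angles are
## low-pass filtered at 6 Hz (zero-phase 4th-order Butterworth, the standard
## for gait kinematics) and the single middle stride per leg is time
## normalised to 101 points (0..100% of the gait cycle).

## ---- Butterworth low-pass design -------------------------------------------

## polynomial coefficients (highest order first) from roots, complex-safe
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Design a digital Butterworth low-pass filter
#'
#' Analog Butterworth prototype mapped with the bilinear transform with
#' frequency pre-warping; DC gain normalised to 1.
#'
#' @param cutoff Cut-off frequency in Hz.
#' @param sample_rate Sampling rate in Hz; must exceed `2 * cutoff`.
#' @param order Filter order (default 4).
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_lowpass <- function(cutoff, sample_rate, order = 4L) {
  if (!is_scalar_number(cutoff) || cutoff <= 0)
    stopf("`cutoff` must be a positive number")
  if (sample_rate <= 2 * cutoff)
    stopf("sample_rate (%g Hz) must exceed twice the cutoff (%g Hz)",
          sample_rate, cutoff)
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order)
  p_analog <- complex(real = -sin(theta), imaginary = cos(theta))
  warped <- 2 * sample_rate * tan(pi * cutoff / sample_rate)
  p <- p_analog * warped
  pz <- (2 * sample_rate + p) / (2 * sample_rate - p)
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)
  list(b = b, a = a)
}

## single-pass IIR filter via stats::filter: MA part then recursive AR part.
## The first sample is subtracted before filtering and added back after (the
## DC gain is 1), which suppresses the zero-initial-state step transient.
iir_filter <- function(x, b, a) {
  x0 <- x[1L]
  z <- stats::filter(c(rep(0, length(b) - 1L), x - x0), b,
                     method = "convolution", sides = 1L)
  z <- as.numeric(z[-seq_len(length(b) - 1L)])
  as.numeric(stats::filter(z, -a[-1L], method = "recursive")) + x0
}

#' Zero-phase low-pass filter for kinematic series
#'
#' Applies a Butterworth low-pass forward and backward (filtfilt) so peaks are
#' not shifted in time. Edges are handled by odd reflection padding.
#'
#' @param series Numeric vector.
#' @param sample_rate Sampling rate in Hz.
#' @param cutoff Cut-off frequency in Hz (default 6, the conventional value
#'   for joint kinematics).
#' @param order Butterworth order of each pass (default 4).
#' @return Filtered series, same length as the input.
#' @export
lowpass_filter <- function(series, sample_rate, cutoff = 6, order = 4L) {
  coefs <- butter_lowpass(cutoff, sample_rate, order)
  pad <- 3L * (length(coefs$a) - 1L) * 2L
  n <- length(series)
  if (n <= pad)
    stopf("series too short for the filter: length %d <= warm-up %d", n, pad)
  front <- 2 * series[1L] - series[(pad + 1L):2L]
  back <- 2 * series[n] - series[(n - 1L):(n - pad)]
  y <- c(front, series, back)
  y <- iir_filter(y, coefs$b, coefs$a)
  y <- rev(iir_filter(rev(y), coefs$b, coefs$a))
  y[(pad + 1L):(pad + n)]
}

#' Magnitude response of a designed filter
#'
#' Evaluates |H(e^{i 2 pi f / fs})| for a single-pass filter; the zero-phase
#' (forward-backward) response is this magnitude squared. Used as an
#' independent check of attenuation at given frequencies.
#'
#' @param coefs List with `b`, `a` (from [butter_lowpass()]).
#' @param freq Frequency in Hz at which to evaluate.
#' @param sample_rate Sampling rate in Hz.
#' @param zero_phase If `TRUE`, return the forward-backward magnitude.
#' @return Magnitude (numeric scalar).
#' @export
filter_response <- function(coefs, freq, sample_rate, zero_phase = FALSE) {
  z <- exp(complex(imaginary = -2 * pi * freq / sample_rate))
  num <- sum(coefs$b * z^(seq_along(coefs$b) - 1L))
  den <- sum(coefs$a * z^(seq_along(coefs$a) - 1L))
  h <- Mod(num / den)
  if (zero_phase) h^2 else h
}

## ---- Event detection -------------------------------------------------------

#' Detect walking steps from anterior-posterior acceleration
#'
#' Steps are the dominant peaks of the anterior-posterior pelvis acceleration:
#' local maxima above an adaptive threshold (signal mean + `prominence_factor`
#' standard deviations) separated by at least `min_step_interval` seconds.
#' When two candidates are closer than the minimum interval the larger one is
#' kept.
#'
#' @param accel_ap Anterior-posterior acceleration series (m/s^2).
#' @param sample_rate Sampling rate in Hz.
#' @param min_step_interval Minimum time between steps in seconds
#'   (default 0.4).
#' @param prominence_factor Multiplier on the signal standard deviation for
#'   the adaptive height threshold (default 0.5).
#' @return Integer vector of step sample indices (possibly empty).
#' @export
detect_walking_steps <- function(accel_ap, sample_rate,
                                 min_step_interval = 0.4,
                                 prominence_factor = 0.5) {
  if (length(accel_ap) == 0L) stopf("`accel_ap` must be non-empty")
  cand <- local_maxima(accel_ap)
  if (length(cand) == 0L) return(integer(0))
  thr <- mean(accel_ap) + prominence_factor * stats::sd(accel_ap)
  cand <- cand[accel_ap[cand] > thr]
  if (length(cand) == 0L) return(integer(0))
  h <- accel_ap
  keep <- integer(0)
  min_gap <- min_step_interval * sample_rate
  for (i in cand[order(h[cand], decreasing = TRUE)]) {
    if (all(abs(i - keep) >= min_gap)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Assign left/right side to detected steps
#'
#' The sign of the mean medio-lateral acceleration in a window centred on each
#' step decides the side: positive means right, negative means left. An exact
#' zero mean is a tie and falls back to `default_side` (recorded in the
#' `"ties"` attribute). Windows extending beyond the series are truncated.
#'
#' @param step_indices Integer step indices (within the series).
#' @param accel_ml Medio-lateral acceleration series.
#' @param sample_rate Sampling rate in Hz.
#' @param window Window width in seconds (default 0.25).
#' @param default_side Side used on a tie (default `"left"`).
#' @return Character vector of `"left"`/`"right"`, one per step, with an
#'   integer attribute `"ties"` listing tie-broken positions.
#' @export
assign_step_sides <- function(step_indices, accel_ml, sample_rate,
                              window = 0.25, default_side = "left") {
  n <- length(accel_ml)
  if (any(step_indices < 1L | step_indices > n))
    stopf("step indices outside the medio-lateral series")
  half <- max(1L, round(window * sample_rate / 2))
  ties <- integer(0)
  sides <- vapply(step_indices, function(i) {
    seg <- accel_ml[max(1L, i - half):min(n, i + half)]
    m <- mean(seg)
    if (m > 0) "right" else if (m < 0) "left" else {
      ties <<- c(ties, i)
      default_side
    }
  }, "")
  attr(sides, "ties") <- ties
  sides
}

#' Detect stair strides from tibia axial acceleration
#'
#' Stride boundaries on stairs are the prominent local maxima of the tibia
#' acceleration (x-direction, the shank's longitudinal axis) that follow a
#' prominent local minimum. Prominence is adaptive: maxima must exceed
#' mean + `prominence_factor` * sd, minima must fall below
#' mean - `prominence_factor` * sd; qualifying maxima closer than
#' `min_stride_interval` keep only the larger. Consecutive boundaries define
#' strides; fewer than two boundaries yield no strides.
#'
#' @param tibia_accel_x Tibia acceleration series for one leg (m/s^2).
#' @param sample_rate Sampling rate in Hz.
#' @param min_stride_interval Minimum stride duration in seconds
#'   (default 0.6).
#' @param prominence_factor Threshold multiplier (default 0.5).
#' @return Two-column integer matrix (`start`, `end`), zero rows if no stride.
#' @export
detect_stair_strides <- function(tibia_accel_x, sample_rate,
                                 min_stride_interval = 0.6,
                                 prominence_factor = 0.5) {
  if (length(tibia_accel_x) == 0L) stopf("`tibia_accel_x` must be non-empty")
  empty <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  x <- tibia_accel_x
  maxs <- local_maxima(x)
  mins <- local_minima(x)
  if (length(maxs) == 0L || length(mins) == 0L) return(empty)
  mu <- mean(x); s <- stats::sd(x)
  maxs <- maxs[x[maxs] > mu + prominence_factor * s]
  mins <- mins[x[mins] < mu - prominence_factor * s]
  if (length(maxs) == 0L || length(mins) == 0L) return(empty)
  ## enforce separation among qualifying maxima (keep larger)
  keep <- integer(0)
  min_gap <- min_stride_interval * sample_rate
  for (i in maxs[order(x[maxs], decreasing = TRUE)]) {
    if (all(abs(i - keep) >= min_gap)) keep <- c(keep, i)
  }
  maxs <- sort(keep)
  ## a boundary is a qualifying max preceded by a qualifying min that lies
  ## after the previous boundary
  bounds <- integer(0)
  prev <- 0L
  for (m in maxs) {
    if (any(mins > prev & mins < m)) {
      bounds <- c(bounds, m)
      prev <- m
    }
  }
  if (length(bounds) < 2L) return(empty)
  cbind(start = bounds[-length(bounds)], end = bounds[-1L])
}

## ---- Stride extraction -----------------------------------------------------

#' Collect gait events for a trial
#'
#' Runs the activity-appropriate event detector on a [kinematic
#' trial][generate_trial]: walking uses anterior-posterior step peaks plus
#' medio-lateral side assignment; stairs use per-leg tibia acceleration.
#'
#' @param trial A `kinematic_trial`.
#' @param min_step_interval,min_stride_interval,prominence_factor Passed to
#'   the detectors.
#' @return A `gait_events` list: `step_indices`, `step_sides`, and
#'   `stride_bounds` (a named list with `left`/`right` start-end matrices).
#' @export
detect_events <- function(trial, min_step_interval = 0.4,
                          min_stride_interval = 0.6,
                          prominence_factor = 0.5) {
  fs <- trial$sample_rate
  if (trial$activity == "walk") {
    steps <- detect_walking_steps(trial$accel_ap, fs, min_step_interval,
                                  prominence_factor)
    sides <- assign_step_sides(steps, trial$accel_ml, fs)
    bounds <- lapply(c(left = "left", right = "right"), function(sd) {
      si <- steps[sides == sd]
      if (length(si) < 2L)
        return(matrix(integer(0), ncol = 2L,
                      dimnames = list(NULL, c("start", "end"))))
      cbind(start = si[-length(si)], end = si[-1L])
    })
  } else {
    steps <- integer(0)
    sides <- character(0)
    bounds <- lapply(trial$tibia_accel_x, detect_stair_strides, sample_rate = fs,
                     min_stride_interval = min_stride_interval,
                     prominence_factor = prominence_factor)
  }
  structure(list(step_indices = steps, step_sides = sides,
                 stride_bounds = bounds),
            class = "gait_events")
}

#' Resample a stride to a fixed number of points
#'
#' Linear interpolation on normalised time; 101 points correspond to
#' 0..100% of the gait cycle in 1% increments. Resampling a series that is
#' already `n_points` long is the identity.
#'
#' @param series Numeric vector (one stride of one channel).
#' @param n_points Output length (default 101).
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(series, n_points = 101L) {
  n <- length(series)
  if (n < 2L) stopf("cannot time-normalise a series of length %d", n)
  stats::approx(x = seq(0, 1, length.out = n), y = series,
                xout = seq(0, 1, length.out = n_points))$y
}

#' Extract the time-normalised middle stride of one leg
#'
#' Requires at least 3 strides for the requested side; selects the stride with
#' 0-based index `floor(n/2)` (for an even count, the later of the two central
#' strides), low-pass filters all nine angle channels over the whole trial,
#' slices the stride and resamples each channel to `n_points`.
#'
#' @param trial A `kinematic_trial`.
#' @param events `gait_events` from [detect_events()].
#' @param side `"left"` or `"right"`.
#' @param cutoff Low-pass cut-off in Hz (default 6).
#' @param n_points Samples per normalised stride (default 101).
#' @return A `stride_window`: subject/activity/timepoint/side metadata plus an
#'   `n_points` x 9 matrix `angles`.
#' @export
extract_middle_stride <- function(trial, events, side, cutoff = 6,
                                  n_points = 101L) {
  side <- match.arg(side, c("left", "right"))
  bounds <- events$stride_bounds[[side]]
  n_strides <- nrow(bounds)
  if (is.null(n_strides) || n_strides < 3L) {
    stop(structure(class = c("insufficient_strides", "error", "condition"),
                   list(message = sprintf(
                     "insufficient strides (%d < 3) for subject %s, %s, %s, %s side",
                     n_strides %||% 0L, trial$subject_id, trial$activity,
                     trial$timepoint, side),
                     call = NULL)))
  }
  mid <- as.integer(n_strides %/% 2L) + 1L   # 0-based floor(n/2) -> 1-based
  from <- bounds[mid, "start"]
  to <- bounds[mid, "end"]
  ang <- vapply(angle_channels(), function(ch) {
    filt <- lowpass_filter(trial$angles[[side]][, ch], trial$sample_rate,
                           cutoff)
    time_normalize(filt[from:to], n_points)
  }, numeric(n_points))
  structure(list(subject_id = trial$subject_id, activity = trial$activity,
                 timepoint = trial$timepoint, side = side,
                 stride_index = mid - 1L, angles = ang),
            class = "stride_window")
}

#' Segment a trial into per-leg middle strides
#'
#' Convenience wrapper: detects events and extracts the middle stride for the
#' requested sides. Sides with fewer than 3 detected strides are skipped with
#' a warning rather than aborting the trial.
#'
#' @param trial A `kinematic_trial`.
#' @param sides Character vector of sides to extract (default both).
#' @param cutoff,n_points,min_step_interval,min_stride_interval Tuning
#'   parameters, see the underlying functions.
#' @return List of `stride_window` objects (possibly shorter than `sides`).
#' @export
segment_trial <- function(trial, sides = c("left", "right"), cutoff = 6,
                          n_points = 101L, min_step_interval = 0.4,
                          min_stride_interval = 0.6) {
  events <- detect_events(trial, min_step_interval, min_stride_interval)
  out <- list()
  for (sd in sides) {
    sw <- tryCatch(
      extract_middle_stride(trial, events, sd, cutoff, n_points),
      insufficient_strides = function(e) {
        warnf("skipping: %s", conditionMessage(e))
        NULL
      })
    if (!is.null(sw)) out[[length(out) + 1L]] <- sw
  }
  out
}

#' Segment every trial of a cohort
#'
#' @param cohort A `cohort_dataset` from [generate_cohort()].
#' @param ... Passed to [segment_trial()].
#' @return Flat list of `stride_window` objects.
#' @export
segment_cohort <- function(cohort, ...) {
  out <- list()
  for (trial in cohort$trials) out <- c(out, segment_trial(trial, ...))
  out
}
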