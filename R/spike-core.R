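#' Detection parameters for the spike-shape algorithm
#'
#' Collects the tunable parameters of the pulse detector. The signal and
#' gradient thresholds are expressed as multiples of a robust noise scale
#' estimated per trace by the scaled median absolute deviation
#' (1.4826 x MAD) of, respectively, the detrended series and its gradient.
#'
#' @param n_baseline Number of initial frames averaged to form the
#'   fluorescence baseline F0 (default 20).
#' @param poly_order Order of the detrending polynomial (default 3; a cubic
#'   absorbs slow drift over a ~1.5 h recording without eating ~40 s
#'   transients). Allowed range 0--5.
#' @param detrend_target Which series the polynomial is fitted to and
#'   subtracted from: `"dff"` (default; thresholds then live on the
#'   scale-free dF/F axis) or `"raw"` fluorescence.
#' @param theta_s_mult Signal threshold, as a multiple of the robust noise
#'   scale of the detrended series (default 0.5; calibrated on simulated
#'   tent transients to minimise boundary bias, see the package vignette).
#' @param theta_g_mult Gradient threshold, as a multiple of the robust noise
#'   scale of the gradient series (default 2).
#' @param amp_mult Minimum peak amplitude for a candidate spike, as a
#'   multiple of the robust noise scale of the screened series (default 5).
#' @param amp_smooth_frames Odd window length (frames) of the centred
#'   running mean on which candidate peaks are screened (default 5; 1
#'   disables smoothing). Averaging a few frames under the pulse leaves
#'   most of a 30--50 s transient's amplitude intact while shrinking the
#'   noise scale, so a single amplitude multiplier can separate true peaks
#'   from single-frame noise excursions. Boundary scans and the reported
#'   peak always use the unsmoothed detrended signal.
#' @param bound_smooth_frames Odd window length (frames) of the centred
#'   running mean applied to the detrended signal (and its gradient)
#'   before the boundary scans (default 3; 1 disables). A three-frame
#'   mean roughly halves the frame-to-frame noise that jitters the
#'   threshold crossings while widening a pulse's support by at most one
#'   frame on either side.
#' @param min_duration_s Minimum accepted pulse duration in seconds;
#'   `NULL` (default) resolves to twice the frame interval.
#' @param onset_tolerance_s Temporal tolerance used when comparing onset
#'   times across channels; `NULL` (default) resolves to one frame interval.
#' @param boundary_refine Sub-frame refinement of the scanned boundary.
#'   `"interpolate"` (default) reports the linearly interpolated time at
#'   which the scanned signal crosses the signal threshold, removing the
#'   up-to-one-frame quantisation bias of the raw index scan.
#'   `"extrapolate"` instead fits a line to the 20--60% band of the limb
#'   and reports its baseline (zero) intercept (exact for noiseless
#'   piecewise-linear pulses, but noisier on real data). `"index"`
#'   reports the stopping frame's time itself.
#' @param redetrend If `TRUE` (default), detection runs in two passes:
#'   pulse intervals found in the first pass are excluded from a second
#'   polynomial fit, and calls are re-estimated on the leakage-free
#'   detrended signal. A single global fit absorbs part of each pulse
#'   into the trend, slightly denting the baseline around it and biasing
#'   the boundary estimates inwards.
#' @param refine_shape If `TRUE` (default), each accepted pulse's onset,
#'   peak and offset are re-estimated by least-squares fitting a
#'   piecewise-linear (tent) pulse template to the unsmoothed detrended
#'   signal over the pulse window, initialised at the threshold-scan
#'   boundaries. Index-based boundary estimates carry noise- and
#'   threshold-dependent biases of up to a frame or two; the template fit
#'   pools all frames on both limbs and is unbiased for piecewise-linear
#'   transients. Set to `FALSE` to report the raw scan boundaries.
#' @param min_amplitude_dff Absolute floor on the detrended peak amplitude
#'   (default 1e-6). This is a numerical guard far below any physiological
#'   dF/F: it rejects rounding-level maxima on effectively constant traces,
#'   where the MAD-based scale collapses towards zero.
#'
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(n_baseline = 20L,
                             poly_order = 3L,
                             detrend_target = c("dff", "raw"),
                             theta_s_mult = 0.5,
                             theta_g_mult = 2,
                             amp_mult = 5,
                             amp_smooth_frames = 5L,
                             bound_smooth_frames = 3L,
                             min_duration_s = NULL,
                             onset_tolerance_s = NULL,
                             boundary_refine = c("interpolate", "extrapolate",
                                                 "index"),
                             redetrend = TRUE,
                             refine_shape = TRUE,
                             min_amplitude_dff = 1e-6) {
  detrend_target <- match.arg(detrend_target)
  boundary_refine <- match.arg(boundary_refine)
  stopifnot(n_baseline >= 1, poly_order >= 0, poly_order <= 5,
            theta_s_mult > 0, theta_g_mult > 0, amp_mult > 0,
            amp_smooth_frames >= 1, amp_smooth_frames %% 2 == 1,
            bound_smooth_frames >= 1, bound_smooth_frames %% 2 == 1,
            min_amplitude_dff >= 0)
  if (!is.null(min_duration_s)) stopifnot(min_duration_s >= 0)
  if (!is.null(onset_tolerance_s)) stopifnot(onset_tolerance_s >= 0)
  structure(list(n_baseline = as.integer(n_baseline),
                 poly_order = as.integer(poly_order),
                 detrend_target = detrend_target,
                 theta_s_mult = theta_s_mult,
                 theta_g_mult = theta_g_mult,
                 amp_mult = amp_mult,
                 amp_smooth_frames = as.integer(amp_smooth_frames),
                 bound_smooth_frames = as.integer(bound_smooth_frames),
                 min_duration_s = min_duration_s,
                 onset_tolerance_s = onset_tolerance_s,
                 boundary_refine = boundary_refine,
                 redetrend = isTRUE(redetrend),
                 refine_shape = isTRUE(refine_shape),
                 min_amplitude_dff = min_amplitude_dff),
            class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat("<detection_params>\n")
  cat(sprintf("  baseline frames: %d, detrend: order-%d polynomial on %s\n",
              x$n_baseline, x$poly_order, x$detrend_target))
  cat(sprintf("  thresholds: signal %g sigma, |gradient| %g sigma_g, peak >= %g sigma\n",
              x$theta_s_mult, x$theta_g_mult, x$amp_mult))
  invisible(x)
}

#' Baseline-normalise a fluorescence trace (dF/F)
#'
#' Computes dF/F = (F - F0)/F0 where F0 is the mean of the first
#' `n_baseline` raw intensities. The result is dimensionless and invariant
#' under multiplicative rescaling of the raw intensities, and the mean of
#' its first `n_baseline` values is exactly zero.
#'
#' @param trace A [fluorescence_trace].
#' @param n_baseline Number of baseline frames averaged into F0.
#' @return An object of class `normalized_trace` with fields `values`,
#'   `f0`, `n_baseline`, `times`, plus the parent trace key.
#' @export
normalize_dff <- function(trace, n_baseline = 20L) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  n <- length(trace$times)
  if (n <= n_baseline) {
    stop(sprintf("trace has %d frame(s); need more than n_baseline = %d",
                 n, n_baseline), call. = FALSE)
  }
  f0 <- mean(trace$intensities[seq_len(n_baseline)])
  if (!is.finite(f0) || f0 <= .Machine$double.eps * max(trace$intensities)) {
    stop("baseline F0 is non-positive or below the numerical noise floor",
         call. = FALSE)
  }
  structure(list(values = (trace$intensities - f0) / f0,
                 f0 = f0,
                 n_baseline = as.integer(n_baseline),
                 times = trace$times,
                 plant_id = trace$plant_id,
                 cell_id = trace$cell_id,
                 channel = trace$channel),
            class = "normalized_trace")
}

# Evaluate a polynomial with ascending-degree coefficients (Horner).
polyval_asc <- function(coeffs, x) {
  y <- rep(0, length(x))
  for (c_k in rev(coeffs)) y <- y * x + c_k
  y
}

# Expand coefficients fitted on u = (t - t0)/scale into ascending-degree
# coefficients on t, via repeated polynomial multiplication.
rebase_poly <- function(coeffs_u, t0, scale) {
  k <- length(coeffs_u) - 1L
  out <- numeric(k + 1L)
  base <- c(-t0 / scale, 1 / scale)  # u as a polynomial in t
  pw <- 1                            # base^j, ascending coefficients
  for (j in 0:k) {
    out[seq_along(pw)] <- out[seq_along(pw)] + coeffs_u[j + 1L] * pw
    if (j < k) {
      # multiply pw by base
      new <- numeric(length(pw) + 1L)
      new[seq_along(pw)] <- new[seq_along(pw)] + pw * base[1]
      new[seq_along(pw) + 1L] <- new[seq_along(pw) + 1L] + pw * base[2]
      pw <- new
    }
  }
  out
}

#' Remove slow baseline drift by polynomial subtraction
#'
#' Fits an ordinary least-squares polynomial of the given order to the
#' series as a function of time over the full recording, and subtracts it.
#' The fit is performed on a unit-rescaled time axis for numerical
#' stability; coefficients are returned in ascending degree on the original
#' seconds axis.
#'
#' @param values Numeric series to detrend (dF/F or raw fluorescence), or a
#'   `normalized_trace` (its `values`/`times` are then used).
#' @param times Acquisition times in seconds (ignored when `values` is a
#'   `normalized_trace`).
#' @param poly_order Non-negative polynomial order; must be strictly less
#'   than the series length.
#' @param source Label recording which series was detrended
#'   (`"dff"` or `"raw"`).
#' @param exclude Optional integer indices of frames excluded from the
#'   polynomial fit (the trend is still evaluated and subtracted there).
#'   Used to keep detected pulses from leaking into the baseline estimate.
#' @return An object of class `detrended_trace` with fields `values`
#'   (detrended series), `fitted` (evaluated trend), `poly_order`,
#'   `poly_coeffs` (ascending degree, seconds axis), `times`, `source`.
#' @export
detrend <- function(values, times = NULL, poly_order = 3L,
                    source = c("dff", "raw"), exclude = NULL) {
  source <- match.arg(source)
  if (inherits(values, "normalized_trace")) {
    times <- values$times
    values <- values$values
    source <- "dff"
  }
  stopifnot(is.numeric(values), is.numeric(times),
            length(values) == length(times))
  poly_order <- as.integer(poly_order)
  n <- length(values)
  if (poly_order < 0) stop("poly_order must be non-negative", call. = FALSE)
  keep <- setdiff(seq_len(n), exclude)
  if (length(keep) < poly_order + 1L) {
    stop(sprintf("need at least %d points to fit an order-%d polynomial",
                 poly_order + 1L, poly_order), call. = FALSE)
  }
  t0 <- times[1]
  scale <- max(times[n] - times[1], 1)
  u <- (times - t0) / scale
  V <- outer(u, 0:poly_order, `^`)
  fit <- stats::lm.fit(V[keep, , drop = FALSE], values[keep])
  coeffs_u <- fit$coefficients
  coeffs_u[is.na(coeffs_u)] <- 0
  fitted <- drop(V %*% coeffs_u)
  structure(list(values = values - fitted,
                 fitted = fitted,
                 poly_order = poly_order,
                 poly_coeffs = rebase_poly(coeffs_u, t0, scale),
                 times = times,
                 source = source),
            class = "detrended_trace")
}

#' Differentiate a detrended series
#'
#' Central differences on interior points and one-sided differences at both
#' edges, divided by the frame interval so the result has per-second units.
#'
#' @param det A `detrended_trace` or numeric vector.
#' @param frame_interval Frame interval in seconds.
#' @param scheme `"central"` (default) or `"forward"` (forward differences,
#'   backward at the final point).
#' @return Numeric vector of the same length as the input series.
#' @export
compute_gradient <- function(det, frame_interval, scheme = c("central", "forward")) {
  scheme <- match.arg(scheme)
  x <- if (inherits(det, "detrended_trace")) det$values else det
  stopifnot(is.numeric(x), frame_interval > 0)
  n <- length(x)
  if (n < 2L) stop("need at least two points to differentiate", call. = FALSE)
  g <- numeric(n)
  if (scheme == "central") {
    if (n > 2L) {
      i <- 2:(n - 1L)
      g[i] <- (x[i + 1L] - x[i - 1L]) / (2 * frame_interval)
    }
    g[1] <- (x[2] - x[1]) / frame_interval
    g[n] <- (x[n] - x[n - 1L]) / frame_interval
  } else {
    g[-n] <- diff(x) / frame_interval
    g[n] <- (x[n] - x[n - 1L]) / frame_interval
  }
  g
}

#' Locate the peak of a detrended series
#'
#' @param det A `detrended_trace` or numeric vector.
#' @param window Optional integer index range restricting the search.
#' @return The index of the maximum value; ties break to the earliest index.
#' @export
locate_peak <- function(det, window = NULL) {
  x <- if (inherits(det, "detrended_trace")) det$values else det
  idx <- if (is.null(window)) seq_along(x) else as.integer(window)
  if (length(idx) == 0L) stop("empty search window", call. = FALSE)
  if (any(idx < 1L) || any(idx > length(x))) {
    stop("window out of bounds", call. = FALSE)
  }
  idx[which.max(x[idx])]
}

# Robust noise scale: 1.4826 * median absolute deviation.
robust_sigma <- function(x) stats::mad(x)

#' Locate pulse boundaries around a peak
#'
#' Scans backward (onset) and forward (offset) from the frames adjacent to
#' the peak for the first index at which the detrended signal falls below
#' the signal threshold AND the absolute gradient falls below the gradient
#' threshold. The absolute gradient is used so that the two scans are
#' symmetric (the signed post-peak gradient is negative and would satisfy a
#' signed criterion immediately). A scan that reaches the trace edge
#' without meeting the condition returns the edge index with its censoring
#' flag raised.
#'
#' @param det Detrended series (`detrended_trace` or numeric vector).
#' @param grad Gradient series, same length.
#' @param peak Peak index.
#' @param theta_s Signal threshold (same units as `det`).
#' @param theta_g Gradient threshold (units of `det` per second).
#' @return A list with `on_idx`, `off_idx`, `censored_onset`,
#'   `censored_offset`.
#' @export
locate_pulse_bounds <- function(det, grad, peak, theta_s, theta_g) {
  x <- if (inherits(det, "detrended_trace")) det$values else det
  stopifnot(length(grad) == length(x), peak >= 1L, peak <= length(x))
  n <- length(x)
  below <- function(i) x[i] < theta_s && abs(grad[i]) < theta_g

  on_idx <- 1L
  censored_onset <- TRUE
  if (peak > 1L) {
    for (i in (peak - 1L):1L) {
      if (below(i)) {
        on_idx <- i
        censored_onset <- FALSE
        break
      }
    }
  }
  off_idx <- n
  censored_offset <- TRUE
  if (peak < n) {
    for (i in (peak + 1L):n) {
      if (below(i)) {
        off_idx <- i
        censored_offset <- FALSE
        break
      }
    }
  }
  list(on_idx = on_idx, off_idx = off_idx,
       censored_onset = censored_onset, censored_offset = censored_offset)
}

#' Measure a single spike from its boundary times
#'
#' @param t_on,t_peak,t_off Onset, peak and offset times in seconds
#'   (must satisfy `t_on <= t_peak <= t_off`).
#' @param amplitude_dff Detrended value at the peak.
#' @param censored Whether a boundary was truncated by the trace edge.
#' @param plant_id,cell_id,channel Trace key carried into the record.
#' @return A one-row `spike_call_table` with rise, fall and duration; by
#'   construction `duration_s = rise_s + fall_s` exactly.
#' @export
measure_spike <- function(t_on, t_peak, t_off, amplitude_dff = NA_real_,
                          censored = FALSE, plant_id = NA_character_,
                          cell_id = NA_character_, channel = NA_character_) {
  if (!(t_on <= t_peak && t_peak <= t_off)) {
    stop("boundary ordering violated: need t_on <= t_peak <= t_off",
         call. = FALSE)
  }
  rise <- t_peak - t_on
  fall <- t_off - t_peak
  as_spike_call_table(data.frame(
    plant_id = plant_id, cell_id = cell_id, channel = channel,
    t_on_s = t_on, t_peak_s = t_peak, t_off_s = t_off,
    rise_s = rise, fall_s = fall, duration_s = rise + fall,
    amplitude_dff = amplitude_dff, censored = censored,
    stringsAsFactors = FALSE))
}

# Sub-frame threshold crossing near a scan's stopping frame `i`. Walks
# inward (towards `peak`) to the nearest frame at or above theta, then
# interpolates across the adjacent bracketing pair; falls back to the
# stopping frame's time when no bracket exists.
interp_crossing <- function(times, x, i, peak, theta) {
  step <- sign(peak - i)
  if (step == 0) return(times[i])
  j <- i + step
  while (j != peak && x[j] < theta) j <- j + step
  if (x[j] < theta) return(times[i])
  k <- j - step  # outward neighbour of the first frame at/above theta
  if (x[k] >= theta || x[j] == x[k]) return(times[i])
  times[k] + (theta - x[k]) / (x[j] - x[k]) * (times[j] - times[k])
}

# Baseline-intercept extrapolation of a limb. Fits an OLS line to the
# frames lying between 20% and 60% of the peak height (moving from the
# stopping frame towards the peak; a band clear of the pulse foot and of
# the peak, where a transient's limb is closest to linear) and returns
# the time where the line reaches zero. Falls back to the interpolated
# crossing when the segment is too short or the slope has the wrong sign.
extrap_baseline <- function(times, x, i, peak, theta, peak_height) {
  step <- sign(peak - i)
  if (step == 0) return(times[i])
  seg <- integer(0)
  j <- i
  while (j != peak) {
    j <- j + step
    if (x[j] >= 0.6 * peak_height) break
    if (x[j] >= 0.2 * peak_height) seg <- c(seg, j)
  }
  if (length(seg) < 2L) return(interp_crossing(times, x, i, peak, theta))
  fit <- stats::lm.fit(cbind(1, times[seg]), x[seg])
  a <- fit$coefficients[1]
  b <- fit$coefficients[2]
  if (!is.finite(b) || b * step <= 0) {
    return(interp_crossing(times, x, i, peak, theta))
  }
  t0 <- -a / b
  # sanity clamp: the foot lies outward of the fitted band, but no
  # further than the limb's own extrapolated duration
  t_in <- if (step > 0) max(times[seg]) else min(times[seg])
  t_out <- if (step > 0) min(times[seg]) else max(times[seg])
  limit <- t_out - step * 0.75 * abs(peak_height / b)
  lo <- min(t_in, limit)
  hi <- max(t_in, limit)
  min(max(t0, lo), hi)
}

# Least-squares fit of a piecewise-linear (tent) pulse to a window of
# the detrended signal. Parameters are onset, rise and fall durations
# and amplitude; returns refined boundary times, or NULL when the fit
# fails or leaves the window.
fit_tent_pulse <- function(times, values, t_on, t_peak, t_off) {
  sse <- function(p) {
    model <- tent_kernel(times, p[1], p[2], p[3], p[4])
    sum((values - model)^2)
  }
  dt <- stats::median(diff(times))
  amp0 <- max(values[which.min(abs(times - t_peak))], 1e-3)
  # coarse grid over breakpoint triples with the amplitude profiled out
  # in closed form: the kinked SSE surface has local basins, and a local
  # optimiser started from the scan boundaries inherits their bias
  best_init <- c(t_on, max(t_peak - t_on, dt), max(t_off - t_peak, dt),
                 amp0)
  best_val <- sse(best_init)
  shifts <- dt * (-3:3)
  for (d_on in shifts) for (d_pk in shifts) for (d_off in shifts) {
    on_c <- t_on + d_on
    pk_c <- t_peak + d_pk
    off_c <- t_off + d_off
    if (pk_c - on_c < dt / 2 || off_c - pk_c < dt / 2) next
    k <- tent_kernel(times, on_c, pk_c - on_c, off_c - pk_c, 1)
    kk <- sum(k * k)
    if (kk == 0) next
    a <- max(sum(k * values) / kk, 0)
    val <- sum((values - a * k)^2)
    if (val < best_val) {
      best_val <- val
      best_init <- c(on_c, pk_c - on_c, off_c - pk_c, a)
    }
  }
  # polish: the surface is piecewise smooth, so a derivative-free step
  # finishes the job from the best grid point
  fit <- tryCatch(
    stats::optim(best_init, function(p) {
      if (p[2] < dt / 2 || p[3] < dt / 2 || p[4] < 0) return(Inf)
      sse(p)
    }, method = "Nelder-Mead",
    control = list(maxit = 500, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- if (fit$value <= best_val) fit$par else best_init
  out <- list(t_on = p[1], t_peak = p[1] + p[2],
              t_off = p[1] + p[2] + p[3], amplitude = p[4])
  if (out$t_off > times[length(times)] + dt || out$t_on < times[1] - dt) {
    return(NULL)
  }
  out
}

# Centred running mean of odd width w; the window is truncated at the
# edges (mean over the frames actually covered).
running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# TRUE at indices that are local maxima of x (>= both neighbours; trace
# edges count as -Inf neighbours).
is_local_max <- function(x) {
  n <- length(x)
  if (n == 1L) return(TRUE)
  left <- c(-Inf, x[-n])
  right <- c(x[-1L], -Inf)
  x >= left & x >= right
}

#' Detect calcium spikes in a fluorescence trace
#'
#' The full spike-shape pipeline: baseline normalisation (dF/F), polynomial
#' detrending, gradient computation, then iterative pulse extraction. At
#' each iteration the highest remaining local maximum of the detrended
#' signal with amplitude at least `amp_mult` noise scales is taken as a
#' candidate peak, its boundaries are located by the dual
#' signal-plus-gradient threshold scan, and a call is emitted if the pulse
#' lasts at least `min_duration_s` and is not censored at both ends. The
#' pulse interval is then masked and the search repeats until no candidate
#' remains. Calls are returned sorted by onset time.
#'
#' @param trace A [fluorescence_trace] or [trace_collection].
#' @param params A [detection_params] object.
#' @param ... Unused; for method extension.
#' @return For a single trace, an object of class `spike_fit` (see Details);
#'   for a collection, a `spike_fit_set` whose `$calls` stacks the calls of
#'   all member traces.
#'
#' @details A `spike_fit` behaves like a classic fitted-model object:
#'   [coef()] returns the detrending polynomial coefficients, [fitted()]
#'   the evaluated trend, [residuals()] the detrended signal the detector
#'   scans, and [plot()] draws the trace with detected pulses. The call
#'   table is available as `fit$calls` or via [spike_calls()].
#' @export
detect_spikes <- function(trace, params = detection_params(), ...) {
  UseMethod("detect_spikes")
}

#' @export
detect_spikes.fluorescence_trace <- function(trace, params = detection_params(),
                                             ...) {
  stopifnot(inherits(params, "detection_params"))
  nt <- normalize_dff(trace, params$n_baseline)
  target <- switch(params$detrend_target,
                   dff = nt$values,
                   raw = trace$intensities)
  min_dur <- if (is.null(params$min_duration_s)) {
    2 * trace$frame_interval
  } else {
    params$min_duration_s
  }

  # one detection pass over a detrended series; sub-frame refinements are
  # only needed on the final pass
  run_pass <- function(det, final) {
    scan_values <- running_mean(det$values, params$bound_smooth_frames)
    grad <- compute_gradient(scan_values, trace$frame_interval)
    sigma <- robust_sigma(scan_values)
    sigma_g <- robust_sigma(grad)
    # floor for effectively noiseless series, where the MAD collapses to
    # exactly zero and a strict `<` comparison would reject everything
    eps <- 1e-9 * max(abs(scan_values), 1e-3)
    theta_s <- max(params$theta_s_mult * sigma, eps)
    theta_g <- max(params$theta_g_mult * sigma_g, eps)
    w <- params$amp_smooth_frames
    smoothed <- running_mean(det$values, w)
    amp_floor <- max(params$amp_mult * robust_sigma(smoothed),
                     params$min_amplitude_dff)
    n <- length(det$values)
    half_w <- (w - 1L) %/% 2L
    available <- rep(TRUE, n)
    localmax <- is_local_max(smoothed)
    calls <- list()
    intervals <- list()
    repeat {
      cand <- which(available)
      if (!length(cand)) break
      peak <- cand[which.max(smoothed[cand])]
      if (smoothed[peak] < amp_floor) break
      if (!localmax[peak]) {
        # shoulder of an already-masked pulse; not a genuine candidate
        available[peak] <- FALSE
        next
      }
      cand_idx <- peak
      # refine on the lightly smoothed scan series: single-frame noise in
      # the raw argmax drifts systematically towards the shallower limb
      peak <- locate_peak(scan_values,
                          max(1L, peak - half_w):min(n, peak + half_w))
      b <- locate_pulse_bounds(scan_values, grad, peak, theta_s, theta_g)
      censored <- b$censored_onset || b$censored_offset
      t_on <- trace$times[b$on_idx]
      t_off <- trace$times[b$off_idx]
      if (final && params$boundary_refine != "index") {
        refine <- if (params$boundary_refine == "extrapolate") {
          function(i) extrap_baseline(trace$times, scan_values, i, peak,
                                      theta_s, scan_values[peak])
        } else {
          function(i) interp_crossing(trace$times, scan_values, i, peak,
                                      theta_s)
        }
        if (!b$censored_onset && b$on_idx < peak) t_on <- refine(b$on_idx)
        if (!b$censored_offset && b$off_idx > peak) t_off <- refine(b$off_idx)
      }
      t_peak_t <- trace$times[peak]
      amp_out <- det$values[peak]
      if (final && params$refine_shape && !censored) {
        widx <- max(1L, b$on_idx - 8L):min(n, b$off_idx + 8L)
        ft <- fit_tent_pulse(trace$times[widx], det$values[widx],
                             t_on, t_peak_t, t_off)
        if (!is.null(ft)) {
          t_on <- ft$t_on
          t_peak_t <- ft$t_peak
          t_off <- ft$t_off
          amp_out <- ft$amplitude
        }
      }
      duration <- t_off - t_on
      keep <- duration >= min_dur && !(b$censored_onset && b$censored_offset)
      if (keep) {
        calls[[length(calls) + 1L]] <- measure_spike(
          t_on = t_on,
          t_peak = t_peak_t,
          t_off = t_off,
          amplitude_dff = amp_out,
          censored = censored,
          plant_id = trace$plant_id, cell_id = trace$cell_id,
          channel = trace$channel)
        intervals[[length(intervals) + 1L]] <- c(b$on_idx, b$off_idx)
      }
      available[b$on_idx:b$off_idx] <- FALSE
      available[cand_idx] <- FALSE
    }
    tab <- if (length(calls)) {
      out <- do.call(rbind, calls)
      out <- out[order(out$t_on_s), , drop = FALSE]
      as_spike_call_table(out)
    } else {
      empty_spike_calls()
    }
    list(calls = tab, intervals = intervals, scan_values = scan_values,
         grad = grad, sigma = sigma, sigma_g = sigma_g,
         theta_s = theta_s, theta_g = theta_g, amp_floor = amp_floor)
  }

  det <- detrend(target, trace$times, params$poly_order,
                 source = params$detrend_target)
  if (params$redetrend) {
    first <- run_pass(det, final = FALSE)
    if (length(first$intervals)) {
      n <- length(target)
      excl <- unique(unlist(lapply(first$intervals, function(iv)
        max(1L, iv[1] - 2L):min(n, iv[2] + 2L))))
      if (length(excl) < n - params$poly_order - 1L) {
        det <- detrend(target, trace$times, params$poly_order,
                       source = params$detrend_target, exclude = excl)
      }
    }
  }
  pass <- run_pass(det, final = TRUE)

  structure(list(trace = trace,
                 normalized = nt,
                 detrended = det,
                 scan_values = pass$scan_values,
                 gradient = pass$grad,
                 sigma = pass$sigma,
                 sigma_g = pass$sigma_g,
                 theta_s = pass$theta_s,
                 theta_g = pass$theta_g,
                 amp_floor = pass$amp_floor,
                 min_duration_s = min_dur,
                 params = params,
                 calls = pass$calls),
            class = "spike_fit")
}

#' @export
detect_spikes.trace_collection <- function(trace, params = detection_params(),
                                           ...) {
  fits <- lapply(trace$traces, detect_spikes, params = params)
  calls <- do.call(rbind, c(lapply(fits, `[[`, "calls"),
                            list(make.row.names = FALSE)))
  calls <- if (is.null(calls) || nrow(calls) == 0) {
    empty_spike_calls()
  } else {
    as_spike_call_table(calls)
  }
  structure(list(fits = fits, calls = calls, params = params),
            class = "spike_fit_set")
}

#' Extract the spike-call table from a fit
#'
#' @param object A `spike_fit` or `spike_fit_set`.
#' @return A `spike_call_table` data frame.
#' @export
spike_calls <- function(object) {
  stopifnot(inherits(object, c("spike_fit", "spike_fit_set")))
  object$calls
}

#' @export
print.spike_fit <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("<spike_fit> plant %s, cell %s, %s channel: %d call(s)\n",
              tr$plant_id, tr$cell_id, tr$channel, nrow(x$calls)))
  cat(sprintf("  order-%d detrend on %s; sigma = %.4g, thresholds s < %.4g, |g| < %.4g /s\n",
              x$detrended$poly_order, x$detrended$source, x$sigma,
              x$theta_s, x$theta_g))
  if (nrow(x$calls)) print(as.data.frame(x$calls))
  invisible(x)
}

#' @export
print.spike_fit_set <- function(x, ...) {
  cat(sprintf("<spike_fit_set> %d trace(s), %d call(s)\n",
              length(x$fits), nrow(x$calls)))
  invisible(x)
}

#' @export
summary.spike_fit <- function(object, ...) {
  cl <- object$calls
  acc <- cl[!cl$censored, , drop = FALSE]
  out <- list(n_calls = nrow(cl), n_censored = sum(cl$censored),
              mean_rise_s = if (nrow(acc)) mean(acc$rise_s) else NA_real_,
              mean_fall_s = if (nrow(acc)) mean(acc$fall_s) else NA_real_,
              mean_duration_s = if (nrow(acc)) mean(acc$duration_s) else NA_real_,
              sigma = object$sigma, theta_s = object$theta_s,
              theta_g = object$theta_g)
  class(out) <- "summary.spike_fit"
  out
}

#' @export
print.summary.spike_fit <- function(x, ...) {
  cat(sprintf("spike fit: %d call(s), %d censored\n", x$n_calls, x$n_censored))
  if (!is.na(x$mean_rise_s)) {
    cat(sprintf("  mean rise %.1f s, fall %.1f s, duration %.1f s\n",
                x$mean_rise_s, x$mean_fall_s, x$mean_duration_s))
  }
  invisible(x)
}

#' @export
coef.spike_fit <- function(object, ...) {
  co <- object$detrended$poly_coeffs
  names(co) <- paste0("t^", seq_along(co) - 1L)
  co
}

#' @export
fitted.spike_fit <- function(object, ...) object$detrended$fitted

#' @export
residuals.spike_fit <- function(object, ...) object$detrended$values

#' Plot a spike fit
#'
#' Draws the detrended signal against time with the detection thresholds
#' and shaded intervals for each accepted pulse.
#'
#' @param x A `spike_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spike_fit <- function(x, ...) {
  det <- x$detrended
  graphics::plot(det$times, det$values, type = "l",
                 xlab = "time (s)",
                 ylab = sprintf("detrended %s", det$source), ...)
  graphics::abline(h = c(x$theta_s, x$amp_floor), lty = c(3, 2),
                   col = "grey40")
  if (nrow(x$calls)) {
    usr <- graphics::par("usr")
    for (i in seq_len(nrow(x$calls))) {
      graphics::rect(x$calls$t_on_s[i], usr[3], x$calls$t_off_s[i], usr[4],
                     col = grDevices::adjustcolor("tomato", 0.15),
                     border = NA)
      graphics::points(x$calls$t_peak_s[i], x$calls$amplitude_dff[i],
                       pch = 19, col = "tomato")
    }
  }
  invisible(x)
}
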