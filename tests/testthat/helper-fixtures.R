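# Small in-code fixtures shared across tests.

# A trace with constant baseline and an optional triangular pulse added on
# the raw intensity scale.
make_trace <- function(n = 60, dt = 2, f0 = 100, tent = NULL,
                       plant = "p1", cell = "c1", channel = "nuclear",
                       position_um = NA_real_) {
  times <- seq(0, by = dt, length.out = n)
  f <- rep(f0, n)
  if (!is.null(tent)) {
    f <- f + f0 * tent_values(times, tent$t_on, tent$rise, tent$fall,
                              tent$amp)
  }
  fluorescence_trace(plant, cell, channel, times, f,
                     frame_interval = dt, position_um = position_um)
}

# Triangular pulse evaluated on a time grid (test-local; independent of
# the package's simulator internals).
tent_values <- function(t, t_on, rise, fall, amp) {
  y <- numeric(length(t))
  up <- t >= t_on & t <= t_on + rise
  down <- t > t_on + rise & t <= t_on + rise + fall
  y[up] <- amp * (t[up] - t_on) / rise
  y[down] <- amp * (1 - (t[down] - t_on - rise) / fall)
  y
}

# Long-format CSV for read_traces tests.
write_trace_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Independent index-scan oracle for pulse boundaries (deliberately a
# plain double loop, separate from the package implementation).
oracle_bounds <- function(det, grad, peak, theta_s, theta_g) {
  n <- length(det)
  on_idx <- 1L; cens_on <- TRUE
  i <- peak - 1L
  while (i >= 1L) {
    if (det[i] < theta_s && abs(grad[i]) < theta_g) {
      on_idx <- i; cens_on <- FALSE; break
    }
    i <- i - 1L
  }
  off_idx <- n; cens_off <- TRUE
  i <- peak + 1L
  while (i <= n) {
    if (det[i] < theta_s && abs(grad[i]) < theta_g) {
      off_idx <- i; cens_off <- FALSE; break
    }
    i <- i + 1L
  }
  list(on_idx = on_idx, off_idx = off_idx,
       censored_onset = cens_on, censored_offset = cens_off)
}
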