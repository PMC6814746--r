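test_that("dF/F normalisation matches its definition and invariances", {
  const <- make_trace(n = 30, f0 = 100)
  nt <- normalize_dff(const, 20)
  expect_equal(nt$values, rep(0, 30), tolerance = 1e-12)
  expect_equal(nt$f0, 100)

  tr <- make_trace(n = 30, f0 = 10)
  tr$intensities[26] <- 15
  expect_equal(normalize_dff(tr, 20)$values[26], 0.5, tolerance = 1e-12)

  # scale invariance: multiplying raw intensities leaves dF/F unchanged
  tr7 <- tr
  tr7$intensities <- tr$intensities * 7
  expect_equal(normalize_dff(tr7, 20)$values, normalize_dff(tr, 20)$values,
               tolerance = 1e-12)

  # mean of the baseline window is exactly zero
  noisy <- make_trace(n = 50)
  noisy$intensities <- noisy$intensities + sin(seq_len(50))
  expect_lt(abs(mean(normalize_dff(noisy, 20)$values[1:20])), 1e-9)

  expect_error(normalize_dff(make_trace(n = 15), 20), "n_baseline")
  zero <- make_trace(n = 30, f0 = 100)
  zero$intensities[] <- 0
  expect_error(normalize_dff(zero, 20), "baseline")
})

test_that("polynomial detrending annihilates polynomials and matches an
           independent normal-equations solve", {
  t <- seq(0, 118, by = 2)
  quad <- 3 + 0.01 * t - 1e-4 * t^2
  det <- detrend(quad, t, poly_order = 3)
  expect_lt(max(abs(det$values)), 1e-9 * max(abs(quad)))

  det0 <- detrend(rep(5, 10), seq(0, 18, 2), poly_order = 0)
  expect_equal(det0$values, rep(0, 10), tolerance = 1e-12)

  # polynomial plus an isolated tent pulse, against a solve() oracle on
  # the scaled-time Vandermonde normal equations
  y <- quad + tent_values(t, 40, 10, 16, 0.8)
  u <- (t - t[1]) / diff(range(t))
  V <- outer(u, 0:3, `^`)
  fit_oracle <- drop(V %*% solve(crossprod(V), crossprod(V, y)))
  det_y <- detrend(y, t, poly_order = 3)
  expect_equal(det_y$values, y - fit_oracle, tolerance = 1e-9)

  # stored coefficients reproduce the subtracted trend on the seconds axis
  trend <- vapply(t, function(tt)
    sum(det_y$poly_coeffs * tt^(0:3)), numeric(1))
  expect_equal(y - trend, det_y$values, tolerance = 1e-9)

  expect_error(detrend(c(1, 2), c(0, 2), poly_order = 3), "at least")
})

test_that("gradient uses central differences with one-sided edges", {
  t <- seq(0, 38, 2)
  ramp <- 0.1 * t
  expect_equal(compute_gradient(ramp, 2), rep(0.1, 20), tolerance = 1e-12)
  expect_equal(compute_gradient(rep(3, 8), 2), rep(0, 8))
  expect_equal(compute_gradient(c(0, 1, 0), 2), c(0.5, 0, -0.5))
  expect_error(compute_gradient(1, 2), "two points")
})

test_that("peak localisation matches an exhaustive-scan oracle", {
  expect_identical(locate_peak(c(0, 0.2, 1.0, 0.4)), 3L)
  expect_identical(locate_peak(c(0, 1.0, 1.0, 0)), 2L)  # earliest tie
  expect_error(locate_peak(c(1, 2), window = integer(0)), "empty")
  expect_error(locate_peak(c(1, 2), window = 3), "bounds")

  set.seed(421)
  for (i in 1:1000) {
    x <- stats::rnorm(sample(5:80, 1))
    best <- 1L
    for (j in seq_along(x)) if (x[j] > x[best]) best <- j
    expect_identical(locate_peak(x), best)
  }
})

test_that("pulse-boundary scan agrees with the hand oracle", {
  det <- c(0, 0, 0.1, 0.5, 1.0, 0.6, 0.2, 0.05, 0)
  grad <- compute_gradient(det, 1)
  b <- locate_pulse_bounds(det, grad, peak = 5L, theta_s = 0.15,
                           theta_g = 0.15)
  o <- oracle_bounds(det, grad, 5L, 0.15, 0.15)
  expect_identical(b, o)
  expect_identical(b$on_idx, 2L)   # hand index-by-index scan
  expect_identical(b$off_idx, 8L)

  # 100 seeded noisy spikes against the oracle
  set.seed(833)
  for (i in 1:100) {
    n <- sample(40:120, 1)
    x <- stats::rnorm(n, 0, 0.1) +
      tent_values(seq_len(n), sample(10:20, 1), runif(1, 3, 8),
                  runif(1, 4, 10), runif(1, 0.5, 1.5))
    g <- compute_gradient(x, 1)
    pk <- locate_peak(x)
    ts <- runif(1, 0.05, 0.3)
    tg <- runif(1, 0.05, 0.3)
    expect_identical(locate_pulse_bounds(x, g, pk, ts, tg),
                     oracle_bounds(x, g, pk, ts, tg))
  }

  # a limb truncated by the recording start censors the onset
  rising <- c(0.5, 0.7, 1.0, 0.4, 0.05, 0)
  g2 <- compute_gradient(rising, 1)
  b2 <- locate_pulse_bounds(rising, g2, 3L, 0.15, 10)
  expect_true(b2$censored_onset)
  expect_identical(b2$on_idx, 1L)
  expect_false(b2$censored_offset)

  # degenerate flat series: nothing falls below a zero threshold
  flat <- rep(0, 9)
  b3 <- locate_pulse_bounds(flat, rep(0, 9), 5L, 0, 0)
  expect_true(b3$censored_onset && b3$censored_offset)
})

test_that("spike measurement enforces the duration identity", {
  one <- measure_spike(2, 4, 7, 0.8)
  expect_equal(one$rise_s, 2)
  expect_equal(one$fall_s, 3)
  expect_equal(one$duration_s, 5)

  # the reported wild-type signature: rise and fall sum to the duration
  wt <- measure_spike(0, 15.4, 39.5, 1)
  expect_equal(wt$rise_s, 15.4)
  expect_equal(wt$fall_s, 24.1)
  expect_identical(wt$duration_s, wt$rise_s + wt$fall_s)

  zero <- measure_spike(5, 5, 5, 0)
  expect_equal(zero$duration_s, 0)
  expect_error(measure_spike(4, 2, 7), "ordering")
})

test_that("detection recovers injected spikes and rejects noise", {
  cfg <- sim_config(seed = 31)

  # pure noise: no calls at the default amplitude gate
  quiet <- simulate_trace(cfg, NULL)
  expect_identical(nrow(spike_calls(detect_spikes(quiet$trace))), 0L)

  # one noiseless tent spike: one call within a frame of ground truth
  cfg0 <- sim_config(seed = 32, noise_sigma = 0)
  sim <- simulate_trace(cfg0, data.frame(t_on = 1000, rise = 16, fall = 26,
                                         amplitude = 0.5))
  fit <- detect_spikes(sim$trace)
  calls <- spike_calls(fit)
  expect_identical(nrow(calls), 1L)
  expect_lt(abs(calls$t_on_s - 1000), 2)
  expect_lt(abs(calls$t_peak_s - 1016), 2)
  expect_lt(abs(calls$t_off_s - 1042), 2)
  expect_false(calls$censored)

  # two well-separated spikes arrive in onset order
  sim2 <- simulate_trace(sim_config(seed = 33),
                         data.frame(t_on = c(900, 3600),
                                    rise = c(15, 20), fall = c(25, 20),
                                    amplitude = c(0.5, 0.6)))
  calls2 <- spike_calls(detect_spikes(sim2$trace))
  expect_identical(nrow(calls2), 2L)
  expect_true(all(diff(calls2$t_on_s) > 0))
  expect_lt(abs(calls2$t_on_s[1] - 900), 6)
  expect_lt(abs(calls2$t_on_s[2] - 3600), 6)

  # every call satisfies the ordering and duration identities
  expect_true(all(calls2$t_on_s <= calls2$t_peak_s))
  expect_true(all(calls2$t_peak_s <= calls2$t_off_s))
  expect_equal(calls2$duration_s, calls2$rise_s + calls2$fall_s)
})

test_that("raising the amplitude gate never adds calls", {
  sim <- simulate_trace(sim_config(seed = 35),
                        data.frame(t_on = c(800, 2600, 4200),
                                   rise = c(12, 18, 25),
                                   fall = c(20, 24, 28),
                                   amplitude = c(0.3, 0.5, 0.8)))
  counts <- vapply(c(2, 3, 5, 8, 12), function(m)
    nrow(spike_calls(detect_spikes(
      sim$trace, detection_params(amp_mult = m)))), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a pulse truncated by the recording edge is flagged censored", {
  n <- 200
  times <- seq(0, by = 2, length.out = n)
  # fall limb runs past the end of the recording
  f <- 100 * (1 + tent_values(times, 300, 20, 200, 0.6))
  tr <- fluorescence_trace("p", "c", "nuclear", times, f,
                           frame_interval = 2)
  calls <- spike_calls(detect_spikes(tr))
  expect_identical(nrow(calls), 1L)
  expect_true(calls$censored)
  expect_equal(calls$t_off_s, times[n])
})

test_that("spike_fit behaves like a fitted-model object", {
  sim <- simulate_trace(sim_config(seed = 36),
                        data.frame(t_on = 2000, rise = 15, fall = 24,
                                   amplitude = 0.5))
  fit <- detect_spikes(sim$trace)
  expect_s3_class(fit, "spike_fit")
  expect_length(coef(fit), 4L)        # cubic trend, ascending degree
  expect_length(fitted(fit), length(sim$trace))
  expect_equal(residuals(fit) + fitted(fit),
               normalize_dff(sim$trace, 20)$values, tolerance = 1e-9)
  expect_output(print(fit), "spike_fit")
  s <- summary(fit)
  expect_identical(s$n_calls, 1L)
  expect_output(print(s), "mean rise")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))

  # collection method stacks calls across member traces
  pair <- simulate_cell_pair(sim_config(seed = 37))
  coll <- trace_collection(list(pair$nuclear, pair$cytosolic))
  set_fit <- detect_spikes(coll)
  expect_s3_class(set_fit, "spike_fit_set")
  expect_identical(nrow(spike_calls(set_fit)), 2L)
})
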