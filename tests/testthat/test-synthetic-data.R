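test_that("the simulator is bitwise deterministic under a fixed seed", {
  cfg <- sim_config(seed = 91, n_plants = 3L, duration_s = 600)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in c("traces.csv", "truth.csv", "plants.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }

  tr1 <- simulate_trace(cfg, data.frame(t_on = 100, rise = 15, fall = 25,
                                        amplitude = 0.5))
  tr2 <- simulate_trace(cfg, data.frame(t_on = 100, rise = 15, fall = 25,
                                        amplitude = 0.5))
  expect_identical(tr1$trace$intensities, tr2$trace$intensities)
})

test_that("a drift-free noise-free configuration yields a flat trace", {
  cfg <- sim_config(seed = 92, noise_sigma = 0, drift_coeffs = 0,
                    duration_s = 300)
  sim <- simulate_trace(cfg, NULL)
  expect_true(all(sim$trace$intensities == cfg$f0_level))
  expect_null(sim$truth)
})

test_that("tent ground truth equals the kernel breakpoints exactly", {
  cfg <- sim_config(seed = 93, noise_sigma = 0)
  sim <- simulate_trace(cfg, data.frame(t_on = 500, rise = 12, fall = 30,
                                        amplitude = 0.4))
  expect_equal(sim$truth$true_t_on, 500)
  expect_equal(sim$truth$true_t_peak, 512)
  expect_equal(sim$truth$true_t_off, 542)
  expect_true(sim$truth$true_t_on < sim$truth$true_t_peak)
  expect_true(sim$truth$true_t_peak < sim$truth$true_t_off)
})

test_that("double-exponential ground truth sits at the 5% crossings", {
  cfg <- sim_config(seed = 94, noise_sigma = 0, drift_coeffs = 0,
                    kernel = "double_exponential", duration_s = 1200)
  sim <- simulate_trace(cfg, data.frame(t_on = 200, rise = 15, fall = 24,
                                        amplitude = 0.5))
  tt <- sim$truth
  expect_true(tt$true_t_on < tt$true_t_peak)
  expect_true(tt$true_t_peak < tt$true_t_off)
  # the noiseless dF/F at the true boundaries is ~5% of the amplitude
  dff <- (sim$trace$intensities - cfg$f0_level) / cfg$f0_level
  level_on <- approx(sim$trace$times, dff, tt$true_t_on)$y
  level_off <- approx(sim$trace$times, dff, tt$true_t_off)$y
  expect_lt(abs(level_on - 0.05 * 0.5), 0.01)
  expect_lt(abs(level_off - 0.05 * 0.5), 0.01)
})

test_that("invalid spike specifications are rejected", {
  cfg <- sim_config(seed = 95, duration_s = 600)
  expect_error(simulate_trace(cfg, data.frame(t_on = 590, rise = 15,
                                              fall = 25, amplitude = 0.5)),
               "within")
  expect_error(simulate_trace(cfg, data.frame(t_on = c(100, 110),
                                              rise = c(15, 15),
                                              fall = c(25, 25),
                                              amplitude = c(0.5, 0.5))),
               "overlap")
  expect_error(sim_config(nuclear_cyto_lag_s = -1))
})

test_that("detection recovers a noiseless simulated spike within a frame", {
  cfg <- sim_config(seed = 96, noise_sigma = 0)
  sim <- simulate_trace(cfg, data.frame(t_on = 2000, rise = 15.4,
                                        fall = 24.1, amplitude = 0.5))
  calls <- spike_calls(detect_spikes(sim$trace))
  expect_identical(nrow(calls), 1L)
  expect_lte(abs(calls$t_on_s - sim$truth$true_t_on),
             cfg$frame_interval_s)
  expect_lte(abs(calls$t_peak_s - sim$truth$true_t_peak),
             cfg$frame_interval_s)
  expect_lte(abs(calls$t_off_s - sim$truth$true_t_off),
             cfg$frame_interval_s)
})

test_that("cohort structure follows its generating distributions", {
  # no responders: silent cohort with an empty truth table
  silent <- simulate_cohort(sim_config(seed = 97, n_plants = 5L,
                                       duration_s = 300,
                                       responder_prob = 0))
  expect_identical(nrow(silent$truth), 0L)

  # spiking cells per responder: Poisson with mean rate x hours
  cfg <- sim_config(seed = 98, n_plants = 50L, duration_s = 3600,
                    responder_prob = 1, spikes_per_responder_rate = 5)
  coh <- simulate_cohort(cfg)
  per_plant <- table(factor(coh$truth$plant_id,
                            levels = coh$plants$plant_id))
  m <- mean(per_plant)
  se <- sd(per_plant) / sqrt(length(per_plant))
  expect_lt(abs(m - 5), 2 * se + 1e-12)

  # meristem share of spiking cells: binomial around the zone mix
  share <- mean(coh$truth$position_um <= cfg$boundary_um)
  n <- nrow(coh$truth)
  expect_lt(abs(share - 0.8), 1.96 * sqrt(0.8 * 0.2 / n))

  # presets encode direction of effect
  lf <- sim_config(seed = 99, genotype_preset = "low_frequency")
  expect_lt(lf$responder_prob, 0.7)
  expect_lt(lf$spikes_per_responder_rate, 5)
  sk <- sim_config(seed = 99, genotype_preset = "slow_kinetics")
  expect_gt(sk$rise_mean_s, 15.4)
  expect_gt(sk$fall_mean_s, 24.1)
})

test_that("simulated cell pairs encode the programmed nuclear lead", {
  cfg <- sim_config(seed = 90, noise_sigma = 0)
  pr <- simulate_cell_pair(cfg)
  tt <- pr$truth
  nuc <- tt[tt$channel == "nuclear", ]
  cyt <- tt[tt$channel == "cytosolic", ]
  expect_equal(cyt$true_t_on - nuc$true_t_on, cfg$nuclear_cyto_lag_s)
  expect_equal(cyt$true_amplitude_dff / nuc$true_amplitude_dff,
               cfg$cyto_amplitude_scale, tolerance = 1e-9)
})
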