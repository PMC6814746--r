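nuc_call <- function(cell, t_on = 100, censored = FALSE, plant = "p1") {
  measure_spike(t_on, t_on + 15, t_on + 40, 0.5, censored, plant, cell,
                "nuclear")
}

test_that("per-plant summaries count accepted nuclear calls in the span", {
  calls <- do.call(rbind, lapply(sprintf("c%d", 1:5), nuc_call))
  pos <- data.frame(cell_id = sprintf("c%d", 1:5),
                    position_um = c(50, 80, 120, 150, 190))
  s <- summarize_plant(calls, pos, "p1", duration_s = 3600)
  expect_identical(s$n_spikes_in_span, 5L)
  expect_equal(s$spikes_per_hour, 5)  # five responding cells per hour
  expect_true(s$responder)

  # one cell beyond the 200 um span drops out of the rate
  pos2 <- transform(pos, position_um = c(50, 80, 250, 150, 190))
  s2 <- summarize_plant(calls[1:3, ], pos2[1:3, ], "p1",
                        duration_s = 1.5 * 3600)
  expect_identical(s2$n_spikes_in_span, 2L)
  expect_equal(s2$spikes_per_hour, 2 / 1.5)

  s0 <- summarize_plant(empty_spike_calls(), pos, "p1", duration_s = 3600)
  expect_identical(s0$n_spikes_in_span, 0L)
  expect_false(s0$responder)

  expect_error(
    summarize_plant(calls, pos[1:3, ], "p1", duration_s = 3600),
    "missing position.*c4")
})

test_that("responder fraction is a per-plant percentage", {
  s <- data.frame(plant_id = sprintf("p%d", 1:10),
                  responder = rep(c(TRUE, FALSE), c(4, 6)))
  expect_equal(responder_fraction(s), 40)
  expect_equal(responder_fraction(transform(s, responder = TRUE)), 100)
  expect_equal(responder_fraction(transform(s, responder = FALSE)), 0)
  expect_error(responder_fraction(s[0, ]), "at least one")

  # duplicating a plant's calls cannot change its responder flag
  calls <- rbind(nuc_call("c1"), nuc_call("c1", t_on = 100.1))
  pos <- data.frame(cell_id = "c1", position_um = 50)
  s1 <- summarize_plant(nuc_call("c1"), pos, "p1", 3600)
  s2 <- summarize_plant(calls, pos, "p1", 3600)
  expect_identical(s1$responder, s2$responder)
})

test_that("zone partition splits at the boundary with an inclusive rule", {
  calls <- do.call(rbind, lapply(sprintf("c%d", 1:10), nuc_call))
  pos <- data.frame(plant_id = "p1", cell_id = sprintf("c%d", 1:10),
                    position_um = c(seq(20, 160, 20), 250, 300))
  z <- partition_by_zone(calls, pos, 200)
  expect_equal(z$meristem_pct, 80)
  expect_equal(z$elongation_pct, 20)
  expect_equal(z$meristem_pct + z$elongation_pct, 100)

  z_all <- partition_by_zone(calls, transform(pos, position_um = 10), 200)
  expect_equal(z_all$meristem_pct, 100)

  # a call exactly at the boundary is meristematic
  z_tie <- partition_by_zone(nuc_call("c1"),
                             data.frame(plant_id = "p1", cell_id = "c1",
                                        position_um = 200), 200)
  expect_equal(z_tie$meristem_pct, 100)

  expect_error(partition_by_zone(
    nuc_call("c1"),
    data.frame(plant_id = "p1", cell_id = "c1", position_um = 100),
    data.frame(plant_id = "p9", boundary_um = 200)), "boundary")
})

test_that("shape means exclude censored calls and keep the duration identity", {
  calls <- rbind(measure_spike(0, 10, 30, 1, FALSE, "p", "c1", "nuclear"),
                 measure_spike(0, 20, 50, 1, FALSE, "p", "c2", "nuclear"))
  sm <- shape_means(calls)
  expect_equal(sm$mean_rise_s, 15)
  expect_equal(sm$mean_fall_s, 25)
  expect_equal(sm$mean_duration_s, 40)
  expect_lt(abs(sm$mean_duration_s - (sm$mean_rise_s + sm$mean_fall_s)),
            1e-9)

  single <- shape_means(calls[1, ])
  expect_identical(single$n, 1L)
  expect_equal(single$sd_rise_s, 0)

  mixed <- rbind(calls, measure_spike(0, 40, 90, 1, TRUE, "p", "c3",
                                      "nuclear"))
  expect_identical(shape_means(mixed)$n, 2L)

  none <- shape_means(mixed[mixed$censored, ])
  expect_identical(none$n, 0L)
  expect_true(is.na(none$mean_rise_s))
})

test_that("growth regression uses every matched point", {
  g <- growth_records(data.frame(plant_id = sprintf("p%d", 1:5),
                                 length_day3_cm = 1,
                                 length_day5_cm = 1 + 2 * c(0.2, 0.3, 0.25,
                                                            0.4, 0.35)))
  expect_equal(g$growth_rate_cm_per_day, c(0.2, 0.3, 0.25, 0.4, 0.35))

  s <- data.frame(plant_id = g$plant_id, spikes_per_hour = c(2, 4, 3, 6, 5))
  g$growth_rate_cm_per_day <- 0.05 * s$spikes_per_hour + 0.1
  fit <- correlate_growth_spiking(g, s)
  expect_equal(fit$slope, 0.05, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)

  g$growth_rate_cm_per_day <- 0.3
  expect_equal(correlate_growth_spiking(g, s)$slope, 0, tolerance = 1e-12)

  # 20 seeded noisy points against the closed-form normal equations
  set.seed(644)
  s20 <- data.frame(plant_id = sprintf("q%d", 1:20),
                    spikes_per_hour = runif(20, 0, 8))
  g20 <- data.frame(plant_id = s20$plant_id, length_day3_cm = 1,
                    length_day5_cm = 1)
  y <- 0.04 * s20$spikes_per_hour + 0.12 + rnorm(20, 0, 0.05)
  g20$length_day5_cm <- g20$length_day3_cm + 2 * y
  g20 <- growth_records(g20)
  fit20 <- correlate_growth_spiking(g20, s20)
  x <- s20$spikes_per_hour
  slope_oracle <- (mean(x * y) - mean(x) * mean(y)) /
    (mean(x^2) - mean(x)^2)
  expect_equal(fit20$slope, slope_oracle, tolerance = 1e-9)
  expect_equal(fit20$intercept, mean(y) - slope_oracle * mean(x),
               tolerance = 1e-9)

  expect_error(correlate_growth_spiking(g20[1, ], s20[1, ]), "two plants")
  s_const <- transform(s20, spikes_per_hour = 3)
  expect_error(correlate_growth_spiking(g20, s_const), "zero variance")
})

test_that("genotype summaries aggregate plants and calls consistently", {
  cfg <- sim_config(seed = 71, n_plants = 8L, duration_s = 1800)
  coh <- simulate_cohort(cfg)
  calls <- spike_calls(detect_spikes(coh$collection))
  summ <- summarize_plants(calls, coh$plants, coh$positions)
  gs <- genotype_summary(summ, calls)
  expect_identical(gs$genotype, "wildtype")
  expect_identical(gs$n_plants, 8L)
  if (gs$n_calls > 0) {
    expect_lt(abs(gs$mean_duration_s - (gs$mean_rise_s + gs$mean_fall_s)),
              1e-9)
    expect_equal(gs$meristem_pct + gs$elongation_pct, 100)
  }
})
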