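test_that("ENSO generator handles degenerate and forced-offset settings", {
  cfg0 <- sim_config(n_estates = 20, seed = 3, enso_ar_coef = 0,
                     enso_sd = 0, event_offsets = list())
  s0 <- generate_enso_series(cfg0)
  expect_true(all(s0$value == 0))
  expect_equal(nrow(s0), 102L + 24L)
  cfg1 <- sim_config(n_estates = 20, seed = 3, enso_ar_coef = 0, enso_sd = 0,
                     event_offsets = list(
                       list(start = "2015-06", end = "2016-04", level = 2)))
  s1 <- generate_enso_series(cfg1)
  win <- ensopalm:::parse_ym(s1$period) >= ensopalm:::parse_ym("2015-06") &
    ensopalm:::parse_ym(s1$period) <= ensopalm:::parse_ym("2016-04")
  expect_equal(mean(s1$value[win]), 2)
  expect_true(all(s1$value[!win] == 0))
})

test_that("AR(1) series has the configured lag-1 autocorrelation", {
  cfg <- sim_config(n_estates = 20, panel_start = "2015-01",
                    panel_end = ensopalm:::format_ym(
                      ensopalm:::parse_ym("2015-01") + 9999L),
                    enso_ar_coef = 0.9, enso_sd = 0.3,
                    event_offsets = list(), seed = 11)
  s <- generate_enso_series(cfg)
  r1 <- stats::cor(s$value[-1], s$value[-nrow(s)])
  expect_lt(abs(r1 - 0.9), 0.02)
  # marginal sd close to sd / sqrt(1 - ar^2)
  expect_lt(abs(stats::sd(s$value) - 0.3 / sqrt(1 - 0.81)), 0.05)
})

test_that("panel collapses to the baseline when all variation is off", {
  cfg <- sim_config(n_estates = 15, seed = 5,
                    surface = surface_params(0, 0),
                    oer_surface = surface_params(0, 0, L_true = 6L),
                    season_amp = 0, oer_season_amp = 0,
                    state_effect_sd = 0, estate_intercept_sd = 0,
                    noise_sd = 0, oer_state_sd = 0, oer_estate_sd = 0,
                    oer_noise_sd = 0, oer_missing_prob = 0,
                    covariate_betas = list(labor = 0, fertilizer = 0,
                                           soil = 0, age = 0))
  p <- generate_panel(cfg)
  expect_true(all(abs(p$ffb_yield - 1.36) < 1e-12))
  expect_true(all(abs(p$oer - 18.71) < 1e-12))
  expect_equal(p$oil_yield, p$ffb_yield * p$oer / 100, tolerance = 1e-12)
})

test_that("default panel is calibrated to the stated means", {
  p <- generate_panel(sim_config(n_estates = 200, seed = 9))
  expect_lt(abs(mean(p$ffb_yield) - 1.36) / 1.36, 0.10)
  expect_lt(abs(mean(p$oer, na.rm = TRUE) - 18.71) / 18.71, 0.10)
  expect_equal(nrow(p), 200L * 102L)
  expect_equal(length(unique(p$state)), 13L)
  # seasonality: February is the trough, September/October the peak
  msd <- tapply(p$ffb_yield, substr(p$period, 6, 7), mean)
  expect_equal(names(which.min(msd)), "02")
  expect_true(names(which.max(msd)) %in% c("09", "10"))
})

test_that("a sustained cool-phase block lowers yields when gamma_neg > 0", {
  cfg <- sim_config(n_estates = 25, seed = 2,
                    enso_ar_coef = 0, enso_sd = 0,
                    event_offsets = list(
                      list(start = "2018-01", end = "2018-12", level = -1)),
                    season_amp = 0, state_effect_sd = 0,
                    estate_intercept_sd = 0, noise_sd = 0,
                    covariate_betas = list(labor = 0, fertilizer = 0,
                                           soil = 0, age = 0))
  p <- generate_panel(cfg)
  ym <- ensopalm:::parse_ym(p$period)
  exposed <- ym >= ensopalm:::parse_ym("2018-01") &
    ym <= ensopalm:::parse_ym("2019-12")        # block + lagged tail
  neutral <- ym < ensopalm:::parse_ym("2018-01")
  expect_lt(mean(p$ffb_yield[exposed]), mean(p$ffb_yield[neutral]))
})

test_that("true_cumulative matches the closed form of the configured surface", {
  surf <- surface_params(0.1, 0.2, L_true = 23L, weights = rep(1, 24))
  expect_equal(true_cumulative(surf, 0, 23), 0)
  expect_equal(true_cumulative(surf, 2, 23), -0.4)
  expect_equal(true_cumulative(surf, -1, 23), -0.2)
  # truncated window refuses to drop part of the profile
  expect_error(true_cumulative(surf, 1, 10), "L must be >=")
  # geometric default still sums weights to 1
  expect_equal(sum(surface_params(L_true = 12L)$w), 1)
})

test_that("generation is deterministic and CSV round-trips byte-identically", {
  cfg <- sim_config(n_estates = 30, seed = 77)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_panel_csv(generate_panel(cfg), f1)
  write_panel_csv(generate_panel(cfg), f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  p2 <- read_panel_csv(f1)
  expect_equal(nrow(p2), 30L * 102L)
  expect_type(p2$lockdown, "logical")
  unlink(c(f1, f2))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(mean_oer = 35), "mean_oer")
  expect_error(sim_config(noise_sd = -1), "SD")
  expect_error(sim_config(panel_start = "2015-01", panel_end = "2015-12"),
               "24 months")
  expect_error(sim_config(enso_ar_coef = 1), "enso_ar_coef")
  expect_error(surface_params(weights = c(-1, 1), L_true = 1L), "nonnegative")
})
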