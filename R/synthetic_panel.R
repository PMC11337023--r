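# Synthetic estate-month panel generator.
#
# Real estate-level administrative yield records are restricted, so analyses
# are exercised on simulated panels that reproduce the statistical structure
# the method assumes: a basin-wide monthly ENSO index shared by all estates,
# an exposure-lag-response surface acting on yields, February-trough /
# September-October-peak seasonality, state and estate heterogeneity, small
# linear covariate effects (so covariate screening has true positives and
# true negatives to find), and state-specific quadratic weather
# teleconnections to the 2-month-lagged index.

#' Ground-truth exposure-lag-response surface
#'
#' The planted surface is f(x, l) = -(g_pos * max(x,0)^2 + g_neg * min(x,0)^2)
#' * w(l), with lag weights w(l) >= 0 summing to 1 over l = 0..L_true. It is
#' zero at the reference exposure x = 0, its cumulative curve is an inverted U
#' with maximum at 0, and g_neg > g_pos makes the cool-phase (La Nina) side
#' steeper.
#'
#' @param gamma_pos,gamma_neg curvature of the warm- and cool-phase arms
#'   (outcome units per squared index unit, cumulated over the lag window).
#' @param L_true last lag with non-zero weight.
#' @param weights optional explicit lag weights (length L_true + 1); they are
#'   normalized to sum to 1. Default: geometric decay `decay^l`, normalized.
#' @param decay geometric decay rate of the default weights.
#' @return object of class `true_surface`.
#' @export
surface_params <- function(gamma_pos = 0.1, gamma_neg = 0.2, L_true = 12L,
                           weights = NULL, decay = 0.8) {
  L_true <- as.integer(L_true)
  if (L_true < 0) stop("L_true must be >= 0")
  if (is.null(weights)) weights <- decay^(0:L_true)
  if (length(weights) != L_true + 1L) stop("weights must have length L_true + 1")
  if (any(weights < 0)) stop("lag weights must be nonnegative")
  s <- sum(weights)
  w <- if (s > 0) weights / s else weights  # all-zero allowed for null surfaces
  structure(list(gamma_pos = gamma_pos, gamma_neg = gamma_neg,
                 L_true = L_true, w = w),
            class = "true_surface")
}

#' Evaluate the ground-truth surface
#' @param surface a [surface_params()] object.
#' @param x exposure value(s).
#' @param l lag(s) in 0..L_true (weights are 0 beyond L_true).
#' @export
surface_f <- function(surface, x, l) {
  w <- ifelse(l >= 0 & l <= surface$L_true, surface$w[pmin(l, surface$L_true) + 1L], 0)
  -(surface$gamma_pos * pmax(x, 0)^2 + surface$gamma_neg * pmin(x, 0)^2) * w
}

#' Ground-truth cumulative effect over lags 0..L
#'
#' Closed-form oracle for recovery tests: sum_l f(x, l). Requires L >= L_true
#' so the whole lag profile is covered (the weights then sum to 1 and the
#' cumulative effect is -(g_pos max(x,0)^2 + g_neg min(x,0)^2)).
#'
#' @param surface a [surface_params()] object.
#' @param x exposure value(s).
#' @param L lag window upper end.
#' @export
true_cumulative <- function(surface, x, L) {
  if (L < surface$L_true) stop("L must be >= L_true (", surface$L_true, ")")
  vapply(x, function(xx) sum(surface_f(surface, xx, 0:L)), numeric(1))
}

#' Simulation configuration
#'
#' Defaults encode the study setting the generator emulates: 13 states,
#' 102 panel months (2015-01..2023-06), mean fresh fruit bunch (FFB) yield
#' 1.36 t/ha/month, mean oil extraction rate (OER) 18.71 %, a stationary
#' AR(1) ENSO index with warm events in 2015-16 and mid-2023 and a cool event
#' in 2020-21, and an asymmetric inverted-U exposure-lag-response surface.
#'
#' @param n_estates number of estates.
#' @param n_states number of states (estates are spread over all of them).
#' @param panel_start,panel_end first/last panel month ("YYYY-MM").
#' @param enso_ar_coef AR(1) coefficient of the index, in (-1, 1).
#' @param enso_sd innovation SD of the AR(1) (index units).
#' @param event_offsets list of `list(start, end, level)` blocks added to the
#'   index (sustained warm/cool events).
#' @param surface [surface_params()] for the FFB-yield surface (t/ha/month).
#' @param oer_surface [surface_params()] for the OER surface (% scale), with a
#'   shorter lag profile.
#' @param season_amp amplitude of the FFB seasonal cycle (t/ha/month).
#' @param oer_season_amp amplitude of the OER seasonal cycle (%).
#' @param state_effect_sd,estate_intercept_sd,noise_sd SDs of state effects,
#'   estate intercepts and idiosyncratic noise on the FFB scale (t/ha/month).
#' @param noise_ar optional within-estate AR(1) coefficient of the noise
#'   (default 0: independent; the marginal SD stays `noise_sd`).
#' @param oer_state_sd,oer_estate_sd,oer_noise_sd same on the OER (%) scale.
#' @param oer_missing_prob probability an OER record is missing.
#' @param mean_yield,mean_oer calibration targets for the sample means.
#' @param covariate_betas named list of true linear covariate effects on FFB
#'   yield: `labor` (per worker/ha), `fertilizer` (invested-indicator),
#'   `soil` (per score point), `age` (per year). Price/COVID/lockdown columns
#'   always have zero true effect (true negatives for screening).
#' @param seed integer root seed; the ENSO series uses `enso_seed` and the
#'   panel body uses `seed + 1`.
#' @param enso_seed seed for the shared index series (default `seed`); give
#'   several configs the same `enso_seed` to simulate strata of one study
#'   region that share the basin-wide exposure but have independent estates.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_estates = 200L, n_states = 13L,
                       panel_start = "2015-01", panel_end = "2023-06",
                       enso_ar_coef = 0.8, enso_sd = 0.54,
                       event_offsets = list(
                         list(start = "2015-06", end = "2016-04", level = 1.5),
                         list(start = "2020-08", end = "2021-03", level = -1.0),
                         list(start = "2023-04", end = "2023-06", level = 1.0)),
                       surface = surface_params(),
                       oer_surface = surface_params(0.05, 0.08, L_true = 6L, decay = 0.7),
                       season_amp = 0.15, oer_season_amp = 0.3,
                       state_effect_sd = 0.15, estate_intercept_sd = 0.25,
                       noise_sd = 0.35, noise_ar = 0,
                       oer_state_sd = 0.5, oer_estate_sd = 0.8, oer_noise_sd = 1.2,
                       oer_missing_prob = 0.02,
                       mean_yield = 1.36, mean_oer = 18.71,
                       covariate_betas = list(labor = 3, fertilizer = 0.08,
                                              soil = 0.03, age = -0.004),
                       seed = 1L, enso_seed = NULL) {
  cfg <- list(n_estates = as.integer(n_estates), n_states = as.integer(n_states),
              panel_start = panel_start, panel_end = panel_end,
              enso_ar_coef = enso_ar_coef, enso_sd = enso_sd,
              event_offsets = event_offsets, surface = surface,
              oer_surface = oer_surface,
              season_amp = season_amp, oer_season_amp = oer_season_amp,
              state_effect_sd = state_effect_sd,
              estate_intercept_sd = estate_intercept_sd,
              noise_sd = noise_sd, noise_ar = noise_ar,
              oer_state_sd = oer_state_sd, oer_estate_sd = oer_estate_sd,
              oer_noise_sd = oer_noise_sd, oer_missing_prob = oer_missing_prob,
              mean_yield = mean_yield, mean_oer = mean_oer,
              covariate_betas = covariate_betas, seed = as.integer(seed),
              enso_seed = as.integer(enso_seed %||% seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  n_months <- parse_ym(cfg$panel_end) - parse_ym(cfg$panel_start) + 1L
  if (n_months < 24L) stop("panel must span at least 24 months, got ", n_months)
  if (cfg$n_estates < 1L) stop("n_estates must be >= 1")
  if (cfg$n_states < 1L || cfg$n_states > cfg$n_estates)
    stop("n_states must be in [1, n_estates]")
  if (abs(cfg$enso_ar_coef) >= 1) stop("enso_ar_coef must be in (-1, 1)")
  sds <- c(cfg$enso_sd, cfg$season_amp, cfg$oer_season_amp, cfg$state_effect_sd,
           cfg$estate_intercept_sd, cfg$noise_sd, cfg$oer_state_sd,
           cfg$oer_estate_sd, cfg$oer_noise_sd)
  if (any(sds < 0)) stop("all SDs / amplitudes must be >= 0")
  if (abs(cfg$noise_ar) >= 1) stop("noise_ar must be in (-1, 1)")
  if (cfg$mean_oer <= 0 || cfg$mean_oer >= 30) stop("mean_oer must be in (0, 30)")
  invisible(cfg)
}

# Seasonal shape on the FFB scale: trough in February, joint peak in
# September-October; centered so it adds nothing to the annual mean.
season_shape <- function() {
  s <- c(-0.8, -1.0, -0.6, -0.3, -0.1, 0.0, 0.2, 0.5, 1.0, 1.0, 0.6, -0.1)
  s - mean(s)
}

#' Generate the shared monthly ENSO index series
#'
#' Stationary AR(1) initialized from its marginal distribution, plus sustained
#' event offsets; starts 24 months before the panel so every observation has a
#' full lag history.
#'
#' @param config a [sim_config()].
#' @return data.frame (`period`, `value`), one row per calendar month from
#'   24 months before `panel_start` through `panel_end`.
#' @export
generate_enso_series <- function(config) {
  validate_sim_config(config)
  set.seed(config$enso_seed %||% config$seed)
  start <- parse_ym(config$panel_start) - 24L
  end <- parse_ym(config$panel_end)
  n <- end - start + 1L
  ar <- config$enso_ar_coef; sd <- config$enso_sd
  x <- numeric(n)
  if (sd > 0) {
    innov <- stats::rnorm(n, 0, sd)
    x[1] <- stats::rnorm(1, 0, sd / sqrt(1 - ar^2))
    for (t in 2:n) x[t] <- ar * x[t - 1L] + innov[t]
  }
  ym <- start:end
  for (ev in config$event_offsets) {
    sel <- ym >= parse_ym(ev$start) & ym <= parse_ym(ev$end)
    x[sel] <- x[sel] + ev$level
  }
  data.frame(period = format_ym(ym), value = x)
}

# Cumulative lagged surface effect for each month of a gap-free series,
# evaluated at months >= L_true from the series start.
lagged_effect <- function(values, surface, at_idx) {
  eff <- numeric(length(at_idx))
  for (l in 0:surface$L_true)
    eff <- eff + surface_f(surface, values[at_idx - l], l)
  eff
}

#' Generate a synthetic estate-month panel
#'
#' FFB yield is built as mean level + seasonality + state effect + estate
#' intercept + cumulative lagged ENSO surface effect + centered covariate
#' effects + noise, truncated at 0; the systematic part is centered so the
#' sample mean matches `mean_yield` by construction. OER is generated
#' analogously on the % scale with its own shorter lag profile, and oil yield
#' is FFB yield x OER / 100. Weather variables follow state-specific
#' quadratics in the 2-month-lagged index.
#'
#' @param config a [sim_config()].
#' @return data.frame, one row per estate-month, ordered by estate then
#'   period, with attributes `config`, `enso` (the index series), `surface`
#'   and `oer_surface` (planted truths).
#' @export
generate_panel <- function(config) {
  validate_sim_config(config)
  enso <- generate_enso_series(config)
  set.seed(config$seed + 1L)

  pym <- parse_ym(config$panel_start):parse_ym(config$panel_end)
  n_m <- length(pym)
  n_e <- config$n_estates
  n_s <- config$n_states
  sym <- parse_ym(enso$period)
  at_idx <- match(pym, sym)

  # estate-level draws
  estate_id <- sprintf("E%04d", seq_len(n_e))
  state_of <- sample(rep_len(seq_len(n_s), n_e))          # every state populated
  harvested_area <- stats::rlnorm(n_e, log(150), 0.5)
  estate_int <- stats::rnorm(n_e, 0, config$estate_intercept_sd)
  oer_estate <- stats::rnorm(n_e, 0, config$oer_estate_sd)
  labor <- stats::rlnorm(n_e, log(0.04), 0.5)
  age <- pmin(pmax(stats::rnorm(n_e, 14, 7), 1), 35)
  soil <- stats::runif(n_e, 1, 7)
  soil[stats::runif(n_e) < 0.45] <- NA

  # state-level draws
  state_eff <- stats::rnorm(n_s, 0, config$state_effect_sd)
  oer_state <- stats::rnorm(n_s, 0, config$oer_state_sd)
  wq <- data.frame(                                        # weather quadratics
    air_a = stats::rnorm(n_s, 26.24, 1.0),
    air_b = stats::rnorm(n_s, 0.30, 0.15),
    air_c = stats::rnorm(n_s, -0.20, 0.10),
    soil_a = stats::rnorm(n_s, 28.0, 1.0),
    soil_b = stats::rnorm(n_s, 0.25, 0.12),
    soil_c = stats::rnorm(n_s, -0.15, 0.08),
    pre_a = stats::rnorm(n_s, 7.09, 0.8),
    pre_b = stats::rnorm(n_s, -0.80, 0.30),
    pre_c = stats::rnorm(n_s, -0.30, 0.20))

  # common monthly series: prices, CPI, exchange rate
  walk <- function(p0, sd, drift = 0) p0 * exp(cumsum(stats::rnorm(n_m, drift, sd)))
  prices <- list(
    price_cpo = walk(800, 0.04), price_rock = walk(120, 0.03),
    price_dap = walk(400, 0.03), price_tsp = walk(350, 0.03),
    price_urea = walk(300, 0.04), price_mop = walk(280, 0.03),
    cpi = walk(100, 0.004, 0.002), exchange_rate = walk(4.2, 0.01))

  # pandemic block: state-month case counts and lockdown windows
  covid_on <- pym >= parse_ym("2020-03")
  lockdown_m <- (pym >= parse_ym("2020-03") & pym <= parse_ym("2020-05")) |
    (pym >= parse_ym("2021-06") & pym <= parse_ym("2021-09"))
  covid_sm <- matrix(0, n_m, n_s)
  covid_sm[covid_on, ] <- round(stats::rlnorm(sum(covid_on) * n_s, log(500), 1))

  # fertilizer: estate-year investment; unrecorded in the first and last year
  years <- sort(unique(pym %/% 12L))
  invest <- matrix(stats::runif(n_e * length(years)) < 0.65, n_e, length(years))
  cost_y <- matrix(0, n_e, length(years))
  cost_y[invest] <- stats::rlnorm(sum(invest), log(1135), 0.6)
  cost_y[, c(1L, length(years))] <- NA

  # month-level ENSO surface effects (common to all estates)
  eff_ffb <- lagged_effect(enso$value, config$surface, at_idx)
  eff_oer <- lagged_effect(enso$value, config$oer_surface, at_idx)
  season <- config$season_amp * season_shape()[month_of(pym)]
  season_oer <- config$oer_season_amp * season_shape()[month_of(pym)]

  # expand to estate x month rows (estate-major ordering)
  ei <- rep(seq_len(n_e), each = n_m)
  mi <- rep(seq_len(n_m), times = n_e)
  si <- state_of[ei]
  x2 <- enso$value[at_idx - 2L][mi]                        # 2-month-lagged index

  b <- config$covariate_betas
  fert_cost <- cost_y[cbind(ei, match(pym[mi] %/% 12L, years))]
  fert_ind <- !is.na(fert_cost) & fert_cost > 0
  soil_c <- ifelse(is.na(soil[ei]), 0, soil[ei] - mean(soil, na.rm = TRUE))
  cov_eff <- b$labor * (labor[ei] - mean(labor)) +
    b$fertilizer * (fert_ind - mean(fert_ind)) +
    b$soil * soil_c +
    b$age * (age[ei] - mean(age))

  noise <- estate_noise(n_e, n_m, config$noise_sd, config$noise_ar)
  sys <- eff_ffb[mi] + season[mi] + state_eff[si] + estate_int[ei] + cov_eff
  ffb_yield <- pmax(config$mean_yield + (sys - mean(sys)) + noise, 0)

  noise_oer <- stats::rnorm(n_e * n_m, 0, config$oer_noise_sd)
  sys_oer <- eff_oer[mi] + season_oer[mi] + oer_state[si] + oer_estate[ei]
  oer <- pmin(pmax(config$mean_oer + (sys_oer - mean(sys_oer)) + noise_oer, 0), 100)
  oer[stats::runif(n_e * n_m) < config$oer_missing_prob] <- NA

  state_lab <- sprintf("S%02d", seq_len(n_s))
  period_lab <- format_ym(pym)
  panel <- data.frame(
    estate_id = estate_id[ei],
    state = state_lab[si],
    period = period_lab[mi],
    harvested_area = harvested_area[ei],
    ffb_mass = ffb_yield * harvested_area[ei],
    ffb_yield = ffb_yield,
    oer = oer,
    oil_yield = ffb_yield * oer / 100,
    labor_intensity = labor[ei],
    fertilizer_cost = fert_cost,
    age_profile = age[ei],
    soil_score = soil[ei],
    covid_cases = covid_sm[cbind(mi, si)],
    lockdown = lockdown_m[mi],
    lapply(prices, function(p) p[mi]),
    air_temp = wq$air_a[si] + wq$air_b[si] * x2 + wq$air_c[si] * x2^2 +
      stats::rnorm(n_e * n_m, 0, 0.5),
    soil_temp = wq$soil_a[si] + wq$soil_b[si] * x2 + wq$soil_c[si] * x2^2 +
      stats::rnorm(n_e * n_m, 0, 0.4),
    precip = pmax(wq$pre_a[si] + wq$pre_b[si] * x2 + wq$pre_c[si] * x2^2 +
                    stats::rnorm(n_e * n_m, 0, 1.5), 0.05),
    row.names = NULL)
  attr(panel, "config") <- config
  attr(panel, "enso") <- enso
  attr(panel, "surface") <- config$surface
  attr(panel, "oer_surface") <- config$oer_surface
  panel
}

# idiosyncratic noise, optionally AR(1) within estate with marginal SD sd
estate_noise <- function(n_e, n_m, sd, ar) {
  if (sd == 0) return(numeric(n_e * n_m))
  if (ar == 0) return(stats::rnorm(n_e * n_m, 0, sd))
  innov <- matrix(stats::rnorm(n_e * n_m, 0, sd * sqrt(1 - ar^2)), n_m, n_e)
  innov[1, ] <- stats::rnorm(n_e, 0, sd)
  e <- apply(innov, 2, function(z) stats::filter(z, ar, method = "recursive"))
  as.numeric(e)                                            # estate-major (col-major)
}

#' Write a panel to CSV
#' @param panel data.frame from [generate_panel()].
#' @param path output path.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' Read a panel CSV
#' @param path CSV path.
#' @export
read_panel_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  d$lockdown <- as.logical(d$lockdown)
  d
}
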