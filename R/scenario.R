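#' Define a synthetic biologging cohort scenario
#'
#' A scenario bundles every parameter needed to simulate a doubly-labelled-water
#' (DLW) + biologging field campaign on a plunge-diving seabird colony: cohort
#' sizes, deployment durations, the minute-resolution behavioural Markov chain
#' over the four states (colony, commuting, foraging, resting), state-specific
#' sensor signatures (wingbeat frequency and amplitude, plunge-dive behaviour,
#' travel speed), true activity-specific metabolic rates, and the isotope
#' physics needed to generate blood-sample enrichments consistent with an
#' assigned true daily energy expenditure.
#'
#' The defaults describe a chick-rearing booby colony: 10 equilibrium birds and
#' 20 deployed birds, deployments of 46-61 h, a behavioural chain whose
#' stationary budget puts roughly 19 h per day at the colony and about 4 h in
#' commuting flight, and per-state metabolic rates in the ratio
#' 1 : 2.7 : 4.6 : 2.6 (colony : commuting : foraging : resting) anchored at a
#' colony rate of 0.0325 kJ h\eqn{^{-1}} g\eqn{^{-1}}.
#'
#' @param seed Integer seed; every simulated quantity derives its own
#'   sub-seed from this, so cohorts are reproducible bird by bird.
#' @param n_equilibrium_birds Number of birds sampled at isotopic equilibrium
#'   (1 h post-injection) used to fit the mass-enrichment relation.
#' @param n_deployed_birds Number of logger-equipped, single-sample birds.
#' @param deployment_hours Length-2 positive range of deployment durations [h].
#' @param transition_matrix 4x4 row-stochastic matrix over
#'   colony, commuting, foraging, resting at 1-min resolution. Structural
#'   zeros enforce that birds enter and leave the colony only through
#'   commuting flight.
#' @param initial_distribution Length-4 initial state distribution
#'   (deployments start at the nest, so the default is all mass on colony).
#' @param state_pars Tibble with one row per state and columns
#'   `state`, `wingbeat_hz`, `flap_amp_g`, `dive_prob`, `speed_m_s`,
#'   `drift_m_min`, `dba_per_min`: the sensor signature of each behaviour.
#'   `dba_per_min` is the expected summed VeDBA per minute (g s) used by the
#'   minute-level cohort generator.
#' @param true_activity_rates Named numeric, metabolic rate per state
#'   (kJ h\eqn{^{-1}} g\eqn{^{-1}}); the ground-truth energetics.
#' @param mass_mean_g,mass_sd_g,mass_range_g Body-mass model: sex-specific
#'   normal means (females larger), common s.d., and truncation range [g].
#' @param mass_loss_frac Length-2 range of fractional mass loss over a
#'   deployment (final mass = initial x (1 - loss)).
#' @param colony Named numeric `c(lon=, lat=)`, colony coordinates
#'   (decimal degrees).
#' @param colony_jitter_km S.d. of positional scatter of birds at the colony
#'   [km]; capped at 0.2 km so colony minutes always fall inside the 0.5 km
#'   colony radius.
#' @param trip_rate_sdlog Between-bird lognormal s.d. (log scale) of the
#'   colony-departure rate: the individual "effort" random effect.
#' @param trip_max_km Maximum foraging range [km]; outbound commuting turns
#'   back at this range.
#' @param dive_depth_m,dive_duration_s Ranges for rectangular plunge-dive
#'   pulses (depth [m], submerged duration [s]) within foraging minutes.
#' @param accel_noise_sd_g Gaussian accelerometer noise s.d. per axis [g].
#' @param depth_noise_sd_m Depth-sensor noise s.d. [m].
#' @param gps_noise_m GPS positional noise s.d. [m].
#' @param gps_gap_prob Probability that any one-minute GPS fix is missing.
#' @param isotope List of isotope parameters: `i_inj` (injectate enrichment
#'   [ppm], named d/o), `mol_inj` (dose [mol]), `i_bg` (background enrichment
#'   [ppm], named d/o), `k_d` (baseline water turnover [h\eqn{^{-1}}]),
#'   `body_water_fraction`, `eq_relation` (true linear mass to initial
#'   enrichment map per isotope: list(d=c(intercept, slope), o=...)), and
#'   `equilibration_h`.
#' @param equilibrium_scatter_ppm Named numeric (d, o): residual s.d. of
#'   measured equilibrium enrichments around the true mass relation [ppm].
#' @param dee_noise_cv Lognormal coefficient of variation of the DLW
#'   measurement relative to the true DEE (analytic + physiological error).
#' @param start_time POSIXct deployment start (UTC).
#'
#' @return An object of class `sim_scenario` (a validated list).
#' @examples
#' sc <- sim_scenario(seed = 1)
#' sc$transition_matrix
#' @export
sim_scenario <- function(seed = 1L,
                         n_equilibrium_birds = 10L,
                         n_deployed_birds = 20L,
                         deployment_hours = c(46, 61),
                         transition_matrix = default_transition_matrix(),
                         initial_distribution = c(1, 0, 0, 0),
                         state_pars = default_state_pars(),
                         true_activity_rates = c(colony = 0.0325,
                                                 commuting = 0.08775,
                                                 foraging = 0.1495,
                                                 resting = 0.0845),
                         mass_mean_g = c(male = 1350, female = 1650),
                         mass_sd_g = 75,
                         mass_range_g = c(1100, 1900),
                         mass_loss_frac = c(0, 0.03),
                         colony = c(lon = -78.9636, lat = -8.5447),
                         colony_jitter_km = 0.05,
                         trip_rate_sdlog = 0.35,
                         trip_max_km = 40,
                         dive_depth_m = c(1, 4),
                         dive_duration_s = c(3, 15),
                         accel_noise_sd_g = 0.05,
                         depth_noise_sd_m = 0.02,
                         gps_noise_m = 20,
                         gps_gap_prob = 0.02,
                         isotope = default_isotope_params(),
                         equilibrium_scatter_ppm = c(d = 3, o = 1.5),
                         dee_noise_cv = 0.05,
                         start_time = as.POSIXct("2019-11-12 11:00:00",
                                                 tz = "UTC")) {
  sc <- structure(
    list(
      seed = as.integer(seed),
      n_equilibrium_birds = as.integer(n_equilibrium_birds),
      n_deployed_birds = as.integer(n_deployed_birds),
      deployment_hours = deployment_hours,
      transition_matrix = transition_matrix,
      initial_distribution = initial_distribution,
      state_pars = state_pars,
      true_activity_rates = true_activity_rates,
      mass_mean_g = mass_mean_g,
      mass_sd_g = mass_sd_g,
      mass_range_g = mass_range_g,
      mass_loss_frac = mass_loss_frac,
      colony = colony,
      colony_jitter_km = colony_jitter_km,
      trip_rate_sdlog = trip_rate_sdlog,
      trip_max_km = trip_max_km,
      dive_depth_m = dive_depth_m,
      dive_duration_s = dive_duration_s,
      accel_noise_sd_g = accel_noise_sd_g,
      depth_noise_sd_m = depth_noise_sd_m,
      gps_noise_m = gps_noise_m,
      gps_gap_prob = gps_gap_prob,
      isotope = isotope,
      equilibrium_scatter_ppm = equilibrium_scatter_ppm,
      dee_noise_cv = dee_noise_cv,
      start_time = start_time
    ),
    class = "sim_scenario"
  )
  validate_scenario(sc)
  sc
}

#' Default behavioural transition matrix
#'
#' Minute-resolution Markov chain over colony, commuting, foraging, resting.
#' Structural zeros force all colony arrivals/departures through commuting.
#' The stationary distribution gives roughly 18.8 h colony, 4.0 h commuting,
#' 0.65 h foraging and 0.55 h resting per 24 h.
#'
#' @return A 4x4 row-stochastic matrix with dimnames over the state set.
#' @export
default_transition_matrix <- function() {
  m <- matrix(c(
    0.985, 0.015, 0.00, 0.00,
    0.070, 0.840, 0.06, 0.03,
    0.000, 0.350, 0.55, 0.10,
    0.000, 0.250, 0.10, 0.65
  ), nrow = 4, byrow = TRUE, dimnames = list(.states, .states))
  m
}

#' Default state sensor signatures
#'
#' Wingbeat frequency and flap amplitude drive the synthetic heave-axis
#' waveform; `dive_prob` is the probability that a foraging minute contains a
#' plunge; `speed_m_s` is sustained commuting ground speed; `drift_m_min` is
#' localized movement for non-commuting at-sea states; `dba_per_min` is the
#' expected summed VeDBA per minute implied by the waveform (used by the
#' minute-level cohort generator).
#'
#' @return A tibble with one row per behavioural state.
#' @export
default_state_pars <- function() {
  tibble(
    state = .states,
    wingbeat_hz = c(0, 5.0, 5.5, 0.3),
    flap_amp_g = c(0, 1.0, 1.2, 0.15),
    dive_prob = c(0, 0, 0.7, 0),
    speed_m_s = c(0, 10, 0, 0),
    drift_m_min = c(0, 0, 100, 25),
    dba_per_min = c(4.5, 41, 48, 10)
  )
}

#' Default isotope parameters
#'
#' Enrichments are in ppm of the heavy isotope (deuterium `d`, oxygen-18 `o`).
#' `eq_relation` is the true linear map from body mass [g] to initial
#' (equilibrium) enrichment [ppm] per isotope; its coefficients are consistent
#' with a ~65% body-water pool diluting a 0.055 mol dose across the default
#' mass range. `k_d` is the baseline deuterium (water) turnover.
#'
#' @return A list of isotope parameters (see [sim_scenario()]).
#' @export
default_isotope_params <- function() {
  list(
    i_inj = c(d = 5e5, o = 2.5e5),
    mol_inj = 0.055,
    i_bg = c(d = 150, o = 2000),
    k_d = 0.035,
    body_water_fraction = 0.65,
    eq_relation = list(
      d = c(intercept = 1263, slope = -0.3836),
      o = c(intercept = 2552, slope = -0.19)
    ),
    equilibration_h = 1
  )
}

#' Validate a simulation scenario
#'
#' Checks the invariants a scenario must satisfy: a row-stochastic transition
#' matrix (rows sum to 1 within 1e-12) with non-negative entries, non-negative
#' rates, frequencies and noise levels, a positive deployment-hours range, and
#' physically ordered isotope enrichments.
#'
#' @param scenario A `sim_scenario` object.
#' @return The scenario, invisibly; aborts with a message on violation.
#' @export
validate_scenario <- function(scenario) {
  if (!inherits(scenario, "sim_scenario")) {
    abort("`scenario` must be created with `sim_scenario()`.")
  }
  tm <- scenario$transition_matrix
  if (!is_row_stochastic(tm) || nrow(tm) != 4L) {
    abort("`transition_matrix` must be 4x4 row-stochastic (rows sum to 1 within 1e-12, entries >= 0).")
  }
  d <- scenario$initial_distribution
  if (length(d) != 4L || any(d < 0) || abs(sum(d) - 1) > 1e-12) {
    abort("`initial_distribution` must be a length-4 probability vector.")
  }
  dh <- scenario$deployment_hours
  if (length(dh) != 2L || any(!is.finite(dh)) || dh[1] <= 0 || dh[2] < dh[1]) {
    abort("`deployment_hours` must be a positive increasing range.")
  }
  sp <- scenario$state_pars
  num_cols <- c("wingbeat_hz", "flap_amp_g", "dive_prob", "speed_m_s",
                "drift_m_min", "dba_per_min")
  if (!all(c("state", num_cols) %in% names(sp)) ||
      !setequal(sp$state, .states)) {
    abort("`state_pars` must have one row per state with the documented columns.")
  }
  if (any(as.matrix(sp[num_cols]) < 0)) {
    abort("All state sensor parameters must be >= 0.")
  }
  if (any(scenario$true_activity_rates < 0)) {
    abort("`true_activity_rates` must be >= 0.")
  }
  for (nm in c("accel_noise_sd_g", "depth_noise_sd_m", "gps_noise_m")) {
    assert_number(scenario[[nm]], nm, lower = 0)
  }
  assert_number(scenario$gps_gap_prob, "gps_gap_prob", 0, 1)
  assert_number(scenario$dee_noise_cv, "dee_noise_cv", 0)
  iso <- scenario$isotope
  for (iso_nm in c("d", "o")) {
    if (!(iso$i_inj[[iso_nm]] > iso$i_bg[[iso_nm]] && iso$i_bg[[iso_nm]] > 0)) {
      abort(sprintf("Isotope '%s': need i_inj > i_bg > 0.", iso_nm))
    }
  }
  assert_number(iso$mol_inj, "isotope$mol_inj", lower = 1e-12)
  assert_number(iso$k_d, "isotope$k_d", lower = 0)
  assert_number(iso$equilibration_h, "isotope$equilibration_h", lower = 0)
  invisible(scenario)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario>\n")
  cat(sprintf("  seed: %d | equilibrium birds: %d | deployed birds: %d\n",
              x$seed, x$n_equilibrium_birds, x$n_deployed_birds))
  cat(sprintf("  deployments: %.1f-%.1f h | DLW noise cv: %.3f\n",
              x$deployment_hours[1], x$deployment_hours[2], x$dee_noise_cv))
  pi_st <- stationary_distribution(x$transition_matrix)
  cat("  stationary budget (h/24h): ",
      paste(sprintf("%s %.2f", .states, 24 * pi_st), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
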