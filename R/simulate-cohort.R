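#' Simulate a full DLW + biologging cohort with known ground truth
#'
#' Composes the per-bird simulators into a campaign-level bundle: an
#' equilibrium set (masses plus 1-h equilibrium enrichments scattered around
#' the true mass relation) and a deployed set (minute-level behavioural state
#' sequences with tracks, per-bird time budgets, true mass-specific DEE from
#' the scenario's activity rates, and blood-isotope panels generated by
#' inverting the one-pool DLW equations from the - optionally noisy -
#' measured DEE). Raw 50 Hz / 1 Hz sensor streams are large, so they are not
#' stored in the bundle; generate them per bird with [simulate_sensors()] or
#' write them to disk with [write_cohort()].
#'
#' The ground-truth msDEE of a bird is
#' \eqn{\sum_s MR_s T_s} over the four states, with \eqn{T_s} the bird's
#' deployment time budget standardized to 24 h, and true DEE multiplies by
#' the interval-mean body mass (the same mass convention the DLW analysis
#' reports against).
#'
#' @param scenario A [sim_scenario()].
#' @return A list of class `dee_cohort`:
#'   \describe{
#'     \item{equilibrium}{tibble `bird`, `sex`, `mass_g`, `i_eq_d`, `i_eq_o`.}
#'     \item{dlw}{tibble in the `dlw.csv` schema (`bird`, `set`, masses,
#'       `i_bg_*`, `i_init_*` (NA for deployed birds: single-sample),
#'       `i_final_*`, `i_inj_*`, `mol_inj`, `t_deploy_h`).}
#'     \item{states}{long tibble of per-minute true states and positions for
#'       all deployed birds.}
#'     \item{truth}{tibble per deployed bird: sex, masses, deployment hours,
#'       trip-rate multiplier, true time budget `t_col/t_com/t_for/t_rest`
#'       [h per 24 h], `msdee_true`, `dee_true_kj_day`, `rco2_true_mmol_h`,
#'       and the DLW-measured (noise-included) `dee_meas_kj_day`.}
#'     \item{scenario}{the input scenario.}
#'   }
#' @examples
#' coh <- simulate_cohort(sim_scenario(seed = 1, n_deployed_birds = 3,
#'                                     deployment_hours = c(2, 3)))
#' coh$truth
#' @export
simulate_cohort <- function(scenario) {
  validate_scenario(scenario)
  if (scenario$n_deployed_birds < 3) {
    warn("Fewer than 3 deployed birds: downstream model fitting is degenerate.")
  }
  iso <- scenario$isotope
  constants <- dlw_constants(equilibration_h = iso$equilibration_h)

  # ---- equilibrium set -------------------------------------------------
  n_eq <- scenario$n_equilibrium_birds
  eq <- withr::with_seed(derive_seed(scenario$seed, 11L), {
    sex <- rep(c("female", "male"), length.out = n_eq)
    mass <- draw_mass(sex, scenario)
    tibble(
      bird = sprintf("E%02d", seq_len(n_eq)),
      sex = sex,
      mass_g = mass,
      i_eq_d = iso$eq_relation$d[["intercept"]] + iso$eq_relation$d[["slope"]] * mass +
        rnorm(n_eq, 0, scenario$equilibrium_scatter_ppm[["d"]]),
      i_eq_o = iso$eq_relation$o[["intercept"]] + iso$eq_relation$o[["slope"]] * mass +
        rnorm(n_eq, 0, scenario$equilibrium_scatter_ppm[["o"]])
    )
  })

  # ---- deployed set ----------------------------------------------------
  n_dep <- scenario$n_deployed_birds
  dep_meta <- withr::with_seed(derive_seed(scenario$seed, 12L), {
    sex <- rep(c("female", "male"), length.out = n_dep)
    mass_i <- draw_mass(sex, scenario)
    loss <- runif(n_dep, scenario$mass_loss_frac[1], scenario$mass_loss_frac[2])
    dee_noise <- if (scenario$dee_noise_cv > 0) {
      sdlog <- sqrt(log(1 + scenario$dee_noise_cv^2))
      rlnorm(n_dep, -sdlog^2 / 2, sdlog)
    } else rep(1, n_dep)
    tibble(sex = sex, mass_initial_g = mass_i,
           mass_final_g = mass_i * (1 - loss), dee_noise = dee_noise)
  })

  rates <- scenario$true_activity_rates[.states]
  states_list <- vector("list", n_dep)
  truth_list <- vector("list", n_dep)
  dlw_list <- vector("list", n_dep)
  for (i in seq_len(n_dep)) {
    st <- simulate_states(scenario, i)
    hours <- nrow(st) / 60 # the realized minute grid, not the drawn duration
    budget <- time_budget(st$state, sampling_hours = hours)
    tvec <- setNames(budget$hours, budget$state)[.states]
    msdee_true <- sum(rates * tvec)
    mass_mean <- (dep_meta$mass_initial_g[i] + dep_meta$mass_final_g[i]) / 2
    dee_true <- msdee_true * mass_mean
    dee_meas <- dee_true * dep_meta$dee_noise[i]
    panel <- simulate_isotopes(
      dee_meas, dep_meta$mass_initial_g[i], dep_meta$mass_final_g[i],
      hours, scenario, constants = constants)
    bird_id <- sprintf("D%02d", i)
    states_list[[i]] <- mutate(st, bird = bird_id)
    truth_list[[i]] <- tibble(
      bird = bird_id,
      sex = dep_meta$sex[i],
      mass_initial_g = dep_meta$mass_initial_g[i],
      mass_final_g = dep_meta$mass_final_g[i],
      mass_g = mass_mean,
      deployment_h = hours,
      trip_multiplier = attr(st, "trip_multiplier"),
      t_col = tvec[["colony"]], t_com = tvec[["commuting"]],
      t_for = tvec[["foraging"]], t_rest = tvec[["resting"]],
      msdee_true = msdee_true,
      dee_true_kj_day = dee_true,
      dee_meas_kj_day = dee_meas,
      rco2_true_mmol_h = dee_true * 1000 /
        (constants$ml_per_mmol * constants$j_per_ml * 24)
    )
    dlw_list[[i]] <- mutate(panel, bird = bird_id,
                            i_init_d = NA_real_, i_init_o = NA_real_)
  }

  dlw_eq <- tibble(
    bird = eq$bird, set = "equilibrium",
    mass_initial_g = eq$mass_g, mass_final_g = eq$mass_g,
    i_bg_d = iso$i_bg[["d"]], i_bg_o = iso$i_bg[["o"]],
    i_init_d = eq$i_eq_d, i_init_o = eq$i_eq_o,
    i_final_d = NA_real_, i_final_o = NA_real_,
    i_inj_d = iso$i_inj[["d"]], i_inj_o = iso$i_inj[["o"]],
    mol_inj = iso$mol_inj,
    t_deploy_h = iso$equilibration_h
  )
  dlw_dep <- bind_rows(dlw_list) %>% select(names(dlw_eq))

  structure(
    list(
      equilibrium = eq,
      dlw = bind_rows(dlw_eq, dlw_dep),
      states = bind_rows(states_list),
      truth = bind_rows(truth_list),
      scenario = scenario
    ),
    class = "dee_cohort"
  )
}

# sex-specific truncated-normal body masses
draw_mass <- function(sex, scenario) {
  mu <- scenario$mass_mean_g[sex]
  m <- rnorm(length(sex), mu, scenario$mass_sd_g)
  pmin(pmax(m, scenario$mass_range_g[1]), scenario$mass_range_g[2])
}

#' @export
print.dee_cohort <- function(x, ...) {
  cat(sprintf("<dee_cohort> %d equilibrium + %d deployed birds, %d state-minutes\n",
              nrow(x$equilibrium), nrow(x$truth), nrow(x$states)))
  cat(sprintf("  true msDEE: %.3f +/- %.3f kJ/day/g\n",
              mean(x$truth$msdee_true), sd(x$truth$msdee_true)))
  invisible(x)
}

#' Write a cohort to the documented file layout
#'
#' Serializes a [simulate_cohort()] bundle as delimited text: `dlw.csv`
#' (cohort-level), `truth.csv`, and per deployed bird a directory
#' `<bird>/` containing `states.csv` (true states; validation only) and -
#' when `sensors = TRUE` - `accel.csv` (timestamp, ax, ay, az in g),
#' `depth.csv` (timestamp, depth m) and `gps.csv` (ISO-8601 UTC timestamp,
#' lon, lat). Sensor streams are regenerated deterministically from the
#' scenario, so writing them is optional.
#'
#' @param cohort A `dee_cohort`.
#' @param dir Output directory (created if needed).
#' @param sensors Write the raw 50 Hz / 1 Hz / 1-min streams per bird
#'   (large; default TRUE, the documented layout).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, sensors = TRUE) {
  stopifnot(inherits(cohort, "dee_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$dlw, file.path(dir, "dlw.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  start <- cohort$scenario$start_time
  birds <- unique(cohort$states$bird)
  for (i in seq_along(birds)) {
    b <- birds[i]
    bdir <- file.path(dir, b)
    dir.create(bdir, showWarnings = FALSE)
    st <- cohort$states %>% filter(.data$bird == b)
    readr::write_csv(st, file.path(bdir, "states.csv"))
    if (sensors) {
      sb <- simulate_sensors(mutate(st, bird = i), cohort$scenario)
      readr::write_csv(sb$accel, file.path(bdir, "accel.csv"))
      readr::write_csv(sb$depth, file.path(bdir, "depth.csv"))
      gps <- sb$gps %>%
        mutate(timestamp = format(start + .data$t, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC")) %>%
        select("timestamp", "t", "lon", "lat")
      readr::write_csv(gps, file.path(bdir, "gps.csv"))
    }
  }
  invisible(dir)
}

#' Simulate a minute-level cohort of daily activity summaries
#'
#' Fast, waveform-free cohort generator for exercising the DEE model stage:
#' per deployed bird it simulates the behavioural state sequence, converts it
#' to a daily time budget, builds daily activity-specific DBA as
#' budget x the scenario's per-state VeDBA rate (with multiplicative
#' lognormal scatter), and produces the DLW-measured msDEE by running the
#' full single-sample DLW chain (equilibrium-set regression included) on
#' isotope panels generated from the true DEE with the scenario's DLW noise.
#'
#' @param scenario A [sim_scenario()].
#' @param dba_cv Lognormal CV of per-activity daily DBA around its expected
#'   value (within-state waveform variability not resolved at minute level).
#' @return A list: `summaries` (one row per bird: `bird`, `sex`, `mass_g`,
#'   `t_col`..`t_rest`, `dba_col`..`dba_rest`, `dba_total`, `msdee`) ready
#'   for [fit_dee_model()], and `truth` (as in [simulate_cohort()]).
#' @examples
#' cs <- simulate_summary_cohort(sim_scenario(seed = 1, n_deployed_birds = 4,
#'                                            deployment_hours = c(4, 5)))
#' cs$summaries
#' @export
simulate_summary_cohort <- function(scenario, dba_cv = 0.1) {
  cohort <- simulate_cohort(scenario)
  res <- dlw_analyse(cohort$dlw)
  sp <- scenario$state_pars[match(.states, scenario$state_pars$state), ]
  n <- nrow(cohort$truth)
  dba <- withr::with_seed(derive_seed(scenario$seed, 13L), {
    sdlog <- sqrt(log(1 + dba_cv^2))
    tmat <- as.matrix(cohort$truth[c("t_col", "t_com", "t_for", "t_rest")])
    noise <- matrix(rlnorm(n * 4, -sdlog^2 / 2, sdlog), n, 4)
    tmat * 60 * rep(sp$dba_per_min, each = n) * noise
  })
  colnames(dba) <- c("dba_col", "dba_com", "dba_for", "dba_rest")
  summaries <- cohort$truth %>%
    select("bird", "sex", "mass_g", "t_col", "t_com", "t_for", "t_rest") %>%
    bind_cols(as_tibble(dba)) %>%
    mutate(dba_total = .data$dba_col + .data$dba_com + .data$dba_for +
             .data$dba_rest) %>%
    left_join(select(res, "bird", "msdee"), by = "bird")
  list(summaries = summaries, truth = cohort$truth)
}
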