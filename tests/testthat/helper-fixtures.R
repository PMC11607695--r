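# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# Full sensor-chain fixture: 3 deployed birds from the default scenario,
# 50 Hz waveforms -> minute features -> fitted HMM -> decoded states.
pipeline_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  sc <- sim_scenario(seed = 1)
  mins <- list()
  truths <- list()
  for (b in 1:3) {
    st <- simulate_states(sc, b)
    sb <- simulate_sensors(st, sc)
    mf <- minute_features(sb$accel, sb$depth, sb$gps, sc$colony,
                          wingbeat_stride_s = 30)
    mins[[b]] <- dplyr::mutate(mf, bird = b)
    truths[[b]] <- st$state[mf$minute + 1]
    rm(sb)
    gc(FALSE)
  }
  minutes <- dplyr::bind_rows(mins)
  truth <- factor(unlist(lapply(truths, as.character)),
                  levels = levels(truths[[1]]))
  fit <- hmm_fit(minutes, default_hmm_spec(), max_iter = 50, tol = 1e-5)
  decoded <- hmm_decode(fit, minutes)
  .fixture_env$fx <- list(scenario = sc, minutes = minutes, truth = truth,
                          fit = fit, decoded = decoded)
  .fixture_env$fx
}

# Identifiable models-level cohort: daily budgets drawn with realistic
# independent between-bird spread (commuting 1-6 h as observed ranges go,
# foraging and resting 0.2-2 h), daily DBA per activity proportional to
# time with 10% lognormal scatter, and msDEE built from a known rate
# vector with multiplicative lognormal noise.
designed_summaries <- function(n = 20, rates = NULL, noise_cv = 0.05,
                               seed = 1, dba_cv = 0.1) {
  if (is.null(rates)) {
    rates <- c(colony = 0.0325, commuting = 0.08775,
               foraging = 0.1495, resting = 0.0845)
  }
  dba_per_min <- c(colony = 4.5, commuting = 41, foraging = 48, resting = 10)
  withr::with_seed(seed, {
    t_com <- runif(n, 1, 6)
    t_for <- runif(n, 0.2, 2)
    t_rest <- runif(n, 0.2, 2)
    t_col <- 24 - t_com - t_for - t_rest
    tmat <- cbind(colony = t_col, commuting = t_com,
                  foraging = t_for, resting = t_rest)
    sdl_d <- sqrt(log(1 + dba_cv^2))
    dba <- tmat * 60 * rep(dba_per_min, each = n) *
      matrix(rlnorm(4 * n, -sdl_d^2 / 2, sdl_d), n, 4)
    msdee_true <- as.numeric(tmat %*% rates)
    sdl <- sqrt(log(1 + noise_cv^2))
    noise <- if (noise_cv > 0) rlnorm(n, -sdl^2 / 2, sdl) else rep(1, n)
    tibble::tibble(
      bird = sprintf("S%02d", seq_len(n)),
      mass_g = runif(n, 1200, 1800),
      t_col = t_col, t_com = t_com, t_for = t_for, t_rest = t_rest,
      dba_col = dba[, 1], dba_com = dba[, 2], dba_for = dba[, 3],
      dba_rest = dba[, 4],
      dba_total = rowSums(dba),
      msdee = msdee_true * noise,
      msdee_true = msdee_true
    )
  })
}

# small scenario for fast whole-pipeline runs; 8 deployed birds is the
# minimum that keeps the richest candidate design estimable (n >= k + 2)
reduced_scenario <- function(seed = 1, ...) {
  sim_scenario(seed = seed, n_equilibrium_birds = 5, n_deployed_birds = 8,
               deployment_hours = c(21, 23), ...)
}
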