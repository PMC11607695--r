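#' Simulate raw logger streams for one deployment
#'
#' Generates the three logger exports for a minute-level state sequence:
#' 50 Hz tri-axial acceleration (gravity on the heave axis plus a
#' state-specific sinusoidal flapping signature and Gaussian noise), 1 Hz
#' depth (rectangular plunge-dive pulses in foraging minutes only), and
#' 1-fix-per-minute GPS (track positions plus noise, with optional missing
#' fixes). The flapping waveform pauses during the submerged seconds of a
#' plunge.
#'
#' @param states Output of [simulate_states()].
#' @param scenario The same [sim_scenario()].
#' @return A list of class `sensor_bundle`: `accel` (tibble `t`, `ax`, `ay`,
#'   `az` in g), `depth` (tibble `t`, `depth_m`), `gps` (tibble `t`, `lon`,
#'   `lat`), plus `bird` and `start_time`. `t` is seconds from deployment
#'   start.
#' @examples
#' sc <- sim_scenario(seed = 1, deployment_hours = c(0.2, 0.2))
#' sb <- simulate_sensors(simulate_states(sc, 1), sc)
#' nrow(sb$accel) / nrow(sb$depth) # 50 Hz vs 1 Hz
#' @export
simulate_sensors <- function(states, scenario) {
  validate_scenario(scenario)
  if (scenario$accel_noise_sd_g < 0 || scenario$depth_noise_sd_m < 0) {
    abort("Noise standard deviations must be >= 0.")
  }
  fs <- 50L
  n_min <- nrow(states)
  st <- as.integer(states$state)
  sp <- scenario$state_pars[match(.states, scenario$state_pars$state), ]
  seed <- derive_seed(scenario$seed, 202L, states$bird[1])

  withr::with_seed(seed, {
    # per-minute waveform parameters
    amp <- sp$flap_amp_g[st]
    freq <- sp$wingbeat_hz[st]
    phase <- runif(n_min, 0, 2 * pi)

    # plunge dives: rectangular pulses in a subset of foraging minutes
    dive <- st == 3L & runif(n_min) < sp$dive_prob[3]
    dur <- ifelse(dive,
                  round(runif(n_min, scenario$dive_duration_s[1],
                              scenario$dive_duration_s[2])), 0)
    dur <- pmin(dur, 59)
    offset <- ifelse(dive, floor(runif(n_min, 0, 60 - dur)), 0)
    depth_val <- ifelse(dive,
                        runif(n_min, scenario$dive_depth_m[1],
                              scenario$dive_depth_m[2]), 0)

    # 50 Hz acceleration
    n_s <- n_min * 60L * fs
    tt <- (seq_len(n_s) - 1) / fs
    sec_in_min <- (tt %% 60)
    m_idx <- rep(seq_len(n_min), each = 60L * fs)
    submerged_acc <- dive[m_idx] & sec_in_min >= offset[m_idx] &
      sec_in_min < (offset[m_idx] + dur[m_idx])
    amp_s <- amp[m_idx] * !submerged_acc
    w <- 2 * pi * freq[m_idx] * tt + phase[m_idx]
    nz <- scenario$accel_noise_sd_g
    az <- 1 + amp_s * sin(w) +
      (if (nz > 0) rnorm(n_s, 0, nz) else 0)
    ax <- 0.25 * amp_s * sin(w + pi / 3) +
      (if (nz > 0) rnorm(n_s, 0, nz) else 0)
    ay <- 0.20 * amp_s * sin(w + 2 * pi / 3) +
      (if (nz > 0) rnorm(n_s, 0, nz) else 0)
    accel <- tibble(t = tt, ax = ax, ay = ay, az = az)

    # 1 Hz depth
    td <- seq_len(n_min * 60L) - 1
    sec_d <- td %% 60
    md <- td %/% 60 + 1L
    sub_d <- dive[md] & sec_d >= offset[md] & sec_d < (offset[md] + dur[md])
    depth <- depth_val[md] * sub_d +
      (if (scenario$depth_noise_sd_m > 0)
        rnorm(length(td), 0, scenario$depth_noise_sd_m) else 0)
    depth_tbl <- tibble(t = as.double(td), depth_m = depth)

    # 1-min GPS with optional gaps; first and last fixes always retained
    noise_deg <- scenario$gps_noise_m / 111195
    lon <- states$lon + (if (scenario$gps_noise_m > 0)
      rnorm(n_min, 0, noise_deg / cos(scenario$colony[["lat"]] * pi / 180))
      else 0)
    lat <- states$lat + (if (scenario$gps_noise_m > 0)
      rnorm(n_min, 0, noise_deg) else 0)
    keep <- runif(n_min) >= scenario$gps_gap_prob
    keep[c(1L, n_min)] <- TRUE
    gps <- tibble(t = states$t[keep], lon = lon[keep], lat = lat[keep])
  })

  structure(
    list(accel = accel, depth = depth_tbl, gps = gps,
         bird = states$bird[1], start_time = scenario$start_time),
    class = "sensor_bundle"
  )
}

#' @export
print.sensor_bundle <- function(x, ...) {
  cat(sprintf(
    "<sensor_bundle> bird %s: %d accel samples (50 Hz), %d depth samples (1 Hz), %d GPS fixes\n",
    x$bird, nrow(x$accel), nrow(x$depth), nrow(x$gps)))
  invisible(x)
}
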