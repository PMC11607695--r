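#' Simulate a bird's minute-level behavioural state sequence and track
#'
#' Draws a Markov-chain state sequence at 1-min resolution from the scenario's
#' transition matrix (with a per-bird lognormal multiplier on the colony
#' departure rate, the individual effort random effect) and lays down a
#' consistent planar track: colony minutes jitter within 0.2 km of the colony,
#' commuting minutes move at commuting speed along outbound/return legs, and
#' foraging/resting minutes drift locally. All at-sea minutes are kept at least
#' 1.05 km from the colony so the colony/at-sea geometry of the colony data
#' stream is unambiguous.
#'
#' @param scenario A [sim_scenario()].
#' @param bird_id Integer bird index (deterministic sub-seed).
#' @return A tibble with one row per minute: `bird`, `minute`, `t` (seconds
#'   from deployment start), `state` (factor over the four states), `x_km`,
#'   `y_km` (planar offsets from the colony), `lon`, `lat`. Attributes:
#'   `deployment_h`, `trip_multiplier`, `tpm_bird`.
#' @examples
#' st <- simulate_states(sim_scenario(seed = 1), bird_id = 1)
#' table(st$state)
#' @export
simulate_states <- function(scenario, bird_id) {
  validate_scenario(scenario)
  bird_id <- as.integer(bird_id)
  seed <- derive_seed(scenario$seed, 101L, bird_id)
  withr::with_seed(seed, {
    hours <- runif(1, scenario$deployment_hours[1], scenario$deployment_hours[2])
    mult <- rlnorm(1, 0, scenario$trip_rate_sdlog)
    tpm <- scenario$transition_matrix
    off <- tpm[1, -1] * mult
    if (sum(off) > 0.95) off <- off * 0.95 / sum(off)
    tpm[1, ] <- c(1 - sum(off), off)

    n_min <- max(1L, as.integer(round(hours * 60)))
    st <- integer(n_min)
    st[1] <- sample.int(4L, 1L, prob = scenario$initial_distribution)
    for (i in seq_len(n_min - 1L)) {
      st[i + 1L] <- sample.int(4L, 1L, prob = tpm[st[i], ])
    }
    pos <- simulate_track_km(st, scenario)
  })
  ll <- km_to_lonlat(pos[, 1], pos[, 2],
                     scenario$colony[["lon"]], scenario$colony[["lat"]])
  out <- tibble(
    bird = bird_id,
    minute = seq_len(n_min) - 1L,
    t = (seq_len(n_min) - 1L) * 60,
    state = factor(.states[st], levels = .states),
    x_km = pos[, 1],
    y_km = pos[, 2],
    lon = ll$lon,
    lat = ll$lat
  )
  attr(out, "deployment_h") <- hours
  attr(out, "trip_multiplier") <- mult
  attr(out, "tpm_bird") <- tpm
  out
}

# Planar track (km, colony at origin) consistent with an integer state
# sequence. Trips are modelled in polar coordinates around the colony: the
# first half of a trip's commuting minutes move radially outward at
# commuting speed, the second half move back inward, so every trip returns
# to the at-sea floor before the bird re-enters the colony; foraging and
# resting minutes drift tangentially at their localized rates; the bearing
# wanders slowly for 2-D realism. Called inside the bird's seeded RNG
# context.
simulate_track_km <- function(st, scenario) {
  n <- length(st)
  sp <- scenario$state_pars
  speed_km_min <- sp$speed_m_s[match(.states, sp$state)] * 60 / 1000
  drift_km_min <- sp$drift_m_min[match(.states, sp$state)] / 1000
  pos <- matrix(0, n, 2)
  is_col <- st == 1L

  # colony minutes: capped Gaussian jitter around the colony point
  n_col <- sum(is_col)
  if (n_col > 0) {
    jit <- matrix(rnorm(2 * n_col, 0, scenario$colony_jitter_km), ncol = 2)
    r <- sqrt(rowSums(jit^2))
    too_far <- r > 0.2
    jit[too_far, ] <- jit[too_far, ] * 0.2 / r[too_far]
    pos[is_col, ] <- jit
  }

  r_min <- 1.05 # km; at-sea floor keeps the colony stream unambiguous
  rl <- rle(is_col)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  for (b in seq_along(rl$values)) {
    if (rl$values[b]) next # colony block
    idx <- starts[b]:ends[b]
    stb <- st[idx]
    com <- stb == 2L
    m <- sum(com)
    radial <- numeric(length(idx))
    if (m > 0) {
      out_n <- ceiling(m / 2)
      radial[com] <- c(rep(speed_km_min[2], out_n),
                       rep(-speed_km_min[2], m - out_n))
    }
    th <- runif(1, 0, 2 * pi)
    wander_km <- rnorm(length(idx), 0, 0.3) # cross-track meander of flight
    d <- r_min
    for (j in seq_along(idx)) {
      s <- stb[j]
      if (s == 2L) {
        d <- d + radial[j]
        th <- th + wander_km[j] / max(d, r_min)
      } else {
        # localized tangential drift
        th <- th + sample(c(-1, 1), 1) * drift_km_min[s] / max(d, r_min)
      }
      d <- min(max(d, r_min), scenario$trip_max_km)
      pos[idx[j], ] <- d * c(cos(th), sin(th))
    }
  }
  pos
}
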