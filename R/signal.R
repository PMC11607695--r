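#' Vectorial dynamic body acceleration (VeDBA)
#'
#' Per-sample VeDBA from 50 Hz tri-axial acceleration:
#' \deqn{VeDBA = \sqrt{(A_x-\bar A_x)^2 + (A_y-\bar A_y)^2 + (A_z-\bar A_z)^2}}
#' where \eqn{\bar A_n} is the static (postural/gravitational) component of
#' each axis, a centered running mean over a 3 s window. Windows are
#' truncated at the record edges so every sample gets a value and minute
#' counts stay aligned with the depth and GPS grids.
#'
#' @param accel Data frame with columns `t` (seconds, strictly increasing at
#'   a nominal 50 Hz), `ax`, `ay`, `az` (g).
#' @param static_window_s Running-window length for the static component [s].
#' @return The input tibble with a `vedba` column (g).
#' @examples
#' acc <- tibble::tibble(t = (0:499) / 50, ax = 0, ay = 0, az = 1)
#' range(vedba_series(acc)$vedba) # 0: purely static signal
#' @export
vedba_series <- function(accel, static_window_s = 3) {
  df <- as_tibble(accel)
  if (!all(c("t", "ax", "ay", "az") %in% names(df))) {
    abort("`accel` needs columns t, ax, ay, az.")
  }
  bad <- which(diff(df$t) <= 0)
  if (length(bad) > 0) {
    abort(sprintf("Timestamps not strictly increasing: first offending index %d.",
                  bad[1] + 1L))
  }
  if (any(abs(df[c("ax", "ay", "az")]) >= 16, na.rm = TRUE)) {
    warn("Acceleration beyond +/-16 g: outside the sensor range guard.")
  }
  fs <- 1 / median(diff(df$t))
  half <- max(1L, as.integer(floor(static_window_s * fs / 2)))
  if (nrow(df) < 2 * half + 1) {
    abort("Record shorter than one full static window.")
  }
  dyn_x <- df$ax - run_mean_trunc(df$ax, half)
  dyn_y <- df$ay - run_mean_trunc(df$ay, half)
  dyn_z <- df$az - run_mean_trunc(df$az, half)
  df$vedba <- sqrt(dyn_x^2 + dyn_y^2 + dyn_z^2)
  df
}

# centered running mean with truncated windows at the edges
run_mean_trunc <- function(x, half) {
  n <- length(x)
  cs <- cumsum(x)
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
}

#' Smooth VeDBA to 1 s and sum per minute (DBA)
#'
#' Mean VeDBA over each second (smoothing), then the sum of the per-second
#' means over each calendar minute: the minute-level DBA stream. Minutes
#' with fewer than 60 populated seconds are flagged `partial`; a minute with
#' no data at all yields a missing DBA with the flag set.
#'
#' @param vedba Numeric VeDBA series (g), e.g. `vedba_series(...)$vedba`.
#' @param t Sample timestamps [s], same length.
#' @return A tibble per minute: `minute` (index, `floor(t/60)`), `dba`
#'   (g s), `n_seconds`, `partial`.
#' @examples
#' sm <- smooth_and_sum(rep(0.5, 50 * 60), (0:(50 * 60 - 1)) / 50)
#' sm$dba # 60 * 0.5
#' @export
smooth_and_sum <- function(vedba, t) {
  if (length(vedba) != length(t)) abort("`vedba` and `t` lengths differ.")
  sec <- vedba_seconds(vedba, t)
  sec %>%
    group_by(minute = .data$second %/% 60) %>%
    summarise(dba = sum(.data$vedba_1s), n_seconds = n(), .groups = "drop") %>%
    mutate(partial = .data$n_seconds < 60L)
}

#' Per-second mean VeDBA
#'
#' @param vedba Numeric VeDBA series (g).
#' @param t Sample timestamps [s].
#' @return A tibble: `second` (index, `floor(t)`), `vedba_1s` (mean over the
#'   second).
#' @export
vedba_seconds <- function(vedba, t) {
  tibble(second = as.integer(floor(t)), vedba = vedba) %>%
    group_by(.data$second) %>%
    summarise(vedba_1s = mean(.data$vedba), .groups = "drop")
}

#' Wingbeat frequency by FFT peak
#'
#' Dominant non-DC spectral frequency of the heave (z) axis over sliding
#' windows: the wingbeat-frequency data stream. Each window's value is the
#' frequency of the maximum-magnitude non-DC bin; an (all-but-)constant
#' window has no non-DC peak and returns 0 Hz with `flat = TRUE`.
#'
#' @param z Heave-axis acceleration (g) at `fs` Hz.
#' @param fs Sampling rate [Hz].
#' @param window_s Window length [s] (frequency resolution = 1/window_s Hz).
#' @param stride_s Window start spacing [s].
#' @return A tibble per window: `start_s`, `center_s`, `minute` (minute
#'   containing the window center), `freq_hz`, `flat`.
#' @examples
#' z <- sin(2 * pi * 5 * (0:(50 * 30 - 1)) / 50)
#' wingbeat_frequency(z)$freq_hz # 5 Hz
#' @export
wingbeat_frequency <- function(z, fs = 50, window_s = 30, stride_s = 1) {
  win <- as.integer(round(window_s * fs))
  if (length(z) < win) abort("Record shorter than one wingbeat window.")
  starts <- seq(1L, length(z) - win + 1L, by = max(1L, as.integer(round(stride_s * fs))))
  n_half <- win %/% 2
  freqs <- (seq_len(n_half)) / window_s # non-DC bins up to Nyquist
  out_f <- numeric(length(starts))
  out_flat <- logical(length(starts))
  # batch the FFTs via mvfft in memory-bounded chunks
  chunk <- 512L
  for (c0 in seq(1L, length(starts), by = chunk)) {
    idx <- c0:min(c0 + chunk - 1L, length(starts))
    m <- vapply(starts[idx], function(s) z[s:(s + win - 1L)], numeric(win))
    flat <- apply(m, 2, function(col) var(col) < 1e-20)
    mags <- Mod(mvfft(m))[2:(n_half + 1L), , drop = FALSE]
    peak <- apply(mags, 2, which.max)
    out_f[idx] <- ifelse(flat, 0, freqs[peak])
    out_flat[idx] <- flat
  }
  start_s <- (starts - 1L) / fs
  tibble(
    start_s = start_s,
    center_s = start_s + window_s / 2,
    minute = as.integer(floor((start_s + window_s / 2) / 60)),
    freq_hz = out_f,
    flat = out_flat
  )
}

#' Thin per-window wingbeat frequencies to one value per minute
#'
#' The per-minute value is the median (50th quantile) of all windows whose
#' center falls in that minute.
#'
#' @param windows Output of [wingbeat_frequency()].
#' @return A tibble: `minute`, `wingbeat_hz`.
#' @export
wingbeat_per_minute <- function(windows) {
  windows %>%
    group_by(.data$minute) %>%
    summarise(wingbeat_hz = median(.data$freq_hz), .groups = "drop")
}

#' Dive fraction per minute
#'
#' Proportion of time underwater in each 1-min window according to the 1 Hz
#' depth sensor: the fraction of samples deeper than the wet threshold
#' (e.g. not diving = 0, submerged 30 s of 60 = 0.5).
#'
#' @param depth Data frame with columns `t` (s) and `depth_m`.
#' @param wet_threshold_m Depth above which a sample counts as submerged
#'   [m]; default 0.1 m, the depth-sensor noise floor.
#' @return A tibble per minute: `minute`, `dive_frac`, `n_samples`.
#' @examples
#' d <- tibble::tibble(t = 0:59, depth_m = c(rep(2, 30), rep(0, 30)))
#' dive_fraction(d)$dive_frac # 0.5
#' @export
dive_fraction <- function(depth, wet_threshold_m = 0.1) {
  df <- as_tibble(depth)
  if (!all(c("t", "depth_m") %in% names(df))) {
    abort("`depth` needs columns t, depth_m.")
  }
  if (any(df$depth_m < -0.5, na.rm = TRUE)) {
    warn("Negative depths beyond the sensor noise band.")
  }
  df %>%
    group_by(minute = as.integer(.data$t %/% 60)) %>%
    summarise(dive_frac = mean(.data$depth_m > wet_threshold_m),
              n_samples = n(), .groups = "drop")
}

#' Interpolate a GPS track to a regular 1-min grid
#'
#' Positions at exact 60 s ticks from irregular fixes. The default is
#' piecewise-linear interpolation in time (deterministic and exactly
#' recovers constant-velocity motion); `method = "spline"` applies a natural
#' cubic spline through the fixes as a smoother for meandering tracks.
#' Minutes whose bracketing fixes are further apart than `max_gap_min` are
#' flagged `gap`.
#'
#' @param gps Data frame with columns `t` (s) and either `lon`, `lat`
#'   (decimal degrees) or `x_km`, `y_km` (planar offsets); >= 2 fixes.
#' @param method "linear" (default) or "spline".
#' @param max_gap_min Gap tolerance [min].
#' @return A tibble per tick: `t`, `minute`, interpolated coordinates, `gap`.
#' @export
interpolate_track <- function(gps, method = c("linear", "spline"),
                              max_gap_min = 10) {
  method <- match.arg(method)
  df <- as_tibble(gps)
  planar <- all(c("x_km", "y_km") %in% names(df))
  cn <- if (planar) c("x_km", "y_km") else c("lon", "lat")
  if (!all(c("t", cn) %in% names(df))) {
    abort("`gps` needs column t plus lon/lat or x_km/y_km.")
  }
  if (nrow(df) < 2) abort("Need >= 2 GPS fixes to interpolate.")
  df <- arrange(df, .data$t)
  ticks <- seq(ceiling(min(df$t) / 60) * 60, floor(max(df$t) / 60) * 60, by = 60)
  interp <- function(y) {
    if (method == "linear") {
      approx(df$t, y, xout = ticks)$y
    } else {
      spline(df$t, y, xout = ticks, method = "natural")$y
    }
  }
  # bracketing-fix spacing at each tick
  i_next <- findInterval(ticks, df$t, left.open = FALSE)
  i_next <- pmin(pmax(i_next, 1L), nrow(df) - 1L)
  spacing <- df$t[i_next + 1L] - df$t[i_next]
  out <- tibble(t = ticks, minute = as.integer(ticks %/% 60))
  out[[cn[1]]] <- interp(df[[cn[1]]])
  out[[cn[2]]] <- interp(df[[cn[2]]])
  out$interp_s <- spacing # spacing of the bracketing fixes
  out$gap <- spacing > max_gap_min * 60
  out
}

#' Step length and colony-presence streams
#'
#' From a regular 1-min track: `step_m`, the distance travelled between
#' consecutive 1-min positions (the displacement arriving at each minute's
#' fix, i.e. assigned to the later minute; the first minute is missing),
#' and the binary colony stream: 1 when the position is
#' within `r_in` km of the colony, 0 when beyond `r_out` km. The band
#' between the two radii is unclassified by the threshold rule; this
#' implementation assigns it 0 (at sea), a documented convention.
#'
#' @param track Output of [interpolate_track()] (lon/lat or planar km).
#' @param colony Named numeric `c(lon=, lat=)` or `c(x_km=0, y_km=0)`
#'   matching the track's coordinate kind.
#' @param r_in Colony radius [km]: distance <= r_in gives colony = 1.
#' @param r_out At-sea radius [km]: distance > r_out gives colony = 0.
#' @return The track tibble plus `dist_km` (distance to colony), `colony`
#'   and `step_m`.
#' @examples
#' tr <- tibble::tibble(t = c(0, 60), minute = 0:1,
#'                      lon = c(-78.9636, -78.9636), lat = c(-8.5447, -8.5411))
#' step_and_colony(tr, c(lon = -78.9636, lat = -8.5447))
#' @export
step_and_colony <- function(track, colony, r_in = 0.5, r_out = 1.0) {
  df <- as_tibble(track)
  planar <- all(c("x_km", "y_km") %in% names(df))
  if (planar) {
    cx <- colony[["x_km"]] %||% 0
    cy <- colony[["y_km"]] %||% 0
    d_km <- sqrt((df$x_km - cx)^2 + (df$y_km - cy)^2)
    stp <- c(NA_real_, sqrt(diff(df$x_km)^2 + diff(df$y_km)^2) * 1000)
  } else {
    p <- cbind(df$lon, df$lat)
    d_km <- gc_dist_m(p, cbind(colony[["lon"]], colony[["lat"]])) / 1000
    stp <- c(NA_real_,
             gc_dist_m(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE]))
  }
  df$dist_km <- d_km
  df$colony <- as.integer(d_km <= r_in) # band (r_in, r_out] and beyond -> 0
  df$step_m <- stp
  df
}

#' Build the per-minute observation table for one deployment
#'
#' Runs the whole signal stage: VeDBA (3 s static window) smoothed to 1 s
#' and summed per minute, wingbeat frequency (30 s FFT windows thinned to
#' the per-minute median), dive fraction, track interpolation to 1-min
#' ticks, and the step-length and colony streams; then joins everything on
#' the minute index.
#'
#' @param accel,depth,gps Logger tibbles as produced by
#'   [simulate_sensors()] (or read from `accel.csv` etc.).
#' @param colony Colony coordinates `c(lon=, lat=)`.
#' @param static_window_s,wingbeat_window_s,wingbeat_stride_s,wet_threshold_m,r_in,r_out,max_gap_min
#'   Signal constants; see the respective stream functions.
#' @return A tibble of minute records: `minute`, `colony`, `wingbeat_hz`,
#'   `dive_frac`, `step_m`, `dba`, plus QC flags (`partial`, `gap`).
#' @export
minute_features <- function(accel, depth, gps, colony,
                            static_window_s = 3,
                            wingbeat_window_s = 30,
                            wingbeat_stride_s = 1,
                            wet_threshold_m = 0.1,
                            r_in = 0.5, r_out = 1.0,
                            max_gap_min = 10) {
  v <- vedba_series(accel, static_window_s = static_window_s)
  dba <- smooth_and_sum(v$vedba, v$t)
  wb <- wingbeat_per_minute(
    wingbeat_frequency(v$az, fs = 1 / median(diff(v$t)),
                       window_s = wingbeat_window_s,
                       stride_s = wingbeat_stride_s))
  dv <- dive_fraction(depth, wet_threshold_m = wet_threshold_m)
  tr <- interpolate_track(gps, max_gap_min = max_gap_min)
  sc <- step_and_colony(tr, colony, r_in = r_in, r_out = r_out)
  # a step interpolated across a missing fix is imputation, not observation:
  # leave it missing so the classifier marginalizes it
  unobserved <- sc$interp_s > 90 | dplyr::lag(sc$interp_s, default = 0) > 90
  sc$step_m[unobserved] <- NA_real_
  dba %>%
    left_join(wb, by = "minute") %>%
    left_join(select(dv, "minute", "dive_frac"), by = "minute") %>%
    left_join(select(sc, "minute", "colony", "step_m", "gap"), by = "minute") %>%
    select("minute", "colony", "wingbeat_hz", "dive_frac", "step_m", "dba",
           "partial", "gap") %>%
    arrange(.data$minute)
}
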