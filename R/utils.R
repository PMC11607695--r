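# Internal helpers shared across modules.

# Deterministic per-task seed derived from a base seed and integer tags.
# Keeps every simulated bird reproducible independently of call order,
# and stays below .Machine$integer.max.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.double(seed) %% 2147483647
  for (tag in tags) {
    x <- (x * 48271 + as.double(tag) * 104729 + 12345) %% 2147483647
  }
  as.integer(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

is_row_stochastic <- function(mat, tol = 1e-12) {
  is.matrix(mat) && nrow(mat) == ncol(mat) &&
    all(mat >= -tol) && all(abs(rowSums(mat) - 1) <= tol)
}

# Stationary distribution of a row-stochastic matrix by eigen-analysis of
# the transpose (left eigenvector for eigenvalue 1).
stationary_distribution <- function(tpm) {
  e <- eigen(t(tpm))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# Great-circle distance in metres on a sphere of mean Earth radius.
# Inputs are matrices/vectors of lon, lat in decimal degrees.
gc_dist_m <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = 6371008.8)
}

# Local tangent-plane conversion between planar km offsets (x east, y north)
# around an anchor lon/lat and geographic coordinates. Adequate at the
# <100 km scale of foraging trips.
km_to_lonlat <- function(x_km, y_km, anchor_lon, anchor_lat) {
  m_per_deg_lat <- 6371008.8 * pi / 180
  m_per_deg_lon <- m_per_deg_lat * cos(anchor_lat * pi / 180)
  tibble(
    lon = anchor_lon + x_km * 1000 / m_per_deg_lon,
    lat = anchor_lat + y_km * 1000 / m_per_deg_lat
  )
}
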