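# Emission families for the per-minute data streams.
#
# Families are pluggable behind one interface: density, weighted M-step,
# mean, and simulation. Supports:
#   bernoulli - binary colony-presence stream, parameter p
#   zigamma   - zero-inflated gamma on [0, Inf): point mass p0 at 0 plus
#               gamma(shape, scale) on the positives (wingbeat Hz, step m)
#   zoibeta   - zero/one-inflated beta on [0, 1]: point masses p0 at 0 and
#               p1 at 1 plus beta(shape1, shape2) in between (dive fraction)

em_dens <- function(family, x, par) {
  d <- rep(1, length(x)) # missing values marginalize to density 1
  ok <- !is.na(x)
  xo <- x[ok]
  d[ok] <- switch(
    family,
    bernoulli = ifelse(xo > 0.5, par$p, 1 - par$p),
    zigamma = ifelse(xo == 0, par$p0,
                     (1 - par$p0) * dgamma(xo, shape = par$shape,
                                           scale = par$scale)),
    zoibeta = ifelse(xo == 0, par$p0,
                     ifelse(xo == 1, par$p1,
                            (1 - par$p0 - par$p1) *
                              dbeta(xo, par$shape1, par$shape2))),
    abort(sprintf("Unknown emission family '%s'.", family))
  )
  d
}

em_mean <- function(family, par) {
  switch(family,
         bernoulli = par$p,
         zigamma = (1 - par$p0) * par$shape * par$scale,
         zoibeta = par$p1 + (1 - par$p0 - par$p1) *
           par$shape1 / (par$shape1 + par$shape2))
}

em_sim <- function(family, n, par) {
  switch(
    family,
    bernoulli = rbinom(n, 1, par$p),
    zigamma = ifelse(runif(n) < par$p0, 0,
                     rgamma(n, shape = par$shape, scale = par$scale)),
    zoibeta = {
      u <- runif(n)
      ifelse(u < par$p0, 0,
             ifelse(u < par$p0 + par$p1, 1,
                    stats::rbeta(n, par$shape1, par$shape2)))
    })
}

# Weighted maximum-likelihood M-step for one state and stream. Falls back
# to the old parameters (pinned, with a warning upstream) when the data are
# degenerate, and never returns a parameter set with lower weighted
# log-likelihood than `old` (generalized-EM safeguard).
em_fit <- function(family, x, w, old) {
  ok <- !is.na(x) & w > 0
  x <- x[ok]; w <- w[ok]
  if (length(x) == 0 || sum(w) <= 0) return(list(par = old, pinned = TRUE))
  new <- switch(
    family,
    bernoulli = list(p = clamp(sum(w * (x > 0.5)) / sum(w), 1e-6, 1 - 1e-6)),
    zigamma = {
      p0 <- clamp(sum(w[x == 0]) / sum(w), 0, 1 - 1e-6)
      pos <- x > 0
      if (sum(pos) >= 2 && sd(x[pos]) > 0) {
        g <- gamma_wmle(x[pos], w[pos])
        list(p0 = p0, shape = g$shape, scale = g$scale)
      } else {
        structure(list(p0 = p0, shape = old$shape, scale = old$scale),
                  pinned = TRUE)
      }
    },
    zoibeta = {
      p0 <- sum(w[x == 0]) / sum(w)
      p1 <- sum(w[x == 1]) / sum(w)
      p0 <- clamp(p0, 0, 1 - 1e-6); p1 <- clamp(p1, 0, 1 - 1e-6 - p0)
      int <- x > 0 & x < 1
      if (sum(int) >= 2 && sd(x[int]) > 0) {
        b <- beta_wmle(x[int], w[int], old)
        list(p0 = p0, p1 = p1, shape1 = b$shape1, shape2 = b$shape2)
      } else {
        structure(list(p0 = p0, p1 = p1, shape1 = old$shape1,
                       shape2 = old$shape2), pinned = TRUE)
      }
    })
  pinned <- isTRUE(attr(new, "pinned"))
  attr(new, "pinned") <- NULL
  # GEM safeguard: keep whichever parameter set has the higher weighted loglik
  ll <- function(par) sum(w * log(pmax(em_dens(family, x, par), 1e-300)))
  if (ll(new) + 1e-12 < ll(old)) new <- old
  list(par = new, pinned = pinned)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Weighted gamma MLE via Newton on the shape (exact M-step maximizer).
gamma_wmle <- function(x, w, max_iter = 25) {
  wm <- sum(w * x) / sum(w)
  wlm <- sum(w * log(x)) / sum(w)
  s <- log(wm) - wlm
  if (!is.finite(s) || s <= 1e-12) {
    # (near-)degenerate spread: method-of-moments cap
    v <- sum(w * (x - wm)^2) / sum(w)
    a <- if (v > 0) min(wm^2 / v, 1e6) else 1e6
    return(list(shape = a, scale = wm / a))
  }
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in seq_len(max_iter)) {
    step <- (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-10 * a) { a <- a_new; break }
    a <- a_new
  }
  a <- clamp(a, 1e-3, 1e6)
  list(shape = a, scale = wm / a)
}

# Weighted beta MLE by quasi-Newton on log-parameters.
beta_wmle <- function(x, w, old) {
  nll <- function(p) {
    s1 <- exp(p[1]); s2 <- exp(p[2])
    -sum(w * dbeta(x, s1, s2, log = TRUE))
  }
  wm <- sum(w * x) / sum(w)
  wv <- max(sum(w * (x - wm)^2) / sum(w), 1e-6)
  c0 <- max(wm * (1 - wm) / wv - 1, 0.1)
  start <- log(c(max(wm * c0, 1e-2), max((1 - wm) * c0, 1e-2)))
  fit <- tryCatch(
    stats::optim(start, nll, method = "BFGS", control = list(maxit = 100)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) {
    return(list(shape1 = old$shape1, shape2 = old$shape2))
  }
  list(shape1 = clamp(exp(fit$par[1]), 1e-3, 1e6),
       shape2 = clamp(exp(fit$par[2]), 1e-3, 1e6))
}

#' Construct a hidden Markov model specification
#'
#' A four-state (or smaller, for testing) HMM over the per-minute data
#' streams. Streams are conditionally independent given the state; each
#' stream has one emission family and per-state parameters. DBA is
#' deliberately not a stream: classification uses colony presence, wingbeat
#' frequency, dive fraction and step length only, and DBA is joined to
#' decoded states afterwards.
#'
#' @param states Character vector of state names (default the four
#'   behavioural states).
#' @param emissions Named list (one element per stream). Each element is
#'   `list(family = , pars = )` where `family` is "bernoulli", "zigamma" or
#'   "zoibeta" and `pars` is a list of per-state parameter lists (same order
#'   as `states`).
#' @param tpm Row-stochastic transition matrix (rows sum to 1 within 1e-10).
#' @param delta Initial state distribution (resets at each bird's record
#'   boundary).
#' @return An object of class `hmm_spec`.
#' @examples
#' sp <- default_hmm_spec()
#' sp$states
#' @export
hmm_spec <- function(states = .states, emissions, tpm, delta) {
  sp <- structure(
    list(states = states, emissions = emissions, tpm = tpm, delta = delta),
    class = "hmm_spec")
  validate_hmm_spec(sp)
  sp
}

#' Validate an HMM specification
#'
#' Collects every violation (non-stochastic transition rows, invalid
#' probabilities, non-positive distribution parameters, wrong parameter
#' counts) and aborts listing all of them.
#'
#' @param spec An `hmm_spec`.
#' @return The spec, invisibly.
#' @export
validate_hmm_spec <- function(spec) {
  bad <- character()
  S <- length(spec$states)
  tpm <- spec$tpm
  if (!is.matrix(tpm) || nrow(tpm) != S || ncol(tpm) != S) {
    bad <- c(bad, sprintf("tpm must be %dx%d", S, S))
  } else if (!is_row_stochastic(tpm, tol = 1e-10)) {
    bad <- c(bad, "tpm rows must sum to 1 within 1e-10 with entries >= 0")
  }
  if (length(spec$delta) != S || any(spec$delta < 0) ||
      abs(sum(spec$delta) - 1) > 1e-10) {
    bad <- c(bad, "delta must be a probability vector over the states")
  }
  for (nm in names(spec$emissions)) {
    em <- spec$emissions[[nm]]
    if (!em$family %in% c("bernoulli", "zigamma", "zoibeta")) {
      bad <- c(bad, sprintf("stream '%s': unknown family '%s'", nm, em$family))
      next
    }
    if (length(em$pars) != S) {
      bad <- c(bad, sprintf("stream '%s': need %d per-state parameter sets", nm, S))
      next
    }
    for (s in seq_len(S)) {
      p <- em$pars[[s]]
      probs <- unlist(p[intersect(names(p), c("p", "p0", "p1"))])
      if (any(probs < 0 | probs > 1)) {
        bad <- c(bad, sprintf("stream '%s' state %s: probabilities outside [0,1]", nm, spec$states[s]))
      }
      if (em$family == "zoibeta" && (p$p0 + p$p1) > 1) {
        bad <- c(bad, sprintf("stream '%s' state %s: p0 + p1 > 1", nm, spec$states[s]))
      }
      shp <- unlist(p[intersect(names(p), c("shape", "scale", "shape1", "shape2"))])
      if (any(shp <= 0)) {
        bad <- c(bad, sprintf("stream '%s' state %s: non-positive distribution parameters", nm, spec$states[s]))
      }
    }
  }
  if (length(bad) > 0) {
    abort(paste0("Invalid hmm_spec:\n", paste("-", bad, collapse = "\n")))
  }
  invisible(spec)
}

#' Default four-state HMM starting specification
#'
#' Starting values for fitting the behavioural classifier. These are
#' package defaults chosen to be plausible for a plunge-diving seabird
#' (colony presence nearly deterministic per state; commuting wingbeat
#' around 5 Hz; plunge dives only in foraging; commuting steps around
#' 600 m per minute), not estimates from any field dataset.
#'
#' @param tpm Starting transition matrix.
#' @return An `hmm_spec`.
#' @export
default_hmm_spec <- function(tpm = default_transition_matrix()) {
  gam <- function(mean, sd) list(shape = (mean / sd)^2, scale = sd^2 / mean)
  zg <- function(p0, mean, sd) c(list(p0 = p0), gam(mean, sd))
  hmm_spec(
    states = .states,
    emissions = list(
      colony = list(
        family = "bernoulli",
        pars = list(list(p = 0.99), list(p = 0.01), list(p = 0.01),
                    list(p = 0.01))),
      wingbeat_hz = list(
        family = "zigamma",
        pars = list(zg(0.01, 12, 7), zg(0.01, 5, 0.5), zg(0.01, 5.5, 1),
                    zg(0.05, 0.5, 0.4))),
      dive_frac = list(
        family = "zoibeta",
        pars = list(
          list(p0 = 0.995, p1 = 1e-4, shape1 = 2, shape2 = 20),
          list(p0 = 0.99, p1 = 1e-4, shape1 = 2, shape2 = 20),
          list(p0 = 0.3, p1 = 1e-3, shape1 = 2, shape2 = 10),
          list(p0 = 0.99, p1 = 1e-4, shape1 = 2, shape2 = 20))),
      step_m = list(
        family = "zigamma",
        pars = list(zg(0.01, 90, 50), zg(0.001, 600, 60), zg(0.01, 120, 60),
                    zg(0.01, 40, 25)))
    ),
    tpm = tpm,
    delta = stationary_distribution(tpm)
  )
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat(sprintf("<hmm_spec> %d states (%s), %d streams (%s)\n",
              length(x$states), paste(x$states, collapse = ", "),
              length(x$emissions), paste(names(x$emissions), collapse = ", ")))
  invisible(x)
}
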