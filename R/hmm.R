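# Forward/backward, EM fitting, Viterbi decoding and simulation for the
# four-state behavioural HMM over per-minute data streams.

# n x S matrix of per-minute state-conditional emission densities.
# Streams multiply (conditional independence given state); missing values
# marginalize to 1. Floored at 1e-300 against underflow.
emission_matrix <- function(spec, minutes) {
  S <- length(spec$states)
  n <- nrow(minutes)
  dens <- matrix(1, n, S)
  for (nm in names(spec$emissions)) {
    if (!nm %in% names(minutes)) {
      abort(sprintf("Stream '%s' missing from `minutes`.", nm))
    }
    em <- spec$emissions[[nm]]
    x <- minutes[[nm]]
    for (s in seq_len(S)) {
      dens[, s] <- dens[, s] * em_dens(em$family, x, em$pars[[s]])
    }
  }
  pmax(dens, 1e-300)
}

# record boundaries: list of row-index vectors, one per bird (delta resets)
record_index <- function(minutes) {
  if ("bird" %in% names(minutes)) {
    split(seq_len(nrow(minutes)), minutes$bird)
  } else {
    list(seq_len(nrow(minutes)))
  }
}

# scaled forward pass for one record; returns loglik, scaled alpha, scales
forward_scaled <- function(dens, tpm, delta) {
  n <- nrow(dens); S <- ncol(dens)
  alpha <- matrix(0, n, S)
  cvec <- numeric(n)
  a <- delta * dens[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  if (n > 1) {
    for (i in 2:n) {
      a <- (alpha[i - 1, ] %*% tpm) * dens[i, ]
      cvec[i] <- sum(a)
      alpha[i, ] <- a / cvec[i]
    }
  }
  list(loglik = sum(log(cvec)), alpha = alpha, scales = cvec)
}

backward_scaled <- function(dens, tpm, scales) {
  n <- nrow(dens); S <- ncol(dens)
  beta <- matrix(0, n, S)
  beta[n, ] <- 1 / scales[n]
  if (n > 1) {
    for (i in (n - 1):1) {
      beta[i, ] <- (tpm %*% (dens[i + 1, ] * beta[i + 1, ])) / scales[i]
    }
  }
  beta
}

#' Forward-algorithm log-likelihood
#'
#' Scaled forward recursion over the per-minute observation table. When a
#' `bird` column is present the initial distribution resets at each bird's
#' record boundary and per-record log-likelihoods add.
#'
#' @param spec A validated [hmm_spec()].
#' @param minutes Data frame with one column per stream named in the spec
#'   (missing values are marginalized out) and optionally `bird`.
#' @return The log-likelihood (scalar).
#' @examples
#' sp <- default_hmm_spec()
#' sim <- hmm_simulate(sp, n_minutes = 100, seed = 1)
#' hmm_loglik(sp, sim$minutes)
#' @export
hmm_loglik <- function(spec, minutes) {
  validate_hmm_spec(spec)
  minutes <- as_tibble(minutes)
  dens <- emission_matrix(spec, minutes)
  sum(vapply(record_index(minutes), function(idx) {
    forward_scaled(dens[idx, , drop = FALSE], spec$tpm, spec$delta)$loglik
  }, numeric(1)))
}

#' Fit the HMM by Baum-Welch EM
#'
#' Expectation-maximization with weighted emission updates: forward-backward
#' posteriors, closed-form transition and initial-distribution updates, and
#' exact weighted maximum-likelihood emission updates per stream and state
#' (with a generalized-EM safeguard so the log-likelihood never decreases).
#' Streams with degenerate data in a state keep their starting parameters
#' (pinned) with a warning. Iteration stops when the relative log-likelihood
#' change drops below `tol`.
#'
#' @param minutes Observation table (see [hmm_loglik()]).
#' @param starting_spec Starting [hmm_spec()] (e.g. [default_hmm_spec()]).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @return An object of class `hmm_fit`: `spec` (fitted), `loglik`,
#'   `trace` (per-iteration log-likelihood), `converged`, `n_minutes`.
#' @examples
#' sp <- default_hmm_spec()
#' sim <- hmm_simulate(sp, n_minutes = 300, seed = 1)
#' fit <- hmm_fit(sim$minutes, sp, max_iter = 5)
#' fit$loglik
#' @export
hmm_fit <- function(minutes, starting_spec, max_iter = 100, tol = 1e-6) {
  validate_hmm_spec(starting_spec)
  minutes <- as_tibble(minutes)
  spec <- starting_spec
  S <- length(spec$states)
  recs <- record_index(minutes)
  trace <- numeric(0)
  pinned_msgs <- character(0)
  ll_old <- -Inf
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    dens <- emission_matrix(spec, minutes)
    post <- matrix(0, nrow(minutes), S)
    xi_sum <- matrix(0, S, S)
    delta_sum <- numeric(S)
    ll <- 0
    for (idx in recs) {
      d <- dens[idx, , drop = FALSE]
      fw <- forward_scaled(d, spec$tpm, spec$delta)
      bw <- backward_scaled(d, spec$tpm, fw$scales)
      ll <- ll + fw$loglik
      g <- fw$alpha * bw * fw$scales # posterior state probabilities
      g <- g / rowSums(g)
      post[idx, ] <- g
      n <- length(idx)
      if (n > 1) {
        for (i in 1:(n - 1)) {
          xi <- (fw$alpha[i, ] %o% (d[i + 1, ] * bw[i + 1, ])) * spec$tpm
          xi_sum <- xi_sum + xi / sum(xi)
        }
      }
      delta_sum <- delta_sum + g[1, ]
    }
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll

    # M-step
    tpm_new <- xi_sum / rowSums(xi_sum)
    tpm_new[!is.finite(tpm_new)] <- 1 / S
    tpm_new <- tpm_new / rowSums(tpm_new)
    dimnames(tpm_new) <- dimnames(spec$tpm)
    spec$tpm <- tpm_new
    spec$delta <- delta_sum / sum(delta_sum)
    for (nm in names(spec$emissions)) {
      em <- spec$emissions[[nm]]
      for (s in seq_len(S)) {
        res <- em_fit(em$family, minutes[[nm]], post[, s], em$pars[[s]])
        if (res$pinned) {
          pinned_msgs <- unique(c(pinned_msgs, sprintf(
            "stream '%s' state '%s': degenerate data, parameters pinned",
            nm, spec$states[s])))
        }
        spec$emissions[[nm]]$pars[[s]] <- res$par
      }
    }
  }
  if (length(pinned_msgs) > 0) warn(paste(pinned_msgs, collapse = "; "))

  structure(
    list(spec = spec, loglik = trace[length(trace)], trace = trace,
         converged = converged, n_minutes = nrow(minutes),
         n_iter = length(trace)),
    class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> %d states, loglik %.2f after %d EM iterations (%s)\n",
              length(x$spec$states), x$loglik, x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Viterbi decoding of behavioural states
#'
#' Maximum a-posteriori state path per bird record, with ties broken toward
#' the lower state index. Minutes with every stream missing carry no
#' emission information; their state is imputed purely from the transition
#' structure and flagged `imputed`. The smoothing posterior probability of
#' the decoded state is reported per minute.
#'
#' @param fit An [hmm_fit()] (or an `hmm_spec` to decode with known
#'   parameters).
#' @param minutes Observation table (see [hmm_loglik()]).
#' @return A tibble: `bird` (if present), `minute` (if present), `state`
#'   (factor over the spec's states), `posterior` (smoothing probability of
#'   the decoded state), `imputed`.
#' @export
hmm_decode <- function(fit, minutes) {
  spec <- if (inherits(fit, "hmm_fit")) fit$spec else fit
  validate_hmm_spec(spec)
  minutes <- as_tibble(minutes)
  S <- length(spec$states)
  dens <- emission_matrix(spec, minutes)
  all_missing <- rowSums(is.na(minutes[names(spec$emissions)])) ==
    length(spec$emissions)
  path <- integer(nrow(minutes))
  postmax <- numeric(nrow(minutes))
  ltpm <- log(pmax(spec$tpm, 1e-300))
  for (idx in record_index(minutes)) {
    d <- log(dens[idx, , drop = FALSE])
    n <- length(idx)
    v <- matrix(-Inf, n, S)
    bp <- matrix(1L, n, S)
    v[1, ] <- log(pmax(spec$delta, 1e-300)) + d[1, ]
    if (n > 1) {
      for (i in 2:n) {
        cand <- v[i - 1, ] + ltpm # S x S: from x to
        bp[i, ] <- apply(cand, 2, which.max) # first max = lower index tie-break
        v[i, ] <- cand[cbind(bp[i, ], seq_len(S))] + d[i, ]
      }
    }
    p <- integer(n)
    p[n] <- which.max(v[n, ])
    if (n > 1) for (i in (n - 1):1) p[i] <- bp[i + 1, p[i + 1]]
    path[idx] <- p
    fw <- forward_scaled(exp(d), spec$tpm, spec$delta)
    bw <- backward_scaled(exp(d), spec$tpm, fw$scales)
    g <- fw$alpha * bw * fw$scales
    g <- g / rowSums(g)
    postmax[idx] <- g[cbind(seq_len(n), p)]
  }
  out <- tibble(
    state = factor(spec$states[path], levels = spec$states),
    posterior = postmax,
    imputed = all_missing
  )
  if ("bird" %in% names(minutes)) out <- bind_cols(tibble(bird = minutes$bird), out)
  if ("minute" %in% names(minutes)) {
    out <- bind_cols(tibble(minute = minutes$minute), out)
  }
  out
}

#' Simulate minute records from an HMM specification
#'
#' Draws a state path from the transition matrix and initial distribution,
#' then one value per stream from the state's emission distribution: the
#' test harness for the classifier.
#'
#' @param spec An [hmm_spec()].
#' @param n_minutes Number of minutes.
#' @param seed Optional integer seed.
#' @return A list: `minutes` (tibble, one column per stream plus `minute`)
#'   and `states` (true state factor).
#' @export
hmm_simulate <- function(spec, n_minutes, seed = NULL) {
  validate_hmm_spec(spec)
  draw <- function() {
    S <- length(spec$states)
    st <- integer(n_minutes)
    st[1] <- sample.int(S, 1, prob = spec$delta)
    if (n_minutes > 1) {
      for (i in 2:n_minutes) {
        st[i] <- sample.int(S, 1, prob = spec$tpm[st[i - 1], ])
      }
    }
    cols <- lapply(names(spec$emissions), function(nm) {
      em <- spec$emissions[[nm]]
      x <- numeric(n_minutes)
      for (s in seq_len(S)) {
        k <- st == s
        if (any(k)) x[k] <- em_sim(em$family, sum(k), em$pars[[s]])
      }
      x
    })
    names(cols) <- names(spec$emissions)
    list(minutes = bind_cols(tibble(minute = seq_len(n_minutes) - 1L),
                             as_tibble(cols)),
         states = factor(spec$states[st], levels = spec$states))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Align decoded states to ground truth by maximum overlap
#'
#' Decoded state labels are only identified up to permutation; before
#' computing accuracy the decoded labels are mapped to the truth by the
#' permutation maximizing total overlap (exhaustive over permutations -
#' the state set is small).
#'
#' @param decoded,truth Factors of equal length over the same number of
#'   levels.
#' @return A list: `accuracy` (proportion of minutes matching after
#'   alignment), `permutation` (decoded level -> truth level mapping).
#' @export
align_states <- function(decoded, truth) {
  ld <- levels(decoded); lt <- levels(truth)
  if (length(ld) > 6) abort("Exhaustive alignment supports up to 6 states.")
  perms <- perm_all(length(ld))
  tab <- table(decoded, truth)
  best <- 0; best_p <- seq_along(ld)
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    hits <- sum(tab[cbind(seq_along(ld), p)])
    if (hits > best) { best <- hits; best_p <- p }
  }
  list(accuracy = best / length(decoded),
       permutation = setNames(lt[best_p], ld))
}

perm_all <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_all(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1)))
  }
  out
}
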