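# small helper specs used across the HMM tests

two_state_spec <- function(p1 = 0.95, p2 = 0.05, mean1 = 2, mean2 = 20,
                           tpm = rbind(c(0.9, 0.1), c(0.2, 0.8)),
                           delta = c(0.5, 0.5)) {
  hmm_spec(
    states = c("A", "B"),
    emissions = list(
      colony = list(family = "bernoulli", pars = list(list(p = p1),
                                                      list(p = p2))),
      step_m = list(family = "zigamma",
                    pars = list(list(p0 = 0.01, shape = 4, scale = mean1 / 4),
                                list(p0 = 0.01, shape = 4, scale = mean2 / 4)))
    ),
    tpm = tpm, delta = delta)
}

# brute-force likelihood by exhaustive path enumeration (independent oracle)
brute_force_loglik <- function(spec, minutes) {
  S <- length(spec$states)
  n <- nrow(minutes)
  dens <- matrix(1, n, S)
  for (nm in names(spec$emissions)) {
    em <- spec$emissions[[nm]]
    for (s in seq_len(S)) {
      x <- minutes[[nm]]
      d <- rep(1, n)
      ok <- !is.na(x)
      d[ok] <- switch(em$family,
        bernoulli = ifelse(x[ok] > 0.5, em$pars[[s]]$p, 1 - em$pars[[s]]$p),
        zigamma = ifelse(x[ok] == 0, em$pars[[s]]$p0,
                         (1 - em$pars[[s]]$p0) *
                           dgamma(x[ok], em$pars[[s]]$shape,
                                  scale = em$pars[[s]]$scale)))
      dens[, s] <- dens[, s] * d
    }
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    lik <- spec$delta[p[1]] * dens[1, p[1]]
    if (n > 1) for (j in 2:n) {
      lik <- lik * spec$tpm[p[j - 1], p[j]] * dens[j, p[j]]
    }
    total <- total + lik
  }
  log(total)
}
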