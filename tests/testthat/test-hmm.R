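test_that("a single-state Bernoulli model has the closed-form likelihood", {
  spec <- hmm_spec(states = "only",
                   emissions = list(colony = list(family = "bernoulli",
                                                  pars = list(list(p = 0.5)))),
                   tpm = matrix(1, 1, 1), delta = 1)
  minutes <- tibble::tibble(colony = c(1, 0, 1, 1, 0, 0, 1))
  expect_equal(hmm_loglik(spec, minutes), 7 * log(0.5), tolerance = 1e-12)
})

test_that("the forward likelihood is invariant to a joint state relabelling", {
  spec <- two_state_spec()
  sim <- hmm_simulate(spec, 200, seed = 5)
  ll <- hmm_loglik(spec, sim$minutes)
  perm <- c(2, 1)
  spec_p <- hmm_spec(
    states = spec$states[perm],
    emissions = lapply(spec$emissions, function(em)
      list(family = em$family, pars = em$pars[perm])),
    tpm = spec$tpm[perm, perm], delta = spec$delta[perm])
  expect_equal(hmm_loglik(spec_p, sim$minutes), ll, tolerance = 1e-12)
})

test_that("the forward likelihood equals exhaustive path enumeration", {
  three_state <- hmm_spec(
    states = c("A", "B", "C"),
    emissions = list(
      colony = list(family = "bernoulli",
                    pars = list(list(p = 0.9), list(p = 0.4), list(p = 0.1))),
      step_m = list(family = "zigamma",
                    pars = list(list(p0 = 0.1, shape = 2, scale = 1),
                                list(p0 = 0.01, shape = 3, scale = 5),
                                list(p0 = 0.5, shape = 5, scale = 20)))),
    tpm = rbind(c(0.7, 0.2, 0.1), c(0.3, 0.4, 0.3), c(0.05, 0.15, 0.8)),
    delta = c(0.6, 0.3, 0.1))
  for (seed in 1:3) {
    sim <- hmm_simulate(three_state, 6, seed = seed)
    sim$minutes$step_m[2] <- NA # missing values marginalize
    expect_equal(hmm_loglik(three_state, sim$minutes),
                 brute_force_loglik(three_state, sim$minutes),
                 tolerance = 1e-10)
  }
  spec2 <- two_state_spec()
  sim2 <- hmm_simulate(spec2, 8, seed = 9)
  expect_equal(hmm_loglik(spec2, sim2$minutes),
               brute_force_loglik(spec2, sim2$minutes), tolerance = 1e-10)
})

test_that("an invalid specification is rejected with the violations listed", {
  expect_error(
    hmm_spec(states = c("A", "B"),
             emissions = list(colony = list(family = "bernoulli",
                                            pars = list(list(p = 1.5),
                                                        list(p = 0.5)))),
             tpm = rbind(c(0.9, 0.2), c(0.2, 0.8)), delta = c(0.5, 0.5)),
    "probabilities outside|sum to 1")
})

test_that("EM recovers transitions and emission means from simulated data", {
  truth <- two_state_spec(p1 = 0.9, p2 = 0.05, mean1 = 3, mean2 = 30)
  sim <- hmm_simulate(truth, 5000, seed = 11)
  start <- two_state_spec(p1 = 0.7, p2 = 0.2, mean1 = 5, mean2 = 20,
                          tpm = rbind(c(0.7, 0.3), c(0.3, 0.7)))
  fit <- hmm_fit(sim$minutes, start, max_iter = 200, tol = 1e-8)
  expect_true(all(diff(fit$trace) >= -1e-6)) # EM monotonicity
  expect_lt(max(abs(fit$spec$tpm - truth$tpm)), 0.05)
  for (nm in names(truth$emissions)) {
    for (s in 1:2) {
      m_true <- plungedee:::em_mean(truth$emissions[[nm]]$family,
                                    truth$emissions[[nm]]$pars[[s]])
      m_fit <- plungedee:::em_mean(fit$spec$emissions[[nm]]$family,
                                   fit$spec$emissions[[nm]]$pars[[s]])
      expect_lt(abs(m_fit - m_true) / m_true, 0.10)
    }
  }
  # starting at the generating spec still never decreases the loglik
  fit2 <- hmm_fit(sim$minutes, truth, max_iter = 20, tol = 0)
  expect_true(all(diff(fit2$trace) >= -1e-6))
  # identical starts give identical fits
  fit3 <- hmm_fit(sim$minutes, start, max_iter = 200, tol = 1e-8)
  expect_identical(fit$spec, fit3$spec)
})

test_that("decoding is exact when emissions do not overlap", {
  spec <- two_state_spec(p1 = 0.999, p2 = 0.001, mean1 = 2, mean2 = 200)
  sim <- hmm_simulate(spec, 500, seed = 13)
  dec <- hmm_decode(spec, sim$minutes)
  expect_equal(as.character(dec$state), as.character(sim$states))
})

test_that("the Viterbi path beats 1000 random paths in joint likelihood", {
  spec <- two_state_spec()
  sim <- hmm_simulate(spec, 40, seed = 17)
  dec <- hmm_decode(spec, sim$minutes)
  dens <- log(plungedee:::emission_matrix(spec, sim$minutes))
  path_ll <- function(p) {
    ll <- log(spec$delta[p[1]]) + dens[1, p[1]]
    for (j in 2:length(p)) {
      ll <- ll + log(spec$tpm[p[j - 1], p[j]]) + dens[j, p[j]]
    }
    ll
  }
  v <- path_ll(as.integer(dec$state))
  rand <- withr::with_seed(1, {
    vapply(1:1000, function(i) path_ll(sample(1:2, 40, replace = TRUE)),
           numeric(1))
  })
  expect_true(all(v >= rand))
})

test_that("simulation matches its transition matrix and degenerate emissions", {
  spec <- two_state_spec()
  sim <- hmm_simulate(spec, 100000, seed = 19)
  st <- as.integer(sim$states)
  for (i in 1:2) {
    from <- which(st[-length(st)] == i)
    n_i <- length(from)
    for (j in 1:2) {
      p_hat <- mean(st[from + 1] == j)
      se <- sqrt(spec$tpm[i, j] * (1 - spec$tpm[i, j]) / n_i)
      expect_lt(abs(p_hat - spec$tpm[i, j]), 3 * se + 1e-9)
    }
  }
  # Bernoulli p = 1 emits all ones
  spec1 <- two_state_spec(p1 = 1, p2 = 0)
  sim1 <- hmm_simulate(spec1, 500, seed = 23)
  expect_true(all(sim1$minutes$colony[sim1$states == "A"] == 1))
  expect_true(all(sim1$minutes$colony[sim1$states == "B"] == 0))
  # fixed-seed reproducibility
  expect_identical(hmm_simulate(spec, 50, seed = 29),
                   hmm_simulate(spec, 50, seed = 29))
})

test_that("the scaled forward recursion stays finite on very long records", {
  spec <- two_state_spec()
  sim <- hmm_simulate(spec, 100000, seed = 31)
  ll <- hmm_loglik(spec, sim$minutes)
  expect_true(is.finite(ll))
  expect_lt(ll, 0)
})

test_that("all-missing minutes are imputed from the transition structure and flagged", {
  spec <- two_state_spec()
  sim <- hmm_simulate(spec, 30, seed = 37)
  sim$minutes$colony[10:12] <- NA
  sim$minutes$step_m[10:12] <- NA
  dec <- hmm_decode(spec, sim$minutes)
  expect_true(all(dec$imputed[10:12]))
  expect_false(any(dec$imputed[-(10:12)]))
  expect_false(any(is.na(dec$state)))
})

test_that("decoding accuracy exceeds 95% on the default-scenario sensor chain", {
  fx <- pipeline_fixture()
  al <- align_states(fx$decoded$state, fx$truth)
  expect_gte(al$accuracy, 0.95)
  # EM loglik monotone on the real feature streams too
  expect_true(all(diff(fx$fit$trace) >= -1e-6))
})
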