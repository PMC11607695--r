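test_that("isotope turnover matches the hand-computed log-ratio form", {
  # ln(1850/350)/47
  expect_equal(isotope_turnover(2000, 500, 150, 47), 0.035426,
               tolerance = 1e-4)
  expect_equal(isotope_turnover(2000, 2000, 150, 47), 0) # no washout
  k1 <- isotope_turnover(2000, 500, 150, 20)
  expect_equal(isotope_turnover(2000, 500, 150, 40), k1 / 2)
  expect_error(isotope_turnover(2000, 140, 150, 47, isotope = "18O"), "18O")
  expect_error(isotope_turnover(100, 90, 150, 47, isotope = "2H"), "2H")
})

test_that("dilution space matches the plateau form and is ratio-invariant", {
  expect_equal(dilution_space(0.05, 90000, 2000, 150), 2.3784,
               tolerance = 1e-4)
  expect_equal(dilution_space(0.05, 2000, 2000, 150), 0)
  n1 <- dilution_space(0.05, 90000, 2000, 150)
  # scaling all enrichment differences by a common factor leaves N unchanged
  f <- 3.7
  n2 <- dilution_space(0.05, 150 + (90000 - 150) * f, 150 + (2000 - 150) * f, 150)
  expect_equal(n2, n1)
  expect_error(dilution_space(0.05, 90000, 100, 150), "dilution space")
})

test_that("a constant enrichment offset leaves k unchanged but shifts N", {
  off <- 500
  expect_equal(isotope_turnover(2000 + off, 500 + off, 150 + off, 47),
               isotope_turnover(2000, 500, 150, 47))
  # offset on the blood samples only (injectate unchanged) shifts N
  expect_false(isTRUE(all.equal(
    dilution_space(0.05, 90000, 2000 + off, 150 + off),
    dilution_space(0.05, 90000, 2000, 150))))
})

test_that("final dilution space follows the percentage-mass method", {
  fd <- final_dilution_space(2.0, 1500, 1425)
  expect_equal(fd$n_f, 1.9)
  expect_equal(fd$n, 1.95)
  fd2 <- final_dilution_space(2.0, 1500, 1500)
  expect_equal(fd2$n_f, 2.0)
  expect_equal(fd2$n, 2.0)
  expect_error(final_dilution_space(2.0, 1500, 0))
})

test_that("one-pool rCO2 matches the reduced formula and flags invalid results", {
  r <- rco2_single_pool(2.0, 0.040, 0.030)
  expect_equal(as.numeric(r), 9.2526, tolerance = 1e-4)
  expect_true(attr(r, "valid"))
  expect_warning(r_bad <- rco2_single_pool(2.0, 0.030, 0.030), "invalid")
  expect_lt(as.numeric(r_bad), 0)
  expect_false(attr(r_bad, "valid"))
  # linear in N at fixed turnover rates
  expect_equal(as.numeric(rco2_single_pool(4.0, 0.040, 0.030)),
               2 * as.numeric(r))
})

test_that("rCO2 and DEE increase strictly with the oxygen turnover", {
  ks <- seq(0.036, 0.06, by = 0.002)
  r <- vapply(ks, function(k) as.numeric(rco2_single_pool(2.0, k, 0.035)),
              numeric(1))
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(dee_kj_per_day(r)) > 0))
})

test_that("energy conversion and mass-specific DEE match hand values", {
  expect_equal(dee_kj_per_day(9.2526), 135.80, tolerance = 1e-4)
  expect_equal(dee_kj_per_day(0), 0)
  # linear in the caloric equivalent
  c2 <- dlw_constants(j_per_ml = 54.6)
  expect_equal(dee_kj_per_day(9.2526, c2), 2 * dee_kj_per_day(9.2526))
  expect_equal(mass_specific_dee(135.80, 1400), 0.097, tolerance = 1e-4)
  expect_equal(mass_specific_dee(0, 1400), 0)
  expect_equal(mass_specific_dee(135.80, 700), 2 * mass_specific_dee(135.80, 1400))
})

test_that("equilibrium relation recovers exact linear enrichments with r = 1", {
  mass <- c(1200, 1350, 1500, 1650)
  eq <- tibble::tibble(mass_g = mass,
                       i_eq_d = 1263 - 0.3836 * mass,
                       i_eq_o = 2552 - 0.19 * mass)
  rel <- fit_equilibrium_relation(eq)
  expect_equal(rel$d$coef, c(intercept = 1263, slope = -0.3836))
  expect_equal(rel$o$coef, c(intercept = 2552, slope = -0.19))
  expect_equal(abs(rel$d$r), 1)
  expect_true(rel$valid) # |r| > 0.7 for both isotopes
  # interpolation through a fitted bird's mass returns its enrichment
  pred <- estimate_initial_enrichment(rel, 1350)
  expect_equal(pred$i_init_d, eq$i_eq_d[2])
  expect_equal(pred$i_init_o, eq$i_eq_o[2])
  expect_error(fit_equilibrium_relation(
    tibble::tibble(mass_g = rep(1400, 4), i_eq_d = 1:4, i_eq_o = 1:4)),
    "singular")
  expect_warning(estimate_initial_enrichment(rel, 2500), "extrapolat")
})

test_that("a slope-zero relation predicts the intercept at any mass", {
  eq <- tibble::tibble(mass_g = c(1200, 1400, 1600),
                       i_eq_d = rep(800, 3), i_eq_o = rep(2300, 3))
  rel <- fit_equilibrium_relation(eq)
  expect_warning(pred <- estimate_initial_enrichment(rel, c(1000, 1800)),
                 "extrapolat")
  expect_equal(pred$i_init_d, c(800, 800))
  expect_equal(pred$i_init_o, c(2300, 2300))
})

test_that("pure-noise enrichments rarely clear |r| = 0.35 at n = 50", {
  # exact null: r^2 ~ Beta(1/2, (n-2)/2)
  p_exact <- pbeta(0.35^2, 0.5, 24)
  expect_equal(p_exact, 0.9873, tolerance = 1e-3)
  reps <- 400
  inside <- withr::with_seed(42, {
    vapply(seq_len(reps), function(i) {
      mass <- runif(50, 1200, 1800)
      abs(cor(mass, rnorm(50))) < 0.35
    }, logical(1))
  })
  se <- sqrt(p_exact * (1 - p_exact) / reps)
  expect_gt(mean(inside), p_exact - 3 * se)
})

test_that("noise-free isotope panels round-trip to the true DEE", {
  sc <- sim_scenario(seed = 1)
  pan <- simulate_isotopes(1600, 1450, 1430, 48, sc)
  pan$bird <- "X"
  res <- dlw_analyse(pan)
  expect_equal(res$dee_kj_day, 1600, tolerance = 1e-6)
  expect_equal(res$msdee, 1600 / 1440, tolerance = 1e-6)
  expect_gt(res$k_o, res$k_d)
})

test_that("washout is monotone in deployment time and fails past the dose", {
  sc <- sim_scenario(seed = 1)
  p1 <- simulate_isotopes(1600, 1450, 1450, 48, sc)
  p2 <- simulate_isotopes(1600, 1450, 1450, 96, sc)
  expect_lt(p2$i_final_d, p1$i_final_d)
  expect_lt(p2$i_final_o, p1$i_final_o)
  expect_error(simulate_isotopes(1600, 1450, 1450, 0.5, sc), "equilibration")
})

test_that("single-sample analysis of a scatter-free cohort recovers truth through the fitted relation", {
  sc <- sim_scenario(seed = 9, equilibrium_scatter_ppm = c(d = 0, o = 0),
                     dee_noise_cv = 0, n_deployed_birds = 5,
                     deployment_hours = c(46, 50))
  coh <- simulate_cohort(sc)
  rel <- fit_equilibrium_relation(tibble::tibble(
    mass_g = coh$equilibrium$mass_g,
    i_eq_d = coh$equilibrium$i_eq_d,
    i_eq_o = coh$equilibrium$i_eq_o))
  expect_equal(abs(rel$d$r), 1, tolerance = 1e-9)
  expect_equal(abs(rel$o$r), 1, tolerance = 1e-9)
  res <- suppressWarnings(dlw_analyse(coh$dlw))
  truth <- coh$truth[match(res$bird, coh$truth$bird), ]
  expect_equal(res$msdee, truth$msdee_true, tolerance = 1e-6)
})
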