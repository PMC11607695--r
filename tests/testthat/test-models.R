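test_that("daily standardization is the 24/h scaling with additivity", {
  expect_equal(standardize_daily(120, 48), 60)
  expect_equal(standardize_daily(7, 24), 7)
  expect_warning(standardize_daily(5, 10), "shorter")
  parts <- c(30, 50, 20, 10)
  expect_equal(sum(standardize_daily(parts, 48)),
               standardize_daily(sum(parts), 48))
})

test_that("time budgets cover the degenerate and symmetric cases", {
  all_col <- factor(rep("colony", 120), levels = plungedee:::.states)
  tb <- time_budget(all_col)
  expect_equal(tb$hours, c(24, 0, 0, 0))
  quarters <- factor(rep(plungedee:::.states, each = 30),
                     levels = plungedee:::.states)
  expect_equal(time_budget(quarters)$hours, rep(6, 4))
  expect_equal(sum(time_budget(quarters)$hours), 24, tolerance = 1e-9)
  # missing minutes go to their own bucket
  with_na <- factor(c(rep("colony", 110), rep(NA, 10)),
                    levels = plungedee:::.states)
  tbm <- time_budget(with_na)
  expect_equal(tbm$hours[tbm$state == "missing"], 2)
  expect_equal(sum(tbm$hours), 24, tolerance = 1e-9)
})

test_that("budget recovery on the simulated cohort is within 0.2 h per state", {
  fx <- pipeline_fixture()
  al <- align_states(fx$decoded$state, fx$truth)
  mapped <- factor(al$permutation[as.character(fx$decoded$state)],
                   levels = levels(fx$truth))
  tb_true <- sapply(split(fx$truth, fx$minutes$bird),
                    function(s) time_budget(s)$hours)
  tb_dec <- sapply(split(mapped, fx$minutes$bird),
                   function(s) time_budget(s)$hours)
  mae <- rowMeans(abs(tb_true - tb_dec))
  expect_true(all(mae < 0.2))
})

test_that("the candidate set has 12 designs incl. the two leading DBA forms", {
  cm <- candidate_models()
  expect_equal(nrow(cm), 12)
  expect_equal(sum(cm$kind == "time"), 5)
  expect_equal(sum(cm$kind == "dba"), 5)
  expect_equal(sum(cm$kind == "null"), 2)
  # every non-null design partitions the four activities
  for (i in which(cm$kind != "null")) {
    expect_setequal(unlist(cm$groups[[i]]), plungedee:::.states)
    expect_equal(anyDuplicated(unlist(cm$groups[[i]])), 0)
  }
  # the two leading two-parameter DBA designs are present
  expect_true("D: col+rest | com+for" %in% cm$design)
  expect_true("D: col | com+for+rest" %in% cm$design)
  expect_error(candidate_models(list(list("colony", "commuting"))), "cover")
})

test_that("noise-free grouped time models are recovered exactly", {
  s <- designed_summaries(n = 12, noise_cv = 0, seed = 2)
  s$msdee <- 2 * (s$t_col + s$t_rest) + 5 * (s$t_com + s$t_for)
  design <- candidate_models()[3, ] # T: col+rest | com+for
  fit <- fit_dee_model(design, s)
  expect_equal(unname(fit$coefficients), c(2, 5), tolerance = 1e-9)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
})

test_that("a single merged activity collapses to the mean rate", {
  s <- designed_summaries(n = 10, noise_cv = 0.05, seed = 3)
  one_group <- tibble::tibble(design = "T: all", kind = "time",
                              groups = list(list(plungedee:::.states)),
                              k_predictors = 1L)
  fit <- fit_dee_model(one_group, s)
  expect_equal(unname(fit$coefficients[1]), mean(s$msdee) / 24,
               tolerance = 1e-9)
})

test_that("collinear grouped predictors are reported by name", {
  s <- designed_summaries(n = 10, noise_cv = 0, seed = 4)
  s$dba_com <- 2 * s$dba_col
  s$dba_for <- 0 * s$dba_for
  s$dba_rest <- 0 * s$dba_rest
  design <- tibble::tibble(
    design = "D: bad", kind = "dba",
    groups = list(list("colony", "commuting", c("foraging", "resting"))),
    k_predictors = 3L)
  expect_error(fit_dee_model(design, s), "Collinear")
})

test_that("recovered activity rates fall within 2 SE of truth in most replicates", {
  rates <- c(colony = 0.0325, commuting = 0.08775, foraging = 0.1495,
             resting = 0.0845)
  full <- candidate_models()[1, ]
  hits <- vapply(1:100, function(i) {
    s <- designed_summaries(n = 20, rates = rates, noise_cv = 0.05, seed = i)
    fit <- fit_dee_model(full, s)
    sm <- summary(fit$lm)$coefficients
    abs(sm[, 1] - rates) <= 2 * sm[, 2]
  }, logical(4))
  expect_true(all(rowMeans(hits) >= 0.90)) # per-coefficient 2 SE coverage
})

test_that("AICc matches the hand formula and ties give equal deltas", {
  n <- 20; rss <- 5; k <- 4
  ll <- -n / 2 * log(2 * pi) - n / 2 * log(rss / n) - n / 2
  expect_equal(plungedee:::aicc_value(ll, k, n),
               -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  s <- designed_summaries(n = 20, seed = 5)
  f <- fit_dee_model(candidate_models()[1, ], s)
  rk <- aicc_rank(list(a = f, b = f))
  expect_equal(rk$daicc, c(0, 0))
  # the fitted Gaussian loglik uses the ML variance estimate
  rss_f <- sum(f$residuals^2)
  ll_f <- -f$n / 2 * log(2 * pi) - f$n / 2 * log(rss_f / f$n) - f$n / 2
  expect_equal(f$logLik, ll_f, tolerance = 1e-9)
  expect_equal(f$aicc, plungedee:::aicc_value(ll_f, f$k, f$n))
})

test_that("AICc is undefined and excluded when n - k - 1 <= 0", {
  expect_true(is.na(plungedee:::aicc_value(-3, 5, 6)))
  s <- designed_summaries(n = 7, seed = 6)
  f_small <- fit_dee_model(candidate_models()[12, ], s) # k = 3
  f_big <- fit_dee_model(candidate_models()[11, ], s)
  f_big$k <- 8 # synthetic over-parameterized fit: n - k - 1 < 0
  f_big$aicc <- plungedee:::aicc_value(f_big$logLik, f_big$k, f_big$n)
  expect_true(is.na(f_big$aicc))
  expect_warning(rk <- aicc_rank(list(big = f_big, small = f_small)),
                 "excluded")
  expect_equal(nrow(rk), 1)
})

test_that("AICc prefers the generating design over pure-noise-augmented supersets", {
  # truth: the colony+resting | commuting+foraging time design, with group
  # rates at the default effect sizes (means of the per-state defaults);
  # the rivals split one or both merged groups, adding parameters that
  # carry no signal
  rates <- c(colony = 0.0585, commuting = 0.118625, foraging = 0.118625,
             resting = 0.0585)
  cm <- candidate_models()
  nested <- c("T: col+rest | com+for", "T: col | com+for | rest",
              "T: col+rest | com | for", "T: col | com | for | rest")
  wins <- vapply(1:100, function(i) {
    s <- designed_summaries(n = 20, rates = rates, noise_cv = 0.05, seed = i)
    rk <- aicc_rank(fit_all_dee_models(s, cm))
    rk$design[rk$design %in% nested][1] == "T: col+rest | com+for"
  }, logical(1))
  expect_gte(mean(wins), 0.70)
})

test_that("predictive r handles perfect, constant and single-predictor fits", {
  s <- designed_summaries(n = 15, noise_cv = 0, seed = 7)
  fit0 <- fit_dee_model(candidate_models()[1, ], s)
  expect_equal(predictive_r(fit0), 1, tolerance = 1e-9)
  s2 <- designed_summaries(n = 15, noise_cv = 0.05, seed = 8)
  null_fit <- fit_dee_model(candidate_models()[11, ], s2)
  expect_true(is.na(null_fit$r))
  expect_false(null_fit$r_defined)
  # r^2 equals the regression R^2 for a free-intercept single-group fit
  dba_null <- fit_dee_model(candidate_models()[12, ], s2)
  expect_equal(dba_null$r^2, summary(dba_null$lm)$r.squared,
               tolerance = 1e-10)
  # predictive_r on new data agrees with refitting the stored coefficients
  expect_equal(predictive_r(dba_null, s2), dba_null$r, tolerance = 1e-12)
})

test_that("activity rates recover the foraging/colony ratio and convert units", {
  full <- candidate_models()[1, ]
  ratios <- vapply(1:20, function(i) {
    s <- designed_summaries(n = 20, noise_cv = 0.05, seed = 100 + i)
    fit <- fit_dee_model(full, s)
    ar <- activity_rates(fit, mass_ref_g = 1450)
    ar$ratio_vs_colony[ar$group == "t_for"]
  }, numeric(1))
  expect_lt(abs(median(ratios) - 4.6) / 4.6, 0.15)
  # self-ratio: BMR equal to an activity's own wattage gives x_bmr = 1
  s <- designed_summaries(n = 20, noise_cv = 0, seed = 9)
  fit <- fit_dee_model(full, s)
  w_col <- fit$coefficients[["t_col"]] * 1450 / 3.6
  ar <- activity_rates(fit, mass_ref_g = 1450, bmr_w = w_col)
  expect_equal(ar$x_bmr[ar$group == "t_col"], 1, tolerance = 1e-9)
  # watts scale linearly with the reference mass
  ar2 <- activity_rates(fit, mass_ref_g = 2900, bmr_w = w_col)
  expect_equal(ar2$watts, 2 * ar$watts, tolerance = 1e-9)
  expect_error(activity_rates(fit_dee_model(candidate_models()[8, ], s), 1450),
               "time-budget")
})

test_that("group contrasts match the two-sample t framework and hold their size", {
  expect_equal(group_difference(c(1, 2, 3, 1, 2, 3),
                                rep(c("f", "m"), each = 3))$estimate, 0)
  gd <- group_difference(c(1, 2, 3, 4, 5, 6), rep(c("f", "m"), each = 3))
  expect_equal(gd$estimate, 3)
  tt <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(gd$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(gd$p, tt$p.value, tolerance = 1e-9)
  # type-I error near nominal under the null
  rej <- withr::with_seed(55, {
    vapply(1:2000, function(i) {
      group_difference(rnorm(20), rep(c("f", "m"), each = 10))$p < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
  expect_error(group_difference(1:5, c("a", "a", "a", "a", "b")), ">= 2")
})

test_that("daily activity summaries conserve budgets and DBA additivity", {
  fx <- pipeline_fixture()
  dlw_res <- tibble::tibble(bird = unique(fx$minutes$bird),
                            mass_g = c(1500, 1400, 1600),
                            msdee = c(1.1, 1.2, 1.0))
  s <- daily_activity_summary(fx$decoded, fx$minutes, dlw_res)
  expect_equal(s$t_col + s$t_com + s$t_for + s$t_rest, rep(24, nrow(s)),
               tolerance = 1e-9)
  expect_equal(s$dba_col + s$dba_com + s$dba_for + s$dba_rest, s$dba_total,
               tolerance = 1e-9)
  expect_true(all(s[paste0("dba_", c("col", "com", "for", "rest"))] >= 0))
})
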