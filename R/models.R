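#' Standardize deployment totals to a 24 h day
#'
#' Daily value = total over the deployment x 24 / sampling hours. The same
#' formula applies to total DBA, activity-specific DBA and activity times.
#' Warns for deployments shorter than `min_hours` (daily extrapolation from
#' a short window is unreliable).
#'
#' @param x Totals over the deployment (numeric, recycled).
#' @param sampling_hours Deployment sampling time [h], > 0.
#' @param min_hours Warning threshold [h].
#' @return Daily-standardized values.
#' @examples
#' standardize_daily(120, 48) # 60 per day
#' @export
standardize_daily <- function(x, sampling_hours, min_hours = 20) {
  if (any(sampling_hours <= 0)) abort("`sampling_hours` must be > 0.")
  if (any(sampling_hours < min_hours)) {
    warn(sprintf("Deployment(s) shorter than %g h: daily standardization extrapolates.",
                 min_hours))
  }
  x * 24 / sampling_hours
}

#' Time budget from decoded minute states
#'
#' Minute counts per behavioural state converted to hours and standardized
#' to a 24 h day. Unlabelled minutes (NA) go to a `missing` bucket; by
#' default they still count toward the sampling time (so labelled hours sum
#' to less than 24), or they can be excluded from the renormalization.
#'
#' @param states Factor (or character) of per-minute states.
#' @param sampling_hours Deployment hours; defaults to `length(states)/60`.
#' @param exclude_missing If TRUE, renormalize over labelled minutes only.
#' @return A tibble: `state`, `minutes`, `hours` (per 24 h).
#' @examples
#' time_budget(factor(rep(c("colony", "commuting"), c(90, 30)),
#'                    levels = c("colony", "commuting", "foraging", "resting")))
#' @export
time_budget <- function(states, sampling_hours = length(states) / 60,
                        exclude_missing = FALSE) {
  if (!is.factor(states)) states <- factor(states, levels = .states)
  n_na <- sum(is.na(states))
  counts <- table(states)
  eff_hours <- if (exclude_missing) {
    sampling_hours - n_na / 60
  } else {
    sampling_hours
  }
  if (eff_hours <= 0) abort("No labelled sampling time.")
  out <- tibble(
    state = names(counts),
    minutes = as.integer(counts),
    hours = as.numeric(counts) / 60 * 24 / eff_hours
  )
  if (n_na > 0) {
    out <- bind_rows(out, tibble(state = "missing", minutes = n_na,
                                 hours = if (exclude_missing) 0 else
                                   n_na / 60 * 24 / eff_hours))
  }
  out
}

#' The candidate set of daily energy expenditure models
#'
#' Twelve designs: five activity partitions x two predictor kinds (time
#' budget and activity-specific daily DBA), plus two null models (intercept
#' only, and total daily DBA). The partitions are the four independent
#' activities, colony vs everything at sea, colony+resting vs
#' commuting+foraging, and the two three-group variants; the set is
#' configurable because only its size and a few members are canonical.
#' Time-budget designs are fitted with the intercept fixed at zero (all
#' activity is accounted for); DBA designs keep a free intercept
#' (DEE with no activity, a proxy for basal metabolic rate).
#'
#' @param partitions List of partitions; each partition is a list of
#'   character vectors jointly covering the four activities exactly once.
#' @return A tibble of class `dee_design_set`: `design` (label), `kind`
#'   ("time", "dba", "null"), `groups` (list-column), `k_predictors`.
#' @examples
#' candidate_models()$design
#' @export
candidate_models <- function(partitions = default_partitions()) {
  for (p in partitions) {
    if (!setequal(unlist(p), .states) || anyDuplicated(unlist(p)) > 0) {
      abort("Each partition must cover the four activities exactly once.")
    }
  }
  lab <- function(p) paste(vapply(p, function(g)
    paste(abbrev_state(g), collapse = "+"), character(1)), collapse = " | ")
  rows <- list()
  for (kind in c("time", "dba")) {
    for (p in partitions) {
      rows[[length(rows) + 1L]] <- tibble(
        design = sprintf("%s: %s", toupper(substr(kind, 1, 1)), lab(p)),
        kind = kind, groups = list(p), k_predictors = length(p))
    }
  }
  rows[[length(rows) + 1L]] <- tibble(design = "null: intercept",
                                      kind = "null", groups = list(NULL),
                                      k_predictors = 0L)
  rows[[length(rows) + 1L]] <- tibble(design = "null: total DBA",
                                      kind = "null", groups = list("total"),
                                      k_predictors = 1L)
  out <- bind_rows(rows)
  class(out) <- c("dee_design_set", class(out))
  out
}

#' @rdname candidate_models
#' @export
default_partitions <- function() {
  list(
    list("colony", "commuting", "foraging", "resting"),
    list("colony", c("commuting", "foraging", "resting")),
    list(c("colony", "resting"), c("commuting", "foraging")),
    list("colony", c("commuting", "foraging"), "resting"),
    list(c("colony", "resting"), "commuting", "foraging")
  )
}

abbrev_state <- function(s) {
  c(colony = "col", commuting = "com", foraging = "for", resting = "rest")[s]
}

# design matrix for one design over the summaries table
design_matrix <- function(design_row, summaries) {
  kind <- design_row$kind
  groups <- design_row$groups[[1]]
  col_of <- function(prefix, a) summaries[[paste0(prefix, "_", abbrev_state(a))]]
  if (kind == "null") {
    if (is.null(groups)) return(NULL) # intercept-only
    return(matrix(summaries$dba_total, ncol = 1,
                  dimnames = list(NULL, "dba_total")))
  }
  prefix <- if (kind == "time") "t" else "dba"
  X <- vapply(groups, function(g) {
    Reduce(`+`, lapply(g, function(a) col_of(prefix, a)))
  }, numeric(nrow(summaries)))
  colnames(X) <- vapply(groups, function(g)
    paste0(prefix, "_", paste(abbrev_state(g), collapse = ".")), character(1))
  X
}

#' Fit one candidate DEE model
#'
#' Ordinary least squares of mass-specific DEE on the design's grouped
#' predictors: summed activity hours (time kind; zero intercept - the
#' coefficients are activity-specific metabolic rates in
#' kJ h\eqn{^{-1}} g\eqn{^{-1}}) or summed activity-specific daily DBA
#' (DBA kind; free intercept, the no-activity DEE). The Gaussian
#' log-likelihood uses the maximum-likelihood variance estimate, and the
#' AICc parameter count includes the residual variance.
#'
#' @param design_row One row of [candidate_models()].
#' @param summaries Daily activity summary table with columns `msdee`,
#'   `t_col`..`t_rest`, `dba_col`..`dba_rest`, `dba_total` (see
#'   [daily_activity_summary()]).
#' @return An object of class `dee_model_fit`: `design`, `kind`, `groups`,
#'   `coefficients` (incl. `(Intercept)` where applicable), `n`, `k`
#'   (parameters incl. residual variance), `logLik`, `aicc`, `fitted`,
#'   `residuals`, `r` (predictive correlation; NA with a flag for
#'   constant predictions), `lm` (the underlying fit).
#' @export
fit_dee_model <- function(design_row, summaries) {
  summaries <- as_tibble(summaries)
  y <- summaries$msdee
  X <- design_matrix(design_row, summaries)
  kind <- design_row$kind
  if (!is.null(X)) {
    qrX <- qr(cbind(if (kind != "time") 1, X))
    if (qrX$rank < ncol(qrX$qr)) {
      abort(sprintf("Collinear grouped predictors in design '%s' (%s).",
                    design_row$design, paste(colnames(X), collapse = ", ")))
    }
  }
  df <- bind_cols(tibble(.msdee = y), as_tibble(X %||% tibble(.rows = length(y))))
  fml <- if (is.null(X)) {
    .msdee ~ 1
  } else if (kind == "time") {
    stats::reformulate(sprintf("`%s`", colnames(X)), response = ".msdee",
                       intercept = FALSE)
  } else {
    stats::reformulate(sprintf("`%s`", colnames(X)), response = ".msdee")
  }
  n <- length(y)
  k <- (if (is.null(X)) 0L else ncol(X)) + (if (kind == "time") 0L else 1L) + 1L
  if (n < k + 2) abort("Too few birds for this design (need >= k + 2).")
  m <- lm(fml, data = df)
  ll <- as.numeric(logLik(m))
  fitted_vals <- as.numeric(stats::fitted(m))
  r <- if (sd(fitted_vals) < 1e-12) NA_real_ else cor(fitted_vals, y)
  structure(
    list(design = design_row$design, kind = kind,
         groups = design_row$groups[[1]],
         coefficients = coef(m), n = n, k = k, logLik = ll,
         aicc = aicc_value(ll, k, n),
         fitted = fitted_vals, residuals = as.numeric(stats::resid(m)),
         r = r, r_defined = !is.na(r), lm = m),
    class = "dee_model_fit")
}

# AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1); NA when the correction blows up
aicc_value <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(NA_real_)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
print.dee_model_fit <- function(x, ...) {
  cat(sprintf("<dee_model_fit> %s (n=%d, k=%d)\n", x$design, x$n, x$k))
  print(round(x$coefficients, 5))
  cat(sprintf("  logLik %.3f | AICc %.3f | predictive r %s\n",
              x$logLik, x$aicc,
              if (x$r_defined) sprintf("%.3f", x$r) else "undefined"))
  invisible(x)
}

#' Fit every candidate design
#'
#' @param summaries Daily activity summary table.
#' @param designs A [candidate_models()] set.
#' @return A named list of [fit_dee_model()] objects.
#' @export
fit_all_dee_models <- function(summaries, designs = candidate_models()) {
  fits <- lapply(seq_len(nrow(designs)), function(i)
    fit_dee_model(designs[i, ], summaries))
  names(fits) <- designs$design
  fits
}

#' Rank fitted models by AICc
#'
#' Sorts ascending by AICc and adds the difference to the best model.
#' Designs whose small-sample correction is undefined (n - k - 1 <= 0) are
#' excluded with a warning. All fits must share the same response vector.
#'
#' @param fits List of [fit_dee_model()] objects.
#' @return A tibble of class `dee_model_ranking`: `design`, `kind`, `k`,
#'   `logLik`, `aicc`, `daicc`, `r`.
#' @export
aicc_rank <- function(fits) {
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) {
    abort("All fits must be on the same response vector (equal n).")
  }
  drop <- vapply(fits, function(f) is.na(f$aicc), logical(1))
  if (any(drop)) {
    warn(sprintf("AICc undefined (n - k - 1 <= 0) for: %s; excluded.",
                 paste(names(fits)[drop], collapse = ", ")))
    fits <- fits[!drop]
  }
  out <- purrr::map_dfr(fits, function(f) {
    tibble(design = f$design, kind = f$kind, k = f$k, logLik = f$logLik,
           aicc = f$aicc, r = f$r)
  }) %>%
    arrange(.data$aicc) %>%
    mutate(daicc = .data$aicc - .data$aicc[1], .after = "aicc")
  class(out) <- c("dee_model_ranking", class(out))
  out
}

#' Predictive correlation of a fitted DEE model
#'
#' Pearson correlation between the model's fitted (predicted) mass-specific
#' DEE and the observed values. Undefined (NA, with `r_defined = FALSE` on
#' the fit) when the predictions are constant, e.g. the intercept-only null.
#'
#' @param fit A [fit_dee_model()] object.
#' @param summaries Optional new summary table; defaults to the fitted
#'   values stored in the fit.
#' @return Pearson r (possibly NA).
#' @export
predictive_r <- function(fit, summaries = NULL) {
  if (is.null(summaries)) return(fit$r)
  X <- design_matrix(tibble(kind = fit$kind, groups = list(fit$groups)),
                     summaries)
  pred <- if (is.null(X)) {
    rep(fit$coefficients[["(Intercept)"]], nrow(summaries))
  } else {
    Xf <- if (fit$kind == "time") X else cbind(`(Intercept)` = 1, X)
    as.numeric(Xf %*% fit$coefficients[colnames(Xf)])
  }
  if (sd(pred) < 1e-12) return(NA_real_)
  cor(pred, summaries$msdee)
}

#' Activity-specific metabolic rates from a time-budget fit
#'
#' Converts the coefficients of a zero-intercept time-budget fit into an
#' activity-rate table: mass-specific metabolic rate (kJ h\eqn{^{-1}}
#' g\eqn{^{-1}}), whole-animal power at a reference mass
#' (W = kJ h\eqn{^{-1}} / 3.6), the multiple of basal metabolic rate, and
#' the rate ratio to the colony (first) group.
#'
#' @param fit A [fit_dee_model()] with `kind = "time"`.
#' @param mass_ref_g Reference body mass [g].
#' @param bmr_w Basal metabolic rate [W] (supplied externally, e.g. from an
#'   allometric formula; default 4.39 W).
#' @return A tibble: `group`, `mr_kj_h_g`, `watts`, `x_bmr`,
#'   `ratio_vs_colony`.
#' @export
activity_rates <- function(fit, mass_ref_g, bmr_w = 4.39) {
  if (!inherits(fit, "dee_model_fit") || fit$kind != "time") {
    abort("`fit` must be a time-budget model fit (kind = 'time').")
  }
  assert_number(mass_ref_g, "mass_ref_g", lower = 1e-9)
  assert_number(bmr_w, "bmr_w", lower = 1e-9)
  mr <- fit$coefficients
  watts <- mr * mass_ref_g / 3.6
  colony_group <- which(vapply(fit$groups, function(g) "colony" %in% g,
                               logical(1)))[1]
  tibble(
    group = names(mr),
    mr_kj_h_g = as.numeric(mr),
    watts = as.numeric(watts),
    x_bmr = as.numeric(watts) / bmr_w,
    ratio_vs_colony = as.numeric(mr) / as.numeric(mr)[colony_group]
  )
}

#' Two-group linear-model contrast
#'
#' Ordinary least-squares contrast between two groups (identical to the
#' pooled-variance two-sample t framework): used for sex differences in
#' mass-specific DEE and day/night differences in hourly DBA.
#'
#' @param values Numeric response.
#' @param group_labels Two-level factor/character of the same length, >= 2
#'   observations per group.
#' @return A tibble: `estimate` (group 2 minus group 1), `se`, `t`, `p`,
#'   `df`.
#' @examples
#' group_difference(c(1, 2, 3, 5, 6, 7), rep(c("a", "b"), each = 3))
#' @export
group_difference <- function(values, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) != 2) abort("`group_labels` must have exactly 2 levels.")
  if (any(table(g) < 2)) abort("Need >= 2 observations per group.")
  m <- lm(values ~ g)
  sm <- summary(m)$coefficients
  tibble(
    contrast = paste(levels(g)[2], "-", levels(g)[1]),
    estimate = sm[2, 1], se = sm[2, 2], t = sm[2, 3], p = sm[2, 4],
    df = m$df.residual
  )
}

#' Build the per-bird daily activity summary table
#'
#' Joins decoded states, per-minute DBA and the DLW results into the
#' modelling table: daily-standardized hours and DBA per activity, total
#' daily DBA, and mass-specific DEE. DBA is attributed to activities by the
#' decoded state of each minute.
#'
#' @param decoded Tibble with `bird`, `minute`, `state` (from
#'   [hmm_decode()]).
#' @param minutes Tibble with `bird`, `minute`, `dba`.
#' @param dlw_results Tibble from [dlw_analyse()] (`bird`, `msdee`,
#'   `mass_g`).
#' @param meta Optional tibble with `bird`, `sex`.
#' @return A tibble, one row per bird: `bird`, `sex` (if given), `mass_g`,
#'   `t_col`..`t_rest`, `dba_col`..`dba_rest`, `dba_total`, `msdee`,
#'   `sampling_hours`.
#' @export
daily_activity_summary <- function(decoded, minutes, dlw_results, meta = NULL) {
  joined <- decoded %>%
    select("bird", "minute", "state") %>%
    left_join(select(minutes, "bird", "minute", "dba"), by = c("bird", "minute"))
  per_bird <- joined %>%
    group_by(.data$bird) %>%
    summarise(sampling_hours = n() / 60,
              .groups = "drop")
  per_state <- joined %>%
    group_by(.data$bird, .data$state) %>%
    summarise(minutes_in = n(), dba_in = sum(.data$dba, na.rm = TRUE),
              .groups = "drop") %>%
    left_join(per_bird, by = "bird") %>%
    mutate(
      t_daily = standardize_daily(.data$minutes_in / 60, .data$sampling_hours,
                                  min_hours = 0),
      dba_daily = standardize_daily(.data$dba_in, .data$sampling_hours,
                                    min_hours = 0),
      st = abbrev_state(as.character(.data$state))
    )
  wide_t <- per_state %>%
    select("bird", "st", "t_daily") %>%
    tidyr::pivot_wider(names_from = "st", values_from = "t_daily",
                       names_prefix = "t_", values_fill = 0)
  wide_d <- per_state %>%
    select("bird", "st", "dba_daily") %>%
    tidyr::pivot_wider(names_from = "st", values_from = "dba_daily",
                       names_prefix = "dba_", values_fill = 0)
  out <- per_bird %>%
    left_join(wide_t, by = "bird") %>%
    left_join(wide_d, by = "bird")
  for (cn in c("t_col", "t_com", "t_for", "t_rest",
               "dba_col", "dba_com", "dba_for", "dba_rest")) {
    if (!cn %in% names(out)) out[[cn]] <- 0
  }
  out <- out %>%
    mutate(dba_total = .data$dba_col + .data$dba_com + .data$dba_for +
             .data$dba_rest) %>%
    left_join(select(dlw_results, "bird", "mass_g", "msdee"), by = "bird")
  if (!is.null(meta)) out <- left_join(out, select(meta, "bird", "sex"),
                                       by = "bird")
  out %>%
    select("bird", dplyr::any_of("sex"), "mass_g",
           "t_col", "t_com", "t_for", "t_rest",
           "dba_col", "dba_com", "dba_for", "dba_rest", "dba_total",
           "msdee", "sampling_hours")
}
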