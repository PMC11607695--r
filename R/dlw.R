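#' Constants for the one-pool DLW calculation
#'
#' All coefficients of the single-sample, single-pool doubly-labelled-water
#' protocol live in one record so alternates can be swapped: the dilution
#' coefficient (2.078) and fractionation correction (0.0062) of the reduced
#' one-pool CO2 equation, the molar gas volume used to convert mmol CO2 to ml
#' (22.4 ml mmol\eqn{^{-1}}), the energetic equivalent of CO2 for a
#' protein-rich (piscivore) diet (27.3 J per ml CO2), and the equilibration
#' time deducted from the sampling interval under the single-sample protocol
#' (1 h in a dark box).
#'
#' @param dilution_coef Denominator coefficient of the one-pool equation.
#' @param fractionation_coef Fractionation-correction coefficient.
#' @param ml_per_mmol Volume conversion, ml CO2 per mmol. The default is the
#'   molar gas volume 22.4; supply 2240 to reproduce a per-mol convention.
#' @param j_per_ml Energy equivalent, joules per ml CO2 (27.3 for piscivores).
#' @param equilibration_h Isotope equilibration time deducted from the total
#'   sampling interval [h].
#' @param msdee_mass Mass convention for mass-specific DEE: `"mean"` of the
#'   initial and final body mass (default) or `"initial"`.
#' @return A list of class `dlw_constants`.
#' @examples
#' dlw_constants()
#' @export
dlw_constants <- function(dilution_coef = 2.078,
                          fractionation_coef = 0.0062,
                          ml_per_mmol = 22.4,
                          j_per_ml = 27.3,
                          equilibration_h = 1,
                          msdee_mass = c("mean", "initial")) {
  assert_number(dilution_coef, "dilution_coef", lower = 1e-9)
  assert_number(fractionation_coef, "fractionation_coef", lower = 0)
  assert_number(ml_per_mmol, "ml_per_mmol", lower = 1e-9)
  assert_number(j_per_ml, "j_per_ml", lower = 1e-9)
  assert_number(equilibration_h, "equilibration_h", lower = 0)
  structure(
    list(dilution_coef = dilution_coef,
         fractionation_coef = fractionation_coef,
         ml_per_mmol = ml_per_mmol,
         j_per_ml = j_per_ml,
         equilibration_h = equilibration_h,
         msdee_mass = match.arg(msdee_mass)),
    class = "dlw_constants"
  )
}

#' Isotope turnover rate
#'
#' Exponential elimination rate of a labelled isotope from body water:
#' \deqn{k = \ln\frac{I_{initial} - I_{background}}{I_{final} - I_{background}} / T_{eff}}
#' where \eqn{T_{eff}} is the effective sampling interval (total interval
#' minus the equilibration time under the single-sample protocol).
#' Enrichments enter only as background-subtracted differences, so a constant
#' offset common to all three samples leaves k unchanged.
#'
#' @param i_initial,i_final,i_background Enrichments [ppm]; vectors recycle.
#' @param t_eff_h Effective sampling interval [h].
#' @param isotope Label used in error messages (e.g. "2H", "18O").
#' @return Turnover rate(s) [h\eqn{^{-1}}].
#' @examples
#' isotope_turnover(2000, 500, 150, 47) # 0.035426
#' @export
isotope_turnover <- function(i_initial, i_final, i_background, t_eff_h,
                             isotope = "isotope") {
  if (any(t_eff_h <= 0)) abort("`t_eff_h` must be > 0.")
  if (any(i_initial <= i_background)) {
    abort(sprintf("Initial enrichment at or below background for %s: turnover undefined.",
                  isotope))
  }
  if (any(i_final <= i_background)) {
    abort(sprintf("Final enrichment at or below background for %s: turnover undefined (washout complete).",
                  isotope))
  }
  log((i_initial - i_background) / (i_final - i_background)) / t_eff_h
}

#' Isotope dilution space
#'
#' Plateau-dilution estimate of the body-water pool seen by one isotope:
#' \deqn{N = Mol_{inj} (I_{inj} - I_{initial}) / (I_{initial} - I_{background})}
#' in moles, where \eqn{Mol_{inj}} is the injected dose.
#'
#' @param mol_inj Injected dose [mol].
#' @param i_inj Injectate enrichment [ppm].
#' @param i_initial,i_background Plasma enrichments [ppm].
#' @param isotope Label used in error messages.
#' @return Dilution space(s) [mol].
#' @examples
#' dilution_space(0.05, 90000, 2000, 150) # 2.3784
#' @export
dilution_space <- function(mol_inj, i_inj, i_initial, i_background,
                           isotope = "isotope") {
  if (any(mol_inj <= 0)) abort("`mol_inj` must be > 0.")
  if (any(i_initial <= i_background)) {
    abort(sprintf("Initial enrichment at or below background for %s: dilution space undefined.",
                  isotope))
  }
  mol_inj * (i_inj - i_initial) / (i_initial - i_background)
}

#' Final dilution space and interval-average pool
#'
#' The final dilution space follows the percentage-mass method: body water is
#' held at a fixed fraction of body mass, so
#' \eqn{N_f = N_o \, m_{final} / m_{initial}}. The pool used in the one-pool
#' CO2 equation is the interval average \eqn{N = (N_o + N_f)/2}.
#'
#' @param n_o Oxygen-18 dilution space at the start of the interval [mol].
#' @param mass_initial_g,mass_final_g Body masses [g].
#' @return A tibble with columns `n_f` and `n` [mol].
#' @examples
#' final_dilution_space(2.0, 1500, 1425) # n_f 1.9, n 1.95
#' @export
final_dilution_space <- function(n_o, mass_initial_g, mass_final_g) {
  if (any(mass_initial_g <= 0) || any(mass_final_g <= 0)) {
    abort("Body masses must be > 0.")
  }
  n_f <- n_o * mass_final_g / mass_initial_g
  tibble(n_f = n_f, n = (n_o + n_f) / 2)
}

#' One-pool CO2 production
#'
#' Reduced single-pool estimator of CO2 production from the two turnover
#' rates and the (average) body-water pool:
#' \deqn{rCO_2 = 1000 [ (N/2.078)(k_o - k_d) - 0.0062\, k_d N ]}
#' with N in mol and k in h\eqn{^{-1}}, giving mmol CO2 h\eqn{^{-1}}. A
#' negative result (possible when \eqn{k_o \le k_d}) is physiologically
#' invalid; the value is still returned for diagnostics with attribute
#' `valid = FALSE` and a warning.
#'
#' @param n Body-water pool [mol].
#' @param k_o,k_d Oxygen and deuterium turnover rates [h\eqn{^{-1}}].
#' @param constants A [dlw_constants()] record.
#' @return CO2 production (mmol h\eqn{^{-1}}) with a logical `valid`
#'   attribute.
#' @examples
#' rco2_single_pool(2.0, 0.040, 0.030) # 9.2526
#' @export
rco2_single_pool <- function(n, k_o, k_d, constants = dlw_constants()) {
  if (any(n <= 0)) abort("`n` must be > 0.")
  if (any(k_o < 0) || any(k_d < 0)) abort("Turnover rates must be >= 0.")
  r <- 1000 * ((n / constants$dilution_coef) * (k_o - k_d) -
                 constants$fractionation_coef * k_d * n)
  valid <- r > 0
  if (any(!valid)) {
    warn("rCO2 <= 0 for at least one record (k_o <= k_d after fractionation): physiologically invalid, returned for diagnostics.")
  }
  attr(r, "valid") <- valid
  r
}

#' Convert CO2 production to daily energy expenditure
#'
#' DEE (kJ day\eqn{^{-1}}) = rCO2 (mmol h\eqn{^{-1}}) x ml-per-mmol x
#' J-per-ml x 24 / 1000.
#'
#' @param rco2_mmol_h CO2 production (mmol h\eqn{^{-1}}).
#' @param constants A [dlw_constants()] record (volume and energy
#'   conversions are configurable there).
#' @return DEE (kJ day\eqn{^{-1}}).
#' @examples
#' dee_kj_per_day(9.2526) # 135.80
#' @export
dee_kj_per_day <- function(rco2_mmol_h, constants = dlw_constants()) {
  rco2_mmol_h * constants$ml_per_mmol * constants$j_per_ml * 24 / 1000
}

#' Mass-specific daily energy expenditure
#'
#' @param dee_kj_day DEE (kJ day\eqn{^{-1}}).
#' @param mass_g Body mass [g] (the mass convention - interval mean or
#'   initial - is decided where the mass is computed; see [dlw_analyse()]).
#' @return msDEE (kJ day\eqn{^{-1}} g\eqn{^{-1}}).
#' @examples
#' mass_specific_dee(135.80, 1400)
#' @export
mass_specific_dee <- function(dee_kj_day, mass_g) {
  if (any(mass_g <= 0)) abort("`mass_g` must be > 0.")
  dee_kj_day / mass_g
}

#' Fit the mass-equilibrium enrichment relation
#'
#' Ordinary least-squares line per isotope relating body mass to the 1-h
#' equilibrium enrichment, fitted on the equilibrium set of birds. Under the
#' single-sample protocol this relation supplies the (unmeasured) initial
#' enrichment of each deployed bird. The fit is considered valid for
#' single-sample use when Pearson's |r| > 0.7 for both isotopes.
#'
#' @param equilibrium_birds Data frame with columns `mass_g`, `i_eq_d`,
#'   `i_eq_o` (equilibrium enrichments [ppm]); >= 3 rows.
#' @return An object of class `equilibrium_relation` with per-isotope
#'   `coef` (intercept, slope), `r`, the gate `valid`, and the fitted mass
#'   range.
#' @examples
#' eq <- tibble::tibble(mass_g = c(1200, 1400, 1600),
#'                      i_eq_d = 1263 - 0.3836 * c(1200, 1400, 1600),
#'                      i_eq_o = 2552 - 0.19 * c(1200, 1400, 1600))
#' fit_equilibrium_relation(eq)$r
#' @export
fit_equilibrium_relation <- function(equilibrium_birds) {
  df <- as_tibble(equilibrium_birds)
  need <- c("mass_g", "i_eq_d", "i_eq_o")
  if (!all(need %in% names(df))) {
    abort(sprintf("`equilibrium_birds` needs columns %s.",
                  paste(need, collapse = ", ")))
  }
  if (nrow(df) < 3) abort("Need >= 3 equilibrium birds.")
  if (sd(df$mass_g) == 0) abort("Zero mass variance: equilibrium fit is singular.")
  fit_one <- function(y) {
    m <- lm(y ~ mass_g, data = df)
    r <- if (sd(y) == 0) 1 else cor(df$mass_g, y)
    list(coef = setNames(coef(m), c("intercept", "slope")), r = r)
  }
  fd <- fit_one(df$i_eq_d)
  fo <- fit_one(df$i_eq_o)
  structure(
    list(d = fd, o = fo,
         valid = abs(fd$r) > 0.7 && abs(fo$r) > 0.7,
         mass_range = range(df$mass_g),
         n = nrow(df)),
    class = "equilibrium_relation"
  )
}

#' @export
print.equilibrium_relation <- function(x, ...) {
  cat("<equilibrium_relation>\n")
  cat(sprintf("  2H : intercept %.3f, slope %.5f, r = %.3f\n",
              x$d$coef[1], x$d$coef[2], x$d$r))
  cat(sprintf("  18O: intercept %.3f, slope %.5f, r = %.3f\n",
              x$o$coef[1], x$o$coef[2], x$o$r))
  cat(sprintf("  single-sample gate (|r| > 0.7 both isotopes): %s\n",
              if (x$valid) "PASS" else "FAIL"))
  invisible(x)
}

#' Predict initial enrichment for a single-sample bird
#'
#' Linear prediction of the equilibrium (initial) enrichment at a deployed
#' bird's capture mass, per isotope. Warns when the mass falls outside the
#' fitted mass range (extrapolation).
#'
#' @param relation An [fit_equilibrium_relation()] object.
#' @param mass_g Body mass(es) at injection [g].
#' @return A tibble with columns `i_init_d`, `i_init_o` [ppm].
#' @export
estimate_initial_enrichment <- function(relation, mass_g) {
  if (!inherits(relation, "equilibrium_relation")) {
    abort("`relation` must come from fit_equilibrium_relation().")
  }
  out_of_range <- mass_g < relation$mass_range[1] | mass_g > relation$mass_range[2]
  if (any(out_of_range)) {
    warn(sprintf("%d mass value(s) outside the fitted equilibrium mass range [%.0f, %.0f] g: extrapolating.",
                 sum(out_of_range), relation$mass_range[1], relation$mass_range[2]))
  }
  tibble(
    i_init_d = relation$d$coef[["intercept"]] + relation$d$coef[["slope"]] * mass_g,
    i_init_o = relation$o$coef[["intercept"]] + relation$o$coef[["slope"]] * mass_g
  )
}

#' Run the full single-sample DLW calculation on a cohort table
#'
#' Takes the cohort's DLW table (the `dlw.csv` schema: one row per bird with
#' `bird`, `set` ("equilibrium"/"deployed"), masses, background/initial/final
#' enrichments per isotope, dose and sampling interval), fits the
#' mass-equilibrium relation on the equilibrium set (unless a fitted relation
#' is supplied), predicts initial enrichments for the deployed set, and runs
#' turnover -> dilution spaces -> one-pool rCO2 -> DEE -> mass-specific DEE.
#'
#' @param dlw_tbl Data frame in the `dlw.csv` schema (see
#'   [simulate_cohort()]).
#' @param constants A [dlw_constants()] record.
#' @param relation Optional pre-fitted [fit_equilibrium_relation()]; by
#'   default fitted from the table's equilibrium rows.
#' @return A tibble with one row per deployed bird: `bird`, `mass_g` (the
#'   msDEE mass convention), `k_d`, `k_o`, `n_d`, `n_o`, `n_f`, `n`,
#'   `rco2_mmol_h`, `dee_kj_day`, `msdee`, `valid`.
#' @export
dlw_analyse <- function(dlw_tbl, constants = dlw_constants(), relation = NULL) {
  df <- as_tibble(dlw_tbl)
  dep <- df %>% filter(.data$set == "deployed")
  if (nrow(dep) == 0) abort("No deployed birds in `dlw_tbl`.")
  need_prediction <- any(is.na(dep$i_init_d)) || any(is.na(dep$i_init_o))
  if (need_prediction && is.null(relation)) {
    eq <- df %>% filter(.data$set == "equilibrium")
    if (nrow(eq) < 3) abort("Need >= 3 equilibrium birds to fit the relation (or supply `relation`).")
    relation <- fit_equilibrium_relation(
      tibble(mass_g = eq$mass_initial_g, i_eq_d = eq$i_init_d, i_eq_o = eq$i_init_o))
  }
  if (need_prediction) {
    pred <- estimate_initial_enrichment(relation, dep$mass_initial_g)
    i_init_d <- ifelse(is.na(dep$i_init_d), pred$i_init_d, dep$i_init_d)
    i_init_o <- ifelse(is.na(dep$i_init_o), pred$i_init_o, dep$i_init_o)
  } else {
    i_init_d <- dep$i_init_d
    i_init_o <- dep$i_init_o
  }
  t_eff <- dep$t_deploy_h - constants$equilibration_h
  k_d <- isotope_turnover(i_init_d, dep$i_final_d, dep$i_bg_d, t_eff, "2H")
  k_o <- isotope_turnover(i_init_o, dep$i_final_o, dep$i_bg_o, t_eff, "18O")
  n_d <- dilution_space(dep$mol_inj, dep$i_inj_d, i_init_d, dep$i_bg_d, "2H")
  n_o <- dilution_space(dep$mol_inj, dep$i_inj_o, i_init_o, dep$i_bg_o, "18O")
  fds <- final_dilution_space(n_o, dep$mass_initial_g, dep$mass_final_g)
  rco2 <- rco2_single_pool(fds$n, k_o, k_d, constants)
  dee <- dee_kj_per_day(as.numeric(rco2), constants)
  mass <- if (constants$msdee_mass == "mean") {
    (dep$mass_initial_g + dep$mass_final_g) / 2
  } else {
    dep$mass_initial_g
  }
  tibble(
    bird = dep$bird,
    mass_g = mass,
    k_d = k_d, k_o = k_o,
    n_d = n_d, n_o = n_o, n_f = fds$n_f, n = fds$n,
    rco2_mmol_h = as.numeric(rco2),
    dee_kj_day = dee,
    msdee = mass_specific_dee(dee, mass),
    valid = attr(rco2, "valid")
  )
}
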