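#' Simulate a blood-isotope panel consistent with a known DEE
#'
#' Inverts the one-pool DLW equations: given a bird's (true) daily energy
#' expenditure, masses and deployment interval, generates initial and final
#' enrichments for both isotopes such that running the DLW module on the
#' panel recovers the DEE exactly (with zero analytic noise). The initial
#' enrichments come from the scenario's true linear mass-equilibrium
#' relation; the deuterium turnover is the scenario's baseline water
#' turnover; the oxygen turnover is solved from the required CO2 production;
#' final enrichments follow exponential washout over the effective interval.
#' Optional multiplicative lognormal noise models analytic error on the
#' final-sample excess enrichments.
#'
#' @param true_dee_kj_day Target DEE (kJ day\eqn{^{-1}}); must be > 0.
#' @param mass_initial_g,mass_final_g Body masses [g].
#' @param deployment_h Total sampling interval [decimal h], including the
#'   equilibration hour.
#' @param scenario A [sim_scenario()] (isotope parameters are read from it).
#' @param enrichment_noise_cv Lognormal CV applied to the final-sample excess
#'   enrichments (default 0: exact round trip).
#' @param constants [dlw_constants()] used for the inversion; must match the
#'   constants used at analysis time for the round trip to be exact.
#' @param seed Optional integer seed for the noise draw.
#' @return One-row tibble in the `dlw.csv` deployed-bird schema (initial
#'   enrichments filled in; the single-sample analysis ignores them and
#'   predicts its own).
#' @examples
#' sc <- sim_scenario(seed = 1)
#' simulate_isotopes(1600, 1450, 1430, 48, sc)
#' @export
simulate_isotopes <- function(true_dee_kj_day, mass_initial_g, mass_final_g,
                              deployment_h, scenario,
                              enrichment_noise_cv = 0,
                              constants = dlw_constants(
                                equilibration_h = scenario$isotope$equilibration_h),
                              seed = NULL) {
  if (any(true_dee_kj_day <= 0)) abort("`true_dee_kj_day` must be > 0.")
  assert_number(enrichment_noise_cv, "enrichment_noise_cv", lower = 0)
  iso <- scenario$isotope
  t_eff <- deployment_h - constants$equilibration_h
  if (any(t_eff <= 0)) abort("Deployment shorter than the equilibration time.")

  i_init_d <- iso$eq_relation$d[["intercept"]] + iso$eq_relation$d[["slope"]] * mass_initial_g
  i_init_o <- iso$eq_relation$o[["intercept"]] + iso$eq_relation$o[["slope"]] * mass_initial_g
  if (any(i_init_d <= iso$i_bg[["d"]]) || any(i_init_o <= iso$i_bg[["o"]])) {
    abort("Mass-equilibrium relation gives enrichment at or below background: dose too small for this mass.")
  }

  n_o <- dilution_space(iso$mol_inj, iso$i_inj[["o"]], i_init_o, iso$i_bg[["o"]], "18O")
  n <- final_dilution_space(n_o, mass_initial_g, mass_final_g)$n

  rco2 <- true_dee_kj_day * 1000 / (constants$ml_per_mmol * constants$j_per_ml * 24)
  k_d <- iso$k_d
  k_o <- k_d + constants$dilution_coef *
    (rco2 / 1000 + constants$fractionation_coef * k_d * n) / n

  decay_d <- exp(-k_d * t_eff)
  decay_o <- exp(-k_o * t_eff)
  i_final_d <- iso$i_bg[["d"]] + (i_init_d - iso$i_bg[["d"]]) * decay_d
  i_final_o <- iso$i_bg[["o"]] + (i_init_o - iso$i_bg[["o"]]) * decay_o

  if (enrichment_noise_cv > 0) {
    sdlog <- sqrt(log(1 + enrichment_noise_cv^2))
    draw <- function(n_draw) rlnorm(n_draw, -sdlog^2 / 2, sdlog)
    noise_fun <- function() {
      i_final_d <<- iso$i_bg[["d"]] + (i_final_d - iso$i_bg[["d"]]) * draw(length(i_final_d))
      i_final_o <<- iso$i_bg[["o"]] + (i_final_o - iso$i_bg[["o"]]) * draw(length(i_final_o))
    }
    if (is.null(seed)) noise_fun() else withr::with_seed(seed, noise_fun())
  }
  if (any(i_final_d <= iso$i_bg[["d"]]) || any(i_final_o <= iso$i_bg[["o"]])) {
    abort("Final enrichment driven to background: deployment too long for this dose.")
  }

  tibble(
    set = "deployed",
    mass_initial_g = mass_initial_g,
    mass_final_g = mass_final_g,
    i_bg_d = iso$i_bg[["d"]], i_bg_o = iso$i_bg[["o"]],
    i_init_d = i_init_d, i_init_o = i_init_o,
    i_final_d = i_final_d, i_final_o = i_final_o,
    i_inj_d = iso$i_inj[["d"]], i_inj_o = iso$i_inj[["o"]],
    mol_inj = iso$mol_inj,
    t_deploy_h = deployment_h
  )
}
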