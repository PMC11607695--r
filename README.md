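# plungedee

Daily energy expenditure (DEE) of plunge-diving seabirds from
doubly-labelled water (DLW) and biologging.

Field metabolic rates of wild seabirds are usually measured with DLW over a
1-3 day deployment, while accelerometers, depth loggers and GPS record what
the bird actually did minute by minute. `plungedee` implements the full
analysis chain that connects the two for a colony-breeding plunge-diver
(the motivating system is a booby rearing chicks on a guano island):

- **Signal processing.** Vectorial dynamic body acceleration from 50 Hz
  tri-axial records,

  VeDBA = sqrt((Ax − Āx)² + (Ay − Āy)² + (Az − Āz)²),

  with the static (postural) component Ān taken as a centered 3 s running
  mean per axis, smoothed to 1 s and summed per minute (DBA); wingbeat
  frequency as the dominant non-DC FFT peak of the heave axis over 30 s
  windows, thinned to per-minute medians; dive fraction from 1 Hz depth
  (proportion of the minute below a 0.1 m wet threshold); GPS tracks
  interpolated to exact 1-min ticks with step lengths and a colony-presence
  indicator (≤ 0.5 km from the colony = 1, > 1 km = 0).
- **Behavioural classification.** A four-state hidden Markov model
  (colony, commuting, foraging, resting) over the four per-minute data
  streams, with Bernoulli, zero-inflated gamma and zero/one-inflated beta
  emissions, fitted by Baum-Welch EM and decoded by Viterbi. DBA is
  deliberately *not* a classification stream; it is joined to decoded
  states afterwards.
- **DLW energetics (single-sample protocol).** Per-isotope turnover
  k = ln[(I_init − I_bg)/(I_final − I_bg)] / T_eff, plateau dilution
  spaces N = Mol_inj (I_inj − I_init)/(I_init − I_bg), the percentage-mass
  final pool, the reduced one-pool CO2 production
  rCO2 = 1000[(N/2.078)(k_o − k_d) − 0.0062 k_d N] (mmol h⁻¹), and the
  energy conversion to kJ day⁻¹ and mass-specific DEE. Initial enrichments
  of deployed birds are predicted from a separate equilibrium cohort's
  mass-enrichment regression (Pearson r > 0.7 validity gate).
- **Time-energy models.** Daily standardization (× 24 / sampling hours),
  time budgets, and a 12-member candidate set of DEE models — five
  activity partitions × {time-budget, DBA} plus two nulls — fitted by OLS
  (zero intercept for time-budget designs, free intercept for DBA designs),
  ranked by AICc with the small-sample correction, with predictive
  correlations and activity-specific metabolic rates (kJ h⁻¹ g⁻¹, watts,
  ×BMR).
- **Synthetic cohorts with known ground truth.** A simulator generates the
  whole campaign — behavioural Markov chains, 50 Hz waveforms, plunge
  pulses, GPS tracks, and blood-isotope panels constructed by inverting the
  one-pool equations from an assigned true DEE — so every stage is testable
  end to end without any field data.

## Worked example

One-pool DLW arithmetic on a single blood panel:

```r
library(plungedee)
isotope_turnover(2000, 500, 150, t_eff_h = 47)  # 0.0354257 h^-1
dilution_space(0.05, 90000, 2000, 150)          # 2.378378 mol
rco2 <- rco2_single_pool(1.95, 0.040, 0.030)    # 9.021323 mmol h^-1
dee_kj_per_day(rco2)                            # 132.4013 kJ day^-1
```

A full synthetic cohort (20 single-sample birds, 46-61 h deployments, 5%
DLW noise) through the model stage:

```r
coh <- simulate_summary_cohort(sim_scenario(seed = 1))
ranking <- aicc_rank(fit_all_dee_models(coh$summaries))
head(ranking, 4)
#>                    design k   aicc daicc      r
#> 1   T: col+rest | com+for 3 -61.28 0.000 0.9130
#> 2   T: col | com+for+rest 3 -59.99 1.286 0.9069
#> 3 T: col+rest | com | for 4 -59.29 1.994 0.9182
#> 4 T: col | com+for | rest 4 -58.23 3.053 0.9135
```

The cohort's mass-specific DEE is 1.142 ± 0.109 kJ day⁻¹ g⁻¹
(mean ± s.d., n = 20), and the most parsimonious model groups colony with
resting and commuting with foraging — several merged designs sit within
ΔAICc < 2, the expected behaviour when group rates are similar. Its
activity-specific rates:

```r
best <- fit_all_dee_models(coh$summaries)[["T: col+rest | com+for"]]
activity_rates(best, mass_ref_g = mean(coh$summaries$mass_g))
#>        group mr_kj_h_g watts x_bmr ratio_vs_colony
#> 1 t_col.rest    0.0338  14.0  3.19            1.00
#> 2  t_com.for    0.1068  44.2 10.06            3.16
```

So time at or near the colony costs ~0.034 kJ h⁻¹ g⁻¹ while flight and
plunge-foraging cost ~3.2× as much; the model's predicted vs observed
msDEE correlate at r = 0.91 on this clean synthetic cohort. `tidy()`,
`glance()` and `autoplot()` methods cover the fitted objects, and
`run_pipeline(run_config(...))` executes the whole chain (simulate →
features → classify → DLW → models) into a run directory of delimited-text
tables plus a report.

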