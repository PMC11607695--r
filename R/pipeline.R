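#' Configuration for a full pipeline run
#'
#' Bundles the scenario (for simulation mode), the signal constants, the
#' HMM starting specification and fitting controls, the DLW constants, the
#' candidate-model set and the reference BMR into one record. A run is
#' deterministic given the scenario seed.
#'
#' @param scenario A [sim_scenario()].
#' @param outdir Output directory for the run (one run = one directory with
#'   every intermediate table, the config and a log).
#' @param wingbeat_stride_s Stride of the wingbeat FFT windows in the
#'   feature stage [s]. The per-window operation defaults to 1 s; the
#'   pipeline uses non-overlapping 30 s windows, which changes the
#'   per-minute median by at most one bin on sustained flight.
#' @param hmm_start Starting [hmm_spec()].
#' @param hmm_max_iter,hmm_tol EM controls.
#' @param constants A [dlw_constants()] record.
#' @param designs A [candidate_models()] set.
#' @param bmr_w Reference basal metabolic rate [W].
#' @param write_sensors Also write raw `accel.csv`/`depth.csv`/`gps.csv`
#'   per bird (large; off by default).
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = sim_scenario(),
                       outdir = tempfile("plungedee_run_"),
                       wingbeat_stride_s = 30,
                       hmm_start = default_hmm_spec(),
                       hmm_max_iter = 50,
                       hmm_tol = 1e-5,
                       constants = dlw_constants(
                         equilibration_h = scenario$isotope$equilibration_h),
                       designs = candidate_models(),
                       bmr_w = 4.39,
                       write_sensors = FALSE) {
  validate_scenario(scenario)
  validate_hmm_spec(hmm_start)
  structure(
    list(scenario = scenario, outdir = outdir,
         wingbeat_stride_s = wingbeat_stride_s,
         hmm_start = hmm_start, hmm_max_iter = hmm_max_iter,
         hmm_tol = hmm_tol, constants = constants, designs = designs,
         bmr_w = bmr_w, write_sensors = write_sensors),
    class = "run_config")
}

#' Run the full pipeline on a simulated cohort
#'
#' Orchestrates simulate -> features -> classify -> DLW -> models: simulates
#' the cohort from the config's scenario, builds per-minute observation
#' tables bird by bird from the raw 50 Hz / 1 Hz / 1-min streams, fits and
#' decodes the four-state HMM (pooled across birds, initial distribution
#' resetting at record boundaries), runs the single-sample DLW calculation,
#' assembles daily activity summaries, fits and AICc-ranks the candidate
#' DEE models, and derives activity-specific rates from the best
#' time-budget design. Every intermediate table is written to the run
#' directory as delimited text together with a run report; any stage
#' failure aborts naming the stage and bird, preserving partial outputs.
#'
#' @param config A [run_config()].
#' @return A list of class `dee_run`: `minutes`, `decoded`, `dlw_results`,
#'   `summaries`, `ranking`, `rates`, `hmm`, `truth`, `qc`, `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$outdir, "run.log")
  say <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, bird, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed%s: %s", name,
                    if (is.null(bird)) "" else paste0(" for bird ", bird),
                    conditionMessage(e)))
    })
  }
  dput_file <- file.path(config$outdir, "config.R")
  dput(config[setdiff(names(config), c("hmm_start", "designs"))],
       file = dput_file)

  sc <- config$scenario
  say("simulate: cohort of %d equilibrium + %d deployed birds (seed %d)",
      sc$n_equilibrium_birds, sc$n_deployed_birds, sc$seed)
  cohort <- stage("simulate", NULL, simulate_cohort(sc))
  readr::write_csv(cohort$dlw, file.path(config$outdir, "dlw.csv"))
  readr::write_csv(cohort$truth, file.path(config$outdir, "truth.csv"))

  birds <- unique(cohort$states$bird)
  minutes_list <- vector("list", length(birds))
  for (i in seq_along(birds)) {
    b <- birds[i]
    say("features: bird %s", b)
    st <- cohort$states %>% filter(.data$bird == b)
    sb <- stage("sensors", b, simulate_sensors(mutate(st, bird = i), sc))
    if (config$write_sensors) {
      bdir <- file.path(config$outdir, b)
      dir.create(bdir, showWarnings = FALSE)
      readr::write_csv(sb$accel, file.path(bdir, "accel.csv"))
      readr::write_csv(sb$depth, file.path(bdir, "depth.csv"))
      readr::write_csv(sb$gps, file.path(bdir, "gps.csv"))
    }
    mf <- stage("features", b, minute_features(
      sb$accel, sb$depth, sb$gps, sc$colony,
      wingbeat_stride_s = config$wingbeat_stride_s))
    minutes_list[[i]] <- mutate(mf, bird = b, .before = 1)
    rm(sb)
  }
  minutes <- bind_rows(minutes_list)
  readr::write_csv(minutes, file.path(config$outdir, "minutes.csv"))

  say("classify: fitting 4-state HMM on %d minutes", nrow(minutes))
  fit <- stage("classify", NULL, hmm_fit(minutes, config$hmm_start,
                                         max_iter = config$hmm_max_iter,
                                         tol = config$hmm_tol))
  decoded <- stage("decode", NULL, hmm_decode(fit, minutes))
  readr::write_csv(decoded, file.path(config$outdir, "states.csv"))

  say("dlw: single-sample analysis of %d deployed birds", length(birds))
  dlw_results <- stage("dlw", NULL, dlw_analyse(cohort$dlw, config$constants))
  readr::write_csv(dlw_results, file.path(config$outdir, "dlw_results.csv"))

  say("models: daily summaries and AICc ranking")
  summaries <- stage("summaries", NULL, daily_activity_summary(
    decoded, minutes, dlw_results,
    meta = select(cohort$truth, "bird", "sex")))
  readr::write_csv(summaries, file.path(config$outdir, "summaries.csv"))
  fits <- stage("models", NULL, fit_all_dee_models(summaries, config$designs))
  ranking <- aicc_rank(fits)
  readr::write_csv(ranking, file.path(config$outdir, "model_ranking.csv"))
  best_time <- fits[[ranking$design[ranking$kind == "time"][1]]]
  rates <- activity_rates(best_time, mass_ref_g = mean(summaries$mass_g),
                          bmr_w = config$bmr_w)
  readr::write_csv(rates, file.path(config$outdir, "activity_rates.csv"))

  qc <- tibble(
    check = c("partial minutes", "gps gap minutes", "invalid rCO2 birds"),
    n = c(sum(minutes$partial), sum(minutes$gap, na.rm = TRUE),
          sum(!dlw_results$valid))
  )
  run <- structure(
    list(minutes = minutes, decoded = decoded, dlw_results = dlw_results,
         summaries = summaries, ranking = ranking, rates = rates,
         hmm = fit, truth = cohort$truth, qc = qc, outdir = config$outdir),
    class = "dee_run")
  writeLines(report_lines(run), file.path(config$outdir, "report.txt"))
  say("done: %s", config$outdir)
  run
}

report_lines <- function(run) {
  s <- run$summaries
  budget <- colMeans(s[c("t_col", "t_com", "t_for", "t_rest")])
  c("plungedee run report",
    strrep("=", 60),
    sprintf("birds: %d | minutes: %d", nrow(s), nrow(run$minutes)),
    sprintf("msDEE (kJ/day/g): %.3f +/- %.3f (mean +/- sd)",
            mean(s$msdee), sd(s$msdee)),
    sprintf("mean time budget (h/24h): colony %.2f, commuting %.2f, foraging %.2f, resting %.2f",
            budget[1], budget[2], budget[3], budget[4]),
    "",
    "model ranking (AICc):",
    utils::capture.output(as.data.frame(run$ranking)),
    "",
    "activity rates (best time-budget design):",
    utils::capture.output(as.data.frame(run$rates)),
    "",
    "QC:",
    utils::capture.output(as.data.frame(run$qc)))
}

#' @export
print.dee_run <- function(x, ...) {
  cat(sprintf("<dee_run> %d birds | best model: %s (r = %s)\n",
              nrow(x$summaries), x$ranking$design[1],
              ifelse(is.na(x$ranking$r[1]), "undefined",
                     sprintf("%.3f", x$ranking$r[1]))))
  cat("  outputs in ", x$outdir, "\n", sep = "")
  invisible(x)
}

#' Validate logger export files for one bird
#'
#' Schema and sampling-rate QC on a bird's directory of delimited-text
#' logger exports: required columns, strictly increasing timestamps
#' (reporting the first bad row), nominal rate conformity (50 Hz
#' acceleration, 1 Hz depth, 1-min GPS within tolerance) and coverage gaps.
#'
#' @param dir Directory containing `accel.csv`, `depth.csv`, `gps.csv`.
#' @param rate_tol Relative tolerance on the median sampling interval.
#' @param gap_factor A gap is flagged when an interval exceeds this multiple
#'   of the nominal interval.
#' @return A QC tibble: `file`, `check`, `ok`, `detail`.
#' @export
validate_inputs <- function(dir, rate_tol = 0.01, gap_factor = 5) {
  specs <- list(
    accel.csv = list(cols = c("t", "ax", "ay", "az"), dt = 1 / 50),
    depth.csv = list(cols = c("t", "depth_m"), dt = 1),
    gps.csv = list(cols = c("t", "lon", "lat"), dt = 60)
  )
  rows <- list()
  add <- function(file, check, ok, detail = "") {
    rows[[length(rows) + 1L]] <<- tibble(file = file, check = check,
                                         ok = ok, detail = detail)
  }
  for (f in names(specs)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) {
      add(f, "exists", FALSE, "file not found")
      next
    }
    df <- tryCatch(readr::read_csv(path, show_col_types = FALSE),
                   error = function(e) NULL)
    if (is.null(df)) {
      add(f, "readable", FALSE, "parse failure")
      next
    }
    add(f, "exists", TRUE)
    miss <- setdiff(specs[[f]]$cols, names(df))
    add(f, "schema", length(miss) == 0,
        if (length(miss)) paste("missing:", paste(miss, collapse = ", ")) else "")
    if (length(miss) > 0 || nrow(df) < 3) next
    dts <- diff(df$t)
    bad <- which(dts <= 0)
    add(f, "monotone timestamps", length(bad) == 0,
        if (length(bad)) sprintf("first bad row %d", bad[1] + 1L) else "")
    nominal <- specs[[f]]$dt
    med <- median(dts)
    add(f, "sampling rate", abs(med - nominal) <= rate_tol * nominal,
        sprintf("median interval %.4g s (nominal %.4g s)", med, nominal))
    gaps <- which(dts > gap_factor * nominal)
    add(f, "coverage gaps", length(gaps) == 0,
        if (length(gaps)) sprintf("%d gap(s), longest %.1f s",
                                  length(gaps), max(dts[gaps])) else "")
  }
  bind_rows(rows)
}
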