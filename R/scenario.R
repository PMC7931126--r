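#' Run one simulation scenario
#'
#' Evolves the synthetic population year by year from the profile's start
#' year to `end_year`, applying in fixed order: ageing, births, net
#' migration, background mortality, remission, incident cancers with their
#' fatality plans, scheduled cancer deaths, and finally the yearly
#' cross-section with costs. With `intervention = NULL` this is the
#' business-as-usual counterfactual; with an `intervention_spec` the exposed
#' individuals' risk-factor exposures are shifted from the implementation
#' year onwards. Two runs with the same seed share every random draw until
#' their states diverge, so a zero-effect intervention reproduces the
#' counterfactual bit for bit.
#'
#' @param inputs a `model_inputs` bundle.
#' @param intervention an `intervention_spec`, or `NULL` for
#'   business-as-usual.
#' @param seed integer master seed of the run.
#' @param end_year last simulated calendar year.
#' @param implementation_year year the intervention starts (effects apply
#'   from the following simulated year's mid-point).
#' @param keep_population keep the final `population` object on the result.
#' @return an object of class `run_result` with tidy tables: `incidence`
#'   (year, cancer, age_band, age, sex, n), `expected_incidence` (the
#'   calibration target: sum of baseline rates over the at-risk
#'   population), `prevalence` (active case-years), `deaths` (cancer
#'   deaths by age and sex), `remissions`, `expenditure` (USD PPP by year
#'   and cancer), `person_years`, `dalys`, `demography` (headcount
#'   accounting), `events` (the disease-event log) and `meta`.
#' @export
run_scenario <- function(inputs, intervention = NULL, seed = 1L,
                         end_year = 2050L, implementation_year = 2019L,
                         keep_population = FALSE) {
  profile <- inputs$profile
  ctx <- .build_sim_context(inputs)
  int_ctx <- if (!is.null(intervention)) {
    .build_intervention_context(intervention, inputs$elasticities,
                                implementation_year)
  }
  pop <- initialize_population(profile, seed, ctx$Q)
  years <- seq.int(profile$start_year + 1L, end_year)
  rec <- new.env(parent = emptyenv())
  for (nm in c("incidence", "expected", "prevalence", "deaths",
               "remissions", "expenditure", "person_years")) {
    rec[[nm]] <- vector("list", length(years))
  }
  for (k in seq_along(years)) {
    y <- years[k]
    pop <- step_demographics(pop, profile, seed)
    pop <- .sim_disease_year(pop, ctx, seed, y, int_ctx, inputs$costs, rec, k)
  }
  run <- list(
    incidence = rbindlist(rec$incidence),
    expected_incidence = rbindlist(rec$expected),
    prevalence = rbindlist(rec$prevalence),
    deaths = rbindlist(rec$deaths),
    remissions = rbindlist(rec$remissions),
    expenditure = rbindlist(rec$expenditure),
    person_years = rbindlist(rec$person_years),
    demography = copy(pop$demography),
    events = disease_event_log(pop),
    meta = list(
      seed = seed,
      intervention = if (is.null(intervention)) "baseline" else intervention$name,
      years = years,
      implementation_year = implementation_year,
      scale = sum(profile$pyramid$count),
      n_quantiles = ctx$Q,
      ppp_factor = profile$ppp_factor
    )
  )
  run$dalys <- compute_dalys(run, inputs$costs$disability_weight,
                             make_life_table(profile))
  if (keep_population) run$population <- pop
  structure(run, class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %s, %d-%d, %d individuals at start\n",
              x$meta$intervention, min(x$meta$years), max(x$meta$years),
              x$meta$scale))
  cat(sprintf("  incident cases %d, cancer deaths %d, expenditure %.0f USD PPP\n",
              sum(x$incidence$n), sum(x$deaths$n), sum(x$expenditure$amount)))
  invisible(x)
}

# One disease-and-accounting year. `rec` is the caller's recording
# environment: yearly tables are assigned into its list slots at position
# `k`; the advanced population is returned.
.sim_disease_year <- function(pop, ctx, seed, y, int_ctx, costs, rec, k) {
  pop <- apply_remission(pop, y)
  tab <- pop$tab
  n <- nrow(tab)
  hz <- .compute_hazards(tab, ctx, y, int_ctx)
  age <- pmin(y - tab$birth_year, 100L)
  bi <- age_band_index(age)
  si <- sex_index(tab$sex)

  new_cases <- vector("list", length(CANCERS))
  for (ci in seq_along(CANCERS)) {
    cc <- CANCERS[ci]
    set.seed(substream_seed(seed, y, 40L + ci))
    u <- runif(n)
    idx <- which(hz[[cc]]$eligible & u < hz[[cc]]$hazard)
    new_cases[[ci]] <- idx
    if (length(idx)) {
      set(tab, i = idx, j = paste0("diag_", cc), value = y)
      # full-row survival streams, subset at the case rows, so paired runs
      # give a given individual the same fatality plan either way
      set.seed(substream_seed(seed, y, 50L + ci))
      dr <- .draw_survival(n, ctx$p5y[cbind(bi, si, ci)], ctx$cw)
      will_die <- dr$will_die[idx]
      set(tab, i = idx, j = paste0("die_", cc), value = will_die)
      dyear <- rep(NA_integer_, length(idx))
      dyear[will_die] <- y + dr$years[idx][will_die] - 1L
      set(tab, i = idx, j = paste0("dyear_", cc), value = dyear)
    }
  }

  # scheduled cancer deaths falling due this year (possibly same-year cases)
  death_cancer <- rep(NA_character_, n)
  for (cc in rev(CANCERS)) {  # reverse so earlier list order wins ties
    dy <- tab[[paste0("dyear_", cc)]]
    hit <- !is.na(dy) & dy == y & tab$alive
    death_cancer[hit] <- cc
  }
  dying <- which(!is.na(death_cancer) & tab$alive)
  if (length(dying)) {
    set(tab, i = dying, j = "alive", value = FALSE)
    set(tab, i = dying, j = "dead_year", value = y)
    set(tab, i = dying, j = "death_cause", value = "cancer")
    set(tab, i = dying, j = "death_cancer", value = death_cancer[dying])
  }

  # ---- yearly cross-section, costs, accounting ---------------------------
  alive_during <- (tab$alive | (!is.na(tab$dead_year) & tab$dead_year == y)) &
    tab$migration_status != "emigrated"
  active <- matrix(FALSE, n, length(CANCERS))
  for (ci in seq_along(CANCERS)) {
    cc <- CANCERS[ci]
    diag <- tab[[paste0("diag_", cc)]]
    rem <- tab[[paste0("remiss_", cc)]]
    active[, ci] <- !is.na(diag) & diag <= y & (is.na(rem) | rem > y) &
      alive_during
  }
  kk <- rowSums(active)
  terminal <- !is.na(tab$death_cause) & tab$death_cause == "cancer" &
    !is.na(tab$dead_year) & tab$dead_year == y
  fac <- (1 + costs$multimorbidity_increment * pmax(kk - 1, 0)) *
    ifelse(terminal, costs$last_year_multiplier, 1)

  exp_rows <- prev_rows <- inc_rows <- exp_base_rows <-
    death_rows <- rem_rows <- vector("list", length(CANCERS))
  for (ci in seq_along(CANCERS)) {
    cc <- CANCERS[ci]
    amt <- sum(costs$annual_cost[[cc]] * fac[active[, ci]])
    exp_rows[[ci]] <- data.table(year = y, cancer = cc, amount = amt)
    prev_rows[[ci]] <- data.table(year = y, cancer = cc,
                                  n = sum(active[, ci]))
    idx <- new_cases[[ci]]
    inc_rows[[ci]] <- if (length(idx)) {
      data.table(year = y, cancer = cc,
                 age_band = AGE_BAND_LABELS[bi[idx]], age = age[idx],
                 sex = tab$sex[idx])[, .(n = .N),
                                     by = .(year, cancer, age_band, age, sex)]
    } else {
      data.table(year = integer(), cancer = character(),
                 age_band = character(), age = integer(),
                 sex = character(), n = integer())
    }
    exp_base_rows[[ci]] <- data.table(year = y, cancer = cc,
                                      expected = hz[[cc]]$expected_baseline)
    didx <- which(!is.na(tab$death_cancer) & tab$death_cancer == cc &
                    !is.na(tab$dead_year) & tab$dead_year == y)
    death_rows[[ci]] <- if (length(didx)) {
      data.table(year = y, cancer = cc, age = age[didx],
                 sex = tab$sex[didx])[, .(n = .N), by = .(year, cancer, age, sex)]
    } else {
      data.table(year = integer(), cancer = character(), age = integer(),
                 sex = character(), n = integer())
    }
    rem <- tab[[paste0("remiss_", cc)]]
    rem_rows[[ci]] <- data.table(year = y, cancer = cc,
                                 n = sum(!is.na(rem) & rem == y))
  }
  rec$incidence[[k]] <- rbindlist(inc_rows)
  rec$expected[[k]] <- rbindlist(exp_base_rows)
  rec$prevalence[[k]] <- rbindlist(prev_rows)
  rec$deaths[[k]] <- rbindlist(death_rows)
  rec$remissions[[k]] <- rbindlist(rem_rows)
  rec$expenditure[[k]] <- rbindlist(exp_rows)
  rec$person_years[[k]] <- data.table(year = y, py = sum(.present(tab)))

  # demography accounting: cancer deaths reduce the end-of-year headcount
  dem <- pop$demography
  set(dem, i = nrow(dem), j = "deaths_cancer", value = length(dying))
  set(dem, i = nrow(dem), j = "n_end", value = sum(.present(tab)))
  pop$tab <- tab
  pop
}

#' Scenario configuration
#'
#' Bundles everything a paired run needs: the synthetic-input seed and
#' scale, the intervention, the horizon (interventions are implemented in
#' 2019 with results expressed over 2020-2050 by default), the number of
#' paired replicates and the master seed.
#'
#' @param intervention one of the six intervention names.
#' @param scale synthetic population size.
#' @param n_quantiles quantile bins per risk factor.
#' @param seed master seed; replicate seeds are derived from it.
#' @param start_year first calendar year (initial cross-section).
#' @param implementation_year intervention start year.
#' @param end_year last simulated year.
#' @param report_start first year entering the reported outcomes.
#' @param replicates number of paired replicate runs (>= 1).
#' @param outdir optional output directory for result files.
#' @param input_seed seed of the synthetic inputs (default: `seed`).
#' @param workdays workdays per week for the workplace programme.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(intervention, scale = 20000L, n_quantiles = 5L,
                            seed = 1L, start_year = 2019L,
                            implementation_year = 2019L, end_year = 2050L,
                            report_start = 2020L, replicates = 5L,
                            outdir = NULL, input_seed = NULL, workdays = 5) {
  if (!intervention %in% INTERVENTION_NAMES) {
    stop_invalid("unknown intervention '%s'", intervention)
  }
  if (end_year <= start_year) stop_invalid("end_year must exceed start_year")
  if (replicates < 1) stop_invalid("replicates must be >= 1")
  structure(
    list(intervention = intervention, scale = as.integer(scale),
         n_quantiles = as.integer(n_quantiles), seed = as.integer(seed),
         start_year = as.integer(start_year),
         implementation_year = as.integer(implementation_year),
         end_year = as.integer(end_year),
         report_start = as.integer(report_start),
         replicates = as.integer(replicates), outdir = outdir,
         input_seed = if (is.null(input_seed)) as.integer(seed)
                      else as.integer(input_seed),
         workdays = workdays),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from a YAML file
#'
#' @param path YAML file whose keys match the [scenario_config()] arguments.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_invalid("unknown config keys: %s", paste(unknown, collapse = ", "))
  }
  do.call(scenario_config, vals)
}

#' Run a paired counterfactual/intervention scenario
#'
#' For each replicate seed derived from the master seed, runs one
#' business-as-usual and one intervention scenario sharing that seed
#' (common random numbers), compares them, and summarises cases avoided,
#' expenditure savings per capita per year and DALYs averted with
#' replicate-based 95% confidence intervals. If `config$outdir` is set,
#' writes `summary.csv`, `yearly_cases_avoided.csv`, `summary.json` and a
#' `run_log.json` with the seeds and configuration.
#'
#' @param config a `scenario_config`.
#' @param inputs optional pre-built `model_inputs` (default: generated from
#'   `config$input_seed`).
#' @return an object of class `paired_scenario_result`: list with `spec`,
#'   `comparisons` (one `scenario_comparison` per replicate), `summary`
#'   (data.table: metric, estimate, lower, upper) and `config`.
#' @export
run_paired_scenario <- function(config, inputs = NULL) {
  if (!inherits(config, "scenario_config")) {
    stop_invalid("`config` must be a scenario_config")
  }
  if (is.null(inputs)) {
    inputs <- generate_model_inputs(config$input_seed, config$scale,
                                    config$n_quantiles, config$start_year)
  }
  spec <- build_intervention(config$intervention, workdays = config$workdays)
  seeds <- vapply(seq_len(config$replicates),
                  function(r) substream_seed(config$seed, 0L, 1000L + r), 1L)
  comparisons <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    base <- run_scenario(inputs, NULL, seeds[r], config$end_year,
                         config$implementation_year)
    intr <- run_scenario(inputs, spec, seeds[r], config$end_year,
                         config$implementation_year)
    comparisons[[r]] <- compare_scenarios(base, intr,
                                          report_start = config$report_start)
  }
  metric <- function(f) vapply(comparisons, f, 1.0)
  metrics <- c(
    list(cases_avoided_total = metric(function(x) x$cases_avoided_total),
         savings_per_capita_per_year =
           metric(function(x) x$savings_per_capita_per_year),
         dalys_averted = metric(function(x) x$dalys_averted)),
    setNames(lapply(CANCERS, function(cc) {
      metric(function(x) {
        v <- x$cases_avoided_by_cancer[cancer == cc, avoided]
        if (length(v)) sum(v) else 0
      })
    }), paste0("cases_avoided_", CANCERS))
  )
  summarise <- function(v) {
    if (length(v) >= 2) replicate_ci(v)
    else list(estimate = v, lower = NA_real_, upper = NA_real_)
  }
  summ <- rbindlist(lapply(names(metrics), function(m) {
    ci <- summarise(metrics[[m]])
    data.table(metric = m, estimate = ci$estimate,
               lower = ci$lower, upper = ci$upper)
  }))
  yearly <- rbindlist(lapply(comparisons,
                             function(x) x$cases_avoided_by_year))
  yearly <- yearly[, .(avoided = mean(avoided)), by = year][order(year)]
  result <- structure(
    list(spec = spec, comparisons = comparisons, summary = summ,
         yearly_cases_avoided = yearly, seeds = seeds, config = config),
    class = "paired_scenario_result"
  )
  if (!is.null(config$outdir)) write_paired_result(result, config$outdir)
  result
}

#' @export
print.paired_scenario_result <- function(x, ...) {
  cat(sprintf("<paired_scenario_result> %s, %d replicates, %d-%d\n",
              x$spec$label, length(x$comparisons),
              x$config$report_start, x$config$end_year))
  print(x$summary)
  invisible(x)
}

#' Write paired-scenario artifacts to disk
#'
#' @param result a `paired_scenario_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_paired_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fwrite(result$summary, file.path(dir, "summary.csv"))
  fwrite(result$yearly_cases_avoided,
         file.path(dir, "yearly_cases_avoided.csv"))
  jsonlite::write_json(
    list(intervention = result$config$intervention,
         replicates = result$config$replicates,
         summary = result$summary),
    file.path(dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(config = unclass(result$config)[!vapply(result$config, is.null, TRUE)],
         replicate_seeds = result$seeds,
         package_version = as.character(utils::packageVersion("oncoprev"))),
    file.path(dir, "run_log.json"), auto_unbox = TRUE
  )
  invisible(dir)
}
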