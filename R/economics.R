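#' Annual treatment cost of one individual
#'
#' Per-case annual cost basis: the sum over the individual's active
#' (non-remitted) cancers of the per-cancer annual cost, multiplied by the
#' last-year-of-life multiplier in the year of cancer death and by the
#' multimorbidity factor `1 + increment * (k - 1)` where `k` is the number
#' of concurrent active cancers.
#'
#' @param cancers character vector of the individual's active cancers in
#'   the costed year (possibly empty).
#' @param costs a `cost_profile`.
#' @param terminal `TRUE` if the costed year is the individual's year of
#'   cancer death.
#' @return cost in USD PPP for that individual-year.
#' @export
#' @examples
#' co <- generate_cost_profile(1)
#' annual_cost(character(0), co)       # 0
#' annual_cost(c("breast", "liver"), co)
annual_cost <- function(cancers, costs, terminal = FALSE) {
  k <- length(cancers)
  if (k == 0) return(0)
  if (!all(cancers %in% names(costs$annual_cost))) {
    stop_invalid("unknown cancer in cost lookup")
  }
  sum(costs$annual_cost[cancers]) *
    (1 + costs$multimorbidity_increment * (k - 1)) *
    (if (terminal) costs$last_year_multiplier else 1)
}

#' Period life table from a country profile
#'
#' Builds survivorship from the background mortality schedule and returns
#' the remaining life expectancy at each age, used to value years of life
#' lost at the age of a cancer death.
#'
#' @param profile a `country_profile`.
#' @return data.table (age, sex, ex).
#' @export
make_life_table <- function(profile) {
  out <- vector("list", 2L)
  for (si in 1:2) {
    q <- profile$mortality[profile$mortality$sex == SEXES[si], ]
    q <- q$qx[order(q$age)]
    n <- length(q)                      # ages 0..100
    l <- cumprod(c(1, 1 - q))           # survivorship to exact age 0..101
    L <- (l[-(n + 1)] + l[-1]) / 2      # person-years lived in each age
    T <- rev(cumsum(rev(L)))
    out[[si]] <- data.table(age = 0:(n - 1), sex = SEXES[si],
                            ex = T / l[-(n + 1)])
  }
  rbindlist(out)
}

#' Disability-adjusted life years of a run
#'
#' YLD = active (non-remitted) prevalent case-years times the cancer's
#' disability weight; YLL = cancer deaths times the life-table remaining
#' life expectancy at the age of death; DALY = YLL + YLD, undiscounted.
#'
#' @param run a `run_result`.
#' @param disability_weights named vector of weights in `[0, 1]` per cancer.
#' @param life_table data.table (age, sex, ex) as from [make_life_table()].
#' @return data.table (year, cancer, yld, yll, daly).
#' @export
compute_dalys <- function(run, disability_weights, life_table) {
  yld <- copy(run$prevalence)
  yld[, yld := n * disability_weights[cancer]]
  lt <- as.data.table(life_table)
  dd <- copy(run$deaths)
  if (nrow(dd)) {
    dd[, age := pmin(age, max(lt$age))]
    dd <- lt[dd, on = c("age", "sex")]
    yll <- dd[, .(yll = sum(n * ex)), by = .(year, cancer)]
  } else {
    yll <- data.table(year = integer(), cancer = character(), yll = numeric())
  }
  out <- merge(yld[, .(year, cancer, yld)], yll,
               by = c("year", "cancer"), all = TRUE)
  out[is.na(yld), yld := 0]
  out[is.na(yll), yll := 0]
  out[, daly := yld + yll]
  out[order(year, cancer)]
}

#' Compare an intervention run against its business-as-usual counterfactual
#'
#' Differences two runs paired on the same seed (common random numbers):
#' cases avoided per (year, cancer, age band, sex), total expenditure
#' savings in USD PPP, savings per capita per year (person-year
#' denominator), and DALYs averted.
#'
#' @param baseline,intervention `run_result`s sharing seed and horizon.
#' @param ppp local-currency per USD-PPP conversion (default: the
#'   baseline's profile factor).
#' @param report_start first calendar year included (default: all years).
#' @return an object of class `scenario_comparison`.
#' @export
compare_scenarios <- function(baseline, intervention, ppp = NULL,
                              report_start = NULL) {
  if (!identical(baseline$meta$years, intervention$meta$years)) {
    stop_invalid("runs do not share the same horizon")
  }
  if (is.null(ppp)) ppp <- baseline$meta$ppp_factor
  keep <- function(dt) {
    if (is.null(report_start)) dt else dt[dt$year >= report_start, ]
  }
  bi <- keep(baseline$incidence)
  ii <- keep(intervention$incidence)
  keys <- intersect(c("year", "cancer", "age_band", "age", "sex"),
                    intersect(names(bi), names(ii)))
  det <- merge(bi, ii, by = keys,
               all = TRUE, suffixes = c("_baseline", "_intervention"))
  for (col in c("n_baseline", "n_intervention")) {
    det[is.na(det[[col]]), (col) := 0L]
  }
  det[, avoided := n_baseline - n_intervention]
  exp_b <- sum(keep(baseline$expenditure)$amount)
  exp_i <- sum(keep(intervention$expenditure)$amount)
  py <- sum(keep(baseline$person_years)$py)
  daly_b <- sum(keep(baseline$dalys)$daly)
  daly_i <- sum(keep(intervention$dalys)$daly)
  years <- baseline$meta$years
  if (!is.null(report_start)) years <- years[years >= report_start]
  structure(
    list(
      cases_avoided = det,
      cases_avoided_total = sum(det$avoided),
      cases_avoided_by_cancer = det[, .(avoided = sum(avoided)), by = cancer],
      cases_avoided_by_year = det[, .(avoided = sum(avoided)), by = year],
      savings_total = (exp_b - exp_i) / ppp,
      savings_per_capita_per_year = (exp_b - exp_i) / ppp / py,
      person_years = py,
      dalys_averted = daly_b - daly_i,
      years = years,
      intervention = intervention$meta$intervention
    ),
    class = "scenario_comparison"
  )
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("<scenario_comparison> %s vs business-as-usual, %d-%d\n",
              x$intervention, min(x$years), max(x$years)))
  cat(sprintf("  cases avoided: %d (breast %d, colorectal %d, oesophageal %d, liver %d)\n",
              x$cases_avoided_total,
              x$cases_avoided_by_cancer[cancer == "breast", avoided],
              x$cases_avoided_by_cancer[cancer == "colorectal", avoided],
              x$cases_avoided_by_cancer[cancer == "oesophageal", avoided],
              x$cases_avoided_by_cancer[cancer == "liver", avoided]))
  cat(sprintf("  expenditure savings: %.0f USD PPP (%.4f per capita per year)\n",
              x$savings_total, x$savings_per_capita_per_year))
  cat(sprintf("  DALYs averted: %.1f\n", x$dalys_averted))
  invisible(x)
}

#' Replicate-based confidence interval
#'
#' Point estimate and percentile-bootstrap interval for the mean of a
#' statistic computed over independent replicate seeds: replicate values
#' are resampled with replacement, the mean of each resample is taken, and
#' the interval is the percentile band of those bootstrap means. Constant
#' replicates give a degenerate interval at their value.
#'
#' @param values numeric vector of per-replicate statistics (>= 2).
#' @param level interval level (default 0.95).
#' @param B bootstrap resamples.
#' @param boot_seed seed of the bootstrap resampling (fixed by default so
#'   the interval is a deterministic function of the replicate values).
#' @return list with `estimate` (replicate mean), `lower`, `upper`,
#'   `level` and `n_replicates`.
#' @export
#' @examples
#' replicate_ci(c(10, 11, 9, 12, 10))
replicate_ci <- function(values, level = 0.95, B = 2000L,
                         boot_seed = 20201018L) {
  if (length(values) < 2) stop_invalid("need at least 2 replicates")
  est <- mean(values)
  if (diff(range(values)) == 0) {
    return(list(estimate = est, lower = est, upper = est,
                level = level, n_replicates = length(values)))
  }
  set.seed(boot_seed)
  m <- matrix(sample(values, length(values) * B, replace = TRUE), nrow = B)
  means <- rowMeans(m)
  qs <- unname(quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
  list(estimate = est, lower = qs[1], upper = qs[2],
       level = level, n_replicates = length(values))
}
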