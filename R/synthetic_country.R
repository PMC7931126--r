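#' Generate a synthetic country profile
#'
#' Builds the demographic world the simulation runs in: a stylised stable
#' population pyramid (ages 0-100 by sex), Gompertz-Makeham background
#' mortality (net of the modelled cancer deaths), an age-specific fertility
#' schedule and a small net-migration schedule, plus a purchasing-power-parity
#' conversion factor. No fidelity to any real country is claimed; the profile
#' has the statistical structure the downstream modules assume.
#'
#' @param seed integer seed; regeneration with the same seed is bit-identical.
#' @param scale target total population size (>= 1000).
#' @param name country label.
#' @param start_year calendar year of the initial cross-section.
#' @return an object of class `country_profile`: a list with elements
#'   `name`, `start_year`, `pyramid` (data.table: age, sex, count),
#'   `fertility` (age, rate: births per woman-year), `mortality`
#'   (age, sex, qx: annual death probability), `migration`
#'   (age, sex, rate: net annual fraction) and `ppp_factor`.
#' @export
#' @examples
#' p <- generate_country_profile(seed = 1, scale = 5000)
#' sum(p$pyramid$count)
generate_country_profile <- function(seed, scale = 100000L, name = "Synthetica",
                                     start_year = 2019L) {
  if (!is.numeric(scale) || length(scale) != 1 || scale < 1000) {
    stop_invalid("`scale` must be a single number >= 1000, got %s",
                 paste(scale, collapse = ","))
  }
  scale <- as.integer(scale)
  set.seed(substream_seed(seed, 0L, 9L))
  ages <- 0:100

  jit <- exp(rnorm(4, 0, 0.05))
  qx_m <- pmin(0.7, 5.0e-4 * jit[1] + 3.2e-5 * jit[2] * exp(0.093 * ages))
  qx_f <- pmin(0.7, 3.5e-4 * jit[1] + 1.9e-5 * jit[2] * exp(0.094 * ages))
  mortality <- data.table(
    age = rep(ages, 2L),
    sex = rep(SEXES, each = length(ages)),
    qx = c(qx_m, qx_f)
  )

  tfr <- 1.7 * jit[3]
  shape <- exp(-0.5 * ((ages - 28) / 5.5)^2)
  shape[ages < 15 | ages > 49] <- 0
  fertility <- data.table(age = ages, rate = tfr * shape / sum(shape))

  mig <- rep(0, length(ages))
  mig[ages >= 20 & ages <= 39] <- 0.002 * jit[4]
  migration <- data.table(
    age = rep(ages, 2L),
    sex = rep(SEXES, each = length(ages)),
    rate = rep(mig, 2L)
  )

  # stable-population weights: survivorship discounted by a small growth rate
  growth <- 0.002
  surv_m <- cumprod(c(1, 1 - qx_m[-length(qx_m)]))
  surv_f <- cumprod(c(1, 1 - qx_f[-length(qx_f)]))
  w <- c(0.512 * surv_m, 0.488 * surv_f) * rep((1 + growth)^(-ages), 2L)
  counts <- round_preserve_total(w, scale)
  pyramid <- data.table(
    age = rep(ages, 2L),
    sex = rep(SEXES, each = length(ages)),
    count = counts
  )

  structure(
    list(
      name = name,
      start_year = as.integer(start_year),
      pyramid = pyramid,
      fertility = fertility,
      mortality = mortality,
      migration = migration,
      ppp_factor = 1.0
    ),
    class = "country_profile"
  )
}

#' @export
print.country_profile <- function(x, ...) {
  cat(sprintf("<country_profile> %s, %d: %d individuals, PPP factor %.2f\n",
              x$name, x$start_year, sum(x$pyramid$count), x$ppp_factor))
  invisible(x)
}

# Target cell means for the continuous risk-factor distributions,
# rows = age bands 0-19 ... 80+, columns = male, female.
.rf_cell_means <- function(factor) {
  switch(factor,
    bmi = cbind(male   = c(18.5, 26.5, 27.8, 28.2, 26.8),
                female = c(18.0, 25.5, 27.2, 27.8, 26.2)),
    physical_activity = cbind(male   = c(2800, 2400, 1900, 1300, 700),
                              female = c(2500, 2150, 1700, 1150, 620)),
    sedentary_time = cbind(male   = c(400, 430, 460, 520, 600),
                           female = c(380, 410, 440, 500, 580)),
    alcohol = cbind(male   = c(4, 18, 20, 16, 10),
                    female = c(2, 9, 10, 8, 5))
  )
}

ALCOHOL_ABSTAINER_SHARE <- 0.18

.rf_draw_cell <- function(factor, n, mu) {
  switch(factor,
    bmi = rlnorm(n, log(mu) - 0.16^2 / 2, 0.16),
    physical_activity = rgamma(n, shape = 1.6, scale = mu / 1.6),
    sedentary_time = pmax(60, rnorm(n, mu, 110)),
    alcohol = {
      x <- rlnorm(n, log(mu / (1 - ALCOHOL_ABSTAINER_SHARE)) - 0.8^2 / 2, 0.8)
      x[runif(n) < ALCOHOL_ABSTAINER_SHARE] <- 0
      x
    }
  )
}

#' Generate risk-factor quantile distributions
#'
#' For each of the four behavioural risk factors (BMI, physical activity,
#' sedentary time, alcohol), draws a synthetic exposure sample per
#' (age band, sex) cell, sorts it into `n_quantiles` equal-mass bins and
#' records each bin's lower edge, upper edge and mean. Individuals are
#' permanently allocated to one bin per factor; their continuous exposure is
#' reconstructed uniformly within the bin of their current age band.
#'
#' The bottom alcohol bin is the abstainer/reference bin: a point mass at
#' zero consumption is injected (share `r ALCOHOL_ABSTAINER_SHARE`), kept
#' below `1/n_quantiles` so bin means remain strictly increasing.
#'
#' @param profile a `country_profile` (used for labelling only; cells cover
#'   the full age-band by sex grid regardless of the pyramid).
#' @param n_quantiles number of quantile bins per factor (>= 2; default 5).
#' @param seed integer seed.
#' @param return_samples keep the raw generating draws as attribute
#'   `samples` on each distribution (used by verification code).
#' @return a named list of `risk_factor_distribution` objects, one per
#'   factor, each with elements `factor`, `unit`, `n_quantiles` and `table`
#'   (data.table: age_band, sex, quantile, lower, upper, mean).
#' @export
generate_risk_distributions <- function(profile, n_quantiles = 5L, seed = 1L,
                                        return_samples = FALSE) {
  if (!is.numeric(n_quantiles) || length(n_quantiles) != 1 || n_quantiles < 2) {
    stop_invalid("`n_quantiles` must be a single integer >= 2")
  }
  Q <- as.integer(n_quantiles)
  n_cell <- Q * 600L
  set.seed(substream_seed(seed, 0L, 10L))

  out <- list()
  for (f in RISK_FACTORS) {
    mus <- .rf_cell_means(f)
    rows <- vector("list", length(AGE_BAND_LABELS) * 2L)
    samples <- list()
    k <- 0L
    for (si in seq_along(SEXES)) {
      for (bi in seq_along(AGE_BAND_LABELS)) {
        x <- sort(.rf_draw_cell(f, n_cell, mus[bi, si]))
        grp <- rep(seq_len(Q), each = n_cell %/% Q)
        k <- k + 1L
        rows[[k]] <- data.table(
          age_band = AGE_BAND_LABELS[bi],
          sex = SEXES[si],
          quantile = seq_len(Q),
          lower = x[match(seq_len(Q), grp)],
          upper = x[n_cell - match(seq_len(Q), rev(grp)) + 1L],
          mean = as.vector(tapply(x, grp, mean))
        )
        if (return_samples) {
          samples[[paste(AGE_BAND_LABELS[bi], SEXES[si], sep = ".")]] <- x
        }
      }
    }
    tab <- rbindlist(rows)
    obj <- structure(
      list(factor = f, unit = RISK_FACTOR_UNITS[[f]],
           n_quantiles = Q, table = tab),
      class = "risk_factor_distribution"
    )
    if (return_samples) attr(obj, "samples") <- samples
    out[[f]] <- obj
  }
  out
}

#' @export
print.risk_factor_distribution <- function(x, ...) {
  cat(sprintf("<risk_factor_distribution> %s (%s), %d quantiles x %d cells\n",
              x$factor, x$unit, x$n_quantiles,
              nrow(x$table) / x$n_quantiles))
  invisible(x)
}

# Baseline incidence per person-year, parametric in age; male/female scalers.
.incidence_curve <- function(cancer, age, sex, level = 1) {
  base <- switch(cancer,
    breast = 2.4e-3 * exp(-0.5 * ((age - 67) / 20)^2) * (age >= 20),
    colorectal = pmin(3e-3, 1.35e-5 * exp(0.085 * pmax(age - 20, 0))) * (age >= 20),
    oesophageal = pmin(1e-3, 2.0e-6 * exp(0.090 * pmax(age - 20, 0))) * (age >= 25),
    liver = pmin(8e-4, 2.6e-6 * exp(0.082 * pmax(age - 20, 0))) * (age >= 25)
  )
  sexmul <- switch(cancer,
    breast = ifelse(sex == "female", 1, 0),  # male breast cancer excluded
    colorectal = ifelse(sex == "female", 0.9, 1.2),
    oesophageal = ifelse(sex == "female", 0.55, 1.6),
    liver = ifelse(sex == "female", 0.7, 1.8)
  )
  base * sexmul * level
}

.p_death_5y_base <- list(
  breast      = c(0.10, 0.10, 0.12, 0.18, 0.30),
  colorectal  = c(0.30, 0.32, 0.36, 0.45, 0.60),
  oesophageal = c(0.78, 0.80, 0.83, 0.87, 0.92),
  liver       = c(0.70, 0.72, 0.76, 0.82, 0.90)
)

DEFAULT_MORTALITY_YEAR_WEIGHTS <- c(0.40, 0.25, 0.15, 0.12, 0.08)

#' Generate baseline cancer epidemiology
#'
#' Baseline incidence per person-year by single year of age and sex for the
#' four modelled cancers, five-year case-fatality probabilities by
#' (cancer, age band, sex), and the five-year mortality timing weights
#' w1..w5 (strictly decreasing, summing to 1: cancer mortality is highest in
#' the first year after diagnosis and declines thereafter, and the weights
#' are held constant across ages). Male breast cancer incidence is set to
#' zero (documented modelling choice).
#'
#' @param profile a `country_profile`.
#' @param seed integer seed; applies a mild lognormal level jitter per cancer.
#' @param mortality_year_weights optional 5-vector replacing the default
#'   `c(0.40, 0.25, 0.15, 0.12, 0.08)`; must be strictly decreasing and
#'   sum to 1.
#' @return an object of class `disease_epidemiology`: list with `incidence`
#'   (data.table: cancer, age, sex, rate), `fatality` (cancer, age_band,
#'   sex, p_death_5y) and `mortality_year_weights`.
#' @export
generate_disease_epidemiology <- function(profile, seed = 1L,
                                          mortality_year_weights = NULL) {
  w <- if (is.null(mortality_year_weights)) DEFAULT_MORTALITY_YEAR_WEIGHTS
       else mortality_year_weights
  if (length(w) != 5 || any(diff(w) >= 0) || abs(sum(w) - 1) > 1e-8) {
    stop_invalid("mortality_year_weights must be 5 strictly decreasing values summing to 1")
  }
  set.seed(substream_seed(seed, 0L, 11L))
  lev <- setNames(exp(rnorm(length(CANCERS), 0, 0.05)), CANCERS)
  fat_jit <- setNames(exp(rnorm(length(CANCERS), 0, 0.04)), CANCERS)

  grid <- CJ(cancer = CANCERS, sex = SEXES, age = 0:100)
  grid[, rate := .incidence_curve(cancer[1], age, sex, lev[cancer[1]]),
       by = cancer]

  fat <- CJ(cancer = CANCERS, sex = SEXES, age_band = AGE_BAND_LABELS,
            sorted = FALSE)
  fat[, p_death_5y := {
    base <- .p_death_5y_base[[cancer[1]]][match(age_band, AGE_BAND_LABELS)]
    pmin(0.95, pmax(0.02, base * fat_jit[cancer[1]]))
  }, by = cancer]

  structure(
    list(
      incidence = grid[, .(cancer, age, sex, rate)],
      fatality = fat[, .(cancer, age_band, sex, p_death_5y)],
      mortality_year_weights = w
    ),
    class = "disease_epidemiology"
  )
}

#' @export
print.disease_epidemiology <- function(x, ...) {
  cat(sprintf("<disease_epidemiology> %d cancers; mortality-year weights %s\n",
              length(unique(x$incidence$cancer)),
              paste(format(x$mortality_year_weights), collapse = " ")))
  invisible(x)
}

# Top-quantile relative risks per (factor, cancer); interior quantiles follow
# a geometric ladder with the bottom (reference) quantile at exactly 1.
# Physical activity is protective: its ladder declines with the quantile.
.rr_top <- rbind(
  bmi               = c(breast = 1.50, colorectal = 1.60, oesophageal = 1.80, liver = 1.90),
  physical_activity = c(breast = 0.85, colorectal = 0.75, oesophageal = 1.00, liver = 1.00),
  sedentary_time    = c(breast = 1.10, colorectal = 1.35, oesophageal = 1.00, liver = 1.00),
  alcohol           = c(breast = 1.35, colorectal = 1.45, oesophageal = 2.60, liver = 2.10)
)

#' Generate the relative-risk table
#'
#' Relative risk of each cancer per risk-factor quantile, with the bottom
#' quantile as the reference (RR exactly 1) and a geometric ladder up to a
#' factor-by-cancer top-quantile value. Harmful exposures are monotone
#' non-decreasing in the quantile; physical activity (protective) is
#' monotone non-increasing. Values are replicated over age bands and sexes.
#'
#' @param n_quantiles number of quantiles (must match the distributions).
#' @return an object of class `relative_risk_table`: data.table with columns
#'   factor, quantile, cancer, age_band, sex, rr; attribute `n_quantiles`.
#' @export
generate_relative_risks <- function(n_quantiles = 5L) {
  if (n_quantiles < 2) stop_invalid("`n_quantiles` must be >= 2")
  Q <- as.integer(n_quantiles)
  tab <- CJ(factor = RISK_FACTORS, quantile = seq_len(Q), cancer = CANCERS,
            age_band = AGE_BAND_LABELS, sex = SEXES, sorted = FALSE)
  tab[, rr := .rr_top[cbind(factor, cancer)]^((quantile - 1) / (Q - 1))]
  setcolorder(tab, c("factor", "quantile", "cancer", "age_band", "sex", "rr"))
  setattr(tab, "class", c("relative_risk_table", class(tab)))
  setattr(tab, "n_quantiles", Q)
  tab[]
}

#' Generate the per-case cost profile
#'
#' Annual treatment cost per prevalent (active, pre-remission) case-year in
#' USD PPP per cancer, a last-year-of-life multiplier applied in the year of
#' cancer death, a multimorbidity increment per additional concurrent
#' cancer, and GBD-style disability weights for DALY computation.
#'
#' @param seed integer seed; applies a mild lognormal jitter to the per-case
#'   annual costs.
#' @return an object of class `cost_profile`.
#' @export
generate_cost_profile <- function(seed = 1L) {
  set.seed(substream_seed(seed, 0L, 12L))
  base <- c(breast = 18000, colorectal = 23000, oesophageal = 28000, liver = 31000)
  structure(
    list(
      annual_cost = base * exp(rnorm(length(base), 0, 0.08)),
      last_year_multiplier = 2.5,
      multimorbidity_increment = 0.2,
      disability_weight = c(breast = 0.30, colorectal = 0.29,
                            oesophageal = 0.36, liver = 0.33)
    ),
    class = "cost_profile"
  )
}

HEAVY_DRINKING_THRESHOLD <- 40  # g ethanol/day

# Elasticity cell baselines, all inside [-0.68, -0.42] so a +-0.01 jitter
# keeps every cell in [-0.69, -0.41] and a +10% price shock maps to
# per-cell consumption reductions inside the 4-7% band.
.elasticity_base <- function() {
  data.table(
    beverage = rep(BEVERAGES, each = 6L),
    age_band = rep(rep(DRINKER_AGE_BANDS, 2L), 3L),
    category = rep(rep(DRINKING_CATEGORIES, each = 3L), 3L),
    elasticity = c(
      -0.50, -0.48, -0.46,  -0.44, -0.43, -0.42,   # beer
      -0.60, -0.58, -0.55,  -0.50, -0.48, -0.46,   # wine
      -0.68, -0.66, -0.63,  -0.56, -0.54, -0.52    # spirits
    )
  )
}

.price_distribution_default <- function() {
  data.table(
    beverage = rep(BEVERAGES, each = 4L),
    price = c(0.70, 0.90, 1.10, 1.40,
              0.80, 0.92, 1.20, 1.60,
              0.70, 0.91, 1.30, 1.80),
    share = c(0.05, 0.15, 0.45, 0.35,
              0.04, 0.08, 0.50, 0.38,
              0.08, 0.07, 0.55, 0.30)
  )
}

#' Generate the alcohol price-elasticity table
#'
#' Own-price elasticities of alcohol demand by beverage type, drinker age
#' band and drinking category (heavy drinkers are less price-responsive),
#' together with market volume shares by beverage and a price-per-unit
#' distribution of market volume (used by minimum unit pricing). The cell
#' values are calibrated, not estimated: they are chosen so that a 10 percent price
#' rise maps every cell to a consumption reduction in the 4-7 percent range, and
#' so that the default price distribution with a floor of 1 currency unit
#' per unit of alcohol yields per-cell reductions in the 0.6-3.3 percent range.
#'
#' @param seed integer seed; jitters each elasticity by up to +-0.01 within
#'   the calibrated band.
#' @return an object of class `elasticity_table`: list with `elasticity`
#'   (data.table: beverage, age_band, category, elasticity), `beverage_share`,
#'   `price_distribution` (beverage, price, share; shares sum to 1 per
#'   beverage) and `heavy_threshold` (g/day separating drinking categories).
#' @export
generate_elasticities <- function(seed = 1L) {
  set.seed(substream_seed(seed, 0L, 13L))
  el <- .elasticity_base()
  el[, elasticity := elasticity + runif(.N, -0.01, 0.01)]
  structure(
    list(
      elasticity = el,
      beverage_share = c(beer = 0.45, wine = 0.30, spirits = 0.25),
      price_distribution = .price_distribution_default(),
      heavy_threshold = HEAVY_DRINKING_THRESHOLD
    ),
    class = "elasticity_table"
  )
}

#' Generate the full synthetic input bundle
#'
#' Convenience constructor producing every model input with one call:
#' country profile, risk-factor distributions, disease epidemiology,
#' relative risks, cost profile and elasticities, all deterministic for a
#' fixed seed.
#'
#' @param seed integer master seed.
#' @param scale target population size.
#' @param n_quantiles quantile bins per risk factor.
#' @param start_year calendar year of the initial cross-section.
#' @return an object of class `model_inputs` (a named list).
#' @export
#' @examples
#' inp <- generate_model_inputs(seed = 1, scale = 2000)
#' names(inp)
generate_model_inputs <- function(seed, scale = 100000L, n_quantiles = 5L,
                                  start_year = 2019L) {
  profile <- generate_country_profile(seed, scale, start_year = start_year)
  structure(
    list(
      profile = profile,
      distributions = generate_risk_distributions(profile, n_quantiles, seed),
      epidemiology = generate_disease_epidemiology(profile, seed),
      relative_risks = generate_relative_risks(n_quantiles),
      costs = generate_cost_profile(seed),
      elasticities = generate_elasticities(seed)
    ),
    class = "model_inputs"
  )
}

#' Validate a model input bundle
#'
#' Checks every type invariant: non-negative counts and rates, probabilities
#' in `[0, 1]`, full age-by-sex pyramid coverage, strictly increasing
#' quantile means, unit reference relative risks with the required
#' monotonicity, strictly decreasing mortality-year weights summing to 1,
#' non-negative costs, disability weights in `[0, 1]`, non-positive
#' elasticities and price shares summing to 1.
#'
#' @param inputs a `model_inputs` object.
#' @return `TRUE` invisibly; aborts with a message on the first violation.
#' @export
validate_model_inputs <- function(inputs) {
  p <- inputs$profile
  stopifnot(all(p$pyramid$count >= 0),
            all(p$mortality$qx >= 0 & p$mortality$qx <= 1),
            all(p$fertility$rate >= 0),
            nrow(p$pyramid) == 2L * 101L)
  for (d in inputs$distributions) {
    inc <- d$table[, all(diff(mean) > 0), by = .(age_band, sex)]$V1
    if (!all(inc)) stop_invalid("quantile means not strictly increasing for %s", d$factor)
    stopifnot(d$n_quantiles >= 2)
  }
  epi <- inputs$epidemiology
  stopifnot(all(epi$incidence$rate >= 0),
            all(epi$fatality$p_death_5y >= 0 & epi$fatality$p_death_5y <= 1),
            all(diff(epi$mortality_year_weights) < 0),
            abs(sum(epi$mortality_year_weights) - 1) < 1e-8,
            all(epi$incidence[cancer == "breast" & sex == "male", rate] == 0))
  rrt <- inputs$relative_risks
  stopifnot(all(rrt$rr >= 0),
            all(rrt[quantile == 1, rr] == 1))
  mono <- rrt[, {
    d <- diff(rr[order(quantile)])
    if (factor[1] == "physical_activity") all(d <= 1e-12) else all(d >= -1e-12)
  }, by = .(factor, cancer, age_band, sex)]$V1
  if (!all(mono)) stop_invalid("relative risks violate quantile monotonicity")
  co <- inputs$costs
  stopifnot(all(co$annual_cost >= 0), co$last_year_multiplier >= 1,
            co$multimorbidity_increment >= 0,
            all(co$disability_weight >= 0 & co$disability_weight <= 1))
  el <- inputs$elasticities
  stopifnot(all(el$elasticity$elasticity <= 0),
            abs(sum(el$beverage_share) - 1) < 1e-8)
  ps <- el$price_distribution[, sum(share), by = beverage]$V1
  stopifnot(all(abs(ps - 1) < 1e-8))
  invisible(TRUE)
}
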