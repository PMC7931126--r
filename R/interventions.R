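#' @title Primary-prevention interventions
#' @description The six modelled policies, each described by four inputs:
#'   the target population (age filter), the exposure of the target
#'   population, the effect on the targeted risk factor at the individual
#'   level, and the effect over time (a piecewise schedule; only the mass
#'   media campaign decays, all other policies hold their full effect).
#' @name interventions
#' @keywords internal
NULL

INTERVENTION_NAMES <- c("menu_labelling", "food_labelling", "mass_media",
                        "workplace_sb", "alcohol_tax", "mup")

#' Construct one of the six intervention specifications
#'
#' Populates the specification with the published input values:
#' \itemize{
#' \item menu labelling: age > 5 years, 12% exposure, 1.05-1.31% BMI drop
#'   after 1 year (sampled uniformly per exposed individual by default);
#' \item food labelling: age > 5 years, 15% exposure, 0.40% lower BMI;
#' \item mass media campaigns: age > 18 years, 100% exposure, 60% increase
#'   in at-least-moderate activity after 1 month, 30% after 1 year, 0%
#'   after 2 years (linear interpolation between knots);
#' \item workplace sedentary-behaviour programmes: ages 18-65, 2.31-6.95%
#'   exposure (midpoint default) thinned by 50% enterprise participation,
#'   -72.78 min of sedentary time per 8-h workday;
#' \item alcohol tax: all ages, 100% exposure, a +10% price change mapped
#'   through the elasticity table;
#' \item minimum unit pricing (mup): all ages, 100% exposure, mapped
#'   through the below-floor price distribution and the elasticities.
#' }
#'
#' @param name one of `"menu_labelling"`, `"food_labelling"`, `"mass_media"`,
#'   `"workplace_sb"`, `"alcohol_tax"`, `"mup"`.
#' @param workplace_exposure scalar exposure for the workplace programme,
#'   inside its 2.31-6.95% range (default: the midpoint, 4.63%).
#' @param menu_fixed_midpoint if `TRUE`, every exposed individual receives
#'   the midpoint of the 1.05-1.31% range instead of a uniform draw.
#' @param workdays workdays per week over which the per-workday sedentary
#'   reduction is spread (default 5).
#' @param mup_floor minimum price per unit of alcohol (default 1.0, on the
#'   scale of the synthetic price distribution).
#' @return an object of class `intervention_spec`.
#' @export
#' @examples
#' build_intervention("food_labelling")$effect_magnitude  # 0.40 percent BMI
build_intervention <- function(name, workplace_exposure = NULL,
                               menu_fixed_midpoint = FALSE,
                               workdays = 5, mup_floor = 1.0) {
  if (!is.character(name) || length(name) != 1 || !name %in% INTERVENTION_NAMES) {
    stop_invalid("unknown intervention '%s'; expected one of: %s",
                 paste(name, collapse = ","),
                 paste(INTERVENTION_NAMES, collapse = ", "))
  }
  flat <- data.table(t = 0, frac = 1)
  spec <- switch(name,
    menu_labelling = list(
      label = "Menu labelling",
      risk_factor = "bmi", effect_kind = "bmi_percent_drop",
      effect_magnitude = c(1.05, 1.31), effect_units = "% BMI drop",
      min_age = 6L, max_age = Inf,
      exposure_fraction = 0.12, participation = 1,
      schedule = flat,
      sample_magnitude = !menu_fixed_midpoint
    ),
    food_labelling = list(
      label = "Food labelling",
      risk_factor = "bmi", effect_kind = "bmi_percent_drop",
      effect_magnitude = 0.40, effect_units = "% BMI drop",
      min_age = 6L, max_age = Inf,
      exposure_fraction = 0.15, participation = 1,
      schedule = flat, sample_magnitude = FALSE
    ),
    mass_media = list(
      label = "Mass media campaigns",
      risk_factor = "physical_activity",
      effect_kind = "activity_percent_increase",
      effect_magnitude = 60, effect_units = "% activity increase",
      min_age = 19L, max_age = Inf,
      exposure_fraction = 1, participation = 1,
      schedule = data.table(t = c(1 / 12, 1, 2), frac = c(1, 0.5, 0)),
      sample_magnitude = FALSE
    ),
    workplace_sb = list(
      label = "Workplace sedentary-behaviour programme",
      risk_factor = "sedentary_time", effect_kind = "sedentary_minutes_drop",
      effect_magnitude = -72.78, effect_units = "min sedentary per 8-h workday",
      min_age = 18L, max_age = 65L,
      exposure_fraction = if (is.null(workplace_exposure)) 0.0463
                          else workplace_exposure,
      exposure_range = c(0.0231, 0.0695),
      participation = 0.5,  # 50% of eligible enterprises participate
      schedule = flat, sample_magnitude = FALSE
    ),
    alcohol_tax = list(
      label = "Alcohol tax (+10% price)",
      risk_factor = "alcohol",
      effect_kind = "consumption_percent_change_via_elasticity",
      effect_magnitude = NA_real_, effect_units = "% consumption change",
      min_age = 0L, max_age = Inf,
      exposure_fraction = 1, participation = 1,
      price_change = 0.10,
      schedule = flat, sample_magnitude = FALSE
    ),
    mup = list(
      label = "Minimum unit pricing",
      risk_factor = "alcohol",
      effect_kind = "consumption_percent_change_via_mup",
      effect_magnitude = NA_real_, effect_units = "% consumption change",
      min_age = 0L, max_age = Inf,
      exposure_fraction = 1, participation = 1,
      mup_floor = mup_floor,
      schedule = flat, sample_magnitude = FALSE
    )
  )
  spec$name <- name
  spec$workdays <- workdays
  if (!is.null(spec$exposure_range)) {
    rng <- spec$exposure_range
    if (spec$exposure_fraction < rng[1] || spec$exposure_fraction > rng[2]) {
      stop_invalid("workplace exposure must lie in [%.4f, %.4f]", rng[1], rng[2])
    }
  }
  structure(spec, class = "intervention_spec")
}

#' @export
print.intervention_spec <- function(x, ...) {
  mag <- if (all(is.na(x$effect_magnitude))) "via elasticities"
         else paste(format(x$effect_magnitude), collapse = "-")
  cat(sprintf("<intervention_spec> %s: ages %s-%s, exposure %.4g%%, effect %s %s\n",
              x$label, x$min_age, x$max_age,
              100 * x$exposure_fraction * x$participation, mag, x$effect_units))
  invisible(x)
}

#' Construct a price shock
#'
#' @param price_change fractional price change (e.g. `0.10` for a 10 percent rise);
#'   must exceed -1.
#' @param mup_floor optional minimum price per unit (for MUP).
#' @return an object of class `price_shock`.
#' @export
price_shock <- function(price_change, mup_floor = NULL) {
  if (price_change <= -1) stop_invalid("price_change must exceed -1")
  structure(list(price_change = price_change, mup_floor = mup_floor),
            class = "price_shock")
}

.schedule_fraction <- function(spec, t) {
  s <- spec$schedule
  if (nrow(s) == 1L) return(rep(s$frac[1], length(t)))
  approx(s$t, s$frac, xout = t, rule = 2)$y
}

#' Intervention effect at a time since implementation
#'
#' Evaluates the effect schedule at `t` years after implementation, in the
#' effect's published units (percent for BMI/activity/consumption effects,
#' minutes per 8-h workday for the workplace programme). Between schedule
#' knots the mass-media effect is linearly interpolated; beyond the last
#' knot the last knot's value holds; ranged magnitudes evaluate at their
#' midpoint.
#'
#' @param spec an `intervention_spec`.
#' @param t years since implementation (>= 0).
#' @return effect magnitude(s) in the spec's units.
#' @export
#' @examples
#' m <- build_intervention("mass_media")
#' effect_at_time(m, c(1 / 12, 1, 2))  # 60, 30, 0
effect_at_time <- function(spec, t) {
  if (any(t < 0)) stop_invalid("t must be >= 0")
  mag <- mean(range(spec$effect_magnitude))
  mag * .schedule_fraction(spec, t)
}

#' Select the exposed subset of the population
#'
#' Flags, among age-eligible individuals, a Bernoulli draw at the spec's
#' exposure fraction (thinned by enterprise participation for the workplace
#' programme). By default the persistent per-individual exposure uniform
#' drawn at entry is used, so membership is stable over the simulation and
#' identical across paired runs; passing `seed` redraws fresh uniforms.
#'
#' @param population a `population`.
#' @param spec an `intervention_spec`.
#' @param seed optional integer seed for a fresh Bernoulli draw.
#' @return the `population` with a logical `exposed` column on its table.
#' @export
select_exposed <- function(population, spec, seed = NULL) {
  tab <- population$tab
  age <- population$current_year - tab$birth_year
  eligible <- .present(tab) & age >= spec$min_age & age <= spec$max_age
  u <- tab$u_expose
  if (!is.null(seed)) {
    set.seed(substream_seed(seed, population$current_year, 20L))
    u <- runif(nrow(tab))
  }
  p <- spec$exposure_fraction * spec$participation
  population$tab$exposed <- eligible & u < p
  population
}

#' Apply a uniform price change through the elasticity table
#'
#' Per-cell fractional consumption change equals elasticity times the
#' fractional price change; consumption is never driven negative.
#'
#' @param consumption data.table/data.frame with columns `beverage`,
#'   `age_band`, `category` and `consumption` (g ethanol/day).
#' @param elasticities an `elasticity_table`.
#' @param shock a `price_shock` with `mup_floor = NULL`.
#' @return the consumption table with added columns `pct_change`
#'   (fractional) and `consumption_adj`.
#' @export
apply_price_intervention <- function(consumption, elasticities, shock) {
  if (!is.null(shock$mup_floor)) {
    stop_invalid("use apply_mup() for a floor-price shock")
  }
  out <- as.data.table(consumption)
  out <- elasticities$elasticity[out, on = c("beverage", "age_band", "category")]
  if (anyNA(out$elasticity)) stop_invalid("elasticity cell missing for some rows")
  out[, pct_change := elasticity * shock$price_change]
  out[, consumption_adj := pmax(0, consumption * (1 + pct_change))]
  out[]
}

#' Consumption change under minimum unit pricing
#'
#' For each beverage: the share of market volume priced below the floor and
#' the average fractional price uplift the floor imposes on that share are
#' computed from the price distribution; the per-cell consumption change is
#' then below-floor share x uplift x elasticity. A floor below the entire
#' distribution yields zero change.
#'
#' @param price_distribution data.table with columns `beverage`, `price`
#'   (per unit of alcohol) and `share` (of market volume; sums to 1 per
#'   beverage).
#' @param mup_floor floor price per unit (> 0).
#' @param elasticities an `elasticity_table`.
#' @return data.table (beverage, age_band, category, pct_change) with the
#'   per-beverage `below_share` and `uplift` attached as attribute
#'   `mup_stats`.
#' @export
apply_mup <- function(price_distribution, mup_floor, elasticities) {
  if (mup_floor <= 0) stop_invalid("mup_floor must be > 0")
  pd <- as.data.table(price_distribution)
  stats <- pd[, {
    below <- price < mup_floor
    s <- sum(share[below])
    if (s > 0) {
      avg <- sum(price[below] * share[below]) / s
      list(below_share = s, uplift = (mup_floor - avg) / avg)
    } else {
      list(below_share = 0, uplift = 0)
    }
  }, by = beverage]
  out <- merge(elasticities$elasticity, stats, by = "beverage")
  out[, pct_change := below_share * uplift * elasticity]
  res <- out[, .(beverage, age_band, category, pct_change)]
  setattr(res, "mup_stats", stats)
  res[]
}

# Per-(drinker age band, drinking category) fractional consumption change,
# volume-weighted across beverages; used to shift individual consumption.
.alcohol_change_map <- function(spec, elasticities) {
  if (spec$effect_kind == "consumption_percent_change_via_elasticity") {
    cells <- copy(elasticities$elasticity)
    cells[, pct_change := elasticity * spec$price_change]
  } else {
    cells <- apply_mup(elasticities$price_distribution, spec$mup_floor,
                       elasticities)
  }
  sh <- elasticities$beverage_share
  agg <- cells[, .(pct = sum(pct_change * sh[beverage]) / sum(sh[beverage])),
               by = .(age_band, category)]
  map <- matrix(0, length(DRINKER_AGE_BANDS), length(DRINKING_CATEGORIES),
                dimnames = list(DRINKER_AGE_BANDS, DRINKING_CATEGORIES))
  map[cbind(match(agg$age_band, DRINKER_AGE_BANDS),
            match(agg$category, DRINKING_CATEGORIES))] <- agg$pct
  map
}

# Intervention runtime context for the simulation loop.
.build_intervention_context <- function(spec, elasticities,
                                        implementation_year) {
  ctx <- list(spec = spec, implementation_year = as.integer(implementation_year))
  if (spec$risk_factor == "alcohol") {
    ctx$map <- .alcohol_change_map(spec, elasticities)
    ctx$heavy_threshold <- elasticities$heavy_threshold
  }
  ctx
}

# Shift the continuous exposures of exposed individuals. Effects inside the
# annual cycle are evaluated at mid-year (t - 0.5) so decaying schedules
# contribute their average path; before implementation nothing changes.
.shift_exposures <- function(vals, tab, int_ctx, age, y) {
  spec <- int_ctx$spec
  t_mid <- y - int_ctx$implementation_year - 0.5
  if (t_mid < 0) return(vals)
  frac <- .schedule_fraction(spec, max(t_mid, 0))
  if (frac == 0) return(vals)
  exposed <- .present(tab) & age >= spec$min_age & age <= spec$max_age &
    tab$u_expose < spec$exposure_fraction * spec$participation
  idx <- which(exposed)
  if (!length(idx)) return(vals)
  kind <- spec$effect_kind
  if (kind == "bmi_percent_drop") {
    mag <- if (isTRUE(spec$sample_magnitude)) {
      spec$effect_magnitude[1] +
        tab$u_effect[idx] * diff(spec$effect_magnitude)
    } else mean(range(spec$effect_magnitude))
    vals$bmi[idx] <- vals$bmi[idx] * (1 - mag * frac / 100)
  } else if (kind == "activity_percent_increase") {
    mag <- mean(range(spec$effect_magnitude))
    vals$physical_activity[idx] <-
      vals$physical_activity[idx] * (1 + mag * frac / 100)
  } else if (kind == "sedentary_minutes_drop") {
    shift <- spec$effect_magnitude * spec$workdays / 7 * frac  # min/day, < 0
    vals$sedentary_time[idx] <- pmax(0, vals$sedentary_time[idx] + shift)
  } else {
    dband <- drinker_band_index(age[idx])
    cat <- 1L + (vals$alcohol[idx] >= int_ctx$heavy_threshold)
    delta <- int_ctx$map[cbind(dband, cat)] * frac
    vals$alcohol[idx] <- pmax(0, vals$alcohol[idx] * (1 + delta))
  }
  vals
}

#' Shift an exposure value under an intervention
#'
#' Applies the intervention's individual-level effect at time `t` to a
#' continuous exposure value in the targeted risk factor's units (BMI,
#' MET-min/week, sedentary min/day or g ethanol/day). Percentage effects
#' are relative changes to the current value; the workplace sedentary
#' reduction is spread over the week (`effect * workdays / 7` per day);
#' alcohol price effects look up the individual's drinker age band and
#' drinking category. Unexposed individuals are unchanged by construction
#' (this function models an exposed individual).
#'
#' @param value exposure value(s) in the factor's units.
#' @param spec an `intervention_spec`.
#' @param t years since implementation.
#' @param u_effect uniform(s) in `[0, 1]` selecting within a ranged effect
#'   magnitude (default 0.5, the midpoint).
#' @param age age(s) in years (used by alcohol interventions).
#' @param elasticities an `elasticity_table` (required for alcohol
#'   interventions).
#' @return the shifted exposure value(s).
#' @export
#' @examples
#' apply_risk_factor_effect(30, build_intervention("food_labelling"), t = 1)
apply_risk_factor_effect <- function(value, spec, t, u_effect = 0.5,
                                     age = 40L, elasticities = NULL) {
  if (any(t < 0)) stop_invalid("t must be >= 0")
  frac <- .schedule_fraction(spec, t)
  kind <- spec$effect_kind
  if (kind == "bmi_percent_drop") {
    mag <- if (isTRUE(spec$sample_magnitude)) {
      spec$effect_magnitude[1] + u_effect * diff(spec$effect_magnitude)
    } else mean(range(spec$effect_magnitude))
    return(value * (1 - mag * frac / 100))
  }
  if (kind == "activity_percent_increase") {
    return(value * (1 + mean(range(spec$effect_magnitude)) * frac / 100))
  }
  if (kind == "sedentary_minutes_drop") {
    return(pmax(0, value + spec$effect_magnitude * spec$workdays / 7 * frac))
  }
  if (is.null(elasticities)) {
    stop_invalid("alcohol interventions need an `elasticity_table`")
  }
  map <- .alcohol_change_map(spec, elasticities)
  dband <- drinker_band_index(rep_len(age, length(value)))
  cat <- 1L + (value >= elasticities$heavy_threshold)
  pmax(0, value * (1 + map[cbind(dband, cat)] * frac))
}
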