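#' Write a model input bundle to delimited text files
#'
#' Serialises every generated structure to CSV files with stable column
#' schemas, plus a `meta.yaml` holding the scalars:
#' \itemize{
#' \item `pyramid.csv` (age, sex, count)
#' \item `fertility.csv` (age, rate), `mortality.csv` (age, sex, qx),
#'   `migration.csv` (age, sex, rate)
#' \item `risk_distributions.csv` (factor, age_band, sex, quantile, lower,
#'   upper, mean)
#' \item `incidence.csv` (cancer, age, sex, rate), `fatality.csv` (cancer,
#'   age_band, sex, p_death_5y)
#' \item `relative_risks.csv` (factor, quantile, cancer, age_band, sex, rr)
#' \item `costs.csv` (cancer, annual_cost, disability_weight)
#' \item `elasticities.csv` (beverage, age_band, category, elasticity),
#'   `price_distribution.csv` (beverage, price, share)
#' }
#'
#' @param inputs a `model_inputs` bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model_inputs <- function(inputs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- inputs$profile
  fwrite(p$pyramid, file.path(dir, "pyramid.csv"))
  fwrite(p$fertility, file.path(dir, "fertility.csv"))
  fwrite(p$mortality, file.path(dir, "mortality.csv"))
  fwrite(p$migration, file.path(dir, "migration.csv"))
  dist <- rbindlist(lapply(inputs$distributions, function(d) {
    cbind(data.table(factor = d$factor), d$table)
  }))
  fwrite(dist, file.path(dir, "risk_distributions.csv"))
  fwrite(inputs$epidemiology$incidence, file.path(dir, "incidence.csv"))
  fwrite(inputs$epidemiology$fatality, file.path(dir, "fatality.csv"))
  fwrite(as.data.table(inputs$relative_risks),
         file.path(dir, "relative_risks.csv"))
  co <- inputs$costs
  fwrite(data.table(cancer = names(co$annual_cost),
                    annual_cost = unname(co$annual_cost),
                    disability_weight = unname(co$disability_weight[names(co$annual_cost)])),
         file.path(dir, "costs.csv"))
  el <- inputs$elasticities
  fwrite(el$elasticity, file.path(dir, "elasticities.csv"))
  fwrite(el$price_distribution, file.path(dir, "price_distribution.csv"))
  yaml::write_yaml(
    list(name = p$name, start_year = p$start_year, ppp_factor = p$ppp_factor,
         n_quantiles = inputs$distributions[[1]]$n_quantiles,
         mortality_year_weights = inputs$epidemiology$mortality_year_weights,
         last_year_multiplier = co$last_year_multiplier,
         multimorbidity_increment = co$multimorbidity_increment,
         beverage_share = as.list(el$beverage_share),
         heavy_threshold = el$heavy_threshold),
    file.path(dir, "meta.yaml")
  )
  invisible(dir)
}

#' Read a model input bundle from a directory of CSV files
#'
#' Inverse of [write_model_inputs()]; reconstructs the classed objects.
#'
#' @param dir directory written by [write_model_inputs()].
#' @return a `model_inputs` bundle.
#' @export
read_model_inputs <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  profile <- structure(
    list(name = meta$name, start_year = as.integer(meta$start_year),
         pyramid = fread(file.path(dir, "pyramid.csv")),
         fertility = fread(file.path(dir, "fertility.csv")),
         mortality = fread(file.path(dir, "mortality.csv")),
         migration = fread(file.path(dir, "migration.csv")),
         ppp_factor = meta$ppp_factor),
    class = "country_profile"
  )
  dist_all <- fread(file.path(dir, "risk_distributions.csv"))
  distributions <- setNames(lapply(RISK_FACTORS, function(f) {
    structure(
      list(factor = f, unit = RISK_FACTOR_UNITS[[f]],
           n_quantiles = as.integer(meta$n_quantiles),
           table = dist_all[dist_all$factor == f,
                            c("age_band", "sex", "quantile",
                              "lower", "upper", "mean")]),
      class = "risk_factor_distribution"
    )
  }), RISK_FACTORS)
  epidemiology <- structure(
    list(incidence = fread(file.path(dir, "incidence.csv")),
         fatality = fread(file.path(dir, "fatality.csv")),
         mortality_year_weights = as.numeric(meta$mortality_year_weights)),
    class = "disease_epidemiology"
  )
  rrt <- fread(file.path(dir, "relative_risks.csv"))
  setattr(rrt, "class", c("relative_risk_table", class(rrt)))
  setattr(rrt, "n_quantiles", as.integer(meta$n_quantiles))
  co <- fread(file.path(dir, "costs.csv"))
  costs <- structure(
    list(annual_cost = setNames(co$annual_cost, co$cancer),
         last_year_multiplier = meta$last_year_multiplier,
         multimorbidity_increment = meta$multimorbidity_increment,
         disability_weight = setNames(co$disability_weight, co$cancer)),
    class = "cost_profile"
  )
  elasticities <- structure(
    list(elasticity = fread(file.path(dir, "elasticities.csv")),
         beverage_share = unlist(meta$beverage_share),
         price_distribution = fread(file.path(dir, "price_distribution.csv")),
         heavy_threshold = meta$heavy_threshold),
    class = "elasticity_table"
  )
  structure(
    list(profile = profile, distributions = distributions,
         epidemiology = epidemiology, relative_risks = rrt,
         costs = costs, elasticities = elasticities),
    class = "model_inputs"
  )
}
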