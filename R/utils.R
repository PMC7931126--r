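#' Model constants
#'
#' The four cancers with a direct link to the modelled risk factors, the four
#' behavioural risk factors, and the age-band grid used for risk-factor
#' distributions, relative risks and reporting.
#'
#' @name model-constants
#' @keywords internal
NULL

CANCERS <- c("breast", "colorectal", "oesophageal", "liver")
RISK_FACTORS <- c("bmi", "physical_activity", "sedentary_time", "alcohol")
RISK_FACTOR_UNITS <- c(
  bmi = "kg/m2",
  physical_activity = "MET-min/week",
  sedentary_time = "min/day",
  alcohol = "g ethanol/day"
)
SEXES <- c("male", "female")
AGE_BAND_BREAKS <- c(0, 20, 40, 60, 80)
AGE_BAND_LABELS <- c("0-19", "20-39", "40-59", "60-79", "80+")
DRINKER_AGE_BANDS <- c("18-29", "30-49", "50+")
BEVERAGES <- c("beer", "wine", "spirits")
DRINKING_CATEGORIES <- c("moderate", "heavy")

#' Map ages to model age bands
#'
#' @param age integer vector of ages in years.
#' @return character vector of age-band labels (`"0-19"` ... `"80+"`).
#' @export
#' @examples
#' cut_age_band(c(3, 25, 47, 60, 92))
cut_age_band <- function(age) {
  AGE_BAND_LABELS[age_band_index(age)]
}

age_band_index <- function(age) {
  findInterval(pmax(age, 0), AGE_BAND_BREAKS)
}

drinker_band_index <- function(age) {
  1L + (age >= 30) + (age >= 50)
}

sex_index <- function(sex) {
  1L + (sex == "female")
}

#' Derive a reproducible substream seed
#'
#' Every stochastic block of the simulation reseeds the generator from a
#' deterministic function of the master seed, the calendar year and a small
#' event code, and draws in id-sorted order. Paired counterfactual and
#' intervention runs therefore consume identical random numbers until the
#' first state divergence (the common-random-numbers contract).
#'
#' @param seed master integer seed.
#' @param year calendar year (use 0 for year-free streams).
#' @param event small non-negative integer identifying the event block.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, year, event) {
  m <- 2147483647
  x <- (abs(as.double(seed)) %% m)
  x <- (x * 69069 + as.double(year) * 9973 + as.double(event) * 101) %% m
  as.integer(x)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Largest-remainder rounding: integer counts summing exactly to `total`.
round_preserve_total <- function(weights, total) {
  if (total == 0 || sum(weights) == 0) return(integer(length(weights)))
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    frac <- raw - base
    top <- order(-frac, seq_along(frac))[seq_len(short)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}
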