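#' @title Risk-to-disease machinery
#' @description Risk-factor quantiles are translated into cancer incidence by
#'   multiplying per-factor relative risks (GBD convention), normalising by
#'   the population mean relative risk so that simulated incidence reproduces
#'   the baseline inputs, and drawing per-individual annual Bernoulli events.
#'   Each incident case receives a five-year fatality plan; survivors of five
#'   full years are considered recovered (remission).
#' @name risk-and-disease
#' @keywords internal
NULL

# Dense lookup array per factor: rr[quantile, cancer, age band, sex].
# Missing (factor, cancer) combinations default to a relative risk of 1.
.rr_array <- function(rr_table) {
  Q <- max(rr_table$quantile)
  out <- list()
  for (f in RISK_FACTORS) {
    arr <- array(1, dim = c(Q, length(CANCERS), length(AGE_BAND_LABELS), 2L))
    sub <- rr_table[rr_table$factor == f, ]
    if (nrow(sub)) {
      arr[cbind(sub$quantile,
                match(sub$cancer, CANCERS),
                match(sub$age_band, AGE_BAND_LABELS),
                sex_index(sub$sex))] <- sub$rr
    }
    out[[f]] <- arr
  }
  out
}

# Dense arrays for the whole input bundle (hot-path lookups).
.build_sim_context <- function(inputs) {
  dist <- list()
  for (f in RISK_FACTORS) {
    d <- inputs$distributions[[f]]
    Q <- d$n_quantiles
    lo <- hi <- mu <- array(NA_real_, dim = c(length(AGE_BAND_LABELS), 2L, Q))
    t <- d$table
    idx <- cbind(match(t$age_band, AGE_BAND_LABELS), sex_index(t$sex), t$quantile)
    lo[idx] <- t$lower; hi[idx] <- t$upper; mu[idx] <- t$mean
    mids <- array(NA_real_, dim = c(length(AGE_BAND_LABELS), 2L, Q - 1L))
    for (bi in seq_along(AGE_BAND_LABELS)) for (si in 1:2) {
      m <- mu[bi, si, ]
      mids[bi, si, ] <- (m[-Q] + m[-1]) / 2
    }
    dist[[f]] <- list(lo = lo, hi = hi, mean = mu, mids = mids, Q = Q)
  }
  inc <- array(0, dim = c(101L, 2L, length(CANCERS)))
  ei <- inputs$epidemiology$incidence
  inc[cbind(ei$age + 1L, sex_index(ei$sex), match(ei$cancer, CANCERS))] <- ei$rate
  p5y <- array(NA_real_, dim = c(length(AGE_BAND_LABELS), 2L, length(CANCERS)))
  ef <- inputs$epidemiology$fatality
  p5y[cbind(match(ef$age_band, AGE_BAND_LABELS), sex_index(ef$sex),
            match(ef$cancer, CANCERS))] <- ef$p_death_5y
  list(
    dist = dist,
    rr = .rr_array(inputs$relative_risks),
    inc = inc,
    p5y = p5y,
    weights = inputs$epidemiology$mortality_year_weights,
    cw = cumsum(inputs$epidemiology$mortality_year_weights),
    Q = inputs$distributions[[1]]$n_quantiles
  )
}

# Continuous exposure values for each factor, reconstructed uniformly within
# the individual's permanent quantile bin of the current age band.
.exposure_values <- function(tab, ctx, bi, si) {
  vals <- list()
  for (f in RISK_FACTORS) {
    q <- tab[[paste0("q_", f)]]
    idx <- cbind(bi, si, q)
    lo <- ctx$dist[[f]]$lo[idx]
    vals[[f]] <- lo + tab[[paste0("u_", f)]] * (ctx$dist[[f]]$hi[idx] - lo)
  }
  vals
}

# Effective quantile per factor: the quantile whose mean is nearest the
# (possibly intervention-shifted) exposure value, within the individual's
# current (age band, sex) cell.
.effective_quantiles <- function(vals, ctx, bi, si) {
  out <- list()
  for (f in RISK_FACTORS) {
    v <- vals[[f]]
    q <- integer(length(v))
    for (b in seq_along(AGE_BAND_LABELS)) for (s in 1:2) {
      idx <- which(bi == b & si == s)
      if (length(idx)) {
        q[idx] <- findInterval(v[idx], ctx$dist[[f]]$mids[b, s, ]) + 1L
      }
    }
    out[[f]] <- q
  }
  out
}

# Product of per-factor relative risks for one cancer (GBD multiplicative
# combination), given effective quantiles.
.rr_product <- function(effq, ctx, ci, bi, si) {
  rr <- rep(1, length(bi))
  for (f in RISK_FACTORS) {
    rr <- rr * ctx$rr[[f]][cbind(effq[[f]], ci, bi, si)]
  }
  rr
}

#' Combined relative risk of an individual
#'
#' Multiplies the per-factor relative risks at the individual's quantiles
#' (the GBD convention for combining independent risk factors). All factors
#' at the reference quantile give exactly 1.
#'
#' @param quantiles named list (or data.frame) with one integer vector per
#'   risk factor (`bmi`, `physical_activity`, `sedentary_time`, `alcohol`);
#'   factors may be omitted (treated as reference).
#' @param cancer one of `"breast"`, `"colorectal"`, `"oesophageal"`, `"liver"`.
#' @param rr_table a `relative_risk_table` (or any data.table with columns
#'   factor, quantile, cancer, age_band, sex, rr).
#' @param age_band age-band label(s), recycled.
#' @param sex `"male"`/`"female"`, recycled.
#' @return numeric vector of relative risks (>= 0).
#' @export
#' @examples
#' rrt <- generate_relative_risks(5)
#' individual_relative_risk(list(bmi = 1L, physical_activity = 1L,
#'                               sedentary_time = 1L, alcohol = 1L),
#'                          "colorectal", rrt, "40-59", "male")
individual_relative_risk <- function(quantiles, cancer, rr_table,
                                     age_band = "40-59", sex = "female") {
  if (!cancer %in% CANCERS) stop_invalid("unknown cancer '%s'", cancer)
  used <- intersect(names(quantiles), RISK_FACTORS)
  n <- max(vapply(quantiles[used], length, 1L), length(age_band), length(sex))
  bi <- rep_len(match(age_band, AGE_BAND_LABELS), n)
  si <- rep_len(sex_index(sex), n)
  ci <- match(cancer, CANCERS)
  arr <- .rr_array(rr_table)
  Q <- max(rr_table$quantile)
  rr <- rep(1, n)
  for (f in used) {
    q <- rep_len(as.integer(quantiles[[f]]), n)
    if (any(q < 1 | q > Q)) {
      stop_invalid("quantile outside 1..%d for factor %s (missing RR cell)", Q, f)
    }
    rr <- rr * arr[[f]][cbind(q, ci, bi, si)]
  }
  rr
}

#' Calibrated annual incidence hazard
#'
#' The annual probability that an individual develops the cancer:
#' `baseline * rr / mean_rr`, clipped to `[0, 1]`. Dividing by the
#' population mean relative risk calibrates the simulation so that, in a
#' business-as-usual run, the simulated age-sex incidence reproduces the
#' baseline input rates while individual heterogeneity follows the relative
#' risks.
#'
#' @param baseline baseline incidence rate(s) per person-year.
#' @param rr individual relative risk(s).
#' @param mean_rr population mean relative risk for the individual's
#'   (age band, sex, cancer) stratum; must be positive.
#' @return hazard(s) in `[0, 1]`.
#' @export
#' @examples
#' calibrated_hazard(0.01, c(1, 3), mean_rr = 2)  # 0.005, 0.015
calibrated_hazard <- function(baseline, rr, mean_rr) {
  if (any(!is.finite(mean_rr)) || any(mean_rr <= 0)) {
    stop_invalid("`mean_rr` must be positive and finite")
  }
  pmin(1, pmax(0, baseline * rr / mean_rr))
}

# Hazards for every cancer over the whole individual table.
# Returns, per cancer: the hazard vector (0 where ineligible), the eligible
# mask, the sum of baseline rates over eligibles (the calibration target)
# and the shifted/unshifted mean-RR bookkeeping.
#
# The mean-RR normalisation is always computed over *unshifted* exposures of
# the at-risk (cancer-free) population, so baseline rates are reproduced
# under business-as-usual and intervention-induced RR reductions translate
# into incidence reductions rather than being normalised away.
.compute_hazards <- function(tab, ctx, y, int_ctx = NULL) {
  present <- .present(tab)
  age <- pmin(y - tab$birth_year, 100L)
  bi <- age_band_index(age)
  si <- sex_index(tab$sex)
  vals <- .exposure_values(tab, ctx, bi, si)
  effq_base <- .effective_quantiles(vals, ctx, bi, si)
  if (!is.null(int_ctx)) {
    vals_shift <- .shift_exposures(vals, tab, int_ctx, age, y)
    effq_shift <- .effective_quantiles(vals_shift, ctx, bi, si)
  } else {
    effq_shift <- effq_base
  }
  grp <- (si - 1L) * length(AGE_BAND_LABELS) + bi
  ngrp <- 2L * length(AGE_BAND_LABELS)
  out <- list()
  for (ci in seq_along(CANCERS)) {
    cc <- CANCERS[ci]
    eligible <- present & is.na(tab[[paste0("diag_", cc)]])
    rr_base <- .rr_product(effq_base, ctx, ci, bi, si)
    rr_shift <- if (is.null(int_ctx)) rr_base
                else .rr_product(effq_shift, ctx, ci, bi, si)
    idx <- which(eligible)
    g <- grp[idx]
    sums <- vapply(split(rr_base[idx], factor(g, levels = seq_len(ngrp))),
                   sum, 0)
    cnts <- tabulate(g, nbins = ngrp)
    mean_rr <- ifelse(cnts > 0, sums / pmax(cnts, 1L), 1)
    base <- ctx$inc[cbind(age[idx] + 1L, si[idx], ci)]
    h <- numeric(nrow(tab))
    h[idx] <- pmin(1, pmax(0, base * rr_shift[idx] / mean_rr[g]))
    out[[cc]] <- list(hazard = h, eligible = eligible,
                      expected_baseline = sum(base))
  }
  out
}

#' Sample incident cancer cases for one year
#'
#' Draws a per-individual Bernoulli event at the calibrated hazard for every
#' cancer. Individuals with the cancer already present or in remission are
#' not at risk (no second primaries of the same cancer); individuals can
#' hold multiple concurrent cancers of different types.
#'
#' @param population a `population`.
#' @param epidemiology a `disease_epidemiology`.
#' @param rr_table a `relative_risk_table`.
#' @param distributions list of `risk_factor_distribution`s.
#' @param seed integer master seed (per-cancer substreams are derived from
#'   the current year).
#' @return the `population` with new cases attached (diagnosis year set to
#'   the population's current year; the fatality plan is assigned
#'   separately by [assign_survival_outcome()]).
#' @export
sample_incident_cases <- function(population, epidemiology, rr_table,
                                  distributions, seed) {
  inputs <- list(distributions = distributions, epidemiology = epidemiology,
                 relative_risks = rr_table)
  ctx <- .build_sim_context(inputs)
  y <- population$current_year
  hz <- .compute_hazards(population$tab, ctx, y)
  for (ci in seq_along(CANCERS)) {
    cc <- CANCERS[ci]
    set.seed(substream_seed(seed, y, 40L + ci))
    u <- runif(nrow(population$tab))
    new_idx <- which(hz[[cc]]$eligible & u < hz[[cc]]$hazard)
    if (length(new_idx)) {
      set(population$tab, i = new_idx, j = paste0("diag_", cc), value = y)
    }
  }
  population
}

# Vectorised survival draw shared by the exported operation and the run loop.
.draw_survival <- function(n, p, cw) {
  u1 <- runif(n)
  u2 <- runif(n)
  will_die <- u1 < p
  k <- pmin(findInterval(u2, cw) + 1L, length(cw))
  list(will_die = will_die, years = k)
}

#' Assign the five-year fatality plan to fresh cases
#'
#' Each new case draws death-within-5-years from the (cancer, age band, sex)
#' case-fatality probability; predicted deaths draw a year of death from the
#' strictly decreasing mortality-year weights: `death_year =
#' diagnosis_year + k - 1` with `k` in 1..5 (so a case can die in its
#' diagnosis year).
#'
#' @param cases data.frame/data.table of fresh diagnoses with columns
#'   `cancer`, `age`, `sex` and optionally `diagnosis_year`.
#' @param epidemiology a `disease_epidemiology`.
#' @param seed integer seed.
#' @return `cases` with columns `will_die`, `years_to_death` (1..5, NA for
#'   survivors) and `death_year` (if `diagnosis_year` was supplied).
#' @export
assign_survival_outcome <- function(cases, epidemiology, seed) {
  cases <- as.data.table(cases)
  n <- nrow(cases)
  p5y <- array(NA_real_, dim = c(length(AGE_BAND_LABELS), 2L, length(CANCERS)))
  ef <- epidemiology$fatality
  p5y[cbind(match(ef$age_band, AGE_BAND_LABELS), sex_index(ef$sex),
            match(ef$cancer, CANCERS))] <- ef$p_death_5y
  p <- p5y[cbind(age_band_index(cases$age), sex_index(cases$sex),
                 match(cases$cancer, CANCERS))]
  set.seed(substream_seed(seed, 0L, 50L))
  dr <- .draw_survival(n, p, cumsum(epidemiology$mortality_year_weights))
  cases$will_die <- dr$will_die
  cases$years_to_death <- ifelse(dr$will_die, dr$years, NA_integer_)
  if ("diagnosis_year" %in% names(cases)) {
    cases$death_year <- ifelse(dr$will_die,
                               cases$diagnosis_year + dr$years - 1L,
                               NA_integer_)
  }
  cases[]
}

#' Apply the five-year remission rule
#'
#' Every alive case that has reached five full years since diagnosis without
#' a planned cancer death is marked as recovered. Remission is absorbing for
#' that cancer: the case stops accruing treatment costs and cancer
#' mortality, and the individual cannot be re-diagnosed with the same
#' cancer; all other risks continue.
#'
#' @param population a `population`.
#' @param year calendar year of the check (default: the population's
#'   current year).
#' @return the updated `population`.
#' @export
apply_remission <- function(population, year = NULL) {
  y <- if (is.null(year)) population$current_year else as.integer(year)
  tab <- population$tab
  for (cc in CANCERS) {
    cols <- .disease_cols(cc)
    diag <- tab[[cols[1]]]
    idx <- which(tab$alive &
                   !is.na(diag) & is.na(tab[[cols[4]]]) &
                   (is.na(tab[[cols[2]]]) | !tab[[cols[2]]]) &
                   (y - diag) >= 5L)
    if (length(idx)) set(tab, i = idx, j = cols[4], value = y)
  }
  population$tab <- tab
  population
}
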