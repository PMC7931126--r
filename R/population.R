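#' @title Synthetic populations
#' @description The population is held as a single data.table with one row
#'   per individual ever created: fixed attributes (id, birth year, sex,
#'   migration status), permanent risk-factor quantiles with persistent
#'   within-bin uniforms, persistent uniforms driving exposure selection and
#'   per-individual effect draws, vital status, and per-cancer disease state
#'   columns (diagnosis year, planned fatality, death year, remission year).
#' @name population
#' @keywords internal
NULL

.disease_cols <- function(cancer) {
  paste0(c("diag_", "die_", "dyear_", "remiss_"), cancer)
}

# Draw the attributes every entrant (initial cohort, newborn, immigrant)
# receives: quantile per factor, within-bin uniform per factor, exposure and
# effect-magnitude uniforms. Assumes the RNG is already seeded.
.draw_entry_attrs <- function(tab, n, Q) {
  for (f in RISK_FACTORS) {
    tab[[paste0("q_", f)]] <- sample.int(Q, n, replace = TRUE)
    tab[[paste0("u_", f)]] <- runif(n)
  }
  tab$u_expose <- runif(n)
  tab$u_effect <- runif(n)
  tab
}

# Entry attributes for newborns, drawn as full-length vectors over the
# parent table and subset at the mothers' row positions. Paired runs then
# give the same mother the same child regardless of how many other births
# occurred, which keeps counterfactual and intervention runs synchronised
# (common random numbers) after their histories first diverge.
.draw_entry_attrs_by_mother <- function(child_tab, mother_rows, n_rows, Q) {
  for (f in RISK_FACTORS) {
    child_tab[[paste0("q_", f)]] <- sample.int(Q, n_rows, TRUE)[mother_rows]
    child_tab[[paste0("u_", f)]] <- runif(n_rows)[mother_rows]
  }
  child_tab$u_expose <- runif(n_rows)[mother_rows]
  child_tab$u_effect <- runif(n_rows)[mother_rows]
  child_tab
}

.new_individual_tab <- function(id, birth_year, sex, migration_status) {
  n <- length(id)
  tab <- data.table(
    id = as.integer(id),
    birth_year = as.integer(birth_year),
    sex = sex,
    migration_status = migration_status,
    alive = rep(TRUE, n),
    dead_year = NA_integer_,
    death_cause = NA_character_,
    death_cancer = NA_character_
  )
  for (cc in CANCERS) {
    cols <- .disease_cols(cc)
    tab[[cols[1]]] <- NA_integer_
    tab[[cols[2]]] <- NA
    tab[[cols[3]]] <- NA_integer_
    tab[[cols[4]]] <- NA_integer_
  }
  tab
}

#' Initialize a synthetic population from a country profile
#'
#' Expands the population pyramid into individuals with a birth year, sex
#' and native migration status, permanently allocates each individual to a
#' fixed quantile per risk factor, and draws the persistent uniforms used
#' for within-bin exposure reconstruction, intervention exposure selection
#' and per-individual effect magnitudes. Everyone starts alive and
#' disease-free.
#'
#' @param profile a `country_profile`.
#' @param seed integer master seed.
#' @param n_quantiles quantile bins per risk factor (must match the
#'   distributions the population will be simulated against).
#' @return an object of class `population`: list with `tab` (the individual
#'   table), `current_year`, `start_year`, `n_quantiles`, `next_id` and
#'   `demography` (per-year accounting of births, deaths and migration).
#' @export
#' @examples
#' pr <- generate_country_profile(seed = 1, scale = 2000)
#' pop <- initialize_population(pr, seed = 1)
#' pop
initialize_population <- function(profile, seed, n_quantiles = 5L) {
  py <- profile$pyramid
  n <- sum(py$count)
  if (n == 0) stop_invalid("profile pyramid is empty")
  Q <- as.integer(n_quantiles)
  idx <- rep(seq_len(nrow(py)), py$count)
  tab <- .new_individual_tab(
    id = seq_len(n),
    birth_year = profile$start_year - py$age[idx],
    sex = py$sex[idx],
    migration_status = "native"
  )
  set.seed(substream_seed(seed, profile$start_year, 6L))
  tab <- .draw_entry_attrs(tab, n, Q)
  structure(
    list(
      tab = tab,
      current_year = profile$start_year,
      start_year = profile$start_year,
      n_quantiles = Q,
      next_id = n + 1L,
      demography = data.table(
        year = integer(), n_start = integer(), births = integer(),
        deaths_background = integer(), deaths_cancer = integer(),
        immigrants = integer(), emigrants = integer(), n_end = integer()
      )
    ),
    class = "population"
  )
}

#' @export
print.population <- function(x, ...) {
  n_alive <- sum(x$tab$alive & x$tab$migration_status != "emigrated")
  cat(sprintf("<population> year %d: %d alive of %d ever simulated\n",
              x$current_year, n_alive, nrow(x$tab)))
  invisible(x)
}

# In-population mask: alive and not emigrated.
.present <- function(tab) {
  tab$alive & tab$migration_status != "emigrated"
}

#' Advance the population one demographic year
#'
#' Applies one annual cycle in fixed event order: ageing (implicit in the
#' birth-year representation), births from the fertility schedule, net
#' migration, then background mortality (which excludes the modelled cancer
#' deaths; those are applied by the disease step). Appends one accounting
#' row to `population$demography` so that the headcount identity
#' N(t+1) = N(t) + births - deaths + net migrants holds exactly.
#'
#' @param population a `population`.
#' @param profile the `country_profile` providing the rates.
#' @param seed integer master seed of the run (substreams are derived per
#'   year and event).
#' @return the advanced `population` (current_year incremented by 1).
#' @export
step_demographics <- function(population, profile, seed) {
  if (population$current_year < profile$start_year) {
    stop_invalid("population year precedes profile start year")
  }
  y <- population$current_year + 1L
  tab <- population$tab
  Q <- population$n_quantiles
  present0 <- .present(tab)
  n_start <- sum(present0)
  age <- y - tab$birth_year

  # -- births --------------------------------------------------------------
  # All event uniforms are drawn over the full row set and indexed by row
  # position, so paired runs keep every common individual on an identical
  # stream even after their populations diverge (common random numbers).
  n0 <- nrow(tab)
  fert <- numeric(101)
  fert[profile$fertility$age + 1L] <- profile$fertility$rate
  set.seed(substream_seed(seed, y, 1L))
  u_birth <- runif(n0)
  mothers <- which(present0 & tab$sex == "female" & age >= 15 & age <= 49 &
                     u_birth < fert[pmin(age, 100) + 1L])
  births <- length(mothers)
  newborns <- NULL
  if (births > 0) {
    ids <- population$next_id + seq_len(births) - 1L
    set.seed(substream_seed(seed, y, 5L))
    sexes <- ifelse(runif(n0)[mothers] < 0.512, "male", "female")
    newborns <- .new_individual_tab(ids, y, sexes, "native")
    set.seed(substream_seed(seed, y, 6L))
    newborns <- .draw_entry_attrs_by_mother(newborns, mothers, n0, Q)
    population$next_id <- population$next_id + births
  }

  # -- net migration -------------------------------------------------------
  mig <- matrix(0, 101, 2)
  mr <- profile$migration
  mig[cbind(mr$age + 1L, sex_index(mr$sex))] <- mr$rate
  rate_i <- mig[cbind(pmin(age, 100) + 1L, sex_index(tab$sex))]
  immigrants_tab <- NULL
  n_imm <- 0L
  n_emi <- 0L
  set.seed(substream_seed(seed, y, 2L))
  # immigrants: per (age, sex) cell binomial at the positive net rate
  pos <- mr[mr$rate > 0]
  if (nrow(pos)) {
    pres_age <- pmin(age, 100)
    key <- paste(pres_age, tab$sex)[present0]
    counts <- table(key)
    cell_key <- paste(pos$age, pos$sex)
    cell_n <- as.integer(counts[cell_key])
    cell_n[is.na(cell_n)] <- 0L
    n_cell <- stats::rbinom(nrow(pos), cell_n, pos$rate)
    n_imm <- sum(n_cell)
    if (n_imm > 0) {
      idx <- rep(seq_len(nrow(pos)), n_cell)
      ids <- population$next_id + seq_len(n_imm) - 1L
      immigrants_tab <- .new_individual_tab(
        ids, y - pos$age[idx], pos$sex[idx], "immigrant")
      set.seed(substream_seed(seed, y, 7L))
      immigrants_tab <- .draw_entry_attrs(immigrants_tab, n_imm, Q)
      population$next_id <- population$next_id + n_imm
    }
  }
  # emigrants: per-individual Bernoulli at the negative net rate
  if (any(rate_i < 0)) {
    set.seed(substream_seed(seed, y, 8L))
    u <- runif(n0)
    leavers <- which(present0 & rate_i < 0 & u < -rate_i)
    if (length(leavers)) {
      set(tab, i = leavers, j = "migration_status", value = "emigrated")
      n_emi <- length(leavers)
    }
  }

  if (!is.null(newborns)) tab <- rbindlist(list(tab, newborns))
  if (!is.null(immigrants_tab)) tab <- rbindlist(list(tab, immigrants_tab))

  # -- background mortality ------------------------------------------------
  qx <- matrix(0, 101, 2)
  mt <- profile$mortality
  qx[cbind(mt$age + 1L, sex_index(mt$sex))] <- mt$qx
  present <- .present(tab)
  deaths_bg <- 0L
  if (any(present)) {
    a <- pmin(y - tab$birth_year, 100)
    p <- qx[cbind(a + 1L, sex_index(tab$sex))]
    set.seed(substream_seed(seed, y, 3L))
    u <- runif(nrow(tab))
    dead <- which(present & u < p)
    if (length(dead)) {
      set(tab, i = dead, j = "alive", value = FALSE)
      set(tab, i = dead, j = "dead_year", value = y)
      set(tab, i = dead, j = "death_cause", value = "background")
      deaths_bg <- length(dead)
    }
  }

  population$tab <- tab
  population$current_year <- y
  population$demography <- rbindlist(list(
    population$demography,
    data.table(year = y, n_start = n_start, births = as.integer(births),
               deaths_background = deaths_bg, deaths_cancer = 0L,
               immigrants = as.integer(n_imm), emigrants = as.integer(n_emi),
               n_end = sum(.present(tab)))
  ))
  population
}

#' Extract a yearly cross-section of the population
#'
#' @param population a `population`.
#' @return data.table with one row per individual ever simulated: year, id,
#'   age, sex, alive, migration status, risk quantiles and per-cancer
#'   disease flags (active / in remission).
#' @export
population_cross_section <- function(population) {
  tab <- population$tab
  y <- population$current_year
  out <- data.table(
    year = y,
    id = tab$id,
    age = y - tab$birth_year,
    sex = tab$sex,
    alive = tab$alive,
    migration_status = tab$migration_status
  )
  for (f in RISK_FACTORS) out[[paste0("q_", f)]] <- tab[[paste0("q_", f)]]
  for (cc in CANCERS) {
    cols <- .disease_cols(cc)
    out[[paste0("has_", cc)]] <- !is.na(tab[[cols[1]]])
    out[[paste0("remitted_", cc)]] <- !is.na(tab[[cols[4]]])
  }
  out[]
}

#' Export the disease-event log
#'
#' @param population a `population`.
#' @return data.table: id, cancer, diagnosis_year, death_year,
#'   remission_year (one row per case ever diagnosed).
#' @export
disease_event_log <- function(population) {
  tab <- population$tab
  out <- vector("list", length(CANCERS))
  for (k in seq_along(CANCERS)) {
    cc <- CANCERS[k]
    cols <- .disease_cols(cc)
    idx <- which(!is.na(tab[[cols[1]]]))
    out[[k]] <- data.table(
      id = tab$id[idx],
      cancer = cc,
      diagnosis_year = tab[[cols[1]]][idx],
      will_die = tab[[cols[2]]][idx],
      death_year = ifelse(!is.na(tab$dead_year[idx]) &
                            tab$death_cause[idx] == "cancer" &
                            !is.na(tab[[cols[3]]][idx]) &
                            tab[[cols[3]]][idx] == tab$dead_year[idx],
                          tab$dead_year[idx], NA_integer_),
      remission_year = tab[[cols[4]]][idx]
    )
  }
  rbindlist(out)[order(id, cancer)]
}
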