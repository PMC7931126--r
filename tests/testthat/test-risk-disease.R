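test_that("relative risks combine multiplicatively with a unit reference", {
  rrt <- generate_relative_risks(5)
  ref <- individual_relative_risk(
    list(bmi = 1L, physical_activity = 1L, sedentary_time = 1L, alcohol = 1L),
    "colorectal", rrt, "40-59", "male")
  expect_equal(ref, 1)
  # two active factors with RR 1.2 and 1.5 combine to 1.8
  toy <- data.table::CJ(factor = c("bmi", "alcohol"), quantile = 1:2,
                        cancer = "liver", age_band = "40-59", sex = "male",
                        sorted = FALSE)
  toy$rr <- ifelse(toy$quantile == 1, 1, ifelse(toy$factor == "bmi", 1.2, 1.5))
  got <- individual_relative_risk(list(bmi = 2L, alcohol = 2L), "liver", toy,
                                  "40-59", "male")
  expect_equal(got, 1.8)
  expect_error(
    individual_relative_risk(list(bmi = 9L), "liver", toy, "40-59", "male"),
    "missing RR cell")
})

test_that("population mean relative risk matches exhaustive enumeration over the joint quantile grid", {
  inp <- test_inputs(scale = 20000)
  rrt <- inp$relative_risks
  pop <- initialize_population(inp$profile, seed = 3)
  tab <- pop$tab
  quant <- list(bmi = tab$q_bmi, physical_activity = tab$q_physical_activity,
                sedentary_time = tab$q_sedentary_time, alcohol = tab$q_alcohol)
  emp <- mean(individual_relative_risk(quant, "oesophageal", rrt,
                                       "40-59", "male"))
  # oracle: enumerate all 5^4 equally likely quantile combinations
  grid <- expand.grid(bmi = 1:5, physical_activity = 1:5,
                      sedentary_time = 1:5, alcohol = 1:5)
  prods <- individual_relative_risk(as.list(grid), "oesophageal", rrt,
                                    "40-59", "male")
  expect_lt(abs(emp - mean(prods)), 3 * stats::sd(prods) / sqrt(nrow(tab)))
})

test_that("calibrated hazard reproduces the arithmetic of baseline x RR / mean RR", {
  # two-quantile toy: RRs {1, 3} in equal shares, baseline 0.01
  h <- calibrated_hazard(0.01, c(1, 3), mean_rr = 2)
  expect_equal(h, c(0.005, 0.015))
  expect_equal(mean(h), 0.01)                       # population mean preserved
  expect_equal(calibrated_hazard(0.02, rep(1, 5), 1), rep(0.02, 5))
  expect_equal(calibrated_hazard(0, 1000, 0.5), 0)  # null baseline
  expect_equal(calibrated_hazard(0.9, 10, 1), 1)    # clipped to [0, 1]
  expect_error(calibrated_hazard(0.01, 1, 0), "mean_rr")
})

test_that("incident case sampling is deterministic, respects zero hazard and matches its expectation", {
  inp <- test_inputs(scale = 20000)
  pop <- initialize_population(inp$profile, seed = 12)
  # zero baseline incidence -> zero cases
  epi0 <- inp$epidemiology
  epi0$incidence <- copy(epi0$incidence)[, rate := 0]
  p0 <- sample_incident_cases(pop, epi0, inp$relative_risks,
                              inp$distributions, seed = 12)
  expect_true(all(is.na(p0$tab$diag_breast)) & all(is.na(p0$tab$diag_liver)))
  # determinism under a fixed seed
  pa <- sample_incident_cases(pop, inp$epidemiology, inp$relative_risks,
                              inp$distributions, seed = 12)
  pb <- sample_incident_cases(pop, inp$epidemiology, inp$relative_risks,
                              inp$distributions, seed = 12)
  expect_identical(pa$tab, pb$tab)
  # with all RRs at 1 the hazard is the baseline rate: Poisson-binomial oracle
  rr1 <- copy(inp$relative_risks)[, rr := 1]
  p1 <- sample_incident_cases(pop, inp$epidemiology, rr1,
                              inp$distributions, seed = 12)
  age <- pop$current_year - pop$tab$birth_year
  inc <- inp$epidemiology$incidence
  for (cc in c("breast", "colorectal")) {
    rates <- inc[cancer == cc]
    expected <- sum(rates$rate[match(paste(pmin(age, 100), pop$tab$sex),
                                     paste(rates$age, rates$sex))])
    realised <- sum(!is.na(p1$tab[[paste0("diag_", cc)]]))
    expect_lt(abs(realised - expected), 3 * sqrt(expected) + 1e-9)
  }
})

test_that("survival outcomes recover the case-fatality probability and the decreasing year weights", {
  inp <- test_inputs()
  epi <- inp$epidemiology
  n <- 10000
  cases <- data.table(cancer = "colorectal", age = 65L, sex = "male",
                      diagnosis_year = 2020L)[rep(1, n)]
  # pool several independent streams: 5 x n cases
  died <- unlist(lapply(1:5, function(s) {
    assign_survival_outcome(cases, epi, seed = s)$will_die
  }))
  p <- epi$fatality[cancer == "colorectal" & age_band == "60-79" &
                      sex == "male", p_death_5y]
  expect_lt(abs(mean(died) - p), 3 * sqrt(p * (1 - p) / length(died)))
  # degenerate cases
  epi0 <- epi; epi0$fatality <- copy(epi$fatality)[, p_death_5y := 0]
  expect_false(any(assign_survival_outcome(cases, epi0, seed = 1)$will_die))
  epi1 <- epi; epi1$fatality <- copy(epi$fatality)[, p_death_5y := 1]
  epi1$mortality_year_weights <- c(1, 0, 0, 0, 0)
  all_now <- assign_survival_outcome(cases, epi1, seed = 1)
  expect_true(all(all_now$will_die))
  expect_true(all(all_now$death_year == 2020L))
  # fatal-case timing follows the weights within 3 SE per bin (multinomial)
  fatal <- assign_survival_outcome(cases, epi1_weights <- {
    e <- epi; e$fatality <- copy(epi$fatality)[, p_death_5y := 1]; e
  }, seed = 33)
  freq <- tabulate(fatal$years_to_death, nbins = 5) / n
  w <- epi$mortality_year_weights
  for (k in 1:5) {
    expect_lt(abs(freq[k] - w[k]), 3 * sqrt(w[k] * (1 - w[k]) / n))
  }
  expect_true(all(fatal$death_year >= 2020 & fatal$death_year <= 2024))
})

test_that("remission marks alive five-year survivors and never fatal cases", {
  inp <- test_inputs(scale = 2000)
  pop <- initialize_population(inp$profile, seed = 2)
  pop$tab$diag_breast[1:3] <- 2020L
  pop$tab$die_breast[1:3] <- c(FALSE, FALSE, TRUE)
  pop$tab$dyear_breast[3] <- 2023L
  pop$tab$alive[2] <- FALSE      # died of something else before year 5
  pop$tab$dead_year[2] <- 2022L
  early <- apply_remission(pop, year = 2024)
  expect_true(all(is.na(early$tab$remiss_breast[1:3])))  # boundary: < 5 years
  late <- apply_remission(pop, year = 2025)
  expect_equal(late$tab$remiss_breast[1], 2025L)
  expect_true(is.na(late$tab$remiss_breast[2]))  # dead, cannot remit
  expect_true(is.na(late$tab$remiss_breast[3]))  # fatal case never remits
})

test_that("raising a harmful relative risk increases expected incidence in the exposed group", {
  inp <- test_inputs(scale = 20000)
  pop <- initialize_population(inp$profile, seed = 14)
  ctx_lo <- oncoprev:::.build_sim_context(inp)
  inp_hi <- inp
  inp_hi$relative_risks <- copy(inp$relative_risks)[
    factor == "alcohol" & cancer == "oesophageal", rr := rr^2]
  ctx_hi <- oncoprev:::.build_sim_context(inp_hi)
  y <- pop$current_year + 1L
  hz_lo <- oncoprev:::.compute_hazards(pop$tab, ctx_lo, y)
  hz_hi <- oncoprev:::.compute_hazards(pop$tab, ctx_hi, y)
  top <- pop$tab$q_alcohol == 5
  expect_gt(sum(hz_hi$oesophageal$hazard[top]),
            sum(hz_lo$oesophageal$hazard[top]))
})
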