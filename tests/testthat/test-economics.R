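test_that("annual cost applies the per-case, multimorbidity and terminal-year rules", {
  co <- toy_costs()
  expect_equal(annual_cost(character(0), co), 0)
  expect_equal(annual_cost("breast", co), 10000)
  # two concurrent cancers at 10000 + 8000 with a 0.2 increment -> 21600
  expect_equal(annual_cost(c("breast", "colorectal"), co), 21600)
  expect_equal(annual_cost("breast", co, terminal = TRUE), 20000)
  expect_equal(annual_cost(c("breast", "colorectal"), co, terminal = TRUE),
               21600 * 2)
  expect_error(annual_cost("lung", co), "unknown cancer")
})

test_that("life-table expectancy matches brute-force survival summation", {
  profile <- generate_country_profile(seed = 5, scale = 2000)
  lt <- make_life_table(profile)
  qx <- profile$mortality[sex == "male"][order(age), qx]
  # oracle: accumulate survival and person-years from age 60 upwards
  for (a0 in c(0, 60, 90)) {
    surv <- 1
    py <- 0
    for (a in a0:100) {
      py <- py + surv * (1 - qx[a + 1] / 2)
      surv <- surv * (1 - qx[a + 1])
    }
    expect_equal(lt[sex == "male" & age == a0, ex], py, tolerance = 1e-9,
                 label = paste("ex at", a0))
  }
  expect_true(all(lt$ex > 0))
  expect_true(lt[age == 0 & sex == "female", ex] >
                lt[age == 0 & sex == "male", ex])
})

test_that("DALYs follow the YLD and YLL definitions", {
  profile <- generate_country_profile(seed = 5, scale = 2000)
  lt <- make_life_table(profile)
  w <- c(breast = 0.2, colorectal = 0.2, oesophageal = 0.2, liver = 0.2)
  run0 <- list(prevalence = data.table(year = 2020L, cancer = "breast", n = 0L),
               deaths = data.table(year = integer(), cancer = character(),
                                   age = integer(), sex = character(),
                                   n = integer()))
  expect_equal(compute_dalys(run0, w, lt)$daly, 0)
  run1 <- list(prevalence = data.table(year = 2020L, cancer = "breast", n = 100L),
               deaths = run0$deaths)
  expect_equal(compute_dalys(run1, w, lt)$yld, 20)  # 100 case-years x 0.2
  run2 <- list(prevalence = run0$prevalence,
               deaths = data.table(year = 2020L, cancer = "breast", age = 60L,
                                   sex = "female", n = 1L))
  got <- compute_dalys(run2, w, lt)
  expect_equal(got$yll, lt[sex == "female" & age == 60, ex])
})

test_that("scenario comparison subtracts paired runs stratum by stratum", {
  mk_run <- function(n1, n2, exp1, exp2) {
    structure(list(
      incidence = data.table(year = c(2020L, 2021L), cancer = "breast",
                             age_band = "60-79", age = 65L, sex = "female",
                             n = c(n1, n2)),
      expenditure = data.table(year = c(2020L, 2021L), cancer = "breast",
                               amount = c(exp1, exp2)),
      person_years = data.table(year = c(2020L, 2021L), py = c(1000L, 1000L)),
      dalys = data.table(year = c(2020L, 2021L), cancer = "breast",
                         yld = 0, yll = 0, daly = c(10, 10)),
      meta = list(years = 2020:2021, ppp_factor = 1,
                  intervention = "toy")), class = "run_result")
  }
  base <- mk_run(70L, 50L, 5e5, 4e5)
  intr <- mk_run(60L, 40L, 4.5e5, 3.5e5)
  cmp <- compare_scenarios(base, intr)
  expect_equal(cmp$cases_avoided_total, 20)       # 120 - 100
  expect_equal(cmp$savings_total, 1e5)
  expect_equal(cmp$savings_per_capita_per_year, 1e5 / 2000)
  expect_equal(sum(cmp$cases_avoided_by_year$avoided), cmp$cases_avoided_total)
  # identical runs compare to exactly zero
  self <- compare_scenarios(base, base)
  expect_equal(self$cases_avoided_total, 0)
  expect_equal(self$savings_total, 0)
  expect_equal(self$dalys_averted, 0)
  # PPP conversion rescales monetary outputs only
  cmp2 <- compare_scenarios(base, intr, ppp = 2)
  expect_equal(cmp2$savings_total, 5e4)
  expect_equal(cmp2$cases_avoided_total, 20)
  short <- mk_run(1L, 1L, 1, 1)
  short$meta$years <- 2020:2030
  expect_error(compare_scenarios(base, short), "horizon")
})

test_that("replicate intervals are degenerate for constants and need two replicates", {
  ci <- replicate_ci(rep(7, 10))
  expect_equal(c(ci$estimate, ci$lower, ci$upper), c(7, 7, 7))
  expect_error(replicate_ci(5), "at least 2")
})

test_that("replicate intervals cover a known mean at about the nominal level", {
  set.seed(424242)
  trials <- 300
  covered <- logical(trials)
  for (i in seq_len(trials)) {
    vals <- rnorm(30, mean = 2, sd = 1)
    ci <- replicate_ci(vals, boot_seed = i)
    covered[i] <- ci$lower <= 2 && 2 <= ci$upper
  }
  # bootstrap percentile coverage for a normal mean at R = 30: near 95%
  expect_gt(mean(covered), 0.89)
})

test_that("replicate interval width shrinks like one over the square root of R", {
  set.seed(77)
  width <- function(R) {
    ws <- replicate(40, {
      ci <- replicate_ci(rnorm(R), boot_seed = sample.int(1e6, 1))
      ci$upper - ci$lower
    })
    mean(ws)
  }
  ratio <- width(25) / width(400)
  expect_gt(ratio, 2.8)  # theoretical ratio 4
  expect_lt(ratio, 5.7)
})
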