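test_that("initialisation conserves the pyramid, starts disease-free and is deterministic", {
  inp <- test_inputs()
  pop <- initialize_population(inp$profile, seed = 9)
  expect_equal(nrow(pop$tab), sum(inp$profile$pyramid$count))
  expect_true(all(pop$tab$alive))
  expect_true(all(is.na(pop$tab$diag_breast)))
  expect_true(all(pop$tab$migration_status == "native"))
  expect_false(any(duplicated(pop$tab$id)))
  # age-sex composition matches the pyramid exactly (up to expansion)
  cs <- population_cross_section(pop)
  got <- cs[, .(count = .N), by = .(age, sex)]
  expect_equal(
    merge(inp$profile$pyramid, got, by = c("age", "sex"), all.x = TRUE)[
      , sum(abs(count.x - fifelse(is.na(count.y), 0L, count.y)))], 0)
  # sex share within 3 binomial SE of the profile share
  p_f <- inp$profile$pyramid[sex == "female", sum(count)] /
    sum(inp$profile$pyramid$count)
  obs <- mean(pop$tab$sex == "female")
  expect_lt(abs(obs - p_f), 3 * sqrt(p_f * (1 - p_f) / nrow(pop$tab)) + 1e-12)
  expect_identical(pop$tab, initialize_population(inp$profile, seed = 9)$tab)
  expect_false(identical(pop$tab$q_bmi,
                         initialize_population(inp$profile, seed = 10)$tab$q_bmi))
})

test_that("quantile assignments are fixed for life across demographic steps", {
  inp <- test_inputs(scale = 2000)
  pop <- initialize_population(inp$profile, seed = 4)
  before <- pop$tab[, .(id, q_bmi, q_alcohol)]
  for (i in 1:3) pop <- step_demographics(pop, inp$profile, seed = 4)
  after <- pop$tab[id %in% before$id, .(id, q_bmi, q_alcohol)]
  expect_identical(before, after[order(id)])
})

test_that("zero-rate dynamics are the identity apart from ageing", {
  p <- zero_rate_profile(scale = 2000)
  pop <- initialize_population(p, seed = 2)
  ages0 <- pop$current_year - pop$tab$birth_year
  pop2 <- step_demographics(pop, p, seed = 2)
  expect_equal(nrow(pop2$tab), nrow(pop$tab))
  expect_true(all(pop2$tab$alive))
  expect_equal(pop2$current_year - pop2$tab$birth_year, ages0 + 1L)
  dem <- pop2$demography
  expect_equal(dem$births + dem$deaths_background + dem$immigrants +
                 dem$emigrants, 0L)
  expect_equal(dem$n_end, dem$n_start)
})

test_that("background deaths match the Poisson-binomial oracle within 3 SE", {
  inp <- test_inputs(scale = 20000)
  pop <- initialize_population(inp$profile, seed = 6)
  y <- pop$current_year + 1L
  # oracle: sum of per-individual death probabilities before stepping
  qx <- inp$profile$mortality
  age_next <- pmin(y - pop$tab$birth_year, 100)
  key <- merge(data.table(age = age_next, sex = pop$tab$sex), qx,
               by = c("age", "sex"), sort = FALSE)
  expected <- sum(key$qx)
  se <- sqrt(sum(key$qx * (1 - key$qx)))
  pop2 <- step_demographics(pop, inp$profile, seed = 6)
  realised <- pop2$demography$deaths_background[1]
  expect_lt(abs(realised - expected), 3 * se)
})

test_that("newborns are born into the new year at age zero", {
  inp <- test_inputs(scale = 20000)
  pop <- initialize_population(inp$profile, seed = 5)
  pop2 <- step_demographics(pop, inp$profile, seed = 5)
  born <- pop2$tab[birth_year == pop2$current_year &
                     migration_status == "native"]
  expect_equal(nrow(born), pop2$demography$births[1])
  expect_gt(nrow(born), 0)
  expect_true(all(pop2$current_year - born$birth_year == 0))
  # births follow the fertility schedule in expectation (3 SE)
  fert <- inp$profile$fertility
  mothers <- pop$tab[sex == "female"]
  a <- pop2$current_year - mothers$birth_year
  rate <- fert$rate[match(pmin(a, 100), fert$age)]
  rate[is.na(rate)] <- 0
  expect_lt(abs(nrow(born) - sum(rate)), 3 * sqrt(sum(rate * (1 - rate))))
})

test_that("headcount accounting is exact every year and steps are reproducible", {
  inp <- test_inputs(scale = 5000)
  popA <- initialize_population(inp$profile, seed = 8)
  popB <- initialize_population(inp$profile, seed = 8)
  for (i in 1:5) {
    popA <- step_demographics(popA, inp$profile, seed = 8)
    popB <- step_demographics(popB, inp$profile, seed = 8)
  }
  expect_identical(popA$tab, popB$tab)  # common-random-number foundation
  dem <- popA$demography
  expect_equal(dem$n_end,
               dem$n_start + dem$births - dem$deaths_background -
                 dem$deaths_cancer + dem$immigrants - dem$emigrants)
  # nobody dies twice, nobody dead before the run's end is still alive
  expect_true(all(table(popA$tab[!is.na(dead_year), id]) == 1))
  expect_true(all(!popA$tab[!is.na(dead_year), alive]))
})
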