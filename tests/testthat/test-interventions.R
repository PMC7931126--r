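test_that("intervention construction rejects unknown names and off-range options", {
  expect_error(build_intervention("soda_tax"), "unknown intervention")
  expect_error(build_intervention("workplace_sb", workplace_exposure = 0.10),
               "workplace exposure")
  spec <- build_intervention("workplace_sb", workplace_exposure = 0.05)
  expect_equal(spec$exposure_fraction, 0.05)
})

test_that("the mass-media schedule evaluates at its knots and interpolates between them", {
  m <- build_intervention("mass_media")
  expect_equal(effect_at_time(m, 1 / 12), 60)
  expect_equal(effect_at_time(m, 1), 30)
  expect_equal(effect_at_time(m, 2), 0)
  expect_equal(effect_at_time(m, 5), 0)             # holds beyond last knot
  expect_equal(effect_at_time(m, 0.5),
               60 + (30 - 60) * (0.5 - 1 / 12) / (1 - 1 / 12))
  expect_error(effect_at_time(m, -0.1), "t must be")
  f <- build_intervention("food_labelling")
  expect_equal(effect_at_time(f, c(0, 1, 30)), rep(0.40, 3))  # sustained
})

test_that("exposure selection hits the target fraction and only eligible individuals", {
  inp <- test_inputs(scale = 20000)
  pop <- initialize_population(inp$profile, seed = 31)
  age <- pop$current_year - pop$tab$birth_year
  for (nm in c("menu_labelling", "food_labelling", "mass_media",
               "workplace_sb", "alcohol_tax", "mup")) {
    spec <- build_intervention(nm)
    sel <- select_exposed(pop, spec)
    exposed <- sel$tab$exposed
    eligible <- age >= spec$min_age & age <= spec$max_age
    expect_true(!any(exposed & !eligible), label = paste(nm, "eligibility"))
    p <- spec$exposure_fraction * spec$participation
    n_el <- sum(eligible)
    expect_lt(abs(mean(exposed[eligible]) - p),
              3 * sqrt(p * (1 - p) / n_el) + 1e-12,
              label = paste(nm, "fraction"))
  }
  # 100% exposure reaches every adult; 0% reaches nobody
  mm <- select_exposed(pop, build_intervention("mass_media"))
  expect_true(all(mm$tab$exposed[age >= 19]))
  zero <- build_intervention("food_labelling")
  zero$exposure_fraction <- 0
  expect_false(any(select_exposed(pop, zero)$tab$exposed))
  # an explicit seed redraws the Bernoulli stream
  s1 <- select_exposed(pop, build_intervention("menu_labelling"), seed = 1)
  s2 <- select_exposed(pop, build_intervention("menu_labelling"), seed = 2)
  expect_false(identical(s1$tab$exposed, s2$tab$exposed))
})

test_that("price elasticity identities hold cell by cell", {
  el <- generate_elasticities(seed = 1)
  toy <- data.table(beverage = "beer", age_band = "30-49",
                    category = "moderate", consumption = 20)
  el_toy <- el
  el_toy$elasticity <- data.table(beverage = "beer", age_band = "30-49",
                                  category = "moderate", elasticity = -0.5)
  out <- apply_price_intervention(toy, el_toy, price_shock(0.10))
  expect_equal(out$pct_change, -0.05)             # elasticity identity
  expect_equal(out$consumption_adj, 20 * 0.95)
  el_toy$elasticity$elasticity <- 0
  expect_equal(apply_price_intervention(toy, el_toy,
                                        price_shock(0.10))$consumption_adj, 20)
  # never negative, even under an extreme elasticity
  el_toy$elasticity$elasticity <- -15
  expect_equal(apply_price_intervention(toy, el_toy,
                                        price_shock(0.9))$consumption_adj, 0)
  expect_error(price_shock(-1.5), "exceed -1")
  expect_error(apply_price_intervention(toy, el_toy,
                                        price_shock(0.1, mup_floor = 1)),
               "apply_mup")
})

test_that("minimum unit pricing follows the below-floor share arithmetic", {
  el <- generate_elasticities(seed = 1)
  el$elasticity <- data.table(beverage = "beer", age_band = "30-49",
                              category = "moderate", elasticity = -0.5)
  # toy: half the volume at 0.8 x floor -> uplift 25% on the affected share
  pd <- data.table(beverage = "beer", price = c(0.8, 1.2), share = c(0.5, 0.5))
  out <- apply_mup(pd, mup_floor = 1.0, elasticities = el)
  st <- attr(out, "mup_stats")
  expect_equal(st$below_share, 0.5)
  expect_equal(st$uplift, 0.25)
  expect_equal(out$pct_change, 0.5 * 0.25 * -0.5)   # hand arithmetic
  # floor below the entire distribution binds nothing
  none <- apply_mup(pd, mup_floor = 0.5, elasticities = el)
  expect_equal(none$pct_change, 0)
  expect_error(apply_mup(pd, 0, el), "mup_floor")
})

test_that("individual-level effects shift exposures by the published magnitudes", {
  food <- build_intervention("food_labelling")
  expect_equal(apply_risk_factor_effect(30, food, t = 1), 30 * (1 - 0.0040))
  menu <- build_intervention("menu_labelling")
  lohi <- apply_risk_factor_effect(c(30, 30), menu, t = 1, u_effect = c(0, 1))
  expect_equal(lohi, c(30 * (1 - 0.0105), 30 * (1 - 0.0131)))
  draws <- apply_risk_factor_effect(rep(30, 500), menu, t = 1,
                                    u_effect = runif(500))
  drop_pct <- 100 * (1 - draws / 30)
  expect_true(all(drop_pct >= 1.05 - 1e-9 & drop_pct <= 1.31 + 1e-9))
  ws <- build_intervention("workplace_sb")
  expect_equal(apply_risk_factor_effect(480, ws, t = 3),
               480 - 72.78 * 5 / 7)
  expect_equal(apply_risk_factor_effect(10, ws, t = 3), 0)  # floored at zero
  mm <- build_intervention("mass_media")
  expect_equal(apply_risk_factor_effect(1000, mm, t = 1), 1000 * 1.30)
  expect_equal(apply_risk_factor_effect(1000, mm, t = 3), 1000)  # decayed
})

test_that("alcohol price effects apply the beverage-weighted cell change and spare abstainers", {
  el <- generate_elasticities(seed = 1)
  tax <- build_intervention("alcohol_tax")
  # oracle: beverage-share-weighted elasticity x price change for the cell
  cell <- el$elasticity[age_band == "30-49" & category == "moderate"]
  delta <- sum(el$beverage_share[cell$beverage] * cell$elasticity * 0.10) /
    sum(el$beverage_share[cell$beverage])
  got <- apply_risk_factor_effect(10, tax, t = 1, age = 40, elasticities = el)
  expect_equal(got, 10 * (1 + delta))
  expect_equal(apply_risk_factor_effect(0, tax, t = 1, age = 40,
                                        elasticities = el), 0)
  # heavy drinkers use the heavy-category cells
  heavy_cell <- el$elasticity[age_band == "50+" & category == "heavy"]
  delta_h <- sum(el$beverage_share[heavy_cell$beverage] *
                   heavy_cell$elasticity * 0.10) /
    sum(el$beverage_share[heavy_cell$beverage])
  expect_equal(apply_risk_factor_effect(60, tax, t = 1, age = 60,
                                        elasticities = el), 60 * (1 + delta_h))
  expect_error(apply_risk_factor_effect(10, tax, t = 1), "elasticity_table")
})
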