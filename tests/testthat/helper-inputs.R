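# Shared fixtures: all synthetic, generated in code, memoised per process so
# repeated calls across test files stay cheap.

library(data.table)

test_inputs <- local({
  cache <- list()
  function(seed = 1, scale = 5000, n_quantiles = 5) {
    key <- paste(seed, scale, n_quantiles, sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_model_inputs(seed, scale, n_quantiles)
    }
    cache[[key]]
  }
})

# A profile with every demographic rate zeroed: identity dynamics.
zero_rate_profile <- function(seed = 1, scale = 2000) {
  p <- generate_country_profile(seed, scale)
  p$fertility$rate <- 0
  p$mortality$qx <- 0
  p$migration$rate <- 0
  p
}

# Minimal hand-built cost profile for arithmetic oracles.
toy_costs <- function(annual = c(breast = 10000, colorectal = 8000,
                                 oesophageal = 5000, liver = 4000),
                      mult = 2, increment = 0.2) {
  structure(
    list(annual_cost = annual, last_year_multiplier = mult,
         multimorbidity_increment = increment,
         disability_weight = c(breast = 0.2, colorectal = 0.2,
                               oesophageal = 0.2, liver = 0.2)),
    class = "cost_profile"
  )
}
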