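# Shared fixtures, built once per test run. Small population so the unit
# suite stays fast; the acceptance tests build their own full-size worlds.
fix <- local({
  pop <- generate_population(population_sigma("I"), c(3, 3, 3), 4000,
                             seed = 101)
  pop2 <- generate_population(population_sigma("II"), c(3, 3, 3), 4000,
                              seed = 102)
  dp <- dp_params(0.5, 0.5)
  np <- np_params(0.5, 1, 0.5, 0.5)           # paper-mode mixture, g = 0.5
  np0 <- np_params(0, 1, 0.5, 0.5)            # printed G exact at g = 0
  list(
    pop = pop, pop2 = pop2, dp = dp, np = np, np0 = np0,
    mom_dp = expected_population_moments(pop, dp, k = 25, seed = 7),
    mom_np = expected_population_moments(pop, np, k = 25, seed = 8),
    mom_np0 = expected_population_moments(pop, np0, k = 25, seed = 9)
  )
})

# closed-form population-level summary for census-identity checks:
# the expected scrambled variance and mean given the true (finite-population)
# moments of Y and the model parameters
census_summary_dp <- function(var_y, mean_y, params, var_x1, var_x2,
                              n = 1000L) {
  sz2 <- var_y * (params$var_t + 1) + params$var_t * mean_y^2 + params$var_s
  sample_summary(n, sz2, var_x1, var_x2, mean_y)
}

census_summary_np <- function(var_y, mean_y, params, var_x1, var_x2,
                              n = 1000L) {
  w2 <- var_y + params$a^2 * params$var_s
  sz2 <- w2 * (1 + params$mult) + params$mult * mean_y^2
  sample_summary(n, sz2, var_x1, var_x2, mean_y)
}

expect_rel_equal <- function(actual, expected, tol = 1e-6) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-8), tol)
}
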