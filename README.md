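# rrtvar

Variance estimation for **sensitive variables** under scrambled
randomized-response (RRT) survey designs.

When a survey question is sensitive (income, grades, drug use),
respondents can report a randomized transformation *Z* of the true value
*Y* instead of *Y* itself. `rrtvar` implements the estimation machinery
for the **finite-population variance** σ²ᵧ = Σ(Yᵢ − Ȳ)²/(N−1) from one
SRSWOR sample of such scrambled responses:

* **Scrambling models** — the multiplicative–additive model
  `Z = T·Y + S` (T mean 1, S mean 0) and a mixture model
  `Z = g(Y + aS) + (1−g)·R·(Y + aS)`, with pluggable normal/uniform
  scrambling distributions and the privacy measure Δ = E(Z − Y)².
* **Estimators** — the basic decoder t₀, ratio and generalized-ratio
  forms, and a generalized exponential class using two auxiliary
  variables, with closed-form optimum constants:

  t₁D = [k₁t₀* + k₂(σ²ₓ₁ − s²ₓ₁) + k₃(σ²ₓ₂ − s²ₓ₂)] ·
  exp{(σ²ₓ₁ − s²ₓ₁)/(σ²ₓ₁ + s²ₓ₁)}^λ₁ · (σ²ₓ₂/s²ₓ₂)^λ₂

* **First-order theory** — closed-form bias/MSE/minimum-MSE for every
  estimator, validated against an independent numerical delta-method
  oracle (`delta_method_mse()`, `delta_method_bias()`); literal
  printed-source readings that the oracle contradicts are retained
  behind `strict_paper = TRUE`.
* **Monte-Carlo engine** — seeded simulations reporting empirical mean,
  MSE, percent relative efficiency (PRE = 100·MSE(t₀)/MSE(tᵢ)) and the
  unified privacy–efficiency measure ϑ = MSE/Δ, formatted as
  publication-style tables.

See the methods vignette (`vignettes/rrt-variance-estimation.Rmd`) for
the model assumptions, parameter defaults and their rationale, and what
the synthetic benchmark does and does not establish.

## Worked example

```r
library(rrtvar)

# a fixed synthetic finite population (benchmark covariance "I")
pop <- generate_population(population_sigma("I"), c(3, 3, 3),
                           100000, seed = 1)
var(pop$y)                       # 10.0706  <- the estimand

dp  <- dp_params(var_t = 0.5, var_s = 0.2)
mom <- expected_population_moments(pop, dp, k = 50, seed = 2)

# closed-form optimum constants and first-order theory at n = 500
kopt <- optimum_constants_t1d(mom, dp, lambda1 = 0, lambda2 = 0, n = 500)
unlist(kopt[c("k1", "k2", "k3")])  # 0.9895 1.7428 1.5522
mse_t0_theory(mom, dp, 500)        # 1.2786
t1d_theory(mom, dp, kopt, 500)$min_mse  # 1.1512
privacy_dp(mean(pop$y), var(pop$y), 0.5, 0.2)$delta  # 9.714

# one scrambled sample, end to end
idx <- draw_srswor(pop$size, 500, seed = 3)
z   <- scramble_dp(pop$y[idx], dp, seed = 4)
s   <- summarize_sample(z, pop$x1[idx], pop$x2[idx])
as.numeric(t0_dp(s, dp))                                  # 9.1994
as.numeric(t1d(s, dp, var(pop$x1), var(pop$x2), kopt))    # 9.3914
```

The generalized estimator's theoretical minimum MSE (1.1512) undercuts
the basic decoder's (1.2786): a PRE of about 111%. A full simulation
sweep:

```r
cfg <- simulation_config(population_sigma("I"), model = "dp",
                         var_s_list = 0.2, n_list = 500,
                         replications = 2000, seed = 42,
                         pop_size = 20000, moment_ensemble = 20)
build_table(run_monte_carlo(cfg), "table4")
#>   var_s   n estimator    mean    mse    pre vartheta
#> 1   0.2 500        t0 10.0618 1.3302 100.00   0.1356
#> 2   0.2 500     ratio 10.0740 1.3828  96.20   0.1410
#> 3   0.2 500    gratio 10.0569 1.2478 106.61   0.1272
#> 4   0.2 500       t1D  9.8997 1.2154 109.45   0.1239
```

Columns: empirical mean of the estimator, its empirical MSE against the
realized σ²ᵧ, PRE against t₀, and ϑ = MSE/Δ (smaller is better). At this
modest replication count the ratio estimator's PRE sits within
Monte-Carlo noise of 100; the generalized estimator is reliably best.

## Command line

```sh
Rscript inst/cli/rrtvar.R simulate --config cfg.json --out results.csv
Rscript inst/cli/rrtvar.R theory   --config cfg.json
Rscript inst/cli/rrtvar.R privacy  --config cfg.json
Rscript inst/cli/rrtvar.R tables   --config cfg.json --layout table4
```

The JSON config mirrors `simulation_config()` (see the header of
`inst/cli/rrtvar.R`).

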