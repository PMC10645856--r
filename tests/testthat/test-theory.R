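# Every closed-form bias/MSE must agree with the generic numerical
# delta-method oracle; the oracle itself is pinned by analytic special cases.

test_that("the oracle reproduces analytic special cases", {
  mom <- fix$mom_dp
  n <- 250
  # identity estimator t = s_z^2: theta sigma_z^4 (mu_400 - 1)
  ident <- function(s2_z, s2_x1, s2_x2, zbar) s2_z
  expect_rel_equal(delta_method_mse(ident, mom, n),
                   (mom$var_z - mom$var_y)^2 +
                     mom$var_z^2 * (mu_moment(mom, 4, 0, 0) - 1) / n, 1e-8)
  # constant estimator t = c: (c - sigma_y^2)^2
  konst <- function(...) 12.34
  expect_rel_equal(delta_method_mse(konst, mom, n),
                   (12.34 - mom$var_y)^2, 1e-10)
})

test_that("all closed-form MSEs match the delta-method oracle to 1e-6", {
  n <- 400
  configs <- list(
    list(params = fix$dp, mom = fix$mom_dp),
    list(params = fix$np0, mom = fix$mom_np0),
    list(params = fix$np, mom = fix$mom_np),                 # paper mode
    list(params = np_params(0.5, 1, 0.5, 0.5, mode = "consistent"),
         mom = fix$mom_np)
  )
  for (cf in configs) {
    p <- cf$params; mom <- cf$mom
    vx1 <- mom$var_x1; vx2 <- mom$var_x2
    is_dp <- inherits(p, "dp_params")
    tag_base <- if (is_dp) "t0" else "tNP1"
    tag_ratio <- if (is_dp) "ratio" else "tNP2"

    f <- as_moment_function(tag_base, p, vx1, vx2)
    expect_rel_equal(mse_t0_theory(mom, p, n), delta_method_mse(f, mom, n))
    expect_rel_equal(bias_t0_theory(mom, p, n),
                     delta_method_bias(f, mom, n), 1e-5)

    f <- as_moment_function(tag_ratio, p, vx1, vx2)
    expect_rel_equal(mse_tratio_theory(mom, p, n),
                     delta_method_mse(f, mom, n))
    expect_rel_equal(bias_tratio_theory(mom, p, n),
                     delta_method_bias(f, mom, n), 1e-5)

    if (is_dp) {
      gc_opt <- optimum_omega_gratio(mom, p, n)
      f <- as_moment_function("gratio", p, vx1, vx2,
                              constants = list(gratio = gc_opt))
      expect_rel_equal(min_mse_tgratio_theory(mom, p, n),
                       delta_method_mse(f, mom, n))
      # arbitrary constants at two (lambda1, lambda2) pairs
      for (cc in list(t1d_constants(0.9, 0.4, -0.3, 1.2, 0.6),
                      t1d_constants(1.05, -0.2, 0.1, 0, 0))) {
        f <- as_moment_function("t1D", p, vx1, vx2,
                                constants = list(t1D = cc))
        th <- t1d_theory(mom, p, cc, n)
        expect_rel_equal(th$mse, delta_method_mse(f, mom, n))
        expect_rel_equal(th$bias, delta_method_bias(f, mom, n), 1e-5)
      }
    } else {
      for (cc in list(t1n_constants(0.9, 0.4, -0.3, 1.2, 0.6),
                      t1n_constants(1.05, -0.2, 0.1, 0, 0))) {
        f <- as_moment_function("t1N", p, vx1, vx2,
                                constants = list(t1N = cc))
        th <- t1n_theory(mom, p, cc, n)
        expect_rel_equal(th$mse, delta_method_mse(f, mom, n))
        expect_rel_equal(th$bias, delta_method_bias(f, mom, n), 1e-5)
      }
    }
  }
})

test_that("minimum MSE is attained at the closed-form optimum", {
  n <- 350
  kopt <- optimum_constants_t1d(fix$mom_dp, fix$dp, 0.5, 1.5, n)
  th <- t1d_theory(fix$mom_dp, fix$dp, kopt, n)
  expect_rel_equal(th$mse, th$min_mse, 1e-10)
  # the minimum is invariant to the generalization constants
  k2 <- optimum_constants_t1d(fix$mom_dp, fix$dp, 0, 0, n)
  expect_rel_equal(t1d_theory(fix$mom_dp, fix$dp, k2, n)$min_mse,
                   th$min_mse, 1e-10)

  wopt <- optimum_constants_t1n(fix$mom_np0, fix$np0, 1, 1, n)
  thn <- t1n_theory(fix$mom_np0, fix$np0, wopt, n)
  expect_rel_equal(thn$mse, thn$min_mse, 1e-10)
})

test_that("reduction identities collapse the generalized forms", {
  n <- 200
  # k = (1,0,0), lambda = 0: generalized MSE equals the base MSE
  th <- t1d_theory(fix$mom_dp, fix$dp, t1d_constants(1, 0, 0, 0, 0), n)
  expect_rel_equal(th$mse, mse_t0_theory(fix$mom_dp, fix$dp, n), 1e-10)
  expect_rel_equal(th$bias, bias_t0_theory(fix$mom_dp, fix$dp, n), 1e-10)
  thn <- t1n_theory(fix$mom_np0, fix$np0, t1n_constants(1, 0, 0, 0, 0), n)
  expect_rel_equal(thn$mse, tnp1_theory(fix$mom_np0, fix$np0, n)$mse, 1e-10)

  # scrambling-free limit: classical first-order MSE of s^2
  p0 <- dp_params(0, 0)
  mom0 <- compute_population_moments(fix$pop, fix$pop$y)
  expect_rel_equal(mse_t0_theory(mom0, p0, n),
                   mom0$var_z^2 * (mu_moment(mom0, 4, 0, 0) - 1) / n, 1e-10)

  # uncorrelated auxiliary: gratio gains nothing
  mom_u <- fix$mom_dp
  mom_u$mu[["220"]] <- 1
  mom_u$mu[["120"]] <- 0
  expect_rel_equal(min_mse_tgratio_theory(mom_u, fix$dp, n),
                   mse_t0_theory(mom_u, fix$dp, n), 1e-10)
})

test_that("gratio improvement term is a true minimum over omega", {
  n <- 300
  mn <- min_mse_tgratio_theory(fix$mom_dp, fix$dp, n)
  expect_lte(mn, mse_t0_theory(fix$mom_dp, fix$dp, n))
  gc_opt <- optimum_omega_gratio(fix$mom_dp, fix$dp, n)
  mse_at <- function(om) {
    f <- as_moment_function("gratio", fix$dp, fix$mom_dp$var_x1,
                            fix$mom_dp$var_x2,
                            constants = list(gratio = gratio_constants(
                              1, 0, om, 1)))
    delta_method_mse(f, fix$mom_dp, n)
  }
  o <- optimize(mse_at, gc_opt$omega + c(-2, 2), tol = 1e-10)
  expect_rel_equal(o$objective, mn, 1e-6)
  expect_lt(abs(o$minimum - gc_opt$omega), 1e-3)
})

test_that("strict_paper variants reproduce the literal printed readings", {
  n <- 300
  mom <- fix$mom_dp; p <- fix$dp
  dflt <- mse_t0_theory(mom, p, n)
  lit <- mse_t0_theory(mom, p, n, strict_paper = TRUE)
  # literal Eq: middle term 4 sigma_T^2 Zbar^2 C_z^2 instead of
  # 4 sigma_T^4 Zbar^4 C_z^2; difference is the predictable gap
  gap <- (4 * p$var_t^2 * mom$mean_z^4 * mom$cv_z^2 -
            4 * p$var_t * mom$mean_z^2 * mom$cv_z^2) / (p$var_t + 1)^2 / n
  expect_rel_equal(dflt - (mom$var_y - attr(
    optimum_constants_t1d(mom, p, 0, 0, n), "terms")$tp)^2 - lit, gap, 1e-6)
  expect_false(isTRUE(all.equal(
    mse_tratio_theory(mom, p, n),
    mse_tratio_theory(mom, p, n, strict_paper = TRUE))))
  expect_false(isTRUE(all.equal(
    min_mse_tgratio_theory(mom, p, n),
    min_mse_tgratio_theory(mom, p, n, strict_paper = TRUE))))
  # literal minimum-MSE reading sigma_y^6 (1 - 1/A7) vs the dimensionally
  # consistent sigma_y^4 (1 - sigma_y^4/A7)
  k <- optimum_constants_t1d(mom, p, 1, 1, n)
  d <- t1d_theory(mom, p, k, n)
  l <- t1d_theory(mom, p, k, n, strict_paper = TRUE)
  expect_rel_equal(l$min_mse,
                   mom$var_y^3 * (1 - 1 / d$terms$A7), 1e-10)
  expect_false(isTRUE(all.equal(l$min_mse, d$min_mse)))
})

test_that("efficiency comparison orders estimators by direct MSE", {
  n <- 300
  tab <- efficiency_compare(fix$mom_dp, fix$dp, n,
                            c("t0", "ratio", "gratio", "t1D",
                              "t1D(3)", "t1D(4)", "t1D(7)"))
  expect_equal(tab$mse[tab$tag == "t0"],
               mse_t0_theory(fix$mom_dp, fix$dp, n))
  expect_true(tab$better_than_t0[tab$tag == "t1D"])
  expect_false(tab$better_than_t0[tab$tag == "t0"])
  # full class dominates every restricted member
  expect_true(all(tab$mse[tab$tag == "t1D"] <= tab$mse + 1e-12))
  # Population II: strong auxiliary correlations make t1D clearly better
  mom2 <- expected_population_moments(fix$pop2, fix$dp, k = 25, seed = 10)
  tab2 <- efficiency_compare(mom2, fix$dp, n, c("t0", "t1D"))
  expect_true(tab2$better_than_t0[tab2$tag == "t1D"])
})

test_that("theory sign agrees with Monte-Carlo MSE differences", {
  # scaled down: 3 configurations x 6000 replications; the t1D-vs-t0
  # difference is large so the sign is unambiguous at this size
  for (cfg in list(list(pop = "I", vs = 0.2), list(pop = "I", vs = 1),
                   list(pop = "II", vs = 0.5))) {
    cc <- simulation_config(population_sigma(cfg$pop), pop_size = 20000,
                            model = "dp", var_s_list = cfg$vs,
                            n_list = 300, replications = 6000,
                            moment_ensemble = 20, seed = 321,
                            estimators = c("t0", "t1D"))
    res <- run_monte_carlo(cc)
    diff_mc <- res$empirical_mse[res$estimator == "t1D"] -
      res$empirical_mse[res$estimator == "t0"]
    expect_lt(diff_mc, 0)   # matches theory: min MSE below t0's MSE
  }
})
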