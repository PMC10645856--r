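test_that("decoding estimators reproduce hand-evaluated arithmetic", {
  s <- sample_summary(100, s2_z = 10, s2_x1 = 1, s2_x2 = 2, zbar = 2)
  p <- dp_params(0.5, 1)
  expect_equal(as.numeric(t0_dp(s, p)), (10 - 1 - 0.5 * 4) / 1.5,
               tolerance = 1e-12)
  expect_equal(as.numeric(t_ratio_dp(s, p, var_x1_pop = 2)),
               (10 - 1 - 2) / 1.5 * 2, tolerance = 1e-12)

  # mixture model, hand-evaluated
  np <- np_params(0.9, 2, 0.0004, 4)
  sn <- sample_summary(20, 6.78^2, 8.66^2, 18.83^2, 52.31)
  G <- 0.9^2 + 0.1^2 * (0.0004 + 1)
  hand <- (6.78^2 - 0.1^2 * 0.0004 * 52.31^2) / G - 4 * 4
  expect_equal(as.numeric(t_np1(sn, np)), hand, tolerance = 1e-12)
  expect_equal(as.numeric(t_np2(sn, np, var_x1_pop = 3)),
               hand * 3 / 8.66^2, tolerance = 1e-12)
})

test_that("negative estimates are flagged, optionally truncated", {
  s <- sample_summary(50, s2_z = 1, s2_x1 = 1, s2_x2 = 1, zbar = 5)
  p <- dp_params(0.5, 1)
  v <- t0_dp(s, p)
  expect_true(attr(v, "negative"))
  expect_lt(as.numeric(v), 0)
  expect_equal(as.numeric(t0_dp(s, p, truncate = TRUE)), 0)
})

test_that("census identities hold exactly at population moments", {
  vy <- var(fix$pop$y); my <- mean(fix$pop$y)
  vx1 <- var(fix$pop$x1); vx2 <- var(fix$pop$x2)

  s <- census_summary_dp(vy, my, fix$dp, vx1, vx2)
  expect_equal(as.numeric(t0_dp(s, fix$dp)), vy, tolerance = 1e-10)
  expect_equal(as.numeric(t_ratio_dp(s, fix$dp, vx1)), vy,
               tolerance = 1e-10)
  expect_equal(as.numeric(
    t_gratio_dp(s, fix$dp, vx1, gratio_constants(2, 1, 0.7, 3))), vy,
    tolerance = 1e-10)
  # generalized estimator at census: k1 * sigma_y^2 for any lambdas
  expect_equal(as.numeric(
    t1d(s, fix$dp, vx1, vx2, t1d_constants(0.8, 5, -2, 1.3, 0.4))),
    0.8 * vy, tolerance = 1e-10)

  # mixture model with g = 1 (additive): exact decoding
  np_add <- np_params(1, 1, 0.5, 0.5)
  sn <- census_summary_np(vy, my, np_add, vx1, vx2)
  expect_equal(as.numeric(t_np1(sn, np_add)), vy, tolerance = 1e-10)
  expect_equal(as.numeric(t_np2(sn, np_add, vx1)), vy, tolerance = 1e-10)
  expect_equal(as.numeric(
    t1n(sn, np_add, vx1, vx2, t1n_constants(1, 0, 0, 2, 1))), vy,
    tolerance = 1e-10)

  # consistent-mode decoder: identity holds for any g
  npc <- np_params(0.5, 1, 0.5, 0.5, mode = "consistent")
  snc <- census_summary_np(vy, my, npc, vx1, vx2)
  expect_equal(as.numeric(t_np1(snc, npc)), vy, tolerance = 1e-10)
})

test_that("paper-mode census gap equals 2g(1-g)sigma_W^2 / G", {
  vy <- var(fix$pop$y); my <- mean(fix$pop$y)
  npp <- fix$np                                      # g = 0.5, paper mode
  s <- census_summary_np(vy, my, npp, var(fix$pop$x1), var(fix$pop$x2))
  w2 <- vy + npp$a^2 * npp$var_s
  gap_pred <- 2 * npp$g * (1 - npp$g) * w2 / npp$G_paper
  expect_equal(as.numeric(t_np1(s, npp)) - vy, gap_pred, tolerance = 1e-10)
  # and by Monte Carlo on a large scrambled population
  z <- scramble_proposed(fix$pop$y, npp, seed = 61)
  smry <- summarize_sample(z, fix$pop$x1, fix$pop$x2)
  expect_lt(abs(as.numeric(t_np1(smry, npp)) - (vy + gap_pred)),
            0.12 * w2)   # loose MC tolerance, N = 4000
})

test_that("generalized class reduces to its named members bit-for-bit", {
  z <- scramble(fix$pop$y, fix$dp, seed = 71)
  idx <- draw_srswor(fix$pop$size, 120, seed = 72)
  s <- summarize_sample(z[idx], fix$pop$x1[idx], fix$pop$x2[idx])
  vx1 <- var(fix$pop$x1); vx2 <- var(fix$pop$x2)

  expect_identical(
    as.numeric(t1d(s, fix$dp, vx1, vx2, t1d_constants(1, 0, 0, 0, 0))),
    as.numeric(t0_dp(s, fix$dp)))
  # member 1D(3): ratio estimator on X2
  m3 <- make_class_estimator("1D(3)")
  expect_identical(m3$constants[c("k1", "k2", "k3", "lambda1", "lambda2")],
                   list(k1 = 1, k2 = 0, k3 = 0, lambda1 = 0, lambda2 = 1))
  expect_equal(
    as.numeric(t1d(s, fix$dp, vx1, vx2, m3$constants)),
    as.numeric(t0_dp(s, fix$dp)) * vx2 / s$s2_x2, tolerance = 1e-12)
  # member 1D(8): lambda2 free, k fixed at (1,0,0)
  m8 <- make_class_estimator("1D(8)")
  expect_identical(m8$free, "lambda2")
  expect_identical(m8$constants$k1, 1)
  # member 1D(1): k1, k2 free, exponential-only adjustment
  m1 <- make_class_estimator("1D(1)")
  expect_setequal(m1$free, c("k1", "k2"))
  expect_identical(m1$constants$lambda1, 1)
  expect_identical(m1$constants$lambda2, 0)
  expect_error(make_class_estimator("1D(9)"), "unknown")

  # gratio reductions: omega = 0 and exponent = 0 drop the bracket
  g0 <- t_gratio_dp(s, fix$dp, vx1, gratio_constants(1, 0, 0, 1))
  e0 <- t_gratio_dp(s, fix$dp, vx1, gratio_constants(1, 0, 0.6, 0))
  plain <- as.numeric(t0_dp(s, fix$dp)) + (vx1 - s$s2_x1)
  expect_equal(as.numeric(g0), plain, tolerance = 1e-12)
  expect_equal(as.numeric(e0), plain, tolerance = 1e-12)

  # t1N reduces to tNP1
  expect_identical(
    as.numeric(t1n(s, fix$np0, vx1, vx2, t1n_constants(1, 0, 0, 0, 0))),
    as.numeric(t_np1(s, fix$np0)))
})

test_that("optimum constants minimize the closed-form MSE", {
  n <- 300
  kopt <- optimum_constants_t1d(fix$mom_dp, fix$dp, 1, 1, n)
  mse_opt <- t1d_theory(fix$mom_dp, fix$dp, kopt, n)$mse
  # 200 random perturbations never do better
  perturb <- withr::with_seed(81, matrix(rnorm(600, 0, 0.05), 200, 3))
  for (i in 1:200) {
    kk <- t1d_constants(kopt$k1 + perturb[i, 1], kopt$k2 + perturb[i, 2],
                        kopt$k3 + perturb[i, 3], 1, 1)
    expect_gte(t1d_theory(fix$mom_dp, fix$dp, kk, n)$mse, mse_opt - 1e-12)
  }
  # numerical minimizer cannot improve beyond relative 1e-6
  obj <- function(k) t1d_theory(fix$mom_dp, fix$dp,
                                t1d_constants(k[1], k[2], k[3], 1, 1),
                                n)$mse
  o <- optim(c(kopt$k1, kopt$k2, kopt$k3), obj, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 1000))
  expect_gte(o$value, mse_opt * (1 - 1e-6))

  # mixture-model counterpart
  wopt <- optimum_constants_t1n(fix$mom_np0, fix$np0, 1, 1, n)
  mse_optn <- t1n_theory(fix$mom_np0, fix$np0, wopt, n)$mse
  objn <- function(w) t1n_theory(fix$mom_np0, fix$np0,
                                 t1n_constants(w[1], w[2], w[3], 1, 1),
                                 n)$mse
  on <- optim(c(wopt$w1, wopt$w2, wopt$w3), objn, method = "BFGS",
              control = list(reltol = 1e-14, maxit = 1000))
  expect_gte(on$value, mse_optn * (1 - 1e-6))
})

test_that("theta -> 0 limit: k1 -> 1 and the minimum MSE vanishes", {
  kopt <- optimum_constants_t1d(fix$mom_dp, fix$dp, 1, 1, n = 10000000L)
  expect_lt(abs(kopt$k1 - 1), 1e-3)
  expect_lt(t1d_theory(fix$mom_dp, fix$dp, kopt, 10000000L)$min_mse, 1e-4)
})

test_that("estimator registry evaluates all tags consistently", {
  z <- scramble(fix$pop$y, fix$dp, seed = 91)
  idx <- draw_srswor(fix$pop$size, 150, seed = 92)
  s <- summarize_sample(z[idx], fix$pop$x1[idx], fix$pop$x2[idx])
  vx1 <- var(fix$pop$x1); vx2 <- var(fix$pop$x2)
  reg <- estimator_registry(c("t0", "ratio", "gratio", "t1D", "t1D(3)"),
                            fix$dp, vx1, vx2)
  vals <- vapply(reg, function(f) as.numeric(f(s)), numeric(1))
  expect_equal(unname(vals["t0"]), as.numeric(t0_dp(s, fix$dp)))
  expect_equal(unname(vals["t1D"]), unname(vals["t0"]))  # default constants
  expect_equal(unname(vals["t1D(3)"]),
               unname(vals["t0"]) * vx2 / s$s2_x2)
  expect_error(estimator_registry("nope", fix$dp, vx1, vx2), "unknown")
})
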