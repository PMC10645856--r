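# First-order (delta-method) bias and MSE theory.
#
# All statistics are functions of (s_z^2, s_x1^2, s_x2^2, zbar). Writing
# their relative errors as delta_z, delta_x1, delta_x2, e_z, the sampling
# moments are, to first order with theta = 1/n (no finite-population
# correction, by convention):
#   E(delta_z^2)   = theta (mu_400 - 1)       E(e_z^2)         = theta C_z^2
#   E(delta_x1^2)  = theta (mu_040 - 1)       E(delta_z e_z)   = theta mu_300 C_z
#   E(delta_x2^2)  = theta (mu_004 - 1)       E(delta_x1 e_z)  = theta mu_120 C_z
#   E(delta_z delta_x1) = theta (mu_220 - 1)  E(delta_x2 e_z)  = theta mu_102 C_z
#   E(delta_z delta_x2) = theta (mu_202 - 1)
#   E(delta_x1 delta_x2) = theta (mu_022 - 1)
# with all mu moments taken over (Z, X1, X2).
#
# The closed forms below are derived from this table and validated against
# the generic numerical delta-method oracle (delta_method_mse /
# delta_method_bias); printed-source variants that disagree with the
# expansion are retained behind `strict_paper` flags.

# shared ingredients of every closed form
.theory_core <- function(moments, params, n) {
  stopifnot(inherits(moments, "population_moments"))
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be at least 2", call. = FALSE)
  d <- decoder_constants(params)
  mu <- function(key) moments$mu[[key]]
  theta <- 1 / n
  sz2 <- moments$var_z
  zbar <- moments$mean_z
  cz <- moments$cv_z
  tp <- (sz2 - d$sub - d$mult * zbar^2) / d$den - d$extra
  # first-order variance of the decoded base estimator
  V0 <- theta * (sz2^2 * (mu("400") - 1) +
                   4 * d$mult^2 * zbar^4 * cz^2 -
                   4 * sz2 * d$mult * zbar^2 * mu("300") * cz) / d$den^2
  # covariance rates between the base estimator and the auxiliary variances
  P1 <- sz2 * (mu("220") - 1) - 2 * d$mult * zbar^2 * mu("120") * cz
  P2 <- sz2 * (mu("202") - 1) - 2 * d$mult * zbar^2 * mu("102") * cz
  list(
    d = d, theta = theta, sz2 = sz2, zbar = zbar, cz = cz, tp = tp,
    V0 = V0, P1 = P1, P2 = P2,
    sy2 = moments$var_y, sx1 = moments$var_x1, sx2 = moments$var_x2,
    m400 = mu("400") - 1, m040 = mu("040") - 1, m004 = mu("004") - 1,
    m220 = mu("220") - 1, m202 = mu("202") - 1, m022 = mu("022") - 1,
    mu300 = mu("300"), mu120 = mu("120"), mu102 = mu("102")
  )
}

#' First-order MSE of the basic decoding estimator
#'
#' Oracle-consistent form (default):
#' \deqn{MSE(t_0) = (t_p-\sigma_y^2)^2 + \frac{\theta}{den^2}\left[
#'   \sigma_z^4(\mu_{400}-1) + 4\,mult^2\bar Z^4 C_z^2 -
#'   4\sigma_z^2\,mult\,\bar Z^2\mu_{300}C_z\right]}
#' with \eqn{den = \sigma_T^2+1}, \eqn{mult = \sigma_T^2} for the
#' Diana-Perri model. `strict_paper = TRUE` evaluates the literal printed
#' expression, whose middle term reads \eqn{4\,mult\,\bar Z^2 C_z^2}.
#'
#' @param moments a `population_moments` (first axis Z).
#' @param params scrambling-model parameters.
#' @param n sample size.
#' @param strict_paper evaluate the literal printed transliteration?
#' @return The first-order MSE (a scalar).
#' @export
mse_t0_theory <- function(moments, params, n, strict_paper = FALSE) {
  co <- .theory_core(moments, params, n)
  if (strict_paper) {
    return(co$theta * (co$sz2^2 * co$m400 +
                         4 * co$d$mult * co$zbar^2 * co$cz^2 -
                         4 * co$sz2 * co$d$mult * co$zbar^2 * co$mu300 *
                           co$cz) / co$d$den^2)
  }
  (co$tp - co$sy2)^2 + co$V0
}

#' First-order bias of the basic decoding estimator
#'
#' \eqn{(t_p - \sigma_y^2) - \theta\, mult\, \sigma_z^2 / den}; for the
#' mixture model this is the printed
#' \eqn{-\theta(1-g)^2\sigma_R^2\bar Z^2 C_z^2/G}.
#'
#' @inheritParams mse_t0_theory
#' @return The first-order bias (a scalar).
#' @export
bias_t0_theory <- function(moments, params, n) {
  co <- .theory_core(moments, params, n)
  (co$tp - co$sy2) - co$theta * co$d$mult * co$sz2 / co$d$den
}

#' First-order MSE of the ratio estimator
#'
#' Oracle-consistent form (default):
#' \eqn{MSE(t_{ratio}) = MSE(t_0) + \theta[t_p^2(\mu_{040}-1) -
#' 2 t_p P_1/den]} with
#' \eqn{P_1 = \sigma_z^2(\mu_{220}-1) - 2\,mult\,\bar Z^2\mu_{120}C_z}.
#' `strict_paper = TRUE` gives the literal printed expression (which has
#' \eqn{\sigma_S^2} where \eqn{\sigma_y^4} is required and drops a
#' \eqn{\sigma_y^2} factor on the covariance terms).
#'
#' @inheritParams mse_t0_theory
#' @return The first-order MSE (a scalar).
#' @export
mse_tratio_theory <- function(moments, params, n, strict_paper = FALSE) {
  co <- .theory_core(moments, params, n)
  if (strict_paper) {
    den <- co$d$den
    s_s2 <- if (inherits(params, "dp_params")) params$var_s else co$d$sub
    return(co$theta / den^2 *
             (co$sz2^2 * co$m400 - 2 * co$sz2 * co$sx1 * co$m220 * den +
                s_s2 * co$m040 * den^2) +
           co$theta / den^2 * 4 * co$cz *
             (co$d$mult * co$zbar^4 * co$cz -
                co$sz2 * co$d$mult * co$zbar^2 * co$mu300 +
                co$d$mult * co$zbar^2 * co$mu120 * den))
  }
  (co$tp - co$sy2)^2 + co$V0 +
    co$theta * (co$tp^2 * co$m040 - 2 * co$tp * co$P1 / co$d$den)
}

#' First-order bias of the ratio estimator
#'
#' @inheritParams mse_t0_theory
#' @return The first-order bias (a scalar).
#' @export
bias_tratio_theory <- function(moments, params, n) {
  co <- .theory_core(moments, params, n)
  (co$tp - co$sy2) +
    co$theta * (-co$d$mult * co$sz2 / co$d$den + co$tp * co$m040 -
                  co$P1 / co$d$den)
}

#' Minimum first-order MSE of the generalized ratio estimator
#'
#' Minimized over the adjustment weight:
#' \eqn{\min MSE(t_{gratio}) = MSE(t_0) - \theta P_1^2 /
#' \{den^2(\mu_{040}-1)\}}. The literal printed form
#' (`strict_paper = TRUE`) omits the \eqn{den^2} divisor on the
#' improvement term.
#'
#' @inheritParams mse_t0_theory
#' @return The minimum first-order MSE (a scalar).
#' @export
min_mse_tgratio_theory <- function(moments, params, n,
                                   strict_paper = FALSE) {
  co <- .theory_core(moments, params, n)
  if (co$m040 <= 0) stop("degenerate auxiliary: mu_040 must exceed 1",
                         call. = FALSE)
  if (strict_paper) {
    return(mse_t0_theory(moments, params, n, strict_paper = TRUE) -
             co$theta * co$P1^2 / co$m040)
  }
  (co$tp - co$sy2)^2 + co$V0 -
    co$theta * co$P1^2 / (co$d$den^2 * co$m040)
}

#' Optimum adjustment weight of the generalized ratio estimator
#'
#' Solves for the weight `omega` at which the first-order MSE of the
#' generalized ratio estimator attains [min_mse_tgratio_theory()], given
#' the remaining constants.
#'
#' @inheritParams mse_t0_theory
#' @param alpha,beta,exponent the non-optimized constants.
#' @return A `gratio_constants` object with the optimum `omega`.
#' @export
optimum_omega_gratio <- function(moments, params, n, alpha = 1, beta = 0,
                                 exponent = 1) {
  co <- .theory_core(moments, params, n)
  if (exponent == 0 || alpha == 0) {
    stop("exponent and alpha must be nonzero to solve for omega",
         call. = FALSE)
  }
  c_star <- co$P1 / (co$d$den * co$sx1 * co$m040)
  omega <- (c_star - 1) * (alpha * co$sx1 + beta) / (co$tp * exponent * alpha)
  gratio_constants(alpha, beta, omega, exponent)
}

# ---- generalized exponential estimator: shared closed forms --------------

# bias / mse / min-mse of the two-auxiliary generalized estimator; the
# constants are (c1, c2, c3) on the head and (l1, l2) on the adjustment.
.generalized_theory <- function(moments, params, c1, c2, c3, l1, l2, n) {
  co <- .theory_core(moments, params, n)
  th <- co$theta
  g1 <- c2 + c1 * co$tp * l1 / (2 * co$sx1)
  g2 <- c3 + c1 * co$tp * l2 / co$sx2
  mse <- (c1 * co$tp - co$sy2)^2 + c1^2 * co$V0 +
    th * (g1^2 * co$sx1^2 * co$m040 + g2^2 * co$sx2^2 * co$m004 +
            2 * g1 * g2 * co$sx1 * co$sx2 * co$m022) -
    2 * c1 * th * (g1 * co$sx1 * co$P1 + g2 * co$sx2 * co$P2) / co$d$den

  # exact second-order bias: 0.5 * sum_ij H_ij C_ij at the population point
  den <- co$d$den; mult <- co$d$mult; zbar <- co$zbar; cz <- co$cz
  C_mm <- th * co$sz2
  C_qp1 <- th * co$sz2 * co$sx1 * co$m220
  C_qp2 <- th * co$sz2 * co$sx2 * co$m202
  C_mp1 <- th * co$sx1 * zbar * co$mu120 * cz
  C_mp2 <- th * co$sx2 * zbar * co$mu102 * cz
  C_p1p1 <- th * co$sx1^2 * co$m040
  C_p2p2 <- th * co$sx2^2 * co$m004
  C_p1p2 <- th * co$sx1 * co$sx2 * co$m022
  H_mm <- -2 * c1 * mult / den
  H_qp1 <- -c1 * l1 / (2 * den * co$sx1)
  H_qp2 <- -c1 * l2 / (den * co$sx2)
  H_mp1 <- c1 * mult * zbar * l1 / (den * co$sx1)
  H_mp2 <- 2 * c1 * mult * zbar * l2 / (den * co$sx2)
  H_p1p1 <- c2 * l1 / co$sx1 + c1 * co$tp * l1 * (2 + l1) / (4 * co$sx1^2)
  H_p2p2 <- 2 * c3 * l2 / co$sx2 + c1 * co$tp * l2 * (l2 + 1) / co$sx2^2
  H_p1p2 <- c2 * l2 / co$sx2 + c3 * l1 / (2 * co$sx1) +
    c1 * co$tp * l1 * l2 / (2 * co$sx1 * co$sx2)
  bias <- (c1 * co$tp - co$sy2) +
    0.5 * (H_mm * C_mm + H_p1p1 * C_p1p1 + H_p2p2 * C_p2p2) +
    H_qp1 * C_qp1 + H_qp2 * C_qp2 + H_mp1 * C_mp1 + H_mp2 * C_mp2 +
    H_p1p2 * C_p1p2

  # optimum constants and minimum MSE for these (l1, l2)
  det6 <- co$m040 * co$m004 - co$m022^2
  if (abs(det6) < 1e-12) {
    stop("collinear auxiliaries: the auxiliary moment matrix is singular",
         call. = FALSE)
  }
  Mi <- matrix(c(co$m004, -co$m022, -co$m022, co$m040), 2, 2) / det6
  Mi <- Mi / th
  Mi[1, 1] <- Mi[1, 1] / co$sx1^2
  Mi[1, 2] <- Mi[1, 2] / (co$sx1 * co$sx2)
  Mi[2, 1] <- Mi[2, 1] / (co$sx1 * co$sx2)
  Mi[2, 2] <- Mi[2, 2] / co$sx2^2
  cvec <- th * c(co$sx1 * co$P1, co$sx2 * co$P2) / co$d$den
  gstar_rate <- as.numeric(Mi %*% cvec)   # g* per unit c1
  Q <- sum(cvec * gstar_rate)
  A7 <- co$tp^2 + co$V0 - Q               # equals sigma_y^4 + theta*A1-type
  c1_opt <- co$tp * co$sy2 / A7
  min_mse <- co$sy2^2 * (co$V0 - Q) / A7
  g_opt <- c1_opt * gstar_rate
  c2_opt <- g_opt[1] - c1_opt * co$tp * l1 / (2 * co$sx1)
  c3_opt <- g_opt[2] - c1_opt * co$tp * l2 / co$sx2

  list(bias = bias, mse = mse, min_mse = min_mse,
       opt = c(c1_opt, c2_opt, c3_opt),
       terms = list(tp = co$tp, V0 = co$V0, P1 = co$P1, P2 = co$P2,
                    Q = Q, A6 = det6, A7 = A7, theta = th))
}

#' Bias, MSE and minimum MSE of the generalized exponential estimator
#' (Diana-Perri model)
#'
#' Returns the first-order bias and MSE at the supplied constants, and the
#' minimum MSE over \eqn{(k_1,k_2,k_3)} for the supplied
#' \eqn{(\lambda_1,\lambda_2)} (the minimum is invariant to the lambdas).
#' The intermediates (`A6`, `A7`, variance/covariance rates) are exposed in
#' `$terms`. `strict_paper = TRUE` reports the literal printed minimum-MSE
#' prefactor \eqn{\sigma_y^6(1 - 1/A_7)} instead of the dimensionally
#' consistent \eqn{\sigma_y^4(1 - \sigma_y^4/A_7)}.
#'
#' @inheritParams mse_t0_theory
#' @param constants a `t1d_constants` object.
#' @return List with `bias`, `mse`, `min_mse`, and `terms`.
#' @export
t1d_theory <- function(moments, params, constants, n, strict_paper = FALSE) {
  stopifnot(inherits(params, "dp_params"),
            inherits(constants, "t1d_constants"))
  out <- .generalized_theory(moments, params, constants$k1, constants$k2,
                             constants$k3, constants$lambda1,
                             constants$lambda2, n)
  if (strict_paper) {
    out$min_mse <- moments$var_y^3 * (1 - 1 / out$terms$A7)
  }
  out[c("bias", "mse", "min_mse", "terms")]
}

#' Closed-form optimum constants of the generalized estimator
#' (Diana-Perri model)
#'
#' Minimizes the first-order MSE over \eqn{(k_1, k_2, k_3)} for fixed
#' \eqn{(\lambda_1, \lambda_2)}; the optimum is closed-form (a 2x2 solve
#' for the auxiliary directions and a scalar shrinkage for \eqn{k_1}).
#'
#' @inheritParams mse_t0_theory
#' @param lambda1,lambda2 generalization constants held fixed.
#' @return A `t1d_constants` object with attribute `"terms"` holding the
#'   intermediates.
#' @export
optimum_constants_t1d <- function(moments, params, lambda1, lambda2, n) {
  stopifnot(inherits(params, "dp_params"))
  out <- .generalized_theory(moments, params, 1, 0, 0, lambda1, lambda2, n)
  k <- t1d_constants(out$opt[1], out$opt[2], out$opt[3], lambda1, lambda2)
  attr(k, "terms") <- out$terms
  k
}

#' Bias and MSE of the basic mixture-model estimator
#'
#' @inheritParams mse_t0_theory
#' @param strict_paper evaluate the literal printed MSE expression?
#' @return List with `bias` and `mse`.
#' @export
tnp1_theory <- function(moments, params, n, strict_paper = FALSE) {
  stopifnot(inherits(params, "np_params"))
  if (strict_paper) {
    co <- .theory_core(moments, params, n)
    mse <- co$theta / co$d$den^2 *
      (co$sz2^2 * co$m400 + 4 * co$d$mult^2 * co$zbar^2 * co$cz^2 -
         4 * co$d$mult * co$zbar^2 * co$mu300 * co$cz)
    return(list(bias = bias_t0_theory(moments, params, n), mse = mse))
  }
  list(bias = bias_t0_theory(moments, params, n),
       mse = mse_t0_theory(moments, params, n))
}

#' Bias and MSE of the mixture-model ratio estimator
#'
#' @inheritParams tnp1_theory
#' @return List with `bias` and `mse`.
#' @export
tnp2_theory <- function(moments, params, n) {
  stopifnot(inherits(params, "np_params"))
  list(bias = bias_tratio_theory(moments, params, n),
       mse = mse_tratio_theory(moments, params, n))
}

#' Bias, MSE and minimum MSE of the generalized exponential estimator
#' (mixture model)
#'
#' @inheritParams tnp1_theory
#' @param constants a `t1n_constants` object.
#' @param strict_paper report the literal printed minimum-MSE prefactor?
#' @return List with `bias`, `mse`, `min_mse`, and `terms`.
#' @export
t1n_theory <- function(moments, params, constants, n, strict_paper = FALSE) {
  stopifnot(inherits(params, "np_params"),
            inherits(constants, "t1n_constants"))
  out <- .generalized_theory(moments, params, constants$w1, constants$w2,
                             constants$w3, constants$v1, constants$v2, n)
  if (strict_paper) {
    out$min_mse <- 1 - moments$var_y^3 / out$terms$A7
  }
  out[c("bias", "mse", "min_mse", "terms")]
}

#' Closed-form optimum constants of the generalized estimator
#' (mixture model)
#'
#' @inheritParams tnp1_theory
#' @param v1,v2 generalization constants held fixed.
#' @return A `t1n_constants` object with attribute `"terms"`.
#' @export
optimum_constants_t1n <- function(moments, params, v1, v2, n) {
  stopifnot(inherits(params, "np_params"))
  out <- .generalized_theory(moments, params, 1, 0, 0, v1, v2, n)
  w <- t1n_constants(out$opt[1], out$opt[2], out$opt[3], v1, v2)
  attr(w, "terms") <- out$terms
  w
}

# ---- generic numerical oracle -------------------------------------------

#' Sampling covariance of the four moment statistics
#'
#' Assembles the 4x4 first-order covariance matrix of
#' \eqn{(s_z^2, s_{x1}^2, s_{x2}^2, \bar z)} from the nine sampling
#' expectation identities.
#'
#' @param moments a `population_moments`.
#' @param n sample size.
#' @return A 4x4 covariance matrix.
#' @export
moment_covariance <- function(moments, n) {
  mu <- function(key) moments$mu[[key]]
  theta <- 1 / n
  sz2 <- moments$var_z; s1 <- moments$var_x1; s2 <- moments$var_x2
  zbar <- moments$mean_z; cz <- moments$cv_z
  C <- matrix(0, 4, 4)
  C[1, 1] <- sz2^2 * (mu("400") - 1)
  C[2, 2] <- s1^2 * (mu("040") - 1)
  C[3, 3] <- s2^2 * (mu("004") - 1)
  C[4, 4] <- zbar^2 * cz^2                       # = sigma_z^2
  C[1, 2] <- C[2, 1] <- sz2 * s1 * (mu("220") - 1)
  C[1, 3] <- C[3, 1] <- sz2 * s2 * (mu("202") - 1)
  C[2, 3] <- C[3, 2] <- s1 * s2 * (mu("022") - 1)
  C[1, 4] <- C[4, 1] <- sz2 * zbar * mu("300") * cz
  C[2, 4] <- C[4, 2] <- s1 * zbar * mu("120") * cz
  C[3, 4] <- C[4, 3] <- s2 * zbar * mu("102") * cz
  theta * C
}

.population_point <- function(moments) {
  c(moments$var_z, moments$var_x1, moments$var_x2, moments$mean_z)
}

.num_gradient <- function(f, x, rel_h = 1e-6, abs_h = 1e-9) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- max(rel_h * abs(x[i]), abs_h)
    xp <- x; xm <- x
    xp[i] <- x[i] + h; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  if (any(!is.finite(g))) {
    stop("non-finite numerical gradient", call. = FALSE)
  }
  g
}

.num_hessian <- function(f, x, rel_h = 1e-4, abs_h = 1e-6) {
  k <- length(x)
  H <- matrix(0, k, k)
  h <- pmax(rel_h * abs(x), abs_h)
  f0 <- f(x)
  for (i in seq_len(k)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
    H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
    for (j in seq_len(k)) {
      if (j <= i) next
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
      xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
      xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  if (any(!is.finite(H))) {
    stop("non-finite numerical Hessian", call. = FALSE)
  }
  H
}

#' Generic delta-method MSE oracle
#'
#' First-order MSE of an arbitrary estimator of \eqn{\sigma_y^2}:
#' \eqn{(t(\mu^*) - \sigma_y^2)^2 + \nabla t^\top C \nabla t}, with
#' \eqn{\mu^*} the population point
#' \eqn{(\sigma_z^2,\sigma_{x1}^2,\sigma_{x2}^2,\bar Z)}, the gradient
#' computed by central differences, and `C` from [moment_covariance()].
#' This is the independent arbiter used to validate every closed form.
#'
#' @param estimator function of `(s2_z, s2_x1, s2_x2, zbar)` returning an
#'   estimate.
#' @param moments a `population_moments`.
#' @param n sample size.
#' @return The first-order MSE (a scalar).
#' @export
delta_method_mse <- function(estimator, moments, n) {
  x0 <- .population_point(moments)
  f <- function(x) estimator(x[1], x[2], x[3], x[4])
  g <- .num_gradient(f, x0)
  C <- moment_covariance(moments, n)
  (f(x0) - moments$var_y)^2 + as.numeric(t(g) %*% C %*% g)
}

#' Generic second-order delta-method bias oracle
#'
#' \eqn{t(\mu^*) - \sigma_y^2 + \frac12\mathrm{tr}(H C)} with a numerical
#' Hessian `H`.
#'
#' @inheritParams delta_method_mse
#' @return The second-order bias approximation (a scalar).
#' @export
delta_method_bias <- function(estimator, moments, n) {
  x0 <- .population_point(moments)
  f <- function(x) estimator(x[1], x[2], x[3], x[4])
  H <- .num_hessian(f, x0)
  C <- moment_covariance(moments, n)
  (f(x0) - moments$var_y) + 0.5 * sum(H * C)
}

#' Wrap a tagged estimator as a function of the four moment statistics
#'
#' Convenience for feeding package estimators to the delta-method oracle.
#'
#' @param tag estimator tag understood by [estimator_registry()].
#' @param params scrambling-model parameters.
#' @param var_x1_pop,var_x2_pop known auxiliary population variances.
#' @param constants passed to [estimator_registry()].
#' @param n nominal sample size recorded in the synthetic summary.
#' @return Function of `(s2_z, s2_x1, s2_x2, zbar)`.
#' @export
as_moment_function <- function(tag, params, var_x1_pop, var_x2_pop,
                               constants = list(), n = 100L) {
  fn <- estimator_registry(tag, params, var_x1_pop, var_x2_pop,
                           constants)[[1]]
  function(s2_z, s2_x1, s2_x2, zbar) {
    as.numeric(fn(sample_summary(n, s2_z, s2_x1, s2_x2, zbar)))
  }
}

#' Theoretical efficiency comparison of estimators
#'
#' Evaluates the first-order MSE of each tagged estimator (optimizing any
#' free constants numerically where the tag names a restricted class
#' member) and compares against the basic decoding estimator. The
#' comparison conditions are decided by direct evaluation of the MSE
#' differences.
#'
#' @inheritParams mse_t0_theory
#' @param estimator_tags character vector of tags; `t0`/`tNP1`, `ratio`/
#'   `tNP2`, `gratio`, `t1D`/`t1N`, `t1D(1)`...`t1D(8)`.
#' @return data.frame with columns `tag`, `mse`, `mse_minus_t0`,
#'   `better_than_t0`.
#' @export
efficiency_compare <- function(moments, params, n, estimator_tags) {
  mse_base <- mse_t0_theory(moments, params, n)
  one <- function(tag) {
    if (tag %in% c("t0", "tNP1")) {
      mse_base
    } else if (tag %in% c("ratio", "tNP2")) {
      mse_tratio_theory(moments, params, n)
    } else if (tag == "gratio") {
      min_mse_tgratio_theory(moments, params, n)
    } else if (tag %in% c("t1D", "t1N")) {
      .generalized_theory(moments, params, 1, 0, 0, 1, 1, n)$min_mse
    } else if (grepl("^t1D\\([1-8]\\)$", tag)) {
      spec <- make_class_estimator(sub("^t", "", tag))
      cst <- spec$constants
      if (length(spec$free) == 0L) {
        .generalized_theory(moments, params, cst$k1, cst$k2, cst$k3,
                            cst$lambda1, cst$lambda2, n)$mse
      } else {
        obj <- function(v) {
          vals <- as.list(cst)
          vals[spec$free] <- as.list(v)
          .generalized_theory(moments, params, vals$k1, vals$k2, vals$k3,
                              vals$lambda1, vals$lambda2, n)$mse
        }
        start <- unlist(cst[spec$free])
        stats::optim(start, obj, method = "BFGS",
                     control = list(reltol = 1e-12, maxit = 500))$value
      }
    } else {
      stop("unknown estimator tag: ", tag, call. = FALSE)
    }
  }
  mse <- vapply(estimator_tags, one, numeric(1))
  data.frame(
    tag = estimator_tags,
    mse = unname(mse),
    mse_minus_t0 = unname(mse - mse_base),
    better_than_t0 = unname(mse < mse_base),
    row.names = NULL
  )
}
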