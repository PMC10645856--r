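# Central and standardized population moments of (Z, X1, X2).
#
# eta_rsa = (1/(N-1)) sum (Z_i - Zbar)^r (X1_i - X1bar)^s (X2_i - X2bar)^a
# mu_rsa  = eta_rsa / (eta_200^{r/2} eta_020^{s/2} eta_002^{a/2})
#
# The first axis is the scrambled response Z by default: every sampling
# expectation the MSE theory consumes -- E(delta_z^2) = theta (mu_400 - 1)
# and its relatives -- is a statement about Z, not Y.

# moment triples every theory formula can ask for
.moment_triples <- rbind(
  c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
  c(4, 0, 0), c(0, 4, 0), c(0, 0, 4),
  c(2, 2, 0), c(2, 0, 2), c(0, 2, 2),
  c(3, 0, 0), c(1, 2, 0), c(1, 0, 2)
)

.triple_key <- function(r, s, a) paste0(r, s, a)

#' Central cross-moment with divisor N - 1
#'
#' \eqn{\eta_{rsa} = \frac{1}{N-1}\sum_i (Y_i-\bar Y)^r (X_{1i}-\bar X_1)^s
#' (X_{2i}-\bar X_2)^a}. The first axis carries whichever variable is passed
#' as `values_y` (the scrambled response Z in all theory uses).
#'
#' @param values_y,values_x1,values_x2 equal-length numeric vectors,
#'   length >= 2.
#' @param r,s,a non-negative integer exponents.
#' @return The central cross-moment (a scalar).
#' @export
eta_moment <- function(values_y, values_x1, values_x2, r, s, a) {
  n <- length(values_y)
  if (length(values_x1) != n || length(values_x2) != n) {
    stop("input vectors must have identical length", call. = FALSE)
  }
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (min(r, s, a) < 0) stop("exponents must be non-negative", call. = FALSE)
  dy <- values_y - mean(values_y)
  d1 <- values_x1 - mean(values_x1)
  d2 <- values_x2 - mean(values_x2)
  sum(dy^r * d1^s * d2^a) / (n - 1)
}

#' Standardized moment mu_rsa from a moments object
#'
#' \eqn{\mu_{rsa} = \eta_{rsa} / (\eta_{200}^{r/2}\eta_{020}^{s/2}
#' \eta_{002}^{a/2})}, so that \eqn{\mu_{200} = \mu_{020} = \mu_{002} = 1}.
#'
#' @param moments a `population_moments` object
#'   (see [compute_population_moments()]).
#' @param r,s,a non-negative integer exponents; the triple must be one of
#'   the precomputed set.
#' @return The standardized moment (a scalar).
#' @export
mu_moment <- function(moments, r, s, a) {
  stopifnot(inherits(moments, "population_moments"))
  key <- .triple_key(r, s, a)
  out <- moments$mu[[key]]
  if (is.null(out)) {
    stop(sprintf("moment triple (%d,%d,%d) was not precomputed", r, s, a),
         call. = FALSE)
  }
  out
}

.eta_lookup <- function(moments, r, s, a) {
  moments$eta[[.triple_key(r, s, a)]]
}

#' Compute all population moments the MSE theory consumes
#'
#' Fills every central (`eta`) and standardized (`mu`) moment needed by the
#' closed-form bias/MSE expressions, together with the means, variances and
#' the coefficient of variation of the scrambled response. Moment triples
#' are over `(Z, X1, X2)` when `first_axis = "Z"` (default; this is the
#' reading forced by the sampling expectation
#' \eqn{E(\delta_z^2)=\theta(\mu_{400}-1)}), or over `(Y, X1, X2)` when
#' `first_axis = "Y"`.
#'
#' @param pop a `finite_population`.
#' @param z_values numeric vector of scrambled responses for the whole
#'   population (length N). May be a stacked ensemble: if
#'   `length(z_values)` is `K * N`, the population columns are recycled `K`
#'   times, which averages the scrambling-noise contribution over `K`
#'   independent scrambles (see [expected_population_moments()]).
#' @param first_axis `"Z"` or `"Y"`.
#' @return Object of class `population_moments` with fields `mean_z`,
#'   `var_z`, `cv_z`, `mean_y`, `var_y`, `var_x1`, `var_x2`, and the moment
#'   tables `eta`, `mu` keyed by `"rsa"` strings.
#' @export
compute_population_moments <- function(pop, z_values,
                                       first_axis = c("Z", "Y")) {
  stopifnot(inherits(pop, "finite_population"))
  first_axis <- match.arg(first_axis)
  N <- pop$size
  k <- length(z_values) / N
  if (k != floor(k) || k < 1) {
    stop("length(z_values) must be a positive multiple of the population size",
         call. = FALSE)
  }
  x1 <- rep(pop$x1, times = k)
  x2 <- rep(pop$x2, times = k)
  first <- if (first_axis == "Z") z_values else rep(pop$y, times = k)

  # fast path: centered columns and their powers computed once (agrees with
  # eta_moment(); the equality is asserted in the test suite)
  M <- length(first)
  dy <- first - mean(first)
  d1 <- x1 - mean(x1)
  d2 <- x2 - mean(x2)
  dy2 <- dy * dy; d12 <- d1 * d1; d22 <- d2 * d2
  eta <- list(
    "200" = sum(dy2), "020" = sum(d12), "002" = sum(d22),
    "400" = sum(dy2 * dy2), "040" = sum(d12 * d12),
    "004" = sum(d22 * d22),
    "220" = sum(dy2 * d12), "202" = sum(dy2 * d22),
    "022" = sum(d12 * d22),
    "300" = sum(dy2 * dy), "120" = sum(dy * d12), "102" = sum(dy * d22)
  )
  eta <- lapply(eta, function(s) s / (M - 1))
  e200 <- eta[["200"]]; e020 <- eta[["020"]]; e002 <- eta[["002"]]
  if (min(e200, e020, e002) <= 0) {
    stop("degenerate population: a marginal variance is zero", call. = FALSE)
  }
  mu <- list()
  for (i in seq_len(nrow(.moment_triples))) {
    tr <- .moment_triples[i, ]
    key <- .triple_key(tr[1], tr[2], tr[3])
    mu[[key]] <- eta[[key]] /
      (e200^(tr[1] / 2) * e020^(tr[2] / 2) * e002^(tr[3] / 2))
  }
  mean_z <- mean(z_values)
  var_z <- stats::var(z_values)
  structure(
    list(
      mean_z = mean_z, var_z = var_z,
      cv_z = sqrt(var_z) / mean_z,
      mean_y = mean(pop$y), var_y = stats::var(pop$y),
      var_x1 = stats::var(pop$x1), var_x2 = stats::var(pop$x2),
      first_axis = first_axis, eta = eta, mu = mu
    ),
    class = "population_moments"
  )
}

#' Expected moments of the scrambled response via a stacked ensemble
#'
#' The theory formulas are stated in terms of moments of Z taken over both
#' the finite population and the scrambling distribution. A single scramble
#' of even a large population leaves several-percent noise in fourth
#' moments, so this helper stacks `k` independent scrambles of the whole
#' population (auxiliaries repeated) and computes the moments on the
#' ensemble.
#'
#' @param pop a `finite_population`.
#' @param params a `dp_params` or `np_params` scrambling model.
#' @param k number of independent scrambles to stack (default 100).
#' @param seed integer seed.
#' @param first_axis passed to [compute_population_moments()].
#' @return A `population_moments` object.
#' @export
expected_population_moments <- function(pop, params, k = 100, seed = 1L,
                                        first_axis = "Z") {
  stopifnot(inherits(pop, "finite_population"))
  seeds <- spawn_seeds(seed, k)
  z <- vector("list", k)
  for (i in seq_len(k)) {
    z[[i]] <- scramble(pop$y, params, seed = seeds[i])
  }
  compute_population_moments(pop, unlist(z), first_axis = first_axis)
}

#' @export
print.population_moments <- function(x, ...) {
  cat("Population moments (first axis:", x$first_axis, ")\n")
  cat(sprintf("  mean_z = %.4f  var_z = %.4f  cv_z = %.4f\n",
              x$mean_z, x$var_z, x$cv_z))
  cat(sprintf("  var_y = %.4f  var_x1 = %.4f  var_x2 = %.4f\n",
              x$var_y, x$var_x1, x$var_x2))
  cat(sprintf("  mu_400 = %.4f  mu_040 = %.4f  mu_004 = %.4f\n",
              x$mu[["400"]], x$mu[["040"]], x$mu[["004"]]))
  cat(sprintf("  mu_220 = %.4f  mu_202 = %.4f  mu_022 = %.4f\n",
              x$mu[["220"]], x$mu[["202"]], x$mu[["022"]]))
  invisible(x)
}
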