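# Scrambled-response models and privacy measures.
#
# Diana-Perri model:  Z = T*Y + S, with E(T) = 1, E(S) = 0, so that
# Var(Z) = sigma_y^2 (sigma_T^2 + 1) + sigma_T^2 mu_Y^2 + sigma_S^2 and the
# reported value can be decoded back to sigma_y^2.
#
# Proposed mixture model:  Z = g(Y + aS) + (1 - g) R (Y + aS): with
# probability weight g the respondent reports the additively scrambled value
# and with weight (1 - g) a multiplicatively re-scaled version of it.

#' Diana-Perri scrambling model parameters
#'
#' The respondent reports \eqn{Z = T Y + S} with multiplier \eqn{T}
#' (mean 1, variance `var_t`) and additive noise \eqn{S} (mean 0, variance
#' `var_s`). The literature writes the multiplier as either T or R; a single
#' slot serves both.
#'
#' @param var_t multiplier variance \eqn{\sigma_T^2 \ge 0}.
#' @param var_s additive-noise variance \eqn{\sigma_S^2 \ge 0}.
#' @param t_family,s_family distribution families (`"normal"` or
#'   `"uniform"`).
#' @param t_mean,s_mean distribution means. The decoding identity requires
#'   `t_mean = 1`, `s_mean = 0`; overriding is allowed but flagged.
#' @return Object of class `dp_params`.
#' @export
dp_params <- function(var_t, var_s, t_family = "normal", s_family = "normal",
                      t_mean = 1, s_mean = 0) {
  check_nonneg(var_t, var_s)
  if (t_mean != 1 || s_mean != 0) {
    warning("decoding identity assumes mean(T) = 1 and mean(S) = 0",
            call. = FALSE)
  }
  structure(
    list(
      var_t = var_t, var_s = var_s,
      t_dist = dist_spec(t_family, t_mean, sqrt(var_t)),
      s_dist = dist_spec(s_family, s_mean, sqrt(var_s))
    ),
    class = "dp_params"
  )
}

#' Mixture scrambling model parameters
#'
#' The respondent reports \eqn{Z = g(Y + aS) + (1-g) R (Y + aS)} with
#' mixing weight \eqn{g \in [0,1]}, additive scale \eqn{a \ge 0},
#' multiplier \eqn{R} (mean 1, variance `var_r`) and additive noise
#' \eqn{S} (mean 0, variance `var_s`).
#'
#' Two decoding conventions are provided. `mode = "paper"` uses the
#' decoding constant \eqn{G = g^2 + (1-g)^2(\sigma_R^2 + 1)}, which treats
#' the two mixture components as independent; for \eqn{g \in (0,1)} it
#' misses their covariance \eqn{2g(1-g)\sigma_W^2} and the census decoding
#' identity fails by that amount. `mode = "consistent"` uses
#' \eqn{G = 1 + (1-g)^2\sigma_R^2}, the exact variance factor of
#' \eqn{W\{g + (1-g)R\}}, which restores the identity. Both modes use the
#' same mean correction \eqn{(1-g)^2\sigma_R^2 \bar Z^2}.
#'
#' @param g mixing weight in \eqn{[0, 1]}.
#' @param a additive scrambling scale \eqn{\ge 0}.
#' @param var_r multiplier variance \eqn{\sigma_R^2 \ge 0}.
#' @param var_s additive-noise variance \eqn{\sigma_S^2 \ge 0}.
#' @param r_family,s_family distribution families.
#' @param mode decoding convention, `"paper"` (default) or `"consistent"`.
#' @return Object of class `np_params` with derived fields `G` (active
#'   decoding constant), `G_paper`, `G_consistent` and
#'   `mult = (1-g)^2 var_r`.
#' @export
np_params <- function(g, a, var_r, var_s, r_family = "normal",
                      s_family = "normal",
                      mode = c("paper", "consistent")) {
  mode <- match.arg(mode)
  check_nonneg(var_r, var_s, a)
  if (g < 0 || g > 1) stop("`g` must lie in [0, 1]", call. = FALSE)
  G_paper <- g^2 + (1 - g)^2 * (var_r + 1)
  G_consistent <- 1 + (1 - g)^2 * var_r
  structure(
    list(
      g = g, a = a, var_r = var_r, var_s = var_s,
      r_dist = dist_spec(r_family, 1, sqrt(var_r)),
      s_dist = dist_spec(s_family, 0, sqrt(var_s)),
      mode = mode,
      G_paper = G_paper, G_consistent = G_consistent,
      G = if (mode == "paper") G_paper else G_consistent,
      mult = (1 - g)^2 * var_r
    ),
    class = "np_params"
  )
}

#' Scramble true values under a model
#'
#' `scramble()` dispatches on the parameter class; `scramble_dp()` and
#' `scramble_proposed()` are the explicit forms. Scrambling noise is drawn
#' independently per unit and per call (each respondent scrambles at
#' response time).
#'
#' @param y numeric vector of true sensitive values.
#' @param params a `dp_params` or `np_params` object.
#' @param seed integer seed (deterministic per seed); `NULL` uses the
#'   current RNG stream.
#' @return Numeric vector of scrambled responses, same length as `y`.
#' @export
scramble <- function(y, params, seed = NULL) UseMethod("scramble", params)

#' @export
scramble.dp_params <- function(y, params, seed = NULL) {
  scramble_dp(y, params, seed)
}

#' @export
scramble.np_params <- function(y, params, seed = NULL) {
  scramble_proposed(y, params, seed)
}

#' @rdname scramble
#' @export
scramble_dp <- function(y, params, seed = NULL) {
  stopifnot(inherits(params, "dp_params"))
  draw <- function() {
    t_i <- draw_dist(params$t_dist, length(y))
    s_i <- draw_dist(params$s_dist, length(y))
    t_i * y + s_i
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' @rdname scramble
#' @export
scramble_proposed <- function(y, params, seed = NULL) {
  stopifnot(inherits(params, "np_params"))
  draw <- function() {
    r_i <- draw_dist(params$r_dist, length(y))
    s_i <- draw_dist(params$s_dist, length(y))
    w <- y + params$a * s_i
    params$g * w + (1 - params$g) * r_i * w
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

.privacy_result <- function(delta, model_tag, components) {
  structure(list(delta = delta, model_tag = model_tag,
                 components = components),
            class = "privacy_result")
}

#' @export
print.privacy_result <- function(x, ...) {
  cat(sprintf("Privacy level (%s model): Delta = %.4f\n",
              x$model_tag, x$delta))
  invisible(x)
}

#' Privacy-protection level of the Diana-Perri model
#'
#' The expected squared perturbation \eqn{\Delta_D = E(Z - Y)^2 =
#' \sigma_R^2(\mu_Y^2 + \sigma_y^2) + \sigma_S^2}, where larger values mean
#' more respondent protection.
#'
#' @param mean_y,var_y population mean and variance of the sensitive
#'   variable.
#' @param var_r multiplier variance.
#' @param var_s additive-noise variance.
#' @return Object of class `privacy_result` (field `delta` holds
#'   \eqn{\Delta_D}).
#' @export
privacy_dp <- function(mean_y, var_y, var_r, var_s) {
  check_nonneg(var_y, var_r, var_s)
  delta <- var_r * (mean_y^2 + var_y) + var_s
  .privacy_result(delta, "diana-perri",
                  list(mean_y = mean_y, var_y = var_y, var_r = var_r,
                       var_s = var_s))
}

#' Privacy-protection level of the mixture model
#'
#' \eqn{\Delta_{PN} = (\mu_Y^2 + \sigma_y^2 + a^2\sigma_S^2)
#' \{1 + (1-g)^2\sigma_R^2\} - (\mu_Y^2 + \sigma_y^2)}, equivalently
#' \eqn{(1-g)^2\sigma_R^2(\mu_Y^2+\sigma_y^2+a^2\sigma_S^2) +
#' a^2\sigma_S^2}.
#'
#' @inheritParams privacy_dp
#' @param a additive scrambling scale.
#' @param g mixing weight in \eqn{[0,1]}.
#' @return Object of class `privacy_result`.
#' @export
privacy_proposed <- function(mean_y, var_y, a, g, var_r, var_s) {
  check_nonneg(var_y, var_r, var_s, a)
  if (g < 0 || g > 1) stop("`g` must lie in [0, 1]", call. = FALSE)
  tot <- mean_y^2 + var_y
  delta <- (tot + a^2 * var_s) * (1 + (1 - g)^2 * var_r) - tot
  .privacy_result(delta, "mixture",
                  list(mean_y = mean_y, var_y = var_y, a = a, g = g,
                       var_r = var_r, var_s = var_s))
}

#' Empirical privacy level from simulated respondents
#'
#' The Monte-Carlo counterpart of the closed forms: the mean of
#' \eqn{(Z_i - Y_i)^2}.
#'
#' @param z,y equal-length vectors of reported and true values.
#' @return Mean squared perturbation (a scalar).
#' @export
privacy_mc <- function(z, y) {
  if (length(z) != length(y)) {
    stop("`z` and `y` must have the same length", call. = FALSE)
  }
  if (length(z) < 1L) stop("need at least one respondent", call. = FALSE)
  mean((z - y)^2)
}

#' Compare the privacy levels of the two models
#'
#' Returns \eqn{\Delta_{PN} - \Delta_D} computed from the two closed forms,
#' together with the algebraically expanded comparison expression
#' \eqn{(\mu_Y^2+\sigma_y^2)\sigma_R^2 g(g-2) - \sigma_S^2[1 -
#' a^2\{1+(1-g)^2\sigma_R^2\}]}, which equals the difference identically.
#'
#' @inheritParams privacy_proposed
#' @return List with `difference` (\eqn{\Delta_{PN} - \Delta_D}),
#'   `expanded` (the expansion, equal to machine tolerance), and
#'   `proposed_more_private` (`difference > 0`).
#' @export
privacy_gain_condition <- function(mean_y, var_y, a, g, var_r, var_s) {
  d_pn <- privacy_proposed(mean_y, var_y, a, g, var_r, var_s)$delta
  d_d <- privacy_dp(mean_y, var_y, var_r, var_s)$delta
  tot <- mean_y^2 + var_y
  expanded <- tot * var_r * g * (g - 2) -
    var_s * (1 - a^2 * (1 + (1 - g)^2 * var_r))
  list(
    difference = d_pn - d_d,
    expanded = expanded,
    proposed_more_private = (d_pn - d_d) > 0
  )
}
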