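# Point estimators of the finite-population variance sigma_y^2 from one
# scrambled SRSWOR sample.
#
# Every estimator is built around a linear "decoder" of the scrambled sample
# variance,
#     base = (s_z^2 - sub - mult * zbar^2) / den - extra,
# whose constants depend only on the scrambling model:
#   Diana-Perri:  den = sigma_T^2 + 1, mult = sigma_T^2, sub = sigma_S^2
#   mixture:      den = G,             mult = (1-g)^2 sigma_R^2,
#                 extra = a^2 sigma_S^2
# so the ratio / generalized / exponential machinery is shared across models.

decoder_constants <- function(params) UseMethod("decoder_constants")

#' @export
decoder_constants.dp_params <- function(params) {
  list(den = params$var_t + 1, mult = params$var_t,
       sub = params$var_s, extra = 0)
}

#' @export
decoder_constants.np_params <- function(params) {
  list(den = params$G, mult = params$mult,
       sub = 0, extra = params$a^2 * params$var_s)
}

.base_estimate <- function(sample, d) {
  (sample$s2_z - d$sub - d$mult * sample$zbar^2) / d$den - d$extra
}

.flag_negative <- function(value, truncate = FALSE) {
  if (truncate && value < 0) value <- 0
  attr(value, "negative") <- unname(value < 0)
  value
}

#' Basic decoding variance estimator (Diana-Perri model)
#'
#' \eqn{t_0 = (s_z^2 - \sigma_S^2 - \sigma_T^2\bar z^2)/(\sigma_T^2+1)}.
#' Negative values are returned as-is with attribute `negative = TRUE`
#' (set `truncate = TRUE` to floor at zero).
#'
#' @param sample a `sample_summary`.
#' @param params a `dp_params`.
#' @param truncate floor negative estimates at zero? Default `FALSE`.
#' @return Estimate of \eqn{\sigma_y^2}.
#' @export
t0_dp <- function(sample, params, truncate = FALSE) {
  stopifnot(inherits(params, "dp_params"))
  .flag_negative(.base_estimate(sample, decoder_constants(params)), truncate)
}

#' Ratio variance estimator (Diana-Perri model)
#'
#' The basic decoder multiplied by \eqn{\sigma_{x1}^2 / s_{x1}^2}; the known
#' population auxiliary variance is passed explicitly.
#'
#' @inheritParams t0_dp
#' @param var_x1_pop known population variance of \eqn{X_1}.
#' @return Estimate of \eqn{\sigma_y^2}.
#' @export
t_ratio_dp <- function(sample, params, var_x1_pop, truncate = FALSE) {
  stopifnot(inherits(params, "dp_params"))
  if (sample$s2_x1 <= 0) {
    stop("degenerate sample: s2_x1 must be positive", call. = FALSE)
  }
  v <- .base_estimate(sample, decoder_constants(params)) *
    var_x1_pop / sample$s2_x1
  .flag_negative(v, truncate)
}

#' Constants of the generalized ratio estimator
#'
#' @param alpha,beta scale/shift constants applied to the auxiliary
#'   variance.
#' @param omega mixing weight between sample and population auxiliary
#'   variance in the denominator.
#' @param exponent power on the adjustment bracket (the exponent the
#'   source literature calls g, renamed to avoid collision with the mixture
#'   model's mixing weight).
#' @return Object of class `gratio_constants`.
#' @export
gratio_constants <- function(alpha = 1, beta = 0, omega = 1, exponent = 1) {
  structure(list(alpha = alpha, beta = beta, omega = omega,
                 exponent = exponent),
            class = "gratio_constants")
}

#' Generalized ratio variance estimator (Diana-Perri model)
#'
#' \deqn{t_{gratio} = \{base + (\sigma_{x1}^2 - s_{x1}^2)\}\left[
#'   \frac{\alpha\sigma_{x1}^2+\beta}{\omega(\alpha s_{x1}^2+\beta) +
#'   (1-\omega)(\alpha\sigma_{x1}^2+\beta)}\right]^{exponent}.}
#'
#' @inheritParams t_ratio_dp
#' @param constants a `gratio_constants` object.
#' @return Estimate of \eqn{\sigma_y^2}.
#' @export
t_gratio_dp <- function(sample, params, var_x1_pop, constants,
                        truncate = FALSE) {
  stopifnot(inherits(params, "dp_params"),
            inherits(constants, "gratio_constants"))
  num <- constants$alpha * var_x1_pop + constants$beta
  den <- constants$omega * (constants$alpha * sample$s2_x1 + constants$beta) +
    (1 - constants$omega) * num
  if (den == 0) stop("degenerate sample: zero adjustment denominator",
                     call. = FALSE)
  base <- .base_estimate(sample, decoder_constants(params))
  v <- (base + (var_x1_pop - sample$s2_x1)) * (num / den)^constants$exponent
  .flag_negative(v, truncate)
}

#' Constants of the generalized exponential estimator (Diana-Perri model)
#'
#' `k1`, `k2`, `k3` are the optimizing constants; `lambda1`, `lambda2` the
#' generalization constants fixed before optimization.
#'
#' @param k1,k2,k3 optimizing constants.
#' @param lambda1,lambda2 generalization constants.
#' @return Object of class `t1d_constants`.
#' @export
t1d_constants <- function(k1 = 1, k2 = 0, k3 = 0, lambda1 = 0, lambda2 = 0) {
  stopifnot(is.finite(c(k1, k2, k3, lambda1, lambda2)))
  structure(list(k1 = k1, k2 = k2, k3 = k3,
                 lambda1 = lambda1, lambda2 = lambda2),
            class = "t1d_constants")
}

#' Constants of the generalized exponential estimator (mixture model)
#'
#' @param w1,w2,w3 optimizing constants.
#' @param v1,v2 generalization constants.
#' @return Object of class `t1n_constants`.
#' @export
t1n_constants <- function(w1 = 1, w2 = 0, w3 = 0, v1 = 0, v2 = 0) {
  stopifnot(is.finite(c(w1, w2, w3, v1, v2)))
  structure(list(w1 = w1, w2 = w2, w3 = w3, v1 = v1, v2 = v2),
            class = "t1n_constants")
}

# shared core of the two-auxiliary generalized exponential estimator
.generalized_estimate <- function(sample, d, var_x1_pop, var_x2_pop,
                                  c1, c2, c3, l1, l2) {
  if (sample$s2_x1 <= 0 || sample$s2_x2 <= 0) {
    stop("degenerate sample: auxiliary sample variances must be positive",
         call. = FALSE)
  }
  base <- .base_estimate(sample, d)
  head <- c1 * base + c2 * (var_x1_pop - sample$s2_x1) +
    c3 * (var_x2_pop - sample$s2_x2)
  adj <- exp((var_x1_pop - sample$s2_x1) /
               (var_x1_pop + sample$s2_x1))^l1 *
    (var_x2_pop / sample$s2_x2)^l2
  head * adj
}

#' Generalized exponential variance estimator, Diana-Perri model
#'
#' \deqn{t_{1D} = [k_1\,base + k_2(\sigma_{x1}^2-s_{x1}^2) +
#'   k_3(\sigma_{x2}^2-s_{x2}^2)]
#'   \exp\!\left(\frac{\sigma_{x1}^2-s_{x1}^2}{\sigma_{x1}^2+s_{x1}^2}
#'   \right)^{\lambda_1} (\sigma_{x2}^2/s_{x2}^2)^{\lambda_2}.}
#'
#' @inheritParams t_ratio_dp
#' @param var_x2_pop known population variance of \eqn{X_2}.
#' @param constants a `t1d_constants` object.
#' @return Estimate of \eqn{\sigma_y^2}.
#' @export
t1d <- function(sample, params, var_x1_pop, var_x2_pop, constants,
                truncate = FALSE) {
  stopifnot(inherits(params, "dp_params"),
            inherits(constants, "t1d_constants"))
  v <- .generalized_estimate(sample, decoder_constants(params),
                             var_x1_pop, var_x2_pop,
                             constants$k1, constants$k2, constants$k3,
                             constants$lambda1, constants$lambda2)
  .flag_negative(v, truncate)
}

#' Basic decoding variance estimator, mixture model
#'
#' \eqn{t_{NP1} = \{s_z^2 - (1-g)^2\sigma_R^2 \bar z^2\}/G -
#' a^2\sigma_S^2}, with `G` the active decoding constant of `params`.
#'
#' @param sample a `sample_summary`.
#' @param params an `np_params`.
#' @param truncate floor negative estimates at zero? Default `FALSE`.
#' @return Estimate of \eqn{\sigma_y^2}.
#' @export
t_np1 <- function(sample, params, truncate = FALSE) {
  stopifnot(inherits(params, "np_params"))
  .flag_negative(.base_estimate(sample, decoder_constants(params)), truncate)
}

#' Ratio variance estimator, mixture model
#'
#' @inheritParams t_np1
#' @param var_x1_pop known population variance of \eqn{X_1}.
#' @return Estimate of \eqn{\sigma_y^2}.
#' @export
t_np2 <- function(sample, params, var_x1_pop, truncate = FALSE) {
  stopifnot(inherits(params, "np_params"))
  if (sample$s2_x1 <= 0) {
    stop("degenerate sample: s2_x1 must be positive", call. = FALSE)
  }
  v <- .base_estimate(sample, decoder_constants(params)) *
    var_x1_pop / sample$s2_x1
  .flag_negative(v, truncate)
}

#' Generalized exponential variance estimator, mixture model
#'
#' Exactly parallel to [t1d()] with the mixture-model decoder inside and
#' constants \eqn{(w_1, w_2, w_3, v_1, v_2)}.
#'
#' @inheritParams t_np2
#' @param var_x2_pop known population variance of \eqn{X_2}.
#' @param constants a `t1n_constants` object.
#' @return Estimate of \eqn{\sigma_y^2}.
#' @export
t1n <- function(sample, params, var_x1_pop, var_x2_pop, constants,
                truncate = FALSE) {
  stopifnot(inherits(params, "np_params"),
            inherits(constants, "t1n_constants"))
  v <- .generalized_estimate(sample, decoder_constants(params),
                             var_x1_pop, var_x2_pop,
                             constants$w1, constants$w2, constants$w3,
                             constants$v1, constants$v2)
  .flag_negative(v, truncate)
}

#' Named sub-estimators of the generalized class
#'
#' Returns the constant configuration of the named class member: which of
#' \eqn{(k_1,k_2,k_3)} are fixed, which remain to be optimized, and the
#' fixed \eqn{(\lambda_1,\lambda_2)}. Tags are `"1D(1)"` ... `"1D(8)"`.
#'
#' @param tag class-member tag.
#' @return List with elements `constants` (a `t1d_constants` holding the
#'   fixed values, free slots at their reduction values) and `free`
#'   (character vector naming the constants left free for optimization).
#' @export
make_class_estimator <- function(tag) {
  table <- list(
    "1D(1)" = list(k1 = NA, k2 = NA, k3 = 0, lambda1 = 1, lambda2 = 0),
    "1D(2)" = list(k1 = NA, k2 = NA, k3 = 0, lambda1 = 0, lambda2 = 1),
    "1D(3)" = list(k1 = 1, k2 = 0, k3 = 0, lambda1 = 0, lambda2 = 1),
    "1D(4)" = list(k1 = 1, k2 = NA, k3 = NA, lambda1 = 0, lambda2 = 0),
    "1D(5)" = list(k1 = 1, k2 = NA, k3 = 0, lambda1 = 1, lambda2 = 0),
    "1D(6)" = list(k1 = 1, k2 = NA, k3 = 0, lambda1 = 0, lambda2 = 1),
    "1D(7)" = list(k1 = 1, k2 = 0, k3 = 0, lambda1 = NA, lambda2 = 0),
    "1D(8)" = list(k1 = 1, k2 = 0, k3 = 0, lambda1 = 0, lambda2 = NA)
  )
  cfg <- table[[tag]]
  if (is.null(cfg)) stop("unknown class tag: ", tag, call. = FALSE)
  free <- names(cfg)[vapply(cfg, is.na, logical(1))]
  vals <- lapply(cfg, function(v) if (is.na(v)) {
    # reduction value used when a free constant is left unoptimized
    0
  } else v)
  if ("k1" %in% free) vals$k1 <- 1
  if ("lambda1" %in% free) vals$lambda1 <- 1
  if ("lambda2" %in% free) vals$lambda2 <- 1
  list(
    tag = tag,
    constants = t1d_constants(vals$k1, vals$k2, vals$k3,
                              vals$lambda1, vals$lambda2),
    free = free
  )
}

#' Registry of estimator tags
#'
#' Maps the estimator names used by the simulation engine and CLI to
#' evaluation closures. `constants` supplies the constants objects needed by
#' the generalized members (`t1D`, `gratio`, `t1N`).
#'
#' @param tags character vector of estimator names; see Details.
#' @param params scrambling-model parameters (`dp_params` for the
#'   `t0`/`ratio`/`gratio`/`t1D` family, `np_params` for `tNP1`/`tNP2`/
#'   `t1N`).
#' @param var_x1_pop,var_x2_pop known population auxiliary variances.
#' @param constants named list; recognized entries `t1D` (a
#'   `t1d_constants`), `t1N` (a `t1n_constants`), `gratio` (a
#'   `gratio_constants`), and one `t1d_constants` per `t1D(j)` tag.
#' @return Named list of functions, each mapping a `sample_summary` to an
#'   estimate.
#' @details Recognized tags: `t0`, `ratio`, `gratio`, `t1D`,
#'   `t1D(1)`...`t1D(8)`, `tNP1`, `tNP2`, `t1N`.
#' @export
estimator_registry <- function(tags, params, var_x1_pop, var_x2_pop,
                               constants = list()) {
  make_one <- function(tag) {
    if (tag == "t0") {
      function(s) t0_dp(s, params)
    } else if (tag == "ratio") {
      function(s) t_ratio_dp(s, params, var_x1_pop)
    } else if (tag == "gratio") {
      cc <- constants[["gratio"]] %||% gratio_constants()
      function(s) t_gratio_dp(s, params, var_x1_pop, cc)
    } else if (tag == "t1D") {
      cc <- constants[["t1D"]] %||% t1d_constants()
      function(s) t1d(s, params, var_x1_pop, var_x2_pop, cc)
    } else if (grepl("^t1D\\([1-8]\\)$", tag)) {
      cc <- constants[[tag]] %||%
        make_class_estimator(sub("^t", "", tag))$constants
      function(s) t1d(s, params, var_x1_pop, var_x2_pop, cc)
    } else if (tag == "tNP1") {
      function(s) t_np1(s, params)
    } else if (tag == "tNP2") {
      function(s) t_np2(s, params, var_x1_pop)
    } else if (tag == "t1N") {
      cc <- constants[["t1N"]] %||% t1n_constants()
      function(s) t1n(s, params, var_x1_pop, var_x2_pop, cc)
    } else {
      stop("unknown estimator tag: ", tag, call. = FALSE)
    }
  }
  stats::setNames(lapply(tags, make_one), tags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
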