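# internal helpers

#' Spawn reproducible child seeds from one root seed
#'
#' A single root seed deterministically generates per-replication (or
#' per-component) seeds, so that any sub-computation can be re-run in
#' isolation. Seeds are kept below 2^31.
#'
#' @param root_seed integer root seed.
#' @param k number of child seeds.
#' @return Integer vector of length `k`.
#' @export
spawn_seeds <- function(root_seed, k) {
  withr::with_seed(as.integer(root_seed),
                   sample.int(.Machine$integer.max - 1L, k))
}

# distribution spec: list(family, mean, sd); families: normal, uniform
dist_spec <- function(family = "normal", mean = 0, sd = 1) {
  family <- match.arg(family, c("normal", "uniform"))
  if (sd < 0) stop("distribution sd must be non-negative", call. = FALSE)
  list(family = family, mean = mean, sd = sd)
}

draw_dist <- function(spec, n) {
  if (spec$sd == 0) return(rep(spec$mean, n))
  switch(spec$family,
    normal = stats::rnorm(n, spec$mean, spec$sd),
    uniform = {
      half <- spec$sd * sqrt(3)
      stats::runif(n, spec$mean - half, spec$mean + half)
    },
    stop("unknown distribution family: ", spec$family, call. = FALSE)
  )
}

check_nonneg <- function(...) {
  vals <- c(...)
  if (any(vals < 0)) {
    stop("variance parameters must be non-negative", call. = FALSE)
  }
  invisible(TRUE)
}
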