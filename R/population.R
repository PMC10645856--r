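#' Generate a synthetic finite population
#'
#' Draws `size` units from a trivariate normal distribution with the given
#' mean vector and covariance matrix. The three columns are the sensitive
#' study variable \eqn{Y} and the two non-sensitive auxiliary variables
#' \eqn{X_1} and \eqn{X_2}. The returned object is the fixed finite
#' population from which all SRSWOR samples are subsequently drawn; its
#' realized (divisor \eqn{N-1}) variance of \eqn{Y} is the estimand of every
#' estimator in the package.
#'
#' @param cov 3x3 symmetric positive-definite covariance matrix for
#'   \eqn{(Y, X_1, X_2)}.
#' @param means numeric length-3 mean vector.
#' @param size integer population size \eqn{N \ge 10}.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return An object of class `finite_population`: a list with numeric
#'   vectors `y`, `x1`, `x2` and the integer `size`.
#' @examples
#' pop <- generate_population(diag(3), c(0, 0, 0), 100, seed = 1)
#' var(pop$y)
#' @export
generate_population <- function(cov, means, size, seed) {
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(dim(cov), c(3L, 3L))) ||
      max(abs(cov - t(cov))) > 1e-8) {
    stop("`cov` must be a symmetric 3x3 matrix", call. = FALSE)
  }
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch)) {
    stop("`cov` must be positive definite", call. = FALSE)
  }
  if (length(means) != 3L) stop("`means` must have length 3", call. = FALSE)
  size <- as.integer(size)
  if (is.na(size) || size < 10L) {
    stop("`size` must be an integer >= 10", call. = FALSE)
  }
  m <- withr::with_seed(seed, matrix(stats::rnorm(3L * size), size, 3L)) %*% ch
  m <- sweep(m, 2L, as.numeric(means), `+`)
  finite_population(y = m[, 1L], x1 = m[, 2L], x2 = m[, 3L])
}

#' Construct a finite population from raw vectors
#'
#' @param y,x1,x2 equal-length numeric vectors (length \eqn{N \ge 4}) holding
#'   the sensitive variable and the two auxiliaries.
#' @return An object of class `finite_population`.
#' @export
finite_population <- function(y, x1, x2) {
  n <- length(y)
  if (length(x1) != n || length(x2) != n) {
    stop("y, x1, x2 must have identical length", call. = FALSE)
  }
  if (n < 4L) stop("population size must be at least 4", call. = FALSE)
  if (anyNA(y) || anyNA(x1) || anyNA(x2)) {
    stop("population values must be non-missing", call. = FALSE)
  }
  if (stats::var(y) <= 0 || stats::var(x1) <= 0 || stats::var(x2) <= 0) {
    stop("all three variables must have strictly positive variance",
         call. = FALSE)
  }
  structure(
    list(y = as.numeric(y), x1 = as.numeric(x1), x2 = as.numeric(x2),
         size = n),
    class = "finite_population"
  )
}

#' @export
print.finite_population <- function(x, ...) {
  cat("Finite population: N =", x$size, "\n")
  cat(sprintf("  mean(Y)  = %.4f  var(Y)  = %.4f\n",
              mean(x$y), stats::var(x$y)))
  cat(sprintf("  mean(X1) = %.4f  var(X1) = %.4f\n",
              mean(x$x1), stats::var(x$x1)))
  cat(sprintf("  mean(X2) = %.4f  var(X2) = %.4f\n",
              mean(x$x2), stats::var(x$x2)))
  invisible(x)
}

#' @export
as.data.frame.finite_population <- function(x, ...) {
  data.frame(Y = x$y, X1 = x$x1, X2 = x$x2)
}

#' Read / write a population as a delimited text table
#'
#' The on-disk format is a plain CSV with header `Y,X1,X2`, one row per unit.
#'
#' @param file path to a CSV file.
#' @return `read_population()` returns a `finite_population`;
#'   `write_population()` invisibly returns `file`.
#' @export
read_population <- function(file) {
  d <- utils::read.csv(file)
  need <- c("Y", "X1", "X2")
  if (!all(need %in% names(d))) {
    stop("population file must have columns Y, X1, X2", call. = FALSE)
  }
  finite_population(d$Y, d$X1, d$X2)
}

#' @param pop a `finite_population`.
#' @rdname read_population
#' @export
write_population <- function(pop, file) {
  stopifnot(inherits(pop, "finite_population"))
  utils::write.csv(as.data.frame(pop), file, row.names = FALSE)
  invisible(file)
}

#' Draw a simple random sample without replacement
#'
#' @param pop_size population size \eqn{N}.
#' @param n sample size, \eqn{2 \le n \le N}.
#' @param seed integer seed (deterministic per seed).
#' @return Integer vector of `n` distinct indices in `1:pop_size`.
#' @export
draw_srswor <- function(pop_size, n, seed) {
  pop_size <- as.integer(pop_size)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be at least 2", call. = FALSE)
  if (n > pop_size) stop("`n` cannot exceed the population size",
                         call. = FALSE)
  withr::with_seed(seed, sample.int(pop_size, n))
}

#' Summarize one scrambled SRSWOR sample
#'
#' Computes the sample variances (divisor \eqn{n-1}) of the scrambled
#' response and the two auxiliaries, the scrambled-response sample mean, and
#' \eqn{\theta = 1/n}.
#'
#' @param z,x1,x2 equal-length numeric vectors of sampled values
#'   (length \eqn{n \ge 2}); `z` holds scrambled responses.
#' @return Object of class `sample_summary` with fields `n`, `s2_z`,
#'   `s2_x1`, `s2_x2`, `zbar`, `theta`.
#' @export
summarize_sample <- function(z, x1, x2) {
  n <- length(z)
  if (length(x1) != n || length(x2) != n) {
    stop("z, x1, x2 must have identical length", call. = FALSE)
  }
  if (n < 2L) stop("sample size must be at least 2", call. = FALSE)
  sample_summary(
    n = n,
    s2_z = stats::var(z), s2_x1 = stats::var(x1), s2_x2 = stats::var(x2),
    zbar = mean(z)
  )
}

#' Assemble a sample summary from precomputed moments
#'
#' Useful for evaluating estimators at arbitrary (e.g. population-level)
#' moment inputs, as in the census-identity checks.
#'
#' @param n sample size.
#' @param s2_z,s2_x1,s2_x2 sample variances.
#' @param zbar sample mean of the scrambled response.
#' @return Object of class `sample_summary`.
#' @export
sample_summary <- function(n, s2_z, s2_x1, s2_x2, zbar) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be at least 2", call. = FALSE)
  if (min(s2_z, s2_x1, s2_x2) < 0) {
    stop("sample variances must be non-negative", call. = FALSE)
  }
  structure(
    list(n = n, s2_z = s2_z, s2_x1 = s2_x1, s2_x2 = s2_x2, zbar = zbar,
         theta = 1 / n),
    class = "sample_summary"
  )
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf(
    "Sample summary: n = %d, s2_z = %.4f, s2_x1 = %.4f, s2_x2 = %.4f, zbar = %.4f\n",
    x$n, x$s2_z, x$s2_x1, x$s2_x2, x$zbar))
  invisible(x)
}
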