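# Published reference values and example populations.

#' Published simulation-study reference tables
#'
#' Returns the published privacy levels, simulation tables and real-survey
#' MSE table shipped as plain-text fixtures. These are inputs for the
#' table-arithmetic consistency checks (recomputing PRE and the unified
#' measure from the printed MSE and privacy columns); the package does not
#' claim to reproduce the printed MSE values themselves, whose generating
#' configuration (population means, distributions, replication count) is
#' not public.
#'
#' @return Named list of data.frames: `privacy` (model, population,
#'   delta), `pop1` and `pop2` (the two simulation tables under the
#'   Diana-Perri model), `mixture` (both populations under the mixture
#'   model), `survey` (the GPA-survey MSE table).
#' @export
reference_tables <- function() {
  rd <- function(f) {
    utils::read.csv(system.file("extdata", f, package = "rrtvar",
                                mustWork = TRUE))
  }
  list(
    privacy = rd("printed_table3.csv"),
    pop1 = rd("printed_table4.csv"),
    pop2 = rd("printed_table5.csv"),
    mixture = rd("printed_table6.csv"),
    survey = rd("printed_table2.csv")
  )
}

#' Covariance matrices of the two benchmark populations
#'
#' Population I has Var(Y) = 10 (correlations with the auxiliaries 0.68 /
#' 0.67), Population II has Var(Y) = 6 (correlations 0.87 / 0.87); both
#' share the auxiliary block.
#'
#' @param which `"I"` or `"II"`.
#' @return 3x3 covariance matrix for (Y, X1, X2).
#' @export
population_sigma <- function(which = c("I", "II")) {
  which <- match.arg(which)
  vy <- if (which == "I") 10 else 6
  matrix(c(vy, 3, 2.9,
           3, 2, 1.1,
           2.9, 1.1, 2), 3, 3, byrow = TRUE)
}

#' Synthetic GPA survey population
#'
#' A synthetic stand-in for a 90-student GPA survey whose raw records are
#' not public: trivariate normal draws rescaled so the sample moments match
#' the published summary characteristics exactly (Y: CGPA, mean 3.889,
#' sd 1.644; X1: weekly study hours, mean 27.61, sd 8.66; X2: courses in
#' recent semesters, mean 19.88, sd 18.83). Shipped as
#' `inst/extdata/gpa_population_synthetic.csv`; this function regenerates
#' it deterministically.
#'
#' @param seed integer seed (default 2023, the shipped fixture's seed).
#' @return A `finite_population` with 90 units.
#' @export
synthetic_gpa_population <- function(seed = 2023L) {
  n <- 90L
  targets <- list(
    mean = c(3.889, 27.61, 19.88),
    sd = c(1.644, 8.66, 18.83)
  )
  rho <- matrix(c(1, 0.35, 0.25,
                  0.35, 1, 0.15,
                  0.25, 0.15, 1), 3, 3)
  m <- withr::with_seed(seed, matrix(stats::rnorm(3L * n), n, 3L)) %*%
    chol(rho)
  # exact moment matching: standardize each column, then rescale
  m <- scale(m)
  m <- sweep(sweep(m, 2L, targets$sd, `*`), 2L, targets$mean, `+`)
  finite_population(y = round(m[, 1L], 4), x1 = round(m[, 2L], 4),
                    x2 = round(m[, 3L], 4))
}
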