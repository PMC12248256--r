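#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stationary AR(1) path with standard-normal marginals
#'
#' @param n length.
#' @param phi lag-1 autocorrelation in [0, 1).
#' @return numeric vector, each element marginally N(0, 1).
#' @keywords internal
#' @noRd
ar1_path <- function(n, phi) {
  stopifnot(n >= 1, phi >= 0, phi < 1)
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, sd = sqrt(1 - phi^2))
    for (i in 2:n) z[i] <- phi * z[i - 1] + innov[i - 1]
  }
  z
}

#' Log-scale spread matching a median/IQR pair
#'
#' For a lognormal fluctuation `m * exp(sigma * z)` around median `m`, the
#' interquartile range is `m * (exp(q75 * sigma) - exp(-q75 * sigma))` with
#' `q75 = qnorm(0.75)`. Inverting the small-sigma approximation gives
#' `sigma ~ iqr / (2 * q75 * m)`. Exact inversion is unnecessary: the
#' generator documents its noise model as a stand-in for unreported
#' within-segment variability.
#'
#' @keywords internal
#' @noRd
sigma_from_iqr <- function(median, iqr) {
  if (median <= 0 || iqr <= 0) return(0)
  iqr / (2 * stats::qnorm(0.75) * median)
}

abort_pape <- function(msg, class) {
  stop(structure(
    class = c(class, "pape_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
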