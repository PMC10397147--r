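#' Epidemic rate and initial-condition parameters
#'
#' Bundle of the rates and initial conditions shared by all solvers:
#' `beta` the per-edge transmission rate, `gamma` the recovery rate (both per
#' unit time), `rho` the initial infected fraction, and `mu` the initial
#' density of SS edges per node.  When `mu` is `NULL` it defaults, at solve
#' time, to the mean degree `psi'(1)` of the supplied degree distribution,
#' which makes the edge-based initial conditions (`x_SS(0) = mu`,
#' `x_SI(0) = mu*rho`) consistent with the Volz initial conditions
#' (`theta(0) = p_S(0) = 1`, `p_I(0) = rho`) so that all mean-field models
#' start from the same state.
#'
#' @param beta per-edge transmission rate, non-negative.
#' @param gamma recovery rate, non-negative.
#' @param rho initial infected fraction in `(0, 1)`.
#' @param mu initial SS-edge density per node (positive), or `NULL` for the
#'   default `psi'(1)`.
#' @return An object of class `"epi_params"`.
#' @export
epi_params <- function(beta, gamma, rho, mu = NULL) {
  stopifnot(is.numeric(beta), beta >= 0, is.numeric(gamma), gamma >= 0,
            is.numeric(rho), rho > 0, rho < 1)
  if (!is.null(mu)) stopifnot(is.numeric(mu), mu > 0)
  structure(list(beta = beta, gamma = gamma, rho = rho, mu = mu),
            class = "epi_params")
}

# resolve the mu default against a distribution
resolve_mu <- function(params, dist) {
  if (!is.null(params$mu)) params$mu else pgf(dist, 1, order = 1L)
}

#' @export
print.epi_params <- function(x, ...) {
  cat("Epidemic parameters: beta = ", x$beta, ", gamma = ", x$gamma,
      ", rho = ", x$rho, ", mu = ",
      if (is.null(x$mu)) "psi'(1) (default)" else format(x$mu),
      "\n", sep = "")
  invisible(x)
}
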