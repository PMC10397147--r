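#' Survival-equation parameters
#'
#' The DSA system for a Poisson-type network reduces to a single autonomous
#' equation for the survival probability `S_t` (the probability that a
#' typical initially susceptible node is still susceptible at `t`), driven by
#' the closure constant `kappa` and three compound rates:
#' `beta_tilde = mu*beta`, `gamma_tilde = beta + gamma`,
#' `rho_tilde = beta*mu*rho`.  Note `rho_tilde / beta_tilde = rho < 1`.
#'
#' @param kappa closure constant, positive.
#' @param beta_tilde,gamma_tilde,rho_tilde compound rates, positive
#'   (`rho_tilde = 0` admitted: it freezes `S_t` at 1).
#' @return An object of class `"survival_params"`.
#' @seealso [as_survival_params()] to build from network-level parameters.
#' @export
survival_params <- function(kappa, beta_tilde, gamma_tilde, rho_tilde) {
  stopifnot(kappa > 0, beta_tilde > 0, gamma_tilde > 0, rho_tilde >= 0)
  if (rho_tilde / beta_tilde >= 1)
    stop("rho_tilde/beta_tilde = rho must be < 1")
  structure(list(kappa = kappa, beta_tilde = beta_tilde,
                 gamma_tilde = gamma_tilde, rho_tilde = rho_tilde),
            class = "survival_params")
}

#' Map network-level parameters to survival-equation parameters
#'
#' Requires a Poisson-type degree distribution (the reduction relies on the
#' exact closure identity `x_SS = mu * x_S^(2*kappa)`); tabulated
#' distributions are classified first and rejected when not PT.
#'
#' @param dist a [degree_dist()] object (must be Poisson-type).
#' @param params an [epi_params()] bundle; `mu = NULL` defaults to `psi'(1)`.
#' @return A `"survival_params"` object.
#' @examples
#' as_survival_params(degree_dist("poisson", lambda = 10),
#'                    epi_params(0.2, 1, 0.025, mu = 9.75))
#' @export
as_survival_params <- function(dist, params) {
  stopifnot(inherits(dist, "degree_dist"), inherits(params, "epi_params"))
  pt <- if (dist$family == "tabulated") {
    cl <- classify_pt(dist)
    if (!cl$is_pt)
      stop("closure not exact: degree distribution is not Poisson-type ",
           "(kappa ranges over [", format(cl$kappa_range[1], digits = 6),
           ", ", format(cl$kappa_range[2], digits = 6), "])")
    cl$pt
  } else pt_params(dist)
  mu <- resolve_mu(params, dist)
  survival_params(pt$kappa, mu * params$beta, params$beta + params$gamma,
                  params$beta * mu * params$rho)
}

#' @export
print.survival_params <- function(x, ...) {
  cat("Survival-equation parameters: kappa = ", format(x$kappa, digits = 10),
      ", beta~ = ", format(x$beta_tilde, digits = 10),
      ", gamma~ = ", format(x$gamma_tilde, digits = 10),
      ", rho~ = ", format(x$rho_tilde, digits = 10), "\n", sep = "")
  invisible(x)
}

# -dS/dt as a closed-form function of S.  The kappa != 1 branch evaluates
# S*(1 - S^(kappa-1))/(1-kappa) as S*expm1((kappa-1)*log(S))/(kappa-1) to
# avoid cancellation near kappa = 1; the branch split is |kappa-1| < 1e-9.
survival_rate <- function(S, sp) {
  k <- sp$kappa
  if (abs(k - 1) < 1e-9) {
    sp$beta_tilde * (S - S^2) + sp$gamma_tilde * S * log(S) +
      sp$rho_tilde * S
  } else {
    Sk <- S^k
    sp$beta_tilde * (1 - Sk) * Sk +
      sp$gamma_tilde * S * expm1((k - 1) * log(S)) / (k - 1) +
      sp$rho_tilde * Sk
  }
}

#' Solve the single survival equation
#'
#' Integrates `-dS/dt = beta_tilde (1-S^kappa) S^kappa +
#' gamma_tilde/(1-kappa) S (1-S^(kappa-1)) + rho_tilde S^kappa` (with the
#' limiting form `beta_tilde (S-S^2) + gamma_tilde S log S + rho_tilde S`
#' at `kappa = 1`) from `S_0 = 1`.  `S_t` decreases to a positive limit
#' `S_inf`: it is an improper survival function, since a positive fraction
#' of nodes escapes infection entirely.  Downstream likelihoods must
#' therefore normalize by `1 - S_T` on an observation window `[0, T]`.
#'
#' @param sp a [survival_params()] object.
#' @param times increasing time grid starting at 0.
#' @param solver list with `method`, `rtol`, `atol`.
#' @return A `"sir_trajectory"` with the single column `S`.
#' @export
solve_survival <- function(sp, times, solver = default_solver()) {
  stopifnot(inherits(sp, "survival_params"), times[1] == 0,
            !is.unsorted(times))
  # the flow cannot cross S = 0; freezing below a floor keeps extreme
  # parameter points (probed during likelihood maximization) integrable
  rhs <- function(t, y, parms)
    list(if (y[1] <= 1e-12) 0 else -survival_rate(y[1], sp))
  out <- run_ode(c(S = 1), times, rhs, solver)
  st <- data.frame(S = pmin(pmax(out[, "S"], 0), 1))
  new_sir_trajectory(times, st, "survival", sp, NULL,
                     extra = list(solver = solver, improper = TRUE))
}

#' Final size of the epidemic
#'
#' Locates the root `S_inf` in `(0, 1)` of the final-size equation
#' `beta_tilde (1 - S^kappa) + rho_tilde =
#'  gamma_tilde/(1-kappa) (1 - S^(1-kappa))` for `kappa != 1`, or
#' `beta_tilde (1 - S) + rho_tilde = -gamma_tilde log S` for `kappa = 1`,
#' by bracketing root search on `[1e-12, 1 - 1e-12]` to a tolerance of
#' `1e-12`.  The endpoint `S = 1` is excluded: `rho_tilde > 0` makes the
#' residual there strictly positive.  `1 - S_inf` is the attack rate.
#'
#' @param sp a [survival_params()] object.
#' @return `S_inf`, the fraction of the population never infected.
#' @export
final_size <- function(sp) {
  stopifnot(inherits(sp, "survival_params"), sp$rho_tilde > 0)
  k <- sp$kappa
  resid <- function(S) {
    if (abs(k - 1) < 1e-9)
      sp$beta_tilde * (1 - S) + sp$rho_tilde + sp$gamma_tilde * log(S)
    else
      sp$beta_tilde * (1 - S^k) + sp$rho_tilde +
        sp$gamma_tilde * expm1((1 - k) * log(S)) / (1 - k)
  }
  lo <- 1e-12; hi <- 1 - 1e-12
  flo <- resid(lo); fhi <- resid(hi)
  if (!is.finite(flo) || flo * fhi > 0)
    stop("no sign change on (", lo, ", ", hi, "): residuals ",
         format(flo), " and ", format(fhi))
  stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
}
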