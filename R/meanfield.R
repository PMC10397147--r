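#' Mean-field SIR models on configuration model networks
#'
#' Three equivalent descriptions of the large-network limit of a stochastic
#' SIR epidemic on a configuration model graph:
#'
#' * [solve_volz()] — the edge-based model in the edge-survival probability
#'   `theta` and the conditional edge-type probabilities `p_I`, `p_S`, with
#'   `x_S = psi(theta)` read off algebraically;
#' * [solve_dsa()] — the dynamical-survival-analysis model in the per-node
#'   edge densities `x_SS`, `x_SI` and the edge-survival probability
#'   `x_theta`;
#' * [solve_pairwise()] — the pairwise model for expected counts of nodes and
#'   ordered pairs, closed with the triple approximation
#'   `[ASI] = kappa [AS][SI]/[S]`, which is exact precisely for Poisson-type
#'   degree distributions.
#'
#' All solvers carry the recovered fraction as an explicit auxiliary state
#' (`dx_R/dt = gamma * x_I`) so that conservation of the total remains a
#' testable property rather than an identity imposed by construction.
#'
#' @name mean_field_models
NULL

default_solver <- function() list(method = "lsoda", rtol = 1e-8, atol = 1e-10)

run_ode <- function(y0, times, rhs, solver = default_solver()) {
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = solver$method, rtol = solver$rtol,
                      atol = solver$atol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed: ", paste(attr(out, "istate"),
                                           collapse = " "))
  out
}

#' Solve the Volz edge-based mean-field model
#'
#' Integrates the system
#' `theta' = -beta p_I theta`,
#' `p_I' = beta p_S p_I theta psi''(theta)/psi'(theta) - beta p_I (1-p_I)
#'  - gamma p_I`,
#' `p_S' = beta p_S p_I (1 - theta psi''(theta)/psi'(theta))`,
#' `x_I' = beta p_I theta psi'(theta) - gamma x_I`,
#' with `x_S = psi(theta)`, from the initial state
#' `theta(0) = p_S(0) = 1`, `p_I(0) = rho`, `x_I(0) = rho`.
#'
#' @param dist a [degree_dist()] with finite `psi''(1)`.
#' @param params an [epi_params()] bundle.
#' @param times increasing time grid starting at 0.
#' @param solver list with `method`, `rtol`, `atol`.
#' @return A `"sir_trajectory"` with columns `theta, p_I, p_S, x_S, x_I, x_R`.
#' @export
solve_volz <- function(dist, params, times,
                       solver = default_solver()) {
  stopifnot(inherits(dist, "degree_dist"), inherits(params, "epi_params"),
            times[1] == 0, !is.unsorted(times))
  beta <- params$beta; gamma <- params$gamma; rho <- params$rho
  rhs <- function(t, y, parms) {
    theta <- y[1]; pI <- y[2]; pS <- y[3]; xI <- y[4]
    d1 <- pgf_unchecked(dist, theta, 1L)
    ratio <- theta * pgf_unchecked(dist, theta, 2L) / d1
    list(c(-beta * pI * theta,
           beta * pS * pI * ratio - beta * pI * (1 - pI) - gamma * pI,
           beta * pS * pI * (1 - ratio),
           beta * pI * theta * d1 - gamma * xI,
           gamma * xI))
  }
  y0 <- c(theta = 1, p_I = rho, p_S = 1, x_I = rho, x_R = 0)
  out <- run_ode(y0, times, rhs, solver)
  st <- data.frame(theta = out[, "theta"], p_I = out[, "p_I"],
                   p_S = out[, "p_S"],
                   x_S = pgf_unchecked(dist, out[, "theta"], 0L),
                   x_I = out[, "x_I"], x_R = out[, "x_R"])
  check_nonneg(st)
  st[] <- lapply(st, function(v) pmax(v, 0))
  new_sir_trajectory(times, st, "volz", params, dist,
                     extra = list(solver = solver))
}

#' Solve the DSA edge-density mean-field model
#'
#' Integrates
#' `x_theta' = -beta x_SI / psi'(x_theta)`,
#' `x_SS' = -2 beta x_SI x_SS psi''(x_theta)/psi'(x_theta)^2`,
#' `x_SI' = x_SI (beta (x_SS - x_SI) psi''(x_theta)/psi'(x_theta)^2
#'  - (beta + gamma))`,
#' `x_S' = -beta x_SI`, `x_I' = beta x_SI - gamma x_I`,
#' from `x_theta(0) = x_S(0) = 1`, `x_I(0) = rho`, `x_SS(0) = mu`,
#' `x_SI(0) = mu * rho`.  `x_S(t)` has a survival-analytic reading: it is the
#' probability that a typical initially susceptible node is still susceptible
#' at time `t`.
#'
#' @inheritParams solve_volz
#' @return A `"sir_trajectory"` with columns
#'   `x_theta, x_SS, x_SI, x_S, x_I, x_R`.
#' @export
solve_dsa <- function(dist, params, times, solver = default_solver()) {
  stopifnot(inherits(dist, "degree_dist"), inherits(params, "epi_params"),
            times[1] == 0, !is.unsorted(times))
  beta <- params$beta; gamma <- params$gamma; rho <- params$rho
  mu <- resolve_mu(params, dist)
  rhs <- function(t, y, parms) {
    xth <- y[1]; xSS <- y[2]; xSI <- y[3]; xI <- y[5]
    d1 <- pgf_unchecked(dist, xth, 1L)
    w <- pgf_unchecked(dist, xth, 2L) / d1^2
    list(c(-beta * xSI / d1,
           -2 * beta * xSI * xSS * w,
           xSI * (beta * (xSS - xSI) * w - (beta + gamma)),
           -beta * xSI,
           beta * xSI - gamma * xI,
           gamma * xI))
  }
  y0 <- c(x_theta = 1, x_SS = mu, x_SI = mu * rho, x_S = 1, x_I = rho,
          x_R = 0)
  out <- run_ode(y0, times, rhs, solver)
  st <- as.data.frame(out[, -1, drop = FALSE])
  check_nonneg(st)
  st[] <- lapply(st, function(v) pmax(v, 0))
  p2 <- params; p2$mu <- mu
  new_sir_trajectory(times, st, "dsa", p2, dist,
                     extra = list(solver = solver))
}

#' Solve the closed pairwise model
#'
#' Integrates the pairwise equations for expected counts, closed with
#' `[ASI] = kappa [AS][SI]/[S]`:
#' `[S]' = -beta [SI]`, `[I]' = beta [SI] - gamma [I]`, `[R]' = gamma [I]`,
#' `[SI]' = [SI] (beta kappa ([SS]-[SI])/[S] - (beta+gamma))`,
#' `[SS]' = -2 beta kappa [SS][SI]/[S]`,
#' from `[S](0) = N`, `[I](0) = rho N`, `[SS](0) = mu N`,
#' `[SI](0) = mu rho N` (pairs counted in both orders).  The closure is exact
#' (in the large-N limit) if and only if the degree distribution is
#' Poisson-type with closure constant `kappa`; a numeric `kappa` may be
#' supplied to apply the approximate closure to a non-PT network, in which
#' case the trajectory is tagged `approximate`.
#'
#' @param pt a `"pt_params"` object (exact closure) or a single numeric
#'   `kappa` (approximate closure for non-PT networks).
#' @param params an [epi_params()] bundle; `mu = NULL` requires `pt` to carry
#'   the mean degree (`alpha`), used as default.
#' @param N population size used to scale the counts.
#' @inheritParams solve_volz
#' @return A `"sir_trajectory"` with columns `S, I, R, SI, SS`.
#' @export
solve_pairwise <- function(pt, params, N = 1, times,
                           solver = default_solver()) {
  stopifnot(inherits(params, "epi_params"), times[1] == 0,
            !is.unsorted(times), N > 0)
  approximate <- FALSE
  if (inherits(pt, "pt_params")) {
    kappa <- pt$kappa
    mu <- if (!is.null(params$mu)) params$mu else pt$alpha
  } else {
    stopifnot(is.numeric(pt), length(pt) == 1L, pt > 0)
    kappa <- pt
    approximate <- TRUE
    mu <- params$mu
    if (is.null(mu))
      stop("supply mu in epi_params() when closing with a bare kappa")
  }
  beta <- params$beta; gamma <- params$gamma; rho <- params$rho
  rhs <- function(t, y, parms) {
    S <- y[1]; I <- y[2]; SI <- y[4]; SS <- y[5]
    if (S <= 0 && SI > 0)
      stop("closure singularity: [S] reached 0 with [SI] > 0")
    list(c(-beta * SI,
           beta * SI - gamma * I,
           gamma * I,
           SI * (beta * kappa * (SS - SI) / S - (beta + gamma)),
           -2 * beta * kappa * SS * SI / S))
  }
  y0 <- c(S = N, I = rho * N, R = 0, SI = mu * rho * N, SS = mu * N)
  out <- run_ode(y0, times, rhs, solver)
  st <- as.data.frame(out[, -1, drop = FALSE])
  check_nonneg(st, tol = 1e-9 * N)
  st[] <- lapply(st, function(v) pmax(v, 0))
  p2 <- params; p2$mu <- mu
  new_sir_trajectory(times, st, "pairwise", p2, NULL,
                     extra = list(kappa = kappa, N = N,
                                  approximate = approximate,
                                  solver = solver))
}

#' Closure ratio along a trajectory
#'
#' Evaluates `kappa(t) = psi''(theta(t)) psi(theta(t)) / psi'(theta(t))^2`
#' along a Volz or DSA trajectory.  The series is constant exactly when the
#' degree distribution is Poisson-type; for other networks it drifts as the
#' susceptible nodes are depleted, which is why no constant-kappa pairwise
#' closure can be exact there.
#'
#' @param dist the [degree_dist()] the trajectory was solved with.
#' @param traj a `"sir_trajectory"` from [solve_volz()] or [solve_dsa()].
#' @return Data frame with columns `time` and `kappa`.
#' @export
kappa_trajectory <- function(dist, traj) {
  stopifnot(inherits(dist, "degree_dist"), inherits(traj, "sir_trajectory"))
  col <- intersect(c("theta", "x_theta"), names(traj$states))
  if (length(col) == 0)
    stop("trajectory has no theta column; need a Volz or DSA trajectory")
  theta <- traj$states[[col[1]]]
  data.frame(time = traj$times, kappa = kappa_ratio(dist, pmin(theta, 1)))
}
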