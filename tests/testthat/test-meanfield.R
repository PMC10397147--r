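grid15 <- seq(0, 15, by = 0.05)

test_that("all three solvers start from the stated initial conditions", {
  d <- degree_dist("poisson", lambda = 10)
  p <- study_params("poisson")
  v <- solve_volz(d, p, c(0, 1))
  expect_equal(unlist(v$states[1, c("theta", "p_I", "p_S", "x_S", "x_I")]),
               c(theta = 1, p_I = 0.025, p_S = 1, x_S = 1, x_I = 0.025))

  ds <- solve_dsa(d, p, c(0, 1))   # default mu = psi'(1) = 10
  expect_equal(
    unlist(ds$states[1, c("x_theta", "x_SS", "x_SI", "x_S", "x_I")]),
    c(x_theta = 1, x_SS = 10, x_SI = 0.25, x_S = 1, x_I = 0.025))

  pw <- solve_pairwise(pt_params(d), p, N = 1000, times = c(0, 1))
  expect_equal(unlist(pw$states[1, ]),
               c(S = 1000, I = 25, R = 0, SI = 250, SS = 10000))
})

test_that("no transmission freezes theta and decays infection at rate gamma", {
  d <- degree_dist("poisson", lambda = 10)
  p <- epi_params(beta = 0, gamma = 1, rho = 0.025)
  tt <- seq(0, 5, by = 0.1)
  v <- solve_volz(d, p, tt)
  expect_equal(v$states$theta, rep(1, length(tt)), tolerance = 1e-10)
  expect_equal(v$states$x_S, rep(1, length(tt)), tolerance = 1e-10)
  expect_equal(v$states$x_I, 0.025 * exp(-tt), tolerance = 1e-8)
  ds <- solve_dsa(d, p, tt)
  expect_equal(ds$states$x_I, 0.025 * exp(-tt), tolerance = 1e-8)
  kt <- kappa_trajectory(d, ds)
  expect_lt(diff(range(kt$kappa)), 1e-12)
})

test_that("adaptive solutions match a fixed-step RK4 oracle", {
  d <- degree_dist("poisson", lambda = 10)
  beta <- 0.2; gamma <- 1; rho <- 0.025; mu <- 10
  p <- epi_params(beta, gamma, rho)

  rhs_volz <- function(t, y) {
    d1 <- pgf(d, min(y[1], 1), order = 1)
    ratio <- y[1] * pgf(d, min(y[1], 1), order = 2) / d1
    c(-beta * y[2] * y[1],
      beta * y[3] * y[2] * ratio - beta * y[2] * (1 - y[2]) - gamma * y[2],
      beta * y[3] * y[2] * (1 - ratio),
      beta * y[2] * y[1] * d1 - gamma * y[4])
  }
  y5 <- rk4_integrate(rhs_volz, c(1, rho, 1, rho), t_end = 5, h = 1e-3)
  v <- solve_volz(d, p, c(0, 5))
  expect_equal(pgf(d, y5[1]), v$states$x_S[2], tolerance = 1e-6)
  expect_equal(y5[4], v$states$x_I[2], tolerance = 1e-6)

  rhs_dsa <- function(t, y) {
    d1 <- pgf(d, min(y[1], 1), order = 1)
    w <- pgf(d, min(y[1], 1), order = 2) / d1^2
    c(-beta * y[3] / d1,
      -2 * beta * y[3] * y[2] * w,
      y[3] * (beta * (y[2] - y[3]) * w - (beta + gamma)),
      -beta * y[3],
      beta * y[3] - gamma * y[5])
  }
  y5 <- rk4_integrate(rhs_dsa, c(1, mu, mu * rho, 1, rho), t_end = 5,
                      h = 1e-3)
  ds <- solve_dsa(d, p, c(0, 5))
  expect_equal(y5[4], ds$states$x_S[2], tolerance = 1e-6)
  expect_equal(y5[5], ds$states$x_I[2], tolerance = 1e-6)

  kap <- 1
  rhs_pw <- function(t, y) {
    c(-beta * y[4],
      beta * y[4] - gamma * y[2],
      gamma * y[2],
      y[4] * (beta * kap * (y[5] - y[4]) / y[1] - (beta + gamma)),
      -2 * beta * kap * y[5] * y[4] / y[1])
  }
  y5 <- rk4_integrate(rhs_pw, c(1, rho, 0, mu * rho, mu), t_end = 5,
                      h = 1e-3)
  pw <- solve_pairwise(pt_params(d), p, N = 1, times = c(0, 5))
  expect_equal(y5[1], pw$states$S[2], tolerance = 1e-6)
  expect_equal(y5[2], pw$states$I[2], tolerance = 1e-6)
})

test_that("Volz and DSA agree for arbitrary degree distributions", {
  for (d in c(study_dists(), list(bimodal = bimodal_dist()))) {
    p <- epi_params(0.2, 1, 0.025)
    v <- solve_volz(d, p, grid15)
    ds <- solve_dsa(d, p, grid15)
    expect_lt(max(abs(v$states$x_S - ds$states$x_S)), 1e-5)
    expect_lt(max(abs(v$states$x_I - ds$states$x_I)), 1e-5)
  }
})

test_that("per-capita closed pairwise equals DSA for Poisson-type networks", {
  for (nm in names(study_dists())) {
    d <- study_dists()[[nm]]
    p <- study_params(nm)
    ds <- solve_dsa(d, p, grid15)
    pw <- solve_pairwise(pt_params(d), p, N = 1, times = grid15)
    expect_lt(max(abs(pw$states$S - ds$states$x_S)), 1e-6)
    expect_lt(max(abs(pw$states$I - ds$states$x_I)), 1e-6)
  }
})

test_that("initial [SS] decline matches the closed-form rate", {
  d <- degree_dist("poisson", lambda = 10)
  p <- study_params("poisson")
  N <- 1000; mu <- 10; kap <- 1
  h <- 1e-6
  pw <- solve_pairwise(pt_params(d), p, N = N, times = c(0, h))
  # d[SS]/dt(0) = -2 beta kappa [SS][SI]/[S] = -2 beta kappa mu^2 rho N
  expect_equal((pw$states$SS[2] - pw$states$SS[1]) / h,
               -2 * 0.2 * kap * mu^2 * 0.025 * N, tolerance = 1e-3)
})

test_that("conservation and monotonicity hold along all trajectories", {
  for (nm in names(study_dists())) {
    d <- study_dists()[[nm]]
    p <- study_params(nm)
    ds <- solve_dsa(d, p, grid15)
    v <- solve_volz(d, p, grid15)
    # the conserved total equals its initial value 1 + rho
    expect_lt(max(abs(ds$states$x_S + ds$states$x_I + ds$states$x_R -
                        1.025)), 1e-8)
    expect_lt(max(abs(v$states$x_S + v$states$x_I + v$states$x_R -
                        1.025)), 1e-8)
    for (col in c("x_theta", "x_S", "x_SS"))
      expect_true(all(diff(ds$states[[col]]) <= 1e-12), label = col)
    expect_true(all(diff(v$states$theta) <= 1e-12))
    expect_true(all(diff(ds$states$x_R) >= -1e-12))

    pw <- solve_pairwise(pt_params(d), p, N = 500, times = grid15)
    expect_lt(max(abs(pw$states$S + pw$states$I + pw$states$R -
                        500 * 1.025)), 500 * 1e-8)
  }
})

test_that("the DSA identity psi(x_theta) = x_S holds along solutions", {
  for (d in c(study_dists(), list(bimodal = bimodal_dist()))) {
    ds <- solve_dsa(d, epi_params(0.2, 1, 0.025), grid15)
    expect_lt(max(abs(pgf(d, pmin(ds$states$x_theta, 1)) - ds$states$x_S)),
              1e-6)
  }
})

test_that("x_SS = mu x_S^(2 kappa) for Poisson-type networks", {
  for (nm in names(study_dists())) {
    d <- study_dists()[[nm]]
    ds <- solve_dsa(d, study_params(nm), grid15)
    mu <- ds$params$mu
    kap <- study_kappas[nm]
    expect_lt(max(abs(ds$states$x_SS / (mu * ds$states$x_S^(2 * kap)) - 1)),
              1e-8)
  }
})

test_that("kappa(t) is constant for PT networks, drifting for bimodal", {
  for (nm in names(study_dists())) {
    d <- study_dists()[[nm]]
    kt <- kappa_trajectory(d, solve_dsa(d, study_params(nm), grid15))
    expect_lt(diff(range(kt$kappa)), 1e-8)
    expect_equal(kt$kappa[1], unname(study_kappas[nm]), tolerance = 1e-10)
  }
  b <- bimodal_dist()
  kt <- kappa_trajectory(b, solve_dsa(b, epi_params(0.2, 1, 0.025), grid15))
  expect_equal(kt$kappa[1], 2.34, tolerance = 1e-8)
  expect_gt(diff(range(kt$kappa)), 0.1)
})

test_that("kappa_trajectory requires a theta column", {
  d <- degree_dist("poisson", lambda = 10)
  pw <- solve_pairwise(pt_params(d), study_params("poisson"), N = 1,
                       times = c(0, 1))
  expect_error(kappa_trajectory(d, pw), "theta")
})

test_that("pairwise closure with a bare kappa is tagged approximate", {
  p <- epi_params(0.2, 1, 0.025, mu = 10)
  pw <- solve_pairwise(1, p, N = 1, times = c(0, 1))
  expect_true(pw$approximate)
  expect_error(solve_pairwise(1, epi_params(0.2, 1, 0.025), N = 1,
                              times = c(0, 1)), "mu")
})

test_that("trajectories round-trip through CSV within 1e-12", {
  tmp <- withr::local_tempdir()
  d <- degree_dist("poisson", lambda = 10)
  ds <- solve_dsa(d, study_params("poisson"), seq(0, 5, by = 0.5))
  path <- file.path(tmp, "traj.csv")
  write_trajectory(ds, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_trajectory(path)
  expect_equal(back$model, "dsa")
  expect_equal(back$states$x_S, ds$states$x_S, tolerance = 1e-12)
  expect_equal(back$times, ds$times, tolerance = 1e-12)
})
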