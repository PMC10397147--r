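sp_study <- survival_params(1, 1.95, 1.2, 0.04875)

test_that("log-likelihood has the sum-over-times structure", {
  times <- c(1.2, 2.5, 4.0)
  ll <- dsa_loglik(infection_sample(times, T = 10), sp_study)
  ll2 <- dsa_loglik(infection_sample(rep(times, 2), T = 10), sp_study)
  expect_equal(ll2, 2 * ll, tolerance = 1e-9)
  # permutation invariance
  ll3 <- dsa_loglik(infection_sample(rev(times), T = 10), sp_study)
  expect_equal(ll3, ll, tolerance = 1e-12)
  # single observation decomposes as log density minus log window mass
  t1 <- 2.5
  S <- solve_survival(sp_study, c(0, t1, 10))$states$S
  expect_equal(dsa_loglik(infection_sample(t1, T = 10), sp_study),
               log(netsir:::survival_rate(S[2], sp_study)) - log(1 - S[3]),
               tolerance = 1e-9)
})

test_that("closed-form density matches a central-difference derivative", {
  tt <- seq(0, 10, length.out = 2001)
  S <- solve_survival(sp_study, tt)$states$S
  mid <- 2:2000
  num <- -(S[mid + 1] - S[mid - 1]) / (tt[3] - tt[1])
  expect_lt(max(abs(num - netsir:::survival_rate(S[mid], sp_study))), 1e-6)
})

test_that("the survival form reproduces the literal sum of log S", {
  times <- c(1, 2, 3)
  S <- solve_survival(sp_study, c(0, times, 10))$states$S
  expect_equal(
    dsa_loglik(infection_sample(times, T = 10), sp_study,
               form = "survival"),
    sum(log(S[2:4])) - 3 * log(1 - S[5]), tolerance = 1e-9)
})

test_that("sampled infection times follow the target distribution", {
  s <- sample_infection_times(sp_study, 10000, T = 10, seed = 51)
  expect_identical(
    sample_infection_times(sp_study, 10000, T = 10, seed = 51)$times,
    s$times)
  tt <- seq(0, 10, length.out = 2001)
  S <- solve_survival(sp_study, tt)$states$S
  cdf <- stats::approxfun(tt, (1 - S) / (1 - S[2001]), rule = 2)
  ks <- stats::ks.test(s$times, cdf)
  expect_gt(ks$p.value, 0.01)
  # Monte-Carlo mean vs quadrature mean of the density
  dens <- netsir:::survival_rate(S, sp_study) / (1 - S[2001])
  w <- (c(0, diff(tt)) + c(diff(tt), 0)) / 2
  mu_q <- sum(w * tt * dens)
  sd_q <- sqrt(sum(w * tt^2 * dens) - mu_q^2)
  expect_lt(abs(mean(s$times) - mu_q), 3 * sd_q / sqrt(10000))
})

test_that("fitting on the expected log-likelihood recovers the truth", {
  # infinite-data limit via fine quadrature over the generating density
  tt <- seq(0, 10, length.out = 1001)
  S <- solve_survival(sp_study, tt)$states$S
  dens <- netsir:::survival_rate(S, sp_study) / (1 - S[1001])
  w <- (c(0, diff(tt)) + c(diff(tt), 0)) / 2
  e_negll <- function(lp) {
    p <- exp(lp)
    if (p[3] / p[1] >= 1) return(1e10)
    v <- tryCatch({
      spp <- survival_params(1, p[1], p[2], p[3])
      Sp <- solve_survival(spp, tt)$states$S
      dp <- netsir:::survival_rate(Sp, spp) / (1 - Sp[1001])
      -sum(w * dens * log(pmax(dp, 1e-300)))
    }, error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }
  o <- stats::optim(log(c(1.5, 1, 0.03)), e_negll, method = "L-BFGS-B",
                    lower = log(rep(1e-4, 3)), upper = log(rep(100, 3)),
                    control = list(maxit = 500, factr = 1e5))
  expect_equal(unname(exp(o$par)), c(1.95, 1.2, 0.04875), tolerance = 5e-3)
})

test_that("initializing at the truth yields a stationary fit", {
  s <- sample_infection_times(sp_study, 800, T = 10, seed = 61)
  fit <- suppressWarnings(
    dsa_fit(s, kappa = 1,
            init = c(beta_tilde = 1.95, gamma_tilde = 1.2,
                     rho_tilde = 0.04875),
            n_starts = 1, n_screen = 4, seed = 62))
  est <- coef(fit)
  # numerical gradient of the per-observation log-likelihood at the optimum
  g <- vapply(1:3, function(j) {
    h <- est[j] * 1e-4
    pp <- est; pm <- est
    pp[j] <- est[j] + h; pm[j] <- est[j] - h
    (dsa_loglik(s, survival_params(1, pp[1], pp[2], pp[3])) -
       dsa_loglik(s, survival_params(1, pm[1], pm[2], pm[3]))) / (2 * h)
  }, numeric(1)) / s$k
  expect_lt(sqrt(sum(g^2)), 1e-3)
  expect_gte(fit$logLik, dsa_loglik(s, sp_study) - 1e-6)
})

test_that("the truth dominates single-coordinate perturbations at large k", {
  s <- sample_infection_times(sp_study, 5000, T = 10, seed = 71)
  ll0 <- dsa_loglik(s, sp_study)
  base <- c(1.95, 1.2, 0.04875)
  for (j in 1:3) for (f in c(0.5, 1.5)) {
    p <- base; p[j] <- p[j] * f
    expect_lt(dsa_loglik(s, survival_params(1, p[1], p[2], p[3])), ll0)
  }
})

test_that("fit object methods are coherent", {
  s <- sample_infection_times(sp_study, 300, T = 10, seed = 81)
  fit <- suppressWarnings(dsa_fit(s, kappa = 1, n_starts = 4, n_screen = 16,
                                  seed = 82))
  expect_s3_class(fit, "dsa_fit")
  expect_named(coef(fit), c("beta_tilde", "gamma_tilde", "rho_tilde"))
  expect_equal(attr(logLik(fit), "nobs"), 300L)
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  expect_equal(fit$logLik,
               dsa_loglik(s, fit$sp), tolerance = 1e-8)
  # predictions: S decreasing from 1, conditional density integrates to ~1
  tt <- seq(0, 10, length.out = 201)
  Sp <- predict(fit, tt, type = "survival")
  expect_equal(Sp[1], 1, tolerance = 1e-10)
  expect_true(all(diff(Sp) <= 0))
  dens <- predict(fit, tt, type = "conditional")
  expect_equal(sum((dens[-1] + dens[-201]) / 2 * diff(tt)), 1,
               tolerance = 1e-2)
  # PIT residuals look uniform
  r <- residuals(fit)
  expect_true(all(r >= 0 & r <= 1))
  expect_lt(abs(mean(r) - 0.5), 0.1)
  # simulate() draws samples of the same shape
  sim <- simulate(fit, nsim = 2, seed = 83)
  expect_length(sim, 2)
  expect_equal(sim[[1]]$k, 300)
  # summary prints standard errors
  sm <- summary(fit)
  expect_true(all(is.finite(sm$coefficients[, "Std. Error"]) |
                    is.na(sm$coefficients[, "Std. Error"])))
})

test_that("samples and fit reports round-trip through files", {
  tmp <- withr::local_tempdir()
  s <- sample_infection_times(sp_study, 50, T = 8, seed = 91)
  path <- file.path(tmp, "times.csv")
  write_infection_sample(s, path)
  s2 <- read_infection_sample(path)
  expect_equal(s2$T, 8)
  expect_equal(s2$times, s$times, tolerance = 1e-15)

  fit <- suppressWarnings(dsa_fit(s, kappa = 1, n_starts = 2, n_screen = 8,
                                  seed = 92))
  fp <- file.path(tmp, "fit.json")
  write_fit(fit, fp)
  rep <- jsonlite::read_json(fp, simplifyVector = TRUE)
  expect_equal(rep$estimates$beta_tilde, unname(coef(fit)[1]))
  expect_equal(rep$k, 50)
})

test_that("degenerate likelihood inputs raise errors", {
  expect_error(dsa_loglik(infection_sample(0.5, T = 1),
                          survival_params(1, 1.95, 1.2, 0)),
               "degenerate")
  expect_error(infection_sample(c(-1, 2)))
  expect_error(infection_sample(c(1, 2), T = 1.5))
})
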