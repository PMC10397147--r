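# Study conditions shared across tests: the four benchmark degree
# distributions (regular 6, Poisson 10, negative binomial (10, 1/2), and the
# non-Poisson-type bimodal pmf with 80% degree 4 / 20% degree 34), with
# recovery rate 1, transmission rate 0.4 on the regular network and 0.2
# elsewhere, and 2.5% initially infected.

study_dists <- function() {
  list(regular = degree_dist("regular", n = 6),
       poisson = degree_dist("poisson", lambda = 10),
       nbinom = degree_dist("negative_binomial", r = 10, p = 0.5))
}

bimodal_dist <- function() {
  degree_dist("tabulated", degrees = c(4, 34), probs = c(0.8, 0.2))
}

study_kappas <- c(regular = 5 / 6, poisson = 1, nbinom = 11 / 10)

study_beta <- c(regular = 0.4, poisson = 0.2, nbinom = 0.2)

study_params <- function(name, mu = NULL) {
  epi_params(beta = unname(study_beta[name]), gamma = 1, rho = 0.025,
             mu = mu)
}

# independent fixed-step classical Runge-Kutta integrator used as the
# solver oracle; rhs(t, y) returns dy/dt
rk4_integrate <- function(rhs, y0, t_end, h) {
  n <- ceiling(t_end / h)
  y <- y0
  t <- 0
  for (i in seq_len(n)) {
    hh <- min(h, t_end - t)
    k1 <- rhs(t, y)
    k2 <- rhs(t + hh / 2, y + hh / 2 * k1)
    k3 <- rhs(t + hh / 2, y + hh / 2 * k2)
    k4 <- rhs(t + hh, y + hh * k3)
    y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + hh
  }
  y
}

# truncated tabulated copy of a parametric distribution
tabulated_copy <- function(dist) {
  tab <- netsir:::tabulate_pmf(dist)
  degree_dist("tabulated", degrees = tab$degrees,
              probs = tab$probs / sum(tab$probs))
}
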