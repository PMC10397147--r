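#' Degree distributions for configuration model networks
#'
#' Construct a degree distribution, the sole structural input of every model
#' in the package.  Parametric families (Poisson, binomial, negative binomial,
#' regular) carry closed-form probability generating functions (PGFs);
#' arbitrary distributions are supplied as a tabulated pmf.  The network
#' interpretation: `psi(theta)` is the probability that a randomly chosen node
#' is still susceptible when infection has crossed any given edge with
#' probability `1 - theta`.
#'
#' The negative binomial is parameterized so that its PGF is
#' `((1-p)/(1-p*u))^r`, i.e. `p` is the per-trial probability attached to the
#' counted events and the mean degree is `r*p/(1-p)`.
#'
#' Distributions must have a positive mean and a finite second factorial
#' moment `psi''(1)`; heavy tails violating this are rejected at construction.
#'
#' @param family one of `"poisson"`, `"binomial"`, `"negative_binomial"`,
#'   `"regular"`, `"tabulated"`.
#' @param ... family parameters: `lambda` (poisson); `n`, `p` (binomial);
#'   `r`, `p` (negative binomial); `n` (regular); `degrees`, `probs`
#'   (tabulated).  Tabulated probabilities are renormalized when they sum to
#'   one within `1e-6` and rejected otherwise.
#' @return An object of class `"degree_dist"`.
#' @examples
#' d <- degree_dist("poisson", lambda = 10)
#' pgf(d, 0.5)              # psi(0.5)
#' pgf(d, 1, order = 1)     # mean degree
#' kappa_ratio(d, 0.37)     # closure ratio, constant = 1 for Poisson
#' @export
degree_dist <- function(family = c("poisson", "binomial", "negative_binomial",
                                   "regular", "tabulated"), ...) {
  family <- match.arg(family)
  prm <- list(...)
  d <- switch(family,
    poisson = {
      lambda <- prm$lambda
      stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda > 0)
      new_degree_dist("poisson", list(lambda = lambda))
    },
    binomial = {
      n <- prm$n; p <- prm$p
      stopifnot(is.numeric(n), n >= 1, n == round(n),
                is.numeric(p), p > 0, p <= 1)
      if (p == 1)
        new_degree_dist("regular", list(n = as.integer(n)))
      else
        new_degree_dist("binomial", list(n = as.integer(n), p = p))
    },
    negative_binomial = {
      r <- prm$r; p <- prm$p
      stopifnot(is.numeric(r), r > 0, is.numeric(p), p > 0, p < 1)
      new_degree_dist("negative_binomial", list(r = r, p = p))
    },
    regular = {
      n <- prm$n
      stopifnot(is.numeric(n), n >= 1, n == round(n))
      new_degree_dist("regular", list(n = as.integer(n)))
    },
    tabulated = {
      degrees <- prm$degrees; probs <- prm$probs
      stopifnot(is.numeric(degrees), is.numeric(probs),
                length(degrees) == length(probs), length(degrees) >= 1,
                all(degrees >= 0), all(degrees == round(degrees)),
                all(probs >= 0))
      s <- sum(probs)
      if (abs(s - 1) > 1e-6)
        stop("tabulated probabilities sum to ", format(s),
             "; must equal 1 within 1e-6")
      o <- order(degrees)
      if (anyDuplicated(degrees)) stop("duplicated degrees in tabulated pmf")
      new_degree_dist("tabulated",
                      list(degrees = as.integer(degrees[o]),
                           probs = probs[o] / s))
    }
  )
  mu1 <- pgf(d, 1, order = 1L)
  if (!is.finite(mu1) || mu1 <= 0)
    stop("degree distribution must have a finite positive mean degree")
  if (!is.finite(pgf(d, 1, order = 2L)))
    stop("second factorial moment psi''(1) must be finite")
  d
}

new_degree_dist <- function(family, params) {
  structure(list(family = family, params = params), class = "degree_dist")
}

#' Evaluate a degree-distribution PGF or its derivatives
#'
#' Returns `psi(u)`, `psi'(u)` or `psi''(u)`.  Parametric families use closed
#' forms; tabulated pmfs use direct power-series summation.
#'
#' @param dist a [degree_dist()] object.
#' @param u evaluation points in `[0, 1]` (vectorized).
#' @param order derivative order, 0, 1 or 2.
#' @return Numeric vector of the same length as `u`.
#' @export
pgf <- function(dist, u, order = 0L) {
  stopifnot(inherits(dist, "degree_dist"))
  if (!is.numeric(order) || length(order) != 1L || !(order %in% 0:2))
    stop("'order' must be 0, 1 or 2")
  if (any(u < 0 | u > 1)) stop("'u' must lie in [0, 1]")
  pgf_unchecked(dist, u, as.integer(order))
}

# no domain check: ODE right-hand sides may probe marginally outside [0, 1]
pgf_unchecked <- function(dist, u, order) {
  p <- dist$params
  switch(dist$family,
    poisson = {
      lam <- p$lambda
      lam^order * exp(lam * (u - 1))
    },
    binomial = {
      n <- p$n; q <- p$p
      base <- 1 - q + q * u
      switch(order + 1L,
        base^n,
        n * q * base^(n - 1),
        n * (n - 1) * q^2 * base^(n - 2))
    },
    regular = {
      n <- p$n
      switch(order + 1L,
        u^n,
        n * u^(n - 1),
        if (n >= 2) n * (n - 1) * u^(n - 2) else 0 * u)
    },
    negative_binomial = {
      r <- p$r; q <- p$p
      switch(order + 1L,
        ((1 - q) / (1 - q * u))^r,
        r * q * (1 - q)^r / (1 - q * u)^(r + 1),
        r * (r + 1) * q^2 * (1 - q)^r / (1 - q * u)^(r + 2))
    },
    tabulated = {
      k <- p$degrees; pk <- p$probs
      vapply(u, function(ui) {
        switch(order + 1L,
          sum(pk * ui^k),
          sum(pk[k >= 1] * k[k >= 1] * ui^(k[k >= 1] - 1)),
          sum(pk[k >= 2] * k[k >= 2] * (k[k >= 2] - 1) * ui^(k[k >= 2] - 2)))
      }, numeric(1))
    }
  )
}

#' Closure ratio kappa at a given theta
#'
#' The quantity `psi''(theta) * psi(theta) / psi'(theta)^2`: the mean excess
#' degree of susceptible nodes divided by their mean degree.  The pairwise
#' triple closure is exact precisely when this ratio is constant in `theta`,
#' which holds if and only if the degree distribution is Poisson-type.
#'
#' @param dist a [degree_dist()] object.
#' @param theta values in `(0, 1]` (vectorized).
#' @return Numeric vector of ratios.
#' @export
kappa_ratio <- function(dist, theta) {
  stopifnot(inherits(dist, "degree_dist"))
  if (any(theta <= 0 | theta > 1)) stop("'theta' must lie in (0, 1]")
  d1 <- pgf_unchecked(dist, theta, 1L)
  if (any(d1 <= 0))
    stop("psi'(theta) = 0: degenerate distribution at this theta")
  pgf_unchecked(dist, theta, 2L) * pgf_unchecked(dist, theta, 0L) / d1^2
}

#' Mean excess degree of susceptible nodes
#'
#' `theta * psi''(theta) / psi'(theta)`: the expected number of further edges
#' from a susceptible node reached by crossing an edge, when infection has
#' crossed each edge independently with probability `1 - theta`.
#'
#' @inheritParams kappa_ratio
#' @export
mean_excess_degree <- function(dist, theta) {
  stopifnot(inherits(dist, "degree_dist"))
  if (any(theta <= 0 | theta > 1)) stop("'theta' must lie in (0, 1]")
  d1 <- pgf_unchecked(dist, theta, 1L)
  if (any(d1 <= 0))
    stop("psi'(theta) = 0: degenerate distribution at this theta")
  theta * pgf_unchecked(dist, theta, 2L) / d1
}

#' Mean degree of a distribution
#' @param dist a [degree_dist()] object.
#' @export
mean_degree <- function(dist) pgf(dist, 1, order = 1L)

# Tabulate a distribution's pmf; parametric tails truncated at the smallest
# k with cumulative mass >= 1 - tol (used for sampling and classification).
tabulate_pmf <- function(dist, tol = 1e-12) {
  p <- dist$params
  switch(dist$family,
    poisson = {
      kmax <- stats::qpois(tol, p$lambda, lower.tail = FALSE) + 2L
      list(degrees = 0:kmax, probs = stats::dpois(0:kmax, p$lambda))
    },
    binomial = list(degrees = 0:p$n, probs = stats::dbinom(0:p$n, p$n, p$p)),
    regular = list(degrees = p$n, probs = 1),
    negative_binomial = {
      kmax <- stats::qnbinom(tol, size = p$r, prob = 1 - p$p,
                             lower.tail = FALSE) + 2L
      list(degrees = 0:kmax,
           probs = stats::dnbinom(0:kmax, size = p$r, prob = 1 - p$p))
    },
    tabulated = list(degrees = p$degrees, probs = p$probs)
  )
}

# i.i.d. degree draws
sample_degrees <- function(dist, n) {
  p <- dist$params
  switch(dist$family,
    poisson = stats::rpois(n, p$lambda),
    binomial = stats::rbinom(n, p$n, p$p),
    regular = rep.int(p$n, n),
    negative_binomial = stats::rnbinom(n, size = p$r, prob = 1 - p$p),
    tabulated = sample(p$degrees, n, replace = TRUE, prob = p$probs)
  )
}

#' @export
print.degree_dist <- function(x, ...) {
  ps <- paste(names(x$params), vapply(x$params, function(v)
    paste(format(v, digits = 6), collapse = ","), ""), sep = " = ",
    collapse = ", ")
  if (x$family == "tabulated")
    ps <- paste0(length(x$params$degrees), " support points, mean degree ",
                 format(mean_degree(x), digits = 6))
  cat("Degree distribution: ", x$family, " (", ps, ")\n", sep = "")
  invisible(x)
}

#' Read a degree distribution from a JSON or CSV file
#'
#' JSON files hold `{"family": "...", "params": {...}}` (tabulated families
#' use `degrees` and `probs` arrays inside `params`).  CSV files need the
#' header `degree,probability` and describe a tabulated pmf.
#'
#' @param path file path; format chosen by extension.
#' @return A [degree_dist()] object.
#' @export
read_degree_dist <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(degree_dist, c(list(family = obj$family), as.list(obj$params)))
  } else {
    df <- utils::read.csv(path, comment.char = "#")
    if (!all(c("degree", "probability") %in% names(df)))
      stop("CSV degree file needs columns 'degree' and 'probability'")
    degree_dist("tabulated", degrees = df$degree, probs = df$probability)
  }
}

#' Write a degree distribution to a JSON or CSV file
#' @param dist a [degree_dist()] object.
#' @param path output path; `.json` or `.csv`.
#' @export
write_degree_dist <- function(dist, path) {
  stopifnot(inherits(dist, "degree_dist"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(family = dist$family, params = dist$params),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    tab <- tabulate_pmf(dist)
    utils::write.csv(data.frame(degree = tab$degrees,
                                probability = format(tab$probs, digits = 17)),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
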