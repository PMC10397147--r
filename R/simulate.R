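#' Build a configuration model network
#'
#' Draws i.i.d. degrees from `dist` (resampling one uniformly chosen node's
#' degree until the stub total is even), then matches half-edges (stubs)
#' uniformly at random.  The default is a pure multigraph — self-loops and
#' multi-edges are kept, matching the uniform-matching assumption of the
#' mean-field theory.  In `simple = TRUE` mode, offending edges are erased
#' and their stubs re-matched among themselves repeatedly until the graph is
#' simple (bounded retries); the distortion is O(1/N).
#'
#' @param dist a [degree_dist()] object.
#' @param n_nodes number of nodes (at least 2).
#' @param seed optional integer seed (set locally).
#' @param simple erase-and-rewire self-loops and multi-edges?
#' @param max_retries rewiring budget for simple mode.
#' @return An object of class `"sir_network"`: `n_nodes`, `edges` (2-column
#'   matrix of node ids), `degrees` (drawn degree sequence).
#' @export
sample_network <- function(dist, n_nodes, seed = NULL, simple = FALSE,
                           max_retries = 200L) {
  stopifnot(inherits(dist, "degree_dist"), n_nodes >= 2)
  if (!is.null(seed)) set.seed(seed)
  deg <- sample_degrees(dist, n_nodes)
  tries <- 0L
  while (sum(deg) %% 2L == 1L) {
    i <- sample.int(n_nodes, 1L)
    deg[i] <- sample_degrees(dist, 1L)
    tries <- tries + 1L
    if (tries > 1000L)
      stop("cannot repair odd stub total by degree resampling")
  }
  stubs <- rep.int(seq_len(n_nodes), deg)
  perm <- sample(stubs)
  edges <- matrix(perm, ncol = 2L)
  if (simple) {
    for (it in seq_len(max_retries)) {
      key <- pmin(edges[, 1], edges[, 2]) * (n_nodes + 1) +
        pmax(edges[, 1], edges[, 2])
      bad <- edges[, 1] == edges[, 2] | key %in% key[duplicated(key)]
      if (!any(bad)) break
      loose <- c(edges[bad, 1], edges[bad, 2])
      edges[bad, ] <- matrix(sample(loose), ncol = 2L)
      if (it == max_retries)
        stop("simple-graph rewiring failed after ", max_retries, " retries")
    }
  }
  structure(list(n_nodes = n_nodes, edges = edges, degrees = deg,
                 simple = simple),
            class = "sir_network")
}

#' Wrap an explicit edge list as a network
#'
#' For simulating on empirical or hand-built graphs rather than sampled
#' configuration models.
#'
#' @param edges two-column matrix of node ids in `1..n_nodes` (undirected;
#'   one row per edge, multi-edges allowed).
#' @param n_nodes number of nodes.
#' @return A `"sir_network"` object.
#' @export
sir_network <- function(edges, n_nodes) {
  edges <- as.matrix(edges)
  stopifnot(ncol(edges) == 2, all(edges >= 1), all(edges <= n_nodes),
            all(edges == round(edges)))
  storage.mode(edges) <- "integer"
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n_nodes)
  structure(list(n_nodes = as.integer(n_nodes), edges = edges,
                 degrees = deg, simple = !any(edges[, 1] == edges[, 2])),
            class = "sir_network")
}

#' @export
print.sir_network <- function(x, ...) {
  cat("Configuration model network: ", x$n_nodes, " nodes, ",
      nrow(x$edges), " edges (", if (x$simple) "simple" else "multigraph",
      "), mean degree ", format(mean(x$degrees), digits = 5), "\n", sep = "")
  invisible(x)
}

#' Write a network as an edge-list TSV
#' @param net a `"sir_network"` object.
#' @param path output path; two tab-separated columns of 0-based node ids.
#' @export
write_edgelist <- function(net, path) {
  utils::write.table(net$edges - 1L, path, sep = "\t", row.names = FALSE,
                     col.names = c("node_a", "node_b"), quote = FALSE)
  invisible(path)
}

# adjacency list with edge multiplicity, self-loops dropped (they cannot
# transmit); nodes of degree zero get integer(0)
adjacency_list <- function(net) {
  e <- net$edges
  keep <- e[, 1] != e[, 2]
  from <- c(e[keep, 1], e[keep, 2])
  to <- c(e[keep, 2], e[keep, 1])
  unname(split(to, factor(from, levels = seq_len(net$n_nodes))))
}

#' Simulate an exact stochastic SIR epidemic on a network
#'
#' Continuous-time Markov SIR: each infected node draws an infectious period
#' from `Exp(gamma)`, and while infectious makes contacts along each incident
#' edge according to an independent Poisson process with intensity `beta`;
#' a contacted susceptible becomes infectious instantly.  The realization is
#' generated by the percolation-style shortest-path construction (each
#' directed edge carries an `Exp(beta)` first-contact time, censored at the
#' infector's recovery), which is equivalent in law to event-driven Gillespie
#' simulation and yields per-node infection times directly.
#'
#' @param net a [sample_network()] object.
#' @param beta per-edge transmission rate.
#' @param gamma recovery rate (`0` means no recovery).
#' @param m number of initially infectious nodes, chosen uniformly at random
#'   without replacement; alternatively a vector of node ids via
#'   `init_nodes`.
#' @param seed optional integer seed.
#' @param init_nodes explicit initial infectious node ids (overrides `m`).
#' @return An object of class `"sir_sim"`: `infection_times` and
#'   `recovery_times` (per node, `NA` if never infected), `seeds`, `counts`
#'   (step-function data frame `time, S, I, R`), `final_size` (total ever
#'   infected, including the seeds).
#' @export
simulate_sir <- function(net, beta, gamma, m = 1L, seed = NULL,
                         init_nodes = NULL) {
  stopifnot(inherits(net, "sir_network"), beta >= 0, gamma >= 0)
  if (!is.null(seed)) set.seed(seed)
  N <- net$n_nodes
  if (is.null(init_nodes)) {
    stopifnot(m >= 1, m < N)
    init_nodes <- sample.int(N, m)
  }
  adj <- adjacency_list(net)
  period <- if (gamma > 0) stats::rexp(N, gamma) else rep(Inf, N)
  inf_t <- rep(Inf, N)
  inf_t[init_nodes] <- 0
  tent <- inf_t                       # tentative times; processed set to Inf
  done <- rep(FALSE, N)
  if (beta > 0) {
    repeat {
      u <- which.min(tent)
      if (!is.finite(tent[u])) break
      tent[u] <- Inf
      done[u] <- TRUE
      nb <- adj[[u]]
      if (length(nb)) {
        x <- stats::rexp(length(nb), beta)
        ok <- x < period[u] & !done[nb]
        if (any(ok)) {
          cand <- inf_t[u] + x[ok]
          vs <- nb[ok]
          for (j in seq_along(vs)) {    # duplicates possible (multi-edges)
            v <- vs[j]
            if (cand[j] < inf_t[v]) {
              inf_t[v] <- cand[j]
              tent[v] <- cand[j]
            }
          }
        }
      }
    }
  }
  infected <- is.finite(inf_t)
  rec_t <- rep(NA_real_, N)
  rec_t[infected] <- inf_t[infected] + period[infected]
  inf_times <- ifelse(infected, inf_t, NA_real_)
  # step-function counts at event times
  ev_t <- c(inf_t[infected], rec_t[infected & is.finite(rec_t)])
  ev_d <- c(rep(1L, sum(infected)),
            rep(2L, sum(infected & is.finite(rec_t))))
  o <- order(ev_t)
  ev_t <- ev_t[o]; ev_d <- ev_d[o]
  n_inf <- cumsum(ev_d == 1L)
  n_rec <- cumsum(ev_d == 2L)
  counts <- data.frame(time = ev_t, S = N - n_inf, I = n_inf - n_rec,
                       R = n_rec)
  structure(list(infection_times = inf_times, recovery_times = rec_t,
                 seeds = init_nodes, counts = counts,
                 final_size = sum(infected), n_nodes = N,
                 beta = beta, gamma = gamma),
            class = "sir_sim")
}

#' @export
print.sir_sim <- function(x, ...) {
  cat("Stochastic SIR realization: N = ", x$n_nodes, ", ",
      length(x$seeds), " seeds, final size ", x$final_size,
      " (", format(100 * x$final_size / x$n_nodes, digits = 4),
      "% attack rate)\n", sep = "")
  invisible(x)
}

#' Write the event log of a simulation as CSV
#' @param sim a `"sir_sim"` object.
#' @param path output CSV (`time,node,event`), 0-based node ids.
#' @export
write_events <- function(sim, path) {
  inf <- which(is.finite(sim$infection_times))
  rec <- which(is.finite(sim$recovery_times))
  df <- data.frame(
    time = c(sim$infection_times[inf], sim$recovery_times[rec]),
    node = c(inf, rec) - 1L,
    event = c(rep("infection", length(inf)), rep("recovery", length(rec))))
  df <- df[order(df$time), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# evaluate a run's S/I/R fractions on a time grid
counts_on_grid <- function(sim, grid) {
  inf <- sort(sim$infection_times[is.finite(sim$infection_times)])
  rec <- sort(sim$recovery_times[is.finite(sim$recovery_times)])
  n_inf <- findInterval(grid, inf)
  n_rec <- findInterval(grid, rec)
  N <- sim$n_nodes
  cbind(S = (N - n_inf) / N, I = (n_inf - n_rec) / N, R = n_rec / N)
}

#' Run an ensemble of stochastic epidemics
#'
#' Simulates `n_runs` epidemics on each of `n_networks` independent network
#' realizations, retains runs whose epidemic reaches `retain_threshold`
#' infections (cumulative by default, concurrent prevalence with
#' `retain_on = "prevalence"`), and averages the retained step functions on
#' a common time grid without re-alignment.  A master seed spawns recorded
#' per-network and per-run seeds.
#'
#' @param dist a [degree_dist()] object.
#' @param n_nodes nodes per network realization.
#' @param params an [epi_params()] bundle; `m = round(rho * n_nodes)` initial
#'   infectious nodes are drawn uniformly at random.
#' @param n_networks,n_runs ensemble dimensions.
#' @param retain_threshold minimum infection count for a run to be retained.
#' @param time_grid grid on which step functions are evaluated and averaged.
#' @param seed master seed.
#' @param retain_on `"cumulative"` (ever-infected, including seeds) or
#'   `"prevalence"` (maximum concurrent infected).
#' @param simple build simple graphs instead of multigraphs?
#' @return An object of class `"sir_ensemble"`: `time`, `mean_S`, `mean_I`,
#'   `mean_R` (fractions, averaged over retained runs), `runs_I` (matrix of
#'   per-retained-run prevalence), `n_retained`, `n_total`, `seeds`.
#' @export
run_ensemble <- function(dist, n_nodes, params, n_networks = 5L,
                         n_runs = 5L, retain_threshold = NULL,
                         time_grid = seq(0, 15, by = 0.1), seed = NULL,
                         retain_on = c("cumulative", "prevalence"),
                         simple = FALSE) {
  stopifnot(inherits(dist, "degree_dist"), inherits(params, "epi_params"))
  retain_on <- match.arg(retain_on)
  if (!is.null(seed)) set.seed(seed)
  m <- max(1L, round(params$rho * n_nodes))
  if (is.null(retain_threshold)) retain_threshold <- m
  stopifnot(retain_threshold >= m)
  net_seeds <- sample.int(.Machine$integer.max - 1L, n_networks)
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 n_networks * n_runs),
                      nrow = n_networks)
  acc <- array(0, dim = c(length(time_grid), 3L))
  runs_I <- NULL
  n_ret <- 0L
  for (i in seq_len(n_networks)) {
    net <- sample_network(dist, n_nodes, seed = net_seeds[i],
                          simple = simple)
    for (j in seq_len(n_runs)) {
      sim <- simulate_sir(net, params$beta, params$gamma, m = m,
                          seed = run_seeds[i, j])
      size <- if (retain_on == "cumulative") sim$final_size
              else max(sim$counts$I)
      if (size >= retain_threshold) {
        g <- counts_on_grid(sim, time_grid)
        acc <- acc + g
        runs_I <- cbind(runs_I, g[, "I"])
        n_ret <- n_ret + 1L
      }
    }
  }
  if (n_ret == 0L)
    stop("empty ensemble: no run reached the retention threshold of ",
         retain_threshold)
  mean_sir <- acc / n_ret
  structure(list(time = time_grid, mean_S = mean_sir[, 1],
                 mean_I = mean_sir[, 2], mean_R = mean_sir[, 3],
                 runs_I = runs_I, n_retained = n_ret,
                 n_total = n_networks * n_runs,
                 retention = n_ret / (n_networks * n_runs),
                 net_seeds = net_seeds, run_seeds = run_seeds,
                 m = m, retain_threshold = retain_threshold,
                 retain_on = retain_on),
            class = "sir_ensemble")
}

#' @export
print.sir_ensemble <- function(x, ...) {
  cat("SIR ensemble: ", x$n_retained, "/", x$n_total,
      " runs retained (threshold ", x$retain_threshold, " ", x$retain_on,
      "), peak mean prevalence ", format(max(x$mean_I), digits = 5),
      "\n", sep = "")
  invisible(x)
}

#' Write an ensemble summary as CSV
#' @param ens a `"sir_ensemble"` object.
#' @param path output CSV (`time,mean_S,mean_I,mean_R,n_retained`).
#' @export
write_ensemble <- function(ens, path) {
  utils::write.csv(data.frame(time = ens$time, mean_S = ens$mean_S,
                              mean_I = ens$mean_I, mean_R = ens$mean_R,
                              n_retained = ens$n_retained),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
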