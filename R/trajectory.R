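#' @title Trajectory container for mean-field solutions
#' @description Internal constructor: a time grid plus named state columns,
#'   tagged with the model that produced them.
#' @keywords internal
new_sir_trajectory <- function(times, states, model, params, dist,
                               extra = list()) {
  stopifnot(length(times) == nrow(states))
  structure(c(list(times = times, states = as.data.frame(states),
                   model = model, params = params, dist = dist), extra),
            class = "sir_trajectory")
}

# negative excursions beyond -1e-9 indicate solver failure; smaller ones are
# rounding and are clipped for reporting only
check_nonneg <- function(states, tol = 1e-9) {
  m <- as.matrix(states)
  if (any(m < -tol))
    stop("solver produced state values below -", format(tol),
         " (min ", format(min(m)), "); integration failed")
  invisible(states)
}

#' @export
print.sir_trajectory <- function(x, ...) {
  cat("SIR mean-field trajectory (", x$model, " model)\n", sep = "")
  cat("  time: [", min(x$times), ", ", max(x$times), "], ",
      length(x$times), " points\n", sep = "")
  cat("  columns:", paste(names(x$states), collapse = ", "), "\n")
  final <- round(utils::tail(as.matrix(x$states), 1), 6)
  cat("  final state:", paste(colnames(final), final[1, ], sep = " = ",
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.sir_trajectory <- function(x, ...) {
  cbind(data.frame(time = x$times), x$states)
}

#' @export
plot.sir_trajectory <- function(x, columns = NULL, ...) {
  df <- x$states
  if (is.null(columns))
    columns <- intersect(c("x_S", "x_I", "x_R", "S", "I", "R"), names(df))
  if (length(columns) == 0) columns <- names(df)
  graphics::matplot(x$times, as.matrix(df[columns]), type = "l", lty = 1,
                    xlab = "time", ylab = "state",
                    main = paste(x$model, "model"), ...)
  graphics::legend("right", legend = columns, lty = 1,
                   col = seq_along(columns))
  invisible(x)
}

#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' The CSV holds `time` plus the state columns at 17 significant digits (so
#' round-trips are lossless); `<path>.json` records the model tag, the
#' epidemic parameters, the degree distribution and solver settings.
#'
#' @param traj a trajectory from [solve_volz()], [solve_dsa()] or
#'   [solve_pairwise()].
#' @param path CSV output path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sir_trajectory"))
  df <- as.data.frame(traj)
  df[] <- lapply(df, function(v) format(v, digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(model = traj$model,
               params = unclass(traj$params),
               dist = if (!is.null(traj$dist))
                 list(family = traj$dist$family, params = traj$dist$params),
               kappa = traj$kappa,
               solver = traj$solver)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#' @param path CSV path; the `<path>.json` sidecar is read when present.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  new_sir_trajectory(df$time, df[setdiff(names(df), "time")],
                     model = if (!is.null(meta$model)) meta$model else "unknown",
                     params = meta$params, dist = NULL,
                     extra = list(kappa = meta$kappa, solver = meta$solver))
}
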