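# Integration engine and trajectory analytics.
#
# The ODE systems are smooth except at therapy starts and gate on-times;
# integration is restarted at every such time so the adaptive solver never
# steps across a jump in the right-hand side.

POPULATIONS <- c("N", "T", "T_R", "T_M")
TUMOR_POPULATIONS <- c("T", "T_M", "T_R") # fixed order, also the tie-break

# validation-free concentration, called inside the solver loop
raw_conc <- function(t, sched) {
  if (t < sched$t_start) return(0)
  clock <- if (sched$decay_from_start) t - sched$t_start else t
  sched$C0 * exp(-sched$decay_rate * clock)
}

raw_rhs_intrinsic <- function(t, y, p, drug) {
  C <- raw_conc(t, drug)
  resp <- 1 - exp(-drug$M * C)
  tot <- y[[1L]] + y[[2L]]
  c(p$r_T * y[[1L]] * (1 - tot / p$K_T) - p$tau * y[[1L]] -
      drug$kill_T * resp * y[[1L]],
    p$r_R * y[[2L]] * (1 - tot / p$K_R) + p$tau * y[[1L]],
    p$r_N * y[[3L]] * (1 - y[[3L]] / p$K_N) +
      p$kappa * tot * (1 - tot / p$T_star) - drug$kill_N * resp * y[[3L]])
}

raw_rhs_extended <- function(t, y, p, drug1, drug2, gates) {
  C1 <- raw_conc(t, drug1)
  C2 <- raw_conc(t, drug2)
  resp1 <- 1 - exp(-drug1$M * C1)
  resp2 <- 1 - exp(-drug2$M * C2)
  g1 <- as.numeric(t >= gates$t_tau1_on)
  g2 <- as.numeric(t >= gates$t_tau2_on)
  gc <- as.numeric(t >= gates$t_conv_on)
  tot <- y[[1L]] + y[[2L]] + y[[3L]]
  conv <- gc * p$tau_MR * resp1 * y[[3L]]
  c(p$r_T * y[[1L]] * (1 - tot / p$K_T) -
      (g1 * p$tau1 + g2 * p$tau2) * y[[1L]] -
      drug1$kill_T * resp1 * y[[1L]],
    p$r_R * y[[2L]] * (1 - tot / p$K_R) + g1 * p$tau1 * y[[1L]] + conv -
      drug2$kill_TR * resp2 * y[[2L]],
    p$r_M * y[[3L]] * (1 - tot / p$K_M) + g2 * p$tau2 * y[[1L]] -
      drug1$kill_TM * resp1 * y[[3L]] - conv,
    p$r_N * y[[4L]] * (1 - y[[4L]] / p$K_N) +
      p$kappa * tot * (1 - tot / p$T_star) - drug1$kill_N * resp1 * y[[4L]])
}

#' Construct a trajectory
#'
#' A trajectory is a data frame with columns `time`, `N`, `T`, `T_R`,
#' `T_M` (days and cells) plus a `meta` attribute describing its origin.
#' [integrate_scenario()] returns one; this constructor lets the
#' analytics ([first_crossing_time()], [analyze_trajectory()], ...) be
#' applied to externally produced time series as well.
#'
#' @param times strictly increasing, non-negative time grid (days).
#' @param states data frame or matrix of non-negative counts with columns
#'   among `N`, `T`, `T_R`, `T_M`; absent columns are filled with 0.
#' @param meta named list of free-form metadata (scenario name, solver
#'   settings, ...).
#' @return An object of class `trajectory` (also a data frame).
#' @export
trajectory <- function(times, states, meta = list()) {
  check_num(times, "times", 0, len = length(times))
  if (length(times) < 1L) stop_field("times", "must be non-empty")
  if (any(diff(times) <= 0)) stop_field("times", "must be strictly increasing")
  states <- as.data.frame(states)
  if (nrow(states) != length(times)) {
    stop_field("states", "must have one row per time point")
  }
  extra <- setdiff(names(states), POPULATIONS)
  if (length(extra)) stop_field("states", paste("unknown column", extra[1]))
  for (pop in setdiff(POPULATIONS, names(states))) states[[pop]] <- 0
  for (pop in POPULATIONS) {
    check_num(states[[pop]], pop, 0, len = nrow(states))
  }
  out <- cbind(data.frame(time = as.numeric(times)), states[POPULATIONS])
  structure(out, meta = meta, class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<trajectory> %d points, t in [%g, %g] days\n",
              nrow(x), x$time[1], x$time[nrow(x)]))
  if (!is.null(meta$scenario)) cat("  scenario:", meta$scenario, "\n")
  if (!is.null(meta$model)) cat("  model:", meta$model, "\n")
  f <- x[nrow(x), ]
  cat(sprintf("  final state: N=%.4g T=%.4g T_R=%.4g T_M=%.4g cells\n",
              f$N, f$T, f$T_R, f$T_M))
  invisible(x)
}

#' Integrate a scenario
#'
#' Runs the model named in the scenario (`"intrinsic"` or `"extended"`)
#' from its initial state to the horizon with an adaptive-step solver
#' (`deSolve`, lsoda by default). Integration is restarted at every
#' discontinuity of the right-hand side (therapy starts and gate
#' on-times) and the solution is reported on a dense regular grid.
#' Tiny negative excursions produced by the solver are clamped to 0 in
#' the returned trajectory only; the state fed back to the solver is
#' left untouched.
#'
#' @param spec a [scenario_spec()] (or [scenario_preset()] output).
#' @param grid_dt dense output spacing in days (default 0.5).
#' @param rtol,atol solver relative / absolute tolerances (defaults 1e-8
#'   and 1e-6 cells).
#' @param method `deSolve` integration method.
#' @param clamp clamp negative output values to 0 (default TRUE).
#' @return A [trajectory()].
#' @export
integrate_scenario <- function(spec, grid_dt = 0.5, rtol = 1e-8, atol = 1e-6,
                               method = "lsoda", clamp = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"))
  check_num(grid_dt, "grid_dt", 0, strict = TRUE)
  horizon <- spec$horizon
  grid <- seq(0, horizon, by = grid_dt)
  if (max(grid) < horizon - 1e-9) grid <- c(grid, horizon)

  breaks <- c(spec$drug1$t_start, spec$drug2$t_start,
              spec$gates$t_tau2_on, spec$gates$t_conv_on,
              spec$gates$t_tau1_on)
  breaks <- sort(unique(breaks[breaks > 1e-9 & breaks < horizon - 1e-9]))
  bounds <- c(0, breaks, horizon)

  s0 <- spec$initial_state
  intrinsic <- identical(spec$model, "intrinsic")
  if (intrinsic) {
    if (s0$T_M != 0) {
      stop("the intrinsic model has no T_M compartment; T_M(0) must be 0",
           call. = FALSE)
    }
    y <- c(T = s0$T, T_R = s0$T_R, N = s0$N)
    func <- function(t, y, parms) {
      list(raw_rhs_intrinsic(t, y, spec$params, spec$drug1))
    }
  } else {
    y <- c(T = s0$T, T_R = s0$T_R, T_M = s0$T_M, N = s0$N)
    func <- function(t, y, parms) {
      list(raw_rhs_extended(t, y, spec$params, spec$drug1, spec$drug2,
                            spec$gates))
    }
  }

  res <- matrix(NA_real_, nrow = length(grid), ncol = length(y),
                dimnames = list(NULL, names(y)))
  res[1L, ] <- y
  keyed <- function(x) round(x, 9)
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i]
    hi <- bounds[i + 1L]
    gsel <- which(grid > lo + 1e-9 & grid <= hi + 1e-9)
    times <- c(lo, grid[gsel], hi)
    times <- times[!duplicated(keyed(times))]
    sol <- deSolve::ode(y = y, times = times, func = func, parms = NULL,
                        method = method, rtol = rtol, atol = atol,
                        tcrit = hi) # never step internally across the jump
    bad <- !stats::complete.cases(sol) | apply(!is.finite(sol), 1L, any)
    if (any(bad)) {
      last_good <- if (all(bad)) lo else max(sol[!bad, 1L])
      stop(sprintf("solver failure: non-finite state; last good time %g days",
                   last_good), call. = FALSE)
    }
    y <- sol[nrow(sol), -1L]
    if (length(gsel)) {
      res[gsel, ] <- sol[match(keyed(grid[gsel]), keyed(sol[, 1L])), -1L,
                         drop = FALSE]
    }
  }
  if (clamp) res[res < 0] <- 0
  states <- as.data.frame(res)
  if (intrinsic) states$T_M <- 0
  trajectory(grid, states,
             meta = list(scenario = spec$name, model = spec$model,
                         grid_dt = grid_dt, rtol = rtol, atol = atol,
                         method = method, clamp = clamp))
}

match_population <- function(population, allowed = POPULATIONS) {
  if (!is.character(population) || length(population) != 1L ||
      !(population %in% allowed)) {
    stop("unknown population label; valid labels: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  population
}

#' Earliest threshold-crossing (detection) time
#'
#' Earliest time at which a population rises to at least `threshold`
#' cells, located by linear interpolation between the bracketing grid
#' points. The default threshold of 2e5 cells is the burden treated as
#' clinically detectable.
#'
#' @param traj a [trajectory()].
#' @param population one of `"N"`, `"T"`, `"T_R"`, `"T_M"`.
#' @param threshold detection threshold in cells (> 0).
#' @return Crossing time in days, or `NA_real_` if never reached.
#' @export
first_crossing_time <- function(traj, population, threshold = 2e5) {
  stopifnot(inherits(traj, "trajectory"))
  check_num(threshold, "threshold", 0, strict = TRUE)
  y <- traj[[match_population(population)]]
  i <- which(y >= threshold)[1L]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(traj$time[1L])
  t0 <- traj$time[i - 1L]
  t1 <- traj$time[i]
  y0 <- y[i - 1L]
  y1 <- y[i]
  t0 + (threshold - y0) / (y1 - y0) * (t1 - t0)
}

#' Extinction (die-out) time
#'
#' Earliest time after which the population stays below `eps` cells for
#' the rest of the horizon, located by linear interpolation at the last
#' downward crossing. With the default `eps = 1`, "extinct" means the
#' deterministic count has fallen below a single cell.
#'
#' @inheritParams first_crossing_time
#' @param eps extinction level in cells (> 0), default 1.
#' @return Time in days (the start of the grid if the population never
#'   reaches `eps`), or `NA_real_` if the population is at or above
#'   `eps` at the end of the horizon.
#' @export
extinction_time <- function(traj, population, eps = 1) {
  stopifnot(inherits(traj, "trajectory"))
  check_num(eps, "eps", 0, strict = TRUE)
  y <- traj[[match_population(population)]]
  n <- length(y)
  if (y[n] >= eps) return(NA_real_)
  above <- which(y >= eps)
  if (!length(above)) return(traj$time[1L])
  j <- max(above) # y[j] >= eps, y[j+1..n] < eps
  t0 <- traj$time[j]
  t1 <- traj$time[j + 1L]
  t0 + (y[j] - eps) / (y[j] - y[j + 1L]) * (t1 - t0)
}

#' Dominant tumor population at a time point
#'
#' The largest of the tumor compartments `T`, `T_M`, `T_R` at the grid
#' point nearest `t` (normal cells are excluded). Ties are broken in the
#' fixed order `T` > `T_M` > `T_R`.
#'
#' @inheritParams first_crossing_time
#' @param t time in days; must lie within the simulated horizon.
#' @return One of `"T"`, `"T_M"`, `"T_R"`, or `NA_character_` when all
#'   tumor populations are 0 at that point.
#' @export
dominant_population <- function(traj, t) {
  stopifnot(inherits(traj, "trajectory"))
  check_num(t, "t")
  if (t < traj$time[1L] - 1e-9 || t > traj$time[nrow(traj)] + 1e-9) {
    stop(sprintf("t = %g is outside the simulated horizon [%g, %g]",
                 t, traj$time[1L], traj$time[nrow(traj)]), call. = FALSE)
  }
  i <- which.min(abs(traj$time - t))
  vals <- vapply(TUMOR_POPULATIONS, function(p) traj[[p]][i], numeric(1))
  if (all(vals == 0)) return(NA_character_)
  TUMOR_POPULATIONS[which.max(vals)] # which.max keeps the fixed tie order
}

#' Trajectory analytics report
#'
#' Bundles the detection time ([first_crossing_time()]) and extinction
#' time ([extinction_time()]) of every population, the dominant tumor
#' population at the end of the horizon ([dominant_population()]), and
#' the final state.
#'
#' @inheritParams first_crossing_time
#' @inheritParams extinction_time
#' @return An object of class `analytics_report`: a list with elements
#'   `detection_time`, `extinction_time` (named numeric vectors over
#'   `N`, `T`, `T_R`, `T_M`, `NA` where the event never happens),
#'   `dominant`, `final_state`, `threshold`, `eps`, `horizon`.
#' @export
analyze_trajectory <- function(traj, threshold = 2e5, eps = 1) {
  stopifnot(inherits(traj, "trajectory"))
  det <- vapply(POPULATIONS, function(p) {
    first_crossing_time(traj, p, threshold)
  }, numeric(1))
  ext <- vapply(POPULATIONS, function(p) {
    extinction_time(traj, p, eps)
  }, numeric(1))
  n <- nrow(traj)
  final <- population_state(N = traj$N[n], T = traj$T[n],
                            T_R = traj$T_R[n], T_M = traj$T_M[n])
  structure(list(detection_time = det,
                 extinction_time = ext,
                 dominant = dominant_population(traj, traj$time[n]),
                 final_state = final,
                 threshold = threshold, eps = eps,
                 horizon = traj$time[n]),
            class = "analytics_report")
}

#' @export
print.analytics_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "-", sprintf("%.1f", v))
  cat(sprintf("<analytics_report>  horizon %g days, threshold %g cells, eps %g\n",
              x$horizon, x$threshold, x$eps))
  cat("  detection  (d):", paste(names(x$detection_time),
                                 fmt(x$detection_time), sep = "=", collapse = "  "), "\n")
  cat("  extinction (d):", paste(names(x$extinction_time),
                                 fmt(x$extinction_time), sep = "=", collapse = "  "), "\n")
  cat("  dominant tumor population:",
      if (is.na(x$dominant)) "none" else x$dominant, "\n")
  print(x$final_state)
  invisible(x)
}
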