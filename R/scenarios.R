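# Treatment scenarios: spec container, the four presets, end-to-end runs,
# and initial-condition calibration.

#' Assemble a runnable scenario
#'
#' A complete experiment: model variant, parameters, drug schedules,
#' gates, initial state, horizon and analytic thresholds.
#'
#' @param name identifier used in outputs and plots.
#' @param model `"extended"` (wild, mutated, resistant and normal cells)
#'   or `"intrinsic"` (no mutated compartment).
#' @param params a [model_params()].
#' @param drug1 a [drug_schedule()] for the drug acting on responsive
#'   cells (and normal tissue).
#' @param drug2 a [drug_schedule()] for the drug acting on resistant
#'   cells; `NULL` for an inactive schedule (no combination therapy).
#' @param gates a [gate_times()].
#' @param initial_state a [population_state()].
#' @param horizon simulation length in days; must exceed every start and
#'   gate time.
#' @param detection_threshold cells treated as clinically detectable
#'   (default 2e5).
#' @param extinction_eps cells below which a population counts as died
#'   out (default 1).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = "custom",
                          model = c("extended", "intrinsic"),
                          params = model_params(),
                          drug1 = drug_schedule(),
                          drug2 = NULL,
                          gates = gate_times(),
                          initial_state = population_state(N = 1e6, T = 1e4),
                          horizon = 500,
                          detection_threshold = 2e5,
                          extinction_eps = 1) {
  model <- match.arg(model)
  if (is.null(drug2)) drug2 <- drug_schedule()
  stopifnot(inherits(params, "model_params"),
            inherits(drug1, "drug_schedule"),
            inherits(drug2, "drug_schedule"),
            inherits(gates, "gate_times"),
            inherits(initial_state, "population_state"))
  check_num(horizon, "horizon", 0, strict = TRUE)
  check_num(detection_threshold, "detection_threshold", 0, strict = TRUE)
  check_num(extinction_eps, "extinction_eps", 0, strict = TRUE)
  tmax <- max(drug1$t_start, drug2$t_start, gates$t_tau1_on,
              gates$t_tau2_on, gates$t_conv_on)
  if (horizon <= tmax) {
    stop_field("horizon", sprintf(
      "must exceed every therapy start and gate time (max %g days)", tmax))
  }
  structure(list(name = as.character(name)[1], model = model, params = params,
                 drug1 = drug1, drug2 = drug2, gates = gates,
                 initial_state = initial_state, horizon = horizon,
                 detection_threshold = detection_threshold,
                 extinction_eps = extinction_eps),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> \"%s\" (%s model), horizon %g days\n",
              x$name, x$model, x$horizon))
  cat(sprintf("  detection threshold %g cells, extinction eps %g cells\n",
              x$detection_threshold, x$extinction_eps))
  cat(sprintf("  gates (d): tau1 on %g, tau2 on %g, conversion on %g\n",
              x$gates$t_tau1_on, x$gates$t_tau2_on, x$gates$t_conv_on))
  cat("  drug1: "); print(x$drug1)
  cat("  drug2: "); print(x$drug2)
  print(x$initial_state)
  invisible(x)
}

#' The four preset treatment scenarios
#'
#' All presets share the growth parameters (`K` = 1e6 cells for all four
#' compartments, `r_T = r_R = r_M` = 0.25 /day, `r_N` = 0.5 /day,
#' `kappa` = 0.0124 /day, `T*` = 3e5 cells), drug-1 settings
#' (`a_T = a_TM = a_N` = 0.15 /day, `M` = 1, start day 50), the
#' wild-to-mutated mutation `tau2` = 1e-3 /day active from day 0 and the
#' conversion rate `tau_MR` = 1e-4 /day. They differ in the drug-1
#' profile, the conversion on-time, and the presence of intrinsic
#' resistance plus a second drug:
#'
#' * `"a"` — constant drug C = 0.2, conversion gated on at day 50;
#' * `"b"` — constant drug, conversion delayed to day 150;
#' * `"c"` — decaying drug C = 0.2 exp(-0.001 t), conversion at day 50;
#' * `"d"` — decaying drug 1 as in `"c"`, intrinsic mutation
#'   `tau1` = 1e-4 /day, plus a constant second drug C2 = 0.6 from day 50
#'   killing resistant cells at `a_TR` = 0.15 /day.
#'
#' Initial conditions (not part of the published parameter set) default
#' to `N(0)` = K_N, `T(0)` = 1e4, `T_R(0) = T_M(0)` = 0; see
#' [calibrate_initial_conditions()].
#'
#' @param name one of `"a"`, `"b"`, `"c"`, `"d"`.
#' @return A [scenario_spec()].
#' @examples
#' scenario_preset("a")$drug1$C0
#' @export
scenario_preset <- function(name) {
  valid <- c("a", "b", "c", "d")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop("unknown scenario preset; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  params <- model_params(r_N = 0.5, r_T = 0.25, r_R = 0.25, r_M = 0.25,
                         K_N = 1e6, K_T = 1e6, K_R = 1e6, K_M = 1e6,
                         kappa = 0.0124, T_star = 3e5,
                         tau1 = if (name == "d") 1e-4 else 0,
                         tau2 = 1e-3, tau_MR = 1e-4)
  drug1 <- drug_schedule(C0 = 0.2, t_start = 50,
                         decay_rate = if (name %in% c("c", "d")) 1e-3 else 0,
                         M = 1, kill_N = 0.15, kill_T = 0.15, kill_TM = 0.15)
  drug2 <- if (name == "d") {
    drug_schedule(C0 = 0.6, t_start = 50, decay_rate = 0, M = 1,
                  kill_TR = 0.15)
  } else {
    drug_schedule()
  }
  gates <- gate_times(t_tau2_on = 0,
                      t_conv_on = if (name == "b") 150 else 50,
                      t_tau1_on = 0)
  scenario_spec(name = name, model = "extended", params = params,
                drug1 = drug1, drug2 = drug2, gates = gates,
                initial_state = population_state(N = 1e6, T = 1e4),
                horizon = 500, detection_threshold = 2e5,
                extinction_eps = 1)
}

#' Run a scenario end to end
#'
#' Integrates the scenario to its horizon and attaches the trajectory
#' analytics. The model is deterministic: two runs of the same spec are
#' identical.
#'
#' @param spec a [scenario_spec()].
#' @param ... passed to [integrate_scenario()] (solver settings).
#' @return An object of class `scenario_result`: a list with `spec`,
#'   `trajectory`, `report`.
#' @export
run_scenario <- function(spec, ...) {
  stopifnot(inherits(spec, "scenario_spec"))
  traj <- integrate_scenario(spec, ...)
  report <- analyze_trajectory(traj, threshold = spec$detection_threshold,
                               eps = spec$extinction_eps)
  structure(list(spec = spec, trajectory = traj, report = report),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> scenario \"%s\"\n", x$spec$name))
  print(x$trajectory)
  print(x$report)
  invisible(x)
}

#' Calibrate the initial wild-tumor count against a detection time
#'
#' The published parameter set leaves the initial populations free. This
#' routine fixes them by bisecting on `T(0)` until the first
#' threshold-crossing time of the chosen population matches a target
#' detection time. Crossing times are monotone in `T(0)` (a larger
#' inoculum is detected no later), so bisection applies; a run in which
#' the threshold is never reached counts as an infinite crossing time.
#'
#' If the crossing time does not bracket the target across `bracket` —
#' in particular when it is insensitive to `T(0)`, which happens
#' whenever the wild population saturates long before detection and the
#' downstream compartments are slaved to it — a calibration-failure
#' error (condition class `resistsim_calibration_error`) is raised
#' rather than returning a spurious fit.
#'
#' @param target_detection_time target crossing time in days.
#' @param spec a [scenario_spec()]; its other initial conditions are
#'   held fixed.
#' @param free_variable the initial condition to vary; only `"T0"` is
#'   supported.
#' @param bracket length-2 positive interval of `T(0)` values (cells).
#' @param population population whose crossing is matched (default
#'   `"T_R"`, the resistant clone).
#' @param tol_days accept when the achieved crossing time is within this
#'   many days of the target (default 1).
#' @param tol_rel stop refining once the bracket's relative width falls
#'   below this (default 1e-6, i.e. `T(0)` resolved far below 1%).
#' @param ... passed to [integrate_scenario()].
#' @return The calibrated [population_state()], with attributes `T0`,
#'   `achieved_detection_time` and `iterations`.
#' @export
calibrate_initial_conditions <- function(target_detection_time, spec,
                                         free_variable = "T0",
                                         bracket = c(1, spec$params$K_T),
                                         population = "T_R",
                                         tol_days = 1, tol_rel = 1e-6, ...) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!identical(free_variable, "T0")) {
    stop("only free_variable = \"T0\" is supported", call. = FALSE)
  }
  check_num(target_detection_time, "target_detection_time", 0, strict = TRUE)
  check_num(bracket, "bracket", 0, strict = TRUE, len = 2L)
  if (bracket[1] >= bracket[2]) stop_field("bracket", "must be increasing")
  population <- match_population(population)

  state_at <- function(T0) {
    population_state(N = spec$initial_state$N, T = T0,
                     T_R = spec$initial_state$T_R,
                     T_M = spec$initial_state$T_M)
  }
  n_eval <- 0L
  f <- function(T0) {
    s <- spec
    s$initial_state <- state_at(T0)
    n_eval <<- n_eval + 1L
    ct <- first_crossing_time(integrate_scenario(s, ...), population,
                              spec$detection_threshold)
    if (is.na(ct)) Inf else ct
  }

  fail <- function(msg) {
    stop(structure(class = c("resistsim_calibration_error", "error",
                             "condition"),
                   list(message = paste0("calibration failure: ", msg),
                        call = NULL)))
  }

  lo <- bracket[1]; hi <- bracket[2]
  glo <- f(lo) - target_detection_time
  ghi <- f(hi) - target_detection_time
  if (glo == 0 || ghi == 0) {
    root <- if (glo == 0) lo else hi
  } else if (sign(glo) == sign(ghi)) {
    fail(sprintf(
      "no sign change in bracket [%g, %g]: crossing time - target is %s at both ends",
      lo, hi, paste(signif(c(glo, ghi), 4), collapse = " and ")))
  } else {
    # bisect in log space: T(0) candidates span orders of magnitude
    repeat {
      mid <- sqrt(lo * hi)
      gm <- f(mid) - target_detection_time
      if (gm == 0) { lo <- hi <- mid; break }
      if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else { hi <- mid }
      if ((hi - lo) / hi < tol_rel) break
    }
    root <- sqrt(lo * hi)
  }
  achieved <- f(root)
  if (!is.finite(achieved) ||
      abs(achieved - target_detection_time) > tol_days) {
    fail(sprintf(
      "best T0 = %g gives crossing at %g days, more than %g day(s) from target %g",
      root, achieved, tol_days, target_detection_time))
  }
  out <- state_at(root)
  attr(out, "T0") <- root
  attr(out, "achieved_detection_time") <- achieved
  attr(out, "iterations") <- n_eval
  out
}
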