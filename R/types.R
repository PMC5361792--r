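# Domain types: light S3 records with validation at construction time.
# All counts are cells, all rates day^-1, concentrations mg.m^-2.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_num <- function(x, field, lower = -Inf, strict = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len) {
    stop_field(field, sprintf("must be numeric of length %d", len))
  }
  if (any(!is.finite(x))) stop_field(field, "must be finite (no NA/NaN/Inf)")
  if (strict) {
    if (any(x <= lower)) stop_field(field, sprintf("must be > %g", lower))
  } else if (any(x < lower)) {
    stop_field(field, sprintf("must be >= %g", lower))
  }
  x
}

#' Instantaneous cell counts
#'
#' The state evolved by the model equations: normal cells `N`, wild
#' (drug-responsive) tumor cells `T`, drug-resistant tumor cells `T_R`,
#' and mutated tumor cells `T_M`. In the intrinsic model `T_M` is fixed
#' at zero.
#'
#' @param N,T,T_R,T_M non-negative, finite cell counts.
#' @return An object of class `population_state` (a named list).
#' @examples
#' population_state(N = 1e6, T = 1e4)
#' @export
population_state <- function(N, T, T_R = 0, T_M = 0) {
  out <- list(
    N   = check_num(N, "N", 0),
    T   = check_num(T, "T", 0),
    T_R = check_num(T_R, "T_R", 0),
    T_M = check_num(T_M, "T_M", 0)
  )
  structure(out, class = "population_state")
}

#' Growth, coupling and transition parameters
#'
#' All symbols of both model variants in one record.
#'
#' @param r_N,r_T,r_R,r_M per-capita logistic growth rates (day^-1) of
#'   normal, wild, resistant and mutated cells.
#' @param K_N,K_T,K_R,K_M carrying capacities (cells); the three tumor
#'   compartments compete against a shared total in each logistic factor.
#' @param kappa tumor-to-normal coupling rate (day^-1).
#' @param T_star critical tumor size (cells) at which the coupling term
#'   changes sign.
#' @param tau intrinsic mutation rate of the intrinsic model (day^-1).
#' @param tau1 wild-to-resistant transition rate, extended model (day^-1).
#' @param tau2 wild-to-mutated transition rate, extended model (day^-1).
#' @param tau_MR mutated-to-resistant conversion rate (day^-1); acts only
#'   in proportion to the drug response `1 - exp(-M * C)`.
#' @return An object of class `model_params`.
#' @export
model_params <- function(r_N = 0.5, r_T = 0.25, r_R = 0.25, r_M = 0.25,
                         K_N = 1e6, K_T = 1e6, K_R = 1e6, K_M = 1e6,
                         kappa = 0.0124, T_star = 3e5,
                         tau = 0, tau1 = 0, tau2 = 0, tau_MR = 0) {
  out <- list(
    r_N = check_num(r_N, "r_N", 0), r_T = check_num(r_T, "r_T", 0),
    r_R = check_num(r_R, "r_R", 0), r_M = check_num(r_M, "r_M", 0),
    K_N = check_num(K_N, "K_N", 0, strict = TRUE),
    K_T = check_num(K_T, "K_T", 0, strict = TRUE),
    K_R = check_num(K_R, "K_R", 0, strict = TRUE),
    K_M = check_num(K_M, "K_M", 0, strict = TRUE),
    kappa = check_num(kappa, "kappa", 0),
    T_star = check_num(T_star, "T_star", 0, strict = TRUE),
    tau = check_num(tau, "tau", 0),
    tau1 = check_num(tau1, "tau1", 0),
    tau2 = check_num(tau2, "tau2", 0),
    tau_MR = check_num(tau_MR, "tau_MR", 0)
  )
  structure(out, class = "model_params")
}

#' One drug's dosing rule and kill coefficients
#'
#' Concentration at the tumor site is 0 before `t_start`; afterwards it is
#' `C0` (when `decay_rate = 0`) or decays exponentially. By default the
#' decay clock is absolute simulation time (matching the printed schedule
#' `C0 * exp(-decay_rate * t)`); set `decay_from_start = TRUE` to count
#' the decay from `t_start` instead.
#'
#' @param C0 initial/plateau concentration (mg.m^-2).
#' @param t_start therapy start time (days).
#' @param decay_rate exponential decay constant (day^-1); 0 for a constant
#'   drug.
#' @param M drug efficiency coefficient (m^2.mg^-1) inside the saturating
#'   response `1 - exp(-M * C)`.
#' @param kill_N,kill_T,kill_TM,kill_TR per-population induced-death
#'   coefficients (day^-1); leave at 0 for populations the drug does not
#'   touch.
#' @param decay_from_start logical; see Description.
#' @return An object of class `drug_schedule`.
#' @export
drug_schedule <- function(C0 = 0, t_start = 0, decay_rate = 0, M = 1,
                          kill_N = 0, kill_T = 0, kill_TM = 0, kill_TR = 0,
                          decay_from_start = FALSE) {
  if (!is.logical(decay_from_start) || length(decay_from_start) != 1L ||
      is.na(decay_from_start)) {
    stop_field("decay_from_start", "must be TRUE or FALSE")
  }
  out <- list(
    C0 = check_num(C0, "C0", 0),
    t_start = check_num(t_start, "t_start", 0),
    decay_rate = check_num(decay_rate, "decay_rate", 0),
    M = check_num(M, "M", 0),
    kill_N = check_num(kill_N, "kill_N", 0),
    kill_T = check_num(kill_T, "kill_T", 0),
    kill_TM = check_num(kill_TM, "kill_TM", 0),
    kill_TR = check_num(kill_TR, "kill_TR", 0),
    decay_from_start = decay_from_start
  )
  structure(out, class = "drug_schedule")
}

#' On-times of the gated transition terms
#'
#' Each transition term of the extended model is multiplied by a hard 0/1
#' step that switches on at the stated time: `t_tau2_on` for the
#' wild-to-mutated mutation, `t_conv_on` for the mutated-to-resistant
#' conversion, `t_tau1_on` for the intrinsic wild-to-resistant mutation.
#'
#' @param t_tau2_on,t_conv_on,t_tau1_on on-times in days (>= 0).
#' @return An object of class `gate_times`.
#' @export
gate_times <- function(t_tau2_on = 0, t_conv_on = 0, t_tau1_on = 0) {
  out <- list(
    t_tau2_on = check_num(t_tau2_on, "t_tau2_on", 0),
    t_conv_on = check_num(t_conv_on, "t_conv_on", 0),
    t_tau1_on = check_num(t_tau1_on, "t_tau1_on", 0)
  )
  structure(out, class = "gate_times")
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state>  (cells)\n")
  cat(sprintf("  N = %g, T = %g, T_R = %g, T_M = %g\n", x$N, x$T, x$T_R, x$T_M))
  invisible(x)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  growth r (day^-1): N=%g T=%g R=%g M=%g\n", x$r_N, x$r_T, x$r_R, x$r_M))
  cat(sprintf("  capacity K (cells): N=%g T=%g R=%g M=%g\n", x$K_N, x$K_T, x$K_R, x$K_M))
  cat(sprintf("  coupling: kappa=%g day^-1, T*=%g cells\n", x$kappa, x$T_star))
  cat(sprintf("  transitions (day^-1): tau=%g tau1=%g tau2=%g tau_MR=%g\n",
              x$tau, x$tau1, x$tau2, x$tau_MR))
  invisible(x)
}

#' @export
print.drug_schedule <- function(x, ...) {
  prof <- if (x$C0 == 0) "inactive" else if (x$decay_rate == 0) {
    sprintf("constant C = %g mg.m^-2", x$C0)
  } else {
    sprintf("C = %g * exp(-%g t) mg.m^-2%s", x$C0, x$decay_rate,
            if (x$decay_from_start) " (clock from t_start)" else "")
  }
  cat("<drug_schedule> ", prof, sprintf(", start t = %g d\n", x$t_start), sep = "")
  cat(sprintf("  M = %g m^2.mg^-1; kill (day^-1): N=%g T=%g TM=%g TR=%g\n",
              x$M, x$kill_N, x$kill_T, x$kill_TM, x$kill_TR))
  invisible(x)
}

as_population_state <- function(x) {
  if (inherits(x, "population_state")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    x <- as.list(x)
  }
  if (is.list(x) && all(c("N", "T") %in% names(x))) {
    return(population_state(N = x$N, T = x$T,
                            T_R = if (is.null(x$T_R)) 0 else x$T_R,
                            T_M = if (is.null(x$T_M)) 0 else x$T_M))
  }
  stop("cannot interpret `state`: need a population_state or a named ",
       "list/vector with at least N and T", call. = FALSE)
}
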