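# Right-hand sides of the two model variants, term by term.

#' Pharmacodynamic kill rate
#'
#' Saturating response to a chemotherapeutic drug: `a * (1 - exp(-M * C))`.
#' The rate is 0 with no drug and approaches the death coefficient `a` as
#' the concentration grows, so `a` is the maximal induced per-capita death
#' rate.
#'
#' @param a induced-death coefficient (day^-1).
#' @param M drug efficiency coefficient (m^2.mg^-1).
#' @param C drug concentration at the tumor site (mg.m^-2).
#' @return Per-day kill rate in `[0, a]`. Vectorised over `C`.
#' @examples
#' kill_rate(0.15, 1, 0.2)
#' @export
kill_rate <- function(a, M, C) {
  check_num(a, "a", 0)
  check_num(M, "M", 0)
  check_num(C, "C", 0, len = length(C))
  a * (1 - exp(-M * C))
}

#' Tumor-to-normal coupling term
#'
#' `kappa * T_total * (1 - T_total / T_star)`: small tumor burdens
#' stimulate normal-cell growth, burdens above the critical size `T_star`
#' suppress it (the term goes negative by design).
#'
#' @param T_total total tumor burden `T + T_R + T_M` (cells).
#' @param kappa coupling rate (day^-1).
#' @param T_star critical tumor size (cells), > 0.
#' @return Contribution to dN/dt (cells.day^-1).
#' @export
coupling_term <- function(T_total, kappa, T_star) {
  check_num(T_total, "T_total", 0, len = length(T_total))
  check_num(kappa, "kappa", 0)
  check_num(T_star, "T_star", 0, strict = TRUE)
  kappa * T_total * (1 - T_total / T_star)
}

#' Time derivatives of the intrinsic-resistance model
#'
#' Wild tumor cells `T` grow logistically against the shared burden
#' `T + T_R`, lose cells to intrinsic mutation (`tau`) and to the drug;
#' resistant cells `T_R` grow logistically and gain the mutants; normal
#' cells `N` grow logistically, are coupled to the tumor burden and are
#' killed by the drug.
#'
#' @param t time (days).
#' @param state a [population_state()] (or named list/vector with `N`,
#'   `T`, `T_R`); `T_M` is ignored (fixed at 0 in this model).
#' @param params a [model_params()]; uses `tau` as the mutation rate.
#' @param drug a [drug_schedule()] for the single drug (kills `T` via
#'   `kill_T` and `N` via `kill_N`).
#' @param conc_fn concentration function `f(t, sched)`; defaults to
#'   [concentration()].
#' @return Named numeric vector of derivatives `c(T=, T_R=, N=)`
#'   (cells.day^-1).
#' @export
rhs_intrinsic <- function(t, state, params, drug, conc_fn = concentration) {
  s <- as_population_state(state)
  C <- conc_fn(t, drug)
  tot <- s$T + s$T_R
  dT <- params$r_T * s$T * (1 - tot / params$K_T) -
    params$tau * s$T - kill_rate(drug$kill_T, drug$M, C) * s$T
  dT_R <- params$r_R * s$T_R * (1 - tot / params$K_R) + params$tau * s$T
  dN <- params$r_N * s$N * (1 - s$N / params$K_N) +
    coupling_term(tot, params$kappa, params$T_star) -
    kill_rate(drug$kill_N, drug$M, C) * s$N
  c(T = dT, T_R = dT_R, N = dN)
}

#' Time derivatives of the extended (drug-induced resistance) model
#'
#' Adds the mutated compartment `T_M`: wild cells transition to resistant
#' (`tau1`) and mutated (`tau2`) cells; mutated cells are partially killed
#' by drug 1 and partially converted to resistant cells at rate
#' `tau_MR * (1 - exp(-M * C1))`; resistant cells are only touched by the
#' second drug. Each transition term is multiplied by a hard 0/1 gate that
#' switches on at the time given in `gates`.
#'
#' @inheritParams rhs_intrinsic
#' @param state a [population_state()] (or named list/vector with `N`,
#'   `T`, `T_R`, `T_M`).
#' @param drug1 [drug_schedule()] of the drug acting on `T`, `T_M`, `N`
#'   (and driving the conversion).
#' @param drug2 [drug_schedule()] of the drug acting on `T_R`; pass an
#'   all-zero schedule when there is no combination therapy.
#' @param gates a [gate_times()].
#' @return Named numeric vector `c(T=, T_R=, T_M=, N=)` (cells.day^-1).
#' @export
rhs_extended <- function(t, state, params, drug1, drug2, gates,
                         conc_fn = concentration) {
  s <- as_population_state(state)
  C1 <- conc_fn(t, drug1)
  C2 <- conc_fn(t, drug2)
  g1 <- gate(t, gates$t_tau1_on)
  g2 <- gate(t, gates$t_tau2_on)
  gc <- gate(t, gates$t_conv_on)
  tot <- s$T + s$T_R + s$T_M
  conv <- gc * params$tau_MR * (1 - exp(-drug1$M * C1)) * s$T_M

  dT <- params$r_T * s$T * (1 - tot / params$K_T) -
    g1 * params$tau1 * s$T - g2 * params$tau2 * s$T -
    kill_rate(drug1$kill_T, drug1$M, C1) * s$T
  dT_R <- params$r_R * s$T_R * (1 - tot / params$K_R) +
    g1 * params$tau1 * s$T + conv -
    kill_rate(drug2$kill_TR, drug2$M, C2) * s$T_R
  dT_M <- params$r_M * s$T_M * (1 - tot / params$K_M) +
    g2 * params$tau2 * s$T -
    kill_rate(drug1$kill_TM, drug1$M, C1) * s$T_M - conv
  dN <- params$r_N * s$N * (1 - s$N / params$K_N) +
    coupling_term(tot, params$kappa, params$T_star) -
    kill_rate(drug1$kill_N, drug1$M, C1) * s$N
  c(T = dT, T_R = dT_R, T_M = dT_M, N = dN)
}
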