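# Small scenario builders shared across tests. Everything is generated in
# code; no stored fixtures.

# single logistic population: only wild tumor cells, no drug, no
# transitions, no coupling
logistic_spec <- function(T0 = 1e4, r = 0.25, K = 1e6, horizon = 200) {
  scenario_spec(
    name = "logistic",
    model = "extended",
    params = model_params(r_T = r, K_T = K, r_N = 0, kappa = 0,
                          tau1 = 0, tau2 = 0, tau_MR = 0),
    drug1 = drug_schedule(),
    gates = gate_times(),
    initial_state = population_state(N = 0, T = T0),
    horizon = horizon
  )
}

logistic_closed_form <- function(t, T0, r = 0.25, K = 1e6) {
  K * T0 * exp(r * t) / (K + T0 * (exp(r * t) - 1))
}

# wild-tumor-only subsystem under a single drug of plateau C0
wild_drug_spec <- function(C0, horizon = 200) {
  scenario_spec(
    name = sprintf("wild_C0_%g", C0),
    model = "extended",
    params = model_params(r_T = 0.25, K_T = 1e6, r_N = 0, kappa = 0),
    drug1 = drug_schedule(C0 = C0, t_start = 50, M = 1, kill_T = 0.15),
    initial_state = population_state(N = 0, T = 1e4),
    horizon = horizon
  )
}

# draws a random admissible state/parameter pair (used by property tests)
random_case <- function() {
  list(
    state = population_state(N = runif(1, 0, 1e6), T = runif(1, 0, 1e6),
                             T_R = runif(1, 0, 1e6), T_M = runif(1, 0, 1e6)),
    params = model_params(r_N = runif(1, 0, 1), r_T = runif(1, 0, 1),
                          r_R = runif(1, 0, 1), r_M = runif(1, 0, 1),
                          K_N = 10^runif(1, 5, 7), K_T = 10^runif(1, 5, 7),
                          K_R = 10^runif(1, 5, 7), K_M = 10^runif(1, 5, 7),
                          kappa = runif(1, 0, 0.1), T_star = 10^runif(1, 4, 6),
                          tau = runif(1, 0, 1e-3), tau1 = runif(1, 0, 1e-3),
                          tau2 = runif(1, 0, 1e-3), tau_MR = runif(1, 0, 1e-3)),
    drug1 = drug_schedule(C0 = runif(1, 0, 1), t_start = runif(1, 0, 100),
                          decay_rate = runif(1, 0, 0.01), M = runif(1, 0.5, 2),
                          kill_N = runif(1, 0, 0.3), kill_T = runif(1, 0, 0.3),
                          kill_TM = runif(1, 0, 0.3)),
    drug2 = drug_schedule(C0 = runif(1, 0, 1), t_start = runif(1, 0, 100),
                          M = runif(1, 0.5, 2), kill_TR = runif(1, 0, 0.3)),
    gates = gate_times(t_tau1_on = runif(1, 0, 100),
                       t_tau2_on = runif(1, 0, 100),
                       t_conv_on = runif(1, 0, 100)),
    t = runif(1, 0, 200)
  )
}
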