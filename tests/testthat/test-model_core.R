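test_that("kill rate follows the saturating response a*(1 - exp(-M*C))", {
  expect_identical(kill_rate(0.15, 1, 0), 0)
  # saturation limit equals the death coefficient
  expect_equal(kill_rate(0.15, 1, 1e6), 0.15, tolerance = 1e-12)
  # closed-form evaluation
  expect_equal(kill_rate(0.15, 1, 0.2), 0.15 * (1 - exp(-0.2)),
               tolerance = 1e-15)
  # monotone non-decreasing in C and bounded by a over a grid
  C <- seq(0, 10, by = 0.05)
  k <- kill_rate(0.15, 1, C)
  expect_true(all(diff(k) > 0))
  expect_true(all(k >= 0 & k <= 0.15))
  expect_error(kill_rate(-0.1, 1, 0.2), "a")
  expect_error(kill_rate(0.15, -1, 0.2), "M")
  expect_error(kill_rate(0.15, 1, -0.2), "C")
})

test_that("coupling term vanishes at 0 and at the critical size", {
  expect_identical(coupling_term(0, 0.0124, 3e5), 0)
  expect_equal(coupling_term(3e5, 0.0124, 3e5), 0, tolerance = 1e-12)
  # substitute T_total = T*/2
  expect_equal(coupling_term(1.5e5, 0.0124, 3e5), 0.0124 * 3e5 / 4,
               tolerance = 1e-12)
  # suppression above the critical size, by design
  expect_lt(coupling_term(6e5, 0.0124, 3e5), 0)
  expect_error(coupling_term(1e5, 0.0124, 0), "T_star")
  expect_error(coupling_term(-1, 0.0124, 3e5), "T_total")
})

test_that("domain types reject invalid fields by name", {
  expect_error(population_state(N = -1, T = 0), "N")
  expect_error(population_state(N = 0, T = NaN), "T")
  expect_error(model_params(r_T = -0.1), "r_T")
  expect_error(model_params(K_T = 0), "K_T")
  expect_error(model_params(T_star = -3e5), "T_star")
  expect_error(drug_schedule(C0 = -0.2), "C0")
  expect_error(drug_schedule(decay_rate = -1e-3), "decay_rate")
  expect_error(gate_times(t_conv_on = -50), "t_conv_on")
})

test_that("intrinsic right-hand side: fixed points and a hand evaluation", {
  p <- model_params(tau = 0)
  d0 <- drug_schedule()
  zero <- population_state(N = 0, T = 0)
  expect_equal(unname(rhs_intrinsic(0, zero, p, d0)), c(0, 0, 0))
  # logistic equilibrium of the wild population
  eq <- population_state(N = 0, T = p$K_T)
  expect_equal(rhs_intrinsic(0, eq, p, d0)[["T"]], 0, tolerance = 1e-12)
  # dT_R/dt = tau * T when T_R = 0: 1e-4 * 1e5 = 10 cells/day
  p2 <- model_params(tau = 1e-4)
  s <- population_state(N = 0, T = 1e5)
  expect_equal(rhs_intrinsic(0, s, p2, d0)[["T_R"]], 10, tolerance = 1e-12)
})

test_that("extended model reduces to the intrinsic model without the mutated pathway", {
  set.seed(42)
  d2_inert <- drug_schedule()
  g0 <- gate_times()
  for (i in 1:100) {
    cs <- random_case()
    p <- cs$params
    p$tau1 <- p$tau      # same wild -> resistant rate
    p$tau2 <- 0
    p$tau_MR <- 0
    s <- cs$state
    s$T_M <- 0
    de <- rhs_extended(cs$t, s, p, cs$drug1, d2_inert, g0)
    di <- rhs_intrinsic(cs$t, s, p, cs$drug1)
    expect_equal(de[["T"]], di[["T"]], tolerance = 1e-12)
    expect_equal(de[["T_R"]], di[["T_R"]], tolerance = 1e-12)
    expect_equal(de[["N"]], di[["N"]], tolerance = 1e-12)
    expect_identical(de[["T_M"]], 0)
  }
})

test_that("no flow out of an empty compartment", {
  set.seed(1)
  for (i in 1:50) {
    cs <- random_case()
    for (pop in c("T", "T_R", "T_M")) {
      s <- cs$state
      s[[pop]] <- 0
      d <- rhs_extended(cs$t, s, cs$params, cs$drug1, cs$drug2, cs$gates)
      expect_gte(d[[pop]], 0)
    }
    # for normal cells the guarantee holds while the tumor burden is at or
    # below the critical size (beyond it the coupling term is suppressive)
    s <- cs$state
    s$N <- 0
    shrink <- cs$params$T_star / max(s$T + s$T_R + s$T_M, 1)
    s$T <- s$T * shrink * 0.3
    s$T_R <- s$T_R * shrink * 0.3
    s$T_M <- s$T_M * shrink * 0.3
    d <- rhs_extended(cs$t, s, cs$params, cs$drug1, cs$drug2, cs$gates)
    expect_gte(d[["N"]], 0)
  }
})

test_that("solver-facing right-hand sides agree with the exported ones", {
  set.seed(7)
  for (i in 1:20) {
    cs <- random_case()
    s <- cs$state
    ye <- c(s$T, s$T_R, s$T_M, s$N)
    raw <- resistsim:::raw_rhs_extended(cs$t, ye, cs$params, cs$drug1,
                                        cs$drug2, cs$gates)
    pub <- rhs_extended(cs$t, s, cs$params, cs$drug1, cs$drug2, cs$gates)
    expect_equal(raw, unname(pub[c("T", "T_R", "T_M", "N")]),
                 tolerance = 1e-14)
    yi <- c(s$T, s$T_R, s$N)
    rawi <- resistsim:::raw_rhs_intrinsic(cs$t, yi, cs$params, cs$drug1)
    pubi <- rhs_intrinsic(cs$t, s, cs$params, cs$drug1)
    expect_equal(rawi, unname(pubi[c("T", "T_R", "N")]), tolerance = 1e-14)
  }
})

test_that("extended logistic equilibrium is a fixed point of the wild compartment", {
  p <- model_params(tau1 = 0, tau2 = 0, tau_MR = 0)
  s <- population_state(N = 0, T = 1e6)
  d <- rhs_extended(0, s, p, drug_schedule(), drug_schedule(), gate_times())
  expect_equal(d[["T"]], 0, tolerance = 1e-12)
})
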