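test_that("gate steady state follows the Boltzmann form", {
  expect_equal(gate_steady_state(-47.1, -47.1, -3.1), 0.5)
  expect_equal(gate_steady_state(-40 + (-6), -40, -6), 1 / (1 + exp(1)),
               tolerance = 1e-12)
  expect_equal(gate_steady_state(-35 + 7, -35, 7), 1 / (1 + exp(1)),
               tolerance = 1e-12)
  # activation gate (k < 0) closes with hyperpolarization
  expect_lt(gate_steady_state(-1e3, -40, -6), 1e-10)
  expect_gt(gate_steady_state(50, -40, -6), 1 - 1e-6)
  # monotonicity, direction set by the sign of k
  v <- seq(-80, 0, by = 0.5)
  expect_true(all(diff(gate_steady_state(v, -40, -6)) > 0))
  expect_true(all(diff(gate_steady_state(v, -40, 6)) < 0))
  expect_error(gate_steady_state(-50, -40, 0), "nonzero")
})

test_that("membrane parameter invariants are enforced", {
  expect_s3_class(membrane_parameters(), "membrane_parameters")
  expect_error(membrane_parameters(g_Na = -1), "conductances")
  expect_error(membrane_parameters(E_K = -60), "E_K < E_L")
  expect_error(membrane_parameters(E_synI = -50), "E_synI")
  bad_gates <- membrane_parameters()$gates
  bad_gates$h_NaP[["tau_max"]] <- 100      # far below 100x C/g_L
  expect_error(membrane_parameters(gates = bad_gates), "100-fold")
  # slow inactivation must exceed the membrane time constant 100-fold
  p <- membrane_parameters()
  expect_gte(p$gates$h_NaP[["tau_max"]], 100 * p$C / p$g_L)
})

test_that("leak-only neuron relaxes exponentially toward E_L", {
  p <- membrane_parameters(g_Na = 0, g_NaP = 0, g_K = 0)
  EL <- -64
  sim <- simulate_neuron(p, EL, duration = 100, dt = 0.1, V_init = -50,
                         record_V = TRUE, record_dt = 1)
  expected <- EL + (-50 - EL) * exp(-sim$V_time * p$g_L / p$C)
  expect_equal(sim$V, expected, tolerance = 1e-8)
  expect_length(sim$spike_times, 0)
})

test_that("pure-R neuron_step agrees with the compiled engine", {
  p <- membrane_parameters()
  EL <- -66
  dt <- 0.1
  sim <- simulate_neuron(p, EL, duration = 300, dt = dt, V_init = -55,
                         record_V = TRUE, record_dt = 1)
  st <- membrane_state(p, V = -55)
  vr <- numeric(300)
  for (i in seq_len(3000)) {
    st <- neuron_step(st, p, E_L_effective = EL, dt = dt)
    if (i %% 10 == 0) vr[i / 10] <- st$V
  }
  # engine interpolates tabulated gate curves; sub-0.1 mV agreement expected
  expect_lt(max(abs(vr - sim$V[-1])), 0.1)
})

test_that("fixed-step trajectories converge to the adaptive reference", {
  skip_if_not_installed("deSolve")
  p <- membrane_parameters()
  EL <- -68                        # subthreshold nonlinear relaxation
  V0 <- -55
  ref <- reference_trajectory(p, EL, V0, times = c(0, 1000))
  v_ref <- ref[2, 2]
  errs <- vapply(c(0.2, 0.1, 0.05, 0.025), function(dt) {
    sim <- simulate_neuron(p, EL, duration = 1000, dt = dt, V_init = V0,
                           record_V = TRUE, record_dt = 1000)
    abs(sim$V[length(sim$V)] - v_ref)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("burst period matches the adaptive reference within 2 percent", {
  skip_if_not_installed("deSolve")
  p <- membrane_parameters()
  EL <- -63
  V0 <- -63
  ref <- reference_trajectory(p, EL, V0, times = seq(0, 20000, by = 0.25),
                              rtol = 1e-9, atol = 1e-9)
  ref_on <- reference_burst_onsets(ref)
  ref_on <- ref_on[ref_on > 3000]
  expect_gte(length(ref_on), 3)
  ref_period <- mean(diff(ref_on))

  sim <- simulate_neuron(p, EL, duration = 20000, dt = 0.05, V_init = V0)
  st <- sim$spike_times[sim$spike_times > 3000]
  on <- st[c(TRUE, diff(st) > 500)]
  expect_gte(length(on), 3)
  period <- mean(diff(on))
  expect_lt(abs(period - ref_period) / ref_period, 0.02)
})

test_that("single-neuron regimes partition the leak-reversal axis", {
  p <- membrane_parameters()
  expect_identical(single_neuron_regime(p, -70), "silence")
  expect_identical(single_neuron_regime(p, -63), "bursting")
  expect_identical(single_neuron_regime(p, -55, T = 20000), "tonic")
  labels <- vapply(seq(-70, -52, by = 2), function(EL)
    single_neuron_regime(p, EL, T = 20000), character(1))
  runs <- rle(labels)$values
  expect_identical(runs, c("silence", "bursting", "tonic"))
})

test_that("without persistent sodium the neuron never bursts", {
  p <- membrane_parameters(g_NaP = 0)
  labels <- vapply(c(-70, -60, -50, -44, -40), function(EL)
    single_neuron_regime(p, EL, T = 20000), character(1))
  expect_false(any(labels == "bursting"))
  expect_true("silence" %in% labels)
  expect_true("tonic" %in% labels)
})

test_that("observation window too short for regime classification errors", {
  p <- membrane_parameters()
  expect_error(single_neuron_regime(p, -63, T = 5000), "insufficient")
})
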