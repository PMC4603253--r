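# Independent adaptive reference integration of the single-neuron equations
# (deSolve::lsoda on the closed-form rate functions; no lookup tables, no
# fixed step).  Used as the oracle for the compiled fixed-step engine.

neuron_ode <- function(params, E_L_effective) {
  g <- params$gates
  ss <- function(V, gate) gate_steady_state(V, g[[gate]][["V_half"]],
                                            g[[gate]][["k"]])
  tf <- function(V, gate) gate_time_constant(
    V, g[[gate]][["V_half"]], spinalcpg:::gate_tau_k(g[[gate]]),
    g[[gate]][["tau_max"]])
  function(t, y, parms) {
    V <- y[1]; hNa <- y[2]; nK <- y[3]; hNaP <- y[4]
    mNa <- ss(V, "m_Na"); mNaP <- ss(V, "m_NaP")
    gNa <- params$g_Na * mNa^3 * hNa
    gNaP <- params$g_NaP * mNaP * hNaP
    gK <- params$g_K * nK^4
    I <- gNa * (V - params$E_Na) + gNaP * (V - params$E_Na) +
      gK * (V - params$E_K) + params$g_L * (V - E_L_effective)
    list(c(-I / params$C,
           (ss(V, "h_Na") - hNa) / tf(V, "h_Na"),
           (ss(V, "n_K") - nK) / tf(V, "n_K"),
           (ss(V, "h_NaP") - hNaP) / tf(V, "h_NaP")))
  }
}

reference_trajectory <- function(params, E_L_effective, V0, times,
                                 rtol = 1e-10, atol = 1e-10) {
  g <- params$gates
  y0 <- c(V0,
          gate_steady_state(V0, g$h_Na[["V_half"]], g$h_Na[["k"]]),
          gate_steady_state(V0, g$n_K[["V_half"]], g$n_K[["k"]]),
          gate_steady_state(V0, g$h_NaP[["V_half"]], g$h_NaP[["k"]]))
  deSolve::lsoda(y0, times, neuron_ode(params, E_L_effective), NULL,
                 rtol = rtol, atol = atol)
}

# burst onsets of a reference voltage trajectory: upward -10 mV crossings,
# grouped into bursts by gaps > gap_ms
reference_burst_onsets <- function(traj, gap_ms = 500) {
  V <- traj[, 2]; t <- traj[, 1]
  up <- which(V[-1] >= -10 & V[-length(V)] < -10)
  st <- t[up + 1]
  if (length(st) == 0) return(numeric(0))
  st[c(TRUE, diff(st) > gap_ms)]
}
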