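#' Membrane parameters for a conductance-based CPG neuron
#'
#' Constructs and validates the parameter set of a single Hodgkin-Huxley
#' style neuron with fast sodium (instantaneous activation \code{m_Na},
#' inactivation \code{h_Na}), delayed-rectifier potassium (\code{n_K}),
#' persistent sodium with slow inactivation (\code{m_NaP} instantaneous,
#' \code{h_NaP} slow), leak, and conductance-based synapses.  Gate steady
#' states are sigmoids \code{1/(1+exp((V-V_half)/k))} and the
#' voltage-dependent time constants are
#' \code{tau_max/cosh((V-V_half)/(2k))}.
#'
#' The slow persistent-sodium inactivation variable \code{h_NaP} is the burst
#' terminating variable: its time-constant scale must exceed the membrane
#' time constant \code{C/g_L} at least 100-fold.
#'
#' @param C membrane capacitance (pF).
#' @param g_Na,g_NaP,g_K,g_L maximal conductances (nS).  Set
#'   \code{g_NaP = 0} for non-rhythmogenic (relay) neurons.
#' @param E_Na,E_K,E_L reversal potentials (mV); \code{E_L} is the baseline
#'   leak reversal, modulated per neuron by the drive protocol.
#' @param E_synE,E_synI synaptic reversal potentials (mV).
#' @param gates named list with one entry per gate (\code{m_Na}, \code{h_Na},
#'   \code{n_K}, \code{m_NaP}, \code{h_NaP}), each a numeric vector
#'   \code{c(V_half, k, tau_max)} in mV, mV, ms.  Activation gates have
#'   negative slope \code{k}; instantaneous gates ignore \code{tau_max}.
#' @param V_th spike-detection threshold (mV).
#' @param tau_E,tau_I synaptic decay time constants (ms).
#' @param refractory refractory gate on spike detection (ms).
#' @return An object of class \code{membrane_parameters}.
#' @examples
#' p <- membrane_parameters()            # rhythmogenic defaults
#' r <- membrane_parameters(g_NaP = 0)   # relay neuron
#' @export
membrane_parameters <- function(C = 20,
                                g_Na = 28, g_NaP = 2.8, g_K = 11.2, g_L = 2.8,
                                E_Na = 50, E_K = -85, E_L = -64,
                                E_synE = -10, E_synI = -80,
                                gates = list(
                                  m_Na  = c(V_half = -34.0, k = -5.0, tau_max = 0),
                                  h_Na  = c(V_half = -29.0, k = 4.0, tau_max = 15),
                                  n_K   = c(V_half = -29.0, k = -4.0, tau_max = 10),
                                  m_NaP = c(V_half = -45.0, k = -6.0, tau_max = 0),
                                  h_NaP = c(V_half = -53.0, k = 8.0, tau_max = 2500)
                                ),
                                V_th = -10, tau_E = 5, tau_I = 15,
                                refractory = 1.5) {
  p <- list(C = C, g_Na = g_Na, g_NaP = g_NaP, g_K = g_K, g_L = g_L,
            E_Na = E_Na, E_K = E_K, E_L = E_L,
            E_synE = E_synE, E_synI = E_synI,
            gates = gates, V_th = V_th, tau_E = tau_E, tau_I = tau_I,
            refractory = refractory)
  class(p) <- "membrane_parameters"
  validate_membrane_parameters(p)
  p
}

validate_membrane_parameters <- function(p) {
  stopifnot(p$C > 0, p$tau_E > 0, p$tau_I > 0)
  if (any(c(p$g_Na, p$g_NaP, p$g_K, p$g_L) < 0))
    stop("all maximal conductances must be >= 0")
  if (!(p$E_K < p$E_L && p$E_L < p$E_Na))
    stop("reversal potentials must satisfy E_K < E_L < E_Na")
  if (!(p$E_synI <= p$E_L && p$E_L < p$E_synE))
    stop("synaptic reversals must satisfy E_synI <= E_L < E_synE")
  need <- c("m_Na", "h_Na", "n_K", "m_NaP", "h_NaP")
  if (!all(need %in% names(p$gates)))
    stop("gates must contain: ", paste(need, collapse = ", "))
  for (g in need) {
    if (p$gates[[g]][["k"]] == 0) stop("gate slope k must be nonzero for ", g)
  }
  for (g in c("h_Na", "n_K", "h_NaP")) {
    if (p$gates[[g]][["tau_max"]] <= 0)
      stop("tau_max must be > 0 for dynamic gate ", g)
  }
  if (p$g_L > 0 && p$gates$h_NaP[["tau_max"]] < 100 * p$C / p$g_L)
    stop("tau_max(h_NaP) must exceed the membrane time constant C/g_L >= 100-fold")
  invisible(p)
}

#' @export
print.membrane_parameters <- function(x, ...) {
  cat("Membrane parameters (HH-style, I_NaP bursting model)\n")
  cat(sprintf("  C = %g pF; g_Na = %g, g_NaP = %g, g_K = %g, g_L = %g nS\n",
              x$C, x$g_Na, x$g_NaP, x$g_K, x$g_L))
  cat(sprintf("  E_Na = %g, E_K = %g, E_L = %g, E_synE = %g, E_synI = %g mV\n",
              x$E_Na, x$E_K, x$E_L, x$E_synE, x$E_synI))
  cat(sprintf("  V_th = %g mV; tau_E = %g, tau_I = %g ms; refractory %g ms\n",
              x$V_th, x$tau_E, x$tau_I, x$refractory))
  invisible(x)
}

#' Sigmoid gate steady state
#'
#' Canonical Boltzmann steady state \code{1/(1 + exp((V - V_half)/k))} for
#' HH-style gating variables.  Activation gates use \code{k < 0} (open with
#' depolarization), inactivation gates \code{k > 0}.
#'
#' @param V membrane potential (mV); vectorized.
#' @param V_half half-activation voltage (mV).
#' @param k slope factor (mV); must be nonzero.
#' @return Gating fraction in (0, 1).
#' @examples
#' gate_steady_state(-47.1, -47.1, -3.1)  # 0.5 at the midpoint
#' @export
gate_steady_state <- function(V, V_half, k) {
  if (any(k == 0)) stop("invalid parameter: gate slope k must be nonzero")
  1 / (1 + exp((V - V_half) / k))
}

#' Voltage-dependent gate time constant
#'
#' Bell-shaped time constant \code{tau_max / cosh((V - V_half)/(2k))},
#' peaking at \code{V_half}.
#'
#' @inheritParams gate_steady_state
#' @param tau_max peak time constant (ms).
#' @return Time constant (ms).
#' @export
gate_time_constant <- function(V, V_half, k, tau_max) {
  if (any(k == 0)) stop("invalid parameter: gate slope k must be nonzero")
  tau_max / cosh((V - V_half) / (2 * k))
}

# The tau-bell slope width defaults to the gate's steady-state slope but can
# be set independently via a fourth "tau_k" element.
gate_tau_k <- function(gate) {
  if ("tau_k" %in% names(gate)) gate[["tau_k"]] else gate[["k"]]
}

# Pack a list of membrane_parameters into the engine's population matrix.
# Column order must match enum ParamCol in src/engine.cpp.
membrane_param_matrix <- function(param_list) {
  cols <- c("C", "g_Na", "g_NaP", "g_K", "g_L", "E_Na", "E_K", "E_synE",
            "E_synI",
            "Vh_mNa", "k_mNa", "Vh_hNa", "k_hNa", "tau_hNa",
            "Vh_nK", "k_nK", "tau_nK", "Vh_mNaP", "k_mNaP",
            "Vh_hNaP", "k_hNaP", "tau_hNaP",
            "V_th", "tau_E", "tau_I", "refractory",
            "tk_hNa", "tk_nK", "tk_hNaP")
  m <- matrix(0, nrow = length(param_list), ncol = length(cols),
              dimnames = list(names(param_list), cols))
  for (i in seq_along(param_list)) {
    p <- param_list[[i]]
    m[i, ] <- c(p$C, p$g_Na, p$g_NaP, p$g_K, p$g_L, p$E_Na, p$E_K,
                p$E_synE, p$E_synI,
                p$gates$m_Na[["V_half"]], p$gates$m_Na[["k"]],
                p$gates$h_Na[["V_half"]], p$gates$h_Na[["k"]],
                p$gates$h_Na[["tau_max"]],
                p$gates$n_K[["V_half"]], p$gates$n_K[["k"]],
                p$gates$n_K[["tau_max"]],
                p$gates$m_NaP[["V_half"]], p$gates$m_NaP[["k"]],
                p$gates$h_NaP[["V_half"]], p$gates$h_NaP[["k"]],
                p$gates$h_NaP[["tau_max"]],
                p$V_th, p$tau_E, p$tau_I, p$refractory,
                gate_tau_k(p$gates$h_Na), gate_tau_k(p$gates$n_K),
                gate_tau_k(p$gates$h_NaP))
  }
  m
}

#' Initial membrane state
#'
#' Gating variables at their steady state for the initial voltage; synaptic
#' conductances at zero.
#'
#' @param params a \code{\link{membrane_parameters}} object.
#' @param V initial membrane potential (mV).
#' @return A list with elements \code{V}, \code{h_Na}, \code{n_K},
#'   \code{h_NaP}, \code{g_E}, \code{g_I}, \code{last_spike_time} (NA).
#' @export
membrane_state <- function(params, V = params$E_L) {
  g <- params$gates
  list(V = V,
       h_Na = gate_steady_state(V, g$h_Na[["V_half"]], g$h_Na[["k"]]),
       n_K = gate_steady_state(V, g$n_K[["V_half"]], g$n_K[["k"]]),
       h_NaP = gate_steady_state(V, g$h_NaP[["V_half"]], g$h_NaP[["k"]]),
       g_E = 0, g_I = 0, last_spike_time = NA_real_, t = 0)
}

#' Advance a single neuron one time step
#'
#' Reference (pure R) implementation of one exponential-Euler step of the
#' neuron model; the compiled network engine applies the identical update to
#' every neuron.  \code{m_Na} and \code{m_NaP} are treated as instantaneous
#' (steady-state) activations.
#'
#' @param state a membrane state as returned by \code{\link{membrane_state}}.
#' @param params a \code{\link{membrane_parameters}} object.
#' @param syn_events numeric vector \code{c(E = , I = )} of synaptic
#'   conductance increments (nS) delivered at this step.
#' @param E_L_effective drive-modulated leak reversal potential (mV).
#' @param dt time step (ms), in (0, 1].
#' @return The updated state; element \code{spike} is TRUE when an upward
#'   crossing of the spike threshold was detected at this step.
#' @export
neuron_step <- function(state, params, syn_events = c(E = 0, I = 0),
                        E_L_effective = params$E_L, dt = 0.1) {
  stopifnot(dt > 0, dt <= 1)
  g <- params$gates
  V <- state$V

  g_E <- state$g_E * exp(-dt / params$tau_E) + unname(syn_events["E"])
  g_I <- state$g_I * exp(-dt / params$tau_I) + unname(syn_events["I"])

  upd <- function(x, gate) {
    inf <- gate_steady_state(V, g[[gate]][["V_half"]], g[[gate]][["k"]])
    tau <- gate_time_constant(V, g[[gate]][["V_half"]], gate_tau_k(g[[gate]]),
                              g[[gate]][["tau_max"]])
    x + (inf - x) * (1 - exp(-dt / tau))
  }
  h_Na <- upd(state$h_Na, "h_Na")
  n_K <- upd(state$n_K, "n_K")
  h_NaP <- upd(state$h_NaP, "h_NaP")

  m_Na <- gate_steady_state(V, g$m_Na[["V_half"]], g$m_Na[["k"]])
  m_NaP <- gate_steady_state(V, g$m_NaP[["V_half"]], g$m_NaP[["k"]])

  gNa <- params$g_Na * m_Na^3 * h_Na
  gNaP <- params$g_NaP * m_NaP * h_NaP
  gK <- params$g_K * n_K^4
  G <- gNa + gNaP + gK + params$g_L + g_E + g_I
  S <- (gNa + gNaP) * params$E_Na + gK * params$E_K +
    params$g_L * E_L_effective + g_E * params$E_synE + g_I * params$E_synI
  Vinf <- S / G
  V_new <- Vinf + (V - Vinf) * exp(-dt * G / params$C)
  t_new <- state$t + dt
  if (!is.finite(V_new))
    stop(sprintf("numerical instability: non-finite V at t = %.3f ms", t_new))

  spike <- FALSE
  last <- state$last_spike_time
  if (V < params$V_th && V_new >= params$V_th &&
      (is.na(last) || (t_new - last) > params$refractory)) {
    spike <- TRUE
    last <- t_new
  }
  list(V = V_new, h_Na = h_Na, n_K = n_K, h_NaP = h_NaP,
       g_E = g_E, g_I = g_I, last_spike_time = last, t = t_new,
       spike = spike)
}

#' Simulate an isolated neuron
#'
#' Runs the compiled engine for a single unconnected neuron at a fixed
#' effective leak reversal potential.
#'
#' @param params a \code{\link{membrane_parameters}} object.
#' @param E_L_effective leak reversal potential (mV) held for the whole run.
#' @param duration simulated time (ms).
#' @param dt integration step (ms).
#' @param V_init optional initial membrane potential (mV); defaults to a
#'   seeded draw near \code{E_L_effective}.
#' @param tonic_g_E constant excitatory conductance (nS).
#' @param seed integer seed for the engine RNG.
#' @param record_V record the voltage trace (sampled every \code{record_dt} ms).
#' @param record_dt trace sampling interval (ms).
#' @return A list with \code{spike_times} (ms), and when requested \code{V}
#'   and \code{V_time}.
#' @export
simulate_neuron <- function(params, E_L_effective, duration, dt = 0.1,
                            V_init = NULL, tonic_g_E = 0, seed = 1,
                            record_V = FALSE, record_dt = 1) {
  pm <- membrane_param_matrix(list(neuron = params))
  res <- .cpg_simulate_cpp(
    pm, 0L, E_L_effective, 0, 1,
    c(0L, 0L), integer(0), numeric(0), logical(0),
    tonic_g_E,
    integer(0), numeric(0), numeric(0), numeric(0), numeric(0),
    c(0, duration), c(0, 0),
    dt, duration, as.integer(seed), 0, 50,
    if (record_V) 0L else integer(0), record_dt,
    if (is.null(V_init)) numeric(0) else V_init)
  out <- list(spike_times = res$spike_time)
  if (record_V) {
    out$V <- as.numeric(res$V)
    out$V_time <- res$V_time
  }
  out
}

#' Classify the activity regime of an isolated neuron
#'
#' Simulates a single neuron at a fixed effective leak reversal and labels
#' the deterministic trajectory as \code{"silence"}, \code{"bursting"} or
#' \code{"tonic"}.  Scanning the leak reversal from hyperpolarized to
#' depolarized values partitions the axis into exactly these three
#' contiguous intervals when the persistent sodium conductance is positive.
#'
#' @inheritParams simulate_neuron
#' @param T observation time (ms); must contain at least 5 putative burst
#'   cycles at the slowest expected burst rate.
#' @param settle initial transient discarded before classification (ms).
#' @param slowest_burst_rate slowest burst rate (Hz) the observation window
#'   is required to resolve.
#' @return One of \code{"silence"}, \code{"bursting"}, \code{"tonic"}.
#' @export
single_neuron_regime <- function(params, E_L_effective, T = 40000,
                                 dt = 0.1, settle = 2000,
                                 slowest_burst_rate = 0.25, seed = 1) {
  if (T < 5 / slowest_burst_rate * 1000)
    stop(sprintf(
      "insufficient observation: T = %g ms cannot contain 5 cycles at %g Hz",
      T, slowest_burst_rate))
  sim <- simulate_neuron(params, E_L_effective, duration = T + settle,
                         dt = dt, seed = seed)
  st <- sim$spike_times[sim$spike_times > settle] - settle
  rec <- spike_record_from_times(st, n_neurons = 1, duration = T,
                                 population = "neuron")
  tr <- rate_histogram(rec, bin = 100)
  bursts <- detect_bursts(tr, population = "neuron")
  classify_regime(tr, bursts, population = "neuron")
}

# Minimal spike-record constructor used by single-neuron classification
# and by tests that synthesize spike trains.
spike_record_from_times <- function(times, n_neurons, duration,
                                    population = "pop", neuron = NULL) {
  if (is.null(neuron)) neuron <- rep(1L, length(times))
  pops <- data.frame(name = population, size = n_neurons, offset = 0L,
                     stringsAsFactors = FALSE)
  structure(list(neuron = as.integer(neuron), time = as.numeric(times),
                 populations = pops, duration = duration,
                 meta = list(dt = NA_real_, seed = NA_integer_,
                             digest = NA_character_)),
            class = "spike_record")
}
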