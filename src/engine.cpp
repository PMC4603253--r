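// Fixed-step exponential-Euler integrator for conductance-based CPG networks.
//
// Each neuron carries fast Na (instantaneous activation m, inactivation h),
// delayed-rectifier K (n), persistent Na (instantaneous activation,
// slow inactivation hNaP), leak, and conductance-based synapses with
// instantaneous rise and single-exponential decay.  Gate steady states are
// sigmoids 1/(1+exp((V-Vh)/k)); voltage-dependent time constants are
// tau_max/cosh((V-Vh)/(2k)).  Spikes are upward crossings of Vth with a
// refractory gate on detection; synaptic events are delivered with a fixed
// one-step delay.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>

using namespace Rcpp;

// Column layout of the population parameter matrix (kept in step with
// membrane_param_matrix() on the R side).
enum ParamCol {
  P_C = 0, P_GNA, P_GNAP, P_GK, P_GL, P_ENA, P_EK, P_ESYNE, P_ESYNI,
  P_VH_MNA, P_K_MNA,
  P_VH_HNA, P_K_HNA, P_TAU_HNA,
  P_VH_NK, P_K_NK, P_TAU_NK,
  P_VH_MNAP, P_K_MNAP,
  P_VH_HNAP, P_K_HNAP, P_TAU_HNAP,
  P_VTH, P_TAUE, P_TAUI, P_REFRAC,
  P_TK_HNA, P_TK_NK, P_TK_HNAP,    // tau-bell slope widths (may differ from k)
  P_NCOL
};

static inline double sigmoid(double V, double Vh, double k) {
  return 1.0 / (1.0 + std::exp((V - Vh) / k));
}

static inline double gate_tau(double V, double Vh, double k, double tau_max) {
  return tau_max / std::cosh((V - Vh) / (2.0 * k));
}

// Deterministic RNG independent of R's RNG state; std::mt19937 output is
// fully specified by the standard, so spike records are platform-stable.
struct EngineRNG {
  std::mt19937 eng;
  bool have_spare;
  double spare;
  explicit EngineRNG(uint32_t seed) : eng(seed), have_spare(false), spare(0.0) {}
  double unif() { return (static_cast<double>(eng()) + 0.5) * (1.0 / 4294967296.0); }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// Tabulated gate quantities on a uniform voltage grid (0.05 mV, linear
// interpolation).  The "f" entries are 1-exp(-dt/tau(V)) so the inner loop
// needs no transcendental calls for the gating variables.
static const double TAB_VLO = -130.0;
static const double TAB_VHI = 70.0;
static const int    TAB_N   = 4001;

struct GateTab {
  std::vector<double> mNa, hNa_inf, hNa_f, nK_inf, nK_f, mNaP, hNaP_inf, hNaP_f;
};

static GateTab build_tab(const NumericMatrix& pp, int p, double dt) {
  GateTab g;
  g.mNa.resize(TAB_N); g.hNa_inf.resize(TAB_N); g.hNa_f.resize(TAB_N);
  g.nK_inf.resize(TAB_N); g.nK_f.resize(TAB_N);
  g.mNaP.resize(TAB_N); g.hNaP_inf.resize(TAB_N); g.hNaP_f.resize(TAB_N);
  double dv = (TAB_VHI - TAB_VLO) / (TAB_N - 1);
  for (int i = 0; i < TAB_N; i++) {
    double V = TAB_VLO + i * dv;
    g.mNa[i]      = sigmoid(V, pp(p, P_VH_MNA), pp(p, P_K_MNA));
    g.hNa_inf[i]  = sigmoid(V, pp(p, P_VH_HNA), pp(p, P_K_HNA));
    g.hNa_f[i]    = 1.0 - std::exp(-dt / gate_tau(V, pp(p, P_VH_HNA), pp(p, P_TK_HNA), pp(p, P_TAU_HNA)));
    g.nK_inf[i]   = sigmoid(V, pp(p, P_VH_NK), pp(p, P_K_NK));
    g.nK_f[i]     = 1.0 - std::exp(-dt / gate_tau(V, pp(p, P_VH_NK), pp(p, P_TK_NK), pp(p, P_TAU_NK)));
    g.mNaP[i]     = sigmoid(V, pp(p, P_VH_MNAP), pp(p, P_K_MNAP));
    g.hNaP_inf[i] = sigmoid(V, pp(p, P_VH_HNAP), pp(p, P_K_HNAP));
    g.hNaP_f[i]   = 1.0 - std::exp(-dt / gate_tau(V, pp(p, P_VH_HNAP), pp(p, P_TK_HNAP), pp(p, P_TAU_HNAP)));
  }
  return g;
}

static inline double tab_at(const std::vector<double>& tab, double pos, int i0) {
  double fr = pos - i0;
  return tab[i0] * (1.0 - fr) + tab[i0 + 1] * fr;
}

// [[Rcpp::export(name = ".cpg_simulate_cpp")]]
List cpg_simulate_cpp(NumericMatrix pop_params,
                      IntegerVector neuron_pop,      // 0-based population index
                      NumericVector neuron_EL0,      // baseline leak reversal (mV)
                      NumericVector neuron_gain,     // drive gain (0 = insensitive)
                      NumericVector neuron_gnap,     // per-neuron g_NaP scale factor
                      IntegerVector syn_ptr,         // CSR by source neuron, length N+1
                      IntegerVector syn_target,      // 0-based target neuron
                      NumericVector syn_weight,      // conductance increment (nS)
                      LogicalVector syn_inhib,
                      NumericVector tonic_gE,        // constant excitatory conductance (nS)
                      IntegerVector pert_neuron,     // 0-based, one row per affected neuron
                      NumericVector pert_on,
                      NumericVector pert_off,
                      NumericVector pert_gE,
                      NumericVector pert_gI,
                      NumericVector alpha_t,         // piecewise-linear schedule knots
                      NumericVector alpha_v,
                      double dt, double duration, int seed,
                      double noise_sigma, double noise_tau,
                      IntegerVector record_neurons,  // 0-based, V traces
                      double record_dt,
                      NumericVector init_V)          // length 0 => random near E_L
{
  const int N = neuron_pop.size();
  const int npop = pop_params.nrow();
  const long nsteps = (long)std::llround(duration / dt);

  List out;
  if (N == 0 || nsteps == 0) {
    out["spike_neuron"] = IntegerVector(0);
    out["spike_time"] = NumericVector(0);
    out["V"] = NumericMatrix(0, record_neurons.size());
    out["V_time"] = NumericVector(0);
    return out;
  }

  std::vector<GateTab> tabs;
  tabs.reserve(npop);
  for (int p = 0; p < npop; p++) tabs.push_back(build_tab(pop_params, p, dt));

  // cache population constants in plain structs (NumericMatrix accessors are
  // too slow for the inner loop)
  struct PopP {
    double C, gNa, gNaP, gK, gL, ENa, EK, EsynE, EsynI, Vth, refrac;
  };
  std::vector<PopP> PP(npop);
  for (int p = 0; p < npop; p++) {
    PP[p] = PopP{pop_params(p, P_C), pop_params(p, P_GNA),
                 pop_params(p, P_GNAP), pop_params(p, P_GK),
                 pop_params(p, P_GL), pop_params(p, P_ENA),
                 pop_params(p, P_EK), pop_params(p, P_ESYNE),
                 pop_params(p, P_ESYNI), pop_params(p, P_VTH),
                 pop_params(p, P_REFRAC)};
  }

  std::vector<double> decE(npop), decI(npop);
  for (int p = 0; p < npop; p++) {
    decE[p] = std::exp(-dt / pop_params(p, P_TAUE));
    decI[p] = std::exp(-dt / pop_params(p, P_TAUI));
  }

  // raw pointers for the hot loop
  const int* npv = INTEGER(neuron_pop);
  const double* el0 = REAL(neuron_EL0);
  const double* gain = REAL(neuron_gain);
  const double* gnap = REAL(neuron_gnap);
  const double* tonic = REAL(tonic_gE);
  const int* sptr = INTEGER(syn_ptr);
  const int* stgt = syn_target.size() ? INTEGER(syn_target) : nullptr;
  const double* swgt = syn_weight.size() ? REAL(syn_weight) : nullptr;
  const int* sinh = syn_inhib.size() ? LOGICAL(syn_inhib) : nullptr;

  EngineRNG rng((uint32_t)seed);

  // alpha at t = 0 (schedule knots are sorted, cover [0, duration])
  const int nknot = alpha_t.size();
  int seg = 0;
  auto alpha_at = [&](double t) {
    while (seg + 1 < nknot - 1 && t >= alpha_t[seg + 1]) seg++;
    double t0 = alpha_t[seg], t1 = alpha_t[seg + 1];
    if (t1 <= t0) return alpha_v[seg];
    double fr = (t - t0) / (t1 - t0);
    if (fr < 0) fr = 0; if (fr > 1) fr = 1;
    return alpha_v[seg] * (1.0 - fr) + alpha_v[seg + 1] * fr;
  };

  // State
  std::vector<double> V(N), hNa(N), nK(N), hNaP(N), gE(N, 0.0), gI(N, 0.0);
  std::vector<double> last_spike(N, -1e18), ou(N, 0.0);
  std::vector<double> incE(N, 0.0), incI(N, 0.0);

  const double a0 = alpha_at(0.0);
  const double dv = (TAB_VHI - TAB_VLO) / (TAB_N - 1);
  const double inv_dv = 1.0 / dv;

  for (int i = 0; i < N; i++) {
    int p = neuron_pop[i];
    double ELe = neuron_EL0[i] * (1.0 - neuron_gain[i] * a0);
    V[i] = (init_V.size() == N) ? init_V[i] : ELe - rng.unif() * 5.0;
    hNa[i]  = sigmoid(V[i], pop_params(p, P_VH_HNA),  pop_params(p, P_K_HNA));
    nK[i]   = sigmoid(V[i], pop_params(p, P_VH_NK),   pop_params(p, P_K_NK));
    hNaP[i] = sigmoid(V[i], pop_params(p, P_VH_HNAP), pop_params(p, P_K_HNAP));
  }

  // Perturbation state
  const int nper = pert_neuron.size();
  std::vector<double> pgE(N, 0.0), pgI(N, 0.0);
  std::vector<char> pact(nper, 0);

  // Noise precomputation (OU conductance, mean 0, clamped at use)
  const bool noisy = noise_sigma > 0.0;
  double ou_a = 0.0, ou_b = 0.0;
  if (noisy) {
    ou_a = std::exp(-dt / noise_tau);
    ou_b = noise_sigma * std::sqrt(1.0 - ou_a * ou_a);
  }

  std::vector<int> spike_id;
  std::vector<double> spike_tm;
  std::vector<int> step_spikes;
  step_spikes.reserve(N);

  // Voltage trace recording
  const int nrec = record_neurons.size();
  const long rec_stride = nrec > 0 ? std::max(1L, (long)std::llround(record_dt / dt)) : 0;
  const long nrec_rows = nrec > 0 ? (nsteps / rec_stride + 1) : 0;
  NumericMatrix Vrec(nrec_rows, nrec);
  NumericVector Vrec_t(nrec_rows);
  long rec_row = 0;

  if (nrec > 0) {
    for (int j = 0; j < nrec; j++) Vrec(0, j) = V[record_neurons[j]];
    Vrec_t[0] = 0.0;
    rec_row = 1;
  }

  for (long s = 0; s < nsteps; s++) {
    double t = s * dt;            // state currently at time t, step to t+dt
    double a = alpha_at(t);

    // perturbation window edges
    for (int q = 0; q < nper; q++) {
      char act = (t >= pert_on[q] && t < pert_off[q]) ? 1 : 0;
      if (act != pact[q]) {
        double sgn = act ? 1.0 : -1.0;
        pgE[pert_neuron[q]] += sgn * pert_gE[q];
        pgI[pert_neuron[q]] += sgn * pert_gI[q];
        pact[q] = act;
      }
    }

    step_spikes.clear();

    for (int i = 0; i < N; i++) {
      int p = npv[i];
      const PopP& pc = PP[p];
      // synaptic conductance decay + delayed delivery from previous step
      gE[i] = gE[i] * decE[p] + incE[i]; incE[i] = 0.0;
      gI[i] = gI[i] * decI[p] + incI[i]; incI[i] = 0.0;

      double v = V[i];
      if (!(v > -200.0 && v < 100.0)) {
        stop("numerical instability: V = %f mV at neuron %d, t = %.3f ms",
             v, i + 1, t);
      }
      double pos = (v - TAB_VLO) * inv_dv;
      if (pos < 0) pos = 0;
      if (pos > TAB_N - 1.001) pos = TAB_N - 1.001;
      int i0 = (int)pos;
      const GateTab& tb = tabs[p];

      // gates (exponential Euler against steady state at current V)
      hNa[i]  += (tab_at(tb.hNa_inf, pos, i0)  - hNa[i])  * tab_at(tb.hNa_f, pos, i0);
      nK[i]   += (tab_at(tb.nK_inf, pos, i0)   - nK[i])   * tab_at(tb.nK_f, pos, i0);
      hNaP[i] += (tab_at(tb.hNaP_inf, pos, i0) - hNaP[i]) * tab_at(tb.hNaP_f, pos, i0);

      double mNa  = tab_at(tb.mNa, pos, i0);
      double mNaP = tab_at(tb.mNaP, pos, i0);

      double nk2 = nK[i] * nK[i];
      double gNa_t  = pc.gNa  * mNa * mNa * mNa * hNa[i];
      double gNaP_t = pc.gNaP * gnap[i] * mNaP * hNaP[i];
      double gK_t   = pc.gK   * nk2 * nk2;
      double ELe    = el0[i] * (1.0 - gain[i] * a);

      if (noisy) ou[i] = ou[i] * ou_a + ou_b * rng.norm();
      double gEx = gE[i] + tonic[i] + pgE[i] + (noisy ? std::max(0.0, ou[i]) : 0.0);
      double gIn = gI[i] + pgI[i];

      double G = gNa_t + gNaP_t + gK_t + pc.gL + gEx + gIn;
      double S = (gNa_t + gNaP_t) * pc.ENa + gK_t * pc.EK
               + pc.gL * ELe + gEx * pc.EsynE + gIn * pc.EsynI;
      double Vinf = S / G;
      double vnew = Vinf + (v - Vinf) * std::exp(-dt * G / pc.C);

      if (!std::isfinite(vnew)) {
        stop("numerical instability: non-finite V at neuron %d, t = %.3f ms",
             i + 1, t + dt);
      }
      V[i] = vnew;

      if (v < pc.Vth && vnew >= pc.Vth &&
          (t + dt - last_spike[i]) > pc.refrac) {
        last_spike[i] = t + dt;
        spike_id.push_back(i + 1);
        spike_tm.push_back(t + dt);
        step_spikes.push_back(i);
      }
    }

    // deliver spikes with one-step delay
    for (size_t k = 0; k < step_spikes.size(); k++) {
      int src = step_spikes[k];
      for (int e = sptr[src]; e < sptr[src + 1]; e++) {
        if (sinh[e]) incI[stgt[e]] += swgt[e];
        else         incE[stgt[e]] += swgt[e];
      }
    }

    if (nrec > 0 && ((s + 1) % rec_stride == 0) && rec_row < nrec_rows) {
      for (int j = 0; j < nrec; j++) Vrec(rec_row, j) = V[record_neurons[j]];
      Vrec_t[rec_row] = (s + 1) * dt;
      rec_row++;
    }

    if ((s & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  if (nrec > 0 && rec_row < nrec_rows) {
    Vrec = Vrec(Range(0, rec_row - 1), Range(0, nrec - 1));
    Vrec_t = Vrec_t[Range(0, rec_row - 1)];
  }

  out["spike_neuron"] = wrap(spike_id);
  out["spike_time"] = wrap(spike_tm);
  out["V"] = Vrec;
  out["V_time"] = Vrec_t;
  return out;
}
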