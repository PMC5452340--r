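#include <Rcpp.h>
using namespace Rcpp;

// Fixed parameter order used by the R wrappers (see pack_params() in R/params.R):
//  0 C, 1 V_Tabs, 2 V_r,
//  3 G_L0, 4 a_GL, 5 tau_GL,
//  6 V_L0, 7 a_VL, 8 tau_VLa, 9 b_VL, 10 tau_VLb,
// 11 V_T0, 12 a_VT, 13 tau_VT,
// 14 DeltaT0, 15 a_DeltaT, 16 tau_DeltaT,
// 17 sigma_ms (mV per sqrt(ms); converted from mV/sqrt(s) on the R side)
struct ReifP {
  double C, VTabs, Vr;
  double GL0, aGL, tauGL;
  double VL0, aVL, tauVLa, bVL, tauVLb;
  double VT0, aVT, tauVT;
  double DT0, aDT, tauDT;
  double sigma_ms;
};

static ReifP unpack(const NumericVector& p) {
  if (p.size() != 18) stop("parameter vector must have length 18");
  ReifP q;
  q.C = p[0]; q.VTabs = p[1]; q.Vr = p[2];
  q.GL0 = p[3]; q.aGL = p[4]; q.tauGL = p[5];
  q.VL0 = p[6]; q.aVL = p[7]; q.tauVLa = p[8]; q.bVL = p[9]; q.tauVLb = p[10];
  q.VT0 = p[11]; q.aVT = p[12]; q.tauVT = p[13];
  q.DT0 = p[14]; q.aDT = p[15]; q.tauDT = p[16];
  q.sigma_ms = p[17];
  return q;
}

// Instantaneous parameter values at time-since-spike T (ms); T = +Inf means
// "never spiked" and yields the basal values exactly.
static inline void relax(const ReifP& p, double T,
                         double& GL, double& VL, double& VT, double& DT) {
  if (!R_FINITE(T)) { GL = p.GL0; VL = p.VL0; VT = p.VT0; DT = p.DT0; return; }
  GL = p.GL0 + p.aGL * std::exp(-T / p.tauGL);
  VL = p.VL0 + p.aVL * std::exp(-T / p.tauVLa) + p.bVL * std::exp(-T / p.tauVLb);
  VT = p.VT0 + p.aVT * std::exp(-T / p.tauVT);
  DT = p.DT0 + p.aDT * std::exp(-T / p.tauDT);
}

// Exponential spike-initiation term with a capped argument.  The cap cannot
// alter spike times for the default parameters: once V reaches V_Tabs the
// reset fires regardless, and below V_Tabs the argument stays under the cap.
static const double EXP_CAP = 20.0;

static inline double drift(const ReifP& p, double V, double T, double Iin) {
  double GL, VL, VT, DT;
  relax(p, T, GL, VL, VT, DT);
  double arg = (V - VT) / DT;
  if (arg > EXP_CAP) arg = EXP_CAP;
  return (-GL * (V - VL) + GL * DT * std::exp(arg) + Iin) / p.C;
}

// [[Rcpp::export]]
NumericVector relax_params_cpp(NumericVector par, double T) {
  ReifP p = unpack(par);
  double GL, VL, VT, DT;
  relax(p, T, GL, VL, VT, DT);
  return NumericVector::create(_["G_L"] = GL, _["V_L"] = VL,
                               _["V_T"] = VT, _["Delta_T"] = DT);
}

// Single-neuron fixed-step Euler-Maruyama integration.
// drive: external current per step (pA), length n_steps, plus optional
// conductance pair (nS) with reversals; total input each step is
//   I_ext[i] + gE[i]*(VE - V) + gI[i]*(VI - V).
// Noise is an additive increment sigma_ms*sqrt(dt)*xi on V; one standard
// normal is consumed per step when sigma > 0 (none when sigma == 0), so a
// run can be split into consecutive calls sharing the R RNG stream.
// [[Rcpp::export]]
List sim_neuron_cpp(NumericVector par,
                    NumericVector I_ext,
                    NumericVector gE, NumericVector gI,
                    double VE, double VI,
                    double dt, double V0, double T0,
                    bool record_v = true) {
  ReifP p = unpack(par);
  int n_steps = I_ext.size();
  bool has_g = gE.size() > 0;
  if (has_g && (gE.size() != n_steps || gI.size() != n_steps))
    stop("conductance drive length does not match current drive length");

  double V = V0, T = T0;
  double sq = std::sqrt(dt);
  bool noisy = p.sigma_ms > 0.0;

  NumericVector Vout;
  if (record_v) Vout = NumericVector(n_steps + 1);
  if (record_v) Vout[0] = V;
  std::vector<double> spikes;

  for (int i = 0; i < n_steps; ++i) {
    double Iin = I_ext[i];
    if (has_g) Iin += gE[i] * (VE - V) + gI[i] * (VI - V);
    double dV = dt * drift(p, V, T, Iin);
    if (noisy) dV += p.sigma_ms * sq * R::norm_rand();
    V += dV;
    if (!R_FINITE(V))
      stop("non-finite voltage at step %d (t = %.3f ms, I_in = %.3f pA)",
           i + 1, (i + 1) * dt, Iin);
    if (V >= p.VTabs) {
      spikes.push_back((i + 1) * dt);
      V = p.Vr;
      T = 0.0;
    } else {
      T += dt;
    }
    if (record_v) Vout[i + 1] = V;
  }

  return List::create(_["V"] = Vout,
                      _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
                      _["V_end"] = V, _["T_end"] = T);
}

// All-to-all excitatory network with presynaptic vesicle depletion.
//
// Per step (order mirrored exactly by the plain-R reference used in tests):
//   1. vesicle recovery        N += dt*(1-N)/tau_N
//   2. conductance decay       G *= exp(-dt/tau_GE)  (and s = W %*% G with it)
//   3. synaptic input          I_i = gmax*s_i*(VE - V_i) + I0
//   4. one N(0,1) draw per neuron, in index order (only when sigma > 0)
//   5. voltage update, absolute-threshold reset, spike flags
//   6. per spiking neuron j:   dG = r*N_j; N_j -= dG; G_j += dG; s += dG*W[,j]
//
// s is carried incrementally: the uniform decay and the sparse spike jumps
// keep it equal to W %*% G without an O(n^2) product every step.
// [[Rcpp::export]]
List sim_network_cpp(NumericVector par, NumericMatrix W,
                     double tauN_ms, double r, double tauGE,
                     double gmax, double I0, double VE,
                     int n_steps, double dt,
                     NumericVector V0, int decim) {
  ReifP p = unpack(par);
  int n = W.nrow();
  if (W.ncol() != n) stop("connectivity matrix must be square");
  if (V0.size() != n) stop("V0 length must equal network size");

  std::vector<double> V(n), T(n, R_PosInf), N(n, 1.0), G(n, 0.0), s(n, 0.0);
  for (int i = 0; i < n; ++i) V[i] = V0[i];

  double decay = std::exp(-dt / tauGE);
  double sq = std::sqrt(dt);
  bool noisy = p.sigma_ms > 0.0;

  std::vector<int> sp_id;
  std::vector<double> sp_t, sp_rel;
  int n_rec = n_steps / decim + 1;
  NumericMatrix N_dec(n, n_rec);
  NumericVector meanG_dec(n_rec), t_dec(n_rec);
  int rec = 0;
  // record initial state
  for (int i = 0; i < n; ++i) N_dec(i, rec) = N[i];
  meanG_dec[rec] = 0.0; t_dec[rec] = 0.0; rec++;

  std::vector<int> spiked;
  spiked.reserve(n);

  for (int k = 0; k < n_steps; ++k) {
    for (int i = 0; i < n; ++i) N[i] += dt * (1.0 - N[i]) / tauN_ms;
    for (int i = 0; i < n; ++i) { G[i] *= decay; s[i] *= decay; }

    spiked.clear();
    double t_now = (k + 1) * dt;
    for (int i = 0; i < n; ++i) {
      double Iin = gmax * s[i] * (VE - V[i]) + I0;
      double dV = dt * drift(p, V[i], T[i], Iin);
      if (noisy) dV += p.sigma_ms * sq * R::norm_rand();
      V[i] += dV;
      if (!R_FINITE(V[i]))
        stop("non-finite voltage for neuron %d at t = %.3f ms", i + 1, t_now);
      if (V[i] >= p.VTabs) {
        V[i] = p.Vr;
        T[i] = 0.0;
        spiked.push_back(i);
      } else {
        T[i] += dt;
      }
    }

    for (size_t m = 0; m < spiked.size(); ++m) {
      int j = spiked[m];
      double dG = r * N[j];
      N[j] -= dG;
      if (N[j] < 0.0 || N[j] > 1.0)
        stop("vesicle fraction outside [0,1] for neuron %d", j + 1);
      G[j] += dG;
      for (int i = 0; i < n; ++i) s[i] += dG * W(i, j);
      sp_id.push_back(j + 1);
      sp_t.push_back(t_now);
      sp_rel.push_back(dG);
    }

    if ((k + 1) % decim == 0 && rec < n_rec) {
      double mg = 0.0;
      for (int i = 0; i < n; ++i) { N_dec(i, rec) = N[i]; mg += G[i]; }
      meanG_dec[rec] = mg / n;
      t_dec[rec] = t_now;
      rec++;
    }
  }

  return List::create(
    _["spike_neuron"] = IntegerVector(sp_id.begin(), sp_id.end()),
    _["spike_time"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["spike_release"] = NumericVector(sp_rel.begin(), sp_rel.end()),
    _["t_dec"] = t_dec, _["N_dec"] = N_dec, _["meanG_dec"] = meanG_dec,
    _["V_end"] = NumericVector(V.begin(), V.end()),
    _["N_end"] = NumericVector(N.begin(), N.end()));
}
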