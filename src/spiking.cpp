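#include <Rcpp.h>
using namespace Rcpp;

// Modified integrate-and-fire stepper for one magnocellular neuron.
//
// Per 1-ms step: all activity variables decay (exponential-factor update,
// exact for the linear decay terms), Poisson synaptic events are applied,
// the membrane potential is assembled, and the threshold is tested. Spike
// increments take effect from the next step. The slow-DAP term is a
// Ca2+-suppressed K+ leak: the quiescent cell rests at V_rest - g_L and
// leak suppression S in [0,1] depolarises by up to g_L. Dynorphin (D)
// subtracts from the Ca2+ excess driving suppression, and the AHP is
// incremented per spike by k_AHP * max(C - C_rest - C_AHP, 0).
//
// pars layout (fixed order, assembled in R):
//  0 I_re, 1 I_ratio, 2 e_h, 3 i_h, 4 lambda_syn, 5 k_HAP, 6 lambda_HAP,
//  7 k_DAP, 8 lambda_DAP, 9 k_AHP, 10 lambda_AHP, 11 C_AHP, 12 C_rest,
// 13 k_C, 14 lambda_C, 15 k_D, 16 lambda_D, 17 k_L, 18 g_L, 19 V_rest,
// 20 V_thresh

static const double LN2 = 0.6931471805599453;

// [[Rcpp::export(name = ".sim_spiking_cpp")]]
IntegerVector sim_spiking_cpp(double duration_ms, NumericVector pars,
                              IntegerVector ev_e, IntegerVector ev_i) {
  const int n = (int)duration_ms;
  const bool use_events = ev_e.size() > 0;
  if (use_events && (ev_e.size() < n || ev_i.size() < n))
    stop("event vectors shorter than duration");

  const double I_re = pars[0], I_ratio = pars[1], e_h = pars[2],
               i_h = pars[3];
  const double dsyn = std::exp(-LN2 / pars[4]);
  const double k_HAP = pars[5], dHAP = std::exp(-LN2 / pars[6]);
  const double k_DAP = pars[7], dDAP = std::exp(-LN2 / pars[8]);
  const double k_AHP = pars[9], dAHP = std::exp(-LN2 / pars[10]);
  const double C_AHP = pars[11], C_rest = pars[12], k_C = pars[13];
  const double dC = std::exp(-LN2 / pars[14]);
  const double k_D = pars[15], dD = std::exp(-LN2 / pars[16]);
  const double k_L = pars[17], g_L = pars[18];
  const double V_rest = pars[19], V_thresh = pars[20];

  const double mu_e = I_re / 1000.0;            // events per ms
  const double mu_i = I_re * I_ratio / 1000.0;

  double syn = 0.0, HAP = 0.0, DAP = 0.0, AHP = 0.0, C = C_rest, D = 0.0;
  std::vector<int> spikes;

  for (int t = 0; t < n; ++t) {
    syn *= dsyn; HAP *= dHAP; DAP *= dDAP; AHP *= dAHP;
    C = C_rest + (C - C_rest) * dC;
    D *= dD;

    double ne, ni;
    if (use_events) {
      ne = ev_e[t]; ni = ev_i[t];
    } else {
      ne = (mu_e > 0.0) ? R::rpois(mu_e) : 0.0;
      ni = (mu_i > 0.0) ? R::rpois(mu_i) : 0.0;
    }
    syn += e_h * ne + i_h * ni;

    double ca_d = C - C_rest - D;
    if (ca_d < 0.0) ca_d = 0.0;
    const double S = (g_L > 0.0) ? ca_d / (ca_d + k_L) : 0.0;
    const double V = V_rest + syn + DAP + g_L * (S - 1.0) - HAP - AHP;

    if (V > V_thresh) {
      spikes.push_back(t);
      HAP += k_HAP; DAP += k_DAP; C += k_C; D += k_D;
      const double exc = C - C_rest - C_AHP;
      if (exc > 0.0) AHP += k_AHP * exc;
    }
  }
  return wrap(spikes);
}

// Single-step state transition, exposed for direct inspection of the
// membrane trajectory. state: syn, HAP, DAP, AHP, C, D. Returns the
// updated state plus V and the spike flag.
// [[Rcpp::export(name = ".step_spiking_cpp")]]
NumericVector step_spiking_cpp(NumericVector state, NumericVector pars,
                               double n_e, double n_i) {
  const double e_h = pars[2], i_h = pars[3];
  const double dsyn = std::exp(-LN2 / pars[4]);
  const double k_HAP = pars[5], dHAP = std::exp(-LN2 / pars[6]);
  const double k_DAP = pars[7], dDAP = std::exp(-LN2 / pars[8]);
  const double k_AHP = pars[9], dAHP = std::exp(-LN2 / pars[10]);
  const double C_AHP = pars[11], C_rest = pars[12], k_C = pars[13];
  const double dC = std::exp(-LN2 / pars[14]);
  const double k_D = pars[15], dD = std::exp(-LN2 / pars[16]);
  const double k_L = pars[17], g_L = pars[18];
  const double V_rest = pars[19], V_thresh = pars[20];

  double syn = state[0] * dsyn, HAP = state[1] * dHAP,
         DAP = state[2] * dDAP, AHP = state[3] * dAHP;
  double C = C_rest + (state[4] - C_rest) * dC;
  double D = state[5] * dD;

  syn += e_h * n_e + i_h * n_i;
  double ca_d = C - C_rest - D;
  if (ca_d < 0.0) ca_d = 0.0;
  const double S = (g_L > 0.0) ? ca_d / (ca_d + k_L) : 0.0;
  const double V = V_rest + syn + DAP + g_L * (S - 1.0) - HAP - AHP;

  double spiked = 0.0;
  if (V > V_thresh) {
    spiked = 1.0;
    HAP += k_HAP; DAP += k_DAP; C += k_C; D += k_D;
    const double exc = C - C_rest - C_AHP;
    if (exc > 0.0) AHP += k_AHP * exc;
  }
  return NumericVector::create(syn, HAP, DAP, AHP, C, D, V, spiked);
}
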