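#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment stimulus-secretion stepper.
//
// Spike-triggered variables b (broadening), c (cytosolic Ca2+) and
// e (submembrane Ca2+) decay exponentially; on a spike step, Ca2+ entry is
// evaluated from the pre-increment values and c, e are incremented in
// proportion to it. Secretion x = alpha * e^3 * p depletes the releasable
// pool p, which is refilled from the reserve store r at beta * (r/r_max)
// pg/s, clamped so p never exceeds p_max; r is debited exactly what p
// receives. Plasma concentration v integrates x with half-life lambda_v.
//
// pars layout:
//  0 k_b, 1 lambda_b (ms), 2 b_base, 3 k_c, 4 lambda_c (ms), 5 k_e,
//  6 lambda_e (ms), 7 c_theta, 8 c_n, 9 e_theta, 10 e_n, 11 beta (pg/s),
// 12 r_max (pg), 13 p_max (pg), 14 alpha (pg/unit), 15 lambda_v (s)
//
// init: b, c, e, p, r, v
// Records every `record_every` steps; cum_x makes window sums exact under
// decimated recording.

static const double LN2 = 0.6931471805599453;

// [[Rcpp::export(name = ".sim_secretion_cpp")]]
List sim_secretion_cpp(IntegerVector spike_ms, double duration_ms,
                       NumericVector pars, bool fatigue,
                       NumericVector init, double dt_ms, int record_every) {
  const double k_b = pars[0], lam_b = pars[1], b_base = pars[2];
  const double k_c = pars[3], lam_c = pars[4];
  const double k_e = pars[5], lam_e = pars[6];
  const double c_th = pars[7], c_n = pars[8];
  const double e_th = pars[9], e_n = pars[10];
  const double beta = pars[11], r_max = pars[12], p_max = pars[13];
  const double alpha = pars[14], tau_v = pars[15] / LN2; // s

  const double db = std::exp(-LN2 * dt_ms / lam_b);
  const double dc = std::exp(-LN2 * dt_ms / lam_c);
  const double de = std::exp(-LN2 * dt_ms / lam_e);
  const double dt_s = dt_ms / 1000.0;
  const double cthn = std::pow(c_th, c_n);
  const double ethn = std::pow(e_th, e_n);

  const long nsteps = (long)std::ceil(duration_ms / dt_ms);
  const int nspk = spike_ms.size();
  const long nrec = nsteps / record_every;

  NumericMatrix out(nrec, 9); // time_ms b c e x p r v cum_x
  double b = init[0], c = init[1], e = init[2];
  double p = init[3], r = init[4], v = init[5];
  double cum_x = 0.0, cum_refill = 0.0;

  int si = 0;
  long irec = 0;
  for (long t = 0; t < nsteps; ++t) {
    b *= db; c *= dc; e *= de;

    // all spikes landing in [t*dt, (t+1)*dt)
    const double t_ms = t * dt_ms;
    while (si < nspk && spike_ms[si] < t_ms + dt_ms) {
      if (spike_ms[si] >= t_ms) {
        const double cinh = fatigue ? cthn / (std::pow(c, c_n) + cthn) : 1.0;
        const double einh = ethn / (std::pow(e, e_n) + ethn);
        const double ca_ent = (b + b_base) * cinh * einh;
        b += k_b;
        c += k_c * ca_ent;
        e += k_e * ca_ent;
      }
      ++si;
    }

    double x = alpha * e * e * e * p;      // pg/s
    double sec = x * dt_s;                 // pg this step
    if (sec > p) { sec = p; x = sec / dt_s; }
    p -= sec;
    cum_x += sec;

    double refill = beta * (r / r_max) * dt_s;
    if (refill > p_max - p) refill = p_max - p;
    if (refill > r) refill = r;
    if (refill < 0.0) refill = 0.0;
    p += refill;
    r -= refill;
    cum_refill += refill;

    v += (x - v / tau_v) * dt_s;
    if (v < 0.0) v = 0.0;

    if ((t + 1) % record_every == 0 && irec < nrec) {
      out(irec, 0) = (t + 1) * dt_ms;
      out(irec, 1) = b; out(irec, 2) = c; out(irec, 3) = e;
      out(irec, 4) = x; out(irec, 5) = p; out(irec, 6) = r;
      out(irec, 7) = v; out(irec, 8) = cum_x;
      ++irec;
    }
  }

  return List::create(_["records"] = out,
                      _["total_secreted"] = cum_x,
                      _["total_refill"] = cum_refill,
                      _["final"] = NumericVector::create(b, c, e, p, r, v));
}
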