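#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler update of the Izhikevich two-variable model.  The discrete
// map at fixed dt is the computational model used throughout the package
// (it matches the published 13-FLOP operation count); coefficients of the
// quadratic voltage equation assume v in mV and t in ms.
//
// Spike convention: after updating (v, u), a step with v >= 30 mV emits a
// spike, the transmitted trace value is clamped to the +30 mV apex, and the
// state is reset to (c, u + d).
//
// Guard: a trajectory that stays beyond +/- guard mV for more than
// `patience` consecutive sub-threshold steps is treated as divergent.

static inline void check_guard(double v, int &over, int patience) {
  if (v > 500.0 || v < -500.0) {
    if (++over > patience)
      stop("membrane potential diverged beyond the +/-500 mV guard "
           "without spiking (v = %f)", v);
  } else {
    over = 0;
  }
}

// [[Rcpp::export(name = ".izh_simulate_cpp")]]
List izh_simulate_cpp(double a, double b, double c, double d,
                      NumericVector current, double dt,
                      double v0, double u0, bool clamp_negative,
                      int patience = 10) {
  int K = current.size();
  double v = v0, u = u0;
  std::vector<double> times;
  NumericVector trace(K);
  LogicalVector spiked(K);
  int over = 0;
  for (int k = 0; k < K; ++k) {
    double i_app = current[k];
    if (clamp_negative && i_app < 0.0) i_app = 0.0;
    double nv = v + dt * (0.04 * v * v + 5.0 * v + 140.0 - u + i_app);
    double nu = u + dt * a * (b * v - u);
    if (nv >= 30.0) {
      times.push_back((k + 1) * dt);
      trace[k] = 30.0;
      spiked[k] = true;
      v = c;
      u = nu + d;
      over = 0;
    } else {
      trace[k] = nv;
      spiked[k] = false;
      v = nv;
      u = nu;
      check_guard(v, over, patience);
    }
  }
  return List::create(_["times"] = wrap(times), _["trace"] = trace,
                      _["spiked"] = spiked, _["v"] = v, _["u"] = u);
}

// Full forward pass of the N-1 network: N first-layer neurons driven by
// constant currents gain * w1[i] * x[i], each first-layer voltage trace fed
// through a capacitive synapse (weight w2, capacitance cref), the summed
// synaptic current (clamped at zero: the output neuron is tonic-spiking)
// driving a single tonic-spiking output neuron.
//
// kind[i] == 0 -> tonic spiking, 1 -> inhibition-induced spiking.
// zero_reset_deriv: suppress the dV/dt term across the post-spike reset
// discontinuity (one step after each presynaptic spike).
//
// [[Rcpp::export(name = ".snn_forward_cpp")]]
NumericVector snn_forward_cpp(NumericVector w1, IntegerVector kind,
                              NumericVector x, double gain, double w2,
                              double cref, double dt, int K,
                              bool zero_reset_deriv = true,
                              int patience = 10) {
  const double ts_a = 0.02, ts_b = -0.1, ts_c = -65.0, ts_d = 6.0;
  const double iis_a = -0.02, iis_b = -1.0, iis_c = -60.0, iis_d = 8.0;
  int N = w1.size();
  if (kind.size() != N || x.size() != N)
    stop("w1, kind and x must have identical length");
  std::vector<double> a(N), b(N), c(N), d(N), v(N), u(N), drive(N), vprev(N);
  std::vector<int> over(N, 0);
  std::vector<bool> lastsp(N, false);
  for (int i = 0; i < N; ++i) {
    bool iis = kind[i] == 1;
    a[i] = iis ? iis_a : ts_a;
    b[i] = iis ? iis_b : ts_b;
    c[i] = iis ? iis_c : ts_c;
    d[i] = iis ? iis_d : ts_d;
    v[i] = c[i];
    u[i] = b[i] * v[i];
    vprev[i] = v[i];
    double drv = gain * w1[i] * x[i];
    if (!iis && drv < 0.0) drv = 0.0;  // tonic model valid for I >= 0 only
    drive[i] = drv;
  }
  double vo = ts_c, uo = ts_b * ts_c;
  int over_o = 0;
  std::vector<double> times;
  for (int k = 0; k < K; ++k) {
    double itot = 0.0;
    for (int i = 0; i < N; ++i) {
      double nv = v[i] +
        dt * (0.04 * v[i] * v[i] + 5.0 * v[i] + 140.0 - u[i] + drive[i]);
      double nu = u[i] + dt * a[i] * (b[i] * v[i] - u[i]);
      bool sp = nv >= 30.0;
      double tr = sp ? 30.0 : nv;
      if (sp) {
        v[i] = c[i];
        u[i] = nu + d[i];
        over[i] = 0;
      } else {
        v[i] = nv;
        u[i] = nu;
        check_guard(v[i], over[i], patience);
      }
      double der = (tr - vprev[i]) / dt;
      if (zero_reset_deriv && lastsp[i]) der = 0.0;
      itot += w2 * tr + cref * der;
      vprev[i] = tr;
      lastsp[i] = sp;
    }
    if (itot < 0.0) itot = 0.0;  // output neuron is tonic spiking
    double nvo = vo + dt * (0.04 * vo * vo + 5.0 * vo + 140.0 - uo + itot);
    double nuo = uo + dt * ts_a * (ts_b * vo - uo);
    if (nvo >= 30.0) {
      times.push_back((k + 1) * dt);
      vo = ts_c;
      uo = nuo + ts_d;
      over_o = 0;
    } else {
      vo = nvo;
      uo = nuo;
      check_guard(vo, over_o, patience);
    }
  }
  return wrap(times);
}
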