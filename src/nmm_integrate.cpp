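// Fixed-step Heun integrator for the six-source delayed neural-mass network.
//
// Each source holds three subpopulations (spiny stellate, pyramidal,
// inhibitory interneurons) with second-order synaptic kinetics; eight state
// variables per source. Extrinsic afferents are delayed by `delay_inter` ms
// and intrinsic (within-source) afferents by `delay_intra` ms, implemented by
// a full state-history buffer on the integration grid (delays are rounded to
// grid steps). Firing is the threshold sigmoid 2*e0/(1+exp(r*(v0-v))) with
// the baseline rate at v = 0 subtracted, so the origin is the resting fixed
// point (zero history is an exact rest state) while the resting slope sits
// low on the sigmoid, giving damped evoked transients rather than
// self-sustained rhythms.
//
// The inner loop is allocation-free: stage buffers are preallocated and the
// history is a contiguous (8*n) x nsteps matrix addressed by column.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// state row indices (0-based): 0 x1 stellate V, 1 x2 pyramidal excit V,
// 2 x3 pyramidal inhib V, 3..5 matching currents, 6 x7 interneuron V,
// 7 x8 interneuron current. Pyramidal depolarisation = x2 - x3.

struct NmmSys {
  const mat &AF, &AB, &AL;
  const vec &g1; double g2, g3, g4;
  const vec &He, &Hi, &te, &ti, &C;
  double e0, r, v0, s0;
  uword n;

  NmmSys(const mat& AF_, const mat& AB_, const mat& AL_, const vec& g1_,
         double g2_, double g3_, double g4_, const vec& He_, const vec& Hi_,
         const vec& te_, const vec& ti_, const vec& C_, double e0_,
         double r_, double v0_)
    : AF(AF_), AB(AB_), AL(AL_), g1(g1_), g2(g2_), g3(g3_), g4(g4_),
      He(He_), Hi(Hi_), te(te_), ti(ti_), C(C_), e0(e0_), r(r_), v0(v0_),
      s0(2.0 * e0_ / (1.0 + std::exp(r_ * v0_))), n(He_.n_elem) {}

  inline double sig(double v) const {
    return 2.0 * e0 / (1.0 + std::exp(r * (v0 - v))) - s0;
  }

  // firing triplets (s9, s1, s7) from a state column (8*n), into out (3*n)
  inline void firing(const double* x, double* out) const {
    for (uword j = 0; j < n; ++j) {
      const double* xj = x + 8 * j;
      out[3 * j] = sig(xj[1] - xj[2]);
      out[3 * j + 1] = sig(xj[0]);
      out[3 * j + 2] = sig(xj[6]);
    }
  }

  // derivative of state x given intrinsic firing fi (3*n, delayed by the
  // intra delay), extrinsic pyramidal firing s9e (n, delayed by the inter
  // delay) and input u; writes into dx (8*n)
  void deriv(const double* x, const double* fi, const vec& s9e, double u,
             double* dx) const {
    vec fin = AF * s9e;
    vec bin = AB * s9e;
    vec lin = AL * s9e;
    for (uword j = 0; j < n; ++j) {
      const double* xj = x + 8 * j;
      double* dj = dx + 8 * j;
      double ke = He(j) / te(j), ki = Hi(j) / ti(j);
      double te2 = te(j) * te(j), ti2 = ti(j) * ti(j);
      double s9 = fi[3 * j], s1 = fi[3 * j + 1], s7 = fi[3 * j + 2];
      dj[0] = xj[3];
      dj[3] = ke * (fin(j) + lin(j) + g1(j) * s9 + C(j) * u)
              - 2.0 * xj[3] / te(j) - xj[0] / te2;
      dj[1] = xj[4];
      dj[4] = ke * (bin(j) + lin(j) + g2 * s1)
              - 2.0 * xj[4] / te(j) - xj[1] / te2;
      dj[2] = xj[5];
      dj[5] = ki * g4 * s7 - 2.0 * xj[5] / ti(j) - xj[2] / ti2;
      dj[6] = xj[7];
      dj[7] = ke * (bin(j) + lin(j) + g3 * s9)
              - 2.0 * xj[7] / te(j) - xj[6] / te2;
    }
  }
};

// [[Rcpp::export]]
arma::mat nmm_integrate_cpp(const arma::mat& AF, const arma::mat& AB,
                            const arma::mat& AL,
                            const arma::vec& g1, double g2, double g3,
                            double g4,
                            const arma::vec& He, const arma::vec& Hi,
                            const arma::vec& te, const arma::vec& ti,
                            const arma::vec& C, const arma::vec& u,
                            double dt, double delay_intra, double delay_inter,
                            double e0, double r, double v0) {
  const uword n = He.n_elem;
  const uword ns = 8 * n;
  const uword nsteps = u.n_elem;
  // delays as integer steps plus a fractional part, handled by linear
  // interpolation of the history (keeps the effective delay independent of
  // the step size)
  const int kf_intra = (int)std::floor(delay_intra / dt);
  const double fr_intra = delay_intra / dt - kf_intra;
  const int kf_inter = (int)std::floor(delay_inter / dt);
  const double fr_inter = delay_inter / dt - kf_inter;

  NmmSys sys(AF, AB, AL, g1, g2, g3, g4, He, Hi, te, ti, C, e0, r, v0);

  mat H(ns, nsteps, fill::zeros);      // state history, column per step
  mat out(n, nsteps, fill::zeros);
  vec fi1(3 * n), fi2(3 * n), s9e1(n), s9e2(n);
  vec k1(ns), k2(ns), Xp(ns), xd(ns);
  vec zero_f(3 * n, fill::zeros);

  // interpolated delayed state column; cur is the candidate state at index
  // j (not yet stored). Returns nullptr when the delayed time is pre-rest.
  auto delayed_state = [&](int j, const double* cur, int kf, double fr)
      -> const double* {
    if (kf == 0 && fr == 0.0) return cur;
    int a = j - kf;                    // newer sample
    int b = a - 1;                     // older sample
    if (a < 0) return nullptr;         // fully before integration start
    const double* xa = (a == j) ? cur : H.colptr(a);
    if (fr == 0.0) return xa;
    if (b < 0) {                       // older sample is rest (zeros)
      for (uword q = 0; q < ns; ++q) xd(q) = (1.0 - fr) * xa[q];
    } else {
      const double* xb = H.colptr(b);
      for (uword q = 0; q < ns; ++q)
        xd(q) = (1.0 - fr) * xa[q] + fr * xb[q];
    }
    return xd.memptr();
  };
  auto ext_firing = [&](int j, const double* cur, vec& s9e) {
    const double* x = delayed_state(j, cur, kf_inter, fr_inter);
    if (!x) { s9e.zeros(); return; }
    for (uword q = 0; q < n; ++q)
      s9e(q) = sys.sig(x[8 * q + 1] - x[8 * q + 2]);
  };
  auto int_firing = [&](int j, const double* cur, vec& fi) {
    const double* x = delayed_state(j, cur, kf_intra, fr_intra);
    if (!x) { fi = zero_f; return; }
    sys.firing(x, fi.memptr());
  };

  for (uword i = 0; i + 1 < nsteps; ++i) {
    const double* Xi = H.colptr(i);
    int_firing((int)i, Xi, fi1);
    ext_firing((int)i, Xi, s9e1);
    sys.deriv(Xi, fi1.memptr(), s9e1, u(i), k1.memptr());
    for (uword q = 0; q < ns; ++q) Xp(q) = Xi[q] + dt * k1(q);
    int_firing((int)i + 1, Xp.memptr(), fi2);
    ext_firing((int)i + 1, Xp.memptr(), s9e2);
    sys.deriv(Xp.memptr(), fi2.memptr(), s9e2, u(i + 1), k2.memptr());
    double* Xn = H.colptr(i + 1);
    bool bad = false;
    for (uword q = 0; q < ns; ++q) {
      Xn[q] = Xi[q] + 0.5 * dt * (k1(q) + k2(q));
      if (!std::isfinite(Xn[q])) bad = true;
    }
    if (bad) { out.fill(datum::nan); return out; }
    for (uword j = 0; j < n; ++j)
      out(j, i + 1) = Xn[8 * j + 1] - Xn[8 * j + 2];
  }
  return out;
}
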