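#include <Rcpp.h>
using namespace Rcpp;

// Exact (direct-method) SSA for the two-stage expression model with a
// photoconvertible reporter:
//   0 -> mRNA            at v0
//   mRNA -> 0            at d0 * m
//   mRNA -> mRNA + green at v1 * m
//   green -> 0           at d1 * g
//   red -> 0             at d1 * r
// Photoconversion is an instantaneous deterministic event handled by the
// callers: green is transferred to red in full.
//
// States are stored as doubles (copy numbers stay far below 2^53).
// Uses R's RNG so results are reproducible under set.seed().

namespace {

struct Rates {
  double v0, d0, v1, d1;
};

// Advance (m, g, r) from t0 to t1, recording the state at the sample times
// ts[ti..] that fall in [t0, t1] (ts ascending, shared cursor ti).
// The state is a right-continuous step function; a sample at time s records
// the state just before any event occurring exactly at s.
void ssa_segment(const Rates& k, double& m, double& g, double& r,
                 double t0, double t1,
                 const double* ts, int nts, int& ti,
                 double* out_m, double* out_g, double* out_r) {
  double t = t0;
  for (;;) {
    const double a1 = k.v0;
    const double a2 = k.d0 * m;
    const double a3 = k.v1 * m;
    const double a4 = k.d1 * g;
    const double a5 = k.d1 * r;
    const double a0 = a1 + a2 + a3 + a4 + a5;
    const double tn = (a0 > 0.0) ? t + R::exp_rand() / a0 : t1 + 1.0;
    while (ti < nts && ts[ti] <= t1 && ts[ti] < tn) {
      if (out_m) out_m[ti] = m;
      if (out_g) out_g[ti] = g;
      if (out_r) out_r[ti] = r;
      ++ti;
    }
    if (tn > t1) break;
    t = tn;
    const double u = R::unif_rand() * a0;
    if (u < a1) m += 1.0;
    else if (u < a1 + a2) m -= 1.0;
    else if (u < a1 + a2 + a3) g += 1.0;
    else if (u < a1 + a2 + a3 + a4) g -= 1.0;
    else r -= 1.0;
  }
}

} // namespace

// One trajectory on an absolute time grid, with photoconversion at t_conv
// (pass a negative t_conv to skip conversion). Samples at times >= t_conv
// see the post-conversion state. Also returns the exact state immediately
// before and after the conversion instant.
// [[Rcpp::export]]
List cpp_ssa_two_stage(double v0, double d0, double v1, double d1,
                       double t_conv, double m0, double g0, double r0,
                       NumericVector times) {
  const Rates k{v0, d0, v1, d1};
  const int nts = times.size();
  NumericMatrix out(nts, 3);
  double m = m0, g = g0, r = r0;
  int ti = 0;
  std::vector<double> ts(times.begin(), times.end());
  double* om = nts ? &out(0, 0) : nullptr;
  double* og = nts ? &out(0, 1) : nullptr;
  double* orr = nts ? &out(0, 2) : nullptr;

  NumericVector conv_pre(3, NA_REAL), conv_post(3, NA_REAL);
  const double t_end = nts ? ts[nts - 1] : 0.0;
  if (t_conv >= 0.0 && t_conv <= t_end) {
    // samples strictly before the conversion instant
    int n_pre = 0;
    while (n_pre < nts && ts[n_pre] < t_conv) ++n_pre;
    ssa_segment(k, m, g, r, 0.0, t_conv, ts.data(), n_pre, ti, om, og, orr);
    conv_pre[0] = m; conv_pre[1] = g; conv_pre[2] = r;
    r += g;  // conversion: the whole green pool turns red
    g = 0.0;
    conv_post[0] = m; conv_post[1] = g; conv_post[2] = r;
    ssa_segment(k, m, g, r, t_conv, t_end, ts.data(), nts, ti, om, og, orr);
  } else {
    ssa_segment(k, m, g, r, 0.0, t_end, ts.data(), nts, ti, om, og, orr);
  }
  return List::create(_["states"] = out, _["conv_pre"] = conv_pre,
                      _["conv_post"] = conv_post);
}

// Ensemble of photoconversion experiments. Each trajectory draws its mRNA
// from the stationary Poisson law, burns in for t_burn hours with its own
// translation rate v1[i], is converted (green -> red), and is then sampled
// at `rel_times` hours after conversion.
// [[Rcpp::export]]
List cpp_kik_ensemble(NumericVector v1, double v0, double d0, double d1,
                      double t_burn, NumericVector rel_times) {
  const int n = v1.size();
  const int nts = rel_times.size();
  std::vector<double> ts(rel_times.begin(), rel_times.end());
  const double t_end = nts ? ts[nts - 1] : 0.0;
  NumericMatrix green(n, nts), red(n, nts);
  std::vector<double> bm(nts), bg(nts), br(nts);
  for (int i = 0; i < n; ++i) {
    const Rates k{v0, d0, v1[i], d1};
    double m = R::rpois(d0 > 0 ? v0 / d0 : 0.0);
    double g = 0.0, r = 0.0;
    int ti0 = 0;
    ssa_segment(k, m, g, r, 0.0, t_burn, nullptr, 0, ti0, nullptr, nullptr, nullptr);
    r += g;
    g = 0.0;
    int ti = 0;
    ssa_segment(k, m, g, r, 0.0, t_end, ts.data(), nts, ti,
                bm.data(), bg.data(), br.data());
    for (int j = 0; j < nts; ++j) {
      green(i, j) = bg[j];
      red(i, j) = br[j];
    }
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["green"] = green, _["red"] = red);
}

// Mother/daughter division ensemble for the dual-reporter system. The two
// reporter genes are conditionally independent given the cell's translation
// rate, so each gene is simulated by the same single-gene engine. The mother
// equilibrates for t_burn with rate v1m[i]; her exact (mRNA, protein) state
// for both genes is copied to two daughters, which then evolve independently
// for ages[i] hours with rates v1a[i] and v1b[i].
// Columns: mC1 pC1 mY1 pY1 mC2 pC2 mY2 pY2.
// [[Rcpp::export]]
NumericMatrix cpp_division_pairs(double v0, double d0, double d1,
                                 NumericVector v1m, NumericVector v1a,
                                 NumericVector v1b, NumericVector ages,
                                 double t_burn) {
  const int n = v1m.size();
  NumericMatrix out(n, 8);
  int ti = 0;
  for (int i = 0; i < n; ++i) {
    const Rates km{v0, d0, v1m[i], d1};
    double state[4][2];  // gene C, gene Y of the mother
    for (int gidx = 0; gidx < 2; ++gidx) {
      double m = R::rpois(d0 > 0 ? v0 / d0 : 0.0), p = 0.0, r = 0.0;
      ti = 0;
      ssa_segment(km, m, p, r, 0.0, t_burn, nullptr, 0, ti, nullptr, nullptr, nullptr);
      state[gidx][0] = m;
      state[gidx][1] = p;
    }
    const double v1d[2] = {v1a[i], v1b[i]};
    for (int d = 0; d < 2; ++d) {
      const Rates kd{v0, d0, v1d[d], d1};
      for (int gidx = 0; gidx < 2; ++gidx) {
        double m = state[gidx][0], p = state[gidx][1], r = 0.0;
        ti = 0;
        ssa_segment(kd, m, p, r, 0.0, ages[i], nullptr, 0, ti, nullptr, nullptr, nullptr);
        out(i, 4 * d + 2 * gidx) = m;
        out(i, 4 * d + 2 * gidx + 1) = p;
      }
    }
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
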