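// Monte-Carlo simulation kernel for the 3AFC confidence observer.
//
// For each target position s we simulate n_mc measurements x ~ N(s, sigma^2 I),
// compute the posterior over the three categories, corrupt it with Dirichlet
// decision noise (concentration alpha), take the MAP category and read out the
// scalar confidence variable. The kernel is shared by two consumers:
//   * response_tables_cpp bins (category, rating) frequencies into the 3 x 4
//     response table per position (lapse mixing happens on the R side);
//   * loglik_structs_cpp keeps the per-position draws as sorted arrays so the
//     likelihood can be re-evaluated for any criteria/lapse by binary search
//     (the inner stage of the factorized fit).
// Because both consumers draw from the identical RNG sequence, binning the
// stored draws with given criteria reproduces the response tables exactly.
//
// Measurement normals are drawn first, in a count that does not depend on the
// observer parameters, so a fixed seed gives common random numbers for the
// sensory stage across parameter evaluations.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Marsaglia-Tsang gamma sampler (rate 1), with the standard shape boost for
// shape < 1. Uses R's RNG (the RNG state is held by Rcpp attributes).
static inline double rgamma_mt(double shape) {
  double boost = 1.0;
  if (shape < 1.0) {
    boost = std::pow(unif_rand(), 1.0 / shape); // G(a) = G(a+1) U^(1/a)
    shape += 1.0;
  }
  const double d = shape - 1.0 / 3.0;
  const double c = 1.0 / std::sqrt(9.0 * d);
  for (;;) {
    double x, v;
    do {
      x = norm_rand();
      v = 1.0 + c * x;
    } while (v <= 0.0);
    v = v * v * v;
    const double u = unif_rand();
    const double x2 = x * x;
    if (u < 1.0 - 0.0331 * x2 * x2) return boost * d * v;
    if (std::log(u) < 0.5 * x2 + d * (1.0 - v + std::log(v))) return boost * d * v;
  }
}

// rule codes: 1 = max, 2 = difference, 3 = entropy, 4 = ratio
static inline double readout(const double q[3], int rule) {
  double q1 = q[0], q2 = q[1], q3 = q[2];
  if (q1 < q2) std::swap(q1, q2);
  if (q2 < q3) std::swap(q2, q3);
  if (q1 < q2) std::swap(q1, q2);
  switch (rule) {
  case 1: return q1;
  case 2: return q1 - q2;
  case 3: {
    double h = 0.0;
    for (int k = 0; k < 3; ++k) if (q[k] > 0.0) h += q[k] * std::log(q[k]);
    return h;
  }
  default: return q1 / (q1 + q2);
  }
}

// Simulate all readouts: fills chat (0-based category) and cstar, both of
// length k * reps, ordered position-major. Returns reps (1 in the fully
// noiseless case, n_mc otherwise).
static int sim_readouts(const NumericMatrix& pos, const NumericMatrix& means,
                        double cat_sd, double sigma, double alpha, int rule,
                        int n_mc, std::vector<int>& chat,
                        std::vector<double>& cstar) {
  const int k = pos.nrow();
  const double v = cat_sd * cat_sd + sigma * sigma;
  const bool no_sens = (sigma <= 0.0);
  const bool no_dec = !R_finite(alpha);
  const double mx[3] = {means(0, 0), means(1, 0), means(2, 0)};
  const double my[3] = {means(0, 1), means(1, 1), means(2, 1)};
  // if all category centers share one y, the vertical measurement coordinate
  // cancels in the posterior and need not be simulated
  const bool collapse_y = (my[0] == my[1]) && (my[1] == my[2]);
  const double clamp = 1e-6;
  const int reps = (no_sens && no_dec) ? 1 : n_mc;

  chat.resize((size_t)k * reps);
  cstar.resize((size_t)k * reps);

  // sensory-stage noise, fixed count -> common random numbers across theta
  std::vector<double> z1, z2;
  if (!no_sens) {
    z1.resize((size_t)k * n_mc);
    for (size_t i = 0; i < z1.size(); ++i) z1[i] = norm_rand();
    if (!collapse_y) {
      z2.resize(z1.size());
      for (size_t i = 0; i < z2.size(); ++i) z2[i] = norm_rand();
    }
  }

  for (int i = 0; i < k; ++i) {
    const double sx = pos(i, 0), sy = pos(i, 1);
    double p0[3]; // posterior at x = s, reused when there is no sensory noise
    for (int j = 0; j < reps; ++j) {
      double p[3];
      if (no_sens && j > 0) {
        p[0] = p0[0]; p[1] = p0[1]; p[2] = p0[2];
      } else {
        double x1 = sx, x2 = sy;
        if (!no_sens) {
          x1 += sigma * z1[(size_t)i * n_mc + j];
          if (!collapse_y) x2 += sigma * z2[(size_t)i * n_mc + j];
        }
        double ll[3], llmax = -INFINITY;
        for (int c = 0; c < 3; ++c) {
          const double dx = x1 - mx[c];
          double d2 = dx * dx;
          if (!collapse_y) {
            const double dy = x2 - my[c];
            d2 += dy * dy;
          }
          ll[c] = -d2 / (2.0 * v);
          if (ll[c] > llmax) llmax = ll[c];
        }
        double psum = 0.0;
        for (int c = 0; c < 3; ++c) {
          p[c] = std::exp(ll[c] - llmax);
          psum += p[c];
        }
        for (int c = 0; c < 3; ++c) p[c] /= psum;
        if (no_sens) { p0[0] = p[0]; p0[1] = p[1]; p0[2] = p[2]; }
      }

      double q[3];
      if (no_dec) {
        q[0] = p[0]; q[1] = p[1]; q[2] = p[2];
      } else {
        double pc[3], csum = 0.0;
        for (int c = 0; c < 3; ++c) {
          pc[c] = (p[c] < clamp) ? clamp : p[c];
          csum += pc[c];
        }
        double g[3], gsum = 0.0;
        for (int c = 0; c < 3; ++c) {
          g[c] = rgamma_mt(alpha * pc[c] / csum);
          gsum += g[c];
        }
        if (gsum > 0.0 && R_finite(gsum)) {
          for (int c = 0; c < 3; ++c) q[c] = g[c] / gsum;
        } else {
          for (int c = 0; c < 3; ++c) q[c] = pc[c] / csum;
        }
      }

      // MAP decision; uniform tie-break (ties only in noiseless variants)
      int best = 0;
      double qmax = q[0];
      for (int c = 1; c < 3; ++c) if (q[c] > qmax) { qmax = q[c]; best = c; }
      int nt = 0;
      for (int c = 0; c < 3; ++c) if (q[c] == qmax) ++nt;
      if (nt > 1) {
        int pick = (int)(unif_rand() * nt);
        if (pick >= nt) pick = nt - 1;
        int seen = 0;
        for (int c = 0; c < 3; ++c) {
          if (q[c] == qmax && seen++ == pick) { best = c; break; }
        }
      }
      chat[(size_t)i * reps + j] = best;
      cstar[(size_t)i * reps + j] = readout(q, rule);
    }
  }
  return reps;
}

// [[Rcpp::export]]
NumericMatrix response_tables_cpp(NumericMatrix pos, NumericMatrix means,
                                  double cat_sd, double sigma, double alpha,
                                  int rule, NumericVector crit, int n_mc) {
  std::vector<int> chat;
  std::vector<double> cstar;
  const int reps = sim_readouts(pos, means, cat_sd, sigma, alpha, rule, n_mc,
                                chat, cstar);
  const int k = pos.nrow();
  const double b1 = crit[0], b2 = crit[1], b3 = crit[2];
  const double w = 1.0 / reps;
  NumericMatrix tab(k, 12);
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j < reps; ++j) {
      const double cs = cstar[(size_t)i * reps + j];
      const int rating = (cs > b1) + (cs > b2) + (cs > b3); // 0..3
      tab(i, rating * 3 + chat[(size_t)i * reps + j]) += w;
    }
  }
  return tab;
}

// Per-position sorted c* arrays for fast likelihood re-evaluation over
// criteria and lapse. For each position i: `sel` holds the sorted c* values
// of the simulations whose decision equals obs_cat[i] (1-based), `n_sel`
// their count; if want_all, `all` holds the sorted c* of all simulations
// (the rating marginal ignores the decision).
// [[Rcpp::export]]
List loglik_structs_cpp(NumericMatrix pos, NumericMatrix means,
                        double cat_sd, double sigma, double alpha,
                        int rule, int n_mc, IntegerVector obs_cat,
                        bool want_all) {
  std::vector<int> chat;
  std::vector<double> cstar;
  const int reps = sim_readouts(pos, means, cat_sd, sigma, alpha, rule, n_mc,
                                chat, cstar);
  const int k = pos.nrow();
  std::vector<double> sel;
  sel.reserve((size_t)k * reps / 2);
  IntegerVector n_sel(k), offset(k);
  NumericVector all(want_all ? (size_t)k * reps : 0);
  for (int i = 0; i < k; ++i) {
    offset[i] = (int)sel.size();
    const int target = obs_cat[i] - 1;
    for (int j = 0; j < reps; ++j) {
      const size_t idx = (size_t)i * reps + j;
      if (chat[idx] == target) sel.push_back(cstar[idx]);
      if (want_all) all[idx] = cstar[idx];
    }
    n_sel[i] = (int)sel.size() - offset[i];
    std::sort(sel.begin() + offset[i], sel.end());
    if (want_all) {
      std::sort(all.begin() + (size_t)i * reps, all.begin() + (size_t)(i + 1) * reps);
    }
  }
  return List::create(
    _["sel"] = NumericVector(sel.begin(), sel.end()),
    _["offset"] = offset, _["n_sel"] = n_sel,
    _["all"] = all, _["reps"] = reps
  );
}

// #(values <= t) within [lo, hi) of a sorted array.
static inline long count_leq(const double* v, size_t lo, size_t hi, double t) {
  return (long)(std::upper_bound(v + lo, v + hi, t) - (v + lo));
}

// Log-likelihood over trials given the sorted-readout structures.
// mode: 1 = joint, 2 = confidence_only, 3 = decision_only.
// rating is 1-based; intervals are (b_{r-1}, b_r], right-closed, matching
// rating = 1 + #{criteria strictly exceeded}.
// [[Rcpp::export]]
double structs_loglik_cpp(List structs, IntegerVector rating,
                          double b1, double b2, double b3, double lapse,
                          int mode) {
  NumericVector sel = structs["sel"];
  IntegerVector offset = structs["offset"];
  IntegerVector n_sel = structs["n_sel"];
  NumericVector all = structs["all"];
  const int reps = as<int>(structs["reps"]);
  const int k = rating.size();
  const double b[5] = {-INFINITY, b1, b2, b3, INFINITY};
  double ll = 0.0;
  for (int i = 0; i < k; ++i) {
    double p;
    if (mode == 3) {
      p = (1.0 - lapse) * n_sel[i] / reps + lapse / 3.0;
    } else if (mode == 1) {
      const size_t lo = (size_t)offset[i], hi = lo + (size_t)n_sel[i];
      const int r = rating[i];
      const long cnt = count_leq(sel.begin(), lo, hi, b[r]) -
                       count_leq(sel.begin(), lo, hi, b[r - 1]);
      p = (1.0 - lapse) * cnt / reps + lapse / 12.0;
    } else {
      const size_t lo = (size_t)i * reps, hi = lo + (size_t)reps;
      const int r = rating[i];
      const long cnt = count_leq(all.begin(), lo, hi, b[r]) -
                       count_leq(all.begin(), lo, hi, b[r - 1]);
      p = (1.0 - lapse) * cnt / reps + lapse / 4.0;
    }
    ll += std::log(p);
  }
  return ll;
}
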