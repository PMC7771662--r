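#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Pearson correlation scan of a short window against a history trace.
//
// For every alignment position p (0-based) the window w[0..W) is compared
// with history[p..p+W).  Zero-variance segments score 0 (the caller flags
// them); a zero-variance window is rejected at the R level.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_pearson_scan(NumericVector window, NumericVector history) {
  const int W = window.size(), H = history.size();
  const int npos = H - W + 1;
  NumericVector out(npos);
  double mw = 0.0, sw2 = 0.0;
  for (int j = 0; j < W; ++j) mw += window[j];
  mw /= W;
  for (int j = 0; j < W; ++j) sw2 += (window[j] - mw) * (window[j] - mw);
  const double sdw = std::sqrt(sw2);
  for (int p = 0; p < npos; ++p) {
    double ms = 0.0;
    for (int j = 0; j < W; ++j) ms += history[p + j];
    ms /= W;
    double ss2 = 0.0, cross = 0.0;
    for (int j = 0; j < W; ++j) {
      const double d = history[p + j] - ms;
      ss2 += d * d;
      cross += d * (window[j] - mw);
    }
    const double den = sdw * std::sqrt(ss2);
    out[p] = (den > 1e-12) ? cross / den : 0.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Causal phase-match series.
//
// x is the ECG resampled to the TR grid (one sample per acquired view).  At
// every step i the trailing window x[i-W+1..i] is correlated against every
// history segment ending at e <= i - excl (Pearson, zero-mean unit-norm).
// Local maxima of the correlation over e that reach min_score are selected
// greedily in descending score with a min_sep exclusion zone; the end
// indices (1-based) of up to n_matches segments are stored in row i.
//
// The naive scan costs O(n^2 * W).  The cross terms are instead maintained
// per lag L = i - e: advancing i by one updates each lag in O(1)
//   cross[L] += x[i]*x[i-L] - x[i-W]*x[i-L-W]
// which makes the whole series O(n^2) and exactly equal to the naive scan.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_match_series(NumericVector x_, int W, int min_sep, double min_score,
                      int n_matches, int excl, bool prefer_recent = true) {
  const int n = x_.size();
  const std::vector<double> x(x_.begin(), x_.end());
  IntegerMatrix matches(n, std::max(n_matches, 1));
  NumericMatrix scores(n, std::max(n_matches, 1));
  std::fill(matches.begin(), matches.end(), NA_INTEGER);
  std::fill(scores.begin(), scores.end(), NA_REAL);
  if (n_matches <= 0 || n < W + excl) return List::create(_["idx"] = matches, _["score"] = scores);

  // prefix sums for O(1) segment mean / sum of squares, plus precomputed
  // per-segment sums and reciprocal standard deviations (segment statistics
  // do not depend on the current step)
  std::vector<double> S1(n + 1, 0.0), S2(n + 1, 0.0);
  for (int j = 0; j < n; ++j) {
    S1[j + 1] = S1[j] + x[j];
    S2[j + 1] = S2[j] + x[j] * x[j];
  }
  std::vector<double> seg_sum(n, 0.0), seg_isd(n, 0.0);
  for (int e = W - 1; e < n; ++e) {
    const double ss = S1[e + 1] - S1[e + 1 - W];
    const double vs = (S2[e + 1] - S2[e + 1 - W]) - ss * ss / W;
    seg_sum[e] = ss;
    seg_isd[e] = vs > 1e-12 ? 1.0 / std::sqrt(vs) : 0.0;
  }
  // cross[L] holds sum_j x[i-j]*x[i-L-j], j = 0..W-1, for the current i
  std::vector<double> cross(n, 0.0);
  std::vector<double> corr(n, 0.0);
  std::vector<int> cand;
  cand.reserve(n);

  const int emin = W - 1;  // earliest complete segment end (0-based)
  for (int i = W - 1; i < n; ++i) {
    const int emax = i - excl;
    const int Lmin = excl, Lmax = i - emin;
    // update existing lags, then initialise the lag that just became valid
    for (int L = Lmin; L < Lmax; ++L) {
      cross[L] += x[i] * x[i - L] - x[i - W] * x[i - L - W];
    }
    if (Lmax >= Lmin) {
      double c = 0.0;
      for (int j = 0; j < W; ++j) c += x[i - j] * x[emin - j];
      cross[Lmax] = c;
    }
    if (emax < emin) continue;

    const double sw = S1[i + 1] - S1[i + 1 - W];
    const double qw = S2[i + 1] - S2[i + 1 - W];
    const double vw = qw - sw * sw / W;
    if (vw <= 1e-12) continue;  // featureless window: no matches this step
    const double isdw = 1.0 / std::sqrt(vw);
    const double swW = sw / W;

    const int ncand = emax - emin + 1;
    for (int e = emin; e <= emax; ++e) {
      corr[e - emin] = (cross[i - e] - swW * seg_sum[e]) * seg_isd[e] * isdw;
    }

    // strict local maxima reaching min_score
    cand.clear();
    for (int p = 1; p + 1 < ncand; ++p) {
      if (corr[p] >= min_score && corr[p] > corr[p - 1] && corr[p] > corr[p + 1])
        cand.push_back(p);
    }
    if (cand.empty()) continue;
    // selection order: the most recent qualifying beats give the frame a
    // coherent sliding temporal footprint (the closed loop then keeps
    // refining one slowly-evolving view set); score order is the
    // alternative used for standalone match queries
    if (prefer_recent)
      std::sort(cand.begin(), cand.end(),
                [&](int a, int b) { return a > b; });
    else
      std::sort(cand.begin(), cand.end(),
                [&](int a, int b) { return corr[a] > corr[b]; });
    int taken = 0;
    std::vector<int> chosen;
    for (size_t c = 0; c < cand.size() && taken < n_matches; ++c) {
      bool ok = true;
      for (size_t k = 0; k < chosen.size(); ++k) {
        if (std::abs(cand[c] - chosen[k]) < min_sep) { ok = false; break; }
      }
      if (!ok) continue;
      chosen.push_back(cand[c]);
      matches(i, taken) = cand[c] + emin + 1;  // 1-based end index
      scores(i, taken) = corr[cand[c]];
      ++taken;
    }
  }
  return List::create(_["idx"] = matches, _["score"] = scores);
}

// ---------------------------------------------------------------------------
// Track matches forward between matchable windows: the cardiac phase of a
// matched point advances one sample per step, so when a step finds fewer
// matches than the previous step had (e.g. the trailing window is flat
// diastole), the previous step's matches are carried forward by one sample.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_track_matches(IntegerMatrix raw) {
  const int n = raw.nrow(), k = raw.ncol();
  IntegerMatrix out = clone(raw);
  auto nvalid = [&](const IntegerMatrix &m, int i) {
    int c = 0;
    for (int j = 0; j < k; ++j) if (m(i, j) != NA_INTEGER) ++c;
    return c;
  };
  for (int i = 1; i < n; ++i) {
    if (nvalid(raw, i) < nvalid(out, i - 1)) {
      for (int j = 0; j < k; ++j)
        out(i, j) = (out(i - 1, j) == NA_INTEGER) ? NA_INTEGER : out(i - 1, j) + 1;
    }
  }
  return out;
}

// x mod 180 for non-negative x (avoids libm fmod)
static inline double mod180(double x) {
  double m = x - 180.0 * std::floor(x / 180.0);
  return (m >= 180.0 || m < 0.0) ? 0.0 : m;
}

// ---------------------------------------------------------------------------
// largest-gap bisection over angles in [0, 180), wrap-aware.
// Ties go to the gap with the smallest start angle (first in sorted order).
// ---------------------------------------------------------------------------
static double bisect_largest_gap(std::vector<double> &a) {
  std::sort(a.begin(), a.end());
  const int n = a.size();
  if (n == 1) return mod180(a[0] + 90.0);
  double best_gap = -1.0, best_start = 0.0;
  for (int j = 0; j < n; ++j) {
    const double gap = (j + 1 < n) ? a[j + 1] - a[j] : 180.0 - a[n - 1] + a[0];
    if (gap > best_gap + 1e-12) { best_gap = gap; best_start = a[j]; }
  }
  return mod180(best_start + best_gap / 2.0);
}

// collate the frame for step i (0-based): Ns/2 most recent views plus, for
// each matched end index m (1-based), the views in [m - Ns/2, m + Ns/2)
static void collate_idx(int i, int Ns, const IntegerMatrix &midx, int n_use,
                        std::vector<int> &out) {
  out.clear();
  const int half = Ns / 2;
  for (int v = std::max(0, i - half); v < i; ++v) out.push_back(v);
  for (int c = 0; c < n_use; ++c) {
    const int m = midx(i, c);
    if (m == NA_INTEGER) continue;
    const int m0 = m - 1;  // 0-based end index of matched segment
    for (int v = std::max(0, m0 - half); v < std::min(i, m0 + half); ++v)
      out.push_back(v);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

// ---------------------------------------------------------------------------
// Closed-loop acquisition.  Training A (golden increments) for the first
// train_a steps; training B (still golden) until at least Nq-1 matches are
// available; then active: collate the frame, bisect its largest gap.
// Single-shot (Nq == 1) is purely geometric: the frame is the Ntheta most
// recent views.  phase: 0 = training A, 1 = training B, 2 = active.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_arks(int n_steps, int Nq, int Ns, int train_a, double theta0,
                  IntegerMatrix match_idx) {
  const double GOLDEN = 111.25;
  const int Ntheta = Ns * (Nq - 1) + Ns / 2;
  NumericVector ang(n_steps);
  IntegerVector phase(n_steps);
  bool active = false;
  int active_start = NA_INTEGER;
  double th = theta0;
  std::vector<int> idx;
  std::vector<double> frame;
  for (int i = 0; i < n_steps; ++i) {
    if (!active && i >= train_a) {
      if (Nq == 1) {
        active = (i >= Ntheta);
      } else {
        int have = 0;
        for (int c = 0; c < match_idx.ncol(); ++c)
          if (match_idx(i, c) != NA_INTEGER) ++have;
        active = (have >= Nq - 1);
      }
      if (active) active_start = i + 1;  // 1-based for R
    }
    if (!active) {
      ang[i] = th;
      th = mod180(th + GOLDEN);
      phase[i] = (i < train_a) ? 0 : 1;
      continue;
    }
    phase[i] = 2;
    if (Nq == 1) {
      frame.clear();
      for (int v = i - Ntheta; v < i; ++v) frame.push_back(ang[v]);
    } else {
      collate_idx(i, Ns, match_idx, Nq - 1, idx);
      frame.clear();
      for (size_t k = 0; k < idx.size(); ++k) frame.push_back(ang[idx[k]]);
    }
    ang[i] = bisect_largest_gap(frame);
  }
  return List::create(_["angle"] = ang, _["phase"] = phase,
                      _["active_start"] = active_start);
}

// uniformity of one frame: interior adjacent differences of the sorted
// angles (N-1 of them), cumulative sums, against the equal-gap ideal 180/N
static double frame_uniformity(std::vector<double> &a) {
  const int n = a.size();
  if (n < 2) return NA_REAL;
  std::sort(a.begin(), a.end());
  std::vector<double> g(n - 1);
  for (int j = 0; j + 1 < n; ++j) g[j] = a[j + 1] - a[j];
  std::sort(g.begin(), g.end());
  double cs = 0.0, num = 0.0;
  for (int j = 0; j + 1 < n; ++j) { cs += g[j]; num += cs; }
  return num / (90.0 * (n - 1));
}

// [[Rcpp::export]]
NumericVector cpp_sliding_uniformity(NumericVector angles, int width) {
  const int n = angles.size();
  if (width < 2 || n < width) return NumericVector(0);
  NumericVector out(n - width + 1);
  std::vector<double> buf(width);
  for (int i = 0; i + width <= n; ++i) {
    for (int j = 0; j < width; ++j) buf[j] = angles[i + j];
    out[i] = frame_uniformity(buf);
  }
  return out;
}

// per-step uniformity of collated frames (multi-shot analysis of any log
// sharing the same ECG-derived match series); steps are 1-based in `steps`
// [[Rcpp::export]]
NumericVector cpp_collated_uniformity(NumericVector angles, IntegerMatrix match_idx,
                                      int Ns, int Nq, IntegerVector steps) {
  NumericVector out(steps.size());
  std::vector<int> idx;
  std::vector<double> frame;
  for (int s = 0; s < steps.size(); ++s) {
    const int i = steps[s] - 1;
    collate_idx(i, Ns, match_idx, Nq - 1, idx);
    frame.clear();
    for (size_t k = 0; k < idx.size(); ++k) frame.push_back(angles[idx[k]]);
    out[s] = frame_uniformity(frame);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_collate_one(int step, IntegerMatrix match_idx, int Ns, int Nq) {
  std::vector<int> idx;
  collate_idx(step - 1, Ns, match_idx, Nq - 1, idx);
  IntegerVector out(idx.size());
  for (size_t k = 0; k < idx.size(); ++k) out[k] = idx[k] + 1;
  return out;
}

// ---------------------------------------------------------------------------
// Kaiser-Bessel gridding of radial spokes onto a Cartesian k-space grid.
//
// Each spoke carries Nr samples at radii (-Nr/2 .. Nr/2-1) * dk with ramp
// density-compensation weight max(|k|, dk * center_frac).  Grid spacing is
// Nr*dk/G (G = 2*Nr gives the standard two-fold oversampled grid); the DC
// cell sits at 0-based index G/2.  Sample values are optional (PSF gridding
// uses pure weights); complex data are passed as re/im.
// ---------------------------------------------------------------------------
static inline double kb_kernel(double d, double half, double beta) {
  const double t = d / half;
  if (std::fabs(t) > 1.0) return 0.0;
  return R::bessel_i(beta * std::sqrt(1.0 - t * t), 0.0, 1.0);
}

// [[Rcpp::export]]
List cpp_grid_spokes(NumericVector theta_deg, int Nr, int G, double dk,
                     double kw, double beta, double center_frac,
                     Nullable<NumericMatrix> re_ = R_NilValue,
                     Nullable<NumericMatrix> im_ = R_NilValue) {
  NumericMatrix gre(G, G), gim(G, G);
  const bool have_data = re_.isNotNull();
  NumericMatrix re, im;
  if (have_data) { re = re_.get(); im = im_.get(); }
  const double dkg = (double)Nr * dk / G;
  const double half = kw / 2.0;
  const int nth = theta_deg.size();
  for (int j = 0; j < nth; ++j) {
    const double th = theta_deg[j] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    for (int s = 0; s < Nr; ++s) {
      const double kr = (s - Nr / 2) * dk;
      const double w = std::max(std::fabs(kr), dk * center_frac);
      const double vr = have_data ? re(j, s) * w : w;
      const double vi = have_data ? im(j, s) * w : 0.0;
      const double kx = kr * ct / dkg, ky = kr * st / dkg;
      const int x0 = (int)std::floor(kx - half), x1 = (int)std::ceil(kx + half);
      const int y0 = (int)std::floor(ky - half), y1 = (int)std::ceil(ky + half);
      for (int ix = x0; ix <= x1; ++ix) {
        const double wx = kb_kernel(ix - kx, half, beta);
        if (wx == 0.0) continue;
        const int gx = ((ix + G / 2) % G + G) % G;
        for (int iy = y0; iy <= y1; ++iy) {
          const double wy = kb_kernel(iy - ky, half, beta);
          if (wy == 0.0) continue;
          const int gy = ((iy + G / 2) % G + G) % G;
          gre(gx, gy) += vr * wx * wy;
          gim(gx, gy) += vi * wx * wy;
        }
      }
    }
  }
  return List::create(_["re"] = gre, _["im"] = gim);
}
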