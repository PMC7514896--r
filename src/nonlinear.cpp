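// O(n^2) kernels for delay-embedding analysis: correlation sums
// (Grassberger-Procaccia), false-nearest-neighbour fractions, Rosenstein
// nearest-neighbour divergence curves and recurrence-plot diagonal-line
// histograms.  Distances are Euclidean throughout.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static inline double dist2_rows(const NumericMatrix &e, int i, int j) {
  double d2 = 0.0;
  for (int k = 0; k < e.ncol(); ++k) {
    double d = e(i, k) - e(j, k);
    d2 += d * d;
  }
  return d2;
}

// Correlation counts: number of pairs (i < j, j - i > theiler) with
// distance < r, for each radius in `radii` (must be increasing).
// [[Rcpp::export]]
NumericVector corr_count_cpp(NumericMatrix emb, NumericVector radii,
                             int theiler) {
  int n = emb.nrow(), nr = radii.size();
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = radii[k] * radii[k];
  std::vector<double> hist(nr + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + theiler + 1; j < n; ++j) {
      double d2 = dist2_rows(emb, i, j);
      // the pair satisfies d < r_k for every radius index >= pos, where
      // pos is the first radius with r_k^2 > d^2 (strict inequality)
      int pos = std::upper_bound(r2.begin(), r2.end(), d2) - r2.begin();
      hist[pos] += 1.0;
    }
  }
  // counts with d < r_k: cumulative from the left-open histogram
  NumericVector out(nr);
  double acc = 0.0;
  for (int k = 0; k < nr; ++k) {
    acc += hist[k];
    out[k] = acc;
  }
  return out;
}

// Deterministically strided sample of pairwise distances (for radius
// quantiles).  Takes every `stride_i`-th point against every `stride_j`-th.
// [[Rcpp::export]]
NumericVector pair_dist_sample_cpp(NumericMatrix emb, int stride_i,
                                   int stride_j, int theiler) {
  int n = emb.nrow();
  std::vector<double> out;
  for (int i = 0; i < n; i += stride_i)
    for (int j = i + theiler + 1; j < n; j += stride_j)
      out.push_back(std::sqrt(dist2_rows(emb, i, j)));
  return NumericVector(out.begin(), out.end());
}

// False nearest neighbours (Kennel): for each embedding dimension m in
// 1..max_dim, the fraction of reference points whose nearest neighbour in
// dimension m fails the rtol or atol test when the (m+1)-th coordinate is
// appended.  References strided to at most max_ref points.
// [[Rcpp::export]]
NumericVector fnn_cpp(NumericVector x, int delay, int max_dim, double rtol,
                      double atol, int theiler, int max_ref) {
  int n = x.size();
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  double sd = 0.0;
  for (int i = 0; i < n; ++i) sd += (x[i] - mean) * (x[i] - mean);
  sd = std::sqrt(sd / (n - 1));

  NumericVector frac(max_dim, NA_REAL);
  for (int m = 1; m <= max_dim; ++m) {
    int npts = n - m * delay; // indices 0..npts-1 have the extra coordinate
    if (npts < 50) break;
    int stride = std::max(1, npts / max_ref);
    long nfalse = 0, ntot = 0;
    for (int i = 0; i < npts; i += stride) {
      double best = R_PosInf;
      int bj = -1;
      for (int j = 0; j < npts; ++j) {
        if (std::abs(i - j) <= theiler) continue;
        double d2 = 0.0;
        for (int k = 0; k < m; ++k) {
          double d = x[i + k * delay] - x[j + k * delay];
          d2 += d * d;
          if (d2 >= best) break;
        }
        if (d2 < best) {
          best = d2;
          bj = j;
        }
      }
      if (bj < 0) continue;
      double rm = std::sqrt(best);
      double extra = std::abs(x[i + m * delay] - x[bj + m * delay]);
      bool is_false;
      if (rm <= 1e-8 * sd) {
        // (near-)exact duplicates, e.g. periodic orbits: only a genuinely
        // distinct next coordinate marks a false neighbour, not rounding dust
        is_false = extra > 1e-8 * sd;
      } else {
        double rm1 = std::sqrt(best + extra * extra);
        is_false = (extra / rm > rtol) || (rm1 / sd > atol);
      }
      ++ntot;
      if (is_false) ++nfalse;
    }
    frac[m - 1] = ntot > 0 ? (double)nfalse / ntot : NA_REAL;
  }
  return frac;
}

// Rosenstein divergence: for strided reference points, find the nearest
// neighbour (temporal separation > theiler, distance > 0), then return the
// mean log distance between the pair images h steps ahead, h = 0..kmax.
// Distances below `floor_dist` are clipped to it: for quantised series
// (e.g. spike counts) pairs can coincide exactly, and the clip encodes that
// states are indistinguishable below the quantisation scale.
// [[Rcpp::export]]
List nn_divergence_cpp(NumericMatrix emb, int theiler, int kmax, int max_ref,
                       double floor_dist = 0.0) {
  int n = emb.nrow();
  int stride = std::max(1, n / max_ref);
  std::vector<int> ri, rj;
  for (int i = 0; i < n; i += stride) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < n; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d2 = dist2_rows(emb, i, j);
      if (d2 > 0.0 && d2 < best) {
        best = d2;
        bj = j;
      }
    }
    if (bj >= 0) {
      ri.push_back(i);
      rj.push_back(bj);
    }
  }
  NumericVector curve(kmax + 1, NA_REAL);
  IntegerVector npairs(kmax + 1, 0);
  const double dmin = (floor_dist > 0.0) ? floor_dist : 1e-12;
  for (int h = 0; h <= kmax; ++h) {
    double acc = 0.0;
    int cnt = 0;
    for (size_t p = 0; p < ri.size(); ++p) {
      int i = ri[p] + h, j = rj[p] + h;
      if (i >= n || j >= n) continue;
      double d = std::sqrt(dist2_rows(emb, i, j));
      acc += std::log(d > dmin ? d : dmin);
      ++cnt;
    }
    if (cnt > 0) {
      curve[h] = acc / cnt;
      npairs[h] = cnt;
    }
  }
  return List::create(_["log_divergence"] = curve, _["n_pairs"] = npairs);
}

// Diagonal-line structure of the recurrence plot at a fixed radius.
// Walks the upper-triangle diagonals (offset k >= 1); returns the lengths of
// interior recurrent runs (runs touching the plot border are censored, which
// removes the border-truncation artefact that otherwise dominates strictly
// periodic signals), plus the recurrent pair count for the recurrence rate.
// [[Rcpp::export]]
List diag_lines_cpp(NumericMatrix emb, double radius, int theiler) {
  int n = emb.nrow();
  double r2 = radius * radius;
  std::vector<int> lengths;
  double rec_pairs = 0.0, tot_pairs = 0.0;
  for (int k = 1; k < n; ++k) {
    int len = n - k;
    int run = 0;
    bool at_start_border = true;
    for (int i = 0; i < len; ++i) {
      bool rec = dist2_rows(emb, i, i + k) < r2;
      if (k > theiler) {
        tot_pairs += 1.0;
        if (rec) rec_pairs += 1.0;
      }
      if (rec) {
        ++run;
      } else {
        if (run > 0 && !at_start_border && k > theiler) lengths.push_back(run);
        run = 0;
        at_start_border = false;
      }
    }
    // a run still open at the end touches the border: censored
  }
  return List::create(_["lengths"] = IntegerVector(lengths.begin(), lengths.end()),
                      _["recurrence_rate"] =
                          tot_pairs > 0 ? rec_pairs / tot_pairs : NA_REAL);
}
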