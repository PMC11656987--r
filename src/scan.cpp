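#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window PWM scan with a range-relative score threshold.
// codes: 0..3 base codes, negative = unknown (N); windows touching an
// unknown base never count as occurrences.
// score: 4 x w matrix of per-base log-odds scores (rows A,C,G,T).
// Threshold is min + rel * (max - min) of the attainable score range.

static double range_threshold(const NumericMatrix& score, double rel,
                              double* out_min, double* out_max) {
  double lo = 0.0, hi = 0.0;
  int w = score.ncol();
  for (int j = 0; j < w; ++j) {
    double cmin = score(0, j), cmax = score(0, j);
    for (int b = 1; b < 4; ++b) {
      cmin = std::min(cmin, score(b, j));
      cmax = std::max(cmax, score(b, j));
    }
    lo += cmin;
    hi += cmax;
  }
  if (out_min) *out_min = lo;
  if (out_max) *out_max = hi;
  return lo + rel * (hi - lo);
}

// [[Rcpp::export]]
IntegerVector scan_pwm_positions_cpp(IntegerVector codes, NumericMatrix score,
                                     double rel_threshold) {
  int L = codes.size(), w = score.ncol();
  std::vector<int> hits;
  if (L >= w) {
    double thr = range_threshold(score, rel_threshold, nullptr, nullptr);
    for (int p = 0; p + w <= L; ++p) {
      double s = 0.0;
      bool ok = true;
      for (int j = 0; j < w; ++j) {
        int b = codes[p + j];
        if (b < 0 || b > 3) { ok = false; break; }
        s += score(b, j);
      }
      if (ok && s >= thr - 1e-12) hits.push_back(p);
    }
  }
  return wrap(hits);
}

// [[Rcpp::export]]
IntegerMatrix scan_pwm_counts_cpp(List code_list, List score_list,
                                  double rel_threshold) {
  int n = code_list.size(), m = score_list.size();
  IntegerMatrix out(n, m);
  std::vector<NumericMatrix> scores;
  std::vector<double> thr(m);
  scores.reserve(m);
  for (int k = 0; k < m; ++k) {
    NumericMatrix s = score_list[k];
    scores.push_back(s);
    thr[k] = range_threshold(s, rel_threshold, nullptr, nullptr);
  }
  for (int i = 0; i < n; ++i) {
    IntegerVector codes = code_list[i];
    int L = codes.size();
    for (int k = 0; k < m; ++k) {
      const NumericMatrix& sc = scores[k];
      int w = sc.ncol();
      if (L < w) { out(i, k) = 0; continue; }
      int cnt = 0;
      for (int p = 0; p + w <= L; ++p) {
        double s = 0.0;
        bool ok = true;
        for (int j = 0; j < w; ++j) {
          int b = codes[p + j];
          if (b < 0 || b > 3) { ok = false; break; }
          s += sc(b, j);
        }
        if (ok && s >= thr[k] - 1e-12) ++cnt;
      }
      out(i, k) = cnt;
    }
  }
  return out;
}
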