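// Shallow-network training engine for code/document embeddings.
// Single-threaded with a private 64-bit LCG stream, so runs are
// bit-reproducible for a given seed. Matrices are modified in place; the
// R caller owns freshly allocated buffers.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Lcg {
  uint64_t state;
  explicit Lcg(uint64_t seed) : state(seed ? seed : 88172645463325252ULL) {}
  uint64_t next_raw() {
    state = state * 6364136223846793005ULL + 1442695040888963407ULL;
    return state;
  }
  double uniform() {  // in [0, 1)
    return (double)(next_raw() >> 11) * (1.0 / 9007199254740992.0);
  }
  int below(int n) { return (int)(uniform() * n); }
};

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Draw from the noise distribution via inverse CDF (binary search),
// rejecting `exclude`.
inline int draw_noise(const std::vector<double>& cdf, Lcg& rng, int exclude) {
  const int V = (int)cdf.size();
  for (;;) {
    double u = rng.uniform();
    int lo = 0, hi = V - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cdf[mid] < u) lo = mid + 1; else hi = mid;
    }
    if (lo != exclude) return lo;
    if (V == 1) return lo;  // degenerate; cannot exclude
  }
}

// One SGD update for a (mean-of-inputs -> target) pair.
//  h          : mean of the input vectors (length M)
//  neu1e      : accumulates the gradient w.r.t. h (caller applies /k to inputs)
//  ctx        : V x M output matrix for negative sampling (column-major, R)
//  hsw        : (V-1) x M output matrix for hierarchical softmax
// Returns nothing; updates ctx/hsw in place unless freeze_out.
inline void update_output(const double* h, double* neu1e,
                          double* ctx, int Vc,
                          double* hsw, int Vh,
                          int target, int M,
                          int negative, const std::vector<double>* cdf,
                          const int* hs_points, const int* hs_bits, int hs_len,
                          double lr, Lcg& rng, bool freeze_out) {
  if (negative > 0) {
    for (int k = 0; k <= negative; ++k) {
      int s; double label;
      if (k == 0) { s = target; label = 1.0; }
      else { s = draw_noise(*cdf, rng, target); label = 0.0; }
      double* row = ctx;  // column-major: element (s, j) at s + j*Vc
      double f = 0.0;
      for (int j = 0; j < M; ++j) f += h[j] * row[s + (size_t)j * Vc];
      double g = (label - sigmoid(f)) * lr;
      for (int j = 0; j < M; ++j) {
        neu1e[j] += g * row[s + (size_t)j * Vc];
        if (!freeze_out) row[s + (size_t)j * Vc] += g * h[j];
      }
    }
  }
  if (hs_len > 0) {
    for (int d = 0; d < hs_len; ++d) {
      int p = hs_points[d];
      double f = 0.0;
      for (int j = 0; j < M; ++j) f += h[j] * hsw[p + (size_t)j * Vh];
      double g = (1.0 - hs_bits[d] - sigmoid(f)) * lr;
      for (int j = 0; j < M; ++j) {
        neu1e[j] += g * hsw[p + (size_t)j * Vh];
        if (!freeze_out) hsw[p + (size_t)j * Vh] += g * h[j];
      }
    }
  }
}

struct HsPaths {
  std::vector<std::vector<int>> points;
  std::vector<std::vector<int>> bits;
  bool active = false;
};

HsPaths unpack_hs(Nullable<List> hs_points, Nullable<List> hs_bits) {
  HsPaths out;
  if (hs_points.isNotNull() && hs_bits.isNotNull()) {
    List p(hs_points), b(hs_bits);
    out.active = p.size() > 0;
    out.points.resize(p.size());
    out.bits.resize(b.size());
    for (int i = 0; i < p.size(); ++i) {
      IntegerVector pi = p[i], bi = b[i];
      out.points[i].assign(pi.begin(), pi.end());
      out.bits[i].assign(bi.begin(), bi.end());
    }
  }
  return out;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_init_matrix(int n, int m, double scale, int seed) {
  Lcg rng((uint64_t)seed * 2654435761ULL + 1013904223ULL);
  NumericMatrix out(n, m);
  // row-major fill so each row is a contiguous draw sequence
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      out(i, j) = (rng.uniform() * 2.0 - 1.0) * scale;
  return out;
}

// Train one epoch over `docs` (0-based token index vectors). doc_rows maps
// each doc to its row in doc_vec. Returns the updated processed-position
// counter (for the linear alpha schedule shared across epochs).
//' @noRd
// [[Rcpp::export]]
double cpp_train_epoch(List docs, IntegerVector doc_rows,
                       NumericMatrix code_vec, NumericMatrix ctx_vec,
                       NumericMatrix hs_vec, NumericMatrix doc_vec,
                       NumericVector noise_cdf, NumericVector keep_prob,
                       Nullable<List> hs_points, Nullable<List> hs_bits,
                       bool dm, int window, bool reduce_window,
                       int negative,
                       double alpha0, double alpha_min,
                       double processed, double total_positions,
                       int seed) {
  const int M = code_vec.ncol();
  const int Vc = ctx_vec.nrow();
  const int Vh = hs_vec.nrow();
  const int Nd = doc_vec.nrow();
  Lcg rng((uint64_t)seed * 6364136223846793005ULL + 97ULL);
  std::vector<double> cdf(noise_cdf.begin(), noise_cdf.end());
  HsPaths hs = unpack_hs(hs_points, hs_bits);
  const bool downsample = keep_prob.size() > 0;
  std::vector<double> h(M), neu1e(M);
  std::vector<int> kept;
  double* code = REAL(code_vec);
  double* ctx = REAL(ctx_vec);
  double* hsw = REAL(hs_vec);
  double* dvec = REAL(doc_vec);
  const int Vcode = code_vec.nrow();

  for (int d = 0; d < docs.size(); ++d) {
    IntegerVector doc = docs[d];
    const int drow = doc_rows[d];
    const int n_raw = doc.size();
    kept.clear();
    if (downsample) {
      for (int t = 0; t < n_raw; ++t)
        if (rng.uniform() < keep_prob[doc[t]]) kept.push_back(doc[t]);
    } else {
      kept.assign(doc.begin(), doc.end());
    }
    const int n = (int)kept.size();
    for (int t = 0; t < n; ++t) {
      double frac = processed / total_positions;
      if (frac > 1.0) frac = 1.0;
      double lr = alpha0 - (alpha0 - alpha_min) * frac;
      if (lr < alpha_min) lr = alpha_min;
      processed += 1.0;

      int b = reduce_window ? 1 + rng.below(window) : window;
      int lo = t - b; if (lo < 0) lo = 0;
      int hi = t + b; if (hi > n - 1) hi = n - 1;
      int target = kept[t];
      const int* tpts = hs.active ? hs.points[target].data() : nullptr;
      const int* tbts = hs.active ? hs.bits[target].data() : nullptr;
      int tlen = hs.active ? (int)hs.points[target].size() : 0;

      if (dm) {
        // mean of doc vector and in-window context code vectors -> target
        int k = 1;
        for (int j = 0; j < M; ++j) h[j] = dvec[drow + (size_t)j * Nd];
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          ++k;
          for (int j = 0; j < M; ++j) h[j] += code[kept[c] + (size_t)j * Vcode];
        }
        for (int j = 0; j < M; ++j) { h[j] /= k; neu1e[j] = 0.0; }
        update_output(h.data(), neu1e.data(), ctx, Vc, hsw, Vh, target, M,
                      negative, &cdf, tpts, tbts, tlen, lr, rng, false);
        for (int j = 0; j < M; ++j) {
          double g = neu1e[j] / k;
          dvec[drow + (size_t)j * Nd] += g;
        }
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          for (int j = 0; j < M; ++j)
            code[kept[c] + (size_t)j * Vcode] += neu1e[j] / k;
        }
      } else {
        // DBOW: interleaved skip-gram (center code -> each context code) ...
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          int out_tok = kept[c];
          const int* cp = hs.active ? hs.points[out_tok].data() : nullptr;
          const int* cb = hs.active ? hs.bits[out_tok].data() : nullptr;
          int cl = hs.active ? (int)hs.points[out_tok].size() : 0;
          for (int j = 0; j < M; ++j) {
            h[j] = code[target + (size_t)j * Vcode];
            neu1e[j] = 0.0;
          }
          update_output(h.data(), neu1e.data(), ctx, Vc, hsw, Vh, out_tok, M,
                        negative, &cdf, cp, cb, cl, lr, rng, false);
          for (int j = 0; j < M; ++j)
            code[target + (size_t)j * Vcode] += neu1e[j];
        }
        // ... then document vector -> target token
        for (int j = 0; j < M; ++j) {
          h[j] = dvec[drow + (size_t)j * Nd];
          neu1e[j] = 0.0;
        }
        update_output(h.data(), neu1e.data(), ctx, Vc, hsw, Vh, target, M,
                      negative, &cdf, tpts, tbts, tlen, lr, rng, false);
        for (int j = 0; j < M; ++j) dvec[drow + (size_t)j * Nd] += neu1e[j];
      }
    }
  }
  return processed;
}

// Infer a document vector with all word/context/hs weights frozen.
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_infer_doc(IntegerVector doc,
                            NumericMatrix code_vec, NumericMatrix ctx_vec,
                            NumericMatrix hs_vec,
                            NumericVector noise_cdf, NumericVector keep_prob,
                            Nullable<List> hs_points, Nullable<List> hs_bits,
                            bool dm, int window, bool reduce_window,
                            int negative, int epochs,
                            double alpha0, double alpha_min, int seed) {
  const int M = code_vec.ncol();
  const int Vc = ctx_vec.nrow();
  const int Vh = hs_vec.nrow();
  const int Vcode = code_vec.nrow();
  Lcg rng((uint64_t)seed * 6364136223846793005ULL + 193ULL);
  std::vector<double> cdf(noise_cdf.begin(), noise_cdf.end());
  HsPaths hs = unpack_hs(hs_points, hs_bits);
  const bool downsample = keep_prob.size() > 0;
  std::vector<double> dv(M), h(M), neu1e(M);
  for (int j = 0; j < M; ++j)
    dv[j] = (rng.uniform() * 2.0 - 1.0) * (0.5 / M);
  double* code = REAL(code_vec);
  double* ctx = REAL(ctx_vec);
  double* hsw = REAL(hs_vec);
  const double total = (double)epochs * doc.size();
  double processed = 0.0;
  std::vector<int> kept;

  for (int ep = 0; ep < epochs; ++ep) {
    kept.clear();
    if (downsample) {
      for (int t = 0; t < doc.size(); ++t)
        if (rng.uniform() < keep_prob[doc[t]]) kept.push_back(doc[t]);
    } else {
      kept.assign(doc.begin(), doc.end());
    }
    const int n = (int)kept.size();
    for (int t = 0; t < n; ++t) {
      double frac = processed / total;
      if (frac > 1.0) frac = 1.0;
      double lr = alpha0 - (alpha0 - alpha_min) * frac;
      if (lr < alpha_min) lr = alpha_min;
      processed += 1.0;
      int b = reduce_window ? 1 + rng.below(window) : window;
      int lo = t - b; if (lo < 0) lo = 0;
      int hi = t + b; if (hi > n - 1) hi = n - 1;
      int target = kept[t];
      const int* tpts = hs.active ? hs.points[target].data() : nullptr;
      const int* tbts = hs.active ? hs.bits[target].data() : nullptr;
      int tlen = hs.active ? (int)hs.points[target].size() : 0;

      int k = 1;
      for (int j = 0; j < M; ++j) h[j] = dv[j];
      if (dm) {
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          ++k;
          for (int j = 0; j < M; ++j) h[j] += code[kept[c] + (size_t)j * Vcode];
        }
        for (int j = 0; j < M; ++j) h[j] /= k;
      }
      for (int j = 0; j < M; ++j) neu1e[j] = 0.0;
      update_output(h.data(), neu1e.data(), ctx, Vc, hsw, Vh, target, M,
                    negative, &cdf, tpts, tbts, tlen, lr, rng, true);
      for (int j = 0; j < M; ++j) dv[j] += neu1e[j] / k;
    }
  }
  return NumericVector(dv.begin(), dv.end());
}

// Single SGD steps exposed for gradient verification. Inputs are the k
// input vectors whose mean forms the hidden activation; outs are the rows
// of the output matrix touched by the update (negative sampling: target
// first with label 1, then negatives with label 0; hierarchical softmax:
// the path nodes with their branch bits).
//' @noRd
// [[Rcpp::export]]
List cpp_sgd_step_ns(NumericMatrix inputs, NumericMatrix outs,
                     IntegerVector labels, double lr) {
  const int k = inputs.nrow(), M = inputs.ncol(), n = outs.nrow();
  NumericMatrix in2 = clone(inputs), out2 = clone(outs);
  std::vector<double> h(M, 0.0), neu1e(M, 0.0);
  for (int j = 0; j < M; ++j) {
    for (int i = 0; i < k; ++i) h[j] += inputs(i, j);
    h[j] /= k;
  }
  for (int s = 0; s < n; ++s) {
    double f = 0.0;
    for (int j = 0; j < M; ++j) f += h[j] * outs(s, j);
    double g = ((double)labels[s] - sigmoid(f)) * lr;
    for (int j = 0; j < M; ++j) {
      neu1e[j] += g * outs(s, j);
      out2(s, j) += g * h[j];
    }
  }
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < M; ++j) in2(i, j) += neu1e[j] / k;
  return List::create(_["inputs"] = in2, _["outs"] = out2);
}

//' @noRd
// [[Rcpp::export]]
List cpp_sgd_step_hs(NumericMatrix inputs, NumericMatrix outs,
                     IntegerVector bits, double lr) {
  const int k = inputs.nrow(), M = inputs.ncol(), n = outs.nrow();
  NumericMatrix in2 = clone(inputs), out2 = clone(outs);
  std::vector<double> h(M, 0.0), neu1e(M, 0.0);
  for (int j = 0; j < M; ++j) {
    for (int i = 0; i < k; ++i) h[j] += inputs(i, j);
    h[j] /= k;
  }
  for (int s = 0; s < n; ++s) {
    double f = 0.0;
    for (int j = 0; j < M; ++j) f += h[j] * outs(s, j);
    double g = (1.0 - (double)bits[s] - sigmoid(f)) * lr;
    for (int j = 0; j < M; ++j) {
      neu1e[j] += g * outs(s, j);
      out2(s, j) += g * h[j];
    }
  }
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < M; ++j) in2(i, j) += neu1e[j] / k;
  return List::create(_["inputs"] = in2, _["outs"] = out2);
}
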