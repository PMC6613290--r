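// Paragraph-vector training (distributed bag-of-words and distributed-memory
// variants) with negative sampling. Single-threaded with an internal seeded
// RNG so that identical inputs always give bit-identical vectors.
//
// Vectors are stored column-major: each column of a (dim x n) matrix is one
// document/word vector, so dot products run over contiguous memory.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

static inline double urand(uint64_t &s) {
  return static_cast<double>(xorshift64(s) >> 11) / 9007199254740992.0; // [0,1)
}

static inline int randint(uint64_t &s, int n) {
  return static_cast<int>(urand(s) * n) % n;
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// one negative-sampling step: input vector `in` predicts word `target`
// against output matrix `out` (dim x vocab); gradient for the input side is
// accumulated into `grad` (caller applies it)
static void ns_update(double *in, double *out, int dim, int target,
                      const int *table, int table_size, int negative,
                      double alpha, uint64_t &rng, std::vector<double> &grad,
                      bool update_out = true) {
  std::fill(grad.begin(), grad.end(), 0.0);
  for (int k = 0; k <= negative; ++k) {
    int label, w;
    if (k == 0) {
      label = 1;
      w = target;
    } else {
      label = 0;
      w = table[randint(rng, table_size)];
      if (w == target) continue;
    }
    double *ov = out + static_cast<size_t>(w) * dim;
    double f = 0.0;
    for (int j = 0; j < dim; ++j) f += in[j] * ov[j];
    double g = (label - sigmoid(f)) * alpha;
    for (int j = 0; j < dim; ++j) grad[j] += g * ov[j];
    if (update_out)
      for (int j = 0; j < dim; ++j) ov[j] += g * in[j];
  }
}

static void init_matrix(NumericMatrix &m, uint64_t &rng, double scale) {
  const R_xlen_t n = m.nrow() * static_cast<R_xlen_t>(m.ncol());
  double *p = REAL(m);
  for (R_xlen_t i = 0; i < n; ++i) p[i] = (urand(rng) - 0.5) * scale;
}

// [[Rcpp::export]]
List pv_train_cpp(List docs, int vocab_size, IntegerVector neg_table, int dim,
                  int window, int epochs, int negative, double alpha,
                  double min_alpha, bool dm, int seed) {
  const int n_docs = docs.size();
  const int table_size = neg_table.size();
  const int *table = INTEGER(neg_table);
  uint64_t rng = static_cast<uint64_t>(seed) * 2654435761u + 1u;

  NumericMatrix doc_vec(dim, n_docs);
  NumericMatrix word_out(dim, vocab_size);
  NumericMatrix word_in(dim, dm ? vocab_size : 1);
  init_matrix(doc_vec, rng, 1.0 / dim);
  if (dm) init_matrix(word_in, rng, 1.0 / dim);
  // word_out starts at zero (standard negative-sampling initialisation)

  std::vector<const int *> dptr(n_docs);
  std::vector<int> dlen(n_docs);
  double total_words = 0.0;
  for (int d = 0; d < n_docs; ++d) {
    IntegerVector v = docs[d];
    dptr[d] = INTEGER(v);
    dlen[d] = v.size();
    total_words += dlen[d];
  }

  std::vector<double> grad(dim), ctx(dim);
  const double span = total_words * epochs + 1.0;
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < n_docs; ++d) {
      double *dv = REAL(doc_vec) + static_cast<size_t>(d) * dim;
      const int *w = dptr[d];
      const int len = dlen[d];
      for (int t = 0; t < len; ++t) {
        double a = alpha * (1.0 - processed / span);
        if (a < min_alpha) a = min_alpha;
        processed += 1.0;
        const int target = w[t];
        if (!dm) {
          ns_update(dv, REAL(word_out), dim, target, table, table_size,
                    negative, a, rng, grad);
          for (int j = 0; j < dim; ++j) dv[j] += grad[j];
        } else {
          // distributed memory: mean of doc vector and context word vectors
          int b = randint(rng, window) + 1; // sampled effective window
          int cnt = 1;
          for (int j = 0; j < dim; ++j) ctx[j] = dv[j];
          for (int c = t - b; c <= t + b; ++c) {
            if (c == t || c < 0 || c >= len) continue;
            const double *wv = REAL(word_in) + static_cast<size_t>(w[c]) * dim;
            for (int j = 0; j < dim; ++j) ctx[j] += wv[j];
            ++cnt;
          }
          for (int j = 0; j < dim; ++j) ctx[j] /= cnt;
          ns_update(ctx.data(), REAL(word_out), dim, target, table, table_size,
                    negative, a, rng, grad);
          for (int j = 0; j < dim; ++j) dv[j] += grad[j];
          for (int c = t - b; c <= t + b; ++c) {
            if (c == t || c < 0 || c >= len) continue;
            double *wv = REAL(word_in) + static_cast<size_t>(w[c]) * dim;
            for (int j = 0; j < dim; ++j) wv[j] += grad[j];
          }
        }
      }
    }
  }

  return List::create(_["doc_vectors"] = doc_vec, _["word_out"] = word_out,
                      _["word_in"] = word_in);
}

// [[Rcpp::export]]
NumericVector pv_infer_cpp(IntegerVector doc, NumericMatrix word_out,
                           NumericMatrix word_in, IntegerVector neg_table,
                           int window, int epochs, int negative, double alpha,
                           double min_alpha, bool dm, int seed) {
  const int dim = word_out.nrow();
  const int table_size = neg_table.size();
  const int *table = INTEGER(neg_table);
  uint64_t rng = static_cast<uint64_t>(seed) * 2654435761u + 1u;

  NumericVector dvec(dim);
  double *dv = REAL(dvec);
  for (int j = 0; j < dim; ++j) dv[j] = (urand(rng) - 0.5) / dim;

  const int len = doc.size();
  if (len == 0) return dvec; // inference prior only (flagged upstream)
  const int *w = INTEGER(doc);

  // word matrices stay frozen at inference; only the new document vector
  // is trained
  std::vector<double> grad(dim), ctx(dim);
  const double span = static_cast<double>(len) * epochs + 1.0;
  double processed = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int t = 0; t < len; ++t) {
      double a = alpha * (1.0 - processed / span);
      if (a < min_alpha) a = min_alpha;
      processed += 1.0;
      const int target = w[t];
      if (!dm) {
        ns_update(dv, REAL(word_out), dim, target, table, table_size,
                  negative, a, rng, grad, false);
        for (int j = 0; j < dim; ++j) dv[j] += grad[j];
      } else {
        int b = randint(rng, window) + 1;
        int cnt = 1;
        for (int j = 0; j < dim; ++j) ctx[j] = dv[j];
        for (int c = t - b; c <= t + b; ++c) {
          if (c == t || c < 0 || c >= len) continue;
          const double *wv = REAL(word_in) + static_cast<size_t>(w[c]) * dim;
          for (int j = 0; j < dim; ++j) ctx[j] += wv[j];
          ++cnt;
        }
        for (int j = 0; j < dim; ++j) ctx[j] /= cnt;
        ns_update(ctx.data(), REAL(word_out), dim, target, table, table_size,
                  negative, a, rng, grad, false);
        for (int j = 0; j < dim; ++j) dv[j] += grad[j];
      }
    }
  }
  return dvec;
}
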