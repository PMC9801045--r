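// Low-level numerical kernels for the sequence network and motif scanner.
//
// Activations flow as (channels, positions, batch) arma::cubes.  To avoid
// copying large tensors across the R boundary on every layer call, cubes and
// layer caches are held in C++ and exposed to R as external pointers; R only
// orchestrates the layer sequence and owns the (small) parameter matrices.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Minibatch training allocates and frees many identically sized tensors.
// By default glibc serves large buffers with mmap and unmaps them on free,
// so every batch pays the page-fault cost again; keeping such buffers on
// the heap lets them be reused.
#ifdef __GLIBC__
struct MallocTuning {
  MallocTuning() {
    mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
  }
};
static MallocTuning malloc_tuning;
#endif

// Fast deterministic stream for dropout masks, seeded from R's RNG (one
// draw per layer call) so results remain reproducible under set.seed()
// without paying for millions of R RNG calls.
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  inline double next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z = z ^ (z >> 31);
    return (double)(z >> 11) * (1.0 / 9007199254740992.0);
  }
};

typedef XPtr<arma::cube> CubePtr;

// ---- tensor arena --------------------------------------------------------
//
// Minibatch passes allocate many large, identically shaped tensors whose R
// handles are only reclaimed at garbage collection; waiting for the GC means
// every batch touches fresh pages.  Instead, tensors live in a C++ arena:
// handles returned to R carry no finalizer, and cpp_pool_reset() (called by
// the R training/prediction loops at the end of each batch, when no handle
// from the batch is used again) recycles everything allocated since the
// previous reset.

static std::vector<arma::cube*> g_active;
static std::unordered_multimap<size_t, arma::cube*> g_free;

static arma::cube* alloc_cube(arma::uword r, arma::uword c, arma::uword s) {
  size_t n = (size_t)r * c * s;
  arma::cube* p;
  std::unordered_multimap<size_t, arma::cube*>::iterator it = g_free.find(n);
  if (it != g_free.end()) {
    p = it->second;
    g_free.erase(it);
    p->set_size(r, c, s);
  } else {
    p = new arma::cube(r, c, s);
  }
  g_active.push_back(p);
  return p;
}

struct PostCache;
static std::vector<PostCache*> g_active_pc;
static std::vector<PostCache*> g_free_pc;
static std::vector<arma::icube*> g_active_ic;
static std::unordered_multimap<size_t, arma::icube*> g_free_ic;

static arma::icube* alloc_icube(arma::uword r, arma::uword c,
                                arma::uword s) {
  size_t n = (size_t)r * c * s;
  arma::icube* p;
  std::unordered_multimap<size_t, arma::icube*>::iterator it =
    g_free_ic.find(n);
  if (it != g_free_ic.end()) {
    p = it->second;
    g_free_ic.erase(it);
    p->set_size(r, c, s);
  } else {
    p = new arma::icube(r, c, s);
  }
  g_active_ic.push_back(p);
  return p;
}

// [[Rcpp::export]]
void cpp_pool_reset() {
  for (size_t i = 0; i < g_active.size(); ++i)
    g_free.insert(std::make_pair((size_t)g_active[i]->n_elem, g_active[i]));
  g_active.clear();
  for (size_t i = 0; i < g_active_ic.size(); ++i)
    g_free_ic.insert(std::make_pair((size_t)g_active_ic[i]->n_elem,
                                    g_active_ic[i]));
  g_active_ic.clear();
  for (size_t i = 0; i < g_active_pc.size(); ++i)
    g_free_pc.push_back(g_active_pc[i]);
  g_active_pc.clear();
}

static arma::cube& deref(SEXP p) {
  CubePtr xp(p);
  return *xp;
}

static SEXP make_cube(arma::cube* c) {
  return CubePtr(c, false);
}

// ---- R-side helpers for tests and feature code ---------------------------

// [[Rcpp::export]]
SEXP cpp_cube_create(const arma::cube& x) {
  arma::cube* out = alloc_cube(x.n_rows, x.n_cols, x.n_slices);
  *out = x;
  return make_cube(out);
}

// [[Rcpp::export]]
arma::cube cpp_cube_get(SEXP p) {
  return deref(p);
}

// [[Rcpp::export]]
IntegerVector cpp_cube_dims(SEXP p) {
  const arma::cube& x = deref(p);
  return IntegerVector::create((int)x.n_rows, (int)x.n_cols,
                               (int)x.n_slices);
}

// [[Rcpp::export]]
SEXP cpp_cube_add(SEXP a, SEXP b) {
  const arma::cube& ca = deref(a);
  arma::cube* out = alloc_cube(ca.n_rows, ca.n_cols, ca.n_slices);
  *out = ca + deref(b);
  return make_cube(out);
}

// [[Rcpp::export]]
void cpp_cube_add_inplace(SEXP a, SEXP b) {
  deref(a) += deref(b);
}

// One-hot encode integer-coded sequences (0 = N/ambiguous, 1..4 = A,C,G,T).
// seqs: batch x length integer matrix. Returns an R array (4, length, batch).
// [[Rcpp::export]]
arma::cube cpp_onehot(const IntegerMatrix& seqs) {
  const int B = seqs.nrow(), P = seqs.ncol();
  arma::cube out(4, P, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int p = 0; p < P; ++p) {
      int code = seqs(b, p);
      if (code >= 1 && code <= 4) out(code - 1, p, b) = 1.0;
    }
  }
  return out;
}

// ---- first-layer convolution on integer sequences ------------------------

// W: (F, 4*K) with position-major blocks of the 4 bases, i.e. a 4xK kernel
// per filter; exploits one-hot sparsity.  Ambiguous bases contribute 0.
// [[Rcpp::export]]
SEXP cpp_seqconv_fw(const IntegerMatrix& seqs, const arma::mat& W,
                    const arma::vec& b, int K) {
  const int B = seqs.nrow(), len = seqs.ncol(), F = W.n_rows;
  const int Pout = len - K + 1;
  if (Pout < 1) stop("sequence shorter than first-layer kernel");
  arma::cube* out = alloc_cube(F, Pout, B);
  std::vector<int> row(len);
  for (int s = 0; s < B; ++s) {
    arma::mat& os = out->slice(s);
    for (int p = 0; p < len; ++p) row[p] = seqs(s, p);
    for (int p = 0; p < Pout; ++p) {
      double* col = os.colptr(p);
      std::copy(b.memptr(), b.memptr() + F, col);
      for (int j = 0; j < K; ++j) {
        int code = row[p + j];
        if (code >= 1) {
          const double* wc = W.colptr(4 * j + code - 1);
          for (int f = 0; f < F; ++f) col[f] += wc[f];
        }
      }
    }
  }
  return make_cube(out);
}

// Weight/bias gradients of cpp_seqconv_fw (input gradients are not needed
// at the input layer).
// [[Rcpp::export]]
List cpp_seqconv_bw(const IntegerMatrix& seqs, SEXP gout_p, int K) {
  const arma::cube& gout = deref(gout_p);
  const int B = seqs.nrow(), F = gout.n_rows, Pout = gout.n_cols;
  arma::mat gW(F, 4 * K, arma::fill::zeros);
  arma::vec gb(F, arma::fill::zeros);
  const int len = seqs.ncol();
  std::vector<int> row(len);
  for (int s = 0; s < B; ++s) {
    const arma::mat& gs = gout.slice(s);
    for (int p = 0; p < len; ++p) row[p] = seqs(s, p);
    for (int p = 0; p < Pout; ++p) {
      const double* g = gs.colptr(p);
      for (int f = 0; f < F; ++f) gb[f] += g[f];
      for (int j = 0; j < K; ++j) {
        int code = row[p + j];
        if (code >= 1) {
          double* wc = gW.colptr(4 * j + code - 1);
          for (int f = 0; f < F; ++f) wc[f] += g[f];
        }
      }
    }
  }
  return List::create(_["gW"] = gW, _["gb"] = gb);
}

// ---- general 1D convolution (im2col + GEMM) ------------------------------

static arma::mat im2col(const arma::cube& x, int K, int pad) {
  const int C = x.n_rows, P = x.n_cols, B = x.n_slices;
  const int Pout = P + 2 * pad - K + 1;
  arma::mat cols(C * K, (arma::uword)Pout * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const arma::mat& xb = x.slice(b);
    for (int p = 0; p < Pout; ++p) {
      double* dst = cols.colptr((arma::uword)b * Pout + p);
      int lo = p - pad;
      if (lo >= 0 && lo + K <= P) {
        std::copy(xb.colptr(lo), xb.colptr(lo) + (arma::uword)C * K, dst);
      } else {
        for (int k = 0; k < K; ++k) {
          int src = lo + k;
          if (src >= 0 && src < P) {
            std::copy(xb.colptr(src), xb.colptr(src) + C,
                      dst + (arma::uword)k * C);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
SEXP cpp_conv1d_fw(SEXP x_p, const arma::mat& W, const arma::vec& b,
                   int K, int pad) {
  const arma::cube& x = deref(x_p);
  const int B = x.n_slices, P = x.n_cols;
  const int Pout = P + 2 * pad - K + 1;
  if (Pout < 1) stop("convolution output has no positions");
  arma::cube* out = alloc_cube(W.n_rows, Pout, B);
  arma::mat y(out->memptr(), W.n_rows, (arma::uword)Pout * B, false, true);
  if (K == 1 && pad == 0) {
    arma::mat xm(const_cast<double*>(x.memptr()), x.n_rows,
                 (arma::uword)P * B, false, true);
    y = W * xm;
  } else {
    y = W * im2col(x, K, pad);
  }
  y.each_col() += b;
  return make_cube(out);
}

// [[Rcpp::export]]
List cpp_conv1d_bw(SEXP x_p, const arma::mat& W, SEXP gout_p, int K,
                   int pad) {
  const arma::cube& x = deref(x_p);
  const arma::cube& gout = deref(gout_p);
  const int C = x.n_rows, P = x.n_cols, B = x.n_slices;
  const int Pout = gout.n_cols;
  arma::mat gy(const_cast<double*>(gout.memptr()), gout.n_rows,
               (arma::uword)Pout * B, false, true);
  arma::vec gb = arma::sum(gy, 1);
  if (K == 1 && pad == 0) {
    arma::mat xm(const_cast<double*>(x.memptr()), C, (arma::uword)P * B,
                 false, true);
    arma::mat gW = gy * xm.t();
    arma::cube* gx = alloc_cube(C, P, B);
    arma::mat gxm(gx->memptr(), C, (arma::uword)P * B, false, true);
    gxm = W.t() * gy;
    return List::create(_["gx"] = make_cube(gx), _["gW"] = gW,
                        _["gb"] = gb);
  }
  arma::mat cols = im2col(x, K, pad);
  arma::mat gW = gy * cols.t();
  arma::mat gcols = W.t() * gy;  // (C*K, Pout*B)
  arma::cube* gx = alloc_cube(C, P, B);
  gx->zeros();
  for (int b = 0; b < B; ++b) {
    arma::mat& gxb = gx->slice(b);
    for (int p = 0; p < Pout; ++p) {
      const double* src = gcols.colptr((arma::uword)b * Pout + p);
      for (int k = 0; k < K; ++k) {
        int dst = p - pad + k;
        if (dst >= 0 && dst < P) {
          double* d = gxb.colptr(dst);
          const double* s = src + (arma::uword)k * C;
          for (int c = 0; c < C; ++c) d[c] += s[c];
        }
      }
    }
  }
  return List::create(_["gx"] = make_cube(gx), _["gW"] = gW, _["gb"] = gb);
}

// ---- fused post-convolution unit: ReLU -> batch norm -> dropout ----------

struct PostCache {
  arma::mat relu;    // ReLU output (C x positions*batch)
  arma::vec mu;      // batch (or running) mean per channel
  arma::vec istd;    // 1/sqrt(var + eps)
  arma::mat dmask;   // inverted-dropout mask, empty if unused
  bool train;
  bool dropped;
  int P, B;
};

static PostCache* alloc_postcache() {
  PostCache* p;
  if (!g_free_pc.empty()) {
    p = g_free_pc.back();
    g_free_pc.pop_back();
  } else {
    p = new PostCache();
  }
  g_active_pc.push_back(p);
  return p;
}

// Training mode uses batch statistics (population variance), updates the
// running moments and draws dropout masks from R's RNG (reproducible under
// set.seed).  Returns the output cube, an opaque cache for the backward
// pass, and the updated running moments.
// [[Rcpp::export]]
List cpp_post_fw(SEXP x_p, const arma::vec& gamma, const arma::vec& beta,
                 arma::vec rmean, arma::vec rvar, double momentum,
                 double eps, bool train, double drop_rate) {
  const arma::cube& x = deref(x_p);
  const int C = x.n_rows;
  const arma::uword n = x.n_cols * x.n_slices;
  arma::mat xm(const_cast<double*>(x.memptr()), C, n, false, true);
  PostCache* pc = alloc_postcache();
  pc->train = train;
  pc->P = x.n_cols;
  pc->B = x.n_slices;
  pc->relu.set_size(C, n);
  pc->relu = arma::clamp(xm, 0.0, arma::datum::inf);
  arma::vec mu(C), v(C);
  if (train) {
    mu = arma::mean(pc->relu, 1);
    v.zeros();
    for (arma::uword j = 0; j < n; ++j) {
      const double* c = pc->relu.colptr(j);
      for (int i = 0; i < C; ++i) {
        double d = c[i] - mu[i];
        v[i] += d * d;
      }
    }
    v /= (double)n;
    rmean = (1 - momentum) * rmean + momentum * mu;
    rvar = (1 - momentum) * rvar + momentum * v;
  } else {
    mu = rmean;
    v = rvar;
  }
  pc->mu = mu;
  pc->istd = 1.0 / arma::sqrt(v + eps);
  arma::cube* out = alloc_cube(C, x.n_cols, x.n_slices);
  arma::mat y(out->memptr(), C, n, false, true);
  pc->dropped = train && drop_rate > 0;
  if (pc->dropped) pc->dmask.set_size(C, n);
  const double keep = 1 - drop_rate;
  const double inv_keep = pc->dropped ? 1.0 / keep : 1.0;
  SplitMix64 rng(pc->dropped
                   ? (uint64_t)(unif_rand() * 9007199254740992.0)
                   : 0ULL);
  for (arma::uword j = 0; j < n; ++j) {
    const double* r = pc->relu.colptr(j);
    double* yy = y.colptr(j);
    for (int i = 0; i < C; ++i) {
      yy[i] = gamma[i] * (r[i] - mu[i]) * pc->istd[i] + beta[i];
    }
    if (pc->dropped) {
      double* dm = pc->dmask.colptr(j);
      for (int i = 0; i < C; ++i) {
        double m = (rng.next() < keep) ? inv_keep : 0.0;
        dm[i] = m;
        yy[i] *= m;
      }
    }
  }
  return List::create(_["out"] = make_cube(out),
                      _["cache"] = XPtr<PostCache>(pc, false),
                      _["rmean"] = rmean, _["rvar"] = rvar);
}

// [[Rcpp::export]]
List cpp_post_bw(SEXP gout_p, SEXP cache_p, const arma::vec& gamma) {
  const arma::cube& gout = deref(gout_p);
  XPtr<PostCache> pc(cache_p);
  const int C = gout.n_rows;
  const arma::uword n = gout.n_cols * gout.n_slices;
  arma::mat g(const_cast<double*>(gout.memptr()), C, n, false, true);
  arma::cube* gxc = alloc_cube(C, gout.n_cols, gout.n_slices);
  arma::mat gx(gxc->memptr(), C, n, false, true);
  arma::vec ggamma(C, arma::fill::zeros), gbeta(C, arma::fill::zeros);
  arma::vec s2(C, arma::fill::zeros);
  // first pass: gy (dropout-adjusted), per-channel sums over gy and gy*xhat
  for (arma::uword j = 0; j < n; ++j) {
    const double* gj = g.colptr(j);
    const double* rj = pc->relu.colptr(j);
    double* xj = gx.colptr(j);
    const double* dm = pc->dropped ? pc->dmask.colptr(j) : NULL;
    for (int i = 0; i < C; ++i) {
      double gy = dm ? gj[i] * dm[i] : gj[i];
      double xhat = (rj[i] - pc->mu[i]) * pc->istd[i];
      ggamma[i] += gy * xhat;
      gbeta[i] += gy;
      xj[i] = gy * gamma[i];  // gxhat, finished in second pass
    }
  }
  if (pc->train) {
    for (arma::uword j = 0; j < n; ++j) {
      double* xj = gx.colptr(j);
      const double* rj = pc->relu.colptr(j);
      for (int i = 0; i < C; ++i) {
        double xhat = (rj[i] - pc->mu[i]) * pc->istd[i];
        double val = pc->istd[i] *
          (xj[i] - (gamma[i] * gbeta[i] + xhat * gamma[i] * ggamma[i]) /
             (double)n);
        xj[i] = (rj[i] > 0) ? val : 0.0;
      }
    }
  } else {
    for (arma::uword j = 0; j < n; ++j) {
      double* xj = gx.colptr(j);
      const double* rj = pc->relu.colptr(j);
      for (int i = 0; i < C; ++i) {
        xj[i] = (rj[i] > 0) ? xj[i] * pc->istd[i] : 0.0;
      }
    }
  }
  return List::create(_["gin"] = make_cube(gxc), _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// ---- pooling -------------------------------------------------------------

// Non-overlapping max pooling of width w (stride w); trailing remainder
// positions are dropped.
// [[Rcpp::export]]
List cpp_maxpool_fw(SEXP x_p, int w) {
  const arma::cube& x = deref(x_p);
  const int C = x.n_rows, P = x.n_cols, B = x.n_slices;
  const int Pout = P / w;
  if (Pout < 1) stop("pooling output has no positions");
  arma::cube* out = alloc_cube(C, Pout, B);
  arma::icube* idx = alloc_icube(C, Pout, B);
  for (int b = 0; b < B; ++b) {
    for (int p = 0; p < Pout; ++p) {
      for (int c = 0; c < C; ++c) {
        double best = x(c, p * w, b);
        int besti = p * w;
        for (int k = 1; k < w; ++k) {
          double v = x(c, p * w + k, b);
          if (v > best) { best = v; besti = p * w + k; }
        }
        (*out)(c, p, b) = best;
        (*idx)(c, p, b) = besti;
      }
    }
  }
  return List::create(_["out"] = make_cube(out),
                      _["idx"] = XPtr<arma::icube>(idx, false),
                      _["in_len"] = P);
}

// [[Rcpp::export]]
SEXP cpp_maxpool_bw(SEXP gout_p, SEXP idx_p, int in_len) {
  const arma::cube& gout = deref(gout_p);
  XPtr<arma::icube> idx(idx_p);
  const int C = gout.n_rows, Pout = gout.n_cols, B = gout.n_slices;
  arma::cube* gx = alloc_cube(C, in_len, B);
  gx->zeros();
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < Pout; ++p)
      for (int c = 0; c < C; ++c)
        (*gx)(c, (*idx)(c, p, b), b) += gout(c, p, b);
  return make_cube(gx);
}

// ---- global average pooling and channel concat ---------------------------

// (C, P, B) -> (C, B); small result, returned as a plain matrix.
// [[Rcpp::export]]
arma::mat cpp_gap_fw(SEXP x_p) {
  const arma::cube& x = deref(x_p);
  const int C = x.n_rows, B = x.n_slices;
  arma::mat out(C, B);
  for (int b = 0; b < B; ++b) out.col(b) = arma::mean(x.slice(b), 1);
  return out;
}

// [[Rcpp::export]]
SEXP cpp_gap_bw(const arma::mat& gout, int P) {
  const int C = gout.n_rows, B = gout.n_cols;
  arma::cube* gx = alloc_cube(C, P, B);
  for (int b = 0; b < B; ++b) {
    arma::vec g = gout.col(b) / (double)P;
    gx->slice(b).each_col() = g;
  }
  return make_cube(gx);
}

// [[Rcpp::export]]
SEXP cpp_cat_channels(const List& cubes) {
  int ctot = 0;
  for (int i = 0; i < cubes.size(); ++i) ctot += deref(cubes[i]).n_rows;
  const arma::cube& first = deref(cubes[0]);
  arma::cube* out = alloc_cube(ctot, first.n_cols, first.n_slices);
  int at = 0;
  for (int i = 0; i < cubes.size(); ++i) {
    const arma::cube& c = deref(cubes[i]);
    out->rows(at, at + c.n_rows - 1) = c;
    at += c.n_rows;
  }
  return make_cube(out);
}

// [[Rcpp::export]]
List cpp_split_channels(SEXP x_p, const IntegerVector& counts) {
  const arma::cube& x = deref(x_p);
  List out(counts.size());
  int at = 0;
  for (int i = 0; i < counts.size(); ++i) {
    arma::cube* piece = alloc_cube(counts[i], x.n_cols, x.n_slices);
    *piece = x.rows(at, at + counts[i] - 1);
    out[i] = make_cube(piece);
    at += counts[i];
  }
  return out;
}

// ---- motif scanning ------------------------------------------------------

// Maximum log-odds motif score over all offsets and both strands.
// seqs: n x len integer-coded matrix (0 = N). lods: list of 4 x W
// log-odds matrices (rows A,C,G,T). N bases contribute 0 (neutral);
// windows consisting solely of N are skipped. If no window is scored the
// floor value is returned.
// [[Rcpp::export]]
NumericMatrix cpp_scan_pwm_max(const IntegerMatrix& seqs, const List& lods,
                               double score_floor) {
  const int n = seqs.nrow(), len = seqs.ncol(), T = lods.size();
  NumericMatrix out(n, T);
  std::vector<arma::mat> fwd(T), rev(T);
  for (int t = 0; t < T; ++t) {
    arma::mat m = as<arma::mat>(lods[t]);
    fwd[t] = m;
    arma::mat r(4, m.n_cols);
    for (arma::uword j = 0; j < m.n_cols; ++j)
      for (int i = 0; i < 4; ++i)
        r(3 - i, m.n_cols - 1 - j) = m(i, j);  // complement + reverse
    rev[t] = r;
  }
  for (int s = 0; s < n; ++s) {
    for (int t = 0; t < T; ++t) {
      const arma::mat& F = fwd[t];
      const arma::mat& R = rev[t];
      const int W = F.n_cols;
      double best = R_NegInf;
      for (int off = 0; off + W <= len; ++off) {
        double sf = 0.0, sr = 0.0;
        bool any_base = false;
        for (int j = 0; j < W; ++j) {
          int code = seqs(s, off + j);
          if (code >= 1) {
            any_base = true;
            sf += F(code - 1, j);
            sr += R(code - 1, j);
          }
        }
        if (!any_base) continue;
        double v = sf > sr ? sf : sr;
        if (v > best) best = v;
      }
      out(s, t) = R_FINITE(best) ? best : score_floor;
    }
  }
  return out;
}

// First-layer kernel activations at every valid offset (no padding),
// for a single kernel given as a 4 x K matrix; seqs are integer coded.
// Returns n x (len - K + 1) activation matrix. Used for PWM extraction.
// [[Rcpp::export]]
NumericMatrix cpp_kernel_activations(const IntegerMatrix& seqs,
                                     const NumericMatrix& kernel) {
  const int n = seqs.nrow(), len = seqs.ncol(), K = kernel.ncol();
  const int Pout = len - K + 1;
  if (Pout < 1) stop("sequence shorter than kernel");
  NumericMatrix out(n, Pout);
  for (int s = 0; s < n; ++s) {
    for (int p = 0; p < Pout; ++p) {
      double v = 0.0;
      for (int j = 0; j < K; ++j) {
        int code = seqs(s, p + j);
        if (code >= 1) v += kernel(code - 1, j);
      }
      out(s, p) = v;
    }
  }
  return out;
}
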