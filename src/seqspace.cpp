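// Core compiled routines: sequence featurization, the SGD trainer with
// K-negative sampling and cosine margin ranking loss, and pairwise k-mer
// dissimilarities for de novo motif clustering.
//
// Featurization here must agree bit-for-bit with the R implementation in
// R/feature-space.R (same canonical indexing, same pair hash); this parity
// is pinned by tests.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

static inline uint64_t rc_code_u64(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int j = 0; j < k; ++j) {
    uint64_t digit = code & 3ULL;
    code >>= 2;
    rc = (rc << 2) | (3ULL - digit);
  }
  return rc;
}

// Canonical k-mer index machinery; dense 0-based index over {kmer, revcomp}
// classes, canonical representative = numeric (lexicographic) minimum.
struct KmerTable {
  int k;
  uint64_t n_codes;
  std::vector<int> lut;  // code -> dense canonical index
  int n_canonical;
  explicit KmerTable(int k_) : k(k_) {
    n_codes = 1ULL << (2 * k);
    lut.resize(n_codes);
    int rank = -1;
    // first pass: rank canonical codes in ascending code order
    std::vector<int> rank_of(n_codes, -1);
    for (uint64_t c = 0; c < n_codes; ++c) {
      if (rc_code_u64(c, k) >= c) rank_of[c] = ++rank;
    }
    n_canonical = rank + 1;
    for (uint64_t c = 0; c < n_codes; ++c) {
      uint64_t rc = rc_code_u64(c, k);
      lut[c] = rank_of[std::min(c, rc)];
    }
  }
};

static inline int base_code(char b) {
  switch (b) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct Featurizer {
  int k, N;
  uint64_t bucket;
  int kmer_rows;
  KmerTable table;
  Featurizer(int k_, int N_, double bucket_)
      : k(k_), N(N_), bucket((uint64_t)(bucket_ + 0.5)), table(k_) {
    kmer_rows = table.n_canonical;
  }

  inline uint64_t pair_hash(uint64_t c1, uint64_t c2) const {
    uint64_t r1 = rc_code_u64(c1, k), r2 = rc_code_u64(c2, k);
    uint64_t h1 = c1, h2 = c2;
    if (r2 < c1 || (r2 == c1 && r1 < c2)) { h1 = r2; h2 = r1; }
    uint64_t p4 = 1ULL << (2 * k);
    return ((h1 % bucket) * (p4 % bucket) + h2) % bucket;
  }

  // Feature rows (global, 0-based) of a sequence window; k-mer windows with
  // ambiguous bases are skipped; pair features from full N-windows of
  // retained k-mers only. Output is NOT sorted (order = occurrence order).
  void featurize(const char* s, int len, std::vector<int>& rows,
                 std::vector<uint64_t>& codes) const {
    rows.clear();
    codes.clear();
    if (len < k) return;
    uint64_t mask = (1ULL << (2 * k)) - 1ULL;
    uint64_t cur = 0;
    int valid = 0;  // consecutive valid bases ending here
    for (int i = 0; i < len; ++i) {
      int b = base_code(s[i]);
      if (b < 0) {
        valid = 0;
        cur = 0;
        continue;
      }
      cur = ((cur << 2) | (uint64_t)b) & mask;
      if (++valid >= k) codes.push_back(cur);
    }
    size_t m = codes.size();
    rows.reserve(m * 4);
    for (size_t i = 0; i < m; ++i) rows.push_back(table.lut[codes[i]]);
    if (N > 1 && (int)m >= N) {
      for (size_t w = 0; w + N <= m; ++w) {
        for (int a = 0; a < N - 1; ++a) {
          for (int b = a + 1; b < N; ++b) {
            uint64_t h = pair_hash(codes[w + a], codes[w + b]);
            rows.push_back(kmer_rows + (int)h);
          }
        }
      }
    }
  }
};

// [[Rcpp::export]]
List cpp_featurize(std::string sequence, int k, int N, double bucket) {
  Featurizer fz(k, N, bucket);
  std::vector<int> rows;
  std::vector<uint64_t> codes;
  fz.featurize(sequence.c_str(), (int)sequence.size(), rows, codes);
  size_t m = codes.size();
  IntegerVector kmer_idx(m);
  for (size_t i = 0; i < m; ++i) kmer_idx[i] = rows[i];
  NumericVector ngram_idx(rows.size() - m);
  for (size_t i = m; i < rows.size(); ++i) ngram_idx[i - m] = (double)rows[i];
  return List::create(_["kmer_indices"] = kmer_idx,
                      _["ngram_indices"] = ngram_idx,
                      _["kmer_rows"] = fz.kmer_rows);
}

// ---------------------------------------------------------------------------
// SGD with cosine margin ranking loss.
//
// LHS entity l = sum(w_r) / M^P over feature rows (with multiplicity).
// Loss = (1/K) sum_k max(0, margin - cos(l, pos) + cos(l, neg_k)).
// Gradients flow to the positive row, active negative rows (hinge > 0) and
// all feature rows (scaled by multiplicity / M^P). Per-row Adagrad scalar
// accumulators; base rate decays linearly over the planned example count.
// Feature rows are updated in sorted order so a strand-flipped (identical
// multiset) example produces bit-identical updates.
// ---------------------------------------------------------------------------

typedef float real;  // embedding storage; StarSpace-style single precision

static inline double vnorm(const double* v, int d) {
  double s = 0;
  for (int i = 0; i < d; ++i) s += v[i] * v[i];
  return std::sqrt(s);
}

template <typename RealT>
static inline double vdot(const double* a, const RealT* b, int d) {
  double s = 0;
  for (int i = 0; i < d; ++i) s += a[i] * (double)b[i];
  return s;
}

template <typename RealT>
static inline double vnorm_r(const RealT* v, int d) {
  double s = 0;
  for (int i = 0; i < d; ++i) s += (double)v[i] * (double)v[i];
  return std::sqrt(s);
}



// d cos(l, x) / dl into out (+= gcoef * ...); zero-norm => no contribution.
template <typename RealT>
static inline void add_dcos_dl(const double* l, double nl, const RealT* x,
                               double nx, double cs, double gcoef, double* out,
                               int d) {
  if (nl == 0 || nx == 0) return;
  for (int i = 0; i < d; ++i)
    out[i] += gcoef * (x[i] / nx - cs * l[i] / nl) / nl;
}

// d cos(l, x) / dx into out.
template <typename RealT>
static inline void add_dcos_dx(const double* l, double nl, const RealT* x,
                               double nx, double cs, double gcoef, double* out,
                               int d) {
  if (nl == 0 || nx == 0) return;
  for (int i = 0; i < d; ++i)
    out[i] += gcoef * (l[i] / nl - cs * x[i] / nx) / nx;
}

struct UpdateScratch {
  std::vector<double> l, gl, gx;
  std::vector<int> sorted_rows;
};

// One SGD step on flat row-major storage. Returns the example loss.
// cellE: n_cells*d, featE: n_feat*d; accCell/accFeat: per-row Adagrad sums.
template <typename RealT>
static double sgd_example(std::vector<int>& rows /* modified: sorted */,
                          int pos, const std::vector<int>& negs, double margin,
                          double P, double lr, int d, RealT* cellE,
                          RealT* featE, double* accCell, double* accFeat,
                          std::vector<double>& hinges, UpdateScratch& sc,
                          long* zero_norm_flags, bool adagrad = true) {
  const double eps = 1e-10;
  size_t M = rows.size();
  std::sort(rows.begin(), rows.end());
  sc.l.assign(d, 0.0);
  for (size_t i = 0; i < M; ++i) {
    const RealT* w = featE + (size_t)rows[i] * d;
    for (int j = 0; j < d; ++j) sc.l[j] += w[j];
  }
  double scale = 1.0 / std::pow((double)M, P);
  for (int j = 0; j < d; ++j) sc.l[j] *= scale;
  double* l = sc.l.data();
  double nl = vnorm(l, d);

  const RealT* p = cellE + (size_t)pos * d;
  double np = vnorm_r(p, d);
  double cp = (nl == 0 || np == 0) ? 0.0 : vdot(l, p, d) / (nl * np);
  if ((nl == 0 || np == 0) && zero_norm_flags) ++(*zero_norm_flags);

  int K = (int)negs.size();
  hinges.assign(K, 0.0);
  double loss = 0;
  std::vector<double> cns(K), nns(K);
  for (int kk = 0; kk < K; ++kk) {
    const RealT* nv = cellE + (size_t)negs[kk] * d;
    double nn = vnorm_r(nv, d);
    double cn = (nl == 0 || nn == 0) ? 0.0 : vdot(l, nv, d) / (nl * nn);
    cns[kk] = cn;
    nns[kk] = nn;
    double h = margin - cp + cn;
    if (h > 0) {
      hinges[kk] = h;
      loss += h;
    }
  }
  loss /= K;
  if (lr <= 0) return loss;

  int n_active = 0;
  for (int kk = 0; kk < K; ++kk)
    if (hinges[kk] > 0) ++n_active;
  if (n_active == 0) return loss;  // zero loss: nothing moves

  // gradient w.r.t. l
  sc.gl.assign(d, 0.0);
  double* gl = sc.gl.data();
  add_dcos_dl(l, nl, p, np, cp, -(double)n_active / K, gl, d);
  for (int kk = 0; kk < K; ++kk) {
    if (hinges[kk] <= 0) continue;
    const RealT* nv = cellE + (size_t)negs[kk] * d;
    add_dcos_dl(l, nl, nv, nns[kk], cns[kk], 1.0 / K, gl, d);
  }

  sc.gx.assign(d, 0.0);
  double* gx = sc.gx.data();

  // feature rows, grouped by unique row in sorted order
  for (size_t i = 0; i < M;) {
    size_t j = i;
    while (j < M && rows[j] == rows[i]) ++j;
    double coef = (double)(j - i) * scale;
    double g2 = 0;
    for (int t = 0; t < d; ++t) {
      gx[t] = coef * gl[t];
      g2 += gx[t] * gx[t];
    }
    double* acc = accFeat + rows[i];
    *acc += g2;
    double step = adagrad ? lr / std::sqrt(*acc + eps) : lr;
    RealT* w = featE + (size_t)rows[i] * d;
    for (int t = 0; t < d; ++t) w[t] -= (RealT)(step * gx[t]);
    i = j;
  }

  // positive cell row
  {
    for (int t = 0; t < d; ++t) gx[t] = 0;
    add_dcos_dx(l, nl, p, np, cp, -(double)n_active / K, gx, d);
    double g2 = 0;
    for (int t = 0; t < d; ++t) g2 += gx[t] * gx[t];
    if (g2 > 0) {
      accCell[pos] += g2;
      double step = adagrad ? lr / std::sqrt(accCell[pos] + eps) : lr;
      RealT* w = cellE + (size_t)pos * d;
      for (int t = 0; t < d; ++t) w[t] -= (RealT)(step * gx[t]);
    }
  }

  // active negative cell rows
  for (int kk = 0; kk < K; ++kk) {
    if (hinges[kk] <= 0) continue;
    RealT* nv = cellE + (size_t)negs[kk] * d;
    for (int t = 0; t < d; ++t) gx[t] = 0;
    add_dcos_dx(l, nl, nv, nns[kk], cns[kk], 1.0 / K, gx, d);
    double g2 = 0;
    for (int t = 0; t < d; ++t) g2 += gx[t] * gx[t];
    if (g2 > 0) {
      accCell[negs[kk]] += g2;
      double step = adagrad ? lr / std::sqrt(accCell[negs[kk]] + eps) : lr;
      for (int t = 0; t < d; ++t) nv[t] -= (RealT)(step * gx[t]);
    }
  }

  for (int t = 0; t < d; ++t) {
    if (!std::isfinite(gl[t])) stop("non-finite gradient encountered");
  }
  return loss;
}

// Single exposed SGD step on small matrices (entity rows x d), for testing
// gradient support and descent behaviour. Returns updated copies.
// [[Rcpp::export]]
List cpp_sgd_step(NumericMatrix cell_emb, NumericMatrix feat_emb,
                  NumericVector feature_rows, int pos, IntegerVector negs,
                  double margin, double P, double lr, NumericVector acc_cell,
                  NumericVector acc_feat) {
  int d = cell_emb.ncol();
  if (feat_emb.ncol() != d) stop("dimension mismatch");
  int nc = cell_emb.nrow(), nf = feat_emb.nrow();
  std::vector<double> cellE((size_t)nc * d), featE((size_t)nf * d);
  for (int r = 0; r < nc; ++r)
    for (int j = 0; j < d; ++j) cellE[(size_t)r * d + j] = cell_emb(r, j);
  for (int r = 0; r < nf; ++r)
    for (int j = 0; j < d; ++j) featE[(size_t)r * d + j] = feat_emb(r, j);
  std::vector<double> accC(acc_cell.begin(), acc_cell.end());
  std::vector<double> accF(acc_feat.begin(), acc_feat.end());
  if ((int)accC.size() != nc || (int)accF.size() != nf)
    stop("accumulator length mismatch");
  std::vector<int> rows(feature_rows.size());
  for (int i = 0; i < feature_rows.size(); ++i) {
    rows[i] = (int)feature_rows[i];
    if (rows[i] < 0 || rows[i] >= nf) stop("feature row out of range");
  }
  std::vector<int> ng(negs.begin(), negs.end());
  std::vector<double> hinges;
  UpdateScratch sc;
  long zf = 0;
  double loss = sgd_example(rows, pos, ng, margin, P, lr, d, cellE.data(),
                            featE.data(), accC.data(), accF.data(), hinges,
                            sc, &zf);
  NumericMatrix outC(nc, d), outF(nf, d);
  for (int r = 0; r < nc; ++r)
    for (int j = 0; j < d; ++j) outC(r, j) = cellE[(size_t)r * d + j];
  for (int r = 0; r < nf; ++r)
    for (int j = 0; j < d; ++j) outF(r, j) = featE[(size_t)r * d + j];
  return List::create(
      _["cell_embeddings"] = outC, _["feature_embeddings"] = outF,
      _["loss"] = loss, _["hinges"] = NumericVector(hinges.begin(), hinges.end()),
      _["acc_cell"] = NumericVector(accC.begin(), accC.end()),
      _["acc_feat"] = NumericVector(accF.begin(), accF.end()),
      _["zero_norm_pairs"] = (double)zf);
}

// ---------------------------------------------------------------------------
// Full training loop. Deterministic for a fixed seed (single-threaded).
// ---------------------------------------------------------------------------
// event_seq: event sequences (already uppercased/canonicalized upstream)
// event_pos: per event, sorted 0-based global ids of accessible cells
// cell_group: 0-based negative-sampling group per cell (dataset, or
//             dataset x batch when batch-aware)
// group_cells: per group, 0-based member cell ids
// [[Rcpp::export]]
List cpp_train(CharacterVector event_seq, List event_pos,
               IntegerVector cell_group, List group_cells, int n_cells, int d,
               int k, int N, double bucket, int L, int epochs,
               int examples_per_event, int K_neg, double margin, double lr0,
               double P, double seed, bool adagrad) {
  Featurizer fz(k, N, bucket);
  size_t n_feat = (size_t)fz.kmer_rows + (size_t)bucket;
  int n_events = event_seq.size();
  if (event_pos.size() != n_events) stop("event_pos length mismatch");

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(-1.0 / d, 1.0 / d);

  std::vector<real> cellE((size_t)n_cells * d), featE(n_feat * d, 0.0f);
  for (size_t i = 0; i < cellE.size(); ++i) cellE[i] = (real)unif(rng);
  // canonical k-mer rows uniform; hashed bucket rows stay zero until touched
  for (size_t r = 0; r < (size_t)fz.kmer_rows; ++r)
    for (int j = 0; j < d; ++j) featE[r * d + j] = (real)unif(rng);

  std::vector<double> accCell(n_cells, 0.0), accFeat(n_feat, 0.0);

  // cache positives and sequences
  std::vector<std::vector<int>> pos(n_events);
  std::vector<std::string> seqs(n_events);
  std::vector<int> usable;
  int n_groups = group_cells.size();
  std::vector<std::vector<int>> groups(n_groups);
  for (int g = 0; g < n_groups; ++g) {
    IntegerVector gv = group_cells[g];
    groups[g].assign(gv.begin(), gv.end());
  }
  for (int e = 0; e < n_events; ++e) {
    IntegerVector pv = event_pos[e];
    pos[e].assign(pv.begin(), pv.end());
    seqs[e] = as<std::string>(event_seq[e]);
    if (!pos[e].empty() && (int)pos[e].size() < n_cells &&
        (int)seqs[e].size() >= k)
      usable.push_back(e);
  }
  if (usable.empty()) stop("no usable events (need >=1 positive, >=1 negative, length >= k)");

  std::vector<int> slots;
  slots.reserve(usable.size() * examples_per_event);
  for (int e : usable)
    for (int r = 0; r < examples_per_event; ++r) slots.push_back(e);
  double T = (double)slots.size() * std::max(epochs, 1);

  std::vector<double> loss_trace(epochs, 0.0);
  std::vector<int> epoch_n(epochs, 0);
  long skipped = 0, zero_norm = 0;
  double t_example = 0;
  std::vector<int> rows;
  std::vector<uint64_t> codes;
  std::vector<int> negs;
  std::vector<double> hinges;
  UpdateScratch sc;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(slots.begin(), slots.end(), rng);
    for (size_t si = 0; si < slots.size(); ++si) {
      int e = slots[si];
      double lr = lr0 * (1.0 - t_example / T);
      t_example += 1.0;
      const std::string& s = seqs[e];
      int len = (int)s.size();
      int off = 0, wlen = len;
      if (len > L) {
        std::uniform_int_distribution<int> od(0, len - L);
        off = od(rng);
        wlen = L;
      }
      fz.featurize(s.c_str() + off, wlen, rows, codes);
      if (rows.empty()) {
        ++skipped;
        continue;
      }
      // positive cell
      std::uniform_int_distribution<int> pd(0, (int)pos[e].size() - 1);
      int p = pos[e][pd(rng)];
      int g = cell_group[p];
      const std::vector<int>& gc = groups[g];
      // eligible negatives = group members not accessible for this event
      int pin = 0;
      for (int c : pos[e])
        if (cell_group[c] == g) ++pin;
      int elig = (int)gc.size() - pin;
      if (elig <= 0) {
        ++skipped;
        continue;
      }
      negs.clear();
      if (elig <= K_neg) {
        for (int c : gc)
          if (!std::binary_search(pos[e].begin(), pos[e].end(), c))
            negs.push_back(c);
      } else {
        std::uniform_int_distribution<int> gd(0, (int)gc.size() - 1);
        while ((int)negs.size() < K_neg) {
          int c = gc[gd(rng)];
          if (std::binary_search(pos[e].begin(), pos[e].end(), c)) continue;
          bool dup = false;
          for (int x : negs)
            if (x == c) { dup = true; break; }
          if (!dup) negs.push_back(c);
        }
      }
      double loss =
          sgd_example(rows, p, negs, margin, P, lr, d, cellE.data(),
                      featE.data(), accCell.data(), accFeat.data(), hinges,
                      sc, &zero_norm, adagrad);
      loss_trace[ep] += loss;
      ++epoch_n[ep];
    }
    if (epoch_n[ep] > 0) loss_trace[ep] /= epoch_n[ep];
  }

  NumericMatrix outC(n_cells, d);
  for (int r = 0; r < n_cells; ++r)
    for (int j = 0; j < d; ++j) outC(r, j) = cellE[(size_t)r * d + j];
  cellE.clear();
  cellE.shrink_to_fit();
  NumericMatrix outF((R_xlen_t)n_feat, d);
  for (size_t r = 0; r < n_feat; ++r)
    for (int j = 0; j < d; ++j) outF(r, j) = featE[r * d + j];

  return List::create(
      _["cell_embeddings"] = outC, _["feature_embeddings"] = outF,
      _["loss_trace"] = NumericVector(loss_trace.begin(), loss_trace.end()),
      _["examples_skipped"] = (double)skipped,
      _["zero_norm_pairs"] = (double)zero_norm,
      _["n_usable_events"] = (int)usable.size(),
      _["kmer_rows"] = fz.kmer_rows);
}

// ---------------------------------------------------------------------------
// Pairwise dissimilarity of equal-length k-mers for de novo motif clustering:
// 1 - (best ungapped overlap match count over all offsets and both strands)/m
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_kmer_dissim(CharacterVector seqs) {
  int n = seqs.size();
  if (n == 0) return NumericMatrix(0, 0);
  int m = LENGTH(STRING_ELT(seqs, 0));
  std::vector<std::string> fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(seqs[i]);
    if ((int)fwd[i].size() != m) stop("k-mers must have equal length");
    std::string r(m, 'N');
    for (int j = 0; j < m; ++j) {
      char b = fwd[i][m - 1 - j];
      r[j] = b == 'A' ? 'T' : b == 'C' ? 'G' : b == 'G' ? 'C' : b == 'T' ? 'A' : 'N';
    }
    rev[i] = r;
  }
  auto best = [m](const std::string& a, const std::string& b) {
    int bestm = 0;
    for (int off = -(m - 1); off <= m - 1; ++off) {
      int cnt = 0;
      int lo = std::max(0, off), hi = std::min(m, m + off);
      for (int i = lo; i < hi; ++i)
        if (a[i] == b[i - off]) ++cnt;
      if (cnt > bestm) bestm = cnt;
    }
    return bestm;
  };
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int bm = std::max(best(fwd[i], fwd[j]), best(fwd[i], rev[j]));
      double dd = 1.0 - (double)bm / m;
      D(i, j) = dd;
      D(j, i) = dd;
    }
  }
  return D;
}
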