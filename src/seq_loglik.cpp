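#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear expected z-scores per stage, filled column-major into M
// ((E+1) x B). Events of each biomarker occupy a contiguous id block
// [bio_start[b], bio_start[b+1]) in ascending threshold order (guaranteed by
// the event-set constructor). The (E, z_max) end anchor wins over a top
// threshold event sitting at position E.
static void stage_means_fill(const IntegerVector& seq, int E, int B,
                             const IntegerVector& bio_start,
                             const NumericVector& thr,
                             const NumericVector& zmax,
                             std::vector<double>& M) {
  std::vector<int> pos(E);
  for (int j = 0; j < E; ++j) pos[seq[j] - 1] = j + 1;
  std::vector<double> x, y;
  x.reserve(8); y.reserve(8);
  for (int b = 0; b < B; ++b) {
    x.clear(); y.clear();
    x.push_back(0.0); y.push_back(0.0);
    for (int e = bio_start[b]; e < bio_start[b + 1]; ++e) {
      if (pos[e] < E) { x.push_back(pos[e]); y.push_back(thr[e]); }
    }
    x.push_back(E); y.push_back(zmax[b]);
    int seg = 0;
    int nseg = (int)x.size() - 1;
    double* col = &M[(size_t)b * (E + 1)];
    for (int k = 0; k <= E; ++k) {
      while (seg + 1 < nseg && k > x[seg + 1]) ++seg;
      col[k] = y[seg] + (y[seg + 1] - y[seg]) * (k - x[seg]) /
               (x[seg + 1] - x[seg]);
    }
    col[E] = zmax[b];
  }
}

// Per-subject stage-marginalised log-likelihood of one sequence:
// log (1/(E+1)) sum_k prod_b Normal(Z[i,b]; g_b(k), sigma).
// [[Rcpp::export]]
NumericVector cpp_marg_loglik(IntegerVector seq, NumericMatrix Z,
                              double sigma, IntegerVector bio_start,
                              NumericVector thr, NumericVector zmax) {
  const int N = Z.nrow(), B = Z.ncol(), E = seq.size(), K = E + 1;
  std::vector<double> M((size_t)B * K);
  stage_means_fill(seq, E, B, bio_start, thr, zmax, M);
  NumericVector out(N);
  const double inv2s2 = 0.5 / (sigma * sigma);
  const double lconst = -B * std::log(sigma) -
    0.5 * B * std::log(2.0 * M_PI) - std::log((double)K);
  const double* z = REAL(Z);
  // G[i + k*N] = sum_b Z[i,b] * M[k,b]; contiguous inner loops vectorize
  std::vector<double> G((size_t)N * K, 0.0);
  std::vector<double> zsq(N, 0.0), m2(K, 0.0);
  for (int b = 0; b < B; ++b) {
    const double* zc = z + (size_t)b * N;
    const double* mc = &M[(size_t)b * K];
    for (int i = 0; i < N; ++i) zsq[i] += zc[i] * zc[i];
    for (int k = 0; k < K; ++k) {
      m2[k] += mc[k] * mc[k];
      const double mk = mc[k];
      double* gc = &G[(size_t)k * N];
      for (int i = 0; i < N; ++i) gc[i] += zc[i] * mk;
    }
  }
  std::vector<double> ll((size_t)N * K);
  std::vector<double> mx(N, R_NegInf);
  for (int k = 0; k < K; ++k) {
    const double* gc = &G[(size_t)k * N];
    double* lc = &ll[(size_t)k * N];
    const double m2k = m2[k];
    for (int i = 0; i < N; ++i) {
      double v = -inv2s2 * (zsq[i] - 2.0 * gc[i] + m2k);
      lc[i] = v;
      if (v > mx[i]) mx[i] = v;
    }
  }
  for (int i = 0; i < N; ++i) out[i] = 0.0;
  for (int k = 0; k < K; ++k) {
    const double* lc = &ll[(size_t)k * N];
    for (int i = 0; i < N; ++i) {
      const double d = lc[i] - mx[i];
      if (d > -37.0) out[i] += std::exp(d);  // below: underflows to 0 anyway
    }
  }
  for (int i = 0; i < N; ++i) out[i] = mx[i] + std::log(out[i]) + lconst;
  return out;
}

// Weighted total of the above (the greedy ascent / EM M-step objective).
// [[Rcpp::export]]
double cpp_seq_loglik(IntegerVector seq, NumericMatrix Z, double sigma,
                      IntegerVector bio_start, NumericVector thr,
                      NumericVector zmax, Nullable<NumericVector> weights) {
  NumericVector ml = cpp_marg_loglik(seq, Z, sigma, bio_start, thr, zmax);
  double tot = 0.0;
  if (weights.isNotNull()) {
    NumericVector w(weights);
    for (int i = 0; i < ml.size(); ++i) tot += w[i] * ml[i];
  } else {
    for (int i = 0; i < ml.size(); ++i) tot += ml[i];
  }
  return tot;
}

// Workspace-reusing weighted total log-likelihood of one candidate sequence.
struct LlWork {
  std::vector<double> M, G, zsq, m2, mx, acc;
};

static double seq_total_ll(const std::vector<int>& seq_v,
                           const double* z, int N, int B, double sigma,
                           const IntegerVector& bio_start,
                           const NumericVector& thr,
                           const NumericVector& zmax,
                           const double* w, LlWork& wk) {
  const int E = (int)seq_v.size(), K = E + 1;
  IntegerVector seq(seq_v.begin(), seq_v.end());
  wk.M.assign((size_t)B * K, 0.0);
  stage_means_fill(seq, E, B, bio_start, thr, zmax, wk.M);
  const double inv2s2 = 0.5 / (sigma * sigma);
  const double lconst = -B * std::log(sigma) -
    0.5 * B * std::log(2.0 * M_PI) - std::log((double)K);
  wk.G.assign((size_t)N * K, 0.0);
  if ((int)wk.zsq.size() != N) {  // Z is fixed within one ascent
    wk.zsq.assign(N, 0.0);
    for (int b = 0; b < B; ++b) {
      const double* zc = z + (size_t)b * N;
      for (int i = 0; i < N; ++i) wk.zsq[i] += zc[i] * zc[i];
    }
  }
  wk.m2.assign(K, 0.0);
  for (int b = 0; b < B; ++b) {
    const double* zc = z + (size_t)b * N;
    const double* mc = &wk.M[(size_t)b * K];
    for (int k = 0; k < K; ++k) {
      wk.m2[k] += mc[k] * mc[k];
      const double mk = mc[k];
      double* gc = &wk.G[(size_t)k * N];
      for (int i = 0; i < N; ++i) gc[i] += zc[i] * mk;
    }
  }
  wk.mx.assign(N, R_NegInf);
  for (int k = 0; k < K; ++k) {
    double* gc = &wk.G[(size_t)k * N];
    const double m2k = wk.m2[k];
    for (int i = 0; i < N; ++i) {
      const double v = -inv2s2 * (wk.zsq[i] - 2.0 * gc[i] + m2k);
      gc[i] = v;  // reuse G as the log-density buffer
      if (v > wk.mx[i]) wk.mx[i] = v;
    }
  }
  wk.acc.assign(N, 0.0);
  for (int k = 0; k < K; ++k) {
    const double* gc = &wk.G[(size_t)k * N];
    for (int i = 0; i < N; ++i) {
      const double d = gc[i] - wk.mx[i];
      if (d > -37.0) wk.acc[i] += std::exp(d);
    }
  }
  double tot = 0.0;
  for (int i = 0; i < N; ++i) {
    const double li = wk.mx[i] + std::log(wk.acc[i]) + lconst;
    tot += (w ? w[i] : 1.0) * li;
  }
  return tot;
}

// Greedy ascent over single-event relocation moves: for each event (in
// random order per pass) try every position compatible with its biomarker's
// threshold ordering and keep the best; stop when a full pass yields no
// improvement. Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_greedy_ascent(IntegerVector init, NumericMatrix Z, double sigma,
                       IntegerVector bio_start, NumericVector thr,
                       NumericVector zmax, Nullable<NumericVector> weights,
                       int max_passes) {
  const int N = Z.nrow(), B = Z.ncol(), E = init.size();
  const double* z = REAL(Z);
  const double* w = nullptr;
  NumericVector wv;
  if (weights.isNotNull()) { wv = NumericVector(weights); w = REAL(wv); }
  // bio_of[e0] and rank boundaries for sibling lookup
  std::vector<int> bio_of(E);
  for (int b = 0; b < B; ++b)
    for (int e = bio_start[b]; e < bio_start[b + 1]; ++e) bio_of[e] = b;
  LlWork wk;
  std::vector<int> s(init.begin(), init.end());
  double cur = seq_total_ll(s, z, N, B, sigma, bio_start, thr, zmax, w, wk);
  std::vector<int> others(E - 1), cand(E), best_s(E);
  for (int pass = 0; pass < max_passes; ++pass) {
    bool improved = false;
    IntegerVector ord = Rcpp::sample(E, E, false);  // 1-based event ids
    for (int oi = 0; oi < E; ++oi) {
      const int e = ord[oi];           // event id (1-based)
      const int e0 = e - 1;
      const int b = bio_of[e0];
      // others = s without e
      int m = 0;
      for (int j = 0; j < E; ++j) if (s[j] != e) others[m++] = s[j];
      // slot bounds from threshold siblings
      int lo = 0, hi = E;              // insert slots are 1..E (1-based)
      const int prev_e = (e0 > bio_start[b]) ? e0 - 1 + 1 : 0;      // id
      const int next_e = (e0 + 1 < bio_start[b + 1]) ? e0 + 1 + 1 : 0;
      if (prev_e) {
        for (int j = 0; j < E - 1; ++j) if (others[j] == prev_e) { lo = j + 1; break; }
      }
      if (next_e) {
        for (int j = 0; j < E - 1; ++j) if (others[j] == next_e) { hi = j + 1; break; }
      }
      double best_ll = cur;
      bool found = false;
      for (int slot = lo + 1; slot <= hi; ++slot) {
        // insert e at position slot (1-based)
        for (int j = 0; j < slot - 1; ++j) cand[j] = others[j];
        cand[slot - 1] = e;
        for (int j = slot - 1; j < E - 1; ++j) cand[j + 1] = others[j];
        const double ll = seq_total_ll(cand, z, N, B, sigma, bio_start, thr,
                                       zmax, w, wk);
        if (ll > best_ll + 1e-12) {
          best_ll = ll;
          best_s = cand;
          found = true;
        }
      }
      if (found) {
        s = best_s;
        cur = best_ll;
        improved = true;
      }
    }
    if (!improved) break;
  }
  return List::create(Named("sequence") = IntegerVector(s.begin(), s.end()),
                      Named("loglik") = cur);
}
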