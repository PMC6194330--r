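#include <Rcpp.h>
using namespace Rcpp;

// Dense k-window counting over the base-L integer coding of windows.
// Window starting at i covers x[i..i+k-1]; the newest symbol x[i+k-1]
// occupies the lowest digit. Caller guarantees L^k fits the counts vector.
// [[Rcpp::export]]
IntegerVector cpp_window_counts(IntegerVector x, int k, int L) {
  const R_xlen_t n = x.size();
  if (k < 1 || k > n) stop("k must be in [1, length(x)]");
  long long nbins = 1;
  for (int j = 0; j < k; ++j) nbins *= L;
  IntegerVector counts((R_xlen_t) nbins);
  long long code = 0, top = nbins / L;
  for (int j = 0; j < k; ++j) code = code * L + x[j];
  counts[(R_xlen_t) code]++;
  for (R_xlen_t i = 1; i + k <= n; ++i) {
    code = (code - (long long) x[i - 1] * top) * L + x[i + k - 1];
    counts[(R_xlen_t) code]++;
  }
  return counts;
}

// Sparse variant: returns the double-valued code of every window
// (valid while L^k < 2^53); counting happens R-side.
// [[Rcpp::export]]
NumericVector cpp_window_codes(IntegerVector x, int k, int L) {
  const R_xlen_t n = x.size();
  if (k < 1 || k > n) stop("k must be in [1, length(x)]");
  NumericVector codes(n - k + 1);
  double code = 0, top = 1;
  for (int j = 0; j < k - 1; ++j) top *= L;
  for (int j = 0; j < k; ++j) code = code * L + x[j];
  codes[0] = code;
  for (R_xlen_t i = 1; i + k <= n; ++i) {
    code = (code - x[i - 1] * top) * L + x[i + k - 1];
    codes[i] = code;
  }
  return codes;
}

// Plug-in joint entropies H_1..H_kmax (bits), each from its own full
// window count (N-k+1 windows). Caller guarantees L^kmax is small.
// [[Rcpp::export]]
NumericVector cpp_entropy_profile(IntegerVector x, int kmax, int L) {
  NumericVector H(kmax);
  const double l2 = std::log(2.0);
  for (int k = 1; k <= kmax; ++k) {
    IntegerVector cnt = cpp_window_counts(x, k, L);
    double tot = 0, s = 0;
    for (R_xlen_t i = 0; i < cnt.size(); ++i) tot += cnt[i];
    for (R_xlen_t i = 0; i < cnt.size(); ++i)
      if (cnt[i] > 0) { double p = cnt[i] / tot; s -= p * std::log(p); }
    H[k - 1] = s / l2;
  }
  return H;
}

// Order-M Markov sampler by inverse-CDF on cumulative table rows.
// cum: (L^M x L) row-wise cumulative transition probabilities; rows for
// unobserved histories are flagged false in `observed` and trigger a
// redraw of the history from hist_cum (cumulative history distribution).
// Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export]]
List cpp_sample_markov(NumericMatrix cum, LogicalVector observed,
                       NumericVector hist_cum, int M, int L, int N) {
  IntegerVector out(N);
  const int nh = hist_cum.size();
  long long topdiv = 1;  // L^(M-1), digit shift for history update
  for (int j = 0; j < M - 1; ++j) topdiv *= L;
  int n_fallback = 0;

  auto draw_hist = [&]() {
    double r = unif_rand();
    int h = 0;
    while (h < nh - 1 && r >= hist_cum[h]) ++h;
    return h;
  };

  long long hist = 0;
  int pos = 0;
  if (M > 0) {
    hist = draw_hist();
    // emit the initial M-history, oldest symbol (highest digit) first
    long long pw = topdiv;
    for (int j = M - 1; j >= 0; --j) {
      out[pos++] = (int)((hist / pw) % L);
      if (j > 0) pw /= L;
    }
  }
  while (pos < N) {
    if (M > 0 && !observed[(R_xlen_t) hist]) {
      hist = draw_hist();
      ++n_fallback;
      continue;
    }
    double r = unif_rand();
    int s = 0;
    const R_xlen_t row = (M > 0) ? (R_xlen_t) hist : 0;
    while (s < L - 1 && r >= cum(row, s)) ++s;
    out[pos++] = s;
    if (M > 0) hist = (hist % topdiv) * L + s;
  }
  return List::create(_["seq"] = out, _["n_fallback"] = n_fallback);
}

// Edge-emitting HMM sampler. Edges grouped by source state:
// edge_ptr[s]..edge_ptr[s+1]-1 (0-based, C-style) index into
// edge_cum (within-state cumulative probability), edge_to, edge_sym.
// [[Rcpp::export]]
IntegerVector cpp_sample_hmm(IntegerVector edge_ptr, NumericVector edge_cum,
                             IntegerVector edge_to, IntegerVector edge_sym,
                             int start_state, int N) {
  IntegerVector out(N);
  int st = start_state;
  for (int i = 0; i < N; ++i) {
    double r = unif_rand();
    int e = edge_ptr[st], last = edge_ptr[st + 1] - 1;
    while (e < last && r >= edge_cum[e]) ++e;
    out[i] = edge_sym[e];
    st = edge_to[e];
  }
  return out;
}

// Single-site Gibbs dynamics of the 2D Ising model (J = 1, k_B = 1),
// periodic boundaries, systematic raster scan, one recorded value per
// sweep after burn-in. Optionally records the full configuration as a
// bit code (requires side*side <= 50).
// [[Rcpp::export]]
List cpp_ising_site(int side, double beta, int n_sweeps, int burn_in,
                    int site_row, int site_col, bool record_configs) {
  const int n = side * side;
  std::vector<int> spin(n);
  for (int i = 0; i < n; ++i) spin[i] = unif_rand() < 0.5 ? -1 : 1;
  // conditional P(spin=+1 | neighbour sum S), S in {-4,-2,0,2,4}
  double pup[9];
  for (int S = -4; S <= 4; S += 2) pup[S + 4] = 1.0 / (1.0 + std::exp(-2.0 * beta * S));
  IntegerVector site(n_sweeps);
  NumericVector configs(record_configs ? n_sweeps : 0);
  const int rec = site_row * side + site_col;
  for (int sw = 0; sw < burn_in + n_sweeps; ++sw) {
    for (int r = 0; r < side; ++r) {
      const int up = (r == 0 ? side - 1 : r - 1) * side;
      const int dn = (r == side - 1 ? 0 : r + 1) * side;
      const int ro = r * side;
      for (int c = 0; c < side; ++c) {
        const int lf = c == 0 ? side - 1 : c - 1;
        const int rt = c == side - 1 ? 0 : c + 1;
        const int S = spin[up + c] + spin[dn + c] + spin[ro + lf] + spin[ro + rt];
        spin[ro + c] = unif_rand() < pup[S + 4] ? 1 : -1;
      }
    }
    if (sw >= burn_in) {
      site[sw - burn_in] = spin[rec] > 0 ? 1 : 0;
      if (record_configs) {
        double code = 0;
        for (int i = n - 1; i >= 0; --i) code = code * 2 + (spin[i] > 0 ? 1 : 0);
        configs[sw - burn_in] = code;
      }
    }
  }
  return List::create(_["site"] = site, _["configs"] = configs);
}

// Euler integration of the double-well Langevin step
// x <- x + (a*x - b*x^3)*dt + xi,  xi ~ N(0, sigma^2) per step.
// [[Rcpp::export]]
NumericVector cpp_double_well(int N, double a, double b, double sigma,
                              double dt, double x0) {
  NumericVector out(N);
  double x = x0;
  const double blow = 10.0 * std::sqrt(a / b);
  for (int i = 0; i < N; ++i) {
    x = x + (a * x - b * x * x * x) * dt + sigma * norm_rand();
    if (std::fabs(x) > blow)
      stop("trajectory diverged (|x| > 10*sqrt(a/b)); reduce dt or the noise scale");
    out[i] = x;
  }
  return out;
}
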