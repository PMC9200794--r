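#include <Rcpp.h>
using namespace Rcpp;

// Sequences arrive as integer codes A=0, C=1, G=2, T=3 (lexicographic order).

// Overlapping counts of every word of length 1..K, ordered by word length
// ascending then lexicographically (first character most significant).
// [[Rcpp::export]]
NumericVector cpp_word_counts(IntegerVector s, int K) {
  int L = s.size();
  int total = 0;
  for (int o = 1; o <= K; ++o) total += (int) pow(4.0, o);
  NumericVector out(total);
  int offset = 0;
  for (int o = 1; o <= K; ++o) {
    int nwords = (int) pow(4.0, o);
    for (int start = 0; start + o <= L; ++start) {
      int code = 0;
      for (int k = 0; k < o; ++k) code = code * 4 + s[start + k];
      out[offset + code] += 1.0;
    }
    offset += nwords;
  }
  return out;
}

// Overlapping counts of patterns left-word (length a) + g wildcards + right-word
// (length b), for g = 1..ngap. Canonical order: gap ascending (outer), then
// left word, then right word, lexicographic with A<C<G<T.
// [[Rcpp::export]]
NumericVector cpp_kgap_counts(IntegerVector s, int a, int b, int ngap) {
  int L = s.size();
  int A = (int) pow(4.0, a), B = (int) pow(4.0, b);
  NumericVector out(A * B * ngap);
  if (L < a + 1 + b) return out;
  // rolling codes for words of length a and b at every start position
  std::vector<int> lcode(L - a + 1), rcode(L - b + 1);
  for (int i = 0; i + a <= L; ++i) {
    int c = 0;
    for (int k = 0; k < a; ++k) c = c * 4 + s[i + k];
    lcode[i] = c;
  }
  if (b == a) {
    rcode.assign(lcode.begin(), lcode.end());
  } else {
    for (int i = 0; i + b <= L; ++i) {
      int c = 0;
      for (int k = 0; k < b; ++k) c = c * 4 + s[i + k];
      rcode[i] = c;
    }
  }
  for (int g = 1; g <= ngap; ++g) {
    int span = a + g + b;
    int base = (g - 1) * A * B;
    for (int i = 0; i + span <= L; ++i)
      out[base + lcode[i] * B + rcode[i + a + g]] += 1.0;
  }
  return out;
}

// Best axis-aligned split by least-squares (variance reduction) on the rows
// flagged in `innode`. `ord` holds 0-based row indices sorted per feature
// (one column per feature) and `Xs` the matching presorted feature values
// (Xs(k, j) = X(ord(k, j), j)); both are computed once per fit so each scan
// is a cache-friendly O(n d) pass. Gain = SSE(parent) - SSE(left) -
// SSE(right); ties broken by lowest feature index then lowest threshold
// (strict > comparison).
// [[Rcpp::export]]
List cpp_sse_scan(NumericMatrix Xs, IntegerMatrix ord, LogicalVector innode,
                  NumericVector r, int min_leaf) {
  int n = Xs.nrow(), d = Xs.ncol();
  double S = 0.0; int N = 0;
  for (int i = 0; i < n; ++i) if (innode[i]) { S += r[i]; ++N; }
  int best_j = -1; double best_thr = NA_REAL, best_gain = 0.0;
  if (N < 2 * min_leaf) return List::create(_["feature"] = 0,
    _["threshold"] = NA_REAL, _["gain"] = 0.0);
  double parent_term = S * S / N;
  for (int j = 0; j < d; ++j) {
    const int *oj = &ord(0, j);
    const double *xj = &Xs(0, j);
    double Sl = 0.0; int nl = 0;
    double prev_val = 0.0; bool have_prev = false;
    for (int k = 0; k < n; ++k) {
      int i = oj[k];
      if (!innode[i]) continue;
      double v = xj[k];
      if (have_prev && v > prev_val && nl >= min_leaf && (N - nl) >= min_leaf) {
        double gain = Sl * Sl / nl + (S - Sl) * (S - Sl) / (N - nl) - parent_term;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_j = j;
          best_thr = 0.5 * (prev_val + v);
        }
      }
      Sl += r[i]; ++nl;
      prev_val = v; have_prev = true;
    }
  }
  return List::create(_["feature"] = best_j + 1, _["threshold"] = best_thr,
                      _["gain"] = best_gain);
}

// Best split by weighted Gini impurity decrease for binary labels y in {0,1}
// with sample weights w. Same presorted layout as cpp_sse_scan. Returns the
// absolute impurity decrease W*G(parent) - Wl*G(left) - Wr*G(right),
// G = 2 p (1-p).
// [[Rcpp::export]]
List cpp_gini_scan(NumericMatrix Xs, IntegerMatrix ord, LogicalVector innode,
                   NumericVector w, IntegerVector y, int min_leaf) {
  int n = Xs.nrow(), d = Xs.ncol();
  double W = 0.0, Wp = 0.0; int N = 0;
  for (int i = 0; i < n; ++i) if (innode[i]) {
    W += w[i]; if (y[i] == 1) Wp += w[i]; ++N;
  }
  int best_j = -1; double best_thr = NA_REAL, best_dec = 0.0;
  if (N < 2 * min_leaf || W <= 0.0)
    return List::create(_["feature"] = 0, _["threshold"] = NA_REAL,
                        _["decrease"] = 0.0);
  // fold weight and class into one signed vector: wy[i] = w[i] * y[i]
  std::vector<double> wv(n), wyv(n);
  for (int i = 0; i < n; ++i) { wv[i] = w[i]; wyv[i] = y[i] == 1 ? w[i] : 0.0; }
  double parent = 2.0 * Wp * (W - Wp) / W;
  for (int j = 0; j < d; ++j) {
    const int *oj = &ord(0, j);
    const double *xj = &Xs(0, j);
    double Wl = 0.0, Wlp = 0.0; int nl = 0;
    double prev_val = 0.0; bool have_prev = false;
    for (int k = 0; k < n; ++k) {
      int i = oj[k];
      if (!innode[i]) continue;
      double v = xj[k];
      if (have_prev && v > prev_val && nl >= min_leaf && (N - nl) >= min_leaf &&
          Wl > 0.0 && (W - Wl) > 0.0) {
        double Wr = W - Wl, Wrp = Wp - Wlp;
        double dec = parent - 2.0 * Wlp * (Wl - Wlp) / Wl
                            - 2.0 * Wrp * (Wr - Wrp) / Wr;
        if (dec > best_dec + 1e-12) {
          best_dec = dec;
          best_j = j;
          best_thr = 0.5 * (prev_val + v);
        }
      }
      Wl += wv[i]; Wlp += wyv[i];
      ++nl;
      prev_val = v; have_prev = true;
    }
  }
  return List::create(_["feature"] = best_j + 1, _["threshold"] = best_thr,
                      _["decrease"] = best_dec);
}

// Presort helper: returns 0-based order indices (n x d) and the sorted
// values, avoiding d separate R-level order() calls.
// [[Rcpp::export]]
List cpp_presort(NumericMatrix X) {
  int n = X.nrow(), d = X.ncol();
  IntegerMatrix ord(n, d);
  NumericMatrix Xs(n, d);
  std::vector<int> idx(n);
  for (int j = 0; j < d; ++j) {
    const double *xj = &X(0, j);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::stable_sort(idx.begin(), idx.end(),
                     [xj](int a, int b) { return xj[a] < xj[b]; });
    for (int k = 0; k < n; ++k) {
      ord(k, j) = idx[k];
      Xs(k, j) = xj[idx[k]];
    }
  }
  return List::create(_["ord"] = ord, _["sorted"] = Xs);
}
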