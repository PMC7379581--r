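#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

// Global pairwise alignment identity.
//
// Scoring: match +1, mismatch -1, gap -2 per column, end gaps penalized
// (plain Needleman-Wunsch). Identity is matches / span, where span counts
// the alignment columns between the first and the last aligned pair
// (terminal gap columns excluded from the denominator). Co-optimal
// alignments are disambiguated lexicographically: maximal score, then
// maximal matches, then minimal span. The scheme is fixed, not tunable,
// so identities are comparable across markers and runs.

static const int NEG = INT_MIN / 4;

struct Tup {
  int score;
  int match;
  int span;
};

static inline bool better(const Tup &a, const Tup &b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.match != b.match) return a.match > b.match;
  return a.span < b.span;
}

static Tup align_tuple(const std::string &a, const std::string &b) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  // best over complete alignments; start from the all-gap alignment
  Tup best = { -2 * (n + m), 0, 0 };
  if (n == 0 || m == 0) return best;

  // L1 layer: >=1 aligned pair so far; rolling rows
  std::vector<int> ps(m + 1), pm(m + 1), pp(m + 1);  // previous row
  std::vector<int> cs(m + 1), cm(m + 1), cp(m + 1);  // current row
  for (int j = 0; j <= m; ++j) { ps[j] = NEG; pm[j] = 0; pp[j] = 0; }

  for (int i = 1; i <= n; ++i) {
    cs[0] = NEG; cm[0] = 0; cp[0] = 0;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const bool eq = (ai == b[j - 1]);
      const int sub = eq ? 1 : -1;
      // first aligned pair: leading gaps -2*(i-1 + j-1), all terminal
      Tup cand = { -2 * (i - 1 + j - 1) + sub, eq ? 1 : 0, 1 };
      if (ps[j - 1] > NEG) {  // diagonal within L1
        Tup t = { ps[j - 1] + sub, pm[j - 1] + (eq ? 1 : 0), pp[j - 1] + 1 };
        if (better(t, cand)) cand = t;
      }
      if (ps[j] > NEG) {      // gap: consume a
        Tup t = { ps[j] - 2, pm[j], pp[j] + 1 };
        if (better(t, cand)) cand = t;
      }
      if (cs[j - 1] > NEG) {  // gap: consume b
        Tup t = { cs[j - 1] - 2, cm[j - 1], cp[j - 1] + 1 };
        if (better(t, cand)) cand = t;
      }
      cs[j] = cand.score; cm[j] = cand.match; cp[j] = cand.span;
      // close out here: remaining residues become terminal gaps
      Tup closed = { cand.score - 2 * ((n - i) + (m - j)),
                     cand.match, cand.span };
      if (better(closed, best)) best = closed;
    }
    std::swap(ps, cs); std::swap(pm, cm); std::swap(pp, cp);
  }
  return best;
}

static inline double tup_identity(const Tup &t) {
  return t.span == 0 ? 0.0 : (double)t.match / (double)t.span;
}

// [[Rcpp::export]]
List pairwise_identity_cpp(std::string a, std::string b) {
  Tup t = align_tuple(a, b);
  return List::create(
    _["identity"] = tup_identity(t),
    _["score"] = t.score,
    _["matches"] = t.match,
    _["columns"] = t.span
  );
}

// [[Rcpp::export]]
NumericMatrix identity_matrix_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double id = tup_identity(align_tuple(s[i], s[j]));
      out(i, j) = id;
      out(j, i) = id;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector identity_to_refs_cpp(std::string q, CharacterVector refs) {
  const int n = refs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = tup_identity(align_tuple(q, as<std::string>(refs[i])));
  }
  return out;
}
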