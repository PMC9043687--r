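#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Equivalence table over raw chars. For the plain metrics this is the
// identity relation; for the property-recoded variants it is the symmetric,
// reflexive (but non-transitive) amino-acid property relation.
struct EqTable {
  bool eq[256][256];
  EqTable() { std::memset(eq, 0, sizeof(eq)); }
  inline bool operator()(unsigned char a, unsigned char b) const {
    return eq[a][b];
  }
};

static EqTable make_table(const CharacterVector &alphabet,
                          const LogicalMatrix &m) {
  int k = alphabet.size();
  if (m.nrow() != k || m.ncol() != k)
    stop("equivalence matrix must be square over the alphabet");
  EqTable t;
  std::vector<unsigned char> ch(k);
  for (int i = 0; i < k; ++i) {
    std::string s = as<std::string>(alphabet[i]);
    if (s.size() != 1) stop("alphabet entries must be single characters");
    ch[i] = (unsigned char)s[0];
  }
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      if (m(i, j)) t.eq[ch[i]][ch[j]] = true;
  return t;
}

static int lcs_len(const std::string &a, const std::string &b,
                   const EqTable &t) {
  int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (t((unsigned char)a[i - 1], (unsigned char)b[j - 1]))
        cur[j] = prev[j - 1] + 1;
      else
        cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

static int hamming_d(const std::string &a, const std::string &b,
                     const EqTable &t) {
  if (a.size() != b.size())
    stop("hamming distance requires equal-length strings");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (!t((unsigned char)a[i], (unsigned char)b[i])) ++d;
  return d;
}

static int lv_d(const std::string &a, const std::string &b, const EqTable &t) {
  int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] +
                (t((unsigned char)a[i - 1], (unsigned char)b[j - 1]) ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Optimal string alignment: Levenshtein plus adjacent transposition, no
// substring edited twice.
static int osa_d(const std::string &a, const std::string &b, const EqTable &t) {
  int n = a.size(), m = b.size();
  std::vector<std::vector<int>> d(n + 1, std::vector<int>(m + 1));
  for (int i = 0; i <= n; ++i) d[i][0] = i;
  for (int j = 0; j <= m; ++j) d[0][j] = j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int cost = t((unsigned char)a[i - 1], (unsigned char)b[j - 1]) ? 0 : 1;
      d[i][j] = std::min(d[i - 1][j - 1] + cost,
                         std::min(d[i - 1][j] + 1, d[i][j - 1] + 1));
      if (i > 1 && j > 1 && t((unsigned char)a[i - 1], (unsigned char)b[j - 2]) &&
          t((unsigned char)a[i - 2], (unsigned char)b[j - 1]))
        d[i][j] = std::min(d[i][j], d[i - 2][j - 2] + 1);
    }
  }
  return d[n][m];
}

// Unrestricted Damerau-Levenshtein. The classic last-occurrence bookkeeping
// assumes character identity is transitive, which the property relation is
// not, so matching rows/columns are located by explicit backwards scans
// (fine for short peptides).
static int dl_d(const std::string &a, const std::string &b, const EqTable &t) {
  int n = a.size(), m = b.size();
  int inf = n + m + 1;
  std::vector<std::vector<int>> d(n + 2, std::vector<int>(m + 2, inf));
  d[1][1] = 0;
  for (int i = 0; i <= n; ++i) d[i + 1][1] = i;
  for (int j = 0; j <= m; ++j) d[1][j + 1] = j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int cost = t((unsigned char)a[i - 1], (unsigned char)b[j - 1]) ? 0 : 1;
      int best = std::min(d[i][j] + cost,
                          std::min(d[i][j + 1] + 1, d[i + 1][j] + 1));
      // transposition: last k < i with a[k-1] ~ b[j-1], last l < j with
      // b[l-1] ~ a[i-1]
      for (int k = i - 1; k >= 1; --k) {
        if (!t((unsigned char)a[k - 1], (unsigned char)b[j - 1])) continue;
        for (int l = j - 1; l >= 1; --l) {
          if (!t((unsigned char)b[l - 1], (unsigned char)a[i - 1])) continue;
          best = std::min(best, d[k][l] + (i - k - 1) + (j - l - 1) + 1);
          break;
        }
        break;
      }
      d[i + 1][j + 1] = best;
    }
  }
  return d[n + 1][m + 1];
}

// [[Rcpp::export(name = ".cpp_pair_metric")]]
NumericVector cpp_pair_metric(CharacterVector s1, CharacterVector s2,
                              std::string metric, CharacterVector alphabet,
                              LogicalMatrix eq) {
  if (s1.size() != s2.size()) stop("s1 and s2 must have equal length");
  EqTable t = make_table(alphabet, eq);
  int n = s1.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(s1[i]);
    std::string b = as<std::string>(s2[i]);
    if (metric == "lcs_length")
      out[i] = lcs_len(a, b, t);
    else if (metric == "lcs")
      out[i] = (double)a.size() + (double)b.size() - 2.0 * lcs_len(a, b, t);
    else if (metric == "hamming")
      out[i] = hamming_d(a, b, t);
    else if (metric == "lv")
      out[i] = lv_d(a, b, t);
    else if (metric == "osa")
      out[i] = osa_d(a, b, t);
    else if (metric == "dl")
      out[i] = dl_d(a, b, t);
    else
      stop("unknown metric id: " + metric);
  }
  return out;
}

// Residue multiset intersection size bounds the LCS from above; used as a
// cheap prefilter before the DP in the all-pairs and one-vs-many scans.
static void count_residues(const std::string &s, int *cnt) {
  std::memset(cnt, 0, 26 * sizeof(int));
  for (char c : s) {
    int k = c - 'A';
    if (k >= 0 && k < 26) ++cnt[k];
  }
}

static inline int multiset_cap(const int *c1, const int *c2) {
  int s = 0;
  for (int k = 0; k < 26; ++k) s += std::min(c1[k], c2[k]);
  return s;
}

// All-pairs adjacency under plain LCS distance <= max_dist. Returns a
// 2-column matrix of 1-based index pairs (i < j).
// [[Rcpp::export(name = ".cpp_adjacency_pairs")]]
IntegerMatrix cpp_adjacency_pairs(CharacterVector seqs, int max_dist) {
  int n = seqs.size();
  EqTable t;
  for (int c = 0; c < 256; ++c) t.eq[c][c] = true;
  std::vector<std::string> s(n);
  std::vector<std::array<int, 26>> cnt(n);
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(seqs[i]);
    count_residues(s[i], cnt[i].data());
  }
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i) {
    int li = s[i].size();
    for (int j = i + 1; j < n; ++j) {
      int lj = s[j].size();
      // need LCS >= (li + lj - max_dist) / 2
      int need2 = li + lj - max_dist; // 2 * needed LCS
      if (2 * multiset_cap(cnt[i].data(), cnt[j].data()) < need2) continue;
      int d = li + lj - 2 * lcs_len(s[i], s[j], t);
      if (d <= max_dist) {
        ei.push_back(i + 1);
        ej.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t k = 0; k < ei.size(); ++k) {
    out(k, 0) = ei[k];
    out(k, 1) = ej[k];
  }
  return out;
}

// For each query sequence, the number of reference sequences within plain
// LCS distance <= max_dist.
// [[Rcpp::export(name = ".cpp_neighbor_counts")]]
IntegerVector cpp_neighbor_counts(CharacterVector query, CharacterVector ref,
                                  int max_dist) {
  int n = query.size(), m = ref.size();
  EqTable t;
  for (int c = 0; c < 256; ++c) t.eq[c][c] = true;
  std::vector<std::string> q(n), r(m);
  std::vector<std::array<int, 26>> qc(n), rc(m);
  for (int i = 0; i < n; ++i) {
    q[i] = as<std::string>(query[i]);
    count_residues(q[i], qc[i].data());
  }
  for (int j = 0; j < m; ++j) {
    r[j] = as<std::string>(ref[j]);
    count_residues(r[j], rc[j].data());
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int li = q[i].size(), c = 0;
    for (int j = 0; j < m; ++j) {
      int need2 = li + (int)r[j].size() - max_dist;
      if (2 * multiset_cap(qc[i].data(), rc[j].data()) < need2) continue;
      int d = li + r[j].size() - 2 * lcs_len(q[i], r[j], t);
      if (d <= max_dist) ++c;
    }
    out[i] = c;
  }
  return out;
}
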