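#include <Rcpp.h>
using namespace Rcpp;

static int lcs_len(const int* a, int na, const int* b, int nb,
                   std::vector<int>& prev, std::vector<int>& cur) {
  if (na == 0 || nb == 0) return 0;
  prev.assign(nb + 1, 0);
  cur.assign(nb + 1, 0);
  for (int i = 1; i <= na; ++i) {
    cur[0] = 0;
    const int ai = a[i - 1];
    for (int j = 1; j <= nb; ++j) {
      if (ai == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = prev[j] >= cur[j - 1] ? prev[j] : cur[j - 1];
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// Longest common subsequence length of two code-point vectors.
// [[Rcpp::export]]
int lcs_length_ids(IntegerVector a, IntegerVector b) {
  std::vector<int> prev, cur;
  return lcs_len(INTEGER(a), a.size(), INTEGER(b), b.size(), prev, cur);
}

// Longest common (contiguous) substring length of two code-point vectors.
// [[Rcpp::export]]
int lcsubstring_length_ids(IntegerVector a, IntegerVector b) {
  int na = a.size(), nb = b.size();
  if (na == 0 || nb == 0) return 0;
  std::vector<int> prev(nb + 1, 0), cur(nb + 1, 0);
  int best = 0;
  for (int i = 1; i <= na; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= nb; ++j) {
      if (a[i - 1] == b[j - 1]) {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) best = cur[j];
      } else cur[j] = 0;
    }
    std::swap(prev, cur);
  }
  return best;
}

// Pairwise LCS lengths between two lists of code-point vectors.
// [[Rcpp::export]]
NumericMatrix lcs_length_matrix(List a, List b) {
  int na = a.size(), nb = b.size();
  NumericMatrix out(na, nb);
  std::vector<int> prev, cur;
  for (int i = 0; i < na; ++i) {
    IntegerVector ai = a[i];
    for (int j = 0; j < nb; ++j) {
      IntegerVector bj = b[j];
      out(i, j) = lcs_len(INTEGER(ai), ai.size(), INTEGER(bj), bj.size(), prev, cur);
    }
  }
  return out;
}
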