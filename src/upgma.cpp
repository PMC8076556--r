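#include <Rcpp.h>
using namespace Rcpp;

// Unweighted average-linkage agglomeration.
//
// Works on sums of the ORIGINAL pairwise distances between clusters rather
// than on running averages: for integer inputs (Levenshtein distances) sums
// stay exact in doubles, so merge heights are exact averages and the result
// is invariant under input permutation up to leaf relabeling.  Candidate
// averages a1/b1 vs a2/b2 are compared by cross-multiplication (a1*b2 vs
// a2*b1), exact below 2^53.  Ties are broken on the smallest leaf label
// ranks contained in each cluster: smallest (min rank, max rank) wins.
//
// Returns an hclust-style merge matrix (negative = leaf, positive = prior
// merge) and the vector of merge heights.
// [[Rcpp::export]]
List upgma_engine(NumericMatrix d, IntegerVector leaf_rank) {
  const int n = d.nrow();
  if (n < 2) stop("need at least two items");
  if (leaf_rank.size() != n) stop("leaf_rank must have one entry per item");

  // S[i][j]: sum of original distances between members of clusters i and j
  std::vector<std::vector<double> > S(n, std::vector<double>(n, 0.0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) S[i][j] = d(i, j);

  std::vector<int> size(n, 1);        // leaves under cluster slot
  std::vector<int> minleaf(n);        // smallest leaf label rank in cluster
  std::vector<int> id(n);             // hclust id: -leaf or +merge step
  std::vector<bool> active(n, true);
  for (int i = 0; i < n; ++i) { minleaf[i] = leaf_rank[i]; id[i] = -(i + 1); }

  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);

  for (int step = 0; step < n - 1; ++step) {
    int bi = -1, bj = -1;
    double bnum = 0.0, bden = 1.0;    // best average = bnum / bden
    int bl1 = 0, bl2 = 0;
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      for (int j = i + 1; j < n; ++j) {
        if (!active[j]) continue;
        double num = S[i][j];
        double den = (double)size[i] * (double)size[j];
        int l1 = minleaf[i] < minleaf[j] ? minleaf[i] : minleaf[j];
        int l2 = minleaf[i] < minleaf[j] ? minleaf[j] : minleaf[i];
        bool better;
        if (bi < 0) better = true;
        else {
          double lhs = num * bden, rhs = bnum * den;
          if (lhs < rhs) better = true;
          else if (lhs > rhs) better = false;
          else better = (l1 < bl1) || (l1 == bl1 && l2 < bl2);
        }
        if (better) { bi = i; bj = j; bnum = num; bden = den; bl1 = l1; bl2 = l2; }
      }
    }

    // record merge (hclust convention: leaves first, else by merge step)
    int a = id[bi], b = id[bj];
    bool aFirst = (a < 0 && b < 0) ? (-a < -b ? true : false)
                : (a < 0) ? true
                : (b < 0) ? false
                : (a < b);
    merge(step, 0) = aFirst ? a : b;
    merge(step, 1) = aFirst ? b : a;
    height[step] = bnum / bden;

    // fold cluster bj into bi
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == bi || k == bj) continue;
      double s = S[bi][k] + S[bj][k];
      S[bi][k] = s; S[k][bi] = s;
    }
    size[bi] += size[bj];
    if (minleaf[bj] < minleaf[bi]) minleaf[bi] = minleaf[bj];
    id[bi] = step + 1;
    active[bj] = false;
  }

  return List::create(_["merge"] = merge, _["height"] = height);
}

// Full Levenshtein distance matrix over a character vector; unit costs.
// [[Rcpp::export]]
IntegerMatrix levenshtein_matrix(CharacterVector x) {
  const int n = x.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
  IntegerMatrix out(n, n);
  std::vector<int> prev, cur;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const std::string &a = s[i], &b = s[j];
      const int la = a.size(), lb = b.size();
      prev.assign(lb + 1, 0); cur.assign(lb + 1, 0);
      for (int q = 0; q <= lb; ++q) prev[q] = q;
      for (int p = 1; p <= la; ++p) {
        cur[0] = p;
        for (int q = 1; q <= lb; ++q) {
          int sub = prev[q - 1] + (a[p - 1] == b[q - 1] ? 0 : 1);
          int del = prev[q] + 1, ins = cur[q - 1] + 1;
          cur[q] = sub < del ? (sub < ins ? sub : ins) : (del < ins ? del : ins);
        }
        std::swap(prev, cur);
      }
      out(i, j) = prev[lb]; out(j, i) = prev[lb];
    }
  }
  return out;
}
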