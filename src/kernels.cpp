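// Convolution tree-kernel dynamic programme (ST and SST modes) over
// flattened trees, plus Gram / cross-Gram assembly.
//
// Trees arrive pre-flattened from R: per tree an integer vector `prod`
// giving a production id per internal node (ids shared across the whole
// call, so integer equality is production equality; the id encodes the
// parent label, the ordered child labels and which children are leaves) and
// a list `kids` of 0-based integer vectors with each node's internal
// children, aligned with the production's child order.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

namespace {

struct FlatTree {
  std::vector<int> prod;               // production id per internal node
  std::vector<std::vector<int>> kids;  // internal children (0-based)
};

std::vector<FlatTree> convert(const List& trees) {
  std::vector<FlatTree> out(trees.size());
  for (R_xlen_t t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector prod = tr["prod"];
    List kids = tr["kids"];
    FlatTree& ft = out[t];
    ft.prod.assign(prod.begin(), prod.end());
    ft.kids.resize(kids.size());
    for (R_xlen_t i = 0; i < kids.size(); ++i) {
      IntegerVector k = kids[i];
      ft.kids[i].assign(k.begin(), k.end());
    }
  }
  return out;
}

// delta(n1, n2): number of common fragments rooted at the pair, decayed.
// 0 when productions differ.  With equal productions: lambda times, over
// aligned internal children, the product of (1 + delta) in SST mode or of
// delta in ST mode (ST requires the full descendant subtrees to match).
double delta_rec(const FlatTree& a, const FlatTree& b, int i, int j,
                 double lambda, bool st_mode, std::vector<double>& memo,
                 std::size_t nb) {
  double& m = memo[i * nb + j];
  if (m >= 0.0) return m;
  if (a.prod[i] != b.prod[j]) return m = 0.0;
  double v = lambda;
  const std::vector<int>& ka = a.kids[i];
  const std::vector<int>& kb = b.kids[j];
  for (std::size_t c = 0; c < ka.size(); ++c) {
    double d = delta_rec(a, b, ka[c], kb[c], lambda, st_mode, memo, nb);
    v *= st_mode ? d : (1.0 + d);
    if (v == 0.0) break;
  }
  return m = v;
}

// Unnormalized kernel: sum of delta over all internal-node pairs.
double pair_kernel(const FlatTree& a, const FlatTree& b, double lambda,
                   bool st_mode, std::vector<double>& memo) {
  const std::size_t na = a.prod.size(), nb = b.prod.size();
  memo.assign(na * nb, -1.0);
  double total = 0.0;
  for (std::size_t i = 0; i < na; ++i) {
    for (std::size_t j = 0; j < nb; ++j) {
      if (a.prod[i] == b.prod[j]) {
        total += delta_rec(a, b, (int)i, (int)j, lambda, st_mode, memo, nb);
      }
    }
  }
  return total;
}

std::vector<double> self_kernels(const std::vector<FlatTree>& ts,
                                 double lambda, bool st_mode) {
  std::vector<double> out(ts.size());
  std::vector<double> memo;
  for (std::size_t i = 0; i < ts.size(); ++i) {
    out[i] = pair_kernel(ts[i], ts[i], lambda, st_mode, memo);
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
double cpp_tree_kernel(List t1, List t2, double lambda, bool st_mode) {
  List both = List::create(t1, t2);
  std::vector<FlatTree> ts = convert(both);
  std::vector<double> memo;
  return pair_kernel(ts[0], ts[1], lambda, st_mode, memo);
}

// [[Rcpp::export]]
NumericMatrix cpp_gram_matrix(List trees, double lambda, bool st_mode,
                              bool normalize) {
  std::vector<FlatTree> ts = convert(trees);
  const std::size_t n = ts.size();
  NumericMatrix K(n, n);
  std::vector<double> selfk = self_kernels(ts, lambda, st_mode);
  if (normalize) {
    for (std::size_t i = 0; i < n; ++i) {
      if (selfk[i] <= 0.0) stop("degenerate instance with zero self-kernel");
    }
  }
  std::vector<double> memo;
  for (std::size_t i = 0; i < n; ++i) {
    K(i, i) = normalize ? 1.0 : selfk[i];
    for (std::size_t j = i + 1; j < n; ++j) {
      double v = pair_kernel(ts[i], ts[j], lambda, st_mode, memo);
      if (normalize) v /= std::sqrt(selfk[i] * selfk[j]);
      K(i, j) = v;
      K(j, i) = v;
    }
  }
  return K;
}

// [[Rcpp::export]]
NumericMatrix cpp_cross_matrix(List trees_a, List trees_b, double lambda,
                               bool st_mode, bool normalize) {
  std::vector<FlatTree> ta = convert(trees_a);
  std::vector<FlatTree> tb = convert(trees_b);
  NumericMatrix K(ta.size(), tb.size());
  std::vector<double> sa, sb;
  if (normalize) {
    sa = self_kernels(ta, lambda, st_mode);
    sb = self_kernels(tb, lambda, st_mode);
    for (double v : sa) if (v <= 0.0) stop("degenerate instance with zero self-kernel");
    for (double v : sb) if (v <= 0.0) stop("degenerate instance with zero self-kernel");
  }
  std::vector<double> memo;
  for (std::size_t i = 0; i < ta.size(); ++i) {
    for (std::size_t j = 0; j < tb.size(); ++j) {
      double v = pair_kernel(ta[i], tb[j], lambda, st_mode, memo);
      if (normalize) v /= std::sqrt(sa[i] * sb[j]);
      K(i, j) = v;
    }
  }
  return K;
}
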