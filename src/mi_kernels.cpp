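// Mutual-information kernels.
//
// Plug-in (maximum-likelihood) MI in bits over integer-coded columns
// (residues 1..20, gap/unknown 21). Permutation nulls are driven by
// permutation index matrices generated in R, so results are reproducible
// under set.seed(). The joint-count scratch array is re-zeroed by walking the
// same cells that were incremented, keeping every pair O(n_rows).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double LOG2 = 0.6931471805599453; // ln 2

// Shannon entropy (bits) of one coded column.
static double column_entropy(const int* x, int n, int nsym,
                             std::vector<int>& cnt) {
  std::fill(cnt.begin(), cnt.begin() + nsym, 0);
  for (int r = 0; r < n; ++r) cnt[x[r] - 1]++;
  double s = 0.0;
  for (int a = 0; a < nsym; ++a) {
    if (cnt[a] > 0) s += cnt[a] * std::log((double)cnt[a]);
  }
  return (std::log((double)n) - s / n) / LOG2;
}

// Joint entropy (bits) of two coded columns; `joint` must be zeroed on entry
// and is left zeroed on exit.
static double joint_entropy(const int* x, const int* y, int n, int nsym,
                            std::vector<int>& joint) {
  for (int r = 0; r < n; ++r) joint[(x[r] - 1) * nsym + (y[r] - 1)]++;
  double s = 0.0;
  for (int r = 0; r < n; ++r) {
    int idx = (x[r] - 1) * nsym + (y[r] - 1);
    if (joint[idx] > 0) {
      s += joint[idx] * std::log((double)joint[idx]);
      joint[idx] = 0;
    }
  }
  return (std::log((double)n) - s / n) / LOG2;
}

// [[Rcpp::export]]
NumericMatrix pairwise_mi_cpp(IntegerMatrix codes, int nsym) {
  const int n = codes.nrow(), p = codes.ncol();
  NumericMatrix mi(p, p);
  std::vector<int> cnt(nsym), joint(nsym * nsym, 0);
  std::vector<double> h(p);
  for (int j = 0; j < p; ++j) h[j] = column_entropy(&codes(0, j), n, nsym, cnt);
  for (int i = 0; i < p; ++i) {
    mi(i, i) = h[i];
    for (int j = i + 1; j < p; ++j) {
      double hij = joint_entropy(&codes(0, i), &codes(0, j), n, nsym, joint);
      double v = h[i] + h[j] - hij;
      if (v < 0) v = 0; // guard tiny negative rounding
      mi(i, j) = v;
      mi(j, i) = v;
    }
  }
  return mi;
}

// Permutation null for all column pairs: for each shuffle, the rows of the
// second column are permuted by perms[, s] (1-based). Returns per-pair null
// mean and sd (upper triangle, i < j).
// [[Rcpp::export]]
List pairwise_mi_null_cpp(IntegerMatrix codes, int nsym, IntegerMatrix perms) {
  const int n = codes.nrow(), p = codes.ncol(), S = perms.ncol();
  std::vector<int> cnt(nsym), joint(nsym * nsym, 0);
  std::vector<double> h(p);
  for (int j = 0; j < p; ++j) h[j] = column_entropy(&codes(0, j), n, nsym, cnt);

  NumericMatrix sum(p, p), sumsq(p, p);
  std::vector<int> perm_col(n);
  IntegerMatrix permuted(n, p);
  for (int s = 0; s < S; ++s) {
    for (int r = 0; r < n; ++r) perm_col[r] = perms(r, s) - 1;
    for (int j = 0; j < p; ++j) {
      for (int r = 0; r < n; ++r) permuted(r, j) = codes(perm_col[r], j);
    }
    for (int i = 0; i < p; ++i) {
      for (int j = i + 1; j < p; ++j) {
        double hij = joint_entropy(&codes(0, i), &permuted(0, j), n, nsym, joint);
        double v = h[i] + h[j] - hij;
        if (v < 0) v = 0;
        sum(i, j) += v;
        sumsq(i, j) += v * v;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix mean(p, p), sd(p, p);
  for (int i = 0; i < p; ++i) {
    for (int j = i + 1; j < p; ++j) {
      double m = sum(i, j) / S;
      double var = (S > 1) ? (sumsq(i, j) - S * m * m) / (S - 1) : 0.0;
      if (var < 0) var = 0;
      mean(i, j) = m;
      sd(i, j) = std::sqrt(var);
    }
  }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}

// Column-vs-partition MI with a shared label-permutation null. labels are
// 1..k; perms[, s] permutes the label vector (the same permutations are
// reused across columns). Returns observed MI and per-column null mean/sd.
// [[Rcpp::export]]
List column_group_mi_null_cpp(IntegerMatrix codes, IntegerVector labels,
                              int nsym, int k, IntegerMatrix perms) {
  const int n = codes.nrow(), p = codes.ncol(), S = perms.ncol();
  std::vector<int> cnt(std::max(nsym, k)), joint(nsym * k, 0);
  std::vector<double> h(p);
  for (int j = 0; j < p; ++j) h[j] = column_entropy(&codes(0, j), n, nsym, cnt);

  std::vector<int> lab(n);
  for (int r = 0; r < n; ++r) lab[r] = labels[r];
  double hlab = column_entropy(lab.data(), n, k, cnt);

  // joint entropy between column x (nsym symbols) and labels y (k symbols)
  std::vector<int> jcnt(nsym * k, 0);
  auto joint_h = [&](const int* x, const int* y) {
    for (int r = 0; r < n; ++r) jcnt[(x[r] - 1) * k + (y[r] - 1)]++;
    double s = 0.0;
    for (int r = 0; r < n; ++r) {
      int idx = (x[r] - 1) * k + (y[r] - 1);
      if (jcnt[idx] > 0) {
        s += jcnt[idx] * std::log((double)jcnt[idx]);
        jcnt[idx] = 0;
      }
    }
    return (std::log((double)n) - s / n) / LOG2;
  };

  NumericVector mi_obs(p), sum(p), sumsq(p);
  for (int j = 0; j < p; ++j) {
    double v = h[j] + hlab - joint_h(&codes(0, j), lab.data());
    mi_obs[j] = v < 0 ? 0 : v;
  }
  std::vector<int> plab(n);
  for (int s = 0; s < S; ++s) {
    for (int r = 0; r < n; ++r) plab[r] = labels[perms(r, s) - 1];
    for (int j = 0; j < p; ++j) {
      double v = h[j] + hlab - joint_h(&codes(0, j), plab.data());
      if (v < 0) v = 0;
      sum[j] += v;
      sumsq[j] += v * v;
    }
    Rcpp::checkUserInterrupt();
  }
  NumericVector mean(p), sd(p);
  for (int j = 0; j < p; ++j) {
    double m = sum[j] / S;
    double var = (S > 1) ? (sumsq[j] - S * m * m) / (S - 1) : 0.0;
    if (var < 0) var = 0;
    mean[j] = m;
    sd[j] = std::sqrt(var);
  }
  return List::create(_["mi"] = mi_obs, _["mean"] = mean, _["sd"] = sd);
}
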