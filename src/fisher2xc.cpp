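#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Exact test of homogeneity for a 2 x c contingency table, by complete
// enumeration of all tables sharing the observed margins. Each table T has
// multivariate hypergeometric probability
//   P(T) = R1! R2! C1! ... Cc! / (N! prod_ij n_ij!)
// and the two-sided p-value sums P(T) over tables with
//   P(T) <= P(obs) * (1 + tie_tol),
// the small relative tolerance guarding exactly-tied tables against
// floating-point misses. All mass arithmetic is done in log space.

static double log_table_term(const std::vector<int> &a,
                             const std::vector<int> &colsum) {
  // -sum_j [ lgamma(a_j + 1) + lgamma(C_j - a_j + 1) ]  (first row a,
  // second row determined by the column sums)
  double s = 0.0;
  for (size_t j = 0; j < a.size(); ++j) {
    s -= std::lgamma(a[j] + 1.0) + std::lgamma(colsum[j] - a[j] + 1.0);
  }
  return s;
}

// Enumerate first rows recursively; accumulate total mass at or below the
// observed table's log-probability.
static void enumerate(size_t j, int remaining, double partial,
                      std::vector<int> &a, const std::vector<int> &colsum,
                      double log_cut, double &acc) {
  size_t c = colsum.size();
  if (j == c - 1) {
    if (remaining > colsum[j]) return;
    double lt = partial - std::lgamma(remaining + 1.0) -
                std::lgamma(colsum[j] - remaining + 1.0);
    if (lt <= log_cut) acc += std::exp(lt);
    return;
  }
  // lower bound so the tail columns can still absorb the remainder
  int tail = 0;
  for (size_t k = j + 1; k < c; ++k) tail += colsum[k];
  int lo = remaining - tail;
  if (lo < 0) lo = 0;
  int hi = remaining < colsum[j] ? remaining : colsum[j];
  for (int v = lo; v <= hi; ++v) {
    double p2 = partial - std::lgamma(v + 1.0) -
                std::lgamma(colsum[j] - v + 1.0);
    enumerate(j + 1, remaining - v, p2, a, colsum, log_cut, acc);
  }
}

static double fisher2xc_one(const std::vector<int> &row1,
                            const std::vector<int> &row2, double tie_tol) {
  size_t c = row1.size();
  std::vector<int> colsum(c);
  int r1 = 0, r2 = 0;
  for (size_t j = 0; j < c; ++j) {
    colsum[j] = row1[j] + row2[j];
    r1 += row1[j];
    r2 += row2[j];
  }
  int n = r1 + r2;
  // log of the margin-dependent constant
  double lconst = std::lgamma(r1 + 1.0) + std::lgamma(r2 + 1.0) -
                  std::lgamma(n + 1.0);
  for (size_t j = 0; j < c; ++j) lconst += std::lgamma(colsum[j] + 1.0);

  std::vector<int> obs(row1);
  double log_obs = lconst + log_table_term(obs, colsum);
  double log_cut = log_obs + std::log1p(tie_tol);

  double acc = 0.0;
  std::vector<int> a(c, 0);
  enumerate(0, r1, lconst, a, colsum, log_cut, acc);
  return acc > 1.0 ? 1.0 : acc;
}

// [[Rcpp::export(name = ".fisher2xc_cpp")]]
double fisher2xc_cpp(IntegerVector row1, IntegerVector row2, double tie_tol) {
  std::vector<int> a(row1.begin(), row1.end());
  std::vector<int> b(row2.begin(), row2.end());
  return fisher2xc_one(a, b, tie_tol);
}

// Batched variant: rows of `row1` / `row2` are the first/second rows of many
// 2 x c tables with a common column count.
// [[Rcpp::export(name = ".fisher2xc_batch_cpp")]]
NumericVector fisher2xc_batch_cpp(IntegerMatrix row1, IntegerMatrix row2,
                                  double tie_tol) {
  int m = row1.nrow(), c = row1.ncol();
  NumericVector out(m);
  std::vector<int> a(c), b(c);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < c; ++j) {
      a[j] = row1(i, j);
      b[j] = row2(i, j);
    }
    out[i] = fisher2xc_one(a, b, tie_tol);
  }
  return out;
}
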