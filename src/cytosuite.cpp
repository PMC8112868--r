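#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// squared Euclidean distance between row i of X and row j of C
static inline double row_dist2(const NumericMatrix &X, int i,
                               const NumericMatrix &C, int j) {
  double s = 0.0;
  const int p = X.ncol();
  for (int d = 0; d < p; ++d) {
    const double diff = X(i, d) - C(j, d);
    s += diff * diff;
  }
  return s;
}

static inline int best_matching_unit(const NumericMatrix &X, int i,
                                     const NumericMatrix &codes) {
  int best = 0;
  double bestd = R_PosInf;
  for (int j = 0; j < codes.nrow(); ++j) {
    const double d = row_dist2(X, i, codes, j);
    if (d < bestd) { bestd = d; best = j; }
  }
  return best;
}

// [[Rcpp::export(name = ".som_online")]]
NumericMatrix som_online(NumericMatrix x, NumericMatrix codes0,
                         NumericMatrix grid_d2, IntegerVector order,
                         double alpha0, double alpha_end,
                         double radius0, double radius_end) {
  NumericMatrix codes = clone(codes0);
  const int m = codes.nrow(), p = codes.ncol();
  const R_xlen_t T = order.size();
  for (R_xlen_t t = 0; t < T; ++t) {
    const double frac = (T > 1) ? (double)t / (double)(T - 1) : 0.0;
    const double alpha = alpha0 + (alpha_end - alpha0) * frac;
    const double radius = radius0 + (radius_end - radius0) * frac;
    const int i = order[t];  // 0-based cell index
    const int b = best_matching_unit(x, i, codes);
    if (radius < 1e-8) {
      for (int d = 0; d < p; ++d)
        codes(b, d) += alpha * (x(i, d) - codes(b, d));
    } else {
      const double denom = 2.0 * radius * radius;
      for (int j = 0; j < m; ++j) {
        const double h = std::exp(-grid_d2(j, b) / denom);
        if (h < 1e-4) continue;
        const double ah = alpha * h;
        for (int d = 0; d < p; ++d)
          codes(j, d) += ah * (x(i, d) - codes(j, d));
      }
    }
  }
  return codes;
}

// [[Rcpp::export(name = ".som_batch")]]
NumericMatrix som_batch(NumericMatrix x, NumericMatrix codes0,
                        NumericMatrix grid_d2, int iterations,
                        double radius0, double radius_end) {
  NumericMatrix codes = clone(codes0);
  const int n = x.nrow(), m = codes.nrow(), p = codes.ncol();
  std::vector<double> num((size_t)m * p), den(m);
  for (int it = 0; it < iterations; ++it) {
    const double frac = (iterations > 1) ? (double)it / (double)(iterations - 1)
                                         : 0.0;
    const double radius = radius0 + (radius_end - radius0) * frac;
    std::fill(num.begin(), num.end(), 0.0);
    std::fill(den.begin(), den.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const int b = best_matching_unit(x, i, codes);
      if (radius < 1e-8) {
        den[b] += 1.0;
        for (int d = 0; d < p; ++d) num[(size_t)b * p + d] += x(i, d);
      } else {
        const double denom = 2.0 * radius * radius;
        for (int j = 0; j < m; ++j) {
          const double h = std::exp(-grid_d2(j, b) / denom);
          if (h < 1e-4) continue;
          den[j] += h;
          for (int d = 0; d < p; ++d) num[(size_t)j * p + d] += h * x(i, d);
        }
      }
    }
    for (int j = 0; j < m; ++j) {
      if (den[j] > 0) {  // empty nodes keep their code (Lloyd convention)
        for (int d = 0; d < p; ++d) codes(j, d) = num[(size_t)j * p + d] / den[j];
      }
    }
  }
  return codes;
}

// nearest code per row + quantization error; 1-based node ids
// [[Rcpp::export(name = ".map_to_codes")]]
List map_to_codes(NumericMatrix x, NumericMatrix codes) {
  const int n = x.nrow();
  IntegerVector node(n);
  double qe = 0.0;
  for (int i = 0; i < n; ++i) {
    const int b = best_matching_unit(x, i, codes);
    node[i] = b + 1;
    qe += std::sqrt(row_dist2(x, i, codes, b));
  }
  return List::create(_["node"] = node,
                      _["quantization_error"] = qe / std::max(n, 1));
}

// Jaccard-weighted union kNN graph: nn is n x k, 1-based neighbour indices
// (self excluded in the input). Edge (i,j) exists if j in N(i) or i in N(j);
// weight is the Jaccard overlap of the self-inclusive neighbourhoods
// |Ñ(i) inter Ñ(j)| / |Ñ(i) union Ñ(j)| with Ñ(i) = N(i) ∪ {i}, so two
// mutual neighbours sharing all other neighbours weigh exactly 1.
// [[Rcpp::export(name = ".jaccard_edges")]]
DataFrame jaccard_edges(IntegerMatrix nn) {
  const int n = nn.nrow(), k = nn.ncol() + 1;
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i) {
    nbr[i].reserve(k);
    nbr[i].push_back(i);
    for (int j = 0; j < k - 1; ++j) nbr[i].push_back(nn(i, j) - 1);
    std::sort(nbr[i].begin(), nbr[i].end());
  }
  std::vector<std::pair<int, int>> pairs;
  pairs.reserve((size_t)n * (k - 1));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k - 1; ++j) {
      const int o = nn(i, j) - 1;
      if (o == i) continue;
      pairs.emplace_back(std::min(i, o), std::max(i, o));
    }
  std::sort(pairs.begin(), pairs.end());
  pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());

  std::vector<int> from, to;
  std::vector<double> w;
  from.reserve(pairs.size()); to.reserve(pairs.size()); w.reserve(pairs.size());
  std::vector<int> tmp(2 * k);
  for (const auto &pr : pairs) {
    const std::vector<int> &a = nbr[pr.first], &b = nbr[pr.second];
    auto it = std::set_intersection(a.begin(), a.end(), b.begin(), b.end(),
                                    tmp.begin());
    const int inter = (int)(it - tmp.begin());
    const int uni = (int)(a.size() + b.size()) - inter;
    const double jw = uni > 0 ? (double)inter / (double)uni : 0.0;
    if (jw > 0) {
      from.push_back(pr.first + 1);
      to.push_back(pr.second + 1);
      w.push_back(jw);
    }
  }
  return DataFrame::create(_["from"] = from, _["to"] = to, _["weight"] = w);
}
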