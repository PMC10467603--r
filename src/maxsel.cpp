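#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Two-group log-rank score U (observed - expected events in the "high" group)
// and hypergeometric variance V, over samples pre-sorted by ascending time.
// g_o[j] = 1 iff sample j (time order) is in the high group. Ties in time are
// handled in blocks: all samples tied at t are at risk for events at t.
static void logrank_uv(const std::vector<int>& g_o,
                       const double* time_o, const int* event_o, int n,
                       double& U, double& V) {
  U = 0.0;
  V = 0.0;
  int nrisk = n, nrisk1 = 0;
  for (int j = 0; j < n; ++j) nrisk1 += g_o[j];
  int i = 0;
  while (i < n) {
    int j = i, d = 0, d1 = 0, c = 0, c1 = 0;
    double t = time_o[i];
    while (j < n && time_o[j] == t) {
      if (event_o[j] == 1) { ++d; d1 += g_o[j]; }
      ++c; c1 += g_o[j];
      ++j;
    }
    if (d > 0) {
      double p1 = (double)nrisk1 / nrisk;
      U += d1 - d * p1;
      if (nrisk > 1)
        V += d * p1 * (1.0 - p1) * (double)(nrisk - d) / (nrisk - 1);
    }
    nrisk -= c;
    nrisk1 -= c1;
    i = j;
  }
}

// Scan midpoints between consecutive sorted unique values of x; a cut is
// admissible when both induced groups hold at least min_group samples.
// Returns the cut maximizing |U|/sqrt(V); ties broken by the smallest cut.
// [[Rcpp::export]]
List cpp_maxsel_scan(NumericVector x, NumericVector time, IntegerVector event,
                     double minprop) {
  int n = x.size();
  if (time.size() != n || event.size() != n)
    stop("x, time and event must have equal length");
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return time[a] < time[b]; });
  std::vector<double> time_o(n), x_o(n);
  std::vector<int> event_o(n);
  for (int i = 0; i < n; ++i) {
    time_o[i] = time[ord[i]];
    event_o[i] = event[ord[i]];
    x_o[i] = x[ord[i]];
  }
  std::vector<double> ux(x.begin(), x.end());
  std::sort(ux.begin(), ux.end());
  ux.erase(std::unique(ux.begin(), ux.end()), ux.end());
  int min_group = std::max(1, (int)std::ceil(minprop * n));

  double best_z = -1.0, best_cut = NA_REAL, best_U = 0.0, best_V = 0.0;
  int best_nhigh = 0;
  std::vector<int> g_o(n);
  bool any_admissible = false;
  for (size_t k = 0; k + 1 < ux.size(); ++k) {
    double cut = (ux[k] + ux[k + 1]) / 2.0;
    int nhigh = 0;
    for (int j = 0; j < n; ++j) {
      g_o[j] = x_o[j] > cut ? 1 : 0;
      nhigh += g_o[j];
    }
    if (nhigh < min_group || n - nhigh < min_group) continue;
    any_admissible = true;
    double U, V;
    logrank_uv(g_o, time_o.data(), event_o.data(), n, U, V);
    double z = (V > 0) ? std::fabs(U) / std::sqrt(V) : 0.0;
    if (z > best_z) {
      best_z = z;
      best_cut = cut;
      best_U = U;
      best_V = V;
      best_nhigh = nhigh;
    }
  }
  if (!any_admissible)
    return List::create(Named("admissible") = false);
  return List::create(Named("admissible") = true,
                      Named("cutpoint") = best_cut,
                      Named("statistic") = best_z,
                      Named("U") = best_U,
                      Named("V") = best_V,
                      Named("chisq") = best_z * best_z,
                      Named("n_high") = best_nhigh,
                      Named("n_low") = n - best_nhigh);
}

// Batch evaluation for beam search: extension e has integer score vector
// parent_scores[, parent_idx[e]] + points[, gene_idx[e]] (original sample
// order); each is classified by the maximally selected log-rank scan over
// integer score cutoffs c + 0.5. ord is the 1-based ascending-time order.
// Returns a matrix with columns chisq, cutoff, admissible.
// [[Rcpp::export]]
NumericMatrix cpp_beam_eval(IntegerMatrix parent_scores, IntegerMatrix points,
                            IntegerVector parent_idx, IntegerVector gene_idx,
                            IntegerVector ord, NumericVector time_o,
                            IntegerVector event_o, double minprop) {
  int n = time_o.size();
  int ne = parent_idx.size();
  if (gene_idx.size() != ne) stop("parent_idx/gene_idx length mismatch");
  NumericMatrix out(ne, 3);
  colnames(out) = CharacterVector::create("chisq", "cutoff", "admissible");
  int min_group = std::max(1, (int)std::ceil(minprop * n));
  const double* tp = REAL(time_o);
  std::vector<int> ev(event_o.begin(), event_o.end());

  // time blocks (tied times share a block) depend only on the outcome and
  // are precomputed once
  std::vector<int> block_start;
  {
    int i = 0;
    while (i < n) {
      block_start.push_back(i);
      int j = i;
      while (j < n && tp[j] == tp[i]) ++j;
      i = j;
    }
    block_start.push_back(n);
  }
  int nblocks = (int)block_start.size() - 1;

  std::vector<int> s_o(n);
  for (int e = 0; e < ne; ++e) {
    int pi = parent_idx[e] - 1, gi = gene_idx[e] - 1;
    int smax = 0;
    for (int j = 0; j < n; ++j) {
      int i = ord[j] - 1;
      int s = parent_scores(i, pi) + points(i, gi);
      s_o[j] = s;
      if (s > smax) smax = s;
    }
    // all cutoffs c = 0..smax-1 in one sweep over event blocks: at each
    // block, suffix sums over score values give the high-group at-risk
    // and event counts for every cutoff simultaneously
    std::vector<int> risk(smax + 1, 0), dv(smax + 1, 0);
    std::vector<double> U(smax, 0.0), V(smax, 0.0);
    for (int j = 0; j < n; ++j) ++risk[s_o[j]];
    // admissibility from full-sample counts
    std::vector<bool> admissible(smax, false);
    bool any = false;
    {
      int nlow = 0;
      for (int c = 0; c < smax; ++c) {
        nlow += risk[c];
        if (nlow >= min_group && n - nlow >= min_group) {
          admissible[c] = true;
          any = true;
        }
      }
    }
    if (!any) {
      out(e, 0) = 0.0;
      out(e, 1) = NA_REAL;
      out(e, 2) = 0.0;
      continue;
    }
    int nrisk = n;
    for (int b = 0; b < nblocks; ++b) {
      int lo = block_start[b], hi = block_start[b + 1];
      int d = 0;
      for (int j = lo; j < hi; ++j)
        if (ev[j] == 1) { ++d; ++dv[s_o[j]]; }
      if (d > 0) {
        double tiecorr = (nrisk > 1)
          ? (double)(nrisk - d) / (nrisk - 1) : 0.0;
        int n1 = 0, d1 = 0;
        for (int c = smax - 1; c >= 0; --c) {
          n1 += risk[c + 1];
          d1 += dv[c + 1];
          double p1 = (double)n1 / nrisk;
          U[c] += d1 - d * p1;
          V[c] += d * p1 * (1.0 - p1) * tiecorr;
        }
        for (int j = lo; j < hi; ++j)
          if (ev[j] == 1) dv[s_o[j]] = 0;
      }
      for (int j = lo; j < hi; ++j) --risk[s_o[j]];
      nrisk -= hi - lo;
    }
    double best_z = -1.0, best_cut = NA_REAL, best_chi = 0.0;
    for (int c = 0; c < smax; ++c) {
      if (!admissible[c]) continue;
      double z = (V[c] > 0) ? std::fabs(U[c]) / std::sqrt(V[c]) : 0.0;
      if (z > best_z) {
        best_z = z;
        best_cut = c + 0.5;
        best_chi = z * z;
      }
    }
    out(e, 0) = best_chi;
    out(e, 1) = best_cut;
    out(e, 2) = 1.0;
  }
  return out;
}

// Plain two-group log-rank score and variance (high = group == 1).
// [[Rcpp::export]]
List cpp_logrank2(NumericVector time, IntegerVector event, IntegerVector group) {
  int n = time.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return time[a] < time[b]; });
  std::vector<double> time_o(n);
  std::vector<int> event_o(n), g_o(n);
  for (int i = 0; i < n; ++i) {
    time_o[i] = time[ord[i]];
    event_o[i] = event[ord[i]];
    g_o[i] = group[ord[i]];
  }
  double U, V;
  logrank_uv(g_o, time_o.data(), event_o.data(), n, U, V);
  return List::create(Named("U") = U, Named("V") = V,
                      Named("chisq") = (V > 0) ? U * U / V : 0.0);
}
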