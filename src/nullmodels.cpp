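#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// beta mean nearest taxon distance for all sample pairs, given an
// assignment of taxa (rows of W) to tips (rows/cols of D).
//
// D: n_tip x n_tip patristic distances
// W: n_taxa x n_samp weights (relative abundances; > 0 marks presence)
// tip_of: n_taxa, 0-based tip index assigned to each taxon
//
// bMNTD(k,m) = 0.5 * ( sum_i w_ik min_j d(i,j) / sum_i w_ik + symm. )
static void bmntd_core(const NumericMatrix& D,
                       const NumericMatrix& W,
                       const std::vector<int>& tip_of,
                       const std::vector<std::vector<int>>& pres,
                       NumericMatrix& out) {
  const int n_tip = D.nrow();
  const int n_samp = W.ncol();
  // M(t, m): distance from tip t to the nearest tip present in sample m
  NumericMatrix M(n_tip, n_samp);
  std::fill(M.begin(), M.end(), R_PosInf);
  for (int m = 0; m < n_samp; ++m) {
    double* Mcol = &M(0, m);
    for (size_t a = 0; a < pres[m].size(); ++a) {
      const int tp = tip_of[pres[m][a]];
      const double* Dcol = &D(0, tp);
      for (int t = 0; t < n_tip; ++t) {
        if (Dcol[t] < Mcol[t]) Mcol[t] = Dcol[t];
      }
    }
  }
  // weighted one-sided means, then symmetrize
  NumericMatrix S(n_samp, n_samp);   // S(k,m) = sum_i W(i,k) M(tip_of[i], m)
  for (int k = 0; k < n_samp; ++k) {
    for (int m = 0; m < n_samp; ++m) {
      if (k == m) continue;
      double acc = 0.0, wsum = 0.0;
      for (size_t a = 0; a < pres[k].size(); ++a) {
        const int i = pres[k][a];
        acc += W(i, k) * M(tip_of[i], m);
        wsum += W(i, k);
      }
      S(k, m) = acc / wsum;
    }
  }
  for (int k = 0; k < n_samp; ++k)
    for (int m = 0; m < n_samp; ++m)
      out(k, m) = (k == m) ? 0.0 : 0.5 * (S(k, m) + S(m, k));
}

// [[Rcpp::export]]
NumericMatrix cpp_bmntd(NumericMatrix D, NumericMatrix W) {
  const int n_taxa = W.nrow(), n_samp = W.ncol();
  if (D.nrow() != n_taxa)
    stop("distance matrix and weight matrix disagree on taxon count");
  std::vector<int> tip_of(n_taxa);
  for (int i = 0; i < n_taxa; ++i) tip_of[i] = i;
  std::vector<std::vector<int>> pres(n_samp);
  for (int m = 0; m < n_samp; ++m)
    for (int i = 0; i < n_taxa; ++i)
      if (W(i, m) > 0) pres[m].push_back(i);
  for (int m = 0; m < n_samp; ++m)
    if (pres[m].empty()) stop("sample with zero present taxa");
  NumericMatrix out(n_samp, n_samp);
  bmntd_core(D, W, tip_of, pres, out);
  return out;
}

// Tip-shuffling null for bNTI: taxa labels are permuted across the whole
// phylogeny; one shared permutation per repetition is reused for every
// sample pair. Returns per-pair null mean and sd (sample sd, n-1).
// [[Rcpp::export]]
List cpp_bnti_null(NumericMatrix D, NumericMatrix W, int reps) {
  const int n_taxa = W.nrow(), n_samp = W.ncol();
  if (reps < 1) stop("reps must be >= 1");
  std::vector<std::vector<int>> pres(n_samp);
  for (int m = 0; m < n_samp; ++m)
    for (int i = 0; i < n_taxa; ++i)
      if (W(i, m) > 0) pres[m].push_back(i);
  NumericMatrix sum(n_samp, n_samp), sumsq(n_samp, n_samp);
  NumericMatrix nullv(n_samp, n_samp);
  std::vector<int> tip_of(n_taxa);
  for (int r = 0; r < reps; ++r) {
    IntegerVector perm = Rcpp::sample(n_taxa, n_taxa, false);  // 1-based
    for (int i = 0; i < n_taxa; ++i) tip_of[i] = perm[i] - 1;
    bmntd_core(D, W, tip_of, pres, nullv);
    for (int k = 0; k < n_samp; ++k)
      for (int m = 0; m < n_samp; ++m) {
        sum(k, m) += nullv(k, m);
        sumsq(k, m) += nullv(k, m) * nullv(k, m);
      }
  }
  NumericMatrix mu(n_samp, n_samp), sd(n_samp, n_samp);
  for (int k = 0; k < n_samp; ++k)
    for (int m = 0; m < n_samp; ++m) {
      mu(k, m) = sum(k, m) / reps;
      double var = (reps > 1)
        ? (sumsq(k, m) - sum(k, m) * sum(k, m) / reps) / (reps - 1)
        : 0.0;
      sd(k, m) = var > 0 ? std::sqrt(var) : 0.0;
    }
  return List::create(_["mean"] = mu, _["sd"] = sd);
}

static double bray_dense(const std::vector<double>& x,
                         const std::vector<double>& y,
                         double xtot, double ytot) {
  double num = 0.0;
  for (size_t i = 0; i < x.size(); ++i)
    num += std::fabs(x[i] / xtot - y[i] / ytot);
  return num / 2.0;  // relative abundances: denominator sums to 2
}

// One null assembly of a community with S species and N individuals:
// species drawn without replacement with probability proportional to
// occupancy (Efraimidis-Spirakis keys), each drawn species seeded with one
// individual, the remaining N - S assigned by a multinomial draw
// proportional to the regional relative abundance of the drawn species.
static void null_community(int n_taxa, int S, int N,
                           const std::vector<double>& occ,
                           const std::vector<double>& pool,
                           std::vector<double>& out,
                           std::vector<double>& keys,
                           std::vector<int>& ord,
                           std::vector<double>& prob,
                           std::vector<int>& draw) {
  std::fill(out.begin(), out.end(), 0.0);
  for (int i = 0; i < n_taxa; ++i) {
    keys[i] = exp_rand() / occ[i];
    ord[i] = i;
  }
  std::nth_element(ord.begin(), ord.begin() + S, ord.end(),
                   [&](int a, int b) { return keys[a] < keys[b]; });
  double psum = 0.0;
  for (int a = 0; a < S; ++a) psum += pool[ord[a]];
  for (int a = 0; a < S; ++a) prob[a] = pool[ord[a]] / psum;
  if (N > S) {
    R::rmultinom(N - S, prob.data(), S, draw.data());
    for (int a = 0; a < S; ++a) out[ord[a]] = 1.0 + draw[a];
  } else {
    for (int a = 0; a < S; ++a) out[ord[a]] = 1.0;
  }
}

// Raup-Crick on Bray-Curtis for all sample pairs.
// counts: n_taxa x n_samp integer matrix.
// Returns matrices: rc, obs (observed Bray-Curtis on relative abundances).
// [[Rcpp::export]]
List cpp_raup_crick(IntegerMatrix counts, int reps) {
  const int n_taxa = counts.nrow(), n_samp = counts.ncol();
  if (reps < 1) stop("reps must be >= 1");
  std::vector<double> occ(n_taxa), pool(n_taxa);
  std::vector<int> richness(n_samp);
  std::vector<double> total(n_samp);
  double grand = 0.0;
  for (int i = 0; i < n_taxa; ++i) {
    double tot = 0.0; int oc = 0;
    for (int m = 0; m < n_samp; ++m) {
      tot += counts(i, m);
      if (counts(i, m) > 0) ++oc;
    }
    pool[i] = tot;
    occ[i] = oc;
    grand += tot;
  }
  for (int i = 0; i < n_taxa; ++i) {
    pool[i] /= grand;
    if (occ[i] <= 0) occ[i] = 1e-12;  // absent everywhere: effectively never drawn
  }
  for (int m = 0; m < n_samp; ++m) {
    int S = 0; double N = 0;
    for (int i = 0; i < n_taxa; ++i) {
      if (counts(i, m) > 0) ++S;
      N += counts(i, m);
    }
    richness[m] = S;
    total[m] = N;
  }
  NumericMatrix rc(n_samp, n_samp), obs(n_samp, n_samp);
  std::vector<double> xa(n_taxa), xb(n_taxa), keys(n_taxa), prob(n_taxa);
  std::vector<int> ord(n_taxa), draw(n_taxa);
  for (int k = 0; k < n_samp; ++k) {
    for (int m = k + 1; m < n_samp; ++m) {
      double num = 0.0;
      for (int i = 0; i < n_taxa; ++i)
        num += std::fabs(counts(i, k) / total[k] - counts(i, m) / total[m]);
      const double ob = num / 2.0;
      obs(k, m) = obs(m, k) = ob;
      int less = 0, equal = 0;
      for (int r = 0; r < reps; ++r) {
        null_community(n_taxa, richness[k], (int) total[k], occ, pool,
                       xa, keys, ord, prob, draw);
        null_community(n_taxa, richness[m], (int) total[m], occ, pool,
                       xb, keys, ord, prob, draw);
        const double bc = bray_dense(xa, xb, total[k], total[m]);
        if (bc < ob - 1e-10) ++less;
        else if (bc <= ob + 1e-10) ++equal;
      }
      const double val = 2.0 * ((less + 0.5 * equal) / (double) reps) - 1.0;
      rc(k, m) = rc(m, k) = val;
    }
  }
  return List::create(_["rc"] = rc, _["obs"] = obs);
}
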