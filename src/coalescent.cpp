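// Structured-coalescent engine for a two-deme isolation-with-migration (IM)
// model with an optional outgroup lineage joining at a deeper split.
//
// Conventions:
//  * time runs backwards in generations, continuous;
//  * deme sizes are diploid effective sizes, so a pair of lineages in a deme
//    of size N coalesces at rate 1/(2N) per generation;
//  * m12/m21 are backward per-lineage migration probabilities per generation
//    (a lineage sampled in deme 1 traces its parent to deme 2 at rate m12);
//  * mutations follow the infinite-sites model, dropped on branches as a
//    Poisson process with rate mu per site per generation, no intralocus
//    recombination;
//  * sample membership is carried as a 64-bit leaf mask, so at most 64
//    sampled chromosomes per locus (enforced by the R callers).
//
// All randomness comes from R's RNG (RNGScope), so set.seed() in R makes
// every simulation reproducible.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Branch {
  uint64_t mask;
  double len;
};

struct Genealogy {
  std::vector<Branch> branches;
  double tmrca;
  double total_len;
};

// Demes: 0 = ancestral, 1, 2 = ingroup demes, 3 = outgroup branch.
// Phase 1: t in [0, t_split)  -- demes 1 and 2 exchange migrants.
// Phase 2: t in [t_split, t_out) -- ingroup lineages merged into deme 0
//          (size Nanc); outgroup lineage(s) still isolated in deme 3.
// Phase 3: t >= t_out -- everything in deme 0.
Genealogy simulate_genealogy(int n1, int n2, int nout,
                             double N1, double N2, double Nanc,
                             double t_split, double t_out,
                             double m12, double m21) {
  const int n = n1 + n2 + nout;
  std::vector<uint64_t> mask(n);
  std::vector<int> deme(n);
  std::vector<double> birth(n, 0.0);
  for (int i = 0; i < n; ++i) {
    mask[i] = (uint64_t)1 << i;
    deme[i] = (i < n1) ? 1 : (i < n1 + n2 ? 2 : 3);
  }
  if (t_split <= 0.0) {
    for (int i = 0; i < n1 + n2; ++i) deme[i] = 0;
  }
  if (nout > 0 && t_out <= 0.0) {
    for (int i = 0; i < n; ++i) deme[i] = 0;
  }

  Genealogy g;
  g.total_len = 0.0;
  double t = 0.0;
  int k = n;  // active lineages

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  while (k > 1) {
    // lineage counts per deme
    int kd[4] = {0, 0, 0, 0};
    for (int j = 0; j < k; ++j) kd[deme[idx[j]]]++;

    const double sizes[4] = {Nanc, N1, N2, Nanc};
    double coal[4], rate = 0.0;
    for (int d = 0; d < 4; ++d) {
      coal[d] = kd[d] > 1 ? kd[d] * (kd[d] - 1) / 2.0 / (2.0 * sizes[d]) : 0.0;
      rate += coal[d];
    }
    double mig1 = (t < t_split) ? kd[1] * m12 : 0.0;
    double mig2 = (t < t_split) ? kd[2] * m21 : 0.0;
    rate += mig1 + mig2;

    // next demographic phase boundary
    double boundary = R_PosInf;
    if (t < t_split) boundary = t_split;
    else if (nout > 0 && t < t_out) boundary = t_out;

    double dt = (rate > 0.0) ? R::exp_rand() / rate : R_PosInf;
    if (t + dt >= boundary) {
      t = boundary;
      if (boundary == t_split) {
        for (int j = 0; j < k; ++j) {
          int i = idx[j];
          if (deme[i] == 1 || deme[i] == 2) deme[i] = 0;
        }
      } else {  // t_out
        for (int j = 0; j < k; ++j) deme[idx[j]] = 0;
      }
      continue;
    }
    t += dt;

    double u = unif_rand() * rate;
    int event_deme = -1;
    bool migration = false, mig_from_1 = false;
    for (int d = 0; d < 4; ++d) {
      if (u < coal[d]) { event_deme = d; break; }
      u -= coal[d];
    }
    if (event_deme < 0) {
      migration = true;
      mig_from_1 = (u < mig1);
    }

    if (migration) {
      int from = mig_from_1 ? 1 : 2;
      int to = mig_from_1 ? 2 : 1;
      int kdeme = kd[from];
      int pick = (int)(unif_rand() * kdeme);
      if (pick >= kdeme) pick = kdeme - 1;
      for (int j = 0, c = 0; j < k; ++j) {
        if (deme[idx[j]] == from && c++ == pick) { deme[idx[j]] = to; break; }
      }
    } else {
      // choose an unordered pair uniformly within event_deme
      int kdeme = kd[event_deme];
      int a = (int)(unif_rand() * kdeme);
      if (a >= kdeme) a = kdeme - 1;
      int b = (int)(unif_rand() * (kdeme - 1));
      if (b >= kdeme - 1) b = kdeme - 2;
      if (b >= a) b++;
      int ia = -1, ib = -1;
      for (int j = 0, c = 0; j < k; ++j) {
        if (deme[idx[j]] == event_deme) {
          if (c == a) ia = j;
          if (c == b) ib = j;
          ++c;
        }
      }
      int la = idx[ia], lb = idx[ib];
      g.branches.push_back({mask[la], t - birth[la]});
      g.branches.push_back({mask[lb], t - birth[lb]});
      g.total_len += (t - birth[la]) + (t - birth[lb]);
      // parent replaces la; lb removed from the active list
      mask[la] |= mask[lb];
      birth[la] = t;
      // deme of parent = event_deme
      std::swap(idx[ib], idx[k - 1]);
      --k;
    }
  }
  g.tmrca = birth[idx[0]];
  return g;
}

inline int popcount_mask(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { c += (int)(x & 1); x >>= 1; }
  return c;
#endif
}

// pick a branch index proportional to length via the cumulative lengths
int sample_branch(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (u < cum[mid]) hi = mid; else lo = mid + 1;
  }
  return lo;
}

}  // namespace

// Simulate a dataset of independent loci and pool the site classification
// counts. Returns c(fixed, shared, exclusive_p1, exclusive_p2, monomorphic)
// and optionally the per-mutation derived counts (for cross-checks against
// the R-level classifier).
// [[Rcpp::export(name = ".cpp_im_dataset")]]
List cpp_im_dataset(int n_loci, int n1, int n2,
                    double N1, double N2, double Nanc,
                    double t_split, double m12, double m21,
                    double mu, double locus_length,
                    bool return_counts = false) {
  if (n1 + n2 > 64) stop("at most 64 sampled chromosomes per locus");
  uint64_t mask1 = (n1 == 64) ? ~(uint64_t)0 : (((uint64_t)1 << n1) - 1);
  long fixed = 0, shared = 0, excl1 = 0, excl2 = 0, mono = 0;
  std::vector<int> d1v, d2v;
  std::vector<double> cum;
  for (int l = 0; l < n_loci; ++l) {
    Genealogy g = simulate_genealogy(n1, n2, 0, N1, N2, Nanc,
                                     t_split, R_PosInf, m12, m21);
    double lambda = mu * locus_length * g.total_len;
    int nmut = (int)R::rpois(lambda);
    if (nmut == 0) continue;
    cum.resize(g.branches.size());
    double s = 0.0;
    for (size_t b = 0; b < g.branches.size(); ++b) {
      s += g.branches[b].len;
      cum[b] = s;
    }
    for (int m = 0; m < nmut; ++m) {
      const Branch& br = g.branches[sample_branch(cum)];
      int d1 = popcount_mask(br.mask & mask1);
      int d2 = popcount_mask(br.mask) - d1;
      bool poly1 = d1 > 0 && d1 < n1;
      bool poly2 = d2 > 0 && d2 < n2;
      if (poly1 && poly2) ++shared;
      else if (poly1) ++excl1;
      else if (poly2) ++excl2;
      else if ((d1 == n1 && d2 == 0) || (d1 == 0 && d2 == n2)) ++fixed;
      else ++mono;
      if (return_counts) { d1v.push_back(d1); d2v.push_back(d2); }
    }
  }
  List out = List::create(
      _["fixed"] = (double)fixed, _["shared"] = (double)shared,
      _["exclusive_p1"] = (double)excl1, _["exclusive_p2"] = (double)excl2,
      _["monomorphic"] = (double)mono);
  if (return_counts) {
    out["derived_p1"] = wrap(d1v);
    out["derived_p2"] = wrap(d2v);
  }
  return out;
}

// Null distribution of the fixed:shared ratio: n_replicates datasets of
// n_loci loci each. Replicates with shared == 0 get ratio = Inf.
// [[Rcpp::export(name = ".cpp_im_ratio_replicates")]]
NumericVector cpp_im_ratio_replicates(int n_replicates, int n_loci,
                                      int n1, int n2,
                                      double N1, double N2, double Nanc,
                                      double t_split, double m12, double m21,
                                      double mu, double locus_length) {
  NumericVector out(n_replicates);
  for (int r = 0; r < n_replicates; ++r) {
    List counts = cpp_im_dataset(n_loci, n1, n2, N1, N2, Nanc,
                                 t_split, m12, m21, mu, locus_length, false);
    double fixed = counts["fixed"], shared = counts["shared"];
    if (shared == 0.0) out[r] = (fixed == 0.0) ? NA_REAL : R_PosInf;
    else out[r] = fixed / shared;
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// One locus with full haplotypes (for the synthetic-genome generator):
// n1 + n2 ingroup chromosomes plus nout outgroup chromosomes splitting at
// t_out. Returns the 0/1 derived-allele matrix (mutations x chromosomes),
// uniform positions in (0,1), and the TMRCA in generations.
// [[Rcpp::export(name = ".cpp_sim_locus")]]
List cpp_sim_locus(int n1, int n2, int nout,
                   double N1, double N2, double Nanc,
                   double t_split, double t_out,
                   double m12, double m21,
                   double mu, double locus_length) {
  int n = n1 + n2 + nout;
  if (n > 64) stop("at most 64 sampled chromosomes per locus");
  Genealogy g = simulate_genealogy(n1, n2, nout, N1, N2, Nanc,
                                   t_split, t_out, m12, m21);
  double lambda = mu * locus_length * g.total_len;
  int nmut = (int)R::rpois(lambda);
  std::vector<double> cum(g.branches.size());
  double s = 0.0;
  for (size_t b = 0; b < g.branches.size(); ++b) {
    s += g.branches[b].len;
    cum[b] = s;
  }
  IntegerMatrix geno(nmut, n);
  NumericVector pos(nmut);
  for (int m = 0; m < nmut; ++m) {
    const Branch& br = g.branches[sample_branch(cum)];
    for (int i = 0; i < n; ++i)
      geno(m, i) = (br.mask >> i) & 1 ? 1 : 0;
    pos[m] = unif_rand();
  }
  return List::create(_["genotypes"] = geno, _["positions"] = pos,
                      _["tmrca"] = g.tmrca);
}

// TMRCA of a single panmictic deme of diploid size N, n chromosomes.
// [[Rcpp::export(name = ".cpp_sim_tmrca")]]
NumericVector cpp_sim_tmrca(int n_replicates, int n, double N) {
  if (n > 64) stop("at most 64 sampled chromosomes");
  NumericVector out(n_replicates);
  for (int r = 0; r < n_replicates; ++r) {
    Genealogy g = simulate_genealogy(n, 0, 0, N, N, N, 0.0, R_PosInf, 0.0, 0.0);
    out[r] = g.tmrca;
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Segregating-site count and mean pairwise diversity of single-deme loci;
// used by engine-calibration tests (E[S] = theta * a_{n-1}, E[pi] = theta).
// [[Rcpp::export(name = ".cpp_sim_single_deme_stats")]]
NumericMatrix cpp_sim_single_deme_stats(int n_loci, int n, double N,
                                        double mu, double locus_length) {
  if (n > 64) stop("at most 64 sampled chromosomes");
  NumericMatrix out(n_loci, 2);
  std::vector<double> cum;
  for (int l = 0; l < n_loci; ++l) {
    Genealogy g = simulate_genealogy(n, 0, 0, N, N, N, 0.0, R_PosInf, 0.0, 0.0);
    int nmut = (int)R::rpois(mu * locus_length * g.total_len);
    cum.resize(g.branches.size());
    double s = 0.0;
    for (size_t b = 0; b < g.branches.size(); ++b) {
      s += g.branches[b].len;
      cum[b] = s;
    }
    double pi_sum = 0.0;
    for (int m = 0; m < nmut; ++m) {
      int d = popcount_mask(g.branches[sample_branch(cum)].mask);
      pi_sum += 2.0 * d * (n - d) / ((double)n * (n - 1));
    }
    out(l, 0) = nmut;
    out(l, 1) = pi_sum / locus_length;
  }
  return out;
}
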