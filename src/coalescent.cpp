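// Structured-coalescent simulation of independently segregating loci.
// Two populations with piecewise-constant relative sizes and symmetric
// migration; time in units of 2 * N_ref generations (pair coalescence
// rate 1/nu, per-lineage migration rate M). Mutations fall on branches
// as a Poisson process with rate theta_locus / 2 per unit time.
//
// Uses R's RNG, so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <set>
using namespace Rcpp;

// [[Rcpp::export(name = ".sim_cohort_cpp")]]
List sim_cohort_cpp(NumericMatrix epochs, IntegerVector hap_pop,
                    int n_loci, double theta_locus, int locus_len) {
  const int n = hap_pop.size();
  if (n > 64) stop("at most 64 haploid samples are supported");
  const int n_nodes = 2 * n - 1;
  const int n_epoch = epochs.nrow();

  std::vector<uint64_t> patterns;   // derived-carrier bitmask per site
  std::vector<int> locus_of, pos_of;

  std::vector<double> node_time(n_nodes);
  std::vector<int> node_parent(n_nodes), node_pop(n_nodes);
  std::vector<uint64_t> desc(n_nodes);
  std::vector<int> active(n);

  for (int locus = 0; locus < n_loci; ++locus) {
    // --- genealogy ---
    int n_active = n;
    for (int i = 0; i < n; ++i) {
      active[i] = i;
      node_time[i] = 0.0;
      node_parent[i] = -1;
      node_pop[i] = epochs(0, 5) > 0.5 ? 1 : hap_pop[i];
    }
    for (int i = n; i < n_nodes; ++i) node_parent[i] = -1;
    int next_node = n;
    double t = 0.0;
    int e = 0;

    while (n_active > 1) {
      const bool merged = epochs(e, 5) > 0.5;
      const double nu1 = epochs(e, 2), nu2 = epochs(e, 3);
      const double M = epochs(e, 4);
      int k1 = 0;
      for (int i = 0; i < n_active; ++i)
        if (node_pop[active[i]] == 1) ++k1;
      const int k2 = n_active - k1;
      const double rc1 = k1 * (k1 - 1) / 2.0 / nu1;
      const double rc2 = merged ? 0.0 : k2 * (k2 - 1) / 2.0 / nu2;
      const double rm = merged ? 0.0 : M * n_active;
      const double rtot = rc1 + rc2 + rm;

      double dt = rtot > 0 ? R::rexp(1.0 / rtot) : R_PosInf;
      if (e < n_epoch - 1 && t + dt >= epochs(e, 1)) {
        t = epochs(e, 1);
        ++e;
        if (epochs(e, 5) > 0.5)
          for (int i = 0; i < n_active; ++i) node_pop[active[i]] = 1;
        continue;
      }
      t += dt;
      const double u = R::runif(0.0, rtot);
      if (u < rc1 + rc2) {
        const int which_pop = (u < rc1) ? 1 : 2;
        // choose two distinct lineages uniformly within the population
        std::vector<int> idx;
        idx.reserve(n_active);
        for (int i = 0; i < n_active; ++i)
          if (node_pop[active[i]] == which_pop) idx.push_back(i);
        const int m = (int) idx.size();
        int a = (int) (R::unif_rand() * m);
        if (a >= m) a = m - 1;
        int b = (int) (R::unif_rand() * (m - 1));
        if (b >= m - 1) b = m - 2;
        if (b >= a) ++b;
        const int ia = idx[a], ib = idx[b];
        const int node = next_node++;
        node_time[node] = t;
        node_pop[node] = which_pop;
        node_parent[active[ia]] = node;
        node_parent[active[ib]] = node;
        // remove the two children, append the parent
        const int hi = ia > ib ? ia : ib, lo = ia > ib ? ib : ia;
        active[hi] = active[n_active - 1];
        active[lo] = active[n_active - 2];
        active[n_active - 2] = node;
        n_active -= 1;
      } else {
        int a = (int) (R::unif_rand() * n_active);
        if (a >= n_active) a = n_active - 1;
        node_pop[active[a]] = 3 - node_pop[active[a]];
      }
    }

    // --- descendant bitmasks (children precede parents by index) ---
    for (int i = 0; i < n; ++i) desc[i] = 1ULL << i;
    for (int i = n; i < n_nodes; ++i) desc[i] = 0;
    for (int v = 0; v < n_nodes; ++v)
      if (node_parent[v] >= 0) desc[node_parent[v]] |= desc[v];

    // --- mutations ---
    std::set<int> used;
    for (int v = 0; v < n_nodes; ++v) {
      if (node_parent[v] < 0) continue;
      const double blen = node_time[node_parent[v]] - node_time[v];
      const int nmut = (int) R::rpois(blen * theta_locus / 2.0);
      for (int m = 0; m < nmut; ++m) {
        if ((int) used.size() >= locus_len) break;
        int pos;
        do {
          pos = (int) (R::unif_rand() * locus_len) + 1;
          if (pos > locus_len) pos = locus_len;
        } while (used.count(pos));
        used.insert(pos);
        patterns.push_back(desc[v]);
        locus_of.push_back(locus + 1);
        pos_of.push_back(pos);
      }
    }
  }

  const int S = (int) patterns.size();
  IntegerMatrix hap(S, n);
  IntegerVector loc(S), pos(S);
  for (int s = 0; s < S; ++s) {
    for (int i = 0; i < n; ++i)
      hap(s, i) = (patterns[s] >> i) & 1ULL;
    loc[s] = locus_of[s];
    pos[s] = pos_of[s];
  }
  return List::create(_["hap"] = hap, _["locus"] = loc, _["pos"] = pos);
}
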