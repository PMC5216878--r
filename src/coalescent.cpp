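// Structured coalescent engine over piecewise-constant epochs.
//
// Conventions (documented in the package vignette):
//  * haploid lineages; a pair in a deme of size N coalesces at rate 1/N per
//    generation, so theta (per site) = 2 * N * mu;
//  * time in generations, increasing into the past; epoch t_start[0] == 0;
//  * migration rates are backward-in-time per-lineage rates (row = current
//    deme of the lineage, column = deme it jumps to);
//  * "moves" attached to an epoch are mass relabelings (population merges)
//    applied when the epoch is entered.
// All randomness comes from R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct Genealogy {
  std::vector<int> child, parent;     // 0-based node ids, edge child -> parent
  std::vector<double> length;         // edge lengths in generations
  std::vector<double> node_time;      // node ages, samples at 0
  int n_samples;
};

struct Epoch {
  double t_start;
  std::vector<double> sizes;                 // per-deme haploid N (>0)
  std::vector< std::vector<double> > mig;    // per-lineage backward rates
  std::vector<double> mig_row;               // row sums
  std::vector< std::pair<int,int> > moves;   // (from, to) applied at entry
};

static std::vector<Epoch> parse_epochs(const List& epochs, int n_demes) {
  int nE = epochs.size();
  std::vector<Epoch> out(nE);
  for (int e = 0; e < nE; ++e) {
    List ep = epochs[e];
    Epoch& E = out[e];
    E.t_start = as<double>(ep["t_start"]);
    NumericVector sz = ep["sizes"];
    if ((int)sz.size() != n_demes) stop("epoch sizes length != n_demes");
    E.sizes.assign(sz.begin(), sz.end());
    for (int d = 0; d < n_demes; ++d)
      if (!(E.sizes[d] > 0)) stop("deme sizes must be positive");
    E.mig.assign(n_demes, std::vector<double>(n_demes, 0.0));
    E.mig_row.assign(n_demes, 0.0);
    if (ep.containsElementNamed("mig") && !Rf_isNull(ep["mig"])) {
      NumericMatrix M = ep["mig"];
      if (M.nrow() != n_demes || M.ncol() != n_demes) stop("mig matrix dims != n_demes");
      for (int i = 0; i < n_demes; ++i)
        for (int j = 0; j < n_demes; ++j)
          if (i != j) {
            if (M(i, j) < 0) stop("negative migration rate");
            E.mig[i][j] = M(i, j);
            E.mig_row[i] += M(i, j);
          }
    }
    if (ep.containsElementNamed("moves") && !Rf_isNull(ep["moves"])) {
      IntegerMatrix mv = ep["moves"];
      for (int r = 0; r < mv.nrow(); ++r)
        E.moves.push_back(std::make_pair(mv(r, 0), mv(r, 1)));
    }
  }
  if (out[0].t_start != 0) stop("first epoch must start at time 0");
  for (int e = 1; e < nE; ++e)
    if (out[e].t_start <= out[e - 1].t_start) stop("epoch start times must increase");
  return out;
}

static Genealogy simulate_genealogy(const std::vector<int>& sample_demes,
                                    const std::vector<Epoch>& eps, int n_demes) {
  int n = sample_demes.size();
  if (n < 2) stop("need at least 2 samples");
  Genealogy G;
  G.n_samples = n;
  G.node_time.assign(n, 0.0);
  std::vector<int> lin_node(n), lin_deme(sample_demes);
  for (int i = 0; i < n; ++i) {
    lin_node[i] = i;
    if (sample_demes[i] < 0 || sample_demes[i] >= n_demes) stop("sample deme out of range");
  }
  int nE = eps.size();
  int e = 0;
  double t = 0.0;
  // entry moves of epoch 0
  for (size_t r = 0; r < eps[0].moves.size(); ++r)
    for (size_t i = 0; i < lin_deme.size(); ++i)
      if (lin_deme[i] == eps[0].moves[r].first) lin_deme[i] = eps[0].moves[r].second;

  std::vector<int> cnt(n_demes);
  long guard = 0;
  while (lin_node.size() > 1) {
    if (++guard > 100000000L) stop("coalescent event limit exceeded");
    const Epoch& E = eps[e];
    double next_t = (e + 1 < nE) ? eps[e + 1].t_start : R_PosInf;
    std::fill(cnt.begin(), cnt.end(), 0);
    for (size_t i = 0; i < lin_deme.size(); ++i) cnt[lin_deme[i]]++;
    double total = 0.0;
    for (int d = 0; d < n_demes; ++d) {
      total += 0.5 * cnt[d] * (cnt[d] - 1) / E.sizes[d];
      total += cnt[d] * E.mig_row[d];
    }
    if (total <= 0.0) {
      if (R_FINITE(next_t)) {
        t = next_t; ++e;
        for (size_t r = 0; r < eps[e].moves.size(); ++r)
          for (size_t i = 0; i < lin_deme.size(); ++i)
            if (lin_deme[i] == eps[e].moves[r].first) lin_deme[i] = eps[e].moves[r].second;
        continue;
      }
      stop("lineages in isolated demes can never coalesce: check the demography");
    }
    double dt = exp_rand() / total;
    if (t + dt >= next_t) {
      t = next_t; ++e;
      for (size_t r = 0; r < eps[e].moves.size(); ++r)
        for (size_t i = 0; i < lin_deme.size(); ++i)
          if (lin_deme[i] == eps[e].moves[r].first) lin_deme[i] = eps[e].moves[r].second;
      continue;
    }
    t += dt;
    double u = unif_rand() * total;
    int d = 0; bool is_coal = false;
    for (d = 0; d < n_demes; ++d) {
      double rc = 0.5 * cnt[d] * (cnt[d] - 1) / eps[e].sizes[d];
      if (u < rc) { is_coal = true; break; }
      u -= rc;
      double rm = cnt[d] * eps[e].mig_row[d];
      if (u < rm) { is_coal = false; break; }
      u -= rm;
    }
    if (d >= n_demes) d = n_demes - 1;  // numeric edge: attribute to last deme coal
    if (is_coal) {
      // choose two distinct lineages in deme d
      int k = cnt[d];
      int a = (int)std::floor(unif_rand() * k); if (a >= k) a = k - 1;
      int b = (int)std::floor(unif_rand() * (k - 1)); if (b >= k - 1) b = k - 2;
      if (b >= a) ++b;
      int ia = -1, ib = -1, seen = 0;
      for (size_t i = 0; i < lin_deme.size(); ++i) {
        if (lin_deme[i] == d) {
          if (seen == a) ia = i;
          if (seen == b) ib = i;
          ++seen;
        }
      }
      int new_node = (int)G.node_time.size();
      G.node_time.push_back(t);
      G.child.push_back(lin_node[ia]); G.parent.push_back(new_node);
      G.length.push_back(t - G.node_time[lin_node[ia]]);
      G.child.push_back(lin_node[ib]); G.parent.push_back(new_node);
      G.length.push_back(t - G.node_time[lin_node[ib]]);
      lin_node[ia] = new_node;
      lin_node[ib] = lin_node.back(); lin_deme[ib] = lin_deme.back();
      lin_node.pop_back(); lin_deme.pop_back();
    } else {
      // migration out of deme d: pick lineage, then destination
      int k = cnt[d];
      int a = (int)std::floor(unif_rand() * k); if (a >= k) a = k - 1;
      int ia = -1, seen = 0;
      for (size_t i = 0; i < lin_deme.size(); ++i)
        if (lin_deme[i] == d) { if (seen == a) { ia = i; break; } ++seen; }
      double v = unif_rand() * eps[e].mig_row[d];
      int dest = -1;
      for (int j = 0; j < n_demes; ++j) {
        if (j == d) continue;
        if (v < eps[e].mig[d][j]) { dest = j; break; }
        v -= eps[e].mig[d][j];
      }
      if (dest < 0) dest = (d == n_demes - 1) ? 0 : n_demes - 1;
      lin_deme[ia] = dest;
    }
  }
  return G;
}

// collect sample leaves under `node` given children adjacency
static void collect_leaves(int node, int n_samples,
                           const std::vector< std::vector<int> >& kids,
                           std::vector<int>& out) {
  std::vector<int> stack(1, node);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    if (v < n_samples) out.push_back(v);
    else for (size_t c = 0; c < kids[v].size(); ++c) stack.push_back(kids[v][c]);
  }
}

// [[Rcpp::export(.sim_tree_cpp)]]
List sim_tree_cpp(IntegerVector sample_demes, List epochs, int n_demes) {
  std::vector<int> sd(sample_demes.begin(), sample_demes.end());
  std::vector<Epoch> eps = parse_epochs(epochs, n_demes);
  Genealogy G = simulate_genealogy(sd, eps, n_demes);
  return List::create(_["child"] = wrap(G.child), _["parent"] = wrap(G.parent),
                      _["length"] = wrap(G.length), _["node_time"] = wrap(G.node_time),
                      _["n_samples"] = G.n_samples);
}

// [[Rcpp::export(.edge_leaves_cpp)]]
List edge_leaves_cpp(IntegerVector child, IntegerVector parent, int n_nodes,
                     int n_samples) {
  int ne = child.size();
  std::vector< std::vector<int> > kids(n_nodes);
  for (int i = 0; i < ne; ++i) kids[parent[i]].push_back(child[i]);
  List out(ne);
  for (int i = 0; i < ne; ++i) {
    std::vector<int> lv;
    collect_leaves(child[i], n_samples, kids, lv);
    IntegerVector v(lv.size());
    for (size_t j = 0; j < lv.size(); ++j) v[j] = lv[j] + 1;  // 1-based for R
    out[i] = v;
  }
  return out;
}

// Poisson infinite-sites mutations on a fresh genealogy; one column per
// mutation (0/1 carrier matrix, rows = samples in input order).
// [[Rcpp::export(.sim_binary_sites_cpp)]]
IntegerMatrix sim_binary_sites_cpp(IntegerVector sample_demes, List epochs,
                                   int n_demes, double mu_total) {
  std::vector<int> sd(sample_demes.begin(), sample_demes.end());
  std::vector<Epoch> eps = parse_epochs(epochs, n_demes);
  Genealogy G = simulate_genealogy(sd, eps, n_demes);
  int n = G.n_samples, ne = G.child.size();
  int n_nodes = (int)G.node_time.size();
  std::vector<int> nmut(ne);
  int S = 0;
  for (int i = 0; i < ne; ++i) {
    nmut[i] = (int)R::rpois(mu_total * G.length[i]);
    S += nmut[i];
  }
  IntegerMatrix M(n, S);
  if (S == 0) return M;
  std::vector< std::vector<int> > kids(n_nodes);
  for (int i = 0; i < ne; ++i) kids[G.parent[i]].push_back(G.child[i]);
  int col = 0;
  for (int i = 0; i < ne; ++i) {
    if (nmut[i] == 0) continue;
    std::vector<int> lv;
    collect_leaves(G.child[i], n, kids, lv);
    for (int k = 0; k < nmut[i]; ++k) {
      for (size_t j = 0; j < lv.size(); ++j) M(lv[j], col) = 1;
      ++col;
    }
  }
  return M;
}

// Symmetric island model: n_demes demes of haploid size N, per-lineage total
// backward migration rate m (destination uniform over the other demes).
// Samples sit in demes 0 and 1. Per replicate a single mutation is placed
// uniformly on the genealogy (biallelic approximation of the infinite-alleles
// run); derived-allele counts in the two sampled demes are returned.
// [[Rcpp::export(.sim_island_snps_cpp)]]
IntegerMatrix sim_island_snps_cpp(int n_sims, int n1, int n2, int n_demes,
                                  double m, double N) {
  if (n_demes < 2) stop("need >= 2 demes");
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per sampled deme");
  int n = n1 + n2;
  IntegerMatrix out(n_sims, 2);
  std::vector<int> lin_node(n), lin_deme(n);
  std::vector<int> cnt(n_demes);
  for (int s = 0; s < n_sims; ++s) {
    std::vector<double> node_time(n, 0.0);
    std::vector<int> child, parent;
    std::vector<double> elen;
    for (int i = 0; i < n; ++i) { lin_node[i] = i; lin_deme[i] = (i < n1) ? 0 : 1; }
    int nl = n;
    double t = 0.0;
    lin_node.resize(n); lin_deme.resize(n);
    while (nl > 1) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int i = 0; i < nl; ++i) cnt[lin_deme[i]]++;
      double coal = 0.0;
      for (int d = 0; d < n_demes; ++d) coal += 0.5 * cnt[d] * (cnt[d] - 1) / N;
      double total = coal + nl * m;
      double dt = exp_rand() / total;
      t += dt;
      double u = unif_rand() * total;
      if (u < coal) {
        int d = 0;
        for (d = 0; d < n_demes; ++d) {
          double rc = 0.5 * cnt[d] * (cnt[d] - 1) / N;
          if (u < rc) break;
          u -= rc;
        }
        if (d >= n_demes) d = n_demes - 1;
        int k = cnt[d];
        int a = (int)std::floor(unif_rand() * k); if (a >= k) a = k - 1;
        int b = (int)std::floor(unif_rand() * (k - 1)); if (b >= k - 1) b = k - 2;
        if (b >= a) ++b;
        int ia = -1, ib = -1, seen = 0;
        for (int i = 0; i < nl; ++i)
          if (lin_deme[i] == d) {
            if (seen == a) ia = i;
            if (seen == b) ib = i;
            ++seen;
          }
        int new_node = (int)node_time.size();
        node_time.push_back(t);
        child.push_back(lin_node[ia]); parent.push_back(new_node);
        elen.push_back(t - node_time[lin_node[ia]]);
        child.push_back(lin_node[ib]); parent.push_back(new_node);
        elen.push_back(t - node_time[lin_node[ib]]);
        lin_node[ia] = new_node;
        lin_node[ib] = lin_node[nl - 1]; lin_deme[ib] = lin_deme[nl - 1];
        --nl;
      } else {
        int a = (int)std::floor(unif_rand() * nl); if (a >= nl) a = nl - 1;
        int dest = (int)std::floor(unif_rand() * (n_demes - 1));
        if (dest >= n_demes - 1) dest = n_demes - 2;
        if (dest >= lin_deme[a]) ++dest;
        lin_deme[a] = dest;
      }
    }
    // single mutation uniform on total branch length
    double L = 0.0;
    for (size_t i = 0; i < elen.size(); ++i) L += elen[i];
    double u = unif_rand() * L;
    int pick = 0;
    for (size_t i = 0; i < elen.size(); ++i) {
      if (u < elen[i]) { pick = i; break; }
      u -= elen[i];
    }
    std::vector< std::vector<int> > kids(node_time.size());
    for (size_t i = 0; i < child.size(); ++i) kids[parent[i]].push_back(child[i]);
    std::vector<int> lv;
    collect_leaves(child[pick], n, kids, lv);
    int c1 = 0, c2 = 0;
    for (size_t j = 0; j < lv.size(); ++j) {
      if (lv[j] < n1) ++c1; else ++c2;
    }
    out(s, 0) = c1; out(s, 1) = c2;
  }
  return out;
}
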