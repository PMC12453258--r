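// Event-driven structured (stepping-stone) coalescent on a deme graph with
// instantaneous mass-migration pulses, independent trees per SNP, and one
// mutation per tree placed uniformly on the branches. Uses R's RNG so draws
// are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct DemeState {
  std::vector<int> members;      // active node ids in this deme
};

}  // namespace

// [[Rcpp::export(name = ".sim_coalescent_snps")]]
IntegerMatrix sim_coalescent_snps(int n_demes,
                                  IntegerMatrix edges,        // m x 2, 1-based
                                  NumericVector edge_nm,      // scaled Nm per edge
                                  NumericVector deme_sizes,   // diploid N per deme
                                  IntegerVector sample_demes, // per diploid ind, 1-based
                                  int n_snps,
                                  NumericMatrix pulses) {     // cols: time, source, dest, c
  const int n_ind = sample_demes.size();
  const int n_leaves = 2 * n_ind;
  const int n_nodes = 2 * n_leaves;  // generous upper bound

  // adjacency with per-neighbour backward migration rate  Nm / N_i
  std::vector<std::vector<int> > nbr(n_demes);
  std::vector<std::vector<double> > nbr_rate(n_demes);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    nbr[a].push_back(b);
    nbr_rate[a].push_back(edge_nm[e] / deme_sizes[a]);
    nbr[b].push_back(a);
    nbr_rate[b].push_back(edge_nm[e] / deme_sizes[b]);
  }
  std::vector<double> mtot(n_demes, 0.0);
  for (int i = 0; i < n_demes; ++i)
    for (size_t j = 0; j < nbr_rate[i].size(); ++j) mtot[i] += nbr_rate[i][j];

  const int n_pulses = pulses.nrow();

  IntegerMatrix geno(n_ind, n_snps);

  std::vector<double> node_time(n_nodes);
  std::vector<int> child1(n_nodes), child2(n_nodes), parent(n_nodes);
  std::vector<int> node_deme(n_nodes), pos_in_deme(n_nodes);
  std::vector<DemeState> deme(n_demes);
  std::vector<double> crate(n_demes), mrate(n_demes);
  // occupied demes only: the deep phase has very few, so event selection
  // scans a short list instead of the whole grid
  std::vector<int> occ;
  std::vector<int> occ_pos(n_demes, -1);

  for (int snp = 0; snp < n_snps; ++snp) {
    // reset
    for (int i = 0; i < n_demes; ++i) deme[i].members.clear();
    for (int v = 0; v < n_leaves; ++v) {
      node_time[v] = 0.0;
      child1[v] = child2[v] = -1;
      parent[v] = -1;
      int d = sample_demes[v / 2] - 1;
      node_deme[v] = d;
      pos_in_deme[v] = deme[d].members.size();
      deme[d].members.push_back(v);
    }
    int next_node = n_leaves;
    int n_active = n_leaves;
    double totC = 0.0, totM = 0.0;
    occ.clear();
    std::fill(occ_pos.begin(), occ_pos.end(), -1);
    for (int i = 0; i < n_demes; ++i) {
      double k = deme[i].members.size();
      crate[i] = k * (k - 1.0) / (4.0 * deme_sizes[i]);
      mrate[i] = k * mtot[i];
      totC += crate[i];
      totM += mrate[i];
      if (k > 0) {
        occ_pos[i] = occ.size();
        occ.push_back(i);
      }
    }

    double t = 0.0;
    int pulse_idx = 0;
    int root = -1;

    auto remove_lineage = [&](int v) {
      int d = node_deme[v];
      std::vector<int>& mem = deme[d].members;
      int p = pos_in_deme[v];
      int last = mem.back();
      mem[p] = last;
      pos_in_deme[last] = p;
      mem.pop_back();
      double k = mem.size();
      totC -= crate[d];
      crate[d] = k * (k - 1.0) / (4.0 * deme_sizes[d]);
      totC += crate[d];
      totM -= mrate[d];
      mrate[d] = k * mtot[d];
      totM += mrate[d];
      if (mem.empty()) {
        int p2 = occ_pos[d];
        int lastd = occ.back();
        occ[p2] = lastd;
        occ_pos[lastd] = p2;
        occ.pop_back();
        occ_pos[d] = -1;
      }
    };
    auto add_lineage = [&](int v, int d) {
      node_deme[v] = d;
      pos_in_deme[v] = deme[d].members.size();
      deme[d].members.push_back(v);
      double k = deme[d].members.size();
      totC -= crate[d];
      crate[d] = k * (k - 1.0) / (4.0 * deme_sizes[d]);
      totC += crate[d];
      totM -= mrate[d];
      mrate[d] = k * mtot[d];
      totM += mrate[d];
      if (occ_pos[d] < 0) {
        occ_pos[d] = occ.size();
        occ.push_back(d);
      }
    };

    long ev_count = 0;
    while (n_active > 1) {
      if (++ev_count % 8192 == 0) {  // guard against float drift
        totC = totM = 0.0;
        for (size_t oi = 0; oi < occ.size(); ++oi) {
          totC += crate[occ[oi]];
          totM += mrate[occ[oi]];
        }
      }
      double rate = totC + totM;
      double dt = (rate > 0) ? R::exp_rand() / rate : R_PosInf;
      if (pulse_idx < n_pulses && t + dt > pulses(pulse_idx, 0)) {
        t = pulses(pulse_idx, 0);
        int ps = (int) pulses(pulse_idx, 1) - 1;
        int pd = (int) pulses(pulse_idx, 2) - 1;
        double pc = pulses(pulse_idx, 3);
        std::vector<int> movers;
        for (size_t j = 0; j < deme[pd].members.size(); ++j)
          if (unif_rand() < pc) movers.push_back(deme[pd].members[j]);
        for (size_t j = 0; j < movers.size(); ++j) {
          remove_lineage(movers[j]);
          add_lineage(movers[j], ps);
        }
        ++pulse_idx;
        continue;
      }
      t += dt;
      double u = unif_rand() * (totC + totM);
      if (u < totC) {
        // coalescence: pick deme by cumulative coalescent rate
        double acc = 0.0;
        int d = -1;
        for (size_t oi = 0; oi < occ.size(); ++oi) {
          int i = occ[oi];
          acc += crate[i];
          if ((u <= acc || oi == occ.size() - 1) && crate[i] > 0) { d = i; break; }
        }
        if (d < 0) continue;
        int k = deme[d].members.size();
        int a = (int)(unif_rand() * k); if (a == k) a = k - 1;
        int b = (int)(unif_rand() * (k - 1)); if (b == k - 1) b = k - 2;
        if (b >= a) ++b;
        int va = deme[d].members[a], vb = deme[d].members[b];
        int vp = next_node++;
        node_time[vp] = t;
        child1[vp] = va; child2[vp] = vb;
        parent[vp] = -1;
        parent[va] = vp; parent[vb] = vp;
        remove_lineage(va);
        remove_lineage(vb);
        add_lineage(vp, d);
        --n_active;
        if (n_active == 1) root = vp;
      } else {
        // migration: pick deme, lineage, neighbour
        double um = u - totC;
        double acc = 0.0;
        int d = -1;
        for (size_t oi = 0; oi < occ.size(); ++oi) {
          int i = occ[oi];
          acc += mrate[i];
          if ((um <= acc || oi == occ.size() - 1) && mrate[i] > 0) { d = i; break; }
        }
        if (d < 0) continue;
        int k = deme[d].members.size();
        int a = (int)(unif_rand() * k); if (a == k) a = k - 1;
        int v = deme[d].members[a];
        double un = unif_rand() * mtot[d];
        double accn = 0.0;
        int to = nbr[d].back();
        for (size_t j = 0; j < nbr[d].size(); ++j) {
          accn += nbr_rate[d][j];
          if (un <= accn) { to = nbr[d][j]; break; }
        }
        remove_lineage(v);
        add_lineage(v, to);
      }
    }

    // place one mutation uniformly on the tree branches
    double total_len = 0.0;
    for (int v = 0; v < next_node; ++v)
      if (v != root && parent[v] >= 0)
        total_len += node_time[parent[v]] - node_time[v];
    double um = unif_rand() * total_len;
    int mut_node = -1;
    double acc = 0.0;
    for (int v = 0; v < next_node; ++v) {
      if (v == root || parent[v] < 0) continue;
      acc += node_time[parent[v]] - node_time[v];
      if (um <= acc) { mut_node = v; break; }
    }
    if (mut_node < 0) mut_node = root >= 0 ? child1[root] : 0;

    // leaves under the mutated branch carry the derived allele
    std::vector<int> stack;
    stack.push_back(mut_node);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (child1[v] < 0) {
        geno(v / 2, snp) += 1;
      } else {
        stack.push_back(child1[v]);
        stack.push_back(child2[v]);
      }
    }
  }
  return geno;
}
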