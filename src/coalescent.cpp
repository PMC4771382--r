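#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Structured coalescent under a finite hierarchical island model.
//
// Demes of equal size N are nested in groups; a lineage migrates to another
// deme of its own group at scaled rate m_within/2 and to a uniformly chosen
// deme of another group at rate m_among/2 (rates are 4Nm-scaled; time in
// units of 2N generations). Two lineages in the same deme coalesce at rate 1
// per pair.
//
// Each replicate simulates the genealogy of the sampled gene copies, places
// a single infinite-sites mutation uniformly on the tree, and forms diploid
// genotypes. Inbreeding / PCR-duplicate bias: each diploid's second gene
// copy is an identical-by-descent copy of the first with probability
// fis[deme] (the individual then contributes a single lineage).
//
// Two engines share the genealogy bookkeeping:
//  * a naive engine that executes every migration event (used as an
//    independent oracle on small configurations), and
//  * a lumped engine exploiting exchangeability of demes within a group and
//    of groups: migrations of a lineage that is alone in its deme (group) to
//    an empty deme (group) leave the co-occupancy pattern unchanged and are
//    self-loops of the lumped chain, so they are skipped without changing
//    the law of the process. This makes the 10-group x 100-deme
//    metapopulation tractable.
//
// Both engines use R's RNG: results are reproducible under set.seed().

namespace {

struct Node {
  double time;
  int parent;         // -1 for root
  int child1, child2; // -1 for leaves
};

inline double npairs(int k) { return 0.5 * (double)k * (double)(k - 1); }

// shared per-replicate output: derived-allele genotype counts per deme
struct RepLayout {
  std::vector<int> ind_deme, ind_l1, ind_l2;
  int n_leaves;
};

// place the single mutation and accumulate genotype counts
void finish_replicate(const std::vector<Node>& nodes, int root,
                      const RepLayout& lay, int rep, int D,
                      IntegerMatrix& out0, IntegerMatrix& out1,
                      IntegerMatrix& out2) {
  double L = 0.0;
  for (int id = 0; id < (int)nodes.size(); ++id)
    if (id != root) L += nodes[nodes[id].parent].time - nodes[id].time;
  double um = unif_rand() * L;
  int mut_node = -1;
  double acc = 0.0;
  for (int id = 0; id < (int)nodes.size(); ++id) {
    if (id == root) continue;
    acc += nodes[nodes[id].parent].time - nodes[id].time;
    if (um <= acc) { mut_node = id; break; }
  }
  if (mut_node < 0) mut_node = (root == (int)nodes.size() - 1)
    ? (int)nodes.size() - 2 : (int)nodes.size() - 1;

  std::vector<char> der(lay.n_leaves, 0);
  std::vector<int> stack;
  stack.push_back(mut_node);
  while (!stack.empty()) {
    int id = stack.back(); stack.pop_back();
    if (nodes[id].child1 < 0) der[id] = 1;
    else { stack.push_back(nodes[id].child1); stack.push_back(nodes[id].child2); }
  }
  int n_ind = (int)lay.ind_deme.size();
  for (int i = 0; i < n_ind; ++i) {
    int a1 = der[lay.ind_l1[i]];
    int a2 = lay.ind_l2[i] < 0 ? a1 : der[lay.ind_l2[i]];
    int g = a1 + a2;
    int d = lay.ind_deme[i];
    if (g == 0) out0(rep, d) += 1;
    else if (g == 1) out1(rep, d) += 1;
    else out2(rep, d) += 1;
  }
}

// draw leaf lineages with IBD collapsing; returns leaf count
int init_leaves(const IntegerVector& n_dip, const NumericVector& fis,
                RepLayout& lay, std::vector<Node>& nodes) {
  int D = n_dip.size();
  int n_ind = 0;
  for (int d = 0; d < D; ++d) n_ind += n_dip[d];
  lay.ind_deme.resize(n_ind); lay.ind_l1.resize(n_ind); lay.ind_l2.resize(n_ind);
  int ind = 0;
  for (int d = 0; d < D; ++d) {
    for (int i = 0; i < n_dip[d]; ++i, ++ind) {
      lay.ind_deme[ind] = d;
      bool ibd = (fis[d] > 0.0) && (unif_rand() < fis[d]);
      lay.ind_l1[ind] = (int)nodes.size();
      lay.ind_l2[ind] = ibd ? -1 : (int)nodes.size() + 1;
      int nl = ibd ? 1 : 2;
      for (int k = 0; k < nl; ++k) {
        Node nd; nd.time = 0.0; nd.parent = -1; nd.child1 = -1; nd.child2 = -1;
        nodes.push_back(nd);
      }
    }
  }
  lay.n_leaves = (int)nodes.size();
  return lay.n_leaves;
}

} // namespace

// ---------------------------------------------------------------- naive ----

// [[Rcpp::export]]
List cpp_sim_hier_island_naive(int n_reps,
                               IntegerVector deme_group,
                               IntegerVector n_dip,
                               NumericVector fis,
                               int n_groups,
                               int demes_per_group,
                               double m_within,
                               double m_among) {
  const int D = deme_group.size();
  if (n_dip.size() != D || fis.size() != D)
    stop("deme_group, n_dip and fis must have equal length");
  std::vector<int> slot(D);
  {
    std::vector<int> used(n_groups, 0);
    for (int d = 0; d < D; ++d) {
      int g = deme_group[d] - 1;
      if (g < 0 || g >= n_groups) stop("deme_group out of range");
      if (used[g] >= demes_per_group) stop("too many sampled demes in a group");
      slot[d] = used[g]++;
    }
  }
  IntegerMatrix out0(n_reps, D), out1(n_reps, D), out2(n_reps, D);
  RNGScope scope;
  std::vector<Node> nodes;
  std::vector<int> active, loc;
  RepLayout lay;

  for (int rep = 0; rep < n_reps; ++rep) {
    nodes.clear(); active.clear(); loc.clear();
    init_leaves(n_dip, fis, lay, nodes);
    std::unordered_map<int, std::vector<int> > occ;
    double pair_sum = 0.0;
    for (int i = 0; i < (int)lay.ind_deme.size(); ++i) {
      int d = lay.ind_deme[i];
      int location = (deme_group[d] - 1) * demes_per_group + slot[d];
      for (int l : {lay.ind_l1[i], lay.ind_l2[i]}) {
        if (l < 0) continue;
        loc.resize(nodes.size(), -1);
        loc[l] = location;
        std::vector<int>& v = occ[location];
        pair_sum += (double)v.size();
        v.push_back(l);
        active.push_back(l);
      }
    }
    loc.resize(nodes.size() * 2 + 2, -1);

    double t = 0.0;
    double mig_per_lin = 0.5 * (m_within + m_among);
    while ((int)active.size() > 1) {
      int k = (int)active.size();
      double total = k * mig_per_lin + pair_sum;
      t += exp_rand() / total;
      double u = unif_rand() * total;
      if (u < k * mig_per_lin) {
        int ai = (int)(unif_rand() * k); if (ai >= k) ai = k - 1;
        int id = active[ai];
        int old_loc = loc[id];
        int g = old_loc / demes_per_group;
        int dm = old_loc % demes_per_group;
        int new_g = g, new_d = dm;
        if (unif_rand() * (m_within + m_among) < m_within) {
          if (demes_per_group > 1) {
            new_d = (int)(unif_rand() * (demes_per_group - 1));
            if (new_d >= dm) new_d += 1;
          }
        } else {
          if (n_groups > 1) {
            new_g = (int)(unif_rand() * (n_groups - 1));
            if (new_g >= g) new_g += 1;
            new_d = (int)(unif_rand() * demes_per_group);
            if (new_d >= demes_per_group) new_d = demes_per_group - 1;
          }
        }
        int new_loc = new_g * demes_per_group + new_d;
        if (new_loc == old_loc) continue;
        std::vector<int>& vo = occ[old_loc];
        pair_sum -= (double)(vo.size() - 1);
        for (size_t j = 0; j < vo.size(); ++j)
          if (vo[j] == id) { vo[j] = vo.back(); vo.pop_back(); break; }
        std::vector<int>& vn = occ[new_loc];
        pair_sum += (double)vn.size();
        vn.push_back(id);
        loc[id] = new_loc;
      } else {
        double v = unif_rand() * pair_sum;
        double acc = 0.0;
        int chosen = -1;
        for (auto it = occ.begin(); it != occ.end(); ++it) {
          int kd = (int)it->second.size();
          if (kd < 2) continue;
          acc += npairs(kd);
          if (v <= acc) { chosen = it->first; break; }
        }
        if (chosen < 0)
          for (auto it = occ.begin(); it != occ.end(); ++it)
            if ((int)it->second.size() >= 2) chosen = it->first;
        std::vector<int>& vd = occ[chosen];
        int kd = (int)vd.size();
        int i1 = (int)(unif_rand() * kd); if (i1 >= kd) i1 = kd - 1;
        int i2 = (int)(unif_rand() * (kd - 1)); if (i2 >= kd - 1) i2 = kd - 2;
        if (i2 >= i1) i2 += 1;
        int a = vd[i1], b = vd[i2];
        Node nd; nd.time = t; nd.parent = -1; nd.child1 = a; nd.child2 = b;
        int id = (int)nodes.size();
        nodes.push_back(nd);
        loc.resize(nodes.size(), -1);
        loc[id] = chosen;
        nodes[a].parent = id;
        nodes[b].parent = id;
        pair_sum -= (double)(kd - 1) + (double)(kd - 2);
        for (int target : {a, b})
          for (size_t j = 0; j < vd.size(); ++j)
            if ((int)vd[j] == target) { vd[j] = vd.back(); vd.pop_back(); break; }
        pair_sum += (double)vd.size();
        vd.push_back(id);
        int rem = 0;
        for (size_t j = 0; j < active.size() && rem < 2;) {
          if (active[j] == a || active[j] == b) {
            active[j] = active.back(); active.pop_back(); ++rem;
          } else ++j;
        }
        active.push_back(id);
      }
    }
    finish_replicate(nodes, active[0], lay, rep, D, out0, out1, out2);
  }
  return List::create(_["n0"] = out0, _["n1"] = out1, _["n2"] = out2);
}

// --------------------------------------------------------------- lumped ----

namespace {

// occupied deme in the lumped engine
struct LDeme {
  int group;
  std::vector<int> members;   // lineage (node) ids
  int idx_occ;                // index in group's occ list
  int idx_single;             // index in group's singleton list, or -1
  int idx_multi;              // index in global multi list, or -1
};

struct LumpedState {
  int G, d;
  double Mw, Ma;              // m_within/2 and m_among/2 per lineage
  std::vector<LDeme> demes;   // active demes (swap-removed)
  std::vector<int> lin_deme;  // node id -> deme index (active lineages only)
  std::vector<std::vector<int> > occ;     // per group: deme indices
  std::vector<std::vector<int> > single;  // per group: singleton deme indices
  std::vector<int> n_lin;     // lineages per group
  std::vector<int> multi;     // demes with >= 2 lineages
  int k;                      // active lineages
  int G_occ;                  // occupied groups
  int cg1;                    // groups with exactly one lineage
  double pair_sum;            // sum over demes of C(c,2)
  double S_w;                 // sum over groups of singles_g * (occ_g - 1)

  void reset(int G_, int d_, double m_within, double m_among, int max_nodes) {
    G = G_; d = d_;
    Mw = 0.5 * m_within; Ma = 0.5 * m_among;
    demes.clear();
    lin_deme.assign(max_nodes, -1);
    occ.assign(G, {}); single.assign(G, {});
    n_lin.assign(G, 0);
    multi.clear();
    k = 0; G_occ = 0; cg1 = 0;
    pair_sum = 0.0; S_w = 0.0;
  }

  double w_contrib(int g) const {
    return (double)single[g].size() * (double)((int)occ[g].size() - 1);
  }

  // maintain singleton/multi membership of deme di after a size change
  void refresh_deme_lists(int di) {
    LDeme& dm = demes[di];
    int c = (int)dm.members.size();
    bool want_single = (c == 1), want_multi = (c >= 2);
    if (want_single && dm.idx_single < 0) {
      dm.idx_single = (int)single[dm.group].size();
      single[dm.group].push_back(di);
    } else if (!want_single && dm.idx_single >= 0) {
      std::vector<int>& s = single[dm.group];
      int last = s.back();
      s[dm.idx_single] = last;
      demes[last].idx_single = dm.idx_single;
      s.pop_back();
      dm.idx_single = -1;
    }
    if (want_multi && dm.idx_multi < 0) {
      dm.idx_multi = (int)multi.size();
      multi.push_back(di);
    } else if (!want_multi && dm.idx_multi >= 0) {
      int last = multi.back();
      multi[dm.idx_multi] = last;
      demes[last].idx_multi = dm.idx_multi;
      multi.pop_back();
      dm.idx_multi = -1;
    }
  }

  int new_deme(int g) {
    S_w -= w_contrib(g);   // occ[g] grows below
    LDeme dm;
    dm.group = g;
    dm.idx_occ = (int)occ[g].size();
    dm.idx_single = -1; dm.idx_multi = -1;
    int di = (int)demes.size();
    demes.push_back(dm);
    occ[g].push_back(di);
    S_w += w_contrib(g);
    return di;
  }

  // add lineage id to deme di (deme must exist)
  void add_lineage(int id, int di) {
    int g = demes[di].group;
    S_w -= w_contrib(g);
    int c = (int)demes[di].members.size();
    pair_sum += (double)c;
    demes[di].members.push_back(id);
    lin_deme[id] = di;
    refresh_deme_lists(di);
    if (n_lin[g] == 0) ++G_occ;
    if (n_lin[g] == 1) --cg1;
    ++n_lin[g];
    if (n_lin[g] == 1) ++cg1;
    ++k;
    S_w += w_contrib(g);
  }

  // remove lineage id from its deme; deme dropped if emptied
  void remove_lineage(int id) {
    int di = lin_deme[id];
    int g = demes[di].group;
    S_w -= w_contrib(g);
    std::vector<int>& mb = demes[di].members;
    int c = (int)mb.size();
    pair_sum -= (double)(c - 1);
    for (size_t j = 0; j < mb.size(); ++j)
      if (mb[j] == id) { mb[j] = mb.back(); mb.pop_back(); break; }
    lin_deme[id] = -1;
    refresh_deme_lists(di);
    if (mb.empty()) drop_deme(di); // re-adds w_contrib inside
    else S_w += w_contrib(g);
    --n_lin[g];
    if (n_lin[g] == 0) { --G_occ; --cg1; }
    else if (n_lin[g] == 1) ++cg1;
    --k;
  }

  void drop_deme(int di) {
    int g = demes[di].group;
    // remove from occ list (deme already absent from single/multi lists)
    std::vector<int>& o = occ[g];
    int last = o.back();
    o[demes[di].idx_occ] = last;
    demes[last].idx_occ = demes[di].idx_occ;
    o.pop_back();
    // swap-remove from demes vector, fixing indices of the moved deme
    int moved = (int)demes.size() - 1;
    if (di != moved) {
      demes[di] = demes[moved];
      for (int id : demes[di].members) lin_deme[id] = di;
      occ[demes[di].group][demes[di].idx_occ] = di;
      if (demes[di].idx_single >= 0)
        single[demes[di].group][demes[di].idx_single] = di;
      if (demes[di].idx_multi >= 0) multi[demes[di].idx_multi] = di;
    }
    demes.pop_back();
    S_w += w_contrib(g);
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_sim_hier_island(int n_reps,
                         IntegerVector deme_group,
                         IntegerVector n_dip,
                         NumericVector fis,
                         int n_groups,
                         int demes_per_group,
                         double m_within,
                         double m_among) {
  const int D = deme_group.size();
  if (n_dip.size() != D || fis.size() != D)
    stop("deme_group, n_dip and fis must have equal length");
  {
    std::vector<int> used(n_groups, 0);
    for (int d = 0; d < D; ++d) {
      int g = deme_group[d] - 1;
      if (g < 0 || g >= n_groups) stop("deme_group out of range");
      if (++used[g] > demes_per_group) stop("too many sampled demes in a group");
    }
  }
  int n_ind = 0;
  for (int d = 0; d < D; ++d) n_ind += n_dip[d];
  const int max_nodes = 4 * n_ind + 4;

  IntegerMatrix out0(n_reps, D), out1(n_reps, D), out2(n_reps, D);
  RNGScope scope;
  std::vector<Node> nodes;
  RepLayout lay;
  LumpedState st;

  for (int rep = 0; rep < n_reps; ++rep) {
    nodes.clear();
    init_leaves(n_dip, fis, lay, nodes);
    st.reset(n_groups, demes_per_group, m_within, m_among, max_nodes);
    // one fresh deme per sampled deme
    std::vector<int> deme_of_sample(D);
    for (int d = 0; d < D; ++d)
      deme_of_sample[d] = st.new_deme(deme_group[d] - 1);
    for (int i = 0; i < (int)lay.ind_deme.size(); ++i) {
      int di = deme_of_sample[lay.ind_deme[i]];
      st.add_lineage(lay.ind_l1[i], di);
      if (lay.ind_l2[i] >= 0) st.add_lineage(lay.ind_l2[i], di);
    }

    double t = 0.0;
    const double dm1 = (double)(demes_per_group - 1);
    while (st.k > 1) {
      int n_shared = 0;
      for (int di : st.multi) n_shared += (int)st.demes[di].members.size();
      double W = 0.0;
      if (demes_per_group > 1)
        W = st.Mw * ((double)n_shared + (dm1 > 0 ? st.S_w / dm1 : 0.0));
      double A = 0.0;
      int lin_shared_grp = 0;
      if (n_groups > 1) {
        lin_shared_grp = st.k - st.cg1;
        A = st.Ma * ((double)lin_shared_grp +
                     (double)st.cg1 * (double)(st.G_occ - 1) /
                     (double)(n_groups - 1));
      }
      double total = st.pair_sum + W + A;
      if (total <= 0.0)
        stop("coalescent stuck: no coalescence or migration possible");
      t += exp_rand() / total;
      double u = unif_rand() * total;

      if (u < st.pair_sum) {
        // ---- coalescence: choose deme proportional to C(c,2)
        double v = unif_rand() * st.pair_sum;
        double acc = 0.0;
        int di = -1;
        for (int cand : st.multi) {
          acc += npairs((int)st.demes[cand].members.size());
          if (v <= acc) { di = cand; break; }
        }
        if (di < 0) di = st.multi.back();
        std::vector<int>& mb = st.demes[di].members;
        int kd = (int)mb.size();
        int i1 = (int)(unif_rand() * kd); if (i1 >= kd) i1 = kd - 1;
        int i2 = (int)(unif_rand() * (kd - 1)); if (i2 >= kd - 1) i2 = kd - 2;
        if (i2 >= i1) i2 += 1;
        int a = mb[i1], b = mb[i2];
        Node nd; nd.time = t; nd.parent = -1; nd.child1 = a; nd.child2 = b;
        int id = (int)nodes.size();
        nodes.push_back(nd);
        nodes[a].parent = id; nodes[b].parent = id;
        st.remove_lineage(b);
        // replace a by the merged lineage in place: deme size and all
        // occupancy counters are unchanged
        int di2 = st.lin_deme[a];
        for (int& m : st.demes[di2].members)
          if (m == a) { m = id; break; }
        st.lin_deme[id] = di2;
        st.lin_deme[a] = -1;
        continue;
      }
      u -= st.pair_sum;

      double w_shared = (demes_per_group > 1) ? st.Mw * (double)n_shared : 0.0;
      if (u < w_shared) {
        // ---- within-group move of a deme-sharing lineage
        double v = unif_rand() * (double)n_shared;
        double acc = 0.0;
        int di = -1;
        for (int cand : st.multi) {
          acc += (double)st.demes[cand].members.size();
          if (v <= acc) { di = cand; break; }
        }
        if (di < 0) di = st.multi.back();
        std::vector<int>& mb = st.demes[di].members;
        int pick = (int)(unif_rand() * mb.size());
        if (pick >= (int)mb.size()) pick = (int)mb.size() - 1;
        int id = mb[pick];
        int g = st.demes[di].group;
        // destination: each of the other d-1 demes equally likely
        int n_occ_other = (int)st.occ[g].size() - 1;
        st.remove_lineage(id); // di stays occupied (it was shared)
        if (unif_rand() * dm1 < (double)n_occ_other) {
          // land in one of the other occupied demes, uniformly
          int j;
          do {
            j = (int)(unif_rand() * st.occ[g].size());
            if (j >= (int)st.occ[g].size()) j = (int)st.occ[g].size() - 1;
          } while (st.occ[g][j] == di);
          st.add_lineage(id, st.occ[g][j]);
        } else {
          st.add_lineage(id, st.new_deme(g));
        }
        continue;
      }
      u -= w_shared;

      double w_alone = (demes_per_group > 1 && dm1 > 0)
        ? st.Mw * st.S_w / dm1 : 0.0;
      if (u < w_alone) {
        // ---- within-group move of a deme-alone lineage onto an occupied deme
        double v = unif_rand() * st.S_w;
        double acc = 0.0;
        int g = -1;
        for (int gg = 0; gg < n_groups; ++gg) {
          acc += st.w_contrib(gg);
          if (v <= acc && st.w_contrib(gg) > 0) { g = gg; break; }
        }
        if (g < 0) { for (int gg = n_groups - 1; gg >= 0; --gg) if (st.w_contrib(gg) > 0) { g = gg; break; } }
        std::vector<int>& sg = st.single[g];
        int si = (int)(unif_rand() * sg.size());
        if (si >= (int)sg.size()) si = (int)sg.size() - 1;
        int di = sg[si];
        int id = st.demes[di].members[0];
        // destination: uniform among the other occupied demes of g
        int j;
        do {
          j = (int)(unif_rand() * st.occ[g].size());
          if (j >= (int)st.occ[g].size()) j = (int)st.occ[g].size() - 1;
        } while (st.occ[g][j] == di);
        int dest = st.occ[g][j];
        st.remove_lineage(id); // drops deme di; indices may move
        // dest index may have been invalidated by drop_deme's swap: dest
        // was != di, and drop_deme moves only the last deme into slot di
        if (dest == (int)st.demes.size()) dest = di;
        st.add_lineage(id, dest);
        continue;
      }
      u -= w_alone;

      // ---- among-group migration
      bool from_shared_group = (u < st.Ma * (double)lin_shared_grp);
      int id = -1, g_from = -1;
      if (from_shared_group) {
        // pick a lineage uniformly among those in groups with >= 2 lineages
        double v = unif_rand() * (double)lin_shared_grp;
        double acc = 0.0;
        for (int gg = 0; gg < n_groups && id < 0; ++gg) {
          if (st.n_lin[gg] < 2) continue;
          acc += (double)st.n_lin[gg];
          if (v <= acc) {
            g_from = gg;
            // choose deme proportional to its size, then a member
            double v2 = unif_rand() * (double)st.n_lin[gg];
            double a2 = 0.0;
            for (int cand : st.occ[gg]) {
              a2 += (double)st.demes[cand].members.size();
              if (v2 <= a2) {
                std::vector<int>& mb = st.demes[cand].members;
                int pick = (int)(unif_rand() * mb.size());
                if (pick >= (int)mb.size()) pick = (int)mb.size() - 1;
                id = mb[pick];
                break;
              }
            }
            if (id < 0) {
              int cand = st.occ[gg].back();
              id = st.demes[cand].members[0];
            }
          }
        }
        if (id < 0) { // numerical fallback
          for (int gg = n_groups - 1; gg >= 0; --gg)
            if (st.n_lin[gg] >= 2) {
              g_from = gg;
              id = st.demes[st.occ[gg][0]].members[0];
              break;
            }
        }
      } else {
        // lineage alone in its group, moving into an occupied other group
        int pickg = (int)(unif_rand() * st.cg1);
        if (pickg >= st.cg1) pickg = st.cg1 - 1;
        int seen = 0;
        for (int gg = 0; gg < n_groups; ++gg) {
          if (st.n_lin[gg] == 1) {
            if (seen == pickg) { g_from = gg; break; }
            ++seen;
          }
        }
        id = st.demes[st.occ[g_from][0]].members[0];
      }
      // destination group
      int g_to = -1;
      if (from_shared_group) {
        g_to = (int)(unif_rand() * (n_groups - 1));
        if (g_to >= n_groups - 1) g_to = n_groups - 2;
        if (g_to >= g_from) g_to += 1;
      } else {
        // uniform among occupied groups other than g_from
        int n_cand = st.G_occ - 1;
        int pickg = (int)(unif_rand() * n_cand);
        if (pickg >= n_cand) pickg = n_cand - 1;
        int seen = 0;
        for (int gg = 0; gg < n_groups; ++gg) {
          if (gg == g_from || st.n_lin[gg] == 0) continue;
          if (seen == pickg) { g_to = gg; break; }
          ++seen;
        }
      }
      st.remove_lineage(id);
      // deme within destination group: uniform over its d demes
      int n_occ_to = (int)st.occ[g_to].size();
      if (unif_rand() * (double)demes_per_group < (double)n_occ_to) {
        int j = (int)(unif_rand() * n_occ_to);
        if (j >= n_occ_to) j = n_occ_to - 1;
        st.add_lineage(id, st.occ[g_to][j]);
      } else {
        st.add_lineage(id, st.new_deme(g_to));
      }
    }
    // root id is the last created node
    finish_replicate(nodes, (int)nodes.size() - 1, lay, rep, D, out0, out1, out2);
  }
  return List::create(_["n0"] = out0, _["n1"] = out1, _["n2"] = out2);
}
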