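#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-population split coalescent for an X-linked locus.
//
// Backwards in time: within each extant population, lineage pairs coalesce
// at rate 1/(2*Ne) per generation (time measured in generations, Ne in
// chromosomes-equivalent effective size, so a pair's expected coalescence
// time is 2*Ne generations).  At t_gen both lineage sets merge into the
// ancestral population of size ne_anc and coalescence continues to the MRCA.
// Mutations follow the infinite-sites model: fixed_s mode places exactly S
// mutations multinomially on branches proportional to length; theta mode
// draws Poisson(total_length * mu_gen * L).
//
// Uses R's RNG throughout (caller must set.seed); all draws are sequential,
// so a run is bit-reproducible given seed + parameters.

namespace {

struct Tree {
  int n_tips;                    // n1 + n2
  std::vector<int> parent;       // -1 for root
  std::vector<int> left, right;  // -1 for tips
  std::vector<double> time;      // node times (generations, tips at 0)
  int root;
};

// simulate the genealogy; tips 0..n1-1 are population 1, n1..n1+n2-1 pop 2
Tree sim_tree(int n1, int n2, double ne1, double ne2, double ne_anc,
              double t_gen) {
  int n = n1 + n2;
  int n_nodes = 2 * n - 1;
  Tree tr;
  tr.n_tips = n;
  tr.parent.assign(n_nodes, -1);
  tr.left.assign(n_nodes, -1);
  tr.right.assign(n_nodes, -1);
  tr.time.assign(n_nodes, 0.0);
  int next_node = n;

  std::vector<int> act1, act2;
  for (int i = 0; i < n1; ++i) act1.push_back(i);
  for (int i = 0; i < n2; ++i) act2.push_back(n1 + i);

  // within-population phase, each clock from 0 up to the split time
  for (int pop = 0; pop < 2; ++pop) {
    std::vector<int>& act = pop == 0 ? act1 : act2;
    double ne = pop == 0 ? ne1 : ne2;
    double t = 0.0;
    while ((int)act.size() >= 2) {
      int k = (int)act.size();
      double rate = k * (k - 1) / 2.0 / (2.0 * ne);
      double w = R::exp_rand() / rate;
      if (t + w >= t_gen) break;
      t += w;
      int i = (int)std::floor(unif_rand() * k);
      int j = (int)std::floor(unif_rand() * (k - 1));
      if (j >= i) ++j;
      int a = act[i], b = act[j];
      int node = next_node++;
      tr.time[node] = t;
      tr.left[node] = a; tr.right[node] = b;
      tr.parent[a] = node; tr.parent[b] = node;
      if (i > j) std::swap(i, j);
      act[i] = node;
      act.erase(act.begin() + j);
    }
  }

  // ancestral phase
  std::vector<int> act(act1);
  act.insert(act.end(), act2.begin(), act2.end());
  double t = t_gen;
  while ((int)act.size() >= 2) {
    int k = (int)act.size();
    double rate = k * (k - 1) / 2.0 / (2.0 * ne_anc);
    t += R::exp_rand() / rate;
    int i = (int)std::floor(unif_rand() * k);
    int j = (int)std::floor(unif_rand() * (k - 1));
    if (j >= i) ++j;
    int a = act[i], b = act[j];
    int node = next_node++;
    tr.time[node] = t;
    tr.left[node] = a; tr.right[node] = b;
    tr.parent[a] = node; tr.parent[b] = node;
    if (i > j) std::swap(i, j);
    act[i] = node;
    act.erase(act.begin() + j);
  }
  tr.root = act[0];
  return tr;
}

// branch lengths (length above each node; 0 for root)
void branch_lengths(const Tree& tr, std::vector<double>& bl, double& total) {
  int n_nodes = (int)tr.parent.size();
  bl.assign(n_nodes, 0.0);
  total = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    if (tr.parent[v] >= 0) {
      bl[v] = tr.time[tr.parent[v]] - tr.time[v];
      total += bl[v];
    }
  }
}

// per-node descendant-tip counts in each population (nodes created in time
// order, so children always precede parents in index order above n_tips)
void desc_counts(const Tree& tr, int n1, std::vector<int>& d1,
                 std::vector<int>& d2) {
  int n_nodes = (int)tr.parent.size();
  d1.assign(n_nodes, 0);
  d2.assign(n_nodes, 0);
  for (int v = 0; v < tr.n_tips; ++v) {
    if (v < n1) d1[v] = 1; else d2[v] = 1;
  }
  for (int v = tr.n_tips; v < n_nodes; ++v) {
    d1[v] = d1[tr.left[v]] + d1[tr.right[v]];
    d2[v] = d2[tr.left[v]] + d2[tr.right[v]];
  }
}

// draw the branch carrying one mutation, prob proportional to length
int sample_branch(const std::vector<double>& bl, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int n = (int)bl.size();
  for (int v = 0; v < n; ++v) {
    acc += bl[v];
    if (u <= acc) return v;
  }
  return n - 2;  // numerical guard; root has zero length
}

// number of mutations: fixed S, or Poisson(total * mu_gen * L) when s < 0
int n_mutations(int s_fixed, double total_len, double theta_site_gen,
                double locus_len) {
  if (s_fixed >= 0) return s_fixed;
  return (int)R::rpois(total_len * theta_site_gen * locus_len);
}

inline double hudson_fst(double p1, double p2, int n1, int n2, bool& ok) {
  double num = (p1 - p2) * (p1 - p2)
             - p1 * (1.0 - p1) / (n1 - 1)
             - p2 * (1.0 - p2) / (n2 - 1);
  double den = p1 * (1.0 - p2) + p2 * (1.0 - p1);
  if (den <= 0.0) { ok = false; return NA_REAL; }
  ok = true;
  return num / den;
}

}  // namespace

// [[Rcpp::export(name = ".sim_split_cpp")]]
List sim_split_cpp(int n1, int n2, double ne1, double ne2, double ne_anc,
                   double t_gen, int s_fixed, double mu_gen, double locus_len,
                   bool make_matrix) {
  Tree tr = sim_tree(n1, n2, ne1, ne2, ne_anc, t_gen);
  std::vector<double> bl;
  double total;
  branch_lengths(tr, bl, total);
  std::vector<int> d1, d2;
  desc_counts(tr, n1, d1, d2);

  int S = n_mutations(s_fixed, total, mu_gen, locus_len);
  IntegerVector der1(S), der2(S), node(S);
  for (int s = 0; s < S; ++s) {
    int v = sample_branch(bl, total);
    node[s] = v;
    der1[s] = d1[v];
    der2[s] = d2[v];
  }

  List out = List::create(
      _["n_sites"] = S, _["derived1"] = der1, _["derived2"] = der2,
      _["total_branch_length"] = total, _["tmrca"] = tr.time[tr.root]);

  if (make_matrix) {
    IntegerMatrix geno(S, tr.n_tips);
    std::vector<int> stack;
    for (int s = 0; s < S; ++s) {
      stack.clear();
      stack.push_back(node[s]);
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        if (v < tr.n_tips) {
          geno(s, v) = 1;
        } else {
          stack.push_back(tr.left[v]);
          stack.push_back(tr.right[v]);
        }
      }
    }
    out["genotypes"] = geno;
  }
  return out;
}

// Batch replicates for the drift test: per replicate, per-site Hudson Fst on
// the simulated sample frequencies, its mean, and a two-sided Welch t-test
// of simulated Fst against the observed vector (summarised by mean/var/n).
// Replicates with no polymorphic site (possible only in theta mode) are
// redrawn; the count is returned.
// [[Rcpp::export(name = ".drift_reps_cpp")]]
List drift_reps_cpp(int n_reps, int n1, int n2, double ne1, double ne2,
                    double ne_anc, double t_gen, int s_fixed, double mu_gen,
                    double locus_len, double obs_mean, double obs_var,
                    int obs_n) {
  NumericVector mean_fst(n_reps), t_p(n_reps);
  int redraws = 0;
  std::vector<double> bl, fst;
  std::vector<int> d1, d2;

  for (int r = 0; r < n_reps; ++r) {
    int S = 0;
    double m = 0.0, v = 0.0;
    int used = 0;
    for (;;) {
      Tree tr = sim_tree(n1, n2, ne1, ne2, ne_anc, t_gen);
      double total;
      branch_lengths(tr, bl, total);
      desc_counts(tr, n1, d1, d2);
      S = n_mutations(s_fixed, total, mu_gen, locus_len);
      if (S < 1) { ++redraws; continue; }
      fst.clear();
      for (int s = 0; s < S; ++s) {
        int b = sample_branch(bl, total);
        double p1 = (double)d1[b] / n1;
        double p2 = (double)d2[b] / n2;
        bool ok;
        double f = hudson_fst(p1, p2, n1, n2, ok);
        if (ok) fst.push_back(f);
      }
      if (fst.empty()) { ++redraws; continue; }
      break;
    }
    used = (int)fst.size();
    for (int s = 0; s < used; ++s) m += fst[s];
    m /= used;
    for (int s = 0; s < used; ++s) v += (fst[s] - m) * (fst[s] - m);
    v = used > 1 ? v / (used - 1) : 0.0;
    mean_fst[r] = m;

    // Welch two-sample t against the observed summary
    double se2 = v / used + obs_var / obs_n;
    if (se2 <= 0.0 || used < 2 || obs_n < 2) {
      t_p[r] = NA_REAL;
    } else {
      double t = (m - obs_mean) / std::sqrt(se2);
      double df = se2 * se2 /
          (std::pow(v / used, 2) / (used - 1) +
           std::pow(obs_var / obs_n, 2) / (obs_n - 1));
      t_p[r] = 2.0 * R::pt(-std::fabs(t), df, 1, 0);
    }
  }
  return List::create(_["mean_fst"] = mean_fst, _["t_p"] = t_p,
                      _["redraws"] = redraws);
}
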