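// Structured-coalescent core for unlinked biallelic SNP loci.
//
// Demes are integer slots 0..D-1 (the sampled leaf demes). Backward-in-time
// events either merge one slot into another (the host slot then carries the
// ancestral lineage's effective size) or split the lineages of one slot
// between two parent slots independently with a fixed fraction (admixture).
// Within a deme of diploid size N holding k gene copies, the waiting time to
// the next coalescence is Exp(k(k-1)/2 * 1/(2N)) generations.
//
// All randomness comes from R's RNG (unif_rand / exp_rand) so set.seed()
// in R governs every stream and reruns are bit-identical.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Event {
  double time;
  int type;      // 0 = merge(child -> parent_a), 1 = admixture(child -> a/b)
  int child;
  int pa;
  int pb;        // unused for merge
  double frac;   // P(lineage -> pa) for admixture
  double nsize;  // new diploid size of pa after a merge
};

struct Tree {
  int n;                          // gene copies (leaves)
  std::vector<int> parent;        // size 2n-1, -1 at root
  std::vector<int> child1, child2;
  std::vector<double> time;       // node times, leaves at 0
};

// Simulate one gene tree. Leaf copy ids are assigned deme-block-wise:
// deme 0 individuals first, two consecutive copies per individual.
Tree sim_tree(const std::vector<Event> &ev,
              const std::vector<double> &leaf_sizes,
              const std::vector<int> &n_ind) {
  const int D = static_cast<int>(leaf_sizes.size());
  int n = 0;
  for (int d = 0; d < D; ++d) n += 2 * n_ind[d];

  Tree tr;
  tr.n = n;
  tr.parent.assign(2 * n - 1, -1);
  tr.child1.assign(2 * n - 1, -1);
  tr.child2.assign(2 * n - 1, -1);
  tr.time.assign(2 * n - 1, 0.0);

  std::vector<double> N(leaf_sizes);
  std::vector<std::vector<int> > act(D);
  {
    int id = 0;
    for (int d = 0; d < D; ++d)
      for (int i = 0; i < 2 * n_ind[d]; ++i) act[d].push_back(id++);
  }

  double t = 0.0;
  std::size_t ei = 0;
  int nact = n, next_node = n;

  while (nact > 1) {
    double tot = 0.0;
    for (int d = 0; d < D; ++d) {
      const double k = static_cast<double>(act[d].size());
      if (k >= 2.0) tot += k * (k - 1.0) * 0.25 / N[d];  // k(k-1)/2 / (2N)
    }
    const double tev = (ei < ev.size()) ? ev[ei].time : R_PosInf;

    bool coalesced = false;
    if (tot > 0.0) {
      const double dt = exp_rand() / tot;
      if (t + dt < tev) {
        t += dt;
        // choose deme proportionally to its coalescence rate
        double u = unif_rand() * tot, acc = 0.0;
        int dsel = -1;
        for (int d = 0; d < D; ++d) {
          const double k = static_cast<double>(act[d].size());
          if (k >= 2.0) {
            acc += k * (k - 1.0) * 0.25 / N[d];
            if (u <= acc) { dsel = d; break; }
          }
        }
        if (dsel < 0) {  // numerical edge: take last eligible deme
          for (int d = D - 1; d >= 0; --d)
            if (act[d].size() >= 2) { dsel = d; break; }
        }
        std::vector<int> &a = act[dsel];
        const int k = static_cast<int>(a.size());
        int i = static_cast<int>(unif_rand() * k); if (i >= k) i = k - 1;
        int j = static_cast<int>(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
        if (j >= i) ++j;
        const int na = a[i], nb = a[j];
        const int id = next_node++;
        tr.time[id] = t;
        tr.parent[na] = id; tr.parent[nb] = id;
        tr.child1[id] = na; tr.child2[id] = nb;
        a[i] = id;
        a.erase(a.begin() + j);
        --nact;
        coalesced = true;
      }
    }
    if (coalesced) continue;

    if (!R_finite(tev))
      stop("lineages cannot coalesce: no further events and no shared deme (invalid scenario)");

    // apply the next event
    t = tev;
    const Event &e = ev[ei++];
    std::vector<int> &ch = act[e.child];
    if (e.type == 0) {
      std::vector<int> &pa = act[e.pa];
      pa.insert(pa.end(), ch.begin(), ch.end());
      ch.clear();
      N[e.pa] = e.nsize;
    } else {
      std::vector<int> &pa = act[e.pa];
      std::vector<int> &pb = act[e.pb];
      for (std::size_t i = 0; i < ch.size(); ++i) {
        if (unif_rand() < e.frac) pa.push_back(ch[i]); else pb.push_back(ch[i]);
      }
      ch.clear();
    }
  }
  return tr;
}

double total_length(const Tree &tr) {
  const int m = 2 * tr.n - 1;
  double total = 0.0;
  for (int v = 0; v < m; ++v)
    if (tr.parent[v] >= 0) total += tr.time[tr.parent[v]] - tr.time[v];
  return total;
}

// One mutation on a branch chosen proportionally to its length; returns the
// derived-carrier indicator over leaf copies. Every non-root branch subtends
// a proper, non-empty subset of the sample, so the locus is always
// polymorphic in the sample.
void drop_mutation(const Tree &tr, std::vector<int> &carrier) {
  const int m = 2 * tr.n - 1;
  const double total = total_length(tr);
  double u = unif_rand() * total, acc = 0.0;
  int sel = -1;
  for (int v = 0; v < m; ++v) {
    if (tr.parent[v] < 0) continue;
    acc += tr.time[tr.parent[v]] - tr.time[v];
    if (u <= acc) { sel = v; break; }
  }
  if (sel < 0) sel = m - 2;  // numerical edge; never the root
  carrier.assign(tr.n, 0);
  std::vector<int> stack;
  stack.push_back(sel);
  while (!stack.empty()) {
    const int v = stack.back(); stack.pop_back();
    if (v < tr.n) { carrier[v] = 1; continue; }
    stack.push_back(tr.child1[v]);
    stack.push_back(tr.child2[v]);
  }
}

std::vector<Event> unpack_events(const NumericVector &ev_time,
                                 const IntegerVector &ev_type,
                                 const IntegerVector &ev_child,
                                 const IntegerVector &ev_pa,
                                 const IntegerVector &ev_pb,
                                 const NumericVector &ev_frac,
                                 const NumericVector &ev_size) {
  std::vector<Event> ev(ev_time.size());
  for (int i = 0; i < ev_time.size(); ++i) {
    ev[i].time = ev_time[i];
    ev[i].type = ev_type[i];
    ev[i].child = ev_child[i];
    ev[i].pa = ev_pa[i];
    ev[i].pb = ev_pb[i];
    ev[i].frac = ev_frac[i];
    ev[i].nsize = ev_size[i];
  }
  return ev;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_sim_dosage(NumericVector ev_time, IntegerVector ev_type,
                             IntegerVector ev_child, IntegerVector ev_pa,
                             IntegerVector ev_pb, NumericVector ev_frac,
                             NumericVector ev_size, NumericVector leaf_sizes,
                             IntegerVector n_ind, int n_loci, double min_maf,
                             int max_attempts) {
  RNGScope rng;
  const std::vector<Event> ev =
      unpack_events(ev_time, ev_type, ev_child, ev_pa, ev_pb, ev_frac, ev_size);
  std::vector<double> ls(leaf_sizes.begin(), leaf_sizes.end());
  std::vector<int> ni(n_ind.begin(), n_ind.end());
  int tot_ind = 0;
  for (std::size_t d = 0; d < ni.size(); ++d) tot_ind += ni[d];
  const int n = 2 * tot_ind;

  IntegerMatrix out(tot_ind, n_loci);
  std::vector<int> carrier;
  long attempts_total = 0;

  // A SNP locus's genealogy is length-biased (in the low-mutation-rate
  // infinite-sites limit, the probability that a locus is variable is
  // proportional to its total branch length). Trees are therefore accepted
  // with probability L / L_cap, with L_cap calibrated from a pilot sample;
  // the rare tree exceeding L_cap is always accepted (negligible truncation).
  double l_cap = 0.0;
  for (int p = 0; p < 32; ++p) {
    Tree tr = sim_tree(ev, ls, ni);
    const double L = total_length(tr);
    if (L > l_cap) l_cap = L;
  }
  l_cap *= 1.6;

  for (int l = 0; l < n_loci; ++l) {
    bool accepted = false;
    for (int a = 0; a < max_attempts; ++a) {
      ++attempts_total;
      Tree tr = sim_tree(ev, ls, ni);
      const double L = total_length(tr);
      if (L < l_cap && unif_rand() * l_cap > L) continue;
      drop_mutation(tr, carrier);
      int cnt = 0;
      for (int i = 0; i < n; ++i) cnt += carrier[i];
      const double maf =
          static_cast<double>(cnt <= n - cnt ? cnt : n - cnt) / n;
      if (cnt > 0 && cnt < n && maf >= min_maf) {
        for (int i = 0; i < tot_ind; ++i)
          out(i, l) = carrier[2 * i] + carrier[2 * i + 1];
        accepted = true;
        break;
      }
    }
    if (!accepted)
      stop("locus rejection cap (%d attempts) exhausted at MAF >= %.3f; "
           "polymorphic loci are vanishingly rare under these parameters",
           max_attempts, min_maf);
  }
  out.attr("attempts") = static_cast<double>(attempts_total);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sim_tmrca(NumericVector ev_time, IntegerVector ev_type,
                            IntegerVector ev_child, IntegerVector ev_pa,
                            IntegerVector ev_pb, NumericVector ev_frac,
                            NumericVector ev_size, NumericVector leaf_sizes,
                            IntegerVector n_ind, int reps) {
  RNGScope rng;
  const std::vector<Event> ev =
      unpack_events(ev_time, ev_type, ev_child, ev_pa, ev_pb, ev_frac, ev_size);
  std::vector<double> ls(leaf_sizes.begin(), leaf_sizes.end());
  std::vector<int> ni(n_ind.begin(), n_ind.end());
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    Tree tr = sim_tree(ev, ls, ni);
    out[r] = tr.time[2 * tr.n - 2];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_sim_tree(NumericVector ev_time, IntegerVector ev_type,
                  IntegerVector ev_child, IntegerVector ev_pa,
                  IntegerVector ev_pb, NumericVector ev_frac,
                  NumericVector ev_size, NumericVector leaf_sizes,
                  IntegerVector n_ind) {
  RNGScope rng;
  const std::vector<Event> ev =
      unpack_events(ev_time, ev_type, ev_child, ev_pa, ev_pb, ev_frac, ev_size);
  std::vector<double> ls(leaf_sizes.begin(), leaf_sizes.end());
  std::vector<int> ni(n_ind.begin(), n_ind.end());
  Tree tr = sim_tree(ev, ls, ni);
  return List::create(_["n_tips"] = tr.n,
                      _["parent"] = IntegerVector(tr.parent.begin(), tr.parent.end()),
                      _["child1"] = IntegerVector(tr.child1.begin(), tr.child1.end()),
                      _["child2"] = IntegerVector(tr.child2.begin(), tr.child2.end()),
                      _["node_time"] = NumericVector(tr.time.begin(), tr.time.end()));
}
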