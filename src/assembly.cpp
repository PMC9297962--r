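// Forward-time Moran birth/death/colonization/speciation engine for the
// local community. Species are integer indices into a growing species
// table; indices [0, S_M) are the metacommunity species, higher indices are
// species born in situ by point-mutation speciation. All randomness goes
// through R's RNG so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int sample_meta(const std::vector<double>& cum) {
  double u = unif_rand();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (u <= cum[mid]) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// [[Rcpp::export(name = ".assembly_run_cpp")]]
List assembly_run_cpp(IntegerVector demes_in,
                      LogicalVector founder_in,
                      NumericVector trait_in,
                      IntegerVector count_in,
                      IntegerVector origin_in,
                      IntegerVector parent_in,
                      IntegerVector first_col_in,
                      IntegerVector col_count_in,
                      IntegerVector spec_step_in,
                      List traj_in,
                      NumericVector meta_cumprob,
                      int model,          // 0 neutral, 1 filtering, 2 competition
                      double sE, double zE,
                      double m, double nu,
                      double sd_spec,     // sd of speciation trait jump
                      double lambda_target,
                      double max_steps,
                      double step_budget, // <0 : unlimited
                      int gen_steps,
                      double step_count_in,
                      int replaced_in,
                      LogicalVector founder_derived_in,
                      bool record_final) {
  const int J = demes_in.size();
  const double FLOOR = 1e-12;
  RNGScope scope;

  std::vector<int> demes(demes_in.begin(), demes_in.end()); // 0-based ids
  std::vector<char> founder(J);
  for (int i = 0; i < J; ++i) founder[i] = founder_in[i] ? 1 : 0;
  // founder_derived: deme ancestry still traces to the initial state
  // (local births inherit the parent deme's tag; immigration and
  // speciation erase it). Lambda = 1 - founder_derived fraction.
  std::vector<char> fdr(J);
  int n_fdr = 0;
  for (int i = 0; i < J; ++i) {
    fdr[i] = founder_derived_in[i] ? 1 : 0;
    n_fdr += fdr[i];
  }

  int nsp = trait_in.size();
  std::vector<double> trait(trait_in.begin(), trait_in.end());
  std::vector<int> count(count_in.begin(), count_in.end());
  std::vector<int> origin(origin_in.begin(), origin_in.end());
  std::vector<int> parent(parent_in.begin(), parent_in.end());
  std::vector<double> first_col(nsp), spec_step(nsp);
  for (int i = 0; i < nsp; ++i) first_col[i] = first_col_in[i];
  for (int i = 0; i < nsp; ++i) spec_step[i] = spec_step_in[i];
  std::vector<int> col_count(col_count_in.begin(), col_count_in.end());
  std::vector<std::vector<int> > traj(nsp);
  for (int i = 0; i < (int)traj_in.size(); ++i) {
    IntegerVector v = traj_in[i];
    traj[i].assign(v.begin(), v.end());
  }
  std::vector<double> cum(meta_cumprob.begin(), meta_cumprob.end());

  // per-species member deme lists + back-pointers
  std::vector<std::vector<int> > members(nsp);
  std::vector<int> pos(J);
  for (int d = 0; d < J; ++d) {
    members[demes[d]].push_back(d);
    pos[d] = (int)members[demes[d]].size() - 1;
  }
  // active species list
  std::vector<int> active;
  for (int s = 0; s < nsp; ++s) if (count[s] > 0) active.push_back(s);

  double sum_zc = 0.0;
  for (size_t a = 0; a < active.size(); ++a)
    sum_zc += trait[active[a]] * count[active[a]];

  double step = step_count_in;
  int replaced = replaced_in;
  double lam = 1.0 - (double)n_fdr / J;
  double used = 0.0;
  std::vector<double> wbuf;

  auto record_tick = [&](void) {
    for (size_t a = 0; a < active.size(); ++a) {
      int s = active[a];
      if (count[s] > 0) traj[s].push_back(count[s]);
    }
  };

  bool converged = (lam >= lambda_target);
  while (!converged) {
    if (step >= max_steps) break;
    if (step_budget >= 0 && used >= step_budget) break;

    // --- choose the individual that dies ---
    int dead;
    if (model == 0) {
      dead = (int)(unif_rand() * J);
      if (dead == J) dead = J - 1;
    } else {
      // compact active list occasionally
      size_t na = active.size();
      wbuf.resize(na);
      double tot = 0.0, zbar = sum_zc / J;
      for (size_t a = 0; a < na; ++a) {
        int s = active[a];
        if (count[s] <= 0) { wbuf[a] = 0.0; continue; }
        double z = trait[s], w;
        if (model == 1) {
          double dz = z - zE;
          w = 1.0 - std::exp(-(dz * dz) / sE);
        } else {
          double dz = z - zbar;
          w = std::exp(-(dz * dz) / sE);
        }
        if (w < FLOOR) w = FLOOR;
        wbuf[a] = w * count[s];
        tot += wbuf[a];
      }
      double u = unif_rand() * tot, acc = 0.0;
      int chosen = -1;
      for (size_t a = 0; a < na; ++a) {
        acc += wbuf[a];
        if (u <= acc) { chosen = active[a]; break; }
      }
      if (chosen < 0) { // numerical fallback
        for (size_t a = na; a-- > 0; )
          if (count[active[a]] > 0) { chosen = active[a]; break; }
      }
      int k = (int)(unif_rand() * members[chosen].size());
      if (k == (int)members[chosen].size()) k--;
      dead = members[chosen][k];
    }

    int sd_sp = demes[dead];
    // remove dead individual
    {
      std::vector<int>& mb = members[sd_sp];
      int k = pos[dead];
      int last = mb.back();
      mb[k] = last; pos[last] = k; mb.pop_back();
      count[sd_sp]--;
      sum_zc -= trait[sd_sp];
    }
    if (founder[dead]) { founder[dead] = 0; replaced++; }

    // --- choose the replacement's parent ---
    int par_sp;
    char new_tag;
    bool immigrant = (unif_rand() < m);
    if (immigrant) {
      par_sp = sample_meta(cum);
      new_tag = 0;
    } else {
      int e;
      do {
        e = (int)(unif_rand() * J);
        if (e == J) e = J - 1;
      } while (e == dead);
      par_sp = demes[e];
      new_tag = fdr[e];
    }

    int new_sp;
    if (nu > 0 && unif_rand() < nu) {
      // point-mutation speciation (fires on local and immigrant births);
      // the new species identity carries no information about the
      // initial state
      new_tag = 0;
      new_sp = nsp++;
      trait.push_back(trait[par_sp] + norm_rand() * sd_spec);
      count.push_back(0);
      origin.push_back(1);
      parent.push_back(par_sp);
      first_col.push_back(-1.0);
      spec_step.push_back(step);
      col_count.push_back(0);
      members.push_back(std::vector<int>());
      traj.push_back(std::vector<int>());
      active.push_back(new_sp);
    } else {
      new_sp = par_sp;
      if (immigrant) {
        col_count[new_sp]++;
        if (first_col[new_sp] < 0) first_col[new_sp] = step;
        if (count[new_sp] == 0) {
          // recolonization of a species currently absent: make sure it is
          // on the active list exactly once
          bool found = false;
          for (size_t a = 0; a < active.size(); ++a)
            if (active[a] == new_sp) { found = true; break; }
          if (!found) active.push_back(new_sp);
        }
      }
    }
    demes[dead] = new_sp;
    members[new_sp].push_back(dead);
    pos[dead] = (int)members[new_sp].size() - 1;
    count[new_sp]++;
    sum_zc += trait[new_sp];
    n_fdr += (int)new_tag - (int)fdr[dead];
    fdr[dead] = new_tag;

    step += 1.0;
    used += 1.0;

    // prune extinct species from the active list periodically
    if ((((long long)step) % 4096LL) == 0LL) {
      std::vector<int> keep;
      keep.reserve(active.size());
      for (size_t a = 0; a < active.size(); ++a)
        if (count[active[a]] > 0) keep.push_back(active[a]);
      active.swap(keep);
    }

    if ((((long long)step) % gen_steps) == 0LL) record_tick();

    lam = 1.0 - (double)n_fdr / J;
    if (lam >= lambda_target) converged = true;
  }

  if (record_final && converged &&
      (((long long)step) % gen_steps) != 0LL)
    record_tick();

  // package results
  List traj_out(nsp);
  for (int s = 0; s < nsp; ++s)
    traj_out[s] = IntegerVector(traj[s].begin(), traj[s].end());

  return List::create(
    _["demes"] = IntegerVector(demes.begin(), demes.end()),
    _["founder"] = LogicalVector(founder.begin(), founder.end()),
    _["trait"] = NumericVector(trait.begin(), trait.end()),
    _["count"] = IntegerVector(count.begin(), count.end()),
    _["origin"] = IntegerVector(origin.begin(), origin.end()),
    _["parent"] = IntegerVector(parent.begin(), parent.end()),
    _["first_col"] = NumericVector(first_col.begin(), first_col.end()),
    _["col_count"] = IntegerVector(col_count.begin(), col_count.end()),
    _["spec_step"] = NumericVector(spec_step.begin(), spec_step.end()),
    _["trajectories"] = traj_out,
    _["step_count"] = step,
    _["replaced"] = replaced,
    _["founder_derived"] = LogicalVector(fdr.begin(), fdr.end()),
    _["lambda"] = lam,
    _["converged"] = converged);
}
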