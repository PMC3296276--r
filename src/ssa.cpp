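#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact SSA (Gillespie direct method) with deterministic timed
// parameter events and piecewise-constant recording on a fixed grid.
//
// Propensities follow the combinatoric mass-action convention: for a
// reactant with copy number n and stoichiometry m the factor is
// n*(n-1)*...*(n-m+1)/m!; modifiers multiply the propensity by their
// copy number without being consumed.  The arithmetic (term order,
// division placement) is mirrored exactly by the pure-R reference
// stepper so that both engines produce bit-identical trajectories
// from the same RNG stream.

static double factorial_small(int m) {
  double f = 1.0;
  for (int j = 2; j <= m; ++j) f *= j;
  return f;
}

struct Term { int species; int count; };  // stoich or modifier order

static double reaction_propensity(const std::vector<Term>& reactants,
                                  const std::vector<Term>& modifiers,
                                  double k,
                                  const std::vector<double>& x) {
  double a = k;
  for (const Term& t : reactants) {
    double n = x[t.species];
    if (n < t.count) return 0.0;
    for (int j = 0; j < t.count; ++j) a *= (n - j);
    a /= factorial_small(t.count);
  }
  for (const Term& t : modifiers) {
    for (int j = 0; j < t.count; ++j) a *= x[t.species];
  }
  return a > 0.0 ? a : 0.0;
}

// [[Rcpp::export(name = ".ssa_simulate_cpp")]]
List ssa_simulate_cpp(IntegerMatrix reactant_stoich,
                      IntegerMatrix product_stoich,
                      IntegerMatrix modifier_stoich,
                      IntegerVector rate_idx,
                      NumericVector params,
                      NumericVector init_counts,
                      NumericVector event_time,
                      IntegerVector event_par,
                      IntegerVector event_action,  // 0 set, 1 multiply
                      NumericVector event_operand,
                      double horizon,
                      NumericVector grid,
                      IntegerVector fp_species) {
  const int nr = reactant_stoich.nrow();
  const int ns = reactant_stoich.ncol();
  const int ng = grid.size();
  const int nev = event_time.size();

  std::vector<std::vector<Term> > reac(nr), prod(nr), mods(nr);
  for (int r = 0; r < nr; ++r) {
    for (int s = 0; s < ns; ++s) {
      if (reactant_stoich(r, s) > 0)
        reac[r].push_back({s, reactant_stoich(r, s)});
      if (product_stoich(r, s) > 0)
        prod[r].push_back({s, product_stoich(r, s)});
      if (modifier_stoich(r, s) > 0)
        mods[r].push_back({s, modifier_stoich(r, s)});
    }
  }
  // dependency graph: reactions whose propensity involves a species
  std::vector<std::vector<int> > dependents(ns);
  for (int r = 0; r < nr; ++r) {
    for (const Term& t : reac[r]) dependents[t.species].push_back(r);
    for (const Term& t : mods[r]) dependents[t.species].push_back(r);
  }

  std::vector<double> x(init_counts.begin(), init_counts.end());
  std::vector<double> p(params.begin(), params.end());
  std::vector<double> a(nr);
  for (int r = 0; r < nr; ++r)
    a[r] = reaction_propensity(reac[r], mods[r], p[rate_idx[r]], x);

  NumericMatrix rec(ns, ng);
  NumericVector fp(fp_species.size(), NA_REAL);
  for (int i = 0; i < fp_species.size(); ++i)
    if (x[fp_species[i]] >= 1.0) fp[i] = 0.0;

  double t = 0.0;
  int gi = 0, ev = 0;
  long long steps = 0;
  const long long max_steps = 500000000LL;

  auto record_until = [&](double tnew) {
    while (gi < ng && grid[gi] < tnew) {
      for (int s = 0; s < ns; ++s) rec(s, gi) = x[s];
      ++gi;
    }
  };
  auto apply_event = [&](int e) {
    if (event_action[e] == 0) p[event_par[e]] = event_operand[e];
    else p[event_par[e]] *= event_operand[e];
    for (int r = 0; r < nr; ++r)
      a[r] = reaction_propensity(reac[r], mods[r], p[rate_idx[r]], x);
  };

  while (t < horizon) {
    double a0 = 0.0;
    for (int r = 0; r < nr; ++r) a0 += a[r];
    double tev = (ev < nev) ? event_time[ev] : R_PosInf;

    if (tev <= t) { apply_event(ev); ++ev; continue; }

    if (a0 <= 0.0) {
      if (tev <= horizon) {
        record_until(tev);
        t = tev;
        apply_event(ev); ++ev;
        continue;
      }
      break;  // nothing can happen before the horizon
    }

    double u1 = unif_rand();
    double tau = -std::log(u1) / a0;
    double tcand = t + tau;

    if (tcand >= tev && tev <= horizon) {
      // the drawn waiting time is discarded (memorylessness); the
      // event interrupts and no reaction fires in between
      record_until(tev);
      t = tev;
      apply_event(ev); ++ev;
      continue;
    }
    if (tcand > horizon) break;

    double u2 = unif_rand();
    double target = u2 * a0;
    double cum = 0.0;
    int j = nr - 1;
    for (int r = 0; r < nr; ++r) {
      cum += a[r];
      if (target < cum) { j = r; break; }
    }

    record_until(tcand);
    t = tcand;
    for (const Term& tm : reac[j]) x[tm.species] -= tm.count;
    for (const Term& tm : prod[j]) x[tm.species] += tm.count;
    for (int i = 0; i < fp_species.size(); ++i)
      if (NumericVector::is_na(fp[i]) && x[fp_species[i]] >= 1.0)
        fp[i] = t;
    for (const Term& tm : reac[j])
      for (int r : dependents[tm.species])
        a[r] = reaction_propensity(reac[r], mods[r], p[rate_idx[r]], x);
    for (const Term& tm : prod[j])
      for (int r : dependents[tm.species])
        a[r] = reaction_propensity(reac[r], mods[r], p[rate_idx[r]], x);

    if (++steps > max_steps)
      stop("SSA exceeded %lld reaction events before the horizon; "
           "propensities appear to diverge", max_steps);
  }

  // remaining events at/inside the horizon but after the last
  // reaction (only reachable when all propensities are zero): apply
  // so final parameter values are faithful
  while (ev < nev && event_time[ev] <= horizon) {
    record_until(event_time[ev]);
    apply_event(ev); ++ev;
  }
  while (gi < ng) {
    for (int s = 0; s < ns; ++s) rec(s, gi) = x[s];
    ++gi;
  }

  return List::create(_["counts"] = rec,
                      _["first_passage"] = fp,
                      _["final_params"] = NumericVector(p.begin(), p.end()),
                      _["final_counts"] = NumericVector(x.begin(), x.end()),
                      _["n_steps"] = (double)steps);
}
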