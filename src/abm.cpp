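// Compiled core of the agent-based simulator.
//
// One iteration = stage-1 contributions, stage-2 random dyadic helping,
// then a single Moran event (mutation with prob mu, else global
// fitness-proportional imitation on e^payoff). Uses R's RNG so runs are
// reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// strategy definition codes (see R/strategies.R)
// contribution: 0 none, 1 club, 2 public
// help_target : 0 none, 1 universal, 2 parochial_ingroup, 3 any_cooperator

static inline int runif_int(int m) {
  // uniform integer in [0, m), robust against the 1.0 edge case
  int v = (int)(unif_rand() * m);
  return v >= m ? m - 1 : v;
}

static inline bool helps(int target, int conditional, int r_contrib,
                         bool same_group, int r_helped_last,
                         bool benefit_of_doubt) {
  bool fires;
  switch (target) {
  case 1: fires = (r_contrib == 2); break;
  case 2: fires = (r_contrib == 1) && same_group; break;
  case 3: fires = (r_contrib != 0); break;
  default: return false;
  }
  if (!fires) return false;
  if (conditional) {
    if (r_helped_last < 0) return benefit_of_doubt;  // unknown history
    return r_helped_last == 1;
  }
  return true;
}

// [[Rcpp::export]]
List abm_run_cpp(IntegerVector group0, IntegerVector strat0,
                 IntegerMatrix sdef,
                 double e, double cc, double ch, double bcg, double bpg,
                 double bh, double p, double mu,
                 int max_iter, bool stop_at_homogeneous,
                 bool benefit_of_doubt, bool neutral_fitness,
                 int fitness_mode,  // 0 realized payoffs, 1 expected (core space)
                 int record_every) {
  const int N = group0.size();
  const int S = sdef.nrow();
  int k = 0;
  for (int a = 0; a < N; ++a) k = std::max(k, group0[a] + 1);

  std::vector<int> strat(strat0.begin(), strat0.end());
  std::vector<int> gsize(k, 0), goffset(k + 1, 0);
  for (int a = 0; a < N; ++a) gsize[group0[a]]++;
  for (int g = 0; g < k; ++g) goffset[g + 1] = goffset[g] + gsize[g];
  // agents ordered by group, and each agent's position within its group
  std::vector<int> ordered(N), pos_in_group(N), fill(k, 0);
  for (int a = 0; a < N; ++a) {
    int g = group0[a];
    pos_in_group[a] = fill[g];
    ordered[goffset[g] + fill[g]++] = a;
  }

  std::vector<int> scount(S, 0);
  for (int a = 0; a < N; ++a) scount[strat[a]]++;

  std::vector<int> helped_prev(N, -1), helped_now(N, 0);
  std::vector<double> pay(N), epay;
  std::vector<int> clubtot(k, 0);
  std::vector<std::vector<int>> gs_count;  // per-group strategy counts (expected mode)
  if (fitness_mode == 1) {
    gs_count.assign(k, std::vector<int>(S, 0));
    for (int a = 0; a < N; ++a) gs_count[group0[a]][strat[a]]++;
  }

  int n_rec = max_iter / record_every + 2;
  IntegerMatrix trace(n_rec, S);
  IntegerVector trace_iter(n_rec);
  int rec = 0;
  for (int s = 0; s < S; ++s) trace(rec, s) = scount[s];
  trace_iter[rec++] = 0;

  bool converged = false;
  int iter = 0;

  if (stop_at_homogeneous) {
    for (int s = 0; s < S; ++s) if (scount[s] == N) { converged = true; break; }
  }
  int start_iter = converged ? max_iter + 1 : 1;  // skip loop if homogeneous at start

  for (iter = start_iter; iter <= max_iter; ++iter) {
    // --- stage 1 ---
    int pubtot = 0;
    std::fill(clubtot.begin(), clubtot.end(), 0);
    for (int a = 0; a < N; ++a) {
      int c = sdef(strat[a], 0);
      if (c == 2) pubtot++;
      else if (c == 1) clubtot[group0[a]]++;
    }
    double pub_share = pubtot * bpg / N;
    for (int a = 0; a < N; ++a) {
      int c = sdef(strat[a], 0);
      int g = group0[a];
      pay[a] = e - (c != 0 ? cc : 0.0) + pub_share + clubtot[g] * bcg / gsize[g]
             + e;  // stage-2 endowment
    }

    // --- stage 2: pairing and helping ---
    // helped_prev holds each agent's standing from the previous round:
    // -1 unknown, 1 good, 0 bad (withheld help from a contributor in good
    // standing). Unconditional rules ignore it.
    for (int a = 0; a < N; ++a) {
      int g = group0[a];
      int r;
      if (unif_rand() < p) {
        int j = runif_int(gsize[g] - 1);
        if (j >= pos_in_group[a]) j++;
        r = ordered[goffset[g] + j];
      } else {
        int j = runif_int(N - gsize[g]);
        if (j >= goffset[g]) j += gsize[g];
        r = ordered[j];
      }
      int s = strat[a];
      bool h = helps(sdef(s, 1), sdef(s, 2), sdef(strat[r], 0),
                     group0[r] == g, helped_prev[r], benefit_of_doubt);
      if (h) {
        pay[a] -= ch;
        pay[r] += bh;
      }
      // standing for next round: helping always earns good standing;
      // withholding is justified iff the receiver contributed nothing in
      // stage 1 or was itself in bad standing
      bool justified = (sdef(strat[r], 0) == 0) || (helped_prev[r] == 0);
      helped_now[a] = (h || justified) ? 1 : 0;
    }

    // --- Moran event ---
    int dying = runif_int(N);
    int newstrat;
    if (unif_rand() < mu) {
      newstrat = runif_int(S);
    } else if (neutral_fitness) {
      newstrat = strat[runif_int(N)];
    } else {
      const std::vector<double>* w_pay = &pay;
      if (fitness_mode == 1) {
        // expected payoffs of the core U/P/F types (k arbitrary; out-group
        // partner uniform over all out-group members)
        epay.assign(N, 0.0);
        int nU = 0;
        for (int g = 0; g < k; ++g) nU += gs_count[g][0];
        for (int a = 0; a < N; ++a) {
          int g = group0[a], n_i = gsize[g];
          int nUi = gs_count[g][0], nPi = gs_count[g][1];
          double common = 2 * e + nU * bpg / N + nPi * bcg / (double)n_i;
          double net = bh - ch;
          int s = strat[a];
          if (s == 0) {
            double meet = 0.0;
            if (n_i > 1) meet += p * (nUi - 1) / (double)(n_i - 1);
            if (N - n_i > 0) meet += (1 - p) * (nU - nUi) / (double)(N - n_i);
            epay[a] = common - cc + meet * net;
          } else if (s == 1) {
            double meet = (n_i > 1) ? p * (nPi - 1) / (double)(n_i - 1) : 0.0;
            epay[a] = common - cc + meet * net;
          } else {
            epay[a] = common;
          }
        }
        w_pay = &epay;
      }
      double mx = (*w_pay)[0];
      for (int a = 1; a < N; ++a) mx = std::max(mx, (*w_pay)[a]);
      double tot = 0.0;
      std::vector<double> cum(N);
      for (int a = 0; a < N; ++a) {
        tot += std::exp((*w_pay)[a] - mx);
        cum[a] = tot;
      }
      double u = unif_rand() * tot;
      int lo = 0, hi = N - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cum[mid] < u) lo = mid + 1; else hi = mid;
      }
      newstrat = strat[lo];
    }
    int old = strat[dying];
    if (newstrat != old) {
      strat[dying] = newstrat;
      scount[old]--; scount[newstrat]++;
      if (fitness_mode == 1) {
        gs_count[group0[dying]][old]--;
        gs_count[group0[dying]][newstrat]++;
      }
    }
    std::swap(helped_prev, helped_now);

    if (iter % record_every == 0) {
      for (int s = 0; s < S; ++s) trace(rec, s) = scount[s];
      trace_iter[rec++] = iter;
    }

    if (stop_at_homogeneous) {
      bool homog = false;
      for (int s = 0; s < S; ++s) if (scount[s] == N) { homog = true; break; }
      if (homog) { converged = true; break; }
    }
  }
  if (start_iter > max_iter) iter = converged ? 0 : max_iter;
  else if (iter > max_iter) iter = max_iter;
  if (trace_iter[rec - 1] != iter) {  // ensure the final state is recorded
    for (int s = 0; s < S; ++s) trace(rec, s) = scount[s];
    trace_iter[rec++] = iter;
  }

  IntegerMatrix trace_out(rec, S);
  IntegerVector iters_out(rec);
  for (int r = 0; r < rec; ++r) {
    iters_out[r] = trace_iter[r];
    for (int s = 0; s < S; ++s) trace_out(r, s) = trace(r, s);
  }
  return List::create(_["trace"] = trace_out,
                      _["trace_iter"] = iters_out,
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["final_strat"] = IntegerVector(strat.begin(), strat.end()),
                      _["final_payoffs"] = NumericVector(pay.begin(), pay.end()));
}
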