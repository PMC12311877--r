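#include <Rcpp.h>
using namespace Rcpp;

// Reputation-dynamics engine.  Mirrors the round-level R reference
// implementation draw for draw (same uniform stream, same order):
//   1. partial Fisher-Yates group sampling (k draws);
//   2. deterministic actions;
//   3. one Bernoulli(q) observation draw per out-of-group, non-pinned player
//      in ascending index order;
//   4. donors in sampled order, observers in ascending order, one
//      Bernoulli(eps) misperception draw per (observer, donor) pair subject
//      to error.  eps_scope selects who can err: 0 = out-group observers
//      only, 1 = everyone but the donor itself, 2 = every observer
//      including the donor's own self-assessment.
// Synchronicity: all assessments of a round read the pre-round matrix; the
// cached row sums over the group plus the not-yet-written entry M(h,i)
// provide the pre-round values, so updates can be applied in place (each
// entry (h, i) is written at most once per round).
//
// cls is 0-based; fixed: 0 = norm, 1 = ALLC (row pinned good), 2 = ALLD
// (row pinned bad).  Pinned rows never update and consume no draws.

// [[Rcpp::export]]
List sim_engine_cpp(IntegerMatrix M0, IntegerMatrix A, IntegerMatrix B,
                    NumericVector lambda, IntegerVector fixed,
                    IntegerVector cls, int n_cls, int k, int steps,
                    int burn_in_steps, double q, double eps, int eps_scope) {
  const int N = M0.nrow();
  IntegerMatrix M = clone(M0);
  std::vector<int> pool(N), group(k), acts(k), in_group(N), observer(N),
      rowsum(N);
  std::vector<double> games(n_cls, 0.0), coop(n_cls, 0.0), ncsum(n_cls, 0.0);
  NumericMatrix good_sum(n_cls, n_cls);
  NumericMatrix cur(n_cls, n_cls);  // running off-diagonal good counts
  for (int j = 0; j < N; ++j)
    for (int h = 0; h < N; ++h)
      if (h != j && M(h, j)) cur(cls[h], cls[j]) += 1.0;

  RNGScope scope;
  for (int t = 1; t <= steps; ++t) {
    // 1. sample group
    for (int j = 0; j < N; ++j) pool[j] = j;
    for (int j = 0; j < k; ++j) {
      int r = j + (int)std::floor(unif_rand() * (N - j));
      if (r > N - 1) r = N - 1;
      std::swap(pool[j], pool[r]);
      group[j] = pool[j];
    }
    std::fill(in_group.begin(), in_group.end(), 0);
    for (int j = 0; j < k; ++j) in_group[group[j]] = 1;

    // cached pre-round row sums over the group
    for (int h = 0; h < N; ++h) {
      int s = 0;
      for (int j = 0; j < k; ++j) s += M(h, group[j]);
      rowsum[h] = s;
    }

    // 2. actions
    int nC = 0;
    for (int j = 0; j < k; ++j) {
      int i = group[j], a;
      if (fixed[i] == 1) a = 1;
      else if (fixed[i] == 2) a = 0;
      else {
        int ra = M(i, i);
        int rp = ((double)(rowsum[i] - M(i, i)) >= lambda[i] * (k - 1)) ? 1 : 0;
        a = B(i, ra * 2 + rp);
      }
      acts[j] = a;
      nC += a;
    }

    // 3. observers
    for (int h = 0; h < N; ++h) {
      if (fixed[h] != 0) { observer[h] = 0; continue; }
      if (in_group[h])   { observer[h] = 1; continue; }
      observer[h] = (unif_rand() < q) ? 1 : 0;
    }

    // 4. synchronous updates
    for (int j = 0; j < k; ++j) {
      int i = group[j];
      for (int h = 0; h < N; ++h) {
        if (!observer[h]) continue;
        int perceived = acts[j];
        bool can_err = (eps_scope == 2) ||
                       (eps_scope == 1 && h != i) ||
                       (eps_scope == 0 && !in_group[h]);
        if (can_err && unif_rand() < eps) perceived = 1 - perceived;
        int old = M(h, i);
        int rp = ((double)(rowsum[h] - old) >= lambda[h] * (k - 1)) ? 1 : 0;
        int neu = A(h, old * 4 + rp * 2 + perceived);
        if (neu != old) {
          M(h, i) = neu;
          if (h != i) cur(cls[h], cls[i]) += neu - old;
        }
      }
    }

    // 5. accumulate after burn-in (post-round matrix)
    if (t > burn_in_steps) {
      for (int j = 0; j < k; ++j) {
        int c0 = cls[group[j]];
        games[c0] += 1.0;
        coop[c0] += acts[j];
        ncsum[c0] += nC;
      }
      for (int b = 0; b < n_cls; ++b)
        for (int a = 0; a < n_cls; ++a) good_sum(a, b) += cur(a, b);
    }
  }

  return List::create(_["M"] = M, _["games"] = NumericVector(games.begin(), games.end()),
                      _["coop"] = NumericVector(coop.begin(), coop.end()),
                      _["ncsum"] = NumericVector(ncsum.begin(), ncsum.end()),
                      _["good_sum"] = good_sum,
                      _["acc_steps"] = steps - burn_in_steps);
}
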