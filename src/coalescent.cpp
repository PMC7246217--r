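#include <Rcpp.h>
using namespace Rcpp;

// Two-population structured-coalescent branch-length JSFS.
//
// Simulates genealogies of n1 + n2 sampled lineages under a two-deme
// coalescent with an ancestral split at time ts (time in units of 2*Nref
// generations, measured backwards from the present) and per-lineage
// backward migration rates m12 (deme 1 -> deme 2) and m21 active only on
// the interval [mig_start, mig_end]. Relative deme sizes n_1, n_2 scale
// the pair coalescence rate 1/N_d; the ancestral deme has size n_anc.
// For every interval between events each lineage contributes the interval
// length to the JSFS cell indexed by its numbers of sampled descendants
// in population 1 and 2; the accumulated table, divided by the number of
// replicates, is the expected branch length t_{i,j}, proportional to the
// expected unfolded JSFS per unit mutation rate.
//
// Uses R's RNG so set.seed() in R makes runs bit-reproducible.
// [[Rcpp::export]]
NumericMatrix coal_jsfs_cpp(int n1, int n2, double N1, double N2,
                            double m12, double m21,
                            double ts, double mig_start, double mig_end,
                            double n_anc, int nreps) {
  NumericMatrix T(n1 + 1, n2 + 1);
  int ntot = n1 + n2;
  std::vector<int> d1(ntot), d2(ntot), deme(ntot);

  for (int rep = 0; rep < nreps; ++rep) {
    int k = ntot;
    for (int i = 0; i < n1; ++i) { d1[i] = 1; d2[i] = 0; deme[i] = 0; }
    for (int i = n1; i < ntot; ++i) { d1[i] = 0; d2[i] = 1; deme[i] = 1; }
    double t = 0.0;

    while (k > 1) {
      bool split_done = t >= ts;
      bool mig_on = !split_done && t >= mig_start && t < mig_end;
      int k1 = 0;
      for (int i = 0; i < k; ++i) if (deme[i] == 0) ++k1;
      int k2 = k - k1;

      double rc1, rc2, rm1, rm2;
      if (split_done) {
        rc1 = k * (k - 1) / 2.0 / n_anc;
        rc2 = 0.0; rm1 = 0.0; rm2 = 0.0;
      } else {
        rc1 = k1 * (k1 - 1) / 2.0 / N1;
        rc2 = k2 * (k2 - 1) / 2.0 / N2;
        rm1 = mig_on ? k1 * m12 : 0.0;
        rm2 = mig_on ? k2 * m21 : 0.0;
      }
      double rate = rc1 + rc2 + rm1 + rm2;

      // next piecewise-constant-rate boundary
      double boundary = R_PosInf;
      if (!split_done) {
        boundary = ts;
        if (t < mig_start && mig_start < boundary) boundary = mig_start;
        if (t >= mig_start && t < mig_end && mig_end < boundary) boundary = mig_end;
      }

      double dt = (rate > 0.0) ? R::rexp(1.0 / rate) : R_PosInf;
      if (t + dt >= boundary) {
        // rates change at the boundary: accumulate up to it, no event
        double step = boundary - t;
        if (!R_FINITE(step)) Rcpp::stop("coalescent simulation stalled");
        for (int i = 0; i < k; ++i) T(d1[i], d2[i]) += step;
        t = boundary;
        continue;
      }
      for (int i = 0; i < k; ++i) T(d1[i], d2[i]) += dt;
      t += dt;

      // event happened at time t
      double u = unif_rand() * rate;
      if (u < rc1) {
        // coalescence in deme 0 (or ancestral deme)
        int target = split_done ? -1 : 0;
        int a = -1, b = -1;
        int kk = 0;
        for (int i = 0; i < k; ++i) if (split_done || deme[i] == target) ++kk;
        int ia = (int)(unif_rand() * kk);
        int ib = (int)(unif_rand() * (kk - 1));
        if (ib >= ia) ++ib;
        int idx = 0;
        for (int i = 0; i < k; ++i) {
          if (split_done || deme[i] == target) {
            if (idx == ia) a = i;
            if (idx == ib) b = i;
            ++idx;
          }
        }
        d1[a] += d1[b]; d2[a] += d2[b];
        d1[b] = d1[k - 1]; d2[b] = d2[k - 1]; deme[b] = deme[k - 1];
        --k;
      } else if (u < rc1 + rc2) {
        // coalescence in deme 1
        int kk = 0;
        for (int i = 0; i < k; ++i) if (deme[i] == 1) ++kk;
        int ia = (int)(unif_rand() * kk);
        int ib = (int)(unif_rand() * (kk - 1));
        if (ib >= ia) ++ib;
        int a = -1, b = -1, idx = 0;
        for (int i = 0; i < k; ++i) {
          if (deme[i] == 1) {
            if (idx == ia) a = i;
            if (idx == ib) b = i;
            ++idx;
          }
        }
        d1[a] += d1[b]; d2[a] += d2[b];
        d1[b] = d1[k - 1]; d2[b] = d2[k - 1]; deme[b] = deme[k - 1];
        --k;
      } else if (u < rc1 + rc2 + rm1) {
        // migration of a deme-0 lineage to deme 1
        int kk = 0;
        for (int i = 0; i < k; ++i) if (deme[i] == 0) ++kk;
        int ia = (int)(unif_rand() * kk);
        int idx = 0;
        for (int i = 0; i < k; ++i) {
          if (deme[i] == 0) { if (idx == ia) { deme[i] = 1; break; } ++idx; }
        }
      } else {
        // migration of a deme-1 lineage to deme 0
        int kk = 0;
        for (int i = 0; i < k; ++i) if (deme[i] == 1) ++kk;
        int ia = (int)(unif_rand() * kk);
        int idx = 0;
        for (int i = 0; i < k; ++i) {
          if (deme[i] == 1) { if (idx == ia) { deme[i] = 0; break; } ++idx; }
        }
      }
    }
  }
  for (int i = 0; i <= n1; ++i)
    for (int j = 0; j <= n2; ++j)
      T(i, j) /= nreps;
  // the root lineage spans the whole sample; its cell is not a segregating
  // configuration and is cleared here
  T(n1, n2) = 0.0;
  return T;
}
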