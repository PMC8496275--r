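// Hudson-style backward-in-time coalescent with recombination and
// piecewise-exponential demography, infinite-sites mutation.
//
// Conventions: time in units of 2N0 generations; a lineage pair coalesces
// at rate 1/lambda(t) where lambda(t) is the relative population size;
// recombination at rate (R/2) per unit span of breakable material per
// lineage; mutations arise at rate (theta/2) per unit of ancestral
// material per unit time. Under equilibrium this gives E[S] = theta * a_n
// and E[pi] = theta for the whole locus.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

struct Seg {
  double l, r;                 // half-open interval on [0,1)
  std::vector<char> desc;      // which samples descend from this material
  int cnt;
};

typedef std::vector<Seg> Lineage;

static double segLen(const Lineage& lin) {
  double s = 0.0;
  for (const Seg& g : lin) s += g.r - g.l;
  return s;
}

static void spanOf(const Lineage& lin, double& lo, double& hi) {
  lo = lin.front().l;
  hi = lin.back().r;
}

// waiting time to next coalescence from t0 with k lineages under the
// piecewise-exponential size history; returns +Inf only if the history is
// degenerate (validated upstream to guarantee eventual coalescence).
static double coalTime(double t0, int k,
                       const std::vector<double>& estart,
                       const std::vector<double>& esize,
                       const std::vector<double>& egrow) {
  const double C = 0.5 * k * (k - 1);
  double E = R::exp_rand();      // target integrated hazard
  double t = t0;
  size_t j = 0;
  while (j + 1 < estart.size() && estart[j + 1] <= t) ++j;
  for (;; ++j) {
    double tend = (j + 1 < estart.size()) ? estart[j + 1] : R_PosInf;
    double s = esize[j], g = egrow[j], tj = estart[j];
    if (g == 0.0) {
      double need = E * s / C;
      if (t + need <= tend) return t + need;
      E -= C / s * (tend - t);
      t = tend;
    } else {
      // hazard = (C/s) exp(g (u - tj)); integrate from t to x
      double base = std::exp(g * (t - tj));
      double rhs = base + E * s * g / C;
      if (rhs > 0.0) {
        double x = tj + std::log(rhs) / g;
        if (x <= tend) return x;
      }
      if (!std::isfinite(tend)) return R_PosInf;
      double Hend = C / (s * g) *
        (std::exp(g * (tend - tj)) - base);
      E -= Hend;
      t = tend;
    }
  }
}

// [[Rcpp::export]]
List sim_arg(int n, double theta, double rho,
             NumericVector epochStart, NumericVector epochSize,
             NumericVector epochGrowth) {
  std::vector<double> estart(epochStart.begin(), epochStart.end());
  std::vector<double> esize(epochSize.begin(), epochSize.end());
  std::vector<double> egrow(epochGrowth.begin(), epochGrowth.end());

  std::vector<Lineage> lin(n);
  for (int i = 0; i < n; ++i) {
    Seg g; g.l = 0.0; g.r = 1.0;
    g.desc.assign(n, 0); g.desc[i] = 1; g.cnt = 1;
    lin[i] = Lineage(1, g);
  }

  std::vector<double> mutPos;
  std::vector< std::vector<char> > mutCarrier;
  double t = 0.0;

  while (lin.size() >= 2) {
    int k = (int)lin.size();
    double recTot = 0.0, mat = 0.0;
    std::vector<double> spans(k);
    for (int i = 0; i < k; ++i) {
      double lo, hi;
      spanOf(lin[i], lo, hi);
      spans[i] = hi - lo;
      recTot += spans[i];
      mat += segLen(lin[i]);
    }
    double recRate = 0.5 * rho * recTot;
    double tRec = (recRate > 0.0) ? R::exp_rand() / recRate : R_PosInf;
    double tCoal = coalTime(t, k, estart, esize, egrow) - t;
    double dt = std::min(tRec, tCoal);
    if (!std::isfinite(dt)) stop("demography never coalesces");

    // mutations during (t, t + dt) on current lineages
    int nm = (int)R::rpois(0.5 * theta * dt * mat);
    for (int m = 0; m < nm; ++m) {
      double u = unif_rand() * mat;
      for (int i = 0; i < k && u >= 0; ++i) {
        for (const Seg& g : lin[i]) {
          double len = g.r - g.l;
          if (u < len) {
            mutPos.push_back(g.l + u);
            mutCarrier.push_back(g.desc);
            u = -1.0; break;
          }
          u -= len;
        }
        if (u < 0) break;
      }
    }
    t += dt;

    if (tRec < tCoal) {
      // recombination: pick lineage weighted by breakable span
      double u = unif_rand() * recTot;
      int pick = 0;
      for (int i = 0; i < k; ++i) {
        if (u < spans[i]) { pick = i; break; }
        u -= spans[i];
      }
      double lo, hi;
      spanOf(lin[pick], lo, hi);
      double bp = lo + unif_rand() * (hi - lo);
      Lineage left, right;
      for (const Seg& g : lin[pick]) {
        if (g.r <= bp) left.push_back(g);
        else if (g.l >= bp) right.push_back(g);
        else {
          Seg a = g, b = g;
          a.r = bp; b.l = bp;
          left.push_back(a); right.push_back(b);
        }
      }
      if (left.empty() || right.empty()) continue;  // breakpoint in a gap edge
      lin[pick] = left;
      lin.push_back(right);
    } else {
      // coalescence of a uniform pair
      int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j >= i) ++j;
      if (j == k) j = k - 1;
      const Lineage& A = lin[i];
      const Lineage& B = lin[j];
      // sweep over elementary intervals
      std::vector<double> bps;
      for (const Seg& g : A) { bps.push_back(g.l); bps.push_back(g.r); }
      for (const Seg& g : B) { bps.push_back(g.l); bps.push_back(g.r); }
      std::sort(bps.begin(), bps.end());
      bps.erase(std::unique(bps.begin(), bps.end()), bps.end());
      Lineage merged;
      for (size_t b = 0; b + 1 < bps.size(); ++b) {
        double x1 = bps[b], x2 = bps[b + 1];
        const Seg* sa = 0;
        const Seg* sb = 0;
        for (const Seg& g : A)
          if (g.l <= x1 && g.r >= x2) { sa = &g; break; }
        for (const Seg& g : B)
          if (g.l <= x1 && g.r >= x2) { sb = &g; break; }
        if (!sa && !sb) continue;
        Seg out;
        out.l = x1; out.r = x2;
        if (sa && sb) {
          out.desc.assign(n, 0);
          out.cnt = 0;
          for (int q = 0; q < n; ++q) {
            out.desc[q] = (sa->desc[q] || sb->desc[q]) ? 1 : 0;
            out.cnt += out.desc[q];
          }
          if (out.cnt == n) continue;   // reached its MRCA: stop tracking
        } else if (sa) {
          out.desc = sa->desc; out.cnt = sa->cnt;
        } else {
          out.desc = sb->desc; out.cnt = sb->cnt;
        }
        // merge with previous interval when identical descendant set
        if (!merged.empty() && merged.back().r == out.l &&
            merged.back().desc == out.desc) {
          merged.back().r = out.r;
        } else {
          merged.push_back(out);
        }
      }
      int hi2 = std::max(i, j), lo2 = std::min(i, j);
      lin.erase(lin.begin() + hi2);
      lin.erase(lin.begin() + lo2);
      if (!merged.empty()) lin.push_back(merged);
    }
  }

  // order sites by position
  int S = (int)mutPos.size();
  std::vector<int> ord(S);
  for (int i = 0; i < S; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return mutPos[a] < mutPos[b]; });
  NumericVector pos(S);
  IntegerMatrix geno(n, S);
  for (int s = 0; s < S; ++s) {
    pos[s] = mutPos[ord[s]];
    for (int q = 0; q < n; ++q) geno(q, s) = mutCarrier[ord[s]][q];
  }
  return List::create(_["positions"] = pos, _["genotypes"] = geno);
}
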