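// Monte Carlo kernels for the genetic-code cost landscape.
//
// All kernels operate on a "cost context": an integer-coded genetic code over
// nPos free (sense) positions and nAA symbols, a symmetric per-symbol penalty
// matrix d, and a sparse single-error neighbour structure with misreading
// weights. The cost of a code is the weight-normalised mean penalty over all
// ordered neighbouring sense-sense codon pairs,
//     cost(a) = sum_{c,c'} w(c,c') d(a(c), a(c')) / sum_{c,c'} w(c,c'),
// and single-symbol flips admit an O(K) incremental update (K = neighbours
// per position), which is what makes 1e8-step chains affordable.
//
// Randomness comes exclusively from R's generator (unif_rand under RNGScope)
// so set.seed() in R makes every kernel bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Ctx {
  int nPos, nAA, K;
  std::vector<double> d;      // nAA x nAA, column-major
  std::vector<int> nbr;       // nPos x K, column-per-position, -1 padded
  std::vector<double> nbw;    // parallel weights
  std::vector<int> minCount;  // per-symbol minimum multiplicity
  double Wtot;                // sum of all ordered-pair weights
};

Ctx buildCtx(const List& ctxL) {
  Ctx c;
  c.nPos = as<int>(ctxL["nPos"]);
  c.nAA = as<int>(ctxL["nAA"]);
  NumericMatrix d = ctxL["d"];
  IntegerMatrix nbr = ctxL["nbr"];
  NumericMatrix nbw = ctxL["nbw"];
  IntegerVector mc = ctxL["minCount"];
  c.K = nbr.nrow();
  c.d.assign(d.begin(), d.end());
  c.nbr.assign(nbr.begin(), nbr.end());
  c.nbw.assign(nbw.begin(), nbw.end());
  c.minCount.assign(mc.begin(), mc.end());
  c.Wtot = as<double>(ctxL["Wtot"]);
  if ((int)c.d.size() != c.nAA * c.nAA) stop("penalty matrix shape mismatch");
  if ((int)c.nbr.size() != c.nPos * c.K) stop("neighbour table shape mismatch");
  return c;
}

inline int randInt(int n) {  // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

inline double fullCost(const Ctx& c, const int* a) {
  double s = 0.0;
  for (int p = 0; p < c.nPos; ++p) {
    const int* nb = &c.nbr[(size_t)p * c.K];
    const double* wv = &c.nbw[(size_t)p * c.K];
    const double* drow = &c.d[(size_t)a[p] * c.nAA];
    for (int k = 0; k < c.K; ++k) {
      if (nb[k] < 0) break;
      s += wv[k] * drow[a[nb[k]]];
    }
  }
  return s / c.Wtot;
}

// cost change for a[pos] -> anew; factor 2 covers both pair orientations
inline double deltaCost(const Ctx& c, const int* a, int pos, int anew) {
  int aold = a[pos];
  const int* nb = &c.nbr[(size_t)pos * c.K];
  const double* wv = &c.nbw[(size_t)pos * c.K];
  const double* dn = &c.d[(size_t)anew * c.nAA];
  const double* doldr = &c.d[(size_t)aold * c.nAA];
  double s = 0.0;
  for (int k = 0; k < c.K; ++k) {
    if (nb[k] < 0) break;
    int aj = a[nb[k]];
    s += wv[k] * (dn[aj] - doldr[aj]);
  }
  return 2.0 * s / c.Wtot;
}

inline void countSymbols(const Ctx& c, const int* a, int* cnt) {
  std::fill(cnt, cnt + c.nAA, 0);
  for (int p = 0; p < c.nPos; ++p) ++cnt[a[p]];
}

inline bool validCounts(const Ctx& c, const int* cnt) {
  for (int s = 0; s < c.nAA; ++s)
    if (cnt[s] < c.minCount[s]) return false;
  return true;
}

// rejection-sample a constraint-satisfying code, uniform on the ensemble
void randomValidCode(const Ctx& c, int* a, int* cnt, long maxTries = 100000) {
  for (long t = 0; t < maxTries; ++t) {
    for (int p = 0; p < c.nPos; ++p) a[p] = randInt(c.nAA);
    countSymbols(c, a, cnt);
    if (validCounts(c, cnt)) return;
  }
  stop("could not draw a constraint-satisfying code (constraints too tight?)");
}

inline int binOf(double cost, double lo, double width, int nbins) {
  int b = (int)std::floor((cost - lo) / width);
  if (b < 0) b = 0;
  if (b >= nbins) b = nbins - 1;
  return b;
}

// mean property over "right" (side 1) minus "left" (side 0) positions
inline double deltaProp(const Ctx& c, const int* a, const double* propVal,
                        const int* side) {
  double sl = 0, sr = 0;
  int nl = 0, nr = 0;
  for (int p = 0; p < c.nPos; ++p) {
    if (side[p]) { sr += propVal[a[p]]; ++nr; }
    else { sl += propVal[a[p]]; ++nl; }
  }
  return (nr ? sr / nr : 0.0) - (nl ? sl / nl : 0.0);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_cost")]]
double cpp_cost(IntegerVector code, List ctxL) {
  Ctx c = buildCtx(ctxL);
  if (code.size() != c.nPos) stop("code length mismatch");
  return fullCost(c, INTEGER(code));
}

// [[Rcpp::export(name = ".cpp_delta")]]
double cpp_delta(IntegerVector code, int pos, int anew, List ctxL) {
  Ctx c = buildCtx(ctxL);
  return deltaCost(c, INTEGER(code), pos, anew);
}

// [[Rcpp::export(name = ".cpp_random_code")]]
IntegerVector cpp_random_code(List ctxL) {
  RNGScope scope;
  Ctx c = buildCtx(ctxL);
  IntegerVector a(c.nPos);
  std::vector<int> cnt(c.nAA);
  randomValidCode(c, INTEGER(a), cnt.data());
  return a;
}

// [[Rcpp::export(name = ".cpp_naive")]]
List cpp_naive(List ctxL, double n, bool keepCodes) {
  RNGScope scope;
  Ctx c = buildCtx(ctxL);
  int nn = (int)n;
  NumericVector costs(nn);
  IntegerMatrix codes(keepCodes ? c.nPos : 0, keepCodes ? nn : 0);
  std::vector<int> a(c.nPos), cnt(c.nAA);
  double tries = 0;
  for (int i = 0; i < nn; ++i) {
    for (;;) {
      ++tries;
      for (int p = 0; p < c.nPos; ++p) a[p] = randInt(c.nAA);
      countSymbols(c, a.data(), cnt.data());
      if (validCounts(c, cnt.data())) break;
    }
    costs[i] = fullCost(c, a.data());
    if (keepCodes)
      std::copy(a.begin(), a.end(), codes.column(i).begin());
  }
  return List::create(_["costs"] = costs, _["codes"] = codes,
                      _["tries"] = tries);
}

// Costs of uniformly random block-structure codes: permutations of the nAA
// symbols over the standard code's amino-acid blocks. B[i,j] holds the total
// ordered-pair misreading weight between block i and block j.
// [[Rcpp::export(name = ".cpp_block_costs")]]
NumericVector cpp_block_costs(double n, NumericMatrix B, NumericVector prop,
                              double Wtot) {
  RNGScope scope;
  int nn = (int)n, m = B.nrow();
  NumericVector costs(nn);
  std::vector<int> perm(m);
  std::vector<double> p(m);
  for (int i = 0; i < nn; ++i) {
    for (int j = 0; j < m; ++j) perm[j] = j;
    for (int j = m - 1; j > 0; --j) std::swap(perm[j], perm[randInt(j + 1)]);
    for (int j = 0; j < m; ++j) p[j] = prop[perm[j]];
    double s = 0.0;
    for (int a = 0; a < m; ++a) {
      double pa = p[a];
      const double* Bcol = &B[(size_t)a * m];
      for (int b = 0; b < m; ++b) {
        double diff = pa - p[b];
        s += Bcol[b] * diff * diff;  // B symmetric: column = row
      }
    }
    costs[i] = s / Wtot;
  }
  return costs;
}

// Wang-Landau training of the multicanonical weight over a binned cost axis.
// logg accumulates the running log density-of-states estimate; the returned
// weight is w = 1/exp(logg). Candidates that violate the symbol-multiplicity
// constraints are rejected in place (the current bin is re-counted), which
// keeps the chain on the constrained ensemble.
// [[Rcpp::export(name = ".cpp_wang_landau")]]
List cpp_wang_landau(List ctxL, double lo, double width, int nbins,
                     double logf0, double flat, double minLogf,
                     double checkEvery, double maxSteps, IntegerVector init) {
  RNGScope scope;
  Ctx c = buildCtx(ctxL);
  std::vector<int> a(init.begin(), init.end()), cnt(c.nAA);
  countSymbols(c, a.data(), cnt.data());
  if (!validCounts(c, cnt.data())) stop("initial code violates constraints");
  double cost = fullCost(c, a.data());
  int bin = binOf(cost, lo, width, nbins);

  std::vector<double> logg(nbins, 0.0), hist(nbins, 0.0);
  std::vector<bool> visited(nbins, false);
  double logf = logf0, steps = 0, sinceCheck = 0, sinceRefresh = 0;
  int stages = 0;

  while (logf >= minLogf && steps < maxSteps) {
    // one MC step
    int pos = randInt(c.nPos);
    int aold = a[pos];
    int anew = randInt(c.nAA - 1);
    if (anew >= aold) ++anew;
    if (cnt[aold] - 1 >= c.minCount[aold]) {  // candidate keeps constraints
      double nc = cost + deltaCost(c, a.data(), pos, anew);
      int nb = binOf(nc, lo, width, nbins);
      if (logg[bin] - logg[nb] >= 0 ||
          std::log(unif_rand()) < logg[bin] - logg[nb]) {
        a[pos] = anew; --cnt[aold]; ++cnt[anew];
        cost = nc; bin = nb;
      }
    }
    logg[bin] += logf;
    hist[bin] += 1;
    visited[bin] = true;
    ++steps; ++sinceCheck; ++sinceRefresh;

    if (sinceRefresh >= 1e6) {  // cure floating drift in the running cost
      cost = fullCost(c, a.data());
      bin = binOf(cost, lo, width, nbins);
      sinceRefresh = 0;
    }
    if (sinceCheck >= checkEvery) {
      sinceCheck = 0;
      double sum = 0, mn = R_PosInf; int nvis = 0;
      for (int b = 0; b < nbins; ++b) {
        if (hist[b] > 0) { sum += hist[b]; ++nvis; if (hist[b] < mn) mn = hist[b]; }
      }
      if (nvis > 0 && mn >= flat * (sum / nvis)) {
        std::fill(hist.begin(), hist.end(), 0.0);
        logf *= 0.5;
        ++stages;
      }
    }
  }

  double mx = R_NegInf;
  for (int b = 0; b < nbins; ++b) if (visited[b] && logg[b] > mx) mx = logg[b];
  NumericVector lg(nbins);
  LogicalVector vis(nbins);
  for (int b = 0; b < nbins; ++b) {
    lg[b] = visited[b] ? logg[b] - mx : NA_REAL;
    vis[b] = visited[b];
  }
  return List::create(_["logg"] = lg, _["visited"] = vis,
                      _["stages"] = stages, _["steps"] = steps,
                      _["finalLogf"] = logf,
                      _["converged"] = (logf < minLogf),
                      _["finalCode"] = IntegerVector(a.begin(), a.end()),
                      _["finalCost"] = cost);
}

// Fixed-weight multicanonical sampling with min(1, w(new)/w(cur)) acceptance.
// Every `thin`-th state is retained (cost, and the right-left property
// difference when propVal is supplied); full codes are retained only below
// `keepBelow` to bound memory. When trackFlow is true the per-step bin-pair
// transition counts are accumulated (only sensible for small grids).
// [[Rcpp::export(name = ".cpp_muca")]]
List cpp_muca(List ctxL, double lo, double width, int nbins,
              NumericVector logw, double steps, int thin, double keepBelow,
              IntegerVector init, NumericVector propVal, IntegerVector side,
              bool trackFlow) {
  RNGScope scope;
  Ctx c = buildCtx(ctxL);
  if (logw.size() != nbins) stop("weight/grid mismatch");
  std::vector<int> a(init.begin(), init.end()), cnt(c.nAA);
  countSymbols(c, a.data(), cnt.data());
  if (!validCounts(c, cnt.data())) stop("initial code violates constraints");
  double cost = fullCost(c, a.data());
  int bin = binOf(cost, lo, width, nbins);
  bool doProp = propVal.size() > 0;

  std::vector<double> hist(nbins, 0.0);
  std::vector<double> flow;
  if (trackFlow) {
    if ((double)nbins * nbins > 4e6) stop("flow tracking needs a small grid");
    flow.assign((size_t)nbins * nbins, 0.0);
  }
  std::vector<double> retCost, retDpr;
  std::vector<int> retCodes;
  retCost.reserve((size_t)(steps / thin) + 1);

  double sinceRefresh = 0;
  int sinceThin = 0;
  for (double s = 0; s < steps; ++s) {
    int prev = bin;
    int pos = randInt(c.nPos);
    int aold = a[pos];
    int anew = randInt(c.nAA - 1);
    if (anew >= aold) ++anew;
    if (cnt[aold] - 1 >= c.minCount[aold]) {
      double nc = cost + deltaCost(c, a.data(), pos, anew);
      int nb = binOf(nc, lo, width, nbins);
      double dl = logw[nb] - logw[bin];
      if (dl >= 0 || std::log(unif_rand()) < dl) {
        a[pos] = anew; --cnt[aold]; ++cnt[anew];
        cost = nc; bin = nb;
      }
    }
    hist[bin] += 1;
    if (trackFlow) flow[(size_t)prev * nbins + bin] += 1;
    if (++sinceThin >= thin) {
      sinceThin = 0;
      retCost.push_back(cost);
      if (doProp)
        retDpr.push_back(deltaProp(c, a.data(), REAL(propVal), INTEGER(side)));
      if (cost < keepBelow)
        retCodes.insert(retCodes.end(), a.begin(), a.end());
    }
    if (++sinceRefresh >= 1e6) {
      cost = fullCost(c, a.data());
      bin = binOf(cost, lo, width, nbins);
      sinceRefresh = 0;
    }
  }

  int nKept = (int)(retCodes.size() / c.nPos);
  IntegerMatrix codes(c.nPos, nKept);
  std::copy(retCodes.begin(), retCodes.end(), codes.begin());
  List out = List::create(
      _["hist"] = NumericVector(hist.begin(), hist.end()),
      _["retCost"] = NumericVector(retCost.begin(), retCost.end()),
      _["retDpr"] = NumericVector(retDpr.begin(), retDpr.end()),
      _["retCodes"] = codes,
      _["finalCode"] = IntegerVector(a.begin(), a.end()),
      _["finalCost"] = cost);
  if (trackFlow) {
    NumericMatrix fm(nbins, nbins);
    for (int i = 0; i < nbins; ++i)
      for (int j = 0; j < nbins; ++j)
        fm(i, j) = flow[(size_t)i * nbins + j];  // row = from, col = to
    out["flow"] = fm;
  }
  return out;
}

// Truncation-selection genetic algorithm. Per generation the nSel cheapest
// codes survive unchanged; the population is refilled by copying each
// survivor exactly once (drawn without replacement, i.e. a random order) and
// mutating every element of each copy independently with probability mu.
// A mutated copy violating the multiplicity constraints is redrawn from its
// survivor ("the mutation process starts over"), up to retryCap attempts.
// [[Rcpp::export(name = ".cpp_ga")]]
List cpp_ga(List ctxL, int N, int nSel, double mu, int gens, int runs,
            double sliceLo, double sliceHi, int retryCap,
            NumericVector propVal, IntegerVector side, bool mutateSurvivors,
            bool recordPopulations) {
  RNGScope scope;
  Ctx c = buildCtx(ctxL);
  const int nPos = c.nPos;
  NumericMatrix bestCost(gens, runs), bestDpr(gens, runs);
  IntegerMatrix sliceCodes(nPos, runs);
  NumericVector sliceCost(runs, NA_REAL);
  IntegerVector sliceGen(runs, NA_INTEGER);
  LogicalVector reached(runs, false);
  std::fill(sliceCodes.begin(), sliceCodes.end(), NA_INTEGER);
  List popRecord(recordPopulations ? gens : 0);

  std::vector<int> pop((size_t)N * nPos), newPop((size_t)N * nPos);
  std::vector<int> cnt((size_t)N * c.nAA), newCnt((size_t)N * c.nAA);
  std::vector<double> cost(N), newCost(N);
  std::vector<int> ord(N), survOrder(nSel), tmp(nPos), tmpCnt(c.nAA);

  for (int r = 0; r < runs; ++r) {
    for (int i = 0; i < N; ++i) {
      randomValidCode(c, &pop[(size_t)i * nPos], &cnt[(size_t)i * c.nAA]);
      cost[i] = fullCost(c, &pop[(size_t)i * nPos]);
    }
    for (int g = 0; g < gens; ++g) {
      for (int i = 0; i < N; ++i) ord[i] = i;
      std::stable_sort(ord.begin(), ord.end(),
                       [&](int x, int y) { return cost[x] < cost[y]; });
      // survivors, in rank order
      for (int i = 0; i < nSel; ++i) {
        int s = ord[i];
        std::copy(&pop[(size_t)s * nPos], &pop[(size_t)s * nPos] + nPos,
                  &newPop[(size_t)i * nPos]);
        std::copy(&cnt[(size_t)s * c.nAA], &cnt[(size_t)s * c.nAA] + c.nAA,
                  &newCnt[(size_t)i * c.nAA]);
        newCost[i] = cost[s];
      }
      // copies: each survivor drawn exactly once, in random order
      for (int i = 0; i < nSel; ++i) survOrder[i] = i;
      for (int i = nSel - 1; i > 0; --i)
        std::swap(survOrder[i], survOrder[randInt(i + 1)]);
      int nCopy = N - nSel;
      for (int i = 0; i < nCopy; ++i) {
        int src = survOrder[i % nSel];
        int dst = nSel + i;
        int* gsrc = &newPop[(size_t)src * nPos];
        int* cs = &newCnt[(size_t)src * c.nAA];
        double c0 = newCost[src];
        int tries = 0;
        for (;;) {
          if (++tries > retryCap) stop("GA mutation retry cap exceeded");
          std::copy(gsrc, gsrc + nPos, tmp.begin());
          std::copy(cs, cs + c.nAA, tmpCnt.begin());
          double cc = c0;
          for (int p = 0; p < nPos; ++p) {
            if (unif_rand() < mu) {
              int anew = randInt(c.nAA - 1);
              if (anew >= tmp[p]) ++anew;
              cc += deltaCost(c, tmp.data(), p, anew);
              --tmpCnt[tmp[p]]; ++tmpCnt[anew];
              tmp[p] = anew;
            }
          }
          if (validCounts(c, tmpCnt.data())) {
            std::copy(tmp.begin(), tmp.end(), &newPop[(size_t)dst * nPos]);
            std::copy(tmpCnt.begin(), tmpCnt.end(), &newCnt[(size_t)dst * c.nAA]);
            newCost[dst] = cc;
            break;
          }
        }
      }
      if (mutateSurvivors) {
        // optional alternative reading: survivors are mutated in place too
        for (int i = 0; i < nSel; ++i) {
          int* gi = &newPop[(size_t)i * nPos];
          int* ci = &newCnt[(size_t)i * c.nAA];
          std::copy(gi, gi + nPos, tmp.begin());
          std::copy(ci, ci + c.nAA, tmpCnt.begin());
          double c0i = newCost[i];
          int tries = 0;
          for (;;) {
            if (++tries > retryCap) stop("GA mutation retry cap exceeded");
            std::copy(gi, gi + nPos, tmp.begin());
            std::copy(ci, ci + c.nAA, tmpCnt.begin());
            double cc = c0i;
            for (int p = 0; p < nPos; ++p) {
              if (unif_rand() < mu) {
                int anew = randInt(c.nAA - 1);
                if (anew >= tmp[p]) ++anew;
                cc += deltaCost(c, tmp.data(), p, anew);
                --tmpCnt[tmp[p]]; ++tmpCnt[anew];
                tmp[p] = anew;
              }
            }
            if (validCounts(c, tmpCnt.data())) {
              std::copy(tmp.begin(), tmp.end(), gi);
              std::copy(tmpCnt.begin(), tmpCnt.end(), ci);
              newCost[i] = cc;
              break;
            }
          }
        }
      }
      pop.swap(newPop); cnt.swap(newCnt); cost.swap(newCost);
      int best = 0;
      for (int i = 1; i < N; ++i) if (cost[i] < cost[best]) best = i;
      double bc = fullCost(c, &pop[(size_t)best * nPos]);  // drift-free
      cost[best] = bc;
      bestCost(g, r) = bc;
      bestDpr(g, r) = deltaProp(c, &pop[(size_t)best * nPos], REAL(propVal),
                                INTEGER(side));
      if (!reached[r] && bc >= sliceLo && bc < sliceHi) {
        reached[r] = true;
        std::copy(&pop[(size_t)best * nPos], &pop[(size_t)best * nPos] + nPos,
                  sliceCodes.column(r).begin());
        sliceCost[r] = bc;
        sliceGen[r] = g + 1;
      }
      if (recordPopulations) {
        IntegerMatrix pm(nPos, N);
        std::copy(pop.begin(), pop.end(), pm.begin());
        popRecord[g] = pm;
      }
    }
  }
  return List::create(_["bestCost"] = bestCost, _["bestDpr"] = bestDpr,
                      _["sliceCodes"] = sliceCodes,
                      _["sliceCost"] = sliceCost, _["sliceGen"] = sliceGen,
                      _["reached"] = reached,
                      _["populations"] = popRecord);
}

// Exhaustive enumeration of all nAA^nPos assignments (odometer order) with
// incremental cost updates; returns exact per-bin counts of the
// constraint-satisfying states.
// [[Rcpp::export(name = ".cpp_enum_dos")]]
List cpp_enum_dos(List ctxL, double lo, double width, int nbins, double cap) {
  Ctx c = buildCtx(ctxL);
  double nStatesD = std::pow((double)c.nAA, (double)c.nPos);
  if (nStatesD > cap) stop("state space exceeds enumeration cap");
  long long nStates = (long long)(nStatesD + 0.5);

  std::vector<int> a(c.nPos, 0), cnt(c.nAA, 0);
  cnt[0] = c.nPos;
  // deficit = number of symbols below their minimum multiplicity
  int deficit = 0;
  for (int s = 0; s < c.nAA; ++s) if (cnt[s] < c.minCount[s]) ++deficit;
  double cost = fullCost(c, a.data());

  std::vector<double> counts(nbins, 0.0);
  double total = 0, minCost = R_PosInf, maxCost = R_NegInf;

  auto assign = [&](int p, int v) {
    int old = a[p];
    cost += deltaCost(c, a.data(), p, v);
    if (cnt[old] == c.minCount[old]) ++deficit;
    --cnt[old];
    ++cnt[v];
    if (cnt[v] == c.minCount[v]) --deficit;
    a[p] = v;
  };

  for (long long s = 0;; ++s) {
    if (deficit == 0) {
      counts[binOf(cost, lo, width, nbins)] += 1;
      total += 1;
      if (cost < minCost) minCost = cost;
      if (cost > maxCost) maxCost = cost;
    }
    if (s == nStates - 1) break;
    int p = 0;
    while (a[p] == c.nAA - 1) { assign(p, 0); ++p; }
    assign(p, a[p] + 1);
    if ((s & 0xFFFFF) == 0) cost = fullCost(c, a.data());  // drift control
  }
  return List::create(_["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["total"] = total, _["minCost"] = minCost,
                      _["maxCost"] = maxCost);
}
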