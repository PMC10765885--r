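// Discrete-generation structured coalescent for independent biallelic sites.
//
// Backward time in whole generations. Each generation: (1) population merges
// whose time has been reached move all lineages from the daughter into the
// parent deme; (2) each lineage migrates between demes with the backward
// per-generation probability implied by the forward migration fraction;
// (3) within each deme of diploid size N(t), every lineage picks a parent
// chromosome uniformly among 2N; lineages sharing a parent coalesce
// (multiple mergers are possible and kept, as in the exact Wright-Fisher
// ancestral process). When exactly two lineages remain, co-located in one
// deme with constant size and no migration band or merge ahead of the next
// boundary, the waiting time to coalescence is geometric and is drawn in
// one step -- an exact shortcut, not an approximation.
//
// Mutations are then placed on the realized genealogy: either exactly one
// mutation on a branch chosen proportionally to its length (one segregating
// site per simulated site), or per-branch Poisson counts at rate mu per
// generation with the allele state of a sample given by the parity of
// mutations on its root path.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct SizeEpoch { int pop; double t0, t1, n0, n1; int type; };
struct MigRow { double t0, t1; int pop, dest; double prob; };

static double epoch_size(const SizeEpoch& e, double t) {
  if (e.type == 0 || e.t1 <= e.t0 || !R_finite(e.t1)) return e.n0;
  double f = (t - e.t0) / (e.t1 - e.t0);
  if (e.type == 1) return e.n0 + f * (e.n1 - e.n0);
  return e.n0 * std::pow(e.n1 / e.n0, f);
}

static const SizeEpoch* find_epoch(const std::vector<SizeEpoch>& eps,
                                   int pop, double t) {
  for (size_t i = 0; i < eps.size(); ++i)
    if (eps[i].pop == pop && t >= eps[i].t0 && t <= eps[i].t1)
      return &eps[i];
  stop("no size epoch covers population %d at generation %f", pop, t);
  return 0;
}

// [[Rcpp::export(name = ".simSitesCpp")]]
List sim_sites_cpp(int nSites, IntegerVector nHap, NumericMatrix sizeEpochs,
                   NumericMatrix merges, NumericMatrix mig,
                   int mutModel, double mu, double maxGen) {
  int nPop = nHap.size();
  int H = 0;
  for (int p = 0; p < nPop; ++p) H += nHap[p];
  if (H < 2) stop("need at least two haploid samples");

  std::vector<SizeEpoch> eps(sizeEpochs.nrow());
  for (int i = 0; i < sizeEpochs.nrow(); ++i) {
    eps[i].pop = (int)sizeEpochs(i, 0); eps[i].t0 = sizeEpochs(i, 1);
    eps[i].t1 = sizeEpochs(i, 2); eps[i].n0 = sizeEpochs(i, 3);
    eps[i].n1 = sizeEpochs(i, 4); eps[i].type = (int)sizeEpochs(i, 5);
  }
  std::vector<MigRow> mg(mig.nrow());
  std::vector< std::vector<int> > migByPop(nPop);
  for (int i = 0; i < mig.nrow(); ++i) {
    mg[i].t0 = mig(i, 0); mg[i].t1 = mig(i, 1);
    mg[i].pop = (int)mig(i, 2); mg[i].dest = (int)mig(i, 3);
    mg[i].prob = mig(i, 4);
    migByPop[mg[i].pop].push_back(i);
  }

  IntegerMatrix haps(nSites, H);
  NumericVector tmrca(nSites), tlen(nSites);
  IntegerVector nmut(nSites);

  // reusable buffers
  std::vector<int> parent; std::vector<double> ntime;
  std::vector<int> lin, linPop, idxBuf, parBuf;
  std::vector<char> dropBuf;
  std::vector<int> bm; std::vector<double> blen;

  for (int s = 0; s < nSites; ++s) {
    parent.clear(); ntime.clear(); lin.clear(); linPop.clear();
    for (int p = 0, k = 0; p < nPop; ++p)
      for (int i = 0; i < nHap[p]; ++i, ++k) {
        parent.push_back(-1); ntime.push_back(0.0);
        lin.push_back(k); linPop.push_back(p);
      }
    int mergeIdx = 0;
    double t = 0.0;
    while (lin.size() > 1) {
      // exact geometric shortcut for an isolated co-located pair
      if (lin.size() == 2 && linPop[0] == linPop[1]) {
        int p = linPop[0];
        const SizeEpoch* e = find_epoch(eps, p, t + 1.0);
        double tCap = std::min(e->t1, maxGen);
        if (mergeIdx < merges.nrow())
          tCap = std::min(tCap, merges(mergeIdx, 0) - 1.0);
        bool migFree = true;
        for (size_t m = 0; m < migByPop[p].size(); ++m) {
          const MigRow& r = mg[migByPop[p][m]];
          if (r.t1 > t && r.prob > 0) {       // band still ahead or active
            if (r.t0 > t) tCap = std::min(tCap, r.t0);
            else migFree = false;
          }
        }
        if (e->type == 0 && migFree && tCap >= t + 1.0) {
          double twoN = std::max(2.0, std::round(2.0 * e->n0));
          double q = 1.0 / twoN;
          double G = 1.0 + std::floor(std::log(unif_rand()) /
                                      std::log1p(-q));
          if (!R_finite(G) || G < 1.0) G = 1.0;
          if (t + G <= tCap) {                // coalesce at t + G
            t += G;
            int node = (int)parent.size();
            parent.push_back(-1); ntime.push_back(t);
            parent[lin[0]] = node; parent[lin[1]] = node;
            lin[0] = node; lin.resize(1); linPop.resize(1);
            break;
          }
          t = tCap;                           // nothing happened up to cap
          if (t >= maxGen)
            stop("genealogy did not coalesce within %g generations; "
                 "check that the model has a single root", maxGen);
          continue;
        }
      }
      t += 1.0;
      if (t > maxGen)
        stop("genealogy did not coalesce within %g generations; "
             "check that the model has a single root", maxGen);
      while (mergeIdx < merges.nrow() && merges(mergeIdx, 0) <= t) {
        int from = (int)merges(mergeIdx, 1), to = (int)merges(mergeIdx, 2);
        for (size_t i = 0; i < linPop.size(); ++i)
          if (linPop[i] == from) linPop[i] = to;
        ++mergeIdx;
      }
      if (!mg.empty()) {
        for (size_t i = 0; i < lin.size(); ++i) {
          const std::vector<int>& rows = migByPop[linPop[i]];
          for (size_t m = 0; m < rows.size(); ++m) {
            const MigRow& r = mg[rows[m]];
            if (t <= r.t0 || t > r.t1) continue;
            if (unif_rand() < r.prob) { linPop[i] = r.dest; break; }
          }
        }
      }
      for (int p = 0; p < nPop; ++p) {
        idxBuf.clear();
        for (size_t i = 0; i < lin.size(); ++i)
          if (linPop[i] == p) idxBuf.push_back((int)i);
        size_t k = idxBuf.size();
        if (k < 2) continue;
        const SizeEpoch* e = find_epoch(eps, p, t);
        double twoN = std::max(2.0, std::round(2.0 * epoch_size(*e, t)));
        parBuf.resize(k);
        for (size_t i = 0; i < k; ++i) {
          double d = std::floor(unif_rand() * twoN);
          parBuf[i] = (int)((d >= twoN) ? twoN - 1 : d);
        }
        dropBuf.assign(lin.size(), 0);
        bool any = false;
        for (size_t i = 0; i < k; ++i) {
          if (dropBuf[idxBuf[i]]) continue;
          int node = -1;
          for (size_t j = i + 1; j < k; ++j) {
            if (dropBuf[idxBuf[j]] || parBuf[j] != parBuf[i]) continue;
            if (node < 0) {
              node = (int)parent.size();
              parent.push_back(-1); ntime.push_back(t);
              parent[lin[idxBuf[i]]] = node;
              lin[idxBuf[i]] = node;
              any = true;
            }
            parent[lin[idxBuf[j]]] = node;
            dropBuf[idxBuf[j]] = 1;
          }
        }
        if (any) {
          size_t w = 0;
          for (size_t i = 0; i < lin.size(); ++i) {
            if (dropBuf[i]) continue;
            lin[w] = lin[i]; linPop[w] = linPop[i]; ++w;
          }
          lin.resize(w); linPop.resize(w);
        }
      }
    }
    int root = lin[0];
    tmrca[s] = ntime[root];
    int nNodes = (int)parent.size();
    double total = 0.0;
    blen.assign(nNodes, 0.0);
    for (int v = 0; v < nNodes; ++v) {
      if (parent[v] < 0) continue;
      blen[v] = ntime[parent[v]] - ntime[v];
      total += blen[v];
    }
    tlen[s] = total;

    if (mutModel == 1) {  // exactly one mutation, branch ~ length
      double u = unif_rand() * total, acc = 0.0;
      int chosen = -1;
      for (int v = 0; v < nNodes; ++v) {
        if (parent[v] < 0) continue;
        acc += blen[v];
        if (u <= acc) { chosen = v; break; }
      }
      if (chosen < 0) chosen = nNodes - 1;
      for (int leaf = 0; leaf < H; ++leaf) {
        int v = leaf, der = 0;
        while (v >= 0) {
          if (v == chosen) { der = 1; break; }
          v = parent[v];
        }
        haps(s, leaf) = der;
      }
      nmut[s] = 1;
    } else {              // Poisson(mu * length) per branch, parity model
      bm.assign(nNodes, 0);
      int total_m = 0;
      for (int v = 0; v < nNodes; ++v) {
        if (parent[v] < 0) continue;
        int k = (int)R::rpois(mu * blen[v]);
        bm[v] = k; total_m += k;
      }
      for (int leaf = 0; leaf < H; ++leaf) {
        int v = leaf, par = 0;
        while (v >= 0) { par += bm[v]; v = parent[v]; }
        haps(s, leaf) = par % 2;
      }
      nmut[s] = total_m;
    }
  }
  return List::create(_["haplotypes"] = haps, _["tmrca"] = tmrca,
                      _["tree_length"] = tlen, _["n_mutations"] = nmut);
}
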