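// Individual-based forward Wright-Fisher simulation of a recombining
// region.  Haplotypes are position-sorted vectors of mutation ids
// (continuous positions in [0, L), infinite sites).  Selection is genic:
// fitness is multiplicative across sites with per-site factor
// (1 + s * genotype), i.e. additive within a locus, no dominance.  Each
// haplotype additionally carries the subset of its mutations under
// selection, so per-generation fitness evaluation scales with the selected
// load only.  All randomness goes through R's RNG so that set.seed() in R
// fully determines the outcome.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Registry {
  std::vector<double> pos;
  std::vector<double> s;
  std::vector<int> origin;
  int add(double p, double sel, int gen) {
    pos.push_back(p);
    s.push_back(sel);
    origin.push_back(gen);
    return static_cast<int>(pos.size()) - 1;
  }
};

struct Hap {
  std::vector<int> all;  // every mutation, sorted by position
  std::vector<int> sel;  // the subset with s != 0, sorted by position
};

// copy mutations of src with position in [lo, hi) into out
inline void copySegment(const std::vector<int>& src,
                        const std::vector<double>& pos,
                        double lo, double hi, std::vector<int>& out) {
  size_t a = std::lower_bound(src.begin(), src.end(), lo,
                              [&](int id, double v) { return pos[id] < v; }) -
             src.begin();
  size_t b = std::lower_bound(src.begin(), src.end(), hi,
                              [&](int id, double v) { return pos[id] < v; }) -
             src.begin();
  out.insert(out.end(), src.begin() + a, src.begin() + b);
}

// merge-walk the selected mutations of one individual's two haplotypes;
// a shared id is genotype 2 (factor 1+2s), otherwise genotype 1 (1+s)
inline double fitness(const std::vector<int>& a, const std::vector<int>& b,
                      const std::vector<double>& s,
                      const std::vector<double>& pos) {
  double w = 1.0;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) {
      w *= 1.0 + 2.0 * s[a[i]];
      ++i; ++j;
    } else if (pos[a[i]] < pos[b[j]] ||
               (pos[a[i]] == pos[b[j]] && a[i] < b[j])) {
      w *= 1.0 + s[a[i]];
      ++i;
    } else {
      w *= 1.0 + s[b[j]];
      ++j;
    }
  }
  for (; i < a.size(); ++i) w *= 1.0 + s[a[i]];
  for (; j < b.size(); ++j) w *= 1.0 + s[b[j]];
  return w > 1e-12 ? w : 1e-12;
}

}  // namespace

// [[Rcpp::export]]
List wf_simulate_cpp(IntegerVector hapSizes, double muPerGamete,
                     double xoverPerMeiosis, double regionLength,
                     double fracSelected, double sSelected,
                     int thinInterval) {
  const int G = hapSizes.size();
  if (G < 2) stop("need at least two generations");
  for (int g = 0; g < G; ++g)
    if (hapSizes[g] < 4 || hapSizes[g] % 2 != 0)
      stop("haplotype counts must be even and >= 4");

  Registry reg;
  std::vector<Hap> cur(hapSizes[0]), nxt;
  long nIntroduced = 0, nFixed = 0;
  std::vector<double> cumw;
  std::vector<double> bps;

  for (int g = 1; g < G; ++g) {
    const int nPrev = static_cast<int>(cur.size());
    const int nInd = nPrev / 2;
    const int nNext = hapSizes[g];

    // cumulative fitness over parental individuals
    cumw.resize(nInd);
    double tot = 0.0;
    for (int i = 0; i < nInd; ++i) {
      tot += fitness(cur[2 * i].sel, cur[2 * i + 1].sel, reg.s, reg.pos);
      cumw[i] = tot;
    }

    nxt.assign(nNext, Hap());
    for (int j = 0; j < nNext; ++j) {
      // choose a parent proportional to fitness
      double u = unif_rand() * tot;
      int par = static_cast<int>(
          std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
      if (par >= nInd) par = nInd - 1;
      const Hap& h0 = cur[2 * par];
      const Hap& h1 = cur[2 * par + 1];

      Hap& gam = nxt[j];
      int k = static_cast<int>(R::rpois(xoverPerMeiosis));
      int phase = unif_rand() < 0.5 ? 0 : 1;
      if (k == 0) {
        gam = phase == 0 ? h0 : h1;
      } else {
        bps.clear();
        for (int c = 0; c < k; ++c) bps.push_back(unif_rand() * regionLength);
        std::sort(bps.begin(), bps.end());
        double lo = 0.0;
        for (int c = 0; c <= k; ++c) {
          double hi = c < k ? bps[c] : regionLength;
          const Hap& src = (phase + c) % 2 == 0 ? h0 : h1;
          copySegment(src.all, reg.pos, lo, hi, gam.all);
          copySegment(src.sel, reg.pos, lo, hi, gam.sel);
          lo = hi;
        }
      }

      // new mutations on this gamete
      int m = static_cast<int>(R::rpois(muPerGamete));
      for (int c = 0; c < m; ++c) {
        double p = unif_rand() * regionLength;
        double sv = unif_rand() < fracSelected ? sSelected : 0.0;
        int id = reg.add(p, sv, g);
        ++nIntroduced;
        auto cmp = [&](int mid, double v) { return reg.pos[mid] < v; };
        gam.all.insert(
            std::lower_bound(gam.all.begin(), gam.all.end(), p, cmp), id);
        if (sv != 0.0)
          gam.sel.insert(
              std::lower_bound(gam.sel.begin(), gam.sel.end(), p, cmp), id);
      }
    }
    cur.swap(nxt);

    // periodically absorb fixed mutations into the background
    if (g % thinInterval == 0 || g == G - 1) {
      const int nh = static_cast<int>(cur.size());
      std::vector<int> cnt(reg.pos.size(), 0);
      for (const Hap& h : cur)
        for (int id : h.all) ++cnt[id];
      std::vector<char> fixed(reg.pos.size(), 0);
      bool any = false;
      for (size_t id = 0; id < cnt.size(); ++id)
        if (cnt[id] == nh) { fixed[id] = 1; any = true; ++nFixed; }
      if (any)
        for (Hap& h : cur) {
          auto drop = [&](int id) { return fixed[id] != 0; };
          h.all.erase(std::remove_if(h.all.begin(), h.all.end(), drop),
                      h.all.end());
          h.sel.erase(std::remove_if(h.sel.begin(), h.sel.end(), drop),
                      h.sel.end());
        }
    }
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
  }

  // final segregating variants
  const int nh = static_cast<int>(cur.size());
  std::vector<int> cnt(reg.pos.size(), 0);
  for (const Hap& h : cur)
    for (int id : h.all) ++cnt[id];
  std::vector<int> seg;
  for (size_t id = 0; id < cnt.size(); ++id)
    if (cnt[id] > 0 && cnt[id] < nh) seg.push_back(static_cast<int>(id));
  std::sort(seg.begin(), seg.end(),
            [&](int a, int b) { return reg.pos[a] < reg.pos[b]; });

  const int S = static_cast<int>(seg.size());
  IntegerMatrix geno(S, nh);
  std::vector<int> row(reg.pos.size(), -1);
  for (int r = 0; r < S; ++r) row[seg[r]] = r;
  for (int h = 0; h < nh; ++h)
    for (int id : cur[h].all)
      if (row[id] >= 0) geno(row[id], h) = 1;

  NumericVector pos(S), sOut(S);
  IntegerVector origin(S), count(S);
  for (int r = 0; r < S; ++r) {
    pos[r] = reg.pos[seg[r]];
    sOut[r] = reg.s[seg[r]];
    origin[r] = reg.origin[seg[r]];
    count[r] = cnt[seg[r]];
  }

  return List::create(_["genotypes"] = geno, _["pos"] = pos,
                      _["s"] = sOut, _["origin"] = origin,
                      _["count"] = count, _["generations"] = G - 1,
                      _["nIntroduced"] = static_cast<double>(nIntroduced),
                      _["nFixed"] = static_cast<double>(nFixed));
}
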