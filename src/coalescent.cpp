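// Coalescent engine: Hudson-style ancestral recombination graph with
// bitset tracking of ancestral material, piecewise-constant demography,
// an arbitrary piecewise-constant recombination map, and an optional
// structured two-background phase driven by a selected-allele frequency
// trajectory (backward in time, per-generation resolution).
//
// Units: time in 2*Ne generations; a pair of lineages in a background of
// relative size lambda coalesces at rate 1/lambda; a lineage spanning
// genetic map mass G recombines at rate G/2 (G in rho = 4*Ne*r units);
// mutations fall at rate theta/2 per unit time on material of physical
// length 1 (positions live on [0,1)).

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<uint64_t> Bits;

struct Seg { double l, r; Bits desc; };
struct Lin { std::vector<Seg> segs; double birth; int bg; };
struct Mut { double pos; Bits desc; };

struct Engine {
  int n, W;
  Bits full;
  double theta;
  std::vector<double> mb, mc;   // recombination map: breaks, cumulative rho
  std::vector<Lin> lin;
  std::vector<Mut> muts;
  long n_rec, n_coal;

  void init(int n_, double theta_, const NumericVector& breaks,
            const NumericVector& cum) {
    n = n_; W = (n + 63) / 64;
    full.assign(W, 0);
    for (int i = 0; i < n; ++i) full[i >> 6] |= (uint64_t)1 << (i & 63);
    theta = theta_;
    mb.assign(breaks.begin(), breaks.end());
    mc.assign(cum.begin(), cum.end());
    n_rec = n_coal = 0;
    lin.clear(); muts.clear();
    for (int i = 0; i < n; ++i) {
      Bits d(W, 0);
      d[i >> 6] |= (uint64_t)1 << (i & 63);
      Lin L; L.birth = 0.0; L.bg = 0;
      L.segs.push_back(Seg{0.0, 1.0, d});
      lin.push_back(L);
    }
  }

  bool isfull(const Bits& b) const {
    for (int i = 0; i < W; ++i) if (b[i] != full[i]) return false;
    return true;
  }

  double cum(double x) const {
    if (x <= mb.front()) return mc.front();
    if (x >= mb.back()) return mc.back();
    size_t i = std::upper_bound(mb.begin(), mb.end(), x) - mb.begin();
    double x0 = mb[i - 1], x1 = mb[i], c0 = mc[i - 1], c1 = mc[i];
    return c0 + (c1 - c0) * (x - x0) / (x1 - x0);
  }

  double icum(double u) const {
    size_t i = std::upper_bound(mc.begin(), mc.end(), u) - mc.begin();
    if (i == 0) i = 1;
    if (i >= mc.size()) i = mc.size() - 1;
    double x0 = mb[i - 1], x1 = mb[i], c0 = mc[i - 1], c1 = mc[i];
    if (c1 <= c0) return x0;
    return x0 + (x1 - x0) * (u - c0) / (c1 - c0);
  }

  // genetic map mass spanned by a lineage's material, optionally extended
  // to cover the selected position (structured phase)
  double glen(const Lin& L, double extend) const {
    double a = L.segs.front().l, b = L.segs.back().r;
    if (extend >= 0) { a = std::min(a, extend); b = std::max(b, extend); }
    return cum(b) - cum(a);
  }

  // Poisson mutations over the lineage's lifetime, emitted when it dies
  void emit(const Lin& L, double t) {
    double dur = t - L.birth;
    if (dur <= 0) return;
    for (size_t s = 0; s < L.segs.size(); ++s) {
      double lam = 0.5 * theta * dur * (L.segs[s].r - L.segs[s].l);
      if (lam <= 0) continue;
      int k = (int)R::rpois(lam);
      for (int j = 0; j < k; ++j) {
        Mut m;
        m.pos = L.segs[s].l + unif_rand() * (L.segs[s].r - L.segs[s].l);
        m.desc = L.segs[s].desc;
        muts.push_back(m);
      }
    }
  }

  // overlay two segment lists; unions covering the whole sample have
  // reached their MRCA and are dropped
  std::vector<Seg> overlay(const std::vector<Seg>& A,
                           const std::vector<Seg>& B) const {
    std::vector<double> cuts;
    for (size_t i = 0; i < A.size(); ++i) { cuts.push_back(A[i].l); cuts.push_back(A[i].r); }
    for (size_t i = 0; i < B.size(); ++i) { cuts.push_back(B[i].l); cuts.push_back(B[i].r); }
    std::sort(cuts.begin(), cuts.end());
    cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
    std::vector<Seg> out;
    size_t ia = 0, ib = 0;
    for (size_t c = 0; c + 1 < cuts.size(); ++c) {
      double a = cuts[c], b = cuts[c + 1];
      while (ia < A.size() && A[ia].r <= a) ++ia;
      while (ib < B.size() && B[ib].r <= a) ++ib;
      bool inA = ia < A.size() && A[ia].l <= a;
      bool inB = ib < B.size() && B[ib].l <= a;
      if (!inA && !inB) continue;
      Bits d(W, 0);
      if (inA) for (int i = 0; i < W; ++i) d[i] |= A[ia].desc[i];
      if (inB) for (int i = 0; i < W; ++i) d[i] |= B[ib].desc[i];
      if (isfull(d)) continue;
      if (!out.empty() && out.back().r == a && out.back().desc == d)
        out.back().r = b;
      else
        out.push_back(Seg{a, b, d});
    }
    return out;
  }

  void coalesce(size_t i, size_t j, double t, int bg) {
    emit(lin[i], t); emit(lin[j], t);
    Lin nw; nw.birth = t; nw.bg = bg;
    nw.segs = overlay(lin[i].segs, lin[j].segs);
    if (i < j) std::swap(i, j);
    lin.erase(lin.begin() + i);
    lin.erase(lin.begin() + j);
    if (!nw.segs.empty()) lin.push_back(nw);
    ++n_coal;
  }

  // split a lineage at a map-weighted breakpoint; in the structured phase
  // (X >= 0) the piece carrying the selected position keeps its background
  // and the other piece draws a background from the current frequency X
  void recombine(size_t i, double t, double X, double selpos) {
    Lin L = lin[i];
    double a = L.segs.front().l, b = L.segs.back().r;
    bool sweep = X >= 0;
    if (sweep) { a = std::min(a, selpos); b = std::max(b, selpos); }
    double ca = cum(a), cb = cum(b);
    if (cb <= ca) return;
    double p = icum(ca + unif_rand() * (cb - ca));
    emit(L, t);
    Lin left, right;
    left.birth = right.birth = t;
    left.bg = right.bg = L.bg;
    for (size_t s = 0; s < L.segs.size(); ++s) {
      const Seg& sg = L.segs[s];
      if (sg.r <= p) left.segs.push_back(sg);
      else if (sg.l >= p) right.segs.push_back(sg);
      else {
        left.segs.push_back(Seg{sg.l, p, sg.desc});
        right.segs.push_back(Seg{p, sg.r, sg.desc});
      }
    }
    if (sweep) {
      int nb = (unif_rand() < X) ? 1 : 0;
      if (p <= selpos) left.bg = nb; else right.bg = nb;
    }
    lin.erase(lin.begin() + i);
    if (!left.segs.empty()) lin.push_back(left);
    if (!right.segs.empty()) lin.push_back(right);
    ++n_rec;
  }
};

// pick two distinct members (by position in idx) uniformly
static void pick_pair(const std::vector<size_t>& idx, size_t& a, size_t& b) {
  int k = (int)idx.size();
  int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
  int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
  if (j >= i) ++j;
  a = idx[i]; b = idx[j];
}

// [[Rcpp::export(name = ".sim_locus_cpp")]]
List sim_locus_cpp(int n, double theta,
                   NumericVector map_breaks, NumericVector map_cum,
                   NumericVector epoch_start, NumericVector epoch_size,
                   int n_derived, NumericVector traj, double dt,
                   double sel_pos) {
  if (n < 2) stop("need at least two haplotypes");
  Engine eng;
  eng.init(n, theta, map_breaks, map_cum);

  double t = 0.0;
  long guard = 0; const long GUARD_MAX = 200000000L;

  // ---- structured sweep phase ----
  if (n_derived >= 1 && traj.size() > 0) {
    for (int i = 0; i < n && i < n_derived; ++i) eng.lin[i].bg = 1;
    R_xlen_t g = 0;
    // lineage-count and map-mass aggregates change only at events, so
    // they are cached across the per-generation trajectory steps
    bool dirty = true;
    int kB = 0, kb = 0;
    double gm = 0;
    std::vector<double> gi;
    while (!eng.lin.empty() && g < traj.size()) {
      if (++guard > GUARD_MAX) stop("event guard exceeded (sweep phase)");
      double X = traj[g];
      if (X < 1e-12) X = 1e-12;
      if (X > 1.0 - 1e-12) X = 1.0 - 1e-12;
      if (dirty) {
        kB = kb = 0; gm = 0;
        gi.assign(eng.lin.size(), 0.0);
        for (size_t i = 0; i < eng.lin.size(); ++i) {
          if (eng.lin[i].bg == 1) ++kB; else ++kb;
          gi[i] = eng.glen(eng.lin[i], sel_pos);
          gm += gi[i];
        }
        dirty = false;
      }
      double cB = 0.5 * kB * (kB - 1) / X;
      double cb = 0.5 * kb * (kb - 1) / (1.0 - X);
      double rr = 0.5 * gm;
      double tot = cB + cb + rr;
      double tend = (double)(g + 1) * dt;
      double w = (tot > 0) ? exp_rand() / tot : R_PosInf;
      if (t + w >= tend) { t = tend; ++g; continue; }
      t += w;
      double u = unif_rand() * tot;
      if (u < cB + cb) {
        int want = (u < cB) ? 1 : 0;
        std::vector<size_t> idx;
        for (size_t i = 0; i < eng.lin.size(); ++i)
          if (eng.lin[i].bg == want) idx.push_back(i);
        size_t a, b; pick_pair(idx, a, b);
        eng.coalesce(a, b, t, want);
      } else {
        double pick = unif_rand() * gm, acc = 0;
        size_t i = 0;
        for (; i < eng.lin.size(); ++i) { acc += gi[i]; if (pick <= acc) break; }
        if (i >= eng.lin.size()) i = eng.lin.size() - 1;
        eng.recombine(i, t, X, sel_pos);
      }
      dirty = true;
    }
    // trajectory exhausted: the selected allele is down to a single copy;
    // all remaining derived-background lineages coalesce into the origin
    for (;;) {
      std::vector<size_t> idx;
      for (size_t i = 0; i < eng.lin.size(); ++i)
        if (eng.lin[i].bg == 1) idx.push_back(i);
      if (idx.size() >= 2) {
        size_t a, b; pick_pair(idx, a, b);
        t += dt;
        eng.coalesce(a, b, t, 1);
      } else {
        if (idx.size() == 1) eng.lin[idx[0]].bg = 0;
        break;
      }
    }
  }

  // ---- neutral phase with piecewise-constant population size ----
  size_t e = 0;
  size_t ne = (size_t)epoch_start.size();
  while (e + 1 < ne && epoch_start[e + 1] <= t) ++e;
  while (!eng.lin.empty()) {
    if (++guard > GUARD_MAX) stop("event guard exceeded (neutral phase)");
    size_t k = eng.lin.size();
    if (k == 1) stop("internal error: single lineage with unresolved material");
    double gm = 0;
    std::vector<double> gi(k);
    for (size_t i = 0; i < k; ++i) { gi[i] = eng.glen(eng.lin[i], -1.0); gm += gi[i]; }
    double crate = 0.5 * (double)k * (double)(k - 1) / epoch_size[e];
    double rr = 0.5 * gm;
    double tot = crate + rr;
    double w = exp_rand() / tot;
    if (e + 1 < ne && t + w >= epoch_start[e + 1]) { t = epoch_start[e + 1]; ++e; continue; }
    t += w;
    if (unif_rand() * tot < crate) {
      std::vector<size_t> idx(k);
      for (size_t i = 0; i < k; ++i) idx[i] = i;
      size_t a, b; pick_pair(idx, a, b);
      eng.coalesce(a, b, t, 0);
    } else {
      double pick = unif_rand() * gm, acc = 0;
      size_t i = 0;
      for (; i < k; ++i) { acc += gi[i]; if (pick <= acc) break; }
      if (i >= k) i = k - 1;
      eng.recombine(i, t, -1.0, sel_pos);
    }
  }

  // ---- assemble output ----
  std::sort(eng.muts.begin(), eng.muts.end(),
            [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
  int S = (int)eng.muts.size();
  IntegerMatrix M(n, S);
  NumericVector pos(S);
  for (int s = 0; s < S; ++s) {
    pos[s] = eng.muts[s].pos;
    const Bits& d = eng.muts[s].desc;
    for (int i = 0; i < n; ++i)
      M(i, s) = (int)((d[i >> 6] >> (i & 63)) & 1);
  }
  return List::create(_["positions"] = pos, _["alleles"] = M,
                      _["t_mrca"] = t, _["n_rec"] = eng.n_rec,
                      _["n_coal"] = eng.n_coal);
}
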