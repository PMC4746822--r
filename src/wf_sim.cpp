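// Rescaled discrete Wright-Fisher simulator, evaluated lineage-wise.
//
// The model is the standard forward WF process with piecewise-constant
// population size, per-meiosis Poisson crossovers and infinite-sites
// Poisson mutation, optionally conditioned on a per-generation carrier
// count trajectory for a beneficial allele at a fixed map position.
// Rather than storing every genome every generation, the sampled
// haplotypes are produced by following the sample's ancestral material
// backwards through the identical per-generation parent/crossover
// draws, which leaves the sampling distribution unchanged and makes the
// cost proportional to the ancestral recombination structure instead of
// (population size) x (generations) x (mutations per genome).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef std::vector<uint64_t> Bits;

struct Seg {
  double l, r;
  Bits b;
};

struct Lin {
  std::vector<Seg> segs;
  int cls;  // allelic class at the selected site: 1 carrier, 0 ancestral
};

static inline int unif_index(int m) {
  int k = (int)(unif_rand() * m);
  return k >= m ? m - 1 : k;
}

static inline void push_seg(std::vector<Seg>& out, double l, double r,
                            const Bits& b) {
  if (r <= l) return;
  if (!out.empty() && out.back().r == l && out.back().b == b) {
    out.back().r = r;
    return;
  }
  out.push_back(Seg{l, r, b});
}

// union of two disjoint-sorted segment lists; overlaps OR their bitsets
static std::vector<Seg> merge_segs(std::vector<Seg> A, std::vector<Seg> B) {
  std::vector<Seg> out;
  out.reserve(A.size() + B.size());
  size_t i = 0, j = 0;
  while (i < A.size() && j < B.size()) {
    Seg& a = A[i];
    Seg& b = B[j];
    if (a.r <= b.l) { push_seg(out, a.l, a.r, a.b); ++i; continue; }
    if (b.r <= a.l) { push_seg(out, b.l, b.r, b.b); ++j; continue; }
    if (a.l < b.l) { push_seg(out, a.l, b.l, a.b); a.l = b.l; }
    else if (b.l < a.l) { push_seg(out, b.l, a.l, b.b); b.l = a.l; }
    double r = std::min(a.r, b.r);
    Bits ob(a.b.size());
    for (size_t w = 0; w < ob.size(); ++w) ob[w] = a.b[w] | b.b[w];
    push_seg(out, a.l, r, ob);
    a.l = r; b.l = r;
    if (a.l >= a.r) ++i;
    if (b.l >= b.r) ++j;
  }
  for (; i < A.size(); ++i) push_seg(out, A[i].l, A[i].r, A[i].b);
  for (; j < B.size(); ++j) push_seg(out, B[j].l, B[j].r, B[j].b);
  return out;
}

struct Mut {
  double pos;
  Bits b;
};

// draw a parent id for the side of the genome carrying the selected
// site, conditioned on the lineage's allelic class
static inline long long cond_parent(int cls, int M, int K) {
  if (K <= 0 || K >= M) return unif_index(M);
  if (cls == 1) return unif_index(K);
  return K + unif_index(M - K);
}

// [[Rcpp::export(name = ".wf_ancestry_sim")]]
List wf_ancestry_sim(int n_sample, IntegerVector sizes_back,
                     double mut_rate, double rec_rate, double sel_pos,
                     IntegerVector carriers_back) {
  const int T = sizes_back.size();
  if (carriers_back.size() != T)
    stop("sizes and carrier trajectories differ in length");
  const int nw = (n_sample + 63) / 64;
  const bool sweep = carriers_back.size() > 0 &&
    *std::max_element(carriers_back.begin(), carriers_back.end()) > 0;

  std::vector<Lin> active(n_sample);
  for (int s = 0; s < n_sample; ++s) {
    Bits b(nw, 0);
    b[s / 64] = 1ULL << (s % 64);
    active[s].segs.push_back(Seg{0.0, 1.0, b});
    active[s].cls = sweep ? 1 : 0;  // sampling happens at/after fixation
  }

  Bits full(nw, 0);
  for (int s = 0; s < n_sample; ++s) full[s / 64] |= 1ULL << (s % 64);
  std::vector<Mut> muts;

  for (int b = 0; b < T && !active.empty(); ++b) {
    const int M = sizes_back[b];
    const int K = sweep ? carriers_back[b] : 0;
    const bool class_active = K > 0 && K < M;
    std::unordered_map<long long, Lin> par;
    par.reserve(active.size() * 2);

    auto add_to = [&](long long pid, int pcls, std::vector<Seg>&& segs) {
      if (segs.empty()) return;
      auto it = par.find(pid);
      if (it == par.end()) {
        Lin l;
        l.segs = std::move(segs);
        l.cls = pcls;
        par.emplace(pid, std::move(l));
      } else {
        it->second.segs = merge_segs(std::move(it->second.segs),
                                     std::move(segs));
      }
    };

    for (Lin& lin : active) {
      double mat_len = 0.0;
      for (const Seg& s : lin.segs) mat_len += s.r - s.l;
      // mutations in the meiosis that produced this chromosome
      int nm = (int)R::rpois(mut_rate * mat_len);
      for (int m = 0; m < nm; ++m) {
        double x = unif_rand() * mat_len, acc = 0.0;
        for (const Seg& s : lin.segs) {
          double len = s.r - s.l;
          if (x < acc + len) {
            muts.push_back(Mut{s.l + (x - acc), s.b});
            break;
          }
          acc += len;
        }
      }
      // crossovers: only those inside the span of the ancestral
      // material (plus the selected site while the sweep is ongoing)
      // can affect the sample, so the Poisson is thinned to there
      double el = lin.segs.front().l, er = lin.segs.back().r;
      int cls = lin.cls;
      if (class_active) {
        el = std::min(el, sel_pos);
        er = std::max(er, sel_pos);
      }
      int nb = (er > el) ? (int)R::rpois(rec_rate * (er - el)) : 0;
      if (K == 0) cls = 0;  // before the allele's origination
      if (nb == 0) {
        long long pid = class_active ? cond_parent(cls, M, K) : unif_index(M);
        int pcls = class_active ? (pid < K ? 1 : 0) : cls;
        add_to(pid, pcls, std::move(lin.segs));
      } else {
        std::vector<double> bp(nb);
        for (int t = 0; t < nb; ++t) bp[t] = el + unif_rand() * (er - el);
        std::sort(bp.begin(), bp.end());
        // genome slots alternate between two parents, slot 0 -> side A
        int ps_slot = 0;
        if (class_active) {
          ps_slot = (int)(std::lower_bound(bp.begin(), bp.end(), sel_pos) -
                          bp.begin());
        }
        int ps_side = ps_slot % 2;
        long long pidA, pidB;
        int clsA, clsB;
        if (class_active) {
          if (ps_side == 0) {
            pidA = cond_parent(cls, M, K);
            pidB = unif_index(M);
          } else {
            pidB = cond_parent(cls, M, K);
            pidA = unif_index(M);
          }
          clsA = pidA < K ? 1 : 0;
          clsB = pidB < K ? 1 : 0;
        } else {
          pidA = unif_index(M);
          pidB = unif_index(M);
          clsA = clsB = cls;
        }
        std::vector<Seg> sa, sb;
        for (const Seg& s : lin.segs) {
          // cut s at breakpoints; piece starting at x goes to side
          // (#breakpoints <= x) mod 2
          double cur = s.l;
          size_t k = std::lower_bound(bp.begin(), bp.end(), s.l) - bp.begin();
          while (cur < s.r) {
            double nxt = (k < bp.size() && bp[k] < s.r) ? bp[k] : s.r;
            Seg piece{cur, nxt, s.b};
            if (k % 2 == 0) push_seg(sa, piece.l, piece.r, piece.b);
            else push_seg(sb, piece.l, piece.r, piece.b);
            cur = nxt;
            ++k;
          }
        }
        add_to(pidA, clsA, std::move(sa));
        add_to(pidB, clsB, std::move(sb));
      }
    }

    // parents become the active lineages; fully coalesced material
    // (carried by every sample) can no longer yield polymorphism
    active.clear();
    active.reserve(par.size());
    for (auto& kv : par) {
      Lin& l = kv.second;
      std::vector<Seg> kept;
      kept.reserve(l.segs.size());
      for (Seg& s : l.segs) {
        if (s.b != full) kept.push_back(std::move(s));
      }
      if (!kept.empty()) {
        l.segs = std::move(kept);
        active.push_back(std::move(l));
      }
    }
  }

  std::sort(muts.begin(), muts.end(),
            [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
  const int S = (int)muts.size();
  IntegerMatrix geno(n_sample, S);
  NumericVector pos(S);
  for (int j = 0; j < S; ++j) {
    pos[j] = muts[j].pos;
    for (int s = 0; s < n_sample; ++s) {
      geno(s, j) = (muts[j].b[s / 64] >> (s % 64)) & 1ULL ? 1 : 0;
    }
  }
  return List::create(_["positions"] = pos, _["geno"] = geno);
}
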