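// Discrete-generation Wright-Fisher forward simulator for one or two
// diploid populations with:
//   - infinite-sites mutation over an annotated contig (at most one
//     mutation segregating per position; positions of lost mutations are
//     freed, positions of fixed mutations stay blocked),
//   - multiplicative viability selection with genic fitnesses
//     1 / 1-hs / 1-s (s < 0 allowed for a beneficial sweep allele),
//   - migration (an offspring is produced by parents drawn from the other
//     population with probability m per individual per generation),
//   - multinomial (fitness-weighted) resampling,
//   - uniform crossover recombination.
//
// Each haplotype keeps its mutations sorted by position; the (few)
// selected mutations are mirrored in a second short list so fitness
// evaluation does not scan the neutral bulk.  All randomness flows
// through R's RNG so set.seed() gives byte-identical runs.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

struct MutTab {
  std::vector<int> pos;                  // 0-based site; -1 = freed slot
  std::vector<unsigned char> alt;        // alt base choice 0..2
  std::vector<unsigned char> cls;        // 0 noncoding 1 syn 2 missense 3 nonsense
  std::vector<double> s;                 // fitness cost (negative = beneficial)
  std::vector<double> h;                 // dominance
  size_t size() const { return pos.size(); }
};

struct Hap {
  std::vector<int> mut;                  // positions of carried mutations, sorted
  std::vector<int> sel;                  // subset with s != 0, sorted
  void clear() { mut.clear(); sel.clear(); }
};

static int sample_weighted(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
}

struct Sim {
  int L;
  RawMatrix eff;                          // 3 x L effect lookup
  double mu, rec, dfe_shape, dfe_scale, h_default, s_max;
  MutTab mt;
  std::vector<bool> used;                 // position occupied (segregating or fixed)
  std::vector<int> site2id;               // position -> mutation id (-1 none)
  std::vector<Hap> pop[2], nxt[2];        // current and scratch generations
  std::vector<int> free_ids;
  std::vector<int> bp;                    // crossover scratch

  Sim(int L_, RawMatrix eff_, double mu_, double rec_, double sh, double sc,
      double h_, double smax)
      : L(L_), eff(eff_), mu(mu_), rec(rec_), dfe_shape(sh), dfe_scale(sc),
        h_default(h_), s_max(smax), used(L_, false), site2id(L_, -1) {}

  int new_mut(int p_site, unsigned char a, unsigned char c, double s_,
              double h_) {
    int id;
    if (!free_ids.empty()) {
      id = free_ids.back();
      free_ids.pop_back();
      mt.pos[id] = p_site; mt.alt[id] = a; mt.cls[id] = c;
      mt.s[id] = s_; mt.h[id] = h_;
    } else {
      id = (int)mt.size();
      mt.pos.push_back(p_site); mt.alt.push_back(a); mt.cls.push_back(c);
      mt.s.push_back(s_); mt.h.push_back(h_);
    }
    used[p_site] = true;
    site2id[p_site] = id;
    return id;
  }

  static void insert_sorted(std::vector<int>& v, int p_site) {
    v.insert(std::lower_bound(v.begin(), v.end(), p_site), p_site);
  }

  void place_mutation(Hap& hp, int id) {
    insert_sorted(hp.mut, mt.pos[id]);
    if (mt.s[id] != 0.0) insert_sorted(hp.sel, mt.pos[id]);
  }

  // recombinant gamete from parent haplotypes a and b into out
  void make_gamete(const Hap& a, const Hap& b, Hap& out) {
    out.clear();
    int k = (int)R::rpois(rec * (L - 1));
    if (k == 0) {
      const Hap& src = (unif_rand() < 0.5) ? a : b;
      out.mut = src.mut;
      out.sel = src.sel;
      return;
    }
    bp.resize(k);
    for (int i = 0; i < k; ++i) bp[i] = 1 + (int)(unif_rand() * (L - 1));
    std::sort(bp.begin(), bp.end());
    bp.push_back(L);
    const Hap* cur = (unif_rand() < 0.5) ? &a : &b;
    const Hap* oth = (cur == &a) ? &b : &a;
    out.mut.reserve(std::max(a.mut.size(), b.mut.size()) + 8);
    int lo = 0;
    for (size_t seg = 0; seg < bp.size(); ++seg) {
      int hi = bp[seg];
      std::vector<int>::const_iterator it = std::lower_bound(
          cur->mut.begin(), cur->mut.end(), lo);
      std::vector<int>::const_iterator ie = std::lower_bound(
          it, cur->mut.end(), hi);
      out.mut.insert(out.mut.end(), it, ie);
      if (!cur->sel.empty()) {
        std::vector<int>::const_iterator is = std::lower_bound(
            cur->sel.begin(), cur->sel.end(), lo);
        std::vector<int>::const_iterator se = std::lower_bound(
            is, cur->sel.end(), hi);
        out.sel.insert(out.sel.end(), is, se);
      }
      std::swap(cur, oth);
      lo = hi;
    }
  }

  // multiplicative fitness of diploid (ha, hb) over selected mutations
  double fitness_of(const Hap& ha, const Hap& hb) const {
    if (ha.sel.empty() && hb.sel.empty()) return 1.0;
    double w = 1.0;
    size_t i = 0, j = 0;
    const std::vector<int>& A = ha.sel;
    const std::vector<int>& B = hb.sel;
    while (i < A.size() || j < B.size()) {
      if (j >= B.size() || (i < A.size() && A[i] < B[j])) {
        int id = site2id[A[i]];
        w *= 1.0 - mt.h[id] * mt.s[id];
        ++i;
      } else if (i >= A.size() || B[j] < A[i]) {
        int id = site2id[B[j]];
        w *= 1.0 - mt.h[id] * mt.s[id];
        ++j;
      } else {                             // homozygous derived
        w *= 1.0 - mt.s[site2id[A[i]]];
        ++i; ++j;
      }
    }
    return (w > 0.0) ? w : 0.0;
  }

  void mutate(int p) {
    int nh = (int)pop[p].size();
    if (nh == 0 || mu <= 0.0) return;
    int nmut = (int)R::rpois((double)nh * mu * (double)L);
    for (int m = 0; m < nmut; ++m) {
      int site, tries = 0;
      do {
        site = (int)(unif_rand() * L);
        if (++tries > 1000000)
          stop("mutation placement failed: contig saturated");
      } while (used[site]);
      unsigned char a = (unsigned char)(unif_rand() * 3.0);
      unsigned char c = eff(a, site);
      double s_ = 0.0;
      if (c >= 2) {
        s_ = R::rgamma(dfe_shape, dfe_scale);
        if (s_ > s_max) s_ = s_max;
      }
      int id = new_mut(site, a, c, s_, h_default);
      place_mutation(pop[p][(int)(unif_rand() * nh)], id);
    }
  }

  void garbage_collect() {
    std::vector<int> count(L, 0);
    int tot = 0;
    for (int p = 0; p < 2; ++p) {
      tot += (int)pop[p].size();
      for (const Hap& hp : pop[p])
        for (int ps : hp.mut) ++count[ps];
    }
    std::vector<bool> fixed_site(L, false);
    bool any_fixed = false;
    for (size_t id = 0; id < mt.size(); ++id) {
      int ps = mt.pos[id];
      if (ps < 0) continue;
      if (count[ps] == 0) {
        used[ps] = false;                  // site reusable
        site2id[ps] = -1;
        free_ids.push_back((int)id);
        mt.pos[id] = -1;
      } else if (count[ps] == tot) {
        fixed_site[ps] = true;
        any_fixed = true;
      }
    }
    if (any_fixed) {
      for (int p = 0; p < 2; ++p)
        for (Hap& hp : pop[p]) {
          hp.mut.erase(std::remove_if(hp.mut.begin(), hp.mut.end(),
                                      [&](int ps) { return fixed_site[ps]; }),
                       hp.mut.end());
          hp.sel.erase(std::remove_if(hp.sel.begin(), hp.sel.end(),
                                      [&](int ps) { return fixed_site[ps]; }),
                       hp.sel.end());
        }
      for (size_t id = 0; id < mt.size(); ++id) {
        int ps = mt.pos[id];
        if (ps >= 0 && fixed_site[ps]) {   // site stays blocked
          site2id[ps] = -1;
          free_ids.push_back((int)id);
          mt.pos[id] = -1;
        }
      }
    }
  }

  // produce the next generation; if from_anc, both populations draw their
  // parents from population 0 (the generation at the split)
  void reproduce(int N1, int N2, double m12, double m21, bool from_anc) {
    int targets[2] = {N1, N2};
    double mig[2] = {m12, m21};
    std::vector<double> cum[2];
    for (int p = 0; p < 2; ++p) {
      int n = (int)pop[p].size() / 2;
      cum[p].resize(n);
      double acc = 0.0;
      for (int i = 0; i < n; ++i) {
        acc += fitness_of(pop[p][2 * i], pop[p][2 * i + 1]);
        cum[p][i] = acc;
      }
      if (n > 0 && !(cum[p][n - 1] > 0.0))
        stop("population %d has zero total fitness", p + 1);
    }
    for (int p = 0; p < 2; ++p) {
      int N = targets[p];
      nxt[p].resize(2 * N);
      for (int i = 0; i < N; ++i) {
        int src = p;
        if (from_anc) src = 0;
        else if (!cum[1 - p].empty() && mig[p] > 0.0 && unif_rand() < mig[p])
          src = 1 - p;
        for (int g = 0; g < 2; ++g) {
          int par = sample_weighted(cum[src]);
          make_gamete(pop[src][2 * par], pop[src][2 * par + 1],
                      nxt[p][2 * i + g]);
        }
      }
    }
    pop[0].swap(nxt[0]);
    pop[1].swap(nxt[1]);
    mutate(0);
    mutate(1);
  }
};

// [[Rcpp::export]]
List cpp_wf_simulate(int L, RawMatrix eff, int n_burn, int N_anc,
                     IntegerVector sizes1, IntegerVector sizes2,
                     double m12, double m21, double mu, double rec,
                     double dfe_shape, double dfe_scale, double h,
                     double s_max, List sweep, int n1, int n2,
                     int gc_interval) {
  if (eff.ncol() != L) stop("effect table must have one column per site");
  if (N_anc < 2) stop("ancestral population extinct (size < 2)");
  Sim sim(L, eff, mu, rec, dfe_shape, dfe_scale, h, s_max);

  sim.pop[0].assign(2 * N_anc, Hap());
  for (int g = 0; g < n_burn; ++g) {
    sim.reproduce(N_anc, 0, 0.0, 0.0, false);
    if ((g + 1) % gc_interval == 0) sim.garbage_collect();
  }

  const int T = sizes1.size();
  bool two_pops = sizes2.size() > 0;
  if (two_pops && sizes2.size() != T)
    stop("post-split size vectors must have equal length");

  int sweep_at = -1, sweep_pos = 0, sweep_copies = 0, sweep_pop = 1;
  double sweep_s = 0.0, sweep_h = 0.5;
  if (sweep.size() > 0) {
    sweep_at = T - as<int>(sweep["t_before_present"]);
    if (sweep_at < 0) stop("sweep older than the split is not supported");
    sweep_pos = as<int>(sweep["pos"]);
    sweep_s = as<double>(sweep["s"]);
    sweep_h = as<double>(sweep["h"]);
    sweep_copies = as<int>(sweep["copies"]);
    sweep_pop = as<int>(sweep["pop"]) - 1;
  }

  for (int t = 0; t < T; ++t) {
    sim.reproduce(sizes1[t], two_pops ? sizes2[t] : 0, m12, m21, t == 0);
    if (sweep_at == t) {
      // place at the nearest unoccupied site if the requested position
      // already segregates
      int place = -1;
      for (int off = 0; off < L; ++off) {
        if (sweep_pos + off < L && !sim.used[sweep_pos + off]) {
          place = sweep_pos + off; break;
        }
        if (sweep_pos - off >= 0 && !sim.used[sweep_pos - off]) {
          place = sweep_pos - off; break;
        }
      }
      if (place < 0) stop("no free site for the sweep mutation");
      sweep_pos = place;
      int id = sim.new_mut(sweep_pos, 0, 2, sweep_s, sweep_h);
      int nh = (int)sim.pop[sweep_pop].size();
      if (sweep_copies > nh) stop("more sweep copies than haplotypes");
      std::vector<int> idx(nh);
      for (int i = 0; i < nh; ++i) idx[i] = i;
      for (int c = 0; c < sweep_copies; ++c) {
        int j = c + (int)(unif_rand() * (nh - c));
        std::swap(idx[c], idx[j]);
        sim.place_mutation(sim.pop[sweep_pop][idx[c]], id);
      }
    }
    if ((t + 1) % gc_interval == 0) sim.garbage_collect();
  }
  sim.garbage_collect();

  // sample diploids without replacement from each population
  int npop1 = (int)sim.pop[0].size() / 2;
  int npop2 = (int)sim.pop[1].size() / 2;
  if (n1 > npop1 || n2 > npop2) stop("sample size exceeds population size");
  std::vector<const Hap*> chosen;
  for (int p = 0; p < 2; ++p) {
    int np = (p == 0) ? npop1 : npop2;
    int ns = (p == 0) ? n1 : n2;
    std::vector<int> idx(np);
    for (int i = 0; i < np; ++i) idx[i] = i;
    for (int c = 0; c < ns; ++c) {
      int j = c + (int)(unif_rand() * (np - c));
      std::swap(idx[c], idx[j]);
    }
    for (int c = 0; c < ns; ++c) {
      chosen.push_back(&sim.pop[p][2 * idx[c]]);
      chosen.push_back(&sim.pop[p][2 * idx[c] + 1]);
    }
  }
  int nh = (int)chosen.size();

  std::vector<int> scount(L, 0);
  for (const Hap* hp : chosen)
    for (int ps : hp->mut) ++scount[ps];
  std::vector<int> keep;                   // segregating site positions
  for (int ps = 0; ps < L; ++ps)
    if (sim.site2id[ps] >= 0 && scount[ps] > 0 && scount[ps] < nh)
      keep.push_back(ps);
  int S = (int)keep.size();
  std::vector<int> col(L, -1);
  for (int k = 0; k < S; ++k) col[keep[k]] = k;

  IntegerMatrix H(S, nh);
  for (int hcol = 0; hcol < nh; ++hcol)
    for (int ps : chosen[hcol]->mut)
      if (col[ps] >= 0) H(col[ps], hcol) = 1;

  IntegerVector pos(S), alt(S), cls(S);
  NumericVector sv(S), hv(S);
  for (int k = 0; k < S; ++k) {
    int id = sim.site2id[keep[k]];
    pos[k] = keep[k];
    alt[k] = sim.mt.alt[id];
    cls[k] = sim.mt.cls[id];
    sv[k] = sim.mt.s[id];
    hv[k] = sim.mt.h[id];
  }
  return List::create(_["pos"] = pos, _["alt"] = alt, _["class"] = cls,
                      _["s"] = sv, _["h"] = hv, _["haplotypes"] = H,
                      _["n_hap"] = nh,
                      _["sweep_pos"] = (sweep.size() > 0) ? sweep_pos : -1);
}
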