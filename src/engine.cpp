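#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <memory>
#include <unordered_map>
using namespace Rcpp;

// Forward Wright-Fisher engine with exact ancestry-segment tracking.
//
// State layout: each haplotype keeps two position-sorted mutation lists
// (selected mutations, which enter fitness, and neutral mutations including
// ancestry markers) plus a run-length ancestry encoding (segment ends +
// origin labels covering [0, L)). List entries carry the position and the
// cached per-locus fitness factors inline. Haplotypes are immutable and
// shared between generations: a gamete with no crossover and no new
// mutation is a pointer copy of its parental haplotype (copy-on-write
// everywhere else), which is what makes low-recombination runs cheap.
// Each haplotype caches the products of its heterozygote and homozygote
// factors: under the within-locus multiplicative scheme additive diploid
// fitness is exactly the product of the two per-haplotype heterozygote
// products, and hemizygous fitness is the homozygote product in every
// dominance mode; other diploid modes use a two-pointer merge over the
// selected lists. All randomness goes through R's RNG so set.seed() in R
// makes runs reproducible.

namespace {

// fast internal generator (xoshiro256++), seeded from R's RNG so that
// set.seed() in R fully determines the run; gamma draws still use R's
// sampler
struct XRng {
  uint64_t s[4];
  void seed_from_R() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x9E3779B97F4A7C15ULL;
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int poisson(double mu) {
    if (mu <= 0) return 0;
    if (mu > 15) return (int)R::rpois(mu); // heavy tail: defer to R
    double lim = std::exp(-mu), p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > lim);
    return k - 1;
  }
};

struct MRef {
  int pos;
  int id;
  float fhet; // heterozygote fitness factor (1 for neutral classes)
  float fhom; // homozygote fitness factor
};

struct Hap {
  std::vector<MRef> sel;              // selected mutations, sorted by position
  std::vector<MRef> neu;              // neutral + marker mutations, sorted by position
  std::vector<int> seg_end;           // ancestry segment ends (bp, exclusive)
  std::vector<unsigned char> seg_org; // origin label per segment (0 recipient, 1 donor)
  double whet, whom;                  // cached products over sel

  Hap() : whet(1.0), whom(1.0) {}

  void reset_segments(int L, unsigned char org) {
    seg_end.assign(1, L);
    seg_org.assign(1, org);
  }
  void recompute_w() {
    whet = whom = 1.0;
    for (size_t i = 0; i < sel.size(); ++i) {
      whet *= sel[i].fhet; whom *= sel[i].fhom;
    }
  }
};

typedef std::shared_ptr<Hap> HapPtr;

struct Ind {
  HapPtr h[2];
  double w;
  unsigned char sex;    // 0 female, 1 male (X mode only)
  unsigned char n_haps; // 2, or 1 for X-mode males
};

struct MutTable {
  std::vector<int> pos;
  std::vector<double> s;          // scaled selection coefficient, <= 0
  std::vector<double> h;          // dominance coefficient
  std::vector<unsigned char> cls; // 0 neutral, 1 nonsynonymous, 2 synonymous, 3 marker
  std::vector<unsigned char> opop;
  std::vector<int> ogen;

  int add(int p, double s_, double h_, unsigned char c, unsigned char op, int g) {
    pos.push_back(p); s.push_back(s_); h.push_back(h_);
    cls.push_back(c); opop.push_back(op); ogen.push_back(g);
    return (int)pos.size() - 1;
  }
  size_t size() const { return pos.size(); }
};

struct Engine {
  // --- configuration ---
  int L;
  std::vector<int> exon_start, exon_end; // merged, sorted
  std::vector<double> exon_cum;          // cumulative exonic bp at exon ends
  double exonic_bp;
  std::vector<int> map_end;              // interval ends, last == L
  std::vector<double> map_rate;          // per-bp crossover probability
  std::vector<double> map_cum;           // cumulative Morgans at interval ends
  double tot_morgans;
  double mu;          // scaled per-bp per-gamete mutation rate
  double ns_frac;     // P(nonsynonymous | exonic)
  double dfe_shape, dfe_scale; // gamma for |s| (already scaled)
  int dominance_mode; // 0 additive, 1 recessive, 2 h(s)
  double hs_h0, hs_k; // h(s) = h0 / (1 - k*s), s <= 0
  int fitness_scheme; // 0 multiplicative-within-locus, 1 textbook additive
  bool neutral_sim;   // force s = 0 everywhere, skip fitness machinery
  bool x_mode;
  bool track_neutral;
  int marker_spacing;
  int prune_every;
  int split_gen, pulse_gen, T;
  double pulse_frac;
  double selfing[3];  // ancestral, recipient, donor
  IntegerMatrix sizes;
  std::vector<char> record_flag;
  bool additive_factorizes; // additive + multiplicative scheme

  // --- state ---
  // hap_pool is declared before the population vectors so that it outlives
  // them: returning haplotypes to the pool on destruction must find it alive
  std::vector<Hap *> hap_pool;
  XRng rng;
  MutTable muts;
  std::vector<Ind> pop[2], nextp[2];
  std::vector<int> occupied;   // infinite-sites guard: occupied iff == occ_epoch
  int occ_epoch;
  std::vector<int> marker_ids;
  std::vector<int> snap_ids;           // ids referenced by the pre-pulse snapshot

  // substitution log
  std::vector<int> sub_id, sub_gen;

  // time series
  std::vector<int> ts_gen, ts_pop, ts_n;
  std::vector<double> ts_w, ts_pi, ts_del, ts_hom;

  // scratch
  std::vector<int> bp_buf;
  std::vector<int> cnt;        // per-id occurrence counts (persistent, zeroed lazily)
  std::vector<int> touched;
  std::vector<double> cw[2];   // cumulative fitness (autosomes)
  std::vector<double> cw_sex[2][2]; // [pop][sex]
  std::vector<int> idx_sex[2][2];

  ~Engine() {
    pop[0].clear(); pop[1].clear(); nextp[0].clear(); nextp[1].clear();
    for (size_t i = 0; i < hap_pool.size(); ++i) delete hap_pool[i];
  }

  // pooled allocation: recycled haplotypes keep their vector capacity
  HapPtr new_hap() {
    Hap *h;
    if (hap_pool.empty()) h = new Hap();
    else {
      h = hap_pool.back(); hap_pool.pop_back();
      h->sel.clear(); h->neu.clear(); h->seg_end.clear(); h->seg_org.clear();
      h->whet = h->whom = 1.0;
    }
    Engine *self = this;
    return HapPtr(h, [self](Hap *p) { self->hap_pool.push_back(p); });
  }
  HapPtr clone_hap(const Hap &src) {
    HapPtr h = new_hap();
    h->sel = src.sel; h->neu = src.neu;
    h->seg_end = src.seg_end; h->seg_org = src.seg_org;
    h->whet = src.whet; h->whom = src.whom;
    return h;
  }

  // ------------------------------------------------------------------
  double mut_h(double s_signed) {
    switch (dominance_mode) {
    case 0: return 0.5;
    case 1: return 0.0;
    default: return hs_h0 / (1.0 - hs_k * s_signed);
    }
  }
  double het_factor_of(double s_, double h_) {
    double f = 1.0 + h_ * s_; // s <= 0
    return f > 0 ? f : 0.0;
  }
  double hom_factor_of(double s_) {
    double sa = -s_;
    double f;
    if (dominance_mode == 1 || fitness_scheme == 1) f = 1.0 - sa;
    else { f = 1.0 - 0.5 * sa; f = f * f; }
    return f > 0 ? f : 0.0;
  }

  double fitness_diploid(const Hap &A, const Hap &B) {
    if (additive_factorizes) return A.whet * B.whet;
    double w = 1.0;
    size_t i = 0, j = 0;
    const size_t na = A.sel.size(), nb = B.sel.size();
    while (i < na && j < nb) {
      const MRef &a = A.sel[i], &b = B.sel[j];
      if (a.id == b.id) { w *= a.fhom; ++i; ++j; }
      else if (a.pos < b.pos || (a.pos == b.pos && a.id < b.id)) { w *= a.fhet; ++i; }
      else { w *= b.fhet; ++j; }
    }
    for (; i < na; ++i) w *= A.sel[i].fhet;
    for (; j < nb; ++j) w *= B.sel[j].fhet;
    return w;
  }

  double fitness_ind(const Ind &ind) {
    if (neutral_sim) return 1.0;
    // dosage compensation: a male carrier has the female homozygote fitness
    if (ind.n_haps == 1) return ind.h[0]->whom;
    return fitness_diploid(*ind.h[0], *ind.h[1]);
  }

  // ------------------------------------------------------------------
  bool in_exon(int p) {
    if (exon_start.empty()) return false;
    size_t k = std::upper_bound(exon_start.begin(), exon_start.end(), p) -
               exon_start.begin();
    if (k == 0) return false;
    return p < exon_end[k - 1];
  }

  // uniform position within exonic sequence
  int exon_position() {
    double u = rng.unif() * exonic_bp;
    size_t k = std::upper_bound(exon_cum.begin(), exon_cum.end(), u) -
               exon_cum.begin();
    if (k >= exon_cum.size()) k = exon_cum.size() - 1;
    double base = (k == 0) ? 0.0 : exon_cum[k - 1];
    int p = exon_start[k] + (int)(u - base);
    if (p >= exon_end[k]) p = exon_end[k] - 1;
    return p;
  }

  int invert_map(double u) {
    // map cumulative-Morgan coordinate to a base-pair position
    size_t k = std::lower_bound(map_cum.begin(), map_cum.end(), u) - map_cum.begin();
    if (k >= map_cum.size()) k = map_cum.size() - 1;
    double cum0 = (k == 0) ? 0.0 : map_cum[k - 1];
    int start = (k == 0) ? 0 : map_end[k - 1];
    double r = map_rate[k];
    int off = (r > 0) ? (int)((u - cum0) / r) : 0;
    int p = start + off;
    if (p >= map_end[k]) p = map_end[k] - 1;
    if (p < 0) p = 0;
    return p;
  }

  void draw_breakpoints() {
    bp_buf.clear();
    if (tot_morgans <= 0) return;
    int k = rng.poisson(tot_morgans);
    for (int i = 0; i < k; ++i) {
      int p = invert_map(rng.unif() * tot_morgans);
      if (p > 0 && p < L) bp_buf.push_back(p);
    }
    std::sort(bp_buf.begin(), bp_buf.end());
    bp_buf.erase(std::unique(bp_buf.begin(), bp_buf.end()), bp_buf.end());
  }

  void copy_segments(const Hap &h, int from, int to, Hap &out) {
    // append ancestry of h over [from, to) to out, merging equal labels
    size_t k = std::upper_bound(h.seg_end.begin(), h.seg_end.end(), from) -
               h.seg_end.begin();
    for (; k < h.seg_end.size(); ++k) {
      int e = std::min(h.seg_end[k], to);
      unsigned char o = h.seg_org[k];
      if (!out.seg_org.empty() && out.seg_org.back() == o) out.seg_end.back() = e;
      else { out.seg_end.push_back(e); out.seg_org.push_back(o); }
      if (h.seg_end[k] >= to) break;
    }
  }

  // crossover product of two parental haplotypes (breakpoints already drawn,
  // bp_buf non-empty)
  HapPtr crossover(const Hap &A, const Hap &B, int cur) {
    HapPtr outp = new_hap();
    Hap &out = *outp;
    const Hap *hp[2] = { &A, &B };
    size_t is[2] = { 0, 0 }, in[2] = { 0, 0 };
    int prev = 0;
    for (size_t j = 0; j <= bp_buf.size(); ++j) {
      int end = (j < bp_buf.size()) ? bp_buf[j] : L;
      const Hap &h = *hp[cur];
      while (is[cur] < h.sel.size() && h.sel[is[cur]].pos < end)
        out.sel.push_back(h.sel[is[cur]++]);
      while (in[cur] < h.neu.size() && h.neu[in[cur]].pos < end)
        out.neu.push_back(h.neu[in[cur]++]);
      int o = 1 - cur;
      while (is[o] < hp[o]->sel.size() && hp[o]->sel[is[o]].pos < end) ++is[o];
      while (in[o] < hp[o]->neu.size() && hp[o]->neu[in[o]].pos < end) ++in[o];
      copy_segments(h, prev, end, out);
      prev = end; cur = o;
    }
    out.recompute_w();
    return outp;
  }

  void insert_sorted(std::vector<MRef> &v, const MRef &m) {
    std::vector<MRef>::iterator it = v.begin();
    while (it != v.end() && it->pos < m.pos) ++it;
    v.insert(it, m);
  }

  void add_one_mutation(int p, unsigned char c, int gen, unsigned char pop_label,
                        Hap &g) {
    double s_ = 0.0, h_ = 0.5;
    if (c == 1 && !neutral_sim) {
      s_ = -R::rgamma(dfe_shape, dfe_scale);
      h_ = mut_h(s_);
    }
    occupied[p] = occ_epoch;
    int id = muts.add(p, s_, h_, c, pop_label, gen);
    MRef m;
    m.pos = p; m.id = id;
    if (s_ < 0) {
      m.fhet = (float)het_factor_of(s_, h_);
      m.fhom = (float)hom_factor_of(s_);
      g.whet *= m.fhet; g.whom *= m.fhom;
      insert_sorted(g.sel, m);
    } else {
      m.fhet = 1.0f; m.fhom = 1.0f;
      insert_sorted(g.neu, m);
    }
  }

  // number of new mutations for one gamete (thinned when neutral classes
  // are not tracked: only exonic nonsynonymous mutations are retained)
  int draw_mutation_count() {
    if (mu <= 0) return 0;
    if (neutral_sim && !track_neutral) return 0; // nothing would be retained
    if (!track_neutral && !neutral_sim)
      return exonic_bp > 0 ? rng.poisson(mu * exonic_bp * ns_frac) : 0;
    return rng.poisson(mu * (double)L);
  }

  void apply_mutations(int n, Hap &g, int gen, unsigned char pop_label) {
    if (!track_neutral && !neutral_sim) {
      for (int i = 0; i < n; ++i) {
        int p = exon_position();
        for (int tries = 0; occupied[p] == occ_epoch && tries < 100; ++tries)
          p = exon_position();
        add_one_mutation(p, 1, gen, pop_label, g);
      }
      return;
    }
    for (int i = 0; i < n; ++i) {
      int p; unsigned char c;
      int tries = 0;
      for (;;) {
        p = (int)(rng.unif() * (double)L);
        if (p >= L) p = L - 1;
        if (in_exon(p)) c = (rng.unif() < ns_frac) ? 1 : 2;
        else c = 0;
        bool keep = (c == 1 && !neutral_sim) || track_neutral;
        if (!keep) { c = 255; break; } // discarded draw, class untracked
        if (occupied[p] != occ_epoch || ++tries > 100) break; // infinite sites: redraw on collision
      }
      if (c == 255) continue;
      add_one_mutation(p, c, gen, pop_label, g);
    }
  }

  // recombined, mutated gamete from a diploid parent; shares the parental
  // haplotype when there is neither crossover nor new mutation
  HapPtr make_gamete(const Ind &parent, int t, unsigned char pop_label) {
    draw_breakpoints();
    int cur = (rng.unif() < 0.5) ? 0 : 1;
    int nmut = draw_mutation_count();
    if (bp_buf.empty()) {
      HapPtr g = parent.h[cur];
      if (nmut == 0) return g;              // plain transmission
      HapPtr outp = clone_hap(*g); // copy-on-write
      apply_mutations(nmut, *outp, t, pop_label);
      return outp;
    }
    HapPtr outp = crossover(*parent.h[0], *parent.h[1], cur);
    if (nmut > 0) apply_mutations(nmut, *outp, t, pop_label);
    return outp;
  }

  // ------------------------------------------------------------------
  void build_weights(int t) {
    for (int p = 0; p < 2; ++p) {
      size_t n = pop[p].size();
      if (!x_mode) {
        cw[p].resize(n);
        double acc = 0;
        for (size_t i = 0; i < n; ++i) { acc += pop[p][i].w; cw[p][i] = acc; }
        if (n > 0 && !(acc > 0))
          stop("all individuals in a parent pool have zero fitness (generation %d)", t);
      } else {
        for (int sx = 0; sx < 2; ++sx) { idx_sex[p][sx].clear(); cw_sex[p][sx].clear(); }
        for (size_t i = 0; i < n; ++i) idx_sex[p][pop[p][i].sex].push_back((int)i);
        for (int sx = 0; sx < 2; ++sx) {
          double acc = 0;
          for (size_t i = 0; i < idx_sex[p][sx].size(); ++i) {
            acc += pop[p][idx_sex[p][sx][i]].w;
            cw_sex[p][sx].push_back(acc);
          }
          if (!idx_sex[p][sx].empty() && !(acc > 0))
            stop("all individuals of one sex have zero fitness (generation %d)", t);
        }
      }
    }
  }

  int sample_weighted(const std::vector<double> &c) {
    double tot = c.back();
    double u = rng.unif() * tot;
    return (int)(std::lower_bound(c.begin(), c.end(), u) - c.begin());
  }

  int sample_parent(int pool) {
    size_t n = pop[pool].size();
    if (neutral_sim) { int i = (int)(rng.unif() * (double)n); return i >= (int)n ? (int)n - 1 : i; }
    return sample_weighted(cw[pool]);
  }

  int sample_parent_sex(int pool, int sx) {
    size_t n = idx_sex[pool][sx].size();
    if (n == 0) stop("no parents of required sex available");
    int i;
    if (neutral_sim) { i = (int)(rng.unif() * (double)n); if (i >= (int)n) i = (int)n - 1; }
    else i = sample_weighted(cw_sex[pool][sx]);
    return idx_sex[pool][sx][i];
  }

  // choose parent pool for one parent of an offspring in population p at time t
  int parent_pool(int p, int t) {
    if (t == pulse_gen && p == 0 && rng.unif() < pulse_frac) return 1;
    if (sizes(t - 1, p) > 0) return p;
    return 0; // population being founded (the split generation)
  }

  void relabel_at_split(Ind &child, int p) {
    // ancestry labels are defined from the split onward
    for (int k = 0; k < child.n_haps; ++k) {
      if (child.h[k].use_count() > 1)
        child.h[k] = clone_hap(*child.h[k]);
      child.h[k]->reset_segments(L, (unsigned char)p);
    }
  }

  void make_offspring_autosomal(int p, int t, Ind &child) {
    double sp = (t <= split_gen) ? selfing[0] : selfing[1 + p];
    int poolA = parent_pool(p, t);
    const Ind *pa, *pb;
    if (sp > 0 && rng.unif() < sp) {
      pa = pb = &pop[poolA][sample_parent(poolA)];
    } else {
      int poolB = parent_pool(p, t);
      pa = &pop[poolA][sample_parent(poolA)];
      pb = &pop[poolB][sample_parent(poolB)];
    }
    child.n_haps = 2; child.sex = 0;
    child.h[0] = make_gamete(*pa, t, (unsigned char)p);
    child.h[1] = make_gamete(*pb, t, (unsigned char)p);
    if (t == split_gen) relabel_at_split(child, p);
    child.w = fitness_ind(child);
  }

  void make_offspring_x(int p, int t, int i, Ind &child) {
    int poolM = parent_pool(p, t), poolF = parent_pool(p, t);
    const Ind &mom = pop[poolM][sample_parent_sex(poolM, 0)];
    const Ind &dad = pop[poolF][sample_parent_sex(poolF, 1)];
    child.sex = (unsigned char)(i % 2); // alternate: even index female
    child.h[0] = make_gamete(mom, t, (unsigned char)p);
    if (child.sex == 0) { // daughter: paternal X transmitted without recombination
      child.n_haps = 2;
      HapPtr g = dad.h[0];
      int nmut = draw_mutation_count();
      if (nmut > 0) {
        g = clone_hap(*g);
        apply_mutations(nmut, *g, t, (unsigned char)p);
      }
      child.h[1] = g;
    } else {
      child.n_haps = 1;
      child.h[1].reset();
    }
    if (t == split_gen) relabel_at_split(child, p);
    child.w = fitness_ind(child);
  }

  // ------------------------------------------------------------------
  size_t count_haps() {
    size_t n = 0;
    for (int p = 0; p < 2; ++p)
      for (size_t i = 0; i < pop[p].size(); ++i) n += pop[p][i].n_haps;
    return n;
  }

  void prune_fixed(int t) {
    size_t nh = count_haps();
    if (nh == 0 || muts.size() == 0) return;
    cnt.resize(muts.size(), 0);
    touched.clear();
    // unique haplotype instances and their multiplicities
    std::unordered_map<Hap *, int> uniq;
    uniq.reserve(nh * 2);
    for (int p = 0; p < 2; ++p)
      for (size_t i = 0; i < pop[p].size(); ++i)
        for (int k = 0; k < pop[p][i].n_haps; ++k)
          ++uniq[pop[p][i].h[k].get()];
    for (std::unordered_map<Hap *, int>::iterator it = uniq.begin();
         it != uniq.end(); ++it) {
      const Hap &h = *it->first;
      int mult = it->second;
      for (size_t j = 0; j < h.sel.size(); ++j) {
        int id = h.sel[j].id;
        if (cnt[id] == 0) touched.push_back(id);
        cnt[id] += mult;
      }
      for (size_t j = 0; j < h.neu.size(); ++j) {
        int id = h.neu[j].id;
        if (cnt[id] == 0) touched.push_back(id);
        cnt[id] += mult;
      }
    }
    bool any = false;
    ++occ_epoch;
    for (size_t ti = 0; ti < touched.size(); ++ti) {
      int id = touched[ti];
      if (cnt[id] == (int)nh && muts.cls[id] != 3) {
        any = true;
        sub_id.push_back(id); sub_gen.push_back(t);
        cnt[id] = -1; // mark fixed
      } else {
        occupied[muts.pos[id]] = occ_epoch;
      }
    }
    if (any) {
      for (std::unordered_map<Hap *, int>::iterator it = uniq.begin();
           it != uniq.end(); ++it) {
        Hap &h = *it->first;
        size_t before = h.sel.size();
        h.sel.erase(std::remove_if(h.sel.begin(), h.sel.end(),
                    [&](const MRef &m) { return cnt[m.id] == -1; }), h.sel.end());
        h.neu.erase(std::remove_if(h.neu.begin(), h.neu.end(),
                    [&](const MRef &m) { return cnt[m.id] == -1; }), h.neu.end());
        if (h.sel.size() != before) h.recompute_w();
      }
      if (!neutral_sim)
        for (int p = 0; p < 2; ++p)
          for (size_t i = 0; i < pop[p].size(); ++i)
            pop[p][i].w = fitness_ind(pop[p][i]);
    }
    for (size_t ti = 0; ti < touched.size(); ++ti) cnt[touched[ti]] = 0;
  }

  void place_markers(int t) {
    if (marker_spacing <= 0) return;
    marker_ids.clear();
    std::vector<MRef> mrefs;
    for (int p = 0; p < L; p += marker_spacing) {
      int id = muts.add(p, 0.0, 0.5, 3, 1, t);
      marker_ids.push_back(id);
      MRef m; m.pos = p; m.id = id; m.fhet = 1.0f; m.fhom = 1.0f;
      mrefs.push_back(m);
    }
    // clone-on-write per unique source haplotype (a haplotype may still be
    // shared with recipient individuals, which must not receive markers)
    std::unordered_map<Hap *, HapPtr> memo;
    for (size_t i = 0; i < pop[1].size(); ++i)
      for (int k = 0; k < pop[1][i].n_haps; ++k) {
        HapPtr &slot = pop[1][i].h[k];
        std::unordered_map<Hap *, HapPtr>::iterator hit = memo.find(slot.get());
        if (hit != memo.end()) { slot = hit->second; continue; }
        HapPtr marked = clone_hap(*slot);
        std::vector<MRef> merged;
        merged.reserve(marked->neu.size() + mrefs.size());
        size_t a = 0, b = 0;
        while (a < marked->neu.size() && b < mrefs.size()) {
          if (marked->neu[a].pos <= mrefs[b].pos) merged.push_back(marked->neu[a++]);
          else merged.push_back(mrefs[b++]);
        }
        while (a < marked->neu.size()) merged.push_back(marked->neu[a++]);
        while (b < mrefs.size()) merged.push_back(mrefs[b++]);
        marked->neu.swap(merged);
        memo[slot.get()] = marked;
        slot = marked;
      }
  }

  double donor_fraction_pop0() {
    double donor_bp = 0; size_t nh = 0;
    for (size_t i = 0; i < pop[0].size(); ++i)
      for (int k = 0; k < pop[0][i].n_haps; ++k) {
        const Hap &h = *pop[0][i].h[k];
        int prev = 0;
        for (size_t j = 0; j < h.seg_end.size(); ++j) {
          if (h.seg_org[j] == 1) donor_bp += h.seg_end[j] - prev;
          prev = h.seg_end[j];
        }
        ++nh;
      }
    if (nh == 0) return NA_REAL;
    return donor_bp / ((double)L * (double)nh);
  }

  void record(int t) {
    for (int p = 0; p < 2; ++p) {
      size_t n = pop[p].size();
      if (n == 0) continue;
      double sw = 0, sdel = 0, shom = 0; size_t nh = 0;
      for (size_t i = 0; i < n; ++i) {
        const Ind &ind = pop[p][i];
        sw += ind.w;
        for (int k = 0; k < ind.n_haps; ++k) { sdel += ind.h[k]->sel.size(); ++nh; }
        if (ind.n_haps == 2) { // homozygous derived deleterious sites
          size_t a = 0, b = 0;
          const std::vector<MRef> &A = ind.h[0]->sel, &B = ind.h[1]->sel;
          while (a < A.size() && b < B.size()) {
            if (A[a].id == B[b].id) { ++shom; ++a; ++b; }
            else if (A[a].pos < B[b].pos ||
                     (A[a].pos == B[b].pos && A[a].id < B[b].id)) ++a;
            else ++b;
          }
        } else { shom += ind.h[0]->sel.size(); } // hemizygous males expose every allele
      }
      ts_gen.push_back(t); ts_pop.push_back(p); ts_n.push_back((int)n);
      ts_w.push_back(sw / n);
      ts_pi.push_back(p == 0 && t >= split_gen ? donor_fraction_pop0() : (p == 0 ? 0.0 : NA_REAL));
      ts_del.push_back(sdel / (double)nh);
      ts_hom.push_back(shom / (double)n);
    }
  }

  // ------------------------------------------------------------------
  List export_state(std::vector<int> *id_log) {
    size_t nh = count_haps();
    IntegerVector hp_pop(nh), hp_ind(nh), hp_which(nh), hp_sex(nh), seg_count(nh);
    List hap_muts(nh);
    std::vector<int> seg_end_all; std::vector<int> seg_org_all;
    size_t r = 0;
    for (int p = 0; p < 2; ++p)
      for (size_t i = 0; i < pop[p].size(); ++i)
        for (int k = 0; k < pop[p][i].n_haps; ++k) {
          const Hap &h = *pop[p][i].h[k];
          hp_pop[r] = p; hp_ind[r] = (int)i + 1; hp_which[r] = k + 1;
          hp_sex[r] = pop[p][i].sex;
          std::vector<int> ids;
          ids.reserve(h.sel.size() + h.neu.size());
          size_t a = 0, b = 0;
          while (a < h.sel.size() && b < h.neu.size()) {
            if (h.sel[a].pos <= h.neu[b].pos) ids.push_back(h.sel[a++].id);
            else ids.push_back(h.neu[b++].id);
          }
          while (a < h.sel.size()) ids.push_back(h.sel[a++].id);
          while (b < h.neu.size()) ids.push_back(h.neu[b++].id);
          if (id_log)
            id_log->insert(id_log->end(), ids.begin(), ids.end());
          hap_muts[r] = IntegerVector(ids.begin(), ids.end());
          seg_count[r] = (int)h.seg_end.size();
          for (size_t j = 0; j < h.seg_end.size(); ++j) {
            seg_end_all.push_back(h.seg_end[j]);
            seg_org_all.push_back(h.seg_org[j]);
          }
          ++r;
        }
    return List::create(
      _["pop"] = hp_pop, _["ind"] = hp_ind, _["which"] = hp_which,
      _["sex"] = hp_sex, _["hap_muts"] = hap_muts,
      _["seg_count"] = seg_count,
      _["seg_end"] = IntegerVector(seg_end_all.begin(), seg_end_all.end()),
      _["seg_org"] = IntegerVector(seg_org_all.begin(), seg_org_all.end()));
  }

  // export table rows for ids referenced by exported states or markers
  List export_mut_table(std::vector<int> &live_ids) {
    live_ids.insert(live_ids.end(), marker_ids.begin(), marker_ids.end());
    live_ids.insert(live_ids.end(), snap_ids.begin(), snap_ids.end());
    std::sort(live_ids.begin(), live_ids.end());
    live_ids.erase(std::unique(live_ids.begin(), live_ids.end()), live_ids.end());
    size_t n = live_ids.size();
    IntegerVector id(n), posv(n), ogen(n);
    NumericVector sv(n), hv(n);
    IntegerVector clsv(n), opop(n);
    for (size_t i = 0; i < n; ++i) {
      int k = live_ids[i];
      id[i] = k; posv[i] = muts.pos[k]; sv[i] = muts.s[k]; hv[i] = muts.h[k];
      clsv[i] = muts.cls[k]; opop[i] = muts.opop[k]; ogen[i] = muts.ogen[k];
    }
    return List::create(_["id"] = id, _["pos"] = posv, _["s"] = sv, _["h"] = hv,
                        _["cls"] = clsv, _["origin_pop"] = opop, _["origin_gen"] = ogen);
  }

  List export_substitutions() {
    size_t n = sub_id.size();
    IntegerVector id(n), posv(n), gen(n), ogen(n);
    NumericVector sv(n);
    IntegerVector clsv(n);
    for (size_t i = 0; i < n; ++i) {
      int k = sub_id[i];
      id[i] = k; posv[i] = muts.pos[k]; sv[i] = muts.s[k];
      clsv[i] = muts.cls[k]; gen[i] = sub_gen[i]; ogen[i] = muts.ogen[k];
    }
    return List::create(_["id"] = id, _["pos"] = posv, _["s"] = sv,
                        _["cls"] = clsv, _["origin_gen"] = ogen,
                        _["gen_fixed"] = gen);
  }
};

} // namespace

// [[Rcpp::export]]
List run_wf_cpp(List par) {
  Engine e;
  e.L = as<int>(par["L"]);
  e.exon_start = as<std::vector<int> >(par["exon_start"]);
  e.exon_end = as<std::vector<int> >(par["exon_end"]);
  e.map_end = as<std::vector<int> >(par["map_end"]);
  e.map_rate = as<std::vector<double> >(par["map_rate"]);
  e.mu = as<double>(par["mu"]);
  e.ns_frac = as<double>(par["ns_frac"]);
  e.dfe_shape = as<double>(par["dfe_shape"]);
  e.dfe_scale = as<double>(par["dfe_scale"]);
  e.dominance_mode = as<int>(par["dominance_mode"]);
  e.hs_h0 = as<double>(par["hs_h0"]);
  e.hs_k = as<double>(par["hs_k"]);
  e.fitness_scheme = as<int>(par["fitness_scheme"]);
  e.neutral_sim = as<bool>(par["neutral_sim"]);
  e.x_mode = as<bool>(par["x_mode"]);
  e.track_neutral = as<bool>(par["track_neutral"]);
  e.marker_spacing = as<int>(par["marker_spacing"]);
  e.prune_every = as<int>(par["prune_every"]);
  e.split_gen = as<int>(par["split_gen"]);
  e.pulse_gen = as<int>(par["pulse_gen"]);
  e.pulse_frac = as<double>(par["pulse_frac"]);
  NumericVector sf = par["selfing"];
  e.selfing[0] = sf[0]; e.selfing[1] = sf[1]; e.selfing[2] = sf[2];
  e.sizes = as<IntegerMatrix>(par["sizes"]);
  e.T = e.sizes.nrow() - 1;
  e.additive_factorizes = (e.dominance_mode == 0 && e.fitness_scheme == 0);
  bool snapshot_prepulse = as<bool>(par["snapshot_prepulse"]);
  bool export_final = as<bool>(par["export_final"]);

  IntegerVector rec = par["record_gens"];
  e.record_flag.assign(e.T + 1, 0);
  for (int i = 0; i < rec.size(); ++i)
    if (rec[i] >= 0 && rec[i] <= e.T) e.record_flag[rec[i]] = 1;

  // cumulative exonic length
  e.exon_cum.resize(e.exon_start.size());
  double exacc = 0;
  for (size_t i = 0; i < e.exon_start.size(); ++i) {
    exacc += e.exon_end[i] - e.exon_start[i];
    e.exon_cum[i] = exacc;
  }
  e.exonic_bp = exacc;

  // cumulative Morgans
  e.map_cum.resize(e.map_rate.size());
  double acc = 0; int prev = 0;
  for (size_t i = 0; i < e.map_rate.size(); ++i) {
    acc += e.map_rate[i] * (e.map_end[i] - prev);
    e.map_cum[i] = acc; prev = e.map_end[i];
  }
  e.tot_morgans = acc;
  e.occupied.assign(e.L, 0);
  e.occ_epoch = 1;
  e.rng.seed_from_R();

  // founders: mutation-free, fully "recipient"-labeled
  int n0 = e.sizes(0, 0);
  e.pop[0].resize(n0);
  {
    HapPtr blank = e.new_hap();
    blank->reset_segments(e.L, 0);
    for (int i = 0; i < n0; ++i) {
      Ind &ind = e.pop[0][i];
      ind.sex = (unsigned char)(e.x_mode ? (i % 2) : 0);
      ind.n_haps = (unsigned char)((e.x_mode && ind.sex == 1) ? 1 : 2);
      for (int k = 0; k < ind.n_haps; ++k) ind.h[k] = blank;
      ind.w = 1.0;
    }
  }
  if (e.record_flag[0]) e.record(0);

  List snapshot = R_NilValue;

  for (int t = 1; t <= e.T; ++t) {
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
    if (!e.neutral_sim || e.x_mode) e.build_weights(t);
    for (int p = 0; p < 2; ++p) {
      int n = e.sizes(t, p);
      e.nextp[p].resize(n);
      for (int i = 0; i < n; ++i) {
        if (e.x_mode) e.make_offspring_x(p, t, i, e.nextp[p][i]);
        else e.make_offspring_autosomal(p, t, e.nextp[p][i]);
      }
    }
    std::swap(e.pop[0], e.nextp[0]);
    std::swap(e.pop[1], e.nextp[1]);
    e.nextp[0].clear(); e.nextp[1].clear(); // release references promptly

    bool rec_now = e.record_flag[t] != 0;
    if (t % e.prune_every == 0 || rec_now || t == e.T) e.prune_fixed(t);
    if (t == e.pulse_gen - 1) {
      e.place_markers(t);
      if (snapshot_prepulse) snapshot = e.export_state(&e.snap_ids);
    }
    if (rec_now) e.record(t);
  }

  std::vector<int> live_ids;
  List final_state = R_NilValue;
  if (export_final) final_state = e.export_state(&live_ids);
  List out = List::create(
    _["timeseries"] = List::create(
      _["gen"] = IntegerVector(e.ts_gen.begin(), e.ts_gen.end()),
      _["pop"] = IntegerVector(e.ts_pop.begin(), e.ts_pop.end()),
      _["n"] = IntegerVector(e.ts_n.begin(), e.ts_n.end()),
      _["mean_w"] = NumericVector(e.ts_w.begin(), e.ts_w.end()),
      _["p_I"] = NumericVector(e.ts_pi.begin(), e.ts_pi.end()),
      _["del_per_hap"] = NumericVector(e.ts_del.begin(), e.ts_del.end()),
      _["hom_per_ind"] = NumericVector(e.ts_hom.begin(), e.ts_hom.end())),
    _["mutations"] = e.export_mut_table(live_ids),
    _["final"] = final_state,
    _["snapshot"] = snapshot,
    _["substitutions"] = e.export_substitutions(),
    _["marker_ids"] = IntegerVector(e.marker_ids.begin(), e.marker_ids.end()),
    _["final_gen"] = e.T);
  return out;
}
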