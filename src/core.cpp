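// Simulation core: toy folding engine, structure decomposition, catalytic site
// detection, and the lattice generation loop. All stochastic draws use R's RNG
// (unif_rand) so that set.seed() in R governs the whole simulation.
#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline char complement_base(char b) {
  switch (b) {
    case 'A': return 'U';
    case 'U': return 'A';
    case 'G': return 'C';
    case 'C': return 'G';
  }
  return 'N';
}

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// ---------------------------------------------------------------------------
// Toy folding backend: base-pair maximization (Watson-Crick + GU wobble),
// minimum hairpin loop of 3 unpaired bases, energy -1 kcal/mol per pair.
// Ties are broken deterministically: an unpaired 3' base is preferred, then
// the 5'-most admissible pairing partner.
// ---------------------------------------------------------------------------
static std::string nussinov_structure(const std::string& s) {
  const int n = (int)s.size();
  std::string db(n, '.');
  if (n < 6) return db;
  std::vector<std::vector<int> > N(n, std::vector<int>(n, 0));
  for (int len = 6; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = N[i][j - 1];
      for (int k = i; k <= j - 4; ++k) {
        if (!can_pair(s[k], s[j])) continue;
        int v = (k > i ? N[i][k - 1] : 0) + N[k + 1][j - 1] + 1;
        if (v > best) best = v;
      }
      N[i][j] = best;
    }
  }
  std::vector<std::pair<int, int> > todo;
  todo.push_back(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.back().first, j = todo.back().second;
    todo.pop_back();
    if (j - i < 4) continue;
    if (N[i][j] == N[i][j - 1]) {
      todo.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - 4; ++k) {
      if (!can_pair(s[k], s[j])) continue;
      int v = (k > i ? N[i][k - 1] : 0) + N[k + 1][j - 1] + 1;
      if (v == N[i][j]) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) todo.push_back(std::make_pair(i, k - 1));
        todo.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return db;
}

static double toy_energy(const std::string& db) {
  int pairs = 0;
  for (size_t i = 0; i < db.size(); ++i)
    if (db[i] == '(') ++pairs;
  return -1.0 * pairs;
}

// [[Rcpp::export]]
List cpp_fold_toy(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector structure(n);
  NumericVector energy(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string db = nussinov_structure(s);
    structure[i] = db;
    energy[i] = toy_energy(db);
  }
  return List::create(_["structure"] = structure, _["energy"] = energy);
}

// ---------------------------------------------------------------------------
// Structure decomposition. Position classes: 0 = paired, 1 = hairpin-loop
// member, 2 = other-unpaired (exterior, bulge, interior, multiloop).
// A hairpin loop is a maximal unpaired run directly enclosed by a base pair.
// ---------------------------------------------------------------------------
struct ParsedStructure {
  std::vector<int> pair;   // 0-based partner, -1 unpaired
  std::vector<int> cls;    // 0/1/2 as above
  std::vector<int> loop_start, loop_end;  // 0-based, inclusive
};

static bool parse_db(const std::string& db, ParsedStructure& P) {
  const int n = (int)db.size();
  P.pair.assign(n, -1);
  P.cls.assign(n, 2);
  P.loop_start.clear();
  P.loop_end.clear();
  std::vector<int> st;
  for (int i = 0; i < n; ++i) {
    if (db[i] == '(') {
      st.push_back(i);
    } else if (db[i] == ')') {
      if (st.empty()) return false;
      int k = st.back();
      st.pop_back();
      P.pair[i] = k;
      P.pair[k] = i;
    } else if (db[i] != '.') {
      return false;
    }
  }
  if (!st.empty()) return false;
  for (int i = 0; i < n; ++i)
    if (P.pair[i] >= 0) P.cls[i] = 0;
  for (int i = 0; i < n; ++i) {
    int j = P.pair[i];
    if (j <= i + 1) continue;
    bool hairpin = true;
    for (int k = i + 1; k < j; ++k)
      if (P.pair[k] >= 0) { hairpin = false; break; }
    if (hairpin) {
      P.loop_start.push_back(i + 1);
      P.loop_end.push_back(j - 1);
      for (int k = i + 1; k < j; ++k) P.cls[k] = 1;
    }
  }
  return true;
}

// [[Rcpp::export]]
List cpp_parse_structure(std::string db) {
  ParsedStructure P;
  if (!parse_db(db, P))
    stop("unbalanced or invalid dot-bracket structure: '%s'", db.c_str());
  int n = (int)db.size();
  IntegerVector pair(n), cls(n);
  for (int i = 0; i < n; ++i) {
    pair[i] = P.pair[i] < 0 ? 0 : P.pair[i] + 1;  // 1-based, 0 = unpaired
    cls[i] = P.cls[i];
  }
  int nl = (int)P.loop_start.size();
  IntegerVector ls(nl), le(nl), sz(nl);
  for (int i = 0; i < nl; ++i) {
    ls[i] = P.loop_start[i] + 1;
    le[i] = P.loop_end[i] + 1;
    sz[i] = P.loop_end[i] - P.loop_start[i] + 1;
  }
  return List::create(
      _["pairTable"] = pair, _["class"] = cls,
      _["loops"] = DataFrame::create(_["start"] = ls, _["end"] = le, _["size"] = sz));
}

// ---------------------------------------------------------------------------
// Catalytic site detection
// ---------------------------------------------------------------------------
struct Spec {
  int index;        // activity 1..3
  int context;      // 0 = unpaired-region, 1 = hairpin-loop
  std::string motif;
  int target_loop;
  double mm_factor;
  int max_mm;
  double loop_factor;
  int max_dev;
};

static std::vector<Spec> specs_from_list(List specsList) {
  std::vector<Spec> out;
  for (int i = 0; i < specsList.size(); ++i) {
    List s = specsList[i];
    Spec sp;
    sp.index = as<int>(s["index"]);
    sp.context = as<std::string>(s["context"]) == "hairpin-loop" ? 1 : 0;
    sp.motif = as<std::string>(s["motif"]);
    sp.target_loop = as<int>(s["targetLoopSize"]);
    sp.mm_factor = as<double>(s["mismatchFactor"]);
    sp.max_mm = as<int>(s["maxMismatch"]);
    sp.loop_factor = as<double>(s["loopSizeFactor"]);
    sp.max_dev = as<int>(s["maxLoopDeviation"]);
    out.push_back(sp);
  }
  return out;
}

struct Site {
  int activity, start, end;  // 1-based inclusive
  double alpha;
};

// One site per (activity, structural element): the highest-alpha window, ties
// resolved to the leftmost placement. alpha = 0 candidates are dropped.
static void detect_sites_impl(const std::string& seq, const ParsedStructure& P,
                              const std::vector<Spec>& specs, std::vector<Site>& out) {
  const int n = (int)seq.size();
  for (size_t si = 0; si < specs.size(); ++si) {
    const Spec& sp = specs[si];
    const int w = (int)sp.motif.size();
    if (sp.context == 0) {
      int i = 0;
      while (i < n) {
        if (P.cls[i] != 2) { ++i; continue; }
        int j = i;
        while (j < n && P.cls[j] == 2) ++j;  // maximal run [i, j)
        double best = 0.0;
        int bpos = -1;
        for (int k = i; k + w <= j; ++k) {
          int mm = 0;
          for (int q = 0; q < w; ++q)
            if (seq[k + q] != sp.motif[q]) ++mm;
          if (mm > sp.max_mm) continue;
          double a = std::pow(sp.mm_factor, (double)mm);
          if (a > best) { best = a; bpos = k; }
        }
        if (bpos >= 0 && best > 0.0) {
          Site s = {sp.index, bpos + 1, bpos + w, best};
          out.push_back(s);
        }
        i = j;
      }
    } else {
      for (size_t L = 0; L < P.loop_start.size(); ++L) {
        int ls = P.loop_start[L], le = P.loop_end[L];
        int size = le - ls + 1;
        int dev = std::abs(size - sp.target_loop);
        if (dev > sp.max_dev) continue;
        double sizef = std::pow(sp.loop_factor, (double)dev);
        if (sizef <= 0.0) continue;
        double best = 0.0;
        int bpos = -1;
        for (int k = ls; k + w - 1 <= le; ++k) {
          int mm = 0;
          for (int q = 0; q < w; ++q)
            if (seq[k + q] != sp.motif[q]) ++mm;
          if (mm > sp.max_mm) continue;
          double a = std::pow(sp.mm_factor, (double)mm) * sizef;
          if (a > best) { best = a; bpos = k; }
        }
        if (bpos >= 0 && best > 0.0) {
          Site s = {sp.index, bpos + 1, bpos + w, best};
          out.push_back(s);
        }
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_detect_sites(std::string seq, std::string structure, List specsList) {
  if (seq.size() != structure.size())
    stop("sequence and structure lengths differ");
  ParsedStructure P;
  if (!parse_db(structure, P))
    stop("unbalanced or invalid dot-bracket structure");
  std::vector<Spec> specs = specs_from_list(specsList);
  std::vector<Site> sites;
  detect_sites_impl(seq, P, specs, sites);
  int n = (int)sites.size();
  IntegerVector act(n), st(n), en(n);
  NumericVector al(n);
  for (int i = 0; i < n; ++i) {
    act[i] = sites[i].activity;
    st[i] = sites[i].start;
    en[i] = sites[i].end;
    al[i] = sites[i].alpha;
  }
  return DataFrame::create(_["activity"] = act, _["start"] = st, _["end"] = en,
                           _["alpha"] = al);
}

// ---------------------------------------------------------------------------
// Phenotype annotation
// ---------------------------------------------------------------------------
struct EnergyPar {
  double c, d0, d1, Emin, g, l, b1, b2;
};

static EnergyPar energy_from_list(List e) {
  EnergyPar ep;
  ep.c = as<double>(e["c"]);
  ep.d0 = as<double>(e["delta0"]);
  ep.d1 = as<double>(e["delta1"]);
  ep.Emin = as<double>(e["Emin"]);
  ep.g = as<double>(e["g"]);
  ep.l = as<double>(e["l"]);
  ep.b1 = as<double>(e["b1"]);
  ep.b2 = as<double>(e["b2"]);
  return ep;
}

struct Pheno {
  std::string seq, db;
  double E, pfold, pdeg, R;
  double a[3];
  int sigma;
};

static void annotate_one(const std::string& seq, const std::string& db, double E,
                         const EnergyPar& ep, double m, const std::vector<Spec>& specs,
                         Pheno& ph) {
  ph.seq = seq;
  ph.db = db;
  ph.E = E;
  ph.pfold = 1.0 / (1.0 + std::exp(ep.c * E));
  double Ec = E;
  if (Ec < ep.Emin) Ec = ep.Emin;
  if (Ec > 0.0) Ec = 0.0;
  ph.pdeg = ep.d0 - ep.d1 * Ec / ep.Emin;
  double L = (double)seq.size();
  ph.R = ep.g * (ep.l + (1.0 - ph.pfold)) / (ep.b1 + ep.b2 * L);
  ParsedStructure P;
  parse_db(db, P);
  std::vector<Site> sites;
  detect_sites_impl(seq, P, specs, sites);
  ph.sigma = (int)sites.size();
  double alpha[3] = {0.0, 0.0, 0.0};
  for (size_t i = 0; i < sites.size(); ++i)
    if (sites[i].alpha > alpha[sites[i].activity - 1])
      alpha[sites[i].activity - 1] = sites[i].alpha;
  double pen = ph.sigma > 1 ? std::pow(m, (double)(ph.sigma - 1)) : 1.0;
  for (int i = 0; i < 3; ++i) ph.a[i] = ph.pfold * alpha[i] / pen;
}

// [[Rcpp::export]]
DataFrame cpp_annotate(CharacterVector seqs, CharacterVector structures,
                       NumericVector energies, List energy, double m, List specsList) {
  EnergyPar ep = energy_from_list(energy);
  std::vector<Spec> specs = specs_from_list(specsList);
  int n = seqs.size();
  NumericVector E(n), pfold(n), pdeg(n), R(n), a1(n), a2(n), a3(n);
  IntegerVector sigma(n), len(n);
  for (int i = 0; i < n; ++i) {
    Pheno ph;
    annotate_one(as<std::string>(seqs[i]), as<std::string>(structures[i]),
                 energies[i], ep, m, specs, ph);
    E[i] = ph.E;
    pfold[i] = ph.pfold;
    pdeg[i] = ph.pdeg;
    R[i] = ph.R;
    a1[i] = ph.a[0];
    a2[i] = ph.a[1];
    a3[i] = ph.a[2];
    sigma[i] = ph.sigma;
    len[i] = (int)ph.seq.size();
  }
  return DataFrame::create(_["length"] = len, _["energy"] = E, _["pfold"] = pfold,
                           _["pdeg"] = pdeg, _["R"] = R, _["a1"] = a1, _["a2"] = a2,
                           _["a3"] = a3, _["sigma"] = sigma);
}

// ---------------------------------------------------------------------------
// Toffoli-Margolus diffusion: alternating 2x2 block partition, each block
// rotated 90 degrees clockwise or counter-clockwise with probability 1/2.
// ---------------------------------------------------------------------------
template <typename T>
static inline void rotate_block(std::vector<T>& v, int a, int b, int c, int d, bool cw) {
  // a = top-left, b = top-right, c = bottom-left, d = bottom-right
  if (cw) {  // a->b->d->c->a
    T t = v[b]; v[b] = v[a]; v[a] = v[c]; v[c] = v[d]; v[d] = t;
  } else {   // a->c->d->b->a
    T t = v[a]; v[a] = v[b]; v[b] = v[d]; v[d] = v[c]; v[c] = t;
  }
}

struct FieldSet {
  std::vector<int>* grid;
  std::vector<double>* A0;
  std::vector<double>* A1;
  std::vector<double>* A2;
};

static void margolus_sweep(FieldSet& F, int W, int H, int parity) {
  int off = parity & 1;
  for (int by = 0; by < H / 2; ++by) {
    for (int bx = 0; bx < W / 2; ++bx) {
      int x0 = (2 * bx + off) % W, y0 = (2 * by + off) % H;
      int x1 = (x0 + 1) % W, y1 = (y0 + 1) % H;
      int a = y0 * W + x0, b = y0 * W + x1, c = y1 * W + x0, d = y1 * W + x1;
      bool cw = unif_rand() < 0.5;
      rotate_block(*F.grid, a, b, c, d, cw);
      if (F.A0) {
        rotate_block(*F.A0, a, b, c, d, cw);
        rotate_block(*F.A1, a, b, c, d, cw);
        rotate_block(*F.A2, a, b, c, d, cw);
      }
    }
  }
}

static int n_sweeps(double D) {
  int ns = (int)std::floor(D);
  if (unif_rand() < D - ns) ++ns;
  return ns;
}

// [[Rcpp::export]]
List cpp_diffuse(IntegerVector grid, int W, int H, double D, int parity) {
  if (W % 2 != 0 || H % 2 != 0)
    stop("Margolus diffusion requires even grid dimensions (got %d x %d)", W, H);
  if ((int)grid.size() != W * H) stop("grid length does not match dimensions");
  std::vector<int> g(grid.begin(), grid.end());
  FieldSet F = {&g, 0, 0, 0};
  int ns = n_sweeps(D);
  for (int s = 0; s < ns; ++s) {
    margolus_sweep(F, W, H, parity);
    ++parity;
  }
  IntegerVector out(g.begin(), g.end());
  return List::create(_["grid"] = out, _["parity"] = parity, _["sweeps"] = ns);
}

// ---------------------------------------------------------------------------
// The generation loop
// ---------------------------------------------------------------------------
struct SimPar {
  double Ce, D, psub, pins, pdel, m;
  int h, rr, minL, maxL;
};

static SimPar simpar_from_list(List p) {
  SimPar sp;
  sp.Ce = as<double>(p["Ce"]);
  sp.D = as<double>(p["D"]);
  sp.psub = as<double>(p["pSub"]);
  sp.pins = as<double>(p["pIns"]);
  sp.pdel = as<double>(p["pDel"]);
  sp.m = as<double>(p["m"]);
  sp.h = as<int>(p["h"]);
  sp.rr = as<int>(p["rr"]);
  sp.minL = as<int>(p["minLength"]);
  sp.maxL = as<int>(p["maxLength"]);
  return sp;
}

struct EventRow {
  int deaths, reps, failed, subs, ins, dels;
  EventRow() : deaths(0), reps(0), failed(0), subs(0), ins(0), dels(0) {}
};

class Engine {
 public:
  int W, H;
  std::vector<int> grid;  // species id, -1 empty
  std::vector<double> A0, A1, A2;
  std::vector<Pheno> species;
  std::unordered_map<std::string, int> sindex;
  std::unordered_map<std::string, std::pair<std::string, double> > fold_cache;
  EnergyPar ep;
  SimPar sp;
  std::vector<Spec> specs;
  bool use_toy;
  Function fold_fun;
  int parity;

  Engine(Function f) : fold_fun(f) {}

  int intern(const std::string& seq) {
    std::unordered_map<std::string, int>::iterator it = sindex.find(seq);
    if (it != sindex.end()) return it->second;
    std::string db;
    double E;
    std::unordered_map<std::string, std::pair<std::string, double> >::iterator cit =
        fold_cache.find(seq);
    if (cit != fold_cache.end()) {
      db = cit->second.first;
      E = cit->second.second;
    } else if (use_toy) {
      db = nussinov_structure(seq);
      E = toy_energy(db);
      fold_cache[seq] = std::make_pair(db, E);
    } else {
      List r = fold_fun(seq);
      db = as<std::string>(r["structure"]);
      E = as<double>(r["energy"]);
      fold_cache[seq] = std::make_pair(db, E);
    }
    Pheno ph;
    annotate_one(seq, db, E, ep, sp.m, specs, ph);
    species.push_back(ph);
    int id = (int)species.size() - 1;
    sindex[seq] = id;
    return id;
  }

  void place(int site, int id) {
    grid[site] = id;
    A0[site] = species[id].a[0];
    A1[site] = species[id].a[1];
    A2[site] = species[id].a[2];
  }

  void clear(int site) {
    grid[site] = -1;
    A0[site] = A1[site] = A2[site] = 0.0;
  }

  // geometric mean of per-activity sums over the Chebyshev-h neighborhood
  // centered on (x, y); focal site included
  double metabolic(int x, int y) const {
    double s0 = 0.0, s1 = 0.0, s2 = 0.0;
    for (int dy = -sp.h; dy <= sp.h; ++dy) {
      int ny = y + dy;
      if (ny < 0) ny += H; else if (ny >= H) ny -= H;
      int row = ny * W;
      for (int dx = -sp.h; dx <= sp.h; ++dx) {
        int nx = x + dx;
        if (nx < 0) nx += W; else if (nx >= W) nx -= W;
        s0 += A0[row + nx];
        s1 += A1[row + nx];
        s2 += A2[row + nx];
      }
    }
    if (s0 <= 0.0 || s1 <= 0.0 || s2 <= 0.0) return 0.0;
    return std::cbrt(s0 * s1 * s2);
  }

  // template-directed synthesis of the reverse complement with per-base
  // mutually exclusive mutation draws; returns false on length-bound failure
  bool replicate(const std::string& tmpl, std::string& out, EventRow& ev) {
    static const char BASES[4] = {'A', 'C', 'G', 'U'};
    out.clear();
    out.reserve(tmpl.size() + 4);
    for (int p = (int)tmpl.size() - 1; p >= 0; --p) {
      char comp = complement_base(tmpl[p]);
      double u = unif_rand();
      if (u < sp.pdel) {
        ++ev.dels;
        continue;
      } else if (u < sp.pdel + sp.psub) {
        ++ev.subs;
        char c;
        do {
          int k = (int)(unif_rand() * 4.0);
          c = BASES[k & 3];
        } while (c == comp);
        out.push_back(c);
      } else if (u < sp.pdel + sp.psub + sp.pins) {
        ++ev.ins;
        int k = (int)(unif_rand() * 4.0);
        out.push_back(BASES[k & 3]);
        out.push_back(comp);
      } else {
        out.push_back(comp);
      }
    }
    if (unif_rand() < sp.pins) {  // trailing insertion opportunity
      ++ev.ins;
      int k = (int)(unif_rand() * 4.0);
      out.push_back(BASES[k & 3]);
    }
    return (int)out.size() >= sp.minL && (int)out.size() <= sp.maxL;
  }

  void one_generation(EventRow& ev) {
    const int n = W * H;
    const int span = 2 * sp.rr + 1;
    std::vector<double> claims(span * span);
    std::vector<int> cand(span * span);
    std::string product;
    for (int u = 0; u < n; ++u) {
      int site = (int)(unif_rand() * n);
      if (site >= n) site = n - 1;
      int id = grid[site];
      if (id >= 0) {
        if (unif_rand() < species[id].pdeg) {
          clear(site);
          ++ev.deaths;
        }
      } else {
        int x = site % W, y = site / W;
        int nc = 0;
        double tot = sp.Ce;
        for (int dy = -sp.rr; dy <= sp.rr; ++dy) {
          for (int dx = -sp.rr; dx <= sp.rr; ++dx) {
            if (dx == 0 && dy == 0) continue;
            int nx = x + dx;
            if (nx < 0) nx += W; else if (nx >= W) nx -= W;
            int ny = y + dy;
            if (ny < 0) ny += H; else if (ny >= H) ny -= H;
            int s2 = ny * W + nx;
            int cid = grid[s2];
            if (cid < 0) continue;
            double M = metabolic(nx, ny);
            if (M <= 0.0) continue;
            double C = M * species[cid].R;
            if (C <= 0.0) continue;
            claims[nc] = C;
            cand[nc] = cid;
            ++nc;
            tot += C;
          }
        }
        if (nc == 0) continue;
        double draw = unif_rand() * tot;
        if (draw < sp.Ce) continue;  // stays empty
        double acc = sp.Ce;
        int winner = -1;
        for (int q = 0; q < nc; ++q) {
          acc += claims[q];
          if (draw < acc) { winner = cand[q]; break; }
        }
        if (winner < 0) winner = cand[nc - 1];  // numerical guard
        if (replicate(species[winner].seq, product, ev)) {
          place(site, intern(product));
          ++ev.reps;
        } else {
          ++ev.failed;
        }
      }
    }
    FieldSet F = {&grid, &A0, &A1, &A2};
    int ns = n_sweeps(sp.D);
    for (int s = 0; s < ns; ++s) {
      margolus_sweep(F, W, H, parity);
      ++parity;
    }
  }
};

struct TrajAcc {
  std::vector<int> t, pop;
  std::vector<double> fE1, fE2, fE3, fP, fCis, mLen, mR, mE, mPf, mA1, mA2, mA3;
};

static void record_state(const Engine& eng, int t, TrajAcc& tr) {
  int pop = 0, nE[3] = {0, 0, 0}, nP = 0, nCis = 0;
  double sLen = 0, sR = 0, sE = 0, sPf = 0;
  double sA[3] = {0, 0, 0};
  int nA[3] = {0, 0, 0};
  for (size_t i = 0; i < eng.grid.size(); ++i) {
    int id = eng.grid[i];
    if (id < 0) continue;
    const Pheno& ph = eng.species[id];
    ++pop;
    sLen += (double)ph.seq.size();
    sR += ph.R;
    sE += ph.E;
    sPf += ph.pfold;
    int ntypes = 0, last = -1;
    for (int k = 0; k < 3; ++k) {
      if (ph.a[k] > 0.0) {
        ++ntypes;
        last = k;
        sA[k] += ph.a[k];
        ++nA[k];
      }
    }
    if (ntypes == 0) ++nP;
    else if (ntypes == 1) ++nE[last];
    else ++nCis;
  }
  double N = (double)eng.grid.size();
  tr.t.push_back(t);
  tr.pop.push_back(pop);
  tr.fE1.push_back(nE[0] / N);
  tr.fE2.push_back(nE[1] / N);
  tr.fE3.push_back(nE[2] / N);
  tr.fP.push_back(nP / N);
  tr.fCis.push_back(nCis / N);
  tr.mLen.push_back(pop ? sLen / pop : 0.0);
  tr.mR.push_back(pop ? sR / pop : 0.0);
  tr.mE.push_back(pop ? sE / pop : 0.0);
  tr.mPf.push_back(pop ? sPf / pop : 0.0);
  tr.mA1.push_back(nA[0] ? sA[0] / nA[0] : 0.0);
  tr.mA2.push_back(nA[1] ? sA[1] / nA[1] : 0.0);
  tr.mA3.push_back(nA[2] ? sA[2] / nA[2] : 0.0);
}

// [[Rcpp::export]]
List cpp_run(CharacterVector gridSeqs, int W, int H, List energy, List simpar,
             List specsList, CharacterVector cacheSeqs, CharacterVector cacheStructs,
             NumericVector cacheEnergies, int generations, int recordEvery,
             int t0, int parityStart, bool useToy, Function foldFun) {
  if (W % 2 != 0 || H % 2 != 0)
    stop("Margolus diffusion requires even grid dimensions (got %d x %d)", W, H);
  if ((int)gridSeqs.size() != W * H)
    stop("grid length does not match dimensions");
  Engine eng(foldFun);
  eng.W = W;
  eng.H = H;
  eng.ep = energy_from_list(energy);
  eng.sp = simpar_from_list(simpar);
  eng.specs = specs_from_list(specsList);
  eng.use_toy = useToy;
  eng.parity = parityStart;
  for (int i = 0; i < cacheSeqs.size(); ++i)
    eng.fold_cache[as<std::string>(cacheSeqs[i])] =
        std::make_pair(as<std::string>(cacheStructs[i]), cacheEnergies[i]);
  eng.grid.assign(W * H, -1);
  eng.A0.assign(W * H, 0.0);
  eng.A1.assign(W * H, 0.0);
  eng.A2.assign(W * H, 0.0);
  for (int i = 0; i < W * H; ++i) {
    if (gridSeqs[i] == NA_STRING) continue;
    std::string s = as<std::string>(gridSeqs[i]);
    if (s.empty()) continue;
    eng.place(i, eng.intern(s));
  }

  TrajAcc tr;
  record_state(eng, t0, tr);
  std::vector<int> ev_t(generations), ev_updates(generations), ev_deaths(generations),
      ev_reps(generations), ev_failed(generations), ev_subs(generations),
      ev_ins(generations), ev_dels(generations);
  for (int ggen = 0; ggen < generations; ++ggen) {
    EventRow ev;
    eng.one_generation(ev);
    int t = t0 + ggen + 1;
    ev_t[ggen] = t;
    ev_updates[ggen] = W * H;
    ev_deaths[ggen] = ev.deaths;
    ev_reps[ggen] = ev.reps;
    ev_failed[ggen] = ev.failed;
    ev_subs[ggen] = ev.subs;
    ev_ins[ggen] = ev.ins;
    ev_dels[ggen] = ev.dels;
    if (recordEvery > 0 && ((ggen + 1) % recordEvery == 0 || ggen + 1 == generations))
      record_state(eng, t, tr);
    if (ggen % 64 == 0) Rcpp::checkUserInterrupt();
  }

  CharacterVector outGrid(W * H);
  for (int i = 0; i < W * H; ++i)
    outGrid[i] = eng.grid[i] < 0 ? "" : eng.species[eng.grid[i]].seq;
  int nsp = (int)eng.species.size();
  CharacterVector spSeq(nsp), spDb(nsp);
  NumericVector spE(nsp);
  for (int i = 0; i < nsp; ++i) {
    spSeq[i] = eng.species[i].seq;
    spDb[i] = eng.species[i].db;
    spE[i] = eng.species[i].E;
  }
  DataFrame traj = DataFrame::create(
      _["t"] = tr.t, _["population"] = tr.pop, _["freqE1"] = tr.fE1,
      _["freqE2"] = tr.fE2, _["freqE3"] = tr.fE3, _["freqP"] = tr.fP,
      _["freqCis"] = tr.fCis, _["meanLength"] = tr.mLen, _["meanR"] = tr.mR,
      _["meanEnergy"] = tr.mE, _["meanPfold"] = tr.mPf, _["meanA1"] = tr.mA1,
      _["meanA2"] = tr.mA2, _["meanA3"] = tr.mA3);
  DataFrame events = DataFrame::create(
      _["t"] = ev_t, _["updates"] = ev_updates, _["degradations"] = ev_deaths,
      _["replications"] = ev_reps, _["failedReplications"] = ev_failed,
      _["substitutions"] = ev_subs, _["insertions"] = ev_ins, _["deletions"] = ev_dels);
  return List::create(_["grid"] = outGrid, _["trajectory"] = traj, _["events"] = events,
                      _["cacheSeqs"] = spSeq, _["cacheStructs"] = spDb,
                      _["cacheEnergies"] = spE, _["parity"] = eng.parity,
                      _["generation"] = t0 + generations);
}
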