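// Monte Carlo core for lattice protocell simulation.
//
// All stochastic state lives in a single World object (held from R as an
// external pointer) with one mt19937_64 stream, so a (seed, params,
// scenario) triple fully determines a run.  Probability kernels are plain
// functions shared between the engine and the exported R-level wrappers:
// each model probability drives exactly one operation.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <cstdint>
#include <deque>
#include <map>
#include <random>
#include <sstream>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// parameters

struct Params {
  double P_AD, P_AF, P_AJM, P_ALM, P_APP, P_AT, P_BB, P_CB, P_CD, P_CF,
      P_FP, P_MC, P_MF, P_MV, P_ND, P_NDE, P_NF, P_NFR, P_NPP, P_RL, P_SP,
      P_TL;
  double P_AABR, P_AAD, P_AADE, P_AAF, P_AAPP, P_AATL, P_NFP, P_PBB, P_PJM,
      P_PLM, P_PLR;
  double N, T_NPB, T_APB, T_AAPB, F_DO, F_DW, F_MSP, L_AM, L_NSR, L_AABS;
};

static double getnum(const List& l, const char* nm) {
  if (!l.containsElementNamed(nm)) stop("missing parameter '%s'", nm);
  return as<double>(l[nm]);
}

static Params params_from_list(const List& l) {
  Params p;
#define GET(f) p.f = getnum(l, #f)
  GET(P_AD); GET(P_AF); GET(P_AJM); GET(P_ALM); GET(P_APP); GET(P_AT);
  GET(P_BB); GET(P_CB); GET(P_CD); GET(P_CF); GET(P_FP); GET(P_MC);
  GET(P_MF); GET(P_MV); GET(P_ND); GET(P_NDE); GET(P_NF); GET(P_NFR);
  GET(P_NPP); GET(P_RL); GET(P_SP); GET(P_TL); GET(P_AABR); GET(P_AAD);
  GET(P_AADE); GET(P_AAF); GET(P_AAPP); GET(P_AATL); GET(P_NFP); GET(P_PBB);
  GET(P_PJM); GET(P_PLM); GET(P_PLR); GET(N); GET(T_NPB); GET(T_APB);
  GET(T_AAPB); GET(F_DO); GET(F_DW); GET(F_MSP); GET(L_AM); GET(L_NSR);
  GET(L_AABS);
#undef GET
  return p;
}

static bool set_param_field(Params& p, const std::string& nm, double v) {
#define SET(f) if (nm == #f) { p.f = v; return true; }
  SET(P_AD) SET(P_AF) SET(P_AJM) SET(P_ALM) SET(P_APP) SET(P_AT) SET(P_BB)
  SET(P_CB) SET(P_CD) SET(P_CF) SET(P_FP) SET(P_MC) SET(P_MF) SET(P_MV)
  SET(P_ND) SET(P_NDE) SET(P_NF) SET(P_NFR) SET(P_NPP) SET(P_RL) SET(P_SP)
  SET(P_TL) SET(P_AABR) SET(P_AAD) SET(P_AADE) SET(P_AAF) SET(P_AAPP)
  SET(P_AATL) SET(P_NFP) SET(P_PBB) SET(P_PJM) SET(P_PLM) SET(P_PLR)
  SET(N) SET(T_NPB) SET(T_APB) SET(T_AAPB) SET(F_DO) SET(F_DW) SET(F_MSP)
  SET(L_AM) SET(L_NSR) SET(L_AABS)
#undef SET
  return false;
}

// ---------------------------------------------------------------------------
// sequence definitions

static const char* AA_LETTERS = "PQRSTL";  // the six amino-acid types

struct SeqDefs {
  std::array<std::string, 6> site;  // binding-site 5-mer per amino-acid type
  int msp[2], nsp[2], ctl[2];       // ordered residue pairs (indices 0..5)
  std::string nsr;                  // ribozyme characteristic domain (10-mer)
  std::string ctr;                  // control RNA motif (10-mer, no function)
  std::string mspg, nspg, ctpg;     // derived dipeptide gene motifs
};

static int aa_index(char c) {
  for (int i = 0; i < 6; ++i)
    if (AA_LETTERS[i] == c) return i;
  stop("unknown amino-acid letter '%c'", c);
  return -1;
}

static SeqDefs seqdefs_from_list(const List& l) {
  SeqDefs sd;
  CharacterVector cb = l["codebook"];
  CharacterVector cbn = cb.names();
  if (cb.size() != 6) stop("codebook must have six entries");
  for (int i = 0; i < 6; ++i) {
    int ai = aa_index(std::string(cbn[i])[0]);
    sd.site[ai] = as<std::string>(cb[i]);
  }
  auto pair_of = [&](const char* nm, int* out) {
    CharacterVector pr = l[nm];
    out[0] = aa_index(std::string(pr[0])[0]);
    out[1] = aa_index(std::string(pr[1])[0]);
  };
  pair_of("msp_pair", sd.msp);
  pair_of("nsp_pair", sd.nsp);
  pair_of("control_pair", sd.ctl);
  sd.nsr = as<std::string>(l["nsr_motif"]);
  sd.ctr = as<std::string>(l["control_rna_motif"]);
  sd.mspg = sd.site[sd.msp[0]] + sd.site[sd.msp[1]];
  sd.nspg = sd.site[sd.nsp[0]] + sd.site[sd.nsp[1]];
  sd.ctpg = sd.site[sd.ctl[0]] + sd.site[sd.ctl[1]];
  return sd;
}

// ---------------------------------------------------------------------------
// probability kernels (closed forms)

static double k_membrane_formation(double a, double P_MF, double L_AM) {
  double x = a - L_AM + 1.0;
  if (x < 1.0) return 0.0;
  if (x == 1.0) return P_MF;  // exact at the threshold
  return 1.0 - std::pow(1.0 - P_MF, x);
}

static double k_separation(double n, double P_SP) {
  return std::pow(P_SP, std::sqrt(n));
}

static double k_bond_break(bool dbl, bool outside, double P_BB, double F_DO) {
  double p = P_BB * (outside ? F_DO : 1.0);
  if (p > 1.0) p = 1.0;
  return dbl ? p * p : p;
}

static double k_division(double b, double P_CD, double L_AM) {
  double v = P_CD * (1.0 - 2.0 * L_AM / b);
  return v > 0.0 ? v : 0.0;
}

static double k_amph_leave(double b, double i, double p, double P_ALM,
                           double F_MSP) {
  double y = 1.0 + i / std::pow(b / 2.0, 1.5);
  double z = 1.0 + F_MSP * p;
  return P_ALM / (y * z);
}

static double k_permeation(int species, double b, double i, const Params& P) {
  double v;
  if (species == 0) {  // nucleotide precursor: Donnan suppression applies
    double y = 1.0 + i / std::pow(b / 2.0, 1.5);
    v = P.P_NPP * (b / P.L_AM) / y;
  } else if (species == 1) {
    v = P.P_APP * (b / P.L_AM);
  } else {
    v = P.P_AAPP * (b / P.L_AM);
  }
  return v > 1.0 ? 1.0 : v;
}

static double k_move(double m, double P_MV) { return P_MV / std::sqrt(m); }

// ---------------------------------------------------------------------------
// entities

static int base_index(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
  }
  stop("invalid base '%c'", c);
  return -1;
}
static char base_char(int i) { return "ACGU"[i]; }
static char wc(char c) {
  switch (c) {
    case 'A': return 'U';
    case 'U': return 'A';
    case 'C': return 'G';
    case 'G': return 'C';
  }
  return 'N';
}

struct Seg {           // complement fragment annealed on a template
  int start;           // 0-based template offset of first paired residue
  std::string bases;   // bases[j] pairs with template position start+j
  bool locked = false; // product of template-directed ligation: part of the
                       // growing complementary chain, which only separates
                       // once it spans the whole template
};

struct Rna {
  std::string seq;
  std::vector<Seg> segs;          // sorted by start, non-overlapping
  std::vector<int> site_off;      // cached amino-acid binding sites
  std::vector<int8_t> site_aa;
  std::vector<int8_t> occ;        // bound residue per site (-1 = empty)
  std::vector<uint8_t> lig;       // lig[k]: residues at sites k,k+1 bonded
  long acted = -1;                // step stamp: one polymer event per step
  bool dead = false;

  bool folded() const {
    for (int8_t o : occ)
      if (o >= 0) return true;
    return false;
  }
  bool has_dipeptide() const {
    for (uint8_t l : lig)
      if (l) return true;
    return false;
  }
  int len() const { return (int)seq.size(); }
  int paired_len() const {
    int n = 0;
    for (const Seg& s : segs) n += (int)s.bases.size();
    return n;
  }
  bool pos_paired(int i) const {
    for (const Seg& s : segs) {
      if (s.start > i) return false;
      if (i < s.start + (int)s.bases.size()) return true;
    }
    return false;
  }
  int bound_count() const {
    int n = 0;
    for (int8_t o : occ)
      if (o >= 0) ++n;
    return n;
  }
  long mass() const { return len() + paired_len() + bound_count(); }
};

// non-overlapping left-to-right scan for codebook 5-mers
static void recompute_sites(Rna& r, const SeqDefs& sd, int Laabs) {
  r.site_off.clear();
  r.site_aa.clear();
  int L = r.len();
  int pos = 0;
  while (pos + Laabs <= L) {
    int hit = -1;
    for (int t = 0; t < 6; ++t) {
      if (r.seq.compare(pos, Laabs, sd.site[t]) == 0) { hit = t; break; }
    }
    if (hit >= 0) {
      r.site_off.push_back(pos);
      r.site_aa.push_back((int8_t)hit);
      pos += Laabs;
    } else {
      ++pos;
    }
  }
  r.occ.assign(r.site_off.size(), (int8_t)-1);
  r.lig.assign(r.site_off.size() ? r.site_off.size() - 1 : 0, (uint8_t)0);
}

static int count_occurrences(const std::string& s, const std::string& motif) {
  if (motif.empty() || s.size() < motif.size()) return 0;
  int n = 0;
  size_t pos = 0;
  while ((pos = s.find(motif, pos)) != std::string::npos) {
    ++n;
    pos += motif.size();
  }
  return n;
}

struct Pep {
  int8_t a1, a2;  // ordered residues; only dipeptides exist as free objects
  long acted = -1;
  bool dead = false;
};

struct Compart {
  long np = 0, ap = 0, aap = 0;         // precursors
  std::array<long, 4> nt{{0, 0, 0, 0}}; // free nucleotides A C G U
  long am = 0;                          // free amphiphiles
  std::array<long, 6> aa{{0, 0, 0, 0, 0, 0}};
  // deque: appending staged fragments/daughters never invalidates
  // references to strands being processed
  std::deque<Rna> rnas;
  std::deque<Pep> peps;

  void compact() {
    rnas.erase(std::remove_if(rnas.begin(), rnas.end(),
                              [](const Rna& r) { return r.dead; }),
               rnas.end());
    peps.erase(std::remove_if(peps.begin(), peps.end(),
                              [](const Pep& p) { return p.dead; }),
               peps.end());
  }
  bool empty_all() const {
    return np == 0 && ap == 0 && aap == 0 && am == 0 &&
           nt[0] + nt[1] + nt[2] + nt[3] == 0 &&
           aa[0] + aa[1] + aa[2] + aa[3] + aa[4] + aa[5] == 0 &&
           rnas.empty() && peps.empty();
  }
};

struct Room {
  Compart out;  // exterior contents (everything, when no protocell)
  Compart in;   // protocell interior
  bool cell = false;
  long b = 0;   // membrane amphiphiles
  long p = 0;   // membrane-embedded MSP
  long cell_stamp = -1;  // one protocell event per step
  long memb_stamp = -1;  // membrane formed this step: no exchange yet
};

struct Ledger {
  long long nt_init = 0, am_init = 0, aa_init = 0;
  long long nt_inoc = 0, am_inoc = 0, aa_inoc = 0;
};

// ---------------------------------------------------------------------------
// world

struct World {
  int N;
  Params par;
  SeqDefs sd;
  std::mt19937_64 rng;
  long step_no = 0;
  std::vector<Room> rooms;
  Ledger led;
  bool randomize_phases = false;  // robustness switch for phase order

  World(int n, const Params& p, const SeqDefs& s, uint64_t seed)
      : N(n), par(p), sd(s), rng(seed), rooms(n * n) {}

  // --- rng helpers (single stream) ---
  double runif() {
    return std::uniform_real_distribution<double>(0.0, 1.0)(rng);
  }
  long rbinom(long n, double p) {
    if (n <= 0 || p <= 0.0) return 0;
    if (p >= 1.0) return n;
    return std::binomial_distribution<long>(n, p)(rng);
  }
  int rint(int n) {  // uniform on 0..n-1
    return (int)std::uniform_int_distribution<long>(0, n - 1)(rng);
  }
  // split n into 4 equal-probability directions
  std::array<long, 4> rsplit4(long n) {
    std::array<long, 4> out{{0, 0, 0, 0}};
    long rem = n;
    for (int k = 0; k < 3; ++k) {
      out[k] = rbinom(rem, 1.0 / (4 - k));
      rem -= out[k];
    }
    out[3] = rem;
    return out;
  }

  int idx(int r, int c) const { return r * N + c; }
  // neighbor in direction d (0 up,1 down,2 left,3 right); -1 if off grid
  int neighbor(int i, int d) const {
    int r = i / N, c = i % N;
    switch (d) {
      case 0: return r > 0 ? idx(r - 1, c) : -1;
      case 1: return r < N - 1 ? idx(r + 1, c) : -1;
      case 2: return c > 0 ? idx(r, c - 1) : -1;
      case 3: return c < N - 1 ? idx(r, c + 1) : -1;
    }
    return -1;
  }

  std::vector<int> shuffled_rooms() {
    std::vector<int> ord(rooms.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
    std::shuffle(ord.begin(), ord.end(), rng);
    return ord;
  }

  long inner_ions(const Compart& c) const {
    long i = c.nt[0] + c.nt[1] + c.nt[2] + c.nt[3];
    for (const Rna& r : c.rnas)
      if (!r.dead) i += r.len() + r.paired_len();
    return i;
  }

  void add_rna(Compart& c, Rna&& r, bool stamp) {
    if (stamp) r.acted = step_no;
    c.rnas.push_back(std::move(r));
  }

  Rna make_rna(const std::string& seq) {
    Rna r;
    r.seq = seq;
    recompute_sites(r, sd, (int)par.L_AABS);
    return r;
  }

  // --- protocell structural events ---

  void dissolve_cell(Room& rm) {
    rm.out.am += rm.b;
    rm.b = 0;
    for (long k = 0; k < rm.p; ++k) {
      Pep q;
      q.a1 = (int8_t)sd.msp[0];
      q.a2 = (int8_t)sd.msp[1];
      q.acted = step_no;
      rm.out.peps.push_back(q);
    }
    rm.p = 0;
    merge_compart(rm.out, rm.in);
    rm.cell = false;
  }

  static void merge_compart(Compart& dst, Compart& src) {
    dst.np += src.np; dst.ap += src.ap; dst.aap += src.aap; dst.am += src.am;
    for (int i = 0; i < 4; ++i) dst.nt[i] += src.nt[i];
    for (int i = 0; i < 6; ++i) dst.aa[i] += src.aa[i];
    for (Rna& r : src.rnas) dst.rnas.push_back(std::move(r));
    for (Pep& p : src.peps) dst.peps.push_back(p);
    src = Compart();
  }

  // ---------------------------------------------------------------------
  // phase 1: protocell events (break, divide, fuse, move; one per cell)

  void phase_cells() {
    std::vector<int> ord = shuffled_rooms();
    std::vector<int> ordpos(rooms.size());
    for (size_t k = 0; k < ord.size(); ++k) ordpos[ord[k]] = (int)k;

    for (int i : ord) {
      Room& rm = rooms[i];
      if (!rm.cell || rm.cell_stamp == step_no) continue;

      // break
      if (runif() < par.P_CB) {
        dissolve_cell(rm);
        rm.cell_stamp = step_no;
        continue;
      }
      // divide
      if (rm.b >= 1 && runif() < k_division((double)rm.b, par.P_CD, par.L_AM)) {
        std::vector<int> elig;
        for (int d = 0; d < 4; ++d) {
          int j = neighbor(i, d);
          if (j >= 0 && !rooms[j].cell) elig.push_back(j);
        }
        if (!elig.empty()) {
          long b1 = rbinom(rm.b, 0.5);
          if (b1 >= 1 && rm.b - b1 >= 1) {
            int j = elig[rint((int)elig.size())];
            Room& nb = rooms[j];
            long p1 = rbinom(rm.p, 0.5);
            nb.cell = true;
            nb.b = b1;
            nb.p = p1;
            rm.b -= b1;
            rm.p -= p1;
            // random assortment: each interior entity/unit to a daughter
            Compart& s = rm.in;
            Compart& d2 = nb.in;
            auto splitc = [&](long& v, long& w) {
              long m = rbinom(v, 0.5);
              v -= m;
              w += m;
            };
            splitc(s.np, d2.np); splitc(s.ap, d2.ap); splitc(s.aap, d2.aap);
            splitc(s.am, d2.am);
            for (int t = 0; t < 4; ++t) splitc(s.nt[t], d2.nt[t]);
            for (int t = 0; t < 6; ++t) splitc(s.aa[t], d2.aa[t]);
            for (size_t k = 0; k < s.rnas.size(); ++k) {
              if (!s.rnas[k].dead && runif() < 0.5) {
                d2.rnas.push_back(std::move(s.rnas[k]));
                s.rnas[k] = Rna();
                s.rnas[k].dead = true;
              }
            }
            for (size_t k = 0; k < s.peps.size(); ++k) {
              if (!s.peps[k].dead && runif() < 0.5) {
                d2.peps.push_back(s.peps[k]);
                s.peps[k].dead = true;
              }
            }
            s.compact();
            rm.cell_stamp = step_no;
            nb.cell_stamp = step_no;
            continue;
          }
        }
      }
      // fuse (each unordered adjacent pair considered once per step)
      {
        bool fused = false;
        std::array<int, 4> dirs{{0, 1, 2, 3}};
        std::shuffle(dirs.begin(), dirs.end(), rng);
        for (int d : dirs) {
          int j = neighbor(i, d);
          if (j < 0) continue;
          Room& nb = rooms[j];
          if (!nb.cell || nb.cell_stamp == step_no) continue;
          if (ordpos[j] < ordpos[i]) continue;  // pair handled from one side
          if (runif() < par.P_CF) {
            rm.b += nb.b;
            rm.p += nb.p;
            nb.b = 0;
            nb.p = 0;
            merge_compart(rm.in, nb.in);
            nb.cell = false;
            nb.cell_stamp = step_no;
            rm.cell_stamp = step_no;
            fused = true;
            break;
          }
        }
        if (fused) continue;
      }
      // move (pushes exterior molecules of the target into the vacated room)
      if (runif() < par.P_MC) {
        int d = rint(4);
        int j = neighbor(i, d);
        if (j >= 0 && !rooms[j].cell) {
          Room& nb = rooms[j];
          merge_compart(rm.out, nb.out);  // displaced into vacated room
          nb.cell = true;
          nb.b = rm.b;
          nb.p = rm.p;
          nb.in = std::move(rm.in);
          rm.in = Compart();
          rm.cell = false;
          rm.b = 0;
          rm.p = 0;
          nb.cell_stamp = step_no;
          rm.cell_stamp = step_no;
        }
      }
    }
  }

  // ---------------------------------------------------------------------
  // phase 2: membrane formation, amphiphile/MSP exchange, permeation

  void phase_membrane() {
    std::vector<int> ord = shuffled_rooms();
    for (int i : ord) {
      Room& rm = rooms[i];
      if (!rm.cell) {
        // membrane formation encloses the room's contents
        double pf =
            k_membrane_formation((double)rm.out.am, par.P_MF, par.L_AM);
        if (pf > 0.0 && runif() < pf) {
          rm.cell = true;
          rm.b = rm.out.am;
          rm.out.am = 0;
          merge_compart(rm.in, rm.out);
          rm.p = 0;
          rm.memb_stamp = step_no;
        }
        continue;
      }
      if (rm.memb_stamp == step_no) continue;

      long i_ions = inner_ions(rm.in);

      // amphiphile exchange (join from both sides, leave to exterior)
      long b0 = rm.b;
      long jo = rbinom(rm.out.am, par.P_AJM);
      long ji = rbinom(rm.in.am, par.P_AJM);
      long lv = rbinom(b0, k_amph_leave((double)b0, (double)i_ions,
                                        (double)rm.p, par.P_ALM, par.F_MSP));
      rm.out.am -= jo;
      rm.in.am -= ji;
      rm.b = b0 + jo + ji - lv;
      rm.out.am += lv;

      // MSP exchange
      long p0 = rm.p;
      for (Pep& q : rm.in.peps) {
        if (q.dead || q.acted == step_no) continue;
        if (q.a1 == sd.msp[0] && q.a2 == sd.msp[1] && runif() < par.P_PJM) {
          q.dead = true;
          rm.p += 1;
        }
      }
      long pl = rbinom(p0, par.P_PLM);
      if (pl > rm.p) pl = rm.p;
      rm.p -= pl;
      for (long k = 0; k < pl; ++k) {
        Pep q;
        q.a1 = (int8_t)sd.msp[0];
        q.a2 = (int8_t)sd.msp[1];
        q.acted = step_no;
        rm.in.peps.push_back(q);
      }
      rm.in.compact();

      // permeation of precursors, identical form both directions
      if (rm.b >= 1) {
        double fnp = k_permeation(0, (double)rm.b, (double)i_ions, par);
        double fap = k_permeation(1, (double)rm.b, (double)i_ions, par);
        double faap = k_permeation(2, (double)rm.b, (double)i_ions, par);
        long in_np = rbinom(rm.out.np, fnp), out_np = rbinom(rm.in.np, fnp);
        long in_ap = rbinom(rm.out.ap, fap), out_ap = rbinom(rm.in.ap, fap);
        long in_aap = rbinom(rm.out.aap, faap),
             out_aap = rbinom(rm.in.aap, faap);
        rm.out.np += out_np - in_np;
        rm.in.np += in_np - out_np;
        rm.out.ap += out_ap - in_ap;
        rm.in.ap += in_ap - out_ap;
        rm.out.aap += out_aap - in_aap;
        rm.in.aap += in_aap - out_aap;
      }
      if (rm.b <= 0) dissolve_cell(rm);
    }
  }

  // ---------------------------------------------------------------------
  // phase 3: polymer events

  // degradation of one unfolded strand; returns true if any event fired
  bool degrade_rna(Compart& C, Rna& T, bool outside) {
    bool fired = false;
    double pe = std::min(1.0, par.P_NDE * (outside ? par.F_DO : 1.0));

    // chain-end residue decay (unpaired ends only; duplex protects)
    if (T.len() >= 2 && !T.pos_paired(0) && runif() < pe) {
      T.seq.erase(0, 1);
      for (Seg& s : T.segs) s.start -= 1;
      C.np += 1;
      fired = true;
    }
    if (T.len() >= 2 && !T.pos_paired(T.len() - 1) && runif() < pe) {
      T.seq.pop_back();
      C.np += 1;
      fired = true;
    }
    if (T.len() == 1) {
      if (T.segs.empty()) {  // a length-1 RNA is a free nucleotide
        C.nt[base_index(T.seq[0])] += 1;
        T.dead = true;
      }  // else: a one-pair duplex; separation will release the partner
      T.acted = step_no;
      return true;
    }

    // phosphodiester bond breaks; a double-strand cut severs both strands
    std::vector<int> cuts;
    for (int i = 0; i + 1 < T.len(); ++i) {
      bool dbl = T.pos_paired(i) && T.pos_paired(i + 1);
      if (runif() < k_bond_break(dbl, outside, par.P_BB, par.F_DO))
        cuts.push_back(i);
    }
    if (!cuts.empty()) {
      fired = true;
      // split segments at every cut (cuts inside a segment are double cuts)
      std::vector<Seg> segs;
      for (Seg& s : T.segs) {
        int a = s.start;
        std::string rem = s.bases;
        for (int c : cuts) {
          // bond between template positions c and c+1; inside the remainder?
          int relbond = c - a;
          if (relbond >= 0 && relbond < (int)rem.size() - 1) {
            segs.push_back(Seg{a, rem.substr(0, relbond + 1), s.locked});
            rem = rem.substr(relbond + 1);
            a = c + 1;
          }
        }
        if (!rem.empty()) segs.push_back(Seg{a, rem, s.locked});
      }
      // split template into fragments
      int prev = 0;
      std::vector<std::pair<int, int>> frags;  // [from, to)
      for (int c : cuts) {
        frags.push_back({prev, c + 1});
        prev = c + 1;
      }
      frags.push_back({prev, T.len()});
      for (auto& fr : frags) {
        int flen = fr.second - fr.first;
        if (flen == 1 && [&] {  // lone residue w/o complement -> nucleotide
              for (Seg& s : segs)
                if (s.start == fr.first) return false;
              return true;
            }()) {
          C.nt[base_index(T.seq[fr.first])] += 1;
          continue;
        }
        Rna f;
        f.seq = T.seq.substr(fr.first, flen);
        for (Seg& s : segs) {
          if (s.start >= fr.first &&
              s.start + (int)s.bases.size() <= fr.second) {
            f.segs.push_back(Seg{s.start - fr.first, s.bases, s.locked});
          }
        }
        recompute_sites(f, sd, (int)par.L_AABS);
        add_rna(C, std::move(f), true);
      }
      T.dead = true;
      T.acted = step_no;
      return true;
    }
    if (fired) {
      recompute_sites(T, sd, (int)par.L_AABS);
      T.acted = step_no;
    }
    return fired;
  }

  // random ligation between free ends in one compartment
  void random_ligation(Compart& C) {
    if (par.P_RL <= 0.0) return;
    long nt_units = C.nt[0] + C.nt[1] + C.nt[2] + C.nt[3];
    // strand ends: index list of (rna index, end: 0 front/1 back)
    std::vector<std::pair<int, int>> ends;
    for (size_t k = 0; k < C.rnas.size(); ++k) {
      Rna& r = C.rnas[k];
      if (r.dead || r.folded() || r.acted == step_no) continue;
      if (!r.pos_paired(0)) ends.push_back({(int)k, 0});
      if (!r.pos_paired(r.len() - 1)) ends.push_back({(int)k, 1});
    }
    double units = (double)nt_units + (double)ends.size();
    if (units < 2) return;
    double pairs = units * (units - 1.0) / 2.0;
    // each unordered pair of candidate ends considered once per step
    long K = rbinom((long)pairs, par.P_RL);
    for (long e = 0; e < K; ++e) {
      long total = nt_units + (long)ends.size();
      if (total < 2) break;
      long u1 = (long)std::uniform_int_distribution<long>(0, total - 1)(rng);
      long u2 = (long)std::uniform_int_distribution<long>(0, total - 2)(rng);
      if (u2 >= u1) u2 += 1;
      auto pick_base = [&](long u) {
        long acc = 0;
        for (int t = 0; t < 4; ++t) {
          acc += C.nt[t];
          if (u < acc) return t;
        }
        return 3;
      };
      bool n1 = u1 < nt_units, n2 = u2 < nt_units;
      if (n1 && n2) {  // dimer
        int b1 = pick_base(u1);
        C.nt[b1] -= 1;
        nt_units -= 1;
        // re-pick second base from updated pool
        long u2b = (long)std::uniform_int_distribution<long>(
            0, nt_units - 1)(rng);
        int b2 = pick_base(u2b);
        C.nt[b2] -= 1;
        nt_units -= 1;
        Rna d = make_rna(std::string(1, base_char(b1)) +
                         std::string(1, base_char(b2)));
        add_rna(C, std::move(d), true);
      } else if (n1 != n2) {  // nucleotide extends a strand end
        long un = n1 ? u1 : u2;
        auto en = n1 ? ends[u2 - nt_units] : ends[u1 - nt_units];
        Rna& r = C.rnas[en.first];
        if (r.dead || r.acted == step_no) continue;
        int b1 = pick_base(un);
        C.nt[b1] -= 1;
        nt_units -= 1;
        if (en.second == 0) {
          r.seq.insert(r.seq.begin(), base_char(b1));
          for (Seg& s : r.segs) s.start += 1;
        } else {
          r.seq.push_back(base_char(b1));
        }
        recompute_sites(r, sd, (int)par.L_AABS);
        r.acted = step_no;
      } else {  // strand + strand: only 3'(back) to 5'(front) joins
        auto e1 = ends[u1 - nt_units], e2 = ends[u2 - nt_units];
        if (e1.first == e2.first) continue;
        if (e1.second == e2.second) continue;  // chemically invalid pairing
        auto eb = e1.second == 1 ? e1 : e2;    // back end of X
        auto ef = e1.second == 0 ? e1 : e2;    // front end of Y
        Rna& X = C.rnas[eb.first];
        Rna& Y = C.rnas[ef.first];
        if (X.dead || Y.dead || X.acted == step_no || Y.acted == step_no)
          continue;
        int off = X.len();
        X.seq += Y.seq;
        for (Seg& s : Y.segs) X.segs.push_back(Seg{s.start + off, s.bases});
        Y.dead = true;
        Y.acted = step_no;
        recompute_sites(X, sd, (int)par.L_AABS);
        X.acted = step_no;
      }
    }
  }

  // template attraction: one substrate recruitment attempt per step.
  // Attraction acts via base-pairing: candidate substrates are the free
  // nucleotides (any base; the Watson-Crick partner is demanded, a
  // mismatch being accepted with P_FP) and the free unfolded strands that
  // pair perfectly at a growth site.  Substrate choice is uniform over
  // these candidates, so complement fragments are recycled into growing
  // chains instead of being lost.
  bool attract(Compart& C, size_t self) {
    Rna& T = C.rnas[self];
    if (runif() >= par.P_AT) return false;
    int L = T.len();
    bool denovo = T.segs.empty();

    // growth sites adjacent to the existing complement (pos, direction)
    std::vector<std::pair<int, int>> sites;
    if (!denovo) {
      for (Seg& s : T.segs) {
        int a = s.start - 1;
        int b2 = s.start + (int)s.bases.size();
        if (a >= 0 && !T.pos_paired(a)) sites.push_back({a, -1});
        if (b2 < L && !T.pos_paired(b2)) sites.push_back({b2, +1});
      }
      if (sites.empty()) return false;
    }

    long nt_units = C.nt[0] + C.nt[1] + C.nt[2] + C.nt[3];

    struct Opt { int strand; int start; };
    std::vector<Opt> opts;
    for (size_t k = 0; k < C.rnas.size(); ++k) {
      if (k == self) continue;
      Rna& r = C.rnas[k];
      if (r.dead || r.folded() || !r.segs.empty() || r.acted == step_no)
        continue;
      int k2 = r.len();
      if (k2 > L) continue;
      std::string bases(r.seq.rbegin(), r.seq.rend());  // antiparallel
      auto fits = [&](int st) {
        if (st < 0 || st + k2 > L) return false;
        for (int j = 0; j < k2; ++j) {
          if (T.pos_paired(st + j)) return false;
          if (bases[j] != wc(T.seq[st + j])) return false;
        }
        return true;
      };
      if (denovo) {
        for (int st = 0; st + k2 <= L; ++st)
          if (fits(st)) opts.push_back({(int)k, st});
      } else {
        for (auto& sp : sites) {
          int st = sp.second > 0 ? sp.first : sp.first - k2 + 1;
          if (fits(st)) opts.push_back({(int)k, st});
        }
      }
    }

    double W = (double)nt_units + (double)opts.size();
    if (W < 1) return false;
    long u = (long)std::uniform_int_distribution<long>(
        0, (long)W - 1)(rng);

    if (u < nt_units) {  // monomer recruitment
      int pos, dummy_dir;
      if (denovo) {
        pos = rint(L);
      } else {
        auto ch = sites[rint((int)sites.size())];
        pos = ch.first;
        dummy_dir = ch.second;
        (void)dummy_dir;
      }
      char need = wc(T.seq[pos]);
      char got;
      if (runif() < par.P_FP) {  // mutation: a mismatching base accepted
        std::array<int, 3> alt;
        int na = 0;
        for (int t = 0; t < 4; ++t) {
          if (base_char(t) != need && C.nt[t] > 0) alt[na++] = t;
        }
        if (na == 0) return false;
        got = base_char(alt[rint(na)]);
      } else {
        if (C.nt[base_index(need)] <= 0) return false;
        got = need;
      }
      C.nt[base_index(got)] -= 1;
      Seg s{pos, std::string(1, got), false};
      T.segs.insert(std::upper_bound(T.segs.begin(), T.segs.end(), s,
                                     [](const Seg& a, const Seg& b2) {
                                       return a.start < b2.start;
                                     }),
                    s);
      T.acted = step_no;
      return true;
    }

    Opt o = opts[u - nt_units];
    Rna& S = C.rnas[o.strand];
    std::string bases(S.seq.rbegin(), S.seq.rend());
    S.dead = true;
    S.acted = step_no;
    Seg s{o.start, bases, false};
    T.segs.insert(std::upper_bound(T.segs.begin(), T.segs.end(), s,
                                   [](const Seg& a, const Seg& b2) {
                                     return a.start < b2.start;
                                   }),
                  s);
    T.acted = step_no;
    return true;
  }

  bool template_ligation(Rna& T) {
    bool fired = false;
    for (size_t k = 0; k + 1 < T.segs.size();) {
      Seg& a = T.segs[k];
      Seg& b2 = T.segs[k + 1];
      if (a.start + (int)a.bases.size() == b2.start && runif() < par.P_TL) {
        a.bases += b2.bases;
        a.locked = true;
        T.segs.erase(T.segs.begin() + k + 1);
        fired = true;
      } else {
        ++k;
      }
    }
    if (fired) T.acted = step_no;
    return fired;
  }

  bool separation(Compart& C, Rna& T) {
    bool fired = false;
    for (size_t k = 0; k < T.segs.size();) {
      Seg& s = T.segs[k];
      int n = (int)s.bases.size();
      // an unligated substrate may leave; a ligated (growing) complement
      // leaves only as the full complementary chain
      bool full = (s.start == 0 && n == T.len());
      if (s.locked && !full) {
        ++k;
        continue;
      }
      if (runif() < k_separation((double)n, par.P_SP)) {
        if (n == 1) {
          C.nt[base_index(s.bases[0])] += 1;
        } else {
          Rna f;
          f.seq.assign(s.bases.rbegin(), s.bases.rend());
          recompute_sites(f, sd, (int)par.L_AABS);
          add_rna(C, std::move(f), true);
        }
        T.segs.erase(T.segs.begin() + k);
        fired = true;
      } else {
        ++k;
      }
    }
    if (fired) T.acted = step_no;
    return fired;
  }

  bool drt_bind(Compart& C, Rna& T) {
    if (T.site_off.empty() || T.has_dipeptide()) return false;
    bool fired = false;
    for (size_t k = 0; k < T.site_off.size(); ++k) {
      if (T.occ[k] >= 0) continue;
      int t = T.site_aa[k];
      if (C.aa[t] > 0 && runif() < par.P_AABR) {
        C.aa[t] -= 1;
        T.occ[k] = (int8_t)t;
        fired = true;
      }
    }
    if (fired) T.acted = step_no;
    return fired;
  }

  bool drt_ligate(Rna& T) {
    bool fired = false;
    for (size_t k = 0; k + 1 < T.site_off.size(); ++k) {
      if (T.lig[k]) { ++k; continue; }
      if (k > 0 && T.lig[k - 1]) continue;
      if (T.occ[k] < 0 || T.occ[k + 1] < 0) continue;
      if (T.site_off[k] + (int)par.L_AABS != T.site_off[k + 1]) continue;
      if (k + 1 < T.lig.size() && T.lig[k + 1]) continue;
      if (runif() < par.P_AATL) {
        T.lig[k] = 1;
        fired = true;
        ++k;
      }
    }
    if (fired) T.acted = step_no;
    return fired;
  }

  bool drt_release(Compart& C, Rna& T) {
    bool fired = false;
    for (size_t k = 0; k < T.site_off.size();) {
      if (k < T.lig.size() && T.lig[k]) {
        if (runif() < par.P_PLR) {
          Pep q;
          q.a1 = T.occ[k];
          q.a2 = T.occ[k + 1];
          q.acted = step_no;
          C.peps.push_back(q);
          T.occ[k] = -1;
          T.occ[k + 1] = -1;
          T.lig[k] = 0;
          fired = true;
        }
        k += 2;
      } else {
        if (T.occ[k] >= 0 && runif() < par.P_PLR) {
          C.aa[T.occ[k]] += 1;
          T.occ[k] = -1;
          fired = true;
        }
        k += 1;
      }
    }
    if (fired) T.acted = step_no;
    return fired;
  }

  void peptide_degradation(Compart& C, double fw) {
    double pbb = std::min(1.0, par.P_PBB * fw);
    double pde = std::min(1.0, par.P_AADE * fw);
    for (Pep& q : C.peps) {
      if (q.dead || q.acted == step_no) continue;
      q.acted = step_no;
      if (runif() < pbb) {  // bond break: residues usable directly
        C.aa[q.a1] += 1;
        C.aa[q.a2] += 1;
        q.dead = true;
        continue;
      }
      bool d1 = runif() < pde, d2 = runif() < pde;
      if (d1 && d2) {
        C.aap += 2;
        q.dead = true;
      } else if (d1) {
        C.aap += 1;
        C.aa[q.a2] += 1;
        q.dead = true;
      } else if (d2) {
        C.aap += 1;
        C.aa[q.a1] += 1;
        q.dead = true;
      }
    }
  }

  void polymer_compartment(Compart& C, bool outside) {
    // 1. degradation
    for (size_t k = 0; k < C.rnas.size(); ++k) {
      Rna& T = C.rnas[k];
      if (T.dead || T.acted == step_no || T.folded()) continue;
      degrade_rna(C, T, outside);
    }
    // 2. random ligation
    random_ligation(C);
    // 3..5 template events, 6..8 DRT events (first fired event claims the
    // strand for this step)
    size_t n0 = C.rnas.size();
    for (size_t k = 0; k < n0; ++k) {
      if (C.rnas[k].dead || C.rnas[k].acted == step_no) continue;
      if (!C.rnas[k].folded()) {
        if (attract(C, k)) continue;
        Rna& T = C.rnas[k];
        if (template_ligation(T)) continue;
        if (separation(C, T)) continue;
      }
      Rna& T = C.rnas[k];
      if (drt_bind(C, T)) continue;
      if (T.folded()) {
        if (drt_ligate(T)) continue;
        drt_release(C, T);
      }
    }
    // 9. free peptide degradation
    peptide_degradation(C, 1.0);
    C.compact();
  }

  void phase_polymers() {
    std::vector<int> ord = shuffled_rooms();
    for (int i : ord) {
      Room& rm = rooms[i];
      polymer_compartment(rm.out, true);
      if (rm.cell) {
        polymer_compartment(rm.in, false);
        // membrane-embedded MSP degradation (protected by factor F_DW)
        double pbb = std::min(1.0, par.P_PBB * par.F_DW);
        double pde = std::min(1.0, par.P_AADE * par.F_DW);
        long kb = rbinom(rm.p, pbb);
        rm.p -= kb;
        rm.in.aa[sd.msp[0]] += kb;
        rm.in.aa[sd.msp[1]] += kb;
        long p1 = rm.p;
        for (long k = 0; k < p1; ++k) {
          bool d1 = runif() < pde, d2 = runif() < pde;
          if (d1 && d2) {
            rm.in.aap += 2;
            rm.p -= 1;
          } else if (d1) {
            rm.in.aap += 1;
            rm.in.aa[sd.msp[1]] += 1;
            rm.p -= 1;
          } else if (d2) {
            rm.in.aap += 1;
            rm.in.aa[sd.msp[0]] += 1;
            rm.p -= 1;
          }
        }
      }
    }
  }

  // ---------------------------------------------------------------------
  // phase 4: monomer chemistry

  void chemistry_compartment(Compart& C, bool outside) {
    // catalysis: co-resident functional NSR / NSP upgrades formation for
    // the whole compartment this step; copies do not stack
    bool has_nsr = false, has_nsp = false;
    for (const Rna& r : C.rnas) {
      if (!r.dead && r.seq.find(sd.nsr) != std::string::npos) {
        has_nsr = true;
        break;
      }
    }
    for (const Pep& q : C.peps) {
      if (!q.dead && q.a1 == sd.nsp[0] && q.a2 == sd.nsp[1]) {
        has_nsp = true;
        break;
      }
    }
    double pnf = par.P_NF;
    if (has_nsr && has_nsp)
      pnf = std::max(par.P_NFR, par.P_NFP);
    else if (has_nsr)
      pnf = par.P_NFR;
    else if (has_nsp)
      pnf = par.P_NFP;

    // formation and decay computed from start-of-phase counts
    long f_nt = rbinom(C.np, std::min(1.0, pnf));
    long f_am = rbinom(C.ap, std::min(1.0, par.P_AF));
    long f_aa = rbinom(C.aap, std::min(1.0, par.P_AAF));
    double pnd = std::min(1.0, par.P_ND * (outside ? par.F_DO : 1.0));
    std::array<long, 4> d_nt;
    for (int t = 0; t < 4; ++t) d_nt[t] = rbinom(C.nt[t], pnd);
    long d_am = rbinom(C.am, std::min(1.0, par.P_AD));
    std::array<long, 6> d_aa;
    for (int t = 0; t < 6; ++t) d_aa[t] = rbinom(C.aa[t], par.P_AAD);

    C.np -= f_nt;
    {  // random base identity
      long rem = f_nt;
      for (int t = 0; t < 3; ++t) {
        long k = rbinom(rem, 1.0 / (4 - t));
        C.nt[t] += k;
        rem -= k;
      }
      C.nt[3] += rem;
    }
    C.ap -= f_am;
    C.am += f_am;
    C.aap -= f_aa;
    {
      long rem = f_aa;
      for (int t = 0; t < 5; ++t) {
        long k = rbinom(rem, 1.0 / (6 - t));
        C.aa[t] += k;
        rem -= k;
      }
      C.aa[5] += rem;
    }
    for (int t = 0; t < 4; ++t) {
      C.nt[t] -= d_nt[t];
      C.np += d_nt[t];
    }
    C.am -= d_am;
    C.ap += d_am;
    for (int t = 0; t < 6; ++t) {
      C.aa[t] -= d_aa[t];
      C.aap += d_aa[t];
    }
  }

  void phase_chemistry() {
    std::vector<int> ord = shuffled_rooms();
    for (int i : ord) {
      Room& rm = rooms[i];
      chemistry_compartment(rm.out, true);
      if (rm.cell) {
        chemistry_compartment(rm.in, false);
        // membrane amphiphile decay (protected); product appears inside
        long k = rbinom(rm.b, std::min(1.0, par.P_AD * par.F_DW));
        rm.b -= k;
        rm.in.ap += k;
        if (rm.b <= 0) dissolve_cell(rm);
      }
    }
  }

  // ---------------------------------------------------------------------
  // phase 5: movement of free entities (exterior compartments only)

  void phase_movement() {
    size_t R = rooms.size();
    std::vector<std::array<long, 14>> delta(R);
    for (auto& d : delta) d.fill(0);
    std::vector<std::pair<int, Rna>> rna_movers;
    std::vector<std::pair<int, Pep>> pep_movers;

    double pmv = std::min(1.0, par.P_MV);
    for (size_t i = 0; i < R; ++i) {
      Compart& C = rooms[i].out;
      long* fields[14] = {&C.np,    &C.ap,    &C.aap,   &C.nt[0], &C.nt[1],
                          &C.nt[2], &C.nt[3], &C.am,    &C.aa[0], &C.aa[1],
                          &C.aa[2], &C.aa[3], &C.aa[4], &C.aa[5]};
      for (int f = 0; f < 14; ++f) {
        long mv = rbinom(*fields[f], pmv);
        if (mv == 0) continue;
        std::array<long, 4> dirs = rsplit4(mv);
        for (int d = 0; d < 4; ++d) {
          int j = neighbor((int)i, d);
          if (j < 0) continue;  // reflecting boundary: move cancelled
          *fields[f] -= dirs[d];
          delta[j][f] += dirs[d];
        }
      }
      for (size_t k = 0; k < C.rnas.size(); ++k) {
        Rna& r = C.rnas[k];
        if (r.dead) continue;
        if (runif() < k_move((double)r.mass(), par.P_MV)) {
          int j = neighbor((int)i, rint(4));
          if (j < 0) continue;
          rna_movers.push_back({j, std::move(r)});
          r = Rna();
          r.dead = true;
        }
      }
      for (size_t k = 0; k < C.peps.size(); ++k) {
        Pep& q = C.peps[k];
        if (q.dead) continue;
        if (runif() < k_move(2.0, par.P_MV)) {
          int j = neighbor((int)i, rint(4));
          if (j < 0) continue;
          pep_movers.push_back({j, q});
          q.dead = true;
        }
      }
      C.compact();
    }
    for (size_t i = 0; i < R; ++i) {
      Compart& C = rooms[i].out;
      long* fields[14] = {&C.np,    &C.ap,    &C.aap,   &C.nt[0], &C.nt[1],
                          &C.nt[2], &C.nt[3], &C.am,    &C.aa[0], &C.aa[1],
                          &C.aa[2], &C.aa[3], &C.aa[4], &C.aa[5]};
      for (int f = 0; f < 14; ++f) *fields[f] += delta[i][f];
    }
    for (auto& mv : rna_movers) {
      mv.second.dead = false;
      rooms[mv.first].out.rnas.push_back(std::move(mv.second));
    }
    for (auto& mv : pep_movers) {
      mv.second.dead = false;
      rooms[mv.first].out.peps.push_back(mv.second);
    }
  }

  // ---------------------------------------------------------------------

  void run_phase(const std::string& ph) {
    if (ph == "protocell") phase_cells();
    else if (ph == "membrane") phase_membrane();
    else if (ph == "polymer") phase_polymers();
    else if (ph == "chemistry") phase_chemistry();
    else if (ph == "movement") phase_movement();
    else stop("unknown phase '%s'", ph.c_str());
  }

  void step() {
    step_no += 1;
    std::array<std::string, 5> order{
        {"protocell", "membrane", "polymer", "chemistry", "movement"}};
    if (randomize_phases) std::shuffle(order.begin(), order.end(), rng);
    for (const auto& ph : order) run_phase(ph);
  }

  // --- accounting ---

  void observed(long long& nt_eq, long long& am_eq, long long& aa_eq) const {
    nt_eq = am_eq = aa_eq = 0;
    for (const Room& rm : rooms) {
      for (const Compart* C : {&rm.out, &rm.in}) {
        nt_eq += C->np + C->nt[0] + C->nt[1] + C->nt[2] + C->nt[3];
        am_eq += C->ap + C->am;
        aa_eq += C->aap;
        for (int t = 0; t < 6; ++t) aa_eq += C->aa[t];
        for (const Rna& r : C->rnas) {
          if (r.dead) continue;
          nt_eq += r.len() + r.paired_len();
          aa_eq += r.bound_count();
        }
        for (const Pep& q : C->peps)
          if (!q.dead) aa_eq += 2;
      }
      am_eq += rm.b;
      aa_eq += 2 * rm.p;  // each membrane MSP is a dipeptide
    }
  }
};

// ---------------------------------------------------------------------------
// exported kernels

// [[Rcpp::export]]
double cpp_membrane_formation_probability(double a, double P_MF,
                                          double L_AM) {
  return k_membrane_formation(a, P_MF, L_AM);
}

// [[Rcpp::export]]
double cpp_separation_probability(double n, double P_SP) {
  return k_separation(n, P_SP);
}

// [[Rcpp::export]]
double cpp_bond_break_probability(bool double_region, bool outside,
                                  double P_BB, double F_DO) {
  return k_bond_break(double_region, outside, P_BB, F_DO);
}

// [[Rcpp::export]]
double cpp_division_probability(double b, double P_CD, double L_AM) {
  return k_division(b, P_CD, L_AM);
}

// [[Rcpp::export]]
double cpp_amphiphile_leave_probability(double b, double i, double p,
                                        double P_ALM, double F_MSP) {
  return k_amph_leave(b, i, p, P_ALM, F_MSP);
}

// [[Rcpp::export]]
double cpp_permeation_probability(int species, double b, double i,
                                  List params) {
  Params P = params_from_list(params);
  return k_permeation(species, b, i, P);
}

// [[Rcpp::export]]
double cpp_polymer_move_probability(double m, double P_MV) {
  return k_move(m, P_MV);
}

// ---------------------------------------------------------------------------
// exported sequence utilities

// [[Rcpp::export]]
List cpp_find_binding_sites(std::string seq, List seqdefs, int L_AABS) {
  SeqDefs sd = seqdefs_from_list(seqdefs);
  Rna r;
  r.seq = seq;
  recompute_sites(r, sd, L_AABS);
  IntegerVector off((int)r.site_off.size());
  CharacterVector typ((int)r.site_off.size());
  for (size_t k = 0; k < r.site_off.size(); ++k) {
    off[(int)k] = r.site_off[k];
    typ[(int)k] = std::string(1, AA_LETTERS[r.site_aa[k]]);
  }
  return List::create(_["offset"] = off, _["type"] = typ);
}

// [[Rcpp::export]]
IntegerVector cpp_scan_motifs(std::string seq, List seqdefs) {
  SeqDefs sd = seqdefs_from_list(seqdefs);
  IntegerVector out = IntegerVector::create(
      _["MSPG"] = count_occurrences(seq, sd.mspg),
      _["NSPG"] = count_occurrences(seq, sd.nspg),
      _["NSR"] = count_occurrences(seq, sd.nsr),
      _["control_gene"] = count_occurrences(seq, sd.ctpg),
      _["control_rna"] = count_occurrences(seq, sd.ctr));
  return out;
}

// ---------------------------------------------------------------------------
// world lifecycle

static World* get_world(SEXP xp) {
  XPtr<World> w(xp);
  if (!w) stop("invalid world pointer");
  return w.get();
}

// [[Rcpp::export]]
SEXP cpp_world_new(List params, List seqdefs, double seed) {
  Params P = params_from_list(params);
  SeqDefs sd = seqdefs_from_list(seqdefs);
  int N = (int)P.N;
  if (N < 1) stop("grid side N must be >= 1");
  XPtr<World> w(new World(N, P, sd, (uint64_t)seed), true);
  return w;
}

// [[Rcpp::export]]
void cpp_world_scatter_precursors(SEXP xp, double t_npb, double t_apb,
                                 double t_aapb) {
  World* w = get_world(xp);
  int R = (int)w->rooms.size();
  for (long k = 0; k < (long)t_npb; ++k) w->rooms[w->rint(R)].out.np += 1;
  for (long k = 0; k < (long)t_apb; ++k) w->rooms[w->rint(R)].out.ap += 1;
  for (long k = 0; k < (long)t_aapb; ++k) w->rooms[w->rint(R)].out.aap += 1;
  w->led.nt_init += (long long)t_npb;
  w->led.am_init += (long long)t_apb;
  w->led.aa_init += (long long)t_aapb;
}

// [[Rcpp::export]]
void cpp_world_step(SEXP xp, int nsteps) {
  World* w = get_world(xp);
  for (int s = 0; s < nsteps; ++s) w->step();
}

// [[Rcpp::export]]
void cpp_world_run_phase(SEXP xp, std::string phase) {
  World* w = get_world(xp);
  w->step_no += 1;
  w->run_phase(phase);
}

// [[Rcpp::export]]
void cpp_world_set_param(SEXP xp, std::string name, double value) {
  World* w = get_world(xp);
  if (!set_param_field(w->par, name, value))
    stop("unknown parameter '%s'", name.c_str());
}

// [[Rcpp::export]]
double cpp_world_get_param(SEXP xp, std::string name) {
  World* w = get_world(xp);
  Params p = w->par;
  // read via a copy + probe: set to sentinel impossible; simpler to map
#define GETF(f) if (name == #f) return p.f;
  GETF(P_AD) GETF(P_AF) GETF(P_AJM) GETF(P_ALM) GETF(P_APP) GETF(P_AT)
  GETF(P_BB) GETF(P_CB) GETF(P_CD) GETF(P_CF) GETF(P_FP) GETF(P_MC)
  GETF(P_MF) GETF(P_MV) GETF(P_ND) GETF(P_NDE) GETF(P_NF) GETF(P_NFR)
  GETF(P_NPP) GETF(P_RL) GETF(P_SP) GETF(P_TL) GETF(P_AABR) GETF(P_AAD)
  GETF(P_AADE) GETF(P_AAF) GETF(P_AAPP) GETF(P_AATL) GETF(P_NFP) GETF(P_PBB)
  GETF(P_PJM) GETF(P_PLM) GETF(P_PLR) GETF(N) GETF(T_NPB) GETF(T_APB)
  GETF(T_AAPB) GETF(F_DO) GETF(F_DW) GETF(F_MSP) GETF(L_AM) GETF(L_NSR)
  GETF(L_AABS)
#undef GETF
  stop("unknown parameter '%s'", name.c_str());
  return NA_REAL;
}

// [[Rcpp::export]]
void cpp_world_set_phase_randomization(SEXP xp, bool on) {
  get_world(xp)->randomize_phases = on;
}

// [[Rcpp::export]]
long cpp_world_step_no(SEXP xp) { return get_world(xp)->step_no; }

// ---------------------------------------------------------------------------
// fixture mutators

// [[Rcpp::export]]
void cpp_room_set_counts(SEXP xp, int row, int col, bool inside,
                         IntegerVector counts) {
  World* w = get_world(xp);
  Room& rm = w->rooms[w->idx(row, col)];
  Compart& C = inside ? rm.in : rm.out;
  if (inside && !rm.cell) stop("room has no protocell; no interior exists");
  CharacterVector nms = counts.names();
  long long d_nt = 0, d_am = 0, d_aa = 0;
  for (int k = 0; k < counts.size(); ++k) {
    std::string nm = as<std::string>(nms[k]);
    long v = counts[k];
    long* tgt = nullptr;
    if (nm == "np") { tgt = &C.np; d_nt += v - C.np; }
    else if (nm == "ap") { tgt = &C.ap; d_am += v - C.ap; }
    else if (nm == "aap") { tgt = &C.aap; d_aa += v - C.aap; }
    else if (nm == "am") { tgt = &C.am; d_am += v - C.am; }
    else if (nm.size() == 4 && nm.substr(0, 3) == "nt_") {
      int t = base_index(nm[3]);
      tgt = &C.nt[t];
      d_nt += v - C.nt[t];
    } else if (nm.size() == 4 && nm.substr(0, 3) == "aa_") {
      int t = aa_index(nm[3]);
      tgt = &C.aa[t];
      d_aa += v - C.aa[t];
    } else {
      stop("unknown count field '%s'", nm.c_str());
    }
    *tgt = v;
  }
  w->led.nt_inoc += d_nt;
  w->led.am_inoc += d_am;
  w->led.aa_inoc += d_aa;
}

// [[Rcpp::export]]
void cpp_room_add_cell(SEXP xp, int row, int col, int b, int p) {
  World* w = get_world(xp);
  Room& rm = w->rooms[w->idx(row, col)];
  if (rm.cell) stop("room already holds a protocell");
  rm.cell = true;
  rm.b = b;
  rm.p = p;
  w->led.am_inoc += b;
  w->led.aa_inoc += 2LL * p;
}

// [[Rcpp::export]]
void cpp_room_add_rna(SEXP xp, int row, int col, bool inside,
                      std::string seq, int comp_start, std::string comp) {
  World* w = get_world(xp);
  Room& rm = w->rooms[w->idx(row, col)];
  if (inside && !rm.cell) stop("room has no protocell; no interior exists");
  Compart& C = inside ? rm.in : rm.out;
  Rna r = w->make_rna(seq);
  long res = (long)seq.size();
  if (!comp.empty()) {
    if (comp_start < 0 || comp_start + (int)comp.size() > (int)seq.size())
      stop("complement does not fit on the template");
    r.segs.push_back(Seg{comp_start, comp});
    res += (long)comp.size();
  }
  C.rnas.push_back(std::move(r));
  w->led.nt_inoc += res;
}

// [[Rcpp::export]]
void cpp_room_add_peptide(SEXP xp, int row, int col, bool inside,
                          std::string residues) {
  World* w = get_world(xp);
  Room& rm = w->rooms[w->idx(row, col)];
  if (inside && !rm.cell) stop("room has no protocell; no interior exists");
  Compart& C = inside ? rm.in : rm.out;
  if (residues.size() != 2) stop("free peptides are dipeptides");
  Pep q;
  q.a1 = (int8_t)aa_index(residues[0]);
  q.a2 = (int8_t)aa_index(residues[1]);
  C.peps.push_back(q);
  w->led.aa_inoc += 2;
}

// ---------------------------------------------------------------------------
// inoculation

// [[Rcpp::export]]
IntegerVector cpp_world_inoculate_cells(SEXP xp, int n_cells, int b,
                                        CharacterVector gene_seqs) {
  World* w = get_world(xp);
  std::vector<int> free_rooms;
  IntegerVector placed;
  for (int c = 0; c < n_cells; ++c) {
    free_rooms.clear();
    for (size_t i = 0; i < w->rooms.size(); ++i)
      if (!w->rooms[i].cell) free_rooms.push_back((int)i);
    if (free_rooms.empty()) break;
    int i = free_rooms[w->rint((int)free_rooms.size())];
    Room& rm = w->rooms[i];
    rm.cell = true;
    rm.b = b;
    rm.p = 0;
    w->led.am_inoc += b;
    for (int g = 0; g < gene_seqs.size(); ++g) {
      std::string s = as<std::string>(gene_seqs[g]);
      rm.in.rnas.push_back(w->make_rna(s));
      w->led.nt_inoc += (long long)s.size();
    }
    placed.push_back(i);
  }
  return placed;
}

// insert one gene copy into a random protocell whose interior contains every
// motif in `required`; returns the room index or -1 when no cell qualifies
// [[Rcpp::export]]
int cpp_world_insert_gene(SEXP xp, std::string seq,
                          CharacterVector required) {
  World* w = get_world(xp);
  std::vector<int> elig;
  for (size_t i = 0; i < w->rooms.size(); ++i) {
    Room& rm = w->rooms[i];
    if (!rm.cell) continue;
    bool ok = true;
    for (int m = 0; m < required.size(); ++m) {
      std::string mot = as<std::string>(required[m]);
      bool found = false;
      for (const Rna& r : rm.in.rnas) {
        if (!r.dead && r.seq.find(mot) != std::string::npos) {
          found = true;
          break;
        }
      }
      if (!found) { ok = false; break; }
    }
    if (ok) elig.push_back((int)i);
  }
  if (elig.empty()) return -1;
  int i = elig[w->rint((int)elig.size())];
  w->rooms[i].in.rnas.push_back(w->make_rna(seq));
  w->led.nt_inoc += (long long)seq.size();
  return i;
}

// `required` interpretation for empty-protocell targets: zero motifs
// [[Rcpp::export]]
int cpp_world_insert_gene_empty_cell(SEXP xp, std::string seq) {
  World* w = get_world(xp);
  std::vector<int> elig;
  for (size_t i = 0; i < w->rooms.size(); ++i) {
    Room& rm = w->rooms[i];
    if (rm.cell && rm.in.rnas.empty()) elig.push_back((int)i);
  }
  if (elig.empty()) return -1;
  int i = elig[w->rint((int)elig.size())];
  w->rooms[i].in.rnas.push_back(w->make_rna(seq));
  w->led.nt_inoc += (long long)seq.size();
  return i;
}

// first free full-length strand that is not the template itself (used by
// the replication-fidelity probe); "" when none exists
// [[Rcpp::export]]
std::string cpp_world_first_free_copy(SEXP xp, std::string template_seq) {
  World* w = get_world(xp);
  for (Room& rm : w->rooms) {
    for (Compart* C : {&rm.out, &rm.in}) {
      for (const Rna& r : C->rnas) {
        if (r.dead || !r.segs.empty()) continue;
        if (r.seq.size() == template_seq.size() && r.seq != template_seq)
          return r.seq;
      }
    }
  }
  return "";
}

// ---------------------------------------------------------------------------
// observables

// [[Rcpp::export]]
List cpp_world_census(SEXP xp) {
  World* w = get_world(xp);
  const SeqDefs& sd = w->sd;
  std::array<std::string, 5> motifs{{sd.mspg, sd.nspg, sd.nsr, sd.ctpg,
                                     sd.ctr}};
  std::array<long, 5> genes{{0, 0, 0, 0, 0}};
  long msp = 0, nsp = 0, ctp = 0;
  long np = 0, ap = 0, aap = 0, ntf = 0, amf = 0, aaf = 0, amm = 0;
  long strands = 0, residues = 0, peps_free = 0, cells = 0;
  std::map<std::string, long> classes;

  auto pep_class = [&](int a1, int a2) {
    if (a1 == sd.msp[0] && a2 == sd.msp[1]) return 0;
    if (a1 == sd.nsp[0] && a2 == sd.nsp[1]) return 1;
    if (a1 == sd.ctl[0] && a2 == sd.ctl[1]) return 2;
    return -1;
  };

  for (Room& rm : w->rooms) {
    for (Compart* C : {&rm.out, &rm.in}) {
      np += C->np;
      ap += C->ap;
      aap += C->aap;
      amf += C->am;
      for (int t = 0; t < 4; ++t) ntf += C->nt[t];
      for (int t = 0; t < 6; ++t) aaf += C->aa[t];
      for (const Rna& r : C->rnas) {
        if (r.dead) continue;
        strands += 1;
        residues += r.len() + r.paired_len();
        for (int m = 0; m < 5; ++m)
          genes[m] += count_occurrences(r.seq, motifs[m]);
        for (size_t k = 0; k < r.lig.size(); ++k) {
          if (r.lig[k]) {
            int cls = pep_class(r.occ[k], r.occ[k + 1]);
            if (cls == 0) msp += 1;
            else if (cls == 1) nsp += 1;
            else if (cls == 2) ctp += 1;
          }
        }
      }
      for (const Pep& q : C->peps) {
        if (q.dead) continue;
        peps_free += 1;
        int cls = pep_class(q.a1, q.a2);
        if (cls == 0) msp += 1;
        else if (cls == 1) nsp += 1;
        else if (cls == 2) ctp += 1;
      }
    }
    if (rm.cell) {
      cells += 1;
      amm += rm.b;
      msp += rm.p;
      // exact gene-content signature of the interior
      bool have[5] = {false, false, false, false, false};
      for (const Rna& r : rm.in.rnas) {
        if (r.dead) continue;
        for (int m = 0; m < 5; ++m)
          if (!have[m] && r.seq.find(motifs[m]) != std::string::npos)
            have[m] = true;
      }
      static const char* keys[5] = {"MSPG", "NSPG", "NSR", "CTPG", "CTR"};
      std::string sig;
      for (int m = 0; m < 5; ++m) {
        if (have[m]) {
          if (!sig.empty()) sig += "+";
          sig += keys[m];
        }
      }
      if (sig.empty()) sig = "empty";
      classes[sig] += 1;
    }
  }

  CharacterVector ck((int)classes.size());
  IntegerVector cv((int)classes.size());
  int k = 0;
  for (auto& kv : classes) {
    ck[k] = kv.first;
    cv[k] = (int)kv.second;
    ++k;
  }
  cv.names() = ck;

  return List::create(
      _["step"] = (double)w->step_no, _["protocells"] = (double)cells,
      _["classes"] = cv,
      _["genes"] = NumericVector::create(
          _["mspg"] = (double)genes[0], _["nspg"] = (double)genes[1],
          _["nsr"] = (double)genes[2], _["ctpg"] = (double)genes[3],
          _["ctr"] = (double)genes[4]),
      _["peptides"] = NumericVector::create(_["msp"] = (double)msp,
                                            _["nsp"] = (double)nsp,
                                            _["ctp"] = (double)ctp),
      _["materials"] = NumericVector::create(
          _["np"] = (double)np, _["ap"] = (double)ap, _["aap"] = (double)aap,
          _["nt"] = (double)ntf, _["aa"] = (double)aaf,
          _["am_free"] = (double)amf, _["am_membrane"] = (double)amm,
          _["rna_strands"] = (double)strands,
          _["rna_residues"] = (double)residues,
          _["peptides_free"] = (double)peps_free));
}

// [[Rcpp::export]]
List cpp_world_audit(SEXP xp) {
  World* w = get_world(xp);
  long long nt_eq, am_eq, aa_eq;
  w->observed(nt_eq, am_eq, aa_eq);
  return List::create(
      _["class"] = CharacterVector::create("nucleotide", "amphiphile",
                                           "amino_acid"),
      _["expected"] = NumericVector::create(
          (double)(w->led.nt_init + w->led.nt_inoc),
          (double)(w->led.am_init + w->led.am_inoc),
          (double)(w->led.aa_init + w->led.aa_inoc)),
      _["observed"] = NumericVector::create((double)nt_eq, (double)am_eq,
                                            (double)aa_eq));
}

// full structural dump (for inspection, tests, and checkpointing)
// [[Rcpp::export]]
List cpp_world_state(SEXP xp) {
  World* w = get_world(xp);
  auto comp_list = [&](const Compart& C) {
    List rl((int)C.rnas.size());
    for (size_t k = 0; k < C.rnas.size(); ++k) {
      const Rna& r = C.rnas[k];
      List segs((int)r.segs.size());
      for (size_t s = 0; s < r.segs.size(); ++s)
        segs[(int)s] = List::create(_["start"] = r.segs[s].start,
                                    _["bases"] = r.segs[s].bases,
                                    _["locked"] = r.segs[s].locked);
      IntegerVector occ((int)r.occ.size());
      for (size_t s = 0; s < r.occ.size(); ++s) occ[(int)s] = r.occ[s];
      IntegerVector lg((int)r.lig.size());
      for (size_t s = 0; s < r.lig.size(); ++s) lg[(int)s] = r.lig[s];
      rl[(int)k] = List::create(_["seq"] = r.seq, _["segs"] = segs,
                                _["occ"] = occ, _["lig"] = lg);
    }
    CharacterVector pl((int)C.peps.size());
    for (size_t k = 0; k < C.peps.size(); ++k) {
      std::string s;
      s += AA_LETTERS[C.peps[k].a1];
      s += AA_LETTERS[C.peps[k].a2];
      pl[(int)k] = s;
    }
    return List::create(
        _["np"] = (double)C.np, _["ap"] = (double)C.ap,
        _["aap"] = (double)C.aap, _["am"] = (double)C.am,
        _["nt"] = NumericVector::create(
            _["A"] = (double)C.nt[0], _["C"] = (double)C.nt[1],
            _["G"] = (double)C.nt[2], _["U"] = (double)C.nt[3]),
        _["aa"] = NumericVector::create(
            _["P"] = (double)C.aa[0], _["Q"] = (double)C.aa[1],
            _["R"] = (double)C.aa[2], _["S"] = (double)C.aa[3],
            _["T"] = (double)C.aa[4], _["L"] = (double)C.aa[5]),
        _["rnas"] = rl, _["peptides"] = pl);
  };
  List rl((int)w->rooms.size());
  for (size_t i = 0; i < w->rooms.size(); ++i) {
    const Room& rm = w->rooms[i];
    rl[(int)i] = List::create(
        _["row"] = (int)(i / w->N), _["col"] = (int)(i % w->N),
        _["cell"] = rm.cell, _["b"] = (double)rm.b, _["p"] = (double)rm.p,
        _["out"] = comp_list(rm.out), _["in"] = comp_list(rm.in));
  }
  std::ostringstream os;
  os << w->rng;
  return List::create(
      _["N"] = w->N, _["step"] = (double)w->step_no, _["rooms"] = rl,
      _["ledger"] = NumericVector::create(
          _["nt_init"] = (double)w->led.nt_init,
          _["am_init"] = (double)w->led.am_init,
          _["aa_init"] = (double)w->led.aa_init,
          _["nt_inoc"] = (double)w->led.nt_inoc,
          _["am_inoc"] = (double)w->led.am_inoc,
          _["aa_inoc"] = (double)w->led.aa_inoc),
      _["rng_state"] = os.str());
}

// [[Rcpp::export]]
void cpp_world_set_rng_state(SEXP xp, std::string state) {
  World* w = get_world(xp);
  std::istringstream is(state);
  is >> w->rng;
}

// [[Rcpp::export]]
void cpp_world_set_step_no(SEXP xp, double step) {
  get_world(xp)->step_no = (long)step;
}

// [[Rcpp::export]]
void cpp_world_set_ledger(SEXP xp, NumericVector led) {
  World* w = get_world(xp);
  w->led.nt_init = (long long)led["nt_init"];
  w->led.am_init = (long long)led["am_init"];
  w->led.aa_init = (long long)led["aa_init"];
  w->led.nt_inoc = (long long)led["nt_inoc"];
  w->led.am_inoc = (long long)led["am_inoc"];
  w->led.aa_inoc = (long long)led["aa_inoc"];
}

// restore one room from its dumped representation (checkpoint/resume)
// [[Rcpp::export]]
void cpp_world_restore_room(SEXP xp, int index, List room) {
  World* w = get_world(xp);
  Room& rm = w->rooms[index];
  rm.cell = as<bool>(room["cell"]);
  rm.b = (long)as<double>(room["b"]);
  rm.p = (long)as<double>(room["p"]);
  auto restore_comp = [&](Compart& C, List cl) {
    C = Compart();
    C.np = (long)as<double>(cl["np"]);
    C.ap = (long)as<double>(cl["ap"]);
    C.aap = (long)as<double>(cl["aap"]);
    C.am = (long)as<double>(cl["am"]);
    NumericVector nt = cl["nt"], aa = cl["aa"];
    for (int t = 0; t < 4; ++t) C.nt[t] = (long)nt[t];
    for (int t = 0; t < 6; ++t) C.aa[t] = (long)aa[t];
    List rl = cl["rnas"];
    for (int k = 0; k < rl.size(); ++k) {
      List rr = rl[k];
      Rna r = w->make_rna(as<std::string>(rr["seq"]));
      List segs = rr["segs"];
      for (int s = 0; s < segs.size(); ++s) {
        List sg = segs[s];
        bool lk = sg.containsElementNamed("locked") && as<bool>(sg["locked"]);
        r.segs.push_back(
            Seg{as<int>(sg["start"]), as<std::string>(sg["bases"]), lk});
      }
      IntegerVector occ = rr["occ"], lg = rr["lig"];
      for (int s = 0; s < occ.size() && s < (int)r.occ.size(); ++s)
        r.occ[s] = (int8_t)occ[s];
      for (int s = 0; s < lg.size() && s < (int)r.lig.size(); ++s)
        r.lig[s] = (uint8_t)lg[s];
      C.rnas.push_back(std::move(r));
    }
    CharacterVector pl = cl["peptides"];
    for (int k = 0; k < pl.size(); ++k) {
      std::string s = as<std::string>(pl[k]);
      Pep q;
      q.a1 = (int8_t)aa_index(s[0]);
      q.a2 = (int8_t)aa_index(s[1]);
      C.peps.push_back(q);
    }
  };
  restore_comp(rm.out, room["out"]);
  restore_comp(rm.in, room["in"]);
}
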