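// Monte Carlo engine for the directional cubic-lattice protein model.
//
// Residues live on Z^3 (optionally periodic per axis).  Each residue has an
// amino-acid type (0..19), a side-chain direction (one of the 6 unit
// vectors, never along a backbone bond) and a strand/coil state.  The
// energy is the sum of hydrogen-bond, pairwise amino-acid, state, solvent
// and steric terms; all parameters and matrix entries are integer-valued by
// convention so that incremental bookkeeping is exact in double precision.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>
#include <cstdlib>
#include <random>

using namespace Rcpp;

static const int DX[6] = {1, -1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, 1, -1, 0, 0};
static const int DZ[6] = {0, 0, 0, 0, 1, -1};
static inline int opp(int d) { return d ^ 1; }

static const int MAXRES = 512;   // residues per chain cap (id encoding)

// ---------------------------------------------------------------- RNG -----
// Self-contained generator so that trajectories replay bit-identically for
// a given seed independent of the standard library's distribution code.
struct RNG {
  std::mt19937_64 g;
  explicit RNG(uint64_t s) : g(s) {}
  double u() { return (g() >> 11) * (1.0 / 9007199254740992.0); }
  int ri(int n) {
    uint64_t un = (uint64_t)n;
    uint64_t lim = UINT64_MAX - UINT64_MAX % un;
    uint64_t v;
    do { v = g(); } while (v >= lim);
    return (int)(v % un);
  }
};
static inline uint64_t splitmix(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// ------------------------------------------------------------- system -----
struct Params {
  std::vector<double> M;  // 21 x 21 row-major, index 20 = solvent
  double eps_hb, eps_st, eps_state, kB;
  bool strict_perp;
};

struct ChainD {
  std::vector<int> x, y, z, aa, dr, st;
  bool alive = true;
  int len() const { return (int)x.size(); }
};

struct EB {
  double hb = 0, aa = 0, state = 0, sol = 0, steric = 0;
  int nhb = 0;
  double total() const { return hb + aa + state + sol + steric; }
  EB operator-(const EB& o) const {
    EB r;
    r.hb = hb - o.hb; r.aa = aa - o.aa; r.state = state - o.state;
    r.sol = sol - o.sol; r.steric = steric - o.steric; r.nhb = nhb - o.nhb;
    return r;
  }
  void operator+=(const EB& o) {
    hb += o.hb; aa += o.aa; state += o.state;
    sol += o.sol; steric += o.steric; nhb += o.nhb;
  }
};

struct Sys {
  int L[3];
  bool per[3];
  std::vector<ChainD> ch;
  std::vector<int> occ;       // linear site -> id + 1 (0 = empty)
  std::vector<uint8_t> mark;  // workspace keyed by id
  int nAlive = 0, nResAlive = 0;

  int vol() const { return L[0] * L[1] * L[2]; }
  int lin(int x, int y, int z) const { return (z * L[1] + y) * L[0] + x; }
  int id(int c, int i) const { return c * MAXRES + i; }
  void decode(int id, int& c, int& i) const { c = id / MAXRES; i = id % MAXRES; }

  // neighbouring site along d; -1 when it falls off a non-periodic wall
  int nbSite(int x, int y, int z, int d) const {
    int p[3] = {x + DX[d], y + DY[d], z + DZ[d]};
    for (int a = 0; a < 3; ++a) {
      if (p[a] < 0 || p[a] >= L[a]) {
        if (!per[a]) return -1;
        p[a] -= L[a] * (p[a] >= L[a] ? 1 : -1);
      }
    }
    return lin(p[0], p[1], p[2]);
  }
  int wrapc(int v, int a) const {
    if (per[a]) { v %= L[a]; if (v < 0) v += L[a]; }
    return v;
  }
  // minimum-image component difference (bond vectors are unit length)
  int mi(int d, int a) const {
    if (per[a]) {
      if (d > L[a] / 2) d -= L[a];
      if (d < -(L[a] / 2)) d += L[a];
    }
    return d;
  }
  void bond(int c, int i, int j, int* b) const {  // r_j - r_i, min image
    const ChainD& C = ch[c];
    b[0] = mi(C.x[j] - C.x[i], 0);
    b[1] = mi(C.y[j] - C.y[i], 1);
    b[2] = mi(C.z[j] - C.z[i], 2);
  }
  bool collinear(int c, int i) const {
    const ChainD& C = ch[c];
    if (i <= 0 || i >= C.len() - 1) return false;
    int b1[3], b2[3];
    bond(c, i - 1, i, b1);
    bond(c, i, i + 1, b2);
    return b1[0] == b2[0] && b1[1] == b2[1] && b1[2] == b2[2];
  }
  // direction code of unit vector, -1 if not unit
  static int dirCode(int x, int y, int z) {
    for (int d = 0; d < 6; ++d)
      if (x == DX[d] && y == DY[d] && z == DZ[d]) return d;
    return -1;
  }
  // directions from residue i towards its sequential neighbours
  int bondDirs(int c, int i, int* out) const {
    const ChainD& C = ch[c];
    int n = 0, b[3];
    if (i > 0) { bond(c, i, i - 1, b); out[n++] = dirCode(b[0], b[1], b[2]); }
    if (i < C.len() - 1) { bond(c, i, i + 1, b); out[n++] = dirCode(b[0], b[1], b[2]); }
    return n;
  }
  int admissible(int c, int i, int* out) const {  // side-chain options
    int bd[2];
    int nb = bondDirs(c, i, bd);
    int n = 0;
    for (int d = 0; d < 6; ++d) {
      bool ok = true;
      for (int k = 0; k < nb; ++k) if (bd[k] == d) ok = false;
      if (ok) out[n++] = d;
    }
    return n;
  }
  void occSet(int c, int i) {
    const ChainD& C = ch[c];
    occ[lin(C.x[i], C.y[i], C.z[i])] = id(c, i) + 1;
  }
  void occClear(int c, int i) {
    const ChainD& C = ch[c];
    occ[lin(C.x[i], C.y[i], C.z[i])] = 0;
  }
  void rebuildOcc() {
    std::fill(occ.begin(), occ.end(), 0);
    nAlive = 0; nResAlive = 0;
    for (int c = 0; c < (int)ch.size(); ++c) {
      if (!ch[c].alive) continue;
      ++nAlive; nResAlive += ch[c].len();
      for (int i = 0; i < ch[c].len(); ++i) occSet(c, i);
    }
    mark.assign(ch.size() * MAXRES, 0);
  }
};

// ------------------------------------------------------ energy terms ------
// contribution of an adjacent residue pair seen from u along direction d
static inline void pairE(const Sys& S, const Params& P,
                         int c1, int i1, int c2, int i2, int d, EB& e) {
  if (c1 == c2 && std::abs(i1 - i2) <= 1) return;  // sequential: no contact
  const ChainD& A = S.ch[c1];
  const ChainD& B = S.ch[c2];
  int du = A.dr[i1], dv = B.dr[i2];
  bool same = (du == dv);
  if (A.st[i1] && B.st[i2] && same &&
      (!P.strict_perp || (du != d && du != opp(d)))) {
    e.hb += P.eps_hb;
    e.nhb += 1;
  }
  bool facing = (du == d && dv == opp(d));
  bool parallel = (same && du != d && du != opp(d));
  if (facing || parallel) e.aa += P.M[A.aa[i1] * 21 + B.aa[i2]];
}

static inline void siteTerms(const Sys& S, const Params& P, int c, int i, EB& e) {
  const ChainD& C = S.ch[c];
  int s = S.nbSite(C.x[i], C.y[i], C.z[i], C.dr[i]);
  if (s < 0 || S.occ[s] == 0) e.sol += P.M[20 * 21 + C.aa[i]];
  e.state += P.eps_state * C.st[i];
}

static EB totalE(const Sys& S, const Params& P) {
  EB e;
  for (int c = 0; c < (int)S.ch.size(); ++c) {
    if (!S.ch[c].alive) continue;
    const ChainD& C = S.ch[c];
    for (int i = 0; i < C.len(); ++i) {
      int myid = S.id(c, i);
      for (int d = 0; d < 6; ++d) {
        int s = S.nbSite(C.x[i], C.y[i], C.z[i], d);
        if (s < 0) continue;
        int v = S.occ[s];
        if (v == 0) continue;
        int id2 = v - 1;
        if (id2 <= myid) continue;  // count each pair once
        int c2, i2;
        S.decode(id2, c2, i2);
        pairE(S, P, c, i, c2, i2, d, e);
      }
      if (i + 1 < C.len() && C.dr[i] == C.dr[i + 1]) e.steric += P.eps_st;
      siteTerms(S, P, c, i, e);
    }
  }
  return e;
}

// energy of all terms touching the id set A (marked in S.mark)
static EB localE(const Sys& S, const Params& P, const std::vector<int>& A) {
  EB e;
  for (int id1 : A) {
    int c, i;
    S.decode(id1, c, i);
    const ChainD& C = S.ch[c];
    for (int d = 0; d < 6; ++d) {
      int s = S.nbSite(C.x[i], C.y[i], C.z[i], d);
      if (s < 0) continue;
      int v = S.occ[s];
      if (v == 0) continue;
      int id2 = v - 1;
      if (id2 == id1) continue;
      if (S.mark[id2] && id2 < id1) continue;  // already counted at id2
      int c2, i2;
      S.decode(id2, c2, i2);
      pairE(S, P, c, i, c2, i2, d, e);
    }
    if (i + 1 < C.len() && C.dr[i] == C.dr[i + 1]) e.steric += P.eps_st;
    if (i > 0 && !S.mark[id1 - 1] && C.dr[i - 1] == C.dr[i]) e.steric += P.eps_st;
    siteTerms(S, P, c, i, e);
  }
  return e;
}

// --------------------------------------------------------- proposals ------
struct MoveRes {  // one residue's change with the revert record
  int c, i;
  int nx, ny, nz, ndr, nst;
  int ox, oy, oz, odr, ost;
};

struct Prop {
  bool valid = false;
  std::string reason = "";
  std::string kind = "";
  std::vector<MoveRes> mr;
};

static void fillOld(const Sys& S, MoveRes& m) {
  const ChainD& C = S.ch[m.c];
  m.ox = C.x[m.i]; m.oy = C.y[m.i]; m.oz = C.z[m.i];
  m.odr = C.dr[m.i]; m.ost = C.st[m.i];
}

static void applyProp(Sys& S, const std::vector<MoveRes>& mr, bool forward) {
  for (const MoveRes& m : mr) S.occClear(m.c, m.i);
  for (const MoveRes& m : mr) {
    ChainD& C = S.ch[m.c];
    if (forward) {
      C.x[m.i] = m.nx; C.y[m.i] = m.ny; C.z[m.i] = m.nz;
      C.dr[m.i] = m.ndr; C.st[m.i] = m.nst;
    } else {
      C.x[m.i] = m.ox; C.y[m.i] = m.oy; C.z[m.i] = m.oz;
      C.dr[m.i] = m.odr; C.st[m.i] = m.ost;
    }
    S.occSet(m.c, m.i);
  }
}

// residues whose energy terms can change: the moved set, its sequential
// neighbours, and every occupant adjacent to an old or new position
static void buildA(const Sys& S, const std::vector<MoveRes>& mr,
                   std::vector<int>& A) {
  A.clear();
  std::vector<uint8_t>& mark = const_cast<Sys&>(S).mark;
  auto add = [&](int id) {
    if (!mark[id]) { mark[id] = 1; A.push_back(id); }
  };
  for (const MoveRes& m : mr) {
    int base = S.id(m.c, m.i);
    add(base);
    if (m.i > 0) add(base - 1);
    if (m.i + 1 < S.ch[m.c].len()) add(base + 1);
    const int P[2][3] = {{m.ox, m.oy, m.oz}, {m.nx, m.ny, m.nz}};
    for (int k = 0; k < 2; ++k)
      for (int d = 0; d < 6; ++d) {
        int s = S.nbSite(P[k][0], P[k][1], P[k][2], d);
        if (s >= 0 && S.occ[s]) add(S.occ[s] - 1);
      }
  }
}
static void clearA(Sys& S, const std::vector<int>& A) {
  for (int id : A) S.mark[id] = 0;
}

// is the target site free, off-wall, and not held by a non-moved residue?
static bool siteFree(const Sys& S, int x, int y, int z,
                     const std::vector<MoveRes>& mr) {
  int p[3] = {x, y, z};
  for (int a = 0; a < 3; ++a)
    if (p[a] < 0 || p[a] >= S.L[a]) return false;  // callers pre-wrap
  int v = S.occ[S.lin(x, y, z)];
  if (v == 0) return true;
  int id2 = v - 1;
  for (const MoveRes& m : mr)
    if (S.id(m.c, m.i) == id2) return true;
  return false;
}

// a backbone move changes the bonds at non-moved sequential neighbours;
// their (kept) side chains must stay admissible or the move is invalid --
// rejecting on target-state validity keeps the proposal kernel symmetric
static bool neighborSideOk(const Sys& S, const std::vector<MoveRes>& mr) {
  for (const MoveRes& m : mr) {
    const ChainD& C = S.ch[m.c];
    for (int j : {m.i - 1, m.i + 1}) {
      if (j < 0 || j >= C.len()) continue;
      bool moved = false;
      for (const MoveRes& o : mr)
        if (o.c == m.c && o.i == j) moved = true;
      if (moved) continue;
      int b[3] = {S.mi(m.nx - C.x[j], 0), S.mi(m.ny - C.y[j], 1),
                  S.mi(m.nz - C.z[j], 2)};
      int code = Sys::dirCode(b[0], b[1], b[2]);
      if (code >= 0 && C.dr[j] == code) return false;
    }
  }
  return true;
}

static bool anyStrand(const Sys& S, int c, int lo, int hi) {
  const ChainD& C = S.ch[c];
  for (int i = std::max(0, lo); i <= std::min(C.len() - 1, hi); ++i)
    if (C.st[i]) return true;
  return false;
}

// pick uniformly from the admissible side-chain directions at the *proposed*
// geometry described by bond direction codes bd[0..nb-1]
static int drawDir(RNG& rng, const int* bd, int nb) {
  int opts[6], n = 0;
  for (int d = 0; d < 6; ++d) {
    bool ok = true;
    for (int k = 0; k < nb; ++k) if (bd[k] == d) ok = false;
    if (ok) opts[n++] = d;
  }
  return opts[rng.ri(n)];
}

static Prop propStateFlip(const Sys& S, int c, int i) {
  Prop p; p.kind = "state_flip";
  const ChainD& C = S.ch[c];
  MoveRes m; m.c = c; m.i = i;
  fillOld(S, m);
  m.nx = m.ox; m.ny = m.oy; m.nz = m.oz; m.ndr = m.odr;
  if (C.st[i]) {               // strand -> coil: always admissible
    m.nst = 0;
  } else {                     // coil -> strand
    if (!S.collinear(c, i)) { p.reason = "turn in backbone"; return p; }
    for (int j : {i - 1, i + 1}) {
      if (j < 0 || j >= C.len()) continue;
      if (C.st[j] && C.dr[j] != opp(C.dr[i])) {
        p.reason = "strand neighbour side chain not opposite";
        return p;
      }
    }
    m.nst = 1;
  }
  p.mr.push_back(m);
  p.valid = true;
  return p;
}

static Prop propSideChain(const Sys& S, int c, int i, RNG& rng, int forceDir) {
  Prop p; p.kind = "side_chain_rotate";
  const ChainD& C = S.ch[c];
  if (C.st[i]) { p.reason = "strand frozen"; return p; }
  MoveRes m; m.c = c; m.i = i;
  fillOld(S, m);
  m.nx = m.ox; m.ny = m.oy; m.nz = m.oz; m.nst = m.ost;
  if (forceDir >= 0) {
    int opts[6];
    int n = S.admissible(c, i, opts);
    bool ok = false;
    for (int k = 0; k < n; ++k) if (opts[k] == forceDir) ok = true;
    if (!ok || forceDir == C.dr[i]) { p.reason = "inadmissible direction"; return p; }
    m.ndr = forceDir;
  } else {
    int opts[6], n = 0, all[6];
    int na = S.admissible(c, i, all);
    for (int k = 0; k < na; ++k)
      if (all[k] != C.dr[i]) opts[n++] = all[k];  // a *new* direction
    m.ndr = opts[rng.ri(n)];
  }
  p.mr.push_back(m);
  p.valid = true;
  return p;
}

static Prop propEndMove(const Sys& S, int c, int i, RNG& rng, int forceDir) {
  Prop p; p.kind = "end_move";
  const ChainD& C = S.ch[c];
  if (i != 0 && i != C.len() - 1) { p.reason = "not a terminal residue"; return p; }
  int j = (i == 0) ? 1 : C.len() - 2;  // inner neighbour
  if (anyStrand(S, c, std::min(i, j), std::max(i, j))) {
    p.reason = "strand frozen"; return p;
  }
  int d = (forceDir >= 0) ? forceDir : rng.ri(6);
  int s = S.nbSite(C.x[j], C.y[j], C.z[j], d);
  if (s < 0) { p.reason = "outside box"; return p; }
  MoveRes m; m.c = c; m.i = i;
  fillOld(S, m);
  m.nx = S.wrapc(C.x[j] + DX[d], 0);
  m.ny = S.wrapc(C.y[j] + DY[d], 1);
  m.nz = S.wrapc(C.z[j] + DZ[d], 2);
  m.nst = 0;
  std::vector<MoveRes> self{m};
  if (!siteFree(S, m.nx, m.ny, m.nz, self)) { p.reason = "site occupied"; return p; }
  if (!neighborSideOk(S, self)) { p.reason = "neighbour side chain blocks"; return p; }
  int bd[1] = {opp(d)};  // backbone bond from the new site towards j
  m.ndr = drawDir(rng, bd, 1);
  p.mr.push_back(m);
  p.valid = true;
  return p;
}

// re-place internal residue i at the alternative site adjacent to both
// sequential neighbours (the corner flip / point rotation of lattice MC)
static Prop propCorner(const Sys& S, int c, int i, RNG& rng) {
  Prop p; p.kind = "point_rotation";
  const ChainD& C = S.ch[c];
  if (i <= 0 || i >= C.len() - 1) { p.reason = "terminal residue"; return p; }
  if (anyStrand(S, c, i - 1, i + 1)) { p.reason = "strand frozen"; return p; }
  int b1[3], b2[3];
  S.bond(c, i - 1, i, b1);   // r_i - r_{i-1}
  S.bond(c, i, i + 1, b2);   // r_{i+1} - r_i
  bool straight = (b1[0] == b2[0] && b1[1] == b2[1] && b1[2] == b2[2]);
  if (straight) { p.reason = "no alternative placement"; return p; }
  // corner: candidate = r_{i-1} + b2 (unwrapped), then wrapped
  MoveRes m; m.c = c; m.i = i;
  fillOld(S, m);
  m.nx = S.wrapc(C.x[i - 1] + b2[0], 0);
  m.ny = S.wrapc(C.y[i - 1] + b2[1], 1);
  m.nz = S.wrapc(C.z[i - 1] + b2[2], 2);
  if (m.nx < 0 || m.nx >= S.L[0] || m.ny < 0 || m.ny >= S.L[1] ||
      m.nz < 0 || m.nz >= S.L[2]) { p.reason = "outside box"; return p; }
  m.nst = 0;
  std::vector<MoveRes> self{m};
  if (!siteFree(S, m.nx, m.ny, m.nz, self)) { p.reason = "site occupied"; return p; }
  if (!neighborSideOk(S, self)) { p.reason = "neighbour side chain blocks"; return p; }
  int bd[2] = {Sys::dirCode(-b2[0], -b2[1], -b2[2]),
               Sys::dirCode(b1[0], b1[1], b1[2])};
  m.ndr = drawDir(rng, bd, 2);
  p.mr.push_back(m);
  p.valid = true;
  return p;
}

static void rot90(int* v, int axis) {  // one right-handed quarter turn
  int x = v[0], y = v[1], z = v[2];
  switch (axis) {
    case 0: v[1] = -z; v[2] = y; break;
    case 1: v[2] = -x; v[0] = z; break;
    case 2: v[0] = -y; v[1] = x; break;
  }
}

static Prop propCrank(const Sys& S, int c, int i, RNG& rng, int forceK) {
  Prop p; p.kind = "crankshaft";
  const ChainD& C = S.ch[c];
  if (i < 1 || i + 2 > C.len() - 1) { p.reason = "no flanking residues"; return p; }
  if (anyStrand(S, c, i - 1, i + 2)) { p.reason = "strand frozen"; return p; }
  int axis[3], w[3], w2[3];
  S.bond(c, i - 1, i + 2, axis);
  if (std::abs(axis[0]) + std::abs(axis[1]) + std::abs(axis[2]) != 1) {
    p.reason = "geometry"; return p;
  }
  S.bond(c, i - 1, i, w);
  S.bond(c, i + 2, i + 1, w2);
  if (w[0] != w2[0] || w[1] != w2[1] || w[2] != w2[2]) { p.reason = "geometry"; return p; }
  int k = (forceK > 0) ? forceK : 1 + rng.ri(3);
  int a = (axis[0] != 0) ? 0 : (axis[1] != 0 ? 1 : 2);
  int sgn = axis[a] > 0 ? 1 : -1;
  int wn[3] = {w[0], w[1], w[2]};
  for (int t = 0; t < ((sgn > 0) ? k : 4 - k) % 4; ++t) rot90(wn, a);
  MoveRes m1, m2;
  m1.c = c; m1.i = i; m2.c = c; m2.i = i + 1;
  fillOld(S, m1); fillOld(S, m2);
  m1.nx = S.wrapc(C.x[i - 1] + wn[0], 0);
  m1.ny = S.wrapc(C.y[i - 1] + wn[1], 1);
  m1.nz = S.wrapc(C.z[i - 1] + wn[2], 2);
  m2.nx = S.wrapc(C.x[i + 2] + wn[0], 0);
  m2.ny = S.wrapc(C.y[i + 2] + wn[1], 1);
  m2.nz = S.wrapc(C.z[i + 2] + wn[2], 2);
  int bad = 0;
  int pts[2][3] = {{m1.nx, m1.ny, m1.nz}, {m2.nx, m2.ny, m2.nz}};
  for (int t = 0; t < 2; ++t)
    for (int axq = 0; axq < 3; ++axq)
      if (pts[t][axq] < 0 || pts[t][axq] >= S.L[axq]) bad = 1;
  if (bad) { p.reason = "outside box"; return p; }
  m1.nst = 0; m2.nst = 0;
  std::vector<MoveRes> self{m1, m2};
  if (!siteFree(S, m1.nx, m1.ny, m1.nz, self) ||
      !siteFree(S, m2.nx, m2.ny, m2.nz, self)) {
    p.reason = "site occupied"; return p;
  }
  if (!neighborSideOk(S, self)) { p.reason = "neighbour side chain blocks"; return p; }
  // backbone bonds at the new geometry: i binds i-1 (-wn) and i+1 (axis)
  int acode = Sys::dirCode(axis[0], axis[1], axis[2]);
  int wcode = Sys::dirCode(wn[0], wn[1], wn[2]);
  int bd1[2] = {opp(wcode), acode};
  int bd2[2] = {opp(wcode), opp(acode)};
  m1.ndr = drawDir(rng, bd1, 2);
  m2.ndr = drawDir(rng, bd2, 2);
  p.mr.push_back(m1);
  p.mr.push_back(m2);
  p.valid = true;
  return p;
}

// unwrap a chain into continuous coordinates starting from residue 0
static void unwrap(const Sys& S, int c, std::vector<int>& ux,
                   std::vector<int>& uy, std::vector<int>& uz) {
  const ChainD& C = S.ch[c];
  int n = C.len();
  ux.resize(n); uy.resize(n); uz.resize(n);
  ux[0] = C.x[0]; uy[0] = C.y[0]; uz[0] = C.z[0];
  for (int i = 1; i < n; ++i) {
    int b[3];
    S.bond(c, i - 1, i, b);
    ux[i] = ux[i - 1] + b[0];
    uy[i] = uy[i - 1] + b[1];
    uz[i] = uz[i - 1] + b[2];
  }
}

static Prop propTranslate(const Sys& S, int c, RNG& rng, int forceDir) {
  Prop p; p.kind = "translate";
  const ChainD& C = S.ch[c];
  int d = (forceDir >= 0) ? forceDir : rng.ri(6);
  std::vector<MoveRes> mr(C.len());
  for (int i = 0; i < C.len(); ++i) {
    MoveRes& m = mr[i];
    m.c = c; m.i = i;
    fillOld(S, m);
    int nx = m.ox + DX[d], ny = m.oy + DY[d], nz = m.oz + DZ[d];
    nx = S.wrapc(nx, 0); ny = S.wrapc(ny, 1); nz = S.wrapc(nz, 2);
    if (nx < 0 || nx >= S.L[0] || ny < 0 || ny >= S.L[1] ||
        nz < 0 || nz >= S.L[2]) { p.reason = "outside box"; return p; }
    m.nx = nx; m.ny = ny; m.nz = nz; m.ndr = m.odr; m.nst = m.ost;
  }
  for (const MoveRes& m : mr)
    if (!siteFree(S, m.nx, m.ny, m.nz, mr)) { p.reason = "site occupied"; return p; }
  p.mr = mr;
  p.valid = true;
  return p;
}

static Prop propRotate(const Sys& S, int c, RNG& rng,
                       int forcePivot, int forceAxis, int forceK) {
  Prop p; p.kind = "rotate";
  const ChainD& C = S.ch[c];
  int n = C.len();
  int pv = (forcePivot >= 0) ? forcePivot : rng.ri(n);
  int a = (forceAxis >= 0) ? forceAxis : rng.ri(3);
  int k = (forceK > 0) ? forceK : 1 + rng.ri(3);
  std::vector<int> ux, uy, uz;
  unwrap(S, c, ux, uy, uz);
  std::vector<MoveRes> mr(n);
  for (int i = 0; i < n; ++i) {
    MoveRes& m = mr[i];
    m.c = c; m.i = i;
    fillOld(S, m);
    int v[3] = {ux[i] - ux[pv], uy[i] - uy[pv], uz[i] - uz[pv]};
    int dv[3] = {DX[C.dr[i]], DY[C.dr[i]], DZ[C.dr[i]]};
    for (int t = 0; t < k; ++t) { rot90(v, a); rot90(dv, a); }
    int nx = C.x[pv] + v[0];  // relative to the pivot's stored position
    int ny = C.y[pv] + v[1];
    int nz = C.z[pv] + v[2];
    nx = S.wrapc(nx, 0); ny = S.wrapc(ny, 1); nz = S.wrapc(nz, 2);
    if (nx < 0 || nx >= S.L[0] || ny < 0 || ny >= S.L[1] ||
        nz < 0 || nz >= S.L[2]) { p.reason = "outside box"; return p; }
    m.nx = nx; m.ny = ny; m.nz = nz;
    m.ndr = Sys::dirCode(dv[0], dv[1], dv[2]);
    m.nst = m.ost;
  }
  for (const MoveRes& m : mr)
    if (!siteFree(S, m.nx, m.ny, m.nz, mr)) { p.reason = "site occupied"; return p; }
  p.mr = mr;
  p.valid = true;
  return p;
}

// --------------------------------------------------- R <-> C++ bridge -----
static Sys sysFromR(List sys) {
  Sys S;
  IntegerVector box = sys["box"];
  LogicalVector per = sys["periodic"];
  for (int a = 0; a < 3; ++a) { S.L[a] = box[a]; S.per[a] = per[a]; }
  List chains = sys["chains"];
  for (int c = 0; c < chains.size(); ++c) {
    List ch = chains[c];
    ChainD C;
    IntegerVector aa = ch["aa"], x = ch["x"], y = ch["y"], z = ch["z"],
                  dr = ch["dir"], st = ch["state"];
    int n = aa.size();
    if (n > MAXRES) stop("chain longer than engine limit");
    C.aa.assign(aa.begin(), aa.end());
    C.x.assign(x.begin(), x.end());
    C.y.assign(y.begin(), y.end());
    C.z.assign(z.begin(), z.end());
    C.dr.assign(dr.begin(), dr.end());
    C.st.assign(st.begin(), st.end());
    S.ch.push_back(C);
  }
  S.occ.assign(S.vol(), 0);
  S.rebuildOcc();
  return S;
}

static List sysToR(const Sys& S) {
  List chains;
  for (int c = 0; c < (int)S.ch.size(); ++c) {
    if (!S.ch[c].alive) continue;
    const ChainD& C = S.ch[c];
    chains.push_back(List::create(
        _["aa"] = IntegerVector(C.aa.begin(), C.aa.end()),
        _["x"] = IntegerVector(C.x.begin(), C.x.end()),
        _["y"] = IntegerVector(C.y.begin(), C.y.end()),
        _["z"] = IntegerVector(C.z.begin(), C.z.end()),
        _["dir"] = IntegerVector(C.dr.begin(), C.dr.end()),
        _["state"] = IntegerVector(C.st.begin(), C.st.end())));
  }
  return List::create(
      _["box"] = IntegerVector::create(S.L[0], S.L[1], S.L[2]),
      _["periodic"] = LogicalVector::create(S.per[0], S.per[1], S.per[2]),
      _["chains"] = chains);
}

static Params paramsFromR(NumericMatrix M, List par) {
  Params P;
  if (M.nrow() != 21 || M.ncol() != 21) stop("interaction matrix must be 21 x 21");
  P.M.assign(M.begin(), M.end());  // column-major == row-major (symmetric)
  P.eps_hb = as<double>(par["eps_hb"]);
  P.eps_st = as<double>(par["eps_steric"]);
  P.eps_state = as<double>(par["eps_state"]);
  P.kB = as<double>(par["k_B"]);
  P.strict_perp = as<bool>(par["hb_strict_perpendicular"]);
  return P;
}

static NumericVector ebToR(const EB& e) {
  return NumericVector::create(
      _["e_hb"] = e.hb, _["e_aa"] = e.aa, _["e_state"] = e.state,
      _["e_solvent"] = e.sol, _["e_steric"] = e.steric,
      _["total"] = e.total(), _["n_hb"] = (double)e.nhb);
}

// [[Rcpp::export]]
NumericVector cpp_total_energy(List sys, NumericMatrix M, List par) {
  Sys S = sysFromR(sys);
  Params P = paramsFromR(M, par);
  return ebToR(totalE(S, P));
}

// ------------------------------------------------------- observables ------
struct Contacts { int total = 0, external = 0; };
static Contacts countContacts(const Sys& S) {
  Contacts r;
  for (int c = 0; c < (int)S.ch.size(); ++c) {
    if (!S.ch[c].alive) continue;
    const ChainD& C = S.ch[c];
    for (int i = 0; i < C.len(); ++i) {
      int myid = S.id(c, i);
      for (int d = 0; d < 6; ++d) {
        int s = S.nbSite(C.x[i], C.y[i], C.z[i], d);
        if (s < 0 || S.occ[s] == 0) continue;
        int id2 = S.occ[s] - 1;
        if (id2 <= myid) continue;
        int c2, i2;
        S.decode(id2, c2, i2);
        if (c2 == c && std::abs(i2 - i) <= 1) continue;
        r.total++;
        if (c2 != c) r.external++;
      }
    }
  }
  return r;
}

static bool isContactPair(const Sys& S, int c1, int i1, int c2, int i2) {
  if (c1 == c2 && std::abs(i1 - i2) <= 1) return false;
  const ChainD& A = S.ch[c1];
  const ChainD& B = S.ch[c2];
  int dx = std::abs(S.mi(A.x[i1] - B.x[i2], 0));
  int dy = std::abs(S.mi(A.y[i1] - B.y[i2], 1));
  int dz = std::abs(S.mi(A.z[i1] - B.z[i2], 2));
  return dx + dy + dz == 1;
}

static int countNative(const Sys& S, const IntegerMatrix& ref) {
  int n = 0;
  for (int k = 0; k < ref.nrow(); ++k)
    if (isContactPair(S, ref(k, 0), ref(k, 1), ref(k, 2), ref(k, 3))) ++n;
  return n;
}

// ------------------------------------------------------ MC iteration ------
struct Accounts {
  long prop[10] = {0};
  long acc[10] = {0};
};
enum MoveSlot { M_STATE = 0, M_SIDE, M_END, M_CORNER, M_CRANK,
                M_TRANS, M_ROT, M_INS, M_DEL };

struct Walker {
  Sys S;
  EB e;
  RNG rng;
  Accounts acct;
  Walker(Sys s, const Params& P, uint64_t seed)
      : S(std::move(s)), rng(seed) { e = totalE(S, P); }
};

static bool metro(RNG& rng, double dE, double kBT) {
  if (dE <= 0) return true;
  return rng.u() < std::exp(-dE / kBT);
}

// evaluate a proposal's energy change; leaves the system in the *applied*
// state when accepted, restored otherwise; updates running energy on accept
static bool decide(Walker& w, const Params& P, Prop& p, double kBT,
                   std::vector<int>& A, double extraLogWeight = 0.0) {
  buildA(w.S, p.mr, A);
  EB before = localE(w.S, P, A);
  applyProp(w.S, p.mr, true);
  EB after = localE(w.S, P, A);
  clearA(w.S, A);
  double dE = after.total() - before.total();
  bool ok;
  if (extraLogWeight == 0.0) {
    ok = metro(w.rng, dE, kBT);
  } else {
    double logp = extraLogWeight - dE / kBT;
    ok = (logp >= 0) || (w.rng.u() < std::exp(logp));
  }
  if (ok) {
    w.e += (after - before);
  } else {
    applyProp(w.S, p.mr, false);
  }
  return ok;
}

// map a flat residue index over alive chains to (chain, residue)
static void pickResidue(const Sys& S, int k, int& c, int& i) {
  for (int cc = 0; cc < (int)S.ch.size(); ++cc) {
    if (!S.ch[cc].alive) continue;
    if (k < S.ch[cc].len()) { c = cc; i = k; return; }
    k -= S.ch[cc].len();
  }
  stop("internal: residue index out of range");
}
static int pickChain(const Sys& S, int k) {
  for (int cc = 0; cc < (int)S.ch.size(); ++cc) {
    if (!S.ch[cc].alive) continue;
    if (k == 0) return cc;
    --k;
  }
  stop("internal: chain index out of range");
}

static void mcIteration(Walker& w, const Params& P, double T, double p_global,
                        std::vector<int>& A) {
  if (w.S.nResAlive == 0) return;
  double kBT = P.kB * T;
  // one local move
  int c, i;
  pickResidue(w.S, w.rng.ri(w.S.nResAlive), c, i);
  int t = w.rng.ri(3);
  Prop p;
  int slot;
  if (t == 0) { p = propStateFlip(w.S, c, i); slot = M_STATE; }
  else if (t == 1) { p = propSideChain(w.S, c, i, w.rng, -1); slot = M_SIDE; }
  else {
    int n = w.S.ch[c].len();
    if (i == 0 || i == n - 1) { p = propEndMove(w.S, c, i, w.rng, -1); slot = M_END; }
    else if (w.rng.ri(2) == 0) { p = propCorner(w.S, c, i, w.rng); slot = M_CORNER; }
    else { p = propCrank(w.S, c, i, w.rng, -1); slot = M_CRANK; }
  }
  w.acct.prop[slot]++;
  if (p.valid && decide(w, P, p, kBT, A)) w.acct.acc[slot]++;
  // one global move with probability p_global
  if (p_global > 0 && w.rng.u() < p_global) {
    int cc = pickChain(w.S, w.rng.ri(w.S.nAlive));
    Prop q;
    int slot2;
    if (w.rng.ri(2) == 0) { q = propTranslate(w.S, cc, w.rng, -1); slot2 = M_TRANS; }
    else { q = propRotate(w.S, cc, w.rng, -1, -1, -1); slot2 = M_ROT; }
    w.acct.prop[slot2]++;
    if (q.valid && decide(w, P, q, kBT, A)) w.acct.acc[slot2]++;
  }
}

// --------------------------------------------------------- recording ------
struct Recorder {
  std::vector<double> iter, ehb, eaa, est, esol, este, etot, echeck;
  std::vector<int> nhb, ncon, next, nnat, npep;
  bool hasRef;
  IntegerMatrix ref;
  Recorder(bool hr, IntegerMatrix r) : hasRef(hr), ref(r) {}
  void take(const Walker& w, const Params& P, long it) {
    iter.push_back((double)it);
    ehb.push_back(w.e.hb); eaa.push_back(w.e.aa); est.push_back(w.e.state);
    esol.push_back(w.e.sol); este.push_back(w.e.steric);
    etot.push_back(w.e.total());
    echeck.push_back(totalE(w.S, P).total());
    nhb.push_back(w.e.nhb);
    Contacts ct = countContacts(w.S);
    ncon.push_back(ct.total); next.push_back(ct.external);
    nnat.push_back(hasRef ? countNative(w.S, ref) : NA_INTEGER);
    npep.push_back(w.S.nAlive);
  }
  DataFrame df() const {
    return DataFrame::create(
        _["iteration"] = iter, _["e_hb"] = ehb, _["e_aa"] = eaa,
        _["e_state"] = est, _["e_solvent"] = esol, _["e_steric"] = este,
        _["e_total"] = etot, _["e_check"] = echeck, _["n_hb"] = nhb,
        _["n_contacts"] = ncon, _["n_external"] = next,
        _["n_native"] = nnat, _["n_peptides"] = npep);
  }
};

static List acctToR(const Accounts& a) {
  CharacterVector nm = CharacterVector::create(
      "state_flip", "side_chain", "end_move", "point_rotation", "crankshaft",
      "translate", "rotate", "insert", "delete");
  NumericVector pr(9), ac(9);
  for (int k = 0; k < 9; ++k) { pr[k] = (double)a.prop[k]; ac[k] = (double)a.acc[k]; }
  pr.names() = nm; ac.names() = nm;
  return List::create(_["proposed"] = pr, _["accepted"] = ac);
}

// [[Rcpp::export]]
List cpp_run_canonical(List sys, NumericMatrix M, List par, List schedule,
                       double temperature, Nullable<IntegerMatrix> native_ref) {
  Sys S0 = sysFromR(sys);
  Params P = paramsFromR(M, par);
  long nIter = (long)as<double>(schedule["n_iterations"]);
  double p_global = as<double>(schedule["p_global"]);
  long sample = (long)as<double>(schedule["sample_interval"]);
  uint64_t seed = (uint64_t)as<double>(schedule["seed"]);
  Walker w(std::move(S0), P, splitmix(seed));
  bool hasRef = native_ref.isNotNull();
  IntegerMatrix ref = hasRef ? IntegerMatrix(native_ref) : IntegerMatrix(0, 4);
  Recorder rec(hasRef, ref);
  std::vector<int> A;
  rec.take(w, P, 0);
  for (long it = 1; it <= nIter; ++it) {
    mcIteration(w, P, temperature, p_global, A);
    if (it % sample == 0) rec.take(w, P, it);
  }
  return List::create(
      _["trajectory"] = rec.df(), _["final_system"] = sysToR(w.S),
      _["final_energy"] = ebToR(w.e),
      _["final_energy_recomputed"] = ebToR(totalE(w.S, P)),
      _["acceptance"] = acctToR(w.acct));
}

// [[Rcpp::export]]
List cpp_run_pt(List sys, NumericMatrix M, List par, NumericVector temperatures,
                List schedule, Nullable<IntegerMatrix> native_ref) {
  Sys S0 = sysFromR(sys);
  Params P = paramsFromR(M, par);
  long nIter = (long)as<double>(schedule["n_iterations"]);
  double p_global = as<double>(schedule["p_global"]);
  long sample = (long)as<double>(schedule["sample_interval"]);
  long swapInt = (long)as<double>(schedule["swap_interval"]);
  uint64_t seed = (uint64_t)as<double>(schedule["seed"]);
  int nrep = temperatures.size();
  bool hasRef = native_ref.isNotNull();
  IntegerMatrix ref = hasRef ? IntegerMatrix(native_ref) : IntegerMatrix(0, 4);

  std::vector<Walker> reps;
  std::vector<Recorder> recs;
  for (int r = 0; r < nrep; ++r) {
    reps.emplace_back(S0, P, splitmix(seed + 1315423911ULL * (r + 1)));
    recs.emplace_back(hasRef, ref);
    recs[r].take(reps[r], P, 0);
  }
  RNG swapRng(splitmix(seed ^ 0xABCDEF1234567890ULL));
  std::vector<int> A;
  long nSwapAttempt = 0, nSwapAcc = 0;
  long rounds = nIter / swapInt;
  for (long rd = 0; rd < rounds; ++rd) {
    for (int r = 0; r < nrep; ++r) {
      for (long k = 1; k <= swapInt; ++k) {
        long it = rd * swapInt + k;
        mcIteration(reps[r], P, temperatures[r], p_global, A);
        if (it % sample == 0) recs[r].take(reps[r], P, it);
      }
    }
    int par0 = (int)(rd % 2);
    for (int r = par0; r + 1 < nrep; r += 2) {
      double T1 = temperatures[r], T2 = temperatures[r + 1];
      double e1 = reps[r].e.total(), e2 = reps[r + 1].e.total();
      double lp = (1.0 / T1 - 1.0 / T2) * (e1 - e2) / P.kB;
      ++nSwapAttempt;
      if (lp >= 0 || swapRng.u() < std::exp(lp)) {
        ++nSwapAcc;
        std::swap(reps[r].S, reps[r + 1].S);
        std::swap(reps[r].e, reps[r + 1].e);
      }
    }
  }
  List traj, finals;
  for (int r = 0; r < nrep; ++r) {
    traj.push_back(recs[r].df());
    finals.push_back(sysToR(reps[r].S));
  }
  return List::create(
      _["trajectories"] = traj, _["final_systems"] = finals,
      _["temperatures"] = temperatures,
      _["swap_attempted"] = (double)nSwapAttempt,
      _["swap_accepted"] = (double)nSwapAcc);
}

// ------------------------------------------------------------- GCMC -------
// Insertions propose straight rods in the coil state with uniformly drawn
// admissible side chains; only conformations that the insertion move could
// have generated (straight, all coil) may be deleted, so insertion/deletion
// satisfy detailed balance with respect to z^N exp(-E/kT).
static double rodOmega(const Sys& S, int len) {
  double dirs = 25.0;  // 5 * 5 terminal options
  for (int i = 0; i < len - 2; ++i) dirs *= 4.0;
  return (double)S.vol() * 6.0 * dirs;
}

static bool isRodCoil(const Sys& S, int c) {
  const ChainD& C = S.ch[c];
  int b0[3];
  S.bond(c, 0, 1, b0);
  for (int i = 0; i < C.len(); ++i) {
    if (C.st[i]) return false;
    if (i + 1 < C.len()) {
      int b[3];
      S.bond(c, i, i + 1, b);
      if (b[0] != b0[0] || b[1] != b0[1] || b[2] != b0[2]) return false;
    }
  }
  return true;
}

// [[Rcpp::export]]
List cpp_run_gcmc(List sys, NumericMatrix M, List par, List schedule,
                  double temperature, double activity, double p_exchange,
                  IntegerVector peptide_aa) {
  Sys S0 = sysFromR(sys);
  Params P = paramsFromR(M, par);
  long nIter = (long)as<double>(schedule["n_iterations"]);
  double p_global = as<double>(schedule["p_global"]);
  long sample = (long)as<double>(schedule["sample_interval"]);
  uint64_t seed = (uint64_t)as<double>(schedule["seed"]);
  int plen = peptide_aa.size();
  if (plen < 2) stop("peptide length must be at least 2");
  Walker w(std::move(S0), P, splitmix(seed ^ 0x6C62272E07BB0142ULL));
  Recorder rec(false, IntegerMatrix(0, 4));
  std::vector<int> A;
  double kBT = P.kB * temperature;
  double Om = rodOmega(w.S, plen);
  rec.take(w, P, 0);
  for (long it = 1; it <= nIter; ++it) {
    mcIteration(w, P, temperature, p_global, A);
    if (w.rng.u() < p_exchange) {
      if (w.rng.ri(2) == 0) {
        // ---- insertion
        w.acct.prop[M_INS]++;
        int x0 = w.rng.ri(w.S.L[0]), y0 = w.rng.ri(w.S.L[1]), z0 = w.rng.ri(w.S.L[2]);
        int d = w.rng.ri(6);
        std::vector<int> xs(plen), ys(plen), zs(plen), ds(plen);
        bool ok = true;
        for (int i = 0; i < plen; ++i) {
          int xi = x0 + i * DX[d], yi = y0 + i * DY[d], zi = z0 + i * DZ[d];
          xi = w.S.wrapc(xi, 0); yi = w.S.wrapc(yi, 1); zi = w.S.wrapc(zi, 2);
          if (xi < 0 || xi >= w.S.L[0] || yi < 0 || yi >= w.S.L[1] ||
              zi < 0 || zi >= w.S.L[2]) { ok = false; break; }
          if (w.S.occ[w.S.lin(xi, yi, zi)] != 0) { ok = false; break; }
          xs[i] = xi; ys[i] = yi; zs[i] = zi;
        }
        // duplicate sites within the rod are impossible for L >= 3
        if (ok) {
          for (int i = 0; i < plen; ++i) {
            int bd[2];
            int nb = 0;
            if (i > 0) bd[nb++] = opp(d);
            if (i < plen - 1) bd[nb++] = d;
            ds[i] = drawDir(w.rng, bd, nb);
          }
          // find a slot
          int slot = -1;
          for (int c = 0; c < (int)w.S.ch.size(); ++c)
            if (!w.S.ch[c].alive) { slot = c; break; }
          if (slot < 0) {
            w.S.ch.push_back(ChainD());
            slot = (int)w.S.ch.size() - 1;
            w.S.mark.resize(w.S.ch.size() * MAXRES, 0);
          }
          ChainD& C = w.S.ch[slot];
          C.alive = true;
          C.aa.assign(peptide_aa.begin(), peptide_aa.end());
          C.x = xs; C.y = ys; C.z = zs; C.dr = ds;
          C.st.assign(plen, 0);
          // local energy around the new residues, before vs after; the
          // "before" evaluation must see only the pre-existing residues
          std::vector<MoveRes> mr(plen);
          for (int i = 0; i < plen; ++i) {
            mr[i].c = slot; mr[i].i = i;
            mr[i].ox = xs[i]; mr[i].oy = ys[i]; mr[i].oz = zs[i];
            mr[i].nx = xs[i]; mr[i].ny = ys[i]; mr[i].nz = zs[i];
          }
          std::vector<int> ids;
          buildA(w.S, mr, ids);  // occ not yet updated: neighbours only
          std::vector<int> idsOld;
          for (int id : ids) {
            if (id / MAXRES == slot) w.S.mark[id] = 0;
            else idsOld.push_back(id);
          }
          EB before = localE(w.S, P, idsOld);
          for (int i = 0; i < plen; ++i) {
            w.S.occSet(slot, i);
            w.S.mark[w.S.id(slot, i)] = 1;
          }
          std::vector<int> ids2 = idsOld;
          for (int i = 0; i < plen; ++i) ids2.push_back(w.S.id(slot, i));
          EB after = localE(w.S, P, ids2);
          for (int id : ids2) w.S.mark[id] = 0;
          double dE = after.total() - before.total();
          int nPep = w.S.nAlive;  // before insertion
          double logp = std::log(activity * Om / (nPep + 1)) - dE / kBT;
          if (logp >= 0 || w.rng.u() < std::exp(logp)) {
            w.acct.acc[M_INS]++;
            w.S.nAlive++; w.S.nResAlive += plen;
            w.e += (after - before);
          } else {
            for (int i = 0; i < plen; ++i) w.S.occClear(slot, i);
            C.alive = false;
          }
        }
      } else if (w.S.nAlive > 0) {
        // ---- deletion
        w.acct.prop[M_DEL]++;
        int c = pickChain(w.S, w.rng.ri(w.S.nAlive));
        if (w.S.ch[c].len() == plen && isRodCoil(w.S, c)) {
          int n = w.S.ch[c].len();
          std::vector<MoveRes> mr(n);
          for (int i = 0; i < n; ++i) {
            mr[i].c = c; mr[i].i = i;
            fillOld(w.S, mr[i]);
            mr[i].nx = mr[i].ox; mr[i].ny = mr[i].oy; mr[i].nz = mr[i].oz;
          }
          std::vector<int> ids;
          buildA(w.S, mr, ids);
          EB before = localE(w.S, P, ids);
          clearA(w.S, ids);
          for (int i = 0; i < n; ++i) w.S.occClear(c, i);
          w.S.ch[c].alive = false;
          std::vector<int> ids2;
          for (int id : ids)
            if (id / MAXRES != c) ids2.push_back(id);
          for (int id : ids2) w.S.mark[id] = 1;
          EB after = localE(w.S, P, ids2);
          for (int id : ids2) w.S.mark[id] = 0;
          double dE = after.total() - before.total();
          int nPep = w.S.nAlive;  // count before deletion
          double logp = std::log((double)nPep / (activity * Om)) - dE / kBT;
          if (logp >= 0 || w.rng.u() < std::exp(logp)) {
            w.acct.acc[M_DEL]++;
            w.S.nAlive--; w.S.nResAlive -= n;
            w.e += (after - before);
          } else {
            w.S.ch[c].alive = true;
            for (int i = 0; i < n; ++i) w.S.occSet(c, i);
          }
        }
      }
    }
    if (it % sample == 0) rec.take(w, P, it);
  }
  return List::create(
      _["trajectory"] = rec.df(), _["final_system"] = sysToR(w.S),
      _["final_energy"] = ebToR(w.e),
      _["final_energy_recomputed"] = ebToR(totalE(w.S, P)),
      _["acceptance"] = acctToR(w.acct));
}

// ---------------------------------------------------------- design --------
// fixed-backbone sequence design: Monte Carlo over point mutations, type
// swaps and side-chain re-orientations, with a Metropolis stage on the
// energy and an independent composition-bias stage exp(-k_bias * dD) for
// moves that change the composition distance D = sum_a (N_a/L - f_a)^2.
// [[Rcpp::export]]
List cpp_design(List sys, NumericMatrix M, List par, NumericVector f_ref,
                double k_bias, double t_start, double t_end, double n_steps,
                double trace_interval, double seed) {
  Sys S = sysFromR(sys);
  Params P = paramsFromR(M, par);
  if (S.ch.size() != 1) stop("design expects a single chain");
  ChainD& C = S.ch[0];
  int n = C.len();
  RNG rng(splitmix((uint64_t)seed ^ 0x5851F42D4C957F2DULL));
  long steps = (long)n_steps;
  std::vector<int> cnt(20, 0);
  for (int i = 0; i < n; ++i) cnt[C.aa[i]]++;
  auto Dcur = [&]() {
    double D = 0;
    for (int a = 0; a < 20; ++a) {
      double d = (double)cnt[a] / n - f_ref[a];
      D += d * d;
    }
    return D;
  };
  double D = Dcur();
  double E = totalE(S, P).total();
  double bestE = E;
  std::vector<int> bestAA = C.aa, bestDR = C.dr;
  std::vector<double> trIt, trE, trD;
  std::vector<int> A;
  for (long s = 0; s < steps; ++s) {
    double T = (t_start == t_end)
                   ? t_start
                   : t_start * std::pow(t_end / t_start, (double)s / (double)(steps - 1));
    double kBT = P.kB * T;
    int mt = rng.ri(3);
    if (mt == 0) {  // point mutation
      int i = rng.ri(n);
      int aOld = C.aa[i], aNew = rng.ri(20);
      if (aNew != aOld) {
        double dD = 0;
        {
          double t1 = (double)(cnt[aOld] - 1) / n - f_ref[aOld];
          double t0 = (double)cnt[aOld] / n - f_ref[aOld];
          double u1 = (double)(cnt[aNew] + 1) / n - f_ref[aNew];
          double u0 = (double)cnt[aNew] / n - f_ref[aNew];
          dD = t1 * t1 - t0 * t0 + u1 * u1 - u0 * u0;
        }
        C.aa[i] = aNew;
        double Enew = totalE(S, P).total();
        double dE = Enew - E;
        bool ok = metro(rng, dE, kBT);
        if (ok && dD > 0) ok = rng.u() < std::exp(-k_bias * dD);
        if (ok) {
          E = Enew; D += dD;
          cnt[aOld]--; cnt[aNew]++;
        } else {
          C.aa[i] = aOld;
        }
      }
    } else if (mt == 1) {  // swap the types of two positions (D unchanged)
      int i = rng.ri(n), j = rng.ri(n);
      if (i != j && C.aa[i] != C.aa[j]) {
        std::swap(C.aa[i], C.aa[j]);
        double Enew = totalE(S, P).total();
        if (metro(rng, Enew - E, kBT)) E = Enew;
        else std::swap(C.aa[i], C.aa[j]);
      }
    } else {  // side-chain re-orientation
      int i = rng.ri(n);
      int opts[6], nn = 0, all[6];
      int na = S.admissible(0, i, all);
      for (int k = 0; k < na; ++k)
        if (all[k] != C.dr[i]) opts[nn++] = all[k];
      int dNew = opts[rng.ri(nn)];
      if (C.st[i]) {  // keep the strand alternation rule intact
        bool ok = true;
        for (int j : {i - 1, i + 1}) {
          if (j < 0 || j >= n) continue;
          if (C.st[j] && C.dr[j] != opp(dNew)) ok = false;
        }
        if (!ok) { goto trace; }
      }
      {
        int dOld = C.dr[i];
        C.dr[i] = dNew;
        double Enew = totalE(S, P).total();
        if (metro(rng, Enew - E, kBT)) E = Enew;
        else C.dr[i] = dOld;
      }
    }
  trace:
    // ties resolve to the most recent state so that equal-energy moves
    // (e.g. composition-improving swaps on a flat landscape) carry through
    if (E <= bestE) { bestE = E; bestAA = C.aa; bestDR = C.dr; }
    if ((s + 1) % (long)trace_interval == 0) {
      trIt.push_back((double)(s + 1));
      trE.push_back(E);
      trD.push_back(D);
    }
  }
  return List::create(
      _["best_aa"] = IntegerVector(bestAA.begin(), bestAA.end()),
      _["best_dir"] = IntegerVector(bestDR.begin(), bestDR.end()),
      _["best_energy"] = bestE,
      _["final_aa"] = IntegerVector(C.aa.begin(), C.aa.end()),
      _["final_D"] = D,
      _["trace"] = DataFrame::create(_["step"] = trIt, _["energy"] = trE,
                                     _["composition_distance"] = trD));
}

// ------------------------------------------------------ single moves ------
// build one named proposal deterministically (seed-driven randomness, with
// optional forced arguments) -- the unit-test surface of the move set
// [[Rcpp::export]]
List cpp_single_move(List sys, NumericMatrix M, List par, std::string kind,
                     int chain, int residue, double seed, List args) {
  Sys S = sysFromR(sys);
  Params P = paramsFromR(M, par);
  RNG rng(splitmix((uint64_t)seed));
  auto geti = [&](const char* nm, int def) {
    return args.containsElementNamed(nm) ? as<int>(args[nm]) : def;
  };
  Prop p;
  if (kind == "state_flip") p = propStateFlip(S, chain, residue);
  else if (kind == "side_chain_rotate")
    p = propSideChain(S, chain, residue, rng, geti("direction", -1));
  else if (kind == "end_move")
    p = propEndMove(S, chain, residue, rng, geti("direction", -1));
  else if (kind == "corner_flip" || kind == "point_rotation")
    p = propCorner(S, chain, residue, rng);
  else if (kind == "crankshaft")
    p = propCrank(S, chain, residue, rng, geti("angle", -1));
  else if (kind == "translate")
    p = propTranslate(S, chain, rng, geti("direction", -1));
  else if (kind == "rotate")
    p = propRotate(S, chain, rng, geti("pivot", -1), geti("axis", -1),
                   geti("angle", -1));
  else stop("unknown move kind: %s", kind.c_str());

  if (!p.valid)
    return List::create(_["kind"] = p.kind, _["valid"] = false,
                        _["reason"] = p.reason);
  std::vector<int> A;
  buildA(S, p.mr, A);
  EB before = localE(S, P, A);
  applyProp(S, p.mr, true);
  EB after = localE(S, P, A);
  clearA(S, A);
  IntegerMatrix payload(p.mr.size(), 7);
  for (int k = 0; k < (int)p.mr.size(); ++k) {
    const MoveRes& m = p.mr[k];
    payload(k, 0) = m.c; payload(k, 1) = m.i;
    payload(k, 2) = m.nx; payload(k, 3) = m.ny; payload(k, 4) = m.nz;
    payload(k, 5) = m.ndr; payload(k, 6) = m.nst;
  }
  return List::create(
      _["kind"] = p.kind, _["valid"] = true, _["reason"] = "",
      _["delta_e"] = after.total() - before.total(),
      _["delta_components"] = ebToR(after - before),
      _["payload"] = payload, _["new_system"] = sysToR(S));
}
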