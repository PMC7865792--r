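// Langevin-dynamics engine for the chromatin block-copolymer model.
//
// Reduced units throughout: length sigma0, energy eps0 = kB*T0, mass 1,
// time tau0 = sigma0*sqrt(m/eps0).  Potential terms:
//   backbone   U = -0.5*K*R0^2*ln(1-(r/R0)^2)        (FENE, diverges at R0)
//              plus, by default, a unit-strength WCA core between the
//              bonded pair (the class pair potential then acts only on
//              non-bonded pairs); optionally the class pair potential is
//              applied to every pair instead
//   pairs      U = 4*eps*[r^-12 - r^-6] shifted to 0 at rc, eps chosen by
//              the two beads' F/P classes
//   TAD bonds  U = eps_b * r^2                        (zero rest length)
//   wall       truncated-shifted LJ on the distance d = R - |x| to the
//              spherical container; LAD beads use (eps_lc, rc = 1.3),
//              all others (eps_rep, rc = 2^(1/6)) i.e. purely repulsive.
// Integrator: BAOAB splitting; with friction = 0 the O-step is the identity
// and the scheme reduces to velocity Verlet (NVE test mode).
//
// Pair search: counting-sort cell binning (forward half-stencil, each pair
// visited once) feeding a flat Verlet pair list with skin; the list is
// rebuilt when the two largest displacements since the last build could
// together close the skin gap (an exact no-missed-pair criterion).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256++, ziggurat normal (Marsaglia & Tsang,
// 128 layers).  Self-contained so trajectories are bit-reproducible for a
// given integer seed independent of R's RNG state.
// ---------------------------------------------------------------------------

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; i++) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline uint32_t next32() { return (uint32_t)(next() >> 32); }
  // uniform on (0,1]
  inline double unif_pos() { return ((next() >> 11) + 1) * 1.1102230246251565e-16; }
  // uniform on [0,1)
  inline double unif() { return (next() >> 11) * 1.1102230246251565e-16; }
};

struct Ziggurat {
  double wn[128], fn[128];
  uint32_t kn[128];
  Ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  inline double draw(Xoshiro256& rng) const {
    for (;;) {
      int32_t hz = (int32_t)rng.next32();
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t ahz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < kn[iz]) return hz * wn[iz];
      const double r = 3.442619855899;
      if (iz == 0) {  // tail
        double x, y;
        do {
          x = -std::log(rng.unif_pos()) / r;
          y = -std::log(rng.unif_pos());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      double x = hz * wn[iz];
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
    }
  }
};

static const Ziggurat ZIG;

// [[Rcpp::export]]
NumericVector cpp_rnorm_stream(int n, int seed) {
  Xoshiro256 rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = ZIG.draw(rng);
  return out;
}

// ---------------------------------------------------------------------------
// System definition shared by energy/force/MD entry points
// ---------------------------------------------------------------------------

struct System {
  int n;
  std::vector<double> r;       // interleaved x,y,z per bead (gather-friendly)
  std::vector<int> type;       // 0 = F, 1 = P
  std::vector<int> chain;
  std::vector<char> lad;
  // bonds
  std::vector<int> b1, b2;           // FENE backbone (0-based)
  std::vector<int> t1, t2;           // TAD boundary bonds
  std::vector<double> teps;          // per-boundary-bond eps
  // pair interaction table (by type pair)
  double eps4[2][2];                 // 4*eps
  double shift[2][2];                // energy shift so U(rc) = 0
  double rc2;
  double fene_k, fene_r0sq, half_k_r0sq;
  double wca_rc2;                    // (2^(1/6))^2: bonded-pair WCA core
  // wall
  double radius;
  double wall_eps4[2], wall_shift[2], wall_rc[2]; // [0]=non-LAD, [1]=LAD
  bool exclude_bonded;
};

static inline double lj_shift(double eps4, double rc) {
  double ir6 = 1.0 / (rc * rc * rc * rc * rc * rc);
  return eps4 * (ir6 * ir6 - ir6);   // 4 eps (rc^-12 - rc^-6); subtracted
}

static System make_system(NumericMatrix coords, IntegerVector type,
                          IntegerVector chain, LogicalVector lad,
                          IntegerMatrix bonds, IntegerMatrix bbonds,
                          NumericVector bbond_eps, NumericMatrix eps_pair,
                          double rc_pair, double fene_k, double fene_r0,
                          double radius, double eps_lc, double rc_wall_lad,
                          double eps_wall_rep, double rc_wall_rep,
                          bool exclude_bonded) {
  System S;
  S.n = coords.nrow();
  S.r.resize(3 * S.n);
  S.type.resize(S.n); S.chain.resize(S.n); S.lad.resize(S.n);
  for (int i = 0; i < S.n; i++) {
    S.r[3*i] = coords(i, 0); S.r[3*i+1] = coords(i, 1); S.r[3*i+2] = coords(i, 2);
    S.type[i] = type[i]; S.chain[i] = chain[i]; S.lad[i] = lad[i] ? 1 : 0;
  }
  for (int b = 0; b < bonds.nrow(); b++) {
    S.b1.push_back(bonds(b, 0) - 1);
    S.b2.push_back(bonds(b, 1) - 1);
  }
  for (int b = 0; b < bbonds.nrow(); b++) {
    S.t1.push_back(bbonds(b, 0) - 1);
    S.t2.push_back(bbonds(b, 1) - 1);
    S.teps.push_back(bbond_eps[b]);
  }
  for (int a = 0; a < 2; a++)
    for (int b = 0; b < 2; b++) {
      S.eps4[a][b] = 4.0 * eps_pair(a, b);
      S.shift[a][b] = lj_shift(S.eps4[a][b], rc_pair);
    }
  S.rc2 = rc_pair * rc_pair;
  S.fene_k = fene_k;
  S.fene_r0sq = fene_r0 * fene_r0;
  S.half_k_r0sq = 0.5 * fene_k * S.fene_r0sq;
  S.wca_rc2 = std::cbrt(2.0);
  S.radius = radius;
  S.wall_eps4[0] = 4.0 * eps_wall_rep;  S.wall_rc[0] = rc_wall_rep;
  S.wall_eps4[1] = 4.0 * eps_lc;        S.wall_rc[1] = rc_wall_lad;
  for (int k = 0; k < 2; k++)
    S.wall_shift[k] = lj_shift(S.wall_eps4[k], S.wall_rc[k]);
  S.exclude_bonded = exclude_bonded;
  return S;
}

// ---------------------------------------------------------------------------
// Neighbour list: counting-sort cell binning (cell size >= rc + skin) feeds
// a flat pair list via a forward half-stencil scan over sorted coordinates.
// ---------------------------------------------------------------------------

struct NeighborList {
  double cut, cut2, skin;
  int ncx, ncy, ncz, ncells;
  double orig, cell;
  std::vector<int> cellid, cstart, fillptr, order;
  std::vector<double> rs;            // interleaved coordinates, sorted order
  std::vector<int> pairs;            // flattened (i, j), original indices
  std::vector<double> rb;            // positions at last build (interleaved)

  void init(const System& S, double skin_) {
    skin = skin_;
    cut = std::sqrt(S.rc2) + skin;
    cut2 = cut * cut;
    double ext = S.radius > 0 ? S.radius + 1.0 : 1.0;
    orig = -ext;
    int nc = (int)std::floor(2.0 * ext / cut);
    if (nc < 1) nc = 1;
    // dilute systems in huge containers need no fine grid: cap the cell
    // count near the bead count (cells only ever grow past `cut`)
    int cap = std::max(8, (int)std::ceil(4.0 * std::cbrt((double)S.n)));
    if (nc > cap) nc = cap;
    ncx = ncy = ncz = nc;
    ncells = ncx * ncy * ncz;
    cell = 2.0 * ext / nc;           // >= cut
    cellid.resize(S.n);
    cstart.resize(ncells + 1); fillptr.resize(ncells);
    order.resize(S.n);
    rs.resize(3 * S.n);
    pairs.reserve(32 * S.n);
    rb.resize(3 * S.n);
  }

  inline int cidx(int cx, int cy, int cz) const {
    return (cz * ncy + cy) * ncx + cx;
  }

  void bin(const System& S) {
    const int n = S.n;
    const double* __restrict r = S.r.data();
    std::fill(cstart.begin(), cstart.end(), 0);
    for (int i = 0; i < n; i++) {
      int a = (int)((r[3*i]   - orig) / cell); if (a < 0) a = 0; if (a >= ncx) a = ncx - 1;
      int b = (int)((r[3*i+1] - orig) / cell); if (b < 0) b = 0; if (b >= ncy) b = ncy - 1;
      int c = (int)((r[3*i+2] - orig) / cell); if (c < 0) c = 0; if (c >= ncz) c = ncz - 1;
      cellid[i] = cidx(a, b, c);
      cstart[cellid[i] + 1]++;
    }
    for (int c = 0; c < ncells; c++) cstart[c + 1] += cstart[c];
    std::copy(cstart.begin(), cstart.end() - 1, fillptr.begin());
    for (int i = 0; i < n; i++) {
      int k = fillptr[cellid[i]]++;
      order[k] = i;
      rs[3*k] = r[3*i]; rs[3*k+1] = r[3*i+1]; rs[3*k+2] = r[3*i+2];
    }
  }

  // scan one sorted slice against bead i; collect pairs within the skin
  // cutoff and (fused) evaluate pair forces for those inside rc, so a
  // rebuild step does not walk the candidates twice
  inline void scan_slices(int i, double xi, double yi, double zi,
                          int lo2, int hi2, const System& S,
                          double* __restrict f, bool want_pe, double& pe) {
    const double* __restrict R = rs.data();
    const int* __restrict ord = order.data();
    const double rc2 = S.rc2;
    const double e4t[4] = {S.eps4[0][0], S.eps4[0][1],
                           S.eps4[1][0], S.eps4[1][1]};
    const double sht[4] = {S.shift[0][0], S.shift[0][1],
                           S.shift[1][0], S.shift[1][1]};
    for (int k2 = lo2; k2 < hi2; k2++) {
      double ddx = xi - R[3*k2], ddy = yi - R[3*k2+1], ddz = zi - R[3*k2+2];
      double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (r2 < cut2) {
        int j = ord[k2];
        if (S.exclude_bonded && S.chain[i] == S.chain[j] &&
            (j - i == 1 || i - j == 1)) continue;
        pairs.push_back(i);
        pairs.push_back(j);
        if (r2 < rc2) {
          int tt = 2 * S.type[i] + S.type[j];
          double e4 = e4t[tt];
          if (e4 != 0.0) {
            double ir2 = 1.0 / r2;
            double ir6 = ir2 * ir2 * ir2;
            double ir12 = ir6 * ir6;
            double fr = e4 * (12.0 * ir12 - 6.0 * ir6) * ir2;
            f[3*i] += fr * ddx; f[3*i+1] += fr * ddy; f[3*i+2] += fr * ddz;
            f[3*j] -= fr * ddx; f[3*j+1] -= fr * ddy; f[3*j+2] -= fr * ddz;
            if (want_pe) pe += e4 * (ir12 - ir6) - sht[tt];
          }
        }
      }
    }
  }

  // build the pair list and simultaneously accumulate the pair forces
  // into f (which is zeroed here); returns the pair potential energy
  double build_forces(const System& S, std::vector<double>& fv,
                      bool want_pe) {
    std::fill(fv.begin(), fv.end(), 0.0);
    double pe = 0.0;
    double* __restrict f = fv.data();
    bin(S);
    pairs.clear();
    const int* __restrict cs = cstart.data();
    const int* __restrict ord = order.data();
    const double* __restrict R = rs.data();
    // forward half-stencil of radius 1 (cells are >= cut): same cell
    // (upper triangle), +x neighbour, the +y row, the three +z rows;
    // every row spans x-1..x+1 contiguously in the sorted layout
    for (int c = 0; c < ncz; c++)
      for (int b = 0; b < ncy; b++)
        for (int a = 0; a < ncx; a++) {
          int cc = cidx(a, b, c);
          int lo = cs[cc], hi = cs[cc + 1];
          if (lo == hi) continue;
          int a0 = a > 0 ? a - 1 : 0, a1 = a < ncx - 1 ? a + 1 : a;
          for (int k1 = lo; k1 < hi; k1++) {
            double xi = R[3*k1], yi = R[3*k1+1], zi = R[3*k1+2];
            int i = ord[k1];
            // same cell, upper triangle
            scan_slices(i, xi, yi, zi, k1 + 1, hi, S, f, want_pe, pe);
            // +x neighbour
            if (a < ncx - 1) scan_slices(i, xi, yi, zi,
                                         cs[cc + 1], cs[cc + 2], S,
                                         f, want_pe, pe);
            // +y row, x-1..x+1
            if (b < ncy - 1) scan_slices(i, xi, yi, zi,
                                         cs[cidx(a0, b + 1, c)],
                                         cs[cidx(a1, b + 1, c) + 1], S,
                                         f, want_pe, pe);
            // +z plane, rows y-1..y+1, each x-1..x+1
            if (c < ncz - 1) {
              int bb0 = b > 0 ? b - 1 : 0, bb1 = b < ncy - 1 ? b + 1 : b;
              for (int b2 = bb0; b2 <= bb1; b2++)
                scan_slices(i, xi, yi, zi,
                            cs[cidx(a0, b2, c + 1)],
                            cs[cidx(a1, b2, c + 1) + 1], S,
                            f, want_pe, pe);
            }
          }
        }
    std::copy(S.r.begin(), S.r.end(), rb.begin());
    return pe;
  }

  // plain rebuild without force evaluation (energy/minimizer paths)
  void build(const System& S) {
    scratch_f.assign(3 * (size_t)rsn(), 0.0);
    build_forces_discard(S);
  }
  std::vector<double> scratch_f;
  int rsn() const { return (int)(rs.size() / 3); }
  void build_forces_discard(const System& S) {
    std::vector<double> tmp(3 * (size_t)S.n);
    build_forces(S, tmp, false);
  }

  // rebuild when the two largest displacements since the last build could
  // together close the skin gap (d1 + d2 >= skin): exact safety bound
  bool stale(const System& S) const {
    const double* __restrict r = S.r.data();
    const double* __restrict r0 = rb.data();
    double m1 = 0.0, m2 = 0.0;
    for (int i = 0; i < S.n; i++) {
      double dx = r[3*i] - r0[3*i], dy = r[3*i+1] - r0[3*i+1],
             dz = r[3*i+2] - r0[3*i+2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > m1) { m2 = m1; m1 = d2; }
      else if (d2 > m2) { m2 = d2; }
    }
    return std::sqrt(m1) + std::sqrt(m2) >= skin;
  }
};

// ---------------------------------------------------------------------------
// Forces and potential energy. status: 0 ok, 1 FENE overstretch, 2 escaped,
// 3 non-finite.
// ---------------------------------------------------------------------------

// pairs_done: the pair forces (and their PE) were already accumulated
// into fv by NeighborList::build_forces on this step
static int compute_forces(const System& S, const NeighborList& NL,
                          std::vector<double>& fv, bool want_pe,
                          double* pe_out, bool pairs_done = false,
                          double pe_pairs = 0.0) {
  const int n = S.n;
  if (!pairs_done) std::fill(fv.begin(), fv.end(), 0.0);
  double pe = pairs_done ? pe_pairs : 0.0;
  const double* __restrict r = S.r.data();
  double* __restrict f = fv.data();
  const int* __restrict typ = S.type.data();
  const double rc2 = S.rc2;
  const double e4t[4] = {S.eps4[0][0], S.eps4[0][1], S.eps4[1][0], S.eps4[1][1]};
  const double sht[4] = {S.shift[0][0], S.shift[0][1], S.shift[1][0], S.shift[1][1]};
  const bool excl = S.exclude_bonded;

  // non-bonded pairs from the flat Verlet list (when bonded pairs are
  // excluded from the class table they are already absent from the list)
  const int* __restrict pr = NL.pairs.data();
  const size_t np = pairs_done ? 0 : NL.pairs.size() / 2;
  for (size_t k = 0; k < np; k++) {
    int i = pr[2 * k], j = pr[2 * k + 1];
    double dx = r[3*i] - r[3*j], dy = r[3*i+1] - r[3*j+1],
           dz = r[3*i+2] - r[3*j+2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) continue;
    int tt = 2 * typ[i] + typ[j];
    double e4 = e4t[tt];
    if (e4 == 0.0) continue;
    double ir2 = 1.0 / r2;
    double ir6 = ir2 * ir2 * ir2;
    double ir12 = ir6 * ir6;
    double fr = e4 * (12.0 * ir12 - 6.0 * ir6) * ir2;   // -(dU/dr)/r
    f[3*i] += fr * dx; f[3*i+1] += fr * dy; f[3*i+2] += fr * dz;
    f[3*j] -= fr * dx; f[3*j+1] -= fr * dy; f[3*j+2] -= fr * dz;
    if (want_pe) pe += e4 * (ir12 - ir6) - sht[tt];
  }

  // FENE backbone (+ unit WCA core when bonded pairs are excluded from
  // the class pair table)
  const int* __restrict b1 = S.b1.data();
  const int* __restrict b2 = S.b2.data();
  for (size_t b = 0; b < S.b1.size(); b++) {
    int i = b1[b], j = b2[b];
    double dx = r[3*i] - r[3*j], dy = r[3*i+1] - r[3*j+1],
           dz = r[3*i+2] - r[3*j+2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= S.fene_r0sq) return 1;
    double w = 1.0 - r2 / S.fene_r0sq;
    double fr = -S.fene_k / w;                          // -(dU/dr)/r
    if (excl && r2 < S.wca_rc2) {
      double ir2 = 1.0 / r2;
      double ir6 = ir2 * ir2 * ir2;
      double ir12 = ir6 * ir6;
      fr += 4.0 * (12.0 * ir12 - 6.0 * ir6) * ir2;
      if (want_pe) pe += 4.0 * (ir12 - ir6) + 1.0;
    }
    f[3*i] += fr * dx; f[3*i+1] += fr * dy; f[3*i+2] += fr * dz;
    f[3*j] -= fr * dx; f[3*j+1] -= fr * dy; f[3*j+2] -= fr * dz;
    if (want_pe) pe += -S.half_k_r0sq * std::log(w);
  }

  // harmonic TAD-boundary bonds
  for (size_t b = 0; b < S.t1.size(); b++) {
    int i = S.t1[b], j = S.t2[b];
    double dx = r[3*i] - r[3*j], dy = r[3*i+1] - r[3*j+1],
           dz = r[3*i+2] - r[3*j+2];
    double fr = -2.0 * S.teps[b];
    f[3*i] += fr * dx; f[3*i+1] += fr * dy; f[3*i+2] += fr * dz;
    f[3*j] -= fr * dx; f[3*j+1] -= fr * dy; f[3*j+2] -= fr * dz;
    if (want_pe) pe += S.teps[b] * (dx * dx + dy * dy + dz * dz);
  }

  // spherical wall
  if (S.radius > 0) {
    double rcw = std::max(S.wall_rc[0], S.wall_rc[1]);
    double s2min = (S.radius - rcw) * (S.radius - rcw);
    for (int i = 0; i < n; i++) {
      double xi = r[3*i], yi = r[3*i+1], zi = r[3*i+2];
      double s2 = xi * xi + yi * yi + zi * zi;
      if (s2 < s2min) continue;      // interior: no wall term, no sqrt
      double s = std::sqrt(s2);
      double d = S.radius - s;
      if (d <= 0) return 2;
      int cls = S.lad[i];
      if (d >= S.wall_rc[cls]) continue;
      double e4 = S.wall_eps4[cls];
      if (e4 == 0.0) continue;
      double id2 = 1.0 / (d * d);
      double id6 = id2 * id2 * id2;
      double id12 = id6 * id6;
      // dU/dd ; radial force on the bead is +dU/dd * (unit radial vector)
      double dUdd = -e4 * (12.0 * id12 - 6.0 * id6) / d;
      if (s > 1e-12) {
        double fr = dUdd / s;
        f[3*i] += fr * xi; f[3*i+1] += fr * yi; f[3*i+2] += fr * zi;
      }
      if (want_pe) pe += e4 * (id12 - id6) - S.wall_shift[cls];
    }
  }

  if (want_pe) {
    if (!std::isfinite(pe)) return 3;
    *pe_out = pe;
  }
  return 0;
}

// [[Rcpp::export]]
List cpp_forces_energy(NumericMatrix coords, IntegerVector type,
                       IntegerVector chain, LogicalVector lad,
                       IntegerMatrix bonds, IntegerMatrix bbonds,
                       NumericVector bbond_eps, NumericMatrix eps_pair,
                       double rc_pair, double fene_k, double fene_r0,
                       double radius, double eps_lc, double rc_wall_lad,
                       double eps_wall_rep, double rc_wall_rep,
                       bool exclude_bonded, double skin) {
  System S = make_system(coords, type, chain, lad, bonds, bbonds, bbond_eps,
                         eps_pair, rc_pair, fene_k, fene_r0, radius, eps_lc,
                         rc_wall_lad, eps_wall_rep, rc_wall_rep, exclude_bonded);
  NeighborList NL;
  NL.init(S, skin);
  NL.build(S);
  std::vector<double> fv(3 * S.n);
  double pe = 0.0;
  int status = compute_forces(S, NL, fv, true, &pe);
  if (status == 1) stop("FENE bond at or beyond R0: infinite energy");
  if (status == 2) stop("bead outside the spherical container");
  if (status == 3) stop("non-finite potential energy");
  NumericMatrix f(S.n, 3);
  for (int i = 0; i < S.n; i++) {
    f(i,0)=fv[3*i]; f(i,1)=fv[3*i+1]; f(i,2)=fv[3*i+2];
  }
  return List::create(_["forces"] = f, _["energy"] = pe);
}

// ---------------------------------------------------------------------------
// Displacement-capped steepest-descent relaxation (push-off): removes the
// steep overlaps of a freshly grown self-avoiding walk before dynamics.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_minimize(NumericMatrix coords, IntegerVector type,
                  IntegerVector chain, LogicalVector lad, IntegerMatrix bonds,
                  IntegerMatrix bbonds, NumericVector bbond_eps,
                  NumericMatrix eps_pair, double rc_pair, double fene_k,
                  double fene_r0, double radius, double eps_lc,
                  double rc_wall_lad, double eps_wall_rep, double rc_wall_rep,
                  bool exclude_bonded, double skin, int max_iter,
                  double max_disp, double ftol) {
  System S = make_system(coords, type, chain, lad, bonds, bbonds, bbond_eps,
                         eps_pair, rc_pair, fene_k, fene_r0, radius, eps_lc,
                         rc_wall_lad, eps_wall_rep, rc_wall_rep, exclude_bonded);
  const int n = S.n;
  NeighborList NL;
  NL.init(S, skin);
  NL.build(S);
  std::vector<double> fv(3 * n), rsave(3 * n);
  double pe = 0.0;
  int status = compute_forces(S, NL, fv, true, &pe);
  if (status) stop("invalid configuration passed to the minimizer");
  double alpha = 1e-4;
  int it = 0;
  for (; it < max_iter; it++) {
    double fmax2 = 0.0;
    for (int i = 0; i < n; i++) {
      double f2 = fv[3*i]*fv[3*i] + fv[3*i+1]*fv[3*i+1] + fv[3*i+2]*fv[3*i+2];
      if (f2 > fmax2) fmax2 = f2;
    }
    double fmax = std::sqrt(fmax2);
    if (fmax < ftol) break;
    double step = alpha;
    if (step * fmax > max_disp) step = max_disp / fmax;
    rsave = S.r;
    for (int k = 0; k < 3 * n; k++) S.r[k] += step * fv[k];
    if (NL.stale(S)) NL.build(S);
    double pe_new = 0.0;
    status = compute_forces(S, NL, fv, true, &pe_new);
    if (status || pe_new > pe) {  // revert and shrink
      S.r = rsave;
      if (NL.stale(S)) NL.build(S);
      status = compute_forces(S, NL, fv, true, &pe);
      if (status) stop("minimizer lost a valid configuration");
      alpha *= 0.5;
      if (alpha < 1e-12) break;
    } else {
      pe = pe_new;
      alpha *= 1.2;
    }
  }
  NumericMatrix xc(n, 3);
  for (int i = 0; i < n; i++) {
    xc(i,0)=S.r[3*i]; xc(i,1)=S.r[3*i+1]; xc(i,2)=S.r[3*i+2];
  }
  return List::create(_["coords"] = xc, _["energy"] = pe,
                      _["iterations"] = it);
}

// ---------------------------------------------------------------------------
// MD driver
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix coords, NumericMatrix vel, IntegerVector type,
                IntegerVector chain, LogicalVector lad, IntegerMatrix bonds,
                IntegerMatrix bbonds, NumericVector bbond_eps,
                NumericMatrix eps_pair, double rc_pair, double fene_k,
                double fene_r0, double radius, double eps_lc,
                double rc_wall_lad, double eps_wall_rep, double rc_wall_rep,
                bool exclude_bonded, double dt, double n_steps_d,
                int snapshot_interval, double temp_from, double temp_to,
                double anneal_steps_d, double friction, double mass, int seed,
                double skin, bool save_frames) {
  System S = make_system(coords, type, chain, lad, bonds, bbonds, bbond_eps,
                         eps_pair, rc_pair, fene_k, fene_r0, radius, eps_lc,
                         rc_wall_lad, eps_wall_rep, rc_wall_rep, exclude_bonded);
  const int n = S.n;
  const long nsteps = (long)n_steps_d;
  const long anneal_steps = (long)anneal_steps_d;
  std::vector<double> vv(3 * n), fvv(3 * n);
  for (int i = 0; i < n; i++) {
    vv[3*i] = vel(i, 0); vv[3*i+1] = vel(i, 1); vv[3*i+2] = vel(i, 2);
  }
  NeighborList NL;
  NL.init(S, skin);
  NL.build(S);

  Xoshiro256 rng((uint64_t)(uint32_t)seed);
  const double c1 = std::exp(-friction * dt);
  const double oc = std::sqrt((1.0 - c1 * c1) / mass);  // times sqrt(T)
  const double hdt = 0.5 * dt;
  const double im = 1.0 / mass;
  const bool thermostat = friction > 0.0;

  double pe = 0.0;
  int status = compute_forces(S, NL, fvv, true, &pe);
  if (status) stop("invalid initial configuration (status %d)", status);
  double* __restrict pr = S.r.data();
  double* __restrict pv = vv.data();
  const double* __restrict pf = fvv.data();
  const int n3 = 3 * n;
  List frames;
  std::vector<double> log_step, log_temp, log_tkin, log_pe, log_ke;

  for (long step = 1; step <= nsteps; step++) {
    double T = temp_to;
    if (anneal_steps > 0 && step <= anneal_steps)
      T = temp_from + (temp_to - temp_from) * ((double)step / (double)anneal_steps);

    // B
    for (int k = 0; k < n3; k++) pv[k] += hdt * im * pf[k];
    // A
    for (int k = 0; k < n3; k++) pr[k] += hdt * pv[k];
    // O
    if (thermostat) {
      double amp = oc * std::sqrt(T);
      for (int k = 0; k < n3; k++) pv[k] = c1 * pv[k] + amp * ZIG.draw(rng);
    }
    // A
    for (int k = 0; k < n3; k++) pr[k] += hdt * pv[k];
    // force at new positions; on rebuild steps the pair forces are fused
    // into the build scan and the force pass only adds bonds and wall
    bool snap = (step % snapshot_interval) == 0;
    bool rebuilt = NL.stale(S);
    double pe_pairs = 0.0;
    if (rebuilt) pe_pairs = NL.build_forces(S, fvv, snap);
    status = compute_forces(S, NL, fvv, snap, &pe, rebuilt, pe_pairs);
    if (status == 1)
      stop("FENE bond reached R0 at step %ld (timestep too large?)", step);
    if (status == 2)
      stop("bead left the container at step %ld", step);
    if (status == 3)
      stop("non-finite energy at step %ld", step);
    // B
    for (int k = 0; k < n3; k++) pv[k] += hdt * im * pf[k];

    if (snap) {
      double ke = 0.0;
      for (int k = 0; k < n3; k++) ke += pv[k] * pv[k];
      ke *= 0.5 * mass;
      if (!std::isfinite(ke)) stop("non-finite kinetic energy at step %ld", step);
      if (save_frames) {
        NumericMatrix fr(n, 3);
        for (int i = 0; i < n; i++) {
          fr(i,0)=pr[3*i]; fr(i,1)=pr[3*i+1]; fr(i,2)=pr[3*i+2];
        }
        frames.push_back(fr);
      }
      log_step.push_back((double)step);
      log_temp.push_back(T);
      log_tkin.push_back(2.0 * ke / (3.0 * n));
      log_pe.push_back(pe);
      log_ke.push_back(ke);
    }
    if ((step & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix xc(n, 3), vc(n, 3);
  for (int i = 0; i < n; i++) {
    xc(i,0)=S.r[3*i]; xc(i,1)=S.r[3*i+1]; xc(i,2)=S.r[3*i+2];
    vc(i,0)=vv[3*i];  vc(i,1)=vv[3*i+1];  vc(i,2)=vv[3*i+2];
  }
  return List::create(
    _["coords"] = xc, _["velocities"] = vc, _["frames"] = frames,
    _["log"] = DataFrame::create(
      _["step"] = log_step, _["temp_target"] = log_temp,
      _["temp_kinetic"] = log_tkin, _["pe"] = log_pe, _["ke"] = log_ke));
}

// ---------------------------------------------------------------------------
// Contact counting over trajectory frames
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_contact_counts(List frames, double threshold) {
  if (frames.size() == 0) stop("no frames");
  NumericMatrix f0 = frames[0];
  const int n = f0.nrow();
  const double th2 = threshold * threshold;
  NumericMatrix counts(n, n);
  for (int f = 0; f < frames.size(); f++) {
    NumericMatrix fr = frames[f];
    if (fr.nrow() != n) stop("inconsistent frame sizes");
    std::vector<double> x(n), y(n), z(n);
    for (int i = 0; i < n; i++) { x[i]=fr(i,0); y[i]=fr(i,1); z[i]=fr(i,2); }
    for (int i = 0; i < n; i++) {
      for (int j = i + 1; j < n; j++) {
        double dx = x[i]-x[j], dy = y[i]-y[j], dz = z[i]-z[j];
        if (dx*dx + dy*dy + dz*dz < th2) {
          counts(i, j) += 1.0;
          counts(j, i) += 1.0;
        }
      }
    }
  }
  return counts;
}
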