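// Hybrid N-MPCD / MD engine.
//
// Solvent: point particles with position, velocity and a unit orientation
// (mesogen axis). Each timestep: ballistic streaming, grid-shifted binning,
// director kicks from the polymer (two-way coupling), Andersen-thermostatted
// velocity collision that conserves cell linear and angular momentum,
// Maier-Saupe orientation collision about the local cell director with
// Jeffery shear coupling and backflow compensation.
//
// Polymer: FENE + WCA + nematic-polymer-coupling (NPC) chain integrated by
// velocity Verlet, substepped between MPCD collisions; monomers participate
// in the velocity collision of the cell they occupy (mass M).
//
// Units: cell size a = mass m = kBT = 1 throughout.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>
#include <sstream>
#include <iomanip>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ with splitmix64 seeding, independent streams by label.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t fnv1a(const std::string &s) {
  uint64_t h = 0xCBF29CE484222325ULL;
  for (char c : s) {
    h ^= (uint64_t)(unsigned char)c;
    h *= 0x100000001B3ULL;
  }
  return h;
}

struct RngStream {
  uint64_t s[4];
  bool have_spare;
  double spare;

  RngStream() : have_spare(false), spare(0.0) { s[0] = s[1] = s[2] = s[3] = 1; }

  void seed(uint64_t seed_value, const std::string &label) {
    uint64_t x = seed_value ^ fnv1a(label);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(x);
    have_spare = false;
    spare = 0.0;
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() { // [0, 1)
    return (double)(next() >> 11) * 0x1.0p-53;
  }

  inline double normal() { // Box-Muller
    if (have_spare) { have_spare = false; return spare; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }

  std::string state_hex() const {
    std::ostringstream os;
    os << std::hex << std::setfill('0');
    for (int i = 0; i < 4; ++i) os << std::setw(16) << s[i];
    return os.str();
  }

  void state_from_hex(const std::string &h) {
    for (int i = 0; i < 4; ++i) {
      uint64_t v = 0;
      for (int k = 0; k < 16; ++k) {
        char c = h[16 * i + k];
        int dig = (c >= '0' && c <= '9') ? c - '0'
                  : (c >= 'a' && c <= 'f') ? c - 'a' + 10
                  : (c >= 'A' && c <= 'F') ? c - 'A' + 10 : 0;
        v = (v << 4) | (uint64_t)dig;
      }
      s[i] = v;
    }
    have_spare = false;
  }
};

// [[Rcpp::export]]
NumericVector cpp_stream_draws(int seed, std::string label, int n,
                               std::string dist = "unif") {
  RngStream rng;
  rng.seed((uint64_t)seed, label);
  NumericVector out(n);
  if (dist == "norm") {
    for (int i = 0; i < n; ++i) out[i] = rng.normal();
  } else {
    for (int i = 0; i < n; ++i) out[i] = rng.unif();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Small linear algebra helpers
// ---------------------------------------------------------------------------

struct Vec3 {
  double x, y, z;
};

static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double norm3(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// Rotate unit vector u about unit axis k by angle th (Rodrigues).
static inline Vec3 rotate_axis(const Vec3 &u, const Vec3 &k, double th) {
  double c = std::cos(th), s = std::sin(th);
  Vec3 kxu = cross(k, u);
  double kd = dot(k, u);
  return {u.x * c + kxu.x * s + k.x * kd * (1 - c),
          u.y * c + kxu.y * s + k.y * kd * (1 - c),
          u.z * c + kxu.z * s + k.z * kd * (1 - c)};
}

// Solve 3x3 symmetric system A w = b by Gaussian elimination with partial
// pivoting; returns false when (numerically) singular.
static bool solve3(double A[3][3], const double b[3], double w[3]) {
  double M[3][4];
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) M[i][j] = A[i][j];
    M[i][3] = b[i];
  }
  for (int col = 0; col < 3; ++col) {
    int piv = col;
    for (int r = col + 1; r < 3; ++r)
      if (std::fabs(M[r][col]) > std::fabs(M[piv][col])) piv = r;
    if (std::fabs(M[piv][col]) < 1e-12) return false;
    if (piv != col)
      for (int j = col; j < 4; ++j) std::swap(M[piv][j], M[col][j]);
    for (int r = 0; r < 3; ++r) {
      if (r == col) continue;
      double f = M[r][col] / M[col][col];
      for (int j = col; j < 4; ++j) M[r][j] -= f * M[col][j];
    }
  }
  for (int i = 0; i < 3; ++i) w[i] = M[i][3] / M[i][i];
  return true;
}

// Generic n x n solver (n <= 4) for the velocity-gradient least-squares fit.
static bool solven(int n, double A[4][4], double b[4], double w[4]) {
  double M[4][5];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) M[i][j] = A[i][j];
    M[i][n] = b[i];
  }
  for (int col = 0; col < n; ++col) {
    int piv = col;
    for (int r = col + 1; r < n; ++r)
      if (std::fabs(M[r][col]) > std::fabs(M[piv][col])) piv = r;
    if (std::fabs(M[piv][col]) < 1e-10) return false;
    if (piv != col)
      for (int j = col; j <= n; ++j) std::swap(M[piv][j], M[col][j]);
    for (int r = 0; r < n; ++r) {
      if (r == col) continue;
      double f = M[r][col] / M[col][col];
      for (int j = col; j <= n; ++j) M[r][j] -= f * M[col][j];
    }
  }
  for (int i = 0; i < n; ++i) w[i] = M[i][n] / M[i][i];
  return true;
}

// Largest eigenpair of a symmetric 3x3 matrix by Jacobi rotations.
static void eig_sym3_max(const double Ain[3][3], double &lmax, Vec3 &vmax) {
  double A[3][3], V[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) A[i][j] = Ain[i][j];
  for (int sweep = 0; sweep < 30; ++sweep) {
    double off = std::fabs(A[0][1]) + std::fabs(A[0][2]) + std::fabs(A[1][2]);
    if (off < 1e-13) break;
    for (int p = 0; p < 2; ++p) {
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(A[p][q]) < 1e-15) continue;
        double theta = (A[q][q] - A[p][p]) / (2.0 * A[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 3; ++k) {
          double Akp = A[k][p], Akq = A[k][q];
          A[k][p] = c * Akp - s * Akq;
          A[k][q] = s * Akp + c * Akq;
        }
        for (int k = 0; k < 3; ++k) {
          double Apk = A[p][k], Aqk = A[q][k];
          A[p][k] = c * Apk - s * Aqk;
          A[q][k] = s * Apk + c * Aqk;
        }
        for (int k = 0; k < 3; ++k) {
          double Vkp = V[k][p], Vkq = V[k][q];
          V[k][p] = c * Vkp - s * Vkq;
          V[k][q] = s * Vkp + c * Vkq;
        }
      }
    }
  }
  int imax = 0;
  if (A[1][1] > A[imax][imax]) imax = 1;
  if (A[2][2] > A[imax][imax]) imax = 2;
  lmax = A[imax][imax];
  vmax = {V[0][imax], V[1][imax], V[2][imax]};
  double nv = norm3(vmax);
  if (nv > 1e-12) {
    vmax.x /= nv; vmax.y /= nv; vmax.z /= nv;
  } else {
    vmax = {0, 0, 1};
  }
}

// ---------------------------------------------------------------------------
// Maier-Saupe sampling: density p(u) propto exp(a (u.n)^2) on the unit
// sphere (circle in 2D), a = U S_c / kBT. Head-tail symmetric by symmetry of
// the density.
// ---------------------------------------------------------------------------

// Sample x = u.n in [-1, 1] with density propto exp(a x^2).
static double draw_ms_cos(double a, RngStream &rng) {
  if (std::fabs(a) < 1e-12) return 2.0 * rng.unif() - 1.0;
  if (a > 0) {
    // envelope exp(a|x|) >= exp(a x^2) on [-1,1]
    double ea = std::expm1(a);
    for (int it = 0; it < 10000; ++it) {
      double u = rng.unif();
      double ax = std::log1p(u * ea) / a; // |x|
      if (rng.unif() < std::exp(a * (ax * ax - ax))) {
        return (rng.unif() < 0.5) ? ax : -ax;
      }
    }
    return 2.0 * rng.unif() - 1.0; // unreachable in practice
  }
  // a < 0: flat envelope
  for (int it = 0; it < 10000; ++it) {
    double x = 2.0 * rng.unif() - 1.0;
    if (rng.unif() < std::exp(a * x * x)) return x;
  }
  return 0.0;
}

// Orthonormal frame perpendicular to unit n.
static void perp_frame(const Vec3 &n, Vec3 &e1, Vec3 &e2) {
  Vec3 ref = (std::fabs(n.z) < 0.9) ? Vec3{0, 0, 1} : Vec3{1, 0, 0};
  e1 = cross(n, ref);
  double ne = norm3(e1);
  e1.x /= ne; e1.y /= ne; e1.z /= ne;
  e2 = cross(n, e1);
}

static Vec3 draw_ms_orientation3(const Vec3 &n, double a, RngStream &rng) {
  double x = draw_ms_cos(a, rng);
  double st = std::sqrt(std::max(0.0, 1.0 - x * x));
  double phi = 2.0 * M_PI * rng.unif();
  Vec3 e1, e2;
  perp_frame(n, e1, e2);
  double cp = std::cos(phi), sp = std::sin(phi);
  return {x * n.x + st * (cp * e1.x + sp * e2.x),
          x * n.y + st * (cp * e1.y + sp * e2.y),
          x * n.z + st * (cp * e1.z + sp * e2.z)};
}

static Vec3 draw_ms_orientation2(const Vec3 &n, double a, RngStream &rng) {
  // angle psi relative to n in the plane, p propto exp(a cos^2 psi)
  double amax = (a > 0) ? a : 0.0;
  for (int it = 0; it < 20000; ++it) {
    double psi = 2.0 * M_PI * rng.unif();
    double c = std::cos(psi);
    if (rng.unif() < std::exp(a * c * c - amax)) {
      double s = std::sin(psi);
      return {c * n.x - s * n.y, c * n.y + s * n.x, 0.0};
    }
  }
  return n;
}

// [[Rcpp::export]]
NumericMatrix cpp_maier_saupe_draws(int n, double a, NumericVector director,
                                    int d, int seed) {
  RngStream rng;
  rng.seed((uint64_t)seed, "maier-saupe");
  Vec3 nc = {director[0], director[1], d == 2 ? 0.0 : director[2]};
  double nn = norm3(nc);
  nc.x /= nn; nc.y /= nn; nc.z /= nn;
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    Vec3 u = (d == 2) ? draw_ms_orientation2(nc, a, rng)
                      : draw_ms_orientation3(nc, a, rng);
    out(i, 0) = u.x; out(i, 1) = u.y; out(i, 2) = u.z;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Engine
// ---------------------------------------------------------------------------

struct Engine {
  // geometry
  int d;                 // dimensionality, 2 or 3
  bool cylinder;         // cylinder (3D) vs periodic box
  double Lx, Ly, Lz;     // box lengths (box); for cylinder Lz = axial length
  double Rcyl;           // cylinder radius
  int ncx, ncy, ncz, ncells;
  double ox, oy;         // grid origin offset (cylinder bounding box)

  // fluid parameters
  double dens, kBT, m, dt, U, lambda, alpha, gammaR;
  bool jeffery_on, backflow_on, angular_collision;

  // polymer parameters
  int Npol;
  double Mmass, kFENE, r0, rmax, eps, sigma, kcoup, dtMD;
  int nsub;

  // forcing (Kolmogorov flow, box only): acceleration amplitude on the
  // flow component with sin(2 pi x / Lx) profile
  double force_amp;

  // state
  int Nf;
  std::vector<double> rx, ry, rz, vx, vy, vz, ux, uy, uz;
  std::vector<double> px, py, pz, pvx, pvy, pvz; // monomers, continuous coords
  std::vector<double> fx, fy, fz;                // cached MD forces
  std::vector<double> twx, twy, twz;             // tracked fluid, unwrapped
  int ntrack;
  long step_count;

  // cell fields (current shifted frame)
  double shx, shy, shz;
  std::vector<double> dirx, diry, dirz, Sfield;
  std::vector<unsigned char> dirvalid, wallcell;
  std::vector<double> kickx, kicky, kickz; // reaction angular impulse per cell

  // binning workspace
  std::vector<int> cellof, cellstart, cellcnt, order;
  std::vector<int> oldcnt;

  // rngs
  RngStream rng_init, rng_shift, rng_vel, rng_ori;

  // diagnostics / accumulators
  double max_cell_mom_err, last_temp;
  long jeffery_skips, kick_clamps;
  bool check_conservation;
  double epot_fene, epot_wca, epot_npc;

  Engine()
      : d(3), cylinder(false), Lx(10), Ly(10), Lz(10), Rcyl(0), ncx(0),
        ncy(0), ncz(0), ncells(0), ox(0), oy(0), dens(20), kBT(1), m(1),
        dt(0.1), U(6), lambda(2), alpha(0.5), gammaR(0.01), jeffery_on(true),
        backflow_on(true), angular_collision(true), Npol(0), Mmass(10),
        kFENE(120), r0(1), rmax(1.5), eps(1), sigma(1), kcoup(0), dtMD(0.002), nsub(50),
        force_amp(0), Nf(0), ntrack(0), step_count(0), shx(0), shy(0),
        shz(0), max_cell_mom_err(0), last_temp(1), jeffery_skips(0),
        kick_clamps(0), check_conservation(false), epot_fene(0), epot_wca(0),
        epot_npc(0) {}

  int ntot() const { return Nf + Npol; }

  // --- geometry helpers ----------------------------------------------------

  inline double wrap(double x, double L) const {
    double w = x - L * std::floor(x / L);
    if (w >= L) w -= L; // guard against rounding at the upper edge
    return w;
  }

  inline double min_image(double dxv, double L) const {
    return dxv - L * std::round(dxv / L);
  }

  void setup_grid() {
    if (cylinder) {
      int W = (int)std::ceil(Rcyl) + 1;
      ncx = ncy = 2 * W;
      ncz = (int)std::round(Lz);
      ox = oy = (double)W; // shifted coordinate = x + shift + W
    } else {
      ncx = (int)std::round(Lx);
      ncy = (int)std::round(Ly);
      ncz = (d == 2) ? 1 : (int)std::round(Lz);
      ox = oy = 0.0;
    }
    ncells = ncx * ncy * ncz;
    dirx.assign(ncells, 0); diry.assign(ncells, 0); dirz.assign(ncells, 0);
    Sfield.assign(ncells, 0);
    dirvalid.assign(ncells, 0);
    wallcell.assign(ncells, 0);
    kickx.assign(ncells, 0); kicky.assign(ncells, 0); kickz.assign(ncells, 0);
    cellstart.assign(ncells + 1, 0);
    cellcnt.assign(ncells, 0);
    oldcnt.assign(ncells, 0);
  }

  // cell index of a (physical) position under shift (sx, sy, sz);
  // also writes the local coordinate within the cell.
  inline int cell_index(double x, double y, double z, double sx, double sy,
                        double sz, double &lx, double &ly, double &lz) const {
    int ix, iy, iz;
    if (cylinder) {
      double cxv = x + sx + ox;
      double cyv = y + sy + oy;
      double czv = wrap(z + sz, Lz);
      ix = (int)std::floor(cxv);
      iy = (int)std::floor(cyv);
      iz = (int)std::floor(czv);
      if (ix < 0) ix = 0; if (ix >= ncx) ix = ncx - 1;
      if (iy < 0) iy = 0; if (iy >= ncy) iy = ncy - 1;
      if (iz < 0) iz = 0; if (iz >= ncz) iz = ncz - 1;
      lx = cxv - ix; ly = cyv - iy; lz = czv - iz;
    } else {
      double cxv = wrap(x + sx, Lx);
      double cyv = wrap(y + sy, Ly);
      ix = (int)std::floor(cxv); if (ix >= ncx) ix = ncx - 1;
      iy = (int)std::floor(cyv); if (iy >= ncy) iy = ncy - 1;
      lx = cxv - ix; ly = cyv - iy;
      if (d == 2) {
        iz = 0; lz = 0;
      } else {
        double czv = wrap(z + sz, Lz);
        iz = (int)std::floor(czv); if (iz >= ncz) iz = ncz - 1;
        lz = czv - iz;
      }
    }
    return (iz * ncy + iy) * ncx + ix;
  }

  // specular (perfect-slip) reflection off the cylinder wall for the
  // displacement segment from (x0,y0) by (dx,dy); z unaffected.
  // Updates position and velocity in place.
  void reflect_cylinder(double &x, double &y, double &vxi, double &vyi,
                        double x0, double y0) const {
    double px0 = x0, py0 = y0;
    double qx = x - x0, qy = y - y0;
    for (int it = 0; it < 5; ++it) {
      double r2 = (px0 + qx) * (px0 + qx) + (py0 + qy) * (py0 + qy);
      if (r2 <= Rcyl * Rcyl) break;
      // solve |p + s q|^2 = R^2 for smallest s in (0, 1]
      double aq = qx * qx + qy * qy;
      double bq = 2.0 * (px0 * qx + py0 * qy);
      double cq = px0 * px0 + py0 * py0 - Rcyl * Rcyl;
      double s;
      if (aq < 1e-30) {
        s = 1.0;
      } else {
        double disc = bq * bq - 4.0 * aq * cq;
        if (disc < 0) disc = 0;
        double sq = std::sqrt(disc);
        s = (-bq + sq) / (2.0 * aq);
        if (s < 0) s = 0;
        if (s > 1) s = 1;
      }
      double cxp = px0 + s * qx, cyp = py0 + s * qy;
      double rn = std::sqrt(cxp * cxp + cyp * cyp);
      double nxv = cxp / rn, nyv = cyp / rn;
      // reflect velocity normal component
      double vn = vxi * nxv + vyi * nyv;
      vxi -= 2.0 * vn * nxv;
      vyi -= 2.0 * vn * nyv;
      // reflect remaining displacement
      double remx = (1.0 - s) * qx, remy = (1.0 - s) * qy;
      double rn2 = remx * nxv + remy * nyv;
      remx -= 2.0 * rn2 * nxv;
      remy -= 2.0 * rn2 * nyv;
      px0 = cxp; py0 = cyp;
      qx = remx; qy = remy;
    }
    x = px0 + qx;
    y = py0 + qy;
    double rr = std::sqrt(x * x + y * y);
    if (rr > Rcyl) { // numerical safety clamp
      double f = (Rcyl * (1.0 - 1e-12)) / rr;
      x *= f; y *= f;
    }
  }

  // --- initialization ------------------------------------------------------

  void init_fluid(const std::string &init_dir) {
    double vol = cylinder ? M_PI * Rcyl * Rcyl * Lz
                          : (d == 2 ? Lx * Ly : Lx * Ly * Lz);
    Nf = (int)std::round(dens * vol);
    rx.resize(Nf); ry.resize(Nf); rz.resize(Nf);
    vx.resize(Nf); vy.resize(Nf); vz.resize(Nf);
    ux.resize(Nf); uy.resize(Nf); uz.resize(Nf);
    double sdv = std::sqrt(kBT / m);
    double mom[3] = {0, 0, 0};
    for (int i = 0; i < Nf; ++i) {
      if (cylinder) {
        double xx, yy;
        do {
          xx = (2.0 * rng_init.unif() - 1.0) * Rcyl;
          yy = (2.0 * rng_init.unif() - 1.0) * Rcyl;
        } while (xx * xx + yy * yy > Rcyl * Rcyl);
        rx[i] = xx; ry[i] = yy; rz[i] = rng_init.unif() * Lz;
      } else {
        rx[i] = rng_init.unif() * Lx;
        ry[i] = rng_init.unif() * Ly;
        rz[i] = (d == 2) ? 0.0 : rng_init.unif() * Lz;
      }
      vx[i] = sdv * rng_init.normal();
      vy[i] = sdv * rng_init.normal();
      vz[i] = (d == 2) ? 0.0 : sdv * rng_init.normal();
      mom[0] += vx[i]; mom[1] += vy[i]; mom[2] += vz[i];
      if (init_dir == "random") {
        Vec3 u;
        if (d == 2) {
          double ph = 2.0 * M_PI * rng_init.unif();
          u = {std::cos(ph), std::sin(ph), 0.0};
        } else {
          double zc = 2.0 * rng_init.unif() - 1.0;
          double ph = 2.0 * M_PI * rng_init.unif();
          double st = std::sqrt(1.0 - zc * zc);
          u = {st * std::cos(ph), st * std::sin(ph), zc};
        }
        ux[i] = u.x; uy[i] = u.y; uz[i] = u.z;
      } else { // aligned with the global axis
        if (d == 2) { ux[i] = 1; uy[i] = 0; uz[i] = 0; }
        else { ux[i] = 0; uy[i] = 0; uz[i] = 1; }
      }
    }
    for (int i = 0; i < Nf; ++i) { // zero net momentum
      vx[i] -= mom[0] / Nf;
      vy[i] -= mom[1] / Nf;
      if (d == 3) vz[i] -= mom[2] / Nf;
    }
  }

  void init_polymer(const std::string &mode) {
    if (Npol <= 0) return;
    px.resize(Npol); py.resize(Npol); pz.resize(Npol);
    pvx.resize(Npol); pvy.resize(Npol); pvz.resize(Npol);
    fx.assign(Npol, 0); fy.assign(Npol, 0); fz.assign(Npol, 0);
    double b0 = 0.9 * r0;
    bool extended = (mode == "extended");
    if (extended) {
      // fully extended on the centre line, aligned with the global director
      double zlen = cylinder ? Lz : (d == 2 ? Lx : Lz);
      double start = 0.5 * zlen - 0.5 * (Npol - 1) * b0;
      for (int j = 0; j < Npol; ++j) {
        if (d == 2) {
          px[j] = start + j * b0; py[j] = 0.5 * Ly; pz[j] = 0.0;
        } else {
          px[j] = cylinder ? 0.0 : 0.5 * Lx;
          py[j] = cylinder ? 0.0 : 0.5 * Ly;
          pz[j] = start + j * b0;
        }
      }
    } else {
      // compact self-avoiding coil grown bond by bond
      px[0] = cylinder ? 0.0 : 0.5 * Lx;
      py[0] = cylinder ? 0.0 : 0.5 * Ly;
      pz[0] = (d == 2) ? 0.0 : (cylinder ? 0.5 * Lz : 0.5 * Lz);
      for (int j = 1; j < Npol; ++j) {
        bool ok = false;
        for (int attempt = 0; attempt < 500 && !ok; ++attempt) {
          Vec3 dir;
          if (d == 2) {
            double ph = 2.0 * M_PI * rng_init.unif();
            dir = {std::cos(ph), std::sin(ph), 0.0};
          } else {
            double zc = 2.0 * rng_init.unif() - 1.0;
            double ph = 2.0 * M_PI * rng_init.unif();
            double st = std::sqrt(1.0 - zc * zc);
            dir = {st * std::cos(ph), st * std::sin(ph), zc};
          }
          double nxp = px[j - 1] + b0 * dir.x;
          double nyp = py[j - 1] + b0 * dir.y;
          double nzp = pz[j - 1] + b0 * dir.z;
          if (cylinder && nxp * nxp + nyp * nyp > (Rcyl - 1.0) * (Rcyl - 1.0))
            continue;
          ok = true;
          for (int l = 0; l < j - 1; ++l) {
            double ddx = nxp - px[l], ddy = nyp - py[l], ddz = nzp - pz[l];
            if (!cylinder) {
              ddx = min_image(ddx, Lx);
              ddy = min_image(ddy, Ly);
              if (d == 3) ddz = min_image(ddz, Lz);
            } else {
              ddz = min_image(ddz, Lz);
            }
            if (ddx * ddx + ddy * ddy + ddz * ddz < 0.81 * sigma * sigma) {
              ok = false;
              break;
            }
          }
          if (ok) { px[j] = nxp; py[j] = nyp; pz[j] = nzp; }
        }
        if (!ok) { // give up on self-avoidance for this bead
          px[j] = px[j - 1] + b0;
          py[j] = py[j - 1];
          pz[j] = pz[j - 1];
        }
      }
    }
    double sdv = std::sqrt(kBT / Mmass);
    for (int j = 0; j < Npol; ++j) {
      pvx[j] = sdv * rng_init.normal();
      pvy[j] = sdv * rng_init.normal();
      pvz[j] = (d == 2) ? 0.0 : sdv * rng_init.normal();
    }
  }

  // --- polymer forces ------------------------------------------------------

  // Director lookup for the cell (current shifted frame) containing a monomer.
  bool director_at(double x, double y, double z, Vec3 &n) const {
    double lx, ly, lz;
    int c = cell_index(x, y, z, shx, shy, shz, lx, ly, lz);
    if (!dirvalid[c]) return false;
    n = {dirx[c], diry[c], dirz[c]};
    return true;
  }

  void compute_forces(bool accumulate_kicks) {
    epot_fene = epot_wca = epot_npc = 0.0;
    for (int j = 0; j < Npol; ++j) { fx[j] = fy[j] = fz[j] = 0; }
    // FENE bonds (continuous coordinates; bonds are never wrapped)
    for (int j = 0; j + 1 < Npol; ++j) {
      double dxv = px[j + 1] - px[j];
      double dyv = py[j + 1] - py[j];
      double dzv = pz[j + 1] - pz[j];
      double r2 = dxv * dxv + dyv * dyv + dzv * dzv;
      double r = std::sqrt(r2);
      if (r >= rmax) {
        stop("FENE bond %d-%d reached the divergence radius (r = %g >= "
             "r_max = %g); the MD timestep is too large for the forces "
             "present.", j + 1, j + 2, r, rmax);
      }
      double w = 1.0 - r2 / (rmax * rmax);
      epot_fene += -0.5 * kFENE * rmax * rmax * std::log(w);
      double fmag = -kFENE / w; // force/r on bead j+1 along +d
      fx[j + 1] += fmag * dxv; fy[j + 1] += fmag * dyv; fz[j + 1] += fmag * dzv;
      fx[j] -= fmag * dxv; fy[j] -= fmag * dyv; fz[j] -= fmag * dzv;
    }
    // WCA on all pairs (minimum image)
    double rc2 = std::pow(2.0, 1.0 / 3.0) * sigma * sigma;
    for (int i = 0; i < Npol; ++i) {
      for (int j = i + 1; j < Npol; ++j) {
        double dxv = px[i] - px[j];
        double dyv = py[i] - py[j];
        double dzv = pz[i] - pz[j];
        if (cylinder) {
          dzv = min_image(dzv, Lz);
        } else {
          dxv = min_image(dxv, Lx);
          dyv = min_image(dyv, Ly);
          if (d == 3) dzv = min_image(dzv, Lz);
        }
        double r2 = dxv * dxv + dyv * dyv + dzv * dzv;
        if (r2 >= rc2) continue;
        if (r2 < 1e-12) stop("monomer overlap (r = 0) in WCA interaction");
        double s2 = sigma * sigma / r2;
        double s6 = s2 * s2 * s2;
        epot_wca += 4.0 * eps * (s6 * s6 - s6) + eps;
        double fr = 24.0 * eps * (2.0 * s6 * s6 - s6) / r2;
        fx[i] += fr * dxv; fy[i] += fr * dyv; fz[i] += fr * dzv;
        fx[j] -= fr * dxv; fy[j] -= fr * dyv; fz[j] -= fr * dzv;
      }
    }
    // NPC: bond tangent vs local director of the cell of the higher-index
    // monomer; reaction torque accumulated for the mesogens of that cell.
    if (kcoup != 0.0) {
      for (int j = 0; j + 1 < Npol; ++j) {
        int jm = j + 1; // "monomer j" of the bond (j, l = j - 1)
        Vec3 n;
        if (!director_at(px[jm], py[jm], pz[jm], n)) continue;
        double dxv = px[jm] - px[j];
        double dyv = py[jm] - py[j];
        double dzv = pz[jm] - pz[j];
        double r = std::sqrt(dxv * dxv + dyv * dyv + dzv * dzv);
        if (r < 1e-12) continue;
        Vec3 t = {dxv / r, dyv / r, dzv / r};
        double c = dot(t, n);
        Vec3 neff = n;
        if (c < 0) { neff = {-n.x, -n.y, -n.z}; c = -c; }
        if (c > 1.0) c = 1.0;
        double theta = std::acos(c);
        epot_npc += 0.5 * kcoup * theta * theta;
        double st = std::sqrt(std::max(0.0, 1.0 - c * c));
        // force prefactor k*theta/sin(theta) -> k as theta -> 0
        double pref = (st > 1e-8) ? kcoup * theta / st : kcoup;
        // F_j = pref * (neff - c t)/r on the higher-index monomer
        double gx = pref * (neff.x - c * t.x) / r;
        double gy = pref * (neff.y - c * t.y) / r;
        double gz = pref * (neff.z - c * t.z) / r;
        fx[jm] += gx; fy[jm] += gy; fz[jm] += gz;
        fx[j] -= gx; fy[j] -= gy; fz[j] -= gz;
        if (accumulate_kicks && st > 1e-8) {
          // torque on the bond: +k*theta about axis (t x neff)/|t x neff|;
          // equal-but-opposite angular impulse goes to the cell's mesogens
          Vec3 axv = cross(t, neff);
          double na = norm3(axv);
          if (na > 1e-12) {
            double tau = kcoup * theta;
            double lxx, lyy, lzz;
            int c_idx = cell_index(px[jm], py[jm], pz[jm], shx, shy, shz,
                                   lxx, lyy, lzz);
            double f = -tau * dtMD / na;
            kickx[c_idx] += f * axv.x;
            kicky[c_idx] += f * axv.y;
            kickz[c_idx] += f * axv.z;
          }
        }
      }
    }
  }

  void md_substep() {
    double half = 0.5 * dtMD;
    for (int j = 0; j < Npol; ++j) {
      pvx[j] += half * fx[j] / Mmass;
      pvy[j] += half * fy[j] / Mmass;
      if (d == 3) pvz[j] += half * fz[j] / Mmass;
      double x0 = px[j], y0 = py[j];
      px[j] += pvx[j] * dtMD;
      py[j] += pvy[j] * dtMD;
      if (d == 3) pz[j] += pvz[j] * dtMD;
      if (cylinder && px[j] * px[j] + py[j] * py[j] > Rcyl * Rcyl) {
        reflect_cylinder(px[j], py[j], pvx[j], pvy[j], x0, y0);
      }
    }
    compute_forces(true);
    for (int j = 0; j < Npol; ++j) {
      pvx[j] += half * fx[j] / Mmass;
      pvy[j] += half * fy[j] / Mmass;
      if (d == 3) pvz[j] += half * fz[j] / Mmass;
    }
  }

  // --- MPCD substeps -------------------------------------------------------

  void stream_fluid() {
    for (int i = 0; i < Nf; ++i) {
      double x0 = rx[i], y0 = ry[i];
      rx[i] += vx[i] * dt;
      ry[i] += vy[i] * dt;
      if (d == 3) rz[i] += vz[i] * dt;
      if (i < ntrack) {
        twx[i] += vx[i] * dt;
        twy[i] += vy[i] * dt;
        if (d == 3) twz[i] += vz[i] * dt;
      }
      if (cylinder) {
        if (rx[i] * rx[i] + ry[i] * ry[i] > Rcyl * Rcyl)
          reflect_cylinder(rx[i], ry[i], vx[i], vy[i], x0, y0);
        rz[i] = wrap(rz[i], Lz);
      } else {
        rx[i] = wrap(rx[i], Lx);
        ry[i] = wrap(ry[i], Ly);
        if (d == 3) rz[i] = wrap(rz[i], Lz);
      }
      if (force_amp != 0.0 && !cylinder) {
        double g = force_amp * std::sin(2.0 * M_PI * rx[i] / Lx) * dt;
        if (d == 2) vy[i] += g; else vz[i] += g;
      }
    }
  }

  // counting-sort binning of all particles (fluid then monomers) under the
  // current shift; fills cellof/cellstart/order and local coordinates.
  std::vector<double> locx, locy, locz;

  void bin_all() {
    int N = ntot();
    cellof.resize(N);
    order.resize(N);
    locx.resize(N); locy.resize(N); locz.resize(N);
    std::fill(cellcnt.begin(), cellcnt.end(), 0);
    for (int i = 0; i < N; ++i) {
      double x, y, z;
      if (i < Nf) { x = rx[i]; y = ry[i]; z = rz[i]; }
      else { int j = i - Nf; x = px[j]; y = py[j]; z = pz[j]; }
      int c = cell_index(x, y, z, shx, shy, shz, locx[i], locy[i], locz[i]);
      cellof[i] = c;
      cellcnt[c]++;
    }
    cellstart[0] = 0;
    for (int c = 0; c < ncells; ++c) cellstart[c + 1] = cellstart[c] + cellcnt[c];
    std::vector<int> fill(cellstart.begin(), cellstart.end() - 1);
    for (int i = 0; i < N; ++i) order[fill[cellof[i]]++] = i;
  }

  void mark_wall_cells() {
    std::fill(wallcell.begin(), wallcell.end(), 0);
    if (!cylinder) return;
    for (int iy = 0; iy < ncy; ++iy) {
      for (int ix = 0; ix < ncx; ++ix) {
        // cell footprint corners in physical coordinates
        double x0 = ix - ox - shx, x1 = x0 + 1.0;
        double y0 = iy - oy - shy, y1 = y0 + 1.0;
        double mx = std::max(x0 * x0, x1 * x1);
        double my = std::max(y0 * y0, y1 * y1);
        if (mx + my > Rcyl * Rcyl) {
          for (int iz = 0; iz < ncz; ++iz)
            wallcell[(iz * ncy + iy) * ncx + ix] = 1;
        }
      }
    }
  }

  // Apply accumulated director kicks (old-frame cells) to the mesogens'
  // orientations: each mesogen of cell c rotates by |J_c|/(gammaR * N_c).
  void apply_kicks(double oshx, double oshy, double oshz) {
    bool any = false;
    for (int c = 0; c < ncells; ++c) {
      if (kickx[c] != 0 || kicky[c] != 0 || kickz[c] != 0) { any = true; break; }
    }
    if (!any) return;
    std::fill(oldcnt.begin(), oldcnt.end(), 0);
    std::vector<int> oc(Nf);
    double lx, ly, lz;
    for (int i = 0; i < Nf; ++i) {
      oc[i] = cell_index(rx[i], ry[i], rz[i], oshx, oshy, oshz, lx, ly, lz);
      oldcnt[oc[i]]++;
    }
    for (int i = 0; i < Nf; ++i) {
      int c = oc[i];
      double jx = kickx[c], jy = kicky[c], jz = kickz[c];
      double jn = std::sqrt(jx * jx + jy * jy + jz * jz);
      if (jn < 1e-15 || oldcnt[c] == 0) continue;
      double th = jn / (gammaR * oldcnt[c]);
      if (th > 0.5 * M_PI) { th = 0.5 * M_PI; kick_clamps++; }
      Vec3 ax = {jx / jn, jy / jn, jz / jn};
      Vec3 u = {ux[i], uy[i], uz[i]};
      Vec3 un = rotate_axis(u, ax, th);
      double nn = norm3(un);
      ux[i] = un.x / nn; uy[i] = un.y / nn; uz[i] = un.z / nn;
    }
    std::fill(kickx.begin(), kickx.end(), 0.0);
    std::fill(kicky.begin(), kicky.end(), 0.0);
    std::fill(kickz.begin(), kickz.end(), 0.0);
  }

  // Andersen-thermostatted velocity collision; conserves cell linear
  // momentum exactly and (optionally) cell angular momentum via a rigid-body
  // restoration term. Monomers participate with mass M.
  void collide_velocity() {
    double temp_acc = 0.0;
    long temp_dof = 0;
    std::vector<double> xi_x, xi_y, xi_z, vold_x, vold_y, vold_z;
    for (int c = 0; c < ncells; ++c) {
      int n0 = cellstart[c], n1 = cellstart[c + 1];
      int nc = n1 - n0;
      if (nc < 1) continue;
      // centre of mass velocity and (for angular term) local COM
      double Msum = 0, vcx = 0, vcy = 0, vcz = 0, cx = 0, cy = 0, cz = 0;
      for (int kk = n0; kk < n1; ++kk) {
        int i = order[kk];
        double mi = (i < Nf) ? m : Mmass;
        double vxi = (i < Nf) ? vx[i] : pvx[i - Nf];
        double vyi = (i < Nf) ? vy[i] : pvy[i - Nf];
        double vzi = (i < Nf) ? vz[i] : pvz[i - Nf];
        Msum += mi;
        vcx += mi * vxi; vcy += mi * vyi; vcz += mi * vzi;
        cx += mi * locx[i]; cy += mi * locy[i]; cz += mi * locz[i];
      }
      vcx /= Msum; vcy /= Msum; vcz /= Msum;
      cx /= Msum; cy /= Msum; cz /= Msum;
      // temperature from velocities relative to the cell COM (pre-collision)
      if (nc >= 2) {
        for (int kk = n0; kk < n1; ++kk) {
          int i = order[kk];
          double mi = (i < Nf) ? m : Mmass;
          double dvx = ((i < Nf) ? vx[i] : pvx[i - Nf]) - vcx;
          double dvy = ((i < Nf) ? vy[i] : pvy[i - Nf]) - vcy;
          double dvz = ((i < Nf) ? vz[i] : pvz[i - Nf]) - vcz;
          temp_acc += mi * (dvx * dvx + dvy * dvy + dvz * dvz);
        }
        temp_dof += d * (nc - 1);
      }
      if (nc == 1) continue; // single member: xi - <xi> = 0, velocity unchanged
      xi_x.assign(nc, 0); xi_y.assign(nc, 0); xi_z.assign(nc, 0);
      vold_x.assign(nc, 0); vold_y.assign(nc, 0); vold_z.assign(nc, 0);
      double mxx = 0, mxy = 0, mxz = 0;
      for (int kk = n0; kk < n1; ++kk) {
        int i = order[kk];
        int q = kk - n0;
        double mi = (i < Nf) ? m : Mmass;
        double sdv = std::sqrt(kBT / mi);
        vold_x[q] = (i < Nf) ? vx[i] : pvx[i - Nf];
        vold_y[q] = (i < Nf) ? vy[i] : pvy[i - Nf];
        vold_z[q] = (i < Nf) ? vz[i] : pvz[i - Nf];
        xi_x[q] = sdv * rng_vel.normal();
        xi_y[q] = sdv * rng_vel.normal();
        xi_z[q] = (d == 2) ? 0.0 : sdv * rng_vel.normal();
        mxx += mi * xi_x[q]; mxy += mi * xi_y[q]; mxz += mi * xi_z[q];
      }
      mxx /= Msum; mxy /= Msum; mxz /= Msum;
      // provisional post-collision velocities
      std::vector<double> vnx(nc), vny(nc), vnz(nc);
      for (int q = 0; q < nc; ++q) {
        vnx[q] = vcx + xi_x[q] - mxx;
        vny[q] = vcy + xi_y[q] - mxy;
        vnz[q] = (d == 2) ? 0.0 : vcz + xi_z[q] - mxz;
      }
      if (angular_collision && nc >= 2) {
        // restore cell angular momentum about the cell COM
        double Lx3[3] = {0, 0, 0};
        double I[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
        for (int kk = n0; kk < n1; ++kk) {
          int i = order[kk];
          int q = kk - n0;
          double mi = (i < Nf) ? m : Mmass;
          double dx = locx[i] - cx, dy = locy[i] - cy, dz = locz[i] - cz;
          double ex = vold_x[q] - vnx[q];
          double ey = vold_y[q] - vny[q];
          double ez = vold_z[q] - vnz[q];
          Lx3[0] += mi * (dy * ez - dz * ey);
          Lx3[1] += mi * (dz * ex - dx * ez);
          Lx3[2] += mi * (dx * ey - dy * ex);
          double r2 = dx * dx + dy * dy + dz * dz;
          I[0][0] += mi * (r2 - dx * dx);
          I[1][1] += mi * (r2 - dy * dy);
          I[2][2] += mi * (r2 - dz * dz);
          I[0][1] -= mi * dx * dy;
          I[0][2] -= mi * dx * dz;
          I[1][2] -= mi * dy * dz;
        }
        I[1][0] = I[0][1]; I[2][0] = I[0][2]; I[2][1] = I[1][2];
        double w[3] = {0, 0, 0};
        bool okI;
        if (d == 2) {
          okI = (I[2][2] > 1e-10);
          if (okI) { w[0] = 0; w[1] = 0; w[2] = Lx3[2] / I[2][2]; }
        } else {
          okI = solve3(I, Lx3, w);
        }
        if (okI) {
          for (int kk = n0; kk < n1; ++kk) {
            int i = order[kk];
            int q = kk - n0;
            double dx = locx[i] - cx, dy = locy[i] - cy, dz = locz[i] - cz;
            vnx[q] += w[1] * dz - w[2] * dy;
            vny[q] += w[2] * dx - w[0] * dz;
            vnz[q] += w[0] * dy - w[1] * dx;
          }
        }
      }
      // write back; optional conservation check
      double chk[3] = {0, 0, 0};
      for (int kk = n0; kk < n1; ++kk) {
        int i = order[kk];
        int q = kk - n0;
        double mi = (i < Nf) ? m : Mmass;
        if (check_conservation) {
          chk[0] += mi * (vnx[q] - vold_x[q]);
          chk[1] += mi * (vny[q] - vold_y[q]);
          chk[2] += mi * (vnz[q] - vold_z[q]);
        }
        if (i < Nf) { vx[i] = vnx[q]; vy[i] = vny[q]; if (d == 3) vz[i] = vnz[q]; }
        else { pvx[i - Nf] = vnx[q]; pvy[i - Nf] = vny[q]; if (d == 3) pvz[i - Nf] = vnz[q]; }
      }
      if (check_conservation) {
        double e = std::sqrt(chk[0] * chk[0] + chk[1] * chk[1] + chk[2] * chk[2]);
        if (e > max_cell_mom_err) max_cell_mom_err = e;
      }
    }
    if (temp_dof > 0) last_temp = temp_acc / (double)temp_dof;
  }

  // Orientation collision + Jeffery coupling + backflow compensation.
  void collide_orientation() {
    std::fill(dirvalid.begin(), dirvalid.end(), 0);
    for (int c = 0; c < ncells; ++c) {
      int n0 = cellstart[c], n1 = cellstart[c + 1];
      if (n1 - n0 < 1) continue;
      // orientation tensor over fluid members
      int nfl = 0;
      double M2[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      for (int kk = n0; kk < n1; ++kk) {
        int i = order[kk];
        if (i >= Nf) continue;
        nfl++;
        M2[0][0] += ux[i] * ux[i];
        M2[0][1] += ux[i] * uy[i];
        M2[0][2] += ux[i] * uz[i];
        M2[1][1] += uy[i] * uy[i];
        M2[1][2] += uy[i] * uz[i];
        M2[2][2] += uz[i] * uz[i];
      }
      if (nfl == 0) continue;
      for (int a2 = 0; a2 < 3; ++a2)
        for (int b2 = 0; b2 < 3; ++b2)
          M2[a2][b2] = (a2 <= b2 ? M2[a2][b2] : M2[b2][a2]) / nfl;
      M2[1][0] = M2[0][1]; M2[2][0] = M2[0][2]; M2[2][1] = M2[1][2];
      double S;
      Vec3 n;
      if (d == 2) {
        // Q = 2 <uu> - I in the plane
        double qxx = 2.0 * M2[0][0] - 1.0;
        double qxy = 2.0 * M2[0][1];
        S = std::sqrt(qxx * qxx + qxy * qxy);
        double ang = 0.5 * std::atan2(qxy, qxx);
        n = {std::cos(ang), std::sin(ang), 0.0};
      } else {
        double Q[3][3];
        for (int a2 = 0; a2 < 3; ++a2)
          for (int b2 = 0; b2 < 3; ++b2)
            Q[a2][b2] = 1.5 * M2[a2][b2] - 0.5 * (a2 == b2 ? 1.0 : 0.0);
        eig_sym3_max(Q, S, n);
      }
      // deterministic sign convention: first nonzero component positive
      if (n.x < 0 || (n.x == 0 && (n.y < 0 || (n.y == 0 && n.z < 0)))) {
        n = {-n.x, -n.y, -n.z};
      }
      dirx[c] = n.x; diry[c] = n.y; dirz[c] = n.z;
      Sfield[c] = S;
      dirvalid[c] = 1;
      // velocity-gradient estimate (all members; post-collision velocities)
      bool haveG = false;
      double G[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      if (jeffery_on) {
        int nmem = n1 - n0;
        int npar = d + 1;
        if (nmem >= npar) {
          double A[4][4] = {{0}}, bx[4] = {0}, by[4] = {0}, bz[4] = {0};
          for (int kk = n0; kk < n1; ++kk) {
            int i = order[kk];
            double X[4] = {1.0, locx[i], locy[i], (d == 3) ? locz[i] : 0.0};
            double vxi = (i < Nf) ? vx[i] : pvx[i - Nf];
            double vyi = (i < Nf) ? vy[i] : pvy[i - Nf];
            double vzi = (i < Nf) ? vz[i] : pvz[i - Nf];
            for (int a2 = 0; a2 < npar; ++a2) {
              for (int b2 = 0; b2 < npar; ++b2) A[a2][b2] += X[a2] * X[b2];
              bx[a2] += X[a2] * vxi;
              by[a2] += X[a2] * vyi;
              bz[a2] += X[a2] * vzi;
            }
          }
          double wx[4], wy[4], wz[4];
          double Acpy1[4][4], Acpy2[4][4];
          std::copy(&A[0][0], &A[0][0] + 16, &Acpy1[0][0]);
          std::copy(&A[0][0], &A[0][0] + 16, &Acpy2[0][0]);
          bool ok = solven(npar, A, bx, wx) && solven(npar, Acpy1, by, wy);
          if (ok && d == 3) ok = solven(npar, Acpy2, bz, wz);
          if (ok) {
            haveG = true;
            G[0][0] = wx[1]; G[0][1] = wx[2]; G[0][2] = (d == 3) ? wx[3] : 0;
            G[1][0] = wy[1]; G[1][1] = wy[2]; G[1][2] = (d == 3) ? wy[3] : 0;
            if (d == 3) { G[2][0] = wz[1]; G[2][1] = wz[2]; G[2][2] = wz[3]; }
          } else {
            jeffery_skips++;
          }
        } else {
          jeffery_skips++;
        }
      }
      double E[3][3], W[3][3];
      if (haveG) {
        for (int a2 = 0; a2 < 3; ++a2)
          for (int b2 = 0; b2 < 3; ++b2) {
            E[a2][b2] = 0.5 * (G[a2][b2] + G[b2][a2]);
            W[a2][b2] = 0.5 * (G[a2][b2] - G[b2][a2]);
          }
      }
      // redraw orientations about n, then Jeffery-rotate; accumulate the
      // director angular momentum change for backflow.
      // Maier-Saupe weight exp(U S P2(u.n)/kBT) i.e. exp(a (u.n)^2) with
      // a = (d/(d-1)) U S / kBT; this convention places the 3D
      // isotropic-nematic transition near U ~ 5 so that U = 6 is nematic.
      double a = ((double)d / (d - 1)) * U * S / kBT;
      double dL[3] = {0, 0, 0};
      for (int kk = n0; kk < n1; ++kk) {
        int i = order[kk];
        if (i >= Nf) continue;
        Vec3 uold = {ux[i], uy[i], uz[i]};
        Vec3 un = (d == 2) ? draw_ms_orientation2(n, a, rng_ori)
                           : draw_ms_orientation3(n, a, rng_ori);
        if (haveG) {
          // du = alpha dt [W u + lambda (E u - (u.E.u) u)]
          double Eu[3] = {
            E[0][0] * un.x + E[0][1] * un.y + E[0][2] * un.z,
            E[1][0] * un.x + E[1][1] * un.y + E[1][2] * un.z,
            E[2][0] * un.x + E[2][1] * un.y + E[2][2] * un.z};
          double Wu[3] = {
            W[0][0] * un.x + W[0][1] * un.y + W[0][2] * un.z,
            W[1][0] * un.x + W[1][1] * un.y + W[1][2] * un.z,
            W[2][0] * un.x + W[2][1] * un.y + W[2][2] * un.z};
          double uEu = un.x * Eu[0] + un.y * Eu[1] + un.z * Eu[2];
          un.x += alpha * dt * (Wu[0] + lambda * (Eu[0] - uEu * un.x));
          un.y += alpha * dt * (Wu[1] + lambda * (Eu[1] - uEu * un.y));
          un.z += alpha * dt * (Wu[2] + lambda * (Eu[2] - uEu * un.z));
          double nn = norm3(un);
          un.x /= nn; un.y /= nn; un.z /= nn;
        }
        if (backflow_on) {
          Vec3 ueff = un;
          if (dot(uold, ueff) < 0) ueff = {-ueff.x, -ueff.y, -ueff.z};
          Vec3 cx3 = cross(uold, ueff);
          double sn = norm3(cx3), cs = dot(uold, ueff);
          if (sn > 1e-12) {
            double ang = std::atan2(sn, cs);
            dL[0] += gammaR * ang * cx3.x / sn;
            dL[1] += gammaR * ang * cx3.y / sn;
            dL[2] += gammaR * ang * cx3.z / sn;
          }
        }
        ux[i] = un.x; uy[i] = un.y; uz[i] = un.z;
      }
      if (backflow_on && (dL[0] != 0 || dL[1] != 0 || dL[2] != 0) &&
          (n1 - n0) >= 2) {
        // give -dL back to the flow as a rigid-body rotation of the members
        double Msum = 0, cx2 = 0, cy2 = 0, cz2 = 0;
        for (int kk = n0; kk < n1; ++kk) {
          int i = order[kk];
          double mi = (i < Nf) ? m : Mmass;
          Msum += mi;
          cx2 += mi * locx[i]; cy2 += mi * locy[i]; cz2 += mi * locz[i];
        }
        cx2 /= Msum; cy2 /= Msum; cz2 /= Msum;
        double I[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
        for (int kk = n0; kk < n1; ++kk) {
          int i = order[kk];
          double mi = (i < Nf) ? m : Mmass;
          double dx = locx[i] - cx2, dy = locy[i] - cy2, dz = locz[i] - cz2;
          double r2 = dx * dx + dy * dy + dz * dz;
          I[0][0] += mi * (r2 - dx * dx);
          I[1][1] += mi * (r2 - dy * dy);
          I[2][2] += mi * (r2 - dz * dz);
          I[0][1] -= mi * dx * dy;
          I[0][2] -= mi * dx * dz;
          I[1][2] -= mi * dy * dz;
        }
        I[1][0] = I[0][1]; I[2][0] = I[0][2]; I[2][1] = I[1][2];
        double mdL[3] = {-dL[0], -dL[1], -dL[2]};
        double w[3];
        bool okI = (d == 2) ? (I[2][2] > 1e-10) : solve3(I, mdL, w);
        if (d == 2 && okI) { w[0] = 0; w[1] = 0; w[2] = mdL[2] / I[2][2]; }
        if (okI) {
          for (int kk = n0; kk < n1; ++kk) {
            int i = order[kk];
            double dx = locx[i] - cx2, dy = locy[i] - cy2, dz = locz[i] - cz2;
            double ax2 = w[1] * dz - w[2] * dy;
            double ay2 = w[2] * dx - w[0] * dz;
            double az2 = w[0] * dy - w[1] * dx;
            if (i < Nf) { vx[i] += ax2; vy[i] += ay2; if (d == 3) vz[i] += az2; }
            else { pvx[i - Nf] += ax2; pvy[i - Nf] += ay2; if (d == 3) pvz[i - Nf] += az2; }
          }
        }
      }
    }
  }

  // strong planar anchoring: mesogens in wall-intersecting cells align with
  // the cylinder axis
  void anchor_walls() {
    if (!cylinder) return;
    for (int c = 0; c < ncells; ++c) {
      if (!wallcell[c]) continue;
      int n0 = cellstart[c], n1 = cellstart[c + 1];
      bool has_fluid = false;
      for (int kk = n0; kk < n1; ++kk) {
        int i = order[kk];
        if (i >= Nf) continue;
        has_fluid = true;
        double sgn = (uz[i] >= 0) ? 1.0 : -1.0;
        ux[i] = 0; uy[i] = 0; uz[i] = sgn;
      }
      if (has_fluid || wallcell[c]) {
        dirx[c] = 0; diry[c] = 0; dirz[c] = 1;
        Sfield[c] = 1.0;
        dirvalid[c] = 1;
      }
    }
  }

  void one_step() {
    if (Npol > 0) {
      compute_forces(false); // refresh cached forces for the current field
      for (int s = 0; s < nsub; ++s) md_substep();
    }
    double oshx = shx, oshy = shy, oshz = shz;
    stream_fluid();
    shx = rng_shift.unif() - 0.5;
    shy = rng_shift.unif() - 0.5;
    shz = (d == 3) ? rng_shift.unif() - 0.5 : 0.0;
    bin_all();
    mark_wall_cells();
    if (Npol > 0 && kcoup != 0.0) apply_kicks(oshx, oshy, oshz);
    collide_velocity();
    collide_orientation();
    anchor_walls();
    step_count++;
  }
};

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------

static double getd(const List &L, const char *nm, double def) {
  if (!L.containsElementNamed(nm)) return def;
  return as<double>(L[nm]);
}
static int geti(const List &L, const char *nm, int def) {
  if (!L.containsElementNamed(nm)) return def;
  return as<int>(L[nm]);
}
static std::string gets(const List &L, const char *nm, std::string def) {
  if (!L.containsElementNamed(nm)) return def;
  return as<std::string>(L[nm]);
}
static bool getb(const List &L, const char *nm, bool def) {
  if (!L.containsElementNamed(nm)) return def;
  return as<bool>(L[nm]);
}

// [[Rcpp::export]]
List cpp_run(List cfg, int nsteps, int out_every, int seed,
             Nullable<List> state_ = R_NilValue) {
  Engine E;
  E.d = geti(cfg, "d", 3);
  std::string geom = gets(cfg, "geometry", "box");
  E.cylinder = (geom == "cylinder");
  E.Lx = getd(cfg, "Lx", 10);
  E.Ly = getd(cfg, "Ly", 10);
  E.Lz = getd(cfg, "Lz", 10);
  E.Rcyl = getd(cfg, "R", 10);
  if (E.cylinder) E.Lz = getd(cfg, "L", 30);
  E.dens = getd(cfg, "density", 20);
  E.kBT = getd(cfg, "kBT", 1);
  E.m = getd(cfg, "m", 1);
  E.dt = getd(cfg, "dt", 0.1);
  E.U = getd(cfg, "U", 6);
  E.lambda = getd(cfg, "lambda", 2);
  E.alpha = getd(cfg, "alpha", 0.5);
  E.gammaR = getd(cfg, "gamma_R", 0.01);
  E.jeffery_on = getb(cfg, "jeffery", true);
  E.backflow_on = getb(cfg, "backflow", true);
  E.angular_collision = getb(cfg, "angular_collision", true);
  E.Npol = geti(cfg, "N", 0);
  E.Mmass = getd(cfg, "M", 10);
  E.kFENE = getd(cfg, "k_FENE", 120);
  E.r0 = getd(cfg, "r0", 1);
  E.rmax = getd(cfg, "r_max", 1.5);
  E.eps = getd(cfg, "epsilon", 1);
  E.sigma = getd(cfg, "sigma", 1);
  E.kcoup = getd(cfg, "k", 0);
  E.dtMD = getd(cfg, "dt_MD", 0.002);
  E.nsub = geti(cfg, "md_substeps", (int)std::round(E.dt / E.dtMD));
  E.force_amp = getd(cfg, "force_amp", 0);
  E.ntrack = geti(cfg, "n_track", 0);
  E.check_conservation = getb(cfg, "check_conservation", false);
  std::string init_dir = gets(cfg, "init_director", "aligned");
  std::string init_pol = gets(cfg, "init_polymer",
                              E.cylinder ? "extended" : "coil");

  E.setup_grid();

  bool resumed = false;
  if (state_.isNotNull()) {
    List st(state_);
    resumed = true;
    E.Nf = as<int>(st["Nf"]);
    NumericMatrix fl = st["fluid"];
    E.rx.resize(E.Nf); E.ry.resize(E.Nf); E.rz.resize(E.Nf);
    E.vx.resize(E.Nf); E.vy.resize(E.Nf); E.vz.resize(E.Nf);
    E.ux.resize(E.Nf); E.uy.resize(E.Nf); E.uz.resize(E.Nf);
    for (int i = 0; i < E.Nf; ++i) {
      E.rx[i] = fl(i, 0); E.ry[i] = fl(i, 1); E.rz[i] = fl(i, 2);
      E.vx[i] = fl(i, 3); E.vy[i] = fl(i, 4); E.vz[i] = fl(i, 5);
      E.ux[i] = fl(i, 6); E.uy[i] = fl(i, 7); E.uz[i] = fl(i, 8);
    }
    if (E.Npol > 0) {
      NumericMatrix pm = st["polymer"];
      E.px.resize(E.Npol); E.py.resize(E.Npol); E.pz.resize(E.Npol);
      E.pvx.resize(E.Npol); E.pvy.resize(E.Npol); E.pvz.resize(E.Npol);
      E.fx.assign(E.Npol, 0); E.fy.assign(E.Npol, 0); E.fz.assign(E.Npol, 0);
      for (int j = 0; j < E.Npol; ++j) {
        E.px[j] = pm(j, 0); E.py[j] = pm(j, 1); E.pz[j] = pm(j, 2);
        E.pvx[j] = pm(j, 3); E.pvy[j] = pm(j, 4); E.pvz[j] = pm(j, 5);
      }
    }
    CharacterVector rs = st["rng"];
    E.rng_init.state_from_hex(as<std::string>(rs[0]));
    E.rng_shift.state_from_hex(as<std::string>(rs[1]));
    E.rng_vel.state_from_hex(as<std::string>(rs[2]));
    E.rng_ori.state_from_hex(as<std::string>(rs[3]));
    NumericVector sh = st["shift"];
    E.shx = sh[0]; E.shy = sh[1]; E.shz = sh[2];
    NumericMatrix df = st["dir_field"];
    for (int c = 0; c < E.ncells; ++c) {
      E.dirx[c] = df(c, 0); E.diry[c] = df(c, 1); E.dirz[c] = df(c, 2);
      E.Sfield[c] = df(c, 3);
      E.dirvalid[c] = (unsigned char)(df(c, 4) != 0);
    }
    E.step_count = as<double>(st["step"]);
  } else {
    E.rng_init.seed((uint64_t)seed, "init");
    E.rng_shift.seed((uint64_t)seed, "grid-shift");
    E.rng_vel.seed((uint64_t)seed, "velocity-collision");
    E.rng_ori.seed((uint64_t)seed, "orientation-collision");
    E.init_fluid(init_dir);
    E.init_polymer(init_pol);
    // initial binning so the director field exists before the first MD block
    E.shx = E.shy = E.shz = 0.0;
    E.bin_all();
    E.mark_wall_cells();
    E.collide_orientation();
    E.anchor_walls();
  }
  if (E.ntrack > E.Nf) E.ntrack = E.Nf;
  E.twx.assign(std::max(E.ntrack, 1), 0.0);
  E.twy.assign(std::max(E.ntrack, 1), 0.0);
  E.twz.assign(std::max(E.ntrack, 1), 0.0);
  for (int i = 0; i < E.ntrack; ++i) {
    E.twx[i] = E.rx[i]; E.twy[i] = E.ry[i]; E.twz[i] = E.rz[i];
  }

  int nframes = nsteps / out_every;
  NumericMatrix frames(E.Npol > 0 ? nframes * E.Npol : 1, 3);
  NumericMatrix cm(nframes, 3);
  NumericMatrix tracked(E.ntrack > 0 ? nframes * E.ntrack : 1, 3);
  NumericVector t_out(nframes), temp_out(nframes), bond_out(nframes),
      flow_out(nframes), align_out(nframes), epot_fene(nframes),
      epot_wca(nframes), epot_npc(nframes), ekin_pol(nframes);
  NumericMatrix Qglob(nframes, 6);

  int fr = 0;
  for (int stp = 1; stp <= nsteps; ++stp) {
    E.one_step();
    if (stp % out_every == 0 && fr < nframes) {
      t_out[fr] = (double)E.step_count * E.dt;
      temp_out[fr] = E.last_temp;
      // global orientation tensor of the fluid
      double Mg[6] = {0, 0, 0, 0, 0, 0};
      for (int i = 0; i < E.Nf; ++i) {
        Mg[0] += E.ux[i] * E.ux[i];
        Mg[1] += E.ux[i] * E.uy[i];
        Mg[2] += E.ux[i] * E.uz[i];
        Mg[3] += E.uy[i] * E.uy[i];
        Mg[4] += E.uy[i] * E.uz[i];
        Mg[5] += E.uz[i] * E.uz[i];
      }
      for (int q = 0; q < 6; ++q) Qglob(fr, q) = Mg[q] / std::max(E.Nf, 1);
      // mean |n_c . z| over occupied interior cells
      double alignacc = 0;
      int aligncnt = 0;
      for (int c = 0; c < E.ncells; ++c) {
        if (!E.dirvalid[c] || E.wallcell[c]) continue;
        if (E.cellstart[c + 1] - E.cellstart[c] < 1) continue;
        alignacc += std::fabs(E.d == 2 ? E.dirx[c] : E.dirz[c]);
        aligncnt++;
      }
      align_out[fr] = (aligncnt > 0) ? alignacc / aligncnt : NA_REAL;
      if (E.force_amp != 0.0 && !E.cylinder) {
        double acc = 0;
        for (int i = 0; i < E.Nf; ++i) {
          double vflow = (E.d == 2) ? E.vy[i] : E.vz[i];
          acc += vflow * std::sin(2.0 * M_PI * E.rx[i] / E.Lx);
        }
        flow_out[fr] = 2.0 * acc / E.Nf;
      } else {
        flow_out[fr] = NA_REAL;
      }
      if (E.Npol > 0) {
        double bacc = 0;
        for (int j = 0; j + 1 < E.Npol; ++j) {
          double dxv = E.px[j + 1] - E.px[j];
          double dyv = E.py[j + 1] - E.py[j];
          double dzv = E.pz[j + 1] - E.pz[j];
          bacc += std::sqrt(dxv * dxv + dyv * dyv + dzv * dzv);
        }
        bond_out[fr] = bacc / (E.Npol - 1);
        double cmx = 0, cmy = 0, cmz = 0, ek = 0;
        for (int j = 0; j < E.Npol; ++j) {
          frames(fr * E.Npol + j, 0) = E.px[j];
          frames(fr * E.Npol + j, 1) = E.py[j];
          frames(fr * E.Npol + j, 2) = E.pz[j];
          cmx += E.px[j]; cmy += E.py[j]; cmz += E.pz[j];
          ek += 0.5 * E.Mmass * (E.pvx[j] * E.pvx[j] + E.pvy[j] * E.pvy[j] +
                                 E.pvz[j] * E.pvz[j]);
        }
        cm(fr, 0) = cmx / E.Npol;
        cm(fr, 1) = cmy / E.Npol;
        cm(fr, 2) = cmz / E.Npol;
        epot_fene[fr] = E.epot_fene;
        epot_wca[fr] = E.epot_wca;
        epot_npc[fr] = E.epot_npc;
        ekin_pol[fr] = ek;
      } else {
        bond_out[fr] = NA_REAL;
        epot_fene[fr] = epot_wca[fr] = epot_npc[fr] = ekin_pol[fr] = NA_REAL;
      }
      for (int i = 0; i < E.ntrack; ++i) {
        tracked(fr * E.ntrack + i, 0) = E.twx[i];
        tracked(fr * E.ntrack + i, 1) = E.twy[i];
        tracked(fr * E.ntrack + i, 2) = E.twz[i];
      }
      fr++;
    }
    if (stp % 200 == 0) Rcpp::checkUserInterrupt();
  }

  // final state for checkpoint/resume
  NumericMatrix fl(E.Nf, 9);
  for (int i = 0; i < E.Nf; ++i) {
    fl(i, 0) = E.rx[i]; fl(i, 1) = E.ry[i]; fl(i, 2) = E.rz[i];
    fl(i, 3) = E.vx[i]; fl(i, 4) = E.vy[i]; fl(i, 5) = E.vz[i];
    fl(i, 6) = E.ux[i]; fl(i, 7) = E.uy[i]; fl(i, 8) = E.uz[i];
  }
  NumericMatrix pm(std::max(E.Npol, 1), 6);
  for (int j = 0; j < E.Npol; ++j) {
    pm(j, 0) = E.px[j]; pm(j, 1) = E.py[j]; pm(j, 2) = E.pz[j];
    pm(j, 3) = E.pvx[j]; pm(j, 4) = E.pvy[j]; pm(j, 5) = E.pvz[j];
  }
  NumericMatrix df(E.ncells, 5);
  for (int c = 0; c < E.ncells; ++c) {
    df(c, 0) = E.dirx[c]; df(c, 1) = E.diry[c]; df(c, 2) = E.dirz[c];
    df(c, 3) = E.Sfield[c]; df(c, 4) = E.dirvalid[c] ? 1.0 : 0.0;
  }
  List state = List::create(
      _["Nf"] = E.Nf, _["fluid"] = fl, _["polymer"] = pm,
      _["rng"] = CharacterVector::create(
          E.rng_init.state_hex(), E.rng_shift.state_hex(),
          E.rng_vel.state_hex(), E.rng_ori.state_hex()),
      _["shift"] = NumericVector::create(E.shx, E.shy, E.shz),
      _["dir_field"] = df, _["step"] = (double)E.step_count);

  return List::create(
      _["time"] = t_out, _["frames"] = frames, _["cm"] = cm,
      _["tracked"] = tracked, _["temperature"] = temp_out,
      _["bond_mean"] = bond_out, _["Q_global"] = Qglob,
      _["flow_amplitude"] = flow_out, _["axis_alignment"] = align_out,
      _["epot_fene"] = epot_fene, _["epot_wca"] = epot_wca,
      _["epot_npc"] = epot_npc, _["ekin_polymer"] = ekin_pol,
      _["n_fluid"] = E.Nf, _["resumed"] = resumed,
      _["diagnostics"] = List::create(
          _["max_cell_momentum_error"] = E.max_cell_mom_err,
          _["jeffery_skips"] = (double)E.jeffery_skips,
          _["kick_clamps"] = (double)E.kick_clamps),
      _["state"] = state);
}
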