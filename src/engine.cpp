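// Discrete crosslinked fiber-network engine: internal forces (stretch, bend,
// volume exclusion, crosslink springs), filopodial zone loading, overdamped
// Euler integration, and stochastic force-sensitive crosslink kinetics.
//
// Units: pN, um, s (so pN/um^2 == Pa). Periodic in x,y; z in [0, Lz] with a
// hard wall at z = 0 (loading boundary) and pinned fiber ends near z = Lz.

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double kappa_e, kappa_b, kappa_cl;
  double diameter, k_rep, rep_cap;
  double Lxy, Lz;
  double zone_depth, force_per_site;
  bool per_fiber;
  double zeta, dt, cap_disp;
  double ku0, lambda, kBT, exp_cap;
  double rebind_rate, rebind_reach;
  double skin;
  int nlist_every;
};

Params read_params(const List& par) {
  Params p;
  p.kappa_e = as<double>(par["kappa_e"]);
  p.kappa_b = as<double>(par["kappa_b"]);
  p.kappa_cl = as<double>(par["kappa_cl"]);
  p.diameter = as<double>(par["diameter"]);
  p.k_rep = as<double>(par["k_rep"]);
  p.rep_cap = as<double>(par["rep_cap"]);
  p.Lxy = as<double>(par["Lxy"]);
  p.Lz = as<double>(par["Lz"]);
  p.zone_depth = as<double>(par["zone_depth"]);
  p.force_per_site = as<double>(par["force_per_site"]);
  p.per_fiber = as<bool>(par["per_fiber"]);
  p.zeta = as<double>(par["zeta"]);
  p.dt = as<double>(par["dt"]);
  p.cap_disp = as<double>(par["cap_disp"]);
  p.ku0 = as<double>(par["ku0"]);
  p.lambda = as<double>(par["lambda"]);
  p.kBT = as<double>(par["kBT"]);
  p.exp_cap = as<double>(par["exp_cap"]);
  p.rebind_rate = as<double>(par["rebind_rate"]);
  p.rebind_reach = as<double>(par["rebind_reach"]);
  p.skin = as<double>(par["skin"]);
  p.nlist_every = as<int>(par["nlist_every"]);
  return p;
}

struct Net {
  int n = 0, ns = 0, nt = 0, nc = 0;
  std::vector<double> X, Y, Z;
  std::vector<int> fixed;
  std::vector<int> sa, sb, sfib;
  std::vector<double> srest;
  std::vector<int> t1, t2, t3;
  std::vector<int> ca, cb;           // crosslink segment indices
  std::vector<double> cta, ctb;      // arc coordinates on each segment
  std::vector<double> crest;         // per-crosslink spring rest length
  std::vector<int> cbound;
  std::vector<double> ctension;      // cached, >= 0 contribution only
};

Net read_net(const NumericMatrix& pos, const LogicalVector& fixed,
             const IntegerVector& sa, const IntegerVector& sb,
             const NumericVector& srest, const IntegerVector& sfib,
             const IntegerVector& t1, const IntegerVector& t2, const IntegerVector& t3,
             const IntegerVector& ca, const IntegerVector& cb,
             const NumericVector& cta, const NumericVector& ctb,
             const NumericVector& crest, const LogicalVector& cbound) {
  Net w;
  w.n = pos.nrow();
  w.X.resize(w.n); w.Y.resize(w.n); w.Z.resize(w.n); w.fixed.resize(w.n);
  for (int i = 0; i < w.n; ++i) {
    w.X[i] = pos(i, 0); w.Y[i] = pos(i, 1); w.Z[i] = pos(i, 2);
    w.fixed[i] = fixed[i] ? 1 : 0;
  }
  w.ns = sa.size();
  w.sa.assign(sa.begin(), sa.end());
  w.sb.assign(sb.begin(), sb.end());
  w.srest.assign(srest.begin(), srest.end());
  w.sfib.assign(sfib.begin(), sfib.end());
  w.nt = t1.size();
  w.t1.assign(t1.begin(), t1.end());
  w.t2.assign(t2.begin(), t2.end());
  w.t3.assign(t3.begin(), t3.end());
  w.nc = ca.size();
  w.ca.assign(ca.begin(), ca.end());
  w.cb.assign(cb.begin(), cb.end());
  w.cta.assign(cta.begin(), cta.end());
  w.ctb.assign(ctb.begin(), ctb.end());
  w.crest.assign(crest.begin(), crest.end());
  w.cbound.resize(w.nc);
  for (int i = 0; i < w.nc; ++i) w.cbound[i] = cbound[i] ? 1 : 0;
  w.ctension.assign(w.nc, 0.0);
  return w;
}

inline double mi(double d, double L) { return d - L * std::nearbyint(d / L); }

// Minimum-image segment vector components
inline void seg_vec(const Net& w, const Params& p, int s,
                    double& dx, double& dy, double& dz) {
  int a = w.sa[s], b = w.sb[s];
  dx = mi(w.X[b] - w.X[a], p.Lxy);
  dy = mi(w.Y[b] - w.Y[a], p.Lxy);
  dz = w.Z[b] - w.Z[a];
}

// Closest approach between segments A: a0 + s*u (s in [0,1]) and B: b0 + t*v.
// Returns squared distance; s, t and the difference vector d = (B(t) - A(s)).
double seg_seg_closest(const double a0[3], const double u[3],
                       const double b0[3], const double v[3],
                       double& s, double& t, double d[3]) {
  double w0[3] = { a0[0] - b0[0], a0[1] - b0[1], a0[2] - b0[2] };
  double aa = u[0]*u[0] + u[1]*u[1] + u[2]*u[2];
  double bb = u[0]*v[0] + u[1]*v[1] + u[2]*v[2];
  double cc = v[0]*v[0] + v[1]*v[1] + v[2]*v[2];
  double dd = u[0]*w0[0] + u[1]*w0[1] + u[2]*w0[2];
  double ee = v[0]*w0[0] + v[1]*w0[1] + v[2]*w0[2];
  double D = aa * cc - bb * bb;
  double sN, sD = D, tN, tD = D;
  const double EPS = 1e-12;
  if (D < EPS) { sN = 0.0; sD = 1.0; tN = ee; tD = cc; }
  else {
    sN = bb * ee - cc * dd;
    tN = aa * ee - bb * dd;
    if (sN < 0.0) { sN = 0.0; tN = ee; tD = cc; }
    else if (sN > sD) { sN = sD; tN = ee + bb; tD = cc; }
  }
  if (tN < 0.0) {
    tN = 0.0;
    if (-dd < 0.0) sN = 0.0;
    else if (-dd > aa) sN = sD;
    else { sN = -dd; sD = aa; }
  } else if (tN > tD) {
    tN = tD;
    double h = -dd + bb;
    if (h < 0.0) sN = 0.0;
    else if (h > aa) sN = sD;
    else { sN = h; sD = aa; }
  }
  s = (std::fabs(sN) < EPS ? 0.0 : sN / sD);
  t = (std::fabs(tN) < EPS ? 0.0 : tN / tD);
  for (int k = 0; k < 3; ++k)
    d[k] = (b0[k] + t * v[k]) - (a0[k] + s * u[k]);
  return d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
}

// Fetch segment geometry with B translated to the minimum image of A
void pair_geometry(const Net& w, const Params& p, int i, int j,
                   double a0[3], double u[3], double b0[3], double v[3]) {
  int ia = w.sa[i], ib = w.sb[i], ja = w.sa[j], jb = w.sb[j];
  a0[0] = w.X[ia]; a0[1] = w.Y[ia]; a0[2] = w.Z[ia];
  double dx, dy, dz;
  seg_vec(w, p, i, dx, dy, dz); u[0] = dx; u[1] = dy; u[2] = dz; (void)ib;
  // translate segment j's base node to the minimum image relative to a0
  double bx = w.X[ja], by = w.Y[ja];
  b0[0] = a0[0] + mi(bx - a0[0], p.Lxy);
  b0[1] = a0[1] + mi(by - a0[1], p.Lxy);
  b0[2] = w.Z[ja];
  seg_vec(w, p, j, dx, dy, dz); v[0] = dx; v[1] = dy; v[2] = dz; (void)jb;
}

struct NList {
  std::vector<std::pair<int,int>> pairs;   // candidate repulsion pairs
  std::vector<double> ref_disp;            // positions at build (for drift check)
  std::vector<double> refX, refY, refZ;
};

inline long long pair_key(int i, int j) {
  if (i > j) std::swap(i, j);
  return (long long)i * 1000000LL + j;
}

void build_nlist(const Net& w, const Params& p,
                 const std::unordered_set<long long>& excluded, NList& nl) {
  nl.pairs.clear();
  double lmax = 0.0;
  for (int s = 0; s < w.ns; ++s) lmax = std::max(lmax, w.srest[s]);
  double cut = p.diameter + p.skin;
  double cell = lmax + cut;
  int nx = std::max(1, (int)std::floor(p.Lxy / cell));
  int nz = std::max(1, (int)std::floor((p.Lz + 2.0) / cell));
  double cx = p.Lxy / nx, cz = (p.Lz + 2.0) / nz;
  std::vector<std::vector<int>> cells(nx * nx * nz);
  std::vector<double> mx(w.ns), my(w.ns), mz(w.ns);
  for (int s = 0; s < w.ns; ++s) {
    double dx, dy, dz;
    seg_vec(w, p, s, dx, dy, dz);
    int a = w.sa[s];
    double px = w.X[a] + 0.5 * dx, py = w.Y[a] + 0.5 * dy, pz = w.Z[a] + 0.5 * dz;
    px -= p.Lxy * std::floor(px / p.Lxy);
    py -= p.Lxy * std::floor(py / p.Lxy);
    mx[s] = px; my[s] = py; mz[s] = pz;
    int ix = std::min(nx - 1, std::max(0, (int)(px / cx)));
    int iy = std::min(nx - 1, std::max(0, (int)(py / cx)));
    int iz = std::min(nz - 1, std::max(0, (int)((pz + 1.0) / cz)));
    cells[(iz * nx + iy) * nx + ix].push_back(s);
  }
  double rlist = lmax + cut;          // midpoint distance bound
  double rlist2 = rlist * rlist;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < nx; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const std::vector<int>& c0 = cells[(iz * nx + iy) * nx + ix];
        if (c0.empty()) continue;
        for (int ddz = -1; ddz <= 1; ++ddz) {
          int jz = iz + ddz;
          if (jz < 0 || jz >= nz) continue;
          for (int ddy = -1; ddy <= 1; ++ddy) {
            int jy = (iy + ddy + nx) % nx;
            for (int ddx = -1; ddx <= 1; ++ddx) {
              int jx = (ix + ddx + nx) % nx;
              int cidx = (jz * nx + jy) * nx + jx;
              int c0idx = (iz * nx + iy) * nx + ix;
              if (cidx < c0idx) continue;   // visit each cell pair once
              const std::vector<int>& c1 = cells[cidx];
              for (size_t ii = 0; ii < c0.size(); ++ii) {
                int i = c0[ii];
                size_t j0 = (cidx == c0idx) ? ii + 1 : 0;
                for (size_t jj = j0; jj < c1.size(); ++jj) {
                  int j = c1[jj];
                  // exclude segments sharing a node
                  if (w.sa[i] == w.sa[j] || w.sa[i] == w.sb[j] ||
                      w.sb[i] == w.sa[j] || w.sb[i] == w.sb[j]) continue;
                  double ddx2 = mi(mx[j] - mx[i], p.Lxy);
                  double ddy2 = mi(my[j] - my[i], p.Lxy);
                  double ddz2 = mz[j] - mz[i];
                  if (ddx2*ddx2 + ddy2*ddy2 + ddz2*ddz2 > rlist2) continue;
                  if (excluded.count(pair_key(i, j))) continue;
                  // keep only pairs genuinely within cutoff + skin at
                  // closest approach; the skin covers drift until rebuild
                  double a0[3], u[3], b0[3], v[3], d[3], s, t;
                  pair_geometry(w, p, i, j, a0, u, b0, v);
                  double d2 = seg_seg_closest(a0, u, b0, v, s, t, d);
                  if (d2 > cut * cut) continue;
                  nl.pairs.push_back(std::make_pair(i, j));
                }
              }
            }
          }
        }
      }
  nl.refX = w.X; nl.refY = w.Y; nl.refZ = w.Z;
}

bool nlist_stale(const Net& w, const Params& p, const NList& nl) {
  if ((int)nl.refX.size() != w.n) return true;
  double lim2 = 0.25 * p.skin * p.skin;
  for (int i = 0; i < w.n; ++i) {
    double dx = w.X[i] - nl.refX[i], dy = w.Y[i] - nl.refY[i], dz = w.Z[i] - nl.refZ[i];
    if (dx*dx + dy*dy + dz*dz > lim2) return true;
  }
  return false;
}

struct Energies {
  double stretch = 0, bend = 0, repulsion = 0, crosslink = 0;
  double total() const { return stretch + bend + repulsion + crosslink; }
};

inline void addF(std::vector<double>& F, int i, double fx, double fy, double fz) {
  F[3*i] += fx; F[3*i+1] += fy; F[3*i+2] += fz;
}

void stretch_forces(const Net& w, const Params& p, std::vector<double>& F,
                    Energies& en, std::vector<double>* seg_tension) {
  for (int s = 0; s < w.ns; ++s) {
    double dx, dy, dz;
    seg_vec(w, p, s, dx, dy, dz);
    double L = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (L < 1e-10) stop("degenerate segment (coincident nodes) in stretch force");
    double dr = L - w.srest[s];
    double f = p.kappa_e * dr;          // > 0: tension
    double ux = dx / L, uy = dy / L, uz = dz / L;
    addF(F, w.sa[s],  f * ux,  f * uy,  f * uz);
    addF(F, w.sb[s], -f * ux, -f * uy, -f * uz);
    en.stretch += 0.5 * p.kappa_e * dr * dr;
    if (seg_tension) (*seg_tension)[s] = f;
  }
}

void bend_forces(const Net& w, const Params& p, std::vector<double>& F, Energies& en) {
  for (int k = 0; k < w.nt; ++k) {
    int i1 = w.t1[k], i2 = w.t2[k], i3 = w.t3[k];
    double ux = mi(w.X[i1] - w.X[i2], p.Lxy), uy = mi(w.Y[i1] - w.Y[i2], p.Lxy),
           uz = w.Z[i1] - w.Z[i2];
    double vx = mi(w.X[i3] - w.X[i2], p.Lxy), vy = mi(w.Y[i3] - w.Y[i2], p.Lxy),
           vz = w.Z[i3] - w.Z[i2];
    double cu = std::sqrt(ux*ux + uy*uy + uz*uz);
    double cv = std::sqrt(vx*vx + vy*vy + vz*vz);
    if (cu < 1e-10 || cv < 1e-10) stop("degenerate bend triplet");
    double ct = (ux*vx + uy*vy + uz*vz) / (cu * cv);
    if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
    double theta = std::acos(ct);
    if (theta < 1e-8) stop("folded bend triplet (angle 0): bend plane undefined");
    double dtheta = M_PI - theta;       // deviation from straight
    en.bend += 0.5 * p.kappa_b * dtheta * dtheta;
    double st = std::sin(theta);
    // g = kappa_b * dtheta / sin(theta); sin(theta) = sin(dtheta), finite limit 1
    double g = (std::fabs(dtheta) < 1e-7) ? p.kappa_b
                                          : p.kappa_b * dtheta / st;
    double iu = 1.0 / cu, iv = 1.0 / cv;
    double uhx = ux * iu, uhy = uy * iu, uhz = uz * iu;
    double vhx = vx * iv, vhy = vy * iv, vhz = vz * iv;
    double f1x = g * iu * (ct * uhx - vhx);
    double f1y = g * iu * (ct * uhy - vhy);
    double f1z = g * iu * (ct * uhz - vhz);
    double f3x = g * iv * (ct * vhx - uhx);
    double f3y = g * iv * (ct * vhy - uhy);
    double f3z = g * iv * (ct * vhz - uhz);
    addF(F, i1, f1x, f1y, f1z);
    addF(F, i3, f3x, f3y, f3z);
    addF(F, i2, -(f1x + f3x), -(f1y + f3y), -(f1z + f3z));
  }
}

void repulsion_pair(const Net& w, const Params& p, int i, int j,
                    std::vector<double>& F, Energies& en) {
  double a0[3], u[3], b0[3], v[3], d[3], s, t;
  pair_geometry(w, p, i, j, a0, u, b0, v);
  double d2 = seg_seg_closest(a0, u, b0, v, s, t, d);
  double dist = std::sqrt(d2);
  if (dist >= p.diameter) return;
  double nx, ny, nz;
  if (dist < 1e-9) { nx = 0; ny = 0; nz = 1; dist = 1e-9; }
  else { nx = d[0] / dist; ny = d[1] / dist; nz = d[2] / dist; }
  double overlap = p.diameter - dist;
  double f = std::min(p.k_rep * overlap, p.rep_cap);
  en.repulsion += 0.5 * p.k_rep * overlap * overlap;
  // push j away from i along +n, i along -n; lever-arm distribution
  addF(F, w.sa[j],  f * nx * (1 - t),  f * ny * (1 - t),  f * nz * (1 - t));
  addF(F, w.sb[j],  f * nx * t,        f * ny * t,        f * nz * t);
  addF(F, w.sa[i], -f * nx * (1 - s), -f * ny * (1 - s), -f * nz * (1 - s));
  addF(F, w.sb[i], -f * nx * s,       -f * ny * s,       -f * nz * s);
}

void repulsion_forces(const Net& w, const Params& p, const NList& nl,
                      std::vector<double>& F, Energies& en) {
  for (size_t k = 0; k < nl.pairs.size(); ++k)
    repulsion_pair(w, p, nl.pairs[k].first, nl.pairs[k].second, F, en);
}

// attachment point of a crosslink side: (segment, arc coordinate), translated
// so both attachments are in the same periodic image
void crosslink_forces(Net& w, const Params& p, std::vector<double>& F, Energies& en) {
  for (int c = 0; c < w.nc; ++c) {
    if (!w.cbound[c]) { w.ctension[c] = 0.0; continue; }
    int si = w.ca[c], sj = w.cb[c];
    double a0[3], u[3], b0[3], v[3];
    pair_geometry(w, p, si, sj, a0, u, b0, v);
    double ta = w.cta[c], tb = w.ctb[c];
    double pax = a0[0] + ta * u[0], pay = a0[1] + ta * u[1], paz = a0[2] + ta * u[2];
    double pbx = b0[0] + tb * v[0], pby = b0[1] + tb * v[1], pbz = b0[2] + tb * v[2];
    double dx = mi(pbx - pax, p.Lxy), dy = mi(pby - pay, p.Lxy), dz = pbz - paz;
    double L = std::sqrt(dx*dx + dy*dy + dz*dz);
    double ext = L - w.crest[c];
    double f = p.kappa_cl * ext;                   // > 0 : stretched
    w.ctension[c] = (f > 0.0) ? f : 0.0;           // only stretching counts
    en.crosslink += 0.5 * p.kappa_cl * ext * ext;
    if (L < 1e-10) continue;
    double fx = f * dx / L, fy = f * dy / L, fz = f * dz / L;
    addF(F, w.sa[si], fx * (1 - ta), fy * (1 - ta), fz * (1 - ta));
    addF(F, w.sb[si], fx * ta,       fy * ta,       fz * ta);
    addF(F, w.sa[sj], -fx * (1 - tb), -fy * (1 - tb), -fz * (1 - tb));
    addF(F, w.sb[sj], -fx * tb,       -fy * tb,       -fz * tb);
  }
}

// Dynamic filopodial loading: each segment whose midpoint lies within
// zone_depth of the z=0 boundary receives a point force toward that boundary,
// split between its end nodes. per_fiber mode divides one site force among a
// fiber's in-zone segments.
int external_forces(const Net& w, const Params& p, std::vector<double>& F) {
  int in_zone = 0;
  if (p.force_per_site == 0.0) return 0;
  if (!p.per_fiber) {
    for (int s = 0; s < w.ns; ++s) {
      double zm = 0.5 * (w.Z[w.sa[s]] + w.Z[w.sb[s]]);
      if (zm < p.zone_depth) {
        ++in_zone;
        addF(F, w.sa[s], 0, 0, -0.5 * p.force_per_site);
        addF(F, w.sb[s], 0, 0, -0.5 * p.force_per_site);
      }
    }
  } else {
    int nf = 0;
    for (int s = 0; s < w.ns; ++s) nf = std::max(nf, w.sfib[s] + 1);
    std::vector<int> cnt(nf, 0);
    for (int s = 0; s < w.ns; ++s) {
      double zm = 0.5 * (w.Z[w.sa[s]] + w.Z[w.sb[s]]);
      if (zm < p.zone_depth) ++cnt[w.sfib[s]];
    }
    for (int s = 0; s < w.ns; ++s) {
      double zm = 0.5 * (w.Z[w.sa[s]] + w.Z[w.sb[s]]);
      if (zm < p.zone_depth) {
        ++in_zone;
        double f = p.force_per_site / cnt[w.sfib[s]];
        addF(F, w.sa[s], 0, 0, -0.5 * f);
        addF(F, w.sb[s], 0, 0, -0.5 * f);
      }
    }
  }
  return in_zone;
}

std::unordered_set<long long> bound_pairs(const Net& w) {
  std::unordered_set<long long> ex;
  for (int c = 0; c < w.nc; ++c)
    if (w.cbound[c]) ex.insert(pair_key(w.ca[c], w.cb[c]));
  return ex;
}

// One Euler step; returns max displacement magnitude. Throws if the stability
// cap is exceeded. Applies periodic wrap in x,y and the z=0 wall.
double euler_update(Net& w, const Params& p, const std::vector<double>& F,
                    const std::vector<double>* Fext, double& wext) {
  double inv = p.dt / p.zeta;
  double maxd2 = 0.0;
  for (int i = 0; i < w.n; ++i) {
    if (w.fixed[i]) continue;
    double dx = F[3*i] * inv, dy = F[3*i+1] * inv, dz = F[3*i+2] * inv;
    double d2 = dx*dx + dy*dy + dz*dz;
    if (d2 > maxd2) maxd2 = d2;
    if (d2 > p.cap_disp * p.cap_disp)
      stop("per-step displacement %.3g um exceeds stability cap %.3g um: use a smaller dt",
           std::sqrt(d2), p.cap_disp);
    if (Fext) wext += (*Fext)[3*i]*dx + (*Fext)[3*i+1]*dy + (*Fext)[3*i+2]*dz;
    double x = w.X[i] + dx, y = w.Y[i] + dy, z = w.Z[i] + dz;
    x -= p.Lxy * std::floor(x / p.Lxy);
    y -= p.Lxy * std::floor(y / p.Lxy);
    if (z < 0.0) z = 0.0;               // loading boundary wall
    w.X[i] = x; w.Y[i] = y; w.Z[i] = z;
  }
  return std::sqrt(maxd2);
}

NumericMatrix make_pos(const Net& w) {
  NumericMatrix out(w.n, 3);
  for (int i = 0; i < w.n; ++i) { out(i,0)=w.X[i]; out(i,1)=w.Y[i]; out(i,2)=w.Z[i]; }
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, LogicalVector fixed,
                IntegerVector sa, IntegerVector sb, NumericVector srest,
                IntegerVector sfib,
                IntegerVector t1, IntegerVector t2, IntegerVector t3,
                IntegerVector ca, IntegerVector cb, NumericVector cta,
                NumericVector ctb, NumericVector crest, LogicalVector cbound,
                List par, bool loading, bool breakdown) {
  Params p = read_params(par);
  Net w = read_net(pos, fixed, sa, sb, srest, sfib, t1, t2, t3,
                   ca, cb, cta, ctb, crest, cbound);
  Energies en;
  std::vector<double> Fs(3*w.n, 0), Fb(3*w.n, 0), Fr(3*w.n, 0), Fc(3*w.n, 0),
                      Fe(3*w.n, 0);
  std::vector<double> seg_tension(w.ns, 0.0);
  stretch_forces(w, p, Fs, en, &seg_tension);
  bend_forces(w, p, Fb, en);
  NList nl;
  std::unordered_set<long long> ex = bound_pairs(w);
  build_nlist(w, p, ex, nl);
  repulsion_forces(w, p, nl, Fr, en);
  crosslink_forces(w, p, Fc, en);
  int in_zone = 0;
  if (loading) in_zone = external_forces(w, p, Fe);

  NumericMatrix Ft(w.n, 3);
  for (int i = 0; i < w.n; ++i)
    for (int k = 0; k < 3; ++k)
      Ft(i, k) = Fs[3*i+k] + Fb[3*i+k] + Fr[3*i+k] + Fc[3*i+k] + Fe[3*i+k];
  List out = List::create(
    _["total"] = Ft,
    _["energies"] = NumericVector::create(
        _["stretch"] = en.stretch, _["bend"] = en.bend,
        _["repulsion"] = en.repulsion, _["crosslink"] = en.crosslink),
    _["cl_tension"] = NumericVector(w.ctension.begin(), w.ctension.end()),
    _["seg_tension"] = NumericVector(seg_tension.begin(), seg_tension.end()),
    _["n_in_zone"] = in_zone);
  if (breakdown) {
    auto tomat = [&](const std::vector<double>& v) {
      NumericMatrix m(w.n, 3);
      for (int i = 0; i < w.n; ++i)
        for (int k = 0; k < 3; ++k) m(i, k) = v[3*i+k];
      return m;
    };
    out["stretch"] = tomat(Fs); out["bend"] = tomat(Fb);
    out["repulsion"] = tomat(Fr); out["crosslink"] = tomat(Fc);
    out["external"] = tomat(Fe);
  }
  return out;
}

// Candidate crosslink pairs: distinct-fiber segment pairs whose closest
// approach distance is at most `reach`. Used at network generation.
// [[Rcpp::export]]
DataFrame cpp_candidate_pairs(NumericMatrix pos,
                              IntegerVector sa, IntegerVector sb,
                              NumericVector srest, IntegerVector sfib,
                              double Lxy, double Lz, double reach) {
  Params p; p.Lxy = Lxy; p.Lz = Lz; p.diameter = reach; p.skin = 0.0;
  Net w;
  w.n = pos.nrow();
  w.X.resize(w.n); w.Y.resize(w.n); w.Z.resize(w.n); w.fixed.assign(w.n, 0);
  for (int i = 0; i < w.n; ++i) { w.X[i]=pos(i,0); w.Y[i]=pos(i,1); w.Z[i]=pos(i,2); }
  w.ns = sa.size();
  w.sa.assign(sa.begin(), sa.end());
  w.sb.assign(sb.begin(), sb.end());
  w.srest.assign(srest.begin(), srest.end());
  w.sfib.assign(sfib.begin(), sfib.end());
  NList nl;
  std::unordered_set<long long> ex;
  build_nlist(w, p, ex, nl);
  std::vector<int> oi, oj; std::vector<double> os, ot, od;
  for (size_t k = 0; k < nl.pairs.size(); ++k) {
    int i = nl.pairs[k].first, j = nl.pairs[k].second;
    if (w.sfib[i] == w.sfib[j]) continue;   // crosslinks join distinct fibers
    double a0[3], u[3], b0[3], v[3], d[3], s, t;
    pair_geometry(w, p, i, j, a0, u, b0, v);
    double d2 = seg_seg_closest(a0, u, b0, v, s, t, d);
    if (d2 <= reach * reach) {
      oi.push_back(i + 1); oj.push_back(j + 1);
      os.push_back(s); ot.push_back(t); od.push_back(std::sqrt(d2));
    }
  }
  return DataFrame::create(_["seg_a"] = oi, _["seg_b"] = oj,
                           _["ta"] = os, _["tb"] = ot, _["dist"] = od);
}

// Relax to mechanical plateau: no loading, no kinetics. Convergence when the
// relative energy change over a sliding window and the max nodal force both
// fall below tolerance.
// [[Rcpp::export]]
List cpp_relax(NumericMatrix pos, LogicalVector fixed,
               IntegerVector sa, IntegerVector sb, NumericVector srest,
               IntegerVector sfib,
               IntegerVector t1, IntegerVector t2, IntegerVector t3,
               IntegerVector ca, IntegerVector cb, NumericVector cta,
               NumericVector ctb, NumericVector crest, LogicalVector cbound,
               List par, int max_steps, int check_every,
               double energy_tol, double force_tol) {
  Params p = read_params(par);
  Net w = read_net(pos, fixed, sa, sb, srest, sfib, t1, t2, t3,
                   ca, cb, cta, ctb, crest, cbound);
  NList nl;
  std::unordered_set<long long> ex = bound_pairs(w);
  build_nlist(w, p, ex, nl);
  std::vector<double> F(3*w.n);
  std::vector<double> tr_step, tr_energy, tr_maxf;
  double e_prev = R_PosInf;
  bool converged = false;
  int steps = 0;
  double maxF = R_PosInf;
  for (int it = 0; it < max_steps; ++it) {
    if (nlist_stale(w, p, nl)) build_nlist(w, p, ex, nl);
    std::fill(F.begin(), F.end(), 0.0);
    Energies en;
    stretch_forces(w, p, F, en, nullptr);
    bend_forces(w, p, F, en);
    repulsion_forces(w, p, nl, F, en);
    crosslink_forces(w, p, F, en);
    if ((it % check_every) == 0) {
      maxF = 0.0;
      for (int i = 0; i < w.n; ++i) {
        if (w.fixed[i]) continue;
        double f2 = F[3*i]*F[3*i] + F[3*i+1]*F[3*i+1] + F[3*i+2]*F[3*i+2];
        if (f2 > maxF) maxF = f2;
      }
      maxF = std::sqrt(maxF);
      double e = en.total();
      tr_step.push_back(it); tr_energy.push_back(e); tr_maxf.push_back(maxF);
      // a near-zero absolute energy is a plateau regardless of its
      // relative fluctuations (nearly prestress-free sparse networks)
      double rel = std::fabs(e - e_prev) / std::max(e, 1e-12);
      bool energy_flat = (rel < energy_tol) || (e < 1e-3);
      if (it > 0 && energy_flat && maxF < force_tol) { converged = true; steps = it; break; }
      e_prev = e;
    }
    double wdummy = 0.0;
    euler_update(w, p, F, nullptr, wdummy);
    steps = it + 1;
  }
  return List::create(
    _["pos"] = make_pos(w),
    _["converged"] = converged,
    _["steps"] = steps,
    _["max_force"] = maxF,
    _["trace"] = DataFrame::create(_["step"] = tr_step, _["energy"] = tr_energy,
                                   _["max_force"] = tr_maxf));
}

// Integrate one protocol phase. Interleaves per step:
// force computation -> unbinding (-> rebinding) -> Euler update.
// Uses R's RNG stream (deterministic under set.seed).
// [[Rcpp::export]]
List cpp_run_phase(NumericMatrix pos, LogicalVector fixed,
                   IntegerVector sa, IntegerVector sb, NumericVector srest,
                   IntegerVector sfib,
                   IntegerVector t1, IntegerVector t2, IntegerVector t3,
                   IntegerVector ca, IntegerVector cb, NumericVector cta,
                   NumericVector ctb, NumericVector crest, LogicalVector cbound,
                   List par, int nsteps, bool loading, bool kinetics,
                   bool rebinding, int snap_every, double t0) {
  Params p = read_params(par);
  Net w = read_net(pos, fixed, sa, sb, srest, sfib, t1, t2, t3,
                   ca, cb, cta, ctb, crest, cbound);
  RNGScope rngs;
  NList nl;
  std::unordered_set<long long> ex = bound_pairs(w);
  build_nlist(w, p, ex, nl);

  int nsnap = nsteps / snap_every + 1;
  NumericVector snaps((R_xlen_t)w.n * 3 * nsnap);
  IntegerMatrix bsnap(nsnap, std::max(w.nc, 1));
  NumericVector stime(nsnap), senergy(nsnap), swork(nsnap);
  IntegerVector sbound(nsnap), sinzone(nsnap);
  NumericMatrix sen(nsnap, 4);
  std::vector<double> ev_time, ev_tension; std::vector<int> ev_id, ev_kind;

  std::vector<double> F(3*w.n), Fe(3*w.n);
  double wext = 0.0, max_kudt = 0.0;
  int isnap = 0;

  auto record = [&](int snap_idx, double tnow, const Energies& en, int inzone) {
    for (int i = 0; i < w.n; ++i) {
      snaps[(R_xlen_t)snap_idx * w.n * 3 + i]            = w.X[i];
      snaps[(R_xlen_t)snap_idx * w.n * 3 + w.n + i]      = w.Y[i];
      snaps[(R_xlen_t)snap_idx * w.n * 3 + 2 * w.n + i]  = w.Z[i];
    }
    int bc = 0;
    for (int c = 0; c < w.nc; ++c) { bsnap(snap_idx, c) = w.cbound[c]; bc += w.cbound[c]; }
    stime[snap_idx] = tnow;
    senergy[snap_idx] = en.total();
    sen(snap_idx, 0) = en.stretch; sen(snap_idx, 1) = en.bend;
    sen(snap_idx, 2) = en.repulsion; sen(snap_idx, 3) = en.crosslink;
    swork[snap_idx] = wext;
    sbound[snap_idx] = bc;
    sinzone[snap_idx] = inzone;
  };

  for (int it = 0; it <= nsteps; ++it) {
    if (nlist_stale(w, p, nl)) { ex = bound_pairs(w); build_nlist(w, p, ex, nl); }
    std::fill(F.begin(), F.end(), 0.0);
    Energies en;
    stretch_forces(w, p, F, en, nullptr);
    bend_forces(w, p, F, en);
    repulsion_forces(w, p, nl, F, en);
    crosslink_forces(w, p, F, en);
    int inzone = 0;
    if (loading) {
      std::fill(Fe.begin(), Fe.end(), 0.0);
      inzone = external_forces(w, p, Fe);
      for (int i = 0; i < 3*w.n; ++i) F[i] += Fe[i];
    }
    if ((it % snap_every) == 0 && isnap < nsnap)
      record(isnap++, t0 + it * p.dt, en, inzone);
    if (it == nsteps) break;

    if (kinetics) {
      double tnow = t0 + it * p.dt;
      for (int c = 0; c < w.nc; ++c) {
        if (w.cbound[c]) {
          double expo = p.lambda * w.ctension[c] / p.kBT;
          if (expo > p.exp_cap) expo = p.exp_cap;
          double ku = p.ku0 * std::exp(expo);
          double kdt = ku * p.dt;
          if (kdt > max_kudt) max_kudt = kdt;
          double pu = 1.0 - std::exp(-kdt);
          if (R::unif_rand() < pu) {
            w.cbound[c] = 0;
            ev_time.push_back(tnow); ev_id.push_back(c + 1);
            ev_tension.push_back(w.ctension[c]); ev_kind.push_back(0);
            ex.erase(pair_key(w.ca[c], w.cb[c]));
            // the pair re-enters volume exclusion immediately
            double a0[3], u[3], b0[3], v[3], d[3], s, t;
            pair_geometry(w, p, w.ca[c], w.cb[c], a0, u, b0, v);
            double d2 = seg_seg_closest(a0, u, b0, v, s, t, d);
            double cut = p.diameter + p.skin;
            if (d2 < cut * cut)
              nl.pairs.push_back(std::make_pair(w.ca[c], w.cb[c]));
          }
        } else if (rebinding && p.rebind_rate > 0.0) {
          // distance between former attachment loci at current geometry
          double a0[3], u[3], b0[3], v[3];
          pair_geometry(w, p, w.ca[c], w.cb[c], a0, u, b0, v);
          double ta = w.cta[c], tb = w.ctb[c];
          double dx = mi((b0[0]+tb*v[0]) - (a0[0]+ta*u[0]), p.Lxy);
          double dy = mi((b0[1]+tb*v[1]) - (a0[1]+ta*u[1]), p.Lxy);
          double dz = (b0[2]+tb*v[2]) - (a0[2]+ta*u[2]);
          double L = std::sqrt(dx*dx + dy*dy + dz*dz);
          if (L <= p.rebind_reach) {
            double pr = 1.0 - std::exp(-p.rebind_rate * p.dt);
            if (R::unif_rand() < pr) {
              w.cbound[c] = 1;
              w.crest[c] = L;          // zero strain at reattachment
              ev_time.push_back(tnow); ev_id.push_back(c + 1);
              ev_tension.push_back(0.0); ev_kind.push_back(1);
              ex.insert(pair_key(w.ca[c], w.cb[c]));
            }
          }
        }
      }
    }
    euler_update(w, p, F, loading ? &Fe : nullptr, wext);
  }

  snaps.attr("dim") = IntegerVector::create(w.n, 3, nsnap);
  LogicalVector bound_out(w.nc);
  for (int c = 0; c < w.nc; ++c) bound_out[c] = w.cbound[c] != 0;
  return List::create(
    _["pos"] = make_pos(w),
    _["bound"] = bound_out,
    _["crest"] = NumericVector(w.crest.begin(), w.crest.end()),
    _["snap_pos"] = snaps,
    _["snap_bound"] = bsnap,
    _["snap_time"] = stime,
    _["snap_energy"] = senergy,
    _["snap_energies"] = sen,
    _["snap_work"] = swork,
    _["snap_bound_count"] = sbound,
    _["snap_in_zone"] = sinzone,
    _["events"] = DataFrame::create(
        _["time"] = ev_time, _["crosslink"] = ev_id,
        _["tension"] = ev_tension, _["kind"] = ev_kind),
    _["max_kudt"] = max_kudt);
}

// Tridiagonal (Thomas) solver for the continuum radial equilibrium system.
// [[Rcpp::export]]
NumericVector cpp_thomas(NumericVector lower, NumericVector diag,
                         NumericVector upper, NumericVector rhs) {
  int n = diag.size();
  std::vector<double> c(n), d(n);
  NumericVector x(n);
  c[0] = upper[0] / diag[0];
  d[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    double m = diag[i] - lower[i - 1] * c[i - 1];
    c[i] = (i < n - 1) ? upper[i] / m : 0.0;
    d[i] = (rhs[i] - lower[i - 1] * d[i - 1]) / m;
  }
  x[n - 1] = d[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = d[i] - c[i] * x[i + 1];
  return x;
}
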