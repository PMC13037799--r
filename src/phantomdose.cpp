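#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Voxelization: classify voxel centers against a closed triangle surface by
// z-column crossing parity.  Surfaces may have several closed components
// (two-boundary shell solids); parity handles nesting automatically.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector voxelize_parity(NumericMatrix verts, IntegerMatrix faces,
                              NumericVector origin, NumericVector pitch_cm,
                              IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = pitch_cm[0], dy = pitch_cm[1], dz = pitch_cm[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  // tiny irrational-ish offset keeps ray-through-edge cases off the columns
  const double ex = dx * 1.23456789e-7, ey = dy * 1.23456789e-7;

  std::vector<std::vector<double>> cross((size_t)nx * ny);
  const int nf = faces.nrow();
  for (int t = 0; t < nf; ++t) {
    const int i0 = faces(t, 0) - 1, i1 = faces(t, 1) - 1, i2 = faces(t, 2) - 1;
    const double ax = verts(i0, 0), ay = verts(i0, 1), az = verts(i0, 2);
    const double bx = verts(i1, 0), by = verts(i1, 1), bz = verts(i1, 2);
    const double cx = verts(i2, 0), cy = verts(i2, 1), cz = verts(i2, 2);
    double xmin = std::min(ax, std::min(bx, cx));
    double xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy));
    double ymax = std::max(ay, std::max(by, cy));
    int ilo = std::max(0, (int)std::ceil((xmin - ox - ex) / dx - 0.5));
    int ihi = std::min(nx - 1, (int)std::floor((xmax - ox - ex) / dx - 0.5));
    int jlo = std::max(0, (int)std::ceil((ymin - oy - ey) / dy - 0.5));
    int jhi = std::min(ny - 1, (int)std::floor((ymax - oy - ey) / dy - 0.5));
    if (ilo > ihi || jlo > jhi) continue;
    const double v0x = bx - ax, v0y = by - ay;
    const double v1x = cx - ax, v1y = cy - ay;
    const double det = v0x * v1y - v1x * v0y;
    if (det == 0.0) continue;                   // degenerate in projection
    for (int i = ilo; i <= ihi; ++i) {
      const double px = ox + (i + 0.5) * dx + ex - ax;
      for (int j = jlo; j <= jhi; ++j) {
        const double py = oy + (j + 0.5) * dy + ey - ay;
        const double u = (px * v1y - v1x * py) / det;
        const double v = (v0x * py - px * v0y) / det;
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        const double z = az + u * (bz - az) + v * (cz - az);
        cross[(size_t)j * nx + i].push_back(z);
      }
    }
  }
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double>& cz = cross[(size_t)j * nx + i];
      if (cz.empty()) continue;
      std::sort(cz.begin(), cz.end());
      // walk voxel centers along z, counting crossings below each center
      size_t kc = 0;
      for (int k = 0; k < nz; ++k) {
        const double zc = oz + (k + 0.5) * dz;
        while (kc < cz.size() && cz[kc] < zc) ++kc;
        if (kc & 1) {
          out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = true;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Self-intersection detection: exact segment-vs-triangle tests over
// bounding-box-filtered pairs; vertex-sharing pairs excluded.
// ---------------------------------------------------------------------------

static inline bool seg_tri_intersect(const double* p, const double* q,
                                     const double* a, const double* b,
                                     const double* c) {
  // Moller-Trumbore for segment p->q against triangle abc (strict interior)
  double d[3] = {q[0] - p[0], q[1] - p[1], q[2] - p[2]};
  double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double h[3] = {d[1] * e2[2] - d[2] * e2[1],
                 d[2] * e2[0] - d[0] * e2[2],
                 d[0] * e2[1] - d[1] * e2[0]};
  double det = e1[0] * h[0] + e1[1] * h[1] + e1[2] * h[2];
  if (std::fabs(det) < 1e-14) return false;    // parallel / coplanar: skip
  double inv = 1.0 / det;
  double s[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double u = (s[0] * h[0] + s[1] * h[1] + s[2] * h[2]) * inv;
  if (u <= 1e-12 || u >= 1.0 - 1e-12) return false;
  double qv[3] = {s[1] * e1[2] - s[2] * e1[1],
                  s[2] * e1[0] - s[0] * e1[2],
                  s[0] * e1[1] - s[1] * e1[0]};
  double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
  if (v <= 1e-12 || u + v >= 1.0 - 1e-12) return false;
  double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
  return (t > 1e-12 && t < 1.0 - 1e-12);
}

// [[Rcpp::export]]
IntegerMatrix tri_self_intersections(NumericMatrix verts, IntegerMatrix faces) {
  const int nf = faces.nrow();
  std::vector<double> bb(6 * (size_t)nf);
  for (int t = 0; t < nf; ++t) {
    for (int d = 0; d < 3; ++d) {
      double v0 = verts(faces(t, 0) - 1, d);
      double v1 = verts(faces(t, 1) - 1, d);
      double v2 = verts(faces(t, 2) - 1, d);
      bb[6 * (size_t)t + d] = std::min(v0, std::min(v1, v2));
      bb[6 * (size_t)t + 3 + d] = std::max(v0, std::max(v1, v2));
    }
  }
  // sweep on x
  std::vector<int> order(nf);
  for (int t = 0; t < nf; ++t) order[t] = t;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    return bb[6 * (size_t)a] < bb[6 * (size_t)b];
  });
  std::vector<std::pair<int, int>> hits;
  for (int ii = 0; ii < nf; ++ii) {
    int t1 = order[ii];
    double x1max = bb[6 * (size_t)t1 + 3];
    for (int jj = ii + 1; jj < nf; ++jj) {
      int t2 = order[jj];
      if (bb[6 * (size_t)t2] > x1max) break;
      bool sep = false;
      for (int d = 1; d < 3; ++d) {
        if (bb[6 * (size_t)t1 + d] > bb[6 * (size_t)t2 + 3 + d] ||
            bb[6 * (size_t)t2 + d] > bb[6 * (size_t)t1 + 3 + d]) {
          sep = true; break;
        }
      }
      if (sep) continue;
      // exclude pairs sharing a vertex (mesh adjacency)
      bool shared = false;
      for (int a = 0; a < 3 && !shared; ++a)
        for (int b = 0; b < 3; ++b)
          if (faces(t1, a) == faces(t2, b)) { shared = true; break; }
      if (shared) continue;
      double tri1[3][3], tri2[3][3];
      for (int a = 0; a < 3; ++a)
        for (int d = 0; d < 3; ++d) {
          tri1[a][d] = verts(faces(t1, a) - 1, d);
          tri2[a][d] = verts(faces(t2, a) - 1, d);
        }
      bool inter = false;
      for (int a = 0; a < 3 && !inter; ++a) {
        int a2 = (a + 1) % 3;
        if (seg_tri_intersect(tri1[a], tri1[a2],
                              tri2[0], tri2[1], tri2[2])) inter = true;
        if (!inter && seg_tri_intersect(tri2[a], tri2[a2],
                                        tri1[0], tri1[1], tri1[2]))
          inter = true;
      }
      if (inter) {
        hits.push_back(std::make_pair(std::min(t1, t2) + 1,
                                      std::max(t1, t2) + 1));
      }
    }
  }
  std::sort(hits.begin(), hits.end());
  hits.erase(std::unique(hits.begin(), hits.end()), hits.end());
  IntegerMatrix out((int)hits.size(), 2);
  for (size_t k = 0; k < hits.size(); ++k) {
    out(k, 0) = hits[k].first;
    out(k, 1) = hits[k].second;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Klein-Nishina incoherent-scatter sampling (free electron).
// Rejection in x = E'/E with envelope x + 1/x; exact KN density.
// ---------------------------------------------------------------------------

static const double MEC2 = 0.510998950;  // electron rest energy, MeV

static inline void kn_sample_one(double E, double& Eprime, double& mu) {
  const double k = E / MEC2;
  const double xmin = 1.0 / (1.0 + 2.0 * k);
  const double M = 1.0 + 1.0 / xmin;           // bound on x + 1/x
  double x, f;
  for (;;) {
    x = xmin + (1.0 - xmin) * unif_rand();
    const double c = 1.0 + 1.0 / k - 1.0 / (k * x);
    const double sin2 = 1.0 - c * c;
    f = x + 1.0 / x - sin2;
    if (unif_rand() * M <= f) { mu = c; break; }
  }
  Eprime = x * E;
  if (mu > 1.0) mu = 1.0;
  if (mu < -1.0) mu = -1.0;
}

// [[Rcpp::export]]
NumericMatrix kn_sample_cpp(double E, int n) {
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double ep, mu;
    kn_sample_one(E, ep, mu);
    out(i, 0) = ep;
    out(i, 1) = mu;
  }
  colnames(out) = CharacterVector::create("Eprime", "mu");
  return out;
}

// ---------------------------------------------------------------------------
// Analog photon transport with Woodcock delta-tracking on a voxel raster,
// kerma approximation (charged-particle energy deposited at the interaction
// site).  Channels: photoelectric, Klein-Nishina incoherent, pair
// production (two back-to-back 0.511 MeV annihilation photons re-emitted).
// Track-length fluence via the delta-tracking collision estimator
// (score 1/mu_majorant at every real or virtual collision).
// ---------------------------------------------------------------------------

struct Photon {
  double x, y, z, ux, uy, uz, E;
  bool primary_uncollided;
};

static inline int find_bin(const std::vector<double>& edges, double E) {
  // bin b covers [edges[b], edges[b+1]); top edge inclusive
  int nb = (int)edges.size() - 1;
  if (E <= edges[0]) return 0;
  if (E >= edges[nb]) return nb - 1;
  int lo = 0, hi = nb;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (E >= edges[mid]) lo = mid; else hi = mid;
  }
  return lo;
}

// log-log interpolation with zero-aware fallback (pair channel)
static inline double interp_mu(const std::vector<double>& logE,
                               const NumericMatrix& tab, int mat,
                               double lE, int idx, double frac) {
  const double y0 = tab(mat, idx), y1 = tab(mat, idx + 1);
  if (y0 <= 0.0 || y1 <= 0.0) {
    return y0 + (y1 - y0) * frac;              // linear across a zero
  }
  return std::exp(std::log(y0) + (std::log(y1) - std::log(y0)) * frac);
}

static inline void rotate_direction(double& ux, double& uy, double& uz,
                                    double mu) {
  const double phi = 2.0 * M_PI * unif_rand();
  const double sint = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  const double cphi = std::cos(phi), sphi = std::sin(phi);
  double nx, ny, nz;
  if (std::fabs(uz) < 0.99999) {
    const double denom = std::sqrt(1.0 - uz * uz);
    nx = mu * ux + sint * (ux * uz * cphi - uy * sphi) / denom;
    ny = mu * uy + sint * (uy * uz * cphi + ux * sphi) / denom;
    nz = mu * uz - sint * denom * cphi;
  } else {
    nx = sint * cphi;
    ny = sint * sphi;
    nz = mu * (uz > 0 ? 1.0 : -1.0);
  }
  const double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / norm; uy = ny / norm; uz = nz / norm;
}

// [[Rcpp::export]]
List transport_kernel(IntegerVector organ, IntegerVector dims,
                      NumericVector pitch_cm, NumericVector origin,
                      IntegerVector id2mat, IntegerVector id2reg,
                      int n_regions,
                      NumericMatrix mu_pe, NumericMatrix mu_inc,
                      NumericMatrix mu_pair,
                      NumericVector egrid,
                      double E0, int nhist,
                      NumericVector bin_edges, double cutoff) {
  RNGScope rng;
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = pitch_cm[0], dy = pitch_cm[1], dz = pitch_cm[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double x1 = ox + nx * dx, y1 = oy + ny * dy, z1 = oz + nz * dz;
  const int nE = egrid.size();
  const int nmat = mu_pe.nrow();
  std::vector<double> logE(nE);
  for (int i = 0; i < nE; ++i) logE[i] = std::log(egrid[i]);
  if (E0 < egrid[0] || E0 > egrid[nE - 1]) {
    stop("beam energy outside cross-section table range");
  }
  const int nb = bin_edges.size() - 1;
  std::vector<double> edges(bin_edges.begin(), bin_edges.end());

  // precompute majorant over materials on the grid (envelope is exact at
  // grid points; interpolated between, matching per-material interpolation)
  std::vector<double> pe_v(nmat), inc_v(nmat), pr_v(nmat);

  NumericVector edep(n_regions);
  NumericMatrix fluence(n_regions, nb);
  NumericMatrix fluence_E(n_regions, nb);   // energy-weighted, for bin means
  double edep_air = 0.0, escaped = 0.0;
  int n_uncollided = 0;

  // per-energy lookup helper
  auto locate = [&](double E, int& idx, double& frac, double& lE) {
    lE = std::log(E);
    int lo = 0, hi = nE - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (lE >= logE[mid]) lo = mid; else hi = mid;
    }
    idx = lo;
    frac = (lE - logE[lo]) / (logE[lo + 1] - logE[lo]);
  };

  auto mu_majorant = [&](int idx, double frac, double lE) {
    double m = 0.0;
    for (int mat = 0; mat < nmat; ++mat) {
      double tot = interp_mu(logE, mu_pe, mat, lE, idx, frac) +
                   interp_mu(logE, mu_inc, mat, lE, idx, frac) +
                   interp_mu(logE, mu_pair, mat, lE, idx, frac);
      if (tot > m) m = tot;
    }
    return m;
  };

  std::vector<Photon> stack;
  for (int h = 0; h < nhist; ++h) {
    stack.clear();
    Photon p;
    p.x = ox + unif_rand() * (x1 - ox);
    p.z = oz + unif_rand() * (z1 - oz);
    p.y = oy + 1e-9 * dy;                      // entering front face
    p.ux = 0.0; p.uy = 1.0; p.uz = 0.0;
    p.E = E0;
    p.primary_uncollided = true;
    stack.push_back(p);

    while (!stack.empty()) {
      Photon ph = stack.back();
      stack.pop_back();
      int idx; double frac, lE;
      locate(ph.E, idx, frac, lE);
      double maj = mu_majorant(idx, frac, lE);
      for (;;) {
        if (maj <= 0.0) {                      // vacuum everywhere
          if (ph.primary_uncollided) ++n_uncollided;
          escaped += ph.E;
          break;
        }
        const double s = -std::log(unif_rand()) / maj;
        ph.x += s * ph.ux; ph.y += s * ph.uy; ph.z += s * ph.uz;
        if (ph.x < ox || ph.x >= x1 || ph.y < oy || ph.y >= y1 ||
            ph.z < oz || ph.z >= z1) {
          if (ph.primary_uncollided) ++n_uncollided;
          escaped += ph.E;
          break;
        }
        const int ix = (int)((ph.x - ox) / dx);
        const int iy = (int)((ph.y - oy) / dy);
        const int iz = (int)((ph.z - oz) / dz);
        const int id = organ[(R_xlen_t)iz * nx * ny + (R_xlen_t)iy * nx + ix];
        const int mat = id2mat[id];
        const int reg = id2reg[id];
        if (reg >= 0) {
          const int b = find_bin(edges, ph.E);
          fluence(reg, b) += 1.0 / maj;
          fluence_E(reg, b) += ph.E / maj;
        }
        if (mat < 0) continue;                 // void voxel: virtual always
        const double m_pe = interp_mu(logE, mu_pe, mat, lE, idx, frac);
        const double m_in = interp_mu(logE, mu_inc, mat, lE, idx, frac);
        const double m_pr = interp_mu(logE, mu_pair, mat, lE, idx, frac);
        const double m_tot = m_pe + m_in + m_pr;
        if (unif_rand() * maj > m_tot) continue;   // virtual collision
        ph.primary_uncollided = false;
        const double xi = unif_rand() * m_tot;
        if (xi < m_pe) {
          // photoelectric: full local absorption
          if (reg >= 0) edep[reg] += ph.E; else edep_air += ph.E;
          break;
        } else if (xi < m_pe + m_in) {
          double ep, mu;
          kn_sample_one(ph.E, ep, mu);
          const double dE = ph.E - ep;
          if (reg >= 0) edep[reg] += dE; else edep_air += dE;
          if (ep < cutoff) {
            if (reg >= 0) edep[reg] += ep; else edep_air += ep;
            break;
          }
          ph.E = ep;
          rotate_direction(ph.ux, ph.uy, ph.uz, mu);
          locate(ph.E, idx, frac, lE);
          maj = mu_majorant(idx, frac, lE);
        } else {
          // pair production: local deposit of E - 2 m_e c^2, two
          // annihilation photons emitted back-to-back isotropically
          const double dE = ph.E - 2.0 * MEC2;
          if (reg >= 0) edep[reg] += dE; else edep_air += dE;
          const double mu = 2.0 * unif_rand() - 1.0;
          const double phi = 2.0 * M_PI * unif_rand();
          const double sint = std::sqrt(std::max(0.0, 1.0 - mu * mu));
          Photon q;
          q.x = ph.x; q.y = ph.y; q.z = ph.z;
          q.ux = sint * std::cos(phi);
          q.uy = sint * std::sin(phi);
          q.uz = mu;
          q.E = MEC2;
          q.primary_uncollided = false;
          stack.push_back(q);
          ph.ux = -q.ux; ph.uy = -q.uy; ph.uz = -q.uz;
          ph.E = MEC2;
          locate(ph.E, idx, frac, lE);
          maj = mu_majorant(idx, frac, lE);
        }
      }
    }
  }

  return List::create(_["edep"] = edep,
                      _["edep_untallied"] = edep_air,
                      _["fluence_tracklength"] = fluence,
                      _["fluence_tracklength_E"] = fluence_E,
                      _["escaped"] = escaped,
                      _["injected"] = (double)nhist * E0,
                      _["n_uncollided"] = n_uncollided);
}
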