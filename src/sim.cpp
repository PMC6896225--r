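// Brownian-dynamics core for the toy ring-assembly model.
//
// Force field (all pairwise terms purely repulsive):
//   (a) WCA repulsion between beads of different molecules, cut at the sum
//       of the bead radii (force and potential continuous at the cutoff);
//   (b) harmonic leaflet confinement on lipid head beads, Fz = -k (z - z0);
//   (c) harmonic positional bias on protomer beads toward the reference,
//       F = -k_bias (x - x_ref).
// Units: nm, ps, kJ/mol. Periodic minimum image in x,y only.
//
// Protomers and lipids move as rigid bodies: net force and torque are
// mapped to an in-plane translation plus a rotation about the body's own
// vertical axis; protomer z is frozen, lipid z follows the net z force.
// Randomness is drawn from R's RNG so set.seed() governs determinism.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double SIXTH_ROOT_TWO = 1.122462048309373;

struct PairField {
  const NumericVector &radii;   // per bead; < 0 means inert (analysis site)
  double epsilon;
  double lx, ly;
  PairField(const NumericVector &r, double eps, double lx_, double ly_)
      : radii(r), epsilon(eps), lx(lx_), ly(ly_) {}
};

static inline void minImage(double &dx, double &dy, double lx, double ly) {
  dx -= lx * std::nearbyint(dx / lx);
  dy -= ly * std::nearbyint(dy / ly);
}

// WCA pair energy/force. Returns energy; adds force on i to (fx,fy,fz).
static inline double wcaPair(double dx, double dy, double dz, double rc,
                             double eps, double *f) {
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= rc * rc || r2 <= 1e-14) {
    f[0] = f[1] = f[2] = 0.0;
    return 0.0;
  }
  double sigma = rc / SIXTH_ROOT_TWO;
  double s2 = sigma * sigma / r2;
  double s6 = s2 * s2 * s2;
  double s12 = s6 * s6;
  double e = 4.0 * eps * (s12 - s6) + eps;
  double fmag_over_r = 24.0 * eps * (2.0 * s12 - s6) / r2;
  f[0] = fmag_over_r * dx;
  f[1] = fmag_over_r * dy;
  f[2] = fmag_over_r * dz;
  return e;
}

// Cell-list construction over the periodic x,y box and bounded z range.
struct CellList {
  int ncx, ncy, ncz;
  double zmin;
  double cut;
  std::vector<int> head;
  std::vector<int> next;
  void build(const std::vector<double> &x, const std::vector<double> &y,
             const std::vector<double> &z, int n, double lx, double ly,
             double cutoff) {
    cut = cutoff;
    ncx = std::max(1, (int)std::floor(lx / cutoff));
    ncy = std::max(1, (int)std::floor(ly / cutoff));
    zmin = z[0];
    double zmax = z[0];
    for (int i = 1; i < n; ++i) {
      if (z[i] < zmin) zmin = z[i];
      if (z[i] > zmax) zmax = z[i];
    }
    ncz = std::max(1, (int)std::floor((zmax - zmin) / cutoff) + 1);
    head.assign((size_t)ncx * ncy * ncz, -1);
    next.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor(x[i] / lx * ncx);
      cx = ((cx % ncx) + ncx) % ncx;
      int cy = (int)std::floor(y[i] / ly * ncy);
      cy = ((cy % ncy) + ncy) % ncy;
      int cz = (int)std::floor((z[i] - zmin) / cut);
      if (cz < 0) cz = 0;
      if (cz >= ncz) cz = ncz - 1;
      size_t c = (size_t)(cz * ncy + cy) * ncx + cx;
      next[i] = head[c];
      head[c] = i;
    }
  }
};

// Accumulate all forces; returns total potential energy.
static double allForces(const std::vector<double> &x,
                        const std::vector<double> &y,
                        const std::vector<double> &z, int n,
                        const NumericVector &radii, double eps, double lx,
                        double ly, const IntegerVector &bodyId,
                        const NumericVector &leafletTarget, double leafletK,
                        const std::vector<double> &refx,
                        const std::vector<double> &refy,
                        const std::vector<double> &refz,
                        const std::vector<int> &biasRow, double kBias,
                        double cutoff, CellList &cl, std::vector<double> &fx,
                        std::vector<double> &fy, std::vector<double> &fz) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  double energy = 0.0;
  double f[3];
  int ncxTry = std::max(1, (int)std::floor(lx / cutoff));
  int ncyTry = std::max(1, (int)std::floor(ly / cutoff));
  bool useCells = (ncxTry >= 3 && ncyTry >= 3 && n > 64);
  if (useCells) {
    cl.build(x, y, z, n, lx, ly, cutoff);
    for (int i = 0; i < n; ++i) {
      if (radii[i] < 0) continue;
      int cx = (int)std::floor(x[i] / lx * cl.ncx);
      cx = ((cx % cl.ncx) + cl.ncx) % cl.ncx;
      int cy = (int)std::floor(y[i] / ly * cl.ncy);
      cy = ((cy % cl.ncy) + cl.ncy) % cl.ncy;
      int cz = (int)std::floor((z[i] - cl.zmin) / cl.cut);
      if (cz < 0) cz = 0;
      if (cz >= cl.ncz) cz = cl.ncz - 1;
      for (int dz = -1; dz <= 1; ++dz) {
        int zc = cz + dz;
        if (zc < 0 || zc >= cl.ncz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yc = ((cy + dy) % cl.ncy + cl.ncy) % cl.ncy;
          for (int dxc = -1; dxc <= 1; ++dxc) {
            int xc = ((cx + dxc) % cl.ncx + cl.ncx) % cl.ncx;
            size_t c = (size_t)(zc * cl.ncy + yc) * cl.ncx + xc;
            for (int j = cl.head[c]; j >= 0; j = cl.next[j]) {
              if (j <= i) continue;
              if (radii[j] < 0) continue;
              if (bodyId[i] >= 0 && bodyId[i] == bodyId[j]) continue;
              double ddx = x[i] - x[j], ddy = y[i] - y[j],
                     ddz = z[i] - z[j];
              minImage(ddx, ddy, lx, ly);
              double rc = radii[i] + radii[j];
              energy += wcaPair(ddx, ddy, ddz, rc, eps, f);
              fx[i] += f[0]; fy[i] += f[1]; fz[i] += f[2];
              fx[j] -= f[0]; fy[j] -= f[1]; fz[j] -= f[2];
            }
          }
        }
      }
    }
  } else {
    for (int i = 0; i < n; ++i) {
      if (radii[i] < 0) continue;
      for (int j = i + 1; j < n; ++j) {
        if (radii[j] < 0) continue;
        if (bodyId[i] >= 0 && bodyId[i] == bodyId[j]) continue;
        double ddx = x[i] - x[j], ddy = y[i] - y[j], ddz = z[i] - z[j];
        minImage(ddx, ddy, lx, ly);
        double rc = radii[i] + radii[j];
        energy += wcaPair(ddx, ddy, ddz, rc, eps, f);
        fx[i] += f[0]; fy[i] += f[1]; fz[i] += f[2];
        fx[j] -= f[0]; fy[j] -= f[1]; fz[j] -= f[2];
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    if (leafletK > 0 && !ISNAN(leafletTarget[i])) {
      double dzt = z[i] - leafletTarget[i];
      fz[i] += -leafletK * dzt;
      energy += 0.5 * leafletK * dzt * dzt;
    }
  }
  if (kBias > 0) {
    for (size_t k = 0; k < biasRow.size(); ++k) {
      int i = biasRow[k];
      double ddx = x[i] - refx[k], ddy = y[i] - refy[k],
             ddz = z[i] - refz[k];
      fx[i] += -kBias * ddx;
      fy[i] += -kBias * ddy;
      fz[i] += -kBias * ddz;
      energy += 0.5 * kBias * (ddx * ddx + ddy * ddy + ddz * ddz);
    }
  }
  return energy;
}

struct SimSpec {
  int n;
  std::vector<double> x, y, z;
  std::vector<double> refx, refy, refz;
  std::vector<int> biasRow;
  double lx, ly;
};

static void unpack(const NumericMatrix &coords, const NumericMatrix &ref,
                   const IntegerVector &biasRows, const NumericVector &box,
                   SimSpec &s) {
  s.n = coords.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = coords(i, 0); s.y[i] = coords(i, 1); s.z[i] = coords(i, 2);
  }
  s.biasRow.assign(biasRows.begin(), biasRows.end());
  s.refx.resize(s.biasRow.size());
  s.refy.resize(s.biasRow.size());
  s.refz.resize(s.biasRow.size());
  for (size_t k = 0; k < s.biasRow.size(); ++k) {
    s.refx[k] = ref(k, 0); s.refy[k] = ref(k, 1); s.refz[k] = ref(k, 2);
  }
  s.lx = box[0]; s.ly = box[1];
}

// [[Rcpp::export(name = ".cppForces")]]
NumericMatrix cppForces(NumericMatrix coords, NumericVector radii,
                        double epsilon, NumericVector box,
                        IntegerVector bodyId, NumericVector leafletTarget,
                        double leafletK, NumericMatrix refCoords,
                        IntegerVector biasRows, double kBias,
                        double cutoff) {
  SimSpec s;
  unpack(coords, refCoords, biasRows, box, s);
  std::vector<double> fx(s.n), fy(s.n), fz(s.n);
  CellList cl;
  allForces(s.x, s.y, s.z, s.n, radii, epsilon, s.lx, s.ly, bodyId,
            leafletTarget, leafletK, s.refx, s.refy, s.refz, s.biasRow,
            kBias, cutoff, cl, fx, fy, fz);
  NumericMatrix out(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    out(i, 0) = fx[i]; out(i, 1) = fy[i]; out(i, 2) = fz[i];
  }
  return out;
}

// [[Rcpp::export(name = ".cppPotential")]]
double cppPotential(NumericMatrix coords, NumericVector radii,
                    double epsilon, NumericVector box, IntegerVector bodyId,
                    NumericVector leafletTarget, double leafletK,
                    NumericMatrix refCoords, IntegerVector biasRows,
                    double kBias, double cutoff) {
  SimSpec s;
  unpack(coords, refCoords, biasRows, box, s);
  std::vector<double> fx(s.n), fy(s.n), fz(s.n);
  CellList cl;
  return allForces(s.x, s.y, s.z, s.n, radii, epsilon, s.lx, s.ly, bodyId,
                   leafletTarget, leafletK, s.refx, s.refy, s.refz,
                   s.biasRow, kBias, cutoff, cl, fx, fy, fz);
}

// [[Rcpp::export(name = ".cppRunStage")]]
List cppRunStage(NumericMatrix coords, NumericVector radii, double epsilon,
                 NumericVector box, IntegerVector bodyId,
                 LogicalVector bodyAllowZ, LogicalVector isStatic,
                 NumericVector leafletTarget, double leafletK,
                 NumericMatrix refCoords, IntegerVector biasRows,
                 double kBias, double gamma, double kBT, double dt,
                 int nSteps, int saveEvery, int checkEvery,
                 double rmsdThreshA, double cutoff, double tStart) {
  SimSpec s;
  unpack(coords, refCoords, biasRows, box, s);
  int n = s.n;
  // group beads into bodies
  int nBodies = 0;
  for (int i = 0; i < n; ++i)
    if (bodyId[i] >= nBodies) nBodies = bodyId[i] + 1;
  std::vector<std::vector<int> > bodies(nBodies);
  std::vector<int> freeBeads;
  for (int i = 0; i < n; ++i) {
    if (isStatic[i]) continue;
    if (bodyId[i] >= 0) bodies[bodyId[i]].push_back(i);
    else freeBeads.push_back(i);
  }
  std::vector<double> fx(n), fy(n), fz(n);
  CellList cl;

  auto rmsdNow = [&]() {
    if (s.biasRow.empty()) return 0.0;
    double ss = 0.0;
    for (size_t k = 0; k < s.biasRow.size(); ++k) {
      int i = s.biasRow[k];
      double ddx = s.x[i] - s.refx[k], ddy = s.y[i] - s.refy[k],
             ddz = s.z[i] - s.refz[k];
      ss += ddx * ddx + ddy * ddy + ddz * ddz;
    }
    return 10.0 * std::sqrt(ss / s.biasRow.size());
  };

  std::vector<double> rmsdT, rmsdV;
  std::vector<double> savedT;
  std::vector<double> savedCoords;  // flattened n x 3 per frame
  auto saveFrame = [&](double t) {
    savedT.push_back(t);
    for (int i = 0; i < n; ++i) {
      savedCoords.push_back(s.x[i]);
      savedCoords.push_back(s.y[i]);
      savedCoords.push_back(s.z[i]);
    }
  };

  double r0 = rmsdNow();
  rmsdT.push_back(tStart);
  rmsdV.push_back(r0);
  bool converged = (rmsdThreshA > 0 && r0 < rmsdThreshA);
  int step = 0;
  double noiseFree = std::sqrt(2.0 * kBT * dt / gamma);
  while (!converged && step < nSteps) {
    ++step;
    allForces(s.x, s.y, s.z, n, radii, epsilon, s.lx, s.ly, bodyId,
              leafletTarget, leafletK, s.refx, s.refy, s.refz, s.biasRow,
              kBias, cutoff, cl, fx, fy, fz);
    // rigid bodies
    for (int b = 0; b < nBodies; ++b) {
      const std::vector<int> &bb = bodies[b];
      if (bb.empty()) continue;
      int nb = (int)bb.size();
      double cx = 0, cy = 0, Fx = 0, Fy = 0, Fz = 0, tau = 0;
      for (int k = 0; k < nb; ++k) {
        int i = bb[k];
        cx += s.x[i]; cy += s.y[i];
        Fx += fx[i]; Fy += fy[i]; Fz += fz[i];
      }
      cx /= nb; cy /= nb;
      double I = 0;
      for (int k = 0; k < nb; ++k) {
        int i = bb[k];
        double rx = s.x[i] - cx, ry = s.y[i] - cy;
        tau += rx * fy[i] - ry * fx[i];
        I += rx * rx + ry * ry;
      }
      double gtr = gamma * nb;
      double ntr = std::sqrt(2.0 * kBT * dt / gtr);
      double ddx = Fx / gtr * dt + ntr * norm_rand();
      double ddy = Fy / gtr * dt + ntr * norm_rand();
      double ddz = 0.0;
      if (bodyAllowZ[b]) ddz = Fz / gtr * dt + ntr * norm_rand();
      double dth = 0.0;
      double Ig = gamma * I;
      if (Ig > 1e-12)
        dth = tau / Ig * dt + std::sqrt(2.0 * kBT * dt / Ig) * norm_rand();
      if (!R_finite(ddx) || !R_finite(ddy) || !R_finite(ddz) ||
          !R_finite(dth) || std::fabs(ddx) > 1.0 || std::fabs(ddy) > 1.0 ||
          std::fabs(ddz) > 1.0)
        stop("divergence at step %d: unstable body displacement", step);
      double c1 = std::cos(dth), s1 = std::sin(dth);
      for (int k = 0; k < nb; ++k) {
        int i = bb[k];
        double rx = s.x[i] - cx, ry = s.y[i] - cy;
        s.x[i] = cx + c1 * rx - s1 * ry + ddx;
        s.y[i] = cy + s1 * rx + c1 * ry + ddy;
        s.z[i] += ddz;
      }
      // wrap body centroid into the box, moving the body as a whole
      double ncx2 = cx + ddx, ncy2 = cy + ddy;
      double wx = s.lx * std::floor(ncx2 / s.lx);
      double wy = s.ly * std::floor(ncy2 / s.ly);
      if (wx != 0.0 || wy != 0.0)
        for (int k = 0; k < nb; ++k) {
          s.x[bb[k]] -= wx;
          s.y[bb[k]] -= wy;
        }
    }
    // free beads
    for (size_t k = 0; k < freeBeads.size(); ++k) {
      int i = freeBeads[k];
      double ddx = fx[i] / gamma * dt + noiseFree * norm_rand();
      double ddy = fy[i] / gamma * dt + noiseFree * norm_rand();
      double ddz = fz[i] / gamma * dt + noiseFree * norm_rand();
      if (!R_finite(ddx) || !R_finite(ddy) || !R_finite(ddz) ||
          std::fabs(ddx) > 1.0 || std::fabs(ddy) > 1.0 ||
          std::fabs(ddz) > 1.0)
        stop("divergence at step %d: unstable bead displacement", step);
      double nx2 = s.x[i] + ddx, ny2 = s.y[i] + ddy;
      s.x[i] = nx2 - s.lx * std::floor(nx2 / s.lx);
      s.y[i] = ny2 - s.ly * std::floor(ny2 / s.ly);
      s.z[i] += ddz;
    }
    if (checkEvery > 0 && step % checkEvery == 0) {
      double r = rmsdNow();
      rmsdT.push_back(tStart + step * dt);
      rmsdV.push_back(r);
      if (rmsdThreshA > 0 && r < rmsdThreshA) converged = true;
    }
    if (saveEvery > 0 && step % saveEvery == 0)
      saveFrame(tStart + step * dt);
  }
  // make sure the last configuration is saved
  if (saveEvery > 0 &&
      (savedT.empty() || savedT.back() < tStart + step * dt - 1e-9))
    saveFrame(tStart + step * dt);

  NumericMatrix finalCoords(n, 3);
  for (int i = 0; i < n; ++i) {
    finalCoords(i, 0) = s.x[i];
    finalCoords(i, 1) = s.y[i];
    finalCoords(i, 2) = s.z[i];
  }
  int nf = (int)savedT.size();
  NumericVector frames(savedCoords.size());
  std::copy(savedCoords.begin(), savedCoords.end(), frames.begin());
  return List::create(
      Named("finalCoords") = finalCoords, Named("frames") = frames,
      Named("frameTimes") = NumericVector(savedT.begin(), savedT.end()),
      Named("nFrames") = nf,
      Named("rmsdTimes") = NumericVector(rmsdT.begin(), rmsdT.end()),
      Named("rmsdVals") = NumericVector(rmsdV.begin(), rmsdV.end()),
      Named("stepsDone") = step, Named("converged") = converged);
}
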