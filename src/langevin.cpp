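// Overdamped Langevin integrator for the beads-on-a-string chromatin fiber.
//
// Forces: harmonic bonds between consecutive beads, a (1 - cos theta) bending
// term on interior triplets, a quartic attractive-repulsive pair potential
// between non-consecutive beads (soft core, permits chain crossing), a
// two-branch quartic with a slow long-range tail between centromeric bead
// pairs, optional harmonic extruder bonds and an optional harmonic spherical
// confinement wall.
//
// The position update is the Leimkuhler-Matthews scheme
//   x <- x + dt F / gamma + sqrt(2 kT dt / gamma) (xi_prev + xi_new) / 2
// whose configurational sampling bias is O(dt^2), versus O(dt) for plain
// Euler-Maruyama.  Neighbour lists (Verlet, skin-based) are rebuilt whenever
// accumulated displacement could invalidate them.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>

using namespace Rcpp;

namespace {

struct CenPar {
  double a, b, rmin, s, c, rcut, ucut;
};

struct NnPar {
  double a, b, rmin, xcut;  // potential is 0 beyond xcut
};

// centromeric pair potential, two branches sharing value/slope at rmin,
// held constant beyond rcut
inline double cen_u(const CenPar& p, double x) {
  if (x > p.rcut) return p.ucut;
  double u = (x <= p.rmin) ? x / p.rmin : x / p.s + p.c;
  double u2 = u * u;
  return p.a + p.b * (u2 * u2 - 2.0 * u2);
}

inline double cen_dudx(const CenPar& p, double x) {
  if (x > p.rcut) return 0.0;
  double scale = (x <= p.rmin) ? p.rmin : p.s;
  double u = (x <= p.rmin) ? x / p.rmin : x / p.s + p.c;
  return 4.0 * p.b * u * (u * u - 1.0) / scale;
}

inline double nn_u(const NnPar& p, double x) {
  if (x >= p.xcut) return 0.0;
  double u = x / p.rmin;
  double u2 = u * u;
  return p.a + p.b * (u2 * u2 - 2.0 * u2);
}

inline double nn_dudx(const NnPar& p, double x) {
  if (x >= p.xcut) return 0.0;
  double u = x / p.rmin;
  return 4.0 * p.b * u * (u * u - 1.0) / p.rmin;
}

inline double dist3(const std::vector<double>& x, const std::vector<double>& y,
                    const std::vector<double>& z, int i, int j,
                    double& dx, double& dy, double& dz) {
  dx = x[j] - x[i];
  dy = y[j] - y[i];
  dz = z[j] - z[i];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

}  // namespace

// [[Rcpp::export]]
List cpp_langevin(NumericMatrix pos0, LogicalVector cen, int n_steps,
                  double dt, double gamma, double kT,
                  double bond_k, double bond_x0, double bend_k,
                  NumericVector cen_par, NumericVector nn_par,
                  IntegerMatrix ex_bonds, double confine_R, double wall_k,
                  int seed, int frame_stride, int energy_stride) {
  const int n = pos0.nrow();
  if (pos0.ncol() != 3) stop("positions must be an n x 3 matrix");
  if (n_steps < 0) stop("n_steps must be >= 0");

  CenPar cp;
  cp.a = cen_par[0]; cp.b = cen_par[1]; cp.rmin = cen_par[2];
  cp.s = cen_par[3]; cp.c = cen_par[4]; cp.rcut = cen_par[5];
  {
    double u = cp.rcut / cp.s + cp.c, u2 = u * u;
    cp.ucut = cp.a + cp.b * (u2 * u2 - 2.0 * u2);
  }
  NnPar np;
  np.a = nn_par[0]; np.b = nn_par[1]; np.rmin = nn_par[2]; np.xcut = nn_par[3];

  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
  }
  std::vector<int> cen_idx;
  for (int i = 0; i < n; ++i) if (cen[i]) cen_idx.push_back(i);

  const int n_ex = ex_bonds.nrow();

  // Verlet lists rebuilt via a uniform cell grid when any bead has moved
  // more than half a skin since the last build
  const double skin_nn = 4.0, skin_cc = 6.0;
  const double cut_nn = np.xcut + skin_nn;
  const double cut_cc = cp.rcut + skin_cc;
  const double trigger2 =
      0.25 * std::min(skin_nn, skin_cc) * std::min(skin_nn, skin_cc);
  std::vector<std::pair<int, int> > nn_list, cc_list;
  std::vector<double> rx(n), ry(n), rz(n);  // positions at last build

  // append all index pairs from `idx` closer than `cutoff` to `out`
  // (skipping chain neighbours |i-j| < 2)
  auto grid_pairs = [&](const std::vector<int>& idx, double cutoff,
                        std::vector<std::pair<int, int> >& out,
                        bool skip_cen_cen) {
    const int m = (int)idx.size();
    if (m < 2) return;
    double minx = x[idx[0]], miny = y[idx[0]], minz = z[idx[0]];
    for (int t = 1; t < m; ++t) {
      minx = std::min(minx, x[idx[t]]);
      miny = std::min(miny, y[idx[t]]);
      minz = std::min(minz, z[idx[t]]);
    }
    const double cell = cutoff;
    const double c2 = cutoff * cutoff;
    // bucket beads by cell; candidate pairs come from the 27 neighbouring
    // cells. Cell coordinates are packed collision-free into 64 bits.
    std::unordered_map<long long, std::vector<int> > cells;
    std::unordered_map<long long, std::vector<int> >::iterator it;
    auto ckey = [](long long cx, long long cy, long long cz) {
      return ((cx + (1LL << 20)) << 42) | ((cy + (1LL << 20)) << 21) |
             (cz + (1LL << 20));
    };
    for (int t = 0; t < m; ++t) {
      int i = idx[t];
      long cx = (long)((x[i] - minx) / cell);
      long cy = (long)((y[i] - miny) / cell);
      long cz = (long)((z[i] - minz) / cell);
      cells[ckey(cx, cy, cz)].push_back(i);
    }
    for (int t = 0; t < m; ++t) {
      int i = idx[t];
      long cx = (long)((x[i] - minx) / cell);
      long cy = (long)((y[i] - miny) / cell);
      long cz = (long)((z[i] - minz) / cell);
      for (long ox = -1; ox <= 1; ++ox)
        for (long oy = -1; oy <= 1; ++oy)
          for (long oz = -1; oz <= 1; ++oz) {
            it = cells.find(ckey(cx + ox, cy + oy, cz + oz));
            if (it == cells.end()) continue;
            for (int j : it->second) {
              if (j <= i) continue;
              if (j - i < 2) continue;
              if (skip_cen_cen && cen[i] && cen[j]) continue;
              double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
              if (dx * dx + dy * dy + dz * dz < c2)
                out.push_back({i, j});
            }
          }
    }
  };

  std::vector<int> all_idx(n);
  for (int i = 0; i < n; ++i) all_idx[i] = i;
  auto rebuild = [&]() {
    nn_list.clear();
    cc_list.clear();
    grid_pairs(all_idx, cut_nn, nn_list, true);
    grid_pairs(cen_idx, cut_cc, cc_list, false);
    rx = x; ry = y; rz = z;
  };
  rebuild();

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::vector<double> gx(n, 0.0), gy(n, 0.0), gz(n, 0.0);  // previous noise
  const bool thermal = kT > 0.0;
  if (thermal) {
    for (int i = 0; i < n; ++i) {
      gx[i] = gauss(rng); gy[i] = gauss(rng); gz[i] = gauss(rng);
    }
  }
  const double mob = dt / gamma;
  const double sig = thermal ? std::sqrt(2.0 * kT * dt / gamma) : 0.0;

  std::vector<double> fx(n), fy(n), fz(n);

  // potential energy over current lists; centromeric pairs use the
  // cutoff-shifted form so that far pairs contribute 0 to the trace
  auto energy = [&]() {
    double e = 0.0;
    for (int i = 0; i + 1 < n; ++i) {
      double dx, dy, dz;
      double r = dist3(x, y, z, i, i + 1, dx, dy, dz);
      double d = r - bond_x0;
      e += 0.5 * bond_k * d * d;
    }
    for (int i = 1; i + 1 < n; ++i) {
      double ax = x[i] - x[i - 1], ay = y[i] - y[i - 1], az = z[i] - z[i - 1];
      double bx = x[i + 1] - x[i], by = y[i + 1] - y[i], bz = z[i + 1] - z[i];
      double la = std::sqrt(ax * ax + ay * ay + az * az);
      double lb = std::sqrt(bx * bx + by * by + bz * bz);
      if (la < 1e-12 || lb < 1e-12) continue;
      double ct = (ax * bx + ay * by + az * bz) / (la * lb);
      e += bend_k * (1.0 - ct);
    }
    for (auto& pr : nn_list) {
      double dx, dy, dz;
      double r = dist3(x, y, z, pr.first, pr.second, dx, dy, dz);
      e += nn_u(np, r);
    }
    for (auto& pr : cc_list) {
      double dx, dy, dz;
      double r = dist3(x, y, z, pr.first, pr.second, dx, dy, dz);
      double u = cen_u(cp, r);
      e += (r < cp.rcut) ? (u - cp.ucut) : 0.0;
    }
    for (int b = 0; b < n_ex; ++b) {
      int i = ex_bonds(b, 0), j = ex_bonds(b, 1);
      double dx, dy, dz;
      double r = dist3(x, y, z, i, j, dx, dy, dz);
      double d = r - bond_x0;
      e += 0.5 * bond_k * d * d;
    }
    if (confine_R > 0.0) {
      for (int i = 0; i < n; ++i) {
        double r = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
        if (r > confine_R) {
          double d = r - confine_R;
          e += 0.5 * wall_k * d * d;
        }
      }
    }
    return e;
  };

  std::vector<double> frames;
  std::vector<int> frame_steps;
  std::vector<double> e_trace;
  std::vector<int> e_steps;
  std::vector<double> maxbond_trace;
  auto max_bond = [&]() {
    double m = 0.0;
    for (int i = 0; i + 1 < n; ++i) {
      double dx, dy, dz;
      double r = dist3(x, y, z, i, i + 1, dx, dy, dz);
      if (r > m) m = r;
    }
    return m;
  };
  auto record_frame = [&](int step) {
    for (int i = 0; i < n; ++i) frames.push_back(x[i]);
    for (int i = 0; i < n; ++i) frames.push_back(y[i]);
    for (int i = 0; i < n; ++i) frames.push_back(z[i]);
    frame_steps.push_back(step);
  };
  auto record_energy = [&](int step) {
    e_trace.push_back(energy());
    e_steps.push_back(step);
    maxbond_trace.push_back(max_bond());
  };
  if (frame_stride > 0) record_frame(0);
  if (energy_stride > 0) record_energy(0);

  for (int step = 1; step <= n_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);

    // bonds
    for (int i = 0; i + 1 < n; ++i) {
      double dx, dy, dz;
      double r = dist3(x, y, z, i, i + 1, dx, dy, dz);
      if (r < 1e-12) continue;
      double f = bond_k * (r - bond_x0) / r;
      fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
      fx[i + 1] -= f * dx; fy[i + 1] -= f * dy; fz[i + 1] -= f * dz;
    }
    // bending
    if (bend_k != 0.0) {
      for (int i = 1; i + 1 < n; ++i) {
        double ax = x[i] - x[i - 1], ay = y[i] - y[i - 1], az = z[i] - z[i - 1];
        double bx = x[i + 1] - x[i], by = y[i + 1] - y[i], bz = z[i + 1] - z[i];
        double la = std::sqrt(ax * ax + ay * ay + az * az);
        double lb = std::sqrt(bx * bx + by * by + bz * bz);
        if (la < 1e-12 || lb < 1e-12) continue;
        double inv = 1.0 / (la * lb);
        double ct = (ax * bx + ay * by + az * bz) * inv;
        // grad of cos(theta) wrt bond vectors
        double gax = (bx / lb - ct * ax / la) / la;
        double gay = (by / lb - ct * ay / la) / la;
        double gaz = (bz / lb - ct * az / la) / la;
        double gbx = (ax / la - ct * bx / lb) / lb;
        double gby = (ay / la - ct * by / lb) / lb;
        double gbz = (az / la - ct * bz / lb) / lb;
        // F_j = -dU/dr_j = bend_k * d(cos)/dr_j
        fx[i - 1] -= bend_k * gax; fy[i - 1] -= bend_k * gay; fz[i - 1] -= bend_k * gaz;
        fx[i + 1] += bend_k * gbx; fy[i + 1] += bend_k * gby; fz[i + 1] += bend_k * gbz;
        fx[i] += bend_k * (gax - gbx);
        fy[i] += bend_k * (gay - gby);
        fz[i] += bend_k * (gaz - gbz);
      }
    }
    // generic non-consecutive pairs
    for (auto& pr : nn_list) {
      int i = pr.first, j = pr.second;
      double dx, dy, dz;
      double r = dist3(x, y, z, i, j, dx, dy, dz);
      if (r < 1e-12 || r >= np.xcut) continue;
      double f = nn_dudx(np, r) / r;  // force on j is -dU/dx * unit vec (j-i)
      fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
      fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
    }
    // centromeric pairs
    for (auto& pr : cc_list) {
      int i = pr.first, j = pr.second;
      double dx, dy, dz;
      double r = dist3(x, y, z, i, j, dx, dy, dz);
      if (r < 1e-12 || r > cp.rcut) continue;
      double f = cen_dudx(cp, r) / r;
      fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
      fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
    }
    // extruder bonds
    for (int b = 0; b < n_ex; ++b) {
      int i = ex_bonds(b, 0), j = ex_bonds(b, 1);
      double dx, dy, dz;
      double r = dist3(x, y, z, i, j, dx, dy, dz);
      if (r < 1e-12) continue;
      double f = bond_k * (r - bond_x0) / r;
      fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
      fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
    }
    // spherical confinement
    if (confine_R > 0.0) {
      for (int i = 0; i < n; ++i) {
        double r = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
        if (r > confine_R && r > 1e-12) {
          double f = -wall_k * (r - confine_R) / r;
          fx[i] += f * x[i]; fy[i] += f * y[i]; fz[i] += f * z[i];
        }
      }
    }

    // Leimkuhler-Matthews update
    double max_d2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double nx = 0.0, ny = 0.0, nz = 0.0;
      if (thermal) {
        double hx = gauss(rng), hy = gauss(rng), hz = gauss(rng);
        nx = 0.5 * (gx[i] + hx); ny = 0.5 * (gy[i] + hy); nz = 0.5 * (gz[i] + hz);
        gx[i] = hx; gy[i] = hy; gz[i] = hz;
      }
      x[i] += mob * fx[i] + sig * nx;
      y[i] += mob * fy[i] + sig * ny;
      z[i] += mob * fz[i] + sig * nz;
      double ex = x[i] - rx[i], ey = y[i] - ry[i], ez = z[i] - rz[i];
      double d2 = ex * ex + ey * ey + ez * ez;
      if (d2 > max_d2) max_d2 = d2;
    }
    if (max_d2 > trigger2) rebuild();

    if (frame_stride > 0 && (step % frame_stride == 0 || step == n_steps))
      record_frame(step);
    if (energy_stride > 0 && (step % energy_stride == 0 || step == n_steps)) {
      record_energy(step);
      if (!std::isfinite(x[0]) || !std::isfinite(e_trace.back()))
        stop("non-finite coordinates or energy at step %d; reduce the timestep",
             step);
    }
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i];
    if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
      stop("non-finite coordinate for bead %d after integration", i + 1);
  }

  List res = List::create(
      _["positions"] = out,
      _["energy"] = NumericVector(e_trace.begin(), e_trace.end()),
      _["energy_steps"] = IntegerVector(e_steps.begin(), e_steps.end()),
      _["max_bond"] = NumericVector(maxbond_trace.begin(), maxbond_trace.end()));
  if (frame_stride > 0) {
    NumericVector fr(frames.begin(), frames.end());
    fr.attr("dim") =
        IntegerVector::create(n, 3, (int)frame_steps.size());
    res["frames"] = fr;
    res["frame_steps"] = IntegerVector(frame_steps.begin(), frame_steps.end());
  }
  return res;
}
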