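// Coarse-grained neurofilament side-arm brush: canonical-ensemble Metropolis
// Monte Carlo with hard-core beads, Debye-Hueckel screened electrostatics and
// hard backbone cylinders. Coordinates are stored unwrapped (arms never jump
// across the periodic box internally); all pair distances use the minimum
// image convention in x, y (period box_xy) and z (period box_z).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

struct Params {
  double Lxy, Lz;          // periodic box lengths (x = y = Lxy)
  double cutoff;           // electrostatic cutoff (nm)
  double diameter;         // bead hard-core diameter (nm)
  double bond;             // bond length (nm)
  double bjerrum;          // Bjerrum length (nm)
  double kappa;            // inverse Debye length (1/nm)
  bool hard_core;          // excluded volume on/off
  bool backbone_on;        // backbone cylinder exclusion on/off
  double backbone_excl;    // min allowed axis distance for bead centres (nm)
  std::vector<double> bbx, bby;  // backbone axis positions in the xy plane
};

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

inline double pair_potential(double r, double zi, double zj, const Params& P) {
  if (P.hard_core && r < P.diameter) return std::numeric_limits<double>::infinity();
  if (zi == 0.0 || zj == 0.0 || r > P.cutoff) return 0.0;
  return P.bjerrum * zi * zj * std::exp(-P.kappa * r) / r;
}

// squared minimum-image distance
inline double dist2(double xi, double yi, double zi,
                    double xj, double yj, double zj, const Params& P) {
  double dx = min_image(xi - xj, P.Lxy);
  double dy = min_image(yi - yj, P.Lxy);
  double dz = min_image(zi - zj, P.Lz);
  return dx * dx + dy * dy + dz * dz;
}

// hard-cylinder term for one bead centre (xy minimum image to each axis)
inline double backbone_energy(double x, double y, const Params& P) {
  if (!P.backbone_on) return 0.0;
  for (size_t b = 0; b < P.bbx.size(); ++b) {
    double dx = min_image(x - P.bbx[b], P.Lxy);
    double dy = min_image(y - P.bby[b], P.Lxy);
    if (std::sqrt(dx * dx + dy * dy) < P.backbone_excl - 1e-9)
      return std::numeric_limits<double>::infinity();
  }
  return 0.0;
}

struct CellList {
  bool active = false;
  int nx = 0, ny = 0, nz = 0;
  double csx = 0, csy = 0, csz = 0;
  std::vector<std::vector<int>> cells;
  std::vector<int> cell_of;   // cell index per bead
  const Params* P = nullptr;

  void init(const Params& par, int nbeads) {
    P = &par;
    double reach = std::max(par.cutoff, par.diameter);
    nx = static_cast<int>(std::floor(par.Lxy / reach));
    ny = nx;
    nz = static_cast<int>(std::floor(par.Lz / reach));
    active = (nx >= 4 && nz >= 4);
    if (!active) return;
    csx = par.Lxy / nx; csy = par.Lxy / ny; csz = par.Lz / nz;
    cells.assign(static_cast<size_t>(nx) * ny * nz, {});
    cell_of.assign(nbeads, -1);
  }
  inline int wrap_idx(double v, double L, double cs, int n) const {
    double w = v - L * std::floor(v / L);
    int i = static_cast<int>(w / cs);
    if (i >= n) i = n - 1;
    if (i < 0) i = 0;
    return i;
  }
  inline int cell_index(double x, double y, double z) const {
    int ix = wrap_idx(x, P->Lxy, csx, nx);
    int iy = wrap_idx(y, P->Lxy, csy, ny);
    int iz = wrap_idx(z, P->Lz, csz, nz);
    return (ix * ny + iy) * nz + iz;
  }
  void insert(int b, double x, double y, double z) {
    if (!active) return;
    int c = cell_index(x, y, z);
    cells[c].push_back(b);
    cell_of[b] = c;
  }
  void move(int b, double x, double y, double z) {
    if (!active) return;
    int c = cell_index(x, y, z);
    if (c == cell_of[b]) return;
    auto& old = cells[cell_of[b]];
    for (size_t k = 0; k < old.size(); ++k) {
      if (old[k] == b) { old[k] = old.back(); old.pop_back(); break; }
    }
    cells[c].push_back(b);
    cell_of[b] = c;
  }
  // visit neighbours of position (27-cell stencil), calling f(bead)
  template <typename F>
  void for_neighbours(double x, double y, double z, F f) const {
    int ix = wrap_idx(x, P->Lxy, csx, nx);
    int iy = wrap_idx(y, P->Lxy, csy, ny);
    int iz = wrap_idx(z, P->Lz, csz, nz);
    for (int dx = -1; dx <= 1; ++dx) {
      int jx = (ix + dx + nx) % nx;
      for (int dy = -1; dy <= 1; ++dy) {
        int jy = (iy + dy + ny) % ny;
        for (int dz = -1; dz <= 1; ++dz) {
          int jz = (iz + dz + nz) % nz;
          const auto& cc = cells[(static_cast<size_t>(jx) * ny + jy) * nz + jz];
          for (int b : cc) f(b);
        }
      }
    }
  }
};

struct System {
  int n;
  std::vector<double> x, y, z, q;
  std::vector<int> arm, bidx, armlen;
  Params P;
  CellList cl;

  void load(const NumericMatrix& coords, const IntegerVector& arm_id,
            const IntegerVector& bead_idx, const NumericVector& charge,
            const List& params) {
    n = coords.nrow();
    x.resize(n); y.resize(n); z.resize(n); q.resize(n);
    arm.resize(n); bidx.resize(n);
    for (int i = 0; i < n; ++i) {
      x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
      q[i] = charge[i]; arm[i] = arm_id[i]; bidx[i] = bead_idx[i];
    }
    int narm = arm.empty() ? 0 : (*std::max_element(arm.begin(), arm.end()) + 1);
    armlen.assign(narm, 0);
    for (int i = 0; i < n; ++i) armlen[arm[i]]++;
    P.Lxy = as<double>(params["box_xy"]);
    P.Lz = as<double>(params["box_z"]);
    P.cutoff = as<double>(params["cutoff"]);
    P.diameter = as<double>(params["bead_diameter"]);
    P.bond = as<double>(params["bond_length"]);
    P.bjerrum = as<double>(params["bjerrum_length"]);
    P.kappa = as<double>(params["kappa"]);
    P.hard_core = as<bool>(params["excluded_volume"]);
    P.backbone_on = as<bool>(params["backbone_on"]);
    P.backbone_excl = as<double>(params["backbone_excl"]);
    NumericMatrix bb = params["backbone_xy"];
    for (int b = 0; b < bb.nrow(); ++b) {
      P.bbx.push_back(bb(b, 0));
      P.bby.push_back(bb(b, 1));
    }
    cl.init(P, n);
    if (cl.active) for (int i = 0; i < n; ++i) cl.insert(i, x[i], y[i], z[i]);
  }

  inline bool bonded(int i, int j) const {
    return arm[i] == arm[j] && std::abs(bidx[i] - bidx[j]) == 1;
  }

  // non-bonded pair + backbone energy of bead b at a trial position
  double local_energy(int b, double px, double py, double pz) const {
    double e = backbone_energy(px, py, P);
    if (!std::isfinite(e)) return e;
    const double reach = std::max(P.cutoff, P.diameter);
    const double reach2 = reach * reach;
    const double cut2 = P.cutoff * P.cutoff;
    const double d2 = P.diameter * P.diameter;
    const double qb = q[b];
    auto add = [&](int j) {
      if (j == b || bonded(b, j)) return;
      double r2 = dist2(px, py, pz, x[j], y[j], z[j], P);
      if (r2 >= reach2) return;
      if (P.hard_core && r2 < d2) {
        e = std::numeric_limits<double>::infinity();
        return;
      }
      double qq = qb * q[j];
      if (qq != 0.0 && r2 <= cut2) {
        double r = std::sqrt(r2);
        e += P.bjerrum * qq * std::exp(-P.kappa * r) / r;
      }
    };
    if (cl.active) {
      cl.for_neighbours(px, py, pz, add);
    } else {
      for (int j = 0; j < n; ++j) add(j);
    }
    return e;
  }

  double total_energy() const {
    double e = 0.0;
    for (int i = 0; i < n; ++i) {
      e += backbone_energy(x[i], y[i], P);
      if (!std::isfinite(e)) return e;
    }
    double reach2 = std::pow(std::max(P.cutoff, P.diameter), 2);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (bonded(i, j)) continue;
        double r2 = dist2(x[i], y[i], z[i], x[j], y[j], z[j], P);
        if (r2 > reach2) continue;
        e += pair_potential(std::sqrt(r2), q[i], q[j], P);
        if (!std::isfinite(e)) return e;
      }
    }
    return e;
  }
};

inline void rand_unit(double& ux, double& uy, double& uz) {
  double s = 2.0, v1 = 0.0, v2 = 0.0;
  while (s >= 1.0 || s == 0.0) {
    v1 = 2.0 * unif_rand() - 1.0;
    v2 = 2.0 * unif_rand() - 1.0;
    s = v1 * v1 + v2 * v2;
  }
  double root = 2.0 * std::sqrt(1.0 - s);
  ux = v1 * root; uy = v2 * root; uz = 1.0 - 2.0 * s;
}

} // namespace

// [[Rcpp::export(name = ".total_energy_cpp")]]
double total_energy_cpp(NumericMatrix coords, IntegerVector arm_id,
                        IntegerVector bead_idx, NumericVector charge,
                        List params) {
  System S;
  S.load(coords, arm_id, bead_idx, charge, params);
  return S.total_energy();
}

// One attempted single-bead move per mobile bead per sweep: crankshaft about
// the axis through the flanking beads for interior beads, uniform sphere
// re-orientation for terminal beads. First bead of every arm stays fixed.
// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(NumericMatrix coords, IntegerVector arm_id,
                IntegerVector bead_idx, NumericVector charge,
                List params, int sweeps, int sample_every) {
  System S;
  S.load(coords, arm_id, bead_idx, charge, params);
  RNGScope rng;

  double E = S.total_energy();
  if (!std::isfinite(E)) stop("initial configuration contains an overlap");

  int narm = static_cast<int>(S.armlen.size());
  std::vector<int> arm_first(narm, 0);
  for (int a = 1; a < narm; ++a) arm_first[a] = arm_first[a - 1] + S.armlen[a - 1];

  long long attempted = 0, accepted = 0;
  std::vector<double> rg_samples, e_samples;
  std::vector<int> sample_sweep;
  int nsamp = 0;

  auto record = [&](int sweep) {
    for (int a = 0; a < narm; ++a) {
      int off = arm_first[a], len = S.armlen[a];
      double cx = 0, cy = 0, cz = 0;
      for (int k = 0; k < len; ++k) { cx += S.x[off + k]; cy += S.y[off + k]; cz += S.z[off + k]; }
      cx /= len; cy /= len; cz /= len;
      double s2 = 0;
      for (int k = 0; k < len; ++k) {
        double dx = S.x[off + k] - cx, dy = S.y[off + k] - cy, dz = S.z[off + k] - cz;
        s2 += dx * dx + dy * dy + dz * dz;
      }
      rg_samples.push_back(std::sqrt(s2 / len));
    }
    e_samples.push_back(E);
    sample_sweep.push_back(sweep);
    ++nsamp;
  };

  for (int sweep = 1; sweep <= sweeps; ++sweep) {
    for (int b = 0; b < S.n; ++b) {
      if (S.bidx[b] == 0) continue;  // grafted first bead: never moved
      ++attempted;
      double nx0, ny0, nz0;
      bool terminal = (S.bidx[b] == S.armlen[S.arm[b]] - 1);
      int prev = b - 1;
      if (terminal) {
        double ux, uy, uz;
        rand_unit(ux, uy, uz);
        nx0 = S.x[prev] + S.P.bond * ux;
        ny0 = S.y[prev] + S.P.bond * uy;
        nz0 = S.z[prev] + S.P.bond * uz;
      } else {
        int next = b + 1;
        double ax = S.x[next] - S.x[prev], ay = S.y[next] - S.y[prev],
               az = S.z[next] - S.z[prev];
        double alen = std::sqrt(ax * ax + ay * ay + az * az);
        if (alen < 1e-9) {
          // flanking beads coincide: any point on the sphere keeps both bonds
          double ux, uy, uz;
          rand_unit(ux, uy, uz);
          nx0 = S.x[prev] + S.P.bond * ux;
          ny0 = S.y[prev] + S.P.bond * uy;
          nz0 = S.z[prev] + S.P.bond * uz;
        } else {
          ax /= alen; ay /= alen; az /= alen;
          double theta = (2.0 * unif_rand() - 1.0) * M_PI;
          double ct = std::cos(theta), st = std::sin(theta);
          double vx = S.x[b] - S.x[prev], vy = S.y[b] - S.y[prev],
                 vz = S.z[b] - S.z[prev];
          double dot = ax * vx + ay * vy + az * vz;
          double cx2 = ay * vz - az * vy, cy2 = az * vx - ax * vz,
                 cz2 = ax * vy - ay * vx;
          nx0 = S.x[prev] + vx * ct + cx2 * st + ax * dot * (1 - ct);
          ny0 = S.y[prev] + vy * ct + cy2 * st + ay * dot * (1 - ct);
          nz0 = S.z[prev] + vz * ct + cz2 * st + az * dot * (1 - ct);
        }
      }
      double e_new = S.local_energy(b, nx0, ny0, nz0);
      if (!std::isfinite(e_new)) continue;  // overlap: reject
      double e_old = S.local_energy(b, S.x[b], S.y[b], S.z[b]);
      double dE = e_new - e_old;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
        S.x[b] = nx0; S.y[b] = ny0; S.z[b] = nz0;
        S.cl.move(b, nx0, ny0, nz0);
        E += dE;
        ++accepted;
      }
    }
    if (sample_every > 0 && sweep % sample_every == 0) record(sweep);
  }

  NumericMatrix out(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    out(i, 0) = S.x[i]; out(i, 1) = S.y[i]; out(i, 2) = S.z[i];
  }
  NumericMatrix rg(nsamp, narm);
  for (int s = 0; s < nsamp; ++s)
    for (int a = 0; a < narm; ++a)
      rg(s, a) = rg_samples[static_cast<size_t>(s) * narm + a];

  return List::create(
    _["coords"] = out,
    _["energy"] = E,
    _["rg"] = rg,
    _["energy_samples"] = NumericVector(e_samples.begin(), e_samples.end()),
    _["sample_sweeps"] = IntegerVector(sample_sweep.begin(), sample_sweep.end()),
    _["attempted"] = static_cast<double>(attempted),
    _["accepted"] = static_cast<double>(accepted));
}

// Grow initial arm conformations as outward-biased self-avoiding walks from
// fixed anchor beads on the backbone surface.
// [[Rcpp::export(name = ".build_arms_cpp")]]
NumericMatrix build_arms_cpp(NumericMatrix anchors, NumericMatrix outward,
                             IntegerVector arm_len, List params,
                             int max_tries) {
  int narm = anchors.nrow();
  int n = 0;
  for (int a = 0; a < narm; ++a) n += arm_len[a];
  std::vector<double> X(n), Y(n), Z(n);
  Params P;
  P.Lxy = as<double>(params["box_xy"]);
  P.Lz = as<double>(params["box_z"]);
  P.cutoff = as<double>(params["cutoff"]);
  P.diameter = as<double>(params["bead_diameter"]);
  P.bond = as<double>(params["bond_length"]);
  P.bjerrum = 0.0; P.kappa = 1.0;
  P.hard_core = as<bool>(params["excluded_volume"]);
  P.backbone_on = as<bool>(params["backbone_on"]);
  P.backbone_excl = as<double>(params["backbone_excl"]);
  NumericMatrix bb = params["backbone_xy"];
  for (int b = 0; b < bb.nrow(); ++b) {
    P.bbx.push_back(bb(b, 0)); P.bby.push_back(bb(b, 1));
  }
  RNGScope rng;

  double d2min = P.diameter * P.diameter;
  std::vector<int> offset(narm, 0);
  for (int a = 1; a < narm; ++a) offset[a] = offset[a - 1] + arm_len[a - 1];
  // commit every anchor bead up front so growing arms avoid all graft sites
  std::vector<int> committed;
  committed.reserve(n);
  for (int a = 0; a < narm; ++a) {
    X[offset[a]] = anchors(a, 0);
    Y[offset[a]] = anchors(a, 1);
    Z[offset[a]] = anchors(a, 2);
    committed.push_back(offset[a]);
  }

  for (int a = 0; a < narm; ++a) {
    int len = arm_len[a], off = offset[a];
    double ox = outward(a, 0), oy = outward(a, 1), oz = outward(a, 2);
    int k = 1, stuck = 0;
    while (k < len) {
      bool ok = false;
      for (int t = 0; t < max_tries; ++t) {
        double gx = norm_rand(), gy = norm_rand(), gz = norm_rand();
        // strong outward bias only while escaping the backbone surface;
        // afterwards grow as a nearly free self-avoiding walk so the
        // starting conformations sit close to coil dimensions
        double w = (k <= 8) ? 1.0 : 0.15;
        double dx = w * ox + gx, dy = w * oy + gy, dz = w * oz + gz;
        double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (dn < 1e-12) continue;
        double px = X[off + k - 1] + P.bond * dx / dn;
        double py = Y[off + k - 1] + P.bond * dy / dn;
        double pz = Z[off + k - 1] + P.bond * dz / dn;
        bool free_ = std::isfinite(backbone_energy(px, py, P));
        if (free_ && P.hard_core) {
          for (int j : committed) {
            if (j == off + k - 1) continue;  // bonded predecessor
            if (dist2(px, py, pz, X[j], Y[j], Z[j], P) < d2min) { free_ = false; break; }
          }
        }
        if (free_) {
          X[off + k] = px; Y[off + k] = py; Z[off + k] = pz;
          committed.push_back(off + k);
          ok = true;
          break;
        }
      }
      if (ok) {
        ++k;
      } else {
        int drop = std::min(5, k - 1);
        k -= drop;
        committed.resize(committed.size() - drop);
        if (++stuck > 500) stop("could not grow side-arm %d without overlap", a + 1);
      }
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = X[i]; out(i, 1) = Y[i]; out(i, 2) = Z[i]; }
  return out;
}
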