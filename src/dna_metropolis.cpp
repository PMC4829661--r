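// Random-loop bead-spring model of nuclear chromatin sampled with the
// Metropolis algorithm.  Beads live inside an oblate ellipsoid (the
// nucleus) and outside two spherical nucleoli.  Four potential terms:
//   chain    harmonic springs between consecutive beads, spring constant
//            by chromatin class (softer of the two bead classes),
//   loops    harmonic springs between randomly linked non-adjacent beads,
//   repel    gravity-like repulsion between chromosome centres weighted
//            by bead counts, to keep chromosome territories apart,
//   periph   softened 1/(d + r_soft) attraction of facultative
//            heterochromatin to the nearest of nuclear envelope and
//            nucleolar surfaces; same form with reversed sign and lower
//            strength pushes constitutive heterochromatin inwards.
//
// Units: positions in micrometres; energies in units of kT at 290 K.
// Chain/loop spring constants are per nm^2, the repulsion constant per
// nm, periphery strengths per um (see the methods vignette).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>

using namespace Rcpp;

namespace {

const double NM_PER_UM2 = 1e6;  // (1000 nm/um)^2, for kappa per nm^2
const double NM_PER_UM = 1e3;

struct Geometry {
  double rx, ry, rz;
  std::vector<double> ncx, ncy, ncz;  // nucleolus centres
  double nrad;

  bool inside(double x, double y, double z) const {
    double m2 = (x / rx) * (x / rx) + (y / ry) * (y / ry)
      + (z / rz) * (z / rz);
    if (m2 > 1.0) return false;
    for (size_t k = 0; k < ncx.size(); ++k) {
      double dx = x - ncx[k], dy = y - ncy[k], dz = z - ncz[k];
      if (dx * dx + dy * dy + dz * dz < nrad * nrad) return false;
    }
    return true;
  }

  // distance (um) to the nearest of the nuclear envelope and the
  // nucleolar surfaces; envelope distance along the radial ray
  double boundary_distance(double x, double y, double z) const {
    double m = std::sqrt((x / rx) * (x / rx) + (y / ry) * (y / ry)
                         + (z / rz) * (z / rz));
    double d;
    if (m < 1e-12) {
      d = std::min(rx, std::min(ry, rz));
    } else {
      double norm = std::sqrt(x * x + y * y + z * z);
      double rdir = norm / m;  // centre-to-surface radius along the ray
      d = rdir * (1.0 - m);
    }
    for (size_t k = 0; k < ncx.size(); ++k) {
      double dx = x - ncx[k], dy = y - ncy[k], dz = z - ncz[k];
      double dn = std::sqrt(dx * dx + dy * dy + dz * dz) - nrad;
      if (dn < d) d = dn;
    }
    return d > 0.0 ? d : 0.0;
  }
};

struct Model {
  int n;
  std::vector<double> x, y, z;
  std::vector<int> chrom, cls;
  // chain bonds
  std::vector<int> b1, b2;
  std::vector<double> bk;
  // loops
  std::vector<int> l1, l2;
  double kl;
  // adjacency: bonds and loops touching each bead
  std::vector<std::vector<int> > bead_bonds, bead_loops;
  // chromosomes
  int n_chrom;
  std::vector<double> csx, csy, csz;  // coordinate sums per chromosome
  std::vector<double> W;              // bead counts
  double krep;
  // periphery
  double kfac, kcon, rsoft;
  Geometry geo;

  double bond_energy(int b) const {
    double dx = x[b1[b]] - x[b2[b]];
    double dy = y[b1[b]] - y[b2[b]];
    double dz = z[b1[b]] - z[b2[b]];
    return 0.5 * bk[b] * NM_PER_UM2 * (dx * dx + dy * dy + dz * dz);
  }
  double loop_energy(int l) const {
    double dx = x[l1[l]] - x[l2[l]];
    double dy = y[l1[l]] - y[l2[l]];
    double dz = z[l1[l]] - z[l2[l]];
    return 0.5 * kl * NM_PER_UM2 * (dx * dx + dy * dy + dz * dz);
  }
  double peri_energy_at(int cls_i, double px, double py, double pz) const {
    if (cls_i == 1 && kfac != 0.0) {
      return -kfac / (geo.boundary_distance(px, py, pz) + rsoft);
    }
    if (cls_i == 2 && kcon != 0.0) {
      return kcon / (geo.boundary_distance(px, py, pz) + rsoft);
    }
    return 0.0;
  }
  // repulsion sum of chromosome m against all others, given its centre
  double rep_of_chrom(int m, double cx, double cy, double cz) const {
    if (krep == 0.0 || n_chrom < 2) return 0.0;
    double u = 0.0;
    for (int c = 0; c < n_chrom; ++c) {
      if (c == m) continue;
      double dx = cx - csx[c] / W[c];
      double dy = cy - csy[c] / W[c];
      double dz = cz - csz[c] / W[c];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      u += krep * W[m] * W[c] / (NM_PER_UM * d + 1.0);
    }
    return u;
  }

  double chain_total() const {
    double u = 0.0;
    for (size_t b = 0; b < b1.size(); ++b) u += bond_energy((int)b);
    return u;
  }
  double loop_total() const {
    double u = 0.0;
    for (size_t l = 0; l < l1.size(); ++l) u += loop_energy((int)l);
    return u;
  }
  double rep_total() const {
    if (krep == 0.0 || n_chrom < 2) return 0.0;
    double u = 0.0;
    for (int m = 0; m < n_chrom; ++m) {
      for (int c = m + 1; c < n_chrom; ++c) {
        double dx = csx[m] / W[m] - csx[c] / W[c];
        double dy = csy[m] / W[m] - csy[c] / W[c];
        double dz = csz[m] / W[m] - csz[c] / W[c];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        u += krep * W[m] * W[c] / (NM_PER_UM * d + 1.0);
      }
    }
    return u;
  }
  double peri_total() const {
    double u = 0.0;
    for (int i = 0; i < n; ++i) u += peri_energy_at(cls[i], x[i], y[i], z[i]);
    return u;
  }
};

Model build_model(NumericMatrix pos, IntegerVector bead_chrom,
                  IntegerVector bead_class, NumericVector kappa_class,
                  IntegerMatrix loops, double kappa_loop, double kappa_rep,
                  double kappa_fac, double kappa_con, double r_soft,
                  NumericVector semi, NumericMatrix nucleoli,
                  double nucleolus_radius) {
  Model m;
  m.n = pos.nrow();
  m.x.resize(m.n); m.y.resize(m.n); m.z.resize(m.n);
  m.chrom.resize(m.n); m.cls.resize(m.n);
  int nc = 0;
  for (int i = 0; i < m.n; ++i) {
    m.x[i] = pos(i, 0); m.y[i] = pos(i, 1); m.z[i] = pos(i, 2);
    m.chrom[i] = bead_chrom[i];
    m.cls[i] = bead_class[i];
    if (m.chrom[i] + 1 > nc) nc = m.chrom[i] + 1;
  }
  m.n_chrom = nc;
  m.csx.assign(nc, 0.0); m.csy.assign(nc, 0.0); m.csz.assign(nc, 0.0);
  m.W.assign(nc, 0.0);
  for (int i = 0; i < m.n; ++i) {
    int c = m.chrom[i];
    m.csx[c] += m.x[i]; m.csy[c] += m.y[i]; m.csz[c] += m.z[i];
    m.W[c] += 1.0;
  }
  // chain bonds between consecutive beads of one chromosome; the softer
  // (smaller) class spring is used across class boundaries
  for (int i = 0; i + 1 < m.n; ++i) {
    if (m.chrom[i] != m.chrom[i + 1]) continue;
    m.b1.push_back(i);
    m.b2.push_back(i + 1);
    m.bk.push_back(std::min(kappa_class[m.cls[i]],
                            kappa_class[m.cls[i + 1]]));
  }
  for (int l = 0; l < loops.nrow(); ++l) {
    m.l1.push_back(loops(l, 0));
    m.l2.push_back(loops(l, 1));
  }
  m.kl = kappa_loop;
  m.krep = kappa_rep;
  m.kfac = kappa_fac; m.kcon = kappa_con; m.rsoft = r_soft;
  m.geo.rx = semi[0]; m.geo.ry = semi[1]; m.geo.rz = semi[2];
  for (int k = 0; k < nucleoli.nrow(); ++k) {
    m.geo.ncx.push_back(nucleoli(k, 0));
    m.geo.ncy.push_back(nucleoli(k, 1));
    m.geo.ncz.push_back(nucleoli(k, 2));
  }
  m.geo.nrad = nucleolus_radius;
  m.bead_bonds.assign(m.n, std::vector<int>());
  m.bead_loops.assign(m.n, std::vector<int>());
  for (size_t b = 0; b < m.b1.size(); ++b) {
    m.bead_bonds[m.b1[b]].push_back((int)b);
    m.bead_bonds[m.b2[b]].push_back((int)b);
  }
  for (size_t l = 0; l < m.l1.size(); ++l) {
    m.bead_loops[m.l1[l]].push_back((int)l);
    m.bead_loops[m.l2[l]].push_back((int)l);
  }
  return m;
}

}  // namespace

// [[Rcpp::export(name = ".folding_energy_cpp")]]
List folding_energy_cpp(NumericMatrix pos, IntegerVector bead_chrom,
                        IntegerVector bead_class, NumericVector kappa_class,
                        IntegerMatrix loops, double kappa_loop,
                        double kappa_rep, double kappa_fac, double kappa_con,
                        double r_soft, NumericVector semi,
                        NumericMatrix nucleoli, double nucleolus_radius) {
  Model m = build_model(pos, bead_chrom, bead_class, kappa_class, loops,
                        kappa_loop, kappa_rep, kappa_fac, kappa_con, r_soft,
                        semi, nucleoli, nucleolus_radius);
  double uc = m.chain_total(), ul = m.loop_total();
  double ur = m.rep_total(), up = m.peri_total();
  return List::create(
    _["chain"] = uc, _["loop"] = ul, _["repulsion"] = ur,
    _["periphery"] = up, _["total"] = uc + ul + ur + up);
}

// [[Rcpp::export(name = ".relax_cpp")]]
List relax_cpp(NumericMatrix pos, IntegerVector bead_chrom,
               IntegerVector bead_class, NumericVector kappa_class,
               IntegerMatrix loops, double kappa_loop, double kappa_rep,
               double kappa_fac, double kappa_con, double r_soft,
               NumericVector semi, NumericMatrix nucleoli,
               double nucleolus_radius,
               int n_sweeps, double step_sigma, bool tune, double beta,
               int seed, int record_every, int track_bond) {
  Model m = build_model(pos, bead_chrom, bead_class, kappa_class, loops,
                        kappa_loop, kappa_rep, kappa_fac, kappa_con, r_soft,
                        semi, nucleoli, nucleolus_radius);
  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  double utotal = m.chain_total() + m.loop_total() + m.rep_total()
    + m.peri_total();
  std::vector<double> trace(n_sweeps);
  std::vector<double> bond_trace;
  long accepted = 0, proposed = 0;
  int tune_sweeps = tune ? std::max(1, n_sweeps / 5) : 0;
  List recorded;
  std::vector<NumericMatrix> rec_list;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    long acc_sweep = 0;
    for (int k = 0; k < m.n; ++k) {
      int i = (int)(unif(rng) * m.n);
      if (i >= m.n) i = m.n - 1;
      double nx = m.x[i] + step_sigma * gauss(rng);
      double ny = m.y[i] + step_sigma * gauss(rng);
      double nz = m.z[i] + step_sigma * gauss(rng);
      ++proposed;
      if (!m.geo.inside(nx, ny, nz)) continue;
      // incremental energy change
      double du = 0.0;
      double ox = m.x[i], oy = m.y[i], oz = m.z[i];
      for (size_t t = 0; t < m.bead_bonds[i].size(); ++t) {
        du -= m.bond_energy(m.bead_bonds[i][t]);
      }
      for (size_t t = 0; t < m.bead_loops[i].size(); ++t) {
        du -= m.loop_energy(m.bead_loops[i][t]);
      }
      du -= m.peri_energy_at(m.cls[i], ox, oy, oz);
      int c = m.chrom[i];
      double ocx = m.csx[c] / m.W[c], ocy = m.csy[c] / m.W[c],
        ocz = m.csz[c] / m.W[c];
      du -= m.rep_of_chrom(c, ocx, ocy, ocz);
      m.x[i] = nx; m.y[i] = ny; m.z[i] = nz;
      for (size_t t = 0; t < m.bead_bonds[i].size(); ++t) {
        du += m.bond_energy(m.bead_bonds[i][t]);
      }
      for (size_t t = 0; t < m.bead_loops[i].size(); ++t) {
        du += m.loop_energy(m.bead_loops[i][t]);
      }
      du += m.peri_energy_at(m.cls[i], nx, ny, nz);
      double ncx2 = ocx + (nx - ox) / m.W[c];
      double ncy2 = ocy + (ny - oy) / m.W[c];
      double ncz2 = ocz + (nz - oz) / m.W[c];
      du += m.rep_of_chrom(c, ncx2, ncy2, ncz2);
      if (du <= 0.0 || unif(rng) < std::exp(-beta * du)) {
        m.csx[c] += nx - ox; m.csy[c] += ny - oy; m.csz[c] += nz - oz;
        utotal += du;
        ++accepted;
        ++acc_sweep;
      } else {
        m.x[i] = ox; m.y[i] = oy; m.z[i] = oz;
      }
    }
    trace[sweep] = utotal;
    if (track_bond && m.n >= 2) {
      double dx = m.x[0] - m.x[1], dy = m.y[0] - m.y[1],
        dz = m.z[0] - m.z[1];
      if (track_bond <= 1 || (sweep % track_bond) == 0) {
        bond_trace.push_back(std::sqrt(dx * dx + dy * dy + dz * dz));
      }
    }
    if (sweep < tune_sweeps) {
      double rate = (double)acc_sweep / (double)m.n;
      if (rate > 0.5) step_sigma *= 1.15;
      else if (rate < 0.3) step_sigma /= 1.15;
    }
    if (record_every > 0 && (sweep + 1) % record_every == 0) {
      NumericMatrix snap(m.n, 3);
      for (int i = 0; i < m.n; ++i) {
        snap(i, 0) = m.x[i]; snap(i, 1) = m.y[i]; snap(i, 2) = m.z[i];
      }
      rec_list.push_back(snap);
    }
    if ((sweep & 63) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(m.n, 3);
  for (int i = 0; i < m.n; ++i) {
    out(i, 0) = m.x[i]; out(i, 1) = m.y[i]; out(i, 2) = m.z[i];
  }
  double uc = m.chain_total(), ul = m.loop_total();
  double ur = m.rep_total(), up = m.peri_total();
  List recs(rec_list.size());
  for (size_t i = 0; i < rec_list.size(); ++i) recs[i] = rec_list[i];
  return List::create(
    _["positions"] = out,
    _["energy_trace"] = NumericVector(trace.begin(), trace.end()),
    _["running_energy"] = utotal,
    _["energy_terms"] = List::create(
      _["chain"] = uc, _["loop"] = ul, _["repulsion"] = ur,
      _["periphery"] = up, _["total"] = uc + ul + ur + up),
    _["acceptance_rate"] = proposed > 0
      ? (double)accepted / (double)proposed : NA_REAL,
    _["step_sigma"] = step_sigma,
    _["bond_trace"] = NumericVector(bond_trace.begin(), bond_trace.end()),
    _["recorded"] = recs);
}

// [[Rcpp::export(name = ".blur_separable_cpp")]]
NumericVector blur_separable_cpp(NumericVector vol, IntegerVector dims,
                                 NumericVector sigmas) {
  // separable Gaussian blur of a 3D array with edge-renormalized kernels
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(vol.begin(), vol.end());
  std::vector<double> b(a.size());
  int strides[3] = {1, nx, nx * ny};
  int sizes[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigmas[axis];
    if (s <= 0.0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * rad + 1);
    for (int k = -rad; k <= rad; ++k) {
      ker[k + rad] = std::exp(-0.5 * k * k / (s * s));
    }
    int nA = sizes[axis], stA = strides[axis];
    int total = nx * ny * nz;
    int nLines = total / nA;
    for (int line = 0; line < nLines; ++line) {
      // base index of this line
      int rem = line, base = 0;
      for (int ax = 0; ax < 3; ++ax) {
        if (ax == axis) continue;
        int sz = sizes[ax];
        int idx = rem % sz;
        rem /= sz;
        base += idx * strides[ax];
      }
      for (int i = 0; i < nA; ++i) {
        double num = 0.0, den = 0.0;
        int k0 = std::max(-rad, -i), k1 = std::min(rad, nA - 1 - i);
        for (int k = k0; k <= k1; ++k) {
          double wgt = ker[k + rad];
          num += wgt * a[base + (i + k) * stA];
          den += wgt;
        }
        b[base + i * stA] = den > 0.0 ? num / den : 0.0;
      }
    }
    a.swap(b);
  }
  return NumericVector(a.begin(), a.end());
}
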