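// Monte-Carlo / simulated-annealing kernel for hinge-region conformational
// sampling.  The R side prepares the degree-of-freedom topology (axis atoms,
// moved-atom sets, allowed ranges, torsion terms) and the nonbonded pair
// list; this kernel runs the temperature ladder.  A dihedral move rotates
// the distal atom block rigidly about the bond axis, so all other internal
// coordinates are preserved exactly.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// splitmix64: tiny, seedable, platform-independent
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(unif() * n) % n; }
};

struct Vec3 { double x, y, z; };

static inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Dof {
  int type;                 // 0 = dihedral, 1 = bond angle
  int a1, a2, a3, a4;       // measurement atoms (0-based); angle uses a1..a3
  std::vector<int> moved;   // 0-based moved atom indices
  double lo, hi;            // allowed absolute range
  std::vector<double> tA, tN, tD;  // torsion terms (dihedrals only)
  std::vector<double> bin_lo, bin_hi;  // retained bins (biased mode)
  double val;               // current value, degrees
  // bond-angle moves perturb the adjacent psi/omega readings; these
  // topologies let the kernel restore them afterwards
  bool has_corr = false;
  int psi_m[4] = {0, 0, 0, 0}, om_m[4] = {0, 0, 0, 0};
  std::vector<int> psi_moved, om_moved;
};

class System {
public:
  int natoms;
  std::vector<Vec3> xyz, saved;
  std::vector<Dof> dih, ang;
  // pair list
  std::vector<int> pi_, pj_;
  std::vector<double> qq_, eij_, rmij_;
  bool dd_dielectric;
  double cut2_nb, cut2_el;

  double wrap(double a) const {
    a -= 360.0 * std::floor((a + 180.0) / 360.0);
    if (a <= -180.0) a += 360.0;
    return a;
  }

  void rotate(const std::vector<int>& moved, const Vec3& origin,
              Vec3 u, double angle_deg) {
    double n = norm(u);
    u = {u.x / n, u.y / n, u.z / n};
    double th = angle_deg * DEG, ct = std::cos(th), st = std::sin(th);
    for (int idx : moved) {
      Vec3 p = sub(xyz[idx], origin);
      Vec3 cr = cross(u, p);
      double du = dot(u, p);
      xyz[idx] = {
        origin.x + p.x * ct + cr.x * st + u.x * du * (1 - ct),
        origin.y + p.y * ct + cr.y * st + u.y * du * (1 - ct),
        origin.z + p.z * ct + cr.z * st + u.z * du * (1 - ct)};
    }
  }

  double measure_dihedral(int a, int b, int c, int dd) const {
    Vec3 b1 = sub(xyz[b], xyz[a]), b2 = sub(xyz[c], xyz[b]),
         b3 = sub(xyz[dd], xyz[c]);
    Vec3 n1 = cross(b1, b2), n2 = cross(b2, b3);
    double nb2 = norm(b2);
    Vec3 u2 = {b2.x / nb2, b2.y / nb2, b2.z / nb2};
    Vec3 m1 = cross(n1, u2);
    return wrap(std::atan2(dot(m1, n2), dot(n1, n2)) / DEG);
  }

  // rotate `moved` about the b->c bond so the a-b-c-d dihedral becomes
  // `target`
  void set_dihedral_raw(const int* m, const std::vector<int>& moved,
                        double target) {
    double cur = measure_dihedral(m[0], m[1], m[2], m[3]);
    Vec3 b = xyz[m[1]], c = xyz[m[2]];
    rotate(moved, c, sub(c, b), -wrap(target - cur));
  }

  // set a dihedral DOF to `target` by rigid rotation of its moved block
  void set_dihedral(Dof& d, double target) {
    Vec3 b = xyz[d.a2], c = xyz[d.a3];
    // rotating the distal block by +t about (c-b) lowers the dihedral by t
    rotate(d.moved, c, sub(c, b), -(target - d.val));
    d.val = wrap(target);
  }

  void set_angle(Dof& d, double target) {
    double psi_old = 0, om_old = 0;
    if (d.has_corr) {
      psi_old = measure_dihedral(d.psi_m[0], d.psi_m[1], d.psi_m[2], d.psi_m[3]);
      om_old = measure_dihedral(d.om_m[0], d.om_m[1], d.om_m[2], d.om_m[3]);
    }
    Vec3 n = xyz[d.a1], ca = xyz[d.a2], c = xyz[d.a3];
    Vec3 axis = cross(sub(n, ca), sub(c, ca));
    rotate(d.moved, ca, axis, target - d.val);
    d.val = target;
    if (d.has_corr) {
      set_dihedral_raw(d.psi_m, d.psi_moved, psi_old);
      set_dihedral_raw(d.om_m, d.om_moved, om_old);
    }
  }

  double energy() const {
    double e = 0.0;
    for (size_t k = 0; k < pi_.size(); ++k) {
      Vec3 dv = sub(xyz[pi_[k]], xyz[pj_[k]]);
      double r2 = dot(dv, dv);
      if (r2 <= cut2_el) {
        e += dd_dielectric ? qq_[k] / r2 : qq_[k] / std::sqrt(r2);
      }
      if (r2 <= cut2_nb && eij_[k] != 0.0) {
        double s2 = (rmij_[k] * rmij_[k]) / r2;
        double s6 = s2 * s2 * s2;
        e += eij_[k] * (s6 * s6 - 2.0 * s6);
      }
    }
    for (const Dof& d : dih) {
      for (size_t t = 0; t < d.tA.size(); ++t) {
        e += d.tA[t] * (1.0 + std::cos((d.tN[t] * d.val - d.tD[t]) * DEG));
      }
    }
    return e;
  }
};

static Dof parse_dof(List spec, int type) {
  Dof d;
  d.type = type;
  IntegerVector meas = spec["meas"];
  d.a1 = meas[0] - 1; d.a2 = meas[1] - 1; d.a3 = meas[2] - 1;
  d.a4 = (type == 0) ? meas[3] - 1 : -1;
  IntegerVector mv = spec["moved"];
  for (int i = 0; i < mv.size(); ++i) d.moved.push_back(mv[i] - 1);
  d.lo = as<double>(spec["lo"]);
  d.hi = as<double>(spec["hi"]);
  d.val = as<double>(spec["init"]);
  if (type == 0 && spec.containsElementNamed("tor_A")) {
    NumericVector A = spec["tor_A"], N = spec["tor_n"], D = spec["tor_d"];
    for (int i = 0; i < A.size(); ++i) {
      d.tA.push_back(A[i]); d.tN.push_back(N[i]); d.tD.push_back(D[i]);
    }
  }
  if (spec.containsElementNamed("bin_lo")) {
    NumericVector bl = spec["bin_lo"], bh = spec["bin_hi"];
    for (int i = 0; i < bl.size(); ++i) {
      d.bin_lo.push_back(bl[i]); d.bin_hi.push_back(bh[i]);
    }
  }
  if (type == 1 && spec.containsElementNamed("psi_meas")) {
    d.has_corr = true;
    IntegerVector pm = spec["psi_meas"], om = spec["om_meas"];
    for (int i = 0; i < 4; ++i) {
      d.psi_m[i] = pm[i] - 1;
      d.om_m[i] = om[i] - 1;
    }
    IntegerVector pmv = spec["psi_moved"], omv = spec["om_moved"];
    for (int i = 0; i < pmv.size(); ++i) d.psi_moved.push_back(pmv[i] - 1);
    for (int i = 0; i < omv.size(); ++i) d.om_moved.push_back(omv[i] - 1);
  }
  return d;
}

// [[Rcpp::export(name = ".cm_kernel")]]
List cm_kernel(NumericMatrix xyz0, List dof_dih, List dof_ang,
               IntegerVector pair_i, IntegerVector pair_j,
               NumericVector pair_qq, NumericVector pair_eij,
               NumericVector pair_rmij, bool dd_dielectric,
               double cutoff_nb, double cutoff_elec,
               NumericVector temps, int steps_per_temp,
               bool biased, List mem_edges, double kB,
               double seed, int record_stride) {
  System sys;
  sys.natoms = xyz0.nrow();
  sys.xyz.resize(sys.natoms);
  for (int i = 0; i < sys.natoms; ++i) {
    sys.xyz[i] = {xyz0(i, 0), xyz0(i, 1), xyz0(i, 2)};
  }
  for (int i = 0; i < dof_dih.size(); ++i) {
    sys.dih.push_back(parse_dof(dof_dih[i], 0));
  }
  for (int i = 0; i < dof_ang.size(); ++i) {
    sys.ang.push_back(parse_dof(dof_ang[i], 1));
  }
  for (int k = 0; k < pair_i.size(); ++k) {
    sys.pi_.push_back(pair_i[k] - 1);
    sys.pj_.push_back(pair_j[k] - 1);
    sys.qq_.push_back(pair_qq[k]);
    sys.eij_.push_back(pair_eij[k]);
    sys.rmij_.push_back(pair_rmij[k]);
  }
  sys.dd_dielectric = dd_dielectric;
  sys.cut2_nb = cutoff_nb * cutoff_nb;
  sys.cut2_el = cutoff_elec * cutoff_elec;

  int ndih = sys.dih.size(), nang = sys.ang.size();
  if (ndih < 1) stop("at least one free dihedral is required");
  if (biased) {
    for (const Dof& d : sys.dih) {
      if (d.bin_lo.empty()) {
        stop("empty retained memory for a free dihedral: lower the retention "
             "threshold");
      }
    }
  }

  // memory histograms (exploratory phase)
  std::vector<std::vector<double>> edges(ndih);
  std::vector<std::vector<int>> counts(ndih);
  bool collect_memory = mem_edges.size() == ndih && !biased;
  if (collect_memory) {
    for (int d = 0; d < ndih; ++d) {
      NumericVector e = mem_edges[d];
      edges[d].assign(e.begin(), e.end());
      counts[d].assign(e.size() - 1, 0);
    }
  }

  SplitMix64 rng((uint64_t)seed);
  int ntemp = temps.size();
  IntegerVector acc_per_temp(ntemp);
  std::vector<double> snap_vals, snap_E;
  std::vector<double> chain;
  double E = sys.energy();
  int nvary = ndih >= 2 ? 2 : 1;

  std::vector<double> old_vals(ndih + nang);
  for (int ti = 0; ti < ntemp; ++ti) {
    double T = temps[ti];
    bool final_temp = (ti == ntemp - 1);
    for (int step = 0; step < steps_per_temp; ++step) {
      sys.saved = sys.xyz;
      for (int d = 0; d < ndih; ++d) old_vals[d] = sys.dih[d].val;
      for (int a = 0; a < nang; ++a) old_vals[ndih + a] = sys.ang[a].val;
      // choose `nvary` distinct dihedrals
      int d1 = rng.below(ndih), d2 = -1;
      if (nvary == 2) {
        d2 = rng.below(ndih - 1);
        if (d2 >= d1) ++d2;
      }
      for (int dsel : {d1, d2}) {
        if (dsel < 0) continue;
        Dof& d = sys.dih[dsel];
        double v;
        if (biased) {
          int b = rng.below((int)d.bin_lo.size());
          v = d.bin_lo[b] + rng.unif() * (d.bin_hi[b] - d.bin_lo[b]);
        } else {
          v = d.lo + rng.unif() * (d.hi - d.lo);
        }
        sys.set_dihedral(d, v);
      }
      if (nang > 0) {
        Dof& a = sys.ang[rng.below(nang)];
        sys.set_angle(a, a.lo + rng.unif() * (a.hi - a.lo));
      }
      double Enew = sys.energy();
      double dE = Enew - E;
      bool accept = dE <= 0.0 || rng.unif() < std::exp(-dE / (kB * T));
      if (accept) {
        E = Enew;
        acc_per_temp[ti]++;
        if (collect_memory) {
          for (int d = 0; d < ndih; ++d) {
            const std::vector<double>& e = edges[d];
            double v = sys.dih[d].val;
            int nb = (int)e.size() - 1;
            int b = (int)std::floor((v - e[0]) / (e[1] - e[0]));
            if (b >= 0 && b < nb) counts[d][b]++;
          }
        }
        if (final_temp) {
          for (int d = 0; d < ndih; ++d) snap_vals.push_back(sys.dih[d].val);
          for (int a = 0; a < nang; ++a) snap_vals.push_back(sys.ang[a].val);
          snap_E.push_back(E);
        }
      } else {
        sys.xyz = sys.saved;
        for (int d = 0; d < ndih; ++d) sys.dih[d].val = old_vals[d];
        for (int a = 0; a < nang; ++a) sys.ang[a].val = old_vals[ndih + a];
      }
      if (record_stride > 0 && final_temp && step % record_stride == 0) {
        for (int d = 0; d < ndih; ++d) chain.push_back(sys.dih[d].val);
      }
    }
  }

  NumericMatrix xyz_out(sys.natoms, 3);
  for (int i = 0; i < sys.natoms; ++i) {
    xyz_out(i, 0) = sys.xyz[i].x;
    xyz_out(i, 1) = sys.xyz[i].y;
    xyz_out(i, 2) = sys.xyz[i].z;
  }
  List mem_out(ndih);
  if (collect_memory) {
    for (int d = 0; d < ndih; ++d) mem_out[d] = wrap(counts[d]);
  }
  int ndof = ndih + nang;
  int nsnap = snap_E.size();
  NumericMatrix snaps(nsnap, ndof);
  for (int s = 0; s < nsnap; ++s) {
    for (int d = 0; d < ndof; ++d) snaps(s, d) = snap_vals[s * ndof + d];
  }
  int nrec = ndih > 0 ? (int)chain.size() / ndih : 0;
  NumericMatrix chain_out(nrec, ndih);
  for (int s = 0; s < nrec; ++s) {
    for (int d = 0; d < ndih; ++d) chain_out(s, d) = chain[s * ndih + d];
  }
  return List::create(
    _["xyz"] = xyz_out, _["memory_counts"] = mem_out,
    _["accepted_per_temperature"] = acc_per_temp,
    _["snapshots"] = snaps, _["snapshot_energies"] = wrap(snap_E),
    _["chain"] = chain_out, _["final_energy"] = E);
}
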