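// Compiled kernels: dihedral geometry, internal-coordinate (NeRF) chain
// building, the stand-in energy, the Metropolis annealer, and Kabsch RMSD.
// All torsion angles cross the R boundary in degrees, coordinates in Angstrom.
// Hot paths (chain building, energies) run on raw double arrays; Armadillo is
// used only at the API boundary and for the Kabsch SVD.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <vector>
using namespace Rcpp;

static const double D2R = M_PI / 180.0;
static const double R2D = 180.0 / M_PI;
// gas constant, kcal mol^-1 K^-1
static const double R_GAS = 1.98720425864e-3;

// ---- raw 3-vector helpers (xyz stored row-contiguous: atom i at xyz + 3*i) --

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }
static inline bool vnormalise(double* a) {
  double n = vnorm(a);
  if (n < 1e-12) return false;
  a[0] /= n; a[1] /= n; a[2] /= n;
  return true;
}

// Signed dihedral p1-p2-p3-p4 in radians, IUPAC convention (cis = 0, sign by
// right-hand rule along p2->p3); NA for a degenerate central triplet.
static double dihedral_raw(const double* p1, const double* p2,
                           const double* p3, const double* p4) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], cx[3];
  vsub(p2, p1, b1); vsub(p3, p2, b2); vsub(p4, p3, b3);
  double nb2 = vnorm(b2);
  if (nb2 < 1e-12) return NA_REAL;
  vcross(b1, b2, n1); vcross(b2, b3, n2);
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) return NA_REAL;
  double x = vdot(n1, n2);
  vcross(n1, n2, cx);
  double y = vdot(cx, b2) / nb2;
  double ang = std::atan2(y, x);
  // atan2 gives (-pi, pi]; map -pi to +pi so the range is (-180, 180]
  if (ang <= -M_PI + 1e-15) ang = M_PI;
  return ang;
}

// [[Rcpp::export(name = ".dihedral_cpp")]]
double dihedral_cpp(NumericVector p1, NumericVector p2, NumericVector p3,
                    NumericVector p4) {
  double a[3] = {p1[0], p1[1], p1[2]}, b[3] = {p2[0], p2[1], p2[2]},
         c[3] = {p3[0], p3[1], p3[2]}, d[3] = {p4[0], p4[1], p4[2]};
  double ang = dihedral_raw(a, b, c, d);
  if (!R_finite(ang)) return NA_REAL;
  return ang * R2D;
}

// copy an R (n x 3) matrix into a row-contiguous raw buffer
static std::vector<double> to_raw(const NumericMatrix& m) {
  int n = m.nrow();
  std::vector<double> out(3 * n);
  for (int i = 0; i < n; ++i) {
    out[3 * i] = m(i, 0); out[3 * i + 1] = m(i, 1); out[3 * i + 2] = m(i, 2);
  }
  return out;
}

static NumericMatrix from_raw(const std::vector<double>& xyz, int n) {
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = xyz[3 * i]; out(i, 1) = xyz[3 * i + 1];
    out(i, 2) = xyz[3 * i + 2];
  }
  return out;
}

// [[Rcpp::export(name = ".measure_dihedrals_cpp")]]
NumericVector measure_dihedrals_cpp(NumericMatrix coords, IntegerMatrix quads) {
  std::vector<double> xyz = to_raw(coords);
  int m = quads.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double ang = dihedral_raw(&xyz[3 * quads(i, 0)], &xyz[3 * quads(i, 1)],
                              &xyz[3 * quads(i, 2)], &xyz[3 * quads(i, 3)]);
    out[i] = R_finite(ang) ? ang * R2D : NA_REAL;
  }
  return out;
}

// Place atom X with |X-A| = b, angle(X,A,B) = theta, dihedral(X,A,B,C) = phi.
static void nerf_place(const double* A, const double* B, const double* C,
                       double b, double theta, double phi, double* X) {
  double ab[3], bc[3], n[3], m[3];
  vsub(B, A, ab); vnormalise(ab);
  vsub(C, B, bc); vnormalise(bc);
  vcross(ab, bc, n);
  if (!vnormalise(n)) {
    // collinear frame: pick any perpendicular
    double ref[3] = {1.0, 0.0, 0.0};
    if (std::fabs(ab[0]) > 0.9) { ref[0] = 0.0; ref[1] = 1.0; }
    vcross(ab, ref, n);
    vnormalise(n);
  }
  vcross(n, ab, m);
  double ct = std::cos(theta), st = std::sin(theta);
  double cp = std::cos(phi), sp = std::sin(phi);
  // direction making angle theta with A->B, rotated phi about the A->B axis
  // out of the ABC plane (sign matching the IUPAC dihedral convention)
  for (int k = 0; k < 3; ++k)
    X[k] = A[k] + b * (ct * ab[k] + st * (cp * m[k] - sp * n[k]));
}

// Z-matrix template in flat arrays (angles/torsion offsets pre-converted to
// radians)
struct ZMat {
  std::vector<int> r1, r2, r3, link;
  std::vector<double> bond, angle, toroff;
  int n;
};

static ZMat make_zmat(const IntegerMatrix& zm_ref, const NumericVector& bond,
                      const NumericVector& angle, const NumericVector& toroff,
                      const IntegerVector& link) {
  ZMat z;
  z.n = zm_ref.nrow();
  z.r1.resize(z.n); z.r2.resize(z.n); z.r3.resize(z.n);
  z.link.assign(link.begin(), link.end());
  z.bond.assign(bond.begin(), bond.end());
  z.angle.resize(z.n);
  z.toroff.resize(z.n);
  for (int i = 0; i < z.n; ++i) {
    z.r1[i] = zm_ref(i, 0); z.r2[i] = zm_ref(i, 1); z.r3[i] = zm_ref(i, 2);
    z.angle[i] = angle[i] * D2R;
    z.toroff[i] = toroff[i] * D2R;
  }
  return z;
}

// torsions in radians; start > 0 rebuilds only atoms >= start (the prefix
// must already hold valid coordinates: atom refs always point backwards)
static void build_chain_from(const ZMat& z, const double* tor, double* xyz,
                             int start) {
  for (int i = std::max(start, 3); i < z.n; ++i) {
    double t = z.toroff[i];
    if (z.link[i] > 0) t += tor[z.link[i] - 1];
    nerf_place(&xyz[3 * z.r1[i]], &xyz[3 * z.r2[i]], &xyz[3 * z.r3[i]],
               z.bond[i], z.angle[i], t, &xyz[3 * i]);
  }
}

static void build_chain(const ZMat& z, const double* tor, double* xyz) {
  if (z.n == 0) return;
  xyz[0] = xyz[1] = xyz[2] = 0.0;
  if (z.n > 1) { xyz[3] = z.bond[1]; xyz[4] = xyz[5] = 0.0; }
  if (z.n > 2) {
    // third atom in the xy plane at bond/angle from its refs
    const double* A = &xyz[3 * z.r1[2]];
    const double* B = &xyz[3 * z.r2[2]];
    double ab[3];
    vsub(B, A, ab); vnormalise(ab);
    double perp[3] = {-ab[1], ab[0], 0.0};
    if (!vnormalise(perp)) { perp[0] = 1.0; perp[1] = perp[2] = 0.0; }
    double ct = std::cos(z.angle[2]), st = std::sin(z.angle[2]);
    for (int k = 0; k < 3; ++k)
      xyz[6 + k] = A[k] + z.bond[2] * (ct * ab[k] + st * perp[k]);
  }
  build_chain_from(z, tor, xyz, 3);
}

// first atom index affected by each torsion variable (everything after it
// must be rebuilt when that torsion moves)
static std::vector<int> first_affected(const ZMat& z, int n_tor) {
  std::vector<int> fa(n_tor, z.n);
  for (int i = 0; i < z.n; ++i)
    if (z.link[i] > 0 && i < fa[z.link[i] - 1]) fa[z.link[i] - 1] = i;
  return fa;
}

// [[Rcpp::export(name = ".build_chain_cpp")]]
NumericMatrix build_chain_cpp(IntegerMatrix zm_ref, NumericVector zm_bond,
                              NumericVector zm_angle, NumericVector zm_toroff,
                              IntegerVector zm_link, NumericVector torsions) {
  ZMat z = make_zmat(zm_ref, zm_bond, zm_angle, zm_toroff, zm_link);
  std::vector<double> tor(torsions.size());
  for (int i = 0; i < torsions.size(); ++i) tor[i] = torsions[i] * D2R;
  std::vector<double> xyz(3 * z.n);
  build_chain(z, tor.data(), xyz.data());
  return from_raw(xyz, z.n);
}

// ---- stand-in energy --------------------------------------------------------

struct EnergyParams {
  std::vector<int> pi, pj;     // 0-based nonbonded pair indices (> 3 bonds)
  std::vector<double> sigma;   // per-pair contact distance (A)
  std::vector<double> sig2, cut2;  // sigma^2 and truncation radius^2 (9 sigma^2)
  double eps, cap;
  std::vector<int> ra, rb;     // 0-based restraint atom indices
  std::vector<double> rup, rk; // upper bounds (A), force constants
  std::vector<int> omega;      // flattened planarity quads (4 ints per entry)
  double k_omega;
};

static double steric_energy(const double* xyz, const EnergyParams& p,
                            bool* clash) {
  double e = 0.0;
  size_t n = p.pi.size();
  for (size_t q = 0; q < n; ++q) {
    const double* a = &xyz[3 * p.pi[q]];
    const double* b = &xyz[3 * p.pj[q]];
    double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > p.cut2[q]) continue;  // (sigma^2/r^2)^6 < 5e-7: truncated
    if (r2 < 1e-4) {  // r < 0.01 A: overlapping atoms
      e += p.cap;
      if (clash) *clash = true;
      continue;
    }
    double s2 = p.sig2[q] / r2;
    double s6 = s2 * s2 * s2;
    double term = p.eps * s6 * s6;
    e += (term > p.cap) ? p.cap : term;
  }
  return e;
}

static double restraint_energy_sum(const double* xyz, const EnergyParams& p,
                                   double* per) {
  double e = 0.0;
  size_t n = p.ra.size();
  for (size_t q = 0; q < n; ++q) {
    const double* a = &xyz[3 * p.ra[q]];
    const double* b = &xyz[3 * p.rb[q]];
    double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double viol = r - p.rup[q];
    double eq = (viol > 0.0) ? p.rk[q] * viol * viol : 0.0;
    if (per) per[q] = eq;
    e += eq;
  }
  return e;
}

static double torsion_energy(const double* xyz, const EnergyParams& p) {
  double e = 0.0;
  size_t m = p.omega.size() / 4;
  for (size_t q = 0; q < m; ++q) {
    const int* o = &p.omega[4 * q];
    double w = dihedral_raw(&xyz[3 * o[0]], &xyz[3 * o[1]], &xyz[3 * o[2]],
                            &xyz[3 * o[3]]);
    if (!R_finite(w)) continue;
    e += p.k_omega * (1.0 + std::cos(2.0 * w - M_PI));
  }
  return e;
}

static double total_energy(const double* xyz, const EnergyParams& p) {
  return steric_energy(xyz, p, nullptr) +
         restraint_energy_sum(xyz, p, nullptr) + torsion_energy(xyz, p);
}

static EnergyParams unpack_params(const List& par) {
  EnergyParams p;
  IntegerVector pi = par["pair_i"], pj = par["pair_j"];
  NumericVector sg = par["sigma"];
  IntegerVector ra = par["restr_a"], rb = par["restr_b"];
  NumericVector ru = par["restr_upper"], rk = par["restr_k"];
  IntegerMatrix om = par["omega_quads"];
  p.pi.assign(pi.begin(), pi.end());
  p.pj.assign(pj.begin(), pj.end());
  p.sigma.assign(sg.begin(), sg.end());
  p.sig2.resize(p.sigma.size());
  p.cut2.resize(p.sigma.size());
  for (size_t i = 0; i < p.sigma.size(); ++i) {
    p.sig2[i] = p.sigma[i] * p.sigma[i];
    p.cut2[i] = 9.0 * p.sig2[i];
  }
  p.eps = as<double>(par["eps"]);
  p.cap = as<double>(par["cap"]);
  p.ra.assign(ra.begin(), ra.end());
  p.rb.assign(rb.begin(), rb.end());
  p.rup.assign(ru.begin(), ru.end());
  p.rk.assign(rk.begin(), rk.end());
  p.omega.resize(4 * om.nrow());
  for (int i = 0; i < om.nrow(); ++i)
    for (int k = 0; k < 4; ++k) p.omega[4 * i + k] = om(i, k);
  p.k_omega = as<double>(par["k_omega"]);
  return p;
}

// [[Rcpp::export(name = ".energy_cpp")]]
List energy_cpp(NumericMatrix coords, List par) {
  EnergyParams p = unpack_params(par);
  std::vector<double> xyz = to_raw(coords);
  bool clash = false;
  std::vector<double> per(p.ra.size(), 0.0);
  double es = steric_energy(xyz.data(), p, &clash);
  double er = restraint_energy_sum(xyz.data(), p, per.data());
  double et = torsion_energy(xyz.data(), p);
  return List::create(_["steric"] = es, _["torsion"] = et, _["restraint"] = er,
                      _["total"] = es + et + er,
                      _["per_restraint"] =
                          NumericVector(per.begin(), per.end()),
                      _["clash"] = clash);
}

static inline double wrap_rad(double a) {
  // (avoids std::fmod: not portable across the glibc versions in play)
  a -= 2.0 * M_PI * std::floor((a + M_PI) / (2.0 * M_PI));  // [-pi, pi)
  return (a <= -M_PI) ? a + 2.0 * M_PI : a;                 // (-pi, pi]
}

// Single-torsion Metropolis Monte Carlo over the staged temperature schedule.
// Uses R's RNG (deterministic under set.seed on the R side).
// [[Rcpp::export(name = ".anneal_cpp")]]
List anneal_cpp(IntegerMatrix zm_ref, NumericVector zm_bond,
                NumericVector zm_angle, NumericVector zm_toroff,
                IntegerVector zm_link, NumericVector torsions0, List par,
                NumericVector stage_T, IntegerVector stage_steps,
                double sigma_hi, double t_ref, double sigma_lo,
                IntegerVector movable) {
  EnergyParams p = unpack_params(par);
  ZMat z = make_zmat(zm_ref, zm_bond, zm_angle, zm_toroff, zm_link);
  int n_mov = movable.size();
  std::vector<double> tor(torsions0.size());
  for (int i = 0; i < torsions0.size(); ++i) tor[i] = torsions0[i] * D2R;
  std::vector<double> xyz(3 * z.n), xyz_new(3 * z.n);
  build_chain(z, tor.data(), xyz.data());
  // the planarity term is invariant under phi/psi moves (its dihedrals are
  // Z-matrix constants), so it is a constant offset during sampling
  double e_omega = torsion_energy(xyz.data(), p);
  double e_cur = steric_energy(xyz.data(), p, nullptr) +
                 restraint_energy_sum(xyz.data(), p, nullptr) + e_omega;
  double e_init = e_cur;
  std::vector<int> fa = first_affected(z, (int)tor.size());
  long accepted = 0, total = 0;
  for (int s = 0; s < stage_T.size(); ++s) {
    double T = stage_T[s];
    double sigma = sigma_hi * std::sqrt(std::max(T, 0.0) / t_ref);
    if (sigma < sigma_lo) sigma = sigma_lo;
    if (sigma > sigma_hi) sigma = sigma_hi;
    sigma *= D2R;
    double beta = (T > 0.0) ? 1.0 / (R_GAS * T) : 0.0;
    int nst = stage_steps[s];
    for (int step = 0; step < nst; ++step) {
      ++total;
      int j = movable[(int)std::floor(unif_rand() * n_mov) % n_mov] - 1;
      double old = tor[j];
      tor[j] = wrap_rad(old + sigma * norm_rand());
      std::copy(xyz.begin(), xyz.begin() + 3 * std::min(fa[j], z.n),
                xyz_new.begin());
      build_chain_from(z, tor.data(), xyz_new.data(), fa[j]);
      double e_new = steric_energy(xyz_new.data(), p, nullptr) +
                     restraint_energy_sum(xyz_new.data(), p, nullptr) +
                     e_omega;
      bool accept;
      if (T > 0.0) {
        double de = e_new - e_cur;
        accept = (de <= 0.0) || (unif_rand() < std::exp(-de * beta));
      } else {
        accept = (e_new <= e_cur);  // greedy descent at 0 K
      }
      if (accept) {
        e_cur = e_new;
        std::swap(xyz, xyz_new);
        ++accepted;
      } else {
        tor[j] = old;
      }
    }
  }
  std::vector<double> per(p.ra.size(), 0.0);
  bool clash = false;
  double es = steric_energy(xyz.data(), p, &clash);
  double er = restraint_energy_sum(xyz.data(), p, per.data());
  double et = torsion_energy(xyz.data(), p);
  NumericVector tor_out((int)tor.size());
  for (size_t i = 0; i < tor.size(); ++i) tor_out[i] = tor[i] * R2D;
  return List::create(
      _["torsions"] = tor_out, _["coords"] = from_raw(xyz, z.n),
      _["steric"] = es, _["torsion"] = et, _["restraint"] = er,
      _["total"] = es + et + er,
      _["per_restraint"] = NumericVector(per.begin(), per.end()),
      _["accepted"] = (double)accepted, _["steps"] = (double)total,
      _["initial_total"] = e_init, _["clash"] = clash);
}

// Constant-temperature production MC recording a frame every `stride` steps.
// [[Rcpp::export(name = ".production_cpp")]]
List production_cpp(IntegerMatrix zm_ref, NumericVector zm_bond,
                    NumericVector zm_angle, NumericVector zm_toroff,
                    IntegerVector zm_link, NumericVector torsions0, List par,
                    double T, int n_steps, int stride, double sigma_move,
                    IntegerVector movable) {
  EnergyParams p = unpack_params(par);
  ZMat z = make_zmat(zm_ref, zm_bond, zm_angle, zm_toroff, zm_link);
  int n_mov = movable.size();
  std::vector<double> tor(torsions0.size());
  for (int i = 0; i < torsions0.size(); ++i) tor[i] = torsions0[i] * D2R;
  std::vector<double> xyz(3 * z.n), xyz_new(3 * z.n);
  build_chain(z, tor.data(), xyz.data());
  double e_omega = torsion_energy(xyz.data(), p);
  double e_cur = steric_energy(xyz.data(), p, nullptr) +
                 restraint_energy_sum(xyz.data(), p, nullptr) + e_omega;
  std::vector<int> fa = first_affected(z, (int)tor.size());
  double beta = (T > 0.0) ? 1.0 / (R_GAS * T) : 0.0;
  double sigma = sigma_move * D2R;
  int n_frames = (stride > 0) ? n_steps / stride : 0;
  NumericVector frames(Dimension(z.n, 3, std::max(n_frames, 1)));
  NumericMatrix tor_frames(std::max(n_frames, 1), (int)tor.size());
  NumericVector e_frames(std::max(n_frames, 1));
  long accepted = 0;
  int fidx = 0;
  for (int step = 1; step <= n_steps; ++step) {
    int j = movable[(int)std::floor(unif_rand() * n_mov) % n_mov] - 1;
    double old = tor[j];
    tor[j] = wrap_rad(old + sigma * norm_rand());
    std::copy(xyz.begin(), xyz.begin() + 3 * std::min(fa[j], z.n),
              xyz_new.begin());
    build_chain_from(z, tor.data(), xyz_new.data(), fa[j]);
    double e_new = steric_energy(xyz_new.data(), p, nullptr) +
                   restraint_energy_sum(xyz_new.data(), p, nullptr) + e_omega;
    bool accept;
    if (T > 0.0) {
      double de = e_new - e_cur;
      accept = (de <= 0.0) || (unif_rand() < std::exp(-de * beta));
    } else {
      accept = (e_new <= e_cur);
    }
    if (accept) {
      e_cur = e_new;
      std::swap(xyz, xyz_new);
      ++accepted;
    } else {
      tor[j] = old;
    }
    if (stride > 0 && step % stride == 0 && fidx < n_frames) {
      for (int a = 0; a < z.n; ++a)
        for (int k = 0; k < 3; ++k)
          frames[a + (long)z.n * k + (long)z.n * 3 * fidx] = xyz[3 * a + k];
      for (size_t t = 0; t < tor.size(); ++t)
        tor_frames(fidx, (int)t) = tor[t] * R2D;
      e_frames[fidx] = e_cur;
      ++fidx;
    }
  }
  return List::create(_["frames"] = frames, _["torsions"] = tor_frames,
                      _["energies"] = e_frames,
                      _["accepted"] = (double)accepted,
                      _["steps"] = (double)n_steps);
}

// ---- Kabsch superposition and RMSD -----------------------------------------

// Optimal proper rotation superposing mobile P onto reference Q.
static double kabsch_rmsd(const arma::mat& P, const arma::mat& Q,
                          arma::mat* rot, arma::vec* trans) {
  arma::rowvec pc = arma::mean(P, 0), qc = arma::mean(Q, 0);
  arma::mat Pc = P.each_row() - pc;
  arma::mat Qc = Q.each_row() - qc;
  arma::mat H = Pc.t() * Qc;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  arma::mat R = V * D * U.t();
  arma::mat Pr = Pc * R.t();
  double ss = arma::accu(arma::square(Pr - Qc));
  if (rot) *rot = R;
  if (trans) {
    arma::vec t = arma::vec{qc[0], qc[1], qc[2]} -
                  R * arma::vec{pc[0], pc[1], pc[2]};
    *trans = t;
  }
  return std::sqrt(ss / P.n_rows);
}

// [[Rcpp::export(name = ".kabsch_cpp")]]
List kabsch_cpp(const arma::mat& P, const arma::mat& Q) {
  arma::mat R;
  arma::vec t;
  double rmsd = kabsch_rmsd(P, Q, &R, &t);
  return List::create(_["rotation"] = R, _["translation"] = t,
                      _["rmsd"] = rmsd);
}

// Pairwise superposed RMSD over frames of a selection (atoms x 3 x frames).
// [[Rcpp::export(name = ".pairwise_rmsd_cpp")]]
arma::mat pairwise_rmsd_cpp(const arma::cube& frames) {
  int nf = frames.n_slices;
  arma::mat D(nf, nf, arma::fill::zeros);
  for (int i = 0; i < nf - 1; ++i) {
    for (int j = i + 1; j < nf; ++j) {
      double r = kabsch_rmsd(frames.slice(i), frames.slice(j), nullptr,
                             nullptr);
      D(i, j) = r;
      D(j, i) = r;
    }
  }
  return D;
}

// [[Rcpp::export(name = ".rmsd_to_ref_cpp")]]
arma::vec rmsd_to_ref_cpp(const arma::cube& frames, const arma::mat& ref) {
  int nf = frames.n_slices;
  arma::vec out(nf);
  for (int i = 0; i < nf; ++i)
    out[i] = kabsch_rmsd(frames.slice(i), ref, nullptr, nullptr);
  return out;
}
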