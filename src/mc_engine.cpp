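#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Equilibrium Metropolis sampler for a discrete worm-like chain tethered
// to a hard wall (z >= 0) at vertex 0, with an optional reporter bead of
// radius Rp whose center sits at distance Rp from the chain end along a
// free orientation vector (its own degree of freedom, so bead and DNA
// orientations decorrelate as the minimal particle correction assumes).
// Bending energy in kBT units: kappa * (1 - cos(phi_i)) at each interior
// joint, except an optional "bend vertex" whose joint sits in a stiff
// harmonic well 0.5 * k_bend * (phi - theta)^2 (or a hard window
// |phi - theta| <= tol). Move set: single-vertex crankshaft rotations of
// interior vertices, pivot rotations of the chain tail, and uniform
// resampling of the bead orientation; all are symmetric proposals, so
// plain energy Metropolis acceptance gives detailed balance. Hard
// constraints (wall, bead-wall) act by rejection.

struct Vec3 {
  double x, y, z;
};

static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// Rodrigues rotation of p about unit axis u through origin
static inline Vec3 rotate(const Vec3 &p, const Vec3 &u, double c, double s) {
  double d = dot(u, p) * (1.0 - c);
  return {p.x * c + (u.y * p.z - u.z * p.y) * s + u.x * d,
          p.y * c + (u.z * p.x - u.x * p.z) * s + u.y * d,
          p.z * c + (u.x * p.y - u.y * p.x) * s + u.z * d};
}

class ChainMC {
public:
  int N; // number of segments; vertices 0..N
  double a, kappa, bead_radius;
  int bend_vertex;      // interior joint index 1..N-1, or -1
  double bend_theta;    // spontaneous joint angle, radians
  double k_bend;        // harmonic well stiffness, kBT/rad^2
  bool hard_bend;
  double hard_tol;      // radians, half-width of the hard window
  bool wall, bead;
  bool bead_excl; // reject chain vertices inside the bead sphere
  bool bead_rigid; // bead center along the last bond instead of free
  double step_crank, step_pivot;
  std::vector<Vec3> v;
  Vec3 bead_dir; // free unit vector from the chain end to the bead center
  long accepted = 0, attempted = 0;

  double joint_energy(int i, const std::vector<Vec3> &vv) const {
    // joint i between bonds i and i+1, i in 1..N-1
    Vec3 b1 = sub(vv[i], vv[i - 1]);
    Vec3 b2 = sub(vv[i + 1], vv[i]);
    double c = dot(b1, b2) / (a * a);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    if (i == bend_vertex) {
      double phi = std::acos(c);
      if (hard_bend)
        return std::fabs(phi - bend_theta) <= hard_tol ? 0.0 : INFINITY;
      double d = phi - bend_theta;
      return 0.5 * k_bend * d * d;
    }
    return kappa * (1.0 - c);
  }

  Vec3 bead_center(const std::vector<Vec3> &vv) const {
    if (bead_rigid) {
      Vec3 b = sub(vv[N], vv[N - 1]);
      double n = norm(b);
      return {vv[N].x + bead_radius * b.x / n,
              vv[N].y + bead_radius * b.y / n,
              vv[N].z + bead_radius * b.z / n};
    }
    return {vv[N].x + bead_radius * bead_dir.x,
            vv[N].y + bead_radius * bead_dir.y,
            vv[N].z + bead_radius * bead_dir.z};
  }

  bool bead_clear(const std::vector<Vec3> &vv, const Vec3 &bc) const {
    double r2 = bead_radius * bead_radius * (1.0 - 1e-9);
    for (int k = 0; k < N; ++k) { // vertex N sits on the bead surface
      Vec3 d = sub(vv[k], bc);
      if (dot(d, d) < r2) return false;
    }
    return true;
  }

  bool constraints_ok(const std::vector<Vec3> &vv, int lo, int hi) const {
    if (wall)
      for (int k = lo; k <= hi; ++k)
        if (vv[k].z < 0.0) return false;
    if (bead) {
      Vec3 bc = bead_center(vv);
      if (wall && hi >= (bead_rigid ? N - 1 : N) && bc.z < bead_radius)
        return false;
      if (bead_excl) {
        if (hi >= N) { // bead moved: recheck the whole chain
          if (!bead_clear(vv, bc)) return false;
        } else {
          for (int k = lo; k <= hi; ++k) {
            Vec3 d = sub(vv[k], bc);
            if (dot(d, d) < bead_radius * bead_radius * (1.0 - 1e-9))
              return false;
          }
        }
      }
    }
    return true;
  }

  // resample the bead orientation uniformly; no energy, wall rejection only
  void bead_rotate() {
    if (!bead || bead_rigid) return;
    ++attempted;
    double z = unif_rand() * 2.0 - 1.0, t = unif_rand() * 2.0 * M_PI;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    Vec3 saved = bead_dir;
    bead_dir = {r * std::cos(t), r * std::sin(t), z};
    Vec3 bc = bead_center(v);
    bool ok = !(wall && bc.z < bead_radius) &&
              (!bead_excl || bead_clear(v, bc));
    if (ok)
      ++accepted;
    else
      bead_dir = saved;
  }


  // acceptance rule; an infinite-energy (constraint-violating) current
  // state is always allowed to relax to any finite-energy one
  static bool metropolis_ok(double e_old, double e_new) {
    if (std::isinf(e_new)) return false;
    if (std::isinf(e_old)) return true;
    double dE = e_new - e_old;
    return dE <= 0.0 || unif_rand() < std::exp(-dE);
  }

  void crankshaft() {
    ++attempted;
    int i = 1 + (int)(unif_rand() * (N - 1));
    if (i > N - 1) i = N - 1;
    Vec3 axis = sub(v[i + 1], v[i - 1]);
    double an = norm(axis);
    if (an < 1e-12) return; // hairpin: axis undefined, reject
    axis.x /= an; axis.y /= an; axis.z /= an;
    double ang = (unif_rand() * 2.0 - 1.0) * step_crank;
    double c = std::cos(ang), s = std::sin(ang);
    Vec3 rel = sub(v[i], v[i - 1]);
    Vec3 nrel = rotate(rel, axis, c, s);
    Vec3 vi_new = {v[i - 1].x + nrel.x, v[i - 1].y + nrel.y,
                   v[i - 1].z + nrel.z};
    double e_old = 0.0, e_new = 0.0;
    for (int j = i - 1; j <= i + 1; ++j)
      if (j >= 1 && j <= N - 1) e_old += joint_energy(j, v);
    Vec3 saved = v[i];
    v[i] = vi_new;
    bool ok = constraints_ok(v, i, i);
    if (ok) {
      for (int j = i - 1; j <= i + 1; ++j)
        if (j >= 1 && j <= N - 1) e_new += joint_energy(j, v);
      if (metropolis_ok(e_old, e_new)) {
        ++accepted;
        return;
      }
    }
    v[i] = saved;
  }

  void pivot() {
    ++attempted;
    int i = (int)(unif_rand() * N); // 0..N-1, tail i+1..N rotates
    if (i > N - 1) i = N - 1;
    // random axis, uniform on the sphere
    double z = unif_rand() * 2.0 - 1.0, t = unif_rand() * 2.0 * M_PI;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    Vec3 axis = {r * std::cos(t), r * std::sin(t), z};
    double ang = (unif_rand() * 2.0 - 1.0) * step_pivot;
    double c = std::cos(ang), s = std::sin(ang);
    double e_old = (i >= 1) ? joint_energy(i, v) : 0.0;
    std::vector<Vec3> saved(v.begin() + i + 1, v.end());
    for (int k = i + 1; k <= N; ++k) {
      Vec3 rel = sub(v[k], v[i]);
      Vec3 nr = rotate(rel, axis, c, s);
      v[k] = {v[i].x + nr.x, v[i].y + nr.y, v[i].z + nr.z};
    }
    bool ok = constraints_ok(v, i + 1, N);
    if (ok) {
      double e_new = (i >= 1) ? joint_energy(i, v) : 0.0;
      if (metropolis_ok(e_old, e_new)) {
        ++accepted;
        return;
      }
    }
    std::copy(saved.begin(), saved.end(), v.begin() + i + 1);
  }
};

// [[Rcpp::export(name = ".mc_run")]]
List mc_run(NumericMatrix vertices, double segment_length, double kappa,
            int bend_vertex, double bend_theta_deg, double k_bend,
            bool hard_bend, double hard_tol_deg, double bead_radius,
            bool wall, bool bead, bool bead_excl, bool bead_rigid,
            int n_sweeps, int burn_in,
            double step_crank, double step_pivot, int n_pivot_per_sweep,
            NumericVector bead_dir0, int n_bead_moves_per_sweep) {
  RNGScope scope;
  ChainMC mc;
  mc.N = vertices.nrow() - 1;
  mc.a = segment_length;
  mc.kappa = kappa;
  mc.bend_vertex = bend_vertex;
  mc.bend_theta = bend_theta_deg * M_PI / 180.0;
  mc.k_bend = k_bend;
  mc.hard_bend = hard_bend;
  mc.hard_tol = hard_tol_deg * M_PI / 180.0;
  mc.bead_radius = bead_radius;
  mc.wall = wall;
  mc.bead = bead;
  mc.bead_excl = bead_excl;
  mc.bead_rigid = bead_rigid;
  mc.step_crank = step_crank;
  mc.step_pivot = step_pivot;
  mc.v.resize(mc.N + 1);
  for (int k = 0; k <= mc.N; ++k)
    mc.v[k] = {vertices(k, 0), vertices(k, 1), vertices(k, 2)};
  mc.bead_dir = {bead_dir0[0], bead_dir0[1], bead_dir0[2]};

  int n_rec = n_sweeps - burn_in;
  NumericVector rpar2(n_rec), r2_3d(n_rec);
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int m = 0; m < mc.N - 1; ++m) mc.crankshaft();
    for (int m = 0; m < n_pivot_per_sweep; ++m) mc.pivot();
    if (bead)
      for (int m = 0; m < n_bead_moves_per_sweep; ++m) mc.bead_rotate();
    if (sweep >= burn_in) {
      Vec3 rep = bead ? mc.bead_center(mc.v) : mc.v[mc.N];
      rpar2[sweep - burn_in] = rep.x * rep.x + rep.y * rep.y;
      Vec3 ee = mc.v[mc.N];
      r2_3d[sweep - burn_in] = dot(ee, ee);
    }
  }
  NumericMatrix out_v(mc.N + 1, 3);
  for (int k = 0; k <= mc.N; ++k) {
    out_v(k, 0) = mc.v[k].x;
    out_v(k, 1) = mc.v[k].y;
    out_v(k, 2) = mc.v[k].z;
  }
  return List::create(
      _["rpar2"] = rpar2, _["r2_3d"] = r2_3d,
      _["acceptance_rate"] = (double)mc.accepted / (double)mc.attempted,
      _["vertices"] = out_v);
}
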