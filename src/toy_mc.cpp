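// Metropolis Monte Carlo sampler with Hamiltonian-exchange swaps, and a
// stratified Monte Carlo configurational-integral oracle, for the desk-scale
// host-guest toy system. Energies are in kcal/mol, distances in angstroms.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};

static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

static double angle_between(const Vec3 &a, const Vec3 &b) {
  double c = dot(a, b) / (norm(a) * norm(b));
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return std::acos(c);
}

// dihedral angle for points p1-p2-p3-p4, in (-pi, pi]
static double dihedral(const Vec3 &p1, const Vec3 &p2, const Vec3 &p3,
                       const Vec3 &p4) {
  Vec3 b1 = sub(p2, p1), b2 = sub(p3, p2), b3 = sub(p4, p3);
  Vec3 n1 = cross(b1, b2), n2 = cross(b2, b3);
  Vec3 m1 = cross(n1, b2);
  double nb2 = norm(b2);
  double x = dot(n1, n2);
  double y = dot(m1, n2) / nb2;
  return std::atan2(y, x);
}

static inline double wrap_pi(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a <= -M_PI) a += 2.0 * M_PI;
  return a;
}

struct ToySystem {
  int ng, nh;
  std::vector<Vec3> guest_ref;  // reference geometry, site 1 at origin
  std::vector<Vec3> host;
  std::vector<double> eps, sig6, qq;  // flattened ng x nh pair tables
  double L;
  bool has_host;
  // restraint: r0, thA0, thB0, phA0, phB0, phC0 (rad), kr, kthA, kthB,
  // kphA, kphB, kphC (kcal/mol/A^2 or rad^2)
  std::vector<double> restr;
  bool has_restraint;
  double kT, alpha;
  int lam_power;
};

static ToySystem unpack_system(const List &sys) {
  ToySystem s;
  NumericMatrix g = sys["guest_ref"], h = sys["host"];
  s.ng = g.nrow();
  s.nh = h.nrow();
  for (int i = 0; i < s.ng; ++i) s.guest_ref.push_back({g(i, 0), g(i, 1), g(i, 2)});
  for (int i = 0; i < s.nh; ++i) s.host.push_back({h(i, 0), h(i, 1), h(i, 2)});
  NumericMatrix eps = sys["eps_pair"], sig = sys["sigma_pair"], qq = sys["qq_pair"];
  for (int i = 0; i < s.ng; ++i)
    for (int j = 0; j < s.nh; ++j) {
      s.eps.push_back(eps(i, j));
      double s6 = std::pow(sig(i, j), 6);
      s.sig6.push_back(s6);
      s.qq.push_back(qq(i, j));  // already includes the Coulomb constant
    }
  s.L = as<double>(sys["box_edge"]);
  s.has_host = as<bool>(sys["has_host"]);
  s.has_restraint = as<bool>(sys["has_restraint"]);
  if (s.has_restraint) {
    NumericVector r = sys["restraint"];
    s.restr.assign(r.begin(), r.end());
  }
  s.kT = as<double>(sys["kT"]);
  s.alpha = as<double>(sys["alpha"]);
  s.lam_power = as<int>(sys["lam_power"]);
  return s;
}

// quaternion (w,x,y,z) rotation of v
static inline Vec3 rotate_q(const double *q, const Vec3 &v) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  Vec3 u = {x, y, z};
  Vec3 uv = cross(u, v);
  Vec3 uuv = cross(u, uv);
  return {v.x + 2.0 * (w * uv.x + uuv.x),
          v.y + 2.0 * (w * uv.y + uuv.y),
          v.z + 2.0 * (w * uv.z + uuv.z)};
}

// place guest sites: translation t is the absolute position of site 1
static void guest_positions(const ToySystem &s, const double *conf,
                            std::vector<Vec3> &pos) {
  Vec3 t = {conf[0], conf[1], conf[2]};
  const double *q = conf + 3;
  for (int i = 0; i < s.ng; ++i) {
    Vec3 r = rotate_q(q, s.guest_ref[i]);
    pos[i] = {t.x + r.x, t.y + r.y, t.z + r.z};
  }
}

static double restraint_energy_cart(const ToySystem &s,
                                    const std::vector<Vec3> &pos) {
  const std::vector<double> &R = s.restr;
  const Vec3 &P1 = s.host[0], &P2 = s.host[1], &P3 = s.host[2];
  const Vec3 &L1 = pos[0], &L2 = pos[1], &L3 = pos[2];
  double r = norm(sub(L1, P1));
  double thA = angle_between(sub(P2, P1), sub(L1, P1));
  double thB = angle_between(sub(P1, L1), sub(L2, L1));
  double phA = dihedral(P3, P2, P1, L1);
  double phB = dihedral(P2, P1, L1, L2);
  double phC = dihedral(P1, L1, L2, L3);
  double e = 0.5 * R[6] * (r - R[0]) * (r - R[0]);
  double dA = thA - R[1], dB = thB - R[2];
  e += 0.5 * R[7] * dA * dA + 0.5 * R[8] * dB * dB;
  double w;
  w = wrap_pi(phA - R[3]); e += 0.5 * R[9] * w * w;
  w = wrap_pi(phB - R[4]); e += 0.5 * R[10] * w * w;
  w = wrap_pi(phC - R[5]); e += 0.5 * R[11] * w * w;
  return e;
}

// potential energy (kcal/mol) at the given couplings
static double toy_energy(const ToySystem &s, const double *conf,
                         double lam_r, double lam_c, double lam_v,
                         std::vector<Vec3> &pos) {
  guest_positions(s, conf, pos);
  double e = 0.0;
  if (s.has_host) {
    double one_m = 1.0 - lam_v;
    double lam_pow = std::pow(lam_v, s.lam_power);
    for (int i = 0; i < s.ng; ++i) {
      for (int j = 0; j < s.nh; ++j) {
        Vec3 d = sub(pos[i], s.host[j]);
        double r2 = dot(d, d);
        int p = i * s.nh + j;
        if (lam_v > 0.0 && s.eps[p] != 0.0) {
          double r6 = r2 * r2 * r2;
          double denom = s.alpha * s.sig6[p] * one_m + r6;
          double t = s.sig6[p] / denom;
          e += lam_pow * 4.0 * s.eps[p] * (t * t - t);
        }
        if (lam_c > 0.0 && s.qq[p] != 0.0) {
          e += lam_c * s.qq[p] / std::sqrt(r2);
        }
      }
    }
    if (s.has_restraint && lam_r > 0.0) {
      e += lam_r * restraint_energy_cart(s, pos);
    }
  }
  return e;
}

// [[Rcpp::export(name = ".cpp_toy_energy")]]
NumericVector cpp_toy_energy(List sys, NumericMatrix confs,
                             NumericVector lam_r, NumericVector lam_c,
                             NumericVector lam_v) {
  ToySystem s = unpack_system(sys);
  std::vector<Vec3> pos(s.ng);
  int n = confs.nrow(), K = lam_r.size();
  if (K == 1) {
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
      std::vector<double> c(confs(i, _).begin(), confs(i, _).end());
      out[i] = toy_energy(s, c.data(), lam_r[0], lam_c[0], lam_v[0], pos);
    }
    return out;
  }
  NumericMatrix out(n, K);
  for (int i = 0; i < n; ++i) {
    std::vector<double> c(confs(i, _).begin(), confs(i, _).end());
    for (int k = 0; k < K; ++k)
      out(i, k) = toy_energy(s, c.data(), lam_r[k], lam_c[k], lam_v[k], pos);
  }
  return out;
}

static void random_quaternion(double *q) {
  // uniform over SO(3) (Shoemake)
  double u1 = unif_rand(), u2 = unif_rand(), u3 = unif_rand();
  double a = std::sqrt(1.0 - u1), b = std::sqrt(u1);
  q[0] = b * std::cos(2.0 * M_PI * u3);
  q[1] = a * std::sin(2.0 * M_PI * u2);
  q[2] = a * std::cos(2.0 * M_PI * u2);
  q[3] = b * std::sin(2.0 * M_PI * u3);
}

static void quat_mult_into(const double *a, const double *b, double *out) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

// [[Rcpp::export(name = ".cpp_run_hrex")]]
List cpp_run_hrex(List sys, NumericMatrix lambdas, int n_sweeps,
                  int swap_interval, int swap_attempts, int sample_interval,
                  double trans_step, double rot_step_rad) {
  ToySystem s = unpack_system(sys);
  int K = lambdas.nrow();
  std::vector<Vec3> scratch(s.ng);
  RNGScope rng;

  // one replica per state; conf[r] = 7 doubles; state_of_replica[r]
  std::vector<std::vector<double>> conf(K, std::vector<double>(7, 0.0));
  std::vector<int> state_of(K), replica_at(K);
  std::vector<double> e_cur(K);  // current energy of replica r at its state
  for (int r = 0; r < K; ++r) {
    state_of[r] = r;
    replica_at[r] = r;
    conf[r][0] = s.L * unif_rand();
    conf[r][1] = s.L * unif_rand();
    conf[r][2] = s.L * unif_rand();
    random_quaternion(&conf[r][3]);
  }
  auto energy_at_state = [&](int r, int k) {
    return toy_energy(s, conf[r].data(), lambdas(k, 0), lambdas(k, 1),
                      lambdas(k, 2), scratch);
  };
  for (int r = 0; r < K; ++r) e_cur[r] = energy_at_state(r, state_of[r]);

  int n_samples_per_state = n_sweeps / sample_interval;
  int N = n_samples_per_state * K;
  NumericMatrix u(N, K);
  IntegerVector origin(N);
  NumericMatrix configs(N, 7);
  int sample_row = 0;

  std::vector<double> move_att(K, 0.0), move_acc(K, 0.0);
  std::vector<double> nb_att(K > 1 ? K - 1 : 0, 0.0), nb_acc(K > 1 ? K - 1 : 0, 0.0);
  double rounds = 0.0, jumps = 0.0, jump_att = 0.0;
  std::vector<double> occupancy(K * K, 0.0);  // replica x state visit counts

  double beta = 1.0 / s.kT;
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int r = 0; r < K; ++r) {
      int k = state_of[r];
      // translation attempt
      {
        std::vector<double> trial = conf[r];
        trial[0] += trans_step * (2.0 * unif_rand() - 1.0);
        trial[1] += trans_step * (2.0 * unif_rand() - 1.0);
        trial[2] += trans_step * (2.0 * unif_rand() - 1.0);
        for (int d = 0; d < 3; ++d) {
          trial[d] -= s.L * std::floor(trial[d] / s.L);
        }
        double e_new = toy_energy(s, trial.data(), lambdas(k, 0),
                                  lambdas(k, 1), lambdas(k, 2), scratch);
        move_att[k] += 1.0;
        if (e_new <= e_cur[r] ||
            unif_rand() < std::exp(-beta * (e_new - e_cur[r]))) {
          conf[r] = trial;
          e_cur[r] = e_new;
          move_acc[k] += 1.0;
        }
      }
      // rotation attempt about guest site 1
      {
        std::vector<double> trial = conf[r];
        double axis[3];
        double nrm;
        do {
          axis[0] = 2.0 * unif_rand() - 1.0;
          axis[1] = 2.0 * unif_rand() - 1.0;
          axis[2] = 2.0 * unif_rand() - 1.0;
          nrm = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] +
                          axis[2] * axis[2]);
        } while (nrm > 1.0 || nrm < 1e-12);
        double ang = rot_step_rad * (2.0 * unif_rand() - 1.0);
        double sa = std::sin(ang / 2.0) / nrm;
        double dq[4] = {std::cos(ang / 2.0), axis[0] * sa, axis[1] * sa,
                        axis[2] * sa};
        double qn[4];
        quat_mult_into(dq, &conf[r][3], qn);
        double qq = std::sqrt(qn[0] * qn[0] + qn[1] * qn[1] + qn[2] * qn[2] +
                              qn[3] * qn[3]);
        for (int d = 0; d < 4; ++d) trial[3 + d] = qn[d] / qq;
        double e_new = toy_energy(s, trial.data(), lambdas(k, 0),
                                  lambdas(k, 1), lambdas(k, 2), scratch);
        move_att[k] += 1.0;
        if (e_new <= e_cur[r] ||
            unif_rand() < std::exp(-beta * (e_new - e_cur[r]))) {
          conf[r] = trial;
          e_cur[r] = e_new;
          move_acc[k] += 1.0;
        }
      }
      occupancy[r * K + state_of[r]] += 1.0;
    }

    // exchange round: many random state-pair swap attempts (Gibbs-style)
    if (K > 1 && swap_interval > 0 && sweep % swap_interval == 0) {
      std::vector<int> state_before = state_of;
      for (int a = 0; a < swap_attempts; ++a) {
        int ki = (int)(K * unif_rand());
        int kj = (int)(K * unif_rand());
        if (ki >= K) ki = K - 1;
        if (kj >= K) kj = K - 1;
        if (ki == kj) continue;
        int ri = replica_at[ki], rj = replica_at[kj];
        double eii = e_cur[ri], ejj = e_cur[rj];
        double eij = energy_at_state(ri, kj);
        double eji = energy_at_state(rj, ki);
        double delta = beta * ((eij + eji) - (eii + ejj));
        bool neighbour = std::abs(ki - kj) == 1;
        if (neighbour) nb_att[std::min(ki, kj)] += 1.0;
        if (delta <= 0.0 || unif_rand() < std::exp(-delta)) {
          state_of[ri] = kj;
          state_of[rj] = ki;
          replica_at[ki] = rj;
          replica_at[kj] = ri;
          e_cur[ri] = eij;
          e_cur[rj] = eji;
          if (neighbour) nb_acc[std::min(ki, kj)] += 1.0;
        }
      }
      rounds += 1.0;
      for (int r = 0; r < K; ++r) {
        jump_att += 1.0;
        if (state_of[r] != state_before[r]) jumps += 1.0;
      }
    }

    if (sweep % sample_interval == 0) {
      // record the configuration currently visiting each state
      for (int k = 0; k < K; ++k) {
        int r = replica_at[k];
        origin[sample_row] = k + 1;
        for (int d = 0; d < 7; ++d) configs(sample_row, d) = conf[r][d];
        for (int l = 0; l < K; ++l) {
          u(sample_row, l) = beta * toy_energy(s, conf[r].data(),
                                               lambdas(l, 0), lambdas(l, 1),
                                               lambdas(l, 2), scratch);
        }
        ++sample_row;
      }
    }
  }

  NumericMatrix occ(K, K);
  for (int r = 0; r < K; ++r)
    for (int k = 0; k < K; ++k) occ(r, k) = occupancy[r * K + k];
  NumericVector macc(K), natt(std::max(K - 1, 0)), nacc(std::max(K - 1, 0));
  for (int k = 0; k < K; ++k)
    macc[k] = move_att[k] > 0 ? move_acc[k] / move_att[k] : NA_REAL;
  for (int k = 0; k + 1 < K; ++k) {
    natt[k] = nb_att[k];
    nacc[k] = nb_att[k] > 0 ? nb_acc[k] / nb_att[k] : NA_REAL;
  }
  return List::create(
      _["u"] = u, _["origin"] = origin, _["configs"] = configs,
      _["move_acceptance"] = macc, _["neighbour_attempts"] = natt,
      _["neighbour_acceptance"] = nacc,
      _["jump_probability"] = (jump_att > 0 ? jumps / jump_att : NA_REAL),
      _["occupancy"] = occ, _["n_exchange_rounds"] = rounds);
}

// [[Rcpp::export(name = ".cpp_quadrature_z")]]
List cpp_quadrature_z(List sys, int n_cells, int n_per_cell) {
  // stratified MC estimate of <exp(-U/kT)> over uniform positions in the
  // box and uniform orientations, at full coupling without restraint
  ToySystem s = unpack_system(sys);
  std::vector<Vec3> scratch(s.ng);
  RNGScope rng;
  double beta = 1.0 / s.kT;
  double cell = s.L / n_cells;
  double conf[7];
  double sum_mean = 0.0, sum_var = 0.0;
  long n_cells_total = (long)n_cells * n_cells * n_cells;
  for (int ix = 0; ix < n_cells; ++ix) {
    for (int iy = 0; iy < n_cells; ++iy) {
      for (int iz = 0; iz < n_cells; ++iz) {
        double m = 0.0, m2 = 0.0;
        for (int t = 0; t < n_per_cell; ++t) {
          conf[0] = (ix + unif_rand()) * cell;
          conf[1] = (iy + unif_rand()) * cell;
          conf[2] = (iz + unif_rand()) * cell;
          random_quaternion(conf + 3);
          double e = toy_energy(s, conf, 0.0, 1.0, 1.0, scratch);
          double w = std::exp(-beta * e);
          m += w;
          m2 += w * w;
        }
        m /= n_per_cell;
        m2 /= n_per_cell;
        sum_mean += m;
        double v = (m2 - m * m) / std::max(n_per_cell - 1, 1);
        sum_var += v;
      }
    }
  }
  double mean = sum_mean / n_cells_total;
  double se = std::sqrt(sum_var) / n_cells_total;
  return List::create(_["mean"] = mean, _["se"] = se,
                      _["n_total"] = (double)n_cells_total * n_per_cell);
}
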