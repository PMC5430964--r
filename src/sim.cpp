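#include <Rcpp.h>
using namespace Rcpp;

// Coarse-grained Langevin dynamics of a Gaussian FENE bead-spring chain in a
// slit with an optional hexagonal array of cylindrical posts.
//
// Units: bead diameter sigma, thermal energy k_B T and bead mass m are the
// base units; the bead diffusion time is t_D = sigma^2 / (kT / (m gamma)).
// Positions are kept unwrapped in the periodic slit plane (x, y); the posts
// are reached through the minimum-image convention. z is bounded by
// reflecting walls at 0 and H.

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// FENE + WCA bonded pair: force magnitude dU/dr (positive = repulsive,
// applied along the bond), and energy.
static inline void bond_pair(double r, double k_s, double r_max, double sigma,
                             bool fene_literal, double &dUdr, double &U) {
  double x = r / r_max;
  double Ufene, dfene;
  if (fene_literal) {
    // literal form with an unsquared argument: U = -(k r0^2/2) ln(1 - r/r0)
    Ufene = -0.5 * k_s * r_max * r_max * std::log(1.0 - x);
    dfene = 0.5 * k_s * r_max / (1.0 - x);
  } else {
    // Kremer-Grest form: U = -(k r0^2/2) ln(1 - (r/r0)^2)
    Ufene = -0.5 * k_s * r_max * r_max * std::log(1.0 - x * x);
    dfene = k_s * r / (1.0 - x * x);
  }
  double Uwca = 0.0, dwca = 0.0;
  double rc = std::pow(2.0, 1.0 / 6.0) * sigma;
  if (r < rc) {
    double sr6 = std::pow(sigma / r, 6), sr12 = sr6 * sr6;
    Uwca = 4.0 * (sr12 - sr6) + 1.0;
    dwca = 4.0 * (-12.0 * sr12 + 6.0 * sr6) / r;
  }
  dUdr = dfene + dwca;
  U = Ufene + Uwca;
}

// Post-bead Lennard-Jones in the surface distance s = r - R, shifted to zero
// at the cutoff. Returns -dU/ds (positive = push away from the post) and U.
static inline void post_pair(double s, double eps, double rcut, double sigma,
                             double &f_out, double &U) {
  f_out = 0.0; U = 0.0;
  if (s >= rcut) return;
  double sr6 = std::pow(sigma / s, 6), sr12 = sr6 * sr6;
  double src6 = std::pow(sigma / rcut, 6), src12 = src6 * src6;
  U = 4.0 * eps * (sr12 - sr6) - 4.0 * eps * (src12 - src6);
  f_out = 4.0 * eps * (12.0 * sr12 - 6.0 * sr6) / s;
}

struct SimParams {
  double k_s, r_max, sigma, kT, mass, gamma, dt;
  bool fene_literal;
  bool has_posts, has_walls;
  double post_R, eps, rcut, H;
  double Lx, Ly;
  int n_posts;
  const double *cx, *cy;  // post centers
};

// Accumulate all conservative forces into F (n x 3, zeroed by caller);
// returns potential energy. Throws on broken bonds / post overlap.
static double forces(const std::vector<double> &px, const std::vector<double> &py,
                     const std::vector<double> &pz,
                     std::vector<double> &fx, std::vector<double> &fy,
                     std::vector<double> &fz, const SimParams &P) {
  int n = (int)px.size();
  double U = 0.0;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  for (int i = 0; i + 1 < n; ++i) {
    double dx = px[i + 1] - px[i], dy = py[i + 1] - py[i], dz = pz[i + 1] - pz[i];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r >= P.r_max) {
      stop("bond %d-%d reached length %.4f >= r_max = %.3f (integration blow-up)",
           i + 1, i + 2, r, P.r_max);
    }
    double dUdr, Ub;
    bond_pair(r, P.k_s, P.r_max, P.sigma, P.fene_literal, dUdr, Ub);
    U += Ub;
    double fac = -dUdr / r;  // force on bead i+1 along +d
    fx[i + 1] += fac * dx; fy[i + 1] += fac * dy; fz[i + 1] += fac * dz;
    fx[i] -= fac * dx; fy[i] -= fac * dy; fz[i] -= fac * dz;
  }
  if (P.has_posts) {
    for (int i = 0; i < n; ++i) {
      // nearest post under minimum image
      double best2 = 1e300; double bx = 0, by = 0;
      for (int k = 0; k < P.n_posts; ++k) {
        double dx = min_image(px[i] - P.cx[k], P.Lx);
        double dy = min_image(py[i] - P.cy[k], P.Ly);
        double d2 = dx * dx + dy * dy;
        if (d2 < best2) { best2 = d2; bx = dx; by = dy; }
      }
      double r = std::sqrt(best2);
      double s = r - P.post_R;
      if (s <= 0.0) stop("bead %d inside a post (r = %.4f <= R)", i + 1, r);
      double f_out, Up;
      post_pair(s, P.eps, P.rcut, P.sigma, f_out, Up);
      U += Up;
      if (f_out != 0.0) {
        fx[i] += f_out * bx / r;
        fy[i] += f_out * by / r;
      }
    }
  }
  return U;
}

// [[Rcpp::export]]
List run_sim_cpp(NumericMatrix pos0, NumericMatrix vel0,
                 double k_s, double r_max, double sigma, double kT,
                 double mass, double gamma, double dt, bool fene_literal,
                 NumericMatrix centers, NumericVector box,
                 double post_R, double eps, double rcut, double H,
                 bool has_posts, bool has_walls, bool thermostat,
                 int n_steps, int sample_every, int snapshot_every,
                 bool sample_energy) {
  int n = pos0.nrow();
  SimParams P;
  P.k_s = k_s; P.r_max = r_max; P.sigma = sigma; P.kT = kT; P.mass = mass;
  P.gamma = gamma; P.dt = dt; P.fene_literal = fene_literal;
  P.has_posts = has_posts; P.has_walls = has_walls;
  P.post_R = post_R; P.eps = eps; P.rcut = rcut; P.H = H;
  P.Lx = box[0]; P.Ly = box[1];
  P.n_posts = has_posts ? centers.nrow() : 0;
  std::vector<double> cxx(P.n_posts), cyy(P.n_posts);
  for (int k = 0; k < P.n_posts; ++k) { cxx[k] = centers(k, 0); cyy[k] = centers(k, 1); }
  P.cx = cxx.data(); P.cy = cyy.data();

  std::vector<double> px(n), py(n), pz(n), vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1); pz[i] = pos0(i, 2);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1); vz[i] = vel0(i, 2);
  }
  std::vector<double> fx(n), fy(n), fz(n), rx(n), ry(n), rz(n);

  int n_samples = n_steps / sample_every + 1;
  NumericVector s_time(n_samples), s_rg(n_samples), s_energy(sample_energy ? n_samples : 0);
  NumericMatrix s_com(n_samples, 2), s_comw(n_samples, 2);
  List snapshots;
  int n_snap = (snapshot_every > 0) ? n_steps / snapshot_every : 0;
  if (n_snap > 0) snapshots = List(n_snap);
  int snap_i = 0;

  RNGScope rng;  // R's RNG: reproducible under set.seed()
  double rstd = std::sqrt(2.0 * mass * gamma * kT / dt);
  double U = forces(px, py, pz, fx, fy, fz, P);

  int si = 0;
  auto take_sample = [&](double t) {
    double cx0 = 0, cy0 = 0;
    for (int i = 0; i < n; ++i) { cx0 += px[i]; cy0 += py[i]; }
    cx0 /= n; cy0 /= n;
    double rg2 = 0;
    for (int i = 0; i < n; ++i) {
      double dx = px[i] - cx0, dy = py[i] - cy0;
      rg2 += dx * dx + dy * dy;
    }
    s_time[si] = t;
    s_com(si, 0) = cx0; s_com(si, 1) = cy0;
    double wx = cx0 - P.Lx * std::floor(cx0 / P.Lx);
    double wy = cy0 - P.Ly * std::floor(cy0 / P.Ly);
    s_comw(si, 0) = wx; s_comw(si, 1) = wy;
    s_rg[si] = std::sqrt(rg2 / n);
    if (sample_energy) {
      double ke = 0;
      for (int i = 0; i < n; ++i)
        ke += 0.5 * mass * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      s_energy[si] = ke + U;
    }
    ++si;
  };
  take_sample(0.0);

  for (int step = 1; step <= n_steps; ++step) {
    // one random force per bead-component per step, used in both half-kicks
    if (thermostat) {
      for (int i = 0; i < n; ++i) {
        rx[i] = rstd * norm_rand();
        ry[i] = rstd * norm_rand();
        rz[i] = rstd * norm_rand();
      }
    }
    double hdt = 0.5 * dt / mass;
    for (int i = 0; i < n; ++i) {
      double ax = fx[i], ay = fy[i], az = fz[i];
      if (thermostat) {
        ax += rx[i] - mass * gamma * vx[i];
        ay += ry[i] - mass * gamma * vy[i];
        az += rz[i] - mass * gamma * vz[i];
      }
      vx[i] += hdt * ax; vy[i] += hdt * ay; vz[i] += hdt * az;
      px[i] += dt * vx[i]; py[i] += dt * vy[i]; pz[i] += dt * vz[i];
      if (has_walls) {  // specular reflection at z = 0 and z = H
        while (pz[i] < 0.0 || pz[i] > H) {
          if (pz[i] < 0.0) { pz[i] = -pz[i]; vz[i] = -vz[i]; }
          if (pz[i] > H)   { pz[i] = 2.0 * H - pz[i]; vz[i] = -vz[i]; }
        }
      }
    }
    U = forces(px, py, pz, fx, fy, fz, P);
    double denom = thermostat ? (1.0 + 0.5 * gamma * dt) : 1.0;
    for (int i = 0; i < n; ++i) {
      double ax = fx[i], ay = fy[i], az = fz[i];
      if (thermostat) { ax += rx[i]; ay += ry[i]; az += rz[i]; }
      vx[i] = (vx[i] + hdt * ax) / denom;
      vy[i] = (vy[i] + hdt * ay) / denom;
      vz[i] = (vz[i] + hdt * az) / denom;
      if (!std::isfinite(px[i]) || !std::isfinite(py[i]) || !std::isfinite(pz[i]))
        stop("non-finite coordinate for bead %d at step %d (instability)", i + 1, step);
    }
    if (step % sample_every == 0) take_sample(step * dt);
    if (snapshot_every > 0 && step % snapshot_every == 0) {
      NumericMatrix snap(n, 3);
      for (int i = 0; i < n; ++i) { snap(i, 0) = px[i]; snap(i, 1) = py[i]; snap(i, 2) = pz[i]; }
      snapshots[snap_i++] = snap;
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix posf(n, 3), velf(n, 3);
  for (int i = 0; i < n; ++i) {
    posf(i, 0) = px[i]; posf(i, 1) = py[i]; posf(i, 2) = pz[i];
    velf(i, 0) = vx[i]; velf(i, 1) = vy[i]; velf(i, 2) = vz[i];
  }
  return List::create(
    _["times"] = s_time, _["com"] = s_com, _["com_wrapped"] = s_comw,
    _["rg"] = s_rg, _["energy"] = s_energy, _["positions"] = posf,
    _["velocities"] = velf, _["snapshots"] = snapshots);
}

// [[Rcpp::export]]
NumericMatrix bonded_forces_cpp(NumericMatrix pos, double k_s, double r_max,
                                double sigma, bool fene_literal) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  for (int i = 0; i + 1 < n; ++i) {
    double dx = pos(i + 1, 0) - pos(i, 0);
    double dy = pos(i + 1, 1) - pos(i, 1);
    double dz = pos(i + 1, 2) - pos(i, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r >= r_max)
      stop("bond %d-%d reached length %.4f >= r_max = %.3f (integration blow-up)",
           i + 1, i + 2, r, r_max);
    double dUdr, Ub;
    bond_pair(r, k_s, r_max, sigma, fene_literal, dUdr, Ub);
    double fac = -dUdr / r;
    F(i + 1, 0) += fac * dx; F(i + 1, 1) += fac * dy; F(i + 1, 2) += fac * dz;
    F(i, 0) -= fac * dx; F(i, 1) -= fac * dy; F(i, 2) -= fac * dz;
  }
  return F;
}

// [[Rcpp::export]]
NumericMatrix post_forces_cpp(NumericMatrix pos, NumericMatrix centers,
                              NumericVector box, double post_R, double eps,
                              double rcut, double sigma) {
  int n = pos.nrow(), m = centers.nrow();
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) {
    double best2 = 1e300, bx = 0, by = 0;
    for (int k = 0; k < m; ++k) {
      double dx = min_image(pos(i, 0) - centers(k, 0), box[0]);
      double dy = min_image(pos(i, 1) - centers(k, 1), box[1]);
      double d2 = dx * dx + dy * dy;
      if (d2 < best2) { best2 = d2; bx = dx; by = dy; }
    }
    double r = std::sqrt(best2), s = r - post_R;
    if (s <= 0.0) stop("bead %d inside a post (r = %.4f <= R)", i + 1, r);
    double f_out, Up;
    post_pair(s, eps, rcut, sigma, f_out, Up);
    if (f_out != 0.0) { F(i, 0) = f_out * bx / r; F(i, 1) = f_out * by / r; }
  }
  return F;
}

// [[Rcpp::export]]
double post_energy_cpp(double s, double eps, double rcut, double sigma) {
  double f, U;
  post_pair(s, eps, rcut, sigma, f, U);
  return U;
}

// [[Rcpp::export]]
double bond_energy_cpp(double r, double k_s, double r_max, double sigma,
                       bool fene_literal) {
  double dUdr, U;
  bond_pair(r, k_s, r_max, sigma, fene_literal, dUdr, U);
  return U;
}

// [[Rcpp::export]]
double bond_dudr_cpp(double r, double k_s, double r_max, double sigma,
                     bool fene_literal) {
  double dUdr, U;
  bond_pair(r, k_s, r_max, sigma, fene_literal, dUdr, U);
  return dUdr;
}
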