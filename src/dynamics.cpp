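#include <Rcpp.h>

#include <cmath>
#include <vector>

#include "model.h"
#include "rng.h"

using namespace Rcpp;

static double e2e_dist(const std::vector<double>& x, int n) {
  double dx = x[3 * (n - 1)] - x[0];
  double dy = x[3 * (n - 1) + 1] - x[1];
  double dz = x[3 * (n - 1) + 2] - x[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static void check_finite(const std::vector<double>& x, long step) {
  for (size_t i = 0; i < x.size(); ++i) {
    if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e6)
      stop("numerical blow-up at step %ld (coordinate %d)", step, (int)i + 1);
  }
}

static std::vector<double> mat_to_vec(const NumericMatrix& pos) {
  std::vector<double> x((size_t)pos.nrow() * 3);
  for (int i = 0; i < pos.nrow(); ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  return x;
}

static NumericMatrix vec_to_mat(const std::vector<double>& x) {
  int n = (int)(x.size() / 3);
  NumericMatrix pos(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) pos(i, d) = x[3 * i + d];
  return pos;
}

// [[Rcpp::export]]
List cpp_energy_forces(List topo, NumericMatrix pos) {
  Topology t = parse_topology(topo);
  if (pos.nrow() != t.n) stop("positions do not match topology size");
  std::vector<double> x = mat_to_vec(pos), f;
  NeighborList nl;
  nl.skin = 0.0;  // exact evaluation for one-shot calls
  EnergyTerms e = compute_forces(t, x, f, nl);
  return List::create(
      _["bonds"] = e.bonds, _["chirality"] = e.chir, _["native_lj"] = e.native,
      _["repulsive"] = e.rep, _["forces"] = vec_to_mat(f));
}

// Plain equilibrium run (overdamped); records end-to-end distance at stride.
// [[Rcpp::export]]
List cpp_cg_run(List topo, NumericMatrix pos, double kT, double gamma,
                double dt, double seed, double n_steps, int stride) {
  Topology t = parse_topology(topo);
  std::vector<double> x = mat_to_vec(pos), f;
  NeighborList nl;
  nl.skin = 1.5;
  Rng rng((uint64_t)seed);
  const double mob = dt / gamma, noise = std::sqrt(2.0 * kT * dt / gamma);
  long ns = (long)n_steps;
  std::vector<double> ts, rcs;
  for (long s = 0; s < ns; ++s) {
    compute_forces(t, x, f, nl);
    for (size_t i = 0; i < x.size(); ++i)
      x[i] += mob * f[i] + noise * rng.norm();
    if ((s + 1) % stride == 0) {
      check_finite(x, s + 1);
      ts.push_back((s + 1) * dt);
      rcs.push_back(e2e_dist(x, t.n));
    }
  }
  check_finite(x, ns);
  return List::create(_["positions"] = vec_to_mat(x), _["time"] = ts,
                      _["end_to_end"] = rcs);
}

// Constant-velocity pulling with springs on both termini. The anchored
// terminus keeps a spring at its initial position; the moving anchor starts
// at the pulled terminus and travels along the initial N->C axis.
// [[Rcpp::export]]
List cpp_cg_pull(List topo, NumericMatrix pos, double kT, double gamma,
                 double dt, double seed, double spring_k, double velocity,
                 double n_steps, int stride, int frame_stride,
                 bool pull_c_terminus) {
  Topology t = parse_topology(topo);
  std::vector<double> x = mat_to_vec(pos), f;
  NeighborList nl;
  nl.skin = 1.5;
  Rng rng((uint64_t)seed);
  const double mob = dt / gamma, noise = std::sqrt(2.0 * kT * dt / gamma);
  long ns = (long)n_steps;

  int ia = pull_c_terminus ? 0 : t.n - 1;      // anchored bead
  int ip = pull_c_terminus ? t.n - 1 : 0;      // pulled bead
  double u[3];                                  // pulling axis, anchored->pulled
  double rc0 = e2e_dist(x, t.n);
  if (rc0 <= 0.0) stop("degenerate initial end-to-end vector");
  for (int d = 0; d < 3; ++d) u[d] = (x[3 * ip + d] - x[3 * ia + d]) / rc0;
  double a_fix[3], a_mov0[3];
  for (int d = 0; d < 3; ++d) {
    a_fix[d] = x[3 * ia + d];
    a_mov0[d] = x[3 * ip + d];
  }

  long nrec = ns / stride;
  NumericVector r_t(nrec), r_rc(nrec), r_ext(nrec), r_force(nrec), r_work(nrec);
  std::vector<NumericMatrix> frames;
  std::vector<double> frame_t, frame_rc;
  double work = 0.0;
  long idx = 0;
  for (long s = 0; s < ns; ++s) {
    compute_forces(t, x, f, nl);
    double disp = velocity * s * dt;
    // static spring on the anchored terminus
    for (int d = 0; d < 3; ++d)
      f[3 * ia + d] += spring_k * (a_fix[d] - x[3 * ia + d]);
    // moving spring on the pulled terminus
    double ext = 0.0;  // extension along the pulling axis
    double ev[3];
    for (int d = 0; d < 3; ++d) {
      ev[d] = a_mov0[d] + disp * u[d] - x[3 * ip + d];
      f[3 * ip + d] += spring_k * ev[d];
      ext += ev[d] * u[d];
    }
    double force = spring_k * ext;  // tension along axis, >0 when stretched
    work += force * velocity * dt;
    for (size_t i = 0; i < x.size(); ++i)
      x[i] += mob * f[i] + noise * rng.norm();
    if ((s + 1) % stride == 0) {
      check_finite(x, s + 1);
      r_t[idx] = (s + 1) * dt;
      r_rc[idx] = e2e_dist(x, t.n);
      r_ext[idx] = ext;
      r_force[idx] = force;
      r_work[idx] = work;
      ++idx;
    }
    if (frame_stride > 0 && (s + 1) % frame_stride == 0) {
      frames.push_back(vec_to_mat(x));
      frame_t.push_back((s + 1) * dt);
      frame_rc.push_back(e2e_dist(x, t.n));
    }
  }
  check_finite(x, ns);
  List fl(frames.size());
  for (size_t i = 0; i < frames.size(); ++i) fl[i] = frames[i];
  return List::create(_["time"] = r_t, _["end_to_end"] = r_rc,
                      _["spring_extension"] = r_ext, _["force"] = r_force,
                      _["work"] = r_work, _["positions"] = vec_to_mat(x),
                      _["frames"] = fl, _["frame_time"] = frame_t,
                      _["frame_end_to_end"] = frame_rc);
}

// Umbrella window: harmonic bias 1/2 k (rc - center)^2 on the end-to-end
// distance; samples rc at stride after n_equil discarded steps.
// [[Rcpp::export]]
List cpp_cg_umbrella(List topo, NumericMatrix pos, double kT, double gamma,
                     double dt, double seed, double k_umb, double center,
                     double n_steps, double n_equil, int stride) {
  Topology t = parse_topology(topo);
  std::vector<double> x = mat_to_vec(pos), f;
  NeighborList nl;
  nl.skin = 1.5;
  Rng rng((uint64_t)seed);
  const double mob = dt / gamma, noise = std::sqrt(2.0 * kT * dt / gamma);
  long ns = (long)n_steps, ne = (long)n_equil;
  std::vector<double> samples;
  int iN = t.n - 1;
  for (long s = 0; s < ns; ++s) {
    compute_forces(t, x, f, nl);
    double rc = e2e_dist(x, t.n);
    if (rc > 0) {
      double fb = -k_umb * (rc - center);  // along +u on last bead
      for (int d = 0; d < 3; ++d) {
        double ud = (x[3 * iN + d] - x[d]) / rc;
        f[3 * iN + d] += fb * ud;
        f[d] -= fb * ud;
      }
    }
    for (size_t i = 0; i < x.size(); ++i)
      x[i] += mob * f[i] + noise * rng.norm();
    if (s >= ne && (s + 1) % stride == 0) {
      check_finite(x, s + 1);
      samples.push_back(e2e_dist(x, t.n));
    }
  }
  check_finite(x, ns);
  return List::create(_["samples"] = samples, _["positions"] = vec_to_mat(x));
}

// One BXD box on the end-to-end coordinate. Overdamped wall rule: a proposed
// update that would cross a wall counts as a hit and has its reaction-
// coordinate component reflected about the wall. The first `equil_events`
// hits are a within-box equilibration burn-in (the trajectory enters through
// the lower wall, which would otherwise bias the early hit statistics) and
// are not counted. After `events` counted hits the trajectory is released
// through the upper wall (unless last box).
// [[Rcpp::export]]
List cpp_cg_bxd_box(List topo, NumericMatrix pos, double kT, double gamma,
                    double dt, double seed, double lo, double hi, int events,
                    double max_steps, bool release, int equil_events) {
  Topology t = parse_topology(topo);
  std::vector<double> x = mat_to_vec(pos), f, xn;
  NeighborList nl;
  nl.skin = 1.5;
  Rng rng((uint64_t)seed);
  const double mob = dt / gamma, noise = std::sqrt(2.0 * kT * dt / gamma);
  long ms = (long)max_steps;
  int n = t.n;
  std::vector<double> hit_time;
  std::vector<int> hit_wall;  // 0 = lower, 1 = upper
  int n_hits = 0, n_equil_hits = 0;
  long s = 0;
  bool quota_done = false, released = false, equilibrated = (equil_events <= 0);
  double res_time = 0.0;

  for (; s < ms; ++s) {
    compute_forces(t, x, f, nl);
    xn = x;
    for (size_t i = 0; i < xn.size(); ++i)
      xn[i] += mob * f[i] + noise * rng.norm();
    double rc = e2e_dist(xn, n);
    bool cross_up = rc >= hi, cross_lo = rc < lo;
    if (!quota_done) {
      if (equilibrated) res_time += dt;
      if (cross_up || cross_lo) {
        double wall = cross_up ? hi : lo;
        if (equilibrated) {
          hit_time.push_back(res_time);
          hit_wall.push_back(cross_up ? 1 : 0);
          ++n_hits;
        } else if (++n_equil_hits >= equil_events) {
          equilibrated = true;
        }
        double target = 2.0 * wall - rc;
        if (target >= lo && target < hi && rc > 0) {
          double shift = (rc - target) / 2.0;
          for (int d = 0; d < 3; ++d) {
            double wd = (xn[3 * (n - 1) + d] - xn[d]) / rc;
            xn[3 * (n - 1) + d] -= shift * wd;
            xn[d] += shift * wd;
          }
        } else {
          xn = x;  // reflection would overshoot the box: reject the move
        }
        if (n_hits >= events) quota_done = true;
      }
      x = xn;
      if (quota_done && !release) break;
    } else {  // release phase: upper wall open, lower wall still reflective
      if (cross_up) {
        x = xn;
        released = true;
        ++s;
        break;
      }
      if (cross_lo) {
        double target = 2.0 * lo - rc;
        if (target >= lo && rc > 0) {
          double shift = (rc - target) / 2.0;
          for (int d = 0; d < 3; ++d) {
            double wd = (xn[3 * (n - 1) + d] - xn[d]) / rc;
            xn[3 * (n - 1) + d] -= shift * wd;
            xn[d] += shift * wd;
          }
        } else {
          xn = x;
        }
      }
      x = xn;
    }
    if ((s & 1023) == 0) check_finite(x, s + 1);
  }
  check_finite(x, s);
  return List::create(
      _["hits_upper"] = std::count(hit_wall.begin(), hit_wall.end(), 1),
      _["hits_lower"] = std::count(hit_wall.begin(), hit_wall.end(), 0),
      _["residence_time"] = res_time, _["hit_time"] = hit_time,
      _["hit_wall"] = hit_wall, _["quota_reached"] = quota_done,
      _["released"] = released, _["steps"] = (double)s,
      _["positions"] = vec_to_mat(x));
}

// ---------------------------------------------------------------------------
// 1D analytic systems for estimator validation
// potential ids: 0 free, 1 harmonic 1/2 k x^2, 2 quartic a x^4, 3 linear c x
// ---------------------------------------------------------------------------

static inline double pot_force(int pot, double p, double x) {
  switch (pot) {
    case 1: return -p * x;
    case 2: return -4.0 * p * x * x * x;
    case 3: return -p;
    default: return 0.0;
  }
}

// [[Rcpp::export]]
NumericVector cpp_bd1d_sample(int pot, double pp, double x0, double kT,
                              double gamma, double dt, double seed,
                              double n_steps, double n_equil, int stride,
                              double k_umb, double center, bool inertial,
                              double mass) {
  Rng rng((uint64_t)seed);
  long ns = (long)n_steps, ne = (long)n_equil;
  std::vector<double> out;
  out.reserve((size_t)((ns - ne) / stride + 1));
  double x = x0, v = 0.0;
  const double mob = dt / gamma, noise = std::sqrt(2.0 * kT * dt / gamma);
  // BAOAB constants (inertial mode)
  const double c1 = std::exp(-gamma * dt / mass);
  const double c3 = std::sqrt(kT / mass * (1.0 - c1 * c1));
  for (long s = 0; s < ns; ++s) {
    double F = pot_force(pot, pp, x) - k_umb * (x - center);
    if (!inertial) {
      x += mob * F + noise * rng.norm();
    } else {
      v += 0.5 * dt * F / mass;
      x += 0.5 * dt * v;
      v = c1 * v + c3 * rng.norm();
      x += 0.5 * dt * v;
      F = pot_force(pot, pp, x) - k_umb * (x - center);
      v += 0.5 * dt * F / mass;
    }
    if (s >= ne && (s + 1) % stride == 0) out.push_back(x);
  }
  return wrap(out);
}

// [[Rcpp::export]]
List cpp_bd1d_bxd_box(int pot, double pp, double x0, double kT, double gamma,
                      double dt, double seed, double lo, double hi, int events,
                      double max_steps, bool release, bool inertial,
                      double mass, int equil_events) {
  Rng rng((uint64_t)seed);
  long ms = (long)max_steps;
  double x = x0, v = 0.0;
  const double mob = dt / gamma, noise = std::sqrt(2.0 * kT * dt / gamma);
  const double c1 = std::exp(-gamma * dt / mass);
  const double c3 = std::sqrt(kT / mass * (1.0 - c1 * c1));
  std::vector<double> hit_time;
  std::vector<int> hit_wall;
  int n_hits = 0, n_equil_hits = 0;
  long s = 0;
  bool quota_done = false, released = false, equilibrated = (equil_events <= 0);
  double res_time = 0.0;
  for (; s < ms; ++s) {
    double F = pot_force(pot, pp, x);
    double xn;
    if (!inertial) {
      xn = x + mob * F + noise * rng.norm();
    } else {
      double vh = v + 0.5 * dt * F / mass;
      xn = x + 0.5 * dt * vh;
      vh = c1 * vh + c3 * rng.norm();
      xn += 0.5 * dt * vh;
      v = vh + 0.5 * dt * pot_force(pot, pp, xn) / mass;
    }
    bool cross_up = xn >= hi, cross_lo = xn < lo;
    if (!quota_done) {
      if (equilibrated) res_time += dt;
      if (cross_up || cross_lo) {
        double wall = cross_up ? hi : lo;
        if (equilibrated) {
          hit_time.push_back(res_time);
          hit_wall.push_back(cross_up ? 1 : 0);
          ++n_hits;
        } else if (++n_equil_hits >= equil_events) {
          equilibrated = true;
        }
        xn = 2.0 * wall - xn;
        if (inertial) v = -v;
        if (xn < lo || xn >= hi) xn = x;
        if (n_hits >= events) quota_done = true;
      }
      x = xn;
      if (quota_done && !release) break;
    } else {
      if (cross_up) {
        x = xn;
        released = true;
        ++s;
        break;
      }
      if (cross_lo) {
        xn = 2.0 * lo - xn;
        if (inertial) v = -v;
        if (xn >= hi) xn = x;
      }
      x = xn;
    }
  }
  return List::create(
      _["hits_upper"] = std::count(hit_wall.begin(), hit_wall.end(), 1),
      _["hits_lower"] = std::count(hit_wall.begin(), hit_wall.end(), 0),
      _["residence_time"] = res_time, _["hit_time"] = hit_time,
      _["hit_wall"] = hit_wall, _["quota_reached"] = quota_done,
      _["released"] = released, _["steps"] = (double)s, _["x"] = x);
}

// Quasi-static 1D drag used in work-definition tests: a single free bead
// pulled by a spring whose anchor moves at constant velocity against a
// constant opposing force.
// [[Rcpp::export]]
List cpp_bd1d_drag(double f_oppose, double spring_k, double velocity,
                   double kT, double gamma, double dt, double seed,
                   double n_steps, int stride) {
  Rng rng((uint64_t)seed);
  long ns = (long)n_steps;
  double x = 0.0, work = 0.0;
  const double mob = dt / gamma, noise = std::sqrt(2.0 * kT * dt / gamma);
  std::vector<double> r_t, r_x, r_f, r_w;
  for (long s = 0; s < ns; ++s) {
    double anchor = velocity * s * dt;
    double fs = spring_k * (anchor - x);
    work += fs * velocity * dt;
    x += mob * (fs - f_oppose) + noise * rng.norm();
    if ((s + 1) % stride == 0) {
      r_t.push_back((s + 1) * dt);
      r_x.push_back(x);
      r_f.push_back(fs);
      r_w.push_back(work);
    }
  }
  return List::create(_["time"] = r_t, _["x"] = r_x, _["force"] = r_f,
                      _["work"] = r_w);
}
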