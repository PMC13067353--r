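// Overdamped Langevin sampling on a closed-form 2D model free-energy
// surface F(xi, phi), with optional harmonic restraints (umbrella windows)
// and multiple-walker well-tempered metadynamics. Uses R's RNG so runs are
// reproducible from set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Surface parameter vector layout (see R/surface.R, make_surface()):
//  0 xi_R   1 xi_P   2 dG    3 A      4 beta   5 u_S
//  6 phi_R  7 phi_S  8 phi_P 9 kappa 10 c_cpl 11 wall 12 bnorm
// 13 beta2 14 bnorm2
struct Surface {
  double xi_R, xi_P, dG, A, beta, u_S;
  double phi_R, phi_S, phi_P, kappa, c_cpl, wall, bnorm;
  double beta2, bnorm2;
  double span;

  explicit Surface(const NumericVector& p) {
    xi_R = p[0]; xi_P = p[1]; dG = p[2]; A = p[3]; beta = p[4]; u_S = p[5];
    phi_R = p[6]; phi_S = p[7]; phi_P = p[8]; kappa = p[9];
    c_cpl = p[10]; wall = p[11]; bnorm = p[12];
    beta2 = p[13]; bnorm2 = p[14];
    span = xi_P - xi_R;
  }

  // quintic smoothstep, clamped: C2 on the whole line
  static double s5(double u) {
    if (u <= 0.0) return 0.0;
    if (u >= 1.0) return 1.0;
    return u * u * u * (10.0 + u * (-15.0 + 6.0 * u));
  }
  // cubic-edged bump (clamped to 0 outside [0,1], C2): interpolates the
  // hydration channel floor; peak value 1 at u = u_S
  double bump3(double u) const {
    if (u <= 0.0 || u >= 1.0) return 0.0;
    double v = u * (1.0 - u);
    return v * v * v * std::exp(beta * u) / bnorm;
  }
  // quadratic-edged barrier bump u^2 (1-u)^2 exp(beta2 u), NOT clamped:
  // its quartic growth outside [0,1] confines the dynamics and gives the
  // two minima genuine quadratic curvature; peak value 1 at u = u_S
  double bump2(double u) const {
    double v = u * (1.0 - u);
    return v * v * std::exp(beta2 * u) / bnorm2;
  }
  double phi_min(double u) const {
    double uc = u < 0.0 ? 0.0 : (u > 1.0 ? 1.0 : u);
    double lin_at_S = phi_R + (phi_P - phi_R) * s5(u_S);
    return phi_R + (phi_P - phi_R) * s5(uc) + (phi_S - lin_at_S) * bump3(uc);
  }
  double value(double xi, double phi) const {
    double u = (xi - xi_R) / span;
    double uc = u < 0.0 ? 0.0 : (u > 1.0 ? 1.0 : u);
    double dphi = phi - phi_min(u);
    double f = dG * s5(uc) + A * bump2(u) * (1.0 + c_cpl * dphi * dphi) +
               kappa * dphi * dphi;
    if (u < 0.0) f += wall * u * u * u * u;
    if (u > 1.0) f += wall * (u - 1.0) * (u - 1.0) * (u - 1.0) * (u - 1.0);
    return f;
  }
  void grad(double xi, double phi, double& gx, double& gp) const {
    const double hx = 1e-5 * span, hp = 1e-6;
    gx = (value(xi + hx, phi) - value(xi - hx, phi)) / (2.0 * hx);
    gp = (value(xi, phi + hp) - value(xi, phi - hp)) / (2.0 * hp);
  }
};

// [[Rcpp::export]]
NumericVector surface_eval_cpp(NumericVector par, NumericVector xi,
                               NumericVector phi) {
  Surface S(par);
  R_xlen_t n = xi.size();
  if (phi.size() != n) stop("xi and phi must have equal length");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = S.value(xi[i], phi[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector surface_phimin_cpp(NumericVector par, NumericVector xi) {
  Surface S(par);
  NumericVector out(xi.size());
  for (R_xlen_t i = 0; i < xi.size(); ++i)
    out[i] = S.phi_min((xi[i] - S.xi_R) / S.span);
  return out;
}

static inline void reflect01(double& x) {
  // reflecting boundaries on [0, 1]
  while (x < 0.0 || x > 1.0) {
    if (x < 0.0) x = -x;
    if (x > 1.0) x = 2.0 - x;
  }
}

// restraints: matrix with columns (cv index 0=xi/1=phi, center, k).
// Integrator: Strang splitting of the overdamped dynamics — half-step
// Euler drift of the surface force, exact Ornstein-Uhlenbeck update of the
// (combined) harmonic restraint with its noise, half-step Euler drift.
// The stiff restraint part (k up to 2500 kcal/mol) is thus sampled without
// time-step bias; unrestrained coordinates take plain Euler-Maruyama noise.
// [[Rcpp::export]]
NumericMatrix langevin_cpp(NumericVector par, NumericMatrix restraints,
                           NumericVector x0, double dt, double friction,
                           double kT, int n_steps, int stride,
                           double guard) {
  Surface S(par);
  double xi = x0[0], phi = x0[1];
  reflect01(phi);
  int n_out = n_steps / stride;
  NumericMatrix out(n_out, 4);
  int nr = restraints.nrow();
  // combine restraints per coordinate: k_tot, effective centre
  double ktot[2] = {0.0, 0.0}, kc[2] = {0.0, 0.0};
  for (int r = 0; r < nr; ++r) {
    int c = restraints(r, 0) < 0.5 ? 0 : 1;
    ktot[c] += restraints(r, 2);
    kc[c] += restraints(r, 2) * restraints(r, 1);
  }
  double ctr[2], decay[2], ou_sd[2];
  double eul_sd = std::sqrt(2.0 * kT * dt / friction);
  for (int c = 0; c < 2; ++c) {
    if (ktot[c] > 0.0) {
      ctr[c] = kc[c] / ktot[c];
      decay[c] = std::exp(-ktot[c] * dt / friction);
      ou_sd[c] = std::sqrt(kT / ktot[c] * (1.0 - decay[c] * decay[c]));
    } else {
      ctr[c] = 0.0; decay[c] = 1.0; ou_sd[c] = eul_sd;
    }
  }
  int row = 0;
  RNGScope scope;
  for (int step = 1; step <= n_steps; ++step) {
    double gx, gp;
    S.grad(xi, phi, gx, gp);
    xi += -gx / friction * dt * 0.5;
    phi += -gp / friction * dt * 0.5;
    if (ktot[0] > 0.0)
      xi = ctr[0] + (xi - ctr[0]) * decay[0] + ou_sd[0] * norm_rand();
    else
      xi += ou_sd[0] * norm_rand();
    if (ktot[1] > 0.0)
      phi = ctr[1] + (phi - ctr[1]) * decay[1] + ou_sd[1] * norm_rand();
    else
      phi += ou_sd[1] * norm_rand();
    S.grad(xi, phi, gx, gp);
    xi += -gx / friction * dt * 0.5;
    phi += -gp / friction * dt * 0.5;
    reflect01(phi);
    double u = (xi - S.xi_R) / S.span;
    if (u < -guard || u > 1.0 + guard)
      stop("trajectory diverged at step %d (xi = %g)", step, xi);
    if (step % stride == 0) {
      double bias = 0.0;
      for (int r = 0; r < nr; ++r) {
        double d = (restraints(r, 0) < 0.5 ? xi : phi) - restraints(r, 1);
        bias += 0.5 * restraints(r, 2) * d * d;
      }
      out(row, 0) = step * dt;
      out(row, 1) = xi;
      out(row, 2) = phi;
      out(row, 3) = bias;
      ++row;
    }
  }
  return out;
}

struct BiasGrid {
  double lo, hi, dx;
  int n;
  std::vector<double> V, dV;
  BiasGrid(double lo_, double hi_, int n_)
    : lo(lo_), hi(hi_), dx((hi_ - lo_) / (n_ - 1)), n(n_),
      V(n_, 0.0), dV(n_, 0.0) {}
  double interp(const std::vector<double>& g, double s) const {
    if (s <= lo) return g[0];
    if (s >= hi) return g[n - 1];
    double t = (s - lo) / dx;
    int i = (int)t;
    if (i >= n - 1) i = n - 2;
    double f = t - i;
    return g[i] * (1.0 - f) + g[i + 1] * f;
  }
  double value(double s) const { return interp(V, s); }
  double deriv(double s) const { return interp(dV, s); }
  void add_hill(double c, double sigma, double h) {
    for (int i = 0; i < n; ++i) {
      double x = lo + i * dx, d = x - c;
      double g = h * std::exp(-0.5 * d * d / (sigma * sigma));
      V[i] += g;
      dV[i] += -d / (sigma * sigma) * g;
    }
  }
};

// Multiple-walker well-tempered metadynamics on one CV of the 2D surface.
// gamma <= 0 encodes an infinite bias factor (standard metadynamics).
// [[Rcpp::export]]
List metad_cpp(NumericVector par, int bias_cv, double w0, double sigma,
               int pace, double gamma, int n_walkers, int share,
               NumericVector grid_spec, NumericMatrix x0, double dt,
               double friction, double kT, int n_steps, int stride,
               double guard) {
  Surface S(par);
  BiasGrid glob(grid_spec[0], grid_spec[1], (int)grid_spec[2]);
  std::vector<double> xi(n_walkers), phi(n_walkers);
  for (int w = 0; w < n_walkers; ++w) {
    xi[w] = x0(w, 0);
    phi[w] = x0(w, 1);
    reflect01(phi[w]);
  }
  double noise = std::sqrt(2.0 * kT * dt / friction);
  int n_out = n_steps / stride;
  std::vector<NumericMatrix> series;
  for (int w = 0; w < n_walkers; ++w)
    series.push_back(NumericMatrix(n_out, 4));
  std::vector<int> rows(n_walkers, 0);
  std::vector<double> h_time, h_center, h_height;
  std::vector<int> h_walker;
  RNGScope scope;

  int done = 0;
  while (done < n_steps) {
    int chunk = std::min(share, n_steps - done);
    // pending hills deposited during this chunk, merged into the shared
    // bias only at the next share boundary
    std::vector<double> p_c, p_h;
    std::vector<int> p_w;
    std::vector<double> p_t;
    for (int w = 0; w < n_walkers; ++w) {
      BiasGrid mine = glob;             // walker's refreshed private view
      for (int k = 1; k <= chunk; ++k) {
        int step = done + k;
        double gx, gp;
        S.grad(xi[w], phi[w], gx, gp);
        double s = (bias_cv == 0) ? xi[w] : phi[w];
        double gb = mine.deriv(s);
        if (bias_cv == 0) gx += gb; else gp += gb;
        xi[w] += -gx / friction * dt + noise * norm_rand();
        phi[w] += -gp / friction * dt + noise * norm_rand();
        reflect01(phi[w]);
        double u = (xi[w] - S.xi_R) / S.span;
        if (u < -guard || u > 1.0 + guard)
          stop("walker %d diverged at step %d (xi = %g)", w + 1, step, xi[w]);
        s = (bias_cv == 0) ? xi[w] : phi[w];
        if (step % pace == 0) {
          double h = (gamma > 0.0)
            ? w0 * std::exp(-mine.value(s) / ((gamma - 1.0) * kT))
            : w0;
          mine.add_hill(s, sigma, h);
          p_c.push_back(s); p_h.push_back(h);
          p_w.push_back(w + 1); p_t.push_back(step * dt);
        }
        if (step % stride == 0) {
          series[w](rows[w], 0) = step * dt;
          series[w](rows[w], 1) = xi[w];
          series[w](rows[w], 2) = phi[w];
          series[w](rows[w], 3) = mine.value(s);
          ++rows[w];
        }
      }
    }
    for (size_t i = 0; i < p_c.size(); ++i) {
      glob.add_hill(p_c[i], sigma, p_h[i]);
      h_time.push_back(p_t[i]);
      h_center.push_back(p_c[i]);
      h_height.push_back(p_h[i]);
      h_walker.push_back(p_w[i]);
    }
    done += chunk;
  }

  List ser(n_walkers);
  for (int w = 0; w < n_walkers; ++w) ser[w] = series[w];
  return List::create(
    _["hill_time"] = wrap(h_time), _["hill_center"] = wrap(h_center),
    _["hill_height"] = wrap(h_height), _["hill_walker"] = wrap(h_walker),
    _["series"] = ser);
}
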