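// Euler-Maruyama integration of the coupled translational/orientational
// Langevin equations for a light-activated particle:
//   dx = v_p(I) cos(theta) dt + sqrt(2 D_t dt) g1
//   dy = v_p(I) sin(theta) dt + sqrt(2 D_t dt) g2
//   dtheta = -omega_eff sin(theta - theta_grad) dt + sqrt(2 D_r dt) g3
// with v_p(I) = v_p_max * I / I_ref (clipped below at 0) and theta_grad in
// {0, pi} the direction of the local intensity gradient; the torque is zero
// wherever the gradient vanishes (outside pulse support and at the apex).
#include <Rcpp.h>
using namespace Rcpp;

static inline double wrap_angle(double a) {
  // wrap to (-pi, pi]
  const double twopi = 2.0 * M_PI;
  double r = (a + M_PI) - twopi * std::floor((a + M_PI) / twopi);
  double out = r - M_PI;   // [-pi, pi)
  if (out <= -M_PI) out = M_PI;
  return out;
}

// f_type: 0 = piecewise-linear pulse train (n = 1 gives a single pulse;
//             u = 0 gives a static triangle), 1 = spatially uniform field.
// Pulse k (k = 0 leads) has center f_center - dir * spacing * k + f_u * t,
// spacing = f_w + |f_u| * f_gap, dir = sign(f_u) (or +1 when u = 0).
// [[Rcpp::export]]
NumericMatrix integrate_langevin_cpp(double x0, double y0, double theta0,
                                     double dt, int n_steps, int save_every,
                                     int f_type, double f_center, double f_u,
                                     double f_w, double f_Imax, int f_n,
                                     double f_gap, double f_baseline,
                                     double vp_max, double I_ref,
                                     double D_t, double D_r,
                                     double omega_max, double grad_sat,
                                     NumericMatrix noise) {
  if (n_steps < 1) stop("n_steps must be >= 1");
  if (save_every < 1 || n_steps % save_every != 0)
    stop("n_steps must be a multiple of save_every");
  if (noise.nrow() < n_steps || noise.ncol() < 3)
    stop("noise matrix must have n_steps rows and 3 columns");
  if (I_ref <= 0.0) stop("I_ref must be > 0");

  const double slope = (f_type == 0) ? 2.0 * f_Imax / f_w : 0.0;
  const double spacing = f_w + std::fabs(f_u) * f_gap;
  const double dir = (f_u >= 0.0) ? 1.0 : -1.0;
  const double sq_t = std::sqrt(2.0 * D_t * dt);
  const double sq_r = std::sqrt(2.0 * D_r * dt);
  const bool ramp = R_finite(grad_sat) && grad_sat > 0.0;

  const int n_out = n_steps / save_every + 1;
  NumericMatrix out(n_out, 6);
  double x = x0, y = y0, th = theta0;
  int row = 0;

  for (int i = 0; i <= n_steps; ++i) {
    const double t = i * dt;
    double I, g;
    if (f_type == 1) {
      I = f_Imax;
      g = 0.0;
    } else {
      I = f_baseline;
      g = 0.0;
      for (int k = 0; k < f_n; ++k) {
        const double c = f_center - dir * spacing * k + f_u * t;
        const double d = x - c;
        const double ad = std::fabs(d);
        if (ad < 0.5 * f_w) {  // pulses never overlap: at most one hit
          I += f_Imax * (1.0 - 2.0 * ad / f_w);
          if (d > 0.0) g = -slope;
          else if (d < 0.0) g = slope;
          break;
        }
      }
    }
    double vp = vp_max * I / I_ref;
    if (vp < 0.0) vp = 0.0;

    if (i % save_every == 0) {
      out(row, 0) = t;
      out(row, 1) = x;
      out(row, 2) = y;
      out(row, 3) = th;
      out(row, 4) = I;
      out(row, 5) = vp;
      ++row;
    }
    if (i == n_steps) break;

    double torque = 0.0;
    if (g != 0.0) {
      double om = omega_max;
      if (ramp) {
        const double f = std::fabs(g) / grad_sat;
        if (f < 1.0) om *= f;
      }
      const double th_grad = (g > 0.0) ? 0.0 : M_PI;
      torque = -om * std::sin(th - th_grad);
    }
    x += vp * std::cos(th) * dt + sq_t * noise(i, 0);
    y += vp * std::sin(th) * dt + sq_t * noise(i, 1);
    th = wrap_angle(th + torque * dt + sq_r * noise(i, 2));
  }
  colnames(out) = CharacterVector::create("t", "x", "y", "theta",
                                          "intensity", "v_p");
  return out;
}
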