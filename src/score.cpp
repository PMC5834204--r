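// Closed-form damped two-spring ball flight and throw scoring.
//
// The ball obeys x(t) = Ax sin(omega t + phix) exp(-t/tau) (same for y).
// For scoring it is more convenient to write each axis as
//   x(t) = exp(-t/tau) * (Px cos(omega t) + Qx sin(omega t))
// with Px = x(0) and Qx = (vx(0) + x(0)/tau) / omega, which follows from
// matching position and velocity at release. The throw error is the
// minimum distance between the flight path and the target centre over one
// oscillation period, truncated at the first post contact; it is located
// by a coarse scan (default 1 ms) followed by golden-section refinement.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double dist2_target(double t, double Px, double Qx,
                                  double Py, double Qy, double omega,
                                  double invtau, double tx, double ty) {
  double E = invtau > 0.0 ? std::exp(-t * invtau) : 1.0;
  double c = std::cos(omega * t), s = std::sin(omega * t);
  double dx = E * (Px * c + Qx * s) - tx;
  double dy = E * (Py * c + Qy * s) - ty;
  return dx * dx + dy * dy;
}

// [[Rcpp::export]]
List score_states_cpp(NumericVector x0, NumericVector y0,
                      NumericVector vx0, NumericVector vy0,
                      double omega, double tau,
                      double tx, double ty,
                      double px, double py,
                      double contact_radius, bool has_post,
                      double t_end, double coarse_dt, double refine_tol) {
  const int n = x0.size();
  const double invtau = std::isinf(tau) ? 0.0 : 1.0 / tau;
  const double cr2 = contact_radius * contact_radius;

  // shared coarse time grid (all states share omega, tau, t_end);
  // cos/sin and the damping factor advance by per-step recurrences so the
  // scan stays in registers
  int nt = (int)std::floor(t_end / coarse_dt) + 1;
  std::vector<double> tg(nt + 1);
  for (int k = 0; k < nt; ++k) tg[k] = k * coarse_dt;
  tg[nt] = t_end;
  const double cd = std::cos(omega * coarse_dt);
  const double sd = std::sin(omega * coarse_dt);
  const double ed = invtau > 0.0 ? std::exp(-coarse_dt * invtau) : 1.0;

  NumericVector err(n), tmin(n);
  LogicalVector hit_post(n);
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;

  for (int i = 0; i < n; ++i) {
    const double Px = x0[i], Py = y0[i];
    const double Qx = (vx0[i] + x0[i] * invtau) / omega;
    const double Qy = (vy0[i] + y0[i] * invtau) / omega;

    bool contact = false;
    double t_last = t_end;      // end of the untruncated portion
    double best = R_PosInf, t_best = 0.0;
    int k_best = 0, k_stop = nt;

    double c = 1.0, s = 0.0, E = 1.0;
    for (int k = 0; k <= nt; ++k) {
      if (k > 0) {
        double cn = c * cd - s * sd;
        s = s * cd + c * sd;
        c = cn;
        E *= ed;
      }
      if (k == nt) {  // final point sits at t_end exactly
        c = std::cos(omega * t_end);
        s = std::sin(omega * t_end);
        E = invtau > 0.0 ? std::exp(-t_end * invtau) : 1.0;
      }
      double xb = E * (Px * c + Qx * s);
      double yb = E * (Py * c + Qy * s);
      if (has_post) {
        double dpx = xb - px, dpy = yb - py;
        if (dpx * dpx + dpy * dpy < cr2) {
          contact = true;
          if (k == 0) {
            t_last = 0.0;
            k_stop = 0;
            double d2 = (xb - tx) * (xb - tx) + (yb - ty) * (yb - ty);
            best = d2; t_best = 0.0; k_best = 0;
            break;
          }
          // bisect the contact time within (tg[k-1], tg[k]), then snap
          // down to the 0.01 ms contact-resolution grid so the end of
          // the untruncated portion is a well-defined sample
          double lo = tg[k - 1], hi = tg[k];
          for (int it = 0; it < 40; ++it) {
            double mid = 0.5 * (lo + hi);
            double Em = invtau > 0.0 ? std::exp(-mid * invtau) : 1.0;
            double cm = std::cos(omega * mid), sm = std::sin(omega * mid);
            double xm = Em * (Px * cm + Qx * sm) - px;
            double ym = Em * (Py * cm + Qy * sm) - py;
            if (xm * xm + ym * ym < cr2) hi = mid; else lo = mid;
          }
          t_last = std::floor(lo / 1e-5) * 1e-5;
          k_stop = k - 1;
          break;
        }
      }
      double dx = xb - tx, dy = yb - ty;
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; t_best = tg[k]; k_best = k; }
    }

    if (!(contact && k_stop == 0)) {
      // refine within the bracketing coarse interval, clipped to the
      // untruncated portion
      double lo = k_best > 0 ? tg[k_best - 1] : 0.0;
      double hi = k_best < k_stop ? tg[k_best + 1] : t_last;
      if (hi > t_last) hi = t_last;
      double a = lo, b = hi;
      double c1 = b - gr * (b - a), c2 = a + gr * (b - a);
      double f1 = dist2_target(c1, Px, Qx, Py, Qy, omega, invtau, tx, ty);
      double f2 = dist2_target(c2, Px, Qx, Py, Qy, omega, invtau, tx, ty);
      while (b - a > refine_tol) {
        if (f1 < f2) {
          b = c2; c2 = c1; f2 = f1;
          c1 = b - gr * (b - a);
          f1 = dist2_target(c1, Px, Qx, Py, Qy, omega, invtau, tx, ty);
        } else {
          a = c1; c1 = c2; f1 = f2;
          c2 = a + gr * (b - a);
          f2 = dist2_target(c2, Px, Qx, Py, Qy, omega, invtau, tx, ty);
        }
      }
      double t_ref = 0.5 * (a + b);
      double f_ref = dist2_target(t_ref, Px, Qx, Py, Qy, omega, invtau,
                                  tx, ty);
      double f_lo = dist2_target(lo, Px, Qx, Py, Qy, omega, invtau, tx, ty);
      double f_hi = dist2_target(hi, Px, Qx, Py, Qy, omega, invtau, tx, ty);
      if (f_ref < best) { best = f_ref; t_best = t_ref; }
      if (f_lo < best)  { best = f_lo;  t_best = lo; }
      if (f_hi < best)  { best = f_hi;  t_best = hi; }
    }

    err[i] = std::sqrt(best);
    tmin[i] = t_best;
    hit_post[i] = contact;
  }

  return List::create(_["error"] = err, _["post_hit"] = hit_post,
                      _["t_min"] = tmin);
}
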