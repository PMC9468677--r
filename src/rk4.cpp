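#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// state y = (x, z, phi, V); independent variable is the arc length s
static inline void shape_deriv(double b, double c, const double y[4],
                               double d[4]) {
  double sp = std::sin(y[2]);
  d[0] = std::cos(y[2]);
  d[1] = sp;
  d[2] = 2.0 * b + c * y[1] - sp / y[0];
  d[3] = M_PI * y[0] * y[0] * sp;
}

// Fixed-step classical RK4 integration of the axisymmetric shape
// equation from the apex series state until phi crosses pi.  The
// crossing is located by linear interpolation inside the final step.
// Used as the independent reference for the adaptive integrator.
// [[Rcpp::export]]
List rk4_shape_cpp(double b, double c, double step, double s0,
                   double max_arc, int thin) {
  if (thin < 1) thin = 1;
  double y[4] = {s0, b * s0 * s0 / 2.0, b * s0,
                 M_PI * b * std::pow(s0, 4) / 4.0};
  double s = s0;
  double xmax = y[0];
  std::vector<double> S, X, Z, P;
  S.push_back(s); X.push_back(y[0]); Z.push_back(y[1]); P.push_back(y[2]);

  double k1[4], k2[4], k3[4], k4[4], yt[4];
  bool closed = false;
  long iter = 0;
  double yprev[4], sprev;

  while (s < max_arc) {
    sprev = s;
    for (int i = 0; i < 4; ++i) yprev[i] = y[i];

    shape_deriv(b, c, y, k1);
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + 0.5 * step * k1[i];
    shape_deriv(b, c, yt, k2);
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + 0.5 * step * k2[i];
    shape_deriv(b, c, yt, k3);
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + step * k3[i];
    shape_deriv(b, c, yt, k4);
    for (int i = 0; i < 4; ++i)
      y[i] += step / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    s += step;
    ++iter;

    if (y[0] > xmax) xmax = y[0];

    if (y[2] >= M_PI) {
      // linear interpolation of the crossing within the step
      double f = (M_PI - yprev[2]) / (y[2] - yprev[2]);
      double st = sprev + f * (s - sprev);
      double yi[4];
      for (int i = 0; i < 4; ++i) yi[i] = yprev[i] + f * (y[i] - yprev[i]);
      S.push_back(st); X.push_back(yi[0]); Z.push_back(yi[1]);
      P.push_back(M_PI);
      closed = true;
      return List::create(
          _["s"] = S, _["x"] = X, _["z"] = Z, _["phi"] = P,
          _["h"] = yi[1], _["w"] = 2.0 * xmax, _["v"] = yi[3],
          _["s_end"] = st, _["x_end"] = yi[0], _["closed"] = closed);
    }
    if (iter % thin == 0) {
      S.push_back(s); X.push_back(y[0]); Z.push_back(y[1]); P.push_back(y[2]);
    }
  }
  return List::create(
      _["s"] = S, _["x"] = X, _["z"] = Z, _["phi"] = P,
      _["h"] = y[1], _["w"] = 2.0 * xmax, _["v"] = y[3],
      _["s_end"] = s, _["x_end"] = y[0], _["closed"] = closed);
}
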