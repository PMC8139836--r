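#include <Rcpp.h>
using namespace Rcpp;

// Reduced circuit right-hand side. `drive` is alpha * Iinput.
static inline void derivs(double V1, double V2, double drive,
                          const double *p, double *dV1, double *dV2) {
  // p: 0 tau1, 1 tau2, 2 gL1, 3 gL2, 4 wfb, 5 w21, 6 k1, 7 k2, 8 k3,
  //    9 beta1, 10 beta2, 11 beta2p, 12 gamma1, 13 gamma2, 14 C1, 15 C2,
  //    16 form (0 = odd, 1 = literal)
  double f12 = p[4] / (1.0 + std::exp(-p[6] * (V2 - p[9])));
  double fwd = p[12] / (1.0 + std::exp(-p[7] * (V1 - p[10])));
  double rev_sign = (p[16] == 0.0) ? -1.0 : 1.0;
  double rev = p[13] / (1.0 + std::exp(-rev_sign * p[8] * (V1 - p[11])));
  double f21 = p[5] * (fwd - rev);
  *dV1 = (-p[2] * V1 + drive + f12 + p[14]) / p[0];
  *dV2 = (-p[3] * V2 + f21 + p[15]) / p[1];
}

static inline void rk4(double *V1, double *V2, double drive,
                       const double *p, double h) {
  double a1, a2, b1, b2, c1, c2, d1, d2;
  derivs(*V1, *V2, drive, p, &a1, &a2);
  derivs(*V1 + h / 2 * a1, *V2 + h / 2 * a2, drive, p, &b1, &b2);
  derivs(*V1 + h / 2 * b1, *V2 + h / 2 * b2, drive, p, &c1, &c2);
  derivs(*V1 + h * c1, *V2 + h * c2, drive, p, &d1, &d2);
  *V1 += h / 6 * (a1 + 2 * b1 + 2 * c1 + d1);
  *V2 += h / 6 * (a2 + 2 * b2 + 2 * c2 + d2);
}

static inline double wrap_angle(double th) {
  // to [-pi, pi)
  return th - 2.0 * M_PI * std::floor((th + M_PI) / (2.0 * M_PI));
}

// Agent stepper. Consumes R's RNG in the same order as the R reference
// engine: one normal deviate per step (sensor noise), one uniform per
// reversal-to-run transition (new heading), plus one uniform up front for
// the initial heading.
// [[Rcpp::export]]
List agent_sim_cpp(int tmax, double step_dt, double speed, double cT,
                   int sense_lag, double noise_sd, double alpha,
                   int nsub, NumericVector par) {
  const double *p = par.begin();
  double h = step_dt / nsub;
  NumericVector x(tmax), y(tmax), heading(tmax), temperature(tmax),
      iinput(tmax), v1s(tmax), v2s(tmax);
  IntegerVector motor(tmax);
  std::vector<double> xhist(tmax + 1, 0.0);  // xhist[t] = x after step t
  double th = R::runif(-M_PI, M_PI);
  double V1 = 1.0, V2 = 1.0;
  int M = 1;
  double cx = 0.0, cy = 0.0;
  for (int t = 0; t < tmax; ++t) {
    // cx is the position after step t-1; sensing compares it with the
    // position sense_lag steps earlier (origin before the start).
    int lag_idx = t - 1 - sense_lag;
    double xlag = (lag_idx < 0) ? 0.0 : xhist[lag_idx];
    double Iraw = cT * (cx - xlag);
    double eps = norm_rand() * noise_sd;
    double I = Iraw + eps;
    double drive = alpha * I;
    for (int j = 0; j < nsub; ++j) rk4(&V1, &V2, drive, p, h);
    if (!std::isfinite(V1) || !std::isfinite(V2))
      stop("non-finite circuit state at step %d", t + 1);
    int Mnew = (V2 > 0) ? 1 : ((V2 < 0) ? 0 : M);
    if (Mnew != M) {
      if (Mnew == 0) th = wrap_angle(th + M_PI);
      else th = R::runif(-M_PI, M_PI);
    }
    M = Mnew;
    cx += speed * step_dt * std::cos(th);
    cy += speed * step_dt * std::sin(th);
    xhist[t] = cx;
    x[t] = cx;
    y[t] = cy;
    heading[t] = th * 180.0 / M_PI;
    motor[t] = M;
    temperature[t] = cT * cx;
    iinput[t] = I;
    v1s[t] = V1;
    v2s[t] = V2;
  }
  return List::create(_["x"] = x, _["y"] = y, _["heading_deg"] = heading,
                      _["motor_state"] = motor,
                      _["temperature"] = temperature, _["Iinput"] = iinput,
                      _["V1"] = v1s, _["V2"] = v2s);
}
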