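#include <Rcpp.h>
using namespace Rcpp;

// Delay-coupled Kuramoto integrator (explicit Euler).
//
//   dtheta_n/dt = omega_n + k * sum_p C_np sin(theta_p(t - D_np) - theta_n(t))
//
// Delays are given in integer steps; the phase history is kept in a ring
// buffer of max_delay + 1 rows. History before t = 0 is initialized by
// backward free rotation, theta_n(-s dt) = theta_n(0) - omega_n * s * dt.
// Phases are stored (wrapped to (-pi, pi]) every store_stride steps after
// the transient. The zero-delay branch performs the identical summation
// order so that a delay matrix of zeros reproduces it bit for bit.

static inline double wrap_pi(double x) {
  const double two_pi = 2.0 * M_PI;
  double y = x - two_pi * std::floor((x + M_PI) / two_pi);
  if (y > M_PI) y -= two_pi;    // guard against rounding at the boundary
  if (y < -M_PI) y += two_pi;
  return y;
}

// [[Rcpp::export(name = ".kuramoto_core")]]
List kuramoto_core(NumericMatrix C, IntegerMatrix delay_steps,
                   NumericVector omega, NumericVector theta0,
                   double k, double dt,
                   int n_steps, int transient_steps, int store_stride) {
  const int N = C.nrow();
  if (C.ncol() != N || delay_steps.nrow() != N || delay_steps.ncol() != N)
    stop("coupling and delay matrices must be N x N");
  if (omega.size() != N || theta0.size() != N)
    stop("omega and theta0 must have length N");
  if (dt <= 0 || n_steps <= 0 || store_stride <= 0)
    stop("dt, n_steps and store_stride must be positive");
  if (transient_steps < 0 || transient_steps >= n_steps)
    stop("transient_steps must be in [0, n_steps)");

  int max_delay = 0;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) {
      if (delay_steps(i, j) < 0) stop("negative delay step");
      if (delay_steps(i, j) > max_delay) max_delay = delay_steps(i, j);
    }
  const bool delayed = max_delay > 0;
  const int buf_len = max_delay + 1;

  // ring buffer: buf[b * N + n] = theta_n at buffered time slot b
  std::vector<double> buf((size_t)buf_len * N);
  for (int s = 0; s < buf_len; ++s)  // slot s holds t = -(s) steps initially
    for (int n = 0; n < N; ++n)
      buf[(size_t)s * N + n] = theta0[n] - omega[n] * (double)s * dt;
  int head = 0;  // slot holding the current time

  const int n_stored = (n_steps - transient_steps + store_stride - 1) / store_stride;
  NumericMatrix stored(N, n_stored);
  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> dtheta(N);

  int out_col = 0;
  for (int step = 0; step < n_steps; ++step) {
    // record state at the start of the step (t = step * dt)
    if (step >= transient_steps && (step - transient_steps) % store_stride == 0) {
      for (int n = 0; n < N; ++n) stored(n, out_col) = wrap_pi(theta[n]);
      ++out_col;
    }
    if (delayed) {
      for (int n = 0; n < N; ++n) {
        double acc = 0.0;
        const double th_n = theta[n];
        for (int p = 0; p < N; ++p) {
          const double c = C(n, p);
          if (c == 0.0) continue;
          const int d = delay_steps(n, p);
          const int slot = (head + d) % buf_len;
          acc += c * std::sin(buf[(size_t)slot * N + p] - th_n);
        }
        dtheta[n] = omega[n] + k * acc;
      }
    } else {
      for (int n = 0; n < N; ++n) {
        double acc = 0.0;
        const double th_n = theta[n];
        for (int p = 0; p < N; ++p) {
          const double c = C(n, p);
          if (c == 0.0) continue;
          acc += c * std::sin(theta[p] - th_n);
        }
        dtheta[n] = omega[n] + k * acc;
      }
    }
    for (int n = 0; n < N; ++n) {
      theta[n] += dt * dtheta[n];
      if (!std::isfinite(theta[n]))
        stop("non-finite phase at step %d, oscillator %d", step, n + 1);
    }
    // advance the ring buffer: new head holds the updated state
    head = (head - 1 + buf_len) % buf_len;
    for (int n = 0; n < N; ++n) buf[(size_t)head * N + n] = theta[n];
  }

  return List::create(_["phases"] = stored, _["n_stored"] = out_col,
                      _["max_delay_steps"] = max_delay);
}
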