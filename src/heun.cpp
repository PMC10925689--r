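#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Six-variable Epileptor right-hand side for one node.
// Diffusive x1 coupling enters the z equation; `coup` is the already-summed
// K * sum_j w(j->i) * (x1_i - x1_j) term (scaled by r or not by the caller).
static inline void epileptor_rhs(const double *u, double coup, double x0,
                                 double I1, double I2, double r, double inv_tau,
                                 double *du) {
  const double x1 = u[0], y1 = u[1], z = u[2], x2 = u[3], y2 = u[4], g = u[5];
  double f1;
  if (x1 < 0.0) {
    f1 = x1 * x1 * x1 - 3.0 * x1 * x1;
  } else {
    const double zm4 = z - 4.0;
    f1 = (x2 - 0.6 * zm4 * zm4) * x1;
  }
  du[0] = y1 - f1 - z + I1;
  du[1] = 1.0 - 5.0 * x1 * x1 - y1;
  double zlin = 4.0 * (x1 - x0) - z;
  if (z < 0.0) {
    const double z2 = z * z;
    zlin -= 0.1 * z2 * z2 * z2 * z; // -0.1 z^7, only on the z < 0 branch
  }
  du[2] = r * zlin + coup;
  const double f2 = (x2 < -0.25) ? 0.0 : 6.0 * (x2 + 0.25);
  du[3] = -y2 + x2 - x2 * x2 * x2 + I2 + 0.002 * g - 0.3 * (z - 3.5);
  du[4] = inv_tau * (-y2 + f2);
  du[5] = -0.01 * (g - 0.1 * x1);
}

// Stochastic Heun integration of N coupled Epileptors.
//
// W is the weight matrix with rows = target, columns = source, so row i holds
// the incoming connections of node i. Additive Gaussian noise of standard
// deviation sigma * sqrt(dt) is applied to the x2 and y2 updates only; the
// same increment is shared by predictor and corrector (additive-noise Heun).
// Noise is drawn from R's RNG so set.seed() governs reproducibility.
//
// Returns matrices sampled every `stride` steps (step 0 included): z and
// lfp = x2 - x1 always; all six state variables when keep_all is true.
// [[Rcpp::export(name = ".heun_epileptor")]]
List heun_epileptor(NumericMatrix W, NumericVector x0,
                    double I1, double I2, double r, double K, double tau,
                    double sigma, double dt, int n_steps, int stride,
                    NumericMatrix init, bool coupling_in_slow, bool keep_all) {
  const int N = W.nrow();
  if (W.ncol() != N) stop("weight matrix must be square");
  if (init.nrow() != 6 || init.ncol() != N) stop("init must be 6 x N");
  if (x0.size() != N) stop("x0 must have one entry per node");
  if (dt <= 0) stop("dt must be positive");
  if (stride < 1) stop("stride must be >= 1");

  const int n_samp = n_steps / stride + 1;
  NumericMatrix z_out(n_samp, N), lfp_out(n_samp, N);
  NumericMatrix x1_out, y1_out, x2_out, y2_out, g_out;
  if (keep_all) {
    x1_out = NumericMatrix(n_samp, N);
    y1_out = NumericMatrix(n_samp, N);
    x2_out = NumericMatrix(n_samp, N);
    y2_out = NumericMatrix(n_samp, N);
    g_out = NumericMatrix(n_samp, N);
  }
  NumericVector times(n_samp);

  std::vector<double> u(6 * N), up(6 * N), k1(6 * N), k2(6 * N);
  std::vector<double> nx2(N), ny2(N), rowsum(N), x1v(N), x1p(N);
  std::vector<double> Wr((size_t)N * N); // row-major copy for fast matvec
  for (int i = 0; i < N; ++i)
    for (int v = 0; v < 6; ++v) u[6 * i + v] = init(v, i);
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int j = 0; j < N; ++j) {
      Wr[(size_t)i * N + j] = W(i, j);
      s += W(i, j);
    }
    rowsum[i] = s;
  }
  const double cscale = coupling_in_slow ? r * K : K;
  const double inv_tau = 1.0 / tau;
  const double sqdt = std::sqrt(dt);
  const bool noisy = sigma > 0.0;
  RNGScope scope;

  int isamp = 0;
  auto record = [&](int step) {
    times[isamp] = step * dt;
    for (int i = 0; i < N; ++i) {
      z_out(isamp, i) = u[6 * i + 2];
      lfp_out(isamp, i) = u[6 * i + 3] - u[6 * i];
      if (keep_all) {
        x1_out(isamp, i) = u[6 * i];
        y1_out(isamp, i) = u[6 * i + 1];
        x2_out(isamp, i) = u[6 * i + 3];
        y2_out(isamp, i) = u[6 * i + 4];
        g_out(isamp, i) = u[6 * i + 5];
      }
    }
    ++isamp;
  };
  record(0);

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < N; ++i) x1v[i] = u[6 * i];
    // predictor
    for (int i = 0; i < N; ++i) {
      double wx = 0.0;
      if (K != 0.0) {
        const double *row = &Wr[(size_t)i * N];
        for (int j = 0; j < N; ++j) wx += row[j] * x1v[j];
      }
      const double coup = cscale * (rowsum[i] * x1v[i] - wx);
      epileptor_rhs(&u[6 * i], coup, x0[i], I1, I2, r, inv_tau, &k1[6 * i]);
    }
    if (noisy)
      for (int i = 0; i < N; ++i) {
        nx2[i] = sigma * sqdt * norm_rand();
        ny2[i] = sigma * sqdt * norm_rand();
      }
    for (int i = 0; i < N; ++i) {
      for (int v = 0; v < 6; ++v) up[6 * i + v] = u[6 * i + v] + dt * k1[6 * i + v];
      if (noisy) {
        up[6 * i + 3] += nx2[i];
        up[6 * i + 4] += ny2[i];
      }
    }
    // corrector
    for (int i = 0; i < N; ++i) x1p[i] = up[6 * i];
    for (int i = 0; i < N; ++i) {
      double wx = 0.0;
      if (K != 0.0) {
        const double *row = &Wr[(size_t)i * N];
        for (int j = 0; j < N; ++j) wx += row[j] * x1p[j];
      }
      const double coup = cscale * (rowsum[i] * x1p[i] - wx);
      epileptor_rhs(&up[6 * i], coup, x0[i], I1, I2, r, inv_tau, &k2[6 * i]);
    }
    for (int i = 0; i < N; ++i) {
      for (int v = 0; v < 6; ++v)
        u[6 * i + v] += 0.5 * dt * (k1[6 * i + v] + k2[6 * i + v]);
      if (noisy) {
        u[6 * i + 3] += nx2[i];
        u[6 * i + 4] += ny2[i];
      }
    }
    if (step % stride == 0) {
      for (int i = 0; i < 6 * N; ++i)
        if (!std::isfinite(u[i])) {
          stop("integration blew up (non-finite state) at t = %f", step * dt);
        }
      record(step);
    }
  }

  List out = List::create(_["times"] = times, _["z"] = z_out, _["lfp"] = lfp_out);
  if (keep_all) {
    out["x1"] = x1_out;
    out["y1"] = y1_out;
    out["x2"] = x2_out;
    out["y2"] = y2_out;
    out["g"] = g_out;
  }
  return out;
}
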