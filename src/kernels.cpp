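#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Unfold a batch of 1-D multichannel signals into a column matrix so that a
// stride-1 "same" convolution becomes a single matrix product.
// x: numeric vector holding an array of dim (C, L, M) in column-major order.
// Output: (C*k) x (L*M); row (j*C + c) holds channel c at kernel offset j,
// with zero padding of width pad on both ends of the length axis.
// [[Rcpp::export]]
NumericMatrix im2col1d(NumericVector x, int C, int L, int M, int k, int pad) {
  NumericMatrix out(C * k, L * M);
  const double *px = x.begin();
  double *po = out.begin();
  int nrow = C * k;
  for (int m = 0; m < M; ++m) {
    const double *xm = px + (size_t)m * C * L;
    for (int l = 0; l < L; ++l) {
      double *col = po + (size_t)(m * L + l) * nrow;
      int lo = l - pad;
      if (lo >= 0 && lo + k <= L) {
        // interior: the whole (C*k) column is one contiguous source block
        std::memcpy(col, xm + (size_t)lo * C, sizeof(double) * nrow);
      } else {
        for (int j = 0; j < k; ++j) {
          int src = lo + j;
          if (src >= 0 && src < L) {
            const double *xs = xm + (size_t)src * C;
            for (int c = 0; c < C; ++c) col[j * C + c] = xs[c];
          }
          // else: stays zero
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col1d: scatter-add a (C*k) x (L*M) gradient back onto the
// (C, L, M) input layout.
// [[Rcpp::export]]
NumericVector col2im1d(NumericMatrix dcol, int C, int L, int M, int k, int pad) {
  NumericVector dx(C * L * M);
  double *pd = dx.begin();
  const double *pc = dcol.begin();
  int nrow = C * k;
  for (int m = 0; m < M; ++m) {
    double *xm = pd + (size_t)m * C * L;
    for (int l = 0; l < L; ++l) {
      const double *col = pc + (size_t)(m * L + l) * nrow;
      int lo = l - pad;
      if (lo >= 0 && lo + k <= L) {
        double *xs = xm + (size_t)lo * C;
        for (int i = 0; i < nrow; ++i) xs[i] += col[i];
      } else {
        for (int j = 0; j < k; ++j) {
          int src = lo + j;
          if (src >= 0 && src < L) {
            double *xs = xm + (size_t)src * C;
            for (int c = 0; c < C; ++c) xs[c] += col[j * C + c];
          }
        }
      }
    }
  }
  return dx;
}

// Fused batch-norm + ReLU + max-pool forward over a conv output.
// Z: (C, L*M) column-major, conceptually (C, L, M). In training mode the
// per-channel mean/var are computed over L*M; in eval mode the supplied
// running statistics are used. Returns pooled activations plus everything
// the backward pass needs.
// [[Rcpp::export]]
List bn_relu_pool_fwd(NumericMatrix Z, int C, int L, int M,
                      NumericVector gamma, NumericVector beta,
                      NumericVector rmean, NumericVector rvar,
                      bool train, double eps, int pool) {
  int np = L * M;
  NumericVector mu(C), var_(C);
  if (train) {
    for (int j = 0; j < np; ++j) {
      const double *z = &Z(0, j);
      for (int c = 0; c < C; ++c) mu[c] += z[c];
    }
    for (int c = 0; c < C; ++c) mu[c] /= np;
    for (int j = 0; j < np; ++j) {
      const double *z = &Z(0, j);
      for (int c = 0; c < C; ++c) {
        double d = z[c] - mu[c];
        var_[c] += d * d;
      }
    }
    for (int c = 0; c < C; ++c) var_[c] /= np;
  } else {
    mu = clone(rmean);
    var_ = clone(rvar);
  }
  NumericVector ivar(C);
  for (int c = 0; c < C; ++c) ivar[c] = 1.0 / std::sqrt(var_[c] + eps);

  int Lp = L / pool;
  NumericMatrix Y(C, Lp * M);
  IntegerVector arg(C * Lp * M);
  std::vector<double> a(C), yb(C);
  for (int m = 0; m < M; ++m) {
    for (int lp = 0; lp < Lp; ++lp) {
      int outj = m * Lp + lp;
      double *y = &Y(0, outj);
      int *ag = &arg[(size_t)outj * C];
      int base = m * L + lp * pool;
      for (int p = 0; p < pool; ++p) {
        const double *z = &Z(0, base + p);
        for (int c = 0; c < C; ++c) {
          double h = gamma[c] * (z[c] - mu[c]) * ivar[c] + beta[c];
          if (h < 0) h = 0;
          if (p == 0 || h > y[c]) { y[c] = h; ag[c] = p + 1; }
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["arg"] = arg, _["mu"] = mu,
                      _["var"] = var_, _["ivar"] = ivar);
}

// Fused backward of max-pool + ReLU + batch-norm. dY: (C, Lp*M).
// Recomputes the normalised activations from the cached pre-normalisation
// Z (saved by the forward pass) instead of storing them. Returns dZ
// (C, L*M) plus the gamma/beta gradients.
// [[Rcpp::export]]
List bn_relu_pool_bwd(NumericMatrix dY, IntegerVector arg, NumericMatrix Z,
                      NumericVector mu, NumericVector gamma,
                      NumericVector beta, NumericVector ivar,
                      int C, int L, int M, int pool, bool train) {
  int np = L * M;
  int Lp = L / pool;
  // scatter pool gradient, gate by ReLU: dA is sparse (one position per
  // pooled output, zero where the activation was clipped)
  NumericMatrix dA(C, np);
  for (int m = 0; m < M; ++m) {
    for (int lp = 0; lp < Lp; ++lp) {
      int outj = m * Lp + lp;
      const double *dy = &dY(0, outj);
      const int *ag = &arg[(size_t)outj * C];
      int base = m * L + lp * pool;
      for (int c = 0; c < C; ++c) {
        int j = base + ag[c] - 1;
        double h = gamma[c] * (Z(c, j) - mu[c]) * ivar[c] + beta[c];
        if (h > 0) dA(c, j) += dy[c];
      }
    }
  }
  NumericVector dgamma(C), dbeta(C), s1(C), s2(C);
  for (int j = 0; j < np; ++j) {
    const double *da = &dA(0, j);
    const double *z = &Z(0, j);
    for (int c = 0; c < C; ++c) {
      double v = da[c];
      if (v != 0.0) {
        double xh = (z[c] - mu[c]) * ivar[c];
        dbeta[c] += v;
        dgamma[c] += v * xh;
        double dxh = v * gamma[c];
        s1[c] += dxh;
        s2[c] += dxh * xh;
      }
    }
  }
  NumericMatrix dZ(C, np);
  if (train) {
    for (int j = 0; j < np; ++j) {
      const double *da = &dA(0, j);
      const double *z = &Z(0, j);
      double *dz = &dZ(0, j);
      for (int c = 0; c < C; ++c) {
        double xh = (z[c] - mu[c]) * ivar[c];
        double dxh = da[c] * gamma[c];
        dz[c] = (ivar[c] / np) * (np * dxh - s1[c] - xh * s2[c]);
      }
    }
  } else {
    for (int j = 0; j < np; ++j) {
      const double *da = &dA(0, j);
      double *dz = &dZ(0, j);
      for (int c = 0; c < C; ++c) dz[c] = da[c] * gamma[c] * ivar[c];
    }
  }
  return List::create(_["dZ"] = dZ, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Christov-style adaptive-threshold QRS scan. Operates on a nonnegative
// detection envelope `env` (rectified, smoothed derivative of the filtered
// ECG) sampled at fs Hz. The steep-slope threshold M is re-seeded at 60% of
// the envelope peak of each accepted beat, averaged over the last five
// beats, and decays to half its value over `decay_s` seconds after the
// refractory period, so that smaller subsequent complexes remain
// detectable. Returns 1-based candidate sample indices of envelope maxima.
// [[Rcpp::export]]
IntegerVector qrs_scan(NumericVector env, double fs, double refractory_s,
                       double decay_s, double init_thresh) {
  int n = env.size();
  std::vector<int> peaks;
  if (n == 0) return IntegerVector(0);

  int refr = (int)std::lround(refractory_s * fs);
  int decay_len = std::max(1, (int)std::lround(decay_s * fs));
  int search = (int)std::lround(0.06 * fs); // forward window to localise the max

  // rolling buffer of the last 5 per-beat threshold seeds
  std::vector<double> mbuf;
  double mbase = init_thresh;
  int last = -n; // index of last accepted peak

  int i = 0;
  while (i < n) {
    double thr = mbase;
    int since = i - last;
    if (since > refr) {
      double u = std::min(1.0, (double)(since - refr) / decay_len);
      thr = mbase * (1.0 - 0.5 * u);
    }
    if (env[i] > thr && since > refr) {
      // localise: maximum of env over the next `search` samples
      int jmax = i;
      double vmax = env[i];
      int jend = std::min(n, i + search + 1);
      for (int j = i + 1; j < jend; ++j) {
        if (env[j] > vmax) { vmax = env[j]; jmax = j; }
      }
      peaks.push_back(jmax + 1); // 1-based for R
      last = jmax;
      mbuf.push_back(0.6 * vmax);
      if (mbuf.size() > 5) mbuf.erase(mbuf.begin());
      double s = 0.0;
      for (double v : mbuf) s += v;
      mbase = s / mbuf.size();
      i = jmax + refr; // skip the refractory period
    } else {
      ++i;
    }
  }
  return wrap(peaks);
}
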