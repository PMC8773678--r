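// Conv / max-pool primitives for the patch classifier.
// Tensors are R arrays in [H, W, N, C] layout (column-major, H fastest),
// so the (n, c) spatial block is a contiguous H*W slab at offset
// H*W*(n + N*c). Convolutions are stride-1 with symmetric zero padding
// (k-1)/2; pooling is 2x2 stride 2. Loops run per sample so the working
// set (input slabs + accumulator) stays cache-resident.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".conv_forward")]]
NumericVector conv_forward(NumericVector X, NumericVector Wt,
                           NumericVector b) {
  IntegerVector dx = X.attr("dim");
  IntegerVector dw = Wt.attr("dim");
  const int H = dx[0], W = dx[1], N = dx[2], Cin = dx[3];
  const int k = dw[0], Cout = dw[3];
  const int pad = (k - 1) / 2;
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector out(HW * N * Cout);
  out.attr("dim") = IntegerVector::create(H, W, N, Cout);
  const double *px = X.begin();
  const double *pw = Wt.begin();
  double *po = out.begin();
  std::vector<double> acc(HW);

  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      std::fill(acc.begin(), acc.end(), b[co]);
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xb = px + HW * (n + (R_xlen_t)N * ci);
        const double *wb = pw + (R_xlen_t)k * k * (ci + (R_xlen_t)Cin * co);
        for (int dj = 0; dj < k; ++dj)
          for (int di = 0; di < k; ++di) {
            const double wv = wb[di + k * dj];
            const int oh = di - pad, ow = dj - pad;
            const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
            const int w0 = std::max(0, -ow), w1 = std::min(W, W - ow);
            for (int w = w0; w < w1; ++w) {
              const double *xcol = xb + (R_xlen_t)H * (w + ow) + oh;
              double *ocol = acc.data() + (R_xlen_t)H * w;
              for (int h = h0; h < h1; ++h) ocol[h] += wv * xcol[h];
            }
          }
      }
      std::copy(acc.begin(), acc.end(), po + HW * (n + (R_xlen_t)N * co));
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv_backward")]]
List conv_backward(NumericVector X, NumericVector Wt, NumericVector dOut) {
  IntegerVector dx = X.attr("dim");
  IntegerVector dw = Wt.attr("dim");
  const int H = dx[0], W = dx[1], N = dx[2], Cin = dx[3];
  const int k = dw[0], Cout = dw[3];
  const int pad = (k - 1) / 2;
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector dX(Rf_xlength(X));
  dX.attr("dim") = dx;
  NumericVector dW(Rf_xlength(Wt));
  dW.attr("dim") = dw;
  NumericVector db(Cout);
  const double *px = X.begin();
  const double *pw = Wt.begin();
  const double *pdo = dOut.begin();
  double *pdx = dX.begin();
  double *pdw = dW.begin();
  double *pdb = db.begin();

  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double *dob = pdo + HW * (n + (R_xlen_t)N * co);
      double bacc = 0.0;
      for (R_xlen_t i = 0; i < HW; ++i) bacc += dob[i];
      pdb[co] += bacc;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xb = px + HW * (n + (R_xlen_t)N * ci);
        double *dxb = pdx + HW * (n + (R_xlen_t)N * ci);
        const double *wb = pw + (R_xlen_t)k * k * (ci + (R_xlen_t)Cin * co);
        double *dwb = pdw + (R_xlen_t)k * k * (ci + (R_xlen_t)Cin * co);
        for (int dj = 0; dj < k; ++dj)
          for (int di = 0; di < k; ++di) {
            const double wv = wb[di + k * dj];
            const int oh = di - pad, ow = dj - pad;
            const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
            const int w0 = std::max(0, -ow), w1 = std::min(W, W - ow);
            double wacc = 0.0;
            for (int w = w0; w < w1; ++w) {
              const double *xcol = xb + (R_xlen_t)H * (w + ow) + oh;
              double *dxcol = dxb + (R_xlen_t)H * (w + ow) + oh;
              const double *dcol = dob + (R_xlen_t)H * w;
              for (int h = h0; h < h1; ++h) {
                wacc += xcol[h] * dcol[h];
                dxcol[h] += wv * dcol[h];
              }
            }
            dwb[di + k * dj] += wacc;
          }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".pool_forward")]]
List pool_forward(NumericVector X) {
  IntegerVector dx = X.attr("dim");
  const int H = dx[0], W = dx[1], N = dx[2], C = dx[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * N * C);
  IntegerVector which((R_xlen_t)Ho * Wo * N * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  which.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  const double *px = X.begin();
  double *po = out.begin();
  int *pwh = which.begin();
  const R_xlen_t HW = (R_xlen_t)H * W;
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double *xb = px + HW * (n + (R_xlen_t)N * c);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          const double *cell = xb + (R_xlen_t)H * 2 * wo + 2 * ho;
          double best = cell[0];
          int arg = 0; // ties go to the first maximum: deterministic
          if (cell[1] > best) { best = cell[1]; arg = 1; }
          if (cell[H] > best) { best = cell[H]; arg = 2; }
          if (cell[H + 1] > best) { best = cell[H + 1]; arg = 3; }
          po[o] = best;
          pwh[o] = arg;
        }
    }
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export(name = ".pool_backward")]]
NumericVector pool_backward(NumericVector dOut, IntegerVector which,
                            int H, int W) {
  IntegerVector dd = dOut.attr("dim");
  const int Ho = dd[0], Wo = dd[1], N = dd[2], C = dd[3];
  NumericVector dX((R_xlen_t)H * W * N * C);
  dX.attr("dim") = IntegerVector::create(H, W, N, C);
  const double *pdo = dOut.begin();
  const int *pwh = which.begin();
  double *pdx = dX.begin();
  const R_xlen_t HW = (R_xlen_t)H * W;
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      double *dxb = pdx + HW * (n + (R_xlen_t)N * c);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          const int arg = pwh[o];
          dxb[(R_xlen_t)H * (2 * wo + (arg >> 1)) + 2 * ho + (arg & 1)] +=
            pdo[o];
        }
    }
  return dX;
}

// Fused batch normalization + ReLU. `x` is [H, W, N, C]; statistics are
// per channel over H, W, N. In training mode batch statistics are used and
// the running moments updated; in inference mode the running moments are
// used. Returns the rectified output, the normalized activations (for the
// backward pass), the inverse SD, and the post-activation mask.
// [[Rcpp::export(name = ".bnrelu_forward")]]
List bnrelu_forward(NumericVector X, NumericVector gamma,
                    NumericVector beta, NumericVector run_mean,
                    NumericVector run_var, bool training,
                    double momentum = 0.1, double eps = 1e-5) {
  IntegerVector dx = X.attr("dim");
  const R_xlen_t M = (R_xlen_t)dx[0] * dx[1] * dx[2];
  const int C = dx[3];
  NumericVector out(Rf_xlength(X)), xhat(Rf_xlength(X));
  out.attr("dim") = dx;
  xhat.attr("dim") = dx;
  LogicalVector mask(Rf_xlength(X));
  mask.attr("dim") = dx;
  NumericVector mu(C), istd(C), new_rm(clone(run_mean)),
    new_rv(clone(run_var));
  const double *px = X.begin();
  double *po = out.begin(), *ph = xhat.begin();
  int *pm = mask.begin();
  for (int c = 0; c < C; ++c) {
    const double *xb = px + M * c;
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (R_xlen_t i = 0; i < M; ++i) { s += xb[i]; s2 += xb[i] * xb[i]; }
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
      new_rm[c] = (1 - momentum) * new_rm[c] + momentum * m;
      new_rv[c] = (1 - momentum) * new_rv[c] +
        momentum * v * M / std::max((double)(M - 1), 1.0);
    } else {
      m = run_mean[c];
      v = run_var[c];
    }
    const double is = 1.0 / std::sqrt(v + eps);
    mu[c] = m;
    istd[c] = is;
    const double g = gamma[c], bt = beta[c];
    double *ob = po + M * c, *hb = ph + M * c;
    int *mb = pm + M * c;
    for (R_xlen_t i = 0; i < M; ++i) {
      const double xh = (xb[i] - m) * is;
      hb[i] = xh;
      const double z = g * xh + bt;
      const bool pos = z > 0;
      mb[i] = pos;
      ob[i] = pos ? z : 0.0;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["istd"] = istd,
                      _["mask"] = mask, _["run_mean"] = new_rm,
                      _["run_var"] = new_rv);
}

// Backward pass of the fused block: routes the gradient through the ReLU
// mask, accumulates dgamma/dbeta, and applies the batch-norm backward
// identity dx = gamma*istd*(dz - mean(dz) - xhat*mean(dz*xhat)).
// [[Rcpp::export(name = ".bnrelu_backward")]]
List bnrelu_backward(NumericVector dOut, NumericVector xhat,
                     NumericVector gamma, NumericVector istd,
                     LogicalVector mask) {
  IntegerVector dx = dOut.attr("dim");
  const R_xlen_t M = (R_xlen_t)dx[0] * dx[1] * dx[2];
  const int C = dx[3];
  NumericVector dX(Rf_xlength(dOut)), dgamma(C), dbeta(C);
  dX.attr("dim") = dx;
  const double *pdo = dOut.begin(), *ph = xhat.begin();
  const int *pm = mask.begin();
  double *pdx = dX.begin();
  for (int c = 0; c < C; ++c) {
    const double *dob = pdo + M * c, *hb = ph + M * c;
    const int *mb = pm + M * c;
    double *dxb = pdx + M * c;
    double sdz = 0, sdzh = 0;
    for (R_xlen_t i = 0; i < M; ++i) {
      const double dz = mb[i] ? dob[i] : 0.0;
      dxb[i] = dz; // stash dz
      sdz += dz;
      sdzh += dz * hb[i];
    }
    dgamma[c] = sdzh;
    dbeta[c] = sdz;
    const double gi = gamma[c] * istd[c];
    const double mdz = sdz / M, mdzh = sdzh / M;
    for (R_xlen_t i = 0; i < M; ++i)
      dxb[i] = gi * (dxb[i] - mdz - hb[i] * mdzh);
  }
  return List::create(_["dx"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
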