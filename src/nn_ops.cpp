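// Hot inner loops of the classifiers: valid 1D convolution forward and
// backward via im2col + GEMM. Arrays arrive from R as N x T x Cin
// (batch, time, channel) and weights as K x Cin x F.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::cube as_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  return arma::cube(const_cast<double*>(x.begin()), d[0], d[1], d[2],
                    false, true);
}

// Xcol layout: column (cin * K + k) holds X[, k + t, cin] stacked over
// (n, t); matches matrix(W, K * Cin, F) with k fastest.
static arma::mat im2col(const arma::cube& X, int K) {
  const int N = X.n_rows, T = X.n_cols, Cin = X.n_slices;
  const int Tout = T - K + 1;
  arma::mat Xcol(N * Tout, K * Cin);
  for (int cin = 0; cin < Cin; ++cin) {
    for (int k = 0; k < K; ++k) {
      // contiguous N x Tout block of slice cin starting at column k
      arma::mat blk(const_cast<double*>(X.slice(cin).colptr(k)), N, Tout,
                    false, true);
      Xcol.col(cin * K + k) = arma::vectorise(blk);
    }
  }
  return Xcol;
}

// [[Rcpp::export]]
List cpp_conv1d_forward(NumericVector Xr, NumericVector Wr,
                        NumericVector br) {
  arma::cube X = as_cube(Xr);
  IntegerVector wd = Wr.attr("dim");
  const int K = wd[0], Cin = wd[1], F = wd[2];
  const int N = X.n_rows, T = X.n_cols;
  const int Tout = T - K + 1;
  arma::mat Wmat(const_cast<double*>(Wr.begin()), K * Cin, F, false, true);
  arma::vec b(const_cast<double*>(br.begin()), F, false, true);
  arma::mat Xcol = im2col(X, K);
  arma::mat Y = Xcol * Wmat;
  Y.each_row() += b.t();
  NumericVector Yr(Y.begin(), Y.end());
  Yr.attr("dim") = IntegerVector::create(N, Tout, F);
  NumericVector Xcolr(Xcol.begin(), Xcol.end());
  Xcolr.attr("dim") = IntegerVector::create(N * Tout, K * Cin);
  return List::create(_["Y"] = Yr, _["Xcol"] = Xcolr,
                      _["dims"] = IntegerVector::create(N, T, Cin, K, F));
}

static const double SELU_L = 1.0507009873554804934193349852946;
static const double SELU_A = 1.6732632423543772848170429916717;

// [[Rcpp::export]]
NumericVector cpp_selu(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    y[i] = v > 0 ? SELU_L * v : SELU_L * SELU_A * expm1(v);
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_selu_backward(NumericVector x, NumericVector dy) {
  NumericVector dx(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    dx[i] = dy[i] * (v > 0 ? SELU_L : SELU_L * SELU_A * exp(v));
  }
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// window-2 stride-2 max pooling over the time axis of an N x T x F array
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector Xr) {
  arma::cube X = as_cube(Xr);
  const int N = X.n_rows, T = X.n_cols, F = X.n_slices;
  const int Tout = T / 2;
  arma::cube Y(N, Tout, F);
  LogicalVector mask(N * Tout * F); // true: first of the pair was max
  R_xlen_t idx = 0;
  for (int f = 0; f < F; ++f)
    for (int t = 0; t < Tout; ++t)
      for (int n = 0; n < N; ++n, ++idx) {
        double a = X(n, 2 * t, f), b = X(n, 2 * t + 1, f);
        bool first = a >= b;
        Y(n, t, f) = first ? a : b;
        mask[idx] = first;
      }
  NumericVector Yr(Y.begin(), Y.end());
  Yr.attr("dim") = IntegerVector::create(N, Tout, F);
  return List::create(_["Y"] = Yr, _["mask"] = mask,
                      _["dims"] = IntegerVector::create(N, T, F));
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dYr, LogicalVector mask,
                                    IntegerVector dims) {
  const int N = dims[0], T = dims[1], F = dims[2];
  const int Tout = T / 2;
  arma::cube dY = as_cube(dYr);
  arma::cube dX(N, T, F, arma::fill::zeros);
  R_xlen_t idx = 0;
  for (int f = 0; f < F; ++f)
    for (int t = 0; t < Tout; ++t)
      for (int n = 0; n < N; ++n, ++idx) {
        if (mask[idx]) dX(n, 2 * t, f) = dY(n, t, f);
        else dX(n, 2 * t + 1, f) = dY(n, t, f);
      }
  NumericVector dXr(dX.begin(), dX.end());
  dXr.attr("dim") = IntegerVector::create(N, T, F);
  return dXr;
}

// [[Rcpp::export]]
List cpp_conv1d_backward(NumericVector dYr, NumericVector Wr,
                         NumericVector Xcolr, IntegerVector dims) {
  const int N = dims[0], T = dims[1], Cin = dims[2], K = dims[3],
            F = dims[4];
  const int Tout = T - K + 1;
  arma::mat dY(const_cast<double*>(dYr.begin()), N * Tout, F, false, true);
  arma::mat Wmat(const_cast<double*>(Wr.begin()), K * Cin, F, false, true);
  arma::mat Xcol(const_cast<double*>(Xcolr.begin()), N * Tout, K * Cin,
                 false, true);
  arma::mat dW = Xcol.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dXcol = dY * Wmat.t();
  arma::cube dX(N, T, Cin, arma::fill::zeros);
  for (int cin = 0; cin < Cin; ++cin) {
    for (int k = 0; k < K; ++k) {
      arma::mat blk(dXcol.colptr(cin * K + k), N, Tout, false, true);
      dX.slice(cin).cols(k, k + Tout - 1) += blk;
    }
  }
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = IntegerVector::create(K, Cin, F);
  NumericVector dXr(dX.begin(), dX.end());
  dXr.attr("dim") = IntegerVector::create(N, T, Cin);
  return List::create(_["dX"] = dXr, _["dW"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
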