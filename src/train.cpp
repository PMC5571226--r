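// Per-sample back-propagation epoch for the compact 1D CNN.
// Mirrors the R reference implementation exactly: valid-mode convolution
// with weight row layout (k-1)*C + c, tanh activations, average
// sub-sampling by S (truncating the remainder), global average pooling of
// the last conv layer, two fully-connected tanh layers, per-item loss
// sum((out - target)^2).  Weights are updated after each item.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// One epoch over the items in `order` (0-based).  Xflat holds one item per
// column, the column being the column-major flattening of the C0 x L0
// channel matrix.  Returns the updated weights and the summed squared
// error accumulated over the epoch (computed before each item's update).
// [[Rcpp::export]]
Rcpp::List cpp_train_epoch(Rcpp::List convW_in, Rcpp::List convb_in,
                           arma::mat fc1W, arma::vec fc1b,
                           arma::mat fc2W, arma::vec fc2b,
                           const arma::mat& Xflat,
                           const arma::mat& targets,
                           const arma::uvec& order,
                           double eps, int C0, int L0, int K, int S) {
  const int nl = convW_in.size();
  std::vector<mat> W(nl);
  std::vector<vec> b(nl);
  for (int l = 0; l < nl; ++l) {
    W[l] = Rcpp::as<mat>(convW_in[l]);
    b[l] = Rcpp::as<vec>(convb_in[l]);
  }
  double sse = 0.0;

  std::vector<mat> Xc(nl), Y(nl);
  std::vector<int> Pv(nl), Cv(nl), Lv(nl);

  for (uword oi = 0; oi < order.n_elem; ++oi) {
    const uword item = order[oi];
    mat act = reshape(Xflat.col(item), C0, L0);

    // ---- forward
    vec f;
    for (int l = 0; l < nl; ++l) {
      const int C = act.n_rows, L = act.n_cols;
      const int P = L - K + 1;
      const int N = W[l].n_cols;
      Cv[l] = C; Lv[l] = L; Pv[l] = P;
      mat xc(P, C * K);
      for (int k = 0; k < K; ++k)
        for (int c = 0; c < C; ++c)
          for (int p = 0; p < P; ++p)
            xc(p, k * C + c) = act(c, p + k);
      mat y = xc * W[l];
      y.each_row() += b[l].t();
      y = tanh(y);                      // P x N
      Xc[l] = xc; Y[l] = y;
      if (l < nl - 1) {
        const int Q = P / S;
        mat pooled(N, Q);
        for (int n = 0; n < N; ++n)
          for (int q = 0; q < Q; ++q) {
            double s = 0.0;
            for (int j = 0; j < S; ++j) s += y(q * S + j, n);
            pooled(n, q) = s / S;
          }
        act = pooled;
      } else {
        f = mean(y, 0).t();             // global average pool, length N
      }
    }
    vec h = tanh(fc1W.t() * f + fc1b);
    vec out = tanh(fc2W.t() * h + fc2b);
    vec e = out - targets.row(item).t();
    sse += accu(e % e);

    // ---- backward (per-item loss: sum of squared output errors)
    vec dout = 2.0 * e % (1.0 - out % out);
    mat gfc2W = h * dout.t();
    vec gfc2b = dout;
    vec dh = (fc2W * dout) % (1.0 - h % h);
    mat gfc1W = f * dh.t();
    vec gfc1b = dh;
    vec df = fc1W * dh;                 // gradient at the pooled features

    std::vector<mat> gW(nl);
    std::vector<vec> gb(nl);
    mat d_act;                          // gradient at a layer's input
    for (int l = nl - 1; l >= 0; --l) {
      const int C = Cv[l], P = Pv[l];
      const int N = W[l].n_cols;
      mat dY(P, N);
      if (l == nl - 1) {
        dY.each_row() = (df / P).t();
      } else {
        const int Q = P / S;
        dY.zeros();
        for (int n = 0; n < N; ++n)
          for (int q = 0; q < Q; ++q) {
            const double g = d_act(n, q) / S;
            for (int j = 0; j < S; ++j) dY(q * S + j, n) = g;
          }
      }
      mat dZ = dY % (1.0 - Y[l] % Y[l]);
      gW[l] = Xc[l].t() * dZ;
      gb[l] = sum(dZ, 0).t();
      if (l > 0) {
        mat dXc = dZ * W[l].t();        // P x (C*K)
        d_act.zeros(C, Lv[l]);
        for (int k = 0; k < K; ++k)
          for (int c = 0; c < C; ++c)
            for (int p = 0; p < P; ++p)
              d_act(c, p + k) += dXc(p, k * C + c);
      }
    }

    // ---- per-sample update
    for (int l = 0; l < nl; ++l) {
      W[l] -= eps * gW[l];
      b[l] -= eps * gb[l];
    }
    fc1W -= eps * gfc1W; fc1b -= eps * gfc1b;
    fc2W -= eps * gfc2W; fc2b -= eps * gfc2b;
  }

  Rcpp::List Wout(nl), bout(nl);
  for (int l = 0; l < nl; ++l) { Wout[l] = W[l]; bout[l] = b[l]; }
  return Rcpp::List::create(
    Rcpp::Named("convW") = Wout, Rcpp::Named("convb") = bout,
    Rcpp::Named("fc1W") = fc1W, Rcpp::Named("fc1b") = fc1b,
    Rcpp::Named("fc2W") = fc2W, Rcpp::Named("fc2b") = fc2b,
    Rcpp::Named("sse") = sse);
}

// Batched forward pass (average pooling), same arithmetic as the per-item
// forward inside cpp_train_epoch; used for the per-iteration train-error
// evaluation.  Returns a B x n_outputs matrix.
// [[Rcpp::export]]
arma::mat cpp_forward_batch(Rcpp::List convW_in, Rcpp::List convb_in,
                            const arma::mat& fc1W, const arma::vec& fc1b,
                            const arma::mat& fc2W, const arma::vec& fc2b,
                            const arma::mat& Xflat,
                            int C0, int L0, int K, int S) {
  const int nl = convW_in.size();
  std::vector<mat> W(nl);
  std::vector<vec> b(nl);
  for (int l = 0; l < nl; ++l) {
    W[l] = Rcpp::as<mat>(convW_in[l]);
    b[l] = Rcpp::as<vec>(convb_in[l]);
  }
  const uword B = Xflat.n_cols;
  mat out(B, fc2W.n_cols);
  for (uword item = 0; item < B; ++item) {
    mat act = reshape(Xflat.col(item), C0, L0);
    vec f;
    for (int l = 0; l < nl; ++l) {
      const int C = act.n_rows, L = act.n_cols;
      const int P = L - K + 1;
      const int N = W[l].n_cols;
      mat xc(P, C * K);
      for (int k = 0; k < K; ++k)
        for (int c = 0; c < C; ++c)
          for (int p = 0; p < P; ++p)
            xc(p, k * C + c) = act(c, p + k);
      mat y = xc * W[l];
      y.each_row() += b[l].t();
      y = tanh(y);
      if (l < nl - 1) {
        const int Q = P / S;
        mat pooled(N, Q);
        for (int n = 0; n < N; ++n)
          for (int q = 0; q < Q; ++q) {
            double s = 0.0;
            for (int j = 0; j < S; ++j) s += y(q * S + j, n);
            pooled(n, q) = s / S;
          }
        act = pooled;
      } else {
        f = mean(y, 0).t();
      }
    }
    vec h = tanh(fc1W.t() * f + fc1b);
    out.row(item) = tanh(fc2W.t() * h + fc2b).t();
  }
  return out;
}
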