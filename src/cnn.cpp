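// Minimal CNN engine: valid (no-padding) convolutions via im2col, 2x2
// stride-2 max pooling (ceil or floor mode), ReLU MLP head, softmax
// cross-entropy. Batches are processed image-by-image; gradients are
// averaged over the batch. Everything is deterministic for fixed weights
// and inputs (pooling ties resolve to the first element scanned,
// column-major).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Patch matrix: rows = output positions (r + c*outH, column-major), cols =
// patch entries ordered (channel, patch col, patch row).
static arma::mat im2col(const arma::cube& in, const int k) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const int oh = H - k + 1, ow = W - k + 1;
  arma::mat M(oh * ow, k * k * C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j)
      for (int i = 0; i < k; ++i)
        M.col(c * k * k + j * k + i) =
          arma::vectorise(in.slice(c).submat(i, j, i + oh - 1, j + ow - 1));
  return M;
}

// Adjoint of im2col: scatter-add patch-gradient columns back to the input.
static arma::cube col2im(const arma::mat& dM, const int k,
                         const int H, const int W, const int C) {
  const int oh = H - k + 1, ow = W - k + 1;
  arma::cube dIn(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j)
      for (int i = 0; i < k; ++i) {
        arma::mat patch(dM.colptr(c * k * k + j * k + i), oh, ow);
        dIn.slice(c).submat(i, j, i + oh - 1, j + ow - 1) += patch;
      }
  return dIn;
}

static arma::cube maxpool(const arma::cube& in, const bool ceil_mode,
                          arma::ucube& argmax) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const int oh = ceil_mode ? (H + 1) / 2 : H / 2;
  const int ow = ceil_mode ? (W + 1) / 2 : W / 2;
  arma::cube out(oh, ow, C);
  argmax.set_size(oh, ow, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& S = in.slice(c);
    for (int pc = 0; pc < ow; ++pc) {
      for (int pr = 0; pr < oh; ++pr) {
        const int r0 = 2 * pr, c0 = 2 * pc;
        const int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
        double best = -arma::datum::inf;
        int best_idx = r0 + c0 * H;
        for (int cc = c0; cc <= c1; ++cc)
          for (int rr = r0; rr <= r1; ++rr)
            if (S(rr, cc) > best) { best = S(rr, cc); best_idx = rr + cc * H; }
        out(pr, pc, c) = best;
        argmax(pr, pc, c) = best_idx;
      }
    }
  }
  return out;
}

static arma::cube pool_backward(const arma::cube& dOut, const arma::ucube& argmax,
                                const int H, const int W) {
  const int C = dOut.n_slices;
  arma::cube dIn(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* slice = dIn.slice_memptr(c);
    for (arma::uword k = 0; k < dOut.n_rows * dOut.n_cols; ++k)
      slice[argmax.slice(c)(k)] += dOut.slice(c)(k);
  }
  return dIn;
}

static arma::vec softmax(arma::vec z) {
  z -= z.max();
  arma::vec e = arma::exp(z);
  return e / arma::accu(e);
}

// Forward (and optionally backward) pass over a batch.
// X: H x W x N single-channel images; y: 0-based class labels (ignored when
// want_grad = false and loss not needed, pass -1s). Weights: conv_W[[j]] is
// (k*k*in_ch x out_ch), dense_W[[j]] is (in x out).
// [[Rcpp::export]]
List cnn_batch_cpp(const arma::cube& X, const arma::ivec& y,
                   const List& conv_W, const List& conv_b,
                   const List& dense_W, const List& dense_b,
                   const arma::ivec& kernel_sizes, const bool ceil_pool,
                   const bool want_grad) {
  const int N = X.n_slices;
  const int n_conv = conv_W.size(), n_dense = dense_W.size();
  const int n_classes = as<arma::vec>(dense_b[n_dense - 1]).n_elem;

  std::vector<arma::mat> cW(n_conv), dW(n_dense);
  std::vector<arma::vec> cB(n_conv), dB(n_dense);
  for (int j = 0; j < n_conv; ++j) {
    cW[j] = as<arma::mat>(conv_W[j]); cB[j] = as<arma::vec>(conv_b[j]);
  }
  for (int j = 0; j < n_dense; ++j) {
    dW[j] = as<arma::mat>(dense_W[j]); dB[j] = as<arma::vec>(dense_b[j]);
  }

  std::vector<arma::mat> g_cW(n_conv), g_dW(n_dense);
  std::vector<arma::vec> g_cB(n_conv), g_dB(n_dense);
  if (want_grad) {
    for (int j = 0; j < n_conv; ++j) {
      g_cW[j].zeros(cW[j].n_rows, cW[j].n_cols); g_cB[j].zeros(cB[j].n_elem);
    }
    for (int j = 0; j < n_dense; ++j) {
      g_dW[j].zeros(dW[j].n_rows, dW[j].n_cols); g_dB[j].zeros(dB[j].n_elem);
    }
  }

  arma::mat probs(N, n_classes);
  double loss = 0.0;
  const bool have_labels = (y.n_elem == (arma::uword)N) && (y.min() >= 0);

  for (int n = 0; n < N; ++n) {
    // ---- forward ----
    arma::cube act(X.n_rows, X.n_cols, 1);
    act.slice(0) = X.slice(n);
    std::vector<arma::mat> cols(n_conv);       // im2col inputs (for dW)
    std::vector<arma::cube> preact(n_conv);    // pre-pool ReLU outputs
    std::vector<arma::ucube> argmax(n_conv);
    std::vector<arma::uvec> in_dims(n_conv);   // input dims per conv stage

    for (int j = 0; j < n_conv; ++j) {
      const int k = kernel_sizes[j];
      in_dims[j] = {act.n_rows, act.n_cols, act.n_slices};
      arma::mat M = im2col(act, k);
      arma::mat Z = M * cW[j];
      Z.each_row() += cB[j].t();
      Z.transform([](double v) { return v > 0.0 ? v : 0.0; });   // ReLU
      const int oh = act.n_rows - k + 1, ow = act.n_cols - k + 1;
      arma::cube A(Z.memptr(), oh, ow, cW[j].n_cols);
      cols[j] = std::move(M);
      preact[j] = A;
      act = maxpool(preact[j], ceil_pool, argmax[j]);
    }

    arma::vec flat = arma::vectorise(act);
    std::vector<arma::vec> hidden(n_dense);
    arma::vec a = flat;
    for (int j = 0; j < n_dense; ++j) {
      arma::vec z = dW[j].t() * a + dB[j];
      if (j < n_dense - 1) z.transform([](double v) { return v > 0.0 ? v : 0.0; });
      hidden[j] = z;
      a = z;
    }
    arma::vec p = softmax(hidden[n_dense - 1]);
    probs.row(n) = p.t();
    if (have_labels) loss += -std::log(std::max(p(y[n]), 1e-300));

    if (!want_grad) continue;

    // ---- backward ----
    arma::vec delta = p;
    delta(y[n]) -= 1.0;                         // d loss / d logits
    for (int j = n_dense - 1; j >= 0; --j) {
      const arma::vec& input = (j == 0) ? flat : hidden[j - 1];
      g_dW[j] += input * delta.t();
      g_dB[j] += delta;
      if (j > 0) {
        delta = dW[j] * delta;
        delta %= arma::conv_to<arma::vec>::from(hidden[j - 1] > 0);
      } else {
        delta = dW[j] * delta;                  // gradient w.r.t. flat
      }
    }

    arma::cube dAct(delta.memptr(), act.n_rows, act.n_cols, act.n_slices);
    for (int j = n_conv - 1; j >= 0; --j) {
      arma::cube dPre = pool_backward(dAct, argmax[j],
                                      preact[j].n_rows, preact[j].n_cols);
      // ReLU mask on the conv activation
      for (arma::uword t = 0; t < dPre.n_elem; ++t)
        if (preact[j](t) <= 0.0) dPre(t) = 0.0;
      arma::mat dZ(dPre.memptr(), dPre.n_rows * dPre.n_cols, dPre.n_slices);
      g_cW[j] += cols[j].t() * dZ;
      g_cB[j] += arma::sum(dZ, 0).t();
      if (j > 0) {
        arma::mat dM = dZ * cW[j].t();
        dAct = col2im(dM, kernel_sizes[j],
                      in_dims[j][0], in_dims[j][1], in_dims[j][2]);
      }
    }
  }

  List out = List::create(Named("probs") = probs,
                          Named("loss") = have_labels ? loss / N : NA_REAL);
  if (want_grad) {
    List gcw(n_conv), gcb(n_conv), gdw(n_dense), gdb(n_dense);
    for (int j = 0; j < n_conv; ++j) {
      gcw[j] = g_cW[j] / N; gcb[j] = g_cB[j] / N;
    }
    for (int j = 0; j < n_dense; ++j) {
      gdw[j] = g_dW[j] / N; gdb[j] = g_dB[j] / N;
    }
    out["grad"] = List::create(Named("conv_W") = gcw, Named("conv_b") = gcb,
                               Named("dense_W") = gdw, Named("dense_b") = gdb);
  }
  return out;
}
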