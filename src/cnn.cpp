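// Spatio-temporal 3D convolutional network for per-pixel flow
// classification. Two valid stride-1 3D convolution layers (8 filters of
// 7x7x7, then 8 of 5x5x5, ReLU), one 2x2x2 max-pool, a 128-unit ReLU
// hidden layer and a 2-way soft-max, trained with Adadelta on the
// categorical cross-entropy. Convolutions are evaluated as im2col + GEMM
// in single precision.

#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

namespace {

const int K1 = 7, K2 = 5, C1 = 8, C2 = 8, POOL = 2, NCLASS = 2;

struct Shapes {
  int H, W, T;              // input block
  int a1, b1, t1, n1;       // after conv1
  int a2, b2, t2, n2;       // after conv2
  int a3, b3, t3, F;        // after pool (F = flattened)
  int hidden;
  Shapes(int H_, int W_, int T_, int hidden_) : H(H_), W(W_), T(T_) {
    a1 = H - K1 + 1; b1 = W - K1 + 1; t1 = T - K1 + 1; n1 = a1 * b1 * t1;
    a2 = a1 - K2 + 1; b2 = b1 - K2 + 1; t2 = t1 - K2 + 1; n2 = a2 * b2 * t2;
    a3 = a2 / POOL; b3 = b2 / POOL; t3 = t2 / POOL;
    F = a3 * b3 * t3 * C2;
    hidden = hidden_;
    if (a1 < 1 || b1 < 1 || t1 < 1 || a2 < 1 || b2 < 1 || t2 < 1 ||
        a3 < 1 || b3 < 1 || t3 < 1)
      stop("input block too small for the network's kernels");
  }
};

struct Weights {
  fmat W1, W2, Wh, Wo;
  fvec b1, b2, bh, bo;
};

Weights weights_from_list(const List &w) {
  Weights out;
  out.W1 = arma::conv_to<fmat>::from(as<arma::mat>(w["W1"]));
  out.W2 = arma::conv_to<fmat>::from(as<arma::mat>(w["W2"]));
  out.Wh = arma::conv_to<fmat>::from(as<arma::mat>(w["Wh"]));
  out.Wo = arma::conv_to<fmat>::from(as<arma::mat>(w["Wo"]));
  out.b1 = arma::conv_to<fvec>::from(as<arma::vec>(w["b1"]));
  out.b2 = arma::conv_to<fvec>::from(as<arma::vec>(w["b2"]));
  out.bh = arma::conv_to<fvec>::from(as<arma::vec>(w["bh"]));
  out.bo = arma::conv_to<fvec>::from(as<arma::vec>(w["bo"]));
  return out;
}

List weights_to_list(const Weights &w) {
  return List::create(
      Named("W1") = arma::conv_to<arma::mat>::from(w.W1),
      Named("b1") = arma::conv_to<arma::vec>::from(w.b1),
      Named("W2") = arma::conv_to<arma::mat>::from(w.W2),
      Named("b2") = arma::conv_to<arma::vec>::from(w.b2),
      Named("Wh") = arma::conv_to<arma::mat>::from(w.Wh),
      Named("bh") = arma::conv_to<arma::vec>::from(w.bh),
      Named("Wo") = arma::conv_to<arma::mat>::from(w.Wo),
      Named("bo") = arma::conv_to<arma::vec>::from(w.bo));
}

// Per-sample work buffers, allocated once.
struct Buffers {
  fmat P1, Z1, P2, Z2;
  fvec f, h, dh, df;
  arma::uvec amax;
  Buffers(const Shapes &s) {
    P1.set_size(s.n1, K1 * K1 * K1);
    Z1.set_size(s.n1, C1);
    P2.set_size(s.n2, K2 * K2 * K2 * C1);
    Z2.set_size(s.n2, C2);
    f.set_size(s.F); h.set_size(s.hidden);
    dh.set_size(s.hidden); df.set_size(s.F);
    amax.set_size(s.F);
  }
};

// Min-max normalize the raw block to [0, 1], center to [-0.5, 0.5]
// (zero-mean inputs keep the deep activations well conditioned), and lay
// it out as im2col for conv1.
void im2col1(const double *x, const Shapes &s, bool normalize, fmat &P1) {
  const size_t n = (size_t)s.H * s.W * s.T;
  float lo = 0.0f, scale = 1.0f, shift = 0.0f;
  if (normalize) {
    double mn = x[0], mx = x[0];
    for (size_t i = 1; i < n; ++i) {
      if (x[i] < mn) mn = x[i];
      if (x[i] > mx) mx = x[i];
    }
    lo = (float)mn;
    scale = (mx > mn) ? (float)(1.0 / (mx - mn)) : 0.0f; // constant -> zeros
    shift = 0.5f;
  }
  for (int dt = 0; dt < K1; ++dt)
    for (int dj = 0; dj < K1; ++dj)
      for (int di = 0; di < K1; ++di) {
        const int q = di + K1 * (dj + K1 * dt);
        float *col = P1.colptr(q);
        for (int t = 0; t < s.t1; ++t)
          for (int j = 0; j < s.b1; ++j) {
            const double *src =
                x + (size_t)s.H * ((j + dj) + (size_t)s.W * (t + dt)) + di;
            float *dst = col + (size_t)s.a1 * (j + (size_t)s.b1 * t);
            for (int i = 0; i < s.a1; ++i)
              dst[i] = ((float)src[i] - lo) * scale - shift;
          }
      }
}

// im2col over the conv1 activation volume (n1 x C1) for conv2.
void im2col2(const fmat &A1, const Shapes &s, fmat &P2) {
  for (int ch = 0; ch < C1; ++ch) {
    const float *a = A1.colptr(ch);
    for (int dt = 0; dt < K2; ++dt)
      for (int dj = 0; dj < K2; ++dj)
        for (int di = 0; di < K2; ++di) {
          const int q = di + K2 * (dj + K2 * (dt + K2 * ch));
          float *col = P2.colptr(q);
          for (int t = 0; t < s.t2; ++t)
            for (int j = 0; j < s.b2; ++j) {
              const float *src =
                  a + (size_t)s.a1 * ((j + dj) + (size_t)s.b1 * (t + dt)) + di;
              float *dst = col + (size_t)s.a2 * (j + (size_t)s.b2 * t);
              for (int i = 0; i < s.a2; ++i)
                dst[i] = src[i];
            }
        }
  }
}

// Forward pass; caches stay in buf for the backward pass.
// Returns the two soft-max probabilities.
fvec forward(const double *x, const Shapes &s, const Weights &w,
             bool normalize, Buffers &buf) {
  im2col1(x, s, normalize, buf.P1);
  buf.Z1 = buf.P1 * w.W1;
  buf.Z1.each_row() += w.b1.t();
  buf.Z1.transform([](float v) { return v > 0 ? v : 0.0f; });
  im2col2(buf.Z1, s, buf.P2);
  buf.Z2 = buf.P2 * w.W2;
  buf.Z2.each_row() += w.b2.t();
  buf.Z2.transform([](float v) { return v > 0 ? v : 0.0f; });
  // 2x2x2 max-pool with argmax bookkeeping
  int out = 0;
  for (int ch = 0; ch < C2; ++ch) {
    const float *a = buf.Z2.colptr(ch);
    for (int t = 0; t < s.t3; ++t)
      for (int j = 0; j < s.b3; ++j)
        for (int i = 0; i < s.a3; ++i) {
          float best = -1.0f;
          size_t barg = 0;
          for (int dt = 0; dt < POOL; ++dt)
            for (int dj = 0; dj < POOL; ++dj)
              for (int di = 0; di < POOL; ++di) {
                size_t idx = (size_t)(POOL * i + di) +
                             (size_t)s.a2 * ((POOL * j + dj) +
                             (size_t)s.b2 * (POOL * t + dt));
                if (a[idx] > best) { best = a[idx]; barg = idx; }
              }
          buf.f(out) = best;
          buf.amax(out) = barg + (size_t)s.n2 * ch;
          ++out;
        }
  }
  buf.h = w.Wh.t() * buf.f + w.bh;
  buf.h.transform([](float v) { return v > 0 ? v : 0.0f; });
  fvec o = w.Wo.t() * buf.h + w.bo;
  o -= o.max();
  fvec p = arma::exp(o);
  p /= arma::accu(p);
  return p;
}

// Backward pass from soft-max gradient d (= p - y); accumulates into g.
void backward(const Shapes &s, const Weights &w, Buffers &buf,
              const fvec &d, Weights &g) {
  g.Wo += buf.h * d.t();
  g.bo += d;
  buf.dh = w.Wo * d;
  for (int i = 0; i < s.hidden; ++i)
    if (buf.h(i) <= 0) buf.dh(i) = 0;
  g.Wh += buf.f * buf.dh.t();
  g.bh += buf.dh;
  buf.df = w.Wh * buf.dh;
  // un-pool into dZ2 (reuse Z2 buffer semantics via a scratch matrix)
  fmat dZ2(s.n2, C2, arma::fill::zeros);
  for (int out = 0; out < s.F; ++out) {
    size_t idx = buf.amax(out);
    if (buf.Z2(idx % s.n2, idx / s.n2) > 0)
      dZ2(idx % s.n2, idx / s.n2) += buf.df(out);
  }
  g.W2 += buf.P2.t() * dZ2;
  g.b2 += arma::sum(dZ2, 0).t();
  fmat dP2 = dZ2 * w.W2.t();
  // col2im back onto conv1 activations, through the ReLU mask
  fmat dA1(s.n1, C1, arma::fill::zeros);
  for (int ch = 0; ch < C1; ++ch) {
    float *da = dA1.colptr(ch);
    for (int dt = 0; dt < K2; ++dt)
      for (int dj = 0; dj < K2; ++dj)
        for (int di = 0; di < K2; ++di) {
          const int q = di + K2 * (dj + K2 * (dt + K2 * ch));
          const float *col = dP2.colptr(q);
          for (int t = 0; t < s.t2; ++t)
            for (int j = 0; j < s.b2; ++j) {
              float *dst =
                  da + (size_t)s.a1 * ((j + dj) + (size_t)s.b1 * (t + dt)) + di;
              const float *src = col + (size_t)s.a2 * (j + (size_t)s.b2 * t);
              for (int i = 0; i < s.a2; ++i)
                dst[i] += src[i];
            }
        }
  }
  for (int ch = 0; ch < C1; ++ch) {
    float *da = dA1.colptr(ch);
    const float *z = buf.Z1.colptr(ch);
    for (int i = 0; i < s.n1; ++i)
      if (z[i] <= 0) da[i] = 0;
  }
  g.W1 += buf.P1.t() * dA1;
  g.b1 += arma::sum(dA1, 0).t();
}

void zero_like(const Weights &w, Weights &g) {
  g.W1.zeros(arma::size(w.W1)); g.b1.zeros(arma::size(w.b1));
  g.W2.zeros(arma::size(w.W2)); g.b2.zeros(arma::size(w.b2));
  g.Wh.zeros(arma::size(w.Wh)); g.bh.zeros(arma::size(w.bh));
  g.Wo.zeros(arma::size(w.Wo)); g.bo.zeros(arma::size(w.bo));
}

struct Adadelta {
  Weights Eg, Ed;
  float rho, eps;
  Adadelta(const Weights &w, float rho_, float eps_) : rho(rho_), eps(eps_) {
    zero_like(w, Eg); zero_like(w, Ed);
  }
  void step_one(fmat &w, const fmat &g, fmat &eg, fmat &ed) {
    eg = rho * eg + (1 - rho) * (g % g);
    fmat dx = -(arma::sqrt(ed + eps) / arma::sqrt(eg + eps)) % g;
    ed = rho * ed + (1 - rho) * (dx % dx);
    w += dx;
  }
  void step_vec(fvec &w, const fvec &g, fvec &eg, fvec &ed) {
    eg = rho * eg + (1 - rho) * (g % g);
    fvec dx = -(arma::sqrt(ed + eps) / arma::sqrt(eg + eps)) % g;
    ed = rho * ed + (1 - rho) * (dx % dx);
    w += dx;
  }
  void step(Weights &w, const Weights &g) {
    step_one(w.W1, g.W1, Eg.W1, Ed.W1); step_vec(w.b1, g.b1, Eg.b1, Ed.b1);
    step_one(w.W2, g.W2, Eg.W2, Ed.W2); step_vec(w.b2, g.b2, Eg.b2, Ed.b2);
    step_one(w.Wh, g.Wh, Eg.Wh, Ed.Wh); step_vec(w.bh, g.bh, Eg.bh, Ed.bh);
    step_one(w.Wo, g.Wo, Eg.Wo, Ed.Wo); step_vec(w.bo, g.bo, Eg.bo, Ed.bo);
  }
};

} // namespace

// [[Rcpp::export]]
List cnn_train_cpp(NumericVector blocks, IntegerVector labels, List w0,
                   int hidden, int batch_size, int max_epochs, double tol,
                   int patience, double rho, double eps, int seed,
                   bool normalize, bool verbose) {
  IntegerVector dims = blocks.attr("dim");
  Shapes s(dims[0], dims[1], dims[2], hidden);
  const int N = dims[3];
  const double *x = blocks.begin();
  const size_t stride = (size_t)s.H * s.W * s.T;

  Weights w = weights_from_list(w0);
  Weights g; zero_like(w, g);
  Buffers buf(s);
  Adadelta opt(w, (float)rho, (float)eps);

  std::mt19937 rng((unsigned)seed);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;

  std::vector<double> loss_hist, err_hist;
  int calm = 0, epochs_run = 0;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double loss = 0.0;
    int errors = 0;
    for (int b0 = 0; b0 < N; b0 += batch_size) {
      int bn = std::min(batch_size, N - b0);
      zero_like(w, g);
      for (int k = 0; k < bn; ++k) {
        int i = idx[b0 + k];
        fvec p = forward(x + stride * i, s, w, normalize, buf);
        int y = labels[i];
        loss += -std::log(std::max(p(y), 1e-12f));
        if ((p(1) >= 0.5f) != (y == 1)) ++errors;
        fvec d = p;
        d(y) -= 1.0f;
        d /= (float)bn;
        backward(s, w, buf, d, g);
      }
      opt.step(w, g);
      Rcpp::checkUserInterrupt();
    }
    loss /= N;
    loss_hist.push_back(loss);
    err_hist.push_back((double)errors / N);
    ++epochs_run;
    if (verbose)
      Rcout << "epoch " << epoch + 1 << " loss " << loss
            << " err " << (double)errors / N << "\n";
    if (epoch > 0 && std::abs(loss_hist[epoch] - loss_hist[epoch - 1]) < tol) {
      if (++calm >= patience) break;
    } else {
      calm = 0;
    }
  }
  return List::create(Named("weights") = weights_to_list(w),
                      Named("loss") = wrap(loss_hist),
                      Named("error_rate") = wrap(err_hist),
                      Named("epochs_run") = epochs_run);
}

// Mean cross-entropy loss and its gradient on a data set, for the given
// weights. Used by the training loop's building blocks and by the
// finite-difference gradient check in the test suite.
// [[Rcpp::export]]
List cnn_grad_cpp(NumericVector blocks, IntegerVector labels, List wlist,
                  int hidden, bool normalize) {
  IntegerVector dims = blocks.attr("dim");
  Shapes s(dims[0], dims[1], dims[2], hidden);
  const int N = dims[3];
  const double *x = blocks.begin();
  const size_t stride = (size_t)s.H * s.W * s.T;
  Weights w = weights_from_list(wlist);
  Weights g; zero_like(w, g);
  Buffers buf(s);
  double loss = 0.0;
  for (int i = 0; i < N; ++i) {
    fvec p = forward(x + stride * i, s, w, normalize, buf);
    int y = labels[i];
    loss += -std::log(std::max(p(y), 1e-12f));
    fvec d = p;
    d(y) -= 1.0f;
    d /= (float)N;
    backward(s, w, buf, d, g);
  }
  return List::create(Named("loss") = loss / N,
                      Named("grad") = weights_to_list(g));
}

// [[Rcpp::export]]
NumericVector cnn_predict_cpp(NumericVector blocks, List wlist, int hidden,
                              bool normalize) {
  IntegerVector dims = blocks.attr("dim");
  Shapes s(dims[0], dims[1], dims[2], hidden);
  const int N = dims[3];
  const double *x = blocks.begin();
  const size_t stride = (size_t)s.H * s.W * s.T;
  Weights w = weights_from_list(wlist);
  Buffers buf(s);
  NumericVector out(N);
  for (int i = 0; i < N; ++i) {
    fvec p = forward(x + stride * i, s, w, normalize, buf);
    out[i] = p(1);
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
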