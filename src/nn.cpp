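// Minimal CNN engine for direction-of-migration prediction.
//
// The network is described on the R side as a list of layers
// (conv / maxpool / fc); this file implements forward, backward,
// SGD-with-momentum training, and the attribution backward passes
// (guided backpropagation, deep Taylor decomposition, occlusion).
//
// The engine is templated on the floating type: the training loop is
// instantiated in single precision (sgemm is ~2x dgemm on this class of
// hardware and CNN training is insensitive to it), while forward passes,
// gradient computation for checking, and attribution run in double
// precision so that conservation / gradient identities hold to ~1e-6.
//
// Layout conventions (must match the R side):
//  * images are (H, W, C) arrays, column-major as in R; C = 1 for input.
//  * flattening a (H, W, C) activation uses R's column-major order,
//    i.e. index r + H*c + H*W*ch.
//  * conv weights are (kh, kw, cin, cout) arrays; fc weights (nin, nout).
//  * convolutions are stride 1 with "same" zero padding, odd kernels.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <string>

using namespace Rcpp;

enum LayerType { CONV = 0, POOL = 1, FC = 2 };

template <typename T>
struct Layer {
  int type;
  // conv: Wmat is (K x cout) with K = kh*kw*cin, rows ordered kr + kh*(kc + kw*ch)
  // fc:   Wmat is (nin x nout)
  arma::Mat<T> W;
  arma::Col<T> b;
  int kh = 0, kw = 0, cin = 0, cout = 0, pad = 0;
  int pool = 2;           // pool window == stride
  bool relu = false;
  double dropout = 0.0;   // fc only, applied after activation in training
};

template <typename T>
struct Net {
  std::vector<Layer<T> > layers;
};

// ---------------------------------------------------------------- parsing

template <typename T>
Net<T> parse_net(const List& layers) {
  Net<T> net;
  for (int i = 0; i < layers.size(); ++i) {
    List lay(layers[i]);
    std::string type = as<std::string>(lay["type"]);
    Layer<T> L;
    if (type == "conv") {
      L.type = CONV;
      NumericVector W(lay["W"]);
      IntegerVector dm = W.attr("dim");
      if (dm.size() != 4) stop("conv weight must be a 4-d array");
      L.kh = dm[0]; L.kw = dm[1]; L.cin = dm[2]; L.cout = dm[3];
      if (L.kh % 2 == 0 || L.kw % 2 == 0) stop("conv kernels must be odd-sized");
      L.pad = (L.kh - 1) / 2;
      int K = L.kh * L.kw * L.cin;
      L.W.set_size(K, L.cout);
      for (int j = 0; j < L.cout; ++j)
        for (int k = 0; k < K; ++k)
          L.W(k, j) = static_cast<T>(W[k + K * j]);
      NumericVector b(lay["b"]);
      L.b.set_size(L.cout);
      for (int j = 0; j < L.cout; ++j) L.b[j] = static_cast<T>(b[j]);
      L.relu = as<std::string>(lay["activation"]) == "relu";
    } else if (type == "maxpool") {
      L.type = POOL;
      L.pool = as<int>(lay["size"]);
    } else if (type == "fc") {
      L.type = FC;
      NumericMatrix W(lay["W"]);
      L.W.set_size(W.nrow(), W.ncol());
      for (int j = 0; j < W.ncol(); ++j)
        for (int k = 0; k < W.nrow(); ++k)
          L.W(k, j) = static_cast<T>(W(k, j));
      NumericVector b(lay["b"]);
      L.b.set_size(b.size());
      for (int j = 0; j < b.size(); ++j) L.b[j] = static_cast<T>(b[j]);
      L.relu = as<std::string>(lay["activation"]) == "relu";
      if (lay.containsElementNamed("dropout"))
        L.dropout = as<double>(lay["dropout"]);
    } else {
      stop("unknown layer type '%s'", type.c_str());
    }
    net.layers.push_back(L);
  }
  return net;
}

// Write (possibly updated) weights back into a copy of the R layer list.
template <typename T>
List unparse_net(const Net<T>& net, const List& tmpl) {
  List out = clone(tmpl);
  for (size_t i = 0; i < net.layers.size(); ++i) {
    const Layer<T>& L = net.layers[i];
    if (L.type == POOL) continue;
    List lay(out[i]);
    if (L.type == CONV) {
      NumericVector W(L.kh * L.kw * L.cin * L.cout);
      W.attr("dim") = IntegerVector::create(L.kh, L.kw, L.cin, L.cout);
      int K = L.kh * L.kw * L.cin;
      for (int j = 0; j < L.cout; ++j)
        for (int k = 0; k < K; ++k)
          W[k + K * j] = static_cast<double>(L.W(k, j));
      lay["W"] = W;
    } else {
      NumericMatrix W(L.W.n_rows, L.W.n_cols);
      for (size_t j = 0; j < L.W.n_cols; ++j)
        for (size_t k = 0; k < L.W.n_rows; ++k)
          W(k, j) = static_cast<double>(L.W(k, j));
      lay["W"] = W;
    }
    NumericVector b(L.b.n_elem);
    for (size_t j = 0; j < L.b.n_elem; ++j) b[j] = static_cast<double>(L.b[j]);
    lay["b"] = b;
    out[i] = lay;
  }
  return out;
}

// ---------------------------------------------------------------- im2col

// cols is (Ho*Wo) x K; column block ordering kr + kh*(kc + kw*ch) matches
// the flattened (kh, kw, cin) weight layout. Stride 1, zero padding; only
// the padded border entries are zeroed explicitly, the interior is
// overwritten, so the buffer can be reused across images.
template <typename T>
void im2col(const arma::Cube<T>& in, int kh, int kw, int pad, arma::Mat<T>& cols) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const int HoWo = H * W;
  cols.set_size(HoWo, kh * kw * C);
  for (int ch = 0; ch < C; ++ch) {
    for (int kc = 0; kc < kw; ++kc) {
      for (int kr = 0; kr < kh; ++kr) {
        const int kcol = kr + kh * (kc + kw * ch);
        T* dst = cols.colptr(kcol);
        const int r0 = std::max(0, pad - kr);
        const int r1 = std::min(H, H + pad - kr);
        for (int c = 0; c < W; ++c) {
          const int ic = c + kc - pad;
          if (ic < 0 || ic >= W) {
            std::fill(dst + H * c, dst + H * (c + 1), T(0));
            continue;
          }
          const T* src = in.slice_colptr(ch, ic) + kr - pad;
          if (r0 > 0) std::fill(dst + H * c, dst + H * c + r0, T(0));
          for (int r = r0; r < r1; ++r) dst[r + H * c] = src[r];
          if (r1 < H) std::fill(dst + H * c + r1, dst + H * (c + 1), T(0));
        }
      }
    }
  }
}

// scatter-add inverse of im2col
template <typename T>
void col2im(const arma::Mat<T>& cols, int kh, int kw, int pad, arma::Cube<T>& out) {
  const int H = out.n_rows, W = out.n_cols, C = out.n_slices;
  out.zeros();
  for (int ch = 0; ch < C; ++ch) {
    for (int kc = 0; kc < kw; ++kc) {
      for (int kr = 0; kr < kh; ++kr) {
        const int kcol = kr + kh * (kc + kw * ch);
        const T* src = cols.colptr(kcol);
        for (int c = 0; c < W; ++c) {
          const int ic = c + kc - pad;
          if (ic < 0 || ic >= W) continue;
          const int r0 = std::max(0, pad - kr);
          const int r1 = std::min(H, H + pad - kr);
          T* dst = out.slice_colptr(ch, ic);
          for (int r = r0; r < r1; ++r)
            dst[r + kr - pad] += src[r + H * c];
        }
      }
    }
  }
}

// ---------------------------------------------------------------- forward

// Reusable per-image workspace: all buffers are sized on first use and
// kept across images, so the hot training loop runs without large
// allocations.
template <typename T>
struct Tape {
  std::vector<arma::Cube<T> > act;    // post-activation output of each layer
  std::vector<arma::Mat<T> > cols;    // im2col buffers (conv layers)
  std::vector<arma::uvec> argmax;     // winner indices (pool layers)
  std::vector<arma::Col<T> > dropmask;// dropout masks (fc layers)
  std::vector<arma::Cube<T> > dact;   // backward deltas per layer
  arma::Cube<T> dx;                   // delta at the input
  std::vector<arma::Mat<T> > scratch; // fc outer-product / conv dcols buffers
  void ensure(size_t n) {
    if (act.size() != n) {
      act.resize(n); cols.resize(n); argmax.resize(n);
      dropmask.resize(n); dact.resize(n); scratch.resize(n);
    }
  }
};

template <typename T>
void ensure_cube(arma::Cube<T>& c, size_t r, size_t co, size_t s) {
  if (c.n_rows != r || c.n_cols != co || c.n_slices != s) c.set_size(r, co, s);
}

// fc layers see the input flattened in R column-major order; an (n) vector
// is represented as a (n, 1, 1) cube so every layer maps cube -> cube.
template <typename T>
arma::Col<T> flat(const arma::Cube<T>& a) {
  return arma::vectorise(a);
}


template <typename T>
void forward(const Net<T>& net, const arma::Cube<T>& x, Tape<T>& tape,
             bool store, bool training, double droprate_override,
             std::mt19937* rng) {
  const size_t n = net.layers.size();
  tape.ensure(n);
  const arma::Cube<T>* cur = &x;
  for (size_t i = 0; i < n; ++i) {
    const Layer<T>& L = net.layers[i];
    if (L.type == CONV) {
      if ((int)cur->n_slices != L.cin)
        stop("layer %d expects %d input channels, got %d", (int)i + 1, L.cin,
             (int)cur->n_slices);
      const int HoWo = cur->n_rows * cur->n_cols;
      im2col(*cur, L.kh, L.kw, L.pad, tape.cols[i]);
      ensure_cube(tape.act[i], cur->n_rows, cur->n_cols, L.cout);
      arma::Mat<T> out(tape.act[i].memptr(), HoWo, L.cout, false, true);
      out = tape.cols[i] * L.W;                // gemm straight into act
      for (int j = 0; j < L.cout; ++j) {
        T* p = out.colptr(j);
        const T bj = L.b[j];
        if (L.relu)
          for (int k = 0; k < HoWo; ++k) {
            T v = p[k] + bj;
            p[k] = v > T(0) ? v : T(0);
          }
        else
          for (int k = 0; k < HoWo; ++k) p[k] += bj;
      }
    } else if (L.type == POOL) {
      const int H = cur->n_rows, W = cur->n_cols, C = cur->n_slices;
      const int p = L.pool, Ho = H / p, Wo = W / p;
      ensure_cube(tape.act[i], Ho, Wo, C);
      if (store && tape.argmax[i].n_elem != (size_t)Ho * Wo * C)
        tape.argmax[i].set_size((size_t)Ho * Wo * C);
      arma::uword* am = store ? tape.argmax[i].memptr() : nullptr;
      for (int ch = 0; ch < C; ++ch) {
        const T* in0 = cur->slice_colptr(ch, 0);
        T* o = tape.act[i].slice_colptr(ch, 0);
        for (int c = 0; c < Wo; ++c) {
          for (int r = 0; r < Ho; ++r) {
            size_t bidx = (size_t)(r * p) + (size_t)H * (c * p);
            T best = in0[bidx];
            for (int dc = 0; dc < p; ++dc)
              for (int dr = 0; dr < p; ++dr) {
                size_t idx = (size_t)(r * p + dr) + (size_t)H * (c * p + dc);
                if (in0[idx] > best) { best = in0[idx]; bidx = idx; }
              }
            o[r + Ho * c] = best;
            if (am)
              am[(size_t)r + Ho * c + (size_t)Ho * Wo * ch] =
                bidx + (size_t)H * W * ch;
          }
        }
      }
    } else { // FC
      if (cur->n_elem != L.W.n_rows)
        stop("fc layer %d expects %d features, got %d", (int)i + 1,
             (int)L.W.n_rows, (int)cur->n_elem);
      arma::Col<T> v(const_cast<T*>(cur->memptr()), cur->n_elem, false, true);
      ensure_cube(tape.act[i], L.W.n_cols, 1, 1);
      arma::Col<T> out(tape.act[i].memptr(), tape.act[i].n_elem, false, true);
      out = L.W.t() * v;                       // gemv straight into act
      out += L.b;
      if (L.relu)
        for (size_t j = 0; j < out.n_elem; ++j)
          if (out[j] < T(0)) out[j] = T(0);
      double rate = (L.dropout > 0 && droprate_override >= 0)
                        ? droprate_override : L.dropout;
      if (training && rate > 0 && rng) {
        std::uniform_real_distribution<double> U(0.0, 1.0);
        if (tape.dropmask[i].n_elem != out.n_elem)
          tape.dropmask[i].set_size(out.n_elem);
        const T scale = static_cast<T>(1.0 / (1.0 - rate));
        for (size_t j = 0; j < out.n_elem; ++j)
          tape.dropmask[i][j] = U(*rng) < rate ? T(0) : scale;
        out %= tape.dropmask[i];
      } else {
        tape.dropmask[i].reset();   // eval mode: no mask in the tape
      }
    }
    cur = &tape.act[i];
  }
}

// ---------------------------------------------------------------- backward

template <typename T>
struct Grads {
  std::vector<arma::Mat<T> > dW;
  std::vector<arma::Col<T> > db;
  void init(const Net<T>& net) {
    dW.resize(net.layers.size());
    db.resize(net.layers.size());
    for (size_t i = 0; i < net.layers.size(); ++i) {
      if (net.layers[i].type == POOL) continue;
      dW[i].zeros(net.layers[i].W.n_rows, net.layers[i].W.n_cols);
      db[i].zeros(net.layers[i].b.n_elem);
    }
  }
};

// Backpropagate dlogits for one image, accumulating into g. tape.dact[i]
// holds the delta at layer i's output; buffers are reused across images.
template <typename T>
void backward(const Net<T>& net, const arma::Cube<T>& x, Tape<T>& tape,
              const arma::Col<T>& dlogits, Grads<T>& g) {
  const int n = net.layers.size();
  ensure_cube(tape.dact[n - 1], dlogits.n_elem, 1, 1);
  std::memcpy(tape.dact[n - 1].memptr(), dlogits.memptr(),
              sizeof(T) * dlogits.n_elem);
  for (int i = n - 1; i >= 0; --i) {
    const Layer<T>& L = net.layers[i];
    const arma::Cube<T>& in = (i == 0) ? x : tape.act[i - 1];
    const arma::Cube<T>& out = tape.act[i];
    arma::Cube<T>& d = tape.dact[i];
    arma::Cube<T>& din = (i == 0) ? tape.dx : tape.dact[i - 1];
    ensure_cube(din, in.n_rows, in.n_cols, in.n_slices);
    if (L.type == FC) {
      arma::Col<T> dv(d.memptr(), d.n_elem, false, true);
      if (tape.dropmask[i].n_elem) dv %= tape.dropmask[i];
      if (L.relu) {
        const T* a = out.memptr();
        for (size_t j = 0; j < dv.n_elem; ++j)
          if (a[j] <= T(0)) dv[j] = T(0);
      }
      arma::Col<T> v(const_cast<T*>(in.memptr()), in.n_elem, false, true);
      // outer product through a reused scratch buffer (no per-image alloc)
      if (tape.scratch[i].n_rows != L.W.n_rows ||
          tape.scratch[i].n_cols != L.W.n_cols)
        tape.scratch[i].set_size(L.W.n_rows, L.W.n_cols);
      tape.scratch[i] = v * dv.t();
      g.dW[i] += tape.scratch[i];
      g.db[i] += dv;
      arma::Col<T> dinv(din.memptr(), din.n_elem, false, true);
      dinv = L.W * dv;
    } else if (L.type == POOL) {
      din.zeros();
      const arma::uvec& am = tape.argmax[i];
      const T* dp = d.memptr();
      T* dip = din.memptr();
      for (size_t j = 0; j < am.n_elem; ++j) dip[am[j]] += dp[j];
    } else { // CONV
      const int HoWo = out.n_rows * out.n_cols;
      arma::Mat<T> D(d.memptr(), HoWo, L.cout, false, true);
      if (L.relu) {
        const T* op = out.memptr();
        T* Dp = D.memptr();
        for (size_t j = 0; j < (size_t)HoWo * L.cout; ++j)
          if (op[j] <= T(0)) Dp[j] = T(0);
      }
      g.dW[i] += tape.cols[i].t() * D;
      g.db[i] += arma::sum(D, 0).t();
      if (i > 0) {  // the delta at the input image is never consumed
        arma::Mat<T>& dcols = tape.scratch[i];
        if (dcols.n_rows != (size_t)HoWo || dcols.n_cols != L.W.n_rows)
          dcols.set_size(HoWo, L.W.n_rows);
        dcols = D * L.W.t();
        col2im(dcols, L.kh, L.kw, L.pad, din);
      }
    }
  }
}

// ---------------------------------------------------------------- helpers

template <typename T>
arma::Cube<T> slice_image(const NumericVector& X, int H, int W, R_xlen_t idx) {
  arma::Cube<T> x(H, W, 1);
  const double* p = REAL(X) + (R_xlen_t)H * W * idx;
  for (int j = 0; j < H * W; ++j) x.memptr()[j] = static_cast<T>(p[j]);
  return x;
}

inline void get_dims(const NumericVector& X, int& H, int& W, int& N) {
  if (X.hasAttribute("dim")) {
    IntegerVector dm = X.attr("dim");
    if (dm.size() == 2) { H = dm[0]; W = dm[1]; N = 1; return; }
    if (dm.size() == 3) { H = dm[0]; W = dm[1]; N = dm[2]; return; }
  }
  stop("images must be a (H, W) matrix or (H, W, N) array");
}

template <typename T>
arma::Col<T> softmax(const arma::Col<T>& z) {
  arma::Col<T> p = z - z.max();
  p.transform([](T v) { return std::exp(v); });
  return p / arma::accu(p);
}

// logits for a batch, eval mode
template <typename T>
arma::Mat<T> forward_logits(const Net<T>& net, const NumericVector& X) {
  int H, W, N;
  get_dims(X, H, W, N);
  int K = net.layers.back().b.n_elem;
  arma::Mat<T> logits(N, K);
  Tape<T> tape;
  for (int i = 0; i < N; ++i) {
    arma::Cube<T> x = slice_image<T>(X, H, W, i);
    forward(net, x, tape, false, false, -1.0, nullptr);
    logits.row(i) = flat(tape.act.back()).t();
  }
  return logits;
}

// ---------------------------------------------------------------- exports

// [[Rcpp::export]]
List nn_forward_cpp(List layers, NumericVector X) {
  Net<double> net = parse_net<double>(layers);
  arma::Mat<double> logits = forward_logits(net, X);
  arma::Mat<double> probs(logits.n_rows, logits.n_cols);
  for (size_t i = 0; i < logits.n_rows; ++i)
    probs.row(i) = softmax(arma::Col<double>(logits.row(i).t())).t();
  return List::create(_["logits"] = wrap(logits), _["probs"] = wrap(probs));
}

// Per-layer post-activation outputs for a single image.
// [[Rcpp::export]]
List nn_activations_cpp(List layers, NumericVector X) {
  Net<double> net = parse_net<double>(layers);
  int H, W, N;
  get_dims(X, H, W, N);
  if (N != 1) stop("nn_activations_cpp takes a single image");
  arma::Cube<double> x = slice_image<double>(X, H, W, 0);
  Tape<double> tape;
  forward(net, x, tape, false, false, -1.0, nullptr);
  List out(net.layers.size());
  for (size_t i = 0; i < net.layers.size(); ++i) {
    const arma::Cube<double>& a = tape.act[i];
    NumericVector v(a.n_elem);
    std::memcpy(REAL(v), a.memptr(), sizeof(double) * a.n_elem);
    if (net.layers[i].type == FC)
      v.attr("dim") = R_NilValue;
    else
      v.attr("dim") = IntegerVector::create(a.n_rows, a.n_cols, a.n_slices);
    out[i] = v;
  }
  return out;
}

// Class-weighted softmax cross-entropy loss and weight gradients.
// Weighted-batch normalization: loss = sum_i w_{y_i} l_i / sum_i w_{y_i}.
// [[Rcpp::export]]
List nn_loss_grad_cpp(List layers, NumericVector X, IntegerVector y,
                      NumericVector class_weights) {
  Net<double> net = parse_net<double>(layers);
  int H, W, N;
  get_dims(X, H, W, N);
  if (y.size() != N) stop("label length does not match image count");
  Grads<double> g;
  g.init(net);
  Tape<double> tape;
  double loss = 0, wsum = 0;
  for (int i = 0; i < N; ++i) {
    int yi = y[i];
    if (yi < 0 || yi >= (int)class_weights.size()) stop("label out of range");
    double w = class_weights[yi];
    wsum += w;
  }
  for (int i = 0; i < N; ++i) {
    arma::Cube<double> x = slice_image<double>(X, H, W, i);
    forward(net, x, tape, true, false, -1.0, nullptr);
    arma::Col<double> z = flat(tape.act.back());
    arma::Col<double> p = softmax(z);
    int yi = y[i];
    double w = class_weights[yi];
    loss += -w * std::log(std::max(p[yi], 1e-12));
    arma::Col<double> dl = p;
    dl[yi] -= 1.0;
    dl *= w / wsum;
    backward(net, x, tape, dl, g);
  }
  loss /= wsum;
  List grads(layers.size());
  for (int i = 0; i < layers.size(); ++i) {
    if (net.layers[i].type == POOL) { grads[i] = R_NilValue; continue; }
    List gl = List::create(_["dW"] = wrap(g.dW[i]), _["db"] = wrap(g.db[i]));
    if (net.layers[i].type == CONV) {
      NumericVector dW(gl["dW"]);
      dW.attr("dim") = IntegerVector::create(net.layers[i].kh, net.layers[i].kw,
                                             net.layers[i].cin, net.layers[i].cout);
      gl["dW"] = dW;
    }
    grads[i] = gl;
  }
  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// Full training loop for one fold: SGD with momentum on class-weighted
// softmax loss. batches is a list over epochs, each a list of integer
// vectors of 1-based indices into X. Tracks the running best validation
// MCA and ACA checkpoints (strict improvement, so ties keep the earlier
// epoch). Single precision.
// [[Rcpp::export]]
List nn_train_cpp(List layers, NumericVector X, IntegerVector y,
                  NumericVector Xval, IntegerVector yval, List batches,
                  double lr, double momentum, NumericVector class_weights,
                  double dropout_rate, int seed) {
  typedef float T;
  Net<T> net = parse_net<T>(layers);
  int H, W, N;
  get_dims(X, H, W, N);
  int Hv, Wv, Nv;
  get_dims(Xval, Hv, Wv, Nv);
  const int K = net.layers.back().b.n_elem;
  std::mt19937 rng(static_cast<uint32_t>(seed));

  // momentum buffers
  Grads<T> vel;
  vel.init(net);
  Grads<T> g;
  g.init(net);
  Tape<T> tape;

  const int n_epochs = batches.size();
  NumericVector tr_loss(n_epochs), v_aca(n_epochs), v_mca(n_epochs);
  Net<T> best_mca_net = net, best_aca_net = net;
  double best_mca = -1, best_aca = -1;
  int best_mca_epoch = -1, best_aca_epoch = -1;

  for (int ep = 0; ep < n_epochs; ++ep) {
    Rcpp::checkUserInterrupt();
    List eb(batches[ep]);
    double ep_loss = 0, ep_w = 0;
    for (int bi = 0; bi < eb.size(); ++bi) {
      IntegerVector idx(eb[bi]);
      double wsum = 0;
      for (int j = 0; j < idx.size(); ++j) wsum += class_weights[y[idx[j] - 1]];
      for (size_t li = 0; li < net.layers.size(); ++li) {
        if (net.layers[li].type == POOL) continue;
        g.dW[li].zeros();
        g.db[li].zeros();
      }
      for (int j = 0; j < idx.size(); ++j) {
        const int ii = idx[j] - 1;
        if (ii < 0 || ii >= N) stop("batch index out of range");
        arma::Cube<T> x = slice_image<T>(X, H, W, ii);
        forward(net, x, tape, true, true, dropout_rate, &rng);
        arma::Col<T> z = flat(tape.act.back());
        arma::Col<T> p = softmax(z);
        const int yi = y[ii];
        const double w = class_weights[yi];
        ep_loss += -w * std::log(std::max((double)p[yi], 1e-12));
        ep_w += w;
        arma::Col<T> dl = p;
        dl[yi] -= T(1);
        dl *= static_cast<T>(w / wsum);
        backward(net, x, tape, dl, g);
      }
      for (size_t li = 0; li < net.layers.size(); ++li) {
        if (net.layers[li].type == POOL) continue;
        vel.dW[li] = static_cast<T>(momentum) * vel.dW[li] -
                     static_cast<T>(lr) * g.dW[li];
        vel.db[li] = static_cast<T>(momentum) * vel.db[li] -
                     static_cast<T>(lr) * g.db[li];
        net.layers[li].W += vel.dW[li];
        net.layers[li].b += vel.db[li];
      }
    }
    tr_loss[ep] = ep_w > 0 ? ep_loss / ep_w : NA_REAL;

    // validation metrics
    arma::Mat<T> logits = forward_logits(net, Xval);
    arma::Mat<double> conf(K, K, arma::fill::zeros);
    for (int i = 0; i < Nv; ++i) {
      int pred = 0;
      for (int k = 1; k < K; ++k)
        if (logits(i, k) > logits(i, pred)) pred = k;
      conf(yval[i], pred) += 1;
    }
    double correct = arma::trace(conf), total = arma::accu(conf);
    double aca = 100.0 * correct / total;
    double mca = 0;
    int nk = 0;
    for (int k = 0; k < K; ++k) {
      double rs = arma::accu(conf.row(k));
      if (rs > 0) { mca += conf(k, k) / rs; ++nk; }
    }
    mca = nk > 0 ? 100.0 * mca / nk : NA_REAL;
    v_aca[ep] = aca;
    v_mca[ep] = mca;
    if (mca > best_mca) { best_mca = mca; best_mca_net = net; best_mca_epoch = ep + 1; }
    if (aca > best_aca) { best_aca = aca; best_aca_net = net; best_aca_epoch = ep + 1; }
  }

  return List::create(
      _["final"] = unparse_net(net, layers),
      _["best_mca_model"] = unparse_net(best_mca_net, layers),
      _["best_aca_model"] = unparse_net(best_aca_net, layers),
      _["train_loss"] = tr_loss, _["val_aca"] = v_aca, _["val_mca"] = v_mca,
      _["best_val_mca"] = best_mca, _["best_val_aca"] = best_aca,
      _["best_mca_epoch"] = best_mca_epoch, _["best_aca_epoch"] = best_aca_epoch);
}

// Guided backpropagation (or the plain gradient when guided = FALSE) of a
// single post-activation unit back to pixel space. target_layer is the
// 1-based layer index, target_unit the 1-based column-major index into
// that layer's output array. At every ReLU the guided rule zeroes the
// backward signal where the forward activation was <= 0 or the incoming
// signal is negative; the target layer's own ReLU gate applies too.
// [[Rcpp::export]]
NumericMatrix nn_gbp_cpp(List layers, NumericVector X, int target_layer,
                         int target_unit, bool guided) {
  Net<double> net = parse_net<double>(layers);
  int H, W, N;
  get_dims(X, H, W, N);
  if (N != 1) stop("nn_gbp_cpp takes a single image");
  if (target_layer < 1 || target_layer > (int)net.layers.size())
    stop("target_layer out of range");
  arma::Cube<double> x = slice_image<double>(X, H, W, 0);
  Tape<double> tape;
  forward(net, x, tape, true, false, -1.0, nullptr);

  const int tl = target_layer - 1;
  const arma::Cube<double>& tact = tape.act[tl];
  if (target_unit < 1 || target_unit > (int)tact.n_elem)
    stop("target_unit out of range");
  arma::Cube<double> d(arma::size(tact), arma::fill::zeros);
  d.memptr()[target_unit - 1] = 1.0;

  for (int i = tl; i >= 0; --i) {
    const Layer<double>& L = net.layers[i];
    const arma::Cube<double>& in = (i == 0) ? x : tape.act[i - 1];
    const arma::Cube<double>& out = tape.act[i];
    if (L.type == FC) {
      arma::Col<double> dv = flat(d);
      if (L.relu) {
        arma::Col<double> a = flat(out);
        for (size_t j = 0; j < dv.n_elem; ++j) {
          if (a[j] <= 0) dv[j] = 0;
          if (guided && dv[j] < 0) dv[j] = 0;
        }
      }
      arma::Col<double> dinv = L.W * dv;
      d.set_size(in.n_rows, in.n_cols, in.n_slices);
      std::memcpy(d.memptr(), dinv.memptr(), sizeof(double) * dinv.n_elem);
    } else if (L.type == POOL) {
      arma::Cube<double> din(in.n_rows, in.n_cols, in.n_slices, arma::fill::zeros);
      const arma::uvec& am = tape.argmax[i];
      for (size_t j = 0; j < am.n_elem; ++j) din.memptr()[am[j]] += d.memptr()[j];
      d = std::move(din);
    } else { // CONV
      const int HoWo = out.n_rows * out.n_cols;
      arma::Mat<double> D(HoWo, L.cout);
      std::memcpy(D.memptr(), d.memptr(), sizeof(double) * d.n_elem);
      if (L.relu) {
        const double* op = out.memptr();
        double* Dp = D.memptr();
        for (size_t j = 0; j < (size_t)HoWo * L.cout; ++j) {
          if (op[j] <= 0) Dp[j] = 0;
          if (guided && Dp[j] < 0) Dp[j] = 0;
        }
      }
      arma::Mat<double> dcols = D * L.W.t();
      arma::Cube<double> din(in.n_rows, in.n_cols, in.n_slices);
      col2im(dcols, L.kh, L.kw, L.pad, din);
      d = std::move(din);
    }
  }
  NumericMatrix map(H, W);
  std::memcpy(REAL(map), d.memptr(), sizeof(double) * (size_t)H * W);
  return map;
}

// Deep Taylor decomposition with the z+ rule in hidden layers, the zB rule
// (box constraints l = 0, h = 1) at the input layer, winner-take-all
// routing through max-pooling, and identity through ReLU. Biases are
// excluded from the propagation. Relevance seed: the pre-softmax logit of
// class_index (1-based).
// [[Rcpp::export]]
List nn_dtd_cpp(List layers, NumericVector X, int class_index) {
  Net<double> net = parse_net<double>(layers);
  int H, W, N;
  get_dims(X, H, W, N);
  if (N != 1) stop("nn_dtd_cpp takes a single image");
  arma::Cube<double> x = slice_image<double>(X, H, W, 0);
  Tape<double> tape;
  forward(net, x, tape, true, false, -1.0, nullptr);

  const int n = net.layers.size();
  arma::Col<double> zout = flat(tape.act.back());
  if (class_index < 1 || class_index > (int)zout.n_elem)
    stop("class_index out of range");
  const double Rf = zout[class_index - 1];
  NumericMatrix map(H, W);
  if (Rf <= 0) {
    return List::create(_["map"] = map, _["Rf"] = Rf, _["defined"] = false);
  }

  arma::Cube<double> R(arma::size(tape.act.back()), arma::fill::zeros);
  R.memptr()[class_index - 1] = Rf;

  for (int i = n - 1; i >= 0; --i) {
    const Layer<double>& L = net.layers[i];
    const arma::Cube<double>& in = (i == 0) ? x : tape.act[i - 1];
    const bool input_layer = (i == 0);
    if (L.type == POOL) {
      arma::Cube<double> Rin(in.n_rows, in.n_cols, in.n_slices, arma::fill::zeros);
      const arma::uvec& am = tape.argmax[i];
      for (size_t j = 0; j < am.n_elem; ++j)
        Rin.memptr()[am[j]] += R.memptr()[j];
      R = std::move(Rin);
    } else if (L.type == FC) {
      arma::Col<double> Rv = flat(R);
      arma::Col<double> a = flat(in);
      arma::Col<double> Rin;
      if (!input_layer) {
        arma::Mat<double> Wp = arma::clamp(L.W, 0.0, arma::datum::inf);
        arma::Col<double> z = Wp.t() * a;
        arma::Col<double> S(Rv.n_elem, arma::fill::zeros);
        for (size_t j = 0; j < Rv.n_elem; ++j)
          if (z[j] > 0) S[j] = Rv[j] / z[j];
        Rin = a % (Wp * S);
      } else {
        // zB with l = 0, h = 1
        arma::Mat<double> Wm = arma::clamp(L.W, -arma::datum::inf, 0.0);
        arma::Col<double> z = L.W.t() * a - Wm.t() * arma::ones(a.n_elem);
        arma::Col<double> S(Rv.n_elem, arma::fill::zeros);
        for (size_t j = 0; j < Rv.n_elem; ++j)
          if (z[j] > 0) S[j] = Rv[j] / z[j];
        Rin = a % (L.W * S) - Wm * S;
      }
      R.set_size(in.n_rows, in.n_cols, in.n_slices);
      std::memcpy(R.memptr(), Rin.memptr(), sizeof(double) * Rin.n_elem);
    } else { // CONV
      const arma::Cube<double>& out = tape.act[i];
      const int HoWo = out.n_rows * out.n_cols;
      arma::Mat<double> Rmat(HoWo, L.cout);
      std::memcpy(Rmat.memptr(), R.memptr(), sizeof(double) * R.n_elem);
      const arma::Mat<double>& cols = tape.cols[i];
      arma::Mat<double> S(HoWo, L.cout, arma::fill::zeros);
      arma::Cube<double> Rin(in.n_rows, in.n_cols, in.n_slices);
      if (!input_layer) {
        arma::Mat<double> Wp = arma::clamp(L.W, 0.0, arma::datum::inf);
        arma::Mat<double> z = cols * Wp;
        for (size_t j = 0; j < z.n_elem; ++j)
          if (z.memptr()[j] > 0) S.memptr()[j] = Rmat.memptr()[j] / z.memptr()[j];
        arma::Mat<double> C = S * Wp.t();
        col2im(C, L.kh, L.kw, L.pad, Rin);
        Rin %= in;
      } else {
        arma::Mat<double> Wm = arma::clamp(L.W, -arma::datum::inf, 0.0);
        // z = conv(x, W) - h * conv(1, W-); the ones-image im2col respects
        // zero padding, so border units use the correctly cropped sum.
        arma::Cube<double> ones(in.n_rows, in.n_cols, in.n_slices,
                                arma::fill::ones);
        arma::Mat<double> cols1;
        im2col(ones, L.kh, L.kw, L.pad, cols1);
        arma::Mat<double> z = cols * L.W - cols1 * Wm;
        for (size_t j = 0; j < z.n_elem; ++j)
          if (z.memptr()[j] > 0) S.memptr()[j] = Rmat.memptr()[j] / z.memptr()[j];
        arma::Cube<double> t1(in.n_rows, in.n_cols, in.n_slices);
        arma::Cube<double> t2(in.n_rows, in.n_cols, in.n_slices);
        arma::Mat<double> C1 = S * L.W.t();
        arma::Mat<double> C2 = S * Wm.t();
        col2im(C1, L.kh, L.kw, L.pad, t1);
        col2im(C2, L.kh, L.kw, L.pad, t2);
        Rin = in % t1 - t2;
      }
      R = std::move(Rin);
    }
  }
  std::memcpy(REAL(map), R.memptr(), sizeof(double) * (size_t)H * W);
  return List::create(_["map"] = map, _["Rf"] = Rf, _["defined"] = true);
}

// Occlusion sensitivity: for every pixel, replace the mask_size x mask_size
// window centered there (cropped at borders) by fill_value, run the
// forward pass, and record the negated class score (pre-softmax logit, or
// the softmax probability when use_softmax). Returns the raw map; min-max
// scaling to [0, 255] is done on the R side.
// [[Rcpp::export]]
NumericMatrix nn_occlusion_cpp(List layers, NumericVector X, int mask_size,
                               double fill_value, int class_index,
                               bool use_softmax) {
  // one forward pass per pixel: single precision keeps the sweep fast,
  // and the map is only used through its [0, 255] ranking
  typedef float T;
  Net<T> net = parse_net<T>(layers);
  int H, W, N;
  get_dims(X, H, W, N);
  if (N != 1) stop("nn_occlusion_cpp takes a single image");
  if (mask_size >= H || mask_size >= W) stop("mask must be smaller than the patch");
  arma::Cube<T> x0 = slice_image<T>(X, H, W, 0);
  const int half = mask_size / 2;
  NumericMatrix map(H, W);
  Tape<T> tape;
  const int ci = class_index - 1;
  for (int c = 0; c < W; ++c) {
    Rcpp::checkUserInterrupt();
    for (int r = 0; r < H; ++r) {
      arma::Cube<T> x = x0;
      const int r0 = std::max(0, r - half), r1 = std::min(H - 1, r + half);
      const int c0 = std::max(0, c - half), c1 = std::min(W - 1, c + half);
      x.slice(0).submat(r0, c0, r1, c1).fill(static_cast<T>(fill_value));
      forward(net, x, tape, false, false, -1.0, nullptr);
      arma::Col<T> z = flat(tape.act.back());
      double score = use_softmax ? (double)softmax(z)[ci] : (double)z[ci];
      map(r, c) = -score;
    }
  }
  return map;
}
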