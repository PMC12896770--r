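// Small 2D CNN for 80x41 log-mel inputs: n conv blocks (3x3 kernel,
// padding 1, ReLU, 2x2 max pooling with floor division) followed by fully
// connected layers with ReLU between them and two output scores. Training
// is plain mini-batch SGD with Adam and softmax cross-entropy. Everything
// is deterministic given the init seed and the epoch permutations supplied
// from R.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// portable uniform in (0,1) from a mt19937 (std::uniform_real_distribution
// is implementation-defined, so map the raw 32-bit draws ourselves)
static double unif01(std::mt19937 &g) {
  return (static_cast<double>(g()) + 0.5) / 4294967296.0;
}

struct Net {
  std::vector<mat> conv_w;  // (C_out x 9*C_in)
  std::vector<vec> conv_b;
  std::vector<mat> fc_w;    // (d_out x d_in)
  std::vector<vec> fc_b;
};

static Net net_from_list(const List &params) {
  Net net;
  List cw = params["conv_w"], cb = params["conv_b"];
  List fw = params["fc_w"], fb = params["fc_b"];
  for (int l = 0; l < cw.size(); ++l) {
    net.conv_w.push_back(as<mat>(cw[l]));
    net.conv_b.push_back(as<vec>(cb[l]));
  }
  for (int l = 0; l < fw.size(); ++l) {
    net.fc_w.push_back(as<mat>(fw[l]));
    net.fc_b.push_back(as<vec>(fb[l]));
  }
  return net;
}

static List net_to_list(const Net &net) {
  List cw(net.conv_w.size()), cb(net.conv_b.size());
  for (size_t l = 0; l < net.conv_w.size(); ++l) {
    cw[l] = net.conv_w[l];
    cb[l] = net.conv_b[l];
  }
  List fw(net.fc_w.size()), fb(net.fc_b.size());
  for (size_t l = 0; l < net.fc_w.size(); ++l) {
    fw[l] = net.fc_w[l];
    fb[l] = net.fc_b[l];
  }
  return List::create(_["conv_w"] = cw, _["conv_b"] = cb,
                      _["fc_w"] = fw, _["fc_b"] = fb);
}

// A is (C x H*W), column-major pixel index p = r + c*H.
// cols is (9*C x H*W); kernel offset k = (dc+1)*3 + (dr+1).
static void im2col(const mat &A, int H, int W, mat &cols) {
  const int C = A.n_rows;
  cols.zeros();
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++k) {
      for (int c = 0; c < W; ++c) {
        const int cs = c + dc;
        if (cs < 0 || cs >= W) continue;
        const int rlo = std::max(0, -dr), rhi = std::min(H, H - dr);
        for (int r = rlo; r < rhi; ++r) {
          std::memcpy(cols.colptr(r + c * H) + k * C,
                      A.colptr((r + dr) + cs * H), C * sizeof(double));
        }
      }
    }
  }
}

// transpose of im2col: scatter-add cols back onto the (C x H*W) image
static void col2im(const mat &cols, int H, int W, mat &A) {
  const int C = A.n_rows;
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++k) {
      for (int c = 0; c < W; ++c) {
        const int cs = c + dc;
        if (cs < 0 || cs >= W) continue;
        const int rlo = std::max(0, -dr), rhi = std::min(H, H - dr);
        for (int r = rlo; r < rhi; ++r) {
          double *dst = A.colptr((r + dr) + cs * H);
          const double *src = cols.colptr(r + c * H) + k * C;
          for (int ch = 0; ch < C; ++ch) dst[ch] += src[ch];
        }
      }
    }
  }
}

// 2x2 max pooling with floor division; trailing odd row/column is dropped
static void maxpool(const mat &Z, int H, int W, mat &P, umat &idx) {
  const int C = Z.n_rows, Ho = H / 2, Wo = W / 2;
  for (int c = 0; c < Wo; ++c) {
    for (int r = 0; r < Ho; ++r) {
      const int cand[4] = {2 * r + 2 * c * H, 2 * r + 1 + 2 * c * H,
                           2 * r + (2 * c + 1) * H, 2 * r + 1 + (2 * c + 1) * H};
      for (int ch = 0; ch < C; ++ch) {
        double best = Z(ch, cand[0]);
        int bi = cand[0];
        for (int q = 1; q < 4; ++q) {
          const double v = Z(ch, cand[q]);
          if (v > best) { best = v; bi = cand[q]; }
        }
        P(ch, r + c * Ho) = best;
        idx(ch, r + c * Ho) = bi;
      }
    }
  }
}

struct Cache {
  std::vector<mat> cols;    // im2col input per conv layer
  std::vector<mat> zrelu;   // post-ReLU pre-pool activations
  std::vector<umat> poolidx;
  std::vector<mat> pooled;  // post-pool activations (layer inputs)
  std::vector<vec> fc_act;  // fc_act[0] = flatten, then post-ReLU hiddens
  std::vector<int> Hs, Ws;  // spatial dims entering each conv layer
};

// forward one sample; x is (H*W) single-channel flattened image
static vec forward_sample(const Net &net, const vec &x, int H, int W,
                          Cache *cache) {
  mat A(1, H * W);
  std::memcpy(A.memptr(), x.memptr(), H * W * sizeof(double));
  for (size_t l = 0; l < net.conv_w.size(); ++l) {
    const int C_in = net.conv_w[l].n_cols / 9;
    const int C_out = net.conv_w[l].n_rows;
    if ((int)A.n_rows != C_in) stop("channel mismatch in conv layer %d", (int)l + 1);
    if (H / 2 == 0 || W / 2 == 0) stop("architecture error: spatial dimension reached 0");
    mat cols(9 * C_in, H * W);
    im2col(A, H, W, cols);
    mat Z = net.conv_w[l] * cols;
    Z.each_col() += net.conv_b[l];
    Z.transform([](double v) { return v > 0 ? v : 0.0; });
    const int Ho = H / 2, Wo = W / 2;
    mat P(C_out, Ho * Wo);
    umat idx(C_out, Ho * Wo);
    maxpool(Z, H, W, P, idx);
    if (cache) {
      cache->cols.push_back(std::move(cols));
      cache->zrelu.push_back(Z);
      cache->poolidx.push_back(std::move(idx));
      cache->Hs.push_back(H);
      cache->Ws.push_back(W);
      cache->pooled.push_back(P);
    }
    A = std::move(P);
    H = Ho;
    W = Wo;
  }
  vec a = vectorise(A);
  if (cache) cache->fc_act.push_back(a);
  const size_t F = net.fc_w.size();
  for (size_t l = 0; l < F; ++l) {
    if (net.fc_w[l].n_cols != a.n_elem)
      stop("fc dimension mismatch in layer %d: expected %d, got %d",
           (int)l + 1, (int)net.fc_w[l].n_cols, (int)a.n_elem);
    a = net.fc_w[l] * a + net.fc_b[l];
    if (l + 1 < F) {
      a.transform([](double v) { return v > 0 ? v : 0.0; });
      if (cache) cache->fc_act.push_back(a);
    }
  }
  return a;
}

// [[Rcpp::export]]
List cpp_cnn_init(IntegerVector channels, IntegerVector fc_dims, int seed) {
  std::mt19937 g(static_cast<uint32_t>(seed));
  Net net;
  for (int l = 0; l + 1 < channels.size(); ++l) {
    const int cin = channels[l], cout = channels[l + 1];
    const double bound = 1.0 / std::sqrt(9.0 * cin);
    mat W(cout, 9 * cin);
    vec b(cout);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = (2.0 * unif01(g) - 1.0) * bound;
    for (uword i = 0; i < b.n_elem; ++i) b(i) = (2.0 * unif01(g) - 1.0) * bound;
    net.conv_w.push_back(W);
    net.conv_b.push_back(b);
  }
  for (int l = 0; l + 1 < fc_dims.size(); ++l) {
    const int din = fc_dims[l], dout = fc_dims[l + 1];
    const double bound = 1.0 / std::sqrt((double)din);
    mat W(dout, din);
    vec b(dout);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = (2.0 * unif01(g) - 1.0) * bound;
    for (uword i = 0; i < b.n_elem; ++i) b(i) = (2.0 * unif01(g) - 1.0) * bound;
    net.fc_w.push_back(W);
    net.fc_b.push_back(b);
  }
  return net_to_list(net);
}

// [[Rcpp::export]]
arma::mat cpp_cnn_forward(List params, arma::cube X) {
  Net net = net_from_list(params);
  const int H = X.n_rows, W = X.n_cols, N = X.n_slices;
  const int n_out = net.fc_w.back().n_rows;
  mat scores(N, n_out);
  for (int i = 0; i < N; ++i) {
    vec x = vectorise(X.slice(i));
    scores.row(i) = forward_sample(net, x, H, W, nullptr).t();
  }
  return scores;
}

static void backward_sample(const Net &net, const Cache &cache, const vec &dscores,
                            Net &grad) {
  const size_t F = net.fc_w.size();
  vec d = dscores;
  for (int l = F - 1; l >= 0; --l) {
    grad.fc_w[l] += d * cache.fc_act[l].t();
    grad.fc_b[l] += d;
    if (l > 0) {
      d = net.fc_w[l].t() * d;
      for (uword i = 0; i < d.n_elem; ++i)
        if (cache.fc_act[l](i) <= 0) d(i) = 0.0;
    } else {
      d = net.fc_w[0].t() * d;
    }
  }
  const size_t L = net.conv_w.size();
  // d currently holds the gradient w.r.t. the flatten vector
  for (int l = L - 1; l >= 0; --l) {
    const int H = cache.Hs[l], W = cache.Ws[l];
    const int C = net.conv_w[l].n_rows;
    const int Ho = H / 2, Wo = W / 2;
    mat dP(C, Ho * Wo);
    std::memcpy(dP.memptr(), d.memptr(), C * Ho * Wo * sizeof(double));
    // unpool: route gradient to the argmax cell
    mat dZ(C, H * W, fill::zeros);
    for (int p = 0; p < Ho * Wo; ++p)
      for (int ch = 0; ch < C; ++ch)
        dZ(ch, cache.poolidx[l](ch, p)) += dP(ch, p);
    // ReLU
    const mat &Zr = cache.zrelu[l];
    for (uword i = 0; i < dZ.n_elem; ++i)
      if (Zr(i) <= 0) dZ(i) = 0.0;
    grad.conv_w[l] += dZ * cache.cols[l].t();
    grad.conv_b[l] += sum(dZ, 1);
    if (l > 0) {
      const int C_in = net.conv_w[l].n_cols / 9;
      mat dcols = net.conv_w[l].t() * dZ;
      mat dA(C_in, H * W, fill::zeros);
      col2im(dcols, H, W, dA);
      d = vectorise(dA);
    }
  }
}

static Net zeros_like(const Net &net) {
  Net z;
  for (const auto &m : net.conv_w) z.conv_w.push_back(mat(size(m), fill::zeros));
  for (const auto &v : net.conv_b) z.conv_b.push_back(vec(size(v), fill::zeros));
  for (const auto &m : net.fc_w) z.fc_w.push_back(mat(size(m), fill::zeros));
  for (const auto &v : net.fc_b) z.fc_b.push_back(vec(size(v), fill::zeros));
  return z;
}

template <typename T>
static void adam_update(T &w, T &m, T &v, const T &g, double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  w -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

// One training epoch. `order` is a 1-based permutation supplied from R so
// that all randomness lives in R's seeded streams.
// [[Rcpp::export]]
List cpp_cnn_train_epoch(List params, List adam, arma::cube X,
                         arma::ivec y, arma::uvec order,
                         int batch_size, double lr) {
  Net net = net_from_list(params);
  Net m = net_from_list(adam["m"]);
  Net v = net_from_list(adam["v"]);
  double t = as<double>(adam["t"]);
  const int H = X.n_rows, W = X.n_cols, N = X.n_slices;
  const int n_out = net.fc_w.back().n_rows;
  double loss_sum = 0.0;
  int correct = 0;
  for (int start = 0; start < N; start += batch_size) {
    const int bend = std::min(start + batch_size, N);
    const int B = bend - start;
    Net grad = zeros_like(net);
    for (int b = 0; b < B; ++b) {
      const int i = order(start + b) - 1;
      Cache cache;
      vec x = vectorise(X.slice(i));
      vec s = forward_sample(net, x, H, W, &cache);
      const double smax = s.max();
      vec p = exp(s - smax);
      p /= accu(p);
      const int yi = y(i);
      loss_sum += -std::log(std::max(p(yi), 1e-12));
      if ((int)p.index_max() == yi) ++correct;
      vec d = p;
      d(yi) -= 1.0;
      d /= (double)B;
      backward_sample(net, cache, d, grad);
    }
    t += 1.0;
    for (size_t l = 0; l < net.conv_w.size(); ++l) {
      adam_update(net.conv_w[l], m.conv_w[l], v.conv_w[l], grad.conv_w[l], lr, t);
      adam_update(net.conv_b[l], m.conv_b[l], v.conv_b[l], grad.conv_b[l], lr, t);
    }
    for (size_t l = 0; l < net.fc_w.size(); ++l) {
      adam_update(net.fc_w[l], m.fc_w[l], v.fc_w[l], grad.fc_w[l], lr, t);
      adam_update(net.fc_b[l], m.fc_b[l], v.fc_b[l], grad.fc_b[l], lr, t);
    }
    (void)n_out;
  }
  return List::create(
    _["params"] = net_to_list(net),
    _["adam"] = List::create(_["m"] = net_to_list(m), _["v"] = net_to_list(v),
                             _["t"] = t),
    _["loss"] = loss_sum / N,
    _["acc"] = (double)correct / N);
}

// mean softmax cross-entropy + gradients for a whole batch, used by the
// finite-difference gradient check in the test suite
// [[Rcpp::export]]
List cpp_cnn_loss_grad(List params, arma::cube X, arma::ivec y) {
  Net net = net_from_list(params);
  Net grad = zeros_like(net);
  const int H = X.n_rows, W = X.n_cols, N = X.n_slices;
  double loss_sum = 0.0;
  for (int i = 0; i < N; ++i) {
    Cache cache;
    vec x = vectorise(X.slice(i));
    vec s = forward_sample(net, x, H, W, &cache);
    const double smax = s.max();
    vec p = exp(s - smax);
    p /= accu(p);
    loss_sum += -std::log(std::max(p(y(i)), 1e-12));
    vec d = p;
    d(y(i)) -= 1.0;
    d /= (double)N;
    backward_sample(net, cache, d, grad);
  }
  return List::create(_["loss"] = loss_sum / N, _["grad"] = net_to_list(grad));
}
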