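// Compact convolutional backbone used by trainModel(): three 3x3 conv
// blocks (ReLU, 2x2 max-pool after the first two), a 64-unit dense layer
// and a softmax head, trained with SGD + momentum + weight decay and
// checkpoint-best-on-validation-loss. Sized to run full experiments on a
// single CPU core.
//
// Layouts: a batch of feature maps is an arma::mat A of shape
// (channels, B*H*W) with column index b*H*W + x*H + y (matching R's
// column-major image flattening for the single-channel input). Convolution
// is im2col + gemm with zero padding 1; pooling uses a ceil rule so odd
// extents survive.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Dims {
  int H, W, C;                 // input to a stage
  int Ho() const { return (H + 1) / 2; }
  int Wo() const { return (W + 1) / 2; }
};

// im2col for 3x3 kernels, zero pad 1, stride 1.
// A: (C, B*H*W)  ->  cols: (C*9, B*H*W)
mat im2col3(const mat& A, int H, int W, int B) {
  const int C = A.n_rows, HW = H * W;
  mat cols(C * 9, (size_t)B * HW, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t base = (size_t)b * HW;
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        const size_t oc = base + (size_t)x * H + y;
        double* dst = cols.colptr(oc);
        for (int kx = -1; kx <= 1; ++kx) {
          const int sx = x + kx;
          for (int ky = -1; ky <= 1; ++ky) {
            const int sy = y + ky;
            const int k = (kx + 1) * 3 + (ky + 1);
            if (sx < 0 || sx >= W || sy < 0 || sy >= H) continue;
            const double* src = A.colptr(base + (size_t)sx * H + sy);
            double* d = dst + (size_t)k * C;
            std::memcpy(d, src, C * sizeof(double));
          }
        }
      }
    }
  }
  return cols;
}

// adjoint of im2col3: scatter-add (C*9, B*H*W) back to (C, B*H*W)
mat col2im3(const mat& cols, int C, int H, int W, int B) {
  const int HW = H * W;
  mat A(C, (size_t)B * HW, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const size_t base = (size_t)b * HW;
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        const size_t oc = base + (size_t)x * H + y;
        const double* src = cols.colptr(oc);
        for (int kx = -1; kx <= 1; ++kx) {
          const int sx = x + kx;
          for (int ky = -1; ky <= 1; ++ky) {
            const int sy = y + ky;
            const int k = (kx + 1) * 3 + (ky + 1);
            if (sx < 0 || sx >= W || sy < 0 || sy >= H) continue;
            double* dst = A.colptr(base + (size_t)sx * H + sy);
            const double* s = src + (size_t)k * C;
            for (int c = 0; c < C; ++c) dst[c] += s[c];
          }
        }
      }
    }
  }
  return A;
}

// 2x2 max pool, stride 2, ceil extents; records flat argmax columns
mat maxpool(const mat& A, int H, int W, int B, umat& arg) {
  const int C = A.n_rows, Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  mat O(C, (size_t)B * Ho * Wo);
  arg.set_size(C, (size_t)B * Ho * Wo);
  for (int b = 0; b < B; ++b) {
    const size_t ibase = (size_t)b * H * W, obase = (size_t)b * Ho * Wo;
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        const size_t oc = obase + (size_t)xo * Ho + yo;
        for (int c = 0; c < C; ++c) {
          double best = -datum::inf; size_t bi = 0;
          for (int dx = 0; dx < 2; ++dx) {
            const int x = 2 * xo + dx; if (x >= W) continue;
            for (int dy = 0; dy < 2; ++dy) {
              const int y = 2 * yo + dy; if (y >= H) continue;
              const size_t ic = ibase + (size_t)x * H + y;
              const double v = A(c, ic);
              if (v > best) { best = v; bi = ic; }
            }
          }
          O(c, oc) = best; arg(c, oc) = bi;
        }
      }
    }
  }
  return O;
}

mat maxpoolBack(const mat& dO, const umat& arg, int C, size_t inCols) {
  mat dA(C, inCols, fill::zeros);
  for (size_t j = 0; j < dO.n_cols; ++j)
    for (int c = 0; c < C; ++c) dA(c, arg(c, j)) += dO(c, j);
  return dA;
}

struct Net {
  int p, q, nclass, c1, c2, c3, fc;
  mat W1, W2, W3, F1, F2;
  vec b1, b2, b3, g1, g2;
  int h1() const { return (p + 1) / 2; }
  int w1() const { return (q + 1) / 2; }
  int h2() const { return (h1() + 1) / 2; }
  int w2() const { return (w1() + 1) / 2; }
  int flat() const { return c3 * h2() * w2(); }

  void init(std::mt19937& rng) {
    auto he = [&](mat& M, int fanin) {
      std::normal_distribution<double> N(0.0, std::sqrt(2.0 / fanin));
      for (auto& v : M) v = N(rng);
    };
    W1.set_size(c1, 9);        he(W1, 9);
    W2.set_size(c2, c1 * 9);   he(W2, c1 * 9);
    W3.set_size(c3, c2 * 9);   he(W3, c2 * 9);
    F1.set_size(fc, flat());   he(F1, flat());
    F2.set_size(nclass, fc);   he(F2, fc);
    b1.zeros(c1); b2.zeros(c2); b3.zeros(c3); g1.zeros(fc); g2.zeros(nclass);
  }
};

struct Cache {
  mat cols1, a1, p1, cols2, a2, p2, cols3, a3, xf, z1, probs;
  umat arg1, arg2;
};

// forward pass over a batch; X columns are flattened p x q images
void forward(const Net& net, const mat& X, Cache& cc, bool keep) {
  const int B = X.n_cols;
  mat A0 = reshape(X, 1, X.n_elem);           // (1, B*p*q) -- column-major ok
  mat cols1 = im2col3(A0, net.p, net.q, B);
  mat z = net.W1 * cols1; z.each_col() += net.b1;
  mat a1 = clamp(z, 0.0, datum::inf);
  umat arg1; mat p1 = maxpool(a1, net.p, net.q, B, arg1);

  mat cols2 = im2col3(p1, net.h1(), net.w1(), B);
  z = net.W2 * cols2; z.each_col() += net.b2;
  mat a2 = clamp(z, 0.0, datum::inf);
  umat arg2; mat p2 = maxpool(a2, net.h1(), net.w1(), B, arg2);

  mat cols3 = im2col3(p2, net.h2(), net.w2(), B);
  z = net.W3 * cols3; z.each_col() += net.b3;
  mat a3 = clamp(z, 0.0, datum::inf);     // (c3, B*h2*w2)

  // flatten: per sample vector (c3*h2*w2)
  const int hw = net.h2() * net.w2();
  mat xf(net.flat(), B);
  for (int b = 0; b < B; ++b)
    xf.col(b) = vectorise(a3.cols((size_t)b * hw, (size_t)(b + 1) * hw - 1));

  mat z1 = net.F1 * xf; z1.each_col() += net.g1;
  mat h = clamp(z1, 0.0, datum::inf);
  mat z2 = net.F2 * h; z2.each_col() += net.g2;
  z2.each_row() -= max(z2, 0);
  mat ez = exp(z2);
  mat probs = ez.each_row() / sum(ez, 0);

  cc.probs = probs;
  if (keep) {
    cc.cols1 = std::move(cols1); cc.a1 = std::move(a1); cc.p1 = std::move(p1);
    cc.cols2 = std::move(cols2); cc.a2 = std::move(a2); cc.p2 = std::move(p2);
    cc.cols3 = std::move(cols3); cc.a3 = std::move(a3);
    cc.xf = std::move(xf); cc.z1 = std::move(h);
    cc.arg1 = std::move(arg1); cc.arg2 = std::move(arg2);
  }
}

struct Grads { mat W1, W2, W3, F1, F2; vec b1, b2, b3, g1, g2; };

void backward(const Net& net, const Cache& cc, const mat& X, const ivec& y,
              Grads& g) {
  const int B = X.n_cols;
  mat dz2 = cc.probs;                          // (nclass, B)
  for (int b = 0; b < B; ++b) dz2(y[b], b) -= 1.0;
  dz2 /= B;
  g.F2 = dz2 * cc.z1.t(); g.g2 = sum(dz2, 1);
  mat dh = net.F2.t() * dz2;
  dh.elem(find(cc.z1 == 0)).zeros();
  g.F1 = dh * cc.xf.t(); g.g1 = sum(dh, 1);
  mat dxf = net.F1.t() * dh;                   // (flat, B)

  const int hw = net.h2() * net.w2();
  mat da3(net.c3, (size_t)B * hw);
  for (int b = 0; b < B; ++b)
    da3.cols((size_t)b * hw, (size_t)(b + 1) * hw - 1) =
      reshape(dxf.col(b), net.c3, hw);
  da3.elem(find(cc.a3 == 0)).zeros();
  g.W3 = da3 * cc.cols3.t(); g.b3 = sum(da3, 1);
  mat dcols3 = net.W3.t() * da3;
  mat dp2 = col2im3(dcols3, net.c2, net.h2(), net.w2(), B);
  mat da2 = maxpoolBack(dp2, cc.arg2, net.c2, cc.a2.n_cols);
  da2.elem(find(cc.a2 == 0)).zeros();
  g.W2 = da2 * cc.cols2.t(); g.b2 = sum(da2, 1);
  mat dcols2 = net.W2.t() * da2;
  mat dp1 = col2im3(dcols2, net.c1, net.h1(), net.w1(), B);
  mat da1 = maxpoolBack(dp1, cc.arg1, net.c1, cc.a1.n_cols);
  da1.elem(find(cc.a1 == 0)).zeros();
  g.W1 = da1 * cc.cols1.t(); g.b1 = sum(da1, 1);
}

double ceLoss(const mat& probs, const ivec& y) {
  double s = 0;
  for (size_t b = 0; b < probs.n_cols; ++b)
    s += -std::log(std::max(probs(y[b], b), 1e-12));
  return s / std::max((size_t)1, (size_t)probs.n_cols);
}

mat predictAll(const Net& net, const mat& X, int batch) {
  mat out(net.nclass, X.n_cols);
  Cache cc;
  for (size_t s = 0; s < X.n_cols; s += batch) {
    const size_t e = std::min((size_t)X.n_cols, s + batch) - 1;
    forward(net, X.cols(s, e), cc, false);
    out.cols(s, e) = cc.probs;
  }
  return out;
}

Rcpp::List packWeights(const Net& net) {
  return Rcpp::List::create(
    Rcpp::Named("conv1W") = net.W1, Rcpp::Named("conv1b") = net.b1,
    Rcpp::Named("conv2W") = net.W2, Rcpp::Named("conv2b") = net.b2,
    Rcpp::Named("conv3W") = net.W3, Rcpp::Named("conv3b") = net.b3,
    Rcpp::Named("fc1W") = net.F1, Rcpp::Named("fc1b") = net.g1,
    Rcpp::Named("fc2W") = net.F2, Rcpp::Named("fc2b") = net.g2,
    Rcpp::Named("dims") = Rcpp::IntegerVector::create(
      net.p, net.q, net.nclass, net.c1, net.c2, net.c3, net.fc));
}

void unpackWeights(const Rcpp::List& w, Net& net) {
  Rcpp::IntegerVector d = w["dims"];
  net.p = d[0]; net.q = d[1]; net.nclass = d[2];
  net.c1 = d[3]; net.c2 = d[4]; net.c3 = d[5]; net.fc = d[6];
  net.W1 = Rcpp::as<mat>(w["conv1W"]); net.b1 = Rcpp::as<vec>(w["conv1b"]);
  net.W2 = Rcpp::as<mat>(w["conv2W"]); net.b2 = Rcpp::as<vec>(w["conv2b"]);
  net.W3 = Rcpp::as<mat>(w["conv3W"]); net.b3 = Rcpp::as<vec>(w["conv3b"]);
  net.F1 = Rcpp::as<mat>(w["fc1W"]);   net.g1 = Rcpp::as<vec>(w["fc1b"]);
  net.F2 = Rcpp::as<mat>(w["fc2W"]);   net.g2 = Rcpp::as<vec>(w["fc2b"]);
}

} // namespace

// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(const arma::mat& X, const arma::ivec& y,
                         const arma::mat& Xval, const arma::ivec& yval,
                         int p, int q, int nclass, int epochs, int batch,
                         double lr, double weightDecay, double momentum,
                         int seed, int c1 = 8, int c2 = 16, int c3 = 32,
                         int fc = 64) {
  if (X.n_rows != (size_t)(p * q)) Rcpp::stop("X rows must equal p*q");
  if (y.n_elem != X.n_cols) Rcpp::stop("one label per image required");
  Net net; net.p = p; net.q = q; net.nclass = nclass;
  net.c1 = c1; net.c2 = c2; net.c3 = c3; net.fc = fc;
  std::mt19937 rng(seed);
  net.init(rng);

  Grads v; // momentum buffers
  v.W1.zeros(size(net.W1)); v.W2.zeros(size(net.W2)); v.W3.zeros(size(net.W3));
  v.F1.zeros(size(net.F1)); v.F2.zeros(size(net.F2));
  v.b1.zeros(size(net.b1)); v.b2.zeros(size(net.b2)); v.b3.zeros(size(net.b3));
  v.g1.zeros(size(net.g1)); v.g2.zeros(size(net.g2));

  const bool hasVal = Xval.n_cols > 0;
  const size_t N = X.n_cols;
  std::vector<size_t> idx(N);
  std::iota(idx.begin(), idx.end(), 0);

  mat history(epochs, 3);
  double bestLoss = datum::inf;
  int bestEpoch = epochs;
  Rcpp::List bestW;
  Cache cc; Grads g;

  auto sgd = [&](mat& W, mat& V, const mat& dW, bool decay) {
    V = momentum * V - lr * (dW + (decay ? weightDecay * W : mat(size(W), fill::zeros)));
    W += V;
  };
  auto sgdv = [&](vec& b, vec& V, const vec& db) {
    V = momentum * V - lr * db; b += V;
  };

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double trSum = 0; size_t trN = 0;
    for (size_t s = 0; s < N; s += batch) {
      const size_t e = std::min(N, s + batch);
      uvec take(e - s);
      for (size_t k = s; k < e; ++k) take[k - s] = idx[k];
      mat Xb = X.cols(take);
      ivec yb(e - s);
      for (size_t k = s; k < e; ++k) yb[k - s] = y[idx[k]];
      forward(net, Xb, cc, true);
      trSum += ceLoss(cc.probs, yb) * (e - s); trN += e - s;
      backward(net, cc, Xb, yb, g);
      sgd(net.W1, v.W1, g.W1, true); sgdv(net.b1, v.b1, g.b1);
      sgd(net.W2, v.W2, g.W2, true); sgdv(net.b2, v.b2, g.b2);
      sgd(net.W3, v.W3, g.W3, true); sgdv(net.b3, v.b3, g.b3);
      sgd(net.F1, v.F1, g.F1, true); sgdv(net.g1, v.g1, g.g1);
      sgd(net.F2, v.F2, g.F2, true); sgdv(net.g2, v.g2, g.g2);
    }
    double valLoss = NA_REAL, valAcc = NA_REAL;
    if (hasVal) {
      mat pv = predictAll(net, Xval, batch);
      valLoss = ceLoss(pv, yval);
      uvec pred = index_max(pv, 0).t();
      size_t ok = 0;
      for (size_t b = 0; b < pv.n_cols; ++b)
        if ((int)pred[b] == yval[b]) ++ok;
      valAcc = 100.0 * ok / pv.n_cols;
      if (valLoss < bestLoss) {
        bestLoss = valLoss; bestEpoch = ep + 1; bestW = packWeights(net);
      }
    }
    history(ep, 0) = trSum / std::max((size_t)1, trN);
    history(ep, 1) = valLoss;
    history(ep, 2) = valAcc;
    Rcpp::checkUserInterrupt();
  }
  if (!hasVal || bestW.size() == 0) { bestW = packWeights(net); bestEpoch = epochs; }
  return Rcpp::List::create(Rcpp::Named("weights") = bestW,
                            Rcpp::Named("history") = history,
                            Rcpp::Named("bestEpoch") = bestEpoch);
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
arma::mat cnn_predict_cpp(const Rcpp::List& weights, const arma::mat& X,
                          int batch = 256) {
  Net net; unpackWeights(weights, net);
  if (X.n_rows != (size_t)(net.p * net.q))
    Rcpp::stop("image shape does not match the trained grid (%d x %d)",
               net.p, net.q);
  return predictAll(net, X, batch).t();   // samples x classes
}
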