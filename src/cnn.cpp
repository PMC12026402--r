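// Small CNN (3x3 same-padding conv blocks, ReLU, 2x2 max-pool, global
// average pooling, softmax head) trained with Adam.
// Self-contained: seeded mt19937 drives init, shuffling and augmentation,
// so training is a deterministic function of (data, spec, seed).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fcube;
using arma::fvec;
using arma::uword;

namespace {

struct ConvLayer {
  fmat W;   // (9*Cin) x F
  fvec b;   // F
  fmat mW, vW;  // Adam moment buffers
  fvec mb, vb;
};

struct Net {
  std::vector<ConvLayer> conv;
  fmat Wd;  // F_last x 2
  fvec bd;  // 2
  fmat mWd, vWd;
  fvec mbd, vbd;
  int inSize;
  int inChan;
};

// im2col for 3x3 same padding: (H*W) x (9*C), column-major pixel order.
fmat im2col3(const fcube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fmat out(H * W, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const fmat& s = x.slice(c);
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di, ++k) {
        float* col = out.colptr(c * 9 + k);
        for (int j = 0; j < W; ++j) {
          int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const float* src = s.colptr(sj);
          float* dst = col + j * H;
          for (int i = i0; i < i1; ++i) dst[i] = src[i + di];
        }
      }
    }
  }
  return out;
}

// scatter-add transpose of im2col3
fcube col2im3(const fmat& cols, int H, int W, int C) {
  fcube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    fmat& s = out.slice(c);
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di, ++k) {
        const float* col = cols.colptr(c * 9 + k);
        for (int j = 0; j < W; ++j) {
          int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          float* dst = s.colptr(sj);
          const float* src = col + j * H;
          for (int i = i0; i < i1; ++i) dst[i + di] += src[i];
        }
      }
    }
  }
  return out;
}

struct BlockCache {
  fmat cols;           // im2col of the block input
  fcube pre;           // pre-pool ReLU output
  arma::ucube argmax;  // pooled argmax linear index into pre
  int H, W, C;         // input dims
};

fcube maxpool2(const fcube& x, arma::ucube& argmax) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  fcube out(H, W, C);
  argmax.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        float best = -1e30f; uword bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            uword idx = (2 * i + di) + (2 * j + dj) * x.n_rows;
            float v = x.slice(c)(idx);
            if (v > best) { best = v; bi = idx; }
          }
        out(i, j, c) = best;
        argmax(i, j, c) = bi;
      }
  return out;
}

fcube forwardConv(const Net& net, const fcube& x0,
                  std::vector<BlockCache>* cache) {
  fcube x = x0;
  for (size_t l = 0; l < net.conv.size(); ++l) {
    BlockCache bc;
    bc.H = x.n_rows; bc.W = x.n_cols; bc.C = x.n_slices;
    fmat cols = im2col3(x);
    fmat z = cols * net.conv[l].W;
    z.each_row() += net.conv[l].b.t();
    z.transform([](float v) { return v > 0 ? v : 0; });
    const int F = net.conv[l].W.n_cols;
    fcube pre(z.memptr(), x.n_rows, x.n_cols, F);
    arma::ucube am;
    fcube pooled = maxpool2(pre, am);
    if (cache) {
      bc.cols = std::move(cols);
      bc.pre = pre;
      bc.argmax = std::move(am);
      cache->push_back(std::move(bc));
    }
    x = std::move(pooled);
  }
  return x;
}

// forward to logits; cache filled when training
fvec forwardLogits(const Net& net, const fcube& x0,
                   std::vector<BlockCache>* cache, fvec* gapOut) {
  fcube x = forwardConv(net, x0, cache);
  const int F = x.n_slices;
  fvec g(F);
  for (int c = 0; c < F; ++c) g(c) = arma::accu(x.slice(c)) / x.slice(c).n_elem;
  if (gapOut) *gapOut = g;
  return net.Wd.t() * g + net.bd;
}

fvec softmax2(const fvec& z) {
  float m = z.max();
  fvec e = arma::exp(z - m);
  return e / arma::accu(e);
}

struct Grads {
  std::vector<fmat> dW;
  std::vector<fvec> db;
  fmat dWd;
  fvec dbd;
  void init(const Net& net) {
    dW.clear(); db.clear();
    for (auto& c : net.conv) {
      dW.push_back(fmat(c.W.n_rows, c.W.n_cols, arma::fill::zeros));
      db.push_back(fvec(c.b.n_elem, arma::fill::zeros));
    }
    dWd = fmat(net.Wd.n_rows, net.Wd.n_cols, arma::fill::zeros);
    dbd = fvec(net.bd.n_elem, arma::fill::zeros);
  }
};

void backward(const Net& net, const std::vector<BlockCache>& cache,
              const fvec& gap, const fvec& dlogits, Grads& g) {
  g.dWd += gap * dlogits.t();
  g.dbd += dlogits;
  // through GAP into the last pooled cube
  const BlockCache& last = cache.back();
  const int Hp = last.pre.n_rows / 2, Wp = last.pre.n_cols / 2;
  const int F = net.conv.back().W.n_cols;
  fvec dgap = net.Wd * dlogits;  // F
  fcube dpool(Hp, Wp, F);
  for (int c = 0; c < F; ++c)
    dpool.slice(c).fill(dgap(c) / (Hp * Wp));
  // walk blocks backwards
  for (int l = (int)net.conv.size() - 1; l >= 0; --l) {
    const BlockCache& bc = cache[l];
    // unpool
    fcube dpre(bc.pre.n_rows, bc.pre.n_cols, bc.pre.n_slices,
               arma::fill::zeros);
    for (uword c = 0; c < dpool.n_slices; ++c)
      for (uword j = 0; j < dpool.n_cols; ++j)
        for (uword i = 0; i < dpool.n_rows; ++i)
          dpre.slice(c)(bc.argmax(i, j, c)) += dpool(i, j, c);
    // ReLU mask
    for (uword k = 0; k < dpre.n_elem; ++k)
      if (bc.pre(k) <= 0) dpre(k) = 0;
    fmat dz((float*)dpre.memptr(), dpre.n_rows * dpre.n_cols, dpre.n_slices,
            false, true);
    g.dW[l] += bc.cols.t() * dz;
    g.db[l] += arma::sum(dz, 0).t();
    if (l > 0) {
      fmat dcols = dz * net.conv[l].W.t();
      fcube dx = col2im3(dcols, bc.H, bc.W, bc.C);
      dpool = std::move(dx);
    }
  }
}

// dihedral augmentation: k in 0..7 (4 rotations x optional flip)
fcube dihedral(const fcube& x, int k) {
  fcube out = x;
  for (uword c = 0; c < x.n_slices; ++c) {
    fmat m = x.slice(c);
    if (k >= 4) m = arma::fliplr(m);
    int rot = k % 4;
    for (int r = 0; r < rot; ++r) m = arma::flipud(m.t());
    out.slice(c) = m;
  }
  return out;
}

fcube sliceImage(const Rcpp::NumericVector& x, int n, int H, int W, int C,
                 int i) {
  fcube out(H, W, C);
  const double* p = x.begin();
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int r = 0; r < H; ++r)
        out(r, j, c) = (float)p[i + (size_t)n * (r + (size_t)H * (j + (size_t)W * c))];
  return out;
}

Net buildNet(const Rcpp::IntegerVector& filters, int inSize, int inChan,
             std::mt19937& rng) {
  Net net;
  net.inSize = inSize;
  net.inChan = inChan;
  std::normal_distribution<float> nd(0.f, 1.f);
  int cin = inChan;
  for (int l = 0; l < filters.size(); ++l) {
    ConvLayer cl;
    int f = filters[l];
    float s = std::sqrt(2.f / (9.f * cin));
    cl.W.set_size(9 * cin, f);
    for (uword k = 0; k < cl.W.n_elem; ++k) cl.W(k) = nd(rng) * s;
    cl.b = fvec(f, arma::fill::zeros);
    cl.mW = fmat(9 * cin, f, arma::fill::zeros);
    cl.vW = fmat(9 * cin, f, arma::fill::zeros);
    cl.mb = fvec(f, arma::fill::zeros);
    cl.vb = fvec(f, arma::fill::zeros);
    net.conv.push_back(std::move(cl));
    cin = f;
  }
  float s = std::sqrt(2.f / cin);
  net.Wd.set_size(cin, 2);
  for (uword k = 0; k < net.Wd.n_elem; ++k) net.Wd(k) = nd(rng) * s;
  net.bd = fvec(2, arma::fill::zeros);
  net.mWd = fmat(cin, 2, arma::fill::zeros);
  net.vWd = fmat(cin, 2, arma::fill::zeros);
  net.mbd = fvec(2, arma::fill::zeros);
  net.vbd = fvec(2, arma::fill::zeros);
  return net;
}

Rcpp::NumericMatrix toR(const fmat& m) {
  arma::mat d = arma::conv_to<arma::mat>::from(m);
  return Rcpp::NumericMatrix(d.n_rows, d.n_cols, d.memptr());
}

Rcpp::List netToList(const Net& net) {
  Rcpp::List conv;
  for (auto& c : net.conv) {
    conv.push_back(Rcpp::List::create(
        Rcpp::Named("W") = toR(c.W),
        Rcpp::Named("b") = arma::conv_to<std::vector<double>>::from(c.b)));
  }
  return Rcpp::List::create(
      Rcpp::Named("conv") = conv,
      Rcpp::Named("Wd") = toR(net.Wd),
      Rcpp::Named("bd") = arma::conv_to<std::vector<double>>::from(net.bd),
      Rcpp::Named("in_size") = net.inSize,
      Rcpp::Named("in_chan") = net.inChan);
}

Net netFromList(const Rcpp::List& l) {
  Net net;
  net.inSize = Rcpp::as<int>(l["in_size"]);
  net.inChan = Rcpp::as<int>(l["in_chan"]);
  Rcpp::List conv = l["conv"];
  for (int i = 0; i < conv.size(); ++i) {
    Rcpp::List cl = conv[i];
    Rcpp::NumericMatrix W = cl["W"];
    std::vector<double> b = Rcpp::as<std::vector<double>>(cl["b"]);
    ConvLayer c;
    c.W.set_size(W.nrow(), W.ncol());
    for (int k = 0; k < W.nrow() * W.ncol(); ++k) c.W(k) = (float)W[k];
    c.b.set_size(b.size());
    for (size_t k = 0; k < b.size(); ++k) c.b(k) = (float)b[k];
    net.conv.push_back(std::move(c));
  }
  Rcpp::NumericMatrix Wd = l["Wd"];
  std::vector<double> bd = Rcpp::as<std::vector<double>>(l["bd"]);
  net.Wd.set_size(Wd.nrow(), Wd.ncol());
  for (int k = 0; k < Wd.nrow() * Wd.ncol(); ++k) net.Wd(k) = (float)Wd[k];
  net.bd.set_size(bd.size());
  for (size_t k = 0; k < bd.size(); ++k) net.bd(k) = (float)bd[k];
  return net;
}

double accuracyOf(const Net& net, const Rcpp::NumericVector& x, int n, int H,
                  int W, int C, const Rcpp::IntegerVector& y) {
  int ok = 0;
  for (int i = 0; i < n; ++i) {
    fcube img = sliceImage(x, n, H, W, C, i);
    fvec z = forwardLogits(net, img, nullptr, nullptr);
    int pred = z(1) > z(0) ? 1 : 0;
    if (pred == y[i]) ++ok;
  }
  return (double)ok / n;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_train")]]
Rcpp::List cnn_train(Rcpp::NumericVector xtr, Rcpp::IntegerVector ytr,
                     Rcpp::NumericVector xval, Rcpp::IntegerVector yval,
                     Rcpp::IntegerVector dims, Rcpp::IntegerVector filters,
                     int maxEpochs, int minEpochs, int patience,
                     double gapTol, double lr, double momentum, int batch,
                     bool augment, Rcpp::NumericVector classWeights,
                     int seed) {
  const int H = dims[0], W = dims[1], C = dims[2];
  const int ntr = ytr.size(), nval = yval.size();
  std::mt19937 rng((unsigned)seed);
  Net net = buildNet(filters, H, C, rng);
  std::uniform_int_distribution<int> dihedralDist(0, 7);

  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = i;

  std::vector<double> trAcc, valAcc;
  int gapRun = 0, noImprove = 0;
  long adamT = 0;
  Net best = net;
  double bestVal = -1;
  for (int epoch = 0; epoch < maxEpochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    int correct = 0;
    for (int b0 = 0; b0 < ntr; b0 += batch) {
      int b1 = std::min(ntr, b0 + batch);
      Grads g; g.init(net);
      for (int k = b0; k < b1; ++k) {
        int i = order[k];
        fcube img = sliceImage(xtr, ntr, H, W, C, i);
        if (augment) img = dihedral(img, dihedralDist(rng));
        std::vector<BlockCache> cache;
        fvec gap;
        fvec z = forwardLogits(net, img, &cache, &gap);
        fvec p = softmax2(z);
        int pred = p(1) > p(0) ? 1 : 0;
        if (pred == ytr[i]) ++correct;
        fvec target(2, arma::fill::zeros);
        target(ytr[i]) = 1.f;
        fvec dlog = (p - target) * (float)classWeights[ytr[i]];
        backward(net, cache, gap, dlog, g);
      }
      // Adam update (beta1 = `momentum`, beta2 = 0.999)
      ++adamT;
      const float b1m = (float)momentum, b2m = 0.999f, eps = 1e-8f;
      const float bc1 = 1.f - std::pow(b1m, (float)adamT);
      const float bc2 = 1.f - std::pow(b2m, (float)adamT);
      const float inv = 1.f / (b1 - b0);
      auto adam = [&](fmat& W, fmat& mW, fmat& vW, const fmat& gW) {
        fmat gg = gW * inv;
        mW = b1m * mW + (1.f - b1m) * gg;
        vW = b2m * vW + (1.f - b2m) * arma::square(gg);
        W -= (float)lr * (mW / bc1) / (arma::sqrt(vW / bc2) + eps);
      };
      auto adamv = [&](fvec& W, fvec& mW, fvec& vW, const fvec& gW) {
        fvec gg = gW * inv;
        mW = b1m * mW + (1.f - b1m) * gg;
        vW = b2m * vW + (1.f - b2m) * arma::square(gg);
        W -= (float)lr * (mW / bc1) / (arma::sqrt(vW / bc2) + eps);
      };
      for (size_t l = 0; l < net.conv.size(); ++l) {
        adam(net.conv[l].W, net.conv[l].mW, net.conv[l].vW, g.dW[l]);
        adamv(net.conv[l].b, net.conv[l].mb, net.conv[l].vb, g.db[l]);
      }
      adam(net.Wd, net.mWd, net.vWd, g.dWd);
      adamv(net.bd, net.mbd, net.vbd, g.dbd);
    }
    double ta = (double)correct / ntr;
    double va = accuracyOf(net, xval, nval, H, W, C, yval);
    trAcc.push_back(ta);
    valAcc.push_back(va);
    if (va > bestVal + 1e-9) { bestVal = va; noImprove = 0; best = net; }
    else ++noImprove;
    gapRun = (std::fabs(ta - va) < gapTol) ? gapRun + 1 : 0;
    // training is complete when the accuracy curves have approached one
    // another (or validation has stopped improving) for `patience` epochs;
    // neither rule may fire while the model still sits at chance, so both
    // are gated on validation accuracy having moved well off 50%
    if (epoch + 1 >= minEpochs && bestVal > 0.6 &&
        (gapRun >= patience || noImprove >= patience))
      break;
  }
  // report the weights of the best validation epoch
  Rcpp::List out = netToList(bestVal >= 0 ? best : net);
  out["train_acc"] = trAcc;
  out["val_acc"] = valAcc;
  return out;
}

// [[Rcpp::export(name = ".cnn_predict")]]
Rcpp::NumericMatrix cnn_predict(Rcpp::List weights, Rcpp::NumericVector x,
                                Rcpp::IntegerVector dims) {
  const int n = dims[0], H = dims[1], W = dims[2], C = dims[3];
  Net net = netFromList(weights);
  Rcpp::NumericMatrix probs(n, 2);
  for (int i = 0; i < n; ++i) {
    fcube img = sliceImage(x, n, H, W, C, i);
    fvec p = softmax2(forwardLogits(net, img, nullptr, nullptr));
    probs(i, 0) = p(0);
    probs(i, 1) = p(1);
  }
  return probs;
}
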