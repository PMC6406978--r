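// 1D-CNN engine: forward, backprop and Adam training for the layer
// kinds used by the sleep-staging architecture (valid 1D convolution,
// max-pooling, inverted dropout, flatten, dense, softmax output).
//
// Layout conventions
//   - A sample is a (channels x length) matrix.
//   - im2col: column j of the patch matrix is the (channels x kernel)
//     input window starting at j*stride, vectorised column-major, i.e.
//     channel index fastest. Convolution weights are (filters x
//     channels*kernel) with the matching column order, so a layer is a
//     single GEMM: Y = W * col + b.
//   - The convolution is the direct sliding inner product
//     (S*W)_n = sum_i W(i) S(i + n - 1)  (no kernel flip), summed over
//     input channels, evaluated at stride multiples.
//
// All per-layer activation, patch and gradient buffers are allocated
// once and reused across samples (layer shapes are fixed), keeping the
// inner loop free of large allocations.
//
// Everything is templated on the element type; the R wrapper selects
// float (training default) or double (reference precision).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace arma;

enum LayerKind { CONV = 1, POOL = 2, DROP = 3, FLAT = 4, DENSE = 5 };
enum ActKind { ACT_NONE = 0, ACT_RELU = 1, ACT_SOFTMAX = 2 };

struct LayerDef {
  int kind = 0;
  int f = 0, k = 0, s = 1;   // conv
  int pool = 0;              // maxpool
  double rate = 0.0;         // dropout
  int units = 0;             // dense
  int act = ACT_NONE;
};

static std::vector<LayerDef> parse_layers(const Rcpp::List& layers) {
  std::vector<LayerDef> defs;
  for (R_xlen_t i = 0; i < layers.size(); ++i) {
    Rcpp::List ly = layers[i];
    LayerDef d;
    d.kind = Rcpp::as<int>(ly["kind"]);
    switch (d.kind) {
      case CONV:
        d.f = Rcpp::as<int>(ly["f"]);
        d.k = Rcpp::as<int>(ly["k"]);
        d.s = Rcpp::as<int>(ly["s"]);
        d.act = Rcpp::as<int>(ly["act"]);
        break;
      case POOL:
        d.pool = Rcpp::as<int>(ly["pool"]);
        d.s = Rcpp::as<int>(ly["s"]);
        break;
      case DROP:
        d.rate = Rcpp::as<double>(ly["rate"]);
        break;
      case FLAT:
        break;
      case DENSE:
        d.units = Rcpp::as<int>(ly["units"]);
        d.act = Rcpp::as<int>(ly["act"]);
        break;
      default:
        Rcpp::stop("unknown layer kind code %d", d.kind);
    }
    defs.push_back(d);
  }
  return defs;
}

// reusable per-layer buffers
template <typename eT>
struct Cache {
  Mat<eT> A;     // layer output (forward) / input gradient (backward)
  Mat<eT> col;   // conv patch matrix (forward) / dcol (backward)
  umat amax;     // pool argmax (column index into the layer input)
  Mat<eT> mask;  // dropout mask
};

template <typename eT>
struct Net {
  std::vector<LayerDef> defs;
  std::vector<Mat<eT>> W;
  std::vector<Col<eT>> b;
  std::vector<int> wslot;            // defs index -> index into W/b, or -1
  std::vector<Cache<eT>> fw, bw;     // forward / backward scratch

  void attach_weights(const Rcpp::List& weights) {
    W.clear(); b.clear(); wslot.assign(defs.size(), -1);
    size_t slot = 0;
    for (size_t i = 0; i < defs.size(); ++i) {
      if (defs[i].kind == CONV || defs[i].kind == DENSE) {
        if (slot >= (size_t)weights.size())
          Rcpp::stop("too few weight matrices for the layer list");
        Rcpp::List wl = weights[slot];
        W.push_back(conv_to<Mat<eT>>::from(Rcpp::as<mat>(wl["W"])));
        b.push_back(conv_to<Col<eT>>::from(Rcpp::as<vec>(wl["b"])));
        wslot[i] = (int)slot;
        ++slot;
      }
    }
    if (slot != (size_t)weights.size())
      Rcpp::stop("too many weight matrices for the layer list");
    fw.assign(defs.size(), Cache<eT>());
    bw.assign(defs.size(), Cache<eT>());
  }

  // fill `col` with the im2col patch matrix of A
  static void im2col(const Mat<eT>& A, int k, int s, Mat<eT>& col) {
    const int c = A.n_rows;
    const int L = A.n_cols;
    if (L < k) Rcpp::stop("input length %d shorter than kernel %d", L, k);
    const int Lout = (L - k) / s + 1;
    col.set_size(c * k, Lout);
    for (int j = 0; j < Lout; ++j) {
      std::memcpy(col.colptr(j), A.colptr(j * s), sizeof(eT) * c * k);
    }
  }

  // forward pass for one sample into the fw scratch; returns the final
  // activation. Dropout is active only when `train`.
  const Mat<eT>& forward(const Mat<eT>& x, bool train, std::mt19937_64& rng,
                         std::vector<std::pair<int, int>>* shapes = nullptr) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    for (size_t i = 0; i < defs.size(); ++i) {
      const LayerDef& d = defs[i];
      const Mat<eT>& Ain = (i == 0) ? x : fw[i - 1].A;
      Cache<eT>& cc = fw[i];
      switch (d.kind) {
        case CONV: {
          im2col(Ain, d.k, d.s, cc.col);
          cc.A = W[wslot[i]] * cc.col;
          cc.A.each_col() += b[wslot[i]];
          if (d.act == ACT_RELU)
            cc.A.transform([](eT v) { return v > eT(0) ? v : eT(0); });
          break;
        }
        case POOL: {
          const int c = Ain.n_rows, L = Ain.n_cols;
          if (L < d.pool) Rcpp::stop("input length %d shorter than pool %d", L, d.pool);
          const int Lout = (L - d.pool) / d.s + 1;
          cc.A.set_size(c, Lout);
          cc.amax.set_size(c, Lout);
          for (int j = 0; j < Lout; ++j) {
            const int j0 = j * d.s;
            for (int r = 0; r < c; ++r) {
              eT best = Ain(r, j0);
              int bi = j0;
              for (int t = 1; t < d.pool; ++t) {
                if (Ain(r, j0 + t) > best) { best = Ain(r, j0 + t); bi = j0 + t; }
              }
              cc.A(r, j) = best;
              cc.amax(r, j) = bi;
            }
          }
          break;
        }
        case DROP: {
          cc.A = Ain;
          if (train && d.rate > 0) {
            cc.mask.set_size(Ain.n_rows, Ain.n_cols);
            const eT scale = eT(1.0 / (1.0 - d.rate));
            for (uword t = 0; t < cc.mask.n_elem; ++t)
              cc.mask(t) = unif(rng) < d.rate ? eT(0) : scale;
            cc.A %= cc.mask;
          } else {
            cc.mask.reset();
          }
          break;
        }
        case FLAT: {
          // column-major (c x L) already matches the flattened order
          cc.A.set_size(Ain.n_elem, 1);
          std::memcpy(cc.A.memptr(), Ain.memptr(), sizeof(eT) * Ain.n_elem);
          break;
        }
        case DENSE: {
          cc.A = W[wslot[i]] * Ain;
          cc.A.each_col() += b[wslot[i]];
          if (d.act == ACT_RELU) {
            cc.A.transform([](eT v) { return v > eT(0) ? v : eT(0); });
          } else if (d.act == ACT_SOFTMAX) {
            eT m = cc.A.max();
            cc.A = exp(cc.A - m);
            cc.A /= accu(cc.A);
          }
          break;
        }
      }
      if (shapes) shapes->emplace_back((int)cc.A.n_rows, (int)cc.A.n_cols);
    }
    return fw.back().A;
  }

  // backprop for one sample (after a training-mode forward pass);
  // accumulates gradients. `y` is the 0-based true class.
  void backward(const Mat<eT>& x, int y,
                std::vector<Mat<eT>>& gW, std::vector<Col<eT>>& gb) {
    if (defs.back().kind != DENSE || defs.back().act != ACT_SOFTMAX)
      Rcpp::stop("training requires a softmax output layer");
    // bw[i].A holds the gradient w.r.t. the output of layer i
    bw.back().A = fw.back().A;
    bw.back().A(y, 0) -= eT(1);  // d(cross-entropy)/d(logits)
    for (int i = (int)defs.size() - 1; i >= 0; --i) {
      const LayerDef& d = defs[i];
      const Mat<eT>& Ain = (i == 0) ? x : fw[i - 1].A;
      Mat<eT>& dA = bw[i].A;
      switch (d.kind) {
        case DENSE: {
          if (d.act == ACT_RELU) {
            const Mat<eT>& A = fw[i].A;
            for (uword t = 0; t < dA.n_elem; ++t)
              if (A(t) <= eT(0)) dA(t) = eT(0);
          }
          gW[wslot[i]] += dA * Ain.t();
          gb[wslot[i]] += dA.col(0);
          if (i > 0) bw[i - 1].A = W[wslot[i]].t() * dA;
          break;
        }
        case FLAT: {
          Mat<eT>& dPrev = bw[i - 1].A;
          dPrev.set_size(Ain.n_rows, Ain.n_cols);
          std::memcpy(dPrev.memptr(), dA.memptr(), sizeof(eT) * dA.n_elem);
          break;
        }
        case DROP: {
          bw[i - 1].A = dA;
          if (fw[i].mask.n_elem > 0) bw[i - 1].A %= fw[i].mask;
          break;
        }
        case POOL: {
          Mat<eT>& dPrev = bw[i - 1].A;
          dPrev.zeros(Ain.n_rows, Ain.n_cols);
          const umat& amax = fw[i].amax;
          for (uword j = 0; j < dA.n_cols; ++j)
            for (uword r = 0; r < dA.n_rows; ++r)
              dPrev(r, amax(r, j)) += dA(r, j);
          break;
        }
        case CONV: {
          if (d.act == ACT_RELU) {
            const Mat<eT>& A = fw[i].A;
            for (uword t = 0; t < dA.n_elem; ++t)
              if (A(t) <= eT(0)) dA(t) = eT(0);
          }
          gW[wslot[i]] += dA * fw[i].col.t();
          gb[wslot[i]] += sum(dA, 1);
          if (i > 0) {  // input gradient not needed at the first layer
            Mat<eT>& dcol = bw[i].col;
            dcol = W[wslot[i]].t() * dA;  // (c*k) x Lout
            Mat<eT>& dPrev = bw[i - 1].A;
            dPrev.zeros(Ain.n_rows, Ain.n_cols);
            const int c = Ain.n_rows;
            for (uword j = 0; j < dcol.n_cols; ++j) {
              Mat<eT> blk(dcol.colptr(j), c, d.k, false, true);
              dPrev.cols(j * d.s, j * d.s + d.k - 1) += blk;
            }
          }
          break;
        }
      }
    }
  }
};

template <typename eT>
static Rcpp::List weights_to_r(const Net<eT>& net) {
  Rcpp::List out(net.W.size());
  for (size_t i = 0; i < net.W.size(); ++i) {
    out[i] = Rcpp::List::create(
        Rcpp::Named("W") = conv_to<mat>::from(net.W[i]),
        Rcpp::Named("b") = conv_to<vec>::from(net.b[i]));
  }
  return out;
}

// convert the (length x channels x n) input cube into per-sample
// (channels x length) matrices in the engine element type, once
template <typename eT>
static std::vector<Mat<eT>> cube_to_samples(const cube& X) {
  std::vector<Mat<eT>> out;
  out.reserve(X.n_slices);
  for (uword i = 0; i < X.n_slices; ++i) {
    out.emplace_back(conv_to<Mat<eT>>::from(X.slice(i).t()));
  }
  return out;
}

template <typename eT>
static Rcpp::List run_forward(const Rcpp::List& layers, const Rcpp::List& weights,
                              const cube& X, bool want_shapes) {
  Net<eT> net;
  net.defs = parse_layers(layers);
  net.attach_weights(weights);
  std::vector<Mat<eT>> samples = cube_to_samples<eT>(X);
  std::mt19937_64 rng(0);
  mat out;
  Rcpp::IntegerMatrix sm;
  for (size_t i = 0; i < samples.size(); ++i) {
    std::vector<std::pair<int, int>> sh;
    const Mat<eT>& y = net.forward(samples[i], false, rng,
                                   want_shapes && i == 0 ? &sh : nullptr);
    if (i == 0) {
      out.set_size(y.n_elem, samples.size());
      if (want_shapes) {
        sm = Rcpp::IntegerMatrix((int)sh.size(), 2);
        for (size_t l = 0; l < sh.size(); ++l) {
          sm(l, 0) = sh[l].first;
          sm(l, 1) = sh[l].second;
        }
      }
    }
    out.col(i) = conv_to<vec>::from(vectorise(y));
  }
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("output") = out);
  if (want_shapes) res["shapes"] = sm;
  return res;
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_forward(Rcpp::List layers, Rcpp::List weights,
                           arma::cube X, bool single = false,
                           bool shapes = false) {
  return single ? run_forward<float>(layers, weights, X, shapes)
                : run_forward<double>(layers, weights, X, shapes);
}

template <typename eT>
struct Adam {
  std::vector<Mat<eT>> mW, vW;
  std::vector<Col<eT>> mb, vb;
  double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  long t = 0;

  void init(const Net<eT>& net) {
    for (size_t i = 0; i < net.W.size(); ++i) {
      mW.push_back(Mat<eT>(size(net.W[i]), fill::zeros));
      vW.push_back(Mat<eT>(size(net.W[i]), fill::zeros));
      mb.push_back(Col<eT>(size(net.b[i]), fill::zeros));
      vb.push_back(Col<eT>(size(net.b[i]), fill::zeros));
    }
  }

  // lr is decayed per update: lr_t = lr0 / (1 + decay * t)
  void step(Net<eT>& net, std::vector<Mat<eT>>& gW, std::vector<Col<eT>>& gb,
            double lr0, double decay) {
    ++t;
    const double lr = lr0 / (1.0 + decay * (double)t);
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < net.W.size(); ++i) {
      mW[i] = eT(b1) * mW[i] + eT(1 - b1) * gW[i];
      vW[i] = eT(b2) * vW[i] + eT(1 - b2) * square(gW[i]);
      net.W[i] -= eT(lr) * (mW[i] / eT(c1)) / (sqrt(vW[i] / eT(c2)) + eT(eps));
      mb[i] = eT(b1) * mb[i] + eT(1 - b1) * gb[i];
      vb[i] = eT(b2) * vb[i] + eT(1 - b2) * square(gb[i]);
      net.b[i] -= eT(lr) * (mb[i] / eT(c1)) / (sqrt(vb[i] / eT(c2)) + eT(eps));
    }
  }
};

template <typename eT>
static Rcpp::List run_train(const Rcpp::List& layers, const Rcpp::List& weights,
                            const cube& X, const ivec& y,
                            const uvec& train_idx, const uvec& val_idx,
                            int epochs, int batch_size, double lr, double decay,
                            unsigned long seed, bool verbose) {
  Net<eT> net;
  net.defs = parse_layers(layers);
  net.attach_weights(weights);
  Adam<eT> opt;
  opt.init(net);

  std::mt19937_64 rng(seed);
  std::vector<uword> order(train_idx.begin(), train_idx.end());
  std::vector<Mat<eT>> samples = cube_to_samples<eT>(X);

  std::vector<Mat<eT>> gW;
  std::vector<Col<eT>> gb;
  for (size_t i = 0; i < net.W.size(); ++i) {
    gW.push_back(Mat<eT>(size(net.W[i]), fill::zeros));
    gb.push_back(Col<eT>(size(net.b[i]), fill::zeros));
  }

  mat history(epochs, 4);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double tr_loss = 0.0;
    long tr_correct = 0;
    for (size_t start = 0; start < order.size(); start += batch_size) {
      Rcpp::checkUserInterrupt();
      const size_t stop = std::min(order.size(), start + batch_size);
      const eT inv = eT(1.0 / (double)(stop - start));
      for (auto& g : gW) g.zeros();
      for (auto& g : gb) g.zeros();
      for (size_t s = start; s < stop; ++s) {
        const uword i = order[s];
        const Mat<eT>& p = net.forward(samples[i], true, rng);
        const int yi = (int)y(i);
        tr_loss += -std::log(std::max((double)p(yi, 0), 1e-12));
        if (p.col(0).index_max() == (uword)yi) ++tr_correct;
        net.backward(samples[i], yi, gW, gb);
      }
      for (auto& g : gW) g *= inv;
      for (auto& g : gb) g *= inv;
      opt.step(net, gW, gb, lr, decay);
    }
    double va_loss = 0.0;
    long va_correct = 0;
    for (uword v = 0; v < val_idx.n_elem; ++v) {
      const uword i = val_idx(v);
      const Mat<eT>& p = net.forward(samples[i], false, rng);
      const int yi = (int)y(i);
      va_loss += -std::log(std::max((double)p(yi, 0), 1e-12));
      if (p.col(0).index_max() == (uword)yi) ++va_correct;
    }
    history(ep, 0) = tr_loss / (double)order.size();
    history(ep, 1) = (double)tr_correct / (double)order.size();
    history(ep, 2) = val_idx.n_elem ? va_loss / (double)val_idx.n_elem : NA_REAL;
    history(ep, 3) = val_idx.n_elem ? (double)va_correct / (double)val_idx.n_elem
                                    : NA_REAL;
    if (verbose) {
      Rcpp::Rcout << "epoch " << (ep + 1) << "/" << epochs
                  << "  loss " << history(ep, 0) << "  acc " << history(ep, 1);
      if (val_idx.n_elem)
        Rcpp::Rcout << "  val_loss " << history(ep, 2)
                    << "  val_acc " << history(ep, 3);
      Rcpp::Rcout << std::endl;
    }
  }
  return Rcpp::List::create(Rcpp::Named("weights") = weights_to_r(net),
                            Rcpp::Named("history") = history);
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(Rcpp::List layers, Rcpp::List weights, arma::cube X,
                         arma::ivec y, arma::uvec train_idx, arma::uvec val_idx,
                         int epochs, int batch_size, double lr, double decay,
                         unsigned long seed, bool single = true,
                         bool verbose = false) {
  return single
             ? run_train<float>(layers, weights, X, y, train_idx, val_idx,
                                epochs, batch_size, lr, decay, seed, verbose)
             : run_train<double>(layers, weights, X, y, train_idx, val_idx,
                                 epochs, batch_size, lr, decay, seed, verbose);
}
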