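// Compact convolutional multi-label tagger: 3x3 conv blocks with batch
// normalization, ReLU, 2x2 max pooling and dropout, global average pooling
// into a feature vector, two fully connected layers and per-category
// sigmoid outputs. Trained with binary cross-entropy, AdamW and a
// caller-supplied per-step learning-rate schedule. All randomness
// (initialization, shuffling, dropout) comes from a seeded mt19937_64, so
// runs are reproducible on one machine.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

namespace {

const double BN_EPS = 1e-5;
const double BN_MOMENTUM = 0.9;
const double ADAM_B1 = 0.9;
const double ADAM_B2 = 0.999;
const double ADAM_EPS = 1e-8;
const double BCE_CLAMP = 1e-7;

struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t s) : eng(s) {}
  double unif() {  // 53-bit uniform in [0, 1)
    return (eng() >> 11) * (1.0 / 9007199254740992.0);
  }
  double gauss() {  // Box-Muller (deterministic given the engine)
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  int randint(int n) { return static_cast<int>(eng() % (uint64_t)n); }
  void shuffle(std::vector<int>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i)
      std::swap(v[i], v[randint(i + 1)]);
  }
};

struct Param {
  mat w, m, v;
  bool decay;
  Param() : decay(false) {}
  void init(int r, int c, bool dec) {
    w.zeros(r, c); m.zeros(r, c); v.zeros(r, c); decay = dec;
  }
};

struct Net {
  int n_blocks, n_mels, n_cat, fc_hidden;
  std::vector<int> channels, pool_h, pool_w;
  double dropout;
  std::vector<Param> convW, convB, gamma, beta;
  std::vector<mat> rmean, rvar;  // BN running stats (not Adam-updated)
  Param fc1W, fc1b, fc2W, fc2b;

  void configure(const List& arch) {
    IntegerVector ch = arch["channels"];
    channels.assign(ch.begin(), ch.end());
    n_blocks = channels.size();
    IntegerVector ph = arch["pool_h"], pw = arch["pool_w"];
    pool_h.assign(ph.begin(), ph.end());
    pool_w.assign(pw.begin(), pw.end());
    if ((int)pool_h.size() != n_blocks || (int)pool_w.size() != n_blocks)
      stop("pool sizes must match the number of conv blocks");
    n_mels = as<int>(arch["n_mels"]);
    n_cat = as<int>(arch["n_categories"]);
    fc_hidden = as<int>(arch["fc_hidden"]);
    dropout = as<double>(arch["dropout"]);
    convW.resize(n_blocks); convB.resize(n_blocks);
    gamma.resize(n_blocks); beta.resize(n_blocks);
    rmean.resize(n_blocks); rvar.resize(n_blocks);
    int cin = 1;
    for (int b = 0; b < n_blocks; ++b) {
      convW[b].init(channels[b], cin * 9, true);
      convB[b].init(channels[b], 1, false);
      gamma[b].init(channels[b], 1, false);
      beta[b].init(channels[b], 1, false);
      rmean[b].zeros(channels[b], 1);
      rvar[b].ones(channels[b], 1);
      cin = channels[b];
    }
    fc1W.init(fc_hidden, channels[n_blocks - 1], true);
    fc1b.init(fc_hidden, 1, false);
    fc2W.init(n_cat, fc_hidden, true);
    fc2b.init(n_cat, 1, false);
  }

  void he_init(Rng& rng) {
    for (int b = 0; b < n_blocks; ++b) {
      double sd = std::sqrt(2.0 / convW[b].w.n_cols);
      for (uword i = 0; i < convW[b].w.n_elem; ++i)
        convW[b].w(i) = sd * rng.gauss();
      gamma[b].w.ones();
    }
    double sd1 = std::sqrt(2.0 / fc1W.w.n_cols);
    for (uword i = 0; i < fc1W.w.n_elem; ++i) fc1W.w(i) = sd1 * rng.gauss();
    double sd2 = std::sqrt(2.0 / fc2W.w.n_cols);
    for (uword i = 0; i < fc2W.w.n_elem; ++i) fc2W.w(i) = sd2 * rng.gauss();
  }

  std::vector<Param*> params() {
    std::vector<Param*> p;
    for (int b = 0; b < n_blocks; ++b) {
      p.push_back(&convW[b]); p.push_back(&convB[b]);
      p.push_back(&gamma[b]); p.push_back(&beta[b]);
    }
    p.push_back(&fc1W); p.push_back(&fc1b);
    p.push_back(&fc2W); p.push_back(&fc2b);
    return p;
  }

  List export_weights() const {
    List out;
    for (int b = 0; b < n_blocks; ++b) {
      std::string s = std::to_string(b + 1);
      out["conv" + s + "_W"] = convW[b].w;
      out["conv" + s + "_b"] = convB[b].w;
      out["bn" + s + "_gamma"] = gamma[b].w;
      out["bn" + s + "_beta"] = beta[b].w;
      out["bn" + s + "_mean"] = rmean[b];
      out["bn" + s + "_var"] = rvar[b];
    }
    out["fc1_W"] = fc1W.w; out["fc1_b"] = fc1b.w;
    out["fc2_W"] = fc2W.w; out["fc2_b"] = fc2b.w;
    return out;
  }

  void import_weights(const List& w) {
    for (int b = 0; b < n_blocks; ++b) {
      std::string s = std::to_string(b + 1);
      convW[b].w = as<mat>(w["conv" + s + "_W"]);
      convB[b].w = as<mat>(w["conv" + s + "_b"]);
      gamma[b].w = as<mat>(w["bn" + s + "_gamma"]);
      beta[b].w = as<mat>(w["bn" + s + "_beta"]);
      rmean[b] = as<mat>(w["bn" + s + "_mean"]);
      rvar[b] = as<mat>(w["bn" + s + "_var"]);
    }
    fc1W.w = as<mat>(w["fc1_W"]); fc1b.w = as<mat>(w["fc1_b"]);
    fc2W.w = as<mat>(w["fc2_W"]); fc2b.w = as<mat>(w["fc2_b"]);
  }
};

// im2col for a 3x3 kernel with zero padding 1, stride 1; column-major
// flattening (y + x*H) is used consistently for spatial positions.
mat im2col3(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat col(C * 9, H * W, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int r = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (int x = 0; x < W; ++x) {
          const int sx = x + dx;
          if (sx < 0 || sx >= W) continue;
          for (int y = 0; y < H; ++y) {
            const int sy = y + dy;
            if (sy < 0 || sy >= H) continue;
            col(r, x * H + y) = X(sy, sx, c);
          }
        }
      }
  return col;
}

cube col2im3(const mat& dcol, int H, int W, int C) {
  cube dX(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int r = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (int x = 0; x < W; ++x) {
          const int sx = x + dx;
          if (sx < 0 || sx >= W) continue;
          for (int y = 0; y < H; ++y) {
            const int sy = y + dy;
            if (sy < 0 || sy >= H) continue;
            dX(sy, sx, c) += dcol(r, x * H + y);
          }
        }
      }
  return dX;
}

cube conv_forward(const mat& col, const mat& W, const mat& b, int H, int Wd) {
  mat Z = W * col;  // Cout x (H*W)
  Z.each_col() += b.col(0);
  cube out(H, Wd, Z.n_rows);
  for (uword c = 0; c < Z.n_rows; ++c)
    out.slice(c) = reshape(Z.row(c).t(), H, Wd);
  return out;
}

cube maxpool_hw(const cube& A, ucube& argmax, int ph, int pw) {
  const int Ho = A.n_rows / ph, Wo = A.n_cols / pw, C = A.n_slices;
  cube out(Ho, Wo, C);
  argmax.set_size(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < Wo; ++x)
      for (int y = 0; y < Ho; ++y) {
        double best = -datum::inf;
        uword bidx = 0;
        for (int dx = 0; dx < pw; ++dx)
          for (int dy = 0; dy < ph; ++dy) {
            const int yy = ph * y + dy, xx = pw * x + dx;
            const double v = A(yy, xx, c);
            if (v > best) { best = v; bidx = xx * A.n_rows + yy; }
          }
        out(y, x, c) = best;
        argmax(y, x, c) = bidx;
      }
  return out;
}

struct BlockCache {
  mat col;          // im2col of the block input
  cube xhat;        // BN-normalized pre-activation (train mode)
  cube act;         // post-ReLU activation (pre pool)
  ucube argmax;     // pooling argmax (linear index into act slice)
  cube drop_mask;   // dropout mask (post pool); empty in eval mode
  int Hin, Win, Cin;
};

struct BatchCache {
  std::vector<std::vector<BlockCache> > blocks;  // [sample][block]
  std::vector<vec> bn_invstd;                    // [block], batch invstd
  mat features;   // B x F (post GAP)
  mat h1;         // fc_hidden x B (post ReLU)
  mat probs;      // n_cat x B
  std::vector<std::pair<int, int> > gap_dims;    // last pooled (Ho, Wo)
};

void forward_batch(Net& net, const std::vector<cube>& inputs, bool train,
                   Rng* rng, BatchCache& cache) {
  const int B = inputs.size();
  cache.blocks.assign(B, std::vector<BlockCache>(net.n_blocks));
  cache.bn_invstd.assign(net.n_blocks, vec());
  std::vector<cube> cur(B);
  for (int i = 0; i < B; ++i) cur[i] = inputs[i];
  for (int b = 0; b < net.n_blocks; ++b) {
    std::vector<cube> pre(B);
    for (int i = 0; i < B; ++i) {
      BlockCache& bc = cache.blocks[i][b];
      bc.Hin = cur[i].n_rows; bc.Win = cur[i].n_cols; bc.Cin = cur[i].n_slices;
      if (bc.Hin < net.pool_h[b] || bc.Win < net.pool_w[b])
        stop("input too small for the configured number of conv blocks");
      bc.col = im2col3(cur[i]);
      pre[i] = conv_forward(bc.col, net.convW[b].w, net.convB[b].w,
                            bc.Hin, bc.Win);
      if (!train) bc.col.reset();  // not needed outside backprop
    }
    const int C = net.channels[b];
    vec mu(C), invstd(C);
    if (train) {
      const double m = (double)B * pre[0].n_rows * pre[0].n_cols;
      for (int c = 0; c < C; ++c) {
        double s = 0, s2 = 0;
        for (int i = 0; i < B; ++i) {
          s += accu(pre[i].slice(c));
          s2 += accu(square(pre[i].slice(c)));
        }
        const double mean = s / m;
        double var = s2 / m - mean * mean;
        if (var < 0) var = 0;
        mu(c) = mean;
        invstd(c) = 1.0 / std::sqrt(var + BN_EPS);
        net.rmean[b](c, 0) = BN_MOMENTUM * net.rmean[b](c, 0) +
          (1 - BN_MOMENTUM) * mean;
        net.rvar[b](c, 0) = BN_MOMENTUM * net.rvar[b](c, 0) +
          (1 - BN_MOMENTUM) * var;
      }
      cache.bn_invstd[b] = invstd;
    } else {
      for (int c = 0; c < C; ++c) {
        mu(c) = net.rmean[b](c, 0);
        invstd(c) = 1.0 / std::sqrt(net.rvar[b](c, 0) + BN_EPS);
      }
    }
    for (int i = 0; i < B; ++i) {
      BlockCache& bc = cache.blocks[i][b];
      cube xhat(pre[i].n_rows, pre[i].n_cols, C);
      for (int c = 0; c < C; ++c)
        xhat.slice(c) = (pre[i].slice(c) - mu(c)) * invstd(c);
      if (train) bc.xhat = xhat;
      cube act(xhat.n_rows, xhat.n_cols, C);
      for (int c = 0; c < C; ++c)
        act.slice(c) = net.gamma[b].w(c, 0) * xhat.slice(c) +
          net.beta[b].w(c, 0);
      act.transform([](double v) { return v > 0 ? v : 0.0; });
      bc.act = act;
      cube pooled = maxpool_hw(act, bc.argmax, net.pool_h[b],
                               net.pool_w[b]);
      if (!train) { bc.act.reset(); bc.argmax.reset(); }
      if (train && net.dropout > 0) {
        bc.drop_mask.set_size(pooled.n_rows, pooled.n_cols, pooled.n_slices);
        const double keep = 1.0 - net.dropout;
        for (uword j = 0; j < pooled.n_elem; ++j)
          bc.drop_mask(j) = (rng->unif() < keep) ? 1.0 / keep : 0.0;
        pooled %= bc.drop_mask;
      }
      cur[i] = pooled;
    }
  }
  const int F = net.channels[net.n_blocks - 1];
  cache.features.set_size(B, F);
  cache.gap_dims.resize(B);
  for (int i = 0; i < B; ++i) {
    cache.gap_dims[i] = std::make_pair((int)cur[i].n_rows,
                                       (int)cur[i].n_cols);
    for (int c = 0; c < F; ++c)
      cache.features(i, c) = accu(cur[i].slice(c)) /
        (cur[i].n_rows * cur[i].n_cols);
  }
  mat z1 = net.fc1W.w * cache.features.t();
  z1.each_col() += net.fc1b.w.col(0);
  cache.h1 = clamp(z1, 0.0, datum::inf);
  mat z2 = net.fc2W.w * cache.h1;
  z2.each_col() += net.fc2b.w.col(0);
  cache.probs = 1.0 / (1.0 + exp(-z2));
}

struct Grads {
  std::vector<mat> convW, convB, gamma, beta;
  mat fc1W, fc1b, fc2W, fc2b;
  void zero_like(Net& n) {
    convW.resize(n.n_blocks); convB.resize(n.n_blocks);
    gamma.resize(n.n_blocks); beta.resize(n.n_blocks);
    for (int b = 0; b < n.n_blocks; ++b) {
      convW[b].zeros(size(n.convW[b].w));
      convB[b].zeros(size(n.convB[b].w));
      gamma[b].zeros(size(n.gamma[b].w));
      beta[b].zeros(size(n.beta[b].w));
    }
    fc1W.zeros(size(n.fc1W.w)); fc1b.zeros(size(n.fc1b.w));
    fc2W.zeros(size(n.fc2W.w)); fc2b.zeros(size(n.fc2b.w));
  }
};

// Gradient of the mean BCE loss wrt all parameters. y is n_cat x B.
void backward_batch(Net& net, BatchCache& cache, const mat& y, Grads& g) {
  const int B = cache.features.n_rows;
  g.zero_like(net);
  mat dz2 = (cache.probs - y) / ((double)B * net.n_cat);
  g.fc2W = dz2 * cache.h1.t();
  g.fc2b = sum(dz2, 1);
  mat dh1 = net.fc2W.w.t() * dz2;
  dh1.elem(find(cache.h1 <= 0)).zeros();
  g.fc1W = dh1 * cache.features;
  g.fc1b = sum(dh1, 1);
  mat dfeat = (net.fc1W.w.t() * dh1).t();  // B x F
  std::vector<cube> dcur(B);
  for (int i = 0; i < B; ++i) {
    const int Ho = cache.gap_dims[i].first, Wo = cache.gap_dims[i].second;
    dcur[i].set_size(Ho, Wo, net.channels[net.n_blocks - 1]);
    for (int c = 0; c < (int)dcur[i].n_slices; ++c)
      dcur[i].slice(c).fill(dfeat(i, c) / (Ho * Wo));
  }
  for (int b = net.n_blocks - 1; b >= 0; --b) {
    const int C = net.channels[b];
    std::vector<cube> dact(B);
    for (int i = 0; i < B; ++i) {
      BlockCache& bc = cache.blocks[i][b];
      if (bc.drop_mask.n_elem > 0) dcur[i] %= bc.drop_mask;
      dact[i].zeros(bc.act.n_rows, bc.act.n_cols, C);
      for (int c = 0; c < C; ++c)
        for (uword x = 0; x < dcur[i].n_cols; ++x)
          for (uword yy = 0; yy < dcur[i].n_rows; ++yy)
            dact[i].slice(c)(bc.argmax(yy, x, c)) += dcur[i](yy, x, c);
      for (int c = 0; c < C; ++c) {
        mat& da = dact[i].slice(c);
        da.elem(find(bc.act.slice(c) <= 0)).zeros();
      }
    }
    // batch-norm backward in the xhat form:
    // dpre = invstd * gamma * (dact - mean(dact) - xhat * mean(dact*xhat))
    const double m = (double)B * cache.blocks[0][b].xhat.n_rows *
      cache.blocks[0][b].xhat.n_cols;
    vec sum_dy(C, fill::zeros), sum_dyx(C, fill::zeros);
    for (int i = 0; i < B; ++i)
      for (int c = 0; c < C; ++c) {
        sum_dy(c) += accu(dact[i].slice(c));
        sum_dyx(c) += accu(dact[i].slice(c) %
                           cache.blocks[i][b].xhat.slice(c));
      }
    g.gamma[b].col(0) = sum_dyx;
    g.beta[b].col(0) = sum_dy;
    for (int i = 0; i < B; ++i) {
      BlockCache& bc = cache.blocks[i][b];
      mat dZ(C, bc.Hin * bc.Win);
      for (int c = 0; c < C; ++c) {
        const double scale = net.gamma[b].w(c, 0) * cache.bn_invstd[b](c);
        mat dpre = scale * (dact[i].slice(c)
                            - sum_dy(c) / m
                            - bc.xhat.slice(c) * (sum_dyx(c) / m));
        dZ.row(c) = vectorise(dpre).t();
      }
      g.convW[b] += dZ * bc.col.t();
      g.convB[b] += sum(dZ, 1);
      if (b > 0) {
        mat dcol = net.convW[b].w.t() * dZ;
        dcur[i] = col2im3(dcol, bc.Hin, bc.Win, bc.Cin);
      }
    }
  }
}

void adamw_step(std::vector<Param*>& params, Grads& g, Net& net,
                double lr, double wd, int t) {
  std::vector<mat*> grads;
  for (int b = 0; b < net.n_blocks; ++b) {
    grads.push_back(&g.convW[b]); grads.push_back(&g.convB[b]);
    grads.push_back(&g.gamma[b]); grads.push_back(&g.beta[b]);
  }
  grads.push_back(&g.fc1W); grads.push_back(&g.fc1b);
  grads.push_back(&g.fc2W); grads.push_back(&g.fc2b);
  const double bc1 = 1.0 - std::pow(ADAM_B1, t);
  const double bc2 = 1.0 - std::pow(ADAM_B2, t);
  for (size_t i = 0; i < params.size(); ++i) {
    Param& p = *params[i];
    const mat& gr = *grads[i];
    p.m = ADAM_B1 * p.m + (1 - ADAM_B1) * gr;
    p.v = ADAM_B2 * p.v + (1 - ADAM_B2) * square(gr);
    mat mhat = p.m / bc1;
    mat vhat = p.v / bc2;
    mat update = mhat / (sqrt(vhat) + ADAM_EPS);
    if (p.decay) update += wd * p.w;   // decoupled weight decay
    p.w -= lr * update;
  }
}

double bce_mean(const mat& probs, const mat& y) {
  mat p = clamp(probs, BCE_CLAMP, 1.0 - BCE_CLAMP);
  return accu(-(y % log(p) + (1.0 - y) % log(1.0 - p))) / p.n_elem;
}

// Non-interpolated AP (no tie handling; scores are continuous here).
double ap_score(const vec& s, const vec& y) {
  const double P = accu(y);
  if (P < 0.5) return datum::nan;
  uvec ord = sort_index(s, "descend");
  double tp = 0, ap = 0;
  for (uword i = 0; i < ord.n_elem; ++i)
    if (y(ord(i)) > 0.5) { tp += 1; ap += tp / (i + 1); }
  return ap / P;
}

double macro_map(const mat& scores, const mat& y) {
  double s = 0; int n = 0;
  for (uword j = 0; j < y.n_cols; ++j) {
    double a = ap_score(scores.col(j), y.col(j));
    if (!std::isnan(a)) { s += a; n += 1; }
  }
  return n > 0 ? s / n : datum::nan;
}

std::vector<cube> slice_inputs(const cube& x, const std::vector<int>& idx) {
  std::vector<cube> out(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) {
    cube c(x.n_rows, x.n_cols, 1);
    c.slice(0) = x.slice(idx[i]);
    out[i] = c;
  }
  return out;
}

mat eval_scores(Net& net, const cube& x, int batch_size) {
  const int N = x.n_slices;
  mat scores(N, net.n_cat);
  for (int start = 0; start < N; start += batch_size) {
    const int end = std::min(start + batch_size, N);
    std::vector<int> idx;
    for (int i = start; i < end; ++i) idx.push_back(i);
    std::vector<cube> inp = slice_inputs(x, idx);
    BatchCache cache;
    forward_batch(net, inp, false, nullptr, cache);
    for (int i = start; i < end; ++i)
      scores.row(i) = cache.probs.col(i - start).t();
  }
  return scores;
}

}  // namespace

// [[Rcpp::export]]
List cnn_init(List arch, int seed) {
  Net net;
  net.configure(arch);
  Rng rng((uint64_t)seed * 2654435761u + 1u);
  net.he_init(rng);
  return net.export_weights();
}

// [[Rcpp::export]]
List cnn_train(const arma::cube& x, const arma::mat& y,
               const arma::cube& xval, const arma::mat& yval,
               List arch, List weights, const arma::vec& lr_steps,
               int epochs, int batch_size, double weight_decay, int seed) {
  Net net;
  net.configure(arch);
  net.import_weights(weights);
  if ((int)y.n_rows != (int)x.n_slices)
    stop("label rows must match number of training clips");
  if ((int)y.n_cols != net.n_cat)
    stop("label columns must match n_categories");
  const int N = x.n_slices;
  if (N == 0) stop("empty training set");
  Rng rng((uint64_t)seed * 0x9E3779B97F4A7C15ull + 13u);
  std::vector<Param*> params = net.params();
  Grads g;
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  const int steps_per_epoch = (N + batch_size - 1) / batch_size;
  vec train_loss(epochs), train_map(epochs), val_map(epochs), lr_used(epochs);
  int best_epoch = -1;
  double best_val = -1;
  List best_weights = net.export_weights();
  int t = 0;
  for (int e = 0; e < epochs; ++e) {
    rng.shuffle(order);
    mat epoch_scores(N, net.n_cat, fill::zeros);
    double loss_sum = 0;
    for (int s = 0; s < steps_per_epoch; ++s) {
      const int start = s * batch_size;
      const int end = std::min(start + batch_size, N);
      std::vector<int> idx(order.begin() + start, order.begin() + end);
      std::vector<cube> inp = slice_inputs(x, idx);
      mat yb(net.n_cat, idx.size());
      for (size_t i = 0; i < idx.size(); ++i)
        yb.col(i) = y.row(idx[i]).t();
      BatchCache cache;
      forward_batch(net, inp, true, &rng, cache);
      loss_sum += bce_mean(cache.probs, yb) * idx.size();
      for (size_t i = 0; i < idx.size(); ++i)
        epoch_scores.row(idx[i]) = cache.probs.col(i).t();
      backward_batch(net, cache, yb, g);
      const double lr = lr_steps(std::min<uword>(t, lr_steps.n_elem - 1));
      ++t;
      adamw_step(params, g, net, lr, weight_decay, t);
      if (s == 0) lr_used(e) = lr;
    }
    train_loss(e) = loss_sum / N;
    train_map(e) = macro_map(epoch_scores, y);
    if (xval.n_slices > 0) {
      mat vs = eval_scores(net, xval, batch_size);
      val_map(e) = macro_map(vs, yval);
      // ties resolve to the later epoch: among equally validating epochs
      // the most-trained weights are kept (validation can saturate early
      // on easy desk-scale tasks)
      if (val_map(e) >= best_val) {
        best_val = val_map(e);
        best_epoch = e;
        best_weights = net.export_weights();
      }
    } else {
      val_map(e) = datum::nan;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["weights_final"] = net.export_weights(),
    _["weights_best"] = best_weights,
    _["best_epoch"] = best_epoch + 1,
    _["best_val_map"] = best_val,
    _["history"] = DataFrame::create(
      _["epoch"] = seq_len(epochs) - 1,
      _["lr"] = NumericVector(lr_used.begin(), lr_used.end()),
      _["train_loss"] = NumericVector(train_loss.begin(), train_loss.end()),
      _["train_map"] = NumericVector(train_map.begin(), train_map.end()),
      _["val_map"] = NumericVector(val_map.begin(), val_map.end())));
}

// [[Rcpp::export]]
arma::mat cnn_features(const arma::cube& x, List arch, List weights,
                       int batch_size = 32) {
  Net net;
  net.configure(arch);
  net.import_weights(weights);
  const int N = x.n_slices;
  mat feats(N, net.channels[net.n_blocks - 1]);
  for (int start = 0; start < N; start += batch_size) {
    const int end = std::min(start + batch_size, N);
    std::vector<int> idx;
    for (int i = start; i < end; ++i) idx.push_back(i);
    std::vector<cube> inp = slice_inputs(x, idx);
    BatchCache cache;
    forward_batch(net, inp, false, nullptr, cache);
    feats.rows(start, end - 1) = cache.features;
  }
  return feats;
}

// Mean BCE loss and its parameter gradients on one batch, for numerical
// gradient checking from the test suite.
// [[Rcpp::export]]
List cnn_loss_grads(const arma::cube& x, const arma::mat& y,
                    List arch, List weights) {
  Net net;
  net.configure(arch);
  net.import_weights(weights);
  std::vector<int> idx;
  for (uword i = 0; i < x.n_slices; ++i) idx.push_back(i);
  std::vector<cube> inp = slice_inputs(x, idx);
  BatchCache cache;
  net.dropout = 0;  // deterministic loss for finite differences
  forward_batch(net, inp, true, nullptr, cache);
  mat yb = y.t();
  double loss = bce_mean(cache.probs, yb);
  Grads g;
  backward_batch(net, cache, yb, g);
  List gl;
  for (int b = 0; b < net.n_blocks; ++b) {
    std::string s = std::to_string(b + 1);
    gl["conv" + s + "_W"] = g.convW[b];
    gl["conv" + s + "_b"] = g.convB[b];
    gl["bn" + s + "_gamma"] = g.gamma[b];
    gl["bn" + s + "_beta"] = g.beta[b];
  }
  gl["fc1_W"] = g.fc1W; gl["fc1_b"] = g.fc1b;
  gl["fc2_W"] = g.fc2W; gl["fc2_b"] = g.fc2b;
  return List::create(_["loss"] = loss, _["grads"] = gl);
}
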