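// Small convolutional network for patch-level malignancy scoring.
//
// Four 3x3 same-padded conv blocks with ReLU, max-pooling after the first
// two (and after the third for inputs >= 32 px), global average pooling and
// a sigmoid head. Trained with Adam on (optionally class-weighted) binary
// cross-entropy. All randomness (init, shuffling, flip augmentation) comes
// from one std::mt19937_64 stream so runs are bit-reproducible for a given
// seed; execution is single-threaded.
//
// Sample layout: one row per sample, element index c*S*S + y*S + x.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

struct Rng {
  std::mt19937_64 eng;
  bool have_spare;
  double spare;
  explicit Rng(uint64_t seed) : eng(seed), have_spare(false), spare(0.0) {}
  double unif() {  // in (0,1); portable across platforms
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {  // Marsaglia polar method, portable across platforms
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
  int integer(int n) { return static_cast<int>(eng() % static_cast<uint64_t>(n)); }
};

// im2col for 3x3 kernel, pad 1, stride 1. A is (Cin, H*H); out (Cin*9, H*H).
mat im2col3(const mat& A, int H) {
  const int Cin = A.n_rows;
  mat out(Cin * 9, H * H, fill::zeros);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < H; ++x) {
      const int pos = y * H + x;
      for (int ky = -1; ky <= 1; ++ky) {
        const int yy = y + ky;
        if (yy < 0 || yy >= H) continue;
        for (int kx = -1; kx <= 1; ++kx) {
          const int xx = x + kx;
          if (xx < 0 || xx >= H) continue;
          const int krow = (ky + 1) * 3 + (kx + 1);
          const int src = yy * H + xx;
          for (int c = 0; c < Cin; ++c)
            out(c * 9 + krow, pos) = A(c, src);
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add column gradients back onto the input maps.
mat col2im3(const mat& D, int Cin, int H) {
  mat out(Cin, H * H, fill::zeros);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < H; ++x) {
      const int pos = y * H + x;
      for (int ky = -1; ky <= 1; ++ky) {
        const int yy = y + ky;
        if (yy < 0 || yy >= H) continue;
        for (int kx = -1; kx <= 1; ++kx) {
          const int xx = x + kx;
          if (xx < 0 || xx >= H) continue;
          const int krow = (ky + 1) * 3 + (kx + 1);
          const int src = yy * H + xx;
          for (int c = 0; c < Cin; ++c)
            out(c, src) += D(c * 9 + krow, pos);
        }
      }
    }
  }
  return out;
}

mat maxpool2(const mat& A, int H, umat& idx) {
  const int F = A.n_rows, Hh = H / 2;
  mat out(F, Hh * Hh);
  idx.set_size(F, Hh * Hh);
  for (int y = 0; y < Hh; ++y) {
    for (int x = 0; x < Hh; ++x) {
      const int pos = y * Hh + x;
      const int p00 = (2 * y) * H + 2 * x;
      const int cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
      for (int f = 0; f < F; ++f) {
        int best = cand[0];
        double bv = A(f, cand[0]);
        for (int k = 1; k < 4; ++k)
          if (A(f, cand[k]) > bv) { bv = A(f, cand[k]); best = cand[k]; }
        out(f, pos) = bv;
        idx(f, pos) = best;
      }
    }
  }
  return out;
}

struct Net {
  int C, S, nL;
  std::vector<int> F;       // filters per conv layer
  std::vector<int> Hin;     // map side at each layer input
  std::vector<bool> pool;   // max-pool after layer?
  int Hf;                   // final map side
  std::vector<mat> W;
  std::vector<vec> b;
  vec wout;
  double bout;

  Net(int C_, int S_, const std::vector<int>& F_) : C(C_), S(S_), nL(4), F(F_) {
    pool = {true, true, S_ >= 32, false};
    Hin.resize(nL);
    int h = S_;
    for (int l = 0; l < nL; ++l) {
      Hin[l] = h;
      if (pool[l]) h /= 2;
    }
    Hf = h;
    W.resize(nL);
    b.resize(nL);
  }

  void init(Rng& rng) {
    int cin = C;
    for (int l = 0; l < nL; ++l) {
      const int fan_in = cin * 9;
      W[l].set_size(F[l], fan_in);
      const double sd = std::sqrt(2.0 / fan_in);
      for (uword i = 0; i < W[l].n_elem; ++i) W[l](i) = sd * rng.norm();
      b[l] = vec(F[l], fill::zeros);
      cin = F[l];
    }
    wout.set_size(F[nL - 1]);
    const double sd = std::sqrt(1.0 / F[nL - 1]);
    for (uword i = 0; i < wout.n_elem; ++i) wout(i) = sd * rng.norm();
    bout = 0.0;
  }
};

struct Cache {
  std::vector<mat> in;    // conv input maps
  std::vector<mat> col;   // im2col of inputs
  std::vector<mat> z;     // pre-activation
  std::vector<mat> a;     // post-ReLU
  std::vector<umat> pidx; // pooling argmax
  vec g;                  // GAP vector
  double logit, p;
};

double forward(const Net& net, const mat& x0, Cache& cc, bool keep) {
  mat cur = x0;
  if (keep) {
    cc.in.assign(net.nL, mat());
    cc.col.assign(net.nL, mat());
    cc.z.assign(net.nL, mat());
    cc.a.assign(net.nL, mat());
    cc.pidx.assign(net.nL, umat());
  }
  for (int l = 0; l < net.nL; ++l) {
    const int H = net.Hin[l];
    mat col = im2col3(cur, H);
    mat z = net.W[l] * col;
    z.each_col() += net.b[l];
    mat a = clamp(z, 0.0, datum::inf);
    if (keep) { cc.in[l] = cur; cc.col[l] = std::move(col); cc.z[l] = z; cc.a[l] = a; }
    if (net.pool[l]) {
      umat idx;
      cur = maxpool2(a, H, idx);
      if (keep) cc.pidx[l] = std::move(idx);
    } else {
      cur = std::move(a);
    }
  }
  vec g = mean(cur, 1);
  double logit = dot(net.wout, g) + net.bout;
  double p = 1.0 / (1.0 + std::exp(-logit));
  cc.g = g;
  cc.logit = logit;
  cc.p = p;
  return p;
}

struct Grads {
  std::vector<mat> W;
  std::vector<vec> b;
  vec wout;
  double bout;
  void zero_like(const Net& net) {
    W.resize(net.nL);
    b.resize(net.nL);
    for (int l = 0; l < net.nL; ++l) {
      W[l] = mat(size(net.W[l]), fill::zeros);
      b[l] = vec(net.F[l], fill::zeros);
    }
    wout = vec(net.F[net.nL - 1], fill::zeros);
    bout = 0.0;
  }
};

// Accumulate gradients of wt * BCE(p, y) for one cached sample.
void backward(const Net& net, const Cache& cc, double y, double wt, Grads& gr) {
  const double dlogit = wt * (cc.p - y);
  gr.wout += cc.g * dlogit;
  gr.bout += dlogit;
  const int nfin = net.Hf * net.Hf;
  vec dg = net.wout * dlogit;
  mat dcur(net.F[net.nL - 1], nfin);
  dcur.each_col() = dg / static_cast<double>(nfin);
  for (int l = net.nL - 1; l >= 0; --l) {
    const int H = net.Hin[l];
    mat dA;
    if (net.pool[l]) {
      dA = mat(net.F[l], H * H, fill::zeros);
      const umat& idx = cc.pidx[l];
      for (uword j = 0; j < idx.n_cols; ++j)
        for (uword f = 0; f < idx.n_rows; ++f)
          dA(f, idx(f, j)) += dcur(f, j);
    } else {
      dA = std::move(dcur);
    }
    mat dZ = dA % conv_to<mat>::from(cc.z[l] > 0.0);
    gr.W[l] += dZ * cc.col[l].t();
    gr.b[l] += sum(dZ, 1);
    if (l > 0) {
      mat dcol = net.W[l].t() * dZ;
      dcur = col2im3(dcol, net.F[l - 1], H);
    }
  }
}

mat row_to_maps(const rowvec& r, int C, int S, bool flipx, bool flipy) {
  mat out(C, S * S);
  for (int c = 0; c < C; ++c) {
    const int off = c * S * S;
    for (int y = 0; y < S; ++y) {
      const int ys = flipy ? (S - 1 - y) : y;
      for (int x = 0; x < S; ++x) {
        const int xs = flipx ? (S - 1 - x) : x;
        out(c, y * S + x) = r[off + ys * S + xs];
      }
    }
  }
  return out;
}

struct Adam {
  std::vector<mat> mW, vW;
  std::vector<vec> mb, vb;
  vec mwo, vwo;
  double mbo, vbo;
  double b1, b2, eps;
  long t;
  void setup(const Net& net) {
    b1 = 0.9; b2 = 0.999; eps = 1e-8; t = 0;
    mW.resize(net.nL); vW.resize(net.nL);
    mb.resize(net.nL); vb.resize(net.nL);
    for (int l = 0; l < net.nL; ++l) {
      mW[l] = mat(size(net.W[l]), fill::zeros);
      vW[l] = mat(size(net.W[l]), fill::zeros);
      mb[l] = vec(net.F[l], fill::zeros);
      vb[l] = vec(net.F[l], fill::zeros);
    }
    mwo = vec(net.F[net.nL - 1], fill::zeros);
    vwo = vec(net.F[net.nL - 1], fill::zeros);
    mbo = vbo = 0.0;
  }
  template <class T>
  void upd(T& w, T& m, T& v, const T& g, double lr, double c1, double c2) {
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * (g % g);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }
  void step(Net& net, const Grads& gr, double lr) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    for (int l = 0; l < net.nL; ++l) {
      upd(net.W[l], mW[l], vW[l], gr.W[l], lr, c1, c2);
      upd(net.b[l], mb[l], vb[l], gr.b[l], lr, c1, c2);
    }
    upd(net.wout, mwo, vwo, gr.wout, lr, c1, c2);
    mbo = b1 * mbo + (1.0 - b1) * gr.bout;
    vbo = b2 * vbo + (1.0 - b2) * gr.bout * gr.bout;
    net.bout -= lr * (mbo / c1) / (std::sqrt(vbo / c2) + eps);
  }
};

List net_to_list(const Net& net) {
  List Wl(net.nL), bl(net.nL);
  for (int l = 0; l < net.nL; ++l) {
    Wl[l] = wrap(net.W[l]);
    bl[l] = wrap(net.b[l]);
  }
  return List::create(_["W"] = Wl, _["b"] = bl, _["wout"] = wrap(net.wout),
                      _["bout"] = net.bout, _["C"] = net.C, _["S"] = net.S,
                      _["filters"] = wrap(std::vector<int>(net.F.begin(), net.F.end())));
}

Net net_from_list(const List& wl) {
  std::vector<int> F = as<std::vector<int>>(wl["filters"]);
  Net net(as<int>(wl["C"]), as<int>(wl["S"]), F);
  List Wl = wl["W"], bl = wl["b"];
  for (int l = 0; l < net.nL; ++l) {
    net.W[l] = as<mat>(Wl[l]);
    net.b[l] = as<vec>(bl[l]);
  }
  net.wout = as<vec>(wl["wout"]);
  net.bout = as<double>(wl["bout"]);
  return net;
}

double eval_loss(const Net& net, const mat& X, const vec& y, double& acc) {
  Cache cc;
  double loss = 0.0;
  int correct = 0;
  for (uword i = 0; i < X.n_rows; ++i) {
    mat x0 = row_to_maps(X.row(i), net.C, net.S, false, false);
    double p = forward(net, x0, cc, false);
    p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
    loss += -(y[i] * std::log(p) + (1.0 - y[i]) * std::log(1.0 - p));
    if ((p >= 0.5) == (y[i] >= 0.5)) ++correct;
  }
  acc = static_cast<double>(correct) / X.n_rows;
  return loss / X.n_rows;
}

}  // namespace

// [[Rcpp::export]]
List cnn_train_cpp(const arma::mat& X, const arma::vec& y, const arma::mat& Xval,
                   const arma::vec& yval, int C, int S, IntegerVector filters,
                   int epochs, int batch_size, double lr, bool class_weighting,
                   bool augment, int seed) {
  std::vector<int> F(filters.begin(), filters.end());
  Net net(C, S, F);
  Rng rng(static_cast<uint64_t>(seed) + 0x9e3779b97f4a7c15ULL);
  net.init(rng);
  Adam opt;
  opt.setup(net);

  const uword n = X.n_rows;
  double wpos = 1.0, wneg = 1.0;
  if (class_weighting) {
    const double npos = accu(y), nneg = n - npos;
    wpos = n / (2.0 * std::max(npos, 1.0));
    wneg = n / (2.0 * std::max(nneg, 1.0));
  }

  std::vector<uword> ord(n);
  for (uword i = 0; i < n; ++i) ord[i] = i;

  NumericVector tr_loss(epochs), va_loss(epochs), va_acc(epochs);
  double best_val = datum::inf;
  int best_epoch = 0;
  Net best = net;
  Cache cc;
  Grads gr;

  for (int e = 0; e < epochs; ++e) {
    for (uword i = n - 1; i > 0; --i)  // Fisher-Yates
      std::swap(ord[i], ord[rng.integer(static_cast<int>(i + 1))]);
    double epoch_loss = 0.0;
    uword start = 0;
    while (start < n) {
      const uword stop = std::min(start + static_cast<uword>(batch_size), n);
      gr.zero_like(net);
      for (uword k = start; k < stop; ++k) {
        const uword i = ord[k];
        const bool fx = augment && rng.unif() < 0.5;
        const bool fy = augment && rng.unif() < 0.5;
        mat x0 = row_to_maps(X.row(i), C, S, fx, fy);
        double p = forward(net, x0, cc, true);
        const double wt = (y[i] >= 0.5) ? wpos : wneg;
        const double pc = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
        epoch_loss += -wt * (y[i] * std::log(pc) + (1.0 - y[i]) * std::log(1.0 - pc));
        backward(net, cc, y[i], wt, gr);
      }
      const double bs = static_cast<double>(stop - start);
      for (int l = 0; l < net.nL; ++l) { gr.W[l] /= bs; gr.b[l] /= bs; }
      gr.wout /= bs;
      gr.bout /= bs;
      opt.step(net, gr, lr);
      start = stop;
    }
    tr_loss[e] = epoch_loss / n;
    double acc = 0.0;
    va_loss[e] = eval_loss(net, Xval, yval, acc);
    va_acc[e] = acc;
    if (va_loss[e] < best_val) {
      best_val = va_loss[e];
      best_epoch = e + 1;
      best = net;
    }
    Rcpp::checkUserInterrupt();
  }

  List out = net_to_list(best);
  out["log"] = DataFrame::create(_["epoch"] = seq_len(epochs), _["train_loss"] = tr_loss,
                                 _["val_loss"] = va_loss, _["val_acc"] = va_acc);
  out["best_epoch"] = best_epoch;
  out["best_val_loss"] = best_val;
  return out;
}

// [[Rcpp::export]]
List cnn_forward_cpp(const List& weights, const arma::mat& X) {
  Net net = net_from_list(weights);
  Cache cc;
  const uword n = X.n_rows;
  NumericVector prob(n);
  mat emb(n, net.F[net.nL - 1]);
  for (uword i = 0; i < n; ++i) {
    mat x0 = row_to_maps(X.row(i), net.C, net.S, false, false);
    prob[i] = forward(net, x0, cc, false);
    emb.row(i) = cc.g.t();
  }
  return List::create(_["prob"] = prob, _["embedding"] = wrap(emb));
}

// Grad-CAM on the final conv block: channel weights are the mean gradient of
// the target-class logit w.r.t. the block's activations, i.e. wout/(Hf*Hf)
// (negated for the benign target), followed by ReLU over the weighted sum.
// [[Rcpp::export]]
NumericMatrix cnn_gradcam_cpp(const List& weights, const arma::rowvec& x, int target_malignant) {
  Net net = net_from_list(weights);
  Cache cc;
  mat x0 = row_to_maps(x, net.C, net.S, false, false);
  forward(net, x0, cc, true);
  const mat& a4 = cc.a[net.nL - 1];
  const double sgn = target_malignant ? 1.0 : -1.0;
  const int nfin = net.Hf * net.Hf;
  vec alpha = sgn * net.wout / static_cast<double>(nfin);
  rowvec m = alpha.t() * a4;  // length Hf*Hf
  NumericMatrix out(net.Hf, net.Hf);
  for (int yy = 0; yy < net.Hf; ++yy)
    for (int xx = 0; xx < net.Hf; ++xx)
      out(yy, xx) = std::max(m[yy * net.Hf + xx], 0.0);
  return out;
}

// Finite-difference check of the analytic gradient on one sample (testing aid).
// [[Rcpp::export]]
double cnn_grad_check_cpp(const arma::rowvec& x, double y, int C, int S,
                          IntegerVector filters, int seed, int n_probe) {
  std::vector<int> F(filters.begin(), filters.end());
  Net net(C, S, F);
  Rng rng(static_cast<uint64_t>(seed));
  net.init(rng);
  Cache cc;
  Grads gr;
  gr.zero_like(net);
  mat x0 = row_to_maps(x, C, S, false, false);
  forward(net, x0, cc, true);
  backward(net, cc, y, 1.0, gr);

  auto loss_at = [&]() {
    Cache c2;
    double p = forward(net, x0, c2, false);
    p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
    return -(y * std::log(p) + (1.0 - y) * std::log(1.0 - p));
  };

  const double h = 1e-5;
  double max_err = 0.0;
  for (int probe = 0; probe < n_probe; ++probe) {
    const int l = rng.integer(net.nL);
    const int i = rng.integer(static_cast<int>(net.W[l].n_elem));
    const double orig = net.W[l](i);
    net.W[l](i) = orig + h;
    const double lp = loss_at();
    net.W[l](i) = orig - h;
    const double lm = loss_at();
    net.W[l](i) = orig;
    const double num = (lp - lm) / (2.0 * h);
    const double ana = gr.W[l](i);
    const double err = std::abs(num - ana) / std::max(1.0, std::max(std::abs(num), std::abs(ana)));
    max_err = std::max(max_err, err);
  }
  return max_err;
}

// Deterministic, platform-stable standard-normal draws for image synthesis.
// [[Rcpp::export]]
NumericVector fast_rnorm_cpp(int n, int seed) {
  Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 97531ULL);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.norm();
  return out;
}

// One-pass finalisation of the color render: base - d_cyto*cov_c - d_nuc*cov_n
// + N(0, sd), rounded and clamped to 8-bit counts.
// [[Rcpp::export]]
IntegerVector finalize_color_cpp(const arma::mat& cov_c, const arma::mat& cov_n,
                                 NumericVector base, NumericVector d_cyto,
                                 NumericVector d_nuc, double sd, int seed) {
  const int H = cov_c.n_rows, W = cov_c.n_cols;
  Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 11ULL);
  IntegerVector out(H * W * 3);
  out.attr("dim") = IntegerVector::create(H, W, 3);
  for (int ch = 0; ch < 3; ++ch) {
    const double b = base[ch], dc = d_cyto[ch], dn = d_nuc[ch];
    int* o = out.begin() + ch * H * W;
    const double* pc = cov_c.memptr();
    const double* pn = cov_n.memptr();
    for (int i = 0; i < H * W; ++i) {
      double v = b - dc * pc[i] - dn * pn[i] + sd * rng.norm();
      v = std::floor(v + 0.5);
      o[i] = static_cast<int>(std::min(255.0, std::max(0.0, v)));
    }
  }
  return out;
}

// One-pass finalisation of the RI render: ri + cyto_amp*cov_c + N(0, sd),
// clamped at zero.
// [[Rcpp::export]]
NumericMatrix finalize_ri_cpp(const arma::mat& ri, const arma::mat& cov_c,
                              double cyto_amp, double sd, int seed) {
  const int H = ri.n_rows, W = ri.n_cols;
  Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 29ULL);
  NumericMatrix out(H, W);
  const double* pr = ri.memptr();
  const double* pc = cov_c.memptr();
  for (int i = 0; i < H * W; ++i) {
    out[i] = std::max(0.0, pr[i] + cyto_amp * pc[i] + sd * rng.norm());
  }
  return out;
}

// Summed-area table with a zero border row/column.
// [[Rcpp::export]]
NumericMatrix integral_image_cpp(const arma::mat& m) {
  const int H = m.n_rows, W = m.n_cols;
  NumericMatrix out(H + 1, W + 1);
  for (int j = 0; j < W; ++j) {
    double colsum = 0.0;
    for (int i = 0; i < H; ++i) {
      colsum += m(i, j);
      out(i + 1, j + 1) = out(i + 1, j) + colsum;
    }
  }
  return out;
}

// Summed-area table (zero-bordered) of the Brenner-gradient field of an
// image: per interior pixel, squared two-pixel forward differences along
// both axes. Avoids materialising intermediate full-size matrices.
// [[Rcpp::export]]
NumericMatrix brenner_integral_cpp(const arma::mat& img) {
  const int H = img.n_rows - 2, W = img.n_cols - 2;
  NumericMatrix out(H + 1, W + 1);
  for (int j = 0; j < W; ++j) {
    double colsum = 0.0;
    for (int i = 0; i < H; ++i) {
      const double dh = img(i, j + 2) - img(i, j);
      const double dv = img(i + 2, j) - img(i, j);
      colsum += dh * dh + dv * dv;
      out(i + 1, j + 1) = out(i + 1, j) + colsum;
    }
  }
  return out;
}

// Rec. 601 luma of an H x W x 3 integer array of 8-bit counts.
// [[Rcpp::export]]
NumericMatrix luminance_cpp(const IntegerVector& arr) {
  IntegerVector d = arr.attr("dim");
  const int H = d[0], W = d[1];
  NumericMatrix out(H, W);
  const int* p = arr.begin();
  const int n = H * W;
  for (int i = 0; i < n; ++i) {
    out[i] = 0.299 * p[i] + 0.587 * p[i + n] + 0.114 * p[i + 2 * n];
  }
  return out;
}

// Max-accumulated soft elliptical coverage field for a set of nuclei.
// Coordinates are 1-based pixel centres; `scale` inflates the ellipse and
// `w` is the soft-edge half-width in units of the scaled ellipse metric.
// [[Rcpp::export]]
NumericMatrix cov_field_cpp(int H, NumericVector cx, NumericVector cy,
                            NumericVector a, NumericVector b, NumericVector theta,
                            double scale, double w) {
  NumericMatrix out(H, H);
  const double hi2 = (1 + w) * (1 + w), lo2 = (1 - w) * (1 - w);
  for (int k = 0; k < cx.size(); ++k) {
    const double ak = a[k] * scale, bk = b[k] * scale;
    const double ct = std::cos(theta[k]), st = std::sin(theta[k]);
    const double ext = std::max(ak, bk) * (1 + w) + 2;
    const int r0 = std::max(0, (int)std::floor(cy[k] - ext) - 1);
    const int r1 = std::min(H - 1, (int)std::ceil(cy[k] + ext) - 1);
    const int c0 = std::max(0, (int)std::floor(cx[k] - ext) - 1);
    const int c1 = std::min(H - 1, (int)std::ceil(cx[k] + ext) - 1);
    const double ia = 1.0 / ak, ib = 1.0 / bk;
    for (int j = c0; j <= c1; ++j) {
      const double dx = (j + 1) - cx[k];
      for (int i = r0; i <= r1; ++i) {
        const double dy = (i + 1) - cy[k];
        const double u = (dx * ct + dy * st) * ia;
        const double v = (-dx * st + dy * ct) * ib;
        const double s2 = u * u + v * v;
        if (s2 >= hi2) continue;
        double cov;
        if (s2 <= lo2) {
          cov = 1.0;
        } else {
          cov = std::min(1.0, std::max(0.0, (1 + w - std::sqrt(s2)) / (2 * w)));
        }
        if (cov > out(i, j)) out(i, j) = cov;
      }
    }
  }
  return out;
}

// Nuclear RI structure: additive dome (projected ellipsoid of height h_c),
// central chromatin clearing and envelope ring (both scaled by the class
// detail contrast), plus pre-sampled intranuclear speckle bumps.
// [[Rcpp::export]]
NumericMatrix ri_geom_cpp(int H, NumericVector cx, NumericVector cy,
                          NumericVector a, NumericVector b, NumericVector theta,
                          NumericVector h_c, double detail, NumericVector ring_amp,
                          NumericVector spx, NumericVector spy,
                          NumericVector srad, NumericVector samp) {
  NumericMatrix out(H, H);
  for (int k = 0; k < cx.size(); ++k) {
    const double ct = std::cos(theta[k]), st = std::sin(theta[k]);
    const double ext = std::max(a[k], b[k]) * 1.12 + 2;
    const int r0 = std::max(0, (int)std::floor(cy[k] - ext) - 1);
    const int r1 = std::min(H - 1, (int)std::ceil(cy[k] + ext) - 1);
    const int c0 = std::max(0, (int)std::floor(cx[k] - ext) - 1);
    const int c1 = std::min(H - 1, (int)std::ceil(cx[k] + ext) - 1);
    for (int j = c0; j <= c1; ++j) {
      const double dx = (j + 1) - cx[k];
      for (int i = r0; i <= r1; ++i) {
        const double dy = (i + 1) - cy[k];
        const double u = (dx * ct + dy * st) / a[k];
        const double v = (-dx * st + dy * ct) / b[k];
        const double s2 = u * u + v * v;
        if (s2 > 1.12 * 1.12) continue;
        const double s = std::sqrt(s2);
        double add = 0.0;
        if (s2 < 1.0) {
          const double dome = h_c[k] * std::sqrt(1.0 - s2);
          const double clr = 0.55 * detail *
            std::min(1.0, std::max(0.0, (0.55 - s) / 0.12));
          add += dome * (1.0 - clr);
        }
        if (std::fabs(s - 0.95) <= 0.12) {
          const double cphase = std::cos(M_PI * (s - 0.95) / 0.24);
          add += ring_amp[k] * cphase * cphase;
        }
        out(i, j) += add;
      }
    }
  }
  for (int k = 0; k < spx.size(); ++k) {
    const double rs = srad[k];
    const int r0 = std::max(0, (int)std::floor(spy[k] - rs) - 1);
    const int r1 = std::min(H - 1, (int)std::ceil(spy[k] + rs) - 1);
    const int c0 = std::max(0, (int)std::floor(spx[k] - rs) - 1);
    const int c1 = std::min(H - 1, (int)std::ceil(spx[k] + rs) - 1);
    for (int j = c0; j <= c1; ++j) {
      const double dx = (j + 1) - spx[k];
      for (int i = r0; i <= r1; ++i) {
        const double dy = (i + 1) - spy[k];
        const double d = std::sqrt(dx * dx + dy * dy) / rs;
        if (d < 1.0) {
          const double cph = std::cos(M_PI * d / 2.0);
          out(i, j) += samp[k] * cph * cph;
        }
      }
    }
  }
  return out;
}

// Hard elliptical membership label map; earlier nuclei win where overlapping.
// [[Rcpp::export]]
IntegerMatrix mask_field_cpp(int H, NumericVector cx, NumericVector cy,
                             NumericVector a, NumericVector b, NumericVector theta) {
  IntegerMatrix out(H, H);
  for (int k = 0; k < cx.size(); ++k) {
    const double ct = std::cos(theta[k]), st = std::sin(theta[k]);
    const double ext = std::max(a[k], b[k]) + 2;
    const int r0 = std::max(0, (int)std::floor(cy[k] - ext) - 1);
    const int r1 = std::min(H - 1, (int)std::ceil(cy[k] + ext) - 1);
    const int c0 = std::max(0, (int)std::floor(cx[k] - ext) - 1);
    const int c1 = std::min(H - 1, (int)std::ceil(cx[k] + ext) - 1);
    for (int j = c0; j <= c1; ++j) {
      const double dx = (j + 1) - cx[k];
      for (int i = r0; i <= r1; ++i) {
        const double dy = (i + 1) - cy[k];
        const double u = (dx * ct + dy * st) / a[k];
        const double v = (-dx * st + dy * ct) / b[k];
        if (u * u + v * v <= 1.0 && out(i, j) == 0) out(i, j) = k + 1;
      }
    }
  }
  return out;
}

// Additive raised-cosine elliptical bumps (staining artifacts).
// [[Rcpp::export]]
NumericMatrix add_bumps_cpp(NumericMatrix img, NumericVector cx, NumericVector cy,
                            NumericVector a, NumericVector b, NumericVector theta,
                            NumericVector amp) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out = clone(img);
  for (int k = 0; k < cx.size(); ++k) {
    const double ct = std::cos(theta[k]), st = std::sin(theta[k]);
    const double ext = std::max(a[k], b[k]) + 2;
    const int r0 = std::max(0, (int)std::floor(cy[k] - ext) - 1);
    const int r1 = std::min(H - 1, (int)std::ceil(cy[k] + ext) - 1);
    const int c0 = std::max(0, (int)std::floor(cx[k] - ext) - 1);
    const int c1 = std::min(W - 1, (int)std::ceil(cx[k] + ext) - 1);
    for (int j = c0; j <= c1; ++j) {
      const double dx = (j + 1) - cx[k];
      for (int i = r0; i <= r1; ++i) {
        const double dy = (i + 1) - cy[k];
        const double u = (dx * ct + dy * st) / a[k];
        const double v = (-dx * st + dy * ct) / b[k];
        const double s = std::sqrt(u * u + v * v);
        if (s < 1.0) {
          const double cph = std::cos(M_PI * s / 2.0);
          out(i, j) += amp[k] * cph * cph;
        }
      }
    }
  }
  return out;
}
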