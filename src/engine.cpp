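// Minimal CNN engine for encoder-decoder segmentation networks.
//
// Feature maps are stored as arma::fmat with one row per channel and one
// column per pixel, pixels in R's column-major order (p = row + H*col),
// batches laid out contiguously (col = b*H*W + p).  Convolutions are
// evaluated as im2col + single-precision GEMM; max pooling records per-cell
// argmax indices that unpooling scatters back to.  All trainable state lives
// in a Net object held behind an external pointer so the R-side training
// loop only ships mini-batches, not weights.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::IntegerVector;
using Rcpp::NumericVector;
using Rcpp::stop;

enum Op { OP_CONV = 1, OP_BN = 2, OP_RELU = 3, OP_POOL = 4, OP_UNPOOL = 5,
          OP_ADD = 6, OP_CONCAT = 7 };

struct ConvP {
  int k = 3, cin = 0, cout = 0, dil = 1;
  fmat W;            // cout x (k*k*cin), column = (ki*k + kj)*cin + c
  fvec b;
  fmat dW, vW;
  fvec db, vb;
  fmat col;          // im2col workspace, kept for the backward pass
  bool has_v = false;
};

struct BNP {
  int c = 0;
  fvec g, bta, dg, dbta, vg, vb;
  fvec rmean, rvar;  // running statistics (inference)
  fvec mu, invstd;   // saved batch statistics (training backward)
  bool has_v = false;
};

struct Instr {
  int op = 0;
  int p = -1;        // index into convs/bns/pools
  std::vector<int> src;
  int dst = 0;
};

struct Slot { fmat a; int C = 0, H = 0, W = 0; };
struct PoolRec { umat idx; int Hin = 0, Win = 0; };

struct Net {
  std::vector<ConvP> convs;
  std::vector<BNP> bns;
  std::vector<Instr> prog;
  std::vector<Slot> slots;   // forward activations (slot 0 = input)
  std::vector<PoolRec> pools;
  int B = 0;
  float eps = 1e-5f;
  float bn_mom = 0.1f;
};

// ---------------------------------------------------------------- im2col

static void im2col(const fmat& X, int C, int H, int W, int B,
                   int k, int dil, fmat& col) {
  const int K = k * k * C, N = H * W;
  const int pad = dil * (k - 1) / 2;
  if ((int)col.n_rows != K || (int)col.n_cols != N * B) col.set_size(K, N * B);
  // pixel-major fill: one contiguous K-float column written per output
  // pixel, reads come from the (much smaller, cache-resident) input map
  for (int b = 0; b < B; b++) {
    const int off = b * N;
    for (int c = 0; c < W; c++) {
      for (int r = 0; r < H; r++) {
        float* dst = col.colptr((size_t)off + (size_t)c * H + r);
        for (int ki = 0; ki < k; ki++) {
          const int sr = r + ki * dil - pad;
          for (int kj = 0; kj < k; kj++) {
            const int sc = c + kj * dil - pad;
            float* d = dst + (ki * k + kj) * C;
            if (sr < 0 || sr >= H || sc < 0 || sc >= W)
              std::memset(d, 0, C * sizeof(float));
            else
              std::memcpy(d, X.colptr((size_t)off + (size_t)sc * H + sr),
                          C * sizeof(float));
          }
        }
      }
    }
  }
}

static void col2im(const fmat& col, int C, int H, int W, int B,
                   int k, int dil, fmat& X) {
  const int N = H * W;
  const int pad = dil * (k - 1) / 2;
  X.zeros(C, (size_t)N * B);
  for (int b = 0; b < B; b++) {
    const int off = b * N;
    for (int c = 0; c < W; c++) {
      for (int r = 0; r < H; r++) {
        const float* src = col.colptr((size_t)off + (size_t)c * H + r);
        for (int ki = 0; ki < k; ki++) {
          const int sr = r + ki * dil - pad;
          if (sr < 0 || sr >= H) continue;
          for (int kj = 0; kj < k; kj++) {
            const int sc = c + kj * dil - pad;
            if (sc < 0 || sc >= W) continue;
            const float* sp = src + (ki * k + kj) * C;
            float* xp = X.colptr((size_t)off + (size_t)sc * H + sr);
            for (int ch = 0; ch < C; ch++) xp[ch] += sp[ch];
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------- pooling

// 2x2 window, stride 2; ties broken by first occurrence scanning the window
// in row-major order ((0,0),(0,1),(1,0),(1,1)).
static void pool_fwd(const fmat& X, int C, int H, int W, int B,
                     fmat& Y, umat& idx) {
  const int Ho = H / 2, Wo = W / 2, No = Ho * Wo, N = H * W;
  Y.set_size(C, No * B);
  idx.set_size(C, No * B);
  for (int b = 0; b < B; b++) {
    for (int oc = 0; oc < Wo; oc++) {
      for (int orow = 0; orow < Ho; orow++) {
        const int ocol = b * No + oc * Ho + orow;
        const int r = 2 * orow, c = 2 * oc;
        // candidate pixel indices, row-major within the window
        const int cand[4] = { r + H * c, r + H * (c + 1),
                              (r + 1) + H * c, (r + 1) + H * (c + 1) };
        for (int ch = 0; ch < C; ch++) {
          float best = X(ch, b * N + cand[0]);
          int besti = cand[0];
          for (int t = 1; t < 4; t++) {
            const float v = X(ch, b * N + cand[t]);
            if (v > best) { best = v; besti = cand[t]; }
          }
          Y(ch, ocol) = best;
          idx(ch, ocol) = besti;   // pixel index within its own image
        }
      }
    }
  }
}

static void unpool_fwd(const fmat& P, const umat& idx, int C, int Ho, int Wo,
                       int B, int H, int W, fmat& Y) {
  const int No = Ho * Wo, N = H * W;
  Y.zeros(C, N * B);
  for (int b = 0; b < B; b++)
    for (int p = 0; p < No; p++)
      for (int ch = 0; ch < C; ch++)
        Y(ch, b * N + idx(ch, b * No + p)) = P(ch, b * No + p);
}

// ---------------------------------------------------------------- helpers

// Writes Y = scale*(X - mean)/sd + shift in one fused pass; X is read as
// (C rows) x (n cols) with channels contiguous within each column.
static void bn_apply(const fmat& X, fmat& Y, const fvec& a, const fvec& c) {
  const int C = X.n_rows;
  const size_t n = X.n_cols;
  Y.set_size(C, n);
  const float* ap = a.memptr();
  const float* cp = c.memptr();
  for (size_t j = 0; j < n; j++) {
    const float* xp = X.colptr(j);
    float* yp = Y.colptr(j);
    for (int ch = 0; ch < C; ch++) yp[ch] = ap[ch] * xp[ch] + cp[ch];
  }
}

static void bn_forward(BNP& bn, const fmat& X, fmat& Y, bool use_batch,
                       bool update_run, float eps, float mom) {
  const int C = bn.c;
  const size_t n = X.n_cols;
  if (!use_batch && bn.rmean.n_elem == 0) use_batch = true;  // untrained net
  fvec a(C), cshift(C);
  if (use_batch) {
    fvec s(C, fill::zeros), ss(C, fill::zeros);
    for (size_t j = 0; j < n; j++) {
      const float* xp = X.colptr(j);
      for (int ch = 0; ch < C; ch++) { s(ch) += xp[ch]; ss(ch) += xp[ch] * xp[ch]; }
    }
    bn.mu = s / (float)n;
    fvec v = ss / (float)n - bn.mu % bn.mu;
    v.transform([](float x) { return x > 0.0f ? x : 0.0f; });
    bn.invstd = 1.0f / sqrt(v + eps);
    if (update_run) {
      if (bn.rmean.n_elem == 0) { bn.rmean = bn.mu; bn.rvar = v; }
      else {
        bn.rmean = (1.0f - mom) * bn.rmean + mom * bn.mu;
        bn.rvar  = (1.0f - mom) * bn.rvar  + mom * v;
      }
    }
    a = bn.g % bn.invstd;
    cshift = bn.bta - a % bn.mu;
  } else {
    fvec inv = 1.0f / sqrt(bn.rvar + eps);
    a = bn.g % inv;
    cshift = bn.bta - a % bn.rmean;
  }
  bn_apply(X, Y, a, cshift);
}

// dX given dY, using the input saved in `xin` plus saved batch statistics.
static void bn_backward(BNP& bn, const fmat& xin, const fmat& dY, fmat& dX) {
  const int C = bn.c;
  const size_t n = xin.n_cols;
  const float nf = (float)n;
  dX.set_size(C, n);
  fvec sdy(C, fill::zeros), sdyx(C, fill::zeros);
  for (size_t j = 0; j < n; j++) {
    const float* xp = xin.colptr(j);
    const float* dp = dY.colptr(j);
    for (int ch = 0; ch < C; ch++) {
      sdy(ch) += dp[ch];
      sdyx(ch) += dp[ch] * (xp[ch] - bn.mu(ch)) * bn.invstd(ch);
    }
  }
  bn.dg = sdyx;
  bn.dbta = sdy;
  fvec a = bn.g % bn.invstd;
  fvec m1 = sdy / nf, m2 = sdyx / nf;
  for (size_t j = 0; j < n; j++) {
    const float* xp = xin.colptr(j);
    const float* dp = dY.colptr(j);
    float* op = dX.colptr(j);
    for (int ch = 0; ch < C; ch++) {
      const float xhat = (xp[ch] - bn.mu(ch)) * bn.invstd(ch);
      op[ch] = a(ch) * (dp[ch] - m1(ch) - xhat * m2(ch));
    }
  }
}

// ---------------------------------------------------------------- network

static Net* get_net(SEXP ptr) {
  Rcpp::XPtr<Net> p(ptr);
  return p.get();
}

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(List instrs, List conv_shapes, IntegerVector bn_channels,
                int n_slots, int n_pools) {
#ifdef __GLIBC__
  // keep large tensor buffers on the heap so they are recycled across
  // iterations instead of being mapped and faulted in afresh every step
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
#endif
  Net* net = new Net();
  for (int i = 0; i < conv_shapes.size(); i++) {
    List s = conv_shapes[i];
    ConvP cp;
    cp.k = s["k"]; cp.cin = s["cin"]; cp.cout = s["cout"]; cp.dil = s["dil"];
    cp.W.zeros(cp.cout, cp.k * cp.k * cp.cin);
    cp.b.zeros(cp.cout);
    net->convs.push_back(std::move(cp));
  }
  for (int i = 0; i < bn_channels.size(); i++) {
    BNP bp;
    bp.c = bn_channels[i];
    bp.g.ones(bp.c); bp.bta.zeros(bp.c);
    bp.dg.zeros(bp.c); bp.dbta.zeros(bp.c);
    net->bns.push_back(std::move(bp));
  }
  for (int i = 0; i < instrs.size(); i++) {
    List in = instrs[i];
    Instr ins;
    ins.op = in["op"];
    ins.p = in["p"];
    IntegerVector s = in["src"];
    for (int j = 0; j < s.size(); j++) ins.src.push_back(s[j]);
    ins.dst = in["dst"];
    net->prog.push_back(ins);
  }
  net->slots.resize(n_slots);
  net->pools.resize(n_pools);
  return Rcpp::XPtr<Net>(net, true);
}

static void forward(Net* net, const fmat& x, int C, int H, int W, int B,
                    bool training, bool use_batch_stats) {
  net->B = B;
  net->slots[0].a = x;
  net->slots[0].C = C; net->slots[0].H = H; net->slots[0].W = W;
  for (auto& ins : net->prog) {
    Slot& d = net->slots[ins.dst];
    Slot& s = net->slots[ins.src[0]];
    switch (ins.op) {
    case OP_CONV: {
      ConvP& cp = net->convs[ins.p];
      if (s.C != cp.cin) stop("conv input channel mismatch");
      im2col(s.a, s.C, s.H, s.W, B, cp.k, cp.dil, cp.col);
      d.a = cp.W * cp.col;
      d.a.each_col() += cp.b;
      d.C = cp.cout; d.H = s.H; d.W = s.W;
      if (!training) cp.col.reset();
      break;
    }
    case OP_BN: {
      bn_forward(net->bns[ins.p], s.a, d.a, use_batch_stats, training,
                 net->eps, net->bn_mom);
      d.C = s.C; d.H = s.H; d.W = s.W;
      break;
    }
    case OP_RELU: {
      d.a.set_size(size(s.a));
      const float* xp = s.a.memptr();
      float* yp = d.a.memptr();
      const size_t ne = s.a.n_elem;
      for (size_t i = 0; i < ne; i++) yp[i] = xp[i] > 0.0f ? xp[i] : 0.0f;
      d.C = s.C; d.H = s.H; d.W = s.W;
      break;
    }
    case OP_POOL: {
      if (s.H % 2 || s.W % 2) stop("pooling requires even height and width");
      PoolRec& pr = net->pools[ins.p];
      pr.Hin = s.H; pr.Win = s.W;
      pool_fwd(s.a, s.C, s.H, s.W, B, d.a, pr.idx);
      d.C = s.C; d.H = s.H / 2; d.W = s.W / 2;
      break;
    }
    case OP_UNPOOL: {
      PoolRec& pr = net->pools[ins.p];
      unpool_fwd(s.a, pr.idx, s.C, s.H, s.W, B, pr.Hin, pr.Win, d.a);
      d.C = s.C; d.H = pr.Hin; d.W = pr.Win;
      break;
    }
    case OP_ADD: {
      Slot& s2 = net->slots[ins.src[1]];
      if (s.C != s2.C || s.H != s2.H || s.W != s2.W) stop("merge shape mismatch");
      d.a = s.a + s2.a;
      d.C = s.C; d.H = s.H; d.W = s.W;
      break;
    }
    case OP_CONCAT: {
      int Ctot = 0;
      for (int si : ins.src) Ctot += net->slots[si].C;
      d.a.set_size(Ctot, s.a.n_cols);
      int at = 0;
      for (int si : ins.src) {
        Slot& ss = net->slots[si];
        d.a.rows(at, at + ss.C - 1) = ss.a;
        at += ss.C;
      }
      d.C = Ctot; d.H = s.H; d.W = s.W;
      break;
    }
    default: stop("unknown opcode");
    }
  }
}

// Backward pass: grads[i] accumulates dLoss/dSlot_i.
static void backward(Net* net, const fmat& dout) {
  const int B = net->B;
  std::vector<fmat> grads(net->slots.size());
  grads[net->prog.back().dst] = dout;
  for (int i = (int)net->prog.size() - 1; i >= 0; i--) {
    Instr& ins = net->prog[i];
    fmat& dY = grads[ins.dst];
    if (dY.n_elem == 0) continue;
    Slot& s = net->slots[ins.src[0]];
    auto add_grad = [&](int slot, fmat&& g) {
      if (grads[slot].n_elem == 0) grads[slot] = std::move(g);
      else grads[slot] += g;
    };
    switch (ins.op) {
    case OP_CONV: {
      ConvP& cp = net->convs[ins.p];
      {
        fmat dWt = cp.col * dY.t();   // (K x Cout): faster GEMM orientation
        cp.dW = dWt.t();
      }
      cp.db = sum(dY, 1);
      fmat dcol = cp.W.t() * dY;
      fmat dX;
      col2im(dcol, cp.cin, s.H, s.W, B, cp.k, cp.dil, dX);
      add_grad(ins.src[0], std::move(dX));
      break;
    }
    case OP_BN: {
      fmat dX;
      bn_backward(net->bns[ins.p], s.a, dY, dX);
      add_grad(ins.src[0], std::move(dX));
      break;
    }
    case OP_RELU: {
      fmat dX(size(dY));
      const float* xp = s.a.memptr();
      const float* dp = dY.memptr();
      float* op = dX.memptr();
      const size_t ne = dY.n_elem;
      for (size_t i = 0; i < ne; i++) op[i] = xp[i] > 0.0f ? dp[i] : 0.0f;
      add_grad(ins.src[0], std::move(dX));
      break;
    }
    case OP_POOL: {
      PoolRec& pr = net->pools[ins.p];
      const int No = (pr.Hin / 2) * (pr.Win / 2), N = pr.Hin * pr.Win;
      fmat dX(s.C, (size_t)N * B, fill::zeros);
      for (int b = 0; b < B; b++)
        for (int p = 0; p < No; p++)
          for (int ch = 0; ch < s.C; ch++)
            dX(ch, b * N + pr.idx(ch, b * No + p)) += dY(ch, b * No + p);
      add_grad(ins.src[0], std::move(dX));
      break;
    }
    case OP_UNPOOL: {
      PoolRec& pr = net->pools[ins.p];
      const int No = s.H * s.W, N = pr.Hin * pr.Win;
      fmat dX(s.C, (size_t)No * B);
      for (int b = 0; b < B; b++)
        for (int p = 0; p < No; p++)
          for (int ch = 0; ch < s.C; ch++)
            dX(ch, b * No + p) = dY(ch, b * N + pr.idx(ch, b * No + p));
      add_grad(ins.src[0], std::move(dX));
      break;
    }
    case OP_ADD: {
      add_grad(ins.src[0], fmat(dY));
      add_grad(ins.src[1], fmat(dY));
      break;
    }
    case OP_CONCAT: {
      int at = 0;
      for (int si : ins.src) {
        Slot& ss = net->slots[si];
        add_grad(si, dY.rows(at, at + ss.C - 1));
        at += ss.C;
      }
      break;
    }
    }
    if (ins.dst != 0) dY.reset();   // free as we go
  }
}

// Softmax over channels (rows), in place; numerically stabilised.
static void softmax_rows(fmat& Z) {
  frowvec m = max(Z, 0);
  Z.each_row() -= m;
  Z = exp(Z);
  frowvec s = sum(Z, 0);
  Z.each_row() /= s;
}

// [[Rcpp::export(name = ".net_forward")]]
NumericVector net_forward(SEXP ptr, NumericVector x, bool batch_stats) {
  Net* net = get_net(ptr);
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 3 && dim.size() != 4) stop("input must be H x W x C [x B]");
  const int H = dim[0], W = dim[1], C = dim[2];
  const int B = dim.size() == 4 ? dim[3] : 1;
  const int N = H * W;
  fmat xin(C, (size_t)N * B);
  for (int b = 0; b < B; b++)
    for (int c = 0; c < C; c++)
      for (int p = 0; p < N; p++)
        xin(c, (size_t)b * N + p) = (float)x[p + N * c + (size_t)N * C * b];
  forward(net, xin, C, H, W, B, false, batch_stats);
  fmat& out = net->slots[net->prog.back().dst].a;
  fmat probs = out;
  softmax_rows(probs);
  const int K = probs.n_rows;
  NumericVector r((size_t)N * K * B);
  for (int b = 0; b < B; b++)
    for (int k = 0; k < K; k++)
      for (int p = 0; p < N; p++)
        r[p + N * k + (size_t)N * K * b] = probs(k, (size_t)b * N + p);
  r.attr("dim") = IntegerVector::create(H, W, K, B);
  return r;
}

// One momentum-SGD step on a mini-batch.  y holds 0-based class labels per
// pixel, in the same pixel/batch order as the input layout.
// [[Rcpp::export(name = ".net_train_step")]]
List net_train_step(SEXP ptr, NumericVector x, IntegerVector y,
                    double lr, double momentum) {
  Net* net = get_net(ptr);
  IntegerVector dim = x.attr("dim");
  const int H = dim[0], W = dim[1], C = dim[2];
  const int B = dim.size() == 4 ? dim[3] : 1;
  const int N = H * W;
  if (y.size() != (R_xlen_t)N * B) stop("label/input size mismatch");
  fmat xin(C, (size_t)N * B);
  for (int b = 0; b < B; b++)
    for (int c = 0; c < C; c++)
      for (int p = 0; p < N; p++)
        xin(c, (size_t)b * N + p) = (float)x[p + N * c + (size_t)N * C * b];
  forward(net, xin, C, H, W, B, true, true);

  fmat probs = net->slots[net->prog.back().dst].a;
  softmax_rows(probs);
  const double ntot = (double)N * B;
  double loss = 0.0;
  long correct = 0;
  fmat dZ = probs;
  for (size_t p = 0; p < (size_t)N * B; p++) {
    const int cls = y[p];
    loss -= std::log(std::max((double)probs(cls, p), 1e-12));
    dZ(cls, p) -= 1.0f;
    const int pred = probs(1, p) > probs(0, p) ? 1 : 0;
    if (pred == cls) correct++;
  }
  loss /= ntot;
  dZ /= (float)ntot;
  backward(net, dZ);

  const float flr = (float)lr, fm = (float)momentum;
  for (auto& cp : net->convs) {
    if (!cp.has_v) { cp.vW.zeros(size(cp.W)); cp.vb.zeros(cp.b.n_elem); cp.has_v = true; }
    cp.vW = fm * cp.vW - flr * cp.dW;  cp.W += cp.vW;
    cp.vb = fm * cp.vb - flr * cp.db;  cp.b += cp.vb;
  }
  for (auto& bp : net->bns) {
    if (!bp.has_v) { bp.vg.zeros(bp.c); bp.vb.zeros(bp.c); bp.has_v = true; }
    bp.vg = fm * bp.vg - flr * bp.dg;   bp.g += bp.vg;
    bp.vb = fm * bp.vb - flr * bp.dbta; bp.bta += bp.vb;
  }
  return List::create(Rcpp::Named("loss") = loss,
                      Rcpp::Named("accuracy") = (double)correct / ntot);
}

// Loss of a labelled batch without touching weights or running statistics
// (batch normalisation uses batch statistics so the value is differentiable
// in the parameters); used by the finite-difference gradient checks.
// [[Rcpp::export(name = ".net_loss")]]
double net_loss(SEXP ptr, NumericVector x, IntegerVector y) {
  Net* net = get_net(ptr);
  IntegerVector dim = x.attr("dim");
  const int H = dim[0], W = dim[1], C = dim[2];
  const int B = dim.size() == 4 ? dim[3] : 1;
  const int N = H * W;
  fmat xin(C, (size_t)N * B);
  for (int b = 0; b < B; b++)
    for (int c = 0; c < C; c++)
      for (int p = 0; p < N; p++)
        xin(c, (size_t)b * N + p) = (float)x[p + N * c + (size_t)N * C * b];
  forward(net, xin, C, H, W, B, false, true);
  fmat probs = net->slots[net->prog.back().dst].a;
  softmax_rows(probs);
  double loss = 0.0;
  for (size_t p = 0; p < (size_t)N * B; p++)
    loss -= std::log(std::max((double)probs(y[p], p), 1e-12));
  return loss / ((double)N * B);
}

// Analytic gradients of the last backward pass, in the layer order of the
// weight lists.
// [[Rcpp::export(name = ".net_get_grads")]]
List net_get_grads(SEXP ptr) {
  Net* net = get_net(ptr);
  List convW(net->convs.size()), convB(net->convs.size());
  for (size_t i = 0; i < net->convs.size(); i++) {
    convW[i] = Rcpp::wrap(conv_to<mat>::from(net->convs[i].dW));
    convB[i] = Rcpp::wrap(conv_to<vec>::from(net->convs[i].db));
  }
  List bnG(net->bns.size()), bnB(net->bns.size());
  for (size_t i = 0; i < net->bns.size(); i++) {
    bnG[i] = Rcpp::wrap(conv_to<vec>::from(net->bns[i].dg));
    bnB[i] = Rcpp::wrap(conv_to<vec>::from(net->bns[i].dbta));
  }
  return List::create(Rcpp::Named("conv_w") = convW,
                      Rcpp::Named("conv_b") = convB,
                      Rcpp::Named("bn_scale") = bnG,
                      Rcpp::Named("bn_shift") = bnB);
}

// [[Rcpp::export(name = ".net_param_count")]]
double net_param_count(SEXP ptr) {
  Net* net = get_net(ptr);
  double n = 0;
  for (auto& cp : net->convs) n += cp.W.n_elem + cp.b.n_elem;
  for (auto& bp : net->bns) n += bp.g.n_elem + bp.bta.n_elem;
  return n;
}

// [[Rcpp::export(name = ".net_set_weights")]]
void net_set_weights(SEXP ptr, List convW, List convB, List bnG, List bnB,
                     List bnRm, List bnRv) {
  Net* net = get_net(ptr);
  for (size_t i = 0; i < net->convs.size(); i++) {
    net->convs[i].W = conv_to<fmat>::from(Rcpp::as<mat>(convW[i]));
    net->convs[i].b = conv_to<fvec>::from(Rcpp::as<vec>(convB[i]));
  }
  for (size_t i = 0; i < net->bns.size(); i++) {
    net->bns[i].g = conv_to<fvec>::from(Rcpp::as<vec>(bnG[i]));
    net->bns[i].bta = conv_to<fvec>::from(Rcpp::as<vec>(bnB[i]));
    if (bnRm.size() > (R_xlen_t)i && !Rf_isNull(bnRm[i])) {
      net->bns[i].rmean = conv_to<fvec>::from(Rcpp::as<vec>(bnRm[i]));
      net->bns[i].rvar = conv_to<fvec>::from(Rcpp::as<vec>(bnRv[i]));
    }
  }
}

// [[Rcpp::export(name = ".net_get_weights")]]
List net_get_weights(SEXP ptr) {
  Net* net = get_net(ptr);
  List convW(net->convs.size()), convB(net->convs.size());
  for (size_t i = 0; i < net->convs.size(); i++) {
    convW[i] = Rcpp::wrap(conv_to<mat>::from(net->convs[i].W));
    convB[i] = Rcpp::wrap(conv_to<vec>::from(net->convs[i].b));
  }
  List bnG(net->bns.size()), bnB(net->bns.size()), bnRm(net->bns.size()),
      bnRv(net->bns.size());
  for (size_t i = 0; i < net->bns.size(); i++) {
    bnG[i] = Rcpp::wrap(conv_to<vec>::from(net->bns[i].g));
    bnB[i] = Rcpp::wrap(conv_to<vec>::from(net->bns[i].bta));
    bnRm[i] = net->bns[i].rmean.n_elem
                  ? Rcpp::wrap(conv_to<vec>::from(net->bns[i].rmean))
                  : R_NilValue;
    bnRv[i] = net->bns[i].rvar.n_elem
                  ? Rcpp::wrap(conv_to<vec>::from(net->bns[i].rvar))
                  : R_NilValue;
  }
  return List::create(Rcpp::Named("conv_w") = convW,
                      Rcpp::Named("conv_b") = convB,
                      Rcpp::Named("bn_scale") = bnG,
                      Rcpp::Named("bn_shift") = bnB,
                      Rcpp::Named("bn_mean") = bnRm,
                      Rcpp::Named("bn_var") = bnRv);
}

// [[Rcpp::export(name = ".net_release_buffers")]]
void net_release_buffers(SEXP ptr) {
  Net* net = get_net(ptr);
  for (auto& sl : net->slots) sl.a.reset();
  for (auto& cp : net->convs) { cp.col.reset(); cp.dW.reset(); }
}

// ------------------------------------------------- standalone layer ops
// These operate on single feature maps passed as C x (H*W) matrices in the
// same pixel order as the engine, and back the exported block operations.

// [[Rcpp::export(name = ".op_conv")]]
arma::mat op_conv(arma::mat x, int H, int W, arma::mat kw, arma::vec kb,
                  int k, int dil) {
  fmat X = conv_to<fmat>::from(x);
  fmat Wm = conv_to<fmat>::from(kw);
  fvec b = conv_to<fvec>::from(kb);
  fmat col;
  im2col(X, X.n_rows, H, W, 1, k, dil, col);
  fmat Y = Wm * col;
  Y.each_col() += b;
  return conv_to<mat>::from(Y);
}

// [[Rcpp::export(name = ".op_pool")]]
List op_pool(arma::mat x, int H, int W) {
  fmat X = conv_to<fmat>::from(x);
  fmat Y; umat idx;
  pool_fwd(X, X.n_rows, H, W, 1, Y, idx);
  return List::create(Rcpp::Named("pooled") = conv_to<mat>::from(Y),
                      Rcpp::Named("indices") = conv_to<imat>::from(
                          conv_to<Mat<long long>>::from(idx)));
}

// [[Rcpp::export(name = ".op_unpool")]]
arma::mat op_unpool(arma::mat p, arma::imat idx, int Ho, int Wo,
                    int H, int W) {
  fmat P = conv_to<fmat>::from(p);
  umat ui = conv_to<umat>::from(idx);
  fmat Y;
  unpool_fwd(P, ui, P.n_rows, Ho, Wo, 1, H, W, Y);
  return conv_to<mat>::from(Y);
}
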