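// Two-stage recurrent network for joint next-action prediction and
// trial-by-trial parameter inference, implemented from scratch (forward pass,
// backpropagation through time, Adam, early stopping) with Armadillo.
//
// Architecture (m = number of latent parameters):
//   stage 1: input x_t = [one-hot(a_t), r_t]  -> GRU (H1 cells, dropout)
//            -> m fully connected heads (hidden ReLU layer of width H1,
//               then a linear layer) producing per-parameter class logits
//            -> m linear regression heads of size 1 fed by the logits
//   stage 2: [logits_1..logits_m (if concatenation enabled), x_t]
//            -> GRU (H2 cells, dropout) -> linear + softmax action head
// Loss: action cross-entropy (targets a_{t+1}, last trial unsupervised)
//       + sum_i lambda_ce_i * CE(class of theta_i,t)
//       + sum_i lambda_mse_i * MSE(theta_i,t).
// With m = 0 the network degenerates to a purely data-driven action
// predictor (single GRU + softmax), which is how the d-RNN baseline is run.
//
// GRU gate convention:
//   z = sigmoid(Wz x + Uz h + bz), r = sigmoid(Wr x + Ur h + br)
//   n = tanh(Wn x + bnx + r * (Un h + bnh))
//   h' = (1 - z) * n + z * h
//
// All sequence-wide linear maps (input projections, heads, weight-gradient
// accumulations) are batched into single GEMMs over the flattened
// (units x batch*time) layout; only the recurrent half stays sequential.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
// single-precision internals: training is stochastic-gradient based and
// tolerant of float rounding; weights cross the R boundary as doubles
typedef arma::fmat mat;
typedef arma::fcube cube;
typedef arma::fvec vec;

struct NetSpec {
  int m, d1, H1, d2, H2, sumK;
  arma::ivec K;
  bool concat;
};

static NetSpec make_spec(int m, IntegerVector bins, int H1, int H2,
                         bool concat) {
  NetSpec s;
  s.m = m;
  s.H1 = H1;
  s.H2 = H2;
  s.d1 = 3;
  s.concat = concat;
  s.K = arma::ivec(std::max(m, 1), arma::fill::zeros);
  s.sumK = 0;
  for (int i = 0; i < m; ++i) {
    s.K[i] = bins[i];
    s.sumK += bins[i];
  }
  s.d2 = s.d1 + ((m > 0 && concat) ? s.sumK : 0);
  return s;
}

// Parameter layout (vectors stored as n x 1 matrices):
//   [gru1: Wz Uz bz Wr Ur br Wn Un bnx bnh]            (only if m > 0)
//   per head i: A1 (H1 x H1), c1, A2 (K_i x H1), c2, w (K_i x 1), d (1 x 1)
//   [gru2: same 10]
//   Wa (2 x H2), ba (2 x 1)
static const int HEAD_NP = 6;

static void push_gru(std::vector<mat>& P, int d, int H, std::mt19937& rng) {
  double b = 1.0 / std::sqrt((double)H);
  std::uniform_real_distribution<double> U(-b, b);
  auto rmat = [&](int r, int c) {
    mat M(r, c);
    for (arma::uword k = 0; k < M.n_elem; ++k) M(k) = U(rng);
    return M;
  };
  P.push_back(rmat(H, d));  P.push_back(rmat(H, H));  P.push_back(rmat(H, 1));
  P.push_back(rmat(H, d));  P.push_back(rmat(H, H));  P.push_back(rmat(H, 1));
  P.push_back(rmat(H, d));  P.push_back(rmat(H, H));  P.push_back(rmat(H, 1));
  P.push_back(rmat(H, 1));
}

static std::vector<mat> init_params(const NetSpec& s, std::mt19937& rng) {
  std::vector<mat> P;
  auto lmat = [&](int r, int c, int fan_in) {
    double b = 1.0 / std::sqrt((double)fan_in);
    std::uniform_real_distribution<double> U(-b, b);
    mat M(r, c);
    for (arma::uword k = 0; k < M.n_elem; ++k) M(k) = U(rng);
    return M;
  };
  if (s.m > 0) push_gru(P, s.d1, s.H1, rng);
  for (int i = 0; i < s.m; ++i) {
    P.push_back(lmat(s.H1, s.H1, s.H1));
    P.push_back(lmat(s.H1, 1, s.H1));
    P.push_back(lmat(s.K[i], s.H1, s.H1));
    P.push_back(lmat(s.K[i], 1, s.H1));
    P.push_back(lmat(s.K[i], 1, s.K[i]));
    P.push_back(lmat(1, 1, s.K[i]));
  }
  push_gru(P, s.d2, s.H2, rng);
  P.push_back(lmat(2, s.H2, s.H2));
  P.push_back(lmat(2, 1, s.H2));
  return P;
}

// fast exp via 2^k * 2^f decomposition with a 5th-order polynomial for the
// fractional part; relative error ~1e-7, ~5x faster than expf. Activations
// use it consistently in forward and (via stored values) backward, so
// gradients are exact for the network as computed.
static inline float fast_expf(float x) {
  if (x < -80.0f) x = -80.0f;
  if (x > 80.0f) x = 80.0f;
  float t = x * 1.4426950408889634f;
  float fi = std::floor(t);
  float f = t - fi;
  float p = 1.0f + f * (0.693147180f + f * (0.240226507f + f *
            (0.055504109f + f * (0.009618130f + f * 0.001333356f))));
  union { int32_t i; float f; } u;
  u.i = ((int32_t)fi + 127) << 23;
  return u.f * p;
}

static inline void sigmoid_inplace(mat& M) {
  float* p = M.memptr();
  for (arma::uword k = 0; k < M.n_elem; ++k)
    p[k] = 1.0f / (1.0f + fast_expf(-p[k]));
}

static inline void tanh_inplace(mat& M) {
  float* p = M.memptr();
  for (arma::uword k = 0; k < M.n_elem; ++k) {
    float s = 1.0f / (1.0f + fast_expf(-2.0f * p[k]));
    p[k] = 2.0f * s - 1.0f;
  }
}

struct GruCache {
  mat X;                    // (d, B*T) inputs, flattened by time blocks
  cube z, r, n, g, h;       // (H, B, T)
  mat mask;                 // (H, B*T); 0 or 1/(1-p)
  mat out;                  // (H, B*T) dropped-out output
  mat XZ, XR, XN;           // input projections (forward workspace)
  mat DAZ, DAR, DAN, DG, D3;  // backward workspace
};

// All large buffers live in a reusable workspace so repeated batches of the
// same shape never reallocate (fresh multi-MB allocations per update were
// a dominant cost through page faulting).
struct Work {
  GruCache C1, C2;
  mat x2, logitAll, dLogit, dH1, dx2;
  std::vector<mat> pre1, rel1, drel;
};

// forward one GRU over X (d, B*T); T time blocks of B columns.
// The three recurrent projections run as one stacked GEMM per step.
static void gru_forward(const mat* W, const mat& X, int B, int T, GruCache& C,
                        double dropout, bool train, std::mt19937& rng) {
  const mat &Wz = W[0], &Uz = W[1], &Wr = W[3], &Ur = W[4], &Wn = W[6],
            &Un = W[7];
  const vec bz = W[2].col(0), br = W[5].col(0), bnx = W[8].col(0),
            bnh = W[9].col(0);
  int H = Wz.n_rows;
  C.X = X;
  C.z.set_size(H, B, T); C.r.set_size(H, B, T); C.n.set_size(H, B, T);
  C.g.set_size(H, B, T); C.h.set_size(H, B, T);
  C.out.set_size(H, B * T);
  // input-to-hidden projections for the whole sequence in one GEMM each,
  // written into persistent workspace buffers
  C.XZ = Wz * X; C.XZ.each_col() += bz;
  C.XR = Wr * X; C.XR.each_col() += br;
  C.XN = Wn * X; C.XN.each_col() += bnx;
  const mat &XZ = C.XZ, &XR = C.XR, &XN = C.XN;
  mat Ustack = arma::join_cols(Uz, Ur, Un);  // (3H, H)
  C.mask.set_size(H, B * T);
  if (train && dropout > 0) {
    double keep = 1.0 - dropout;
    std::uniform_real_distribution<double> U01(0.0, 1.0);
    for (arma::uword k = 0; k < C.mask.n_elem; ++k)
      C.mask(k) = (U01(rng) < keep) ? 1.0 / keep : 0.0;
  } else {
    C.mask.ones();
  }
  mat h(H, B, arma::fill::zeros);
  mat Rp(3 * H, B);
  const int HB = H * B;
  for (int t = 0; t < T; ++t) {
    Rp = Ustack * h;  // rows: [Uz h; Ur h; Un h]
    // fused gate/state update, one pass over the H x B block
    const float* xz = XZ.colptr(t * B);
    const float* xr = XR.colptr(t * B);
    const float* xn = XN.colptr(t * B);
    const float* msk = C.mask.colptr(t * B);
    float* zp = C.z.slice_memptr(t);
    float* rp = C.r.slice_memptr(t);
    float* np = C.n.slice_memptr(t);
    float* gp = C.g.slice_memptr(t);
    float* hc = C.h.slice_memptr(t);
    float* op = C.out.colptr(t * B);
    float* hp = h.memptr();
    const float* rpp = Rp.memptr();
    const float* bn = bnh.memptr();
    for (int j = 0; j < B; ++j) {
      const float* rj = rpp + 3 * H * j;
      for (int i = 0; i < H; ++i) {
        int k = j * H + i;
        float z = 1.0f / (1.0f + fast_expf(-(xz[k] + rj[i])));
        float r = 1.0f / (1.0f + fast_expf(-(xr[k] + rj[i + H])));
        float g = rj[i + 2 * H] + bn[i];
        float s = 1.0f / (1.0f + fast_expf(-2.0f * (xn[k] + r * g)));
        float n = 2.0f * s - 1.0f;
        float hn = (1.0f - z) * n + z * hp[k];
        zp[k] = z; rp[k] = r; np[k] = n; gp[k] = g;
        hc[k] = hn; hp[k] = hn;
        op[k] = hn * msk[k];
      }
    }
    (void)HB;
  }
}

// backward through a GRU. dOut: (H, B*T) gradient wrt the dropped-out
// output. Accumulates weight gradients into G[0..9]; optionally fills dX.
static void gru_backward(const mat* W, const GruCache& C, int B, int T,
                         const mat& dOut, mat* G, mat* dX) {
  const mat &Wz = W[0], &Uz = W[1], &Wr = W[3], &Ur = W[4], &Wn = W[6],
            &Un = W[7];
  int H = Wz.n_rows;
  GruCache& Cw = const_cast<GruCache&>(C);
  Cw.DAZ.set_size(H, B * T); Cw.DAR.set_size(H, B * T);
  Cw.DAN.set_size(H, B * T); Cw.DG.set_size(H, B * T);
  Cw.D3.set_size(3 * H, B);
  mat &DAZ = Cw.DAZ, &DAR = Cw.DAR, &DAN = Cw.DAN, &DG = Cw.DG, &D3 = Cw.D3;
  mat Ustack_t = arma::join_rows(Uz.t(), Ur.t(), Un.t());  // (H, 3H)
  mat carry(H, B, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    // fused gate-gradient pass over the H x B block
    const float* dop = dOut.colptr(t * B);
    const float* msk = C.mask.colptr(t * B);
    const float* hq = (t == 0) ? nullptr : C.h.slice_memptr(t - 1);
    const float* zp = C.z.slice_memptr(t);
    const float* rp = C.r.slice_memptr(t);
    const float* np = C.n.slice_memptr(t);
    const float* gp = C.g.slice_memptr(t);
    float* dazp = DAZ.colptr(t * B);
    float* darp = DAR.colptr(t * B);
    float* danp = DAN.colptr(t * B);
    float* dgp = DG.colptr(t * B);
    float* d3p = D3.memptr();
    float* cp = carry.memptr();
    for (int j = 0; j < B; ++j) {
      float* d3j = d3p + 3 * H * j;
      for (int i = 0; i < H; ++i) {
        int k = j * H + i;
        float dh = dop[k] * msk[k] + cp[k];
        float hprev = hq ? hq[k] : 0.0f;
        float z = zp[k], r = rp[k], n = np[k], g = gp[k];
        float dz = dh * (hprev - n);
        float dan = dh * (1.0f - z) * (1.0f - n * n);
        float dr = dan * g;
        float dg = dan * r;
        float daz = dz * z * (1.0f - z);
        float dar = dr * r * (1.0f - r);
        dazp[k] = daz; darp[k] = dar; danp[k] = dan; dgp[k] = dg;
        d3j[i] = daz; d3j[i + H] = dar; d3j[i + 2 * H] = dg;
        cp[k] = dh * z;  // partial; recurrent term added via one GEMM below
      }
    }
    carry += Ustack_t * D3;
  }
  // batched weight-gradient GEMMs over the whole sequence
  mat Hprev(H, B * T);
  Hprev.cols(0, B - 1).zeros();
  if (T > 1) {
    // columns [B, B*T) are h at t-1
    Hprev.cols(B, B * T - 1) =
        mat(const_cast<float*>(C.h.memptr()), H, B * (T - 1), false, true);
  }
  G[0] += DAZ * C.X.t();  G[1] += DAZ * Hprev.t();
  G[2].col(0) += arma::sum(DAZ, 1);
  G[3] += DAR * C.X.t();  G[4] += DAR * Hprev.t();
  G[5].col(0) += arma::sum(DAR, 1);
  G[6] += DAN * C.X.t();  G[7] += DG * Hprev.t();
  G[8].col(0) += arma::sum(DAN, 1);
  G[9].col(0) += arma::sum(DG, 1);
  if (dX) *dX = Wz.t() * DAZ + Wr.t() * DAR + Wn.t() * DAN;
}

struct Batch {
  mat X;            // (3, B*T)
  arma::imat cls;   // (m, B*T) 0-based class labels
  mat theta;        // (m, B*T)
  arma::ivec anext; // (B*T), -1 = no target
  int B, T;
};

struct Losses {
  double total = 0, act_ce = 0;
  vec ce, mse;
};

// forward (+ optional backward) over one batch
static Losses run_batch(const NetSpec& s, const std::vector<mat>& P,
                        const Batch& b, const vec& lam_ce, const vec& lam_mse,
                        double dropout, bool train, std::mt19937& rng,
                        std::vector<mat>* G, mat* pL_out, mat* theta_out,
                        Work& ws) {
  int B = b.B, T = b.T, BT = B * T;
  int off2 = (s.m > 0) ? 10 + HEAD_NP * s.m : 0;
  double nTB = (double)BT;
  Losses L;
  L.ce = vec(std::max(s.m, 1), arma::fill::zeros);
  L.mse = vec(std::max(s.m, 1), arma::fill::zeros);

  GruCache &C1 = ws.C1, &C2 = ws.C2;
  mat &x2 = ws.x2, &logitAll = ws.logitAll, &dLogit = ws.dLogit;
  ws.pre1.resize(s.m); ws.rel1.resize(s.m); ws.drel.resize(s.m);
  std::vector<mat> &pre1 = ws.pre1, &rel1 = ws.rel1;
  if (s.m > 0) {
    gru_forward(&P[0], b.X, B, T, C1, dropout, train, rng);
    logitAll.set_size(s.sumK, BT);
    if (G) dLogit.zeros(s.sumK, BT);
    if (theta_out) theta_out->set_size(s.m, BT);
    int kof = 0;
    for (int i = 0; i < s.m; ++i) {
      const mat& A1 = P[10 + HEAD_NP * i];
      const vec c1 = P[10 + HEAD_NP * i + 1].col(0);
      const mat& A2 = P[10 + HEAD_NP * i + 2];
      const vec c2 = P[10 + HEAD_NP * i + 3].col(0);
      const vec w = P[10 + HEAD_NP * i + 4].col(0);
      double d0 = P[10 + HEAD_NP * i + 5](0, 0);
      int K = s.K[i];
      pre1[i] = A1 * C1.out;
      pre1[i].each_col() += c1;
      rel1[i] = pre1[i];
      rel1[i].elem(arma::find(pre1[i] < 0)).zeros();
      mat lg = A2 * rel1[i];
      lg.each_col() += c2;
      logitAll.rows(kof, kof + K - 1) = lg;
      // softmax CE per column
      arma::frowvec mx = arma::max(lg, 0);
      mat e = arma::exp(lg.each_row() - mx);
      arma::frowvec se = arma::sum(e, 0);
      mat sm = e.each_row() / se;
      arma::frowvec y = w.t() * lg + (float)d0;  // regression head on the logits
      if (theta_out) theta_out->row(i) = y;
      double ce = 0, msev = 0;
      for (int c = 0; c < BT; ++c) {
        int cl = b.cls(i, c);
        double p = sm(cl, c);
        ce -= std::log(std::max(p, 1e-12));
        double dy = y[c] - b.theta(i, c);
        msev += dy * dy;
      }
      L.ce[i] = ce / nTB;
      L.mse[i] = msev / nTB;
      if (G) {
        mat dlg = sm;  // CE part: lam * (softmax - onehot) / nTB
        for (int c = 0; c < BT; ++c) dlg(b.cls(i, c), c) -= 1.0;
        dlg *= lam_ce[i] / nTB;
        arma::frowvec dyv = (y - b.theta.row(i)) * (float)(2.0 * lam_mse[i] / nTB);
        dlg += w * dyv;  // MSE part through the regression head
        (*G)[10 + HEAD_NP * i + 4].col(0) += lg * dyv.t();
        (*G)[10 + HEAD_NP * i + 5](0, 0) += arma::accu(dyv);
        dLogit.rows(kof, kof + K - 1) = dlg;
      }
      kof += K;
    }
    // stage-2 input: [logits (optional), one-hot action, reward]
    if (s.concat) {
      x2.set_size(s.d2, BT);
      x2.rows(0, s.sumK - 1) = logitAll;
      x2.rows(s.sumK, s.d2 - 1) = b.X;
    } else {
      x2 = b.X;
    }
  } else {
    x2 = b.X;
  }

  gru_forward(&P[off2], x2, B, T, C2, dropout, train, rng);
  const mat& Wa = P[off2 + 10];
  const vec ba = P[off2 + 11].col(0);
  mat al = Wa * C2.out;
  al.each_col() += ba;
  arma::frowvec mx = arma::max(al, 0);
  mat e = arma::exp(al.each_row() - mx);
  arma::frowvec se = arma::sum(e, 0);
  mat sm = e.each_row() / se;
  if (pL_out) *pL_out = sm.row(0);
  int nAct = 0;
  for (int c = 0; c < BT; ++c)
    if (b.anext[c] >= 0) ++nAct;
  mat dal;
  if (G) dal.zeros(2, BT);
  for (int c = 0; c < BT; ++c) {
    int a1 = b.anext[c];
    if (a1 < 0) continue;
    L.act_ce -= std::log(std::max((double)sm(a1, c), 1e-12));
    if (G) {
      dal(0, c) = (sm(0, c) - (a1 == 0 ? 1.0 : 0.0)) / nAct;
      dal(1, c) = (sm(1, c) - (a1 == 1 ? 1.0 : 0.0)) / nAct;
    }
  }
  if (nAct > 0) L.act_ce /= nAct;
  L.total = L.act_ce;
  for (int i = 0; i < s.m; ++i)
    L.total += lam_ce[i] * L.ce[i] + lam_mse[i] * L.mse[i];

  if (!G) return L;

  // backward: action head, stage-2 GRU, heads, stage-1 GRU
  (*G)[off2 + 10] += dal * C2.out.t();
  (*G)[off2 + 11].col(0) += arma::sum(dal, 1);
  mat dH2 = Wa.t() * dal;
  mat& dx2 = ws.dx2;
  gru_backward(&P[off2], C2, B, T, dH2, &(*G)[off2],
               s.m > 0 ? &dx2 : nullptr);
  if (s.m > 0) {
    if (s.concat) dLogit += dx2.rows(0, s.sumK - 1);
    mat& dH1 = ws.dH1;
    dH1.zeros(s.H1, BT);
    int kof = 0;
    for (int i = 0; i < s.m; ++i) {
      const mat& A1 = P[10 + HEAD_NP * i];
      const mat& A2 = P[10 + HEAD_NP * i + 2];
      int K = s.K[i];
      mat dlg = dLogit.rows(kof, kof + K - 1);
      (*G)[10 + HEAD_NP * i + 2] += dlg * rel1[i].t();
      (*G)[10 + HEAD_NP * i + 3].col(0) += arma::sum(dlg, 1);
      mat& drel = ws.drel[i];
      drel = A2.t() * dlg;
      drel.elem(arma::find(pre1[i] <= 0)).zeros();
      (*G)[10 + HEAD_NP * i] += drel * C1.out.t();
      (*G)[10 + HEAD_NP * i + 1].col(0) += arma::sum(drel, 1);
      dH1 += A1.t() * drel;
      kof += K;
    }
    gru_backward(&P[0], C1, B, T, dH1, &(*G)[0], nullptr);
  }
  return L;
}

// Assemble a batch in the flattened (features, B*T) layout from the
// (features, T, N) session arrays.
static Batch gather(const arma::cube& X, const arma::icube& cls,
                    const arma::cube& theta, const arma::imat& anext,
                    const arma::uvec& idx, int m) {
  int T = X.n_cols, B = idx.n_elem;
  Batch b;
  b.B = B;
  b.T = T;
  b.X.set_size(3, B * T);
  if (m > 0) {
    b.cls.set_size(m, B * T);
    b.theta.set_size(m, B * T);
  }
  b.anext.set_size(B * T);
  for (int j = 0; j < B; ++j) {
    int a = idx[j];
    for (int t = 0; t < T; ++t) {
      int c = t * B + j;
      for (int d = 0; d < 3; ++d) b.X(d, c) = X(d, t, a);
      for (int i = 0; i < m; ++i) {
        b.cls(i, c) = cls(i, t, a);
        b.theta(i, c) = theta(i, t, a);
      }
      b.anext[c] = anext(t, a);
    }
  }
  return b;
}

static List params_to_list(const std::vector<mat>& P) {
  List out(P.size());
  for (size_t i = 0; i < P.size(); ++i)
    out[i] = wrap(arma::conv_to<arma::mat>::from(P[i]));
  return out;
}

static std::vector<mat> list_to_params(List L) {
  std::vector<mat> P;
  for (int i = 0; i < L.size(); ++i)
    P.push_back(arma::conv_to<mat>::from(as<arma::mat>(L[i])));
  return P;
}

// [[Rcpp::export]]
List trnn_train_cpp(const arma::cube& X, const arma::icube& cls,
                    const arma::cube& theta, const arma::imat& anext,
                    const arma::uvec& train_idx, const arma::uvec& val_idx,
                    IntegerVector bins, const arma::vec& lam_ce,
                    const arma::vec& lam_mse, int H1, int H2, double dropout,
                    double lr, int batch_size, int max_epochs, int patience,
                    bool concat, int seed, double grad_clip = 5.0,
                    Rcpp::Nullable<List> init_weights = R_NilValue,
                    int eval_every = 1) {
  int m = bins.size();
  NetSpec s = make_spec(m, bins, H1, H2, concat);
  std::mt19937 rng((unsigned)seed);
  vec flam_ce = arma::conv_to<vec>::from(lam_ce);
  vec flam_mse = arma::conv_to<vec>::from(lam_mse);
  std::vector<mat> P = init_params(s, rng);
  if (init_weights.isNotNull()) P = list_to_params(init_weights.get());
  std::vector<mat> M, V;
  for (auto& p : P) {
    M.push_back(mat(p.n_rows, p.n_cols, arma::fill::zeros));
    V.push_back(mat(p.n_rows, p.n_cols, arma::fill::zeros));
  }
  std::vector<arma::uword> tr(train_idx.begin(), train_idx.end());
  Work ws, ws_eval;
  int nval = val_idx.n_elem;
  double best = arma::datum::inf;
  std::vector<mat> bestP = P;
  int best_epoch = 0, wait = 0, step = 0;
  std::vector<double> h_ep, h_tr, h_val, h_val_act;
  std::vector<std::vector<double>> h_val_ce(m), h_val_mse(m);

  auto eval_set = [&](const arma::uvec& idx) {
    Losses acc;
    acc.ce = vec(std::max(m, 1), arma::fill::zeros);
    acc.mse = vec(std::max(m, 1), arma::fill::zeros);
    int n = idx.n_elem, done = 0;
    while (done < n) {
      int B = std::min(batch_size, n - done);
      Batch b = gather(X, cls, theta, anext,
                       idx.subvec(done, done + B - 1), m);
      Losses L = run_batch(s, P, b, flam_ce, flam_mse, 0.0, false, rng,
                           nullptr, nullptr, nullptr, ws_eval);
      double w = (double)B / n;
      acc.total += w * L.total;
      acc.act_ce += w * L.act_ce;
      acc.ce += w * L.ce;
      acc.mse += w * L.mse;
      done += B;
    }
    return acc;
  };

  for (int ep = 1; ep <= max_epochs; ++ep) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double trloss = 0;
    int nb = 0;
    for (size_t done = 0; done < tr.size(); done += batch_size) {
      size_t B = std::min((size_t)batch_size, tr.size() - done);
      arma::uvec idx(B);
      for (size_t j = 0; j < B; ++j) idx[j] = tr[done + j];
      Batch b = gather(X, cls, theta, anext, idx, m);
      std::vector<mat> G;
      for (auto& p : P) G.push_back(mat(p.n_rows, p.n_cols, arma::fill::zeros));
      Losses L = run_batch(s, P, b, flam_ce, flam_mse, dropout, true, rng, &G,
                           nullptr, nullptr, ws);
      trloss += L.total;
      ++nb;
      // global-norm gradient clipping (numerical safeguard for long BPTT)
      double nrm = 0;
      for (auto& g : G) nrm += arma::accu(g % g);
      nrm = std::sqrt(nrm);
      if (nrm > grad_clip)
        for (auto& g : G) g *= grad_clip / nrm;
      ++step;
      double b1 = 1.0 - std::pow(0.9, step), b2 = 1.0 - std::pow(0.999, step);
      for (size_t k = 0; k < P.size(); ++k) {
        M[k] = 0.9 * M[k] + 0.1 * G[k];
        V[k] = 0.999 * V[k] + 0.001 * (G[k] % G[k]);
        P[k] -= lr * (M[k] / b1) / (arma::sqrt(V[k] / b2) + 1e-8);
      }
      Rcpp::checkUserInterrupt();
    }
    if (ep % eval_every != 0 && ep != max_epochs) continue;
    Losses val = eval_set(val_idx);
    h_ep.push_back(ep);
    h_tr.push_back(nb > 0 ? trloss / nb : NA_REAL);
    h_val.push_back(val.total);
    h_val_act.push_back(val.act_ce);
    for (int i = 0; i < m; ++i) {
      h_val_ce[i].push_back(val.ce[i]);
      h_val_mse[i].push_back(val.mse[i]);
    }
    if (nval > 0 && val.total < best - 1e-6) {
      best = val.total;
      bestP = P;
      best_epoch = ep;
      wait = 0;
    } else if (nval > 0) {
      if (++wait >= patience) break;
    } else {
      bestP = P;
      best_epoch = ep;
    }
  }
  List hist = List::create(
      _["epoch"] = h_ep, _["train_total"] = h_tr, _["val_total"] = h_val,
      _["val_action_ce"] = h_val_act, _["val_param_ce"] = wrap(h_val_ce),
      _["val_param_mse"] = wrap(h_val_mse));
  return List::create(_["weights"] = params_to_list(bestP),
                      _["history"] = hist, _["best_epoch"] = best_epoch,
                      _["best_val"] = best);
}

// Deterministic forward pass (dropout off). Returns, per agent, the
// next-action probability P(a_{t+1} = L) produced at step t and the
// continuous parameter estimates theta_hat_t (unclipped; the R wrapper
// clips to supports).
// [[Rcpp::export]]
List trnn_predict_cpp(List weights, const arma::cube& X, IntegerVector bins,
                      int H1, int H2, bool concat) {
  int m = bins.size();
  NetSpec s = make_spec(m, bins, H1, H2, concat);
  std::vector<mat> P = list_to_params(weights);
  int T = X.n_cols, N = X.n_slices;
  std::mt19937 rng(1);
  arma::icube cls;
  arma::cube th;
  if (m > 0) {
    cls.zeros(m, T, N);
    th.zeros(m, T, N);
  }
  arma::imat an(T, N);
  an.fill(-1);
  arma::uvec idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  Batch b = gather(X, cls, th, an, idx, m);
  vec lz(std::max(m, 1), arma::fill::zeros);
  mat pL, tht;
  Work ws;
  run_batch(s, P, b, lz, lz, 0.0, false, rng, nullptr, &pL,
            m > 0 ? &tht : nullptr, ws);
  // columns are (t * N + agent); reshape to (T, N)
  arma::mat pmat(T, N);
  for (int a = 0; a < N; ++a)
    for (int t = 0; t < T; ++t) pmat(t, a) = pL(0, t * N + a);
  List out = List::create(_["p_next_left"] = pmat);
  if (m > 0) {
    List est(m);
    for (int i = 0; i < m; ++i) {
      arma::mat e(T, N);
      for (int a = 0; a < N; ++a)
        for (int t = 0; t < T; ++t) e(t, a) = tht(i, t * N + a);
      est[i] = e;
    }
    out["theta_hat"] = est;
  }
  return out;
}

// Loss (and optionally analytic gradients) on a full dataset with fixed
// weights; used for diagnostics and for finite-difference gradient checks.
// [[Rcpp::export]]
List trnn_loss_cpp(List weights, const arma::cube& X, const arma::icube& cls,
                   const arma::cube& theta, const arma::imat& anext,
                   IntegerVector bins, const arma::vec& lam_ce,
                   const arma::vec& lam_mse, int H1, int H2, bool concat,
                   bool gradients = false) {
  int m = bins.size();
  NetSpec s = make_spec(m, bins, H1, H2, concat);
  std::vector<mat> P = list_to_params(weights);
  int N = X.n_slices;
  arma::uvec idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  Batch b = gather(X, cls, theta, anext, idx, m);
  vec flam_ce = arma::conv_to<vec>::from(lam_ce);
  vec flam_mse = arma::conv_to<vec>::from(lam_mse);
  std::mt19937 rng(1);
  List out;
  if (gradients) {
    std::vector<mat> G;
    for (auto& p : P) G.push_back(mat(p.n_rows, p.n_cols, arma::fill::zeros));
    Work ws;
    Losses L = run_batch(s, P, b, flam_ce, flam_mse, 0.0, false, rng, &G,
                         nullptr, nullptr, ws);
    out = List::create(_["total"] = L.total, _["action_ce"] = L.act_ce,
                       _["param_ce"] = wrap(arma::conv_to<arma::vec>::from(L.ce)),
                       _["param_mse"] = wrap(arma::conv_to<arma::vec>::from(L.mse)),
                       _["gradients"] = params_to_list(G));
  } else {
    Work ws;
    Losses L = run_batch(s, P, b, flam_ce, flam_mse, 0.0, false, rng, nullptr,
                         nullptr, nullptr, ws);
    out = List::create(_["total"] = L.total, _["action_ce"] = L.act_ce,
                       _["param_ce"] = wrap(arma::conv_to<arma::vec>::from(L.ce)),
                       _["param_mse"] = wrap(arma::conv_to<arma::vec>::from(L.mse)));
  }
  return out;
}

// [[Rcpp::export]]
List trnn_init_cpp(IntegerVector bins, int H1, int H2, bool concat, int seed) {
  NetSpec s = make_spec(bins.size(), bins, H1, H2, concat);
  std::mt19937 rng((unsigned)seed);
  return params_to_list(init_params(s, rng));
}
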