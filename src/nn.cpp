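// Batch-level compute kernels for the conv/dense classifier.
//
// The training schedule (epochs, callbacks, early stopping) lives in R; this
// file implements one epoch of minibatch SGD (forward, backward, Adam) and
// inference. Arithmetic is single precision, as is standard for neural
// network training; weights cross the R boundary as doubles.
//
// Layouts: conv activations are (Pp*B) x channels matrices over the
// zero-padded (T+2) x (C+2) plane, rows ordered padded-position fastest then
// batch; conv kernels are (9*chIn) x filters with rows grouped by kernel
// offset (channel fastest within each offset); dense activations are
// B x units. Minibatch order comes from R (R RNG); dropout masks come from a
// xoshiro256++ stream seeded per epoch from R's RNG, so a fixed R seed
// reproduces training exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uvec;
using arma::uword;

namespace {

// xoshiro256++ for dropout masks (seeded via splitmix64).
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double uniform() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

struct Plan {
  int T, C, B, P, Pp;
  std::vector<uvec> rowsK;
  uvec interior;
};

Plan makePlan(int T, int C, int B) {
  Plan pl;
  pl.T = T; pl.C = C; pl.B = B; pl.P = T * C;
  const int Tp = T + 2;
  pl.Pp = Tp * (C + 2);
  pl.rowsK.resize(9);
  for (int k = 0; k < 9; ++k) {
    const int dt = k % 3, dc = k / 3;
    uvec r(static_cast<uword>(pl.P) * B);
    uword i = 0;
    for (int b = 0; b < B; ++b)
      for (int c = 1; c <= C; ++c)
        for (int t = 1; t <= T; ++t)
          r(i++) = (t + dt) + Tp * (c + dc - 1) + b * pl.Pp - 1;
    pl.rowsK[k] = r;
  }
  uvec itr(static_cast<uword>(pl.P) * B);
  uword i = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 1; c <= C; ++c)
      for (int t = 1; t <= T; ++t)
        itr(i++) = (t + 1) + Tp * c + b * pl.Pp - 1;
  pl.interior = itr;
  return pl;
}

struct Weights {
  fmat conv1W; fvec conv1b, bn1g, bn1b, bn1rm, bn1rv;
  fmat conv2W; fvec conv2b, bn2g, bn2b, bn2rm, bn2rv;
  fmat d1W; fvec d1b;
  fmat d2W; fvec d2b;
  fmat hW; fvec hb;
};

fmat getM(const List& w, const std::string& nm) {
  return arma::conv_to<fmat>::from(as<arma::mat>(w[nm]));
}
fvec getV(const List& w, const std::string& nm) {
  return arma::conv_to<fvec>::from(as<arma::vec>(w[nm]));
}

Weights readWeights(const List& w) {
  Weights W;
  W.conv1W = getM(w, "conv1_W"); W.conv1b = getV(w, "conv1_b");
  W.bn1g = getV(w, "bn1_gamma"); W.bn1b = getV(w, "bn1_beta");
  W.bn1rm = getV(w, "bn1_rmean"); W.bn1rv = getV(w, "bn1_rvar");
  W.conv2W = getM(w, "conv2_W"); W.conv2b = getV(w, "conv2_b");
  W.bn2g = getV(w, "bn2_gamma"); W.bn2b = getV(w, "bn2_beta");
  W.bn2rm = getV(w, "bn2_rmean"); W.bn2rv = getV(w, "bn2_rvar");
  W.d1W = getM(w, "dense1_W"); W.d1b = getV(w, "dense1_b");
  W.d2W = getM(w, "dense2_W"); W.d2b = getV(w, "dense2_b");
  W.hW = getM(w, "head_W"); W.hb = getV(w, "head_b");
  return W;
}

SEXP putM(const fmat& m) { return wrap(arma::conv_to<arma::mat>::from(m)); }
SEXP putV(const fvec& v) { return wrap(arma::conv_to<arma::vec>::from(v)); }

List writeWeights(const Weights& W) {
  return List::create(
      Named("conv1_W") = putM(W.conv1W), Named("conv1_b") = putV(W.conv1b),
      Named("bn1_gamma") = putV(W.bn1g), Named("bn1_beta") = putV(W.bn1b),
      Named("bn1_rmean") = putV(W.bn1rm), Named("bn1_rvar") = putV(W.bn1rv),
      Named("conv2_W") = putM(W.conv2W), Named("conv2_b") = putV(W.conv2b),
      Named("bn2_gamma") = putV(W.bn2g), Named("bn2_beta") = putV(W.bn2b),
      Named("bn2_rmean") = putV(W.bn2rm), Named("bn2_rvar") = putV(W.bn2rv),
      Named("dense1_W") = putM(W.d1W), Named("dense1_b") = putV(W.d1b),
      Named("dense2_W") = putM(W.d2W), Named("dense2_b") = putV(W.d2b),
      Named("head_W") = putM(W.hW), Named("head_b") = putV(W.hb));
}

fmat convFwd(const fmat& Apad, const fmat& W, const fvec& b, const Plan& pl,
             fmat& Xcol) {
  const int ch = Apad.n_cols;
  Xcol.set_size(static_cast<uword>(pl.P) * pl.B, 9 * ch);
  for (int k = 0; k < 9; ++k)
    Xcol.cols(k * ch, (k + 1) * ch - 1) = Apad.rows(pl.rowsK[k]);
  fmat Z = Xcol * W;
  Z.each_row() += b.t();
  return Z;
}

void convBwd(const fmat& dZ, const fmat& Xcol, const fmat& W, const Plan& pl,
             int chIn, fmat& dW, fvec& db, fmat* dApad) {
  dW = Xcol.t() * dZ;
  db = arma::sum(dZ, 0).t();
  if (dApad != nullptr) {
    const fmat dXcol = dZ * W.t();
    dApad->zeros(static_cast<uword>(pl.Pp) * pl.B, chIn);
    for (int k = 0; k < 9; ++k)
      dApad->rows(pl.rowsK[k]) += dXcol.cols(k * chIn, (k + 1) * chIn - 1);
  }
}

// Batch norm forward (training): per-column standardization with double
// accumulators for the batch statistics.
fmat bnFwdTrain(const fmat& Z, const fvec& g, const fvec& be, double eps,
                fvec& mu, fvec& va, fmat& xhat, fvec& invstd) {
  const uword n = Z.n_rows, f = Z.n_cols;
  mu.set_size(f); va.set_size(f); invstd.set_size(f);
  xhat.set_size(n, f);
  fmat out(n, f);
  for (uword j = 0; j < f; ++j) {
    const float* z = Z.colptr(j);
    double s = 0.0, s2 = 0.0;
    for (uword i = 0; i < n; ++i) s += z[i];
    const double m = s / n;
    for (uword i = 0; i < n; ++i) { const double d = z[i] - m; s2 += d * d; }
    const double v = s2 / n;
    const float istd = static_cast<float>(1.0 / std::sqrt(v + eps));
    mu(j) = static_cast<float>(m);
    va(j) = static_cast<float>(v);
    invstd(j) = istd;
    const float gj = g(j), bj = be(j), mf = static_cast<float>(m);
    float* xh = xhat.colptr(j);
    float* o = out.colptr(j);
    for (uword i = 0; i < n; ++i) {
      const float x = (z[i] - mf) * istd;
      xh[i] = x;
      o[i] = x * gj + bj;
    }
  }
  return out;
}

fmat bnFwdInfer(const fmat& Z, const fvec& g, const fvec& be, const fvec& rm,
                const fvec& rv, double eps) {
  const uword n = Z.n_rows, f = Z.n_cols;
  fmat out(n, f);
  for (uword j = 0; j < f; ++j) {
    const float istd = static_cast<float>(1.0 / std::sqrt(rv(j) + eps));
    const float gj = g(j) * istd, bj = be(j) - rm(j) * gj;
    const float* z = Z.colptr(j);
    float* o = out.colptr(j);
    for (uword i = 0; i < n; ++i) o[i] = z[i] * gj + bj;
  }
  return out;
}

fmat bnBwd(const fmat& dOut, const fmat& xhat, const fvec& invstd,
           const fvec& g, fvec& dgamma, fvec& dbeta) {
  const uword n = dOut.n_rows, f = dOut.n_cols;
  dgamma.set_size(f); dbeta.set_size(f);
  fmat dx(n, f);
  for (uword j = 0; j < f; ++j) {
    const float* dO = dOut.colptr(j);
    const float* xh = xhat.colptr(j);
    double sg = 0.0, sb = 0.0;
    for (uword i = 0; i < n; ++i) { sg += dO[i] * xh[i]; sb += dO[i]; }
    dgamma(j) = static_cast<float>(sg);
    dbeta(j) = static_cast<float>(sb);
    const float gj = g(j), istd = invstd(j);
    const float m2 = static_cast<float>(gj * sg / n);  // mean(dxhat*xhat)
    const float m1 = static_cast<float>(gj * sb / n);  // mean(dxhat)
    float* d = dx.colptr(j);
    for (uword i = 0; i < n; ++i)
      d[i] = (dO[i] * gj - xh[i] * m2 - m1) * istd;
  }
  return dx;
}

// Fused inverted-dropout + ReLU: draws one uniform per unit and returns the
// activation A = Z * G, where G is the combined gradient mask (dropout scale
// where Z > 0, else 0) — exactly what the backward pass multiplies by.
fmat maskedRelu(const fmat& Z, double rate, fmat& G, Xoshiro& rng) {
  const double keep = 1.0 - rate;
  const float inv = static_cast<float>(1.0 / keep);
  G.set_size(Z.n_rows, Z.n_cols);
  fmat A(Z.n_rows, Z.n_cols);
  const float* z = Z.memptr();
  float* g = G.memptr();
  float* a = A.memptr();
  for (uword i = 0; i < Z.n_elem; ++i) {
    float gv = (rng.uniform() < keep) ? inv : 0.0f;
    if (z[i] <= 0.0f) gv = 0.0f;
    g[i] = gv;
    a[i] = z[i] * gv;
  }
  return A;
}

fmat relu(const fmat& Z) {
  fmat A(Z.n_rows, Z.n_cols);
  const float* z = Z.memptr();
  float* a = A.memptr();
  for (uword i = 0; i < Z.n_elem; ++i) a[i] = z[i] > 0.0f ? z[i] : 0.0f;
  return A;
}

// (P*B) x f conv activations (position fastest, then batch) -> B x (P*f).
fmat flatten(const fmat& A, int P, int B) {
  const int f = A.n_cols;
  fmat Fl(B, static_cast<uword>(P) * f);
  float* out = Fl.memptr();
  for (int j = 0; j < f; ++j) {
    const float* src = A.colptr(j);
    for (int b = 0; b < B; ++b) {
      const float* s = src + static_cast<uword>(b) * P;
      float* d = out + b + static_cast<uword>(P) * j * B;
      for (int p = 0; p < P; ++p) d[static_cast<uword>(p) * B] = s[p];
    }
  }
  return Fl;
}

fmat unflatten(const fmat& dFl, int P, int B) {
  const int f = dFl.n_cols / P;
  fmat dA(static_cast<uword>(P) * B, f);
  const float* in = dFl.memptr();
  for (int j = 0; j < f; ++j) {
    float* dst = dA.colptr(j);
    for (int b = 0; b < B; ++b) {
      float* d = dst + static_cast<uword>(b) * P;
      const float* s = in + b + static_cast<uword>(P) * j * B;
      for (int p = 0; p < P; ++p) d[p] = s[static_cast<uword>(p) * B];
    }
  }
  return dA;
}

struct AdamState {
  std::vector<fmat> m, v;
  double t;
};

void adamUpdate(float* wp, const float* gp, float* mp, float* vp, uword n,
                float lr, float c1, float c2) {
  for (uword i = 0; i < n; ++i) {
    mp[i] = 0.9f * mp[i] + 0.1f * gp[i];
    vp[i] = 0.999f * vp[i] + 0.001f * gp[i] * gp[i];
    wp[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + 1e-7f);
  }
}

void adamStep(fmat& w, const fmat& g, fmat& m, fmat& v, float lr, float c1,
              float c2) {
  adamUpdate(w.memptr(), g.memptr(), m.memptr(), v.memptr(), w.n_elem, lr,
             c1, c2);
}

void adamStepV(fvec& w, const fvec& g, fmat& m, fmat& v, float lr, float c1,
               float c2) {
  adamUpdate(w.memptr(), g.memptr(), m.memptr(), v.memptr(), w.n_elem, lr,
             c1, c2);
}

}  // namespace

// One epoch of minibatch training. `perm` is the (1-based) shuffled index
// order from R, `dropSeed` seeds this epoch's dropout stream; `adam` carries
// m/v slots per trainable tensor plus the step counter t. Returns updated
// weights, Adam state and summed training loss / correct-prediction counts.
// [[Rcpp::export(name = ".nnEpochCpp", rng = false)]]
List nnEpochCpp(List wIn, List adamIn, double lr, const arma::mat& Xflat,
                const arma::vec& y, int T, int C, const arma::ivec& perm,
                int batchSize, double dropSeed, double drop1, double drop2,
                double drop3, double drop4, double l2, double bnEps,
                double bnMom) {
  Weights W = readWeights(wIn);
  const fmat Xf = arma::conv_to<fmat>::from(Xflat);
  const int N = Xf.n_cols;
  const int P = T * C;
  const int f1 = W.conv1b.n_elem;
  const float bnm = static_cast<float>(bnMom);
  const float flr = static_cast<float>(lr);
  const float fl2 = static_cast<float>(l2);
  Xoshiro rng(static_cast<uint64_t>(dropSeed));

  std::vector<std::string> nm = {"conv1_W", "conv1_b", "bn1_gamma", "bn1_beta",
                                 "conv2_W", "conv2_b", "bn2_gamma", "bn2_beta",
                                 "dense1_W", "dense1_b", "dense2_W", "dense2_b",
                                 "head_W", "head_b"};
  AdamState st;
  st.t = as<double>(adamIn["t"]);
  for (const auto& n : nm) {
    st.m.push_back(getM(adamIn, "m_" + n));
    st.v.push_back(getM(adamIn, "v_" + n));
  }

  Plan plFull = makePlan(T, C, batchSize);
  double lossSum = 0.0, accSum = 0.0;

  for (int s = 0; s < N; s += batchSize) {
    const int B = std::min(batchSize, N - s);
    Plan plPart;
    const Plan& pl = (B == batchSize) ? plFull
                                      : (plPart = makePlan(T, C, B), plPart);
    uvec bidx(B);
    fvec yb(B);
    for (int i = 0; i < B; ++i) {
      bidx(i) = static_cast<uword>(perm(s + i) - 1);
      yb(i) = static_cast<float>(y(bidx(i)));
    }

    // forward
    fmat Apad0(static_cast<uword>(pl.Pp) * B, 1, arma::fill::zeros);
    Apad0.rows(pl.interior) = arma::vectorise(Xf.cols(bidx));
    fmat Xcol1, Xcol2;
    fmat Z1 = convFwd(Apad0, W.conv1W, W.conv1b, pl, Xcol1);
    fvec mu1, va1, inv1;
    fmat xhat1;
    fmat bn1out = bnFwdTrain(Z1, W.bn1g, W.bn1b, bnEps, mu1, va1, xhat1, inv1);
    fmat G1;
    fmat A1 = maskedRelu(bn1out, drop1, G1, rng);

    fmat Apad1(static_cast<uword>(pl.Pp) * B, f1, arma::fill::zeros);
    Apad1.rows(pl.interior) = A1;
    fmat Z2 = convFwd(Apad1, W.conv2W, W.conv2b, pl, Xcol2);
    fvec mu2, va2, inv2;
    fmat xhat2;
    fmat bn2out = bnFwdTrain(Z2, W.bn2g, W.bn2b, bnEps, mu2, va2, xhat2, inv2);
    fmat G2;
    fmat A2 = maskedRelu(bn2out, drop2, G2, rng);

    fmat Fl = flatten(A2, P, B);
    fmat Z3 = Fl * W.d1W;
    Z3.each_row() += W.d1b.t();
    fmat G3;
    fmat A3 = maskedRelu(Z3, drop3, G3, rng);
    fmat Z4 = A3 * W.d2W;
    Z4.each_row() += W.d2b.t();
    fmat G4;
    fmat A4 = maskedRelu(Z4, drop4, G4, rng);
    fvec z = A4 * W.hW + W.hb(0);
    fvec p = 1.0f / (1.0f + arma::exp(-z));

    // loss + accuracy bookkeeping (training-mode values, batch-summed)
    double bce = 0.0;
    for (int i = 0; i < B; ++i) {
      const double pc = std::min(std::max(static_cast<double>(p(i)), 1e-7),
                                 1.0 - 1e-7);
      bce -= yb(i) > 0.5f ? std::log(pc) : std::log(1.0 - pc);
      accSum += ((p(i) >= 0.5f) == (yb(i) == 1.0f)) ? 1.0 : 0.0;
    }
    const double pen = static_cast<double>(l2) *
        (arma::accu(arma::square(arma::conv_to<arma::mat>::from(W.d1W))) +
         arma::accu(arma::square(arma::conv_to<arma::mat>::from(W.d2W))));
    lossSum += bce + B * pen;

    // running batch-norm statistics
    W.bn1rm = bnm * W.bn1rm + (1 - bnm) * mu1;
    W.bn1rv = bnm * W.bn1rv + (1 - bnm) * va1;
    W.bn2rm = bnm * W.bn2rm + (1 - bnm) * mu2;
    W.bn2rv = bnm * W.bn2rv + (1 - bnm) * va2;

    // backward
    fmat dz(B, 1);
    for (int i = 0; i < B; ++i) dz(i, 0) = (p(i) - yb(i)) / B;
    fmat g_hW = A4.t() * dz;
    fvec g_hb(1);
    g_hb(0) = arma::accu(dz);
    fmat dA4 = dz * W.hW.t();

    fmat dZ4 = dA4 % G4;
    fmat g_d2W = A3.t() * dZ4 + 2.0f * fl2 * W.d2W;
    fvec g_d2b = arma::sum(dZ4, 0).t();
    fmat dA3 = dZ4 * W.d2W.t();

    fmat dZ3 = dA3 % G3;
    fmat g_d1W = Fl.t() * dZ3 + 2.0f * fl2 * W.d1W;
    fvec g_d1b = arma::sum(dZ3, 0).t();
    fmat dFl = dZ3 * W.d1W.t();

    fmat dBn2 = unflatten(dFl, P, B) % G2;
    fvec g_bn2g, g_bn2b;
    fmat dZ2 = bnBwd(dBn2, xhat2, inv2, W.bn2g, g_bn2g, g_bn2b);
    fmat g_c2W;
    fvec g_c2b;
    fmat dApad1;
    convBwd(dZ2, Xcol2, W.conv2W, pl, f1, g_c2W, g_c2b, &dApad1);

    fmat dBn1 = dApad1.rows(pl.interior) % G1;
    fvec g_bn1g, g_bn1b;
    fmat dZ1 = bnBwd(dBn1, xhat1, inv1, W.bn1g, g_bn1g, g_bn1b);
    fmat g_c1W;
    fvec g_c1b;
    convBwd(dZ1, Xcol1, W.conv1W, pl, 1, g_c1W, g_c1b, nullptr);

    // Adam update
    st.t += 1.0;
    const float c1 = static_cast<float>(1.0 - std::pow(0.9, st.t));
    const float c2 = static_cast<float>(1.0 - std::pow(0.999, st.t));
    adamStep(W.conv1W, g_c1W, st.m[0], st.v[0], flr, c1, c2);
    adamStepV(W.conv1b, g_c1b, st.m[1], st.v[1], flr, c1, c2);
    adamStepV(W.bn1g, g_bn1g, st.m[2], st.v[2], flr, c1, c2);
    adamStepV(W.bn1b, g_bn1b, st.m[3], st.v[3], flr, c1, c2);
    adamStep(W.conv2W, g_c2W, st.m[4], st.v[4], flr, c1, c2);
    adamStepV(W.conv2b, g_c2b, st.m[5], st.v[5], flr, c1, c2);
    adamStepV(W.bn2g, g_bn2g, st.m[6], st.v[6], flr, c1, c2);
    adamStepV(W.bn2b, g_bn2b, st.m[7], st.v[7], flr, c1, c2);
    adamStep(W.d1W, g_d1W, st.m[8], st.v[8], flr, c1, c2);
    adamStepV(W.d1b, g_d1b, st.m[9], st.v[9], flr, c1, c2);
    adamStep(W.d2W, g_d2W, st.m[10], st.v[10], flr, c1, c2);
    adamStepV(W.d2b, g_d2b, st.m[11], st.v[11], flr, c1, c2);
    adamStep(W.hW, g_hW, st.m[12], st.v[12], flr, c1, c2);
    adamStepV(W.hb, g_hb, st.m[13], st.v[13], flr, c1, c2);
  }

  List adamOut = clone(adamIn);
  adamOut["t"] = st.t;
  for (size_t i = 0; i < nm.size(); ++i) {
    adamOut["m_" + nm[i]] = putM(st.m[i]);
    adamOut["v_" + nm[i]] = putM(st.v[i]);
  }
  return List::create(Named("w") = writeWeights(W), Named("adam") = adamOut,
                      Named("lossSum") = lossSum, Named("accSum") = accSum);
}

// Inference over columns of Xflat (one flattened window per column),
// chunked; dropout off, batch norm on running statistics.
// [[Rcpp::export(name = ".nnPredictCpp", rng = false)]]
arma::vec nnPredictCpp(List wIn, const arma::mat& Xflat, int T, int C,
                       double bnEps, int chunk) {
  Weights W = readWeights(wIn);
  const fmat Xf = arma::conv_to<fmat>::from(Xflat);
  const int N = Xf.n_cols;
  const int P = T * C;
  const int f1 = W.conv1b.n_elem;
  arma::vec out(N);

  for (int s = 0; s < N; s += chunk) {
    const int B = std::min(chunk, N - s);
    Plan pl = makePlan(T, C, B);
    fmat Apad0(static_cast<uword>(pl.Pp) * B, 1, arma::fill::zeros);
    Apad0.rows(pl.interior) = arma::vectorise(Xf.cols(s, s + B - 1));
    fmat Xcol1, Xcol2;
    fmat Z1 = convFwd(Apad0, W.conv1W, W.conv1b, pl, Xcol1);
    fmat A1 = relu(bnFwdInfer(Z1, W.bn1g, W.bn1b, W.bn1rm, W.bn1rv, bnEps));
    fmat Apad1(static_cast<uword>(pl.Pp) * B, f1, arma::fill::zeros);
    Apad1.rows(pl.interior) = A1;
    fmat Z2 = convFwd(Apad1, W.conv2W, W.conv2b, pl, Xcol2);
    fmat A2 = relu(bnFwdInfer(Z2, W.bn2g, W.bn2b, W.bn2rm, W.bn2rv, bnEps));
    fmat Fl = flatten(A2, P, B);
    fmat Z3 = Fl * W.d1W;
    Z3.each_row() += W.d1b.t();
    fmat A3 = relu(Z3);
    fmat Z4 = A3 * W.d2W;
    Z4.each_row() += W.d2b.t();
    fmat A4 = relu(Z4);
    fvec z = A4 * W.hW + W.hb(0);
    for (int i = 0; i < B; ++i)
      out(s + i) = 1.0 / (1.0 + std::exp(-static_cast<double>(z(i))));
  }
  return out;
}
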