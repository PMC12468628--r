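// Hierarchically densely connected 3D U-Net: forward, backward and Adam
// updates, hand-written as direct cache-resident convolution sweeps.
// Single-channel input volume -> single-channel non-negative output.
//
// Feature maps are stored as (n_voxels x n_channels) matrices; the voxel
// linear index runs x fastest (x + d*(y + h*z)), matching R's column-major
// 3D arrays with dim c(d, h, w).
//
// Convolution weights are ((k^3 * cin) x cout) matrices with row index
// r = k + 27*c for kernel offset index k = (dx+1) + 3*(dy+1) + 9*(dz+1).
// All convolutions are 3x3x3 with zero padding 1; down-sampling uses
// stride 2, up-sampling is channel-reducing convolution followed by
// nearest-neighbour doubling (transposed-convolution equivalent).

#include <RcppArmadillo.h>
#include <memory>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

#if defined(__GNUC__) && !defined(__clang__)
// the surrounding build may default to -O2; these kernels are the hot path
#pragma GCC optimize("O3", "unroll-loops")
#endif

#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

// Gradients shrink exponentially through the layer stack; flushing float
// denormals to zero avoids pathological microcode stalls without any
// effect at the magnitudes that matter for training.
static inline void flushDenormals() {
#ifdef __SSE2__
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}

using namespace arma;

struct Dims3 {
  int d, h, w;
  int n() const { return d * h * w; }
  Dims3 half() const { return Dims3{d / 2, h / 2, w / 2}; }
};

// Hot single-precision plane sweeps. Deliberately compiled for the
// baseline instruction set only: runtime ISA dispatch would change
// floating-point reduction order between machines and make training
// trajectories hardware-dependent, which matters more here than the last
// factor in throughput.
#define GK_CLONES

GK_CLONES static void fwd_sweep4_f(float *__restrict__ yp,
                                   const float *x0, const float *x1,
                                   const float *x2, const float *x3,
                                   float w0, float w1, float w2, float w3,
                                   Dims3 din, Dims3 dout, int dx, int dy,
                                   int dz) {
  const int lo = dx < 0 ? -dx : 0;
  const int hi = din.d - dx < dout.d ? din.d - dx : dout.d;
  for (int zo = 0; zo < dout.w; ++zo) {
    const int zi = zo + dz;
    if (zi < 0 || zi >= din.w) continue;
    for (int yo = 0; yo < dout.h; ++yo) {
      const int yi = yo + dy;
      if (yi < 0 || yi >= din.h) continue;
      const long inb = din.d * (yi + (long)din.h * zi) + dx;
      float *__restrict__ d = yp + dout.d * (yo + (long)dout.h * zo);
      const float *__restrict__ s0 = x0 + inb;
      const float *__restrict__ s1 = x1 + inb;
      const float *__restrict__ s2 = x2 + inb;
      const float *__restrict__ s3 = x3 + inb;
      for (int x = lo; x < hi; ++x)
        d[x] += w0 * s0[x] + w1 * s1[x] + w2 * s2[x] + w3 * s3[x];
    }
  }
}

GK_CLONES static void fwd_sweep1_f(float *__restrict__ yp, const float *x0,
                                   float w0, Dims3 din, Dims3 dout, int dx,
                                   int dy, int dz) {
  const int lo = dx < 0 ? -dx : 0;
  const int hi = din.d - dx < dout.d ? din.d - dx : dout.d;
  for (int zo = 0; zo < dout.w; ++zo) {
    const int zi = zo + dz;
    if (zi < 0 || zi >= din.w) continue;
    for (int yo = 0; yo < dout.h; ++yo) {
      const int yi = yo + dy;
      if (yi < 0 || yi >= din.h) continue;
      const long inb = din.d * (yi + (long)din.h * zi) + dx;
      float *__restrict__ d = yp + dout.d * (yo + (long)dout.h * zo);
      const float *__restrict__ s0 = x0 + inb;
      for (int x = lo; x < hi; ++x) d[x] += w0 * s0[x];
    }
  }
}

GK_CLONES static void bwd_sweep4_f(const float *xp, float *dxp,
                                   const float *g0, const float *g1,
                                   const float *g2, const float *g3,
                                   const float *w, float *acc, Dims3 din,
                                   Dims3 dout, int dx, int dy, int dz,
                                   bool want_dx) {
  const int lo = dx < 0 ? -dx : 0;
  const int hi = din.d - dx < dout.d ? din.d - dx : dout.d;
  float a0 = 0, a1 = 0, a2 = 0, a3 = 0;
  const float w0 = w[0], w1 = w[1], w2 = w[2], w3 = w[3];
  for (int zo = 0; zo < dout.w; ++zo) {
    const int zi = zo + dz;
    if (zi < 0 || zi >= din.w) continue;
    for (int yo = 0; yo < dout.h; ++yo) {
      const int yi = yo + dy;
      if (yi < 0 || yi >= din.h) continue;
      const long inb = din.d * (yi + (long)din.h * zi) + dx;
      const long outb = dout.d * (yo + (long)dout.h * zo);
      const float *__restrict__ s = xp + inb;
      const float *__restrict__ p0 = g0 + outb;
      const float *__restrict__ p1 = g1 + outb;
      const float *__restrict__ p2 = g2 + outb;
      const float *__restrict__ p3 = g3 + outb;
      if (want_dx) {
        float *__restrict__ dd = dxp + inb;
        for (int x = lo; x < hi; ++x) {
          const float sx = s[x];
          const float v0 = p0[x], v1 = p1[x], v2 = p2[x], v3 = p3[x];
          a0 += sx * v0;
          a1 += sx * v1;
          a2 += sx * v2;
          a3 += sx * v3;
          dd[x] += w0 * v0 + w1 * v1 + w2 * v2 + w3 * v3;
        }
      } else {
        for (int x = lo; x < hi; ++x) {
          const float sx = s[x];
          a0 += sx * p0[x];
          a1 += sx * p1[x];
          a2 += sx * p2[x];
          a3 += sx * p3[x];
        }
      }
    }
  }
  acc[0] += a0;
  acc[1] += a1;
  acc[2] += a2;
  acc[3] += a3;
}

GK_CLONES static void bwd_sweep1_f(const float *xp, float *dxp,
                                   const float *g0, float w0, float *acc,
                                   Dims3 din, Dims3 dout, int dx, int dy,
                                   int dz, bool want_dx) {
  const int lo = dx < 0 ? -dx : 0;
  const int hi = din.d - dx < dout.d ? din.d - dx : dout.d;
  float a0 = 0;
  for (int zo = 0; zo < dout.w; ++zo) {
    const int zi = zo + dz;
    if (zi < 0 || zi >= din.w) continue;
    for (int yo = 0; yo < dout.h; ++yo) {
      const int yi = yo + dy;
      if (yi < 0 || yi >= din.h) continue;
      const long inb = din.d * (yi + (long)din.h * zi) + dx;
      const long outb = dout.d * (yo + (long)dout.h * zo);
      const float *__restrict__ s = xp + inb;
      const float *__restrict__ p0 = g0 + outb;
      if (want_dx) {
        float *__restrict__ dd = dxp + inb;
        for (int x = lo; x < hi; ++x) {
          const float gx = p0[x];
          a0 += s[x] * gx;
          dd[x] += w0 * gx;
        }
      } else {
        for (int x = lo; x < hi; ++x) a0 += s[x] * p0[x];
      }
    }
  }
  acc[0] += a0;
}

template <typename eT> struct ConvT {
  Mat<eT> W;
  Row<eT> b;
  Mat<eT> dW;
  Row<eT> db;
  Mat<eT> mW, vW;
  Row<eT> mb, vb;
  int cin = 0, cout = 0;

  void init(int cin_, int cout_) {
    cin = cin_;
    cout = cout_;
    W.zeros(27 * cin, cout);
    b.zeros(cout);
    dW.zeros(27 * cin, cout);
    db.zeros(cout);
    mW.zeros(27 * cin, cout);
    vW.zeros(27 * cin, cout);
    mb.zeros(cout);
    vb.zeros(cout);
  }
  long long nparams() const { return (long long)27 * cin * cout + cout; }
};

// Direct 3x3x3 convolution: for each (cout, cin-block, offset) triple a
// handful of weights multiply shifted copies of input channels. The
// per-channel grids are cache-resident and the inner x-loops are
// contiguous saxpy/dot sweeps, which beats an im2col + GEMM formulation
// at these very skinny channel counts. Single-precision sweeps go through
// the runtime-dispatched clones above.
template <typename eT>
static void conv_forward(const Mat<eT> &X, const Dims3 &din, int stride,
                         const ConvT<eT> &cv, Mat<eT> &Y, const Dims3 &dout) {
  Y.set_size(dout.n(), cv.cout);
  for (int co = 0; co < cv.cout; ++co) {
    eT *yp = Y.colptr(co);
    std::fill(yp, yp + dout.n(), cv.b(co));
    for (int k = 0; k < 27; ++k) {
      const int dx = k % 3 - 1, dy = (k / 3) % 3 - 1, dz = k / 9 - 1;
      if (stride == 1) {
        int c = 0;
        if constexpr (std::is_same<eT, float>::value) {
          for (; c + 4 <= cv.cin; c += 4)
            fwd_sweep4_f(yp, X.colptr(c), X.colptr(c + 1), X.colptr(c + 2),
                         X.colptr(c + 3), cv.W(k + 27 * c, co),
                         cv.W(k + 27 * (c + 1), co),
                         cv.W(k + 27 * (c + 2), co),
                         cv.W(k + 27 * (c + 3), co), din, dout, dx, dy, dz);
          for (; c < cv.cin; ++c)
            fwd_sweep1_f(yp, X.colptr(c), cv.W(k + 27 * c, co), din, dout,
                         dx, dy, dz);
        } else {
          const int lo = std::max(0, -dx), hi = std::min(dout.d, din.d - dx);
          for (; c < cv.cin; ++c) {
            const eT w = cv.W(k + 27 * c, co);
            for (int zo = 0; zo < dout.w; ++zo) {
              const int zi = zo + dz;
              if (zi < 0 || zi >= din.w) continue;
              for (int yo = 0; yo < dout.h; ++yo) {
                const int yi = yo + dy;
                if (yi < 0 || yi >= din.h) continue;
                const eT *__restrict__ sp =
                    X.colptr(c) + din.d * (yi + (long)din.h * zi) + dx;
                eT *__restrict__ dp =
                    yp + dout.d * (yo + (long)dout.h * zo);
                for (int x = lo; x < hi; ++x) dp[x] += w * sp[x];
              }
            }
          }
        }
      } else {
        for (int c = 0; c < cv.cin; ++c) {
          const eT w = cv.W(k + 27 * c, co);
          const eT *xp = X.colptr(c);
          for (int zo = 0; zo < dout.w; ++zo) {
            const int zi = stride * zo + dz;
            if (zi < 0 || zi >= din.w) continue;
            for (int yo = 0; yo < dout.h; ++yo) {
              const int yi = stride * yo + dy;
              if (yi < 0 || yi >= din.h) continue;
              const eT *src = xp + din.d * (yi + (long)din.h * zi);
              eT *dst = yp + dout.d * (yo + (long)dout.h * zo);
              for (int xo = 0; xo < dout.d; ++xo) {
                const int xi = stride * xo + dx;
                if (xi >= 0 && xi < din.d) dst[xo] += w * src[xi];
              }
            }
          }
        }
      }
    }
  }
}

// backward for one (input channel, block of CO output channels) pair
template <typename eT, int CO>
static void conv_bwd_block(const Mat<eT> &X, const Dims3 &din, int stride,
                           ConvT<eT> &cv, const Mat<eT> &dY,
                           const Dims3 &dout, Mat<eT> &dX, bool want_dx,
                           int c, int co0) {
  const eT *xp = X.colptr(c);
  eT *dxp = want_dx ? dX.colptr(c) : nullptr;
  const eT *gbase[CO];
  for (int j = 0; j < CO; ++j) gbase[j] = dY.colptr(co0 + j);
  for (int k = 0; k < 27; ++k) {
    const int dx = k % 3 - 1, dy = (k / 3) % 3 - 1, dz = k / 9 - 1;
    eT w[CO], acc[CO];
    for (int j = 0; j < CO; ++j) {
      w[j] = cv.W(k + 27 * c, co0 + j);
      acc[j] = eT(0);
    }
    if (stride == 1) {
      bool done = false;
      if constexpr (std::is_same<eT, float>::value) {
        if (CO == 4)
          bwd_sweep4_f(xp, dxp, gbase[0], gbase[1], gbase[2], gbase[3], w,
                       acc, din, dout, dx, dy, dz, want_dx);
        else
          bwd_sweep1_f(xp, dxp, gbase[0], w[0], acc, din, dout, dx, dy, dz,
                       want_dx);
        done = true;
      }
      if (!done) {
        const int lo = std::max(0, -dx), hi = std::min(dout.d, din.d - dx);
        for (int zo = 0; zo < dout.w; ++zo) {
          const int zi = zo + dz;
          if (zi < 0 || zi >= din.w) continue;
          for (int yo = 0; yo < dout.h; ++yo) {
            const int yi = yo + dy;
            if (yi < 0 || yi >= din.h) continue;
            const long inb = din.d * (yi + (long)din.h * zi) + dx;
            const long outb = dout.d * (yo + (long)dout.h * zo);
            const eT *__restrict__ s = xp + inb;
            for (int x = lo; x < hi; ++x) {
              const eT sx = s[x];
              eT gsum = eT(0);
              for (int j = 0; j < CO; ++j) {
                const eT gx = gbase[j][outb + x];
                acc[j] += sx * gx;
                gsum += w[j] * gx;
              }
              if (want_dx) dxp[inb + x] += gsum;
            }
          }
        }
      }
    } else {
      for (int zo = 0; zo < dout.w; ++zo) {
        const int zi = stride * zo + dz;
        if (zi < 0 || zi >= din.w) continue;
        for (int yo = 0; yo < dout.h; ++yo) {
          const int yi = stride * yo + dy;
          if (yi < 0 || yi >= din.h) continue;
          const long inb = din.d * (yi + (long)din.h * zi);
          const long outb = dout.d * (yo + (long)dout.h * zo);
          for (int xo = 0; xo < dout.d; ++xo) {
            const int xi = stride * xo + dx;
            if (xi < 0 || xi >= din.d) continue;
            const eT sx = xp[inb + xi];
            eT gsum = eT(0);
            for (int j = 0; j < CO; ++j) {
              const eT gx = gbase[j][outb + xo];
              acc[j] += sx * gx;
              gsum += w[j] * gx;
            }
            if (want_dx) dxp[inb + xi] += gsum;
          }
        }
      }
    }
    for (int j = 0; j < CO; ++j) cv.dW(k + 27 * c, co0 + j) += acc[j];
  }
}

template <typename eT>
static void conv_backward(const Mat<eT> &X, const Dims3 &din, int stride,
                          ConvT<eT> &cv, const Mat<eT> &dY, const Dims3 &dout,
                          Mat<eT> &dX, bool want_dx) {
  if (want_dx) dX.zeros(din.n(), cv.cin);
  for (int c = 0; c < cv.cin; ++c) {
    int co = 0;
    for (; co + 4 <= cv.cout; co += 4)
      conv_bwd_block<eT, 4>(X, din, stride, cv, dY, dout, dX, want_dx, c, co);
    for (; co < cv.cout; ++co)
      conv_bwd_block<eT, 1>(X, din, stride, cv, dY, dout, dX, want_dx, c, co);
  }
  cv.db += sum(dY, 0);
}

template <typename eT>
static void maxpool_forward(const Mat<eT> &X, const Dims3 &din, Mat<eT> &Y,
                            umat &idx) {
  const Dims3 dout = din.half();
  const int n = dout.n();
  Y.set_size(n, X.n_cols);
  idx.set_size(n, X.n_cols);
  for (int c = 0; c < (int)X.n_cols; ++c) {
    const eT *xp = X.colptr(c);
    eT *yp = Y.colptr(c);
    uword *ip = idx.colptr(c);
    for (int zo = 0; zo < dout.w; ++zo)
      for (int yo = 0; yo < dout.h; ++yo)
        for (int xo = 0; xo < dout.d; ++xo) {
          eT best = -std::numeric_limits<eT>::max();
          uword bi = 0;
          for (int kz = 0; kz < 2; ++kz)
            for (int ky = 0; ky < 2; ++ky)
              for (int kx = 0; kx < 2; ++kx) {
                const uword j = (2 * xo + kx) +
                                (uword)din.d * ((2 * yo + ky) +
                                                (uword)din.h * (2 * zo + kz));
                if (xp[j] > best) {
                  best = xp[j];
                  bi = j;
                }
              }
          const int o = xo + dout.d * (yo + dout.h * zo);
          yp[o] = best;
          ip[o] = bi;
        }
  }
}

template <typename eT>
static void maxpool_backward(const Mat<eT> &dY, const umat &idx,
                             const Dims3 &din, Mat<eT> &dX) {
  dX.zeros(din.n(), dY.n_cols);
  for (int c = 0; c < (int)dY.n_cols; ++c) {
    const eT *gp = dY.colptr(c);
    const uword *ip = idx.colptr(c);
    eT *xp = dX.colptr(c);
    for (uword i = 0; i < dY.n_rows; ++i) xp[ip[i]] += gp[i];
  }
}

static void upsample_parents(const Dims3 &dlow, const Dims3 &dout, uvec &par) {
  par.set_size(dout.n());
  uword i = 0;
  for (int z = 0; z < dout.w; ++z)
    for (int y = 0; y < dout.h; ++y)
      for (int x = 0; x < dout.d; ++x)
        par(i++) = (x / 2) + (uword)dlow.d * ((y / 2) + (uword)dlow.h * (z / 2));
}

template <typename eT>
static void upsample_backward(const Mat<eT> &dY, const uvec &par, int nlow,
                              Mat<eT> &dX) {
  dX.zeros(nlow, dY.n_cols);
  for (int c = 0; c < (int)dY.n_cols; ++c) {
    const eT *gp = dY.colptr(c);
    eT *xp = dX.colptr(c);
    for (uword i = 0; i < dY.n_rows; ++i) xp[par(i)] += gp[i];
  }
}

template <typename eT> struct HDUNetT {
  int L, g, U, inC;
  double dropout;
  Dims3 dims0;
  std::vector<Dims3> dims;           // per level
  std::vector<ConvT<eT>> enc, down, up, dec;
  ConvT<eT> outc;
  std::vector<int> skipC;            // channels of the skip tensor per level
  std::vector<int> levelInC;         // channels entering each level
  std::vector<uvec> uppar;           // upsample parent maps per decoder level
  long long adam_t = 0;

  // per-sample training caches
  bool cached = false;
  std::vector<Mat<eT>> encIn, encA, encDropM; // dense conv blocks (enc)
  std::vector<Mat<eT>> downIn, downA;         // strided conv blocks
  std::vector<umat> poolIdx;
  std::vector<Mat<eT>> upIn, upA;             // channel-reducing up convs
  std::vector<Mat<eT>> decIn, decA, decDropM; // dense conv blocks (dec)
  Mat<eT> outIn, outA;

  HDUNetT(int L_, int g_, int U_, int inC_, Dims3 d0, double drop)
      : L(L_), g(g_), U(U_), inC(inC_), dropout(drop), dims0(d0) {
    dims.resize(L);
    dims[0] = d0;
    for (int l = 1; l < L; ++l) dims[l] = dims[l - 1].half();
    enc.resize(L);
    down.resize(L - 1);
    up.resize(L - 1);
    dec.resize(L - 1);
    skipC.assign(L, 0);
    levelInC.assign(L, 0);
    int c = inC;
    for (int l = 0; l < L; ++l) {
      levelInC[l] = c;
      enc[l].init(c, g);
      c += g;
      skipC[l] = c;
      if (l < L - 1) {
        down[l].init(c, g);
        c += g;
      }
    }
    for (int l = L - 2; l >= 0; --l) {
      up[l].init(c, U);
      c = U + skipC[l];
      dec[l].init(c, g);
      c += g;
    }
    outc.init(c, 1);
    uppar.resize(L - 1);
    for (int l = 0; l < L - 1; ++l)
      upsample_parents(dims[l + 1], dims[l], uppar[l]);
    encIn.resize(L); encA.resize(L); encDropM.resize(L);
    downIn.resize(L - 1); downA.resize(L - 1); poolIdx.resize(L - 1);
    upIn.resize(L - 1); upA.resize(L - 1);
    decIn.resize(L - 1); decA.resize(L - 1); decDropM.resize(L - 1);
  }

  long long nparams() const {
    long long n = outc.nparams();
    for (auto &cv : enc) n += cv.nparams();
    for (auto &cv : down) n += cv.nparams();
    for (auto &cv : up) n += cv.nparams();
    for (auto &cv : dec) n += cv.nparams();
    return n;
  }

  std::vector<ConvT<eT> *> layers() {
    std::vector<ConvT<eT> *> v;
    for (auto &cv : enc) v.push_back(&cv);
    for (auto &cv : down) v.push_back(&cv);
    for (auto &cv : up) v.push_back(&cv);
    for (auto &cv : dec) v.push_back(&cv);
    v.push_back(&outc);
    return v;
  }

  Mat<eT> forward(const Mat<eT> &x, bool train, uint64_t seed) {
    flushDenormals();
    std::mt19937_64 rng(seed);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    const eT keep_scale = (eT)(1.0 / (1.0 - dropout));
    auto dense_block = [&](const Mat<eT> &F, ConvT<eT> &cv, const Dims3 &dd,
                           Mat<eT> &cacheIn, Mat<eT> &cacheA,
                           Mat<eT> &cacheM) -> Mat<eT> {
      Mat<eT> A;
      conv_forward(F, dd, 1, cv, A, dd);
      A.for_each([](eT &v) { if (v < eT(0)) v = eT(0); });
      if (train) {
        cacheIn = F;
        cacheA = A; // pre-dropout activations: >0 gives the ReLU mask
        if (dropout > 0) {
          cacheM.set_size(A.n_rows, A.n_cols);
          for (uword j = 0; j < A.n_elem; ++j)
            cacheM(j) = unif(rng) < dropout ? eT(0) : keep_scale;
          A %= cacheM;
        } else
          cacheM.reset();
      }
      return join_rows(F, A);
    };

    std::vector<Mat<eT>> skip(L);
    Mat<eT> F = x;
    for (int l = 0; l < L; ++l) {
      F = dense_block(F, enc[l], dims[l], encIn[l], encA[l], encDropM[l]);
      skip[l] = F;
      if (l < L - 1) {
        Mat<eT> D;
        conv_forward(F, dims[l], 2, down[l], D, dims[l + 1]);
        D.for_each([](eT &v) { if (v < eT(0)) v = eT(0); });
        Mat<eT> P;
        umat pidx;
        maxpool_forward(F, dims[l], P, pidx);
        if (train) {
          downIn[l] = F;
          downA[l] = D;
          poolIdx[l] = pidx;
        }
        F = join_rows(P, D);
      }
    }
    for (int l = L - 2; l >= 0; --l) {
      Mat<eT> Uf;
      conv_forward(F, dims[l + 1], 1, up[l], Uf, dims[l + 1]);
      Uf.for_each([](eT &v) { if (v < eT(0)) v = eT(0); });
      if (train) {
        upIn[l] = F;
        upA[l] = Uf;
      }
      Mat<eT> Uu = Uf.rows(uppar[l]);
      F = join_rows(Uu, skip[l]);
      F = dense_block(F, dec[l], dims[l], decIn[l], decA[l], decDropM[l]);
    }
    Mat<eT> out;
    conv_forward(F, dims[0], 1, outc, out, dims[0]);
    out.for_each([](eT &v) { if (v < eT(0)) v = eT(0); });
    if (train) {
      outIn = F;
      outA = out;
      cached = true;
    }
    return out;
  }

  // dLdOut: (n0 x 1) gradient of the scalar loss w.r.t. the network output.
  void backward(const Mat<eT> &dLdOut) {
    flushDenormals();
    if (!cached) Rcpp::stop("backward() requires a prior training-mode forward pass");
    auto relu_mask = [](Mat<eT> &G, const Mat<eT> &A) {
      for (uword j = 0; j < G.n_elem; ++j)
        if (A(j) <= eT(0)) G(j) = eT(0);
    };
    Mat<eT> dOut = dLdOut;
    relu_mask(dOut, outA);
    Mat<eT> dF;
    conv_backward(outIn, dims[0], 1, outc, dOut, dims[0], dF, true);

    std::vector<Mat<eT>> dSkip(L);
    for (int l = 0; l <= L - 2; ++l) {
      // invert: F_out = [Fin, A] after dec[l]; Fin = [Uu, skip[l]]
      const int cinl = dec[l].cin;
      Mat<eT> dA = dF.cols(cinl, cinl + g - 1);
      if (decDropM[l].n_elem) dA %= decDropM[l];
      relu_mask(dA, decA[l]);
      Mat<eT> dFin;
      conv_backward(decIn[l], dims[l], 1, dec[l], dA, dims[l], dFin, true);
      dFin += dF.cols(0, cinl - 1);
      Mat<eT> dUu = dFin.cols(0, U - 1);
      dSkip[l] = dFin.cols(U, U + skipC[l] - 1);
      Mat<eT> dUf;
      upsample_backward(dUu, uppar[l], dims[l + 1].n(), dUf);
      relu_mask(dUf, upA[l]);
      conv_backward(upIn[l], dims[l + 1], 1, up[l], dUf, dims[l + 1], dF, true);
    }
    // dF now holds the gradient at the bottom level's post-enc tensor? No:
    // after the loop above, dF is the gradient w.r.t. the input of up[L-2],
    // which is the tensor at level L-1 after enc[L-1].
    for (int l = L - 1; l >= 0; --l) {
      if (l < L - 1) {
        // dF is gradient w.r.t. [maxpool(skipF_l), D] at level l+1 entry
        const int cs = skipC[l];
        Mat<eT> dP = dF.cols(0, cs - 1);
        Mat<eT> dD = dF.cols(cs, cs + g - 1);
        relu_mask(dD, downA[l]);
        Mat<eT> dFs1;
        conv_backward(downIn[l], dims[l], 2, down[l], dD, dims[l + 1], dFs1,
                      true);
        Mat<eT> dFs2;
        maxpool_backward(dP, poolIdx[l], dims[l], dFs2);
        dF = dFs1 + dFs2 + dSkip[l];
      } // at the bottom level dF is already the gradient w.r.t. skip[L-1]
      // back through enc[l]: F_out = [Fin, A]
      const int cinl = enc[l].cin;
      Mat<eT> dA = dF.cols(cinl, cinl + g - 1);
      if (encDropM[l].n_elem) dA %= encDropM[l];
      relu_mask(dA, encA[l]);
      Mat<eT> dFin;
      const bool want = (l > 0); // input gradient not needed at the very top
      conv_backward(encIn[l], dims[l], 1, enc[l], dA, dims[l], dFin, want);
      if (want) {
        dFin += dF.cols(0, cinl - 1);
        dF = dFin;
      }
    }
  }

  void zero_grad() {
    for (auto *cv : layers()) {
      cv->dW.zeros();
      cv->db.zeros();
    }
  }

  void adam_step(double lr, double scale, double b1, double b2, double eps) {
    ++adam_t;
    const double c1 = 1.0 - std::pow(b1, (double)adam_t);
    const double c2 = 1.0 - std::pow(b2, (double)adam_t);
    for (auto *cv : layers()) {
      Mat<eT> gW = cv->dW * (eT)scale;
      Row<eT> gb = cv->db * (eT)scale;
      cv->mW = (eT)b1 * cv->mW + (eT)(1 - b1) * gW;
      cv->vW = (eT)b2 * cv->vW + (eT)(1 - b2) * (gW % gW);
      cv->mb = (eT)b1 * cv->mb + (eT)(1 - b1) * gb;
      cv->vb = (eT)b2 * cv->vb + (eT)(1 - b2) * (gb % gb);
      cv->W -= (eT)lr * (cv->mW / (eT)c1) / (sqrt(cv->vW / (eT)c2) + (eT)eps);
      cv->b -= (eT)lr * (cv->mb / (eT)c1) / (sqrt(cv->vb / (eT)c2) + (eT)eps);
    }
  }
};

// Type-erasing wrapper so R holds one external pointer type for either
// precision.
struct NetHandle {
  std::unique_ptr<HDUNetT<float>> f;
  std::unique_ptr<HDUNetT<double>> d;
  bool is_double() const { return (bool)d; }
};

using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::XPtr;

// [[Rcpp::export]]
SEXP cppNetCreate(int n_levels, int growth, int upsample, int in_channels,
                  Rcpp::IntegerVector dims, double dropout,
                  std::string precision) {
  if (dims.size() != 3) Rcpp::stop("dims must have length 3");
  Dims3 d0{dims[0], dims[1], dims[2]};
  int div = 1 << (n_levels - 1);
  if (d0.d % div || d0.h % div || d0.w % div)
    Rcpp::stop("input edge not divisible by 2^(n_levels-1)");
  if (n_levels < 2) Rcpp::stop("n_levels must be >= 2");
  auto *h = new NetHandle();
  if (precision == "double")
    h->d.reset(new HDUNetT<double>(n_levels, growth, upsample, in_channels,
                                   d0, dropout));
  else
    h->f.reset(new HDUNetT<float>(n_levels, growth, upsample, in_channels, d0,
                                  dropout));
  XPtr<NetHandle> p(h, true);
  return p;
}

template <typename eT> static List layer_list(HDUNetT<eT> &net) {
  std::vector<std::string> names;
  for (int l = 0; l < net.L; ++l) names.push_back("enc" + std::to_string(l));
  for (int l = 0; l < net.L - 1; ++l) names.push_back("down" + std::to_string(l));
  for (int l = 0; l < net.L - 1; ++l) names.push_back("up" + std::to_string(l));
  for (int l = 0; l < net.L - 1; ++l) names.push_back("dec" + std::to_string(l));
  names.push_back("out");
  auto ls = net.layers();
  // reorder: layers() gives enc..., down..., up..., dec..., out (same order)
  List out(names.size());
  for (size_t i = 0; i < ls.size(); ++i) {
    NumericMatrix W(ls[i]->W.n_rows, ls[i]->W.n_cols);
    for (uword j = 0; j < ls[i]->W.n_elem; ++j) W[j] = ls[i]->W(j);
    NumericVector b(ls[i]->b.n_elem);
    for (uword j = 0; j < ls[i]->b.n_elem; ++j) b[j] = ls[i]->b(j);
    out[i] = List::create(Rcpp::Named("W") = W, Rcpp::Named("b") = b);
  }
  out.attr("names") = Rcpp::wrap(names);
  return out;
}

// [[Rcpp::export]]
List cppNetGetWeights(SEXP ptr) {
  XPtr<NetHandle> p(ptr);
  return p->is_double() ? layer_list(*p->d) : layer_list(*p->f);
}

template <typename eT> static void set_layers(HDUNetT<eT> &net, List wl) {
  auto ls = net.layers();
  if ((size_t)wl.size() != ls.size()) Rcpp::stop("weight list length mismatch");
  for (size_t i = 0; i < ls.size(); ++i) {
    List li = wl[i];
    NumericMatrix W = li["W"];
    NumericVector b = li["b"];
    if ((uword)W.nrow() != ls[i]->W.n_rows ||
        (uword)W.ncol() != ls[i]->W.n_cols)
      Rcpp::stop("weight matrix %d has wrong shape", (int)i + 1);
    for (uword j = 0; j < ls[i]->W.n_elem; ++j) ls[i]->W(j) = (eT)W[j];
    for (uword j = 0; j < ls[i]->b.n_elem; ++j) ls[i]->b(j) = (eT)b[j];
  }
}

// [[Rcpp::export]]
void cppNetSetWeights(SEXP ptr, List weights) {
  XPtr<NetHandle> p(ptr);
  if (p->is_double())
    set_layers(*p->d, weights);
  else
    set_layers(*p->f, weights);
}

// [[Rcpp::export]]
double cppNetNParams(SEXP ptr) {
  XPtr<NetHandle> p(ptr);
  return (double)(p->is_double() ? p->d->nparams() : p->f->nparams());
}

// [[Rcpp::export]]
Rcpp::DataFrame cppNetLayerInfo(SEXP ptr) {
  XPtr<NetHandle> p(ptr);
  std::vector<std::string> names;
  std::vector<int> cin, cout;
  auto fill = [&](auto &net) {
    List dummy; // reuse naming logic inline
    for (int l = 0; l < net.L; ++l) names.push_back("enc" + std::to_string(l));
    for (int l = 0; l < net.L - 1; ++l) names.push_back("down" + std::to_string(l));
    for (int l = 0; l < net.L - 1; ++l) names.push_back("up" + std::to_string(l));
    for (int l = 0; l < net.L - 1; ++l) names.push_back("dec" + std::to_string(l));
    names.push_back("out");
    for (auto *cv : net.layers()) {
      cin.push_back(cv->cin);
      cout.push_back(cv->cout);
    }
  };
  if (p->is_double()) fill(*p->d); else fill(*p->f);
  return Rcpp::DataFrame::create(Rcpp::Named("layer") = names,
                                 Rcpp::Named("cin") = cin,
                                 Rcpp::Named("cout") = cout);
}

template <typename eT>
static NumericVector run_forward(HDUNetT<eT> &net, NumericVector x, bool train,
                                 double seed) {
  const int n = net.dims0.n();
  if ((int)x.size() != n * net.inC) Rcpp::stop("input length mismatch");
  Mat<eT> X(n, net.inC);
  for (int j = 0; j < n * net.inC; ++j) X(j) = (eT)x[j];
  Mat<eT> Y = net.forward(X, train, (uint64_t)seed);
  NumericVector out(n);
  for (int j = 0; j < n; ++j) out[j] = (double)Y(j, 0);
  out.attr("dim") =
      Rcpp::IntegerVector::create(net.dims0.d, net.dims0.h, net.dims0.w);
  return out;
}

// [[Rcpp::export]]
NumericVector cppNetForward(SEXP ptr, NumericVector x, bool train,
                            double seed) {
  XPtr<NetHandle> p(ptr);
  return p->is_double() ? run_forward(*p->d, x, train, seed)
                        : run_forward(*p->f, x, train, seed);
}

// [[Rcpp::export]]
void cppNetBackward(SEXP ptr, NumericVector grad_out) {
  XPtr<NetHandle> p(ptr);
  if (p->is_double()) {
    Mat<double> G(p->d->dims0.n(), 1);
    for (uword j = 0; j < G.n_elem; ++j) G(j) = grad_out[j];
    p->d->backward(G);
  } else {
    Mat<float> G(p->f->dims0.n(), 1);
    for (uword j = 0; j < G.n_elem; ++j) G(j) = (float)grad_out[j];
    p->f->backward(G);
  }
}

// [[Rcpp::export]]
void cppNetZeroGrad(SEXP ptr) {
  XPtr<NetHandle> p(ptr);
  if (p->is_double()) p->d->zero_grad(); else p->f->zero_grad();
}

// [[Rcpp::export]]
void cppNetAdamStep(SEXP ptr, double lr, double scale, double beta1,
                    double beta2, double eps) {
  XPtr<NetHandle> p(ptr);
  if (p->is_double())
    p->d->adam_step(lr, scale, beta1, beta2, eps);
  else
    p->f->adam_step(lr, scale, beta1, beta2, eps);
}

template <typename eT> static List grad_list(HDUNetT<eT> &net) {
  auto ls = net.layers();
  List out(ls.size());
  for (size_t i = 0; i < ls.size(); ++i) {
    NumericMatrix W(ls[i]->dW.n_rows, ls[i]->dW.n_cols);
    for (uword j = 0; j < ls[i]->dW.n_elem; ++j) W[j] = ls[i]->dW(j);
    NumericVector b(ls[i]->db.n_elem);
    for (uword j = 0; j < ls[i]->db.n_elem; ++j) b[j] = ls[i]->db(j);
    out[i] = List::create(Rcpp::Named("W") = W, Rcpp::Named("b") = b);
  }
  return out;
}

// [[Rcpp::export]]
List cppNetGrads(SEXP ptr) {
  XPtr<NetHandle> p(ptr);
  return p->is_double() ? grad_list(*p->d) : grad_list(*p->f);
}
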