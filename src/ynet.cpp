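// Y-Net forward/backward engine.
//
// Feature maps for a batch are stacked row-wise: sample b occupies rows
// [b*H*W, (b+1)*H*W) of an (B*H*W) x C matrix, with pixel index y + x*H
// (column-major, matching R). 3x3 convolutions are im2col + sgemm; 2x2/2
// transposed convolutions are four sgemms with strided pointer scatter;
// pooling is 2x2 max with cached argmax rows. Arithmetic is single
// precision (the usual choice for convolutional training); parameters and
// losses cross the R boundary in double.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;

// 1/0 mask of strictly-positive entries (ReLU derivative)
static fmat gtz(const fmat& A) {
  fmat m(A.n_rows, A.n_cols);
  for (uword i = 0; i < A.n_elem; ++i) m(i) = A(i) > 0 ? 1.0f : 0.0f;
  return m;
}

static fmat getP(const List& p, const std::string& nm) {
  return conv_to<fmat>::from(Rcpp::as<mat>(p[nm]));
}
static frowvec getB(const List& p, const std::string& nm) {
  return conv_to<frowvec>::from(Rcpp::as<rowvec>(p[nm]));
}

// ---- primitive ops ---------------------------------------------------------

static void im2col3(const fmat& X, int H, int W, int B, fmat& out) {
  const int C = X.n_cols;
  out.zeros((size_t)B * H * W, 9 * C);
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      const int k = (dx + 1) * 3 + (dy + 1);
      const int y0 = std::max(0, -dy), y1 = H - 1 - std::max(0, dy);
      const int x0 = std::max(0, -dx), x1 = W - 1 - std::max(0, dx);
      if (y1 < y0 || x1 < x0) continue;
      const int len = y1 - y0 + 1;
      for (int c = 0; c < C; ++c) {
        const float* src = X.colptr(c);
        float* dst = out.colptr((size_t)k * C + c);
        for (int b = 0; b < B; ++b) {
          const size_t base = (size_t)b * H * W;
          for (int x = x0; x <= x1; ++x) {
            std::memcpy(dst + base + y0 + (size_t)x * H,
                        src + base + (y0 + dy) + (size_t)(x + dx) * H,
                        sizeof(float) * len);
          }
        }
      }
    }
  }
}

static fmat col2im3(const fmat& G, int H, int W, int B, int C) {
  fmat out((size_t)B * H * W, C, fill::zeros);
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      const int k = (dx + 1) * 3 + (dy + 1);
      const int y0 = std::max(0, -dy), y1 = H - 1 - std::max(0, dy);
      const int x0 = std::max(0, -dx), x1 = W - 1 - std::max(0, dx);
      if (y1 < y0 || x1 < x0) continue;
      const int len = y1 - y0 + 1;
      for (int c = 0; c < C; ++c) {
        const float* src = G.colptr((size_t)k * C + c);
        float* dst = out.colptr(c);
        for (int b = 0; b < B; ++b) {
          const size_t base = (size_t)b * H * W;
          for (int x = x0; x <= x1; ++x) {
            float* d = dst + base + (y0 + dy) + (size_t)(x + dx) * H;
            const float* s = src + base + y0 + (size_t)x * H;
            for (int i = 0; i < len; ++i) d[i] += s[i];
          }
        }
      }
    }
  }
  return out;
}

static void maxpool2(const fmat& X, int H, int W, int B, fmat& Y, umat& idx) {
  const int C = X.n_cols, h = H / 2, w = W / 2;
  Y.set_size((size_t)B * h * w, C);
  idx.set_size((size_t)B * h * w, C);
  for (int c = 0; c < C; ++c) {
    const float* xc = X.colptr(c);
    float* yc = Y.colptr(c);
    uword* ic = idx.colptr(c);
    for (int b = 0; b < B; ++b) {
      const size_t bi = (size_t)b * H * W, bo = (size_t)b * h * w;
      for (int x = 0; x < w; ++x) {
        for (int y = 0; y < h; ++y) {
          const size_t r0 = bi + 2 * y + (size_t)(2 * x) * H;
          const size_t r1 = bi + 2 * y + (size_t)(2 * x + 1) * H;
          size_t best = r0;
          if (xc[r0 + 1] > xc[best]) best = r0 + 1;
          if (xc[r1] > xc[best]) best = r1;
          if (xc[r1 + 1] > xc[best]) best = r1 + 1;
          const size_t ro = bo + y + (size_t)x * h;
          yc[ro] = xc[best];
          ic[ro] = best;
        }
      }
    }
  }
}

static fmat maxpool2_back(const fmat& dY, const umat& idx, size_t nrows_in) {
  fmat dX(nrows_in, dY.n_cols, fill::zeros);
  for (uword c = 0; c < dY.n_cols; ++c) {
    float* dc = dX.colptr(c);
    const float* gc = dY.colptr(c);
    const uword* ic = idx.colptr(c);
    for (uword r = 0; r < dY.n_rows; ++r) dc[ic[r]] += gc[r];
  }
  return dX;
}

// transposed conv 2x2 stride 2; Wt is Cin x (4*Cout), block k = di + 2*dj
static fmat upconv2(const fmat& X, const fmat& Wt, const frowvec& bias,
                    int h, int w, int B) {
  const int Cout = Wt.n_cols / 4, H = 2 * h;
  fmat Y((size_t)B * H * 2 * w, Cout, fill::zeros);
  for (int k = 0; k < 4; ++k) {
    const int di = k % 2, dj = k / 2;
    fmat Yk = X * Wt.cols((size_t)k * Cout, (size_t)(k + 1) * Cout - 1);
    for (int c = 0; c < Cout; ++c) {
      const float* src = Yk.colptr(c);
      float* dst = Y.colptr(c);
      for (int b = 0; b < B; ++b) {
        const size_t bi = (size_t)b * h * w, bo = (size_t)b * H * 2 * w;
        for (int x = 0; x < w; ++x) {
          const float* s = src + bi + (size_t)x * h;
          float* d = dst + bo + di + (size_t)(2 * x + dj) * H;
          for (int y = 0; y < h; ++y) d[2 * y] += s[y];
        }
      }
    }
  }
  Y.each_row() += bias;
  return Y;
}

static void upconv2_back(const fmat& X, const fmat& Wt, const fmat& dY,
                         int h, int w, int B,
                         fmat& dX, fmat& dWt, frowvec& db) {
  const int Cout = Wt.n_cols / 4, H = 2 * h;
  dX.zeros(X.n_rows, X.n_cols);
  dWt.set_size(Wt.n_rows, Wt.n_cols);
  db = conv_to<frowvec>::from(sum(dY, 0));
  fmat dYk(X.n_rows, Cout);
  for (int k = 0; k < 4; ++k) {
    const int di = k % 2, dj = k / 2;
    for (int c = 0; c < Cout; ++c) {
      float* dst = dYk.colptr(c);
      const float* src = dY.colptr(c);
      for (int b = 0; b < B; ++b) {
        const size_t bi = (size_t)b * h * w, bo = (size_t)b * H * 2 * w;
        for (int x = 0; x < w; ++x) {
          float* d = dst + bi + (size_t)x * h;
          const float* s = src + bo + di + (size_t)(2 * x + dj) * H;
          for (int y = 0; y < h; ++y) d[y] = s[2 * y];
        }
      }
    }
    dX += dYk * Wt.cols((size_t)k * Cout, (size_t)(k + 1) * Cout - 1).t();
    dWt.cols((size_t)k * Cout, (size_t)(k + 1) * Cout - 1) = X.t() * dYk;
  }
}

static inline void relu_(fmat& A) {
  for (uword i = 0; i < A.n_elem; ++i) if (A(i) < 0) A(i) = 0;
}

// ---- network ---------------------------------------------------------------

struct Cache {
  std::vector<fmat> enc_a1, enc_a2, enc_im1, enc_im2, pooled;
  std::vector<umat> pidx;
  std::vector<int> Hs, Ws;               // resolution at each encoder stage
  fmat bot_in_im1, bot_a1, bot_im2, bot_a2;
  int Hb, Wb;
  fmat reg_im, reg_a, gap, vars;
  std::vector<fmat> up_in, up_out, cat_a, dec_a1, dec_im1, dec_im2, dec_a2;
  fmat out_in, out3;
};

static void forward_pass(const List& par, const fcube& x, int D, Cache& C) {
  const int H = x.n_rows, W = x.n_cols, B = x.n_slices;
  if (H % (1 << D) || W % (1 << D)) {
    Rcpp::stop("image height and width must be divisible by 2^depth = %d",
               1 << D);
  }
  C.enc_a1.resize(D); C.enc_a2.resize(D); C.enc_im1.resize(D);
  C.enc_im2.resize(D); C.pooled.resize(D); C.pidx.resize(D);
  C.Hs.resize(D); C.Ws.resize(D);
  C.up_in.resize(D + 1); C.up_out.resize(D + 1); C.cat_a.resize(D + 1);
  C.dec_a1.resize(D + 1); C.dec_im1.resize(D + 1); C.dec_im2.resize(D + 1);
  C.dec_a2.resize(D + 1);

  fmat a(const_cast<float*>(x.memptr()), (size_t)H * W * B, 1);
  int h = H, w = W;
  for (int s = 1; s <= D; ++s) {
    C.Hs[s - 1] = h; C.Ws[s - 1] = w;
    const std::string pre = "enc" + std::to_string(s);
    im2col3(a, h, w, B, C.enc_im1[s - 1]);
    fmat a1 = C.enc_im1[s - 1] * getP(par, pre + "_c1_W");
    a1.each_row() += getB(par, pre + "_c1_b");
    relu_(a1);
    C.enc_a1[s - 1] = std::move(a1);
    im2col3(C.enc_a1[s - 1], h, w, B, C.enc_im2[s - 1]);
    fmat a2 = C.enc_im2[s - 1] * getP(par, pre + "_c2_W");
    a2.each_row() += getB(par, pre + "_c2_b");
    relu_(a2);
    C.enc_a2[s - 1] = std::move(a2);
    maxpool2(C.enc_a2[s - 1], h, w, B, C.pooled[s - 1], C.pidx[s - 1]);
    h /= 2; w /= 2;
    a = C.pooled[s - 1];
  }
  C.Hb = h; C.Wb = w;
  im2col3(a, h, w, B, C.bot_in_im1);
  fmat b1 = C.bot_in_im1 * getP(par, "bot_c1_W");
  b1.each_row() += getB(par, "bot_c1_b");
  relu_(b1);
  C.bot_a1 = std::move(b1);
  im2col3(C.bot_a1, h, w, B, C.bot_im2);
  fmat b2 = C.bot_im2 * getP(par, "bot_c2_W");
  b2.each_row() += getB(par, "bot_c2_b");
  relu_(b2);
  C.bot_a2 = std::move(b2);

  // regression head: conv3 + relu + global average pool + affine
  im2col3(C.bot_a2, h, w, B, C.reg_im);
  fmat ra = C.reg_im * getP(par, "reg_c_W");
  ra.each_row() += getB(par, "reg_c_b");
  relu_(ra);
  C.reg_a = std::move(ra);
  const size_t hw = (size_t)h * w;
  C.gap.set_size(B, C.reg_a.n_cols);
  for (int bb = 0; bb < B; ++bb) {
    C.gap.row(bb) = mean(C.reg_a.rows((size_t)bb * hw, (size_t)(bb + 1) * hw - 1), 0);
  }
  C.vars = C.gap * getP(par, "reg_f_W");
  C.vars.each_row() += getB(par, "reg_f_b");

  // expansive path
  fmat cur = C.bot_a2;
  for (int s = D; s >= 1; --s) {
    const std::string pre = "dec" + std::to_string(s);
    const std::string upn = "up" + std::to_string(s);
    C.up_in[s] = cur;
    C.up_out[s] = upconv2(cur, getP(par, upn + "_W"), getB(par, upn + "_b"),
                          h, w, B);
    h *= 2; w *= 2;
    C.cat_a[s] = join_rows(C.enc_a2[s - 1], C.up_out[s]);
    im2col3(C.cat_a[s], h, w, B, C.dec_im1[s]);
    fmat d1 = C.dec_im1[s] * getP(par, pre + "_c1_W");
    d1.each_row() += getB(par, pre + "_c1_b");
    relu_(d1);
    C.dec_a1[s] = std::move(d1);
    im2col3(C.dec_a1[s], h, w, B, C.dec_im2[s]);
    fmat d2 = C.dec_im2[s] * getP(par, pre + "_c2_W");
    d2.each_row() += getB(par, pre + "_c2_b");
    relu_(d2);
    C.dec_a2[s] = std::move(d2);
    cur = C.dec_a2[s];
  }
  C.out_in = cur;
  C.out3 = cur * getP(par, "out_W");
  C.out3.each_row() += getB(par, "out_b");
}

static cube fcol_to_cube(const fvec& v, int H, int W, int B) {
  cube out(H, W, B);
  for (uword i = 0; i < v.n_elem; ++i) out(i) = v(i);
  return out;
}

// [[Rcpp::export]]
List cpp_ynet_forward(List par, arma::cube x, int depth) {
  Cache C;
  const fcube xf = conv_to<fcube>::from(x);
  forward_pass(par, xf, depth, C);
  const int H = x.n_rows, W = x.n_cols, B = x.n_slices;
  return List::create(
    Rcpp::Named("logit") = fcol_to_cube(C.out3.col(0), H, W, B),
    Rcpp::Named("amp") = fcol_to_cube(C.out3.col(1), H, W, B),
    Rcpp::Named("phase") = fcol_to_cube(C.out3.col(2), H, W, B),
    Rcpp::Named("vars") = conv_to<mat>::from(C.vars)
  );
}

static inline double stable_sigmoid(double t) {
  if (t >= 0) return 1.0 / (1.0 + std::exp(-t));
  const double e = std::exp(t);
  return e / (1.0 + e);
}
static inline double softplus(double t) {
  return std::max(t, 0.0) + std::log1p(std::exp(-std::fabs(t)));
}

// [[Rcpp::export]]
List cpp_ynet_loss(List par, arma::cube x,
                   arma::cube tprob, arma::cube tamp, arma::cube tphase,
                   arma::mat tvars, arma::vec alpha, double omega,
                   bool want_grad) {
  const int D = Rcpp::as<int>(par.attr("depth"));
  const int H = x.n_rows, W = x.n_cols, B = x.n_slices;
  if ((int)tprob.n_rows != H || (int)tprob.n_cols != W ||
      (int)tprob.n_slices != B || (int)tvars.n_rows != B) {
    Rcpp::stop("target dimensions do not match the input batch");
  }
  Cache C;
  const fcube xf = conv_to<fcube>::from(x);
  forward_pass(par, xf, D, C);

  const vec yp(const_cast<double*>(tprob.memptr()), (size_t)H * W * B, false);
  const vec ya(const_cast<double*>(tamp.memptr()), (size_t)H * W * B, false);
  const vec yf(const_cast<double*>(tphase.memptr()), (size_t)H * W * B, false);
  const vec lg = conv_to<vec>::from(C.out3.col(0));
  const vec am = conv_to<vec>::from(C.out3.col(1));
  const vec ph = conv_to<vec>::from(C.out3.col(2));
  const mat varsd = conv_to<mat>::from(C.vars);

  const double npix = (double)H * W * B;
  double L2 = 0;
  for (size_t i = 0; i < lg.n_elem; ++i) {
    L2 += omega * yp(i) * softplus(-lg(i)) + (1.0 - yp(i)) * softplus(lg(i));
  }
  L2 /= npix;
  const double L3 = accu(yp % square(am - ya)) / B;
  const double L4 = accu(yp % square(ph - yf)) / B;
  const mat dv = varsd - tvars;
  const double L1 = accu(square(dv)) / (double)dv.n_elem;
  const double total = alpha(0) * L1 + alpha(1) * L2 + alpha(2) * L3 +
                       alpha(3) * L4;

  List out = List::create(
    Rcpp::Named("L1") = L1, Rcpp::Named("L2") = L2,
    Rcpp::Named("L3") = L3, Rcpp::Named("L4") = L4,
    Rcpp::Named("total") = total
  );
  if (!want_grad) return out;

  // head gradients
  fmat dOut3(C.out3.n_rows, 3);
  for (size_t i = 0; i < lg.n_elem; ++i) {
    const double s = stable_sigmoid(lg(i));
    dOut3(i, 0) = (float)(alpha(1) / npix *
      (omega * yp(i) * (s - 1.0) + (1.0 - yp(i)) * s));
    dOut3(i, 1) = (float)(alpha(2) * (2.0 / B) * (yp(i) * (am(i) - ya(i))));
    dOut3(i, 2) = (float)(alpha(3) * (2.0 / B) * (yp(i) * (ph(i) - yf(i))));
  }
  fmat dVars = conv_to<fmat>::from(alpha(0) * (2.0 / dv.n_elem) * dv);

  List g;
  // output 1x1 conv
  g["out_W"] = conv_to<mat>::from(C.out_in.t() * dOut3);
  g["out_b"] = conv_to<rowvec>::from(sum(dOut3, 0));
  fmat dcur = dOut3 * getP(par, "out_W").t();

  // decoder, shallow to deep
  int h = H, w = W;
  std::vector<fmat> dSkip(D + 1);
  for (int s = 1; s <= D; ++s) {
    const std::string pre = "dec" + std::to_string(s);
    const std::string upn = "up" + std::to_string(s);
    fmat dPre2 = dcur % gtz(C.dec_a2[s]);
    g[pre + "_c2_W"] = conv_to<mat>::from(C.dec_im2[s].t() * dPre2);
    g[pre + "_c2_b"] = conv_to<rowvec>::from(sum(dPre2, 0));
    fmat dA1 = col2im3(dPre2 * getP(par, pre + "_c2_W").t(), h, w, B,
                       C.dec_a1[s].n_cols);
    fmat dPre1 = dA1 % gtz(C.dec_a1[s]);
    g[pre + "_c1_W"] = conv_to<mat>::from(C.dec_im1[s].t() * dPre1);
    g[pre + "_c1_b"] = conv_to<rowvec>::from(sum(dPre1, 0));
    fmat dCat = col2im3(dPre1 * getP(par, pre + "_c1_W").t(), h, w, B,
                        C.cat_a[s].n_cols);
    const int cs = C.enc_a2[s - 1].n_cols;
    dSkip[s] = dCat.cols(0, cs - 1);
    fmat dUp = dCat.cols(cs, dCat.n_cols - 1);
    h /= 2; w /= 2;
    fmat dX, dWt; frowvec db;
    upconv2_back(C.up_in[s], getP(par, upn + "_W"), dUp, h, w, B, dX, dWt, db);
    g[upn + "_W"] = conv_to<mat>::from(dWt);
    g[upn + "_b"] = conv_to<rowvec>::from(db);
    dcur = dX;
  }
  const fmat dBotFromUp = dcur;

  // regression head backward
  g["reg_f_W"] = conv_to<mat>::from(C.gap.t() * dVars);
  g["reg_f_b"] = conv_to<rowvec>::from(sum(dVars, 0));
  fmat dGap = dVars * getP(par, "reg_f_W").t();
  const size_t hwb = (size_t)C.Hb * C.Wb;
  fmat dRegA(C.reg_a.n_rows, C.reg_a.n_cols);
  for (int bb = 0; bb < B; ++bb) {
    dRegA.rows((size_t)bb * hwb, (size_t)(bb + 1) * hwb - 1) =
      repmat(dGap.row(bb) / (float)hwb, hwb, 1);
  }
  fmat dRegPre = dRegA % gtz(C.reg_a);
  g["reg_c_W"] = conv_to<mat>::from(C.reg_im.t() * dRegPre);
  g["reg_c_b"] = conv_to<rowvec>::from(sum(dRegPre, 0));
  fmat dBot = dBotFromUp +
    col2im3(dRegPre * getP(par, "reg_c_W").t(), C.Hb, C.Wb, B,
            C.bot_a2.n_cols);

  // bottleneck backward
  fmat dPreB2 = dBot % gtz(C.bot_a2);
  g["bot_c2_W"] = conv_to<mat>::from(C.bot_im2.t() * dPreB2);
  g["bot_c2_b"] = conv_to<rowvec>::from(sum(dPreB2, 0));
  fmat dB1 = col2im3(dPreB2 * getP(par, "bot_c2_W").t(), C.Hb, C.Wb, B,
                     C.bot_a1.n_cols);
  fmat dPreB1 = dB1 % gtz(C.bot_a1);
  g["bot_c1_W"] = conv_to<mat>::from(C.bot_in_im1.t() * dPreB1);
  g["bot_c1_b"] = conv_to<rowvec>::from(sum(dPreB1, 0));
  fmat dPooled = col2im3(dPreB1 * getP(par, "bot_c1_W").t(), C.Hb, C.Wb, B,
                         C.pooled[D - 1].n_cols);

  // encoder backward, deep to shallow
  for (int s = D; s >= 1; --s) {
    const std::string pre = "enc" + std::to_string(s);
    const int hs = C.Hs[s - 1], ws = C.Ws[s - 1];
    fmat dA2 = maxpool2_back(dPooled, C.pidx[s - 1], C.enc_a2[s - 1].n_rows) +
               dSkip[s];
    fmat dPre2 = dA2 % gtz(C.enc_a2[s - 1]);
    g[pre + "_c2_W"] = conv_to<mat>::from(C.enc_im2[s - 1].t() * dPre2);
    g[pre + "_c2_b"] = conv_to<rowvec>::from(sum(dPre2, 0));
    fmat dA1 = col2im3(dPre2 * getP(par, pre + "_c2_W").t(), hs, ws, B,
                       C.enc_a1[s - 1].n_cols);
    fmat dPre1 = dA1 % gtz(C.enc_a1[s - 1]);
    g[pre + "_c1_W"] = conv_to<mat>::from(C.enc_im1[s - 1].t() * dPre1);
    g[pre + "_c1_b"] = conv_to<rowvec>::from(sum(dPre1, 0));
    if (s > 1) {
      dPooled = col2im3(dPre1 * getP(par, pre + "_c1_W").t(), hs, ws, B,
                        C.pooled[s - 2].n_cols);
    }
  }

  out["grads"] = g;
  return out;
}
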