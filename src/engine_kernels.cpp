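// Hot loops of the network engine: the LSTM cell recursion (forward and
// backward-through-time) and the temporal-convolution im2col/col2im
// transforms. Matrix products use Armadillo (same BLAS R links against);
// array layouts match R's column-major conventions: a B x T x U array
// stores element (b, t, u) at b + B*t + B*T*u.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat slice_bt(const double* x, int B, int T, int U, int t) {
  // strided read of a B x U matrix at time t from a B x T x U array
  mat out(B, U);
  for (int u = 0; u < U; ++u)
    std::memcpy(out.colptr(u), x + (size_t)B * t + (size_t)B * T * u,
                sizeof(double) * B);
  return out;
}

static inline void store_bt(double* x, int B, int T, int U, int t,
                            const mat& m) {
  for (int u = 0; u < U; ++u)
    std::memcpy(x + (size_t)B * t + (size_t)B * T * u, m.colptr(u),
                sizeof(double) * B);
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_fw(const arma::mat& Zin, const arma::mat& Wh,
                       int B, int T, bool return_sequences) {
  const int U = Wh.n_rows;
  Rcpp::NumericVector Hs(Rcpp::Dimension(B, T, U)),
      Cs(Rcpp::Dimension(B, T, U)), Ig(Rcpp::Dimension(B, T, U)),
      Fg(Rcpp::Dimension(B, T, U)), Gg(Rcpp::Dimension(B, T, U)),
      Og(Rcpp::Dimension(B, T, U));
  mat h(B, U, fill::zeros);
  std::vector<double> c((size_t)B * U, 0.0);
  mat z(B, 4 * U);
  for (int t = 0; t < T; ++t) {
    z = h * Wh;                                   // gemm, reused buffer
    z += Zin.rows((size_t)t * B, (size_t)t * B + B - 1);
    for (int u = 0; u < U; ++u) {
      const double* zi = z.colptr(u);
      const double* zf = z.colptr(U + u);
      const double* zg = z.colptr(2 * U + u);
      const double* zo = z.colptr(3 * U + u);
      double* cp = c.data() + (size_t)B * u;
      double* hp = h.colptr(u);
      const size_t off = (size_t)B * t + (size_t)B * T * u;
      double* hs = Hs.begin() + off; double* cs = Cs.begin() + off;
      double* igp = Ig.begin() + off; double* fgp = Fg.begin() + off;
      double* ggp = Gg.begin() + off; double* ogp = Og.begin() + off;
      for (int b = 0; b < B; ++b) {
        const double ig = 1.0 / (1.0 + std::exp(-zi[b]));
        const double fg = 1.0 / (1.0 + std::exp(-zf[b]));
        const double gg = std::tanh(zg[b]);
        const double og = 1.0 / (1.0 + std::exp(-zo[b]));
        const double cc = fg * cp[b] + ig * gg;
        const double hh = og * std::tanh(cc);
        cp[b] = cc; hp[b] = hh;
        hs[b] = hh; cs[b] = cc;
        igp[b] = ig; fgp[b] = fg; ggp[b] = gg; ogp[b] = og;
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("h_last") = h, Rcpp::Named("Hs") = Hs,
      Rcpp::Named("Cs") = Cs, Rcpp::Named("Ig") = Ig,
      Rcpp::Named("Fg") = Fg, Rcpp::Named("Gg") = Gg,
      Rcpp::Named("Og") = Og);
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_bw(const arma::mat& Wh,
                       const Rcpp::NumericVector& Hs,
                       const Rcpp::NumericVector& Cs,
                       const Rcpp::NumericVector& Ig,
                       const Rcpp::NumericVector& Fg,
                       const Rcpp::NumericVector& Gg,
                       const Rcpp::NumericVector& Og,
                       Rcpp::Nullable<Rcpp::NumericVector> dH_,
                       Rcpp::Nullable<Rcpp::NumericMatrix> dh_last_,
                       int B, int T) {
  const int U = Wh.n_rows;
  const bool has_dH = dH_.isNotNull();
  const double* dHp = nullptr;
  Rcpp::NumericVector dH_keep;
  if (has_dH) { dH_keep = dH_.get(); dHp = dH_keep.begin(); }
  mat dh_last(B, U, fill::zeros);
  if (dh_last_.isNotNull()) dh_last = Rcpp::as<mat>(dh_last_.get());

  const mat WhT = Wh.t();
  mat dh_rec(B, U, fill::zeros);
  std::vector<double> dc_next((size_t)B * U, 0.0);
  mat dWh(U, 4 * U, fill::zeros);
  vec db(4 * U, fill::zeros);
  mat DZ((size_t)B * T, 4 * U);
  mat dz(B, 4 * U), h_prev(B, U);
  for (int t = T - 1; t >= 0; --t) {
    for (int u = 0; u < U; ++u) {
      const size_t off = (size_t)B * t + (size_t)B * T * u;
      const double* cs = Cs.begin() + off;
      const double* igp = Ig.begin() + off;
      const double* fgp = Fg.begin() + off;
      const double* ggp = Gg.begin() + off;
      const double* ogp = Og.begin() + off;
      const double* cprev =
          (t > 0) ? Cs.begin() + off - B : nullptr;
      const double* dhr = dh_rec.colptr(u);
      const double* dHt = has_dH ? dHp + off : nullptr;
      const double* dlast = (t == T - 1) ? dh_last.colptr(u) : nullptr;
      double* dzi = dz.colptr(u);
      double* dzf = dz.colptr(U + u);
      double* dzg = dz.colptr(2 * U + u);
      double* dzo = dz.colptr(3 * U + u);
      double* dcn = dc_next.data() + (size_t)B * u;
      double s0 = 0, s1 = 0, s2 = 0, s3 = 0;
      for (int b = 0; b < B; ++b) {
        double dh = dhr[b];
        if (dHt) dh += dHt[b];
        if (dlast) dh += dlast[b];
        const double tc = std::tanh(cs[b]);
        const double og = ogp[b], ig = igp[b], fg = fgp[b],
                     gg = ggp[b];
        const double dc = dcn[b] + dh * og * (1.0 - tc * tc);
        const double cp = (t > 0) ? cprev[b] : 0.0;
        dzi[b] = dc * gg * ig * (1.0 - ig);
        dzf[b] = dc * cp * fg * (1.0 - fg);
        dzg[b] = dc * ig * (1.0 - gg * gg);
        dzo[b] = dh * tc * og * (1.0 - og);
        dcn[b] = dc * fg;
        s0 += dzi[b]; s1 += dzf[b]; s2 += dzg[b]; s3 += dzo[b];
      }
      db(u) += s0; db(U + u) += s1; db(2 * U + u) += s2;
      db(3 * U + u) += s3;
    }
    DZ.rows((size_t)t * B, (size_t)t * B + B - 1) = dz;
    if (t > 0) {
      for (int u = 0; u < U; ++u)
        std::memcpy(h_prev.colptr(u),
                    Hs.begin() + (size_t)B * (t - 1) + (size_t)B * T * u,
                    sizeof(double) * B);
      dWh += h_prev.t() * dz;
    }
    dh_rec = dz * WhT;
  }
  return Rcpp::List::create(Rcpp::Named("DZ") = DZ,
                            Rcpp::Named("dWh") = dWh,
                            Rcpp::Named("db") = db);
}

// im2col for a k x 1 temporal kernel over a B x T x W x C array with
// output rows enumerating (b, tout, w) sample-fastest and columns
// enumerating (tap, channel) tap-fastest within channel blocks.
// [[Rcpp::export]]
arma::mat cpp_im2col_time(const Rcpp::NumericVector& X, int B, int T,
                          int W, int C, int k, int stride, int pad_beg,
                          int Tout) {
  const double* xp = X.begin();
  mat M((size_t)B * Tout * W, (size_t)k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < k; ++ki) {
      double* mcol = M.colptr((size_t)ki * C + c);
      for (int w = 0; w < W; ++w) {
        for (int to = 0; to < Tout; ++to) {
          int tin = to * stride + ki - pad_beg;
          if (tin < 0 || tin >= T) continue;
          const double* src = xp + (size_t)B * (tin + (size_t)T * (w + (size_t)W * c));
          double* dst = mcol + (size_t)B * (to + (size_t)Tout * w);
          std::memcpy(dst, src, sizeof(double) * B);
        }
      }
    }
  }
  return M;
}

// Adjoint of cpp_im2col_time: scatter-add patch gradients back. The
// result is a flat vector; the caller restores the B x T x W x C dims.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_col2im_time(const arma::mat& dM, int B, int T,
                                    int W, int C, int k, int stride,
                                    int pad_beg, int Tout) {
  Rcpp::NumericVector dX((R_xlen_t)B * T * W * C);
  double* xp = dX.begin();
  for (int c = 0; c < C; ++c) {
    for (int ki = 0; ki < k; ++ki) {
      const double* mcol = dM.colptr((size_t)ki * C + c);
      for (int w = 0; w < W; ++w) {
        for (int to = 0; to < Tout; ++to) {
          int tin = to * stride + ki - pad_beg;
          if (tin < 0 || tin >= T) continue;
          double* dst = xp + (size_t)B * (tin + (size_t)T * (w + (size_t)W * c));
          const double* src = mcol + (size_t)B * (to + (size_t)Tout * w);
          for (int b = 0; b < B; ++b) dst[b] += src[b];
        }
      }
    }
  }
  return dX;
}
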