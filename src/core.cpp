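// Iterative cores for Richardson-Lucy and anchor-update (AU) deconvolution.
//
// All rasters are real column-major matrices with the zero-shift origin at
// the center pixel c0 = floor(extent/2) (0-based) per axis.  The centered
// convolution/correlation conventions used throughout the package are
//
//   conv_c(f, g)  = circshift(IDFT(F f . F g), -c0)
//   corr_c(f, g)  = circshift(IDFT(conj(F f) . F g), +c0)
//
// which fold into pure spectral products here: with A = F(h) . W, where
// W[k] = exp(+2i pi k.c0/n), one RL iteration is
//
//   denom = IDFT(F(o) . A),  ratio = f / denom,  o *= IDFT(F(ratio) . conj(A))
//
// and the AU effective kernel K_t = corr_c(o_t, H) (unit-sum normalized)
// enters solely through A = conj(F o) . F(H) / (sum(o) sum(H)), so a single
// AU iteration costs four transforms and no explicit shifts.  These
// identities are cross-checked against the plain R implementations in the
// test suite.

#include <Rcpp.h>
#include <fftw3.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;

namespace {

struct FFT2 {
  int nr, nc, N;
  std::vector<cplx> buf;
  fftw_plan fwd, bwd;
  FFT2(int nr_, int nc_) : nr(nr_), nc(nc_), N(nr_ * nc_), buf(nr_ * nc_) {
    fftw_complex* b = reinterpret_cast<fftw_complex*>(buf.data());
    // R matrices are column-major: fastest-varying index has extent nr,
    // so the FFTW row-major dims are (nc, nr).
    fwd = fftw_plan_dft_2d(nc, nr, b, b, FFTW_FORWARD, FFTW_ESTIMATE);
    bwd = fftw_plan_dft_2d(nc, nr, b, b, FFTW_BACKWARD, FFTW_ESTIMATE);
  }
  ~FFT2() {
    fftw_destroy_plan(fwd);
    fftw_destroy_plan(bwd);
  }
  void forward_real(const double* x, std::vector<cplx>& out) {
    for (int i = 0; i < N; ++i) buf[i] = cplx(x[i], 0.0);
    fftw_execute(fwd);
    out.assign(buf.begin(), buf.end());
  }
  // IDFT of spec, real part, 1/N normalized
  void inverse_to_real(const std::vector<cplx>& spec, std::vector<double>& out) {
    std::copy(spec.begin(), spec.end(), buf.begin());
    fftw_execute(bwd);
    out.resize(N);
    const double s = 1.0 / N;
    for (int i = 0; i < N; ++i) out[i] = buf[i].real() * s;
  }
};

double vec_sum(const double* x, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += x[i];
  return s;
}

// centered autocorrelation |corr_c(x, x)| and its spectrum
void centered_abs_autocorr_spec(FFT2& fft, const std::vector<double>& x,
                                std::vector<cplx>& spec_out,
                                double& sum_out) {
  const int nr = fft.nr, nc = fft.nc, N = fft.N;
  std::vector<cplx> Fx;
  fft.forward_real(x.data(), Fx);
  for (int i = 0; i < N; ++i) Fx[i] = cplx(std::norm(Fx[i]), 0.0);
  std::vector<double> raw;
  fft.inverse_to_real(Fx, raw);
  // circshift by +c0 per axis, then abs
  const int sr = nr / 2, sc = nc / 2;
  std::vector<double> H(N);
  for (int j = 0; j < nc; ++j) {
    const int jj = (j + sc) % nc;
    for (int i = 0; i < nr; ++i) {
      const int ii = (i + sr) % nr;
      H[ii + jj * nr] = std::fabs(raw[i + j * nr]);
    }
  }
  sum_out = vec_sum(H.data(), N);
  fft.forward_real(H.data(), spec_out);
}

// One multiplicative AU sweep on `x` against data `chi` using the fixed
// autocorrelation spectrum FH (spectrum of the centered field); the
// effective kernel is recomputed from x at every iteration.
void au_sweep(FFT2& fft, std::vector<double>& x, const double* chi,
              const std::vector<cplx>& FH, double sumH, int n_iter,
              double eps_rel) {
  const int N = fft.N;
  std::vector<cplx> Fx, A(N), tmp(N);
  std::vector<double> denom, upd, ratio(N);
  for (int it = 0; it < n_iter; ++it) {
    fft.forward_real(x.data(), Fx);
    const double s = vec_sum(x.data(), N) * sumH;
    const double inv_s = 1.0 / s;
    for (int i = 0; i < N; ++i) A[i] = std::conj(Fx[i]) * FH[i] * inv_s;
    for (int i = 0; i < N; ++i) tmp[i] = Fx[i] * A[i];
    fft.inverse_to_real(tmp, denom);
    double dmax = 0.0;
    for (int i = 0; i < N; ++i) dmax = std::max(dmax, denom[i]);
    const double floor_ = std::max(eps_rel * dmax, 1e-300);
    for (int i = 0; i < N; ++i)
      ratio[i] = chi[i] / std::max(denom[i], floor_);
    fft.forward_real(ratio.data(), Fx);
    for (int i = 0; i < N; ++i) tmp[i] = Fx[i] * std::conj(A[i]);
    fft.inverse_to_real(tmp, upd);
    for (int i = 0; i < N; ++i) x[i] *= std::max(upd[i], 0.0);
  }
}

}  // namespace

// Richardson-Lucy: n_iter multiplicative updates of o against measurement f
// with fixed unit-sum kernel h.  Returns the estimate and, optionally, the
// per-iteration energy-normalized MSE between o_t * h and f.
// [[Rcpp::export]]
List cpp_rl_run(NumericMatrix f, NumericMatrix h, NumericMatrix o0,
                int n_iter, double eps_rel, bool record_mse) {
  const int nr = f.nrow(), nc = f.ncol(), N = nr * nc;
  FFT2 fft(nr, nc);
  std::vector<cplx> Fh, A(N), Fx, tmp(N);
  fft.forward_real(h.begin(), Fh);
  // W[k] = exp(+2i pi (k_r c0_r / nr + k_c c0_c / nc))
  const int c0r = nr / 2, c0c = nc / 2;
  for (int j = 0; j < nc; ++j) {
    const double pj = 2.0 * M_PI * (double)j * c0c / nc;
    for (int i = 0; i < nr; ++i) {
      const double ph = 2.0 * M_PI * (double)i * c0r / nr + pj;
      A[i + j * nr] = Fh[i + j * nr] * cplx(std::cos(ph), std::sin(ph));
    }
  }
  std::vector<double> x(f.begin(), f.end());
  std::copy(o0.begin(), o0.end(), x.begin());
  std::vector<double> denom, upd, ratio(N), mse_trace;
  double f_energy = 0.0;
  for (int i = 0; i < N; ++i) f_energy += f[i] * f[i];
  const double f_l2 = std::sqrt(f_energy);
  for (int it = 0; it < n_iter; ++it) {
    fft.forward_real(x.data(), Fx);
    for (int i = 0; i < N; ++i) tmp[i] = Fx[i] * A[i];
    fft.inverse_to_real(tmp, denom);
    if (record_mse) {
      double e = 0.0;
      for (int i = 0; i < N; ++i) e += denom[i] * denom[i];
      const double bl2 = std::sqrt(e);
      double acc = 0.0;
      for (int i = 0; i < N; ++i) {
        const double d = denom[i] / bl2 - f[i] / f_l2;
        acc += d * d;
      }
      mse_trace.push_back(acc);
    }
    double dmax = 0.0;
    for (int i = 0; i < N; ++i) dmax = std::max(dmax, denom[i]);
    const double floor_ = std::max(eps_rel * dmax, 1e-300);
    for (int i = 0; i < N; ++i)
      ratio[i] = f[i] / std::max(denom[i], floor_);
    fft.forward_real(ratio.data(), Fx);
    for (int i = 0; i < N; ++i) tmp[i] = Fx[i] * std::conj(A[i]);
    fft.inverse_to_real(tmp, upd);
    for (int i = 0; i < N; ++i) x[i] *= std::max(upd[i], 0.0);
  }
  NumericMatrix out(nr, nc);
  std::copy(x.begin(), x.end(), out.begin());
  return List::create(_["estimate"] = out,
                      _["mse_trace"] = NumericVector(mse_trace.begin(),
                                                     mse_trace.end()));
}

// AU inversion of chi with a fixed kernel autocorrelation H (centered
// raster).  Optionally records, before each iteration, the scale-invariant
// residual || m/||m|| - chi/||chi|| ||_2 with m = o (x) o * H (the model
// autocorrelation); energy normalization because the unit-sum kernel
// convention fixes the estimate's flux to sum(chi), not to the data scale.
// [[Rcpp::export]]
List cpp_au_run(NumericMatrix chi, NumericMatrix H, NumericMatrix o0,
                int n_iter, double eps_rel, bool record_residual) {
  const int nr = chi.nrow(), nc = chi.ncol(), N = nr * nc;
  FFT2 fft(nr, nc);
  std::vector<cplx> FH, Fx, tmp(N), A(N);
  fft.forward_real(H.begin(), FH);
  const double sumH = vec_sum(H.begin(), N);
  std::vector<double> x(o0.begin(), o0.end());
  std::vector<double> denom, upd, model, ratio(N), res_trace;
  double chi_e = 0.0;
  for (int i = 0; i < N; ++i) chi_e += chi[i] * chi[i];
  const double chi_l2 = std::sqrt(chi_e);
  for (int it = 0; it < n_iter; ++it) {
    fft.forward_real(x.data(), Fx);
    if (record_residual) {
      for (int i = 0; i < N; ++i) tmp[i] = std::norm(Fx[i]) * FH[i];
      fft.inverse_to_real(tmp, model);
      double me = 0.0;
      for (int i = 0; i < N; ++i) me += model[i] * model[i];
      const double ml2 = std::sqrt(me);
      double acc = 0.0;
      for (int i = 0; i < N; ++i) {
        const double d = model[i] / ml2 - chi[i] / chi_l2;
        acc += d * d;
      }
      res_trace.push_back(std::sqrt(acc));
    }
    const double s = vec_sum(x.data(), N) * sumH;
    const double inv_s = 1.0 / s;
    for (int i = 0; i < N; ++i) A[i] = std::conj(Fx[i]) * FH[i] * inv_s;
    for (int i = 0; i < N; ++i) tmp[i] = Fx[i] * A[i];
    fft.inverse_to_real(tmp, denom);
    double dmax = 0.0;
    for (int i = 0; i < N; ++i) dmax = std::max(dmax, denom[i]);
    const double floor_ = std::max(eps_rel * dmax, 1e-300);
    for (int i = 0; i < N; ++i)
      ratio[i] = chi[i] / std::max(denom[i], floor_);
    fft.forward_real(ratio.data(), Fx);
    for (int i = 0; i < N; ++i) tmp[i] = Fx[i] * std::conj(A[i]);
    fft.inverse_to_real(tmp, upd);
    for (int i = 0; i < N; ++i) x[i] *= std::max(upd[i], 0.0);
  }
  NumericMatrix out(nr, nc);
  std::copy(x.begin(), x.end(), out.begin());
  return List::create(_["estimate"] = out,
                      _["residual_trace"] = NumericVector(res_trace.begin(),
                                                          res_trace.end()));
}

// Blind-AU: `cycles` alternations of an object block (t iterations, PSF
// fixed through its autocorrelation H) and a PSF block (t_prime iterations,
// object fixed through O).  h is renormalized to unit sum at each PSF block
// boundary.  Returns the updated pair; checkpointing is handled by the R
// driver, which calls this in chunks of cycles.
// [[Rcpp::export]]
List cpp_blind_run(NumericMatrix chi, NumericMatrix o0, NumericMatrix h0,
                   int t, int t_prime, int cycles, double eps_rel) {
  const int nr = chi.nrow(), nc = chi.ncol(), N = nr * nc;
  FFT2 fft(nr, nc);
  std::vector<double> o(o0.begin(), o0.end());
  std::vector<double> h(h0.begin(), h0.end());
  std::vector<cplx> spec;
  double ssum;
  for (int k = 0; k < cycles; ++k) {
    centered_abs_autocorr_spec(fft, h, spec, ssum);   // H_{k-1}
    au_sweep(fft, o, chi.begin(), spec, ssum, t, eps_rel);
    centered_abs_autocorr_spec(fft, o, spec, ssum);   // O_k
    au_sweep(fft, h, chi.begin(), spec, ssum, t_prime, eps_rel);
    const double hs = vec_sum(h.data(), N);
    if (hs > 0) {
      const double inv = 1.0 / hs;
      for (int i = 0; i < N; ++i) h[i] *= inv;
    }
    if ((k & 15) == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix oo(nr, nc), hh(nr, nc);
  std::copy(o.begin(), o.end(), oo.begin());
  std::copy(h.begin(), h.end(), hh.begin());
  return List::create(_["object"] = oo, _["psf"] = hh);
}
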