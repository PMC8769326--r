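#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Zeroth-order modified Bessel function of the first kind (power series).
static double bessel_i0(double x) {
  double sum = 1.0, term = 1.0;
  double hx = x / 2.0;
  for (int k = 1; k < 60; ++k) {
    term *= (hx / k) * (hx / k);
    sum += term;
    if (term < 1e-16 * sum) break;
  }
  return sum;
}

//' @title Windowed-sinc resampler (internal kernel)
//' @description Resamples \code{x} from \code{fs_in} to \code{fs_out} with a
//'   Kaiser-windowed sinc interpolation filter whose cutoff sits at the lower
//'   of the two Nyquist frequencies (anti-aliased downsampling). The kernel is
//'   precomputed on a fine grid and linearly interpolated, so the cost per
//'   output sample is one dot product.
//' @param x numeric input signal
//' @param fs_in,fs_out input/output sampling rates (Hz)
//' @param half_width filter half-width in output-rate zero crossings
//' @param beta Kaiser window shape parameter
//' @return numeric vector of length floor(length(x) * fs_out / fs_in)
//' @keywords internal
// [[Rcpp::export(name = ".resample_kernel")]]
NumericVector resample_kernel(NumericVector x, double fs_in, double fs_out,
                              int half_width = 48, double beta = 10.0) {
  const R_xlen_t n_in = x.size();
  const R_xlen_t n_out = (R_xlen_t) std::floor((double) n_in * fs_out / fs_in);
  NumericVector y(n_out);
  const double ratio = fs_in / fs_out;                 // input samples / output sample
  const double cutoff = std::min(1.0, fs_out / fs_in); // rel. to input Nyquist
  const double width = half_width / cutoff;            // input samples
  const double i0b = bessel_i0(beta);

  // kernel table h(u), u in [0, width], grid step 1/grid input samples
  const int grid = 512;
  const R_xlen_t n_tab = (R_xlen_t)(width * grid) + 2;
  std::vector<double> tab(n_tab);
  for (R_xlen_t i = 0; i < n_tab; ++i) {
    const double u = (double) i / grid;
    if (u > width) { tab[i] = 0.0; continue; }
    const double v = u / width;
    const double win =
      bessel_i0(beta * std::sqrt(std::max(0.0, 1.0 - v * v))) / i0b;
    const double arg = M_PI * cutoff * u;
    const double s = (arg < 1e-12) ? cutoff : cutoff * std::sin(arg) / arg;
    tab[i] = s * win;
  }
  const double scale = grid;

  for (R_xlen_t n = 0; n < n_out; ++n) {
    const double t = n * ratio;
    const R_xlen_t k0 = std::max((R_xlen_t) 0, (R_xlen_t) std::ceil(t - width));
    const R_xlen_t k1 = std::min(n_in - 1, (R_xlen_t) std::floor(t + width));
    double acc = 0.0;
    for (R_xlen_t k = k0; k <= k1; ++k) {
      const double u = std::fabs(t - k) * scale;
      const R_xlen_t i = (R_xlen_t) u;
      if (i + 1 >= n_tab) continue;
      const double frac = u - i;
      const double tap = tab[i] + frac * (tab[i + 1] - tab[i]);
      acc += tap * x[k];
    }
    // samples beyond the signal are treated as zeros (short fade at the
    // boundaries instead of renormalisation, which would amplify the
    // truncated kernel's stopband leakage)
    y[n] = acc;
  }
  return y;
}
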