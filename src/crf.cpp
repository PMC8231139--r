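// Pairwise message passing for mean-field CRF inference: truncated Gaussian
// appearance (spatial + intensity) and smoothness (spatial only) kernels,
// applied channel-wise with shared pairwise weights. The centre pixel is
// excluded from the sum, following the usual dense-CRF convention.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_crf_filter(NumericVector q, NumericVector img,
                             double sigma_s, double sigma_r,
                             bool use_intensity, int radius) {
  IntegerVector qd = q.attr("dim");
  int H = qd[0], W = qd[1], C = qd[2];
  NumericVector out(Dimension(H, W, C));
  const double* qp = q.begin();
  const double* ip = img.begin();
  double* op = out.begin();
  const double is2 = 1.0 / (2.0 * sigma_s * sigma_s);
  const double ir2 = use_intensity ? 1.0 / (2.0 * sigma_r * sigma_r) : 0.0;
  const int HW = H * W;
  std::vector<double> spat((2 * radius + 1) * (2 * radius + 1));
  for (int dj = -radius; dj <= radius; ++dj)
    for (int di = -radius; di <= radius; ++di)
      spat[(di + radius) + (2 * radius + 1) * (dj + radius)] =
        std::exp(-(di * di + dj * dj) * is2);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double ic = ip[i + (std::size_t)H * j];
      const int jlo = std::max(0, j - radius), jhi = std::min(W - 1, j + radius);
      const int ilo = std::max(0, i - radius), ihi = std::min(H - 1, i + radius);
      for (int jj = jlo; jj <= jhi; ++jj) {
        for (int ii = ilo; ii <= ihi; ++ii) {
          if (ii == i && jj == j) continue;
          double wgt = spat[(ii - i + radius) + (2 * radius + 1) * (jj - j + radius)];
          if (use_intensity) {
            const double d = ip[ii + (std::size_t)H * jj] - ic;
            wgt *= std::exp(-d * d * ir2);
          }
          if (wgt < 1e-12) continue;
          const std::size_t src = ii + (std::size_t)H * jj;
          const std::size_t dst = i + (std::size_t)H * j;
          for (int c = 0; c < C; ++c)
            op[dst + (std::size_t)c * HW] += wgt * qp[src + (std::size_t)c * HW];
        }
      }
    }
  }
  return out;
}
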