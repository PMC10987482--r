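// Defocus blur: convolution with an anti-aliased disk kernel whose pixel
// weights are the approximate disk coverage clamp(radius + 0.5 - d, 0, 1),
// so the kernel varies continuously with radius. Border handling: replicate.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".disk_blur_cpp")]]
NumericMatrix disk_blur_cpp(const NumericMatrix& img, double radius) {
  int nr = img.nrow(), nc = img.ncol();
  if (radius <= 0.0) return clone(img);
  int R = (int)std::ceil(radius + 0.5);
  std::vector<int> oi, oj;
  std::vector<double> w;
  double wsum = 0.0;
  for (int a = -R; a <= R; ++a) {
    for (int b = -R; b <= R; ++b) {
      double d = std::sqrt((double)(a * a + b * b));
      double cov = radius + 0.5 - d;
      if (cov <= 0) continue;
      if (cov > 1) cov = 1;
      oi.push_back(a);
      oj.push_back(b);
      w.push_back(cov);
      wsum += cov;
    }
  }
  int K = w.size();
  for (int k = 0; k < K; ++k) w[k] /= wsum;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        int ii = i + oi[k];
        int jj = j + oj[k];
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        s += w[k] * img(ii, jj);
      }
      out(i, j) = s;
    }
  }
  return out;
}
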