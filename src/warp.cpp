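#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mirror index i (0-based, possibly out of range) into [0, n-1] without
// repeating the edge sample (reflect-101 convention).
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  const int p = 2 * n - 2;
  i %= p;
  if (i < 0) i += p;
  return (i >= n) ? (p - i) : i;
}

// Copy a matrix into a buffer padded by `pad` on every side with reflected
// borders, so the filter loops below need no boundary tests.
static std::vector<double> pad_reflect(const NumericMatrix& m, int pad) {
  const int h = m.nrow(), w = m.ncol();
  const int ph = h + 2 * pad, pw = w + 2 * pad;
  std::vector<double> buf((size_t)ph * pw);
  for (int j = 0; j < pw; ++j) {
    const int sj = reflect_index(j - pad, w);
    for (int i = 0; i < ph; ++i) {
      buf[(size_t)i + (size_t)j * ph] = m(reflect_index(i - pad, h), sj);
    }
  }
  return buf;
}

// Separable Gaussian smoothing with reflected borders. Kernel radius is
// ceil(3*sigma), the usual truncation of the Gaussian filter applied to
// elastic-distortion displacement fields.
// [[Rcpp::export(name = ".gaussSmooth")]]
NumericMatrix gauss_smooth(const NumericMatrix& m, double sigma) {
  if (sigma <= 0) stop("sigma must be > 0");
  const int h = m.nrow(), w = m.ncol();
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;

  std::vector<double> pad = pad_reflect(m, r);
  const int ph = h + 2 * r;
  // vertical pass into tmp (h x w, but keep horizontal padding)
  std::vector<double> tmp((size_t)h * (w + 2 * r));
  for (int j = 0; j < w + 2 * r; ++j) {
    const double* col = &pad[(size_t)j * ph];
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      for (int t = 0; t <= 2 * r; ++t) acc += k[t] * col[i + t];
      tmp[(size_t)i + (size_t)j * h] = acc;
    }
  }
  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      const double* row = &tmp[(size_t)i];
      for (int t = 0; t <= 2 * r; ++t) acc += k[t] * row[(size_t)(j + t) * h];
      out(i, j) = acc;
    }
  }
  return out;
}

// Resample an h x w x 3 raster at (row + dy, col + dx) with reflected
// borders. interp = 0 -> bilinear, 1 -> nearest neighbour. dx/dy are in
// pixels; zero displacement reproduces the input exactly.
// [[Rcpp::export(name = ".warpRaster")]]
NumericVector warp_raster(const NumericVector& img,
                          const NumericMatrix& dy,
                          const NumericMatrix& dx,
                          int interp) {
  IntegerVector dims = img.attr("dim");
  if (dims.size() != 3 || dims[2] != 3) stop("img must be an h x w x 3 array");
  const int h = dims[0], w = dims[1];
  if (dy.nrow() != h || dy.ncol() != w || dx.nrow() != h || dx.ncol() != w)
    stop("displacement fields must match image dimensions");
  NumericVector out(img.size());
  out.attr("dim") = dims;
  const double* src = img.begin();
  double* dst = out.begin();
  const int plane = h * w;

  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      const double ys = i + dy(i, j);
      const double xs = j + dx(i, j);
      if (interp == 1) {                      // nearest
        const int yi = reflect_index((int)std::lround(ys), h);
        const int xi = reflect_index((int)std::lround(xs), w);
        for (int c = 0; c < 3; ++c)
          dst[i + j * h + c * plane] = src[yi + xi * h + c * plane];
      } else {                                // bilinear
        const double yf = std::floor(ys), xf = std::floor(xs);
        const double fy = ys - yf, fx = xs - xf;
        const int y0 = reflect_index((int)yf, h);
        const int y1 = reflect_index((int)yf + 1, h);
        const int x0 = reflect_index((int)xf, w);
        const int x1 = reflect_index((int)xf + 1, w);
        for (int c = 0; c < 3; ++c) {
          const double* p = src + c * plane;
          const double v =
            (1 - fy) * ((1 - fx) * p[y0 + x0 * h] + fx * p[y0 + x1 * h]) +
            fy       * ((1 - fx) * p[y1 + x0 * h] + fx * p[y1 + x1 * h]);
          dst[i + j * h + c * plane] = v;
        }
      }
    }
  }
  return out;
}

// Rectangular grayscale min/max filter (seH x seW structuring element) per
// channel, reflected borders, centred origin (rounded down for even sizes).
// op = 0 -> min (bar dilation on white background), 1 -> max (bar erosion).
// [[Rcpp::export(name = ".rectFilter")]]
NumericVector rect_filter(const NumericVector& img, int seH, int seW, int op) {
  IntegerVector dims = img.attr("dim");
  if (dims.size() != 3 || dims[2] != 3) stop("img must be an h x w x 3 array");
  if (seH < 1 || seW < 1) stop("structuring element must be at least 1 x 1");
  const int h = dims[0], w = dims[1];
  NumericVector out(clone(img));
  if (seH == 1 && seW == 1) return out;
  const int up = (seH - 1) / 2, down = seH - 1 - up;
  const int left = (seW - 1) / 2, right = seW - 1 - left;
  const int plane = h * w;
  for (int c = 0; c < 3; ++c) {
    NumericMatrix ch(h, w);
    std::copy(img.begin() + (size_t)c * plane,
              img.begin() + (size_t)(c + 1) * plane, ch.begin());
    const int pad = std::max(std::max(up, down), std::max(left, right));
    std::vector<double> buf = pad_reflect(ch, pad);
    const int ph = h + 2 * pad;
    double* dst = out.begin() + (size_t)c * plane;
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double v = buf[(size_t)(i + pad - up) + (size_t)(j + pad - left) * ph];
        for (int dj = -left; dj <= right; ++dj) {
          const double* col = &buf[(size_t)(j + pad + dj) * ph];
          for (int di = -up; di <= down; ++di) {
            const double x = col[i + pad + di];
            v = op == 0 ? (x < v ? x : v) : (x > v ? x : v);
          }
        }
        dst[i + (size_t)j * h] = v;
      }
    }
  }
  return out;
}
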