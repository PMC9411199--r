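#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Bilinear sample with edge clamping.
static inline double sampleBilinear(const NumericMatrix &img, double y,
                                    double x) {
  int H = img.nrow(), W = img.ncol();
  if (y < 0) y = 0;
  if (y > H - 1) y = H - 1;
  if (x < 0) x = 0;
  if (x > W - 1) x = W - 1;
  int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
  double fy = y - y0, fx = x - x0;
  return (1 - fy) * (1 - fx) * img(y0, x0) + (1 - fy) * fx * img(y0, x1) +
         fy * (1 - fx) * img(y1, x0) + fy * fx * img(y1, x1);
}

// out(y, x) = img(y + dy(y, x), x + dx(y, x)); out-of-bounds samples clamp
// to the edge value (0-based pixel coordinates).
// [[Rcpp::export]]
NumericMatrix warp_bilinear_cpp(NumericMatrix img, NumericMatrix dy,
                                NumericMatrix dx) {
  int H = img.nrow(), W = img.ncol();
  if (dy.nrow() != H || dy.ncol() != W || dx.nrow() != H || dx.ncol() != W)
    stop("field shape must match image shape");
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      out(i, j) = sampleBilinear(img, i + dy(i, j), j + dx(i, j));
  return out;
}

// Bilinear resize to (h, w), aligning image corners.
// [[Rcpp::export]]
NumericMatrix resize_bilinear_cpp(NumericMatrix img, int h, int w) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(h, w);
  double sy = (h > 1) ? (double)(H - 1) / (h - 1) : 0.0;
  double sx = (w > 1) ? (double)(W - 1) / (w - 1) : 0.0;
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j)
      out(i, j) = sampleBilinear(img, i * sy, j * sx);
  return out;
}

// Rectangular (ky x kx) median filter with reflect boundary handling.
// [[Rcpp::export]]
NumericMatrix median_filter2d_cpp(NumericMatrix img, int ky, int kx) {
  if (ky < 1 || kx < 1 || ky % 2 == 0 || kx % 2 == 0)
    stop("kernel dimensions must be odd and positive");
  int H = img.nrow(), W = img.ncol();
  int ry = ky / 2, rx = kx / 2;
  NumericMatrix out(H, W);
  std::vector<double> buf;
  buf.reserve((size_t)ky * kx);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      buf.clear();
      for (int a = -ry; a <= ry; ++a) {
        int ii = i + a;
        if (ii < 0) ii = -ii - 1;            // reflect
        if (ii >= H) ii = 2 * H - ii - 1;
        for (int b = -rx; b <= rx; ++b) {
          int jj = j + b;
          if (jj < 0) jj = -jj - 1;
          if (jj >= W) jj = 2 * W - jj - 1;
          buf.push_back(img(ii, jj));
        }
      }
      size_t m = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double med = buf[m];
      if (buf.size() % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + m);
        med = 0.5 * (med + lo);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Quadratic optic-flow energy at one pyramid level, linearized around the
// incoming flow (dy0, dx0):
//   E(dy, dx) = sum_p [Iy (dy - dy0) + Ix (dx - dx0) + It]^2
//             + lambda * sum (forward-difference gradients of dy and dx)^2
// movw is the moving frame pre-warped by (dy0, dx0); It = movw - ref.
// Minimized by exact per-pixel 2x2 block Gauss-Seidel sweeps (coordinate
// descent on a convex quadratic, so the energy is non-increasing).
// [[Rcpp::export]]
List hs_level_cpp(NumericMatrix ref, NumericMatrix movw, NumericMatrix dy0,
                  NumericMatrix dx0, double lambda, int niter, double tol) {
  int H = ref.nrow(), W = ref.ncol();
  NumericMatrix Iy(H, W), Ix(H, W), It(H, W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      int ip = std::min(i + 1, H - 1), im = std::max(i - 1, 0);
      int jp = std::min(j + 1, W - 1), jm = std::max(j - 1, 0);
      double denY = (double)(ip - im), denX = (double)(jp - jm);
      Iy(i, j) = 0.5 * ((ref(ip, j) - ref(im, j)) / denY +
                        (movw(ip, j) - movw(im, j)) / denY);
      Ix(i, j) = 0.5 * ((ref(i, jp) - ref(i, jm)) / denX +
                        (movw(i, jp) - movw(i, jm)) / denX);
      It(i, j) = movw(i, j) - ref(i, j);
    }
  }
  NumericMatrix dy = clone(dy0), dx = clone(dx0);
  std::vector<double> energies;
  energies.reserve(niter);
  auto energy = [&]() {
    double e = 0;
    for (int i = 0; i < H; ++i)
      for (int j = 0; j < W; ++j) {
        double r = Iy(i, j) * (dy(i, j) - dy0(i, j)) +
                   Ix(i, j) * (dx(i, j) - dx0(i, j)) + It(i, j);
        e += r * r;
        if (i + 1 < H) {
          double gy = dy(i + 1, j) - dy(i, j), gx = dx(i + 1, j) - dx(i, j);
          e += lambda * (gy * gy + gx * gx);
        }
        if (j + 1 < W) {
          double gy = dy(i, j + 1) - dy(i, j), gx = dx(i, j + 1) - dx(i, j);
          e += lambda * (gy * gy + gx * gx);
        }
      }
    return e;
  };
  for (int it = 0; it < niter; ++it) {
    double delta = 0;
    for (int i = 0; i < H; ++i) {
      for (int j = 0; j < W; ++j) {
        double su = 0, sv = 0;
        int n = 0;
        if (i > 0) { su += dy(i - 1, j); sv += dx(i - 1, j); ++n; }
        if (i + 1 < H) { su += dy(i + 1, j); sv += dx(i + 1, j); ++n; }
        if (j > 0) { su += dy(i, j - 1); sv += dx(i, j - 1); ++n; }
        if (j + 1 < W) { su += dy(i, j + 1); sv += dx(i, j + 1); ++n; }
        double iy = Iy(i, j), ix = Ix(i, j);
        double c = It(i, j) - iy * dy0(i, j) - ix * dx0(i, j);
        double a11 = iy * iy + lambda * n;
        double a22 = ix * ix + lambda * n;
        double a12 = iy * ix;
        double b1 = lambda * su - iy * c;
        double b2 = lambda * sv - ix * c;
        double det = a11 * a22 - a12 * a12;
        double nu = (a22 * b1 - a12 * b2) / det;
        double nv = (a11 * b2 - a12 * b1) / det;
        delta += std::abs(nu - dy(i, j)) + std::abs(nv - dx(i, j));
        dy(i, j) = nu;
        dx(i, j) = nv;
      }
    }
    energies.push_back(energy());
    if (delta / (2.0 * H * W) < tol) break;
  }
  return List::create(_["dy"] = dy, _["dx"] = dx,
                      _["energy"] = NumericVector(energies.begin(),
                                                  energies.end()));
}
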