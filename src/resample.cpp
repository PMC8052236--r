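#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Interpolating cubic B-spline machinery: a causal/anticausal IIR prefilter
// (pole sqrt(3)-2, mirror boundary) turns samples into spline coefficients,
// after which the spline interpolates the original samples exactly at the
// integer nodes.

static const double POLE = -0.26794919243112270647; // sqrt(3) - 2
static const double GAIN = 6.0;                     // (1-z1)(1-1/z1)

static void prefilter_line(double *c, int n, int stride) {
  if (n < 2) return;
  // gain
  for (int i = 0; i < n; ++i) c[i * stride] *= GAIN;
  // causal initialization (mirror boundary): truncated horizon when the
  // line is long enough, exact closed form otherwise
  int horizon = (int)std::ceil(std::log(1e-14) / std::log(std::fabs(POLE)));
  double sum;
  if (horizon < n) {
    sum = c[0];
    double zk = POLE;
    for (int k = 1; k < horizon; ++k) {
      sum += zk * c[k * stride];
      zk *= POLE;
    }
  } else {
    double zn = POLE, iz = 1.0 / POLE;
    double z2n = std::pow(POLE, n - 1);
    sum = c[0] + z2n * c[(n - 1) * stride];
    z2n *= z2n * iz;
    for (int k = 1; k <= n - 2; ++k) {
      sum += (zn + z2n) * c[k * stride];
      zn *= POLE;
      z2n *= iz;
    }
    sum /= (1.0 - std::pow(POLE, 2 * n - 2));
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i)
    c[i * stride] += POLE * c[(i - 1) * stride];
  // anticausal initialization and backward pass
  c[(n - 1) * stride] = (POLE / (POLE * POLE - 1.0)) *
    (c[(n - 1) * stride] + POLE * c[(n - 2) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[i * stride] = POLE * (c[(i + 1) * stride] - c[i * stride]);
}

static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i > n - 1) {
    if (i < 0) i = -i;
    if (i > n - 1) i = 2 * (n - 1) - i;
  }
  return i;
}

// evaluate the cubic spline (coefficients c) at position t in [0, n-1];
// positions outside are clamped to the edge (nearest-edge value)
static inline double spline_eval(const double *c, int n, int stride, double t) {
  if (n == 1) return c[0];
  if (t < 0) t = 0;
  if (t > n - 1) t = (double)(n - 1);
  int i = (int)std::floor(t);
  if (i > n - 2) i = n - 2;
  double f = t - i;
  double f2 = f * f, f3 = f2 * f;
  double w0 = (1.0 - 3.0 * f + 3.0 * f2 - f3) / 6.0; // node i-1
  double w1 = (4.0 - 6.0 * f2 + 3.0 * f3) / 6.0;     // node i
  double g = 1.0 - f;
  double w2 = (4.0 - 6.0 * g * g + 3.0 * g * g * g) / 6.0; // node i+1
  double w3 = f3 / 6.0;                                    // node i+2
  return w0 * c[mirror_idx(i - 1, n) * stride] +
         w1 * c[i * stride] +
         w2 * c[mirror_idx(i + 1, n) * stride] +
         w3 * c[mirror_idx(i + 2, n) * stride];
}

// Resample one axis of a 3D array: output node k sits at input coordinate
// k * scale (0-based voxel coordinates).
static std::vector<double> resample_axis(std::vector<double> &a,
                                         int nx, int ny, int nz,
                                         int axis, double scale, int n_out) {
  int dims[3] = {nx, ny, nz};
  int n = dims[axis];
  size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  size_t strides[3] = {sx, sy, sz};
  size_t stride = strides[axis];

  // prefilter all lines along `axis` in place
  int d1 = (axis + 1) % 3, d2 = (axis + 2) % 3;
  for (int j2 = 0; j2 < dims[d2]; ++j2)
    for (int j1 = 0; j1 < dims[d1]; ++j1) {
      size_t base = (size_t)j1 * strides[d1] + (size_t)j2 * strides[d2];
      prefilter_line(&a[base], n, (int)stride);
    }

  int odims[3] = {nx, ny, nz};
  odims[axis] = n_out;
  std::vector<double> out((size_t)odims[0] * odims[1] * odims[2]);
  size_t osx = 1, osy = (size_t)odims[0], osz = (size_t)odims[0] * odims[1];
  size_t ostrides[3] = {osx, osy, osz};

  for (int j2 = 0; j2 < dims[d2]; ++j2)
    for (int j1 = 0; j1 < dims[d1]; ++j1) {
      size_t base = (size_t)j1 * strides[d1] + (size_t)j2 * strides[d2];
      size_t obase = (size_t)j1 * ostrides[d1] + (size_t)j2 * ostrides[d2];
      const double *line = &a[base];
      for (int k = 0; k < n_out; ++k)
        out[obase + (size_t)k * ostrides[axis]] =
          spline_eval(line, n, (int)stride, k * scale);
    }
  return out;
}

// [[Rcpp::export(name = ".cpp_resample_bspline")]]
NumericVector cpp_resample_bspline(NumericVector vol, IntegerVector dims,
                                   NumericVector scale, IntegerVector out_dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(vol.begin(), vol.end());
  a = resample_axis(a, nx, ny, nz, 0, scale[0], out_dims[0]);
  nx = out_dims[0];
  a = resample_axis(a, nx, ny, nz, 1, scale[1], out_dims[1]);
  ny = out_dims[1];
  a = resample_axis(a, nx, ny, nz, 2, scale[2], out_dims[2]);
  nz = out_dims[2];
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Separable Gaussian convolution, reflect boundary; sigma in voxels per axis.
// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dims,
                                NumericVector sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int dd[3] = {nx, ny, nz};
  size_t strides[3] = {1, (size_t)nx, (size_t)nx * ny};
  std::vector<double> a(vol.begin(), vol.end());
  std::vector<double> tmp(a.size());

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(4.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + r];
    }
    for (int i = 0; i <= 2 * r; ++i) k[i] /= ksum;

    int n = dd[axis];
    size_t stride = strides[axis];
    int d1 = (axis + 1) % 3, d2 = (axis + 2) % 3;
    for (int j2 = 0; j2 < dd[d2]; ++j2)
      for (int j1 = 0; j1 < dd[d1]; ++j1) {
        size_t base = (size_t)j1 * strides[d1] + (size_t)j2 * strides[d2];
        for (int i = 0; i < n; ++i) {
          double acc = 0;
          for (int t = -r; t <= r; ++t)
            acc += k[t + r] * a[base + (size_t)mirror_idx(i + t, n) * stride];
          tmp[base + (size_t)i * stride] = acc;
        }
      }
    std::swap(a, tmp);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}
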