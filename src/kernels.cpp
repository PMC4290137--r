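#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double INF = 1e20;

// ---------------------------------------------------------------------------
// 1D squared Euclidean distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher. f: input costs, d: output, n: length.
// ---------------------------------------------------------------------------
static void dt1d(const double* f, double* d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = +INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = +INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// squared EDT of a 3D cost grid in place (0 at sites, INF elsewhere)
static void edt3_sq(std::vector<double>& D, int nx, int ny, int nz) {
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* line = &D[(size_t)nx * (j + (size_t)ny * k)];
      dt1d(line, d.data(), nx, v, z);
      std::copy(d.begin(), d.begin() + nx, line);
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = D[i + (size_t)nx * (j + (size_t)ny * k)];
      dt1d(f.data(), d.data(), ny, v, z);
      for (int j = 0; j < ny; ++j) D[i + (size_t)nx * (j + (size_t)ny * k)] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = D[i + (size_t)nx * (j + (size_t)ny * k)];
      dt1d(f.data(), d.data(), nz, v, z);
      for (int k = 0; k < nz; ++k) D[i + (size_t)nx * (j + (size_t)ny * k)] = d[k];
    }
}

// ---------------------------------------------------------------------------
// Signed Euclidean distance field of a level-set field, in voxel units:
// |out(v)| is the distance from voxel v to the zero level set of phi
// (located to first order by linear interpolation along grid edges where
// phi changes sign), with sign(out) = sign(phi). Voxels adjacent to a sign
// change are seeded with their sub-voxel interface distance and the exact
// distance transform propagates the far field. For an indicator-style
// field (+-1) every crossing sits midway between voxel centers, so
// adjacent voxels get +-1/2. Keeping the sub-voxel position lets fronts
// moving slower than one voxel per iteration accumulate progress instead
// of being snapped back to the grid at every reinitialization.
// Caller guarantees both signs are present.
// ---------------------------------------------------------------------------
static void signed_edt_impl(const double* phi, double* out, int nx, int ny,
                            int nz) {
  size_t n = (size_t)nx * ny * nz;
  long stride[3] = {1, nx, (long)nx * ny};
  int dims[3] = {nx, ny, nz};

  // first-order sub-voxel distance at voxels adjacent to a sign change
  std::vector<double> d0(n, INF);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t v = i + (size_t)nx * (j + (size_t)ny * k);
        bool inside = phi[v] >= 0;
        int ijk[3] = {i, j, k};
        double best = INF;
        for (int ax = 0; ax < 3; ++ax)
          for (int dir = -1; dir <= 1; dir += 2) {
            int q = ijk[ax] + dir;
            if (q < 0 || q >= dims[ax]) continue;
            size_t w = v + dir * stride[ax];
            if ((phi[w] >= 0) == inside) continue;
            double denom = phi[v] - phi[w];
            double frac = denom != 0 ? phi[v] / denom : 0.5;
            if (frac < 0) frac = 0;
            if (frac > 1) frac = 1;
            if (frac < best) best = frac;
          }
        d0[v] = best;
      }

  // propagate the interface-adjacent seeds (with their squared sub-voxel
  // offsets as initial costs) by one exact distance transform; both phases
  // share the seed set, whose costs are consistent across each crossing
  std::vector<double> D(n);
  for (size_t v = 0; v < n; ++v) D[v] = d0[v] < INF ? d0[v] * d0[v] : INF;
  edt3_sq(D, nx, ny, nz);
  for (size_t v = 0; v < n; ++v)
    out[v] = (phi[v] >= 0 ? 1.0 : -1.0) * std::sqrt(D[v]);
}

// [[Rcpp::export(name = ".signed_edt")]]
NumericVector signed_edt_cpp(NumericVector phi, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)nx * ny * nz);
  signed_edt_impl(phi.begin(), out.begin(), nx, ny, nz);
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian convolution, symmetric ("reflect") boundary handling,
// kernel truncated at 4 sigma. Preserves constants exactly.
// ---------------------------------------------------------------------------
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static void blur_axis(const std::vector<double>& src, std::vector<double>& dst,
                      int nx, int ny, int nz, int axis,
                      const std::vector<double>& w, int rad) {
  int n[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  int na = n[axis];
  size_t sa = stride[axis];
  int b1 = axis == 0 ? 1 : 0, b2 = axis == 2 ? 1 : 2;
  for (int k = 0; k < n[b2]; ++k)
    for (int j = 0; j < n[b1]; ++j) {
      size_t base = stride[b1] * j + stride[b2] * k;
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int t = -rad; t <= rad; ++t)
          acc += w[t + rad] * src[base + sa * reflect_idx(i + t, na)];
        dst[base + sa * i] = acc;
      }
    }
}

// [[Rcpp::export(name = ".gauss_blur3")]]
NumericVector gauss_blur3_cpp(NumericVector x, IntegerVector dims, double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  if (sigma <= 0) return clone(x);
  int rad = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> w(2 * rad + 1);
  double s = 0.0;
  for (int t = -rad; t <= rad; ++t) {
    w[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += w[t + rad];
  }
  for (double& v : w) v /= s;
  std::vector<double> a(x.begin(), x.end()), b(n);
  blur_axis(a, b, nx, ny, nz, 0, w, rad);
  blur_axis(b, a, nx, ny, nz, 1, w, rad);
  blur_axis(a, b, nx, ny, nz, 2, w, rad);
  NumericVector out(n);
  std::copy(b.begin(), b.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component labelling of a binary mask (stack flood fill).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".label26")]]
List label26_cpp(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s0 = 0; s0 < n; ++s0) {
    if (!mask[s0] || lab[s0]) continue;
    ++next;
    lab[s0] = next;
    stack.push_back(s0);
    while (!stack.empty()) {
      size_t s = stack.back();
      stack.pop_back();
      int i = s % nx, j = (s / nx) % ny, k = s / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t t = ii + (size_t)nx * (jj + (size_t)ny * kk);
            if (mask[t] && !lab[t]) {
              lab[t] = next;
              stack.push_back(t);
            }
          }
    }
  }
  return List::create(_["labels"] = lab, _["n"] = next);
}

// ---------------------------------------------------------------------------
// Tube fields for the vessel phantom. Segments are rows of
// (x0,y0,z0,x1,y1,z1,r0,r1) in 0-based voxel coordinates; seg_branch maps
// each segment to its branch (1-based), branch_f are per-branch intensity
// dim factors. Intensity profile by distance d to the local centreline with
// radius r: f*peak for d <= r-w, linear to f*boundary at d = r, linear to
// background at d = r+w. Intensity accumulates by max across branches; the
// margin field min(d - r) and the branch label at its argmin support mask
// extraction and per-branch bookkeeping.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".tube_fields")]]
List tube_fields_cpp(NumericMatrix segs, IntegerVector seg_branch,
                     NumericVector branch_f, IntegerVector dims,
                     double peak, double boundary, double background,
                     double w) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector intensity(n, background);
  NumericVector margin(n, INF);
  IntegerVector label(n, 0);

  for (int s = 0; s < segs.nrow(); ++s) {
    double ax = segs(s, 0), ay = segs(s, 1), az = segs(s, 2);
    double bx = segs(s, 3), by = segs(s, 4), bz = segs(s, 5);
    double r0 = segs(s, 6), r1 = segs(s, 7);
    double f = branch_f[seg_branch[s] - 1];
    double rmax = std::max(r0, r1);
    double pad = rmax + w + 1.0;
    int i0 = std::max(0, (int)std::floor(std::min(ax, bx) - pad));
    int i1 = std::min(nx - 1, (int)std::ceil(std::max(ax, bx) + pad));
    int j0 = std::max(0, (int)std::floor(std::min(ay, by) - pad));
    int j1 = std::min(ny - 1, (int)std::ceil(std::max(ay, by) + pad));
    int k0 = std::max(0, (int)std::floor(std::min(az, bz) - pad));
    int k1 = std::min(nz - 1, (int)std::ceil(std::max(az, bz) + pad));
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double L2 = ux * ux + uy * uy + uz * uz;
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double px = i - ax, py = j - ay, pz = k - az;
          double t = L2 > 0 ? (px * ux + py * uy + pz * uz) / L2 : 0.0;
          if (t < 0) t = 0;
          if (t > 1) t = 1;
          double dx = px - t * ux, dy = py - t * uy, dz = pz - t * uz;
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          double r = r0 + (r1 - r0) * t;
          if (d > r + w) continue;
          double val;
          if (d <= r - w)
            val = f * peak;
          else if (d <= r)
            val = f * peak + (f * boundary - f * peak) * (d - (r - w)) / w;
          else
            val = f * boundary + (background - f * boundary) * (d - r) / w;
          size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
          if (val > intensity[idx]) intensity[idx] = val;
          if (d - r < margin[idx]) {
            margin[idx] = d - r;
            label[idx] = seg_branch[s];
          }
        }
  }
  return List::create(_["intensity"] = intensity, _["margin"] = margin,
                      _["label"] = label);
}

// ---------------------------------------------------------------------------
// Finite differences: central in the interior, one-sided at the faces.
// ---------------------------------------------------------------------------
static void grad_axis(const double* src, double* dst, int nx, int ny, int nz,
                      int axis) {
  int n[3] = {nx, ny, nz};
  long stride[3] = {1, nx, (long)nx * ny};
  int na = n[axis];
  long sa = stride[axis];
  int b1 = axis == 0 ? 1 : 0, b2 = axis == 2 ? 1 : 2;
  for (int k = 0; k < n[b2]; ++k)
    for (int j = 0; j < n[b1]; ++j) {
      long base = stride[b1] * j + stride[b2] * k;
      if (na == 1) {
        dst[base] = 0.0;
        continue;
      }
      dst[base] = src[base + sa] - src[base];
      dst[base + sa * (na - 1)] =
          src[base + sa * (na - 1)] - src[base + sa * (na - 2)];
      for (int i = 1; i < na - 1; ++i)
        dst[base + sa * i] =
            0.5 * (src[base + sa * (i + 1)] - src[base + sa * (i - 1)]);
    }
}

// div(g * grad(phi)) with the same scheme
static void ewdiv_impl(const double* phi, const double* g, double* out,
                       int nx, int ny, int nz,
                       std::vector<double>& t1, std::vector<double>& t2) {
  size_t n = (size_t)nx * ny * nz;
  std::fill(out, out + n, 0.0);
  for (int axis = 0; axis < 3; ++axis) {
    grad_axis(phi, t1.data(), nx, ny, nz, axis);
    for (size_t i = 0; i < n; ++i) t1[i] *= g[i];
    grad_axis(t1.data(), t2.data(), nx, ny, nz, axis);
    for (size_t i = 0; i < n; ++i) out[i] += t2[i];
  }
}

// [[Rcpp::export(name = ".ewdiv")]]
NumericVector ewdiv_cpp(NumericVector phi, NumericVector g, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> t1(n), t2(n);
  ewdiv_impl(phi.begin(), g.begin(), out.begin(), nx, ny, nz, t1, t2);
  return out;
}

// [[Rcpp::export(name = ".grad3")]]
List grad3_cpp(NumericVector x, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector gx(n), gy(n), gz(n);
  grad_axis(x.begin(), gx.begin(), nx, ny, nz, 0);
  grad_axis(x.begin(), gy.begin(), nx, ny, nz, 1);
  grad_axis(x.begin(), gz.begin(), nx, ny, nz, 2);
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

static inline double dirac_eps(double s, double eps) {
  return M_1_PI * eps / (eps * eps + s * s);
}

// ---------------------------------------------------------------------------
// Hybrid level-set evolution. Per iteration:
//   1. reinitialize phi to a signed distance field
//   2/3. region force delta_eps(phi) * (V - mu)       (mu precomputed)
//   4. phi' = phi + dt*alpha*force
//   5. reinitialize phi'
//   6. phi  = phi' + dt*beta*delta_eps(.)*div(g grad .)
// With strict_steps the Dirac weight and gradient in step 6 are evaluated on
// the step-1 field rather than the freshly reinitialized step-5 field.
// Stops when the inside/outside labelling changes at <= tol voxels for 3
// consecutive iterations. status: 0 converged, 1 max_iters, 2 degenerate
// interface, 3 non-finite values (iter = offending iteration, 1-based).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".evolve_loop")]]
List evolve_loop_cpp(NumericVector phi0, NumericVector V, NumericVector mu,
                     NumericVector g, IntegerVector dims, double dt,
                     double alpha, double beta, double eps, int max_iters,
                     int tol_voxels, bool strict_steps, bool record_phi) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> phi1(n), divg(n), t1(n), t2(n);
  std::vector<int> prev(n);
  for (size_t i = 0; i < n; ++i) prev[i] = phi[i] >= 0;

  NumericMatrix trace(max_iters, 4);  // iter, interior, changed, band mean |V-mu|
  List snapshots(record_phi ? max_iters : 0);
  int status = 1, done = 0, streak = 0;

  for (int it = 1; it <= max_iters; ++it) {
    // step 1: reinitialize
    size_t npos = 0;
    for (size_t i = 0; i < n; ++i) npos += phi[i] >= 0;
    if (npos == 0 || npos == n) { status = 2; done = it; break; }
    signed_edt_impl(phi.data(), t1.data(), nx, ny, nz);
    std::swap(phi, t1);

    // steps 3-4: region update
    for (size_t i = 0; i < n; ++i)
      phi1[i] = phi[i] + dt * alpha * dirac_eps(phi[i], eps) * (V[i] - mu[i]);

    // step 5: reinitialize
    npos = 0;
    for (size_t i = 0; i < n; ++i) npos += phi1[i] >= 0;
    if (npos == 0 || npos == n) { status = 2; done = it; break; }
    signed_edt_impl(phi1.data(), t1.data(), nx, ny, nz);
    std::swap(phi1, t1);

    // step 6: edge (geodesic) update
    const double* base = strict_steps ? phi.data() : phi1.data();
    ewdiv_impl(base, g.begin(), divg.data(), nx, ny, nz, t1, t2);
    bool finite = true;
    for (size_t i = 0; i < n; ++i) {
      phi[i] = phi1[i] + dt * beta * dirac_eps(base[i], eps) * divg[i];
      if (!std::isfinite(phi[i])) finite = false;
    }
    if (!finite) { status = 3; done = it; break; }

    // bookkeeping
    size_t interior = 0, changed = 0, nband = 0;
    double band_sum = 0.0;
    for (size_t i = 0; i < n; ++i) {
      int m = phi[i] >= 0;
      interior += m;
      changed += (m != prev[i]);
      prev[i] = m;
      if (std::fabs(phi1[i]) <= 1.5) {
        band_sum += std::fabs(V[i] - mu[i]);
        ++nband;
      }
    }
    trace(it - 1, 0) = it;
    trace(it - 1, 1) = (double)interior;
    trace(it - 1, 2) = (double)changed;
    trace(it - 1, 3) = nband ? band_sum / nband : NA_REAL;
    if (record_phi) {
      NumericVector snap(n);
      std::copy(phi.begin(), phi.end(), snap.begin());
      snapshots[it - 1] = snap;
    }
    done = it;
    streak = (changed <= (size_t)tol_voxels) ? streak + 1 : 0;
    if (streak >= 3) { status = 0; break; }
  }

  NumericVector phi_out(n);
  std::copy(phi.begin(), phi.end(), phi_out.begin());
  return List::create(_["phi"] = phi_out, _["trace"] = trace,
                      _["status"] = status, _["iters"] = done,
                      _["snapshots"] = snapshots);
}
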