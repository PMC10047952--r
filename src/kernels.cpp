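#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Dense 3D tensors follow R's column-major layout with dimensions
// (nx, ny, nz, channels, batch). Convolutions are "valid" (no padding),
// stride 1; pooling is non-overlapping (stride == window).

static void get_dims5(const NumericVector& a, int d[5]) {
  IntegerVector dim = a.attr("dim");
  if (dim.size() != 5) stop("expected a 5-d array (x, y, z, channel, batch)");
  for (int i = 0; i < 5; ++i) d[i] = dim[i];
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int xd[5], wd[5];
  get_dims5(x, xd);
  get_dims5(w, wd);
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3], nb = xd[4];
  const int kx = wd[0], ky = wd[1], kz = wd[2], co = wd[4];
  if (wd[3] != ci) stop("kernel input channels do not match input");
  const int ox = nx - kx + 1, oy = ny - ky + 1, oz = nz - kz + 1;
  if (ox < 1 || oy < 1 || oz < 1) stop("kernel larger than input");

  NumericVector y(static_cast<R_xlen_t>(ox) * oy * oz * co * nb);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  double* yp = REAL(y);

  const R_xlen_t xsc = static_cast<R_xlen_t>(nx) * ny * nz;
  const R_xlen_t xsn = xsc * ci;
  const R_xlen_t ysc = static_cast<R_xlen_t>(ox) * oy * oz;
  const R_xlen_t ysn = ysc * co;

  for (int n = 0; n < nb; ++n) {
    for (int c = 0; c < co; ++c) {
      double* yc = yp + n * ysn + c * ysc;
      const double bias = b[c];
      for (R_xlen_t i = 0; i < ysc; ++i) yc[i] = bias;
      for (int ic = 0; ic < ci; ++ic) {
        const double* xc = xp + n * xsn + ic * xsc;
        for (int dz = 0; dz < kz; ++dz)
          for (int dy = 0; dy < ky; ++dy)
            for (int dx = 0; dx < kx; ++dx) {
              const double wv =
                  wp[dx + kx * (dy + ky * (dz + kz * (ic + ci * c)))];
              if (wv == 0.0) continue;
              for (int z = 0; z < oz; ++z)
                for (int yy = 0; yy < oy; ++yy) {
                  const double* xr = xc + dx + static_cast<R_xlen_t>(nx) * (yy + dy) +
                                     static_cast<R_xlen_t>(nx) * ny * (z + dz);
                  double* yr = yc + static_cast<R_xlen_t>(ox) * (yy + oy * z);
                  for (int xx = 0; xx < ox; ++xx) yr[xx] += wv * xr[xx];
                }
            }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, co, nb);
  return y;
}

// Gradients of the valid 3D convolution. Returns dx, dw, db.
// need_dx = false skips the input gradient (first layer of a network).
// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                bool need_dx = true) {
  int xd[5], wd[5], yd[5];
  get_dims5(x, xd);
  get_dims5(w, wd);
  get_dims5(dy, yd);
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3], nb = xd[4];
  const int kx = wd[0], ky = wd[1], kz = wd[2], co = wd[4];
  const int ox = yd[0], oy = yd[1], oz = yd[2];

  NumericVector dx(need_dx ? x.size() : R_xlen_t(0));
  NumericVector dw(w.size());
  NumericVector db(co);
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  double* dwp = REAL(dw);

  const R_xlen_t xsc = static_cast<R_xlen_t>(nx) * ny * nz;
  const R_xlen_t xsn = xsc * ci;
  const R_xlen_t ysc = static_cast<R_xlen_t>(ox) * oy * oz;
  const R_xlen_t ysn = ysc * co;

  for (int n = 0; n < nb; ++n) {
    for (int c = 0; c < co; ++c) {
      const double* gc = dyp + n * ysn + c * ysc;
      double acc = 0.0;
      for (R_xlen_t i = 0; i < ysc; ++i) acc += gc[i];
      db[c] += acc;
      for (int ic = 0; ic < ci; ++ic) {
        const double* xc = xp + n * xsn + ic * xsc;
        double* dxc = dxp + n * xsn + ic * xsc;
        for (int dz = 0; dz < kz; ++dz)
          for (int dyk = 0; dyk < ky; ++dyk)
            for (int dxk = 0; dxk < kx; ++dxk) {
              const R_xlen_t wi =
                  dxk + kx * (dyk + ky * (dz + kz * (ic + ci * c)));
              const double wv = wp[wi];
              double wacc = 0.0;
              for (int z = 0; z < oz; ++z)
                for (int yy = 0; yy < oy; ++yy) {
                  const R_xlen_t xoff = dxk + static_cast<R_xlen_t>(nx) * (yy + dyk) +
                                        static_cast<R_xlen_t>(nx) * ny * (z + dz);
                  const double* xr = xc + xoff;
                  const double* gr = gc + static_cast<R_xlen_t>(ox) * (yy + oy * z);
                  if (need_dx) {
                    double* dxr = dxc + xoff;
                    for (int xx = 0; xx < ox; ++xx) {
                      dxr[xx] += wv * gr[xx];
                      wacc += xr[xx] * gr[xx];
                    }
                  } else {
                    for (int xx = 0; xx < ox; ++xx) wacc += xr[xx] * gr[xx];
                  }
                }
              dwp[wi] += wacc;
            }
      }
    }
  }
  if (need_dx) dx.attr("dim") = x.attr("dim");
  dw.attr("dim") = w.attr("dim");
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Non-overlapping max pooling; argmax is a 1-based index into the
// flattened input so the backward pass is a plain scatter in R.
// [[Rcpp::export(name = ".maxpool3d_fwd")]]
List maxpool3d_fwd(NumericVector x, int pool) {
  int xd[5];
  get_dims5(x, xd);
  const int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3], nb = xd[4];
  const int ox = nx / pool, oy = ny / pool, oz = nz / pool;
  if (ox < 1 || oy < 1 || oz < 1) stop("pooling window larger than input");

  const R_xlen_t ylen = static_cast<R_xlen_t>(ox) * oy * oz * nc * nb;
  NumericVector y(ylen);
  IntegerVector arg(ylen);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ap = INTEGER(arg);

  R_xlen_t j = 0;
  for (int n = 0; n < nb; ++n)
    for (int c = 0; c < nc; ++c) {
      const R_xlen_t base = (static_cast<R_xlen_t>(n) * nc + c) *
                            (static_cast<R_xlen_t>(nx) * ny * nz);
      for (int z = 0; z < oz; ++z)
        for (int yy = 0; yy < oy; ++yy)
          for (int xx = 0; xx < ox; ++xx) {
            double best = R_NegInf;
            R_xlen_t besti = 0;
            for (int pz = 0; pz < pool; ++pz)
              for (int py = 0; py < pool; ++py)
                for (int px = 0; px < pool; ++px) {
                  const R_xlen_t xi =
                      base + (xx * pool + px) +
                      static_cast<R_xlen_t>(nx) * ((yy * pool + py) +
                      static_cast<R_xlen_t>(ny) * ((z * pool + pz)));
                  const double v = xp[xi];
                  if (v > best) { best = v; besti = xi; }
                }
            yp[j] = best;
            ap[j] = static_cast<int>(besti + 1);
            ++j;
          }
    }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc, nb);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// 6-connected component labelling of a logical 3D mask.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("expected a 3-d mask");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector lab(n, 0);
  const int* mp = LOGICAL(mask);
  int* lp = INTEGER(lab);

  int current = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mp[s] != TRUE || lp[s] != 0) continue;
    ++current;
    stack.push_back(s);
    lp[s] = current;
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int x = static_cast<int>(v % nx);
      const int y = static_cast<int>((v / nx) % ny);
      const int z = static_cast<int>(v / (static_cast<R_xlen_t>(nx) * ny));
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t u = xx + static_cast<R_xlen_t>(nx) * (yy + static_cast<R_xlen_t>(ny) * zz);
        if (mp[u] == TRUE && lp[u] == 0) {
          lp[u] = current;
          stack.push_back(u);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
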