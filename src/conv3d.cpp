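// Hot loops of the 3D convolution layers: im2col gathers plus BLAS matrix
// products via Armadillo.
//
// Tensors arrive as flat numeric vectors in R's column-major layout with
// axis order (n, z, y, x, c). Weights W are (E*cin) x cout matrices whose
// rows are grouped kernel-offset-major (cin rows per offset; offsets
// enumerated dz fastest, then dy, then dx). Zero padding of (k-1)/2 per
// axis; strides (sz, sy, sx).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct ConvGeom {
  int n, Z, Y, X, cin, kz, ky, kx, sz, sy, sx, pz, py, px, Zo, Yo, Xo, E;
  long long R;
};

static ConvGeom geom(const IntegerVector &dims, const IntegerVector &kernel,
                     const IntegerVector &stride) {
  ConvGeom g;
  g.n = dims[0]; g.Z = dims[1]; g.Y = dims[2]; g.X = dims[3]; g.cin = dims[4];
  g.kz = kernel[0]; g.ky = kernel[1]; g.kx = kernel[2];
  g.sz = stride[0]; g.sy = stride[1]; g.sx = stride[2];
  g.pz = (g.kz - 1) / 2; g.py = (g.ky - 1) / 2; g.px = (g.kx - 1) / 2;
  g.Zo = (g.Z + 2 * g.pz - g.kz) / g.sz + 1;
  g.Yo = (g.Y + 2 * g.py - g.ky) / g.sy + 1;
  g.Xo = (g.X + 2 * g.px - g.kx) / g.sx + 1;
  g.E = g.kz * g.ky * g.kx;
  g.R = (long long)g.n * g.Zo * g.Yo * g.Xo;
  return g;
}

// Gather the im2col matrix (R x E*cin); rows ordered (n,zo,yo,xo)
// column-major, column blocks kernel-offset-major with cin columns each.
static arma::mat im2col(const double *xp, const ConvGeom &g) {
  arma::mat Xcol(g.R, (size_t)g.E * g.cin, arma::fill::zeros);
  const long long cstep = (long long)g.n * g.Z * g.Y * g.X;
  for (int dxk = 0; dxk < g.kx; ++dxk)
    for (int dyk = 0; dyk < g.ky; ++dyk)
      for (int dzk = 0; dzk < g.kz; ++dzk) {
        const int e = dzk + g.kz * (dyk + g.ky * dxk);
        for (int ci = 0; ci < g.cin; ++ci) {
          double *col = Xcol.colptr((size_t)e * g.cin + ci);
          const double *xc = xp + cstep * ci;
          long long r = 0;
          for (int xo = 0; xo < g.Xo; ++xo) {
            const int xi = xo * g.sx + dxk - g.px;
            for (int yo = 0; yo < g.Yo; ++yo) {
              const int yi = yo * g.sy + dyk - g.py;
              for (int zo = 0; zo < g.Zo; ++zo) {
                const int zi = zo * g.sz + dzk - g.pz;
                if (zi < 0 || zi >= g.Z || yi < 0 || yi >= g.Y ||
                    xi < 0 || xi >= g.X) {
                  r += g.n;
                  continue;
                }
                const double *src = xc + (long long)g.n *
                  (zi + (long long)g.Z * (yi + (long long)g.Y * xi));
                std::copy(src, src + g.n, col + r);
                r += g.n;
              }
            }
          }
        }
      }
  return Xcol;
}

// [[Rcpp::export]]
List conv3d_forward_cpp(NumericVector x, IntegerVector dims,
                        NumericMatrix W, NumericVector b,
                        IntegerVector kernel, IntegerVector stride,
                        bool want_xcol) {
  ConvGeom g = geom(dims, kernel, stride);
  const int cout = W.ncol();
  arma::mat Xcol = im2col(x.begin(), g);
  arma::mat Wm(W.begin(), W.nrow(), cout, false);
  arma::mat out = Xcol * Wm;
  for (int co = 0; co < cout; ++co) out.col(co) += b[co];
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(g.n, g.Zo, g.Yo, g.Xo, cout);
  if (!want_xcol) return List::create(_["out"] = res);
  NumericMatrix Xr(Xcol.n_rows, Xcol.n_cols, Xcol.begin());
  return List::create(_["out"] = res, _["Xcol"] = Xr);
}

// [[Rcpp::export]]
List conv3d_backward_cpp(NumericVector x, IntegerVector dims,
                         NumericMatrix W, NumericVector dout,
                         IntegerVector kernel, IntegerVector stride,
                         Nullable<NumericMatrix> xcol_cache) {
  ConvGeom g = geom(dims, kernel, stride);
  const int cout = W.ncol();
  arma::mat Xcol;
  if (xcol_cache.isNotNull()) {
    NumericMatrix Xr(xcol_cache.get());
    Xcol = arma::mat(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  } else {
    Xcol = im2col(x.begin(), g);
  }
  arma::mat Wm(W.begin(), W.nrow(), cout, false);
  arma::mat dmat(dout.begin(), g.R, cout, false);
  arma::mat dW = Xcol.t() * dmat;
  arma::rowvec db = arma::sum(dmat, 0);
  arma::mat dXcol = dmat * Wm.t(); // R x E*cin
  // scatter-add back to input layout (adjoint of im2col)
  NumericVector dx((long long)g.n * g.Z * g.Y * g.X * g.cin);
  double *dxp = dx.begin();
  const long long cstep = (long long)g.n * g.Z * g.Y * g.X;
  for (int dxk = 0; dxk < g.kx; ++dxk)
    for (int dyk = 0; dyk < g.ky; ++dyk)
      for (int dzk = 0; dzk < g.kz; ++dzk) {
        const int e = dzk + g.kz * (dyk + g.ky * dxk);
        for (int ci = 0; ci < g.cin; ++ci) {
          const double *col = dXcol.colptr((size_t)e * g.cin + ci);
          double *dxc = dxp + cstep * ci;
          long long r = 0;
          for (int xo = 0; xo < g.Xo; ++xo) {
            const int xi = xo * g.sx + dxk - g.px;
            for (int yo = 0; yo < g.Yo; ++yo) {
              const int yi = yo * g.sy + dyk - g.py;
              for (int zo = 0; zo < g.Zo; ++zo) {
                const int zi = zo * g.sz + dzk - g.pz;
                if (zi < 0 || zi >= g.Z || yi < 0 || yi >= g.Y ||
                    xi < 0 || xi >= g.X) {
                  r += g.n;
                  continue;
                }
                double *dst = dxc + (long long)g.n *
                  (zi + (long long)g.Z * (yi + (long long)g.Y * xi));
                const double *src = col + r;
                for (int ni = 0; ni < g.n; ++ni) dst[ni] += src[ni];
                r += g.n;
              }
            }
          }
        }
      }
  dx.attr("dim") = IntegerVector::create(g.n, g.Z, g.Y, g.X, g.cin);
  NumericMatrix dWr(dW.n_rows, dW.n_cols, dW.begin());
  NumericVector dbr(db.begin(), db.end());
  return List::create(_["dx"] = dx, _["dW"] = dWr, _["db"] = dbr);
}
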