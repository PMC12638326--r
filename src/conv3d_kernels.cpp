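// Low-level tensor kernels for the 3D convolutional age-regression network.
//
// Feature maps are stored channel-first as a C x (V * N) matrix, where
// V = d1*d2*d3 voxels in column-major spatial order (x fastest) and the
// column index is (n * V + v) for sample n.  Convolution is realised as
// im2col + GEMM on the R side; these kernels supply the gather/scatter
// halves and 2x2x2 max pooling with argmax bookkeeping for backprop.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int pooled_dim(int d) {
  // floor halving, but a singleton axis is passed through untouched
  return d > 1 ? d / 2 : 1;
}

// Gather 3x3x3 neighbourhoods (zero padding 1) into a (27*C) x (V*N) matrix.
// Row block o*C..(o+1)*C-1 holds the channels for kernel offset o, with
// o = ox + 3*(oy + 3*oz), offsets in {-1,0,1}^3.
// [[Rcpp::export]]
arma::mat cpp_im2col3(const arma::mat& x, const IntegerVector& dims) {
  const int C = dims[0], d1 = dims[1], d2 = dims[2], d3 = dims[3], N = dims[4];
  const arma::uword V = (arma::uword)d1 * d2 * d3;
  if (x.n_rows != (arma::uword)C || x.n_cols != V * N)
    stop("im2col: input matrix does not match dims");
  arma::mat cols(27 * (arma::uword)C, V * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const arma::uword base = (arma::uword)n * V;
    for (int oz = -1; oz <= 1; ++oz) {
      for (int oy = -1; oy <= 1; ++oy) {
        for (int ox = -1; ox <= 1; ++ox) {
          const int o = (ox + 1) + 3 * ((oy + 1) + 3 * (oz + 1));
          const arma::uword r0 = (arma::uword)o * C;
          for (int z = 0; z < d3; ++z) {
            const int zs = z + oz;
            if (zs < 0 || zs >= d3) continue;
            for (int y = 0; y < d2; ++y) {
              const int ys = y + oy;
              if (ys < 0 || ys >= d2) continue;
              // contiguous run over x
              const int x0 = (ox < 0) ? 1 : 0;
              const int x1 = (ox > 0) ? d1 - 1 : d1;
              if (x1 <= x0) continue;
              for (int xx = x0; xx < x1; ++xx) {
                const arma::uword vdst = base + (arma::uword)xx + (arma::uword)d1 * (y + (arma::uword)d2 * z);
                const arma::uword vsrc = base + (arma::uword)(xx + ox) + (arma::uword)d1 * (ys + (arma::uword)d2 * zs);
                std::memcpy(cols.colptr(vdst) + r0, x.colptr(vsrc), sizeof(double) * C);
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add the transpose of im2col: given gradients w.r.t. the column
// matrix, accumulate gradients w.r.t. the input feature map.
// [[Rcpp::export]]
arma::mat cpp_col2im3(const arma::mat& cols, const IntegerVector& dims) {
  const int C = dims[0], d1 = dims[1], d2 = dims[2], d3 = dims[3], N = dims[4];
  const arma::uword V = (arma::uword)d1 * d2 * d3;
  if (cols.n_rows != 27 * (arma::uword)C || cols.n_cols != V * N)
    stop("col2im: column matrix does not match dims");
  arma::mat x(C, V * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const arma::uword base = (arma::uword)n * V;
    for (int oz = -1; oz <= 1; ++oz) {
      for (int oy = -1; oy <= 1; ++oy) {
        for (int ox = -1; ox <= 1; ++ox) {
          const int o = (ox + 1) + 3 * ((oy + 1) + 3 * (oz + 1));
          const arma::uword r0 = (arma::uword)o * C;
          for (int z = 0; z < d3; ++z) {
            const int zs = z + oz;
            if (zs < 0 || zs >= d3) continue;
            for (int y = 0; y < d2; ++y) {
              const int ys = y + oy;
              if (ys < 0 || ys >= d2) continue;
              const int x0 = (ox < 0) ? 1 : 0;
              const int x1 = (ox > 0) ? d1 - 1 : d1;
              for (int xx = x0; xx < x1; ++xx) {
                const arma::uword vdst = base + (arma::uword)xx + (arma::uword)d1 * (y + (arma::uword)d2 * z);
                const arma::uword vsrc = base + (arma::uword)(xx + ox) + (arma::uword)d1 * (ys + (arma::uword)d2 * zs);
                double* dst = x.colptr(vsrc);
                const double* src = cols.colptr(vdst) + r0;
                for (int c = 0; c < C; ++c) dst[c] += src[c];
              }
            }
          }
        }
      }
    }
  }
  return x;
}

// 2x2x2 max pooling, stride 2, floor division (trailing odd slices dropped);
// singleton axes pass through.  Returns the pooled map and, per entry, the
// 1-based linear index (into the flattened input matrix) of the argmax, for
// the backward pass.
// [[Rcpp::export]]
List cpp_maxpool3(const arma::mat& x, const IntegerVector& dims) {
  const int C = dims[0], d1 = dims[1], d2 = dims[2], d3 = dims[3], N = dims[4];
  const arma::uword V = (arma::uword)d1 * d2 * d3;
  if (x.n_rows != (arma::uword)C || x.n_cols != V * N)
    stop("maxpool: input matrix does not match dims");
  const int p1 = pooled_dim(d1), p2 = pooled_dim(d2), p3 = pooled_dim(d3);
  const arma::uword Vp = (arma::uword)p1 * p2 * p3;
  arma::mat out(C, Vp * N);
  arma::umat idx(C, Vp * N);
  const int w1 = d1 > 1 ? 2 : 1, w2 = d2 > 1 ? 2 : 1, w3 = d3 > 1 ? 2 : 1;
  for (int n = 0; n < N; ++n) {
    const arma::uword ibase = (arma::uword)n * V;
    const arma::uword obase = (arma::uword)n * Vp;
    for (int z = 0; z < p3; ++z) {
      for (int y = 0; y < p2; ++y) {
        for (int xx = 0; xx < p1; ++xx) {
          const arma::uword ocol = obase + (arma::uword)xx + (arma::uword)p1 * (y + (arma::uword)p2 * z);
          for (int c = 0; c < C; ++c) {
            double best = -std::numeric_limits<double>::infinity();
            arma::uword bestlin = 0;
            for (int kz = 0; kz < w3; ++kz)
              for (int ky = 0; ky < w2; ++ky)
                for (int kx = 0; kx < w1; ++kx) {
                  const arma::uword icol = ibase +
                    (arma::uword)(w1 * xx + kx) +
                    (arma::uword)d1 * ((w2 * y + ky) + (arma::uword)d2 * (w3 * z + kz));
                  const double v = x(c, icol);
                  if (v > best) { best = v; bestlin = (arma::uword)c + (arma::uword)C * icol; }
                }
            out(c, ocol) = best;
            idx(c, ocol) = bestlin + 1;  // 1-based for R
          }
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx,
                      _["dims"] = IntegerVector::create(C, p1, p2, p3, N));
}

// Route pooled gradients back to the argmax voxels.
// [[Rcpp::export]]
arma::mat cpp_maxpool3_bwd(const arma::mat& dout, const arma::umat& idx,
                           const IntegerVector& dims_in) {
  const int C = dims_in[0];
  const arma::uword V = (arma::uword)dims_in[1] * dims_in[2] * dims_in[3];
  const int N = dims_in[4];
  arma::mat dx(C, V * (arma::uword)N, arma::fill::zeros);
  double* px = dx.memptr();
  const double* pd = dout.memptr();
  const arma::uword* pi = idx.memptr();
  const arma::uword M = dout.n_elem;
  for (arma::uword i = 0; i < M; ++i) px[pi[i] - 1] += pd[i];
  return dx;
}
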