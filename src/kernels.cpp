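#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Tensors are R arrays in column-major order.
// Volumes/feature maps: dim = (X, Y, Z, C); conv weights: dim = (k, k, k, Cin, Cout).

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// valid output range [lo, hi) for one kernel tap: 0 <= o*stride + t - pad < N
static inline void tap_range(int t, int stride, int pad, int N, int No,
                             int &lo, int &hi) {
  lo = 0;
  while (lo < No && lo * stride + t - pad < 0) ++lo;
  hi = No;
  while (hi > lo && (hi - 1) * stride + t - pad >= N) --hi;
}

// One contiguous-x pass per (channel pair, kernel tap): the inner loops are
// branch-free and unit-stride for stride 1, which is what the training
// patches use almost everywhere.
// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector xd,
                            NumericVector w, IntegerVector wd,
                            NumericVector bias, int stride, int pad) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3];
  const int k = wd[0], Cout = wd[4];
  const int Xo = out_dim(X, k, stride, pad);
  const int Yo = out_dim(Y, k, stride, pad);
  const int Zo = out_dim(Z, k, stride, pad);
  NumericVector y(static_cast<R_xlen_t>(Xo) * Yo * Zo * Cout);
  const double *px = x.begin(), *pw = w.begin(), *pb = bias.begin();
  double *py = y.begin();
  const R_xlen_t xcs = static_cast<R_xlen_t>(X) * Y * Z;
  const R_xlen_t ycs = static_cast<R_xlen_t>(Xo) * Yo * Zo;
  const R_xlen_t wk3 = static_cast<R_xlen_t>(k) * k * k;
  int xlo, xhi, ylo, yhi, zlo, zhi;
  for (int co = 0; co < Cout; ++co) {
    double *yc = py + co * ycs;
    const double b = pb[co];
    for (R_xlen_t i = 0; i < ycs; ++i) yc[i] = b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = px + ci * xcs;
      const double *wci = pw + (co * static_cast<R_xlen_t>(Cin) + ci) * wk3;
      for (int kz = 0; kz < k; ++kz) {
        tap_range(kz, stride, pad, Z, Zo, zlo, zhi);
        for (int ky = 0; ky < k; ++ky) {
          tap_range(ky, stride, pad, Y, Yo, ylo, yhi);
          for (int kx = 0; kx < k; ++kx) {
            tap_range(kx, stride, pad, X, Xo, xlo, xhi);
            const double wv = wci[kx + k * (ky + k * kz)];
            if (wv == 0.0 || xhi <= xlo) continue;
            for (int zo = zlo; zo < zhi; ++zo) {
              const int zi = zo * stride + kz - pad;
              for (int yo = ylo; yo < yhi; ++yo) {
                const int yi = yo * stride + ky - pad;
                double *yrow = yc + Xo * (yo + static_cast<R_xlen_t>(Yo) * zo);
                const double *xrow = xc + X * (yi + static_cast<R_xlen_t>(Y) * zi)
                                     + (xlo * stride + kx - pad);
                if (stride == 1) {
                  for (int xo = xlo; xo < xhi; ++xo)
                    yrow[xo] += wv * xrow[xo - xlo];
                } else {
                  for (int xo = xlo; xo < xhi; ++xo)
                    yrow[xo] += wv * xrow[(xo - xlo) * stride];
                }
              }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector xd,
                   NumericVector w, IntegerVector wd,
                   NumericVector gy, int stride, int pad) {
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3];
  const int k = wd[0], Cout = wd[4];
  const int Xo = out_dim(X, k, stride, pad);
  const int Yo = out_dim(Y, k, stride, pad);
  const int Zo = out_dim(Z, k, stride, pad);
  NumericVector gx(x.size());
  NumericVector gw(w.size());
  NumericVector gb(Cout);
  const double *px = x.begin(), *pw = w.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  const R_xlen_t xcs = static_cast<R_xlen_t>(X) * Y * Z;
  const R_xlen_t ycs = static_cast<R_xlen_t>(Xo) * Yo * Zo;
  const R_xlen_t wk3 = static_cast<R_xlen_t>(k) * k * k;
  int xlo, xhi, ylo, yhi, zlo, zhi;
  for (int co = 0; co < Cout; ++co) {
    const double *gyc = pgy + co * ycs;
    double acc_b = 0.0;
    for (R_xlen_t i = 0; i < ycs; ++i) acc_b += gyc[i];
    pgb[co] = acc_b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *xc = px + ci * xcs;
      double *gxc = pgx + ci * xcs;
      const double *wci = pw + (co * static_cast<R_xlen_t>(Cin) + ci) * wk3;
      double *gwci = pgw + (co * static_cast<R_xlen_t>(Cin) + ci) * wk3;
      for (int kz = 0; kz < k; ++kz) {
        tap_range(kz, stride, pad, Z, Zo, zlo, zhi);
        for (int ky = 0; ky < k; ++ky) {
          tap_range(ky, stride, pad, Y, Yo, ylo, yhi);
          for (int kx = 0; kx < k; ++kx) {
            tap_range(kx, stride, pad, X, Xo, xlo, xhi);
            if (xhi <= xlo) continue;
            const double wv = wci[kx + k * (ky + k * kz)];
            double acc_w = 0.0;
            for (int zo = zlo; zo < zhi; ++zo) {
              const int zi = zo * stride + kz - pad;
              for (int yo = ylo; yo < yhi; ++yo) {
                const int yi = yo * stride + ky - pad;
                const double *grow = gyc + Xo * (yo + static_cast<R_xlen_t>(Yo) * zo);
                const R_xlen_t xoff = X * (yi + static_cast<R_xlen_t>(Y) * zi)
                                      + (xlo * stride + kx - pad);
                const double *xrow = xc + xoff;
                double *gxrow = gxc + xoff;
                if (stride == 1) {
                  for (int xo = xlo; xo < xhi; ++xo) {
                    const double g = grow[xo];
                    acc_w += g * xrow[xo - xlo];
                    gxrow[xo - xlo] += wv * g;
                  }
                } else {
                  for (int xo = xlo; xo < xhi; ++xo) {
                    const double g = grow[xo];
                    acc_w += g * xrow[(xo - xlo) * stride];
                    gxrow[(xo - xlo) * stride] += wv * g;
                  }
                }
              }
            }
            gwci[kx + k * (ky + k * kz)] += acc_w;
          }
        }
      }
    }
  }
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Directed Hausdorff: max over a in A of min over b in B of ||a-b||.
static double directed_hd(const NumericMatrix &A, const NumericMatrix &B) {
  const int na = A.nrow(), nb = B.nrow();
  double worst = 0.0;
  for (int i = 0; i < na; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        if (best <= worst) break; // cannot raise the running maximum
      }
    }
    if (best > worst) worst = best;
  }
  return std::sqrt(worst);
}

// [[Rcpp::export]]
double cpp_hausdorff(NumericMatrix A, NumericMatrix B) {
  const double dab = directed_hd(A, B);
  const double dba = directed_hd(B, A);
  return dab > dba ? dab : dba;
}

// 6-connected component labelling of a binary 3D mask.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector d) {
  const int X = d[0], Y = d[1], Z = d[2];
  const R_xlen_t n = static_cast<R_xlen_t>(X) * Y * Z;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int x = v % X;
      const int y = (v / X) % Y;
      const int z = v / (static_cast<R_xlen_t>(X) * Y);
      const int nx[6] = {x - 1, x + 1, x, x, x, x};
      const int ny[6] = {y, y, y - 1, y + 1, y, y};
      const int nz[6] = {z, z, z, z, z - 1, z + 1};
      for (int t = 0; t < 6; ++t) {
        if (nx[t] < 0 || nx[t] >= X || ny[t] < 0 || ny[t] >= Y || nz[t] < 0 || nz[t] >= Z)
          continue;
        const R_xlen_t u = nx[t] + static_cast<R_xlen_t>(X) * (ny[t] + static_cast<R_xlen_t>(Y) * nz[t]);
        if (mask[u] && lab[u] == 0) {
          lab[u] = next;
          stack.push_back(u);
        }
      }
    }
  }
  lab.attr("dim") = d;
  return lab;
}
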