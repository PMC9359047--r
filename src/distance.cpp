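#include <Rcpp.h>
#include <vector>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// 1D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher)
// on samples at positions i*h, i = 0..n-1. f holds input costs (0 at sites,
// BIG elsewhere); d receives min_q ((x_p - x_q)^2 + f[q]).
static void dt1d(const std::vector<double>& f, double h, int n,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& z) {
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; q++) {
        double xq = q * h;
        double s;
        for (;;) {
            double xv = v[k] * h;
            s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
            if (s <= z[k]) k--; else break;
        }
        k++;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        double xq = q * h;
        while (z[k + 1] < xq) k++;
        double dx = xq - v[k] * h;
        d[q] = dx * dx + f[v[k]];
    }
}

// squared Euclidean distance (mm^2) from every voxel center to the nearest
// TRUE voxel center, on an anisotropic grid. Voxels farther than ~1e15 mm
// (no site at all) come back astronomically large; the caller guards.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
    const double BIG = 1e30;
    int n1 = dims[0], n2 = dims[1], n3 = dims[2];
    R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : BIG;

    int nmax = std::max(n1, std::max(n2, n3));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // axis 1 (fastest varying)
    for (int k = 0; k < n3; k++)
        for (int j = 0; j < n2; j++) {
            R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
            for (int i = 0; i < n1; i++) f[i] = out[base + i];
            dt1d(f, spacing[0], n1, d, v, z);
            for (int i = 0; i < n1; i++) out[base + i] = d[i];
        }
    // axis 2
    for (int k = 0; k < n3; k++)
        for (int i = 0; i < n1; i++) {
            R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
            for (int j = 0; j < n2; j++) f[j] = out[base + (R_xlen_t)j * n1];
            dt1d(f, spacing[1], n2, d, v, z);
            for (int j = 0; j < n2; j++) out[base + (R_xlen_t)j * n1] = d[j];
        }
    // axis 3
    R_xlen_t plane = (R_xlen_t)n1 * n2;
    for (int j = 0; j < n2; j++)
        for (int i = 0; i < n1; i++) {
            R_xlen_t base = (R_xlen_t)j * n1 + i;
            for (int k = 0; k < n3; k++) f[k] = out[base + (R_xlen_t)k * plane];
            dt1d(f, spacing[2], n3, d, v, z);
            for (int k = 0; k < n3; k++) out[base + (R_xlen_t)k * plane] = d[k];
        }
    return out;
}
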