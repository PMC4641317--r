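#include <Rcpp.h>
#include <vector>
#include <cmath>

// Exact Euclidean distance transform on a regular 3-D grid with
// anisotropic spacing, via the separable lower-envelope-of-parabolas
// algorithm (Felzenszwalb & Huttenlocher). Distances are physical (mm):
// the 1-D pass along each axis uses that axis' squared spacing as the
// parabola width, so the composed transform is exact for any spacing.

static const double EDT_INF = 1e30;

// One 1-D squared-distance pass: d[p] = min_q f[q] + h2 * (p - q)^2.
static void dt1d(const double* f, double* d, int n, double h2,
                 std::vector<int>& v, std::vector<double>& z)
{
    int k = 0;
    v[0] = 0;
    z[0] = -EDT_INF;
    z[1] = EDT_INF;
    for (int q = 1; q < n; ++q) {
        double s;
        for (;;) {
            int p = v[k];
            // intersection of parabolas rooted at q and p
            s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) /
                (2.0 * h2 * (q - p));
            if (s <= z[k] && k > 0) { --k; } else break;
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = EDT_INF;
    }
    k = 0;
    for (int p = 0; p < n; ++p) {
        while (z[k + 1] < p) ++k;
        int q = v[k];
        d[p] = f[q] + h2 * (p - q) * (p - q);
    }
}

// [[Rcpp::export]]
Rcpp::NumericVector edt3d_sq(Rcpp::LogicalVector feature,
                             Rcpp::IntegerVector dims,
                             Rcpp::NumericVector spacing)
{
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (feature.size() != n)
        Rcpp::stop("feature length does not match dims");

    Rcpp::NumericVector out(n);
    double* D = REAL(out);
    for (R_xlen_t i = 0; i < n; ++i)
        D[i] = (feature[i] == TRUE) ? 0.0 : EDT_INF;

    const int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x (fastest-varying, column-major)
    double h2 = spacing[0] * spacing[0];
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            double* line = D + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
            dt1d(line, f.data(), nx, h2, v, z);
            std::copy(f.begin(), f.begin() + nx, line);
        }

    // pass along y
    h2 = spacing[1] * spacing[1];
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            double* base = D + i + (R_xlen_t)nx * ny * k;
            for (int j = 0; j < ny; ++j) f[j] = base[(R_xlen_t)nx * j];
            dt1d(f.data(), d.data(), ny, h2, v, z);
            for (int j = 0; j < ny; ++j) base[(R_xlen_t)nx * j] = d[j];
        }

    // pass along z
    h2 = spacing[2] * spacing[2];
    const R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            double* base = D + i + (R_xlen_t)nx * j;
            for (int k = 0; k < nz; ++k) f[k] = base[stride * k];
            dt1d(f.data(), d.data(), nz, h2, v, z);
            for (int k = 0; k < nz; ++k) base[stride * k] = d[k];
        }

    return out;
}
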