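#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exact squared Euclidean distance transform on an anisotropic lattice,
// lower-envelope-of-parabolas method applied separably along each axis.
// Physical coordinate along an axis with spacing s is x_i = i*s.

static const double BIG = 1e30;

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
    if (n == 1) { d[0] = f[0]; return; }
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = 0;
    v[0] = 0;
    z[0] = -BIG;
    z[1] = BIG;
    for (int q = 1; q < n; ++q) {
        double xq = q * s;
        for (;;) {
            double xv = v[k] * s;
            double sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) /
                          (2.0 * xq - 2.0 * xv);
            if (sint <= z[k]) {
                --k;
            } else {
                ++k;
                v[k] = q;
                z[k] = sint;
                z[k + 1] = BIG;
                break;
            }
        }
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * s;
        while (z[k + 1] < xq) ++k;
        double xv = v[k] * s;
        d[q] = (xq - xv) * (xq - xv) + f[v[k]];
    }
}

// Squared distance from every voxel center to the nearest foreground
// voxel center. dim = (d1, d2, d3) in R's column-major layout,
// spacing = physical mm per step along each of the three axes.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector vox, IntegerVector dim,
                         NumericVector spacing) {
    const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
    NumericVector out(n);
    bool any_fg = false;
    for (R_xlen_t i = 0; i < n; ++i) {
        bool fg = vox[i] == TRUE;
        out[i] = fg ? 0.0 : BIG;
        if (fg) any_fg = true;
    }
    if (!any_fg) {
        std::fill(out.begin(), out.end(), R_PosInf);
        return out;
    }
    std::vector<double> f, d;

    // axis 1 (fastest-varying)
    f.resize(d1); d.resize(d1);
    for (int k = 0; k < d3; ++k)
        for (int j = 0; j < d2; ++j) {
            R_xlen_t base = (R_xlen_t)k * d1 * d2 + (R_xlen_t)j * d1;
            for (int i = 0; i < d1; ++i) f[i] = out[base + i];
            dt1d(f, d, d1, spacing[0]);
            for (int i = 0; i < d1; ++i) out[base + i] = d[i];
        }

    // axis 2
    f.resize(d2); d.resize(d2);
    for (int k = 0; k < d3; ++k)
        for (int i = 0; i < d1; ++i) {
            R_xlen_t base = (R_xlen_t)k * d1 * d2 + i;
            for (int j = 0; j < d2; ++j) f[j] = out[base + (R_xlen_t)j * d1];
            dt1d(f, d, d2, spacing[1]);
            for (int j = 0; j < d2; ++j) out[base + (R_xlen_t)j * d1] = d[j];
        }

    // axis 3 (slowest-varying)
    f.resize(d3); d.resize(d3);
    const R_xlen_t plane = (R_xlen_t)d1 * d2;
    for (int j = 0; j < d2; ++j)
        for (int i = 0; i < d1; ++i) {
            R_xlen_t base = (R_xlen_t)j * d1 + i;
            for (int k = 0; k < d3; ++k) f[k] = out[base + (R_xlen_t)k * plane];
            dt1d(f, d, d3, spacing[2]);
            for (int k = 0; k < d3; ++k) out[base + (R_xlen_t)k * plane] = d[k];
        }

    return out;
}

// Connected-component labelling, connectivity 6 or 26.
// Returns integer labels, 0 = background, components numbered from 1
// in first-encounter (column-major scan) order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector vox, IntegerVector dim,
                                   int connectivity) {
    const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
    const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
    IntegerVector lab(n, 0);

    std::vector<int> off1, off2, off3;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (connectivity == 6 && manh != 1) continue;
                off1.push_back(dx);
                off2.push_back(dy);
                off3.push_back(dz);
            }
    const int noff = (int)off1.size();

    std::vector<R_xlen_t> stack;
    int next = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (vox[s] != TRUE || lab[s] != 0) continue;
        ++next;
        lab[s] = next;
        stack.clear();
        stack.push_back(s);
        while (!stack.empty()) {
            R_xlen_t cur = stack.back();
            stack.pop_back();
            int i = (int)(cur % d1);
            int j = (int)((cur / d1) % d2);
            int k = (int)(cur / ((R_xlen_t)d1 * d2));
            for (int m = 0; m < noff; ++m) {
                int ii = i + off1[m], jj = j + off2[m], kk = k + off3[m];
                if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 ||
                    kk < 0 || kk >= d3)
                    continue;
                R_xlen_t q = (R_xlen_t)kk * d1 * d2 + (R_xlen_t)jj * d1 + ii;
                if (vox[q] == TRUE && lab[q] == 0) {
                    lab[q] = next;
                    stack.push_back(q);
                }
            }
        }
    }
    lab.attr("ncomp") = next;
    return lab;
}
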