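#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Banded (bandwidth-2) Cholesky solve of (diag(w) + lambda * D'D) z = w*y,
// where D is the (n-2) x n second-difference operator. The system matrix is
// symmetric positive definite and pentadiagonal, so an O(n) LL' factorisation
// replaces a general sparse solve.
static void penta_solve(const std::vector<double>& a0,
                        const std::vector<double>& a1,
                        const std::vector<double>& a2,
                        const std::vector<double>& b,
                        std::vector<double>& x) {
    const int n = (int)a0.size();
    std::vector<double> dg(n), e1(n > 1 ? n - 1 : 0), e2(n > 2 ? n - 2 : 0);
    for (int i = 0; i < n; ++i) {
        double v = a0[i];
        if (i >= 1) v -= e1[i - 1] * e1[i - 1];
        if (i >= 2) v -= e2[i - 2] * e2[i - 2];
        dg[i] = std::sqrt(v);
        if (i + 1 < n) {
            double w = a1[i];
            if (i >= 1) w -= e2[i - 1] * e1[i - 1];
            e1[i] = w / dg[i];
        }
        if (i + 2 < n) e2[i] = a2[i] / dg[i];
    }
    // forward: L zf = b
    std::vector<double> zf(n);
    for (int i = 0; i < n; ++i) {
        double v = b[i];
        if (i >= 1) v -= e1[i - 1] * zf[i - 1];
        if (i >= 2) v -= e2[i - 2] * zf[i - 2];
        zf[i] = v / dg[i];
    }
    // backward: L' x = zf
    for (int i = n - 1; i >= 0; --i) {
        double v = zf[i];
        if (i + 1 < n) v -= e1[i] * x[i + 1];
        if (i + 2 < n) v -= e2[i] * x[i + 2];
        x[i] = v / dg[i];
    }
}

// Asymmetric least squares baseline (Eilers): iteratively reweighted smooth
// fit with second-difference penalty lambda and asymmetry p.
// [[Rcpp::export]]
NumericVector cpp_als_baseline(NumericVector y, double lambda, double p,
                               int niter) {
    const int n = y.size();
    if (n < 3) stop("spectrum too short for baseline estimation");
    // lambda * D'D band entries (constant across iterations)
    std::vector<double> pd0(n, 0.0), pd1(n - 1, 0.0), pd2(n - 2, 0.0);
    for (int k = 0; k + 2 < n; ++k) {
        pd0[k] += 1.0; pd0[k + 1] += 4.0; pd0[k + 2] += 1.0;
        pd1[k] += -2.0; pd1[k + 1] += -2.0;
        pd2[k] += 1.0;
    }
    for (int i = 0; i < n; ++i) pd0[i] *= lambda;
    for (int i = 0; i + 1 < n; ++i) pd1[i] *= lambda;
    for (int i = 0; i + 2 < n; ++i) pd2[i] *= lambda;

    std::vector<double> w(n, 1.0), a0(n), b(n), z(n, 0.0);
    for (int it = 0; it < niter; ++it) {
        for (int i = 0; i < n; ++i) {
            a0[i] = pd0[i] + w[i];
            b[i] = w[i] * y[i];
        }
        penta_solve(a0, pd1, pd2, b, z);
        for (int i = 0; i < n; ++i) w[i] = (y[i] > z[i]) ? p : 1.0 - p;
    }
    return NumericVector(z.begin(), z.end());
}
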