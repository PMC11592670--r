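// Inner loops of the CRU repulsion schedule: one displacement step and the
// nearest-neighbor distances, both under the (optionally periodic) domain
// metric. Plain O(n^2) scans without temporaries.

#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline double wrapDiff(double d, double L, bool periodic) {
    if (periodic) d -= L * std::floor(d / L + 0.5);
    return d;
}

// [[Rcpp::export(name = ".nndDomain_cpp")]]
NumericVector nnd_domain_cpp(NumericMatrix p, double W, double H,
                             bool periodic) {
    const int n = p.nrow();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        double best = std::numeric_limits<double>::infinity();
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            const double dx = wrapDiff(p(i, 0) - p(j, 0), W, periodic);
            const double dy = wrapDiff(p(i, 1) - p(j, 1), H, periodic);
            const double d2 = dx * dx + dy * dy;
            if (d2 < best) best = d2;
        }
        out[i] = std::sqrt(best);
    }
    return out;
}

// [[Rcpp::export(name = ".repelStep_cpp")]]
List repel_step_cpp(NumericMatrix p, double W, double H, bool periodic,
                    double rInt, double gain, double maxDisp) {
    const int n = p.nrow();
    std::vector<double> fx(n, 0.0), fy(n, 0.0), nnd2(n),
        x(n), y(n);
    for (int i = 0; i < n; ++i) {
        x[i] = p(i, 0);
        y[i] = p(i, 1);
        nnd2[i] = std::numeric_limits<double>::infinity();
    }
    const double r2 = rInt * rInt;
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            const double dx = wrapDiff(x[i] - x[j], W, periodic);
            const double dy = wrapDiff(y[i] - y[j], H, periodic);
            const double d2 = dx * dx + dy * dy;
            if (d2 < nnd2[i]) nnd2[i] = d2;
            if (d2 < nnd2[j]) nnd2[j] = d2;
            if (d2 < r2) {
                double d = std::sqrt(d2);
                if (d < 1e-9) d = 1e-9;
                const double mag = gain * (rInt - d) / 2.0; // per point
                const double ux = dx / d, uy = dy / d;      // j -> i
                fx[i] += mag * ux;
                fy[i] += mag * uy;
                fx[j] -= mag * ux;
                fy[j] -= mag * uy;
            }
        }
    }
    double sumNnd = 0.0;
    for (int i = 0; i < n; ++i) sumNnd += std::sqrt(nnd2[i]);
    NumericMatrix out(n, 2);
    for (int i = 0; i < n; ++i) {
        double gx = fx[i], gy = fy[i];
        const double nrm = std::sqrt(gx * gx + gy * gy);
        if (nrm > maxDisp) {
            gx *= maxDisp / nrm;
            gy *= maxDisp / nrm;
        }
        double nx = x[i] + gx, ny = y[i] + gy;
        if (periodic) {
            nx -= W * std::floor(nx / W);
            ny -= H * std::floor(ny / H);
        } else {
            nx = std::min(std::max(nx, 0.0), W);
            ny = std::min(std::max(ny, 0.0), H);
        }
        out(i, 0) = nx;
        out(i, 1) = ny;
    }
    return List::create(_["p"] = out, _["nndIn"] = sumNnd / n);
}
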