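#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bilinear neuronal model + balloon-Windkessel hemodynamics, integrated with
// fixed-step RK4. Inputs are zero-order-hold at scan (TR) resolution, so the
// effective coupling matrix A + sum_j u_j B_j is constant within a scan and is
// refreshed once per scan. BOLD is sampled at each volume onset.
//
// State per region: z (neuronal), s (vasodilatory signal), f (inflow),
// v (venous volume), q (deoxyhemoglobin). Rest state z=s=0, f=v=q=1.

struct Deriv {
    int n;
    const double *Aeff; // n x n, column-major
    const double *Cu;   // n
    const double *kappa, *gamma, *tau, *ialpha, *rho;

    // y layout: [z(n), s(n), f(n), v(n), q(n)]
    // returns false when f/v/q leave the positive domain
    bool operator()(const double *y, double *dy) const {
        const double *z = y, *s = y + n, *f = y + 2 * n, *v = y + 3 * n,
                     *q = y + 4 * n;
        double *dz = dy, *ds = dy + n, *df = dy + 2 * n, *dv = dy + 3 * n,
               *dq = dy + 4 * n;
        for (int i = 0; i < n; ++i) {
            if (!(f[i] > 0.0) || !(v[i] > 0.0) || !(q[i] > 0.0)) return false;
            double acc = Cu[i];
            for (int j = 0; j < n; ++j) acc += Aeff[i + n * j] * z[j];
            dz[i] = acc;
            ds[i] = z[i] - kappa[i] * s[i] - gamma[i] * (f[i] - 1.0);
            df[i] = s[i];
            double fv = std::exp(std::log(v[i]) * ialpha[i]); // v^(1/alpha)
            double E = 1.0 - std::exp(std::log1p(-rho[i]) / f[i]);
            dv[i] = (f[i] - fv) / tau[i];
            dq[i] = (f[i] * E / rho[i] - fv * q[i] / v[i]) / tau[i];
        }
        return true;
    }
};

// A: n x n intrinsic coupling (diagonal included, negative)
// Bflat: n*n*m modulatory matrices, column-major slices
// C: n x m direct input weights
// U: n_scans x m input values (zero-order hold over each scan)
// H: n x 9 hemodynamic constants per region
//    (kappa, gamma, tau, alpha, rho, V0, k1, k2, k3)
// [[Rcpp::export]]
List sim_bold_cpp(NumericMatrix A, NumericVector Bflat, NumericMatrix C,
                  NumericMatrix U, NumericMatrix H, double TR, int nsub,
                  double z_bound) {
    const int n = A.nrow();
    const int m = U.ncol();
    const int n_scans = U.nrow();
    const int ns = 5 * n;
    const double dt = TR / nsub;

    std::vector<double> kappa(n), gamma(n), tau(n), ialpha(n), rho(n), V0(n),
        k1(n), k2(n), k3(n);
    for (int i = 0; i < n; ++i) {
        kappa[i] = H(i, 0);
        gamma[i] = H(i, 1);
        tau[i] = H(i, 2);
        ialpha[i] = 1.0 / H(i, 3);
        rho[i] = H(i, 4);
        V0[i] = H(i, 5);
        k1[i] = H(i, 6);
        k2[i] = H(i, 7);
        k3[i] = H(i, 8);
    }

    std::vector<double> y(ns, 0.0);
    for (int i = 0; i < n; ++i) {
        y[2 * n + i] = 1.0;
        y[3 * n + i] = 1.0;
        y[4 * n + i] = 1.0;
    }

    std::vector<double> Aeff(n * n), Cu(n);
    std::vector<double> k1v(ns), k2v(ns), k3v(ns), k4v(ns), tmp(ns);
    NumericMatrix bold(n_scans, n);
    Deriv deriv{n,          Aeff.data(), Cu.data(), kappa.data(),
                gamma.data(), tau.data(), ialpha.data(), rho.data()};

    bool ok = true;
    double t_div = NA_REAL;

    for (int scan = 0; scan < n_scans && ok; ++scan) {
        // sample BOLD at volume onset, before integrating over this TR
        for (int i = 0; i < n; ++i) {
            double v = y[3 * n + i], q = y[4 * n + i];
            bold(scan, i) =
                V0[i] * (k1[i] * (1.0 - q) + k2[i] * (1.0 - q / v) +
                         k3[i] * (1.0 - v));
        }
        // refresh effective coupling for this scan's (held) input
        for (int j = 0; j < n * n; ++j) Aeff[j] = A[j];
        for (int i = 0; i < n; ++i) Cu[i] = 0.0;
        for (int jm = 0; jm < m; ++jm) {
            double u = U(scan, jm);
            if (u != 0.0) {
                const double *B = &Bflat[jm * n * n];
                for (int j = 0; j < n * n; ++j) Aeff[j] += u * B[j];
                for (int i = 0; i < n; ++i) Cu[i] += C(i, jm) * u;
            }
        }
        for (int sub = 0; sub < nsub; ++sub) {
            if (!deriv(y.data(), k1v.data())) { ok = false; break; }
            for (int j = 0; j < ns; ++j) tmp[j] = y[j] + 0.5 * dt * k1v[j];
            if (!deriv(tmp.data(), k2v.data())) { ok = false; break; }
            for (int j = 0; j < ns; ++j) tmp[j] = y[j] + 0.5 * dt * k2v[j];
            if (!deriv(tmp.data(), k3v.data())) { ok = false; break; }
            for (int j = 0; j < ns; ++j) tmp[j] = y[j] + dt * k3v[j];
            if (!deriv(tmp.data(), k4v.data())) { ok = false; break; }
            for (int j = 0; j < ns; ++j)
                y[j] += dt / 6.0 *
                        (k1v[j] + 2.0 * k2v[j] + 2.0 * k3v[j] + k4v[j]);
            for (int i = 0; i < n; ++i) {
                if (!std::isfinite(y[i]) || std::fabs(y[i]) > z_bound) {
                    ok = false;
                    break;
                }
            }
            if (!ok) break;
        }
        if (!ok) t_div = scan * TR;
    }

    return List::create(_["bold"] = bold, _["ok"] = ok, _["t_div"] = t_div);
}
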