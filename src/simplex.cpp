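#include <Rcpp.h>
using namespace Rcpp;

// Dense two-phase primal simplex for the parsimony covering LP:
//   min 1'x  s.t.  A x >= 1,  x >= 0,
// with A a 0/1 constraint matrix. Equality form uses surplus and
// artificial variables; Bland's rule (lowest eligible index) on both the
// entering and leaving choices guarantees termination without cycling.
// Covering-polyhedron vertices satisfy x <= 1 componentwise, so no upper
// bounds are needed.

static const double EPS = 1e-9;

static void runPhase(std::vector<double>& tab, std::vector<double>& rhs,
                     std::vector<int>& basis, const std::vector<double>& cost,
                     int m, int nv, int banFrom) {
    std::vector<double> red(nv);
    for (;;) {
        // reduced costs r = cost - cost[basis] %*% tab
        for (int j = 0; j < nv; ++j) red[j] = cost[j];
        for (int i = 0; i < m; ++i) {
            double cb = cost[basis[i]];
            if (cb != 0.0) {
                const double* row = &tab[(size_t)i * nv];
                for (int j = 0; j < nv; ++j) red[j] -= cb * row[j];
            }
        }
        int enter = -1;
        for (int j = 0; j < nv; ++j) {
            if (banFrom >= 0 && j >= banFrom) break;
            if (red[j] < -EPS) { enter = j; break; }   // Bland
        }
        if (enter < 0) return;
        // ratio test, Bland tie-break on smallest basis index
        int leave = -1;
        double best = R_PosInf;
        for (int i = 0; i < m; ++i) {
            double a = tab[(size_t)i * nv + enter];
            if (a > EPS) {
                double ratio = rhs[i] / a;
                if (ratio < best - EPS ||
                    (ratio <= best + EPS &&
                     (leave < 0 || basis[i] < basis[leave]))) {
                    if (ratio < best) best = ratio;
                    leave = i;
                }
            }
        }
        if (leave < 0) stop("LP unbounded (cannot occur for covering LP)");
        // pivot
        double piv = tab[(size_t)leave * nv + enter];
        double* prow = &tab[(size_t)leave * nv];
        for (int j = 0; j < nv; ++j) prow[j] /= piv;
        rhs[leave] /= piv;
        for (int i = 0; i < m; ++i) {
            if (i == leave) continue;
            double f = tab[(size_t)i * nv + enter];
            if (f != 0.0) {
                double* row = &tab[(size_t)i * nv];
                for (int j = 0; j < nv; ++j) row[j] -= f * prow[j];
                rhs[i] -= f * rhs[leave];
                if (rhs[i] < 0 && rhs[i] > -1e-11) rhs[i] = 0;
            }
        }
        basis[leave] = enter;
    }
}

// [[Rcpp::export(name = ".simplexCoverCpp")]]
NumericVector simplexCover(NumericMatrix A) {
    const int m = A.nrow(), n = A.ncol();
    const int nv = n + 2 * m;
    std::vector<double> tab((size_t)m * nv, 0.0);
    std::vector<double> rhs(m, 1.0);
    std::vector<int> basis(m);
    for (int i = 0; i < m; ++i) {
        for (int j = 0; j < n; ++j) tab[(size_t)i * nv + j] = A(i, j);
        tab[(size_t)i * nv + n + i] = -1.0;       // surplus
        tab[(size_t)i * nv + n + m + i] = 1.0;    // artificial
        basis[i] = n + m + i;
    }
    // phase 1: minimise sum of artificials
    std::vector<double> cost1(nv, 0.0);
    for (int j = n + m; j < nv; ++j) cost1[j] = 1.0;
    runPhase(tab, rhs, basis, cost1, m, nv, -1);
    double infeas = 0.0;
    for (int i = 0; i < m; ++i)
        if (basis[i] >= n + m) infeas += rhs[i];
    if (infeas > 1e-7) stop("LP infeasible");
    // phase 2: minimise sum x, artificials banned from re-entering
    std::vector<double> cost2(nv, 0.0);
    for (int j = 0; j < n; ++j) cost2[j] = 1.0;
    runPhase(tab, rhs, basis, cost2, m, nv, n + m);
    NumericVector x(n);
    for (int i = 0; i < m; ++i)
        if (basis[i] < n) x[basis[i]] = rhs[i];
    return x;
}
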