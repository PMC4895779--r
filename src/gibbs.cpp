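#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the Bayesian domain-disease association model.
//
// Latent structure: for each candidate pair k, lambda_k in (0,1) with a
// Beta(alpha, beta) (or flat) prior; observation noise rates fp ~
// Unif[up, vp], fn ~ Unif[un, vn] (a degenerate interval pins the rate).
// Row r of the evaluation universe carries O_r in {0,1} and the running
// sum S_r = sum over contained pairs of log(1 - lambda_k), so
// h_r = 1 - exp(S_r) and Pr(O_r = 1) = h_r (1 - fn) + (1 - h_r) fp.
//
// Each full conditional is sampled by shrinkage slice sampling on its
// bounded support: derivative-free, no log-concavity requirement, exact
// stationary distribution. All randomness comes from R's RNG, so set.seed
// upstream makes runs reproducible.

static const double PCLIP_LO = 1e-300;
static const double PCLIP_HI = 1.0 - 1e-16;

static inline double rowLogLik(double S, int O, double fp, double fn) {
    double h = -expm1(S);
    double p1 = (1.0 - fn) * h + fp * (1.0 - h);
    if (p1 < PCLIP_LO) p1 = PCLIP_LO;
    if (p1 > PCLIP_HI) p1 = PCLIP_HI;
    return O ? log(p1) : log1p(-p1);
}

// log full conditional of lambda_k at value v, up to a constant
static double lambdaLogPost(double v, double lamCur,
                            const std::vector<int>& rows,
                            const std::vector<double>& S,
                            const IntegerVector& O,
                            double fp, double fn,
                            double alpha, double beta) {
    if (v <= 0.0 || v >= 1.0) return R_NegInf;
    double lp = 0.0;
    double dOld = log1p(-lamCur), dNew = log1p(-v);
    for (size_t t = 0; t < rows.size(); ++t) {
        int r = rows[t];
        lp += rowLogLik(S[r] - dOld + dNew, O[r], fp, fn);
    }
    if (alpha != 1.0) lp += (alpha - 1.0) * log(v);
    if (beta != 1.0) lp += (beta - 1.0) * log1p(-v);
    return lp;
}

// total log likelihood over all rows at given noise rates
static double totalLogLik(const std::vector<double>& S,
                          const IntegerVector& O,
                          double fp, double fn) {
    double lp = 0.0;
    for (size_t r = 0; r < S.size(); ++r)
        lp += rowLogLik(S[r], O[r], fp, fn);
    return lp;
}

// shrinkage slice sampler on (lo, hi); f must be callable at x0
template <class F>
static double sliceSample(double x0, double lo, double hi, F logf) {
    double y = logf(x0) - R::exp_rand();
    double L = lo, Rr = hi;
    for (int it = 0; it < 200; ++it) {
        double x1 = R::runif(L, Rr);
        if (logf(x1) >= y) return x1;
        if (x1 < x0) L = x1; else Rr = x1;
        if (Rr - L < 1e-14) break;
    }
    return x0;  // degenerate slice; keep current value
}

// [[Rcpp::export(name = ".gibbsSampler")]]
List gibbsSampler(IntegerVector colPtr, IntegerVector rowIdx,
                  IntegerVector O, NumericVector lambdaInit,
                  double fpInit, double fnInit,
                  double up, double vp, double un, double vn,
                  double alpha, double beta,
                  int nSamples, int burnIn, int thin,
                  bool keepChains) {
    const int K = lambdaInit.size();
    const int Rn = O.size();
    std::vector<double> lam(lambdaInit.begin(), lambdaInit.end());
    double fp = fpInit, fn = fnInit;
    const bool fpFixed = (vp - up) < 1e-15;
    const bool fnFixed = (vn - un) < 1e-15;

    // column -> affected rows
    std::vector< std::vector<int> > cols(K);
    for (int k = 0; k < K; ++k)
        for (int p = colPtr[k]; p < colPtr[k + 1]; ++p)
            cols[k].push_back(rowIdx[p]);

    std::vector<double> S(Rn, 0.0);
    for (int k = 0; k < K; ++k) {
        double d = log1p(-lam[k]);
        for (size_t t = 0; t < cols[k].size(); ++t) S[cols[k][t]] += d;
    }

    std::vector<double> lamSum(K, 0.0);
    double fpSum = 0.0, fnSum = 0.0;
    int nKept = 0;
    NumericMatrix lamChain(keepChains ? nSamples : 0, keepChains ? K : 0);
    NumericVector fpChain(keepChains ? nSamples : 0);
    NumericVector fnChain(keepChains ? nSamples : 0);

    const int totalSweeps = burnIn + nSamples * thin;
    for (int sweep = 0; sweep < totalSweeps; ++sweep) {
        for (int k = 0; k < K; ++k) {
            double cur = lam[k];
            double prop = sliceSample(cur, 0.0, 1.0, [&](double v) {
                return lambdaLogPost(v, cur, cols[k], S, O, fp, fn,
                                     alpha, beta);
            });
            if (prop != cur) {
                double shift = log1p(-prop) - log1p(-cur);
                for (size_t t = 0; t < cols[k].size(); ++t)
                    S[cols[k][t]] += shift;
                lam[k] = prop;
            }
        }
        if (!fpFixed) {
            fp = sliceSample(fp, up, vp, [&](double v) {
                if (v < up || v > vp) return R_NegInf;
                return totalLogLik(S, O, v, fn);
            });
        }
        if (!fnFixed) {
            fn = sliceSample(fn, un, vn, [&](double v) {
                if (v < un || v > vn) return R_NegInf;
                return totalLogLik(S, O, fp, v);
            });
        }
        if (sweep >= burnIn && ((sweep - burnIn) % thin == 0)) {
            for (int k = 0; k < K; ++k) lamSum[k] += lam[k];
            fpSum += fp; fnSum += fn;
            if (keepChains) {
                for (int k = 0; k < K; ++k) lamChain(nKept, k) = lam[k];
                fpChain[nKept] = fp;
                fnChain[nKept] = fn;
            }
            ++nKept;
        }
    }

    NumericVector lamMean(K);
    for (int k = 0; k < K; ++k)
        lamMean[k] = nKept ? lamSum[k] / nKept : NA_REAL;
    List out = List::create(
        _["lambdaMean"] = lamMean,
        _["fpMean"] = nKept ? fpSum / nKept : NA_REAL,
        _["fnMean"] = nKept ? fnSum / nKept : NA_REAL,
        _["nKept"] = nKept);
    if (keepChains) {
        out["lambdaChain"] = lamChain;
        out["fpChain"] = fpChain;
        out["fnChain"] = fnChain;
    }
    return out;
}
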