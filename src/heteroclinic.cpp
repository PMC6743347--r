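#include <Rcpp.h>
using namespace Rcpp;

// Drift of the heteroclinic-cycle system on the 3-sphere: an ambient
// field g is projected onto the tangent space, dx/dt = g - (x.g) x, so
// the noise-free flow conserves ||x|| exactly in continuous time.
static inline void drift(const double *x, double a1, double a2, double b,
                         double *dx) {
    double g[4];
    g[0] = (a1 * x[3] + a2) * x[0];
    g[1] = (-a1 * x[3] + a2) * x[1];
    g[2] = a2 * x[2];
    g[3] = b * (x[1] * x[1] - x[0] * x[0]);
    double xg = 0.0;
    for (int k = 0; k < 4; ++k) xg += x[k] * g[k];
    for (int k = 0; k < 4; ++k) dx[k] = g[k] - xg * x[k];
}

// Fixed-step integration: classical RK4 for the deterministic drift plus
// an Euler-Maruyama Brownian increment on the fourth coordinate with
// time-dependent amplitude sigma(t) = noiseA * (1 + t). Noisy steps are
// renormalized back onto the sphere; noise-free runs are left untouched
// so that sphere conservation can be verified. Rows are recorded every
// `sampleEvery` steps (including the initial state).
//
// [[Rcpp::export(name = ".heteroclinic_integrate")]]
List heteroclinic_integrate(NumericVector init, double alpha1,
                            double alpha2, double b, double noiseA,
                            double dt, int nSteps, int sampleEvery) {
    if (init.size() != 4) stop("initial state must be 4-dimensional");
    if (dt <= 0) stop("'dt' must be positive");
    if (sampleEvery < 1) stop("'sampleEvery' must be >= 1");
    const int nOut = nSteps / sampleEvery + 1;
    NumericMatrix out(nOut, 4);
    NumericVector times(nOut);
    double x[4], k1[4], k2[4], k3[4], k4[4], tmp[4];
    for (int k = 0; k < 4; ++k) x[k] = init[k];
    int row = 0;
    for (int k = 0; k < 4; ++k) out(0, k) = x[k];
    times[0] = 0.0;
    ++row;
    for (int step = 1; step <= nSteps; ++step) {
        const double t = (step - 1) * dt;
        drift(x, alpha1, alpha2, b, k1);
        for (int k = 0; k < 4; ++k) tmp[k] = x[k] + 0.5 * dt * k1[k];
        drift(tmp, alpha1, alpha2, b, k2);
        for (int k = 0; k < 4; ++k) tmp[k] = x[k] + 0.5 * dt * k2[k];
        drift(tmp, alpha1, alpha2, b, k3);
        for (int k = 0; k < 4; ++k) tmp[k] = x[k] + dt * k3[k];
        drift(tmp, alpha1, alpha2, b, k4);
        for (int k = 0; k < 4; ++k)
            x[k] += dt / 6.0 * (k1[k] + 2 * k2[k] + 2 * k3[k] + k4[k]);
        if (noiseA > 0) {
            const double sigma = noiseA * (1.0 + t);
            x[3] += sigma * std::sqrt(dt) * R::norm_rand();
            double nrm = 0.0;
            for (int k = 0; k < 4; ++k) nrm += x[k] * x[k];
            nrm = std::sqrt(nrm);
            for (int k = 0; k < 4; ++k) x[k] /= nrm;
        }
        for (int k = 0; k < 4; ++k)
            if (!std::isfinite(x[k]))
                stop("integration blew up at t = %.4f", t + dt);
        if (step % sampleEvery == 0) {
            for (int k = 0; k < 4; ++k) out(row, k) = x[k];
            times[row] = step * dt;
            ++row;
        }
    }
    return List::create(_["values"] = out, _["times"] = times);
}
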