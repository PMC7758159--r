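#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Direct-form II transposed IIR filter, zero initial state.
 * b, a: coefficients in z^-1 convention, a[0] == 1. */
SEXP nq_lfilter(SEXP xs, SEXP bs, SEXP as)
{
    R_xlen_t n = XLENGTH(xs);
    int nb = LENGTH(bs), na = LENGTH(as);
    int nz = (nb > na ? nb : na) - 1;
    SEXP ys = PROTECT(allocVector(REALSXP, n));
    const double *x = REAL(xs), *b = REAL(bs), *a = REAL(as);
    double *y = REAL(ys);
    if (nz == 0) {
        double b0 = b[0];
        for (R_xlen_t i = 0; i < n; i++) y[i] = b0 * x[i];
        UNPROTECT(1);
        return ys;
    }
    double *z = (double *) R_alloc(nz, sizeof(double));
    for (int j = 0; j < nz; j++) z[j] = 0.0;
    for (R_xlen_t i = 0; i < n; i++) {
        double xi = x[i];
        double yi = b[0] * xi + z[0];
        for (int j = 0; j < nz - 1; j++) {
            double bj = (j + 1 < nb) ? b[j + 1] : 0.0;
            double aj = (j + 1 < na) ? a[j + 1] : 0.0;
            z[j] = bj * xi + z[j + 1] - aj * yi;
        }
        {
            double bj = (nz < nb) ? b[nz] : 0.0;
            double aj = (nz < na) ? a[nz] : 0.0;
            z[nz - 1] = bj * xi - aj * yi;
        }
        y[i] = yi;
    }
    UNPROTECT(1);
    return ys;
}

static const R_CallMethodDef CallEntries[] = {
    {"nq_lfilter", (DL_FUNC) &nq_lfilter, 3},
    {NULL, NULL, 0}
};

void R_init_nervequant(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
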