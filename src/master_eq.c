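/* Exact solution of the one-step master equation for multivalent IC
 * dissociation: states m = 0..M closed bonds, M = min(nR, nL), absorbing at
 * m = 0, unbinding rate r(m) = m*koff, rebinding rate g(m) = C(m)*kon with
 * C(m) = (nR - m)(nL - m) (all-to-all configuration count) and g(0) = 0.
 *
 * The transient block (states 1..M) is a birth-death sub-generator; with all
 * interior g(m) > 0 it is similar to a symmetric tridiagonal matrix via a
 * diagonal transform D, so LAPACK dstev gives the full eigensystem in O(M^2)
 * storage.  Survival S(t) = sum_k w_k exp(lambda_k t).  kon == 0 (singular
 * transform) is handled by a closed form on the R side.
 */
#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <Rconfig.h>
#include <R_ext/Lapack.h>
#include <math.h>

#ifndef FCONE
# define FCONE
#endif

/* Fill lambda (eigenvalues), Z (M x M eigenvectors of the symmetrized
 * block, column-major) and logd (log of the similarity diagonal).
 * Returns LAPACK info (0 = success).  Requires M >= 1 and kon > 0 when
 * M > 1. */
static int me_eig(int nR, int nL, double koff, double kon,
                  int M, double *lambda, double *Z, double *logd)
{
    double *e = (double *) R_alloc((size_t)(M > 1 ? M - 1 : 1), sizeof(double));
    double *work = (double *) R_alloc((size_t)(M > 1 ? 2 * M - 2 : 1), sizeof(double));
    int info = 0;

    for (int m = 1; m <= M; m++) {
        double Cm = (double)(nR - m) * (double)(nL - m);
        lambda[m - 1] = -((double)m * koff + Cm * kon);
    }
    logd[0] = 0.0;
    for (int m = 1; m < M; m++) {
        double g = (double)(nR - m) * (double)(nL - m) * kon; /* m -> m+1 */
        double r = (double)(m + 1) * koff;                    /* m+1 -> m */
        e[m - 1] = sqrt(g * r);
        /* symmetry of D Q D^-1 needs d_{m+1}/d_m = sqrt(r(m+1)/g(m)) */
        logd[m] = logd[m - 1] + 0.5 * (log(r) - log(g));
    }
    F77_CALL(dstev)("V", &M, lambda, e, Z, &M, work, &info FCONE);
    return info;
}

/* Survival-curve weights: S(t) = sum_k w_k exp(lambda_k t) with
 * w_k = Z[M-1,k] * sum_m Z[m,k] * exp(logd[M-1] - logd[m]).  Returns 0 on
 * success, 1 if any weight is non-finite (overflowed similarity scale). */
static int surv_weights(int M, const double *Z, const double *logd, double *w,
                        double tol)
{
    int bad = 0;
    double s0 = 0.0;
    for (int k = 0; k < M; k++) {
        double acc = 0.0;
        for (int m = 0; m < M; m++)
            acc += Z[m + k * M] * exp(logd[M - 1] - logd[m]);
        w[k] = acc * Z[(M - 1) + k * M];
        if (!R_FINITE(w[k])) bad = 1;
        s0 += w[k];
    }
    /* S(0) must be exactly 1; drift flags catastrophic cancellation in the
     * similarity-scaled weights and triggers the ODE fallback */
    if (!bad && fabs(s0 - 1.0) > tol) bad = 1;
    return bad;
}

/* .Call: eigensystem of the transient block, for the full P_m(t) solution
 * assembled in R.  Returns list(values, vectors, logd). */
SEXP C_me_eig(SEXP s_nR, SEXP s_nL, SEXP s_koff, SEXP s_kon)
{
    int nR = asInteger(s_nR), nL = asInteger(s_nL);
    double koff = asReal(s_koff), kon = asReal(s_kon);
    int M = nR < nL ? nR : nL;
    if (M < 1) error("transient block requires min(n_R, n_L) >= 1");

    SEXP values = PROTECT(allocVector(REALSXP, M));
    SEXP vectors = PROTECT(allocMatrix(REALSXP, M, M));
    SEXP logd = PROTECT(allocVector(REALSXP, M));
    int info = me_eig(nR, nL, koff, kon, M,
                      REAL(values), REAL(vectors), REAL(logd));
    if (info != 0) error("LAPACK dstev failed (info = %d)", info);

    SEXP out = PROTECT(allocVector(VECSXP, 3));
    SET_VECTOR_ELT(out, 0, values);
    SET_VECTOR_ELT(out, 1, vectors);
    SET_VECTOR_ELT(out, 2, logd);
    SEXP nms = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nms, 0, mkChar("values"));
    SET_STRING_ELT(nms, 1, mkChar("vectors"));
    SET_STRING_ELT(nms, 2, mkChar("logd"));
    setAttrib(out, R_NamesSymbol, nms);
    UNPROTECT(5);
    return out;
}

/* .Call: single-patch survival S(t) on a time grid.  Returns numeric vector,
 * or logical NA scalar if the symmetrized weights overflowed (caller falls
 * back to an ODE solve). */
SEXP C_patch_survival(SEXP s_nR, SEXP s_nL, SEXP s_koff, SEXP s_kon,
                      SEXP s_times, SEXP s_tol)
{
    int nR = asInteger(s_nR), nL = asInteger(s_nL);
    double koff = asReal(s_koff), kon = asReal(s_kon);
    double tol = asReal(s_tol);
    int M = nR < nL ? nR : nL;
    int T = LENGTH(s_times);
    const double *times = REAL(s_times);

    SEXP out = PROTECT(allocVector(REALSXP, T));
    double *S = REAL(out);
    if (M < 1) {
        for (int i = 0; i < T; i++) S[i] = 0.0;
        UNPROTECT(1);
        return out;
    }
    const void *vmax = vmaxget();
    double *lambda = (double *) R_alloc((size_t)M, sizeof(double));
    double *Z = (double *) R_alloc((size_t)M * M, sizeof(double));
    double *logd = (double *) R_alloc((size_t)M, sizeof(double));
    double *w = (double *) R_alloc((size_t)M, sizeof(double));
    int info = me_eig(nR, nL, koff, kon, M, lambda, Z, logd);
    if (info != 0) error("LAPACK dstev failed (info = %d)", info);
    if (surv_weights(M, Z, logd, w, tol)) {
        vmaxset(vmax);
        UNPROTECT(1);
        return ScalarLogical(NA_LOGICAL);
    }
    for (int i = 0; i < T; i++) {
        double acc = 0.0;
        for (int k = 0; k < M; k++)
            acc += w[k] * exp(lambda[k] * times[i]);
        S[i] = acc;
    }
    vmaxset(vmax);
    UNPROTECT(1);
    return out;
}

/* .Call: Poisson-mixture survival <S(t)> = sum_i weight_i * S_{nR_i}(t).
 * nRs/weights give the truncated Poisson window (nR = 0 terms contribute
 * nothing and are skipped).  Returns list(S, bad): the accumulated
 * survival over the well-conditioned terms, plus a logical vector marking
 * terms whose weights cancelled catastrophically (the caller adds those
 * via an ODE solve). */
SEXP C_poisson_survival(SEXP s_nRs, SEXP s_weights, SEXP s_nL, SEXP s_koff,
                        SEXP s_kon, SEXP s_times, SEXP s_tol)
{
    int nterms = LENGTH(s_nRs);
    const int *nRs = INTEGER(s_nRs);
    const double *wt = REAL(s_weights);
    int nL = asInteger(s_nL);
    double koff = asReal(s_koff), kon = asReal(s_kon);
    double tol = asReal(s_tol);
    int T = LENGTH(s_times);
    const double *times = REAL(s_times);

    SEXP out = PROTECT(allocVector(REALSXP, T));
    SEXP badv = PROTECT(allocVector(LGLSXP, nterms));
    double *S = REAL(out);
    int *bad = LOGICAL(badv);
    for (int i = 0; i < T; i++) S[i] = 0.0;

    for (int j = 0; j < nterms; j++) {
        int nR = nRs[j];
        int M = nR < nL ? nR : nL;
        bad[j] = 0;
        if (M < 1 || wt[j] <= 0.0) continue;
        const void *vmax = vmaxget();
        double *lambda = (double *) R_alloc((size_t)M, sizeof(double));
        double *Z = (double *) R_alloc((size_t)M * M, sizeof(double));
        double *logd = (double *) R_alloc((size_t)M, sizeof(double));
        double *w = (double *) R_alloc((size_t)M, sizeof(double));
        int info = me_eig(nR, nL, koff, kon, M, lambda, Z, logd);
        if (info != 0) error("LAPACK dstev failed (info = %d)", info);
        if (surv_weights(M, Z, logd, w, tol)) {
            bad[j] = 1;
            vmaxset(vmax);
            continue;
        }
        for (int i = 0; i < T; i++) {
            double acc = 0.0;
            for (int k = 0; k < M; k++)
                acc += w[k] * exp(lambda[k] * times[i]);
            S[i] += wt[j] * acc;
        }
        vmaxset(vmax);
        R_CheckUserInterrupt();
    }
    SEXP res = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(res, 0, out);
    SET_VECTOR_ELT(res, 1, badv);
    UNPROTECT(3);
    return res;
}
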