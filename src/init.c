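#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_me_eig(SEXP, SEXP, SEXP, SEXP);
SEXP C_patch_survival(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_poisson_survival(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_me_eig",           (DL_FUNC) &C_me_eig,           4},
    {"C_patch_survival",   (DL_FUNC) &C_patch_survival,   6},
    {"C_poisson_survival", (DL_FUNC) &C_poisson_survival, 7},
    {NULL, NULL, 0}
};

void R_init_fdcretention(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
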