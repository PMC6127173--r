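#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP C_set_model(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                        SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                        SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP C_eval_rhs(SEXP, SEXP);
extern SEXP C_signal(SEXP);

extern void vegf_derivs(int *, double *, double *, double *, double *, int *);
extern void vegf_root(int *, double *, double *, int *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
    {"C_set_model", (DL_FUNC) &C_set_model, 21},
    {"C_eval_rhs", (DL_FUNC) &C_eval_rhs, 2},
    {"C_signal", (DL_FUNC) &C_signal, 1},
    {NULL, NULL, 0}
};

/* registered as .C so deSolve can resolve them via getNativeSymbolInfo */
static const R_CMethodDef CEntries[] = {
    {"vegf_derivs", (DL_FUNC) &vegf_derivs, 6},
    {"vegf_root", (DL_FUNC) &vegf_root, 7},
    {NULL, NULL, 0}
};

void R_init_angiotrial(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
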