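#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Rcpp attribute exports (see RcppExports.cpp) */
extern SEXP _hybridnet_neg_cycle_nodes_cpp(SEXP, SEXP, SEXP, SEXP);
extern SEXP _hybridnet_path_profile_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

/* compiled ODE right-hand side consumed by deSolve (see ode_rhs.c) */
extern void hn_initmod(void (*odeparms)(int *, double *));
extern void hn_derivs(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
  {"_hybridnet_neg_cycle_nodes_cpp",
   (DL_FUNC) &_hybridnet_neg_cycle_nodes_cpp, 4},
  {"_hybridnet_path_profile_cpp",
   (DL_FUNC) &_hybridnet_path_profile_cpp, 6},
  {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
  {"hn_derivs", (DL_FUNC) &hn_derivs, 6},
  {"hn_initmod", (DL_FUNC) &hn_initmod, 1},
  {NULL, NULL, 0}
};

void R_init_hybridnet(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
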