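/* Generic compiled mass-action right-hand side for deSolve.
 *
 * Parameter vector layout (doubles):
 *   [0] nr   number of reactions
 *   [1] ns   number of states
 *   [2] kmax factors per reaction (padded)
 *   [3] nnz  stoichiometry triplet count
 *   then nr effective rate constants,
 *   then nr*kmax factor indices, column-major (1-based into c(1, y),
 *        index 1 = multiplicative padding),
 *   then nnz triplets (state index, reaction index, coefficient),
 *        each 1-based, stored consecutively.
 */

#include <R.h>

#define HN_MAX_PARMS 8192
#define HN_MAX_RX 4096
static double hn_parms[HN_MAX_PARMS];
static double hn_rate[HN_MAX_RX];

void hn_initmod(void (*odeparms)(int *, double *)) {
  int n = HN_MAX_PARMS;
  odeparms(&n, hn_parms);
}

void hn_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip) {
  const double *p = hn_parms;
  const int nr = (int) p[0];
  const int kmax = (int) p[2];
  const int nnz = (int) p[3];
  const double *effk = p + 4;
  const double *fidx = p + 4 + nr;
  const double *trip = p + 4 + nr + (size_t) nr * kmax;
  int i, k;

  for (i = 0; i < nr; i++) {
    double rate = effk[i];
    for (k = 0; k < kmax; k++) {
      int idx = (int) fidx[(size_t) k * nr + i];
      if (idx > 1) rate *= y[idx - 2];
    }
    hn_rate[i] = rate;
  }
  for (i = 0; i < *neq; i++) ydot[i] = 0.0;
  for (k = 0; k < nnz; k++) {
    int si = (int) trip[(size_t) k * 3];
    int rj = (int) trip[(size_t) k * 3 + 1];
    ydot[si - 1] += trip[(size_t) k * 3 + 2] * hn_rate[rj - 1];
  }
}
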