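/* Hodgkin-Huxley-type alpha-cell membrane model for deSolve.
 *
 * States: V (mV), hNa, n (KDR), hCaT, hKA, Cac (uM).
 * The amino-acid (iGluR) and cAMP modulation factors enter as fixed
 * multipliers on the Na, K and Ca current families; they are computed on the
 * R side and passed as parameters FCA (= fcAMP,Ca * fAA,Ca), FNA (= fAA,Na)
 * and FK (= fAA,K).
 *
 * Parameter order must match membraneParVector() in R/membrane.R.
 */
#include <R.h>
#include <math.h>

#define NPAR 43

enum {
  CM, GNA, VNA, VM_NA, SM_NA, VH_NA, SH_NA, TAUH_NA,
  GCAL, VCA, VM_CAL, SM_CAL,
  GCAPQ, VM_CAPQ, SM_CAPQ,
  GCAT, VM_CAT, SM_CAT, VH_CAT, SH_CAT, TAUH_CAT,
  GKDR, VK, VN_KDR, SN_KDR, TAUN_KDR,
  GKA, VA_KA, SA_KA, VH_KA, SH_KA, TAUH_KA,
  GKATP, GL, VL, GSOC, VSOC,
  KIN, KOUT, CA0,
  FCA, FNA, FK
};

static double parms[NPAR];

void alphacell_init(void (*odeparms)(int *, double *))
{
  int n = NPAR;
  odeparms(&n, parms);
}

static double act(double v, double vh, double s)
{
  return 1.0 / (1.0 + exp((vh - v) / s));
}

static double inact(double v, double vh, double s)
{
  return 1.0 / (1.0 + exp((v - vh) / s));
}

void alphacell_deriv(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
  double v = y[0], hna = y[1], n = y[2], hcat = y[3], hka = y[4], cac = y[5];
  double mna, mcal, mcapq, mcat, aka;
  double ina, ical, icapq, icat, ikdr, ika, ikatp, il, isoc;
  double ina_aa, ica_aa, ik_aa;

  if (ip[0] < 9) error("nout should be at least 9");

  mna   = act(v, parms[VM_NA], parms[SM_NA]);
  mcal  = act(v, parms[VM_CAL], parms[SM_CAL]);
  mcapq = act(v, parms[VM_CAPQ], parms[SM_CAPQ]);
  mcat  = act(v, parms[VM_CAT], parms[SM_CAT]);
  aka   = act(v, parms[VA_KA], parms[SA_KA]);

  ina   = parms[GNA] * mna * mna * mna * hna * (v - parms[VNA]);
  ical  = parms[GCAL] * mcal * mcal * (v - parms[VCA]);
  icapq = parms[GCAPQ] * mcapq * mcapq * (v - parms[VCA]);
  icat  = parms[GCAT] * mcat * mcat * mcat * hcat * (v - parms[VCA]);
  ikdr  = parms[GKDR] * n * n * n * n * (v - parms[VK]);
  ika   = parms[GKA] * aka * hka * (v - parms[VK]);
  ikatp = parms[GKATP] * (v - parms[VK]);
  il    = parms[GL] * (v - parms[VL]);
  isoc  = parms[GSOC] * (v - parms[VSOC]);

  ina_aa = parms[FNA] * ina;
  ik_aa  = parms[FK] * (ikdr + ika);
  ica_aa = parms[FCA] * (ical + icat + icapq);

  ydot[0] = -(ina_aa + ica_aa + ik_aa + ikatp + il + isoc) / parms[CM];
  ydot[1] = (inact(v, parms[VH_NA], parms[SH_NA]) - hna) / parms[TAUH_NA];
  ydot[2] = (act(v, parms[VN_KDR], parms[SN_KDR]) - n) / parms[TAUN_KDR];
  ydot[3] = (inact(v, parms[VH_CAT], parms[SH_CAT]) - hcat) / parms[TAUH_CAT];
  ydot[4] = (inact(v, parms[VH_KA], parms[SH_KA]) - hka) / parms[TAUH_KA];
  ydot[5] = -parms[KIN] * ica_aa - parms[KOUT] * (cac - parms[CA0]);

  yout[0] = ina_aa;
  yout[1] = ica_aa;
  yout[2] = ik_aa;
  yout[3] = ikatp;
  yout[4] = il;
  yout[5] = isoc;
  yout[6] = parms[FCA] * ical;
  yout[7] = parms[FCA] * icapq;
  yout[8] = parms[FCA] * icat;
}
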