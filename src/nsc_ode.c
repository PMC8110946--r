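/* Right-hand sides of the dormant/resting/active NSC compartment model,
 * in the deSolve compiled-model interface.
 *
 * Parameter vector (shared by both systems):
 *   0 alpha_d0   1 theta   2 rho   3 k_div   4 p_rest   5 p_active
 *   6 slope_rest 7 slope_cycle
 *   8 lab_mode (0/1: EdU labeling enabled)  9 w0  10 w_eff
 *   (labeling is active while w0 <= t <= w_eff)
 *
 * Base system (4 states): D, R, A, Dep.
 *
 * Labeled system (8 states): D, RU, RL, AU, AL, Dep, ZRU, ZRL.
 *   RU/RL, AU/AL: unlabeled/labeled resting and active cells. During the
 *   labeling window every division completion marks the persisting NSC as
 *   labeled, so unlabeled active cells exit AU on any division (to RL, AL
 *   or depletion).
 *   ZRU/ZRL: cells currently resting whose last return to rest happened
 *   after the last reset of Z (dZ/dt = influx - alpha_r Z); the caller
 *   resets Z at (t_obs - Ki67 perdurance) so that Z(t_obs) counts resting
 *   cells still within the Ki67 perdurance window.
 */
#include <R.h>

static double parms[11];
#define P_ALPHA_D0  parms[0]
#define P_THETA     parms[1]
#define P_RHO       parms[2]
#define P_KDIV      parms[3]
#define P_PREST     parms[4]
#define P_PACTIVE   parms[5]
#define P_SLOPER    parms[6]
#define P_SLOPEC    parms[7]
#define P_LABMODE   parms[8]
#define P_W0        parms[9]
#define P_WEFF      parms[10]

void nsc_initparms(void (*odeparms)(int *, double *)) {
  int n = 11;
  odeparms(&n, parms);
}

static void rates_at(double t, double *aD, double *aR, double *k,
                     double *pr, double *pd) {
  *aD = P_ALPHA_D0 * exp(-P_THETA * t);
  *aR = P_RHO * (*aD);
  *k = P_KDIV + P_SLOPEC * t;
  if (*k < 1e-10) *k = 1e-10;
  *pr = P_PREST + P_SLOPER * t;
  if (*pr < 0.0) *pr = 0.0;
  if (*pr > 1.0 - P_PACTIVE) *pr = 1.0 - P_PACTIVE;
  *pd = 1.0 - P_PACTIVE - *pr;
}

void nsc_base_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip) {
  double aD, aR, k, pr, pd;
  rates_at(*t, &aD, &aR, &k, &pr, &pd);
  double D = y[0], R = y[1], A = y[2];
  ydot[0] = -aD * D;
  ydot[1] = pr * k * A - aR * R;
  ydot[2] = aD * D + aR * R - (1.0 - P_PACTIVE) * k * A;
  ydot[3] = pd * k * A;
}

void nsc_label_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip) {
  double aD, aR, k, pr, pd;
  rates_at(*t, &aD, &aR, &k, &pr, &pd);
  double D = y[0], RU = y[1], RL = y[2], AU = y[3], AL = y[4];
  double ZRU = y[6], ZRL = y[7];
  double lab = (P_LABMODE != 0.0 && *t >= P_W0 && *t <= P_WEFF) ? 1.0 : 0.0;
  double inRU = (1.0 - lab) * pr * k * AU;
  double inRL = pr * k * AL + lab * pr * k * AU;
  ydot[0] = -aD * D;
  ydot[1] = inRU - aR * RU;                                         /* RU */
  ydot[2] = inRL - aR * RL;                                         /* RL */
  ydot[3] = aD * D + aR * RU
            - k * AU * (lab + (1.0 - lab) * (1.0 - P_PACTIVE));     /* AU */
  ydot[4] = aR * RL + lab * P_PACTIVE * k * AU
            - (1.0 - P_PACTIVE) * k * AL;                           /* AL */
  ydot[5] = pd * k * (AU + AL);                                     /* Dep */
  ydot[6] = inRU - aR * ZRU;                                        /* ZRU */
  ydot[7] = inRL - aR * ZRL;                                        /* ZRL */
}
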