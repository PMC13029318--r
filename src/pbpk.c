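/* Right-hand side of the perfusion-limited whole-body model, in the
 * deSolve compiled-model convention (initfunc + derivs looked up by name).
 *
 * States (amounts, mg):
 *   y[0] arterial blood, y[1] venous blood,
 *   y[2] muscle, y[3] adipose, y[4] kidney, y[5] liver, y[6] rest,
 *   y[7] cumulative amount eliminated.
 *
 * Parameter vector (see .pbpk_parms() on the R side):
 *   0..6   volumes L (art, ven, mus, adi, kid, liv, rest)
 *   7..11  tissue blood flows L/h (mus, adi, kid, liv, rest)
 *   12     cardiac output L/h
 *   13..17 tissue:plasma partition coefficients (mus, adi, kid, liv, rest)
 *   18     blood:plasma ratio
 *   19     renal plasma clearance L/h
 *   20     unspecific plasma clearance L/h (from venous blood)
 *   21     infusion rate mg/h into venous blood
 */
#include <R.h>

static double parms[22];

void pbpk_init(void (*odeparms)(int *, double *))
{
    int n = 22;
    odeparms(&n, parms);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double *V = parms, *Q = parms + 7, *kp = parms + 13;
    const double qco = parms[12], bp = parms[18];
    const double clr = parms[19], clu = parms[20], rin = parms[21];

    double cart = y[0] / V[0];  /* blood concentrations, mg/L */
    double cven = y[1] / V[1];
    double elim_r = clr * cart / bp;  /* filtration of arterial plasma */
    double elim_u = clu * cven / bp;

    double sumq = 0.0, sumqc = 0.0;
    for (int i = 0; i < 5; i++) {
        double cout = y[2 + i] / V[2 + i] * bp / kp[i];
        ydot[2 + i] = Q[i] * (cart - cout);
        sumq += Q[i];
        sumqc += Q[i] * cout;
    }
    ydot[4] -= elim_r;  /* kidney */
    ydot[0] = qco * cven - sumq * cart;
    ydot[1] = sumqc - qco * cven + rin - elim_u;
    ydot[7] = elim_r + elim_u;
}
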