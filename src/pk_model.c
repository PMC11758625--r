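/* Compiled right-hand side of the one-compartment oral 3-HB model for
 * deSolve. States: y[0] = gut amount X (mmol), y[1] = serum concentration
 * C (mM), y[2] = cumulative absorbed amount (mmol).
 * Parameters (in order): CL, C0, ka, Km', Vd, Vmax. */
#include <R.h>

static double parms[6];
#define CL   parms[0]
#define C0   parms[1]
#define KA   parms[2]
#define KM   parms[3]
#define VD   parms[4]
#define VMAX parms[5]

void pk_initmod(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void pk_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double X = y[0];
    double sat = (VMAX > 0.0) ? VMAX * X / (KM + X) : 0.0;
    double absorbed = sat + KA * X;
    ydot[0] = -absorbed;
    ydot[1] = (CL * C0 + absorbed - CL * y[1]) / VD;
    ydot[2] = absorbed;
}
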