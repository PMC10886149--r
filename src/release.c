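/* Right-hand sides of the enzymatic glucose-release model, in the form
 * expected by deSolve's compiled-code interface.  A single call integrates
 * n independent, identically parameterised vessels stacked into one state
 * vector (6 states per vessel: P, S, WS, E, V, Rcum), which keeps the
 * solver-call count low during multi-experiment parameter estimation.
 *
 * Parameter vector (shared across vessels):
 *   p[0]  n       number of stacked vessels
 *   p[1]  kS      catalytic constant, susceptible fraction  [g (U h)^-1]
 *   p[2]  kR      catalytic constant, resistant fraction    [g (U h)^-1]
 *   p[3]  K       Michaelis constant                        [g L^-1]
 *   p[4]  nu      anhydroglucose -> glucose conversion factor
 *   p[5]  r_evap  evaporation rate                          [L h^-1]
 *   p[6]  k1      catalytic constant, single-substrate variants
 *   p[7]  KiP     product-inhibition constant (Inf when unused)
 *   p[8]  KiS     substrate-inhibition constant (Inf when unused)
 *   p[9]  variant 1..7 (see R/variants.R for the tag order)
 *   p[10] eps     zero-substrate threshold for the WS equation
 *
 * States per vessel:
 *   P    free glucose            [g L^-1]
 *   S    total dextrin SS + SR   [g L^-1]
 *   WS   susceptible proportion  [-]
 *   E    enzyme activity         [U L^-1]
 *   V    liquid volume           [L]
 *   Rcum cumulative glucose released by the reaction, dilution-free [g L^-1]
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define NPAR 11
static double p[NPAR];

void enzfeed_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

void enzfeed_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int nsys = (int) p[0];
    int variant = (int) p[9];
    int two = variant >= 5;
    int pin = (variant == 2 || variant == 4 || variant == 6 || variant == 7);
    int sin_ = (variant == 3 || variant == 4 || variant == 7);

    for (int i = 0; i < nsys; i++) {
        double *yi = y + 6 * i;
        double *di = ydot + 6 * i;

        double P  = yi[0] > 0.0 ? yi[0] : 0.0;
        double S  = yi[1] > 0.0 ? yi[1] : 0.0;
        double WS = yi[2];
        double E  = yi[3] > 0.0 ? yi[3] : 0.0;
        double V  = yi[4];
        if (WS < 0.0) WS = 0.0;
        if (WS > 1.0) WS = 1.0;

        double Keff = pin ? p[3] * (1.0 + P / p[7]) : p[3];
        double denom = S + Keff + (sin_ ? S * S / p[8] : 0.0);

        double rS = 0.0, rR = 0.0, R;
        if (two) {
            rS = p[1] * E * WS * S / denom;
            rR = p[2] * E * (1.0 - WS) * S / denom;
            R = rS + rR;
        } else {
            R = p[6] * E * S / denom;
        }

        double dV  = -p[5];
        double dil = dV / V;

        di[0] = p[4] * R - dil * P;
        di[1] = -R - dil * S;
        di[2] = (two && S > p[10]) ? (-rS + WS * R) / S : 0.0;
        di[3] = -dil * E;
        di[4] = dV;
        di[5] = p[4] * R;
    }
}
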