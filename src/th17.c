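/* Right-hand sides of the Th17 core-network ODE system for deSolve.
 *
 * Two variants are provided:
 *   th17_derivs6  - reduced 6-state system in which the intracellular
 *                   cytokine levels enter through their closed-form
 *                   solutions (dose_ratio * (1 - exp(-rate * t)));
 *   th17_derivs10 - full 10-state system in which the extracellular ->
 *                   intracellular cytokine conversion is integrated
 *                   explicitly (used for mass-balance validation).
 *
 * Parameter layout (shared, length 20):
 *   parms[0..17]  theta_1 .. theta_18 (inactive mechanisms carry 0)
 *   parms[18]     il6_added / il6_input   (dimensionless dose ratio)
 *   parms[19]     tgfb_added / tgfb_input (dimensionless dose ratio)
 *
 * State layout, 6-state system:
 *   y[0] stat3_mrna, y[1] stat3_prot, y[2] stat3_prot_star,
 *   y[3] rorgt_mrna, y[4] foxp3_mrna, y[5] foxp3_prot_star
 * State layout, 10-state system:
 *   y[0] il6_ext, y[1] il6_int, y[2] tgfb_ext, y[3] tgfb_int,
 *   y[4..9] as y[0..5] above.
 */

#include <R.h>
#include <math.h>

static double parms[20];
#define TH(i) parms[(i) - 1]
#define IL6_RATIO parms[18]
#define TGFB_RATIO parms[19]

void th17_initmod(void (*odeparms)(int *, double *))
{
    int n = 20;
    odeparms(&n, parms);
}

static void core_derivs(const double *y, double il6_int, double tgfb_int,
                        double *ydot)
{
    const double s_m = y[0], s_p = y[1], s_s = y[2];
    const double r_m = y[3], f_m = y[4], f_s = y[5];

    /* STAT3: basal transcription, autoregulation by phosphoprotein,
     * translation, IL6-driven phosphorylation, first-order decays */
    ydot[0] = TH(2) + TH(3) * s_s - TH(4) * s_m;
    ydot[1] = TH(5) * s_m - TH(6) * il6_int * s_p - TH(7) * s_p;
    ydot[2] = TH(6) * il6_int * s_p - TH(8) * s_s;

    /* RORgt: joint activation by TGFb and phospho-STAT3, optional
     * inhibition by FOXP3 protein, degradation; no basal term */
    ydot[3] = TH(10) * tgfb_int * s_s - TH(11) * f_s * r_m - TH(12) * r_m;

    /* FOXP3: optional basal and TGFb-driven production, optional
     * inhibition by phospho-STAT3, degradation */
    ydot[4] = TH(13) + TH(14) * tgfb_int - TH(15) * s_s * f_m - TH(16) * f_m;
    ydot[5] = TH(17) * f_m - TH(18) * f_s;
}

void th17_derivs6(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const double il6_int = IL6_RATIO * (1.0 - exp(-TH(1) * *t));
    const double tgfb_int = TGFB_RATIO * (1.0 - exp(-TH(9) * *t));
    core_derivs(y, il6_int, tgfb_int, ydot);
}

void th17_derivs10(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    ydot[0] = -TH(1) * y[0];
    ydot[1] = TH(1) * y[0];
    ydot[2] = -TH(9) * y[2];
    ydot[3] = TH(9) * y[2];
    core_derivs(y + 4, y[1], y[3], ydot + 4);
}
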