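/* Compiled right-hand sides for the three-region Pdu pathway model.
 *
 * Parameter vector layout (see rhs_constants() on the R side):
 *  0 kA_comp   shell permeability x effective area per compartment (um^3/h)
 *  1 V_comp    volume per compartment (um^3)
 *  2 count     compartments per cell
 *  3 V_cyt     cytosol volume (um^3)
 *  4 kmA_cell  membrane permeability x membrane area (um^3/h)
 *  5..9        membrane permeability flags per species (0/1)
 * 10..21       vC kmC vP kmP vPr kmPr vQ kmQ vQr kmQr vL kmL
 *              (lumen vmax values already carry the enzyme-scaling factor)
 *
 * Two forcings: (1) log(cell density in cells/mL) — linear interpolation of
 * this forcing realizes the piecewise log-linear growth contract — and
 * (2) the specific growth rate d log(n)/dt (1/h) driving intracellular
 * dilution (supplied as 0 when dilution is disabled).
 */
#include <R.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 22
static double parms[N_PARMS];
static double forc[2];

void pdu_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void pdu_initforc(void (*odeforcs)(int *, double *))
{
    int n = 2;
    odeforcs(&n, forc);
}

static double mm(double s, double v, double k)
{
    if (s < 0.0) s = 0.0;
    return v * s / (k + s);
}

void pdu_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double kA = parms[0], Vc = parms[1], n = parms[2], Vcyt = parms[3],
                 kmA = parms[4];
    const double *mem = parms + 5;
    const double vC = parms[10], kmC = parms[11], vP = parms[12],
                 kmP = parms[13], vPr = parms[14], kmPr = parms[15],
                 vQ = parms[16], kmQ = parms[17], vQr = parms[18],
                 kmQr = parms[19], vL = parms[20], kmL = parms[21];
    const double *lum = y, *cyt = y + 5, *ext = y + 10;
    double rho = exp(forc[0]) * 1e-12; /* cells/mL -> cells/um^3 */
    double mu = forc[1];               /* dilution by growth, 1/h */
    int i;

    double R_CDE = mm(lum[0], vC, kmC);
    double R_P = mm(lum[1], vP, kmP) - mm(lum[2], vPr, kmPr);
    double R_Q = mm(lum[1], vQ, kmQ) - mm(lum[3], vQr, kmQr);
    double R_LW = mm(cyt[2], vL, kmL);

    for (i = 0; i < 5; i++) {
        double Tl = (kA / Vc) * (cyt[i] - lum[i]);
        double Tc = (kA * n / Vcyt) * (lum[i] - cyt[i]);
        double Tm = (kmA / Vcyt) * mem[i] * (ext[i] - cyt[i]);
        ydot[i] = Tl - mu * lum[i];
        ydot[5 + i] = Tc + Tm - mu * cyt[i];
        ydot[10 + i] = -rho * kmA * mem[i] * (ext[i] - cyt[i]);
    }
    ydot[0] += -R_CDE;
    ydot[1] += R_CDE - R_P - R_Q;
    ydot[2] += R_P;
    ydot[3] += R_Q;
    ydot[7] += -R_LW;
    ydot[9] += R_LW;
}

void pdu_derivs_wm(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double Vc = parms[1], n = parms[2], Vcyt = parms[3], kmA = parms[4];
    const double *mem = parms + 5;
    const double f = Vc * n / Vcyt; /* lumen enzymes diluted into cytosol */
    const double vC = parms[10] * f, kmC = parms[11], vP = parms[12] * f,
                 kmP = parms[13], vPr = parms[14] * f, kmPr = parms[15],
                 vQ = parms[16] * f, kmQ = parms[17], vQr = parms[18] * f,
                 kmQr = parms[19], vL = parms[20], kmL = parms[21];
    const double *cyt = y, *ext = y + 5;
    double rho = exp(forc[0]) * 1e-12;
    double mu = forc[1];
    int i;

    double R_CDE = mm(cyt[0], vC, kmC);
    double R_P = mm(cyt[1], vP, kmP) - mm(cyt[2], vPr, kmPr);
    double R_Q = mm(cyt[1], vQ, kmQ) - mm(cyt[3], vQr, kmQr);
    double R_LW = mm(cyt[2], vL, kmL);

    for (i = 0; i < 5; i++) {
        double Tm = (kmA / Vcyt) * mem[i] * (ext[i] - cyt[i]);
        ydot[i] = Tm - mu * cyt[i];
        ydot[5 + i] = -rho * kmA * mem[i] * (ext[i] - cyt[i]);
    }
    ydot[0] += -R_CDE;
    ydot[1] += R_CDE - R_P - R_Q;
    ydot[2] += R_P - R_LW;
    ydot[3] += R_Q;
    ydot[4] += R_LW;
}

static const R_CMethodDef CEntries[] = {
    {"pdu_initmod", (DL_FUNC) &pdu_initmod, 1},
    {"pdu_initforc", (DL_FUNC) &pdu_initforc, 1},
    {"pdu_derivs", (DL_FUNC) &pdu_derivs, 6},
    {"pdu_derivs_wm", (DL_FUNC) &pdu_derivs_wm, 6},
    {NULL, NULL, 0}
};

void R_init_pdukinetics(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
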