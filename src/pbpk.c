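/* Whole-body perfusion-limited PBPK right-hand side with a mechanistic
 * kidney submodel (glomerular filtration, OAT3 basolateral uptake, NPT1
 * apical efflux, intracellular DPEP1 metabolism) and an optional dialyzer
 * elimination flux. Used through deSolve's compiled-model interface; the
 * R driver integrates piecewise between infusion/dialysis discontinuities
 * and passes the segment-constant infusion rate and dialyzer clearance in
 * the parameter vector.
 *
 * Internal units: amounts umol, volumes L, flows L/min, time min.
 *
 * Parameter vector layout (see R/pbpk_core.R, .pbpk_parms_vector):
 *  [0]  V_ven        venous plasma volume
 *  [1]  V_art        arterial plasma volume
 *  [2]  V_lung
 *  [3]  Kp_lung
 *  [4..13]   V_i     ten perfused organs (heart, brain, muscle, adipose,
 *                    skin, bone, liver, gut, spleen, rest)
 *  [14..23]  Kp_i
 *  [24..33]  Q_i     organ plasma flows
 *  [34] Q_co         cardiac output (plasma)
 *  [35] Q_kid        renal plasma flow
 *  [36] Vk_app       apparent kidney volume (vascular plasma + Kp*tissue)
 *  [37] V_cell       proximal-tubule-cell volume
 *  [38] k_lumen      first-order lumen -> urine drain rate (1/min)
 *  [39] fu           fraction unbound in plasma
 *  [40] GFRf         gfr_fraction * GFR (L/min), acts on unbound kidney plasma
 *  [41] VmaxO [42] KmO   OAT3 uptake   (umol/min total; umol/L)
 *  [43] VmaxN [44] KmN   NPT1 efflux
 *  [45] VmaxD [46] KmD   DPEP1 metabolism
 *  [47] R_inf        zero-order infusion rate into venous plasma (umol/min)
 *  [48] CL_hd        dialyzer clearance on arterial plasma (L/min; 0 = off)
 *
 * State layout (amounts, umol):
 *  y[0] venous plasma   y[1] arterial plasma   y[2] lung
 *  y[3..12] organs (order as above)
 *  y[13] kidney (apparent)   y[14] tubule cell   y[15] tubular lumen
 *  y[16] urine sink   y[17] metabolized sink   y[18] dialyzed sink
 */

#include <R.h>

#define N_PARMS 49
#define N_STATE 19

static double p[N_PARMS];

void pbpk_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

static double mm(double vmax, double km, double c)
{
    if (c <= 0.0) return 0.0;
    return vmax * c / (km + c);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int i;
    double Vven = p[0], Vart = p[1], Vlung = p[2], Kplung = p[3];
    double Qco = p[34], Qkid = p[35];
    double Vkapp = p[36], Vcell = p[37], klu = p[38];
    double fu = p[39], GFRf = p[40];
    double Rinf = p[47], CLhd = p[48];

    double Cven = y[0] / Vven;
    double Cart = y[1] / Vart;
    double Clung = y[2] / (Vlung * Kplung);

    double sumQ = 0.0, sumIn = 0.0;
    for (i = 0; i < 10; i++) {
        double V = p[4 + i], Kp = p[14 + i], Q = p[24 + i];
        double Ci = y[3 + i] / (V * Kp); /* plasma-equivalent outflow conc */
        ydot[3 + i] = Q * (Cart - Ci);
        sumQ += Q;
        sumIn += Q * Ci;
    }

    /* glomerular filtration acts on arterial (pre-glomerular) unbound
     * plasma; tubular uptake on peritubular kidney plasma */
    double filt = GFRf * fu * Cart;
    double Ckp = y[13] / Vkapp;           /* kidney plasma concentration */
    double Cu = fu * Ckp;                 /* unbound */
    double upt = mm(p[41], p[42], Cu);    /* OAT3 plasma -> cell */
    ydot[13] = Qkid * (Cart - Ckp) - upt;

    double Ccell = y[14] / Vcell;
    double npt = mm(p[43], p[44], Ccell); /* NPT1 cell -> lumen */
    double dpe = mm(p[45], p[46], Ccell); /* DPEP1 cell -> metabolites */
    ydot[14] = upt - npt - dpe;

    ydot[15] = filt + npt - klu * y[15];  /* tubular lumen */
    ydot[16] = klu * y[15];               /* urine sink */
    ydot[17] = dpe;                       /* metabolized sink */

    double dial = CLhd * Cart;
    ydot[18] = dial;                      /* dialyzed sink */

    ydot[2] = Qco * (Cven - Clung);
    ydot[1] = Qco * Clung - (sumQ + Qkid) * Cart - filt - dial;
    ydot[0] = sumIn + Qkid * Ckp - Qco * Cven + Rinf;
}
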