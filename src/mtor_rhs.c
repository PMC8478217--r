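/* Compiled right-hand side of the mTOR switch ODE family for deSolve.
 *
 * Parameter vector layout: the 49 kinetic constants in the order of
 * param_names(), followed by insulin (nM) and three wiring flags:
 * otud7b activated by pIRS (vs pINSR), MLST8 required for mTORC1,
 * mTORC2 activated by pIRS (vs pAKT T308). Kept in lockstep with the
 * pure-R evaluator in R/rates.R (tested to 1e-12).
 */
#include <R.h>

#define N_PARMS 53
static double parms[N_PARMS];

#define k_f1   parms[0]
#define Km_1   parms[1]
#define k_r1   parms[2]
#define k_f1b  parms[3]
#define Km_1b  parms[4]
#define k_f2   parms[5]
#define Km_2   parms[6]
#define k_r2   parms[7]
#define k_f2b  parms[8]
#define Km_2b  parms[9]
#define k_r2b  parms[10]
#define k_f3   parms[11]
#define Km_3   parms[12]
#define k_r3   parms[13]
#define k_f4   parms[14]
#define Km_4   parms[15]
#define k_r4   parms[16]
#define Km_4b  parms[17]
#define k_f5   parms[18]
#define k_r5   parms[19]
#define k_f6   parms[20]
#define k_r6   parms[21]
#define k_f7   parms[22]
#define Km_7   parms[23]
#define k_f7b  parms[24]
#define k_r7   parms[25]
#define k_f8   parms[26]
#define Km_8   parms[27]
#define k_r8   parms[28]
#define k_f9   parms[29]
#define Km_9   parms[30]
#define k_r9   parms[31]
#define k_f10a parms[32]
#define Km_10a parms[33]
#define k_f10b parms[34]
#define Km_10b parms[35]
#define k_r10a parms[36]
#define k_r10b parms[37]
#define k_f11a parms[38]
#define k_i1   parms[39]
#define k_r11  parms[40]
#define k_f11b parms[41]
#define Km_11b parms[42]
#define k_r11b parms[43]
#define k_f12a parms[44]
#define Km_12a parms[45]
#define k_f12b parms[46]
#define Km_12b parms[47]
#define k_r12  parms[48]
#define INS    parms[49]
#define F_OTUD_IRS parms[50]
#define F_MLST8    parms[51]
#define F_M2_IRS   parms[52]

/* species indices */
#define iINSR 0
#define ipINSR 1
#define iIRSs 2
#define ipIRS 3
#define iiIRS 4
#define iOTUD 5
#define iaOTUD 6
#define iM8 7
#define iM8ub 8
#define iSIN1 9
#define iRAP 10
#define iC2 11
#define iaC2 12
#define iC1i 13
#define iC1a 14
#define iAKT 15
#define ipT308 16
#define ipS473 17
#define ippAKT 18
#define iTSC2a 19
#define ipTSC2 20
#define iS6K 21
#define ipS6K 22
#define iTRAF2 23

void mtor_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double mm(double kcat, double E, double S, double Km)
{
    return kcat * E * S / (Km + S);
}

void mtor_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double otud_enz = (F_OTUD_IRS > 0.5) ? y[ipIRS] : y[ipINSR];
    double m2_enz   = (F_M2_IRS > 0.5) ? y[ipIRS] : y[ipT308];

    double v_insr_act  = mm(k_f1, INS, y[iINSR], Km_1);
    double v_insr_de   = k_r1 * y[ipINSR];
    double v_insr_fb   = mm(k_f1b, y[iC1a], y[ipINSR], Km_1b);
    double v_irs_ph    = mm(k_f2, y[ipINSR], y[iIRSs], Km_2);
    double v_irs_de    = k_r2 * y[ipIRS];
    double v_irs_inh   = mm(k_f2b, y[ipS6K], y[ipIRS], Km_2b);
    double v_irs_rec   = k_r2b * y[iiIRS];
    double v_otud_act  = mm(k_f3, otud_enz, y[iOTUD], Km_3);
    double v_otud_de   = k_r3 * y[iaOTUD];
    double v_ub        = mm(k_f4, y[iTRAF2], y[iM8], Km_4);
    double v_deub      = mm(k_r4, y[iaOTUD], y[iM8ub], Km_4b);
    double v_c2_on     = k_f6 * y[iM8] * y[iSIN1];
    double v_c2_off    = k_r6 * y[iC2];
    double v_c2_act    = mm(k_f7, m2_enz, y[iC2], Km_7) + k_f7b * y[iC2];
    double v_c2_de     = k_r7 * y[iaC2];
    double v_t308      = mm(k_f8, y[ipIRS], y[iAKT], Km_8);
    double v_t308_de   = k_r8 * y[ipT308];
    double v_s473      = mm(k_f9, y[iaC2], y[iAKT], Km_9);
    double v_s473_de   = k_r9 * y[ipS473];
    double v_pp_a      = mm(k_f10a, y[iaC2], y[ipT308], Km_10a);
    double v_pp_b      = mm(k_f10b, y[ipIRS], y[ipS473], Km_10b);
    double v_pp_de_a   = k_r10a * y[ippAKT]; /* -> pAKT_T308 */
    double v_pp_de_b   = k_r10b * y[ippAKT]; /* -> pAKT_S473 */
    double v_c1_act    = k_f11a * y[iC1i] / (1.0 + y[iTSC2a] / k_i1);
    double v_c1_de     = k_r11 * y[iC1a];
    double v_s6k       = mm(k_f11b, y[iC1a], y[iS6K], Km_11b);
    double v_s6k_de    = k_r11b * y[ipS6K];
    double v_tsc_a     = mm(k_f12a, y[ipT308], y[iTSC2a], Km_12a);
    double v_tsc_b     = mm(k_f12b, y[ippAKT], y[iTSC2a], Km_12b);
    double v_tsc_de    = k_r12 * y[ipTSC2];

    double v_c1_on = 0.0, v_c1_off = 0.0;
    if (F_MLST8 > 0.5) {
        v_c1_on  = k_f5 * y[iM8ub] * y[iRAP];
        v_c1_off = k_r5 * y[iC1i];
    }

    ydot[iINSR]  = -v_insr_act + v_insr_de + v_insr_fb;
    ydot[ipINSR] =  v_insr_act - v_insr_de - v_insr_fb;
    ydot[iIRSs]  = -v_irs_ph + v_irs_de + v_irs_rec;
    ydot[ipIRS]  =  v_irs_ph - v_irs_de - v_irs_inh;
    ydot[iiIRS]  =  v_irs_inh - v_irs_rec;
    ydot[iOTUD]  = -v_otud_act + v_otud_de;
    ydot[iaOTUD] =  v_otud_act - v_otud_de;
    ydot[iM8]    = -v_ub + v_deub - v_c2_on + v_c2_off;
    ydot[iM8ub]  =  v_ub - v_deub - v_c1_on + v_c1_off;
    ydot[iSIN1]  = -v_c2_on + v_c2_off;
    ydot[iRAP]   = -v_c1_on + v_c1_off;
    ydot[iC2]    =  v_c2_on - v_c2_off - v_c2_act + v_c2_de;
    ydot[iaC2]   =  v_c2_act - v_c2_de;
    ydot[iC1i]   =  v_c1_on - v_c1_off - v_c1_act + v_c1_de;
    ydot[iC1a]   =  v_c1_act - v_c1_de;
    ydot[iAKT]   = -v_t308 - v_s473 + v_t308_de + v_s473_de;
    ydot[ipT308] =  v_t308 - v_t308_de - v_pp_a + v_pp_de_a;
    ydot[ipS473] =  v_s473 - v_s473_de - v_pp_b + v_pp_de_b;
    ydot[ippAKT] =  v_pp_a + v_pp_b - v_pp_de_a - v_pp_de_b;
    ydot[iTSC2a] = -v_tsc_a - v_tsc_b + v_tsc_de;
    ydot[ipTSC2] =  v_tsc_a + v_tsc_b - v_tsc_de;
    ydot[iS6K]   = -v_s6k + v_s6k_de;
    ydot[ipS6K]  =  v_s6k - v_s6k_de;
    ydot[iTRAF2] = 0.0;
}
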