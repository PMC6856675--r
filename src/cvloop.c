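/* Closed-loop 0D cardiovascular model: compiled right-hand side for deSolve.
 *
 * State (14): V_lv V_la V_rv V_ra | P_sas P_sat P_svn P_pas P_pat P_pvn |
 *             Q_sas Q_sat Q_pas Q_pat
 * Output (10): P_lv P_la P_rv P_ra | Q_ao Q_mi Q_ti Q_po | Q_svn Q_pvn
 * Units: mmHg, ml, s throughout.
 *
 * Parameter order must match .pack_params() in R/model.R.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 41

static double parms[N_PARMS];

#define P_T       parms[0]
#define P_Ts1     parms[1]
#define P_Ts2     parms[2]
#define P_Tpwb    parms[3]
#define P_Tpww    parms[4]
#define P_Elv_max parms[5]
#define P_Elv_min parms[6]
#define P_Vlv0    parms[7]
#define P_Ela_max parms[8]
#define P_Ela_min parms[9]
#define P_Vla0    parms[10]
#define P_Erv_max parms[11]
#define P_Erv_min parms[12]
#define P_Vrv0    parms[13]
#define P_Era_max parms[14]
#define P_Era_min parms[15]
#define P_Vra0    parms[16]
#define P_CQ_ao   parms[17]
#define P_CQ_mi   parms[18]
#define P_CQ_ti   parms[19]
#define P_CQ_po   parms[20]
#define P_R_sas   parms[21]
#define P_C_sas   parms[22]
#define P_L_sas   parms[23]
#define P_R_sat   parms[24]
#define P_C_sat   parms[25]
#define P_L_sat   parms[26]
#define P_R_sar   parms[27]
#define P_R_scp   parms[28]
#define P_R_svn   parms[29]
#define P_C_svn   parms[30]
#define P_R_pas   parms[31]
#define P_C_pas   parms[32]
#define P_L_pas   parms[33]
#define P_R_pat   parms[34]
#define P_C_pat   parms[35]
#define P_L_pat   parms[36]
#define P_R_par   parms[37]
#define P_R_pcp   parms[38]
#define P_R_pvn   parms[39]
#define P_C_pvn   parms[40]

void cv_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* ventricular activation: cosine rise on [0, Ts1), fall on [Ts1, Ts2), 0 after */
static double act_ventricle(double t)
{
    double tc = fmod(t, P_T);
    if (tc < 0.0) tc += P_T;
    if (tc < P_Ts1)
        return 0.5 * (1.0 - cos(M_PI * tc / P_Ts1));
    if (tc < P_Ts2)
        return 0.5 * (1.0 + cos(M_PI * (tc - P_Ts1) / (P_Ts2 - P_Ts1)));
    return 0.0;
}

/* atrial activation: full-cosine bump of width Tpww starting at Tpwb (wraps) */
static double act_atrium(double t)
{
    double tc = fmod(t - P_Tpwb, P_T);
    if (tc < 0.0) tc += P_T;
    if (tc < P_Tpww)
        return 0.5 * (1.0 - cos(2.0 * M_PI * tc / P_Tpww));
    return 0.0;
}

static double valve_q(double p_up, double p_down, double cq)
{
    double dp = p_up - p_down;
    return dp > 0.0 ? cq * sqrt(dp) : 0.0;
}

void cv_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double ev, ea, Plv, Pla, Prv, Pra;
    double Qao, Qmi, Qti, Qpo, Qsvn, Qpvn;

    double Vlv = y[0], Vla = y[1], Vrv = y[2], Vra = y[3];
    double Psas = y[4], Psat = y[5], Psvn = y[6];
    double Ppas = y[7], Ppat = y[8], Ppvn = y[9];
    double Qsas = y[10], Qsat = y[11], Qpas = y[12], Qpat = y[13];

    if (ip[0] < 10) error("cv_derivs: nout must be >= 10");

    ev = act_ventricle(*t);
    ea = act_atrium(*t);

    Plv = (P_Elv_min + (P_Elv_max - P_Elv_min) * ev) * (Vlv - P_Vlv0);
    Prv = (P_Erv_min + (P_Erv_max - P_Erv_min) * ev) * (Vrv - P_Vrv0);
    Pla = (P_Ela_min + (P_Ela_max - P_Ela_min) * ea) * (Vla - P_Vla0);
    Pra = (P_Era_min + (P_Era_max - P_Era_min) * ea) * (Vra - P_Vra0);

    Qao  = valve_q(Plv, Psas, P_CQ_ao);
    Qmi  = valve_q(Pla, Plv,  P_CQ_mi);
    Qti  = valve_q(Pra, Prv,  P_CQ_ti);
    Qpo  = valve_q(Prv, Ppas, P_CQ_po);
    Qsvn = (Psvn - Pra) / P_R_svn;
    Qpvn = (Ppvn - Pla) / P_R_pvn;

    ydot[0] = Qmi - Qao;           /* V_lv */
    ydot[1] = Qpvn - Qmi;          /* V_la */
    ydot[2] = Qti - Qpo;           /* V_rv */
    ydot[3] = Qsvn - Qti;          /* V_ra */

    ydot[4] = (Qao - Qsas) / P_C_sas;
    ydot[5] = (Qsas - Qsat) / P_C_sat;
    ydot[6] = (Qsat - Qsvn) / P_C_svn;
    ydot[7] = (Qpo - Qpas) / P_C_pas;
    ydot[8] = (Qpas - Qpat) / P_C_pat;
    ydot[9] = (Qpat - Qpvn) / P_C_pvn;

    ydot[10] = (Psas - Psat - P_R_sas * Qsas) / P_L_sas;
    ydot[11] = (Psat - Psvn - (P_R_sat + P_R_sar + P_R_scp) * Qsat) / P_L_sat;
    ydot[12] = (Ppas - Ppat - P_R_pas * Qpas) / P_L_pas;
    ydot[13] = (Ppat - Ppvn - (P_R_pat + P_R_par + P_R_pcp) * Qpat) / P_L_pat;

    yout[0] = Plv;
    yout[1] = Pla;
    yout[2] = Prv;
    yout[3] = Pra;
    yout[4] = Qao;
    yout[5] = Qmi;
    yout[6] = Qti;
    yout[7] = Qpo;
    yout[8] = Qsvn;
    yout[9] = Qpvn;
}
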