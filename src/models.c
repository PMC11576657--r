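/* Compiled right-hand sides for the ADC disposition models.
 *
 * All states are amounts in nmol, time in days, concentrations in nM,
 * systemic volumes in L, tumor volume in mm^3 (1 mm^3 = 1e-6 L),
 * lengths in cm.  Parameter orderings must stay in sync with R/ode.R.
 */

#include <R.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* ================= in vitro cellular model ================= */

#define NP_CELL 18

enum {
  C_DAR, C_KDEC, C_KON, C_KOFF, C_KCLV, C_KINPL, C_KOUTPL, C_KONPL, C_KOFFPL,
  C_KENDO, C_KENDOB, C_KREC, C_KRECB, C_KDEG, C_KDEGB, C_VMEDIA, C_VCYT, C_TARGC
};

static double pc[NP_CELL];

void cell_init(void (*odeparms)(int *, double *))
{
  int n = NP_CELL;
  odeparms(&n, pc);
}

/* states: 0 ADC_media 1 Ab_media 2 PL_media
 *         3 HER2_surf 4 HER2ADC_surf 5 HER2Ab_surf
 *         6 HER2_endo 7 HER2ADC_endo 8 HER2Ab_endo
 *         9 PL_endo  10 PL_cyto_free 11 PL_cyto_bound
 */
void cell_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
  double cadc = y[0] / pc[C_VMEDIA];
  double cab  = y[1] / pc[C_VMEDIA];
  /* monovalent reversible surface binding, net forward amount-rates */
  double bc = pc[C_KON] * cadc * y[3] - pc[C_KOFF] * y[4];
  double ba = pc[C_KON] * cab  * y[3] - pc[C_KOFF] * y[5];
  /* synthesis exactly replaces degraded receptor: total receptor constant */
  double syn = pc[C_KDEG] * y[6] + pc[C_KDEGB] * (y[7] + y[8]);
  double tfree = pc[C_TARGC] * pc[C_VCYT] - y[11];
  if (tfree < 0.0) tfree = 0.0;
  double cplf = pc[C_VCYT] > 0.0 ? y[10] / pc[C_VCYT] : 0.0;
  double bpl = pc[C_KONPL] * cplf * tfree - pc[C_KOFFPL] * y[11];

  ydot[0]  = -pc[C_KDEC] * y[0] - bc;
  ydot[1]  =  pc[C_KDEC] * y[0] - ba;
  ydot[2]  =  pc[C_DAR] * pc[C_KDEC] * y[0]
              - pc[C_KINPL] * y[2] + pc[C_KOUTPL] * y[10];
  ydot[3]  = -bc - ba - pc[C_KENDO] * y[3] + pc[C_KREC] * y[6] + syn;
  ydot[4]  =  bc - pc[C_KENDOB] * y[4] + pc[C_KRECB] * y[7];
  ydot[5]  =  ba - pc[C_KENDOB] * y[5] + pc[C_KRECB] * y[8];
  ydot[6]  =  pc[C_KENDO] * y[3] - (pc[C_KREC] + pc[C_KDEG]) * y[6];
  ydot[7]  =  pc[C_KENDOB] * y[4]
              - (pc[C_KRECB] + pc[C_KDEGB] + pc[C_KCLV]) * y[7];
  ydot[8]  =  pc[C_KENDOB] * y[5] - (pc[C_KRECB] + pc[C_KDEGB]) * y[8]
              + pc[C_KCLV] * y[7];
  ydot[9]  =  pc[C_DAR] * (pc[C_KDEGB] + pc[C_KCLV]) * y[7]
              - pc[C_KINPL] * y[9];
  ydot[10] =  pc[C_KINPL] * (y[9] + y[2]) - pc[C_KOUTPL] * y[10] - bpl;
  ydot[11] =  bpl;
}

/* ================= in vivo model (mouse/human + tumor + TGI) ========= */

#define NP_VIVO 51

enum {
  I_DAR, I_KDEC, I_KON, I_KOFF, I_KCLV, I_KINPL, I_KOUTPL, I_KONPL, I_KOFFPL,
  I_KENDO, I_KENDOB, I_KREC, I_KRECB, I_KDEG, I_KDEGB,
  I_K12, I_K21, I_KELAB, I_K12PL, I_K21PL, I_KELPL,
  I_VC, I_VP,
  I_KSHED, I_KELS, I_KELSB,
  I_TARGC, I_RDENS, I_FCELL, I_EPSAB, I_EPSPL,
  I_DAB, I_PAB, I_DPL, I_PPL, I_RCAP, I_RKR, I_EXMODE,
  I_KEXP, I_KLIN, I_VMAX, I_PSI, I_KKILL, I_KC50, I_KTAU,
  I_GROWTH, I_KFREEONLY, I_FTUMOR, I_FSURF,
  I_INFRATE, I_INFTARGET
};

static double pv[NP_VIVO];

void vivo_init(void (*odeparms)(int *, double *))
{
  int n = NP_VIVO;
  odeparms(&n, pv);
}

/* state layout (0-based):
 *  0 ADC_c   1 ADC_p   2 Ab_c   3 Ab_p   4 PL_c   5 PL_p
 *  6 sHER2_c 7 sHER2ADC_c 8 sHER2Ab_c  9 sHER2_p 10 sHER2ADC_p 11 sHER2Ab_p
 * 12..17 healthy central:  R_s RC_s RA_s R_e RC_e RA_e
 * 18..23 healthy peripheral: same order
 * 24 ADC_t 25 Ab_t 26 PL_t        (tumor extracellular)
 * 27..32 tumor cell receptors: R_s RC_s RA_s R_e RC_e RA_e
 * 33 PL_endo_t 34 PL_cytofree_t 35 PL_cytobound_t
 * 36 N1 37 N2 38 N3 39 N4        (tumor cell masses, mm^3)
 */
void vivo_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
  int i;
  for (i = 0; i < 40; i++) ydot[i] = 0.0;

  double vc = pv[I_VC], vp = pv[I_VP];
  double cadc_c = y[0] / vc, cadc_p = y[1] / vp;
  double cab_c  = y[2] / vc, cab_p  = y[3] / vp;

  /* ---- plasma two-compartment ADC / Ab / payload ---- */
  ydot[0] += -(pv[I_K12] + pv[I_KELAB] + pv[I_KDEC]) * y[0] + pv[I_K21] * y[1];
  ydot[1] +=  pv[I_K12] * y[0] - (pv[I_K21] + pv[I_KELAB] + pv[I_KDEC]) * y[1];
  ydot[2] +=  pv[I_KDEC] * y[0] - (pv[I_K12] + pv[I_KELAB]) * y[2]
              + pv[I_K21] * y[3];
  ydot[3] +=  pv[I_KDEC] * y[1] + pv[I_K12] * y[2]
              - (pv[I_K21] + pv[I_KELAB]) * y[3];
  ydot[4] +=  pv[I_DAR] * pv[I_KDEC] * y[0]
              - (pv[I_K12PL] + pv[I_KELPL]) * y[4] + pv[I_K21PL] * y[5];
  ydot[5] +=  pv[I_DAR] * pv[I_KDEC] * y[1] + pv[I_K12PL] * y[4]
              - (pv[I_K21PL] + pv[I_KELPL]) * y[5];

  /* ---- soluble receptor species: binding, elimination, distribution ---- */
  {
    double bS_c = pv[I_KON] * cadc_c * y[6] - pv[I_KOFF] * y[7];
    double bA_c = pv[I_KON] * cab_c  * y[6] - pv[I_KOFF] * y[8];
    double bS_p = pv[I_KON] * cadc_p * y[9] - pv[I_KOFF] * y[10];
    double bA_p = pv[I_KON] * cab_p  * y[9] - pv[I_KOFF] * y[11];

    ydot[6]  += -bS_c - bA_c - pv[I_KELS]  * y[6]  - pv[I_K12] * y[6]
                + pv[I_K21] * y[9];
    ydot[7]  +=  bS_c - pv[I_KELSB] * y[7]  - pv[I_K12] * y[7]
                + pv[I_K21] * y[10];
    ydot[8]  +=  bA_c - pv[I_KELSB] * y[8]  - pv[I_K12] * y[8]
                + pv[I_K21] * y[11];
    ydot[9]  += -bS_p - bA_p - pv[I_KELS]  * y[9]  + pv[I_K12] * y[6]
                - pv[I_K21] * y[9];
    ydot[10] +=  bS_p - pv[I_KELSB] * y[10] + pv[I_K12] * y[7]
                - pv[I_K21] * y[10];
    ydot[11] +=  bA_p - pv[I_KELSB] * y[11] + pv[I_K12] * y[8]
                - pv[I_K21] * y[11];

    ydot[0] += -bS_c;  ydot[1] += -bS_p;
    ydot[2] += -bA_c;  ydot[3] += -bA_p;
  }

  /* ---- healthy-cell receptor blocks (central k = 0, peripheral k = 1) --- */
  for (int k = 0; k < 2; k++) {
    int o = 12 + 6 * k;                 /* receptor block offset */
    double cadc = k == 0 ? cadc_c : cadc_p;
    double cab  = k == 0 ? cab_c  : cab_p;
    int iadc = k, iab = 2 + k, ipl = 4 + k, isol = 6 + 3 * k;

    double bc = pv[I_KON] * cadc * y[o] - pv[I_KOFF] * y[o + 1];
    double ba = pv[I_KON] * cab  * y[o] - pv[I_KOFF] * y[o + 2];
    double shed_tot = pv[I_KSHED] * (y[o] + y[o + 1] + y[o + 2]);
    double syn = pv[I_KDEG] * y[o + 3]
               + pv[I_KDEGB] * (y[o + 4] + y[o + 5]) + shed_tot;

    ydot[o]     += -bc - ba - pv[I_KENDO] * y[o] + pv[I_KREC] * y[o + 3]
                   - pv[I_KSHED] * y[o] + syn;
    ydot[o + 1] +=  bc - pv[I_KENDOB] * y[o + 1] + pv[I_KRECB] * y[o + 4]
                   - pv[I_KSHED] * y[o + 1];
    ydot[o + 2] +=  ba - pv[I_KENDOB] * y[o + 2] + pv[I_KRECB] * y[o + 5]
                   - pv[I_KSHED] * y[o + 2];
    ydot[o + 3] +=  pv[I_KENDO] * y[o] - (pv[I_KREC] + pv[I_KDEG]) * y[o + 3];
    ydot[o + 4] +=  pv[I_KENDOB] * y[o + 1]
                   - (pv[I_KRECB] + pv[I_KDEGB] + pv[I_KCLV]) * y[o + 4];
    ydot[o + 5] +=  pv[I_KENDOB] * y[o + 2]
                   - (pv[I_KRECB] + pv[I_KDEGB]) * y[o + 5]
                   + pv[I_KCLV] * y[o + 4];

    /* drug bound/unbound bookkeeping */
    ydot[iadc] += -bc;
    ydot[iab]  += -ba;
    /* catabolized / cleaved payload released to the compartment pool */
    ydot[ipl]  += pv[I_DAR] * (pv[I_KDEGB] + pv[I_KCLV]) * y[o + 4];
    /* shed membrane species feed soluble pools of the same compartment */
    ydot[isol]     += pv[I_KSHED] * y[o];
    ydot[isol + 1] += pv[I_KSHED] * y[o + 1];
    ydot[isol + 2] += pv[I_KSHED] * y[o + 2];
  }

  /* ---- tumor compartment ---- */
  if (pv[I_FTUMOR] > 0.5) {
    double vt = y[36] + y[37] + y[38] + y[39];      /* mm^3 */
    if (vt < 1e-9) vt = 1e-9;
    double vt_l = vt * 1e-6;                        /* L */
    double rtum_cm = 0.1 * cbrt(3.0 * vt / (4.0 * M_PI)); /* mm -> cm */

    double ks_ab = 6.0 * pv[I_DAB] / (rtum_cm * rtum_cm);
    double kv_ab = 2.0 * pv[I_PAB] * pv[I_RCAP] / (pv[I_RKR] * pv[I_RKR]);
    double ks_pl = 6.0 * pv[I_DPL] / (rtum_cm * rtum_cm);
    double kv_pl = 2.0 * pv[I_PPL] * pv[I_RCAP] / (pv[I_RKR] * pv[I_RKR]);
    double kex_ab, kex_pl;
    if (pv[I_EXMODE] > 0.5) {        /* hard switch: dominant mechanism */
      kex_ab = ks_ab > kv_ab ? ks_ab : kv_ab;
      kex_pl = ks_pl > kv_pl ? ks_pl : kv_pl;
    } else {                         /* default: sum of both routes */
      kex_ab = ks_ab + kv_ab;
      kex_pl = ks_pl + kv_pl;
    }

    /* accessible-volume driving force */
    double cadc_t = y[24] / vt_l / pv[I_EPSAB];
    double cab_t  = y[25] / vt_l / pv[I_EPSAB];
    double cpl_t  = y[26] / vt_l / pv[I_EPSPL];
    double f_adc = kex_ab * vt_l * (cadc_c - cadc_t);
    double f_ab  = kex_ab * vt_l * (cab_c  - cab_t);
    double f_pl  = kex_pl * vt_l * (y[4] / vc - cpl_t);

    ydot[0] += -f_adc;  ydot[2] += -f_ab;  ydot[4] += -f_pl;

    /* tumor-cell surface binding against interstitial concentrations */
    double bc = pv[I_KON] * cadc_t * y[27] - pv[I_KOFF] * y[28];
    double ba = pv[I_KON] * cab_t  * y[27] - pv[I_KOFF] * y[29];

    ydot[24] += f_adc - pv[I_KDEC] * y[24] - bc;
    ydot[25] += f_ab  + pv[I_KDEC] * y[24] - ba;
    ydot[26] += f_pl  + pv[I_DAR] * pv[I_KDEC] * y[24]
                - pv[I_KINPL] * y[26] + pv[I_KOUTPL] * y[34];

    /* TGI: growth of N1, Michaelis-Menten kill, Erlang-3 transit cascade */
    double vintra = pv[I_FCELL] * vt;               /* L of cytosol */
    double ckill;
    if (pv[I_KFREEONLY] > 0.5)
      ckill = vintra > 0 ? y[34] / vintra : 0.0;
    else
      ckill = vintra > 0 ? (y[34] + y[35]) / vintra : 0.0;
    if (ckill < 0.0) ckill = 0.0;
    double kill = pv[I_KKILL] * ckill / (pv[I_KC50] + ckill);

    double g = 0.0;
    if (pv[I_GROWTH] > 0.5) {
      double sw = pow(1.0 + pow(pv[I_KEXP] * vt / pv[I_KLIN], pv[I_PSI]),
                      1.0 / pv[I_PSI]);
      double cap = 1.0 - vt / pv[I_VMAX];
      g = pv[I_KEXP] * y[36] / sw * cap;   /* cap<0 clips growth below 0 */
    }

    ydot[36] += g - kill * y[36];
    ydot[37] += kill * y[36] - pv[I_KTAU] * y[37];
    ydot[38] += pv[I_KTAU] * (y[37] - y[38]);
    ydot[39] += pv[I_KTAU] * (y[38] - y[39]);

    /* specific removal rate of cell-associated material with dying mass */
    double drem = pv[I_KTAU] * y[39] / vt;
    double gsrc = (g > 0.0 ? g : 0.0) * pv[I_RDENS];

    double shed_tot = pv[I_KSHED] * (y[27] + y[28] + y[29]);
    double syn = pv[I_KDEG] * y[30]
               + pv[I_KDEGB] * (y[31] + y[32]) + shed_tot;

    ydot[27] += -bc - ba - pv[I_KENDO] * y[27] + pv[I_KREC] * y[30]
                - pv[I_KSHED] * y[27] + syn
                + gsrc * pv[I_FSURF] - drem * y[27];
    ydot[28] +=  bc - pv[I_KENDOB] * y[28] + pv[I_KRECB] * y[31]
                - pv[I_KSHED] * y[28] - drem * y[28];
    ydot[29] +=  ba - pv[I_KENDOB] * y[29] + pv[I_KRECB] * y[32]
                - pv[I_KSHED] * y[29] - drem * y[29];
    ydot[30] +=  pv[I_KENDO] * y[27] - (pv[I_KREC] + pv[I_KDEG]) * y[30]
                + gsrc * (1.0 - pv[I_FSURF]) - drem * y[30];
    ydot[31] +=  pv[I_KENDOB] * y[28]
                - (pv[I_KRECB] + pv[I_KDEGB] + pv[I_KCLV]) * y[31]
                - drem * y[31];
    ydot[32] +=  pv[I_KENDOB] * y[29] - (pv[I_KRECB] + pv[I_KDEGB]) * y[32]
                + pv[I_KCLV] * y[31] - drem * y[32];

    /* shed tumor membrane species enter the central soluble pools */
    ydot[6] += pv[I_KSHED] * y[27];
    ydot[7] += pv[I_KSHED] * y[28];
    ydot[8] += pv[I_KSHED] * y[29];

    /* intracellular payload on tumor cells */
    double tfree = pv[I_TARGC] * vintra - y[35];
    if (tfree < 0.0) tfree = 0.0;
    double cplf = vintra > 0 ? y[34] / vintra : 0.0;
    double bpl = pv[I_KONPL] * cplf * tfree - pv[I_KOFFPL] * y[35];

    ydot[33] += pv[I_DAR] * (pv[I_KDEGB] + pv[I_KCLV]) * y[31]
                - pv[I_KINPL] * y[33] - drem * y[33];
    ydot[34] += pv[I_KINPL] * (y[33] + y[26]) - pv[I_KOUTPL] * y[34]
                - bpl - drem * y[34];
    ydot[35] += bpl - drem * y[35];
  }

  /* ---- zero-order infusion into an arbitrary state ---- */
  if (pv[I_INFTARGET] > 0.5)
    ydot[(int) pv[I_INFTARGET] - 1] += pv[I_INFRATE];
}

/* ================= registration ================= */

static const R_CMethodDef cMethods[] = {
  {"cell_init",   (DL_FUNC) &cell_init,   1},
  {"cell_derivs", (DL_FUNC) &cell_derivs, 6},
  {"vivo_init",   (DL_FUNC) &vivo_init,   1},
  {"vivo_derivs", (DL_FUNC) &vivo_derivs, 6},
  {NULL, NULL, 0}
};

void R_init_adcsim(DllInfo *dll)
{
  R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
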