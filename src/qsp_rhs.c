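/* Three-compartment BCMA-CD3 bispecific model: mass-action binding,
 * logistic tumor growth with trimer-occupancy Hill kill, sBCMA sink,
 * paraprotein production, IL-6 pool-depletion release, T-cell trafficking,
 * linear subcutaneous PK.  deSolve compiled-model convention.
 *
 * States (nM unless noted):
 *  0 A      SC depot (nmol)
 *  1 Dc     free drug, central        2 Dp  free drug, peripheral
 *  3 Dbm    free drug, bone marrow
 *  4 Sc     free sBCMA, central       5 Sbm free sBCMA, BM
 *  6 DSc    drug-sBCMA dimer, central 7 DSbm drug-sBCMA dimer, BM
 *  8 DCSc   CD3-drug-sBCMA nonfunctional trimer, central T cells
 *  9 DCSbm  same, BM T cells
 * 10 Bf     free membrane BCMA (BM)  11 DB  drug-BCMA dimer  12 TRI trimer
 * 13 Cbm    free CD3, BM T cells     14 DCbm drug-CD3 dimer, BM
 * 15 Cc     free CD3, central        16 DCc  drug-CD3 dimer, central
 * 17 M      serum M-protein (g/dL)   18 F   serum FLC (mg/L)
 * 19 I      IL-6 (pg/mL)             20 R   releasable IL-6 pool (fraction)
 * 21 elim   cumulative eliminated drug (nmol)
 *
 * Tumor cells and T-cell counts are derived from the receptor pools
 * (receptors/cell conversion applied once in R at state assembly), so the
 * receptor conservation identities hold by construction.
 */

#include <R.h>
#include <math.h>

#define NPARMS 35

static double p[NPARMS];

void qsp_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, p);
}

void qsp_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double ka = p[0], CL = p[1], Vc = p[2], Vp = p[3], Q = p[4],
        qBM = p[5], Vbm = p[6],
        konB = p[7], koffB = p[8], konC = p[9], koffC = p[10], chi = p[11],
        kshed = p[12], kclS = p[13], qS = p[14],
        kmax = p[15], nkill = p[16], akill = p[17], aresis = p[18],
        tfirst = p[19],
        g = p[20], BtotMax = p[21],
        kM = p[22], kelimM = p[23], kF = p[24], kelimF = p[25],
        kin = p[26], kout = p[27], I50 = p[28],
        krelI = p[29], kdegI = p[30], kdep = p[31], krep = p[32],
        solTri = p[33], clampDbm = p[34];

    const double A = y[0], Dc = y[1], Dp = y[2], Dbm = y[3],
        Sc = y[4], Sbm = y[5], DSc = y[6], DSbm = y[7],
        DCSc = y[8], DCSbm = y[9],
        Bf = y[10], DB = y[11], TRI = y[12],
        Cbm = y[13], DCbm = y[14], Cc = y[15], DCc = y[16],
        M = y[17], F = y[18], I = y[19], R = y[20];

    /* ---- PK: SC depot, central/peripheral/BM distribution ---- */
    double dA = -ka * A;
    double f_cp = Q * (Dc - Dp);              /* nmol/day */
    double f_cb = qBM * Vbm * (Dc - Dbm);     /* nmol/day */
    double dDc = ka * A / Vc - CL * Dc / Vc - f_cp / Vc - f_cb / Vc;
    double dDp = f_cp / Vp;
    double dDbm = f_cb / Vbm;

    /* ---- central binding: D+S, D+C, DC+S ---- */
    double rbc = konB * Dc * Sc - koffB * DSc;
    double rcc = konC * Dc * Cc - koffC * DCc;
    double rsc = solTri * (chi * konB * DCc * Sc - koffB * DCSc);
    dDc += -rbc - rcc;
    double dSc = -rbc - rsc;
    double dDSc = rbc;
    double dCc = -rcc;
    double dDCc = rcc - rsc;
    double dDCSc = rsc;

    /* ---- BM binding: D+S, D+C, D+B, DB+C, DC+B (chi-scaled), DC+S ---- */
    double rbb = konB * Dbm * Sbm - koffB * DSbm;
    double rcb = konC * Dbm * Cbm - koffC * DCbm;
    double rB = konB * Dbm * Bf - koffB * DB;
    double tri1 = chi * konC * DB * Cbm - koffC * TRI;
    double tri2 = chi * konB * DCbm * Bf - koffB * TRI;
    double rsb = solTri * (chi * konB * DCbm * Sbm - koffB * DCSbm);
    dDbm += -rbb - rcb - rB;
    double dSbm = -rbb - rsb;
    double dDSbm = rbb;
    double dBf = -rB - tri2;
    double dDB = rB - tri1;
    double dTRI = tri1 + tri2;
    double dCbm = -rcb - tri1;
    double dDCbm = rcb - tri2 - rsb;
    double dDCSbm = rsb;

    /* ---- sBCMA shedding (surface density maintained), transfer, clearance */
    dSbm += kshed * Bf;
    double fS = qS * (Sbm * Vbm - Sc * Vc);
    dSbm += -fS / Vbm;
    dSc += fS / Vc - kclS * Sc;
    double fDS = qS * (DSbm * Vbm - DSc * Vc);
    dDSbm += -fDS / Vbm;
    dDSc += fDS / Vc - kclS * DSc;

    /* ---- tumor: logistic growth, trimer-occupancy Hill kill, resistance */
    double Btot = Bf + DB + TRI;
    double theta = (Btot > 0.0) ? TRI / Btot : 0.0;
    if (theta < 0.0) theta = 0.0;
    double ttreat = *t - tfirst;
    if (ttreat < 0.0) ttreat = 0.0;
    double kill = 0.0;
    if (theta > 0.0 && kmax > 0.0) {
        double th_n = pow(theta, nkill), a_n = pow(akill, nkill);
        kill = kmax * th_n / (a_n + th_n) / (1.0 + aresis * ttreat);
    }
    double gr = g * (1.0 - Btot / BtotMax);
    dBf += gr * Btot - kill * Bf;   /* newborn cells carry free receptors */
    dDB += -kill * DB;              /* dimer drug lost with killed cells  */
    dTRI += -kill * TRI;
    dDCbm += kill * TRI;            /* CD3-drug arm survives the kill     */

    /* ---- T-cell trafficking, egress slowed by IL-6 ---- */
    double kouteff = kout / (1.0 + I / I50);
    double vb2c = Vbm / Vc, vc2b = Vc / Vbm;
    double e1 = kouteff * Cbm, e2 = kouteff * DCbm, e3 = kouteff * DCSbm;
    double i1 = kin * Cc, i2 = kin * DCc, i3 = kin * DCSc;
    dCbm += -e1 + i1 * vc2b;
    dCc += e1 * vb2c - i1;
    dDCbm += -e2 + i2 * vc2b;
    dDCc += e2 * vb2c - i2;
    dDCSbm += -e3 + i3 * vc2b;
    dDCSc += e3 * vb2c - i3;

    /* ---- paraproteins ---- */
    double dM = kM * Btot - kelimM * M;
    double dF = kF * Btot - kelimF * F;

    /* ---- IL-6 release from a depletable pool ---- */
    double dI = krelI * TRI * R - kdegI * I;
    double dR = krep * (1.0 - R) - kdep * TRI * R;

    /* ---- eliminated drug bookkeeping (nmol) ---- */
    double delim = CL * Dc + kill * DB * Vbm + kclS * DSc * Vc;

    if (clampDbm > 0.5) dDbm = 0.0;   /* test hook: hold BM free drug */

    ydot[0] = dA; ydot[1] = dDc; ydot[2] = dDp; ydot[3] = dDbm;
    ydot[4] = dSc; ydot[5] = dSbm; ydot[6] = dDSc; ydot[7] = dDSbm;
    ydot[8] = dDCSc; ydot[9] = dDCSbm;
    ydot[10] = dBf; ydot[11] = dDB; ydot[12] = dTRI;
    ydot[13] = dCbm; ydot[14] = dDCbm; ydot[15] = dCc; ydot[16] = dDCc;
    ydot[17] = dM; ydot[18] = dF; ydot[19] = dI; ydot[20] = dR;
    ydot[21] = delim;

    if (ip[0] >= 2) {
        yout[0] = theta;
        yout[1] = kill;
    }
}
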