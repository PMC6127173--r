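/* Mass-action right-hand side for the three-compartment VEGF network
 * coupled to the switching tumour growth law.
 *
 * The network is loaded into static storage by C_set_model() before each
 * integration; deSolve then calls vegf_derivs()/vegf_root() directly, so
 * the whole integration (including the internally generated numerical
 * Jacobian) stays at C level.
 *
 * State vector: y[0..nsp-1] species concentrations (mol cm^-3 of the
 * fluid volume of their compartment), y[nsp] total tumour volume (cm^3).
 * Time unit: days.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <stdlib.h>
#include <string.h>

static int nsp = 0, nrx = 0, ntr = 0, nsec = 0, nsig = 0, ndose = 0;

/* reactions: a + b <-> c, mass action */
static int *rx_a = NULL, *rx_b = NULL, *rx_c = NULL;
static double *rx_kf = NULL, *rx_kr = NULL;

/* transports: amount flux F = rate * (vscale ? V : 1) * y[src];
 * dst < 0 encodes clearance (no destination). rate is a conductance
 * (cm^3/day), or cm^3/day per cm^3 tumour when vscale. */
static int *tr_src = NULL, *tr_dst = NULL, *tr_vscale = NULL;
static double *tr_rate = NULL;

/* secretions: amount rate (mol/day), vscale as above */
static int *sec_idx = NULL, *sec_vscale = NULL;
static double *sec_rate = NULL;

/* species whose concentrations sum to the angiogenic signal */
static int *sig_idx = NULL;

static int *sp_comp = NULL; /* 0 normal, 1 blood, 2 tumour */

static double vol_normal = 1.0, vol_blood = 1.0, fvfrac = 0.5;
static double g_k0 = 0.0, g_k1 = 1.0, g_psi = 20.0, g_ang0 = 1.0;
static int growth_on = 1;

/* infusion dosing: constant rate (mol/day) into drug_idx (blood) over
 * [dose_t[i], dose_t[i] + dose_dur) */
static int drug_idx = -1;
static double *dose_t = NULL;
static double dose_rate = 0.0, dose_dur = 0.0;

static double root_vol = -1.0;

static int *icopy(SEXP x, int n, int shift)
{
    int i, *p = NULL;
    if (n == 0) return NULL;
    p = (int *) R_Calloc(n, int);
    for (i = 0; i < n; i++) p[i] = INTEGER(x)[i] + shift;
    return p;
}

static double *dcopy(SEXP x, int n)
{
    int i;
    double *p = NULL;
    if (n == 0) return NULL;
    p = (double *) R_Calloc(n, double);
    for (i = 0; i < n; i++) p[i] = REAL(x)[i];
    return p;
}

static void free_all(void)
{
    if (rx_a) R_Free(rx_a); if (rx_b) R_Free(rx_b); if (rx_c) R_Free(rx_c);
    if (rx_kf) R_Free(rx_kf); if (rx_kr) R_Free(rx_kr);
    if (tr_src) R_Free(tr_src); if (tr_dst) R_Free(tr_dst);
    if (tr_vscale) R_Free(tr_vscale); if (tr_rate) R_Free(tr_rate);
    if (sec_idx) R_Free(sec_idx); if (sec_vscale) R_Free(sec_vscale);
    if (sec_rate) R_Free(sec_rate);
    if (sig_idx) R_Free(sig_idx); if (sp_comp) R_Free(sp_comp);
    if (dose_t) R_Free(dose_t);
    rx_a = rx_b = rx_c = NULL; rx_kf = rx_kr = NULL;
    tr_src = tr_dst = tr_vscale = NULL; tr_rate = NULL;
    sec_idx = sec_vscale = NULL; sec_rate = NULL;
    sig_idx = sp_comp = NULL; dose_t = NULL;
}

/* Arguments (all indices 1-based from R):
 *  spComp, rxA, rxB, rxC, rxKf, rxKr,
 *  trSrc, trDst (0 = clearance), trVs, trRate,
 *  secIdx, secVs, secRate, sigIdx,
 *  vols = c(vol_normal, vol_blood, fvfrac),
 *  growth = c(k0_day, k1_day, psi, ang0, on),
 *  doseIdx (0 = none), doseTimes, doseRate, doseDur, rootVol
 */
SEXP C_set_model(SEXP spComp, SEXP rxA, SEXP rxB, SEXP rxC, SEXP rxKf,
                 SEXP rxKr, SEXP trSrc, SEXP trDst, SEXP trVs, SEXP trRate,
                 SEXP secIdx, SEXP secVs, SEXP secRate, SEXP sigIdx,
                 SEXP vols, SEXP growth, SEXP doseIdx, SEXP doseTimes,
                 SEXP doseRate, SEXP doseDur, SEXP rootVol)
{
    free_all();

    nsp = LENGTH(spComp);
    nrx = LENGTH(rxA);
    ntr = LENGTH(trSrc);
    nsec = LENGTH(secIdx);
    nsig = LENGTH(sigIdx);
    ndose = LENGTH(doseTimes);

    sp_comp = icopy(spComp, nsp, -1);
    rx_a = icopy(rxA, nrx, -1);
    rx_b = icopy(rxB, nrx, -1);
    rx_c = icopy(rxC, nrx, -1);
    rx_kf = dcopy(rxKf, nrx);
    rx_kr = dcopy(rxKr, nrx);
    tr_src = icopy(trSrc, ntr, -1);
    tr_dst = icopy(trDst, ntr, -1); /* 0 -> -1 = clearance */
    tr_vscale = icopy(trVs, ntr, 0);
    tr_rate = dcopy(trRate, ntr);
    sec_idx = icopy(secIdx, nsec, -1);
    sec_vscale = icopy(secVs, nsec, 0);
    sec_rate = dcopy(secRate, nsec);
    sig_idx = icopy(sigIdx, nsig, -1);

    vol_normal = REAL(vols)[0];
    vol_blood = REAL(vols)[1];
    fvfrac = REAL(vols)[2];

    g_k0 = REAL(growth)[0];
    g_k1 = REAL(growth)[1];
    g_psi = REAL(growth)[2];
    g_ang0 = REAL(growth)[3];
    growth_on = (int) REAL(growth)[4];

    drug_idx = INTEGER(doseIdx)[0] - 1;
    dose_t = dcopy(doseTimes, ndose);
    dose_rate = REAL(doseRate)[0];
    dose_dur = REAL(doseDur)[0];
    root_vol = REAL(rootVol)[0];

    return ScalarInteger(nsp + 1);
}

static double growth_rate_c(double V, double ang)
{
    double m, q, denom;
    if (!growth_on || V <= 0.0) return 0.0;
    m = ang / g_ang0;
    if (m < 0.0) m = 0.0;
    q = g_k0 * V / g_k1;
    if (q <= 1.0)
        denom = pow(1.0 + pow(q, g_psi), 1.0 / g_psi);
    else /* overflow-safe for large q and sharp psi */
        denom = q * pow(pow(q, -g_psi) + 1.0, 1.0 / g_psi);
    return m * g_k0 * V / denom;
}

void vegf_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int i;
    double vol[3], V, Vl, ang, v, F;

    V = y[nsp];
    Vl = (V > 1e-12) ? V : 1e-12;
    vol[0] = vol_normal;
    vol[1] = vol_blood;
    vol[2] = fvfrac * Vl;

    for (i = 0; i <= nsp; i++) ydot[i] = 0.0;

    for (i = 0; i < nrx; i++) {
        v = rx_kf[i] * y[rx_a[i]] * y[rx_b[i]] - rx_kr[i] * y[rx_c[i]];
        ydot[rx_a[i]] -= v;
        ydot[rx_b[i]] -= v;
        ydot[rx_c[i]] += v;
    }

    for (i = 0; i < ntr; i++) {
        F = tr_rate[i] * (tr_vscale[i] ? Vl : 1.0) * y[tr_src[i]];
        ydot[tr_src[i]] -= F / vol[sp_comp[tr_src[i]]];
        if (tr_dst[i] >= 0)
            ydot[tr_dst[i]] += F / vol[sp_comp[tr_dst[i]]];
    }

    for (i = 0; i < nsec; i++)
        ydot[sec_idx[i]] += sec_rate[i] * (sec_vscale[i] ? Vl : 1.0)
            / vol[sp_comp[sec_idx[i]]];

    if (drug_idx >= 0 && dose_rate > 0.0) {
        for (i = 0; i < ndose; i++)
            if (*t >= dose_t[i] && *t < dose_t[i] + dose_dur)
                ydot[drug_idx] += dose_rate / vol[1];
    }

    ang = 0.0;
    for (i = 0; i < nsig; i++) ang += y[sig_idx[i]];

    ydot[nsp] = growth_rate_c(V, ang);
}

void vegf_root(int *neq, double *t, double *y, int *ng, double *gout,
               double *rpar, int *ipar)
{
    gout[0] = y[nsp] - root_vol;
}

/* Evaluate the currently loaded RHS once (the derivative-evaluator
 * contract exposed to R). */
SEXP C_eval_rhs(SEXP t, SEXP y)
{
    int neq = nsp + 1, ip = 0;
    double tt = REAL(t)[0], yout = 0.0;
    SEXP ans;
    if (LENGTH(y) != neq)
        error("state length %d does not match model dimension %d",
              LENGTH(y), neq);
    ans = PROTECT(allocVector(REALSXP, neq));
    vegf_derivs(&neq, &tt, REAL(y), REAL(ans), &yout, &ip);
    UNPROTECT(1);
    return ans;
}

SEXP C_signal(SEXP y)
{
    int i;
    double ang = 0.0;
    if (LENGTH(y) < nsp)
        error("state length %d smaller than species count %d",
              LENGTH(y), nsp);
    for (i = 0; i < nsig; i++) ang += REAL(y)[sig_idx[i]];
    return ScalarReal(ang);
}
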