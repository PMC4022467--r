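/* Compiled right-hand side for the TDL recirculation model, in the
 * standard deSolve compiled-model form (initparms/derivs pair).
 *
 * Parameter vector (length 18):
 *  [0..5]  entry rates s_i from blood: lung, liver, spleen, scln, mln, pp
 *  [6..11] exit rates m_i to blood:    lung, liver, spleen, scln, mln, pp
 *  [12] mu   removal rate from blood
 *  [13] phi  fraction of removed cells retained in liver as dead
 *  [14] f    fraction of SCLN efflux routed via the thoracic duct
 *  [15] k    number of sub-compartments in each LN/PP chain (1..3)
 *  [16] xi   cannulation switch (0/1)
 *  [17] nu   exponential decline rate of LN/PP exit during cannulation
 *
 * State vector (length 7 + 3k):
 *  [0] blood, [1] lung, [2] liver (live), [3] liver (dead), [4] spleen,
 *  [5..5+k-1] scln chain, [5+k..5+2k-1] mln chain, [5+2k..5+3k-1] pp chain,
 *  [5+3k] removed (not deposited in liver), [5+3k+1] duct collected.
 *
 * Conservation: the derivatives sum to zero identically.
 */
#include <math.h>

#define N_PARMS 18

static double parms[N_PARMS];

void initparms(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void derivs(int *neq, double *t, double *y, double *ydot, double *yout, int *ip)
{
    const double s_lung = parms[0], s_liver = parms[1], s_spleen = parms[2];
    const double s_scln = parms[3], s_mln = parms[4], s_pp = parms[5];
    const double m_lung = parms[6], m_liver = parms[7], m_spleen = parms[8];
    const double m_scln = parms[9], m_mln = parms[10], m_pp = parms[11];
    const double mu = parms[12], phi = parms[13], f = parms[14];
    const int k = (int) (parms[15] + 0.5);
    const double xi = parms[16], nu = parms[17];

    /* cannulation slows all LN/PP chain transitions; ignored otherwise */
    const double e = (xi > 0.5) ? exp(-nu * (*t)) : 1.0;

    const double B = y[0];
    double *scln = y + 5, *mln = y + 5 + k, *pp = y + 5 + 2 * k;
    double *dscln = ydot + 5, *dmln = ydot + 5 + k, *dpp = ydot + 5 + 2 * k;
    int j;

    const double Es = m_scln * e * scln[k - 1]; /* SCLN terminal efflux  */
    const double Em = m_mln * e * mln[k - 1];   /* MLN terminal efflux   */
    const double Ep = m_pp * e * pp[k - 1];     /* PP -> MLN throughput  */

    const double s_tot = s_lung + s_liver + s_spleen + s_scln + s_mln + s_pp;

    /* blood: organ returns; during cannulation only the right-lymphatic
     * share (1-f) of SCLN efflux comes back, MLN efflux is harvested */
    ydot[0] = -(s_tot + mu) * B + m_lung * y[1] + m_liver * y[2] +
              m_spleen * y[4] +
              (xi > 0.5 ? (1.0 - f) * Es : Es + Em);
    ydot[1] = s_lung * B - m_lung * y[1];
    ydot[2] = s_liver * B - m_liver * y[2];
    ydot[3] = phi * mu * B;
    ydot[4] = s_spleen * B - m_spleen * y[4];

    dscln[0] = s_scln * B - m_scln * e * scln[0];
    dmln[0] = s_mln * B + Ep - m_mln * e * mln[0];
    dpp[0] = s_pp * B - m_pp * e * pp[0];
    for (j = 1; j < k; j++) {
        dscln[j] = m_scln * e * (scln[j - 1] - scln[j]);
        dmln[j] = m_mln * e * (mln[j - 1] - mln[j]);
        dpp[j] = m_pp * e * (pp[j - 1] - pp[j]);
    }

    ydot[5 + 3 * k] = (1.0 - phi) * mu * B;                 /* removed */
    ydot[5 + 3 * k + 1] = (xi > 0.5) ? (Em + f * Es) : 0.0; /* duct    */
}
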