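/* Compiled right-hand side of the seagrass-sulfide-OM-Loripes model for
 * deSolve. Mirrors the pure-R reference model_rhs(); kept in C because the
 * bifurcation scans, bisection searches and stochastic ensembles integrate
 * the system tens of thousands of times.
 *
 * Parameter vector (15 entries, order fixed, see .rhs_parms() on the R side):
 *   0 Z_max  1 r  2 m_s  3 m_n  4 C_om  5 C_s  6 e_s  7 C_z  8 e_m
 *   9 S_min 10 S_max 11 r_L 12 L_max 13 m_L 14 mutualism flag (0/1)
 *
 * Numerical guards (integration-time only, not part of the model):
 *  - Z enters the vector field through max(Z, ZFLOOR): a refuge density of
 *    1e-10 shoots m^-2 so that recovery after a collapse phase is never
 *    blocked by the solver flooring Z at exactly zero. During slow-fast
 *    cycles Z would mathematically pass through ~1e-200; any positive floor
 *    changes the cycle period only logarithmically.
 *  - A component pushed below zero by a solver step gets a restoring
 *    derivative -y so trajectories cannot escape the non-negative orthant.
 */

#include <R.h>

#define NPAR 15
static double p[NPAR];

#define ZFLOOR 1e-10

void seagrass_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

void seagrass_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double Z = y[0], S = y[1], OM = y[2], L = y[3];
    double z  = Z  > ZFLOOR ? Z  : ZFLOOR;
    double s  = S  > 0      ? S  : 0;
    double om = OM > 0      ? OM : 0;
    double l  = L  > 0      ? L  : 0;

    double fS;
    if (s <= p[9])       fS = 0.0;
    else if (s >= p[10]) fS = 1.0;
    else                 fS = (s - p[9]) / (p[10] - p[9]);

    double mort = (p[2] * fS + p[3]) * z;

    ydot[0] = p[1] * (1.0 - z / p[0]) * z - mort;
    ydot[1] = p[4] * om - p[5] * l * s - p[6] * s;
    ydot[2] = p[7] * mort - p[8] * om;
    ydot[3] = (p[14] > 0.5)
        ? p[11] * (z / p[0]) * (1.0 - l / p[12]) - p[13] * l
        : 0.0;

    if (Z < 0)  ydot[0] = -Z;
    if (S < 0)  ydot[1] = -S;
    if (OM < 0) ydot[2] = -OM;
    if (L < 0)  ydot[3] = -L;
}
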