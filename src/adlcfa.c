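/* Compiled right-hand side of the LCFA-inhibited anaerobic digestion model,
 * in the deSolve compiled-code convention (initfunc + derivs).
 *
 * State vector (10):
 *   y[0] S_p   particulate substrate        [kg COD/m3]
 *   y[1] S_h   soluble hydrolysate          [kg COD/m3]
 *   y[2] S_v   VFA                          [kg COD/m3]
 *   y[3] S_fa  LCFA (tracking pool)         [kg COD/m3]
 *   y[4] S_m   cumulative methane           [kg COD/m3]
 *   y[5] X_h   hydrolytic bacteria          [kg COD/m3]
 *   y[6] X_v   acidogens                    [kg COD/m3]
 *   y[7] X_m   methanogens                  [kg COD/m3]
 *   y[8] S_Ca  calcium binding equivalent   [kg COD/m3], dS_Ca/dt = 0
 *   y[9] growth_cod: integral of biomass-synthesis COD source, used by the
 *        COD balance report (the product pools receive the full uptake flux
 *        while biomass is synthesised in addition, so the conserved quantity
 *        is the pool sum minus this integral).
 *
 * Parameter order must match .param_order on the R side.
 */
#include <R.h>
#include <math.h>

static double parms[20];

#define KM_P  parms[0]
#define KM_H  parms[1]
#define KM_FA parms[2]
#define KM_V  parms[3]
#define KS_P  parms[4]
#define KS_H  parms[5]
#define KS_FA parms[6]
#define KS_V  parms[7]
#define Y_H   parms[8]
#define Y_V   parms[9]
#define Y_M   parms[10]
#define KD_H  parms[11]
#define KD_V  parms[12]
#define KD_M  parms[13]
#define F_FA  parms[14]
#define KHFA  parms[15]
#define KVFA  parms[16]
#define KMFA  parms[17]
#define A_W   parms[18]
#define B_W   parms[19]

void adlcfa_init(void (*odeparms)(int *, double *))
{
    int n = 20;
    odeparms(&n, parms);
}

/* Contois uptake: km * S / (Ks*X + S) * X * K, zero when the denominator
 * or either pool is zero (no biomass or no substrate means no flux). */
static double contois(double km, double Ks, double S, double X, double K)
{
    double den = Ks * X + S;
    if (S <= 0.0 || X <= 0.0 || den <= 0.0)
        return 0.0;
    return km * S / den * X * K;
}

/* Non-competitive LCFA inhibition in the simplified form
 * K_ifa*C / (K_ifa*C + S_fa^2), C = a*X_total + b*S_Ca, with the
 * S_fa -> 0 limit equal to 1 (no LCFA, no inhibition). */
static double inhib(double Kifa, double C, double Sfa)
{
    if (Sfa <= 0.0)
        return 1.0;
    return Kifa * C / (Kifa * C + Sfa * Sfa);
}

void adlcfa_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double S_p  = fmax(y[0], 0.0);
    double S_h  = fmax(y[1], 0.0);
    double S_v  = fmax(y[2], 0.0);
    double S_fa = fmax(y[3], 0.0);
    double X_h  = fmax(y[5], 0.0);
    double X_v  = fmax(y[6], 0.0);
    double X_m  = fmax(y[7], 0.0);
    double S_Ca = fmax(y[8], 0.0);

    double C   = A_W * (X_h + X_v + X_m) + B_W * S_Ca;
    double K_h = inhib(KHFA, C, S_fa);
    double K_v = inhib(KVFA, C, S_fa);
    double K_m = inhib(KMFA, C, S_fa);

    double r_p  = contois(KM_P,  KS_P,  S_p,  X_h, K_h);
    double r_h  = contois(KM_H,  KS_H,  S_h,  X_v, K_v);
    double r_v  = contois(KM_V,  KS_V,  S_v,  X_m, K_m);
    double r_fa = contois(KM_FA, KS_FA, S_fa, X_v, K_v);

    ydot[0] = -r_p + KD_H * X_h + KD_V * X_v + KD_M * X_m;
    ydot[1] = r_p - r_h;
    ydot[2] = r_h - r_v;
    ydot[3] = F_FA * r_p - r_fa;
    ydot[4] = r_v;
    ydot[5] = Y_H * r_p - KD_H * X_h;
    ydot[6] = Y_V * r_h - KD_V * X_v;
    ydot[7] = Y_M * r_v - KD_M * X_m;
    ydot[8] = 0.0;
    ydot[9] = Y_H * r_p + Y_V * r_h + Y_M * r_v;
}
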