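/* Compiled right-hand side of the HER1-3 activation / trafficking model.
 *
 * State layout (0-based, compartment-major):
 *   y[0..16]  surface, y[17..33] early endosome, y[34..50] late endosome
 * Species order within a compartment:
 *   E, H, R1, R1E, R2, R3, R3H, R11E, R11EE, R12E, R13E, R13H, R13EH,
 *   R22, R23H, R33H, R33HH
 *
 * Parameter vector layout (must match .build_parms() on the R side):
 *   0..3   kon1s koff1s kon3s koff3s
 *   4..7   kon1e koff1e kon3e koff3e   (EE volume factor already applied)
 *   8..9   kc_s kc_e
 *   10..19 ku at surface (11e 11ee 12e 13e 13h 13eh 22 23h 33h 33hh)
 *   20..29 ku in early endosome (same order)
 *   30..32 affinity folds: r12_egf (1.6), r23_hrg (25), r13_hrg_egf (3)
 *   33..49 kint[17]   (surface -> EE; kt monomers, ke dimers, 0 ligands)
 *   50..66 kr[17]     (EE -> surface recycling)
 *   67..83 kl[17]     (EE -> LE entry / sorting loss)
 *   84..100 kd[17]    (LE degradation)
 *   101..103 synthesis of R1, R2, R3 at the surface
 *
 * Surface free-ligand derivatives are clamped to zero: extracellular
 * ligand concentration is held at the protocol dose (no depletion).
 * The late endosome carries no biochemistry.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define NPARMS 104
#define NSP 17

/* species indices within a compartment */
#define iE 0
#define iH 1
#define iR1 2
#define iR1E 3
#define iR2 4
#define iR3 5
#define iR3H 6
#define iR11E 7
#define iR11EE 8
#define iR12E 9
#define iR13E 10
#define iR13H 11
#define iR13EH 12
#define iR22 13
#define iR23H 14
#define iR33H 15
#define iR33HH 16

static double parms[NPARMS];

void initparms(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

/* reaction fluxes within one reactive compartment */
static void compartment_reactions(const double *x, double *dx,
                                  double kon1, double koff1,
                                  double kon3, double koff3,
                                  double kc, const double *ku,
                                  double f12, double f23, double f13)
{
    double v;

    /* ligand association */
    v = kon1 * x[iE] * x[iR1];
    dx[iE] -= v; dx[iR1] -= v; dx[iR1E] += v;
    v = kon3 * x[iH] * x[iR3];
    dx[iH] -= v; dx[iR3] -= v; dx[iR3H] += v;
    v = kon1 * x[iE] * x[iR11E];
    dx[iE] -= v; dx[iR11E] -= v; dx[iR11EE] += v;
    v = kon3 * x[iH] * x[iR33H];
    dx[iH] -= v; dx[iR33H] -= v; dx[iR33HH] += v;
    v = kon1 * x[iE] * x[iR13H];
    dx[iE] -= v; dx[iR13H] -= v; dx[iR13EH] += v;
    v = kon3 * x[iH] * x[iR13E];
    dx[iH] -= v; dx[iR13E] -= v; dx[iR13EH] += v;

    /* ligand dissociation leaving a stable complex */
    v = koff1 * x[iR1E];
    dx[iR1E] -= v; dx[iE] += v; dx[iR1] += v;
    v = koff3 * x[iR3H];
    dx[iR3H] -= v; dx[iH] += v; dx[iR3] += v;
    v = 2.0 * koff1 * x[iR11EE];
    dx[iR11EE] -= v; dx[iE] += v; dx[iR11E] += v;
    v = 2.0 * koff3 * x[iR33HH];
    dx[iR33HH] -= v; dx[iH] += v; dx[iR33H] += v;
    v = f13 * koff1 * x[iR13EH];
    dx[iR13EH] -= v; dx[iE] += v; dx[iR13H] += v;
    v = koff3 * x[iR13EH];
    dx[iR13EH] -= v; dx[iH] += v; dx[iR13E] += v;

    /* loss of the sole ligand: lumped collapse into free monomers */
    v = koff1 * x[iR11E];
    dx[iR11E] -= v; dx[iE] += v; dx[iR1] += 2.0 * v;
    v = (koff1 / f12) * x[iR12E];
    dx[iR12E] -= v; dx[iE] += v; dx[iR1] += v; dx[iR2] += v;
    v = koff1 * x[iR13E];
    dx[iR13E] -= v; dx[iE] += v; dx[iR1] += v; dx[iR3] += v;
    v = koff3 * x[iR13H];
    dx[iR13H] -= v; dx[iH] += v; dx[iR1] += v; dx[iR3] += v;
    v = (koff3 / f23) * x[iR23H];
    dx[iR23H] -= v; dx[iH] += v; dx[iR2] += v; dx[iR3] += v;
    v = koff3 * x[iR33H];
    dx[iR33H] -= v; dx[iH] += v; dx[iR3] += 2.0 * v;

    /* dimerization, common forward rate */
    v = kc * x[iR1E] * x[iR1];
    dx[iR1E] -= v; dx[iR1] -= v; dx[iR11E] += v;
    v = kc * x[iR1E] * x[iR1E];
    dx[iR1E] -= 2.0 * v; dx[iR11EE] += v;
    v = kc * x[iR1E] * x[iR2];
    dx[iR1E] -= v; dx[iR2] -= v; dx[iR12E] += v;
    v = kc * x[iR1E] * x[iR3];
    dx[iR1E] -= v; dx[iR3] -= v; dx[iR13E] += v;
    v = kc * x[iR1] * x[iR3H];
    dx[iR1] -= v; dx[iR3H] -= v; dx[iR13H] += v;
    v = kc * x[iR1E] * x[iR3H];
    dx[iR1E] -= v; dx[iR3H] -= v; dx[iR13EH] += v;
    v = kc * x[iR2] * x[iR2];
    dx[iR2] -= 2.0 * v; dx[iR22] += v;
    v = kc * x[iR2] * x[iR3H];
    dx[iR2] -= v; dx[iR3H] -= v; dx[iR23H] += v;
    v = kc * x[iR3] * x[iR3H];
    dx[iR3] -= v; dx[iR3H] -= v; dx[iR33H] += v;
    v = kc * x[iR3H] * x[iR3H];
    dx[iR3H] -= 2.0 * v; dx[iR33HH] += v;

    /* dimer dissociation (free ku rates) */
    v = ku[0] * x[iR11E];
    dx[iR11E] -= v; dx[iR1E] += v; dx[iR1] += v;
    v = ku[1] * x[iR11EE];
    dx[iR11EE] -= v; dx[iR1E] += 2.0 * v;
    v = ku[2] * x[iR12E];
    dx[iR12E] -= v; dx[iR1E] += v; dx[iR2] += v;
    v = ku[3] * x[iR13E];
    dx[iR13E] -= v; dx[iR1E] += v; dx[iR3] += v;
    v = ku[4] * x[iR13H];
    dx[iR13H] -= v; dx[iR1] += v; dx[iR3H] += v;
    v = ku[5] * x[iR13EH];
    dx[iR13EH] -= v; dx[iR1E] += v; dx[iR3H] += v;
    v = ku[6] * x[iR22];
    dx[iR22] -= v; dx[iR2] += 2.0 * v;
    v = ku[7] * x[iR23H];
    dx[iR23H] -= v; dx[iR2] += v; dx[iR3H] += v;
    v = ku[8] * x[iR33H];
    dx[iR33H] -= v; dx[iR3] += v; dx[iR3H] += v;
    v = ku[9] * x[iR33HH];
    dx[iR33HH] -= v; dx[iR3H] += 2.0 * v;
}

void derivs(int *neq, double *t, double *y, double *ydot,
            double *yout, int *ip)
{
    int i;
    const double *kint = parms + 33;
    const double *kr = parms + 50;
    const double *kl = parms + 67;
    const double *kd = parms + 84;

    for (i = 0; i < 3 * NSP; i++) ydot[i] = 0.0;

    compartment_reactions(y, ydot,
                          parms[0], parms[1], parms[2], parms[3],
                          parms[8], parms + 10,
                          parms[30], parms[31], parms[32]);
    compartment_reactions(y + NSP, ydot + NSP,
                          parms[4], parms[5], parms[6], parms[7],
                          parms[9], parms + 20,
                          parms[30], parms[31], parms[32]);

    /* trafficking: surface <-> EE -> LE -> degraded */
    for (i = 0; i < NSP; i++) {
        ydot[i] += -kint[i] * y[i] + kr[i] * y[NSP + i];
        ydot[NSP + i] += kint[i] * y[i] - (kr[i] + kl[i]) * y[NSP + i];
        ydot[2 * NSP + i] += kl[i] * y[NSP + i] - kd[i] * y[2 * NSP + i];
    }

    /* constant synthesis of receptor monomers at the surface */
    ydot[iR1] += parms[101];
    ydot[iR2] += parms[102];
    ydot[iR3] += parms[103];

    /* extracellular ligand held at the protocol dose */
    ydot[iE] = 0.0;
    ydot[iH] = 0.0;
}

static const R_CMethodDef cMethods[] = {
    {NULL, NULL, 0}
};

void R_init_herdimer(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    /* deSolve looks the symbols up by name */
    R_useDynamicSymbols(dll, TRUE);
}
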