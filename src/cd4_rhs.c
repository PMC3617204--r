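/* Compiled right-hand side for cd4sim reaction-network models.
 *
 * The model is flattened in R (compile_plan) into a fixed-length numeric
 * "plan" vector passed through deSolve's parms mechanism:
 *
 *   [ n_spec, base_levels[n_spec],
 *     n_state, species_index[n_state],
 *     n_clamp, (species_index, state_pos_or_0, value) * n_clamp,
 *     n_rxn,
 *     per reaction:
 *       kind(1=mass action, 2=hill), enabled(0/1),
 *       mass action: k, n_fac, (species_index, exponent) * n_fac
 *       hill:        vmax, km, n, driver_index,
 *                    n_cat, cat_index * n_cat,
 *                    n_inh, (species_index, ki) * n_inh
 *       n_net, (state_pos, net_stoich) * n_net ]
 *
 * All indices are 1-based. Boundary species live only in the base levels;
 * clamped species are overwritten before rate evaluation and their
 * derivatives forced to zero after scattering.
 */

#include <R.h>
#include <math.h>

#define CD4_PLAN_LEN 4096
#define CD4_MAX_SPEC 256

static double cd4_plan[CD4_PLAN_LEN];

void cd4_init(void (*odeparms)(int *, double *))
{
    int n = CD4_PLAN_LEN;
    odeparms(&n, cd4_plan);
}

static double cd4_hill_occ(double d, double km, double n)
{
    double lr;
    if (d <= 0.0) return 0.0;
    lr = n * (log(d) - log(km));
    if (lr > 500.0) return 1.0;
    lr = exp(lr);
    return lr / (1.0 + lr);
}

void cd4_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double F[CD4_MAX_SPEC];
    const double *p = cd4_plan;
    int pos = 0, i, r;
    int n_spec, n_state, n_clamp, n_rxn;
    int clamp_state[CD4_MAX_SPEC];
    int n_clamped_states = 0;

    n_spec = (int) p[pos++];
    for (i = 0; i < n_spec; i++) F[i] = p[pos++];
    n_state = (int) p[pos++];
    for (i = 0; i < n_state; i++) F[(int) p[pos++] - 1] = y[i];
    n_clamp = (int) p[pos++];
    for (i = 0; i < n_clamp; i++) {
        int sp = (int) p[pos++];
        int st = (int) p[pos++];
        double val = p[pos++];
        F[sp - 1] = val;
        if (st > 0) clamp_state[n_clamped_states++] = st - 1;
    }
    for (i = 0; i < *neq; i++) ydot[i] = 0.0;

    n_rxn = (int) p[pos++];
    for (r = 0; r < n_rxn; r++) {
        int kind = (int) p[pos++];
        double enabled = p[pos++];
        double rate;
        int n_net;

        if (kind == 1) {            /* mass action */
            double k = p[pos++];
            int n_fac = (int) p[pos++];
            rate = k;
            for (i = 0; i < n_fac; i++) {
                int sp = (int) p[pos++];
                double expo = p[pos++];
                double lev = F[sp - 1];
                if (lev < 0.0) lev = 0.0;
                rate *= (expo == 1.0) ? lev : pow(lev, expo);
            }
        } else {                    /* hill with catalysts and inhibitors */
            double vmax = p[pos++];
            double km = p[pos++];
            double n = p[pos++];
            int drv = (int) p[pos++];
            int n_cat, n_inh;
            double d = F[drv - 1];
            if (d < 0.0) d = 0.0;
            rate = vmax * cd4_hill_occ(d, km, n);
            n_cat = (int) p[pos++];
            for (i = 0; i < n_cat; i++) {
                double lev = F[(int) p[pos++] - 1];
                if (lev < 0.0) lev = 0.0;
                rate *= lev;
            }
            n_inh = (int) p[pos++];
            for (i = 0; i < n_inh; i++) {
                int sp = (int) p[pos++];
                double ki = p[pos++];
                double lev = F[sp - 1];
                if (lev < 0.0) lev = 0.0;
                rate *= ki / (ki + lev);
            }
        }
        rate *= enabled;

        n_net = (int) p[pos++];
        for (i = 0; i < n_net; i++) {
            int st = (int) p[pos++];
            double sto = p[pos++];
            ydot[st - 1] += sto * rate;
        }
    }

    for (i = 0; i < n_clamped_states; i++) ydot[clamp_state[i]] = 0.0;
}
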