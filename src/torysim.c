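/* Method-of-lines right-hand sides for the 2-D reaction-diffusion model.
 *
 * Fields are stored column-major as nx-by-ny matrices flattened to vectors;
 * the 5-point Laplacian uses ghost-cell reflection, i.e. zero-flux
 * (Neumann) boundaries.  The deSolve solvers call rhs_parasitoid_2d /
 * rhs_wasp_2d directly; the season-constant fields (previous season's egg
 * density, emergence flux) and scalar parameters are staged beforehand
 * from R via the C_set_* entry points.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static int g_nx = 0, g_ny = 0, g_n = 0;
static double g_h2i = 0.0; /* 1/h^2 */
static double g_delta = 0.0, g_tau = 1.0, g_Et = 0.0, g_Ed = 0.0, g_mu = 1.0;
static double *g_vprev = NULL, *g_emerg = NULL;

static void lap5(const double *f, double *out, int nx, int ny, double h2i)
{
    for (int j = 0; j < ny; j++) {
        for (int i = 0; i < nx; i++) {
            int k = i + nx * j;
            double c = f[k];
            double w = (i > 0)      ? f[k - 1]  : c;
            double e = (i < nx - 1) ? f[k + 1]  : c;
            double s = (j > 0)      ? f[k - nx] : c;
            double n = (j < ny - 1) ? f[k + nx] : c;
            out[k] = (w + e + s + n - 4.0 * c) * h2i;
        }
    }
}

SEXP C_set_spatial_params(SEXP nx, SEXP ny, SEXP h, SEXP delta, SEXP tau,
                          SEXP Et, SEXP Ed, SEXP mu)
{
    g_nx = INTEGER(nx)[0];
    g_ny = INTEGER(ny)[0];
    g_n = g_nx * g_ny;
    double hh = REAL(h)[0];
    g_h2i = 1.0 / (hh * hh);
    g_delta = REAL(delta)[0];
    g_tau = REAL(tau)[0];
    g_Et = REAL(Et)[0];
    g_Ed = REAL(Ed)[0];
    g_mu = REAL(mu)[0];
    return R_NilValue;
}

static void stage_field(double **slot, SEXP v, int n)
{
    if (LENGTH(v) != n)
        error("staged field length %d does not match grid size %d",
              LENGTH(v), n);
    if (*slot != NULL) R_Free(*slot);
    *slot = R_Calloc(n, double);
    memcpy(*slot, REAL(v), n * sizeof(double));
}

SEXP C_set_vprev(SEXP v)
{
    stage_field(&g_vprev, v, g_n);
    return R_NilValue;
}

SEXP C_set_emergence(SEXP v)
{
    stage_field(&g_emerg, v, g_n);
    return R_NilValue;
}

/* deSolve-compatible derivative routines (.C calling convention). */

void rhs_parasitoid_2d(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    int n = g_n;
    const double *p = y, *q = y + n;
    double *dp = ydot, *dq = ydot + n;
    lap5(p, dp, g_nx, g_ny, g_h2i);
    for (int k = 0; k < n; k++) {
        double r = (g_vprev[k] - q[k]) * p[k] / g_tau;
        dp[k] = g_delta * dp[k] - r;
        dq[k] = g_Et * r;
    }
}

void rhs_wasp_2d(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    int n = g_n;
    const double *u = y, *v = y + n;
    double *du = ydot, *dv = ydot + n;
    lap5(u, du, g_nx, g_ny, g_h2i);
    for (int k = 0; k < n; k++) {
        du[k] += -g_mu * (2.0 - v[k]) * u[k] + g_emerg[k];
        dv[k] = g_Ed * g_mu * (1.0 - v[k]) * u[k];
    }
}

/* no-op parameter initializer so deSolve's compiled-model interface has a
 * well-defined initfunc */
void torysim_initmod(void (*odeparms)(int *, double *))
{
    int n = 0;
    odeparms(&n, NULL);
}

/* standalone Laplacian for tests/diagnostics (does not touch globals) */
SEXP C_laplacian(SEXP f, SEXP h)
{
    SEXP dim = getAttrib(f, R_DimSymbol);
    if (dim == R_NilValue || LENGTH(dim) != 2)
        error("field must be a matrix");
    int nx = INTEGER(dim)[0], ny = INTEGER(dim)[1];
    double h2i = 1.0 / (REAL(h)[0] * REAL(h)[0]);
    SEXP out = PROTECT(allocMatrix(REALSXP, nx, ny));
    lap5(REAL(f), REAL(out), nx, ny, h2i);
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"C_set_spatial_params", (DL_FUNC) &C_set_spatial_params, 8},
    {"C_set_vprev",          (DL_FUNC) &C_set_vprev,          1},
    {"C_set_emergence",      (DL_FUNC) &C_set_emergence,      1},
    {"C_laplacian",          (DL_FUNC) &C_laplacian,          2},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"rhs_parasitoid_2d", (DL_FUNC) &rhs_parasitoid_2d, 6},
    {"rhs_wasp_2d",       (DL_FUNC) &rhs_wasp_2d,       6},
    {NULL, NULL, 0}
};

void R_init_torysim(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
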