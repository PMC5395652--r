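/* TMDD pharmacokinetic system for deSolve's compiled-model interface.
 *
 * States: C (central concentration, pM), A_T (peripheral amount,
 * pmol/kg), RC (drug-receptor complex, pM), optionally followed by
 * forward-sensitivity triplets dState/dc_j for each basis coefficient.
 *
 * The absorption input u(t) (pmol/min/kg) is either
 *   - exp(sum_j c_j B_j(t)), B_j linearly interpolated on a uniform grid
 *     (log-domain basis representation used during estimation), or
 *   - the two-Erlang-peak plus bi-exponential-burst test input used to
 *     generate synthetic validation data.
 *
 * Model/input configuration is pushed from R via .Call before each solve;
 * solves are single-threaded and immediate, so static storage is safe.
 */

#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>
#include <R_ext/Rdynload.h>

#define INPUT_NONE  0
#define INPUT_BASIS 1
#define INPUT_TEST  2
#define MAX_BASIS   64

/* kel, kpt, ktp, Vc (L/kg), kon, koff, kint, Rtot */
static double pk[8];

static int input_type = INPUT_NONE;
static int sens = 0;

static SEXP basis_B = NULL;
static SEXP basis_c = NULL;
static double *Bp = NULL, *cp = NULL;
static int Ngrid = 0, mb = 0;
static double tg0 = 0.0, dtg = 1.0;

/* n1, a1, ktr1, n2, a2, ktr2, r1, k1, r2, k2 */
static double tip[10];

SEXP C_set_pk(SEXP p)
{
    if (LENGTH(p) != 8)
        error("expected 8 PK parameters");
    for (int i = 0; i < 8; i++)
        pk[i] = REAL(p)[i];
    return R_NilValue;
}

static void release_basis(void)
{
    if (basis_B != NULL) { R_ReleaseObject(basis_B); basis_B = NULL; }
    if (basis_c != NULL) { R_ReleaseObject(basis_c); basis_c = NULL; }
}

SEXP C_set_input_basis(SEXP t0, SEXP dt, SEXP B, SEXP coef, SEXP do_sens)
{
    SEXP dim = getAttrib(B, R_DimSymbol);
    if (dim == R_NilValue || LENGTH(dim) != 2)
        error("basis matrix must be a numeric matrix");
    int n = INTEGER(dim)[0], m = INTEGER(dim)[1];
    if (m > MAX_BASIS)
        error("at most %d basis functions supported", MAX_BASIS);
    if (LENGTH(coef) != m)
        error("coefficient length does not match basis columns");
    release_basis();
    basis_B = B; R_PreserveObject(basis_B);
    basis_c = coef; R_PreserveObject(basis_c);
    Bp = REAL(basis_B); cp = REAL(basis_c);
    Ngrid = n; mb = m;
    tg0 = REAL(t0)[0]; dtg = REAL(dt)[0];
    input_type = INPUT_BASIS;
    sens = LOGICAL(do_sens)[0];
    return R_NilValue;
}

SEXP C_set_input_test(SEXP p)
{
    if (LENGTH(p) != 10)
        error("expected 10 test-input parameters");
    for (int i = 0; i < 10; i++)
        tip[i] = REAL(p)[i];
    input_type = INPUT_TEST;
    sens = 0;
    return R_NilValue;
}

SEXP C_set_input_none(void)
{
    input_type = INPUT_NONE;
    sens = 0;
    return R_NilValue;
}

/* Erlang-shaped rate a * ktr^n t^(n-1) exp(-ktr t) / (n-1)!, in log space
 * to stay finite for large n and t. */
static double erlang_rate(double a, double n, double ktr, double t)
{
    if (t <= 0.0)
        return (n == 1.0) ? a * ktr : 0.0;
    return exp(log(a) + n * log(ktr) + (n - 1.0) * log(t) - ktr * t
               - lgammafn(n));
}

static double test_u(double t)
{
    return erlang_rate(tip[1], tip[0], tip[2], t)
         + erlang_rate(tip[4], tip[3], tip[5], t)
         + tip[6] * exp(-tip[7] * t)
         + tip[8] * exp(-tip[9] * t);
}

/* log u(t) = sum_j c_j B_j(t); rows interpolated linearly between grid
 * nodes, constant extrapolation outside the grid.  If b != NULL the
 * interpolated basis values are stored there. */
static double basis_log_u(double t, double *b)
{
    double x = (t - tg0) / dtg;
    int i; double w;
    if (x <= 0.0)            { i = 0;         w = 0.0; }
    else if (x >= Ngrid - 1) { i = Ngrid - 2; w = 1.0; }
    else                     { i = (int) x;   w = x - i; }
    double s = 0.0;
    for (int j = 0; j < mb; j++) {
        double bj = (1.0 - w) * Bp[i + j * Ngrid] + w * Bp[i + 1 + j * Ngrid];
        if (b) b[j] = bj;
        s += cp[j] * bj;
    }
    return s;
}

void tmdd_init(void (*odeparms)(int *, double *))
{
    /* configuration arrives via .Call setters, not via parms */
    (void) odeparms;
}

void tmdd_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    (void) yout; (void) ip;
    double kel = pk[0], kpt = pk[1], ktp = pk[2], Vc = pk[3];
    double kon = pk[4], koff = pk[5], kint = pk[6], Rtot = pk[7];
    double b[MAX_BASIS];
    double u;

    if (input_type == INPUT_BASIS)
        u = exp(basis_log_u(*t, sens ? b : NULL));
    else if (input_type == INPUT_TEST)
        u = test_u(*t);
    else
        u = 0.0;

    double C = y[0], AT = y[1], RC = y[2];
    ydot[0] = u / Vc - (kel + kpt) * C + ktp * AT / Vc
              - kon * (Rtot - RC) * C + koff * RC;
    ydot[1] = kpt * C * Vc - ktp * AT;
    ydot[2] = kon * (Rtot - RC) * C - (koff + kint) * RC;

    if (sens && input_type == INPUT_BASIS) {
        if (*neq != 3 + 3 * mb)
            error("sensitivity state dimension mismatch");
        double j11 = -(kel + kpt) - kon * (Rtot - RC);
        double j12 = ktp / Vc;
        double j13 = kon * C + koff;
        double j21 = kpt * Vc, j22 = -ktp;
        double j31 = kon * (Rtot - RC), j33 = -kon * C - koff - kint;
        for (int j = 0; j < mb; j++) {
            double *S  = y    + 3 + 3 * j;
            double *dS = ydot + 3 + 3 * j;
            /* du/dc_j = u * B_j(t) in the log-domain parameterization */
            dS[0] = j11 * S[0] + j12 * S[1] + j13 * S[2] + u * b[j] / Vc;
            dS[1] = j21 * S[0] + j22 * S[1];
            dS[2] = j31 * S[0] + j33 * S[2];
        }
    }
}

static const R_CMethodDef CEntries[] = {
    {"tmdd_derivs", (DL_FUNC) &tmdd_derivs, 6},
    {"tmdd_init",   (DL_FUNC) &tmdd_init,   1},
    {NULL, NULL, 0}
};

static const R_CallMethodDef CallEntries[] = {
    {"C_set_pk",          (DL_FUNC) &C_set_pk,          1},
    {"C_set_input_basis", (DL_FUNC) &C_set_input_basis, 5},
    {"C_set_input_test",  (DL_FUNC) &C_set_input_test,  1},
    {"C_set_input_none",  (DL_FUNC) &C_set_input_none,  0},
    {NULL, NULL, 0}
};

void R_init_erdeconv(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
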