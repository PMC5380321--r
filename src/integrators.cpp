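// Explicit forward-Euler integrators for the four-variable branching model
// and the decoupled two-variable activator-inhibitor model on 2-D grids.
// Five-point Laplacian with periodic wrap or mirrored ghost cells
// (zero-flux). Fields are ny x nx R matrices (column-major, index
// i + ny * j with i the row / y index).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double H_FLOOR = 1e-9;
// Negatives beyond this magnitude abort as instability; smaller ones are
// explicit-Euler round-off and are clamped to zero.
static const double NEG_TOL = 1e-12;

// Parameter vector layout (kept in sync with par_vector() on the R side).
enum Par { P_C, P_MU, P_RHOA, P_DA, P_V, P_RHOH, P_DH,
           P_C0, P_GAMMA, P_EPS, P_DS, P_D, P_E, P_F, P_KAPPA, P_N };

static inline int reflect(int i, int n, bool periodic) {
  if (periodic) {
    if (i < 0) return i + n;
    if (i >= n) return i - n;
    return i;
  }
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

static inline double lap_at(const double* u, int i, int j, int ny, int nx,
                            bool periodic, double inv_dx2) {
  int iu = reflect(i - 1, ny, periodic), id = reflect(i + 1, ny, periodic);
  int jl = reflect(j - 1, nx, periodic), jr = reflect(j + 1, nx, periodic);
  double c = u[i + ny * j];
  return (u[iu + ny * j] + u[id + ny * j] +
          u[i + ny * jl] + u[i + ny * jr] - 4.0 * c) * inv_dx2;
}

static inline double guard(double val, const char* field, int step) {
  if (!std::isfinite(val)) {
    stop("instability: non-finite value in field %s at step %d", field, step);
  }
  if (val < 0.0) {
    if (val > -NEG_TOL) return 0.0;
    stop("instability: negative value (%g) in field %s at step %d",
         val, field, step);
  }
  return val;
}

// [[Rcpp::export]]
List run_branching_cpp(NumericMatrix A0, NumericMatrix H0, NumericMatrix S0,
                       NumericMatrix Y0, NumericVector par, double dx,
                       double dt, int n_steps, int snap_every, bool periodic) {
  if (par.size() != P_N) stop("parameter vector has wrong length");
  int ny = A0.nrow(), nx = A0.ncol();
  NumericMatrix A = clone(A0), H = clone(H0), S = clone(S0), Y = clone(Y0);
  NumericMatrix An(ny, nx), Hn(ny, nx), Sn(ny, nx), Yn(ny, nx);
  double inv_dx2 = 1.0 / (dx * dx);
  const double c = par[P_C], mu = par[P_MU], rhoA = par[P_RHOA],
    DA = par[P_DA], v = par[P_V], rhoH = par[P_RHOH], DH = par[P_DH],
    c0 = par[P_C0], gam = par[P_GAMMA], eps = par[P_EPS], DS = par[P_DS],
    d = par[P_D], e = par[P_E], f = par[P_F], kappa = par[P_KAPPA];

  List snaps;
  snaps.push_back(List::create(_["A"] = clone(A), _["H"] = clone(H),
                               _["S"] = clone(S), _["Y"] = clone(Y),
                               _["t"] = 0.0));
  for (int step = 1; step <= n_steps; ++step) {
    double *pA = A.begin(), *pH = H.begin(), *pS = S.begin(), *pY = Y.begin();
    double *qA = An.begin(), *qH = Hn.begin(), *qS = Sn.begin(),
      *qY = Yn.begin();
    for (int j = 0; j < nx; ++j) {
      for (int i = 0; i < ny; ++i) {
        int idx = i + ny * j;
        double a = pA[idx], h = pH[idx], s = pS[idx], y = pY[idx];
        double hf = h > H_FLOOR ? h : H_FLOOR;
        double a2 = kappa > 0.0 ? a * a / (1.0 + kappa * a * a) : a * a;
        double autoc = c * a2 * s;
        double dA = autoc / hf - mu * a + rhoA * y +
          DA * lap_at(pA, i, j, ny, nx, periodic, inv_dx2);
        double dH = autoc - v * h + rhoH * y +
          DH * lap_at(pH, i, j, ny, nx, periodic, inv_dx2);
        double dS = c0 - gam * s - eps * y * s +
          DS * lap_at(pS, i, j, ny, nx, periodic, inv_dx2);
        double dY = d * a - e * y + y * y / (1.0 + f * y * y);
        qA[idx] = guard(a + dt * dA, "A", step);
        qH[idx] = guard(h + dt * dH, "H", step);
        qS[idx] = guard(s + dt * dS, "S", step);
        qY[idx] = guard(y + dt * dY, "Y", step);
      }
    }
    std::swap(A, An); std::swap(H, Hn); std::swap(S, Sn); std::swap(Y, Yn);
    if ((snap_every > 0 && step % snap_every == 0) || step == n_steps) {
      snaps.push_back(List::create(_["A"] = clone(A), _["H"] = clone(H),
                                   _["S"] = clone(S), _["Y"] = clone(Y),
                                   _["t"] = step * dt));
    }
    if (step % 2048 == 0) checkUserInterrupt();
  }
  return List::create(_["snapshots"] = snaps, _["steps"] = n_steps);
}

// [[Rcpp::export]]
List run_ai_cpp(NumericMatrix A0, NumericMatrix H0, double S, double Y,
                NumericVector par, double dx, double dt, int max_steps,
                int snap_every, double stat_tol, int stat_consec,
                bool periodic) {
  if (par.size() != P_N) stop("parameter vector has wrong length");
  int ny = A0.nrow(), nx = A0.ncol();
  NumericMatrix A = clone(A0), H = clone(H0);
  NumericMatrix An(ny, nx), Hn(ny, nx);
  double inv_dx2 = 1.0 / (dx * dx);
  const double c = par[P_C], mu = par[P_MU], rhoA = par[P_RHOA],
    DA = par[P_DA], v = par[P_V], rhoH = par[P_RHOH], DH = par[P_DH],
    kappa = par[P_KAPPA];

  List snaps;
  snaps.push_back(List::create(_["A"] = clone(A), _["H"] = clone(H),
                               _["t"] = 0.0));
  int consec = 0, step = 0;
  bool converged = false;
  for (step = 1; step <= max_steps; ++step) {
    double *pA = A.begin(), *pH = H.begin();
    double *qA = An.begin(), *qH = Hn.begin();
    double max_rate = 0.0;
    for (int j = 0; j < nx; ++j) {
      for (int i = 0; i < ny; ++i) {
        int idx = i + ny * j;
        double a = pA[idx], h = pH[idx];
        double hf = h > H_FLOOR ? h : H_FLOOR;
        double a2 = kappa > 0.0 ? a * a / (1.0 + kappa * a * a) : a * a;
        double autoc = c * a2 * S;
        double dA = autoc / hf - mu * a + rhoA * Y +
          DA * lap_at(pA, i, j, ny, nx, periodic, inv_dx2);
        double dH = autoc - v * h + rhoH * Y +
          DH * lap_at(pH, i, j, ny, nx, periodic, inv_dx2);
        double ra = std::fabs(dA), rh = std::fabs(dH);
        if (ra > max_rate) max_rate = ra;
        if (rh > max_rate) max_rate = rh;
        qA[idx] = guard(a + dt * dA, "A", step);
        qH[idx] = guard(h + dt * dH, "H", step);
      }
    }
    std::swap(A, An); std::swap(H, Hn);
    bool last = false;
    if (max_rate < stat_tol) {
      if (++consec >= stat_consec) { converged = true; last = true; }
    } else {
      consec = 0;
    }
    if ((snap_every > 0 && step % snap_every == 0) || last ||
        step == max_steps) {
      snaps.push_back(List::create(_["A"] = clone(A), _["H"] = clone(H),
                                   _["t"] = step * dt));
    }
    if (last) break;
    if (step % 2048 == 0) checkUserInterrupt();
  }
  if (step > max_steps) step = max_steps;
  return List::create(_["snapshots"] = snaps, _["steps"] = step,
                      _["converged"] = converged);
}
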