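#include <Rcpp.h>
#include <R_ext/Lapack.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Bernoulli function B(x) = x / (exp(x) - 1), stable near 0 and at the tails.
static inline double bern(double x) {
  if (std::fabs(x) < 1e-8) return 1.0 - x / 2.0 + x * x / 12.0;
  if (x < -700.0) return -x;
  double e = std::expm1(x);
  if (!std::isfinite(e)) return 0.0; // x very large positive
  return x / e;
}

// Outgoing rates from 0-based cell s toward E, W, N, S neighbours
// (zero where the face is a reflecting boundary). Diffusion uses the
// TARGET cell's permeability (step-selection / conductance form), so the
// drift-free equilibrium is proportional to D.
// scheme 0 = exponentially fitted, 1 = first-order upwind.
static inline void rates4(int s, int nx, int ny, double h, double xll,
                          double yll, const double* D, double cdrift,
                          double mux, double muy, int scheme, double* r) {
  int ix = s % nx, iy = s / nx;
  double h2 = h * h;
  r[0] = r[1] = r[2] = r[3] = 0.0;
  if (ix < nx - 1) { // east face at x = xll + (ix+1) h, direction +x
    double Dt = D[s + 1];
    double vf = cdrift * (mux - (xll + (ix + 1) * h));
    r[0] = scheme == 0 ? Dt / h2 * bern(-vf * h / Dt)
                       : Dt / h2 + (vf > 0 ? vf / h : 0.0);
  }
  if (ix > 0) {      // west face at x = xll + ix h, direction -x
    double Dt = D[s - 1];
    double vf = cdrift * (mux - (xll + ix * h));
    r[1] = scheme == 0 ? Dt / h2 * bern(vf * h / Dt)
                       : Dt / h2 + (vf < 0 ? -vf / h : 0.0);
  }
  if (iy < ny - 1) { // north face, direction +y
    double Dt = D[s + nx];
    double vf = cdrift * (muy - (yll + (iy + 1) * h));
    r[2] = scheme == 0 ? Dt / h2 * bern(-vf * h / Dt)
                       : Dt / h2 + (vf > 0 ? vf / h : 0.0);
  }
  if (iy > 0) {      // south face, direction -y
    double Dt = D[s - nx];
    double vf = cdrift * (muy - (yll + iy * h));
    r[3] = scheme == 0 ? Dt / h2 * bern(vf * h / Dt)
                       : Dt / h2 + (vf < 0 ? -vf / h : 0.0);
  }
}

static double max_outflow(int nx, int ny, double h, double xll, double yll,
                          const double* D, double cdrift, double mux,
                          double muy, int scheme) {
  double r[4], m = 0.0;
  for (int s = 0; s < nx * ny; ++s) {
    rates4(s, nx, ny, h, xll, yll, D, cdrift, mux, muy, scheme, r);
    double tot = r[0] + r[1] + r[2] + r[3];
    if (tot > m) m = tot;
  }
  return m;
}

// Simulate movement tracks for several individuals on a shared landscape.
// Each individual has its own activity centre (mux, muy) and start cell.
// One observation step of length dt = 1 is split into m substeps with
// m = ceil(margin * max_i |Q_ii|), so that every substep transition
// probability 1 + delta Q_ii stays non-negative; within a substep the next
// cell is drawn from the categorical distribution {stay, 4 neighbours}.
// Records cell indices (1-based) at unit times after discarding burn_in.
// [[Rcpp::export]]
IntegerMatrix sim_tracks_cpp(int nx, int ny, double h, double xll, double yll,
                             NumericVector D, double cdrift,
                             NumericVector mux, NumericVector muy,
                             IntegerVector start_cell, int n_record,
                             int burn_in, int scheme, double margin) {
  int N = mux.size();
  IntegerMatrix out(n_record, N);
  const double* Dp = REAL(D);
  double r[4];
  for (int ind = 0; ind < N; ++ind) {
    double mout = max_outflow(nx, ny, h, xll, yll, Dp, cdrift, mux[ind],
                              muy[ind], scheme);
    int m = (int)std::ceil(margin * mout);
    if (m < 1) m = 1;
    double delta = 1.0 / m;
    int cur = start_cell[ind] - 1;
    for (int step = 0; step < burn_in + n_record; ++step) {
      for (int sub = 0; sub < m; ++sub) {
        rates4(cur, nx, ny, h, xll, yll, Dp, cdrift, mux[ind], muy[ind],
               scheme, r);
        double u = unif_rand();
        double acc = 0.0;
        int nxt = cur;
        acc += delta * r[0]; if (u < acc) { nxt = cur + 1;  goto moved; }
        acc += delta * r[1]; if (u < acc) { nxt = cur - 1;  goto moved; }
        acc += delta * r[2]; if (u < acc) { nxt = cur + nx; goto moved; }
        acc += delta * r[3]; if (u < acc) { nxt = cur - nx; goto moved; }
        moved:
        cur = nxt;
      }
      if (step >= burn_in) out(step - burn_in, ind) = cur + 1;
    }
  }
  return out;
}

// Number of substeps the simulator would use (shared logic, for callers
// that need to report or test the positivity bound).
// [[Rcpp::export]]
int substeps_cpp(int nx, int ny, double h, double xll, double yll,
                 NumericVector D, double cdrift, double mux, double muy,
                 int scheme, double margin) {
  double mout = max_outflow(nx, ny, h, xll, yll, REAL(D), cdrift, mux, muy,
                            scheme);
  int m = (int)std::ceil(margin * mout);
  return m < 1 ? 1 : m;
}

// Equilibrium distributions for a batch of activity centres.
// For each centre, the stationary system p' Q = 0 is solved as the banded
// linear system M p = e_k, where M = Q' with row k (k = the centre's cell)
// replaced by e_k' (pinning p_k = 1; the dropped stationarity equation is
// implied by the zero column sums of Q'), then renormalized to sum 1.
// The matrix has bandwidth nx, so LAPACK's dgbsv factorizes each system in
// O(n nx^2) time. Returns an (n_cells x n_centres) matrix of cell masses.
// [[Rcpp::export]]
NumericMatrix equilibrium_batch_cpp(int nx, int ny, double h, double xll,
                                    double yll, NumericVector D,
                                    double cdrift, NumericVector mux,
                                    NumericVector muy, int scheme) {
  int n = nx * ny, M = mux.size();
  int kl = nx, ku = nx, ldab = 2 * kl + ku + 1, nrhs = 1, info = 0;
  NumericMatrix out(n, M);
  std::vector<double> ab((size_t)ldab * n);
  std::vector<double> b(n);
  std::vector<int> ipiv(n);
  const double* Dp = REAL(D);
  double r[4];
  for (int c = 0; c < M; ++c) {
    // cell containing the centre
    int kx = (int)std::floor((mux[c] - xll) / h);
    int ky = (int)std::floor((muy[c] - yll) / h);
    if (kx < 0) kx = 0; if (kx > nx - 1) kx = nx - 1;
    if (ky < 0) ky = 0; if (ky > ny - 1) ky = ny - 1;
    int k = kx + ky * nx;
    std::fill(ab.begin(), ab.end(), 0.0);
    // column s of M = Q' holds the outgoing rates of cell s (rows = target)
    for (int s = 0; s < n; ++s) {
      rates4(s, nx, ny, h, xll, yll, Dp, cdrift, mux[c], muy[c], scheme, r);
      double diag = -(r[0] + r[1] + r[2] + r[3]);
      // band storage: A(i,j) -> ab[kl + ku + i - j + j*ldab]
      if (s != k) ab[(size_t)(kl + ku) + (size_t)s * ldab] = diag;
      if (r[0] > 0 && s + 1 != k)
        ab[(size_t)(kl + ku + 1) + (size_t)s * ldab] = r[0];
      if (r[1] > 0 && s - 1 != k)
        ab[(size_t)(kl + ku - 1) + (size_t)s * ldab] = r[1];
      if (r[2] > 0 && s + nx != k)
        ab[(size_t)(kl + ku + nx) + (size_t)s * ldab] = r[2];
      if (r[3] > 0 && s - nx != k)
        ab[(size_t)(kl + ku - nx) + (size_t)s * ldab] = r[3];
    }
    ab[(size_t)(kl + ku) + (size_t)k * ldab] = 1.0; // row k -> e_k
    std::fill(b.begin(), b.end(), 0.0);
    b[k] = 1.0;
    F77_CALL(dgbsv)(&n, &kl, &ku, &nrhs, ab.data(), &ldab, ipiv.data(),
                    b.data(), &n, &info);
    if (info != 0) stop("banded equilibrium solve failed (dgbsv info=%d)", info);
    double tot = 0.0;
    for (int s = 0; s < n; ++s) {
      if (b[s] < 0) b[s] = 0; // clip rounding noise
      tot += b[s];
    }
    for (int s = 0; s < n; ++s) out(s, c) = b[s] / tot;
  }
  return out;
}
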