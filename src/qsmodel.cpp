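// Backward-Euler integrator for the 1D coupled glucose / AI-2 model along a
// dead-end pore. Glucose: Dirichlet c0 at the juncture (x=0), no-flux at the
// tip, zeroth-order consumption where glucose remains (projected update:
// clamped after the diffusion solve). AI-2: Dirichlet 0 at the juncture
// (advective washout), no-flux at the tip, zeroth-order production and
// mass-limited zeroth-order uptake gated by the glucose threshold.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Constant-coefficient tridiagonal (Thomas) solver with precomputed forward
// sweep. Rows: 0 = identity (Dirichlet), interior (1+2r, -r), last (1+r).
struct Tridiag {
  int n;
  double r;
  std::vector<double> cp;   // modified super-diagonal
  std::vector<double> denom;
  void init(int n_, double r_) {
    n = n_; r = r_;
    cp.assign(n, 0.0);
    denom.assign(n, 1.0);
    // row 0: 1 * x0 = d0
    cp[0] = 0.0; denom[0] = 1.0;
    for (int i = 1; i < n; ++i) {
      double b = (i == n - 1) ? 1.0 + r : 1.0 + 2.0 * r;
      double a = -r;                        // sub-diagonal
      double c = (i == n - 1) ? 0.0 : -r;   // super-diagonal
      double den = b - a * cp[i - 1];
      denom[i] = den;
      cp[i] = c / den;
    }
  }
  void solve(std::vector<double>& d) const {
    // forward
    for (int i = 1; i < n; ++i)
      d[i] = (d[i] + r * d[i - 1]) / denom[i];
    // back substitution
    for (int i = n - 2; i >= 0; --i)
      d[i] -= cp[i] * d[i + 1];
  }
};

// [[Rcpp::export]]
List cpp_qs_integrate(NumericVector c_B, double c0, double U1c,
                      double kp, double km, double thetaG,
                      double DG, double DA, double dx, double dt,
                      int n_steps, IntegerVector save_steps) {
  int nx = c_B.size();
  int ns = save_steps.size();
  NumericMatrix CG(nx, ns), CA(nx, ns);
  Tridiag tg, ta;
  tg.init(nx, dt * DG / (dx * dx));
  ta.init(nx, dt * DA / (dx * dx));
  std::vector<double> cg(nx, c0), ca(nx, 0.0), rhs(nx);
  int rec = 0;
  // save step 0 if requested
  while (rec < ns && save_steps[rec] <= 0) {
    for (int i = 0; i < nx; ++i) { CG(i, rec) = cg[i]; CA(i, rec) = ca[i]; }
    ++rec;
  }
  for (int k = 1; k <= n_steps; ++k) {
    // glucose
    for (int i = 0; i < nx; ++i)
      rhs[i] = cg[i] - dt * U1c * c_B[i] * (cg[i] > 0.0 ? 1.0 : 0.0);
    rhs[0] = c0;
    tg.solve(rhs);
    for (int i = 0; i < nx; ++i) {
      double v = rhs[i];
      if (v < 0.0) v = 0.0;
      if (v > c0) v = c0;
      // AI-2 source assembled with the *pre-update* glucose switch
      cg[i] = v;
    }
    // AI-2 (glucose switch evaluated on the updated field; both fields are
    // quasi-steady on the extraction time scale)
    for (int i = 0; i < nx; ++i) {
      double f = (cg[i] < thetaG) ? 1.0 : 0.0;
      double prod = kp * c_B[i];
      double upt = km * f * c_B[i];
      double avail = ca[i] / dt + prod;
      if (upt > avail) upt = avail;
      rhs[i] = ca[i] + dt * (prod - upt);
    }
    rhs[0] = 0.0;
    ta.solve(rhs);
    for (int i = 0; i < nx; ++i) ca[i] = rhs[i] > 0.0 ? rhs[i] : 0.0;
    while (rec < ns && save_steps[rec] <= k) {
      for (int i = 0; i < nx; ++i) { CG(i, rec) = cg[i]; CA(i, rec) = ca[i]; }
      ++rec;
    }
  }
  return List::create(_["CG"] = CG, _["CA"] = CA);
}
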