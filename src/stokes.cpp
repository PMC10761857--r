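// Assembly of the staggered-grid (MAC) Stokes saddle-point system on a
// binary pore geometry. Unknowns: u at vertical faces (including inlet and
// outlet boundary faces), v at interior horizontal faces, p at pore cells.
// No-slip on solid and on the top/bottom domain walls via ghost reflection;
// pressures p_in/p_out imposed at the inlet/outlet ghost cells.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_stokes_assemble(LogicalMatrix pore, double p_in, double p_out) {
  int nr = pore.nrow(), nc = pore.ncol();
  IntegerMatrix uid(nr, nc + 1), vid(nr - 1, nc), pid(nr, nc);
  int nxt = 0;
  for (int j = 0; j <= nc; ++j)
    for (int i = 0; i < nr; ++i) {
      bool active;
      if (j == 0) active = pore(i, 0);
      else if (j == nc) active = pore(i, nc - 1);
      else active = pore(i, j - 1) && pore(i, j);
      if (active) uid(i, j) = ++nxt;
    }
  int n_u = nxt;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr - 1; ++i)
      if (pore(i, j) && pore(i + 1, j)) vid(i, j) = ++nxt;
  int n_v = nxt - n_u;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (pore(i, j)) pid(i, j) = ++nxt;
  int n_tot = nxt;

  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve(7 * n_tot); tj.reserve(7 * n_tot); tx.reserve(7 * n_tot);
  NumericVector rhs(n_tot);
  // x-momentum
  for (int j = 0; j <= nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int r = uid(i, j);
      if (!r) continue;
      double diag = -4.0;
      for (int s = -1; s <= 1; s += 2) {          // E/W (normal)
        int jn = j + s;
        if (jn < 0 || jn > nc) { diag += 1.0; continue; } // zero-gradient at edge
        int un = uid(i, jn);
        if (un) { ti.push_back(r); tj.push_back(un); tx.push_back(1.0); }
        // else: neighbouring face sits on solid -> u = 0
      }
      for (int s = -1; s <= 1; s += 2) {          // N/S (tangential)
        int in = i + s;
        if (in < 0 || in >= nr) { diag -= 1.0; continue; } // wall ghost
        int un = uid(in, j);
        if (un) { ti.push_back(r); tj.push_back(un); tx.push_back(1.0); }
        else diag -= 1.0;                          // solid wall ghost: u_g = -u
      }
      ti.push_back(r); tj.push_back(r); tx.push_back(diag);
      if (j == 0) {
        ti.push_back(r); tj.push_back(pid(i, 0)); tx.push_back(-1.0);
        rhs[r - 1] = -p_in;
      } else if (j == nc) {
        ti.push_back(r); tj.push_back(pid(i, nc - 1)); tx.push_back(1.0);
        rhs[r - 1] = p_out;
      } else {
        ti.push_back(r); tj.push_back(pid(i, j)); tx.push_back(-1.0);
        ti.push_back(r); tj.push_back(pid(i, j - 1)); tx.push_back(1.0);
      }
    }
  // y-momentum
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr - 1; ++i) {
      int r = vid(i, j);
      if (!r) continue;
      double diag = -4.0;
      for (int s = -1; s <= 1; s += 2) {          // N/S (normal)
        int in = i + s;
        if (in < 0 || in >= nr - 1) continue;      // v = 0 on wall faces
        int vn = vid(in, j);
        if (vn) { ti.push_back(r); tj.push_back(vn); tx.push_back(1.0); }
      }
      for (int s = -1; s <= 1; s += 2) {          // E/W (tangential)
        int jn = j + s;
        if (jn < 0 || jn >= nc) { diag -= 1.0; continue; }
        int vn = vid(i, jn);
        if (vn) { ti.push_back(r); tj.push_back(vn); tx.push_back(1.0); }
        else diag -= 1.0;
      }
      ti.push_back(r); tj.push_back(r); tx.push_back(diag);
      ti.push_back(r); tj.push_back(pid(i + 1, j)); tx.push_back(-1.0);
      ti.push_back(r); tj.push_back(pid(i, j)); tx.push_back(1.0);
    }
  // continuity
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int r = pid(i, j);
      if (!r) continue;
      int ue = uid(i, j + 1), uw = uid(i, j);
      if (ue) { ti.push_back(r); tj.push_back(ue); tx.push_back(1.0); }
      if (uw) { ti.push_back(r); tj.push_back(uw); tx.push_back(-1.0); }
      int vs = (i < nr - 1) ? vid(i, j) : 0;
      int vn = (i > 0) ? vid(i - 1, j) : 0;
      if (vs) { ti.push_back(r); tj.push_back(vs); tx.push_back(1.0); }
      if (vn) { ti.push_back(r); tj.push_back(vn); tx.push_back(-1.0); }
    }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx),
                      _["rhs"] = rhs, _["uid"] = uid, _["vid"] = vid,
                      _["pid"] = pid, _["n_u"] = n_u, _["n_v"] = n_v,
                      _["n_tot"] = n_tot);
}
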