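#include <Rcpp.h>
using namespace Rcpp;

// Nearest lipid residue for each grid point of one area-per-lipid plane.
// Plain all-pairs scan: G * N distance evaluations with xy minimum image and
// an optional z term (the grid sits at a fixed z).  Atom coordinates are
// wrapped into the box once so the minimum image reduces to a compare, and
// the z contribution is hoisted out of the grid loop.  Ties break toward the
// earlier atom in file order (strict less-than).
// [[Rcpp::export]]
IntegerVector grid_nearest(NumericMatrix grid_xy, double gz,
                           NumericMatrix atoms, IntegerVector resid,
                           double Lx, double Ly, bool use_z) {
  const int G = grid_xy.nrow();
  const int N = atoms.nrow();
  if (N == 0) stop("no candidate atoms for grid assignment");
  std::vector<double> wx(N), wy(N), dz2(N);
  for (int i = 0; i < N; ++i) {
    wx[i] = atoms(i, 0) - Lx * std::floor(atoms(i, 0) / Lx);
    wy[i] = atoms(i, 1) - Ly * std::floor(atoms(i, 1) / Ly);
    const double dz = use_z ? atoms(i, 2) - gz : 0.0;
    dz2[i] = dz * dz;
  }
  IntegerVector out(G);
  for (int g = 0; g < G; ++g) {
    const double gx = grid_xy(g, 0), gy = grid_xy(g, 1);
    double best = R_PosInf;
    int win = -1;
    for (int i = 0; i < N; ++i) {
      double dx = std::fabs(wx[i] - gx);
      if (dx > Lx - dx) dx = Lx - dx;
      double dy = std::fabs(wy[i] - gy);
      if (dy > Ly - dy) dy = Ly - dy;
      const double d2 = dx * dx + dy * dy + dz2[i];
      if (d2 < best) {
        best = d2;
        win = i;
      }
    }
    out[g] = resid[win];
  }
  return out;
}
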