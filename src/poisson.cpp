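#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Red-black successive over-relaxation for the 7-point finite-difference
// discretisation of div(eps grad phi) = -4 pi k rho on a regular grid.
//
// eps_x/eps_y/eps_z hold the edge dielectric between node (i,j,k) and its
// +x/+y/+z neighbour (last slice along the respective axis unused).
// src holds 4 pi k q_node / h per node. Boundary nodes are Dirichlet
// (taken from the initial phi) and never updated.
// [[Rcpp::export]]
List poisson_sor(NumericVector phi_init, NumericVector eps_x,
                 NumericVector eps_y, NumericVector eps_z,
                 NumericVector src, IntegerVector dims,
                 double omega, double tol, int max_iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi = clone(phi_init);
  auto id = [&](int i, int j, int k) { return i + nx * (j + ny * k); };
  double maxphi = 1e-30;
  for (int n = 0; n < phi.size(); ++n)
    maxphi = std::max(maxphi, std::fabs(phi[n]));
  int it = 0;
  double maxdiff = 0.0;
  for (it = 1; it <= max_iter; ++it) {
    maxdiff = 0.0;
    for (int colour = 0; colour < 2; ++colour) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          for (int i = 1; i < nx - 1; ++i) {
            if (((i + j + k) & 1) != colour) continue;
            const int c = id(i, j, k);
            const double exm = eps_x[id(i - 1, j, k)], exp_ = eps_x[c];
            const double eym = eps_y[id(i, j - 1, k)], eyp = eps_y[c];
            const double ezm = eps_z[id(i, j, k - 1)], ezp = eps_z[c];
            const double denom = exm + exp_ + eym + eyp + ezm + ezp;
            const double gs =
              (exm * phi[id(i - 1, j, k)] + exp_ * phi[id(i + 1, j, k)] +
               eym * phi[id(i, j - 1, k)] + eyp * phi[id(i, j + 1, k)] +
               ezm * phi[id(i, j, k - 1)] + ezp * phi[id(i, j, k + 1)] +
               src[c]) / denom;
            const double nv = (1.0 - omega) * phi[c] + omega * gs;
            const double d = std::fabs(nv - phi[c]);
            if (d > maxdiff) maxdiff = d;
            phi[c] = nv;
            const double av = std::fabs(nv);
            if (av > maxphi) maxphi = av;
          }
        }
      }
    }
    if (maxdiff / maxphi < tol) break;
  }
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["converged"] = (maxdiff / maxphi < tol));
}
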