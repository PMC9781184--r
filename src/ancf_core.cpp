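// Compiled kernels for the 3363 ANCF continuum beam element.
//
// The hot path of the static solver is the per-element internal force and
// its finite-difference tangent, evaluated over several hundred quadrature
// points per element. These kernels mirror the reference R implementations
// exactly (same isochoric/volumetric neo-Hookean split, same displacement
// based deformation gradient); the R versions remain in the package and the
// test suite asserts agreement between the two routes. All 3x3 algebra is
// written out closed-form to avoid allocation in the inner loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// S (column-major 3x3, symmetric) and energy density at one point from the
// deformation gradient F (column-major). Returns false when J <= 0.
static inline bool pk2_point(const double *F, double mu, double k,
                             double *S, double &psi) {
  const double J = F[0] * (F[4] * F[8] - F[7] * F[5])
                 - F[3] * (F[1] * F[8] - F[7] * F[2])
                 + F[6] * (F[1] * F[5] - F[4] * F[2]);
  if (!(J > 0.0) || !std::isfinite(J)) return false;
  // C = F^T F (symmetric; store unique entries)
  const double C11 = F[0] * F[0] + F[1] * F[1] + F[2] * F[2];
  const double C22 = F[3] * F[3] + F[4] * F[4] + F[5] * F[5];
  const double C33 = F[6] * F[6] + F[7] * F[7] + F[8] * F[8];
  const double C12 = F[0] * F[3] + F[1] * F[4] + F[2] * F[5];
  const double C13 = F[0] * F[6] + F[1] * F[7] + F[2] * F[8];
  const double C23 = F[3] * F[6] + F[4] * F[7] + F[5] * F[8];
  const double I1 = C11 + C22 + C33;
  const double detC = J * J;
  // C^{-1} via the adjugate
  const double i11 = (C22 * C33 - C23 * C23) / detC;
  const double i22 = (C11 * C33 - C13 * C13) / detC;
  const double i33 = (C11 * C22 - C12 * C12) / detC;
  const double i12 = (C13 * C23 - C12 * C33) / detC;
  const double i13 = (C12 * C23 - C13 * C22) / detC;
  const double i23 = (C12 * C13 - C11 * C23) / detC;
  const double Jm23 = std::pow(J, -2.0 / 3.0);
  const double a = mu * Jm23;
  const double b = -mu * Jm23 * I1 / 3.0 + 2.0 * k * (J - 1.0) * J;
  S[0] = a + b * i11; S[4] = a + b * i22; S[8] = a + b * i33;
  S[1] = S[3] = b * i12;
  S[2] = S[6] = b * i13;
  S[5] = S[7] = b * i23;
  psi = mu / 2.0 * (Jm23 * I1 - 3.0) + k * (J - 1.0) * (J - 1.0);
  return true;
}

// f (3 x 18) += W * F * S * B^T for one quadrature point
static inline void accumulate_force(const double *F, const double *S,
                                    const double *B, double W, double *f) {
  double M[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      M[3 * c + r] = W * (F[r] * S[3 * c] + F[3 + r] * S[3 * c + 1] +
                          F[6 + r] * S[3 * c + 2]);
  for (int a = 0; a < 18; ++a) {
    const double b0 = B[a], b1 = B[18 + a], b2 = B[36 + a];
    f[3 * a + 0] += M[0] * b0 + M[3] * b1 + M[6] * b2;
    f[3 * a + 1] += M[1] * b0 + M[4] * b1 + M[7] * b2;
    f[3 * a + 2] += M[2] * b0 + M[5] * b1 + M[8] * b2;
  }
}

// internal force of one element: f = sum_p W_p F_p S_p B_p^T with
// F_p = I + Ue B_p (displacement form: exact identity at the reference).
// Ue: 3 x 18 nodal displacements, Bq: 54 x nqp (the three 18-long B columns
// of each point stacked), W: nqp. Empty matrix signals J <= 0.
// [[Rcpp::export(name = ".elt_force_cpp2")]]
arma::mat elt_force_cpp2(const arma::mat &Ue, const arma::mat &Bq,
                         const arma::vec &W, double mu, double k) {
  const uword nqp = W.n_elem;
  mat fout(3, 18, fill::zeros);
  double F[9], S[9], psi;
  const double *U = Ue.memptr();
  double *f = fout.memptr();
  for (uword p = 0; p < nqp; ++p) {
    const double *B = Bq.colptr(p);
    for (int c = 0; c < 3; ++c) {
      const double *bc = B + 18 * c;
      double f0 = 0, f1 = 0, f2 = 0;
      for (int a = 0; a < 18; ++a) {
        f0 += U[3 * a + 0] * bc[a];
        f1 += U[3 * a + 1] * bc[a];
        f2 += U[3 * a + 2] * bc[a];
      }
      F[3 * c + 0] = f0 + (c == 0);
      F[3 * c + 1] = f1 + (c == 1);
      F[3 * c + 2] = f2 + (c == 2);
    }
    if (!pk2_point(F, mu, k, S, psi)) return mat();
    accumulate_force(F, S, B, W(p), f);
  }
  return fout;
}

// total strain energy of one element; NaN on a degenerate state
// [[Rcpp::export(name = ".elt_energy_cpp2")]]
double elt_energy_cpp2(const arma::mat &Ue, const arma::mat &Bq,
                       const arma::vec &W, double mu, double k) {
  const uword nqp = W.n_elem;
  double total = 0.0, F[9], S[9], psi;
  const double *U = Ue.memptr();
  for (uword p = 0; p < nqp; ++p) {
    const double *B = Bq.colptr(p);
    for (int c = 0; c < 3; ++c) {
      const double *bc = B + 18 * c;
      double f0 = 0, f1 = 0, f2 = 0;
      for (int a = 0; a < 18; ++a) {
        f0 += U[3 * a + 0] * bc[a];
        f1 += U[3 * a + 1] * bc[a];
        f2 += U[3 * a + 2] * bc[a];
      }
      F[3 * c + 0] = f0 + (c == 0);
      F[3 * c + 1] = f1 + (c == 1);
      F[3 * c + 2] = f2 + (c == 2);
    }
    if (!pk2_point(F, mu, k, S, psi)) return datum::nan;
    total += W(p) * psi;
  }
  return total;
}

// element tangent by central finite differences of the internal force;
// h is scaled per dof by max(1, |q|). Empty matrix on degenerate states.
// [[Rcpp::export(name = ".elt_tangent_cpp2")]]
arma::mat elt_tangent_cpp2(const arma::mat &Ue, const arma::mat &Qb,
                           const arma::mat &Bq, const arma::vec &W,
                           double mu, double k, double h) {
  mat K(54, 54, fill::zeros);
  for (uword a = 0; a < 54; ++a) {
    const uword c = a % 3, shp = a / 3;
    const double q_a = Ue(c, shp) + Qb(c, shp);
    const double ha = h * std::max(1.0, std::fabs(q_a));
    mat Up = Ue, Um = Ue;
    Up(c, shp) += ha;
    Um(c, shp) -= ha;
    const mat fp = elt_force_cpp2(Up, Bq, W, mu, k);
    const mat fm = elt_force_cpp2(Um, Bq, W, mu, k);
    if (fp.n_elem == 0 || fm.n_elem == 0) return mat();
    K.col(a) = vectorise(fp - fm) / (2.0 * ha);
  }
  return 0.5 * (K + K.t());
}
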