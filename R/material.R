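#' Near-incompressible neo-Hookean material
#'
#' Isochoric/volumetric split of the deformation gradient, F = J^(1/3) Fbar,
#' with strain energy
#'   Psi = (mu / 2) (Ibar1 - 3) + k (J - 1)^2,
#' where Ibar1 = tr(Cbar), Cbar = J^(-2/3) C, C = F^T F. The quadratic
#' volumetric penalty enforces near-incompressibility; k is chosen large
#' against mu (default k = 1000 c10). The second Piola-Kirchhoff stress is
#' S = 2 dPsi/dC, split into
#'   Sbar  = mu J^(-2/3) (I - Ibar1 Cbar^{-1} / 3)
#'   Svol  = 2 k (J - 1) J C^{-1}.
#'
#' Tendon literature reports "shear modulus c10"; the energy above uses
#' mu = c10 (convention `"shear"`, the default), which reproduces published
#' tendon load-elongation data. The literal one-parameter form
#' Psi_iso = c10 (Ibar1 - 3), i.e. mu = 2 c10, is available as convention
#' `"literal"`.
#'
#' @param c10 shear-modulus-like constant (MPa), > 0
#' @param k volumetric penalty (MPa), > 0 and >> c10
#' @param convention `"shear"` (mu = c10) or `"literal"` (mu = 2 c10)
#' @return object of class `neo_hookean` with fields `mu`, `k`, `c10`
#' @export
neo_hookean <- function(c10, k = 1000 * c10, convention = c("shear", "literal")) {
  convention <- match.arg(convention)
  if (!is.numeric(c10) || c10 <= 0) stop("neo_hookean: 'c10' must be positive")
  if (!is.numeric(k) || k <= 0) stop("neo_hookean: 'k' must be positive")
  structure(list(c10 = c10, k = k, convention = convention,
                 mu = if (convention == "shear") c10 else 2 * c10),
            class = "neo_hookean")
}

.check_F <- function(F) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop(structure(class = c("ancf_degenerate_state", "error", "condition"),
                   list(message = sprintf("constitutive failure: J = %.3g <= 0", J),
                        call = sys.call())))
  list(F = F, J = J)
}

#' Isochoric/volumetric split of a deformation gradient
#'
#' @param F 3 x 3 deformation gradient with det F > 0
#' @return list with `J`, `Fbar` (unimodular), `Cbar`
#' @export
split_deformation <- function(F) {
  s <- .check_F(F)
  Fbar <- s$J^(-1 / 3) * s$F
  list(J = s$J, Fbar = Fbar, Cbar = crossprod(Fbar))
}

#' Green-Lagrange strain tensor E = (F^T F - I) / 2
#'
#' @param F 3 x 3 deformation gradient
#' @return symmetric 3 x 3 matrix
#' @export
strain_green <- function(F) {
  (crossprod(as.matrix(F)) - diag(3)) / 2
}

#' Isochoric part of the second Piola-Kirchhoff stress
#'
#' @param F 3 x 3 deformation gradient
#' @param mat a [neo_hookean()] material
#' @return symmetric 3 x 3 matrix
#' @export
pk2_isochoric <- function(F, mat) {
  s <- .check_F(F)
  C <- crossprod(s$F)
  mat$mu * s$J^(-2 / 3) * (diag(3) - sum(diag(C)) * solve(C) / 3)
}

#' Volumetric (penalty) part of the second Piola-Kirchhoff stress
#'
#' @inheritParams pk2_isochoric
#' @return symmetric 3 x 3 matrix, zero at J = 1
#' @export
pk2_volumetric <- function(F, mat) {
  s <- .check_F(F)
  C <- crossprod(s$F)
  2 * mat$k * (s$J - 1) * s$J * solve(C)
}

#' Total second Piola-Kirchhoff stress S = 2 dPsi/dC
#'
#' @inheritParams pk2_isochoric
#' @return symmetric 3 x 3 matrix, zero at F = I
#' @export
pk2_stress <- function(F, mat) {
  pk2_isochoric(F, mat) + pk2_volumetric(F, mat)
}

#' Strain energy density Psi(F)
#'
#' @inheritParams pk2_isochoric
#' @return scalar energy density (MPa = N/mm^2 per unit reference volume)
#' @export
strain_energy <- function(F, mat) {
  s <- .check_F(F)
  C <- crossprod(s$F)
  mat$mu / 2 * (s$J^(-2 / 3) * sum(diag(C)) - 3) + mat$k * (s$J - 1)^2
}

# Vectorized constitutive evaluation over many deformation gradients.
# F9: n x 9 matrix, columns F11,F21,F31,F12,F22,F32,F13,F23,F33 (column-major
# 3 x 3). Returns list(S9 = n x 9 second PK stress, psi = n energies, J = n).
# Non-positive J is signalled as an 'ancf_degenerate_state' condition.
.pk2_vec <- function(F9, mat) {
  F11 <- F9[, 1]; F21 <- F9[, 2]; F31 <- F9[, 3]
  F12 <- F9[, 4]; F22 <- F9[, 5]; F32 <- F9[, 6]
  F13 <- F9[, 7]; F23 <- F9[, 8]; F33 <- F9[, 9]
  J <- F11 * (F22 * F33 - F23 * F32) - F12 * (F21 * F33 - F23 * F31) +
    F13 * (F21 * F32 - F22 * F31)
  if (any(!is.finite(J)) || any(J <= 0))
    stop(structure(class = c("ancf_degenerate_state", "error", "condition"),
                   list(message = "element inversion: J <= 0 at a quadrature point",
                        call = sys.call())))
  C11 <- F11^2 + F21^2 + F31^2
  C22 <- F12^2 + F22^2 + F32^2
  C33 <- F13^2 + F23^2 + F33^2
  C12 <- F11 * F12 + F21 * F22 + F31 * F32
  C13 <- F11 * F13 + F21 * F23 + F31 * F33
  C23 <- F12 * F13 + F22 * F23 + F32 * F33
  I1 <- C11 + C22 + C33
  detC <- J^2
  # inverse of symmetric C via adjugate
  iC11 <- (C22 * C33 - C23^2) / detC
  iC22 <- (C11 * C33 - C13^2) / detC
  iC33 <- (C11 * C22 - C12^2) / detC
  iC12 <- (C13 * C23 - C12 * C33) / detC
  iC13 <- (C12 * C23 - C13 * C22) / detC
  iC23 <- (C12 * C13 - C11 * C23) / detC
  Jm23 <- J^(-2 / 3)
  a <- mat$mu * Jm23                 # coefficient of I
  b <- -mat$mu * Jm23 * I1 / 3 + 2 * mat$k * (J - 1) * J  # coefficient of C^{-1}
  S11 <- a + b * iC11; S22 <- a + b * iC22; S33 <- a + b * iC33
  S12 <- b * iC12; S13 <- b * iC13; S23 <- b * iC23
  list(S9 = cbind(S11, S12, S13, S12, S22, S23, S13, S23, S33),
       psi = mat$mu / 2 * (Jm23 * I1 - 3) + mat$k * (J - 1)^2,
       J = J)
}
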