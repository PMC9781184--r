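#' The three-node 3363 ANCF continuum beam element
#'
#' Nodal unknowns are global position vectors and their spatial derivatives.
#' Each of the three nodes (at local axial coordinates xi = -1, 0, +1)
#' carries six 3-vectors: the position r, the transverse slope vectors
#' r_y and r_z, and the second-derivative vectors r_yz, r_yy and r_zz,
#' i.e. 18 scalar degrees of freedom per node and 54 per element. The
#' interpolation is quadratic in the axial direction and a complete
#' quadratic in the two cross-section directions, so cross-sections can
#' stretch, shear and warp. Local coordinates (xi, eta, zeta) range over
#' [-1, 1]^3 with x = lx xi / 2, y = ly eta / 2, z = lz zeta / 2.
#'
#' Per-node ordering of the vector degrees of freedom follows the shape
#' function list: (r, r_y, r_z, r_yz, r_yy, r_zz).
#'
#' @name ancf_kinematics
NULL

#' Element physical dimensions
#'
#' @param lx,ly,lz element dimensions (mm): axial length and the
#'   cross-section bounding-box edges used to binormalize (eta, zeta)
#' @return object of class `element_geometry`
#' @export
element_geometry <- function(lx, ly, lz) {
  if (any(c(lx, ly, lz) <= 0)) stop("element_geometry: dimensions must be positive")
  structure(list(lx = lx, ly = ly, lz = lz), class = "element_geometry")
}

#' Shape functions of the 3363 element
#'
#' Returns the 18 scalar shape functions; the 3 x 54 interpolation matrix is
#' their Kronecker expansion with the 3 x 3 identity. Vectorized over
#' evaluation points.
#'
#' @param xi,eta,zeta local coordinates in [-1, 1] (equal-length vectors)
#' @param geom an [element_geometry()]
#' @return an 18 x n matrix (n = number of points); for a single point a
#'   plain length-18 vector
#' @export
shape_functions <- function(xi, eta, zeta, geom) {
  y <- geom$ly * eta / 2; z <- geom$lz * zeta / 2
  L1 <- xi * (xi - 1) / 2; L2 <- 1 - xi^2; L3 <- xi * (xi + 1) / 2
  N <- rbind(L1, y * L1, z * L1, y * z * L1, y^2 / 2 * L1, z^2 / 2 * L1,
             L2, y * L2, z * L2, y * z * L2, y^2 / 2 * L2, z^2 / 2 * L2,
             L3, y * L3, z * L3, y * z * L3, y^2 / 2 * L3, z^2 / 2 * L3)
  if (ncol(N) == 1L) dim(N) <- NULL
  N
}

#' Shape function derivatives with respect to (xi, eta, zeta)
#'
#' Analytic closed-form derivatives of [shape_functions()].
#'
#' @inheritParams shape_functions
#' @return for a single point an 18 x 3 matrix; for n points an
#'   18 x 3 x n array
#' @export
shape_derivatives <- function(xi, eta, zeta, geom) {
  hy <- geom$ly / 2; hz <- geom$lz / 2
  y <- hy * eta; z <- hz * zeta
  L1 <- xi * (xi - 1) / 2; L2 <- 1 - xi^2; L3 <- xi * (xi + 1) / 2
  d1 <- xi - 0.5; d2 <- -2 * xi; d3 <- xi + 0.5
  n <- length(xi)
  out <- array(0, c(18L, 3L, n))
  blocks <- list(list(L1, d1), list(L2, d2), list(L3, d3))
  for (b in 1:3) {
    L <- blocks[[b]][[1]]; dL <- blocks[[b]][[2]]
    i0 <- (b - 1L) * 6L
    out[i0 + 1L, 1L, ] <- dL
    out[i0 + 2L, 1L, ] <- y * dL;          out[i0 + 2L, 2L, ] <- hy * L
    out[i0 + 3L, 1L, ] <- z * dL;          out[i0 + 3L, 3L, ] <- hz * L
    out[i0 + 4L, 1L, ] <- y * z * dL
    out[i0 + 4L, 2L, ] <- hy * z * L;      out[i0 + 4L, 3L, ] <- hz * y * L
    out[i0 + 5L, 1L, ] <- y^2 / 2 * dL;    out[i0 + 5L, 2L, ] <- hy * y * L
    out[i0 + 6L, 1L, ] <- z^2 / 2 * dL;    out[i0 + 6L, 3L, ] <- hz * z * L
  }
  if (n == 1L) out[, , 1L] else out
}

#' Second derivatives of the shape functions (for contact surface curvature)
#'
#' @inheritParams shape_functions
#' @return 18 x 6 matrix (single point) or 18 x 6 x n array; columns are the
#'   second derivatives in the order (xixi, xieta, xizeta, etaeta, etazeta,
#'   zetazeta)
#' @keywords internal
shape_second_derivatives <- function(xi, eta, zeta, geom) {
  hy <- geom$ly / 2; hz <- geom$lz / 2
  y <- hy * eta; z <- hz * zeta
  L <- list(xi * (xi - 1) / 2, 1 - xi^2, xi * (xi + 1) / 2)
  dL <- list(xi - 0.5, -2 * xi, xi + 0.5)
  d2L <- list(rep(1, length(xi)), rep(-2, length(xi)), rep(1, length(xi)))
  n <- length(xi)
  out <- array(0, c(18L, 6L, n))
  for (b in 1:3) {
    i0 <- (b - 1L) * 6L
    out[i0 + 1L, 1L, ] <- d2L[[b]]
    out[i0 + 2L, 1L, ] <- y * d2L[[b]];       out[i0 + 2L, 2L, ] <- hy * dL[[b]]
    out[i0 + 3L, 1L, ] <- z * d2L[[b]];       out[i0 + 3L, 3L, ] <- hz * dL[[b]]
    out[i0 + 4L, 1L, ] <- y * z * d2L[[b]]
    out[i0 + 4L, 2L, ] <- hy * z * dL[[b]];   out[i0 + 4L, 3L, ] <- hz * y * dL[[b]]
    out[i0 + 4L, 5L, ] <- hy * hz * L[[b]]
    out[i0 + 5L, 1L, ] <- y^2 / 2 * d2L[[b]]; out[i0 + 5L, 2L, ] <- hy * y * dL[[b]]
    out[i0 + 5L, 4L, ] <- hy^2 * L[[b]]
    out[i0 + 6L, 1L, ] <- z^2 / 2 * d2L[[b]]; out[i0 + 6L, 3L, ] <- hz * z * dL[[b]]
    out[i0 + 6L, 6L, ] <- hz^2 * L[[b]]
  }
  if (n == 1L) out[, , 1L] else out
}

#' Interpolate the position field of an element
#'
#' @param q element coordinate vector (length 54) or 3 x 18 matrix
#' @param xi,eta,zeta local coordinates (vectors of equal length)
#' @param geom an [element_geometry()]
#' @return 3 x n matrix of positions (a plain 3-vector for a single point)
#' @export
evaluate_position <- function(q, xi, eta, zeta, geom) {
  Q <- if (is.matrix(q)) q else matrix(q, nrow = 3L)
  r <- Q %*% shape_functions(xi, eta, zeta, geom)
  if (is.matrix(r) && ncol(r) == 1L) dim(r) <- NULL
  r
}

#' Deformation gradient of an element at a local point
#'
#' F = (dr/dxi) (drbar/dxi)^{-1}, together with J = det F. The reference
#' Jacobian must be invertible; a non-positive J is reported through a
#' condition of class `ancf_degenerate_state` so the static solver can cut
#' the load step.
#'
#' @param q current element coordinates (54-vector or 3 x 18)
#' @param qbar reference element coordinates
#' @param xi,eta,zeta local point
#' @param geom an [element_geometry()]
#' @param check_J signal an error for J <= 0 (default TRUE)
#' @return list with `F` (3 x 3) and `J`
#' @export
deformation_gradient <- function(q, qbar, xi, eta, zeta, geom, check_J = TRUE) {
  Q <- if (is.matrix(q)) q else matrix(q, nrow = 3L)
  Qb <- if (is.matrix(qbar)) qbar else matrix(qbar, nrow = 3L)
  dN <- shape_derivatives(xi, eta, zeta, geom)
  Jb <- Qb %*% dN
  dJ <- det(Jb)
  if (abs(dJ) < 1e-14) stop("deformation_gradient: singular reference Jacobian")
  F <- (Q %*% dN) %*% solve(Jb)
  J <- det(F)
  if (check_J && J <= 0)
    stop(structure(class = c("ancf_degenerate_state", "error", "condition"),
                   list(message = sprintf("deformation_gradient: J = %.3g <= 0", J),
                        call = sys.call())))
  list(F = F, J = J)
}

#' Reference nodal coordinates of a pretwisted beam chain
#'
#' Nodes are equally spaced along the axial direction. The beam's own
#' centerline passes through `offset` (mm, in the cross-section plane)
#' rotated about the global x axis by theta(x) = psi x / L, so a beam with
#' a nonzero offset and twist winds helically around the straight twist
#' axis while its cross-section rides along. The rotation is
#' counterclockwise seen from x = 0 towards x = L (right-handed about +x;
#' pass a negative `twist_deg` for the opposite handedness). Slope vectors
#' are the rotated transverse unit directions (no initial cross-section
#' stretch); all second-derivative coordinates are zero in the reference.
#'
#' @param L beam length (mm)
#' @param twist_deg total pretwist angle psi in degrees over `[0, L]`
#' @param n_elements number of 3363 elements in the chain (>= 1)
#' @param offset centerline position in the (y, z) plane at x = 0 (mm)
#' @return list with `node_x` (axial positions, length 2 n + 1), `qnodes`
#'   (18 x n_nodes matrix of nodal coordinates) and `qbar` (the stacked
#'   coordinate vector)
#' @export
reference_nodes <- function(L, twist_deg, n_elements, offset = c(0, 0)) {
  if (L <= 0) stop("reference_nodes: L must be positive")
  n_elements <- as.integer(n_elements)
  if (n_elements < 1L) stop("reference_nodes: n_elements must be >= 1")
  node_x <- seq(0, L, length.out = 2L * n_elements + 1L)
  th <- (twist_deg * pi / 180) * node_x / L
  qn <- matrix(0, 18L, length(node_x))
  qn[1L, ] <- node_x
  qn[2L, ] <- cos(th) * offset[1] - sin(th) * offset[2]
  qn[3L, ] <- sin(th) * offset[1] + cos(th) * offset[2]
  qn[5L, ] <- cos(th); qn[6L, ] <- sin(th)        # r_y
  qn[8L, ] <- -sin(th); qn[9L, ] <- cos(th)       # r_z
  list(node_x = node_x, qnodes = qn, qbar = as.vector(qn))
}
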