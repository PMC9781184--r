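#' Frictionless surface-to-surface contact between subtendon beams
#'
#' Contact couples pairs of beams through a penalty on the normal gap
#' between their lateral surfaces. Surface samples live on the "slave" beam
#' A: axial Gauss stations times arc points on the sector of A's
#' cross-section border that faces B in the reference configuration. Each
#' sample is projected onto B's lateral surface (closest-point projection,
#' warm-started damped Gauss-Newton over the axial coordinate and a global
#' cyclic arc parameter of B's boundary). The gap is the distance resolved
#' along B's outward surface normal; with the first-order optimality of the
#' projection, the gap variation reduces to n . (delta xA - delta xB), which
#' yields equal-and-opposite nodal force contributions on A and B.
#'
#' Two enforcement modes exist. The default, `"bilateral"`, penalizes the
#' change of the gap from its reference value (a sliding tie: neighbouring
#' subtendons can slide axially but neither separate nor penetrate), so the
#' reference configuration is exactly stress-free. Mode `"unilateral"`
#' penalizes only penetration (g < 0) of the actual surfaces.
#'
#' @name contact
NULL

# cyclic global arc parameter over the boundary of a section. By default
# the contact surface uses a C2 periodic cubic spline through a dense
# resampling of the outline: polygonal sections would otherwise expose
# corner ridges on which closest-point projections are non-smooth (the gap
# gradient formula assumes an interior optimum), which destroys the
# consistency of the contact energy. In bilateral (tie) mode the smoothing
# is force-free at the reference because only gap *changes* are penalized.
.section_curve <- function(spec, smooth = TRUE, n_pts = 48L) {
  if (!smooth) {
    bs <- parametrize_boundary(spec)
    lens <- vapply(bs$splines, function(s) s$t[length(s$t)], numeric(1))
    return(list(splines = bs$splines, lens = lens,
                offsets = c(0, cumsum(lens)), total = sum(lens)))
  }
  per_seg <- max(4L, ceiling(n_pts / length(spec$segments)))
  P <- .boundary_polyline(spec, per_seg)
  P <- rbind(P, P[1L, ])                     # close the loop
  t <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  fx <- stats::splinefun(t, P[, 1], method = "periodic")
  fy <- stats::splinefun(t, P[, 2], method = "periodic")
  total <- t[length(t)]
  seg <- list(t = c(0, total), dt = total,
              eval = function(tt, deriv = 0L) cbind(fx(tt, deriv = deriv),
                                                    fy(tt, deriv = deriv)),
              degree = 3L, m = 2L)
  list(splines = list(seg), lens = total, offsets = c(0, total), total = total)
}

# evaluate the section boundary curve at global arc parameters u (vector):
# returns mm coordinates and derivatives with respect to u
.curve_eval <- function(curve, u) {
  u <- u %% curve$total
  seg <- pmin(findInterval(u, curve$offsets, rightmost.closed = TRUE),
              length(curve$splines))
  out <- matrix(0, length(u), 6L)
  for (s in unique(seg)) {
    i <- which(seg == s)
    tt <- u[i] - curve$offsets[s]
    out[i, 1:2] <- curve$splines[[s]]$eval(tt, 0L)
    out[i, 3:4] <- curve$splines[[s]]$eval(tt, 1L)
    out[i, 5:6] <- curve$splines[[s]]$eval(tt, 2L)
  }
  out
}

.beam_Q <- function(model, bi, q) {
  b <- model$beams[[bi]]
  off <- model$offsets[bi]
  lapply(b$elements, function(elt) matrix(q[off + elt$dofs], nrow = 3L))
}

# evaluate B's lateral surface at (s, u) pairs; s in [0, n_el] axial,
# u cyclic arc parameter. Returns positions, tangents, normals and the
# shape-function matrix needed for force distribution.
.surf_eval <- function(beam, Qlist, s, u, curve, derivs = TRUE) {
  n <- length(s)
  # the axial parameter may overshoot the physical ends by half an element:
  # the element polynomials extend smoothly, which keeps the gap function
  # differentiable when a sample slides past the partner beam's end
  s <- pmin(pmax(s, -0.5), beam$n_el + 0.5)
  e <- pmin(pmax(floor(s), 0), beam$n_el - 1L) + 1L
  xi <- 2 * (s - (e - 1L)) - 1
  cv <- .curve_eval(curve, u)
  ly <- beam$geom$ly; lz <- beam$geom$lz
  eta <- 2 * cv[, 1] / ly; zeta <- 2 * cv[, 2] / lz
  pos <- matrix(0, n, 3L)
  drds <- matrix(0, n, 3L); drdu <- matrix(0, n, 3L)
  Nmat <- matrix(0, 18L, n)
  for (ee in unique(e)) {
    i <- which(e == ee)
    Q <- Qlist[[ee]]
    N <- shape_functions(xi[i], eta[i], zeta[i], beam$geom)
    if (!is.matrix(N)) N <- matrix(N, ncol = 1L)
    Nmat[, i] <- N
    pos[i, ] <- t(Q %*% N)
    if (derivs) {
      dN <- shape_derivatives(xi[i], eta[i], zeta[i], beam$geom)
      if (length(dim(dN)) == 2L) dim(dN) <- c(18L, 3L, 1L)
      ni <- length(i)
      G <- Q %*% matrix(dN, nrow = 18L)   # 3 x (3 ni), blocks per sample
      gx <- matrix(G, nrow = 9L)          # 9 x ni, column-major per sample
      drds[i, ] <- t(gx[1:3, , drop = FALSE]) * 2          # dxi/ds = 2
      drdu[i, ] <- t(gx[4:6, , drop = FALSE]) * (2 / ly) * cv[i, 3] +
        t(gx[7:9, , drop = FALSE]) * (2 / lz) * cv[i, 4]
    }
  }
  nrm <- NULL
  if (derivs) {
    nrm <- cbind(drdu[, 2] * drds[, 3] - drdu[, 3] * drds[, 2],
                 drdu[, 3] * drds[, 1] - drdu[, 1] * drds[, 3],
                 drdu[, 1] * drds[, 2] - drdu[, 2] * drds[, 1])
    nrm <- nrm / sqrt(rowSums(nrm^2))
  }
  list(pos = pos, drds = drds, drdu = drdu, normal = nrm, N = Nmat,
       elem = e, xi = xi, eta = eta, zeta = zeta)
}

# damped, clamped Gauss-Newton closest-point projection for a batch of
# target points x (n x 3) onto the lateral surface of `beam`
.project_batch <- function(beam, Qlist, curve, x, s, u, iters = 25L) {
  sv <- .surf_eval(beam, Qlist, s, u, curve)
  dist2 <- rowSums((x - sv$pos)^2)
  for (it in seq_len(iters)) {
    d <- x - sv$pos
    g1 <- rowSums(d * sv$drds); g2 <- rowSums(d * sv$drdu)
    a11 <- rowSums(sv$drds^2); a12 <- rowSums(sv$drds * sv$drdu)
    a22 <- rowSums(sv$drdu^2)
    det <- pmax(a11 * a22 - a12^2, 1e-12)
    ds <- (a22 * g1 - a12 * g2) / det
    du <- (a11 * g2 - a12 * g1) / det
    # cap the arc step, then backtrack per sample until the distance drops
    lim <- 0.25 * curve$total
    alpha <- pmin(1, lim / pmax(abs(du), 1e-30))
    for (bt in 1:6) {
      s_try <- pmin(pmax(s + alpha * ds, -0.5), beam$n_el + 0.5)
      u_try <- (u + alpha * du) %% curve$total
      sv_try <- .surf_eval(beam, Qlist, s_try, u_try, curve)
      d2_try <- rowSums((x - sv_try$pos)^2)
      worse <- d2_try > dist2 * (1 + 1e-12)
      if (!any(worse)) break
      alpha[worse] <- alpha[worse] / 2
    }
    keep <- d2_try <= dist2 * (1 + 1e-12)
    s[keep] <- s_try[keep]; u[keep] <- u_try[keep]
    dist2[keep] <- d2_try[keep]
    sv <- .surf_eval(beam, Qlist, s, u, curve)
    if (max(abs(ds * alpha), abs(du * alpha)) < 1e-12) break
  }
  d <- x - sv$pos
  opt <- sqrt(rowSums(cbind(rowSums(d * sv$drds) / sqrt(rowSums(sv$drds^2)),
                            rowSums(d * sv$drdu) / sqrt(rowSums(sv$drdu^2)))^2))
  list(s = s, u = u, surf = sv, dist = sqrt(rowSums(d^2)), opt = opt)
}

# coarse-grid initialization: for each target pick the best (s, u) cell
.project_init <- function(beam, Qlist, curve, x, n_s = NULL, n_u = 36L) {
  if (is.null(n_s)) n_s <- 2L * beam$n_el + 1L
  sg <- seq(0, beam$n_el, length.out = n_s)
  ug <- seq(0, curve$total, length.out = n_u + 1L)[seq_len(n_u)]
  grid <- expand.grid(s = sg, u = ug)
  sv <- .surf_eval(beam, Qlist, grid$s, grid$u, curve, derivs = FALSE)
  n <- nrow(x)
  best_s <- numeric(n); best_u <- numeric(n)
  d2 <- outer(x[, 1], sv$pos[, 1], "-")^2 + outer(x[, 2], sv$pos[, 2], "-")^2 +
    outer(x[, 3], sv$pos[, 3], "-")^2
  j <- apply(d2, 1L, which.min)      # ties: first index = smaller axial s
  list(s = grid$s[j], u = grid$u[j])
}

#' Closest-point projection onto a beam's lateral surface
#'
#' @param beam an `ancf_beam`
#' @param x points to project, n x 3 matrix (or a single 3-vector), mm
#' @param q beam coordinate vector (defaults to the reference)
#' @param iters Gauss-Newton iterations after grid initialization
#' @return list with `s` (axial parameter in `[0, n_el]`), `u` (cyclic
#'   boundary arc parameter), `point` (n x 3 surface points), `distance`,
#'   `normal` (outward), `opt` (first-order optimality residual)
#' @export
closest_point_projection <- function(beam, x, q = beam$qbar, iters = 30L,
                                     smooth = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  curve <- .section_curve(beam$section, smooth = smooth)
  Qlist <- lapply(beam$elements, function(elt) matrix(q[elt$dofs], nrow = 3L))
  ini <- .project_init(beam, Qlist, curve, x)
  pr <- .project_batch(beam, Qlist, curve, x, ini$s, ini$u, iters)
  list(s = pr$s, u = pr$u, point = pr$surf$pos, distance = pr$dist,
       normal = pr$surf$normal, opt = pr$opt)
}

#' Create a contact pair between two beams of a model
#'
#' Samples the facing sector of beam A's surface (axial Gauss stations times
#' boundary-arc points within `facing_dist` of B's reference outline) and
#' caches reference gaps and projection warm starts. The pair holds mutable
#' state (warm starts) in an environment.
#'
#' @param model an [fe_model()]
#' @param a,b beam indices or names (A carries the samples)
#' @param pn contact penalty (N/mm^3)
#' @param mode `"bilateral"` (sliding tie on the gap change, default) or
#'   `"unilateral"` (penalize penetration only)
#' @param n_arc arc samples per contiguous facing strip
#' @param facing_dist reference distance (mm) within which boundary points
#'   count as facing
#' @param n_axial axial Gauss stations per element of A
#' @return object of class `contact_pair` (an environment)
#' @export
contact_pair <- function(model, a, b, pn, mode = c("bilateral", "unilateral"),
                         n_arc = 6L, facing_dist = 0.5, n_axial = 4L,
                         smooth_surface = TRUE) {
  mode <- match.arg(mode)
  ai <- if (is.character(a)) match(a, names(model$beams)) else as.integer(a)
  bi <- if (is.character(b)) match(b, names(model$beams)) else as.integer(b)
  stopifnot(!is.na(ai), !is.na(bi), ai != bi)
  if (!is.numeric(pn) || pn <= 0) stop("contact_pair: 'pn' must be positive")
  A <- model$beams[[ai]]; B <- model$beams[[bi]]
  # facing strip on A's section boundary, assessed in the global reference
  # cross-section plane at x = 0 (sections rotate together along x, so the
  # facing relation is axially invariant); sample coordinates stay local
  polyA <- .boundary_polyline(A$section, 16L)
  polyB <- sweep(.boundary_polyline(B$section, 16L), 2L, B$offset, "+")
  polyA_g <- sweep(polyA, 2L, A$offset, "+")
  nA <- nrow(polyA)
  nxt <- c(2:nA, 1L); prv <- c(nA, 1:(nA - 1L))
  spacing <- (sqrt(rowSums((polyA - polyA[prv, ])^2)) +
                sqrt(rowSums((polyA[nxt, ] - polyA)^2))) / 2
  dB <- sqrt(apply(outer(polyA_g[, 1], polyB[, 1], "-")^2 +
                     outer(polyA_g[, 2], polyB[, 2], "-")^2, 1L, min))
  mask <- dB <= facing_dist
  if (!any(mask))
    stop(sprintf("contact_pair: no boundary points of '%s' within %.3g mm of '%s'",
                 A$name, facing_dist, B$name))
  # contiguous cyclic runs of facing points, thinned to ~n_arc each
  runs <- split(which(mask), cumsum(c(1, diff(which(mask)) != 1)))
  if (length(runs) > 1L && mask[1L] && mask[nA]) {   # merge wrap-around run
    runs[[1L]] <- c(runs[[length(runs)]], runs[[1L]])
    runs[[length(runs)]] <- NULL
  }
  arc_pts <- NULL; arc_w <- NULL
  for (r in runs) {
    len <- sum(spacing[r])
    pick <- r[unique(round(seq(1, length(r), length.out = min(n_arc, length(r)))))]
    arc_pts <- rbind(arc_pts, polyA[pick, , drop = FALSE])
    arc_w <- c(arc_w, rep(len / length(pick), length(pick)))
  }
  ga <- gauss_legendre(n_axial)
  n_sec <- nrow(arc_pts)
  cp <- new.env(parent = emptyenv())
  cp$a <- ai; cp$b <- bi; cp$pn <- pn; cp$mode <- mode
  cp$curveB <- .section_curve(B$section, smooth = smooth_surface)
  # per-sample data across all A elements
  cp$elemA <- rep(seq_len(A$n_el), each = n_axial * n_sec)
  xi <- rep(rep(ga$nodes, each = n_sec), times = A$n_el)
  eta <- rep(2 * arc_pts[, 1] / A$geom$ly, times = n_axial * A$n_el)
  zeta <- rep(2 * arc_pts[, 2] / A$geom$lz, times = n_axial * A$n_el)
  cp$NA_mat <- shape_functions(xi, eta, zeta, A$geom)    # 18 x n samples
  cp$w <- rep(rep(ga$weights, each = n_sec), times = A$n_el) *
    (A$geom$lx / 2) * rep(arc_w, times = n_axial * A$n_el)
  cp$n_samp <- length(cp$w)
  class(cp) <- "contact_pair"
  # reference projection: warm starts and reference gaps
  QlistB <- .beam_Q(model, bi, model$q0)
  xA <- t(.posA(model, cp, model$q0))
  ini <- .project_init(B, QlistB, cp$curveB, xA)
  pr <- .project_batch(B, QlistB, cp$curveB, xA, ini$s, ini$u, 30L)
  # samples whose closest point sits on a boundary kink (corner of B's
  # outline) have no well-defined surface normal: the projection cannot
  # satisfy first-order optimality there and the gap would be discontinuous.
  # Such samples are flagged inactive and removed from the quadrature set.
  active <- pr$opt < 1e-4
  if (!any(active))
    stop(sprintf("contact_pair: no smooth-surface contact samples between '%s' and '%s'",
                 A$name, B$name))
  if (any(!active))
    message(sprintf("contact_pair %s-%s: %d of %d samples inactive (projection on a boundary kink)",
                    A$name, B$name, sum(!active), length(active)))
  cp$elemA <- cp$elemA[active]
  cp$NA_mat <- cp$NA_mat[, active, drop = FALSE]
  cp$w <- cp$w[active]
  cp$n_samp <- sum(active)
  xA <- xA[active, , drop = FALSE]
  cp$s <- pr$s[active]; cp$u <- pr$u[active]
  nrm <- pr$surf$normal[active, , drop = FALSE]
  cp$g0 <- rowSums((xA - pr$surf$pos[active, , drop = FALSE]) * nrm)
  if (mode == "bilateral" && any(cp$g0 < 0))
    stop(sprintf("contact_pair: beams '%s' and '%s' penetrate in the reference configuration",
                 A$name, B$name))
  cp
}

# positions of the A-side samples under the current state (3 x n)
.posA <- function(model, cp, q) {
  A <- model$beams[[cp$a]]
  out <- matrix(0, 3L, cp$n_samp)
  for (e in unique(cp$elemA)) {
    i <- which(cp$elemA == e)
    Q <- matrix(q[model$offsets[cp$a] + A$elements[[e]]$dofs], nrow = 3L)
    out[, i] <- Q %*% cp$NA_mat[, i, drop = FALSE]
  }
  out
}

# snapshot / restore projection warm starts (used by line searches and
# finite differencing so that rejected trial states cannot strand the
# projections in a different local basin)
.contact_snapshot <- function(model) {
  lapply(model$contacts, function(cp) list(s = cp$s, u = cp$u))
}

.contact_restore <- function(model, snap) {
  for (i in seq_along(model$contacts)) {
    model$contacts[[i]]$s <- snap[[i]]$s
    model$contacts[[i]]$u <- snap[[i]]$u
  }
  invisible(NULL)
}

# update projections and return per-sample kinematics; mutates warm starts
.contact_state <- function(cp, model, q, proj_iters = 12L) {
  B <- model$beams[[cp$b]]
  QlistB <- .beam_Q(model, cp$b, q)
  xA <- t(.posA(model, cp, q))
  pr <- .project_batch(B, QlistB, cp$curveB, xA, cp$s, cp$u, proj_iters)
  # re-initialize samples stranded away from first-order optimality
  # (e.g. warm starts left on the wrong face by a rejected trial state)
  bad <- which(pr$opt > 1e-6 & pmin(pr$s + 0.5, B$n_el + 0.5 - pr$s) > 1e-9)
  if (length(bad)) {
    ini <- .project_init(B, QlistB, cp$curveB, xA[bad, , drop = FALSE])
    pr2 <- .project_batch(B, QlistB, cp$curveB, xA[bad, , drop = FALSE],
                          ini$s, ini$u, 30L)
    better <- pr2$dist <= pr$dist[bad]
    if (any(better)) {
      bb <- bad[better]
      pr$s[bb] <- pr2$s[better]; pr$u[bb] <- pr2$u[better]
      full <- .project_batch(B, QlistB, cp$curveB, xA, pr$s, pr$u, proj_iters)
      pr <- full
    }
  }
  cp$s <- pr$s; cp$u <- pr$u
  g <- rowSums((xA - pr$surf$pos) * pr$surf$normal)
  ghat <- if (cp$mode == "bilateral") g - cp$g0 else pmin(g, 0)
  list(xA = xA, g = g, ghat = ghat, surf = pr$surf, opt = pr$opt)
}

#' Per-sample contact diagnostics
#'
#' @param cp a [contact_pair()]
#' @param model the owning [fe_model()]
#' @param q global coordinate vector
#' @return data frame with sample coordinates, gap `g`, gap change relative
#'   to the reference, normal force density and projection optimality
#' @export
contact_gaps <- function(cp, model, q = model$q0) {
  st <- .contact_state(cp, model, q, proj_iters = 30L)
  data.frame(element_a = cp$elemA, s_b = cp$s, u_b = cp$u,
             g = st$g, g0 = cp$g0, ghat = st$ghat,
             force_density = -cp$pn * st$ghat, weight = cp$w,
             optimality = st$opt)
}

#' Contact penalty energy of a pair
#'
#' @inheritParams contact_gaps
#' @return scalar: 0.5 pn sum w ghat^2
#' @export
contact_energy <- function(cp, model, q) {
  st <- .contact_state(cp, model, q)
  0.5 * cp$pn * sum(cp$w * st$ghat^2)
}

#' Contact residual (gradient of the penalty energy)
#'
#' Contributions are equal and opposite on the two beams by construction.
#'
#' @inheritParams contact_gaps
#' @param proj_iters warm-started projection update iterations
#' @return full-length global force vector
#' @export
contact_residual <- function(cp, model, q, proj_iters = 12L) {
  st <- .contact_state(cp, model, q, proj_iters)
  R <- numeric(model$ndof)
  coef <- cp$pn * cp$w * st$ghat
  if (all(coef == 0)) return(R)
  A <- model$beams[[cp$a]]; B <- model$beams[[cp$b]]
  nA <- st$surf$normal  # outward normal of B at the projections
  for (e in unique(cp$elemA)) {
    i <- which(cp$elemA == e)
    idx <- model$offsets[cp$a] + A$elements[[e]]$dofs
    fa <- (t(nA[i, , drop = FALSE]) * rep(coef[i], each = 3L)) %*%
      t(cp$NA_mat[, i, drop = FALSE])
    R[idx] <- R[idx] + as.vector(fa)
  }
  for (e in unique(st$surf$elem)) {
    i <- which(st$surf$elem == e)
    idx <- model$offsets[cp$b] + B$elements[[e]]$dofs
    fb <- (t(nA[i, , drop = FALSE]) * rep(coef[i], each = 3L)) %*%
      t(st$surf$N[, i, drop = FALSE])
    R[idx] <- R[idx] - as.vector(fb)
  }
  R
}

#' Contact tangent by central finite differences of the contact residual
#'
#' Projections are re-solved (warm-started) inside every perturbed residual
#' evaluation, so the projection-parameter sensitivity is included through
#' the differencing.
#'
#' @inheritParams contact_gaps
#' @param h base finite-difference step
#' @return full `ndof` x `ndof` matrix contribution
#' @export
contact_tangent <- function(cp, model, q, h = 1e-6, central = FALSE) {
  K <- matrix(0, model$ndof, model$ndof)
  cols <- integer(0)
  for (bi in unique(c(cp$a, cp$b))) {
    b <- model$beams[[bi]]
    cols <- c(cols, model$offsets[bi] + seq_len(b$ndof))
  }
  s0 <- cp$s; u0 <- cp$u
  R0 <- if (central) NULL else contact_residual(cp, model, q, proj_iters = 2L)
  for (j in cols) {
    hj <- h * max(1, abs(q[j]))
    cp$s <- s0; cp$u <- u0
    qp <- q; qp[j] <- q[j] + hj
    Rp <- contact_residual(cp, model, qp, proj_iters = 2L)
    if (central) {
      cp$s <- s0; cp$u <- u0
      qm <- q; qm[j] <- q[j] - hj
      Rm <- contact_residual(cp, model, qm, proj_iters = 2L)
      K[cols, j] <- (Rp - Rm)[cols] / (2 * hj)
    } else {
      K[cols, j] <- (Rp - R0)[cols] / hj
    }
  }
  cp$s <- s0; cp$u <- u0
  (K + t(K)) / 2
}

# analytic contact stiffness with projections and normals held fixed:
# K = pn sum w (NA^T n - NB^T n)(NA^T n - NB^T n)^T over active samples.
# This is the standard penalty-contact tangent (curvature terms omitted);
# the solver uses it, while contact_tangent() provides the full FD check.
.contact_tangent_fixed <- function(cp, model, q) {
  st <- .contact_state(cp, model, q, proj_iters = 12L)
  K <- matrix(0, model$ndof, model$ndof)
  active <- if (cp$mode == "bilateral") rep(TRUE, cp$n_samp) else st$g < 0
  if (!any(active)) return(K)
  A <- model$beams[[cp$a]]; B <- model$beams[[cp$b]]
  nA <- st$surf$normal
  for (i in which(active)) {
    idx <- c(model$offsets[cp$a] + A$elements[[cp$elemA[i]]]$dofs,
             model$offsets[cp$b] + B$elements[[st$surf$elem[i]]]$dofs)
    v <- c(as.vector(outer(nA[i, ], cp$NA_mat[, i])),
           -as.vector(outer(nA[i, ], st$surf$N[, i])))
    K[idx, idx] <- K[idx, idx] + (cp$pn * cp$w[i]) * tcrossprod(v)
  }
  K
}

#' Register a contact pair on a model
#'
#' @inheritParams contact_pair
#' @return the model with the pair appended
#' @export
add_contact <- function(model, a, b, pn, mode = c("bilateral", "unilateral"),
                        n_arc = 6L, facing_dist = 0.5, n_axial = 4L,
                        smooth_surface = TRUE) {
  pair <- contact_pair(model, a = a, b = b, pn = pn, mode = mode,
                       n_arc = n_arc, facing_dist = facing_dist,
                       n_axial = n_axial, smooth_surface = smooth_surface)
  model$contacts <- c(model$contacts, list(pair))
  model
}
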