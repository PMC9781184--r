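#' Spline-bounded cross-section domains and Gauss-Green cubature
#'
#' A cross-section domain is described by a closed, counterclockwise piecewise
#' boundary. Each piece ("segment") carries its own control points and spline
#' degree; the segment curves are interpolating splines through the control
#' points under the cumulative chordal parametrization. Area integrals over
#' the enclosed domain are evaluated with a Gauss-Green cubature rule of
#' prescribed polynomial exactness 2n - 1: Green's theorem converts the area
#' integral into a boundary integral whose inner (abscissa) and outer
#' (boundary-parameter) integrals are both handled by Gauss-Legendre rules.
#'
#' @name cross_section_cubature
NULL

.shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Define a piecewise spline boundary
#'
#' @param segments list of segments; each segment is a list with `points`
#'   (an m x 2 matrix of control points, first and last being the segment's
#'   end vertices) and `degree` (spline degree p, with p <= m - 1).
#'   Consecutive segments must share their joint vertex and the last segment
#'   must close the boundary back to the first vertex.
#' @param check_orientation reject clockwise boundaries (default TRUE);
#'   weights of the cubature rule change sign with orientation, so a
#'   counterclockwise traversal is required rather than silently flipped.
#' @return object of class `boundary_spec`
#' @export
boundary_spec <- function(segments, check_orientation = TRUE) {
  if (!is.list(segments) || length(segments) < 1L)
    stop("boundary_spec: 'segments' must be a non-empty list")
  segments <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    P <- as.matrix(s$points)
    if (ncol(P) != 2L || nrow(P) < 2L)
      stop(sprintf("boundary_spec: segment %d needs an m x 2 matrix with m >= 2", i))
    if (!all(is.finite(P)))
      stop(sprintf("boundary_spec: segment %d has non-finite control points", i))
    p <- as.integer(if (is.null(s$degree)) 1L else s$degree)
    if (p < 1L || p > nrow(P) - 1L)
      stop(sprintf("boundary_spec: segment %d degree %d violates 1 <= p <= m - 1 (m = %d)",
                   i, p, nrow(P)))
    chord <- sqrt(rowSums((P[-1L, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
    if (any(chord == 0)) {
      j <- which(chord == 0)[1L]
      stop(sprintf("boundary_spec: segment %d has coincident control points %d and %d (zero chord)",
                   i, j, j + 1L))
    }
    list(points = unname(P), degree = p)
  })
  nseg <- length(segments)
  for (i in seq_len(nseg)) {
    Pi <- segments[[i]]$points
    Pn <- segments[[if (i == nseg) 1L else i + 1L]]$points
    if (max(abs(Pi[nrow(Pi), ] - Pn[1L, ])) > 1e-9)
      stop(sprintf("boundary_spec: boundary not closed between segment %d and %d", i,
                   if (i == nseg) 1L else i + 1L))
  }
  allP <- do.call(rbind, lapply(segments, function(s) s$points[-nrow(s$points), , drop = FALSE]))
  if (check_orientation && .shoelace(allP) <= 0)
    stop("boundary_spec: boundary is clockwise (or degenerate); supply a counterclockwise traversal")
  structure(list(segments = segments,
                 vertices = do.call(rbind, lapply(segments, function(s) s$points[1L, ]))),
            class = "boundary_spec")
}

#' Polygonal boundary from a vertex list
#'
#' @param vertices n x 2 matrix of polygon vertices, counterclockwise, not
#'   repeating the first vertex at the end.
#' @return `boundary_spec` with one linear segment per edge
#' @export
polygon_boundary <- function(vertices) {
  V <- as.matrix(vertices)
  n <- nrow(V)
  segs <- lapply(seq_len(n), function(i) {
    list(points = rbind(V[i, ], V[if (i == n) 1L else i + 1L, ]), degree = 1L)
  })
  boundary_spec(segs)
}

#' Circular boundary sampled on n_pts points, cubic spline segments
#'
#' The circle is split into four quadrant segments, each interpolated by a
#' natural cubic spline through its sample points; the radial interpolation
#' error shrinks with the sample count.
#'
#' @param radius circle radius
#' @param n_pts total number of boundary sample points (multiple of 4, >= 16)
#' @param centre circle centre (length-2)
#' @return `boundary_spec`
#' @export
circle_boundary <- function(radius, n_pts = 32L, centre = c(0, 0)) {
  n_pts <- as.integer(n_pts)
  if (n_pts < 16L || n_pts %% 4L != 0L)
    stop("circle_boundary: n_pts must be a multiple of 4 and >= 16")
  per <- n_pts %/% 4L
  segs <- lapply(0:3, function(qd) {
    th <- seq(qd * pi / 2, (qd + 1) * pi / 2, length.out = per + 1L)
    list(points = cbind(centre[1] + radius * cos(th), centre[2] + radius * sin(th)),
         degree = 3L)
  })
  boundary_spec(segs)
}

.segment_spline <- function(P, degree) {
  m <- nrow(P)
  chord <- sqrt(rowSums((P[-1L, , drop = FALSE] - P[-m, , drop = FALSE])^2))
  t <- c(0, cumsum(chord))
  ev <- if (degree == 1L) {
    force(P); force(t)
    function(tt, deriv = 0L) {
      j <- pmin(pmax(findInterval(tt, t, rightmost.closed = TRUE), 1L), m - 1L)
      dir <- (P[j + 1L, , drop = FALSE] - P[j, , drop = FALSE]) / chord[j]
      if (deriv == 0L) P[j, , drop = FALSE] + dir * (tt - t[j])
      else if (deriv == 1L) dir
      else matrix(0, length(tt), 2L)
    }
  } else if (degree == 2L) {
    if (m != 3L)
      stop("parametrize_boundary: degree-2 segments are supported for exactly 3 control points")
    # exact Lagrange quadratic through the three points
    cf <- apply(P, 2L, function(y) solve(cbind(1, t, t^2), y))
    function(tt, deriv = 0L) {
      if (deriv == 0L) cbind(cf[1, 1] + cf[2, 1] * tt + cf[3, 1] * tt^2,
                             cf[1, 2] + cf[2, 2] * tt + cf[3, 2] * tt^2)
      else if (deriv == 1L) cbind(cf[2, 1] + 2 * cf[3, 1] * tt,
                                  cf[2, 2] + 2 * cf[3, 2] * tt)
      else cbind(rep(2 * cf[3, 1], length(tt)), rep(2 * cf[3, 2], length(tt)))
    }
  } else if (degree == 3L) {
    fx <- stats::splinefun(t, P[, 1], method = "natural")
    fy <- stats::splinefun(t, P[, 2], method = "natural")
    function(tt, deriv = 0L) cbind(fx(tt, deriv = deriv), fy(tt, deriv = deriv))
  } else {
    stop(sprintf("parametrize_boundary: spline degree %d not supported (use 1, 2 or 3)", degree))
  }
  list(t = t, dt = chord, eval = ev, degree = degree, m = m)
}

#' Parametrize a boundary by cumulative chordal interpolating splines
#'
#' Each segment's parameter values are the cumulative sums of the chord
#' lengths between consecutive control points, starting at 0; the segment
#' curve interpolates all its control points.
#'
#' @param spec a [boundary_spec()]
#' @return object of class `boundary_splines`
#' @export
parametrize_boundary <- function(spec) {
  stopifnot(inherits(spec, "boundary_spec"))
  structure(list(splines = lapply(spec$segments,
                                  function(s) .segment_spline(s$points, s$degree)),
                 spec = spec),
            class = "boundary_splines")
}

#' Build a Gauss-Green cubature rule over a spline-bounded domain
#'
#' Constructs nodes and weights with polynomial exactness degree 2n - 1 over
#' the domain enclosed by the boundary. For every boundary quadrature point
#' the inner integral from the reference line `Xi` to the boundary abscissa
#' is resolved by an n-point Gauss-Legendre rule; the boundary-parameter
#' integral uses n_i = n p_i + ceiling(p_i / 2) Gauss points per control-point
#' subinterval, where p_i is the segment's spline degree. The choice of `Xi`
#' does not influence the integral values (it shifts weight between nodes).
#'
#' @param splines a [parametrize_boundary()] result (or a `boundary_spec`,
#'   which is parametrized on the fly)
#' @param n exactness parameter (integer >= 1; rule is exact for total degree
#'   2n - 1 on polygonal boundaries)
#' @param Xi abscissa of the vertical reference line; default: mid-abscissa of
#'   the boundary's bounding box
#' @return object of class `cubature_rule` with `nodes` (matrix, columns
#'   eta/zeta), `weights` (signed), `area`, `n`, `Xi`
#' @export
build_cubature <- function(splines, n, Xi = NULL) {
  if (inherits(splines, "boundary_spec")) splines <- parametrize_boundary(splines)
  stopifnot(inherits(splines, "boundary_splines"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("build_cubature: exactness parameter 'n' must be >= 1")
  allP <- do.call(rbind, lapply(splines$spec$segments, function(s) s$points))
  if (is.null(Xi)) Xi <- (min(allP[, 1]) + max(allP[, 1])) / 2
  if (!is.finite(Xi)) stop("build_cubature: 'Xi' must be finite")
  gh <- gauss_legendre(n)                      # inner (abscissa) rule
  nodes <- NULL; weights <- NULL
  for (seg in splines$splines) {
    p <- seg$degree
    ni <- n * p + ceiling(p / 2)               # boundary-parameter rule size
    gk <- gauss_legendre(ni)
    for (j in seq_len(seg$m - 1L)) {
      dt <- seg$dt[j]
      q <- dt / 2 * gk$nodes + (seg$t[j + 1L] + seg$t[j]) / 2
      S <- seg$eval(q, 0L)
      dS <- seg$eval(q, 1L)
      if (!all(is.finite(dS)))
        stop("build_cubature: non-finite spline derivative on the boundary")
      # outer product over inner Gauss index h
      eta <- outer((S[, 1] - Xi) / 2, gh$nodes) + (S[, 1] + Xi) / 2
      zeta <- matrix(S[, 2], nrow = ni, ncol = n)
      w <- outer(dt / 4 * gk$weights * (S[, 1] - Xi) * dS[, 2], gh$weights)
      nodes <- rbind(nodes, cbind(as.vector(eta), as.vector(zeta)))
      weights <- c(weights, as.vector(w))
    }
  }
  area <- sum(weights)
  if (!is.finite(area) || area <= 0)
    stop("build_cubature: non-positive area; check boundary orientation")
  structure(list(nodes = nodes, weights = weights, area = area, n = n, Xi = Xi),
            class = "cubature_rule")
}

#' Integrate a scalar field with a cubature rule
#'
#' @param rule a [build_cubature()] rule
#' @param f function of two vectors (eta, zeta) returning a vector of values
#' @return the weighted sum \eqn{\sum_\lambda f(\eta_\lambda, \zeta_\lambda) w_\lambda}
#' @export
cubature_integrate <- function(rule, f) {
  stopifnot(inherits(rule, "cubature_rule"))
  v <- f(rule$nodes[, 1], rule$nodes[, 2])
  if (length(v) == 1L) v <- rep(v, length(rule$weights))
  sum(v * rule$weights)
}

#' Area, centroid and second moments of a cross-section
#'
#' Second moments are reported about the centroid. Requires a rule with
#' exactness parameter n >= 2 for exact moments on polygonal domains.
#'
#' @param rule a [build_cubature()] rule
#' @return list with `area`, `centroid` (length-2), `Iyy` (integral of
#'   (zeta - zc)^2), `Izz` (integral of (eta - ec)^2) and `Iyz`
#' @export
section_properties <- function(rule) {
  stopifnot(inherits(rule, "cubature_rule"))
  A <- sum(rule$weights)
  if (!is.finite(A) || A <= 0)
    stop("section_properties: non-positive area; boundary orientation error")
  e <- rule$nodes[, 1]; z <- rule$nodes[, 2]; w <- rule$weights
  ec <- sum(e * w) / A; zc <- sum(z * w) / A
  list(area = A, centroid = c(ec, zc),
       Iyy = sum((z - zc)^2 * w), Izz = sum((e - ec)^2 * w),
       Iyz = sum((e - ec) * (z - zc) * w))
}

#' Read / write the plain-text boundary format
#'
#' One "eta zeta" control-point pair per line; blank lines separate segments;
#' an optional `degree: p` line inside a segment sets its spline degree
#' (default 1). Units are millimetres.
#'
#' @param path file path
#' @return `read_boundary`: a [boundary_spec()]
#' @export
read_boundary <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!grepl("^#", lines)]
  brk <- c(0L, which(lines == ""), length(lines) + 1L)
  segs <- list()
  for (i in seq_len(length(brk) - 1L)) {
    if (brk[i + 1L] - 1L < brk[i] + 1L) next
    chunk <- lines[seq(brk[i] + 1L, brk[i + 1L] - 1L)]
    chunk <- chunk[chunk != ""]
    if (!length(chunk)) next
    deg <- 1L
    dl <- grepl("^degree:", chunk)
    if (any(dl)) { deg <- as.integer(sub("^degree:\\s*", "", chunk[dl][1L])); chunk <- chunk[!dl] }
    P <- do.call(rbind, lapply(strsplit(chunk, "\\s+"), as.numeric))
    segs[[length(segs) + 1L]] <- list(points = P, degree = deg)
  }
  boundary_spec(segs)
}

#' @rdname read_boundary
#' @param spec a [boundary_spec()] to write
#' @export
write_boundary <- function(spec, path) {
  stopifnot(inherits(spec, "boundary_spec"))
  con <- file(path, "w"); on.exit(close(con))
  for (s in spec$segments) {
    writeLines(sprintf("degree: %d", s$degree), con)
    writeLines(apply(s$points, 1L, function(r) sprintf("%.12g %.12g", r[1], r[2])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Export cubature nodes and weights as CSV
#'
#' @param rule a [build_cubature()] rule
#' @param path output CSV path (columns eta, zeta, w)
#' @export
write_cubature_csv <- function(rule, path) {
  stopifnot(inherits(rule, "cubature_rule"))
  utils::write.csv(data.frame(eta = rule$nodes[, 1], zeta = rule$nodes[, 2],
                              w = rule$weights),
                   path, row.names = FALSE)
  invisible(path)
}
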