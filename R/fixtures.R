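#' Synthetic cross-section fixtures
#'
#' Parametric stand-ins for subtendon cross-sections. Published tendon
#' geometry gives reliable cross-section areas but no vertex-level outlines,
#' so the package ships shape families (disc, ellipse, kidney polygon,
#' annular-sector polygon) that are uniformly scaled to an exact target area.
#' Shape realism is secondary to area fidelity: for a straight prismatic
#' homogeneous bar the axial response depends on the area, not the outline.
#' Users with real outlines supply them as vertex lists instead.
#'
#' @name fixtures
NULL

.with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.scale_to_area <- function(spec, target_area, centre = c(0, 0)) {
  # uniform scaling about the current centroid, then translation to 'centre';
  # polygons are matched through the shoelace area (exact), curved boundaries
  # through the cubature area of the spline-bounded domain
  all_linear <- all(vapply(spec$segments, function(s) s$degree == 1L, logical(1)))
  if (all_linear) {
    V <- do.call(rbind, lapply(spec$segments,
                               function(s) s$points[-nrow(s$points), , drop = FALSE]))
    A <- .shoelace(V)
    cx <- sum((V[, 1] + c(V[-1, 1], V[1, 1])) *
                (V[, 1] * c(V[-1, 2], V[1, 2]) - c(V[-1, 1], V[1, 1]) * V[, 2])) / (6 * A)
    cy <- sum((V[, 2] + c(V[-1, 2], V[1, 2])) *
                (V[, 1] * c(V[-1, 2], V[1, 2]) - c(V[-1, 1], V[1, 1]) * V[, 2])) / (6 * A)
    ctr <- c(cx, cy)
  } else {
    pr <- section_properties(build_cubature(spec, 3))
    A <- pr$area; ctr <- pr$centroid
  }
  s <- sqrt(target_area / A)
  segs <- lapply(spec$segments, function(sg) {
    sg$points <- sweep(sweep(sg$points, 2L, ctr) * s, 2L, centre, "+")
    sg
  })
  boundary_spec(segs)
}

#' Generate a synthetic cross-section boundary
#'
#' @param shape one of `"disc"`, `"ellipse"`, `"kidney"`, `"sector"`
#' @param target_area exact area in mm^2 the emitted boundary encloses
#'   (shoelace area for the polygonal families, cubature area for the curved
#'   ones)
#' @param centre section centroid position (mm) relative to the common beam
#'   axis; default on the axis
#' @param n_pts boundary sample count (resolution of the outline)
#' @param aspect ellipse axis ratio
#' @param r_inner,span_deg,start_deg annular-sector parameters (mm / degrees)
#' @param jitter relative radial jitter for irregular variants (0 = none)
#' @param seed RNG seed for jittered variants; the global RNG state is left
#'   untouched and a fixed seed reproduces the vertex list bitwise
#' @return a [boundary_spec()] in mm coordinates
#' @export
make_section <- function(shape = c("disc", "ellipse", "kidney", "sector"),
                         target_area,
                         centre = c(0, 0),
                         n_pts = 32L,
                         aspect = 1.6,
                         r_inner = 0.3, span_deg = 120, start_deg = 0,
                         jitter = 0, seed = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(target_area) || target_area <= 0)
    stop("make_section: 'target_area' must be positive")
  jit <- if (jitter > 0)
    .with_local_seed(seed, stats::runif(n_pts, 1 - jitter, 1 + jitter))
  else rep(1, n_pts)
  spec <- switch(shape,
    disc = {
      th <- 2 * pi * (seq_len(n_pts) - 1L) / n_pts
      r <- sqrt(target_area / pi) * jit
      if (jitter > 0) polygon_boundary(cbind(r * cos(th), r * sin(th)))
      else circle_boundary(sqrt(target_area / pi), n_pts)
    },
    ellipse = {
      th <- 2 * pi * (seq_len(n_pts) - 1L) / n_pts
      b <- sqrt(target_area / (pi * aspect)); a <- aspect * b
      polygon_boundary(cbind(a * cos(th) * jit, b * sin(th) * jit))
    },
    kidney = {
      # bean-like outline: circle with a cosine indentation on one side
      th <- 2 * pi * (seq_len(n_pts) - 1L) / n_pts
      r <- (1 - 0.35 * cos(th) * exp(-2 * sin(th / 2)^2)) * jit
      polygon_boundary(cbind(r * cos(th), r * sin(th)))
    },
    sector = {
      a0 <- start_deg * pi / 180; a1 <- (start_deg + span_deg) * pi / 180
      r_out <- max(3 * r_inner, sqrt(target_area))
      n_out <- max(6L, ceiling(span_deg / 8))
      th_o <- seq(a0, a1, length.out = n_out + 1L)
      th_i <- seq(a1, a0, length.out = max(3L, ceiling(n_out / 3)))
      polygon_boundary(rbind(cbind(r_out * cos(th_o), r_out * sin(th_o)) *
                               c(jit[seq_len(n_out + 1L)], jit[seq_len(n_out + 1L)]),
                             cbind(r_inner * cos(th_i), r_inner * sin(th_i))))
    })
  sp <- .scale_to_area(spec, target_area, centre)
  if (.self_intersects(sp))
    stop("make_section: jittered boundary self-intersects; reduce 'jitter'")
  sp
}

.boundary_polyline <- function(spec, per_seg = 24L) {
  bs <- parametrize_boundary(spec)
  do.call(rbind, lapply(bs$splines, function(sg) {
    tt <- seq(sg$t[1L], sg$t[length(sg$t)], length.out = per_seg + 1L)[-(per_seg + 1L)]
    sg$eval(tt, 0L)
  }))
}

.self_intersects <- function(spec) {
  P <- .boundary_polyline(spec, 8L)
  n <- nrow(P)
  a <- P; b <- P[c(2:n, 1L), ]
  for (i in seq_len(n - 2L)) {
    js <- seq(i + 2L, n); js <- js[!(i == 1L & js == n)]
    d1 <- (b[i, 1] - a[i, 1]) * (a[js, 2] - a[i, 2]) - (b[i, 2] - a[i, 2]) * (a[js, 1] - a[i, 1])
    d2 <- (b[i, 1] - a[i, 1]) * (b[js, 2] - a[i, 2]) - (b[i, 2] - a[i, 2]) * (b[js, 1] - a[i, 1])
    d3 <- (b[js, 1] - a[js, 1]) * (a[i, 2] - a[js, 2]) - (b[js, 2] - a[js, 2]) * (a[i, 1] - a[js, 1])
    d4 <- (b[js, 1] - a[js, 1]) * (b[i, 2] - a[js, 2]) - (b[js, 2] - a[js, 2]) * (b[i, 1] - a[js, 1])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Translate a boundary specification in the cross-section plane
#'
#' @param spec a [boundary_spec()]
#' @param shift length-2 translation (mm)
#' @return the translated `boundary_spec`
#' @export
translate_boundary <- function(spec, shift) {
  stopifnot(inherits(spec, "boundary_spec"), length(shift) == 2L)
  boundary_spec(lapply(spec$segments, function(sg) {
    sg$points <- sweep(sg$points, 2L, shift, "+")
    sg
  }))
}

#' Minimum distance between two boundary polylines
#'
#' Used for reference-clearance checks between neighbouring cross-sections.
#'
#' @param spec_a,spec_b two [boundary_spec()] objects
#' @param per_seg polyline sampling density per boundary segment
#' @return minimum pairwise distance between the sampled outlines (mm)
#' @export
boundary_clearance <- function(spec_a, spec_b, per_seg = 24L) {
  A <- .boundary_polyline(spec_a, per_seg)
  B <- .boundary_polyline(spec_b, per_seg)
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  sqrt(min(d2))
}

#' Type III subtendon cross-section layout
#'
#' Three annular-sector polygons arranged around a common central axis with
#' positive mutual clearance, scaled to the published subtendon areas
#' (soleus 16.31, medial gastrocnemius 15.98, lateral gastrocnemius
#' 19.57 mm^2; total 51.86 mm^2). Angular spans are proportional to the
#' areas; shrinking each sector about its own centroid to the exact target
#' area creates the clearance gaps at the shared radial borders.
#'
#' @param areas named or positional areas (mm^2) for soleus, medial, lateral
#' @param r_disc outer radius (mm) of the enclosing disc before shrinking;
#'   default slightly above the equal-area radius of the total area
#' @param r_inner inner hole radius (mm) keeping outlines off the axis
#' @param gap_deg angular gap (degrees) inserted between sectors
#' @return named list (soleus, medial, lateral); each entry has `boundary`
#'   (a [boundary_spec()] in mm, offset from the common axis), `area`,
#'   `centroid` and `name`
#' @export
make_type3_layout <- function(areas = c(soleus = 16.31, medial = 15.98, lateral = 19.57),
                              r_disc = NULL, r_inner = 0.35, gap_deg = 1.5) {
  stopifnot(length(areas) == 3L, all(areas > 0))
  nm <- if (!is.null(names(areas)) && all(nzchar(names(areas)))) names(areas)
        else c("soleus", "medial", "lateral")
  total <- sum(areas)
  if (is.null(r_disc)) r_disc <- 1.03 * sqrt(total / pi)  # ~1-2% diameter clearance
  avail <- 360 - 3 * gap_deg
  spans <- avail * areas / total
  starts <- 90 + c(0, cumsum(spans[-3] + gap_deg))  # soleus opens at posterior
  out <- lapply(seq_len(3L), function(i) {
    raw <- make_section("sector", target_area = areas[[i]], centre = c(0, 0),
                        r_inner = r_inner, span_deg = spans[[i]], start_deg = starts[[i]])
    # make_section scales about the centroid and re-centres at the origin;
    # rebuild at the sector's natural position, then shrink about its own
    # centroid so the clearance gaps open up
    a0 <- starts[[i]] * pi / 180; a1 <- (starts[[i]] + spans[[i]]) * pi / 180
    n_out <- max(6L, ceiling(spans[[i]] / 8))
    th_o <- seq(a0, a1, length.out = n_out + 1L)
    th_i <- seq(a1, a0, length.out = max(3L, ceiling(n_out / 3)))
    V <- rbind(cbind(r_disc * cos(th_o), r_disc * sin(th_o)),
               cbind(r_inner * cos(th_i), r_inner * sin(th_i)))
    sp0 <- polygon_boundary(V)
    A0 <- .shoelace(V)
    if (A0 <= areas[[i]])
      stop("make_type3_layout: enclosing disc too small for the requested areas; increase r_disc")
    cx <- sum((V[, 1] + c(V[-1, 1], V[1, 1])) *
                (V[, 1] * c(V[-1, 2], V[1, 2]) - c(V[-1, 1], V[1, 1]) * V[, 2])) / (6 * A0)
    cy <- sum((V[, 2] + c(V[-1, 2], V[1, 2])) *
                (V[, 1] * c(V[-1, 2], V[1, 2]) - c(V[-1, 1], V[1, 1]) * V[, 2])) / (6 * A0)
    bnd <- .scale_to_area(sp0, areas[[i]], centre = c(cx, cy))
    list(boundary = bnd, area = areas[[i]], centroid = c(cx, cy), name = nm[i])
  })
  names(out) <- nm
  for (i in 1:2) for (j in (i + 1):3) {
    if (boundary_clearance(out[[i]]$boundary, out[[j]]$boundary) <= 0)
      stop(sprintf("make_type3_layout: sections '%s' and '%s' overlap", nm[i], nm[j]))
  }
  out
}
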