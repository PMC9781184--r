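#' The three-subtendon Achilles tendon model
#'
#' Assembles the Type III Achilles tendon: soleus, medial-gastrocnemius and
#' lateral-gastrocnemius subtendons as three pretwisted ANCF continuum beams
#' around a single straight common axis (the line where the subtendons meet).
#' Each subtendon carries its cross-section as an offset domain in the
#' common (y, z) plane, so the pretwist is realized purely by rotating the
#' nodal slope vectors about the axis; material centroid lines then wind
#' helically around the straight axis. The soleus is loaded axially at its
#' last node; the first node of every subtendon is held (position fixed and
#' root cross-section orientation clamped, in-plane contraction free).
#'
#' @name tendon_model
NULL

.TABLE_LOADS <- c(10, 20, 30, 40, 45, 60, 80, 90, 100, 150, 200, 300, 400)

#' Specification of a tendon model
#'
#' Defaults reproduce the published Type III setup: length L = 70 mm,
#' cross-section areas 16.31 / 15.98 / 19.57 mm^2, shear moduli
#' c10 = 103.1 / 143.2 / 226.7 MPa (soleus / medial / lateral), volumetric
#' penalty k = 1000 c10, pretwist in {0, 15, 45} degrees, load schedule
#' 10..400 N.
#'
#' @param L tendon length; mm (or a string with units, e.g. `"0.07 m"`)
#' @param twist_deg total pretwist angle psi over the length (degrees)
#' @param areas cross-section areas (mm^2), order soleus/medial/lateral
#' @param c10 per-subtendon shear-modulus constants (MPa)
#' @param k_factor volumetric penalty multiplier, k = k_factor * c10
#' @param convention `"shear"` (mu = c10) or `"literal"` (mu = 2 c10); see
#'   [neo_hookean()]
#' @param n_elements elements per subtendon
#' @param loads strictly increasing load schedule (N)
#' @param contact list: `enabled`, `pn` (N/mm^3), `mode`, `n_arc`,
#'   `facing_dist` (mm)
#' @param n_cubature cross-section cubature exactness parameter
#' @param n_axial axial Gauss points per element
#' @param handedness `"right"` (counterclockwise twist seen from x = 0) or
#'   `"left"`
#' @param layout optional precomputed [make_type3_layout()] result
#' @return object of class `tendon_spec`
#' @export
tendon_spec <- function(L = 70, twist_deg = 0,
                        areas = c(soleus = 16.31, medial = 15.98, lateral = 19.57),
                        c10 = c(soleus = 103.1, medial = 143.2, lateral = 226.7),
                        k_factor = 1000,
                        convention = c("shear", "literal"),
                        n_elements = 4L,
                        loads = .TABLE_LOADS,
                        contact = list(),
                        n_cubature = 2L, n_axial = 4L,
                        handedness = c("right", "left"),
                        layout = NULL) {
  convention <- match.arg(convention)
  handedness <- match.arg(handedness)
  L <- parse_length_mm(L)
  if (L <= 0) stop("tendon_spec: L must be positive")
  stopifnot(length(areas) == 3L, all(areas > 0), length(c10) == 3L, all(c10 > 0))
  cdef <- list(enabled = TRUE, pn = 5, mode = "bilateral",
               n_arc = 6L, facing_dist = 0.5, n_axial = 4L)
  unknown <- setdiff(names(contact), names(cdef))
  if (length(unknown))
    stop(sprintf("tendon_spec: unknown contact option(s): %s",
                 paste(unknown, collapse = ", ")))
  cdef[names(contact)] <- contact
  structure(list(L = L, twist_deg = twist_deg, areas = areas, c10 = c10,
                 k_factor = k_factor, convention = convention,
                 n_elements = as.integer(n_elements), loads = loads,
                 contact = cdef, n_cubature = as.integer(n_cubature),
                 n_axial = as.integer(n_axial), handedness = handedness,
                 layout = layout),
            class = "tendon_spec")
}

#' Build the three-beam tendon finite-element model
#'
#' @param spec a [tendon_spec()]
#' @return an [fe_model()] with boundary conditions, the soleus tip load
#'   direction and (if enabled) the three pairwise contact pairs registered
#' @export
build_tendon_model <- function(spec) {
  stopifnot(inherits(spec, "tendon_spec"))
  layout <- if (is.null(spec$layout)) make_type3_layout(spec$areas) else spec$layout
  nm <- names(layout)
  tw <- if (spec$handedness == "right") spec$twist_deg else -spec$twist_deg
  # each subtendon beam carries its own centerline through its section
  # centroid; the common tendon axis is the twist axis the centerlines
  # wind around. Loading a subtendon at its last node is then free of
  # artificial bending eccentricity in the straight configuration.
  beams <- lapply(seq_len(3L), function(i) {
    ctr <- layout[[i]]$centroid
    build_reference_beam(translate_boundary(layout[[i]]$boundary, -ctr),
                         spec$L, tw, spec$n_elements,
                         neo_hookean(spec$c10[[i]], spec$k_factor * spec$c10[[i]],
                                     spec$convention),
                         n_cubature = spec$n_cubature, n_axial = spec$n_axial,
                         offset = ctr, name = nm[i])
  })
  names(beams) <- nm
  bad <- character(0)
  for (i in 1:2) for (j in (i + 1):3) {
    if (boundary_clearance(layout[[i]]$boundary, layout[[j]]$boundary) <= 0)
      bad <- c(bad, sprintf("%s-%s", nm[i], nm[j]))
  }
  if (length(bad))
    stop(sprintf("build_tendon_model: overlapping reference cross-sections: %s",
                 paste(bad, collapse = ", ")))
  model <- fe_model(beams)
  # node-1 position fixed; root section orientation clamped (swing and spin
  # rigid modes removed), in-plane contraction left free
  for (i in seq_len(3L)) {
    model <- apply_bcs(model, list(
      list(beam = i, node = 1, field = "r"),
      list(beam = i, node = 1, field = "ry", comp = c(1, 3)),
      list(beam = i, node = 1, field = "rz", comp = c(1, 2))))
  }
  tip <- model_dofs(model, "soleus", beams$soleus$n_nodes, "r", 1)
  model <- apply_point_load(model, tip)
  if (isTRUE(spec$contact$enabled)) {
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      model <- add_contact(model, pair[1], pair[2], pn = spec$contact$pn,
                           mode = spec$contact$mode,
                           n_arc = spec$contact$n_arc,
                           facing_dist = spec$contact$facing_dist,
                           n_axial = spec$contact$n_axial)
    }
  }
  model$spec <- spec
  model
}

#' Tip axial elongations of all subtendons in a state
#'
#' Elongation is the axial (x) displacement of each subtendon's last node.
#'
#' @param model the tendon [fe_model()]
#' @param q global coordinate vector
#' @return named numeric vector (mm)
#' @export
tip_elongations <- function(model, q) {
  vapply(seq_along(model$beams), function(i) {
    b <- model$beams[[i]]
    q[model_dofs(model, i, b$n_nodes, "r", 1)] - b$L
  }, numeric(1)) -> el
  stats::setNames(el, names(model$beams))
}

#' Solve the load schedule and tabulate subtendon elongations
#'
#' @param model a [build_tendon_model()] result
#' @param loads load schedule (N); defaults to the model spec's schedule
#' @param tol,max_iter,verbose passed to [solve_static()]
#' @return data frame with one row per load level: `load_N`, per-subtendon
#'   elongations (mm), Newton `iterations`, `residual` and the maximum
#'   absolute gap change `max_gap_dev` over all contact pairs; the solved
#'   states are attached as attribute `"states"`
#' @export
run_elongation_sweep <- function(model, loads = NULL, tol = 1e-4,
                                 max_iter = 30L, verbose = FALSE) {
  if (is.null(loads)) loads <- model$spec$loads
  states <- solve_static(model, loads, tol = tol, max_iter = max_iter,
                         verbose = verbose)
  rows <- lapply(states, function(st) {
    el <- tip_elongations(model, st$q)
    gd <- if (length(model$contacts))
      max(vapply(model$contacts, function(cp)
        max(abs(.contact_state(cp, model, st$q, 10L)$ghat)), numeric(1)))
    else NA_real_
    data.frame(load_N = st$load, t(el), iterations = st$iters,
               residual = st$resnorm, max_gap_dev = gd)
  })
  out <- do.call(rbind, rows)
  names(out)[2:4] <- paste0("elong_", names(model$beams), "_mm")
  attr(out, "states") <- states
  out
}

#' Mesh-refinement study at a single load
#'
#' Rebuilds the model with increasing element counts and reports the soleus
#' tip elongation at the maximum load of the schedule.
#'
#' @param spec a [tendon_spec()]
#' @param elements element counts per subtendon to compare
#' @param load target load (N); intermediate levels are inserted for robust
#'   stepping
#' @param tol Newton tolerance (N)
#' @return data frame with `elements` and `elong_soleus_mm`
#' @export
mesh_study <- function(spec, elements = c(1L, 2L, 4L), load = 400,
                       tol = 1e-4) {
  rows <- lapply(elements, function(ne) {
    sp <- spec; sp$n_elements <- as.integer(ne)
    m <- build_tendon_model(sp)
    schedule <- unique(sort(c(load * c(0.25, 0.5, 0.75), load)))
    states <- solve_static(m, schedule, tol = tol)
    el <- tip_elongations(m, states[[length(states)]]$q)
    data.frame(elements = ne, elong_soleus_mm = el[["soleus"]])
  })
  do.call(rbind, rows)
}
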