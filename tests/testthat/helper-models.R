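# Shared builders and a cache for the expensive acceptance-scale solves.
# Everything is generated in code; nothing is read from disk.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# a small straight single-beam tension model (centred disc section), used
# by solver and material-consistency tests
small_disc_beam <- function(area = 16.31, mu = 103.1, L = 70, n_el = 2,
                            n_pts = 16) {
  build_reference_beam(make_section("disc", area, n_pts = n_pts), L,
                       twist_deg = 0, n_elements = n_el,
                       material = neo_hookean(mu), name = "bar")
}

single_beam_model <- function(beam) {
  m <- fe_model(list(beam))
  m <- apply_bcs(m, list(
    list(beam = 1, node = 1, field = "r"),
    list(beam = 1, node = 1, field = "ry", comp = c(1, 3)),
    list(beam = 1, node = 1, field = "rz", comp = c(1, 2))))
  apply_point_load(m, model_dofs(m, 1, beam$n_nodes, "r", 1))
}

# two parallel beams with rectangular cross-sections facing each other
# across a gap: flat facing strips give closed-form contact checks
rect_section <- function(w, h, centre) {
  polygon_boundary(cbind(centre[1] + c(-w, w, w, -w) / 2,
                         centre[2] + c(-h, -h, h, h) / 2))
}

rect_pair_model <- function(gap = 0.2, w = 2, h = 2, L = 20, n_el = 1,
                            pn = 10, mode = "bilateral", smooth = TRUE) {
  mat <- neo_hookean(100)
  bA <- build_reference_beam(rect_section(w, h, c(-(w + gap) / 2, 0)), L, 0,
                             n_el, mat, name = "A")
  bB <- build_reference_beam(rect_section(w, h, c((w + gap) / 2, 0)), L, 0,
                             n_el, mat, name = "B")
  m <- fe_model(list(bA, bB))
  add_contact(m, 1, 2, pn = pn, mode = mode, facing_dist = gap * 1.5,
              smooth_surface = smooth)
}

# rigid-translation helper: shift all position dofs of one beam of a model
translate_beam <- function(model, bi, q, dxyz) {
  b <- model$beams[[bi]]
  for (nd in seq_len(b$n_nodes)) {
    idx <- model_dofs(model, bi, nd, "r")
    q[idx] <- q[idx] + dxyz
  }
  q
}

# analytic incompressible neo-Hookean uniaxial stretch under nominal
# stress P = F / A0: solves mu (lambda - lambda^-2) = P
uniaxial_lambda <- function(force_N, mu = 103.1, area = 16.31) {
  vapply(force_N, function(F)
    stats::uniroot(function(l) mu * (l - l^-2) - F / area,
                   c(1, 3), tol = 1e-12)$root, numeric(1))
}

table1_loads <- c(10, 20, 30, 40, 45, 60, 80, 90, 100, 150, 200, 300, 400)

# acceptance-scale solves, computed once per test run
tendon_sweep_cached <- function(psi) {
  cached(sprintf("sweep_psi%g", psi), {
    m <- build_tendon_model(tendon_spec(twist_deg = psi))
    sw <- run_elongation_sweep(m)
    attr(sw, "model") <- m
    sw
  })
}

mesh_study_cached <- function() {
  cached("mesh_study", mesh_study(tendon_spec(), elements = c(1L, 2L, 4L, 8L)))
}
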