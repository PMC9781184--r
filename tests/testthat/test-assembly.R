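# element assembly, tangent and the static solver

test_that("internal force vanishes at the reference and equals the energy gradient", {
  beam <- small_disc_beam(n_el = 1)
  expect_lt(max(abs(beam_internal_force(beam))), 1e-9)

  set.seed(51)
  q <- beam$qbar + 1e-3 * rnorm(beam$ndof)
  f <- beam_internal_force(beam, q)
  h <- 1e-6
  idx <- sample(beam$ndof, 12)
  for (j in idx) {
    qp <- q; qp[j] <- q[j] + h
    qm <- q; qm[j] <- q[j] - h
    fd <- (beam_energy(beam, qp) - beam_energy(beam, qm)) / (2 * h)
    expect_equal(f[j], fd, tolerance = 1e-5 * max(1, abs(fd)))
  }
})

test_that("compiled and reference element kernels agree (dual route)", {
  beam <- small_disc_beam(n_el = 1)
  elt <- beam$elements[[1]]
  set.seed(52)
  Qe <- matrix(beam$qbar, nrow = 3) + 0.01 * matrix(rnorm(54), 3, 18)
  f_r <- ancftendon:::.elt_force_r(elt, Qe, beam$material)
  f_c <- ancftendon:::.elt_force_cpp2(Qe - elt$Qb, elt$Bq, elt$W,
                                     beam$material$mu, beam$material$k)
  expect_equal(unname(f_c), unname(f_r), tolerance = 1e-12)
  e_r <- ancftendon:::.elt_energy_r(elt, Qe, beam$material)
  e_c <- ancftendon:::.elt_energy_cpp2(Qe - elt$Qb, elt$Bq, elt$W,
                                      beam$material$mu, beam$material$k)
  expect_equal(e_c, e_r, tolerance = 1e-12)
})

test_that("quadrature integrates the reference volume", {
  sec <- make_section("sector", 12.5, span_deg = 130)
  beam <- build_reference_beam(sec, 50, 0, 3, neo_hookean(100))
  expect_equal(beam_volume(beam), 50 * 12.5, tolerance = 1e-3 * 50 * 12.5)
})

test_that("the assembled tangent matches finite differences of the force", {
  beam <- small_disc_beam(n_el = 1)
  set.seed(53)
  q <- beam$qbar + 1e-3 * rnorm(beam$ndof)
  K <- beam_tangent(beam, q)                     # internal FD, h = 1e-6
  h <- 5e-5                                      # different step for the oracle
  for (j in sample(beam$ndof, 8)) {
    qp <- q; qp[j] <- q[j] + h
    qm <- q; qm[j] <- q[j] - h
    col <- (beam_internal_force(beam, qp) - beam_internal_force(beam, qm)) / (2 * h)
    expect_equal(K[, j], col, tolerance = 1e-4 * max(abs(col)))
  }
})

test_that("reference tangent: symmetric PSD with a 6-dimensional rigid nullspace", {
  # stocky element so the spectral gap between rigid modes and the softest
  # elastic mode is clean
  beam <- build_reference_beam(make_section("disc", pi * 16, n_pts = 16), 10,
                               0, 1, neo_hookean(100))
  K <- beam_tangent(beam)
  expect_equal(K, t(K), tolerance = 1e-6 * max(abs(K)))
  ev <- sort(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  scale <- max(ev)
  expect_gt(ev[1] / scale, -1e-8)                # PSD up to FD rounding
  expect_lt(abs(ev[6]) / scale, 1e-8)            # six rigid-body modes
  expect_gt(ev[7] / scale, 1e-6)                 # and no more

  # the no-contact tangent is linear in the modulus at the reference
  beam2 <- build_reference_beam(make_section("disc", pi * 16, n_pts = 16), 10,
                                0, 1, neo_hookean(300))
  expect_equal(beam_tangent(beam2), 3 * K, tolerance = 1e-6 * max(abs(K)))
})

test_that("boundary conditions pin dofs and reactions balance the load", {
  beam <- small_disc_beam(n_el = 2)
  m <- single_beam_model(beam)
  expect_error(model_dofs(m, 1, 99), "does not exist")
  expect_error(model_dofs(m, 1, 1, "bogus"), "unknown field")

  st <- solve_static(m, c(50, 100))
  fixed_vals <- st[[2]]$q[m$fixed]
  expect_equal(fixed_vals, m$q0[m$fixed], tolerance = 1e-12)

  rx <- reaction_forces(m, st[[2]]$q, 100)
  axial <- rx[as.character(model_dofs(m, 1, 1, "r", 1))]
  expect_equal(unname(axial), -100, tolerance = 1e-3)
})

test_that("clamping the root orientation removes the rigid rotation modes", {
  beam <- small_disc_beam(n_el = 1)
  m_pin <- single_beam_model(beam)
  m_loose <- apply_point_load(
    apply_bcs(fe_model(list(beam)), list(list(beam = 1, node = 1, field = "r"))),
    model_dofs(fe_model(list(beam)), 1, beam$n_nodes, "r", 1))
  K <- beam_tangent(beam)
  ev_pin <- sort(eigen(K[-m_pin$fixed, -m_pin$fixed], symmetric = TRUE,
                       only.values = TRUE)$values)
  ev_loose <- sort(eigen(K[-m_loose$fixed, -m_loose$fixed], symmetric = TRUE,
                         only.values = TRUE)$values)
  # without the clamp three rigid rotations survive at numerically zero
  # stiffness; with it the softest mode is genuine bending, many orders
  # of magnitude stiffer
  expect_lt(abs(ev_loose[3]), 1e-10 * max(ev_loose))
  expect_gt(ev_pin[1], 1e3 * abs(ev_loose[1]))
  expect_gt(ev_pin[1], 1e-12 * max(ev_pin))
})

test_that("static solve: zero elongation at zero load and monotone under load", {
  beam <- small_disc_beam(n_el = 2)
  m <- single_beam_model(beam)
  st <- solve_static(m, c(20, 60, 120, 200))
  tip <- model_dofs(m, 1, beam$n_nodes, "r", 1)
  el <- vapply(st, function(s) s$q[tip] - beam$L, numeric(1))
  expect_true(all(diff(el) > 0))
  expect_true(all(vapply(st, function(s) s$iters, numeric(1)) >= 1))
  expect_error(solve_static(m, c(10, 5)), "strictly increasing")
})

test_that("small-load stiffness matches the incompressible Young's modulus", {
  beam <- small_disc_beam(area = 16.31, mu = 103.1, L = 70, n_el = 2)
  m <- single_beam_model(beam)
  st <- solve_static(m, 10, tol = 1e-6)
  tip <- model_dofs(m, 1, beam$n_nodes, "r", 1)
  el <- st[[1]]$q[tip] - beam$L
  # E = 3 mu for an incompressible solid; compliance L / (3 mu A0)
  el_lin <- 10 * beam$L / (3 * 103.1 * 16.31)
  expect_equal(el, el_lin, tolerance = 0.05 * el_lin)
})

test_that("external work along the path balances the stored energy", {
  beam <- small_disc_beam(n_el = 2)
  m <- single_beam_model(beam)
  loads <- seq(25, 400, by = 25)
  st <- solve_static(m, loads)
  tip <- model_dofs(m, 1, beam$n_nodes, "r", 1)
  el <- c(0, vapply(st, function(s) s$q[tip] - beam$L, numeric(1)))
  P <- c(0, loads)
  work <- sum((P[-1] + P[-length(P)]) / 2 * diff(el))    # trapezoid in u
  U <- beam_energy(beam, st[[length(st)]]$q)
  expect_equal(work, U, tolerance = 0.01 * U)
})
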