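# 3363 ANCF element kinematics

geom0 <- element_geometry(10, 2, 3)

test_that("shape functions take nodal values and partition unity on the axis", {
  N <- shape_functions(-1, 0, 0, geom0)
  expect_equal(N[1], 1)
  expect_equal(max(abs(N[-1])), 0)
  N0 <- shape_functions(0, 0, 0, geom0)
  expect_equal(N0[7], 1)                       # the mid-node position function
  expect_equal(max(abs(N0[-7])), 0)
  for (xi in c(-0.73, 0.21, 0.9)) {
    N <- shape_functions(xi, 0, 0, geom0)
    expect_equal(N[1] + N[7] + N[13], 1, tolerance = 1e-14)
  }
})

test_that("analytic shape derivatives match finite differences", {
  # the mid-node transverse slope function: dN8/deta = (ly/2)(1 - xi^2)
  p <- c(0.3, -0.4, 0.6)
  dN <- shape_derivatives(p[1], p[2], p[3], geom0)
  expect_equal(dN[8, 2], geom0$ly / 2 * (1 - p[1]^2), tolerance = 1e-12)
  expect_equal(shape_derivatives(0, 0.2, -0.1, geom0)[7, 1], 0)  # extremum of 1 - xi^2

  h <- 1e-6
  set.seed(11)
  for (rep in 1:5) {
    p <- runif(3, -0.9, 0.9)
    dN <- shape_derivatives(p[1], p[2], p[3], geom0)
    for (k in 1:3) {
      pp <- p; pp[k] <- p[k] + h
      pm <- p; pm[k] <- p[k] - h
      fd <- (shape_functions(pp[1], pp[2], pp[3], geom0) -
               shape_functions(pm[1], pm[2], pm[3], geom0)) / (2 * h)
      expect_equal(dN[, k], fd, tolerance = 1e-8)
    }
  }
})

test_that("position interpolation reproduces quadratic fields exactly", {
  set.seed(21)
  cf <- rnorm(10)
  poly <- function(x, y, z)
    cf[1] + cf[2] * x + cf[3] * y + cf[4] * z + cf[5] * x^2 + cf[6] * y^2 +
    cf[7] * z^2 + cf[8] * x * y + cf[9] * x * z + cf[10] * y * z
  # nodal dofs from the field's exact derivatives (per-node Taylor data)
  lx <- geom0$lx
  q <- matrix(0, 3, 18)
  for (i in 1:3) {
    x <- (i - 2) * lx / 2
    i0 <- (i - 1) * 6
    q[1, i0 + 1] <- poly(x, 0, 0)
    q[1, i0 + 2] <- cf[3] + cf[8] * x               # d/dy
    q[1, i0 + 3] <- cf[4] + cf[9] * x               # d/dz
    q[1, i0 + 4] <- cf[10]                          # d2/dydz
    q[1, i0 + 5] <- 2 * cf[6]                       # d2/dy2
    q[1, i0 + 6] <- 2 * cf[7]                       # d2/dz2
  }
  set.seed(22)
  for (rep in 1:10) {
    p <- runif(3, -1, 1)
    x <- p[1] * lx / 2; y <- p[2] * geom0$ly / 2; z <- p[3] * geom0$lz / 2
    r <- evaluate_position(q, p[1], p[2], p[3], geom0)
    expect_equal(r[1], poly(x, y, z), tolerance = 1e-12)
  }
})

test_that("interpolation is exact at nodes and equivariant under translation", {
  ref <- reference_nodes(10, 0, 1)
  q <- ref$qbar
  for (i in 1:3) {
    r <- evaluate_position(q, c(-1, 0, 1)[i], 0, 0, geom0)
    expect_equal(r, c(ref$node_x[i], 0, 0), tolerance = 1e-13)
  }
  qs <- q
  shift <- c(1.5, -2, 0.25)
  for (nd in 1:3) qs[(nd - 1) * 18 + 1:3] <- qs[(nd - 1) * 18 + 1:3] + shift
  p <- c(0.37, 0.5, -0.81)
  expect_equal(evaluate_position(qs, p[1], p[2], p[3], geom0),
               evaluate_position(q, p[1], p[2], p[3], geom0) + shift,
               tolerance = 1e-12)
})

test_that("pretwisted reference rotates off-axis points as a rigid map", {
  psi <- 45
  ref <- reference_nodes(70, psi, 2)
  geom <- element_geometry(35, 2, 2)
  # last node of the chain (xi = +1 of element 2): rotation by psi
  q2 <- matrix(ref$qbar[as.vector(outer(1:18, (3:5 - 1) * 18, "+"))], nrow = 3)
  th <- psi * pi / 180
  r <- evaluate_position(q2, 1, 0.6, 0, geom)
  y0 <- 0.6 * geom$ly / 2
  expect_equal(r, c(70, y0 * cos(th), y0 * sin(th)), tolerance = 1e-12)
  # psi = 0: all nodes share identical slope dofs
  r0 <- reference_nodes(70, 0, 2)
  expect_true(all(apply(r0$qnodes[4:18, ], 1, function(v) max(abs(v - v[1]))) == 0))
})

test_that("deformation gradient: identity, rotation, uniaxial stretch", {
  ref <- reference_nodes(10, 0, 1)
  q <- ref$qbar
  p <- c(0.3, -0.5, 0.7)
  fg <- deformation_gradient(q, q, p[1], p[2], p[3], geom0)
  expect_equal(fg$F, diag(3), tolerance = 1e-12)
  expect_equal(fg$J, 1, tolerance = 1e-12)

  th <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  qr <- as.vector(R %*% matrix(q, nrow = 3))
  fr <- deformation_gradient(qr, q, p[1], p[2], p[3], geom0)
  expect_equal(fr$F, R, tolerance = 1e-12)
  expect_equal(fr$J, 1, tolerance = 1e-12)

  lam <- 1.13
  qs <- q
  for (nd in 1:3) qs[(nd - 1) * 18 + 1] <- lam * qs[(nd - 1) * 18 + 1]
  fs <- deformation_gradient(qs, q, p[1], p[2], p[3], geom0)
  expect_equal(fs$F, diag(c(lam, 1, 1)), tolerance = 1e-12)

  # inverted state is signalled as a recoverable condition
  qi <- q
  for (nd in 1:3) qi[(nd - 1) * 18 + 1] <- -qi[(nd - 1) * 18 + 1]
  expect_error(deformation_gradient(qi, q, 0, 0, 0, geom0),
               class = "ancf_degenerate_state")
})

test_that("Green-Lagrange strain is objective at every material point", {
  set.seed(31)
  ref <- reference_nodes(10, 15, 1)
  q <- ref$qbar + 0.05 * rnorm(54)
  th <- c(0.7, -0.3, 1.2)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  R <- Rx %*% Ry
  qQ <- as.vector(R %*% matrix(q, nrow = 3))
  shift <- c(3, -1, 2)
  for (nd in 1:3) qQ[(nd - 1) * 18 + 1:3] <- qQ[(nd - 1) * 18 + 1:3] + shift
  for (rep in 1:5) {
    p <- runif(3, -0.9, 0.9)
    F1 <- deformation_gradient(q, ref$qbar, p[1], p[2], p[3], geom0)$F
    F2 <- deformation_gradient(qQ, ref$qbar, p[1], p[2], p[3], geom0)$F
    expect_equal(strain_green(F2), strain_green(F1), tolerance = 1e-10)
  }
})

test_that("twisted reference beams keep their volume (J = 1 in the reference)", {
  sec <- make_section("sector", 10, span_deg = 110, start_deg = 20)
  for (psi in c(0, 15, 45)) {
    b <- build_reference_beam(sec, 70, psi, 4, neo_hookean(100))
    expect_equal(beam_volume(b), 70 * 10, tolerance = 1e-3 * 700,
                 label = sprintf("psi=%g", psi))
  }
  expect_error(reference_nodes(-1, 0, 1), "positive")
  expect_error(reference_nodes(10, 0, 0), ">= 1")
})
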