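# beam-to-beam contact: projection, gaps, penalty forces

test_that("closest-point projection: surface points and brute-force oracle", {
  mat <- neo_hookean(100)
  bB <- build_reference_beam(make_section("disc", pi, centre = c(1.1, 0),
                                          n_pts = 32), 50, 0, 2, mat)
  # a point on the surface projects onto itself
  pr <- closest_point_projection(bB, c(25, 2.1, 0))
  expect_lt(pr$distance, 5e-3)    # within the spline-boundary resolution
  expect_equal(pr$normal[1, ], c(0, 1, 0), tolerance = 5e-2)

  # random exterior points against a dense brute-force surface sampling
  set.seed(61)
  X <- cbind(runif(6, 5, 45), runif(6, -3, 3), runif(6, -3, 3))
  pr <- closest_point_projection(bB, X)
  curve <- ancftendon:::.section_curve(bB$section)
  Ql <- lapply(bB$elements, function(e) matrix(bB$qbar[e$dofs], 3))
  grid <- expand.grid(s = seq(0, 2, length.out = 501),
                      u = seq(0, curve$total, length.out = 401)[-401])
  sv <- ancftendon:::.surf_eval(bB, Ql, grid$s, grid$u, curve, derivs = FALSE)
  for (i in seq_len(nrow(X))) {
    brute <- sqrt(min((X[i, 1] - sv$pos[, 1])^2 + (X[i, 2] - sv$pos[, 2])^2 +
                        (X[i, 3] - sv$pos[, 3])^2))
    expect_lt(abs(pr$distance[i] - brute), 1e-3)
  }

  # a point on the axis of a circular beam: symmetric tie broken
  # deterministically (same answer on repeated calls)
  p1 <- closest_point_projection(bB, c(25, 1.1, 0))
  p2 <- closest_point_projection(bB, c(25, 1.1, 0))
  expect_identical(p1$u, p2$u)
  expect_equal(p1$distance, 1, tolerance = 2e-3)   # the section radius
})

test_that("cylinder gap geometry: touching, separated, penetrating", {
  mat <- neo_hookean(100)
  mk <- function(dy) {
    bA <- build_reference_beam(make_section("disc", pi, centre = c(-1 - dy / 2, 0),
                                            n_pts = 32), 30, 0, 1, mat, name = "A")
    bB <- build_reference_beam(make_section("disc", pi, centre = c(1 + dy / 2, 0),
                                            n_pts = 32), 30, 0, 1, mat, name = "B")
    fe_model(list(bA, bB))
  }
  delta <- 0.15
  m <- mk(delta)   # separated by delta
  cp <- contact_pair(m, 1, 2, pn = 10, mode = "unilateral",
                     facing_dist = 2 * delta, n_arc = 25L)
  g <- contact_gaps(cp, m)
  expect_equal(min(g$g), delta, tolerance = 0.01 * delta + 2e-3)
  expect_true(all(g$optimality < 1e-6))

  # penetration by delta: push A towards B
  q <- translate_beam(m, 1, m$q0, c(0, delta + delta, 0))
  g2 <- contact_gaps(cp, m, q)
  expect_equal(min(g2$g), -delta, tolerance = 0.02 * delta + 2e-3)
})

test_that("uniform penetration of flat strips gives pn * delta * area", {
  delta <- 0.05
  m <- rect_pair_model(gap = 0.2, w = 2, h = 2, L = 20, pn = 10,
                       mode = "unilateral", smooth = FALSE)
  q <- translate_beam(m, 1, m$q0, c(0, 0.2 + delta, 0))
  cp <- m$contacts[[1]]
  R <- contact_residual(cp, m, q)
  posA <- unlist(lapply(seq_len(m$beams[[1]]$n_nodes),
                        function(nd) model_dofs(m, 1, nd, "r")))
  FA <- rowSums(matrix(R[posA], nrow = 3))
  # strip area: length x facing height (quadrature resolves the strip; the
  # corner-adjacent samples are inactive, so the covered strip is slightly
  # narrower than the full face)
  expect_equal(abs(FA[2]), 10 * delta * 20 * 2, tolerance = 0.15 * 10 * delta * 40)
  expect_equal(FA[3], 0, tolerance = 1e-8)
})

test_that("action equals reaction and separated unilateral pairs are inert", {
  m <- rect_pair_model(gap = 0.2, mode = "unilateral", smooth = FALSE)
  cp <- m$contacts[[1]]
  # separated: zero residual
  expect_identical(max(abs(contact_residual(cp, m, m$q0))), 0)

  q <- translate_beam(m, 1, m$q0, c(0, 0.27, 0.01))
  R <- contact_residual(cp, m, q)
  sum3 <- function(bi) {
    idx <- unlist(lapply(seq_len(m$beams[[bi]]$n_nodes),
                         function(nd) model_dofs(m, bi, nd, "r")))
    rowSums(matrix(R[idx], nrow = 3))
  }
  expect_equal(sum3(1), -sum3(2), tolerance = 1e-10)
  expect_gt(max(abs(sum3(1))), 0)
})

test_that("bilateral pairs are stress-free in the reference configuration", {
  m <- rect_pair_model(gap = 0.15, mode = "bilateral")
  expect_lt(max(abs(contact_residual(m$contacts[[1]], m, m$q0))), 1e-9)
  expect_lt(contact_energy(m$contacts[[1]], m, m$q0), 1e-12)
})

test_that("contact tangent matches finite differences of the residual", {
  # circular sections: curvature makes every closest-point projection
  # unique, so the differentiated residual is smooth (flat faces leave the
  # arc parameter indeterminate and are unsuitable for FD checks)
  mat <- neo_hookean(100)
  bA <- build_reference_beam(make_section("disc", pi, centre = c(0, -1.1),
                                          n_pts = 32), 20, 0, 1, mat, name = "A")
  bB <- build_reference_beam(make_section("disc", pi, centre = c(0, 1.1),
                                          n_pts = 32), 20, 0, 1, mat, name = "B")
  m <- fe_model(list(bA, bB))
  m <- add_contact(m, 1, 2, pn = 10, mode = "unilateral", facing_dist = 0.4,
                   n_arc = 8L)
  q <- translate_beam(m, 1, m$q0, c(0, 0, 0.25))   # light penetration
  cp <- m$contacts[[1]]
  K <- contact_tangent(cp, m, q, central = TRUE)
  h <- 3e-6
  set.seed(62)
  cols <- sample(which(m$q0 != 0 | seq_along(m$q0) %% 18 <= 9), 6)
  s0 <- cp$s; u0 <- cp$u
  for (j in cols) {
    cp$s <- s0; cp$u <- u0
    qp <- q; qp[j] <- q[j] + h
    Rp <- contact_residual(cp, m, qp, proj_iters = 12)
    cp$s <- s0; cp$u <- u0
    qm <- q; qm[j] <- q[j] - h
    Rm <- contact_residual(cp, m, qm, proj_iters = 12)
    col <- (Rp - Rm) / (2 * h)
    denom <- max(abs(col), 1)
    expect_lt(max(abs(col - K[, j])) / denom, 1e-3)
  }
  # zero gap, zero force: tangent of an inert pair vanishes
  K0 <- contact_tangent(cp, m, m$q0)
  expect_equal(max(abs(K0)), 0)
})

test_that("equilibrium gap violation shrinks as the penalty grows", {
  gap_at <- function(pn) {
    sp <- tendon_spec(n_elements = 1L, contact = list(pn = pn),
                      loads = c(25, 50))
    m <- build_tendon_model(sp)
    sw <- run_elongation_sweep(m)
    sw$max_gap_dev[nrow(sw)]
  }
  g_small <- gap_at(1)
  g_large <- gap_at(10)
  expect_lt(g_large, g_small)
})
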