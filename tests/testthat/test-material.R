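# near-incompressible neo-Hookean constitutive law

random_F <- function(n = 1, spread = 0.15) {
  lapply(seq_len(n), function(i) {
    repeat {
      F <- diag(3) + matrix(rnorm(9, sd = spread), 3, 3)
      if (det(F) > 0.8 && det(F) < 1.2) return(F)
    }
  })
}

test_that("deformation split: dilation, isochoric maps, failure signalling", {
  mat <- neo_hookean(103.1)
  s <- split_deformation(diag(3))
  expect_equal(s$J, 1); expect_equal(s$Fbar, diag(3))

  s2 <- split_deformation(2 * diag(3))
  expect_equal(s2$J, 8, tolerance = 1e-12)
  expect_equal(s2$Fbar, diag(3), tolerance = 1e-12)

  lam <- 1.3
  Fi <- diag(c(lam, lam^-0.5, lam^-0.5))
  si <- split_deformation(Fi)
  expect_equal(si$J, 1, tolerance = 1e-12)
  expect_equal(si$Cbar, crossprod(Fi), tolerance = 1e-12)
  expect_equal(det(si$Fbar), 1, tolerance = 1e-10)

  expect_error(split_deformation(diag(c(-1, 1, 1))), class = "ancf_degenerate_state")
  expect_error(neo_hookean(-1), "positive")
})

test_that("stress parts vanish where they must and keep their structure", {
  mat <- neo_hookean(103.1)
  expect_equal(pk2_stress(diag(3), mat), matrix(0, 3, 3), tolerance = 1e-12)
  # isochoric part is blind to pure dilation
  expect_equal(pk2_isochoric(1.23 * diag(3), mat), matrix(0, 3, 3), tolerance = 1e-10)
  # volumetric part vanishes at J = 1 and tracks the sign of J - 1
  lam <- 1.2
  expect_equal(pk2_volumetric(diag(c(lam, lam^-0.5, lam^-0.5)), mat),
               matrix(0, 3, 3), tolerance = 1e-8)
  a <- 1.05
  Sv <- pk2_volumetric(a * diag(3), mat)
  expect_equal(Sv, 2 * mat$k * (a^3 - 1) * a^3 * a^-2 * diag(3), tolerance = 1e-10)
  expect_gt(sum(diag(Sv)), 0)
  Svc <- pk2_volumetric(0.97 * diag(3), mat)
  expect_lt(sum(diag(Svc)), 0)

  # Kirchhoff-deviatoric structure: tr(Sbar C) = 0
  set.seed(41)
  for (F in random_F(5)) {
    Sb <- pk2_isochoric(F, mat)
    C <- crossprod(F)
    expect_lt(abs(sum(Sb * C)) / mat$mu, 1e-8)
    S <- pk2_stress(F, mat)
    expect_equal(S, t(S), tolerance = 1e-9)
  }
})

test_that("Green-Lagrange strain closed forms", {
  expect_equal(strain_green(diag(3)), matrix(0, 3, 3))
  lam <- 1.4
  expect_equal(strain_green(diag(c(lam, 1, 1))),
               diag(c((lam^2 - 1) / 2, 0, 0)), tolerance = 1e-12)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(strain_green(R), matrix(0, 3, 3), tolerance = 1e-12)
})

test_that("hyperelastic consistency: S = 2 dPsi/dC on random states", {
  # directional derivative check: dPsi(C + t dC)/dt |_0 = (S : dC) / 2
  mat <- neo_hookean(103.1, k = 2000)   # moderate k keeps FD well-conditioned
  psi_of_C <- function(C, mat) {
    e <- eigen(C, symmetric = TRUE)
    F <- e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
    strain_energy(F, mat)
  }
  set.seed(42)
  h <- 1e-6
  worst <- 0
  for (F in random_F(100)) {
    C <- crossprod(F)
    S <- pk2_stress(F, mat)
    dC <- matrix(rnorm(9), 3, 3); dC <- (dC + t(dC)) / 2
    fd <- (psi_of_C(C + h * dC, mat) - psi_of_C(C - h * dC, mat)) / (2 * h)
    ref <- sum(S * dC) / 2
    worst <- max(worst, abs(fd - ref) / max(abs(ref), 1e-8))
  }
  expect_lt(worst, 1e-5)
})

test_that("material frame indifference", {
  mat <- neo_hookean(103.1)
  set.seed(43)
  for (F in random_F(10)) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    Q <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    expect_equal(pk2_stress(Q %*% F, mat), pk2_stress(F, mat), tolerance = 1e-9)
  }
})

test_that("uniaxial response matches the incompressible closed form", {
  mu <- 103.1; A0 <- 16.31; P <- 400 / A0
  lam <- uniaxial_lambda(400)
  expect_equal(lam, 1.0859, tolerance = 2e-3)
  # with the penalty material, minimise the energy over the lateral stretch
  # and verify the nominal axial stress matches the applied load
  mat <- neo_hookean(mu)
  lat <- optimize(function(c) strain_energy(diag(c(lam, c, c)), mat),
                  c(0.8, 1.0), tol = 1e-12)$minimum
  h <- 1e-7
  P_num <- (strain_energy(diag(c(lam + h, lat, lat)), mat) -
              strain_energy(diag(c(lam - h, lat, lat)), mat)) / (2 * h)
  expect_equal(P_num, P, tolerance = 0.01 * P)
})

test_that("lateral contraction approaches lambda^(-1/2) monotonically in k", {
  mu <- 103.1; lam <- 1.0859
  lats <- vapply(c(10, 100, 1000, 10000) * mu, function(k) {
    mat <- neo_hookean(mu, k = k)
    optimize(function(c) strain_energy(diag(c(lam, c, c)), mat),
             c(0.8, 1.0), tol = 1e-12)$minimum
  }, numeric(1))
  errs <- abs(lats - lam^-0.5)
  expect_true(all(diff(errs) < 0))
})

test_that("the literal one-parameter convention doubles the shear modulus", {
  m1 <- neo_hookean(100, convention = "shear")
  m2 <- neo_hookean(100, convention = "literal")
  expect_equal(m1$mu, 100)
  expect_equal(m2$mu, 200)
  F <- diag(c(1.1, 0.96, 0.96))
  expect_equal(pk2_isochoric(F, m2), 2 * pk2_isochoric(F, m1), tolerance = 1e-12)
})

test_that("vectorized constitutive kernel agrees with the matrix route", {
  mat <- neo_hookean(103.1)
  set.seed(44)
  Fs <- random_F(20)
  F9 <- t(vapply(Fs, as.vector, numeric(9)))
  out <- ancftendon:::.pk2_vec(F9, mat)
  for (i in seq_along(Fs)) {
    expect_equal(matrix(out$S9[i, ], 3, 3), pk2_stress(Fs[[i]], mat),
                 tolerance = 1e-10)
    expect_equal(out$psi[i], strain_energy(Fs[[i]], mat), tolerance = 1e-10)
  }
})
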