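# Integral engine against independent quadrature oracles and structural
# invariants.

test_that("one-electron integrals match radial quadrature on an s function", {
  mol <- molecule("He", matrix(0, 1, 3), unit = "bohr")
  b <- toy_basis(mol, 0.8)
  oe <- one_electron(b)
  a <- 0.8
  f <- function(r) (2 * a / pi)^0.75 * exp(-a * r^2)
  expect_equal(oe$S[1, 1], 1, tolerance = 1e-12)
  Tnum <- stats::integrate(function(r) 4 * pi * r^2 * f(r) *
                             (-0.5 * ((4 * a^2 * r^2 - 6 * a) * f(r))),
                           0, Inf)$value
  expect_equal(oe$T[1, 1], Tnum, tolerance = 1e-9)
  Vnum <- -2 * stats::integrate(function(r) 4 * pi * r^2 * f(r)^2 / r,
                                0, Inf)$value
  expect_equal(oe$V[1, 1], Vnum, tolerance = 1e-9)
})

test_that("four-center Coulomb integral matches the closed-form oracle", {
  mol <- molecule("He", matrix(0, 1, 3), unit = "bohr")
  b <- toy_basis(mol, c(0.8, 1.3))
  eri <- four_center_oracle(b)
  f <- function(r) (2 * 0.8 / pi)^0.75 * exp(-0.8 * r^2)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  # potential of the (normalized s)^2 density with exponent 2*1.3
  oracle <- stats::integrate(function(r) 4 * pi * r^2 * f(r)^2 *
                               erf(sqrt(2 * 1.3) * r) / r,
                             0, Inf)$value
  expect_equal(eri[1, 1, 2, 2], oracle, tolerance = 1e-9)
  # 8-fold permutational symmetry
  expect_lt(max(abs(eri - aperm(eri, c(2, 1, 3, 4))),
                abs(eri - aperm(eri, c(3, 4, 1, 2))),
                abs(eri - aperm(eri, c(1, 2, 4, 3)))), 1e-12)
})

test_that("geminal operator kernels match 2D radial quadrature", {
  mol <- molecule("He", matrix(0, 1, 3), unit = "bohr")
  b <- toy_basis(mol, c(0.8, 1.3))
  gem <- make_geminal(gamma = 1.2)
  P <- function(r) (2 * 0.8 / pi)^0.75 * exp(-0.8 * r^2)
  Q <- function(r) (2 * 1.3 / pi)^0.75 * exp(-1.3 * r^2)
  avg2c <- function(K) {
    inner <- function(r1) vapply(r1, function(x)
      stats::integrate(function(r2) vapply(r2, function(y) {
        v <- stats::integrate(function(u) K(u) * u,
                              abs(x - y), x + y)$value / (2 * x * y)
        4 * pi * y^2 * Q(y) * v
      }, 0), 1e-8, 12, rel.tol = 1e-8)$value, 0)
    stats::integrate(function(r1) 4 * pi * r1^2 * P(r1) * inner(r1),
                     1e-8, 12, rel.tol = 1e-7)$value
  }
  g <- 1.2
  # exact Slater kernels; the engine uses the 6-Gaussian expansion, so the
  # comparison is limited by the stored fit residual (the doubled-exponent
  # kernels carry roughly double the relative expansion error again)
  tol <- 3 * gem$fit_residual
  tc_f <- two_center(b, b, "f12", gem)
  expect_equal(tc_f[1, 2], avg2c(function(u) -(1 / g) * exp(-g * u)),
               tolerance = tol)
  tc_fr <- two_center(b, b, "f12_over_r12", gem)
  expect_equal(tc_fr[1, 2], avg2c(function(u) -(1 / g) * exp(-g * u) / u),
               tolerance = tol)
  tc_g <- two_center(b, b, "grad_f12_squared", gem)
  expect_equal(tc_g[1, 2], avg2c(function(u) exp(-2 * g * u)),
               tolerance = 8 * gem$fit_residual)
})

test_that("operator identities hold at expansion level", {
  b <- build_basis(molecule(c("O", "H"), rbind(c(0, 0, 0), c(0, 0, 1.8)),
                            unit = "bohr"), "DZ")
  gem <- make_geminal("DZ")
  tsq <- two_center(b, b, "f12_squared", gem)
  tgr <- two_center(b, b, "grad_f12_squared", gem)
  expect_lt(max(abs(tsq - tgr / gem$gamma^2)), 1e-10)
})

test_that("f12 integrals vanish between well-separated centers at large gamma", {
  mol <- molecule(c("He", "He"), rbind(c(0, 0, 0), c(0, 0, 14)), unit = "bohr")
  b <- toy_basis(mol, c(1.1, 1.1), cen_idx = c(1L, 2L))
  gem <- make_geminal(gamma = 8)
  tc <- two_center(b, b, "f12", gem)
  expect_lt(abs(tc[1, 2]), 1e-12)
})

test_that("integral tensors are invariant under rigid translation", {
  mol <- molecule(c("O", "H"), rbind(c(0, 0, 0), c(0, 0, 1.8)), unit = "bohr")
  b1 <- build_basis(mol, "DZ")
  mol2 <- transform_molecule(mol, shift = c(3.3, -1.1, 0.7))
  b2 <- build_basis(mol2, "DZ")
  oe1 <- one_electron(b1); oe2 <- one_electron(b2)
  expect_lt(max(abs(oe1$S - oe2$S)), 1e-10)
  expect_lt(max(abs(oe1$T - oe2$T)), 1e-10)
  expect_lt(max(abs(oe1$V - oe2$V)), 1e-10)
  gem <- make_geminal("DZ")
  a1 <- build_basis(mol, "RI-DZ"); a2 <- build_basis(mol2, "RI-DZ")
  t1 <- three_center(b1, b1, a1, "f12", gem)
  t2 <- three_center(b2, b2, a2, "f12", gem)
  expect_lt(max(abs(t1 - t2)), 1e-10)
})

test_that("four-center oracle refuses oversized spaces", {
  b <- build_basis(water1(), "DZ")
  expect_error(four_center_oracle(b, max_dim = 5), "guard")
})
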