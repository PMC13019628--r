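# Boys localization and projected atomic orbitals.

test_that("single-orbital block is returned unchanged (up to sign)", {
  ref <- ref_h2("MIN")
  oe <- one_electron(ref$basis)
  dip <- list(oe$DX, oe$DY, oe$DZ)
  blk <- ref$mo_coefficients[, 1, drop = FALSE]
  out <- boys_localize(blk, dip)
  expect_lt(max(abs(abs(out$coefficients) - abs(blk))), 1e-12)
})

test_that("localization does not decrease the Boys objective", {
  ref <- ref_water_dz()
  oe <- one_electron(ref$basis)
  dip <- list(oe$DX, oe$DY, oe$DZ)
  Cv <- ref$mo_coefficients[, 2:5]
  obj0 <- sum(vapply(dip, function(M) sum(diag(crossprod(Cv, M %*% Cv))^2), 0))
  out <- boys_localize(Cv, dip)
  expect_gte(out$boys_objective, obj0 - 1e-12)
})

test_that("2x2 rotation matches a dense angle-scan oracle", {
  ref <- ref_water_dz()
  oe <- one_electron(ref$basis)
  dip <- list(oe$DX, oe$DY, oe$DZ)
  C2 <- ref$mo_coefficients[, 4:5]
  grid <- seq(-pi / 4, pi / 4, length.out = 20001)
  vals <- vapply(grid, function(th) {
    cs <- cos(th); sn <- sin(th)
    Cg <- cbind(cs * C2[, 1] + sn * C2[, 2], -sn * C2[, 1] + cs * C2[, 2])
    sum(vapply(dip, function(M) sum(diag(crossprod(Cg, M %*% Cg))^2), 0))
  }, 0)
  out <- boys_localize(C2, dip)
  expect_equal(out$boys_objective, max(vals), tolerance = 1e-8)
})

test_that("core and valence are localized separately with preserved spans", {
  ref <- ref_water_dz()
  loc <- localize_core_and_valence(ref)
  expect_equal(ncol(loc$core$coefficients), 1)
  expect_equal(ncol(loc$valence$coefficients), 4)
  occ <- ref$mo_coefficients[, seq_len(ref$n_occ)]
  L <- cbind(loc$core$coefficients, loc$valence$coefficients)
  # occupied density matrix unchanged
  expect_lt(max(abs(tcrossprod(occ) - tcrossprod(L))), 1e-10)
})

test_that("far-separated water LMOs localize onto one monomer each", {
  w1 <- water1()
  dim2 <- combine_molecules(w1, transform_molecule(w1, shift = c(0, 0, 25)))
  ref <- load_reference(hf_reference(dim2, "MIN"))
  loc <- localize_core_and_valence(ref)
  origin <- colSums(dim2$coords * dim2$charges) / sum(dim2$charges)
  cents <- sweep(loc$valence$centroids, 2, -origin)
  for (k in seq_len(nrow(cents))) {
    dists <- sqrt(colSums((t(dim2$coords) - cents[k, ])^2))
    expect_lt(min(dists), 1.0)   # within 1 bohr of some atom of one monomer
  }
})

test_that("PAOs span the virtual complement and are occupied-orthogonal", {
  ref <- ref_h2("MIN")
  paos <- build_paos(ref)
  S <- ref$overlap_ao
  # minimal H2: 2 AOs, 1 occupied -> 2 raw PAOs spanning a 1-dim space
  expect_equal(ncol(paos$coefficients), 2)
  ev <- eigen(crossprod(paos$coefficients, S %*% paos$coefficients))$values
  expect_equal(sum(ev > 1e-8 * max(ev)), 1)
  refw <- ref_water_dz()
  pw <- build_paos(refw)
  occ <- refw$mo_coefficients[, seq_len(refw$n_occ)]
  expect_lt(max(abs(crossprod(occ, refw$overlap_ao %*% pw$coefficients))), 1e-8)
  # occupied span + PAO span resolve the identity on the AO space
  sc <- semicanonicalize(pw$coefficients, refw$fock_ao, refw$overlap_ao)
  full <- cbind(occ, sc$coefficients)
  P <- full %*% crossprod(full, refw$overlap_ao)
  expect_lt(max(abs(P - diag(nrow(P)))), 1e-8)
})

test_that("PAO centroids are translation-covariant", {
  w <- water1()
  r1 <- load_reference(hf_reference(w, "MIN"))
  w2 <- transform_molecule(w, shift = c(2, -1, 4))
  r2 <- load_reference(hf_reference(w2, "MIN"))
  p1 <- build_paos(r1); p2 <- build_paos(r2)
  expect_lt(max(abs(p1$coefficients - p2$coefficients)), 1e-6)
  expect_equal(p1$parent_atom, p2$parent_atom)
})
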