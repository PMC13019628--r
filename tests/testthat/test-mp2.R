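# Canonical MP2, extended-domain contributions, pair-domain energies.

test_that("canonical DF-MP2 matches the dense four-index explicit sum (H2)", {
  ref <- ref_h2("DZ")
  mp2 <- canonical_mp2(ref)
  # independent evaluation: DF-reconstructed integrals, explicit loops
  metric <- build_metric(ref$aux_basis)
  T3 <- three_center(ref$basis, ref$basis, ref$aux_basis)
  C <- ref$mo_coefficients
  nocc <- ref$n_occ; nmo <- ncol(C)
  Tm <- lmf12:::.transform_3c(T3, C, C)
  J <- fit_J(Tm, metric)
  G <- array(tcrossprod(J), c(nmo, nmo, nmo, nmo))
  eps <- ref$orbital_energies
  E <- 0
  for (i in seq_len(nocc)) for (j in seq_len(nocc))
    for (a in (nocc + 1):nmo) for (b in (nocc + 1):nmo) {
      D <- eps[i] + eps[j] - eps[a] - eps[b]
      E <- E + (2 * G[a, i, b, j] - G[a, j, b, i]) * G[a, i, b, j] / D
    }
  expect_equal(mp2$E_corr, E, tolerance = 1e-12)
})

test_that("spin components partition the correlation energy", {
  mp2 <- mp2_water()
  expect_equal(mp2$E_os + mp2$E_ss, mp2$E_corr, tolerance = 1e-12)
  expect_lt(mp2$E_os, 0); expect_lt(mp2$E_ss, 0)
  expect_equal(sum(mp2$pair_energies), mp2$E_corr, tolerance = 1e-10)
})

test_that("canonical MP2 is size consistent for two far H2 molecules", {
  m1 <- h2mol()
  dimer <- combine_molecules(m1, transform_molecule(m1, shift = c(0, 0, 100)))
  ref1 <- ref_h2("DZ")
  refd <- load_reference(hf_reference(dimer, "DZ"))
  e1 <- canonical_mp2(ref1)$E_corr
  ed <- canonical_mp2(refd)$E_corr
  expect_lt(abs(ed - 2 * e1), 1e-8)
})

test_that("ED contribution with one occupied orbital matches the dense oracle", {
  ref <- ref_h2("DZ")
  lctx <- lmp2_context(ref, collapse_config())
  ed <- lctx$eds[[1]]
  out <- ed_mp2_contribution(lctx, ed)
  expect_equal(out$energy, canonical_mp2(ref)$E_corr, tolerance = 1e-8)
})

test_that("ED energies are invariant under a uniform Fock level shift", {
  ref <- ref_h2("DZ")
  lctx <- lmp2_context(ref, collapse_config())
  ed <- lctx$eds[[1]]
  e0 <- ed_mp2_contribution(lctx, ed)$energy
  ed2 <- ed
  ed2$eps_virt <- ed$eps_virt + 0.37
  ed2$eps_occ <- ed$eps_occ + 0.37
  e1 <- ed_mp2_contribution(lctx, ed2)$energy
  expect_equal(e0, e1, tolerance = 1e-9)
})

test_that("pair-domain energy agrees with the full-dimer OS pair energy", {
  sep <- 10
  lctx <- lctx_hehe(sep)
  ref <- lctx$ref
  est <- pair_domain_mp2(lctx$pds[[1]], lctx$pds[[2]], lctx$C_lmo,
                         ref$basis, ref$aux_basis, ref$fock_ao,
                         ref$overlap_ao, 1e-8,
                         ref$mo_coefficients[, seq_len(ref$n_occ)])
  # full-dimer opposite-spin cross pair energy (canonical)
  mp2 <- canonical_mp2(ref)
  eps <- ref$orbital_energies
  act <- mp2$active; virt <- mp2$virtuals
  metric <- build_metric(ref$aux_basis)
  T3 <- three_center(ref$basis, ref$basis, ref$aux_basis)
  C <- ref$mo_coefficients
  # localized occupieds for a like-for-like OS pair split
  Cl <- lctx$C_lmo
  Tm <- lmf12:::.transform_3c(T3, C[, virt], Cl)
  J <- fit_J(Tm, metric)
  nv <- length(virt)
  Jarr <- array(J, c(nv, 2, ncol(J)))
  g <- tcrossprod(Jarr[, 1, ], Jarr[, 2, ])
  f11 <- crossprod(Cl[, 1], ref$fock_ao %*% Cl[, 1])[1]
  f22 <- crossprod(Cl[, 2], ref$fock_ao %*% Cl[, 2])[1]
  D <- f11 + f22 - outer(eps[virt], eps[virt], `+`)
  e_os_full <- 2 * sum(g^2 / D)
  expect_lt(abs(est - e_os_full) / abs(e_os_full), 0.05)
  # opposite-spin-only neglect makes the pair value an incomplete
  # negative sum: it lies above the full (OS+SS) pair energy
  expect_lt(est, 0)
})

test_that("LMP2 assembly audits double counting", {
  pairs <- data.frame(i = c(1, 1), j = c(2, 3),
                      estimate = c(-1e-4, -1e-6), method = "multipole",
                      class = c("strong", "distant"))
  out <- assemble_lmp2(c(-0.1, -0.2, -0.05), pairs)
  expect_equal(out$E_corr, -0.35 + -1e-6)
  bad <- pairs; bad$class <- c("strong", "strong")
  bad2 <- rbind(bad, data.frame(i = 1, j = 2, estimate = -1e-4,
                                method = "multipole", class = "distant"))
  expect_error(assemble_lmp2(c(-0.1), bad2), "accounted")
})

test_that("LMP2 equals canonical MP2 in the full-domain limit (water)", {
  ref <- ref_water_dz()
  lm <- lmp2(ref, collapse_config())
  expect_equal(lm$E_corr, mp2_water()$E_corr, tolerance = 1e-8)
  expect_equal(lm$E_pairs, 0)
})
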