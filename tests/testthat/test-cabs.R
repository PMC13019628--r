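# Complementary auxiliary space and the CABS singles correction.

test_that("complementary space is orthogonal to the MO space", {
  ctx <- f12ctx_water()
  comp <- ctx$complementary
  ref <- ref_water_dz()
  C_mo <- rbind(ref$mo_coefficients,
                matrix(0, comp$joint_basis$n - ref$basis$n,
                       ncol(ref$mo_coefficients)))
  ov <- crossprod(comp$coefficients, comp$S_joint %*% C_mo)
  expect_lt(max(abs(ov)), 1e-8)
  # internally orthonormal
  Sc <- crossprod(comp$coefficients, comp$S_joint %*% comp$coefficients)
  expect_lt(max(abs(Sc - diag(ncol(Sc)))), 1e-8)
})

test_that("RI dimension equals MO plus complementary with full rank", {
  ctx <- f12ctx_water()
  ref <- ref_water_dz()
  nmo <- ncol(ref$mo_coefficients)
  expect_equal(ctx$nri, nmo + ctx$complementary$n_comp)
  SRI <- crossprod(ctx$C_RI, ctx$complementary$S_joint %*% ctx$C_RI)
  ev <- eigen(SRI, symmetric = TRUE)$values
  expect_gt(min(ev), 1e-6)        # no overcounting / linear dependence
  expect_lt(max(abs(SRI - diag(ctx$nri))), 1e-7)
})

test_that("a CABS source inside the AO span leaves only the augmentation", {
  ref <- ref_h2("DZ")
  # use the orbital basis itself as the CABS source: the projected-CABS
  # block must vanish, only projected-AO augmentation can survive
  comp <- build_complementary(ref, cabs_basis = ref$basis)
  expect_equal(ncol(comp$cabs_block), 0)
})

test_that("CABS singles is negative, zero without complementary functions", {
  ref <- ref_water_dz()
  ctx <- f12ctx_water()
  s <- cabs_singles(ref, ctx$complementary, ctx$fock_joint)
  expect_lt(s$energy, 0)
  empty <- ctx$complementary
  empty$n_comp <- 0L
  expect_equal(cabs_singles(ref, empty)$energy, 0)
})

test_that("CABS singles vanishes in the Brillouin limit and matches a
          dense second-order oracle", {
  ref <- ref_water_dz()
  ctx <- f12ctx_water()
  comp <- ctx$complementary
  fj <- ctx$fock_joint
  nocc <- ref$n_occ
  Cocc <- rbind(ref$mo_coefficients[, seq_len(nocc)],
                matrix(0, comp$joint_basis$n - ref$basis$n, nocc))
  # dense oracle: solve (F_cc - e_i) x = F_ci per occupied orbital
  Cc <- comp$coefficients
  Fcc <- crossprod(Cc, fj$F %*% Cc)
  Foc <- crossprod(Cocc, fj$F %*% Cc)
  eo <- ref$orbital_energies[seq_len(nocc)]
  E_oracle <- 0
  for (i in seq_len(nocc)) {
    x <- solve(Fcc - diag(eo[i], nrow(Fcc)), Foc[i, ])
    E_oracle <- E_oracle - sum(Foc[i, ] * x)
  }
  s <- cabs_singles(ref, comp, fj)
  expect_equal(s$energy, E_oracle, tolerance = 1e-10)
  # Brillouin limit: occupied-complementary coupling zeroed
  fj0 <- fj
  P <- Cc %*% crossprod(Cc, fj$S)
  O <- Cocc %*% crossprod(Cocc, fj$S)
  fj0$F <- fj$F - t(O) %*% fj$F %*% P - t(P) %*% fj$F %*% O
  s0 <- cabs_singles(ref, comp, fj0)
  expect_equal(s0$energy, 0, tolerance = 1e-12)
})

test_that("larger CABS domains never shrink the complementary dimension", {
  ref <- ref_h2("DZ")
  dims <- vapply(c("BPo", "BPEDo", "PCD", "ED"), function(cd) {
    cfg <- domain_config(cabs_domain = cd, cd_threshold = 1e-8)
    lctx <- lmp2_context(ref, cfg)
    comp_global <- build_complementary(ref)
    fj <- joint_fock(ref, comp_global$joint_basis)
    fctx <- lmf12:::.ed_f12_context(lctx, lctx$eds[[1]],
                                    make_geminal("DZ"), comp_global, fj)
    length(fctx$comp_pos)
  }, 0)
  expect_true(all(diff(dims) >= 0))
})
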