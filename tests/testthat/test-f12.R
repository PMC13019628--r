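# Explicitly correlated intermediates and the MP2-F12 assembly.

test_that("all F12 intermediates vanish with a null geminal", {
  ref <- ref_he("DZ")
  gem0 <- make_geminal(gamma = 1)
  gem0$coefs[] <- 0
  ctx <- f12_context(ref, geminal = gem0)
  vxb <- compute_VXB(ctx)
  expect_true(all(abs(vxb$B) < 1e-12))
  expect_true(all(abs(vxb$X) < 1e-12))
  expect_true(all(abs(vxb$V) < 1e-12))
  expect_lt(max(abs(compute_R(ctx, 1, 1))), 1e-12)
  expect_equal(compute_C_canonical(ctx, 1, 1), 0, tolerance = 1e-14)
})

test_that("R obeys the pair-exchange symmetry R_ij^ab = R_ji^ba", {
  ctx <- f12ctx_water()
  act <- ctx$act_pos
  i <- match(act[1], ctx$occ_pos); j <- match(act[3], ctx$occ_pos)
  Rij <- compute_R(ctx, i, j)
  Rji <- compute_R(ctx, j, i)
  expect_lt(max(abs(Rij - t(Rji))), 1e-10)
})

test_that("R matches a brute-force index-loop oracle (H2)", {
  ref <- ref_h2("DZ")
  ctx <- cache_get("f12ctx_h2", f12_context(ref))
  R <- compute_R(ctx, 1, 1)
  # explicit loops over Eq-8-type sums with complementary indices
  v <- ctx$virt_pos; cp <- ctx$comp_pos
  Om <- lmf12:::.pair_mat(ctx, 1, 1, "f12")
  F <- ctx$F_RI
  nv <- length(v)
  Rloop <- matrix(0, nv, nv)
  for (a in seq_len(nv)) for (b in seq_len(nv)) {
    s <- 0
    for (ap in cp) s <- s + F[v[a], ap] * Om[ap, v[b]]
    for (bp in cp) s <- s + Om[v[a], bp] * F[bp, v[b]]
    Rloop[a, b] <- s
  }
  expect_lt(max(abs(R - Rloop)), 1e-12)
})

test_that("R vanishes when the Fock coupling to the complementary space
          is zero", {
  ref <- ref_h2("DZ")
  ctx <- cache_get("f12ctx_h2", f12_context(ref))
  ctx0 <- ctx
  ctx0$F_RI[ctx$virt_pos, ctx$comp_pos] <- 0
  ctx0$F_RI[ctx$comp_pos, ctx$virt_pos] <- 0
  expect_lt(max(abs(compute_R(ctx0, 1, 1))), 1e-14)
})

test_that("X and B pair scalars are symmetric in i and j", {
  ctx <- f12ctx_water()
  act <- ctx$act_pos
  p12 <- rbind(c(act[2], act[4]))
  p21 <- rbind(c(act[4], act[2]))
  a <- compute_VXB(ctx, p12)
  b <- compute_VXB(ctx, p21)
  expect_equal(a$X, b$X, tolerance = 1e-10)
  expect_equal(a$B, b$B, tolerance = 1e-10)
  expect_equal(a$V, b$V, tolerance = 1e-10)
})

test_that("the geminal quadratic form is positive above the pair level", {
  # B - (e_i + e_j) X contracted in the singlet channel must be positive
  # (Fock gap of the residual space); checked on helium
  ref <- ref_he("DZ")
  ctx <- cache_get("f12ctx_he", f12_context(ref))
  vxb <- compute_VXB(ctx)
  expect_gt(vxb$B[1] - vxb$X[1], 0)
})

test_that("diagonal pairs enter with weight 1/2", {
  res <- cache_get("canf12_he", canonical_mp2_f12(ref_he("DZ"),
                                                  ctx = cache_get("f12ctx_he",
                                                                  f12_context(ref_he("DZ")))))
  expect_equal(res$f12_pairs$weight, 0.5)   # helium: single (1,1) pair
  expect_equal(res$E_f12,
               0.5 * with(res$f12_pairs, B - X + C + V), tolerance = 1e-12)
})

test_that("helium F12 correction has the right sign and magnitude", {
  mD <- canonical_mp2(ref_he("DZ"))
  mQ <- canonical_mp2(ref_he("QZ"))
  f12 <- cache_get("canf12_he", canonical_mp2_f12(ref_he("DZ")))
  expect_lt(f12$E_f12, 0)
  # F12 moves the small-basis correlation energy past the large-basis one
  expect_lt(abs(f12$E_mp2f12 - mQ$E_corr), abs(mD$E_corr - mQ$E_corr))
})

test_that("Eq-20-style half pair sums reproduce the i<=j assembly", {
  # two-active-orbital audit: sum_i (1/2) sum_j scalar_ij equals
  # sum_{i<=j} scalar_ij/(1+delta_ij) for symmetric pair scalars
  ctx <- cache_get("f12ctx_h2dim", {
    m <- combine_molecules(h2mol(), transform_molecule(h2mol(),
                                                       shift = c(0, 0, 7)))
    f12_context(load_reference(hf_reference(m, "MIN")),
                geminal = make_geminal(gamma = 1.0))
  })
  act <- ctx$act_pos
  full <- expand.grid(i = act, j = act)
  vxb_all <- compute_VXB(ctx, as.matrix(full))
  sc <- with(vxb_all, B - X + V)
  half_sum <- 0.5 * sum(sc)
  upper <- vxb_all$i <= vxb_all$j
  w <- ifelse(vxb_all$i == vxb_all$j, 0.5, 1)
  ij_sum <- sum((w * sc)[upper])
  expect_equal(half_sum, ij_sum, tolerance = 1e-10)
})

test_that("local C equals canonical C on a full-system domain (H2)", {
  ref <- ref_h2("DZ")
  loc <- lmp2_f12(ref, collapse_config())
  can <- canonical_mp2_f12(ref,
                           ctx = cache_get("f12ctx_h2", f12_context(ref)))
  expect_equal(loc$E_f12, can$E_f12, tolerance = 1e-8)
  expect_equal(loc$E_lmp2, can$E_corr, tolerance = 1e-8)
})
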