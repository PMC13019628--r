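# Density fitting: metric factorization, fitted J, robust K.

test_that("metric factor reproduces the two-center matrix", {
  aux <- build_basis(water1(), "RI-DZ")
  m <- build_metric(aux)
  V <- m$V[m$piv, m$piv]
  expect_lt(max(abs(V - tcrossprod(m$L))), 1e-10)
  expect_equal(m$n_dropped, 0)
})

test_that("one-function metric is the scalar square root", {
  mol <- molecule("He", matrix(0, 1, 3), unit = "bohr")
  aux <- toy_basis(mol, 1.7)
  m <- build_metric(aux)
  expect_equal(as.numeric(m$L), sqrt(m$V[1, 1]), tolerance = 1e-12)
})

test_that("a duplicated auxiliary function is removed by conditioning", {
  mol <- molecule("He", matrix(0, 1, 3), unit = "bohr")
  aux <- toy_basis(mol, c(0.9, 1.7, 1.7))
  m <- build_metric(aux)
  expect_equal(m$n_dropped, 1)
  expect_equal(length(m$piv), 2)
})

test_that("fitting is exact when the aux basis spans all orbital products", {
  mol <- molecule("He", matrix(0, 1, 3), unit = "bohr")
  orb <- toy_basis(mol, c(0.6, 1.5))
  # same-center s x s products are s functions with summed exponents
  aux <- toy_basis(mol, c(1.2, 2.1, 3.0))
  metric <- build_metric(aux)
  T3 <- three_center(orb, orb, aux)
  J <- fit_J(T3, metric)
  eri <- four_center_oracle(orb)
  rec <- array(tcrossprod(J), dim(eri))
  expect_lt(max(abs(eri - rec)), 1e-10)
  # robust fitting of the geminal operator is exact there too
  gem <- make_geminal(gamma = 1.1)
  T3f <- three_center(orb, orb, aux, "f12", gem)
  V2f <- two_center(aux, aux, "f12", gem)
  K <- fit_K(T3f, V2f, J, metric)
  erif <- four_center_oracle(orb, op = "f12", geminal = gem)
  recf <- array(df_reconstruct(J, J, K, K), dim(erif))
  expect_lt(max(abs(erif - recf)), 1e-10)
})

test_that("zero three-center input gives zero J; zero two-center reduces K", {
  mol <- molecule("He", matrix(0, 1, 3), unit = "bohr")
  orb <- toy_basis(mol, c(0.6, 1.5))
  aux <- toy_basis(mol, c(1.2, 2.1, 3.0))
  metric <- build_metric(aux)
  T3 <- three_center(orb, orb, aux)
  Z <- array(0, dim(T3))
  expect_true(all(fit_J(Z, metric) == 0))
  J <- fit_J(T3, metric)
  gem <- make_geminal(gamma = 1.1)
  T3f <- three_center(orb, orb, aux, "f12", gem)
  K0 <- fit_K(T3f, matrix(0, aux$n, aux$n), J, metric)
  K1 <- t(forwardsolve(metric$L, t(matrix(T3f, orb$n^2, aux$n)[, metric$piv])))
  expect_lt(max(abs(K0 - K1)), 1e-12)
  expect_error(fit_K(T3f, NULL, J, metric), "required")
})

test_that("robust fitting error decays with twice the log-slope of the
          one-sided fit on nested aux sets", {
  mol <- molecule("He", matrix(0, 1, 3), unit = "bohr")
  orb <- toy_basis(mol, c(0.6, 1.5))
  gem <- make_geminal(gamma = 1.1)
  erif <- four_center_oracle(orb, op = "f12", geminal = gem)
  sizes <- c(3, 4, 5, 6)
  err_rob <- err_one <- numeric(length(sizes))
  for (s in seq_along(sizes)) {
    n <- sizes[s]
    aux <- toy_basis(mol, 0.55 * 2.6^(seq_len(n) - 1))
    metric <- build_metric(aux)
    J <- fit_J(three_center(orb, orb, aux), metric)
    T3f <- three_center(orb, orb, aux, "f12", gem)
    V2f <- two_center(aux, aux, "f12", gem)
    K <- fit_K(T3f, V2f, J, metric)
    rec_rob <- array(df_reconstruct(J, J, K, K), dim(erif))
    K1 <- t(forwardsolve(metric$L,
                         t(matrix(T3f, orb$n^2, aux$n)[, metric$piv,
                                                       drop = FALSE])))
    rec_one <- array(tcrossprod(J, K1), dim(erif))
    err_rob[s] <- max(abs(erif - rec_rob))
    err_one[s] <- max(abs(erif - rec_one))
  }
  # both errors shrink monotonically as the nested sets grow
  expect_true(all(diff(err_rob) < 0))
  expect_true(all(diff(err_one) < 0))
  slope_rob <- stats::coef(stats::lm(log(err_rob) ~ sizes))[2]
  slope_one <- stats::coef(stats::lm(log(err_one) ~ sizes))[2]
  expect_gt(slope_rob / slope_one, 1.4)
  expect_lt(slope_rob / slope_one, 2.8)
})

test_that("fitted Coulomb error shrinks as nested aux subsets grow (water)", {
  ref <- ref_water_dz()
  eri <- NULL
  orb <- ref$basis
  aux_full <- ref$aux_basis
  # nested even-tempered s/p/d subsets: take growing prefixes per atom
  errs <- numeric(0)
  for (frac in c(0.5, 0.75, 1)) {
    keep <- unlist(lapply(split(seq_len(aux_full$n), aux_full$atom_of_ao),
                          function(ix) ix[seq_len(ceiling(length(ix) * frac))]))
    aux <- subset_basis(aux_full, sort(keep))
    metric <- build_metric(aux)
    J <- fit_J(three_center(orb, orb, aux), metric)
    if (is.null(eri)) eri <- four_center_oracle(orb)
    rec <- array(tcrossprod(J), dim(eri))
    errs <- c(errs, max(abs(eri - rec)))
  }
  expect_true(all(diff(errs) < 0))
})
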