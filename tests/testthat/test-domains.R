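# Boughton-Pulay lists, primary/extended domains, pair classification.

test_that("configuration guards reject invalid thresholds", {
  expect_error(domain_config(T_trf = 1.5), "strictly in")
  expect_error(domain_config(T_trf = 0.99), "T_trf > T_EDo")
  expect_error(domain_config(eps_w = -1), "non-negative")
  expect_equal(domain_config()$cabs_domain, "BPEDo")
})

test_that("a fully localized orbital gets a single-atom BP list", {
  mol <- molecule(c("He", "H", "H"),
                  rbind(c(0, 0, 0), c(0, 0, 20), c(0, 0, 21.4)),
                  unit = "bohr")
  ref <- load_reference(hf_reference(mol, "MIN"))
  loc <- localize_core_and_valence(ref)
  # one LMO sits on the distant He
  S <- ref$overlap_ao; ao <- ref$basis$atom_of_ao
  lists <- lapply(seq_len(2), function(k)
    bp_atom_list(loc$valence$coefficients[, k], S, ao, 0.999))
  he_list <- lists[[which(vapply(lists, function(l) 1 %in% l$atoms, TRUE))[1]]]
  expect_equal(he_list$atoms, 1)
  expect_gte(he_list$completeness, 0.999)
})

test_that("greedy BP list matches the exhaustive minimal-subset oracle", {
  ref <- ref_water_dz()
  loc <- localize_core_and_valence(ref)
  S <- ref$overlap_ao; ao <- ref$basis$atom_of_ao
  comp <- function(coef, atoms) {
    idx <- which(ao %in% atoms)
    b <- (S %*% coef)[idx]
    as.numeric(crossprod(b, solve(S[idx, idx], b)))
  }
  for (k in seq_len(4)) {
    coef <- loc$valence$coefficients[, k]
    bl <- bp_atom_list(coef, S, ao, 0.98)
    # brute force: smallest subset of the 3 atoms reaching 0.98
    best <- NULL
    for (m in 1:3) {
      subs <- utils::combn(3, m)
      for (c2 in seq_len(ncol(subs)))
        if (comp(coef, subs[, c2]) >= 0.98) { best <- subs[, c2]; break }
      if (!is.null(best)) break
    }
    expect_equal(length(bl$atoms), length(best))
    expect_gte(bl$completeness, 0.98)
  }
})

test_that("BP completeness grows monotonically along the greedy ranking", {
  ref <- ref_water_dz()
  loc <- localize_core_and_valence(ref)
  S <- ref$overlap_ao; ao <- ref$basis$atom_of_ao
  coef <- loc$valence$coefficients[, 1]
  comp <- function(atoms) {
    idx <- which(ao %in% atoms)
    b <- (S %*% coef)[idx]
    as.numeric(crossprod(b, solve(S[idx, idx], b)))
  }
  vals <- vapply(1:3, function(m) comp(seq_len(m)), 0)
  expect_true(all(diff(vals) > -1e-12))
})

test_that("tightening thresholds enlarges domains monotonically", {
  ref <- ref_water_dz()
  w2 <- combine_molecules(water1(),
                          transform_molecule(water1(), shift = c(0, 0, 7)))
  ref2 <- load_reference(hf_reference(w2, "MIN"))
  loose <- lmp2_context(ref2, domain_config(T_PDo = 0.98, T_PDv = 0.97,
                                            T_EDo = 0.99, T_o = 0.985))
  tight <- lmp2_context(ref2, domain_config(T_PDo = 0.999, T_PDv = 0.98,
                                            T_EDo = 0.99999, T_o = 0.985,
                                            T_trf = 0.999999))
  for (k in seq_along(loose$pds))
    expect_true(all(loose$pds[[k]]$atoms %in% tight$pds[[k]]$atoms))
  for (k in seq_along(loose$eds))
    expect_true(all(loose$eds[[k]]$atoms %in% tight$eds[[k]]$atoms))
})

test_that("single-water domains cover the whole molecule", {
  ref <- ref_water_dz()
  lctx <- lmp2_context(ref)
  for (pd in lctx$pds) expect_equal(pd$atoms, 1:3)
  for (ed in lctx$eds) expect_equal(ed$atoms, 1:3)
  # all pairs strong for a compact molecule
  expect_true(all(lctx$pairs$class == "strong"))
  # CABS domain defaults to the BPEDo list of the CMO
  for (ed in lctx$eds)
    expect_equal(ed$cabs_atoms, lctx$bp$edo[[ed$cmo]]$atoms)
})

test_that("primary domains of a far helium dimer stay on their monomer", {
  lctx <- lctx_hehe(20)
  expect_equal(lctx$pds[[1]]$atoms, unique(lctx$pds[[1]]$atoms))
  atoms <- sort(unique(c(lctx$pds[[1]]$atoms, lctx$pds[[2]]$atoms)))
  expect_equal(vapply(lctx$pds, function(p) length(p$atoms), 0L), c(1L, 1L))
})

test_that("truncated PAO span is contained in the original PAO span", {
  ref <- ref_water_dz()
  lctx <- lmp2_context(ref)
  paos <- lctx$paos
  S <- ref$overlap_ao
  full <- semicanonicalize(paos$coefficients, ref$fock_ao, S)$coefficients
  P <- full %*% crossprod(full, S)
  for (pd in lctx$pds) {
    resid <- pd$C_virt - P %*% pd$C_virt
    expect_lt(max(abs(resid)), 1e-7)
  }
})

test_that("pair estimates follow an R^-6 law and the eps_w boundary", {
  seps <- c(8, 10, 12, 14, 16)
  ests <- vapply(seps, function(s) lctx_hehe(s)$pairs$estimate[1], 0)
  expect_true(all(ests < 0))
  slope <- stats::coef(stats::lm(log(abs(ests)) ~ log(seps)))[2]
  expect_gt(slope, -6.3); expect_lt(slope, -5.7)
  # classification flips exactly where |estimate| crosses eps_w = 1e-5
  scan <- c(3.5, 4, 4.5, 5, 5.6, 8, 12, 16)
  cls <- character(0); est <- numeric(0)
  for (s in scan) {
    p <- lctx_hehe(s)$pairs
    cls <- c(cls, p$class[1]); est <- c(est, p$estimate[1])
  }
  expect_identical(cls, ifelse(abs(est) >= 1e-5, "strong", "distant"))
  expect_true(all(c("strong", "distant") %in% cls))
})

test_that("estimate for a far-separated water pair is below eps_w", {
  w2 <- combine_molecules(water1(),
                          transform_molecule(water1(), shift = c(0, 0, 20)))
  ref <- load_reference(hf_reference(w2, "MIN"))
  lctx <- lmp2_context(ref)
  # cross-monomer pairs identified by PD atom sets
  mono <- vapply(lctx$pds, function(p) all(p$atoms <= 3), TRUE)
  p <- lctx$pairs
  cross <- p[mono[p$i] != mono[p$j], ]
  expect_true(all(abs(cross$estimate) < 1e-5))
  expect_true(all(cross$class == "distant"))
})

test_that("pair classification is symmetric and i = j is rejected", {
  lctx <- lctx_hehe(10)
  p <- lctx$pairs
  expect_true(all(p$i < p$j))
  expect_error(pair_domain_mp2(lctx$pds[[1]], lctx$pds[[1]], lctx$C_lmo,
                               lctx$ref$basis, lctx$ref$aux_basis,
                               lctx$ref$fock_ao, lctx$ref$overlap_ao),
               "i != j")
})

test_that("far water dimer EDs respect the core coverage rule", {
  w2 <- combine_molecules(water1(),
                          transform_molecule(water1(), shift = c(0, 0, 30)))
  ref <- load_reference(hf_reference(w2, "MIN"))
  lctx <- lmp2_context(ref)
  monoA <- 1:3
  for (ed in lctx$eds) {
    onA <- all(ed$atoms %in% monoA)
    onB <- all(!(ed$atoms %in% monoA))
    expect_true(onA || onB)   # no ED mixes monomers at 30 bohr
    # included core LMOs must have their BPEDo lists inside the ED
    for (ck in ed$core_lmos)
      expect_true(all(lctx$bp$core_edo[[ck]]$atoms %in% ed$atoms))
    expect_equal(length(ed$core_lmos), 1)  # own oxygen core only
  }
})
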