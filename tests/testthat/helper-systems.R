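# Shared lazily-built fixtures.  Everything is generated in code; heavy
# objects (references, F12 contexts) are cached across test files.

.tcache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (is.null(.tcache[[key]])) .tcache[[key]] <- force(expr)
  .tcache[[key]]
}

# single-center toy basis of s-type functions with given exponents
toy_basis <- function(mol, ex, cen_idx = rep(1L, length(ex)), l = 0L) {
  n <- length(ex)
  lm <- matrix(0L, n, 3)
  lm[, 1] <- as.integer(rep_len(l, n))
  structure(list(mol = mol, name = "toy",
                 l = lm, center = mol$coords[cen_idx, , drop = FALSE],
                 exps = as.list(ex),
                 coefs = lapply(seq_len(n), function(i) {
                   cf <- lmf12:::.prim_norm(ex[i], lm[i, 1], 0, 0)
                   cf / sqrt(lmf12:::.self_overlap(ex[i], cf, lm[i, 1], 0, 0))
                 }),
                 atom_of_ao = cen_idx, shell_of_ao = seq_len(n), n = n),
            class = "lmf12_basis")
}

water1 <- function() generate_fixture("water_chain", 1)

ref_water_dz <- function() cache_get("ref_water_dz",
  load_reference(hf_reference(water1(), "DZ")))

ref_he <- function(card) cache_get(paste0("ref_he_", card),
  load_reference(hf_reference(molecule("He", matrix(0, 1, 3), unit = "bohr"),
                              card)))

h2mol <- function() molecule(c("H", "H"),
                             rbind(c(0, 0, 0), c(0, 0, 0.7414)),
                             unit = "angstrom")

ref_h2 <- function(card = "DZ") cache_get(paste0("ref_h2_", card),
  load_reference(hf_reference(h2mol(), card)))

# thresholds that force every domain to the full system
collapse_config <- function() domain_config(
  T_PDo = 1 - 1e-6, T_PDv = 1 - 1e-6, T_EDo = 1 - 1e-7, T_o = 1 - 1e-6,
  T_trf = 1 - 1e-8, eps_w = 0, cd_threshold = 1e-10, cabs_domain = "ED")

mp2_water <- function() cache_get("mp2_water", canonical_mp2(ref_water_dz()))

f12ctx_water <- function() cache_get("f12ctx_water", f12_context(ref_water_dz()))

can_f12_water <- function() cache_get("can_f12_water",
  canonical_mp2_f12(ref_water_dz(), ctx = f12ctx_water()))

loc_f12_water <- function() cache_get("loc_f12_water",
  lmp2_f12(ref_water_dz(), collapse_config()))

ref_ch4 <- function() cache_get("ref_ch4",
  load_reference(hf_reference(generate_fixture("alkane", 1), "DZ")))

can_f12_ch4 <- function() cache_get("can_f12_ch4", canonical_mp2_f12(ref_ch4()))

loc_f12_ch4 <- function() cache_get("loc_f12_ch4",
  lmp2_f12(ref_ch4(), collapse_config()))

lctx_hehe <- function(sep) cache_get(paste0("lctx_hehe_", sep), {
  ref <- load_reference(hf_reference(generate_fixture("noble_pair",
                                                      separation = sep), "DZ"))
  lmp2_context(ref)
})

# LMP2-F12 of a small molecule with default local thresholds
lmp2f12_h2 <- function() cache_get("lmp2f12_h2",
  lmp2_f12(ref_h2(), domain_config(cd_threshold = 1e-8)))
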