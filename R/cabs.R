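# Complementary auxiliary space (CABS) construction, the Fock matrix in
# the joint AO+CABS basis, and the CABS singles correction.

# Generic complementary-space builder over a joint function set.
#
# S_joint: overlap over the joint functions; ao_cols: joint-function
# indices forming the domain's AO basis; cabs_cols: indices of the CABS
# source functions considered; C_mo: MO-space coefficients over the joint
# functions (columns span the domain's occupied+virtual MO space).
# Two blocks are produced: (1) CABS functions with the AO span projected
# out, Lowdin-orthogonalized dropping overlap eigenvalues < lindep_cabs;
# (2) an augmentation block of AOs with the MO span projected out, cutoff
# lindep_aug, filling the gap between the MO space and the AO span.
.complementary_space <- function(S_joint, ao_cols, cabs_cols, C_mo,
                                 lindep_cabs = 1e-7, lindep_aug = 1e-4) {
  nj <- nrow(S_joint)
  lowdin_cols <- function(V, cutoff) {
    if (ncol(V) == 0) return(V)
    Sv <- crossprod(V, S_joint %*% V)
    e <- eigen((Sv + t(Sv)) / 2, symmetric = TRUE)
    keep <- e$values > cutoff
    V %*% (e$vectors[, keep, drop = FALSE] %*%
             diag(1 / sqrt(e$values[keep]), sum(keep)))
  }
  # orthonormal basis of the AO span
  Eao <- diag(nj)[, ao_cols, drop = FALSE]
  Cao <- lowdin_cols(Eao, 1e-9)
  # block 1: project AO span out of the CABS functions
  Ecab <- diag(nj)[, cabs_cols, drop = FALSE]
  V1 <- Ecab - Cao %*% crossprod(Cao, S_joint %*% Ecab)
  V1 <- lowdin_cols(V1, lindep_cabs)
  # block 2: project the MO span out of the AO functions (gap filler)
  V2 <- Eao - C_mo %*% crossprod(C_mo, S_joint %*% Eao)
  V2 <- lowdin_cols(V2, lindep_aug)
  # numerical cleanup: V2 against V1 span (exactly orthogonal in theory)
  if (ncol(V1) && ncol(V2)) {
    V2 <- V2 - V1 %*% crossprod(V1, S_joint %*% V2)
    V2 <- lowdin_cols(V2, 1e-8)
  }
  list(cabs_block = V1, aug_block = V2,
       coefficients = cbind(V1, V2))
}

#' Build the complementary (CABS) space
#'
#' Global variant: constructs the orthonormal complementary virtual space
#' of the whole molecule from a CABS source basis, plus the augmentation
#' block of projected AOs.  The resolution-of-the-identity space is the
#' MO space plus this complementary space.
#'
#' @param reference an [load_reference()] object.
#' @param cabs_basis `lmf12_basis` of CABS source functions (default
#'   derived from the orbital cardinal).
#' @param lindep_cabs,lindep_aug Lowdin overlap-eigenvalue cutoffs for the
#'   projected CABS block and the augmentation block.
#' @return `lmf12_complementary`: coefficients over the joint AO+CABS
#'   function set, the joint basis object, index bookkeeping.
#' @export
build_complementary <- function(reference, cabs_basis = NULL,
                                lindep_cabs = 1e-7, lindep_aug = 1e-4) {
  ref <- reference
  cardinal <- sub("^(RI-|CABS-)", "", ref$basis$name)
  if (is.null(cabs_basis)) cabs_basis <- build_basis(ref$mol, paste0("CABS-", cardinal))
  joint <- join_basis(ref$basis, cabs_basis)
  oej <- one_electron(joint)
  nao <- ref$basis$n
  C_mo <- rbind(ref$mo_coefficients,
                matrix(0, cabs_basis$n, ncol(ref$mo_coefficients)))
  cs <- .complementary_space(oej$S, seq_len(nao), nao + seq_len(cabs_basis$n),
                             C_mo, lindep_cabs, lindep_aug)
  structure(list(coefficients = cs$coefficients,
                 cabs_block = cs$cabs_block, aug_block = cs$aug_block,
                 joint_basis = joint, cabs_basis = cabs_basis,
                 n_ao = nao, n_comp = ncol(cs$coefficients),
                 S_joint = oej$S),
            class = "lmf12_complementary")
}

#' @export
print.lmf12_complementary <- function(x, ...) {
  cat(sprintf("<lmf12_complementary> %d functions (%d projected CABS + %d augmented AO)\n",
              x$n_comp, ncol(x$cabs_block), ncol(x$aug_block)))
  invisible(x)
}

#' Fock matrix in the joint AO+CABS basis
#'
#' Dense desk-scale build: one-electron part over the joint functions plus
#' the Coulomb/exchange field of the converged AO density.
#'
#' @param reference an [load_reference()] object.
#' @param joint_basis joint basis from [build_complementary()].
#' @return list(F, S, h) over the joint functions.
#' @export
joint_fock <- function(reference, joint_basis) {
  ref <- reference
  oej <- one_electron(joint_basis)
  h <- oej$T + oej$V
  nao <- ref$basis$n
  nocc <- ref$n_occ
  Cocc <- ref$mo_coefficients[, seq_len(nocc), drop = FALSE]
  D <- 2 * tcrossprod(Cocc)
  # (p'q'|mu nu) and (p'mu|q'nu) tensors against the AO density
  W1 <- four_center_oracle(joint_basis, joint_basis, ref$basis, ref$basis,
                           max_dim = 200)
  nj <- joint_basis$n
  Jm <- matrix(as.numeric(matrix(W1, nj * nj, nao * nao) %*% as.numeric(D)),
               nj, nj)
  W2 <- four_center_oracle(joint_basis, ref$basis, joint_basis, ref$basis,
                           max_dim = 200)
  Km <- matrix(0, nj, nj)
  # K_{p'q'} = sum_{mu nu} D_{mu nu} (p'mu|q'nu)
  W2m <- aperm(W2, c(1, 3, 2, 4))          # p', q', mu, nu
  Km <- matrix(matrix(W2m, nj * nj, nao * nao) %*% as.numeric(D), nj, nj)
  Fj <- h + Jm - 0.5 * Km
  list(F = Fj, S = oej$S, h = h)
}

#' CABS singles correction to the HF energy
#'
#' Non-iterative second-order correction built from the occupied ->
#' complementary Fock couplings: E = - sum_i |F_{i a'}|^2 / (e_a' - e_i)
#' with the complementary block pseudo-canonicalized.
#'
#' @param reference an [load_reference()] object.
#' @param complementary an [build_complementary()] object.
#' @param fock_joint optional precomputed [joint_fock()] result.
#' @return list(energy, n_comp).
#' @export
cabs_singles <- function(reference, complementary, fock_joint = NULL) {
  ref <- reference
  comp <- complementary
  if (comp$n_comp == 0) return(list(energy = 0, n_comp = 0L))
  if (is.null(fock_joint)) fock_joint <- joint_fock(ref, comp$joint_basis)
  Fj <- fock_joint$F
  nocc <- ref$n_occ
  Cocc <- rbind(ref$mo_coefficients[, seq_len(nocc), drop = FALSE],
                matrix(0, comp$joint_basis$n - ref$basis$n, nocc))
  Cc <- comp$coefficients
  Fcc <- crossprod(Cc, Fj %*% Cc)
  ev <- eigen((Fcc + t(Fcc)) / 2, symmetric = TRUE)
  Cct <- Cc %*% ev$vectors
  Foc <- crossprod(Cocc, Fj %*% Cct)       # nocc x ncomp
  eo <- ref$orbital_energies[seq_len(nocc)]
  den <- outer(eo, ev$values, `-`)         # e_i - e_a'
  list(energy = sum(Foc^2 / den), n_comp = comp$n_comp)
}
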