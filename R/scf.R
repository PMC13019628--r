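# Restricted Hartree-Fock reference provider and reference-state handling.
#
# The correlation machinery only consumes a converged spin-restricted
# reference through `load_reference()`; `hf_reference()` is the built-in
# provider (density-fitted closed-shell SCF with DIIS).

.sym_orth <- function(S, cutoff = 1e-9) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > cutoff * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
}

#' Density-fitted restricted Hartree-Fock
#'
#' Closed-shell SCF with DIIS acceleration; Coulomb and exchange are built
#' through the fitting basis.  Serves as the reference provider for the
#' correlation modules.
#'
#' @param mol a [molecule()].
#' @param basis orbital basis name or `lmf12_basis`.
#' @param aux fitting basis name or `lmf12_basis` (default derived from
#'   the orbital cardinal).
#' @param conv density RMS convergence threshold.
#' @param maxiter maximum SCF iterations.
#' @param verbose print iterations.
#' @return provider payload: list with `mo_coefficients`,
#'   `orbital_energies`, `fock_ao`, `overlap_ao`, `n_core`, `n_occ`,
#'   `nuclear_repulsion`, `hf_energy`, plus the molecule/basis objects.
#' @export
hf_reference <- function(mol, basis = "DZ", aux = NULL, conv = 1e-9,
                         maxiter = 120, verbose = FALSE) {
  bas <- if (inherits(basis, "lmf12_basis")) basis else build_basis(mol, basis)
  cardinal <- sub("^(RI-|CABS-)", "", bas$name)
  if (is.null(aux)) aux <- paste0("RI-", cardinal)
  auxb <- if (inherits(aux, "lmf12_basis")) aux else build_basis(mol, aux)
  if (mol$n_electrons %% 2 != 0)
    stop("restricted reference requires an even electron count")
  nocc <- mol$n_electrons / 2
  oe <- one_electron(bas)
  S <- oe$S; H <- oe$T + oe$V
  n <- nrow(S)
  metric <- build_metric(auxb)
  T3 <- three_center(bas, bas, auxb)
  U <- matrix(T3, n * n, dim(T3)[3])
  # fitted b tensor: (mu nu|Q)(L^-T), so (munu|lasi) ~ sum_Q b b
  B <- t(forwardsolve(metric$L, t(U[, metric$piv, drop = FALSE])))
  X <- .sym_orth(S)
  # initial guess: core Hamiltonian
  Ft <- crossprod(X, H %*% X)
  ev <- eigen(Ft, symmetric = TRUE)
  ord <- order(ev$values)
  C <- X %*% ev$vectors[, ord, drop = FALSE]
  Cocc <- C[, seq_len(nocc), drop = FALSE]
  D <- 2 * tcrossprod(Cocc)
  diis_F <- list(); diis_e <- list()
  Eold <- 0
  for (it in seq_len(maxiter)) {
    d <- as.numeric(crossprod(B, as.numeric(D)))
    Jm <- matrix(B %*% d, n, n)
    # exchange: K = sum_Q (B_Q C_occ)(B_Q C_occ)^T, over half density
    K <- matrix(0, n, n)
    for (q in seq_len(ncol(B))) {
      Bq <- matrix(B[, q], n, n)
      Mq <- Bq %*% Cocc
      K <- K + tcrossprod(Mq)
    }
    Fm <- H + Jm - K
    E <- 0.5 * sum(D * (H + Fm)) + mol$nuclear_repulsion
    err <- Fm %*% D %*% S - S %*% D %*% Fm
    err <- crossprod(X, err %*% X)
    if (verbose) message(sprintf("SCF %3d  E = %18.10f  |err| = %.2e",
                                 it, E, max(abs(err))))
    if (max(abs(err)) < conv && it > 1) break
    diis_F[[length(diis_F) + 1]] <- Fm
    diis_e[[length(diis_e) + 1]] <- err
    if (length(diis_F) > 8) { diis_F <- diis_F[-1]; diis_e <- diis_e[-1] }
    m <- length(diis_F)
    if (m > 1) {
      Bm <- matrix(0, m + 1, m + 1)
      for (a in 1:m) for (b in 1:m)
        Bm[a, b] <- sum(diis_e[[a]] * diis_e[[b]])
      Bm[m + 1, 1:m] <- Bm[1:m, m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      cw <- tryCatch(solve(Bm, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cw) && all(is.finite(cw))) {
        Fm <- Reduce(`+`, Map(`*`, diis_F, cw))
      }
    }
    Ft <- crossprod(X, Fm %*% X)
    ev <- eigen(Ft, symmetric = TRUE)
    ord <- order(ev$values)
    C <- X %*% ev$vectors[, ord, drop = FALSE]
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    D <- 2 * tcrossprod(Cocc)
    Eold <- E
  }
  # final canonical orbitals from the last (un-extrapolated) Fock
  d <- as.numeric(crossprod(B, as.numeric(D)))
  Jm <- matrix(B %*% d, n, n)
  K <- matrix(0, n, n)
  for (q in seq_len(ncol(B))) {
    Bq <- matrix(B[, q], n, n)
    Mq <- Bq %*% Cocc
    K <- K + tcrossprod(Mq)
  }
  Fm <- H + Jm - K
  Ft <- crossprod(X, Fm %*% X)
  ev <- eigen(Ft, symmetric = TRUE)
  ord <- order(ev$values)
  C <- X %*% ev$vectors[, ord, drop = FALSE]
  eps <- ev$values[ord]
  Cocc <- C[, seq_len(nocc), drop = FALSE]
  D <- 2 * tcrossprod(Cocc)
  E <- 0.5 * sum(D * (H + Fm)) + mol$nuclear_repulsion
  list(mo_coefficients = C, orbital_energies = eps, fock_ao = Fm,
       overlap_ao = S, hcore_ao = H,
       n_core = n_core_orbitals(mol), n_occ = nocc,
       nuclear_repulsion = mol$nuclear_repulsion, hf_energy = E,
       mol = mol, basis = bas, aux_basis = auxb, n_iter = it)
}

#' Validate and load a restricted reference
#'
#' Enforces the reference-state invariants: S-orthonormal MO coefficients,
#' consistent dimensions and counts.  Accepts any provider payload with
#' the documented fields.
#'
#' @param payload list with at least `mo_coefficients`,
#'   `orbital_energies`, `fock_ao`, `overlap_ao`, `n_core`, `n_occ`,
#'   `nuclear_repulsion`, `hf_energy`, and (for downstream integral work)
#'   `mol` and `basis`.
#' @param tol orthonormality rejection threshold.
#' @return an object of class `lmf12_reference`.
#' @export
load_reference <- function(payload, tol = 1e-6) {
  need <- c("mo_coefficients", "orbital_energies", "fock_ao", "overlap_ao",
            "n_core", "n_occ", "nuclear_repulsion", "hf_energy")
  miss <- setdiff(need, names(payload))
  if (length(miss)) stop("reference payload missing fields: ",
                         paste(miss, collapse = ", "))
  C <- payload$mo_coefficients
  S <- payload$overlap_ao
  nmo <- ncol(C)
  if (length(payload$orbital_energies) != nmo)
    stop("orbital_energies length does not match MO count")
  if (!(payload$n_core <= payload$n_occ && payload$n_occ <= nmo))
    stop("need n_core <= n_occ <= n_MO")
  orth <- crossprod(C, S %*% C) - diag(nmo)
  if (max(abs(orth)) > tol)
    stop(sprintf("MO coefficients not S-orthonormal: max |C'SC - 1| = %.2e",
                 max(abs(orth))))
  structure(payload, class = "lmf12_reference")
}

#' @export
print.lmf12_reference <- function(x, ...) {
  cat(sprintf("<lmf12_reference> %d MOs, %d occupied (%d core), E_HF = %.10f Eh\n",
              ncol(x$mo_coefficients), x$n_occ, x$n_core, x$hf_energy))
  invisible(x)
}

#' Semicanonicalize an orbital block
#'
#' Lowdin-orthonormalizes the given orbital block in the S metric
#' (dropping linearly dependent directions below `lindep`), then
#' diagonalizes the Fock matrix within the block.  Eigenvalue ties and
#' ordering are resolved by ascending pseudo-energy with ties broken by
#' original column index; signs are fixed by making the largest-magnitude
#' coefficient positive.
#'
#' @param block AO x k matrix of orbital coefficients.
#' @param fock_ao AO Fock matrix.
#' @param overlap_ao AO overlap matrix.
#' @param lindep metric eigenvalue drop threshold (relative).
#' @return list(coefficients, energies, n_dropped).
#' @export
semicanonicalize <- function(block, fock_ao, overlap_ao, lindep = 1e-7) {
  if (ncol(block) == 0)
    return(list(coefficients = block, energies = numeric(0), n_dropped = 0L))
  Sb <- crossprod(block, overlap_ao %*% block)
  e <- eigen(Sb, symmetric = TRUE)
  keep <- e$values > lindep * max(e$values)
  n_drop <- sum(!keep)
  Xb <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
  Bo <- block %*% Xb
  Fb <- crossprod(Bo, fock_ao %*% Bo)
  ev <- eigen((Fb + t(Fb)) / 2, symmetric = TRUE)
  ord <- order(ev$values)
  U <- ev$vectors[, ord, drop = FALSE]
  out <- Bo %*% U
  # deterministic sign fix
  for (k in seq_len(ncol(out))) {
    i <- which.max(abs(out[, k]))
    if (out[i, k] < 0) out[, k] <- -out[, k]
  }
  list(coefficients = out, energies = ev$values[ord], n_dropped = n_drop)
}
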