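# Boys localization of occupied orbitals and projected atomic orbitals.

#' Boys localization of an orbital block
#'
#' Maximizes the Boys objective sum_i |<i|r|i>|^2 by pairwise Jacobi
#' sweeps with analytic 2x2 rotations (row-major pair order, deterministic,
#' no random seed).  Converges when the largest rotation angle in a sweep
#' falls below `conv` radians; the objective is non-decreasing across
#' sweeps.
#'
#' @param block AO x k S-orthonormal orbital coefficients.
#' @param dipole list of three AO dipole matrices (DX, DY, DZ).
#' @param conv rotation-angle convergence threshold (radians).
#' @param max_sweeps hard sweep limit.
#' @return `lmf12_localized`: list(coefficients, boys_objective, n_sweeps,
#'   centroids).
#' @export
boys_localize <- function(block, dipole, conv = 1e-8, max_sweeps = 500) {
  k <- ncol(block)
  C <- block
  objective <- function(C) {
    s <- 0
    for (d in 1:3) s <- s + sum(diag(crossprod(C, dipole[[d]] %*% C))^2)
    s
  }
  trace <- numeric(0)
  if (k >= 2) {
    for (sweep in seq_len(max_sweeps)) {
      DC <- lapply(dipole, function(M) M %*% C)
      maxang <- 0
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        A <- 0; Bv <- 0
        for (d in 1:3) {
          dii <- sum(C[, i] * DC[[d]][, i])
          djj <- sum(C[, j] * DC[[d]][, j])
          dij <- sum(C[, i] * DC[[d]][, j])
          A <- A + dij^2 - 0.25 * (dii - djj)^2
          Bv <- Bv + dij * (dii - djj)
        }
        if (abs(A) < 1e-300 && abs(Bv) < 1e-300) next
        ang <- 0.25 * atan2(Bv, -A)
        if (abs(ang) < 1e-14) next
        cs <- cos(ang); sn <- sin(ang)
        ci <- C[, i]; cj <- C[, j]
        C[, i] <- cs * ci + sn * cj
        C[, j] <- -sn * ci + cs * cj
        for (d in 1:3) {
          di <- DC[[d]][, i]; dj <- DC[[d]][, j]
          DC[[d]][, i] <- cs * di + sn * dj
          DC[[d]][, j] <- -sn * di + cs * dj
        }
        maxang <- max(maxang, abs(ang))
      }
      trace <- c(trace, objective(C))
      if (maxang < conv) break
      if (sweep == max_sweeps)
        stop("Boys localization did not converge; objective trace: ",
             paste(sprintf("%.8f", utils::tail(trace, 5)), collapse = ", "))
    }
  }
  # deterministic sign fix
  for (m in seq_len(k)) {
    idx <- which.max(abs(C[, m]))
    if (C[idx, m] < 0) C[, m] <- -C[, m]
  }
  cent <- vapply(1:3, function(d) diag(crossprod(C, dipole[[d]] %*% C)),
                 numeric(k))
  if (k == 1) cent <- matrix(cent, 1, 3)
  structure(list(coefficients = C, boys_objective = objective(C),
                 n_sweeps = length(trace), centroids = cent),
            class = "lmf12_localized")
}

#' Localize core and valence occupied orbitals separately
#'
#' Core and correlated (valence) occupied MOs are localized in two
#' independent Boys procedures so that their spans remain disjoint and the
#' union spans the full occupied space.
#'
#' @param reference an [load_reference()] object.
#' @param dipole optional precomputed AO dipole matrices.
#' @return list(core, valence): two [boys_localize()] results (the core
#'   set may have zero columns).
#' @export
localize_core_and_valence <- function(reference, dipole = NULL) {
  if (is.null(dipole)) {
    oe <- one_electron(reference$basis)
    dipole <- list(oe$DX, oe$DY, oe$DZ)
  }
  C <- reference$mo_coefficients
  ncore <- reference$n_core; nocc <- reference$n_occ
  core_block <- C[, seq_len(ncore), drop = FALSE]
  val_block <- C[, setdiff(seq_len(nocc), seq_len(ncore)), drop = FALSE]
  list(core = boys_localize(core_block, dipole),
       valence = boys_localize(val_block, dipole))
}

#' Construct projected atomic orbitals
#'
#' One PAO per AO: p_mu = (1 - sum_i |i><i| S) chi_mu, exactly orthogonal
#' to the occupied space; PAOs with S-norm below `drop` are discarded.
#'
#' @param reference an [load_reference()] object.
#' @param drop S-norm drop threshold.
#' @return `lmf12_paos`: list(coefficients, parent_atom, norms).
#' @export
build_paos <- function(reference, drop = 1e-8) {
  C <- reference$mo_coefficients
  S <- reference$overlap_ao
  occ <- C[, seq_len(reference$n_occ), drop = FALSE]
  n <- nrow(S)
  P <- diag(n) - occ %*% crossprod(occ, S)
  norms <- sqrt(pmax(0, diag(crossprod(P, S %*% P))))
  keep <- norms > drop
  structure(list(coefficients = P[, keep, drop = FALSE],
                 parent_atom = reference$basis$atom_of_ao[keep],
                 norms = norms[keep]),
            class = "lmf12_paos")
}

#' @export
print.lmf12_paos <- function(x, ...) {
  cat(sprintf("<lmf12_paos> %d PAOs on %d atoms\n", ncol(x$coefficients),
              length(unique(x$parent_atom))))
  invisible(x)
}
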