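# Boughton-Pulay atom lists, primary/extended domains, pair classification.

#' Domain construction thresholds
#'
#' Completeness thresholds of the modified Boughton-Pulay domain scheme
#' and the strong-pair energy threshold.  Defaults: T_PDo = 0.999,
#' T_PDv = 0.98 (primary domains), T_EDo = 0.9999, T_o = 0.985 (extended
#' domains / PAO-center domains), T_trf = 0.99999 (LMO truncation at the
#' integral transformation), eps_w = 1e-5 hartree (strong pairs), CABS
#' domain = BPEDo of the central MO.
#'
#' @param T_PDo,T_PDv,T_EDo,T_o,T_trf BP completeness thresholds in (0,1).
#' @param eps_w strong-pair threshold (hartree).
#' @param cabs_domain one of "BPEDo", "ED", "PCD", "BPo".
#' @param cd_threshold Cholesky residual threshold for the denominator
#'   factorization (1/hartree).
#' @param overlap_policy treatment of pairs whose primary domains share
#'   atoms: "evaluate" (default) computes the pair-domain energy exactly;
#'   "strong" classifies them as strong outright (their pair energies are
#'   orders of magnitude above eps_w at any bonded geometry), which is
#'   the economical choice for large scaling audits.
#' @return `lmf12_domain_config`.
#' @export
domain_config <- function(T_PDo = 0.999, T_PDv = 0.98, T_EDo = 0.9999,
                          T_o = 0.985, T_trf = 0.99999, eps_w = 1e-5,
                          cabs_domain = c("BPEDo", "ED", "PCD", "BPo"),
                          cd_threshold = 1e-4,
                          overlap_policy = c("evaluate", "strong")) {
  cabs_domain <- match.arg(cabs_domain)
  overlap_policy <- match.arg(overlap_policy)
  th <- c(T_PDo = T_PDo, T_PDv = T_PDv, T_EDo = T_EDo, T_o = T_o, T_trf = T_trf)
  if (any(th <= 0 | th >= 1))
    stop("all BP completeness thresholds must lie strictly in (0, 1)")
  if (!(T_trf > T_EDo && T_EDo > T_PDo))
    stop("need T_trf > T_EDo > T_PDo")
  if (eps_w < 0) stop("eps_w must be non-negative")
  structure(list(T_PDo = T_PDo, T_PDv = T_PDv, T_EDo = T_EDo, T_o = T_o,
                 T_trf = T_trf, eps_w = eps_w, cabs_domain = cabs_domain,
                 cd_threshold = cd_threshold, overlap_policy = overlap_policy),
            class = "lmf12_domain_config")
}

#' Boughton-Pulay atom list of one orbital
#'
#' Greedy growth over atoms ranked by descending Lowdin population (ties
#' by atom index); an atom list is complete once the squared S-norm of the
#' least-squares projection of the orbital onto the listed atoms' AOs
#' reaches the threshold T.
#'
#' @param coef AO coefficient vector of an S-normalized orbital.
#' @param overlap AO overlap matrix.
#' @param atom_of_ao atom index per AO.
#' @param T completeness threshold.
#' @param S_half optional precomputed S^(1/2) for the Lowdin ranking.
#' @return list(atoms, completeness, reached) - `reached` is FALSE when
#'   even the full atom list stays below T (numerical fallback).
#' @export
bp_atom_list <- function(coef, overlap, atom_of_ao, T, S_half = NULL) {
  if (is.null(S_half)) {
    e <- eigen(overlap, symmetric = TRUE)
    S_half <- e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
  }
  w <- as.numeric(S_half %*% coef)^2
  pop <- vapply(split(w, atom_of_ao), sum, 0)
  atoms_ranked <- as.integer(names(pop))[order(-pop, as.integer(names(pop)))]
  Sc <- as.numeric(overlap %*% coef)
  comp <- function(atoms) {
    idx <- which(atom_of_ao %in% atoms)
    b <- Sc[idx]
    Skk <- overlap[idx, idx, drop = FALSE]
    as.numeric(crossprod(b, solve(Skk, b)))
  }
  sel <- integer(0); last <- 0
  for (a in atoms_ranked) {
    sel <- c(sel, a)
    last <- comp(sel)
    if (last >= T) break
  }
  list(atoms = sort(sel), completeness = last, reached = last >= T)
}

# BP lists for all columns of a coefficient matrix
.bp_lists <- function(C, overlap, atom_of_ao, T, S_half) {
  lapply(seq_len(ncol(C)), function(k)
    bp_atom_list(C[, k], overlap, atom_of_ao, T, S_half))
}

# Project the in-domain components of the occupied space out of a block of
# domain-truncated virtual candidates.  The occupied coefficients are first
# truncated to the domain AOs (keeping the block inside the domain span),
# orthonormalized with a linear-dependence drop, and then projected out.
.project_out_occ <- function(Cp, C_occ_all, ao_idx, overlap_ao) {
  if (is.null(C_occ_all) || ncol(Cp) == 0) return(Cp)
  Od <- C_occ_all
  Od[-ao_idx, ] <- 0
  So <- crossprod(Od, overlap_ao %*% Od)
  e <- eigen((So + t(So)) / 2, symmetric = TRUE)
  # only occupied orbitals with genuine in-domain weight; projecting the
  # tiny tails of distant occupieds would annihilate valid virtual
  # directions of small domains
  keep <- e$values > 1e-2 * max(e$values)
  X <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
  Oo <- Od %*% X
  Cp - Oo %*% crossprod(Oo, overlap_ao %*% Cp)
}

# ---------------------------------------------------------------- PDs

#' Assemble the primary domain of one LMO
#'
#' PD atoms are the union of the LMO's BPPDo list and the BPPDv lists of
#' the PAOs centered on those atoms; the PAOs are truncated to the PD
#' atoms, orthogonalized against the LMO and each other, and
#' canonicalized.
#'
#' @param lmo_idx index of the LMO in `C_lmo`.
#' @param C_lmo AO x nLMO localized valence coefficients.
#' @param bp_pdo BP lists (threshold T_PDo) of the LMOs.
#' @param paos [build_paos()] object.
#' @param bp_pdv BP lists (threshold T_PDv) of the normalized PAOs.
#' @param fock_ao,overlap_ao AO matrices.
#' @param atom_of_ao atom index per AO.
#' @param C_occ_all full occupied coefficients (core + valence); their
#'   in-domain components are projected out of the truncated PAOs so that
#'   domain truncation cannot reintroduce occupied character.
#' @return `lmf12_pd`: atoms, pao ids, canonical local virtuals with
#'   pseudo-energies, LMO diagonal Fock element.
#' @export
assemble_primary_domain <- function(lmo_idx, C_lmo, bp_pdo, paos, bp_pdv,
                                    fock_ao, overlap_ao, atom_of_ao,
                                    C_occ_all = NULL) {
  atoms0 <- bp_pdo[[lmo_idx]]$atoms
  pao_sel <- which(paos$parent_atom %in% atoms0)
  atoms <- sort(unique(c(atoms0, unlist(lapply(pao_sel, function(p)
    bp_pdv[[p]]$atoms)))))
  ao_idx <- which(atom_of_ao %in% atoms)
  Cp <- paos$coefficients[, pao_sel, drop = FALSE]
  Cp[-ao_idx, ] <- 0
  lmo <- C_lmo[, lmo_idx]
  # orthogonalize against the LMO and the in-domain occupied components,
  # then among themselves, then canonicalize
  Cp <- Cp - lmo %*% crossprod(lmo, overlap_ao %*% Cp)
  Cp <- .project_out_occ(Cp, C_occ_all, ao_idx, overlap_ao)
  # 1e-4 redundancy cutoff: truncated PAOs are strongly redundant and
  # near-null directions amplify residual occupied tails
  sc <- semicanonicalize(Cp, fock_ao, overlap_ao, lindep = 1e-4)
  if (ncol(sc$coefficients) == 0)
    warning("degenerate primary domain: empty virtual space for LMO ", lmo_idx)
  structure(list(lmo = lmo_idx, atoms = atoms, pao_ids = pao_sel,
                 C_virt = sc$coefficients, eps_virt = sc$energies,
                 f_ii = as.numeric(crossprod(lmo, fock_ao %*% lmo))),
            class = "lmf12_pd")
}

# -------------------------------------------------- pair energy estimates

#' Multipole (dipole-dipole) opposite-spin pair energy estimate
#'
#' Leading-order multipole approximation of the opposite-spin MP2 pair
#' energy between two non-overlapping primary domains; always <= 0.
#'
#' @param pd_i,pd_j [assemble_primary_domain()] results.
#' @param C_lmo localized valence coefficients.
#' @param dipole list of three AO dipole matrices.
#' @return estimate in hartree.
#' @export
pair_energy_multipole <- function(pd_i, pd_j, C_lmo, dipole) {
  li <- C_lmo[, pd_i$lmo]; lj <- C_lmo[, pd_j$lmo]
  mu_i <- vapply(dipole, function(M) as.numeric(crossprod(pd_i$C_virt, M %*% li)),
                 numeric(ncol(pd_i$C_virt)))
  mu_j <- vapply(dipole, function(M) as.numeric(crossprod(pd_j$C_virt, M %*% lj)),
                 numeric(ncol(pd_j$C_virt)))
  if (ncol(pd_i$C_virt) == 1) mu_i <- matrix(mu_i, 1)
  if (ncol(pd_j$C_virt) == 1) mu_j <- matrix(mu_j, 1)
  ci <- vapply(dipole, function(M) sum(li * (M %*% li)), 0)
  cj <- vapply(dipole, function(M) sum(lj * (M %*% lj)), 0)
  Rv <- cj - ci
  R <- sqrt(sum(Rv^2))
  Rh <- Rv / R
  pi_r <- as.numeric(mu_i %*% Rh)
  pj_r <- as.numeric(mu_j %*% Rh)
  Tm <- (mu_i %*% t(mu_j) - 3 * outer(pi_r, pj_r)) / R^3
  D <- pd_i$f_ii + pd_j$f_ii - outer(pd_i$eps_virt, pd_j$eps_virt, `+`)
  2 * sum(Tm^2 / D)
}

#' Pair-domain opposite-spin MP2 energy
#'
#' Exact evaluation of the opposite-spin pair energy of LMOs i and j in
#' the union of their primary domains, through local density fitting and
#' the Cholesky denominator factorization.
#'
#' @param pd_i,pd_j primary domains.
#' @param C_lmo localized valence coefficients.
#' @param basis,aux_basis AO and fitting bases.
#' @param fock_ao,overlap_ao AO matrices.
#' @param cd_threshold denominator Cholesky residual threshold.
#' @return energy in hartree (<= 0); zero with a warning when the pair
#'   domain has no virtual space.
#' @export
pair_domain_mp2 <- function(pd_i, pd_j, C_lmo, basis, aux_basis,
                            fock_ao, overlap_ao, cd_threshold = 1e-4,
                            C_occ_all = NULL, prep_cache = NULL) {
  if (pd_i$lmo == pd_j$lmo) stop("pair energies require i != j")
  atom_of_ao <- basis$atom_of_ao
  atoms <- sort(union(pd_i$atoms, pd_j$atoms))
  ao_idx <- which(atom_of_ao %in% atoms)
  aux_idx <- which(aux_basis$atom_of_ao %in% atoms)
  li <- C_lmo[, pd_i$lmo]; lj <- C_lmo[, pd_j$lmo]
  Cv <- cbind(pd_i$C_virt, pd_j$C_virt)
  occ2 <- cbind(li, lj)
  Cv <- Cv - occ2 %*% crossprod(occ2, overlap_ao %*% Cv)
  Cv <- .project_out_occ(Cv, C_occ_all, ao_idx, overlap_ao)
  sc <- semicanonicalize(Cv, fock_ao, overlap_ao, lindep = 1e-4)
  if (ncol(sc$coefficients) == 0) {
    warning("empty pair-domain virtual space")
    return(0)
  }
  # metric and three-center integrals depend only on the atom set; reuse
  # them across pairs sharing the same union domain
  key <- paste(atoms, collapse = ",")
  prep <- if (!is.null(prep_cache)) prep_cache[[key]] else NULL
  if (is.null(prep)) {
    bsub <- subset_basis(basis, ao_idx)
    asub <- subset_basis(aux_basis, aux_idx)
    metric <- build_metric(asub)
    T3 <- three_center(bsub, bsub, asub)
    prep <- list(metric = metric, T3 = T3)
    if (!is.null(prep_cache)) prep_cache[[key]] <- prep
  }
  metric <- prep$metric; T3 <- prep$T3
  Cva <- sc$coefficients[ao_idx, , drop = FALSE]
  Coa <- occ2[ao_idx, , drop = FALSE]
  Tm <- .transform_3c(T3, Cva, Coa)
  J <- fit_J(Tm, metric)
  nv <- ncol(Cva)
  Jarr <- array(J, c(nv, 2, ncol(J)))
  fii <- pd_i$f_ii; fjj <- pd_j$f_ii
  ev <- sc$energies
  g <- tcrossprod(Jarr[, 1, ], Jarr[, 2, ])     # (a i | b j)
  om <- cd_denominator(c(ev - fii, ev - fjj), cd_threshold)
  t <- matrix(0, nv, nv)
  for (w in seq_len(om$n_omega)) {
    e1 <- om$vectors[seq_len(nv), w]
    e2 <- om$vectors[nv + seq_len(nv), w]
    t <- t - (Jarr[, 1, ] * e1) %*% t(Jarr[, 2, ] * e2)
  }
  2 * sum(g * t)
}

#' Estimate and classify all LMO pairs
#'
#' Every pair receives the dipole-dipole multipole pair-energy estimate,
#' which decides the strong/distant class at eps_w.  The multipole form
#' is invalid for interpenetrating orbital distributions: pairs whose
#' primary domains share atoms AND whose centroids are closer than 5 bohr
#' (plus any pair with a degenerate centroid separation) fall back to the
#' exact pair-domain evaluation.
#'
#' @param pds list of primary domains (one per valence LMO).
#' @param C_lmo localized valence coefficients.
#' @param dipole AO dipole matrices.
#' @param basis,aux_basis,fock_ao,overlap_ao integral inputs for the
#'   pair-domain fallback.
#' @param config [domain_config()].
#' @return `lmf12_pairs`: data.frame (i, j, estimate, method, class) over
#'   unordered pairs i < j.
#' @export
classify_pairs <- function(pds, C_lmo, dipole, basis, aux_basis,
                           fock_ao, overlap_ao, config = domain_config(),
                           C_occ_all = NULL) {
  n <- length(pds)
  out <- NULL
  prep_cache <- new.env(parent = emptyenv())
  cents <- vapply(seq_len(n), function(k) {
    lk <- C_lmo[, pds[[k]]$lmo]
    vapply(dipole, function(M) sum(lk * (M %*% lk)), 0)
  }, numeric(3))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      overlapping <- length(intersect(pds[[i]]$atoms, pds[[j]]$atoms)) > 0
      est <- pair_energy_multipole(pds[[i]], pds[[j]], C_lmo, dipole)
      meth <- "multipole"
      if (overlapping) {
        Rij <- sqrt(sum((cents[, i] - cents[, j])^2))
        if (config$overlap_policy == "strong") {
          est <- NA_real_; meth <- "pd_overlap"
        } else if (!is.finite(est) || Rij < 5) {
          # interpenetrating distributions: the multipole form is invalid
          est <- pair_domain_mp2(pds[[i]], pds[[j]], C_lmo, basis, aux_basis,
                                 fock_ao, overlap_ao, config$cd_threshold,
                                 C_occ_all, prep_cache)
          meth <- "pair_domain"
        } else {
          # domain overlap is incidental at this separation
          meth <- "multipole_overlap"
        }
      }
      out <- rbind(out, data.frame(i = i, j = j, estimate = est, method = meth))
    }
  }
  if (is.null(out))
    out <- data.frame(i = integer(0), j = integer(0), estimate = numeric(0),
                      method = character(0))
  out$class <- ifelse(is.na(out$estimate) | abs(out$estimate) >= config$eps_w,
                      "strong", "distant")
  class(out) <- c("lmf12_pairs", class(out))
  out
}

# ---------------------------------------------------------------- EDs

#' Assemble the extended domain of one central MO
#'
#' The ED's occupied space holds the CMO and its strong-pair partners
#' (truncated to their BPtrf-within-ED atom lists, Lowdin orthonormalized
#' and canonicalized); core LMOs are included when their full BPEDo list
#' is covered by the ED; virtuals are the PAOs of the PAO-center domain
#' truncated to the ED, orthogonalized against the ED occupied space and
#' canonicalized.  Fitting functions live on the PCD atoms, the CABS
#' domain is chosen per configuration.
#'
#' @param cmo central (valence) LMO index.
#' @param pairs [classify_pairs()] result.
#' @param C_lmo,C_core valence/core localized coefficients.
#' @param bp lists: `edo` (valence BPEDo), `o` (BPo), `trf` (BPtrf),
#'   `core_edo` (core BPEDo).
#' @param paos [build_paos()] object.
#' @param basis AO basis; `aux_basis` fitting basis.
#' @param fock_ao,overlap_ao AO matrices.
#' @param config [domain_config()].
#' @return `lmf12_ed`.
#' @export
assemble_extended_domain <- function(cmo, pairs, C_lmo, C_core, bp, paos,
                                     basis, aux_basis, fock_ao, overlap_ao,
                                     config = domain_config(),
                                     C_occ_all = NULL) {
  atom_of_ao <- basis$atom_of_ao
  partners <- sort(unique(c(pairs$j[pairs$i == cmo & pairs$class == "strong"],
                            pairs$i[pairs$j == cmo & pairs$class == "strong"])))
  occ_lmos <- sort(unique(c(cmo, partners)))
  atoms <- sort(unique(unlist(lapply(occ_lmos, function(k) bp$edo[[k]]$atoms))))
  pcd_atoms <- sort(unique(unlist(lapply(occ_lmos, function(k) bp$o[[k]]$atoms))))
  ao_idx <- which(atom_of_ao %in% atoms)
  # core LMOs whose entire BPEDo list is covered by the ED
  core_lmos <- integer(0)
  if (!is.null(C_core) && ncol(C_core) > 0) {
    core_lmos <- which(vapply(seq_len(ncol(C_core)), function(k)
      all(bp$core_edo[[k]]$atoms %in% atoms), TRUE))
  }
  # valence LMOs truncated to BPtrf within the ED, renormalized
  Cval <- C_lmo[, occ_lmos, drop = FALSE]
  for (m in seq_along(occ_lmos)) {
    keep_atoms <- intersect(bp$trf[[occ_lmos[m]]]$atoms, atoms)
    Cval[!(atom_of_ao %in% keep_atoms), m] <- 0
    nrm <- sqrt(as.numeric(crossprod(Cval[, m], overlap_ao %*% Cval[, m])))
    Cval[, m] <- Cval[, m] / nrm
  }
  lowdin <- function(V, cutoff = 1e-7) {
    if (ncol(V) == 0) return(list(C = V, X = matrix(0, 0, 0)))
    Sv <- crossprod(V, overlap_ao %*% V)
    e <- eigen((Sv + t(Sv)) / 2, symmetric = TRUE)
    keep <- e$values > cutoff * max(e$values)
    X <- e$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(e$values[keep]), sum(keep))
    # symmetric orthogonalization (stay close to the truncated LMOs)
    Xs <- X %*% t(e$vectors[, keep, drop = FALSE])
    list(C = V %*% Xs, X = Xs)
  }
  lv <- lowdin(Cval)
  Cval_lo <- lv$C
  # canonicalize: orthogonal rotation on top of the Lowdin set
  Fb <- crossprod(Cval_lo, fock_ao %*% Cval_lo)
  evv <- eigen((Fb + t(Fb)) / 2, symmetric = TRUE)
  ordv <- order(evv$values)
  rot_occ <- evv$vectors[, ordv, drop = FALSE]
  Cval_pc <- Cval_lo %*% rot_occ
  eps_occ <- evv$values[ordv]
  # core block: truncate to BPEDo, project out valence, orthonormalize
  Ccore_lo <- matrix(0, nrow(C_lmo), 0)
  if (length(core_lmos)) {
    Cc <- C_core[, core_lmos, drop = FALSE]
    for (m in seq_along(core_lmos)) {
      keep_atoms <- bp$core_edo[[core_lmos[m]]]$atoms
      Cc[!(atom_of_ao %in% keep_atoms), m] <- 0
      nrm <- sqrt(as.numeric(crossprod(Cc[, m], overlap_ao %*% Cc[, m])))
      Cc[, m] <- Cc[, m] / nrm
    }
    Cc <- Cc - Cval_lo %*% crossprod(Cval_lo, overlap_ao %*% Cc)
    Ccore_lo <- lowdin(Cc)$C
  }
  # ED virtuals: PAOs of the PCD atoms truncated to the ED AO list
  pao_sel <- which(paos$parent_atom %in% pcd_atoms)
  Cp <- paos$coefficients[, pao_sel, drop = FALSE]
  Cp[-ao_idx, ] <- 0
  occ_all <- cbind(Ccore_lo, Cval_lo)
  if (ncol(occ_all))
    Cp <- Cp - occ_all %*% crossprod(occ_all, overlap_ao %*% Cp)
  Cp <- .project_out_occ(Cp, C_occ_all, ao_idx, overlap_ao)
  scv <- semicanonicalize(Cp, fock_ao, overlap_ao, lindep = 1e-4)
  if (ncol(scv$coefficients) == 0)
    stop("extended domain of LMO ", cmo, " has a null virtual space")
  fit_idx <- which(aux_basis$atom_of_ao %in% pcd_atoms)
  cabs_atoms <- switch(config$cabs_domain,
                       ED = atoms, PCD = pcd_atoms,
                       BPEDo = bp$edo[[cmo]]$atoms,
                       BPo = bp$o[[cmo]]$atoms)
  structure(list(cmo = cmo, occ_lmos = occ_lmos, core_lmos = core_lmos,
                 atoms = atoms, ao_idx = ao_idx, pcd_atoms = pcd_atoms,
                 cabs_atoms = cabs_atoms, fit_idx = fit_idx,
                 C_occ_lo = Cval_lo, rot_occ = rot_occ, C_occ_pc = Cval_pc,
                 eps_occ = eps_occ, C_core_lo = Ccore_lo,
                 C_virt = scv$coefficients, eps_virt = scv$energies,
                 cmo_local = match(cmo, occ_lmos)),
            class = "lmf12_ed")
}

#' @export
print.lmf12_ed <- function(x, ...) {
  cat(sprintf("<lmf12_ed> CMO %d: %d atoms, %d occ (+%d core), %d virt, %d AO\n",
              x$cmo, length(x$atoms), length(x$occ_lmos), length(x$core_lmos),
              ncol(x$C_virt), length(x$ao_idx)))
  invisible(x)
}
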