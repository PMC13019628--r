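# Explicitly correlated (F12) intermediates: ansatz 2B with fixed geminal
# amplitudes, the F+K commutator treatment of B, and the coupling
# intermediate C.
#
# Working equations (derived from the closed-shell Hylleraas functional
# with the rational fixed-amplitude generator 3/8 + 1/8 P12; the weights
# reproduce the printed coupling pattern (1/16)[40, -8, 7, 1] exactly):
#   per pair (i <= j), energy = sum 1/(1+delta_ij) (B - X + C + V) with
#   V_ij = (5/2) V_d - (1/2) V_x,         V_d = <ij|f Q g|ij>, V_x = <ij|f Q g|ji>
#   B_ij = (7/16) B_d + (1/16) B_x,       B   = <.|f Q (F1+F2) Q f|.>
#   X_ij = sum_k f_ik [ (7/16) X_{ij,kj} + (1/16) X_{ij,jk} ]
#        +       f_jk [ (7/16) X_{ij,ik} + (1/16) X_{ij,ki} ],  X = <.|f Q f|.>
#   C_ij = (1/16) sum_ab [40 (ai|bj) - 8 (aj|bi) + 7 R_ij + R_ji] r_ij
# The ansatz-2B projector Q12 = (1-o1)(1-o2) - v1v2 is applied by
# resolution in the RI (MO + complementary) orbital space.

# ------------------------------------------------------------------ context

#' Assemble the canonical F12 integral context
#'
#' Builds everything the F12 intermediates need over the whole molecule:
#' the complementary space, the joint Fock matrix, RI-orbital Fock and
#' exchange matrices, and robust-fitted three-index coefficients of the
#' five two-electron operators.
#'
#' @param reference an [load_reference()] object.
#' @param geminal an [make_geminal()]; default chosen from the basis
#'   cardinal.
#' @param complementary optional [build_complementary()] result.
#' @param fock_joint optional [joint_fock()] result.
#' @param freeze_core freeze core orbitals in the pair list.
#' @return `lmf12_f12_context`.
#' @export
f12_context <- function(reference, geminal = NULL, complementary = NULL,
                        fock_joint = NULL, freeze_core = TRUE) {
  ref <- reference
  cardinal <- sub("^(RI-|CABS-)", "", ref$basis$name)
  if (is.null(geminal)) geminal <- make_geminal(cardinal)
  if (is.null(complementary)) complementary <- build_complementary(ref)
  if (is.null(fock_joint)) fock_joint <- joint_fock(ref, complementary$joint_basis)
  joint <- complementary$joint_basis
  nao <- ref$basis$n
  nmo <- ncol(ref$mo_coefficients)
  nocc <- ref$n_occ
  C_mo_j <- rbind(ref$mo_coefficients, matrix(0, joint$n - nao, nmo))
  C_RI <- cbind(C_mo_j, complementary$coefficients)
  nri <- ncol(C_RI)
  occ_pos <- seq_len(nocc)
  virt_pos <- (nocc + 1):nmo
  comp_pos <- if (nri > nmo) (nmo + 1):nri else integer(0)
  act_pos <- if (freeze_core) setdiff(occ_pos, seq_len(ref$n_core)) else occ_pos
  F_RI <- crossprod(C_RI, fock_joint$F %*% C_RI)
  aux <- ref$aux_basis
  metric <- build_metric(aux)
  Cocc_ao <- ref$mo_coefficients[, occ_pos, drop = FALSE]
  # three-center tensors: joint-row operators and AO-row operators
  ops_j <- c("coulomb", "f12", "f12_squared")
  Jb <- list(); Kb <- list()
  for (op in ops_j) {
    T3 <- three_center(joint, ref$basis, aux, op, geminal)
    Tm <- .transform_3c(T3, C_RI, Cocc_ao)       # (q', i, P)
    Um <- matrix(Tm, nri * nocc, dim(Tm)[3])
    if (op == "coulomb") {
      Jb$coulomb <- fit_J(Um, metric)
    } else {
      V2 <- two_center(aux, aux, op, geminal)
      Kb[[op]] <- fit_K(Um, V2, Jb$coulomb, metric)
    }
  }
  ops_o <- c("f12_over_r12", "grad_f12_squared")
  Joo <- list(); Koo <- list()
  # occ-occ rows are a subset of the (RI, occ) rows: reuse
  sel_oo <- as.numeric(outer(occ_pos, (seq_len(nocc) - 1) * nri, `+`))
  Joo$coulomb <- Jb$coulomb[sel_oo, , drop = FALSE]
  Koo$f12 <- Kb$f12[sel_oo, , drop = FALSE]
  Koo$f12_squared <- Kb$f12_squared[sel_oo, , drop = FALSE]
  for (op in ops_o) {
    T3 <- three_center(ref$basis, ref$basis, aux, op, geminal)
    Tm <- .transform_3c(T3, Cocc_ao, Cocc_ao)
    Um <- matrix(Tm, nocc * nocc, dim(Tm)[3])
    V2 <- two_center(aux, aux, op, geminal)
    Koo[[op]] <- fit_K(Um, V2, Joo$coulomb, metric)
  }
  # exchange matrix over RI orbitals from the Coulomb fits
  Jarr <- array(Jb$coulomb, c(nri, nocc, ncol(Jb$coulomb)))
  kRI <- matrix(0, nri, nri)
  for (m in seq_len(nocc)) kRI <- kRI + tcrossprod(Jarr[, m, ])
  # ansatz-2B complement-projector weights over RI pairs
  wP <- matrix(0, nri, nri)
  wP[occ_pos, ] <- 1; wP[, occ_pos] <- 1
  wP[virt_pos, virt_pos] <- 1
  structure(list(ref = ref, geminal = geminal, complementary = complementary,
                 fock_joint = fock_joint, C_RI = C_RI, F_RI = F_RI, kRI = kRI,
                 metric = metric, J = Jarr,
                 Kf = array(Kb$f12, c(nri, nocc, ncol(Jb$coulomb))),
                 Kf2 = array(Kb$f12_squared, c(nri, nocc, ncol(Jb$coulomb))),
                 Joo = array(Joo$coulomb, c(nocc, nocc, ncol(Jb$coulomb))),
                 Kfr_oo = array(Koo$f12_over_r12, c(nocc, nocc, ncol(Jb$coulomb))),
                 Kgr_oo = array(Koo$grad_f12_squared, c(nocc, nocc, ncol(Jb$coulomb))),
                 Kf_oo = array(Koo$f12, c(nocc, nocc, ncol(Jb$coulomb))),
                 Kf2_oo = array(Koo$f12_squared, c(nocc, nocc, ncol(Jb$coulomb))),
                 occ_pos = occ_pos, act_pos = act_pos, virt_pos = virt_pos,
                 comp_pos = comp_pos, wP = wP, nri = nri,
                 eps = ref$orbital_energies),
            class = "lmf12_f12_context")
}

# pair matrices over the RI space:
#   Omega^{ij} = <ij|f12|p'q'>, Gamma^{ij} = <ij|1/r12|p'q'>,
#   Phi^{ij}   = <ij|f12^2|p'q'>
.pair_mat <- function(ctx, i, j, kind = c("f12", "coulomb", "f12_squared")) {
  kind <- match.arg(kind)
  Ji <- ctx$J[, i, ]; Jj <- ctx$J[, j, ]
  switch(kind,
         coulomb = tcrossprod(Ji, Jj),
         f12 = tcrossprod(Ji, ctx$Kf[, j, ]) + tcrossprod(ctx$Kf[, i, ], Jj),
         f12_squared = tcrossprod(Ji, ctx$Kf2[, j, ]) +
           tcrossprod(ctx$Kf2[, i, ], Jj))
}

# robust-fitted occ-occ four-index element <ij|op|kl> = (ik|op|jl)
.oo_elem <- function(ctx, op, i, j, k, l) {
  Jik <- ctx$Joo[i, k, ]; Jjl <- ctx$Joo[j, l, ]
  Kb <- switch(op, f12 = ctx$Kf_oo, f12_squared = ctx$Kf2_oo,
               f12_over_r12 = ctx$Kfr_oo, grad_f12_squared = ctx$Kgr_oo)
  sum(Jik * Kb[j, l, ]) + sum(Kb[i, k, ] * Jjl)
}

# <ij| f Q op |kl> with Q resolved in the RI space
.fQ_elem <- function(ctx, Om_ij, ket_mat, lead) {
  lead - sum((ctx$wP * Om_ij) * ket_mat)
}

# ---------------------------------------------------------------- B matrix

# unsymmetrized B element <ij| f Q (F1+F2) Q f |kl> (approximation C:
# [F+K, f] = [T, f], exchange part resolved in RI)
.B_raw <- function(ctx, i, j, k, l, Om, Phi) {
  Omij <- Om[[paste(i, j)]]; Omkl <- Om[[paste(k, l)]]
  Phij <- Phi[[paste(i, j)]]
  F <- ctx$F_RI; kx <- ctx$kRI; wP <- ctx$wP
  pk <- ctx$occ_pos[k]; pl <- ctx$occ_pos[l]
  M <- F + kx
  su <- function(A, B) sum(A * B)
  T1 <- .oo_elem(ctx, "grad_f12_squared", i, j, k, l)
  T2 <- sum(Phij[, pl] * M[, pk]) + sum(Phij[pk, ] * M[, pl])
  T3 <- -su(crossprod(kx, Omij), Omkl) - su(Omij %*% kx, Omkl)
  Akl <- wP * Omkl
  T4 <- -2 * su(F %*% Omij + Omij %*% F, Akl)
  Aij <- wP * Omij
  T5 <- su(F %*% Aij, Akl) + su(Aij %*% F, Akl)
  T1 + T2 + T3 + T4 + T5
}

# ------------------------------------------------------- canonical C / R

#' Fock-transformed geminal tensor R (coupling intermediate)
#'
#' R_ij^{ab} = sum_{a'} f_{a a'} (a'i|f12|bj) + sum_{b'} f_{b b'} (ai|f12|b'j)
#' with a', b' running over the complementary space.
#'
#' @param ctx an [f12_context()].
#' @param i,j occupied orbital indices.
#' @return virt x virt matrix.
#' @export
compute_R <- function(ctx, i, j) {
  Om <- .pair_mat(ctx, i, j, "f12")
  v <- ctx$virt_pos; cp <- ctx$comp_pos
  if (!length(cp)) return(matrix(0, length(v), length(v)))
  Fvc <- ctx$F_RI[v, cp, drop = FALSE]
  Fvc %*% Om[cp, v, drop = FALSE] + Om[v, cp, drop = FALSE] %*% t(Fvc)
}

#' Canonical coupling intermediate C
#'
#' Contracts the conventional and Fock-transformed geminal amplitudes with
#' the fixed-amplitude coefficient pattern (1/16)[40, -8, 7, 1] and the
#' canonical denominators r = R / D.
#'
#' @param ctx an [f12_context()].
#' @param i,j occupied orbital indices.
#' @return scalar C_ij in hartree.
#' @export
compute_C_canonical <- function(ctx, i, j) {
  v <- ctx$virt_pos
  R <- compute_R(ctx, i, j)
  Rt <- compute_R(ctx, j, i)                                 # R_ji^{ab}
  G <- .pair_mat(ctx, i, j, "coulomb")[v, v, drop = FALSE]   # (ai|bj)
  Gx <- .pair_mat(ctx, j, i, "coulomb")[v, v, drop = FALSE]  # (aj|bi)
  ev <- ctx$eps[v]
  D <- ctx$eps[ctx$occ_pos[i]] + ctx$eps[ctx$occ_pos[j]] - outer(ev, ev, `+`)
  r <- R / D
  sum((40 * G - 8 * Gx + 7 * R + Rt) * r) / 16
}

# ------------------------------------------------ V, X, B pair scalars

#' F12 intermediates V, X, B for occupied pairs
#'
#' Evaluates the fixed-amplitude pair scalars of the geminal-only energy
#' for all active pairs (the coupling term C is computed separately).
#'
#' @param ctx an [f12_context()] (or a structurally identical local
#'   domain context).
#' @param pairs optional two-column matrix of active-pair indices
#'   (defaults to all i <= j over active occupieds).
#' @return data.frame with i, j, B, X, V (pair-energy scalars in
#'   hartree, already carrying the fixed-amplitude weights).
#' @export
compute_VXB <- function(ctx, pairs = NULL) {
  act <- ctx$act_pos
  if (is.null(pairs)) {
    pairs <- do.call(rbind, lapply(seq_along(act), function(a)
      cbind(act[a], act[a:length(act)])))
  }
  occ <- ctx$occ_pos
  nocc <- length(occ)
  # precompute pair matrices for all needed (occ, occ) ordered pairs
  Om <- list(); Ga <- list(); Phi <- list()
  for (i in seq_len(nocc)) for (j in seq_len(nocc)) {
    key <- paste(i, j)
    Om[[key]] <- .pair_mat(ctx, i, j, "f12")
    Ga[[key]] <- .pair_mat(ctx, i, j, "coulomb")
    Phi[[key]] <- .pair_mat(ctx, i, j, "f12_squared")
  }
  Focc <- ctx$F_RI[occ, occ, drop = FALSE]
  Xel <- function(i, j, k, l)
    .fQ_elem(ctx, Om[[paste(i, j)]], Om[[paste(k, l)]],
             .oo_elem(ctx, "f12_squared", i, j, k, l))
  out <- data.frame(i = integer(0), j = integer(0), B = numeric(0),
                    X = numeric(0), V = numeric(0))
  acti <- match(ctx$act_pos, occ)
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs[r, 1], occ); j <- match(pairs[r, 2], occ)
    Vd <- .fQ_elem(ctx, Om[[paste(i, j)]], Ga[[paste(i, j)]],
                   .oo_elem(ctx, "f12_over_r12", i, j, i, j))
    Vx <- .fQ_elem(ctx, Om[[paste(i, j)]], Ga[[paste(j, i)]],
                   .oo_elem(ctx, "f12_over_r12", i, j, j, i))
    Vsc <- 2.5 * Vd - 0.5 * Vx
    # hermitian symmetrization: B_{ij,kl} = (B_raw(ij,kl) + B_raw(kl,ij))/2;
    # the diagonal element is self-adjoint as computed
    Bd <- .B_raw(ctx, i, j, i, j, Om, Phi)
    Bx <- 0.5 * (.B_raw(ctx, i, j, j, i, Om, Phi) +
                   .B_raw(ctx, j, i, i, j, Om, Phi))
    Bsc <- (7 / 16) * Bd + (1 / 16) * Bx
    Xsc <- 0
    for (k in acti) {
      fik <- Focc[i, k]; fjk <- Focc[j, k]
      if (abs(fik) > 1e-14)
        Xsc <- Xsc + fik * ((7 / 16) * Xel(i, j, k, j) + (1 / 16) * Xel(i, j, j, k))
      if (abs(fjk) > 1e-14)
        Xsc <- Xsc + fjk * ((7 / 16) * Xel(i, j, i, k) + (1 / 16) * Xel(i, j, k, i))
    }
    out <- rbind(out, data.frame(i = pairs[r, 1], j = pairs[r, 2],
                                 B = Bsc, X = Xsc, V = Vsc))
  }
  out
}

# ----------------------------------------------------------- assembly

#' Assemble the explicitly correlated energy report
#'
#' Combines an MP2 report with per-pair F12 intermediates using the
#' 1/(1 + delta_ij) pair weighting, plus an optional CABS singles value.
#'
#' @param mp2 an `lmf12_energy` from [canonical_mp2()].
#' @param f12_pairs data.frame with columns i, j, B, X, C, V.
#' @param cabs_singles_energy scalar correction to the HF energy.
#' @param method report label.
#' @return `lmf12_energy` with the F12 breakdown.
#' @export
assemble_f12 <- function(mp2, f12_pairs, cabs_singles_energy = 0,
                         method = "canonical-DF-MP2-F12") {
  w <- ifelse(f12_pairs$i == f12_pairs$j, 0.5, 1)
  E_f12 <- sum(w * (f12_pairs$B - f12_pairs$X + f12_pairs$C + f12_pairs$V))
  out <- list(E_hf = mp2$E_hf, E_corr = mp2$E_corr,
              E_os = mp2$E_os, E_ss = mp2$E_ss,
              E_f12 = E_f12,
              f12_pairs = cbind(f12_pairs, weight = w),
              E_cabs_singles = cabs_singles_energy,
              E_mp2f12 = mp2$E_corr + E_f12,
              E_total = mp2$E_hf + cabs_singles_energy + mp2$E_corr + E_f12,
              method = method)
  class(out) <- "lmf12_energy"
  out
}

#' Canonical MP2-F12 energy
#'
#' MP2 plus the explicitly correlated correction E_F12 =
#' sum_{i<=j} (B - X + C + V)/(1 + delta_ij), plus the CABS singles
#' correction to the HF energy.
#'
#' @param reference an [load_reference()] object.
#' @param geminal optional [make_geminal()].
#' @param ctx optional precomputed [f12_context()].
#' @param freeze_core freeze core orbitals.
#' @return `lmf12_energy` with F12 breakdown.
#' @export
canonical_mp2_f12 <- function(reference, geminal = NULL, ctx = NULL,
                              freeze_core = TRUE) {
  ref <- reference
  if (is.null(ctx)) ctx <- f12_context(ref, geminal, freeze_core = freeze_core)
  mp2 <- canonical_mp2(ref, freeze_core = freeze_core)
  vxb <- compute_VXB(ctx)
  Cv <- numeric(nrow(vxb))
  occ <- ctx$occ_pos
  for (r in seq_len(nrow(vxb)))
    Cv[r] <- compute_C_canonical(ctx, match(vxb$i[r], occ),
                                 match(vxb$j[r], occ))
  sing <- cabs_singles(ref, ctx$complementary, ctx$fock_joint)
  assemble_f12(mp2, cbind(vxb, C = Cv), sing$energy)
}
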