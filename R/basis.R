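# Built-in basis-set family.
#
# The package generates all of its basis sets by rule rather than shipping
# tabulated literature sets: occupied Slater shells (Clementi-type
# exponents) are expanded in three Gaussians with the universal
# least-squares 1s/2s/2p expansion coefficients, valence shells are split,
# and polarization / RI / CABS shells are even-tempered.  The family is
# internally consistent, which is all the correctness properties of the
# method require; cardinal labels DZ/TZ/QZ control the splitting level and
# select the default geminal exponent.

# universal 3-Gaussian expansions of Slater 1s/2s/2p with unit exponent
.STO3G <- list(
  s1 = list(ex = c(0.109818, 0.405771, 2.227660),
            cf = c(0.444635, 0.535328, 0.154329)),
  s2 = list(ex = c(0.0751386, 0.231031, 0.994203),
            cf = c(0.700115, 0.399513, -0.0999672)),
  p2 = list(ex = c(0.0751386, 0.231031, 0.994203),
            cf = c(0.391957, 0.607684, 0.155916)))

# Slater exponents (Clementi-type, sp-averaged valence)
.SLATER <- list(
  H  = list(z1 = 1.24),
  He = list(z1 = 1.6875),
  C  = list(z1 = 5.67, z2 = 1.60),
  N  = list(z1 = 6.67, z2 = 1.92),
  O  = list(z1 = 7.66, z2 = 2.25))

# number of (frozen) core orbitals per element
.NCORE <- c(H = 0, He = 0, C = 1, N = 1, O = 1)

# ---------------------------------------------------------------- shells

# a shell: list(l, ex, cf) with cf for normalized primitives
.shell <- function(l, ex, cf = rep(1, length(ex))) list(l = l, ex = ex, cf = cf)

.scale_sh <- function(sh, z2) .shell(sh$l, sh$ex * z2, sh$cf)

.element_shells <- function(sym, cardinal) {
  sl <- .SLATER[[sym]]
  heavy <- !is.null(sl$z2)
  s1 <- .STO3G$s1; s2 <- .STO3G$s2; p2 <- .STO3G$p2
  sh <- list()
  zv <- if (heavy) sl$z2 else sl$z1
  if (cardinal == "MIN" || (cardinal == "SV" && !heavy)) {
    sh <- c(sh, list(.shell(0, s1$ex * sl$z1^2, s1$cf)))
    if (heavy) sh <- c(sh, list(.shell(0, s2$ex * sl$z2^2, s2$cf),
                                .shell(1, p2$ex * sl$z2^2, p2$cf)))
    return(sh)
  }
  if (cardinal == "SV") cardinal <- "DZ"   # split-valence heavy, minimal H
  split2 <- function(tab, l, z2) {
    # contract the two tightest primitives, free the most diffuse one
    o <- order(tab$ex, decreasing = TRUE)
    list(.shell(l, tab$ex[o[1:2]] * z2, tab$cf[o[1:2]]),
         .shell(l, tab$ex[o[3]] * z2, 1))
  }
  uncon <- function(tab, l, z2) lapply(tab$ex * z2, function(e) .shell(l, e, 1))
  pol <- zv^2 / 2
  if (cardinal == "DZ") {
    if (heavy) {
      sh <- c(sh, list(.shell(0, s1$ex * sl$z1^2, s1$cf)),
              split2(s2, 0, sl$z2^2), split2(p2, 1, sl$z2^2))
    } else {
      sh <- c(sh, split2(s1, 0, sl$z1^2), list(.shell(1, pol, 1)))
    }
  } else if (cardinal %in% c("TZ", "QZ")) {
    if (heavy) {
      sh <- c(sh, list(.shell(0, s1$ex * sl$z1^2, s1$cf)),
              uncon(s2, 0, sl$z2^2), uncon(p2, 1, sl$z2^2),
              list(.shell(2, pol, 1)))
    } else {
      sh <- c(sh, uncon(s1, 0, sl$z1^2),
              list(.shell(1, pol * 1.7, 1), .shell(1, pol * 0.5, 1)))
    }
    if (cardinal == "QZ") {
      dif <- min(vapply(sh, function(s) min(s$ex), 0)) / 2.5
      sh <- c(sh, list(.shell(0, dif, 1), .shell(1, dif * 1.6, 1)))
      sh <- c(sh, list(.shell(2, pol * (if (heavy) 2.4 else 1), 1)))
    }
  } else stop("unknown basis cardinal: ", cardinal)
  sh
}

.geom_seq <- function(lo, hi, ratio) {
  if (hi <= lo) return(lo)
  n <- max(1L, ceiling(log(hi / lo) / log(ratio)))
  lo * ratio^(0:n)
}

# even-tempered RI fitting shells derived from the orbital shells; higher
# angular momenta are kept lean (they only fit valence-product densities)
.element_shells_ri <- function(sym, cardinal) {
  orb <- .element_shells(sym, cardinal)
  allex <- unlist(lapply(orb, `[[`, "ex"))
  ls <- vapply(orb, function(s) as.integer(s$l), 0L)
  lmax <- max(ls)
  valex <- unlist(lapply(orb[ls > 0], `[[`, "ex"))
  if (!length(valex)) valex <- allex[allex <= stats::quantile(allex, 0.6)]
  sex <- unlist(lapply(orb[ls == 0], `[[`, "ex"))
  laux <- min(2L * lmax, 3L)
  capped <- function(lo, hi, ratio, cap) {
    e <- .geom_seq(lo, hi, ratio)
    if (length(e) > cap) e <- exp(seq(log(min(e)), log(max(e)),
                                      length.out = cap))
    e
  }
  sh <- list()
  for (l in 0:laux) {
    e <- switch(as.character(l),
      "0" = .geom_seq(1.4 * min(allex), 2.4 * max(allex), 3.0),
      "1" = capped(1.4 * min(allex),
                   1.2 * (max(valex) + stats::median(sex)), 3.0, 4),
      "2" = if (length(unique(valex)) == 1) 2 * valex[1] else
        capped(1.4 * min(valex), 2.4 * max(valex), 3.0, 3),
      "3" = capped(1.6 * min(valex), 2.2 * max(valex), 3.5, 2))
    for (x in e) sh <- c(sh, list(.shell(l, x, 1)))
  }
  sh
}

# complementary-auxiliary (CABS source) shells: interleaved even-tempered
# exponents spanning the orbital range plus one higher angular momentum
.element_shells_cabs <- function(sym, cardinal) {
  orb <- .element_shells(sym, cardinal)
  allex <- unlist(lapply(orb, `[[`, "ex"))
  lmax <- max(vapply(orb, function(s) as.integer(s$l), 0L))
  sh <- list()
  for (l in 0:lmax) {
    hi <- if (l == 0) max(allex) * 2.0 else max(allex) * 0.6
    for (e in .geom_seq(0.55 * min(allex), hi, 3.4))
      sh <- c(sh, list(.shell(l, e * 1.45, 1)))  # offset between orbital exps
  }
  zv <- if (!is.null(.SLATER[[sym]]$z2)) .SLATER[[sym]]$z2 else .SLATER[[sym]]$z1
  sh <- c(sh, list(.shell(lmax + 1L, 0.7 * zv^2, 1),
                   .shell(lmax + 1L, 2.1 * zv^2, 1)))
  sh
}

# ----------------------------------------------------------- AO assembly

.cart_components <- function(l) {
  out <- NULL
  for (lx in l:0) for (ly in (l - lx):0) out <- rbind(out, c(lx, ly, l - lx - ly))
  out
}

.prim_norm <- function(alpha, lx, ly, lz) {
  l <- lx + ly + lz
  dd <- function(n) if (n <= 0) 1 else prod(seq(2 * n - 1, 1, by = -2))
  (2 * alpha / pi)^0.75 * (4 * alpha)^(l / 2) /
    sqrt(dd(lx) * dd(ly) * dd(lz))
}

.self_overlap <- function(ex, cf, lx, ly, lz) {
  dd <- function(n) if (n <= 0) 1 else prod(seq(2 * n - 1, 1, by = -2))
  s <- 0
  for (p in seq_along(ex)) for (q in seq_along(ex)) {
    pp <- ex[p] + ex[q]
    s <- s + cf[p] * cf[q] * (pi / pp)^1.5 *
      dd(lx) * dd(ly) * dd(lz) / (2 * pp)^(lx + ly + lz)
  }
  s
}

#' Build an AO basis for a molecule
#'
#' @param mol a [molecule()].
#' @param name basis name: a cardinal "MIN", "DZ", "TZ", "QZ" for the
#'   orbital basis, "RI-DZ" (etc.) for the fitting basis, "CABS-DZ" (etc.)
#'   for the complementary auxiliary source basis.
#' @return `lmf12_basis` object: per-AO Cartesian powers, centers,
#'   normalized primitive expansions, and atom bookkeeping.
#' @export
build_basis <- function(mol, name = "DZ") {
  kind <- "orb"; cardinal <- name
  if (grepl("^RI-", name)) { kind <- "ri"; cardinal <- sub("^RI-", "", name) }
  if (grepl("^CABS-", name)) { kind <- "cabs"; cardinal <- sub("^CABS-", "", name) }
  l <- NULL; cen <- NULL; exps <- list(); coefs <- list()
  atom_of_ao <- integer(0); shell_of_ao <- integer(0)
  shell_id <- 0L
  for (ia in seq_along(mol$symbols)) {
    sym <- mol$symbols[ia]
    shells <- switch(kind,
                     orb = .element_shells(sym, cardinal),
                     ri = .element_shells_ri(sym, cardinal),
                     cabs = .element_shells_cabs(sym, cardinal))
    for (sh in shells) {
      shell_id <- shell_id + 1L
      comps <- .cart_components(sh$l)
      for (k in seq_len(nrow(comps))) {
        lx <- comps[k, 1]; ly <- comps[k, 2]; lz <- comps[k, 3]
        cf <- sh$cf * vapply(sh$ex, .prim_norm, 0, lx, ly, lz)
        cf <- cf / sqrt(.self_overlap(sh$ex, cf, lx, ly, lz))
        l <- rbind(l, c(lx, ly, lz))
        cen <- rbind(cen, mol$coords[ia, ])
        exps[[length(exps) + 1L]] <- sh$ex
        coefs[[length(coefs) + 1L]] <- cf
        atom_of_ao <- c(atom_of_ao, ia)
        shell_of_ao <- c(shell_of_ao, shell_id)
      }
    }
  }
  structure(list(mol = mol, name = name,
                 l = matrix(as.integer(l), ncol = 3),
                 center = cen, exps = exps, coefs = coefs,
                 atom_of_ao = atom_of_ao, shell_of_ao = shell_of_ao,
                 n = nrow(l)),
            class = "lmf12_basis")
}

#' @export
print.lmf12_basis <- function(x, ...) {
  cat(sprintf("<lmf12_basis> %s: %d functions on %d atoms (lmax = %d)\n",
              x$name, x$n, length(x$mol$symbols), max(rowSums(x$l))))
  invisible(x)
}

#' Restrict a basis to a subset of its functions
#' @param basis an `lmf12_basis`.
#' @param idx integer indices of functions to keep.
#' @export
subset_basis <- function(basis, idx) {
  basis$l <- basis$l[idx, , drop = FALSE]
  basis$center <- basis$center[idx, , drop = FALSE]
  basis$exps <- basis$exps[idx]
  basis$coefs <- basis$coefs[idx]
  basis$atom_of_ao <- basis$atom_of_ao[idx]
  basis$shell_of_ao <- basis$shell_of_ao[idx]
  basis$n <- length(idx)
  basis
}

#' Concatenate two bases over the same molecule
#' @param a,b `lmf12_basis` objects.
#' @export
join_basis <- function(a, b) {
  a$l <- rbind(a$l, b$l)
  a$center <- rbind(a$center, b$center)
  a$exps <- c(a$exps, b$exps)
  a$coefs <- c(a$coefs, b$coefs)
  a$atom_of_ao <- c(a$atom_of_ao, b$atom_of_ao)
  a$shell_of_ao <- c(a$shell_of_ao, max(a$shell_of_ao, 0L) + b$shell_of_ao)
  a$n <- a$n + b$n
  a$name <- paste0(a$name, "+", b$name)
  a
}

# number of core orbitals of a molecule
n_core_orbitals <- function(mol) sum(.NCORE[mol$symbols])
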