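# R-level wrappers around the McMurchie-Davidson engine.

.as_engine_basis <- function(basis) {
  list(l = basis$l, center = basis$center, exps = basis$exps, coefs = basis$coefs)
}

#' One-electron AO integrals
#'
#' Overlap, kinetic, nuclear attraction and dipole integrals between two
#' AO spaces over the same molecule.
#'
#' @param basA,basB `lmf12_basis` objects (defaults `basB = basA`).
#' @param origin dipole origin (bohr); default the center of nuclear charge.
#' @return list with matrices S, T, V, DX, DY, DZ.
#' @export
one_electron <- function(basA, basB = basA, origin = NULL) {
  mol <- basA$mol
  if (is.null(origin))
    origin <- colSums(mol$coords * mol$charges) / sum(mol$charges)
  .cpp_one_electron(.as_engine_basis(basA), .as_engine_basis(basB),
                    as.numeric(mol$charges), mol$coords, as.numeric(origin))
}

#' Two-center two-electron integrals (P|op|Q)
#'
#' @param basP,basQ auxiliary bases.
#' @param op operator name, see [operator_kernel()].
#' @param geminal geminal factor for non-Coulomb operators.
#' @return matrix nP x nQ in atomic units.
#' @export
two_center <- function(basP, basQ = basP, op = "coulomb", geminal = NULL) {
  k <- operator_kernel(op, geminal)
  .cpp_two_center(.as_engine_basis(basP), .as_engine_basis(basQ),
                  k$kernel, k$zetas, k$coefs)
}

#' Three-center two-electron integrals (mu nu|op|P)
#'
#' @param basA,basB orbital-side bases (bra pair).
#' @param basP auxiliary basis.
#' @param op operator name.
#' @param geminal geminal factor for non-Coulomb operators.
#' @param screen Cauchy-Schwarz screening threshold.
#' @return array [nA, nB, nP].
#' @export
three_center <- function(basA, basB, basP, op = "coulomb", geminal = NULL,
                         screen = 1e-12) {
  k <- operator_kernel(op, geminal)
  .cpp_three_center(.as_engine_basis(basA), .as_engine_basis(basB),
                    .as_engine_basis(basP), k$kernel, k$zetas, k$coefs, screen)
}

#' Exact four-center integrals (reference oracle)
#'
#' Dense four-index two-electron integrals, intended as a test oracle and
#' for the desk-scale joint-basis Fock build; guarded against large spaces.
#'
#' @param basA,basB,basC,basD AO bases for the four slots (Mulliken order:
#'   (AB|op|CD)).
#' @param op operator name.
#' @param geminal geminal factor for non-Coulomb operators.
#' @param screen Cauchy-Schwarz screening threshold.
#' @param max_dim refuse beyond this many functions in any slot pair.
#' @return array [nA, nB, nC, nD].
#' @export
four_center_oracle <- function(basA, basB = basA, basC = basA, basD = basC,
                               op = "coulomb", geminal = NULL,
                               screen = 1e-14, max_dim = 130) {
  if (max(basA$n, basB$n, basC$n, basD$n) > max_dim)
    stop("four_center_oracle: basis too large (", max_dim, " function guard)")
  k <- operator_kernel(op, geminal)
  .cpp_four_center(.as_engine_basis(basA), .as_engine_basis(basB),
                   .as_engine_basis(basC), .as_engine_basis(basD),
                   k$kernel, k$zetas, k$coefs, screen)
}
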