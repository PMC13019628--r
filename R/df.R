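# Density fitting: Coulomb metric decomposition, fitted coefficients J,
# and robust-fitting coefficients K for the geminal-operator integrals.

# Pivoted Cholesky with a relative drop tolerance; returns the lower
# factor over the kept pivots (in pivot order).
.pivoted_chol <- function(A, tol = 1e-10) {
  n <- nrow(A)
  d <- diag(A)
  thr <- tol * max(d)
  L <- matrix(0, n, n)
  piv <- integer(0)
  avail <- rep(TRUE, n)
  for (k in seq_len(n)) {
    j <- which(avail)[which.max(d[avail])]
    if (!length(j) || d[j] <= thr) break
    piv <- c(piv, j)
    avail[j] <- FALSE
    m <- length(piv)
    lkj <- A[, j]
    if (m > 1) lkj <- lkj - L[, seq_len(m - 1), drop = FALSE] %*% L[j, seq_len(m - 1)]
    L[, m] <- lkj / sqrt(d[j])
    d <- d - L[, m]^2
    d[piv] <- 0
  }
  m <- length(piv)
  list(L = L[piv, seq_len(m), drop = FALSE], piv = piv,
       n_dropped = n - m)
}

#' Build the Coulomb fitting metric
#'
#' Computes the two-center Coulomb matrix (P|Q) over the auxiliary basis
#' and its pivoted Cholesky factor; near-singular directions (pivots below
#' `tol` times the largest diagonal) are discarded.
#'
#' @param aux_basis `lmf12_basis` for the fitting set.
#' @param tol relative pivot drop tolerance.
#' @return `lmf12_metric`: list(L, piv, V, n_dropped, basis); the factor
#'   satisfies V[piv, piv] = L %*% t(L).
#' @export
build_metric <- function(aux_basis, tol = 1e-10) {
  V <- two_center(aux_basis, aux_basis, "coulomb")
  pc <- .pivoted_chol(V, tol)
  if (!length(pc$piv)) stop("fitting metric is not positive definite")
  structure(list(L = pc$L, piv = pc$piv, V = V, n_dropped = pc$n_dropped,
                 basis = aux_basis),
            class = "lmf12_metric")
}

#' @export
print.lmf12_metric <- function(x, ...) {
  cat(sprintf("<lmf12_metric> %d aux functions, %d kept, %d dropped\n",
              nrow(x$V), length(x$piv), x$n_dropped))
  invisible(x)
}

# flatten a 3c tensor to (pair x aux) over the kept pivots
.flatten3c <- function(T3, metric) {
  d <- dim(T3)
  matrix(T3, d[1] * d[2], d[3])[, metric$piv, drop = FALSE]
}

#' Fitted coefficients J
#'
#' Solves the Coulomb-metric linear system through the Cholesky factor so
#' that `sum_P J[pq, P] J[rs, P]` reproduces the density-fitted integral
#' (pq|rs).
#'
#' @param three_center_coulomb array (n1, n2, naux) of (pq|P) integrals,
#'   or an already flattened (n1*n2, naux) matrix.
#' @param metric an [build_metric()] result.
#' @return matrix (n1*n2) x nkept with attribute `dim_orb` = c(n1, n2).
#' @export
fit_J <- function(three_center_coulomb, metric) {
  if (is.array(three_center_coulomb) && length(dim(three_center_coulomb)) == 3) {
    d12 <- dim(three_center_coulomb)[1:2]
    U <- .flatten3c(three_center_coulomb, metric)
  } else {
    U <- three_center_coulomb[, metric$piv, drop = FALSE]
    d12 <- c(nrow(U), 1L)
  }
  J <- t(forwardsolve(metric$L, t(U)))
  attr(J, "dim_orb") <- d12
  J
}

#' Robust-fitting coefficients K
#'
#' For a non-Coulomb operator the robust fitted integral is
#' (pq|op|rs) ~ sum_P (J[pq,P] K[rs,P] + K[pq,P] J[rs,P]) which is correct
#' to second order in the fitting residual.
#'
#' @param three_center_op array (n1, n2, naux) of (pq|op|P) integrals.
#' @param two_center_op matrix (P|op|Q) over the full auxiliary set.
#' @param J fitted Coulomb coefficients of the same orbital pairs.
#' @param metric an [build_metric()] result.
#' @return matrix like `J`.
#' @export
fit_K <- function(three_center_op, two_center_op, J, metric) {
  if (is.null(two_center_op)) stop("two-center operator matrix is required")
  W <- if (is.array(three_center_op) && length(dim(three_center_op)) == 3)
    .flatten3c(three_center_op, metric) else three_center_op[, metric$piv, drop = FALSE]
  A <- two_center_op[metric$piv, metric$piv, drop = FALSE]
  # K = (pq|f|Q) L^{-T} - 1/2 J (L^{-1} A L^{-T})
  K1 <- t(forwardsolve(metric$L, t(W)))
  M <- forwardsolve(metric$L, t(forwardsolve(metric$L, A)))
  K <- K1 - 0.5 * J %*% t(M)
  attr(K, "dim_orb") <- attr(J, "dim_orb")
  K
}

#' Reconstruct four-index integrals from fitted coefficients
#'
#' @param Jb,Jk fitted J blocks for bra and ket pairs.
#' @param Kb,Kk optional robust K blocks (non-Coulomb operators).
#' @return matrix (bra pairs) x (ket pairs).
#' @export
df_reconstruct <- function(Jb, Jk, Kb = NULL, Kk = NULL) {
  if (is.null(Kb)) tcrossprod(Jb, Jk)
  else tcrossprod(Jb, Kk) + tcrossprod(Kb, Jk)
}
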