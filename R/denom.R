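# Cholesky / Laplace factorization of orbital-energy denominators.
#
# The reciprocal denominator 1/(eps_a - eps_i + eps_b - eps_j) over the
# composite indices x_ai = eps_a - eps_i is a Cauchy-like positive matrix
# Delta_(ai),(bj) = 1/(x_ai + x_bj).  A pivoted Cholesky decomposition (or
# a Laplace quadrature 1/x = int exp(-x t) dt) yields separable vectors
# e_omega with Delta ~ sum_omega e_omega e_omega^T, which removes the
# denominator from the amplitude expressions.

#' Cholesky factorization of the energy-denominator matrix
#'
#' Pivoted Cholesky of Delta = 1/(x + x') over the composite
#' (virtual, occupied) gap list, stopped when the largest diagonal
#' residual falls below `cd_threshold`.
#'
#' @param gaps positive excitation gaps x_ai = eps_a - eps_i (hartree).
#' @param cd_threshold residual threshold (default 1e-4, in units of
#'   1/hartree).
#' @return `lmf12_omega`: list(mode = "CD", vectors (n x n_omega),
#'   n_omega, gaps, max_residual).
#' @export
cd_denominator <- function(gaps, cd_threshold = 1e-4) {
  gaps <- as.numeric(gaps)
  if (any(gaps <= 0))
    stop("non-positive excitation gap: reference is not a closed-shell ",
         "ground-state minimum")
  n <- length(gaps)
  d <- 1 / (2 * gaps)              # diagonal of Delta
  V <- matrix(0, n, 0)
  piv <- integer(0)
  resid <- d
  Delta_col <- function(j) 1 / (gaps + gaps[j])
  while (max(resid) >= cd_threshold && ncol(V) < n) {
    j <- which.max(resid)
    col <- Delta_col(j)
    if (ncol(V) > 0) col <- col - V %*% V[j, ]
    v <- as.numeric(col) / sqrt(resid[j])
    V <- cbind(V, v)
    resid <- pmax(0, resid - v^2)
    piv <- c(piv, j)
  }
  structure(list(mode = "CD", vectors = V, n_omega = ncol(V), gaps = gaps,
                 max_residual = max(resid), pivots = piv),
            class = "lmf12_omega")
}

#' Laplace quadrature factorization of the energy denominator
#'
#' Nonlinear least-squares (log-spaced start, Levenberg-Marquardt) fit of
#' quadrature nodes/weights so that sum_w w exp(-x t) approximates 1/x on
#' [2 gap_min, 2 gap_max].  Each returned vector carries sqrt(w) so that
#' the omega-contraction reproduces the denominator product form.
#'
#' @param gap_min,gap_max positive bounds of the excitation gaps.
#' @param n_points number of quadrature points.
#' @param gaps optional gap list; when given, `vectors` are also returned
#'   as sqrt(w) exp(-x t) over the composite index.
#' @return `lmf12_omega` with mode "Laplace", nodes `t`, weights `w`.
#' @export
laplace_denominator <- function(gap_min, gap_max, n_points, gaps = NULL) {
  if (n_points < 1) stop("n_points must be >= 1")
  if (!(gap_min > 0 && gap_max >= gap_min)) stop("need 0 < gap_min <= gap_max")
  lo <- 2 * gap_min; hi <- 2 * gap_max
  if (n_points == 1 && hi / lo < 1 + 1e-12) {
    tw <- list(t = 1 / lo, w = exp(1) / lo)  # w e^{-x t} = 1/x exactly at x = lo
    # choose t, w so value and slope match at x = lo: t = 1/lo, w = e/lo
  } else {
    # initial guesses from the trapezoidal (sinc) rule on the log-scaled
    # integral representation 1/x = int exp(-x e^u) e^u du, then
    # Levenberg-Marquardt refinement of nodes and weights on a relative
    # error grid; a small restart grid over the truncation window
    x <- exp(seq(log(lo), log(hi), length.out = max(120, 25 * n_points)))
    n <- n_points
    fn <- function(par) {
      tt <- exp(par[seq_len(n)])
      ww <- exp(par[n + seq_len(n)])
      (as.numeric(exp(-outer(x, tt)) %*% ww) - 1 / x) * x
    }
    best <- NULL
    for (c1 in c(0.005, 0.02, 0.08)) for (c2 in c(15, 30, 60)) {
      umin <- log(c1 / hi); umax <- log(c2 / lo)
      h <- (umax - umin) / max(n - 1, 1)
      t0 <- exp(seq(umin, umax, length.out = n))
      fit <- minpack.lm::nls.lm(par = c(log(t0), log(h * t0)), fn = fn,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 800, ftol = 1e-16, ptol = 1e-16))
      err <- max(abs(fn(fit$par)))
      if (is.null(best) || err < best$err) best <- list(par = fit$par, err = err)
    }
    tt <- exp(best$par[seq_len(n)])
    ww <- exp(best$par[n + seq_len(n)])
    o <- order(tt)
    tw <- list(t = tt[o], w = ww[o])
  }
  vectors <- NULL
  if (!is.null(gaps)) {
    if (any(gaps <= 0)) stop("non-positive excitation gap")
    vectors <- vapply(seq_along(tw$t),
                      function(k) sqrt(tw$w[k]) * exp(-gaps * tw$t[k]),
                      numeric(length(gaps)))
    if (length(gaps) == 1) vectors <- matrix(vectors, 1)
  }
  structure(list(mode = "Laplace", t = tw$t, w = tw$w, vectors = vectors,
                 n_omega = length(tw$t), gaps = gaps),
            class = "lmf12_omega")
}

#' @export
print.lmf12_omega <- function(x, ...) {
  cat(sprintf("<lmf12_omega> mode %s, %d vectors/points\n", x$mode, x$n_omega))
  invisible(x)
}

#' Scale fitted coefficients by denominator factors
#'
#' Returns the per-omega scaled blocks J^w[x, P] = J[x, P] * e_w[x] over a
#' composite (virtual, occupied) index.
#'
#' @param J_block (composite x naux) fitted coefficients.
#' @param omega an `lmf12_omega` whose composite index matches rows of J.
#' @return list of per-omega matrices.
#' @export
apply_omega <- function(J_block, omega) {
  V <- omega$vectors
  if (is.null(V)) stop("omega object carries no vectors over a composite index")
  if (nrow(V) != nrow(J_block))
    stop("composite index mismatch between omega vectors and J block")
  lapply(seq_len(ncol(V)), function(k) J_block * V[, k])
}
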