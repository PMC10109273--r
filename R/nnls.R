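# Non-negative least squares, Lawson-Hanson active-set algorithm.
#
# Solves min ||A x - b||_2 subject to x >= 0. Written in-package because the
# recipe solver is central to phantom design and no NNLS routine ships with
# the base stack. For the small systems here (p = 3 dopants, ~1000 rows)
# the active-set method terminates in a handful of iterations.

#' Non-negative least squares
#'
#' Lawson–Hanson active-set solution of \eqn{\min_x \|Ax - b\|_2} subject to
#' \eqn{x \ge 0}.
#'
#' @param A numeric matrix (n x p), n >= 1.
#' @param b numeric vector, length n.
#' @param tol dual-feasibility tolerance; default scales with the problem.
#' @return list with `x` (length p, non-negative), `residual_norm`, and
#'   `passive` (logical, which coefficients ended strictly positive).
#' @examples
#' A <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2)
#' nnls_solve(A, c(1, -1, 0))
#' @export
nnls_solve <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  n <- nrow(A); p <- ncol(A)
  assert_num(b, "b", len = n)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(p, n)
  x <- numeric(p)
  passive <- rep(FALSE, p) # TRUE = in the positive (passive) set
  w <- drop(crossprod(A, b)) # gradient of -0.5||Ax-b||^2 at x = 0
  iter <- 0L
  max_iter <- 30L * p
  while (any(!passive) && max(w[!passive]) > tol && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(p)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- qr.coef(qr(Ap), b)
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > tol)) {
        x <- z
        break
      }
      # step back along x -> z to the boundary, drop the blocking variable(s)
      viol <- passive & (z <= tol)
      alpha <- min(x[viol] / (x[viol] - z[viol]))
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, residual_norm = sqrt(sum((b - A %*% x)^2)), passive = passive)
}
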