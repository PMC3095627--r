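# Non-negative least squares by the Lawson-Hanson active-set method,
# run on the normal equations (G = A'A, a = A'b). Per-pixel problems
# here are tiny (m ~ 86, k ~ 4-6), so the k x k solves dominate and the
# Gram form lets the unmixer share one G across every pixel of a stack.

# Solve min ||Ax - b||^2, x >= 0 given G = A'A and a = A'b.
# Returns the coefficient vector only; callers compute the residual
# against the original (A, b) for accuracy.
.nnlsGram <- function(G, a) {
  k <- length(a)
  x <- numeric(k)
  P <- logical(k)
  tol <- 1e-10 * max(abs(a), .Machine$double.xmin)
  w <- a
  outer <- 0L
  while (any(!P) && max(w[!P]) > tol) {
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      z <- numeric(k)
      zp <- try(solve(G[P, P, drop = FALSE], a[P]), silent = TRUE)
      if (inherits(zp, "try-error"))
        zp <- qr.solve(G[P, P, drop = FALSE], a[P], tol = 1e-12)
      z[P] <- zp
      if (all(z[P] > 0)) { x <- z; break }
      Q <- P & (z <= 0)
      alpha <- min(x[Q] / (x[Q] - z[Q]))
      x <- x + alpha * (z - x)
      P <- P & (x > .Machine$double.eps * max(abs(x), 1))
      x[!P] <- 0
      if (!any(P)) break
    }
    w <- a - drop(G %*% x)
    outer <- outer + 1L
    if (outer > 3L * k + 20L) break   # safeguard; never hit in practice
  }
  x
}

#' Non-negative least squares
#'
#' Minimizes \eqn{\|Ax - b\|^2} subject to \eqn{x \ge 0} with the
#' Lawson--Hanson active-set algorithm -- the fit applied to every
#' pixel's concatenated excitation spectrum during unmixing. At the
#' solution the Karush--Kuhn--Tucker conditions hold: each coefficient
#' is either zero (with non-positive gradient pressure) or has a
#' vanishing gradient component.
#'
#' @param A Design matrix \code{[m x k]} (basis spectra as columns).
#' @param b Observation vector of length \code{m}.
#' @return List with \code{x} (non-negative coefficients, length
#'   \code{k}) and \code{rnorm2} (squared Euclidean residual norm at
#'   \code{x}).
#' @export
#' @examples
#' fit <- nnlsSolve(diag(4), c(1, 2, 0, 3))
#' fit$x       # (1, 2, 0, 3)
#' fit$rnorm2  # 0
nnlsSolve <- function(A, b) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  if (nrow(A) != length(b))
    stop("nrow(A) must equal length(b)", call. = FALSE)
  .assertFinite(A, "A")
  .assertFinite(b, "b")
  if (nrow(A) < 1L || ncol(A) < 1L)
    stop("A must have at least one row and one column", call. = FALSE)
  G <- crossprod(A)
  a <- drop(crossprod(A, b))
  x <- .nnlsGram(G, a)
  r <- b - drop(A %*% x)
  list(x = x, rnorm2 = sum(r * r))
}
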