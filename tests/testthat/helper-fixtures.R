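# Shared fixtures: everything is generated in code at test time.

# Tiny stack with data[r, c, i, b] = f(r, c, i, b); default constant.
tinyStack <- function(nr = 4, nc = 4, wl = c(710, 715), nb = 3,
                      fill = function(r, c, i, b) 7) {
  d <- array(0, c(nr, nc, length(wl), nb))
  for (r in seq_len(nr)) for (c_ in seq_len(nc))
    for (i in seq_along(wl)) for (b in seq_len(nb))
      d[r, c_, i, b] <- fill(r, c_, i, b)
  HyperStack(d, wavelengths = wl,
             bands = defaultEmissionBands()[seq_len(nb), ])
}

# A stack whose every pixel carries the same [n_ex x n_bands] spectrum.
uniformSpectrumStack <- function(spec, nr = 5, nc = 5, wl, bands = NULL) {
  nb <- ncol(spec)
  d <- array(0, c(nr, nc, nrow(spec), nb))
  for (i in seq_len(nrow(spec))) for (b in seq_len(nb))
    d[, , i, b] <- spec[i, b]
  HyperStack(d, wavelengths = wl,
             bands = bands %||% defaultEmissionBands()[seq_len(nb), ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sinusoidal test envelope over an axis (strictly positive).
testEnvelope <- function(wl) 2 + sin((wl - 710) / 40)

# Exhaustive active-set NNLS oracle, independent of the package
# implementation: solve the unconstrained LS on every support subset
# directly from (A, b) with qr.solve, keep feasible candidates (and
# x = 0), return the minimum-residual one.
oracleNNLS <- function(A, b) {
  k <- ncol(A)
  best <- list(x = numeric(k), rnorm2 = sum(b^2))
  for (code in seq_len(2^k - 1)) {
    S <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    As <- A[, S, drop = FALSE]
    xs <- tryCatch(qr.solve(As, b), error = function(e) NULL)
    if (is.null(xs) || any(xs < -1e-12)) next
    x <- numeric(k); x[S] <- pmax(xs, 0)
    rn <- sum((b - A %*% x)^2)
    if (rn < best$rnorm2) best <- list(x = x, rnorm2 = rn)
  }
  best
}
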