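# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All stochastic code in the package routes through this.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Half-up quantization of values in [0, 1] to 8-bit integers.
.quantize8 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  storage.mode(x) <- "double"
  q <- floor(x * 255 + 0.5)
  storage.mode(q) <- "integer"
  q
}

.assertFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(TRUE)
}

.isCount <- function(x) length(x) == 1L && is.finite(x) && x == as.integer(x)

# 3x3 replicate-padded mean filter; used to create narrow (<= 2 px) linear
# mixing zones at phantom region boundaries.
.boxBlur3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  acc <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + p[dr + seq_len(nr), dc + seq_len(nc)]
  acc / 9
}
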