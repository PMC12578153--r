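# Internal geometry and bookkeeping helpers.

DEG <- pi / 180
GRAV <- 9.81 # m/s^2

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation of vector v by angle (rad) about unit axis k.
rotate_about <- function(v, k, angle) {
  v * cos(angle) + cross3(k, v) * sin(angle) + k * sum(k * v) * (1 - cos(angle))
}

is_unit <- function(v, tol = 1e-6) abs(vnorm(v) - 1) <= tol

# Deterministic sub-seed derivation: fold integer keys into a master seed with
# an LCG step per key. All intermediates stay below 2^53 so arithmetic is exact.
derive_seed <- function(master, ...) {
  keys <- c(...)
  s <- as.numeric(master) %% 2147483647
  for (k in keys) {
    s <- (s * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(s %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run fn() under set.seed(seed) without disturbing the caller's RNG stream.
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  fn()
}
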