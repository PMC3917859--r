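# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so generators never perturb user-level randomness.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Rodrigues rotation of vector v about unit axis n by `ang` radians.
rotate_about <- function(v, n, ang) {
  v * cos(ang) + cross3(n, v) * sin(ang) + n * sum(n * v) * (1 - cos(ang))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Polynomial rolling hash (mod 2^31 - 1) over serialized R objects; stable
# provenance tag for run manifests. Exact in double arithmetic.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 3L))
  m <- 2147483647
  h <- 0
  for (b in bytes) h <- (h * 131 + b + 1) %% m
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
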