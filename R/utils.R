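# Internal helpers shared across modules.

# Run code with a temporarily fixed RNG state, restoring the caller's.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Derive a reproducible sub-seed (kept well below 2^31).
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

vnorm <- function(x) sqrt(sum(x * x))

rowNorms <- function(m) sqrt(rowSums(m * m))

normalize <- function(x) {
  n <- vnorm(x)
  if (n == 0) stop("cannot normalize a zero vector")
  x / n
}

as3d <- function(x, what = "point") {
  x <- as.numeric(x)
  if (length(x) != 3L || !all(is.finite(x)))
    stop(what, " must be a finite 3D vector")
  x
}

# Accumulate rows of `val` into rows `idx` of matrix `M` (duplicates sum).
addRowsAt <- function(M, idx, val) {
  s <- rowsum(val, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(s))
  M[rows, ] <- M[rows, , drop = FALSE] + s
  M
}

# Uniform random rotation matrix (via a random unit quaternion).
randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Two unit vectors completing `n` to an orthonormal right-handed basis.
planeBasis <- function(n) {
  n <- normalize(as3d(n, "normal"))
  ref <- if (abs(n[1]) <= abs(n[2]) && abs(n[1]) <= abs(n[3]))
    c(1, 0, 0) else if (abs(n[2]) <= abs(n[3])) c(0, 1, 0) else c(0, 0, 1)
  u <- normalize(ref - sum(ref * n) * n)
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v)
}
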