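# internal helpers

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalized")
  v / n
}

# orthonormal basis (u, v) spanning the plane orthogonal to unit vector w
plane_basis <- function(w) {
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(pracma_cross(a, w))
  v <- pracma_cross(w, u)
  list(u = u, v = v)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180

#' Plane specification
#' @param point a point on the plane (mm).
#' @param normal plane normal (normalized internally).
#' @return list with `point` and unit `normal`.
#' @export
plane <- function(point = c(0, 0, 0), normal = c(1, 0, 0)) {
  list(point = as.numeric(point), normal = unit(as.numeric(normal)))
}

# unsigned distances of points (n x 3) to a plane
plane_distance <- function(pl, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  abs(as.vector((points - matrix(pl$point, nrow(points), 3, byrow = TRUE)) %*% pl$normal))
}

# FNV-1a hash of a character scalar, as hex; used for run provenance.
# Kept exact in doubles: xor touches only the low byte, and the 32-bit
# modular product is split into 16-bit halves to stay within 2^53.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    a1 <- h %/% 65536
    a0 <- h %% 65536
    h <- (a0 * 16777619 + ((a1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
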