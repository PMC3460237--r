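#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames
#' @importFrom utils write.table read.delim head
NULL

# van der Waals radii (Angstrom), Bondi (1964) with common extensions.
# Used for steric-clash detection; clash if d < scale * (r_i + r_j).
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98,
  B = 1.92, Si = 2.10, Se = 1.90, Na = 2.27, K = 2.75,
  Li = 1.82, Mg = 1.73, Ca = 2.31, Zn = 1.39, Fe = 2.05
)

vdw_radius <- function(element) {
  r <- .vdw_radii[element]
  r[is.na(r)] <- 1.70  # fall back to carbon for exotic elements
  unname(r)
}

# Atomic numbers for fingerprint invariants
.atomic_number <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26, Zn = 30, Se = 34,
  Br = 35, I = 53
)

atomic_number <- function(element) {
  z <- .atomic_number[element]
  z[is.na(z)] <- 0
  unname(z)
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Squared distances between rows of A (n x 3) and rows of B (m x 3): n x m
cross_dist2 <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Deterministic evenly-spread points on the unit sphere (golden-angle spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Rotation matrix about unit axis by angle (radians), Rodrigues form
rotation_about_axis <- function(axis, angle) {
  u <- unitv(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Quaternion (w,x,y,z) -> rotation matrix
quat_to_rot <- function(q) {
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Halton low-discrepancy sequence in [0,1)
halton_seq <- function(n, base) {
  vapply(seq_len(n), function(i) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }, numeric(1))
}

# Deterministic quasi-uniform rotation set (Shoemake subgroup method on a
# Halton sequence); identity first so trivial placements are tried early.
rotation_grid <- function(n) {
  if (n <= 1) return(list(diag(3)))
  u1 <- halton_seq(n - 1, 2); u2 <- halton_seq(n - 1, 3); u3 <- halton_seq(n - 1, 5)
  qs <- cbind(
    sqrt(1 - u1) * sin(2 * pi * u2),
    sqrt(1 - u1) * cos(2 * pi * u2),
    sqrt(u1) * sin(2 * pi * u3),
    sqrt(u1) * cos(2 * pi * u3)
  )
  c(list(diag(3)), lapply(seq_len(n - 1), function(i) {
    q <- qs[i, ]
    quat_to_rot(c(q[4], q[1], q[2], q[3]))
  }))
}

# Cubic grid of points inside a sphere, ordered center-outwards
sphere_grid <- function(center, radius, spacing) {
  if (radius <= 0) return(matrix(center, 1, 3))
  s <- seq(-radius, radius, by = spacing)
  g <- as.matrix(expand.grid(x = s, y = s, z = s))
  r2 <- rowSums(g^2)
  g <- g[r2 <= radius^2 + 1e-12, , drop = FALSE]
  g <- g[order(rowSums(g^2)), , drop = FALSE]
  sweep(g, 2, center, "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
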