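# Internal linear algebra for screw transforms and helix placement.
# Angles in degrees at the API surface, radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalise a zero vector")
  v / n
}

# wrap an angle in degrees to (-180, 180]
wrap_deg <- function(x) {
  w <- (x + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

# rotation matrix about unit axis u by angle (deg), right-handed
rotation_about <- function(u, angle_deg) {
  u <- unitize(u)
  a <- deg2rad(angle_deg)
  c_ <- cos(a); s_ <- sin(a)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * (u %*% t(u))
}

# cylindrical -> cartesian (azimuth in degrees about +z)
cyl2cart <- function(r, az_deg, z) {
  a <- deg2rad(az_deg)
  c(r * cos(a), r * sin(a), z)
}

# Kabsch: rotation R and translation t minimising ||R a + t - b||
# a, b: n x 3 matrices of paired points
kabsch <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cb - as.vector(R %*% ca)
  list(R = R, t = t)
}

# axis (unit vector) and angle (deg, in (-180, 180]) of a rotation matrix
rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  cos_a <- max(-1, min(1, (tr - 1) / 2))
  angle <- acos(cos_a)
  if (angle < 1e-9) {
    return(list(axis = c(0, 0, 1), angle = 0))
  }
  if (abs(angle - pi) < 1e-7) {
    # near 180 deg: axis from the largest diagonal of (R + I) / 2
    M <- (R + diag(3)) / 2
    i <- which.max(diag(M))
    axis <- unitize(M[, i])
    return(list(axis = axis, angle = 180))
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  axis <- unitize(v / (2 * sin(angle)))
  list(axis = axis, angle = rad2deg(angle))
}

# coordinates matrix from a structure tibble
coords_mat <- function(s) {
  as.matrix(s[, c("x", "y", "z")])
}

set_coords <- function(s, m) {
  s$x <- m[, 1]; s$y <- m[, 2]; s$z <- m[, 3]
  s
}

rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# signed angle (deg) from v1 to v2 about unit axis u (v1, v2 projected first)
signed_angle_about <- function(v1, v2, u) {
  p1 <- v1 - sum(v1 * u) * u
  p2 <- v2 - sum(v2 * u) * u
  n1 <- vnorm(p1); n2 <- vnorm(p2)
  if (n1 < 1e-9 || n2 < 1e-9) return(NA_real_)
  p1 <- p1 / n1; p2 <- p2 / n2
  s <- sum(u * c(p1[2] * p2[3] - p1[3] * p2[2],
                 p1[3] * p2[1] - p1[1] * p2[3],
                 p1[1] * p2[2] - p1[2] * p2[1]))
  c_ <- max(-1, min(1, sum(p1 * p2)))
  rad2deg(atan2(s, c_))
}

# run code with a temporarily-set RNG seed, restoring prior state
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
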