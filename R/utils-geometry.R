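#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' @keywords internal
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle in degrees into (-180, 180]
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into (-180, 180].
#' @keywords internal
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}

# Right-handed rotation matrices about the laboratory +x and +z axes.
# "Counterclockwise for an observer looking down the positive axis toward
# the origin" is the right-handed positive sense adopted here.
rot_x <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(1, 0, 0,
           0, cos(t), -sin(t),
           0, sin(t), cos(t)), nrow = 3, byrow = TRUE)
}

rot_z <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), -sin(t), 0,
           sin(t), cos(t), 0,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

#' Measure a proper dihedral angle
#'
#' Returns the torsion a-b-c-d in degrees in [0, 360), using the standard
#' atan2 construction (IUPAC sign, then shifted to the 0-360 convention used
#' for side-chain chi angles here).
#'
#' @param a,b,c,d numeric length-3 coordinate vectors (Angstrom).
#' @return dihedral angle in degrees in [0, 360).
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  (ang + 360) %% 360
}

# cross product (kept local; avoids pulling a package for one primitive)
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three previously placed atoms a-b-c, place atom d bonded to c with
#' bond length \code{length}, bond angle d-c-b of \code{angle} degrees, and
#' dihedral d-c-b-a of \code{dihedral} degrees. The construction is
#' frame-local, so label geometry built with it is equivariant under rigid
#' motion of the host structure.
#'
#' @param a,b,c numeric length-3 coordinates of the frame atoms.
#' @param length bond length c-d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param dihedral torsion a-b-c-d in degrees.
#' @return coordinates of the new atom d.
#' @export
place_atom <- function(a, b, c, length, angle, dihedral) {
  ang <- deg2rad(angle)
  tor <- -deg2rad(dihedral)
  d_local <- c(-length * cos(ang),
               length * sin(ang) * cos(tor),
               length * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(c + rot %*% d_local)
}

# Evaluate expr with a temporary RNG state seeded at `seed`; restores the
# caller's RNG afterwards so generators are deterministic without side
# effects on the session.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
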