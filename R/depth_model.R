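#' Hyperbolic depth-calibration parameters
#'
#' Container for the four parameters of the hyperbolic relationship between
#' a nitroxide's membrane position and its depth parameter Phi. \code{m} and
#' \code{i} are the slope and intercept (Phi-units per Angstrom, Phi-units)
#' of the linear branch followed by labels in the membrane interior; \code{b}
#' is the aqueous plateau reached by labels far from the membrane; \code{c}
#' (>= 0, Phi-units squared) sets the curvature of the transition between the
#' two branches.
#'
#' Sign convention: the mean lipid phosphate plane is y = 0; positive y is
#' the aqueous side, the membrane interior is negative y. Phi rises toward
#' the interior, so \code{m} < 0 is the expected regime.
#'
#' @param m slope of the linear (membrane-interior) branch.
#' @param i intercept of the linear branch at r = 0.
#' @param b aqueous plateau value of Phi.
#' @param c curvature parameter, must be >= 0.
#' @return an object of class \code{hyperbola_params}.
#' @export
hyperbola_params <- function(m, i, b, c) {
  stopifnot(is.finite(m), is.finite(i), is.finite(b), is.finite(c))
  if (c < 0) stop("curvature parameter c must be >= 0")
  structure(list(m = m, i = i, b = b, c = c), class = "hyperbola_params")
}

#' Rigid-body docking transform
#'
#' Rotation about the laboratory x axis, then about the z axis, then a
#' translation along y (the bilayer normal). Angles are in degrees, reported
#' wrapped into (-180, 180]; the translation is in Angstrom.
#'
#' @param theta_x rotation about x, degrees.
#' @param theta_z rotation about z, degrees.
#' @param y_trans translation along y, Angstrom.
#' @return an object of class \code{docking_transform}.
#' @export
docking_transform <- function(theta_x, theta_z, y_trans) {
  stopifnot(is.finite(theta_x), is.finite(theta_z), is.finite(y_trans))
  structure(list(theta_x = wrap_angle(theta_x),
                 theta_z = wrap_angle(theta_z),
                 y_trans = y_trans),
            class = "docking_transform")
}

#' Canonicalize a docking transform
#'
#' The membrane-normal direction determined by (theta_x, theta_z) has a
#' two-fold parameter ambiguity: (theta_x + 180, 180 - theta_z) produces the
#' same physical pose. The canonical representative has cos(theta_z) >= 0,
#' with both angles wrapped into (-180, 180].
#'
#' @param t a \code{docking_transform}.
#' @return the equivalent canonical \code{docking_transform}.
#' @export
canonicalize_transform <- function(t) {
  tx <- t$theta_x
  tz <- t$theta_z
  if (cos(deg2rad(tz)) < 0) {
    tx <- tx + 180
    tz <- 180 - tz
  }
  docking_transform(tx, tz, t$y_trans)
}

#' Linear branch of the depth calibration
#'
#' @param r signed membrane position in Angstrom (negative = interior).
#' @param m slope.
#' @param i intercept.
#' @return L = m * r + i.
#' @export
linear_term <- function(r, m, i) m * r + i

#' Hyperbolic depth-parameter model
#'
#' Smooth-maximum hyperbola with asymptotes L(r) = m r + i (membrane
#' interior) and the constant aqueous plateau b:
#' Phi(r) = (L + b)/2 + sqrt(((L - b)/2)^2 + c).
#' With c = 0 this reduces exactly to max(L(r), b); c > 0 rounds the elbow.
#'
#' @param r signed membrane position(s), Angstrom.
#' @param params a \code{hyperbola_params} object.
#' @return predicted Phi value(s).
#' @export
hyperbola <- function(r, params) {
  stopifnot(inherits(params, "hyperbola_params"))
  if (params$c < 0) stop("curvature parameter c must be >= 0")
  L <- linear_term(r, params$m, params$i)
  (L + params$b) / 2 + sqrt(((L - params$b) / 2)^2 + params$c)
}

#' Apply a docking transform to points
#'
#' p' = Rz(theta_z) Rx(theta_x) p + (0, y_trans, 0). The structure is assumed
#' to be centered (rotations are about the origin).
#'
#' @param p numeric length-3 vector or n x 3 matrix of coordinates.
#' @param t a \code{docking_transform}.
#' @return transformed coordinates, same shape as \code{p}.
#' @export
transform_point <- function(p, t) {
  stopifnot(inherits(t, "docking_transform"))
  rot <- rot_z(t$theta_z) %*% rot_x(t$theta_x)
  vec <- is.null(dim(p))
  pm <- if (vec) matrix(p, nrow = 1) else as.matrix(p)
  stopifnot(ncol(pm) == 3, all(is.finite(pm)))
  out <- pm %*% t(rot)
  out[, 2] <- out[, 2] + t$y_trans
  if (vec) as.numeric(out) else out
}

#' Predicted depth parameter for dataset rows
#'
#' Composite forward model: for protein rows (P = 1) the membrane position r
#' is the y component of the transformed nitroxide coordinates; for
#' calibration rows (P = 0) it is the known lipid label depth D, independent
#' of the transform. The prediction is \code{hyperbola(r, params)}.
#'
#' @param rows a data.frame with columns \code{is_protein}, \code{x},
#'   \code{y}, \code{z} (protein rows) and \code{depth} (calibration rows).
#' @param t a \code{docking_transform}.
#' @param params a \code{hyperbola_params}.
#' @return numeric vector of predicted Phi, one per row.
#' @export
predicted_phi <- function(rows, t, params) {
  stopifnot(is.data.frame(rows), "is_protein" %in% names(rows))
  r <- numeric(nrow(rows))
  prot <- rows$is_protein
  if (any(prot)) {
    xyz <- as.matrix(rows[prot, c("x", "y", "z")])
    if (any(!is.finite(xyz)))
      stop("protein rows must carry finite nitroxide coordinates")
    r[prot] <- transform_point(xyz, t)[, 2]
  }
  if (any(!prot)) {
    d <- rows$depth[!prot]
    if (any(!is.finite(d)))
      stop("calibration rows must carry a finite known depth")
    r[!prot] <- d
  }
  hyperbola(r, params)
}

#' Membrane position r for each dataset row under a transform
#' @inheritParams predicted_phi
#' @return numeric vector of signed membrane positions, Angstrom.
#' @export
membrane_position <- function(rows, t) {
  r <- numeric(nrow(rows))
  prot <- rows$is_protein
  if (any(prot))
    r[prot] <- transform_point(as.matrix(rows[prot, c("x", "y", "z")]), t)[, 2]
  if (any(!prot)) r[!prot] <- rows$depth[!prot]
  r
}
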