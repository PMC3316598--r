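#' Apply a fitted docking model to a structure
#'
#' Transforms every atom by the model's rigid-body transform. The structure
#' must already be centered on the fit's center-of-mass convention; if it is
#' not (mean ATOM position > 0.5 Angstrom from the origin) it is
#' auto-centered with a warning.
#'
#' @param structure a \code{structure_model}.
#' @param model a \code{docking_model} (or bare \code{docking_transform}).
#' @return the transformed \code{structure_model}.
#' @export
apply_model <- function(structure, model) {
  t <- if (inherits(model, "docking_transform")) model else model$transform
  at <- structure$atoms
  sel <- at$type == "ATOM"
  if (any(sel)) {
    ctr <- colMeans(at[sel, c("x", "y", "z")])
    if (sqrt(sum(ctr^2)) > 0.5) {
      warning("structure is not centered; auto-centering before transform")
      structure <- center_structure(structure)$structure
      at <- structure$atoms
    }
  }
  xyz <- transform_point(as.matrix(at[, c("x", "y", "z")]), t)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  out <- structure_model(at, structure$label_sites, structure$source)
  out$label_sites <- lapply(out$label_sites, function(s) {
    s$nitroxide <- transform_point(s$nitroxide, t); s
  })
  out
}

#' Signed bilayer depth of a named atom
#'
#' In the docked frame the mean phosphate plane is y = 0; the signed depth
#' of an atom is simply its y coordinate (positive = aqueous side).
#'
#' @param structure transformed \code{structure_model}.
#' @param resno residue number.
#' @param atom atom name (e.g. "CA").
#' @param chain optional chain id.
#' @return signed depth in Angstrom.
#' @export
residue_depth <- function(structure, resno, atom = "CA", chain = NULL) {
  at <- structure$atoms
  idx <- residue_atoms(structure, resno, chain)
  i <- idx[at$elety[idx] == atom][1]
  if (is.na(i)) stop("atom ", atom, " of residue ", resno, " not found")
  at$y[i]
}

#' Angle of an interatomic axis to the membrane plane
#'
#' Angle of the A-to-B vector relative to the x-z (phosphate) plane:
#' arcsin(|dy| / |d|), in [0, 90] degrees. Translation-invariant and
#' invariant under rotations about the bilayer normal.
#'
#' @param structure transformed \code{structure_model}.
#' @param resno_a,atom_a residue number and atom name of endpoint A.
#' @param resno_b,atom_b residue number and atom name of endpoint B.
#' @return angle in degrees.
#' @export
axis_angle <- function(structure, resno_a, atom_a, resno_b, atom_b) {
  at <- structure$atoms
  pick <- function(resno, atom) {
    idx <- residue_atoms(structure, resno)
    i <- idx[at$elety[idx] == atom][1]
    if (is.na(i)) stop("atom ", atom, " of residue ", resno, " not found")
    atom_xyz(at, i)
  }
  a <- pick(resno_a, atom_a)
  b <- pick(resno_b, atom_b)
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len < 1e-9) stop("axis endpoints are coincident")
  rad2deg(asin(abs(d[2]) / len))
}

#' Angle of a free vector to the membrane plane
#' @param d numeric length-3 vector.
#' @return arcsin(|dy|/|d|) in degrees.
#' @export
vector_plane_angle <- function(d) {
  len <- sqrt(sum(d^2))
  if (len < 1e-9) stop("zero vector has no direction")
  rad2deg(asin(abs(d[2]) / len))
}

#' Classify bilayer-contacting residues by chemistry
#'
#' A residue contacts the bilayer when any of its side-chain atoms (atoms
#' other than backbone N, CA, C, O, OXT) lies below \code{cutoff} on the y
#' axis. Contacts are partitioned into basic (Arg/Lys/His), acidic
#' (Asp/Glu) and hydrophobic/polar (everything else); the partition is
#' disjoint and exhaustive.
#'
#' @param structure transformed \code{structure_model}.
#' @param cutoff contact cutoff in Angstrom above the phosphate plane
#'   (default +3: within the headgroup layer).
#' @return list of data.frames \code{basic}, \code{acidic},
#'   \code{hydrophobic_polar}, each with resno, resid, chain and the
#'   minimum side-chain y (\code{min_y}).
#' @export
classify_contacts <- function(structure, cutoff = 3) {
  at <- structure$atoms
  side <- at$type == "ATOM" & !(at$elety %in% c("N", "CA", "C", "O", "OXT"))
  sc <- at[side, , drop = FALSE]
  out <- list(basic = NULL, acidic = NULL, hydrophobic_polar = NULL)
  if (nrow(sc) > 0) {
    key <- paste(sc$chain, sc$resno)
    min_y <- tapply(sc$y, key, min)
    first <- !duplicated(key)
    info <- sc[first, c("chain", "resno", "resid")]
    info$min_y <- as.numeric(min_y[paste(info$chain, info$resno)])
    hit <- info[info$min_y < cutoff, , drop = FALSE]
    basic <- hit$resid %in% c("ARG", "LYS", "HIS")
    acidic <- hit$resid %in% c("ASP", "GLU")
    out$basic <- hit[basic, , drop = FALSE]
    out$acidic <- hit[acidic, , drop = FALSE]
    out$hydrophobic_polar <- hit[!basic & !acidic, , drop = FALSE]
  }
  empty <- data.frame(chain = character(), resno = integer(),
                      resid = character(), min_y = numeric())
  for (nm in names(out)) if (is.null(out[[nm]])) out[[nm]] <- empty
  out
}

# twist/tilt of a ring: tilt = angle between the ring-plane normal and the
# bilayer normal (y), in [0, 90]; twist = azimuth in the x-z plane of the
# ring-fixed vector from the ring centroid to its first atom, measured from
# +x toward +z.
ring_orientation <- function(ring_xyz) {
  stopifnot(is.matrix(ring_xyz), nrow(ring_xyz) >= 3)
  ctr <- colMeans(ring_xyz)
  rel <- sweep(ring_xyz, 2, ctr)
  sv <- svd(rel)
  normal <- sv$v[, 3]
  if (normal[2] < 0) normal <- -normal
  tilt <- rad2deg(acos(min(max(abs(normal[2]), -1), 1)))
  v1 <- rel[1, ]
  twist <- rad2deg(atan2(v1[3], v1[1]))
  list(tilt = tilt, twist = twist, centroid = ctr, normal = normal)
}

#' Headgroup displacement relative to a reference conformation
#'
#' Compares the docked position/orientation of a lipid headgroup to a
#' user-supplied reference (from external literature, never hard-coded):
#' delta depth is the backbone-phosphate y minus the reference depth; tilt
#' is the angle between the inositol-ring normal and the bilayer normal;
#' twist is the azimuthal rotation of a ring-fixed vector about the
#' normal. Angle differences are wrapped into (-180, 180].
#'
#' @param phosphate_xyz length-3 coordinates of the backbone phosphate.
#' @param ring_xyz n x 3 (n >= 3) coordinates of the inositol ring atoms,
#'   first row defining the ring-fixed twist reference vector.
#' @param reference list with numbers \code{depth} (Angstrom),
#'   \code{twist}, \code{tilt} (degrees).
#' @return named numeric vector c(d_depth, d_twist, d_tilt).
#' @export
headgroup_displacement <- function(phosphate_xyz, ring_xyz, reference) {
  stopifnot(all(c("depth", "twist", "tilt") %in% names(reference)))
  if (length(phosphate_xyz) != 3 || any(!is.finite(phosphate_xyz)))
    stop("phosphate anchor coordinates missing or non-finite")
  o <- ring_orientation(as.matrix(ring_xyz))
  c(d_depth = phosphate_xyz[2] - reference$depth,
    d_twist = wrap_angle(o$twist - reference$twist),
    d_tilt = o$tilt - reference$tilt)
}

#' Full geometry report for a docked structure
#'
#' @param structure centered \code{structure_model}.
#' @param model fitted \code{docking_model}.
#' @param axis list(resno_a, atom_a, resno_b, atom_b) defining the
#'   structural axis to report, or NULL.
#' @param contact_cutoff contact cutoff in Angstrom.
#' @return list with the transformed structure, per-residue CA depths
#'   (data.frame), the axis angle (or NA) and the contact classification.
#' @export
geometry_report <- function(structure, model, axis = NULL,
                            contact_cutoff = 3) {
  docked <- apply_model(structure, model)
  at <- docked$atoms
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  depths <- data.frame(chain = ca$chain, resno = ca$resno, resid = ca$resid,
                       depth = ca$y, stringsAsFactors = FALSE)
  ang <- if (is.null(axis)) NA_real_ else
    axis_angle(docked, axis$resno_a, axis$atom_a, axis$resno_b, axis$atom_b)
  list(structure = docked, ca_depths = depths, axis_angle = ang,
       contacts = classify_contacts(docked, contact_cutoff))
}
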