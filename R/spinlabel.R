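# MTSSL (R1) side-chain template, built outward from the backbone by
# internal coordinates. Only chi1 (N-CA-CB-SG) and chi2 (CA-CB-SG-SD) vary;
# dihedrals beyond chi2 are fixed template values. Bond lengths/angles are
# standard values for Cys disulfide and pyrroline-ring geometry; the atom
# that matters downstream is the nitroxide nitrogen N1.
r1_template <- list(
  list(name = "SG", elesy = "S", length = 1.81, angle = 114.2, dihedral = NA),
  list(name = "SD", elesy = "S", length = 2.04, angle = 103.8, dihedral = NA),
  list(name = "CE", elesy = "C", length = 1.81, angle = 103.8, dihedral = -90),
  list(name = "C3", elesy = "C", length = 1.50, angle = 113.5, dihedral = 180),
  list(name = "C4", elesy = "C", length = 1.34, angle = 126.0, dihedral = 77),
  list(name = "C5", elesy = "C", length = 1.51, angle = 112.5, dihedral = 180),
  list(name = "N1", elesy = "N", length = 1.47, angle = 101.0, dihedral = 0),
  list(name = "O1", elesy = "O", length = 1.27, angle = 122.0, dihedral = 180)
)

r1_sidechain_atoms <- c("CB", vapply(r1_template, `[[`, "", "name"))

# bond distance of each label atom from the attachment CA
r1_bond_depth <- stats::setNames(seq_along(r1_sidechain_atoms),
                                 r1_sidechain_atoms)

# Rotamer convention: g+ = +300 deg, t = 180 deg, g- = +60 deg (the
# crystallographically preferred R1 state is (g+, g+) = (300, 300)).
# Canonical preference order for tie-breaking: g+ < t < g-.
rotamer_rank <- function(chi) match(round(chi), c(300, 180, 60))

#' Van der Waals radius lookup by element symbol
#' @param elesy character vector of element symbols.
#' @return numeric radii in Angstrom (C 1.70, N 1.55, O 1.52, S 1.80,
#'   1.70 otherwise).
#' @export
vdw_radius <- function(elesy) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  out <- unname(r[toupper(elesy)])
  out[is.na(out)] <- 1.70
  out
}

residue_atoms <- function(structure, resno, chain = NULL) {
  at <- structure$atoms
  hit <- at$resno == resno
  if (!is.null(chain)) hit <- hit & at$chain == chain
  which(hit)
}

atom_xyz <- function(atoms, idx) as.numeric(atoms[idx, c("x", "y", "z")])

#' Attach an R1 spin-label side chain at a residue
#'
#' Replaces the native side chain beyond C-beta with the MTSSL (R1)
#' template, setting chi1 about N-CA-CB-SG and chi2 about CA-CB-SG-SD. The
#' residue is renamed R1A; the nitroxide nitrogen position and the clash
#' count against the rest of the structure are recorded in the returned
#' label-site record.
#'
#' @param structure a \code{structure_model}.
#' @param resno residue number to label.
#' @param chi1,chi2 side-chain dihedrals in degrees (default the preferred
#'   (g+, g+) = (300, 300) state).
#' @param chain chain id; default the first chain containing \code{resno}.
#' @param ideal_cb build an ideal C-beta when the residue lacks one
#'   (required for glycine targets).
#' @param tolerance clash tolerance in Angstrom passed to
#'   \code{\link{detect_clashes}}.
#' @return list with the modified \code{structure} and the \code{site}
#'   record (resno, chain, chi1, chi2, nitroxide coordinates, clash_count).
#' @export
attach_r1 <- function(structure, resno, chi1 = 300, chi2 = 300,
                      chain = NULL, ideal_cb = FALSE, tolerance = 0.4) {
  stopifnot(inherits(structure, "structure_model"))
  at <- structure$atoms
  idx <- residue_atoms(structure, resno, chain)
  if (length(idx) == 0) stop("residue ", resno, " not found")
  chain <- at$chain[idx[1]]
  idx <- residue_atoms(structure, resno, chain)
  res <- at[idx, ]
  need <- c("N", "CA", "C")
  if (!all(need %in% res$elety))
    stop("residue ", resno, " lacks backbone atoms ",
         paste(setdiff(need, res$elety), collapse = ", "))
  n_xyz <- atom_xyz(at, idx[res$elety == "N"][1])
  ca_xyz <- atom_xyz(at, idx[res$elety == "CA"][1])
  c_xyz <- atom_xyz(at, idx[res$elety == "C"][1])
  if ("CB" %in% res$elety) {
    cb_xyz <- atom_xyz(at, idx[res$elety == "CB"][1])
  } else {
    if (res$resid[1] == "GLY" && !ideal_cb)
      stop("glycine target has no C-beta frame; set ideal_cb = TRUE ",
           "to build an ideal one")
    cb_xyz <- place_atom(c_xyz, n_xyz, ca_xyz, 1.53, 110.4, 122.5)
  }
  # drop native side chain beyond CB
  keep_names <- c("N", "CA", "C", "O", "CB", "OXT")
  drop <- idx[!(res$elety %in% keep_names)]
  if (length(drop)) {
    at <- at[-drop, , drop = FALSE]
    idx <- residue_atoms(structure_model(at), resno, chain)
  }
  # rebuild CB row if the residue had none
  if (!"CB" %in% at$elety[idx]) {
    cb_row <- at[idx[1], ]
    cb_row$elety <- "CB"; cb_row$elesy <- "C"
    cb_row[c("x", "y", "z")] <- as.list(cb_xyz)
    at <- rbind(at[seq_len(max(idx)), ], cb_row,
                if (max(idx) < nrow(at)) at[(max(idx) + 1):nrow(at), ])
    idx <- residue_atoms(structure_model(at), resno, chain)
  }
  # place the R1 chain by internal coordinates
  frame <- list(n_xyz, ca_xyz, cb_xyz)
  placed <- list()
  dihedrals <- c(chi1, chi2,
                 vapply(r1_template[3:8], `[[`, 0, "dihedral"))
  for (k in seq_along(r1_template)) {
    tpl <- r1_template[[k]]
    p <- place_atom(frame[[1]], frame[[2]], frame[[3]],
                    tpl$length, tpl$angle, dihedrals[k])
    placed[[tpl$name]] <- p
    frame <- list(frame[[2]], frame[[3]], p)
  }
  new_rows <- do.call(rbind, lapply(seq_along(r1_template), function(k) {
    tpl <- r1_template[[k]]
    data.frame(type = "ATOM", eleno = 0, elety = tpl$name, resid = "R1A",
               chain = chain, resno = resno,
               x = placed[[tpl$name]][1], y = placed[[tpl$name]][2],
               z = placed[[tpl$name]][3], elesy = tpl$elesy,
               stringsAsFactors = FALSE)
  }))
  at$resid[idx] <- "R1A"
  last <- max(idx)
  at <- rbind(at[seq_len(last), ], new_rows,
              if (last < nrow(at)) at[(last + 1):nrow(at), ])
  at$eleno <- seq_len(nrow(at))
  out <- structure_model(at, structure$label_sites, structure$source)
  site <- list(resno = resno, chain = chain, chi1 = chi1, chi2 = chi2,
               nitroxide = placed[["N1"]], clash_count = NA_integer_)
  site$clash_count <- nrow(detect_clashes(out, site, tolerance = tolerance))
  out$label_sites[[as.character(resno)]] <- site
  list(structure = out, site = site)
}

#' Measure chi1/chi2 of an attached R1 side chain
#' @param structure a labeled \code{structure_model}.
#' @param resno labeled residue number.
#' @param chain optional chain id.
#' @return named numeric vector c(chi1, chi2) in degrees, [0, 360).
#' @export
measure_chi <- function(structure, resno, chain = NULL) {
  at <- structure$atoms
  idx <- residue_atoms(structure, resno, chain)
  get1 <- function(name) {
    i <- idx[at$elety[idx] == name][1]
    if (is.na(i)) stop("atom ", name, " missing at residue ", resno)
    atom_xyz(at, i)
  }
  c(chi1 = dihedral_angle(get1("N"), get1("CA"), get1("CB"), get1("SG")),
    chi2 = dihedral_angle(get1("CA"), get1("CB"), get1("SG"), get1("SD")))
}

#' Detect steric clashes of a label side chain against its environment
#'
#' A pair (label atom, environment atom) clashes when their distance is
#' below r_vdw_i + r_vdw_j - tolerance. Pairs within 3 covalent bonds of
#' the attachment C-alpha are excluded (counting bonds along the side chain
#' and along the backbone through N/C).
#'
#' @param structure a labeled \code{structure_model}.
#' @param site a label-site record (needs \code{resno}, \code{chain}).
#' @param tolerance clash tolerance in Angstrom (default 0.4).
#' @return data.frame with one row per clashing pair: label atom name,
#'   environment atom index/name/residue, distance and cutoff.
#' @export
detect_clashes <- function(structure, site, tolerance = 0.4) {
  at <- structure$atoms
  idx <- residue_atoms(structure, site$resno, site$chain)
  lab <- idx[at$elety[idx] %in% r1_sidechain_atoms]
  env <- setdiff(seq_len(nrow(at)), idx)
  empty <- data.frame(label_atom = character(), env_index = integer(),
                      env_atom = character(), env_resno = integer(),
                      dist = numeric(), cutoff = numeric(),
                      stringsAsFactors = FALSE)
  if (length(lab) == 0 || length(env) == 0) return(empty)
  # backbone bond depth of environment atoms relative to the attachment CA
  env_depth <- rep(Inf, length(env))
  same_chain <- at$chain[env] == site$chain
  prev <- same_chain & at$resno[env] == site$resno - 1
  nxt <- same_chain & at$resno[env] == site$resno + 1
  env_depth[prev & at$elety[env] == "C"] <- 2
  env_depth[prev & at$elety[env] %in% c("O", "CA")] <- 3
  env_depth[nxt & at$elety[env] == "N"] <- 2
  env_depth[nxt & at$elety[env] == "CA"] <- 3
  lab_xyz <- as.matrix(at[lab, c("x", "y", "z")])
  env_xyz <- as.matrix(at[env, c("x", "y", "z")])
  lab_r <- vdw_radius(at$elesy[lab])
  env_r <- vdw_radius(at$elesy[env])
  lab_depth <- r1_bond_depth[at$elety[lab]]
  out <- empty
  for (i in seq_along(lab)) {
    d2 <- colSums((t(env_xyz) - lab_xyz[i, ])^2)
    cutoff <- lab_r[i] + env_r - tolerance
    hit <- d2 < cutoff^2 & (lab_depth[i] + env_depth) > 3
    if (any(hit)) {
      out <- rbind(out, data.frame(
        label_atom = at$elety[lab[i]], env_index = env[hit],
        env_atom = at$elety[env[hit]], env_resno = at$resno[env[hit]],
        dist = sqrt(d2[hit]), cutoff = cutoff[hit],
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Enumerate the nine canonical R1 rotamers at a residue
#'
#' Scores every (chi1, chi2) combination from \{60, 180, 300\} degrees by
#' steric clash count, returning all nine sorted by ascending clash count
#' with ties broken by ascending (chi1, chi2).
#'
#' @inheritParams attach_r1
#' @return data.frame with columns chi1, chi2, clash_count and the
#'   nitroxide coordinates nx, ny, nz of each rotamer.
#' @export
enumerate_rotamers <- function(structure, resno, chain = NULL,
                               ideal_cb = FALSE, tolerance = 0.4) {
  states <- expand.grid(chi1 = c(60, 180, 300), chi2 = c(60, 180, 300))
  res <- do.call(rbind, lapply(seq_len(nrow(states)), function(k) {
    a <- attach_r1(structure, resno, states$chi1[k], states$chi2[k],
                   chain = chain, ideal_cb = ideal_cb, tolerance = tolerance)
    data.frame(chi1 = states$chi1[k], chi2 = states$chi2[k],
               clash_count = a$site$clash_count,
               nx = a$site$nitroxide[1], ny = a$site$nitroxide[2],
               nz = a$site$nitroxide[3])
  }))
  res[order(res$clash_count, res$chi1, res$chi2), , drop = FALSE]
}
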