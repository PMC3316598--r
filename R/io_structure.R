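#' Construct a structure model
#'
#' Light container for atomic coordinates plus spin-label site annotations.
#' \code{atoms} is a data.frame with columns \code{type} ("ATOM"/"HETATM"),
#' \code{eleno}, \code{elety} (atom name), \code{resid} (residue name),
#' \code{chain}, \code{resno}, \code{x}, \code{y}, \code{z}, \code{elesy}
#' (element symbol). \code{label_sites} is a named list of spin-label sites
#' (see \code{\link{attach_r1}}).
#'
#' @param atoms atom data.frame as described above.
#' @param label_sites list of label-site records.
#' @param source free-text provenance tag.
#' @return object of class \code{structure_model}.
#' @export
structure_model <- function(atoms, label_sites = list(), source = "") {
  req <- c("type", "eleno", "elety", "resid", "chain", "resno",
           "x", "y", "z", "elesy")
  stopifnot(is.data.frame(atoms), all(req %in% names(atoms)))
  if (nrow(atoms) > 0 &&
      !all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  for (s in label_sites) {
    hit <- atoms$resno == s$resno
    if (!any(hit)) stop("label site refers to residue ", s$resno,
                        " absent from the structure")
  }
  structure(list(atoms = atoms, label_sites = label_sites, source = source),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues,",
      length(x$label_sites), "label sites",
      if (nzchar(x$source)) paste0("[", x$source, "]") else "", "\n")
  invisible(x)
}

# infer element symbol from a PDB atom name when the element column is blank
infer_element <- function(elety) {
  e <- toupper(sub("^[0-9']*", "", trimws(elety)))
  substr(e, 1, 1)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM and HETATM records via bio3d. Alternate locations are
#' resolved to a single conformer: the altloc with the highest occupancy is
#' kept, ties going to the first listed. Residue numbering follows the file.
#'
#' @param path path to a PDB-format file.
#' @return a \code{structure_model}.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) > 0) {
    # altloc resolution: per (chain, resno, atom name) keep highest occupancy
    alt <- !is.na(at$alt) & at$alt != ""
    if (any(alt)) {
      key <- paste(at$chain, at$resno, at$insert, at$elety)
      occ <- ifelse(is.na(at$o), 1, at$o)
      keep <- rep(TRUE, nrow(at))
      for (k in unique(key[alt])) {
        idx <- which(key == k)
        if (length(idx) > 1) {
          best <- idx[which.max(occ[idx])]  # which.max: first on ties
          keep[setdiff(idx, best)] <- FALSE
        }
      }
      at <- at[keep, , drop = FALSE]
    }
  }
  elesy <- at$elesy
  blank <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[blank] <- infer_element(at$elety[blank])
  atoms <- data.frame(type = at$type, eleno = at$eleno, elety = at$elety,
                      resid = at$resid,
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno,
                      x = at$x, y = at$y, z = at$z,
                      elesy = trimws(elesy),
                      stringsAsFactors = FALSE)
  structure_model(atoms, source = basename(path))
}

#' Write a structure model to a PDB file
#'
#' Coordinates are written at standard PDB precision (0.001 Angstrom), in
#' input atom order. An empty structure produces a header-only file.
#'
#' @param structure a \code{structure_model}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "structure_model"))
  at <- structure$atoms
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(sprintf("REMARK   1 WRITTEN BY EPRDOCK %s",
                     format(nrow(at))), con)
  if (nrow(at) > 0) {
    name4 <- ifelse(nchar(at$elety) < 4 & nchar(at$elesy) == 1,
                    sprintf(" %-3s", at$elety), sprintf("%-4s", at$elety))
    lines <- sprintf(
      "%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$type, at$eleno %% 100000, name4, at$resid, at$chain, at$resno,
      at$x, at$y, at$z, 1.00, 0.00, at$elesy)
    writeLines(lines, con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an accessibility/calibration table
#'
#' CSV with mandatory header and columns \code{site}, \code{role}
#' ("protein"/"calibration"), \code{pi_o2}, \code{pi_o2_sem}, \code{pi_ni},
#' \code{pi_ni_sem}, and optional \code{depth} (signed Angstrom; mandatory
#' and negative for calibration rows, forbidden for protein rows). Extra
#' columns (e.g. a printed Phi column) are carried through untouched.
#'
#' @param path CSV file path.
#' @return list with data.frames \code{protein} and \code{calibration}.
#' @export
read_accessibility_table <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(list(protein = df, calibration = df))
  req <- c("site", "role", "pi_o2", "pi_o2_sem", "pi_ni", "pi_ni_sem")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$role %in% c("protein", "calibration")))
    stop("role must be 'protein' or 'calibration'")
  if (any(df$pi_o2 <= 0 | df$pi_ni <= 0))
    stop("accessibility parameters must be strictly positive ",
         "(depth parameter ln-ratio is undefined otherwise)")
  if (any(df$pi_o2_sem < 0 | df$pi_ni_sem < 0))
    stop("SEMs must be >= 0")
  cal <- df[df$role == "calibration", , drop = FALSE]
  pro <- df[df$role == "protein", , drop = FALSE]
  if (nrow(cal) > 0) {
    if (!"depth" %in% names(df) || any(is.na(cal$depth)))
      stop("calibration rows require a depth")
    if (any(cal$depth >= 0))
      stop("calibration depths must be negative ",
           "(below the mean phosphate plane)")
  }
  if (nrow(pro) > 0 && "depth" %in% names(df) && any(!is.na(pro$depth)))
    stop("protein rows must not carry a depth")
  list(protein = pro, calibration = cal)
}
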