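# Shared fixtures, built in code at test time.

# three-atom PDB text fixture
tiny_pdb_lines <- c(
  "REMARK   1 TINY FIXTURE",
  "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       3.000   3.400   3.250  1.00  0.00           C",
  "END")

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tiny_pdb_lines, path)
  path
}

# a centered synthetic structure with R1 labels attached at (300, 300)
labeled_synthetic <- function(n_label = 10, seed = 7) {
  s <- make_structure(n_sites = n_label, seed = seed)
  resnos <- vapply(s$label_sites, `[[`, 0, "resno")
  s$label_sites <- list()
  for (r in resnos) s <- attach_r1(s, r, 300, 300)$structure
  cent <- center_structure(s)
  list(structure = cent$structure, resnos = unname(resnos))
}

# brute-force clash oracle: independent O(n^2) loop re-implementing the
# contact rule (distance < r_i + r_j - tol, skipping pairs within 3 bonds
# of the attachment CA)
brute_force_clashes <- function(structure, site, tolerance = 0.4) {
  at <- structure$atoms
  lab_names <- c("CB", "SG", "SD", "CE", "C3", "C4", "C5", "N1", "O1")
  depth_lab <- stats::setNames(seq_along(lab_names), lab_names)
  n_hits <- 0
  for (i in seq_len(nrow(at))) {
    if (at$resno[i] != site$resno || !(at$elety[i] %in% lab_names)) next
    for (j in seq_len(nrow(at))) {
      if (at$resno[j] == site$resno && at$chain[j] == site$chain) next
      dl <- depth_lab[[at$elety[i]]]
      de <- Inf
      if (at$chain[j] == site$chain) {
        if (at$resno[j] == site$resno - 1) {
          if (at$elety[j] == "C") de <- 2
          if (at$elety[j] %in% c("O", "CA")) de <- 3
        } else if (at$resno[j] == site$resno + 1) {
          if (at$elety[j] == "N") de <- 2
          if (at$elety[j] == "CA") de <- 3
        }
      }
      if (dl + de <= 3) next
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      if (d < vdw_radius(at$elesy[i]) + vdw_radius(at$elesy[j]) - tolerance)
        n_hits <- n_hits + 1
    }
  }
  n_hits
}

table1_path <- function() {
  system.file("extdata", "grp1_table1_synthetic_calibration.csv",
              package = "eprdock")
}
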