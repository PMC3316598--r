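test_that("dihedral set-then-measure roundtrip is exact for all rotamers", {
  s <- make_structure(6, seed = 21)
  resnos <- vapply(s$label_sites, `[[`, 0, "resno")
  states <- expand.grid(chi1 = c(60, 180, 300), chi2 = c(60, 180, 300))
  for (r in resnos[1:3]) {
    for (k in seq_len(nrow(states))) {
      a <- attach_r1(s, r, states$chi1[k], states$chi2[k])
      chi <- measure_chi(a$structure, r)
      expect_equal(unname(chi["chi1"]), states$chi1[k], tolerance = 0.1)
      expect_equal(unname(chi["chi2"]), states$chi2[k], tolerance = 0.1)
    }
  }
})

test_that("distinct rotamers move the nitroxide by more than 2 Angstrom", {
  s <- make_structure(5, seed = 9)
  r <- s$label_sites[[1]]$resno
  n_gg <- attach_r1(s, r, 300, 300)$site$nitroxide
  n_tt <- attach_r1(s, r, 180, 180)$site$nitroxide
  expect_gt(sqrt(sum((n_gg - n_tt)^2)), 2)
})

test_that("nitroxide placement is equivariant under rigid motion", {
  s <- make_structure(5, seed = 13)
  r <- s$label_sites[[2]]$resno
  t <- docking_transform(33, -70, 5)
  before <- transform_point(attach_r1(s, r, 300, 300)$site$nitroxide, t)
  after <- attach_r1(apply_model(s, t), r, 300, 300)$site$nitroxide
  expect_equal(before, after, tolerance = 1e-9)
})

test_that("attachment requires a backbone and handles glycine frames", {
  s <- make_structure(4, seed = 2)
  r <- s$label_sites[[1]]$resno
  broken <- s
  drop <- which(broken$atoms$resno == r & broken$atoms$elety == "N")
  broken$atoms <- broken$atoms[-drop, ]
  expect_error(attach_r1(broken, r), "backbone")

  gly <- s
  gly$atoms$resid[gly$atoms$resno == r] <- "GLY"
  gly$atoms <- gly$atoms[!(gly$atoms$resno == r & gly$atoms$elety == "CB"), ]
  expect_error(attach_r1(gly, r, ideal_cb = FALSE), "ideal_cb")
  a <- attach_r1(gly, r, 300, 300, ideal_cb = TRUE)
  expect_equal(unname(measure_chi(a$structure, r)["chi1"]), 300,
               tolerance = 0.1)
})

test_that("rotamer enumeration scores all nine states, isolated site clash-free", {
  # single isolated residue: no environment, so no clashes anywhere
  s <- make_structure(4, seed = 5)
  r <- s$label_sites[[1]]$resno
  iso <- s
  iso$atoms <- iso$atoms[iso$atoms$resno == r, ]
  iso$label_sites <- list()
  rot <- enumerate_rotamers(iso, r)
  expect_equal(nrow(rot), 9)
  expect_true(all(rot$clash_count == 0))
  expect_equal(nrow(unique(rot[, c("chi1", "chi2")])), 9)
})

test_that("an obstacle on the (g+,g+) arm penalizes only that region", {
  s <- make_structure(4, seed = 5)
  r <- s$label_sites[[1]]$resno
  iso <- s
  iso$atoms <- iso$atoms[iso$atoms$resno == r, ]
  iso$label_sites <- list()
  n_gg <- attach_r1(iso, r, 300, 300)$site$nitroxide
  obstacle <- data.frame(type = "ATOM", eleno = 999L, elety = "CA",
                         resid = "ALA", chain = "A", resno = r + 50L,
                         x = n_gg[1], y = n_gg[2], z = n_gg[3], elesy = "C")
  iso$atoms <- rbind(iso$atoms, obstacle)
  rot <- enumerate_rotamers(iso, r)
  gg <- rot[rot$chi1 == 300 & rot$chi2 == 300, ]
  expect_gt(gg$clash_count, 0)
  expect_true(any(rot$clash_count == 0))
  # sorted ascending by clash count
  expect_true(!is.unsorted(rot$clash_count))
})

test_that("clash detection follows the distance rule and matches brute force", {
  # two carbons 10 A apart: no clash; 2.0 A apart: clash (cutoff 3.0)
  mk <- function(d) {
    at <- data.frame(
      type = "ATOM", eleno = 1:7,
      elety = c("N", "CA", "C", "O", "CB", "SG", "CA"),
      resid = c(rep("R1A", 6), "ALA"), chain = "A",
      resno = c(rep(1L, 6), 5L),
      x = c(0, 1.5, 2.2, 2.2, 1.8, 3.2, 3.2 + d),
      y = c(0, 0, 1.2, 2.4, -1.4, -2.0, -2.0),
      z = 0, elesy = c("N", "C", "C", "O", "C", "S", "C"))
    structure_model(at)
  }
  site <- list(resno = 1L, chain = "A")
  expect_equal(nrow(detect_clashes(mk(10), site)), 0)
  near <- detect_clashes(mk(0.5), site)  # SG..CA pair ~ 0.5+? well below cutoff
  expect_gt(nrow(near), 0)
  expect_true(all(near$dist < near$cutoff))
})

test_that("clash list size equals the brute-force all-pairs oracle", {
  lab <- labeled_synthetic(n_label = 6, seed = 31)
  for (r in lab$resnos[1:4]) {
    site <- lab$structure$label_sites[[as.character(r)]]
    fast <- detect_clashes(lab$structure, site)
    expect_equal(nrow(fast), brute_force_clashes(lab$structure, site))
  }
})
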