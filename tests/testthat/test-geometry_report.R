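test_that("apply_model is rigid and the identity model is a no-op", {
  s <- make_structure(6, seed = 4)
  s <- center_structure(s)$structure
  same <- apply_model(s, docking_transform(0, 0, 0))
  expect_equal(same$atoms[, c("x", "y", "z")], s$atoms[, c("x", "y", "z")])
  moved <- apply_model(s, docking_transform(-11.6, -59.8, -50.2))
  expect_equal(as.numeric(dist(as.matrix(moved$atoms[, c("x", "y", "z")]))),
               as.numeric(dist(as.matrix(s$atoms[, c("x", "y", "z")]))),
               tolerance = 1e-9)
  # transformed nitroxide y equals the membrane position used in the fit
  t <- docking_transform(-11.6, -59.8, 8)
  nx <- t(vapply(s$label_sites, `[[`, numeric(3), "nitroxide"))
  moved2 <- apply_model(s, t)
  nx2 <- t(vapply(moved2$label_sites, `[[`, numeric(3), "nitroxide"))
  expect_equal(nx2[, 2], transform_point(nx, t)[, 2], tolerance = 1e-12)
})

test_that("residue depth is the signed y coordinate", {
  at <- data.frame(type = "ATOM", eleno = 1:2, elety = c("CA", "CA"),
                   resid = "ALA", chain = "A", resno = 1:2,
                   x = c(5, 0), y = c(0, 2.4), z = c(-3, 0), elesy = "C")
  s <- structure_model(at)
  expect_equal(residue_depth(s, 1), 0.0)
  expect_equal(residue_depth(s, 2), 2.4)
  expect_error(residue_depth(s, 1, atom = "CB"), "not found")
  # minimum-over-CA query equals a brute-force scan
  s2 <- make_structure(5, seed = 6)
  ca <- s2$atoms[s2$atoms$elety == "CA", ]
  depths <- vapply(ca$resno, function(r) residue_depth(s2, r), numeric(1))
  expect_equal(min(depths), min(ca$y))
  expect_equal(ca$resno[which.min(depths)], ca$resno[which.min(ca$y)])
})

test_that("axis angle matches closed forms and its invariances", {
  mk <- function(d) {
    at <- data.frame(type = "ATOM", eleno = 1:2, elety = "CA",
                     resid = "ALA", chain = "A", resno = 1:2,
                     x = c(0, d[1]), y = c(0, d[2]), z = c(0, d[3]),
                     elesy = "C")
    structure_model(at)
  }
  expect_equal(axis_angle(mk(c(1, 0, 0)), 1, "CA", 2, "CA"), 0)
  expect_equal(axis_angle(mk(c(0, 1, 0)), 1, "CA", 2, "CA"), 90)
  expect_equal(axis_angle(mk(c(1, 1, 0)), 1, "CA", 2, "CA"), 45)
  expect_error(axis_angle(mk(c(0, 0, 0)), 1, "CA", 2, "CA"), "coincident")
  # invariance under translation and rotation about y
  d <- c(2, 1.3, -0.7)
  base <- vector_plane_angle(d)
  s <- mk(d)
  s$atoms[, c("x", "y", "z")] <- s$atoms[, c("x", "y", "z")] +
    rep(c(10, -4, 2), each = 2)
  expect_equal(axis_angle(s, 1, "CA", 2, "CA"), base, tolerance = 1e-9)
  ry <- matrix(c(cos(0.7), 0, sin(0.7), 0, 1, 0, -sin(0.7), 0, cos(0.7)),
               3, 3)
  s2 <- mk(as.numeric(ry %*% d))
  expect_equal(axis_angle(s2, 1, "CA", 2, "CA"), base, tolerance = 1e-9)
})

test_that("contact classification partitions contacting residues", {
  at <- rbind(
    data.frame(type = "ATOM", eleno = 1:3, elety = c("N", "CA", "NZ"),
               resid = "LYS", chain = "A", resno = 1L,
               x = 0, y = c(10, 10, 1), z = 0, elesy = c("N", "C", "N")),
    data.frame(type = "ATOM", eleno = 4:5, elety = c("CA", "OD1"),
               resid = "ASP", chain = "A", resno = 2L,
               x = 3, y = c(10, 2), z = 0, elesy = c("C", "O")),
    data.frame(type = "ATOM", eleno = 6:7, elety = c("CA", "CB"),
               resid = "VAL", chain = "A", resno = 3L,
               x = 6, y = c(10, 30), z = 0, elesy = "C"))
  s <- structure_model(at)
  ct <- classify_contacts(s, cutoff = 3)
  expect_equal(ct$basic$resno, 1L)
  expect_equal(ct$acidic$resno, 2L)
  expect_equal(nrow(ct$hydrophobic_polar), 0)
  # partition is disjoint and exhaustive over contacting residues
  all_hit <- c(ct$basic$resno, ct$acidic$resno, ct$hydrophobic_polar$resno)
  expect_equal(anyDuplicated(all_hit), 0)
  # everything above the cutoff: empty lists
  ct2 <- classify_contacts(s, cutoff = -50)
  expect_equal(nrow(ct2$basic) + nrow(ct2$acidic) +
                 nrow(ct2$hydrophobic_polar), 0)
})

test_that("headgroup displacement recovers constructed perturbations", {
  # flat hexagonal ring in the x-z plane, phosphate below it
  theta <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- cbind(1.4 * cos(theta), 0, 1.4 * sin(theta))
  phos <- c(0, -3, 0)
  ref <- list(depth = -3, twist = 0, tilt = 0)
  expect_equal(headgroup_displacement(phos, ring, ref),
               c(d_depth = 0, d_twist = 0, d_tilt = 0), tolerance = 1e-9)
  # rigid +2 A lift
  expect_equal(
    unname(headgroup_displacement(phos + c(0, 2, 0),
                                  sweep(ring, 2, c(0, 2, 0), `+`), ref)[1]),
    2, tolerance = 1e-9)
  # 27-degree rotation about an in-plane axis changes tilt by 27
  rx <- matrix(c(1, 0, 0, 0, cos(0.4712389), -sin(0.4712389),
                 0, sin(0.4712389), cos(0.4712389)), 3, 3, byrow = TRUE)
  tilted <- ring %*% t(rx)
  out <- headgroup_displacement(phos, tilted, ref)
  expect_equal(unname(out["d_tilt"]), 27, tolerance = 1e-6)
})

test_that("geometry report is deterministic given model and structure", {
  lab <- labeled_synthetic(6, seed = 12)
  mdl_t <- docking_transform(-11.6, -59.8, 8)
  r1 <- geometry_report(lab$structure, mdl_t)
  r2 <- geometry_report(lab$structure, mdl_t)
  expect_identical(r1$ca_depths, r2$ca_depths)
  expect_identical(r1$contacts, r2$contacts)
})
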