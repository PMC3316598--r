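#' Default synthetic ground truth
#'
#' The default study design mirrors the real experiment's scale: a docking
#' pose with rotations of -11.6 and -59.8 degrees, the protein body held
#' 20 Angstrom above the phosphate plane so that docking is shallow -- the
#' deepest label sites just pass the plane and the protein depth parameters
#' span roughly -1.8 to +0.5, like the measured table -- a hyperbola whose
#' aqueous plateau is -1.8, four calibration lipid labels on the linear
#' branch, and Gaussian Phi noise at the SEM scale of the measured table
#' (~0.02).
#'
#' @param seed RNG seed stored with the truth.
#' @return list of class \code{synthetic_truth}: transform, hyperbola,
#'   sigma_phi, calibration_depths, seed.
#' @export
default_truth <- function(seed = 1) {
  structure(list(
    transform = docking_transform(-11.6, -59.8, 20),
    hyperbola = hyperbola_params(-0.15, -1.05, -1.8, 0.04),
    sigma_phi = 0.02,
    calibration_depths = c(-8, -11, -13, -16),
    seed = seed), class = "synthetic_truth")
}

#' Generate a synthetic labeled structure
#'
#' Builds a rigid globular body of backbone pseudo-residues (N, CA, C atoms)
#' on an ellipsoid surface approximating a beta-sandwich footprint, and
#' places \code{n_sites} surface label sites whose nitroxide positions sit
#' 6.5-8.5 Angstrom outward of the backbone. Deterministic per seed.
#'
#' @param n_sites number of label sites (>= 3).
#' @param seed RNG seed.
#' @param n_residues number of backbone pseudo-residues (default 140).
#' @param semiaxes ellipsoid semi-axes in Angstrom.
#' @return a \code{structure_model} with \code{label_sites} carrying
#'   nitroxide coordinates.
#' @export
make_structure <- function(n_sites = 18, seed = 1, n_residues = 140,
                           semiaxes = c(30, 22, 19)) {
  if (n_sites < 3) stop("need at least 3 label sites")
  stopifnot(n_residues >= n_sites)
  with_seed(seed, {
    # deterministic golden-spiral points on the unit sphere -> ellipsoid
    k <- seq_len(n_residues)
    zu <- (2 * k - 1) / n_residues - 1
    phi_ang <- k * pi * (3 - sqrt(5))
    u <- cbind(sqrt(1 - zu^2) * cos(phi_ang),
               sqrt(1 - zu^2) * sin(phi_ang), zu)
    ca <- sweep(u, 2, semiaxes, `*`)
    # local backbone tetrad around each CA, with the C-beta pointing along
    # the outward surface normal: labeling targets on real proteins are
    # solvent-exposed sites whose side chains project into solvent
    rows <- vector("list", n_residues)
    for (i in k) {
      nrm <- u[i, ] / sqrt(sum(u[i, ]^2))
      tang <- pracma_cross(nrm, c(0, 0, 1))
      if (sqrt(sum(tang^2)) < 1e-6) tang <- pracma_cross(nrm, c(0, 1, 0))
      tang <- tang / sqrt(sum(tang^2))
      bno <- pracma_cross(nrm, tang)
      jit <- stats::rnorm(3, 0, 0.08)
      cb <- ca[i, ] + 1.53 * nrm
      # N and C at ~110 deg polar angle from the CB direction, azimuths
      # 122.5 deg apart so the N-CA-C angle is ~111 deg
      dir_at <- function(azim) {
        cos(deg2rad(110.4)) * nrm +
          sin(deg2rad(110.4)) * (cos(azim) * tang + sin(azim) * bno)
      }
      azim0 <- stats::runif(1, 0, 2 * pi)
      n_at <- ca[i, ] + 1.46 * dir_at(azim0) + jit
      c_at <- ca[i, ] + 1.52 * dir_at(azim0 + deg2rad(122.5)) - jit
      rows[[i]] <- data.frame(
        type = "ATOM", eleno = 0,
        elety = c("N", "CA", "C", "CB"), resid = "ALA", chain = "A",
        resno = i,
        x = c(n_at[1], ca[i, 1], c_at[1], cb[1]),
        y = c(n_at[2], ca[i, 2], c_at[2], cb[2]),
        z = c(n_at[3], ca[i, 3], c_at[3], cb[3]),
        elesy = c("N", "C", "C", "C"), stringsAsFactors = FALSE)
    }
    atoms <- do.call(rbind, rows)
    atoms$eleno <- seq_len(nrow(atoms))
    site_res <- sort(sample.int(n_residues, n_sites))
    sites <- stats::setNames(lapply(site_res, function(i) {
      nrm <- u[i, ] / sqrt(sum(u[i, ]^2))
      arm <- stats::runif(1, 6.5, 8.5)
      list(resno = i, chain = "A", chi1 = NA_real_, chi2 = NA_real_,
           nitroxide = ca[i, ] + arm * nrm, clash_count = 0L)
    }), as.character(site_res))
    structure_model(atoms, label_sites = sites, source = "synthetic")
  })
}

#' Simulate a depth dataset from a labeled structure and a ground truth
#'
#' Protein rows take Phi from the forward model evaluated at the (centered)
#' nitroxide coordinates under the truth transform, plus Gaussian noise;
#' calibration rows evaluate the hyperbola directly at the known lipid
#' depths. Row SEMs are set to the noise SD.
#'
#' @param structure a \code{structure_model} with label sites (will be
#'   centered on its ATOM records).
#' @param truth a \code{synthetic_truth} (see \code{\link{default_truth}}).
#' @param calibration_depths signed depths of the calibration labels,
#'   Angstrom (negative); default from the truth.
#' @param sigma_phi noise SD on Phi; default from the truth.
#' @param seed RNG seed; default from the truth.
#' @return list: \code{dataset} (a \code{\link{depth_dataset}}),
#'   \code{structure} (the centered structure), \code{site_resno}, and the
#'   noiseless \code{phi_true}.
#' @export
simulate_dataset <- function(structure, truth = default_truth(),
                             calibration_depths = truth$calibration_depths,
                             sigma_phi = truth$sigma_phi,
                             seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (any(calibration_depths >= 0))
    stop("calibration depths must be negative (membrane interior)")
  cent <- center_structure(structure)
  structure <- cent$structure
  sites <- structure$label_sites
  if (length(sites) == 0) stop("structure carries no label sites")
  nx <- t(vapply(sites, `[[`, numeric(3), "nitroxide"))
  prot <- data.frame(site = paste0("S", vapply(sites, `[[`, 0, "resno")),
                     phi = NA_real_, phi_sem = sigma_phi,
                     x = nx[, 1], y = nx[, 2], z = nx[, 3])
  cal <- data.frame(site = paste0("CAL", seq_along(calibration_depths)),
                    phi = NA_real_, phi_sem = sigma_phi,
                    depth = calibration_depths)
  ds <- depth_dataset(prot, cal)
  phi_true <- predicted_phi(ds, truth$transform, truth$hyperbola)
  ds$phi <- with_seed(seed,
                      phi_true + stats::rnorm(nrow(ds), 0, sigma_phi))
  list(dataset = ds, structure = structure,
       site_resno = vapply(sites, `[[`, 0, "resno"), phi_true = phi_true)
}

#' Membrane-normal direction of a docking transform
#'
#' Unit vector, in the body frame, that maps onto the bilayer normal (+y)
#' under the transform's rotations; the physically identifiable content of
#' (theta_x, theta_z). Misorientation between a fitted and a true transform
#' is the angle between their normals.
#'
#' @param t a \code{docking_transform}.
#' @return unit length-3 vector.
#' @export
membrane_normal <- function(t) {
  tx <- deg2rad(t$theta_x)
  tz <- deg2rad(t$theta_z)
  c(sin(tz), cos(tz) * cos(tx), -cos(tz) * sin(tx))
}

#' Misorientation angle between two docking transforms
#' @param t1,t2 \code{docking_transform} objects.
#' @return angle between their membrane normals, degrees in [0, 180].
#' @export
misorientation <- function(t1, t2) {
  d <- sum(membrane_normal(t1) * membrane_normal(t2))
  rad2deg(acos(min(max(d, -1), 1)))
}

truth_par <- function(truth) {
  c(theta_x = truth$transform$theta_x, theta_z = truth$transform$theta_z,
    y_trans = truth$transform$y_trans, m = truth$hyperbola$m,
    i = truth$hyperbola$i, b = truth$hyperbola$b, c = truth$hyperbola$c)
}

model_par <- function(model) {
  c(theta_x = model$transform$theta_x, theta_z = model$transform$theta_z,
    y_trans = model$transform$y_trans, m = model$hyperbola$m,
    i = model$hyperbola$i, b = model$hyperbola$b, c = model$hyperbola$c)
}

#' Construct a planted-rotamer refinement fixture
#'
#' Builds a labeled synthetic structure (all R1 side chains at the
#' preferred (g+, g+) state) and a noiseless depth dataset in which one
#' site's Phi was generated from a different, clash-free rotamer of that
#' site -- the known answer a rotamer-refinement pass must recover. The
#' planted site/rotamer pair is chosen to maximize the separation between
#' the planted arm's predicted Phi and every alternative rotamer's, so the
#' correct selection is unambiguous; structures are regenerated from
#' deterministic seed offsets until the separation reaches
#' \code{min_separation} (or \code{max_tries} is exhausted, keeping the
#' best candidate).
#'
#' @param seed base RNG seed.
#' @param n_sites number of label sites.
#' @param truth a \code{synthetic_truth} used to generate Phi.
#' @param min_separation required Phi separation (Phi units).
#' @param max_tries maximum structure regenerations.
#' @return list: \code{structure} (centered, labeled), \code{dataset},
#'   \code{resnos}, \code{wrong_site} (residue number of the corrupted
#'   site), \code{planted} (chi1, chi2 of the generating rotamer) and the
#'   achieved \code{separation}.
#' @export
make_refinement_fixture <- function(seed = 1, n_sites = 18,
                                    truth = default_truth(seed),
                                    min_separation = 0.45,
                                    max_tries = 12) {
  best <- NULL
  for (try in seq_len(max_tries) - 1) {
    s <- make_structure(n_sites, seed = seed + 101 * try)
    resnos <- vapply(s$label_sites, `[[`, 0, "resno")
    s$label_sites <- list()
    for (r in resnos) s <- attach_r1(s, r, 300, 300)$structure
    s <- center_structure(s)$structure
    nx <- t(vapply(s$label_sites, `[[`, numeric(3), "nitroxide"))
    rot_all <- lapply(resnos, function(r) enumerate_rotamers(s, r))
    # per site: clash-free rotamers and their predicted Phi under truth
    cand <- NULL
    for (k in seq_along(resnos)) {
      rot <- rot_all[[k]]
      free <- rot[rot$clash_count == 0, , drop = FALSE]
      gg_free <- any(free$chi1 == 300 & free$chi2 == 300)
      if (!gg_free || nrow(free) < 2) next
      pf <- hyperbola(
        transform_point(as.matrix(free[, c("nx", "ny", "nz")]),
                        truth$transform)[, 2], truth$hyperbola)
      for (j in seq_len(nrow(free))) {
        if (free$chi1[j] == 300 && free$chi2[j] == 300) next
        sep <- min(abs(pf[-j] - pf[j]))
        if (is.null(cand) || sep > cand$sep)
          cand <- list(k = k, chi1 = free$chi1[j], chi2 = free$chi2[j],
                       nx = c(free$nx[j], free$ny[j], free$nz[j]),
                       sep = sep)
      }
    }
    if (!is.null(cand) &&
        (is.null(best) || cand$sep > best$cand$sep))
      best <- list(structure = s, resnos = resnos, nx = nx, cand = cand)
    if (!is.null(best) && best$cand$sep >= min_separation) break
  }
  if (is.null(best)) stop("could not construct a refinement fixture")
  s <- best$structure
  resnos <- best$resnos
  nx <- best$nx
  cand <- best$cand
  gen <- nx
  gen[cand$k, ] <- cand$nx
  rg <- transform_point(gen, truth$transform)[, 2]
  prot <- data.frame(site = paste0("S", resnos),
                     phi = hyperbola(rg, truth$hyperbola),
                     phi_sem = truth$sigma_phi,
                     x = nx[, 1], y = nx[, 2], z = nx[, 3])
  cal <- data.frame(site = paste0("CAL", seq_along(truth$calibration_depths)),
                    phi_sem = truth$sigma_phi,
                    depth = truth$calibration_depths)
  cal$phi <- hyperbola(cal$depth, truth$hyperbola)
  list(structure = s, dataset = depth_dataset(prot, cal),
       resnos = unname(resnos), wrong_site = resnos[[cand$k]],
       planted = c(chi1 = cand$chi1, chi2 = cand$chi2),
       separation = cand$sep)
}

#' Parameter-recovery experiment on the synthetic design
#'
#' Simulates \code{n_replicates} noisy datasets from one structure/truth,
#' fits each by \code{\link{multistart_fit}}, and summarizes per-parameter
#' bias, RMSE and (optionally) the coverage of reported 1-sigma intervals.
#' Individual fit failures are recorded, not fatal.
#'
#' @param n_replicates number of replicates (>= 10).
#' @param truth a \code{synthetic_truth}.
#' @param sigma_phi Phi noise SD per replicate.
#' @param seed master seed; replicate r uses seed + r.
#' @param n_sites label sites in the synthetic structure.
#' @param angle_grid multistart grid (default 3 x 3 over -60/0/60).
#' @param coverage_method NULL to skip coverage, else "covariance" or
#'   "montecarlo".
#' @return list: \code{summary} data.frame (parameter, truth, bias, rmse,
#'   sd, mae, coverage), \code{estimates} matrix, per-replicate
#'   membrane-normal misorientation \code{normal_err_deg} with its RMSE
#'   \code{normal_rmse_deg}, and \code{n_failed}.
#' @export
recovery_experiment <- function(n_replicates = 100, truth = default_truth(),
                                sigma_phi = 0.05, seed = 1, n_sites = 18,
                                angle_grid = NULL,
                                coverage_method = NULL) {
  if (n_replicates < 10) stop("need at least 10 replicates")
  if (is.null(angle_grid))
    angle_grid <- expand.grid(theta_x = c(-60, 0, 60),
                              theta_z = c(-60, 0, 60))
  str0 <- make_structure(n_sites = n_sites, seed = seed)
  tp <- truth_par(truth)
  est <- matrix(NA_real_, n_replicates, 7,
                dimnames = list(NULL, names(tp)))
  cover <- matrix(NA, n_replicates, 7)
  normal_err <- rep(NA_real_, n_replicates)
  n_failed <- 0
  for (r in seq_len(n_replicates)) {
    sim <- simulate_dataset(str0, truth, sigma_phi = sigma_phi,
                            seed = seed + r)
    mdl <- tryCatch(multistart_fit(sim$dataset, angle_grid),
                    error = function(e) NULL)
    if (is.null(mdl)) { n_failed <- n_failed + 1; next }
    est[r, ] <- model_par(mdl)
    normal_err[r] <- misorientation(mdl$transform, truth$transform)
    if (!is.null(coverage_method)) {
      un <- tryCatch(estimate_uncertainties(mdl, sim$dataset,
                                            method = coverage_method,
                                            seed = seed + r),
                     error = function(e) rep(NA_real_, 7))
      cover[r, ] <- abs(est[r, ] - tp) <= un
    }
  }
  ok <- stats::complete.cases(est)
  summary <- data.frame(
    parameter = names(tp), truth = unname(tp),
    bias = colMeans(est[ok, , drop = FALSE]) - tp,
    rmse = sqrt(colMeans(sweep(est[ok, , drop = FALSE], 2, tp)^2)),
    sd = apply(est[ok, , drop = FALSE], 2, stats::sd),
    mae = apply(abs(sweep(est[ok, , drop = FALSE], 2, tp)), 2,
                stats::median),
    coverage = if (is.null(coverage_method)) NA_real_
               else colMeans(cover[ok, , drop = FALSE], na.rm = TRUE),
    row.names = NULL)
  list(summary = summary, estimates = est, n_failed = n_failed,
       normal_err_deg = normal_err,
       normal_rmse_deg = sqrt(mean(normal_err[ok]^2)))
}
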