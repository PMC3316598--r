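#' Assemble a depth dataset
#'
#' Unified table consumed by the docking fit: protein rows carry measured
#' Phi and nitroxide coordinates in the centered structure frame; calibration
#' rows carry measured Phi and a known signed lipid-label depth (negative,
#' below the mean phosphate plane).
#'
#' @param protein data.frame with columns site, phi, phi_sem, x, y, z.
#' @param calibration data.frame with columns site, phi, phi_sem, depth.
#' @return data.frame with a logical \code{is_protein} column.
#' @export
depth_dataset <- function(protein, calibration) {
  p <- data.frame(site = protein$site, phi = protein$phi,
                  phi_sem = protein$phi_sem, is_protein = TRUE,
                  x = protein$x, y = protein$y, z = protein$z,
                  depth = NA_real_, stringsAsFactors = FALSE)
  k <- data.frame(site = calibration$site, phi = calibration$phi,
                  phi_sem = calibration$phi_sem, is_protein = FALSE,
                  x = NA_real_, y = NA_real_, z = NA_real_,
                  depth = calibration$depth, stringsAsFactors = FALSE)
  if (nrow(p) > 0 && any(!is.finite(as.matrix(p[, c("x", "y", "z")]))))
    stop("protein rows require finite coordinates")
  if (nrow(k) > 0 && any(!is.finite(k$depth)))
    stop("calibration rows require a finite depth")
  rbind(p, k)
}

#' Center a structure on the mean of selected atoms
#'
#' The fit convention places the origin at the (unweighted) mean position of
#' the protein ATOM records; HETATM groups (ligand, waters) are excluded by
#' default.
#'
#' @param structure a \code{structure_model}.
#' @param selection "protein" (ATOM records only, default) or "all".
#' @return list with the centered \code{structure} and the \code{center}
#'   vector that was subtracted.
#' @export
center_structure <- function(structure, selection = c("protein", "all")) {
  selection <- match.arg(selection)
  at <- structure$atoms
  sel <- if (selection == "protein") at$type == "ATOM" else rep(TRUE, nrow(at))
  if (!any(sel)) stop("empty selection: nothing to center on")
  ctr <- colMeans(at[sel, c("x", "y", "z")])
  at$x <- at$x - ctr[1]; at$y <- at$y - ctr[2]; at$z <- at$z - ctr[3]
  out <- structure_model(at, structure$label_sites, structure$source)
  out$label_sites <- lapply(out$label_sites, function(s) {
    s$nitroxide <- s$nitroxide - as.numeric(ctr); s
  })
  list(structure = out, center = as.numeric(ctr))
}

check_identifiability <- function(dataset) {
  np <- sum(dataset$is_protein)
  nc <- sum(!dataset$is_protein)
  if (nrow(dataset) < 7 || nc < 2 || np < 3)
    stop("unidentifiable dataset: need >= 7 rows with >= 3 protein and ",
         ">= 2 calibration rows (got ", np, " protein, ", nc, " calibration)")
  if (stats::sd(dataset$phi) == 0)
    stop("unidentifiable dataset: no spread in measured Phi")
  xyz <- as.matrix(dataset[dataset$is_protein, c("x", "y", "z")])
  if (max(apply(xyz, 2, stats::sd)) < 1e-8)
    stop("unidentifiable dataset: protein nitroxide positions are ",
         "coincident, the transform cannot be resolved")
}

par_to_model <- function(par) {
  list(transform = docking_transform(par[1], par[2], par[3]),
       hyperbola = hyperbola_params(par[4], par[5], par[6], max(par[7], 0)))
}

#' Joint hyperbola / rigid-body nonlinear least-squares fit
#'
#' Estimates the seven unknowns (theta_x, theta_z, y_trans, m, i, b, c) by
#' minimizing sum of w * (Phi_obs - Phi_pred)^2 over the full dataset, with
#' \code{\link{predicted_phi}} as forward model. Residuals are unweighted by
#' default; set \code{weighted = TRUE} for 1/sem^2 weighting. The curvature
#' c is kept >= 1e-9 by a box bound; fitted angles are reported in the
#' canonical branch (see \code{\link{canonicalize_transform}}).
#'
#' @param dataset a \code{\link{depth_dataset}}.
#' @param init list with \code{transform} (docking_transform) and
#'   \code{hyperbola} (hyperbola_params) starting values.
#' @param weighted logical; use 1/sem^2 residual weights.
#' @return object of class \code{docking_model}: transform, hyperbola,
#'   residuals, fitted values, correlation \code{r} between measured and
#'   fitted Phi, cost, convergence info, and the internal fit object.
#' @export
fit_docking <- function(dataset, init, weighted = FALSE) {
  check_identifiability(dataset)
  w <- if (weighted) {
    if (any(dataset$phi_sem <= 0))
      stop("weighted fit requires strictly positive phi_sem")
    1 / dataset$phi_sem^2
  } else rep(1, nrow(dataset))
  sw <- sqrt(w)
  resid_fn <- function(par) {
    mdl <- par_to_model(par)
    sw * (dataset$phi - predicted_phi(dataset, mdl$transform, mdl$hyperbola))
  }
  par0 <- c(init$transform$theta_x, init$transform$theta_z,
            init$transform$y_trans, init$hyperbola$m, init$hyperbola$i,
            init$hyperbola$b, max(init$hyperbola$c, 1e-9))
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    lower = c(rep(-Inf, 6), 1e-9),
    control = minpack.lm::nls.lm.control(
      maxiter = 1000, ftol = 1e-15, ptol = 1e-15, gtol = 1e-15))
  if (fit$info == 0) stop("docking fit failed to converge: ", fit$message)
  mdl <- par_to_model(fit$par)
  mdl$transform <- canonicalize_transform(mdl$transform)
  pred <- predicted_phi(dataset, mdl$transform, mdl$hyperbola)
  res <- dataset$phi - pred
  r <- if (stats::sd(pred) == 0) NA_real_ else stats::cor(dataset$phi, pred)
  structure(list(transform = mdl$transform, hyperbola = mdl$hyperbola,
                 residuals = res, fitted = pred, r = r,
                 cost = sum(w * res^2), weighted = weighted,
                 info = list(niter = fit$niter, message = fit$message,
                             info = fit$info),
                 fit = fit, n = nrow(dataset)),
            class = "docking_model")
}

#' @export
print.docking_model <- function(x, ...) {
  cat(sprintf(paste0("docking_model: theta_x = %.3f deg, theta_z = %.3f deg, ",
                     "y_trans = %.3f A\n  hyperbola m = %.4f, i = %.4f, ",
                     "b = %.4f, c = %.5f\n  R = %.4f, cost = %.4g (n = %d)\n"),
              x$transform$theta_x, x$transform$theta_z, x$transform$y_trans,
              x$hyperbola$m, x$hyperbola$i, x$hyperbola$b, x$hyperbola$c,
              x$r, x$cost, x$n))
  invisible(x)
}

# data-driven initialization of the five non-angle parameters: (m, i) from a
# straight line through the calibration rows, b from the most aqueous
# protein Phi, c at its floor, and y_trans chosen so the median protein
# label lands at the linear-branch position implied by the median Phi.
default_init <- function(dataset, theta_x, theta_z) {
  cal <- dataset[!dataset$is_protein, ]
  lf <- stats::lm(phi ~ depth, data = cal)
  m0 <- unname(stats::coef(lf)[2])
  i0 <- unname(stats::coef(lf)[1])
  if (!is.finite(m0) || m0 == 0) { m0 <- -0.1; i0 <- mean(cal$phi) }
  b0 <- min(dataset$phi[dataset$is_protein])
  prot <- dataset[dataset$is_protein, ]
  rot_y <- transform_point(as.matrix(prot[, c("x", "y", "z")]),
                           docking_transform(theta_x, theta_z, 0))[, 2]
  phi_med <- stats::median(prot$phi)
  r_target <- (phi_med - i0) / m0
  r_target <- min(max(r_target, -30), 10)
  list(transform = docking_transform(theta_x, theta_z,
                                     r_target - stats::median(rot_y)),
       hyperbola = hyperbola_params(m0, i0, b0, 1e-6))
}

#' Multistart docking fit over an angle grid
#'
#' Runs \code{\link{fit_docking}} from every (theta_x, theta_z) start on the
#' grid, with the remaining five parameters initialized from the data, and
#' returns the converged model with the lowest cost (first in grid order on
#' ties). Deterministic given the grid.
#'
#' @param dataset a \code{\link{depth_dataset}}.
#' @param angle_grid data.frame with columns theta_x, theta_z (degrees);
#'   default the 5 x 5 grid over \{-90, -45, 0, 45, 90\}^2.
#' @param weighted passed to \code{\link{fit_docking}}.
#' @return best \code{docking_model}, with the number of successful starts
#'   in \code{$info$n_starts_ok}.
#' @export
multistart_fit <- function(dataset, angle_grid = NULL, weighted = FALSE) {
  if (is.null(angle_grid))
    angle_grid <- expand.grid(theta_x = c(-90, -45, 0, 45, 90),
                              theta_z = c(-90, -45, 0, 45, 90))
  stopifnot(nrow(angle_grid) >= 1)
  best <- NULL
  errs <- character()
  n_ok <- 0
  for (k in seq_len(nrow(angle_grid))) {
    tx <- angle_grid$theta_x[k]
    tz <- angle_grid$theta_z[k]
    # each grid point seeds a local search from its stated orientation and
    # from the antipodal membrane normal (theta_x + 180, -theta_z): depth
    # data alone cannot steer LM across hemispheres, so both are explored
    mdl <- NULL
    for (start in list(c(tx, tz), c(tx + 180, -tz))) {
      cand <- tryCatch(
        fit_docking(dataset, default_init(dataset, start[1], start[2]),
                    weighted = weighted),
        error = function(e) e)
      if (inherits(cand, "error")) {
        errs <- c(errs, conditionMessage(cand))
      } else if (is.null(mdl) || cand$cost < mdl$cost) mdl <- cand
    }
    if (is.null(mdl)) next
    n_ok <- n_ok + 1
    if (is.null(best) || mdl$cost < best$cost) best <- mdl
  }
  if (is.null(best))
    stop("all ", nrow(angle_grid), " starts failed: ",
         paste(unique(errs), collapse = "; "))
  best$info$n_starts_ok <- n_ok
  best
}

#' Residual-driven rotamer refinement
#'
#' Iteratively flags protein sites that disagree with the consensus model
#' and re-selects their side-chain rotamers. Disagreement is judged by the
#' jackknife (leave-one-out) residual: the model is refitted without the
#' site and the site's Phi compared with that model's prediction, so a
#' misassigned rotamer cannot mask itself by dragging the fit. For each
#' flagged site every clash-free canonical rotamer (falling back to the
#' least-clashing set) is evaluated under the site's leave-one-out model
#' and the rotamer best matching the measured Phi is selected (ties to the
#' preferred order g+ < t < g-); the dataset coordinates are updated and
#' the model refitted. A round is accepted only if the cost decreases;
#' iteration stops when no flagged site changes, a round fails to improve,
#' or \code{max_rounds} is reached.
#'
#' @param structure labeled, centered \code{structure_model} whose
#'   label_sites cover the protein rows of \code{dataset} (site names =
#'   residue numbers as character).
#' @param dataset a \code{\link{depth_dataset}} whose protein row order
#'   matches \code{site_resno}.
#' @param model current fitted \code{docking_model}.
#' @param site_resno integer vector mapping protein rows to residue numbers.
#' @param residual_threshold flagging threshold in Phi units; default
#'   max(0.3, 2 * MAD of the leave-one-out residuals).
#' @param max_rounds maximum refinement rounds (default 5).
#' @param tolerance clash tolerance passed to rotamer enumeration.
#' @return list: updated \code{dataset}, \code{model}, \code{structure},
#'   and a \code{changes} data.frame logging site, old and new rotamer per
#'   round.
#' @export
refine_rotamers <- function(structure, dataset, model, site_resno,
                            residual_threshold = NULL, max_rounds = 5,
                            tolerance = 0.4) {
  stopifnot(length(site_resno) == sum(dataset$is_protein))
  changes <- data.frame(round = integer(), site = integer(),
                        chi1_old = numeric(), chi2_old = numeric(),
                        chi1_new = numeric(), chi2_new = numeric(),
                        stringsAsFactors = FALSE)
  prot_idx <- which(dataset$is_protein)
  # leave-one-out refit: seeded from the current model plus a coarse angle
  # grid, so a high-leverage outlier cannot trap its own diagnostic fit in
  # the distorted basin
  loo_grid <- expand.grid(theta_x = c(-60, 0, 60),
                          theta_z = c(-60, 0, 60))
  loo_fit <- function(row) {
    ds <- dataset[-row, , drop = FALSE]
    warm <- tryCatch(
      fit_docking(ds, list(transform = model$transform,
                           hyperbola = model$hyperbola),
                  weighted = model$weighted),
      error = function(e) NULL)
    cold <- tryCatch(
      multistart_fit(ds, loo_grid, weighted = model$weighted),
      error = function(e) NULL)
    cands <- Filter(Negate(is.null), list(warm, cold))
    if (length(cands) == 0) return(model)
    cands[[which.min(vapply(cands, `[[`, 0, "cost"))]]
  }
  for (round in seq_len(max_rounds)) {
    loo_models <- lapply(prot_idx, loo_fit)
    loo_res <- vapply(seq_along(prot_idx), function(k) {
      mdl <- loo_models[[k]]
      dataset$phi[prot_idx[k]] -
        predicted_phi(dataset[prot_idx[k], , drop = FALSE],
                      mdl$transform, mdl$hyperbola)
    }, numeric(1))
    # robust scale: an outlier inflates the plain RMS of the diagnostics
    # enough to hide itself, so the default threshold uses the MAD
    scale <- stats::mad(loo_res, center = 0)
    thr <- if (is.null(residual_threshold)) max(0.3, 2 * scale)
           else residual_threshold
    flagged <- prot_idx[abs(loo_res) > thr]
    if (length(flagged) == 0) break
    # greedy best-improvement: one change per round -- with a misassigned
    # rotamer still in the data every leave-one-out model is somewhat
    # distorted, so all flagged candidates are evaluated and only the
    # single change that lowers the refitted cost the most is accepted
    best_change <- NULL
    for (row in flagged) {
      resno <- site_resno[match(row, prot_idx)]
      cur <- structure$label_sites[[as.character(resno)]]
      loo <- loo_models[[match(row, prot_idx)]]
      rot <- enumerate_rotamers(structure, resno, tolerance = tolerance)
      # candidates: all clash-free rotamers; if none exist, fall back to
      # the least-clashing set rather than refusing to move
      ok <- rot[rot$clash_count == 0, , drop = FALSE]
      if (nrow(ok) == 0)
        ok <- rot[rot$clash_count == min(rot$clash_count), , drop = FALSE]
      pred <- hyperbola(
        transform_point(as.matrix(ok[, c("nx", "ny", "nz")]),
                        loo$transform)[, 2],
        loo$hyperbola)
      err <- abs(dataset$phi[row] - pred)
      ord <- order(err, rotamer_rank(ok$chi1), rotamer_rank(ok$chi2))
      pick <- ok[ord[1], ]
      if (!is.na(cur$chi1) && !is.na(cur$chi2) &&
          pick$chi1 == cur$chi1 && pick$chi2 == cur$chi2) next
      new_dataset <- dataset
      new_dataset[row, c("x", "y", "z")] <-
        as.list(c(pick$nx, pick$ny, pick$nz))
      new_model <- tryCatch(
        fit_docking(new_dataset, list(transform = loo$transform,
                                      hyperbola = loo$hyperbola),
                    weighted = model$weighted),
        error = function(e) NULL)
      if (is.null(new_model) || new_model$cost >= model$cost) next
      if (is.null(best_change) || new_model$cost < best_change$model$cost)
        best_change <- list(row = row, resno = resno, cur = cur,
                            pick = pick, dataset = new_dataset,
                            model = new_model)
    }
    if (is.null(best_change)) break
    structure <- attach_r1(structure, best_change$resno,
                           best_change$pick$chi1, best_change$pick$chi2,
                           tolerance = tolerance)$structure
    dataset <- best_change$dataset
    model <- best_change$model
    changes <- rbind(changes, data.frame(
      round = round, site = best_change$resno,
      chi1_old = best_change$cur$chi1, chi2_old = best_change$cur$chi2,
      chi1_new = best_change$pick$chi1, chi2_new = best_change$pick$chi2))
    if (round == max_rounds)
      warning("rotamer refinement reached max_rounds without settling")
  }
  list(dataset = dataset, model = model, structure = structure,
       changes = changes)
}

#' Parameter uncertainties for a fitted docking model
#'
#' \code{method = "covariance"}: square roots of the diagonal of the
#' variance-scaled inverse Gauss-Newton Hessian from the least-squares fit.
#' \code{method = "montecarlo"}: refits over \code{n_mc} synthetic datasets
#' with Gaussian Phi noise at per-row SEMs (or \code{sigma} if given) and
#' reports the standard deviation of each parameter across replicates.
#'
#' @param model a fitted \code{docking_model}.
#' @param dataset the dataset it was fitted to.
#' @param method "covariance" or "montecarlo".
#' @param n_mc Monte-Carlo replicates (>= 200 recommended).
#' @param sigma optional scalar noise SD overriding per-row SEMs.
#' @param seed RNG seed for the Monte-Carlo method.
#' @return named numeric vector of standard uncertainties for theta_x,
#'   theta_z, y_trans, m, i, b, c.
#' @export
estimate_uncertainties <- function(model, dataset,
                                   method = c("covariance", "montecarlo"),
                                   n_mc = 200, sigma = NULL, seed = 1) {
  method <- match.arg(method)
  pnames <- c("theta_x", "theta_z", "y_trans", "m", "i", "b", "c")
  if (method == "covariance") {
    h <- model$fit$hessian
    df <- model$n - 7
    if (df <= 0) stop("not enough rows for covariance-based uncertainties")
    cv <- tryCatch(solve(h) * (model$fit$deviance / df),
                   error = function(e) {
                     ev <- eigen(h, symmetric = TRUE)
                     bad <- which(ev$values < max(ev$values) * 1e-10)
                     stop("singular information matrix; unidentifiable ",
                          "directions (parameter loadings): ",
                          paste(apply(ev$vectors[, bad, drop = FALSE], 2,
                                      function(v) pnames[which.max(abs(v))]),
                                collapse = ", "))
                   })
    return(stats::setNames(sqrt(pmax(diag(cv), 0)), pnames))
  }
  sd_row <- if (!is.null(sigma)) rep(sigma, nrow(dataset)) else dataset$phi_sem
  base <- model$fitted
  pars <- with_seed(seed, {
    t(vapply(seq_len(n_mc), function(k) {
      ds <- dataset
      ds$phi <- base + stats::rnorm(nrow(ds), 0, sd_row)
      m <- tryCatch(fit_docking(ds, list(transform = model$transform,
                                         hyperbola = model$hyperbola),
                                weighted = model$weighted),
                    error = function(e) NULL)
      if (is.null(m)) return(rep(NA_real_, 7))
      c(m$transform$theta_x, m$transform$theta_z, m$transform$y_trans,
        m$hyperbola$m, m$hyperbola$i, m$hyperbola$b, m$hyperbola$c)
    }, numeric(7)))
  })
  stats::setNames(apply(pars, 2, stats::sd, na.rm = TRUE), pnames)
}
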