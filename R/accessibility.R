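#' Fit an EPR power-saturation curve
#'
#' Fits the field-standard saturation model
#' A(P) = scale * sqrt(P) * (1 + (2^(1/eps) - 1) * P / P_half)^(-eps)
#' to (microwave power, peak-to-peak amplitude) pairs by Levenberg-Marquardt
#' least squares. \code{eps} is bounded to [0.5, 1.5]; \code{P_half} is the
#' power at half saturation. A curve that never saturates drives P_half to
#' its upper bound and is flagged.
#'
#' @param curve data.frame with columns \code{power} (mW, strictly positive,
#'   distinct, n >= 5) and \code{amplitude} (arbitrary units).
#' @return list with \code{P_half} (mW), \code{epsilon}, \code{scale},
#'   \code{unsaturated} flag, and the residual sum of squares \code{rss}.
#' @export
fit_saturation_curve <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("power", "amplitude") %in% names(curve)))
  p <- curve$power
  a <- curve$amplitude
  if (length(p) < 5) stop("at least 5 power settings are required")
  if (any(p <= 0) || anyDuplicated(p)) stop("powers must be positive and distinct")
  p_hi <- 100 * max(p)
  model <- function(par) {
    ph <- par[1]; eps <- par[2]; sc <- par[3]
    sc * sqrt(p) * (1 + (2^(1 / eps) - 1) * p / ph)^(-eps)
  }
  start <- c(P_half = stats::median(p), epsilon = 1,
             scale = max(a / sqrt(p)))
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(par) a - model(par),
    lower = c(1e-6, 0.5, 1e-12),
    upper = c(p_hi, 1.5, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info == 0)
    stop("saturation fit failed to converge: ", fit$message)
  est <- fit$par
  list(P_half = unname(est[1]), epsilon = unname(est[2]),
       scale = unname(est[3]),
       unsaturated = est[1] > 0.99 * p_hi,
       rss = fit$deviance)
}

#' Accessibility (collision) parameter from saturation powers
#'
#' Pi = ((P_half_relaxant - P_half_control) / dHpp) / reference_norm: the
#' relaxant-induced increase in half-saturation power, normalized by the
#' center-line peak-to-peak width and a reference standard. With the default
#' reference of 1 the value is a relative Pi.
#'
#' @param p_half_relaxant half-saturation power with relaxant present, mW.
#' @param p_half_control half-saturation power of the N2 control, mW.
#' @param dhpp center-line peak-to-peak linewidth, gauss.
#' @param reference_norm reference normalization, mW/gauss (default 1).
#' @return dimensionless Pi >= 0.
#' @export
accessibility_parameter <- function(p_half_relaxant, p_half_control, dhpp,
                                    reference_norm = 1) {
  stopifnot(p_half_relaxant > 0, p_half_control > 0, dhpp > 0,
            reference_norm > 0)
  if (p_half_relaxant < p_half_control)
    stop("relaxant must increase the half-saturation power ",
         "(delta P_half < 0)")
  ((p_half_relaxant - p_half_control) / dhpp) / reference_norm
}

#' Membrane depth parameter
#'
#' Phi = ln(Pi(O2) / Pi(NiEDDA)). Strongly positive values indicate membrane
#' burial (high O2 access), strongly negative values aqueous exposure.
#'
#' @param pi_o2 O2 accessibility parameter, > 0.
#' @param pi_ni NiEDDA accessibility parameter, > 0.
#' @return Phi, dimensionless. Vectorized.
#' @export
depth_parameter <- function(pi_o2, pi_ni) {
  if (any(pi_o2 <= 0) || any(pi_ni <= 0))
    stop("accessibility parameters must be strictly positive")
  log(pi_o2 / pi_ni)
}

#' First-order SEM of the depth parameter
#'
#' Propagates accessibility SEMs through the ln-ratio:
#' sigma_Phi = sqrt((sigma_O2/Pi_O2)^2 + (sigma_Ni/Pi_Ni)^2).
#'
#' @param pi_o2,pi_ni accessibility parameters, > 0.
#' @param pi_o2_sem,pi_ni_sem their SEMs, >= 0.
#' @return sigma_Phi. Vectorized.
#' @export
depth_parameter_sem <- function(pi_o2, pi_o2_sem, pi_ni, pi_ni_sem) {
  if (any(pi_o2 <= 0) || any(pi_ni <= 0))
    stop("accessibility parameters must be strictly positive")
  if (any(pi_o2_sem < 0) || any(pi_ni_sem < 0)) stop("SEMs must be >= 0")
  sqrt((pi_o2_sem / pi_o2)^2 + (pi_ni_sem / pi_ni)^2)
}

#' Depth parameters for a whole accessibility table
#'
#' Applies \code{\link{depth_parameter}} and
#' \code{\link{depth_parameter_sem}} row-wise. If the table carries a
#' user-supplied \code{phi_sem} column it is kept verbatim alongside the
#' propagated value.
#'
#' @param tab data.frame with columns \code{site}, \code{pi_o2},
#'   \code{pi_o2_sem}, \code{pi_ni}, \code{pi_ni_sem}.
#' @return data.frame with \code{site}, \code{phi}, \code{phi_sem}
#'   (propagated) and, when present on input, \code{phi_sem_supplied}.
#' @export
depth_parameter_table <- function(tab) {
  out <- data.frame(
    site = tab$site,
    phi = depth_parameter(tab$pi_o2, tab$pi_ni),
    phi_sem = depth_parameter_sem(tab$pi_o2, tab$pi_o2_sem,
                                  tab$pi_ni, tab$pi_ni_sem),
    stringsAsFactors = FALSE)
  if ("phi_sem" %in% names(tab)) out$phi_sem_supplied <- tab$phi_sem
  out
}
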