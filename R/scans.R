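#' One-dimensional equilibrium parameter scan
#'
#' Repeats the equilibrium dose-response while varying a single kinetic
#' parameter (or the tumor antigen surface density) over a log-spaced grid.
#' The default 30 parameter values x 30 doses gives 900 equilibrium
#' simulations per scan.  The ternary matrix is normalized by its global
#' maximum across all simulations.
#'
#' `KD1..KD4` scans alter the reverse rate at fixed forward rate (see
#' [set_param()]); `antigens_per_target` alters the setup.
#'
#' @param name one of `kf1..kf4`, `kr1..kr4`, `KD1..KD4`,
#'   `antigens_per_target`.
#' @param bounds `c(low, high)`, both positive, low < high; scanned
#'   log-spaced.
#' @param params base [binding_params()].
#' @param setup base [experiment_setup()].
#' @param n_param,n_dose grid sizes (default 30 x 30).
#' @param rtol integrator relative tolerance.
#' @return object of class `scan_result`: `parameter` (name),
#'   `values` (length `n_param`), `dose_grid` (ug/mL, length `n_dose`),
#'   `ternary_nM` (`n_param` x `n_dose` matrix), `ternary_normalized`.
#' @examples
#' p <- binding_params(2e-3, 2.2e-4, 2.2e-4, 2e-3, 2e-4, 3.3e-4, 3.3e-4, 2e-4)
#' sc <- scan_parameter("kf1", c(1e-6, 1e-1), p, experiment_setup(),
#'                      n_param = 8, n_dose = 10)
#' plateau_threshold(sc)
#' @export
scan_parameter <- function(name, bounds, params, setup,
                           n_param = 30L, n_dose = 30L, rtol = 1e-8) {
  allowed <- c(RATE_NAMES, paste0("KD", 1:4), "antigens_per_target")
  if (!name %in% allowed)
    stop("invalid input: unknown parameter '", name, "'; allowed: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  if (length(bounds) != 2L || any(bounds <= 0) || bounds[1] >= bounds[2])
    stop("invalid input: bounds must be positive with low < high",
         call. = FALSE)
  values <- if (n_param == 1L) bounds[1] else
    10^seq(log10(bounds[1]), log10(bounds[2]), length.out = n_param)
  doses <- default_dose_grid(n = n_dose, low = min(setup$dose_grid),
                             high = max(setup$dose_grid))

  mat <- matrix(NA_real_, nrow = length(values), ncol = length(doses))
  for (i in seq_along(values)) {
    if (name == "antigens_per_target") {
      setup_i <- setup
      setup_i$antigens_per_target <- values[i]
      params_i <- params
    } else {
      setup_i <- setup
      params_i <- set_param(params, name, values[i])
    }
    dr <- equilibrium_dose_response(setup_i, params_i, doses = doses,
                                    rtol = rtol)
    mat[i, ] <- dr$ternary_nM
  }
  gmax <- max(mat)
  structure(list(parameter = name, values = values, dose_grid = doses,
                 ternary_nM = mat,
                 ternary_normalized = if (gmax > 0) mat / gmax else mat),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Scan of %s over [%.3g, %.3g]: %d values x %d doses (%d simulations)\n",
              x$parameter, min(x$values), max(x$values), length(x$values),
              length(x$dose_grid), length(x$ternary_nM)))
  invisible(x)
}

#' Plateau threshold of a parameter scan
#'
#' The smallest scanned parameter value whose dose-response maximum reaches
#' `fraction` of the asymptotic maximum (the row maximum at the largest
#' scanned value).  Used to locate where further increases of a rate (for
#' example the receptor-antibody on-rate) stop improving ternary complex
#' formation.
#'
#' @param scan a `scan_result` with rows ordered by ascending parameter
#'   value.
#' @param fraction plateau fraction (default 0.95).
#' @param monotone_tol tolerated relative dips of the row-maximum profile
#'   before the profile is declared ambiguous.
#' @return the scanned parameter value at the plateau threshold.
#' @export
plateau_threshold <- function(scan, fraction = 0.95, monotone_tol = 1e-3) {
  stopifnot(inherits(scan, "scan_result"))
  rm_ <- apply(scan$ternary_nM, 1, max)
  asym <- rm_[length(rm_)]
  if (asym <= 0)
    stop("invalid input: scan ternary is identically zero", call. = FALSE)
  dips <- diff(rm_) / max(rm_)
  if (any(dips < -monotone_tol))
    stop("ambiguity error: row maxima are not monotone; profile: ",
         paste(signif(rm_, 4), collapse = ", "), call. = FALSE)
  idx <- which(rm_ >= fraction * asym)[1]
  scan$values[idx]
}
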