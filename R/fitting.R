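#' Observed activation dose-response series
#'
#' One series of arbitrary-unit activation readouts (flow-cytometry MFI)
#' versus antibody dose, for one antibody/receptor pair.
#'
#' @param pair_id label, e.g. `"FMC63_synNotch"`.
#' @param doses antibody doses (ug/mL), strictly positive, ascending.
#' @param readout activation readout (MFI, arbitrary units), finite.
#' @param readout_kind readout channel, e.g. `"TagBFP-MFI"` for a synNotch
#'   reporter or `"CD25-MFI"` for CAR activation.
#' @return object of class `observed_dose_response`.
#' @export
observed_dose_response <- function(pair_id, doses, readout,
                                   readout_kind = NA_character_) {
  if (length(doses) != length(readout))
    stop("invalid input: doses and readout lengths differ", call. = FALSE)
  if (any(!is.finite(doses)) || any(doses <= 0))
    stop("invalid input: doses must be positive and finite", call. = FALSE)
  if (any(!is.finite(readout)))
    stop("invalid input: readout must be finite", call. = FALSE)
  o <- order(doses)
  structure(list(pair_id = as.character(pair_id), doses = doses[o],
                 readout = readout[o], readout_kind = readout_kind),
            class = "observed_dose_response")
}

#' Put an observed series and a simulated curve on a common unitless scale
#'
#' Both series are min-max normalized to `[0, 1]` over the observed doses:
#' the observed readout (arbitrary MFI units) loses any affine gain/offset
#' of the instrument scale, and the simulated ternary concentration
#' (evaluated at the observed doses by exact match, else linear
#' interpolation in log dose) is treated identically, so a noise-free
#' affine image of the simulation normalizes to exactly the same series.
#' A flat simulated curve normalizes to all zeros.
#'
#' @param observed an [observed_dose_response()].
#' @param simulated a `dose_response` from [equilibrium_dose_response()].
#' @return list with `doses`, `observed_norm`, `simulated_norm`.
#' @export
normalize_pair <- function(observed, simulated) {
  stopifnot(inherits(observed, "observed_dose_response"))
  if (!is.data.frame(simulated) ||
      !all(c("dose_ug_per_ml", "ternary_nM") %in% names(simulated)))
    stop("invalid input: simulated must be a dose_response", call. = FALSE)
  rng <- range(observed$readout)
  if (rng[1] == rng[2])
    stop("degenerate data: observed readout is constant for pair '",
         observed$pair_id, "'", call. = FALSE)
  obs_norm <- (observed$readout - rng[1]) / (rng[2] - rng[1])

  sim <- interp_simulated(observed$doses, simulated)
  srng <- range(sim)
  sim_norm <- if (srng[2] > srng[1])
    (sim - srng[1]) / (srng[2] - srng[1]) else sim * 0
  list(doses = observed$doses, observed_norm = obs_norm,
       simulated_norm = sim_norm)
}

interp_simulated <- function(doses, simulated) {
  sd_ <- simulated$dose_ug_per_ml
  sv <- simulated$ternary_nM
  out <- numeric(length(doses))
  for (i in seq_along(doses)) {
    j <- which(sd_ == doses[i])
    if (length(j)) {
      out[i] <- sv[j[1]]
    } else {
      if (doses[i] < min(sd_) || doses[i] > max(sd_))
        stop("invalid input: observed dose ", signif(doses[i], 4),
             " ug/mL outside the simulated grid", call. = FALSE)
      out[i] <- approx(log(sd_), sv, xout = log(doses[i]))$y
    }
  }
  out
}

#' Sum of squared errors between two normalized series
#'
#' @param observed_norm,simulated_norm unitless series of equal length.
#' @return scalar SSE.
#' @export
sse <- function(observed_norm, simulated_norm) {
  if (length(observed_norm) != length(simulated_norm))
    stop("invalid input: series lengths differ", call. = FALSE)
  sum((observed_norm - simulated_norm)^2)
}

# SSE of a parameter set against one observed series (shared by fit_pair)
pair_objective <- function(observed, params, setup, rtol = 1e-7, atol = 1e-12) {
  sim <- equilibrium_dose_response(setup, params, doses = observed$doses,
                                   rtol = rtol, atol = atol)
  np <- normalize_pair(observed, sim)
  sse(np$observed_norm, np$simulated_norm)
}

#' Bounded least-squares fit of the kinetic rates to one observed series
#'
#' Minimizes the normalized SSE over the eight rate constants, starting
#' from the literature values and box-bounded within one order of magnitude
#' of them (`[lit/10, lit*10]` per rate).  Optimization is a deterministic
#' local search (`L-BFGS-B` on log10-transformed rates, numerical
#' gradients); the start point is feasible, and the best parameter set seen
#' during the search is returned, so the fitted SSE never exceeds the
#' initial SSE.
#'
#' @param observed an [observed_dose_response()].
#' @param literature a [binding_params()] object: the initial estimate.
#' @param setup an [experiment_setup()].
#' @param control passed to [stats::optim()] (default `maxit = 100`).
#' @param rtol integrator relative tolerance during fitting (looser than
#'   the default simulation tolerance for speed; the returned SSEs are
#'   recomputed at this tolerance consistently).
#' @return object of class `fit_result`: `pair_id`, `params` (fitted
#'   [binding_params()]), `sse_initial`, `sse_fitted`, `bounds` (2 x 8
#'   matrix), `converged`.
#' @export
fit_pair <- function(observed, literature, setup,
                     control = list(maxit = 100), rtol = 1e-7) {
  stopifnot(inherits(observed, "observed_dose_response"),
            inherits(literature, "binding_params"),
            inherits(setup, "experiment_setup"))
  lit <- vapply(RATE_NAMES, function(nm) literature[[nm]], numeric(1))
  lower <- log10(lit) - 1
  upper <- log10(lit) + 1

  best <- new.env(parent = emptyenv())
  best$sse <- Inf
  best$par <- log10(lit)
  obj <- function(lp) {
    p <- do.call(binding_params,
                 c(as.list(setNames(10^lp, RATE_NAMES)),
                   list(check_balance = FALSE)))
    val <- tryCatch(pair_objective(observed, p, setup, rtol = rtol),
                    error = function(e) NA_real_)
    if (!is.finite(val)) return(1e10)
    if (val < best$sse) {
      best$sse <- val
      best$par <- lp
    }
    val
  }
  sse_initial <- obj(log10(lit))
  fit <- tryCatch(
    optim(log10(lit), obj, method = "L-BFGS-B", lower = lower,
          upper = upper, control = control),
    error = function(e) NULL)

  converged <- !is.null(fit) && fit$convergence == 0
  fitted_par <- pmin(pmax(best$par, lower), upper)
  fitted <- do.call(binding_params,
                    c(as.list(setNames(10^fitted_par, RATE_NAMES)),
                      list(metadata = literature$metadata,
                           check_balance = FALSE)))
  structure(list(pair_id = observed$pair_id, params = fitted,
                 sse_initial = sse_initial, sse_fitted = best$sse,
                 bounds = rbind(lower = lit / 10, upper = lit * 10),
                 converged = converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit '%s': SSE %.4g (literature) -> %.4g (fitted); converged: %s\n",
              x$pair_id, x$sse_initial, x$sse_fitted, x$converged))
  invisible(x)
}

#' Fit a cohort of antibody/receptor pairs
#'
#' Runs [fit_pair()] per pair (errors are caught and reported per pair
#' without aborting the rest) and summarizes with unweighted mean SSEs.
#' A pair is flagged as a literature-value outlier when its initial SSE
#' exceeds the cohort median by more than three median absolute deviations
#' plus an absolute floor of 0.01 on the normalized scale.
#'
#' @param observations list of [observed_dose_response()] objects.
#' @param literature list of [binding_params()], one per observation (or a
#'   single set recycled).
#' @param setups list of [experiment_setup()], one per observation (or a
#'   single setup recycled).
#' @param ... passed to [fit_pair()].
#' @return object of class `fit_cohort`: per-pair `fits` (a `fit_result`
#'   or a condition object on failure), `mean_sse_initial`,
#'   `mean_sse_fitted`, `outlier_pairs` (character), `failed_pairs`.
#' @export
fit_cohort <- function(observations, literature, setups, ...) {
  n <- length(observations)
  if (n == 0) stop("invalid input: empty cohort", call. = FALSE)
  if (inherits(literature, "binding_params")) literature <- rep(list(literature), n)
  if (inherits(setups, "experiment_setup")) setups <- rep(list(setups), n)
  stopifnot(length(literature) == n, length(setups) == n)

  fits <- vector("list", n)
  names(fits) <- vapply(observations, function(o) o$pair_id, character(1))
  for (i in seq_len(n)) {
    fits[[i]] <- tryCatch(
      fit_pair(observations[[i]], literature[[i]], setups[[i]], ...),
      error = function(e) e)
  }
  ok <- vapply(fits, inherits, logical(1), what = "fit_result")
  si <- vapply(fits[ok], function(f) f$sse_initial, numeric(1))
  sf <- vapply(fits[ok], function(f) f$sse_fitted, numeric(1))
  thr <- stats::median(si) + 3 * stats::mad(si) + 0.01
  structure(list(fits = fits,
                 mean_sse_initial = mean(si),
                 mean_sse_fitted = mean(sf),
                 outlier_pairs = names(si)[si > thr],
                 failed_pairs = names(fits)[!ok]),
            class = "fit_cohort")
}

#' @export
print.fit_cohort <- function(x, ...) {
  ok <- vapply(x$fits, inherits, logical(1), what = "fit_result")
  cat(sprintf("Cohort fit: %d/%d pairs; mean SSE %.4g (literature) -> %.4g (fitted)\n",
              sum(ok), length(x$fits), x$mean_sse_initial, x$mean_sse_fitted))
  if (length(x$outlier_pairs))
    cat("  literature-value outliers:", paste(x$outlier_pairs, collapse = ", "), "\n")
  if (length(x$failed_pairs))
    cat("  failed:", paste(x$failed_pairs, collapse = ", "), "\n")
  invisible(x)
}
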