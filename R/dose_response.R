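#' Equilibrium dose-response curve
#'
#' For each antibody dose on the setup's grid, integrates the kinetic model
#' from the fully dissociated initial condition (all receptor, antibody and
#' antigen free; no complexes) to `t_max` and records the ternary complex
#' concentration at the terminal (equilibrium) state.  The curve is
#' unimodal in dose: formation rises with dose and is then suppressed by
#' the hook effect as excess antibody saturates both receptor pools.
#'
#' @param setup an [experiment_setup()].
#' @param params a [binding_params()] object.
#' @param doses optional override of `setup$dose_grid` (ug/mL).
#' @param rtol,atol integrator tolerances.
#' @param verify cross-check every terminal state against the independent
#'   steady-state root-finder; disagreement beyond `verify_tol` relative is
#'   an error.  Slower; intended for tests and spot checks.
#' @param verify_tol relative agreement required when `verify = TRUE`.
#' @param labels optional named list (antibody, antigen, receptor) carried
#'   in the result's attributes.
#' @return A `dose_response`: data.frame with columns `dose_ug_per_ml`,
#'   `ternary_nM`, `ternary_normalized` (divided by the curve maximum; all
#'   zero if the curve is identically zero), with attributes `labels` and
#'   `pair_id`.
#' @examples
#' s <- experiment_setup(dose_grid = default_dose_grid(n = 25))
#' p <- binding_params(2e-3, 2.2e-4, 2.2e-4, 2e-3, 2e-4, 3.3e-4, 3.3e-4, 2e-4)
#' dr <- equilibrium_dose_response(s, p)
#' hook_metrics(dr)
#' @export
equilibrium_dose_response <- function(setup, params, doses = NULL,
                                      rtol = 1e-8, atol = 1e-12,
                                      verify = FALSE, verify_tol = 1e-6,
                                      labels = list()) {
  stopifnot(inherits(setup, "experiment_setup"), inherits(params, "binding_params"))
  if (is.null(doses)) doses <- setup$dose_grid
  if (length(doses) < 1L)
    stop("invalid input: empty dose grid", call. = FALSE)
  tot <- setup_totals(setup)
  ab_nM <- antibody_dose_to_molar(doses, setup$antibody_mw_g_per_mol)

  res <- .equilibrium_states_cpp(ab_nM, tot[["Tc"]], tot[["Tu"]],
                                 param_vector(params), setup$t_max,
                                 rtol, atol, 500000L)
  if (any(res$status != 0)) {
    bad <- which(res$status != 0)[1]
    stop("integration error at dose ", signif(doses[bad], 4),
         " ug/mL (status ", res$status[bad], ")", call. = FALSE)
  }
  states <- res$states
  colnames(states) <- SPECIES
  ternary <- states[, "Tc.Ab.Tu"]

  if (verify) {
    for (i in seq_along(doses)) {
      ss <- steady_state_solve(params, c(Tc_total = tot[["Tc"]],
                                         Ab_total = ab_nM[i],
                                         Tu_total = tot[["Tu"]]))
      ref <- ss[["Tc.Ab.Tu"]]
      scale <- max(ternary[i], ref, 1e-6 * max(tot))
      if (abs(ternary[i] - ref) / scale > verify_tol)
        stop("steady-state verification failed at dose ",
             signif(doses[i], 4), " ug/mL: integration ",
             signif(ternary[i], 8), " vs root-finding ", signif(ref, 8),
             call. = FALSE)
    }
  }

  norm <- if (max(ternary) > 0) ternary / max(ternary) else ternary * 0
  out <- data.frame(dose_ug_per_ml = doses, ternary_nM = ternary,
                    ternary_normalized = norm)
  structure(out, class = c("dose_response", "data.frame"),
            labels = labels,
            pair_id = labels$pair_id %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hook-effect summary metrics of a dose-response curve
#'
#' @param curve a `dose_response` (or any data.frame with `dose_ug_per_ml`
#'   and `ternary_nM` columns).
#' @return list of class `hook_metrics`: `peak_dose` (ug/mL, smallest dose
#'   on ties), `peak_ternary` (nM), `effective_window` (range of the
#'   contiguous dose span holding >= 50% of peak), and `hook_detected`
#'   (TRUE when the peak is interior and the curve has fallen below 50% of
#'   peak at the largest dose).  An all-zero curve gives zero peak, a
#'   degenerate window and `hook_detected = FALSE`.
#' @export
hook_metrics <- function(curve) {
  if (!is.data.frame(curve) || nrow(curve) < 1L ||
      !all(c("dose_ug_per_ml", "ternary_nM") %in% names(curve)))
    stop("invalid input: curve must have dose_ug_per_ml and ternary_nM",
         call. = FALSE)
  d <- curve$dose_ug_per_ml
  v <- curve$ternary_nM
  if (max(v) <= 0) {
    return(structure(list(peak_dose = d[1], peak_ternary = 0,
                          effective_window = c(d[1], d[1]),
                          hook_detected = FALSE), class = "hook_metrics"))
  }
  ip <- which.max(v)  # which.max returns the first (smallest dose) on ties
  half <- 0.5 * v[ip]
  # contiguous run of >= 50% of peak containing the peak
  lo <- ip
  while (lo > 1 && v[lo - 1] >= half) lo <- lo - 1
  hi <- ip
  while (hi < length(v) && v[hi + 1] >= half) hi <- hi + 1
  structure(list(peak_dose = d[ip], peak_ternary = v[ip],
                 effective_window = c(d[lo], d[hi]),
                 hook_detected = (ip > 1 && ip < length(v) &&
                                  v[length(v)] < half)),
            class = "hook_metrics")
}

#' @export
print.hook_metrics <- function(x, ...) {
  cat(sprintf("Hook metrics: peak %.4g nM at %.4g ug/mL; 50%% window [%.4g, %.4g] ug/mL; hook %s\n",
              x$peak_ternary, x$peak_dose,
              x$effective_window[1], x$effective_window[2],
              if (x$hook_detected) "detected" else "not detected"))
  invisible(x)
}
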