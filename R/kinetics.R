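#' Kinetic simulation of the binding network
#'
#' Integrates the six-species mass-action system from `initial` to
#' `setup$t_max` with a stiff (L-stable Rosenbrock) adaptive integrator.
#' Equilibrium is declared when the change of every species across the
#' trailing 10% of the horizon is below `setup$equilibrium_tolerance`
#' relative to the species' conserved pool scale.
#'
#' @param setup an [experiment_setup()]; supplies `t_max` and the
#'   equilibrium tolerance.
#' @param params a [binding_params()] object.
#' @param initial initial state, see [system_state()].
#' @param times optional strictly increasing output times (s) starting at 0;
#'   default 0 plus 200 log-spaced points up to `t_max`.
#' @param rtol,atol integrator tolerances (relative; absolute in nM).
#' @param max_steps step budget per output interval.
#' @return A `ternary_trajectory`: data.frame with column `time` and one
#'   column per species, with attributes `equilibrium_reached` (logical) and
#'   `time_to_equilibrium` (s, `NA` if not reached).
#' @examples
#' s <- experiment_setup()
#' p <- binding_params(2e-3, 2.2e-4, 2.2e-4, 2e-3, 2e-4, 3.3e-4, 3.3e-4, 2e-4)
#' tot <- setup_totals(s)
#' tr <- simulate_kinetics(s, p, system_state(Tc = tot[["Tc"]], Ab = 1,
#'                                            Tu = tot[["Tu"]]))
#' attr(tr, "equilibrium_reached")
#' @export
simulate_kinetics <- function(setup, params, initial, times = NULL,
                              rtol = 1e-8, atol = 1e-12, max_steps = 500000L) {
  stopifnot(inherits(setup, "experiment_setup"))
  initial <- validate_state(initial)
  if (is.null(times)) {
    times <- c(0, 10^seq(log10(max(setup$t_max * 1e-8, 1e-6)),
                         log10(setup$t_max), length.out = 200))
  }
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("invalid input: 'times' must start at 0 and increase strictly",
         call. = FALSE)

  res <- .integrate_kinetics_cpp(unname(initial), param_vector(params),
                                 times, rtol, atol, as.integer(max_steps))
  if (res$status != 0) {
    last <- res$states[max(res$n_times_completed - 1L, 1L), ]
    stop("integration error (status ", res$status, ") at t <= ",
         signif(times[res$n_times_completed], 4),
         " s; last valid state: ",
         paste(sprintf("%s=%.4g", SPECIES, last), collapse = ", "),
         call. = FALSE)
  }
  states <- res$states
  if (any(!is.finite(states)))
    stop("numerical error: non-finite state in trajectory", call. = FALSE)
  colnames(states) <- SPECIES

  eq <- equilibrium_from_states(times, states, setup$equilibrium_tolerance)
  out <- data.frame(time = times, states, check.names = FALSE)
  structure(out, class = c("ternary_trajectory", "data.frame"),
            equilibrium_reached = eq$reached,
            time_to_equilibrium = eq$time)
}

# Trailing-window equilibrium test: every species must move less than
# tol * (scale of its conserved pool) across the final 10% of the horizon.
equilibrium_from_states <- function(times, states, tol) {
  t_end <- times[length(times)]
  tot <- conserved_totals(states[nrow(states), ])
  scale <- pmax(c(tot[["Tc_total"]], tot[["Ab_total"]], tot[["Tu_total"]],
                  tot[["Tc_total"]], tot[["Ab_total"]], tot[["Tc_total"]]),
                .Machine$double.xmin)
  in_win <- times >= 0.9 * t_end
  if (sum(in_win) < 2L) return(list(reached = FALSE, time = NA_real_))
  win <- states[in_win, , drop = FALSE]
  drift <- apply(win, 2, function(x) max(x) - min(x)) / scale
  reached <- all(drift < tol)
  time <- NA_real_
  if (reached) {
    # earliest stored time from which every species stays within tolerance
    # of the terminal state
    final <- states[nrow(states), ]
    dev <- sweep(abs(sweep(states, 2, final)), 2, scale, "/")
    ok_from <- rev(cumprod(rev(apply(dev < tol, 1, all)))) == 1
    time <- times[which(ok_from)[1]]
  }
  list(reached = reached, time = time)
}

#' @export
print.ternary_trajectory <- function(x, ...) {
  cat(sprintf("Kinetic trajectory: %d time points to t=%.3g s; equilibrium %s\n",
              nrow(x), max(x$time),
              if (isTRUE(attr(x, "equilibrium_reached")))
                sprintf("reached by t=%.3g s", attr(x, "time_to_equilibrium"))
              else "not reached"))
  print.data.frame(utils::head(as.data.frame(x), 4))
  cat("...\n")
  invisible(x)
}
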