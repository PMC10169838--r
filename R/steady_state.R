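#' Steady state by root-finding on the reduced system
#'
#' Independent of the kinetic integrator: eliminates the three free species
#' via the conserved totals and solves the three complex balance equations
#' (d[Tc.Ab]/dt = d[Ab.Tu]/dt = d[Tc.Ab.Tu]/dt = 0) with a damped Newton
#' iteration from several spread starting points, returning the physically
#' admissible root (all six species non-negative).
#'
#' @param params a [binding_params()] object.
#' @param totals named vector `c(Tc_total=, Ab_total=, Tu_total=)` (nM),
#'   non-negative.
#' @param tol residual tolerance: each component of the scaled right-hand
#'   side must fall below `tol` (default 1e-10 after scaling by the fastest
#'   flux scale).
#' @param n_starts number of starting points (>= 4).
#' @return named state vector (length 6) at steady state.
#' @examples
#' p <- binding_params(2e-3, 2.2e-4, 2.2e-4, 2e-3, 2e-4, 3.3e-4, 3.3e-4, 2e-4)
#' steady_state_solve(p, c(Tc_total = 0.08, Ab_total = 1, Tu_total = 0.17))
#' @export
steady_state_solve <- function(params, totals, tol = 1e-10, n_starts = 6L) {
  stopifnot(inherits(params, "binding_params"))
  need <- c("Tc_total", "Ab_total", "Tu_total")
  if (!all(need %in% names(totals)))
    stop("invalid input: totals must be named ", paste(need, collapse = ", "),
         call. = FALSE)
  tt <- totals[["Tc_total"]]; ta <- totals[["Ab_total"]]; tu <- totals[["Tu_total"]]
  if (any(c(tt, ta, tu) < 0) || any(!is.finite(c(tt, ta, tu))))
    stop("invalid input: totals must be non-negative and finite", call. = FALSE)

  if (ta == 0 || tt == 0 && tu == 0)
    return(state_from_complexes(c(0, 0, 0), tt, ta, tu))

  k <- param_vector(params)
  # residual: time derivatives of the three complexes, complexes as unknowns
  resid <- function(u) {
    st <- state_from_complexes(u, tt, ta, tu)
    x <- st[["Tc"]]; y <- st[["Ab"]]; z <- st[["Tu"]]
    c1 <- u[1]; c2 <- u[2]; Tn <- u[3]
    c(k[1] * x * y - k[5] * c1 - k[3] * c1 * z + k[7] * Tn,
      k[2] * y * z - k[6] * c2 - k[4] * x * c2 + k[8] * Tn,
      k[3] * c1 * z - k[7] * Tn + k[4] * x * c2 - k[8] * Tn)
  }
  # scale for declaring convergence: largest possible flux magnitude
  conc <- max(tt, ta, tu)
  fscale <- max(max(k[1:4]) * conc * conc, max(k[5:8]) * conc)

  starts <- steady_starts(tt, ta, tu, n_starts)
  best <- NULL
  best_res <- Inf
  residuals <- numeric(0)
  for (s in seq_len(nrow(starts))) {
    sol <- damped_newton(resid, starts[s, ], tt, ta, tu)
    r <- max(abs(resid(sol))) / fscale
    residuals <- c(residuals, r)
    if (r < best_res && admissible(sol, tt, ta, tu)) {
      best_res <- r
      best <- sol
    }
    if (best_res < tol) break
  }
  if (is.null(best) || best_res >= tol)
    stop("convergence error: no admissible steady state found; scaled ",
         "residuals of starts: ",
         paste(signif(residuals, 3), collapse = ", "), call. = FALSE)
  st <- state_from_complexes(best, tt, ta, tu)
  pmax(st, 0)
}

state_from_complexes <- function(u, tt, ta, tu) {
  c(Tc = tt - u[1] - u[3],
    Ab = ta - u[1] - u[2] - u[3],
    Tu = tu - u[2] - u[3],
    "Tc.Ab" = u[1], "Ab.Tu" = u[2], "Tc.Ab.Tu" = u[3])
}

admissible <- function(u, tt, ta, tu) {
  st <- state_from_complexes(u, tt, ta, tu)
  slack <- 1e-9 * max(tt, ta, tu, 1e-300)
  all(st > -slack)
}

steady_starts <- function(tt, ta, tu, n_starts) {
  n_starts <- max(4L, as.integer(n_starts))
  m <- min(tt, ta, tu)
  base <- rbind(
    c(0, 0, 0),
    c(0.5 * min(tt, ta), 0.5 * min(tu, ta), 0),
    c(0, 0, 0.9 * m),
    c(0.25 * min(tt, ta), 0.25 * min(tu, ta), 0.4 * m))
  extra <- n_starts - nrow(base)
  if (extra > 0) {
    # deterministic interior lattice, no RNG involvement
    fr <- (seq_len(extra)) / (extra + 1)
    base <- rbind(base, cbind(fr * 0.6 * min(tt, ta),
                              fr * 0.6 * min(tu, ta),
                              (1 - fr) * 0.5 * m))
  }
  base
}

damped_newton <- function(resid, u0, tt, ta, tu, max_iter = 200L) {
  u <- u0
  f <- resid(u)
  scale <- max(tt, ta, tu)
  for (it in seq_len(max_iter)) {
    J <- numeric_jacobian(resid, u, scale)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) {
      # near-singular when a species pool is (effectively) absent: damp the
      # null directions with a small ridge; LAPACK QR skips rank detection
      ridge <- 1e-10 * max(abs(J), 1e-300)
      step <- tryCatch(solve(qr(J + diag(ridge, 3), LAPACK = TRUE), -f),
                       error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
    }
    lambda <- 1
    improved <- FALSE
    for (half in 1:40) {
      u_new <- u + lambda * step
      f_new <- tryCatch(resid(u_new), error = function(e) NULL)
      if (!is.null(f_new) && all(is.finite(f_new)) &&
          sum(f_new^2) < sum(f^2)) {
        u <- u_new; f <- f_new; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
    if (max(abs(f)) == 0) break
    if (max(abs(lambda * step)) < 1e-15 * scale) break
  }
  u
}

numeric_jacobian <- function(fn, u, scale) {
  f0 <- fn(u)
  J <- matrix(0, length(f0), length(u))
  for (j in seq_along(u)) {
    h <- max(abs(u[j]), 1e-6 * scale) * 1e-7
    up <- u; up[j] <- up[j] + h
    um <- u; um[j] <- um[j] - h
    J[, j] <- (fn(up) - fn(um)) / (2 * h)
  }
  J
}
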