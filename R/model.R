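#' Construct a six-species system state
#'
#' @param Tc,Ab,Tu free T cell receptor, free antibody, free tumor antigen
#'   concentrations (nM).
#' @param Tc.Ab,Ab.Tu,Tc.Ab.Tu binary and ternary complex concentrations (nM).
#' @return named numeric vector of length 6 in canonical species order.
#' @export
system_state <- function(Tc = 0, Ab = 0, Tu = 0,
                         Tc.Ab = 0, Ab.Tu = 0, Tc.Ab.Tu = 0) {
  st <- c(Tc = Tc, Ab = Ab, Tu = Tu,
          "Tc.Ab" = Tc.Ab, "Ab.Tu" = Ab.Tu, "Tc.Ab.Tu" = Tc.Ab.Tu)
  validate_state(st)
  st
}

validate_state <- function(state) {
  if (!is.numeric(state) || length(state) != 6L)
    stop("invalid input: state must be a numeric vector of length 6",
         call. = FALSE)
  if (is.null(names(state))) names(state) <- SPECIES
  bad <- which(!is.finite(state) | state < 0)
  if (length(bad))
    stop("invalid input: negative or non-finite concentration for species '",
         names(state)[bad[1]], "'", call. = FALSE)
  invisible(state)
}

#' The eight elementary mass-action reaction rates
#'
#' Fluxes of the four reversible binding steps, split into forward and
#' reverse components: rxn1/2 receptor + antibody, rxn3/4 antibody +
#' antigen, rxn5/6 receptor-bound antibody + antigen, rxn7/8 receptor +
#' antigen-bound antibody.
#'
#' @param state named state vector (see [system_state()]).
#' @param params a [binding_params()] object.
#' @return named numeric vector `rxn1..rxn8` (nM/s), all non-negative.
#' @export
reaction_rates <- function(state, params) {
  state <- validate_state(state)
  stopifnot(inherits(params, "binding_params"))
  c(rxn1 = params$kf1 * state[["Tc"]] * state[["Ab"]],
    rxn2 = params$kr1 * state[["Tc.Ab"]],
    rxn3 = params$kf2 * state[["Ab"]] * state[["Tu"]],
    rxn4 = params$kr2 * state[["Ab.Tu"]],
    rxn5 = params$kf3 * state[["Tc.Ab"]] * state[["Tu"]],
    rxn6 = params$kr3 * state[["Tc.Ab.Tu"]],
    rxn7 = params$kf4 * state[["Tc"]] * state[["Ab.Tu"]],
    rxn8 = params$kr4 * state[["Tc.Ab.Tu"]])
}

#' Time derivatives of the six species
#'
#' Signed sums of [reaction_rates()]; this is the right-hand side the
#' kinetic integrator solves.
#'
#' @inheritParams reaction_rates
#' @return named numeric vector of d/dt for each species (nM/s).
#' @export
ode_rhs <- function(state, params) {
  r <- reaction_rates(state, params)
  c(Tc         = -r[["rxn1"]] + r[["rxn2"]] - r[["rxn7"]] + r[["rxn8"]],
    Ab         = -r[["rxn1"]] + r[["rxn2"]] - r[["rxn3"]] + r[["rxn4"]],
    Tu         = -r[["rxn3"]] + r[["rxn4"]] - r[["rxn5"]] + r[["rxn6"]],
    "Tc.Ab"    =  r[["rxn1"]] - r[["rxn2"]] - r[["rxn5"]] + r[["rxn6"]],
    "Ab.Tu"    =  r[["rxn3"]] - r[["rxn4"]] - r[["rxn7"]] + r[["rxn8"]],
    "Tc.Ab.Tu" =  r[["rxn5"]] - r[["rxn6"]] + r[["rxn7"]] - r[["rxn8"]])
}

#' Conserved totals of a state
#'
#' The network conserves three linear combinations: total T cell receptor
#' (`Tc + Tc.Ab + Tc.Ab.Tu`), total antibody
#' (`Ab + Tc.Ab + Ab.Tu + Tc.Ab.Tu`) and total tumor antigen
#' (`Tu + Ab.Tu + Tc.Ab.Tu`).
#'
#' @param state named state vector.
#' @return named vector `c(Tc_total=, Ab_total=, Tu_total=)` (nM).
#' @export
conserved_totals <- function(state) {
  if (is.null(names(state))) names(state) <- SPECIES
  c(Tc_total = state[["Tc"]] + state[["Tc.Ab"]] + state[["Tc.Ab.Tu"]],
    Ab_total = state[["Ab"]] + state[["Tc.Ab"]] + state[["Ab.Tu"]] +
               state[["Tc.Ab.Tu"]],
    Tu_total = state[["Tu"]] + state[["Ab.Tu"]] + state[["Tc.Ab.Tu"]])
}
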