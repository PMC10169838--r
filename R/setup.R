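#' Experimental design for a co-incubation assay
#'
#' Captures the bench quantities needed to pose the well-mixed binding model:
#' cell numbers, surface sites per cell, incubation volume, antibody
#' molecular weight, the antibody dose grid, and the integration horizon.
#' All quantities are converted to molar units at this boundary; the model
#' itself works exclusively in nM and seconds.
#'
#' Defaults mirror a 96-well co-incubation of 1e5 effector cells with 2e5
#' target cells in 0.2 mL.  Receptor and antigen surface densities default
#' to 1e5 sites/cell, a placeholder typical of engineered receptor and tumor
#' antigen expression; override with measured values when available.
#'
#' @param n_effector_cells number of receptor-bearing effector cells.
#' @param n_target_cells number of antigen-bearing target cells.
#' @param receptors_per_effector adaptor receptors per effector cell.
#' @param antigens_per_target antigen molecules per target cell.
#' @param volume_ml co-incubation volume (mL).
#' @param antibody_mw_g_per_mol adaptor molecular weight (g/mol); 150000 for
#'   IgG, 50000 for a Fab fragment.
#' @param dose_grid antibody doses (ug/mL), sorted ascending; default 60
#'   log-spaced points over 1e-4 to 1e1 ug/mL.
#' @param t_max integration horizon (s).
#' @param equilibrium_tolerance relative change threshold declaring
#'   equilibrium over the trailing 10% of the horizon.
#' @return An object of class `experiment_setup`.
#' @examples
#' s <- experiment_setup()
#' setup_totals(s)  # receptor and antigen pool concentrations in nM
#' @export
experiment_setup <- function(n_effector_cells = 1e5,
                             n_target_cells = 2e5,
                             receptors_per_effector = 1e5,
                             antigens_per_target = 1e5,
                             volume_ml = 0.2,
                             antibody_mw_g_per_mol = 150000,
                             dose_grid = default_dose_grid(),
                             t_max = 1e6,
                             equilibrium_tolerance = 1e-8) {
  num <- list(n_effector_cells = n_effector_cells,
              n_target_cells = n_target_cells,
              receptors_per_effector = receptors_per_effector,
              antigens_per_target = antigens_per_target,
              volume_ml = volume_ml,
              antibody_mw_g_per_mol = antibody_mw_g_per_mol,
              t_max = t_max,
              equilibrium_tolerance = equilibrium_tolerance)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid input: '", nm, "' must be a positive finite number",
           call. = FALSE)
  }
  if (!is.numeric(dose_grid) || length(dose_grid) < 1L ||
      any(!is.finite(dose_grid)) || any(dose_grid < 0))
    stop("invalid input: 'dose_grid' must be non-negative finite doses",
         call. = FALSE)
  if (is.unsorted(dose_grid))
    stop("invalid input: 'dose_grid' must be sorted ascending", call. = FALSE)
  structure(c(num, list(dose_grid = dose_grid)), class = "experiment_setup")
}

#' Default antibody dose grid
#'
#' 60 log-spaced doses over 1e-4 to 1e1 ug/mL, the range titrated in the
#' co-incubation assays this model describes.
#'
#' @param n number of doses.
#' @param low,high grid bounds (ug/mL).
#' @return numeric vector of doses (ug/mL), ascending.
#' @export
default_dose_grid <- function(n = 60, low = 1e-4, high = 1e1) {
  10^seq(log10(low), log10(high), length.out = n)
}

#' @export
print.experiment_setup <- function(x, ...) {
  tot <- setup_totals(x)
  cat("Co-incubation setup\n")
  cat(sprintf("  %g effector cells x %g receptors, %g target cells x %g antigens in %g mL\n",
              x$n_effector_cells, x$receptors_per_effector,
              x$n_target_cells, x$antigens_per_target, x$volume_ml))
  cat(sprintf("  receptor pool %.4g nM, antigen pool %.4g nM; antibody MW %g g/mol\n",
              tot[["Tc"]], tot[["Tu"]], x$antibody_mw_g_per_mol))
  cat(sprintf("  %d doses %.3g-%.3g ug/mL; t_max %g s\n",
              length(x$dose_grid), min(x$dose_grid), max(x$dose_grid), x$t_max))
  invisible(x)
}

#' Convert an antibody dose to molar concentration
#'
#' @param dose_ug_per_ml dose in ug/mL (vectorised, non-negative).
#' @param mw_g_per_mol molecular weight (g/mol).
#' @return concentration in nM.
#' @examples
#' antibody_dose_to_molar(0.25, 150000)  # ~1.667 nM
#' @export
antibody_dose_to_molar <- function(dose_ug_per_ml, mw_g_per_mol) {
  if (!is.numeric(mw_g_per_mol) || length(mw_g_per_mol) != 1L ||
      !is.finite(mw_g_per_mol) || mw_g_per_mol <= 0)
    stop("invalid input: 'mw_g_per_mol' must be positive", call. = FALSE)
  if (any(dose_ug_per_ml < 0))
    stop("invalid input: 'dose_ug_per_ml' must be non-negative", call. = FALSE)
  # ug/mL = mg/L = 1e-3 g/L; / (g/mol) -> mol/L; * 1e9 -> nM
  dose_ug_per_ml * 1e6 / mw_g_per_mol
}

#' Convert cell-surface sites to a well-mixed molar concentration
#'
#' @param n_cells number of cells.
#' @param sites_per_cell surface sites (receptors or antigens) per cell.
#' @param volume_ml volume (mL).
#' @return concentration in nM.
#' @examples
#' sites_to_molar(1e5, 1e4, 1)  # ~1.661e-3 nM
#' @export
sites_to_molar <- function(n_cells, sites_per_cell, volume_ml) {
  for (nm in c("n_cells", "sites_per_cell", "volume_ml")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid input: '", nm, "' must be positive", call. = FALSE)
  }
  n_cells * sites_per_cell / (AVOGADRO * volume_ml * 1e-3) * 1e9
}

#' Conserved receptor and antigen pool concentrations for a setup
#'
#' @param setup an [experiment_setup()].
#' @return named vector `c(Tc=, Tu=)`: total T cell receptor and total tumor
#'   antigen concentrations (nM).
#' @export
setup_totals <- function(setup) {
  stopifnot(inherits(setup, "experiment_setup"))
  c(Tc = sites_to_molar(setup$n_effector_cells, setup$receptors_per_effector,
                        setup$volume_ml),
    Tu = sites_to_molar(setup$n_target_cells, setup$antigens_per_target,
                        setup$volume_ml))
}
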