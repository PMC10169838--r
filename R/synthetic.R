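#' Specification of one synthetic dose-response pair
#'
#' Describes how to fabricate an observed activation series with the
#' structure the fitting machinery assumes: a hook-shaped equilibrium
#' ternary curve mapped to an arbitrary-unit MFI scale by an affine gain
#' and offset, with additive Gaussian noise on the normalized scale,
#' clipped at zero.
#'
#' @param pair_id label for the pair.
#' @param params ground-truth [binding_params()].
#' @param setup [experiment_setup()] for the pair.
#' @param gain MFI per normalized unit (> 0).
#' @param offset baseline MFI (>= 0).
#' @param sigma additive Gaussian noise s.d. on the normalized scale
#'   (>= 0; default 0.05, a typical replicate-level spread for
#'   flow-cytometry MFI summaries).
#' @param doses doses at which the pair is observed (ug/mL); default 8
#'   log-spaced points over 1e-4 to 1e1 ug/mL, the titration range of the
#'   co-incubation assays.
#' @param readout_kind readout channel label.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(pair_id, params, setup, gain = 1e4, offset = 500,
                           sigma = 0.05,
                           doses = default_dose_grid(n = 8),
                           readout_kind = "TagBFP-MFI", seed = 1L) {
  stopifnot(inherits(params, "binding_params"),
            inherits(setup, "experiment_setup"))
  if (!is.numeric(gain) || gain <= 0)
    stop("invalid input: gain must be > 0", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0)
    stop("invalid input: sigma must be >= 0", call. = FALSE)
  structure(list(pair_id = pair_id, params = params, setup = setup,
                 gain = gain, offset = offset, sigma = sigma,
                 doses = sort(doses), readout_kind = readout_kind,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Noise-free ground-truth curve for a synthetic spec
#'
#' @param spec a [synthetic_spec()].
#' @return a `dose_response` at the spec's doses under the ground-truth
#'   parameters.
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  equilibrium_dose_response(spec$setup, spec$params, doses = spec$doses,
                            labels = list(pair_id = spec$pair_id))
}

#' Map a truth curve to a noisy arbitrary-unit observed series
#'
#' `readout = max(gain * (normalized_truth + N(0, sigma)) + offset, 0)`,
#' generated under the spec's seed.
#'
#' @param truth a `dose_response` on the spec's doses (from
#'   [generate_truth()]).
#' @param spec a [synthetic_spec()].
#' @return an [observed_dose_response()].
#' @export
observe <- function(truth, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!isTRUE(all.equal(truth$dose_ug_per_ml, spec$doses)))
    stop("invalid input: truth doses do not match spec doses", call. = FALSE)
  norm <- truth$ternary_normalized
  noisy <- with_seed(spec$seed, norm + rnorm(length(norm), sd = spec$sigma))
  observed_dose_response(spec$pair_id, spec$doses,
                         pmax(spec$gain * noisy + spec$offset, 0),
                         readout_kind = spec$readout_kind)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default synthetic cohort: four antibodies by two receptor types
#'
#' Mirrors the experimental design the generator emulates: FMC63 (CD19),
#' Rituximab (CD20), Herceptin (HER2) and Cetuximab (EGFR), each paired
#' with a synNotch-style and a CAR-style readout, 8 doses each.  Ground
#' truth is the packaged stand-in literature table; per-pair gain and
#' offset are drawn once from wide ranges (gain 1e3-1e5, offset 1e2-1e3
#' MFI, log-uniform and uniform respectively) to exercise normalization.
#'
#' @param seed integer master seed; per-pair seeds are derived from it.
#' @param sigma noise s.d. on the normalized scale.
#' @param doses observation doses (ug/mL).
#' @return named list of [synthetic_spec()] (8 pairs).
#' @export
default_synthetic_specs <- function(seed = 1L, sigma = 0.05,
                                    doses = default_dose_grid(n = 8)) {
  lit <- literature_params()
  setup <- experiment_setup()
  n <- length(lit)
  draws <- with_seed(seed, list(gain = 10^runif(n, 3, 5),
                                offset = runif(n, 100, 1000)))
  specs <- vector("list", n)
  names(specs) <- names(lit)
  for (i in seq_len(n)) {
    kind <- if (grepl("synNotch", names(lit)[i])) "TagBFP-MFI" else "CD25-MFI"
    specs[[i]] <- synthetic_spec(
      pair_id = names(lit)[i], params = lit[[i]], setup = setup,
      gain = draws$gain[i], offset = draws$offset[i], sigma = sigma,
      doses = doses, readout_kind = kind,
      seed = (as.integer(seed) * 1000L + i) %% .Machine$integer.max)
  }
  specs
}

#' Write a synthetic dataset bundle
#'
#' Generates truth and observed series for each spec and writes four text
#' artifacts to `dir`: `observed.csv` (the fitting input schema),
#' `truth.csv`, `params.json` (ground-truth rates per pair) and
#' `manifest.json` (seeds and a hash of the spec list, enabling exact
#' regeneration).
#'
#' @param specs list of [synthetic_spec()].
#' @param dir output directory (created if missing).
#' @return invisibly, a list with the observed/truth objects and file
#'   paths.
#' @export
generate_dataset <- function(specs, dir) {
  if (length(specs) == 0) stop("invalid input: empty spec list", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  truth_rows <- list()
  obs_rows <- list()
  observed <- list()
  for (spec in specs) {
    tr <- generate_truth(spec)
    ob <- observe(tr, spec)
    observed[[spec$pair_id]] <- ob
    truth_rows[[spec$pair_id]] <- data.frame(
      pair_id = spec$pair_id, dose_ug_per_ml = tr$dose_ug_per_ml,
      ternary_nM = tr$ternary_nM, ternary_normalized = tr$ternary_normalized)
    obs_rows[[spec$pair_id]] <- data.frame(
      pair_id = ob$pair_id, dose_ug_per_ml = ob$doses,
      readout_mfi = ob$readout, readout_kind = ob$readout_kind)
  }
  paths <- c(observed = file.path(dir, "observed.csv"),
             truth = file.path(dir, "truth.csv"),
             params = file.path(dir, "params.json"),
             manifest = file.path(dir, "manifest.json"))
  write.csv(do.call(rbind, obs_rows), paths[["observed"]], row.names = FALSE)
  write.csv(do.call(rbind, truth_rows), paths[["truth"]], row.names = FALSE)

  par_list <- lapply(specs, function(s)
    c(setNames(lapply(RATE_NAMES, function(nm) s$params[[nm]]), RATE_NAMES),
      list(metadata = s$params$metadata)))
  names(par_list) <- vapply(specs, function(s) s$pair_id, character(1))
  jsonlite::write_json(par_list, paths[["params"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(
    pairs = lapply(specs, function(s)
      list(pair_id = s$pair_id, seed = s$seed, gain = s$gain,
           offset = s$offset, sigma = s$sigma, doses = s$doses,
           readout_kind = s$readout_kind)),
    file_md5 = as.list(tools::md5sum(paths[c("observed", "truth", "params")])))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(observed = observed, truth = truth_rows, paths = paths))
}
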