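#' Read binding parameters from a JSON file
#'
#' Expects keys `kf1..kf4`, `kr1..kr4` (nM^-1 s^-1 and s^-1) and an
#' optional `metadata` block.
#'
#' @param path JSON file path.
#' @return a [binding_params()] object.
#' @export
read_binding_params <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(RATE_NAMES, names(x))
  if (length(missing))
    stop("schema error in ", path, ": missing key(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(binding_params,
          c(lapply(setNames(RATE_NAMES, RATE_NAMES),
                   function(nm) as.numeric(x[[nm]])),
            list(metadata = as.list(x$metadata))))
}

#' Read an experiment setup from a JSON file
#'
#' Keys mirror [experiment_setup()] arguments (units in the key names:
#' `volume_ml`, `antibody_mw_g_per_mol`, ...); absent keys take the
#' defaults.
#'
#' @param path JSON file path.
#' @return an [experiment_setup()].
#' @export
read_experiment_setup <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(experiment_setup))
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("schema error in ", path, ": unknown key(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(experiment_setup, x)
}

#' The packaged stand-in literature parameter table
#'
#' Eight antibody/receptor pairs (FMC63/CD19, Rituximab/CD20,
#' Herceptin/HER2, Cetuximab/EGFR, each as synNotch and CAR).  These are
#' SYNTHETIC STAND-IN values: the receptor-antibody arm (kf1/kr1, kf4/kr4)
#' emulates a tight tag-receptor bond (KD 0.1 nM), and the antibody-antigen
#' arm (kf2/kr2, kf3/kr3) uses published surface-plasmon-resonance kinetics
#' for each antibody.  See the package vignette for the construction.
#'
#' @param pair optional pair id; default returns all pairs.
#' @return a named list of [binding_params()] (or a single object if
#'   `pair` is given).
#' @export
literature_params <- function(pair = NULL) {
  path <- system.file("extdata", "literature_params_synthetic.json",
                      package = "ternarybinding", mustWork = TRUE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(x$pairs), function(id) {
    p <- x$pairs[[id]]
    # the stand-in table's detailed-balance violation is by construction
    # and documented in the file itself; do not re-warn on every load
    do.call(binding_params,
            c(lapply(setNames(RATE_NAMES, RATE_NAMES),
                     function(nm) as.numeric(p[[nm]])),
              list(metadata = as.list(p$metadata), check_balance = FALSE)))
  })
  names(out) <- names(x$pairs)
  if (is.null(pair)) return(out)
  if (!pair %in% names(out))
    stop("unknown pair '", pair, "'; available: ",
         paste(names(out), collapse = ", "), call. = FALSE)
  out[[pair]]
}

#' Read observed dose-response series from CSV
#'
#' Strict schema: columns `pair_id`, `dose_ug_per_ml`, `readout_mfi` and
#' optionally `readout_kind`; numeric doses strictly positive; no duplicate
#' (pair_id, dose) records.  Rows are grouped by pair and sorted by dose.
#'
#' @param path CSV file path (UTF-8, comma-separated, header row).
#' @return named list of [observed_dose_response()] objects.
#' @export
read_observed_csv <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("pair_id", "dose_ug_per_ml", "readout_mfi")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("dose_ug_per_ml", "readout_mfi")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("schema error in ", path, ": non-numeric '", col, "' at row ",
           bad[1], call. = FALSE)
    df[[col]] <- v
  }
  bad <- which(df$dose_ug_per_ml <= 0)
  if (length(bad))
    stop("schema error in ", path, ": non-positive dose at row ", bad[1],
         call. = FALSE)
  dup <- which(duplicated(df[c("pair_id", "dose_ug_per_ml")]))
  if (length(dup))
    stop("duplicate record in ", path, ": (pair_id, dose) repeated at row ",
         dup[1], call. = FALSE)
  if (!"readout_kind" %in% names(df)) df$readout_kind <- NA_character_

  out <- lapply(split(df, df$pair_id), function(g)
    observed_dose_response(g$pair_id[1], g$dose_ug_per_ml, g$readout_mfi,
                           readout_kind = g$readout_kind[1]))
  out[unique(df$pair_id)]
}

#' Write a dose-response curve as CSV
#'
#' Columns: `pair_id`, `dose_ug_per_ml`, `ternary_nM`,
#' `ternary_normalized`.
#'
#' @param curve a `dose_response`.
#' @param path output path.
#' @param pair_id overrides the curve's pair id attribute.
#' @return invisibly, the path.
#' @export
write_dose_response_csv <- function(curve, path, pair_id = NULL) {
  id <- pair_id %||% attr(curve, "pair_id") %||% NA_character_
  df <- data.frame(pair_id = id, curve)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write scan results as long-format CSV plus a JSON metadata sidecar
#'
#' @param scan a `scan_result`.
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return invisibly, the CSV path.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "scan_result"))
  df <- expand.grid(dose_ug_per_ml = scan$dose_grid,
                    parameter_value = scan$values,
                    KEEP.OUT.ATTRS = FALSE)[, 2:1]
  df$ternary_nM <- as.vector(t(scan$ternary_nM))
  df$ternary_normalized <- as.vector(t(scan$ternary_normalized))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(parameter = scan$parameter, n_param = length(scan$values),
         n_dose = length(scan$dose_grid),
         bounds = range(scan$values), dose_bounds = range(scan$dose_grid)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write cohort fit results as JSON and a CSV summary
#'
#' @param cohort a `fit_cohort`.
#' @param json_path,csv_path output paths.
#' @return invisibly, the JSON path.
#' @export
write_fit_results <- function(cohort, json_path, csv_path) {
  stopifnot(inherits(cohort, "fit_cohort"))
  ok <- vapply(cohort$fits, inherits, logical(1), what = "fit_result")
  per_pair <- lapply(cohort$fits[ok], function(f)
    list(pair_id = f$pair_id,
         params = setNames(lapply(RATE_NAMES, function(nm) f$params[[nm]]),
                           RATE_NAMES),
         sse_initial = f$sse_initial, sse_fitted = f$sse_fitted,
         bounds = list(lower = unname(f$bounds["lower", ]),
                       upper = unname(f$bounds["upper", ])),
         converged = f$converged))
  jsonlite::write_json(
    list(pairs = per_pair,
         mean_sse_initial = cohort$mean_sse_initial,
         mean_sse_fitted = cohort$mean_sse_fitted,
         outlier_pairs = cohort$outlier_pairs,
         failed_pairs = cohort$failed_pairs),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  df <- data.frame(
    pair_id = names(cohort$fits)[ok],
    sse_initial = vapply(cohort$fits[ok], function(f) f$sse_initial, 1),
    sse_fitted = vapply(cohort$fits[ok], function(f) f$sse_fitted, 1),
    converged = vapply(cohort$fits[ok], function(f) f$converged, TRUE))
  write.csv(df, csv_path, row.names = FALSE)
  invisible(json_path)
}
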