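#' Kinetic binding parameters for the ternary complex network
#'
#' Holds the eight mass-action rate constants of the four reversible binding
#' reactions: (1) T cell receptor + antibody, (2) antibody + tumor antigen,
#' (3) receptor-bound antibody + tumor antigen, (4) T cell receptor +
#' antigen-bound antibody.  Forward rates are in nM^-1 s^-1, reverse rates in
#' s^-1; dissociation constants KD_i = kr_i / kf_i (nM) are derived.
#'
#' The binding cycle closes thermodynamically only when
#' `KD1 * KD3 == KD2 * KD4` (detailed balance).  Literature rate sets
#' assembled from independent measurements need not satisfy this, so a
#' violation is reported as a warning, never an error.
#'
#' @param kf1,kf2,kf3,kf4 forward rate constants (nM^-1 s^-1), strictly
#'   positive and finite.
#' @param kr1,kr2,kr3,kr4 reverse rate constants (s^-1), strictly positive
#'   and finite.
#' @param metadata optional named list (antibody, antigen, receptor type,
#'   source) carried along unchanged.
#' @param check_balance warn when the detailed-balance ratio
#'   `KD1*KD3/(KD2*KD4)` deviates from 1 by more than 1e-6 relative.
#' @return An object of class `binding_params`: a list with the eight rates,
#'   a `KD` vector of length 4 and the metadata.
#' @examples
#' p <- binding_params(kf1 = 2e-3, kf2 = 2.2e-4, kf3 = 2.2e-4, kf4 = 2e-3,
#'                     kr1 = 2e-4, kr2 = 3.3e-4, kr3 = 3.3e-4, kr4 = 2e-4)
#' p$KD
#' @export
binding_params <- function(kf1, kf2, kf3, kf4, kr1, kr2, kr3, kr4,
                           metadata = list(), check_balance = TRUE) {
  rates <- c(kf1 = kf1, kf2 = kf2, kf3 = kf3, kf4 = kf4,
             kr1 = kr1, kr2 = kr2, kr3 = kr3, kr4 = kr4)
  for (nm in names(rates)) {
    v <- rates[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid input: rate constant '", nm,
           "' must be a strictly positive finite number", call. = FALSE)
  }
  kd <- unname(rates[5:8] / rates[1:4])
  names(kd) <- paste0("KD", 1:4)
  obj <- structure(
    c(as.list(rates), list(KD = kd, metadata = metadata)),
    class = "binding_params")
  if (check_balance) {
    ratio <- (kd[["KD1"]] * kd[["KD3"]]) / (kd[["KD2"]] * kd[["KD4"]])
    if (abs(ratio - 1) > 1e-6)
      warning("binding cycle violates detailed balance: KD1*KD3/(KD2*KD4) = ",
              signif(ratio, 4), " (not enforced)", call. = FALSE)
  }
  obj
}

#' @export
print.binding_params <- function(x, ...) {
  cat("Ternary binding rate constants\n")
  cat(sprintf("  forward (nM^-1 s^-1): kf1=%.3g kf2=%.3g kf3=%.3g kf4=%.3g\n",
              x$kf1, x$kf2, x$kf3, x$kf4))
  cat(sprintf("  reverse (s^-1):       kr1=%.3g kr2=%.3g kr3=%.3g kr4=%.3g\n",
              x$kr1, x$kr2, x$kr3, x$kr4))
  cat(sprintf("  KD (nM):              %s\n",
              paste(sprintf("%s=%.3g", names(x$KD), x$KD), collapse = " ")))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# rate constants as the numeric vector the C++ code expects
param_vector <- function(params) {
  stopifnot(inherits(params, "binding_params"))
  c(params$kf1, params$kf2, params$kf3, params$kf4,
    params$kr1, params$kr2, params$kr3, params$kr4)
}

#' Replace one rate constant or dissociation constant
#'
#' Used by parameter scans.  Rate names `kf1..kf4`/`kr1..kr4` set the rate
#' directly; `KD1..KD4` set the affinity by moving the *reverse* rate at
#' fixed forward rate (affinity here is bond persistence, as for covalent
#' tag chemistry).
#'
#' @param params a [binding_params()] object.
#' @param name parameter name.
#' @param value new positive value.
#' @return a new `binding_params` object.
#' @export
set_param <- function(params, name, value) {
  stopifnot(inherits(params, "binding_params"))
  allowed <- c(RATE_NAMES, paste0("KD", 1:4))
  if (!name %in% allowed)
    stop("invalid input: unknown parameter '", name, "'; allowed: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  r <- lapply(RATE_NAMES, function(nm) params[[nm]])
  names(r) <- RATE_NAMES
  if (name %in% RATE_NAMES) {
    r[[name]] <- value
  } else {
    i <- as.integer(substring(name, 3))
    r[[paste0("kr", i)]] <- value * r[[paste0("kf", i)]]
  }
  do.call(binding_params,
          c(r, list(metadata = params$metadata, check_balance = FALSE)))
}
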