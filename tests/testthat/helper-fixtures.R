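# shared fixtures; everything is generated in code, no stored data

RN <- c("kf1", "kf2", "kf3", "kf4", "kr1", "kr2", "kr3", "kr4")

params_from_vec <- function(k, ...) {
  do.call(binding_params,
          c(as.list(setNames(k, RN)), list(check_balance = FALSE, ...)))
}

# log-uniform random parameter draw over 4 orders of magnitude
rand_params <- function() params_from_vec(10^runif(8, -4, 0))

base_pair_params <- function() literature_params("FMC63_synNotch")

# reaction pair 1/2 only: all other rates negligibly small but positive
isolated_pair1 <- function(kf1 = 1, kr1 = 1) {
  params_from_vec(c(kf1, 1e-30, 1e-30, 1e-30, kr1, 1e-30, 1e-30, 1e-30))
}

# closed form for 1:1 binding A + B <-> AB at equilibrium
quadratic_bound <- function(a0, b0, kd) {
  s <- a0 + b0 + kd
  (s - sqrt(s^2 - 4 * a0 * b0)) / 2
}

# single local maximum on a grid, up to tol
is_unimodal <- function(v, tol = 1e-9 * max(v, 1e-300)) {
  dv <- diff(v)
  sgn <- ifelse(dv > tol, 1L, ifelse(dv < -tol, -1L, 0L))
  sgn <- sgn[sgn != 0L]
  if (length(sgn) <= 1L) return(TRUE)
  changes <- sum(diff(sgn) != 0L)
  changes == 0L || (changes == 1L && sgn[1] == 1L)
}

# truth perturbed by up to `factor` per rate (ground truth stays in bounds)
perturbed_params <- function(truth, factor = 3) {
  k <- vapply(RN, function(nm) truth[[nm]], numeric(1))
  params_from_vec(k * factor^runif(8, -1, 1))
}

# interpolated log10-dose width of the span where v >= half
interp_halfwidth <- function(d, v, half) {
  ld <- log10(d)
  if (!any(v >= half)) return(0)
  ip <- which.max(v)
  lo <- ld[1]
  hi <- ld[length(ld)]
  if (ip > 1 && any(v[1:ip] < half)) {
    i <- max(which(v[1:ip] < half))
    lo <- approx(v[c(i, i + 1)], ld[c(i, i + 1)], xout = half)$y
  }
  if (ip < length(v) && any(v[ip:length(v)] < half)) {
    j <- ip - 1 + min(which(v[ip:length(v)] < half))
    hi <- approx(v[c(j - 1, j)], ld[c(j - 1, j)], xout = half)$y
  }
  hi - lo
}
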