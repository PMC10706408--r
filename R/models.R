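## Kinetic model catalog: consecutive-reaction-chain (CRC) recruitment,
## exponential decay, single/double-exponential FRAP recovery with
## derived half-time and mobile fraction, and uniform-disk
## diffusion-limited recovery with derived effective diffusion
## coefficient.

## ---- consecutive reaction chain -------------------------------------------
## Occupancy of the final bound state of the linear first-order chain
## S0 -> S1 -> ... -> Sm -> (removed), S0(0) = 1, with rate vector
## r = (k1..km, kr): the Bateman closed form
##   S_m(t) = prod(k) * sum_j exp(-r_j t) / prod_{l != j} (r_l - r_j).
## Coincident rates are a removable singularity; rates closer than a
## relative 1e-9 are symmetrically perturbed by +/- eps before evaluation
## so the formula stays continuous in the parameters.

separate_rates <- function(r, eps_rel = 1e-9) {
  scale <- pmax(abs(r), 1e-12)
  repeat {
    clash <- FALSE
    for (i in seq_along(r)) for (j in seq_along(r)) {
      if (i < j && abs(r[i] - r[j]) < eps_rel * max(scale[i], scale[j])) {
        d <- eps_rel * max(scale[i], scale[j])
        r[i] <- r[i] - d / 2
        r[j] <- r[j] + d / 2
        clash <- TRUE
      }
    }
    if (!clash) return(r)
  }
}

bateman_terminal <- function(t, rates) {
  m <- length(rates) - 1L                 # chain steps (k1..km), last is kr
  if (m < 1L) input_error("need at least one chain rate")
  r <- separate_rates(rates)
  amp <- prod(r[seq_len(m)])
  out <- numeric(length(t))
  for (j in seq_along(r)) {
    denom <- prod(r[-j] - r[j])
    out <- out + exp(-r[j] * t) / denom
  }
  amp * out
}

#' Consecutive-reaction-chain recruitment model
#'
#' Recruitment of a repair protein to a lesion through up to three
#' sequential first-order steps with rates `k`, residence in the final
#' bound state, and first-order removal at rate `kr`. The observed signal
#' is the sum of a removable fraction `f_rem` (removal at `kr`) and a
#' non-removable fraction (removal rate 0):
#' `y(t) = B + A * (f_rem * S(t; k, kr) + (1 - f_rem) * S(t; k, 0))`.
#'
#' @param t time, seconds (>= 0).
#' @param k chain rates `k1..km`, 1/s, length 1..3.
#' @param kr removal rate, 1/s, >= 0.
#' @param f_rem removable fraction in [0, 1].
#' @param A amplitude (> 0); `B` baseline.
#' @param B baseline intensity.
#' @return intensity at `t`.
#' @examples
#' crc_model(c(0, 10, 1e3), k = 0.1)          # single step: B + A(1 - e^-kt)
#' @export
crc_model <- function(t, k, kr = 0, f_rem = 1, A = 1, B = 0) {
  if (length(k) < 1L || length(k) > 3L) input_error("1 to 3 chain rates required")
  if (any(k <= 0)) input_error("chain rates must be > 0")
  if (kr < 0) input_error("kr must be >= 0")
  if (f_rem < 0 || f_rem > 1) input_error("f_rem must be in [0, 1]")
  rem <- if (f_rem > 0) bateman_terminal(t, c(k, kr)) else 0
  fix <- if (f_rem < 1) bateman_terminal(t, c(k, 0)) else 0
  B + A * (f_rem * rem + (1 - f_rem) * fix)
}

#' Negative exponential decay model
#'
#' `y = C + A * exp(-k t)` — the depletion model for proteins locally
#' excluded from the damage site.
#'
#' @param t time, seconds.
#' @param A amplitude; `C` plateau; `k` decay rate 1/s (> 0).
#' @param k decay rate, 1/s.
#' @param C plateau.
#' @return intensity at `t`.
#' @export
exp_decay_model <- function(t, A, k, C = 0) {
  if (k <= 0) input_error("k must be > 0")
  C + A * exp(-k * t)
}

## ---- FRAP -----------------------------------------------------------------

#' FRAP recovery parameters
#'
#' @param variant `"single"` or `"double"`.
#' @param F0 post-bleach intensity; `Finf` recovery plateau.
#' @param Finf recovery plateau (`>= F0`).
#' @param k single-exponential exchange rate, 1/s.
#' @param B1,B2 double-exponential amplitudes (`B1 + B2 = Finf - F0`,
#'   checked to a relative 1e-6), with rates `k1 > k2 > 0`.
#' @param k1,k2 double-exponential rates, 1/s.
#' @param F_pre pre-bleach reference (1 on normalized curves).
#' @return an object of class `"FrapParams"`.
#' @export
frap_params <- function(variant = c("single", "double"), F0, Finf = NULL,
                        k = NULL, B1 = NULL, B2 = NULL, k1 = NULL, k2 = NULL,
                        F_pre = 1) {
  variant <- match.arg(variant)
  if (variant == "single") {
    if (is.null(Finf) || is.null(k)) input_error("single variant needs Finf and k")
    if (k <= 0) input_error("k must be > 0")
  } else {
    if (is.null(B1) || is.null(B2) || is.null(k1) || is.null(k2))
      input_error("double variant needs B1, B2, k1, k2")
    if (B1 < 0 || B2 < 0) input_error("B1 and B2 must be >= 0")
    if (!(k1 > 0 && k2 > 0)) input_error("rates must be > 0")
    if (is.null(Finf)) Finf <- F0 + B1 + B2
    if (abs((B1 + B2) - (Finf - F0)) >
        1e-6 * max(1, abs(Finf - F0)))
      consistency_error("B1 + B2 must equal Finf - F0")
  }
  if (Finf < F0) input_error("Finf must be >= F0")
  structure(list(variant = variant, F0 = F0, Finf = Finf, k = k,
                 B1 = B1, B2 = B2, k1 = k1, k2 = k2, F_pre = F_pre),
            class = "FrapParams")
}

#' FRAP recovery model
#'
#' Single: `F(t) = Finf - (Finf - F0) exp(-k t)`;
#' double: `F(t) = Finf - B1 exp(-k1 t) - B2 exp(-k2 t)`,
#' with `t` measured from the bleach.
#'
#' @param t post-bleach time, seconds (>= 0).
#' @param p a [frap_params()].
#' @return intensity at `t`.
#' @export
frap_model <- function(t, p) {
  if (!inherits(p, "FrapParams")) p <- do.call(frap_params, p)
  if (p$variant == "single")
    p$Finf - (p$Finf - p$F0) * exp(-p$k * t)
  else
    p$Finf - p$B1 * exp(-p$k1 * t) - p$B2 * exp(-p$k2 * t)
}

#' Half-time of FRAP recovery
#'
#' The smallest post-bleach time at which the recovery reaches the
#' midpoint `(F0 + Finf) / 2`. Analytic `ln 2 / k` for the single
#' exponential; bisection on the fitted curve for the double (no closed
#' form), to a relative time tolerance of 1e-6.
#'
#' @param p a [frap_params()] with `Finf > F0`.
#' @param t_max bisection bracket end; default `100 / min(rate)`.
#' @return half-time in seconds.
#' @export
frap_half_time <- function(p, t_max = NULL) {
  if (!inherits(p, "FrapParams")) p <- do.call(frap_params, p)
  if (p$Finf <= p$F0) input_error("non-recovering parameters (Finf <= F0)")
  if (p$variant == "single") return(log(2) / p$k)
  target <- (p$F0 + p$Finf) / 2
  t_max <- t_max %||% (100 / min(p$k1, p$k2))
  f <- function(t) frap_model(t, p) - target
  lo <- 0; hi <- t_max
  if (f(hi) < 0) input_error("recovery does not reach the midpoint by t_max")
  while (hi - lo > 1e-12 * max(hi, 1)) {   # near machine precision in t
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Mobile fraction of a FRAP recovery
#'
#' `M = (Finf - F0) / (F_pre - F0)`: the proportion of molecules that
#' exchange into the bleached region during recovery.
#'
#' @param p a [frap_params()] with `F_pre > F0`.
#' @return dimensionless fraction.
#' @export
mobile_fraction <- function(p) {
  if (!inherits(p, "FrapParams")) p <- do.call(frap_params, p)
  if (p$F_pre <= p$F0) input_error("F_pre must exceed F0")
  (p$Finf - p$F0) / (p$F_pre - p$F0)
}

## ---- diffusion-limited recovery -------------------------------------------

## e^-x (I0(x) + I1(x)), evaluated with scaled Bessel functions
ebessel_sum <- function(x) {
  besselI(x, 0, expon.scaled = TRUE) + besselI(x, 1, expon.scaled = TRUE)
}

#' Uniform-disk diffusion-limited FRAP recovery model
#'
#' Recovery of a uniformly bleached disk by pure diffusion:
#' `F(t) = F0 + (M - F0) * exp(-2 tau/t) * [I0(2 tau/t) + I1(2 tau/t)]`,
#' with `I0`, `I1` the modified Bessel functions of the first kind and
#' `tau_D` the characteristic diffusion time. The value at `t = 0` is the
#' limit `F0`. The effective diffusion coefficient is
#' `D_eff = w^2 / (4 tau_D)` for bleach-spot radius `w` (not fitted).
#'
#' @param t post-bleach time, seconds (>= 0).
#' @param tau_D characteristic diffusion time, s (> 0).
#' @param M mobile plateau.
#' @param F0 post-bleach intensity.
#' @return intensity at `t`.
#' @export
diffusion_model <- function(t, tau_D, M, F0 = 0) {
  if (tau_D <= 0) input_error("tau_D must be > 0")
  out <- rep(F0, length(t))
  pos <- t > 0
  x <- 2 * tau_D / t[pos]
  out[pos] <- F0 + (M - F0) * ebessel_sum(x)
  out
}

#' Effective diffusion coefficient from a diffusion-recovery fit
#' @param w bleach-spot radius, micrometres.
#' @param tau_D characteristic diffusion time, seconds.
#' @return `D_eff = w^2 / (4 tau_D)` in um^2/s.
#' @export
effective_diffusion <- function(w, tau_D) {
  chk_num1(w, "w", positive = TRUE)
  chk_num1(tau_D, "tau_D", positive = TRUE)
  w^2 / (4 * tau_D)
}
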