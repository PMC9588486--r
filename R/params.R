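#' Rate constants of the full mass-action ERK model
#'
#' Bundles the six elementary rate constants of the two-step MEK/ERK
#' phosphorylation network: substrate binding (`kf1`, `kf2`, 1/(uM min)),
#' unbinding (`kr1`, `kr2`, 1/min) and catalysis (`kc1`, `kc2`, 1/min).
#' The network is non-degenerate only when `kr1 + kc1 > 0` and
#' `kr2 + kc2 > 0`; both are enforced.
#'
#' @param kf1,kr1,kc1 first-site binding, unbinding and catalytic rates.
#' @param kf2,kr2,kc2 second-site binding, unbinding and catalytic rates.
#' @return An object of class `full_params` (named numeric vector).
#' @export
full_params <- function(kf1, kr1, kc1, kf2, kr2, kc2) {
  p <- c(kf1 = kf1, kr1 = kr1, kc1 = kc1, kf2 = kf2, kr2 = kr2, kc2 = kc2)
  if (anyNA(p) || any(p < 0))
    stop("all rate constants must be non-negative and finite")
  if ((p[["kr1"]] + p[["kc1"]]) <= 0 || (p[["kr2"]] + p[["kc2"]]) <= 0)
    stop("degenerate network: kr_i + kc_i must be positive for both sites")
  structure(p, class = "full_params")
}

#' Parameters of the reduced (Rational / Linear) ERK models
#'
#' `kappa1`, `kappa2` (1/min) are the kinetic efficiencies of the two
#' phosphorylation steps, `pi` (dimensionless, in `[0, 1]`) is the
#' processivity -- the probability that both phosphorylations happen in a
#' single enzyme encounter -- and `gamma1`, `gamma2` (1/uM) are the
#' saturation coefficients of the Rational model (ignored by the Linear
#' model, where they are effectively zero).
#'
#' @param kappa1,kappa2 kinetic efficiencies, 1/min.
#' @param pi processivity in `[0, 1]`.
#' @param gamma1,gamma2 saturation coefficients, 1/uM (default 0).
#' @return An object of class `reduced_params` (named numeric vector).
#' @export
reduced_params <- function(kappa1, kappa2, pi, gamma1 = 0, gamma2 = 0) {
  p <- c(kappa1 = kappa1, kappa2 = kappa2, pi = pi,
         gamma1 = gamma1, gamma2 = gamma2)
  if (anyNA(p) || any(p[c("kappa1", "kappa2", "gamma1", "gamma2")] < 0))
    stop("kappa_i and gamma_i must be non-negative")
  if (p[["pi"]] < 0 || p[["pi"]] > 1)
    stop("pi must lie in [0, 1]")
  structure(p, class = "reduced_params")
}

#' Experimental design of a time-course assay
#'
#' @param times strictly increasing positive measurement times, minutes.
#' @param replicates number of replicates, a positive integer.
#' @param S_tot total substrate concentration, uM (default 5).
#' @param E_tot total (activated) enzyme concentration, uM (default 0.65).
#' @param label variant name.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(times, replicates, S_tot = 5, E_tot = 0.65,
                              label = "synthetic") {
  times <- as.numeric(times)
  if (length(times) < 1 || any(times <= 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing and positive")
  replicates <- as.integer(replicates)
  if (replicates < 1) stop("replicates must be >= 1")
  if (S_tot <= 0 || E_tot < 0) stop("require S_tot > 0 and E_tot >= 0")
  structure(list(times = times, replicates = replicates,
                 S_tot = S_tot, E_tot = E_tot, label = label),
            class = "experiment_design")
}

#' Michaelis-Menten constants of the two phosphorylation steps
#'
#' `kM_i = (kc_i + kr_i) / kf_i`, in uM.  Experimentally both constants are
#' about 25 uM for the MEK/ERK system modelled here.
#'
#' @param params a [full_params] object.
#' @return Named numeric vector `c(kM1, kM2)`.
#' @export
michaelis_menten <- function(params) {
  if (params[["kf1"]] <= 0 || params[["kf2"]] <= 0)
    stop("kf_i must be positive to define a Michaelis-Menten constant")
  c(kM1 = (params[["kc1"]] + params[["kr1"]]) / params[["kf1"]],
    kM2 = (params[["kc2"]] + params[["kr2"]]) / params[["kf2"]])
}

#' Map full rate constants to reduced-model parameters
#'
#' Computes the reduced parameterisation
#' `kappa_i = E_tot * kf_i * kc_i / (kc_i + kr_i)`,
#' `pi = kc2 / (kc2 + kr2)` and
#' `gamma_i = kf_i * (kc1 + kc2) / ((kc1 + kr1) * (kc2 + kr2))`.
#'
#' @param params a [full_params] object.
#' @param E_tot total enzyme, uM.
#' @return A [reduced_params] object.
#' @export
reduced_from_full <- function(params, E_tot) {
  A <- params[["kc1"]] + params[["kr1"]]
  B <- params[["kc2"]] + params[["kr2"]]
  if (A <= 0 || B <= 0)
    stop("degenerate network: kr_i + kc_i must be positive")
  kcs <- params[["kc1"]] + params[["kc2"]]
  reduced_params(
    kappa1 = E_tot * params[["kf1"]] * params[["kc1"]] / A,
    kappa2 = E_tot * params[["kf2"]] * params[["kc2"]] / B,
    pi     = params[["kc2"]] / B,
    gamma1 = params[["kf1"]] * kcs / (A * B),
    gamma2 = params[["kf2"]] * kcs / (A * B))
}
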