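## Vector fields, conservation laws and trajectories of the Full, Rational
## and Linear ERK models.  States are named numeric vectors:
##   full model:    (S0, C1, C2, S1, S2, E)   [uM]
##   reduced model: (S0, S1, S2)              [uM]
## Time is in minutes throughout.

#' Right-hand side of the full mass-action ERK model
#'
#' The six coupled mass-action ODEs for unphosphorylated substrate `S0`,
#' the two enzyme-substrate complexes `C1`, `C2`, the mono- and dually
#' phosphorylated substrates `S1`, `S2`, and free enzyme `E`.  Two linear
#' conservation laws hold exactly: `S0+S1+S2+C1+C2` and `E+C1+C2` are
#' constant, so the six returned rates satisfy
#' `dS0+dC1+dC2+dS1+dS2 = 0` and `dE+dC1+dC2 = 0`.
#'
#' @param state named numeric vector `(S0, C1, C2, S1, S2, E)`, uM.
#' @param params a [full_params] object.
#' @return Named numeric vector of the six time derivatives, uM/min.
#' @export
full_rhs <- function(state, params) {
  S0 <- state[["S0"]]; C1 <- state[["C1"]]; C2 <- state[["C2"]]
  S1 <- state[["S1"]]; S2 <- state[["S2"]]; E <- state[["E"]]
  kf1 <- params[["kf1"]]; kr1 <- params[["kr1"]]; kc1 <- params[["kc1"]]
  kf2 <- params[["kf2"]]; kr2 <- params[["kr2"]]; kc2 <- params[["kc2"]]
  bind1 <- kf1 * E * S0
  bind2 <- kf2 * E * S1
  c(S0 = -bind1 + kr1 * C1,
    C1 = bind1 - (kr1 + kc1) * C1,
    C2 = kc1 * C1 - (kr2 + kc2) * C2 + bind2,
    S1 = -bind2 + kr2 * C2,
    S2 = kc2 * C2,
    E  = -bind1 + kr1 * C1 - bind2 + (kr2 + kc2) * C2)
}

#' Conserved quantities of the full ERK model
#'
#' @param state named full-model state vector.
#' @return `c(S_tot, E_tot)` = `(S0+S1+S2+C1+C2, E+C1+C2)`.
#' @export
conserved_quantities <- function(state) {
  c(S_tot = state[["S0"]] + state[["S1"]] + state[["S2"]] +
      state[["C1"]] + state[["C2"]],
    E_tot = state[["E"]] + state[["C1"]] + state[["C2"]])
}

#' Right-hand side of the Rational ERK model
#'
#' Three-species reduction with Michaelis-Menten-type saturation:
#' all three rates share the denominator `gamma1*S0 + gamma2*S1 + 1`,
#' and they sum to zero (substrate conservation).
#'
#' @param state named numeric vector `(S0, S1, S2)`, uM.
#' @param params a [reduced_params] object.
#' @return Named numeric vector of the three time derivatives, uM/min.
#' @export
rational_rhs <- function(state, params) {
  S0 <- state[["S0"]]; S1 <- state[["S1"]]
  den <- params[["gamma1"]] * S0 + params[["gamma2"]] * S1 + 1
  k1S0 <- params[["kappa1"]] * S0
  k2S1 <- params[["kappa2"]] * S1
  p <- params[["pi"]]
  c(S0 = -k1S0 / den,
    S1 = (-k2S1 + (1 - p) * k1S0) / den,
    S2 = (p * k1S0 + k2S1) / den)
}

#' Right-hand side of the Linear ERK model
#'
#' The fully linear reduction: `dS0 = -kappa1*S0`,
#' `dS1 = -kappa2*S1 + (1-pi)*kappa1*S0`, `dS2 = pi*kappa1*S0 + kappa2*S1`.
#' Identical to [rational_rhs] with `gamma1 = gamma2 = 0`.
#'
#' @inheritParams rational_rhs
#' @return Named numeric vector of the three time derivatives, uM/min.
#' @export
linear_rhs <- function(state, params) {
  S0 <- state[["S0"]]; S1 <- state[["S1"]]
  k1S0 <- params[["kappa1"]] * S0
  k2S1 <- params[["kappa2"]] * S1
  p <- params[["pi"]]
  c(S0 = -k1S0,
    S1 = -k2S1 + (1 - p) * k1S0,
    S2 = p * k1S0 + k2S1)
}

## Numerically stable difference quotient (exp(-k2 t) - exp(-k1 t))/(k1 - k2)
## = t exp(-k1 t) * expm1(u)/u with u = (k1 - k2) t; series near u = 0.
exp_diff_quot <- function(t, k1, k2) {
  u <- (k1 - k2) * t
  small <- abs(u) < 1e-8 * pmax(abs(k1), abs(k2), 1) * pmax(t, 1)
  q <- numeric(length(u))
  q[small] <- t[small] * exp(-k1 * t[small]) *
    (1 + u[small] / 2 + u[small]^2 / 6)
  if (any(!small)) {
    ts <- t[!small]
    q[!small] <- (exp(-k2 * ts) - exp(-k1 * ts)) / (k1 - k2)
  }
  q
}

#' Closed-form solution of the Linear ERK model
#'
#' `S0(t) = S_tot e^{-kappa1 t}`;
#' `S1(t) = S_tot kappa1 (1-pi) t e^{-kappa1 t}` when `kappa1 = kappa2`, and
#' `S_tot kappa1 (1-pi) (e^{-kappa2 t} - e^{-kappa1 t})/(kappa1 - kappa2)`
#' otherwise; `S2 = S_tot - S0 - S1`.  The two branches are evaluated
#' through a single series-stable difference quotient, so the solution is
#' continuous across the `kappa1 = kappa2` locus.
#'
#' @param t vector of times, minutes (>= 0).
#' @param params a [reduced_params] object (gammas ignored).
#' @param S_tot total substrate, uM.
#' @return Matrix with rows `S0`, `S1`, `S2` and one column per time.
#' @export
linear_solution <- function(t, params, S_tot) {
  stopifnot(all(t >= 0))
  k1 <- params[["kappa1"]]; k2 <- params[["kappa2"]]; p <- params[["pi"]]
  S0 <- S_tot * exp(-k1 * t)
  S1 <- S_tot * k1 * (1 - p) * exp_diff_quot(t, k1, k2)
  out <- rbind(S0 = S0, S1 = S1, S2 = S_tot - S0 - S1)
  colnames(out) <- as.character(t)
  out
}

#' Integrate a model numerically
#'
#' Adaptive explicit Runge-Kutta solution (Dormand-Prince via
#' \pkg{deSolve}'s `ode45`) sampled at the requested times.  The systems
#' are non-stiff at the experimentally relevant parameter magnitudes
#' (rates of order 1/min, Michaelis constants ~25 uM), so an explicit
#' method with tight tolerances is appropriate.
#'
#' @param rhs one of [full_rhs], [rational_rhs], [linear_rhs], or any
#'   function `(state, params) -> rates` over named states.
#' @param params parameter object understood by `rhs`.
#' @param x0 named initial state.
#' @param times increasing output times (minutes); 0 is prepended if absent.
#' @param rel_tol,abs_tol solver tolerances.
#' @return Matrix: one row per species (named as in `x0`), one column per
#'   requested time (excluding the prepended 0 unless requested).
#' @export
simulate_model <- function(rhs, params, x0, times,
                           rel_tol = 1e-8, abs_tol = 1e-10) {
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  t_out <- if (times[1] > 0) c(0, times) else times
  deriv <- function(t, y, parms) list(unname(rhs(y, parms)))
  sol <- deSolve::ode(y = x0, times = t_out, func = deriv, parms = params,
                      method = "ode45", rtol = rel_tol, atol = abs_tol)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failure near t = ", max(sol[, 1]))
  keep <- match(times, sol[, 1])
  out <- t(sol[keep, -1, drop = FALSE])
  rownames(out) <- names(x0)
  colnames(out) <- as.character(times)
  out
}

#' Default initial condition of a model
#'
#' The assay starts with all substrate unphosphorylated and all enzyme
#' free: the full model at `(S_tot, 0, 0, 0, 0, E_tot)`, the reduced
#' models at `(S_tot, 0, 0)`.
#'
#' @param design an [experiment_design].
#' @param model `"full"`, `"rational"` or `"linear"`.
#' @return Named initial state vector.
#' @export
initial_state <- function(design, model = c("full", "rational", "linear")) {
  model <- match.arg(model)
  if (model == "full")
    c(S0 = design$S_tot, C1 = 0, C2 = 0, S1 = 0, S2 = 0, E = design$E_tot)
  else
    c(S0 = design$S_tot, S1 = 0, S2 = 0)
}

#' Noise-free observable trajectory of a model
#'
#' Returns the three observed phosphorylation states (S0, S1, S2) at the
#' design's time points.  The full model uses the fast compiled integrator;
#' `compound = TRUE` returns the experimentally measured channels
#' `(S0 + C1, S1 + C2, S2)` instead of the bare substrate states.
#'
#' @param params [full_params] (model "full") or [reduced_params].
#' @param design an [experiment_design].
#' @param model `"full"`, `"rational"` or `"linear"`.
#' @param compound full model only: report compound measurement channels.
#' @return 3 x l matrix (rows S0, S1, S2; columns = times).
#' @export
model_trajectory <- function(params, design,
                             model = c("full", "rational", "linear"),
                             compound = FALSE) {
  model <- match.arg(model)
  tt <- design$times
  if (model == "linear")
    return(linear_solution(tt, params, design$S_tot))
  if (model == "rational") {
    tr <- ode_rational_cpp(unname(params[c("kappa1", "kappa2", "pi",
                                           "gamma1", "gamma2")]),
                           design$S_tot, tt, 1e-8, 1e-10)
    dimnames(tr) <- list(c("S0", "S1", "S2"), as.character(tt))
    return(tr)
  }
  tr <- ode_full_cpp(unname(params[c("kf1", "kr1", "kc1",
                                     "kf2", "kr2", "kc2")]),
                     design$S_tot, design$E_tot, tt, 1e-8, 1e-10)
  dimnames(tr) <- list(c("S0", "C1", "C2", "S1", "S2", "E"),
                       as.character(tt))
  if (compound)
    rbind(S0 = tr["S0", ] + tr["C1", ],
          S1 = tr["S1", ] + tr["C2", ],
          S2 = tr["S2", ])
  else
    tr[c("S0", "S1", "S2"), , drop = FALSE]
}

#' Write a trajectory as long-format CSV
#'
#' Columns `time,species,value`, one row per (time, species) pair.
#'
#' @param traj species x time matrix as returned by [model_trajectory].
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(
    time = rep(as.numeric(colnames(traj)), each = nrow(traj)),
    species = rep(rownames(traj), ncol(traj)),
    value = as.vector(traj))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
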