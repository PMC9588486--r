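## Algebraic quasi-steady-state reduction.
##
## A system dx/dt = f(x, theta) is split into retained variables x1 and
## eliminated variables x2 with blocks f1, f2.  Where the Jacobian D2f2 is
## invertible, the reduced dynamics
##     dx1/dt = f1(x, theta),  dx2/dt = -D2f2^{-1} D1f2 f1(x, theta)
## has the zero set of f2 (the quasi-steady-state variety) as an invariant
## set and agrees there with the classically eliminated model.
##
## For the ERK network the retained variables are the substrate states
## (S0, S1, S2) and the eliminated ones the complexes (C1, C2), after one
## of two conservation-law substitutions for free enzyme:
##   "conservation_E":  E = E_tot - C1 - C2            (Rational path)
##   "conservation_S":  E = E_tot - S_tot + S0 + S1 + S2  (Linear path)

#' Construct a split system for quasi-steady-state reduction
#'
#' @param f1 function `(x1, x2, params) -> rates of x1`.
#' @param f2 function `(x1, x2, params) -> rates of x2`.
#' @param D1f2,D2f2 optional analytic Jacobians of `f2` with respect to
#'   `x1` and `x2`; central finite differences are used when absent.
#' @param fd_step relative finite-difference step.
#' @return An object of class `split_system`.
#' @export
split_system <- function(f1, f2, D1f2 = NULL, D2f2 = NULL, fd_step = 1e-6) {
  num_jac <- function(fun, wrt) {
    function(x1, x2, params) {
      base <- if (wrt == 1) x1 else x2
      f0 <- f2(x1, x2, params)
      J <- matrix(0, length(f0), length(base))
      for (i in seq_along(base)) {
        h <- fd_step * max(1, abs(base[i]))
        up <- base; up[i] <- base[i] + h
        dn <- base; dn[i] <- base[i] - h
        fp <- if (wrt == 1) f2(up, x2, params) else f2(x1, up, params)
        fm <- if (wrt == 1) f2(dn, x2, params) else f2(x1, dn, params)
        J[, i] <- (fp - fm) / (2 * h)
      }
      J
    }
  }
  structure(list(f1 = f1, f2 = f2,
                 D1f2 = if (is.null(D1f2)) num_jac(f2, 1) else D1f2,
                 D2f2 = if (is.null(D2f2)) num_jac(f2, 2) else D2f2),
            class = "split_system")
}

#' Eliminated-variable dynamics of the ERK network
#'
#' The two complex equations after substituting free enzyme through one of
#' the two conservation laws.
#'
#' @param substitution `"conservation_E"` (`E = E_tot - C1 - C2`, the
#'   Rational path) or `"conservation_S"`
#'   (`E = E_tot - S_tot + S0 + S1 + S2`, the Linear path).
#' @param state named vector with `S0, S1, S2, C1, C2` (uM).
#' @param params a [full_params] object.
#' @param design an [experiment_design] (supplies `S_tot`, `E_tot`).
#' @return Numeric 2-vector `(dC1/dt, dC2/dt)`.
#' @export
erk_f2 <- function(substitution = c("conservation_E", "conservation_S"),
                   state, params, design) {
  substitution <- match.arg(substitution)
  E <- erk_free_enzyme(substitution, state, design)
  c(params[["kf1"]] * E * state[["S0"]] -
      (params[["kr1"]] + params[["kc1"]]) * state[["C1"]],
    params[["kc1"]] * state[["C1"]] +
      params[["kf2"]] * E * state[["S1"]] -
      (params[["kr2"]] + params[["kc2"]]) * state[["C2"]])
}

erk_free_enzyme <- function(substitution, state, design) {
  if (substitution == "conservation_E")
    design$E_tot - state[["C1"]] - state[["C2"]]
  else
    design$E_tot - design$S_tot +
      state[["S0"]] + state[["S1"]] + state[["S2"]]
}

#' Split system for the ERK network
#'
#' Builds the [split_system] (retained `(S0, S1, S2)`, eliminated
#' `(C1, C2)`) for either conservation-law substitution, with analytic
#' Jacobians.
#'
#' @inheritParams erk_f2
#' @return A `split_system`; its functions take `(x1, x2, params)` with
#'   `x1 = (S0, S1, S2)` and `x2 = (C1, C2)`.
#' @export
erk_split_system <- function(substitution = c("conservation_E",
                                              "conservation_S"),
                             design) {
  substitution <- match.arg(substitution)
  pack <- function(x1, x2)
    c(S0 = x1[[1]], S1 = x1[[2]], S2 = x1[[3]], C1 = x2[[1]], C2 = x2[[2]])
  f1 <- function(x1, x2, params) {
    st <- pack(x1, x2)
    E <- erk_free_enzyme(substitution, st, design)
    c(-params[["kf1"]] * E * st[["S0"]] + params[["kr1"]] * st[["C1"]],
      -params[["kf2"]] * E * st[["S1"]] + params[["kr2"]] * st[["C2"]],
      params[["kc2"]] * st[["C2"]])
  }
  f2 <- function(x1, x2, params)
    erk_f2(substitution, pack(x1, x2), params, design)
  if (substitution == "conservation_E") {
    D1f2 <- function(x1, x2, params) {
      E <- design$E_tot - x2[[1]] - x2[[2]]
      rbind(c(params[["kf1"]] * E, 0, 0),
            c(0, params[["kf2"]] * E, 0))
    }
    D2f2 <- function(x1, x2, params)
      rbind(c(-params[["kf1"]] * x1[[1]] -
                (params[["kr1"]] + params[["kc1"]]),
              -params[["kf1"]] * x1[[1]]),
            c(-params[["kf2"]] * x1[[2]] + params[["kc1"]],
              -params[["kf2"]] * x1[[2]] -
                (params[["kr2"]] + params[["kc2"]])))
  } else {
    D1f2 <- function(x1, x2, params) {
      E <- design$E_tot - design$S_tot + sum(x1)
      rbind(params[["kf1"]] * c(E + x1[[1]], x1[[1]], x1[[1]]),
            params[["kf2"]] * c(x1[[2]], E + x1[[2]], x1[[2]]))
    }
    D2f2 <- function(x1, x2, params)
      rbind(c(-(params[["kr1"]] + params[["kc1"]]), 0),
            c(params[["kc1"]],
              -(params[["kr2"]] + params[["kc2"]])))
  }
  split_system(f1, f2, D1f2, D2f2)
}

#' Rank check of the eliminated-block Jacobian
#'
#' Scale-free invertibility test: `|det D2f2| >` `rank_tol` times the
#' product of the row infinity-norms.
#'
#' @param system a [split_system].
#' @param x1,x2 retained and eliminated state.
#' @param params parameters.
#' @param rank_tol relative determinant tolerance.
#' @return `TRUE` iff `D2f2` is (numerically) invertible at the point.
#' @export
d2_rank_check <- function(system, x1, x2, params, rank_tol = 1e-12) {
  J <- system$D2f2(x1, x2, params)
  scale <- prod(apply(abs(J), 1, max))
  abs(det(J)) > rank_tol * max(scale, .Machine$double.xmin)
}

#' Reduced dynamics on the quasi-steady-state variety
#'
#' Evaluates the reduction
#' `(f1, -D2f2^{-1} D1f2 f1)` at a state.
#'
#' @inheritParams d2_rank_check
#' @return List with components `retained` (rates of `x1`) and
#'   `eliminated` (induced rates of `x2`).
#' @export
qss_reduced_rhs <- function(system, x1, x2, params) {
  if (!d2_rank_check(system, x1, x2, params))
    stop("singular eliminated-block Jacobian D2f2 at this state")
  r1 <- system$f1(x1, x2, params)
  J2 <- system$D2f2(x1, x2, params)
  J1 <- system$D1f2(x1, x2, params)
  list(retained = r1, eliminated = as.vector(-solve(J2, J1 %*% r1)))
}

#' Complex concentrations slaved to the substrate state
#'
#' Solves `f2 = 0` for `(C1, C2)` at a given substrate state (a 2x2
#' linear solve for both substitutions), i.e. the point of the
#' quasi-steady-state variety above `(S0, S1, S2)`.
#'
#' @inheritParams erk_f2
#' @param S named vector `(S0, S1, S2)`.
#' @return Named vector `(C1, C2)`.
#' @export
erk_slaved_state <- function(substitution = c("conservation_E",
                                              "conservation_S"),
                             S, params, design) {
  substitution <- match.arg(substitution)
  sys <- erk_split_system(substitution, design)
  J <- sys$D2f2(S, c(0, 0), params)
  b <- -erk_f2(substitution, c(S, C1 = 0, C2 = 0), params, design)
  C <- solve(J, b)
  c(C1 = C[[1]], C2 = C[[2]])
}

#' Residual of the variety equations along a trajectory
#'
#' Supremum over sampled times of the infinity norm of `f2`; a small value
#' certifies numerical invariance of the quasi-steady-state variety under
#' the reduced dynamics.
#'
#' @param trajectory 5 x l matrix with rows `S0, S1, S2, C1, C2`.
#' @param system a [split_system] whose `f2` takes `(x1, x2, params)`.
#' @param params parameters.
#' @return Scalar sup-norm residual.
#' @export
variety_residual <- function(trajectory, system, params) {
  res <- apply(trajectory, 2, function(x)
    max(abs(system$f2(x[1:3], x[4:5], params))))
  max(res)
}

#' Sup-norm difference between two trajectories per species
#'
#' @param full_traj,reduced_traj species x time matrices sampled at the
#'   same times, with matching row names for the compared species.
#' @return Named vector of per-species sup-norm differences.
#' @export
reduction_error <- function(full_traj, reduced_traj) {
  sp <- intersect(rownames(full_traj), rownames(reduced_traj))
  if (length(sp) == 0 ||
      ncol(full_traj) != ncol(reduced_traj))
    stop("trajectories must share species rows and time columns")
  apply(abs(full_traj[sp, , drop = FALSE] -
              reduced_traj[sp, , drop = FALSE]), 1, max)
}
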