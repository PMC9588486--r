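wt_design <- function() experiment_design(c(0.5, 2, 3.25, 3.75, 5, 10, 20),
                                          11)

test_that("eliminated-block dynamics match the printed subsystems", {
  d <- wt_design()
  p <- full_params(0.08, 1.2, 0.9, 0.07, 0.8, 1.1)
  ## on the substrate simplex with no complexes and no enzyme, both
  ## substitutions are at quasi-steady state
  d0 <- experiment_design(d$times, 1, S_tot = 5, E_tot = 0)
  st <- c(S0 = 2, S1 = 2, S2 = 1, C1 = 0, C2 = 0)
  expect_equal(erk_f2("conservation_E", st, p, d0), c(0, 0))
  expect_equal(erk_f2("conservation_S", st, p, d0), c(0, 0))
  ## with kf1 = 0 the first component is pure complex decay
  p0 <- c(kf1 = 0, kr1 = 1.2, kc1 = 0.9, kf2 = 0.07, kr2 = 0.8, kc2 = 1.1)
  st2 <- c(S0 = 2, S1 = 1, S2 = 1, C1 = 0.3, C2 = 0.2)
  expect_equal(erk_f2("conservation_S", st2, p0, d)[1],
               -(1.2 + 0.9) * 0.3)
  ## both substitutions coincide when C1 = C2 = 0 and S0+S1+S2 = S_tot
  st3 <- c(S0 = 2, S1 = 2, S2 = 1, C1 = 0, C2 = 0)
  expect_equal(erk_f2("conservation_E", st3, p, d),
               erk_f2("conservation_S", st3, p, d))
})

test_that("the eliminated-block Jacobian rank test", {
  d <- wt_design()
  p <- full_params(0.08, 1.2, 0.9, 0.07, 0.8, 1.1)
  sysS <- erk_split_system("conservation_S", d)
  sysE <- erk_split_system("conservation_E", d)
  S <- c(2, 1, 2); C <- c(0.1, 0.1)
  expect_true(d2_rank_check(sysS, S, C, p))
  expect_true(d2_rank_check(sysE, c(0, 0, 5), C, p))
  pdeg <- c(kf1 = 0.08, kr1 = 0, kc1 = 0, kf2 = 0.07, kr2 = 0.8,
            kc2 = 1.1)
  expect_false(d2_rank_check(sysS, S, C, pdeg))
})

test_that("finite-difference Jacobians agree with the analytic ones", {
  d <- wt_design()
  p <- full_params(0.08, 1.2, 0.9, 0.07, 0.8, 1.1)
  for (sub in c("conservation_E", "conservation_S")) {
    sys <- erk_split_system(sub, d)
    num <- split_system(sys$f1, sys$f2)
    S <- c(2.3, 1.1, 1.6); C <- c(0.2, 0.1)
    expect_equal(sys$D2f2(S, C, p), num$D2f2(S, C, p), tolerance = 1e-7)
    expect_equal(sys$D1f2(S, C, p), num$D1f2(S, C, p), tolerance = 1e-7)
  }
})

test_that("generic reduction formula: zero retained dynamics and
           implicit-function consistency", {
  ## f1 == 0 makes the whole reduced field zero
  sys0 <- split_system(f1 = function(x1, x2, p) c(0, 0),
                       f2 = function(x1, x2, p) x2 - x1)
  out <- qss_reduced_rhs(sys0, c(1, 2), c(1, 2), NULL)
  expect_equal(out$retained, c(0, 0))
  expect_equal(out$eliminated, c(0, 0))
  ## f2 = x2 - g(x1) with D2f2 = I reproduces the chain rule dx2 = Dg f1
  g <- function(x1) c(x1[1]^2, x1[1] * x1[2])
  sys <- split_system(f1 = function(x1, x2, p) c(1, -2),
                      f2 = function(x1, x2, p) x2 - g(x1))
  x1 <- c(0.7, 1.3)
  out <- qss_reduced_rhs(sys, x1, g(x1), NULL)
  Dg <- rbind(c(2 * x1[1], 0), c(x1[2], x1[1]))
  expect_equal(out$eliminated, as.vector(Dg %*% c(1, -2)),
               tolerance = 1e-6)
  ## singular Jacobian is an error
  syss <- split_system(f1 = function(x1, x2, p) 1,
                       f2 = function(x1, x2, p) c(0 * x2[1], 0 * x2[2]))
  expect_error(qss_reduced_rhs(syss, 1, c(1, 1), NULL), "singular")
})

test_that("conservation-S slaving reproduces the Linear model exactly", {
  set.seed(4)
  d <- wt_design()
  sys <- erk_split_system("conservation_S", d)
  for (i in 1:100) {
    p <- full_params(runif(1, 0.01, 0.5), runif(1, 0.2, 3),
                     runif(1, 0.2, 3), runif(1, 0.01, 0.5),
                     runif(1, 0.2, 3), runif(1, 0.2, 3))
    rp <- reduced_from_full(p, d$E_tot)
    u <- runif(3); u <- u / sum(u) * d$S_tot
    S <- c(S0 = u[1], S1 = u[2], S2 = u[3])
    C <- erk_slaved_state("conservation_S", S, p, d)
    out <- qss_reduced_rhs(sys, S, C, p)
    ref <- linear_rhs(S, rp)
    expect_lt(max(abs(out$retained - ref) / pmax(abs(ref), 1e-12)), 1e-10)
  }
})

test_that("conservation-E slaving is rational of the same form, with the
           exact-elimination denominator", {
  ## Solving f2 = 0 under E = E_tot - C1 - C2 gives a saturation
  ## denominator 1 + kf1(kc1+kc2+kr2)S0/(AB) + kf2(kc1+kr1)S1/(AB)
  ## (A = kc1+kr1, B = kc2+kr2); the reduced-parameter map's printed
  ## gamma_i = kf_i (kc1+kc2)/(AB) uses kc1+kc2 in both slots, so the two
  ## denominators differ unless kr2 = 0 and kr1 = kc2.  The retained block
  ## equals the rational field built with the exact coefficients.
  set.seed(5)
  d <- wt_design()
  sys <- erk_split_system("conservation_E", d)
  for (i in 1:100) {
    p <- full_params(runif(1, 0.01, 0.5), runif(1, 0.2, 3),
                     runif(1, 0.2, 3), runif(1, 0.01, 0.5),
                     runif(1, 0.2, 3), runif(1, 0.2, 3))
    A <- p[["kc1"]] + p[["kr1"]]; B <- p[["kc2"]] + p[["kr2"]]
    rp <- reduced_from_full(p, d$E_tot)
    exact <- reduced_params(rp[["kappa1"]], rp[["kappa2"]], rp[["pi"]],
                            gamma1 = p[["kf1"]] *
                              (p[["kc1"]] + p[["kc2"]] + p[["kr2"]]) /
                              (A * B),
                            gamma2 = p[["kf2"]] / B)
    u <- runif(3, 0.2, 2)
    S <- c(S0 = u[1], S1 = u[2], S2 = u[3])
    C <- erk_slaved_state("conservation_E", S, p, d)
    out <- qss_reduced_rhs(sys, S, C, p)
    ref <- rational_rhs(S, exact)
    expect_lt(max(abs(out$retained - ref) / pmax(abs(ref), 1e-12)), 1e-10)
    ## the printed-parameter field deviates by a common positive factor
    printed <- rational_rhs(S, rp)
    ratio <- out$retained / printed
    expect_lt(diff(range(ratio)), 1e-8)
  }
})

test_that("the quasi-steady-state variety is invariant under the reduced
           dynamics when it contains the initial condition", {
  d0 <- experiment_design(c(0.5, 2, 5, 10), 1, S_tot = 5, E_tot = 0)
  p <- full_params(0.08, 1.2, 0.9, 0.07, 0.8, 1.1)
  sys <- erk_split_system("conservation_E", d0)
  rhs5 <- function(x, pp) {
    out <- qss_reduced_rhs(sys, x[1:3], x[4:5], pp)
    c(out$retained, out$eliminated)
  }
  x0 <- c(S0 = 5, S1 = 0, S2 = 0, C1 = 0, C2 = 0)
  tr <- simulate_model(rhs5, p, x0, d0$times, abs_tol = 1e-10)
  expect_lt(variety_residual(tr, sys, p), 10 * 1e-10)
})

test_that("reduction error: axioms and the experimental-regime comparison", {
  grid <- experiment_design(seq(0.5, 20, by = 0.5), 1)
  fp <- full_params(0.08, 1, 1, 0.08, 1, 1)  # kM = 25 both sites
  rp <- reduced_from_full(fp, 0.65)
  f <- model_trajectory(fp, grid, "full")
  expect_equal(unname(reduction_error(f, f)), c(0, 0, 0))
  e_lin <- reduction_error(f, model_trajectory(rp, grid, "linear"))
  e_rat <- reduction_error(f, model_trajectory(rp, grid, "rational"))
  expect_true(all(e_lin >= 0) && all(e_rat >= 0))
  ## both reductions track the full model to within 10% of S_tot, and
  ## neither is more than an order of magnitude worse than the other
  expect_lt(max(e_lin), 0.1 * 5)
  expect_lt(max(e_rat), 0.1 * 5)
  expect_lt(max(e_lin) / max(e_rat), 10)
  expect_error(reduction_error(f[, 1:3], f[, 1:5]), "share")
})

test_that("linear reduction error vanishes monotonically with E_tot", {
  errs <- vapply(c(0.65, 0.2, 0.05), function(et) {
    grid <- experiment_design(seq(0.5, 20, by = 0.5), 1, E_tot = et)
    fp <- full_params(0.08, 1, 1, 0.08, 1, 1)
    rp <- reduced_from_full(fp, et)
    max(reduction_error(model_trajectory(fp, grid, "full"),
                        model_trajectory(rp, grid, "linear")))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 5)
})
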