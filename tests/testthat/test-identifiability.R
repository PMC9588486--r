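wt_data <- function(sigma = 0.1, seed = 42,
                    truth = reduced_params(0.5, 1.5, 0.3)) {
  d <- default_designs()[["wild-type"]]
  generate_timecourse(variant_scenario(d, truth, sigma), "linear", seed)
}

test_that("the prediction map has the documented shape and values", {
  d <- default_designs()[["wild-type"]]
  rp <- reduced_params(0.5, 1.5, 0.3)
  v <- prediction_map(rp, d, "linear")
  expect_length(v, 3 * 7 * 11)
  ## all replicates repeat the same block
  expect_equal(v[1:21], v[22:42])
  ## entries equal the closed-form solution, species fastest
  sol <- linear_solution(d$times, rp, d$S_tot)
  expect_equal(v[1:21], as.vector(sol))
  ## kappa1 = 0 freezes S0 at S_tot
  v0 <- prediction_map(reduced_params(0, 1, 0.5), d, "linear")
  expect_equal(unique(v0[seq(1, 21, by = 3)]), d$S_tot)
})

test_that("maximum-likelihood fitting recovers truth and flags boundary
           solutions", {
  z0 <- wt_data(sigma = 0)
  fit0 <- mle_fit(z0, "linear", seed = 1)
  expect_lt(fit0$rss, 1e-10)
  expect_lt(max(abs(fit0$theta_hat - c(0.5, 1.5, 0.3))), 1e-6)
  expect_false(fit0$at_bound)
  ## noisy fit lands within a few standard errors of the truth
  z <- wt_data(sigma = 0.1)
  fit <- mle_fit(z, "linear", seed = 1)
  se <- c(0.01, 0.1, 0.04)  # curvature-scale errors at this design
  expect_lt(max(abs(fit$theta_hat - c(0.5, 1.5, 0.3)) / (3 * se)), 1)
  ## all-zero data has no interior optimum: the three channels pull in
  ## conflicting directions and the fit parks kappa2 on its lower bound,
  ## which the boundary flag reports
  d <- default_designs()[["wild-type"]]
  zz <- timecourse_data(array(0, c(3, 7, 11)), d)
  fitz <- mle_fit(zz, "linear", seed = 1)
  expect_true(fitz$at_bound)
})

test_that("noise estimation follows the maximum-likelihood convention", {
  z0 <- wt_data(sigma = 0)
  expect_lt(estimate_sigma(z0, c(0.5, 1.5, 0.3), "linear"), 1e-9)
  ## constant offset c on every entry gives sigma = |c|
  z <- wt_data(sigma = 0)
  z$values <- z$values + 0.25
  expect_equal(estimate_sigma(z, c(0.5, 1.5, 0.3), "linear"), 0.25,
               tolerance = 1e-8)
  ## consistency at large replicate count
  d <- experiment_design(c(0.5, 2, 3.25, 3.75, 5, 10, 20), 400)
  zb <- generate_timecourse(
    variant_scenario(d, reduced_params(0.5, 1.5, 0.3), 0.1), "linear", 7)
  expect_equal(estimate_sigma(zb, c(0.5, 1.5, 0.3), "linear"), 0.1,
               tolerance = 0.02)
})

test_that("the Gaussian negative log-likelihood is the stated quadratic
           form", {
  z <- wt_data(sigma = 0.05)
  n <- length(z$values)
  truth <- c(0.5, 1.5, 0.3)
  ## a perfect fit leaves only the normalisation term
  z0 <- wt_data(sigma = 0)
  expect_equal(neg_log_likelihood(truth, z0, 0.2, "linear"),
               n / 2 * log(2 * pi * 0.04), tolerance = 1e-9)
  ## brute-force product of Gaussian densities on a tiny dataset
  d2 <- experiment_design(c(1, 4), 2)
  zt <- generate_timecourse(
    variant_scenario(d2, reduced_params(0.4, 1, 0.6), 0.3), "linear", 3)
  pred <- prediction_map(reduced_params(0.4, 1, 0.6), d2, "linear")
  direct <- -sum(stats::dnorm(as.vector(zt$values), pred, 0.3,
                              log = TRUE))
  expect_equal(neg_log_likelihood(c(0.4, 1, 0.6), zt, 0.3, "linear"),
               direct, tolerance = 1e-9)
})

test_that("Wilks thresholds", {
  expect_equal(wilks_neg_log_kstar(0.05, 3), 3.907, tolerance = 5e-4)
  expect_equal(wilks_neg_log_kstar(0.05, 1), 1.9207, tolerance = 5e-5)
  expect_lt(wilks_neg_log_kstar(1 - 1e-6, 3), 1e-3)
})

test_that("simulated likelihood-ratio calibration is monotone in alpha", {
  z <- wt_data()
  fit <- mle_fit(z, "linear", seed = 1)
  d <- z$design
  a1 <- algorithm1_neg_log_kstar(fit$theta_hat, fit$sigma_hat, d,
                                 "linear", alpha = 0.05, n_sim = 100,
                                 seed = 2)
  a2 <- algorithm1_neg_log_kstar(fit$theta_hat, fit$sigma_hat, d,
                                 "linear", alpha = 0.2, n_sim = 100,
                                 seed = 2)
  expect_gte(as.numeric(a1), as.numeric(a2))
  expect_gte(as.numeric(a2), 0)
})

test_that("the delta form and the rho-ball form of the region coincide", {
  z <- wt_data()
  fit <- mle_fit(z, "linear", seed = 1)
  spec <- confidence_spec(z, fit$theta_hat, fit$sigma_hat, 3.907,
                          "linear")
  expect_true(region_membership(fit$theta_hat, z, spec))
  set.seed(6)
  for (i in 1:200) {
    th <- c(runif(1, 0.3, 0.7), runif(1, 0.8, 2.5), runif(1))
    in_rho <- region_membership(th, z, spec)
    in_delta <- neg_log_likelihood(th, z, spec$sigma, "linear") <
      spec$delta
    expect_identical(in_rho, in_delta)
  }
  ## rho degenerates with a zero threshold and a perfect fit
  z0 <- wt_data(sigma = 0)
  fit0 <- mle_fit(z0, "linear", seed = 1)
  spec0 <- confidence_spec(z0, fit0$theta_hat, 1e-6, 0, "linear")
  expect_lt(spec0$rho, 1e-4)
  ## the boundary is excluded (strict inequality): at -log k* = 0 the MLE
  ## itself sits exactly on the boundary
  specb <- confidence_spec(z, fit$theta_hat, fit$sigma_hat, 0, "linear")
  expect_false(region_membership(fit$theta_hat, z, specb))
})

test_that("boundedness verdicts on sampled regions", {
  mk <- function(acc, lo, hi) {
    colnames(acc) <- c("kappa1", "kappa2")
    structure(list(accepted = acc, accepted_full = acc,
                   bounds = list(lower = c(kappa1 = lo[1], kappa2 = lo[2]),
                                 upper = c(kappa1 = hi[1], kappa2 = hi[2])),
                   marginal_pair = c("kappa1", "kappa2"),
                   n_proposed = 100L, method = "profile"),
              class = "region_sample")
  }
  empty <- mk(matrix(numeric(0), 0, 2), c(0, 0), c(1, 1))
  expect_equal(boundedness_assessment(empty), "empty")
  central <- mk(cbind(runif(50, 0.4, 0.6), runif(50, 0.4, 0.6)),
                c(0, 0), c(1, 1))
  expect_equal(boundedness_assessment(central), "bounded")
  touching <- mk(cbind(c(runif(20, 0.4, 0.6), 0.999), runif(21, 0.4, 0.6)),
                 c(0, 0), c(1, 1))
  expect_equal(boundedness_assessment(touching), "boundary-contact")
})

test_that("linear-model parameters are recovered from three time points", {
  tr <- linear_solution(c(2, 5, 10), reduced_params(0.3, 0.7, 0.2), 5)
  rec <- recover_linear_params(tr["S0", ], tr["S1", ], c(2, 5, 10), 5)
  expect_lt(max(abs(rec[1:3] - c(0.3, 0.7, 0.2))), 1e-8)
  ## invariance under the choice of time points feeding the S1 solve
  for (pts in list(c(1, 2), c(1, 3), c(2, 3))) {
    r2 <- recover_linear_params(tr["S0", ], tr["S1", ], c(2, 5, 10), 5,
                                s1_points = pts)
    expect_lt(max(abs(r2[1:3] - c(0.3, 0.7, 0.2))), 1e-8)
  }
  ## property: random draws, random distinct time triples scaled to the
  ## faster rate so both exponentials stay resolvable in double precision
  set.seed(8)
  for (i in 1:50) {
    th <- c(runif(1, 0.05, 3), runif(1, 0.05, 3), runif(1, 0.02, 0.98))
    tt <- sort(runif(3, 0.1, 6)) / max(th[1], th[2])
    sol <- linear_solution(tt, reduced_params(th[1], th[2], th[3]), 5)
    r <- recover_linear_params(sol["S0", ], sol["S1", ], tt, 5)
    expect_lt(max(abs(r[1:3] - th)), 1e-8)
  }
  ## kappa1 = 0 leaves the processivity undetermined
  flat <- linear_solution(c(2, 5, 10), reduced_params(0, 1, 0.5), 5)
  expect_error(recover_linear_params(pmax(pmin(flat["S0", ], 5 - 1e-9),
                                          1e-9),
                                     flat["S1", ], c(2, 5, 10), 5))
  ## inconsistent data (not from the model) is rejected
  expect_error(recover_linear_params(c(4, 3.9, 2), tr["S1", ],
                                     c(2, 5, 10), 5), "inconsistent")
})
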