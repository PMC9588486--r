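test_that("Vietoris-Rips complexes enumerate the right simplices", {
  pts <- matrix(c(0, 1, 2), 3, 1)
  cx <- vietoris_rips(pts, 1, 2)
  expect_equal(ncol(cx$simplices[[1]]), 3)
  expect_equal(unname(cx$simplices[[2]]), rbind(c(1, 2), c(2, 3)))
  expect_equal(ncol(cx$simplices[[3]]), 0)
  ## scale at least the diameter gives the full simplex
  cx2 <- vietoris_rips(pts, 2, 2)
  expect_equal(ncol(cx2$simplices[[3]]), 1)
  ## scale zero keeps vertices only
  cx3 <- vietoris_rips(pts, 0, 2)
  expect_equal(ncol(cx3$simplices[[2]]), 0)
  ## brute-force check of edges and triangles on a random cloud
  set.seed(21)
  p <- matrix(rnorm(24), 12, 2)
  b <- 0.9
  cx4 <- vietoris_rips(p, b, 2)
  D <- as.matrix(dist(p))
  ref_e <- 0; ref_t <- 0
  for (i in 1:11) for (j in (i + 1):12) {
    if (D[i, j] <= b) ref_e <- ref_e + 1
    if (j < 12) for (k in (j + 1):12)
      if (max(D[i, j], D[i, k], D[j, k]) <= b) ref_t <- ref_t + 1
  }
  expect_equal(ncol(cx4$simplices[[2]]), ref_e)
  expect_equal(ncol(cx4$simplices[[3]]), ref_t)
})

test_that("the Epanechnikov density estimate behaves as a compact kernel", {
  est <- density_estimate(matrix(0, 1, 1), 1)
  expect_equal(kde_evaluate(est, 0), 0.75)
  expect_equal(kde_evaluate(est, 2), 0)
  ## doubling the bandwidth flattens the peak and doubles the support
  est2 <- density_estimate(matrix(0, 1, 1), 2)
  expect_lt(kde_evaluate(est2, 0), kde_evaluate(est, 0))
  expect_gt(kde_evaluate(est2, 1.5), 0)
  ## the m-dimensional kernel integrates to one (Monte Carlo over a box)
  set.seed(22)
  u <- matrix(runif(3 * 40000, -1, 1), ncol = 3)
  est3 <- density_estimate(matrix(0, 1, 3), 1)
  expect_equal(mean(kde_evaluate(est3, u)) * 8, 1, tolerance = 0.02)
})

test_that("bandwidth selection is scale-equivariant and shrinks with n", {
  set.seed(23)
  p <- matrix(rnorm(150 * 2), 150, 2)
  b1 <- select_bandwidth(p)
  b2 <- select_bandwidth(3 * p)
  expect_equal(b2 / b1, 3, tolerance = 1e-9)
  big <- matrix(rnorm(1200 * 2), 1200, 2)
  expect_lt(select_bandwidth(big), b1)
  expect_error(select_bandwidth(matrix(1, 5, 2)), "degenerate")
  ## two tight, widely separated clusters: bandwidth below the gap
  cl <- rbind(matrix(rnorm(60, sd = 0.05), 30, 2),
              matrix(rnorm(60, mean = 5, sd = 0.05), 30, 2))
  expect_lt(select_bandwidth(cl), 5)
})

test_that("density filtrations take the max of minus the vertex density", {
  pts <- matrix(c(0, 0.5), 2, 1)
  cx <- vietoris_rips(pts, 1, 1)
  f <- density_filtration(cx, c(0.75, 0.25))
  expect_equal(f$values[[1]], c(-0.75, -0.25))
  expect_equal(f$values[[2]], -0.25)
  ## monotone on a random complex: every face value <= coface value
  set.seed(24)
  p <- matrix(rnorm(30), 15, 2)
  cx2 <- vietoris_rips(p, 1.2, 2)
  dens <- runif(15)
  f2 <- density_filtration(cx2, dens)
  for (d in 2:3) {
    mat <- cx2$simplices[[d]]
    for (j in seq_len(ncol(mat))) {
      for (drop in seq_len(d)) {
        face <- mat[-drop, j]
        fi <- which(colSums(cx2$simplices[[d - 1]] != face) == 0)
        expect_lte(f2$values[[d - 1]][fi], f2$values[[d]][j])
      }
    }
  }
})

test_that("persistent homology matches hand-checked small filtrations", {
  ## single vertex
  f1 <- as_pkg_filtration(list(1L), 0)
  expect_equal(persistent_homology(f1, 0)[[1]],
               data.frame(birth = 0, death = Inf))
  ## two vertices at 0 joined at 1
  f2 <- as_pkg_filtration(list(1L, 2L, c(1L, 2L)), c(0, 0, 1))
  b2 <- sort_barcode(persistent_homology(f2, 1)[[1]])
  expect_equal(b2, data.frame(birth = c(0, 0), death = c(1, Inf)))
  expect_equal(nrow(persistent_homology(f2, 1)[[2]]), 0)
  ## hollow triangle: one essential loop born with the last edge
  f3 <- as_pkg_filtration(list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L),
                               c(2L, 3L)),
                          c(0, 0, 0, 1, 1, 1))
  expect_equal(persistent_homology(f3, 1)[[2]],
               data.frame(birth = 1, death = Inf))
})

test_that("persistent homology agrees with the brute-force sublevel-Betti
           oracle on small complexes", {
  set.seed(25)
  for (cx in small_test_complexes()) {
    for (rep in 1:2) {
      vals <- random_monotone_values(cx)
      filt <- as_pkg_filtration(cx, vals)
      got <- persistent_homology(filt, 1)
      for (k in 0:1) {
        expect_equal(sort_barcode(got[[k + 1]]),
                     sort_barcode(oracle_barcode(cx, vals, k)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("bottleneck distance: hand values, exhaustive oracle and metric
           axioms", {
  b <- data.frame(birth = 0, death = 10)
  e <- data.frame(birth = numeric(0), death = numeric(0))
  expect_equal(bottleneck(b, b), 0)
  expect_equal(bottleneck(b, e), 5)
  expect_equal(bottleneck(e, b), 5)
  ## essential bars only match essential bars
  i1 <- data.frame(birth = 1, death = Inf)
  i2 <- data.frame(birth = 3, death = Inf)
  expect_equal(bottleneck(i1, i2), 2)
  expect_equal(bottleneck(i1, e), Inf)
  set.seed(26)
  bars <- replicate(12, random_barcode(), simplify = FALSE)
  for (i in seq_along(bars)) {
    for (j in seq_along(bars)) {
      dij <- bottleneck(bars[[i]], bars[[j]])
      expect_equal(dij, oracle_bottleneck(bars[[i]], bars[[j]]),
                   tolerance = 1e-9)
      expect_equal(dij, bottleneck(bars[[j]], bars[[i]]),
                   tolerance = 1e-12)
    }
  }
  ## triangle inequality on random triples
  for (r in 1:15) {
    tri <- replicate(3, random_barcode(3, p_inf = 0), simplify = FALSE)
    d12 <- bottleneck(tri[[1]], tri[[2]])
    d23 <- bottleneck(tri[[2]], tri[[3]])
    d13 <- bottleneck(tri[[1]], tri[[3]])
    expect_lte(d13, d12 + d23 + 1e-9)
  }
})

test_that("filtration perturbations move barcodes by at most the sup norm", {
  set.seed(27)
  for (r in 1:50) {
    n <- 12
    p <- matrix(rnorm(2 * n), n, 2)
    cx <- vietoris_rips(p, 1.5, 2)
    dens <- runif(n)
    eps <- runif(1, 0.01, 0.3)
    dens2 <- dens + runif(n, -eps, eps)
    f1 <- density_filtration(cx, dens)
    f2 <- density_filtration(cx, dens2)
    gap <- max(abs(unlist(f1$values) - unlist(f2$values)))
    ph1 <- persistent_homology(f1, 1)
    ph2 <- persistent_homology(f2, 1)
    for (k in 0:1)
      expect_lte(bottleneck(ph1[[k + 1]], ph2[[k + 1]]), gap + 1e-9)
  }
})

test_that("the density-filtration convergence bound evaluates and has the
           right limits", {
  expect_equal(ceiling(1 / (2 * 0.25)), 2)
  b1 <- bobrowski_bound(0.25, 1e6, 0.5, 3, 1)
  expect_gte(b1, 0); expect_lte(b1, 1)
  expect_equal(bobrowski_bound(0.25, 1e9, 0.5, 3, 1), 1, tolerance = 1e-9)
  ## monotone non-decreasing in N beyond the turning point
  c_eta <- (0.25 / 2)^2 / (3 + 0.25 / 2)
  n0 <- ceiling(1 / (c_eta * 0.5^3)) + 10
  vals <- vapply(c(n0, 2 * n0, 8 * n0), bobrowski_bound, numeric(1),
                 eta = 0.25, b = 0.5, m = 3, p_max = 1)
  expect_true(all(diff(vals) >= 0))
})

test_that("cloud pipeline: mode structure and translation invariance", {
  set.seed(28)
  uni <- matrix(rnorm(200 * 3, sd = 0.3), 200, 3)
  p1 <- ph_of_cloud(uni, k_max = 0)
  h0 <- p1$barcodes[[1]]
  ## one dominant (essential) component; any residual bars are shallow
  expect_equal(sum(is.infinite(h0$death)), 1)
  if (nrow(h0) > 1) {
    fin <- h0[is.finite(h0$death), ]
    expect_lt(max(fin$death - fin$birth), max(p1$density) / 5)
  }
  ## two well-separated modes give two deep components
  bi <- rbind(matrix(rnorm(100 * 3, sd = 0.2), 100, 3),
              matrix(rnorm(100 * 3, mean = 3, sd = 0.2), 100, 3))
  p2 <- ph_of_cloud(bi, k_max = 0)
  h0b <- p2$barcodes[[1]]
  pers <- ifelse(is.infinite(h0b$death), Inf, h0b$death - h0b$birth)
  expect_gte(sum(pers > max(p2$density) / 2), 2)
  ## translation leaves every barcode unchanged
  p3 <- ph_of_cloud(uni + 10, k_max = 0)
  expect_equal(p1$barcodes, p3$barcodes, tolerance = 1e-9)
})

test_that("resampling p-values have the exceedance form and range", {
  set.seed(29)
  sampler <- function(n) matrix(rnorm(n * 2, sd = 0.5), n, 2)
  a <- sampler(120); b <- sampler(120)
  out <- empirical_pvalue(a, a, sampler, sampler, beta = 19, n = 120,
                          k = 0, seed = 1)
  expect_equal(out$d_bd, 0)
  expect_equal(out$p_hat, 1)
  out2 <- empirical_pvalue(a, b, sampler, sampler, beta = 19, n = 120,
                           k = 0, seed = 1)
  expect_gte(out2$p_hat, 1 / 20)
  expect_lte(out2$p_hat, 1)
})

test_that("loop-bearing clouds carry an essential 1-cycle that blobs lack", {
  set.seed(30)
  th <- seq(0, 2 * pi, length.out = 151)[-151] + rnorm(150, sd = 0.02)
  ring <- cbind(3 * cos(th), 3 * sin(th)) +
    matrix(rnorm(300, sd = 0.1), 150, 2)
  ph_ring <- ph_of_cloud(ring, k_max = 1)
  expect_equal(sum(is.infinite(ph_ring$barcodes[[2]]$death)), 1)
  blob <- matrix(rnorm(300, sd = 0.4), 150, 2)
  ph_blob <- ph_of_cloud(blob, k_max = 1)
  expect_equal(nrow(ph_blob$barcodes[[2]]), 0)
  ## unmatched essential cycles make the barcodes infinitely far apart
  expect_equal(bottleneck(ph_ring$barcodes[[2]], ph_blob$barcodes[[2]]),
               Inf)
})

test_that("variant comparison singles out a topologically distinct cloud", {
  mk <- function(seed, sd) {
    set.seed(seed)
    matrix(rnorm(400 * 2, sd = sd), 400, 2)
  }
  clouds <- list(A = mk(1, 0.40), B = mk(2, 0.45), C = mk(3, 0.05))
  cmp <- compare_variants(clouds, beta = 19, n = 120, k = 0, seed = 4)
  D <- cmp$distance
  expect_true(isTRUE(all.equal(D, t(D))))
  expect_true(all(diag(D) == 0))
  ## the concentrated cloud's density signature dominates
  expect_gt(min(D["C", c("A", "B")]), D["A", "B"])
  expect_equal(names(which.max(rowSums(D))), "C")
  expect_equal(unname(cmp$p_value["C", c("A", "B")]), c(0.05, 0.05))
})
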