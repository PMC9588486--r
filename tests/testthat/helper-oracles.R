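## Independent brute-force oracles used by the tests.  These deliberately
## avoid the package's own algorithms: homology ranks come from dense
## GF(2) Gaussian elimination on explicit boundary matrices, bottleneck
## distances from exhaustive enumeration of partial matchings.

## ---- GF(2) linear algebra ----------------------------------------------

gf2_rank <- function(M) {
  if (length(M) == 0 || nrow(M) == 0 || ncol(M) == 0) return(0L)
  M <- M %% 2
  r <- 0L
  for (c_ in seq_len(ncol(M))) {
    piv <- which(M[, c_] == 1)
    piv <- piv[piv > r]
    if (length(piv) == 0) next
    r <- r + 1L
    if (piv[1] != r) M[c(r, piv[1]), ] <- M[c(piv[1], r), ]
    for (row in which(M[, c_] == 1)) {
      if (row != r) M[row, ] <- (M[row, ] + M[r, ]) %% 2
    }
  }
  r
}

## dim of (column space U  intersect  column space V) over GF(2)
gf2_dim_intersection <- function(U, V) {
  dU <- gf2_rank(U); dV <- gf2_rank(V)
  dU + dV - gf2_rank(cbind(U, V))
}

## nullspace basis of M over GF(2) (columns)
gf2_nullspace <- function(M) {
  n <- ncol(M)
  if (n == 0) return(matrix(0, 0, 0))
  if (nrow(M) == 0) return(diag(n) %% 2)
  A <- M %% 2
  pivots <- integer(0)
  r <- 0L
  for (c_ in seq_len(n)) {
    piv <- which(A[, c_] == 1)
    piv <- piv[piv > r]
    if (length(piv) == 0) next
    r <- r + 1L
    if (piv[1] != r) A[c(r, piv[1]), ] <- A[c(piv[1], r), ]
    for (row in which(A[, c_] == 1))
      if (row != r) A[row, ] <- (A[row, ] + A[r, ]) %% 2
    pivots <- c(pivots, c_)
  }
  free <- setdiff(seq_len(n), pivots)
  if (length(free) == 0) return(matrix(0, n, 0))
  basis <- matrix(0, n, length(free))
  for (i in seq_along(free)) {
    f <- free[i]
    v <- numeric(n); v[f] <- 1
    for (j in seq_along(pivots)) {
      ## row j of reduced A: pivot pivots[j]; solve for pivot coordinate
      v[pivots[j]] <- (sum(A[j, ] * v) - A[j, pivots[j]] * v[pivots[j]]) %% 2
    }
    basis[, i] <- v %% 2
  }
  basis
}

## ---- brute-force persistent homology -----------------------------------

## A test complex is a list of simplices (integer vectors, sorted); values
## is a parallel numeric vector (monotone: face value <= coface value).
oracle_boundary <- function(simplices, keep, k) {
  ## boundary matrix from k-simplices (columns) to (k-1)-simplices (rows),
  ## restricted to the sublevel set `keep` (logical)
  kidx <- which(keep & vapply(simplices, length, 1L) == k + 1)
  ridx <- which(keep & vapply(simplices, length, 1L) == k)
  M <- matrix(0, length(ridx), length(kidx))
  if (length(kidx) == 0) return(M)
  key <- vapply(simplices, paste, "", collapse = ",")
  for (j in seq_along(kidx)) {
    v <- simplices[[kidx[j]]]
    for (i in seq_along(v)) {
      fk <- paste(v[-i], collapse = ",")
      M[match(fk, key[ridx]), j] <- 1
    }
  }
  M
}

## persistent Betti number beta_k(K_i -> K_j): rank of the induced map
oracle_persistent_betti <- function(simplices, values, li, lj, k) {
  keep_i <- values <= li
  keep_j <- values <= lj
  Zi <- gf2_nullspace(oracle_boundary(simplices, keep_i, k))
  ## embed cycle basis into the K_j chain space
  kidx_i <- which(keep_i & vapply(simplices, length, 1L) == k + 1)
  kidx_j <- which(keep_j & vapply(simplices, length, 1L) == k + 1)
  Zi_in_j <- matrix(0, length(kidx_j), ncol(Zi))
  if (ncol(Zi)) Zi_in_j[match(kidx_i, kidx_j), ] <- Zi
  Bj <- oracle_boundary(simplices, keep_j, k + 1)
  ncol(Zi) - gf2_dim_intersection(Zi_in_j, Bj)
}

## full barcode for homology dimension k by inclusion-exclusion over the
## critical levels
oracle_barcode <- function(simplices, values, k) {
  lev <- sort(unique(values))
  Tn <- length(lev)
  pb <- function(i, j) {
    if (i < 1) return(0)
    oracle_persistent_betti(simplices, values, lev[i], lev[j], k)
  }
  births <- numeric(0); deaths <- numeric(0)
  for (i in seq_len(Tn)) {
    for (j in i:Tn) {
      if (j == i) next
      mu <- (pb(i, j - 1) - pb(i, j)) - (pb(i - 1, j - 1) - pb(i - 1, j))
      if (mu > 0) {
        births <- c(births, rep(lev[i], mu))
        deaths <- c(deaths, rep(lev[j], mu))
      }
    }
    ess <- pb(i, Tn) - pb(i - 1, Tn)
    if (ess > 0) {
      births <- c(births, rep(lev[i], ess))
      deaths <- c(deaths, rep(Inf, ess))
    }
  }
  df <- data.frame(birth = births, death = deaths)
  df[order(df$birth, df$death), , drop = FALSE]
}

sort_barcode <- function(df) {
  df <- df[order(df$birth, df$death), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## ---- exhaustive bottleneck ---------------------------------------------

## all partial injections for small barcodes
oracle_bottleneck <- function(B, B2) {
  infa <- B[is.infinite(B$death), , drop = FALSE]
  infb <- B2[is.infinite(B2$death), , drop = FALSE]
  if (nrow(infa) != nrow(infb)) return(Inf)
  dinf <- if (nrow(infa))
    max(abs(sort(infa$birth) - sort(infb$birth))) else 0
  A <- B[is.finite(B$death), , drop = FALSE]
  Bm <- B2[is.finite(B2$death), , drop = FALSE]
  na <- nrow(A); nb <- nrow(Bm)
  best <- Inf
  assign_rec <- function(i, used, cur) {
    if (cur >= best) return()
    if (i > na) {
      unmatched_b <- setdiff(seq_len(nb), used)
      tot <- cur
      for (j in unmatched_b)
        tot <- max(tot, (Bm$death[j] - Bm$birth[j]) / 2)
      best <<- min(best, tot)
      return()
    }
    ## leave bar i unmatched
    assign_rec(i + 1, used,
               max(cur, (A$death[i] - A$birth[i]) / 2))
    for (j in setdiff(seq_len(nb), used)) {
      c_ij <- max(abs(A$birth[i] - Bm$birth[j]),
                  abs(A$death[i] - Bm$death[j]))
      assign_rec(i + 1, c(used, j), max(cur, c_ij))
    }
  }
  assign_rec(1, integer(0), 0)
  max(best, dinf)
}

## ---- small-complex generators ------------------------------------------

## all simplicial complexes on 3 vertices (closed families), plus a few on
## 4 vertices, as simplex lists
small_test_complexes <- function() {
  tri_faces <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L),
                    c(1L, 2L, 3L))
  closed <- function(sub) {
    key <- vapply(sub, paste, "", collapse = ",")
    for (s in sub) {
      if (length(s) == 1) next
      for (i in seq_along(s))
        if (!(paste(s[-i], collapse = ",") %in% key)) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (mask in 1:(2^7 - 1)) {
    sub <- tri_faces[as.logical(bitwAnd(mask, 2^(0:6)))]
    if (closed(sub)) out[[length(out) + 1L]] <- sub
  }
  ## 4-vertex examples: hollow square, square with one diagonal + triangle,
  ## tetrahedron boundary (8 simplices after dropping vertices count? no --
  ## boundary has 4+6+4 = 14; use partial shells instead)
  out[[length(out) + 1L]] <- list(1L, 2L, 3L, 4L, c(1L, 2L), c(2L, 3L),
                                  c(3L, 4L), c(1L, 4L))  # hollow square
  out[[length(out) + 1L]] <- list(1L, 2L, 3L, 4L, c(1L, 2L), c(1L, 3L),
                                  c(2L, 3L), c(1L, 2L, 3L))  # tri + point
  out
}

## random monotone filtration values for a simplex list
random_monotone_values <- function(simplices, tie_prob = 0.3) {
  vals <- numeric(length(simplices))
  dims <- vapply(simplices, length, 1L)
  key <- vapply(simplices, paste, "", collapse = ",")
  for (i in order(dims)) {
    if (dims[i] == 1) {
      vals[i] <- round(stats::runif(1), 2)
    } else {
      s <- simplices[[i]]
      fmax <- max(vapply(seq_along(s), function(k)
        vals[match(paste(s[-k], collapse = ","), key)], numeric(1)))
      vals[i] <- if (stats::runif(1) < tie_prob) fmax else
        fmax + round(stats::runif(1, 0, 0.5), 2)
    }
  }
  vals
}

## package filtration object from a simplex list + values
as_pkg_filtration <- function(simplices, values) {
  dims <- vapply(simplices, length, 1L)
  n <- max(unlist(simplices))
  mats <- lapply(sort(unique(dims)), function(d)
    matrix(unlist(simplices[dims == d]), nrow = d))
  ## ensure every dimension from 1..max is present
  full <- list()
  vlist <- list()
  for (d in seq_len(max(dims))) {
    if (d %in% dims) {
      full[[d]] <- matrix(unlist(simplices[dims == d]), nrow = d)
      vlist[[d]] <- values[dims == d]
    } else {
      full[[d]] <- matrix(integer(0), d, 0)
      vlist[[d]] <- numeric(0)
    }
  }
  cx <- structure(list(n_vertices = n, simplices = full),
                  class = "simplicial_complex")
  structure(list(complex = cx, values = vlist), class = "filtration")
}

## random barcode with <= max_bars bars
random_barcode <- function(max_bars = 4, p_inf = 0.15) {
  nb <- sample(0:max_bars, 1)
  if (nb == 0) return(data.frame(birth = numeric(0), death = numeric(0)))
  birth <- round(stats::runif(nb, 0, 5), 2)
  pers <- round(stats::runif(nb, 0, 3), 2)
  death <- ifelse(stats::runif(nb) < p_inf, Inf, birth + pers)
  data.frame(birth = birth, death = death)
}
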