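## Topological comparison of point clouds.
##
## Pipeline: select a kernel bandwidth b, estimate the density with a
## compactly supported (Epanechnikov) kernel, build the Vietoris-Rips
## complex at scale b, filter it by minus the density (a super-level-set
## filtration: a simplex enters when its least-dense vertex reaches the
## level), compute persistent homology over F2, and compare barcodes by
## bottleneck distance with a resampling p-value.

#' Vietoris-Rips complex at a fixed scale
#'
#' All subsets of at most `max_dim + 1` points whose pairwise Euclidean
#' distances are all `<= b`.
#'
#' @param points `n x m` coordinate matrix.
#' @param b scale (>= 0).
#' @param max_dim maximal simplex dimension.
#' @return Object of class `simplicial_complex`: `n_vertices` and
#'   `simplices`, a list whose d-th entry is a `(d+1) x N_d` matrix of
#'   sorted vertex indices (columns), for d = 0..max_dim.
#' @export
vietoris_rips <- function(points, b, max_dim = 2) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(b >= 0, max_dim >= 0)
  simplices <- list(matrix(seq_len(n), nrow = 1))
  if (max_dim >= 1 && n >= 2) {
    adj <- as.matrix(stats::dist(points)) <= b
    diag(adj) <- FALSE
    ee <- which(adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(ee)) {
      ord <- order(ee[, 1], ee[, 2])
      simplices[[2]] <- t(ee[ord, , drop = FALSE])
      dimnames(simplices[[2]]) <- NULL
      storage.mode(simplices[[2]]) <- "integer"
    } else simplices[[2]] <- matrix(integer(0), 2, 0)
    if (max_dim >= 2 && ncol(simplices[[2]]) > 0)
      simplices[[3]] <- vr_triangles_cpp(simplices[[2]], adj)
    d <- 2
    while (d < max_dim && length(simplices) >= d + 1 &&
           ncol(simplices[[d + 1]]) > 0) {
      prev <- simplices[[d + 1]]
      cols <- list()
      for (j in seq_len(ncol(prev))) {
        tau <- prev[, j]
        common <- which(Reduce(`&`, lapply(tau, function(v) adj[v, ])))
        common <- common[common > tau[length(tau)]]
        for (w in common) cols[[length(cols) + 1L]] <- c(tau, w)
      }
      simplices[[d + 2]] <- if (length(cols))
        matrix(as.integer(unlist(cols)), nrow = d + 2) else
          matrix(integer(0), d + 2, 0)
      d <- d + 1
    }
  }
  structure(list(n_vertices = n, simplices = simplices),
            class = "simplicial_complex")
}

epanechnikov_const <- function(m) {
  ## normalises K(u) = c_m (1 - |u|^2) on the unit ball of R^m
  vol <- pi^(m / 2) / gamma(m / 2 + 1)
  (m + 2) / (2 * vol)
}

#' Kernel density estimate with a compactly supported kernel
#'
#' `p_hat(x) = (1 / (n b^m)) sum_i K((x - v_i)/b)` with the Epanechnikov
#' kernel `K(u) = c_m (1 - |u|^2)` supported on the unit ball (smooth
#' enough, unimodal, symmetric -- the hypotheses of the density-filtration
#' convergence theory).
#'
#' @param points `n x m` sample matrix.
#' @param bandwidth kernel bandwidth `b > 0`.
#' @return Object of class `density_estimate`.
#' @export
density_estimate <- function(points, bandwidth) {
  points <- as.matrix(points)
  stopifnot(bandwidth > 0)
  structure(list(points = points, bandwidth = bandwidth,
                 m = ncol(points),
                 const = epanechnikov_const(ncol(points))),
            class = "density_estimate")
}

#' Evaluate a kernel density estimate
#'
#' @param est a [density_estimate].
#' @param x query points (`q x m` matrix or a single vector).
#' @return Numeric vector of densities (>= 0; exactly 0 farther than the
#'   bandwidth from every sample).
#' @export
kde_evaluate <- function(est, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  v <- est$points; b <- est$bandwidth; n <- nrow(v)
  ## squared distances query x sample
  d2 <- outer(rowSums(x^2), rowSums(v^2), "+") - 2 * x %*% t(v)
  u2 <- pmax(d2, 0) / b^2
  k <- est$const * pmax(1 - u2, 0)
  rowSums(k) / (n * b^est$m)
}

#' Bandwidth selection: normal-reference start, cross-validated refinement
#'
#' Starts from a Silverman-style normal-reference value
#' `b0 = 2.2 * s * n^(-1/(m+4))` (with `s` the root mean per-coordinate
#' standard deviation; the constant reflects the Epanechnikov kernel's
#' wider canonical bandwidth), then maximises K-fold cross-validated
#' held-out log-density over a multiplicative grid around `b0`.
#' Deterministic for a fixed `seed` (fold assignment).
#'
#' @param points `n x m` sample matrix (`n >= 2`).
#' @param folds number of cross-validation folds.
#' @param n_grid grid size.
#' @param seed fold-assignment seed.
#' @return Selected bandwidth (scalar).
#' @export
select_bandwidth <- function(points, folds = 5, n_grid = 25, seed = 1) {
  points <- as.matrix(points)
  n <- nrow(points); m <- ncol(points)
  stopifnot(n >= 2)
  s <- sqrt(mean(apply(points, 2, stats::var)))
  if (s == 0) stop("degenerate data: all points coincide")
  b0 <- 2.2 * s * n^(-1 / (m + 4))
  grid <- b0 * 2^seq(-1.5, 1.5, length.out = n_grid)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  scores <- vapply(grid, function(b) {
    tot <- 0
    for (f in seq_len(folds)) {
      est <- density_estimate(points[fold_id != f, , drop = FALSE], b)
      dens <- kde_evaluate(est, points[fold_id == f, , drop = FALSE])
      tot <- tot + sum(log(pmax(dens, 1e-12)))
    }
    tot / n
  }, numeric(1))
  grid[which.max(scores)]
}

## single-linkage merge radius: the longest edge of the Euclidean
## minimum spanning tree, i.e. the smallest scale at which the
## fixed-radius complex is connected (Prim's algorithm)
connectivity_radius <- function(points) {
  D <- as.matrix(stats::dist(points))
  n <- nrow(D)
  if (n < 2) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  longest <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    longest <- max(longest, best[nxt])
    in_tree[nxt] <- TRUE
    best <- pmin(best, D[nxt, ])
  }
  longest
}

#' Filtration of a complex by minus a vertex density
#'
#' Extends the density to simplices by the minimum over vertices and
#' filters by `-p_hat`, i.e. `value(tau) = max_{v in tau} (-p_hat(v))`:
#' monotone by construction (supersets have no larger minimum density).
#'
#' @param complex a [vietoris_rips] complex.
#' @param vertex_density densities at the vertices (vector of length
#'   `n_vertices`), e.g. [kde_evaluate] at the sample points.
#' @return Object of class `filtration`: the complex plus per-dimension
#'   value vectors.
#' @export
density_filtration <- function(complex, vertex_density) {
  stopifnot(length(vertex_density) == complex$n_vertices)
  mp <- -as.numeric(vertex_density)
  values <- lapply(complex$simplices, function(mat) {
    if (ncol(mat) == 0) return(numeric(0))
    do.call(pmax, lapply(seq_len(nrow(mat)), function(i) mp[mat[i, ]]))
  })
  structure(list(complex = complex, values = values),
            class = "filtration")
}

#' Generic filtration from explicit simplexwise values
#'
#' @param complex a [vietoris_rips] complex.
#' @param values list of per-dimension value vectors; must be monotone
#'   (faces never exceed cofaces), which is checked.
#' @return A `filtration`.
#' @export
filtration <- function(complex, values) {
  f <- structure(list(complex = complex, values = values),
                 class = "filtration")
  idx <- simplex_index(complex)
  for (d in seq_along(complex$simplices)[-1]) {
    mat <- complex$simplices[[d]]
    if (ncol(mat) == 0) next
    for (j in seq_len(ncol(mat))) {
      for (i in seq_len(nrow(mat))) {
        facet <- mat[-i, j]
        fi <- idx[[d - 1]][[key_of(facet, complex$n_vertices)]]
        if (values[[d - 1]][fi] > values[[d]][j] + 1e-12)
          stop("non-monotone filtration values")
      }
    }
  }
  f
}

key_of <- function(v, n) paste(v, collapse = ",")

simplex_index <- function(complex) {
  lapply(complex$simplices, function(mat) {
    if (ncol(mat) == 0) return(list())
    keys <- apply(mat, 2, paste, collapse = ",")
    stats::setNames(as.list(seq_len(ncol(mat))), keys)
  })
}

## Flatten a filtration into filtration order: (value, dim, lex tuple).
## Returns values, dims and the F2 boundary columns.  Simplices are
## identified by an integer encoding of their sorted vertex tuple so that
## facet positions resolve through a single vectorised match.
flatten_filtration <- function(filt) {
  cx <- filt$complex
  n <- cx$n_vertices
  pad <- length(cx$simplices)
  vmat_l <- list(); dims_l <- list(); vals_l <- list()
  for (d in seq_along(cx$simplices)) {
    mat <- cx$simplices[[d]]
    if (ncol(mat) == 0) next
    vm <- matrix(0, ncol(mat), pad)
    vm[, seq_len(d)] <- t(mat)
    vmat_l[[length(vmat_l) + 1L]] <- vm
    dims_l[[length(dims_l) + 1L]] <- rep(d - 1L, ncol(mat))
    vals_l[[length(vals_l) + 1L]] <- filt$values[[d]]
  }
  vmat <- do.call(rbind, vmat_l)
  dims_all <- unlist(dims_l)
  vals_all <- unlist(vals_l)
  ord <- do.call(order, c(list(vals_all, dims_all),
                          lapply(seq_len(pad), function(i) vmat[, i])))
  vmat <- vmat[ord, , drop = FALSE]
  vals_all <- vals_all[ord]; dims_all <- dims_all[ord]
  m_tot <- nrow(vmat)
  base <- (n + 1)^(seq_len(pad) - 1)
  enc <- as.vector(vmat %*% base)
  ## facet keys, vectorised per dimension block, one global match call;
  ## boundary columns are passed to the reduction as one flat vector
  lens <- dims_all + 1L
  lens[dims_all == 0L] <- 0L
  offs <- c(0L, cumsum(lens))
  flat <- integer(offs[m_tot + 1L])
  for (d in unique(dims_all[dims_all >= 1L])) {
    rows <- which(dims_all == d)
    block <- vmat[rows, seq_len(d + 1L), drop = FALSE]
    fk <- matrix(0, length(rows), d + 1L)  # key of facet omitting slot i
    for (i in seq_len(d + 1L)) {
      for (k in seq_len(d + 1L)) {
        if (k == i) next
        shift <- if (k < i) k else k - 1L
        fk[, i] <- fk[, i] + block[, k] * base[shift]
      }
    }
    pos <- matrix(match(as.vector(fk), enc), length(rows), d + 1L)
    idx <- rep(offs[rows], each = d + 1L) +
      rep(seq_len(d + 1L), times = length(rows))
    flat[idx] <- as.integer(t(pos))
  }
  list(values = vals_all, dims = dims_all, flat = flat, lens = lens)
}

#' Persistent homology of a filtration over F2
#'
#' Standard boundary-matrix column reduction in filtration order
#' (simplices sorted by value, then dimension, then lexicographic vertex
#' tuple -- a deterministic order with faces before cofaces).  Unpaired
#' classes receive death `Inf`; zero-persistence pairs are dropped.
#'
#' @param filt a [density_filtration] / [filtration].
#' @param k_max maximal homology dimension reported.
#' @return List of `k_max + 1` data frames (`birth`, `death`), one per
#'   homology dimension 0..k_max.
#' @export
persistent_homology <- function(filt, k_max = 1) {
  fl <- flatten_filtration(filt)
  kills <- reduce_boundaries_cpp(fl$flat, fl$lens)
  m_tot <- length(kills)
  killed <- logical(m_tot)
  killed[kills[kills > 0]] <- TRUE
  ## paired classes: column j kills the class born with simplex kills[j]
  death_col <- which(kills > 0)
  birth_col <- kills[death_col]
  pos_pers <- fl$values[death_col] > fl$values[birth_col]
  pk <- fl$dims[birth_col]
  ## essential classes: zero (unpaired) columns never killed later
  ess <- which(kills == 0 & !killed)
  lapply(0:k_max, function(k) {
    sel <- pos_pers & pk == k
    e <- ess[fl$dims[ess] == k]
    data.frame(birth = c(fl$values[birth_col[sel]], fl$values[e]),
               death = c(fl$values[death_col[sel]],
                         rep(Inf, length(e))))
  })
}

## ---- bottleneck distance ----------------------------------------------

## Maximum bipartite matching (Kuhn's augmenting paths) on a logical
## adjacency matrix; returns the matching size.
max_bipartite_matching <- function(adj) {
  nl <- nrow(adj); nr <- ncol(adj)
  match_r <- rep(0L, nr)
  try_kuhn <- function(u, seen) {
    for (v in which(adj[u, ])) {
      if (!seen[v]) {
        seen[v] <- TRUE
        if (match_r[v] == 0L || Recall(match_r[v], seen)) {
          match_r[v] <<- u
          return(TRUE)
        }
      }
    }
    FALSE
  }
  size <- 0L
  for (u in seq_len(nl)) {
    if (try_kuhn(u, rep(FALSE, nr))) size <- size + 1L
  }
  size
}

## Feasibility of bottleneck value eps for finite bars: perfect matching
## in the augmented bipartite graph (bars may match the diagonal at cost
## persistence/2).
bottleneck_feasible <- function(cost, diag_a, diag_b, eps) {
  na <- length(diag_a); nb <- length(diag_b)
  tol <- 1e-12 + 1e-9 * eps
  nl <- na + nb; nr <- nb + na
  adj <- matrix(FALSE, nl, nr)
  if (na && nb) adj[seq_len(na), seq_len(nb)] <- cost <= eps + tol
  if (na) adj[seq_len(na), nb + seq_len(na)] <-
      matrix(diag_a <= eps + tol, na, na)
  if (nb) adj[na + seq_len(nb), seq_len(nb)] <-
      t(matrix(diag_b <= eps + tol, nb, nb))
  if (na && nb) adj[na + seq_len(nb), nb + seq_len(na)] <- TRUE
  max_bipartite_matching(adj) == nl
}

#' Bottleneck distance between two barcodes
#'
#' Exact optimal-matching distance: matched bars pay the sup-norm
#' distance of their endpoints, unmatched bars pay half their
#' persistence.  Essential bars (death `Inf`) may only match essential
#' bars (`Inf - Inf = 0` on the death coordinate); if the two barcodes
#' have different numbers of essential bars the distance is `Inf`.
#'
#' @param B,B2 barcode data frames (`birth`, `death`) of one homology
#'   dimension.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
bottleneck <- function(B, B2) {
  inf_a <- B[is.infinite(B$death), , drop = FALSE]
  inf_b <- B2[is.infinite(B2$death), , drop = FALSE]
  fin_a <- B[is.finite(B$death), , drop = FALSE]
  fin_b <- B2[is.finite(B2$death), , drop = FALSE]
  if (nrow(inf_a) != nrow(inf_b)) return(Inf)
  d_inf <- if (nrow(inf_a))
    max(abs(sort(inf_a$birth) - sort(inf_b$birth))) else 0
  na <- nrow(fin_a); nb <- nrow(fin_b)
  if (na == 0 && nb == 0) return(d_inf)
  diag_a <- if (na) (fin_a$death - fin_a$birth) / 2 else numeric(0)
  diag_b <- if (nb) (fin_b$death - fin_b$birth) / 2 else numeric(0)
  cost <- if (na && nb)
    pmax(abs(outer(fin_a$birth, fin_b$birth, "-")),
         abs(outer(fin_a$death, fin_b$death, "-"))) else
    matrix(numeric(0), na, nb)
  cand <- sort(unique(c(0, diag_a, diag_b, as.vector(cost))))
  lo <- 1L; hi <- length(cand)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (bottleneck_feasible(cost, diag_a, diag_b, cand[mid]))
      hi <- mid else lo <- mid + 1L
  }
  max(cand[lo], d_inf)
}

#' Density-filtration convergence probability bound
#'
#' The probability that the bottleneck distance between the persistent
#' homology of the true density and of the discretised KDE filtration
#' exceeds `5 eta` is at most `3 eta* N exp(-C_eta N b^m)`, with
#' `eta* = ceil(p_max / (2 eta))` and
#' `C_eta = (eta/2)^2 / (3 p_max + eta/2)`.  Returns the resulting lower
#' bound on the success probability, clipped to `[0, 1]`.
#'
#' @param eta discretisation level (> 0).
#' @param N sample size.
#' @param b bandwidth (the complex scale).
#' @param m ambient dimension.
#' @param p_max supremum of the density (> 0).
#' @return Probability lower bound in `[0, 1]`.
#' @export
bobrowski_bound <- function(eta, N, b, m, p_max) {
  stopifnot(eta > 0, p_max > 0)
  eta_star <- ceiling(p_max / (2 * eta))
  c_eta <- (eta / 2)^2 / (3 * p_max + eta / 2)
  min(max(1 - 3 * eta_star * N * exp(-c_eta * N * b^m), 0), 1)
}

#' Persistent homology of a point cloud's density filtration
#'
#' Composition: bandwidth selection, KDE at the sample points,
#' Vietoris-Rips complex at the bandwidth scale, filtration by minus the
#' density, persistent homology.
#'
#' @param points `n x m` matrix (`n >= 2`).
#' @param k_max maximal homology dimension (the complex is built to
#'   dimension `k_max + 1`); default 1.
#' @param bandwidth optional fixed bandwidth (selected if `NULL`).
#' @return List: `barcodes` (per dimension 0..k_max), `bandwidth`,
#'   `density` at the sample points.
#' @export
ph_of_cloud <- function(points, k_max = 1, bandwidth = NULL) {
  points <- as.matrix(points)
  b <- if (is.null(bandwidth)) select_bandwidth(points) else bandwidth
  est <- density_estimate(points, b)
  dens <- kde_evaluate(est, points)
  cx <- vietoris_rips(points, b, max_dim = k_max + 1)
  filt <- density_filtration(cx, dens)
  list(barcodes = persistent_homology(filt, k_max), bandwidth = b,
       density = dens)
}

#' Bottleneck distance with a resampling p-value
#'
#' Observed statistic `d = d_BD(PH_k(A), PH_k(B))`.  For each source,
#' `beta` fresh clouds are drawn with its sampler and the null distances
#' to the original cloud's barcode are collected; the estimate is the
#' exceedance form
#' `p_hat = min over the two null samples of (#\{null >= d\} + 1)/(beta + 1)`,
#' so `p_hat` always lies in `\{1/(beta+1), ..., 1\}`.
#'
#' @param cloudA,cloudB observed point clouds.
#' @param sampler_A,sampler_B functions `(n) -> cloud` drawing fresh
#'   clouds from the two source distributions.
#' @param beta number of null resamples per source (>= 19).
#' @param n size of resampled clouds.
#' @param k homology dimension compared (default 1).
#' @param seed integer seed.
#' @return List `d_bd`, `p_hat`, `null_A`, `null_B`.
#' @export
empirical_pvalue <- function(cloudA, cloudB, sampler_A, sampler_B,
                             beta = 99, n = 200, k = 1, seed = 1) {
  stopifnot(beta >= 19)
  resA <- ph_of_cloud(cloudA, k_max = k)
  resB <- ph_of_cloud(cloudB, k_max = k)
  phA <- resA$barcodes[[k + 1]]
  phB <- resB$barcodes[[k + 1]]
  d <- bottleneck(phA, phB)
  ## nulls reuse each source's selected bandwidth (re-selection noise is
  ## amplified by b^-m in the density scale and would dominate the null),
  ## floored at each resample's connectivity radius
  null_one <- function(bar_ref, b_ref, sampler) {
    cl <- sampler(n)
    b <- max(b_ref, 1.05 * connectivity_radius(cl))
    bottleneck(bar_ref,
               ph_of_cloud(cl, k_max = k, bandwidth = b)$barcodes[[k + 1]])
  }
  with_seed(seed, {
    null_A <- vapply(seq_len(beta), function(i)
      null_one(phA, resA$bandwidth, sampler_A), numeric(1))
    null_B <- vapply(seq_len(beta), function(i)
      null_one(phB, resB$bandwidth, sampler_B), numeric(1))
    p_hat <- min((sum(null_A >= d) + 1) / (beta + 1),
                 (sum(null_B >= d) + 1) / (beta + 1))
    list(d_bd = d, p_hat = p_hat, null_A = null_A, null_B = null_B)
  })
}

#' Pairwise topological comparison of labelled clouds
#'
#' For each variant, a reference subsample of size `n` is drawn and its
#' `beta` null resampling distances are computed once; all pairwise
#' bottleneck distances and exceedance p-values are then assembled into
#' symmetric matrices (distance diagonal 0; the degenerate
#' self-comparison p-value is reported as `NA`).
#'
#' @param clouds named list of point clouds (rows = samples).
#' @param beta null resamples per variant.
#' @param n subsample size used for every persistence computation.
#' @param k homology dimension (default 1).
#' @param seed integer seed.
#' @return List `distance`, `p_value` (labelled matrices), `bandwidths`.
#' @export
compare_variants <- function(clouds, beta = 99, n = 200, k = 1, seed = 1) {
  stopifnot(length(clouds) >= 2)
  labs <- names(clouds)
  nv <- length(clouds)
  with_seed(seed, {
    sub <- function(cl, size) cl[sample.int(nrow(cl), size), , drop = FALSE]
    refs <- lapply(clouds, sub, size = n)
    phs <- lapply(refs, function(r) ph_of_cloud(r, k_max = k))
    bars <- lapply(phs, function(p) p$barcodes[[k + 1]])
    ## per-variant bandwidth selected once on the reference subsample,
    ## reused for that variant's nulls (floored at each resample's
    ## connectivity radius); see empirical_pvalue for the rationale
    nulls <- lapply(seq_len(nv), function(i)
      vapply(seq_len(beta), function(s) {
        cl <- sub(clouds[[i]], n)
        b <- max(phs[[i]]$bandwidth, 1.05 * connectivity_radius(cl))
        bottleneck(bars[[i]],
                   ph_of_cloud(cl, k_max = k,
                               bandwidth = b)$barcodes[[k + 1]])
      }, numeric(1)))
    D <- matrix(0, nv, nv, dimnames = list(labs, labs))
    P <- matrix(NA_real_, nv, nv, dimnames = list(labs, labs))
    for (i in seq_len(nv - 1)) {
      for (j in (i + 1):nv) {
        d <- bottleneck(bars[[i]], bars[[j]])
        D[i, j] <- D[j, i] <- d
        p <- min((sum(nulls[[i]] >= d) + 1) / (beta + 1),
                 (sum(nulls[[j]] >= d) + 1) / (beta + 1))
        P[i, j] <- P[j, i] <- p
      }
    }
    list(distance = D, p_value = P,
         bandwidths = vapply(phs, function(p) p$bandwidth, numeric(1)))
  })
}
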