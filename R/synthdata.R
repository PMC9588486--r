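## Synthetic data emulating the statistical structure of the MEK/ERK
## time-course assay: 3 measured phosphorylation states at 7 time points,
## replicate counts per variant as in the experimental design, i.i.d.
## additive Gaussian noise with one shared variance.

#' Experimental designs of the five MEK variants
#'
#' Wild type: times {0.5, 2, 3.25, 3.75, 5, 10, 20} min, 11 replicates;
#' SSDD (phosphomimetic): times {1, 2, 3.25, 5, 10, 20, 40} min, 6
#' replicates; Y130C, F53S, E203K (activating mutants): wild-type times, 5
#' replicates.  All with `S_tot` = 5 uM and `E_tot` = 0.65 uM.
#'
#' @return Named list of [experiment_design] objects.
#' @export
default_designs <- function() {
  wt_times <- c(0.5, 2, 3.25, 3.75, 5, 10, 20)
  ssdd_times <- c(1, 2, 3.25, 5, 10, 20, 40)
  list(
    `wild-type` = experiment_design(wt_times, 11, label = "wild-type"),
    Y130C = experiment_design(wt_times, 5, label = "Y130C"),
    F53S  = experiment_design(wt_times, 5, label = "F53S"),
    E203K = experiment_design(wt_times, 5, label = "E203K"),
    SSDD  = experiment_design(ssdd_times, 6, label = "SSDD"))
}

#' Scenario bundling a design with a simulation truth
#'
#' @param design an [experiment_design].
#' @param true_params [reduced_params] or [full_params].
#' @param sigma noise standard deviation, uM (>= 0).
#' @param label scenario label (defaults to the design's).
#' @return Object of class `variant_scenario`.
#' @export
variant_scenario <- function(design, true_params, sigma = 0.1,
                             label = design$label) {
  stopifnot(sigma >= 0)
  structure(list(label = label, design = design,
                 true_params = true_params, sigma = sigma),
            class = "variant_scenario")
}

## Demonstration truth: visible dynamics over 20 min, well inside the
## prior box.  The experimental study reports no fitted values to reuse.
default_truth <- function() reduced_params(0.5, 1.5, 0.3)

#' Generate a synthetic time course
#'
#' Simulates the scenario's model at the design's times and adds i.i.d.
#' `N(0, sigma^2)` noise to every entry of every replicate.  Negative
#' values are kept (they have positive likelihood under the Gaussian
#' observation model).  For the full model, `compound = TRUE` observes
#' the measured channels `(S0 + C1, S1 + C2, S2)`.
#'
#' @param scenario a [variant_scenario].
#' @param model `"linear"`, `"rational"` or `"full"`.
#' @param seed integer seed (fully determines the output).
#' @param compound observe compound channels (full model only).
#' @return A [timecourse_data].
#' @export
generate_timecourse <- function(scenario,
                                model = c("linear", "rational", "full"),
                                seed = 1, compound = FALSE) {
  model <- match.arg(model)
  design <- scenario$design
  pred <- model_trajectory(scenario$true_params, design, model,
                           compound = compound)
  r <- design$replicates
  vals <- with_seed(seed,
    array(rep(as.vector(pred), r), c(3, length(design$times), r)) +
      stats::rnorm(3 * length(design$times) * r, 0, scenario$sigma))
  timecourse_data(vals, design)
}

#' Write a synthetic time course as CSV
#'
#' Columns `replicate,time,species,value` with species in {S0, S1, S2}.
#' (Physically the measured channels correspond to `S0+C1`, `S1+C2`,
#' `S2`; at the experimental regime `kM ~ 25 uM >> E_tot` the complex
#' contributions are negligible, so the substrate labels are used.)
#'
#' @param z a [timecourse_data].
#' @param path output file.
#' @export
write_timecourse_csv <- function(z, path) {
  d <- dim(z$values)
  df <- data.frame(
    replicate = rep(seq_len(d[3]), each = d[1] * d[2]),
    time = rep(rep(z$design$times, each = d[1]), d[3]),
    species = rep(c("S0", "S1", "S2"), d[2] * d[3]),
    value = as.vector(z$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time course from CSV
#'
#' Inverse of [write_timecourse_csv]; the design's replicate count and
#' times are inferred from the file.
#'
#' @param path CSV with columns `replicate,time,species,value`.
#' @param S_tot,E_tot,label design fields not stored in the file.
#' @return A [timecourse_data].
#' @export
read_timecourse_csv <- function(path, S_tot = 5, E_tot = 0.65,
                                label = "file") {
  df <- utils::read.csv(path)
  times <- sort(unique(df$time))
  reps <- sort(unique(df$replicate))
  design <- experiment_design(times, length(reps), S_tot, E_tot, label)
  vals <- array(NA_real_, c(3, length(times), length(reps)))
  sp <- c(S0 = 1, S1 = 2, S2 = 3)
  vals[cbind(sp[df$species], match(df$time, times),
             match(df$replicate, reps))] <- df$value
  timecourse_data(vals, design)
}

#' Sample a Gaussian-mixture point cloud
#'
#' Fixture generator for the topological stage: draws `n` points from a
#' mixture of multivariate normals.
#'
#' @param modes list of `list(center, cov, weight)`; weights must sum to
#'   1 and covariances be positive definite.
#' @param n number of points.
#' @param seed integer seed.
#' @return `n x m` matrix.
#' @export
generate_posterior_like_cloud <- function(modes, n, seed = 1) {
  w <- vapply(modes, function(m) m$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop("invalid mixture: weights must sum to 1")
  chols <- lapply(modes, function(m) {
    ch <- try(chol(m$cov), silent = TRUE)
    if (inherits(ch, "try-error"))
      stop("invalid mixture: covariance not positive definite")
    ch
  })
  m_dim <- length(modes[[1]]$center)
  with_seed(seed, {
    comp <- sample.int(length(modes), n, replace = TRUE, prob = w)
    z <- matrix(stats::rnorm(n * m_dim), n, m_dim)
    out <- matrix(NA_real_, n, m_dim)
    for (i in seq_along(modes)) {
      idx <- which(comp == i)
      if (length(idx))
        out[idx, ] <- z[idx, , drop = FALSE] %*% chols[[i]] +
          rep(modes[[i]]$center, each = length(idx))
    }
    out
  })
}

#' Synthetic stand-in for the five per-variant posterior clouds
#'
#' Five labelled point clouds in `(kappa1, kappa2, pi)` space emulating
#' marginal posterior samples: four variants share a similar dispersion
#' scale (unimodal Gaussians with nearby covariances, shifted centres),
#' while SSDD is deliberately much more concentrated (clouds are
#' truncated at Mahalanobis radius 2.5, emulating compactly supported
#' posteriors), giving it a distinct density profile -- and hence the largest topological distance
#' from every other variant.  All coordinates lie inside the prior box.
#'
#' @param seed integer seed.
#' @param n points per cloud (default 2000).
#' @return Named list of `n x 3` matrices with columns
#'   `kappa1, kappa2, pi`.
#' @export
make_variant_suite <- function(seed = 1, n = 2000) {
  spec <- list(
    `wild-type` = list(c(0.50, 1.50, 0.30), c(0.050, 0.100, 0.050)),
    Y130C       = list(c(0.65, 1.20, 0.35), c(0.060, 0.120, 0.045)),
    F53S        = list(c(0.40, 1.80, 0.25), c(0.050, 0.090, 0.055)),
    E203K       = list(c(0.55, 1.40, 0.45), c(0.045, 0.110, 0.060)),
    SSDD        = list(c(0.30, 0.90, 0.60), c(0.015, 0.030, 0.015)))
  out <- lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    ## truncate at Mahalanobis radius 2.5 (compact support: far-tail
    ## strays sit in near-zero local density, destabilising the
    ## fixed-scale complex and its density signature across resamples)
    cl <- generate_posterior_like_cloud(
      list(list(center = s[[1]], cov = diag(s[[2]]^2), weight = 1)),
      2 * n, seed = seed + i)
    r2 <- colSums((t(cl) - s[[1]])^2 / s[[2]]^2)
    cl <- cl[r2 <= 2.5^2, , drop = FALSE][seq_len(n), , drop = FALSE]
    colnames(cl) <- c("kappa1", "kappa2", "pi")
    cl
  })
  names(out) <- names(spec)
  out
}
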