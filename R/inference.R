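## Bayesian inference of the reduced kinetic parameters.
##
## For the Linear ERK model the parameter is theta = (kappa1, kappa2, pi,
## sigma): the three kinetic parameters plus the noise standard deviation,
## which is inferred jointly and marginalised afterwards.  Priors are
## independent uniforms: kappa_i ~ U(0, 10) 1/min, sigma ~ U(0, 10) uM,
## pi ~ U(0, 1).  The sampler is an adaptive random-walk Metropolis with a
## jointly adapted proposal covariance (frozen after warm-up), run as
## several independent chains and gated on split-Rhat / effective sample
## size diagnostics.  Any asymptotically correct MCMC satisfies the
## downstream contract; nothing later depends on the sampler family.

#' Uniform prior specification
#'
#' @param model `"linear"` (default), `"rational"` or `"full"`.  The
#'   rational/full boxes extend the same pattern (gammas in (0, 1000),
#'   elementary rates in (0, 100)); posteriors for those models are
#'   prior-sensitive because of their practical non-identifiability, and
#'   are provided for inspection rather than routine use.
#' @param kappa_max,sigma_max box upper edges.
#' @return Object of class `prior_spec` with `lower`, `upper` named
#'   vectors over the model parameters plus `sigma`.
#' @export
prior_spec <- function(model = c("linear", "rational", "full"),
                       kappa_max = 10, sigma_max = 10) {
  model <- match.arg(model)
  b <- default_bounds(model)
  nm <- model_param_names(model)
  lower <- stats::setNames(rep(0, length(nm) + 1), c(nm, "sigma"))
  upper <- c(pmin(b$upper, ifelse(grepl("^kappa", nm), kappa_max,
                                  b$upper)),
             sigma = sigma_max)
  names(upper) <- c(nm, "sigma")
  structure(list(model = model, lower = lower, upper = upper),
            class = "prior_spec")
}

#' Log prior density (unnormalised)
#'
#' Zero inside the open box, `-Inf` on the boundary and outside.
#'
#' @param theta parameter vector including `sigma` as last component.
#' @param prior a [prior_spec].
#' @return 0 or `-Inf`.
#' @export
log_prior <- function(theta, prior) {
  if (length(theta) != length(prior$lower)) stop("theta length mismatch")
  if (all(theta > prior$lower) && all(theta < prior$upper)) 0 else -Inf
}

#' Unnormalised log posterior
#'
#' `log_prior + log-likelihood` with `sigma = theta[last]`; integration
#' failures yield `-Inf` with a warning.
#'
#' @param theta parameter vector including `sigma`.
#' @param z a [timecourse_data].
#' @param prior a [prior_spec].
#' @return Scalar log density (unnormalised).
#' @export
log_posterior <- function(theta, z, prior) {
  lp <- log_prior(theta, prior)
  if (!is.finite(lp)) return(-Inf)
  d <- length(theta)
  stats_ <- data_stats(z)
  rss <- rss_value(theta[-d], stats_, z$design, prior$model)
  if (is.na(rss)) {
    warning("integration failed; log posterior set to -Inf")
    return(-Inf)
  }
  sig <- theta[d]
  lp - stats_$n / 2 * log(2 * pi * sig^2) - rss / (2 * sig^2)
}

run_chain <- function(log_post, lower, upper, init, n_keep, warmup) {
  d <- length(init)
  x <- init
  lpx <- log_post(x)
  scale <- (upper - lower) / 50
  samples <- matrix(NA_real_, n_keep, d)
  hist_buf <- matrix(NA_real_, warmup, d)
  cov_chol <- NULL
  n_acc <- 0L; n_try <- 0L
  lambda <- 1
  for (it in seq_len(warmup + n_keep)) {
    if (!is.null(cov_chol)) {
      prop <- x + lambda * as.vector(stats::rnorm(d) %*% cov_chol)
    } else {
      prop <- x + stats::rnorm(d, 0, scale)
    }
    lpp <- log_post(prop)
    n_try <- n_try + 1L
    if (is.finite(lpp) && log(stats::runif(1)) < lpp - lpx) {
      x <- prop; lpx <- lpp; n_acc <- n_acc + 1L
    }
    if (it <= warmup) {
      hist_buf[it, ] <- x
      ## adapt: rescale every 100 iterations toward ~30% acceptance,
      ## switch to an empirical-covariance proposal mid-warm-up
      if (it %% 100 == 0) {
        rate <- n_acc / n_try
        adj <- exp(0.8 * (rate - 0.3))
        if (is.null(cov_chol)) scale <- scale * adj else
          lambda <- lambda * adj
        n_acc <- 0L; n_try <- 0L
        if (it >= warmup / 2 && it %% 200 == 0) {
          S <- stats::cov(hist_buf[seq(max(1, it - 1000), it), ,
                                   drop = FALSE])
          S <- S + diag(1e-10 * diag(S) + 1e-12, d)
          ch <- try(chol(2.38^2 / d * S), silent = TRUE)
          if (!inherits(ch, "try-error")) {
            if (is.null(cov_chol)) lambda <- 1
            cov_chol <- ch
          }
        }
      }
    } else {
      samples[it - warmup, ] <- x
    }
  }
  samples
}

#' Sample the posterior by adaptive Metropolis MCMC
#'
#' Runs `n_chains` independent adaptive random-walk chains, pools
#' `n_samples` post-warm-up draws and gates the result on convergence
#' diagnostics (all split-Rhat < 1.05 and ESS > 100 per coordinate),
#' retrying with a doubled warm-up before failing.
#'
#' @param z a [timecourse_data].
#' @param prior a [prior_spec].
#' @param n_samples pooled post-warm-up draws (default 2000).
#' @param n_chains number of chains (>= 2).
#' @param warmup warm-up iterations per chain.
#' @param seed integer seed; output is reproducible given the seed.
#' @param max_retries diagnostic-failure retries.
#' @return Object of class `posterior_cloud`: `samples` (n x (p+1) matrix,
#'   last column `sigma`), `variant`, `seed`, `n_chains`, `diagnostics`.
#' @export
sample_posterior <- function(z, prior = prior_spec(), n_samples = 2000,
                             n_chains = 4, warmup = 2000, seed = 1,
                             max_retries = 2) {
  stopifnot(n_chains >= 2)
  d <- length(prior$lower)
  ## cached-sufficient-statistics version of log_posterior
  stats_ <- data_stats(z)
  rss_fun <- make_rss_fun(stats_, z$design, prior$model)
  n_obs <- stats_$n
  lo <- prior$lower; up <- prior$upper
  lp <- function(th) {
    if (any(th <= lo) || any(th >= up)) return(-Inf)
    rss <- rss_fun(th[-d])
    if (is.na(rss)) return(-Inf)
    sig <- th[d]
    -n_obs / 2 * log(2 * pi * sig^2) - rss / (2 * sig^2)
  }
  n_keep <- ceiling(n_samples / n_chains)
  for (attempt in 0:max_retries) {
    wu <- warmup * 2^attempt
    chains <- with_seed(seed + attempt, {
      lapply(seq_len(n_chains), function(ch) {
        init <- prior$lower + (prior$upper - prior$lower) *
          stats::runif(d, 0.05, 0.95)
        ## start sigma low: flat high-sigma starts waste warm-up
        init[d] <- stats::runif(1, 0.02, 1)
        run_chain(lp, prior$lower, prior$upper, init, n_keep, wu)
      })
    })
    diag_ <- mcmc_diagnostics(chains)
    if (diag_$pass) break
  }
  if (!diag_$pass)
    stop("MCMC diagnostics failed after ", max_retries + 1, " attempts ",
         "(max split-Rhat = ", round(max(diag_$rhat), 3),
         ", min ESS = ", round(min(diag_$ess), 1), ")")
  samples <- do.call(rbind, chains)[seq_len(n_samples), , drop = FALSE]
  colnames(samples) <- names(prior$lower)
  structure(list(samples = samples, variant = z$design$label,
                 seed = seed, n_chains = n_chains, diagnostics = diag_),
            class = "posterior_cloud")
}

split_chains <- function(chains) {
  out <- list()
  for (ch in chains) {
    h <- floor(nrow(ch) / 2)
    out <- c(out, list(ch[seq_len(h), , drop = FALSE],
                       ch[(h + 1):(2 * h), , drop = FALSE]))
  }
  out
}

ess_one <- function(v) {
  n <- length(v)
  if (stats::var(v) == 0) return(0)
  ac <- stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE,
                   demean = TRUE)$acf[-1]
  ## Geyer-style truncation at the first non-positive autocorrelation
  neg <- which(ac <= 0)
  if (length(neg)) ac <- ac[seq_len(neg[1] - 1)]
  n / (1 + 2 * sum(ac))
}

#' MCMC convergence diagnostics
#'
#' Split-Rhat (each chain halved) and a per-coordinate effective sample
#' size (initial-positive-sequence autocorrelation truncation, summed
#' over chains).  The pass gate is all split-Rhat < 1.05 and ESS > 100.
#'
#' @param chains list (>= 2) of equal-size sample matrices.
#' @return List `rhat`, `ess` (per coordinate), `pass`.
#' @export
mcmc_diagnostics <- function(chains) {
  stopifnot(length(chains) >= 2)
  sp <- split_chains(chains)
  m <- length(sp); n <- nrow(sp[[1]]); d <- ncol(sp[[1]])
  rhat <- numeric(d); ess <- numeric(d)
  for (j in seq_len(d)) {
    means <- vapply(sp, function(c_) mean(c_[, j]), numeric(1))
    vars <- vapply(sp, function(c_) stats::var(c_[, j]), numeric(1))
    W <- mean(vars); B <- n * stats::var(means)
    rhat[j] <- if (W > 0) sqrt(((n - 1) / n * W + B / n) / W) else Inf
    ess[j] <- sum(vapply(chains, function(c_) ess_one(c_[, j]),
                         numeric(1)))
  }
  nm <- colnames(chains[[1]])
  if (!is.null(nm)) names(rhat) <- names(ess) <- nm
  list(rhat = rhat, ess = ess,
       pass = all(rhat < 1.05) && all(ess > 100))
}

#' Marginalise a posterior cloud to named coordinates
#'
#' @param cloud a `posterior_cloud` (or plain matrix with column names).
#' @param keep character vector of parameter names to keep; the
#'   topological comparison keeps `(kappa1, kappa2, pi)`, dropping sigma.
#' @return Matrix with the selected columns.
#' @export
marginalize <- function(cloud, keep = c("kappa1", "kappa2", "pi")) {
  samples <- if (inherits(cloud, "posterior_cloud")) cloud$samples
  else as.matrix(cloud)
  bad <- setdiff(keep, colnames(samples))
  if (length(bad)) stop("unknown parameter name(s): ",
                        paste(bad, collapse = ", "))
  samples[, keep, drop = FALSE]
}
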