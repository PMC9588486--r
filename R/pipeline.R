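## Orchestration of the full analysis on synthetic data:
## simulate -> reduction check -> identifiability -> inference -> topology.
## The package is a library rather than a shell tool; these functions (and
## the vignette) are the pipeline interface.

#' Default pipeline configuration
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param stages subset of
#'   `c("simulate", "reduce-check", "identify", "infer", "tda-compare")`.
#' @param model model used by the identifiability/inference stages.
#' @param alpha significance level for confidence regions.
#' @param n_region Algorithm-2 proposals.
#' @param n_sim Algorithm-1 simulated datasets.
#' @param n_posterior pooled posterior draws.
#' @param beta,n_sub topological comparison: null resamples and
#'   subsample size.
#' @return Configuration list.
#' @export
pipeline_config <- function(seed = 1,
                            stages = c("simulate", "reduce-check",
                                       "identify", "infer",
                                       "tda-compare"),
                            model = "linear", alpha = 0.05,
                            n_region = 2000, n_sim = 200,
                            n_posterior = 2000, beta = 19, n_sub = 150) {
  list(seed = seed, stages = stages, model = model, alpha = alpha,
       n_region = n_region, n_sim = n_sim, n_posterior = n_posterior,
       beta = beta, n_sub = n_sub)
}

#' Run the synthetic analysis pipeline
#'
#' Executes the requested stages in order on wild-type-design synthetic
#' data, writing CSV/JSON artifacts and a JSON manifest to `out_dir`.
#' Re-running with the same configuration reproduces the artifacts.
#'
#' @param config list from [pipeline_config].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, model = config$model,
                   stages = config$stages, files = list())
  add <- function(stage, name, path) {
    manifest$files[[stage]] <<- c(manifest$files[[stage]],
                                  stats::setNames(list(path), name))
  }
  design <- default_designs()[["wild-type"]]
  scen <- variant_scenario(design, default_truth(), sigma = 0.1)
  z <- generate_timecourse(scen, model = "linear", seed = config$seed)

  if ("simulate" %in% config$stages) {
    p <- file.path(out_dir, "timecourse.csv")
    write_timecourse_csv(z, p); add("simulate", "timecourse", p)
    full <- full_params(0.08, 1, 1, 0.08, 1, 1)
    tr <- model_trajectory(full, design, "full")
    p2 <- file.path(out_dir, "trajectory_full.csv")
    write_trajectory_csv(tr, p2); add("simulate", "trajectory_full", p2)
  }
  if ("reduce-check" %in% config$stages) {
    full <- full_params(0.08, 1, 1, 0.08, 1, 1)
    red <- reduced_from_full(full, design$E_tot)
    grid <- experiment_design(seq(0.5, 20, by = 0.5), 1)
    err <- rbind(
      linear = reduction_error(model_trajectory(full, grid, "full"),
                               model_trajectory(red, grid, "linear")),
      rational = reduction_error(model_trajectory(full, grid, "full"),
                                 model_trajectory(red, grid, "rational")))
    p <- file.path(out_dir, "reduction_error.csv")
    utils::write.csv(err, p); add("reduce-check", "reduction_error", p)
  }
  if ("identify" %in% config$stages) {
    fit <- mle_fit(z, config$model, seed = config$seed)
    sig <- fit$sigma_hat
    nlk <- algorithm1_neg_log_kstar(fit$theta_hat, sig, design,
                                    config$model, alpha = config$alpha,
                                    n_sim = config$n_sim,
                                    seed = config$seed)
    spec <- confidence_spec(z, fit$theta_hat, sig, as.numeric(nlk),
                            config$model)
    se <- mle_standard_errors(z, fit, config$model)
    bounds <- list(lower = pmax(fit$theta_hat - 12 * se, 0),
                   upper = fit$theta_hat + 12 * se)
    if (config$model == "linear")
      bounds$upper["pi"] <- min(bounds$upper["pi"], 1)
    region <- algorithm2_marginal_region(z, spec, bounds,
                                         c("kappa1", "kappa2"),
                                         n_samples = config$n_region,
                                         seed = config$seed)
    verdict <- boundedness_assessment(region)
    p <- file.path(out_dir, "region.csv")
    utils::write.csv(data.frame(region$accepted, accept = TRUE), p,
                     row.names = FALSE)
    add("identify", "region", p)
    p2 <- file.path(out_dir, "identifiability.json")
    jsonlite::write_json(list(theta_hat = as.list(fit$theta_hat),
                              sigma_hat = sig,
                              neg_log_kstar = as.numeric(nlk),
                              wilks = wilks_neg_log_kstar(config$alpha, 3),
                              verdict = verdict),
                         p2, auto_unbox = TRUE, digits = NA)
    add("identify", "summary", p2)
  }
  if ("infer" %in% config$stages) {
    cloud <- sample_posterior(z, prior_spec(), config$n_posterior,
                              seed = config$seed)
    p <- file.path(out_dir, "posterior.csv")
    write_cloud_csv(cloud$samples, p); add("infer", "posterior", p)
    p2 <- file.path(out_dir, "posterior_meta.json")
    jsonlite::write_json(list(variant = cloud$variant, seed = cloud$seed,
                              n_chains = cloud$n_chains,
                              rhat = as.list(cloud$diagnostics$rhat),
                              ess = as.list(cloud$diagnostics$ess)),
                         p2, auto_unbox = TRUE, digits = NA)
    add("infer", "posterior_meta", p2)
  }
  if ("tda-compare" %in% config$stages) {
    suite <- make_variant_suite(seed = config$seed)
    ## H0 carries the density-scale signature for the unimodal suite (the
    ## vignette discusses the choice of homology dimension)
    cmp <- compare_variants(suite, beta = config$beta, n = config$n_sub,
                            k = 0, seed = config$seed)
    p <- file.path(out_dir, "distance_matrix.csv")
    utils::write.csv(cmp$distance, p); add("tda-compare", "distance", p)
    p2 <- file.path(out_dir, "pvalue_matrix.csv")
    utils::write.csv(cmp$p_value, p2); add("tda-compare", "p_value", p2)
    ref <- suite[[1]][seq_len(config$n_sub), ]
    p3 <- file.path(out_dir, "barcodes_wild-type.csv")
    write_barcodes_csv(ph_of_cloud(ref, k_max = 0)$barcodes, p3)
    add("tda-compare", "barcodes", p3)
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Human-readable pipeline summary
#'
#' @param manifest manifest list from [run_pipeline], or the path of a
#'   `manifest.json`.
#' @return Character vector of summary lines (also printed).
#' @export
report_pipeline <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("missing manifest: ", manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  if (length(manifest$files) == 0) stop("empty manifest: nothing was run")
  lines <- c(sprintf("pipeline run (seed %s, model %s)",
                     manifest$seed, manifest$model))
  fi <- manifest$files
  if (!is.null(fi$identify)) {
    s <- jsonlite::read_json(fi$identify$summary, simplifyVector = TRUE)
    lines <- c(lines,
               sprintf("identifiability: region %s; -log k* = %.3f (Wilks %.3f)",
                       s$verdict, s$neg_log_kstar, s$wilks),
               sprintf("  theta_hat: kappa1 = %.4f, kappa2 = %.4f, pi = %.4f; sigma_hat = %.4f",
                       s$theta_hat$kappa1, s$theta_hat$kappa2,
                       s$theta_hat$pi, s$sigma_hat))
  }
  if (!is.null(fi$`tda-compare`)) {
    D <- as.matrix(utils::read.csv(fi$`tda-compare`$distance,
                                   row.names = 1, check.names = FALSE))
    far <- rownames(D)[which.max(rowSums(D))]
    lines <- c(lines,
               sprintf("topology: most distant variant = %s", far),
               utils::capture.output(print(round(D, 4))))
  }
  for (l in lines) cat(l, "\n")
  invisible(lines)
}
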