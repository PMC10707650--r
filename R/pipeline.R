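# Pipeline stages. Each run_* function is a thin orchestration layer over
# the analysis functions: it resolves a configuration, writes its outputs
# as CSV, and drops a JSON manifest echoing the fully resolved
# configuration plus software versions, so any artifact can be traced back
# to the exact settings that produced it.

.write_manifest <- function(out_dir, stage, config) {
  manifest <- list(stage = stage,
                   package = "radshoots",
                   package_version = as.character(
                     utils::packageVersion("radshoots")),
                   r_version = R.version.string,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config)
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

.resolve_table <- function(input) {
  if (inherits(input, "sample_table")) return(input)
  if (is.character(input) && length(input) == 1L) return(read_samples(input))
  stop("input must be a sample_table or a CSV path")
}

# censoring-filter with the 453 -> 418 style accounting logged
.filtered_with_accounting <- function(table, quiet = FALSE) {
  total <- nrow(table)
  filtered <- exclude_censored(table)
  if (!quiet) {
    message(sprintf("records: %d total, %d censored-excluded (%.1f%%), %d analysed",
                    total, total - nrow(filtered$table),
                    100 * filtered$excluded_fraction, nrow(filtered$table)))
  }
  filtered
}

#' Pipeline stage: simulate a survey
#'
#' Generates a synthetic sample table from `config`, writes it as CSV
#' together with the generating truth (JSON) and a manifest.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [generator_config].
#' @param quiet suppress progress messages.
#' @return Invisibly, a named vector of output paths.
#' @export
run_simulate <- function(out_dir, config = generator_config(),
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_samples(config)
  paths <- write_simulation(sim, file.path(out_dir, "samples.csv"))
  cfg <- unclass(config)
  cfg$truth <- unclass(cfg$truth)
  manifest <- .write_manifest(out_dir, "simulate", cfg)
  if (!quiet) {
    message(sprintf("simulated %d records in %d stands -> %s",
                    nrow(sim$table), config$n_stands, paths[["csv"]]))
  }
  invisible(c(paths, manifest = manifest))
}

#' Pipeline stage: fit a model
#'
#' Reads (or takes) a sample table, excludes censored records with logged
#' accounting, fits the requested model, and writes the posterior draws,
#' a Table-5-style summary (mean, SD, 2.5%/97.5% quantiles, R-hat) and a
#' convergence report. By default the stage refuses to write summaries when
#' any R-hat is 1.1 or larger ("convergence gate"); pass
#' `allow_nonconverged = TRUE` to override.
#'
#' @param input a [sample_table] or CSV path.
#' @param out_dir output directory.
#' @param model one of `"model1"`, `"model2"`, `"full"`.
#' @param mcmc an [mcmc_config].
#' @param allow_nonconverged write outputs even when R-hat >= 1.1.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the `posterior_draws`, the summary
#'   `data.frame` and output paths.
#' @export
run_fit <- function(input, out_dir, model = "full",
                    mcmc = mcmc_config(), allow_nonconverged = FALSE,
                    quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- .resolve_table(input)
  filtered <- .filtered_with_accounting(table, quiet)
  spec <- model_spec(model)
  draws <- fit_model(spec, filtered$table, mcmc)
  summ <- summarize_draws(draws)
  r <- summ$rhat[is.finite(summ$rhat)]
  converged <- length(r) > 0 && all(r < 1.1)
  if (!converged && !allow_nonconverged) {
    stop(sprintf(
      "convergence gate: max R-hat = %.3f >= 1.1; rerun with more iterations or allow_nonconverged = TRUE",
      max(r)))
  }
  draws_path <- file.path(out_dir, paste0(model, "_draws.csv"))
  pooled <- as.matrix(draws)
  chain_col <- rep(seq_along(draws$chains),
                   each = nrow(draws$chains[[1]]))
  utils::write.csv(cbind(chain = chain_col, as.data.frame(pooled)),
                   draws_path, row.names = FALSE)
  summary_path <- file.path(out_dir, paste0(model, "_summary.csv"))
  utils::write.csv(summ, summary_path, row.names = FALSE)
  manifest <- .write_manifest(out_dir, paste0("fit_", model),
                              list(model = model, mcmc = unclass(mcmc),
                                   excluded_fraction =
                                     filtered$excluded_fraction,
                                   converged = converged,
                                   max_rhat = max(r)))
  if (!quiet) {
    message(sprintf("fitted %s: max R-hat %.3f -> %s", model, max(r),
                    summary_path))
  }
  invisible(list(draws = draws, summary = summ,
                 paths = c(draws = draws_path, summary = summary_path,
                           manifest = manifest)))
}

#' Pipeline stage: compare the constant-SD and heteroscedastic models
#'
#' Fits `model1` and `model2` to the same (censoring-filtered) data,
#' computes new-stand WAIC for both, and writes a comparison table
#' (posterior means of the variance parameters plus lppd, p_waic, WAIC and
#' the difference to the best model) and the selection verdict.
#'
#' @inheritParams run_fit
#' @param mc_samples Monte Carlo points for the heteroscedastic marginal.
#' @param tolerance WAIC difference treated as small (simpler model wins).
#' @param thin thinning applied to pooled draws before the WAIC pass.
#' @return Invisibly, a list with the comparison `data.frame`, the verdict
#'   and output paths.
#' @export
run_select <- function(input, out_dir, mcmc = mcmc_config(),
                       mc_samples = 1000L, tolerance = 2, thin = 1L,
                       quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- .resolve_table(input)
  filtered <- .filtered_with_accounting(table, quiet)
  fits <- list()
  waics <- list()
  for (m in c("model1", "model2")) {
    spec <- model_spec(m)
    fits[[m]] <- fit_model(spec, filtered$table, mcmc)
    pll <- marginal_loglik(fits[[m]], filtered$table,
                           mc_samples = mc_samples, seed = mcmc$seed,
                           thin = thin)
    waics[[m]] <- waic(pll)
  }
  verdict <- select_model(waics$model1, waics$model2,
                          tolerance = tolerance)
  mean_of <- function(fit, par) {
    mat <- as.matrix(fit)
    if (par %in% colnames(mat)) mean(mat[, par]) else NA_real_
  }
  comp <- data.frame(
    model = c("model1", "model2"),
    mu_bar = c(mean_of(fits$model1, "mu_bar"),
               mean_of(fits$model2, "mu_bar")),
    sigma_bar = c(mean_of(fits$model1, "sigma_bar"),
                  mean_of(fits$model2, "sigma_bar")),
    sigma_M = c(mean_of(fits$model1, "sigma_M"),
                mean_of(fits$model2, "sigma_M")),
    sigma_V = c(NA_real_, mean_of(fits$model2, "sigma_V")),
    lppd = c(waics$model1$lppd, waics$model2$lppd),
    p_waic = c(waics$model1$p_waic, waics$model2$p_waic),
    waic = c(waics$model1$waic, waics$model2$waic),
    stringsAsFactors = FALSE)
  comp$delta_waic <- comp$waic - min(comp$waic)
  comp_path <- file.path(out_dir, "model_comparison.csv")
  utils::write.csv(comp, comp_path, row.names = FALSE)
  verdict_path <- file.path(out_dir, "selection.json")
  jsonlite::write_json(list(selected = as.character(verdict),
                            delta_waic = attr(verdict, "delta"),
                            tolerance = tolerance),
                       verdict_path, auto_unbox = TRUE, digits = NA)
  manifest <- .write_manifest(out_dir, "select",
                              list(mcmc = unclass(mcmc),
                                   mc_samples = mc_samples,
                                   tolerance = tolerance, thin = thin))
  if (!quiet) {
    message(sprintf("WAIC: model1 %.1f, model2 %.1f -> selected %s",
                    comp$waic[1], comp$waic[2], as.character(verdict)))
  }
  invisible(list(comparison = comp, verdict = verdict, fits = fits,
                 paths = c(comparison = comp_path, verdict = verdict_path,
                           manifest = manifest)))
}

#' Pipeline stage: sample-size and threshold predictions
#'
#' Writes the sample-size curve (expected stand mean and predictive SD per
#' candidate `n`) and, when a threshold is given, the model-implied
#' fraction of individuals below it at the assumed true stand mean.
#'
#' @param out_dir output directory.
#' @param hyper a [hyperparams] (point estimates), or `NULL` when `draws`
#'   supplied.
#' @param draws optional `posterior_draws` to propagate posterior
#'   uncertainty into the curve band.
#' @param n_range candidate sample sizes.
#' @param true_bq assumed true stand concentration in Bq kg^-1.
#' @param threshold_bq optional regulatory threshold in Bq kg^-1.
#' @param level band coverage probability.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the curve `data.frame` and output paths.
#' @export
run_predict <- function(out_dir, hyper = NULL, draws = NULL,
                        n_range = 1:10, true_bq = 10,
                        threshold_bq = 50, level = 0.95, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(true_bq > 0)
  curve <- sample_size_curve(n_range, log(true_bq), hyper = hyper,
                             draws = draws, level = level)
  curve_path <- file.path(out_dir, "sample_size_curve.csv")
  utils::write.csv(curve, curve_path, row.names = FALSE)
  paths <- c(curve = curve_path)
  if (!is.null(threshold_bq)) {
    sb <- if (!is.null(hyper)) hyper$sigma_bar else
      mean(as.matrix(draws)[, "sigma_bar"])
    p <- prob_below_threshold(log(true_bq), sb, threshold_bq)
    thr_path <- file.path(out_dir, "threshold.json")
    jsonlite::write_json(list(threshold_bq = threshold_bq,
                              true_bq = true_bq,
                              prob_below = p),
                         thr_path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, threshold = thr_path)
  }
  manifest <- .write_manifest(out_dir, "predict",
                              list(n_range = n_range, true_bq = true_bq,
                                   threshold_bq = threshold_bq,
                                   level = level,
                                   from_draws = !is.null(draws)))
  if (!quiet) message("sample-size curve -> ", curve_path)
  invisible(list(curve = curve, paths = c(paths, manifest = manifest)))
}
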