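#' Population-level parameters of the hierarchical log-normal model
#'
#' Collects the hyperparameters shared by all model variants: the overall mean
#' `mu_bar` of log activity, the within-stand SD `sigma_bar`, the SD
#' `sigma_M` of random stand effects on the mean, the SD `sigma_V` of random
#' stand effects on the log of the within-stand SD (0 for the
#' constant-variance model), the SD `sigma_S` of random species effects
#' (0 when species are not modelled) and the stem-origin coefficient `beta`
#' (0 when origin is not modelled). All SDs are on the natural-log scale.
#'
#' @param mu_bar overall mean of log_e activity.
#' @param sigma_bar overall within-stand SD (> 0).
#' @param sigma_M SD of stand effects on the mean (>= 0).
#' @param sigma_V SD of stand effects on the log-SD (>= 0).
#' @param sigma_S SD of species effects (>= 0).
#' @param beta coefficient of stem origin (0 = sprout, 1 = plantation).
#' @return A list of class `hyperparams`.
#' @export
hyperparams <- function(mu_bar, sigma_bar, sigma_M, sigma_V = 0,
                        sigma_S = 0, beta = 0) {
  stopifnot(is.numeric(mu_bar), length(mu_bar) == 1L,
            sigma_bar > 0, sigma_M >= 0, sigma_V >= 0, sigma_S >= 0)
  structure(list(mu_bar = mu_bar, sigma_bar = sigma_bar, sigma_M = sigma_M,
                 sigma_V = sigma_V, sigma_S = sigma_S, beta = beta),
            class = "hyperparams")
}

#' @export
print.hyperparams <- function(x, ...) {
  cat("<hyperparams>",
      sprintf("mu_bar=%.3g sigma_bar=%.3g sigma_M=%.3g sigma_V=%.3g sigma_S=%.3g beta=%.3g",
              x$mu_bar, x$sigma_bar, x$sigma_M, x$sigma_V, x$sigma_S, x$beta),
      "\n")
  invisible(x)
}

#' Model structure specification
#'
#' Three structures are supported:
#' \describe{
#'   \item{`model1`}{stand effects on the mean only; one shared within-stand
#'     SD. Used for the single-species model comparison.}
#'   \item{`model2`}{as `model1` plus a random stand effect on the log of the
#'     within-stand SD (heteroscedastic stands).}
#'   \item{`full`}{the all-species model: stand effects on the mean, a random
#'     species effect and the stem-origin covariate, with the shared SD of
#'     `model1` (the structure retained by model selection).}
#' }
#'
#' The prior on `mu_bar` is a vague Normal(0, 100^2); the origin coefficient
#' `beta` gets the same vague normal prior; every SD gets a weakly
#' informative half-normal prior with scale 10.
#'
#' @param name one of `"model1"`, `"model2"`, `"full"`.
#' @param prior_mu_scale SD of the normal prior on `mu_bar` (and `beta`).
#' @param prior_sd_scale scale of the half-normal priors on SD parameters.
#' @return A list of class `model_spec` with logical fields
#'   `has_varying_sd`, `has_species`, `has_origin`.
#' @export
model_spec <- function(name = c("model1", "model2", "full"),
                       prior_mu_scale = 100, prior_sd_scale = 10) {
  name <- match.arg(name)
  structure(list(name = name,
                 has_varying_sd = name == "model2",
                 has_species = name == "full",
                 has_origin = name == "full",
                 prior_mu_scale = prior_mu_scale,
                 prior_sd_scale = prior_sd_scale),
            class = "model_spec")
}

# Internal: index a censoring-filtered table for likelihood work.
# Stand/species levels use order of first appearance (stable ordering).
.model_data <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  if (nrow(table) == 0L) stop("sample table is empty")
  if (any(table$censored)) {
    stop("censored records present; call exclude_censored() first")
  }
  if (any(table$activity <= 0)) {
    stop("non-positive activity in a non-censored record")
  }
  stand <- factor(table$stand_id, levels = unique(table$stand_id))
  species <- factor(table$species, levels = unique(table$species))
  list(y = log(table$activity),
       stand = as.integer(stand), stand_levels = levels(stand),
       species = as.integer(species), species_levels = levels(species),
       origin = as.numeric(table$origin),
       n = nrow(table), n_stands = nlevels(stand),
       n_species = nlevels(species))
}

# Internal: per-record mean and SD given hyperparameters and latent effects
.record_mean_sd <- function(spec, hyper, latent, md) {
  mu <- rep(hyper$mu_bar, md$n)
  if (spec$has_origin) mu <- mu + hyper$beta * md$origin
  mu <- mu + latent$eps_M[md$stand]
  if (spec$has_species) mu <- mu + latent$eps_S[md$species]
  sigma <- rep(hyper$sigma_bar, md$n)
  if (spec$has_varying_sd) sigma <- hyper$sigma_bar * exp(latent$eps_V[md$stand])
  list(mu = mu, sigma = sigma)
}

.check_latent <- function(spec, latent, md) {
  if (length(latent$eps_M) != md$n_stands) {
    stop("eps_M must have one value per stand (", md$n_stands, ")")
  }
  if (spec$has_varying_sd && length(latent$eps_V) != md$n_stands) {
    stop("eps_V must have one value per stand (", md$n_stands, ")")
  }
  if (spec$has_species && length(latent$eps_S) != md$n_species) {
    stop("eps_S must have one value per species (", md$n_species, ")")
  }
}

#' Log likelihood of a sample table under a model
#'
#' Sum over individuals of the normal log density of log_e(activity) with
#' mean `mu_bar + beta*origin + eps_M[stand] + eps_S[species]` (terms present
#' according to the model structure) and SD `sigma_bar * exp(eps_V[stand])`
#' (the factor present only in `model2`).
#'
#' @param spec a [model_spec].
#' @param hyper a [hyperparams].
#' @param latent list with numeric vectors `eps_M` (one per stand) and,
#'   as the structure requires, `eps_V` (per stand) and `eps_S` (per species).
#'   Stands and species are indexed by order of first appearance in `table`.
#' @param table a censoring-filtered [sample_table].
#' @return A single numeric log likelihood.
#' @export
log_likelihood <- function(spec, hyper, latent, table) {
  md <- .model_data(table)
  .check_latent(spec, latent, md)
  if (hyper$sigma_bar <= 0) return(-Inf)
  ms <- .record_mean_sd(spec, hyper, latent, md)
  sum(stats::dnorm(md$y, ms$mu, ms$sigma, log = TRUE))
}

#' Log prior density of hyperparameters and latent effects
#'
#' `mu_bar` (and `beta`, when present) get Normal(0, `prior_mu_scale`^2);
#' each SD parameter that the structure uses gets a half-normal with scale
#' `prior_sd_scale`; latent effects get their hierarchical normal densities
#' Normal(0, sigma_M^2), Normal(0, sigma_V^2), Normal(0, sigma_S^2).
#' Out-of-support values (`sigma_bar <= 0`, any used SD < 0) return `-Inf`
#' rather than raising an error.
#'
#' @inheritParams log_likelihood
#' @return A single numeric log prior density (`-Inf` out of support).
#' @export
log_prior <- function(spec, hyper, latent) {
  half_normal <- function(x, scale) {
    if (x < 0) return(-Inf)
    log(2) + stats::dnorm(x, 0, scale, log = TRUE)
  }
  if (hyper$sigma_bar <= 0 || hyper$sigma_M < 0) return(-Inf)
  lp <- stats::dnorm(hyper$mu_bar, 0, spec$prior_mu_scale, log = TRUE) +
    half_normal(hyper$sigma_bar, spec$prior_sd_scale) +
    half_normal(hyper$sigma_M, spec$prior_sd_scale)
  lp <- lp + sum(stats::dnorm(latent$eps_M, 0, hyper$sigma_M, log = TRUE))
  if (spec$has_varying_sd) {
    if (hyper$sigma_V < 0) return(-Inf)
    lp <- lp + half_normal(hyper$sigma_V, spec$prior_sd_scale) +
      sum(stats::dnorm(latent$eps_V, 0, hyper$sigma_V, log = TRUE))
  }
  if (spec$has_species) {
    if (hyper$sigma_S < 0) return(-Inf)
    lp <- lp + half_normal(hyper$sigma_S, spec$prior_sd_scale) +
      sum(stats::dnorm(latent$eps_S, 0, hyper$sigma_S, log = TRUE))
  }
  if (spec$has_origin) {
    lp <- lp + stats::dnorm(hyper$beta, 0, spec$prior_mu_scale, log = TRUE)
  }
  lp
}

#' Log posterior density (unnormalised)
#'
#' `log_likelihood + log_prior`; `-Inf` from either term propagates. This
#' density is the single source of truth for the MCMC sampler in
#' [fit_model()].
#'
#' @inheritParams log_likelihood
#' @return A single numeric value.
#' @export
log_posterior <- function(spec, hyper, latent, table) {
  lp <- log_prior(spec, hyper, latent)
  if (!is.finite(lp)) return(lp)
  lp + log_likelihood(spec, hyper, latent, table)
}
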