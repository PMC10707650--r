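# Univariate slice sampler (Neal 2003): stepping out + shrinkage.
# Used for the non-conjugate conditionals (SD hyperparameters on the log
# scale, and the per-stand log-SD effects of the heteroscedastic model).
.slice1 <- function(x0, logf, w = 1, m = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started outside support")
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(m * stats::runif(1))
  k <- m - 1 - j
  while (j > 0 && logf(L) > z) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > z) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

#' MCMC sampler configuration
#'
#' Defaults follow the survey analysis protocol: four independent chains,
#' each with 8,000 warmup iterations discarded and 8,000 retained.
#' `test_scale` divides both iteration counts (e.g. `test_scale = 16` gives
#' 500/500) so tests and quick exploratory fits stay fast; summaries from
#' scaled runs carry proportionally more Monte Carlo error.
#'
#' @param chains number of chains (>= 2 so split-R-hat is computable).
#' @param warmup warmup iterations per chain (discarded).
#' @param sampling retained iterations per chain.
#' @param seed integer seed; chain `c` uses `seed + 104729 * c`.
#' @param test_scale optional factor by which to divide `warmup` and
#'   `sampling`.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, warmup = 8000L, sampling = 8000L,
                        seed = 1L, test_scale = NULL) {
  stopifnot(chains >= 1, warmup >= 0, sampling >= 1)
  if (!is.null(test_scale)) {
    stopifnot(test_scale >= 1)
    warmup <- max(1L, as.integer(round(warmup / test_scale)))
    sampling <- max(2L, as.integer(round(sampling / test_scale)))
  }
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 sampling = as.integer(sampling), seed = as.integer(seed),
                 test_scale = test_scale),
            class = "mcmc_config")
}

# One Gibbs pass over the model state. Location parameters have exact
# conjugate normal full conditionals under the centered parameterization;
# SD parameters and eps_V are slice-sampled on the log scale. The targets
# are the full conditionals of log_posterior(); a test asserts agreement.
.gibbs_iteration <- function(state, spec, md, fixed, rs) {
  y <- md$y
  prior_prec_mu <- 1 / spec$prior_mu_scale^2
  pscale2 <- 2 * spec$prior_sd_scale^2

  sig_i <- if (spec$has_varying_sd)
    state$sigma_bar * exp(state$eps_V[md$stand]) else
    rep(state$sigma_bar, md$n)
  wi <- 1 / sig_i^2

  lin <- function(drop) {
    r <- y
    if (drop != "mu_bar") r <- r - state$mu_bar
    if (spec$has_origin && drop != "beta") r <- r - state$beta * md$origin
    if (drop != "eps_M") r <- r - state$eps_M[md$stand]
    if (spec$has_species && drop != "eps_S")
      r <- r - state$eps_S[md$species]
    r
  }

  if (!"mu_bar" %in% fixed) {
    r <- lin("mu_bar")
    prec <- sum(wi) + prior_prec_mu
    state$mu_bar <- stats::rnorm(1, sum(wi * r) / prec, sqrt(1 / prec))
  }
  if (spec$has_origin && !"beta" %in% fixed) {
    r <- lin("beta")
    prec <- sum(wi * md$origin^2) + prior_prec_mu
    state$beta <- stats::rnorm(1, sum(wi * md$origin * r) / prec,
                               sqrt(1 / prec))
  }
  {
    r <- lin("eps_M")
    swr <- rs$by_stand(wi * r)
    sw <- rs$by_stand(wi)
    prec <- 1 / state$sigma_M^2 + sw
    state$eps_M <- stats::rnorm(md$n_stands, swr / prec, sqrt(1 / prec))
  }
  if (spec$has_species) {
    r <- lin("eps_S")
    swr <- rs$by_species(wi * r)
    sw <- rs$by_species(wi)
    prec <- 1 / state$sigma_S^2 + sw
    state$eps_S <- stats::rnorm(md$n_species, swr / prec, sqrt(1 / prec))
  }

  # Interweaving translation moves: the likelihood depends on eps_M and
  # eps_S only through mu_bar + eps_M[s] (+ eps_S[sp]), so the sampler
  # shifts mass along those flat directions with exact conjugate updates.
  # Without these the intercept mixes very slowly under the centered
  # parameterization.
  if (!"mu_bar" %in% fixed) {
    prec <- prior_prec_mu + md$n_stands / state$sigma_M^2
    mn <- (-state$mu_bar * prior_prec_mu +
             sum(state$eps_M) / state$sigma_M^2) / prec
    delta <- stats::rnorm(1, mn, sqrt(1 / prec))
    state$mu_bar <- state$mu_bar + delta
    state$eps_M <- state$eps_M - delta
    if (spec$has_species) {
      prec <- prior_prec_mu + md$n_species / state$sigma_S^2
      mn <- (-state$mu_bar * prior_prec_mu +
               sum(state$eps_S) / state$sigma_S^2) / prec
      delta <- stats::rnorm(1, mn, sqrt(1 / prec))
      state$mu_bar <- state$mu_bar + delta
      state$eps_S <- state$eps_S - delta
    }
  }
  if (spec$has_varying_sd && !"sigma_bar" %in% fixed &&
      !"eps_V" %in% fixed) {
    # same flat direction between log sigma_bar and the eps_V mean
    th <- log(state$sigma_bar)
    sV <- max(state$sigma_V, 1e-12)
    delta <- .slice1(0, function(d) {
      -exp(2 * (th + d)) / pscale2 + (th + d) -
        sum((state$eps_V - d)^2) / (2 * sV^2)
    }, w = 0.5)
    state$sigma_bar <- exp(th + delta)
    state$eps_V <- state$eps_V - delta
  }

  if (!"sigma_M" %in% fixed) {
    sse <- sum(state$eps_M^2)
    k <- md$n_stands
    state$sigma_M <- exp(.slice1(log(state$sigma_M), function(th) {
      -k * th - sse / (2 * exp(2 * th)) - exp(2 * th) / pscale2 + th
    }))
  }
  if (spec$has_species && !"sigma_S" %in% fixed) {
    sse <- sum(state$eps_S^2)
    k <- md$n_species
    state$sigma_S <- exp(.slice1(log(state$sigma_S), function(th) {
      -k * th - sse / (2 * exp(2 * th)) - exp(2 * th) / pscale2 + th
    }))
  }
  if (spec$has_varying_sd && !"sigma_V" %in% fixed) {
    sse <- sum(state$eps_V^2)
    k <- md$n_stands
    state$sigma_V <- exp(.slice1(log(state$sigma_V), function(th) {
      -k * th - sse / (2 * exp(2 * th)) - exp(2 * th) / pscale2 + th
    }))
  }

  mu_i <- state$mu_bar +
    (if (spec$has_origin) state$beta * md$origin else 0) +
    state$eps_M[md$stand] +
    (if (spec$has_species) state$eps_S[md$species] else 0)
  res2_by_stand <- rs$by_stand((y - mu_i)^2)

  if (spec$has_varying_sd && !"eps_V" %in% fixed) {
    sV <- max(state$sigma_V, 1e-12)
    lsb <- log(state$sigma_bar)
    for (s in seq_len(md$n_stands)) {
      ns <- md$n_per_stand[s]
      ss <- res2_by_stand[s]
      state$eps_V[s] <- .slice1(state$eps_V[s], function(e) {
        -ns * (lsb + e) - ss / (2 * exp(2 * (lsb + e))) -
          e^2 / (2 * sV^2)
      }, w = 0.5)
    }
  }
  if (!"sigma_bar" %in% fixed) {
    ssw <- if (spec$has_varying_sd)
      sum(res2_by_stand * exp(-2 * state$eps_V)) else sum(res2_by_stand)
    n <- md$n
    state$sigma_bar <- exp(.slice1(log(state$sigma_bar), function(th) {
      -n * th - ssw / (2 * exp(2 * th)) - exp(2 * th) / pscale2 + th
    }))
  }
  state
}

.state_vector <- function(state, spec, md) {
  out <- c(mu_bar = state$mu_bar)
  if (spec$has_origin) out <- c(out, beta = state$beta)
  out <- c(out, sigma_bar = state$sigma_bar, sigma_M = state$sigma_M)
  if (spec$has_varying_sd) out <- c(out, sigma_V = state$sigma_V)
  if (spec$has_species) out <- c(out, sigma_S = state$sigma_S)
  eM <- state$eps_M
  names(eM) <- sprintf("eps_M[%s]", md$stand_levels)
  out <- c(out, eM)
  if (spec$has_varying_sd) {
    eV <- state$eps_V
    names(eV) <- sprintf("eps_V[%s]", md$stand_levels)
    out <- c(out, eV)
  }
  if (spec$has_species) {
    eS <- state$eps_S
    names(eS) <- sprintf("eps_S[%s]", md$species_levels)
    out <- c(out, eS)
  }
  out
}

#' Fit a hierarchical model by MCMC
#'
#' Samples the posterior defined by [log_posterior()] with a Gibbs scheme:
#' exact conjugate normal updates for the location parameters (`mu_bar`,
#' `beta`, `eps_M`, `eps_S`) and univariate slice sampling for the SD
#' parameters and the per-stand log-SD effects `eps_V`. Runs `config$chains`
#' independent chains from jittered data-based starting points; warmup draws
#' are discarded. Fits are deterministic given the seed.
#'
#' @param spec a [model_spec].
#' @param table a censoring-filtered [sample_table].
#' @param config an [mcmc_config].
#' @param fixed optional named list of hyperparameters to hold fixed at the
#'   given values instead of sampling them (any of `mu_bar`, `beta`,
#'   `sigma_bar`, `sigma_M`, `sigma_V`, `sigma_S`). Useful for conjugate
#'   cross-checks where only the stand effects are unknown.
#' @return A `posterior_draws` object: per-chain draw matrices with named
#'   columns (`mu_bar`, `beta`, `sigma_bar`, `sigma_M`, `sigma_V`,
#'   `sigma_S`, `eps_M[stand]`, `eps_V[stand]`, `eps_S[species]` as the
#'   structure requires), plus the spec, config and a data fingerprint.
#' @export
fit_model <- function(spec, table, config = mcmc_config(), fixed = list()) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "mcmc_config"))
  md <- .model_data(table)
  md$n_per_stand <- tabulate(md$stand, md$n_stands)
  fixed_names <- names(fixed)
  bad <- setdiff(fixed_names, c("mu_bar", "beta", "sigma_bar", "sigma_M",
                                "sigma_V", "sigma_S"))
  if (length(bad)) stop("cannot fix unknown parameter(s): ",
                        paste(bad, collapse = ", "))

  stand_f <- factor(md$stand, levels = seq_len(md$n_stands))
  species_f <- factor(md$species, levels = seq_len(md$n_species))
  rs <- list(
    by_stand = function(x) as.numeric(rowsum(x, stand_f)),
    by_species = function(x) as.numeric(rowsum(x, species_f))
  )

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))

  stand_means <- rs$by_stand(md$y) / md$n_per_stand
  pooled_sd <- max(stats::sd(md$y - stand_means[md$stand]), 0.1)

  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + 104729L * ch)
    state <- list(
      mu_bar = if ("mu_bar" %in% fixed_names) fixed$mu_bar else
        mean(md$y) + stats::rnorm(1, 0, 0.5),
      beta = if ("beta" %in% fixed_names) fixed$beta else
        stats::rnorm(1, 0, 0.2),
      sigma_bar = if ("sigma_bar" %in% fixed_names) fixed$sigma_bar else
        pooled_sd * exp(stats::rnorm(1, 0, 0.2)),
      sigma_M = if ("sigma_M" %in% fixed_names) fixed$sigma_M else
        max(stats::sd(stand_means), 0.2) * exp(stats::rnorm(1, 0, 0.2)),
      sigma_V = if ("sigma_V" %in% fixed_names) fixed$sigma_V else 0.2,
      sigma_S = if ("sigma_S" %in% fixed_names) fixed$sigma_S else 0.5,
      eps_M = stats::rnorm(md$n_stands, 0, 0.1),
      eps_V = rep(0, md$n_stands),
      eps_S = rep(0, md$n_species)
    )
    total <- config$warmup + config$sampling
    first <- .state_vector(state, spec, md)
    draws <- matrix(NA_real_, config$sampling, length(first),
                    dimnames = list(NULL, names(first)))
    for (it in seq_len(total)) {
      state <- .gibbs_iteration(state, spec, md, fixed_names, rs)
      if (it > config$warmup) {
        draws[it - config$warmup, ] <- .state_vector(state, spec, md)
      }
    }
    chains[[ch]] <- draws
  }
  structure(list(chains = chains, spec = spec, config = config,
                 fixed = fixed,
                 data_fingerprint = list(n = md$n, n_stands = md$n_stands,
                                         n_species = md$n_species,
                                         sum_log = sum(md$y)),
                 stand_levels = md$stand_levels,
                 species_levels = md$species_levels),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %s: %d chains x %d draws, %d parameters\n",
              x$spec$name, length(x$chains), nrow(x$chains[[1]]),
              ncol(x$chains[[1]])))
  invisible(x)
}

#' Pool posterior draws into a single matrix
#'
#' @param x a `posterior_draws` object.
#' @param ... unused.
#' @return A matrix with one row per retained draw (chains stacked in
#'   order) and one named column per parameter.
#' @export
as.matrix.posterior_draws <- function(x, ...) {
  do.call(rbind, x$chains)
}

#' Split-R-hat convergence diagnostic
#'
#' The Gelman-Rubin potential scale reduction factor computed on split
#' chains: each chain is halved, and R-hat is the square root of the ratio
#' of the pooled-variance estimate `((n-1)/n) W + B/n` to the mean
#' within-half variance `W`. Values below 1.1 for every parameter are taken
#' as convergence. Parameters with zero variance everywhere (e.g. fixed
#' hyperparameters) report `NA`.
#'
#' @param draws a `posterior_draws` object with at least 2 chains and 4
#'   draws per chain.
#' @return Named numeric vector of R-hat values, with attribute
#'   `converged` (TRUE when all finite values are < 1.1).
#' @export
rhat <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (length(draws$chains) < 2L) {
    stop("R-hat requires at least 2 chains; refit with chains >= 2")
  }
  iter <- nrow(draws$chains[[1]])
  if (iter < 4L) stop("R-hat requires at least 4 draws per chain")
  half <- iter %/% 2L
  halves <- list()
  for (ch in draws$chains) {
    halves <- c(halves, list(ch[seq_len(half), , drop = FALSE],
                             ch[(iter - half + 1L):iter, , drop = FALSE]))
  }
  params <- colnames(draws$chains[[1]])
  out <- vapply(params, function(p) {
    mat <- vapply(halves, function(h) h[, p], numeric(half))
    means <- colMeans(mat)
    vars <- apply(mat, 2, stats::var)
    w <- mean(vars)
    b <- half * stats::var(means)
    if (w == 0) return(if (b == 0) NA_real_ else Inf)
    sqrt(((half - 1) / half * w + b / half) / w)
  }, numeric(1))
  finite <- out[is.finite(out)]
  attr(out, "converged") <- length(finite) > 0 && all(finite < 1.1)
  out
}

#' Posterior summary table
#'
#' Pooled-chain posterior mean, SD and empirical 2.5%/97.5% quantiles per
#' parameter, with split-R-hat appended when at least two chains are
#' available.
#'
#' @param draws a `posterior_draws` object.
#' @return A `data.frame` with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`, `rhat`.
#' @export
summarize_draws <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  mat <- as.matrix(draws)
  q <- t(apply(mat, 2, stats::quantile, probs = c(0.025, 0.975), type = 7,
               names = FALSE))
  r <- if (length(draws$chains) >= 2L && nrow(draws$chains[[1]]) >= 4L)
    as.numeric(rhat(draws)) else rep(NA_real_, ncol(mat))
  data.frame(parameter = colnames(mat),
             mean = colMeans(mat),
             sd = apply(mat, 2, stats::sd),
             q2.5 = q[, 1], q97.5 = q[, 2],
             rhat = r,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Species-effect posterior summaries
#'
#' Convenience extraction of the random species effects from a full-model
#' fit: posterior median and 90%/95% credible intervals per species, the
#' quantities shown in forest-plot style figures of species effects.
#'
#' @param draws a `posterior_draws` object from the `full` model.
#' @return A `data.frame` with columns `species`, `median`, `q5`, `q95`,
#'   `q2.5`, `q97.5`.
#' @export
species_effect_summary <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!draws$spec$has_species) {
    stop("model '", draws$spec$name, "' has no species effects")
  }
  mat <- as.matrix(draws)
  cols <- grep("^eps_S\\[", colnames(mat), value = TRUE)
  q <- t(apply(mat[, cols, drop = FALSE], 2, stats::quantile,
               probs = c(0.5, 0.05, 0.95, 0.025, 0.975), names = FALSE))
  data.frame(species = sub("^eps_S\\[(.*)\\]$", "\\1", cols),
             median = q[, 1], q5 = q[, 2], q95 = q[, 3],
             q2.5 = q[, 4], q97.5 = q[, 5],
             row.names = NULL, stringsAsFactors = FALSE)
}
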