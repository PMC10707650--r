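# log(sum(exp(x))) without overflow
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Pointwise log predictive density for a new stand
#'
#' Computes, for every posterior draw and every observation, the log
#' predictive density with the stand-level random effects integrated out —
#' the quantity WAIC needs when the prediction target is a *new* stand
#' rather than the stands that were sampled. Species effects and the origin
#' coefficient (present only in the full model) are conditioned on, since
#' the target is a new stand, not a new species.
#'
#' For the constant-SD structure the integral is closed-form:
#' `y_i ~ Normal(mu_base_i, sigma_bar^2 + sigma_M^2)` with
#' `mu_base_i = mu_bar + beta*O_i + eps_S[species_i]`. For the
#' heteroscedastic structure (`model2`) the pair `(eps_M, eps_V)` is
#' integrated by fresh Monte Carlo per posterior draw: `mc_samples`
#' standard-normal pairs are scaled by that draw's `(sigma_M, sigma_V)` and
#' averaged with log-mean-exp.
#'
#' @param draws a `posterior_draws` object from [fit_model()].
#' @param table the [sample_table] the model was fitted to.
#' @param mc_samples Monte Carlo points per draw for the heteroscedastic
#'   integral (>= 2).
#' @param seed RNG seed for the Monte Carlo integration.
#' @param method `"auto"` (closed form when the structure permits, MC
#'   otherwise), `"closed"`, or `"mc"` (force MC even for constant-SD
#'   models, e.g. to check the closed form).
#' @param thin keep every `thin`-th pooled posterior draw.
#' @return A matrix of class `pointwise_loglik`, draws in rows and
#'   observations in columns, with attributes `method`, `mc_samples`,
#'   `seed` and (for MC) `mc_rel_var`, the per-entry relative variance of
#'   the Monte Carlo density estimate used by [lppd_mc_se()].
#' @export
marginal_loglik <- function(draws, table, mc_samples = 1000L, seed = 1L,
                            method = c("auto", "closed", "mc"), thin = 1L) {
  stopifnot(inherits(draws, "posterior_draws"))
  method <- match.arg(method)
  spec <- draws$spec
  md <- .model_data(table)
  if (method == "closed" && spec$has_varying_sd) {
    stop("no closed-form stand-marginal for the heteroscedastic model")
  }
  if (method == "auto") {
    method <- if (spec$has_varying_sd) "mc" else "closed"
  }
  if (method == "mc" && mc_samples < 2L) {
    stop("mc_samples must be at least 2 for Monte Carlo integration")
  }
  mat <- as.matrix(draws)
  mat <- mat[seq(1L, nrow(mat), by = thin), , drop = FALSE]
  t_draws <- nrow(mat)

  mu_base <- matrix(mat[, "mu_bar"], t_draws, md$n)
  if (spec$has_origin) {
    mu_base <- mu_base + outer(mat[, "beta"], md$origin)
  }
  if (spec$has_species) {
    eps_s_cols <- sprintf("eps_S[%s]", md$species_levels)
    mu_base <- mu_base + mat[, eps_s_cols, drop = FALSE][, md$species,
                                                         drop = FALSE]
  }

  if (method == "closed") {
    sd_marg <- sqrt(mat[, "sigma_bar"]^2 + mat[, "sigma_M"]^2)
    ll <- stats::dnorm(matrix(md$y, t_draws, md$n, byrow = TRUE),
                       mu_base, sd_marg, log = TRUE)
    rel <- NULL
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    ll <- matrix(NA_real_, t_draws, md$n)
    rel <- matrix(NA_real_, t_draws, md$n)
    ymat_row <- matrix(md$y, mc_samples, md$n, byrow = TRUE)
    sigma_v_t <- if (spec$has_varying_sd) mat[, "sigma_V"] else
      rep(0, t_draws)
    for (t in seq_len(t_draws)) {
      z_m <- stats::rnorm(mc_samples) * mat[t, "sigma_M"]
      z_v <- stats::rnorm(mc_samples) * sigma_v_t[t]
      sd_k <- mat[t, "sigma_bar"] * exp(z_v)
      dev <- ymat_row - matrix(mu_base[t, ], mc_samples, md$n,
                               byrow = TRUE) - z_m
      ld <- -0.5 * (dev / sd_k)^2 - log(sd_k) - 0.5 * log(2 * pi)
      m <- apply(ld, 2, max)
      a <- exp(sweep(ld, 2, m))
      s1 <- colSums(a)
      s2 <- colSums(a^2)
      ll[t, ] <- m + log(s1 / mc_samples)
      # relative variance of the MC mean: var(p_hat)/p_hat^2
      rel[t, ] <- pmax(s2 / s1^2 - 1 / mc_samples, 0)
    }
  }
  structure(ll, class = c("pointwise_loglik", "matrix"),
            method = method, mc_samples = mc_samples, seed = seed,
            mc_rel_var = rel)
}

#' Widely applicable information criterion
#'
#' From a pointwise log predictive density matrix:
#' `lppd = sum_i log(mean_t exp(ll_ti))` (numerically stable log-sum-exp),
#' `p_waic = sum_i var_t(ll_ti)` (unbiased variance over draws), and
#' `WAIC = -2 (lppd - p_waic)` on the deviance scale, so smaller predicts
#' better.
#'
#' @param pll a `pointwise_loglik` matrix (or any draws x observations
#'   matrix of finite log densities) with at least 2 draws.
#' @return A list of class `waic_result` with elements `lppd`, `p_waic`,
#'   `waic`, and per-observation vectors `pointwise_lppd`,
#'   `pointwise_p`.
#' @export
waic <- function(pll) {
  pll <- unclass(pll)
  stopifnot(is.matrix(pll), nrow(pll) >= 2L)
  bad <- which(!is.finite(pll), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-finite log likelihood at draw %d, observation %d",
                 bad[1, 1], bad[1, 2]))
  }
  t_draws <- nrow(pll)
  lppd_i <- apply(pll, 2, .logsumexp) - log(t_draws)
  p_i <- apply(pll, 2, stats::var)
  lppd <- sum(lppd_i)
  p_waic <- sum(p_i)
  structure(list(lppd = lppd, p_waic = p_waic,
                 waic = -2 * (lppd - p_waic),
                 pointwise_lppd = lppd_i, pointwise_p = p_i),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("<waic_result> lppd = %.2f, p_waic = %.2f, WAIC = %.2f\n",
              x$lppd, x$p_waic, x$waic))
  invisible(x)
}

#' Monte Carlo standard error of the total lppd
#'
#' Delta-method standard error of `lppd` induced by the Monte Carlo
#' integration inside [marginal_loglik()] (zero for the closed form). Used
#' to check that MC-integrated and closed-form marginals agree within
#' simulation noise.
#'
#' @param pll a `pointwise_loglik` from [marginal_loglik()].
#' @return A single non-negative number.
#' @export
lppd_mc_se <- function(pll) {
  rel <- attr(pll, "mc_rel_var")
  if (is.null(rel)) return(0)
  ll <- unclass(pll)
  var_i <- vapply(seq_len(ncol(ll)), function(i) {
    m <- max(ll[, i])
    a <- exp(ll[, i] - m)
    sum(a^2 * rel[, i]) / sum(a)^2
  }, numeric(1))
  sqrt(sum(var_i))
}

#' Choose between the constant-SD and heteroscedastic models
#'
#' Applies the selection rule used in the survey analysis: when the WAIC
#' difference is within `tolerance` (a conventional noise scale, default 2),
#' the simpler model — the one with fewer variance components — is adopted;
#' otherwise the model with the smaller WAIC wins.
#'
#' @param waic_model1 [waic()] result for the constant-SD model.
#' @param waic_model2 [waic()] result for the heteroscedastic model.
#' @param tolerance WAIC difference treated as "small".
#' @return `"model1"` or `"model2"`, with attribute `delta`
#'   (`waic_model2$waic - waic_model1$waic`).
#' @export
select_model <- function(waic_model1, waic_model2, tolerance = 2) {
  stopifnot(inherits(waic_model1, "waic_result"),
            inherits(waic_model2, "waic_result"))
  delta <- waic_model2$waic - waic_model1$waic
  choice <- if (abs(delta) <= tolerance) "model1" else
    if (waic_model1$waic <= waic_model2$waic) "model1" else "model2"
  structure(choice, delta = delta)
}
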