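#' Conjugate posterior of a new stand's mean
#'
#' Given `n` log-scale measurements `y` from a previously unsampled stand
#' and population-level hyperparameters, the stand mean has the conjugate
#' normal posterior
#' `mu_n = (mu_bar/sigma_M^2 + sum(y)/sigma_bar^2) /
#'        (1/sigma_M^2 + n/sigma_bar^2)` and
#' `1/sigma_n^2 = 1/sigma_M^2 + n/sigma_bar^2`:
#' a precision-weighted compromise (shrinkage) between the population mean
#' and the stand's sample mean. With empty `y` the prior `(mu_bar,
#' sigma_M)` is returned.
#'
#' @param y numeric vector of log_e activities from the new stand (may be
#'   empty).
#' @param hyper a [hyperparams] with `sigma_bar > 0` and `sigma_M > 0`.
#' @return A list of class `new_stand_posterior` with elements `mu_n`,
#'   `sigma_n`, `n` and `hyper`.
#' @export
update_stand_posterior <- function(y, hyper) {
  stopifnot(inherits(hyper, "hyperparams"), hyper$sigma_bar > 0,
            hyper$sigma_M > 0)
  y <- as.numeric(y)
  n <- length(y)
  prec <- 1 / hyper$sigma_M^2 + n / hyper$sigma_bar^2
  mu_n <- (hyper$mu_bar / hyper$sigma_M^2 + sum(y) / hyper$sigma_bar^2) /
    prec
  structure(list(mu_n = mu_n, sigma_n = sqrt(1 / prec), n = n,
                 hyper = hyper),
            class = "new_stand_posterior")
}

#' Expected posterior mean of a new stand after n measurements
#'
#' The expectation of the shrinkage posterior mean when the stand's true
#' log-scale mean is `true_mu_s`:
#' `(mu_bar/sigma_M^2 + n*true_mu_s/sigma_bar^2) /
#'  (1/sigma_M^2 + n/sigma_bar^2)`.
#' With few measurements the value sits near the population mean; as `n`
#' grows it approaches the stand's true mean.
#'
#' @param n number of measurements (>= 0); vectorised.
#' @param true_mu_s true stand mean of log_e activity.
#' @param hyper a [hyperparams].
#' @return Numeric vector, one value per element of `n`.
#' @export
expected_stand_mean <- function(n, true_mu_s, hyper) {
  stopifnot(inherits(hyper, "hyperparams"), all(n >= 0))
  prec_prior <- 1 / hyper$sigma_M^2
  prec_data <- n / hyper$sigma_bar^2
  (hyper$mu_bar * prec_prior + true_mu_s * prec_data) /
    (prec_prior + prec_data)
}

#' Predictive SD of the next measurement after n measurements
#'
#' Log-scale standard deviation of the predictive distribution of a further
#' individual from the same stand,
#' `sqrt(sigma_bar^2 + 1/(1/sigma_M^2 + n/sigma_bar^2))`. It is strictly
#' decreasing in `n` and bounded below by the within-stand SD `sigma_bar`.
#'
#' @inheritParams expected_stand_mean
#' @return Numeric vector, one value per element of `n`.
#' @export
predictive_sd <- function(n, hyper) {
  stopifnot(inherits(hyper, "hyperparams"), all(n >= 0))
  sqrt(hyper$sigma_bar^2 +
         1 / (1 / hyper$sigma_M^2 + n / hyper$sigma_bar^2))
}

#' Prediction interval for the next measurement
#'
#' Normal interval `mu_n +/- z(level) * sqrt(sigma_bar^2 + sigma_n^2)` for
#' the log activity of one further individual, with linear-scale (Bq kg^-1)
#' bounds by exponentiation. When no `point` posterior is supplied the
#' prior-predictive interval after `n` hypothetical measurements centred on
#' the population mean is returned.
#'
#' @param n number of measurements already made (used when `point` is
#'   missing).
#' @param hyper a [hyperparams].
#' @param level coverage probability in (0, 1).
#' @param point optional [update_stand_posterior()] result giving the
#'   stand's actual posterior.
#' @return A list of class `predictive_distribution` with `mean`, `sd`,
#'   `lower_log`, `upper_log`, `lower_bq`, `upper_bq`, `level`.
#' @export
prediction_interval <- function(n, hyper, level = 0.95, point = NULL) {
  stopifnot(level > 0, level < 1)
  if (is.null(point)) {
    mean_log <- hyper$mu_bar
    sd_log <- predictive_sd(n, hyper)
  } else {
    stopifnot(inherits(point, "new_stand_posterior"))
    mean_log <- point$mu_n
    sd_log <- sqrt(hyper$sigma_bar^2 + point$sigma_n^2)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  lower <- mean_log - z * sd_log
  upper <- mean_log + z * sd_log
  structure(list(mean = mean_log, sd = sd_log,
                 lower_log = lower, upper_log = upper,
                 lower_bq = exp(lower), upper_bq = exp(upper),
                 level = level),
            class = "predictive_distribution")
}

#' Geometric standard deviation of a log-normal
#'
#' `exp(sigma_log)`: the multiplicative spread corresponding to a log-scale
#' SD (a log-scale SD of 0.74 is a geometric SD of about 2.1).
#'
#' @param sigma_log log-scale SD (>= 0); vectorised.
#' @return Numeric vector.
#' @export
geometric_sd <- function(sigma_log) {
  stopifnot(all(sigma_log >= 0))
  exp(sigma_log)
}

#' Fold change corresponding to a log-scale difference
#'
#' `exp(delta_log)`: a difference of -1 on the natural-log scale is a
#' 0.37-fold change on the linear scale.
#'
#' @param delta_log log-scale difference; vectorised.
#' @return Numeric vector.
#' @export
fold_change <- function(delta_log) {
  exp(delta_log)
}

#' Model-implied fraction of individuals below an activity threshold
#'
#' Under the log-normal model, the fraction of individuals in a stand with
#' activity below `threshold_bq` is
#' `Phi((ln threshold_bq - mu_s) / sigma_s)`. Useful against regulatory
#' limits such as 50 Bq kg^-1 for mushroom bed logs.
#'
#' @param mu_s stand mean of log_e activity.
#' @param sigma_s within-stand SD of log_e activity (> 0).
#' @param threshold_bq threshold in Bq kg^-1 (> 0).
#' @return Probability in (0, 1).
#' @export
prob_below_threshold <- function(mu_s, sigma_s, threshold_bq) {
  stopifnot(all(sigma_s > 0), all(threshold_bq > 0))
  stats::pnorm((log(threshold_bq) - mu_s) / sigma_s)
}

#' Sample-size curve for surveying a new stand
#'
#' For each candidate number of measurements `n`, the expected shrinkage
#' posterior mean of the stand (given its true mean) and the predictive SD
#' of a further individual. Supplying posterior `draws` instead of point
#' hyperparameters propagates posterior uncertainty: the expected value is
#' computed per draw and the 2.5%/97.5% quantiles form the uncertainty
#' band; with point hyperparameters the band is
#' `expected +/- z(level) * sigma_n`, the credible interval of the stand
#' mean after `n` measurements.
#'
#' @param n_range integer vector of candidate sample sizes.
#' @param true_mu_s assumed true stand mean of log_e activity.
#' @param hyper a [hyperparams] (point estimates); ignored when `draws`
#'   supplied.
#' @param draws optional `posterior_draws` from [fit_model()].
#' @param level band coverage probability.
#' @return A `data.frame` with columns `n`, `expected_mean_log`,
#'   `predictive_sd_log`, `lower`, `upper`, `expected_mean_bq`.
#' @export
sample_size_curve <- function(n_range, true_mu_s, hyper = NULL,
                              draws = NULL, level = 0.95) {
  stopifnot(length(n_range) >= 1, all(n_range >= 0),
            level > 0, level < 1)
  n_range <- as.integer(n_range)
  if (!is.null(draws)) {
    stopifnot(inherits(draws, "posterior_draws"))
    mat <- as.matrix(draws)
    per_n <- lapply(n_range, function(n) {
      prec_prior <- 1 / mat[, "sigma_M"]^2
      prec_data <- n / mat[, "sigma_bar"]^2
      ev <- (mat[, "mu_bar"] * prec_prior + true_mu_s * prec_data) /
        (prec_prior + prec_data)
      psd <- sqrt(mat[, "sigma_bar"]^2 + 1 / (prec_prior + prec_data))
      q <- stats::quantile(ev, probs = c((1 - level) / 2,
                                         1 - (1 - level) / 2),
                           type = 7, names = FALSE)
      c(mean(ev), mean(psd), q[1], q[2])
    })
    per_n <- do.call(rbind, per_n)
    out <- data.frame(n = n_range, expected_mean_log = per_n[, 1],
                      predictive_sd_log = per_n[, 2],
                      lower = per_n[, 3], upper = per_n[, 4])
  } else {
    stopifnot(inherits(hyper, "hyperparams"))
    ev <- expected_stand_mean(n_range, true_mu_s, hyper)
    psd <- predictive_sd(n_range, hyper)
    sigma_n <- sqrt(1 / (1 / hyper$sigma_M^2 +
                           n_range / hyper$sigma_bar^2))
    z <- stats::qnorm(1 - (1 - level) / 2)
    out <- data.frame(n = n_range, expected_mean_log = ev,
                      predictive_sd_log = psd,
                      lower = ev - z * sigma_n, upper = ev + z * sigma_n)
  }
  out$expected_mean_bq <- exp(out$expected_mean_log)
  out
}
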