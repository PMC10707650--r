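#' Configuration for the synthetic shoot-survey generator
#'
#' Defaults reproduce the structure of the Fukushima coppice survey the
#' models were built for: 40 stands, five hardwood species sampled with
#' strongly unequal frequencies (weights proportional to 184:111:86:30:7),
#' and population parameters set to the posterior means of the all-species
#' model (overall log mean 4.92, within-stand SD 0.74, between-stand SD 1.32,
#' species SD 0.62, origin effect -0.39, constant within-stand SD across
#' stands). Per-stand sample size defaults to 10 individuals, matching the
#' survey's average of roughly ten shoots per stand (about two species
#' sampled at five shoots each).
#'
#' @param n_stands number of stands.
#' @param per_stand_n individuals per stand; a single count or a vector of
#'   length `n_stands`.
#' @param species_pool named numeric vector of species sampling weights
#'   (normalised internally).
#' @param origin_prob probability that a stem is of plantation origin
#'   (remainder are coppice sprouts).
#' @param truth a [hyperparams] giving the generating parameters.
#' @param detection_limit activity (Bq kg^-1) below which a record is marked
#'   censored, or `NULL` for no censoring. See [detection_limit_quantile()].
#' @param seed integer RNG seed; generation is reproducible from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_stands = 40,
                             per_stand_n = 10,
                             species_pool = c(Q_serrata = 184,
                                              C_jamasakura = 111,
                                              C_crenata = 86,
                                              Q_acutissima = 30,
                                              Z_serrata = 7),
                             origin_prob = 0.5,
                             truth = hyperparams(mu_bar = 4.92,
                                                 sigma_bar = 0.74,
                                                 sigma_M = 1.32,
                                                 sigma_V = 0,
                                                 sigma_S = 0.62,
                                                 beta = -0.39),
                             detection_limit = NULL,
                             seed = 1L) {
  stopifnot(n_stands >= 1, all(per_stand_n >= 1),
            origin_prob >= 0, origin_prob <= 1,
            inherits(truth, "hyperparams"),
            is.null(detection_limit) || detection_limit > 0)
  if (is.null(names(species_pool)) || any(!nzchar(names(species_pool)))) {
    stop("species_pool must be a named vector of weights")
  }
  if (any(species_pool < 0) || sum(species_pool) <= 0) {
    stop("species_pool weights must be non-negative and sum to > 0")
  }
  if (!length(per_stand_n) %in% c(1L, n_stands)) {
    stop("per_stand_n must be length 1 or n_stands")
  }
  structure(list(n_stands = as.integer(n_stands),
                 per_stand_n = as.integer(per_stand_n),
                 species_pool = species_pool / sum(species_pool),
                 origin_prob = origin_prob,
                 truth = truth,
                 detection_limit = detection_limit,
                 seed = as.integer(seed),
                 rng_kind = "Mersenne-Twister"),
            class = "generator_config")
}

#' Generate a synthetic sample table
#'
#' Draws data from exactly the process the models assume. For individual
#' `i` in stand `s` of species `sp`:
#' `log_e(activity) ~ Normal(mu_bar + beta*O_i + eps_M[s] + eps_S[sp],
#' sigma_s^2)` with `sigma_s = sigma_bar * exp(eps_V[s])`, where
#' `eps_M[s] ~ N(0, sigma_M^2)`, `eps_V[s] ~ N(0, sigma_V^2)` and
#' `eps_S[sp] ~ N(0, sigma_S^2)` (a single species effect per species,
#' crossed with stands). Setting `sigma_V = 0` gives the constant-SD
#' process. Records with activity below `detection_limit` are marked
#' censored (the simulated value is retained in the table, as a lab would
#' retain a trace reading, but flagged unusable).
#'
#' @param config a [generator_config].
#' @return A list with `table` (a [sample_table]) and `truth` (a list with
#'   the generating `hyperparams`, per-stand `eps_M`/`eps_V`, per-species
#'   `eps_S`, and RNG metadata).
#' @export
generate_samples <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  tr <- config$truth
  n_per <- rep_len(config$per_stand_n, config$n_stands)
  if (sum(n_per) < 1) stop("configuration generates zero individuals")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed, kind = config$rng_kind)

  stands <- sprintf("S%02d", seq_len(config$n_stands))
  species_names <- names(config$species_pool)
  eps_M <- stats::rnorm(config$n_stands, 0, tr$sigma_M)
  eps_V <- if (tr$sigma_V > 0)
    stats::rnorm(config$n_stands, 0, tr$sigma_V) else
    rep(0, config$n_stands)
  eps_S <- if (tr$sigma_S > 0)
    stats::rnorm(length(species_names), 0, tr$sigma_S) else
    rep(0, length(species_names))
  names(eps_S) <- species_names

  stand_idx <- rep(seq_len(config$n_stands), times = n_per)
  n <- length(stand_idx)
  sp_idx <- sample.int(length(species_names), n, replace = TRUE,
                       prob = config$species_pool)
  origin <- stats::rbinom(n, 1L, config$origin_prob)
  mu <- tr$mu_bar + tr$beta * origin + eps_M[stand_idx] + eps_S[sp_idx]
  sigma <- tr$sigma_bar * exp(eps_V[stand_idx])
  activity <- exp(stats::rnorm(n, mu, sigma))
  censored <- if (!is.null(config$detection_limit))
    activity < config$detection_limit else rep(FALSE, n)

  table <- sample_table(stand_id = stands[stand_idx],
                        species = species_names[sp_idx],
                        origin = origin, activity = activity,
                        censored = censored,
                        provenance = sprintf(
                          "synthetic survey (seed %d, %s)", config$seed,
                          config$rng_kind))
  truth <- list(hyper = tr, eps_M = stats::setNames(eps_M, stands),
                eps_V = stats::setNames(eps_V, stands), eps_S = eps_S,
                seed = config$seed, rng_kind = config$rng_kind)
  list(table = table, truth = truth)
}

#' Detection limit giving a target censored fraction
#'
#' Computes, by large-sample simulation from the configured generating
#' process, the activity quantile below which a fraction `p` of individuals
#' falls. Used to emulate surveys where a known share of samples (about 7.7%
#' in the motivating survey) fell below detection.
#'
#' @param config a [generator_config] (its `detection_limit` is ignored).
#' @param p target censored fraction.
#' @param nsim number of simulated individuals used to estimate the
#'   marginal activity distribution.
#' @param seed RNG seed for the quantile simulation.
#' @return Activity in Bq kg^-1.
#' @export
detection_limit_quantile <- function(config, p = 0.077, nsim = 2e5,
                                     seed = config$seed + 1L) {
  stopifnot(inherits(config, "generator_config"), p > 0, p < 1)
  tr <- config$truth
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed, kind = config$rng_kind)
  # marginal over stands, species and origin: every individual gets fresh
  # stand/species effects, which is exactly the marginal distribution
  eps_S <- if (tr$sigma_S > 0) stats::rnorm(nsim, 0, tr$sigma_S) else 0
  eps_M <- stats::rnorm(nsim, 0, tr$sigma_M)
  eps_V <- if (tr$sigma_V > 0) stats::rnorm(nsim, 0, tr$sigma_V) else 0
  origin <- stats::rbinom(nsim, 1L, config$origin_prob)
  mu <- tr$mu_bar + tr$beta * origin + eps_M + eps_S
  y <- stats::rnorm(nsim, mu, tr$sigma_bar * exp(eps_V))
  as.numeric(stats::quantile(exp(y), probs = p, type = 7, names = FALSE))
}

#' Write a generated dataset to disk
#'
#' Emits the CSV dialect [read_samples] reads plus a JSON file with the
#' generating truth (hyperparameters, latent effects, seed and RNG kind).
#'
#' @param sim result of [generate_samples].
#' @param csv_path output CSV path.
#' @param truth_path output JSON path (default: `csv_path` with
#'   `_truth.json`).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_simulation <- function(sim, csv_path,
                             truth_path = sub("\\.csv$", "_truth.json",
                                              csv_path)) {
  write_samples(sim$table, csv_path)
  truth <- sim$truth
  truth$hyper <- unclass(truth$hyper)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv_path, truth = truth_path))
}
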