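test_that("fits are deterministic given the seed", {
  sim <- generate_samples(model1_config(n_stands = 6, per_stand_n = 5,
                                        seed = 3))
  cfg <- quick_mcmc(seed = 8, warmup = 50, sampling = 60)
  f1 <- fit_model(model_spec("model1"), sim$table, cfg)
  f2 <- fit_model(model_spec("model1"), sim$table, cfg)
  expect_identical(f1$chains, f2$chains)
  f3 <- fit_model(model_spec("model1"), sim$table,
                  quick_mcmc(seed = 9, warmup = 50, sampling = 60))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("MCMC with fixed hyperparameters matches the conjugate posterior", {
  set.seed(41)
  hy <- hyperparams(mu_bar = 4.92, sigma_bar = 0.74, sigma_M = 1.33)
  y <- rnorm(7, log(30), 0.74)
  tab <- sample_table(rep("S1", 7), rep("oak", 7), rep(0, 7), exp(y))
  fit <- fit_model(model_spec("model1"), tab,
                   quick_mcmc(seed = 5, warmup = 100, sampling = 2000),
                   fixed = list(mu_bar = hy$mu_bar,
                                sigma_bar = hy$sigma_bar,
                                sigma_M = hy$sigma_M))
  m <- as.matrix(fit)
  mu_s <- m[, "mu_bar"] + m[, "eps_M[S1]"]
  oracle <- update_stand_posterior(y, hy)
  n_draws <- length(mu_s)
  # with hyperparameters fixed the Gibbs draws are iid from the exact
  # conditional, so the MC standard error of the mean is sigma_n/sqrt(T)
  expect_equal(mean(mu_s), oracle$mu_n,
               tolerance = 3 * oracle$sigma_n / sqrt(n_draws) /
                 abs(oracle$mu_n))
  expect_equal(sd(mu_s), oracle$sigma_n, tolerance = 0.05)
})

test_that("fit with effectively flat priors recovers the sample mean", {
  set.seed(6)
  y <- rnorm(20, 3, 0.5)
  tab <- sample_table(rep("S1", 20), rep("oak", 20), rep(0, 20), exp(y))
  fit <- fit_model(model_spec("model1"), tab,
                   quick_mcmc(seed = 2, warmup = 200, sampling = 1500),
                   fixed = list(mu_bar = 0, sigma_M = 1e4,
                                sigma_bar = 0.5))
  m <- as.matrix(fit)
  mu_s <- m[, "mu_bar"] + m[, "eps_M[S1]"]
  expect_equal(mean(mu_s), mean(y), tolerance = 0.02)
})

test_that("split R-hat separates converged from disjoint chains", {
  set.seed(12)
  same <- fake_draws(list(
    matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("a", "b"))),
    matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("a", "b")))))
  r <- rhat(same)
  expect_true(all(abs(r - 1) < 0.02))
  expect_true(attr(r, "converged"))

  apart <- fake_draws(list(
    matrix(rnorm(1000, 0), 1000, 1, dimnames = list(NULL, "a")),
    matrix(rnorm(1000, 10), 1000, 1, dimnames = list(NULL, "a"))))
  r2 <- rhat(apart)
  expect_true(r2["a"] > 3)
  expect_false(attr(r2, "converged"))

  # the convergence threshold is 1.1
  drifting <- fake_draws(list(
    matrix(rnorm(1000, 0) + seq(0, 3, length.out = 1000), 1000, 1,
           dimnames = list(NULL, "a")),
    matrix(rnorm(1000, 0) + seq(0, 3, length.out = 1000), 1000, 1,
           dimnames = list(NULL, "a"))))
  r3 <- rhat(drifting)
  expect_true(r3["a"] >= 1.1)
  expect_false(attr(r3, "converged"))
})

test_that("R-hat rejects single chains and is affine-invariant", {
  single <- fake_draws(list(matrix(rnorm(100), 100, 1,
                                   dimnames = list(NULL, "a"))))
  expect_error(rhat(single), "2 chains")

  set.seed(3)
  ch <- lapply(1:3, function(i) matrix(rnorm(500, i * 0.1), 500, 1,
                                       dimnames = list(NULL, "a")))
  r_raw <- rhat(fake_draws(ch))
  ch_t <- lapply(ch, function(m) m * -7.5 + 2)
  r_t <- rhat(fake_draws(ch_t))
  expect_equal(unname(r_raw["a"]), unname(r_t["a"]))
})

test_that("posterior summaries match known distributions", {
  const <- fake_draws(list(matrix(3.2, 50, 1, dimnames = list(NULL, "c")),
                           matrix(3.2, 50, 1, dimnames = list(NULL, "c"))))
  s <- summarize_draws(const)
  expect_equal(s$mean, 3.2)
  expect_equal(s$sd, 0)
  expect_equal(s$q2.5, 3.2)
  expect_equal(s$q97.5, 3.2)

  set.seed(14)
  norm <- fake_draws(list(
    matrix(rnorm(2e5), ncol = 1, dimnames = list(NULL, "z")),
    matrix(rnorm(2e5), ncol = 1, dimnames = list(NULL, "z"))))
  s2 <- summarize_draws(norm)
  expect_equal(s2$mean, 0, tolerance = 0.01)
  expect_equal(s2$q2.5, -1.96, tolerance = 0.02)
  expect_equal(s2$q97.5, 1.96, tolerance = 0.02)

  # invariant to chain concatenation order
  flipped <- fake_draws(rev(norm$chains))
  expect_equal(summarize_draws(flipped)$mean, s2$mean)
})

test_that("posterior SD of sigma_bar shrinks as sample size grows", {
  sds <- vapply(c(100, 400, 1600), function(n_total) {
    sim <- generate_samples(model1_config(n_stands = 20,
                                          per_stand_n = n_total / 20,
                                          seed = 19))
    fit <- fit_model(model_spec("model1"), sim$table,
                     quick_mcmc(seed = 4, warmup = 200, sampling = 300))
    s <- summarize_draws(fit)
    s$sd[s$parameter == "sigma_bar"]
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("species effects are summarised per species from the full model", {
  sim <- generate_samples(generator_config(n_stands = 12, per_stand_n = 8,
                                           seed = 27))
  fit <- fit_model(model_spec("full"), sim$table,
                   quick_mcmc(seed = 3, warmup = 150, sampling = 200))
  se <- species_effect_summary(fit)
  expect_setequal(se$species, unique(sim$table$species))
  expect_true(all(se$q2.5 <= se$median & se$median <= se$q97.5))
  expect_true(all(se$q5 >= se$q2.5 & se$q95 <= se$q97.5))

  fit1 <- fit_model(model_spec("model1"), sim$table,
                    quick_mcmc(seed = 3, warmup = 50, sampling = 60))
  expect_error(species_effect_summary(fit1), "no species effects")
})
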