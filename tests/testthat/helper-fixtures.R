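# Shared fixtures: everything is built in code at test time.

# small deterministic table: 2 stands, 2 species, known activities
toy_table <- function() {
  sample_table(
    stand_id = c("A", "A", "A", "B", "B", "B"),
    species = c("oak", "oak", "cherry", "oak", "cherry", "cherry"),
    origin = c(0, 1, 0, 0, 1, 0),
    activity = c(10, 20, 15, 100, 250, 80)
  )
}

# single-species homoscedastic generating process (model1's own process)
model1_config <- function(n_stands = 40, per_stand_n = 10, seed = 1,
                          sigma_V = 0,
                          mu_bar = 5.6, sigma_bar = 0.74, sigma_M = 1.1) {
  generator_config(
    n_stands = n_stands, per_stand_n = per_stand_n,
    species_pool = c(Q_serrata = 1), origin_prob = 0,
    truth = hyperparams(mu_bar = mu_bar, sigma_bar = sigma_bar,
                        sigma_M = sigma_M, sigma_V = sigma_V),
    seed = seed
  )
}

# short chains for tests; long enough for stable summaries of toy problems
quick_mcmc <- function(seed = 1, chains = 2, warmup = 300, sampling = 400) {
  mcmc_config(chains = chains, warmup = warmup, sampling = sampling,
              seed = seed)
}

# hand-built posterior_draws object (for diagnostics/WAIC unit tests)
fake_draws <- function(chains, spec_name = "model1") {
  structure(list(chains = chains, spec = model_spec(spec_name),
                 config = NULL, fixed = list(),
                 data_fingerprint = NULL,
                 stand_levels = NULL, species_levels = NULL),
            class = "posterior_draws")
}
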