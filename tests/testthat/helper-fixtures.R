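# shared fixtures, all generated in code

age_grid <- seq(0, 4, by = 0.01)

# logistic hominin-brain-volume-like curve, SD-scaled for use in rate models
brain_fixture <- function(scale = TRUE)
  new_predictor_curve(age_grid, 500 + 1000 / (1 + exp((age_grid - 2) / 0.45)),
                      scale = scale)

# a linearly increasing covariate on the standard grid
linear_curve_fixture <- function(scale = FALSE)
  new_predictor_curve(age_grid, age_grid, scale = scale)

# small constant-rate fossil record
record_fixture <- function(seed = 11, n = 40, mu0 = 0.25, q = 2,
                           lambda0 = 0.25) {
  simulate_fossil_record(sim_config(
    seed = seed, n_species_target = n, lambda0 = lambda0,
    mu_model = mu_constant(mu0), q = q, age_error_width = 0.3))
}

# deterministic lineage-history table (no simulation)
histories_fixture <- function() {
  data.frame(species = c("a", "b", "c"),
             s = c(3.5, 2.8, 4.0), e = c(1.2, 0.0, 0.6),
             n = c(3L, 2L, 5L), extant = c(FALSE, TRUE, FALSE),
             age_max_obs = c(3.0, 2.5, 3.8), age_min_obs = c(1.5, 0.4, 0.9))
}

# fast MCMC profile for structural tests
quick_mcmc <- function(seed = 1, n_iter = 1200, ti = 4)
  mcmc_config(n_iter = n_iter, thin = 5, seed = seed, ti_categories = ti,
              burnin = 0.2)

extdata <- function(f) system.file("extdata", f, package = "paleocarn")
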