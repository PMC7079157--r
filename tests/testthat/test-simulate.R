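test_that("fossil simulation is byte-identical under a fixed seed", {
  a <- record_fixture(seed = 5)
  b <- record_fixture(seed = 5)
  expect_identical(a, b)
  c <- record_fixture(seed = 6)
  expect_false(identical(a$occurrences, c$occurrences))
})

test_that("occurrence intervals contain true ages inside lineage spans", {
  r <- record_fixture(seed = 7, n = 50)
  to <- r$truth_occurrences
  expect_true(all(to$age_min <= to$true_age + 1e-12))
  expect_true(all(to$true_age <= to$age_max + 1e-12))
  spans <- r$truth[match(to$species, r$truth$species), ]
  expect_true(all(to$true_age <= spans$s + 1e-12))
  expect_true(all(to$true_age >= spans$e - 1e-12))
  # the observable table never reveals the latent truth
  expect_false(any(c("true_age", "s", "e") %in% names(r$occurrences)))
})

test_that("zero extinction with a closed window leaves every lineage extant", {
  r <- simulate_fossil_record(sim_config(
    seed = 2, n_species_target = 20, lambda0 = 0.1,
    mu_model = mu_constant(1e-9), q = 2))
  expect_true(all(r$occurrences$extant))
  expect_true(all(r$truth$e == 0))
})

test_that("occurrence counts follow the Poisson preservation mean", {
  # near-saturating preservation on a single full-window lineage
  r <- simulate_fossil_record(sim_config(
    seed = 3, n_species_target = 1, lambda0 = 1e-9,
    mu_model = mu_constant(1e-9), q = 1000, window = c(2, 0)))
  n <- r$truth$n[1]
  expect_lt(abs(n - 2000), 3 * sqrt(2000))

  # Monte-Carlo oracle: under plain ("thinned") Poisson preservation, the
  # mean occurrence count over all lineages equals q x mean lifespan
  tot_n <- 0; tot_d <- 0
  for (i in 1:50) {
    ri <- simulate_fossil_record(sim_config(
      seed = 1000 + i, n_species_target = 40, lambda0 = 0.3,
      mu_model = mu_constant(0.2), q = 2), preservation = "thinned")
    tot_n <- tot_n + sum(ri$truth_all$n)
    tot_d <- tot_d + sum(ri$truth_all$s - ri$truth_all$e)
  }
  expect_lt(abs(tot_n / (2 * tot_d) - 1), 0.05)
})

test_that("degenerate windows and unsampleable records raise errors", {
  expect_error(sim_config(window = c(0, 4)))
  cfg <- sim_config(seed = 1, n_species_target = 2, lambda0 = 1e-9,
                    mu_model = mu_constant(30), q = 1e-4)
  expect_error(simulate_fossil_record(cfg, preservation = "thinned",
                                      max_rejections = 5), "empty record")
})

test_that("proxy simulation honours its noise and dating contracts", {
  f <- function(t) 3 * t - 1
  m <- simulate_proxy(f, n_points = 9, dating_half_width = 0, noise_sd = 0,
                      seed = 1)
  expect_equal(m$value, f(m$true_age), tolerance = 1e-12)
  expect_equal(m$age_min, m$age_max)
  expect_error(simulate_proxy(f, 9, dating_half_width = -0.1), "negative")

  # law of large numbers on a constant curve
  m2 <- simulate_proxy(function(t) rep(7, length(t)), n_points = 1e4,
                       dating_half_width = 0.1, noise_sd = 1, seed = 2)
  expect_lt(abs(mean(m2$value) - 7), 3 / 100)

  # brain-volume-like linear growth hits its stated endpoints
  m3 <- simulate_proxy(function(t) 500 + 250 * (4 - t), n_points = 5,
                       dating_half_width = 0, noise_sd = 0, seed = 3)
  expect_equal(m3$value[m3$true_age == 4], 500)
  expect_equal(m3$value[m3$true_age == 0], 1500)
})

test_that("spatial grid generator reproduces its own regression truth", {
  # lambda = 0, no noise: y is exactly X beta
  cfg <- sim_config(seed = 5, grid_dims = c(6, 6), beta_true = c(1, -2),
                    sar_lambda_true = 0, noise_sd = 0)
  ds <- simulate_spatial_grid(cfg)
  X <- as.matrix(as.data.frame(ds)[c("x1", "x2")])
  expect_equal(ds$fraction_large, unname(drop(X %*% c(1, -2))),
               tolerance = 1e-12)

  # all-zero configuration gives an identically zero response
  cfg0 <- sim_config(seed = 5, grid_dims = c(6, 6), beta_true = c(0, 0),
                     sar_lambda_true = 0, noise_sd = 0)
  ds0 <- simulate_spatial_grid(cfg0)
  expect_true(all(ds0$fraction_large == 0))
})

test_that("OLS on SAR-error data is unbiased for beta across seeds", {
  beta_true <- c(-0.3, 0, -0.3)
  est <- t(vapply(1:200, function(i) {
    ds <- simulate_spatial_grid(sim_config(
      seed = 7000 + i, grid_dims = c(10, 10), beta_true = beta_true,
      sar_lambda_true = 0.5, noise_sd = 0.5))
    # undo the response standardisation to compare on the generative scale
    fit_linear(ds)$coefficients[-1] * attr(ds, "scale")[["fraction_large"]]
  }, numeric(3)))
  mc_se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est) - beta_true) < 2 * mc_se + 1e-8))
})
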