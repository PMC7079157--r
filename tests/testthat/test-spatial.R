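test_that("build_grid computes large-carnivore fractions and drops empties", {
  cells <- behrmann_cells(3, 2)
  cells$precip <- rnorm(6); cells$temp <- rnorm(6)
  sp <- paste0("sp", 1:10)
  mass <- setNames(c(rep(50, 3), rep(5, 7)), sp)  # 3 large, 7 small
  presence <- matrix(0, 6, 10, dimnames = list(NULL, sp))
  presence[1, ] <- 1                    # all 10 species: fraction 0.3
  presence[2, 1:3] <- 1                 # all large: fraction 1
  presence[3, 4:5] <- 1                 # all small: fraction 0
  presence[4, c(1, 4)] <- 1             # 1 of 2: 0.5
  presence[5, c(2, 5)] <- 1
  # row 6 empty: dropped
  ds <- build_grid(presence, mass, cells, predictors = c("precip", "temp"))
  expect_equal(nrow(ds), 5)
  expect_equal(ds$fraction_large, c(0.3, 1, 0, 0.5, 0.5))
  expect_equal(attr(ds, "n_dropped_empty"), 1)
  z <- as.data.frame(ds)[c("z_precip", "z_temp")]
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_true(all(abs(vapply(z, sd, 0) - 1) < 1e-10))
})

test_that("Behrmann cells at one-degree column width are about 9000 km2", {
  bc <- behrmann_cells(20, 4)
  expect_true(all(abs(bc$area_km2 - 9000) / 9000 < 0.15))
  # equal-area: all cells agree to numerical precision
  expect_lt(diff(range(bc$area_km2)), 1e-6)
})

test_that("OLS recovers a deterministic predictor exactly", {
  cells <- behrmann_cells(6, 6)
  set.seed(2)
  cells$x1 <- rnorm(36)
  cells$fraction_large <- 2 * cells$x1 + 5
  ds <- new_spatial_dataset(cells, predictors = "x1")
  f <- suppressWarnings(fit_linear(ds))  # lm warns on an exact fit
  expect_equal(unname(f$coefficients["x1"]), 1, tolerance = 1e-10)
  expect_equal(f$pseudo_r2, 1, tolerance = 1e-10)
})

test_that("OLS type-I error is calibrated on independent noise", {
  hits <- 0
  for (i in 1:100) {
    ds <- simulate_spatial_grid(sim_config(
      seed = 5000 + i, grid_dims = c(8, 8), beta_true = c(0, 0, 0),
      sar_lambda_true = 0, noise_sd = 1))
    f <- fit_linear(ds)
    if (all(abs(f$coefficients[-1]) < 3 * f$se[-1])) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("SAR-error with lambda fixed at zero reproduces OLS exactly", {
  ds <- simulate_spatial_grid(sim_config(seed = 71, grid_dims = c(8, 8),
                                         sar_lambda_true = 0.4, noise_sd = 0.5))
  ols <- fit_linear(ds)
  sar0 <- fit_sar_error(ds, attr(ds, "W"), fix_lambda = 0)
  expect_equal(sar0$coefficients, ols$coefficients, tolerance = 1e-8)
  expect_equal(sar0$pseudo_r2, ols$pseudo_r2, tolerance = 1e-8)
})

test_that("SAR fit on uncorrelated data stays near lambda = 0", {
  ds <- simulate_spatial_grid(sim_config(seed = 72, grid_dims = c(10, 10),
                                         sar_lambda_true = 0, noise_sd = 0.5))
  W <- attr(ds, "W")
  f <- fit_sar_error(ds, W)
  expect_lt(abs(f$sar_lambda), 2 * f$lambda_se + 0.05)
  # optimised likelihood can never fall below the lambda = 0 profile
  f0 <- fit_sar_error(ds, W, fix_lambda = 0)
  expect_gte(f$loglik, f0$loglik - 1e-9)
})

test_that("standardised fits are invariant to affine predictor rescaling", {
  cells <- behrmann_cells(7, 7)
  set.seed(3)
  cells$a <- rnorm(49); cells$b <- rnorm(49)
  cells$fraction_large <- 0.4 * cells$a - 0.2 * cells$b + rnorm(49, 0, 0.3)
  ds1 <- new_spatial_dataset(cells, predictors = c("a", "b"))
  cells2 <- cells
  cells2$a <- 100 * cells2$a - 7
  cells2$b <- cells2$b / 3 + 2
  ds2 <- new_spatial_dataset(cells2, predictors = c("a", "b"))
  f1 <- fit_linear(ds1); f2 <- fit_linear(ds2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  f1s <- fit_sar_error(ds1, spatial_weights(ds1, neighborhood_candidates()[[4]]))
  f2s <- fit_sar_error(ds2, spatial_weights(ds2, neighborhood_candidates()[[4]]))
  expect_equal(f1s$coefficients, f2s$coefficients, tolerance = 1e-8)
  expect_equal(f1s$sar_lambda, f2s$sar_lambda, tolerance = 1e-8)
})

test_that("the candidate roster enumerates exactly forty neighbourhoods", {
  cand <- neighborhood_candidates()
  expect_length(cand, 40)
  kinds <- vapply(cand, `[[`, "", "kind")
  expect_equal(sum(kinds == "knn"), 10)
  expect_equal(sum(kinds == "band"), 30)
  labels <- vapply(cand, `[[`, "", "label")
  expect_equal(anyDuplicated(labels), 0L)
})

test_that("weighting schemes satisfy their normalisation identities", {
  ds <- simulate_spatial_grid(sim_config(seed = 73, grid_dims = c(6, 6)))
  spec <- structure(list(kind = "band", cutoff = 250, scheme = "B",
                         label = "b"), class = "nb_spec")
  A <- spatial_weights(ds, spec)
  n_ok <- sum(rowSums(A) > 0)
  for (sch in c("W", "C", "U", "S")) {
    spec$scheme <- sch
    W <- spatial_weights(ds, spec)
    if (sch == "W") expect_true(all(abs(rowSums(W)[rowSums(A) > 0] - 1) < 1e-12))
    if (sch == "C") expect_equal(sum(W), n_ok, tolerance = 1e-9)
    if (sch == "U") expect_equal(sum(W), 1, tolerance = 1e-9)
    if (sch == "S") expect_equal(sum(W), n_ok, tolerance = 1e-9)
  }
})

test_that("neighbourhood selection is deterministic and tie-break stable", {
  ds <- simulate_spatial_grid(sim_config(seed = 74, grid_dims = c(7, 7),
                                         sar_lambda_true = 0.5, noise_sd = 0.5))
  one <- neighborhood_candidates()[4]
  sel1 <- select_neighborhood(ds, one)
  expect_equal(sel1$best$label, one[[1]]$label)
  dup <- c(one, one)
  sel2 <- suppressWarnings(select_neighborhood(ds, dup))
  expect_equal(sel2$best$label, sel1$best$label)
  # scalar-multiple schemes tie in AIC; the earlier spec order wins
  full <- suppressWarnings(select_neighborhood(ds))
  expect_lte(nrow(full$table), 40)
  expect_equal(full$table$aic, sort(full$table$aic))
})

test_that("a nearest-neighbour generating process is detected by the search", {
  wins <- 0
  for (i in 1:10) {
    cfg <- sim_config(seed = 7600 + i, grid_dims = c(8, 8),
                      sar_lambda_true = 0.65, noise_sd = 0.4)
    cells <- behrmann_cells(8, 8)
    fake <- cells; fake$fraction_large <- 0; fake$x1 <- rnorm(64)
    base <- new_spatial_dataset(fake, predictors = "x1")
    Wk <- spatial_weights(base, structure(list(kind = "knn", k = 4,
                                               scheme = "W", label = "knn04"),
                                          class = "nb_spec"))
    ds <- simulate_spatial_grid(cfg, W = Wk)
    sel <- suppressWarnings(select_neighborhood(
      ds, neighborhood_candidates()[c(1:6, 11, 16, 21)]))
    if (sel$best$kind == "knn" && sel$best$k <= 6) wins <- wins + 1
  }
  expect_gte(wins, 6)
})

test_that("back-casting anchors and composes predictor contributions", {
  cells <- behrmann_cells(6, 6)
  set.seed(5)
  cells$precip <- rnorm(36, 1000, 100)
  cells$temp <- rnorm(36, 24, 2)
  cells$fraction_large <- 0.3 - 0.001 * (cells$precip - 1000) +
    rnorm(36, 0, 0.02)
  ds <- new_spatial_dataset(cells, predictors = c("precip", "temp"))
  fit <- fit_linear(ds)
  grid <- seq(0, 4, 0.1)

  # constant palaeo curves: flat line exactly at the anchor
  flat <- list(precip = new_predictor_curve(grid, rep(900, length(grid))),
               temp = new_predictor_curve(grid, rep(23, length(grid))))
  bc <- backcast_fraction(fit, flat, ds, anchor = c(4, 0.42), grid = grid)
  expect_equal(bc$predicted, rep(0.42, length(grid)))

  # zero coefficients: flat at the anchor whatever the curves do
  fit0 <- fit
  fit0$coefficients[] <- 0
  wavy <- list(precip = new_predictor_curve(grid, 900 + 100 * sin(grid)),
               temp = new_predictor_curve(grid, 23 + grid))
  bc0 <- backcast_fraction(fit0, wavy, ds, anchor = c(4, 0.42), grid = grid)
  expect_equal(bc0$predicted, rep(0.42, length(grid)))

  # a single active predictor back-casts its standardised trajectory
  bc1 <- backcast_fraction(fit, wavy["precip"], ds, anchor = c(4, 0.5),
                           grid = grid)
  z <- (900 + 100 * sin(grid) - attr(ds, "center")[["precip"]]) /
    attr(ds, "scale")[["precip"]]
  manual <- fit$coefficients[["precip"]] * z *
    attr(ds, "scale")[["fraction_large"]]
  manual <- manual - manual[length(grid)] + 0.5
  expect_equal(bc1$predicted, manual, tolerance = 1e-10)

  expect_error(backcast_fraction(fit, wavy, list()), "standardisation")
})
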