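test_that("age resampling is uniform, deterministic and respects intervals", {
  occ <- record_fixture(seed = 4, n = 20)$occurrences
  r1 <- resample_ages(occ, replicate_id = 3, seed = 10)
  r2 <- resample_ages(occ, replicate_id = 3, seed = 10)
  expect_identical(r1$age, r2$age)
  r3 <- resample_ages(occ, replicate_id = 4, seed = 10)
  expect_false(identical(r1$age, r3$age))
  expect_true(all(r1$age >= occ$age_min & r1$age <= occ$age_max))

  # degenerate intervals reproduce the input ages exactly
  occ0 <- occ
  occ0$age_max <- occ0$age_min
  expect_equal(resample_ages(occ0, 1, 99)$age, occ0$age_min)

  # uniform mean on a single interval
  one <- data.frame(species = "a", site = "s", age_min = 2, age_max = 3,
                    size_class = "large", extant = FALSE)
  many <- one[rep(1, 1e4), ]
  many$species <- sprintf("a%05d", 1:1e4)
  expect_lt(abs(mean(resample_ages(many, 1, 1)$age) - 2.5), 0.011)
})

test_that("preservation log-likelihood matches its closed form", {
  h <- data.frame(species = "a", s = 1, e = 0, n = 1L, extant = FALSE)
  expect_equal(preservation_loglik(h, q = 1),
               log(exp(-1)) - log(1 - exp(-1)), tolerance = 1e-9)
  expect_equal(preservation_loglik(h, q = 1), -0.5413249, tolerance = 1e-6)

  # q d -> 0 with n = 1: the conditional point-process density approaches
  # the uniform density 1/d, so exp(loglik) * d -> 1
  h2 <- data.frame(species = "a", s = 1e-8, e = 0, n = 1L, extant = FALSE)
  expect_equal(exp(preservation_loglik(h2, q = 1)) * 1e-8, 1,
               tolerance = 1e-6)

  expect_error(preservation_loglik(
    data.frame(species = "a", s = 1, e = 1, n = 1L, extant = FALSE), 1))
  expect_error(preservation_loglik(
    data.frame(species = "a", s = 1, e = 0, n = 0L, extant = FALSE), 1))
  expect_error(preservation_loglik(h, q = -1))
})

test_that("preservation rate is recoverable by maximising the likelihood", {
  r <- record_fixture(seed = 21, n = 100, q = 2)
  h <- r$truth
  h$extant <- h$e == 0
  qs <- seq(0.5, 5, by = 0.01)
  ll <- vapply(qs, function(q) preservation_loglik(h, q), 0)
  q_hat <- qs[which.max(ll)]
  expect_lt(abs(q_hat - 2) / 2, 0.10)
})

test_that("gamma-heterogeneous preservation marginalises sensibly", {
  h <- histories_fixture()
  hom <- preservation_loglik(h, 1.5)
  # very large shape: heterogeneity vanishes, recovering the homogeneous case
  near_hom <- preservation_loglik(h, 1.5, gamma_shape = 1e6)
  expect_equal(near_hom, hom, tolerance = 1e-3)
  het <- preservation_loglik(h, 1.5, gamma_shape = 0.5)
  expect_false(isTRUE(all.equal(het, hom)))
  # category means of the discretised gamma average to 1
  expect_equal(mean(paleocarn:::discrete_gamma_means(0.7, 4)), 1,
               tolerance = 1e-6)
})

test_that("birth-death log-likelihood matches hand evaluation", {
  h <- data.frame(species = "a", s = 4, e = 0, n = 3L, extant = TRUE)
  expect_equal(bd_loglik(h, lambda0 = 0.2, mu_constant(0.1), B = 1),
               log(0.2) - 4 * 0.3, tolerance = 1e-6)
  # zero extinction rates are not constructible
  expect_error(mu_constant(0))
})

test_that("constant-rate extinction MLE equals extinctions over lineage time", {
  r <- record_fixture(seed = 31, n = 60, mu0 = 0.3)
  h <- r$truth
  h$extant <- h$e == 0
  D <- sum(!h$extant); Tt <- sum(h$s - h$e)
  opt <- optimize(function(m) bd_loglik(h, 0.25, mu_constant(m)),
                  c(0.01, 2), maximum = TRUE, tol = 1e-10)
  expect_equal(opt$maximum, D / Tt, tolerance = 1e-6)
})

test_that("likelihoods are invariant to species relabelling", {
  h <- histories_fixture()
  hp <- h[c(3, 1, 2), ]
  hp$species <- c("x", "y", "z")
  m <- mu_covariate("exponential", 0.2, 0.8, curve = brain_fixture())
  expect_equal(preservation_loglik(h, 1.2), preservation_loglik(hp, 1.2))
  expect_equal(bd_loglik(h, 0.3, m), bd_loglik(hp, 0.3, m))
})

test_that("model-family limit cases collapse to each other", {
  cv <- brain_fixture()
  h <- histories_fixture()
  ts <- seq(0, 4, by = 0.05)

  # threshold at the old window edge == plain covariate, pointwise
  for (link in c("linear", "exponential")) {
    m_thr <- mu_threshold(link, 0.2, 0.9, tau = 4, curve = cv)
    m_cov <- mu_covariate(link, 0.2, 0.9, curve = cv)
    expect_lt(max(abs(eval_mu(m_thr, ts) - eval_mu(m_cov, ts))), 1e-12)
    expect_equal(bd_loglik(h, 0.3, m_thr), bd_loglik(h, 0.3, m_cov),
                 tolerance = 1e-10)
  }

  # gamma = 0 == constant model
  for (m0 in c(0.1, 0.5)) {
    m_cov <- mu_covariate("linear", m0, 0, curve = cv)
    m_con <- mu_constant(m0)
    expect_equal(bd_loglik(h, 0.3, m_cov), bd_loglik(h, 0.3, m_con),
                 tolerance = 1e-10)
  }

  # exponential link closed form at x~ = 1
  lin <- linear_curve_fixture()  # centred values: t - 2
  m <- mu_covariate("exponential", 0.1, log(2), curve = lin)
  expect_equal(eval_mu(m, 3), 0.2, tolerance = 1e-12)  # x~(3) = 1

  # linear link flooring keeps rates positive
  m_neg <- mu_covariate("linear", 0.1, 10, curve = lin)
  expect_true(all(eval_mu(m_neg, ts) >= 1e-5))
})

test_that("shift models integrate exactly and pick the right regime", {
  m <- mu_shift(shift_times = 2, rates = c(0.1, 0.4))
  expect_equal(eval_mu(m, c(3, 2.01)), c(0.1, 0.1))
  expect_equal(eval_mu(m, c(1.99, 0.5)), c(0.4, 0.4))
  h <- data.frame(species = "a", s = 4, e = 0, n = 2L, extant = TRUE)
  # integral = 0.1 * 2 + 0.4 * 2; no extinction term; B = 0 at the edge
  expect_equal(bd_loglik(h, 0.2, m, B = 0),
               -0.2 * 4 - (0.1 * 2 + 0.4 * 2), tolerance = 1e-10)
})

test_that("halving the integration bin width barely moves the likelihood", {
  h <- histories_fixture()
  m <- mu_covariate("exponential", 0.25, 1.1, curve = brain_fixture())
  l1 <- bd_loglik(h, 0.3, m, bin_width = 0.01)
  l2 <- bd_loglik(h, 0.3, m, bin_width = 0.005)
  expect_lt(abs(l1 - l2), 1e-3)
})

test_that("the sampler's fast likelihood path equals the public one", {
  r <- record_fixture(seed = 41, n = 30)
  rep1 <- resample_ages(r$occurrences, 1, seed = 2)
  h <- init_histories(rep1)
  for (m in list(mu_constant(0.3),
                 mu_shift(1.5, c(0.2, 0.5)),
                 mu_covariate("linear", 0.3, 0.5, curve = brain_fixture()),
                 mu_threshold("exponential", 0.3, 0.8, tau = 2.2,
                              curve = brain_fixture()))) {
    span <- c(max(4, max(h$s)), 0)
    bins <- paleocarn:::make_bins(m, span, 0.01)
    expect_equal(
      paleocarn:::bd_ll_fast(h$s, h$e, !h$extant, 0.3, m, span, 0.01, bins),
      bd_loglik(h, 0.3, m), tolerance = 1e-10)
  }
})
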