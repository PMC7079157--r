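test_that("trapezoid thermodynamic integration is exact for a flat integrand", {
  betas <- ti_betas(6)
  expect_equal(ti_integrate(betas, rep(-12.5, 6)), -12.5)
  expect_error(ti_integrate(betas, c(rep(1, 5), NaN)), "non-finite")
  expect_equal(min(betas), 0)
  expect_equal(max(betas), 1)
  expect_true(!is.unsorted(betas))
})

test_that("TI recovers the closed-form marginal likelihood of a conjugate toy", {
  # y_i ~ Exponential(theta), theta ~ Gamma(a, b):
  # m(y) = b^a Gamma(a+n) / (Gamma(a) (b+S)^(a+n))
  set.seed(4)
  y <- rexp(20, 1.5); a <- 2; b <- 1; S <- sum(y); n <- length(y)
  logml_true <- a * log(b) + lgamma(a + n) - lgamma(a) - (a + n) * log(b + S)
  betas <- ti_betas(8)
  mll <- vapply(betas, function(bt) {
    ch <- mh_chain(
      c(theta = 1),
      log_prior = function(s) dgamma(s[["theta"]], a, rate = b, log = TRUE),
      log_lik = function(s) n * log(s[["theta"]]) - s[["theta"]] * S,
      propose = function(s) {
        m <- exp(runif(1, -0.8, 0.8))
        list(state = c(theta = s[["theta"]] * m), log_hastings = log(m))
      },
      n_iter = 20000, beta = bt, seed = round(bt * 1000) + 1)
    mean(ch$log_lik)
  }, 0)
  expect_lt(abs(ti_integrate(betas, mll) - logml_true), 0.1)
})

test_that("a prior-only chain reproduces the prior moments", {
  r <- record_fixture(seed = 13, n = 20)
  rep1 <- resample_ages(r$occurrences, 1, seed = 3)
  cfg <- mcmc_config(n_iter = 12000, thin = 4, seed = 5, burnin = 0.1)
  tr <- run_mcmc(rep1, mu_covariate("exponential", 0.3, 0,
                                    curve = brain_fixture()), beta = 0,
                 cfg = cfg)
  # rates ~ Gamma(1.1, 1): mean 1.1, sd ~1.05; gamma ~ N(0, 1)
  expect_lt(abs(mean(tr$mu0) - 1.1), 0.3)
  expect_lt(abs(mean(tr$q) - 1.1), 0.3)
  expect_lt(abs(mean(tr$gamma)), 0.3)
  expect_lt(abs(sd(tr$gamma) - 1), 0.3)
})

test_that("the posterior concentrates on the generating constant rate", {
  hits <- 0
  for (i in 1:10) {
    r <- record_fixture(seed = 300 + i, n = 40, mu0 = 0.2)
    rep1 <- resample_ages(r$occurrences, 1, seed = derive_seed(60, i))
    tr <- run_mcmc(rep1, mu_constant(0.3),
                   mcmc_config(n_iter = 3000, thin = 5, seed = derive_seed(61, i),
                               burnin = 0.2))
    ci <- quantile(tr$mu0, c(0.025, 0.975))
    if (ci[1] <= 0.2 && 0.2 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("a long constant-rate chain passes a Geweke-style drift check", {
  r <- record_fixture(seed = 17, n = 40, mu0 = 0.25)
  rep1 <- resample_ages(r$occurrences, 1, seed = 2)
  tr <- run_mcmc(rep1, mu_constant(0.3),
                 mcmc_config(n_iter = 20000, thin = 5, seed = 8, burnin = 0.2))
  geweke_z <- function(x) {
    n <- length(x)
    a <- x[1:floor(0.1 * n)]; b <- x[(floor(0.5 * n) + 1):n]
    sv <- function(v) {  # spectral density at zero via AR fit
      fit <- try(ar(v, order.max = 10), silent = TRUE)
      if (inherits(fit, "try-error") || length(fit$ar) == 0) return(var(v))
      fit$var.pred / (1 - sum(fit$ar))^2
    }
    (mean(a) - mean(b)) / sqrt(sv(a) / length(a) + sv(b) / length(b))
  }
  for (p in c("lambda0", "q", "mu0"))
    expect_lt(abs(geweke_z(tr[[p]])), 3)
})

test_that("acceptance rates are tracked and traces carry their metadata", {
  r <- record_fixture(seed = 19, n = 25)
  rep1 <- resample_ages(r$occurrences, 2, seed = 3)
  tr <- run_mcmc(rep1, mu_threshold("exponential", 0.3, 0.5, tau = 2,
                                    curve = brain_fixture()),
                 quick_mcmc(seed = 4))
  acc <- attr(tr, "acceptance")
  expect_true(all(c("times", "lambda0", "q", "mu_pos", "gamma", "times_par")
                  %in% names(acc)))
  expect_true(all(acc[!is.na(acc)] >= 0 & acc[!is.na(acc)] <= 1))
  expect_true(all(c("tau", "gamma", "mu0") %in% names(tr)))
  expect_equal(attr(tr, "replicate_id"), 2L)
  expect_equal(ncol(attr(tr, "s_trace")), length(attr(tr, "species")))
  # tau stays inside the window
  expect_true(all(tr$tau >= 0 & tr$tau <= 4))
})

test_that("bayes factors are antisymmetric and zero on self-comparison", {
  a <- structure(list(label = "a", logml = -100, replicate_id = 1L),
                 class = "model_score")
  b <- structure(list(label = "b", logml = -100 - log(3), replicate_id = 1L),
                 class = "model_score")
  expect_equal(bayes_factor(a, a), 0)
  expect_equal(bayes_factor(a, b), -bayes_factor(b, a))
  expect_equal(bayes_factor(a, b), 2 * log(3))
  c_other <- structure(list(label = "c", logml = -1, replicate_id = 2L),
                       class = "model_score")
  expect_error(bayes_factor(a, c_other), "different replicates")
})

test_that("relative probabilities are a softmax over log marginal likelihoods", {
  mk <- function(lab, lml) structure(
    list(label = lab, logml = lml, replicate_id = 1L), class = "model_score")
  expect_equal(unname(relative_probabilities(list(mk("only", -5)))), 1.0)
  w <- relative_probabilities(list(mk("a", -7), mk("b", -7)))
  expect_equal(unname(w), c(0.5, 0.5))
  w2 <- relative_probabilities(list(mk("a", 0), mk("b", -log(3))))
  expect_equal(unname(w2), c(0.75, 0.25))
  expect_equal(sum(w2), 1)
  expect_error(relative_probabilities(list()), "empty")
})

test_that("rate-through-time summaries behave on degenerate traces", {
  tr <- data.frame(iter = 1:5, log_post = 0, log_lik = 0,
                   lambda0 = 0.3, q = 1, mu0 = 0.1)
  attr(tr, "model") <- mu_constant(0.1)
  attr(tr, "window") <- c(4, 0)
  grid <- seq(0, 4, 0.5)
  rtt <- extract_rtt(tr, grid)
  expect_equal(rtt$mean, rep(0.1, length(grid)))
  expect_equal(rtt$lo, rtt$hi)
  expect_true(all(rtt$lo <= rtt$mean & rtt$mean <= rtt$hi))
  # pooling two identical traces changes nothing
  rtt2 <- extract_rtt(list(tr, tr), grid)
  expect_equal(rtt2, rtt)
  expect_error(extract_rtt(tr, c(-1, 5)), "outside")
})
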