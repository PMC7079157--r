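#' Resample occurrence ages within their dating intervals
#'
#' Draws one age per occurrence uniformly in [age_min, age_max], independently
#' across occurrences, deterministically given (seed, replicate_id). This is
#' how dating uncertainty enters the replicated analyses: each replicate is a
#' complete re-analysis on one such age draw.
#'
#' @param occurrences validated occurrence table.
#' @param replicate_id integer replicate label.
#' @param seed master seed; the draw uses [derive_seed()] of (seed,
#'   replicate_id).
#' @return data.frame with columns of \code{occurrences} plus \code{age};
#'   attributes \code{replicate_id} and \code{seed}.
#' @export
resample_ages <- function(occurrences, replicate_id = 1L, seed = 1L) {
  occ <- validate_occurrences(occurrences)
  s <- derive_seed(seed, replicate_id)
  old <- set_local_seed(s)
  on.exit(restore_seed(old), add = TRUE)
  occ$age <- stats::runif(nrow(occ), occ$age_min, occ$age_max)
  attr(occ, "replicate_id") <- as.integer(replicate_id)
  attr(occ, "seed") <- s
  occ
}

#' Initial lineage histories from a replicate dataset
#'
#' Builds the per-species latent variables of the model: origination time s_i,
#' extinction time e_i (0 and fixed for extant species) and occurrence count
#' n_i, initialised just outside the sampled age range and respecting
#' s_i > e_i, s_i >= max sampled age, e_i <= min sampled age.
#'
#' @param replicate output of [resample_ages()] (needs columns species, age,
#'   size_class, extant).
#' @param window analysis window \code{c(old, young)} in Ma.
#' @return data.frame with species, s, e, n, extant, age_max_obs, age_min_obs.
#' @export
init_histories <- function(replicate, window = c(4, 0)) {
  old <- window[1]; young <- window[2]
  if (!(old > young)) stop("window must be c(old, young) with old > young")
  sp <- split(replicate, replicate$species)
  h <- data.frame(
    species = names(sp),
    s = NA_real_, e = NA_real_,
    n = vapply(sp, nrow, 0L),
    extant = vapply(sp, function(d) d$extant[1], TRUE),
    age_max_obs = vapply(sp, function(d) max(d$age), 0),
    age_min_obs = vapply(sp, function(d) min(d$age), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  # originations start just above the oldest sampled age (possibly beyond
  # the window edge: boundary entrants); extinctions halfway to the present
  h$s <- h$age_max_obs + 0.2
  h$e <- ifelse(h$extant, 0, pmax(young, 0.5 * pmin(h$age_min_obs, old)))
  check_histories(h)
  h
}

check_histories <- function(h) {
  stopifnot(all(c("species", "s", "e", "n") %in% names(h)))
  if (any(h$s <= h$e)) stop("lineage histories must satisfy s > e")
  if (any(h$e < 0)) stop("extinction times must be >= 0")
  if (any(h$n < 1L)) stop("unsampled lineages (n = 0) are not representable")
  if (!is.null(h$extant) && any(h$extant & h$e != 0))
    stop("extant lineages must have e = 0")
  invisible(TRUE)
}

#' Poisson preservation log-likelihood
#'
#' Homogeneous Poisson fossil preservation over each lineage's lifespan
#' d_i = s_i - e_i, conditioned on at least one occurrence (unsampled lineages
#' cannot be observed): per species the point-process density of its dated
#' occurrences,
#' \deqn{n_i \log q - q d_i - \log(1 - e^{-q d_i}),}
#' summed over species. The point-process form (not the Poisson count
#' probability, which carries an extra \eqn{d_i^{n_i}} factor) is essential
#' when the lifespans are latent variables: the count form systematically
#' rewards stretched lifespans and biases the joint inference. For fixed
#' lifespans the two differ by a constant in q. With \code{gamma_shape} set,
#' preservation-rate
#' heterogeneity across species is marginalised over a discrete gamma with
#' \code{ncat} equal-weight categories of mean 1 (category means), i.e. each
#' species' likelihood is averaged over q multiplied by each category mean.
#'
#' @param histories lineage-history data.frame (s, e, n).
#' @param q preservation rate (occurrences/lineage/Myr), > 0.
#' @param gamma_shape optional gamma shape for rate heterogeneity.
#' @param ncat number of discrete gamma categories (default 4).
#' @return log-likelihood (scalar).
#' @export
preservation_loglik <- function(histories, q, gamma_shape = NULL, ncat = 4L) {
  check_histories(histories)
  if (q <= 0) stop("preservation rate q must be > 0")
  d <- histories$s - histories$e
  n <- histories$n
  pres_ll_total(q, d, n, gamma_shape, ncat)
}

# unvalidated fast path shared with the sampler
pres_ll_total <- function(q, d, n, gamma_shape = NULL, ncat = 4L) {
  if (is.null(gamma_shape)) return(sum(pres_ll_one(q, d, n)))
  if (gamma_shape <= 0) stop("gamma_shape must be > 0")
  mult <- discrete_gamma_means(gamma_shape, ncat)
  # per-species log mean_k L(q * m_k)
  ll_k <- vapply(mult, function(m) pres_ll_one(q * m, d, n), numeric(length(d)))
  if (is.null(dim(ll_k))) ll_k <- matrix(ll_k, nrow = 1)
  mx <- apply(ll_k, 1, max)
  sum(mx + log(rowMeans(exp(ll_k - mx))))
}

# precomputed quadrature context for the sampler: bin edges plus the centred
# covariate at bin midpoints (curve and grid never change within a chain)
make_bins <- function(model, window, bin_width) {
  edges <- seq(window[2], window[1], by = bin_width)
  if (edges[length(edges)] < window[1]) edges <- c(edges, window[1])
  lo <- edges[-length(edges)]; hi <- edges[-1]
  mids <- (lo + hi) / 2
  x <- if (model$variant %in% c("covariate", "covariate_threshold"))
    covariate_value(model$curve, pmin(pmax(mids, min(model$curve$grid)),
                                      max(model$curve$grid)))
  else NULL
  list(lo = lo, hi = hi, mids = mids, x = x)
}

# linear interpolation of the centred covariate with range clamping
cov_val_fast <- function(curve, t) {
  g <- curve$grid
  tc <- pmin(pmax(t, g[1]), g[length(g)])
  i <- pmin(findInterval(tc, g), length(g) - 1L)
  frac <- (tc - g[i]) / (g[i + 1L] - g[i])
  v <- curve$values[i] + frac * (curve$values[i + 1L] - curve$values[i])
  (v - curve$center) / curve$scale
}

mu_at_fast <- function(model, t, bins = NULL) {
  switch(model$variant,
    constant = rep(model$mu0, length(t)),
    shift = model$rates[1L + vapply(t, function(ti) sum(model$shift_times > ti), 0L)],
    covariate = mu_link(model$link, model$mu0, model$gamma,
                        cov_val_fast(model$curve, t)),
    covariate_threshold = {
      x <- cov_val_fast(model$curve, t)
      x_tau <- cov_val_fast(model$curve, model$tau)
      out <- rep(mu_link(model$link, model$mu0, model$gamma, x_tau), length(t))
      recent <- t <= model$tau
      out[recent] <- mu_link(model$link, model$mu0, model$gamma, x[recent])
      out
    })
}

# unvalidated fast birth-death log-likelihood on raw vectors (sampler path);
# bd_loglik is the checked public wrapper with identical arithmetic.
# `window` here is the integration span c(top, young): the quadrature bins
# (and bins$x, the clamped covariate) must cover it.
bd_ll_fast <- function(s, e, extinct, lambda0, model, window, bin_width,
                       bins = NULL, B = length(s) - 1L) {
  young <- window[2]
  e2 <- pmax(e, young)
  ll <- B * log(lambda0) - lambda0 * sum(s - e2)
  if (any(extinct)) {
    mu_e <- mu_at_fast(model, e2[extinct], bins)
    if (any(mu_e <= 0)) return(-Inf)
    ll <- ll + sum(log(mu_e))
  }
  if (model$variant == "constant")
    return(ll - model$mu0 * sum(s - e2))
  if (model$variant == "shift") {
    # exact piecewise integral; the oldest regime extends above the window
    bounds <- c(Inf, model$shift_times, young)
    tot <- 0
    for (k in seq_along(model$rates)) {
      hi <- bounds[k]; lo <- bounds[k + 1]
      ov <- (if (is.finite(hi)) pmin(s, hi) else s) - pmax(e2, lo)
      tot <- tot + model$rates[k] * sum(ov[ov > 0])
    }
    return(ll - tot)
  }
  if (is.null(bins)) bins <- make_bins(model, window, bin_width)
  mu_m <- if (model$variant == "covariate")
    mu_link(model$link, model$mu0, model$gamma, bins$x)
  else {
    x_tau <- cov_val_fast(model$curve, model$tau)
    mm <- rep(mu_link(model$link, model$mu0, model$gamma, x_tau), length(bins$mids))
    recent <- bins$mids <= model$tau
    mm[recent] <- mu_link(model$link, model$mu0, model$gamma, bins$x[recent])
    mm
  }
  Lb <- bin_lineage_time(s, e2, bins$lo, bins$hi)
  ll - sum(Lb * mu_m)
}

# vectorised per-species conditional Poisson point-process log-likelihood
pres_ll_one <- function(q, d, n) {
  if (any(d <= 0)) stop("lifespans must be positive")
  qd <- q * d
  n * log(q) - qd - log1p(-exp(-qd))
}

# means of ncat equal-probability gamma(shape, shape) categories (mean 1)
discrete_gamma_means <- function(shape, ncat) {
  p <- seq(0, 1, length.out = ncat + 1L)
  qs <- stats::qgamma(p, shape = shape, rate = shape)
  m <- numeric(ncat)
  for (k in seq_len(ncat)) {
    # mean of the category via the incomplete-gamma identity
    m[k] <- (stats::pgamma(qs[k + 1], shape + 1, rate = shape) -
               stats::pgamma(qs[k], shape + 1, rate = shape)) * ncat
  }
  m
}

#' Birth-death log-likelihood with time-varying extinction
#'
#' Log-likelihood of the lineage histories under a birth-death process with
#' constant speciation rate lambda0 and extinction rate mu(t) given by an
#' extinction model:
#' \deqn{B \log\lambda_0 + \sum_{extinct} \log\mu(e_i)
#'       - \int N(t)\,(\lambda_0 + \mu(t))\,dt,}
#' where B counts origination events inside the window, N(t) is the number of
#' lineages alive at age t, and the integral runs over the window. The
#' lambda0 part of the integral is exact (lambda0 times total lineage time);
#' the mu part is exact for constant and shift models and computed on a fixed
#' age grid (0.01 Myr bins by default) for covariate models, summing per-bin
#' lineage time times mu at the bin midpoint.
#'
#' The process is modelled over the full lineage spans: every lineage except
#' one (the root of the assemblage) contributes a birth event, so by default
#' B = number of lineages - 1; an explicit \code{B} overrides the count.
#' Extinction models driven by a covariate are constant-extrapolated beyond
#' the curve's coverage window, so originations older than the window are
#' handled without truncating the process (truncating at the window edge
#' forces all originations inside it and distorts rates near the edge).
#'
#' @param histories lineage-history data.frame (s, e, n, extant).
#' @param lambda0 speciation rate, > 0.
#' @param model an \code{extinction_model}.
#' @param window covariate coverage window \code{c(old, young)} Ma; the rate
#'   integral itself runs over \code{[young, max(old, max(s))]}.
#' @param B optional explicit number of birth events.
#' @param bin_width grid bin width (Myr) for covariate-model integrals.
#' @return log-likelihood (scalar); \code{-Inf} with an error if any extinct
#'   lineage has mu(e_i) <= 0 (prevented by the linear-link floor).
#' @export
bd_loglik <- function(histories, lambda0, model, window = c(4, 0), B = NULL,
                      bin_width = 0.01) {
  check_histories(histories)
  if (lambda0 <= 0) stop("lambda0 must be > 0")
  old <- window[1]; young <- window[2]
  s <- histories$s
  e <- pmax(histories$e, young)
  extinct <- if (!is.null(histories$extant)) !histories$extant else histories$e > young
  if (is.null(B)) B <- nrow(histories) - 1L
  top <- max(old, max(s))
  bins <- make_bins(model, c(top, young), bin_width)
  bd_ll_fast(s, e, extinct, lambda0, model, c(top, young), bin_width, bins,
             B = B)
}

# exact total lineage time per bin via the cumulative identity
# F(t) = sum_i (min(s_i, t) - min(e_i, t)) and Lb = F(hi) - F(lo)
bin_lineage_time <- function(s, e, lo, hi) {
  edges <- c(lo[1], hi)
  Fs <- sum_min(s, edges) - sum_min(e, edges)
  diff(Fs)
}

# sum_i min(v_i, t) for ascending t, via sorted cumulative sums
sum_min <- function(v, t) {
  sv <- sort(v)
  cs <- c(0, cumsum(sv))
  k <- findInterval(t, sv)
  cs[k + 1] + (length(v) - k) * t
}

# linear interpolation of the centred covariate with range clamping
cov_val_fast <- function(curve, t) {
  g <- curve$grid
  tc <- pmin(pmax(t, g[1]), g[length(g)])
  i <- pmin(findInterval(tc, g), length(g) - 1L)
  frac <- (tc - g[i]) / (g[i + 1L] - g[i])
  v <- curve$values[i] + frac * (curve$values[i + 1L] - curve$values[i])
  (v - curve$center) / curve$scale
}

mu_at_fast <- function(model, t, bins = NULL) {
  switch(model$variant,
    constant = rep(model$mu0, length(t)),
    shift = model$rates[1L + vapply(t, function(ti) sum(model$shift_times > ti), 0L)],
    covariate = mu_link(model$link, model$mu0, model$gamma,
                        cov_val_fast(model$curve, t)),
    covariate_threshold = {
      x <- cov_val_fast(model$curve, t)
      x_tau <- cov_val_fast(model$curve, model$tau)
      out <- rep(mu_link(model$link, model$mu0, model$gamma, x_tau), length(t))
      recent <- t <= model$tau
      out[recent] <- mu_link(model$link, model$mu0, model$gamma, x[recent])
      out
    })
}
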