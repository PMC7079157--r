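#' MCMC configuration
#'
#' Settings for the Metropolis-Hastings sampler over latent lineage times and
#' model parameters, and for thermodynamic integration.
#'
#' Priors (all proper and vague, exposed here): lambda0, mu0, q and shift
#' rates ~ Gamma(shape 1.1, rate 1); gamma ~ Normal(0, 1); tau and shift
#' times ~ Uniform over the window; latent times uniform subject to the
#' occurrence constraints.
#'
#' @param n_iter total iterations.
#' @param burnin fraction of iterations discarded (default 0.1).
#' @param thin keep every \code{thin}-th iteration after burn-in.
#' @param seed chain seed.
#' @param ti_categories number K of inverse temperatures for thermodynamic
#'   integration (>= 4); the betas are quantiles of Beta(0.3, 1) including 0
#'   and 1.
#' @param rate_mult half-width of the log-multiplier proposal for positive
#'   parameters (lambda0, mu0, q, shift rates).
#' @param gamma_sd SD of the normal random-walk proposal for gamma.
#' @param time_win half-width (Myr) of the sliding-window proposal for latent
#'   s_i / e_i.
#' @param tau_win half-width (Myr) of the sliding-window proposal for tau and
#'   shift times.
#' @param frac_times fraction of species whose latent times are updated per
#'   times-move.
#' @param prior_rate_shape,prior_rate_rate Gamma prior on positive rates.
#' @param prior_gamma_sd SD of the normal prior on gamma.
#' @param gamma_shape optional preservation heterogeneity shape (fixed, not
#'   sampled); NULL for homogeneous preservation.
#' @param origin_headroom how far (Myr) latent originations may precede the
#'   old window edge. Such lineages enter the window at its boundary: they
#'   carry no birth-event term and no rate exposure before the edge, but
#'   their preservation still covers the full lifespan. Without this slack
#'   every origination is forced inside the window, which distorts rates
#'   near the old edge.
#' @return list of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_iter = 20000, burnin = 0.1, thin = 20, seed = 1,
                        ti_categories = 6, rate_mult = 0.6, gamma_sd = 0.35,
                        time_win = 0.4, tau_win = 0.5, frac_times = 0.2,
                        prior_rate_shape = 1.1, prior_rate_rate = 1,
                        prior_gamma_sd = 1, gamma_shape = NULL,
                        origin_headroom = 3) {
  stopifnot(n_iter > n_iter * burnin, ti_categories >= 4)
  structure(as.list(environment()), class = "mcmc_config")
}

reflect <- function(x, lo, hi) {
  w <- hi - lo
  out <- ifelse(w <= 0, lo, {
    y <- (x - lo) %% pmax(2 * w, .Machine$double.eps)
    lo + ifelse(y > w, 2 * w - y, y)
  })
  out
}

log_prior_rates <- function(x, cfg)
  sum(stats::dgamma(x, shape = cfg$prior_rate_shape,
                    rate = cfg$prior_rate_rate, log = TRUE))

# full log prior of a sampler state (latent-time priors are uniform on fixed
# bounded ranges and hence constant; omitted)
state_log_prior <- function(st, cfg, window) {
  lp <- log_prior_rates(c(st$lambda0, st$q), cfg)
  m <- st$model
  spec <- model_param_spec(m)
  if (m$variant == "shift") {
    lp <- lp + log_prior_rates(m$rates, cfg)
    if (any(m$shift_times >= window[1] | m$shift_times <= window[2]))
      return(-Inf)
  } else {
    lp <- lp + log_prior_rates(m$mu0, cfg)
  }
  if ("gamma" %in% spec$real)
    lp <- lp + stats::dnorm(m$gamma, 0, cfg$prior_gamma_sd, log = TRUE)
  if (m$variant == "covariate_threshold") {
    if (m$tau > window[1] || m$tau < window[2]) return(-Inf)
    lp <- lp - log(window[1] - window[2])  # uniform density
  }
  lp
}

#' Run the Metropolis-Hastings sampler for one replicate and model
#'
#' Samples (lambda0, extinction-model parameters, q, all latent s_i and e_i,
#' and tau where present) from the tempered posterior
#' prior x likelihood^beta. Proposal blocks: log-multipliers for positive
#' rates, normal random walk for gamma, reflected sliding windows for times
#' and thresholds; a times-move updates a random fraction of species jointly.
#' Likelihood components (preservation vs birth-death) are cached and only
#' the affected part is recomputed per move.
#'
#' @param replicate output of [resample_ages()].
#' @param model an \code{extinction_model} providing the initial parameter
#'   values; covariate models must carry their predictor curve.
#' @param cfg an [mcmc_config()].
#' @param beta inverse temperature in [0, 1] (1 = posterior).
#' @param window analysis window \code{c(old, young)} Ma.
#' @param lambda0 initial speciation rate; NULL (default) uses a
#'   moment-based starting value.
#' @param q initial preservation rate; NULL (default) uses a moment-based
#'   starting value.
#' @param bin_width integration bin width (Myr).
#' @param init_state optional full sampler state (lambda0, q, model, h) to
#'   warm-start from, e.g. the \code{"final_state"} attribute of a previous
#'   trace; used by [thermodynamic_ml()] to chain tempered runs.
#' @return data.frame trace of retained samples (iter, log-posterior,
#'   log-likelihood, lambda0, q and model parameters), with attributes
#'   \code{model} (template), \code{s_trace}, \code{e_trace} (retained latent
#'   times, species in columns), \code{species}, \code{size_class},
#'   \code{acceptance} (per-block rates), \code{window}, \code{replicate_id}.
#' @export
run_mcmc <- function(replicate, model, cfg = mcmc_config(), beta = 1,
                     window = c(4, 0), lambda0 = NULL, q = NULL,
                     bin_width = 0.01, init_state = NULL) {
  stopifnot(inherits(model, "extinction_model"), beta >= 0, beta <= 1)
  old_seed <- set_local_seed(cfg$seed)
  on.exit(restore_seed(old_seed), add = TRUE)

  if (is.null(init_state)) {
    h <- init_histories(replicate, window)
    # moment-based starting values: q from occurrences per observed span,
    # rates from extinction counts over total lineage time
    if (is.null(q))
      q <- max(0.2, sum(h$n) / sum(h$s - h$e))
    if (is.null(lambda0))
      lambda0 <- max(0.05, nrow(h) / (2 * sum(h$s - h$e)))
    st <- list(lambda0 = lambda0, q = q, model = model, h = h)
  } else {
    st <- list(lambda0 = init_state$lambda0, q = init_state$q,
               model = init_state$model, h = init_state$h)
  }
  h <- st$h
  # hot state: plain vectors (data.frame access is too slow for the loop)
  st$s <- h$s; st$e <- h$e
  nv <- h$n; ext <- !h$extant
  amax <- h$age_max_obs; amin <- h$age_min_obs
  span <- c(window[1] + cfg$origin_headroom, window[2])
  bins <- make_bins(model, span, bin_width)
  st$pres <- pres_ll_total(st$q, st$s - st$e, nv, cfg$gamma_shape)
  st$bd <- bd_ll_fast(st$s, st$e, ext, st$lambda0, st$model, span, bin_width,
                      bins)
  st$h <- NULL
  st$lp <- state_log_prior(st, cfg, window)
  spec <- model_param_spec(model)

  moves <- c("times", "times_ind", "lambda0", "q", "mu_pos")
  wts <- c(0.22, 0.22, 0.10, 0.15, 0.20)
  s_hi <- pmax(amax + 0.5, window[1] + cfg$origin_headroom)
  if (length(spec$real)) { moves <- c(moves, "gamma"); wts <- c(wts, 0.10) }
  if (length(spec$times)) { moves <- c(moves, "times_par"); wts <- c(wts, 0.08) }
  wts <- wts / sum(wts)

  n_keep <- floor((cfg$n_iter - cfg$n_iter * cfg$burnin) / cfg$thin)
  keep_from <- ceiling(cfg$n_iter * cfg$burnin)
  par_names <- c("lambda0", "q",
                 if (model$variant == "shift")
                   c(paste0("rate", seq_along(model$rates)),
                     if (length(model$shift_times))
                       paste0("shift", seq_along(model$shift_times)))
                 else "mu0",
                 spec$real,
                 if (model$variant == "covariate_threshold") "tau")
  trace <- matrix(NA_real_, n_keep, 3 + length(par_names),
                  dimnames = list(NULL, c("iter", "log_post", "log_lik", par_names)))
  ns <- nrow(h)
  s_tr <- matrix(NA_real_, n_keep, ns)
  e_tr <- matrix(NA_real_, n_keep, ns)
  acc <- stats::setNames(numeric(length(moves)), moves)
  tries <- acc
  kept <- 0L
  consec_rej <- 0L

  mvs <- sample.int(length(moves), cfg$n_iter, replace = TRUE, prob = wts)
  for (it in seq_len(cfg$n_iter)) {
    mv <- moves[mvs[it]]
    tries[mv] <- tries[mv] + 1
    prop <- st
    log_hast <- 0
    redo_pres <- FALSE; redo_bd <- FALSE
    ok <- TRUE

    if (mv == "lambda0") {
      m <- exp(stats::runif(1, -cfg$rate_mult, cfg$rate_mult))
      prop$lambda0 <- st$lambda0 * m; log_hast <- log(m); redo_bd <- TRUE
    } else if (mv == "q") {
      m <- exp(stats::runif(1, -cfg$rate_mult, cfg$rate_mult))
      prop$q <- st$q * m; log_hast <- log(m); redo_pres <- TRUE
    } else if (mv == "mu_pos") {
      m <- exp(stats::runif(1, -cfg$rate_mult, cfg$rate_mult))
      if (st$model$variant == "shift") {
        k <- sample.int(length(st$model$rates), 1L)
        prop$model$rates[k] <- st$model$rates[k] * m
      } else prop$model$mu0 <- st$model$mu0 * m
      log_hast <- log(m); redo_bd <- TRUE
    } else if (mv == "gamma") {
      prop$model$gamma <- st$model$gamma + stats::rnorm(1, 0, cfg$gamma_sd)
      redo_bd <- TRUE
    } else if (mv == "times_par") {
      if (st$model$variant == "covariate_threshold") {
        prop$model$tau <- reflect(st$model$tau + stats::runif(1, -cfg$tau_win, cfg$tau_win),
                                  window[2], window[1])
      } else {
        k <- sample.int(length(st$model$shift_times), 1L)
        tt <- reflect(st$model$shift_times[k] + stats::runif(1, -cfg$tau_win, cfg$tau_win),
                      window[2], window[1])
        prop$model$shift_times[k] <- tt
        if (is.unsorted(rev(prop$model$shift_times))) ok <- FALSE
      }
      redo_bd <- TRUE
    } else if (mv == "times_ind") {
      # metropolized independence move: latent gaps proposed from truncated
      # exponentials anchored at the observed age range -- close to the
      # conditional shape, so latent times decorrelate fast even in weakly
      # tempered chains. The proposal rate uses q and lambda0, which this
      # move never changes, so the reverse density uses the same rate.
      nup <- max(1L, round(0.75 * cfg$frac_times * ns))
      idx <- sample.int(ns, nup)
      # tempering widens the latent gaps ~ 1/beta; match the proposal to it
      r <- 0.1 + beta * (st$q + st$lambda0)
      Ls <- s_hi[idx] - amax[idx]
      gap_old_s <- st$s[idx] - amax[idx]
      u <- stats::runif(nup)
      gap_new_s <- -log1p(-u * (1 - exp(-r * Ls))) / r
      prop$s[idx] <- amax[idx] + pmin(gap_new_s, Ls - 1e-9)
      dtexp <- function(g, L) log(r) - r * g - log1p(-exp(-r * L))
      log_hast <- sum(dtexp(gap_old_s, Ls)) - sum(dtexp(gap_new_s, Ls))
      eu <- idx[ext[idx]]
      if (length(eu)) {
        Le <- pmax(amin[eu] - window[2], 1e-9)
        gap_old_e <- amin[eu] - st$e[eu]
        u2 <- stats::runif(length(eu))
        gap_new_e <- -log1p(-u2 * (1 - exp(-r * Le))) / r
        prop$e[eu] <- amin[eu] - pmin(gap_new_e, Le - 1e-9)
        log_hast <- log_hast +
          sum(dtexp(gap_old_e, Le)) - sum(dtexp(gap_new_e, Le))
      }
      if (any(prop$s[idx] <= prop$e[idx])) ok <- FALSE
      redo_pres <- TRUE; redo_bd <- TRUE
    } else { # times
      nup <- max(1L, round(cfg$frac_times * ns))
      idx <- sample.int(ns, nup)
      s_new <- reflect(st$s[idx] + stats::runif(nup, -cfg$time_win, cfg$time_win),
                       amax[idx], s_hi[idx])
      prop$s[idx] <- s_new
      eu <- idx[ext[idx]]
      if (length(eu)) {
        e_new <- reflect(st$e[eu] + stats::runif(length(eu), -cfg$time_win, cfg$time_win),
                         window[2], amin[eu])
        prop$e[eu] <- e_new
      }
      if (any(prop$s[idx] <= prop$e[idx])) ok <- FALSE
      redo_pres <- TRUE; redo_bd <- TRUE
    }

    if (ok) {
      if (redo_pres)
        prop$pres <- pres_ll_total(prop$q, prop$s - prop$e, nv, cfg$gamma_shape)
      if (redo_bd)
        prop$bd <- bd_ll_fast(prop$s, prop$e, ext, prop$lambda0, prop$model,
                              span, bin_width, bins)
      prop$lp <- state_log_prior(prop, cfg, window)
      a <- (prop$lp + beta * (prop$pres + prop$bd)) -
        (st$lp + beta * (st$pres + st$bd)) + log_hast
      if (is.finite(a) && log(stats::runif(1)) < a) {
        st <- prop
        acc[mv] <- acc[mv] + 1
        consec_rej <- 0L
      } else consec_rej <- consec_rej + 1L
    } else consec_rej <- consec_rej + 1L
    if (consec_rej >= 10000L)
      stop("MCMC stalled: 10000 consecutive rejections (check proposal scales)")

    if (it > keep_from && ((it - keep_from) %% cfg$thin == 0L) && kept < n_keep) {
      kept <- kept + 1L
      pv <- c(st$lambda0, st$q,
              if (st$model$variant == "shift")
                c(st$model$rates, st$model$shift_times)
              else st$model$mu0,
              if (length(spec$real)) st$model$gamma,
              if (st$model$variant == "covariate_threshold") st$model$tau)
      trace[kept, ] <- c(it, st$lp + beta * (st$pres + st$bd),
                         st$pres + st$bd, pv)
      s_tr[kept, ] <- st$s
      e_tr[kept, ] <- st$e
    }
  }
  h$s <- st$s; h$e <- st$e

  out <- as.data.frame(trace[seq_len(kept), , drop = FALSE])
  attr(out, "model") <- model
  attr(out, "s_trace") <- s_tr[seq_len(kept), , drop = FALSE]
  attr(out, "e_trace") <- e_tr[seq_len(kept), , drop = FALSE]
  attr(out, "species") <- h$species
  attr(out, "size_class") <- vapply(split(replicate$size_class, replicate$species),
                                    function(x) x[1], "")[h$species]
  attr(out, "acceptance") <- ifelse(tries > 0, acc / tries, NA_real_)
  attr(out, "window") <- window
  attr(out, "replicate_id") <- attr(replicate, "replicate_id")
  attr(out, "final_state") <- list(lambda0 = st$lambda0, q = st$q,
                                   model = st$model, h = h)
  out
}

#' Trapezoid integration of mean log-likelihoods over inverse temperatures
#'
#' The thermodynamic-integration identity: log marginal likelihood =
#' integral over beta in [0,1] of E_beta[log L]. Given per-chain mean
#' log-likelihoods at an ascending beta grid, returns the trapezoid estimate.
#'
#' @param betas ascending inverse temperatures in [0, 1].
#' @param mean_ll mean log-likelihood of the chain run at each beta.
#' @return log marginal likelihood estimate.
#' @export
ti_integrate <- function(betas, mean_ll) {
  stopifnot(length(betas) == length(mean_ll), !is.unsorted(betas))
  if (any(!is.finite(mean_ll))) stop("non-finite mean log-likelihood")
  sum(diff(betas) * (utils::head(mean_ll, -1) + utils::tail(mean_ll, -1)) / 2)
}

#' Inverse-temperature schedule for thermodynamic integration
#'
#' K betas at the quantiles of Beta(0.3, 1), including 0 and 1; the schedule
#' concentrates temperatures near 0 where the integrand changes fastest.
#' @param k number of temperatures (>= 4).
#' @return ascending numeric vector of length k.
#' @export
ti_betas <- function(k) {
  stopifnot(k >= 4)
  stats::qbeta(seq(0, 1, length.out = k), 0.3, 1)
}

#' Marginal likelihood of a model by thermodynamic integration
#'
#' Runs one tempered chain per inverse temperature (independent chains, no
#' swap moves), averages the log-likelihood post burn-in in each, and
#' integrates over beta by the trapezoid rule.
#'
#' @inheritParams run_mcmc
#' @param label model label for the score table (defaults to the model's).
#' @return a \code{model_score}: list with label, logml, mean_ll, betas,
#'   replicate_id.
#' @export
thermodynamic_ml <- function(replicate, model, cfg = mcmc_config(),
                             window = c(4, 0), lambda0 = 0.3, q = 1,
                             bin_width = 0.01, label = model$label) {
  betas <- ti_betas(cfg$ti_categories)
  K <- length(betas)
  mean_ll <- numeric(K)
  # trapezoid node weights: how much each chain's mean contributes
  node_w <- c(diff(betas) / 2, 0) + c(0, diff(betas) / 2)

  # near-prior nodes: the tempered target is essentially the prior, where the
  # chain mixes poorly but iid sampling is trivial -- estimate E_beta[logL]
  # by importance-reweighting iid prior draws (exact at beta = 0)
  prior_nodes <- which(betas < 0.005)
  chain_nodes <- setdiff(seq_len(K), prior_nodes)
  if (length(prior_nodes)) {
    ll0 <- prior_loglik_draws(replicate, model, cfg, window, bin_width,
                              n_draws = 3000,
                              seed = derive_seed(cfg$seed, 999L))
    for (k in prior_nodes) {
      lw <- betas[k] * ll0
      w <- exp(lw - max(lw))
      mean_ll[k] <- sum(w * ll0) / sum(w)
    }
  }

  # chains run from beta = 1 downward, each warm-started from the previous
  # chain's final state; chain length scales with the node's trapezoid
  # weight so sampling effort goes where the integral is most sensitive
  state <- NULL
  for (k in rev(chain_nodes)) {
    ck <- cfg
    ck$thin <- min(cfg$thin, 4L)  # mean log-likelihoods want dense retention
    ck$n_iter <- max(500, round(cfg$n_iter *
                                  min(1.8, max(0.35, node_w[k] / 0.2))))
    # weakly tempered chains explore a much wider latent-time space: widen
    # the sliding-window proposals to keep the random walk mixing
    ck$time_win <- cfg$time_win / sqrt(max(betas[k], 0.05))
    ck$tau_win <- cfg$tau_win / sqrt(max(betas[k], 0.05))
    ck$rate_mult <- cfg$rate_mult / sqrt(max(betas[k], 0.1))
    ck$gamma_sd <- cfg$gamma_sd / sqrt(max(betas[k], 0.1))
    if (!is.null(state)) ck$burnin <- min(cfg$burnin, 0.1)
    else ck$n_iter <- round(1.4 * ck$n_iter)  # cold start pays extra burn-in
    ck$seed <- derive_seed(cfg$seed, 1000L + k)
    tr <- run_mcmc(replicate, model, ck, beta = betas[k], window = window,
                   lambda0 = lambda0, q = q, bin_width = bin_width,
                   init_state = state)
    state <- attr(tr, "final_state")
    mean_ll[k] <- mean(tr$log_lik)
  }
  if (any(!is.finite(mean_ll)))
    stop("non-finite mean log-likelihood at beta = ",
         signif(betas[which(!is.finite(mean_ll))[1]], 3))
  structure(list(label = label, logml = ti_integrate(betas, mean_ll),
                 mean_ll = mean_ll, betas = betas,
                 replicate_id = attr(replicate, "replicate_id")),
            class = "model_score")
}

# iid draws of the log-likelihood under the prior: parameters from their
# priors, latent times uniform within the occurrence constraints
prior_loglik_draws <- function(replicate, model, cfg, window, bin_width,
                               n_draws = 3000, seed = 1) {
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  h <- init_histories(replicate, window)
  ns <- nrow(h)
  ext <- !h$extant
  span <- c(window[1] + cfg$origin_headroom, window[2])
  bins <- make_bins(model, span, bin_width)
  spec <- model_param_spec(model)
  rg <- function(n) stats::rgamma(n, shape = cfg$prior_rate_shape,
                                  rate = cfg$prior_rate_rate)
  e_hi <- h$age_min_obs
  ll <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    lambda0 <- rg(1); q <- rg(1)
    m <- model
    if (model$variant == "shift") {
      m$rates <- rg(length(model$rates))
      if (length(model$shift_times))
        m$shift_times <- sort(stats::runif(length(model$shift_times),
                                           window[2], window[1]),
                              decreasing = TRUE)
    } else m$mu0 <- rg(1)
    if (length(spec$real)) m$gamma <- stats::rnorm(1, 0, cfg$prior_gamma_sd)
    if (model$variant == "covariate_threshold")
      m$tau <- stats::runif(1, window[2], window[1])
    s_hi <- pmax(h$age_max_obs + 0.5, window[1] + cfg$origin_headroom)
    s <- h$age_max_obs + (s_hi - h$age_max_obs) * stats::runif(ns)
    e <- numeric(ns)
    e[ext] <- window[2] + (e_hi[ext] - window[2]) * stats::runif(sum(ext))
    e <- pmin(e, s - 1e-9)
    ll[i] <- pres_ll_total(q, s - e, h$n, cfg$gamma_shape) +
      bd_ll_fast(s, e, ext, lambda0, m, span, bin_width, bins)
  }
  ll
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("model_score [%s] logML = %.3f (replicate %s)\n",
              x$label, x$logml, as.character(x$replicate_id)))
  invisible(x)
}

#' Bayes factor between two model scores (2 ln BF scale)
#'
#' Returns 2 (logML_a - logML_b): > 2 positive, > 6 strong, > 10 very strong
#' support for model a over model b.
#'
#' @param a,b \code{model_score} objects for the same replicate.
#' @return scalar 2 ln BF.
#' @export
bayes_factor <- function(a, b) {
  stopifnot(inherits(a, "model_score"), inherits(b, "model_score"))
  ra <- a$replicate_id; rb <- b$replicate_id
  if (!is.null(ra) && !is.null(rb) && !identical(ra, rb))
    stop("model scores come from different replicates")
  2 * (a$logml - b$logml)
}

#' Relative model probabilities from log marginal likelihoods
#'
#' Softmax of the log MLs (subtract the max, exponentiate, normalise).
#' @param scores list of \code{model_score} objects sharing a replicate.
#' @return named numeric vector of weights summing to 1.
#' @export
relative_probabilities <- function(scores) {
  if (length(scores) == 0L) stop("empty model-score list")
  rid <- unique(lapply(scores, `[[`, "replicate_id"))
  if (length(rid) > 1L) stop("scores must share a replicate_id")
  lml <- vapply(scores, `[[`, 0, "logml")
  w <- exp(lml - max(lml))
  stats::setNames(w / sum(w), vapply(scores, `[[`, "", "label"))
}

#' Rate-through-time summary from posterior traces
#'
#' Evaluates mu(t) at each grid age for every retained posterior sample
#' (re-instantiating the extinction model with that sample's parameters),
#' pooling samples across the supplied traces, and returns the pointwise
#' mean and central 95% credible interval.
#'
#' @param traces list of [run_mcmc()] traces (same model family).
#' @param grid ages (Ma) inside the analysis window.
#' @return data.frame with age, mean, lo, hi.
#' @export
extract_rtt <- function(traces, grid) {
  if (is.data.frame(traces)) traces <- list(traces)
  if (length(traces) == 0L) stop("need at least one trace")
  win <- attr(traces[[1]], "window")
  if (any(grid > win[1] + 1e-9 | grid < win[2] - 1e-9))
    stop("grid outside the analysis window")
  rows <- list()
  for (tr in traces) {
    model <- attr(tr, "model")
    for (i in seq_len(nrow(tr))) {
      m <- trace_row_model(model, tr[i, ])
      rows[[length(rows) + 1L]] <- eval_mu(m, grid)
    }
  }
  M <- do.call(rbind, rows)
  data.frame(age = grid,
             mean = colMeans(M),
             lo = apply(M, 2, stats::quantile, 0.025),
             hi = apply(M, 2, stats::quantile, 0.975))
}

# rebuild an extinction model from one trace row
trace_row_model <- function(model, row) {
  if (model$variant == "shift") {
    k <- length(model$rates)
    model$rates <- as.numeric(row[paste0("rate", seq_len(k))])
    if (length(model$shift_times))
      model$shift_times <- as.numeric(row[paste0("shift", seq_along(model$shift_times))])
  } else {
    model$mu0 <- row[["mu0"]]
    if (!is.null(model$gamma) && "gamma" %in% names(row)) model$gamma <- row[["gamma"]]
    if (model$variant == "covariate_threshold") model$tau <- row[["tau"]]
  }
  model
}

#' Generic Metropolis-Hastings chain on a user-supplied target
#'
#' A small general-purpose sampler used for calibration tests (e.g. conjugate
#' toys with known marginal likelihood). The target is
#' prior x likelihood^beta.
#'
#' @param init named numeric initial state.
#' @param log_prior function(state) -> log prior density.
#' @param log_lik function(state) -> log likelihood.
#' @param propose function(state) -> list(state, log_hastings).
#' @param n_iter iterations.
#' @param beta inverse temperature.
#' @param seed RNG seed.
#' @param burnin burn-in fraction.
#' @return data.frame with the state components and \code{log_lik}.
#' @export
mh_chain <- function(init, log_prior, log_lik, propose, n_iter = 5000,
                     beta = 1, seed = 1, burnin = 0.1) {
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  st <- init
  lp <- log_prior(st); ll <- log_lik(st)
  keep_from <- ceiling(n_iter * burnin)
  out <- matrix(NA_real_, n_iter - keep_from, length(init) + 1,
                dimnames = list(NULL, c(names(init), "log_lik")))
  kept <- 0L
  for (it in seq_len(n_iter)) {
    pr <- propose(st)
    lp2 <- log_prior(pr$state)
    if (is.finite(lp2)) {
      ll2 <- log_lik(pr$state)
      a <- (lp2 + beta * ll2) - (lp + beta * ll) + pr$log_hastings
      if (is.finite(a) && log(stats::runif(1)) < a) {
        st <- pr$state; lp <- lp2; ll <- ll2
      }
    }
    if (it > keep_from) {
      kept <- kept + 1L
      out[kept, ] <- c(st, ll)
    }
  }
  as.data.frame(out[seq_len(kept), , drop = FALSE])
}
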