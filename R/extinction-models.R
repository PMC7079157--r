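#' Extinction-rate models
#'
#' Constructors for the extinction-rate families compared by the pipeline.
#' Time runs backward in Ma before present, so "after" a threshold time tau
#' means ages t < tau numerically.
#'
#' \describe{
#'   \item{constant}{mu(t) = mu0.}
#'   \item{shift}{piecewise-constant: k shift times inside the window and
#'     k+1 rates, oldest regime first.}
#'   \item{covariate}{mu driven by a predictor curve through a linear link
#'     mu0 * (1 + gamma * x~(t)), floored at 1e-5, or an exponential link
#'     mu0 * exp(gamma * x~(t)); x~ is the centred covariate.}
#'   \item{covariate_threshold}{mu = mu0 for t > tau; for t <= tau the
#'     covariate link applies with the curve re-centred at x(tau), so the
#'     rate is continuous at tau.}
#' }
#'
#' @param mu0 baseline extinction rate (events/lineage/Myr), > 0.
#' @param shift_times ages (Ma) of rate shifts, strictly inside the window.
#' @param rates k+1 regime rates, oldest first.
#' @param link \code{"linear"} or \code{"exponential"}.
#' @param gamma covariate effect size.
#' @param curve a \code{predictor_curve} supplying x(t).
#' @param tau threshold age (Ma).
#' @param label optional model label used in score tables.
#' @return an object of class \code{extinction_model}.
#' @name extinction_models
NULL

MU_FLOOR <- 1e-5

#' @rdname extinction_models
#' @export
mu_constant <- function(mu0, label = "constant") {
  stopifnot(mu0 > 0)
  structure(list(variant = "constant", mu0 = mu0, label = label),
            class = "extinction_model")
}

#' @rdname extinction_models
#' @export
mu_shift <- function(shift_times, rates, label = NULL) {
  stopifnot(length(rates) == length(shift_times) + 1L, all(rates > 0))
  if (is.unsorted(rev(shift_times)) && is.unsorted(shift_times))
    stop("shift_times must be sorted")
  st <- sort(shift_times, decreasing = TRUE)  # oldest first
  if (is.null(label)) label <- sprintf("shift%d", length(st))
  structure(list(variant = "shift", shift_times = st, rates = rates,
                 label = label),
            class = "extinction_model")
}

#' @rdname extinction_models
#' @export
mu_covariate <- function(link = c("linear", "exponential"), mu0, gamma, curve,
                         label = NULL) {
  link <- match.arg(link)
  stopifnot(mu0 > 0, inherits(curve, "predictor_curve"))
  if (is.null(label)) label <- paste0("covariate_", link)
  structure(list(variant = "covariate", link = link, mu0 = mu0,
                 gamma = gamma, curve = curve, label = label),
            class = "extinction_model")
}

#' @rdname extinction_models
#' @export
mu_threshold <- function(link = c("linear", "exponential"), mu0, gamma, tau,
                         curve, label = NULL) {
  link <- match.arg(link)
  stopifnot(mu0 > 0, inherits(curve, "predictor_curve"))
  if (is.null(label)) label <- paste0("threshold_", link)
  structure(list(variant = "covariate_threshold", link = link, mu0 = mu0,
                 gamma = gamma, tau = tau, curve = curve, label = label),
            class = "extinction_model")
}

#' @export
print.extinction_model <- function(x, ...) {
  cat("extinction_model [", x$label, "] variant:", x$variant, "\n")
  invisible(x)
}

#' Evaluate an extinction model at given ages
#'
#' @param model an \code{extinction_model}.
#' @param t ages (Ma); for covariate variants they must lie on the curve grid.
#' @return extinction rates (events/lineage/Myr), strictly positive.
#' @export
eval_mu <- function(model, t) {
  switch(model$variant,
    constant = rep(model$mu0, length(t)),
    shift = {
      # regimes: oldest first; regime index = 1 + number of shifts older than t
      idx <- 1L + vapply(t, function(ti) sum(model$shift_times > ti), 0L)
      model$rates[idx]
    },
    covariate = {
      x <- covariate_value(model$curve, t)
      mu_link(model$link, model$mu0, model$gamma, x)
    },
    covariate_threshold = {
      # constant before the threshold (t > tau, i.e. older), covariate-driven
      # after it; the pre-threshold rate is pinned to the link value at tau so
      # mu is continuous there, and tau at the old window edge recovers the
      # plain covariate model exactly
      x <- covariate_value(model$curve, t)
      x_tau <- covariate_value(model$curve, model$tau)
      recent <- t <= model$tau
      out <- rep(mu_link(model$link, model$mu0, model$gamma, x_tau), length(t))
      if (any(recent))
        out[recent] <- mu_link(model$link, model$mu0, model$gamma, x[recent])
      out
    },
    stop("unknown extinction model variant: ", model$variant)
  )
}

mu_link <- function(link, mu0, gamma, x) {
  if (link == "linear") pmax(mu0 * (1 + gamma * x), MU_FLOOR)
  else mu0 * exp(gamma * x)
}

# Replace the free parameters of a model from a named numeric vector
# (mu0/gamma/tau for covariate variants; rates/shift_times for shift).
# Used by the MCMC to propose in parameter space without rebuilding objects.
set_model_params <- function(model, par) {
  for (nm in names(par)) {
    if (nm == "rates" || nm == "shift_times") model[[nm]] <- par[[nm]]
    else model[[nm]] <- unname(par[[nm]])
  }
  model
}

# Free-parameter template for each variant: names, positivity, and priors are
# resolved by the sampler from this description.
model_param_spec <- function(model) {
  switch(model$variant,
    constant = list(positive = "mu0", real = character(), times = character()),
    shift = list(positive = "rates", real = character(), times = "shift_times"),
    covariate = list(positive = "mu0", real = "gamma", times = character()),
    covariate_threshold = list(positive = "mu0", real = "gamma", times = "tau")
  )
}
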