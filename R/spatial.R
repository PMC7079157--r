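#' Construct a spatial dataset
#'
#' Wraps per-cell data for the contemporary spatial regression: centroids,
#' the response (fraction of large carnivores), raw predictors and their
#' standardised copies (mean 0, SD 1; prefixed \code{z_}). The response is
#' standardised too (column \code{z_y}), matching regressions run with both
#' dependent and independent variables standardised.
#'
#' @param df data.frame with columns lon, lat, the response and predictors.
#' @param predictors character vector of predictor column names.
#' @param response response column name.
#' @return data.frame of class \code{spatial_dataset} with standardisation
#'   constants in attributes \code{center} and \code{scale}.
#' @export
new_spatial_dataset <- function(df, predictors, response = "fraction_large") {
  stopifnot(all(c("lon", "lat", response, predictors) %in% names(df)))
  ctr <- vapply(df[c(response, predictors)], mean, 0)
  scl <- vapply(df[c(response, predictors)], stats::sd, 0)
  if (any(scl[predictors] == 0))
    stop("zero-variance predictor; cannot standardise")
  # a constant response (e.g. a degenerate simulation) is centred only
  if (scl[[response]] == 0) scl[[response]] <- 1
  df$z_y <- (df[[response]] - ctr[[response]]) / scl[[response]]
  for (p in predictors) df[[paste0("z_", p)]] <- (df[[p]] - ctr[[p]]) / scl[[p]]
  structure(df, class = c("spatial_dataset", "data.frame"),
            predictors = predictors, response = response,
            center = ctr, scale = scl)
}

#' Build the spatial dataset from a presence matrix
#'
#' Computes the per-cell fraction of large carnivores (body mass above the
#' 21 kg threshold) from a cell x species presence matrix and per-species
#' body masses, joins per-cell predictor values, and standardises. Cells
#' with zero species are dropped and counted; retained cells with a missing
#' predictor are dropped with a warning.
#'
#' @param presence logical/0-1 matrix, cells in rows, species in columns.
#' @param body_mass named numeric vector of body masses (kg) per species.
#' @param cells data.frame with lon, lat and one column per predictor,
#'   rows aligned with \code{presence}.
#' @param predictors predictor column names in \code{cells}.
#' @param threshold_kg large/small body-mass threshold (default 21).
#' @return a \code{spatial_dataset}; attribute \code{n_dropped_empty} counts
#'   zero-species cells removed.
#' @export
build_grid <- function(presence, body_mass, cells, predictors,
                       threshold_kg = 21) {
  stopifnot(nrow(presence) == nrow(cells),
            all(colnames(presence) %in% names(body_mass)))
  large <- body_mass[colnames(presence)] > threshold_kg
  n_sp <- rowSums(presence > 0)
  n_large <- rowSums(presence[, large, drop = FALSE] > 0)
  keep <- n_sp > 0
  n_empty <- sum(!keep)
  df <- cells[keep, , drop = FALSE]
  df$fraction_large <- n_large[keep] / n_sp[keep]
  miss <- !stats::complete.cases(df[predictors])
  if (any(miss)) {
    warning("dropping ", sum(miss), " cell(s) with missing predictor values")
    df <- df[!miss, , drop = FALSE]
  }
  ds <- new_spatial_dataset(df, predictors)
  attr(ds, "n_dropped_empty") <- n_empty
  ds
}

#' Ordinary least squares fit on the standardised dataset
#'
#' Classical linear regression of the standardised response on the
#' standardised predictors, with Gaussian AIC and pseudo-R-squared (squared
#' correlation of fitted fixed effects with the response; identical to the
#' usual R-squared for OLS).
#'
#' @param ds a \code{spatial_dataset}.
#' @return list of class \code{regression_fit}: coefficients (with
#'   intercept), SEs, sar_lambda (NA), pseudo_r2, aic, loglik, neighborhood.
#' @export
fit_linear <- function(ds) {
  preds <- attr(ds, "predictors")
  zx <- as.matrix(as.data.frame(ds)[paste0("z_", preds)])
  if (nrow(zx) <= ncol(zx) + 1) stop("need more cells than predictors")
  if (kappa(cbind(1, zx)) > 1e10) stop("collinear predictors")
  y <- ds$z_y
  fit <- stats::lm(y ~ zx)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  names(beta) <- names(se) <- c("(Intercept)", preds)
  yhat <- stats::fitted(fit)
  structure(list(coefficients = beta, se = se, sar_lambda = NA_real_,
                 lambda_se = NA_real_,
                 pseudo_r2 = stats::cor(y, yhat)^2,
                 aic = stats::AIC(fit), loglik = as.numeric(stats::logLik(fit)),
                 neighborhood = NULL, fitted_fixed = yhat, method = "ols"),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat("regression_fit (", x$method, ")\n", sep = "")
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  if (!is.na(x$sar_lambda))
    cat(sprintf("sar_lambda = %.4f\n", x$sar_lambda))
  cat(sprintf("pseudo_R2 = %.4f  AIC = %.2f\n", x$pseudo_r2, x$aic))
  invisible(x)
}

#' Candidate neighbourhood specifications
#'
#' The 40 candidates searched for the SAR error model: k nearest neighbours
#' for k = 1..10 (row-standardised), and all combinations of distance bands
#' (cells up to 250, 500, 750, 1000, 1250 or 1500 km away) with five standard
#' weighting schemes: \code{"B"} binary, \code{"W"} row-standardised,
#' \code{"C"} globally standardised (weights sum to n), \code{"U"} unit sum,
#' and \code{"S"} variance-stabilising.
#'
#' @return list of \code{nb_spec} objects (length 40).
#' @export
neighborhood_candidates <- function() {
  out <- lapply(1:10, function(k)
    structure(list(kind = "knn", k = k, scheme = "W",
                   label = sprintf("knn%02d", k)), class = "nb_spec"))
  for (cut in c(250, 500, 750, 1000, 1250, 1500))
    for (sch in c("B", "W", "C", "U", "S"))
      out[[length(out) + 1L]] <- structure(
        list(kind = "band", cutoff = cut, scheme = sch,
             label = sprintf("band%04d_%s", cut, sch)), class = "nb_spec")
  out
}

#' Spatial weights matrix for a neighbourhood spec
#'
#' Neighbour links are defined on great-circle distances between cell
#' centroids (the km cutoffs are physical distances on the sphere, not
#' projected ones). Weighting schemes follow the standard definitions:
#' B binary; W row-standardised; C globally standardised so all weights sum
#' to n; U so they sum to 1; S variance-stabilising (rows scaled by the root
#' sum of squared weights, then globally rescaled to sum to n).
#'
#' @param ds a \code{spatial_dataset} (uses lon/lat).
#' @param spec an \code{nb_spec} from [neighborhood_candidates()].
#' @return n x n weights matrix; attribute \code{n_isolated} counts
#'   zero-neighbour cells (their rows are zero and the caller should drop
#'   them).
#' @export
spatial_weights <- function(ds, spec) {
  coords <- cbind(ds$lon, ds$lat)
  n <- nrow(coords)
  D <- geosphere::distm(coords) / 1000  # km
  A <- matrix(0, n, n)
  if (spec$kind == "knn") {
    for (i in seq_len(n)) {
      ord <- order(D[i, -i])
      nb <- setdiff(order(D[i, ]), i)[seq_len(spec$k)]
      A[i, nb] <- 1
    }
  } else {
    A[D <= spec$cutoff] <- 1
    diag(A) <- 0
  }
  iso <- rowSums(A) == 0
  W <- switch(spec$scheme,
    B = A,
    W = A / pmax(rowSums(A), 1),
    C = A * (sum(!iso) / max(sum(A), 1)),
    U = A / max(sum(A), 1),
    S = {
      qd <- sqrt(rowSums(A^2))
      S0 <- A / ifelse(qd > 0, qd, 1)
      S0 * (sum(!iso) / sum(S0))
    },
    stop("unknown weighting scheme: ", spec$scheme))
  attr(W, "n_isolated") <- sum(iso)
  W
}

#' Maximum-likelihood SAR error model fit
#'
#' Fits y = X beta + u, u = lambda W u + eps by profile maximum likelihood:
#' for each lambda, beta and sigma^2 are profiled out by GLS with
#' A = I - lambda W, and the profile log-likelihood
#' ln|A| - n/2 (ln(2 pi sigma^2(lambda)) + 1) is maximised over lambda inside
#' the interval bounded by the reciprocal extreme eigenvalues of W (the
#' log-determinant uses the eigenvalues of W). Cells left with no neighbours
#' are dropped with a warning (the SAR likelihood is undefined for them).
#' Pseudo-R-squared is computed from the fixed effects X beta only.
#'
#' @param ds a \code{spatial_dataset}.
#' @param nb an \code{nb_spec}, or a precomputed weights matrix.
#' @param fix_lambda optional fixed value for lambda (no optimisation);
#'   \code{fix_lambda = 0} reduces the fit exactly to OLS.
#' @return a \code{regression_fit} with sar_lambda and its asymptotic SE.
#' @export
fit_sar_error <- function(ds, nb, fix_lambda = NULL) {
  preds <- attr(ds, "predictors")
  W <- if (is.matrix(nb)) nb else spatial_weights(ds, nb)
  keep <- rowSums(abs(W)) > 0 | colSums(abs(W)) > 0
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " isolated cell(s) for the SAR fit")
    ds2 <- as.data.frame(ds)[keep, , drop = FALSE]
    ds <- new_spatial_dataset(ds2, predictors = preds,
                              response = attr(ds, "response"))
    W <- W[keep, keep, drop = FALSE]
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(ds)[paste0("z_", preds)]))
  y <- ds$z_y
  n <- length(y)
  ev <- eigen(W, only.values = TRUE)$values
  emax <- max(Re(ev)); emin <- min(Re(ev))
  lo <- if (emin < 0) 1 / emin + 1e-6 else -0.999
  hi <- if (emax > 0) 1 / emax - 1e-6 else 0.999
  if (!(lo < 0 && hi > 0)) stop("degenerate eigenvalue bounds for W")

  prof <- function(lambda) {
    A <- diag(n) - lambda * W
    Ay <- A %*% y; AX <- A %*% X
    qr_ <- qr(AX)
    if (qr_$rank < ncol(X)) return(-Inf)
    beta <- qr.coef(qr_, Ay)
    r <- Ay - AX %*% beta
    s2 <- sum(r^2) / n
    ld <- sum(log(Mod(1 - lambda * ev)))
    ld - n / 2 * (log(2 * pi * s2) + 1)
  }
  if (is.null(fix_lambda)) {
    opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-8)
    lambda <- opt$maximum
    if (min(lambda - lo, hi - lambda) < 1e-4)
      warning("sar_lambda at the search boundary")
  } else {
    lambda <- fix_lambda
    opt <- list(maximum = lambda, objective = prof(lambda))
  }
  A <- diag(n) - lambda * W
  Ay <- A %*% y; AX <- A %*% X
  qr_ <- qr(AX)
  beta <- drop(qr.coef(qr_, Ay))
  r <- Ay - AX %*% beta
  s2 <- sum(r^2) / n
  XtX <- crossprod(AX)
  se <- sqrt(diag(s2 * solve(XtX)))
  names(beta) <- names(se) <- c("(Intercept)", preds)
  # numeric curvature of the profile likelihood for lambda's SE
  h <- min(1e-4, (hi - lo) / 100)
  d2 <- (prof(lambda + h) - 2 * opt$objective + prof(lambda - h)) / h^2
  lambda_se <- if (is.null(fix_lambda) && is.finite(d2) && d2 < 0)
    sqrt(-1 / d2) else NA_real_
  ll <- opt$objective
  k_par <- ncol(X) + 2  # betas + sigma2 + lambda
  yhat <- drop(X %*% beta)
  structure(list(coefficients = beta, se = se, sar_lambda = lambda,
                 lambda_se = lambda_se,
                 pseudo_r2 = stats::cor(y, yhat)^2,
                 aic = -2 * ll + 2 * k_par, loglik = ll,
                 neighborhood = if (is.matrix(nb)) NULL else nb,
                 fitted_fixed = yhat, method = "sar_error"),
            class = "regression_fit")
}

#' AIC search over the 40 candidate neighbourhoods
#'
#' Fits the SAR error model under every candidate spec and returns the
#' minimum-AIC winner (ties broken by fewer neighbours, then by the roster
#' order of [neighborhood_candidates()]) plus the full AIC table. Candidates
#' that fail to fit are excluded and recorded.
#'
#' @param ds a \code{spatial_dataset}.
#' @param candidates list of \code{nb_spec}s (default all 40).
#' @return list with \code{best} (nb_spec), \code{best_fit}
#'   (regression_fit), \code{table} (label, kind, size, scheme, aic, lambda),
#'   \code{failed} (labels).
#' @export
select_neighborhood <- function(ds, candidates = neighborhood_candidates()) {
  if (!length(candidates)) stop("no candidates supplied")
  rows <- list(); fits <- list(); failed <- character()
  for (i in seq_along(candidates)) {
    sp <- candidates[[i]]
    f <- tryCatch(suppressWarnings(fit_sar_error(ds, sp)),
                  error = function(e) NULL)
    if (is.null(f)) { failed <- c(failed, sp$label); next }
    rows[[length(rows) + 1L]] <- data.frame(
      label = sp$label, kind = sp$kind,
      size = if (sp$kind == "knn") sp$k else sp$cutoff,
      scheme = sp$scheme, aic = f$aic, sar_lambda = f$sar_lambda,
      order = i, stringsAsFactors = FALSE)
    fits[[sp$label]] <- f
  }
  if (!length(rows)) stop("all neighbourhood candidates failed")
  tab <- do.call(rbind, rows)
  # schemes that differ only by a scalar factor (B/C/U) give identical
  # likelihoods; round the AIC so the documented tie-break actually engages
  tab <- tab[order(round(tab$aic, 6), tab$size, tab$order), ]
  best_label <- tab$label[1]
  best <- candidates[[tab$order[1]]]
  list(best = best, best_fit = fits[[best_label]],
       table = tab[, c("label", "kind", "size", "scheme", "aic", "sar_lambda")],
       failed = failed)
}

#' Back-cast the large-carnivore fraction from palaeo predictor curves
#'
#' Projects the contemporary regression into the past: for each age t,
#' each palaeo curve is standardised by the contemporary mean/SD of the
#' matching predictor, multiplied by that predictor's fitted coefficient and
#' summed; the resulting line is then shifted by a constant so the predicted
#' value at the anchor age equals the anchor value (the interest is in
#' temporal change, not absolute level). Predictors without a palaeo curve
#' (e.g. human footprint) are simply absent from the sum.
#'
#' @param fit a \code{regression_fit} (typically the OLS fit).
#' @param paleo_curves named list of \code{predictor_curve}s; names must be
#'   predictors of the fit.
#' @param standardization the fitted dataset (a \code{spatial_dataset}) or a
#'   list with \code{center}/\code{scale} supplying contemporary constants.
#' @param anchor \code{c(age, value)}: age (Ma) and value to pin.
#' @param grid ages (Ma) at which to predict.
#' @return data.frame with age and predicted fraction (response scale of the
#'   anchor); attribute \code{contributions} holds the per-predictor
#'   standardised ranges over the grid.
#' @export
backcast_fraction <- function(fit, paleo_curves, standardization,
                              anchor = c(4, 0.5), grid = seq(0, 4, by = 0.01)) {
  ctr <- attr(standardization, "center")
  scl <- attr(standardization, "scale")
  if (is.null(ctr) || is.null(scl)) {
    ctr <- standardization$center; scl <- standardization$scale
  }
  if (is.null(ctr) || is.null(scl))
    stop("missing contemporary standardisation constants")
  beta <- fit$coefficients
  resp <- attr(standardization, "response")
  if (is.null(resp)) resp <- names(ctr)[1]
  pred <- rep(0, length(grid))
  contrib <- list()
  for (nm in names(paleo_curves)) {
    if (!nm %in% names(beta)) next
    if (!nm %in% names(ctr))
      stop("no contemporary standardisation constants for predictor: ", nm)
    raw <- stats::approx(paleo_curves[[nm]]$grid, paleo_curves[[nm]]$values,
                         xout = grid, rule = 2)$y
    z <- (raw - ctr[[nm]]) / scl[[nm]]
    part <- beta[[nm]] * z
    pred <- pred + part
    contrib[[nm]] <- range(part)
  }
  # the fit is on the standardised response; convert back to response units
  pred <- pred * scl[[resp]]
  at_anchor <- stats::approx(grid, pred, xout = anchor[1], rule = 2)$y
  out <- data.frame(age = grid, predicted = pred - at_anchor + anchor[2])
  attr(out, "contributions") <- contrib
  out
}
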