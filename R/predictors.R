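#' Construct a predictor curve object
#'
#' A temporal predictor curve x(t) on a fixed age grid, as used as a covariate
#' in the extinction-rate models. The curve stores its own centering constants
#' so that covariate links operate on the mean-centred (optionally
#' SD-scaled) value, making the baseline rate interpretable as the rate at the
#' mean covariate value.
#'
#' @param grid ascending ages (Ma).
#' @param values predictor values on the grid (no missing values).
#' @param n_resamples number of loess resamples that produced the curve.
#' @param span loess span used.
#' @param scale if TRUE the centred curve is also divided by its SD.
#' @param extrapolated logical vector flagging grid points filled by constant
#'   extrapolation beyond the outermost resampled measurement age.
#' @return an object of class \code{predictor_curve}.
#' @export
new_predictor_curve <- function(grid, values, n_resamples = NA_integer_,
                                span = NA_real_, scale = FALSE,
                                extrapolated = rep(FALSE, length(grid))) {
  stopifnot(length(grid) == length(values), !is.unsorted(grid),
            all(is.finite(values)))
  ctr <- mean(values)
  scl <- if (scale) stats::sd(values) else 1
  structure(
    list(grid = as.numeric(grid), values = as.numeric(values),
         n_resamples = n_resamples, span = span,
         center = ctr, scale = scl, extrapolated = extrapolated),
    class = "predictor_curve")
}

#' @export
print.predictor_curve <- function(x, ...) {
  cat(sprintf(
    "predictor_curve: %d grid points, %.2f-%.2f Ma, value range [%.4g, %.4g]\n",
    length(x$grid), min(x$grid), max(x$grid), min(x$values), max(x$values)))
  if (!is.na(x$n_resamples))
    cat(sprintf("  median of %d loess resamples (span %.2f)\n",
                x$n_resamples, x$span))
  if (any(x$extrapolated))
    cat(sprintf("  %d grid points constant-extrapolated beyond data\n",
                sum(x$extrapolated)))
  invisible(x)
}

#' Centred covariate value x~(t)
#'
#' Linear interpolation of the curve at time \code{t}, centred (and scaled,
#' if the curve was built with scaling) by the curve's stored constants.
#'
#' @param curve a \code{predictor_curve}.
#' @param t ages (Ma); must lie within the curve's grid.
#' @return numeric vector of centred covariate values.
#' @export
covariate_value <- function(curve, t) {
  if (any(t < min(curve$grid) - 1e-9 | t > max(curve$grid) + 1e-9))
    stop("time outside the predictor curve grid")
  v <- stats::approx(curve$grid, curve$values, xout = t, rule = 2)$y
  (v - curve$center) / curve$scale
}

#' Build a predictor curve by date-resampled loess smoothing
#'
#' Turns dated proxy measurements (value + age interval) into a temporal
#' predictor curve: for each of \code{n_resamples} resamples, every
#' measurement's age is drawn uniformly within its dating interval, a loess
#' regression of value on age is fitted (degree 2, tricube weights), and the
#' fit is evaluated on the grid; the returned curve is the pointwise median
#' across resamples. Grid points beyond the outermost resampled age in a given
#' resample are filled by constant extrapolation from the nearest fitted value
#' and flagged in the result's metadata.
#'
#' @param measurements data.frame with columns \code{value}, \code{age_min},
#'   \code{age_max} (Ma).
#' @param grid evaluation ages (Ma), ascending; default 0-4 Ma in 0.01 steps.
#' @param n_resamples number of age resamples (default 1000).
#' @param span loess span fraction (default 0.75).
#' @param degree loess polynomial degree (default 2).
#' @param seed RNG seed for the age resampling.
#' @param scale passed to [new_predictor_curve()].
#' @return a \code{predictor_curve}.
#' @export
build_predictor <- function(measurements, grid = seq(0, 4, by = 0.01),
                            n_resamples = 1000, span = 0.75, degree = 2,
                            seed = 1, scale = FALSE) {
  stopifnot(is.data.frame(measurements))
  m <- measurements
  if (nrow(m) < 4L)
    stop("need at least 4 measurements to fit a loess curve")
  if (any(m$age_min > m$age_max)) stop("age_min > age_max in measurements")
  if (any(!is.finite(m$value))) stop("non-finite measurement values")
  n <- nrow(m)
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  preds <- matrix(NA_real_, n_resamples, length(grid))
  extrap <- rep(FALSE, length(grid))
  for (r in seq_len(n_resamples)) {
    ages <- stats::runif(n, m$age_min, m$age_max)
    fit <- suppressWarnings(stats::loess(
      m$value ~ ages, span = span, degree = degree,
      control = stats::loess.control(surface = "direct")))
    inside <- grid >= min(ages) & grid <= max(ages)
    y <- rep(NA_real_, length(grid))
    y[inside] <- suppressWarnings(stats::predict(fit, data.frame(ages = grid[inside])))
    # constant extrapolation outside the resampled age range
    if (any(!inside)) {
      extrap <- extrap | !inside
      lo <- grid < min(ages)
      hi <- grid > max(ages)
      if (any(inside)) {
        y[lo] <- y[which(inside)[1]]
        y[hi] <- y[which(inside)[length(which(inside))]]
      } else {
        y[] <- suppressWarnings(stats::predict(fit, data.frame(ages = mean(ages))))
      }
    }
    preds[r, ] <- y
  }
  med <- apply(preds, 2, stats::median)
  if (any(!is.finite(med))) stop("loess median curve contains non-finite values")
  new_predictor_curve(grid, med, n_resamples = n_resamples, span = span,
                      scale = scale, extrapolated = extrap)
}

#' Squared Pearson correlation between two predictor curves
#'
#' @param a,b \code{predictor_curve} objects on identical grids.
#' @return r-squared in [0, 1].
#' @export
predictor_r2 <- function(a, b) {
  stopifnot(inherits(a, "predictor_curve"), inherits(b, "predictor_curve"))
  if (length(a$grid) != length(b$grid) ||
      any(abs(a$grid - b$grid) > 1e-9))
    stop("curves must share an identical grid")
  if (stats::sd(a$values) == 0 || stats::sd(b$values) == 0)
    stop("zero variance in a curve; r-squared undefined")
  stats::cor(a$values, b$values)^2
}

# seed scoping helpers: run a block under a given seed without disturbing the
# caller's RNG stream
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
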