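#' Simulation configuration
#'
#' Bundles the knobs for the three synthetic generators: fossil records
#' (birth-death with Poisson preservation and site-age uncertainty), dated
#' proxy curves, and spatial grids with known regression coefficients and
#' SAR error autocorrelation.
#'
#' @param seed integer; fixing it makes every generator byte-identical.
#' @param n_species_target intended number of root lineages in the fossil
#'   simulation (the sampled species count fluctuates around it).
#' @param window \code{c(old, young)} Ma with old > young >= 0.
#' @param lambda0 speciation rate (events/lineage/Myr).
#' @param mu_model an \code{extinction_model} giving mu(t).
#' @param q preservation rate (occurrences/lineage/Myr), > 0.
#' @param age_error_width width (Myr) of the dating interval wrapped around
#'   each true occurrence age.
#' @param grid_dims \code{c(rows, cols)} of the spatial grid (>= 5 each).
#' @param beta_true spatial regression coefficients (standardised scale).
#' @param sar_lambda_true spatial error autocorrelation, |value| < 1.
#' @param noise_sd residual SD for proxy and spatial noise.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1, n_species_target = 60, window = c(4, 0),
                       lambda0 = 0.25, mu_model = mu_constant(0.25), q = 2,
                       age_error_width = 0.3, grid_dims = c(10, 10),
                       beta_true = c(-0.3, 0, -0.3), sar_lambda_true = 0.5,
                       noise_sd = 0.5) {
  stopifnot(window[1] > window[2], window[2] >= 0, q > 0,
            abs(sar_lambda_true) < 1, n_species_target >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Forward-simulate a fossil occurrence record
#'
#' Simulates a birth-death process forward in time across the window
#' (exponential waiting times; time-inhomogeneous extinction via thinning
#' against the envelope max mu over the window), starting from
#' \code{n_species_target} root lineages at the old edge, with speciation at
#' rate lambda0 spawning new lineages. Each lineage drops fossil occurrences
#' as a Poisson process with rate q over its lifespan; lineages with zero
#' occurrences are discarded (they are unobservable). Each surviving
#' occurrence's true age is wrapped in a dating interval of width
#' \code{age_error_width} containing it. The simulation conditions on at
#' least one sampled lineage by rejection and reports the rejection count.
#'
#' @param cfg a [sim_config()].
#' @param size_class size class stamped on the simulated species
#'   (\code{"large"} or \code{"small"}).
#' @param preservation \code{"conditioned"} (default) draws each lineage's
#'   occurrence count from the zero-truncated Poisson, i.e. conditions every
#'   lineage on being sampled -- exactly the conditioning the inference
#'   applies, so recovery experiments are calibrated. \code{"thinned"} draws
#'   plain Poisson counts and discards unsampled lineages; this emulates the
#'   real observation process, in which short-lived lineages (concentrated
#'   near the window edges) silently vanish from the record.
#' @param max_rejections rejection budget before giving up.
#' @return list with \code{occurrences} (observable table: species, site,
#'   age_min, age_max, size_class, extant), \code{truth} (latent s, e, n of
#'   the sampled lineages), \code{truth_all} (all simulated lineages,
#'   including unsampled ones with n = 0), \code{truth_occurrences} (true
#'   occurrence ages with their dating intervals), and \code{rejections}.
#' @export
simulate_fossil_record <- function(cfg, size_class = "large",
                                   preservation = c("conditioned", "thinned"),
                                   max_rejections = 100L) {
  preservation <- match.arg(preservation)
  stopifnot(inherits(cfg, "sim_config"))
  old <- cfg$window[1]; young <- cfg$window[2]
  if (old <= young) stop("degenerate window")
  old_seed <- set_local_seed(cfg$seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  mu_max <- max(eval_mu(cfg$mu_model, seq(young, old, length.out = 401)))

  for (rej in 0:max_rejections) {
    # event-driven forward simulation; ages decrease from old to young
    births <- rep(old, cfg$n_species_target)  # root lineages enter at the edge
    s_out <- numeric(0); e_out <- numeric(0)
    queue <- births
    while (length(queue)) {
      t0 <- queue[1]; queue <- queue[-1]
      t <- t0
      repeat {
        wait <- stats::rexp(1, cfg$lambda0 + mu_max)
        t_next <- t - wait
        if (t_next <= young) { s_out <- c(s_out, t0); e_out <- c(e_out, young); break }
        if (stats::runif(1) < cfg$lambda0 / (cfg$lambda0 + mu_max)) {
          queue <- c(queue, t_next)      # speciation: daughter lineage
          t <- t_next
        } else {
          # candidate extinction; thinning against the envelope
          if (stats::runif(1) < eval_mu(cfg$mu_model, t_next) / mu_max) {
            s_out <- c(s_out, t0); e_out <- c(e_out, t_next); break
          }
          t <- t_next
        }
      }
      if (length(s_out) > 5000L) stop("runaway birth-death simulation")
    }
    # Poisson preservation over each lifespan
    d <- s_out - e_out
    if (preservation == "conditioned") {
      # zero-truncated Poisson via the inverse cdf
      u <- stats::runif(length(d), stats::ppois(0, cfg$q * d), 1)
      n_occ <- stats::qpois(pmin(u, 1 - 1e-16), cfg$q * d)
      n_occ <- pmax(n_occ, 1L)
    } else {
      n_occ <- stats::rpois(length(d), cfg$q * d)
    }
    keep <- n_occ > 0L
    if (!any(keep)) next
    sp_id <- sprintf("sp%03d", seq_along(s_out))
    rows <- list()
    for (i in which(keep)) {
      ages <- stats::runif(n_occ[i], e_out[i], s_out[i])
      u <- stats::runif(n_occ[i], 0, cfg$age_error_width)
      amin <- pmax(0, ages - u)
      amax <- amin + cfg$age_error_width
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp_id[i],
        true_age = ages, age_min = amin, age_max = amax,
        stringsAsFactors = FALSE)
    }
    occ <- do.call(rbind, rows)
    occ$site <- sprintf("site%03d",
                        sample.int(max(3L, nrow(occ) %/% 3L), nrow(occ), replace = TRUE))
    occ$size_class <- size_class
    extant_sp <- sp_id[keep][e_out[keep] <= young + 1e-12]
    occ$extant <- occ$species %in% extant_sp
    truth <- data.frame(species = sp_id[keep], s = s_out[keep], e = e_out[keep],
                        n = n_occ[keep], stringsAsFactors = FALSE)
    truth_all <- data.frame(species = sp_id, s = s_out, e = e_out, n = n_occ,
                            stringsAsFactors = FALSE)
    observable <- occ[, c("species", "site", "age_min", "age_max",
                          "size_class", "extant")]
    truth_occ <- occ[, c("species", "true_age", "age_min", "age_max")]
    return(list(occurrences = validate_occurrences(observable),
                truth = truth, truth_all = truth_all,
                truth_occurrences = truth_occ,
                rejections = rej))
  }
  stop("empty record: no lineage sampled after ", max_rejections, " rejections")
}

#' Simulate a dated proxy measurement table
#'
#' Emulates a palaeo proxy series: measurement times spread over the window,
#' values = true_curve(t) + Gaussian noise, and symmetric dating intervals of
#' half-width \code{dating_half_width} around each true time.
#'
#' @param true_curve function of age (Ma) returning the noiseless proxy value.
#' @param n_points number of measurements (>= 3).
#' @param dating_half_width half-width (Myr) of each dating interval, >= 0.
#' @param noise_sd measurement noise SD.
#' @param seed RNG seed.
#' @param window \code{c(old, young)} Ma over which times are spread.
#' @return data.frame with value, age_min, age_max (and true_age).
#' @export
simulate_proxy <- function(true_curve, n_points, dating_half_width = 0.2,
                           noise_sd = 0, seed = 1, window = c(4, 0)) {
  if (n_points < 3) stop("need at least 3 measurements")
  if (dating_half_width < 0) stop("negative dating half-width")
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  t <- seq(window[1], window[2], length.out = n_points)
  v <- true_curve(t) + stats::rnorm(n_points, 0, noise_sd)
  data.frame(value = v,
             age_min = pmax(0, t - dating_half_width),
             age_max = t + dating_half_width,
             true_age = t)
}

#' Simulate a spatial grid with known regression truth
#'
#' Lays out an equal-area grid (Behrmann, 1 degree column width), draws
#' standardised predictors, and builds the response by the SAR error model
#' y = X beta_true + u with u = lambda W u + eps solved exactly as
#' u = (I - lambda W)^(-1) eps. The weights W used for generation are
#' row-standardised rook contiguity.
#'
#' @param cfg a [sim_config()] (grid_dims, beta_true, sar_lambda_true,
#'   noise_sd, seed).
#' @param W optional generating weights matrix (defaults to row-standardised
#'   rook contiguity on the grid).
#' @return a \code{spatial_dataset} (see [new_spatial_dataset()]) with
#'   attributes \code{beta_true}, \code{lambda_true}, \code{W}.
#' @export
simulate_spatial_grid <- function(cfg, W = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  dims <- cfg$grid_dims
  if (any(dims < 5)) stop("grid must be at least 5 x 5")
  old_seed <- set_local_seed(cfg$seed)
  on.exit(restore_seed(old_seed), add = TRUE)
  cells <- behrmann_cells(dims[1], dims[2])
  n <- nrow(cells)
  p <- length(cfg$beta_true)
  X <- matrix(stats::rnorm(n * p), n, p)
  X <- scale(X)  # standardised predictors
  if (is.null(W)) W <- rook_weights(dims[1], dims[2])
  stopifnot(nrow(W) == n, ncol(W) == n)
  A <- diag(n) - cfg$sar_lambda_true * W
  if (abs(det(A)) < 1e-12) stop("(I - lambda W) is singular")
  eps <- stats::rnorm(n, 0, cfg$noise_sd)
  u <- solve(A, eps)
  y <- drop(X %*% cfg$beta_true + u)
  pred_names <- paste0("x", seq_len(p))
  df <- data.frame(lon = cells$lon, lat = cells$lat, fraction_large = y)
  df[pred_names] <- as.data.frame(X)
  ds <- new_spatial_dataset(df, predictors = pred_names,
                            response = "fraction_large")
  attr(ds, "beta_true") <- cfg$beta_true
  attr(ds, "lambda_true") <- cfg$sar_lambda_true
  attr(ds, "W") <- W
  ds
}

# row-standardised rook-contiguity weights on an r x c lattice
rook_weights <- function(r, c) {
  n <- r * c
  idx <- function(i, j) (j - 1L) * r + i
  W <- matrix(0, n, n)
  for (j in seq_len(c)) for (i in seq_len(r)) {
    k <- idx(i, j)
    nb <- c(if (i > 1) idx(i - 1, j), if (i < r) idx(i + 1, j),
            if (j > 1) idx(i, j - 1), if (j < c) idx(i, j + 1))
    W[k, nb] <- 1 / length(nb)
  }
  W
}

#' Centroids of an equal-area Behrmann grid block
#'
#' Builds an r x c block of square cells in the Behrmann projection
#' (equal-area cylindrical, standard parallel 30 degrees) with a column width
#' of 1 degree, centred on the equator/20E, and returns geographic centroids
#' plus cell latitude bounds. Every cell has the same area, about 9275 km2.
#'
#' @param r,c rows and columns.
#' @param lon0 western edge longitude (degrees).
#' @return data.frame lon, lat, lat_lo, lat_hi, area_km2.
#' @export
behrmann_cells <- function(r, c, lon0 = 20) {
  R <- 6371.0088
  side <- (pi / 180) * R * cos(30 * pi / 180)  # 1 degree of longitude at 30N
  # latitude band edges: y = R sin(phi) / cos(30), y in steps of `side`
  y0 <- -side * r / 2
  y_edges <- y0 + side * (0:r)
  sinphi <- pmin(1, pmax(-1, y_edges * cos(30 * pi / 180) / R))
  phi_edges <- asin(sinphi) * 180 / pi
  lons <- lon0 + (seq_len(c) - 0.5)
  out <- expand.grid(row = seq_len(r), col = seq_len(c))
  lat_lo <- phi_edges[out$row]; lat_hi <- phi_edges[out$row + 1]
  area <- 2 * pi * R^2 * (sin(lat_hi * pi / 180) - sin(lat_lo * pi / 180)) *
    (1 / 360)  # 1 degree column
  data.frame(lon = lons[out$col],
             lat = (lat_lo + lat_hi) / 2,
             lat_lo = lat_lo, lat_hi = lat_hi, area_km2 = area)
}
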