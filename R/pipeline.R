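#' Pipeline configuration
#'
#' Settings for the replicated model-selection design: how many age-resampled
#' replicates, which extinction models (the roster), and the MCMC profile.
#'
#' @param n_replicates number of age-resampling replicates (the full design
#'   uses 100).
#' @param roster named list of \code{extinction_model} templates to compare.
#' @param mcmc an [mcmc_config()].
#' @param window analysis window \code{c(old, young)} Ma.
#' @param seed master seed; replicate seeds derive from it via
#'   [derive_seed()].
#' @param max_failure_frac abort if more than this fraction of replicates
#'   fails (default 0.1).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_replicates = 100, roster, mcmc = mcmc_config(),
                            window = c(4, 0), seed = 1,
                            max_failure_frac = 0.1) {
  stopifnot(n_replicates >= 1, length(roster) >= 1)
  if (is.null(names(roster)) || any(names(roster) == ""))
    names(roster) <- vapply(roster, `[[`, "", "label")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the replicated model-selection pipeline for one guild
#'
#' For each replicate: resample occurrence ages within their dating
#' intervals, estimate the marginal likelihood of every roster model by
#' thermodynamic integration, and convert log MLs to relative model
#' probabilities. Pools the per-model weight distributions across replicates
#' (median, quartiles, 1.5 IQR whiskers) and records each replicate's
#' winning model. A failing replicate is recorded and skipped; if more than
#' \code{max_failure_frac} of replicates fail the pipeline errors.
#'
#' @param occurrences validated occurrence table (one guild).
#' @param cfg a [pipeline_config()].
#' @param posterior_models optional character vector of roster labels for
#'   which a full (beta = 1) posterior trace is also kept, for
#'   rate-through-time and lineage-time summaries.
#' @return list with \code{scores} (per replicate x model log ML),
#'   \code{weights} (per replicate x model relative probability),
#'   \code{weight_summary} (per model: median, quartiles, whiskers),
#'   \code{winners}, \code{traces} (replicate -> label -> trace),
#'   \code{failed} (replicate ids).
#' @export
run_pipeline <- function(occurrences, cfg, posterior_models = character()) {
  occ <- validate_occurrences(occurrences)
  roster <- cfg$roster
  score_rows <- list(); weight_rows <- list(); winners <- character()
  traces <- list(); failed <- integer()
  for (r in seq_len(cfg$n_replicates)) {
    res <- tryCatch({
      rep_ds <- resample_ages(occ, replicate_id = r, seed = cfg$seed)
      scores <- list()
      for (lab in names(roster)) {
        mc <- cfg$mcmc
        mc$seed <- derive_seed(cfg$seed, r * 131L + match(lab, names(roster)))
        scores[[lab]] <- thermodynamic_ml(rep_ds, roster[[lab]], mc,
                                          window = cfg$window, label = lab)
        if (lab %in% posterior_models) {
          mc2 <- mc; mc2$seed <- derive_seed(mc$seed, 7L)
          traces[[as.character(r)]][[lab]] <-
            run_mcmc(rep_ds, roster[[lab]], mc2, beta = 1, window = cfg$window)
        }
      }
      w <- relative_probabilities(scores)
      list(scores = scores, w = w)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, r)
      warning("replicate ", r, " failed: ", conditionMessage(res))
      next
    }
    for (lab in names(roster))
      score_rows[[length(score_rows) + 1L]] <- data.frame(
        replicate = r, model = lab, logml = res$scores[[lab]]$logml,
        stringsAsFactors = FALSE)
    weight_rows[[length(weight_rows) + 1L]] <- data.frame(
      replicate = r, t(res$w), check.names = FALSE)
    winners <- c(winners, names(which.max(res$w)))
  }
  if (length(failed) > cfg$max_failure_frac * cfg$n_replicates)
    stop("more than ", round(100 * cfg$max_failure_frac),
         "% of replicates failed (", length(failed), "/", cfg$n_replicates, ")")
  weights <- do.call(rbind, weight_rows)
  summ <- do.call(rbind, lapply(names(roster), function(lab) {
    w <- weights[[lab]]
    qs <- stats::quantile(w, c(0.25, 0.5, 0.75))
    iqr <- qs[3] - qs[1]
    data.frame(model = lab, median = qs[2], q1 = qs[1], q3 = qs[3],
               whisker_lo = max(min(w), qs[1] - 1.5 * iqr),
               whisker_hi = min(max(w), qs[3] + 1.5 * iqr),
               stringsAsFactors = FALSE)
  }))
  list(scores = do.call(rbind, score_rows), weights = weights,
       weight_summary = summ, winners = winners, traces = traces,
       failed = failed)
}

#' Fraction of large carnivores through time from posterior lineage times
#'
#' For each replicate and grid age t, the fraction of lineages alive at t
#' (posterior-median origination/extinction times by default, or per-sample
#' draws) that belong to the large guild; summarised across replicates by
#' the median and full min-max range. Grid points where no lineage is alive
#' in a replicate are masked (NA) for that replicate.
#'
#' @param traces_by_replicate list over replicates; each element is either a
#'   single [run_mcmc()] trace covering both guilds, or a list of traces
#'   (e.g. one per guild) pooled together.
#' @param grid ages (Ma).
#' @param use one of \code{"median"} (posterior-median s, e per species) or
#'   \code{"draws"} (average the indicator over posterior samples).
#' @return data.frame with age, median, min, max across replicates.
#' @export
fraction_large_curve <- function(traces_by_replicate, grid, use = c("median", "draws")) {
  use <- match.arg(use)
  frac_one <- function(s, e, large, grid) {
    vapply(grid, function(t) {
      alive <- s >= t & e <= t
      if (!any(alive)) return(NA_real_)
      sum(alive & large) / sum(alive)
    }, 0)
  }
  per_rep <- lapply(traces_by_replicate, function(trs) {
    if (is.data.frame(trs)) trs <- list(trs)
    s <- c(); e <- c(); large <- c()
    if (use == "median") {
      for (tr in trs) {
        s <- c(s, apply(attr(tr, "s_trace"), 2, stats::median))
        e <- c(e, apply(attr(tr, "e_trace"), 2, stats::median))
        large <- c(large, attr(tr, "size_class") == "large")
      }
      frac_one(s, e, large, grid)
    } else {
      n_samp <- min(vapply(trs, nrow, 0L))
      acc <- matrix(NA_real_, n_samp, length(grid))
      for (i in seq_len(n_samp)) {
        s <- c(); e <- c(); large <- c()
        for (tr in trs) {
          s <- c(s, attr(tr, "s_trace")[i, ])
          e <- c(e, attr(tr, "e_trace")[i, ])
          large <- c(large, attr(tr, "size_class") == "large")
        }
        acc[i, ] <- frac_one(s, e, large, grid)
      }
      colMeans(acc, na.rm = TRUE)
    }
  })
  M <- do.call(rbind, per_rep)
  data.frame(age = grid,
             median = apply(M, 2, stats::median, na.rm = TRUE),
             min = suppressWarnings(apply(M, 2, min, na.rm = TRUE)),
             max = suppressWarnings(apply(M, 2, max, na.rm = TRUE)))
}
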