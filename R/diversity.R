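#' Geological stage table
#'
#' An ordered table of stages with old/young bounds (Ma), contiguous and
#' descending in age. Used for the stage-level range-through diversity
#' comparison.
#'
#' @param name stage names, oldest first.
#' @param old,young bounds (Ma).
#' @return data.frame of class \code{stage_table}.
#' @export
stage_table <- function(name, old, young) {
  stopifnot(length(name) == length(old), length(old) == length(young),
            all(old > young))
  if (is.unsorted(rev(old))) stop("stages must be ordered oldest first")
  if (any(abs(utils::head(young, -1) - utils::tail(old, -1)) > 1e-9))
    stop("stages must be contiguous")
  structure(data.frame(name = name, old = old, young = young,
                       stringsAsFactors = FALSE),
            class = c("stage_table", "data.frame"))
}

#' Plio-Pleistocene stage table
#'
#' The default stage boundaries (Ma) used for the inter-continental
#' comparison, from the standard geological time scale: Messinian through
#' Late Pleistocene.
#' @return a \code{stage_table}.
#' @export
default_stages <- function() {
  stage_table(
    name = c("Messinian", "Zanclean", "Piacenzian", "Gelasian",
             "Calabrian", "Chibanian", "Late Pleistocene"),
    old = c(7.246, 5.333, 3.600, 2.588, 1.806, 0.774, 0.129),
    young = c(5.333, 3.600, 2.588, 1.806, 0.774, 0.129, 0.0117)
  )
}

#' Assign species to geological stages by occurrence midpoints
#'
#' A species is scored present in a stage iff the midpoint of some
#' occurrence's age interval falls in the stage. Stage intervals are
#' half-open [young, old): a midpoint exactly on a boundary goes to the
#' older stage. Midpoints outside the table are skipped with a warning.
#'
#' @param occurrences occurrence table with species, age_min, age_max.
#' @param stages a \code{stage_table}.
#' @return logical presence matrix, species in rows (sorted), stages in
#'   columns (oldest first).
#' @export
assign_stages <- function(occurrences, stages = default_stages()) {
  mid <- (occurrences$age_min + occurrences$age_max) / 2
  # half-open [young, old): boundary midpoints belong to the older stage
  k <- rep(NA_integer_, length(mid))
  for (j in seq_len(nrow(stages)))
    k[is.na(k) & mid < stages$old[j] & mid >= stages$young[j]] <- j
  # a midpoint equal to the oldest bound goes to the oldest stage
  k[is.na(k) & abs(mid - stages$old[1]) < 1e-12] <- 1L
  if (any(is.na(k)))
    warning("skipping ", sum(is.na(k)),
            " occurrence(s) with midpoints outside the stage table")
  sp <- sort(unique(occurrences$species))
  M <- matrix(FALSE, length(sp), nrow(stages),
              dimnames = list(sp, stages$name))
  keep <- !is.na(k)
  for (i in which(keep)) M[occurrences$species[i], k[i]] <- TRUE
  M
}

#' Fill range-through presences
#'
#' If a species is present in both an older and a younger stage, it is
#' assumed present in every stage in between. Presences are never removed;
#' the operation is idempotent.
#'
#' @param presence logical presence matrix (species x stages, oldest column
#'   first).
#' @return filled presence matrix of the same shape.
#' @export
range_through <- function(presence) {
  stopifnot(is.matrix(presence))
  out <- presence
  for (i in seq_len(nrow(out))) {
    occ <- which(out[i, ])
    if (length(occ) >= 2L) out[i, occ[1]:occ[length(occ)]] <- TRUE
  }
  out
}

#' Fraction of large carnivores per geological stage
#'
#' Per stage, the number of large species present divided by the number of
#' species present; stages with zero species are returned as NA.
#'
#' @param presence (filled) presence matrix, species in rows.
#' @param size_class named character vector ("large"/"small") per species.
#' @return named numeric vector of per-stage fractions.
#' @export
fraction_large_by_stage <- function(presence, size_class) {
  if (!all(rownames(presence) %in% names(size_class)))
    stop("every species needs a size class")
  large <- size_class[rownames(presence)] == "large"
  n_tot <- colSums(presence)
  n_lrg <- colSums(presence & large)
  out <- ifelse(n_tot > 0, n_lrg / n_tot, NA_real_)
  stats::setNames(out, colnames(presence))
}
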