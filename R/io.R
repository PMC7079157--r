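#' Read a fossil occurrence table
#'
#' Reads a tab-delimited occurrence table (one row per dated fossil occurrence)
#' and validates it. Required columns: \code{species}, \code{site},
#' \code{age_min}, \code{age_max} (Ma), \code{size_class} (\code{"large"} or
#' \code{"small"}; 21 kg body-mass threshold) and \code{extant} (0/1 or
#' TRUE/FALSE).
#'
#' @param path path to a TSV file with a one-line header.
#' @param strict if TRUE (default) any malformed row aborts with its line
#'   number; if FALSE malformed rows are dropped with a warning.
#' @return a validated \code{data.frame} of occurrences with a
#'   \code{"summary"} attribute (occurrence/species/extant counts per guild).
#' @export
read_occurrences <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no records in occurrence file: ", path)
  required <- c("species", "site", "age_min", "age_max", "size_class", "extant")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("occurrence table missing columns: ", paste(missing, collapse = ", "))
  raw$extant <- as.logical(raw$extant)
  bad <- !is.finite(raw$age_min) | !is.finite(raw$age_max) |
    raw$age_min < 0 | raw$age_min > raw$age_max |
    !(raw$size_class %in% c("large", "small")) | is.na(raw$extant)
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    if (strict)
      stop("malformed occurrence row(s) at file line(s): ",
           paste(lines, collapse = ", "))
    warning("dropping ", sum(bad), " malformed occurrence row(s) at line(s): ",
            paste(lines, collapse = ", "))
    raw <- raw[!bad, , drop = FALSE]
    if (nrow(raw) == 0L) stop("no valid records remain in: ", path)
  }
  validate_occurrences(raw)
}

#' Validate an in-memory occurrence table
#'
#' Checks column types, per-species consistency of size class and extant flag,
#' and attaches the bookkeeping summary.
#'
#' @param occ occurrence data.frame (see [read_occurrences()]).
#' @return the validated data.frame with a \code{"summary"} attribute.
#' @export
validate_occurrences <- function(occ) {
  stopifnot(is.data.frame(occ), nrow(occ) > 0L)
  occ$species <- as.character(occ$species)
  occ$site <- as.character(occ$site)
  occ$extant <- as.logical(occ$extant)
  if (any(occ$age_min < 0 | occ$age_min > occ$age_max))
    stop("age_min must satisfy 0 <= age_min <= age_max")
  sc <- tapply(occ$size_class, occ$species, function(x) length(unique(x)))
  if (any(sc > 1L))
    stop("size_class differs across occurrences of: ",
         paste(names(sc)[sc > 1L], collapse = ", "))
  ex <- tapply(occ$extant, occ$species, function(x) length(unique(x)))
  if (any(ex > 1L))
    stop("extant flag differs across occurrences of: ",
         paste(names(ex)[ex > 1L], collapse = ", "))
  attr(occ, "summary") <- occurrence_summary(occ)
  occ
}

#' Restrict an occurrence table to the fauna of an analysis window
#'
#' Keeps the species that have at least one occurrence whose dating-interval
#' midpoint is younger than the old window edge, retaining all occurrences of
#' those species (including older ones, which inform their origination).
#' Species known only from occurrences older than the window are not part of
#' the analysed fauna and are dropped.
#'
#' @param occ occurrence table.
#' @param old_age old edge of the analysis window (Ma, default 4).
#' @return filtered occurrence table; attribute \code{n_dropped_species}.
#' @export
restrict_to_window <- function(occ, old_age = 4) {
  mid <- (occ$age_min + occ$age_max) / 2
  in_sp <- unique(occ$species[mid <= old_age])
  out <- occ[occ$species %in% in_sp, , drop = FALSE]
  dropped <- length(unique(occ$species)) - length(in_sp)
  out <- validate_occurrences(out)
  attr(out, "n_dropped_species") <- dropped
  out
}

#' Summarise an occurrence table
#'
#' @param occ occurrence data.frame.
#' @return list with n_occurrences, n_species, n_extant, n_extinct and
#'   per-guild species counts.
#' @export
occurrence_summary <- function(occ) {
  sp <- occ[!duplicated(occ$species), c("species", "size_class", "extant")]
  list(
    n_occurrences = nrow(occ),
    n_species = nrow(sp),
    n_extant = sum(sp$extant),
    n_extinct = sum(!sp$extant),
    n_large = sum(sp$size_class == "large"),
    n_small = sum(sp$size_class == "small")
  )
}

#' Write an occurrence table as TSV
#' @param occ occurrence data.frame.
#' @param path output path.
#' @export
write_occurrences <- function(occ, path) {
  out <- occ
  out$age_min <- round(out$age_min, 4)
  out$age_max <- round(out$age_max, 4)
  out$extant <- as.integer(out$extant)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a proxy measurement table
#'
#' TSV with columns \code{value}, \code{age_min}, \code{age_max}: one dated
#' measurement per row, the age interval expressing dating uncertainty.
#'
#' @param path path to TSV.
#' @return data.frame of measurements.
#' @export
read_proxy <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("value", "age_min", "age_max")
  if (!all(required %in% names(m)))
    stop("proxy table must have columns: ", paste(required, collapse = ", "))
  if (any(!is.finite(m$value))) stop("non-finite proxy values")
  if (any(m$age_min > m$age_max)) stop("proxy rows with age_min > age_max")
  m
}

#' Write a proxy measurement table as TSV
#' @param m data.frame with value, age_min, age_max.
#' @param path output path.
#' @export
write_proxy <- function(m, path) {
  out <- m[, c("value", "age_min", "age_max")]
  out$age_min <- round(out$age_min, 4)
  out$age_max <- round(out$age_max, 4)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a predictor curve as a two-column TSV (age, value)
#' @param curve a \code{predictor_curve}.
#' @param path output path.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(
    data.frame(age = round(curve$grid, 4), value = curve$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictor curve written by [write_curve()]
#'
#' The curve is reconstituted with its centering recomputed from the stored
#' values; resampling metadata is not round-tripped.
#' @param path path to TSV.
#' @return a \code{predictor_curve}.
#' @export
read_curve <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  new_predictor_curve(d$age, d$value, n_resamples = NA_integer_, span = NA_real_)
}

#' Derive a reproducible child seed from a master seed and an id
#'
#' A small multiplicative hash keeping the result in 1..2^31-2 so replicate
#' streams are reproducible and distinct without correlated low bits.
#' @param master integer master seed.
#' @param id integer stream id (e.g. replicate number).
#' @return integer seed.
#' @export
derive_seed <- function(master, id) {
  x <- (as.double(master) %% 2147483647) * 48271 + as.double(id) * 69621 + 12345
  as.integer(x %% 2147483646) + 1L
}

#' Write a run manifest as JSON
#'
#' Lists every artifact a run produced together with the seed and a hash of
#' the configuration, so outputs can be traced back to their inputs.
#' @param path output JSON path.
#' @param seed master seed of the run.
#' @param config list; hashed (not stored verbatim) into the manifest.
#' @param artifacts character vector of file paths produced by the run.
#' @export
write_manifest <- function(path, seed, config, artifacts) {
  cfg_hash <- sum(utf8ToInt(paste(deparse(config), collapse = "")) *
                    seq_along(utf8ToInt(paste(deparse(config), collapse = "")))) %% 2147483647
  man <- list(
    run_id = format(Sys.time(), "%Y%m%dT%H%M%S"),
    seed = seed,
    config_hash = cfg_hash,
    artifacts = as.list(artifacts)
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
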