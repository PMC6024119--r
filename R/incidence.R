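#' Build a species-by-unit incidence matrix
#'
#' Constructs the core presence/absence structure of the package from
#' long-format records (one row per species-unit pair). Presence is strictly
#' binary: duplicated pairs are collapsed to one, with a warning giving the
#' number of duplicates dropped (herbarium-derived occurrence data routinely
#' repeats records).
#'
#' @param records Data frame of presence records.
#' @param species_col,unit_col Names of the species and unit identifier
#'   columns.
#' @return An object of class `incidence` with components `species` and
#'   `units` (sorted identifier vectors), `species_by_unit` and
#'   `units_by_species` (named lists of identifier sets).
#' @examples
#' inc <- incidence_matrix(data.frame(
#'   species_id = c("sp1", "sp2", "sp1"),
#'   unit_id    = c("u1", "u1", "u2")))
#' unit_richness(inc)
#' @export
incidence_matrix <- function(records, species_col = "species_id",
                             unit_col = "unit_id") {
  if (!is.data.frame(records)) stop("`records` must be a data frame")
  miss <- setdiff(c(species_col, unit_col), names(records))
  if (length(miss)) {
    stop("presence records lack required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) stop("presence records are empty", call. = FALSE)
  sp <- as.character(records[[species_col]])
  un <- as.character(records[[unit_col]])
  bad <- is.na(sp) | is.na(un) | !nzchar(sp) | !nzchar(un)
  if (any(bad)) {
    stop("missing species or unit identifiers in rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(paste(sp, un, sep = "\r"))
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate presence record(s)", sum(dup)),
            call. = FALSE)
    sp <- sp[!dup]
    un <- un[!dup]
  }
  units <- sort(unique(un))
  species <- sort(unique(sp))
  species_by_unit <- lapply(split(sp, factor(un, levels = units)), sort)
  units_by_species <- lapply(split(un, factor(sp, levels = species)), sort)
  structure(list(species = species, units = units,
                 species_by_unit = species_by_unit,
                 units_by_species = units_by_species),
            class = "incidence")
}

#' @export
print.incidence <- function(x, ...) {
  cat(sprintf("incidence matrix: %d species x %d units, %d presence records\n",
              length(x$species), length(x$units),
              sum(lengths(x$species_by_unit))))
  invisible(x)
}

#' @export
as.data.frame.incidence <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    species_id = rep(x$species, lengths(x$units_by_species)),
    unit_id = unlist(x$units_by_species, use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Species pooled over one or more units
#'
#' @param incidence An [incidence_matrix()] object.
#' @param units Character vector of unit identifiers (unknown units are
#'   ignored).
#' @return Sorted character vector: the union of the units' species sets.
#' @export
species_of <- function(incidence, units) {
  stopifnot(inherits(incidence, "incidence"))
  sort(unique(as.character(unlist(incidence$species_by_unit[
    intersect(units, incidence$units)], use.names = FALSE))))
}

#' Per-unit species richness
#'
#' @param incidence An [incidence_matrix()] object.
#' @param universe Optional character vector restricting the species counted
#'   (e.g. threatened species only); `NULL` counts all species.
#' @return Named integer vector over all units.
#' @export
unit_richness <- function(incidence, universe = NULL) {
  stopifnot(inherits(incidence, "incidence"))
  if (is.null(universe)) {
    lengths(incidence$species_by_unit)
  } else {
    vapply(incidence$species_by_unit,
           function(s) sum(s %in% universe), integer(1))
  }
}

#' Restrict an incidence matrix to a subset of units
#'
#' Species left with zero occurrences are dropped, preserving the invariant
#' that every listed species occurs somewhere. Used by the bootstrap to build
#' per-replicate sub-datasets.
#'
#' @param incidence An [incidence_matrix()] object.
#' @param keep_units Character vector of unit identifiers to retain.
#' @return A new `incidence` object.
#' @export
restrict_units <- function(incidence, keep_units) {
  stopifnot(inherits(incidence, "incidence"))
  keep <- intersect(incidence$units, keep_units)
  if (length(keep) == 0L) stop("no units left after restriction", call. = FALSE)
  sbu <- incidence$species_by_unit[keep]
  sp <- sort(unique(unlist(sbu, use.names = FALSE)))
  ubs <- lapply(incidence$units_by_species[sp],
                function(u) intersect(u, keep))
  structure(list(species = sp, units = keep,
                 species_by_unit = sbu, units_by_species = ubs),
            class = "incidence")
}

#' Read long-format presence records from delimited text
#'
#' @param path Path to a UTF-8 delimited text file with a header row naming
#'   the species and unit identifier columns.
#' @param sep Field separator; `NULL` auto-detects comma versus tab.
#' @inheritParams incidence_matrix
#' @return An [incidence_matrix()] object.
#' @export
read_presence_records <- function(path, sep = NULL,
                                  species_col = "species_id",
                                  unit_col = "unit_id") {
  df <- read_delim_table(path, sep)
  incidence_matrix(df, species_col = species_col, unit_col = unit_col)
}

#' Write presence records as delimited text
#'
#' Inverse of [read_presence_records()]; the round trip preserves the
#' incidence relation exactly.
#'
#' @param incidence An [incidence_matrix()] object.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_presence_records <- function(incidence, path, sep = ",") {
  stopifnot(inherits(incidence, "incidence"))
  write_delim_table(as.data.frame(incidence), path, sep)
  invisible(path)
}
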