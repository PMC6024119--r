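#' Validate a planning-unit attribute table
#'
#' Checks identifiers, strata, land areas and protected-area (PA) coverage
#' fractions, and derives `pa_present` from `pa_coverage > 0` unless an
#' explicit `pa_present` column overrides it (useful for point-only PA
#' records that carry no area).
#'
#' @param units Data frame with columns `unit_id`, `stratum`, `area`
#'   (hectares, > 0) and `pa_coverage` (fraction of unit area protected, in
#'   \[0, 1\]). Optional: `pa_present`, `region`, and per-year coverage
#'   columns named `cov_<year>`.
#' @return The validated data frame with `pa_present` filled in, invisibly
#'   classed for reuse.
#' @export
validate_unit_table <- function(units) {
  if (!is.data.frame(units)) stop("`units` must be a data frame")
  req <- c("unit_id", "stratum", "area", "pa_coverage")
  miss <- setdiff(req, names(units))
  if (length(miss)) {
    stop("unit table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  units$unit_id <- as.character(units$unit_id)
  units$stratum <- as.character(units$stratum)
  if (anyDuplicated(units$unit_id)) {
    stop("duplicate unit_id: ",
         paste(unique(units$unit_id[duplicated(units$unit_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_area <- which(!is.finite(units$area) | units$area <= 0)
  if (length(bad_area)) {
    stop("non-positive area for unit(s): ",
         paste(units$unit_id[utils::head(bad_area, 10L)], collapse = ", "),
         call. = FALSE)
  }
  bad_cov <- which(!is.finite(units$pa_coverage) |
                     units$pa_coverage < 0 | units$pa_coverage > 1)
  if (length(bad_cov)) {
    stop("pa_coverage outside [0, 1] for unit(s): ",
         paste(units$unit_id[utils::head(bad_cov, 10L)], collapse = ", "),
         call. = FALSE)
  }
  if ("pa_present" %in% names(units)) {
    units$pa_present <- parse_flag(units$pa_present, "pa_present")
    # coverage implies presence even under an explicit override
    units$pa_present <- units$pa_present | units$pa_coverage > 0
  } else {
    units$pa_present <- units$pa_coverage > 0
  }
  yr <- grep("^cov_[0-9]+$", names(units), value = TRUE)
  for (cn in yr) {
    v <- units[[cn]]
    if (any(!is.finite(v) | v < 0 | v > 1)) {
      stop("per-year coverage column ", cn, " outside [0, 1]", call. = FALSE)
    }
  }
  units
}

#' Read a planning-unit attribute table from delimited text
#'
#' @inheritParams read_presence_records
#' @return A validated data frame; see [validate_unit_table()].
#' @export
read_unit_table <- function(path, sep = NULL) {
  validate_unit_table(read_delim_table(path, sep))
}

#' Validate a species attribute table
#'
#' The flags `threatened` (IUCN CR/EN/VU), `nationally_protected` and
#' `endemic` parse from logical, 0/1 or "true"/"false"; columns absent from
#' the table default to `FALSE` with a message. A missing `taxon_group`
#' column defaults to a single group; a missing `region` stays `NA`.
#'
#' @param species Data frame with at least a `species_id` column.
#' @param groups Optional character vector of permitted taxon groups; when
#'   given, values outside it are an error.
#' @return The validated data frame with all flag columns present.
#' @export
validate_species_table <- function(species, groups = NULL) {
  if (!is.data.frame(species)) stop("`species` must be a data frame")
  if (!"species_id" %in% names(species)) {
    stop("species table lacks required column species_id", call. = FALSE)
  }
  species$species_id <- as.character(species$species_id)
  if (anyDuplicated(species$species_id)) {
    stop("duplicate species_id: ",
         paste(unique(species$species_id[duplicated(species$species_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (fl in c("threatened", "nationally_protected", "endemic")) {
    if (fl %in% names(species)) {
      species[[fl]] <- parse_flag(species[[fl]], fl)
    } else {
      message("species table has no '", fl, "' column; defaulting to FALSE")
      species[[fl]] <- FALSE
    }
  }
  if (!"taxon_group" %in% names(species)) {
    species$taxon_group <- "unassigned"
  }
  species$taxon_group <- as.character(species$taxon_group)
  if (!is.null(groups)) {
    bad <- setdiff(unique(species$taxon_group), groups)
    if (length(bad)) {
      stop("taxon_group value(s) outside declared set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!"region" %in% names(species)) species$region <- NA_character_
  species
}

#' Read a species attribute table from delimited text
#'
#' @inheritParams read_presence_records
#' @inheritParams validate_species_table
#' @return A validated data frame; see [validate_species_table()].
#' @export
read_species_table <- function(path, sep = NULL, groups = NULL) {
  validate_species_table(read_delim_table(path, sep), groups = groups)
}

#' Cross-check incidence, species and unit tables
#'
#' Reports (without erroring) species listed in the attribute table but
#' absent from the incidence matrix and vice versa, and units likewise.
#' Attribute rows without occurrences are legitimate (e.g. a national
#' checklist wider than the survey) and are retained.
#'
#' @param incidence An [incidence_matrix()] object.
#' @param species,units Validated attribute tables.
#' @param json_path Optional path; when given the report is also written as
#'   JSON.
#' @return A list of identifier vectors, class `validation_report`.
#' @export
validate_dataset <- function(incidence, species, units, json_path = NULL) {
  stopifnot(inherits(incidence, "incidence"))
  rep <- list(
    species_without_occurrences = setdiff(species$species_id,
                                          incidence$species),
    species_missing_from_table = setdiff(incidence$species,
                                         species$species_id),
    units_without_occurrences = setdiff(units$unit_id, incidence$units),
    units_missing_from_table = setdiff(incidence$units, units$unit_id))
  class(rep) <- "validation_report"
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(rep), json_path, auto_unbox = FALSE)
  }
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("dataset validation report\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %d\n", nm, length(x[[nm]])))
  }
  invisible(x)
}

#' Extract long-format per-year PA coverage from a unit table
#'
#' Converts wide `cov_<year>` columns into the long (unit_id, year,
#' pa_coverage) layout consumed by [representation_time_series()].
#'
#' @param units A validated unit table with `cov_<year>` columns.
#' @return Data frame with columns `unit_id`, `year`, `pa_coverage`.
#' @export
coverage_by_year <- function(units) {
  yr <- grep("^cov_[0-9]+$", names(units), value = TRUE)
  if (length(yr) == 0L) {
    stop("unit table has no cov_<year> columns", call. = FALSE)
  }
  years <- as.integer(sub("^cov_", "", yr))
  out <- data.frame(
    unit_id = rep(units$unit_id, times = length(yr)),
    year = rep(years, each = nrow(units)),
    pa_coverage = unlist(units[yr], use.names = FALSE))
  out[order(out$year, out$unit_id), , drop = FALSE]
}
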