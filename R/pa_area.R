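#' Allocate protected-area extent to planning units
#'
#' A protected area that spans several units contributes area to each. When
#' the registry reports its area within each unit, those figures are used as
#' given; when only the PA's total area is known, the total is divided
#' equally among the units it intersects.
#'
#' @param pa_table Data frame with columns `pa_id` and `total_area` (one row
#'   per protected area).
#' @param pa_units Data frame with columns `pa_id` and `unit_id` (one row
#'   per PA-unit intersection) and optionally `area`, the PA's area within
#'   that unit. Within one PA the `area` column must be either all known or
#'   all missing.
#' @return Data frame `pa_id`, `unit_id`, `allocated_area`; allocations sum
#'   per PA to its total area (before any capping at unit area, which
#'   happens in [compute_pa_coverage()]).
#' @export
allocate_pa_area <- function(pa_table, pa_units) {
  stopifnot(is.data.frame(pa_table), is.data.frame(pa_units))
  miss <- setdiff(c("pa_id", "total_area"), names(pa_table))
  if (length(miss)) {
    stop("pa_table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(c("pa_id", "unit_id"), names(pa_units))
  if (length(miss)) {
    stop("pa_units lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pa_table$pa_id <- as.character(pa_table$pa_id)
  pa_units$pa_id <- as.character(pa_units$pa_id)
  pa_units$unit_id <- as.character(pa_units$unit_id)
  orphan <- setdiff(pa_table$pa_id, pa_units$pa_id)
  if (length(orphan)) {
    stop("protected area(s) naming zero units: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(pa_table$total_area) | pa_table$total_area < 0)) {
    stop("negative or missing total_area in pa_table", call. = FALSE)
  }
  has_breakdown <- "area" %in% names(pa_units)
  out <- lapply(seq_len(nrow(pa_table)), function(i) {
    id <- pa_table$pa_id[i]
    rows <- pa_units[pa_units$pa_id == id, , drop = FALSE]
    if (has_breakdown && !all(is.na(rows$area))) {
      if (any(is.na(rows$area))) {
        stop("PA ", id, " has a partial per-unit area breakdown",
             call. = FALSE)
      }
      if (any(rows$area < 0)) {
        stop("PA ", id, " has negative per-unit areas", call. = FALSE)
      }
      alloc <- rows$area
    } else {
      alloc <- rep(pa_table$total_area[i] / nrow(rows), nrow(rows))
    }
    data.frame(pa_id = id, unit_id = rows$unit_id, allocated_area = alloc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Derive per-unit PA coverage from area allocations
#'
#' Sums the contributions of all protected areas intersecting each unit.
#' Where overlapping PAs push the summed protected area above the unit's
#' land area, the protected area is capped at the unit area (coverage 1.0)
#' with a warning giving the number of capped units.
#'
#' @param units Unit attribute table (see [validate_unit_table()]); its
#'   `pa_coverage`/`pa_present` columns are recomputed.
#' @param allocation Output of [allocate_pa_area()]. Allocations to units
#'   absent from `units` are an error.
#' @return The unit table with `pa_coverage` and `pa_present` replaced.
#' @export
compute_pa_coverage <- function(units, allocation) {
  units <- validate_unit_table(units)
  unknown <- setdiff(allocation$unit_id, units$unit_id)
  if (length(unknown)) {
    stop("allocation names unknown unit(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tot <- tapply(allocation$allocated_area, allocation$unit_id, sum)
  pa_area <- rep(0, nrow(units))
  names(pa_area) <- units$unit_id
  pa_area[names(tot)] <- tot
  over <- pa_area > units$area
  if (any(over)) {
    warning(sprintf(
      "PA area exceeds unit area in %d unit(s); coverage capped at 1",
      sum(over)), call. = FALSE)
    pa_area <- pmin(pa_area, units$area)
  }
  units$pa_coverage <- as.numeric(pa_area / units$area)
  units$pa_present <- units$pa_coverage > 0
  units
}
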