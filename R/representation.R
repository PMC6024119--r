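#' Units meeting a protection criterion
#'
#' @param units Validated unit attribute table.
#' @param criterion `"presence"` selects units where any protected area
#'   exists regardless of extent; `"coverage"` selects units whose PA
#'   coverage fraction is greater than or equal to `threshold` (inclusive).
#' @param threshold Coverage threshold in \[0, 1\]; required for
#'   `criterion = "coverage"`.
#' @return Character vector of qualifying unit identifiers.
#' @export
select_protected_units <- function(units,
                                   criterion = c("presence", "coverage"),
                                   threshold = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "presence") {
    return(units$unit_id[units$pa_present])
  }
  if (is.null(threshold) || !is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("coverage criterion requires a threshold in [0, 1]", call. = FALSE)
  }
  units$unit_id[units$pa_coverage >= threshold]
}

#' Ecological representation index of a protected-area layer
#'
#' With `a` the number of complementary-set units meeting the protection
#' criterion and `b` the number that do not,
#' \deqn{I_E = a / (a + b) \times 100\%.}
#' The index is computed on exact counts; `i_e_rounded` applies half-up
#' rounding to one decimal for presentation.
#'
#' @param cs A `complementary_set` or character vector of its member units
#'   (must be non-empty).
#' @param s_p Character vector of units meeting the protection criterion
#'   (from [select_protected_units()]).
#' @param threshold Optional annotation stored in the result (a coverage
#'   fraction or the token `"presence"`).
#' @return Object of class `representation_result` with `a`, `b`, `n_cs`,
#'   `i_e`, `i_e_rounded`, `threshold`.
#' @examples
#' cs <- paste0("u", 1:552)
#' representation_index(cs, cs[1:261])$i_e_rounded # 47.3
#' @export
representation_index <- function(cs, s_p, threshold = NA) {
  members <- cs_members(cs)
  if (length(members) == 0L) {
    stop("complementary set is empty", call. = FALSE)
  }
  a <- length(intersect(members, s_p))
  b <- length(members) - a
  i_e <- 100 * a / (a + b)
  structure(list(threshold = threshold, a = a, b = b, n_cs = a + b,
                 i_e = i_e, i_e_rounded = round_half_up(i_e, 1)),
            class = "representation_result")
}

#' @export
print.representation_result <- function(x, ...) {
  cat(sprintf("I_E = %.1f%% (a = %d, b = %d, criterion: %s)\n",
              x$i_e_rounded, x$a, x$b, as.character(x$threshold)))
  invisible(x)
}

#' Representation at the presence criterion and a grid of thresholds
#'
#' Convenience wrapper running [select_protected_units()] and
#' [representation_index()] for the PA-presence criterion plus each coverage
#' threshold (sorted ascending).
#'
#' @inheritParams representation_index
#' @param units Validated unit attribute table.
#' @param thresholds Numeric vector of coverage thresholds in \[0, 1\].
#' @param include_presence Include the presence criterion as the first row.
#' @return Data frame with columns `criterion`, `threshold`, `a`, `b`,
#'   `i_e`, `i_e_rounded`.
#' @export
assess_representation <- function(cs, units,
                                  thresholds = c(0.1, 0.2, 0.3, 0.4),
                                  include_presence = TRUE) {
  thresholds <- sort(thresholds)
  rows <- list()
  if (include_presence) {
    r <- representation_index(cs, select_protected_units(units, "presence"),
                              "presence")
    rows[[1L]] <- data.frame(criterion = "presence", threshold = NA_real_,
                             a = r$a, b = r$b, i_e = r$i_e,
                             i_e_rounded = r$i_e_rounded)
  }
  for (t in thresholds) {
    r <- representation_index(
      cs, select_protected_units(units, "coverage", t), t)
    rows[[length(rows) + 1L]] <- data.frame(
      criterion = "coverage", threshold = t, a = r$a, b = r$b,
      i_e = r$i_e, i_e_rounded = r$i_e_rounded)
  }
  do.call(rbind, rows)
}

#' Conservation gaps of a protected-area layer
#'
#' Gap units are complementary-set units that fail the protection criterion.
#' Unprotected species are defined either range-wide (`"rangewide"`: zero
#' occurrences in any protected unit, across the whole study region — the
#' default) or relative to the complementary set (`"cs_only"`: every
#' occurrence the species has within the complementary set lies in a gap
#' unit).
#'
#' @param cs A `complementary_set` (or character vector of members).
#' @param s_p Character vector of protected units.
#' @param incidence An [incidence_matrix()] object.
#' @param universe Species to assess; defaults to the set's universe.
#' @param species_table Optional species attributes used to flag threatened
#'   and endemic subsets of the uncovered species.
#' @param definition `"rangewide"` or `"cs_only"`.
#' @return Object of class `gap_report`: `gap_units`, `uncovered_species`,
#'   `threatened_uncovered`, `endemic_uncovered`, `definition`.
#' @export
identify_gaps <- function(cs, s_p, incidence, universe = NULL,
                          species_table = NULL,
                          definition = c("rangewide", "cs_only")) {
  definition <- match.arg(definition)
  members <- cs_members(cs)
  if (is.null(universe)) {
    universe <- if (inherits(cs, "complementary_set")) cs$universe
                else species_of(incidence, members)
  }
  gap_units <- setdiff(members, s_p)
  occ <- incidence$units_by_species[intersect(universe, incidence$species)]
  uncovered <- if (definition == "rangewide") {
    names(occ)[vapply(occ, function(u) !any(u %in% s_p), logical(1))]
  } else {
    names(occ)[vapply(occ, function(u) {
      inside <- intersect(u, members)
      length(inside) > 0L && all(inside %in% gap_units)
    }, logical(1))]
  }
  thr <- end <- character(0)
  if (!is.null(species_table)) {
    i <- match(uncovered, species_table$species_id)
    thr <- uncovered[which(species_table$threatened[i])]
    end <- uncovered[which(species_table$endemic[i])]
  }
  structure(list(gap_units = gap_units, uncovered_species = sort(uncovered),
                 threatened_uncovered = sort(thr),
                 endemic_uncovered = sort(end),
                 definition = definition),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf(
    "gap report (%s): %d gap units; %d uncovered species (%d threatened, %d endemic)\n",
    x$definition, length(x$gap_units), length(x$uncovered_species),
    length(x$threatened_uncovered), length(x$endemic_uncovered)))
  invisible(x)
}

#' Congruence between a complementary set and the PA network
#'
#' Counts and areas are expressed relative to the union of the
#' complementary-set units and the PA-present units. Percentages are carried
#' exactly and also rounded: to whole percent (the presentation used for
#' count panels) and one decimal.
#'
#' @param cs A `complementary_set` (or character vector of members).
#' @param pa_units Character vector of units where PAs are present.
#' @param units Unit attribute table supplying `area` for every unit of the
#'   union.
#' @return Object of class `congruence_summary`: `n_cs`, `n_pa`, `n_union`,
#'   `n_common`, `pct_common`, `pct_common_int`, `area_union`,
#'   `area_common`, `area_pct_common`, `area_pct_common_int`.
#' @export
congruence_summary <- function(cs, pa_units, units) {
  members <- cs_members(cs)
  pa_units <- unique(as.character(pa_units))
  common <- intersect(members, pa_units)
  union_u <- union(members, pa_units)
  missing <- setdiff(union_u, units$unit_id)
  if (length(missing)) {
    stop("unit table lacks area for unit(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  area_of <- function(ids) sum(units$area[match(ids, units$unit_id)])
  pct <- 100 * length(common) / length(union_u)
  apct <- 100 * area_of(common) / area_of(union_u)
  structure(list(
    n_cs = length(members), n_pa = length(pa_units),
    n_union = length(union_u), n_common = length(common),
    pct_common = pct, pct_common_int = round_half_up(pct, 0),
    area_union = area_of(union_u), area_common = area_of(common),
    area_pct_common = apct, area_pct_common_int = round_half_up(apct, 0)),
    class = "congruence_summary")
}

#' @export
print.congruence_summary <- function(x, ...) {
  cat(sprintf(
    "congruence: %d of %d union units in common (%d%%); area share %d%%\n",
    x$n_common, x$n_union, x$pct_common_int, x$area_pct_common_int))
  invisible(x)
}

#' PA-coverage class distribution over a complementary set
#'
#' Partitions the units of a complementary set by PA coverage into a
#' distinguished exact-zero class (no protected area at all) followed by
#' half-open classes `[lo, hi)` on the given edges, the last class closed at
#' 1. Reports unit counts and each class's share of the set's total land
#' area.
#'
#' @param cs A `complementary_set` (or character vector of members).
#' @param units Unit attribute table covering all members.
#' @param class_edges Strictly increasing thresholds in \[0, 1\], starting
#'   at 0.
#' @return Data frame `class`, `lower`, `upper`, `n_units`, `area`,
#'   `area_pct`; counts sum to the set size and `area_pct` to 100.
#' @export
coverage_class_areas <- function(cs, units,
                                 class_edges = c(0, 0.05, 0.1, 0.2, 0.3,
                                                 0.4, 0.5, 0.6)) {
  members <- cs_members(cs)
  if (any(diff(class_edges) <= 0) || class_edges[1L] != 0 ||
      any(class_edges < 0 | class_edges > 1)) {
    stop("class_edges must be strictly increasing in [0, 1], starting at 0",
         call. = FALSE)
  }
  i <- match(members, units$unit_id)
  if (anyNA(i)) {
    stop("unit table lacks row(s) for complementary-set unit(s): ",
         paste(utils::head(members[is.na(i)], 5L), collapse = ", "),
         call. = FALSE)
  }
  cov <- units$pa_coverage[i]
  area <- units$area[i]
  k <- length(class_edges)
  lower <- c(0, class_edges)
  upper <- c(0, class_edges[-1L], 1)
  labels <- c("0",
              sprintf("(0,%g)", class_edges[2L]),
              if (k > 2L) sprintf("[%g,%g)", class_edges[2:(k - 1L)],
                                  upper[3:k]),
              sprintf("[%g,1]", class_edges[k]))
  # class index: 1 = exact zero; j+1 = j-th interval
  idx <- ifelse(cov == 0, 1L,
                findInterval(cov, class_edges, rightmost.closed = FALSE) + 1L)
  idx <- pmin(idx, k + 1L)
  n_units <- tabulate(idx, nbins = k + 1L)
  a <- vapply(seq_len(k + 1L), function(j) sum(area[idx == j]), numeric(1))
  data.frame(class = labels, lower = lower, upper = upper,
             n_units = n_units, area = a,
             area_pct = 100 * a / sum(area),
             stringsAsFactors = FALSE)
}

#' Per-region species capture of a complementary set
#'
#' For each biogeographic region and taxon group, the proportion of the
#' region's species that occur in at least one complementary-set unit
#' located inside that region. The mean and standard deviation of the
#' proportions across region-by-group cells (those holding at least one
#' species) summarise how evenly the set represents regional biotas.
#'
#' @param cs A `complementary_set` (or character vector of members).
#' @param incidence An [incidence_matrix()] object.
#' @param species_table Species attributes with a `region` column (no
#'   missing values among assessed species).
#' @param units Unit attribute table; regions are taken from a `region`
#'   column when present, otherwise from `stratum`.
#' @param universe Species to assess; defaults to the set's universe.
#' @return Data frame `region`, `taxon_group`, `n_species`, `n_captured`,
#'   `pct`, with attributes `mean` and `sd` over cells with species.
#' @export
regional_effectiveness <- function(cs, incidence, species_table, units,
                                   universe = NULL) {
  members <- cs_members(cs)
  if (is.null(universe)) {
    universe <- if (inherits(cs, "complementary_set")) cs$universe
                else species_of(incidence, members)
  }
  unit_region <- if ("region" %in% names(units)) units$region else
    units$stratum
  if (anyNA(unit_region)) {
    stop("missing region assignment for unit(s): ",
         paste(utils::head(units$unit_id[is.na(unit_region)], 5L),
               collapse = ", "), call. = FALSE)
  }
  tab <- species_table[match(universe, species_table$species_id), ,
                       drop = FALSE]
  if (anyNA(tab$species_id) || anyNA(tab$region)) {
    off <- universe[is.na(tab$species_id) | is.na(tab$region)]
    stop("missing region assignment for species: ",
         paste(utils::head(off, 5L), collapse = ", "), call. = FALSE)
  }
  names(unit_region) <- units$unit_id
  cells <- unique(tab[c("region", "taxon_group")])
  cells <- cells[order(cells$region, cells$taxon_group), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    r <- cells$region[i]
    g <- cells$taxon_group[i]
    sp <- tab$species_id[tab$region == r & tab$taxon_group == g]
    cs_in_r <- members[unit_region[members] == r]
    captured <- sum(sp %in% species_of(incidence, cs_in_r))
    data.frame(region = r, taxon_group = g, n_species = length(sp),
               n_captured = captured, pct = 100 * captured / length(sp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- out$n_species > 0
  attr(out, "mean") <- mean(out$pct[ok])
  attr(out, "sd") <- stats::sd(out$pct[ok])
  out
}

#' Representation index through time
#'
#' Applies the protection criterion to a per-year PA coverage layer and
#' recomputes the representation index for each year. No monotonicity is
#' imposed: protected areas can be downsized or degazetted.
#'
#' @param cs A `complementary_set` (or character vector of members).
#' @param coverage Long data frame `unit_id`, `year`, `pa_coverage` (see
#'   [coverage_by_year()]).
#' @param criterion,threshold As in [select_protected_units()].
#' @param years Years to evaluate; default all years present. A requested
#'   year absent from `coverage` is an error naming the year.
#' @return Data frame `year`, `a`, `b`, `i_e`, `i_e_rounded`.
#' @export
representation_time_series <- function(cs, coverage,
                                       criterion = c("presence", "coverage"),
                                       threshold = NULL, years = NULL) {
  criterion <- match.arg(criterion)
  req <- c("unit_id", "year", "pa_coverage")
  miss <- setdiff(req, names(coverage))
  if (length(miss)) {
    stop("coverage table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(years)) years <- sort(unique(coverage$year))
  rows <- lapply(years, function(y) {
    sub <- coverage[coverage$year == y, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("no coverage data for requested year ", y, call. = FALSE)
    }
    u <- data.frame(unit_id = as.character(sub$unit_id),
                    stratum = "all", area = 1,
                    pa_coverage = sub$pa_coverage)
    u <- validate_unit_table(u)
    r <- representation_index(
      cs, select_protected_units(u, criterion, threshold),
      if (criterion == "presence") "presence" else threshold)
    data.frame(year = y, a = r$a, b = r$b, i_e = r$i_e,
               i_e_rounded = r$i_e_rounded)
  })
  do.call(rbind, rows)
}
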