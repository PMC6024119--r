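#' Build a complementary set of planning units
#'
#' Assembles a set of units that jointly represents every species of the
#' target universe at least once. The procedure is the staged greedy
#' algorithm used in complementarity-based reserve selection:
#'
#' 1. Seed with the unit of greatest species richness (counted within the
#'    configured universe).
#' 2. For each priority stage in order (by default: nationally protected or
#'    threatened species first, then all remaining species), repeatedly pick
#'    the unit maximising the configured criterion — the complementarity
#'    score between the candidate and the pooled species of the current set,
#'    or the count of newly covered species — among units that still add at
#'    least one uncovered species of the stage's class, until that class is
#'    fully covered.
#'
#' Within a stage, scores and coverage targets are computed on the stage's
#' species class only, but every species a selected unit carries counts as
#' covered from then on. Ties break by criterion, then universe richness,
#' then unit identifier, so runs are fully deterministic.
#'
#' @param incidence An [incidence_matrix()] object.
#' @param species_table Species attribute table (see
#'   [validate_species_table()]); may be `NULL` when `universe = "all"` and
#'   the default stages reduce to a single pass.
#' @param config A [selection_config()].
#' @return Object of class `complementary_set`: `steps` (data frame with
#'   `step`, `stage`, `unit_id`, `score`, `n_new_species`,
#'   `cumulative_covered`), `members` (units in selection order),
#'   `covered_species`, `universe`, `universe_label` and `mode`.
#' @examples
#' inc <- incidence_matrix(data.frame(
#'   species_id = c("a", "b", "c", "b", "c", "d"),
#'   unit_id    = c("u1", "u1", "u1", "u2", "u2", "u3")))
#' build_complementary_set(inc)$members
#' @export
build_complementary_set <- function(incidence, species_table = NULL,
                                    config = selection_config()) {
  stopifnot(inherits(incidence, "incidence"),
            inherits(config, "selection_config"))
  universe <- resolve_universe(incidence, species_table, config)
  if (length(universe) == 0L) {
    stop("species universe is empty under the configured filter",
         call. = FALSE)
  }
  n_sp <- length(universe)
  sp_index <- stats::setNames(seq_len(n_sp), universe)

  # per-unit integer species sets within the universe
  unit_sets <- lapply(incidence$species_by_unit, function(s) {
    i <- sp_index[s]
    as.integer(i[!is.na(i)])
  })
  unit_ids <- incidence$units
  richness_u <- vapply(unit_sets, length, integer(1))

  # stage membership masks, sequential subtraction
  if (is.null(species_table)) {
    stage_masks <- list(all = rep(TRUE, n_sp))
  } else {
    tab <- species_table[match(universe, species_table$species_id), ,
                         drop = FALSE]
    if (anyNA(tab$species_id)) {
      missing <- universe[is.na(tab$species_id)]
      warning(sprintf(
        "%d species in the incidence matrix lack attribute rows; flags treated as FALSE",
        length(missing)), call. = FALSE)
      tab$species_id <- universe
      for (fl in c("threatened", "nationally_protected", "endemic")) {
        tab[[fl]][is.na(tab[[fl]])] <- FALSE
      }
    }
    assigned <- rep(FALSE, n_sp)
    stage_masks <- lapply(config$stages, function(pred) {
      m <- pred(tab) & !assigned
      assigned <<- assigned | m
      m
    })
    if (!all(assigned)) {
      stop("selection stages do not jointly cover the species universe",
           call. = FALSE)
    }
  }

  covered <- logical(n_sp)
  selected <- logical(length(unit_ids))
  steps <- list()

  add_step <- function(stage, u_idx, score) {
    newly <- sum(!covered[unit_sets[[u_idx]]])
    covered[unit_sets[[u_idx]]] <<- TRUE
    selected[u_idx] <<- TRUE
    steps[[length(steps) + 1L]] <<- data.frame(
      step = length(steps) + 1L, stage = stage,
      unit_id = unit_ids[u_idx], score = score,
      n_new_species = as.integer(newly),
      cumulative_covered = as.integer(sum(covered)),
      stringsAsFactors = FALSE)
  }

  # step 1: seed with the richest unit (ties: lexicographic unit id)
  seed_idx <- order(-richness_u, unit_ids)[1L]
  if (richness_u[seed_idx] == 0L) {
    stop("no unit contains any species of the universe", call. = FALSE)
  }
  add_step("seed", seed_idx, NA_real_)

  for (stage_name in names(stage_masks)) {
    mask <- stage_masks[[stage_name]]
    if (!any(mask)) next
    repeat {
      if (!any(mask & !covered)) break
      cand <- which(!selected)
      if (length(cand) == 0L) break
      # stage-restricted species sets and gains
      gains <- vapply(cand, function(u) {
        s <- unit_sets[[u]]
        sum(mask[s] & !covered[s])
      }, integer(1))
      keep <- gains >= 1L
      if (!any(keep)) break  # remaining stage species unreachable
      cand <- cand[keep]
      gains <- gains[keep]
      if (config$mode == "new_species_count") {
        score <- as.numeric(gains)
      } else {
        n_pooled <- sum(mask & covered)
        score <- vapply(cand, function(u) {
          s <- unit_sets[[u]]
          a <- s[mask[s]]          # candidate's stage species
          v <- sum(covered[a])     # shared with pooled stage species
          1 - v / (length(a) + n_pooled - v)
        }, numeric(1))
      }
      pick <- order(-score, -richness_u[cand], unit_ids[cand])[1L]
      add_step(stage_name, cand[pick], score[pick])
    }
  }

  steps <- do.call(rbind, steps)
  members <- steps$unit_id
  structure(list(
    steps = steps,
    members = members,
    covered_species = universe[covered],
    universe = universe,
    universe_label = config$universe,
    mode = config$mode), class = "complementary_set")
}

#' @export
print.complementary_set <- function(x, ...) {
  cat(sprintf(
    "complementary set (%s species, mode %s): %d units covering %d/%d species\n",
    x$universe_label, x$mode, length(x$members),
    length(x$covered_species), length(x$universe)))
  invisible(x)
}

#' @export
summary.complementary_set <- function(object, ...) {
  st <- object$steps
  cat(sprintf("complementary set: %d units, universe %d species (%s)\n",
              length(object$members), length(object$universe),
              object$universe_label))
  print(utils::head(st, 10L))
  if (nrow(st) > 10L) cat(sprintf("... and %d more steps\n", nrow(st) - 10L))
  invisible(object)
}

#' Write a complementary-set selection trace
#'
#' Emits the step table as delimited text plus a JSON run manifest (universe
#' label and size, selection mode, seed unit).
#'
#' @param cs A `complementary_set`.
#' @param path Output path for the trace table.
#' @param manifest_path Optional path for the JSON manifest; defaults to
#'   `path` with a `.json` extension.
#' @param sep Field separator.
#' @export
write_cs_trace <- function(cs, path, manifest_path = NULL, sep = ",") {
  stopifnot(inherits(cs, "complementary_set"))
  write_delim_table(cs$steps, path, sep)
  manifest_path <- manifest_path %||% sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(list(
    universe_label = cs$universe_label,
    universe_size = length(cs$universe),
    mode = cs$mode,
    n_units = length(cs$members),
    seed_unit = cs$members[1L]),
    manifest_path, auto_unbox = TRUE)
  invisible(path)
}
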