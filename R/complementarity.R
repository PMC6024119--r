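#' Pairwise complementarity score between two species sets
#'
#' For sites j and k with species counts S_j and S_k sharing V_jk species,
#' the complementarity score is
#' \deqn{C_{jk} = 1 - V_{jk} / S_{jk}, \quad S_{jk} = S_j + S_k - V_{jk},}
#' i.e. one minus the Jaccard similarity of the two species sets. C is 0 for
#' identical sets, 1 for disjoint sets, and symmetric in its arguments. It
#' is undefined (an error) when both sets are empty.
#'
#' @param species_j,species_k Character vectors of species identifiers (one
#'   may be empty).
#' @return Object of class `pair_overlap` with fields `s_j`, `s_k`, `v_jk`
#'   (shared), `s_jk` (union) and `c_jk` (score in \[0, 1\]).
#' @examples
#' complementarity_score(letters[1:10], letters[7:14])$c_jk # 1 - 4/14
#' @export
complementarity_score <- function(species_j, species_k) {
  sj <- unique(as.character(species_j))
  sk <- unique(as.character(species_k))
  s_j <- length(sj)
  s_k <- length(sk)
  if (s_j == 0L && s_k == 0L) {
    stop("complementarity is undefined for two empty species sets",
         call. = FALSE)
  }
  v <- length(intersect(sj, sk))
  s_u <- s_j + s_k - v
  structure(list(s_j = s_j, s_k = s_k, v_jk = v, s_jk = s_u,
                 c_jk = 1 - v / s_u),
            class = "pair_overlap")
}

#' @export
print.pair_overlap <- function(x, ...) {
  cat(sprintf("pair overlap: S_j=%d S_k=%d V=%d union=%d C=%.4f\n",
              x$s_j, x$s_k, x$v_jk, x$s_jk, x$c_jk))
  invisible(x)
}

#' Configure complementary-set selection
#'
#' @param universe Which species the complementary set must cover: `"all"`,
#'   `"threatened"`, or `"custom"` with `custom_filter`.
#' @param custom_filter For `universe = "custom"`: a function taking the
#'   species attribute table and returning a logical vector.
#' @param mode Selection criterion at each greedy step:
#'   `"complementarity_score"` maximises the score between a candidate unit
#'   and the pooled species of the set built so far (the formal statement of
#'   the algorithm); `"new_species_count"` maximises the number of
#'   not-yet-covered species a candidate adds (the classic richness-gain
#'   greedy). Candidates adding no new species are never eligible under
#'   either mode, so both terminate exactly when the universe is covered.
#' @param stages Named list of predicate functions over the species table,
#'   processed in order with sequential subtraction; each stage runs the
#'   greedy loop until its own species class is covered. The default mirrors
#'   priority-first selection: first nationally protected or threatened
#'   species, then all remaining species. Stages must jointly cover the
#'   universe.
#'
#' @details Ties are broken deterministically: first by the selection
#' criterion, then by total species richness within the configured universe,
#' then by lexicographic unit identifier. The richness tie-break is part of
#' the algorithm; the final lexicographic rule exists only to make runs
#' reproducible.
#'
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(universe = c("all", "threatened", "custom"),
                             custom_filter = NULL,
                             mode = c("complementarity_score",
                                      "new_species_count"),
                             stages = NULL) {
  universe <- match.arg(universe)
  mode <- match.arg(mode)
  if (universe == "custom" && !is.function(custom_filter)) {
    stop("universe = \"custom\" requires a custom_filter function",
         call. = FALSE)
  }
  if (is.null(stages)) {
    stages <- list(
      priority = function(sp) sp$nationally_protected | sp$threatened,
      remainder = function(sp) rep(TRUE, nrow(sp)))
  }
  if (!length(stages) || is.null(names(stages)) || any(!nzchar(names(stages)))) {
    stop("stages must be a non-empty named list of predicates", call. = FALSE)
  }
  structure(list(universe = universe, custom_filter = custom_filter,
                 mode = mode, stages = stages),
            class = "selection_config")
}

# Resolve the species universe of a config against incidence + species table.
resolve_universe <- function(incidence, species_table, config) {
  if (config$universe == "all" && is.null(species_table)) {
    return(incidence$species)
  }
  if (is.null(species_table)) {
    stop("a species table is required for universe \"", config$universe,
         "\"", call. = FALSE)
  }
  keep <- switch(config$universe,
    all = rep(TRUE, nrow(species_table)),
    threatened = species_table$threatened,
    custom = config$custom_filter(species_table))
  intersect(incidence$species, species_table$species_id[keep])
}

#' Species currently represented by a complementary set
#'
#' Union of the member units' species sets, restricted to the target
#' universe: the set built so far is treated as one pooled composite site.
#'
#' @param cs A `complementary_set` object, or a character vector of unit
#'   identifiers.
#' @param incidence An [incidence_matrix()] object.
#' @param universe Character vector of target species.
#' @return Sorted character vector of covered species.
#' @export
pooled_species <- function(cs, incidence, universe) {
  intersect(species_of(incidence, cs_members(cs)), universe)
}

# Members of a complementary set, or pass a bare character vector through.
cs_members <- function(cs) {
  if (inherits(cs, "complementary_set")) cs$members
  else as.character(cs)
}

#' One greedy selection step
#'
#' Among units not yet in the set that add at least one uncovered species of
#' the target universe, picks the winner under the configured criterion
#' (complementarity score against the pooled species of the current set, or
#' raw count of new species), breaking ties by universe richness then unit
#' identifier.
#'
#' @param incidence An [incidence_matrix()] object.
#' @param cs Current `complementary_set` (or character vector of members).
#' @param universe Character vector: the species the step must make progress
#'   on.
#' @param config A [selection_config()] (only `mode` is used here).
#' @return `NULL` when no candidate adds a new species (exhaustion);
#'   otherwise a list with `unit_id`, `overlap` (the [complementarity_score()]
#'   of the chosen unit against the pooled set) and `n_new`.
#' @export
greedy_step <- function(incidence, cs, universe,
                        config = selection_config()) {
  members <- cs_members(cs)
  covered <- pooled_species(cs, incidence, universe)
  candidates <- setdiff(incidence$units, members)
  if (length(candidates) == 0L) return(NULL)
  cand_sets <- lapply(incidence$species_by_unit[candidates],
                      intersect, universe)
  gains <- vapply(cand_sets, function(s) length(setdiff(s, covered)),
                  integer(1))
  ok <- gains >= 1L
  if (!any(ok)) return(NULL)
  candidates <- candidates[ok]
  cand_sets <- cand_sets[ok]
  gains <- gains[ok]
  score <- if (config$mode == "new_species_count") {
    as.numeric(gains)
  } else {
    n_cov <- length(covered)
    vapply(cand_sets, function(s) {
      v <- length(intersect(s, covered))
      1 - v / (length(s) + n_cov - v)
    }, numeric(1))
  }
  richness <- lengths(cand_sets)
  pick <- order(-score, -richness, candidates)[1L]
  chosen <- candidates[pick]
  list(unit_id = chosen,
       overlap = complementarity_score(cand_sets[[pick]], covered),
       n_new = as.integer(gains[pick]))
}
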