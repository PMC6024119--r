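# Shared fixtures and independent oracles for the test suite.

# Incidence matrix from a named list unit -> species vector.
make_inc <- function(unit_sets) {
  incidence_matrix(data.frame(
    species_id = unlist(unit_sets, use.names = FALSE),
    unit_id = rep(names(unit_sets), lengths(unit_sets)),
    stringsAsFactors = FALSE))
}

# Minimal unit table wrapper.
make_units <- function(unit_id, stratum = "s1", area = 100, pa_coverage = 0) {
  validate_unit_table(data.frame(
    unit_id = unit_id, stratum = stratum, area = area,
    pa_coverage = pa_coverage, stringsAsFactors = FALSE))
}

# Random incidence instance in which every species occurs at least once.
rand_instance <- function(n_units, n_species) {
  units <- paste0("u", sprintf("%02d", seq_len(n_units)))
  species <- paste0("s", sprintf("%02d", seq_len(n_species)))
  # each species gets 1..3 random units; each unit may stay empty
  sets <- lapply(species, function(s) sample(units, sample(1:3, 1)))
  df <- data.frame(species_id = rep(species, lengths(sets)),
                   unit_id = unlist(sets), stringsAsFactors = FALSE)
  suppressWarnings(incidence_matrix(df))
}

# Exact minimum set-cover size by exhaustive bitmask search (<= 25 species,
# any unit count small enough to enumerate subsets of).
min_cover_size <- function(incidence, universe = incidence$species) {
  sp <- universe
  stopifnot(length(sp) <= 25)
  bit_of <- stats::setNames(2^(seq_along(sp) - 1), sp)
  masks <- vapply(incidence$species_by_unit,
                  function(s) sum(bit_of[intersect(s, sp)]), numeric(1))
  full <- sum(bit_of)
  n <- length(masks)
  for (k in seq_len(n)) {
    combos <- utils::combn(n, k)
    for (j in seq_len(ncol(combos))) {
      m <- 0
      for (i in combos[, j]) m <- bitwOr(m, masks[i])
      if (m == full) return(k)
    }
  }
  stop("no cover exists")
}

# Straight-line independent simulation of the single-stage greedy algorithm
# (seed on richness, then iterate; ties by score, richness, unit id). Kept
# deliberately naive and separate from the package implementation.
naive_greedy <- function(incidence, universe = incidence$species,
                         mode = "complementarity_score") {
  sets <- lapply(incidence$species_by_unit, intersect, universe)
  units <- incidence$units
  richness <- lengths(sets)
  pick_best <- function(cand, score) {
    ord <- order(-score, -richness[cand], units[cand])
    cand[ord[1]]
  }
  cand0 <- which(richness > 0)
  seed <- pick_best(cand0, richness[cand0])
  chosen <- units[seed]
  covered <- sets[[seed]]
  repeat {
    cand <- which(!(units %in% chosen))
    if (!length(cand)) break
    gains <- vapply(cand, function(i) length(setdiff(sets[[i]], covered)),
                    integer(1))
    cand <- cand[gains >= 1]
    if (!length(cand)) break
    score <- vapply(cand, function(i) {
      if (mode == "new_species_count") {
        length(setdiff(sets[[i]], covered))
      } else {
        v <- length(intersect(sets[[i]], covered))
        1 - v / (length(sets[[i]]) + length(covered) - v)
      }
    }, numeric(1))
    best <- pick_best(cand, score)
    chosen <- c(chosen, units[best])
    covered <- union(covered, sets[[best]])
  }
  chosen
}
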