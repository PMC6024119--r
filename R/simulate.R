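#' Configure the synthetic occurrence simulator
#'
#' The generator emulates the statistical shape of a national, county-level
#' species occurrence database: six taxon groups of very different sizes,
#' heavy-tailed species occupancy (many narrow-range species, a few
#' widespread ones), ranges clustered within biogeographic strata,
#' threatened status concentrated among narrow-range species, and a PA
#' layer in which many units have no protection and most protected units
#' have low coverage.
#'
#' Defaults are a desk-scale rendition of such a database: 240 planning
#' units in 8 strata; per-group species counts 520/115/20/23/68/30 (woody
#' plants, ferns, amphibians, reptiles, birds, mammals — the relative sizes
#' of a national flora/fauna, scaled down); per-group threatened fractions
#' equal to the national Red-List ratios of those groups; 30% of units with
#' zero PA coverage and Beta(0.6, 4) coverage elsewhere (right-skewed,
#' mostly below 10%).
#'
#' @param n_units Number of planning units.
#' @param n_strata Number of biogeographic strata (units split evenly).
#' @param species_per_group Named integer vector of species per taxon group.
#' @param occupancy List: `distribution = "logseries"` with parameter
#'   `theta` in (0, 1) (P(n) proportional to theta^n / n, truncated to
#'   1..n_units), or `distribution = "lognormal"` with `meanlog`, `sdlog`
#'   (rounded and truncated likewise).
#' @param range_cohesion Probability mass of a species' occurrences placed
#'   in its home stratum, in \[0.5, 1\].
#' @param threatened_fraction Per-group (recycled) fraction of threatened
#'   species.
#' @param protected_fraction Fraction of nationally protected species.
#' @param endemic_fraction Fraction of endemic species.
#' @param threat_rank_power Strength of the association between threat
#'   status and narrow range: threatened species are drawn with weight
#'   `(rank from narrowest)^-power`-like preference (0 = independent).
#' @param pa_zero_fraction Proportion of units with zero PA coverage.
#' @param pa_coverage_distribution List `shape1`, `shape2` of the Beta
#'   distribution for non-zero coverage.
#' @param seed RNG seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_units = 240L,
    n_strata = 8L,
    species_per_group = c(woody_plant = 520L, fern = 115L, amphibian = 20L,
                          reptile = 23L, bird = 68L, mammal = 30L),
    occupancy = list(distribution = "logseries", theta = 0.98),
    range_cohesion = 0.8,
    threatened_fraction = c(woody_plant = 1490 / 10396, fern = 148 / 2305,
                            amphibian = 176 / 406, reptile = 138 / 460,
                            bird = 146 / 1364, mammal = 156 / 590),
    protected_fraction = 0.05,
    endemic_fraction = 0.4,
    threat_rank_power = 2,
    pa_zero_fraction = 0.3,
    pa_coverage_distribution = list(shape1 = 0.6, shape2 = 4),
    seed = 1L) {
  if (n_units < 1L || n_strata < 1L || n_strata > n_units) {
    stop("need 1 <= n_strata <= n_units", call. = FALSE)
  }
  if (is.null(names(species_per_group))) {
    stop("species_per_group must be named by taxon group", call. = FALSE)
  }
  if (any(species_per_group < 1L)) {
    stop("species_per_group must be positive", call. = FALSE)
  }
  if (range_cohesion < 0.5 || range_cohesion > 1) {
    stop("range_cohesion must lie in [0.5, 1]", call. = FALSE)
  }
  fr <- c(threatened_fraction, protected_fraction, endemic_fraction,
          pa_zero_fraction)
  if (any(fr < 0 | fr > 1)) {
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_units = as.integer(n_units), n_strata = as.integer(n_strata),
    species_per_group = species_per_group, occupancy = occupancy,
    range_cohesion = range_cohesion,
    threatened_fraction = threatened_fraction,
    protected_fraction = protected_fraction,
    endemic_fraction = endemic_fraction,
    threat_rank_power = threat_rank_power,
    pa_zero_fraction = pa_zero_fraction,
    pa_coverage_distribution = pa_coverage_distribution,
    seed = as.integer(seed)), class = "simulation_config")
}

# Occupancy pmf on 1..n_units under the configured distribution.
occupancy_pmf <- function(occupancy, n_units) {
  n <- seq_len(n_units)
  p <- switch(occupancy$distribution,
    logseries = occupancy$theta^n / n,
    lognormal = stats::dlnorm(n, occupancy$meanlog, occupancy$sdlog),
    stop("unknown occupancy distribution: ", occupancy$distribution,
         call. = FALSE))
  p / sum(p)
}

#' Simulate a full synthetic dataset
#'
#' Draws species occupancies, places occurrences with range cohesion around
#' a home stratum, assigns threat/protection/endemism flags (threat biased
#' toward narrow-range species) and a zero-inflated right-skewed PA
#' coverage layer. Fully reproducible from `config$seed`. Strata double as
#' the region assignment of both species (home stratum) and units.
#'
#' @param config A [simulation_config()].
#' @return List with components `incidence` ([incidence_matrix()] object),
#'   `species` and `units` (validated attribute tables), and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_units <- config$n_units
  strata <- paste0("str", sprintf("%02d", seq_len(config$n_strata)))
  unit_ids <- paste0("u", sprintf("%04d", seq_len(n_units)))
  unit_stratum <- rep(strata, length.out = n_units)

  pmf <- occupancy_pmf(config$occupancy, n_units)
  groups <- names(config$species_per_group)
  thr_frac <- rep(config$threatened_fraction, length.out = length(groups))

  sp_rows <- list()
  occ_sp <- character(0)
  occ_un <- character(0)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n_g <- config$species_per_group[[gi]]
    ids <- paste0(g, "_", sprintf("%04d", seq_len(n_g)))
    occ_n <- sample(n_units, n_g, replace = TRUE, prob = pmf)
    home <- sample(strata, n_g, replace = TRUE)
    for (si in seq_len(n_g)) {
      in_home <- unit_stratum == home[si]
      w <- ifelse(in_home,
                  config$range_cohesion / sum(in_home),
                  (1 - config$range_cohesion) / sum(!in_home))
      picked <- sample(unit_ids, occ_n[si], prob = w)
      occ_sp <- c(occ_sp, rep(ids[si], occ_n[si]))
      occ_un <- c(occ_un, picked)
    }
    # threat biased toward narrow ranges via rank weights
    n_thr <- as.integer(round_half_up(thr_frac[gi] * n_g))
    threatened <- rep(FALSE, n_g)
    if (n_thr > 0L) {
      rk <- rank(occ_n, ties.method = "first")
      w_thr <- (n_g - rk + 1)^config$threat_rank_power
      threatened[sample(n_g, n_thr, prob = w_thr)] <- TRUE
    }
    sp_rows[[gi]] <- data.frame(
      species_id = ids, taxon_group = g, threatened = threatened,
      nationally_protected = stats::runif(n_g) < config$protected_fraction,
      endemic = stats::runif(n_g) < config$endemic_fraction,
      region = home, stringsAsFactors = FALSE)
  }
  species <- validate_species_table(do.call(rbind, sp_rows))

  cov <- ifelse(stats::runif(n_units) < config$pa_zero_fraction, 0,
                stats::rbeta(n_units,
                             config$pa_coverage_distribution$shape1,
                             config$pa_coverage_distribution$shape2))
  units <- validate_unit_table(data.frame(
    unit_id = unit_ids, stratum = unit_stratum, region = unit_stratum,
    area = stats::rlnorm(n_units, meanlog = log(2e5), sdlog = 0.5),
    pa_coverage = pmin(cov, 1), stringsAsFactors = FALSE))

  incidence <- incidence_matrix(
    data.frame(species_id = occ_sp, unit_id = occ_un,
               stringsAsFactors = FALSE))
  list(incidence = incidence, species = species, units = units,
       config = config)
}

#' Planted known-answer cover fixture
#'
#' Constructs a block structure with a unique minimal cover, for testing
#' site-selection correctness. Each of `k_blocks` designated units is the
#' sole holder of one endemic (and threatened) species, making it
#' irreplaceable, and additionally carries its block's shared species.
#' Decoy units carry only strict subsets of the shared species; extra units
#' carry nothing new either. The unique minimal cover is therefore exactly
#' the `k_blocks` designated units, for any correct selection rule.
#'
#' @param k_blocks Number of designated (irreplaceable) units.
#' @param shared_per_block Shared species per block, also present in the
#'   block's decoys.
#' @param decoys_per_block Decoy units per block.
#' @param extra_units Additional units holding a random covered species.
#' @param n_strata Strata over which blocks are distributed.
#' @param seed RNG seed (used only for the extra units' species draws).
#' @return List `incidence`, `species`, `units`, `truth` where `truth` has
#'   `planted_units`, `decoy_units`, `extra_units`, `minimal_cover` and
#'   `endemic_species`.
#' @export
simulate_planted_cover <- function(k_blocks = 5L, shared_per_block = 2L,
                                   decoys_per_block = 0L, extra_units = 0L,
                                   n_strata = min(k_blocks, 4L), seed = 1L) {
  if (k_blocks < 1L) stop("k_blocks must be >= 1", call. = FALSE)
  set.seed(seed)
  planted <- paste0("core", sprintf("%02d", seq_len(k_blocks)))
  strata <- paste0("str", sprintf("%02d", seq_len(n_strata)))
  sp <- character(0); un <- character(0)
  sp_rows <- list(); unit_rows <- list()
  decoys <- character(0)
  endemics <- character(0)
  shared_all <- character(0)
  for (b in seq_len(k_blocks)) {
    endemic_b <- sprintf("end%02d", b)
    shared_b <- if (shared_per_block > 0L) {
      sprintf("sh%02d_%02d", b, seq_len(shared_per_block))
    } else character(0)
    endemics <- c(endemics, endemic_b)
    shared_all <- c(shared_all, shared_b)
    sp <- c(sp, endemic_b, shared_b)
    un <- c(un, rep(planted[b], 1L + length(shared_b)))
    stratum_b <- strata[(b - 1L) %% n_strata + 1L]
    unit_rows[[length(unit_rows) + 1L]] <- data.frame(
      unit_id = planted[b], stratum = stratum_b, stringsAsFactors = FALSE)
    if (decoys_per_block > 0L && length(shared_b) > 0L) {
      for (d in seq_len(decoys_per_block)) {
        dk <- sprintf("decoy%02d_%02d", b, d)
        decoys <- c(decoys, dk)
        take <- shared_b[seq_len(max(1L, length(shared_b) - 1L))]
        sp <- c(sp, take)
        un <- c(un, rep(dk, length(take)))
        unit_rows[[length(unit_rows) + 1L]] <- data.frame(
          unit_id = dk, stratum = stratum_b, stringsAsFactors = FALSE)
      }
    }
  }
  extras <- character(0)
  if (extra_units > 0L && length(shared_all) > 0L) {
    extras <- paste0("extra", sprintf("%02d", seq_len(extra_units)))
    for (i in seq_along(extras)) {
      pickable <- sample(shared_all, 1L)
      sp <- c(sp, pickable)
      un <- c(un, extras[i])
      unit_rows[[length(unit_rows) + 1L]] <- data.frame(
        unit_id = extras[i], stratum = strata[(i - 1L) %% n_strata + 1L],
        stringsAsFactors = FALSE)
    }
  }
  units <- do.call(rbind, unit_rows)
  units$area <- 100
  units$pa_coverage <- 0
  units <- validate_unit_table(units)
  all_sp <- unique(sp)
  species <- validate_species_table(data.frame(
    species_id = all_sp,
    taxon_group = "planted",
    threatened = all_sp %in% endemics,
    nationally_protected = FALSE,
    endemic = all_sp %in% endemics,
    region = "str01", stringsAsFactors = FALSE))
  incidence <- incidence_matrix(
    data.frame(species_id = sp, unit_id = un, stringsAsFactors = FALSE))
  list(incidence = incidence, species = species, units = units,
       truth = list(planted_units = planted, decoy_units = decoys,
                    extra_units = extras, minimal_cover = planted,
                    endemic_species = endemics))
}

#' Simulate a protected-area coverage timeline
#'
#' Generates per-unit, per-year coverage paths ending at the unit's current
#' coverage. Under `growth_rule = "monotone"` every path is nondecreasing
#' (PA networks that only grow); `"constant"` repeats current coverage;
#' `"with_degazettement"` inserts occasional decreases at the given rate,
#' reflecting downgrading and degazettement of protected areas.
#'
#' @param units Validated unit attribute table.
#' @param years Increasing integer vector of years.
#' @param growth_rule One of `"monotone"`, `"constant"`,
#'   `"with_degazettement"`.
#' @param degazettement_rate Probability that a unit-year transition
#'   decreases, under `"with_degazettement"`.
#' @param seed RNG seed.
#' @return Long data frame `unit_id`, `year`, `pa_coverage`.
#' @export
simulate_pa_timeline <- function(units, years,
                                 growth_rule = c("monotone", "constant",
                                                 "with_degazettement"),
                                 degazettement_rate = 0.1, seed = 1L) {
  growth_rule <- match.arg(growth_rule)
  if (is.unsorted(years, strictly = TRUE)) {
    stop("years must be strictly increasing", call. = FALSE)
  }
  set.seed(seed)
  n_y <- length(years)
  paths <- lapply(seq_len(nrow(units)), function(i) {
    final <- units$pa_coverage[i]
    if (growth_rule == "constant" || n_y == 1L) {
      return(rep(final, n_y))
    }
    # nondecreasing ramp from a random starting share of final coverage
    start <- final * stats::runif(1, 0, 0.5)
    incr <- stats::runif(n_y - 1L)
    path <- start + (final - start) * c(0, cumsum(incr) / sum(incr))
    if (growth_rule == "with_degazettement") {
      for (t in 2:n_y) {
        if (stats::runif(1) < degazettement_rate) {
          path[t] <- path[t - 1L] * stats::runif(1, 0.5, 0.99)
        }
      }
      path <- pmin(pmax(path, 0), 1)
    }
    path
  })
  data.frame(
    unit_id = rep(units$unit_id, each = n_y),
    year = rep(years, times = nrow(units)),
    pa_coverage = unlist(paths, use.names = FALSE))
}
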