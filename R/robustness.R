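#' Configure the stratified bootstrap
#'
#' @param fractions Proportions of units sampled per stratum; the default
#'   grid is 60/70/80/90%.
#' @param replicates Replicates per fraction (default 1000; reduce for large
#'   datasets).
#' @param seed Master RNG seed. Per-replicate substreams are derived from
#'   it, so runs with different replicate counts share their first draws.
#' @param stratum_field Unit attribute used as the sampling stratum.
#' @return Object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(fractions = c(0.6, 0.7, 0.8, 0.9),
                             replicates = 1000L, seed = 1L,
                             stratum_field = "stratum") {
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("replicates must be >= 1", call. = FALSE)
  }
  structure(list(fractions = fractions, replicates = replicates,
                 seed = as.integer(seed), stratum_field = stratum_field),
            class = "bootstrap_config")
}

#' Stratified random sample of planning units
#'
#' Independently within each stratum, draws `round-half-up(fraction * n)`
#' units (at least 1) uniformly without replacement, using the current RNG
#' state. Strata are visited in sorted order so the draw is a deterministic
#' function of the RNG state.
#'
#' @param units Unit attribute table.
#' @param fraction Sampling proportion in (0, 1].
#' @param stratum_field Column holding the stratum.
#' @return Character vector of sampled unit identifiers.
#' @export
stratified_sample <- function(units, fraction, stratum_field = "stratum") {
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  strata <- units[[stratum_field]]
  if (is.null(strata) || anyNA(strata)) {
    stop("every unit needs a stratum in column '", stratum_field, "'",
         call. = FALSE)
  }
  out <- lapply(sort(unique(strata)), function(s) {
    ids <- units$unit_id[strata == s]
    n_take <- max(1L, as.integer(round_half_up(fraction * length(ids))))
    if (n_take >= length(ids)) ids else sample(ids, n_take)
  })
  unlist(out, use.names = FALSE)
}

#' Proportional overlap between two complementary sets
#'
#' The robustness statistic N_c / N_s: the share of the subset-derived set's
#' units that also belong to the full-data set.
#'
#' @param cs_subset Complementary set built on a data subset (non-empty).
#' @param cs_original Complementary set built on the full data.
#' @return List `n_s`, `n_c`, `overlap`.
#' @export
proportional_overlap <- function(cs_subset, cs_original) {
  sub <- cs_members(cs_subset)
  orig <- cs_members(cs_original)
  if (length(sub) == 0L) stop("subset complementary set is empty",
                              call. = FALSE)
  if (length(orig) == 0L) stop("original complementary set is empty",
                               call. = FALSE)
  n_c <- length(intersect(sub, orig))
  list(n_s = length(sub), n_c = n_c, overlap = n_c / length(sub))
}

# Deterministic per-replicate seed: depends only on (master, fraction index,
# replicate index), so extending the replicate count preserves earlier draws.
replicate_seed <- function(master, f_idx, r) {
  as.integer((as.double(master) * 1000003 + f_idx * 10007 + r * 101) %%
               2147483629)
}

#' Bootstrap robustness of complementary-set selection
#'
#' For each sampling fraction and replicate: draw a stratified subset of
#' units, restrict the incidence matrix to it (species losing all
#' occurrences drop out of that replicate's universe), rebuild the
#' complementary set with the same selection configuration, and compute its
#' proportional overlap with the full-data set. High average overlap means
#' the selection is insensitive to which units happened to be sampled —
#' i.e. robust to geographic sampling error in the occurrence data.
#'
#' @param incidence An [incidence_matrix()] object.
#' @param species_table Species attribute table (may be `NULL` for an
#'   all-species run without priority stages).
#' @param units Unit attribute table with the stratum column.
#' @param selection A [selection_config()].
#' @param config A [bootstrap_config()].
#' @return Object of class `bootstrap_result`: `replicates` (data frame
#'   `fraction`, `replicate`, `n_s`, `n_c`, `overlap`, `failed`), `summary`
#'   (per-fraction mean/sd overlap and failure count), `cs_full`, `config`.
#'   Replicates whose restricted universe is empty are flagged failed and
#'   excluded from the means.
#' @export
bootstrap_robustness <- function(incidence, species_table, units,
                                 selection = selection_config(),
                                 config = bootstrap_config()) {
  stopifnot(inherits(config, "bootstrap_config"))
  cs_full <- build_complementary_set(incidence, species_table, selection)
  rows <- vector("list", length(config$fractions) * config$replicates)
  k <- 0L
  for (f_idx in seq_along(config$fractions)) {
    f <- config$fractions[f_idx]
    for (r in seq_len(config$replicates)) {
      set.seed(replicate_seed(config$seed, f_idx, r))
      sub_units <- stratified_sample(units, f, config$stratum_field)
      k <- k + 1L
      res <- tryCatch({
        sub_inc <- restrict_units(incidence, sub_units)
        cs_sub <- build_complementary_set(sub_inc, species_table, selection)
        ov <- proportional_overlap(cs_sub, cs_full)
        data.frame(fraction = f, replicate = r, n_s = ov$n_s, n_c = ov$n_c,
                   overlap = ov$overlap, failed = FALSE)
      }, error = function(e) {
        data.frame(fraction = f, replicate = r, n_s = NA_integer_,
                   n_c = NA_integer_, overlap = NA_real_, failed = TRUE)
      })
      rows[[k]] <- res
    }
  }
  reps <- do.call(rbind, rows)
  n_failed <- sum(reps$failed)
  if (n_failed > 0L) {
    message(sprintf("%d replicate(s) failed (empty restricted universe)",
                    n_failed))
  }
  ok <- !reps$failed
  summ <- do.call(rbind, lapply(config$fractions, function(f) {
    v <- reps$overlap[ok & reps$fraction == f]
    data.frame(fraction = f, n_ok = length(v),
               n_failed = sum(reps$failed & reps$fraction == f),
               mean_overlap = mean(v), sd_overlap = stats::sd(v),
               min_overlap = min(v), max_overlap = max(v))
  }))
  structure(list(replicates = reps, summary = summ, cs_full = cs_full,
                 config = config), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap robustness: %d fractions x %d replicates\n",
              length(x$config$fractions), x$config$replicates))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
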