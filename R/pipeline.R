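#' Simulate a dataset and write its input tables
#'
#' Writes the three standard input tables (presence records, species
#' attributes, unit attributes) plus a JSON manifest echoing the
#' configuration, so a full analysis can start from files on disk.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the simulated dataset list.
#' @export
run_simulate <- function(config = simulation_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(config)
  write_presence_records(ds$incidence, file.path(out_dir, "presence.csv"))
  write_delim_table(ds$species, file.path(out_dir, "species.csv"))
  units <- ds$units
  write_delim_table(units, file.path(out_dir, "units.csv"))
  cfg <- ds$config
  cfg$species_per_group <- as.list(cfg$species_per_group)
  cfg$threatened_fraction <- as.list(cfg$threatened_fraction)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ds)
}

# Load a dataset from a directory written by run_simulate(), or pass a
# dataset list straight through.
resolve_dataset <- function(input) {
  if (is.list(input) && inherits(input$incidence, "incidence")) return(input)
  if (is.character(input) && length(input) == 1L && dir.exists(input)) {
    return(list(
      incidence = read_presence_records(file.path(input, "presence.csv")),
      species = read_species_table(file.path(input, "species.csv")),
      units = read_unit_table(file.path(input, "units.csv"))))
  }
  stop("`input` must be a dataset list or a directory of input tables",
       call. = FALSE)
}

#' Build and write complementary sets
#'
#' Builds the all-species and threatened-species complementary sets with the
#' given selection mode and writes their traces (`cs_all.csv`,
#' `cs_threatened.csv`) and manifests.
#'
#' @param input Dataset list (from [simulate_dataset()]) or directory of
#'   input tables.
#' @param out_dir Output directory.
#' @param mode Selection criterion, see [selection_config()].
#' @param universes Which universes to build.
#' @return Invisibly, a named list of `complementary_set` objects.
#' @export
run_build_cs <- function(input, out_dir,
                         mode = c("complementarity_score",
                                  "new_species_count"),
                         universes = c("all", "threatened")) {
  mode <- match.arg(mode)
  ds <- resolve_dataset(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (u in universes) {
    cs <- build_complementary_set(
      ds$incidence, ds$species, selection_config(universe = u, mode = mode))
    write_cs_trace(cs, file.path(out_dir, paste0("cs_", u, ".csv")))
    out[[u]] <- cs
  }
  invisible(out)
}

#' Run the full representation assessment and write the report bundle
#'
#' For each complementary set: representation at the presence criterion and
#' a threshold grid, gap identification, congruence with the PA-present
#' units, coverage-class areas, regional effectiveness (when region
#' assignments exist), and optionally a representation time series from a
#' per-year coverage table.
#'
#' @param input Dataset list or input directory.
#' @param cs_list Named list of `complementary_set` objects (e.g. from
#'   [run_build_cs()]).
#' @param out_dir Output directory.
#' @param thresholds Coverage thresholds (sorted ascending in output).
#' @param gap_definition Passed to [identify_gaps()].
#' @param coverage_timeline Optional long per-year coverage table for
#'   [representation_time_series()].
#' @return Invisibly, a nested list of all result objects.
#' @export
run_assess <- function(input, cs_list, out_dir,
                       thresholds = c(0.1, 0.2, 0.3, 0.4),
                       gap_definition = "rangewide",
                       coverage_timeline = NULL) {
  ds <- resolve_dataset(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pa_units <- select_protected_units(ds$units, "presence")
  results <- list()
  summary_json <- list()
  for (label in names(cs_list)) {
    cs <- cs_list[[label]]
    rep_tab <- assess_representation(cs, ds$units, thresholds)
    gaps <- identify_gaps(cs, pa_units, ds$incidence,
                          species_table = ds$species,
                          definition = gap_definition)
    cong <- congruence_summary(cs, pa_units, ds$units)
    classes <- coverage_class_areas(cs, ds$units)
    write_delim_table(rep_tab,
                      file.path(out_dir, paste0("representation_", label,
                                                ".csv")))
    write_delim_table(
      data.frame(unit_id = gaps$gap_units),
      file.path(out_dir, paste0("gap_units_", label, ".csv")))
    write_delim_table(
      data.frame(species_id = gaps$uncovered_species,
                 threatened = gaps$uncovered_species %in%
                   gaps$threatened_uncovered,
                 endemic = gaps$uncovered_species %in%
                   gaps$endemic_uncovered),
      file.path(out_dir, paste0("uncovered_species_", label, ".csv")))
    write_delim_table(classes,
                      file.path(out_dir, paste0("coverage_classes_", label,
                                                ".csv")))
    res <- list(representation = rep_tab, gaps = gaps, congruence = cong,
                coverage_classes = classes)
    if (!all(is.na(ds$species$region))) {
      reg <- regional_effectiveness(cs, ds$incidence, ds$species, ds$units)
      write_delim_table(reg,
                        file.path(out_dir, paste0("regional_effectiveness_",
                                                  label, ".csv")))
      res$regional <- reg
      res$regional_mean <- attr(reg, "mean")
      res$regional_sd <- attr(reg, "sd")
    }
    if (!is.null(coverage_timeline)) {
      ts <- representation_time_series(cs, coverage_timeline, "presence")
      write_delim_table(ts, file.path(out_dir, paste0("time_series_", label,
                                                      ".csv")))
      res$time_series <- ts
    }
    results[[label]] <- res
    summary_json[[label]] <- list(
      n_cs = length(cs$members),
      universe_size = length(cs$universe),
      n_gap_units = length(gaps$gap_units),
      n_uncovered_species = length(gaps$uncovered_species),
      pct_common = cong$pct_common_int,
      area_pct_common = cong$area_pct_common_int,
      i_e = stats::setNames(as.list(rep_tab$i_e_rounded),
                            ifelse(rep_tab$criterion == "presence",
                                   "presence",
                                   paste0("ge_", rep_tab$threshold))))
  }
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Run the bootstrap robustness analysis and write its tables
#'
#' @param input Dataset list or input directory.
#' @param out_dir Output directory.
#' @param selection A [selection_config()].
#' @param config A [bootstrap_config()].
#' @return Invisibly, the `bootstrap_result`.
#' @export
run_bootstrap <- function(input, out_dir,
                          selection = selection_config(),
                          config = bootstrap_config()) {
  ds <- resolve_dataset(input)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- bootstrap_robustness(ds$incidence, ds$species, ds$units,
                              selection, config)
  write_delim_table(res$replicates,
                    file.path(out_dir, "bootstrap_replicates.csv"))
  write_delim_table(res$summary, file.path(out_dir, "bootstrap_summary.csv"))
  jsonlite::write_json(unclass(res$config),
                       file.path(out_dir, "bootstrap_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Assemble a human-readable report from a results directory
#'
#' Concatenates the summary tables written by [run_assess()] and
#' [run_bootstrap()] into one markdown file.
#'
#' @param out_dir Directory holding the report bundle; the report is written
#'   there as `report.md`.
#' @return Invisibly, the report path.
#' @export
run_report <- function(out_dir) {
  lines <- c("# Protected-area representation report", "")
  fmt_tab <- function(df) {
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1L, function(r) paste(trimws(format(r)), collapse = " | ")),
      "")
  }
  for (f in sort(list.files(out_dir, pattern = "\\.csv$"))) {
    df <- read_delim_table(file.path(out_dir, f))
    lines <- c(lines, paste0("## ", sub("\\.csv$", "", f)), "",
               fmt_tab(utils::head(df, 25L)))
    if (nrow(df) > 25L) {
      lines <- c(lines, sprintf("(%d further rows omitted)", nrow(df) - 25L),
                 "")
    }
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
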