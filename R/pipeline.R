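#' Simulate a probing experiment and write its files
#'
#' Runs a named benchmark scenario and writes the plus- and minus-channel
#' count tables, the ground-truth dot-bracket structure and a manifest
#' JSON recording the scenario name and seed.
#'
#' @param name Scenario name (see [make_benchmark_scenario()]).
#' @param out_dir Output directory, created if missing.
#' @param seed Integer seed.
#' @param n_molecules Number of simulated molecules.
#' @return A tibble listing the files written, invisibly.
#' @export
pipeline_simulate <- function(name, out_dir, seed = 1L,
                              n_molecules = 100000L) {
  scenario <- make_benchmark_scenario(name, seed = seed,
                                      n_molecules = n_molecules)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- simulate_experiment(scenario$config)
  paths <- c(plus = file.path(out_dir, "counts_plus.tsv"),
             minus = file.path(out_dir, "counts_minus.tsv"),
             structure = file.path(out_dir, "structure.dbn"),
             manifest = file.path(out_dir, "manifest.json"))
  write_counts_tsv(sim$plus, paths[["plus"]])
  write_counts_tsv(sim$minus, paths[["minus"]])
  write_dotbracket(scenario$structure, paths[["structure"]])
  jsonlite::write_json(
    list(scenario = name, seed = seed, n_molecules = n_molecules,
         rna_id = rna_id(scenario$structure),
         mode = scenario$config$mode,
         tool = "probeval", version = as.character(utils::packageVersion("probeval"))),
    paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(tibble(role = names(paths), path = unname(paths)))
}

#' Compute a filtered reactivity profile from count tables
#'
#' Chains the reactivity stages: rate computation from the plus channel,
#' optional background subtraction of the minus channel, the strict
#' coverage filter, and the probe-specific base filter.
#'
#' @param counts_plus A `count_profile` or path to a counts TSV
#'   (probe-treated channel).
#' @param counts_minus Optional `count_profile` or path (probe-free
#'   background); when given, reactivity is background-subtracted.
#' @param probe `"DMS"` (A/C only) or `"SHAPE"` (all bases).
#' @param min_depth Coverage that must be strictly exceeded (default 500).
#' @param clamp Floor negative background-adjusted values at 0.
#' @param out Optional path; when given the profile is written as a
#'   reactivity TSV.
#' @return A `reactivity_profile`.
#' @export
pipeline_react <- function(counts_plus, counts_minus = NULL,
                           probe = c("SHAPE", "DMS"),
                           min_depth = 500L, clamp = FALSE, out = NULL) {
  probe <- match.arg(probe)
  if (is.character(counts_plus)) counts_plus <- read_counts_tsv(counts_plus)
  if (is.character(counts_minus)) counts_minus <- read_counts_tsv(counts_minus)
  rate_fun <- if (profile_mode(counts_plus) == "stop") stop_rate else mutation_rate
  profile <- rate_fun(counts_plus)
  if (!is.null(counts_minus)) {
    profile <- background_adjust(profile, rate_fun(counts_minus), clamp = clamp)
    # both channels must clear the coverage filter
    profile <- apply_coverage_filter(profile, counts_minus, min_depth)
  }
  profile <- apply_coverage_filter(profile, counts_plus, min_depth)
  profile <- apply_base_filter(profile, probe)
  if (!is.null(out)) write_reactivity_tsv(profile, out)
  profile
}

#' Evaluate a reactivity profile against a reference structure
#'
#' Produces a run report: AUC of unpaired-base discrimination, the
#' top-x% unpaired-fraction curve, the fraction of bases with rate at
#' least 0.1, and class-conditional summaries. Degenerate label sets
#' (all valid bases paired, or all unpaired) yield `NULL` metric fields
#' with a reason instead of an error.
#'
#' @param reactivity A `reactivity_profile` or path to a reactivity TSV.
#' @param structure A `secondary_structure` or path to a dot-bracket
#'   file. Its `rna_id` must match the profile's.
#' @param x_grid Percentages for the top-x% curve (default 5, 10, 20,
#'   ..., 100).
#' @param out Optional path for the JSON report.
#' @return A `run_report` list with fields `rna_id`, `mode`, `probe`,
#'   `background_used`, `n_valid`, `auc`, `top_x_curve`,
#'   `fraction_rate_ge_0.1`, `class_summary`, `overlap`, `reason` and
#'   `provenance`.
#' @export
pipeline_evaluate <- function(reactivity, structure,
                              x_grid = c(5, seq(10, 100, by = 10)),
                              out = NULL) {
  if (is.character(reactivity)) reactivity <- read_reactivity_tsv(reactivity)
  if (is.character(structure)) structure <- read_dotbracket(structure)
  if (!identical(rna_id(reactivity), rna_id(structure))) {
    abort(sprintf("rna_id mismatch: profile '%s' vs structure '%s'.",
                  rna_id(reactivity), rna_id(structure)),
          class = "probeval_pairing_error")
  }
  report <- list(
    rna_id = rna_id(reactivity),
    mode = profile_mode(reactivity),
    probe = attr(reactivity, "probe"),
    background_used = identical(attr(reactivity, "background"), "subtracted"),
    n_valid = length(valid_positions(reactivity)),
    auc = NULL, top_x_curve = NULL, fraction_rate_ge_0.1 = NULL,
    class_summary = NULL, overlap = NULL, reason = NULL,
    provenance = list(x_grid = x_grid,
                      tool = "probeval",
                      version = as.character(utils::packageVersion("probeval")))
  )
  degenerate <- tryCatch({
    roc <- roc_auc(reactivity, structure)
    report$auc <- roc$auc
    cs <- class_conditional_summary(reactivity, structure)
    report$class_summary <- cs$by_class
    report$overlap <- cs$overlap
    NULL
  }, probeval_degenerate_labels_error = function(e) conditionMessage(e),
     probeval_degenerate_data_error = function(e) conditionMessage(e))
  if (!is.null(degenerate)) {
    report$reason <- degenerate
  } else {
    report$top_x_curve <- tibble(
      x = x_grid,
      fraction_unpaired = vapply(
        x_grid, function(x) top_fraction_unpaired(reactivity, structure, x),
        numeric(1))
    )
    report$fraction_rate_ge_0.1 <- fraction_at_least(reactivity, 0.1)
  }
  class(report) <- "run_report"
  if (!is.null(out)) write_run_report(report, out)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> rna=%s mode=%s probe=%s background=%s\n",
              x$rna_id, x$mode, x$probe, x$background_used))
  if (is.null(x$auc)) {
    cat(sprintf("  metrics unavailable: %s\n", x$reason))
  } else {
    cat(sprintf("  AUC = %.4f over %d valid bases; fraction rate >= 0.1: %.4f\n",
                x$auc, x$n_valid, x$fraction_rate_ge_0.1))
  }
  invisible(x)
}

#' Write a run report as JSON
#'
#' @param report A `run_report` from [pipeline_evaluate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  invisible(path)
}

#' Solvent accessibility report for one chain
#'
#' Computes per-residue absolute and relative accessibility and, when a
#' reactivity profile is supplied, Pearson correlations between
#' reactivity and relative accessibility for the `all`, `top10` and
#' `bottom90` subsets (plus `paired`/`unpaired` when a secondary
#' structure is supplied). Subsets that are too small or degenerate get
#' `NA` correlation with a reason instead of an error.
#'
#' @param pdb_path Path to a PDB file.
#' @param chain Chain identifier.
#' @param offset Residue-numbering offset: profile position = residue
#'   index + offset (default 0).
#' @param probe_radius Probe radius in Angstrom (default 3).
#' @param n_sphere_points Test points per atom (default 960).
#' @param reactivity Optional `reactivity_profile` or path.
#' @param structure Optional `secondary_structure` or path.
#' @return A list with `accessibility` (tibble) and `correlations`
#'   (tibble with columns `subset`, `r`, `n`, `reason`; `NULL` when no
#'   reactivity was supplied).
#' @export
pipeline_sasa <- function(pdb_path, chain, offset = 0L, probe_radius = 3,
                          n_sphere_points = 960L,
                          reactivity = NULL, structure = NULL) {
  atoms <- read_pdb_atoms(pdb_path, chain)
  access <- residue_accessibility(atoms, probe_radius, n_sphere_points)
  correlations <- NULL
  if (!is.null(reactivity)) {
    if (is.character(reactivity)) reactivity <- read_reactivity_tsv(reactivity)
    if (is.character(structure)) structure <- read_dotbracket(structure)
    subsets <- c("all", "top10", "bottom90")
    if (!is.null(structure)) subsets <- c(subsets, "paired", "unpaired")
    correlations <- purrr::map_dfr(subsets, function(s) {
      tryCatch(
        reactivity_accessibility_correlation(reactivity, access, s,
                                             structure, offset) |>
          mutate(reason = NA_character_),
        probeval_degenerate_data_error = function(e) {
          tibble(subset = s, r = NA_real_, n = NA_integer_,
                 reason = conditionMessage(e))
        })
    })
  }
  list(accessibility = access, correlations = correlations)
}
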