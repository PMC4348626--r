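# End-to-end orchestration: simulate (or load) -> index -> count ->
# normalise -> classify -> venn -> heterosis -> correlate.

#' Run the full hybrid-vs-parent expression pipeline
#'
#' Executes every stage in order on either a simulated experiment (pass a
#' [sim_config()]) or user data (pass `paths`, a list with `reference`,
#' `tags`, `design`, `traits` file paths). Exactly one of the two must be
#' supplied. When `out_dir` is given, every stage's table is written as
#' plain text together with a JSON run manifest (package version, seed,
#' config hash), and rerunning with an identical config reproduces
#' identical outputs.
#'
#' @param config A [sim_config()], or `NULL` when `paths` is given.
#' @param paths Named list of input files for real data, or `NULL`.
#' @param out_dir Optional output directory.
#' @param floor TPM floor for fold differences.
#' @param threshold Classification cut-off (log2 units).
#' @param consistency_rule See [consistent_patterns()].
#' @param heterosis_mode Correlate `h_mid` (default) or `h_best`.
#' @param tag_length Tag bases after CATG (used for real data; simulated
#'   runs take it from the config).
#' @return A `heterotag_run` list: all stage outputs plus the manifest.
#' @export
run_heterosis_pipeline <- function(config = NULL, paths = NULL, out_dir = NULL,
                                   floor = 1, threshold = 2,
                                   consistency_rule = "both_sexes",
                                   heterosis_mode = c("mid", "best"),
                                   tag_length = 17) {
  heterosis_mode <- match.arg(heterosis_mode)
  if (!is.null(config) && !is.null(paths)) {
    abort("supply either a simulation config or real-data paths, not both")
  }
  if (is.null(config) && is.null(paths)) {
    abort("supply a simulation config or real-data paths")
  }

  if (!is.null(config)) {
    stopifnot(inherits(config, "heterotag_sim_config"))
    sim <- simulate_dge_experiment(config)
    transcripts <- sim$transcripts
    libraries <- sim$libraries
    design <- sim$design
    traits <- sim$traits
    tag_length <- config$tag_length
    seed <- config$seed
  } else {
    for (need in c("reference", "tags", "design", "traits")) {
      if (is.null(paths[[need]])) abort(sprintf("paths$%s is required", need))
    }
    sim <- NULL
    transcripts <- read_reference_fasta(paths$reference)
    libraries <- read_tags(paths$tags)
    design <- read_design(paths$design)
    traits <- read_traits(paths$traits)
    seed <- NA_integer_
  }

  index <- build_tag_index(transcripts, tag_length = tag_length)
  counts <- map_tags(libraries, index)
  report <- mapping_report(counts)
  expr <- tpm_normalize(counts)
  partition <- venn_partition(counts, libraries = design$library_id)
  folds <- fold_differences(expr, design, floor = floor)
  calls <- classify_patterns(folds, threshold = threshold)
  summary <- pattern_summary(calls)
  consistent <- consistent_patterns(calls, rule = consistency_rule)
  heterosis <- heterosis_table(traits)
  correlations <- correlate_patterns_traits(
    summary, heterosis,
    h_col = paste0("h_", heterosis_mode)
  )

  manifest <- list(
    package = "heterotag",
    version = as.character(utils::packageVersion("heterotag")),
    seed = seed,
    n_libraries = length(unique(design$library_id)),
    input = if (is.null(paths)) "simulation" else "files",
    config_hash = hash(if (is.null(config)) paths else unclass(config)),
    tag_length = as.integer(tag_length),
    floor = floor, threshold = threshold,
    consistency_rule = consistency_rule, heterosis_mode = heterosis_mode
  )

  run <- structure(
    list(
      transcripts = transcripts, libraries = libraries, design = design,
      index = index, counts = counts, mapping_report = report, expr = expr,
      partition = partition, folds = folds, calls = calls,
      summary = summary, consistent = consistent, traits = traits,
      heterosis = heterosis, correlations = correlations,
      truth = if (!is.null(sim)) sim$truth else NULL,
      planted_h = if (!is.null(sim)) sim$planted_h else NULL,
      manifest = manifest
    ),
    class = "heterotag_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write every stage output of a pipeline run
#'
#' @param run A `heterotag_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "heterotag_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_reference_fasta(run$transcripts, p("reference.fasta"))
  write_tags(run$libraries, p("tags.tsv"))
  write_design(run$design, p("design.csv"))
  write_traits(run$traits, p("traits.csv"))
  write_counts(run$counts, p("gene_counts.tsv"))
  readr::write_tsv(run$mapping_report, p("mapping_report.tsv"))
  readr::write_tsv(as_tibble(run$expr), p("tpm.tsv"))
  readr::write_tsv(venn_region_sizes(run$partition), p("venn_regions.tsv"))
  readr::write_tsv(as_tibble(run$calls), p("pattern_calls.tsv"))
  readr::write_tsv(as_tibble(run$summary), p("pattern_summary.tsv"))
  readr::write_tsv(as_tibble(run$consistent), p("consistent_genes.tsv"))
  readr::write_tsv(as_tibble(run$heterosis), p("heterosis.tsv"))
  readr::write_tsv(tidy(run$correlations), p("correlations.tsv"))
  if (!is.null(run$truth)) readr::write_tsv(run$truth, p("ground_truth.tsv"))
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.heterotag_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "heterotag pipeline run (%s input, %d libraries, seed %s)\n",
    m$input, m$n_libraries, m$seed
  ))
  cat(sprintf(
    "  %d genes indexed (%d with CATG site), %d pattern calls, %d consistent-trend genes\n",
    attr(x$index, "n_genes_total"), attr(x$index, "n_genes_with_site"),
    nrow(x$calls), nrow(x$consistent)
  ))
  invisible(x)
}

#' Compare pattern calls with the planted ground truth
#'
#' For a simulated run, joins the classifier's calls to the planted labels
#' and reports per-group and overall recovery of the planted non-ND
#' labels.
#'
#' @param run A simulated `heterotag_run` (or a calls table plus `truth`).
#' @param truth Optional ground-truth tibble (defaults to the run's).
#' @return A list: `by_gene` (joined tibble), `recovery` (per group), and
#'   `overall_non_nd` (fraction of planted non-ND labels recovered).
#' @export
recovery_vs_truth <- function(run, truth = NULL) {
  calls <- if (inherits(run, "heterotag_run")) run$calls else run
  truth <- truth %||% (if (inherits(run, "heterotag_run")) run$truth else NULL)
  if (is.null(truth)) abort("no ground truth available; run a simulated pipeline")
  joined <- truth %>%
    select("gene_id", "group", planted = "label") %>%
    left_join(
      calls %>% as_tibble() %>% select("gene_id", "group", called = "label"),
      by = c("gene_id", "group")
    )
  by_group <- joined %>%
    filter(.data$planted != "ND") %>%
    group_by(.data$group) %>%
    summarise(
      n = n(),
      recovered = sum(!is.na(.data$called) & .data$called == .data$planted),
      recovery = .data$recovered / .data$n,
      .groups = "drop"
    )
  non_nd <- joined %>% filter(.data$planted != "ND")
  list(
    by_gene = joined,
    recovery = by_group,
    overall_non_nd = sum(!is.na(non_nd$called) & non_nd$called == non_nd$planted) / nrow(non_nd)
  )
}
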