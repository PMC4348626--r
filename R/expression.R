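# TPM normalisation and presence/absence (Venn) analysis across libraries.

#' TPM-normalise a gene count table
#'
#' Standardised expression level: clean tags of the gene divided by the
#' library's total clean tags, times one million (transcripts per million
#' clean tags). The divisor defaults to the library's total clean tags
#' (mapped + ambiguous + unmapped); set `divisor = "mapped"` to normalise
#' by mapped copies only.
#'
#' @param counts Tibble `library_id`, `gene_id`, `count`, typically from
#'   [map_tags()].
#' @param library_totals Optional tibble `library_id`, `total_clean_tags`;
#'   defaults to the mapping report attached to `counts`.
#' @param divisor `"total"` (default) or `"mapped"`.
#' @return An `expression_table` tibble: `library_id`, `gene_id`, `count`,
#'   `tpm`.
#' @export
tpm_normalize <- function(counts, library_totals = NULL, divisor = c("total", "mapped")) {
  divisor <- match.arg(divisor)
  assert_columns(counts, c("library_id", "gene_id", "count"), "counts")
  if (is.null(library_totals)) {
    rep <- attr(counts, "report")
    if (is.null(rep)) {
      abort("supply `library_totals` or counts produced by map_tags()")
    }
    library_totals <- rep %>%
      transmute(
        .data$library_id,
        denom = if (divisor == "total") .data$total_clean_tags else .data$mapped
      )
  } else {
    assert_columns(library_totals, c("library_id", "total_clean_tags"), "library_totals")
    library_totals <- library_totals %>%
      transmute(.data$library_id, denom = .data$total_clean_tags)
  }
  if (any(library_totals$denom <= 0)) {
    abort("zero total clean tags in at least one library")
  }
  out <- counts %>%
    inner_join(library_totals, by = "library_id") %>%
    mutate(tpm = .data$count / .data$denom * 1e6) %>%
    select(-"denom")
  if (nrow(out) < nrow(counts)) {
    abort("some libraries in `counts` have no entry in `library_totals`")
  }
  structure(out, class = c("expression_table", class(tibble())))
}

#' Partition genes by the set of libraries they are detected in
#'
#' Assigns each gene to the exact subset of libraries where it passes the
#' detection rule (default: at least one unambiguously mapped tag), the
#' generalised Venn-diagram partition. Regions are disjoint and their
#' union is the set of all detected genes.
#'
#' @param counts Tibble `library_id`, `gene_id`, `count` (or an
#'   `expression_table` with a `tpm` column when using a TPM rule).
#' @param libraries Optional character vector restricting/ordering the
#'   libraries considered.
#' @param min_count Detection threshold on unambiguous tag counts.
#' @param min_tpm Optional detection threshold on TPM instead; requires a
#'   `tpm` column.
#' @return A `presence_partition` tibble: `gene_id`, `subset` (a
#'   `+`-separated library key), `n_libraries`.
#' @export
venn_partition <- function(counts, libraries = NULL, min_count = 1, min_tpm = NULL) {
  assert_columns(counts, c("library_id", "gene_id"), "counts")
  libs <- libraries %||% sort(unique(counts$library_id))
  unknown <- setdiff(libs, unique(counts$library_id))
  if (length(unknown) > 0) {
    abort(sprintf("unknown library id(s): %s", paste(unknown, collapse = ", ")))
  }
  if (length(libs) < 2) abort("venn partition needs at least 2 libraries")
  dat <- counts %>% filter(.data$library_id %in% libs)
  detected <- if (!is.null(min_tpm)) {
    assert_columns(dat, "tpm", "counts")
    dat %>% filter(.data$tpm >= min_tpm)
  } else {
    assert_columns(dat, "count", "counts")
    dat %>% filter(.data$count >= min_count)
  }
  out <- detected %>%
    distinct(.data$gene_id, .data$library_id) %>%
    mutate(library_id = factor(.data$library_id, levels = libs)) %>%
    arrange(.data$gene_id, .data$library_id) %>%
    group_by(.data$gene_id) %>%
    summarise(
      subset = paste(.data$library_id, collapse = "+"),
      n_libraries = n(),
      .groups = "drop"
    )
  structure(out, libraries = libs, class = c("presence_partition", class(tibble())))
}

#' Region sizes of a presence partition
#'
#' @param partition A [venn_partition()] result.
#' @return Tibble `subset`, `n_libraries`, `n_genes`, sorted by size.
#' @export
venn_region_sizes <- function(partition) {
  partition %>%
    as_tibble() %>%
    count(.data$subset, .data$n_libraries, name = "n_genes") %>%
    arrange(dplyr::desc(.data$n_genes))
}

#' Genes detected in every library of a group
#'
#' @param partition A [venn_partition()] result.
#' @param group Character vector of library ids; the result is the
#'   intersection of their detected gene sets (sorted).
#' @return Character vector of gene ids.
#' @export
shared_genes <- function(partition, group) {
  if (length(group) == 0) abort("`group` must name at least one library")
  libs <- attr(partition, "libraries")
  unknown <- setdiff(group, libs)
  if (length(unknown) > 0) {
    abort(sprintf("unknown library id(s): %s", paste(unknown, collapse = ", ")))
  }
  hit <- map(partition$subset, function(s) strsplit(s, "+", fixed = TRUE)[[1]])
  keep <- vapply(hit, function(s) all(group %in% s), logical(1))
  sort(partition$gene_id[keep])
}
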