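# Plain-text readers/writers: FASTA references, tag TSVs, design and trait
# CSVs. Every writer's output is readable by its paired reader.

#' Write / read reference transcripts as FASTA
#'
#' @param transcripts Tibble `gene_id`, `sequence`.
#' @param path FASTA file path.
#' @return `write_reference_fasta()` returns `path` invisibly;
#'   `read_reference_fasta()` a tibble `gene_id`, `sequence`.
#' @export
write_reference_fasta <- function(transcripts, path) {
  assert_columns(transcripts, c("gene_id", "sequence"), "transcripts")
  x <- Biostrings::DNAStringSet(setNames(transcripts$sequence, transcripts$gene_id))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(gene_id = names(x), sequence = unname(as.character(x)))
}

#' Write / read per-library clean-tag tables (TSV)
#'
#' Columns: `library_id`, `tag`, `count`.
#'
#' @param tags Tag tibble.
#' @param path TSV path.
#' @export
write_tags <- function(tags, path) {
  assert_columns(tags, c("library_id", "tag", "count"), "tags")
  readr::write_tsv(tags %>% select("library_id", "tag", "count"), path)
  invisible(path)
}

#' @rdname write_tags
#' @export
read_tags <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    library_id = readr::col_character(),
    tag = readr::col_character(),
    count = readr::col_integer()
  ))
  if (any(out$count < 1)) abort("tag copy counts must be >= 1")
  out
}

#' Write / read the library design (CSV)
#'
#' Columns: `library_id`, `generation` (`parent`/`F1`), `parent_role`
#' (`female_line`/`male_line`, empty for F1), `combination`
#' (`cross`/`reciprocal`), `sex` (`female`/`male`). Free-text codes such
#' as `"M"` or `"recip"` are normalised on read.
#'
#' @param design Design tibble.
#' @param path CSV path.
#' @export
write_design <- function(design, path) {
  assert_columns(design, c("library_id", "generation", "parent_role", "combination", "sex"), "design")
  readr::write_csv(design, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  assert_columns(out, c("library_id", "generation", "parent_role", "combination", "sex"), "design file")
  if (anyDuplicated(out$library_id)) {
    abort(sprintf(
      "duplicate library_id(s): %s",
      paste(unique(out$library_id[duplicated(out$library_id)]), collapse = ", ")
    ))
  }
  out %>%
    mutate(
      generation = normalise_generation(.data$generation),
      combination = normalise_combination(.data$combination),
      sex = normalise_sex(.data$sex),
      parent_role = ifelse(
        is.na(.data$parent_role) | .data$parent_role == "", NA_character_, .data$parent_role
      )
    )
}

#' Write / read trait tables (CSV)
#'
#' Long layout: `trait`, `sex`, `line`, `generation`, `combination`,
#' `value`.
#'
#' @param traits Trait tibble.
#' @param path CSV path.
#' @export
write_traits <- function(traits, path) {
  assert_columns(traits, c("trait", "sex", "line", "generation", "combination", "value"), "traits")
  readr::write_csv(traits, path)
  invisible(path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    trait = readr::col_character(), sex = readr::col_character(),
    line = readr::col_character(), generation = readr::col_character(),
    combination = readr::col_character(), value = readr::col_double()
  ))
  if (any(out$value < 0)) abort("trait values must be non-negative")
  pct <- grepl("pct|percentage", out$trait)
  if (any(out$value[pct] > 100)) abort("percentage traits must lie in [0, 100]")
  out %>%
    mutate(
      sex = normalise_sex(.data$sex),
      generation = normalise_generation(.data$generation),
      combination = ifelse(
        is.na(.data$combination), NA_character_,
        normalise_combination(.data$combination)
      )
    )
}

#' Write a gene-by-library count matrix (TSV)
#'
#' @param counts Long count tibble (`library_id`, `gene_id`, `count`).
#' @param path TSV path.
#' @export
write_counts <- function(counts, path) {
  assert_columns(counts, c("library_id", "gene_id", "count"), "counts")
  wide <- counts %>%
    select("gene_id", "library_id", "count") %>%
    pivot_wider(names_from = "library_id", values_from = "count", values_fill = 0L)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_integer()
  ))
  wide %>% pivot_longer(-"gene_id", names_to = "library_id", values_to = "count")
}
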