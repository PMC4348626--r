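# CATG-anchored tag reference, exact-match tag-to-gene counting, and the
# sequencing-quality summaries (saturation, copy-number distribution,
# tag-position distribution).

#' Build the CATG-anchored tag reference
#'
#' Scans each sense-strand transcript for CATG sites. Every site with at
#' least `tag_length` bases 3' of the anchor contributes one tag (the CATG
#' plus the following `tag_length` bases). Site ranks count from the 3'
#' end, so the canonical DGE tag of a gene is its rank-1 entry.
#'
#' @param transcripts Tibble with columns `gene_id`, `sequence`.
#' @param tag_length Tag bases after the CATG anchor (default 17, the
#'   standard 21-bp NlaIII DGE tag).
#' @return A `tag_index` tibble with columns `tag`, `gene_id`,
#'   `site_rank`, plus attributes `tag_length`, `n_genes_total`,
#'   `n_genes_with_site`.
#' @export
build_tag_index <- function(transcripts, tag_length = 17) {
  assert_columns(transcripts, c("gene_id", "sequence"), "transcripts")
  if (nrow(transcripts) == 0) abort("empty transcript set")
  assert_scalar_number(tag_length, "tag_length", lower = 1)
  seqs <- toupper(transcripts$sequence)
  odd <- grepl("[^ACGT]", seqs)
  if (any(odd)) {
    warn(sprintf(
      "%d transcript(s) contain non-ACGT characters; tags spanning them are skipped",
      sum(odd)
    ))
  }
  entries <- map2(transcripts$gene_id, seqs, function(g, s) {
    hits <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(NULL)
    ok <- (nchar(s) - (hits + 3L)) >= tag_length
    hits <- hits[ok]
    if (length(hits) == 0) return(NULL)
    tags <- substring(s, hits, hits + 3L + tag_length)
    keep <- !grepl("[^ACGT]", tags)
    tags <- tags[keep]
    if (length(tags) == 0) return(NULL)
    # 3'-most qualifying site gets rank 1
    tibble(tag = rev(tags), gene_id = g, site_rank = seq_along(tags))
  })
  idx <- list_rbind(entries)
  if (is.null(idx) || nrow(idx) == 0) {
    idx <- tibble(tag = character(), gene_id = character(), site_rank = integer())
  }
  structure(
    idx,
    tag_length = as.integer(tag_length),
    n_genes_total = nrow(transcripts),
    n_genes_with_site = length(unique(idx$gene_id)),
    class = c("tag_index", class(idx))
  )
}

#' Map a clean-tag library against a tag index
#'
#' Exact-match lookup: a tag matching exactly one gene adds its copy count
#' to that gene; tags matching more than one gene are ambiguous and
#' excluded from counting; unmatched tags are unmapped.
#'
#' @param library Tibble of clean tags: columns `tag`, `count` (and
#'   optionally `library_id`, mapped per library).
#' @param index A [build_tag_index()] result.
#' @return A tibble of per-gene unambiguous counts (`library_id`,
#'   `gene_id`, `count`) covering every gene in the index, with attribute
#'   `report`: per-library copies mapped / ambiguous / unmapped, the total,
#'   and `first_site_fraction` (fraction of mapped copies from rank-1
#'   sites).
#' @export
map_tags <- function(library, index) {
  stopifnot(inherits(index, "tag_index"))
  assert_columns(library, c("tag", "count"), "library")
  if (!"library_id" %in% names(library)) {
    library <- library %>% mutate(library_id = "library_1")
  }
  tlen <- attr(index, "tag_length") + 4L
  bad <- nchar(library$tag) != tlen
  if (any(bad)) {
    abort(sprintf(
      "tag-length mismatch: index expects %d-base tags, library has %d tag(s) of other lengths",
      tlen, sum(bad)
    ))
  }
  tag_info <- index %>%
    as_tibble() %>%
    group_by(.data$tag) %>%
    summarise(
      n_genes = length(unique(.data$gene_id)),
      gene_id = .data$gene_id[1],
      site_rank = .data$site_rank[1],
      .groups = "drop"
    )
  joined <- library %>%
    left_join(tag_info, by = "tag") %>%
    mutate(status = dplyr::case_when(
      is.na(.data$n_genes) ~ "unmapped",
      .data$n_genes > 1 ~ "ambiguous",
      TRUE ~ "mapped"
    ))
  report <- joined %>%
    group_by(.data$library_id) %>%
    summarise(
      total_clean_tags = sum(.data$count),
      mapped = sum(.data$count[.data$status == "mapped"]),
      ambiguous = sum(.data$count[.data$status == "ambiguous"]),
      unmapped = sum(.data$count[.data$status == "unmapped"]),
      first_site_fraction = ifelse(
        mapped > 0,
        sum(.data$count[.data$status == "mapped" & .data$site_rank == 1], na.rm = TRUE) / mapped,
        NA_real_
      ),
      .groups = "drop"
    )
  counts <- joined %>%
    filter(.data$status == "mapped") %>%
    group_by(.data$library_id, .data$gene_id) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    complete(
      library_id = unique(library$library_id),
      gene_id = unique(index$gene_id),
      fill = list(count = 0L)
    ) %>%
    mutate(count = as.integer(.data$count)) %>%
    arrange(.data$library_id, .data$gene_id)
  structure(counts, report = report, class = c("gene_counts", class(counts)))
}

#' Mapping report of a counted library
#'
#' @param counts A [map_tags()] result.
#' @return The per-library mapping report tibble.
#' @export
mapping_report <- function(counts) {
  rep <- attr(counts, "report")
  if (is.null(rep)) abort("no mapping report attached; was this produced by map_tags()?")
  rep
}

#' Sequencing saturation curve
#'
#' Subsamples the library's tag copies without replacement at cumulative
#' depths and reports the number of distinct genes with at least one
#' unambiguously mapped tag, the classic saturation diagnostic.
#'
#' @param library Tibble of clean tags (`tag`, `count`) for one library.
#' @param index A [build_tag_index()].
#' @param step Copy increment between curve points.
#' @param seed Seed for the subsampling order.
#' @return A `saturation_curve` tibble: `sampled_copies`,
#'   `genes_detected`.
#' @export
saturation_curve <- function(library, index, step = 5000, seed = 1) {
  stopifnot(inherits(index, "tag_index"))
  assert_columns(library, c("tag", "count"), "library")
  assert_scalar_number(step, "step", lower = 1)
  total <- sum(library$count)
  if (step > total) {
    warn("step exceeds total tag copies; returning a single-point curve")
  }
  tag_info <- index %>%
    as_tibble() %>%
    group_by(.data$tag) %>%
    summarise(n_genes = length(unique(.data$gene_id)), gene_id = .data$gene_id[1], .groups = "drop")
  lib <- library %>% left_join(tag_info, by = "tag")
  gene_of <- ifelse(!is.na(lib$n_genes) & lib$n_genes == 1, lib$gene_id, NA_character_)
  copies <- rep.int(gene_of, lib$count)
  perm <- with_seed(seed, sample.int(length(copies)))
  copies <- copies[perm]
  depths <- unique(c(seq(min(step, total), total, by = step), total))
  first_seen <- tapply(seq_along(copies), copies, min)
  genes_at <- vapply(depths, function(d) sum(first_seen <= d), integer(1))
  structure(
    tibble(sampled_copies = as.integer(depths), genes_detected = as.integer(genes_at)),
    class = c("saturation_curve", class(tibble()))
  )
}

#' Copy-number distribution of distinct tags
#'
#' Bins distinct clean tags by copy number; the counts partition the
#' distinct tag types.
#'
#' @param library Tibble of clean tags (`tag`, `count`).
#' @param breaks Left-closed bin edges (the last bin is open-ended).
#' @return A `copy_number_dist` tibble: `bin`, `n_tags`.
#' @export
copy_number_distribution <- function(library, breaks = c(1, 5, 10, 50, 100)) {
  assert_columns(library, c("tag", "count"), "library")
  if (nrow(library) == 0) abort("empty library")
  edges <- c(breaks, Inf)
  labels <- paste0(
    "[", breaks, ",",
    c(breaks[-1], "Inf"), ")"
  )
  bin <- cut(library$count, breaks = edges, right = FALSE, labels = labels)
  out <- tibble(bin = factor(labels, levels = labels)) %>%
    left_join(
      tibble(bin = bin) %>% count(.data$bin, name = "n_tags"),
      by = "bin"
    ) %>%
    mutate(n_tags = ifelse(is.na(.data$n_tags), 0L, .data$n_tags))
  structure(out, class = c("copy_number_dist", class(tibble())))
}
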