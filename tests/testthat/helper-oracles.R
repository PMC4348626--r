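# Independent oracles and small fixture builders used across the suite.

# Brute-force CATG-site enumeration: scan every transcript left to right,
# record every site with enough downstream bases, rank from the 3' end.
# Written independently of build_tag_index (regmatches-based).
oracle_tag_scan <- function(transcripts, tag_length) {
  out <- list()
  for (i in seq_len(nrow(transcripts))) {
    s <- toupper(transcripts$sequence[i])
    n <- nchar(s)
    pos <- c()
    p <- 1
    while (p <= n - 3) {
      if (substr(s, p, p + 3) == "CATG") pos <- c(pos, p)
      p <- p + 1
    }
    pos <- pos[(n - (pos + 3)) >= tag_length]
    if (length(pos) == 0) next
    tags <- vapply(pos, function(q) substr(s, q, q + 3 + tag_length), character(1))
    out[[length(out) + 1]] <- data.frame(
      tag = tags,
      gene_id = transcripts$gene_id[i],
      site_rank = rev(seq_along(tags)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Brute-force tag-to-gene counting: substring search of every distinct tag
# against every transcript; unique hits counted, multi-hits dropped.
oracle_count_tags <- function(library, transcripts) {
  genes <- transcripts$gene_id
  counts <- stats::setNames(rep(0L, length(genes)), genes)
  for (j in seq_len(nrow(library))) {
    hits <- genes[vapply(
      transcripts$sequence,
      function(s) grepl(library$tag[j], s, fixed = TRUE),
      logical(1)
    )]
    if (length(hits) == 1) counts[hits] <- counts[hits] + library$count[j]
  }
  counts
}

# Independent 9-label lookup: decision tree written without the grid table.
oracle_label <- function(fF, fM, t = 2) {
  up_f <- fF >= t; dn_f <- fF <= -t
  up_m <- fM >= t; dn_m <- fM <= -t
  if (up_f && up_m) return("OPS")
  if (dn_f && dn_m) return("UPS")
  if (up_f && dn_m) return("MAF")
  if (dn_f && up_m) return("FAM")
  if (up_f) return("OF")
  if (dn_f) return("UF")
  if (up_m) return("OM")
  if (dn_m) return("UM")
  "ND"
}

# Tiny deterministic transcript set with known CATG structure.
toy_transcripts <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    sequence = c(
      "AACATGTTTTTCATGGGGGG", # two qualifying sites at tag_length 5
      "AAAAAAAAAAAAAAAAAAAA", # no site
      "GGCATGCCCCCTTTTTTTTT"  # one site
    )
  )
}

small_config <- function(seed = 1, n_genes = 120, depth = 6000, ...) {
  sim_config(seed = seed, n_genes = n_genes, library_depth = depth, ...)
}
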