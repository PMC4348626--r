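test_that("tag index matches a hand-worked transcript", {
  tx <- toy_transcripts()
  idx <- build_tag_index(tx, tag_length = 5)
  ga <- idx[idx$gene_id == "gA", ]
  # 3'-most qualifying site first: CATG at position 12 then position 3
  expect_equal(ga$tag[ga$site_rank == 1], "CATGGGGGG")
  expect_equal(ga$tag[ga$site_rank == 2], "CATGTTTTT")
  expect_equal(nrow(idx[idx$gene_id == "gB", ]), 0)
  expect_equal(idx$tag[idx$gene_id == "gC"], "CATGCCCCC")
  expect_equal(attr(idx, "n_genes_total"), 3)
  expect_equal(attr(idx, "n_genes_with_site"), 2)
  expect_true(all(startsWith(idx$tag, "CATG")))
  expect_true(all(nchar(idx$tag) == 9))
})

test_that("sites too close to the 3' end do not qualify", {
  tx <- tibble::tibble(gene_id = "g1", sequence = "AACATGTT")
  idx <- build_tag_index(tx, tag_length = 5)
  expect_equal(nrow(idx), 0)
  expect_equal(attr(idx, "n_genes_with_site"), 0)
})

test_that("index agrees with brute-force site enumeration on random sets", {
  cfg <- sim_config(seed = 21, n_genes = 30, transcript_length_range = c(60, 400))
  tx <- simulate_reference(cfg)
  idx <- build_tag_index(tx, tag_length = cfg$tag_length)
  oracle <- oracle_tag_scan(tx, cfg$tag_length)
  got <- dplyr::arrange(tibble::as_tibble(idx), gene_id, site_rank)
  want <- dplyr::arrange(tibble::as_tibble(oracle), gene_id, site_rank)
  expect_equal(got$tag, want$tag)
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$site_rank, want$site_rank)
})

test_that("non-ACGT characters trigger a warning and are skipped", {
  tx <- tibble::tibble(gene_id = "g1", sequence = "AACATGNNTTTCATGAAAAAGG")
  expect_warning(idx <- build_tag_index(tx, tag_length = 5), "non-ACGT")
  expect_equal(idx$tag, "CATGAAAAA")
})

test_that("empty transcript sets are rejected", {
  expect_error(build_tag_index(tibble::tibble(gene_id = character(), sequence = character())),
               "empty")
})

test_that("mapping splits copies into mapped / ambiguous / unmapped exactly", {
  tx <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    sequence = c(
      "AAACATGAAAAACCCCC",  # unique tag CATGAAAAA
      "TTTCATGTTTTTGGGGG",  # unique tag CATGTTTTT
      "CCCCATGAAAAATTTTT"   # shares CATGAAAAA with g1 -> ambiguous
    )
  )
  idx <- build_tag_index(tx, tag_length = 5)
  lib <- tibble::tibble(
    library_id = "L1",
    tag = c("CATGAAAAA", "CATGTTTTT", "CATGGGGGG"),
    count = c(5L, 3L, 7L)
  )
  counts <- map_tags(lib, idx)
  rep <- mapping_report(counts)
  expect_equal(rep$mapped, 3)
  expect_equal(rep$ambiguous, 5)
  expect_equal(rep$unmapped, 7)
  expect_equal(rep$mapped + rep$ambiguous + rep$unmapped, rep$total_clean_tags)
  expect_equal(counts$count[counts$gene_id == "g2"], 3L)
  expect_equal(counts$count[counts$gene_id == "g1"], 0L)

  lone <- tibble::tibble(library_id = "L2", tag = "CATGCCCCC", count = 7L)
  c2 <- map_tags(lone, idx)
  expect_true(all(c2$count == 0L))
  expect_equal(mapping_report(c2)$unmapped, 7)

  expect_error(map_tags(tibble::tibble(tag = "CATGAA", count = 1L), idx), "tag-length mismatch")
})

test_that("synthetic library counts equal the brute-force substring oracle", {
  cfg <- sim_config(seed = 13, n_genes = 40, library_depth = 1500,
                    transcript_length_range = c(100, 500))
  tx <- simulate_reference(cfg)
  pl <- plant_expression(tx, cfg)
  libs <- simulate_libraries(tx, pl$means, cfg)
  idx <- build_tag_index(tx, cfg$tag_length)
  one <- libs[libs$library_id == "cross_F1m", ]
  got <- map_tags(one, idx)
  want <- oracle_count_tags(one, tx)
  expect_equal(got$count, unname(want[got$gene_id]))
})

test_that("saturation curves are monotone and end at the full-library count", {
  cfg <- small_config(seed = 8, n_genes = 60, depth = 3000)
  tx <- simulate_reference(cfg)
  pl <- plant_expression(tx, cfg)
  libs <- simulate_libraries(tx, pl$means, cfg)
  idx <- build_tag_index(tx, cfg$tag_length)
  one <- libs[libs$library_id == "cross_Pf", ]
  cur <- saturation_curve(one, idx, step = 250, seed = 3)
  expect_true(all(diff(cur$genes_detected) >= 0))
  expect_equal(max(cur$sampled_copies), sum(one$count))
  full <- map_tags(one, idx)
  expect_equal(
    cur$genes_detected[nrow(cur)],
    sum(tapply(full$count, full$gene_id, sum) > 0)
  )
  expect_warning(single <- saturation_curve(one, idx, step = 1e7), "single-point")
  expect_equal(nrow(single), 1)
})

test_that("a one-gene library saturates immediately", {
  tx <- tibble::tibble(gene_id = "g1", sequence = "AAACATGAAAAACCCCC")
  idx <- build_tag_index(tx, tag_length = 5)
  lib <- tibble::tibble(tag = "CATGAAAAA", count = 50L)
  cur <- saturation_curve(lib, idx, step = 10, seed = 1)
  expect_true(all(cur$genes_detected == 1))
})

test_that("copy-number bins partition the distinct tags", {
  lib <- tibble::tibble(tag = c("A", "B", "C"), count = c(1L, 3L, 200L))
  d <- copy_number_distribution(lib)
  expect_equal(d$n_tags[d$bin == "[1,5)"], 2L)
  expect_equal(d$n_tags[d$bin == "[100,Inf)"], 1L)
  expect_equal(sum(d$n_tags), nrow(lib))

  cfg <- small_config(seed = 2)
  tx <- simulate_reference(cfg)
  pl <- plant_expression(tx, cfg)
  libs <- simulate_libraries(tx, pl$means, cfg)
  one <- libs[libs$library_id == "reciprocal_Pf", ]
  d2 <- copy_number_distribution(one)
  expect_equal(sum(d2$n_tags), nrow(one))
  expect_error(copy_number_distribution(one[0, ]), "empty")
})

test_that("low-copy tag types dominate in a heavy-tailed shallow library", {
  # untruncated heavy-tailed abundance: the modal bin of distinct tag
  # types is the [1,5) copy class, as in shallow DGE libraries
  cfg <- sim_config(seed = 6, n_genes = 1000, library_depth = 50000,
                    baseline_floor = 0, baseline_sdlog = 1.5)
  tx <- simulate_reference(cfg)
  pl <- plant_expression(tx, cfg)
  libs <- simulate_libraries(tx, pl$means, cfg)
  one <- libs[libs$library_id == "cross_Pf", ]
  d <- copy_number_distribution(one)
  expect_equal(as.character(d$bin[which.max(d$n_tags)]), "[1,5)")
})
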