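test_that("reference generation respects the site-free fraction exactly", {
  cfg <- sim_config(seed = 1, n_genes = 10, frac_genes_without_site = 0.2)
  tx <- simulate_reference(cfg)
  expect_equal(nrow(tx), 10)
  has <- grepl("CATG", tx$sequence, fixed = TRUE)
  expect_equal(sum(!has), 2)
  expect_equal(tx$has_site, has)
  expect_true(all(grepl("^[ACGT]+$", tx$sequence)))
})

test_that("reference generation is byte-identical under the same seed", {
  cfg <- sim_config(seed = 11, n_genes = 40)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_reference_fasta(simulate_reference(cfg), f1)
  write_reference_fasta(simulate_reference(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every site-bearing transcript yields at least one extractable tag", {
  cfg <- sim_config(seed = 7, n_genes = 300)
  tx <- simulate_reference(cfg)
  idx <- build_tag_index(tx, tag_length = cfg$tag_length)
  scanned <- oracle_tag_scan(tx, cfg$tag_length)
  expect_setequal(unique(idx$gene_id), unique(scanned$gene_id))
  expect_setequal(unique(idx$gene_id), tx$gene_id[tx$has_site])
})

test_that("degenerate transcript length range is rejected", {
  expect_error(
    sim_config(transcript_length_range = c(10, 15), tag_length = 17),
    "degenerate"
  )
  expect_error(
    sim_config(class_proportions = c(ND = 0.6, OPS = 0.3)),
    "sum to 1"
  )
})

test_that("planted labels follow configured proportions (multinomial check)", {
  # all-W-class labels so the two sexes are sampled independently
  cfg <- sim_config(
    seed = 1, n_genes = 1000, frac_genes_without_site = 0,
    class_proportions = c(ND = 0.5, OPS = 0.1, UPS = 0.4)
  )
  pl <- plant_expression(simulate_reference(cfg), cfg)
  counts <- table(pl$truth$label[pl$truth$group == "cross_female"])
  probs <- c(ND = 0.5, OPS = 0.1, UPS = 0.4)
  for (lab in names(probs)) {
    ci <- qbinom(c(0.005 / 3, 1 - 0.005 / 3), 1000, probs[[lab]])
    expect_gte(counts[[lab]], ci[1])
    expect_lte(counts[[lab]], ci[2])
  }
})

test_that("noise-free planted folds satisfy each label's inequalities with margin", {
  cfg <- small_config(seed = 3, n_genes = 200)
  pl <- plant_expression(simulate_reference(cfg), cfg)
  tr <- pl$truth
  # construction contract: significant sides clear the threshold by the
  # margin, null sides stay inside it by the margin
  t <- cfg$threshold; m <- cfg$margin
  ops <- tr[tr$label == "OPS", ]
  expect_true(all(ops$lfc_female >= t + m & ops$lfc_male >= t + m))
  nd <- tr[tr$label == "ND", ]
  expect_true(all(abs(nd$lfc_female) < t - m & abs(nd$lfc_male) < t - m))
  # classifier applied to the noise-free mean ratios reproduces every label
  mw <- tidyr::pivot_wider(pl$means, names_from = "library_id", values_from = "mean_expr")
  for (comb in c("cross", "reciprocal")) {
    for (sx in c("female", "male")) {
      sub <- tr[tr$combination == comb & tr$sex == sx, ]
      i <- match(sub$gene_id, mw$gene_id)
      f1 <- mw[[paste0(comb, "_F1", substr(sx, 1, 1))]][i]
      pf <- mw[[paste0(comb, "_Pf")]][i]
      pm <- mw[[paste0(comb, "_Pm")]][i]
      relab <- classify_fold(log2(f1 / pf), log2(f1 / pm), threshold = t)
      expect_identical(relab, sub$label)
    }
  }
})

test_that("library sampling conserves depth and is seed-deterministic", {
  cfg <- small_config(seed = 5)
  tx <- simulate_reference(cfg)
  pl <- plant_expression(tx, cfg)
  lib1 <- simulate_libraries(tx, pl$means, cfg)
  lib2 <- simulate_libraries(tx, pl$means, cfg)
  expect_identical(lib1, lib2)
  totals <- tapply(lib1$count, lib1$library_id, sum)
  expect_true(all(totals == cfg$library_depth))
  expect_true(all(lib1$count >= 1))
})

test_that("zero planted expression yields zero tags and all-rank-1 in the no-bleed limit", {
  cfg <- sim_config(seed = 9, n_genes = 20, library_depth = 2000,
                    frac_genes_without_site = 0, fraction_non3prime = 0)
  tx <- simulate_reference(cfg)
  pl <- plant_expression(tx, cfg)
  means <- pl$means
  means$mean_expr[means$gene_id == "gene_0001" & means$library_id == "cross_Pf"] <- 0
  libs <- simulate_libraries(tx, means, cfg)
  idx <- build_tag_index(tx, cfg$tag_length)
  counts <- map_tags(libs, idx)
  g1 <- counts[counts$gene_id == "gene_0001" & counts$library_id == "cross_Pf", ]
  expect_equal(g1$count, 0L)
  rep <- mapping_report(counts)
  expect_true(all(rep$first_site_fraction == 1))
})

test_that("noiseless planted trait correlation is exact; degenerate input is flagged", {
  cfg <- sim_config(
    seed = 2,
    trait_plan = tibble::tibble(
      trait = c("pupal_weight", "fiber_length"),
      pattern = c("UM", "UM"),
      target_r = c(1.0, 0.0),
      noise_sigma = 0
    )
  )
  props <- tidyr::expand_grid(
    group = paste0("g", 1:6, c("_female", "_male")),
    pattern = "UM"
  )
  props$prop <- seq(0.05, 0.30, length.out = 6)
  tr <- simulate_traits(props, cfg)
  h1 <- tr$planted_h[tr$planted_h$trait == "pupal_weight", ]
  expect_equal(cor(h1$h_pct, props$prop), 1.0, tolerance = 1e-12)
  h0 <- tr$planted_h[tr$planted_h$trait == "fiber_length", ]
  expect_lt(abs(cor(h0$h_pct, props$prop)), 1e-10)

  flat <- props
  flat$prop <- 0.2
  tr2 <- simulate_traits(flat, cfg)
  expect_true(all(tr2$planted_h$degenerate))

  expect_error(
    sim_config(trait_plan = tibble::tibble(
      trait = "t", pattern = "UM", target_r = 1.5, noise_sigma = 0
    )),
    "\\[-1, 1\\]"
  )
})

test_that("population-mode trait noise gives near-target correlations at large n", {
  cfg <- sim_config(
    seed = 4, trait_empirical = FALSE,
    trait_plan = tibble::tibble(
      trait = "pupal_weight", pattern = "UM", target_r = 0, noise_sigma = 0.3
    )
  )
  withr::local_seed(42)
  props <- tibble::tibble(
    group = paste0("g", sprintf("%02d", 1:100), rep(c("_female", "_male"), 50)),
    pattern = "UM",
    prop = runif(100, 0.05, 0.3)
  )
  tr <- simulate_traits(props, cfg)
  expect_lt(abs(cor(tr$planted_h$h_pct, props$prop)), 0.2)
})
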