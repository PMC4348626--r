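test_that("the 9-label grid matches an independent oracle on all 49 cells", {
  grid <- tidyr::expand_grid(fF = -3:3, fM = -3:3)
  got <- classify_fold(grid$fF, grid$fM, threshold = 2)
  want <- mapply(oracle_label, grid$fF, grid$fM)
  expect_identical(got, unname(want))
  # exhaustive and mutually exclusive: one label per cell, all 9 occur
  expect_true(all(!is.na(got)))
  expect_setequal(unique(got), c("ND", "OPS", "UPS", "OF", "OM", "UF", "UM", "MAF", "FAM"))
})

test_that("spot checks and boundary semantics of the classifier", {
  expect_equal(classify_fold(3.1, 2.4), "OPS")
  expect_equal(classify_fold(0, 0), "ND")
  # inclusive thresholds: exactly +/-2 is significant
  expect_equal(classify_fold(2, 0), "OF")
  expect_equal(classify_fold(0, -2), "UM")
  expect_error(classify_fold(Inf, 0), "non-finite")
  # MAF/FAM orientation is configurable
  expect_equal(classify_fold(2.5, -2.5), "MAF")
  expect_equal(classify_fold(2.5, -2.5, orientation = "maf_up_male"), "FAM")
})

test_that("fold differences floor TPM values and exclude undetected genes", {
  design <- simulated_design()
  expr <- tidyr::expand_grid(
    gene_id = c("g1", "g2"), library_id = design$library_id
  )
  expr$tpm <- 0
  expr$tpm[expr$gene_id == "g1" & expr$library_id == "cross_Pf"] <- 64
  # g2 undetected in the cross trio but present in reciprocal
  expr$tpm[expr$gene_id == "g2" & expr$library_id == "reciprocal_F1f"] <- 400
  expr$tpm[expr$gene_id == "g2" & expr$library_id == "reciprocal_Pf"] <- 100
  expr$tpm[expr$gene_id == "g2" & expr$library_id == "reciprocal_Pm"] <- 400
  folds <- fold_differences(expr, design, floor = 1)
  g1 <- folds[folds$gene_id == "g1" & folds$group == "cross_female", ]
  expect_equal(g1$lfc_female, -6)         # log2(1/64) after flooring F1 = 0
  expect_equal(g1$lfc_male, 0)            # both floored
  expect_true(g1$floor_applied)
  expect_equal(nrow(folds[folds$gene_id == "g2" & folds$combination == "cross", ]), 0)
  g2 <- folds[folds$gene_id == "g2" & folds$group == "reciprocal_female", ]
  expect_equal(g2$lfc_female, 2)          # log2(400/100)
  expect_equal(g2$lfc_male, 0)            # equal TPM
})

test_that("a missing parental library is a design error", {
  design <- simulated_design()[-1, ]
  expr <- tibble::tibble(gene_id = "g", library_id = design$library_id, tpm = 1)
  expect_error(fold_differences(expr, design), "design error")
})

test_that("classification summaries count and normalise per group", {
  folds <- tibble::tibble(
    gene_id = rep(sprintf("g%d", 1:4), 2),
    group = rep(c("cross_female", "cross_male"), each = 4),
    combination = "cross",
    sex = rep(c("female", "male"), each = 4),
    lfc_female = c(0, 3, -3, 0, 0, 0, 0, 0),
    lfc_male = c(0, 3, 0, -2.5, 0, 0, 0, 0)
  )
  calls <- classify_patterns(folds)
  expect_equal(
    calls$label[calls$group == "cross_female"],
    c("ND", "OPS", "UF", "UM")
  )
  s <- pattern_summary(calls)
  expect_equal(sum(s$n[s$group == "cross_female"]), 4)
  expect_equal(sum(s$prop[s$group == "cross_female"]), 1, tolerance = 1e-9)
  expect_equal(s$n[s$group == "cross_male" & s$pattern == "ND"], 4)
  s2 <- pattern_summary(calls, denominator = "non_nd")
  expect_equal(sum(s2$prop[s2$group == "cross_female"]), 1, tolerance = 1e-9)
})

test_that("raising the threshold never moves a gene out of ND", {
  withr::local_seed(23)
  folds <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:200),
    group = "cross_female", combination = "cross", sex = "female",
    lfc_female = runif(200, -4, 4), lfc_male = runif(200, -4, 4)
  )
  lo <- classify_patterns(folds, threshold = 2)
  hi <- classify_patterns(folds, threshold = 3)
  expect_true(all(hi$label[lo$label == "ND"] == "ND"))
})

test_that("consistency rules match a brute-force evaluation", {
  withr::local_seed(41)
  labels <- c("ND", "OPS", "UPS", "UF", "UM", "OF", "OM", "FAM", "MAF")
  calls <- tidyr::expand_grid(
    gene_id = sprintf("g%02d", 1:30),
    group = c("cross_female", "cross_male", "reciprocal_female", "reciprocal_male")
  )
  calls$combination <- sub("_(female|male)$", "", calls$group)
  calls$sex <- sub("^.*_", "", calls$group)
  calls$label <- sample(labels, nrow(calls), replace = TRUE, prob = c(0.4, rep(0.075, 8)))
  wide <- tidyr::pivot_wider(calls[, c("gene_id", "group", "label")],
                             names_from = "group", values_from = "label")
  for (rule in c("both_sexes", "any_sex", "all_groups")) {
    got <- consistent_patterns(calls, rule = rule)
    ok_f <- wide$cross_female == wide$reciprocal_female & wide$cross_female != "ND"
    ok_m <- wide$cross_male == wide$reciprocal_male & wide$cross_male != "ND"
    want <- switch(rule,
      both_sexes = wide$gene_id[ok_f & ok_m],
      any_sex = wide$gene_id[ok_f | ok_m],
      all_groups = wide$gene_id[ok_f & ok_m & wide$cross_female == wide$cross_male]
    )
    expect_setequal(got$gene_id, want)
  }
  expect_error(
    consistent_patterns(calls[calls$group != "cross_male", ]),
    "missing group"
  )
})

test_that("consistency spot cases behave as defined", {
  mk <- function(f_cf, f_cm, f_rf, f_rm) {
    tibble::tibble(
      gene_id = "g1",
      group = c("cross_female", "cross_male", "reciprocal_female", "reciprocal_male"),
      combination = rep(c("cross", "reciprocal"), each = 2),
      sex = rep(c("female", "male"), 2),
      label = c(f_cf, f_cm, f_rf, f_rm)
    )
  }
  all_ops <- consistent_patterns(mk("OPS", "OPS", "OPS", "OPS"))
  expect_equal(all_ops$label, "OPS")
  flipped <- consistent_patterns(mk("OPS", "OPS", "UPS", "UPS"))
  expect_equal(nrow(flipped), 0)
  tally <- consistent_tally(all_ops)
  expect_equal(tally$total, 1)
})

test_that("parent swap maps labels by the mirror symmetry with no violations", {
  expect_equal(classify_fold(0, 2.5), "OM")   # swap of (2.5, 0) = OF
  expect_equal(classify_fold(-2.5, 2.5), "FAM") # swap of (2.5, -2.5) = MAF
  withr::local_seed(51)
  folds <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:300),
    group = "cross_female", combination = "cross", sex = "female",
    lfc_female = runif(300, -5, 5), lfc_male = runif(300, -5, 5)
  )
  calls <- classify_patterns(folds)
  violations <- check_parent_swap(calls)
  expect_equal(nrow(violations), 0)
  expect_equal(attr(violations, "n_checked"), 300)
})
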