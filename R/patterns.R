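# Nine-class gene-action pattern calling from F1-vs-parent log2 fold
# differences, pattern summaries, and cross/reciprocal-cross consistency.

#' F1-vs-parent log2 fold differences
#'
#' For every (combination, sex) group named by the design, computes the
#' binary logarithms of the TPM ratios of the F1 library to the female
#' parent (`lfc_female`) and to the male parent (`lfc_male`) library of
#' that combination. TPM values below `floor` are raised to `floor` before
#' taking ratios, keeping folds finite; genes undetected in all three
#' libraries of a comparison are excluded rather than floored.
#'
#' @param expr An [tpm_normalize()] expression table.
#' @param design Library design tibble (`library_id`, `generation`,
#'   `parent_role`, `combination`, `sex`), e.g. [simulated_design()].
#' @param floor TPM floor applied before ratios (default 1).
#' @return A `fold_table` tibble: `gene_id`, `group`, `combination`,
#'   `sex`, `tpm_f1`, `tpm_pf`, `tpm_pm`, `lfc_female`, `lfc_male`,
#'   `floor_applied`.
#' @export
fold_differences <- function(expr, design, floor = 1) {
  assert_columns(expr, c("library_id", "gene_id", "tpm"), "expr")
  assert_columns(design, c("library_id", "generation", "parent_role", "combination", "sex"), "design")
  assert_scalar_number(floor, "floor", lower = 1e-300)
  f1 <- design %>% filter(.data$generation == "F1")
  groups <- vector("list", nrow(f1))
  for (i in seq_len(nrow(f1))) {
    comb <- f1$combination[i]
    pf <- design$library_id[design$combination == comb &
                              design$generation == "parent" &
                              design$parent_role == "female_line"]
    pm <- design$library_id[design$combination == comb &
                              design$generation == "parent" &
                              design$parent_role == "male_line"]
    if (length(pf) != 1 || length(pm) != 1) {
      abort(sprintf("design error: combination %s lacks a unique female/male parental library", comb))
    }
    w <- expr %>%
      filter(.data$library_id %in% c(f1$library_id[i], pf, pm)) %>%
      select("gene_id", "library_id", "tpm") %>%
      pivot_wider(names_from = "library_id", values_from = "tpm", values_fill = 0)
    for (need in c(f1$library_id[i], pf, pm)) {
      if (!need %in% names(w)) w[[need]] <- 0
    }
    groups[[i]] <- w %>%
      transmute(
        gene_id = .data$gene_id,
        group = group_id(comb, f1$sex[i]),
        combination = comb,
        sex = f1$sex[i],
        tpm_f1 = .data[[f1$library_id[i]]],
        tpm_pf = .data[[pf]],
        tpm_pm = .data[[pm]]
      ) %>%
      filter(.data$tpm_f1 > 0 | .data$tpm_pf > 0 | .data$tpm_pm > 0) %>%
      mutate(
        floor_applied = .data$tpm_f1 < floor | .data$tpm_pf < floor | .data$tpm_pm < floor,
        lfc_female = log2(pmax(.data$tpm_f1, floor) / pmax(.data$tpm_pf, floor)),
        lfc_male = log2(pmax(.data$tpm_f1, floor) / pmax(.data$tpm_pm, floor))
      )
  }
  structure(
    list_rbind(groups) %>% arrange(.data$group, .data$gene_id),
    floor = floor,
    class = c("fold_table", class(tibble()))
  )
}

#' Classify a pair of fold differences into the nine-class scheme
#'
#' Each side is called UP if the fold is `>= threshold`, DOWN if
#' `<= -threshold`, N otherwise; the 3x3 grid of (female side, male side)
#' maps onto the nine labels: (N,N) ND; (UP,UP) OPS; (DOWN,DOWN) UPS;
#' (UP,N) OF; (N,UP) OM; (DOWN,N) UF; (N,DOWN) UM; (UP,DOWN) MAF;
#' (DOWN,UP) FAM. The mapping is total: every finite input pair gets
#' exactly one label.
#'
#' The additive labels' orientation follows `orientation = "maf_up_female"`
#' (default): MAF means the F1 sits above the female parent and below the
#' male parent; `"maf_up_male"` mirrors the two.
#'
#' @param lfc_female,lfc_male Finite log2 fold differences (vectorised).
#' @param threshold Significance cut-off in log2 units (default 2).
#' @param orientation Orientation of the MAF/FAM pair.
#' @return Character vector of labels.
#' @export
classify_fold <- function(lfc_female, lfc_male, threshold = 2,
                          orientation = c("maf_up_female", "maf_up_male")) {
  orientation <- match.arg(orientation)
  assert_scalar_number(threshold, "threshold", lower = 1e-9)
  if (any(!is.finite(lfc_female)) || any(!is.finite(lfc_male))) {
    abort("non-finite fold difference; floor TPM values before classification")
  }
  sF <- ifelse(lfc_female >= threshold, 1L, ifelse(lfc_female <= -threshold, -1L, 0L))
  sM <- ifelse(lfc_male >= threshold, 1L, ifelse(lfc_male <= -threshold, -1L, 0L))
  key <- paste(sF, sM)
  grid <- c(
    "0 0" = "ND", "1 1" = "OPS", "-1 -1" = "UPS",
    "1 0" = "OF", "0 1" = "OM", "-1 0" = "UF", "0 -1" = "UM",
    "1 -1" = "MAF", "-1 1" = "FAM"
  )
  if (orientation == "maf_up_male") {
    grid[["1 -1"]] <- "FAM"
    grid[["-1 1"]] <- "MAF"
  }
  unname(grid[key])
}

#' Call patterns for a whole fold table
#'
#' @param folds A [fold_differences()] table.
#' @param threshold Significance cut-off in log2 units.
#' @param orientation See [classify_fold()].
#' @return A `pattern_calls` tibble: the fold table plus a `label` column.
#' @export
classify_patterns <- function(folds, threshold = 2,
                              orientation = c("maf_up_female", "maf_up_male")) {
  orientation <- match.arg(orientation)
  assert_columns(folds, c("gene_id", "group", "lfc_female", "lfc_male"), "folds")
  if (nrow(folds) == 0) abort("empty fold table")
  out <- folds %>%
    mutate(label = classify_fold(.data$lfc_female, .data$lfc_male, threshold, orientation))
  structure(out, threshold = threshold, class = c("pattern_calls", class(tibble())))
}

#' Per-group pattern counts and proportions
#'
#' Proportions use all classified genes of the group (including ND) as
#' denominator by default; set `denominator = "non_nd"` to use the
#' differentially expressed genes only.
#'
#' @param calls A [classify_patterns()] table.
#' @param denominator `"all"` or `"non_nd"`.
#' @return A `pattern_summary` tibble: `group`, `pattern`, `n`, `prop`,
#'   `denominator`.
#' @export
pattern_summary <- function(calls, denominator = c("all", "non_nd")) {
  denominator <- match.arg(denominator)
  assert_columns(calls, c("gene_id", "group", "label"), "calls")
  out <- calls %>%
    count(.data$group, label = factor(.data$label, levels = PATTERN_LEVELS),
          name = "n", .drop = FALSE) %>%
    rename(pattern = "label") %>%
    mutate(pattern = as.character(.data$pattern)) %>%
    group_by(.data$group) %>%
    mutate(
      denominator = if (denominator == "all") sum(.data$n) else sum(.data$n[.data$pattern != "ND"]),
      prop = ifelse(.data$denominator > 0, .data$n / .data$denominator, NA_real_)
    ) %>%
    ungroup()
  if (denominator == "non_nd") out <- out %>% filter(.data$pattern != "ND")
  structure(out, class = c("pattern_summary", class(tibble())))
}

#' Consistent-trend genes between cross and reciprocal cross
#'
#' Default rule (`"both_sexes"`): a gene is consistent when it carries the
#' same non-ND label in the cross and reciprocal-cross group of the same
#' sex, in both sexes. `"any_sex"` requires that in at least one sex;
#' `"all_groups"` requires one shared non-ND label across all four groups
#' (equivalent to `"both_sexes"` plus agreement between sexes).
#'
#' @param calls A [classify_patterns()] table covering the four F1 groups.
#' @param rule Consistency rule.
#' @return A `consistent_genes` tibble (`gene_id`, `label`) with attribute
#'   `counts` (per-label tally); see [consistent_tally()].
#' @export
consistent_patterns <- function(calls, rule = c("both_sexes", "any_sex", "all_groups")) {
  rule <- match.arg(rule)
  assert_columns(calls, c("gene_id", "group", "combination", "sex", "label"), "calls")
  need <- GROUP_LEVELS
  missing_groups <- setdiff(need, unique(calls$group))
  if (length(missing_groups) > 0) {
    abort(sprintf("design error: missing group(s): %s", paste(missing_groups, collapse = ", ")))
  }
  wide <- calls %>%
    select("gene_id", "group", "label") %>%
    pivot_wider(names_from = "group", values_from = "label")
  cf <- wide$cross_female; cm <- wide$cross_male
  rf <- wide$reciprocal_female; rm_ <- wide$reciprocal_male
  sex_ok_f <- !is.na(cf) & !is.na(rf) & cf == rf & cf != "ND"
  sex_ok_m <- !is.na(cm) & !is.na(rm_) & cm == rm_ & cm != "ND"
  keep <- switch(rule,
    both_sexes = sex_ok_f & sex_ok_m,
    any_sex = sex_ok_f | sex_ok_m,
    all_groups = sex_ok_f & sex_ok_m & !is.na(cf) & !is.na(cm) & cf == cm
  )
  keep[is.na(keep)] <- FALSE
  lab <- dplyr::case_when(
    sex_ok_f & sex_ok_m & cf == cm ~ cf,
    sex_ok_f & sex_ok_m ~ paste(cf, cm, sep = "/"),
    sex_ok_f ~ cf,
    sex_ok_m ~ cm,
    TRUE ~ NA_character_
  )
  out <- tibble(gene_id = wide$gene_id[keep], label = lab[keep]) %>%
    arrange(.data$gene_id)
  counts <- out %>% count(.data$label, name = "n") %>% arrange(dplyr::desc(.data$n))
  structure(out, counts = counts, rule = rule,
            class = c("consistent_genes", class(tibble())))
}

#' Tally consistent-trend genes per pattern
#'
#' Returns the per-label counts together with their total; also accepts a
#' plain per-label count table (columns `label`, `n`), so published
#' per-pattern counts can be totalled with the same bookkeeping.
#'
#' @param x A [consistent_patterns()] result or a tibble with columns
#'   `label`, `n`.
#' @return A list with `counts` (tibble `label`, `n`) and `total`.
#' @export
consistent_tally <- function(x) {
  counts <- if (inherits(x, "consistent_genes")) {
    attr(x, "counts")
  } else {
    assert_columns(x, c("label", "n"), "x")
    as_tibble(x)
  }
  list(counts = counts, total = sum(counts$n))
}

#' Check the parent-swap symmetry of pattern calls
#'
#' Swapping the two parental columns must map OF<->OM, UF<->UM, FAM<->MAF
#' and fix ND, OPS, UPS. Recomputes labels with the parents swapped and
#' reports any violations (an empty table on a correct classifier).
#'
#' @param calls A [classify_patterns()] table with fold columns.
#' @param threshold Cut-off used for the original calls.
#' @return A tibble of violations (empty when the symmetry holds), with
#'   attribute `n_checked`.
#' @export
check_parent_swap <- function(calls, threshold = attr(calls, "threshold") %||% 2) {
  assert_columns(calls, c("gene_id", "group", "lfc_female", "lfc_male", "label"), "calls")
  swap_map <- c(
    ND = "ND", OPS = "OPS", UPS = "UPS",
    OF = "OM", OM = "OF", UF = "UM", UM = "UF",
    FAM = "MAF", MAF = "FAM"
  )
  swapped <- classify_fold(calls$lfc_male, calls$lfc_female, threshold)
  expect <- unname(swap_map[calls$label])
  bad <- swapped != expect
  out <- calls %>%
    as_tibble() %>%
    filter(bad) %>%
    select("gene_id", "group", "lfc_female", "lfc_male", "label") %>%
    mutate(swapped_label = swapped[bad], expected_label = expect[bad])
  structure(out, n_checked = nrow(calls))
}
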