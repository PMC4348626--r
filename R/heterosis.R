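# Trait heterosis rates and correlation of pattern proportions with trait
# heterosis.

#' Heterosis rate of a trait
#'
#' Mid-parent heterosis: `H% = (F1 - MP) / MP * 100` with
#' `MP = (P1 + P2) / 2`; better-parent heterosis uses `max(P1, P2)` as the
#' reference instead. Vectorised.
#'
#' @param f1 F1 trait value(s).
#' @param p1,p2 Parental trait values (must be positive).
#' @param mode `"mid"` (default) or `"best"`.
#' @return Heterosis rate(s) in percent.
#' @export
heterosis_rate <- function(f1, p1, p2, mode = c("mid", "best")) {
  mode <- match.arg(mode)
  if (any(!is.finite(p1)) || any(!is.finite(p2)) || any(p1 <= 0) || any(p2 <= 0)) {
    abort("parental trait values must be positive")
  }
  ref <- if (mode == "mid") (p1 + p2) / 2 else pmax(p1, p2)
  (f1 - ref) / ref * 100
}

#' Heterosis table from a trait table
#'
#' Computes per (trait, combination, sex) the mid-parent and better-parent
#' heterosis of the F1 against the two parental lines of that combination,
#' using the parental values measured in the same sex.
#'
#' @param traits Long trait tibble with columns `trait`, `sex`, `line`
#'   (`lineA`, `lineB` or `hybrid`), `generation` (`parent`/`F1`),
#'   `combination` (NA for parents), `value`.
#' @return A `heterosis_table` tibble: `trait`, `group`, `combination`,
#'   `sex`, `f1`, `p_female`, `p_male`, `h_mid`, `h_best`.
#' @export
heterosis_table <- function(traits) {
  assert_columns(traits, c("trait", "sex", "line", "generation", "combination", "value"), "traits")
  parents <- traits %>%
    filter(.data$generation == "parent") %>%
    select("trait", "sex", "line", "value") %>%
    pivot_wider(names_from = "line", values_from = "value")
  assert_columns(parents, c("lineA", "lineB"), "parental trait values")
  f1 <- traits %>%
    filter(.data$generation == "F1") %>%
    select("trait", "sex", "combination", f1 = "value")
  out <- f1 %>%
    left_join(parents, by = c("trait", "sex")) %>%
    mutate(
      # female parent of the cross is line A; of the reciprocal, line B
      p_female = ifelse(.data$combination == "cross", .data$lineA, .data$lineB),
      p_male = ifelse(.data$combination == "cross", .data$lineB, .data$lineA),
      group = group_id(.data$combination, .data$sex),
      h_mid = heterosis_rate(.data$f1, .data$p_female, .data$p_male, "mid"),
      h_best = heterosis_rate(.data$f1, .data$p_female, .data$p_male, "best")
    ) %>%
    select("trait", "group", "combination", "sex", "f1", "p_female", "p_male", "h_mid", "h_best")
  structure(out, class = c("heterosis_table", class(tibble())))
}

#' Correlate pattern proportions with trait heterosis
#'
#' Pearson correlation across groups between the proportion of each
#' expression pattern (independent variable) and the heterosis rate of
#' each trait (dependent variable); the p-value comes from the regression
#' F-test, `F = r^2 (n-2) / (1 - r^2)` on (1, n-2) df, identical to the
#' two-tailed t-test of the correlation.
#'
#' Cells whose pattern proportion is constant across groups have an
#' undefined correlation and are flagged (`degenerate = TRUE`) rather than
#' fabricated.
#'
#' @param summary A [pattern_summary()] (or any tibble `group`, `pattern`,
#'   `prop`).
#' @param heterosis A [heterosis_table()] (or any tibble `trait`, `group`,
#'   plus the column named by `h_col`).
#' @param h_col Which heterosis column to correlate (default `h_mid`).
#' @param patterns Patterns to include (default: all non-ND).
#' @return A `pattern_trait_cor` object; see [tidy()] and [glance()]
#'   methods, [correlation_report()].
#' @export
correlate_patterns_traits <- function(summary, heterosis, h_col = "h_mid",
                                      patterns = setdiff(PATTERN_LEVELS, "ND")) {
  assert_columns(summary, c("group", "pattern", "prop"), "summary")
  assert_columns(heterosis, c("trait", "group", h_col), "heterosis")
  groups <- intersect(unique(summary$group), unique(heterosis$group))
  n <- length(groups)
  if (n < 3) abort("at least 3 paired (group) observations are required")
  prop_w <- summary %>%
    filter(.data$pattern %in% patterns, .data$group %in% groups) %>%
    select("group", "pattern", "prop")
  h_w <- heterosis %>%
    filter(.data$group %in% groups) %>%
    select("trait", "group", h = all_of(h_col))
  cells <- expand_grid(trait = unique(h_w$trait), pattern = patterns)
  res <- pmap(cells, function(trait, pattern) {
    px <- prop_w[prop_w$pattern == pattern, ]
    hy <- h_w[h_w$trait == trait, ]
    x <- px$prop[match(groups, px$group)]
    y <- hy$h[match(groups, hy$group)]
    x[is.na(x)] <- 0
    if (any(is.na(y))) {
      return(tibble(trait, pattern, r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
    }
    if (sd(x) < 1e-12 || sd(y) < 1e-12) {
      return(tibble(trait, pattern, r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
    }
    r <- cor(x, y)
    p <- if (abs(r) >= 1) 0 else pf(r^2 * (n - 2) / (1 - r^2), 1, n - 2, lower.tail = FALSE)
    tibble(trait, pattern, r = r, p = p, n = n, degenerate = FALSE)
  }) %>% list_rbind()
  structure(
    list(estimates = res, groups = groups, h_col = h_col),
    class = "pattern_trait_cor"
  )
}

#' @export
print.pattern_trait_cor <- function(x, ...) {
  cat(sprintf(
    "Pattern-trait Pearson correlations over %d groups (%s)\n",
    length(x$groups), x$h_col
  ))
  print(correlation_report(x), n = Inf)
  invisible(x)
}

#' Tidy a pattern-trait correlation object
#'
#' @param x A [correlate_patterns_traits()] result.
#' @param ... Unused.
#' @return One row per (trait, pattern): `r`, `p`, `n`, `degenerate`,
#'   `signif` (`*` for p < 0.05, `**` for p < 0.01, two-tailed).
#' @method tidy pattern_trait_cor
#' @export
tidy.pattern_trait_cor <- function(x, ...) {
  x$estimates %>%
    mutate(signif = dplyr::case_when(
      is.na(.data$p) ~ "",
      .data$p < 0.01 ~ "**",
      .data$p < 0.05 ~ "*",
      TRUE ~ ""
    ))
}

#' Glance at a pattern-trait correlation object
#'
#' @param x A [correlate_patterns_traits()] result.
#' @param ... Unused.
#' @return A one-row tibble: number of traits, patterns, groups, tested
#'   cells, and cells significant at 0.05 / 0.01 (two-tailed, uncorrected).
#' @method glance pattern_trait_cor
#' @export
glance.pattern_trait_cor <- function(x, ...) {
  e <- x$estimates
  tibble(
    n_traits = length(unique(e$trait)),
    n_patterns = length(unique(e$pattern)),
    n_groups = length(x$groups),
    n_cells = nrow(e),
    n_degenerate = sum(e$degenerate),
    n_sig_05 = sum(e$p < 0.05, na.rm = TRUE),
    n_sig_01 = sum(e$p < 0.01, na.rm = TRUE)
  )
}

#' Correlation matrix in traits-by-patterns layout
#'
#' Renders the correlation object as a wide table, one row per trait, one
#' column per pattern, each cell `r` with its significance mark (`*`
#' p < 0.05, `**` p < 0.01, two-tailed); degenerate cells show `NA`.
#'
#' @param x A [correlate_patterns_traits()] result.
#' @param digits Digits for the correlation coefficients.
#' @return A tibble in the wide layout.
#' @export
correlation_report <- function(x, digits = 3) {
  tidy.pattern_trait_cor(x) %>%
    mutate(cell = ifelse(
      is.na(.data$r), "NA",
      paste0(formatC(.data$r, digits = digits, format = "f"), .data$signif)
    )) %>%
    select("trait", "pattern", "cell") %>%
    pivot_wider(names_from = "pattern", values_from = "cell")
}
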