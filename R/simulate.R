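# Synthetic DGE experiment generator: reference transcripts, eight seeded
# tag libraries with planted gene-action classes, and trait tables with
# planted pattern-heterosis correlations.

# sign grid of the nine gene-action labels: c(female-side, male-side) where
# +1 = F1 significantly above that parent, -1 below, 0 no difference
label_signs <- function() {
  list(
    ND = c(0, 0), OPS = c(1, 1), UPS = c(-1, -1),
    OF = c(1, 0), OM = c(0, 1), UF = c(-1, 0), UM = c(0, -1),
    MAF = c(1, -1), FAM = c(-1, 1)
  )
}

label_effect_class <- function() {
  c(
    ND = "null", OPS = "overdominance", UPS = "overdominance",
    OF = "dominance", OM = "dominance", UF = "dominance", UM = "dominance",
    MAF = "additive", FAM = "additive"
  )
}

#' Default planted pattern proportions per (combination, sex) group
#'
#' The four F1 groups get different pattern mixes (as real cross and
#' reciprocal-cross libraries do), which is what gives the pattern
#' proportions the across-group variance that trait correlations are
#' planted against.
#'
#' @return A tibble with columns `group`, `pattern`, `prop`; proportions
#'   sum to 1 within each group.
#' @export
default_class_proportions <- function() {
  props <- list(
    cross_female      = c(ND = 0.640, OPS = 0.030, UPS = 0.050, UF = 0.040, UM = 0.100, OF = 0.060, OM = 0.040, FAM = 0.015, MAF = 0.025),
    cross_male        = c(ND = 0.560, OPS = 0.090, UPS = 0.060, UF = 0.030, UM = 0.110, OF = 0.070, OM = 0.050, FAM = 0.010, MAF = 0.020),
    reciprocal_female = c(ND = 0.655, OPS = 0.055, UPS = 0.020, UF = 0.045, UM = 0.075, OF = 0.040, OM = 0.070, FAM = 0.020, MAF = 0.020),
    reciprocal_male   = c(ND = 0.610, OPS = 0.095, UPS = 0.030, UF = 0.050, UM = 0.045, OF = 0.030, OM = 0.090, FAM = 0.025, MAF = 0.025)
  )
  imap(props, function(p, g) {
    tibble(group = g, pattern = names(p), prop = unname(p))
  }) %>% list_rbind()
}

#' Default planted pattern-trait correlation plan
#'
#' One driving pattern per silkworm economic trait, with target Pearson
#' correlations of the magnitude seen in strong pattern-trait associations.
#'
#' @return A tibble with columns `trait`, `pattern`, `target_r`,
#'   `noise_sigma`.
#' @export
default_trait_plan <- function() {
  tibble(
    trait = c(
      "pupal_weight", "cocoon_shell_weight", "whole_cocoon_weight",
      "cocoon_shell_pct", "fiber_length", "fiber_diameter"
    ),
    pattern = c("UF", "FAM", "UF", "OF", "OM", "OM"),
    target_r = c(0.88, 0.95, 0.90, 0.95, -0.81, 0.95),
    noise_sigma = 0.3
  )
}

#' Default parental trait values
#'
#' Plausible per-sex trait values for the two parental lines (line A is the
#' female parent of the cross combination, line B of the reciprocal cross).
#' Units: weights in grams, cocoon shell percentage in percent, fibre
#' length in metres, fibre diameter in micrometres.
#'
#' @return A tibble with columns `trait`, `sex`, `lineA`, `lineB`.
#' @export
default_parent_traits <- function() {
  tibble(
    trait = rep(c(
      "pupal_weight", "cocoon_shell_weight", "whole_cocoon_weight",
      "cocoon_shell_pct", "fiber_length", "fiber_diameter"
    ), each = 2),
    sex = rep(c("female", "male"), times = 6),
    lineA = c(1.15, 0.90, 0.46, 0.41, 2.10, 1.75, 21.9, 23.4, 1150, 1180, 20.5, 19.5),
    lineB = c(1.05, 0.82, 0.42, 0.38, 1.95, 1.62, 21.5, 23.5, 1050, 1100, 19.8, 18.9)
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic DGE experiment. Defaults emulate
#' the study design the package targets: eight libraries (two sexed
#' parental libraries per combination plus F1 females and males, for a
#' cross and its reciprocal), a library depth of 50,000 clean-tag copies,
#' a fraction of reference genes lacking a CATG site, a strong bias of
#' tags to the 3'-most CATG site, and planted nine-class gene-action
#' memberships with at least `margin` log2 units of clearance beyond the
#' +/- `threshold` classification cut-offs.
#'
#' @param seed Root seed; every stochastic stage derives its own substream
#'   from it, so adding a library never perturbs earlier ones.
#' @param n_genes Number of reference transcripts.
#' @param transcript_length_range Length range (bp) of simulated transcripts.
#' @param frac_genes_without_site Fraction of genes with no CATG site.
#' @param tag_length Tag bases after the CATG anchor (total tag = 4 + this).
#' @param library_depth Total clean-tag copies sampled per library.
#' @param fraction_non3prime Fraction of tag copies drawn from CATG sites
#'   other than the 3'-most one (emulates the ~99% first-site statistic).
#' @param baseline_meanlog,baseline_sdlog Log-normal (natural-log scale)
#'   parameters of per-gene baseline relative abundance.
#' @param baseline_floor Lower truncation of relative abundance; genes are
#'   redrawn above this detection floor so that planted classes concern
#'   genes quantifiable at the configured depth. Set to 0 for an
#'   untruncated, heavy-tailed abundance model.
#' @param noise_sigma Multiplicative log-normal noise sd per gene per
#'   library (natural-log scale).
#' @param threshold Significance cut-off on the log2 fold scale.
#' @param margin Guaranteed clearance of every planted noise-free fold
#'   beyond the cut-offs (log2 units).
#' @param fold_windows Planted |log2 fold| windows per effect class:
#'   `overdominance`, `dominance`, `additive` (each `c(lo, hi)`) and
#'   `null_halfwidth` for non-significant sides.
#' @param class_proportions Either a tibble (`group`, `pattern`, `prop`)
#'   or a single named proportion vector applied to every group.
#' @param trait_plan Planted pattern-trait correlation plan, see
#'   [default_trait_plan()].
#' @param parent_traits Parental trait values, see [default_parent_traits()].
#' @param trait_h_mean,trait_h_sd Location/scale (percent) of planted
#'   mid-parent heterosis values.
#' @param trait_empirical If `TRUE` (default) trait noise is orthogonalised
#'   against the pattern proportions so the planted correlation is the
#'   exact sample correlation; if `FALSE` it is the population correlation.
#' @param n_trait_groups Number of groups used as correlation observations
#'   (the standard design has 4).
#'
#' @return An object of class `heterotag_sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1,
                       n_genes = 1000,
                       transcript_length_range = c(300, 1500),
                       frac_genes_without_site = 0.16,
                       tag_length = 17,
                       library_depth = 50000,
                       fraction_non3prime = 0.01,
                       baseline_meanlog = 0,
                       baseline_sdlog = 0.35,
                       baseline_floor = 0.6,
                       noise_sigma = 0.1,
                       threshold = 2,
                       margin = 0.5,
                       fold_windows = list(
                         overdominance = c(3.25, 3.75),
                         dominance = c(3.25, 3.75),
                         additive = c(4.25, 4.75),
                         null_halfwidth = 0.4
                       ),
                       class_proportions = default_class_proportions(),
                       trait_plan = default_trait_plan(),
                       parent_traits = default_parent_traits(),
                       trait_h_mean = 15,
                       trait_h_sd = 8,
                       trait_empirical = TRUE,
                       n_trait_groups = 4) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(frac_genes_without_site, "frac_genes_without_site", 0, 1)
  assert_scalar_number(library_depth, "library_depth", lower = 1)
  assert_scalar_number(tag_length, "tag_length", lower = 8)
  assert_scalar_number(fraction_non3prime, "fraction_non3prime", 0, 1)
  assert_scalar_number(threshold, "threshold", lower = 1e-9)
  assert_scalar_number(margin, "margin", lower = 0)
  assert_scalar_number(n_trait_groups, "n_trait_groups", lower = 3)
  if (length(transcript_length_range) != 2 ||
      transcript_length_range[2] < transcript_length_range[1]) {
    abort("`transcript_length_range` must be c(min, max) with max >= min")
  }
  if (transcript_length_range[2] < 4 + tag_length) {
    abort("degenerate transcript length range: max length < CATG length + tag_length")
  }
  if (is.numeric(class_proportions) && !is.null(names(class_proportions))) {
    class_proportions <- crossing(
      group = GROUP_LEVELS,
      tibble(pattern = names(class_proportions), prop = unname(class_proportions))
    )
  }
  assert_columns(class_proportions, c("group", "pattern", "prop"), "class_proportions")
  bad <- class_proportions %>%
    group_by(.data$group) %>%
    summarise(s = sum(.data$prop), .groups = "drop") %>%
    filter(abs(.data$s - 1) > 1e-9)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "class proportions must sum to 1 per group; offending group(s): %s",
      paste(bad$group, collapse = ", ")
    ))
  }
  if (!all(class_proportions$pattern %in% PATTERN_LEVELS)) {
    abort("class_proportions contains unknown pattern labels")
  }
  sig_lo <- min(fold_windows$overdominance[1], fold_windows$dominance[1], fold_windows$additive[1])
  if (sig_lo < threshold + margin) {
    abort("fold windows violate the planted margin: significant folds must be >= threshold + margin")
  }
  if (fold_windows$null_halfwidth > threshold - margin) {
    abort("fold windows violate the planted margin: null folds must stay <= threshold - margin")
  }
  if (any(abs(trait_plan$target_r) > 1)) {
    abort("trait plan target correlations must lie in [-1, 1]")
  }
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      transcript_length_range = as.integer(transcript_length_range),
      frac_genes_without_site = frac_genes_without_site,
      tag_length = as.integer(tag_length),
      library_depth = as.integer(library_depth),
      fraction_non3prime = fraction_non3prime,
      baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
      baseline_floor = baseline_floor, noise_sigma = noise_sigma,
      threshold = threshold, margin = margin, fold_windows = fold_windows,
      class_proportions = as_tibble(class_proportions),
      trait_plan = as_tibble(trait_plan),
      parent_traits = as_tibble(parent_traits),
      trait_h_mean = trait_h_mean, trait_h_sd = trait_h_sd,
      trait_empirical = trait_empirical,
      n_trait_groups = as.integer(n_trait_groups)
    ),
    class = "heterotag_sim_config"
  )
}

#' Library design of the simulated experiment
#'
#' Eight libraries: for each combination (cross = line A female x line B
#' male; reciprocal = line B female x line A male) a sexed library per
#' parent plus F1 female and F1 male libraries.
#'
#' @return A tibble with columns `library_id`, `generation`, `parent_role`,
#'   `combination`, `sex`, `line`.
#' @export
simulated_design <- function() {
  tibble(
    library_id = c(
      "cross_Pf", "cross_Pm", "cross_F1f", "cross_F1m",
      "reciprocal_Pf", "reciprocal_Pm", "reciprocal_F1f", "reciprocal_F1m"
    ),
    generation = rep(c("parent", "parent", "F1", "F1"), 2),
    parent_role = rep(c("female_line", "male_line", NA, NA), 2),
    combination = rep(c("cross", "reciprocal"), each = 4),
    sex = rep(c("female", "male", "female", "male"), 2),
    line = c("lineA", "lineB", "hybrid", "hybrid", "lineB", "lineA", "hybrid", "hybrid")
  )
}

random_dna <- function(n, lengths) {
  map_chr(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  })
}

strip_catg <- function(seqs) {
  # replace the G of every CATG occurrence until none remain
  repeat {
    has <- grepl("CATG", seqs, fixed = TRUE)
    if (!any(has)) return(seqs)
    seqs[has] <- vapply(seqs[has], function(s) {
      i <- regexpr("CATG", s, fixed = TRUE)
      substr(s, i + 3, i + 3) <- sample(c("A", "C", "T"), 1)
      s
    }, character(1), USE.NAMES = FALSE)
  }
}

#' Simulate reference transcripts
#'
#' Generates `n_genes` random mRNA sense-strand transcripts. A configured
#' fraction carries no CATG site at all; every remaining transcript is
#' guaranteed at least one CATG site with `tag_length` bases 3' of it, so
#' it yields an extractable tag.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `gene_id`, `sequence` and a logical
#'   `has_site` flag.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "heterotag_sim_config"))
  with_seed(substream_seed(config$seed, 1), {
    n <- config$n_genes
    lr <- config$transcript_length_range
    lens <- if (lr[1] == lr[2]) rep(lr[1], n) else sample(lr[1]:lr[2], n, replace = TRUE)
    seqs <- random_dna(n, lens)
    n_free <- round(config$frac_genes_without_site * n)
    free_idx <- if (n_free > 0) sample.int(n, n_free) else integer(0)
    seqs[free_idx] <- strip_catg(seqs[free_idx])
    # guarantee a qualifying site on every site-bearing transcript
    need <- config$tag_length
    site_idx <- setdiff(seq_len(n), free_idx)
    for (i in site_idx) {
      s <- seqs[i]
      hits <- gregexpr("CATG", s, fixed = TRUE)[[1]]
      ok <- any(hits > 0 & (nchar(s) - (hits + 3)) >= need)
      if (!ok) {
        pos <- sample.int(nchar(s) - need - 3, 1)
        substr(s, pos, pos + 3) <- "CATG"
        seqs[i] <- s
      }
    }
    tibble(
      gene_id = sprintf("gene_%04d", seq_len(n)),
      sequence = seqs,
      has_site = !seq_len(n) %in% free_idx
    )
  })
}

# admissible |fold| window for one side of a label
side_window <- function(sign, eff_class, fw) {
  if (sign == 0) {
    c(-fw$null_halfwidth, fw$null_halfwidth)
  } else {
    w <- fw[[eff_class]]
    if (sign > 0) w else c(-w[2], -w[1])
  }
}

# feasible range of delta = fF - fM (= log2 Pm - log2 Pf) for a label
delta_range <- function(label, fw) {
  s <- label_signs()[[label]]
  cls <- label_effect_class()[[label]]
  wf <- side_window(s[1], cls, fw)
  wm <- side_window(s[2], cls, fw)
  c(wf[1] - wm[2], wf[2] - wm[1])
}

#' Plant per-library expression means realising the nine-class scheme
#'
#' For each gene and combination, draws gene-action labels for the two F1
#' sexes and constructs parental and F1 mean expression levels whose
#' noise-free log2(F1/parent) folds satisfy the labels' defining
#' inequalities with the configured margin beyond the +/- threshold.
#'
#' Because the two F1 sexes of a combination share the same two parental
#' libraries, their labels are geometrically coupled: the parental log2
#' difference delta implied by one sex's label must be attainable under the
#' other's. Labels are therefore sampled jointly -- the first sex (rotated
#' gene by gene) from the group's proportions, the second restricted to
#' delta-compatible labels -- and the realised labels are returned as the
#' ground truth.
#'
#' @param transcripts Output of [simulate_reference()].
#' @param config A [sim_config()].
#' @return A list with `means` (tibble `gene_id`, `library_id`,
#'   `mean_expr`), `truth` (tibble `gene_id`, `group`, `combination`,
#'   `sex`, `label`, `lfc_female`, `lfc_male`), and `design`.
#' @export
plant_expression <- function(transcripts, config) {
  stopifnot(inherits(config, "heterotag_sim_config"))
  assert_columns(transcripts, c("gene_id", "sequence"), "transcripts")
  design <- simulated_design()
  fw <- config$fold_windows
  labels <- PATTERN_LEVELS
  dr <- lapply(setNames(labels, labels), delta_range, fw = fw)
  compat <- lapply(dr, function(a) {
    names(which(vapply(dr, function(b) min(a[2], b[2]) - max(a[1], b[1]) > 1e-9, logical(1))))
  })
  props <- config$class_proportions %>%
    pivot_wider(names_from = "pattern", values_from = "prop", values_fill = 0)
  prop_for <- function(group) {
    row <- props[props$group == group, labels[labels %in% names(props)], drop = FALSE]
    p <- setNames(rep(0, length(labels)), labels)
    p[names(row)] <- as.numeric(row[1, ])
    p
  }

  has_site <- if ("has_site" %in% names(transcripts)) {
    transcripts$has_site
  } else {
    grepl("CATG", transcripts$sequence, fixed = TRUE)
  }
  genes <- transcripts$gene_id
  n <- length(genes)

  with_seed(substream_seed(config$seed, 2), {
    base <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
    if (config$baseline_floor > 0) {
      while (any(base < config$baseline_floor)) {
        i <- base < config$baseline_floor
        base[i] <- rlnorm(sum(i), config$baseline_meanlog, config$baseline_sdlog)
      }
    }
    lbase <- log2(base)

    means <- matrix(rep(base, 8), nrow = n,
                    dimnames = list(genes, design$library_id))
    truth <- vector("list", 2L)
    for (ci in 1:2) {
      comb <- c("cross", "reciprocal")[ci]
      pF <- prop_for(group_id(comb, "female"))
      pM <- prop_for(group_id(comb, "male"))
      lab_f <- lab_m <- character(n)
      lfcs <- matrix(NA_real_, n, 4) # fF_female, fM_female, fF_male, fM_male
      for (i in seq_len(n)) {
        if (!has_site[i]) next
        female_first <- (runif(1) < 0.5)
        p1 <- if (female_first) pF else pM
        p2 <- if (female_first) pM else pF
        l1 <- sample(labels, 1, prob = p1)
        ok <- compat[[l1]]
        p2r <- p2[ok]
        l2 <- if (sum(p2r) > 0) sample(ok, 1, prob = p2r) else l1
        lf <- if (female_first) l1 else l2
        lm <- if (female_first) l2 else l1
        dlo <- max(dr[[lf]][1], dr[[lm]][1])
        dhi <- min(dr[[lf]][2], dr[[lm]][2])
        delta <- runif(1, dlo, dhi)
        draw_folds <- function(lab) {
          s <- label_signs()[[lab]]
          cls <- label_effect_class()[[lab]]
          wf <- side_window(s[1], cls, fw)
          wm <- side_window(s[2], cls, fw)
          lo <- max(wf[1], wm[1] + delta)
          hi <- min(wf[2], wm[2] + delta)
          fF <- runif(1, lo, hi)
          c(fF, fF - delta)
        }
        ff <- draw_folds(lf)
        fm <- draw_folds(lm)
        lab_f[i] <- lf; lab_m[i] <- lm
        lfcs[i, ] <- c(ff, fm)
      }

      # build the four library columns: parents split the planted delta
      # symmetrically around the gene's baseline, F1s sit at the planted
      # folds relative to the female parent
      libs <- design$library_id[design$combination == comb]
      site <- which(has_site)
      d_raw <- lfcs[site, 1] - lfcs[site, 2]
      pf_l <- lbase[site] - d_raw / 2
      means[site, libs] <- 2^cbind(
        pf_l, pf_l + d_raw, pf_l + lfcs[site, 1], pf_l + lfcs[site, 3]
      )

      keep <- has_site
      truth[[ci]] <- bind_rows(
        tibble(
          gene_id = genes[keep], combination = comb, sex = "female",
          label = lab_f[keep], lfc_female = lfcs[keep, 1], lfc_male = lfcs[keep, 2]
        ),
        tibble(
          gene_id = genes[keep], combination = comb, sex = "male",
          label = lab_m[keep], lfc_female = lfcs[keep, 3], lfc_male = lfcs[keep, 4]
        )
      )
    }
    truth <- list_rbind(truth) %>%
      mutate(group = group_id(.data$combination, .data$sex), .after = "gene_id") %>%
      arrange(.data$group, .data$gene_id)
    means_tbl <- as_tibble(means, rownames = "gene_id") %>%
      pivot_longer(-"gene_id", names_to = "library_id", values_to = "mean_expr")
    list(means = means_tbl, truth = truth, design = design)
  })
}

#' Sample the eight tag libraries
#'
#' Per library, `library_depth` tag copies are drawn by multinomial
#' sampling over genes with probability proportional to the planted mean
#' expression perturbed by multiplicative log-normal noise. A configured
#' small fraction of copies comes from CATG sites other than the 3'-most
#' one; the rest are the canonical rank-1 tags.
#'
#' @param transcripts Output of [simulate_reference()].
#' @param means Mean-expression tibble from [plant_expression()].
#' @param config A [sim_config()].
#' @return A tibble of clean tags with columns `library_id`,
#'   `tag`, `count`.
#' @export
simulate_libraries <- function(transcripts, means, config) {
  stopifnot(inherits(config, "heterotag_sim_config"))
  design <- simulated_design()
  idx <- build_tag_index(transcripts, tag_length = config$tag_length)
  rank1 <- idx %>% filter(.data$site_rank == 1)
  deeper <- idx %>% filter(.data$site_rank > 1)
  genes <- rank1$gene_id
  tag1 <- setNames(rank1$tag, rank1$gene_id)
  deep_by_gene <- split(deeper$tag, deeper$gene_id)
  mean_wide <- means %>%
    pivot_wider(names_from = "library_id", values_from = "mean_expr")

  out <- vector("list", nrow(design))
  for (li in seq_len(nrow(design))) {
    lib <- design$library_id[li]
    mu <- mean_wide[[lib]][match(genes, mean_wide$gene_id)]
    mu[is.na(mu)] <- 0
    if (sum(mu) <= 0) {
      abort(sprintf("library %s has zero total planted expression", lib))
    }
    out[[li]] <- with_seed(substream_seed(config$seed, c(3, li)), {
      noisy <- mu * rlnorm(length(mu), 0, config$noise_sigma)
      depth <- config$library_depth
      eligible <- names(deep_by_gene)
      can_non3 <- length(eligible) > 0 && config$fraction_non3prime > 0
      m <- if (can_non3) rbinom(1, depth, config$fraction_non3prime) else 0L
      counts1 <- as.integer(rmultinom(1, depth - m, noisy))
      tags <- tibble(tag = unname(tag1), count = counts1)
      if (m > 0) {
        w <- noisy[match(eligible, genes)]
        if (sum(w) <= 0) w <- rep(1, length(w))
        gsel <- as.integer(rmultinom(1, m, w))
        picked <- unlist(map2(deep_by_gene, gsel, function(tg, k) {
          if (k == 0) character(0) else sample(tg, k, replace = TRUE)
        }), use.names = FALSE)
        tags <- bind_rows(tags, tibble(tag = picked, count = 1L))
      }
      tags %>%
        filter(.data$count > 0) %>%
        group_by(.data$tag) %>%
        summarise(count = sum(.data$count), .groups = "drop") %>%
        mutate(library_id = lib, .before = 1)
    })
  }
  list_rbind(out)
}

#' Simulate trait heterosis coupled to pattern proportions
#'
#' For each planted (pattern, trait, target r) the trait's mid-parent
#' heterosis values across groups are a linear function of that group's
#' pattern proportion plus Gaussian noise. With `trait_empirical = TRUE`
#' the noise is orthogonalised against the proportions so the planted r is
#' the exact sample correlation (the construction used by
#' `MASS::mvrnorm(empirical = TRUE)`).
#'
#' @param proportions Tibble `group`, `pattern`, `prop` — typically the
#'   realised planted proportions of the simulated experiment.
#' @param config A [sim_config()].
#' @param seed Optional seed override (defaults to a substream of
#'   `config$seed`).
#' @return A list with `traits` (per-line/hybrid trait values), and
#'   `planted_h` (per trait and group: planted H% plus a `degenerate`
#'   flag set when the driving proportions have zero variance).
#' @export
simulate_traits <- function(proportions, config, seed = NULL) {
  stopifnot(inherits(config, "heterotag_sim_config"))
  assert_columns(proportions, c("group", "pattern", "prop"), "proportions")
  groups <- unique(proportions$group)
  n <- length(groups)
  if (n < 3) abort("at least 3 groups are required to plant trait correlations")
  seed <- seed %||% substream_seed(config$seed, 4)
  plan <- config$trait_plan
  with_seed(seed, {
    planted <- pmap(plan, function(trait, pattern, target_r, noise_sigma) {
      x <- proportions %>%
        filter(.data$pattern == !!pattern) %>%
        arrange(match(.data$group, groups))
      x <- x$prop[match(groups, x$group)]
      x[is.na(x)] <- 0
      degenerate <- isTRUE(sd(x) < 1e-12)
      if (degenerate) {
        h <- rep(config$trait_h_mean, n)
      } else {
        zx <- as.numeric(scale(x))
        e <- rnorm(n)
        if (config$trait_empirical) {
          ep <- resid(lm(e ~ zx))
          ep <- if (sd(ep) < 1e-12) rep(0, n) else as.numeric(scale(ep))
          y <- target_r * zx + sqrt(1 - target_r^2) * ep
        } else {
          y <- target_r * zx + sqrt(1 - target_r^2) * rnorm(n, 0, max(noise_sigma, 1e-12))
        }
        h <- config$trait_h_mean + config$trait_h_sd * y
      }
      tibble(
        group = groups, trait = trait, pattern = pattern,
        target_r = target_r, h_pct = h, degenerate = degenerate
      )
    }) %>% list_rbind()

    pt <- config$parent_traits
    parents <- pt %>%
      pivot_longer(c("lineA", "lineB"), names_to = "line", values_to = "value") %>%
      mutate(generation = "parent", combination = NA_character_)
    grp_tbl <- tibble(
      group = groups,
      combination = sub("_(female|male)$", "", groups),
      sex = sub("^.*_", "", groups)
    )
    hybrids <- planted %>%
      left_join(grp_tbl, by = "group") %>%
      left_join(pt, by = c("trait", "sex")) %>%
      mutate(
        midparent = (.data$lineA + .data$lineB) / 2,
        value = .data$midparent * (1 + .data$h_pct / 100),
        line = "hybrid", generation = "F1"
      ) %>%
      select("trait", "sex", "line", "generation", "combination", "value")
    traits <- bind_rows(
      parents %>% select("trait", "sex", "line", "generation", "combination", "value"),
      hybrids
    )
    list(traits = traits, planted_h = planted)
  })
}

#' Run the whole synthetic experiment
#'
#' Convenience wrapper: reference, planted expression, eight tag
#' libraries, and trait tables, all derived deterministically from the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `transcripts`, `design`, `means`, `truth`,
#'   `libraries`, `traits`, `planted_h`, `planted_proportions`, `config`.
#' @export
simulate_dge_experiment <- function(config = sim_config()) {
  transcripts <- simulate_reference(config)
  planted <- plant_expression(transcripts, config)
  libraries <- simulate_libraries(transcripts, planted$means, config)
  planted_props <- planted$truth %>%
    count(.data$group, .data$label) %>%
    group_by(.data$group) %>%
    mutate(prop = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    rename(pattern = "label")
  tr <- simulate_traits(planted_props, config)
  list(
    transcripts = transcripts, design = planted$design,
    means = planted$means, truth = planted$truth, libraries = libraries,
    traits = tr$traits, planted_h = tr$planted_h,
    planted_proportions = planted_props, config = config
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
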