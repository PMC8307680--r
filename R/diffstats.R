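# Differential abundance: Kruskal-Wallis omnibus screen, Conover-Iman post
# hoc pairwise tests with rank-based effect sizes, Benjamini-Hochberg
# adjustment, presence/absence chi-squared analysis and median fold-changes.

values_matrix <- function(values) {
  if (inherits(values, "normalized_panel")) {
    if (is.null(values$permille)) {
      abort("Run normalize_permille() first (the screens operate on the permille scale).",
            class = "sevlip_stats_error")
    }
    return(values$permille)
  }
  as.matrix(values)
}

#' Benjamini-Hochberg adjustment within a named family
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement; each
#' test family (omnibus, each group pair, presence) is adjusted separately.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param family Optional label carried in error messages.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(pvalues, family = "pvalues") {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    abort(sprintf("Family '%s' contains p-values outside [0, 1].", family),
          class = "sevlip_stats_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Kruskal-Wallis omnibus screen
#'
#' Tie-corrected Kruskal-Wallis H with chi-squared approximation p per
#' metabolite, plus the eta-squared effect size
#' `(H - k + 1) / (n - k)` clipped to `[0, 1]`. A compound constant across
#' all samples gets `H = 0`, `p = 1` and is flagged rather than raising.
#'
#' @param values Samples x metabolites matrix on the permille scale (or a
#'   `normalized_panel` whose permille matrix is used).
#' @param groups Group labels (factor, one per sample).
#' @return A tibble with `metabolite_id`, `statistic`, `p_value`, `q_value`
#'   (BH within the omnibus family), `eta_squared`, `flag`.
#' @export
kruskal_wallis_screen <- function(values, groups = NULL) {
  if (inherits(values, "normalized_panel") && is.null(groups)) {
    groups <- values$samples$group
  }
  m <- values_matrix(values)
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups); n <- length(groups)
  if (k < 2 || any(tabulate(groups) < 2)) {
    abort("Need >= 2 groups with >= 2 samples each.", class = "sevlip_stats_error")
  }
  res <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    if (length(unique(x)) == 1L) {
      return(c(0, 1, 1))
    }
    kt <- kruskal.test(x, groups)
    c(unname(kt$statistic), kt$p.value, 0)
  })
  res <- do.call(rbind, res)
  h <- res[, 1]
  tibble(
    metabolite_id = colnames(m) %||% paste0("m", seq_len(ncol(m))),
    statistic = h,
    p_value = res[, 2],
    q_value = bh_adjust(res[, 2], "omnibus"),
    eta_squared = pmin(1, pmax(0, (h - k + 1) / (n - k))),
    flag = ifelse(res[, 3] == 1, "constant", NA_character_)
  )
}

default_pairs <- function(levels) {
  cmb <- utils::combn(levels, 2)
  lapply(seq_len(ncol(cmb)), function(i) c(cmb[2, i], cmb[1, i]))
}

pair_label <- function(pair) paste0(pair[1], "_vs_", pair[2])

#' Conover-Iman post hoc pairwise tests
#'
#' For each requested pair of groups, the Conover-Iman t statistic built on
#' the omnibus ranks: pooled tie-corrected rank variance `S2`, the
#' `(n - 1 - H) / (n - k)` correction, and a two-sided p-value from the t
#' distribution with `n - k` degrees of freedom. The statistic standardized
#' by the square root of the two compared groups' total size gives the
#' rank-based effect size `r`. The median-based fold-change
#' (first pair element over second) is reported alongside.
#'
#' @inheritParams kruskal_wallis_screen
#' @param pairs List of `c(numerator, denominator)` label pairs; by default
#'   all pairs with the later-declared group as numerator (e.g. `LC_vs_HC`).
#' @return A tibble with one row per metabolite x pair: `statistic`,
#'   `p_value`, `q_value` (BH within each pair family), `effect_r`,
#'   `fold_change`, and `rank` (1 = smallest p within the pair family).
#' @export
conover_posthoc <- function(values, groups = NULL, pairs = NULL) {
  if (inherits(values, "normalized_panel") && is.null(groups)) {
    groups <- values$samples$group
  }
  m <- values_matrix(values)
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups); n <- length(groups)
  pairs <- pairs %||% default_pairs(levels(groups))
  for (p in pairs) {
    if (!all(p %in% levels(groups))) {
      abort(sprintf("Pair (%s, %s) uses an undeclared or empty group.", p[1], p[2]),
            class = "sevlip_stats_error")
    }
  }
  sizes <- tabulate(groups, k)
  names(sizes) <- levels(groups)
  out <- vector("list", length(pairs))
  ids <- colnames(m) %||% paste0("m", seq_len(ncol(m)))

  stats_one <- function(x) {
    r <- rank(x)
    rbar <- tapply(r, groups, mean)
    s2 <- (sum(r^2) - n * (n + 1)^2 / 4) / (n - 1)
    h <- if (s2 > 0) (sum(tapply(r, groups, sum)^2 / sizes) - n * (n + 1)^2 / 4) / s2 else 0
    list(rbar = rbar, s2 = s2, h = h)
  }
  st <- lapply(seq_len(ncol(m)), function(j) stats_one(m[, j]))

  for (pi in seq_along(pairs)) {
    p <- pairs[[pi]]
    ni <- sizes[[p[1]]]; nj <- sizes[[p[2]]]
    tval <- vapply(st, function(s) {
      if (s$s2 == 0) return(0)
      corr <- (n - 1 - s$h) / (n - k)
      denom2 <- s$s2 * corr * (1 / ni + 1 / nj)
      diff <- s$rbar[[p[1]]] - s$rbar[[p[2]]]
      if (denom2 <= 0) return(sign(diff) * Inf)
      diff / sqrt(denom2)
    }, numeric(1))
    pval <- ifelse(is.infinite(tval), 0, 2 * pt(-abs(tval), df = n - k))
    fc <- fold_change_median(m, groups, p)$fold_change
    out[[pi]] <- tibble(
      metabolite_id = ids,
      pair = pair_label(p),
      statistic = tval,
      p_value = pval,
      q_value = bh_adjust(pval, pair_label(p)),
      effect_r = abs(tval) / sqrt(ni + nj),
      fold_change = fc,
      rank = rank(pval, ties.method = "min")
    )
  }
  bind_rows(out)
}

#' Median-based fold change between two groups
#'
#' `median(numerator group) / median(denominator group)` per metabolite.
#' A zero denominator median yields `NA` with a flag rather than an error.
#'
#' @inheritParams kruskal_wallis_screen
#' @param pair `c(numerator, denominator)` group labels.
#' @return A tibble with `metabolite_id`, `fold_change`, `flag`.
#' @export
fold_change_median <- function(values, groups = NULL, pair = NULL) {
  if (inherits(values, "normalized_panel") && is.null(groups)) {
    groups <- values$samples$group
  }
  m <- values_matrix(values)
  groups <- as.factor(groups)
  if (is.null(pair) || length(pair) != 2 || !all(pair %in% levels(groups)) ||
      !all(tabulate(groups)[match(pair, levels(groups))] > 0)) {
    abort("`pair` must name two non-empty groups.", class = "sevlip_stats_error")
  }
  num <- unname(apply(m[groups == pair[1], , drop = FALSE], 2, median))
  den <- unname(apply(m[groups == pair[2], , drop = FALSE], 2, median))
  fc <- ifelse(den == 0, NA_real_, num / den)
  tibble(metabolite_id = colnames(m) %||% paste0("m", seq_len(ncol(m))),
         fold_change = fc,
         flag = ifelse(den == 0, "zero_denominator_median", NA_character_))
}

#' Presence/absence chi-squared analysis
#'
#' For compounds excluded from the quantitative tier, tests whether
#' detection (code `OBSERVED`) is a group-related feature via a Pearson
#' chi-squared independence test on the group x present/absent contingency
#' table (no continuity correction). Degenerate tables (all present or all
#' absent) get `p = 1` and a flag; tables with fewer than 80 percent of
#' expected counts >= 5 are flagged `low_expected`.
#'
#' @param panel A [metabolite_panel()].
#' @param excluded_ids Metabolite ids to test.
#' @return A tibble with `metabolite_id`, `statistic`, `p_value`, `q_value`,
#'   `min_expected`, `flag`, and per-group presence counts.
#' @export
presence_chi2 <- function(panel, excluded_ids) {
  groups_lv <- levels(panel$samples$group)
  if (!length(excluded_ids)) {
    out <- tibble(metabolite_id = character(), statistic = numeric(),
                  p_value = numeric(), q_value = numeric(),
                  min_expected = numeric(), flag = character())
    for (g in groups_lv) out[[paste0("present_", g)]] <- integer()
    return(out)
  }
  cols <- match(excluded_ids, panel$metabolites$metabolite_id)
  if (anyNA(cols)) {
    abort(sprintf("Metabolite %s not in panel.", excluded_ids[which(is.na(cols))[1]]),
          class = "sevlip_stats_error")
  }
  g <- panel$samples$group
  groups <- levels(g)
  res <- lapply(seq_along(cols), function(i) {
    present <- panel$codes[, cols[i]] == "OBSERVED"
    n_pres <- tapply(present, g, sum)
    n_tot <- tabulate(g, length(groups))
    if (all(present) || all(!present)) {
      return(tibble(metabolite_id = excluded_ids[i], statistic = 0,
                    p_value = 1, min_expected = NA_real_, flag = "degenerate",
                    !!!setNames(as.list(as.integer(n_pres)),
                                paste0("present_", groups))))
    }
    tab <- rbind(present = n_pres, absent = n_tot - n_pres)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    low <- mean(ct$expected >= 5) < 0.8
    tibble(metabolite_id = excluded_ids[i],
           statistic = unname(ct$statistic), p_value = ct$p.value,
           min_expected = min(ct$expected),
           flag = if (low) "low_expected" else NA_character_,
           !!!setNames(as.list(as.integer(n_pres)), paste0("present_", groups)))
  })
  out <- bind_rows(res)
  out$q_value <- bh_adjust(out$p_value, "presence")
  dplyr::relocate(out, "q_value", .after = "p_value")
}

#' Cross-compartment comparison of top differential compounds
#'
#' Takes the top `top_n` compounds by pairwise p-value in compartment A
#' (e.g. sEV), split by fold-change direction, and reports each compound's
#' p-value, p-based rank and fold-change in compartment B (e.g. whole serum),
#' marking compounds absent from B as not detected/quantitated.
#'
#' @param table_a,table_b Pairwise tibbles from [conover_posthoc()], filtered
#'   to the same group pair.
#' @param top_n Compounds per direction (default 5).
#' @return A tibble with columns `direction`, `metabolite_id`, `p_a`,
#'   `rank_a`, `fold_change_a`, `p_b`, `rank_b`, `fold_change_b`, `status_b`.
#' @export
compare_compartments <- function(table_a, table_b, top_n = 5) {
  stopifnot(all(c("metabolite_id", "p_value", "fold_change") %in% names(table_a)))
  if ("pair" %in% names(table_a) && "pair" %in% names(table_b)) {
    shared <- intersect(unique(table_a$pair), unique(table_b$pair))
    if (length(unique(table_a$pair)) > 1 || !length(shared)) {
      abort("Tables must be filtered to one matching group pair.",
            class = "sevlip_stats_error")
    }
  }
  table_a <- mutate(table_a, rank = rank(.data$p_value, ties.method = "min"))
  table_b <- mutate(table_b, rank = rank(.data$p_value, ties.method = "min"))
  pick <- function(dir) {
    sub <- if (dir == "up") filter(table_a, .data$fold_change > 1)
           else filter(table_a, .data$fold_change < 1)
    if (nrow(sub) < top_n) {
      warn(sprintf("Only %d %s-regulated compounds available (top_n = %d).",
                   nrow(sub), dir, top_n))
    }
    head(arrange(sub, .data$p_value), top_n) |>
      mutate(direction = dir)
  }
  sel <- bind_rows(pick("up"), pick("down"))
  b <- select(table_b, "metabolite_id", p_b = "p_value",
              rank_b = "rank", fold_change_b = "fold_change")
  sel |>
    select("direction", "metabolite_id", p_a = "p_value",
           rank_a = "rank", fold_change_a = "fold_change") |>
    left_join(b, by = "metabolite_id") |>
    mutate(status_b = ifelse(is.na(.data$p_b), "not detected/quantitated",
                             "quantitated"))
}

#' Full differential-abundance analysis
#'
#' Convenience wrapper: omnibus Kruskal-Wallis screen, Conover post hoc for
#' all pairs, and the significance gate marking "differential" compounds
#' (omnibus raw p below `alpha` and pairwise raw p below `alpha`; adjusted
#' q-values are reported alongside). Pairwise rows for compounds failing the
#' omnibus screen are kept but gated, so pairwise findings are only
#' interpreted behind the omnibus protection.
#'
#' @param np A `normalized_panel` with a permille matrix.
#' @param config An [analysis_config()].
#' @return A list with tibbles `omnibus` and `pairwise` (the latter with a
#'   logical `differential` column applying the gate).
#' @export
differential_analysis <- function(np, config = analysis_config()) {
  omnibus <- kruskal_wallis_screen(np)
  pairwise <- conover_posthoc(np)
  gate <- omnibus$metabolite_id[omnibus$p_value < config$alpha]
  pairwise <- mutate(pairwise,
    differential = .data$metabolite_id %in% gate & .data$p_value < config$alpha)
  list(omnibus = omnibus, pairwise = pairwise)
}
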