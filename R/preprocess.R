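# Preprocessing chain: missingness policy -> below-LOQ imputation -> kNN
# imputation -> log2 + empirical-Bayes batch correction; permille
# normalization operates on the (unlogged) imputed concentrations.

#' Apply the two-tier missingness policy
#'
#' Per compound and group, the fractions of below-LOQ ("zero") cells and of
#' internal-standard failures are computed over that group's samples. Tier 1
#' retains a compound iff, in every group, the below-LOQ fraction does not
#' exceed `zero_missing_ceiling` (default 50 percent, equality allowed) and
#' the IS-failure fraction does not exceed `is_missing_ceiling` (default 10
#' percent). The quantitative tier additionally requires the below-LOQ
#' fraction to be strictly below the ceiling in every group; only
#' quantitative-tier compounds enter the differential and classification
#' stages, while tier-excluded compounds feed the presence/absence analysis.
#'
#' @param panel A [metabolite_panel()].
#' @param config An [analysis_config()].
#' @return A `missingness_policy` object with fields `retained_all`,
#'   `retained_quant`, `excluded` (tibble with the violated rule) and
#'   `fractions` (per compound x group missing fractions by type).
#' @export
apply_missingness_policy <- function(panel, config = analysis_config()) {
  groups <- levels(panel$samples$group)
  gsize <- tabulate(panel$samples$group, length(groups))
  if (any(gsize == 0L)) {
    abort(sprintf("Group '%s' has no samples.", groups[which(gsize == 0)[1]]),
          class = "sevlip_policy_error")
  }
  g <- panel$samples$group
  frac_by <- function(code) {
    ind <- panel$codes == code
    t(rowsum(ind + 0, g, reorder = FALSE) / gsize)
  }
  fz <- frac_by("BELOW_LOQ")     # metabolites x groups
  fi <- frac_by("IS_FAILURE")
  ids <- panel$metabolites$metabolite_id

  zmax <- apply(fz, 1L, max)
  imax <- apply(fi, 1L, max)
  tier1 <- zmax <= config$zero_missing_ceiling & imax <= config$is_missing_ceiling
  tier2 <- tier1 & zmax < config$zero_missing_ceiling

  rule <- dplyr::case_when(
    zmax > config$zero_missing_ceiling & imax > config$is_missing_ceiling ~
      "below_loq_and_is_failure",
    zmax > config$zero_missing_ceiling ~ "below_loq_fraction",
    imax > config$is_missing_ceiling ~ "is_failure_fraction",
    TRUE ~ NA_character_
  )
  fractions <- tibble(
    metabolite_id = rep(ids, times = length(groups)),
    group = rep(groups, each = length(ids)),
    frac_below_loq = as.vector(fz),
    frac_is_failure = as.vector(fi)
  )
  structure(
    list(retained_all = ids[tier1],
         retained_quant = ids[tier2],
         excluded = tibble(metabolite_id = ids[!tier1], rule = rule[!tier1]),
         fractions = fractions),
    class = "missingness_policy"
  )
}

#' @export
print.missingness_policy <- function(x, ...) {
  cat(sprintf("<missingness_policy> %d retained (tier 1), %d quantitative, %d excluded\n",
              length(x$retained_all), length(x$retained_quant), nrow(x$excluded)))
  invisible(x)
}

panel_provenance <- function(panel) {
  panel$provenance %||% matrix("observed", nrow(panel$conc), ncol(panel$conc),
                               dimnames = dimnames(panel$conc))
}

#' Impute below-LOQ cells from a truncated normal
#'
#' Every `BELOW_LOQ` cell of a retained compound is replaced by an independent
#' draw from a normal distribution truncated to `(0, LOQ)`, where LOQ is the
#' limit of quantitation of that compound on the sample's plate. The
#' untruncated parameters are mean `LOQ/2` and SD `LOQ/4`, centring the mass
#' mid-interval with negligible boundary pile-up. Observed cells are never
#' touched; draws are reproducible from `seed`.
#'
#' @param panel A [metabolite_panel()].
#' @param retained Metabolite ids to impute (typically tier-1 retained).
#' @param seed Integer seed.
#' @param mean_frac,sd_frac Untruncated mean and SD as fractions of LOQ.
#' @return The panel with those cells filled and a `provenance` matrix
#'   recording `zero_imputed` cells.
#' @export
impute_below_loq <- function(panel, retained = panel$metabolites$metabolite_id,
                             seed = 1L, mean_frac = 0.5, sd_frac = 0.25) {
  cols <- match(retained, panel$metabolites$metabolite_id)
  idx <- which(panel$codes[, cols, drop = FALSE] == "BELOW_LOQ", arr.ind = TRUE)
  prov <- panel_provenance(panel)
  if (nrow(idx)) {
    mcol <- cols[idx[, 2]]
    ids <- panel$metabolites$metabolite_id[mcol]
    plates <- panel$samples$plate[idx[, 1]]
    # per-cell LOQ: plates can differ across cells, look each one up
    loq <- vapply(seq_along(ids), function(i) {
      panel$metabolites[[paste0("loq_", plates[i])]][mcol[i]]
    }, numeric(1))
    if (anyNA(loq)) {
      j <- which(is.na(loq))[1]
      abort(sprintf("No LOQ for metabolite %s on plate %s.", ids[j], plates[j]),
            class = "sevlip_imputation_error")
    }
    draws <- with_rng(seed, {
      u <- runif(nrow(idx))
      qtruncnorm(u, mean_frac * loq, sd_frac * loq, 0, loq)
    })
    flat <- cbind(idx[, 1], mcol)
    panel$conc[flat] <- draws
    prov[flat] <- "zero_imputed"
  }
  panel$provenance <- prov
  panel
}

# Correlation-distance neighbour search shared state: pairwise Pearson
# correlation of log2 profiles over metabolites observed in both samples,
# with the number of shared metabolites tracked so unstable pairs (< min_shared)
# can be ruled ineligible.
knn_distances <- function(log2m, min_shared) {
  ok <- !is.na(log2m)
  shared <- tcrossprod(ok + 0)
  cc <- suppressWarnings(cor(t(log2m), use = "pairwise.complete.obs"))
  d <- 1 - cc
  d[shared < min_shared] <- NA_real_
  diag(d) <- NA_real_
  d
}

#' Impute internal-standard failures by k-nearest neighbours
#'
#' Each `IS_FAILURE` cell (sample `s`, metabolite `m`) is replaced by the mean
#' concentration of `m` in the `k` samples nearest to `s` by correlation
#' distance (1 - Pearson correlation of log2 profiles over metabolites
#' observed in both samples, requiring at least `min_shared` shared
#' metabolites). Candidates must have `m` observed and, at the first tier,
#' share `s`'s group and plate. When fewer than `k` candidates exist the
#' fallback ladder applies: same group/any plate, then same plate/any group,
#' then the global mean of the metabolite; every fallback is logged.
#' Below-LOQ imputation must have been applied first.
#'
#' @param panel A panel returned by [impute_below_loq()].
#' @param retained Metabolite ids to impute.
#' @param k Neighbour count (default 3).
#' @param min_shared Minimum shared observed metabolites for a correlation to
#'   count (default 10).
#' @return The panel with IS-failure cells filled, provenance updated, and a
#'   `knn_log` tibble recording the tier used for each cell.
#' @export
impute_knn <- function(panel, retained = panel$metabolites$metabolite_id,
                       k = 3, min_shared = 10) {
  if (k < 1) abort("`k` must be >= 1.", class = "sevlip_imputation_error")
  cols <- match(retained, panel$metabolites$metabolite_id)
  sub_conc <- panel$conc[, cols, drop = FALSE]
  sub_codes <- panel$codes[, cols, drop = FALSE]
  miss <- which(sub_codes == "IS_FAILURE", arr.ind = TRUE)
  prov <- panel_provenance(panel)
  log_rows <- list()
  if (nrow(miss)) {
    if (any(is.na(sub_conc) & sub_codes == "BELOW_LOQ")) {
      abort("Apply impute_below_loq() before impute_knn().",
            class = "sevlip_imputation_error")
    }
    d <- knn_distances(log2(sub_conc), min_shared)
    group <- panel$samples$group
    plate <- panel$samples$plate
    for (i in seq_len(nrow(miss))) {
      s <- miss[i, 1]; j <- miss[i, 2]
      has_m <- which(!is.na(sub_conc[, j]) & sub_codes[, j] != "IS_FAILURE")
      tiers <- list(
        group_plate = has_m[group[has_m] == group[s] & plate[has_m] == plate[s]],
        group_any   = has_m[group[has_m] == group[s]],
        plate_any   = has_m[plate[has_m] == plate[s]]
      )
      value <- NA_real_; tier_used <- "global_mean"
      for (tn in names(tiers)) {
        cand <- tiers[[tn]]
        cand <- cand[!is.na(d[s, cand])]
        if (length(cand) >= k) {
          nb <- cand[order(d[s, cand], cand)[seq_len(k)]]
          value <- mean(sub_conc[nb, j])
          tier_used <- tn
          break
        }
      }
      if (is.na(value)) {
        pool <- sub_conc[has_m, j]
        if (!length(pool)) {
          abort(sprintf("No candidate for sample %s, metabolite %s after all fallbacks.",
                        panel$samples$sample_id[s], retained[j]),
                class = "sevlip_imputation_error")
        }
        value <- mean(pool)
      }
      panel$conc[s, cols[j]] <- value
      prov[s, cols[j]] <- "knn_imputed"
      log_rows[[i]] <- tibble(sample_id = panel$samples$sample_id[s],
                              metabolite_id = retained[j], tier = tier_used)
    }
  }
  panel$provenance <- prov
  panel$knn_log <- if (length(log_rows)) bind_rows(log_rows) else
    tibble(sample_id = character(), metabolite_id = character(), tier = character())
  panel
}

#' Log2 transform and empirical-Bayes batch correction
#'
#' Transforms the imputed concentrations of the retained compounds with log2
#' and removes per-plate location/scale effects estimated per metabolite and
#' shrunk via parametric empirical Bayes across metabolites (ComBat), treating
#' each 96-well preparation plate as one batch. With `protect_group = TRUE`
#' the group label enters the location model as a preserved covariate, so
#' group differences survive correction even on group-imbalanced plates.
#' Single-plate panels are returned untouched (there is no batch to remove).
#'
#' @param panel A panel with complete concentrations over `retained` (after
#'   both imputation steps).
#' @param retained Metabolite ids to carry forward.
#' @param protect_group Preserve group structure via a design covariate.
#' @return A `normalized_panel` with fields `conc` (imputed micromol matrix),
#'   `log2bc` (batch-corrected log2 matrix), `provenance`, `samples`,
#'   `metabolites`, `retained`.
#' @export
log2_and_batch_correct <- function(panel, retained = panel$metabolites$metabolite_id,
                                   protect_group = TRUE) {
  cols <- match(retained, panel$metabolites$metabolite_id)
  x <- panel$conc[, cols, drop = FALSE]
  if (anyNA(x)) {
    abort("Panel must be complete over `retained` before batch correction.",
          class = "sevlip_batch_error")
  }
  lx <- log2(x)
  plates <- unique(panel$samples$plate)
  if (length(plates) > 1L) {
    sizes <- table(panel$samples$plate)
    if (any(sizes < 2)) {
      abort(sprintf("Plate %s has fewer than 2 samples.",
                    names(sizes)[which(sizes < 2)[1]]),
            class = "sevlip_batch_error")
    }
    mod <- if (protect_group) model.matrix(~ group, data = panel$samples) else NULL
    corrected <- suppressMessages(
      sva::ComBat(dat = t(lx), batch = panel$samples$plate, mod = mod,
                  par.prior = TRUE)
    )
    lx <- t(corrected)
  }
  structure(
    list(conc = x, log2bc = lx,
         provenance = panel_provenance(panel)[, cols, drop = FALSE],
         samples = panel$samples,
         metabolites = panel$metabolites[cols, ],
         retained = retained, permille = NULL, quant_ids = NULL,
         policy = NULL, knn_log = panel$knn_log %||% NULL),
    class = "normalized_panel"
  )
}

#' @export
print.normalized_panel <- function(x, ...) {
  cat(sprintf("<normalized_panel> %d samples x %d retained metabolites\n",
              nrow(x$conc), ncol(x$conc)))
  if (!is.null(x$permille)) {
    cat(sprintf("  permille matrix over %d quantitative compounds\n",
                ncol(x$permille)))
  }
  invisible(x)
}

#' Permille normalization
#'
#' Expresses each quantitative compound as the permille of the sample's total
#' lipid concentration: `1000 * conc / sum(conc over quant_ids)`. Chosen in
#' place of per-vesicle quantities, which are unavailable when the number of
#' vesicles per sample is not measured. Each row of the result sums to 1000.
#'
#' @param x A `normalized_panel` (or a bare concentration matrix).
#' @param quant_ids Quantitative-tier metabolite ids.
#' @return For a `normalized_panel`, the panel with a `permille` field; for a
#'   matrix, the permille matrix.
#' @export
normalize_permille <- function(x, quant_ids = NULL) {
  if (inherits(x, "normalized_panel")) {
    quant_ids <- quant_ids %||% x$retained
    x$permille <- normalize_permille(x$conc[, quant_ids, drop = FALSE])
    x$quant_ids <- quant_ids
    return(x)
  }
  m <- if (is.null(quant_ids)) x else x[, quant_ids, drop = FALSE]
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    abort(sprintf("Sample %s has non-positive total concentration.",
                  rownames(m)[which(totals <= 0)[1]] %||% which(totals <= 0)[1]),
          class = "sevlip_normalization_error")
  }
  1000 * m / totals
}

#' Aggregate concentrations by lipid class
#'
#' Sums the imputed concentrations of each class's member compounds per
#' sample and reports each class's relative contribution to the sample total.
#'
#' @param np A `normalized_panel`.
#' @return A tibble with columns `sample_id`, `group`, `class`, `total`
#'   (micromol) and `share_pct` (percent of the sample's total).
#' @export
aggregate_classes <- function(np) {
  cls <- np$metabolites$class
  totals <- t(rowsum(t(np$conc), cls, reorder = FALSE))
  tibble(
    sample_id = rep(np$samples$sample_id, times = ncol(totals)),
    group = rep(np$samples$group, times = ncol(totals)),
    class = rep(colnames(totals), each = nrow(totals)),
    total = as.vector(totals),
    share_pct = as.vector(100 * totals / rowSums(np$conc))
  )
}

#' Run the full preprocessing chain
#'
#' Policy -> below-LOQ imputation -> kNN imputation -> log2 + batch
#' correction -> permille normalization, in that fixed order. Re-running with
#' the same seed is bit-identical.
#'
#' @param panel A [metabolite_panel()].
#' @param config An [analysis_config()].
#' @return A `normalized_panel` carrying the policy result, the complete
#'   imputed concentration matrix over tier-1 compounds, the batch-corrected
#'   log2 matrix, the permille matrix over quantitative-tier compounds, and
#'   per-cell provenance flags.
#' @export
preprocess_panel <- function(panel, config = analysis_config()) {
  policy <- apply_missingness_policy(panel, config)
  panel <- impute_below_loq(panel, policy$retained_all, seed = config$seed)
  panel <- impute_knn(panel, policy$retained_all, k = config$knn_k)
  np <- log2_and_batch_correct(panel, policy$retained_all,
                               protect_group = config$protect_group)
  np <- normalize_permille(np, policy$retained_quant)
  np$policy <- policy
  np
}
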