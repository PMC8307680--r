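#' Lipid classes carried by the panel format
#'
#' Acylcarnitines (AC), lysophosphatidylcholines (LPC), diacyl and ether
#' phosphatidylcholines (PC, PC-O), sphingomyelins (SM), ceramides (Cer),
#' di- and triglycerides (DG, TG), cholesteryl esters (CE) and hexose (HEX).
#'
#' @export
LIPID_CLASSES <- c("AC", "LPC", "PC", "PC-O", "SM", "Cer", "DG", "TG", "CE", "HEX")

default_class_counts <- c(
  AC = 53, LPC = 22, PC = 140, `PC-O` = 26, SM = 20,
  Cer = 20, DG = 14, TG = 42, CE = 14, HEX = 1
)

# Per-class generating means on the log2-micromol scale. Chosen so that
# cholesteryl esters dominate the total lipid mass (about two-thirds) and
# choline-containing phospholipids contribute about a quarter, the composition
# typical of an LDL-depleted serum sEV fraction.
default_class_log2_mean <- c(
  AC = -2, LPC = -1, PC = 0, `PC-O` = -1, SM = -1,
  Cer = -2, DG = -2, TG = -1.5, CE = 5, HEX = 3
)

#' Planted differential effect for the synthetic generator
#'
#' @param metabolite_id Compound identifier (must exist in the generated panel).
#' @param group Group label whose samples receive the effect.
#' @param fold_change Multiplicative effect on the concentration scale (> 0).
#'
#' @return A one-row tibble; rows from several calls can be `bind_rows()`-ed
#'   into the `effects` field of [simulation_config()].
#' @export
planted_effect <- function(metabolite_id, group, fold_change) {
  if (!is.numeric(fold_change) || any(fold_change <= 0)) {
    abort("`fold_change` must be > 0.", class = "sevlip_config_error")
  }
  tibble(metabolite_id = metabolite_id, group = group, fold_change = fold_change)
}

#' Default planted effects at screening-study magnitudes
#'
#' Ten compounds carry lung-cancer-group effects with the median fold-changes
#' observed for the top differential sEV lipids in a three-group screening
#' cohort: five upregulated (e.g. Cer(42:1) at 1.326, CE(19:2) at 1.360) and
#' five downregulated (e.g. TG(56:8) at 0.783) in the LC group.
#'
#' @param group Affected group label (default `"LC"`).
#' @return A tibble of planted effects.
#' @export
default_planted_effects <- function(group = "LC") {
  planted_effect(
    c("CE(19:2)", "Cer(42:1)", "TG(54:2)", "PC-O(33:3)", "PC(24:0)",
      "PC(38:6)", "PC(38:7)", "PC(37:5)", "TG(56:8)", "PC(38:5)"),
    group,
    c(1.360, 1.326, 1.410, 1.215, 1.673,
      0.922, 0.918, 0.926, 0.783, 0.952)
  )
}

cfg_check <- function(ok, field, msg) {
  if (!ok) {
    abort(sprintf("Invalid `%s`: %s", field, msg),
          class = "sevlip_config_error")
  }
}

rate_ok <- function(r) {
  is.numeric(r) && length(r) %in% 1:2 && all(r >= 0 & r <= 1) &&
    (length(r) == 1L || r[1] <= r[2])
}

#' Configuration of the synthetic-panel generator
#'
#' Defines the study conditions the generator emulates: three balanced groups
#' of 81 screening participants, 352 quantifiable lipids over ten classes
#' measured on three 96-well plates, log-normal concentrations with per-plate
#' additive log2 shifts, strong inter-individual heterogeneity, two kinds of
#' injected missingness, and (by default) ten planted group effects at
#' screening-study magnitudes.
#'
#' @param n_per_group Samples per group (>= 2).
#' @param groups Ordered group labels.
#' @param n_metabolites Number of compounds.
#' @param class_proportions Named fractions over [LIPID_CLASSES]; must sum to 1.
#' @param n_plates Number of 96-well batches; samples are assigned to plates in
#'   enrolment order with groups interleaved, so plates stay group-balanced.
#' @param plate_shift_sd SD of the additive per-plate, per-metabolite shift on
#'   the log2 scale.
#' @param base_log2_mean Named per-class mean of log2 concentration (micromol).
#' @param base_log2_sd SD of the per-compound offset around its class mean.
#' @param marker_log2_mean,marker_log2_sd Generating mean/SD (log2 micromol)
#'   of the curated marker species (the field-named compounds that planted
#'   effects can target, e.g. Cer(42:1), CE(19:2)). Markers are minor,
#'   mid-abundance species: quantifiable in most samples yet carrying only a
#'   small share of the total lipid mass, so a planted fold-change does not
#'   propagate through the permille closure to other compounds.
#' @param residual_sd Per-cell residual SD on the log2 scale. 0.25 log2 units
#'   corresponds to a concentration CV of roughly 25 percent.
#' @param heterogeneity_sd SD of the per-sample log2 shift common to all
#'   compounds (inter-individual heterogeneity of total lipid load).
#' @param within_class_cor Optional within-class correlation of residuals in
#'   `[0, 1)`, induced by a shared per-sample, per-class factor.
#' @param loq_quantile Quantile of each compound's per-plate generating
#'   distribution at which the plate limit of quantitation is set, so
#'   below-LOQ missingness also arises mechanistically by truncation.
#' @param zero_missing_rate Below-LOQ injection probability. A scalar applies
#'   to every compound; a length-2 range assigns per-compound rates along the
#'   abundance rank (least abundant compound at the upper end), emulating
#'   detectability-driven censoring. The default `c(0, 0.80)` pushes roughly
#'   4 in 10 compounds - the low-abundance tail - over the 50 percent
#'   ceiling in some group, reproducing the split between quantifiable
#'   compounds and those analysed only as present/absent.
#' @param is_missing_rate Internal-standard failure probability; scalar or
#'   range, as above.
#' @param effects Tibble of planted effects (see [planted_effect()]); the
#'   default plants the ten screening-study fold-changes of
#'   [default_planted_effects()].
#' @param seed Integer seed; fully determines the generated panel.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_per_group = 81,
                              groups = c("HC", "LN", "LC"),
                              n_metabolites = 352,
                              class_proportions = default_class_counts / sum(default_class_counts),
                              n_plates = 3,
                              plate_shift_sd = 0.15,
                              base_log2_mean = default_class_log2_mean,
                              base_log2_sd = 0.8,
                              marker_log2_mean = 0,
                              marker_log2_sd = 0.5,
                              residual_sd = 0.25,
                              heterogeneity_sd = 0.35,
                              within_class_cor = 0,
                              loq_quantile = 0.025,
                              zero_missing_rate = c(0, 0.80),
                              is_missing_rate = c(0, 0.05),
                              effects = default_planted_effects(),
                              seed = 1L) {
  cfg_check(is.numeric(n_per_group) && n_per_group >= 2, "n_per_group", "need at least 2 samples per group")
  cfg_check(length(groups) >= 2 && !anyDuplicated(groups), "groups", "need >= 2 distinct labels")
  cfg_check(n_metabolites >= 1, "n_metabolites", "need >= 1 compound")
  cfg_check(!is.null(names(class_proportions)) &&
              all(names(class_proportions) %in% LIPID_CLASSES),
            "class_proportions", "names must be lipid classes")
  cfg_check(abs(sum(class_proportions) - 1) < 1e-6, "class_proportions", "must sum to 1")
  cfg_check(n_plates >= 1, "n_plates", "need >= 1 plate")
  cfg_check(plate_shift_sd >= 0, "plate_shift_sd", "must be >= 0")
  cfg_check(all(names(class_proportions) %in% names(base_log2_mean)),
            "base_log2_mean", "must name every used class")
  cfg_check(base_log2_sd >= 0, "base_log2_sd", "must be >= 0")
  cfg_check(marker_log2_sd >= 0, "marker_log2_sd", "must be >= 0")
  cfg_check(residual_sd > 0, "residual_sd", "must be > 0")
  cfg_check(heterogeneity_sd >= 0, "heterogeneity_sd", "must be >= 0")
  cfg_check(is.numeric(within_class_cor) && within_class_cor >= 0 && within_class_cor < 1,
            "within_class_cor", "must lie in [0, 1)")
  cfg_check(loq_quantile > 0 && loq_quantile < 1, "loq_quantile", "must lie in (0, 1)")
  cfg_check(rate_ok(zero_missing_rate), "zero_missing_rate", "must be a probability or an ordered range in [0, 1]")
  cfg_check(rate_ok(is_missing_rate), "is_missing_rate", "must be a probability or an ordered range in [0, 1]")
  if (is.null(effects)) {
    effects <- tibble(metabolite_id = character(), group = character(),
                      fold_change = numeric())
  }
  effects <- as_tibble(effects)
  if (nrow(effects)) {
    cfg_check(all(c("metabolite_id", "group", "fold_change") %in% names(effects)),
              "effects", "needs columns metabolite_id, group, fold_change")
    cfg_check(all(effects$fold_change > 0), "effects", "fold changes must be > 0")
    cfg_check(all(effects$group %in% groups), "effects", "affected group not among declared groups")
  }
  cfg_check(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed", "must be a single integer")
  structure(
    list(n_per_group = as.integer(n_per_group), groups = groups,
         n_metabolites = as.integer(n_metabolites),
         class_proportions = class_proportions, n_plates = as.integer(n_plates),
         plate_shift_sd = plate_shift_sd, base_log2_mean = base_log2_mean,
         base_log2_sd = base_log2_sd,
         marker_log2_mean = marker_log2_mean, marker_log2_sd = marker_log2_sd,
         residual_sd = residual_sd,
         heterogeneity_sd = heterogeneity_sd, within_class_cor = within_class_cor,
         loq_quantile = loq_quantile, zero_missing_rate = zero_missing_rate,
         is_missing_rate = is_missing_rate, effects = effects,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Configuration of the analysis pipeline
#'
#' Houses every numeric policy constant of the preprocessing, differential
#' and classification stages.
#'
#' @param zero_missing_ceiling Maximum allowed per-group fraction of below-LOQ
#'   values (tier 1 allows equality; the quantitative tier is strict).
#' @param is_missing_ceiling Maximum allowed per-group fraction of
#'   internal-standard failures.
#' @param knn_k Neighbour count for IS-failure imputation.
#' @param mrcv_repeats Repeats of the inner multiple random cross-validation.
#' @param outer_folds Outer cross-validation folds.
#' @param test_per_group Test samples drawn per group per outer fold.
#' @param teach_fraction Teaching share of each MRCV split.
#' @param delta_bic_stop Forward selection stops when the best candidate
#'   improves BIC by no more than this.
#' @param ci_level Confidence level for fold-aggregated metrics.
#' @param alpha Significance level for the differential screens.
#' @param max_candidates Cap on the number of candidate features offered to
#'   the forward search (applied as a Kruskal-Wallis prescreen on training
#'   samples only); `Inf` disables the cap.
#' @param ridge Tiny ridge penalty on slopes protecting the multinomial fit
#'   against perfect separation; excluded from the BIC parameter count.
#' @param protect_group Should batch correction preserve group differences via
#'   a group covariate in its location model?
#' @param seed Integer seed for every stochastic stage.
#'
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(zero_missing_ceiling = 0.50,
                            is_missing_ceiling = 0.10,
                            knn_k = 3,
                            mrcv_repeats = 100,
                            outer_folds = 8,
                            test_per_group = 8,
                            teach_fraction = 0.70,
                            delta_bic_stop = 2.0,
                            ci_level = 0.95,
                            alpha = 0.05,
                            max_candidates = Inf,
                            ridge = 1e-6,
                            protect_group = TRUE,
                            seed = 1L) {
  cfg_check(zero_missing_ceiling >= 0 && zero_missing_ceiling <= 1, "zero_missing_ceiling", "must lie in [0, 1]")
  cfg_check(is_missing_ceiling >= 0 && is_missing_ceiling <= 1, "is_missing_ceiling", "must lie in [0, 1]")
  cfg_check(knn_k >= 1, "knn_k", "must be >= 1")
  cfg_check(mrcv_repeats >= 1, "mrcv_repeats", "must be >= 1")
  cfg_check(outer_folds >= 2, "outer_folds", "must be >= 2")
  cfg_check(test_per_group >= 1, "test_per_group", "must be >= 1")
  cfg_check(teach_fraction > 0 && teach_fraction < 1, "teach_fraction", "must lie in (0, 1)")
  cfg_check(delta_bic_stop > 0, "delta_bic_stop", "must be > 0")
  cfg_check(ci_level > 0 && ci_level < 1, "ci_level", "must lie in (0, 1)")
  cfg_check(alpha > 0 && alpha < 1, "alpha", "must lie in (0, 1)")
  cfg_check(max_candidates >= 1, "max_candidates", "must be >= 1")
  cfg_check(ridge >= 0, "ridge", "must be >= 0")
  structure(
    list(zero_missing_ceiling = zero_missing_ceiling,
         is_missing_ceiling = is_missing_ceiling,
         knn_k = as.integer(knn_k), mrcv_repeats = as.integer(mrcv_repeats),
         outer_folds = as.integer(outer_folds),
         test_per_group = as.integer(test_per_group),
         teach_fraction = teach_fraction, delta_bic_stop = delta_bic_stop,
         ci_level = ci_level, alpha = alpha, max_candidates = max_candidates,
         ridge = ridge, protect_group = protect_group, seed = as.integer(seed)),
    class = "analysis_config"
  )
}
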