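# Ten samples per group in one plate, codes fully controlled per compound.
policy_panel <- function() {
  n <- 30
  groups <- rep(c("HC", "LN", "LC"), each = 10)
  codes <- matrix("OBSERVED", n, 4,
                  dimnames = list(NULL, c("A(1:0)", "B(1:0)", "C(1:0)", "D(1:0)")))
  codes[1:6, 1] <- "BELOW_LOQ"               # 60% zeros in HC -> tier-1 out
  codes[1:5, 2] <- "BELOW_LOQ"               # exactly 50% zeros in HC
  codes[11:13, 4] <- "IS_FAILURE"            # 30% IS failures in LN -> out
  conc <- matrix(1, n, 4, dimnames = dimnames(codes))
  conc[codes != "OBSERVED"] <- NA
  make_panel(conc, codes, groups, plates = rep("P1", n))
}

test_that("missingness policy separates the two tiers at the 50% boundary", {
  pol <- apply_missingness_policy(policy_panel())
  expect_setequal(pol$retained_all, c("B(1:0)", "C(1:0)"))
  expect_setequal(pol$retained_quant, "C(1:0)")   # 50% allowed but not quantitative
  expect_setequal(pol$excluded$metabolite_id, c("A(1:0)", "D(1:0)"))
  expect_equal(
    pol$excluded$rule[pol$excluded$metabolite_id == "A(1:0)"], "below_loq_fraction")
  expect_equal(
    pol$excluded$rule[pol$excluded$metabolite_id == "D(1:0)"], "is_failure_fraction")
  expect_true(all(pol$retained_quant %in% pol$retained_all))
  expect_equal(sort(c(pol$retained_all, pol$excluded$metabolite_id)),
               sort(policy_panel()$metabolites$metabolite_id))
  # fractions are per-group
  fr <- dplyr::filter(pol$fractions, metabolite_id == "A(1:0)", group == "HC")
  expect_equal(fr$frac_below_loq, 0.6)
})

test_that("below-LOQ imputation draws from the truncated normal on (0, LOQ)", {
  n <- 10000
  codes <- matrix("BELOW_LOQ", n, 1, dimnames = list(NULL, "A(1:0)"))
  conc <- matrix(NA_real_, n, 1, dimnames = dimnames(codes))
  p <- make_panel(conc, codes, groups = rep(c("HC", "LC"), each = n / 2),
                  plates = rep("P1", n), loq = 0.08)
  imp <- impute_below_loq(p, "A(1:0)", seed = 9L)
  v <- imp$conc[, 1]
  expect_true(all(v > 0 & v < 0.08))
  expect_true(all(imp$provenance == "zero_imputed"))
  # closed-form truncated-normal mean: symmetric truncation at +-2 sd -> L/2
  sd_trunc <- 0.02 * sqrt(1 - 4 * dnorm(2) / (pnorm(2) - pnorm(-2)))
  expect_lt(abs(mean(v) - 0.04), 3 * sd_trunc / sqrt(n))
  expect_identical(impute_below_loq(p, "A(1:0)", seed = 9L)$conc, imp$conc)
  expect_false(identical(impute_below_loq(p, "A(1:0)", seed = 10L)$conc, imp$conc))
})

test_that("kNN imputation averages the k nearest profiles by correlation distance", {
  # 8 samples, 13 metabolites; sample 1 misses m13. Candidates 2-4 are exact
  # scaled copies of sample 1's profile (correlation 1, distance 0); 5-7 are
  # scrambled (lower correlation); 8 lacks m13.
  m <- 13
  base <- seq(0.5, 3.5, length.out = m - 1)
  perm <- c(5, 3, 9, 1, 11, 7, 2, 12, 4, 10, 8, 6)  # fixed scramble
  conc <- rbind(
    c(base, NA),                     # sample 1: the cell to impute
    c(base * 1.1, 2),                # exact scaled copies: correlation 1
    c(base * 0.9, 4),
    c(base * 1.2, 6),
    c(base[perm], 50),               # scrambled: weak correlation
    c(base[rev(seq_len(m - 1))], 60),
    c(base[perm] * 2, 70),
    c(base * 1.3, NA)                # candidate without the metabolite
  )
  codes <- matrix("OBSERVED", 8, m)
  codes[1, m] <- "IS_FAILURE"
  codes[8, m] <- "IS_FAILURE"
  colnames(conc) <- colnames(codes) <- sprintf("PC(%d:0)", 20 + seq_len(m))
  conc[codes == "IS_FAILURE"] <- NA
  p <- make_panel(conc, codes, groups = rep("HC", 8), plates = rep("P1", 8))
  imp <- impute_knn(p, colnames(conc), k = 3)
  expect_equal(unname(imp$conc[1, m]), mean(c(2, 4, 6)))
  expect_equal(imp$provenance[1, m], "knn_imputed")
  expect_equal(unique(imp$knn_log$tier), "group_plate")
})

test_that("kNN fallback ladder widens the candidate pool and logs the tier", {
  # sample 1 (group HC, plate P1) has only one same-group/same-plate
  # candidate, so the ladder falls back to same group, any plate
  m <- 12
  base <- seq(1, 4, length.out = m)
  conc <- rbind(base, base * 1.1, base * 0.9,
                base * 1.05, base * 0.95, base * 1.2)
  codes <- matrix("OBSERVED", 6, m)
  codes[1, 1] <- "IS_FAILURE"
  colnames(conc) <- colnames(codes) <- sprintf("PC(%d:0)", 20 + seq_len(m))
  conc[1, 1] <- NA
  p <- make_panel(conc, codes, groups = c(rep("HC", 4), "LC", "LC"),
                  plates = c("P1", "P1", "P2", "P2", "P2", "P2"))
  imp <- impute_knn(p, colnames(conc), k = 3)
  expect_equal(imp$knn_log$tier, "group_any")
  expect_equal(unname(imp$conc[1, 1]), mean(conc[2:4, 1]))
})

test_that("kNN beats global-mean imputation in a masking experiment", {
  # kNN can only pay off when sample profiles genuinely correlate, so the
  # masking panel carries strong within-class correlation; error is scored on
  # the log2 scale, the conventional metric for multiplicative abundances
  cfg <- small_config(n_per_group = 25, n_metabolites = 60,
                      zero_missing_rate = 0, is_missing_rate = 0,
                      loq_quantile = 1e-12, heterogeneity_sd = 0.15,
                      within_class_cor = 0.85, effects = NULL, seed = 21L)
  p <- generate_panel(cfg)
  truth <- p$conc
  set.seed(77)
  mask <- which(matrix(runif(length(truth)) < 0.05, nrow(truth)))
  p$codes[mask] <- "IS_FAILURE"
  p$conc[mask] <- NA
  imp <- impute_knn(p, colnames(truth), k = 3)
  col_mean <- matrix(colMeans(p$conc, na.rm = TRUE), nrow(truth), ncol(truth),
                     byrow = TRUE)
  rmse <- function(x) sqrt(mean((log2(x[mask]) - log2(truth[mask]))^2))
  expect_lt(rmse(imp$conc), rmse(col_mean))
})

test_that("batch correction removes planted plate shifts and preserves group effects", {
  cfg <- small_config(n_per_group = 60, n_metabolites = 20, n_plates = 2,
                      zero_missing_rate = 0, is_missing_rate = 0,
                      loq_quantile = 1e-12, plate_shift_sd = 0,
                      residual_sd = 0.1, heterogeneity_sd = 0.1,
                      effects = NULL, seed = 31L)
  p <- generate_panel(cfg)
  plate_b <- p$samples$plate == "P2"
  p$conc[plate_b, ] <- p$conc[plate_b, ] * 2          # +1.0 log2 on plate B
  grp_lc <- p$samples$group == "LC"
  p$conc[grp_lc, 1] <- p$conc[grp_lc, 1] * 2^0.5      # orthogonal group effect
  pre_gap <- mean(log2(p$conc[grp_lc, 1])) - mean(log2(p$conc[!grp_lc, 1]))

  np <- log2_and_batch_correct(p, colnames(p$conc), protect_group = TRUE)
  plate_gap <- colMeans(np$log2bc[plate_b, ]) - colMeans(np$log2bc[!plate_b, ])
  expect_true(all(abs(plate_gap) < 0.05))
  expect_lt(abs(mean(plate_gap)), 0.02)
  post_gap <- mean(np$log2bc[grp_lc, 1]) - mean(np$log2bc[!grp_lc, 1])
  expect_lt(abs(post_gap / pre_gap - 1), 0.10)
})

test_that("single-plate panels pass through batch correction unchanged", {
  cfg <- small_config(n_per_group = 5, n_metabolites = 8, n_plates = 1,
                      zero_missing_rate = 0, is_missing_rate = 0,
                      loq_quantile = 1e-12, effects = NULL)
  p <- generate_panel(cfg)
  np <- log2_and_batch_correct(p, colnames(p$conc))
  expect_lt(max(abs(np$log2bc - log2(p$conc))), 1e-8)
})

test_that("permille normalization is a row-wise closure to 1000", {
  m <- matrix(c(2, 1, 1,   3, 1, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  pm <- normalize_permille(m)
  expect_equal(rowSums(pm), c(s1 = 1000, s2 = 1000), tolerance = 1e-9)
  expect_equal(unname(pm["s1", "a"]), 500)               # half the total
  expect_equal(unname(pm["s2", c("a", "b")]), c(750, 250))  # 3:1 of total 4
  expect_equal(normalize_permille(m * 2), pm)            # scale invariance
  m_bad <- rbind(m, s3 = c(0, 0, 0))
  expect_error(normalize_permille(m_bad), "s3",
               class = "sevlip_normalization_error")
})

test_that("class aggregation reproduces designed composition", {
  conc <- matrix(c(2, 0.5, 0.5), 4, 3, byrow = TRUE,
                 dimnames = list(NULL, c("CE(18:2)", "PC(34:1)", "PC(36:2)")))
  codes <- matrix("OBSERVED", 4, 3, dimnames = dimnames(conc))
  p <- make_panel(conc, codes, groups = rep(c("HC", "LC"), 2),
                  plates = rep("P1", 4), classes = c("CE", "PC", "PC"))
  np <- log2_and_batch_correct(p, colnames(conc))
  agg <- aggregate_classes(np)
  ce <- dplyr::filter(agg, class == "CE")
  expect_equal(ce$share_pct, rep(200 / 3, 4))            # CE built as 2/3 of mass
  by_sample <- dplyr::summarise(dplyr::group_by(agg, sample_id),
                                s = sum(share_pct))
  expect_equal(by_sample$s, rep(100, 4))
  # single-class panel: class total equals the sample total
  p1 <- make_panel(conc[, 1, drop = FALSE],
                   codes[, 1, drop = FALSE], groups = rep(c("HC", "LC"), 2),
                   plates = rep("P1", 4), classes = "CE")
  agg1 <- aggregate_classes(log2_and_batch_correct(p1, "CE(18:2)"))
  expect_equal(agg1$total, rowSums(conc[, 1, drop = FALSE]))
})

test_that("the full preprocessing chain is bit-reproducible and conserves shape", {
  cfg <- small_config(seed = 13L)
  ac <- analysis_config(seed = 13L)
  p <- generate_panel(cfg)
  np1 <- preprocess_panel(p, ac)
  np2 <- preprocess_panel(generate_panel(cfg), ac)
  expect_identical(np1$conc, np2$conc)
  expect_identical(np1$log2bc, np2$log2bc)
  expect_identical(np1$permille, np2$permille)
  expect_equal(nrow(np1$log2bc), nrow(p$conc))
  expect_false(anyNA(np1$conc))
  expect_true(all(rowSums(np1$permille) - 1000 < 1e-9))
  expect_setequal(unique(as.vector(np1$provenance)),
                  intersect(c("observed", "zero_imputed", "knn_imputed"),
                            unique(as.vector(np1$provenance))))
})

test_that("the full chain introduces no anti-conservative artifact on null panels", {
  p <- null_panel(simulation_config(seed = 99L))
  np <- preprocess_panel(p, analysis_config(seed = 99L))
  kw <- kruskal_wallis_screen(np)
  frac <- mean(kw$p_value < 0.05)
  m <- nrow(kw)
  expect_lt(frac, 0.05 + 4 * sqrt(0.05 * 0.95 / m))
})
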