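# 12 x 2 feature fixture used for the cross-check against independent GLM
# implementations (values printed here, nothing stored).
mlr_fixture <- function() {
  x <- cbind(f1 = c(0.2, 1.1, -0.4, 2.3, 0.9, -1.2, 1.8, 0.1, -0.7, 2.0, 1.4, -0.3),
             f2 = c(1.0, -0.5, 0.8, 1.9, -1.1, 0.4, 2.2, -0.9, 1.3, 0.6, -0.2, 1.7))
  y2 <- factor(c("a", "a", "a", "b", "b", "a", "b", "a", "a", "b", "b", "b"))
  y3 <- factor(c("a", "b", "c", "b", "b", "a", "c", "a", "a", "c", "b", "c"))
  list(x = x, y2 = y2, y3 = y3)
}

test_that("intercept-only fits give symmetric probabilities and BIC bookkeeping", {
  y <- factor(rep(c("HC", "LN", "LC"), each = 10), levels = c("HC", "LN", "LC"))
  x <- matrix(numeric(0), 30, 0)
  m <- fit_mlr(x, y)
  P <- predict(m, matrix(numeric(0), 5, 0))
  expect_equal(unname(P), matrix(1 / 3, 5, 3), tolerance = 1e-8)
  expect_equal(m$loglik, 30 * log(1 / 3), tolerance = 1e-8)
  expect_equal(m$bic, -2 * m$loglik + 2 * log(30), tolerance = 1e-8)
  # MAP ties resolve to the first declared class
  expect_equal(as.character(map_classify(m, matrix(numeric(0), 3, 0))),
               rep("HC", 3))
})

test_that("binary log-likelihood and BIC match glm to 1e-6", {
  fx <- mlr_fixture()
  m <- fit_mlr(fx$x, fx$y2, ridge = 0)
  g <- glm(fx$y2 ~ fx$x, family = binomial())
  expect_equal(m$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
  expect_equal(m$bic, BIC(g), tolerance = 1e-6)
  expect_equal(unname(m$coef[, 1]), unname(coef(g)), tolerance = 1e-4)
})

test_that("three-class log-likelihood matches an independent multinomial fit to 1e-6", {
  skip_if_not_installed("nnet")
  fx <- mlr_fixture()
  m <- fit_mlr(fx$x, fx$y3, ridge = 0)
  nn <- nnet::multinom(fx$y3 ~ fx$x, trace = FALSE, reltol = 1e-14)
  expect_equal(-2 * m$loglik, nn$deviance, tolerance = 1e-6)
})

test_that("degenerate fits are rejected or flagged appropriately", {
  fx <- mlr_fixture()
  # collinear columns are named
  x_bad <- cbind(fx$x, f3 = fx$x[, 1] * 2)
  expect_error(fit_mlr(x_bad, fx$y2), "f3", class = "sevlip_model_error")
  expect_error(fit_mlr(fx$x[c(1, 4, 2), ], fx$y2[c(1, 4, 2)]), "n > p",
               class = "sevlip_model_error")
  expect_error(fit_mlr(fx$x, factor(rep("a", 12))), "2 classes",
               class = "sevlip_model_error")
  # perfect separation stays finite under the ridge and is flagged
  x_sep <- cbind(f = c(-(5:1), 1:5))
  y_sep <- factor(rep(c("a", "b"), each = 5))
  m <- fit_mlr(x_sep, y_sep)
  expect_true(all(is.finite(m$coef)))
  expect_equal(m$flag, "possible_separation")
  expect_equal(mean(map_classify(m, x_sep) == y_sep), 1)
  expect_error(predict(m, matrix(1, 2, 1, dimnames = list(NULL, "other"))),
               "missing", class = "sevlip_model_error")
})

test_that("forward selection respects the delta-BIC stop rule", {
  set.seed(4)
  n <- 90
  y <- factor(rep(c("HC", "LN", "LC"), each = 30), levels = c("HC", "LN", "LC"))
  x <- matrix(rnorm(n * 21), n, 21,
              dimnames = list(NULL, sprintf("f%02d", 1:21)))
  x[, "f11"] <- x[, "f11"] + 2 * (as.integer(y) - 2)  # strong 3-class signal
  sel <- forward_select(x, y, delta_bic_stop = 2)
  expect_equal(sel$features[1], "f11")
  # an infinite stop criterion binds immediately
  sel0 <- forward_select(x, y, delta_bic_stop = Inf)
  expect_equal(length(sel0$features), 0)
  expect_equal(sel0$n_params, 2)
})

test_that("MRCV is reproducible, sized correctly, and chance-level on noise", {
  set.seed(10)
  n <- 60
  y <- factor(rep(c("HC", "LN", "LC"), each = 20))
  x <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, sprintf("f%d", 1:10)))
  one <- mrcv(x, y, repeats = 1, seed = 2L)
  expect_length(one$models, 1)
  a <- mrcv(x, y, repeats = 20, seed = 3L)
  b <- mrcv(x, y, repeats = 20, seed = 3L)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(lapply(a$models, `[[`, "features"),
                   lapply(b$models, `[[`, "features"))
  # pure-noise features: near-chance test accuracy, rare selection
  expect_lt(abs(mean(a$accuracy$test_accuracy) - 1 / 3), 0.10)
  freq <- rank_features(a)$ranking$frequency
  expect_true(length(freq) == 0 || max(freq) < 0.5)
})

test_that("feature ranking and elbow extraction follow frequency drops", {
  fake <- function(features) structure(list(features = features),
                                       class = "signature_model")
  models <- c(
    replicate(35, fake(c("a", "b", "c")), simplify = FALSE),
    replicate(60, fake(c("a", "b", "c", "d")), simplify = FALSE),
    replicate(3, fake(c("a", "b", "e")), simplify = FALSE),
    replicate(2, fake(c("a", "e")), simplify = FALSE)
  )
  # frequencies: a 1.00, b 0.98, c 0.95, d 0.60, e 0.05
  rk <- rank_features(models)
  expect_equal(rk$ranking$feature[1:3], c("a", "b", "c"))
  expect_equal(rk$ranking$frequency[1:5], c(1, 0.98, 0.95, 0.60, 0.05))
  expect_equal(rk$elbow, 4L)  # largest drop (0.55) sits after position 4
  expect_equal(rk$final, c("a", "b", "c", "d"))
  # a feature selected first in every model ranks first
  expect_equal(rk$ranking$feature[1], "a")
  expect_equal(rk$ranking$mean_order[1], 1)
  # all-empty collections are flagged
  empty <- rank_features(list(fake(character()), fake(character())))
  expect_equal(empty$flag, "all_models_empty")
  expect_length(empty$final, 0)
})

test_that("a stepped frequency pattern cuts after the largest consecutive drop", {
  fake <- function(features) structure(list(features = features),
                                       class = "signature_model")
  # frequencies 1.00, 0.98, 0.95, 0.40, 0.35 over 100 models
  models <- lapply(seq_len(100), function(i) {
    f <- c("a", if (i <= 98) "b", if (i <= 95) "c", if (i <= 40) "d",
           if (i <= 35) "e")
    fake(f)
  })
  rk <- rank_features(models)
  expect_equal(rk$ranking$frequency, c(1, 0.98, 0.95, 0.40, 0.35))
  expect_equal(rk$elbow, 3L)
  expect_equal(rk$final, c("a", "b", "c"))
})

test_that("Youden threshold maximizes J and lands mid-interval on ties", {
  th <- youden_threshold(c(0.1, 0.2, 0.8, 0.9),
                         factor(c("n", "n", "p", "p"), levels = c("n", "p")))
  expect_gt(th, 0.2); expect_lt(th, 0.8)
  # brute-force oracle over a dense cut-point grid
  set.seed(6)
  scores <- round(runif(40), 2)
  labs <- factor(ifelse(runif(40) < plogis(4 * (scores - 0.5)), "p", "n"),
                 levels = c("n", "p"))
  skip_if(nlevels(droplevels(labs)) < 2)
  th <- youden_threshold(scores, labs)
  jfun <- function(t) mean(scores[labs == "p"] >= t) +
    mean(scores[labs == "n"] < t) - 1
  grid <- sort(unique(c(scores - 1e-6, scores + 1e-6, th)))
  expect_equal(jfun(th), max(vapply(grid, jfun, numeric(1))), tolerance = 1e-12)
  expect_error(youden_threshold(runif(5), factor(rep("p", 5))),
               class = "sevlip_model_error")
})

test_that("evaluation metrics follow the confusion matrix and ROC definitions", {
  # hand-built model: prob of class B = plogis(10 f)
  m <- structure(list(features = "f", classes = c("A", "B"),
                      coef = matrix(c(0, 10), 2, 1,
                                    dimnames = list(c("(Intercept)", "f"), "B")),
                      loglik = 0, bic = 0, n = 16, n_params = 2, ridge = 0,
                      threshold = NULL, flag = NA_character_),
                 class = "signature_model")
  x <- matrix(c(rep(-1, 8), rep(-1, 4), rep(1, 4)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- factor(rep(c("A", "B"), each = 8), levels = c("A", "B"))
  ev <- evaluate_model(m, x, y)
  expect_equal(ev$accuracy, 12 / 16)
  expect_equal(ev$sens_B, 0.5)
  expect_equal(ev$spec_B, 1.0)
  expect_equal(ev$sens_A, 1.0)
  expect_equal(ev$spec_A, 0.5)

  # perfect separation: accuracy and AUC 1
  x2 <- matrix(c(-(8:1) / 8, (1:8) / 8), ncol = 1, dimnames = list(NULL, "f"))
  m2 <- fit_mlr(x2, y)
  ev2 <- evaluate_model(m2, x2, y)
  expect_equal(ev2$accuracy, 1)
  expect_equal(ev2$auc, 1)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- runif(60)
  y <- factor(ifelse(runif(60) < plogis(3 * (scores - 0.5)), "p", "n"),
              levels = c("n", "p"))
  mine <- sevlip:::auc_rank(scores, y == "p")
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, scores,
                                                         levels = c("n", "p"),
                                                         direction = "<"))))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("label-independent scores give chance AUC", {
  set.seed(13)
  n <- 2000
  scores <- runif(n)
  pos <- runif(n) < 0.5
  a <- sevlip:::auc_rank(scores, pos)
  se <- sqrt((sum(pos) + sum(!pos) + 1) / (12 * sum(pos) * sum(!pos)))
  expect_lt(abs(a - 0.5), 3 * se)
})

test_that("outer cross-validation is deterministic and internally consistent", {
  cfg <- small_config(n_per_group = 16, n_metabolites = 24, seed = 17L,
                      effects = planted_effect("Cer(42:1)", "LC", 1.8))
  p <- generate_panel(cfg)
  ac <- analysis_config(seed = 17L, mrcv_repeats = 4, outer_folds = 4,
                        test_per_group = 4, max_candidates = 10)
  np <- preprocess_panel(p, ac)
  cv1 <- outer_cv(np, config = ac)
  cv2 <- outer_cv(np, config = ac)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$final_model$features, cv2$final_model$features)
  expect_identical(cv1$summary, cv2$summary)

  metr <- dplyr::select(cv1$folds, dplyr::where(is.numeric), -fold)
  expect_true(all(metr >= 0 & metr <= 1, na.rm = TRUE))
  s <- cv1$summary
  expect_true(all(s$ci_lo <= s$mean + 1e-12 & s$mean <= s$ci_hi + 1e-12))
  expect_length(cv1$fold_signatures, 4)
  expect_true(all(cv1$fold_selection$n_folds >= 1 &
                    cv1$fold_selection$n_folds <= 4))
})

test_that("binary outer CV attaches a Youden threshold to its models", {
  cfg <- small_config(n_per_group = 16, n_metabolites = 16,
                      groups = c("HC", "LC"), seed = 19L,
                      effects = planted_effect("Cer(42:1)", "LC", 2))
  p <- generate_panel(cfg)
  ac <- analysis_config(seed = 19L, mrcv_repeats = 4, outer_folds = 3,
                        test_per_group = 4, max_candidates = 8)
  np <- preprocess_panel(p, ac)
  cv <- outer_cv(np, config = ac)
  expect_true(is.numeric(cv$final_model$threshold))
  expect_gt(cv$final_model$threshold, 0)
  expect_lt(cv$final_model$threshold, 1)
})

test_that("tidiers expose models and reports as tibbles", {
  fx <- mlr_fixture()
  m <- fit_mlr(fx$x, fx$y3)
  td <- tidy(m)
  expect_equal(nrow(td), 6)  # (2 features + intercept) x 2 contrasts
  gl <- glance(m)
  expect_equal(gl$BIC, m$bic)
  expect_equal(gl$n_features, 2)
})
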