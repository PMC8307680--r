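# Outer cross-validation of the signature procedure, classification metrics
# and the Youden-thresholded decision rule for binary models.

# Rank-based AUC (equals the trapezoidal area under the ROC curve, with ties
# handled by the midrank convention).
auc_rank <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Macro-averaged one-vs-rest AUC for >= 3 classes.
auc_macro <- function(P, y) {
  vals <- vapply(colnames(P), function(cl) auc_rank(P[, cl], y == cl), numeric(1))
  mean(vals)
}

#' Youden-optimal decision threshold
#'
#' Over all ROC cut-points of the positive-class scores (classify positive
#' when `score >= t`), returns the threshold maximizing Youden's
#' `J = sensitivity + specificity - 1`. When several cut-points tie, the
#' midpoint of the tied interval is returned.
#'
#' @param scores Predicted positive-class probabilities.
#' @param labels Binary labels; the factor's second level (or `positive`) is
#'   the positive class.
#' @param positive Positive class label.
#' @return The threshold (a single number).
#' @export
youden_threshold <- function(scores, labels, positive = NULL) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) {
    abort("Youden threshold needs exactly two classes present.",
          class = "sevlip_model_error")
  }
  positive <- positive %||% levels(labels)[2]
  pos <- labels == positive
  s <- sort(unique(scores))
  cand <- if (length(s) == 1L) s else
    c(s[1] - 1e-9, (s[-length(s)] + s[-1]) / 2, s[length(s)] + 1e-9)
  j <- vapply(cand, function(t) {
    sens <- mean(scores[pos] >= t)
    spec <- mean(scores[!pos] < t)
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  mean(range(cand[best]))
}

#' Classification metrics for a fitted signature model
#'
#' Overall accuracy under maximum-a-posteriori classification (or, for a
#' binary model carrying a Youden threshold, under the thresholded rule),
#' AUC (rank/trapezoidal for two classes, macro-averaged one-vs-rest for
#' three or more), and per-class sensitivity and specificity from the
#' confusion matrix. A single-class evaluation set yields `NA` AUC.
#'
#' @param model A `signature_model`.
#' @param features Samples x features matrix.
#' @param labels True class labels.
#' @return A one-row tibble: `accuracy`, `auc`, then `sens_<class>` and
#'   `spec_<class>` per class.
#' @export
evaluate_model <- function(model, features, labels) {
  labels <- factor(labels, levels = model$classes)
  P <- predict(model, features)
  K <- length(model$classes)
  if (K == 2 && !is.null(model$threshold)) {
    pos <- model$classes[2]
    pred <- factor(ifelse(P[, pos] >= model$threshold, pos, model$classes[1]),
                   levels = model$classes)
  } else {
    pred <- map_classify(model, features)
  }
  acc <- mean(pred == labels)
  auc <- if (nlevels(droplevels(labels)) < 2) NA_real_
         else if (K == 2) auc_rank(P[, model$classes[2]], labels == model$classes[2])
         else auc_macro(P, labels)
  out <- tibble(accuracy = acc, auc = auc)
  for (cl in model$classes) {
    is_cl <- labels == cl
    out[[paste0("sens_", cl)]] <- if (any(is_cl)) mean(pred[is_cl] == cl) else NA_real_
    out[[paste0("spec_", cl)]] <- if (any(!is_cl)) mean(pred[!is_cl] != cl) else NA_real_
  }
  out
}

kw_prescreen <- function(x, y, max_candidates) {
  if (!is.finite(max_candidates) || ncol(x) <= max_candidates) {
    return(colnames(x))
  }
  p <- vapply(seq_len(ncol(x)), function(j) {
    if (length(unique(x[, j])) == 1L) return(1)
    kruskal.test(x[, j], y)$p.value
  }, numeric(1))
  colnames(x)[order(p, seq_along(p))[seq_len(max_candidates)]]
}

ci_t <- function(v, level) {
  v <- v[!is.na(v)]
  m <- mean(v)
  if (length(v) < 2) return(c(mean = m, lo = m, hi = m))
  half <- qt(1 - (1 - level) / 2, df = length(v) - 1) * sd(v) / sqrt(length(v))
  c(mean = m, lo = m - half, hi = m + half)
}

#' Nested cross-validation of the signature procedure
#'
#' The outer loop draws `test_per_group` samples per group per fold, without
#' replacement and non-overlapping across folds, as the outer test sets
#' (with 81 per group and 8 folds of 8, 17 samples per group are never
#' tested but remain in every training set). On each fold's training
#' remainder the inner [mrcv()] loop runs forward-BIC selection, the fold's
#' models are ranked and cut at the elbow, the fold model is refitted on the
#' whole training remainder with the elbow set (binary models additionally
#' get a Youden threshold from the training scores), and training and test
#' metrics are recorded. Fold metrics are aggregated as means with
#' t-distribution confidence intervals. A summary ranking over all folds'
#' model collections yields the final model, fitted on all samples.
#'
#' @param values Samples x features matrix on the permille scale, or a
#'   `normalized_panel` (its permille matrix is used).
#' @param groups Class labels (ignored when `values` is a panel).
#' @param config An [analysis_config()].
#' @param seed Seed (defaults to the config's).
#' @return A `cv_report`: per-fold metrics, aggregated summary with CIs,
#'   per-fold signatures and their size range, the pooled feature ranking
#'   with elbow, per-feature fold-selection counts, and the final model.
#' @export
outer_cv <- function(values, groups = NULL, config = analysis_config(),
                     seed = config$seed) {
  if (inherits(values, "normalized_panel")) {
    groups <- groups %||% values$samples$group
    values <- values$permille %||%
      abort("Panel has no permille matrix; run normalize_permille().",
            class = "sevlip_model_error")
  }
  x <- as.matrix(values)
  y <- droplevels(as.factor(groups))
  folds <- config$outer_folds
  tpg <- config$test_per_group
  min_n <- min(tabulate(y))
  if (folds * tpg > min_n) {
    tpg <- floor(min_n / folds)
    if (tpg < 1) {
      abort("Too few samples per group for the requested outer folds.",
            class = "sevlip_model_error")
    }
    warn(sprintf("test_per_group reduced to %d to fit the smallest group.", tpg))
  }

  with_rng(seed, {
    fold_of <- rep(NA_integer_, length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl), folds * tpg)
      fold_of[idx] <- rep(seq_len(folds), each = tpg)
    }

    fold_rows <- list(); fold_models <- list(); all_models <- list()
    fold_sets <- list()
    for (f in seq_len(folds)) {
      test <- which(fold_of == f)
      train <- setdiff(seq_along(y), test)
      if (nlevels(droplevels(y[train])) < nlevels(y)) {
        abort(sprintf("Fold %d lost a class from its training remainder.", f),
              class = "sevlip_model_error")
      }
      cand <- kw_prescreen(x[train, , drop = FALSE], y[train], config$max_candidates)
      mr <- mrcv(x[train, cand, drop = FALSE], y[train],
                 repeats = config$mrcv_repeats,
                 teach_fraction = config$teach_fraction,
                 delta_bic_stop = config$delta_bic_stop,
                 ridge = config$ridge, seed = NULL)
      rk <- rank_features(mr)
      sig <- rk$final
      model <- fit_mlr(x[train, sig, drop = FALSE], y[train], ridge = config$ridge)
      if (nlevels(y) == 2) {
        P_tr <- predict(model, x[train, , drop = FALSE])
        model$threshold <- youden_threshold(P_tr[, levels(y)[2]], y[train])
      }
      all_models <- c(all_models, mr$models)
      fold_models[[f]] <- model
      fold_sets[[f]] <- sig
      fold_rows[[f]] <- bind_rows(
        mutate(evaluate_model(model, x[train, , drop = FALSE], y[train]),
               fold = f, set = "training", .before = 1),
        mutate(evaluate_model(model, x[test, , drop = FALSE], y[test]),
               fold = f, set = "test", .before = 1)
      )
    }

    folds_tbl <- bind_rows(fold_rows)
    metrics <- setdiff(names(folds_tbl), c("fold", "set"))
    summary_tbl <- folds_tbl |>
      tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric") |>
      group_by(.data$set, .data$metric) |>
      summarise(res = list(ci_t(.data$value, config$ci_level)), .groups = "drop") |>
      mutate(mean = vapply(.data$res, `[[`, numeric(1), "mean"),
             ci_lo = vapply(.data$res, `[[`, numeric(1), "lo"),
             ci_hi = vapply(.data$res, `[[`, numeric(1), "hi")) |>
      select(-"res")

    pooled <- rank_features(all_models)
    final_sig <- pooled$final
    final_model <- fit_mlr(x[, final_sig, drop = FALSE], y, ridge = config$ridge)
    if (nlevels(y) == 2) {
      P_all <- predict(final_model, x)
      final_model$threshold <- youden_threshold(P_all[, levels(y)[2]], y)
    }
    sel_counts <- table(unlist(lapply(fold_sets, unique)))
    structure(
      list(folds = folds_tbl, summary = summary_tbl,
           fold_signatures = fold_sets,
           signature_sizes = range(lengths(fold_sets)),
           fold_selection = tibble(feature = names(sel_counts),
                                   n_folds = as.integer(sel_counts)) |>
             arrange(desc(.data$n_folds), .data$feature),
           ranking = pooled, final_model = final_model,
           fold_models = fold_models,
           classes = levels(y), n_folds = folds, test_per_group = tpg),
      class = "cv_report"
    )
  })
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d outer folds, %d test samples/group, classes: %s\n",
              x$n_folds, x$test_per_group, paste(x$classes, collapse = ", ")))
  acc <- filter(x$summary, .data$metric %in% c("accuracy", "auc"))
  for (i in seq_len(nrow(acc))) {
    cat(sprintf("  %s %s: %.3f (%.3f-%.3f)\n", acc$set[i], acc$metric[i],
                acc$mean[i], acc$ci_lo[i], acc$ci_hi[i]))
  }
  cat(sprintf("  fold signature sizes %d-%d; final model %d features\n",
              x$signature_sizes[1], x$signature_sizes[2],
              length(x$final_model$features)))
  invisible(x)
}
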