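# broom-style tidiers for the fitted objects.

#' Tidy a signature model
#'
#' One row per coefficient: the contrasted class (relative to the baseline
#' class), the term (intercept or feature) and the estimate on the log-odds
#' scale.
#'
#' @param x A `signature_model`.
#' @param ... Unused.
#' @return A tibble with columns `class`, `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.signature_model <- function(x, ...) {
  tibble(
    class = rep(colnames(x$coef), each = nrow(x$coef)),
    term = rep(rownames(x$coef), times = ncol(x$coef)),
    estimate = as.vector(x$coef)
  )
}

#' @rdname tidy.signature_model
#' @exportS3Method generics::glance
glance.signature_model <- function(x, ...) {
  tibble(n = x$n, n_features = length(x$features), n_classes = length(x$classes),
         logLik = x$loglik, BIC = x$bic, df = x$n_params,
         threshold = x$threshold %||% NA_real_)
}

#' Tidy a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return The fold-aggregated metric table (`set`, `metric`, `mean`,
#'   `ci_lo`, `ci_hi`).
#' @exportS3Method generics::tidy
tidy.cv_report <- function(x, ...) x$summary

#' @rdname tidy.cv_report
#' @exportS3Method generics::glance
glance.cv_report <- function(x, ...) {
  get <- function(set, metric) {
    r <- filter(x$summary, .data$set == !!set, .data$metric == !!metric)
    if (nrow(r)) r$mean else NA_real_
  }
  tibble(n_folds = x$n_folds, test_per_group = x$test_per_group,
         train_accuracy = get("training", "accuracy"),
         test_accuracy = get("test", "accuracy"),
         train_auc = get("training", "auc"),
         test_auc = get("test", "auc"),
         final_size = length(x$final_model$features))
}

#' Tidy a feature ranking
#'
#' @param x A `feature_ranking`.
#' @param ... Unused.
#' @return The ranking tibble with an `in_final` flag marking the elbow set.
#' @exportS3Method generics::tidy
tidy.feature_ranking <- function(x, ...) {
  mutate(x$ranking, in_final = .data$rank <= x$elbow)
}

#' Tidy a missingness-policy result
#'
#' @param x A `missingness_policy`.
#' @param ... Unused.
#' @return Per compound x group missing fractions with the tier outcome.
#' @exportS3Method generics::tidy
tidy.missingness_policy <- function(x, ...) {
  mutate(x$fractions,
         tier = dplyr::case_when(
           .data$metabolite_id %in% x$retained_quant ~ "quantitative",
           .data$metabolite_id %in% x$retained_all ~ "retained",
           TRUE ~ "excluded"))
}
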