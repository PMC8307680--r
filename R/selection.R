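# Forward-BIC feature selection and the inner multiple random
# cross-validation (MRCV) loop that stabilizes it.

#' Greedy forward feature selection by BIC
#'
#' Starting from the intercept-only model, each step fits every remaining
#' candidate added to the current set and takes the candidate with the lowest
#' BIC, accepting it only if it improves the current BIC by more than
#' `delta_bic_stop`; otherwise the search stops. Ties are broken by feature
#' (column) order. Candidates whose fit fails (e.g. collinear with the
#' current set) are skipped and recorded.
#'
#' @param x Samples x candidate-features matrix with column names.
#' @param y Class labels (factor).
#' @param delta_bic_stop Minimal BIC improvement to accept a candidate
#'   (default 2); `Inf` returns the intercept-only model.
#' @param ridge Ridge passed to [fit_mlr()].
#' @param max_features Optional hard cap on the selected set size.
#' @return A `signature_model` whose `features` are in addition order; the
#'   attribute `"skipped"` lists candidates whose fits failed.
#' @export
forward_select <- function(x, y, delta_bic_stop = 2, ridge = 1e-6,
                           max_features = Inf) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (ncol(x) < 1) abort("Need >= 1 candidate feature.", class = "sevlip_model_error")
  y <- droplevels(as.factor(y))
  current <- character()
  model <- fit_mlr(x[, current, drop = FALSE], y, ridge = ridge)
  remaining <- colnames(x)
  skipped <- character()
  while (length(remaining) && length(current) < max_features &&
         nrow(x) > length(current) + 3) {
    best_bic <- Inf; best_j <- NA_character_; best_model <- NULL
    for (j in remaining) {
      cand <- tryCatch(
        fit_mlr(x[, c(current, j), drop = FALSE], y, ridge = ridge),
        error = function(e) NULL
      )
      if (is.null(cand)) { skipped <- c(skipped, j); next }
      if (cand$bic < best_bic) {
        best_bic <- cand$bic; best_j <- j; best_model <- cand
      }
    }
    remaining <- setdiff(remaining, skipped)
    if (is.na(best_j) || !(model$bic - best_bic > delta_bic_stop)) break
    current <- c(current, best_j)
    model <- best_model
    remaining <- setdiff(remaining, best_j)
  }
  attr(model, "skipped") <- unique(skipped)
  model
}

stratified_split <- function(y, teach_fraction) {
  teach <- integer()
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < 2) {
      abort(sprintf("Class '%s' too small to stratify a teaching/testing split.", cl),
            class = "sevlip_model_error")
    }
    n_teach <- min(max(round(teach_fraction * length(idx)), 1L), length(idx) - 1L)
    teach <- c(teach, sample(idx, n_teach))
  }
  sort(teach)
}

map_accuracy <- function(model, x, y) {
  mean(map_classify(model, x) == y)
}

#' Multiple random cross-validation (MRCV)
#'
#' Repeats a stratified teaching/testing split (default 70/30) `repeats`
#' times; on each teaching subset a forward-BIC selection is run and the
#' resulting model's maximum-a-posteriori accuracy is evaluated on both
#' subsets. The model collection feeds [rank_features()].
#'
#' @param x Samples x candidate-features matrix.
#' @param y Class labels (all classes must be represented).
#' @param repeats Number of random splits (default 100).
#' @param teach_fraction Teaching share (default 0.7).
#' @param delta_bic_stop,ridge Passed to [forward_select()].
#' @param seed Integer seed; `NULL` continues the caller's RNG stream (used
#'   when nested inside [outer_cv()]).
#' @return An `mrcv_result`: `models` (list of `signature_model`) and
#'   `accuracy` (tibble with per-repeat teaching/testing accuracy and
#'   selected-set size).
#' @export
mrcv <- function(x, y, repeats = 100, teach_fraction = 0.7,
                 delta_bic_stop = 2, ridge = 1e-6, seed = NULL) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  run <- function() {
    models <- vector("list", repeats)
    acc <- matrix(NA_real_, repeats, 3)
    for (r in seq_len(repeats)) {
      teach <- stratified_split(y, teach_fraction)
      test <- setdiff(seq_along(y), teach)
      m <- forward_select(x[teach, , drop = FALSE], y[teach],
                          delta_bic_stop = delta_bic_stop, ridge = ridge)
      models[[r]] <- m
      acc[r, ] <- c(map_accuracy(m, x[teach, , drop = FALSE], y[teach]),
                    map_accuracy(m, x[test, , drop = FALSE], y[test]),
                    length(m$features))
    }
    structure(
      list(models = models,
           accuracy = tibble(repeat_id = seq_len(repeats),
                             teach_accuracy = acc[, 1],
                             test_accuracy = acc[, 2],
                             n_features = as.integer(acc[, 3]))),
      class = "mrcv_result"
    )
  }
  if (is.null(seed)) run() else with_rng(seed, run())
}

#' Rank features across an MRCV model collection
#'
#' Each feature's selection frequency and mean addition order are computed
#' across the collection; features are ranked by frequency (descending), then
#' mean order (ascending), then id. The elbow cutoff sits at the largest
#' consecutive drop in frequency along the ranked list (first such drop on
#' ties), and the final set is everything above the cutoff.
#'
#' @param models A list of `signature_model`s or an `mrcv_result`.
#' @return A `feature_ranking`: `ranking` tibble (`feature`, `frequency`,
#'   `mean_order`, `rank`), `elbow` index, `final` feature set, `flag`.
#' @export
rank_features <- function(models) {
  if (inherits(models, "mrcv_result")) models <- models$models
  if (!length(models)) abort("Need >= 1 model.", class = "sevlip_model_error")
  n_models <- length(models)
  feats <- lapply(models, function(m) m$features)
  all_feats <- unique(unlist(feats))
  if (!length(all_feats)) {
    return(structure(list(ranking = tibble(feature = character(),
                                           frequency = numeric(),
                                           mean_order = numeric(),
                                           rank = integer()),
                          elbow = 0L, final = character(),
                          flag = "all_models_empty"),
                     class = "feature_ranking"))
  }
  freq <- unname(vapply(all_feats, function(f) {
    mean(vapply(feats, function(v) f %in% v, logical(1)))
  }, numeric(1)))
  mean_order <- unname(vapply(all_feats, function(f) {
    pos <- unlist(lapply(feats, function(v) which(v == f)))
    mean(pos)
  }, numeric(1)))
  ranking <- tibble(feature = all_feats, frequency = freq, mean_order = mean_order) |>
    arrange(desc(.data$frequency), .data$mean_order, .data$feature) |>
    mutate(rank = row_number())
  fr <- ranking$frequency
  elbow <- if (nrow(ranking) == 1L) 1L else which.max(fr[-length(fr)] - fr[-1])
  structure(
    list(ranking = ranking, elbow = as.integer(elbow),
         final = ranking$feature[seq_len(elbow)], flag = NA_character_),
    class = "feature_ranking"
  )
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %d features ranked, elbow at %d\n",
              nrow(x$ranking), x$elbow))
  if (length(x$final)) cat("  final set: ", paste(x$final, collapse = ", "), "\n", sep = "")
  invisible(x)
}
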