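# Unsupervised 2-D embedding of the batch-corrected panel, used purely
# descriptively: no downstream decision consumes its coordinates.

#' Two-dimensional unsupervised embedding
#'
#' Projects the batch-corrected log2 matrix to two dimensions by non-metric
#' multidimensional scaling (a nonlinear ordination preserving the rank
#' structure of inter-sample distances), and scores how well the group labels
#' separate in the embedding with the mean silhouette width. On panels with
#' strong inter-individual heterogeneity and weak group effects the expected
#' picture is a single cloud with silhouette near zero.
#'
#' @param x A `normalized_panel` (its `log2bc` matrix is embedded) or a bare
#'   samples x features matrix.
#' @param groups Group labels (taken from the panel when omitted).
#' @param seed Integer seed for the random starts.
#' @param try,trymax Random-start counts passed to [vegan::metaMDS()].
#' @return An `embedding_result`: `coords` tibble (`sample_id`, `group`,
#'   `dim1`, `dim2`), mean `silhouette` of the group labels in embedding
#'   space, `stress`, and the parameters used.
#' @export
embed_2d <- function(x, groups = NULL, seed = 1L, try = 5, trymax = 10) {
  if (inherits(x, "normalized_panel")) {
    groups <- groups %||% x$samples$group
    ids <- x$samples$sample_id
    x <- x$log2bc
  } else {
    ids <- rownames(x) %||% paste0("S", seq_len(nrow(x)))
  }
  x <- as.matrix(x)
  groups <- droplevels(as.factor(groups))
  d <- dist(x)
  fit <- with_rng(seed, suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = 2, trace = 0, try = try, trymax = trymax,
                   autotransform = FALSE, wascores = FALSE)
  )))
  coords <- fit$points
  sil <- if (nlevels(groups) < 2) NA_real_ else {
    sw <- cluster::silhouette(as.integer(groups), dist(coords))
    mean(sw[, "sil_width"])
  }
  structure(
    list(coords = tibble(sample_id = ids, group = groups,
                         dim1 = coords[, 1], dim2 = coords[, 2]),
         silhouette = sil, stress = fit$stress,
         params = list(method = "NMDS", distance = "euclidean", k = 2,
                       try = try, trymax = trymax, seed = seed)),
    class = "embedding_result"
  )
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> NMDS, %d samples, stress %.4f, group silhouette %.3f\n",
              nrow(x$coords), x$stress, x$silhouette))
  invisible(x)
}
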