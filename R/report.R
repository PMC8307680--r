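# Run-level markdown report assembling the outputs of whichever stages ran.

section_absent <- function(title) {
  c(paste0("## ", title), "", "_Not computed in this run._", "")
}

#' Build a run report
#'
#' Assembles a single markdown document from whichever stage outputs are
#' supplied: missingness-policy summary, class composition, differential
#' table excerpts, presence/absence excerpts, embedding summary, and
#' cross-validated classification metrics. Sections for absent stages are
#' marked as such. The body is deterministic: two runs on identical inputs
#' produce byte-identical documents.
#'
#' @param policy A `missingness_policy`, or `NULL`.
#' @param class_composition Output of [aggregate_classes()], or `NULL`.
#' @param differential Output of [differential_analysis()], or `NULL`.
#' @param presence Output of [presence_chi2()], or `NULL`.
#' @param embedding An `embedding_result`, or `NULL`.
#' @param cv A `cv_report`, or `NULL`.
#' @param config The [analysis_config()] used.
#' @param seed The run seed.
#' @param path Optional file to write the report to.
#' @param top_n Differential rows to show per table.
#' @return The report lines, invisibly; written to `path` when given.
#' @export
build_report <- function(policy = NULL, class_composition = NULL,
                         differential = NULL, presence = NULL,
                         embedding = NULL, cv = NULL,
                         config = analysis_config(), seed = config$seed,
                         path = NULL, top_n = 10) {
  if (is.null(policy) && is.null(class_composition) && is.null(differential) &&
      is.null(presence) && is.null(embedding) && is.null(cv)) {
    abort("At least one stage output is required.", class = "sevlip_report_error")
  }
  lines <- c("# sEV lipidomics pipeline report", "",
             sprintf("Seed: %d. Config: zero ceiling %.2f, IS ceiling %.2f, knn k %d, MRCV repeats %d, outer folds %d, test/group %d, teach fraction %.2f, dBIC stop %.1f, alpha %.2f.",
                     seed, config$zero_missing_ceiling, config$is_missing_ceiling,
                     config$knn_k, config$mrcv_repeats, config$outer_folds,
                     config$test_per_group, config$teach_fraction,
                     config$delta_bic_stop, config$alpha),
             "")

  lines <- c(lines, if (is.null(policy)) section_absent("Missingness policy") else c(
    "## Missingness policy", "",
    sprintf("- retained (tier 1): %d compounds", length(policy$retained_all)),
    sprintf("- quantitative tier: %d compounds", length(policy$retained_quant)),
    sprintf("- excluded: %d compounds", nrow(policy$excluded)), ""))

  lines <- c(lines, if (is.null(class_composition)) section_absent("Class composition") else {
    comp <- class_composition |>
      group_by(.data$class) |>
      summarise(mean_share_pct = mean(.data$share_pct), .groups = "drop") |>
      arrange(desc(.data$mean_share_pct))
    c("## Class composition", "", md_table(comp), "")
  })

  lines <- c(lines, if (is.null(differential)) section_absent("Differential abundance") else {
    top_om <- head(arrange(differential$omnibus, .data$p_value), top_n)
    top_pw <- head(arrange(filter(differential$pairwise, .data$differential),
                           .data$p_value), top_n)
    c("## Differential abundance", "",
      sprintf("%d compounds with omnibus raw p < 0.05.",
              sum(differential$omnibus$p_value < 0.05)), "",
      "Top omnibus compounds:", "",
      md_table(select(top_om, "metabolite_id", "statistic", "p_value",
                      "q_value", "eta_squared")), "",
      "Top differential pairwise rows (omnibus-gated):", "",
      md_table(select(top_pw, "metabolite_id", "pair", "p_value", "q_value",
                      "effect_r", "fold_change")), "")
  })

  lines <- c(lines, if (is.null(presence)) section_absent("Presence/absence analysis") else c(
    "## Presence/absence analysis", "",
    sprintf("%d compounds tested; %d with q < 0.05.",
            nrow(presence), sum(presence$q_value < 0.05, na.rm = TRUE)), ""))

  lines <- c(lines, if (is.null(embedding)) section_absent("Global structure") else c(
    "## Global structure", "",
    sprintf("NMDS embedding (stress %.4f): mean group silhouette %.3f.",
            embedding$stress, embedding$silhouette),
    "Silhouette near zero indicates no group separation in the unsupervised 2-D view.",
    ""))

  lines <- c(lines, if (is.null(cv)) section_absent("Classification") else c(
    "## Classification", "",
    md_table(cv$summary), "",
    sprintf("Fold signature sizes %d-%d; final model uses %d features: %s.",
            cv$signature_sizes[1], cv$signature_sizes[2],
            length(cv$final_model$features),
            paste(cv$final_model$features, collapse = ", ")), ""))

  if (!is.null(path)) writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}
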