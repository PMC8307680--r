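#' Missingness codes used throughout the pipeline
#'
#' Targeted panels distinguish two kinds of missing measurement: a
#' concentration below the plate-specific limit of quantitation (a "zero"
#' value, imputed from a truncated normal) and a measurement lost to an
#' internal-standard failure (imputed by k-nearest neighbours). All code
#' matrices in the package use these three states.
#'
#' @format A character vector of length 3.
#' @export
MISSING_CODES <- c("OBSERVED", "BELOW_LOQ", "IS_FAILURE")

#' Construct a metabolite panel
#'
#' The central data container: a samples x metabolites concentration matrix
#' (micromol) with a parallel missingness-code matrix, plus sample metadata
#' (group, 96-well plate) and metabolite metadata (lipid class and one
#' limit-of-quantitation column per plate).
#'
#' @param conc Numeric matrix, samples x metabolites. Cells whose code is not
#'   `"OBSERVED"` must be `NA`; observed cells must be finite and >= 0.
#'   Row names are sample ids, column names metabolite ids.
#' @param codes Character matrix of the same dimension with values from
#'   [MISSING_CODES].
#' @param samples Data frame with columns `sample_id`, `group` (factor whose
#'   levels declare the group order), `plate`.
#' @param metabolites Data frame with columns `metabolite_id`, `class`, and
#'   one numeric `loq_<plate>` column per plate.
#' @param truth Optional complete concentration matrix kept alongside a
#'   synthetic panel (values before missingness injection); used by
#'   oracle-style checks, never by the pipeline itself.
#'
#' @return An object of class `metabolite_panel`.
#' @export
metabolite_panel <- function(conc, codes, samples, metabolites, truth = NULL) {
  samples <- as_tibble(samples)
  metabolites <- as_tibble(metabolites)
  if (!is.factor(samples$group)) samples$group <- factor(samples$group)
  x <- structure(
    list(conc = conc, codes = codes, samples = samples, metabolites = metabolites,
         truth = truth),
    class = "metabolite_panel"
  )
  validate_panel(x)
  x
}

loq_cols <- function(metabolites) {
  grep("^loq_", names(metabolites), value = TRUE)
}

#' @rdname metabolite_panel
#' @param x A `metabolite_panel`.
#' @export
validate_panel <- function(x) {
  conc <- x$conc; codes <- x$codes
  if (!is.matrix(conc) || !is.numeric(conc)) {
    abort("`conc` must be a numeric matrix.", class = "sevlip_format_error")
  }
  if (!identical(dim(conc), dim(codes))) {
    abort("Concentration and code matrices have different dimensions.",
          class = "sevlip_format_error")
  }
  if (nrow(conc) != nrow(x$samples)) {
    abort(sprintf("Matrix has %d rows but sample table has %d.",
                  nrow(conc), nrow(x$samples)), class = "sevlip_format_error")
  }
  if (ncol(conc) != nrow(x$metabolites)) {
    abort(sprintf("Matrix has %d columns but metabolite table has %d.",
                  ncol(conc), nrow(x$metabolites)), class = "sevlip_format_error")
  }
  if (!identical(rownames(conc), x$samples$sample_id)) {
    abort("Matrix row names do not match `samples$sample_id`.",
          class = "sevlip_format_error")
  }
  if (!identical(colnames(conc), x$metabolites$metabolite_id)) {
    abort("Matrix column names do not match `metabolites$metabolite_id`.",
          class = "sevlip_format_error")
  }
  bad_code <- !(codes %in% MISSING_CODES)
  if (any(bad_code)) {
    idx <- which(bad_code, arr.ind = TRUE)[1L, ]
    abort(sprintf("Unknown missingness code at row %d (%s), column %d (%s).",
                  idx[1], rownames(conc)[idx[1]], idx[2], colnames(conc)[idx[2]]),
          class = "sevlip_format_error")
  }
  obs <- codes == "OBSERVED"
  if (any(!is.finite(conc[obs])) || any(conc[obs] < 0)) {
    idx <- which(obs & (!is.finite(conc) | conc < 0), arr.ind = TRUE)[1L, ]
    abort(sprintf("Observed concentration at row %d (%s), column %d (%s) is not a finite non-negative number.",
                  idx[1], rownames(conc)[idx[1]], idx[2], colnames(conc)[idx[2]]),
          class = "sevlip_format_error")
  }
  if (any(!is.na(conc[!obs]))) {
    abort("Cells coded missing must have NA concentration.",
          class = "sevlip_format_error")
  }
  lc <- loq_cols(x$metabolites)
  if (length(lc) == 0L) {
    abort("Metabolite table carries no `loq_<plate>` column.",
          class = "sevlip_format_error")
  }
  declared_plates <- sub("^loq_", "", lc)
  orphan <- !(x$samples$plate %in% declared_plates)
  if (any(orphan)) {
    abort(sprintf("Sample %s sits on plate '%s' which has no LOQ column.",
                  x$samples$sample_id[which(orphan)[1]],
                  x$samples$plate[which(orphan)[1]]),
          class = "sevlip_format_error")
  }
  invisible(x)
}

#' @export
print.metabolite_panel <- function(x, ...) {
  n_missing <- table(factor(x$codes, levels = MISSING_CODES))
  cat(sprintf("<metabolite_panel> %d samples x %d metabolites\n",
              nrow(x$conc), ncol(x$conc)))
  cat("  groups: ",
      paste(sprintf("%s (%d)", levels(x$samples$group),
                    tabulate(x$samples$group, nlevels(x$samples$group))),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  plates: %s\n", paste(unique(x$samples$plate), collapse = ", ")))
  cat(sprintf("  cells: %d observed, %d below-LOQ, %d IS-failure\n",
              n_missing[1], n_missing[2], n_missing[3]))
  invisible(x)
}

# LOQ for a given metabolite/plate pair, vectorized over metabolites.
panel_loq <- function(panel, metabolite_id, plate) {
  col <- paste0("loq_", plate)
  if (!col %in% names(panel$metabolites)) {
    abort(sprintf("No LOQ column for plate '%s'.", plate),
          class = "sevlip_imputation_error")
  }
  panel$metabolites[[col]][match(metabolite_id, panel$metabolites$metabolite_id)]
}
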