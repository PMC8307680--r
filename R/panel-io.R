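# Panel exchange format: a directory of three UTF-8 tab-separated files.
#
#   concentrations.tsv  sample_id + one column per metabolite (wide matrix);
#                       missing cells carry the sentinels `<LOQ` or `NA_IS`
#   samples.tsv         leading "# groups: ..." comment declaring the ordered
#                       group set, then sample_id / group / plate
#   metabolites.tsv     metabolite_id / class / one LOQ_<plate> column per plate
#
# Numbers are written with 17 significant digits so write -> read round-trips
# bit-exactly.

SENTINEL_BELOW_LOQ <- "<LOQ"
SENTINEL_IS <- "NA_IS"

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Write a metabolite panel to disk
#'
#' @param panel A [metabolite_panel()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  if (ncol(panel$conc) == 0L || nrow(panel$conc) == 0L) {
    abort("Refusing to write a panel with no samples or no metabolites.",
          class = "sevlip_format_error")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)

  cells <- matrix(fmt_num(panel$conc), nrow(panel$conc), ncol(panel$conc))
  cells[panel$codes == "BELOW_LOQ"] <- SENTINEL_BELOW_LOQ
  cells[panel$codes == "IS_FAILURE"] <- SENTINEL_IS
  lines <- c(
    paste(c("sample_id", colnames(panel$conc)), collapse = "\t"),
    vapply(seq_len(nrow(cells)), function(i) {
      paste(c(rownames(panel$conc)[i], cells[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, file.path(path, "concentrations.tsv"), useBytes = TRUE)

  s_lines <- c(
    paste0("# groups: ", paste(levels(panel$samples$group), collapse = ",")),
    "sample_id\tgroup\tplate",
    sprintf("%s\t%s\t%s", panel$samples$sample_id,
            as.character(panel$samples$group), panel$samples$plate)
  )
  writeLines(s_lines, file.path(path, "samples.tsv"), useBytes = TRUE)

  lc <- loq_cols(panel$metabolites)
  out_names <- c("metabolite_id", "class", sub("^loq_", "LOQ_", lc))
  body <- cbind(panel$metabolites$metabolite_id, panel$metabolites$class,
                do.call(cbind, lapply(lc, function(cl) fmt_num(panel$metabolites[[cl]]))))
  m_lines <- c(paste(out_names, collapse = "\t"),
               apply(body, 1L, paste, collapse = "\t"))
  writeLines(m_lines, file.path(path, "metabolites.tsv"), useBytes = TRUE)
  invisible(path)
}

read_tsv_chr <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  if (length(parts) == 1L) {
    m <- matrix(character(), 0, length(header))
  } else {
    m <- do.call(rbind, parts[-1])
  }
  colnames(m) <- header
  m
}

#' Read a metabolite panel from disk
#'
#' Reads a directory written by [write_panel()], decoding the `<LOQ` and
#' `NA_IS` sentinels into the three-state missingness code matrix and
#' validating all invariants; malformed numeric cells are rejected with their
#' row/column coordinates.
#'
#' @param path Panel directory.
#' @return A [metabolite_panel()].
#' @export
read_panel <- function(path) {
  for (f in c("concentrations.tsv", "samples.tsv", "metabolites.tsv")) {
    if (!file.exists(file.path(path, f))) {
      abort(sprintf("Panel directory is missing %s.", f),
            class = "sevlip_format_error")
    }
  }
  s_lines <- readLines(file.path(path, "samples.tsv"), encoding = "UTF-8")
  if (!startsWith(s_lines[1], "# groups:")) {
    abort("samples.tsv must open with a '# groups:' declaration.",
          class = "sevlip_format_error")
  }
  group_levels <- strsplit(trimws(sub("^# groups:", "", s_lines[1])), ",")[[1]]
  s_mat <- read_tsv_chr(file.path(path, "samples.tsv"))
  samples <- tibble(sample_id = s_mat[, "sample_id"],
                    group = s_mat[, "group"], plate = s_mat[, "plate"])
  bad_group <- !(samples$group %in% group_levels)
  if (any(bad_group)) {
    abort(sprintf("Sample %s has undeclared group label '%s'.",
                  samples$sample_id[which(bad_group)[1]],
                  samples$group[which(bad_group)[1]]),
          class = "sevlip_format_error")
  }
  samples$group <- factor(samples$group, levels = group_levels)

  m_mat <- read_tsv_chr(file.path(path, "metabolites.tsv"))
  metabolites <- tibble(metabolite_id = m_mat[, "metabolite_id"],
                        class = m_mat[, "class"])
  for (cl in grep("^LOQ_", colnames(m_mat), value = TRUE)) {
    v <- as.numeric(m_mat[, cl])
    if (anyNA(v)) {
      abort(sprintf("Malformed LOQ value in column %s, row %d.",
                    cl, which(is.na(v))[1]), class = "sevlip_format_error")
    }
    metabolites[[sub("^LOQ_", "loq_", cl)]] <- v
  }

  c_mat <- read_tsv_chr(file.path(path, "concentrations.tsv"))
  ids <- setdiff(colnames(c_mat), "sample_id")
  cells <- c_mat[, ids, drop = FALSE]
  codes <- matrix("OBSERVED", nrow(cells), ncol(cells))
  codes[cells == SENTINEL_BELOW_LOQ] <- "BELOW_LOQ"
  codes[cells == SENTINEL_IS] <- "IS_FAILURE"
  conc <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  malformed <- codes == "OBSERVED" & is.na(conc)
  if (any(malformed)) {
    idx <- which(malformed, arr.ind = TRUE)[1L, ]
    abort(sprintf("Malformed numeric cell at sample %s, metabolite %s.",
                  c_mat[idx[1], "sample_id"], ids[idx[2]]),
          class = "sevlip_format_error")
  }
  conc[codes != "OBSERVED"] <- NA_real_
  dimnames(conc) <- dimnames(codes) <- list(c_mat[, "sample_id"], ids)
  metabolite_panel(conc, codes, samples, metabolites)
}

#' Write a result table as TSV with a provenance header
#'
#' All pipeline result tables (differential tables, rankings, CV reports) can
#' be persisted with a `#`-prefixed header recording the configuration and
#' seed that produced them.
#'
#' @param df Data frame to write.
#' @param path Output file.
#' @param comment Character vector of provenance lines (written with `# `).
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, comment = character()) {
  body <- strsplit(readr::format_tsv(df), "\n", fixed = TRUE)[[1]]
  lines <- c(if (length(comment)) paste0("# ", comment), body)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
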