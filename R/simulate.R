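# Synthetic-panel generator: emulates the statistical structure of a targeted
# sEV lipidomics screening panel so every downstream stage is testable without
# patient data.

# Curated species names seeded first within each class so that planted effects
# can target compounds by their field shorthand, e.g. Cer(42:1).
seed_names <- list(
  AC  = c("AC(18:0)", "AC(16:0)", "AC(2:0)"),
  LPC = c("LPC(20:1)", "LPC(16:0)", "LPC(18:2)"),
  PC  = c("PC(24:0)", "PC(38:6)", "PC(38:7)", "PC(37:5)", "PC(38:5)",
          "PC(42:2)", "PC(36:5)", "PC(38:3)", "PC(42:4)", "PC(34:1)"),
  `PC-O` = c("PC-O(33:3)", "PC-O(32:0)", "PC-O(36:4)"),
  SM  = c("SM(34:1)", "SM(42:2)"),
  Cer = c("Cer(42:1)", "Cer(42:2)", "Cer(40:1)"),
  DG  = c("DG(36:2)", "DG(34:1)"),
  TG  = c("TG(54:2)", "TG(56:8)", "TG(52:2)"),
  CE  = c("CE(19:2)", "CE(18:2)", "CE(16:0)"),
  HEX = "H1"
)

name_grid <- list(
  AC  = list(c = 2:20,  d = 0:2),
  LPC = list(c = 14:24, d = 0:4),
  PC  = list(c = 24:44, d = 0:8),
  `PC-O` = list(c = 26:44, d = 0:6),
  SM  = list(c = 30:42, d = 0:3),
  Cer = list(c = 30:44, d = 0:3),
  DG  = list(c = 28:40, d = 0:6),
  TG  = list(c = 44:58, d = 0:10),
  CE  = list(c = 14:22, d = 0:6),
  HEX = NULL
)

class_names <- function(class, n) {
  seeds <- seed_names[[class]] %||% character()
  if (is.null(name_grid[[class]])) {
    pool <- seeds
  } else {
    g <- name_grid[[class]]
    grid <- expand.grid(d = g$d, c = g$c)     # vary saturation fastest
    pool <- unique(c(seeds, sprintf("%s(%d:%d)", class, grid$c, grid$d)))
  }
  if (n > length(pool)) {
    pool <- c(pool, sprintf("%s_x%03d", class, seq_len(n - length(pool))))
  }
  pool[seq_len(n)]
}

class_counts_from_proportions <- function(props, n) {
  counts <- floor(props * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    # hand remaining slots to the classes with the largest rounding residue
    resid <- props * n - counts
    top <- order(resid, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  counts[counts > 0]
}

#' Generate a synthetic metabolite panel
#'
#' Draws a samples x metabolites concentration table from the generating model
#' `log2 x = class mean + compound offset + plate shift + sample heterogeneity
#' (+ optional shared class factor) + residual`, applies planted group effects
#' multiplicatively on the concentration scale, then injects missingness:
#' cells falling below the plate limit of quantitation (set at a low quantile
#' of the compound's per-plate generating distribution) or selected at the
#' configured zero rate are coded `BELOW_LOQ`; an independent fraction is
#' coded `IS_FAILURE`. Samples enter plates in enrolment order with groups
#' interleaved, so plates are group-balanced. The complete pre-missingness
#' matrix is kept in the panel's `truth` slot for oracle-style checks.
#'
#' @param config A [simulation_config()].
#' @return A [metabolite_panel()].
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must come from simulation_config().", class = "sevlip_config_error")
  }
  with_rng(config$seed, {
    counts <- class_counts_from_proportions(config$class_proportions,
                                            config$n_metabolites)
    classes <- rep(names(counts), counts)
    ids <- unlist(lapply(names(counts), function(cl) class_names(cl, counts[[cl]])),
                  use.names = FALSE)
    m <- config$n_metabolites
    groups <- config$groups
    n <- config$n_per_group * length(groups)

    # enrolment order interleaves groups; plates filled sequentially
    group_vec <- rep(groups, times = config$n_per_group)
    plate_size <- ceiling(n / config$n_plates)
    plate_vec <- paste0("P", ceiling(seq_len(n) / plate_size))
    plates <- paste0("P", seq_len(config$n_plates))
    sample_ids <- sprintf("S%03d", seq_len(n))

    mu <- config$base_log2_mean[classes] + rnorm(m, 0, config$base_log2_sd)
    # curated marker species (the plantable, field-named compounds) are minor
    # species pinned to the mid-range of the global abundance distribution:
    # differential markers must be quantifiable yet carry little of the total
    # mass, so planted effects do not ripple through the permille closure
    curated <- ids %in% unlist(seed_names, use.names = FALSE)
    mu[curated] <- config$marker_log2_mean +
      rnorm(sum(curated), 0, config$marker_log2_sd)
    shift <- matrix(rnorm(config$n_plates * m, 0, config$plate_shift_sd),
                    config$n_plates, m, dimnames = list(plates, ids))
    het <- rnorm(n, 0, config$heterogeneity_sd)

    log2x <- matrix(rnorm(n * m, 0, config$residual_sd), n, m,
                    dimnames = list(sample_ids, ids))
    log2x <- sweep(log2x, 2, mu, "+")
    log2x <- log2x + shift[plate_vec, , drop = FALSE]
    log2x <- log2x + het
    class_var <- 0
    if (config$within_class_cor > 0) {
      rho <- config$within_class_cor
      sd_c <- config$residual_sd * sqrt(rho / (1 - rho))
      fac <- matrix(rnorm(n * length(counts), 0, sd_c), n, length(counts),
                    dimnames = list(NULL, names(counts)))
      log2x <- log2x + fac[, classes, drop = FALSE]
      class_var <- sd_c^2
    }
    if (nrow(config$effects)) {
      missing_id <- setdiff(config$effects$metabolite_id, ids)
      if (length(missing_id)) {
        abort(sprintf("Invalid `effects`: metabolite %s not in the generated panel.",
                      missing_id[1]), class = "sevlip_config_error")
      }
      for (i in seq_len(nrow(config$effects))) {
        e <- config$effects[i, ]
        rows <- group_vec == e$group
        log2x[rows, e$metabolite_id] <- log2x[rows, e$metabolite_id] +
          log2(e$fold_change)
      }
    }
    conc <- 2^log2x
    truth <- conc

    # plate LOQ at a low quantile of the compound's generating distribution
    cell_sd <- sqrt(config$heterogeneity_sd^2 + class_var + config$residual_sd^2)
    loq <- 2^(qnorm(config$loq_quantile,
                    sweep(shift, 2, mu, "+"), cell_sd))

    # Below-LOQ ("zero") missingness is detectability-driven: with a rate
    # range, per-compound rates follow the abundance rank (least abundant
    # compound -> upper end of the range), so censoring concentrates in the
    # low-abundance tail as it does when values fall under an assay LOQ.
    # IS failures are technical and abundance-independent.
    zr <- config$zero_missing_rate
    zero_rate <- if (length(zr) == 1L) rep(zr, m) else {
      pctl <- (rank(mu, ties.method = "first") - 0.5) / m
      zr[1] + (zr[2] - zr[1]) * (1 - pctl)
    }
    ir <- config$is_missing_rate
    is_rate <- if (length(ir) == 1L) rep(ir, m) else runif(m, ir[1], ir[2])

    codes <- matrix("OBSERVED", n, m, dimnames = dimnames(conc))
    codes[conc < loq[plate_vec, , drop = FALSE]] <- "BELOW_LOQ"
    u_zero <- matrix(runif(n * m), n, m)
    codes[u_zero < rep(zero_rate, each = n)] <- "BELOW_LOQ"
    u_is <- matrix(runif(n * m), n, m)
    codes[u_is < rep(is_rate, each = n)] <- "IS_FAILURE"
    conc[codes != "OBSERVED"] <- NA_real_

    metabolites <- tibble(metabolite_id = ids, class = classes)
    for (p in plates) metabolites[[paste0("loq_", p)]] <- unname(loq[p, ])

    metabolite_panel(
      conc = conc, codes = codes,
      samples = tibble(sample_id = sample_ids,
                       group = factor(group_vec, levels = groups),
                       plate = plate_vec),
      metabolites = metabolites,
      truth = truth
    )
  })
}

#' Generate a null panel
#'
#' Identical to [generate_panel()] with the planted-effect list emptied, so
#' group labels carry no signal: each compound's group distributions share one
#' generating law. Used for calibration checks (false-positive rates, chance
#' accuracy of the classifier).
#'
#' @inheritParams generate_panel
#' @return A [metabolite_panel()].
#' @export
null_panel <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must come from simulation_config().", class = "sevlip_config_error")
  }
  config$effects <- config$effects[0, ]
  generate_panel(config)
}
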