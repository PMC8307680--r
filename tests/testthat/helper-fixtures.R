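# Shared fixture builders. Everything is constructed in code; no stored data.

# A small hand-built two-plate panel with fully controllable codes.
make_panel <- function(conc, codes, groups, plates, classes = NULL, loq = 0.08) {
  n <- nrow(conc); m <- ncol(conc)
  sample_ids <- sprintf("S%02d", seq_len(n))
  ids <- colnames(conc) %||% sprintf("PC(%d:0)", 30 + seq_len(m))
  dimnames(conc) <- dimnames(codes) <- list(sample_ids, ids)
  metab <- tibble::tibble(metabolite_id = ids,
                          class = classes %||% rep("PC", m))
  for (p in unique(plates)) metab[[paste0("loq_", p)]] <- rep(loq, length.out = m)
  metabolite_panel(
    conc = conc, codes = codes,
    samples = tibble::tibble(sample_id = sample_ids,
                             group = factor(groups, levels = unique(groups)),
                             plate = plates),
    metabolites = metab
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small, fast simulation settings used when full study size is unnecessary.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_per_group = 20, n_metabolites = 40, n_plates = 2,
                   zero_missing_rate = 0.05, is_missing_rate = 0.02,
                   effects = planted_effect("Cer(42:1)", "LC", 1.5),
                   seed = 42L)
  for (nm in names(args)) defaults[nm] <- list(args[[nm]])  # keeps NULLs
  do.call(simulation_config, defaults)
}

# Fixture used for the frozen statistical-oracle comparisons: 3 groups x 5
# samples, two metabolites (the second with ties).
oracle_values <- function() {
  m1 <- c(1.1, 2.3, 3.1, 4.2, 5.5,  2.0, 3.3, 4.1, 5.2, 6.6,  4.0, 5.1, 6.2, 7.3, 8.1)
  m2 <- c(1, 1, 2, 3, 4,  2, 2, 3, 4, 5,  5, 5, 6, 7, 8)
  list(values = cbind(m1 = m1, m2 = m2),
       groups = factor(rep(c("A", "B", "C"), each = 5), levels = c("A", "B", "C")))
}
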