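# Internal helpers shared across modules.

# Draw from a normal truncated to (lo, hi) by inverse-CDF. Vectorized over
# mean/sd/lo/hi; u must be U(0,1) draws of the same length.
qtruncnorm <- function(u, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

# Deterministic RNG scope: everything stochastic in the package funnels
# through here so (input, config, seed) fully determines output.
with_rng <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Format a data frame as a GitHub-style markdown table (report module).
md_table <- function(df, digits = 4) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = digits, format = "g") else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L, dimnames = list(NULL, names(df)))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(fmt, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

# Row-wise max over the columns of a matrix without apply() overhead.
row_max <- function(m) do.call(pmax, as.data.frame(m))
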