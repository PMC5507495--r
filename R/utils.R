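# shared internal helpers

# round half away from zero, matching how percentages are printed in tables
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

# per-gene means over fresh-stage groups, columns ordered by DAF
fresh_stage_means <- function(mat, design) {
  des <- design[design$treatment == "fresh", ]
  stages <- unique(des$stage[order(des$daf)])
  out <- vapply(stages, function(s) {
    cols <- des$sample[des$stage == s]
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  dimnames(out) <- list(rownames(mat), stages)
  out
}
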