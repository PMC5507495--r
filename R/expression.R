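# Count-matrix QC, normalization, filtering, differential expression and
# sample-level diagnostics.

#' Library mapping QC table
#'
#' Percent mapped reads per library (1 decimal, half-up rounding as printed
#' in sequencing reports) and the minimum across libraries.
#'
#' @param qc data.frame with columns `sample` (optional), `total_reads`,
#'   `mapped_reads`.
#' @return The input with a `pct_mapped` column; the minimum percentage is
#'   attached as attribute `min_pct`.
#' @export
library_qc <- function(qc) {
  stopifnot(all(c("total_reads", "mapped_reads") %in% names(qc)))
  if (any(qc$total_reads <= 0)) stop("total reads must be positive")
  if (any(qc$mapped_reads > qc$total_reads)) {
    stop("mapped reads cannot exceed total reads")
  }
  qc$pct_mapped <- round_half_up(100 * qc$mapped_reads / qc$total_reads, 1)
  attr(qc, "min_pct") <- min(qc$pct_mapped)
  qc
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the reference profile is the per-gene
#' geometric mean over samples (restricted to genes positive in every
#' sample); each sample's factor is the median ratio of its counts to the
#' reference, rescaled so the factors have geometric mean 1.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene has positive counts in every sample")
  logref <- rowMeans(log(counts[pos, , drop = FALSE]))
  f <- apply(counts[pos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - logref))
  })
  f / exp(mean(log(f)))
}

#' Normalize counts and compute the log2 layer
#'
#' Divides counts by size factors and computes log2(normalized + pseudocount)
#' together with the per-gene variance of the log2 layer (the scale on which
#' the variance filter operates).
#'
#' @param counts Count matrix, genes x samples.
#' @param factors Size factors (default: [size_factors()] of `counts`).
#' @param pseudocount Positive pseudocount for the log layer (default 1).
#' @return Object of class `norm_matrix`: list with `normalized`, `log2`,
#'   `size_factors`, `gene_variance`, `pseudocount`.
#' @export
normalize_counts <- function(counts, factors = NULL, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (is.null(factors)) factors <- size_factors(counts)
  stopifnot(length(factors) == ncol(counts), all(factors > 0))
  normalized <- sweep(counts, 2, factors, "/")
  lg <- log2(normalized + pseudocount)
  structure(list(normalized = normalized, log2 = lg,
                 size_factors = factors, gene_variance = rowVars(lg),
                 pseudocount = pseudocount),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("Normalized count matrix: %d genes x %d samples (pseudocount %g)\n",
              nrow(x$normalized), ncol(x$normalized), x$pseudocount))
  invisible(x)
}

#' Variance filter on the log2 layer
#'
#' Retains genes whose log2-scale variance across samples strictly exceeds
#' the threshold; constant genes are always excluded.
#'
#' @param norm A `norm_matrix`.
#' @param threshold Variance threshold (default 1).
#' @return Character vector of retained gene ids.
#' @export
variance_filter <- function(norm, threshold = 1) {
  rownames(norm$log2)[norm$gene_variance > threshold]
}

#' Consecutive-stage expression ratios
#'
#' Per-gene ratios of stage n+1 over stage n mean normalized expression,
#' over consecutive fresh stages ordered by DAF (replicates averaged per
#' stage first). With `log2 = TRUE` the statistic is the difference of
#' pseudocounted log2 stage means (safe at zero counts), the input of the
#' bin-wise Wilcoxon enrichment.
#'
#' @param norm A `norm_matrix`.
#' @param design Sample design data.frame (sample, stage, daf, treatment).
#' @param log2 Return log2 stage-mean differences instead of linear ratios.
#' @return Matrix genes x (stage transitions), columns named "next/prev".
#' @export
stage_ratio <- function(norm, design, log2 = FALSE) {
  layer <- if (log2) norm$log2 else norm$normalized
  sm <- fresh_stage_means(layer, design)
  if (ncol(sm) < 2) stop("need at least 2 fresh stages")
  idx <- seq_len(ncol(sm) - 1)
  out <- if (log2) sm[, idx + 1, drop = FALSE] - sm[, idx, drop = FALSE]
         else sm[, idx + 1, drop = FALSE] / sm[, idx, drop = FALSE]
  colnames(out) <- paste(colnames(sm)[idx + 1], colnames(sm)[idx], sep = "/")
  out
}

#' Method-of-moments NB dispersion from replicated groups
#'
#' For every stage/treatment group with at least two libraries, estimates
#' per-gene dispersion alpha from normalized counts via
#' Var(y) = mu * mean(1/sf) + alpha * mu^2, then pools genes.
#'
#' @param counts Count matrix.
#' @param factors Size factors.
#' @param design Sample design data.frame.
#' @param min_mean Minimum normalized mean for a gene to enter the pool.
#' @param pool Pooling rule: "pooled" (default; ratio of summed excess
#'   variances to summed squared means, stable with few replicates) or
#'   "mean"/"median" of the per-gene estimates. With one or two replicates
#'   per group the per-gene estimates have about one degree of freedom each,
#'   so their median is severely biased low; the pooled ratio is nearly
#'   unbiased.
#' @return Single pooled dispersion (floored at 1e-8), with the per-gene
#'   estimates attached as attribute `per_gene`.
#' @export
estimate_dispersion_mom <- function(counts, factors, design, min_mean = 5,
                                    pool = c("pooled", "mean", "median")) {
  pool <- match.arg(pool)
  if (is.null(names(factors))) names(factors) <- colnames(counts)
  grp <- paste(design$stage, design$treatment)
  tab <- table(grp)
  reps <- names(tab)[tab >= 2]
  if (!length(reps)) stop("no replicated group to estimate dispersion from")
  y <- sweep(counts, 2, factors, "/")
  parts <- lapply(reps, function(g) {
    cols <- design$sample[grp == g]
    yy <- y[, cols, drop = FALSE]
    m <- rowMeans(yy)
    v <- rowVars(yy)
    cc <- mean(1 / factors[cols])
    keep <- m >= min_mean
    list(excess = v[keep] - cc * m[keep], msq = m[keep]^2,
         per_gene = (v[keep] - cc * m[keep]) / m[keep]^2)
  })
  per_gene <- unlist(lapply(parts, `[[`, "per_gene"))
  per_gene <- per_gene[is.finite(per_gene)]
  est <- switch(pool,
    pooled = sum(unlist(lapply(parts, `[[`, "excess"))) /
             sum(unlist(lapply(parts, `[[`, "msq"))),
    mean = mean(per_gene),
    median = stats::median(per_gene))
  out <- max(est, 1e-8)
  attr(out, "per_gene") <- per_gene
  out
}

#' Negative binomial Wald test of differential expression
#'
#' Per-gene Wald test of the log fold change between two sample groups on
#' normalized counts, using a single pooled NB dispersion (supplied, or
#' estimated by method of moments from the replicated groups of the design).
#' A gene is flagged significant when its fold change is at least
#' `fold_threshold` (inclusive) and its BH-adjusted p-value is below
#' `alpha`. This is a deliberate approximation of a DESeq2-style analysis:
#' no shrinkage, one dispersion for all genes.
#'
#' @param counts Count matrix, genes x samples.
#' @param group_a,group_b Sample id vectors naming the two groups
#'   (fold change is a over b).
#' @param factors Size factors (default: from the full matrix).
#' @param fold_threshold Linear fold-change threshold (default 2, inclusive).
#' @param alpha Adjusted-p threshold (default 0.05; the enforced-drying
#'   contrasts of the study use 0.01).
#' @param dispersion Pooled NB dispersion; if NULL, estimated from `design`.
#' @param design Sample design (required when `dispersion` is NULL).
#' @param delta Normalized-count offset stabilizing log fold changes at low
#'   counts.
#' @return data.frame: gene, log2fc, se, p, padj, significant; the
#'   dispersion used is attached as attribute `dispersion`.
#' @export
de_test <- function(counts, group_a, group_b, factors = NULL,
                    fold_threshold = 2, alpha = 0.05, dispersion = NULL,
                    design = NULL, delta = 0.5) {
  if (!all(c(group_a, group_b) %in% colnames(counts))) {
    stop("contrast references unknown samples")
  }
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(names(factors))) names(factors) <- colnames(counts)
  if (is.null(dispersion)) {
    if (is.null(design)) stop("supply either dispersion or design")
    dispersion <- as.numeric(
      estimate_dispersion_mom(counts, factors, design))
  }
  if (dispersion <= 0) stop("dispersion must be positive")
  y <- sweep(counts, 2, factors, "/")
  mu_a <- rowMeans(y[, group_a, drop = FALSE])
  mu_b <- rowMeans(y[, group_b, drop = FALSE])
  # var(log mu_hat) by the delta method: counts are NB(mu*sf, alpha)
  vl <- function(mu, grp) {
    sf <- factors[grp]
    rowSums(outer(1 / (mu + delta), 1 / sf) + dispersion) / length(grp)^2
  }
  se_log <- sqrt(vl(mu_a, group_a) + vl(mu_b, group_b))
  # ratio of means; the offset enters only at zero means so that an exact
  # two-fold ratio sits exactly on the (inclusive) threshold
  eff_a <- mu_a + delta * (mu_a == 0)
  eff_b <- mu_b + delta * (mu_b == 0)
  lfc <- log2(eff_a) - log2(eff_b)
  z <- (log(eff_a) - log(eff_b)) / se_log
  p <- 2 * stats::pnorm(-abs(z))
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    gene = rownames(counts), log2fc = lfc, se = se_log / log(2), p = p,
    padj = padj,
    significant = (abs(lfc) >= log2(fold_threshold)) & (padj < alpha),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dispersion") <- dispersion
  out
}

#' Pairwise sample correlation matrix
#'
#' Pearson correlations between samples on the log2 layer, typically
#' restricted to variance-retained genes.
#'
#' @param norm A `norm_matrix`.
#' @param genes Optional gene ids to restrict to.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_cor_matrix <- function(norm, genes = NULL) {
  x <- norm$log2
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("sample with zero variance")
  stats::cor(x)
}

#' Median-centered principal component analysis of samples
#'
#' Subtracts the per-gene median, then decomposes by SVD. The sign of each
#' component is fixed so that its largest-magnitude gene loading is
#' positive, making coordinates reproducible.
#'
#' @param norm A `norm_matrix`.
#' @param genes Optional gene ids to restrict to.
#' @param n_pc Number of components to return (default 2).
#' @return List: `scores` (samples x PCs), `explained` (variance
#'   fractions), `loadings` (genes x PCs).
#' @export
pca_median_centered <- function(norm, genes = NULL, n_pc = 2) {
  x <- norm$log2
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 samples")
  xc <- x - apply(x, 1, stats::median)
  sv <- svd(xc)
  k <- min(n_pc, length(sv$d))
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) { u[, j] <- -u[, j]; v[, j] <- -v[, j] }
  }
  scores <- sweep(v, 2, sv$d[seq_len(k)], "*")
  dimnames(scores) <- list(colnames(x), paste0("PC", seq_len(k)))
  dimnames(u) <- list(rownames(x), colnames(scores))
  list(scores = scores, explained = sv$d^2 / sum(sv$d^2), loadings = u)
}
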