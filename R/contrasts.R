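# Set-algebra comparisons between DE contrasts, heat-map gene selection,
# and comparative 2^-ddCt qPCR quantification.

#' Venn overlap of two gene sets
#'
#' Intersection counts and integer-rounded overlap percentages of each set.
#'
#' @param a,b Character vectors of gene ids.
#' @param label_a,label_b Set labels.
#' @return List: labels, n_a, n_b, n_both, n_a_only, n_b_only, pct_of_a,
#'   pct_of_b (percentages rounded half-up to integers).
#' @export
venn_overlap <- function(a, b, label_a = "A", label_b = "B") {
  a <- unique(a); b <- unique(b)
  both <- length(intersect(a, b))
  list(labels = c(label_a, label_b),
       n_a = length(a), n_b = length(b), n_both = both,
       n_a_only = length(a) - both, n_b_only = length(b) - both,
       pct_of_a = if (length(a)) round_half_up(100 * both / length(a)) else NA,
       pct_of_b = if (length(b)) round_half_up(100 * both / length(b)) else NA)
}

#' Fraction of a compartment's genes contained in a gene set
#'
#' E.g. the share of chloroplast-encoded genes among transcripts
#' down-regulated in long-lived mature seeds.
#'
#' @param gene_set Character vector of gene ids.
#' @param annotation data.frame with columns gene, compartment.
#' @param compartment Compartment label (default "chloroplast").
#' @return List: n_compartment, n_in_set, pct (rounded half-up to integer).
#' @export
compartment_overlap <- function(gene_set, annotation,
                                compartment = "chloroplast") {
  comp_genes <- annotation$gene[annotation$compartment == compartment]
  if (!length(comp_genes)) stop("empty compartment: ", compartment)
  hit <- length(intersect(comp_genes, gene_set))
  list(n_compartment = length(comp_genes), n_in_set = hit,
       pct = round_half_up(100 * hit / length(comp_genes)))
}

#' Select genes for the longevity heat map
#'
#' Genes whose absolute log2 stage-mean difference between two stages
#' strictly exceeds `fc_log2` and whose gene significance strictly exceeds
#' `gs_cutoff`; returned with a mean-centered log2 stage-mean matrix for
#' plotting. Only genes present in the GS table (i.e. variance-retained)
#' are eligible.
#'
#' @param norm A `norm_matrix`.
#' @param gs data.frame from [gene_significance()].
#' @param design Sample design data.frame.
#' @param stages Length-2 stage labels compared (default c("7.2", "9")).
#' @param fc_log2 Log2 difference threshold (default 4, strict).
#' @param gs_cutoff GS threshold (default 0.85, strict).
#' @return List: `genes` (selected ids) and `matrix` (mean-centered log2
#'   stage means of the selection).
#' @export
heatmap_selection <- function(norm, gs, design, stages = c("7.2", "9"),
                              fc_log2 = 4, gs_cutoff = 0.85) {
  sm <- fresh_stage_means(norm$log2, design)
  if (!all(stages %in% colnames(sm))) stop("missing stage in design")
  diff <- abs(sm[, stages[2]] - sm[, stages[1]])
  gs_v <- stats::setNames(gs$gs, gs$gene)
  eligible <- intersect(rownames(sm), gs$gene)
  sel <- eligible[diff[eligible] > fc_log2 &
                    !is.na(gs_v[eligible]) & gs_v[eligible] > gs_cutoff]
  m <- sm[sel, , drop = FALSE]
  list(genes = sel, matrix = m - rowMeans(m))
}

#' Comparative 2^-ddCt relative expression
#'
#' dCt = Ct(target) - mean(Ct of the two reference genes); ddCt is taken
#' against the calibrator sample, and relative expression is 2^-ddCt (the
#' calibrator's own value is exactly 1). Amplification efficiency is
#' assumed to be 2.0.
#'
#' @param records data.frame: gene, sample, ct_target, ct_ref1, ct_ref2.
#' @param calibrator Sample id used as calibrator.
#' @return The input with dct, ddct and rel_expr columns appended.
#' @export
ddct_relative_expression <- function(records, calibrator) {
  need <- c("gene", "sample", "ct_target", "ct_ref1", "ct_ref2")
  stopifnot(all(need %in% names(records)))
  if (any(is.na(records$ct_ref1)) || any(is.na(records$ct_ref2))) {
    stop("missing reference Ct")
  }
  if (!calibrator %in% records$sample) stop("unknown calibrator sample")
  records$dct <- records$ct_target - (records$ct_ref1 + records$ct_ref2) / 2
  cal <- records[records$sample == calibrator, c("gene", "dct")]
  records$ddct <- records$dct - cal$dct[match(records$gene, cal$gene)]
  records$rel_expr <- 2^(-records$ddct)
  records
}

#' Agreement between qPCR and RNA-seq expression profiles
#'
#' Per-gene squared Pearson correlation between log2 qPCR relative
#' expression and log2 RNA-seq stage means over shared stages; the sign of
#' the underlying correlation is reported alongside.
#'
#' @param qpcr data.frame with gene, sample, rel_expr (output of
#'   [ddct_relative_expression()]).
#' @param rnaseq_means Matrix of RNA-seq stage means (genes x stages,
#'   linear or log2 scale set by `rnaseq_log2`).
#' @param rnaseq_log2 Whether `rnaseq_means` is already log2.
#' @return data.frame: gene, r_squared, sign, n_stages.
#' @export
rnaseq_qpcr_agreement <- function(qpcr, rnaseq_means, rnaseq_log2 = TRUE) {
  lm2 <- if (rnaseq_log2) rnaseq_means else log2(rnaseq_means)
  out <- do.call(rbind, lapply(split(qpcr, qpcr$gene), function(d) {
    shared <- intersect(d$sample, colnames(lm2))
    if (length(shared) < 3) stop("need at least 3 shared stages")
    x <- log2(d$rel_expr[match(shared, d$sample)])
    y <- lm2[d$gene[1], shared]
    r <- stats::cor(x, y)
    data.frame(gene = d$gene[1], r_squared = r^2,
               sign = ifelse(r >= 0, 1, -1), n_stages = length(shared),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
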