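# Over-representation statistics: chi-square family enrichment,
# hypergeometric GO tests, BH/Bonferroni correction, and bin-wise Wilcoxon
# enrichment with z-score conversion.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni adjustment
#'
#' Family-wise min(1, m * p) correction (wraps [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Convert a (corrected) two-sided p-value to a signed z-score
#'
#' z = qnorm(1 - p/2), signed by the direction of the shift; the scale used
#' to color bin-wise enrichment maps (p = 0.05 maps to |z| = 1.96).
#'
#' @param p Two-sided p-values.
#' @param direction Sign of the underlying shift (+1/-1; default +1).
#' @return Signed z-scores.
#' @export
z_from_p <- function(p, direction = 1) {
  stats::qnorm(1 - pmin(p, 1) / 2) * sign(direction)
}

#' Chi-square family enrichment of a gene cohort
#'
#' For each TF family, a 2x2 Pearson chi-square test (no continuity
#' correction, 1 df) of membership in the cohort (e.g. the transient network
#' tail) against the background TF set, plus the family's share of the
#' cohort as a percentage.
#'
#' @param cohort Gene ids of the cohort (subset of `background`).
#' @param background Gene ids of the background set.
#' @param annotation data.frame with columns gene, family.
#' @return data.frame: family, n_cohort, n_background, pct_of_cohort,
#'   chisq, p.
#' @export
chi2_family_enrichment <- function(cohort, background, annotation) {
  if (!all(cohort %in% background)) stop("cohort must be within background")
  fam_bg <- annotation$family[match(background, annotation$gene)]
  fam_co <- annotation$family[match(cohort, annotation$gene)]
  fams <- sort(unique(fam_bg[!is.na(fam_bg)]))
  n_co <- length(cohort); n_bg <- length(background)
  out <- do.call(rbind, lapply(fams, function(f) {
    a <- sum(fam_co == f, na.rm = TRUE)
    b <- n_co - a
    cfam <- sum(fam_bg == f, na.rm = TRUE) - a
    d <- (n_bg - n_co) - cfam
    tab <- matrix(c(a, cfam, b, d), 2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0)) stop("expected cell count of 0 for family ", f)
    ts <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(family = f, n_cohort = a,
               n_background = a + cfam,
               pct_of_cohort = 100 * a / n_co,
               chisq = unname(ts$statistic), p = ts$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Parse an annotation table into a term-to-gene map
#'
#' @param annotation data.frame with columns gene and go (semicolon-joined
#'   term ids); annotations are assumed already propagated.
#' @return Named list of gene-id vectors per term.
#' @export
annotation_to_term_map <- function(annotation) {
  terms <- strsplit(annotation$go, ";", fixed = TRUE)
  long <- data.frame(gene = rep(annotation$gene, lengths(terms)),
                     term = unlist(terms), stringsAsFactors = FALSE)
  split(long$gene, long$term)
}

#' Hypergeometric term over-representation
#'
#' For each term, the upper-tail hypergeometric probability
#' P(X >= k | N, K, n) of observing k list members annotated to a term of
#' genome count K, and the matching lower tail P(X <= k) for
#' under-representation. The reported direction is the enriched side
#' (observed k above or below its expectation n*K/N); correction is BH by
#' default with Bonferroni available.
#'
#' @param gene_list Gene ids of the query list (subset of `genome`).
#' @param term_map Named list term -> gene ids (see
#'   [annotation_to_term_map()]).
#' @param genome Gene universe; defaults to the union of all term genes.
#' @param correction "BH" or "bonferroni".
#' @return data.frame: term, genome_count, list_count, list_size,
#'   genome_size, p_over, p_under, direction, p, p_corrected.
#' @export
hypergeometric_enrichment <- function(gene_list, term_map, genome = NULL,
                                      correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  if (is.null(genome)) genome <- unique(unlist(term_map))
  if (!all(gene_list %in% genome)) stop("gene list must be within the genome")
  N <- length(genome); n <- length(gene_list)
  out <- do.call(rbind, lapply(names(term_map), function(tm) {
    K <- length(intersect(term_map[[tm]], genome))
    k <- length(intersect(term_map[[tm]], gene_list))
    if (k > K || k > n) stop("annotation inconsistency for term ", tm)
    p_over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_under <- stats::phyper(k, K, N - K, n)
    over <- k >= n * K / N
    data.frame(term = tm, genome_count = K, list_count = k, list_size = n,
               genome_size = N, p_over = p_over, p_under = p_under,
               direction = if (over) "over" else "under",
               p = if (over) p_over else p_under,
               stringsAsFactors = FALSE)
  }))
  out$p_corrected <- if (correction == "BH") bh_adjust(out$p)
                     else bonferroni_adjust(out$p)
  rownames(out) <- NULL
  out
}

# exact two-sided rank-sum p by enumeration of the permutation distribution
# of the bin's rank sum (handles ties; feasible for small bins)
exact_ranksum_p <- function(x, y) {
  r <- rank(c(x, y))
  m <- length(x); N <- length(r)
  w <- sum(r[seq_len(m)])
  sums <- utils::combn(r, m, sum)
  e <- mean(sums)
  mean(abs(sums - e) >= abs(w - e) - 1e-12)
}

#' Bin-wise Wilcoxon enrichment with z-score conversion
#'
#' For each bin (functional class), a two-sided Wilcoxon rank-sum test of
#' the bin members' per-gene statistic (typically a stage-wise log2
#' expression change) against all other genes. Small bins (< `exact_below`
#' members) use exact enumeration of the permutation distribution of the
#' rank sum; larger bins use the normal approximation with tie correction.
#' P-values are Bonferroni-corrected over bins and converted to signed
#' z-scores (z = qnorm(1 - p/2), signed by the bin's median shift), so a
#' corrected p of 0.05 maps to |z| = 1.96.
#'
#' @param values Named numeric vector of per-gene statistics.
#' @param bins Named list of gene-id vectors (a gene may sit in several
#'   bins).
#' @param correction "bonferroni" (default) or "BH".
#' @param exact_below Bin size below which the exact enumeration is used.
#' @return data.frame: bin, n_bin, direction, p, p_corrected, z.
#' @export
wilcoxon_bin_test <- function(values, bins,
                              correction = c("bonferroni", "BH"),
                              exact_below = 10) {
  correction <- match.arg(correction)
  genes <- names(values)
  if (is.null(genes)) stop("values must be named by gene")
  rows <- lapply(names(bins), function(b) {
    memb <- intersect(bins[[b]], genes)
    if (!length(memb)) stop("bin ", b, " has no members")
    rest <- setdiff(genes, memb)
    if (!length(rest)) stop("bin ", b, " covers the entire gene set")
    x <- values[memb]; y <- values[rest]
    N <- length(values); m <- length(x)
    if (m < exact_below && choose(N, m) <= 2e4) {
      p <- exact_ranksum_p(x, y)
    } else {
      r <- rank(c(x, y))
      w <- sum(r[seq_len(m)])
      e <- m * (N + 1) / 2
      ties <- table(r)
      v <- m * (N - m) / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
      p <- if (v <= 0) 1 else 2 * stats::pnorm(-abs(w - e) / sqrt(v))
      p <- min(p, 1)
    }
    dir <- sign(stats::median(x) - stats::median(y))
    if (dir == 0) dir <- sign(mean(x) - mean(y))
    data.frame(bin = b, n_bin = m, direction = dir, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- if (correction == "bonferroni") bonferroni_adjust(out$p)
                     else bh_adjust(out$p)
  out$z <- z_from_p(out$p_corrected, out$direction)
  rownames(out) <- NULL
  out
}
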