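# Readers for the plain-text exchange formats of the pipeline.

#' Read a gene x sample count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path counts.tsv path.
#' @return Integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) stop("duplicate gene ids in count matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("counts must be non-negative")
  m
}

#' Read a sample design table from TSV
#'
#' @param path design.tsv path.
#' @return data.frame with sample, stage, daf, treatment, replicate.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, colClasses = c(stage = "character"),
                          stringsAsFactors = FALSE)
  need <- c("sample", "stage", "daf", "treatment", "replicate")
  if (!all(need %in% names(df))) {
    stop("design table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in design")
  df
}

#' Read a gene annotation table from TSV
#'
#' @param path annotation.tsv path (columns gene, family, go, compartment).
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a germination assay table from CSV
#'
#' @param path germination.csv path (stage, time_d, replicate, n_seeds,
#'   n_germinated).
#' @return data.frame.
#' @export
read_germination <- function(path) {
  utils::read.csv(path, colClasses = c(stage = "character"),
                  stringsAsFactors = FALSE)
}

#' Read a sugar content table from CSV
#'
#' @param path sugars.csv path.
#' @return data.frame.
#' @export
read_sugars <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published library read-mapping summary
#'
#' The read-mapping summary of the ten soybean seed maturation libraries
#' (total and unambiguously mapped reads per library, with the percentage as
#' printed in the original report), shipped with the package as the input
#' of the library-QC arithmetic.
#'
#' @return data.frame: sample, stage, treatment, replicate, total_reads,
#'   mapped_reads, reported_pct.
#' @export
library_read_counts <- function() {
  path <- system.file("extdata", "library_read_counts.tsv",
                      package = "seedlong")
  utils::read.delim(path, colClasses = c(stage = "character"),
                    stringsAsFactors = FALSE)
}
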