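# TF co-expression network: PCC-thresholded edges, temporal annotation,
# trait-based gene significance against P50, longevity module extraction.

#' Positive-correlation co-expression edges
#'
#' All-pairs Pearson correlations across samples; a pair becomes an edge
#' when its PCC is positive and at least `cutoff` (inclusive boundary). The
#' graph is undirected and self-loop free; only genes with at least one
#' qualifying edge appear as nodes downstream.
#'
#' @param mat Expression matrix (typically the log2 layer restricted to
#'   variance-retained TF genes), genes x samples.
#' @param cutoff PCC threshold in (0, 1] (default 0.97).
#' @return data.frame of edges: gene_a, gene_b, pcc (gene_a < gene_b).
#' @export
coexpression_edges <- function(mat, cutoff = 0.97) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) stop("genes with zero variance cannot be correlated")
  cc <- stats::cor(t(mat))
  cc[lower.tri(cc, diag = TRUE)] <- NA
  hit <- which(cc >= cutoff, arr.ind = TRUE)
  out <- data.frame(gene_a = rownames(cc)[hit[, 1]],
                    gene_b = colnames(cc)[hit[, 2]],
                    pcc = cc[hit], stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Stage of maximal expression per gene
#'
#' The fresh stage (dried samples excluded, replicates averaged) at which a
#' gene's stage-mean log2 expression peaks; exact ties resolve to the
#' earliest stage. Used to color network nodes temporally.
#'
#' @param norm A `norm_matrix`.
#' @param design Sample design data.frame.
#' @return Named character vector of stage labels per gene.
#' @export
assign_stage_of_max <- function(norm, design) {
  sm <- fresh_stage_means(norm$log2, design)
  stages <- colnames(sm)
  stats::setNames(stages[apply(sm, 1, which.max)], rownames(sm))
}

#' Trait-based gene significance against P50
#'
#' GS(gene) = |PCC(stage-mean expression profile, P50 trajectory)| over
#' fresh stages, with the sign of the underlying correlation retained.
#' Replicates are averaged per stage first, so replicate imbalance cannot
#' weight the correlation; the dried sample has no P50 and is excluded.
#'
#' @param norm A `norm_matrix`.
#' @param p50 Named numeric vector of P50 (days) per fresh stage.
#' @param design Sample design data.frame.
#' @param genes Optional gene ids to restrict to.
#' @return data.frame: gene, gs (in [0, 1]), sign (+1/-1).
#' @export
gene_significance <- function(norm, p50, design, genes = NULL) {
  sm <- fresh_stage_means(norm$log2, design)
  if (!is.null(genes)) sm <- sm[genes, , drop = FALSE]
  stages <- colnames(sm)
  if (length(stages) < 3) stop("need at least 3 fresh stages for GS")
  if (!all(stages %in% names(p50))) stop("p50 must cover every fresh stage")
  p50v <- p50[stages]
  sds <- apply(sm, 1, stats::sd)
  keep <- sds > 0
  r <- rep(NA_real_, nrow(sm))
  r[keep] <- as.numeric(stats::cor(t(sm[keep, , drop = FALSE]), p50v))
  data.frame(gene = rownames(sm), gs = abs(r),
             sign = ifelse(r >= 0, 1, -1), stringsAsFactors = FALSE)
}

#' Extract the longevity module from the network
#'
#' Members are network nodes whose gene significance strictly exceeds
#' `gs_cutoff`. Reports family composition and the edge density of the
#' induced subgraph.
#'
#' @param edges Edge data.frame from [coexpression_edges()].
#' @param gs data.frame from [gene_significance()].
#' @param gs_cutoff GS threshold (default 0.9, strict, matching the
#'   "PCC > 0.9" projection rule).
#' @param annotation Optional annotation data.frame (gene, family) for the
#'   family composition summary.
#' @return List: `members` (gene ids), `gs_cutoff`, `families` (count
#'   table or NULL), `edge_density` of the induced subgraph.
#' @export
extract_longevity_module <- function(edges, gs, gs_cutoff = 0.9,
                                     annotation = NULL) {
  nodes <- union(edges$gene_a, edges$gene_b)
  if (!length(nodes)) stop("empty graph")
  gs_ok <- gs$gene[!is.na(gs$gs) & gs$gs > gs_cutoff]
  members <- intersect(nodes, gs_ok)
  if (!length(members)) warning("no network node exceeds the GS cutoff")
  sub <- edges[edges$gene_a %in% members & edges$gene_b %in% members, ]
  n <- length(members)
  dens <- if (n >= 2) nrow(sub) / (n * (n - 1) / 2) else NA_real_
  fams <- NULL
  if (!is.null(annotation)) {
    fams <- table(annotation$family[match(members, annotation$gene)],
                  useNA = "no")
  }
  list(members = members, gs_cutoff = gs_cutoff, families = fams,
       edge_density = dens)
}

#' Convert an edge list to an igraph graph
#'
#' @param edges Edge data.frame (gene_a, gene_b, pcc).
#' @param node_attrs Optional data.frame keyed by `gene` with extra node
#'   attributes (e.g. stage_of_max, gs, family).
#' @return Undirected weighted igraph object.
#' @export
as_coexpression_graph <- function(edges, node_attrs = NULL) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$gene_a, to = edges$gene_b, weight = edges$pcc),
    directed = FALSE)
  if (!is.null(node_attrs)) {
    idx <- match(igraph::V(g)$name, node_attrs$gene)
    for (col in setdiff(names(node_attrs), "gene")) {
      g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][idx])
    }
  }
  g
}

#' Summarize the co-expression network
#'
#' Node/edge counts, connected components, per-stage-of-max node counts and
#' the degree distribution.
#'
#' @param edges Edge data.frame from [coexpression_edges()].
#' @param stage_of_max Optional named stage labels (from
#'   [assign_stage_of_max()]).
#' @return List: n_nodes, n_edges, n_components, component_sizes, degree
#'   (named vector), nodes_per_stage (or NULL).
#' @export
network_summary <- function(edges, stage_of_max = NULL) {
  if (nrow(edges) == 0) {
    return(list(n_nodes = 0L, n_edges = 0L, n_components = 0L,
                component_sizes = integer(0), degree = integer(0),
                nodes_per_stage = NULL))
  }
  g <- as_coexpression_graph(edges)
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  nps <- if (!is.null(stage_of_max)) {
    table(stage_of_max[igraph::V(g)$name])
  }
  list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
       n_components = comp$no, component_sizes = as.integer(comp$csize),
       degree = deg, nodes_per_stage = nps)
}

#' Export the network as GraphML
#'
#' @param edges Edge data.frame.
#' @param path Output file path.
#' @param node_attrs Optional node attribute data.frame (see
#'   [as_coexpression_graph()]).
#' @return Invisibly, the path.
#' @export
write_graphml <- function(edges, path, node_attrs = NULL) {
  g <- as_coexpression_graph(edges, node_attrs)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
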