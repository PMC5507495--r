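#' Default transcription factor family set
#'
#' The 32 plant TF family labels used by the synthetic annotation generator.
#' The first two (AP2/EREBP, WRKY) carry elevated tail-enrichment weights by
#' default, mirroring their over-representation among transiently expressed
#' maturation-phase regulators.
#'
#' @return Character vector of 32 family labels.
#' @export
tf_families <- function() {
  c("AP2/EREBP", "WRKY", "MYB", "bZIP", "bHLH", "NAC", "C2H2", "HSF",
    "ARF", "HD-ZIP", "MADS", "GRAS", "B3", "Dof", "GATA", "TCP",
    "Trihelix", "NF-YA", "NF-YB", "NF-YC", "SBP", "ARR-B", "CO-like",
    "E2F/DP", "EIL", "G2-like", "LBD", "WOX", "YABBY", "ZF-HD", "C3H",
    "NF-X1")
}

#' Default library design of the simulated study
#'
#' Ten libraries spanning phenological stages 7.1 to 9: single libraries at
#' 7.1, 7.3, 8.1 and 8.2, duplicated libraries at 7.2 and 9, and a duplicated
#' rapidly-dried 7.2 sample (treatment "dried").
#'
#' @return data.frame with columns stage, daf, treatment, n_rep.
#' @export
default_stage_design <- function() {
  data.frame(
    stage = c("7.1", "7.2", "7.2", "7.3", "8.1", "8.2", "9"),
    daf = c(57, 63, 63, 69, 71, 73, 77),
    treatment = c("fresh", "fresh", "dried", "fresh", "fresh", "fresh",
                  "fresh"),
    n_rep = c(1L, 2L, 2L, 1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Default P50 trajectory over fresh stages
#'
#' Longevity (P50, days of storage at 35 degrees C / 75\% RH until
#' germination falls to half its initial value) is essentially zero at the
#' end of seed filling (stage 7.1), jumps to 28 d at physiological maturity
#' (7.2) and rises to 48 d in the dry mature seed (stage 9). Intermediate
#' stages are interpolated.
#'
#' @return Named numeric vector (days) keyed by fresh stage label.
#' @export
default_p50 <- function() {
  c("7.1" = 0, "7.2" = 28, "7.3" = 33, "8.1" = 38, "8.2" = 43, "9" = 48)
}

#' Configuration for the synthetic seed-maturation study
#'
#' Bundles every parameter of the seeded generator: the library design, the
#' P50 trajectory the planted longevity module tracks, cohort sizes, the
#' negative binomial dispersion of the counts, and the TF family weights used
#' when sampling families for the transient ("tail") cohort.
#'
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @param n_genes Total number of genes in the simulated matrix.
#' @param stages data.frame as [default_stage_design()]: one row per
#'   (stage, treatment) with replicate count.
#' @param p50_by_stage Named vector of true P50 (days) per fresh stage;
#'   must be non-decreasing in stage order.
#' @param module_size Number of longevity-tracking TFs (planted module).
#' @param tail_size Number of transient TFs peaking around stages 7.2-7.3.
#' @param chloro_size Number of chloroplast-like genes repressed after 7.1.
#' @param n_reference Number of low-variance reference genes.
#' @param n_tf Total number of TF genes (module + tail + filler TFs).
#' @param nb_dispersion NB dispersion alpha (Var = mu + alpha mu^2); > 0.
#' @param lib_size_range Range of library-size multipliers (log-uniform).
#' @param noise_sd Log2-scale Gaussian noise added to module/tail stage means.
#' @param module_amplitude Log2 dynamic range of module genes over the P50
#'   trajectory.
#' @param tail_amplitude Range of log2 bump heights for tail genes.
#' @param drying_mix Mixture weight on stage 7.3 means for the dried-7.2
#'   sample (remainder on stage 8.1); premature drying fast-forwards the
#'   transcriptome to between 7.3 and 8.1.
#' @param families Character vector of TF family labels.
#' @param tail_weights Named numeric sampling weights for the tail cohort's
#'   families; defaults up-weight AP2/EREBP and WRKY.
#'
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       stages = default_stage_design(),
                       p50_by_stage = default_p50(),
                       module_size = 27L,
                       tail_size = 80L,
                       chloro_size = 111L,
                       n_reference = 50L,
                       n_tf = 300L,
                       nb_dispersion = 0.05,
                       lib_size_range = c(0.5, 2),
                       noise_sd = 0.25,
                       module_amplitude = 8,
                       tail_amplitude = c(4.5, 6.5),
                       drying_mix = 0.6,
                       families = tf_families(),
                       tail_weights = NULL) {
  if (length(families) == 0) stop("family list must not be empty")
  if (is.null(tail_weights)) {
    tail_weights <- stats::setNames(rep(1, length(families)), families)
    if ("AP2/EREBP" %in% families) tail_weights["AP2/EREBP"] <- 8
    if ("WRKY" %in% families) tail_weights["WRKY"] <- 4.5
  }
  if (!all(names(tail_weights) %in% families)) {
    stop("tail_weights must be named by declared families")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  key <- paste(stages$stage, stages$treatment)
  if (anyDuplicated(key)) stop("duplicate stage/treatment rows in design")
  fresh <- stages$stage[stages$treatment == "fresh"]
  if (!all(fresh %in% names(p50_by_stage))) {
    stop("p50_by_stage must cover every fresh stage")
  }
  p50 <- p50_by_stage[fresh[order(stages$daf[stages$treatment == "fresh"])]]
  if (is.unsorted(p50)) stop("p50_by_stage must be non-decreasing over fresh stages")
  if (n_genes < module_size + tail_size + chloro_size + n_reference) {
    stop("n_genes too small for the requested cohorts")
  }
  if (n_tf < module_size + tail_size) stop("n_tf must cover module and tail")
  if (n_genes < n_tf + chloro_size + n_reference) {
    stop("n_genes too small for n_tf plus non-TF cohorts")
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         stages = stages, p50_by_stage = p50_by_stage,
         module_size = as.integer(module_size),
         tail_size = as.integer(tail_size),
         chloro_size = as.integer(chloro_size),
         n_reference = as.integer(n_reference), n_tf = as.integer(n_tf),
         nb_dispersion = nb_dispersion, lib_size_range = lib_size_range,
         noise_sd = noise_sd, module_amplitude = module_amplitude,
         tail_amplitude = tail_amplitude, drying_mix = drying_mix,
         families = families, tail_weights = tail_weights),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic seed-maturation study configuration\n")
  cat(sprintf("  genes: %d (module %d, tail %d, chloroplast-like %d, reference %d, TF total %d)\n",
              x$n_genes, x$module_size, x$tail_size, x$chloro_size,
              x$n_reference, x$n_tf))
  cat(sprintf("  libraries: %d; NB dispersion %.3g; log2 noise sd %.3g; seed %d\n",
              sum(x$stages$n_rep), x$nb_dispersion, x$noise_sd, x$seed))
  cat("  P50 (d):", paste(sprintf("%s=%g", names(x$p50_by_stage),
                                  x$p50_by_stage), collapse = ", "), "\n")
  invisible(x)
}
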