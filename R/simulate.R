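# Seeded generators for the synthetic seed-maturation study. All generators
# set the RNG from config$seed so equal seeds give bit-identical output.

gene_ids <- function(n) {
  chr <- sprintf("%02d", ((seq_len(n) - 1L) %% 20L) + 1L)
  num <- sprintf("%06d", seq_len(n))
  paste0("SYN.", chr, "G", num)
}

# log2 stage-mean matrix (genes x fresh stages) plus the dried-7.2 column.
build_log2_means <- function(config) {
  fresh <- config$stages[config$stages$treatment == "fresh", ]
  fresh <- fresh[order(fresh$daf), ]
  stages <- fresh$stage
  daf <- fresh$daf
  n_stage <- length(stages)
  p50 <- config$p50_by_stage[stages]
  ids <- gene_ids(config$n_genes)

  n_mod <- config$module_size; n_tail <- config$tail_size
  n_chl <- config$chloro_size; n_ref <- config$n_reference
  idx_mod <- seq_len(n_mod)
  idx_tail <- n_mod + seq_len(n_tail)
  idx_chl <- n_mod + n_tail + seq_len(n_chl)
  idx_ref <- n_mod + n_tail + n_chl + seq_len(n_ref)
  idx_fill <- setdiff(seq_len(config$n_genes),
                      c(idx_mod, idx_tail, idx_chl, idx_ref))

  m <- matrix(0, config$n_genes, n_stage, dimnames = list(ids, stages))

  # longevity module: log2 means affine in P50 plus stage-wise noise
  p50_unit <- if (max(p50) > 0) p50 / max(p50) else p50
  base_mod <- stats::runif(n_mod, 2, 4)
  m[idx_mod, ] <- outer(base_mod, rep(1, n_stage)) +
    config$module_amplitude * outer(rep(1, n_mod), p50_unit) +
    matrix(stats::rnorm(n_mod * n_stage, 0, config$noise_sd), n_mod)

  # transient tail: Gaussian bump in DAF centred between stages 7.2 and 7.3
  daf_lo <- daf[min(2, n_stage)]; daf_hi <- daf[min(3, n_stage)]
  centre <- stats::runif(n_tail, min(daf_lo, daf_hi), max(daf_lo, daf_hi))
  amp <- stats::runif(n_tail, config$tail_amplitude[1], config$tail_amplitude[2])
  base_tail <- stats::runif(n_tail, 4, 6)
  bump <- exp(-(outer(centre, daf, "-"))^2 / (2 * 3^2))
  m[idx_tail, ] <- base_tail + amp * bump +
    matrix(stats::rnorm(n_tail * n_stage, 0, config$noise_sd), n_tail)

  # chloroplast-like cohort: high at the first stage, monotone decay after
  start <- stats::runif(n_chl, 6, 9)
  steps <- matrix(stats::runif(n_chl * (n_stage - 1), 0.5, 1.5), n_chl)
  m[idx_chl, ] <- cbind(start, start - t(apply(steps, 1, cumsum)))

  # reference genes: flat with log2-scale variance well under 0.1
  base_ref <- stats::runif(n_ref, 5, 8)
  m[idx_ref, ] <- base_ref +
    matrix(stats::rnorm(n_ref * n_stage, 0, 0.05), n_ref)

  # filler genes: smooth random-walk profiles
  if (length(idx_fill)) {
    base_f <- stats::runif(length(idx_fill), 1, 8)
    walk <- matrix(stats::rnorm(length(idx_fill) * (n_stage - 1), 0, 0.8),
                   length(idx_fill))
    m[idx_fill, ] <- cbind(base_f, base_f + t(apply(walk, 1, cumsum)))
  }
  m[m < 0] <- 0

  # dried 7.2: transcriptome fast-forwarded between stages 7.3 and 8.1
  has_dried <- any(config$stages$treatment == "dried")
  dried <- NULL
  if (has_dried && n_stage >= 4) {
    dried <- config$drying_mix * m[, 3] + (1 - config$drying_mix) * m[, 4]
  } else if (has_dried) {
    dried <- m[, n_stage]
  }

  # TF membership: module + tail + uniformly chosen filler genes
  n_extra_tf <- config$n_tf - n_mod - n_tail
  idx_tf <- c(idx_mod, idx_tail,
              if (n_extra_tf > 0) idx_fill[seq_len(n_extra_tf)])

  list(log2_means = m, dried = dried, ids = ids,
       idx = list(module = idx_mod, tail = idx_tail, chloro = idx_chl,
                  reference = idx_ref, filler = idx_fill, tf = idx_tf),
       stages = stages, daf = daf, p50 = p50)
}

#' Generate a synthetic count matrix with planted ground truth
#'
#' Draws a gene x library negative binomial count matrix whose latent log2
#' stage means contain four planted cohorts: a longevity module affine in the
#' P50 trajectory, a transient tail bumping at stages 7.2-7.3, a repressed
#' chloroplast-like cohort, and flat low-variance reference genes. The
#' dried-7.2 libraries use a mixture of the 7.3 and 8.1 stage means.
#'
#' @param config A [sim_config()].
#' @return List with elements `counts` (integer matrix, genes x samples),
#'   `design` (data.frame: sample, stage, daf, treatment, replicate) and
#'   `truth` (cohort gene-id sets, true P50, latent log2 stage means, and
#'   true log2 fold changes for the 9 vs 7.2 and 7.2D vs 7.2F contrasts).
#' @export
generate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lat <- build_log2_means(config)

  des_rows <- config$stages[rep(seq_len(nrow(config$stages)),
                                config$stages$n_rep), ]
  rep_id <- stats::ave(seq_len(nrow(des_rows)),
                       paste(des_rows$stage, des_rows$treatment),
                       FUN = seq_along)
  design <- data.frame(
    sample = sprintf("st%s_%s_r%d", des_rows$stage,
                     ifelse(des_rows$treatment == "fresh", "F", "D"), rep_id),
    stage = des_rows$stage, daf = des_rows$daf,
    treatment = des_rows$treatment, replicate = as.integer(rep_id),
    stringsAsFactors = FALSE)
  design <- design[order(design$daf, design$treatment, design$replicate), ]
  rownames(design) <- NULL

  lsr <- config$lib_size_range
  libsize <- exp(stats::runif(nrow(design), log(lsr[1]), log(lsr[2])))
  counts <- matrix(0L, config$n_genes, nrow(design),
                   dimnames = list(lat$ids, design$sample))
  for (j in seq_len(nrow(design))) {
    mu_log2 <- if (design$treatment[j] == "dried") lat$dried
               else lat$log2_means[, design$stage[j]]
    mu <- libsize[j] * 2^mu_log2
    counts[, j] <- as.integer(stats::rnbinom(config$n_genes, mu = mu,
                                             size = 1 / config$nb_dispersion))
  }

  ids <- lat$ids
  l2m <- lat$log2_means
  truth <- list(
    module_genes = ids[lat$idx$module],
    tail_genes = ids[lat$idx$tail],
    chloro_genes = ids[lat$idx$chloro],
    reference_genes = ids[lat$idx$reference],
    tf_genes = ids[lat$idx$tf],
    true_p50 = lat$p50,
    lib_size = stats::setNames(libsize, design$sample),
    log2_stage_means = l2m,
    log2_dried_means = lat$dried,
    true_log2fc = data.frame(
      gene = ids,
      lfc_9_vs_7.2F = l2m[, ncol(l2m)] - l2m[, "7.2"],
      lfc_7.2D_vs_7.2F = if (is.null(lat$dried)) NA_real_
                         else lat$dried - l2m[, "7.2"],
      stringsAsFactors = FALSE)
  )
  list(counts = counts, design = design, truth = truth)
}

#' Generate storage loss-of-viability curves
#'
#' For each fresh stage, germination probability during storage follows a
#' logistic decay q(t) = 1 / (1 + exp((t - P50) / s)) and replicate counts
#' are drawn Binomial(n_seeds, q(t)). The logistic scale grows with P50
#' (steep immediate loss for non-longevous lots, broader curves as longevity
#' is acquired), so a stage with true P50 = 0 yields essentially no
#' germination at any positive storage time.
#'
#' @param config A [sim_config()].
#' @param times Storage sampling times in days (must be >= 0).
#' @param n_rep Replicates per time point (study protocol: 4).
#' @param n_seeds Seeds per replicate (study protocol: 25).
#' @param scale Logistic scale (days) at the maximal P50.
#' @return data.frame: stage, time_d, replicate, n_seeds, n_germinated, with
#'   the true P50 vector attached as attribute `true_p50`.
#' @export
generate_viability_curves <- function(config, times = seq(0, 70, by = 7),
                                      n_rep = 4, n_seeds = 25, scale = 5) {
  stopifnot(inherits(config, "sim_config"))
  if (any(times < 0)) stop("storage times must be non-negative")
  set.seed(config$seed + 1L)
  fresh <- config$stages[config$stages$treatment == "fresh", ]
  fresh <- fresh[order(fresh$daf), ]
  p50 <- config$p50_by_stage[fresh$stage]
  p50_max <- max(p50, 1)
  out <- do.call(rbind, lapply(seq_along(p50), function(i) {
    s_eff <- max(0.5, scale * p50[i] / p50_max)
    q <- 1 / (1 + exp((times - p50[i]) / s_eff))
    data.frame(
      stage = fresh$stage[i],
      time_d = rep(times, each = n_rep),
      replicate = rep(seq_len(n_rep), times = length(times)),
      n_seeds = n_seeds,
      n_germinated = stats::rbinom(length(times) * n_rep, n_seeds,
                                   rep(q, each = n_rep)),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "true_p50") <- p50
  out
}

#' Generate the gene annotation table
#'
#' Every gene receives at least one GO term and a compartment label; TF genes
#' (module, tail and filler TFs) receive a family drawn from the configured
#' family set. Tail genes oversample families according to
#' `config$tail_weights` (AP2/EREBP and WRKY by default); other TF genes draw
#' families uniformly. The planted module and chloroplast cohorts each share
#' a marker GO term so term-level enrichment has ground truth.
#'
#' @param config A [sim_config()].
#' @return data.frame: gene, family (NA for non-TF genes), go
#'   (semicolon-joined GO ids), compartment ("nuclear" or "chloroplast").
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$families) == 0) stop("family list must not be empty")
  set.seed(config$seed + 2L)
  lat_idx <- local({
    # reproduce the cohort index layout without drawing expression noise
    n_mod <- config$module_size; n_tail <- config$tail_size
    n_chl <- config$chloro_size; n_ref <- config$n_reference
    idx_mod <- seq_len(n_mod)
    idx_tail <- n_mod + seq_len(n_tail)
    idx_chl <- n_mod + n_tail + seq_len(n_chl)
    idx_ref <- n_mod + n_tail + n_chl + seq_len(n_ref)
    idx_fill <- setdiff(seq_len(config$n_genes),
                        c(idx_mod, idx_tail, idx_chl, idx_ref))
    n_extra_tf <- config$n_tf - n_mod - n_tail
    idx_tf <- c(idx_mod, idx_tail,
                if (n_extra_tf > 0) idx_fill[seq_len(n_extra_tf)])
    list(module = idx_mod, tail = idx_tail, chloro = idx_chl, tf = idx_tf)
  })
  ids <- gene_ids(config$n_genes)
  fam <- rep(NA_character_, config$n_genes)
  w <- stats::setNames(rep(0, length(config$families)), config$families)
  w[names(config$tail_weights)] <- config$tail_weights
  fam[lat_idx$tail] <- sample(config$families, length(lat_idx$tail),
                              replace = TRUE, prob = w)
  other_tf <- setdiff(lat_idx$tf, lat_idx$tail)
  fam[other_tf] <- sample(config$families, length(other_tf), replace = TRUE)

  go_pool <- sprintf("GO:%07d", 1:40)
  go <- vapply(seq_len(config$n_genes), function(i) {
    paste(sample(go_pool, sample(1:3, 1)), collapse = ";")
  }, character(1))
  go[lat_idx$module] <- paste(go[lat_idx$module], "GO:SYN0001", sep = ";")
  go[lat_idx$chloro] <- paste(go[lat_idx$chloro], "GO:SYN0002", sep = ";")
  comp <- rep("nuclear", config$n_genes)
  comp[lat_idx$chloro] <- "chloroplast"
  data.frame(gene = ids, family = fam, go = go, compartment = comp,
             stringsAsFactors = FALSE)
}

#' Generate soluble sugar profiles per tissue and DAF
#'
#' Emulates the sugar chemistry of late maturation: glucose and fructose
#' decline to near zero, stachyose rises and plateaus (declining late in
#' cotyledons), sucrose declines in the axis, so the axis RFO/Suc ratio is
#' non-decreasing over development. Replicate noise is a common per-row
#' multiplicative factor so that the RFO/Suc ratio is exactly preserved
#' within replicates.
#'
#' @param config A [sim_config()].
#' @param n_rep Replicates per tissue and DAF (default 3).
#' @return data.frame: tissue, daf, replicate, glc, fru, suc, raf, sta, ver
#'   (mg per g dry weight).
#' @export
generate_sugars <- function(config, n_rep = 3) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  daf <- c(46, 57, 63, 69, 71, 73, 77)
  axis <- data.frame(
    tissue = "axis", daf = daf,
    glc = c(30, 20, 10, 5, 2, 1, 0.5),
    fru = c(15, 10, 5, 2.5, 1, 0.6, 0.3),
    suc = c(80, 80, 70, 55, 45, 40, 38),
    raf = c(1, 2, 3.5, 5, 6, 7, 8),
    sta = c(2, 10, 25, 30, 30, 30, 30),
    ver = c(0.5, 0.9, 1.5, 2, 2.4, 2.7, 3))
  cot <- data.frame(
    tissue = "cotyledon", daf = daf,
    glc = c(25, 18, 6, 3, 1.5, 0.8, 0.4),
    fru = c(12, 8, 3, 1.5, 0.8, 0.4, 0.2),
    suc = c(33, 33, 13, 13, 13, 13, 13),
    raf = c(0.5, 1, 2, 3, 3.5, 4, 4),
    sta = c(1, 3, 8, 15, 22, 24, 17),
    ver = c(0.2, 0.4, 0.8, 1.2, 1.6, 1.8, 1.5))
  base <- rbind(axis, cot)
  out <- base[rep(seq_len(nrow(base)), each = n_rep), ]
  out$replicate <- rep(seq_len(n_rep), times = nrow(base))
  fac <- exp(stats::rnorm(nrow(out), 0, 0.05))
  for (col in c("glc", "fru", "suc", "raf", "sta", "ver")) {
    out[[col]] <- out[[col]] * fac
  }
  rownames(out) <- NULL
  out[, c("tissue", "daf", "replicate", "glc", "fru", "suc", "raf", "sta",
          "ver")]
}

#' Generate qPCR Ct tables consistent with the expression ground truth
#'
#' Target Ct values are derived from the latent log2 stage means (one cycle
#' per log2 unit, inverted), with two flat reference genes, so 2^-ddCt
#' quantification recovers profiles proportional to the simulated expression.
#'
#' @param sim Output of [generate_expression_dataset()].
#' @param genes Gene ids to assay (default: first 3 module genes).
#' @param ct_noise_sd Gaussian Ct noise (cycles).
#' @param seed RNG seed.
#' @return data.frame: gene, sample (fresh stage label), ct_target, ct_ref1,
#'   ct_ref2.
#' @export
simulate_qpcr <- function(sim, genes = utils::head(sim$truth$module_genes, 3),
                          ct_noise_sd = 0.1, seed = 1L) {
  set.seed(seed)
  l2m <- sim$truth$log2_stage_means[genes, , drop = FALSE]
  stages <- colnames(l2m)
  out <- expand.grid(gene = genes, sample = stages,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$ct_target <- 30 - l2m[cbind(out$gene, out$sample)] +
    stats::rnorm(nrow(out), 0, ct_noise_sd)
  out$ct_ref1 <- 22 + stats::rnorm(nrow(out), 0, ct_noise_sd)
  out$ct_ref2 <- 24 + stats::rnorm(nrow(out), 0, ct_noise_sd)
  out
}

#' Simulate the complete synthetic study
#'
#' Convenience wrapper running every generator under one configuration.
#'
#' @param config A [sim_config()].
#' @return List: counts, design, truth, germination, annotation, sugars.
#' @export
simulate_seed_study <- function(config) {
  expr <- generate_expression_dataset(config)
  list(counts = expr$counts, design = expr$design, truth = expr$truth,
       germination = generate_viability_curves(config),
       annotation = generate_annotation(config),
       sugars = generate_sugars(config))
}

#' Write a simulated study to disk as plain-text files
#'
#' Writes counts.tsv, design.tsv, annotation.tsv, germination.csv,
#' sugars.csv and truth.json into `dir`.
#'
#' @param sim Output of [simulate_seed_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cpath <- file.path(dir, "counts.tsv")
  utils::write.table(data.frame(gene = rownames(sim$counts), sim$counts,
                                check.names = FALSE),
                     cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  dpath <- file.path(dir, "design.tsv")
  utils::write.table(sim$design, dpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  apath <- file.path(dir, "annotation.tsv")
  utils::write.table(sim$annotation, apath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gpath <- file.path(dir, "germination.csv")
  utils::write.csv(sim$germination, gpath, row.names = FALSE)
  spath <- file.path(dir, "sugars.csv")
  utils::write.csv(sim$sugars, spath, row.names = FALSE)
  tpath <- file.path(dir, "truth.json")
  truth <- sim$truth
  truth$log2_stage_means <- NULL  # large; regenerate from config if needed
  truth$true_log2fc <- NULL
  jsonlite::write_json(truth, tpath, auto_unbox = TRUE, digits = NA)
  invisible(c(cpath, dpath, apath, gpath, spath, tpath))
}
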