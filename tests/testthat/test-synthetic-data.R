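test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(nb_dispersion = -1), "dispersion")
  des <- default_stage_design()
  expect_error(sim_config(stages = rbind(des, des[1, ])), "duplicate")
  expect_error(sim_config(families = character(0)), "empty")
  expect_error(sim_config(n_genes = 100), "too small")
  bad_p50 <- default_p50(); bad_p50["9"] <- 1
  expect_error(sim_config(p50_by_stage = bad_p50), "non-decreasing")
})

test_that("equal seeds give bit-identical output across all generators", {
  a <- simulate_seed_study(small_config(seed = 11))
  b <- simulate_seed_study(small_config(seed = 11))
  expect_identical(a$counts, b$counts)
  expect_identical(a$design, b$design)
  expect_identical(a$germination, b$germination)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$sugars, b$sugars)
  c <- generate_expression_dataset(small_config(seed = 12))
  expect_false(identical(a$counts, c$counts))
})

test_that("counts are non-negative integers matching the design exactly", {
  sim <- generate_expression_dataset(small_config(seed = 2))
  expect_true(is.integer(sim$counts))
  expect_true(all(sim$counts >= 0))
  expect_identical(colnames(sim$counts), sim$design$sample)
  expect_equal(nrow(sim$design), sum(small_config()$stages$n_rep))
})

test_that("ground-truth cohorts are disjoint and present in the matrix", {
  sim <- generate_expression_dataset(small_config(seed = 3))
  tr <- sim$truth
  sets <- list(tr$module_genes, tr$tail_genes, tr$chloro_genes,
               tr$reference_genes)
  expect_equal(length(unlist(sets)), length(unique(unlist(sets))))
  expect_true(all(unlist(sets) %in% rownames(sim$counts)))
  expect_true(all(tr$module_genes %in% tr$tf_genes))
  expect_true(all(tr$tail_genes %in% tr$tf_genes))
})

test_that("noise-free module stage means are exactly affine in P50", {
  cfg <- small_config(seed = 4, noise_sd = 0)
  sim <- generate_expression_dataset(cfg)
  l2m <- sim$truth$log2_stage_means[sim$truth$module_genes, ]
  p50 <- sim$truth$true_p50
  cors <- apply(l2m, 1, cor, y = p50)
  expect_equal(unname(cors), rep(1, nrow(l2m)), tolerance = 1e-12)
})

test_that("module latent profiles track P50 with |cor| > 0.9 across seeds", {
  cors <- sapply(1:20, function(s) {
    sim <- generate_expression_dataset(small_config(seed = s))
    l2m <- sim$truth$log2_stage_means[sim$truth$module_genes, ]
    mean(abs(apply(l2m, 1, cor, y = sim$truth$true_p50)))
  })
  expect_gt(mean(cors), 0.9)
})

test_that("empirical NB dispersion matches the configured value", {
  cfg <- sim_config(seed = 5)  # default: 2000 genes
  sim <- generate_expression_dataset(cfg)
  # independent method-of-moments oracle over the replicated groups,
  # computed from counts and the known library sizes
  grp <- paste(sim$design$stage, sim$design$treatment)
  reps <- names(which(table(grp) >= 2))
  ests <- unlist(lapply(reps, function(g) {
    cols <- sim$design$sample[grp == g]
    y <- sweep(sim$counts[, cols], 2, sim$truth$lib_size[cols], "/")
    m <- rowMeans(y)
    v <- apply(y, 1, var)
    cc <- mean(1 / sim$truth$lib_size[cols])
    a <- (v - cc * m) / m^2
    a[m >= 5]
  }))
  expect_lt(abs(mean(ests) - cfg$nb_dispersion), 0.25 * cfg$nb_dispersion)
})

test_that("viability curves become step functions in the steep-scale limit", {
  cfg <- small_config(seed = 6)
  g <- generate_viability_curves(cfg, times = c(0, 21, 35), scale = 1e-6)
  # per-stage effective scale is floored near zero: full germination well
  # before P50, none well after
  g72 <- g[g$stage == "7.2", ]  # true P50 = 28
  expect_true(all(g72$n_germinated[g72$time_d == 21] == 25))
  expect_true(all(g72$n_germinated[g72$time_d == 35] == 0))
})

test_that("a stage with true P50 = 0 gives no post-storage germination", {
  g <- generate_viability_curves(small_config(seed = 7))
  g71 <- g[g$stage == "7.1" & g$time_d > 0, ]
  expect_true(all(g71$n_germinated == 0))
})

test_that("germination counts respect the seed count and time validation", {
  g <- generate_viability_curves(small_config(seed = 8))
  expect_true(all(g$n_germinated >= 0 & g$n_germinated <= g$n_seeds))
  expect_error(generate_viability_curves(small_config(), times = c(-1, 5)),
               "non-negative")
})

test_that("tail family draws follow the configured enrichment weights", {
  fams <- tf_families()
  # degenerate weights: every tail gene is AP2/EREBP
  w <- setNames(c(1, rep(0, length(fams) - 1)), fams)
  ann <- generate_annotation(small_config(seed = 9, tail_weights = w))
  sim <- generate_expression_dataset(small_config(seed = 9, tail_weights = w))
  expect_true(all(ann$family[ann$gene %in% sim$truth$tail_genes] ==
                    "AP2/EREBP"))
  # uniform weights: no family significantly enriched in the tail
  wu <- setNames(rep(1, length(fams)), fams)
  cfgu <- small_config(seed = 10, tail_weights = wu)
  annu <- generate_annotation(cfgu)
  simu <- generate_expression_dataset(cfgu)
  enr <- chi2_family_enrichment(simu$truth$tail_genes, simu$truth$tf_genes,
                                annu)
  expect_gt(min(enr$p), 0.01)
})

test_that("every gene is annotated; chloroplast cohort labelled as such", {
  cfg <- small_config(seed = 11)
  ann <- generate_annotation(cfg)
  sim <- generate_expression_dataset(cfg)
  expect_true(all(nchar(ann$go) > 0))
  expect_setequal(ann$gene[ann$compartment == "chloroplast"],
                  sim$truth$chloro_genes)
  tf_ann <- ann$gene[!is.na(ann$family)]
  expect_setequal(tf_ann, sim$truth$tf_genes)
  expect_true(all(ann$family[!is.na(ann$family)] %in% cfg$families))
})

test_that("axis RFO/Suc ratio is non-decreasing over development", {
  sug <- generate_sugars(small_config(seed = 12))
  ax <- sug[sug$tissue == "axis", ]
  for (r in unique(ax$replicate)) {
    d <- ax[ax$replicate == r, ]
    d <- d[order(d$daf), ]
    ratio <- rfo_suc_ratio(d$raf, d$sta, d$ver, d$suc)
    expect_true(all(diff(ratio) >= -1e-12))
  }
  expect_true(all(sug[, c("glc", "fru", "suc", "raf", "sta", "ver")] >= 0))
})

test_that("simulated studies round-trip through the plain-text writers", {
  dir <- withr::local_tempdir()
  sim <- simulate_seed_study(small_config(seed = 13))
  write_simulation(sim, dir)
  counts <- read_counts(file.path(dir, "counts.tsv"))
  expect_identical(counts, sim$counts)
  design <- read_design(file.path(dir, "design.tsv"))
  expect_equal(design, sim$design)
  germ <- read_germination(file.path(dir, "germination.csv"))
  expect_equal(germ$n_germinated, sim$germination$n_germinated)
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(ann$gene, sim$annotation$gene)
  sug <- read_sugars(file.path(dir, "sugars.csv"))
  expect_equal(sug$suc, sim$sugars$suc, tolerance = 1e-10)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$module_genes, sim$truth$module_genes)
})
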