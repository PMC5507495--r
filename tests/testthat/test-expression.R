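test_that("library QC reproduces printed mapping percentages", {
  qc <- library_qc(data.frame(total_reads = c(25673031, 38088839, 100),
                              mapped_reads = c(24112015, 34971702, 100)))
  expect_equal(qc$pct_mapped, c(93.9, 91.8, 100.0))
  expect_equal(attr(qc, "min_pct"), 91.8)
  expect_error(library_qc(data.frame(total_reads = 10, mapped_reads = 11)),
               "exceed")
  expect_error(library_qc(data.frame(total_reads = 0, mapped_reads = 0)),
               "positive")
})

test_that("median-of-ratios size factors match closed forms", {
  counts <- matrix(rpois(200, 50) + 1, 50, 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(size_factors(cbind(counts[, 1], counts[, 1]))),
               c(1, 1))
  two <- cbind(a = counts[, 1], b = 2L * counts[, 1])
  expect_equal(unname(size_factors(two)), c(1 / sqrt(2), sqrt(2)))
  # permutation equivariance
  f <- size_factors(counts)
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(size_factors(counts[, perm])), unname(f[perm]))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "positive counts")
})

test_that("normalization and the log layer follow their definitions", {
  counts <- matrix(c(0, 3, 15), 1, dimnames = list("g", paste0("s", 1:3)))
  norm <- normalize_counts(counts, factors = rep(1, 3))
  expect_equal(unname(norm$log2[1, ]), c(0, 2, 4))
  expect_equal(unname(norm$gene_variance), 4)  # sample variance, n - 1
  # identical columns: zero variance
  same <- normalize_counts(cbind(a = c(5, 9), b = c(5, 9)),
                           factors = c(1, 1))
  expect_equal(unname(same$gene_variance), c(0, 0))
  # doubling counts and factors cancels
  m <- matrix(rpois(40, 30) + 1, 10, 4)
  n1 <- normalize_counts(m, factors = rep(1, 4))
  n2 <- normalize_counts(2L * m, factors = rep(2, 4))
  expect_equal(n1$normalized, n2$normalized)
  expect_error(normalize_counts(m, pseudocount = 0), "pseudocount")
})

test_that("rescaling one library changes normalized values only globally", {
  m <- matrix(rpois(200, 100) + 1, 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  n1 <- normalize_counts(m)
  m2 <- m; m2[, 2] <- 3L * m2[, 2]
  n2 <- normalize_counts(m2)
  # size factors keep geometric mean 1, so the matrix shifts by one global
  # constant; relative expression is preserved exactly
  expect_equal(exp(mean(log(n2$size_factors))), 1)
  ratio <- n2$normalized / n1$normalized
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
  expect_equal(unique(round(as.numeric(ratio), 10)), round(3^(1 / 4), 10))
})

test_that("variance filter is strict and excludes constants", {
  l2 <- rbind(const = rep(3, 3), exact1 = c(0, 1, 2), big = c(0, 3, 6))
  colnames(l2) <- paste0("s", 1:3)
  norm <- norm_from_log2(l2)
  expect_equal(unname(norm$gene_variance["exact1"]), 1)
  expect_equal(variance_filter(norm, 1), "big")
})

test_that("stage ratios divide consecutive stage means after averaging", {
  des <- data.frame(sample = paste0("s", 1:6),
                    stage = c("7.1", "7.1", "7.2", "7.2", "7.3", "7.3"),
                    daf = c(57, 57, 63, 63, 69, 69), treatment = "fresh",
                    replicate = c(1, 2, 1, 2, 1, 2))
  norm <- norm_from_log2(matrix(0, 2, 6,
                                dimnames = list(c("a", "b"), des$sample)))
  norm$normalized <- rbind(a = c(3, 5, 8, 8, 2, 2),
                           b = c(1, 1, 2, 2, 4, 4))
  colnames(norm$normalized) <- des$sample
  r <- stage_ratio(norm, des)
  expect_equal(unname(r["a", ]), c(2, 0.25))   # means (4, 8, 2)
  expect_equal(unname(r["b", ]), c(2, 2))      # doubling each stage
  flat <- norm; flat$normalized[] <- 7
  expect_equal(unname(stage_ratio(flat, des)[1, ]), c(1, 1))
  expect_error(stage_ratio(norm, des[des$stage == "7.1", ]), "2 fresh")
})

test_that("identical groups give null DE results", {
  m <- matrix(rep(c(30L, 60L, 10L), 4), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  de <- de_test(m, c("s1", "s2"), c("s3", "s4"), factors = rep(1, 4),
                dispersion = 0.05)
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$p, rep(1, 3))
  expect_false(any(de$significant))
})

test_that("an exact two-fold ratio satisfies the inclusive threshold", {
  m <- matrix(c(40L, 40L, 20L, 20L), 1,
              dimnames = list("g1", paste0("s", 1:4)))
  de <- de_test(m, c("s1", "s2"), c("s3", "s4"), factors = rep(1, 4),
                dispersion = 1e-4)
  expect_equal(de$log2fc, 1)
  expect_true(de$significant)
  expect_error(de_test(m, c("s1", "nope"), c("s3", "s4")), "unknown samples")
  expect_error(de_test(m, c("s1", "s2"), c("s3", "s4"), factors = rep(1, 4),
                       dispersion = -1), "positive")
})

test_that("adjusted p-values are monotone in raw p and order-invariant", {
  set.seed(41)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  ord <- order(p)
  expect_true(!is.unsorted(adj[ord]))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("pooled moment dispersion recovers the simulation truth", {
  sim <- generate_expression_dataset(small_config(seed = 21))
  sf <- size_factors(sim$counts)
  d <- estimate_dispersion_mom(sim$counts, sf, sim$design)
  expect_lt(abs(as.numeric(d) - 0.05), 0.025)
  one_rep <- sim$design[!duplicated(paste(sim$design$stage,
                                          sim$design$treatment)), ]
  expect_error(estimate_dispersion_mom(
    sim$counts[, one_rep$sample], sf[one_rep$sample], one_rep),
    "no replicated group")
})

test_that("sample correlations match the direct PCC formula", {
  l2 <- matrix(c(1, 2, 3, 2, 4, 6.5, 5, 1, 0), 3,
               dimnames = list(paste0("g", 1:3), c("a", "b", "c")))
  cc <- sample_cor_matrix(norm_from_log2(l2))
  pcc <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(cc["a", "b"], pcc(l2[, "a"], l2[, "b"]), tolerance = 1e-12)
  expect_equal(cc["a", "c"], pcc(l2[, "a"], l2[, "c"]), tolerance = 1e-12)
  expect_equal(diag(cc), c(a = 1, b = 1, c = 1))
  expect_equal(cc, t(cc))
  dup <- norm_from_log2(cbind(l2, d = l2[, "a"]))
  expect_equal(sample_cor_matrix(dup)["a", "d"], 1)
  # perfectly reversed standardized profiles
  rev2 <- norm_from_log2(cbind(x = c(1, 2, 3), y = c(3, 2, 1)))
  expect_equal(sample_cor_matrix(rev2)["x", "y"], -1)
  flat <- norm_from_log2(cbind(x = c(1, 2, 3), y = c(2, 2, 2)))
  expect_error(sample_cor_matrix(flat), "zero variance")
})

test_that("median-centered PCA is deterministic and reproducible", {
  sim <- generate_expression_dataset(small_config(seed = 22))
  norm <- normalize_counts(sim$counts)
  kept <- variance_filter(norm)
  pca <- pca_median_centered(norm, genes = kept)
  expect_true(all(pca$explained >= 0) && sum(pca$explained) <= 1 + 1e-9)
  # sign convention: largest-magnitude loading positive per component
  for (j in 1:2) {
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }
  # duplicated sample lands on identical coordinates
  l2 <- norm$log2[kept, ]
  dup <- norm_from_log2(cbind(l2, dup = l2[, 1]))
  sc <- pca_median_centered(dup)$scores
  expect_equal(sc[1, ], sc["dup", ])
})

test_that("replicate pairs lie closer than other stages in PC space", {
  sim <- generate_expression_dataset(small_config(seed = 23))
  norm <- normalize_counts(sim$counts)
  pca <- pca_median_centered(norm, genes = variance_filter(norm))
  d <- as.matrix(dist(pca$scores))
  des <- sim$design
  for (st in c("7.2", "9")) {
    reps <- des$sample[des$stage == st & des$treatment == "fresh"]
    others <- setdiff(des$sample, reps)
    expect_lt(d[reps[1], reps[2]], min(d[reps, others]))
  }
})
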