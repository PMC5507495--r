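# fixture builders shared across test files

# small but fully-featured study configuration, fast to simulate
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 500, module_size = 27, tail_size = 40,
             chloro_size = 50, n_reference = 20, n_tf = 100, ...)
}

# a norm_matrix built directly from a chosen log2 layer (size factors 1),
# for tests that need exact stage means
norm_from_log2 <- function(log2_layer) {
  structure(list(normalized = 2^log2_layer - 1, log2 = log2_layer,
                 size_factors = rep(1, ncol(log2_layer)),
                 gene_variance = apply(log2_layer, 1, var),
                 pseudocount = 1),
            class = "norm_matrix")
}

# minimal fresh-stage design: one sample per stage
stage_design <- function(stages, daf = seq_along(stages)) {
  data.frame(sample = paste0("s", seq_along(stages)), stage = stages,
             daf = daf, treatment = "fresh", replicate = 1L,
             stringsAsFactors = FALSE)
}
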