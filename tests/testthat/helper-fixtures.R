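# Small, fast configurations and table builders shared across tests.

tiny_config <- function(...) {
  args <- utils::modifyList(list(
    n_founders_per_breed = 4,
    n_f1_pairs = 3,
    n_f2_per_family = 4,
    n_autosomal_genes = 30,
    n_z_genes = 8,
    n_w_genes = 2,
    n_neutral_variants = 10,
    breed_fixed_fraction = 0.3,
    het_null_fraction = 0.2,
    trans_module_size = 4,
    mesenchyme_module_size = 4,
    n_lps_induced = 4,
    n_lps_repressed = 4,
    noise_sd_log2 = 0.1,
    seed = 42
  ), list(...))
  do.call(sim_config, args)
}

# the study-scale cohort used in acceptance-style checks: 15 families,
# 28 F2 birds (6 + 2x8 + 1x6), paired control/LPS samples
cohort_config <- function(...) {
  args <- utils::modifyList(list(seed = 2024), list(...))
  do.call(sim_config, args)
}

# wide expression tibble from a genes x samples matrix
expr_tbl <- function(m, genes = NULL) {
  if (is.null(genes)) genes <- rownames(m)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m))
}

# long genotype tibble from explicit allele vectors
geno_tbl <- function(variant_id, sample, a1, a2, gq = 99) {
  tibble::tibble(variant_id = variant_id, sample = sample,
                 a1 = as.integer(a1), a2 = as.integer(a2),
                 gq = as.numeric(gq))
}
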