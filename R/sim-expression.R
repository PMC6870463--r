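#' Simulate TPM expression under the additive cis model
#'
#' Expression of gene *g* in sample *s* is built multiplicatively from the
#' planted architecture:
#' \deqn{E[g,s] = \mathrm{cis}(g,s) \times \mathrm{dosage}(g,s) \times
#'   2^{\mathrm{lfc}(g,s)} \times \mathrm{mes}(g,s)}
#' where cis is the sum of per-allele-copy effects at the gene's cis locus
#' (a null allele contributes exactly 0, so heterozygote expression is the
#' exact midpoint of the two homozygote classes at zero noise); dosage
#' multiplies the single-copy female value of Z genes by the compensation
#' factor (expected M/F ratio `2/factor`); the LPS term applies the gene's
#' log2 fold change to treated samples, scaled for trans-module genes by
#' `trans_effect_per_alt_allele` once per alternative allele at the trans
#' locus; the mesenchyme term multiplies mesenchyme-module genes by the
#' sample's contamination fraction (and, only when `renormalize_tpm` is
#' set, all other genes by one minus it). The realized value is the
#' expectation times `2^N(0, noise_sd_log2)`. W genes emit exactly 0 in
#' males.
#'
#' @param geno Long genotype tibble covering every individual in `design`.
#' @param genes Ground-truth gene table from [simulate_founders()].
#' @param design Sample sheet tibble: `sample`, `individual`, `sex`
#'   (`"M"`/`"F"`), `family`, `generation`, `treatment` (`"control"` or
#'   `"LPS"`).
#' @param config The [sim_config()].
#' @param trans_locus `variant_id` of the trans-regulator locus (`NA` to
#'   disable trans modulation).
#' @return A list: `expr` (wide tibble, `gene` column + one column per
#'   sample, TPM), `design` (input sheet plus the drawn
#'   `mesenchyme_fraction`), `genes` (the truth table).
#' @export
simulate_expression <- function(geno, genes, design, config,
                                trans_locus = NA_character_) {
  stopifnot(inherits(config, "sim_config"))
  bad_tr <- setdiff(unique(design$treatment), c("control", "LPS"))
  if (length(bad_tr) > 0) {
    stop("treatment labels must be 'control' or 'LPS'; found: ",
         paste(bad_tr, collapse = ", "), call. = FALSE)
  }
  has_sex_genes <- any(genes$chromosome %in% c("Z", "W"))
  if (has_sex_genes && any(is.na(design$sex) | !design$sex %in% c("M", "F"))) {
    stop("configuration error: samples must carry an M/F sex label when ",
         "Z or W genes are simulated", call. = FALSE)
  }
  missing_ind <- setdiff(design$individual, unique(geno$sample))
  if (length(missing_ind) > 0) {
    stop("samples map to ungenotyped individual(s): ",
         paste(utils::head(missing_ind, 5), collapse = ", "), call. = FALSE)
  }

  set.seed(stage_seed(config, "expression"))
  individuals <- unique(design$individual)
  mats <- geno_long_to_matrices(geno, genes$variant_id, individuals)

  # cis term per individual: sum of allele-copy effects at the cis locus
  n_alt <- (mats$a1 == 1L) + ifelse(is.na(mats$a2), 0L, mats$a2 == 1L)
  n_ref <- (mats$a1 == 0L) + ifelse(is.na(mats$a2), 0L, mats$a2 == 0L)
  cis <- genes$effect_ref * n_ref + genes$effect_alt * n_alt

  ind_of <- match(design$individual, individuals)
  expected <- cis[, ind_of, drop = FALSE]
  colnames(expected) <- design$sample

  # Z dosage: females carry one copy; multiply by the compensation factor
  is_z <- genes$chromosome == "Z"
  is_w <- genes$chromosome == "W"
  female <- design$sex == "F"
  if (any(is_z) && any(female)) {
    expected[is_z, female] <- expected[is_z, female] *
      config$dosage_compensation_factor
  }
  if (any(is_w)) expected[is_w, !female] <- 0

  # LPS term, modulated at the trans locus for the trans-target module
  lps_cols <- design$treatment == "LPS"
  if (any(lps_cols)) {
    lfc <- matrix(genes$lps_log2fc, nrow(genes), sum(lps_cols))
    if (!is.na(trans_locus)) {
      tl <- geno[geno$variant_id == trans_locus, ]
      t_alt <- (tl$a1 == 1L) + ifelse(is.na(tl$a2), 0L, tl$a2 == 1L)
      names(t_alt) <- tl$sample
      copies <- t_alt[design$individual[lps_cols]]
      copies[is.na(copies)] <- 0L
      tt <- genes$module == "lps_trans_target"
      scale_row <- config$trans_effect_per_alt_allele ^ copies
      lfc[tt, ] <- lfc[tt, , drop = FALSE] *
        matrix(scale_row, sum(tt), length(scale_row), byrow = TRUE)
    }
    expected[, lps_cols] <- expected[, lps_cols, drop = FALSE] * 2 ^ lfc
  }

  # mesenchyme contamination
  mfrac <- stats::runif(nrow(design), config$mesenchyme_fraction_range[1],
                        config$mesenchyme_fraction_range[2])
  mes <- genes$module == "mesenchyme"
  if (any(mes)) {
    expected[mes, ] <- expected[mes, , drop = FALSE] *
      matrix(mfrac, sum(mes), length(mfrac), byrow = TRUE)
    if (config$renormalize_tpm) {
      expected[!mes, ] <- expected[!mes, , drop = FALSE] *
        matrix(1 - mfrac, sum(!mes), length(mfrac), byrow = TRUE)
    }
  }

  tpm <- expected
  if (config$noise_sd_log2 > 0) {
    tpm <- tpm * 2 ^ matrix(stats::rnorm(length(tpm), 0,
                                         config$noise_sd_log2),
                            nrow(tpm))
  }
  if (any(is_w)) tpm[is_w, !female] <- 0  # exact zero survives noise

  expr <- dplyr::bind_cols(tibble::tibble(gene = genes$gene),
                           tibble::as_tibble(tpm))
  design$mesenchyme_fraction <- mfrac
  list(expr = expr, design = design, genes = genes)
}

#' Simulate the full F2 cohort: genotypes, design and expression
#'
#' Runs the whole generative pipeline: founder panel, pedigree, gene drop,
#' paired control/LPS sample sheet over all F2 birds, and the TPM matrix.
#'
#' @param config A [sim_config()].
#' @return A list of class `sib_cohort`: `config`, `pedigree`, `variants`,
#'   `geno` (all individuals), `genes` (ground truth), `samples` (sample
#'   sheet incl. mesenchyme fractions), `expr` (wide TPM tibble),
#'   `trans_locus`, `founders` (founder ids).
#' @examples
#' co <- simulate_cross(sim_config(n_autosomal_genes = 40, n_z_genes = 10,
#'                                 n_w_genes = 2, n_neutral_variants = 10,
#'                                 trans_module_size = 5,
#'                                 mesenchyme_module_size = 5,
#'                                 n_lps_induced = 5, n_lps_repressed = 5,
#'                                 n_f1_pairs = 4, n_f2_per_family = 3,
#'                                 seed = 11))
#' dim(co$expr)
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- simulate_founders(config)
  ped <- build_pedigree(config, fs$individuals)
  geno <- gene_drop(ped, fs, seed = stage_seed(config, "gene_drop"))

  f2 <- ped[ped$generation == 2L, ]
  design <- tibble::tibble(
    sample = c(paste0(f2$id, "_ctrl"), paste0(f2$id, "_lps")),
    individual = rep(f2$id, 2L),
    sex = rep(f2$sex, 2L),
    family = rep(f2$family, 2L),
    generation = 2L,
    treatment = rep(c("control", "LPS"), each = nrow(f2))
  )
  sim <- simulate_expression(geno, fs$genes, design, config,
                             trans_locus = fs$trans_locus)
  structure(list(config = config, pedigree = ped, variants = fs$variants,
                 geno = geno, genes = sim$genes, samples = sim$design,
                 expr = sim$expr, trans_locus = fs$trans_locus,
                 founders = fs$individuals$id),
            class = "sib_cohort")
}

#' @export
print.sib_cohort <- function(x, ...) {
  cat("<sib_cohort> ", sum(x$pedigree$generation == 2L), " F2 birds in ",
      length(unique(stats::na.omit(x$pedigree$family))), " families; ",
      nrow(x$expr), " genes x ", nrow(x$samples), " samples; ",
      nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}
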