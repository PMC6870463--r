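#' Simulation configuration for the two-breed F2 intercross design
#'
#' Builds and validates the parameter set that drives every stage of the
#' synthetic cohort: the breeding design (founders per breed, F1 sibling
#' pairs, F2 family sizes), the gene panel (autosomal / Z / W gene counts),
#' the genetic architecture (breed near-fixation, heterozygous null
#' expression alleles), and the expression model (baseline TPM, Z dosage
#' compensation, LPS induction, a trans-regulated LPS module, mesenchymal
#' contamination, multiplicative log-normal noise).
#'
#' @param n_founders_per_breed Founders sequenced per breed (split as evenly
#'   as possible between sexes).
#' @param n_f1_pairs Number of F1 brother-sister matings, i.e. F2 families.
#' @param n_f2_per_family F2 birds per family; a single count recycled to
#'   all families or a vector of length `n_f1_pairs`.
#' @param n_autosomal_genes,n_z_genes,n_w_genes Genes simulated per
#'   chromosome class. W genes are expressed only in females.
#' @param n_neutral_variants Extra non-genic biallelic variants carried
#'   through the pedigree (they feed the variant-panel and PCA stages but
#'   have no expression effect).
#' @param breed_fixed_fraction Proportion of variants whose alternative
#'   allele is near-fixed in one breed and near-absent in the other
#'   (frequencies drawn above 0.95 / below 0.05).
#' @param het_null_fraction Proportion of autosomal genes carrying a null
#'   expression allele (cis effect exactly 0) heterozygous in exactly one
#'   founder.
#' @param baseline_tpm_range Two positive numbers; per-gene baseline
#'   expression of a functional homozygote is drawn log-uniformly on this
#'   interval (TPM).
#' @param dosage_compensation_factor Multiplier on single-Z female
#'   expression, in \[1, 2\]. The expected male/female ratio of a Z gene is
#'   `2 / factor`: 1 gives the fully uncompensated 2-fold ratio, 2 full
#'   compensation, 4/3 the ~1.5-fold ratio seen in hatchling spleen.
#' @param lps_log2fc_location,lps_log2fc_scale Location and scale of the
#'   half-normal log2 fold-change magnitudes given to LPS-responsive genes
#'   (`location + scale * |N(0,1)|`).
#' @param n_lps_induced,n_lps_repressed Constitutively LPS-responsive genes
#'   planted outside the trans module.
#' @param trans_module_size Genes in the trans-regulated LPS-inducible
#'   module. Their induction is modulated by the genotype at a dedicated
#'   breed-fixed trans locus.
#' @param trans_effect_per_alt_allele Multiplicative scalar applied to the
#'   module log2 fold change once per alternative allele carried at the
#'   trans locus (0.5 halves the induction per copy).
#' @param mesenchyme_module_size Genes tracking the contaminating
#'   mesenchymal fraction of each culture.
#' @param mesenchyme_fraction_range Per-sample contamination fraction is
#'   drawn uniformly on this sub-interval of \[0, 1\].
#' @param renormalize_tpm If `TRUE`, columns are rescaled so that
#'   non-mesenchyme genes are multiplied by (1 - fraction), emulating TPM
#'   compositional coupling. Default `FALSE` so planted effects stay
#'   exactly recoverable.
#' @param noise_sd_log2 Standard deviation of the multiplicative log2-normal
#'   noise applied to every expression value.
#' @param low_expression_allele_effect Cis effect (fraction of the
#'   functional-allele effect) given to "null" alleles; 0 is a true null,
#'   small positive values emulate hypomorphic low-expression alleles.
#' @param seed Master seed; named substreams are derived from it so each
#'   stage is independently reproducible.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_autosomal_genes = 50, n_z_genes = 10, seed = 1)
#' cfg$n_f1_pairs
#' @export
sim_config <- function(n_founders_per_breed = 10,
                       n_f1_pairs = 15,
                       n_f2_per_family = c(6, rep(2, 8), rep(1, 6)),
                       n_autosomal_genes = 400,
                       n_z_genes = 200,
                       n_w_genes = 20,
                       n_neutral_variants = 200,
                       breed_fixed_fraction = 0.3,
                       het_null_fraction = 0.1,
                       baseline_tpm_range = c(50, 500),
                       dosage_compensation_factor = 4 / 3,
                       lps_log2fc_location = 2,
                       lps_log2fc_scale = 1,
                       n_lps_induced = 50,
                       n_lps_repressed = 40,
                       trans_module_size = 40,
                       trans_effect_per_alt_allele = 0.5,
                       mesenchyme_module_size = 40,
                       mesenchyme_fraction_range = c(0.2, 0.5),
                       renormalize_tpm = FALSE,
                       noise_sd_log2 = 0.2,
                       low_expression_allele_effect = 0,
                       seed = 1L) {
  cfg <- list(
    n_founders_per_breed = as.integer(n_founders_per_breed),
    n_f1_pairs = as.integer(n_f1_pairs),
    n_f2_per_family = as.integer(n_f2_per_family),
    n_autosomal_genes = as.integer(n_autosomal_genes),
    n_z_genes = as.integer(n_z_genes),
    n_w_genes = as.integer(n_w_genes),
    n_neutral_variants = as.integer(n_neutral_variants),
    breed_fixed_fraction = breed_fixed_fraction,
    het_null_fraction = het_null_fraction,
    baseline_tpm_range = as.numeric(baseline_tpm_range),
    dosage_compensation_factor = dosage_compensation_factor,
    lps_log2fc_location = lps_log2fc_location,
    lps_log2fc_scale = lps_log2fc_scale,
    n_lps_induced = as.integer(n_lps_induced),
    n_lps_repressed = as.integer(n_lps_repressed),
    trans_module_size = as.integer(trans_module_size),
    trans_effect_per_alt_allele = trans_effect_per_alt_allele,
    mesenchyme_module_size = as.integer(mesenchyme_module_size),
    mesenchyme_fraction_range = as.numeric(mesenchyme_fraction_range),
    renormalize_tpm = isTRUE(renormalize_tpm),
    noise_sd_log2 = noise_sd_log2,
    low_expression_allele_effect = low_expression_allele_effect,
    seed = as.integer(seed)
  )
  if (length(cfg$n_f2_per_family) == 1L) {
    cfg$n_f2_per_family <- rep(cfg$n_f2_per_family, cfg$n_f1_pairs)
  }
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_founders_per_breed", "n_f1_pairs", "n_autosomal_genes",
              "n_z_genes", "n_w_genes", "n_neutral_variants",
              "n_lps_induced", "n_lps_repressed", "trans_module_size",
              "mesenchyme_module_size")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 0L) {
      stop("`", nm, "` must be a single nonnegative count", call. = FALSE)
    }
  }
  if (cfg$n_founders_per_breed < 2L) {
    stop("`n_founders_per_breed` must be at least 2 ",
         "(one founder of each sex per breed)", call. = FALSE)
  }
  if (length(cfg$n_f2_per_family) != cfg$n_f1_pairs ||
      any(cfg$n_f2_per_family < 0L)) {
    stop("`n_f2_per_family` must give a nonnegative count per F1 pair",
         call. = FALSE)
  }
  for (nm in c("breed_fixed_fraction", "het_null_fraction")) {
    v <- cfg[[nm]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("`", nm, "` must be a proportion in [0, 1]", call. = FALSE)
    }
  }
  rng <- cfg$baseline_tpm_range
  if (length(rng) != 2L || any(rng <= 0) || rng[2] < rng[1]) {
    stop("`baseline_tpm_range` must be a positive increasing interval",
         call. = FALSE)
  }
  d <- cfg$dosage_compensation_factor
  if (length(d) != 1L || is.na(d) || d < 1 || d > 2) {
    stop("`dosage_compensation_factor` must lie in [1, 2]", call. = FALSE)
  }
  mfr <- cfg$mesenchyme_fraction_range
  if (length(mfr) != 2L || any(mfr < 0) || any(mfr > 1) || mfr[2] < mfr[1]) {
    stop("`mesenchyme_fraction_range` must be an interval inside [0, 1]",
         call. = FALSE)
  }
  if (cfg$noise_sd_log2 < 0) {
    stop("`noise_sd_log2` must be nonnegative", call. = FALSE)
  }
  if (cfg$low_expression_allele_effect < 0 ||
      cfg$low_expression_allele_effect >= 1) {
    stop("`low_expression_allele_effect` must lie in [0, 1)", call. = FALSE)
  }
  n_genic <- cfg$n_autosomal_genes + cfg$n_z_genes + cfg$n_w_genes
  n_special <- cfg$n_lps_induced + cfg$n_lps_repressed +
    cfg$trans_module_size + cfg$mesenchyme_module_size
  if (n_special > cfg$n_autosomal_genes) {
    stop("module and LPS gene counts exceed `n_autosomal_genes`",
         call. = FALSE)
  }
  if (n_genic + cfg$n_neutral_variants < 1L) {
    stop("configuration simulates no loci at all", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  design: ", 2L * x$n_founders_per_breed, " founders, ",
      x$n_f1_pairs, " F1 sib pairs, ",
      sum(x$n_f2_per_family), " F2 birds\n", sep = "")
  cat("  genes:  ", x$n_autosomal_genes, " autosomal / ",
      x$n_z_genes, " Z / ", x$n_w_genes, " W; ",
      x$n_neutral_variants, " neutral variants\n", sep = "")
  cat("  model:  het-null fraction ", x$het_null_fraction,
      ", dosage factor ", signif(x$dosage_compensation_factor, 4),
      ", noise sd(log2) ", x$noise_sd_log2, "\n", sep = "")
  cat("  seed:   ", x$seed, "\n", sep = "")
  invisible(x)
}

# Named substreams off the master seed: each stage reseeds from a stable
# offset so regenerating one stage never perturbs another.
stage_seed <- function(cfg_or_seed, stage) {
  seed <- if (inherits(cfg_or_seed, "sim_config")) cfg_or_seed$seed
          else as.integer(cfg_or_seed)
  offsets <- c(founders = 101L, pedigree = 211L, gene_drop = 307L,
               expression = 401L, design = 503L, segregation = 601L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (seed %% 1000000L) * 1000L + offsets[[stage]]
}
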