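#' Simulate founder genotypes and planted expression architecture
#'
#' Draws two breed-labelled founder panels (broiler and layer) genotyped at
#' every simulated locus, together with the ground-truth gene table: per-gene
#' cis allele effects (a null allele has effect exactly 0), module
#' membership (constitutive, mesenchyme, LPS-induced/repressed, trans-target)
#' and the cis variant each gene is tied to.
#'
#' A `breed_fixed_fraction` of non-null loci is near-fixed for the
#' alternative allele in one breed (realized alt-allele frequency at least
#' 0.95) and near-absent in the other (at most 0.05), emulating
#' breed-enriched haplotypes. A `het_null_fraction` of autosomal genes
#' carries a null allele heterozygous in exactly one founder, the situation
#' that yields the 1/16 homozygote expectation in F2. One dedicated
#' autosomal locus, breed-fixed by construction, acts as the trans regulator
#' of the LPS-inducible module. Z loci are hemizygous in females and W loci
#' absent in males.
#'
#' @param config A [sim_config()].
#' @return A list with class `founder_sim`:
#' \describe{
#'   \item{individuals}{tibble: `id`, `sex` (`"M"`/`"F"`), `generation` (0),
#'     `family` (`NA`), `breed`, `sire`, `dam`.}
#'   \item{variants}{tibble: `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'     `qual`, `gene`, `consequence`.}
#'   \item{geno}{long tibble of calls: `variant_id`, `sample`, `a1`, `a2`
#'     (0 = ref, 1 = alt, `NA` = no allele at hemizygous/absent loci),
#'     `gq`.}
#'   \item{genes}{ground-truth tibble: `gene`, `chromosome` class
#'     (`autosome`/`Z`/`W`), `module`, `baseline_tpm`, `effect_ref`,
#'     `effect_alt` (per allele copy, TPM), `null_gene`, `lps_log2fc`,
#'     `variant_id` of the cis locus.}
#'   \item{trans_locus}{`variant_id` of the trans-regulator locus (or `NA`
#'     when the module is empty).}
#' }
#' @examples
#' fs <- simulate_founders(sim_config(n_autosomal_genes = 30, n_z_genes = 5,
#'                                    n_w_genes = 2, n_neutral_variants = 10,
#'                                    trans_module_size = 5,
#'                                    mesenchyme_module_size = 5,
#'                                    n_lps_induced = 5, n_lps_repressed = 5,
#'                                    seed = 7))
#' dplyr::count(fs$genes, module)
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_founders_per_breed <= 0L) {
    stop("configuration error: zero founders requested", call. = FALSE)
  }
  set.seed(stage_seed(config, "founders"))

  nb <- config$n_founders_per_breed
  individuals <- tibble::tibble(
    id = c(sprintf("F0_BR_%02d", seq_len(nb)),
           sprintf("F0_LA_%02d", seq_len(nb))),
    sex = rep(rep_len(c("M", "F"), nb), 2L),
    generation = 0L,
    family = NA_character_,
    breed = rep(c("broiler", "layer"), each = nb),
    sire = NA_character_,
    dam = NA_character_
  )

  genes <- build_gene_table(config)
  variants <- build_variant_table(config, genes)
  genes <- dplyr::left_join(genes, attr(variants, "gene_vid"), by = "gene")

  # Which loci are breed-fixed: null cis loci are excluded (their alt allele
  # is the rare het null), the trans locus is forced in.
  null_vids <- genes$variant_id[genes$null_gene]
  trans_vid <- attr(variants, "trans_locus")
  eligible <- setdiff(variants$variant_id, c(null_vids, trans_vid))
  n_fixed <- round(config$breed_fixed_fraction * length(eligible))
  fixed_vids <- sample(eligible, n_fixed)
  if (!is.na(trans_vid)) fixed_vids <- c(fixed_vids, trans_vid)

  geno <- draw_founder_genotypes(variants, individuals, fixed_vids,
                                 null_vids, trans_vid)

  structure(list(individuals = individuals, variants = variants,
                 geno = geno, genes = genes, trans_locus = trans_vid),
            class = "founder_sim")
}

build_gene_table <- function(config) {
  na <- config$n_autosomal_genes
  gene_auto <- if (na > 0) sprintf("gene_A%03d", seq_len(na)) else character()
  gene_z <- if (config$n_z_genes > 0) {
    sprintf("gene_Z%03d", seq_len(config$n_z_genes))
  } else character()
  gene_w <- if (config$n_w_genes > 0) {
    sprintf("gene_W%03d", seq_len(config$n_w_genes))
  } else character()

  module <- rep("constitutive", na)
  idx <- seq_len(na)
  take <- function(n) {
    got <- utils::head(idx, n)
    idx <<- utils::tail(idx, length(idx) - length(got))
    got
  }
  module[take(config$mesenchyme_module_size)] <- "mesenchyme"
  module[take(config$trans_module_size)] <- "lps_trans_target"
  module[take(config$n_lps_induced)] <- "lps_induced"
  module[take(config$n_lps_repressed)] <- "lps_repressed"

  genes <- tibble::tibble(
    gene = c(gene_auto, gene_z, gene_w),
    chromosome = c(rep("autosome", na),
                   rep("Z", config$n_z_genes),
                   rep("W", config$n_w_genes)),
    module = c(module, rep("constitutive",
                           config$n_z_genes + config$n_w_genes))
  )
  genes$baseline_tpm <- exp(stats::runif(
    nrow(genes),
    log(config$baseline_tpm_range[1]),
    log(config$baseline_tpm_range[2])
  ))

  # Per-copy cis effects: diploid classes see effect * 2 at homozygosity,
  # single-copy W genes carry the full baseline on their one allele.
  genes$effect_ref <- ifelse(genes$chromosome == "W",
                             genes$baseline_tpm, genes$baseline_tpm / 2)
  genes$effect_alt <- genes$effect_ref

  # Null expression alleles on autosomal genes: alt allele effect 0 (or a
  # configurable hypomorphic fraction), heterozygous in one founder only.
  genes$null_gene <- FALSE
  auto_idx <- which(genes$chromosome == "autosome")
  n_null <- round(config$het_null_fraction * length(auto_idx))
  if (n_null > 0) {
    null_idx <- sample(auto_idx, n_null)
    genes$null_gene[null_idx] <- TRUE
    genes$effect_alt[null_idx] <-
      genes$effect_ref[null_idx] * config$low_expression_allele_effect
  }

  # LPS log2 fold-change magnitudes: half-normal above a location, signed by
  # module; trans targets share the induced distribution before modulation.
  mag <- config$lps_log2fc_location +
    config$lps_log2fc_scale * abs(stats::rnorm(nrow(genes)))
  genes$lps_log2fc <- dplyr::case_when(
    genes$module %in% c("lps_induced", "lps_trans_target") ~ mag,
    genes$module == "lps_repressed" ~ -mag,
    TRUE ~ 0
  )
  genes
}

build_variant_table <- function(config, genes) {
  n_genes <- nrow(genes)
  chrom <- dplyr::case_when(
    genes$chromosome == "Z" ~ "chrZ",
    genes$chromosome == "W" ~ "chrW",
    TRUE ~ paste0("chr", 1L + (seq_len(n_genes) - 1L) %% 10L)
  )
  gene_var <- tibble::tibble(
    chrom = chrom, gene = genes$gene,
    consequence = ifelse(genes$null_gene,
                         sample(c("stop_gained", "start_lost", "stop_lost",
                                  "splice_acceptor", "splice_donor"),
                                n_genes, replace = TRUE),
                         "other")
  )
  neutral <- if (config$n_neutral_variants > 0) {
    tibble::tibble(
      chrom = paste0("chr",
                     1L + (seq_len(config$n_neutral_variants) - 1L) %% 10L),
      gene = NA_character_,
      consequence = "other"
    )
  } else {
    tibble::tibble(chrom = character(), gene = character(),
                   consequence = character())
  }
  trans <- if (config$trans_module_size > 0) {
    tibble::tibble(chrom = "chr11", gene = "IRF_like_regulator",
                   consequence = "other")
  } else {
    tibble::tibble(chrom = character(), gene = character(),
                   consequence = character())
  }
  variants <- dplyr::bind_rows(gene_var, neutral, trans)
  variants <- variants |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(pos = 10000L * dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      ref = sample(c("A", "C", "G", "T"), dplyr::n(), replace = TRUE),
      qual = round(stats::runif(dplyr::n(), 50, 1500), 1),
      variant_id = paste0(.data$chrom, ":", .data$pos)
    )
  variants$alt <- purrr::map_chr(variants$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1L)
  })
  variants <- variants[, c("variant_id", "chrom", "pos", "ref", "alt",
                           "qual", "gene", "consequence")]
  # Tie genes to their cis locus.
  genes$variant_id <- variants$variant_id[match(genes$gene, variants$gene)]
  trans_vid <- if (config$trans_module_size > 0) {
    variants$variant_id[variants$gene == "IRF_like_regulator"][1]
  } else NA_character_
  attr(variants, "trans_locus") <- trans_vid
  # Propagate the variant ids back to the caller's gene table by attribute:
  # simulate_founders rebuilds `genes` with the join below.
  attr(variants, "gene_vid") <- genes[, c("gene", "variant_id")]
  variants
}

draw_founder_genotypes <- function(variants, individuals, fixed_vids,
                                   null_vids, trans_vid) {
  n_var <- nrow(variants)
  ids <- individuals$id
  sexes <- individuals$sex
  breeds <- individuals$breed
  is_z <- variants$chrom == "chrZ"
  is_w <- variants$chrom == "chrW"
  # Allele-slot counts: autosome 2, Z 2 (M) / 1 (F), W 0 (M) / 1 (F).
  a1 <- matrix(0L, n_var, length(ids), dimnames = list(variants$variant_id,
                                                       ids))
  a2 <- a1
  a2[is_z, sexes == "F"] <- NA_integer_
  a1[is_w, sexes == "M"] <- NA_integer_
  a2[is_w, ] <- NA_integer_
  a2[is_w, sexes == "F"] <- NA_integer_

  is_fixed <- variants$variant_id %in% fixed_vids
  is_null <- variants$variant_id %in% null_vids
  alt_breed <- rep(NA_character_, n_var)
  alt_breed[is_fixed] <- sample(c("broiler", "layer"), sum(is_fixed),
                                replace = TRUE)
  if (!is.na(trans_vid)) {
    alt_breed[variants$variant_id == trans_vid] <- "broiler"
  }
  common_af <- stats::runif(n_var, 0.1, 0.6)

  for (v in seq_len(n_var)) {
    slots1 <- !is.na(a1[v, ])
    slots2 <- !is.na(a2[v, ])
    if (is_null[v]) {
      # exactly one founder heterozygous for the (autosomal) null allele
      carrier <- sample(which(slots1 & slots2), 1L)
      a1[v, carrier] <- 1L
      next
    }
    if (is_fixed[v]) {
      for (b in c("broiler", "layer")) {
        in_b <- breeds == b
        n_slots <- sum(slots1 & in_b) + sum(slots2 & in_b)
        # minority alleles capped at floor(5% of slots): realized
        # frequencies are >= 0.95 / <= 0.05 by construction
        n_minor <- sample.int(floor(0.05 * n_slots) + 1L, 1L) - 1L
        major <- if (b == alt_breed[v]) 1L else 0L
        vals <- rep(major, n_slots)
        if (n_minor > 0) vals[sample.int(n_slots, n_minor)] <- 1L - major
        k1 <- sum(slots1 & in_b)
        a1[v, slots1 & in_b] <- vals[seq_len(k1)]
        if (sum(slots2 & in_b) > 0) {
          a2[v, slots2 & in_b] <- vals[(k1 + 1L):n_slots]
        }
      }
    } else {
      a1[v, slots1] <- stats::rbinom(sum(slots1), 1L, common_af[v])
      a2[v, slots2] <- stats::rbinom(sum(slots2), 1L, common_af[v])
    }
  }
  geno_matrices_to_long(a1, a2, gq = 99)
}

geno_matrices_to_long <- function(a1, a2, gq = 99) {
  tibble::tibble(
    variant_id = rep(rownames(a1), times = ncol(a1)),
    sample = rep(colnames(a1), each = nrow(a1)),
    a1 = as.integer(a1),
    a2 = as.integer(a2),
    gq = as.numeric(gq)
  )
}

geno_long_to_matrices <- function(geno, variant_ids = NULL,
                                  sample_ids = NULL) {
  if (is.null(variant_ids)) variant_ids <- unique(geno$variant_id)
  if (is.null(sample_ids)) sample_ids <- unique(geno$sample)
  vi <- match(geno$variant_id, variant_ids)
  si <- match(geno$sample, sample_ids)
  a1 <- matrix(NA_integer_, length(variant_ids), length(sample_ids),
               dimnames = list(variant_ids, sample_ids))
  a2 <- a1
  keep <- !is.na(vi) & !is.na(si)
  a1[cbind(vi[keep], si[keep])] <- geno$a1[keep]
  a2[cbind(vi[keep], si[keep])] <- geno$a2[keep]
  list(a1 = a1, a2 = a2)
}
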