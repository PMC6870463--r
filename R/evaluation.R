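#' Recovery of planted null alleles from a simulated cohort
#'
#' Compares the extreme-variation screen against the simulator's ground
#' truth. A planted null gene counts as *segregating* in the cohort when
#' at least one profiled F2 bird is homozygous for the null allele and at
#' least one carries a functional allele. Sensitivity is the fraction of
#' segregating null genes flagged by the extreme-variation criterion
#' (union of the control and LPS qualifying sets); the near-zero check
#' asks, per flagged gene, whether every hom-null bird lands in the
#' dosage group whose raw mean is below `null_tpm`. False nulls are
#' non-null genes that qualify.
#'
#' @param cohort A `sib_cohort` from [simulate_cross()].
#' @param max_thresh,min_thresh Extreme-variation thresholds (20 / 1).
#' @param null_tpm Near-zero group threshold passed to
#'   [classify_dosage_groups()].
#' W-chromosome genes qualify for the extreme-variation criterion
#' trivially (they are structurally zero in males), so they are tallied
#' apart (`n_flagged_w`) rather than as false nulls; real analyses
#' likewise report chromosome class next to the flag.
#'
#' @return A list: `per_gene` tibble (`gene`, `segregating_null`,
#'   `flagged`, `hom_null_in_null_group`), `sensitivity`,
#'   `null_group_rate` (fraction of flagged segregating-null genes whose
#'   hom-null birds all sit in the near-zero group), `n_false_null`
#'   (flagged non-null genes outside the W chromosome), `n_flagged_w`,
#'   `n_segregating`.
#' @export
planted_null_recovery <- function(cohort, max_thresh = 20,
                                  min_thresh = 1, null_tpm = 1) {
  stopifnot(inherits(cohort, "sib_cohort"))
  samples <- cohort$samples
  ctrl <- samples$sample[samples$treatment == "control"]
  lps <- samples$sample[samples$treatment == "LPS"]
  ev <- extreme_variation_sets(cohort$expr[, c("gene", ctrl)],
                               cohort$expr[, c("gene", lps)],
                               max_thresh = max_thresh,
                               min_thresh = min_thresh)
  flagged <- unique(c(ev$control_only, ev$lps_only, ev$shared))

  birds <- unique(samples$individual)
  null_genes <- cohort$genes[cohort$genes$null_gene, ]
  geno <- cohort$geno[cohort$geno$sample %in% birds &
                        cohort$geno$variant_id %in% null_genes$variant_id, ]
  seg <- geno |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      n_hom_null = sum(.data$a1 == 1L & .data$a2 == 1L, na.rm = TRUE),
      n_functional = sum(.data$a1 + .data$a2 < 2L, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(segregating = .data$n_hom_null > 0 &
                    .data$n_functional > 0)
  null_genes <- dplyr::left_join(null_genes, seg, by = "variant_id")

  m <- expr_values(cohort$expr[, c("gene", ctrl)])
  ind_of <- samples$individual[match(colnames(m), samples$sample)]
  in_null_group <- vapply(seq_len(nrow(null_genes)), function(i) {
    g <- null_genes$gene[i]
    if (!isTRUE(null_genes$segregating[i]) || !(g %in% flagged)) {
      return(NA)
    }
    vals <- m[g, ]
    names(vals) <- colnames(m)
    dg <- classify_dosage_groups(vals, null_tpm = null_tpm)
    if (is.na(dg$null_group)) return(FALSE)
    gg <- cohort$geno[cohort$geno$variant_id == null_genes$variant_id[i], ]
    hom_null_birds <- gg$sample[!is.na(gg$a1) & !is.na(gg$a2) &
                                  gg$a1 == 1L & gg$a2 == 1L]
    cols <- names(vals)[ind_of %in% hom_null_birds]
    if (length(cols) == 0) return(NA)
    all(dg$assignment$group[match(cols, dg$assignment$sample)] ==
          dg$null_group)
  }, logical(1))

  per_gene <- tibble::tibble(
    gene = null_genes$gene,
    segregating_null = isTRUE_vec(null_genes$segregating),
    flagged = null_genes$gene %in% flagged,
    hom_null_in_null_group = in_null_group
  )
  n_seg <- sum(per_gene$segregating_null)
  sens <- if (n_seg > 0) {
    sum(per_gene$flagged & per_gene$segregating_null) / n_seg
  } else NA_real_
  checked <- per_gene$hom_null_in_null_group[
    !is.na(per_gene$hom_null_in_null_group)]
  w_genes <- cohort$genes$gene[cohort$genes$chromosome == "W"]
  false_null <- setdiff(flagged,
                        c(cohort$genes$gene[cohort$genes$null_gene],
                          w_genes))
  list(per_gene = per_gene,
       sensitivity = sens,
       null_group_rate = if (length(checked) > 0) mean(checked)
                         else NA_real_,
       n_false_null = length(false_null),
       n_flagged_w = length(intersect(flagged, w_genes)),
       n_segregating = n_seg)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Recovery of the planted trans-regulated LPS module by clustering
#'
#' Builds the gene-to-gene correlation graph of the cohort at `r_min`,
#' clusters it with MCL, and reports how much of the planted
#' trans-target module is captured by the single best cluster, together
#' with that cluster's LPS trend label.
#'
#' @param cohort A `sib_cohort`.
#' @param r_min Edge threshold (default 0.85).
#' @param inflation MCL inflation (default 1.7).
#' @param min_max_tpm Expression filter before correlation (default 10).
#' @return A list: `recall` (fraction of module genes in the best
#'   cluster), `cluster` (its number), `trend` (its profile label),
#'   `module_size`, `cluster_size`, `clusters` (the `mcl_clusters`
#'   object).
#' @export
trans_module_recovery <- function(cohort, r_min = 0.85, inflation = 1.7,
                                  min_max_tpm = 10) {
  stopifnot(inherits(cohort, "sib_cohort"))
  module <- cohort$genes$gene[cohort$genes$module == "lps_trans_target"]
  if (length(module) == 0) stop("cohort has no trans-target module",
                                call. = FALSE)
  expressed <- filter_expressed(cohort$expr, min_max_tpm)
  corr <- correlation_matrix(expressed)
  gr <- threshold_graph(corr, r_min)
  cl <- mcl(gr, inflation = inflation)
  mem <- cl$membership
  mod_cl <- mem$cluster[mem$node %in% module]
  tab <- sort(table(mod_cl), decreasing = TRUE)
  if (length(tab) == 0) {
    return(list(recall = 0, cluster = NA_integer_, trend = NA_character_,
                module_size = length(module), cluster_size = NA_integer_,
                clusters = cl))
  }
  best <- as.integer(names(tab)[1])
  prof <- cluster_profiles(cl, expressed, cohort$samples)
  list(recall = unname(tab[1]) / length(module),
       cluster = best,
       trend = prof$trend[prof$cluster == best],
       module_size = length(module),
       cluster_size = cl$sizes$size[cl$sizes$cluster == best],
       clusters = cl)
}

#' Recovery of the Z dosage-compensation median under known factors
#'
#' Simulates cohorts at the given compensation factors and returns the
#' recovered median male/female Z-gene ratio for each (expected
#' `2 / factor`).
#'
#' @param factors Compensation factors to simulate.
#' @param config Base [sim_config()]; its
#'   `dosage_compensation_factor` is replaced per run.
#' @param n_boot Bootstrap replicates inside [sex_ratio_analysis()] (0
#'   disables the per-gene flag, which this summary does not need).
#' @return Tibble: `factor`, `expected_ratio`, `median_ratio`, `n_genes`.
#' @export
dosage_compensation_recovery <- function(factors = c(1, 4 / 3, 2),
                                         config = sim_config(),
                                         n_boot = 0L) {
  purrr::map_dfr(factors, function(f) {
    cfg <- config
    cfg$dosage_compensation_factor <- f
    validate_sim_config(cfg)
    co <- simulate_cross(cfg)
    sr <- sex_ratio_analysis(filter_expressed(co$expr),
                             co$samples, co$genes, n_boot = n_boot)
    tibble::tibble(factor = f, expected_ratio = 2 / f,
                   median_ratio = sr$median_ratio, n_genes = sr$n_genes)
  })
}
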