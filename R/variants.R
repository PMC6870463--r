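#' Filter a genotype panel on quality and missingness
#'
#' Applies the three-stage filtration used for the founder SNV panel:
#' variants below the site-quality threshold are dropped, genotype calls
#' below the genotype-quality threshold are masked to missing, and variants
#' whose post-masking missing rate exceeds the cap are dropped. All
#' thresholds pass at equality (a site at exactly quality 30 survives).
#'
#' @param geno Long genotype tibble (`variant_id`, `sample`, `a1`, `a2`,
#'   `gq`) — a missing call has `a1` `NA` (hemizygous calls have only `a2`
#'   `NA`).
#' @param variants Variant table carrying `variant_id` and `qual`.
#' @param min_site_quality Minimum phred site quality (default 30).
#' @param min_genotype_quality Minimum genotype quality; calls below it are
#'   masked (default 15).
#' @param max_missing_rate Maximum tolerated fraction of missing calls per
#'   variant after masking (default 0.20).
#' @return A list: `geno` (filtered long tibble, masked calls set to `NA`),
#'   `variants` (surviving variant rows), `summary` (tibble of counts in /
#'   dropped by each stage / out).
#' @examples
#' v <- tibble::tibble(variant_id = c("v1", "v2"), qual = c(29.9, 45))
#' g <- tidyr::expand_grid(variant_id = c("v1", "v2"),
#'                         sample = c("s1", "s2"))
#' g$a1 <- 0L; g$a2 <- 1L; g$gq <- c(99, 99, 10, 99)
#' filter_panel(g, v)$summary
#' @export
filter_panel <- function(geno, variants, min_site_quality = 30,
                         min_genotype_quality = 15,
                         max_missing_rate = 0.20) {
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1)
  if (nrow(variants) == 0 || nrow(geno) == 0) {
    warning("empty panel: nothing to filter")
    return(list(geno = geno[0, ], variants = variants[0, ],
                summary = tibble::tibble(n_in = 0L, n_fail_site_quality = 0L,
                                         n_fail_missing_rate = 0L,
                                         n_out = 0L)))
  }
  n_in <- nrow(variants)
  keep_q <- variants$qual >= min_site_quality
  kept <- variants[keep_q, ]
  g <- geno[geno$variant_id %in% kept$variant_id, ]

  mask <- !is.na(g$gq) & g$gq < min_genotype_quality
  g$a1[mask] <- NA_integer_
  g$a2[mask] <- NA_integer_

  miss <- g |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(missing_rate = mean(is.na(.data$a1)),
                     .groups = "drop")
  ok_vids <- miss$variant_id[miss$missing_rate <= max_missing_rate]
  n_fail_miss <- sum(!kept$variant_id %in% ok_vids)
  kept <- kept[kept$variant_id %in% ok_vids, ]
  g <- g[g$variant_id %in% ok_vids, ]

  list(
    geno = g,
    variants = kept,
    summary = tibble::tibble(
      n_in = n_in,
      n_fail_site_quality = sum(!keep_q),
      n_fail_missing_rate = n_fail_miss,
      n_out = nrow(kept)
    )
  )
}

high_impact_categories <- c("stop_gained", "stop_lost", "start_lost",
                            "splice_acceptor", "splice_donor", "frameshift")

known_categories <- c(high_impact_categories, "missense_deleterious",
                      "other")

#' Classify variant consequence annotations
#'
#' Maps raw consequence strings onto the screening taxonomy and flags the
#' HIGH-impact classes — stop gained/lost, start lost, splice
#' acceptor/donor — plus frameshift (tallied under its own category so
#' either counting convention is recoverable). Deleterious missense
#' variants are a separate, non-HIGH category. Unknown strings fall back to
#' `"other"` with a warning.
#'
#' @param variants Variant table with a `consequence` column (e.g. the
#'   first-effect token of a VCF `ANN`/`CSQ` field).
#' @return The input tibble with `category` and `high_impact` columns,
#'   with a `tallies` attribute (tibble of per-category counts).
#' @examples
#' classify_consequences(tibble::tibble(
#'   variant_id = "v1", consequence = "stop_gained"))$high_impact
#' @export
classify_consequences <- function(variants) {
  raw <- variants$consequence
  norm <- tolower(gsub("[ -]", "_", ifelse(is.na(raw), "other", raw)))
  norm <- sub("_variant$", "", norm)
  category <- dplyr::case_when(
    norm %in% known_categories ~ norm,
    grepl("^frameshift", norm) ~ "frameshift",
    grepl("missense.*deleterious|deleterious.*missense", norm) ~
      "missense_deleterious",
    TRUE ~ "other"
  )
  unknown <- !(norm %in% known_categories) & category == "other" &
    !is.na(raw) & norm != "other"
  if (any(unknown)) {
    warning("unknown consequence annotation(s) mapped to 'other': ",
            paste(unique(raw[unknown])[1:min(5, sum(unknown))],
                  collapse = ", "))
  }
  out <- variants
  out$category <- category
  out$high_impact <- category %in% high_impact_categories
  attr(out, "tallies") <- out |>
    dplyr::count(.data$category, .data$high_impact, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  out
}

#' Per-variant genotype-class counts
#'
#' Tallies hom-alt / het / hom-ref / hemizygous / missing calls per
#' variant, the summary shape used to report candidate null variants
#' (e.g. a variant het in a single founder shows 0 / 1 / n-1).
#'
#' @param geno Long genotype tibble.
#' @return Tibble: `variant_id`, `hom_alt`, `het`, `hom_ref`, `hemi`,
#'   `missing`; the five counts partition the samples of each variant.
#' @export
genotype_class_counts <- function(geno) {
  geno |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      hom_alt = sum(!is.na(.data$a1) & !is.na(.data$a2) &
                      .data$a1 == 1L & .data$a2 == 1L),
      het = sum(!is.na(.data$a1) & !is.na(.data$a2) &
                  .data$a1 + .data$a2 == 1L),
      hom_ref = sum(!is.na(.data$a1) & !is.na(.data$a2) &
                      .data$a1 == 0L & .data$a2 == 0L),
      hemi = sum(!is.na(.data$a1) & is.na(.data$a2)),
      missing = sum(is.na(.data$a1)),
      .groups = "drop"
    )
}

#' Breed allele-frequency contrast
#'
#' Computes per-variant alternative-allele frequencies in each breed from
#' non-missing calls (hemizygous calls contribute one allele) and flags
#' variants near-fixed for opposite alleles: one breed at or above
#' `fixed_hi`, the other at or below `fixed_lo`.
#'
#' @param geno Long genotype tibble.
#' @param breeds Tibble mapping `sample` to `breed` (exactly two breeds).
#' @param fixed_hi,fixed_lo Near-fixation thresholds (defaults 0.95 and
#'   0.05).
#' @return Tibble: `variant_id`, `af_breed1`, `af_breed2` (`NaN` when a
#'   breed has no called allele, with `undefined = TRUE`), `delta`
#'   (absolute difference), `near_fixed_opposite`.
#' @export
breed_frequency_contrast <- function(geno, breeds, fixed_hi = 0.95,
                                     fixed_lo = 0.05) {
  bl <- sort(unique(breeds$breed))
  if (length(bl) != 2L) {
    stop("`breeds` must label exactly two breeds", call. = FALSE)
  }
  g <- dplyr::inner_join(geno, breeds, by = "sample")
  af <- g |>
    dplyr::group_by(.data$variant_id, .data$breed) |>
    dplyr::summarise(
      alt = sum(.data$a1 == 1L, na.rm = TRUE) +
        sum(.data$a2 == 1L, na.rm = TRUE),
      total = sum(!is.na(.data$a1)) + sum(!is.na(.data$a2)),
      .groups = "drop"
    ) |>
    dplyr::mutate(af = .data$alt / .data$total) |>
    dplyr::select("variant_id", "breed", "af") |>
    tidyr::pivot_wider(names_from = "breed", values_from = "af")
  out <- tibble::tibble(
    variant_id = af$variant_id,
    af_breed1 = af[[bl[1]]],
    af_breed2 = af[[bl[2]]]
  )
  out$delta <- abs(out$af_breed1 - out$af_breed2)
  out$undefined <- is.nan(out$af_breed1) | is.na(out$af_breed1) |
    is.nan(out$af_breed2) | is.na(out$af_breed2)
  out$near_fixed_opposite <- !out$undefined &
    ((out$af_breed1 >= fixed_hi & out$af_breed2 <= fixed_lo) |
       (out$af_breed2 >= fixed_hi & out$af_breed1 <= fixed_lo))
  attr(out, "breeds") <- bl
  out
}

#' Principal component analysis of genotype dosages
#'
#' Codes genotypes as 0/1/2 alternative-allele dosage (hemizygous calls
#' 0/1), mean-imputes missing calls per variant, and runs a centred PCA
#' over samples. On two divergent breeds the first component separates the
#' breeds.
#'
#' @param geno Long genotype tibble.
#' @param k Number of components requested (reduced with a warning when
#'   more than samples allow).
#' @return An object of class `geno_pca`: `scores` tibble (`sample`,
#'   `PC1`..`PCk`), `var_explained` proportion per component, `k`.
#' @export
genotype_pca <- function(geno, k = 2L) {
  samples <- unique(geno$sample)
  if (length(samples) < 3L) stop("need at least 3 samples", call. = FALSE)
  mats <- geno_long_to_matrices(geno, sample_ids = samples)
  dos <- ifelse(is.na(mats$a1), NA_real_, mats$a1) +
    ifelse(is.na(mats$a2), 0, mats$a2)
  # variants x samples -> samples x variants, mean imputation per variant
  x <- t(dos)
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
  }
  x[is.nan(x)] <- 0
  keep <- apply(x, 2L, function(col) stats::var(col) > 0)
  if (sum(keep) < 2L) stop("fewer than 2 variable variants", call. = FALSE)
  x <- x[, keep, drop = FALSE]
  k_max <- min(nrow(x) - 1L, ncol(x))
  if (k > k_max) {
    warning("reducing requested components from ", k, " to ", k_max)
    k <- k_max
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(sample = rownames(x)), scores)
  ve <- pc$sdev ^ 2 / sum(pc$sdev ^ 2)
  structure(list(scores = scores, var_explained = ve[seq_len(k)], k = k),
            class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat("<geno_pca> ", nrow(x$scores), " samples, ", x$k, " components (",
      paste0(round(100 * x$var_explained, 1), "%", collapse = ", "),
      " variance)\n", sep = "")
  invisible(x)
}
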