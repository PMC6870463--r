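#' Family-versus-rest expression contrast
#'
#' The low-fitness-family screen: within one treatment stratum, per-gene
#' mean TPM in a target group (e.g. one F2 family) and in all other
#' samples; genes where at least one of the two averages exceeds
#' `min_mean` are eligible, and the target/other ratio (0.5 TPM
#' pseudocount only when the denominator is 0) flags genes up
#' (ratio strictly above `ratio_hi`) or down (strictly below `ratio_lo`).
#'
#' @param expr Wide expression tibble.
#' @param samples Sample sheet: `sample`, `family`, `treatment`.
#' @param target_family Family label of the target group.
#' @param stratum Treatment stratum analyzed (`"control"` or `"LPS"`);
#'   strata are never pooled.
#' @param min_mean Eligibility threshold on the larger group mean
#'   (default 1 TPM, strict).
#' @param ratio_hi,ratio_lo Ratio cutoffs (defaults 1.5 and 0.67, both
#'   strict; 0.67 is used literally as printed, not 1/1.5).
#' @return A list of class `family_contrast`: `table` (per-gene tibble:
#'   `gene`, `mean_target`, `mean_other`, `eligible`, `ratio`, `status`),
#'   `up`, `down` (gene vectors), `n_target`, `n_other`, `stratum`,
#'   `target_family`.
#' @export
group_contrast <- function(expr, samples, target_family,
                           stratum = c("control", "LPS"), min_mean = 1,
                           ratio_hi = 1.5, ratio_lo = 0.67) {
  stratum <- match.arg(stratum)
  stopifnot(ratio_lo < 1, ratio_hi > 1)
  meta <- samples[match(expr_sample_ids(expr), samples$sample), ]
  in_str <- meta$treatment == stratum
  tgt <- meta$sample[in_str & meta$family == target_family]
  oth <- meta$sample[in_str & meta$family != target_family]
  if (length(tgt) == 0 || length(oth) == 0) {
    stop("stratum '", stratum, "' has an empty group (target n = ",
         length(tgt), ", other n = ", length(oth), ")", call. = FALSE)
  }
  m <- expr_values(expr)
  mean_t <- unname(rowMeans(m[, tgt, drop = FALSE]))
  mean_o <- unname(rowMeans(m[, oth, drop = FALSE]))
  eligible <- pmax(mean_t, mean_o) > min_mean
  ratio <- ifelse(mean_o > 0, mean_t / mean_o,
                  (mean_t + 0.5) / (mean_o + 0.5))
  status <- dplyr::case_when(
    !eligible ~ "ineligible",
    ratio > ratio_hi ~ "up",
    ratio < ratio_lo ~ "down",
    TRUE ~ "unchanged"
  )
  tab <- tibble::tibble(gene = expr$gene, mean_target = mean_t,
                        mean_other = mean_o, eligible = eligible,
                        ratio = ratio, status = status)
  structure(list(table = tab,
                 up = tab$gene[tab$status == "up"],
                 down = tab$gene[tab$status == "down"],
                 n_target = length(tgt), n_other = length(oth),
                 stratum = stratum, target_family = target_family),
            class = "family_contrast")
}

#' @export
print.family_contrast <- function(x, ...) {
  cat("<family_contrast> family ", x$target_family, " (n = ", x$n_target,
      ") vs rest (n = ", x$n_other, "), ", x$stratum, " stratum: ",
      length(x$up), " up, ", length(x$down), " down\n", sep = "")
  invisible(x)
}

#' Enrichment of contrast gene lists
#'
#' Runs [gene_set_enrichment()] on the up and the down list of a
#' [group_contrast()] result against the eligible-gene universe.
#'
#' @param contrast A `family_contrast` object.
#' @param gene_sets Named list of annotation gene sets.
#' @param universe Optional universe; defaults to the contrast's eligible
#'   genes.
#' @return A list with `up` and `down` enrichment tibbles.
#' @export
contrast_enrichment <- function(contrast, gene_sets, universe = NULL) {
  stopifnot(inherits(contrast, "family_contrast"))
  if (is.null(universe)) {
    universe <- contrast$table$gene[contrast$table$eligible]
  }
  list(up = gene_set_enrichment(contrast$up, gene_sets, universe),
       down = gene_set_enrichment(contrast$down, gene_sets, universe))
}
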