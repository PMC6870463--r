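#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for sibxpress result objects
#'
#' `tidy()` returns the per-unit table of a result (one row per node,
#' gene or sample); `glance()` a one-row summary.
#'
#' @param x A result object (`mcl_clusters`, `geno_pca`, `sex_ratio`,
#'   `lps_response`, `family_contrast`, `dosage_groups`,
#'   `extreme_variation`).
#' @param ... Unused.
#' @return A tibble.
#' @name sibxpress_tidiers
NULL

#' @rdname sibxpress_tidiers
#' @method tidy mcl_clusters
#' @export
tidy.mcl_clusters <- function(x, ...) x$membership

#' @rdname sibxpress_tidiers
#' @method glance mcl_clusters
#' @export
glance.mcl_clusters <- function(x, ...) {
  tibble::tibble(n_clusters = x$n_clusters,
                 n_clustered = sum(!is.na(x$membership$cluster)),
                 largest = if (nrow(x$sizes) > 0) max(x$sizes$size) else 0L,
                 inflation = x$inflation,
                 iterations = x$iterations,
                 converged = x$converged)
}

#' @rdname sibxpress_tidiers
#' @method tidy geno_pca
#' @export
tidy.geno_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"sample", names_to = "component",
                      values_to = "score")
}

#' @rdname sibxpress_tidiers
#' @method glance geno_pca
#' @export
glance.geno_pca <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores), k = x$k,
                 pc1_var = x$var_explained[1])
}

#' @rdname sibxpress_tidiers
#' @method tidy sex_ratio
#' @export
tidy.sex_ratio <- function(x, ...) x$per_gene

#' @rdname sibxpress_tidiers
#' @method glance sex_ratio
#' @export
glance.sex_ratio <- function(x, ...) {
  tibble::tibble(chromosome = x$chromosome, n_genes = x$n_genes,
                 median_mf_ratio = x$median_ratio,
                 frac_compensated = mean(x$per_gene$compensated))
}

#' @rdname sibxpress_tidiers
#' @method tidy lps_response
#' @export
tidy.lps_response <- function(x, ...) x$per_gene

#' @rdname sibxpress_tidiers
#' @method glance lps_response
#' @export
glance.lps_response <- function(x, ...) {
  tibble::tibble(n_expressed = x$n_expressed, n_pairs = x$n_pairs,
                 n_induced = x$n_induced, n_repressed = x$n_repressed)
}

#' @rdname sibxpress_tidiers
#' @method tidy family_contrast
#' @export
tidy.family_contrast <- function(x, ...) x$table

#' @rdname sibxpress_tidiers
#' @method glance family_contrast
#' @export
glance.family_contrast <- function(x, ...) {
  tibble::tibble(target_family = x$target_family, stratum = x$stratum,
                 n_target = x$n_target, n_other = x$n_other,
                 n_up = length(x$up), n_down = length(x$down),
                 n_eligible = sum(x$table$eligible))
}

#' @rdname sibxpress_tidiers
#' @method tidy dosage_groups
#' @export
tidy.dosage_groups <- function(x, ...) x$assignment

#' @rdname sibxpress_tidiers
#' @method glance dosage_groups
#' @export
glance.dosage_groups <- function(x, ...) {
  tibble::tibble(k = x$k,
                 additivity_score = x$additivity_score,
                 null_group = x$null_group,
                 min_group_mean = min(x$group_means),
                 max_group_mean = max(x$group_means))
}

#' @rdname sibxpress_tidiers
#' @method tidy extreme_variation
#' @export
tidy.extreme_variation <- function(x, ...) x$summary

#' @rdname sibxpress_tidiers
#' @method glance extreme_variation
#' @export
glance.extreme_variation <- function(x, ...) {
  tibble::tibble(union_n = x$union_n,
                 n_shared = length(x$shared),
                 n_control_only = length(x$control_only),
                 n_lps_only = length(x$lps_only))
}
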