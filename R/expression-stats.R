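#' Restrict an expression matrix to detectably expressed genes
#'
#' Keeps genes whose maximum TPM across samples is at least `min_max_tpm`
#' (equivalently: removes genes with maximum expression below the
#' threshold; the boundary value itself is retained).
#'
#' @param expr Wide expression tibble: `gene` column plus one numeric
#'   column per sample (TPM).
#' @param min_max_tpm Detection threshold, default 10 TPM.
#' @return The retained rows of `expr`.
#' @examples
#' expr <- tibble::tibble(gene = c("g1", "g2"), s1 = c(9.99, 10), s2 = 0)
#' filter_expressed(expr)$gene
#' @export
filter_expressed <- function(expr, min_max_tpm = 10) {
  stopifnot(nrow(expr) > 0)
  m <- expr_values(expr)
  expr[row_max_(m) >= min_max_tpm, ]
}

#' Per-gene max/min fold-difference statistics
#'
#' The range screen: per gene, the maximum and minimum TPM across samples
#' and their ratio as a fold-difference value. A gene undetected in some
#' bird (min = 0) gets an infinite ratio sentinel with both extremes
#' preserved; `ratio_pseudo` adds 0.5 TPM to both extremes for a finite
#' companion statistic.
#'
#' @param expr Wide expression tibble.
#' @param min_max_tpm Detection threshold used for the `expressed` flag.
#' @return Tibble: `gene`, `max`, `min`, `ratio` (`Inf` when `min` = 0),
#'   `ratio_pseudo`, `expressed`.
#' @examples
#' max_min_ratio(tibble::tibble(gene = "avidin_like",
#'                              s1 = 5, s2 = 121))$ratio  # 24.2
#' @export
max_min_ratio <- function(expr, min_max_tpm = 10) {
  m <- expr_values(expr)
  mx <- row_max_(m)
  mn <- row_min_(m)
  tibble::tibble(
    gene = expr$gene,
    max = mx,
    min = mn,
    ratio = ifelse(mn > 0, mx / mn, Inf),
    ratio_pseudo = (mx + 0.5) / (mn + 0.5),
    expressed = mx >= min_max_tpm
  )
}

#' Extreme-variation calls and the control/LPS overlap partition
#'
#' A gene qualifies as extremely variable in a condition when its maximum
#' TPM exceeds `max_thresh` and its minimum falls below `min_thresh`
#' (strict on both sides) — the signature of a segregating null expression
#' allele. The qualifying sets of the control and LPS matrices are
#' partitioned into control-specific, LPS-specific and shared genes, with
#' percentages relative to the union.
#'
#' @param expr_control,expr_lps Wide expression tibbles over the same gene
#'   universe.
#' @param max_thresh,min_thresh Qualification thresholds (defaults 20 and
#'   1 TPM).
#' @return A list of class `extreme_variation`: `control_only`,
#'   `lps_only`, `shared` (character vectors), `summary` tibble (`set`,
#'   `n`, `pct` of the union), `union_n`.
#' @export
extreme_variation_sets <- function(expr_control, expr_lps,
                                   max_thresh = 20, min_thresh = 1) {
  if (!setequal(expr_control$gene, expr_lps$gene) ||
      nrow(expr_control) != nrow(expr_lps)) {
    mism <- c(setdiff(expr_control$gene, expr_lps$gene),
              setdiff(expr_lps$gene, expr_control$gene))
    stop("gene universes differ between matrices: ",
         paste(utils::head(mism, 5), collapse = ", "), call. = FALSE)
  }
  qualifying <- function(expr) {
    m <- expr_values(expr)
    expr$gene[row_max_(m) > max_thresh &
                row_min_(m) < min_thresh]
  }
  qc <- qualifying(expr_control)
  ql <- qualifying(expr_lps)
  shared <- intersect(qc, ql)
  c_only <- setdiff(qc, ql)
  l_only <- setdiff(ql, qc)
  un <- length(shared) + length(c_only) + length(l_only)
  summary <- tibble::tibble(
    set = c("control_only", "lps_only", "shared"),
    n = c(length(c_only), length(l_only), length(shared)),
    pct = if (un > 0) 100 * c(length(c_only), length(l_only),
                              length(shared)) / un else rep(NA_real_, 3)
  )
  structure(list(control_only = c_only, lps_only = l_only, shared = shared,
                 summary = summary, union_n = un),
            class = "extreme_variation")
}

#' @export
print.extreme_variation <- function(x, ...) {
  cat("<extreme_variation> ", x$union_n, " qualifying genes: ",
      length(x$shared), " shared, ", length(x$control_only),
      " control-only, ", length(x$lps_only), " LPS-only\n", sep = "")
  invisible(x)
}

#' Partition samples of one gene into allele-dosage groups
#'
#' Models the visual grouping of a null-segregating gene — birds clustering
#' at 0x, 1x and 2x functional-allele expression — as an exhaustive search
#' over contiguous partitions of the sorted `log2(TPM + 0.5)` values into
#' k = 1..`max_groups` groups, scored by total within-group sum of squares
#' plus `penalty` per extra group. For k = 3 an additivity score
#' `|m_mid - (m_low + m_high)/2| / m_high` (on raw TPM group means)
#' measures consistency with additive 0/1/2 copy expression, and a group
#' whose raw mean falls below `null_tpm` is flagged as the candidate-null
#' class.
#'
#' @param values Named numeric vector of TPM values (names = samples) for
#'   one gene; at least 4 samples.
#' @param max_groups Maximum number of groups (1-3).
#' @param penalty Score penalty per extra group, in squared log2 units
#'   (default 0.5).
#' @param null_tpm Raw-mean threshold for the near-zero class (default 1).
#' @return A list of class `dosage_groups`: `assignment` tibble (`sample`,
#'   `value`, `group` — group 1 has the lowest mean), `k`, `group_means`
#'   (raw TPM), `additivity_score` (`NA` unless k = 3), `null_group`
#'   (index of the near-zero group or `NA`).
#' @examples
#' v <- c(a = 0, b = 0.1, c = 5, d = 5.2, e = 10, f = 9.8)
#' classify_dosage_groups(v)$k
#' @export
classify_dosage_groups <- function(values, max_groups = 3L, penalty = 0.5,
                                   null_tpm = 1) {
  if (length(values) < 4L) {
    stop("dosage grouping needs at least 4 samples", call. = FALSE)
  }
  stopifnot(max_groups >= 1L, max_groups <= 3L)
  if (is.null(names(values))) {
    names(values) <- paste0("s", seq_along(values))
  }
  ord <- order(values)
  x <- log2(values[ord] + 0.5)
  n <- length(x)

  wss <- function(seg) {
    if (length(seg) <= 1L) return(0)
    sum((seg - mean(seg)) ^ 2)
  }
  best <- list(score = Inf, cuts = integer(), k = 1L)
  # cuts are positions after which a new group starts (0..2 cuts)
  for (k in seq_len(max_groups)) {
    if (k == 1L) {
      cand <- list(integer())
    } else if (k == 2L) {
      cand <- lapply(seq_len(n - 1L), function(c1) c1)
    } else {
      cand <- list()
      for (c1 in seq_len(n - 2L)) for (c2 in (c1 + 1L):(n - 1L)) {
        cand[[length(cand) + 1L]] <- c(c1, c2)
      }
    }
    for (cuts in cand) {
      bounds <- c(0L, cuts, n)
      s <- sum(vapply(seq_len(k), function(i) {
        wss(x[(bounds[i] + 1L):bounds[i + 1L]])
      }, numeric(1))) + penalty * (k - 1L)
      if (s < best$score - 1e-12) best <- list(score = s, cuts = cuts, k = k)
    }
  }
  bounds <- c(0L, best$cuts, n)
  group_sorted <- rep(seq_len(best$k), diff(bounds))
  raw_sorted <- values[ord]
  group_means <- vapply(seq_len(best$k),
                        function(i) mean(raw_sorted[group_sorted == i]),
                        numeric(1))
  additivity <- if (best$k == 3L && group_means[3] > 0) {
    abs(group_means[2] - (group_means[1] + group_means[3]) / 2) /
      group_means[3]
  } else NA_real_
  null_group <- which(group_means < null_tpm)
  structure(list(
    assignment = tibble::tibble(sample = names(values)[ord],
                                value = unname(raw_sorted),
                                group = group_sorted)[order(ord), ],
    k = best$k,
    group_means = group_means,
    additivity_score = additivity,
    null_group = if (length(null_group) > 0) min(null_group) else NA_integer_
  ), class = "dosage_groups")
}

#' @export
print.dosage_groups <- function(x, ...) {
  cat("<dosage_groups> k = ", x$k, "; group means (TPM): ",
      paste(signif(x$group_means, 4), collapse = ", "), sep = "")
  if (!is.na(x$additivity_score)) {
    cat("; additivity score ", signif(x$additivity_score, 3), sep = "")
  }
  if (!is.na(x$null_group)) cat("; null group #", x$null_group, sep = "")
  cat("\n")
  invisible(x)
}

#' Male/female expression ratios and Z dosage-compensation summary
#'
#' Per gene, the ratio of mean male TPM to mean female TPM (over genes
#' expressed in both sexes), the median ratio across genes of the chosen
#' chromosome class (incomplete Z compensation shows a median between 1
#' and 2), and a per-gene "dosage compensated" flag from a nonparametric
#' bootstrap: samples are resampled within sex and the gene is flagged
#' when the 95% interval of the ratio covers 1.
#'
#' @param expr Wide expression tibble.
#' @param samples Sample sheet with `sample` and `sex`.
#' @param gene_meta Tibble with `gene` and `chromosome`
#'   (`autosome`/`Z`/`W`).
#' @param chromosome Class summarized (default `"Z"`).
#' @param min_mean_tpm Both sex means must exceed this to call a gene
#'   expressed in both sexes (default 0.5).
#' @param n_boot Bootstrap replicates for the compensated flag (default
#'   1000; 0 disables the flag).
#' @param conf Bootstrap interval coverage (default 0.95).
#' @return A list of class `sex_ratio`: `per_gene` tibble (`gene`,
#'   `mean_m`, `mean_f`, `mf_ratio`, `compensated`), `median_ratio`,
#'   `chromosome`, `n_genes`.
#' @export
sex_ratio_analysis <- function(expr, samples, gene_meta,
                               chromosome = "Z", min_mean_tpm = 1,
                               n_boot = 1000L, conf = 0.95) {
  sex <- samples$sex[match(expr_sample_ids(expr), samples$sample)]
  if (length(unique(stats::na.omit(sex))) < 2L) {
    stop("single-sex dataset: male/female ratios undefined", call. = FALSE)
  }
  if (sum(sex == "M", na.rm = TRUE) < 2L ||
      sum(sex == "F", na.rm = TRUE) < 2L) {
    stop("need at least 2 samples of each sex", call. = FALSE)
  }
  genes_cls <- gene_meta$gene[gene_meta$chromosome == chromosome]
  e <- expr[expr$gene %in% genes_cls, ]
  m <- expr_values(e)
  mcols <- which(sex == "M")
  fcols <- which(sex == "F")
  mean_m <- unname(rowMeans(m[, mcols, drop = FALSE]))
  mean_f <- unname(rowMeans(m[, fcols, drop = FALSE]))
  both <- mean_m > min_mean_tpm & mean_f > min_mean_tpm
  per_gene <- tibble::tibble(
    gene = e$gene[both],
    mean_m = mean_m[both],
    mean_f = mean_f[both],
    mf_ratio = mean_m[both] / mean_f[both]
  )
  per_gene$compensated <- NA
  if (n_boot > 0 && nrow(per_gene) > 0) {
    mm <- m[both, mcols, drop = FALSE]
    mf <- m[both, fcols, drop = FALSE]
    lo_i <- (1 - conf) / 2
    ratios <- matrix(NA_real_, nrow(per_gene), n_boot)
    for (b in seq_len(n_boot)) {
      bm <- mm[, sample.int(ncol(mm), replace = TRUE), drop = FALSE]
      bf <- mf[, sample.int(ncol(mf), replace = TRUE), drop = FALSE]
      ratios[, b] <- rowMeans(bm) / rowMeans(bf)
    }
    qs <- t(apply(ratios, 1L, stats::quantile,
                  probs = c(lo_i, 1 - lo_i), na.rm = TRUE))
    per_gene$compensated <- qs[, 1] <= 1 & qs[, 2] >= 1
  }
  structure(list(per_gene = per_gene,
                 median_ratio = stats::median(per_gene$mf_ratio),
                 chromosome = chromosome,
                 n_genes = nrow(per_gene)),
            class = "sex_ratio")
}

#' @export
print.sex_ratio <- function(x, ...) {
  cat("<sex_ratio> ", x$n_genes, " ", x$chromosome,
      " genes expressed in both sexes; median M/F ratio ",
      signif(x$median_ratio, 4), "\n", sep = "")
  invisible(x)
}

#' LPS response: per-gene fold change and induced/repressed counts
#'
#' For genes expressed above `min_max_tpm` in at least one sample, the
#' mean TPM of paired LPS samples over the mean of their control partners
#' (0.5 TPM pseudocount on both means) gives the fold change; a gene is
#' induced when the fold strictly exceeds `fold` and repressed when it
#' falls strictly below `1/fold`. Samples without a partner of the other
#' treatment from the same bird are excluded with a warning.
#'
#' @param expr Wide expression tibble (control and LPS columns together).
#' @param samples Sample sheet: `sample`, `individual`, `treatment`.
#' @param min_max_tpm Expression filter (default 10).
#' @param fold Fold threshold (default 2).
#' @return A list of class `lps_response`: `per_gene` tibble (`gene`,
#'   `mean_control`, `mean_lps`, `fold_change`, `log2fc`, `status`),
#'   `n_induced`, `n_repressed`, `n_expressed`, `n_pairs`.
#' @export
lps_response <- function(expr, samples, min_max_tpm = 10, fold = 2) {
  meta <- samples[match(expr_sample_ids(expr), samples$sample), ]
  ctrl <- meta[meta$treatment == "control", ]
  lps <- meta[meta$treatment == "LPS", ]
  paired_ind <- intersect(ctrl$individual, lps$individual)
  unpaired <- setdiff(meta$sample,
                      meta$sample[meta$individual %in% paired_ind])
  if (length(unpaired) > 0) {
    warning("excluding unpaired sample(s): ",
            paste(utils::head(unpaired, 5), collapse = ", "))
  }
  if (length(paired_ind) == 0) {
    stop("no control/LPS pairs share an individual", call. = FALSE)
  }
  e <- filter_expressed(expr, min_max_tpm)
  m <- expr_values(e)
  cs <- meta$sample[meta$treatment == "control" &
                      meta$individual %in% paired_ind]
  ls <- meta$sample[meta$treatment == "LPS" &
                      meta$individual %in% paired_ind]
  mean_c <- unname(rowMeans(m[, cs, drop = FALSE]))
  mean_l <- unname(rowMeans(m[, ls, drop = FALSE]))
  fc <- (mean_l + 0.5) / (mean_c + 0.5)
  status <- dplyr::case_when(fc > fold ~ "induced",
                             fc < 1 / fold ~ "repressed",
                             TRUE ~ "unchanged")
  per_gene <- tibble::tibble(gene = e$gene, mean_control = mean_c,
                             mean_lps = mean_l, fold_change = fc,
                             log2fc = log2(fc), status = status)
  structure(list(per_gene = per_gene,
                 n_induced = sum(status == "induced"),
                 n_repressed = sum(status == "repressed"),
                 n_expressed = nrow(e),
                 n_pairs = length(paired_ind)),
            class = "lps_response")
}

#' @export
print.lps_response <- function(x, ...) {
  cat("<lps_response> ", x$n_expressed, " expressed genes over ",
      x$n_pairs, " bird pairs: ", x$n_induced, " induced, ",
      x$n_repressed, " repressed\n", sep = "")
  invisible(x)
}

# ---- internal helpers on wide expression tibbles ----

expr_sample_ids <- function(expr) setdiff(names(expr), "gene")

expr_values <- function(expr) {
  m <- as.matrix(expr[, expr_sample_ids(expr), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene
  m
}

row_max_ <- function(m) {
  do.call(pmax, c(as.data.frame(m), list(na.rm = TRUE)))
}

row_min_ <- function(m) {
  do.call(pmin, c(as.data.frame(m), list(na.rm = TRUE)))
}
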