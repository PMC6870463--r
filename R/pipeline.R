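default_pipeline_config <- function() {
  list(
    simulation = list(),   # overrides for sim_config()
    filtration = list(min_site_quality = 30, min_genotype_quality = 15,
                      max_missing_rate = 0.20),
    stats = list(min_max_tpm = 10, lps_fold = 2,
                 extreme_max_thresh = 20, extreme_min_thresh = 1,
                 sex_ratio_n_boot = 200),
    network = list(r_min = 0.85, inflation = 1.7, prune_threshold = 1e-5,
                   tol = 1e-6, max_iter = 200, min_cluster_size = 3),
    contrast = list(target_family = "A", min_mean = 1,
                    ratio_hi = 1.5, ratio_lo = 0.67)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a nested list) with sections `simulation`,
#' `filtration`, `stats`, `network` and `contrast`, fills unset values
#' with the package defaults (the thresholds in routine use: quality
#' 30/15/20%, 10 TPM, 2-fold, max > 20 / min < 1, r 0.85, inflation 1.7,
#' 1.5/0.67) and rejects unknown keys.
#'
#' @param config Path to a YAML file, a nested list, or `NULL` for pure
#'   defaults.
#' @return A validated nested list of class `pipeline_config`.
#' @export
load_pipeline_config <- function(config = NULL) {
  defaults <- default_pipeline_config()
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop("`config` must be a YAML path, a list, or NULL", call. = FALSE)
  }
  bad_sections <- setdiff(names(user), names(defaults))
  if (length(bad_sections) > 0) {
    stop("unknown config section(s): ",
         paste(bad_sections, collapse = ", "), call. = FALSE)
  }
  sim_keys <- names(formals(sim_config))
  for (sec in names(user)) {
    allowed <- if (sec == "simulation") sim_keys else
      names(defaults[[sec]])
    bad <- setdiff(names(user[[sec]]), allowed)
    if (length(bad) > 0) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    defaults[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  structure(defaults, class = "pipeline_config")
}

#' Run the full simulate-and-analyze pipeline
#'
#' End-to-end demonstration and reporting run: simulates the F2 cohort,
#' filters the variant panel and summarizes genotype classes and breed
#' frequency contrasts, computes genotype PCA, tabulates analytic vs
#' simulated segregation expectations (including the 1/16 founder-het and
#' 1/4 breed-fixed cases), runs the per-gene expression screens, the
#' co-expression network with MCL clustering and profiles, and the
#' family-versus-rest contrast, writing every table plus a machine-readable
#' JSON summary to `out_dir`. Deterministic given `seed`.
#'
#' When `input_dir` points at an existing expression bundle (written by
#' [write_expression_bundle()]), those tables are analyzed instead of a
#' fresh simulation and the genotype/segregation stages are skipped; a
#' missing file is a clean error naming the path.
#'
#' @param config A [load_pipeline_config()] input (path, list or `NULL`).
#' @param out_dir Output directory.
#' @param seed Master seed overriding the simulation section's.
#' @param input_dir Optional directory with `expression_tpm.tsv`,
#'   `samples.tsv`, `genes.tsv` to analyze instead of simulating.
#' @return The summary list, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("sibxpress_"),
                         seed = NULL, input_dir = NULL) {
  cfg <- load_pipeline_config(config)
  sim_args <- cfg$simulation
  if (!is.null(seed)) sim_args$seed <- as.integer(seed)
  scfg <- do.call(sim_config, sim_args)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(input_dir)) {
    for (f in c("expression_tpm.tsv", "samples.tsv", "genes.tsv")) {
      p <- file.path(input_dir, f)
      if (!file.exists(p)) {
        stop("input file not found: ", p, call. = FALSE)
      }
    }
    return(run_pipeline_on_bundle(read_expression_bundle(input_dir),
                                  cfg, out_dir))
  }

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  cohort <- stage("simulate", simulate_cross(scfg))
  write_expression_bundle(cohort$expr, cohort$samples, cohort$genes,
                          file.path(out_dir, "simulated"))
  write_panel_vcf(cohort$geno, cohort$variants,
                  file.path(out_dir, "simulated", "panel.vcf"))

  founder_geno <- cohort$geno[cohort$geno$sample %in% cohort$founders, ]
  filt <- stage("variants", filter_panel(
    founder_geno, cohort$variants,
    min_site_quality = cfg$filtration$min_site_quality,
    min_genotype_quality = cfg$filtration$min_genotype_quality,
    max_missing_rate = cfg$filtration$max_missing_rate))
  cons <- classify_consequences(filt$variants)
  counts <- genotype_class_counts(filt$geno)
  breeds <- cohort$pedigree[cohort$pedigree$generation == 0L,
                            c("id", "breed")]
  names(breeds) <- c("sample", "breed")
  freq <- breed_frequency_contrast(filt$geno, breeds)
  pca <- genotype_pca(filt$geno)
  tab2 <- dplyr::left_join(
    dplyr::left_join(cons, counts, by = "variant_id"),
    freq[, c("variant_id", "af_breed1", "af_breed2",
             "near_fixed_opposite")], by = "variant_id")
  utils::write.table(tab2, file.path(out_dir, "variant_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  seg <- stage("segregation", {
    rbind(
      cbind(case = "founder_het_null",
            simulate_f2_genotype_freqs(c("het", "hom_ref"), 20000L,
                                       seed = stage_seed(scfg,
                                                         "segregation"))),
      cbind(case = "breed_fixed",
            simulate_f2_genotype_freqs(c("hom_alt", "hom_ref"), 20000L,
                                       seed = stage_seed(scfg,
                                                         "segregation") + 1L))
    )
  })
  utils::write.table(seg, file.path(out_dir, "segregation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  st <- cfg$stats
  samples <- cohort$samples
  ctrl_ids <- samples$sample[samples$treatment == "control"]
  lps_ids <- samples$sample[samples$treatment == "LPS"]
  expr_c <- cohort$expr[, c("gene", ctrl_ids)]
  expr_l <- cohort$expr[, c("gene", lps_ids)]

  stats_out <- stage("stats", {
    expressed <- filter_expressed(cohort$expr, st$min_max_tpm)
    mm <- max_min_ratio(expressed, st$min_max_tpm)
    ev <- extreme_variation_sets(
      expr_c[expr_c$gene %in% expressed$gene, ],
      expr_l[expr_l$gene %in% expressed$gene, ],
      max_thresh = st$extreme_max_thresh,
      min_thresh = st$extreme_min_thresh)
    sr <- sex_ratio_analysis(expressed, samples, cohort$genes,
                             n_boot = st$sex_ratio_n_boot)
    lr <- lps_response(cohort$expr, samples, st$min_max_tpm, st$lps_fold)
    list(expressed = expressed, mm = mm, ev = ev, sr = sr, lr = lr)
  })
  utils::write.table(stats_out$mm,
                     file.path(out_dir, "max_min_ratio.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(stats_out$lr$per_gene,
                     file.path(out_dir, "lps_response.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(stats_out$ev$shared,
             file.path(out_dir, "extreme_shared_genes.txt"))

  net <- stage("network", {
    corr <- correlation_matrix(stats_out$expressed)
    gr <- threshold_graph(corr, cfg$network$r_min)
    cl <- mcl(gr, inflation = cfg$network$inflation,
              prune_threshold = cfg$network$prune_threshold,
              tol = cfg$network$tol, max_iter = cfg$network$max_iter,
              min_cluster_size = cfg$network$min_cluster_size)
    prof <- cluster_profiles(cl, stats_out$expressed, samples)
    list(graph = gr, clusters = cl, profiles = prof)
  })
  write_edge_list(net$graph, file.path(out_dir, "edges.tsv"))
  utils::write.table(
    dplyr::left_join(net$clusters$membership,
                     net$profiles[, c("cluster", "size", "trend")],
                     by = "cluster"),
    file.path(out_dir, "clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  ctr <- stage("contrast", group_contrast(
    expr_c, samples, cfg$contrast$target_family, "control",
    min_mean = cfg$contrast$min_mean, ratio_hi = cfg$contrast$ratio_hi,
    ratio_lo = cfg$contrast$ratio_lo))
  writeLines(ctr$up, file.path(out_dir, "contrast_up.txt"))
  writeLines(ctr$down, file.path(out_dir, "contrast_down.txt"))

  summary <- list(
    version = as.character(utils::packageVersion("sibxpress")),
    seed = scfg$seed,
    config_hash = rlang::hash(cfg),
    n_variants_in = filt$summary$n_in,
    n_variants_out = filt$summary$n_out,
    n_high_impact = sum(cons$high_impact),
    pca_pc1_separates_breeds = pc1_separates(pca, breeds),
    f2_hom_null_prob =
      seg$expected[seg$case == "founder_het_null" &
                     seg$genotype == "hom_alt"],
    f2_hom_null_freq =
      seg$freq[seg$case == "founder_het_null" & seg$genotype == "hom_alt"],
    f2_hom_fixed_prob =
      seg$expected[seg$case == "breed_fixed" & seg$genotype == "hom_alt"],
    n_expressed = nrow(stats_out$expressed),
    median_max_min_ratio =
      stats::median(stats_out$mm$ratio[is.finite(stats_out$mm$ratio)]),
    extreme_shared_pct =
      stats_out$ev$summary$pct[stats_out$ev$summary$set == "shared"],
    extreme_lps_only_pct =
      stats_out$ev$summary$pct[stats_out$ev$summary$set == "lps_only"],
    median_mf_z_ratio = stats_out$sr$median_ratio,
    n_lps_induced = stats_out$lr$n_induced,
    n_lps_repressed = stats_out$lr$n_repressed,
    n_clusters = net$clusters$n_clusters,
    n_contrast_up = length(ctr$up),
    n_contrast_down = length(ctr$down)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

# Analysis-only path over a pre-existing expression bundle.
run_pipeline_on_bundle <- function(bundle, cfg, out_dir) {
  st <- cfg$stats
  samples <- bundle$samples
  expr <- bundle$expr
  expressed <- filter_expressed(expr, st$min_max_tpm)
  mm <- max_min_ratio(expressed, st$min_max_tpm)
  ctrl <- samples$sample[samples$treatment == "control"]
  lps <- samples$sample[samples$treatment == "LPS"]
  ev <- extreme_variation_sets(expressed[, c("gene", ctrl)],
                               expressed[, c("gene", lps)],
                               max_thresh = st$extreme_max_thresh,
                               min_thresh = st$extreme_min_thresh)
  lr <- lps_response(expr, samples, st$min_max_tpm, st$lps_fold)
  corr <- correlation_matrix(expressed)
  gr <- threshold_graph(corr, cfg$network$r_min)
  cl <- mcl(gr, inflation = cfg$network$inflation,
            min_cluster_size = cfg$network$min_cluster_size)
  ctr <- group_contrast(expressed[, c("gene", ctrl)], samples,
                        cfg$contrast$target_family, "control",
                        min_mean = cfg$contrast$min_mean,
                        ratio_hi = cfg$contrast$ratio_hi,
                        ratio_lo = cfg$contrast$ratio_lo)
  utils::write.table(mm, file.path(out_dir, "max_min_ratio.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lr$per_gene, file.path(out_dir, "lps_response.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    version = as.character(utils::packageVersion("sibxpress")),
    config_hash = rlang::hash(cfg),
    n_expressed = nrow(expressed),
    extreme_shared_pct = ev$summary$pct[ev$summary$set == "shared"],
    n_lps_induced = lr$n_induced,
    n_lps_repressed = lr$n_repressed,
    n_clusters = cl$n_clusters,
    n_contrast_up = length(ctr$up),
    n_contrast_down = length(ctr$down)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

pc1_separates <- function(pca, breeds) {
  s <- dplyr::inner_join(pca$scores, breeds, by = "sample")
  bl <- unique(s$breed)
  if (length(bl) != 2L) return(NA)
  r1 <- range(s$PC1[s$breed == bl[1]])
  r2 <- range(s$PC1[s$breed == bl[2]])
  r1[2] < r2[1] || r2[2] < r1[1]
}
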