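test_that("sim_config validates its inputs", {
  expect_s3_class(tiny_config(), "sim_config")
  expect_error(tiny_config(dosage_compensation_factor = 2.5), "1, 2")
  expect_error(tiny_config(het_null_fraction = 1.2), "proportion")
  expect_error(tiny_config(noise_sd_log2 = -1), "nonnegative")
  expect_error(tiny_config(n_founders_per_breed = 1), "each sex")
  expect_error(tiny_config(baseline_tpm_range = c(5, 1)), "interval")
  expect_error(tiny_config(n_autosomal_genes = 5), "exceed")
})

test_that("founder simulation respects the null and breed-fixation fractions", {
  # no nulls requested -> no zero-effect alleles in the ground truth
  fs0 <- simulate_founders(tiny_config(het_null_fraction = 0))
  expect_false(any(fs0$genes$effect_alt == 0))
  expect_false(any(fs0$genes$null_gene))

  # full fixation -> every non-null locus divergent between breeds
  cfg1 <- tiny_config(breed_fixed_fraction = 1, het_null_fraction = 0,
                      n_founders_per_breed = 5)
  fs1 <- simulate_founders(cfg1)
  breeds <- fs1$individuals[, c("id", "breed")]
  names(breeds) <- c("sample", "breed")
  fr <- breed_frequency_contrast(fs1$geno, breeds)
  expect_true(all(fr$near_fixed_opposite[!fr$undefined]))

  # het-null architecture: exactly one het founder, no hom-alt founders
  fs <- simulate_founders(tiny_config())
  null_vids <- fs$genes$variant_id[fs$genes$null_gene]
  expect_gt(length(null_vids), 0)
  cc <- genotype_class_counts(
    fs$geno[fs$geno$variant_id %in% null_vids, ])
  expect_true(all(cc$het == 1))
  expect_true(all(cc$hom_alt == 0))
  expect_true(all(fs$genes$effect_alt[fs$genes$null_gene] == 0))
})

test_that("founder simulation is byte-for-byte reproducible", {
  fs_a <- simulate_founders(tiny_config(seed = 5))
  fs_b <- simulate_founders(tiny_config(seed = 5))
  expect_identical(fs_a$geno, fs_b$geno)
  expect_identical(fs_a$genes, fs_b$genes)
  fs_c <- simulate_founders(tiny_config(seed = 6))
  expect_false(identical(fs_a$geno, fs_c$geno))
})

test_that("Z/W founder genotypes respect sex", {
  fs <- simulate_founders(tiny_config())
  zv <- fs$variants$variant_id[fs$variants$chrom == "chrZ"]
  wv <- fs$variants$variant_id[fs$variants$chrom == "chrW"]
  g <- dplyr::left_join(fs$geno, fs$individuals[, c("id", "sex")],
                        by = c(sample = "id"))
  zf <- g[g$variant_id %in% zv & g$sex == "F", ]
  expect_true(all(!is.na(zf$a1) & is.na(zf$a2)))     # hemizygous Z
  zm <- g[g$variant_id %in% zv & g$sex == "M", ]
  expect_true(all(!is.na(zm$a1) & !is.na(zm$a2)))    # ZZ males
  wm <- g[g$variant_id %in% wv & g$sex == "M", ]
  expect_true(all(is.na(wm$a1)))                     # no W in males
})

test_that("pedigree has the sib-mating structure and is acyclic", {
  cfg <- tiny_config(n_f1_pairs = 1, n_f2_per_family = 4)
  ped <- build_pedigree(cfg)
  f2 <- ped[ped$generation == 2L, ]
  expect_equal(nrow(f2), 4L)
  f1 <- ped[ped$generation == 1L, ]
  # each F2's sire and dam are F1 full sibs: same F0 parents
  for (i in seq_len(nrow(f2))) {
    s <- f1[f1$id == f2$sire[i], ]
    d <- f1[f1$id == f2$dam[i], ]
    expect_equal(s$sire, d$sire)
    expect_equal(s$dam, d$dam)
    expect_equal(s$sex, "M")
    expect_equal(d$sex, "F")
  }
  # no individual is its own ancestor
  parent_of <- stats::setNames(Map(c, ped$sire, ped$dam), ped$id)
  for (id in ped$id) {
    seen <- character()
    frontier <- stats::na.omit(unlist(parent_of[[id]]))
    while (length(frontier) > 0) {
      expect_false(id %in% frontier)
      seen <- union(seen, frontier)
      frontier <- setdiff(
        stats::na.omit(unlist(parent_of[frontier])), seen)
    }
  }
  # the full design yields 15 distinct F2 families
  ped15 <- build_pedigree(cohort_config())
  expect_length(unique(stats::na.omit(
    ped15$family[ped15$generation == 2L])), 15L)
})

test_that("gene drop obeys fixed crosses and sex-chromosome bookkeeping", {
  cfg <- tiny_config(n_f1_pairs = 2, n_f2_per_family = 5,
                     breed_fixed_fraction = 0, het_null_fraction = 0)
  fs <- simulate_founders(cfg)
  # make every founder hom-alt at an autosomal locus -> all descendants too
  auto_vid <- fs$variants$variant_id[!fs$variants$chrom %in%
                                       c("chrZ", "chrW")][1]
  fs$geno$a1[fs$geno$variant_id == auto_vid] <- 1L
  fs$geno$a2[fs$geno$variant_id == auto_vid] <- 1L
  ped <- build_pedigree(cfg, fs$individuals)
  g <- gene_drop(ped, fs, seed = 9)
  ga <- g[g$variant_id == auto_vid, ]
  expect_true(all(ga$a1 == 1L & ga$a2 == 1L))

  # daughters carry exactly one Z allele, sons two; W absent in males
  zv <- fs$variants$variant_id[fs$variants$chrom == "chrZ"]
  wv <- fs$variants$variant_id[fs$variants$chrom == "chrW"]
  sexes <- stats::setNames(ped$sex, ped$id)
  gz <- g[g$variant_id %in% zv, ]
  expect_true(all(is.na(gz$a2[sexes[gz$sample] == "F"])))
  expect_true(all(!is.na(gz$a1[sexes[gz$sample] == "F"])))
  expect_true(all(!is.na(gz$a2[sexes[gz$sample] == "M"])))
  gw <- g[g$variant_id %in% wv, ]
  expect_true(all(is.na(gw$a1[sexes[gw$sample] == "M"])))
  expect_true(all(!is.na(gw$a1[sexes[gw$sample] == "F"])))

  expect_error(gene_drop(dplyr::mutate(ped,
                                       sire = dplyr::if_else(
                                         id == ped$id[nrow(ped)],
                                         "ghost", sire)),
                         fs, seed = 1),
               "unknown individual")
})

test_that("F1 het x het matings give 1:2:1 F2 ratios", {
  # a het x het F1 pair is forced by a hom_alt x hom_ref founder cross;
  # chi-square goodness of fit should not reject 1/4:1/2:1/4
  sim <- simulate_f2_genotype_freqs(c("hom_alt", "hom_ref"),
                                    n_replicates = 10000, seed = 31)
  counts <- round(sim$freq * sim$n)
  p <- stats::chisq.test(counts, p = c(1, 2, 1) / 4)$p.value
  expect_gt(p, 0.001)
})

test_that("expression follows the additive zero-noise closed forms", {
  cfg <- tiny_config(noise_sd_log2 = 0, het_null_fraction = 0.2,
                     mesenchyme_module_size = 0)
  co <- simulate_cross(cfg)
  genes <- co$genes
  ctrl <- co$samples[co$samples$treatment == "control", ]
  m <- as.matrix(co$expr[, ctrl$sample])
  rownames(m) <- co$expr$gene

  # hom-functional = baseline, het = baseline/2, hom-null = 0 (additivity)
  ng <- genes[genes$null_gene, ][1, ]
  gg <- co$geno[co$geno$variant_id == ng$variant_id &
                  co$geno$sample %in% ctrl$individual, ]
  dos <- stats::setNames(gg$a1 + gg$a2, gg$sample)
  vals <- m[ng$gene, ]
  expected <- ng$baseline_tpm * (2 - dos[ctrl$individual]) / 2
  expect_equal(unname(vals), unname(expected), tolerance = 1e-12)

  # het equals the exact midpoint of the homozygote classes
  if (any(dos == 1) && any(dos == 0) && any(dos == 2)) {
    v_by <- split(vals, dos[ctrl$individual])
    expect_equal(mean(v_by[["1"]]),
                 (mean(v_by[["0"]]) + mean(v_by[["2"]])) / 2,
                 tolerance = 1e-12)
  }

  # W genes are exactly 0 in male samples
  wg <- genes$gene[genes$chromosome == "W"]
  males <- co$samples$sample[co$samples$sex == "M"]
  expect_true(all(as.matrix(co$expr[co$expr$gene %in% wg, males]) == 0))
})

test_that("Z male/female ratios follow 2 / compensation factor", {
  for (f in c(1, 2)) {
    cfg <- tiny_config(noise_sd_log2 = 0, dosage_compensation_factor = f,
                       n_z_genes = 10, het_null_fraction = 0)
    co <- simulate_cross(cfg)
    sr <- sex_ratio_analysis(co$expr, co$samples, co$genes, n_boot = 0)
    expect_equal(unique(round(sr$per_gene$mf_ratio, 10)), 2 / f)
    expect_equal(sr$median_ratio, 2 / f, tolerance = 1e-10)
  }
})

test_that("the whole cohort simulation is deterministic", {
  a <- simulate_cross(tiny_config(seed = 99))
  b <- simulate_cross(tiny_config(seed = 99))
  expect_identical(a$expr, b$expr)
  expect_identical(a$geno, b$geno)
  expect_identical(a$samples, b$samples)
})
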