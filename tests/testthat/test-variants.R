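make_panel <- function(qual, gq_matrix) {
  n_var <- length(qual)
  n_s <- ncol(gq_matrix)
  vids <- sprintf("chr1:%d", seq_len(n_var))
  variants <- tibble::tibble(
    variant_id = vids, chrom = "chr1", pos = seq_len(n_var),
    ref = "A", alt = "T", qual = qual,
    gene = NA_character_, consequence = "other")
  geno <- tidyr::expand_grid(variant_id = vids,
                             sample = paste0("s", seq_len(n_s)))
  geno$a1 <- 0L
  geno$a2 <- 1L
  # expand_grid is variant-major: fill row v's qualities in one block
  geno$gq <- unlist(lapply(seq_len(n_var),
                           function(v) gq_matrix[v, ]))
  list(variants = variants, geno = geno)
}

test_that("filtration applies the quality and missingness rules", {
  # site quality 29.9 fails the >= 30 rule; exactly 30 passes
  p <- make_panel(c(29.9, 30), matrix(99, 2, 4))
  out <- filter_panel(p$geno, p$variants)
  expect_equal(out$variants$variant_id, "chr1:2")
  expect_equal(out$summary$n_fail_site_quality, 1L)

  # 5 of 20 genotypes masked (25% missing) vs 20% cap -> dropped
  gq <- matrix(99, 1, 20)
  gq[1, 1:5] <- 10
  p2 <- make_panel(100, gq)
  out2 <- filter_panel(p2$geno, p2$variants)
  expect_equal(out2$summary$n_out, 0L)
  expect_equal(out2$summary$n_fail_missing_rate, 1L)
  # exactly 20% missing passes (<= cap)
  gq[1, 5] <- 99
  out3 <- filter_panel(make_panel(100, gq)$geno, p2$variants)
  expect_equal(out3$summary$n_out, 1L)
  # masked calls are set missing in the surviving genotypes
  expect_equal(sum(is.na(out3$geno$a1)), 4L)
})

test_that("filtration matches hand enumeration on a mixed fixture", {
  # 10 variants: 2 fail site quality, 1 fails missingness, 7 survive
  gq <- matrix(99, 10, 10)
  gq[3, 1:3] <- 5          # 30% missing -> dropped
  gq[4, 1] <- 5            # 10% missing -> kept
  p <- make_panel(c(10, 29, rep(100, 8)), gq)
  out <- filter_panel(p$geno, p$variants)
  expect_equal(out$summary$n_in, 10L)
  expect_equal(out$summary$n_out, 7L)
  expect_setequal(out$variants$variant_id,
                  sprintf("chr1:%d", c(4:10)))
  # order independence: permuting rows yields the same surviving set
  perm <- sample(nrow(p$geno))
  out_p <- filter_panel(p$geno[perm, ], p$variants[sample(10), ])
  expect_setequal(out_p$variants$variant_id, out$variants$variant_id)
  # empty panel warns, does not fail
  expect_warning(filter_panel(p$geno[0, ], p$variants[0, ]), "empty")
})

test_that("consequence classification flags the HIGH-impact classes", {
  v <- tibble::tibble(
    variant_id = paste0("v", 1:8),
    consequence = c("stop_gained", "stop_lost", "start_lost",
                    "splice_acceptor_variant", "splice_donor",
                    "frameshift_variant", "missense_deleterious",
                    "synonymous_weirdness"))
  expect_warning(classify_consequences(v), "synonymous_weirdness")
  out <- suppressWarnings(classify_consequences(v))
  expect_equal(out$high_impact, c(rep(TRUE, 6), FALSE, FALSE))
  expect_equal(out$category[7], "missense_deleterious")
  expect_equal(out$category[8], "other")
  # unannotated record is "other" without drama
  out2 <- classify_consequences(
    tibble::tibble(variant_id = "x", consequence = NA))
  expect_false(out2$high_impact)
  tl <- attr(out, "tallies")
  expect_equal(sum(tl$n), 8L)
})

test_that("genotype class counts partition the samples", {
  # the candidate-null pattern: 0 hom-alt, 1 het, 18 hom-ref
  g <- geno_tbl("chr22:1281321", paste0("b", 1:19),
                a1 = c(0L, rep(0L, 18)), a2 = c(1L, rep(0L, 18)))
  cc <- genotype_class_counts(g)
  expect_equal(unlist(cc[, c("hom_alt", "het", "hom_ref", "missing")]),
               c(hom_alt = 0L, het = 1L, hom_ref = 18L, missing = 0L))

  # all-missing variant
  gm <- geno_tbl("v", paste0("s", 1:5), a1 = NA, a2 = NA)
  ccm <- genotype_class_counts(gm)
  expect_equal(ccm$missing, 5L)
  expect_equal(ccm$hom_alt + ccm$het + ccm$hom_ref, 0L)

  # random fixture vs brute-force tally; counts always partition samples
  set.seed(1)
  a1 <- sample(c(0L, 1L, NA), 50, replace = TRUE)
  a2 <- ifelse(is.na(a1), NA, sample(c(0L, 1L), 50, replace = TRUE))
  gr <- geno_tbl("v", paste0("s", 1:50), a1, a2)
  cc2 <- genotype_class_counts(gr)
  expect_equal(cc2$hom_alt, sum(!is.na(a1) & a1 == 1 & a2 == 1))
  expect_equal(cc2$het, sum(!is.na(a1) & a1 + a2 == 1))
  expect_equal(cc2$hom_ref, sum(!is.na(a1) & a1 == 0 & a2 == 0))
  expect_equal(cc2$hom_alt + cc2$het + cc2$hom_ref + cc2$hemi +
                 cc2$missing, 50L)
})

test_that("breed frequency contrasts and fixation flags are exact", {
  samples <- paste0("s", 1:10)
  breeds <- tibble::tibble(sample = samples,
                           breed = rep(c("broiler", "layer"), each = 5))
  # breed1 all hom-alt, breed2 all hom-ref
  g <- geno_tbl("v1", samples, a1 = rep(c(1L, 0L), each = 5),
                a2 = rep(c(1L, 0L), each = 5))
  fr <- breed_frequency_contrast(g, breeds)
  expect_equal(fr$af_breed1, 1)
  expect_equal(fr$af_breed2, 0)
  expect_equal(fr$delta, 1)
  expect_true(fr$near_fixed_opposite)

  # a single het among 5 birds -> af 0.1
  g2 <- geno_tbl("v2", samples, a1 = c(1L, rep(0L, 9)), a2 = 0L)
  fr2 <- breed_frequency_contrast(g2, breeds)
  expect_equal(fr2$af_breed1, 0.1)

  # all-missing breed flagged undefined
  g3 <- geno_tbl("v3", samples, a1 = c(rep(NA, 5), rep(1L, 5)),
                 a2 = c(rep(NA, 5), rep(1L, 5)))
  fr3 <- breed_frequency_contrast(g3, breeds)
  expect_true(fr3$undefined)
  expect_false(fr3$near_fixed_opposite)

  # simulator ground truth: flagged fraction tracks breed_fixed_fraction
  cfg <- tiny_config(breed_fixed_fraction = 0.3, het_null_fraction = 0,
                     n_neutral_variants = 200, n_founders_per_breed = 8)
  fs <- simulate_founders(cfg)
  bt <- fs$individuals[, c("id", "breed")]
  names(bt) <- c("sample", "breed")
  auto <- fs$variants$variant_id[!fs$variants$chrom %in% c("chrZ", "chrW")]
  frs <- breed_frequency_contrast(
    fs$geno[fs$geno$variant_id %in% auto, ], bt)
  frac <- mean(frs$near_fixed_opposite)
  # 0.3 of eligible loci are planted fixed (plus the trans locus);
  # non-fixed loci can fix by chance only negligibly often
  expect_gt(frac, 0.25)
  expect_lt(frac, 0.36)
})

test_that("genotype PCA separates constructed divergent breeds", {
  cfg <- tiny_config(breed_fixed_fraction = 1, het_null_fraction = 0,
                     n_z_genes = 0, n_w_genes = 0)
  fs <- simulate_founders(cfg)
  pca <- genotype_pca(fs$geno)
  breeds <- fs$individuals[, c("id", "breed")]
  names(breeds) <- c("sample", "breed")
  s <- dplyr::inner_join(pca$scores, breeds, by = "sample")
  r_br <- range(s$PC1[s$breed == "broiler"])
  r_la <- range(s$PC1[s$breed == "layer"])
  expect_true(r_br[2] < r_la[1] || r_la[2] < r_br[1])

  # identical samples get identical coordinates
  g <- dplyr::bind_rows(
    geno_tbl(rep(paste0("v", 1:4), each = 3),
             rep(c("a", "b", "c"), 4),
             a1 = rep(c(0L, 0L, 1L), 4), a2 = rep(c(0L, 1L, 1L), 4)))
  p2 <- genotype_pca(g, k = 2)
  expect_equal(p2$scores$PC1[p2$scores$sample == "a"],
               p2$scores$PC1[p2$scores$sample == "a"])
  # k larger than allowed is reduced with a warning
  expect_warning(genotype_pca(g, k = 5), "reducing")
  # a constant variant contributes nothing: scores unchanged if added
  g_const <- dplyr::bind_rows(g, geno_tbl("vc", c("a", "b", "c"),
                                          a1 = 1L, a2 = 1L))
  p3 <- suppressWarnings(genotype_pca(g_const, k = 2))
  expect_equal(abs(p3$scores$PC1), abs(p2$scores$PC1), tolerance = 1e-10)
})
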