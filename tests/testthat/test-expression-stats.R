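test_that("expression filter keeps genes at or above 10 TPM max", {
  expr <- expr_tbl(rbind(g_low = c(9.99, 9.5), g_edge = c(10, 0),
                         g_high = c(100, 3)))
  kept <- filter_expressed(expr)
  expect_setequal(kept$gene, c("g_edge", "g_high"))

  # retained set equals a brute-force scan on a random fixture
  set.seed(4)
  m <- matrix(stats::rexp(100 * 6, rate = 0.05), 100)
  e2 <- expr_tbl(m)
  want <- e2$gene[apply(m, 1, max) >= 10]
  expect_setequal(filter_expressed(e2)$gene, want)
})

test_that("max/min ratios behave at the boundaries and on known spreads", {
  expr <- expr_tbl(rbind(constant = c(7, 7, 7),
                         avidin_like = c(5, 121, 40),
                         vanishing = c(0, 12, 30)))
  mm <- max_min_ratio(expr)
  expect_equal(mm$ratio[mm$gene == "constant"], 1)
  expect_equal(mm$ratio[mm$gene == "avidin_like"], 24.2)
  expect_identical(mm$ratio[mm$gene == "vanishing"], Inf)
  expect_equal(mm$max[mm$gene == "vanishing"], 30)
  expect_equal(mm$min[mm$gene == "vanishing"], 0)
  # statistics are invariant to sample and gene order
  mm2 <- max_min_ratio(expr[c(3, 1, 2), c(1, 4, 2, 3)])
  expect_equal(mm2[match(mm$gene, mm2$gene), ]$ratio, mm$ratio)
})

test_that("housekeeping-like noise gives the order-statistic ratio regime", {
  # n iid log-normal draws: E[log2 max/min] = sd * E[range of n std
  # normals]; for sd = 0.1 log2-units and n = 18 the expected ratio is
  # 2^(0.1 * 3.58) ~ 1.28, squarely in the 1.3-1.6 reference-gene regime
  # once sampling spread is included
  set.seed(11)
  n <- 18
  m <- matrix(100 * 2 ^ stats::rnorm(200 * n, 0, 0.1), nrow = 200)
  mm <- max_min_ratio(expr_tbl(m))
  med <- stats::median(mm$ratio)
  d2 <- mean(apply(matrix(stats::rnorm(2000 * n), ncol = n), 1,
                   function(z) diff(range(z))))
  expect_equal(med, 2 ^ (0.1 * d2), tolerance = 0.05)
  expect_gt(med, 1.2)
  expect_lt(med, 1.6)
})

test_that("extreme-variation sets partition exactly", {
  # identical matrices: everything shared
  m <- rbind(q1 = c(25, 0.5), q2 = c(50, 0.2), n1 = c(25, 5))
  e <- expr_tbl(m)
  ev <- extreme_variation_sets(e, e)
  expect_setequal(ev$shared, c("q1", "q2"))
  expect_length(ev$control_only, 0)

  # planted disjoint qualifiers: 10 control-only, 10 lps-only
  base <- matrix(10, 20, 4)
  mc <- base; ml <- base
  mc[1:10, 1] <- 30; mc[1:10, 2] <- 0.1
  ml[11:20, 1] <- 30; ml[11:20, 2] <- 0.1
  rn <- paste0("g", 1:20)
  ev2 <- extreme_variation_sets(expr_tbl(mc, rn), expr_tbl(ml, rn))
  expect_equal(ev2$summary$n, c(10L, 10L, 0L))
  expect_equal(ev2$union_n, 20L)
  expect_equal(ev2$summary$pct, c(50, 50, 0))

  # random fixture equals brute-force set algebra
  set.seed(9)
  rmc <- matrix(stats::rexp(60 * 5, 0.03), 60)
  rml <- matrix(stats::rexp(60 * 5, 0.03), 60)
  rn2 <- paste0("r", 1:60)
  ev3 <- extreme_variation_sets(expr_tbl(rmc, rn2), expr_tbl(rml, rn2))
  qc <- rn2[apply(rmc, 1, max) > 20 & apply(rmc, 1, min) < 1]
  ql <- rn2[apply(rml, 1, max) > 20 & apply(rml, 1, min) < 1]
  expect_setequal(ev3$shared, intersect(qc, ql))
  expect_setequal(ev3$control_only, setdiff(qc, ql))
  expect_setequal(ev3$lps_only, setdiff(ql, qc))

  expect_error(extreme_variation_sets(expr_tbl(mc, rn),
                                      expr_tbl(ml, paste0("x", 1:20))),
               "universes differ")
})

test_that("dosage grouping recovers exact additive classes", {
  # planted per-copy effects (5, 0): classes 0 / 5 / 10, additivity 0
  v <- c(b1 = 0, b2 = 0, b3 = 5, b4 = 5, b5 = 10, b6 = 10)
  dg <- classify_dosage_groups(v)
  expect_equal(dg$k, 3L)
  expect_equal(dg$group_means, c(0, 5, 10))
  expect_equal(dg$additivity_score, 0)
  expect_equal(dg$null_group, 1L)
  expect_equal(dg$assignment$group[dg$assignment$sample == "b5"], 3L)

  # all equal -> one group
  expect_equal(classify_dosage_groups(rep(4, 6))$k, 1L)
  expect_error(classify_dosage_groups(c(1, 2, 3)), "at least 4")
})

test_that("noisy dosage grouping equals the exhaustive partition optimum", {
  set.seed(23)
  for (rep in 1:5) {
    dos <- sample(0:2, 12, replace = TRUE)
    truth_mean <- c(0, 12, 24)[dos + 1]
    vals <- truth_mean * 2 ^ stats::rnorm(12, 0, 0.2)
    vals[dos == 0] <- 0
    names(vals) <- paste0("s", 1:12)
    dg <- classify_dosage_groups(vals)
    oracle <- brute_force_dosage_partition(vals)
    expect_equal(dg$k, oracle$k)
    bounds <- c(0, oracle$cuts, length(vals))
    oracle_groups <- rep(seq_len(oracle$k), diff(bounds))
    got <- dg$assignment$group[order(dg$assignment$value)]
    expect_equal(got, oracle_groups)
  }
})

test_that("sex-ratio analysis has the closed-form and monotone behavior", {
  cfg <- tiny_config(noise_sd_log2 = 0, het_null_fraction = 0,
                     n_z_genes = 12)
  meds <- vapply(c(1, 4 / 3, 2), function(f) {
    c2 <- tiny_config(noise_sd_log2 = 0, het_null_fraction = 0,
                      n_z_genes = 12, dosage_compensation_factor = f)
    co <- simulate_cross(c2)
    sex_ratio_analysis(co$expr, co$samples, co$genes,
                       n_boot = 0)$median_ratio
  }, numeric(1))
  expect_equal(meds, c(2, 1.5, 1), tolerance = 1e-10)
  expect_true(all(diff(meds) < 0))   # monotone in the factor

  # bootstrap flag: a perfectly balanced gene is called compensated
  set.seed(2)
  m <- rbind(bal = c(stats::rnorm(6, 100, 5), stats::rnorm(6, 100, 5)),
             up = c(stats::rnorm(6, 200, 5), stats::rnorm(6, 100, 5)))
  e <- expr_tbl(m)
  samples <- tibble::tibble(sample = paste0("s", 1:12),
                            sex = rep(c("M", "F"), each = 6))
  gm <- tibble::tibble(gene = c("bal", "up"), chromosome = "Z")
  sr <- sex_ratio_analysis(e, samples, gm, n_boot = 300)
  expect_true(sr$per_gene$compensated[sr$per_gene$gene == "bal"])
  expect_false(sr$per_gene$compensated[sr$per_gene$gene == "up"])
  expect_error(sex_ratio_analysis(e, dplyr::mutate(samples, sex = "M"),
                                  gm), "single-sex")
})

test_that("LPS response counts use strict 2-fold boundaries and pairing", {
  samples <- tibble::tibble(
    sample = c("i1c", "i2c", "i1l", "i2l", "orphan"),
    individual = c("i1", "i2", "i1", "i2", "i9"),
    treatment = c("control", "control", "LPS", "LPS", "LPS"))
  # exact 2.0-fold after pseudocount: (mean_l + .5)/(mean_c + .5) = 2
  m <- rbind(edge = c(1.5, 1.5, 3.5, 3.5, 99),
             induced = c(10, 10, 80, 80, 99),
             repressed = c(80, 80, 10, 10, 99),
             flat = c(50, 50, 50, 50, 99))
  e <- expr_tbl(m, c("edge", "induced", "repressed", "flat"))
  names(e) <- c("gene", samples$sample)
  expect_warning(lps_response(e, samples), "orphan")
  lr <- suppressWarnings(lps_response(e, samples))
  pg <- lr$per_gene
  expect_equal(pg$status[pg$gene == "edge"], "unchanged")
  expect_equal(pg$status[pg$gene == "induced"], "induced")
  expect_equal(pg$status[pg$gene == "repressed"], "repressed")
  expect_equal(lr$n_induced, 1L)
  # identical matrices: nothing moves
  e0 <- e
  e0$i1l <- e0$i1c; e0$i2l <- e0$i2c
  lr0 <- suppressWarnings(lps_response(e0, samples))
  expect_equal(lr0$n_induced + lr0$n_repressed, 0L)
})

test_that("planted LPS genes are recovered exactly at zero noise", {
  cfg <- tiny_config(noise_sd_log2 = 0, het_null_fraction = 0,
                     mesenchyme_module_size = 0, trans_module_size = 0,
                     n_lps_induced = 10, n_lps_repressed = 6,
                     lps_log2fc_location = 3, lps_log2fc_scale = 0)
  co <- simulate_cross(cfg)
  lr <- lps_response(co$expr, co$samples)
  truth_ind <- co$genes$gene[co$genes$module == "lps_induced"]
  truth_rep <- co$genes$gene[co$genes$module == "lps_repressed"]
  pg <- lr$per_gene
  expect_setequal(pg$gene[pg$status == "induced"], truth_ind)
  expect_setequal(pg$gene[pg$status == "repressed"], truth_rep)
})

test_that("extreme-variation calls sit inside the expressed set", {
  co <- simulate_cross(tiny_config())
  expressed <- filter_expressed(co$expr)$gene
  ctrl <- co$samples$sample[co$samples$treatment == "control"]
  lps <- co$samples$sample[co$samples$treatment == "LPS"]
  ev <- extreme_variation_sets(co$expr[, c("gene", ctrl)],
                               co$expr[, c("gene", lps)])
  flagged <- c(ev$shared, ev$control_only, ev$lps_only)
  # max > 20 implies max >= 10, so flagged genes are all "expressed"
  expect_true(all(flagged %in% expressed))
})
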