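test_that("genotype encoding follows the genetic model", {
  expect_equal(encode_genotype(c(0, 1, 2), "additive"), c(0, 1, 2))
  expect_equal(encode_genotype(c(0, 1, 2), "recessive"), c(0, 0, 1))
  expect_true(is.na(encode_genotype(NA_real_, "recessive")))
  expect_error(encode_genotype(3, "additive"), "invalid")
})

test_that("residualized association equals full-design OLS to 1e-10", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    covars <- data.frame(
      sex = sample(c("f", "m"), n, replace = TRUE),
      ethnicity = sample(c("a", "b", "c"), n, replace = TRUE),
      site = sample(c("s1", "s2"), n, replace = TRUE))
    g <- rbinom(n, 2, 0.4)
    y <- 0.3 * g + (covars$sex == "m") * 0.5 + rnorm(n)
    rec <- linear_assoc(y, g, covars)
    fit <- lm(y ~ g + sex + ethnicity + site, data = covars)
    co <- summary(fit)$coefficients["g", ]
    expect_equal(rec$beta, unname(co["Estimate"]), tolerance = 1e-10)
    expect_equal(rec$t_stat, unname(co["t value"]), tolerance = 1e-10)
    expect_equal(rec$p, unname(co["Pr(>|t|)"]), tolerance = 1e-10)
    expect_equal(rec$df, unname(fit$df.residual))
  }
})

test_that("association degenerate cases are handled per contract", {
  set.seed(42)
  n <- 60
  g <- rbinom(n, 2, 0.5)
  y <- rnorm(n)
  # genotype collinear with a covariate copy of itself
  expect_error(linear_assoc(y, g, data.frame(gcopy = g)), "collinear")
  # rank-deficient covariates are named
  cov2 <- data.frame(a = rnorm(n))
  cov2$b <- 2 * cov2$a
  expect_error(linear_assoc(y, g, cov2), "b")
  # constant genotype is skipped with a reason
  rec <- linear_assoc(y, rep(1, n))
  expect_true(is.na(rec$p))
  expect_equal(rec$note, "constant genotype")
})

test_that("association p-values are uniform under the null", {
  set.seed(43)
  ps <- replicate(1000, {
    g <- rbinom(100, 2, 0.3)
    linear_assoc(rnorm(100), g)$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.02)
})

test_that("the slope is recovered at its simulated value", {
  set.seed(44)
  g <- rbinom(200, 2, 0.4)
  y <- 0.5 * g + rnorm(200, 0, 0.1)
  expect_equal(linear_assoc(y, g)$beta, 0.5, tolerance = 0.05)
})

test_that("targeted screen ranks a planted additive effect first", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_donors = 120, n_variants = 300, n_species = 30,
                      n_pathways = 2, related_pairs = c(),
                      zero_inflation = 0,
                      planted_variant_effects = data.frame(
                        variant = 10, feature = 1, model = "additive",
                        slope = 1.5),
                      seed = 1000 + s)
    co <- sim_cohort(cfg)
    sp <- log_transform(average_replicates(co$species))
    g <- encode_genotype(co$genotypes$dosages[, 10], "additive")
    names(g) <- co$genotypes$donors
    screen <- targeted_screen(sp, g, test = "regression")
    screen$feature[which.min(screen$q)] == "sp001"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("recessive t-test mode follows the two-group contract", {
  set.seed(45)
  Y <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  Y[, 1] <- 1 # identical values in both groups
  tab <- toy_transformed_table(Y)
  g <- rep(c(0, 1), 10)
  res <- targeted_screen(tab, g, test = "t_test")
  expect_equal(res$t_stat[res$feature == "f1"], 0)
  expect_equal(res$p[res$feature == "f1"], 1)
  # pooled Student's t matches stats::t.test with var.equal
  tt <- t.test(Y[g == 1, 2], Y[g == 0, 2], var.equal = TRUE)
  expect_equal(res$p[res$feature == "f2"], tt$p.value)
  # degenerate group sizes are skipped
  res2 <- targeted_screen(tab, c(1, rep(0, 19)), test = "t_test")
  expect_true(all(!is.na(res2$note)))
})

test_that("a null screen shows order-statistic behavior of the minimum p", {
  set.seed(46)
  min_ps <- replicate(60, {
    Y <- matrix(rnorm(80 * 30), 80, 30,
                dimnames = list(NULL, paste0("f", 1:30)))
    g <- rbinom(80, 2, 0.4)
    min(targeted_screen(toy_transformed_table(Y), g)$p)
  })
  # median of the minimum of 30 uniforms is about 1 - 0.5^(1/30)
  expect_lt(abs(median(min_ps) - (1 - 0.5^(1 / 30))), 0.015)
})

test_that("the scan conserves test cardinality and honors variant subsets", {
  set.seed(47)
  cfg <- sim_config(n_donors = 100, n_variants = 100, n_species = 20,
                    n_pathways = 2, related_pairs = c(),
                    zero_inflation = 0, seed = 12)
  co <- sim_cohort(cfg)
  sp <- log_transform(average_replicates(co$species))
  scan <- gwas_scan(co$genotypes, sp, maf_min = 0.01)
  v_kept <- dplyr::n_distinct(scan$id)
  expect_equal(nrow(scan), v_kept * 20)
  expect_equal(attr(scan, "n_tests"), nrow(scan))
  # restriction to a user-supplied subset returns exactly those variants
  sub <- co$genotypes$variants$id[c(5, 20, 40)]
  scan_sub <- gwas_scan(co$genotypes, sp, maf_min = 0.01,
                        variant_subset = sub)
  expect_setequal(unique(scan_sub$id), sub)
  expect_equal(nrow(scan_sub), 3 * 20)
  # donor mismatch is an explicit error
  bad <- sp
  bad$donor[1] <- "ghost"
  expect_error(gwas_scan(co$genotypes, bad), "ghost")
})

test_that("scan p-values are calibrated on null data", {
  set.seed(48)
  cfg <- sim_config(n_donors = 100, n_variants = 500, n_species = 100,
                    n_pathways = 2, related_pairs = c(),
                    zero_inflation = 0, seed = 13)
  co <- sim_cohort(cfg)
  sp <- log_transform(average_replicates(co$species))
  scan <- gwas_scan(co$genotypes, sp, maf_min = 0.05)
  expect_gt(attr(scan, "n_tests"), 40000)
  expect_lt(abs(mean(scan$p < 0.01) - 0.01), 0.005)
  expect_lt(abs(attr(qq_points(scan$p), "slope") - 1), 0.1)
})

test_that("Bonferroni thresholds divide alpha by the test count", {
  expect_equal(bonferroni_threshold(10, 0.05), 0.005)
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(1.66e10, 0.05), 3e-12, tolerance = 0.01)
  expect_error(bonferroni_threshold(0), "at least 1")
})

test_that("clumping groups by gap and picks minimum-p representatives", {
  rec <- tibble::tibble(pos = c(100, 5000, 20000),
                        p = c(0.01, 0.001, 0.02),
                        id = c("a", "b", "c"))
  cl <- clump_associations(rec, max_gap = 10000)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$id, c("b", "c"))
  expect_equal(cl$span_start, c(100, 20000))
  expect_equal(cl$n_members, c(2L, 1L))
  # a gap of exactly the maximum stays in one group
  cl2 <- clump_associations(tibble::tibble(pos = c(0, 10000),
                                           p = c(0.5, 0.4)))
  expect_equal(nrow(cl2), 1)
  # single record is its own representative
  cl3 <- clump_associations(tibble::tibble(pos = 7, p = 0.3))
  expect_equal(cl3$n_members, 1L)
  expect_error(clump_associations(tibble::tibble(pos = c(5, 1),
                                                 p = c(0.1, 0.2))),
               "sorted")
})

test_that("clumping partitions records per the exhaustive oracle", {
  set.seed(49)
  for (rep in 1:10) {
    k <- sample(2:20, 1)
    rec <- tibble::tibble(pos = sort(sample.int(100000, k)),
                          p = runif(k))
    cl <- clump_associations(rec, max_gap = 10000)
    members <- dplyr::bind_rows(cl$members)
    # every record in exactly one group
    expect_equal(sort(members$pos), rec$pos)
    for (i in seq_len(nrow(cl))) {
      g <- cl$members[[i]]
      expect_equal(cl$p[i], min(g$p)) # representative is the group minimum
      if (nrow(g) > 1) expect_true(all(diff(g$pos) <= 10000))
      if (i > 1) {
        expect_gt(min(g$pos) - max(cl$members[[i - 1]]$pos), 10000)
      }
    }
  }
})

test_that("gene annotation respects the 50-kb window arithmetic", {
  genes <- tibble::tibble(gene = "G1", chrom = "chrS",
                          start = 100000, end = 120000)
  near <- annotate_genes(tibble::tibble(chrom = "chrS", pos = 60000), genes)
  expect_equal(near$gene, "G1")
  expect_equal(near$distance, 40000)
  inside <- annotate_genes(tibble::tibble(chrom = "chrS", pos = 110000), genes)
  expect_equal(inside$distance, 0)
  far <- annotate_genes(tibble::tibble(chrom = "chrS", pos = 170001), genes)
  expect_equal(nrow(far), 0)
  at_edge <- annotate_genes(tibble::tibble(chrom = "chrS", pos = 170000), genes)
  expect_equal(at_edge$distance, 50000)
  other_chrom <- annotate_genes(tibble::tibble(chrom = "chr2", pos = 110000),
                                genes)
  expect_equal(nrow(other_chrom), 0)
})

test_that("QQ points use midpoint plotting positions", {
  one <- qq_points(0.5)
  expect_equal(one$expected, -log10(0.5))
  expect_equal(one$observed, -log10(0.5))
  ten <- qq_points(rep(1e-6, 10))
  expect_equal(ten$observed, rep(6, 10))
  expect_warning(clipped <- qq_points(c(0, 0.5)), "clipped")
  expect_true(all(is.finite(clipped$observed)))
})
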